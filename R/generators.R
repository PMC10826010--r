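#' Correlation alignment penalty
#'
#' The additive generator-loss term that penalizes the L1 disparity between
#' the intervariable correlation structure of the real and synthetic data:
#' \deqn{\lambda \sum_{i} \sum_{j < i} | \hat r_{ij} - r_{ij} |}
#' where \eqn{\hat r_{ij}} is the correlation between two synthetic variables
#' and \eqn{r_{ij}} its real counterpart. The sum runs over the strict lower
#' triangle; cells undefined on either side (zero-variance variables) are
#' excluded.
#'
#' @param real_assoc,synth_assoc Square association matrices with identical
#'   dimensions and variable order (plain matrices or
#'   [mixed_association_matrix()] results).
#' @param lambda_align Nonnegative alignment coefficient \eqn{\lambda}
#'   (default 10, the value used throughout training).
#' @return A single nonnegative number; 0 iff `lambda_align = 0` or the
#'   matrices agree on the (defined) lower triangle.
#' @examples
#' r <- diag(2); r[2, 1] <- r[1, 2] <- 0.5
#' s <- diag(2); s[2, 1] <- s[1, 2] <- 0.3
#' correlation_alignment_penalty(r, s, 10)  # 10 * |0.3 - 0.5| = 2
#' @export
correlation_alignment_penalty <- function(real_assoc, synth_assoc,
                                          lambda_align = 10) {
  R <- as_assoc_matrix(real_assoc)
  S <- as_assoc_matrix(synth_assoc)
  if (!identical(dim(R), dim(S))) {
    stop("association matrices must have the same shape", call. = FALSE)
  }
  if (lambda_align < 0) stop("lambda_align must be >= 0", call. = FALSE)
  D <- abs(S - R)
  lt <- lower.tri(D)
  lambda_align * sum(D[lt], na.rm = TRUE)
}

as_assoc_matrix <- function(x) {
  if (inherits(x, "stsg_assoc")) x$matrix else as.matrix(x)
}

## ---------------------------------------------------------------------------
## design matrices: dataset <-> numeric [0,1] matrix used by the backends

# encoding: "onehot" (WGAN-GP, baseline) or "label" (DGAN)
prepare_training <- function(d, encoding, mode) {
  validate_dataset(d, rectangular = !identical(mode, "metadata_only"))
  if (anyNA(d$static) || anyNA(d$series)) {
    stop("dataset contains missing values; run interpolate_missing() or ",
         "forward_fill() first", call. = FALSE)
  }
  schema0 <- d$schema
  if (any(d$schema$encoding == "none" & d$schema$kind == "categorical")) {
    d <- encode_categoricals(d, encoding)
  }
  sc <- scale_minmax(d)
  list(dataset = sc$dataset, scaling = sc$scaling, schema = schema0,
       encoded_schema = sc$dataset$schema)
}

# layout describes each design column so samples can be decoded again
design_static <- function(d) {
  cols <- character(0)
  for (v in dataset_static_vars(d)) {
    row <- schema_row(d$schema, v)
    cc <- variable_columns(d$schema, v)
    if (row$kind == "categorical" && row$encoding == "label") {
      k <- length(row$categories[[1]])
      d$static[[v]] <- if (k > 1) d$static[[v]] / (k - 1) else d$static[[v]] * 0
    }
    cols <- c(cols, cc)
  }
  X <- as.matrix(d$static[cols])
  storage.mode(X) <- "double"
  list(X = X, cols = cols)
}

design_series <- function(d) {
  T_ <- series_length(d)
  cols <- unlist(lapply(dataset_dynamic_vars(d), variable_columns,
                        schema = d$schema))
  mats <- lapply(cols, function(cn) {
    m <- series_matrix(d, cn)
    row_var <- sub("=.*$", "", cn)
    row <- schema_row(d$schema, row_var)
    if (row$kind == "categorical" && row$encoding == "label") {
      k <- length(row$categories[[1]])
      if (k > 1) m <- m / (k - 1)
    }
    m
  })
  list(X = do.call(cbind, mats), cols = cols, T = T_)
}

# invert a static design block into a decoded static tibble
decode_static <- function(M, layout, gen) {
  schema <- gen$schema  # original, unencoded
  out <- tibble::tibble(subject_id = sprintf("syn%05d", seq_len(nrow(M))))
  M <- pmin(pmax(M, 0), 1)
  for (v in schema_vars(schema, "static")) {
    row <- schema_row(schema, v)
    if (row$kind == "numeric") {
      x <- M[, match(v, layout$cols)]
      sc <- gen$scaling[gen$scaling$variable == v, ]
      out[[v]] <- if (nrow(sc)) x * (sc$max - sc$min) + sc$min else x
    } else {
      cats <- row$categories[[1]]
      if (gen$encoding == "onehot") {
        idx <- match(paste0(v, "=", cats), layout$cols)
        out[[v]] <- cats[max.col(M[, idx, drop = FALSE],
                                 ties.method = "first")]
      } else {
        code <- round(M[, match(v, layout$cols)] * (length(cats) - 1))
        out[[v]] <- cats[pmin(pmax(code, 0), length(cats) - 1) + 1L]
      }
    }
  }
  out
}

decode_series <- function(M, layout, gen, subject_ids) {
  schema <- gen$schema
  T_ <- layout$T
  n <- nrow(M)
  M <- pmin(pmax(M, 0), 1)
  series <- tibble::tibble(subject_id = rep(subject_ids, each = T_),
                           t = rep(seq_len(T_) - 1L, times = n))
  for (v in schema_vars(schema, "dynamic")) {
    row <- schema_row(schema, v)
    if (row$kind == "numeric") {
      j0 <- (match(v, layout$cols) - 1L) * T_
      m <- M[, j0 + seq_len(T_), drop = FALSE]
      sc <- gen$scaling[gen$scaling$variable == v, ]
      if (nrow(sc)) m <- m * (sc$max - sc$min) + sc$min
      series[[v]] <- as.vector(t(m))
    } else {
      cats <- row$categories[[1]]
      if (gen$encoding == "onehot") {
        vals <- matrix(NA_integer_, n, T_)
        for (tt in seq_len(T_)) {
          idx <- (match(paste0(v, "=", cats), layout$cols) - 1L) * T_ + tt
          vals[, tt] <- max.col(M[, idx, drop = FALSE], ties.method = "first")
        }
        series[[v]] <- cats[as.vector(t(vals))]
      } else {
        j0 <- (match(v, layout$cols) - 1L) * T_
        code <- round(M[, j0 + seq_len(T_), drop = FALSE] * (length(cats) - 1))
        series[[v]] <- cats[as.vector(t(pmin(pmax(code, 0),
                                             length(cats) - 1))) + 1L]
      }
    }
  }
  series
}

subset_schema <- function(schema, component) {
  sch <- schema[schema$component %in% component, , drop = FALSE]
  validate_schema(sch)
}

# assemble a decoded longitudinal_dataset (or static-only table) from design
# matrices; used by every backend's generate() method
assemble_sample <- function(gen, M_static, M_series) {
  if (gen$mode == "metadata_only") {
    st <- decode_static(M_static, gen$layout$static, gen)
    return(longitudinal_dataset(subset_schema(gen$schema, "static"), st,
                                tibble::tibble(subject_id = character(0),
                                               t = integer(0)),
                                time_unit = gen$time_unit))
  }
  sid <- sprintf("syn%05d", seq_len(nrow(M_series)))
  if (gen$mode == "series_only") {
    st <- tibble::tibble(subject_id = sid)
    sch <- subset_schema(gen$schema, "dynamic")
  } else {
    st <- decode_static(M_static, gen$layout$static, gen)
    st$subject_id <- sid
    sch <- gen$schema
  }
  se <- decode_series(M_series, gen$layout$series, gen, sid)
  longitudinal_dataset(sch, st, se, time_unit = gen$time_unit)
}

## ---------------------------------------------------------------------------
## configurations

#' Backend configurations
#'
#' `wgan_gp_config()` parameterizes the Wasserstein GAN with gradient penalty
#' and correlation-alignment loss; `dgan_config()` parameterizes the
#' DoppelGANger-style metadata-conditioned recurrent generator. Training
#' schedule defaults follow the reference setting for this family of models:
#' 5000 epochs, batch size 64, learning rate 0.001, five critic updates per
#' generator update, alignment coefficient 10 and gradient-penalty
#' coefficient 10. Network sizes (two hidden layers of 128 units, recurrent
#' state of 128, noise dimension 32) are package defaults.
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (64 suits cohorts of several hundred
#'   subjects; use smaller values for small cohorts).
#' @param critic_updates_per_gen Critic updates per generator update.
#' @param learning_rate Adam learning rate for all networks.
#' @param lambda_align Alignment coefficient \eqn{\lambda} on the correlation
#'   disparity term of the generator loss (0 disables it).
#' @param gp_coefficient Gradient-penalty coefficient.
#' @param noise_dim Latent dimension of the generator input.
#' @param hidden Hidden-layer widths of the generator and critic MLPs.
#' @param seed Integer seed making training bit-reproducible.
#' @return A config list of class `wgan_gp_config` / `dgan_config`.
#' @export
wgan_gp_config <- function(epochs = 5000, batch_size = 64,
                           critic_updates_per_gen = 5,
                           learning_rate = 0.001, lambda_align = 10,
                           gp_coefficient = 10, noise_dim = 32,
                           hidden = c(128, 128), seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, critic_updates_per_gen >= 1,
            learning_rate > 0, lambda_align >= 0, gp_coefficient >= 0,
            noise_dim >= 1, all(hidden >= 1))
  structure(as.list(environment()), class = "wgan_gp_config")
}

#' @rdname wgan_gp_config
#' @param S Records emitted per recurrent iteration (batch generation);
#'   must divide the padded series length — series are right-padded by
#'   repeating the last sample when T is not a multiple of S, and trimmed
#'   after generation.
#' @param rnn_hidden Recurrent state size.
#' @export
dgan_config <- function(S = 6, epochs = 5000, batch_size = 64,
                        learning_rate = 0.001, gp_coefficient = 10,
                        noise_dim = 32, hidden = c(128, 128),
                        rnn_hidden = 128, seed = 1L) {
  stopifnot(S >= 1, epochs >= 1, batch_size >= 1, learning_rate > 0,
            gp_coefficient >= 0, noise_dim >= 1, rnn_hidden >= 1)
  structure(as.list(environment()), class = "dgan_config")
}

new_generator <- function(backend, mode, fields) {
  structure(c(list(backend = backend, mode = mode), fields),
            class = "stsg_generator")
}

#' @export
print.stsg_generator <- function(x, ...) {
  cat(sprintf("<stsg_generator> backend = %s, mode = %s, trained on %d subjects\n",
              x$backend, x$mode, x$n_train))
  invisible(x)
}

## ---------------------------------------------------------------------------
## WGAN-GP

#' Train a WGAN-GP with correlation-alignment loss
#'
#' Adversarial training of a multilayer-perceptron generator against a
#' critic under the Wasserstein objective with gradient penalty. The
#' generator loss is
#' \deqn{L_G = -E[D(G(z))] + \lambda \sum_{i>j} |\hat r_{ij} - r_{ij}|}
#' where the alignment term compares batch-level Pearson correlations of the
#' numeric design columns between the synthetic and the real minibatch. The
#' critic is updated `critic_updates_per_gen` times per generator step with
#' the standard interpolated-sample gradient penalty.
#'
#' Categorical variables are onehot-encoded and all numeric variables
#' min-max scaled internally; the captured encoding and scaling state is
#' inverted on sampling, so [generate()] returns data in original units.
#'
#' @param d A complete (no missing values), rectangular
#'   `longitudinal_dataset`.
#' @param config A [wgan_gp_config()].
#' @param mode `"joint"` (metadata + flattened series), `"metadata_only"`
#'   (static table alone, e.g. after [augment_metadata()]), or
#'   `"series_only"`.
#' @return An `stsg_generator` with a per-step loss trace (`$trace`:
#'   epoch, step, critic and generator losses, alignment penalty).
#' @export
train_wgan_gp <- function(d, config = wgan_gp_config(),
                          mode = c("joint", "metadata_only", "series_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "wgan_gp_config"))
  if (n_subjects(d) == 0) stop("empty dataset", call. = FALSE)
  prep <- prepare_training(d, "onehot", mode)
  dd <- prep$dataset

  lay_static <- if (mode != "series_only") design_static(dd) else NULL
  lay_series <- if (mode != "metadata_only") design_series(dd) else NULL
  X <- cbind(if (!is.null(lay_static)) lay_static$X,
             if (!is.null(lay_series)) lay_series$X)
  n <- nrow(X); p <- ncol(X)
  # alignment acts on numeric columns (onehot indicators carry no Pearson
  # structure worth aligning); indicator columns are excluded
  is_onehot <- c(
    if (!is.null(lay_static)) grepl("=", lay_static$cols, fixed = TRUE),
    if (!is.null(lay_series)) rep(grepl("=", lay_series$cols, fixed = TRUE),
                                  each = lay_series$T)
  )
  num_idx <- which(!is_onehot)

  b <- min(config$batch_size, n)
  steps <- max(1L, n %/% b)

  with_seed(config$seed, {
    G <- nn_new(c(config$noise_dim, config$hidden, p),
                hidden_act = "relu", out_act = "sigmoid")
    D <- nn_new(c(p, config$hidden, 1),
                hidden_act = "lrelu", out_act = "linear")
    oG <- adam_new(G); oD <- adam_new(D)
    trace <- vector("list", config$epochs * steps)
    step_id <- 0L

    for (ep in seq_len(config$epochs)) {
      for (st in seq_len(steps)) {
        step_id <- step_id + 1L
        closs <- NA_real_
        for (cu in seq_len(config$critic_updates_per_gen)) {
          Xr <- X[sample.int(n, b, replace = (b > n)), , drop = FALSE]
          Z <- matrix(stats::rnorm(b * config$noise_dim), b)
          Xf <- nn_forward(G, Z, keep_cache = FALSE)
          fwd_f <- nn_forward(D, Xf); fwd_r <- nn_forward(D, Xr)
          g <- nn_add_grads(
            nn_backward(D, fwd_f, matrix(1 / b, b, 1)),
            nn_backward(D, fwd_r, matrix(1 / b, b, 1)), scale = -1)
          eps_i <- stats::runif(b)
          Xi <- eps_i * Xr + (1 - eps_i) * Xf
          gp <- nn_gp_grads(D, Xi)
          g <- nn_add_grads(g, gp, scale = config$gp_coefficient)
          upd <- adam_step(D, oD, g, config$learning_rate)
          D <- upd$net; oD <- upd$opt
          closs <- mean(fwd_f$out) - mean(fwd_r$out) +
            config$gp_coefficient * gp$loss
        }

        Z <- matrix(stats::rnorm(b * config$noise_dim), b)
        fwdG <- nn_forward(G, Z)
        Xf <- fwdG$out
        ig <- nn_input_grad(D, Xf)
        dXf <- -ig$G / b
        Xr <- X[sample.int(n, b, replace = (b > n)), , drop = FALSE]
        Rr <- batch_pearson(Xr[, num_idx, drop = FALSE])$R
        ap <- align_penalty_grad(Xf[, num_idx, drop = FALSE], Rr,
                                 config$lambda_align)
        dXf[, num_idx] <- dXf[, num_idx] + ap$grad
        gG <- nn_backward(G, fwdG, dXf)
        upd <- adam_step(G, oG, gG, config$learning_rate)
        G <- upd$net; oG <- upd$opt
        gloss <- -mean(ig$out) + ap$value

        if (!is.finite(closs) || !is.finite(gloss)) {
          stop("divergence: non-finite loss at step ", step_id, call. = FALSE)
        }
        trace[[step_id]] <- c(epoch = ep, step = step_id,
                              critic_loss = closs, gen_loss = gloss,
                              align_penalty = ap$value)
      }
    }

    new_generator("wgan_gp", mode, list(
      G = G, D = D, config = config, schema = prep$schema,
      encoded_schema = prep$encoded_schema, scaling = prep$scaling,
      encoding = "onehot",
      layout = list(static = lay_static, series = lay_series),
      n_train = n, time_unit = d$time_unit,
      trace = tibble::as_tibble(do.call(rbind, trace))
    ))
  })
}

## ---------------------------------------------------------------------------
## DGAN (DoppelGANger-style)

#' Train a metadata-conditioned recurrent GAN
#'
#' The generator first produces the metadata component with an MLP, then
#' conditions a recurrent network on it at every step to produce the series,
#' emitting `S` consecutive records per recurrent iteration (batch
#' generation, capturing longer-range effects with T/S iterations). Two
#' critics judge the output: an auxiliary critic on the metadata alone and a
#' combined critic on metadata plus series, both trained with gradient
#' penalty. Categoricals are label-encoded (scaled integer codes), the
#' model-specific requirement of this architecture.
#'
#' When T is not a multiple of `S`, series are right-padded by repeating the
#' final sample and the padding is trimmed from generated output.
#'
#' @param d A complete, rectangular `longitudinal_dataset`.
#' @param config A [dgan_config()].
#' @param mode `"joint"` (default, the architecture's purpose) or
#'   `"metadata_only"` (trains only the metadata generator against the
#'   auxiliary critic).
#' @return An `stsg_generator` with per-step losses of both critics.
#' @export
train_dgan <- function(d, config = dgan_config(),
                       mode = c("joint", "metadata_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "dgan_config"))
  if (n_subjects(d) == 0) stop("empty dataset", call. = FALSE)
  prep <- prepare_training(d, "label", mode)
  dd <- prep$dataset

  lay_static <- design_static(dd)
  dm <- ncol(lay_static$X)
  config$S <- as.integer(config$S)
  if (mode == "joint") {
    lay_series <- design_series(dd)
    T_ <- lay_series$T
    pdyn <- length(lay_series$cols)
    n_it <- as.integer(ceiling(T_ / config$S))
    T_pad <- n_it * config$S
    Y <- lay_series$X
    if (T_pad > T_) {  # right-pad by repeating the last sample
      Yp <- matrix(0, nrow(Y), pdyn * T_pad)
      for (v in seq_len(pdyn)) {
        blk <- Y[, (v - 1) * T_ + seq_len(T_), drop = FALSE]
        Yp[, (v - 1) * T_pad + seq_len(T_pad)] <-
          cbind(blk, blk[, rep(T_, T_pad - T_), drop = FALSE])
      }
      Y <- Yp
    }
    # chunk index map: iteration it, chunk column (s-1)*pdyn + v  <->
    # padded series column (v-1)*T_pad + (it-1)*S + s
    chunk_idx <- lapply(seq_len(n_it), function(it) {
      as.vector(vapply(seq_len(config$S), function(s) {
        (seq_len(pdyn) - 1L) * T_pad + (it - 1L) * config$S + s
      }, integer(pdyn)))
    })
  } else {
    lay_series <- NULL; Y <- NULL; n_it <- 0L; T_pad <- 0L; pdyn <- 0L
  }

  n <- nrow(lay_static$X)
  b <- min(config$batch_size, n)
  steps <- max(1L, n %/% b)
  nz <- config$noise_dim

  with_seed(config$seed, {
    Gm <- nn_new(c(nz, config$hidden, dm), hidden_act = "relu",
                 out_act = "sigmoid")
    Da <- nn_new(c(dm, config$hidden, 1), hidden_act = "lrelu",
                 out_act = "linear")
    oGm <- adam_new(Gm); oDa <- adam_new(Da)
    if (mode == "joint") {
      H <- config$rnn_hidden
      rnn <- list(
        Wx = matrix(stats::rnorm((nz + dm) * H, 0, sqrt(1 / (nz + dm))),
                    nz + dm, H),
        Wh = matrix(stats::rnorm(H * H, 0, sqrt(1 / H)), H, H),
        bh = rep(0, H),
        Wo = matrix(stats::rnorm(H * config$S * pdyn, 0, sqrt(1 / H)),
                    H, config$S * pdyn),
        bo = rep(0, config$S * pdyn)
      )
      rnn_nets <- list(W = rnn[c("Wx", "Wh", "Wo")],
                       b = rnn[c("bh", "bo")])
      oR <- adam_new(rnn_nets)
      Dc <- nn_new(c(dm + pdyn * T_pad, config$hidden, 1),
                   hidden_act = "lrelu", out_act = "linear")
      oDc <- adam_new(Dc)
    }

    rnn_generate <- function(rn, meta, Zs) {
      # Zs: list of n_it noise matrices (b x nz)
      bs <- nrow(meta)
      h <- matrix(0, bs, H)
      Hs <- vector("list", n_it); Us <- vector("list", n_it)
      Os <- vector("list", n_it)
      Yf <- matrix(0, bs, pdyn * T_pad)
      for (it in seq_len(n_it)) {
        U <- cbind(Zs[[it]], meta)
        zh <- sweep(U %*% rn$W$Wx + h %*% rn$W$Wh, 2, rn$b$bh, "+")
        h <- tanh(zh)
        zo <- sweep(h %*% rn$W$Wo, 2, rn$b$bo, "+")
        O <- 1 / (1 + exp(-pmin(pmax(zo, -30), 30)))
        Yf[, chunk_idx[[it]]] <- O
        Hs[[it]] <- h; Us[[it]] <- U; Os[[it]] <- O
      }
      list(Y = Yf, Hs = Hs, Us = Us, Os = Os)
    }

    rnn_backward <- function(rn, cache, dY, meta) {
      bs <- nrow(meta)
      gWx <- rn$W$Wx * 0; gWh <- rn$W$Wh * 0; gWo <- rn$W$Wo * 0
      gbh <- rn$b$bh * 0; gbo <- rn$b$bo * 0
      dmeta <- matrix(0, bs, dm)
      dh_next <- matrix(0, bs, H)
      for (it in rev(seq_len(n_it))) {
        O <- cache$Os[[it]]
        dzo <- dY[, chunk_idx[[it]], drop = FALSE] * O * (1 - O)
        gWo <- gWo + crossprod(cache$Hs[[it]], dzo)
        gbo <- gbo + colSums(dzo)
        dh <- dzo %*% t(rn$W$Wo) + dh_next
        dzh <- dh * (1 - cache$Hs[[it]]^2)
        hprev <- if (it > 1) cache$Hs[[it - 1]] else matrix(0, bs, H)
        gWx <- gWx + crossprod(cache$Us[[it]], dzh)
        gWh <- gWh + crossprod(hprev, dzh)
        gbh <- gbh + colSums(dzh)
        dh_next <- dzh %*% t(rn$W$Wh)
        dU <- dzh %*% t(rn$W$Wx)
        dmeta <- dmeta + dU[, nz + seq_len(dm), drop = FALSE]
      }
      list(grads = list(gW = list(gWx, gWh, gWo), gb = list(gbh, gbo)),
           dmeta = dmeta)
    }

    critic_update <- function(Dnet, oD, Xr, Xf) {
      bs <- nrow(Xr)
      fwd_f <- nn_forward(Dnet, Xf); fwd_r <- nn_forward(Dnet, Xr)
      g <- nn_add_grads(nn_backward(Dnet, fwd_f, matrix(1 / bs, bs, 1)),
                        nn_backward(Dnet, fwd_r, matrix(1 / bs, bs, 1)),
                        scale = -1)
      eps_i <- stats::runif(bs)
      gp <- nn_gp_grads(Dnet, eps_i * Xr + (1 - eps_i) * Xf)
      g <- nn_add_grads(g, gp, scale = config$gp_coefficient)
      upd <- adam_step(Dnet, oD, g, config$learning_rate)
      list(net = upd$net, opt = upd$opt,
           loss = mean(fwd_f$out) - mean(fwd_r$out) +
             config$gp_coefficient * gp$loss)
    }

    trace <- vector("list", config$epochs * steps)
    step_id <- 0L
    for (ep in seq_len(config$epochs)) {
      for (st in seq_len(steps)) {
        step_id <- step_id + 1L
        idx <- sample.int(n, b, replace = (b > n))
        Mr <- lay_static$X[idx, , drop = FALSE]

        Zm <- matrix(stats::rnorm(b * nz), b)
        fwdm <- nn_forward(Gm, Zm)
        Mf <- fwdm$out
        if (mode == "joint") {
          Zs <- lapply(seq_len(n_it), function(i) matrix(stats::rnorm(b * nz), b))
          gen <- rnn_generate(list(W = rnn_nets$W, b = rnn_nets$b), Mf, Zs)
          names(gen$Hs) <- NULL
          Yr <- Y[idx, , drop = FALSE]
        }

        ua <- critic_update(Da, oDa, Mr, Mf)
        Da <- ua$net; oDa <- ua$opt
        if (mode == "joint") {
          uc <- critic_update(Dc, oDc, cbind(Mr, Yr), cbind(Mf, gen$Y))
          Dc <- uc$net; oDc <- uc$opt
        }

        # generator step (fresh noise)
        Zm <- matrix(stats::rnorm(b * nz), b)
        fwdm <- nn_forward(Gm, Zm)
        Mf <- fwdm$out
        dM <- -nn_input_grad(Da, Mf)$G / b
        gloss <- -mean(nn_forward(Da, Mf, keep_cache = FALSE))
        if (mode == "joint") {
          Zs <- lapply(seq_len(n_it), function(i) matrix(stats::rnorm(b * nz), b))
          rn <- list(W = rnn_nets$W, b = rnn_nets$b)
          names(rn$W) <- c("Wx", "Wh", "Wo"); names(rn$b) <- c("bh", "bo")
          gen <- rnn_generate(rn, Mf, Zs)
          Xc <- cbind(Mf, gen$Y)
          igc <- nn_input_grad(Dc, Xc)
          gloss <- gloss - mean(igc$out)
          dM <- dM - igc$G[, seq_len(dm), drop = FALSE] / b
          dY <- -igc$G[, dm + seq_len(pdyn * T_pad), drop = FALSE] / b
          bw <- rnn_backward(rn, gen, dY, Mf)
          upd <- adam_step(rnn_nets, oR, bw$grads, config$learning_rate)
          rnn_nets <- upd$net; oR <- upd$opt
          dM <- dM + bw$dmeta
        }
        gGm <- nn_backward(Gm, fwdm, dM)
        upd <- adam_step(Gm, oGm, gGm, config$learning_rate)
        Gm <- upd$net; oGm <- upd$opt

        aux_loss <- ua$loss
        comb_loss <- if (mode == "joint") uc$loss else NA_real_
        if (!is.finite(aux_loss) || !is.finite(gloss) ||
            (mode == "joint" && !is.finite(comb_loss))) {
          stop("divergence: non-finite loss at step ", step_id, call. = FALSE)
        }
        trace[[step_id]] <- c(epoch = ep, step = step_id,
                              aux_critic_loss = aux_loss,
                              comb_critic_loss = comb_loss,
                              gen_loss = gloss)
      }
    }

    fields <- list(
      Gm = Gm, Da = Da, config = config, schema = prep$schema,
      encoded_schema = prep$encoded_schema, scaling = prep$scaling,
      encoding = "label",
      layout = list(static = lay_static, series = lay_series),
      n_train = n, time_unit = d$time_unit, n_it = n_it, T_pad = T_pad,
      pdyn = pdyn,
      trace = tibble::as_tibble(do.call(rbind, trace))
    )
    if (mode == "joint") {
      fields$rnn <- rnn_nets
      fields$Dc <- Dc
      fields$chunk_idx <- chunk_idx
    }
    new_generator("dgan", if (mode == "joint") "joint" else "metadata_only",
                  fields)
  })
}

## ---------------------------------------------------------------------------
## baseline

#' Train the resampling baseline generator
#'
#' A fast deterministic stand-in for the adversarial backends: sampling
#' resamples real subjects and adds seeded Gaussian jitter (scale `jitter`
#' times the per-variable standard deviation) to numeric values. With
#' `jitter = 0` every sampled record is an exact copy of a real record; in
#' the special case `jitter = 0` and `n` equal to the training size,
#' [generate()] returns the training records themselves in original order,
#' so copy-case oracles (correlation similarity 1, zero autocorrelation
#' error) hold exactly. Because it is unconditionally fast and its expected
#' behaviour is known in closed form, it serves as the end-to-end oracle for
#' the evaluation pipeline and as a lightweight backend for large sweeps.
#'
#' @param d A complete, rectangular `longitudinal_dataset`.
#' @param jitter Nonnegative noise scale relative to each variable's SD.
#' @param seed Integer seed (stored; [generate()] takes its own seed).
#' @param mode `"joint"`, `"metadata_only"` or `"series_only"`.
#' @return An `stsg_generator`.
#' @export
train_baseline <- function(d, jitter = 0.05, seed = 1L,
                           mode = c("joint", "metadata_only", "series_only")) {
  mode <- match.arg(mode)
  stopifnot(jitter >= 0)
  validate_dataset(d, rectangular = (mode != "metadata_only"))
  if (anyNA(d$static) || anyNA(d$series)) {
    stop("dataset contains missing values; preprocess first", call. = FALSE)
  }
  sds <- list(
    static = vapply(schema_vars(d$schema, "static", "numeric"),
                    function(v) stats::sd(d$static[[v]]), numeric(1)),
    series = vapply(schema_vars(d$schema, "dynamic", "numeric"),
                    function(v) stats::sd(d$series[[v]]), numeric(1))
  )
  new_generator("baseline", mode, list(
    data = d, jitter = jitter, sds = sds, config = list(seed = seed),
    schema = d$schema, n_train = n_subjects(d), time_unit = d$time_unit,
    trace = tibble::tibble(epoch = 1L, step = 1L, gen_loss = 0)
  ))
}

## ---------------------------------------------------------------------------
## sampling

#' Draw synthetic records from a trained generator
#'
#' Applies the generator's captured inverse scaling and categorical decoding
#' (onehot by argmax), so output is in the original units and labels. Joint
#' and series modes return a `longitudinal_dataset`; metadata-only mode
#' returns a static-only dataset (empty series component).
#'
#' @param generator An `stsg_generator`.
#' @param n Number of synthetic subjects (> 0).
#' @param seed Integer seed for the sampling noise.
#' @return A `longitudinal_dataset`.
#' @export
generate <- function(generator, n, seed = 1L) {
  UseMethod("generate")
}

#' @export
generate.stsg_generator <- function(generator, n, seed = 1L) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  gen <- generator
  with_seed(seed, {
    if (gen$backend == "baseline") {
      return(baseline_sample(gen, n))
    }
    if (gen$backend == "wgan_gp") {
      Z <- matrix(stats::rnorm(n * gen$config$noise_dim), n)
      M <- nn_forward(gen$G, Z, keep_cache = FALSE)
      if (gen$mode == "metadata_only") {
        return(assemble_sample(gen, M, NULL))
      }
      if (gen$mode == "series_only") {
        return(assemble_sample(gen, NULL, M))
      }
      ps <- ncol(gen$layout$static$X)
      return(assemble_sample(gen, M[, seq_len(ps), drop = FALSE],
                             M[, -seq_len(ps), drop = FALSE]))
    }
    # dgan
    nz <- gen$config$noise_dim
    Mf <- nn_forward(gen$Gm, matrix(stats::rnorm(n * nz), n),
                     keep_cache = FALSE)
    if (gen$mode == "metadata_only") {
      return(assemble_sample(gen, Mf, NULL))
    }
    H <- gen$config$rnn_hidden
    h <- matrix(0, n, H)
    Yf <- matrix(0, n, gen$pdyn * gen$T_pad)
    for (it in seq_len(gen$n_it)) {
      U <- cbind(matrix(stats::rnorm(n * nz), n), Mf)
      h <- tanh(sweep(U %*% gen$rnn$W[[1]] + h %*% gen$rnn$W[[2]], 2,
                      gen$rnn$b[[1]], "+"))
      zo <- sweep(h %*% gen$rnn$W[[3]], 2, gen$rnn$b[[2]], "+")
      Yf[, gen$chunk_idx[[it]]] <- 1 / (1 + exp(-pmin(pmax(zo, -30), 30)))
    }
    # trim padding back to T
    T_ <- gen$layout$series$T
    if (gen$T_pad > T_) {
      keep <- as.vector(vapply(seq_len(gen$pdyn), function(v) {
        (v - 1L) * gen$T_pad + seq_len(T_)
      }, integer(T_)))
      Yf <- Yf[, keep, drop = FALSE]
    }
    assemble_sample(gen, Mf, Yf)
  })
}

baseline_sample <- function(gen, n) {
  d <- gen$data
  n0 <- n_subjects(d)
  idx <- if (gen$jitter == 0 && n == n0) seq_len(n0)
         else sample.int(n0, n, replace = TRUE)
  sid_new <- sprintf("syn%05d", seq_len(n))

  static <- d$static[idx, , drop = FALSE]
  static$subject_id <- sid_new
  T_ <- if (nrow(d$series)) series_length(d) else 0L
  series <- if (T_ > 0) {
    rows <- unlist(lapply(idx, function(i) (i - 1L) * T_ + seq_len(T_)))
    se <- d$series[rows, , drop = FALSE]
    se$subject_id <- rep(sid_new, each = T_)
    se
  } else {
    tibble::tibble(subject_id = character(0), t = integer(0))
  }

  if (gen$jitter > 0) {
    for (v in names(gen$sds$static)) {
      static[[v]] <- static[[v]] +
        stats::rnorm(n, 0, gen$jitter * gen$sds$static[[v]])
    }
    for (v in names(gen$sds$series)) {
      series[[v]] <- series[[v]] +
        stats::rnorm(nrow(series), 0, gen$jitter * gen$sds$series[[v]])
    }
  }

  if (gen$mode == "metadata_only") {
    longitudinal_dataset(subset_schema(d$schema, "static"),
                         static[c("subject_id",
                                  unlist(lapply(dataset_static_vars(d),
                                                variable_columns,
                                                schema = d$schema)))],
                         tibble::tibble(subject_id = character(0),
                                        t = integer(0)),
                         time_unit = d$time_unit)
  } else if (gen$mode == "series_only") {
    longitudinal_dataset(subset_schema(d$schema, "dynamic"),
                         tibble::tibble(subject_id = sid_new), series,
                         time_unit = d$time_unit)
  } else {
    longitudinal_dataset(d$schema, static, series, time_unit = d$time_unit)
  }
}
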