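# Shared model zoo for the data-labelling analysis (classification) and the
# TSTR/TRTR utility study (regression): random forest (100 trees, Gini),
# k-nearest neighbours (k = 10), decision tree (Gini), linear SVM (C = 100)
# and an MLP with hidden layers 64 + 32, relu activations, adam, batch 200,
# learning rate 0.001, at most 100 epochs. The MLP runs on the package's own
# dense-network engine. Features are z-scored (train statistics) for the
# scale-sensitive models (kNN, SVM, MLP).
#
# The libsvm backend behind e1071::svm has no iteration cap, so the
# 300-epoch SVM limit is not applicable there; cost and kernel are set.

ml_model_configs <- function() {
  tibble::tibble(
    model = c("rf", "knn", "dt", "svm", "mlp"),
    configuration = c(
      "number of trees: 100, split criterion: Gini index",
      "number of neighbors: 10",
      "split criterion: Gini index",
      "regularization parameter C: 100, kernel: linear, maximum epochs: 300",
      "hidden layers: 64 + 32, activation: relu, solver: adam, batch size: 200, learning rate: 0.001, maximum epochs: 100"
    )
  )
}

ml_scale_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-12)
  list(mu = mu, sd = sdv)
}
ml_scale_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

# own-engine MLP: binary classification (sigmoid + cross-entropy) or
# regression (linear + squared error)
mlp_fit <- function(X, y, task, seed, epochs = 100, batch = 200, lr = 0.001) {
  with_seed(seed, {
    n <- nrow(X)
    net <- nn_new(c(ncol(X), 64, 32, 1), hidden_act = "relu",
                  out_act = if (task == "class") "sigmoid" else "linear")
    opt <- adam_new(net)
    b <- min(batch, n)
    steps <- max(1L, n %/% b)
    for (ep in seq_len(epochs)) {
      idx_all <- sample.int(n)
      for (st in seq_len(steps)) {
        idx <- idx_all[((st - 1) * b + 1):(st * b)]
        fwd <- nn_forward(net, X[idx, , drop = FALSE])
        resid <- fwd$out - y[idx]  # gradient of both BCE (sigmoid) and MSE/2
        dOut <- if (task == "class") {
          # d BCE/d out for sigmoid output: (out - y) / (out (1 - out)); the
          # sigmoid factor cancels in nn_backward, so feed the quotient
          resid / pmax(fwd$out * (1 - fwd$out), 1e-8) / b
        } else {
          resid / b
        }
        g <- nn_backward(net, fwd, dOut)
        upd <- adam_step(net, opt, g, lr, beta1 = 0.9, beta2 = 0.999)
        net <- upd$net; opt <- upd$opt
      }
    }
    net
  })
}

mlp_predict <- function(net, X) as.numeric(nn_forward(net, X, FALSE))

# returns continuous scores for the positive class
ml_classify <- function(model, X_train, y_train, X_test, seed) {
  y_f <- factor(y_train, levels = c(0, 1))
  switch(model,
    rf = {
      fit <- with_seed(seed, randomForest::randomForest(
        x = X_train, y = y_f, ntree = 100))
      predict(fit, X_test, type = "prob")[, "1"]
    },
    knn = {
      st <- ml_scale_fit(X_train)
      fit <- caret::knn3(ml_scale_apply(X_train, st), y_f, k = 10)
      predict(fit, ml_scale_apply(X_test, st), type = "prob")[, "1"]
    },
    dt = {
      df <- data.frame(X_train); df$.y <- y_f
      fit <- rpart::rpart(.y ~ ., df, method = "class",
                          parms = list(split = "gini"))
      predict(fit, data.frame(X_test), type = "prob")[, "1"]
    },
    svm = {
      st <- ml_scale_fit(X_train)
      fit <- with_seed(seed, e1071::svm(
        ml_scale_apply(X_train, st), y_f, kernel = "linear", cost = 100,
        scale = FALSE))
      dv <- attr(predict(fit, ml_scale_apply(X_test, st),
                         decision.values = TRUE), "decision.values")
      # orient decision values towards class "1"
      if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
    },
    mlp = {
      st <- ml_scale_fit(X_train)
      net <- mlp_fit(ml_scale_apply(X_train, st), y_train, "class", seed)
      mlp_predict(net, ml_scale_apply(X_test, st))
    },
    stop("unknown classifier: ", model, call. = FALSE)
  )
}

ml_regress <- function(model, X_train, y_train, X_test, seed) {
  fit_err <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("regressor ", model, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  switch(model,
    rf = {
      fit <- fit_err(with_seed(seed, randomForest::randomForest(
        x = X_train, y = y_train, ntree = 100)))
      as.numeric(predict(fit, X_test))
    },
    knn = {
      st <- ml_scale_fit(X_train)
      fit <- fit_err(caret::knnreg(ml_scale_apply(X_train, st), y_train,
                                   k = 10))
      as.numeric(predict(fit, ml_scale_apply(X_test, st)))
    },
    dt = {
      df <- data.frame(X_train); df$.y <- y_train
      fit <- fit_err(rpart::rpart(.y ~ ., df, method = "anova"))
      as.numeric(predict(fit, data.frame(X_test)))
    },
    svm = {
      st <- ml_scale_fit(X_train)
      fit <- fit_err(with_seed(seed, e1071::svm(
        ml_scale_apply(X_train, st), y_train, kernel = "linear", cost = 100,
        scale = FALSE)))
      as.numeric(predict(fit, ml_scale_apply(X_test, st)))
    },
    mlp = {
      st <- ml_scale_fit(X_train)
      ys <- ml_scale_fit(matrix(y_train))
      net <- fit_err(mlp_fit(ml_scale_apply(X_train, st),
                             (y_train - ys$mu) / ys$sd, "regress", seed))
      mlp_predict(net, ml_scale_apply(X_test, st)) * ys$sd + ys$mu
    },
    stop("unknown regressor: ", model, call. = FALSE)
  )
}

# record tables: accept a longitudinal_dataset (flattened) or a data frame
record_matrix <- function(x, series_points = 8) {
  if (inherits(x, "longitudinal_dataset")) x <- flatten_records(x, series_points)
  x <- tibble::as_tibble(x)
  x$subject_id <- NULL
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}
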