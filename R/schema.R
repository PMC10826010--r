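#' Build a variable schema
#'
#' The schema is the single source of truth for variable typing throughout the
#' package: every column of the static (metadata) table and of the long-format
#' series table is declared here as numeric or categorical and as static
#' (one value per subject) or dynamic (one value per subject and time step).
#'
#' @param name Character vector of unique variable names.
#' @param kind `"numeric"` or `"categorical"`, recycled to `length(name)`.
#' @param component `"static"` or `"dynamic"`, recycled likewise.
#' @param categories List of character vectors giving the ordered category
#'   labels of each categorical variable (`NULL` entries for numeric ones).
#'   Label codes are assigned in this order (0-based), not in order of
#'   appearance in the data, so encodings are deterministic across files.
#' @param encoding Current encoding of each variable in the data:
#'   `"none"` (raw labels), `"label"` (integer codes) or `"onehot"`
#'   (indicator columns). Usually `"none"` at read time.
#'
#' @return A tibble with class `stsg_schema`, one row per variable.
#' @examples
#' variable_schema(
#'   name       = c("age", "sex", "HR"),
#'   kind       = c("numeric", "categorical", "numeric"),
#'   component  = c("static", "static", "dynamic"),
#'   categories = list(NULL, c("F", "M"), NULL)
#' )
#' @export
variable_schema <- function(name, kind, component,
                            categories = vector("list", length(name)),
                            encoding = "none") {
  sch <- tibble::tibble(
    name = as.character(name),
    kind = rep_len(as.character(kind), length(name)),
    component = rep_len(as.character(component), length(name)),
    categories = categories,
    encoding = rep_len(as.character(encoding), length(name))
  )
  validate_schema(sch)
}

validate_schema <- function(schema) {
  if (!all(c("name", "kind", "component", "categories", "encoding") %in%
        names(schema))) {
    stop("schema must have columns name, kind, component, categories, encoding",
         call. = FALSE)
  }
  if (anyDuplicated(schema$name)) {
    stop("schema variable names must be unique: ",
         paste(unique(schema$name[duplicated(schema$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(schema$kind %in% c("numeric", "categorical"))) {
    stop("schema kind must be 'numeric' or 'categorical'", call. = FALSE)
  }
  if (!all(schema$component %in% c("static", "dynamic"))) {
    stop("schema component must be 'static' or 'dynamic'", call. = FALSE)
  }
  if (!all(schema$encoding %in% c("none", "label", "onehot"))) {
    stop("schema encoding must be 'none', 'label' or 'onehot'", call. = FALSE)
  }
  bad <- schema$kind == "categorical" &
    vapply(schema$categories, function(x) length(x) == 0, logical(1))
  if (any(bad)) {
    stop("categorical variables need a non-empty category set: ",
         paste(schema$name[bad], collapse = ", "), call. = FALSE)
  }
  class(schema) <- unique(c("stsg_schema", class(schema)))
  schema
}

schema_vars <- function(schema, component = NULL, kind = NULL) {
  keep <- rep(TRUE, nrow(schema))
  if (!is.null(component)) keep <- keep & schema$component %in% component
  if (!is.null(kind)) keep <- keep & schema$kind %in% kind
  schema$name[keep]
}

schema_row <- function(schema, var) {
  i <- match(var, schema$name)
  if (is.na(i)) stop("unknown schema variable: ", var, call. = FALSE)
  schema[i, ]
}

#' Read and write schema files
#'
#' The on-disk schema format is a plain-text key/value block per variable:
#' ```
#' [age]
#' kind = numeric
#' component = static
#'
#' [sex]
#' kind = categorical
#' component = static
#' categories = F, M
#' ```
#'
#' @param path File path.
#' @param schema An `stsg_schema` tibble (for writing).
#' @return `read_schema()` returns an `stsg_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  header <- grepl("^\\[.+\\]$", lines)
  if (!any(header)) stop("no variable blocks found in schema file: ", path,
                         call. = FALSE)
  idx <- cumsum(header)
  blocks <- split(lines, idx)
  rows <- purrr::map(blocks, function(b) {
    nm <- sub("^\\[(.+)\\]$", "\\1", b[1])
    kv <- strsplit(b[-1], "=", fixed = TRUE)
    keys <- trimws(vapply(kv, `[`, "", 1))
    vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
    get <- function(k, default = NA_character_) {
      if (k %in% keys) vals[match(k, keys)] else default
    }
    cats <- get("categories")
    list(
      name = nm,
      kind = get("kind", "numeric"),
      component = get("component", "static"),
      categories = if (is.na(cats)) NULL else trimws(strsplit(cats, ",")[[1]]),
      encoding = get("encoding", "none")
    )
  })
  variable_schema(
    name = vapply(rows, `[[`, "", "name"),
    kind = vapply(rows, `[[`, "", "kind"),
    component = vapply(rows, `[[`, "", "component"),
    categories = unname(purrr::map(rows, "categories")),
    encoding = vapply(rows, `[[`, "", "encoding")
  )
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  schema <- validate_schema(schema)
  out <- purrr::pmap(schema, function(name, kind, component, categories,
                                      encoding) {
    b <- c(sprintf("[%s]", name),
           sprintf("kind = %s", kind),
           sprintf("component = %s", component))
    if (length(categories)) {
      b <- c(b, sprintf("categories = %s", paste(categories, collapse = ", ")))
    }
    if (!identical(encoding, "none")) {
      b <- c(b, sprintf("encoding = %s", encoding))
    }
    c(b, "")
  })
  writeLines(unlist(out), path)
  invisible(path)
}
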