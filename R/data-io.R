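#' Read or write a categorical survey dataset as CSV
#'
#' Datasets are plain tibbles whose columns are described by a [codebook()]:
#' indicator and covariate columns hold category *labels* (strings), the
#' weight column positive reals, and cluster/group columns arbitrary labels.
#' Missing entries are empty strings or `NA`.
#'
#' @param path CSV file path (header row, string categories).
#' @param cb A [codebook()] describing the columns.
#' @return `read_lca_data()` returns a validated tibble.
#' @export
read_lca_data <- function(path, cb) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""))
  validate_lca_data(tibble::as_tibble(df), cb)
}

#' @rdname read_lca_data
#' @param data A dataset tibble.
#' @export
write_lca_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a dataset against a codebook
#'
#' Checks that every codebook column is present, that all non-missing
#' categorical values are legal categories, that weights are positive, that
#' the group label is observed for every row, and that every row retains at
#' least one non-missing indicator.
#'
#' @inheritParams read_lca_data
#' @return The dataset, invisibly validated (with weight coerced to numeric).
#' @export
validate_lca_data <- function(data, cb) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(cb$name, names(data))
  if (length(missing_cols)) {
    abort_config(paste0("dataset lacks codebook columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  for (i in which(cb$role %in% c("indicator", "covariate"))) {
    v <- data[[cb$name[i]]]
    bad <- !is.na(v) & !(v %in% cb$categories[[i]])
    if (any(bad)) {
      abort_config(paste0("column ", cb$name[i], " has values outside its categories: ",
                          paste(utils::head(unique(v[bad]), 3), collapse = ", ")))
    }
  }
  wn <- weight_name(cb)
  if (!is.null(wn)) {
    w <- as.numeric(data[[wn]])
    if (anyNA(w) || any(w <= 0)) abort_config("weights must be positive and non-missing")
    data[[wn]] <- w
  }
  gn <- group_name(cb)
  if (!is.null(gn) && anyNA(data[[gn]])) abort_config("group label missing for some rows")
  ind <- as.matrix(data[indicator_names(cb)])
  if (any(rowSums(!is.na(ind)) == 0)) {
    abort_config("some rows have no observed indicator at all")
  }
  data
}

# Encode a labelled tibble into the numeric structures the likelihood uses.
# Returns list(Y: n x J integer matrix with NA, ncat, Xcov: n x p dummy matrix
# (NA rows where a covariate is missing), w (normalised to mean 1 when
# `normalise`), cluster, group (integer 1..G), group_levels, n).
encode_lca_data <- function(data, cb, normalise_weights = TRUE) {
  data <- tibble::as_tibble(data)
  ind <- indicator_names(cb)
  ncat <- indicator_ncat(cb)
  Y <- matrix(NA_integer_, nrow(data), length(ind), dimnames = list(NULL, ind))
  for (j in seq_along(ind)) {
    Y[, j] <- match(data[[ind[j]]], indicator_categories(cb, ind[j]))
  }
  covs <- covariate_names(cb)
  dn <- covariate_dummy_names(cb)
  X <- matrix(NA_real_, nrow(data), length(dn), dimnames = list(NULL, dn))
  k <- 0L
  for (cv in covs) {
    lv <- setdiff(indicator_categories(cb, cv), covariate_reference(cb, cv))
    v <- data[[cv]]
    for (l in lv) {
      k <- k + 1L
      X[, k] <- ifelse(is.na(v), NA_real_, as.numeric(v == l))
    }
  }
  wn <- weight_name(cb)
  w <- if (is.null(wn)) rep(1, nrow(data)) else as.numeric(data[[wn]])
  if (normalise_weights) w <- w / mean(w)
  gn <- group_name(cb)
  if (is.null(gn)) {
    group <- rep(1L, nrow(data)); group_levels <- "all"
  } else {
    gl <- sort(unique(data[[gn]]))
    group <- match(data[[gn]], gl)
    group_levels <- as.character(gl)
  }
  cn <- cluster_name(cb)
  cluster <- if (is.null(cn)) seq_len(nrow(data)) else data[[cn]]
  list(Y = Y, ncat = ncat, Xcov = X, w = w, cluster = cluster,
       group = group, group_levels = group_levels, n = nrow(data))
}
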