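# internal numerical helpers

row_maxs <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))

# rowwise log-sum-exp of a matrix, guarded against -Inf rows
row_logsumexp <- function(m) {
  mx <- row_maxs(m)
  mx + log(rowSums(exp(m - mx)))
}

softmax_rows <- function(eta) {
  e <- exp(eta - row_maxs(eta))
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stream child seeds from one master seed; order-independent
split_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# run expr with a local RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}

abort_config <- function(msg) rlang::abort(msg, class = "lcat_config_error")
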