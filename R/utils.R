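# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count_matrix <- function(x, what = "counts") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_("%s must be a numeric matrix (samples x features)", what)
  if (any(x < 0)) stop_("%s contains negative values", what)
  if (any(x != round(x))) stop_("%s contains non-integer values", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_("%s must have sample row names and feature column names", what)
  if (anyDuplicated(rownames(x))) stop_("duplicate sample IDs in %s", what)
  if (anyDuplicated(colnames(x))) stop_("duplicate feature IDs in %s", what)
  invisible(x)
}

# p-values clamped away from 0/1 before normal-quantile transformation
clamp_p <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)
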