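#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

#' Area under the precision-recall curve
#'
#' Average-precision estimate of the area under the precision-recall curve,
#' used to score how well a ranking (e.g. mutual-information or CLR scores)
#' separates planted regulator-target pairs from background pairs.
#'
#' @param scores numeric vector of candidate scores (higher = more confident).
#' @param labels logical or 0/1 vector, `TRUE` for true (planted) pairs.
#' @return scalar average precision in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  # average precision: mean of precision at each true positive
  sum(precision[lab]) / sum(lab)
}
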