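#' Percentile bootstrap confidence interval for a mean
#'
#' @param values numeric vector (non-empty)
#' @param B number of bootstrap replicates (default 1000)
#' @param level confidence level (default 0.95)
#' @param seed RNG seed
#' @param statistic_name label stored with the result
#' @return object of class `bootstrap_ci`: list with `statistic`, `B`,
#'   `estimate`, `ci_low`, `ci_high`, `level`, `replicates`
#' @export
bootstrap_ci <- function(values, B = 1000L, level = 0.95, seed = NULL,
                         statistic_name = "mean") {
  if (length(values) == 0) stop("bootstrap_ci: empty input")
  stopifnot(B >= 1, level > 0, level < 1)
  n <- length(values)
  reps <- with_seed(seed, vapply(seq_len(B), function(b) {
    mean(values[sample.int(n, n, replace = TRUE)])
  }, 0))
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(statistic = statistic_name, B = as.integer(B),
                 estimate = mean(values), ci_low = qs[1], ci_high = qs[2],
                 level = level, replicates = reps),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("Bootstrap %s: %.4g  %g%% CI (%.4g, %.4g)  [B=%d]\n",
              x$statistic, x$estimate, 100 * x$level, x$ci_low, x$ci_high, x$B))
  invisible(x)
}

#' Bootstrap quantile-separation test
#'
#' Tests whether the W feature distribution lies distinctly below the non-W
#' distribution. Per replicate, both groups are resampled with replacement and
#' the difference `min(non-W resample) - max(W resample)` recorded; `p` is the
#' fraction of replicates in which this difference is not positive. The
#' literal-order difference (100th quantile of W minus 0th quantile of non-W)
#' is retained with flipped sign in `literal_diffs`.
#'
#' @param w_values feature values of the W group (non-empty)
#' @param nonw_values feature values of the non-W group (non-empty)
#' @param B bootstrap replicates (default 1000)
#' @param seed RNG seed
#' @return object of class `separation_test`: list with `diffs`,
#'   `literal_diffs`, `p`, `B`
#' @export
quantile_separation_test <- function(w_values, nonw_values, B = 1000L,
                                     seed = NULL) {
  if (length(w_values) == 0 || length(nonw_values) == 0)
    stop("quantile_separation_test: empty group")
  stopifnot(B >= 1)
  nw <- length(w_values); nn <- length(nonw_values)
  diffs <- with_seed(seed, vapply(seq_len(B), function(b) {
    min(nonw_values[sample.int(nn, nn, replace = TRUE)]) -
      max(w_values[sample.int(nw, nw, replace = TRUE)])
  }, 0))
  structure(list(diffs = diffs, literal_diffs = -diffs,
                 p = mean(diffs <= 0), B = as.integer(B)),
            class = "separation_test")
}

#' @export
print.separation_test <- function(x, ...) {
  p_lab <- if (x$p == 0) sprintf("< %.3g", 1 / x$B) else sprintf("= %.4g", x$p)
  cat(sprintf("Quantile-separation test: p %s  (B=%d, mean gap %.4g)\n",
              p_lab, x$B, mean(x$diffs)))
  invisible(x)
}

#' Bootstrap coverage threshold from known W contigs
#'
#' The mean, over bootstrap replicates, of the maximum coverage in a
#' resample of the W group (the mean 100th quantile); used as the coverage
#' cutoff for the false-positive-rate-by-length curve.
#'
#' @param w_coverages coverage values of known W contigs (non-empty)
#' @param B bootstrap replicates (default 1000)
#' @param seed RNG seed
#' @return numeric threshold
#' @export
w_coverage_threshold <- function(w_coverages, B = 1000L, seed = NULL) {
  if (length(w_coverages) == 0) stop("w_coverage_threshold: empty input")
  stopifnot(B >= 1)
  n <- length(w_coverages)
  with_seed(seed, mean(vapply(seq_len(B), function(b) {
    max(w_coverages[sample.int(n, n, replace = TRUE)])
  }, 0)))
}

#' False-positive rate by fragment length
#'
#' Per length bin, the fraction of non-W fragments whose coverage falls below
#' the threshold (i.e. that would be mistaken for W). Empty bins are omitted
#' with a warning.
#'
#' @param features feature data.frame with columns `label`, `coverage`, and
#'   `L` (fragment length / length bin)
#' @param threshold coverage cutoff, e.g. from [w_coverage_threshold()]
#' @return data.frame with `L`, `n_nonw`, `fpr`, ordered by `L`
#' @export
fpr_by_length <- function(features, threshold) {
  stopifnot(all(c("label", "coverage", "L") %in% names(features)))
  out <- list()
  for (L in sort(unique(features$L))) {
    nw <- features[features$L == L & features$label == "NONW", , drop = FALSE]
    if (nrow(nw) == 0) {
      warning("fpr_by_length: no non-W fragments at L=", L, "; bin omitted")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      L = L, n_nonw = nrow(nw), fpr = mean(nw$coverage < threshold))
  }
  do.call(rbind, out)
}
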