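#' Per-rank significance thresholds for a family of m tests
#'
#' Computes the ordered sequence of per-rank significance thresholds used to
#' control the error rate across a family of `m` hypothesis tests whose
#' p-values have been sorted in ascending order.
#'
#' Two sequences are available:
#' \describe{
#'   \item{`paper_stepdown`}{Holm-type step-down thresholds
#'     \eqn{\alpha / (m - k + 1)} for rank \eqn{k}. This is the sequence that
#'     reproduces the per-rank threshold columns of published regional
#'     test-retest tables for the 27-region cytoarchitectonic family
#'     (rank 1 gets \eqn{\alpha/m}, rank m gets \eqn{\alpha}).}
#'   \item{`bh_classic`}{Textbook Benjamini-Hochberg thresholds
#'     \eqn{\alpha k / m}.}
#' }
#' The two sequences agree at rank `m` and everywhere when `m = 1`.
#'
#' @param m Number of tests in the family (>= 1).
#' @param alpha Family error-rate level, in (0, 1). Default 0.05.
#' @param method `"paper_stepdown"` (default) or `"bh_classic"`.
#' @return Numeric vector of length `m`: the threshold for ranks 1..m.
#' @examples
#' threshold_sequence(27, 0.05)[c(1, 24, 27)]
#' @export
threshold_sequence <- function(m, alpha = 0.05,
                               method = c("paper_stepdown", "bh_classic")) {
  method <- match.arg(method)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m != floor(m)) {
    stop("`m` must be a single integer >= 1")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)")
  }
  k <- seq_len(m)
  switch(method,
    paper_stepdown = alpha / (m - k + 1),
    bh_classic     = alpha * k / m
  )
}

#' Apply a per-rank multiple-testing correction to a family of p-values
#'
#' Ranks the p-values (ascending, ties broken by input order), assigns each
#' the per-rank threshold from [threshold_sequence()], and applies the
#' method's rejection rule. `paper_stepdown` uses the step-down rule: ranks
#' 1..K are rejected where K is the largest prefix such that every sorted
#' p-value up to K sits at or below its threshold. `bh_classic` uses the
#' usual Benjamini-Hochberg step-up rule: all ranks up to the largest k with
#' p_(k) <= alpha k / m are rejected.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\]; names (e.g. region
#'   labels) are preserved and reported.
#' @param alpha Family error-rate level. Default 0.05.
#' @param method See [threshold_sequence()].
#' @return A data frame of class `correction_result` with one row per input
#'   p-value, in the original input order: `region`, `p`, `rank`,
#'   `threshold`, `reject`. Attributes `method`, `alpha` and `m` record the
#'   correction applied.
#' @examples
#' p <- c(CA2 = 0.004, SUBC = 0.042, DG = 0.4)
#' apply_correction(p, alpha = 0.05)
#' @export
apply_correction <- function(pvalues, alpha = 0.05,
                             method = c("paper_stepdown", "bh_classic")) {
  method <- match.arg(method)
  if (length(pvalues) < 1L) stop("need at least one p-value")
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  labels <- names(pvalues)
  if (is.null(labels)) labels <- paste0("test", seq_len(m))

  ord <- order(pvalues)              # stable: ties keep input order
  thr <- threshold_sequence(m, alpha, method)
  p_sorted <- pvalues[ord]
  below <- p_sorted <= thr
  reject_sorted <- if (method == "paper_stepdown") {
    k_fail <- match(FALSE, below, nomatch = m + 1L)
    seq_len(m) < k_fail
  } else {
    k_max <- max(c(0L, which(below)))
    seq_len(m) <= k_max
  }

  rank <- integer(m)
  rank[ord] <- seq_len(m)
  out <- data.frame(
    region = labels,
    p = as.numeric(pvalues),
    rank = rank,
    threshold = thr[rank],
    reject = reject_sorted[rank],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  class(out) <- c("correction_result", "data.frame")
  out
}
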