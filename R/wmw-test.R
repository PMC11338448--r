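#' Two-sample Wilcoxon-Mann-Whitney test with explicit tie handling
#'
#' The package's front door: runs the exact permutation, Monte-Carlo
#' permutation, or tie-corrected asymptotic Wilcoxon-Mann-Whitney test
#' under one of two tie policies.
#'
#' With `ties = "include"` (recommended) the complete samples are used and
#' tied values carry mid-ranks; the exact permutation test then still
#' guarantees its significance level. With `ties = "omit"` every
#' observation involved in a pooled tie is removed first
#' ([omit_pooled_ties()]); if that empties a group no test can be
#' performed, and an error of class `"wmw_empty_group"` is signalled so
#' simulation code can count skipped tests rather than absorb them into a
#' p-value.
#'
#' @inheritParams exact_pvalue
#' @param method `"exact"` (default), `"montecarlo"`, or `"asymptotic"`.
#' @param ties Tie policy, `"include"` (default) or `"omit"`.
#' @param B,seed Monte-Carlo settings, see [montecarlo_pvalue()].
#' @param correct Continuity correction for the asymptotic method, see
#'   [asymptotic_pvalue()].
#' @return An object of class `"wmw_test"` (also `"htest"`) with the rank
#'   sum `W` of group 1 (computed on the data actually tested), `p.value`,
#'   `method`, `alternative`, `tie.policy`, the effective group sizes
#'   `n1.used`, `n2.used`, and `n.omitted`.
#' @examples
#' x <- c(1.2, 2.4, 2.4, 3.1)
#' y <- c(2.4, 3.1, 4.0, 5.2)
#' wmw_test(x, y)                              # exact, ties included
#' wmw_test(x, y, ties = "omit")$n.omitted     # 4 observations dropped
#' @export
wmw_test <- function(x, y,
                     method = c("exact", "montecarlo", "asymptotic"),
                     alternative = c("two.sided", "less", "greater"),
                     ties = c("include", "omit"),
                     B = 10000L, seed = NULL, correct = TRUE) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  ties <- match.arg(ties)
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  d <- check_two_sample(x, y)
  n_omitted <- 0L
  if (ties == "omit") {
    out <- omit_pooled_ties(d$x, d$y)
    if (any(out$emptied)) {
      emptied <- paste(which(out$emptied), collapse = " and ")
      stop(errorCondition(
        paste0("omission of tied observations emptied group ", emptied,
               "; no test could be performed"),
        class = "wmw_empty_group"))
    }
    d$x <- out$x_reduced
    d$y <- out$y_reduced
    n_omitted <- out$n_omitted
  }
  res <- switch(method,
    exact      = exact_pvalue(d$x, d$y, alternative),
    montecarlo = montecarlo_pvalue(d$x, d$y, alternative, B = B, seed = seed),
    asymptotic = asymptotic_pvalue(d$x, d$y, alternative, correct = correct))
  res$tie.policy <- ties
  res$n.omitted <- n_omitted
  res$data.name <- dname
  if (ties == "omit")
    res$method <- paste(res$method, "after omission of tied observations")
  res
}

#' @export
print.wmw_test <- function(x, ...) {
  # htest layout plus the tie bookkeeping
  cat("\n\t", x$method, "\n\n", sep = "")
  cat("data: ", x$data.name, "\n", sep = "")
  cat(sprintf("W = %g, p-value = %s\n",
              unname(x$statistic), format.pval(x$p.value, digits = 4)))
  cat("alternative hypothesis:", x$alternative, "\n")
  cat(sprintf("ties: %s (n1 used = %d, n2 used = %d, omitted = %d)\n",
              x$tie.policy, x$n1.used, x$n2.used, x$n.omitted))
  invisible(x)
}
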