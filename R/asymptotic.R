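#' Asymptotic (normal-approximation) Wilcoxon-Mann-Whitney p-value
#'
#' Standardises the mid-rank sum W by its permutation mean
#' \eqn{n_1(N+1)/2} and the tie-corrected permutation variance
#' \deqn{Var(W) = \frac{n_1 n_2}{12}\left[(N+1) -
#'   \frac{\sum_j (t_j^3 - t_j)}{N(N-1)}\right],}
#' where the \eqn{t_j} are the pooled tie-group sizes, and refers the
#' z-score to the standard normal. By default a continuity correction of
#' 0.5 toward the mean is applied, matching [stats::wilcox.test()].
#'
#' When every pooled value is tied the variance is zero and no
#' standardisation is possible; the function then returns p = 1 with a
#' warning, the degenerate-distribution answer the exact test also gives.
#'
#' @inheritParams exact_pvalue
#' @param correct Logical; apply the continuity correction (default `TRUE`).
#' @return As [exact_pvalue()].
#' @examples
#' asymptotic_pvalue(c(1.1, 2.3, 2.3), c(2.3, 3.5, 4.1))$p.value
#' @export
asymptotic_pvalue <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              correct = TRUE) {
  alternative <- match.arg(alternative)
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  d <- check_two_sample(x, y)
  N <- d$n1 + d$n2
  pool <- pooled_midranks(x, y)
  w <- sum(pool$ranks[seq_len(d$n1)])
  mu <- d$n1 * (N + 1) / 2
  t_j <- tie_summary(pool)
  method <- paste0("Asymptotic Wilcoxon-Mann-Whitney test",
                   if (correct) " with continuity correction")
  if (length(t_j) == 1L) {  # single tie group: all pooled values equal
    warning("all pooled values are tied; variance is zero, p-value set to 1")
    return(wmw_result(w, 1, method, alternative, "include",
                      d$n1, d$n2, 0L, dname))
  }
  if (N < 2L) stop("need at least two pooled observations", call. = FALSE)
  sigma2 <- d$n1 * d$n2 / 12 * ((N + 1) - sum(t_j^3 - t_j) / (N * (N - 1)))
  z <- w - mu
  cc <- if (correct) {
    switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5, less = -0.5)
  } else 0
  z <- (z - cc) / sqrt(sigma2)
  p <- switch(alternative,
    less      = stats::pnorm(z),
    greater   = stats::pnorm(z, lower.tail = FALSE),
    two.sided = min(1, 2 * stats::pnorm(-abs(z))))
  wmw_result(w, p, method, alternative, "include", d$n1, d$n2, 0L, dname)
}
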