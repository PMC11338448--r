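#' Exact permutation distribution of the rank sum
#'
#' Computes the full conditional null distribution of the Wilcoxon rank sum
#' W of group 1 over all \eqn{\binom{N}{n_1}} equally likely reassignments
#' of the group labels to the observed pooled values, with tied values
#' carrying mid-ranks. Mid-ranks are doubled so every achievable rank sum is
#' an integer; the counts are accumulated by a dynamic-programming shift
#' algorithm that convolves the doubled ranks one at a time, tracking the
#' number of ways to choose k of the first i ranks with each partial sum.
#' No explicit enumeration of assignments takes place.
#'
#' Counts are held in doubles, which represent integers exactly up to
#' \eqn{2^{53}}; the function refuses when \eqn{\binom{N}{n_1}} exceeds that
#' bound (use the Monte-Carlo test for such sample sizes).
#'
#' @inheritParams pooled_midranks
#' @return A list of class `"rank_sum_distribution"` with components
#'   `support` (achievable values of the doubled rank sum 2W, ascending),
#'   `counts` (number of label assignments realising each value; exact
#'   integers), `total` (\eqn{\binom{N}{n_1}}), `n1`, `n2`, `N`.
#' @examples
#' d <- rank_sum_distribution(c(1, 2), c(3, 4))
#' d$support            # 6 8 10 12 14
#' d$counts             # 1 1 2 1 1
#' @seealso [exact_pvalue()], [brute_force_pvalue()]
#' @export
rank_sum_distribution <- function(x, y) {
  d <- check_two_sample(x, y)
  pool <- pooled_midranks(x, y)
  dist_from_doubled_ranks(doubled_ranks(pool$ranks), d$n1)
}

# Shift-algorithm DP on a vector of doubled pooled ranks. Returns the
# distribution object; ranks need not be sorted.
dist_from_doubled_ranks <- function(dr, n1) {
  N <- length(dr)
  total <- choose(N, n1)
  if (total > 2^53)
    stop("choose(N, n1) exceeds 2^53; exact counts are no longer ",
         "representable - use the Monte-Carlo permutation test",
         call. = FALSE)
  S <- sum(dr)
  # counts[k + 1, s + 1] = number of k-subsets of the ranks processed so far
  # with doubled sum s
  counts <- matrix(0, n1 + 1L, S + 1L)
  counts[1L, 1L] <- 1
  for (r in dr) {
    counts[2L:(n1 + 1L), (r + 1L):(S + 1L)] <-
      counts[2L:(n1 + 1L), (r + 1L):(S + 1L)] +
      counts[1L:n1, 1L:(S + 1L - r)]
  }
  cnt <- counts[n1 + 1L, ]
  sup <- which(cnt > 0) - 1L
  structure(
    list(support = sup, counts = cnt[sup + 1L], total = total,
         n1 = n1, n2 = N - n1, N = N),
    class = "rank_sum_distribution")
}

#' @export
print.rank_sum_distribution <- function(x, ...) {
  cat("Exact permutation distribution of the doubled rank sum (2W)\n")
  cat(sprintf("  n1 = %d, n2 = %d, assignments = %s, support points = %d\n",
              x$n1, x$n2, format(x$total, big.mark = ","),
              length(x$support)))
  invisible(x)
}

# Tail probability of the permutation distribution at observed doubled rank
# sum w2. Alternatives follow wilcox.test: "less" means group 1 shifted
# down, i.e. small W. The two-sided p-value is the probability of a rank
# sum at least as distant from the permutation mean n1(N+1)/2 as the
# observed one; all comparisons are on the integer lattice of doubled
# sums, so no floating-point tolerance is needed.
ptail_doubled <- function(dist, w2, alternative) {
  e2 <- dist$n1 * (dist$N + 1L)  # doubled permutation mean
  inc <- switch(alternative,
    less      = dist$support <= w2,
    greater   = dist$support >= w2,
    two.sided = abs(dist$support - e2) >= abs(w2 - e2))
  sum(dist$counts[inc]) / dist$total
}

# Common constructor for test results; an htest so the standard print
# method applies.
wmw_result <- function(w, p, method, alternative, tie_policy,
                       n1_used, n2_used, n_omitted, data_name) {
  structure(
    list(statistic = c(W = w), p.value = p, method = method,
         alternative = alternative, tie.policy = tie_policy,
         n1.used = n1_used, n2.used = n2_used, n.omitted = n_omitted,
         data.name = data_name),
    class = c("wmw_test", "htest"))
}

#' Exact permutation p-value of the Wilcoxon-Mann-Whitney test
#'
#' P-value of the rank-sum statistic under its full permutation null
#' distribution ([rank_sum_distribution()]), valid with or without ties.
#' One-sided p-values are the exact tail probabilities
#' \eqn{P(W^* \le w)} ("less") or \eqn{P(W^* \ge w)} ("greater"); the
#' two-sided p-value is \eqn{P(|W^* - E W| \ge |w - E W|)} with
#' \eqn{E W = n_1(N+1)/2}, i.e. both tails at the observed distance from
#' the permutation mean. All probabilities are ratios of exact integer
#' counts.
#'
#' @inheritParams pooled_midranks
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return An object of class `"wmw_test"` (also `"htest"`): statistic `W`,
#'   `p.value`, `method`, `alternative`, tie policy and effective sample
#'   sizes.
#' @examples
#' exact_pvalue(c(1, 2), c(3, 4), alternative = "less")$p.value  # 1/6
#' @export
exact_pvalue <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  d <- check_two_sample(x, y)
  pool <- pooled_midranks(x, y)
  dr <- doubled_ranks(pool$ranks)
  dist <- dist_from_doubled_ranks(dr, d$n1)
  w2 <- sum(dr[seq_len(d$n1)])
  p <- ptail_doubled(dist, w2, alternative)
  wmw_result(w2 / 2, p, "Exact permutation Wilcoxon-Mann-Whitney test",
             alternative, "include", d$n1, d$n2, 0L, dname)
}

#' Brute-force permutation p-value (validation oracle)
#'
#' Recomputes the exact permutation p-value by explicitly enumerating every
#' \eqn{n_1}-subset of the pooled mid-ranks, with the same tail definitions
#' as [exact_pvalue()]. Exists purely as an independent cross-check of the
#' shift-algorithm distribution in the test suite; refuses problems with
#' more than \eqn{10^6} assignments.
#'
#' @inheritParams exact_pvalue
#' @return As [exact_pvalue()].
#' @export
brute_force_pvalue <- function(x, y,
                               alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  d <- check_two_sample(x, y)
  N <- d$n1 + d$n2
  if (choose(N, d$n1) > 1e6)
    stop("more than 1e6 label assignments; brute force refused", call. = FALSE)
  pool <- pooled_midranks(x, y)
  dr <- doubled_ranks(pool$ranks)
  w2_all <- utils::combn(dr, d$n1, FUN = sum)
  w2 <- sum(dr[seq_len(d$n1)])
  e2 <- d$n1 * (N + 1L)
  extreme <- switch(alternative,
    less      = w2_all <= w2,
    greater   = w2_all >= w2,
    two.sided = abs(w2_all - e2) >= abs(w2 - e2))
  wmw_result(w2 / 2, mean(extreme),
             "Brute-force permutation Wilcoxon-Mann-Whitney test",
             alternative, "include", d$n1, d$n2, 0L, dname)
}

#' Monte-Carlo permutation p-value of the Wilcoxon-Mann-Whitney test
#'
#' Approximates the exact permutation p-value from `B` uniformly random
#' reassignments of the group labels, using the add-one estimator
#' \eqn{p = (b + 1)/(B + 1)} where `b` counts resampled rank sums at least
#' as extreme as the observed one. The add-one estimator never reports
#' zero, so the test remains valid at any `B`. Intended for sample sizes
#' where the full enumeration behind [exact_pvalue()] is unavailable.
#'
#' @inheritParams exact_pvalue
#' @param B Number of random permutations (at least 1).
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG state is used.
#' @return As [exact_pvalue()].
#' @export
montecarlo_pvalue <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              B = 10000L, seed = NULL) {
  alternative <- match.arg(alternative)
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  if (length(B) != 1L || is.na(B) || B < 1)
    stop("'B' must be a positive integer", call. = FALSE)
  B <- as.integer(B)
  if (!is.null(seed)) set.seed(seed)
  d <- check_two_sample(x, y)
  N <- d$n1 + d$n2
  pool <- pooled_midranks(x, y)
  dr <- doubled_ranks(pool$ranks)
  w2 <- sum(dr[seq_len(d$n1)])
  e2 <- d$n1 * (N + 1L)
  w2_star <- vapply(seq_len(B),
                    function(i) sum(dr[sample.int(N, d$n1)]), numeric(1))
  b <- switch(alternative,
    less      = sum(w2_star <= w2),
    greater   = sum(w2_star >= w2),
    two.sided = sum(abs(w2_star - e2) >= abs(w2 - e2)))
  wmw_result(w2 / 2, (b + 1) / (B + 1),
             sprintf("Monte-Carlo permutation Wilcoxon-Mann-Whitney test (B = %d)", B),
             alternative, "include", d$n1, d$n2, 0L, dname)
}
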