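#' Validate a two-sample data set
#'
#' Checks the two numeric vectors that every test in this package consumes:
#' both groups must be non-empty and all values finite.
#'
#' @param x,y Numeric vectors, the observations of group 1 and group 2.
#' @return Invisibly, a list with components `x`, `y`, `n1`, `n2`.
#' @keywords internal
check_two_sample <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("'x' and 'y' must be numeric vectors", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("all observations must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (length(x) < 1L || length(y) < 1L)
    stop("each group must contain at least one observation", call. = FALSE)
  invisible(list(x = as.numeric(x), y = as.numeric(y),
                 n1 = length(x), n2 = length(y)))
}

#' Pooled mid-ranks of a two-sample data set
#'
#' Ranks the pooled sample of both groups in ascending order, assigning each
#' set of tied values the average of the integer ranks it jointly occupies
#' (mid-ranks). Ties are detected by exact equality of the stored values;
#' data rounded to a fixed number of decimals therefore tie deterministically.
#'
#' @param x,y Numeric vectors, the observations of group 1 and group 2.
#' @return A list of class `"ranked_pool"` with components
#'   \describe{
#'     \item{ranks}{mid-ranks of the pooled values, group 1 first;
#'       they always sum to \eqn{N(N+1)/2} with \eqn{N = n_1 + n_2};}
#'     \item{group}{integer vector of group labels (1 or 2) per pooled value;}
#'     \item{tie_multiplicities}{sizes \eqn{t_j} of the tied groups in the
#'       pooled sample, in ascending order of value; they sum to \eqn{N}.}
#'   }
#' @examples
#' pooled_midranks(c(1, 2), c(2, 3))$ranks   # 1.0 2.5 2.5 4.0
#' @seealso [rank_sum()], [tie_summary()]
#' @export
pooled_midranks <- function(x, y) {
  d <- check_two_sample(x, y)
  pooled <- c(d$x, d$y)
  structure(
    list(ranks = rank(pooled),
         group = rep(1:2, c(d$n1, d$n2)),
         tie_multiplicities = as.integer(table(pooled))),
    class = "ranked_pool")
}

#' Wilcoxon rank-sum statistic with mid-ranks
#'
#' The sum W of the mid-ranks of group 1 in the pooled ranking; the test
#' statistic of every variant in this package. Its permutation mean is
#' \eqn{n_1(N+1)/2}.
#'
#' @inheritParams pooled_midranks
#' @return The rank sum W (a single number; half-integers can occur with
#'   even-sized tie groups).
#' @examples
#' rank_sum(c(1, 2), c(3, 4))  # 3, the smallest achievable value
#' @export
rank_sum <- function(x, y) {
  pool <- pooled_midranks(x, y)
  sum(pool$ranks[pool$group == 1L])
}

#' Tie multiplicities of a pooled sample
#'
#' Sizes of the tied groups in a ranked pool, the quantities entering the
#' tie-corrected variance of the asymptotic test.
#'
#' @param pool A `"ranked_pool"` as returned by [pooled_midranks()].
#' @return Integer vector of tie-group sizes \eqn{t_j}; singletons count as 1
#'   and the sizes sum to the pooled sample size.
#' @examples
#' tie_summary(pooled_midranks(c(1, 2), c(2, 4)))  # 1 2 1
#' @export
tie_summary <- function(pool) {
  stopifnot(inherits(pool, "ranked_pool"))
  pool$tie_multiplicities
}

# Doubled mid-ranks of the pooled sample, as exact integers. Doubling makes
# every mid-rank integral (a tie group of even size has a half-integer
# mid-rank), so rank sums live on an integer lattice and permutation counts
# can be accumulated exactly.
doubled_ranks <- function(ranks) as.integer(round(2 * ranks))
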