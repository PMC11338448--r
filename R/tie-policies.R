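#' Omit all tied observations from a two-sample data set
#'
#' Removes every observation whose value occurs two or more times in the
#' pooled sample of both groups — within-group ties are removed along with
#' between-group ties, since a tie is a property of the pooled data. This is
#' the tie-handling policy the package's simulation study compares against
#' keeping the complete data with mid-ranks; omission can empty a group, in
#' which case no test can be performed on the reduced data.
#'
#' @inheritParams pooled_midranks
#' @return A list of class `"tie_policy_outcome"` with components
#'   `x_reduced`, `y_reduced` (the surviving observations, all distinct in
#'   the reduced pool), `n_omitted`, and `emptied`, a logical vector of
#'   length 2 flagging groups left without observations.
#' @examples
#' omit_pooled_ties(c(1, 2), c(2, 3))  # keeps x' = 1, y' = 3
#' @export
omit_pooled_ties <- function(x, y) {
  d <- check_two_sample(x, y)
  pooled <- c(d$x, d$y)
  mult <- table(pooled)
  keep <- mult[as.character(pooled)] == 1L
  x_red <- d$x[keep[seq_len(d$n1)]]
  y_red <- d$y[keep[d$n1 + seq_len(d$n2)]]
  structure(
    list(x_reduced = x_red, y_reduced = y_red,
         n_omitted = d$n1 + d$n2 - length(x_red) - length(y_red),
         emptied = c(length(x_red) == 0L, length(y_red) == 0L)),
    class = "tie_policy_outcome")
}

#' Round values to a fixed number of decimal places
#'
#' Rounding to `d` decimals under round-half-to-even (the IEC 60559
#' behaviour of base [round()]). Applied to continuous draws it models the
#' limited precision of a measuring instrument and is the mechanism by which
#' the synthetic-data generator creates ties; exact halves have probability
#' zero for continuous draws, so the half-to-even convention cannot affect
#' simulated results.
#'
#' @param values Numeric vector.
#' @param d Non-negative integer, number of decimal places to keep.
#' @return `values` rounded to `d` decimals.
#' @examples
#' round_values(c(1.04, 1.04999), 1)  # both 1.0: a rounding-induced tie
#' @export
round_values <- function(values, d) {
  if (length(d) != 1L || is.na(d) || d < 0 || d != trunc(d))
    stop("'d' must be a single non-negative integer", call. = FALSE)
  round(values, digits = d)
}
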