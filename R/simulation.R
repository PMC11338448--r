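# Internal fast paths for the simulation engine. Both work from the pooled
# mid-ranks already computed for a replicate, avoiding repeated validation
# and ranking. The exact path memoises the permutation distribution on the
# doubled-rank multiset (the tie pattern): replicates sharing a tie pattern
# share the distribution, which makes the 10000-replicate scenarios cheap.

exact_p2_cached <- function(rk, n1, cache) {
  dr <- doubled_ranks(rk)
  key <- paste(n1, paste(sort(dr), collapse = ","), sep = "|")
  dist <- cache[[key]]
  if (is.null(dist)) {
    dist <- dist_from_doubled_ranks(dr, n1)
    cache[[key]] <- dist
  }
  ptail_doubled(dist, sum(dr[seq_len(n1)]), "two.sided")
}

asym_p2_from_ranks <- function(rk, n1, correct = TRUE) {
  N <- length(rk)
  t_j <- as.integer(table(rk))
  if (length(t_j) == 1L) return(1)
  sigma2 <- n1 * (N - n1) / 12 * ((N + 1) - sum(t_j^3 - t_j) / (N * (N - 1)))
  z <- sum(rk[seq_len(n1)]) - n1 * (N + 1) / 2
  if (correct) z <- z - sign(z) * 0.5
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

#' Run one simulation scenario
#'
#' Estimates rejection proportions of the two-sided exact permutation and
#' asymptotic Wilcoxon-Mann-Whitney tests, under both tie policies, by
#' Monte-Carlo simulation: per replicate a data set is drawn from the
#' scenario ([draw_dataset()]), the four test variants are applied, and a
#' rejection is counted when p is strictly below the nominal level. When
#' omission of tied observations empties a group, that replicate is counted
#' in `empty_group_count` and excluded from the omit-variant denominators —
#' the estimate divides by the number of tests actually performed. The mean
#' pooled sample size remaining after omission is averaged over all
#' replicates, emptied ones included.
#'
#' @param scenario A [wmw_scenario()].
#' @param reps Number of simulation replicates.
#' @param seed Optional integer seed (scenario results are then fully
#'   reproducible in isolation).
#' @param correct Continuity correction for the asymptotic variant.
#' @return A list of class `"wmw_scenario_result"`: the `scenario`,
#'   `reps_total`, a data frame `rejection` with one row per
#'   (method, tie policy, alpha) holding `rejections`, `n_performed` and
#'   `rate`, `mean_size_after_omission`, and `empty_group_count`.
#' @examples
#' sc <- wmw_scenario("normal", shift = 0, n1 = 10, n2 = 10, decimals = 2)
#' run_scenario(sc, reps = 50, seed = 1)
#' @export
run_scenario <- function(scenario, reps = 10000L, seed = NULL, correct = TRUE) {
  stopifnot(inherits(scenario, "wmw_scenario"), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  alphas <- scenario$alphas
  n1 <- scenario$n1
  n2 <- scenario$n2
  cache <- new.env(parent = emptyenv())
  rej <- matrix(0L, nrow = 4L, ncol = length(alphas),
                dimnames = list(c("exact.include", "asymptotic.include",
                                  "exact.omit", "asymptotic.omit"), NULL))
  empty_groups <- 0L
  size_sum <- 0
  for (i in seq_len(reps)) {
    dat <- draw_dataset(scenario)
    pooled <- c(dat$x, dat$y)
    rk <- rank(pooled)
    p_ex <- exact_p2_cached(rk, n1, cache)
    p_as <- asym_p2_from_ranks(rk, n1, correct)
    rej["exact.include", ] <- rej["exact.include", ] + (p_ex < alphas)
    rej["asymptotic.include", ] <- rej["asymptotic.include", ] + (p_as < alphas)
    keep <- !(duplicated(pooled) | duplicated(pooled, fromLast = TRUE))
    xr <- dat$x[keep[seq_len(n1)]]
    yr <- dat$y[keep[n1 + seq_len(n2)]]
    size_sum <- size_sum + length(xr) + length(yr)
    if (length(xr) == 0L || length(yr) == 0L) {
      empty_groups <- empty_groups + 1L
      next
    }
    rkr <- rank(c(xr, yr))
    p_exo <- exact_p2_cached(rkr, length(xr), cache)
    p_aso <- asym_p2_from_ranks(rkr, length(xr), correct)
    rej["exact.omit", ] <- rej["exact.omit", ] + (p_exo < alphas)
    rej["asymptotic.omit", ] <- rej["asymptotic.omit", ] + (p_aso < alphas)
  }
  performed <- c(reps, reps, reps - empty_groups, reps - empty_groups)
  rejection <- data.frame(
    method = rep(c("exact", "asymptotic"), 2L)[rep(1:4, each = length(alphas))],
    policy = rep(c("include", "omit"), each = 2L)[rep(1:4, each = length(alphas))],
    alpha = rep(alphas, times = 4L),
    rejections = as.vector(t(rej)),
    n_performed = rep(performed, each = length(alphas)))
  rejection$rate <- ifelse(rejection$n_performed > 0,
                           rejection$rejections / rejection$n_performed, NA_real_)
  structure(
    list(scenario = scenario, reps_total = as.integer(reps),
         rejection = rejection,
         mean_size_after_omission = size_sum / reps,
         empty_group_count = empty_groups),
    class = "wmw_scenario_result")
}

#' @export
print.wmw_scenario_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  %d replicates; mean pooled size after omission %.1f; %d emptied-group replicates\n",
              x$reps_total, x$mean_size_after_omission, x$empty_group_count))
  print(x$rejection, row.names = FALSE)
  invisible(x)
}

#' Extract a rejection rate from a scenario result
#'
#' @param result A `"wmw_scenario_result"`.
#' @param method `"exact"` or `"asymptotic"`.
#' @param policy `"include"` or `"omit"`.
#' @param alpha One of the scenario's nominal levels.
#' @return The rejection proportion (rejections over performed tests).
#' @export
rejection_rate <- function(result, method = "exact", policy = "include",
                           alpha = 0.05) {
  stopifnot(inherits(result, "wmw_scenario_result"))
  r <- result$rejection
  i <- which(r$method == method & r$policy == policy & r$alpha == alpha)
  if (length(i) != 1L)
    stop("no unique rejection entry for the requested variant", call. = FALSE)
  r$rate[i]
}

#' The full replicated scenario grid
#'
#' All 64 cells of the simulation design: four distributions, shifts 0,
#' 0.5, 1, 1.5 applied to group 2, balanced (10, 10) and unbalanced
#' (14, 7) group sizes, rounding to 2 or 1 decimal places, levels 5% and
#' 1%.
#'
#' @return A list of [wmw_scenario()] objects.
#' @export
default_study_grid <- function() {
  grid <- expand.grid(decimals = c(2L, 1L), design = 1:2,
                      shift = c(0, 0.5, 1, 1.5),
                      distribution = wmw_distributions,
                      stringsAsFactors = FALSE)
  designs <- list(c(10L, 10L), c(14L, 7L))
  lapply(seq_len(nrow(grid)), function(i) {
    ns <- designs[[grid$design[i]]]
    wmw_scenario(grid$distribution[i], grid$shift[i],
                 n1 = ns[1], n2 = ns[2], decimals = grid$decimals[i])
  })
}

# Deterministic per-scenario seed stream below 2^31.
scenario_seed <- function(master, index) {
  as.integer((as.double(master) + 1000003 * index) %% (2^31 - 1))
}

#' Run a grid of simulation scenarios
#'
#' Runs [run_scenario()] over a scenario grid with a deterministic seed
#' substream per scenario, so every scenario is reproducible in isolation
#' and the study result does not depend on grid order. A scenario that
#' fails is recorded as a condition object in its slot; the others proceed.
#'
#' @param grid List of [wmw_scenario()] objects, e.g.
#'   [default_study_grid()].
#' @param reps Replicates per scenario.
#' @param seed Master integer seed.
#' @param correct Continuity correction for the asymptotic variant.
#' @param progress Emit a [message()] per completed scenario.
#' @return A list of class `"wmw_study"` with components `results` (one
#'   `"wmw_scenario_result"` or error condition per grid cell), `reps`,
#'   and `seed`.
#' @export
run_study <- function(grid, reps = 10000L, seed = 1L, correct = TRUE,
                      progress = interactive()) {
  if (!is.list(grid) || length(grid) == 0L)
    stop("'grid' must be a non-empty list of scenarios", call. = FALSE)
  results <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    results[[i]] <- tryCatch(
      run_scenario(grid[[i]], reps = reps, seed = scenario_seed(seed, i),
                   correct = correct),
      error = function(e) e)
    if (progress) {
      sc <- grid[[i]]
      message(sprintf("[%d/%d] %s shift %g n=(%d,%d) d=%d done",
                      i, length(grid), sc$distribution, sc$shift,
                      sc$n1, sc$n2, sc$decimals))
    }
  }
  structure(list(results = results, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "wmw_study")
}

#' Assemble one results table for a design / rounding combination
#'
#' Collects the scenario results for one sample-size design and one
#' rounding precision into the table layout of the study report: one row
#' per distribution and shift; columns for the exact and asymptotic
#' rejection rates at 5% and 1% with ties included, the average pooled
#' sample size after tie omission, and the same four rates after omission.
#' Grid cells without a (successful) result are reported as `NA`.
#'
#' @param study A `"wmw_study"`, or a plain list of
#'   `"wmw_scenario_result"` objects.
#' @param design Integer vector `c(n1, n2)` selecting the sample sizes.
#' @param decimals Rounding precision selecting the table.
#' @return A data frame with columns `distribution`, `shift`,
#'   `exact_5_include`, `exact_1_include`, `asymptotic_5_include`,
#'   `asymptotic_1_include`, `avg_sample_size`, `exact_5_omit`,
#'   `exact_1_omit`, `asymptotic_5_omit`, `asymptotic_1_omit`.
#' @export
build_table <- function(study, design = c(10L, 10L), decimals = 2L) {
  results <- if (inherits(study, "wmw_study")) study$results else study
  ok <- vapply(results, inherits, logical(1), "wmw_scenario_result")
  results <- results[ok]
  sel <- Filter(function(r) {
    sc <- r$scenario
    sc$n1 == design[1] && sc$n2 == design[2] && sc$decimals == decimals
  }, results)
  key <- function(sc) paste(sc$distribution, sc$shift)
  by_key <- stats::setNames(sel, vapply(sel, function(r) key(r$scenario),
                                        character(1)))
  shifts <- sort(unique(c(0, 0.5, 1, 1.5,
                          vapply(sel, function(r) r$scenario$shift, numeric(1)))))
  rows <- expand.grid(shift = shifts, distribution = wmw_distributions,
                      stringsAsFactors = FALSE)[, 2:1]
  cell <- function(r, method, policy, alpha)
    if (is.null(r)) NA_real_ else rejection_rate(r, method, policy, alpha)
  tab <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    r <- by_key[[paste(rows$distribution[i], rows$shift[i])]]
    data.frame(
      distribution = rows$distribution[i], shift = rows$shift[i],
      exact_5_include = cell(r, "exact", "include", 0.05),
      exact_1_include = cell(r, "exact", "include", 0.01),
      asymptotic_5_include = cell(r, "asymptotic", "include", 0.05),
      asymptotic_1_include = cell(r, "asymptotic", "include", 0.01),
      avg_sample_size = if (is.null(r)) NA_real_ else r$mean_size_after_omission,
      exact_5_omit = cell(r, "exact", "omit", 0.05),
      exact_1_omit = cell(r, "exact", "omit", 0.01),
      asymptotic_5_omit = cell(r, "asymptotic", "omit", 0.05),
      asymptotic_1_omit = cell(r, "asymptotic", "omit", 0.01))
  }))
  tab
}

#' Format a results table for display
#'
#' Applies the report's rounding style: proportions in null rows
#' (shift 0) to 3 decimals, power rows to 2, average sample sizes to 1.
#'
#' @param tab A table from [build_table()].
#' @return A character data frame of the same shape.
#' @export
format_study_table <- function(tab) {
  out <- tab
  prop_cols <- setdiff(names(tab), c("distribution", "shift", "avg_sample_size"))
  digits <- ifelse(tab$shift == 0, 3L, 2L)
  for (cl in prop_cols)
    out[[cl]] <- ifelse(is.na(tab[[cl]]), "",
                        sprintf(paste0("%.", digits, "f"), tab[[cl]]))
  out$avg_sample_size <- ifelse(is.na(tab$avg_sample_size), "",
                                sprintf("%.1f", tab$avg_sample_size))
  out
}
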