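#' Read a two-sample data set from disk
#'
#' Either a single CSV with header `group,value` (the first two distinct
#' group labels, in order of appearance, become groups 1 and 2), or two
#' plain-text files with one numeric value per line.
#'
#' @param csv Path to a `group,value` CSV. Mutually exclusive with
#'   `x_file`/`y_file`.
#' @param x_file,y_file Paths to one-value-per-line files for the two
#'   groups.
#' @return A list with numeric components `x` and `y`.
#' @export
read_samples <- function(csv = NULL, x_file = NULL, y_file = NULL) {
  if (!is.null(csv)) {
    if (!is.null(x_file) || !is.null(y_file))
      stop("give either 'csv' or 'x_file'/'y_file', not both", call. = FALSE)
    if (!file.exists(csv)) stop("file not found: ", csv, call. = FALSE)
    tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
    if (!all(c("group", "value") %in% names(tab)))
      stop("CSV ", csv, " must have columns 'group' and 'value'",
           call. = FALSE)
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab$value))))
    if (length(bad))
      stop("non-numeric value in ", csv, " at data line ", bad[1],
           call. = FALSE)
    labels <- unique(tab$group)
    if (length(labels) != 2L)
      stop("CSV ", csv, " must contain exactly two group labels, found: ",
           paste(labels, collapse = ", "), call. = FALSE)
    return(list(x = as.numeric(tab$value[tab$group == labels[1]]),
                y = as.numeric(tab$value[tab$group == labels[2]])))
  }
  if (is.null(x_file) || is.null(y_file))
    stop("give either 'csv' or both 'x_file' and 'y_file'", call. = FALSE)
  read_one <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    vals <- suppressWarnings(as.numeric(lines))
    if (anyNA(vals))
      stop("non-numeric line ", which(is.na(vals))[1], " in ", path,
           call. = FALSE)
    vals
  }
  list(x = read_one(x_file), y = read_one(y_file))
}

#' Read a study configuration
#'
#' A YAML (or JSON) file naming the scenario grid — lists `distributions`,
#' `shifts`, `designs` (each an `[n1, n2]` pair), `decimals`, `alphas` —
#' plus `reps` and `seed`. Missing fields fall back to the replicated
#' study design.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with `grid` (list of [wmw_scenario()]), `reps`, `seed`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  distributions <- cfg$distributions %||% wmw_distributions
  bad <- setdiff(distributions, wmw_distributions)
  if (length(bad))
    stop("unknown distribution(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  shifts <- cfg$shifts %||% c(0, 0.5, 1, 1.5)
  designs <- cfg$designs %||% list(c(10L, 10L), c(14L, 7L))
  if (!is.list(designs)) designs <- list(designs)
  decimals <- cfg$decimals %||% c(2L, 1L)
  alphas <- cfg$alphas %||% c(0.05, 0.01)
  grid <- list()
  for (dist in distributions) for (sh in shifts)
    for (ns in designs) for (d in decimals)
      grid[[length(grid) + 1L]] <-
        wmw_scenario(dist, sh, n1 = ns[1], n2 = ns[2], decimals = d,
                     alphas = alphas)
  list(grid = grid,
       reps = as.integer(cfg$reps %||% 10000L),
       seed = as.integer(cfg$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write study results to disk
#'
#' One CSV per (design, rounding) combination present in the study, in the
#' display-rounded layout of [format_study_table()], plus a JSON sidecar
#' `study.json` holding every scenario's full-precision rejection rates,
#' mean post-omission sample size, emptied-group count, and the study seed.
#'
#' @param study A `"wmw_study"` from [run_study()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(study, out_dir) {
  stopifnot(inherits(study, "wmw_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- Filter(function(r) inherits(r, "wmw_scenario_result"), study$results)
  combos <- unique(do.call(rbind, lapply(ok, function(r)
    data.frame(n1 = r$scenario$n1, n2 = r$scenario$n2,
               decimals = r$scenario$decimals))))
  paths <- character(0)
  for (i in seq_len(nrow(combos))) {
    tab <- build_table(study, design = c(combos$n1[i], combos$n2[i]),
                       decimals = combos$decimals[i])
    path <- file.path(out_dir, sprintf("table_n%d_%d_d%d.csv",
                                       combos$n1[i], combos$n2[i],
                                       combos$decimals[i]))
    utils::write.csv(format_study_table(tab), path, row.names = FALSE)
    paths <- c(paths, path)
  }
  sidecar <- list(
    seed = study$seed, reps = study$reps,
    scenarios = lapply(study$results, function(r) {
      if (!inherits(r, "wmw_scenario_result"))
        return(list(error = conditionMessage(r)))
      list(scenario = unclass(r$scenario), reps_total = r$reps_total,
           rejection = r$rejection,
           mean_size_after_omission = r$mean_size_after_omission,
           empty_group_count = r$empty_group_count)
    }))
  json_path <- file.path(out_dir, "study.json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, json_path))
}

#' Serialise a single test result as JSON
#'
#' @param result A `"wmw_test"` object.
#' @return A JSON string (also what the command-line `wmw test` prints).
#' @export
test_result_json <- function(result) {
  stopifnot(inherits(result, "wmw_test"))
  jsonlite::toJSON(
    list(statistic = unname(result$statistic), p_value = result$p.value,
         method = result$method, alternative = result$alternative,
         tie_policy = result$tie.policy, n1_used = result$n1.used,
         n2_used = result$n2.used, n_omitted = result$n.omitted),
    auto_unbox = TRUE, digits = NA)
}
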