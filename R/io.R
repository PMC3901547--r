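#' Write summary-statistic vectors to CSV
#'
#' One column per statistic with a header row of statistic names; one row
#' per vector.
#'
#' @param stats a named statistic vector, or a matrix/list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  if (is.numeric(stats) && !is.matrix(stats)) stats <- rbind(stats)
  if (is.list(stats)) stats <- do.call(rbind, stats)
  write.csv(as.data.frame(stats, check.names = FALSE), path,
            row.names = FALSE)
  invisible(path)
}

#' Persist a reference table as CSV with a JSON provenance sidecar
#'
#' Writes `<stem>.csv` (model label, parameter columns, statistic columns)
#' and `<stem>.json` (simulation counts, parameter names per model,
#' mutation-model settings, package version).
#'
#' @param table a [simulate_reference_table()] result.
#' @param stem output path stem (without extension).
#' @return The CSV path, invisibly.
#' @export
write_ref_table <- function(table, stem) {
  stopifnot(inherits(table, "ref_table"))
  df <- data.frame(model = as.character(table$model), table$params,
                   table$stats, check.names = FALSE)
  csv <- paste0(stem, ".csv")
  write.csv(df, csv, row.names = FALSE)
  side <- list(
    n_per_model = table$n_per_model,
    models = lapply(table$specs, function(s)
      list(scenario_id = s$scenario_id, params = s$params,
           generations_per_year = s$clock$gpy, anchor = s$anchor)),
    mutation = table$mutation[c("mu_median", "rate_shape", "p_gsm",
                                "n_states")],
    n_params = ncol(table$params), n_stats = ncol(table$stats),
    package_version = as.character(utils::packageVersion("irsabc")))
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csv)
}

#' Reload a persisted reference table
#'
#' Restores the `model`, `params` and `stats` components written by
#' [write_ref_table()]; the scenario specs themselves are not
#' reconstructed (rebuild them with [build_scenario()] or
#' [scenario_from_yaml()] if needed).
#'
#' @param stem the path stem used by [write_ref_table()].
#' @return A `ref_table` (without `specs`).
#' @export
read_ref_table <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"))
  df <- read.csv(paste0(stem, ".csv"), check.names = FALSE)
  np <- side$n_params
  structure(list(model = factor(df$model, levels = unique(df$model)),
                 stats = as.matrix(df[, (2 + np):ncol(df), drop = FALSE]),
                 params = df[, 2:(1 + np), drop = FALSE],
                 specs = NULL,
                 mutation = do.call(mutation_model, side$mutation),
                 n_per_model = side$n_per_model),
            class = "ref_table")
}

#' Write posterior summaries to JSON
#'
#' Accepts the output of [scenario_posteriors()] or
#' [parameter_posteriors()] (or any list of numeric summaries).
#'
#' @param posterior the object to serialize.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_posterior_json <- function(posterior, path) {
  as_named_lists <- function(x) {
    if (is.list(x)) lapply(x, as_named_lists)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(as_named_lists(posterior), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Write a stage-projection trajectory to CSV
#'
#' One row per step (step 0 = initial state), one column per stage.
#'
#' @param traj a [project()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "stage_trajectory"))
  df <- data.frame(step = seq_len(nrow(traj$N)) - 1, traj$N,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a temporal dataset as tidy CSV
#'
#' One row per individual x locus: group label, collection date, individual
#' index, locus name, and the two allele sizes (empty when missing).
#'
#' @param dataset a [temporal_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "temporal_dataset"))
  L <- length(dataset$loci)
  rows <- lapply(dataset$groups, function(g) {
    n <- nrow(g$geno)
    data.frame(
      group = g$label,
      date = if (is.null(g$date) || all(is.na(g$date))) NA
      else format(as.Date(g$date)),
      individual = rep(seq_len(n), each = L),
      locus = rep(dataset$loci, times = n),
      allele1 = as.vector(t(g$geno[, c(TRUE, FALSE), drop = FALSE])),
      allele2 = as.vector(t(g$geno[, c(FALSE, TRUE), drop = FALSE])))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
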