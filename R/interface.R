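#' Run the full survival-path pipeline
#'
#' Panel construction, map building, node classification, per-slice
#' evaluation and (optionally) a full artifact dump: the canonical map JSON,
#' a DOT rendering, node / bifurcation / evaluation / transition / assignment
#' CSVs, a map plot, and a configuration echo with hash.  All outputs are
#' deterministic for fixed inputs and seed.
#'
#' @param measurements,outcomes,treatments,stages data frames or CSV paths
#'   (`treatments` and `stages` optional); see [read_cohort()] for schemas.
#'   `stages` has columns `patient_id, slice, system, stage`.
#' @param rules dichotomization rule set (default [default_hcc_rules()]).
#' @param interval,horizon slice grid in months.
#' @param family_alpha family-wise selection level.
#' @param gate,epv sample-size gate rule and events-per-variable.
#' @param min_node minimum node size.
#' @param out_dir optional output directory for artifacts.
#' @param seed seed for the bootstrap CIs.
#' @param n_boot bootstrap resamples for c-index CIs (0 disables).
#' @return list with `panel`, `map` (classified), `evaluation`,
#'   `bifurcations`, `assignments`, `config_hash`.
#' @export
run_build <- function(measurements, outcomes, treatments = NULL, stages = NULL,
                      rules = default_hcc_rules(), interval = 3, horizon = 24,
                      family_alpha = 0.05, gate = "epv", epv = 10,
                      min_node = 6L, out_dir = NULL, seed = 1L, n_boot = 0L) {
  as_df <- function(x) {
    if (is.null(x) || is.data.frame(x)) return(x)
    utils::read.csv(x, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  co <- cohort(as_df(measurements), as_df(outcomes), as_df(treatments))
  stages <- as_df(stages)
  cfg <- slice_config(interval, horizon)
  panel <- build_slice_panel(co, cfg, rules)
  sel <- selection_config(family_alpha, cfg$m)
  map <- build_survival_map(panel, sel, gate = gate, epv = epv,
                            min_node = min_node)
  map <- classify_nodes(map, co$treatments)
  evaluation <- evaluate_map(map, panel, stages, threshold = sel$alpha,
                             n_boot = n_boot, seed = seed)
  bifurcations <- map_bifurcation_tests(map, panel)
  assignments <- assign_patients(map, panel)
  hash <- map_hash(map)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_map(map, file.path(out_dir, "map.json"))
    write_map_dot(map, file.path(out_dir, "map.dot"))
    wcsv <- function(df, name) {
      p <- file.path(out_dir, name)
      con <- file(p, "w")
      writeLines(sprintf("# config %s", hash), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    wcsv(map_nodes_df(map), "nodes.csv")
    wcsv(bifurcations, "bifurcations.csv")
    if (!is.null(evaluation) && nrow(evaluation)) wcsv(evaluation, "evaluation.csv")
    wcsv(assignments, "assignments.csv")
    if (length(map$transitions)) {
      tdf <- do.call(rbind, lapply(map$transitions, function(t)
        data.frame(node = t$node, method = t$method, p_value = t$p_value,
                   surgery_rate = t$surgery_rate,
                   up_given_treatment = t$up_given_treatment,
                   t(as.vector(t$table)), stringsAsFactors = FALSE)))
      wcsv(tdf, "transitions.csv")
    }
    jsonlite::write_json(c(map_meta(map), list(config_hash = hash, seed = seed)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = I(17))
    ok <- !all(vapply(map$nodes, function(nd)
      nd$excluded || is.na(nd$median), logical(1)))
    if (ok) {
      grDevices::pdf(file.path(out_dir, "map.pdf"), width = 9, height = 6)
      plot(map, main = "Survival map")
      grDevices::dev.off()
    }
  }
  list(panel = panel, map = map, evaluation = evaluation,
       bifurcations = bifurcations, assignments = assignments,
       config_hash = hash)
}

#' Assign new patients from serialized artifacts
#'
#' Loads a map JSON, builds a panel for the given patients with the supplied
#' rule set, and routes them through the map.
#'
#' @param map_file path to a map JSON written by [write_map()].
#' @param measurements,outcomes data frames or CSV paths.
#' @param rules the rule set the map was built with.
#' @param out_csv optional path for the trajectory report.
#' @return the trajectory data frame (see [assign_patients()]).
#' @export
run_assign <- function(map_file, measurements, outcomes,
                       rules = default_hcc_rules(), out_csv = NULL) {
  map <- read_map(map_file)
  as_df <- function(x) if (is.data.frame(x)) x else
    utils::read.csv(x, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  om <- as_df(outcomes)
  if (nrow(om) == 0L) {
    out <- data.frame(patient_id = character(), slice = integer(),
                      node = character(), path = integer(),
                      predicted_median_os = numeric(), status = character())
  } else {
    co <- cohort(as_df(measurements), om)
    panel <- build_slice_panel(co, map$cfg, rules)
    out <- assign_patients(map, panel)
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
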