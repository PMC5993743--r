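#' Dichotomization rules
#'
#' A dichotomization rule maps the newest in-window value(s) of one or two
#' raw source variables to a binary prognostic feature, coded 0 for the
#' favorable arm and 1 for the unfavorable arm.  One source variable may
#' spawn several rules (e.g. serum AFP cut at 200 and again at 400 IU/ml),
#' and every rule is total over its source domain: any non-missing raw value
#' maps to 0 or 1.
#'
#' Rules are ordered; the order is the fixed feature-priority used to break
#' ties in screening p-values and importance scores, so a rule set is
#' deterministic end to end.
#'
#' @param feature name of the derived binary feature.
#' @param variable name of the raw source variable in the measurements table.
#' @param cutoff numeric cut point.
#' @param direction `"ge"` flags values `>= cutoff` as unfavorable, `"gt"`
#'   flags values `> cutoff`.
#' @param unfavorable character or numeric vector of category values mapped
#'   to 1.
#' @param imaging logical; imaging-derived variables anchor the time origin
#'   of a slice (overall survival from a slice is measured from the earliest
#'   imaging examination inside its window).
#' @return an object of class `sp_rule`.
#' @name rules
NULL

new_rule <- function(feature, variables, kind, params = list(), imaging = FALSE) {
  stopifnot(is.character(feature), length(feature) == 1L, nzchar(feature))
  structure(list(feature = feature, variables = variables, kind = kind,
                 params = params, imaging = isTRUE(imaging)),
            class = "sp_rule")
}

#' @rdname rules
#' @export
rule_threshold <- function(feature, variable, cutoff, direction = c("ge", "gt"),
                           imaging = FALSE) {
  direction <- match.arg(direction)
  new_rule(feature, variable, "threshold",
           list(cutoff = cutoff, direction = direction), imaging)
}

#' @rdname rules
#' @export
rule_category <- function(feature, variable, unfavorable, imaging = FALSE) {
  new_rule(feature, variable, "category", list(unfavorable = unfavorable), imaging)
}

#' @rdname rules
#' @export
rule_binary <- function(feature, variable, imaging = FALSE) {
  new_rule(feature, variable, "binary", list(), imaging)
}

#' Composite lesion-burden rule
#'
#' Unfavorable when the lesion count exceeds `count_threshold`, or when there
#' are 2..`count_threshold` lesions and the reference diameter exceeds
#' `diameter_cutoff` mm.  A solitary lesion is favorable regardless of size
#' (size is covered by the separate main-diameter rules).
#'
#' @param feature feature name.
#' @param count_variable raw variable holding the lesion count.
#' @param diameter_variable raw variable holding the reference diameter (mm).
#' @param count_threshold lesion count above which the burden is unfavorable.
#' @param diameter_cutoff diameter (mm) above which 2-3 lesions are unfavorable.
#' @export
rule_lesion_burden <- function(feature = "lesion_burden",
                               count_variable = "n_lesions",
                               diameter_variable = "main_diameter_mm",
                               count_threshold = 3, diameter_cutoff = 30) {
  new_rule(feature, c(count_variable, diameter_variable), "lesion_burden",
           list(count_threshold = count_threshold,
                diameter_cutoff = diameter_cutoff), imaging = TRUE)
}

#' Bundle rules into an ordered rule set
#'
#' @param ... `sp_rule` objects, in feature-priority order.
#' @return an object of class `sp_rules`.
#' @export
rule_set <- function(...) {
  rules <- list(...)
  if (length(rules) == 1L && is.list(rules[[1]]) && !inherits(rules[[1]], "sp_rule"))
    rules <- rules[[1]]
  ok <- vapply(rules, inherits, logical(1), what = "sp_rule")
  if (!all(ok)) stop("all elements must be sp_rule objects")
  feats <- vapply(rules, `[[`, character(1), "feature")
  if (anyDuplicated(feats)) stop("duplicate feature names: ",
                                 paste(unique(feats[duplicated(feats)]), collapse = ", "))
  structure(rules, class = "sp_rules")
}

#' @export
print.sp_rules <- function(x, ...) {
  cat("Dichotomization rule set:", length(x), "features\n")
  for (r in x)
    cat(sprintf("  %-22s <- %-28s [%s]%s\n", r$feature,
                paste(r$variables, collapse = " + "), r$kind,
                if (r$imaging) " (imaging)" else ""))
  invisible(x)
}

rule_features <- function(rules) vapply(rules, `[[`, character(1), "feature")
rule_variables <- function(rules) unique(unlist(lapply(rules, `[[`, "variables")))
imaging_variables <- function(rules)
  unique(unlist(lapply(rules[vapply(rules, `[[`, logical(1), "imaging")],
                       `[[`, "variables")))

#' Check a rule set against the variables present in a cohort
#'
#' @param rules an `sp_rules` set.
#' @param known_variables character vector of raw variable names observed in
#'   the measurement table.
#' @return invisibly `TRUE`; unknown source variables raise a configuration
#'   error naming them.
#' @export
check_rules <- function(rules, known_variables) {
  missing <- setdiff(rule_variables(rules), known_variables)
  if (length(missing))
    stop("configuration error: unknown source variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# value(s) -> 0/1/NA for one rule; `values` is a named list of scalars
apply_rule <- function(rule, values) {
  v <- values[rule$variables]
  if (any(vapply(v, function(x) is.null(x) || (length(x) == 1L && is.na(x)), logical(1))))
    return(NA_integer_)
  switch(rule$kind,
    threshold = {
      x <- as.numeric(v[[1]])
      cut <- rule$params$cutoff
      as.integer(if (rule$params$direction == "ge") x >= cut else x > cut)
    },
    category = as.integer(as.character(v[[1]]) %in% as.character(rule$params$unfavorable)),
    binary = as.integer(as.numeric(v[[1]]) > 0),
    lesion_burden = {
      n <- as.numeric(v[[1]]); d <- as.numeric(v[[2]])
      as.integer(n > rule$params$count_threshold ||
                   (n >= 2 && d > rule$params$diameter_cutoff))
    },
    stop("unknown rule kind: ", rule$kind))
}

#' Default rule set for a BCLC-stage-B HCC-like cohort
#'
#' Nine raw variable groups are dichotomized into 14 binary features:
#' serum AFP at 200 and 400 IU/ml; Child-Pugh class (B/C vs A, and C vs A/B);
#' main-lesion diameter at 50, 70 and 100 mm; a composite lesion burden
#' (solitary or 2-3 lesions with reference diameter <= 30 mm favorable vs
#' more than 3 lesions or 2-3 lesions larger than 30 mm); lesion count at 4;
#' vascular invasion; distant metastasis; the combined vascular-invasion/
#' nodal/metastasis flag; presence of viable lesion after treatment; and
#' performance status above 2.
#'
#' @return an `sp_rules` set in the fixed priority order described above.
#' @export
default_hcc_rules <- function() {
  rule_set(
    rule_threshold("afp_ge_200", "afp", 200, "ge"),
    rule_threshold("afp_ge_400", "afp", 400, "ge"),
    rule_category("child_pugh_bc", "child_pugh", c("B", "C")),
    rule_category("child_pugh_c", "child_pugh", "C"),
    rule_threshold("main_diam_gt_50", "main_diameter_mm", 50, "gt", imaging = TRUE),
    rule_threshold("main_diam_gt_70", "main_diameter_mm", 70, "gt", imaging = TRUE),
    rule_threshold("main_diam_gt_100", "main_diameter_mm", 100, "gt", imaging = TRUE),
    rule_lesion_burden(),
    rule_threshold("lesions_ge_4", "n_lesions", 4, "ge", imaging = TRUE),
    rule_binary("vascular_invasion", "vascular_invasion", imaging = TRUE),
    rule_binary("distant_metastasis", "distant_metastasis", imaging = TRUE),
    rule_binary("vasc_inv_n1_m1", "vasc_inv_n1_m1", imaging = TRUE),
    rule_binary("viable_lesion", "viable_lesion", imaging = TRUE),
    rule_threshold("ps_gt_2", "performance_status", 2, "gt")
  )
}

#' Identity rules for already-binary simulated variables
#'
#' @param variables character vector of binary variable names.
#' @return an `sp_rules` set with one pass-through rule per variable, all
#'   marked as imaging so measurement times anchor slice origins.
#' @export
binary_rules <- function(variables) {
  rule_set(lapply(variables, function(v) rule_binary(v, v, imaging = TRUE)))
}

#' Read / write rule sets as structured config files
#'
#' The on-disk format is YAML: a list of records with fields `feature`,
#' `variables`, `kind`, `params`, `imaging`.
#'
#' @param rules an `sp_rules` set.
#' @param path file path.
#' @return `read_rules` returns an `sp_rules` set.
#' @export
write_rules <- function(rules, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for rule-set files")
  recs <- lapply(rules, function(r)
    list(feature = r$feature, variables = as.list(r$variables), kind = r$kind,
         params = r$params, imaging = r$imaging))
  writeLines(yaml::as.yaml(recs), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for rule-set files")
  recs <- yaml::read_yaml(path)
  rule_set(lapply(recs, function(r)
    new_rule(r$feature, unlist(r$variables), r$kind, r$params, isTRUE(r$imaging))))
}

#' Dichotomize one patient's measurements at one time slice
#'
#' For each rule the newest in-window value of each source variable is
#' selected (ties on time resolved by last record in file order) and the
#' rule's predicate applied.  If any source variable required by any rule
#' has no in-window value the whole vector is missing: a slice is only
#' usable with complete data.
#'
#' @param measurements data frame with columns `time_months`, `variable`,
#'   `value` for a single patient.
#' @param slice_idx slice index in `1..m`.
#' @param rules an `sp_rules` set.
#' @param cfg a [slice_config()].
#' @param known_variables optional character vector of the cohort-wide
#'   variable universe; when given, rules naming variables outside it raise
#'   a configuration error.
#' @return named integer vector of 0/1 features, or `NULL` when the slice is
#'   incomplete.
#' @export
dichotomize <- function(measurements, slice_idx, rules, cfg = slice_config(),
                        known_variables = NULL) {
  stopifnot(inherits(rules, "sp_rules"), length(rules) > 0L)
  if (slice_idx < 1L || slice_idx > cfg$m) stop("slice_idx out of 1..m")
  if (!is.null(known_variables)) check_rules(rules, known_variables)
  w <- slice_window(cfg, slice_idx)
  inw <- measurements$time_months >= w[1] & measurements$time_months <= w[2]
  if (slice_idx > 1L) inw <- measurements$time_months > w[1] &
      measurements$time_months <= w[2]
  ms <- measurements[inw, , drop = FALSE]
  values <- newest_values(ms)
  out <- vapply(rules, apply_rule, integer(1), values = values)
  names(out) <- rule_features(rules)
  if (anyNA(out)) return(NULL)
  out
}

# newest value per variable; ties on time broken by last record in file order
newest_values <- function(ms) {
  if (nrow(ms) == 0L) return(list())
  ord <- order(ms$variable, ms$time_months)  # stable: file order preserved in ties
  ms <- ms[ord, , drop = FALSE]
  last <- !duplicated(ms$variable, fromLast = TRUE)
  stats::setNames(as.list(ms$value[last]), ms$variable[last])
}
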