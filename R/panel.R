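#' Build the patients-by-slices feature panel
#'
#' Projects irregular longitudinal measurements onto the fixed slice grid.
#' For each patient and slice the newest in-window value of every source
#' variable is dichotomized by the rule set.  Each cell carries one of three
#' statuses:
#'
#' * `complete` -- every feature computable from in-window data;
#' * `no_surveillance` -- the patient is alive at the window opening but the
#'   slice data are incomplete; by default this state is irrevocable (all
#'   later living slices are also `no_surveillance`);
#' * `nonexistent` -- the window opens at or after the patient's death or
#'   loss to follow-up.
#'
#' Overall survival from a slice is measured from that slice's time origin:
#' diagnosis (time 0) for slice 1, and the earliest imaging examination
#' inside the window (falling back to the window opening when no imaging
#' timestamp is available) for later slices.
#'
#' @param x an [cohort()] object.
#' @param cfg a [slice_config()].
#' @param rules an `sp_rules` dichotomization set.
#' @param sticky_dropout logical; `TRUE` (default, the canonical reading)
#'   makes `no_surveillance` propagate to all subsequent living slices.
#'   `FALSE` lets surveillance resume when a later slice is complete
#'   (non-canonical, provided for sensitivity analysis).
#' @return an object of class `slice_panel`.
#' @export
build_slice_panel <- function(x, cfg = slice_config(), rules = default_hcc_rules(),
                              sticky_dropout = TRUE) {
  stopifnot(inherits(x, "sp_cohort"), inherits(cfg, "slice_config"),
            inherits(rules, "sp_rules"))
  check_rules(rules, unique(x$measurements$variable))
  ids <- x$outcomes$patient_id
  n <- length(ids)
  m <- cfg$m
  os <- x$outcomes$os_months
  event <- as.integer(x$outcomes$event)
  feats <- rule_features(rules)
  k <- length(feats)

  ms <- x$measurements
  ms$slice <- slice_of_time(cfg, ms$time_months)
  ms <- ms[!is.na(ms$slice), , drop = FALSE]
  # newest value per (patient, slice, variable); stable order keeps file
  # order so equal times resolve to the last record
  ord <- order(ms$patient_id, ms$slice, ms$variable, ms$time_months)
  ms <- ms[ord, , drop = FALSE]
  key <- paste(ms$patient_id, ms$slice, ms$variable, sep = "\r")
  newest <- ms[!duplicated(key, fromLast = TRUE), , drop = FALSE]

  pidx <- match(newest$patient_id, ids)
  vars <- rule_variables(rules)
  imag <- imaging_variables(rules)

  feature_mats <- vector("list", m)
  origin <- matrix(NA_real_, n, m, dimnames = list(ids, NULL))
  status <- matrix("no_surveillance", n, m, dimnames = list(ids, NULL))

  for (ts in seq_len(m)) {
    sel <- newest$slice == ts
    vm <- matrix(NA_character_, n, length(vars), dimnames = list(ids, vars))
    hit <- sel & newest$variable %in% vars
    vm[cbind(pidx[hit], match(newest$variable[hit], vars))] <-
      as.character(newest$value[hit])
    vlist <- stats::setNames(lapply(seq_along(vars), function(j) vm[, j]), vars)
    fm <- matrix(NA_integer_, n, k, dimnames = list(ids, feats))
    for (j in seq_len(k)) fm[, j] <- apply_rule_vec(rules[[j]], vlist)
    feature_mats[[ts]] <- fm

    w <- slice_window(cfg, ts)
    if (ts == 1L) {
      origin[, ts] <- 0
    } else {
      im <- sel & ms_in(newest$variable, imag)
      o <- rep(w[1], n)
      if (any(im)) {
        tmin <- tapply(newest$time_months[im], pidx[im], min)
        o[as.integer(names(tmin))] <- tmin
      }
      origin[, ts] <- o
    }

    complete <- !apply(is.na(fm), 1L, any)
    gone <- os <= w[1] + 1e-9           # window opens at/after death or LTFU
    status[gone, ts] <- "nonexistent"
    status[complete & !gone, ts] <- "complete"
  }
  if (sticky_dropout) {
    for (ts in seq_len(m - 1L)) {
      ns <- status[, ts] == "no_surveillance"
      later <- (ts + 1L):m
      status[ns, later][status[ns, later, drop = FALSE] == "complete"] <-
        "no_surveillance"
    }
  }
  os_slice <- os - origin

  structure(list(patient_id = ids, status = status, features = feature_mats,
                 origin = origin, os_slice = os_slice, os_months = os,
                 event = event, feature_names = feats, cfg = cfg,
                 rules = rules, sticky_dropout = sticky_dropout),
            class = "slice_panel")
}

ms_in <- function(x, set) if (length(set)) x %in% set else rep(FALSE, length(x))

# vectorized rule application over a named list of per-patient value vectors
apply_rule_vec <- function(rule, vlist) {
  v1 <- vlist[[rule$variables[1]]]
  out <- switch(rule$kind,
    threshold = {
      x <- suppressWarnings(as.numeric(v1))
      if (rule$params$direction == "ge") as.integer(x >= rule$params$cutoff)
      else as.integer(x > rule$params$cutoff)
    },
    category = ifelse(is.na(v1), NA_integer_,
                      as.integer(v1 %in% as.character(rule$params$unfavorable))),
    binary = as.integer(suppressWarnings(as.numeric(v1)) > 0),
    lesion_burden = {
      nles <- suppressWarnings(as.numeric(v1))
      d <- suppressWarnings(as.numeric(vlist[[rule$variables[2]]]))
      as.integer(nles > rule$params$count_threshold |
                   (nles >= 2 & nles <= rule$params$count_threshold &
                      d > rule$params$diameter_cutoff))
    },
    stop("unknown rule kind: ", rule$kind))
  out
}

#' @export
print.slice_panel <- function(x, ...) {
  cat(sprintf("slice_panel: %d patients x %d slices, %d features\n",
              length(x$patient_id), x$cfg$m, length(x$feature_names)))
  tab <- apply(x$status, 2L, function(s) sum(s == "complete"))
  cat("  complete per slice:", paste(tab, collapse = ", "), "\n")
  invisible(x)
}

#' Per-slice overall survival for one patient
#'
#' Slice 1 measures OS from diagnosis; later slices measure OS from the
#' slice's imaging origin.  Requesting OS for a slice without complete data
#' is a contract violation.
#'
#' @param panel a [build_slice_panel()] result.
#' @param patient_id patient identifier.
#' @param slice_idx slice index.
#' @return list with `time` (months) and `event` (1 = death).
#' @export
slice_os <- function(panel, patient_id, slice_idx) {
  i <- match(as.character(patient_id), panel$patient_id)
  if (is.na(i)) stop("unknown patient: ", patient_id)
  if (panel$status[i, slice_idx] != "complete")
    stop("contract violation: slice ", slice_idx, " of patient ", patient_id,
         " is ", panel$status[i, slice_idx], ", not complete")
  list(time = unname(panel$os_slice[i, slice_idx]), event = panel$event[i])
}

#' Assemble modelling data for a set of patients at one slice
#'
#' @param panel a `slice_panel`.
#' @param ids patient identifiers (must be complete at the slice).
#' @param slice_idx slice index.
#' @return data frame with columns `os`, `event` and one 0/1 column per
#'   feature, rownames the patient ids.
#' @export
node_data <- function(panel, ids, slice_idx) {
  i <- match(as.character(ids), panel$patient_id)
  if (anyNA(i)) stop("unknown patient id(s)")
  bad <- panel$status[i, slice_idx] != "complete"
  if (any(bad))
    stop("contract violation: non-complete patients at slice ", slice_idx)
  df <- data.frame(os = panel$os_slice[i, slice_idx], event = panel$event[i],
                   panel$features[[slice_idx]][i, , drop = FALSE],
                   check.names = FALSE)
  rownames(df) <- panel$patient_id[i]
  df
}

#' Patients with complete data at a slice
#'
#' @param panel a `slice_panel`.
#' @param slice_idx slice index.
#' @param within optional id subset to intersect with.
#' @return character vector of patient ids.
#' @export
complete_ids <- function(panel, slice_idx, within = NULL) {
  ids <- panel$patient_id[panel$status[, slice_idx] == "complete"]
  if (!is.null(within)) ids <- ids[ids %in% within]
  ids
}

#' Write / read a slice panel as plain-text files
#'
#' `write_panel` emits `cells.csv` (one row per patient-slice with status,
#' origin and per-slice OS), `features.csv` (long table of 0/1 features for
#' complete cells) and `panel.json` (config, rule echo, outcomes), such that
#' `read_panel` reconstructs a bit-identical panel.
#'
#' @param panel a `slice_panel`.
#' @param dir directory.
#' @return `read_panel` returns a `slice_panel`.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(panel$patient_id); m <- panel$cfg$m
  cells <- data.frame(patient_id = rep(panel$patient_id, m),
                      slice = rep(seq_len(m), each = n),
                      status = as.vector(panel$status),
                      origin = as.vector(panel$origin))
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  fl <- do.call(rbind, lapply(seq_len(m), function(ts) {
    fm <- panel$features[[ts]]
    idx <- which(!is.na(fm), arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(patient_id = panel$patient_id[idx[, 1]], slice = ts,
               feature = panel$feature_names[idx[, 2]], value = fm[idx])
  }))
  if (is.null(fl))
    fl <- data.frame(patient_id = character(), slice = integer(),
                     feature = character(), value = integer())
  utils::write.csv(fl, file.path(dir, "features.csv"), row.names = FALSE)
  meta <- list(interval = panel$cfg$interval, horizon = panel$cfg$horizon,
               patient_id = panel$patient_id, os_months = panel$os_months,
               event = panel$event, feature_names = panel$feature_names,
               sticky_dropout = panel$sticky_dropout)
  jsonlite::write_json(meta, file.path(dir, "panel.json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_panel
#' @param rules rule set to attach to the re-read panel (rule logic is not
#'   serialized with the cell data).
#' @export
read_panel <- function(dir, rules = NULL) {
  meta <- jsonlite::read_json(file.path(dir, "panel.json"), simplifyVector = TRUE)
  cfg <- slice_config(meta$interval, meta$horizon)
  ids <- meta$patient_id; n <- length(ids); m <- cfg$m
  cells <- utils::read.csv(file.path(dir, "cells.csv"), stringsAsFactors = FALSE)
  cells$patient_id <- as.character(cells$patient_id)
  fl <- utils::read.csv(file.path(dir, "features.csv"), stringsAsFactors = FALSE)
  fl$patient_id <- as.character(fl$patient_id)
  status <- matrix("no_surveillance", n, m, dimnames = list(ids, NULL))
  origin <- matrix(NA_real_, n, m, dimnames = list(ids, NULL))
  ij <- cbind(match(cells$patient_id, ids), cells$slice)
  status[ij] <- cells$status
  origin[ij] <- cells$origin
  feats <- meta$feature_names
  fmats <- lapply(seq_len(m), function(ts) {
    fm <- matrix(NA_integer_, n, length(feats), dimnames = list(ids, feats))
    sub <- fl[fl$slice == ts, , drop = FALSE]
    if (nrow(sub))
      fm[cbind(match(sub$patient_id, ids), match(sub$feature, feats))] <-
        as.integer(sub$value)
    fm
  })
  structure(list(patient_id = ids, status = status, features = fmats,
                 origin = origin, os_slice = meta$os_months - origin,
                 os_months = meta$os_months, event = as.integer(meta$event),
                 feature_names = feats, cfg = cfg, rules = rules,
                 sticky_dropout = isTRUE(meta$sticky_dropout)),
            class = "slice_panel")
}
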