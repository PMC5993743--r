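#' Sample-size gate for multivariable Cox selection
#'
#' A node only proceeds to feature selection when it can support a
#' multivariable Cox model.  The default rule is the events-per-variable
#' heuristic: at least `epv` observed deaths per candidate entering the
#' model (candidates counted after screening).  The alternative `"power"`
#' rule uses the Schoenfeld required-events formula
#' `D = (z[1-alpha/2] + z[power])^2 / (prev (1-prev) log(hr)^2)`.
#' A node with no deaths, or no candidates, never passes.
#'
#' @param data node data frame (only its `event` column is used), or a
#'   single number of observed deaths.
#' @param n_candidates number of candidate features entering the model.
#' @param rule `"epv"` (default) or `"power"`.
#' @param epv required events per variable (default 10).
#' @param alpha,power,hr,prevalence parameters of the power rule.
#' @return `TRUE` when selection may proceed.
#' @export
sample_size_gate <- function(data, n_candidates, rule = c("epv", "power"),
                             epv = 10, alpha = 0.006, power = 0.8, hr = 2,
                             prevalence = 0.5) {
  rule <- match.arg(rule)
  d <- if (is.data.frame(data)) sum(data$event) else as.numeric(data)
  if (d <= 0 || n_candidates < 1L) return(FALSE)
  if (rule == "epv") return(d >= epv * n_candidates)
  need <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 /
    (prevalence * (1 - prevalence) * log(hr)^2)
  d >= need
}

node_id <- function(p, ts) sprintf("p%d.t%d", p, ts)

#' @export
format.sp_node <- function(x, ...) sprintf("S(p=%d, ts=%d)", x$p, x$ts)

new_node <- function(p, ts, members, median, excluded, parent_id, curve_max) {
  structure(list(p = p, ts = ts, id = node_id(p, ts), members = members,
                 n = length(members), median = median, curve_max = curve_max,
                 excluded = excluded, parent_id = parent_id,
                 split_feature = NA_character_, upper_id = NA_character_,
                 lower_id = NA_character_, upper_value = NA_integer_,
                 child_id = NA_character_, classification = character(0),
                 trace = NULL),
            class = "sp_node")
}

#' Build the survival map
#'
#' Breadth-first over slices: the whole cohort (complete at slice 1) is the
#' root group; each group at slice `ts` is screened, gated and, when a
#' feature is selected, bifurcated into an upper (longer median OS) and a
#' lower child at the same slice; every resulting node advances its members
#' (those still complete) to the next slice, where the cycle repeats until
#' the last slice.  Nodes with fewer than `min_node` members are marked
#' excluded, never split, and are dropped from rendered output and c-index
#' computation.  Construction is deterministic: no randomness, total
#' tie-breaks.
#'
#' @param panel a [build_slice_panel()] result.
#' @param sel_cfg a [selection_config()]; defaults to family level 0.05 over
#'   the panel's `m` slices.
#' @param gate gate rule passed to [sample_size_gate()].
#' @param epv events-per-variable for the default gate.
#' @param min_node minimum node size (default 6).
#' @param gate_args extra arguments for the power gate.
#' @return an object of class `survival_map`.
#' @export
build_survival_map <- function(panel, sel_cfg = NULL, gate = "epv", epv = 10,
                               min_node = 6L, gate_args = list()) {
  stopifnot(inherits(panel, "slice_panel"))
  if (is.null(sel_cfg)) sel_cfg <- selection_config(m = panel$cfg$m)
  m <- panel$cfg$m
  root_members <- complete_ids(panel, 1L)
  if (length(root_members) == 0L) stop("empty panel: no complete data at slice 1")

  nodes <- list()
  next_path <- 1L
  new_path <- function() { p <- next_path; next_path <<- next_path + 1L; p }
  root <- list(id = "root", split_feature = NA_character_,
               upper_id = NA_character_, lower_id = NA_character_,
               upper_value = NA_integer_, child_id = NA_character_,
               n = length(root_members), trace = NULL)

  # groups: members inherited from a parent node (or the root), to be
  # realized and possibly split at slice ts
  groups <- list(list(p = new_path(), incoming = root_members, ts = 1L,
                      parent = "root"))
  set_child <- function(parent, field, value) {
    if (parent == "root") root[[field]] <<- value
    else nodes[[parent]][[field]] <<- value
  }

  for (ts in seq_len(m)) {
    here <- Filter(function(g) g$ts == ts, groups)
    groups <- Filter(function(g) g$ts > ts, groups)
    for (g in here) {
      members <- complete_ids(panel, ts, within = g$incoming)
      if (length(members) == 0L) next
      dat <- node_data(panel, members, ts)
      km <- km_median_os(dat$os, dat$event)
      excluded <- length(members) < min_node

      split <- NULL
      trace <- NULL
      if (!excluded) {
        screened <- suppressWarnings(
          km_screen(dat, sel_cfg$alpha, sel_cfg$min_level_count))
        trace <- list(screen_p = attr(screened, "p_values"),
                      screened = as.character(screened))
        ok <- do.call(sample_size_gate,
                      c(list(dat, length(screened), rule = gate, epv = epv),
                        gate_args))
        if (ok) {
          feat <- select_split_feature(dat, sel_cfg, screened = screened)
          trace <- attr(feat, "trace")
          if (length(feat) == 1L) split <- as.character(feat)
        }
      }

      if (is.null(split)) {
        nd <- new_node(g$p, ts, members, km$median, excluded, g$parent,
                       max(dat$os))
        nd$trace <- trace
        nodes[[nd$id]] <- nd
        set_child(g$parent, "child_id", nd$id)
        if (ts < m)
          groups <- c(groups, list(list(p = g$p, incoming = members,
                                        ts = ts + 1L, parent = nd$id)))
      } else {
        val <- dat[[split]]
        side <- list(`0` = members[val == 0], `1` = members[val == 1])
        meds <- lapply(side, function(ids) {
          d <- dat[match(ids, members), ]
          km_median_os(d$os, d$event)
        })
        rank_med <- vapply(meds, function(x)
          if (is.na(x$median)) Inf else x$median, numeric(1))
        upper_val <- if (rank_med[["1"]] > rank_med[["0"]]) 1L else 0L
        lower_val <- 1L - upper_val
        up_ids <- side[[as.character(upper_val)]]
        lo_ids <- side[[as.character(lower_val)]]
        up <- new_node(g$p, ts, up_ids, meds[[as.character(upper_val)]]$median,
                       length(up_ids) < min_node, g$parent,
                       max(dat$os[val == upper_val]))
        lo <- new_node(new_path(), ts, lo_ids,
                       meds[[as.character(lower_val)]]$median,
                       length(lo_ids) < min_node, g$parent,
                       max(dat$os[val == lower_val]))
        nodes[[up$id]] <- up
        nodes[[lo$id]] <- lo
        set_child(g$parent, "split_feature", split)
        set_child(g$parent, "upper_id", up$id)
        set_child(g$parent, "lower_id", lo$id)
        set_child(g$parent, "upper_value", upper_val)
        if (g$parent != "root") nodes[[g$parent]]$trace <- trace
        else root$trace <- trace
        if (ts < m) {
          groups <- c(groups,
                      list(list(p = up$p, incoming = up_ids, ts = ts + 1L,
                                parent = up$id),
                           list(p = lo$p, incoming = lo_ids, ts = ts + 1L,
                                parent = lo$id)))
        }
      }
    }
  }

  map <- structure(list(nodes = nodes, root = root, cfg = panel$cfg,
                        sel_cfg = sel_cfg, gate = gate, epv = epv,
                        min_node = as.integer(min_node),
                        feature_names = panel$feature_names,
                        n_paths = next_path - 1L),
                   class = "survival_map")
  map <- renumber_paths(map)
  map$slice_counts <- slice_counts(map)
  map
}

# relabel paths 1..K top-to-bottom by terminal-node median OS (undefined
# median ranks best); the upper child keeps its parent's index by
# construction, so whole chains are relabelled consistently
renumber_paths <- function(map) {
  paths <- sort(unique(vapply(map$nodes, `[[`, integer(1), "p")))
  term <- vapply(paths, function(p) {
    ns <- Filter(function(nd) nd$p == p, map$nodes)
    ts <- vapply(ns, `[[`, integer(1), "ts")
    nd <- ns[[which.max(ts)]]
    if (is.na(nd$median)) Inf else nd$median
  }, numeric(1))
  ord <- order(-term, paths)
  relabel <- stats::setNames(seq_along(paths), paths[ord])
  old_ids <- names(map$nodes)
  for (id in old_ids) {
    nd <- map$nodes[[id]]
    nd$p <- unname(relabel[as.character(nd$p)])
    nd$id <- node_id(nd$p, nd$ts)
    map$nodes[[id]] <- nd
  }
  id_map <- stats::setNames(vapply(map$nodes, `[[`, character(1), "id"), old_ids)
  fix <- function(x) if (is.na(x) || x == "root") x else unname(id_map[x])
  for (id in old_ids) {
    nd <- map$nodes[[id]]
    nd$parent_id <- fix(nd$parent_id)
    nd$upper_id <- fix(nd$upper_id)
    nd$lower_id <- fix(nd$lower_id)
    nd$child_id <- fix(nd$child_id)
    map$nodes[[id]] <- nd
  }
  names(map$nodes) <- unname(id_map[old_ids])
  for (f in c("upper_id", "lower_id", "child_id"))
    if (!is.na(map$root[[f]])) map$root[[f]] <- unname(id_map[map$root[[f]]])
  map$n_paths <- length(paths)
  ord2 <- order(vapply(map$nodes, `[[`, integer(1), "ts"),
                vapply(map$nodes, `[[`, integer(1), "p"))
  map$nodes <- map$nodes[ord2]
  map
}

slice_counts <- function(map) {
  ts <- vapply(map$nodes, `[[`, integer(1), "ts")
  excl <- vapply(map$nodes, `[[`, logical(1), "excluded")
  m <- map$cfg$m
  data.frame(slice = seq_len(m),
             nodes = vapply(seq_len(m), function(t) sum(ts == t), integer(1)),
             rendered = vapply(seq_len(m), function(t) sum(ts == t & !excl),
                               integer(1)))
}

#' @export
print.survival_map <- function(x, ...) {
  cat(sprintf("survival_map: %d paths, %d nodes over %d slices (alpha = %.4g, gate = %s, min node %d)\n",
              x$n_paths, length(x$nodes), x$cfg$m, x$sel_cfg$alpha, x$gate,
              x$min_node))
  cat("  subclasses per slice:", paste(x$slice_counts$nodes, collapse = ", "), "\n")
  bf <- map_bifurcations(x)
  if (nrow(bf))
    cat("  bifurcations:", paste(bf$label, "on", bf$feature, collapse = "; "), "\n")
  invisible(x)
}

#' Node summary table
#'
#' @param map a `survival_map`.
#' @return data frame with one row per node: path, slice, size, median OS,
#'   exclusion flag, split feature and family links.
#' @export
map_nodes_df <- function(map) {
  do.call(rbind, lapply(unname(map$nodes), function(nd)
    data.frame(id = nd$id, p = nd$p, ts = nd$ts, n = nd$n,
               median_os = nd$median, excluded = nd$excluded,
               split_feature = nd$split_feature, parent = nd$parent_id,
               upper = nd$upper_id, lower = nd$lower_id, child = nd$child_id,
               classification = paste(nd$classification, collapse = "+"),
               stringsAsFactors = FALSE)))
}

#' Bifurcation table
#'
#' One row per bifurcating node (including the root, labelled
#' `S(all; ts=1)`), with the selected feature and the children.
#'
#' @param map a `survival_map`.
#' @return data frame `label`, `parent_id`, `feature`, `upper_id`, `lower_id`.
#' @export
map_bifurcations <- function(map) {
  out <- list()
  if (!is.na(map$root$split_feature))
    out[[length(out) + 1L]] <- data.frame(
      label = "S(all; ts=1)", parent_id = "root",
      feature = map$root$split_feature, upper_id = map$root$upper_id,
      lower_id = map$root$lower_id, stringsAsFactors = FALSE)
  for (nd in map$nodes)
    if (!is.na(nd$split_feature))
      out[[length(out) + 1L]] <- data.frame(
        label = sprintf("S(p=%d, ts=%d)", nd$p, nd$ts), parent_id = nd$id,
        feature = nd$split_feature, upper_id = nd$upper_id,
        lower_id = nd$lower_id, stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(label = character(), parent_id = character(),
                      feature = character(), upper_id = character(),
                      lower_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-bifurcation hazard ratios
#'
#' Evaluates every bifurcation of the map with [bifurcation_hr()]: the
#' children's members at the child slice, overall survival measured from
#' that slice.
#'
#' @param map a `survival_map`.
#' @param panel the panel the map was built from (or a compatible panel for
#'   external validation).
#' @return data frame `label`, `feature`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `method`, `n_upper`, `n_lower`.
#' @export
map_bifurcation_tests <- function(map, panel) {
  bf <- map_bifurcations(map)
  if (!nrow(bf)) return(cbind(bf, hr = numeric(0)))
  rows <- lapply(seq_len(nrow(bf)), function(i) {
    up <- map$nodes[[bf$upper_id[i]]]
    lo <- map$nodes[[bf$lower_id[i]]]
    iu <- match(up$members, panel$patient_id)
    il <- match(lo$members, panel$patient_id)
    r <- bifurcation_hr(panel$os_slice[iu, up$ts], panel$event[iu],
                        panel$os_slice[il, lo$ts], panel$event[il],
                        min_side = map$min_node)
    data.frame(label = bf$label[i], feature = bf$feature[i], hr = r$hr,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               method = r$method, n_upper = r$n_upper, n_lower = r$n_lower,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# surgery/ablation events of given patients inside (open, close]
treated_ids <- function(treatments, ids, open, close,
                        kinds = c("surgery", "ablation")) {
  tr <- treatments[treatments$patient_id %in% ids &
                     treatments$kind %in% kinds &
                     treatments$time_months > open &
                     treatments$time_months <= close, , drop = FALSE]
  unique(tr$patient_id)
}

#' Classify map nodes and analyse treatment transitions
#'
#' For every bifurcating (non-root) node, cross-tabulates surgery/ablation
#' received between the node's window opening and the child slice's window
#' closing against the member's fate (upper child, lower child, died or no
#' surveillance), and applies the rule-based classifications:
#'
#' * *chance node* -- the upper child's median OS exceeds the lower child's
#'   by at least `chance_gap` months **and** more than `chance_rate` percent
#'   of treated members transfer to the upper child;
#' * *incurable node* -- a bifurcated node with no valid (at least
#'   `min_node`-member) child and median OS below `incurable_median` months;
#' * *long-term path* -- a path whose terminal node's median OS exceeds
#'   `long_term` months (an undefined median qualifies when follow-up in the
#'   node extends beyond `long_term`).
#'
#' @param map a `survival_map`.
#' @param treatments treatment-event table (`patient_id, time_months, kind`).
#' @param chance_gap,chance_rate,incurable_median,long_term rule constants
#'   (months, percent, months, months); defaults 10, 80, 5, 60.
#' @return the map with per-node `classification` filled, a `transitions`
#'   element (list of `sp_transition` keyed by node id) and
#'   `long_term_paths`.
#' @export
classify_nodes <- function(map, treatments = NULL, chance_gap = 10,
                           chance_rate = 80, incurable_median = 5,
                           long_term = 60) {
  if (is.null(treatments))
    treatments <- data.frame(patient_id = character(), time_months = numeric(),
                             kind = character(), stringsAsFactors = FALSE)
  transitions <- list()
  for (id in names(map$nodes)) {
    nd <- map$nodes[[id]]
    if (is.na(nd$split_feature)) next
    up <- map$nodes[[nd$upper_id]]
    lo <- map$nodes[[nd$lower_id]]
    open <- slice_window(map$cfg, nd$ts)[1]
    close <- slice_window(map$cfg, up$ts)[2]
    tr <- treated_ids(treatments, nd$members, open, close)
    fate <- ifelse(nd$members %in% up$members, "go_up",
                   ifelse(nd$members %in% lo$members, "go_down", "died_ns"))
    treated <- nd$members %in% tr
    counts <- rbind(
      with_surgery_ablation = c(sum(treated & fate == "go_up"),
                                sum(treated & fate == "go_down"),
                                sum(treated & fate == "died_ns")),
      without = c(sum(!treated & fate == "go_up"),
                  sum(!treated & fate == "go_down"),
                  sum(!treated & fate == "died_ns")))
    ta <- transition_analysis(counts)
    ta$node <- sprintf("S(p=%d, ts=%d)", nd$p, nd$ts)
    transitions[[id]] <- ta

    cls <- character(0)
    meds_ok <- !is.na(up$median) && !is.na(lo$median)
    gap_ok <- if (is.na(lo$median)) FALSE
              else if (is.na(up$median)) TRUE else (up$median - lo$median) >= chance_gap
    if (gap_ok && sum(treated) > 0 &&
        ta$up_given_treatment > chance_rate)
      cls <- c(cls, "chance")
    no_valid_child <- up$n < map$min_node && lo$n < map$min_node
    if (no_valid_child && !is.na(nd$median) && nd$median < incurable_median)
      cls <- c(cls, "incurable")
    map$nodes[[id]]$classification <- cls
  }
  # long-term paths from terminal nodes
  ps <- vapply(map$nodes, `[[`, integer(1), "p")
  lt <- integer(0)
  for (p in sort(unique(ps))) {
    ns <- Filter(function(nd) nd$p == p, map$nodes)
    nd <- ns[[which.max(vapply(ns, `[[`, integer(1), "ts"))]]
    qualifies <- (!is.na(nd$median) && nd$median > long_term) ||
      (is.na(nd$median) && nd$curve_max > long_term)
    if (qualifies) {
      lt <- c(lt, p)
      map$nodes[[nd$id]]$classification <-
        union(map$nodes[[nd$id]]$classification, "long_term_path")
    }
  }
  map$transitions <- transitions
  map$long_term_paths <- lt
  map
}

#' Route patients through a built map
#'
#' Each patient starts at the root and follows split features slice by
#' slice; at a slice without complete data the trajectory halts with the
#' panel status reported.  The prediction at each slice is the derivation
#' median OS of the occupied node.
#'
#' @param map a `survival_map`.
#' @param panel a panel built with the same rule set (the building panel for
#'   self-consistency, or a new cohort's panel for prospective assignment).
#' @param ids patient ids to route (default: all panel patients).
#' @return data frame `patient_id, slice, node, path, predicted_median_os,
#'   status`; halted trajectories end with a row whose `node` is `NA` and
#'   whose `status` explains why.
#' @export
assign_patients <- function(map, panel, ids = panel$patient_id) {
  if (!identical(map$feature_names, panel$feature_names))
    stop("rule-set mismatch: map features differ from panel features (",
         paste(setdiff(map$feature_names, panel$feature_names), collapse = ", "),
         ")")
  out <- list()
  for (pid in as.character(ids)) {
    i <- match(pid, panel$patient_id)
    if (is.na(i)) stop("unknown patient: ", pid)
    holder <- map$root
    for (ts in seq_len(map$cfg$m)) {
      st <- panel$status[i, ts]
      if (st != "complete") {
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pid, slice = ts, node = NA_character_, path = NA_integer_,
          predicted_median_os = NA_real_, status = st, stringsAsFactors = FALSE)
        break
      }
      nxt <- if (!is.na(holder$split_feature)) {
        v <- panel$features[[ts]][i, holder$split_feature]
        if (is.na(v))
          stop("routing error: feature '", holder$split_feature,
               "' missing for patient ", pid, " at slice ", ts)
        if (v == holder$upper_value) holder$upper_id else holder$lower_id
      } else holder$child_id
      if (is.na(nxt) || is.null(map$nodes[[nxt]])) break
      nd <- map$nodes[[nxt]]
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, slice = ts, node = sprintf("S(p=%d, ts=%d)", nd$p, nd$ts),
        path = nd$p, predicted_median_os = nd$median, status = "complete",
        stringsAsFactors = FALSE)
      holder <- nd
    }
  }
  if (!length(out))
    return(data.frame(patient_id = character(), slice = integer(),
                      node = character(), path = integer(),
                      predicted_median_os = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-slice concordance of the map against comparator systems
#'
#' At each slice, patients in non-excluded nodes are ranked by their node's
#' derivation median OS (shorter median = higher risk) and Harrell's c is
#' computed on OS from that slice.  Comparator systems, supplied as
#' precomputed per-slice ordinal labels, are evaluated on the same patients
#' and compared with the paired jackknife Z test.
#'
#' @param map a `survival_map`.
#' @param panel the panel to evaluate on.
#' @param stages optional data frame `patient_id, slice, system, stage`
#'   (stage ordinal, larger = worse).
#' @param threshold comparison significance level (default 0.006).
#' @param n_boot bootstrap resamples for c-index CIs (0 disables).
#' @param seed bootstrap seed.
#' @return data frame with one row per slice and system: `slice`, `system`,
#'   `n_modeling`, `n_all`, `n_classes`, `c_index`, `ci_low`, `ci_high`,
#'   `z`, `p`, `verdict` (comparators vs the map).
#' @export
evaluate_map <- function(map, panel, stages = NULL, threshold = 0.006,
                         n_boot = 0L, seed = 1L) {
  rows <- list()
  assign_df <- assign_patients(map, panel)
  assign_df <- assign_df[assign_df$status == "complete", , drop = FALSE]
  for (ts in seq_len(map$cfg$m)) {
    sub <- assign_df[assign_df$slice == ts, , drop = FALSE]
    n_all <- length(complete_ids(panel, ts))
    if (nrow(sub) == 0L) next
    # node risk = rank of node by median OS, descending (NA median best)
    nds <- Filter(function(nd) nd$ts == ts && !nd$excluded, map$nodes)
    if (!length(nds)) next
    meds <- vapply(nds, function(nd) if (is.na(nd$median)) Inf else nd$median,
                   numeric(1))
    labels <- vapply(nds, function(nd) sprintf("S(p=%d, ts=%d)", nd$p, nd$ts),
                     character(1))
    risk_of <- stats::setNames(rank(-meds, ties.method = "min"), labels)
    sub <- sub[sub$node %in% labels, , drop = FALSE]
    if (nrow(sub) < 2L) next
    i <- match(sub$patient_id, panel$patient_id)
    os <- panel$os_slice[i, ts]; ev <- panel$event[i]
    risk_map <- unname(risk_of[sub$node])
    ci <- concordance_index(risk_map, os, ev, n_boot = n_boot, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      slice = ts, system = "survival_path", n_modeling = nrow(sub),
      n_all = n_all, n_classes = length(nds), c_index = ci$c_index,
      ci_low = ci$ci_low, ci_high = ci$ci_high, z = NA_real_, p = NA_real_,
      verdict = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(stages)) {
      for (sys in unique(stages$system)) {
        ss <- stages[stages$system == sys & stages$slice == ts, , drop = FALSE]
        j <- match(sub$patient_id, ss$patient_id)
        keep <- !is.na(j)
        if (sum(keep) < 2L) next
        risk_sys <- as.numeric(ss$stage[j[keep]])
        cs <- concordance_index(risk_sys, os[keep], ev[keep],
                                n_boot = n_boot, seed = seed)
        cmp <- compare_cindex(risk_sys, risk_map[keep], os[keep], ev[keep],
                              threshold = threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          slice = ts, system = sys, n_modeling = sum(keep), n_all = n_all,
          n_classes = length(unique(risk_sys)), c_index = cs$c_index,
          ci_low = cs$ci_low, ci_high = cs$ci_high, z = cmp$z, p = cmp$p,
          verdict = switch(cmp$verdict, a_superior = "comparator_superior",
                           b_superior = "map_superior", "no_difference"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
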