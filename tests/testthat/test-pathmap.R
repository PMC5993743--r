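# hand-built minimal map for the classification rules
mini_map <- function() {
  mk <- function(p, ts, members, median, split = NA_character_,
                 upper = NA_character_, lower = NA_character_,
                 child = NA_character_, curve_max = 40) {
    p <- as.integer(p); ts <- as.integer(ts)
    structure(list(p = p, ts = ts, id = sprintf("p%d.t%d", p, ts),
                   members = members, n = length(members), median = median,
                   curve_max = curve_max, excluded = length(members) < 6,
                   parent_id = NA_character_, split_feature = split,
                   upper_id = upper, lower_id = lower, upper_value = 0L,
                   child_id = child, classification = character(0)),
              class = "sp_node")
  }
  m <- sprintf("m%02d", 1:20); q <- paste0("q", 1:8); r <- paste0("r", 1:5)
  s <- paste0("s", 1:8)
  nodes <- list(
    mk(1, 1, m, 12, split = "f", upper = "p1.t2", lower = "p2.t2"),
    mk(1, 2, m[1:8], 21),
    mk(2, 2, m[9:14], 6),
    mk(3, 3, q, 4, split = "g", upper = "p3.t4", lower = "p4.t4"),
    mk(3, 4, r[1:3], 2),
    mk(4, 4, r[4:5], 1),
    mk(5, 2, s, 70, curve_max = 80))
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  structure(list(nodes = nodes,
                 root = list(id = "root", n = 20, split_feature = NA_character_,
                             upper_id = NA, lower_id = NA, upper_value = NA,
                             child_id = "p1.t1"),
                 cfg = slice_config(), sel_cfg = selection_config(),
                 gate = "epv", epv = 10, min_node = 6L,
                 feature_names = c("f", "g"), n_paths = 5L),
            class = "survival_map")
}

test_that("sample-size gate: EPV default and power-formula alternative", {
  d <- function(k) data.frame(event = rep(1L, k))
  expect_false(sample_size_gate(d(0), 3))
  expect_true(sample_size_gate(d(50), 4))
  expect_false(sample_size_gate(d(25), 4))
  expect_false(sample_size_gate(d(50), 0))
  # Schoenfeld formula needs ~107 events at alpha 0.006, power 0.8, HR 2
  expect_false(sample_size_gate(d(100), 3, rule = "power"))
  expect_true(sample_size_gate(d(110), 3, rule = "power"))
})

test_that("map construction: partition, ordering, determinism, exclusion rules", {
  sim <- sim_fixture("planted")
  panel <- build_slice_panel(sim$cohort, slice_config(), sim$rules)
  map <- build_survival_map(panel)

  # every patient with complete data at a slice sits in exactly one node
  for (ts in seq_len(map$cfg$m)) {
    members <- unname(unlist(lapply(Filter(function(nd) nd$ts == ts, map$nodes),
                                    `[[`, "members")))
    expect_identical(sort(members), sort(complete_ids(panel, ts)))
    expect_identical(anyDuplicated(members), 0L)
  }

  # children partition the parent's members that remain complete
  bf <- map_bifurcations(map)
  for (i in seq_len(nrow(bf))) {
    up <- map$nodes[[bf$upper_id[i]]]; lo <- map$nodes[[bf$lower_id[i]]]
    parent_members <- if (bf$parent_id[i] == "root") panel$patient_id
                      else map$nodes[[bf$parent_id[i]]]$members
    expect_identical(sort(c(up$members, lo$members)),
                     sort(complete_ids(panel, up$ts, within = parent_members)))
    # upper child has the longer (or unreached) median
    upm <- if (is.na(up$median)) Inf else up$median
    lom <- if (is.na(lo$median)) Inf else lo$median
    expect_gte(upm, lom)
    # the upper child keeps its parent's path index
    if (bf$parent_id[i] != "root")
      expect_identical(up$p, map$nodes[[bf$parent_id[i]]]$p)
  }

  # node counts can at most double slice to slice
  cnt <- map$slice_counts$nodes
  expect_true(all(cnt[-1] <= 2 * cnt[-length(cnt)]))

  # excluded nodes never parent a split
  for (nd in map$nodes)
    if (nd$excluded) expect_true(is.na(nd$split_feature))

  # paths are numbered top-to-bottom by terminal median OS
  term <- vapply(seq_len(map$n_paths), function(p) {
    ns <- Filter(function(nd) nd$p == p, map$nodes)
    nd <- ns[[which.max(vapply(ns, `[[`, integer(1), "ts"))]]
    if (is.na(nd$median)) Inf else nd$median
  }, numeric(1))
  expect_true(all(diff(term) <= 0))

  # rebuilding from the same panel is bit-identical
  map2 <- build_survival_map(panel)
  expect_identical(map_nodes_df(map), map_nodes_df(map2))
  expect_identical(lapply(map$nodes, `[[`, "members"),
                   lapply(map2$nodes, `[[`, "members"))
})

test_that("a cohort without prognostic structure stays essentially unsplit", {
  sim <- sim_fixture("null")
  panel <- build_slice_panel(sim$cohort, slice_config(), sim$rules)
  map <- build_survival_map(panel)
  expect_lte(map$n_paths, 2)
})

test_that("planted two-level structure is recovered at the planted nodes", {
  feat <- default_sim_features()
  feat$flip01[1:2] <- 0; feat$flip10[1:2] <- 0
  feat$prevalence[1:2] <- 0.5
  cfg <- sim_config(800, seed = 1234, features = feat,
                    planted_splits = list(list(slice = 1, feature = "f1", hr = 3),
                                          list(slice = 2, feature = "f2", hr = 3)),
                    baseline_hazard = 0.05, censoring_rate = 0.002,
                    surveillance_dropout = 0.05)
  sim <- simulate_cohort(cfg)
  panel <- build_slice_panel(sim$cohort, slice_config(), sim$rules)
  map <- build_survival_map(panel)
  rs <- recovery_score(map, cfg)
  expect_identical(map$root$split_feature, "f1")
  expect_equal(rs$score, 1)
  sk <- planted_structure(cfg)
  expect_identical(sk$feature, c("f1", "f2"))
  expect_identical(sk$max_parent_nodes, c(1, 2))
})

test_that("chance, incurable and long-term classifications follow their definitions", {
  map <- mini_map()
  treatments <- data.frame(patient_id = sprintf("m%02d", 1:5),
                           time_months = 1, kind = "surgery")
  cl <- classify_nodes(map, treatments)
  expect_identical(cl$nodes[["p1.t1"]]$classification, "chance")
  expect_identical(cl$nodes[["p3.t3"]]$classification, "incurable")
  expect_identical(cl$long_term_paths, 5L)
  expect_true("long_term_path" %in% cl$nodes[["p5.t2"]]$classification)
  # transition table bookkeeping
  ta <- cl$transitions[["p1.t1"]]
  expect_equal(unname(rowSums(ta$table)), c(5, 15))
  expect_equal(unname(ta$table[1, ]), c(5, 0, 0))
  expect_equal(unname(ta$table[2, ]), c(3, 6, 6))
  expect_equal(ta$up_given_treatment, 100)

  # equal child medians can never be a chance node
  map2 <- mini_map()
  map2$nodes[["p1.t2"]]$median <- 6  # gap collapses to zero
  cl2 <- classify_nodes(map2, treatments)
  expect_false("chance" %in% cl2$nodes[["p1.t1"]]$classification)

  # a treated majority going down blocks the chance label too
  tr3 <- data.frame(patient_id = sprintf("m%02d", 9:14), time_months = 1,
                    kind = "ablation")
  cl3 <- classify_nodes(mini_map(), tr3)
  expect_false("chance" %in% cl3$nodes[["p1.t1"]]$classification)
})

test_that("patients route through the map exactly as the member sets say", {
  sim <- sim_fixture("tiny")
  panel <- build_slice_panel(sim$cohort, slice_config(), sim$rules)
  # the tiny cohort deliberately provokes a separation drop in one node
  map <- suppressWarnings(build_survival_map(panel))
  traj <- assign_patients(map, panel)
  done <- traj[traj$status == "complete", ]
  for (i in seq_len(nrow(done))) {
    nd <- Filter(function(nd) sprintf("S(p=%d, ts=%d)", nd$p, nd$ts) ==
                   done$node[i], map$nodes)[[1]]
    expect_true(done$patient_id[i] %in% nd$members)
    expect_equal(done$predicted_median_os[i], nd$median)
  }
  # a surveillance gap halts the trajectory with the status reported
  ns <- which(panel$status[, 3] == "no_surveillance" &
                panel$status[, 2] == "complete")[1]
  pid <- panel$patient_id[ns]
  tr <- traj[traj$patient_id == pid, ]
  expect_identical(tr$status[nrow(tr)], "no_surveillance")
  expect_true(all(tr$status[-nrow(tr)] == "complete"))
})
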