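#' Default simulated feature set
#'
#' Nine binary prognostic features with baseline prevalences spanning the
#' common (e.g. elevated AFP) to the rare (e.g. distant metastasis) and
#' slice-to-slice flip probabilities that let covariates evolve under
#' treatment and progression.
#'
#' @return data frame `name`, `prevalence`, `flip01` (0 to 1 per slice),
#'   `flip10` (1 to 0 per slice).
#' @export
default_sim_features <- function() {
  data.frame(
    name = paste0("f", 1:9),
    prevalence = c(0.50, 0.35, 0.45, 0.30, 0.25, 0.20, 0.15, 0.30, 0.40),
    flip01 = c(0.06, 0.08, 0.08, 0.06, 0.05, 0.04, 0.03, 0.08, 0.10),
    flip10 = c(0.10, 0.12, 0.10, 0.08, 0.06, 0.04, 0.03, 0.15, 0.12),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Generative parameters for a synthetic longitudinal cohort shaped like an
#' intermediate-stage HCC surveillance programme: fixed visit cadence with
#' jittered measurement times, evolving binary covariates, a
#' piecewise-exponential event model whose hazard is the baseline rate
#' multiplied by the hazard ratio of every active planted feature the
#' patient currently carries, independent exponential censoring, and
#' surveillance dropout truncating the measurement stream.
#'
#' @param n_patients cohort size.
#' @param seed RNG seed (mandatory: cohorts are reproducible by contract).
#' @param n_slices,interval_months slice grid (defaults 9 slices of 3 months).
#' @param features data frame as [default_sim_features()].
#' @param planted_splits list of `list(slice=, feature=, hr=)`; the feature's
#'   hazard-ratio effect is active from the planted slice onward.
#' @param baseline_hazard per-month death hazard with no unfavorable
#'   features (default 0.045, median survival about 15 months).
#' @param censoring_rate per-month exponential censoring rate.
#' @param surveillance_dropout per-slice probability that surveillance stops
#'   at that slice (slices 2 onward).
#' @param treatment_prob probability a patient has one surgery/ablation
#'   event (no effect on hazard; plumbing for transition analysis).
#' @param admin_censor_months administrative censoring horizon.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients, seed, n_slices = 9L, interval_months = 3,
                       features = default_sim_features(),
                       planted_splits = list(), baseline_hazard = 0.045,
                       censoring_rate = 0.004, surveillance_dropout = 0.12,
                       treatment_prob = 0.15, admin_censor_months = 120) {
  cfg <- structure(list(n_patients = as.integer(n_patients), seed = seed,
                        n_slices = as.integer(n_slices),
                        interval_months = interval_months, features = features,
                        planted_splits = planted_splits,
                        baseline_hazard = baseline_hazard,
                        censoring_rate = censoring_rate,
                        surveillance_dropout = surveillance_dropout,
                        treatment_prob = treatment_prob,
                        admin_censor_months = admin_censor_months),
                   class = "sim_config")
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(is.finite(cfg$n_patients) && cfg$n_patients >= 1, "n_patients must be >= 1")
  chk(length(seed) == 1 && is.finite(seed), "seed is mandatory and finite")
  chk(cfg$n_slices >= 1, "n_slices must be >= 1")
  chk(cfg$interval_months > 0, "interval_months must be > 0")
  chk(all(c("name", "prevalence", "flip01", "flip10") %in% names(features)),
      "features must have name/prevalence/flip01/flip10")
  chk(all(features$prevalence >= 0 & features$prevalence <= 1),
      "feature prevalences must be in [0,1]")
  chk(all(features$flip01 >= 0 & features$flip01 <= 1 &
            features$flip10 >= 0 & features$flip10 <= 1),
      "flip probabilities must be in [0,1]")
  chk(cfg$baseline_hazard > 0, "baseline_hazard must be > 0")
  chk(cfg$censoring_rate >= 0, "censoring_rate must be >= 0")
  chk(cfg$surveillance_dropout >= 0 && cfg$surveillance_dropout <= 1,
      "surveillance_dropout must be in [0,1]")
  for (pl in planted_splits) {
    chk(all(c("slice", "feature", "hr") %in% names(pl)),
        "planted split needs slice/feature/hr")
    if (!is.null(pl$feature))
      chk(pl$feature %in% features$name,
          paste0("planted feature not in feature set: ", pl$feature))
    if (!is.null(pl$hr)) chk(pl$hr > 0, "planted hazard ratios must be > 0")
    if (!is.null(pl$slice))
      chk(pl$slice >= 1 && pl$slice <= n_slices, "planted slice out of range")
  }
  if (length(errs))
    stop("invalid sim_config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  cfg
}

#' Simulate a longitudinal cohort with known truth
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sp_sim`: `cohort` (an [cohort()] ready for
#'   [build_slice_panel()]), `rules` (identity pass-through rules for the
#'   binary variables), `truth` (latent states, true event and censoring
#'   times, dropout slices -- kept separate so pipelines cannot consume it
#'   by accident) and the `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients; m <- cfg$n_slices; int <- cfg$interval_months
  fts <- cfg$features; k <- nrow(fts)
  ids <- sprintf("P%04d", seq_len(n))

  # latent states: S[, j, ts] is the value measured in slice ts's window
  S <- array(0L, dim = c(n, k, m), dimnames = list(ids, fts$name, NULL))
  S[, , 1] <- matrix(stats::rbinom(n * k, 1L, rep(fts$prevalence, each = n)), n, k)
  if (m > 1) for (ts in 2:m) {
    prev <- S[, , ts - 1]
    up <- matrix(stats::rbinom(n * k, 1L, rep(fts$flip01, each = n)), n, k)
    down <- matrix(stats::rbinom(n * k, 1L, rep(fts$flip10, each = n)), n, k)
    S[, , ts] <- ifelse(prev == 1L, 1L - down, up)
  }

  # piecewise-exponential event times: the state measured in slice ts drives
  # the hazard on [(ts-1) int, ts int), the last state extending to infinity
  mult <- matrix(1, n, m)
  for (pl in cfg$planted_splits)
    for (ts in pl$slice:m)
      mult[, ts] <- mult[, ts] * pl$hr^S[, pl$feature, ts]
  lam <- cfg$baseline_hazard * mult
  E <- stats::rexp(n)
  cumH <- t(apply(lam * int, 1L, cumsum))
  T_true <- numeric(n)
  for (i in seq_len(n)) {
    idx <- which(cumH[i, ] >= E[i])[1]
    if (is.na(idx)) {
      T_true[i] <- m * int + (E[i] - cumH[i, m]) / lam[i, m]
    } else {
      prev <- if (idx == 1L) 0 else cumH[i, idx - 1L]
      T_true[i] <- (idx - 1L) * int + (E[i] - prev) / lam[i, idx]
    }
  }
  C <- if (cfg$censoring_rate > 0) stats::rexp(n, cfg$censoring_rate) else rep(Inf, n)
  os <- pmin(T_true, C, cfg$admin_censor_months)
  event <- as.integer(T_true <= pmin(C, cfg$admin_censor_months))

  # surveillance dropout: first slice (>= 2) at which surveillance stops
  drop_slice <- rep(Inf, n)
  if (m > 1 && cfg$surveillance_dropout > 0) {
    dmat <- matrix(stats::runif(n * (m - 1)) < cfg$surveillance_dropout, n, m - 1)
    first <- apply(dmat, 1L, function(x) if (any(x)) which(x)[1] + 1L else Inf)
    drop_slice <- first
  }

  # measurements: one jittered visit per observed slice, all variables at
  # the visit time, only while the patient is alive
  meas <- vector("list", m)
  visit <- matrix(NA_real_, n, m)
  for (ts in seq_len(m)) {
    lo <- if (ts == 1L) -1 else (ts - 2) * int
    hi <- if (ts == 1L) 0 else (ts - 1) * int
    u <- stats::runif(n, lo + 1e-6, hi)
    obs <- ts < drop_slice & u < os
    visit[obs, ts] <- u[obs]
    if (any(obs)) {
      w <- which(obs)
      meas[[ts]] <- data.frame(
        patient_id = rep(ids[w], each = k),
        time_months = rep(u[w], each = k),
        variable = rep(fts$name, times = length(w)),
        value = as.integer(t(S[w, , ts, drop = FALSE][, , 1])),
        stringsAsFactors = FALSE)
    }
  }
  measurements <- do.call(rbind, meas[!vapply(meas, is.null, logical(1))])
  measurements <- measurements[order(measurements$patient_id,
                                     measurements$time_months), ]
  rownames(measurements) <- NULL

  treated <- stats::runif(n) < cfg$treatment_prob
  tt <- stats::runif(n, 0, pmin(os, m * int))
  treatments <- data.frame(
    patient_id = ids[treated], time_months = tt[treated],
    kind = sample(c("surgery", "ablation"), sum(treated), replace = TRUE),
    stringsAsFactors = FALSE)

  outcomes <- data.frame(patient_id = ids, os_months = os, event = event,
                         stringsAsFactors = FALSE)
  structure(list(
    cohort = cohort(measurements, outcomes, treatments),
    rules = binary_rules(fts$name),
    truth = list(states = S, true_event_time = T_true, censor_time = C,
                 dropout_slice = drop_slice, visit_times = visit),
    config = cfg), class = "sp_sim")
}

#' @export
print.sp_sim <- function(x, ...) {
  cat(sprintf("sp_sim: n = %d, %d slices, %d planted split(s), seed %s\n",
              x$config$n_patients, x$config$n_slices,
              length(x$config$planted_splits), format(x$config$seed)))
  print(x$cohort)
  invisible(x)
}

#' Expected map skeleton under the planted structure
#'
#' The node/feature skeleton a perfect recovery would produce: a split
#' planted at slice `s` should appear at every node of the level reached by
#' that slice (one node for the first planted slice, up to twice as many at
#' each subsequent planted slice).
#'
#' @param cfg a [sim_config()] with nonempty `planted_splits`.
#' @return data frame `slice`, `feature`, `hr`, `level`,
#'   `max_parent_nodes` (2^(level-1)).
#' @export
planted_structure <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), length(cfg$planted_splits) > 0L)
  sl <- vapply(cfg$planted_splits, `[[`, numeric(1), "slice")
  ord <- order(sl)
  pls <- cfg$planted_splits[ord]
  data.frame(
    slice = vapply(pls, `[[`, numeric(1), "slice"),
    feature = vapply(pls, `[[`, character(1), "feature"),
    hr = vapply(pls, `[[`, numeric(1), "hr"),
    level = seq_along(pls),
    max_parent_nodes = 2^(seq_along(pls) - 1L),
    stringsAsFactors = FALSE)
}

#' Structure-recovery score of a built map
#'
#' For each planted `(slice, feature)` split, the fraction of eligible
#' bifurcation opportunities at which the map actually split on that
#' feature: the root for a slice-1 plant, and the non-excluded nodes at
#' slice `s - 1` for later plants.  The overall score is the mean over
#' planted splits.
#'
#' @param map a [build_survival_map()] result.
#' @param cfg the generating [sim_config()].
#' @return list `score` (mean), `per_split` (data frame).
#' @export
recovery_score <- function(map, cfg) {
  sk <- planted_structure(cfg)
  hit <- numeric(nrow(sk))
  for (i in seq_len(nrow(sk))) {
    s <- sk$slice[i]; f <- sk$feature[i]
    if (s == 1) {
      hit[i] <- as.numeric(identical(map$root$split_feature, f))
    } else {
      parents <- Filter(function(nd) nd$ts == s - 1 && !nd$excluded, map$nodes)
      if (!length(parents)) { hit[i] <- 0; next }
      found <- vapply(parents, function(nd)
        identical(nd$split_feature, f), logical(1))
      hit[i] <- mean(found)
    }
  }
  list(score = mean(hit), per_split = cbind(sk, recovered = hit))
}

#' Canned fixture cohorts for examples and tests
#'
#' Small deterministic cohorts: `"null"` has no prognostic structure,
#' `"planted"` has strong splits at slices 1 and 2, `"tiny"` is a 60-patient
#' cohort for fast smoke tests.
#'
#' @param name fixture name.
#' @param seed RNG seed.
#' @return an `sp_sim`.
#' @export
sim_fixture <- function(name = c("planted", "null", "tiny"), seed = 20260930) {
  name <- match.arg(name)
  cfg <- switch(name,
    planted = sim_config(500, seed = seed,
                         planted_splits = list(
                           list(slice = 1, feature = "f1", hr = 3),
                           list(slice = 2, feature = "f2", hr = 3)),
                         surveillance_dropout = 0.08),
    null = sim_config(300, seed = seed),
    tiny = sim_config(60, seed = seed,
                      planted_splits = list(list(slice = 1, feature = "f1", hr = 4)),
                      surveillance_dropout = 0.05))
  simulate_cohort(cfg)
}
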