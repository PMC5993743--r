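#' Kaplan-Meier median overall survival
#'
#' The median is the first time at which the Kaplan-Meier estimator drops to
#' 0.5 or below; it is undefined (`NA`) when the curve never reaches 0.5.
#'
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return list with `median` (months or `NA`) and `curve` (data frame of
#'   `time`, `surv`, `n_risk`).
#' @export
km_median_os <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) > 0L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, surv = fit$surv, n_risk = fit$n.risk)
  hit <- which(fit$surv <= 0.5 + 1e-12)
  med <- if (length(hit)) fit$time[hit[1]] else NA_real_
  list(median = med, curve = curve)
}

# pair counts for Harrell's c with per-patient contributions.
# Usable pairs: the earlier time is an event; equal times are usable only
# when exactly one of the two is an event (the event is taken as earlier);
# tied risk scores count 1/2.
cindex_counts <- function(risk, time, event) {
  n <- length(time)
  C <- 0; P <- 0
  Ci <- numeric(n); Pi <- numeric(n)
  for (i in which(event == 1)) {
    comp <- (time > time[i]) | (time == time[i] & event == 0)
    comp[i] <- FALSE
    if (!any(comp)) next
    w <- (risk[i] > risk[comp]) + 0.5 * (risk[i] == risk[comp])
    C <- C + sum(w); P <- P + sum(comp)
    Ci[i] <- Ci[i] + sum(w); Pi[i] <- Pi[i] + sum(comp)
    Ci[comp] <- Ci[comp] + w
    Pi[comp] <- Pi[comp] + 1
  }
  list(C = C, P = P, Ci = Ci, Pi = Pi)
}

#' Harrell's concordance index
#'
#' Probability that, of two comparable patients, the one ranked higher-risk
#' fails first; tied risk scores count one half.  The optional confidence
#' interval is a seeded nonparametric bootstrap (percentile bounds).
#'
#' @param risk per-patient risk score (any strictly monotone transform gives
#'   the same c).
#' @param time,event follow-up and 0/1 death indicator.
#' @param n_boot bootstrap resamples for the CI (0 = point estimate only).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return list `c_index`, `ci_low`, `ci_high`, `n_used`, `n_pairs`.
#' @export
concordance_index <- function(risk, time, event, n_boot = 0L, seed = 1L,
                              conf = 0.95) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  cc <- cindex_counts(risk, time, event)
  if (cc$P == 0) {
    warning("no comparable pairs; c-index undefined")
    return(list(c_index = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_used = length(time), n_pairs = 0))
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    bs <- local_rng(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(time), replace = TRUE)
        r <- cindex_counts(risk[idx], time[idx], event[idx])
        if (r$P == 0) NA_real_ else r$C / r$P
      }, numeric(1))
    })
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(a, 1 - a), na.rm = TRUE))
  }
  list(c_index = cc$C / cc$P, ci_low = ci[1], ci_high = ci[2],
       n_used = length(time), n_pairs = cc$P)
}

# run expr under a temporary RNG state
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Paired comparison of two concordance indices
#'
#' Compares two risk rankings evaluated on the same patients with a Z test
#' whose standard error of the c-index difference comes from a paired
#' leave-one-out jackknife (deterministic).
#'
#' @param risk_a,risk_b the two per-patient risk scores.
#' @param time,event shared follow-up data.
#' @param threshold significance level for the verdict (default 0.006, the
#'   slice-corrected working level).
#' @return list `c_a`, `c_b`, `z`, `p`, `verdict` in
#'   `a_superior` / `b_superior` / `no_difference`.
#' @export
compare_cindex <- function(risk_a, risk_b, time, event, threshold = 0.006) {
  n <- length(time)
  stopifnot(length(risk_a) == n, length(risk_b) == n, length(event) == n)
  ca <- cindex_counts(risk_a, time, event)
  cb <- cindex_counts(risk_b, time, event)
  if (ca$P == 0 || cb$P == 0) stop("no comparable pairs")
  cA <- ca$C / ca$P; cB <- cb$C / cb$P
  la <- (ca$C - ca$Ci) / (ca$P - ca$Pi)
  lb <- (cb$C - cb$Ci) / (cb$P - cb$Pi)
  d <- la - lb
  d <- d[is.finite(d)]
  se <- sqrt((length(d) - 1) / length(d) * sum((d - mean(d))^2))
  if (!is.finite(se) || se < 1e-12) {
    z <- 0; p <- 1
  } else {
    z <- (cA - cB) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  verdict <- if (p >= threshold) "no_difference"
             else if (cA > cB) "a_superior" else "b_superior"
  list(c_a = cA, c_b = cB, z = z, p = p, verdict = verdict)
}

#' Hazard ratio across one bifurcation
#'
#' Univariate Cox hazard ratio of the lower (worse) child versus the upper
#' (better) child with Wald 95% CI and P.  When one side has no deaths the
#' partial likelihood is monotone, so a Kaplan-Meier log-rank P is reported
#' instead and no HR.  Comparisons where either side has fewer than
#' `min_side` members are suppressed.
#'
#' @param time_upper,event_upper follow-up data of the upper (better) child.
#' @param time_lower,event_lower follow-up data of the lower (worse) child.
#' @param min_side minimum members per side (default 6).
#' @return list `hr`, `ci_low`, `ci_high`, `p`, `method` in
#'   `cox` / `logrank_km` / `suppressed`, `n_upper`, `n_lower`.
#' @export
bifurcation_hr <- function(time_upper, event_upper, time_lower, event_lower,
                           min_side = 6L) {
  nu <- length(time_upper); nl <- length(time_lower)
  out <- list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              p = NA_real_, method = "suppressed", n_upper = nu, n_lower = nl)
  if (min(nu, nl) < min_side) return(out)
  df <- data.frame(os = c(time_upper, time_lower),
                   event = c(event_upper, event_lower),
                   g = rep(c(0L, 1L), c(nu, nl)))   # 1 = lower (worse)
  if (sum(event_upper) == 0L || sum(event_lower) == 0L) {
    if (sum(df$event) == 0L) return(out)
    sd <- survival::survdiff(survival::Surv(os, event) ~ g, data = df)
    out$p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
    out$method <- "logrank_km"
    return(out)
  }
  fit <- survival::coxph(survival::Surv(os, event) ~ g, data = df, ties = "efron")
  b <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  out$hr <- exp(b)
  out$ci_low <- exp(b - stats::qnorm(0.975) * se)
  out$ci_high <- exp(b + stats::qnorm(0.975) * se)
  out$p <- 2 * stats::pnorm(-abs(b / se))
  out$method <- "cox"
  out
}

#' Treatment-transition contingency analysis
#'
#' Cross-tabulates surgery/ablation in a bifurcating node against the fate
#' of its members at the next slice (transfer to the upper child, to the
#' lower child, or death / no surveillance).  Tested with Pearson's
#' chi-square without continuity correction, switching to Fisher's exact
#' test when any expected cell count is below 5.
#'
#' @param counts 2x3 matrix of non-negative integers; rows are
#'   with / without surgery-ablation, columns go-up / go-down / died-or-NS.
#' @return object of class `sp_transition`: the table, expected counts, the
#'   test used, its P value, the surgery/ablation rate (% of node members
#'   treated) and the up-transfer rate given treatment (%).
#' @export
transition_analysis <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2L, ncol(counts) == 3L, all(counts >= 0))
  dimnames(counts) <- list(c("with_surgery_ablation", "without"),
                           c("go_up", "go_down", "died_ns"))
  N <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / N
  if (any(expected < 5)) {
    method <- "fisher_exact"
    p <- stats::fisher.test(counts)$p.value
  } else {
    method <- "chi_square"
    p <- stats::chisq.test(counts, correct = FALSE)$p.value
  }
  structure(list(table = counts, expected = expected, method = method,
                 p_value = p,
                 surgery_rate = 100 * sum(counts[1, ]) / N,
                 up_given_treatment = 100 * counts[1, 1] / sum(counts[1, ])),
            class = "sp_transition")
}

#' @export
print.sp_transition <- function(x, ...) {
  print(x$table)
  cat(sprintf("surgery/ablation rate %.1f%%; go-up given treatment %.1f%%; %s P = %.3g\n",
              x$surgery_rate, x$up_given_treatment, x$method, x$p_value))
  invisible(x)
}
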