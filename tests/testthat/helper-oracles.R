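# Independent oracles used across the suite.  Everything here is written
# from first principles (pair enumeration, hand-coded partial likelihood,
# brute-force optimization) so it never shares code paths with the package.

# Harrell's c by exhaustive enumeration of all ordered pairs.
# A pair is usable when the earlier time is an event; equal times are usable
# only when exactly one member is an event (the event counted as earlier);
# tied risk scores contribute one half.
oracle_cindex <- function(risk, time, event) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1L) next
      first <- if (event[i] == 1L) i else j
    } else {
      first <- if (time[i] < time[j]) i else j
      if (event[first] != 1L) next
    }
    second <- if (first == i) j else i
    den <- den + 1
    if (risk[first] > risk[second]) num <- num + 1
    else if (risk[first] == risk[second]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

# Cox partial log-likelihood for tie-free data (Breslow = Efron = exact
# when no event times coincide), written directly from the definition.
oracle_cox_loglik <- function(beta, X, time, event) {
  n <- length(time)
  eta <- if (length(beta)) as.vector(X %*% beta) else rep(0, n)
  ord <- order(time)
  eta <- eta[ord]; ev <- event[ord]
  risk_denominator <- rev(cumsum(rev(exp(eta))))
  sum(eta[ev == 1] - log(risk_denominator[ev == 1]))
}

# brute-force maximum partial likelihood via optim (BFGS from zero)
oracle_cox_fit <- function(X, time, event) {
  p <- ncol(X)
  if (p == 0L)
    return(list(coef = numeric(0),
                loglik = oracle_cox_loglik(numeric(0), X, time, event)))
  opt <- stats::optim(rep(0, p),
                      function(b) -oracle_cox_loglik(b, X, time, event),
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(coef = opt$par, loglik = -opt$value)
}

# dense 1-D grid maximization of the partial likelihood (single feature)
oracle_cox_grid <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  eta_base <- outer(x, grid)             # n x G
  ord <- order(time)
  ev <- event[ord]
  E <- exp(eta_base[ord, , drop = FALSE])
  denom <- apply(E, 2L, function(col) rev(cumsum(rev(col))))
  ll <- colSums(eta_base[ord, , drop = FALSE][ev == 1, , drop = FALSE]) -
    colSums(log(denom[ev == 1, , drop = FALSE]))
  grid[which.max(ll)]
}

# exhaustive-submodel backward elimination: the maximized log-likelihood of
# every one of the 2^p submodels is computed with the brute-force fitter,
# then the elimination decisions (drop the smallest LR statistic while its
# P >= alpha, lowest-priority feature on ties) are replayed on that table.
oracle_backward <- function(X, time, event, alpha) {
  feats <- colnames(X)
  key <- function(set) paste0("s:", paste(sort(set), collapse = ","))
  tab <- new.env(parent = emptyenv())
  subsets <- unlist(lapply(0:length(feats), utils::combn, x = feats,
                           simplify = FALSE), recursive = FALSE)
  for (s in subsets)
    assign(key(s), oracle_cox_fit(X[, s, drop = FALSE], time, event)$loglik,
           envir = tab)
  ll <- function(set) get(key(set), envir = tab)
  cur <- feats
  while (length(cur)) {
    stat <- vapply(cur, function(q) 2 * (ll(cur) - ll(setdiff(cur, q))),
                   numeric(1))
    stat <- pmax(stat, 0)
    worst <- which(stat == min(stat)); worst <- worst[length(worst)]
    if (stats::pchisq(stat[worst], 1, lower.tail = FALSE) < alpha) break
    cur <- setdiff(cur, cur[worst])
  }
  cur
}

# random survival node with binary features and log-hazard coefficients;
# continuous times, so ties have probability zero
make_node <- function(n, beta, seed, base_rate = 0.05, cens_rate = 0.01,
                      prevalence = 0.5) {
  set.seed(seed)
  k <- length(beta)
  X <- matrix(rbinom(n * k, 1L, prevalence), n, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  t_ev <- rexp(n, base_rate * exp(as.vector(X %*% beta)))
  t_c <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  data.frame(os = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c), X,
             check.names = FALSE)
}

# hand-built four-patient measurement table covering all default HCC rules
full_hcc_measurements <- function(patient_id, time, afp = 50, cp = "A",
                                  diam = 40, nles = 1, vi = 0, dm = 0,
                                  vinm = 0, viable = 1, ps = 0) {
  data.frame(
    patient_id = patient_id,
    time_months = time,
    variable = c("afp", "child_pugh", "main_diameter_mm", "n_lesions",
                 "vascular_invasion", "distant_metastasis", "vasc_inv_n1_m1",
                 "viable_lesion", "performance_status"),
    value = as.character(c(afp, cp, diam, nles, vi, dm, vinm, viable, ps)),
    stringsAsFactors = FALSE)
}
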