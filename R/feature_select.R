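#' Slice-corrected significance level
#'
#' Each per-node feature selection is treated as an independent experiment;
#' with `m` time slices the family-wise level is divided evenly across
#' slices, so the working level is `family_alpha / m`.  With the defaults
#' (0.05 over nine slices) this is 0.00556, i.e. 0.006 at three decimals.
#'
#' @param family_alpha family-wise significance level in (0, 1].
#' @param m number of time slices (>= 1).
#' @return the per-selection significance level.
#' @export
adjusted_alpha <- function(family_alpha = 0.05, m = 9L) {
  if (!(family_alpha > 0 && family_alpha <= 1)) stop("family_alpha must be in (0, 1]")
  if (!(is.numeric(m) && m >= 1)) stop("m must be a positive integer")
  family_alpha / m
}

#' Selection configuration
#'
#' @param family_alpha family-wise significance level (default 0.05).
#' @param m number of time slices.
#' @param min_level_count minimum cases required in each level of a binary
#'   candidate before it is screened (default 2); features failing this are
#'   skipped, not tested.
#' @return an object of class `selection_config` with the derived working
#'   `alpha = family_alpha / m`, used both for screening and for backward-
#'   elimination retention.
#' @export
selection_config <- function(family_alpha = 0.05, m = 9L, min_level_count = 2L) {
  structure(list(family_alpha = family_alpha, m = as.integer(m),
                 alpha = adjusted_alpha(family_alpha, m),
                 min_level_count = as.integer(min_level_count)),
            class = "selection_config")
}

#' Kaplan-Meier univariate screening
#'
#' Tests each binary candidate with a two-group log-rank test and returns
#' the features significant at the working level.  Degenerate candidates
#' (constant, or with fewer than `min_level_count` cases in either level)
#' are skipped.
#'
#' @param data node data frame from [node_data()]: columns `os`, `event`
#'   and 0/1 feature columns.
#' @param alpha working significance level.
#' @param min_level_count minimum cases per feature level.
#' @param features candidate feature names (default: all feature columns).
#' @return character vector of significant candidates, in input (priority)
#'   order; attribute `"p_values"` carries the log-rank P of every tested
#'   candidate.
#' @export
km_screen <- function(data, alpha, min_level_count = 2L,
                      features = setdiff(names(data), c("os", "event"))) {
  if (sum(data$event) == 0L) {
    warning("no deaths in node data; nothing to screen")
    return(structure(character(0), p_values = numeric(0)))
  }
  p <- stats::setNames(rep(NA_real_, length(features)), features)
  for (f in features) {
    x <- data[[f]]
    tab <- table(factor(x, levels = 0:1))
    if (any(tab < min_level_count)) next
    sd <- survival::survdiff(survival::Surv(os, event) ~ g,
                             data = data.frame(os = data$os, event = data$event,
                                               g = x))
    p[f] <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  }
  hits <- features[!is.na(p) & p < alpha]
  structure(hits, p_values = p)
}

#' Fit a multivariable Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood over the given binary features with
#' the Efron approximation for ties.  Aliased features (collinear within the
#' node) and features driving a monotone likelihood (complete separation,
#' detected as a diverging coefficient) are dropped with a warning and the
#' model refitted.
#'
#' @param data node data frame (`os`, `event`, feature columns).
#' @param features feature names to include; may be empty (null model).
#' @return an object of class `sp_cox`: `features`, `coef`, `loglik`
#'   (maximized partial log-likelihood), `loglik_null`, `n`, `nevent`, and
#'   the underlying `coxph` fit (`NULL` for the null model).
#' @export
fit_cox <- function(data, features) {
  y <- survival::Surv(data$os, data$event)
  null_fit <- survival::coxph(y ~ 1, data = data)
  ll0 <- null_fit$loglik[1]
  mk <- function(fit, feats) {
    structure(list(features = feats, coef = stats::coef(fit),
                   loglik = if (length(feats)) fit$loglik[2] else ll0,
                   loglik_null = ll0, n = nrow(data),
                   nevent = sum(data$event), ties = "efron", fit = fit),
              class = "sp_cox")
  }
  if (length(features) == 0L)
    return(mk(null_fit, character(0)))
  repeat {
    fml <- stats::reformulate(sprintf("`%s`", features), response = "y")
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(fml, data = data, ties = "efron"),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(fit, "error"))
      stop("Cox fit failed: ", conditionMessage(fit))
    cf <- stats::coef(fit)
    names(cf) <- features
    drop <- features[is.na(cf) | abs(cf) > 15]
    if (length(drop) == 0L) {
      fit2 <- fit; fit2$coefficients <- cf
      return(mk(fit2, features))
    }
    warning("dropping non-identifiable feature(s): ",
            paste(drop, collapse = ", "))
    features <- setdiff(features, drop)
    if (length(features) == 0L) return(mk(null_fit, character(0)))
  }
}

#' @export
print.sp_cox <- function(x, ...) {
  cat(sprintf("sp_cox: %d features, n = %d, events = %d, logLik = %.4f (Efron ties)\n",
              length(x$features), x$n, x$nevent, x$loglik))
  if (length(x$features)) {
    print(round(stats::setNames(x$coef, x$features), 4))
  } else cat("  (null model)\n")
  invisible(x)
}

# likelihood-ratio statistic for dropping each single feature from a model
single_drop_stats <- function(model, data) {
  vapply(model$features, function(q) {
    sub <- fit_cox(data, setdiff(model$features, q))
    2 * (model$loglik - sub$loglik)
  }, numeric(1))
}

#' Backward elimination at the working level
#'
#' Starting from the fitted model, repeatedly removes the feature with the
#' smallest likelihood-ratio statistic (the Cox analogue of the lowest
#' partial F) as long as that statistic is non-significant at the working
#' level, refitting after each removal; stops when every retained feature is
#' significant.  May return an empty (null) model when nothing survives.
#'
#' @param model an `sp_cox` from [fit_cox()].
#' @param data the node data the model was fitted on.
#' @param cfg a [selection_config()] (its `alpha` is the retention level).
#' @return the reduced `sp_cox`; attribute `"be_path"` records each removal
#'   (feature, LR statistic, P).
#' @export
backward_eliminate <- function(model, data, cfg) {
  path <- data.frame(feature = character(), statistic = numeric(),
                     p = numeric(), stringsAsFactors = FALSE)
  while (length(model$features) > 0L) {
    stat <- single_drop_stats(model, data)
    stat <- pmax(stat, 0)
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    worst <- which(stat == min(stat))
    worst <- worst[length(worst)]     # tie: drop the lowest-priority feature
    if (p[worst] < cfg$alpha) break
    path <- rbind(path, data.frame(feature = model$features[worst],
                                   statistic = stat[worst], p = p[worst]))
    model <- fit_cox(data, model$features[-worst])
  }
  structure(model, be_path = path)
}

#' Likelihood-drop variable importance
#'
#' For each retained feature `q` the model is refitted without it and the
#' importance is twice the drop in maximized partial log-likelihood,
#' `gamma_q = 2 (logL_full - logL_without_q)`, non-negative up to numerical
#' tolerance because the full model nests every single-removal submodel.
#'
#' @param model an `sp_cox` with at least one feature.
#' @param data the node data the model was fitted on.
#' @param priority optional character vector giving the fixed feature
#'   priority used to break exact ties (defaults to the model's feature
#'   order).
#' @return data frame `feature`, `gamma`, sorted by decreasing `gamma` (ties
#'   by priority).  A refit failure records `gamma = Inf` with a warning.
#' @export
variable_importance <- function(model, data, priority = model$features) {
  stopifnot(length(model$features) >= 1L)
  gamma <- vapply(model$features, function(q) {
    sub <- tryCatch(fit_cox(data, setdiff(model$features, q)),
                    error = function(e) NULL)
    if (is.null(sub)) {
      warning("refit without '", q, "' failed; gamma recorded as Inf")
      return(Inf)
    }
    2 * (model$loglik - sub$loglik)
  }, numeric(1))
  pr <- match(model$features, priority)
  ord <- order(-gamma, pr)
  data.frame(feature = model$features[ord], gamma = unname(gamma[ord]),
             stringsAsFactors = FALSE)
}

#' Select the single splitting feature for a node
#'
#' Runs the full selection cycle: log-rank screening at the working level,
#' multivariable Cox fit of the screened candidates, backward elimination at
#' the same level, then likelihood-drop importance; the retained feature
#' whose removal drops the likelihood the most is the split feature.
#' Returns `NULL` (node stays unsplit) when screening or elimination leaves
#' nothing.
#'
#' @param data node data frame (`os`, `event`, feature columns in priority
#'   order).
#' @param cfg a [selection_config()].
#' @param screened optional precomputed result of [km_screen()] (used by the
#'   map builder, which screens before the sample-size gate).
#' @return the selected feature name (length-1 character) with attribute
#'   `"trace"` (screening P values, elimination path, importance table), or
#'   a length-0 character with the same attribute when no feature is
#'   selected.
#' @export
select_split_feature <- function(data, cfg, screened = NULL) {
  if (is.null(screened))
    screened <- km_screen(data, cfg$alpha, cfg$min_level_count)
  trace <- list(screen_p = attr(screened, "p_values"),
                screened = as.character(screened),
                be_path = NULL, importance = NULL)
  if (length(screened) == 0L)
    return(structure(character(0), trace = trace))
  full <- fit_cox(data, as.character(screened))
  red <- backward_eliminate(full, data, cfg)
  trace$be_path <- attr(red, "be_path")
  if (length(red$features) == 0L)
    return(structure(character(0), trace = trace))
  imp <- variable_importance(red, data,
                             priority = setdiff(names(data), c("os", "event")))
  trace$importance <- imp
  structure(imp$feature[1], trace = trace)
}
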