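test_that("slice correction divides the family level by the slice count", {
  expect_equal(adjusted_alpha(0.05, 9), 0.05 / 9)
  expect_equal(round(adjusted_alpha(0.05, 9), 3), 0.006)
  expect_equal(adjusted_alpha(0.05, 1), 0.05)
  expect_equal(adjusted_alpha(0.05, 5), 0.01)
  expect_error(adjusted_alpha(0.05, 0), "positive")
  expect_error(adjusted_alpha(1.2, 9), "family_alpha")
})

test_that("log-rank screening keeps real signals and skips degenerate features", {
  # identical survival experience in the two levels: not returned
  d <- data.frame(os = rep(c(1, 3, 5, 7, 9, 11), 2),
                  event = rep(1L, 12),
                  same = rep(c(0L, 1L), each = 6),
                  const = 0L,
                  near_const = c(1L, rep(0L, 11)))
  hits <- km_screen(d, alpha = 0.05)
  p <- attr(hits, "p_values")
  expect_length(hits, 0)
  expect_gt(p[["same"]], 0.9)
  expect_true(is.na(p[["const"]]))       # degenerate level: skipped
  expect_true(is.na(p[["near_const"]]))  # below min_level_count: skipped

  # a strong signal is returned
  d2 <- make_node(120, beta = log(4), seed = 11)
  expect_identical(as.character(km_screen(d2, alpha = 0.006)), "x1")

  # no deaths: empty with a warning, not an error
  d3 <- data.frame(os = 1:6, event = 0L, x1 = rep(0:1, 3))
  expect_warning(out <- km_screen(d3, alpha = 0.05), "no deaths")
  expect_length(out, 0)
})

test_that("screening finds a planted HR-4 feature almost always at the corrected level", {
  hits <- vapply(1:200, function(r) {
    d <- make_node(200, beta = log(4), seed = 3000 + r, cens_rate = 0.03)
    "x1" %in% km_screen(d, alpha = 0.006)
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("the Cox fit maximizes the partial likelihood (grid-search oracle)", {
  d <- make_node(20, beta = log(2.5), seed = 7, cens_rate = 0.02)
  fit <- fit_cox(d, "x1")
  b_grid <- oracle_cox_grid(d$x1, d$os, d$event)
  expect_lt(abs(unname(fit$coef[1]) - b_grid), 2e-4)
  expect_equal(fit$loglik, oracle_cox_loglik(fit$coef, cbind(d$x1), d$os,
                                             d$event), tolerance = 1e-8)
  # symmetry: identical event patterns in the two groups give beta ~ 0
  ds <- data.frame(os = rep(c(2, 4, 6, 8), 2), event = 1L,
                   x1 = rep(0:1, each = 4))
  expect_lt(abs(fit_cox(ds, "x1")$coef[1]), 1e-8)
})

test_that("the Cox fit is consistent for a true hazard ratio of 2", {
  d <- make_node(1000, beta = log(2), seed = 42, cens_rate = 0.01)
  fit <- fit_cox(d, "x1")
  expect_gt(exp(fit$coef[1]), 1.8)
  expect_lt(exp(fit$coef[1]), 2.2)
})

test_that("backward elimination drops noise, keeps planted signal", {
  cfg <- selection_config(0.05, 9)
  kept <- vapply(1:200, function(r) {
    d <- make_node(300, beta = c(log(3), 0, 0, 0), seed = 9000 + r,
                   cens_rate = 0.02)
    m <- backward_eliminate(fit_cox(d, paste0("x", 1:4)), d, cfg)
    paste(sort(m$features), collapse = ",")
  }, character(1))
  expect_gt(mean(grepl("x1", kept)), 0.9)           # signal retained
  expect_gt(mean(kept == "x1"), 0.75)               # usually nothing else
})

test_that("a single already-significant feature passes elimination unchanged", {
  d <- make_node(150, beta = log(3), seed = 5)
  full <- fit_cox(d, "x1")
  red <- backward_eliminate(full, d, selection_config(0.05, 9))
  expect_identical(red$features, "x1")
  expect_equal(red$coef, full$coef)
  expect_identical(nrow(attr(red, "be_path")), 0L)
})

test_that("elimination agrees with exhaustive submodel search on small instances", {
  cfg <- selection_config(0.05, 9)
  for (r in 1:8) {
    d <- make_node(40, beta = c(log(3), log(1.5), 0, 0), seed = 600 + r,
                   cens_rate = 0.02)
    mine <- backward_eliminate(fit_cox(d, paste0("x", 1:4)), d, cfg)
    orc <- oracle_backward(as.matrix(d[paste0("x", 1:4)]), d$os, d$event,
                           cfg$alpha)
    expect_identical(sort(mine$features), sort(orc))
  }
})

test_that("variable importance equals the direct log-likelihood drop and is non-negative", {
  d <- make_node(120, beta = c(log(2.5), log(1.8)), seed = 21, cens_rate = 0.02)
  full <- fit_cox(d, c("x1", "x2"))
  imp <- variable_importance(full, d)
  for (q in c("x1", "x2")) {
    direct <- 2 * (full$loglik - fit_cox(d, setdiff(c("x1", "x2"), q))$loglik)
    expect_equal(imp$gamma[imp$feature == q], direct, tolerance = 1e-6)
    # and against the independent brute-force fitter
    orc <- 2 * (oracle_cox_fit(as.matrix(d[c("x1", "x2")]), d$os, d$event)$loglik -
                  oracle_cox_fit(as.matrix(d[setdiff(c("x1", "x2"), q)]),
                                 d$os, d$event)$loglik)
    expect_equal(imp$gamma[imp$feature == q], orc, tolerance = 1e-4)
  }
  expect_true(all(imp$gamma >= 0))
  # a null feature has importance ~ 0
  d0 <- make_node(200, beta = c(log(3), 0), seed = 23)
  imp0 <- variable_importance(fit_cox(d0, c("x1", "x2")), d0)
  expect_lt(imp0$gamma[imp0$feature == "x2"], 4)
})

test_that("split selection returns the dominant planted feature, or nothing", {
  cfg <- selection_config(0.05, 9)
  # nothing screens: no selection, node stays unsplit
  d_null <- make_node(100, beta = c(0, 0), seed = 31)
  sel <- select_split_feature(d_null, cfg)
  expect_length(sel, 0)
  expect_named(attr(sel, "trace"), c("screen_p", "screened", "be_path",
                                     "importance"))
  # forced choice
  d1 <- make_node(200, beta = log(4), seed = 33)
  expect_identical(as.character(select_split_feature(d1, cfg)), "x1")
  # the HR-3 feature beats the HR-1.5 feature almost always
  wins <- vapply(1:200, function(r) {
    d <- make_node(500, beta = c(log(3), log(1.5)), seed = 40000 + r,
                   cens_rate = 0.02)
    s <- select_split_feature(d, cfg)
    length(s) == 1L && s == "x1"
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("selection is deterministic for identical inputs", {
  cfg <- selection_config(0.05, 9)
  d <- make_node(250, beta = c(log(2), log(2), 0), seed = 77)
  s1 <- select_split_feature(d, cfg)
  s2 <- select_split_feature(d, cfg)
  expect_identical(s1, s2)
  expect_identical(attr(s1, "trace")$importance, attr(s2, "trace")$importance)
})
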