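test_that("univariate screening ranks and filters by simple-regression r2", {
  tab <- iam_fixture()
  cal <- recovered_calibrations()
  x <- cbind(delta_mg = compute_delta_table(tab, cal$MG)$delta,
             delta_dd2 = compute_delta_table(tab, cal$DD2)$delta)
  rownames(x) <- tab$name
  scr <- univariate_screen(descriptor_matrix(x), tab$logbb)
  expect_setequal(attr(scr, "kept"), c("delta_mg", "delta_dd2"))
  # DD2 ranks at or above MG, as published
  expect_lte(which(scr$descriptor == "delta_dd2"),
             which(scr$descriptor == "delta_mg"))
  # a descriptor identical to the response is kept with r2 = 1
  x2 <- cbind(x, self = tab$logbb)
  scr2 <- univariate_screen(descriptor_matrix(x2), tab$logbb)
  expect_equal(scr2$r2[scr2$descriptor == "self"], 1)
  # a seeded pure-noise column falls below the screen
  set.seed(5)
  x3 <- cbind(x, noise = rnorm(56))
  scr3 <- univariate_screen(descriptor_matrix(x3), tab$logbb)
  r2_noise <- scr3$r2[scr3$descriptor == "noise"]
  expect_lt(r2_noise, 0.1)
  expect_false("noise" %in% attr(scr3, "kept"))
  expect_equal(r2_noise, stats::cor(x3[, "noise"], tab$logbb)^2)
  # constant columns are skipped with a warning
  x4 <- cbind(x, flat = rep(1, 56))
  expect_warning(univariate_screen(descriptor_matrix(x4), tab$logbb),
                 "flat")
})

test_that("VIF matches the two-predictor closed form and filters iteratively", {
  # orthogonal design: both kept, VIF exactly 1
  xo <- cbind(a = c(1, -1, 1, -1, 1, -1), b = c(1, 1, -1, -1, 1, -1))
  xo[, "b"] <- xo[, "b"] - mean(xo[, "b"])
  set.seed(13)
  z1 <- scale(rnorm(50))[, 1]
  z2 <- stats::resid(stats::lm(rnorm(50) ~ z1))
  z2 <- z2 / sqrt(sum(z2^2) / (50 - 1))
  # construct an exactly 0.95-correlated pair
  pair <- cbind(p = z1, q = 0.95 * z1 + sqrt(1 - 0.95^2) * z2)
  expect_equal(stats::cor(pair[, 1], pair[, 2]), 0.95)
  v <- vif_filter(pair, threshold = Inf)
  expect_equal(unname(v$vif), rep(1 / (1 - 0.95^2), 2))  # 10.256...
  v5 <- vif_filter(pair, threshold = 5)
  expect_identical(length(v5$kept), 1L)
  expect_identical(nrow(v5$removed), 1L)
  # duplicated column: infinite VIF, later-listed copy removed
  dup <- cbind(a = z1, b = rnorm(50), a2 = z1)
  vd <- vif_filter(dup, threshold = 5)
  expect_identical(vd$removed$descriptor, "a2")
  expect_setequal(vd$kept, c("a", "b"))
  # order invariance away from exact ties
  set.seed(14)
  x3 <- cbind(u = rnorm(40), v = rnorm(40), w = rnorm(40))
  x3[, "w"] <- 0.97 * scale(x3[, "u"])[, 1] + 0.1 * rnorm(40)
  k1 <- sort(vif_filter(x3, 5)$kept)
  k2 <- sort(vif_filter(x3[, c("w", "v", "u")], 5)$kept)
  expect_identical(k1, k2)
  expect_error(vif_filter(x3[, 1, drop = FALSE]), "at least 2")
})

test_that("model search recovers a planted model among decoys", {
  cfg <- synthetic_config(seed = 404)
  g <- gen_descriptor_matrix(cfg)
  # candidates as a screened set: the generated columns minus the
  # deliberately collinear twin
  x <- g$x[, setdiff(colnames(g$x), "collin")]
  res <- search_models(descriptor_matrix(x), g$y, max_vars = 3)
  top3 <- Filter(function(m) length(m$selected) == 3L, res$models)[[1L]]
  expect_setequal(top3$selected, names(g$truth$planted))
  # recovered coefficients within 3 standard errors of the planted truth
  fit_se <- sqrt(diag(stats::vcov(top3$summary$fit)))[-1L]
  est <- top3$summary$coefficients
  truth <- g$truth$planted[names(est)]
  expect_true(all(abs(est - truth) <= 3 * fit_se))
  expect_true(all(top3$vif < 5))
})

test_that("degenerate searches reduce to the simple fit and ranking", {
  set.seed(77)
  x <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "only"))
  y <- 2 * x[, 1] + rnorm(30)
  res <- search_models(descriptor_matrix(x, sprintf("c%02d", 1:30)), y)
  expect_identical(length(res$models), 1L)
  direct <- fit_ols(x, y)
  expect_equal(res$models[[1L]]$summary$r2, direct$r2)
  expect_equal(res$models[[1L]]$summary$coefficients, direct$coefficients)
  # max_vars = 1 is exactly the univariate ranking
  cfg <- synthetic_config(seed = 55)
  g <- gen_descriptor_matrix(cfg)
  res1 <- search_models(g$x, g$y, max_vars = 1, objective = "r2")
  scr <- univariate_screen(g$x, g$y, r2_min = 0)
  expect_identical(vapply(res1$models, function(m) m$selected, ""),
                   scr$descriptor)
  expect_error(search_models(g$x[, 0], g$y), "empty")
})

test_that("a planted single outlier is found by the exclusion search", {
  cfg <- synthetic_config(seed = 88)
  g <- gen_descriptor_matrix(cfg)
  y <- g$y
  shifted <- 7L
  y[shifted] <- y[shifted] + 5 * stats::sd(y)
  x <- g$x[, setdiff(colnames(g$x), "collin")]
  res <- search_models(descriptor_matrix(x), y, max_vars = 3,
                       exclusion_search = TRUE, n_exclusion = 3)
  top <- res$models[[1L]]
  expect_identical(top$excluded_compound, rownames(x)[shifted])
  expect_gt(top$summary_excluded$q2_loo, top$summary$q2_loo)
})

test_that("decoys cannot lower the best in-sample fit but can lose on q2", {
  cfg <- synthetic_config(seed = 99)
  g <- gen_descriptor_matrix(cfg)
  x <- g$x[, setdiff(colnames(g$x), "collin")]
  planted <- names(g$truth$planted)
  base <- search_models(descriptor_matrix(x[, planted]), g$y,
                        max_vars = 3, objective = "r2")
  best_r2_base <- max(vapply(base$models, function(m) m$summary$r2, 0))
  wide <- search_models(descriptor_matrix(x), g$y, max_vars = 3,
                        objective = "r2")
  best_r2_wide <- max(vapply(Filter(function(m) length(m$selected) == 3L,
                                    wide$models),
                             function(m) m$summary$r2, 0))
  expect_gte(best_r2_wide, best_r2_base - 1e-12)
})

test_that("the combined screen/VIF/search pipeline holds its thresholds", {
  cfg <- synthetic_config(seed = 123)
  g <- gen_descriptor_matrix(cfg)
  res <- stepwise_qspr(g$x, g$y, exclusion_search = FALSE)
  vf <- attr(res, "vif")
  # the collinear twin pair cannot survive jointly at VIF threshold 5
  expect_false(all(g$truth$collinear_pair %in% vf$kept))
  for (m in res$models) {
    expect_true(all(m$vif < 5))
    expect_true(all(m$selected %in% attr(res, "screen")$descriptor[
      attr(res, "screen")$kept]))
    expect_true(length(m$selected) >= 1L && length(m$selected) <= 5L)
  }
})
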