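test_that("lipophilicity selection follows the ionization-dependent policy", {
  tab <- iam_fixture()
  rec <- function(nm) tab[tab$name == nm, , drop = FALSE]
  # acids always use log D at pH 7.4, even when an experimental log P exists
  amo <- select_lipophilicity(rec("amobarbital"))
  expect_identical(amo, list(value = 1.60, source = "calculated_logD74"))
  # neutrals with an experimental log P use it
  cyc <- select_lipophilicity(rec("cyclohexane"))
  expect_identical(cyc, list(value = 3.44, source = "experimental_logP"))
  # fallback is the MarvinSketch calculated column
  hep <- select_lipophilicity(rec("n-heptane"))
  expect_identical(hep, list(value = 3.28, source = "calculated_logP"))
  # forcing experimental-only never falls back silently
  expect_error(select_lipophilicity(rec("n-heptane"), "exp-only"),
               "n-heptane.*exp-only")
  # the alogps policy errors where that column is empty
  expect_error(select_lipophilicity(rec("cyclohexane"), "calc-alogps"),
               "cyclohexane")
})

test_that("calibration lines are exactly recoverable from the reference table", {
  cal <- recovered_calibrations()
  expect_equal(cal$MG$slope, 0.792, tolerance = 1e-3)
  expect_equal(cal$MG$intercept, -0.732, tolerance = 1e-3)
  expect_equal(cal$DD2$slope, 0.934, tolerance = 1e-3)
  expect_equal(cal$DD2$intercept, -0.883, tolerance = 1e-3)
  for (ph in c("MG", "DD2")) {
    d <- attr(cal[[ph]], "diagnostics")
    expect_gt(d$r2, 0.9999)   # the affine reconstruction exists
    expect_lt(d$max_abs_resid, 0.001)
    expect_false(d$degenerate)
  }
})

test_that("the as-printed table isolates isoflurane as the single outlier", {
  printed <- iam_fixture(apply_errata = FALSE)
  cal <- suppressWarnings(
    recover_calibration(printed, phase = "MG", outlier_resid = 0.05))
  d <- attr(cal, "diagnostics")
  expect_identical(d$excluded, "isoflurane")
  expect_equal(cal$slope, 0.792, tolerance = 1e-3)
  expect_equal(cal$intercept, -0.732, tolerance = 1e-3)
  # the printed isoflurane deltas back-solve to lipophilicity 2.06 on both
  # phases, the experimental log P the printed table omits
  for (ph in c("mg", "dd2")) {
    cc <- recovered_calibrations()[[toupper(ph)]]
    row <- printed[printed$name == "isoflurane", ]
    implied <- (row[[paste0("clogkw_", ph)]] - row[[paste0("delta_", ph)]] -
                  cc$intercept) / cc$slope
    expect_equal(implied, 2.06, tolerance = 0.005)
  }
})

test_that("expected retention is the calibration line", {
  cal <- recovered_calibrations()
  c0 <- phase_calibration("MG", 0.5, -1.25)
  expect_identical(expected_logkw(0, c0), -1.25)
  # back-solved from printed rows: 1,1,1-trichloroethane (MG),
  # cyclohexane (DD2)
  expect_equal(expected_logkw(2.49, cal$MG), 1.063 - (-0.177),
               tolerance = 0.005)
  expect_equal(expected_logkw(3.44, cal$DD2), 1.671 - (-0.659),
               tolerance = 0.005)
  expect_error(phase_calibration("MG", -0.1, 0), "positive")
})

test_that("delta computation reproduces printed values and is exact", {
  tab <- iam_fixture()
  cal <- recovered_calibrations()
  vpa <- compute_delta(tab[tab$name == "valproic acid", ], cal$DD2)
  expect_equal(vpa$delta, 2.079, tolerance = 0.005)
  expect_true(vpa$is_prime)
  expect_identical(vpa$lipophilicity_source, "calculated_logD74")
  tfp <- compute_delta(tab[tab$name == "trifluoperazine", ], cal$MG)
  expect_equal(tfp$delta, 0.053, tolerance = 0.005)
  expect_false(tfp$is_prime)
  # identity: a compound sitting on the line has delta zero
  on_line <- list(name = "x", ionization_class = "N",
                  clogkw_mg = expected_logkw(2, cal$MG), explogp = 2)
  expect_equal(compute_delta(on_line, cal$MG)$delta, 0)
  # exactness: delta + expected = clogkw to machine precision, all rows
  dt <- compute_delta_table(tab, cal$MG)
  expect_equal(dt$delta + dt$expected_logkw, tab$clogkw_mg,
               tolerance = 1e-12)
  # monotonicity: at fixed clogkw the delta decreases in lipophilicity
  d_lo <- compute_delta(list(name = "a", ionization_class = "N",
                             clogkw_mg = 1, explogp = 1), cal$MG)$delta
  d_hi <- compute_delta(list(name = "b", ionization_class = "N",
                             clogkw_mg = 1, explogp = 3), cal$MG)$delta
  expect_lt(d_hi, d_lo)
})

test_that("all 112 printed deltas reproduce within half the printed digit", {
  tab <- iam_fixture()
  cal <- recovered_calibrations()
  for (ph in c("MG", "DD2")) {
    dt <- compute_delta_table(tab, cal[[ph]])
    printed <- tab[[paste0("delta_", tolower(ph))]]
    expect_identical(nrow(dt), 56L)
    expect_true(all(abs(dt$delta - printed) <= 0.005))
  }
})

test_that("delta tables report policy failures instead of dropping rows silently", {
  printed <- iam_fixture(apply_errata = FALSE)
  cal <- recovered_calibrations()
  expect_warning(
    dt <- compute_delta_table(printed, cal$MG, policy = "exp-only"),
    "failed")
  fails <- attr(dt, "failures")
  # the 15 compounds published as lacking an experimental log P
  expect_identical(nrow(fails), 15L)
  expect_setequal(fails$name,
    c("1-chloro-2,2,2-trifluoroethane", "1-hydroxymidazolam",
      "3-methylhexane", "4-hydroxymidazolam", "bretazenil",
      "desmonomethylpromazine", "fluroxene", "isoflurane", "n-heptane",
      "n-hexane", "nordazepam", "northioridazine", "n-pentane", "teflurane",
      "trichloroethylene"))
  expect_identical(nrow(dt), 41L)
  # with the errata applied isoflurane regains its experimental value
  dt2 <- suppressWarnings(
    compute_delta_table(iam_fixture(), cal$MG, policy = "exp-only"))
  expect_identical(nrow(attr(dt2, "failures")), 14L)
})

test_that("lipophilicities outside the calibration range are flagged, not rejected", {
  tab <- iam_fixture()
  cal <- recovered_calibrations()
  dt <- compute_delta_table(tab, cal$MG)
  expect_true(dt$out_of_calibration_range[dt$name == "ethanol"])
  expect_false(dt$out_of_calibration_range[dt$name == "cyclohexane"])
  # empty table gives an empty result
  empty <- filter_subset(tab, -10)
  expect_identical(nrow(compute_delta_table(empty, cal$MG)), 0L)
})

test_that("calibration recovery rejects degenerate inputs", {
  tab <- toy_table()
  expect_error(recover_calibration(tab[1L, ], printed_deltas = 0,
                                   phase = "MG"),
               "at least 2")
  same <- compound_table(data.frame(
    name = c("a", "b"), ionization_class = "N", clogkw_mg = c(1, 2),
    clogkw_dd2 = c(1, 2), explogp = c(2, 2), clogp_alogps = NA_real_,
    clogp_marvin = c(2, 2), clogd74 = NA_real_, logbb = NA_real_))
  expect_error(recover_calibration(same, printed_deltas = c(0, 0),
                                   phase = "MG"),
               "degenerate spread")
})
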