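# Shared fixtures: the packaged reference table (with and without errata)
# and calibrations recovered from it, loaded once per test run.

iam_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(apply_errata = TRUE) {
    key <- if (apply_errata) "errata" else "printed"
    if (is.null(cache[[key]]))
      cache[[key]] <- iam_dataset(apply_errata = apply_errata)
    cache[[key]]
  }
})

recovered_calibrations <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$cal))
      cache$cal <- list(
        MG = recover_calibration(iam_fixture(), phase = "MG"),
        DD2 = recover_calibration(iam_fixture(), phase = "DD2"))
    cache$cal
  }
})

# tiny hand-built table used by unit tests
toy_table <- function() {
  compound_table(data.frame(
    name = c("acid1", "base1", "neutral1", "neutral2"),
    ionization_class = c("A", "B", "N", "N"),
    clogkw_mg = c(0.5, 1.2, 0.8, 1.5),
    clogkw_dd2 = c(0.6, 1.4, 0.9, 1.7),
    explogp = c(2.0, NA, 1.5, NA),
    clogp_alogps = c(1.9, 2.6, 1.4, 2.2),
    clogp_marvin = c(1.8, 2.5, 1.6, 2.3),
    clogd74 = c(0.7, NA, NA, NA),
    logbb = c(-0.5, 0.3, 0.1, NA),
    stringsAsFactors = FALSE), provenance = "toy")
}
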