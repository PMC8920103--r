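# Isolipophilic-neutral calibration lines and the phospholipophilicity-excess
# descriptor cDelta/Delta'log kw(IAM).

# Lipophilicity range over which the calibration lines were established.
.calibration_range <- c(1.0, 4.8)

#' Isolipophilic-neutral calibration line for one IAM phase
#'
#' IAM retention of structurally unrelated neutral compounds is linear in
#' octanol-water log P: `expected log kw = slope * lipophilicity + intercept`.
#' A `phase_calibration` carries that line for one phase (`MG` or `DD2`).
#'
#' @param phase `"MG"` or `"DD2"`.
#' @param slope log kw per log P unit; must be positive (retention increases
#'   with lipophilicity).
#' @param intercept log kw units.
#' @param provenance free text describing where the coefficients came from.
#' @return an object of class `phase_calibration`.
#' @export
phase_calibration <- function(phase, slope, intercept, provenance = "user") {
  phase <- match.arg(toupper(phase), c("MG", "DD2"))
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  if (slope <= 0)
    stop("calibration slope must be positive (retention increases with ",
         "lipophilicity)", call. = FALSE)
  structure(list(phase = phase, slope = slope, intercept = intercept,
                 provenance = provenance),
            class = "phase_calibration")
}

#' @export
print.phase_calibration <- function(x, ...) {
  cat(sprintf("IAM.PC.%s calibration: expected log kw = %.4f * lip %+.4f  [%s]\n",
              x$phase, x$slope, x$intercept, x$provenance))
  if (!is.null(attr(x, "diagnostics"))) {
    d <- attr(x, "diagnostics")
    cat(sprintf("  recovered from %d compound(s), r2 = %.6f, max |resid| = %.4g\n",
                d$n_used, d$r2, d$max_abs_resid))
    if (length(d$excluded) > 0L)
      cat("  excluded as outlier(s):", paste(d$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Calibration lines shipped with the package
#'
#' The default coefficients, recovered by least squares from the packaged
#' reference dataset (see [recover_calibration()]): MG slope 0.792, intercept
#' -0.732; DD2 slope 0.934, intercept -0.883.
#'
#' @return named list of [phase_calibration] objects (`MG`, `DD2`).
#' @export
iam_calibrations <- function() {
  list(
    MG  = phase_calibration("MG", 0.792, -0.732,
                            "recovered from packaged reference dataset"),
    DD2 = phase_calibration("DD2", 0.934, -0.883,
                            "recovered from packaged reference dataset")
  )
}

#' Select the lipophilicity input for one compound
#'
#' The descriptor compares a compound's IAM retention with that of a neutral
#' molecule of equal lipophilicity, so the lipophilicity scale must reflect
#' the species actually in solution: acids (class `A`) always use the
#' calculated pH 7.4 distribution coefficient log D (the primed, Delta'
#' convention); all other classes use the neutral-species log P —
#' experimental when available, otherwise a calculated column.
#'
#' @param record one-row [compound_table] (or a list with the schema fields).
#' @param policy source preference for non-acids: `"default"` (experimental,
#'   falling back to the MarvinSketch column), `"exp-only"`, `"calc-alogps"`,
#'   `"calc-marvin"`.
#' @return list with `value` (log units) and `source` (one of
#'   `experimental_logP`, `calculated_logP`, `calculated_logD74`).
#' @export
select_lipophilicity <- function(record,
                                 policy = c("default", "exp-only",
                                            "calc-alogps", "calc-marvin")) {
  policy <- match.arg(policy)
  nm <- record$name
  get <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NULL else as.numeric(v)
  }
  if (identical(record$ionization_class, "A")) {
    v <- get("clogd74")
    if (is.null(v))
      stop("no clogd74 for acid '", nm, "'", call. = FALSE)
    return(list(value = v, source = "calculated_logD74"))
  }
  pick <- switch(policy,
    "default"     = list(c("explogp", "experimental_logP"),
                         c("clogp_marvin", "calculated_logP")),
    "exp-only"    = list(c("explogp", "experimental_logP")),
    "calc-alogps" = list(c("clogp_alogps", "calculated_logP")),
    "calc-marvin" = list(c("clogp_marvin", "calculated_logP")))
  for (p in pick) {
    v <- get(p[1L])
    if (!is.null(v)) return(list(value = v, source = p[2L]))
  }
  stop("no usable lipophilicity for compound '", nm, "' under policy '",
       policy, "'", call. = FALSE)
}

#' Expected phospholipophilicity of an isolipophilic neutral
#'
#' Evaluates the calibration line at a lipophilicity value.
#'
#' @param lipophilicity log P (or log D for acids), log units.
#' @param calibration a [phase_calibration].
#' @return expected log kw, log units.
#' @export
expected_logkw <- function(lipophilicity, calibration) {
  stopifnot(inherits(calibration, "phase_calibration"))
  calibration$slope * lipophilicity + calibration$intercept
}

#' Phospholipophilicity excess of one compound
#'
#' The descriptor is the compound's calculated IAM retention minus the
#' retention expected for a neutral molecule of equal lipophilicity:
#' `delta = clog kw(phase) - expected_logkw(lipophilicity)`. For acids the
#' lipophilicity is log D at pH 7.4 and the value follows the primed (Delta')
#' convention, flagged by `is_prime`. Lipophilicities outside the calibration
#' range 1.0–4.8 are flagged (`out_of_calibration_range`), not rejected: the
#' line is routinely extrapolated to hydrophilic solutes.
#'
#' @inheritParams select_lipophilicity
#' @param calibration a [phase_calibration].
#' @return one-row data frame of class `delta_result`: `name`, `phase`,
#'   `lipophilicity_used`, `lipophilicity_source`, `expected_logkw`, `delta`,
#'   `is_prime`, `out_of_calibration_range`.
#' @export
compute_delta <- function(record, calibration, policy = "default") {
  stopifnot(inherits(calibration, "phase_calibration"))
  kw_col <- if (calibration$phase == "MG") "clogkw_mg" else "clogkw_dd2"
  kw <- record[[kw_col]]
  if (is.null(kw) || length(kw) != 1L || is.na(kw))
    stop("compound '", record$name, "' has no ", kw_col, call. = FALSE)
  lip <- select_lipophilicity(record, policy)
  exp_kw <- expected_logkw(lip$value, calibration)
  out <- data.frame(
    name = record$name,
    phase = calibration$phase,
    lipophilicity_used = lip$value,
    lipophilicity_source = lip$source,
    expected_logkw = exp_kw,
    delta = kw - exp_kw,
    is_prime = identical(lip$source, "calculated_logD74"),
    out_of_calibration_range =
      lip$value < .calibration_range[1L] | lip$value > .calibration_range[2L],
    stringsAsFactors = FALSE)
  class(out) <- c("delta_result", "data.frame")
  out
}

#' Phospholipophilicity excess for a whole table
#'
#' Applies [compute_delta()] to every record. Records that fail the
#' lipophilicity policy are reported in the `"failures"` attribute (name and
#' message) and as a warning — never silently dropped.
#'
#' @param table a [compound_table].
#' @inheritParams compute_delta
#' @return data frame of class `delta_table`, one row per successful record.
#' @export
compute_delta_table <- function(table, calibration, policy = "default") {
  stopifnot(inherits(table, "compound_table"))
  rows <- vector("list", nrow(table))
  fail <- list()
  for (i in seq_len(nrow(table))) {
    rec <- table[i, , drop = FALSE]
    rows[[i]] <- tryCatch(compute_delta(rec, calibration, policy),
                          error = function(e) {
                            fail[[length(fail) + 1L]] <<-
                              data.frame(name = rec$name,
                                         message = conditionMessage(e),
                                         stringsAsFactors = FALSE)
                            NULL
                          })
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- compute_delta(
      list(name = "x", ionization_class = "N", clogkw_mg = 0, clogkw_dd2 = 0,
           explogp = 0), calibration)[0L, ]
  failures <- if (length(fail) > 0L) do.call(rbind, fail) else
    data.frame(name = character(), message = character())
  if (nrow(failures) > 0L)
    warning(nrow(failures), " record(s) failed the lipophilicity policy: ",
            paste(failures$name, collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  structure(out, failures = failures, policy = policy,
            class = c("delta_table", "data.frame"))
}

#' Recover a calibration line from a compound table
#'
#' The published calibration equations pin expected retention to
#' lipophilicity; their coefficients are exactly recoverable from a table
#' that carries both the calculated log kw and the published delta values:
#' for each compound `clogkw - delta` is the expected retention of its
#' isolipophilic neutral, an affine function of the selected lipophilicity.
#' A least-squares fit of `clogkw - delta` on lipophilicity returns the line.
#'
#' Isolated gross outliers (typically data-entry inconsistencies in the
#' source table) can be excluded iteratively: while any absolute residual
#' exceeds `outlier_resid`, the worst point is dropped and the line refitted
#' (at most `max_outliers` drops, each logged in the diagnostics).
#'
#' @param table a [compound_table].
#' @param printed_deltas numeric vector of published delta values aligned
#'   with `table` rows, or `NULL` to use the table's own `delta_mg` /
#'   `delta_dd2` column.
#' @param phase `"MG"` or `"DD2"`.
#' @param policy lipophilicity policy passed to [select_lipophilicity()].
#' @param r2_min fits with r-squared below this are flagged degenerate
#'   (default 0.999).
#' @param outlier_resid absolute-residual threshold for iterative outlier
#'   exclusion; `Inf` disables it.
#' @param max_outliers maximum points to drop (default 3).
#' @return a [phase_calibration] with a `"diagnostics"` attribute (`r2`,
#'   `n_used`, `max_abs_resid`, `excluded`, `degenerate`).
#' @export
recover_calibration <- function(table, printed_deltas = NULL,
                                phase = c("MG", "DD2"), policy = "default",
                                r2_min = 0.999, outlier_resid = Inf,
                                max_outliers = 3L) {
  stopifnot(inherits(table, "compound_table"))
  phase <- match.arg(toupper(phase), c("MG", "DD2"))
  kw_col <- if (phase == "MG") "clogkw_mg" else "clogkw_dd2"
  if (is.null(printed_deltas)) {
    dcol <- if (phase == "MG") "delta_mg" else "delta_dd2"
    if (!dcol %in% names(table))
      stop("no printed_deltas given and table has no ", dcol, " column",
           call. = FALSE)
    printed_deltas <- table[[dcol]]
  }
  stopifnot(length(printed_deltas) == nrow(table))
  lip <- vapply(seq_len(nrow(table)), function(i)
    select_lipophilicity(table[i, , drop = FALSE], policy)$value, numeric(1))
  y <- table[[kw_col]] - printed_deltas
  ok <- is.finite(lip) & is.finite(y)
  lip <- lip[ok]; y <- y[ok]; nm <- table$name[ok]
  if (length(y) < 2L)
    stop("need at least 2 compounds with usable lipophilicity and delta",
         call. = FALSE)
  if (diff(range(lip)) < .Machine$double.eps^0.5)
    stop("degenerate spread of lipophilicities: cannot identify a slope",
         call. = FALSE)
  excluded <- character()
  repeat {
    fit <- stats::lm(y ~ lip)
    res <- stats::resid(fit)
    worst <- which.max(abs(res))
    if (length(excluded) >= max_outliers || abs(res[worst]) <= outlier_resid)
      break
    excluded <- c(excluded, nm[worst])
    lip <- lip[-worst]; y <- y[-worst]; nm <- nm[-worst]
    if (length(y) < 3L) stop("too few points left after outlier exclusion",
                             call. = FALSE)
  }
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  cal <- phase_calibration(phase, unname(stats::coef(fit)[2L]),
                           unname(stats::coef(fit)[1L]),
                           provenance = "recovered by least squares")
  attr(cal, "diagnostics") <- list(
    r2 = r2, n_used = length(y),
    max_abs_resid = max(abs(stats::resid(fit))),
    excluded = excluded, degenerate = r2 < r2_min)
  if (r2 < r2_min)
    warning(sprintf("calibration fit is degenerate: r2 = %.5f < %.5f",
                    r2, r2_min), call. = FALSE)
  cal
}

#' Write a delta table to CSV
#'
#' Columns: `name,phase,lipophilicity_used,lipophilicity_source,`
#' `expected_logkw,delta,is_prime,out_of_calibration_range`.
#'
#' @param deltas a `delta_table` from [compute_delta_table()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_delta_table <- function(deltas, path) {
  stopifnot(inherits(deltas, "delta_table"))
  utils::write.csv(as.data.frame(deltas), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a calibration file
#'
#' Accepts CSV (`phase,slope,intercept,provenance`) or YAML (a mapping or a
#' list of mappings with those keys).
#'
#' @param path file to read.
#' @return named list of [phase_calibration] objects keyed by phase.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$phase)) y <- list(y)
    recs <- lapply(y, function(r)
      phase_calibration(r$phase, r$slope, r$intercept,
                        r$provenance %||% "file"))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(df)), function(i)
      phase_calibration(df$phase[i], df$slope[i], df$intercept[i],
                        if ("provenance" %in% names(df)) df$provenance[i]
                        else "file"))
  }
  stats::setNames(recs, vapply(recs, `[[`, "", "phase"))
}
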