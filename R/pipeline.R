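# End-to-end orchestration: the analyses of the reference study as single
# calls, with optional file output and a reproducibility manifest.

.write_manifest <- function(out_dir, command, params) {
  manifest <- list(
    command = command,
    package = "iamdelta",
    version = as.character(utils::packageVersion("iamdelta")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameters = params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.resolve_calibration <- function(calibration, table, policy) {
  if (inherits(calibration, "phase_calibration"))
    return(stats::setNames(list(calibration), calibration$phase))
  if (is.list(calibration)) return(calibration)
  if (identical(calibration, "shipped")) return(iam_calibrations())
  if (identical(calibration, "recover"))
    return(list(
      MG = recover_calibration(table, phase = "MG", policy = policy),
      DD2 = recover_calibration(table, phase = "DD2", policy = policy)))
  if (is.character(calibration) && file.exists(calibration))
    return(read_calibration(calibration))
  stop("calibration must be 'shipped', 'recover', a file path, or ",
       "phase_calibration object(s)", call. = FALSE)
}

#' Compute delta descriptors for a table, both phases
#'
#' Runs [compute_delta_table()] for the requested phases and optionally
#' writes one CSV per phase, a calibration report and a manifest.
#'
#' @param table a [compound_table] (default: the packaged dataset).
#' @param phases subset of `c("MG", "DD2")`.
#' @param policy lipophilicity policy, see [select_lipophilicity()].
#' @param calibration `"shipped"`, `"recover"`, a calibration file path, or a
#'   named list of [phase_calibration] objects.
#' @param out_dir optional output directory (created if needed).
#' @return list with `deltas` (named list of `delta_table`s) and
#'   `calibration` (the calibrations used).
#' @export
run_deltas <- function(table = iam_dataset(), phases = c("MG", "DD2"),
                       policy = "default", calibration = "shipped",
                       out_dir = NULL) {
  phases <- match.arg(toupper(phases), c("MG", "DD2"), several.ok = TRUE)
  cals <- .resolve_calibration(calibration, table, policy)
  deltas <- lapply(phases, function(ph)
    compute_delta_table(table, cals[[ph]], policy))
  names(deltas) <- phases
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ph in phases)
      write_delta_table(deltas[[ph]],
                        file.path(out_dir, sprintf("deltas_%s.csv",
                                                   tolower(ph))))
    cal_df <- do.call(rbind, lapply(cals[phases], function(cc)
      data.frame(phase = cc$phase, slope = cc$slope,
                 intercept = cc$intercept, provenance = cc$provenance)))
    utils::write.csv(cal_df, file.path(out_dir, "calibration.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, "deltas",
                    list(phases = phases, policy = policy,
                         n_compounds = nrow(table),
                         provenance = attr(table, "provenance")))
  }
  list(deltas = deltas, calibration = cals[phases])
}

#' Reproduce the headline log BB analyses
#'
#' For each phase: the full-dataset simple regression of log BB on the delta
#' descriptor, and the low-permeation subset regression
#' (`logbb < subset_threshold`, with the flagged outlier excluded). Also
#' emits the x-y point sets behind the regressions so the figures can be
#' redrawn from files.
#'
#' @inheritParams run_deltas
#' @param subset_threshold log BB cut for the subset analysis (strict `<`).
#' @param exclude compounds excluded from the subset analysis (explicit and
#'   logged; default the flagged outlier valproic acid).
#' @return list of class `iam_report`: `full` and `subset` (named lists of
#'   `iam_ols` per phase), `stats_table` (data frame panel), `deltas`,
#'   `calibration`, `figure_data`.
#' @export
run_reproduce <- function(table = iam_dataset(), policy = "default",
                          calibration = "recover",
                          subset_threshold = -0.20,
                          exclude = "valproic acid", out_dir = NULL) {
  dr <- run_deltas(table, c("MG", "DD2"), policy, calibration)
  fits_full <- lapply(c(MG = "MG", DD2 = "DD2"), function(ph)
    fit_logbb_simple(table, dr$deltas[[ph]], ph))
  fits_sub <- lapply(c(MG = "MG", DD2 = "DD2"), function(ph)
    fit_logbb_simple(table, dr$deltas[[ph]], ph,
                     subset_threshold = subset_threshold,
                     exclude = exclude))
  panel <- function(f, label, scope) data.frame(
    variable = label, scope = scope, n = f$n, r2 = f$r2, q2 = f$q2_loo,
    se = f$se, f_stat = f$f_stat, p = f$p_value,
    pc_sse = f$pc_amemiya[["sse_like"]],
    pc_standard = f$pc_amemiya[["standard"]],
    slope = unname(f$coefficients[1L]), intercept = f$intercept,
    excluded = paste(f$excluded, collapse = ";"),
    stringsAsFactors = FALSE)
  stats_table <- rbind(
    panel(fits_full$MG, "delta_mg", "full"),
    panel(fits_full$DD2, "delta_dd2", "full"),
    panel(fits_sub$MG, "delta_mg", "subset"),
    panel(fits_sub$DD2, "delta_dd2", "subset"))
  fig <- lapply(c(MG = "MG", DD2 = "DD2"), function(ph) {
    d <- dr$deltas[[ph]]
    idx <- match(table$name, d$name)
    data.frame(name = table$name, delta = d$delta[idx],
               logbb = table$logbb,
               in_subset = table$name %in% fits_sub[[ph]]$compounds,
               stringsAsFactors = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(stats_table, file.path(out_dir, "regression_panel.csv"),
                     row.names = FALSE)
    for (ph in c("MG", "DD2"))
      utils::write.csv(fig[[ph]],
                       file.path(out_dir,
                                 sprintf("figure_logbb_vs_delta_%s.csv",
                                         tolower(ph))),
                       row.names = FALSE, na = "")
    .write_manifest(out_dir, "reproduce",
                    list(policy = policy,
                         subset_threshold = subset_threshold,
                         exclude = exclude, n_compounds = nrow(table)))
  }
  structure(list(full = fits_full, subset = fits_sub,
                 stats_table = stats_table, deltas = dr$deltas,
                 calibration = dr$calibration, figure_data = fig),
            class = "iam_report")
}

#' @export
print.iam_report <- function(x, ...) {
  cat("log BB vs phospholipophilicity-excess report\n")
  df <- x$stats_table
  df$r2 <- round(df$r2, 3); df$q2 <- round(df$q2, 3)
  df$se <- round(df$se, 3); df$f_stat <- round(df$f_stat, 2)
  print(df[, c("variable", "scope", "n", "r2", "q2", "se", "f_stat",
               "excluded")])
  invisible(x)
}

#' Run the automatic model search end to end
#'
#' Thin wrapper over [stepwise_qspr()] that can write the ranked-model
#' report as JSON together with a manifest.
#'
#' @inheritParams stepwise_qspr
#' @param out_dir optional output directory.
#' @return the `stepwise_search` object.
#' @export
run_stepwise <- function(matrix, response, r2_min = 0.1, vif_threshold = 5,
                         max_vars = 5, objective = "q2",
                         exclusion_search = FALSE, out_dir = NULL) {
  res <- stepwise_qspr(matrix, response, r2_min = r2_min,
                       vif_threshold = vif_threshold, max_vars = max_vars,
                       objective = objective,
                       exclusion_search = exclusion_search)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- lapply(res$models, function(m) {
      s <- if (!is.null(m$excluded_compound)) m$summary_excluded else
        m$summary
      list(selected = m$selected,
           coefficients = as.list(s$coefficients),
           intercept = s$intercept, n = s$n, k = s$k, r2 = s$r2,
           q2 = s$q2_loo, se = s$se, f = s$f_stat, p = s$p_value,
           pc_sse = s$pc_amemiya[["sse_like"]],
           pc_standard = s$pc_amemiya[["standard"]],
           vif = as.list(m$vif),
           excluded_compound = m$excluded_compound)
    })
    jsonlite::write_json(report, file.path(out_dir, "stepwise_models.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    vf <- attr(res, "vif")
    .write_manifest(out_dir, "stepwise",
                    list(r2_min = r2_min, vif_threshold = vif_threshold,
                         max_vars = max_vars, objective = objective,
                         exclusion_search = exclusion_search,
                         vif_removed = if (!is.null(vf))
                           vf$removed$descriptor else character()))
  }
  res
}

#' Generate and write a synthetic study bundle
#'
#' Writes the synthetic compound table (CSV), descriptor matrix (CSV) and
#' the generating truths (JSON) for a configuration.
#'
#' @param config a [synthetic_config].
#' @param out_dir output directory (created if needed).
#' @return list with `compounds` (generator output), `descriptors`
#'   (generator output) and the file paths written.
#' @export
run_synth <- function(config = synthetic_config(), out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comp <- gen_compound_table(config)
  desc <- gen_descriptor_matrix(config)
  paths <- list(
    compounds = file.path(out_dir, "synthetic_compounds.csv"),
    descriptors = file.path(out_dir, "synthetic_descriptors.csv"),
    truths = file.path(out_dir, "synthetic_truths.json"))
  write_compound_table(comp$table, paths$compounds)
  utils::write.csv(data.frame(name = rownames(desc$x),
                              as.data.frame(unclass(desc$x)),
                              check.names = FALSE),
                   paths$descriptors, row.names = FALSE)
  truths <- list(
    seed = config$seed,
    calibration = lapply(comp$truth$calibration, function(cc)
      list(phase = cc$phase, slope = cc$slope, intercept = cc$intercept)),
    logbb_model = comp$truth$logbb_model,
    deltas = comp$truth$deltas,
    descriptor_model = list(
      planted = as.list(desc$truth$planted),
      intercept = desc$truth$intercept,
      collinear_pair = desc$truth$collinear_pair,
      rho = desc$truth$rho, noise_sd = desc$truth$noise_sd),
    response = desc$y)
  jsonlite::write_json(truths, paths$truths, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")
  .write_manifest(out_dir, "synth", list(seed = config$seed,
                                         n_compounds = config$n_compounds))
  list(compounds = comp, descriptors = desc, paths = paths)
}
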