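# Seeded generators producing compound tables and descriptor matrices with
# the statistical structure the analysis assumes: a linear retention vs
# lipophilicity backbone, class-dependent polar excess, and descriptor
# matrices with a planted linear response model, a collinear pair and
# pure-noise decoys.

# Substream offsets of the seed-splitting scheme: each generator seeds its
# own stream as (seed + offset), so adding a generator never perturbs the
# output of an existing one.
.seed_offsets <- c(compounds = 0L, descriptors = 1000000L)

#' Configuration of the synthetic generators
#'
#' Defaults mimic the packaged reference dataset: 56 compounds, the shipped
#' calibration lines as the generating truth, lipophilicity spanning
#' -1.5 to 6 log units, class-dependent polar excess roughly spanning the
#' observed -1 to 2 range of the delta descriptor, and a log BB model that is
#' linear in the DD2 delta with negative slope.
#'
#' @param seed integer; drives every random stream through a documented
#'   offset-splitting scheme.
#' @param n_compounds number of compounds to generate.
#' @param class_proportions named probabilities over `A`, `B`, `BB`, `N`
#'   (must sum to 1).
#' @param calibration_true named list of [phase_calibration] (`MG`, `DD2`)
#'   used as the generating truth.
#' @param polar_excess data frame with columns `class`, `mean`, `sd`: the
#'   per-class distribution of the true phospholipophilicity excess.
#' @param lip_range min/max of the uniform lipophilicity draw.
#' @param acid_shift_range min/max of the (positive) ionization shift
#'   subtracted from an acid's log P to give its pH 7.4 log D.
#' @param noise_sd per-phase retention noise (log kw units).
#' @param p_explogp probability a non-acid carries an experimental log P.
#' @param logbb_model list `intercept`, `slope` (on the DD2 delta), `sd`.
#' @param descriptor_config list `n_obs`, `n_descriptors`, `planted` (named
#'   coefficient vector over descriptor names), `intercept`,
#'   `collinear_rho`, `noise_sd`.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_compounds = 56L,
                             class_proportions = c(A = 5, B = 8, BB = 2,
                                                   N = 41) / 56,
                             calibration_true = iam_calibrations(),
                             polar_excess = data.frame(
                               class = c("A", "B", "BB", "N"),
                               mean = c(1.1, 0.1, 0.7, 0.1),
                               sd = c(0.4, 0.3, 0.6, 0.5)),
                             lip_range = c(-1.5, 6),
                             acid_shift_range = c(0.3, 2.5),
                             noise_sd = 0.05,
                             p_explogp = 0.75,
                             logbb_model = list(intercept = 0.3,
                                                slope = -0.55, sd = 0.4),
                             descriptor_config = list(
                               n_obs = 60L, n_descriptors = 15L,
                               planted = c(d01 = 1.5, d02 = -2.0,
                                           d03 = 0.8),
                               intercept = 0.5, collinear_rho = 0.95,
                               noise_sd = 0.1)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  if (!all(sort(names(class_proportions)) == c("A", "B", "BB", "N")))
    stop("class proportions must be named A, B, BB, N", call. = FALSE)
  if (any(polar_excess$sd < 0) || noise_sd < 0 || logbb_model$sd < 0 ||
      descriptor_config$noise_sd < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  if (length(descriptor_config$planted) > descriptor_config$n_descriptors)
    stop("planted subset larger than n_descriptors", call. = FALSE)
  if (diff(range(acid_shift_range)) < 0 || acid_shift_range[1L] <= 0)
    stop("acid ionization shift must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_compounds = as.integer(n_compounds),
                 class_proportions = class_proportions,
                 calibration_true = calibration_true,
                 polar_excess = polar_excess, lip_range = lip_range,
                 acid_shift_range = acid_shift_range, noise_sd = noise_sd,
                 p_explogp = p_explogp, logbb_model = logbb_model,
                 descriptor_config = descriptor_config),
            class = "synthetic_config")
}

#' Read a synthetic-generator configuration from YAML
#'
#' Keys map one-to-one onto the arguments of [synthetic_config()]; omitted
#' keys keep their defaults.
#'
#' @param path YAML file.
#' @return a [synthetic_config].
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("seed", "n_compounds", "lip_range", "acid_shift_range",
               "noise_sd", "p_explogp"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$class_proportions))
    args$class_proportions <- unlist(y$class_proportions)
  if (!is.null(y$calibration_true))
    args$calibration_true <- lapply(y$calibration_true, function(r)
      phase_calibration(r$phase, r$slope, r$intercept, "config file"))
  if (!is.null(y$polar_excess))
    args$polar_excess <- do.call(rbind, lapply(y$polar_excess, as.data.frame))
  if (!is.null(y$logbb_model)) args$logbb_model <- y$logbb_model
  if (!is.null(y$descriptor_config)) {
    dc <- y$descriptor_config
    if (!is.null(dc$planted)) dc$planted <- unlist(dc$planted)
    args$descriptor_config <-
      utils::modifyList(formals(synthetic_config)$descriptor_config |>
                          eval(), dc)
  }
  do.call(synthetic_config, args)
}

#' Generate a synthetic compound table with known truths
#'
#' Retention on each phase is the calibration line evaluated at the
#' compound's effective lipophilicity, plus a class-dependent polar excess
#' (shared across phases) and per-phase noise. Acids get
#' `clogd74 = explogp - shift` with a positive ionization shift, and their
#' effective lipophilicity is the log D, mirroring the primed-delta
#' convention. The generating truths (calibrations, per-compound true delta
#' on each phase) are returned alongside the table.
#'
#' @param config a [synthetic_config].
#' @return list with `table` (a [compound_table]) and `truth` (list:
#'   `calibration`, `deltas` data frame with the true per-phase excess, and
#'   the `logbb` model used).
#' @export
gen_compound_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + .seed_offsets[["compounds"]])
  n <- config$n_compounds
  cls <- sample(names(config$class_proportions), n, replace = TRUE,
                prob = config$class_proportions)
  lip <- stats::runif(n, config$lip_range[1L], config$lip_range[2L])
  shift <- stats::runif(n, config$acid_shift_range[1L],
                        config$acid_shift_range[2L])
  has_exp <- stats::runif(n) < config$p_explogp
  is_a <- cls == "A"
  explogp <- ifelse(is_a | has_exp, lip, NA_real_)
  clogd74 <- ifelse(is_a, lip - shift, NA_real_)
  clogp_marvin <- lip + stats::rnorm(n, 0, 0.3)
  clogp_alogps <- lip + stats::rnorm(n, 0, 0.3)
  # the retention backbone is built on the lipophilicity a consumer of the
  # table will select: log D for acids, experimental log P when recorded,
  # otherwise the calculated fallback column
  eff_lip <- ifelse(is_a, clogd74, ifelse(has_exp, lip, clogp_marvin))
  pe <- config$polar_excess
  idx <- match(cls, pe$class)
  excess <- stats::rnorm(n, pe$mean[idx], pe$sd[idx])
  cal <- config$calibration_true
  kw_mg <- expected_logkw(eff_lip, cal$MG) + excess +
    stats::rnorm(n, 0, config$noise_sd)
  kw_dd2 <- expected_logkw(eff_lip, cal$DD2) + excess +
    stats::rnorm(n, 0, config$noise_sd)
  delta_mg <- kw_mg - expected_logkw(eff_lip, cal$MG)
  delta_dd2 <- kw_dd2 - expected_logkw(eff_lip, cal$DD2)
  lb <- config$logbb_model
  logbb <- lb$intercept + lb$slope * delta_dd2 + stats::rnorm(n, 0, lb$sd)
  nm <- sprintf("cmpd%03d", seq_len(n))
  tab <- compound_table(data.frame(
    name = nm, ionization_class = cls,
    clogkw_mg = kw_mg, clogkw_dd2 = kw_dd2,
    explogp = explogp, clogp_alogps = clogp_alogps,
    clogp_marvin = clogp_marvin,
    clogd74 = clogd74, logbb = logbb, stringsAsFactors = FALSE),
    provenance = sprintf("synthetic (seed %d)", config$seed))
  list(table = tab,
       truth = list(calibration = cal,
                    deltas = data.frame(name = nm, class = cls,
                                        lipophilicity = eff_lip,
                                        excess = excess,
                                        delta_mg = delta_mg,
                                        delta_dd2 = delta_dd2,
                                        stringsAsFactors = FALSE),
                    logbb_model = lb))
}

#' Generate a synthetic descriptor matrix with a planted linear model
#'
#' Independent standard-normal descriptor columns, of which a named subset
#' drives the response linearly; one extra column (`collin`) is correlated
#' with the first planted descriptor at the configured correlation, and all
#' remaining columns are pure-noise decoys. The planted coefficients,
#' intercept and collinear pair are returned as truths.
#'
#' @param config a [synthetic_config] (uses its `descriptor_config`).
#' @return list with `x` (a [descriptor_matrix]), `y` (response vector) and
#'   `truth` (list: `planted`, `intercept`, `collinear_pair`, `rho`,
#'   `noise_sd`).
#' @export
gen_descriptor_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + .seed_offsets[["descriptors"]])
  dc <- config$descriptor_config
  n <- dc$n_obs; p <- dc$n_descriptors
  nm <- sprintf("d%02d", seq_len(p))
  x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(
    sprintf("obs%03d", seq_len(n)), nm))
  planted <- dc$planted
  if (!all(names(planted) %in% nm))
    stop("planted descriptor names must be among the generated columns",
         call. = FALSE)
  rho <- dc$collinear_rho
  anchor <- if (length(planted) > 0L) names(planted)[1L] else nm[1L]
  collin <- rho * x[, anchor] + sqrt(1 - rho^2) * stats::rnorm(n)
  x <- cbind(x, collin = collin)
  y <- dc$intercept +
    as.numeric(x[, names(planted), drop = FALSE] %*% planted) +
    stats::rnorm(n, 0, dc$noise_sd)
  list(x = descriptor_matrix(x), y = y,
       truth = list(planted = planted, intercept = dc$intercept,
                    collinear_pair = c(anchor, "collin"), rho = rho,
                    noise_sd = dc$noise_sd))
}
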