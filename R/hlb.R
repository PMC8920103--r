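# Hydrophilic-lipophilic balance (HLB) calculators and a pluggable linear
# QSPR evaluator for phospholipophilicity models.

#' Griffin HLB
#'
#' Mass-fraction definition: `20 * hydrophilic_mass / molar_mass`, bounded in
#' \[0, 20\].
#'
#' @param hydrophilic_mass mass of the hydrophilic portion of the molecule.
#' @param molar_mass total molar mass (> 0).
#' @return dimensionless HLB value.
#' @export
hlb_griffin <- function(hydrophilic_mass, molar_mass) {
  if (any(molar_mass <= 0))
    stop("molar_mass must be positive", call. = FALSE)
  if (any(hydrophilic_mass < 0 | hydrophilic_mass > molar_mass))
    stop("hydrophilic_mass must lie in [0, molar_mass]", call. = FALSE)
  20 * hydrophilic_mass / molar_mass
}

#' Davies HLB
#'
#' Group-contribution definition:
#' `7 + sum(hydrophilic group numbers) - 0.475 * n_lipophilic_groups`.
#' The standard group numbers of the Davies method ship as an editable table,
#' see [davies_groups()].
#'
#' @param hydrophilic_group_numbers numeric vector of group-contribution
#'   values (may be empty).
#' @param n_lipophilic_groups non-negative count of lipophilic (CH-type)
#'   groups.
#' @return dimensionless HLB value.
#' @export
hlb_davies <- function(hydrophilic_group_numbers = numeric(),
                       n_lipophilic_groups = 0) {
  stopifnot(is.numeric(hydrophilic_group_numbers),
            length(n_lipophilic_groups) == 1L, n_lipophilic_groups >= 0)
  7 + sum(hydrophilic_group_numbers) - 0.475 * n_lipophilic_groups
}

#' Standard Davies group-contribution table
#'
#' Loads the packaged table of standard hydrophilic group numbers and the
#' lipophilic CH-group decrement (-0.475) used by [hlb_davies()]. Users may
#' edit a copy and load it with `utils::read.csv`.
#'
#' @return data frame with columns `group`, `contribution`, `type`.
#' @export
davies_groups <- function() {
  utils::read.csv(system.file("extdata", "davies_groups.csv",
                              package = "iamdelta", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Surface-based HLB
#'
#' Steric variant built from surface areas: `scale * PSA / Surface`, where
#' PSA is the polar surface area and Surface the total molecular surface.
#' The scale defaults to 20 so the value spans the same \[0, 20\] range as
#' the Griffin scale.
#'
#' @param psa polar surface area (area units).
#' @param total_surface total surface area (same units, > 0).
#' @param scale range scale (default 20).
#' @return dimensionless HLB value.
#' @export
hlb_psa <- function(psa, total_surface, scale = 20) {
  if (any(total_surface <= 0))
    stop("total_surface must be positive", call. = FALSE)
  if (any(psa < 0 | psa > total_surface))
    stop("psa must lie in [0, total_surface]", call. = FALSE)
  scale * psa / total_surface
}

#' Combined HLB profile
#'
#' Collects the three HLB variants and their arithmetic mean (the balanced
#' HLB used as a descriptor, `hlb_mean`). All three components are required.
#'
#' @param hlb_griffin,hlb_davies,hlb_psa the three component values.
#' @return list of class `hlb_profile` with fields `hlb_griffin`,
#'   `hlb_davies`, `hlb_psa`, `hlb_mean`.
#' @export
hlb_profile <- function(hlb_griffin, hlb_davies, hlb_psa) {
  comps <- list(griffin = hlb_griffin, davies = hlb_davies, psa = hlb_psa)
  missing <- names(comps)[vapply(comps, function(v)
    is.null(v) || length(v) != 1L || is.na(v), logical(1))]
  if (length(missing) > 0L)
    stop("missing HLB component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(hlb_griffin = hlb_griffin, hlb_davies = hlb_davies,
                 hlb_psa = hlb_psa,
                 hlb_mean = mean(c(hlb_griffin, hlb_davies, hlb_psa))),
            class = "hlb_profile")
}

#' @export
print.hlb_profile <- function(x, ...) {
  cat(sprintf("HLB profile: Griffin %.3f | Davies %.3f | surface %.3f | mean %.3f\n",
              x$hlb_griffin, x$hlb_davies, x$hlb_psa, x$hlb_mean))
  invisible(x)
}

#' Pluggable linear phospholipophilicity model
#'
#' A linear QSPR `log kw = intercept + sum(coefficient * descriptor)` with
#' user-supplied coefficients (e.g. from the published IAM retention models
#' or the associated web service — the package ships no coefficients of its
#' own; the packaged dataset's clog kw columns are the authoritative
#' precomputed output).
#'
#' @param phase `"MG"` or `"DD2"`.
#' @param terms named numeric vector: coefficients keyed by descriptor name
#'   (names must be unique).
#' @param intercept log kw units.
#' @param metadata optional list of published statistics (`n`, `r2`, `se`,
#'   `f`, `p`, `pc`).
#' @return object of class `linear_qspr`.
#' @export
linear_qspr <- function(phase, terms, intercept, metadata = NULL) {
  phase <- match.arg(toupper(phase), c("MG", "DD2"))
  stopifnot(is.numeric(terms), is.numeric(intercept),
            length(intercept) == 1L)
  if (length(terms) > 0L &&
      (is.null(names(terms)) || any(!nzchar(names(terms)))))
    stop("every model term needs a descriptor name", call. = FALSE)
  if (anyDuplicated(names(terms)))
    stop("duplicate descriptor names in model terms", call. = FALSE)
  structure(list(phase = phase, terms = terms, intercept = intercept,
                 metadata = metadata),
            class = "linear_qspr")
}

#' Evaluate a linear QSPR
#'
#' @param descriptors named numeric vector or list of descriptor values; must
#'   contain every descriptor named by the model.
#' @param model a [linear_qspr].
#' @return predicted log kw (log units).
#' @export
predict_logkw <- function(descriptors, model) {
  stopifnot(inherits(model, "linear_qspr"))
  descriptors <- unlist(descriptors)
  need <- names(model$terms)
  missing <- setdiff(need, names(descriptors))
  if (length(missing) > 0L)
    stop("missing descriptor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  model$intercept + sum(model$terms * descriptors[need])
}

#' @export
predict.linear_qspr <- function(object, newdata, ...) {
  if (is.data.frame(newdata))
    return(vapply(seq_len(nrow(newdata)), function(i)
      predict_logkw(as.list(newdata[i, , drop = FALSE]), object), numeric(1)))
  predict_logkw(newdata, object)
}

#' @export
print.linear_qspr <- function(x, ...) {
  rhs <- if (length(x$terms) == 0L) "" else
    paste(sprintf(" %+.4g %s", x$terms, names(x$terms)), collapse = "")
  cat(sprintf("Linear QSPR [IAM.PC.%s]: log kw = %.4g%s\n",
              x$phase, x$intercept, rhs))
  invisible(x)
}

#' Read a linear QSPR model from YAML
#'
#' Expected keys: `phase`, `intercept`, `terms` (list of
#' `{descriptor, coefficient}`), optional `metadata`.
#'
#' @param path YAML file.
#' @return a [linear_qspr].
#' @export
read_qspr <- function(path) {
  y <- yaml::read_yaml(path)
  terms <- vapply(y$terms, function(t) as.numeric(t$coefficient), numeric(1))
  names(terms) <- vapply(y$terms, function(t) as.character(t$descriptor), "")
  linear_qspr(y$phase, terms, as.numeric(y$intercept), y$metadata)
}
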