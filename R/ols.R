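# Ordinary least squares with the QSPR statistics panel: r2, leave-one-out
# q2, SE of the estimate, F, p, and the Amemiya predictive criterion.

#' Fit an OLS model with the full QSPR statistics panel
#'
#' Least-squares regression of `response` on the columns of `predictors`
#' (intercept always included), returning a classed model object carrying the
#' panel used throughout the package: r-squared, leave-one-out
#' cross-validated q-squared (`1 - PRESS/SST`, computed by the exact
#' hat-matrix identity `PRESS = sum((e_i / (1 - h_ii))^2)`), standard error
#' of the estimate `sqrt(SSE / (n - k - 1))`, the Fisher statistic
#' `(r2/k) / ((1 - r2)/(n - k - 1))` with its upper-tail p-value, and both
#' variants of the Amemiya predictive criterion (see [amemiya_pc()]).
#'
#' @param predictors numeric matrix or data frame, observations in rows.
#' @param response numeric vector, same length as `nrow(predictors)`.
#' @param variable_names optional predictor names (default: column names).
#' @param excluded names of observations removed upstream, recorded verbatim
#'   in the summary.
#' @param loo compute q2 (default `TRUE`; needs `n >= k + 3`).
#' @return object of class `iam_ols` with `print`, `summary`, `coef`,
#'   `predict` and `residuals` methods.
#' @export
fit_ols <- function(predictors, response, variable_names = NULL,
                    excluded = character(), loo = TRUE) {
  x <- as.matrix(predictors)
  storage.mode(x) <- "double"
  y <- as.numeric(response)
  n <- length(y); k <- ncol(x)
  if (nrow(x) != n) stop("predictors and response lengths differ",
                         call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("absent values in the regression inputs", call. = FALSE)
  if (n < k + 2L)
    stop("too few observations: need n >= k + 2 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  if (is.null(variable_names))
    variable_names <- colnames(x) %||% paste0("x", seq_len(k))
  colnames(x) <- variable_names
  qrx <- qr(cbind(1, x))
  if (qrx$rank < k + 1L) {
    drop_idx <- qrx$pivot[seq.int(qrx$rank + 1L, k + 1L)] - 1L
    stop("rank-deficient predictors; collinear column(s): ",
         paste(variable_names[drop_idx[drop_idx > 0L]], collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(.y = y, x, check.names = FALSE)
  fit <- stats::lm(stats::reformulate(sprintf("`%s`", variable_names),
                                      response = ".y"), data = df)
  e <- stats::resid(fit)
  sse <- sum(e^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  se <- sqrt(sse / (n - k - 1L))
  f_stat <- (r2 / k) / ((1 - r2) / (n - k - 1L))
  p_value <- stats::pf(f_stat, k, n - k - 1L, lower.tail = FALSE)
  q2 <- NA_real_
  if (loo && n >= k + 3L) {
    h <- stats::lm.influence(fit, do.coef = FALSE)$hat
    press <- sum((e / (1 - h))^2)
    q2 <- 1 - press / sst
  }
  cf <- stats::coef(fit)
  structure(list(
    fit = fit, n = n, k = k,
    coefficients = cf[-1L], intercept = unname(cf[1L]),
    variable_names = variable_names,
    r2 = r2, q2_loo = q2, se = se, f_stat = f_stat, p_value = p_value,
    sse = sse, sst = sst,
    pc_amemiya = c(standard = amemiya_pc(sse, n, k, "standard"),
                   sse_like = amemiya_pc(sse, n, k, "sse_like")),
    excluded = excluded), class = "iam_ols")
}

#' @export
print.iam_ols <- function(x, digits = 3, ...) {
  cat(sprintf("OLS: n = %d, k = %d\n", x$n, x$k))
  cat("  intercept:", format(x$intercept, digits = digits + 1), "\n")
  cat("  slopes:\n")
  print(round(x$coefficients, digits + 1))
  cat(sprintf("  r2 = %.*f | q2(LOO) = %s | SE = %.*f\n", digits, x$r2,
              if (is.na(x$q2_loo)) "NA" else
                formatC(x$q2_loo, digits = digits, format = "f"),
              digits, x$se))
  cat(sprintf("  F(%d,%d) = %.2f, p = %.3g | PC: standard %.4g, SSE-like %.4g\n",
              x$k, x$n - x$k - 1L, x$f_stat, x$p_value,
              x$pc_amemiya[["standard"]], x$pc_amemiya[["sse_like"]]))
  if (length(x$excluded) > 0L)
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.iam_ols <- function(object, ...) {
  out <- object[c("n", "k", "coefficients", "intercept", "r2", "q2_loo",
                  "se", "f_stat", "p_value", "pc_amemiya", "excluded")]
  class(out) <- "summary.iam_ols"
  out
}

#' @export
print.summary.iam_ols <- function(x, ...) {
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
coef.iam_ols <- function(object, ...)
  c("(Intercept)" = object$intercept, object$coefficients)

#' @export
predict.iam_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  nd <- as.data.frame(newdata)
  missing <- setdiff(object$variable_names, names(nd))
  if (length(missing) > 0L)
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  object$intercept +
    as.numeric(as.matrix(nd[, object$variable_names, drop = FALSE]) %*%
                 object$coefficients)
}

#' @export
residuals.iam_ols <- function(object, ...) stats::resid(object$fit)

#' Leave-one-out cross-validated q-squared (brute force)
#'
#' Computes `q2 = 1 - PRESS/SST` by explicitly refitting the model `n` times,
#' each time with one observation held out and predicted from the remaining
#' fit; SST is taken about the full-sample mean. This is the reference
#' implementation: [fit_ols()] reports the same quantity via the exact
#' hat-matrix shortcut, and the two are tested against each other.
#'
#' @inheritParams fit_ols
#' @return q2, dimensionless.
#' @export
loo_q2 <- function(predictors, response) {
  x <- as.matrix(predictors)
  storage.mode(x) <- "double"
  y <- as.numeric(response)
  n <- length(y); k <- ncol(x)
  if (n < k + 3L)
    stop("too few observations for leave-one-out: need n >= k + 3",
         call. = FALSE)
  press <- 0
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    qrx <- qr(cbind(1, xi))
    if (qrx$rank < k + 1L)
      stop("leave-one-out fit is rank-deficient when dropping observation ",
           i, call. = FALSE)
    beta <- qr.coef(qrx, y[-i])
    press <- press + (y[i] - sum(c(1, x[i, ]) * beta))^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Amemiya predictive criterion
#'
#' Two variants are exposed because published QSPR software disagrees on the
#' formula. `"standard"` is the textbook criterion
#' `(SSE / (n - k - 1)) * (1 + (k + 1)/n)`; `"sse_like"` reports the raw SSE,
#' which is the scale on which the packaged reference statistics tabulate
#' their `PC` column. Neither is asserted as canonical; both are always
#' reported by [fit_ols()].
#'
#' @param sse residual sum of squares.
#' @param n observations; must exceed `k + 1`.
#' @param k number of predictors (excluding intercept).
#' @param variant `"standard"` or `"sse_like"`.
#' @return criterion value.
#' @export
amemiya_pc <- function(sse, n, k, variant = c("standard", "sse_like")) {
  variant <- match.arg(variant)
  stopifnot(n > k + 1L, sse >= 0)
  switch(variant,
         standard = (sse / (n - k - 1L)) * (1 + (k + 1L) / n),
         sse_like = sse)
}

#' Regress log BB on a phospholipophilicity-excess descriptor
#'
#' The headline analysis: simple OLS of experimental log BB on the delta
#' descriptor of one IAM phase, optionally restricted to the low-permeation
#' subset (`logbb < subset_threshold`) and with named compounds excluded
#' (exclusions are explicit, logged in the returned summary, never silent).
#'
#' @param table a [compound_table] with `logbb` values.
#' @param deltas a `delta_table` from [compute_delta_table()] (or any data
#'   frame with `name` and `delta` columns) covering the regressed compounds.
#' @param phase `"MG"` or `"DD2"` (label only; `deltas` must already be for
#'   this phase).
#' @param subset_threshold optional log BB cut; strict `<` comparison.
#' @param exclude compound names to drop before fitting.
#' @return an `iam_ols` fit of `logbb ~ delta` with the exclusions recorded.
#' @export
fit_logbb_simple <- function(table, deltas, phase = c("MG", "DD2"),
                             subset_threshold = NULL, exclude = character()) {
  stopifnot(inherits(table, "compound_table"))
  phase <- match.arg(toupper(phase), c("MG", "DD2"))
  if (!is.null(subset_threshold)) {
    table <- filter_subset(table, subset_threshold, exclude)
  } else if (length(exclude) > 0L) {
    table <- filter_subset(table, Inf, exclude)
  }
  table <- table[!is.na(table$logbb), , drop = FALSE]
  idx <- match(table$name, deltas$name)
  if (anyNA(idx))
    stop("deltas missing for compound(s): ",
         paste(table$name[is.na(idx)], collapse = ", "), call. = FALSE)
  if (nrow(table) < 4L)
    stop("subset too small to regress (n = ", nrow(table), " < 4)",
         call. = FALSE)
  d <- deltas$delta[idx]
  nm <- sprintf("delta_%s", tolower(phase))
  fit <- fit_ols(matrix(d, ncol = 1, dimnames = list(NULL, nm)),
                 table$logbb, excluded = exclude)
  fit$phase <- phase
  fit$compounds <- table$name
  fit
}
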