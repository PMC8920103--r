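# Automatic multiple-linear-regression model building: univariate pre-screen,
# VIF collinearity filter, exhaustive/greedy subset search with LOO
# validation and optional single-compound exclusion.

#' Construct a descriptor matrix
#'
#' A numeric matrix of per-compound descriptor values with unique compound
#' names on the rows and unique descriptor labels on the columns.
#'
#' @param values numeric matrix or data frame (compounds x descriptors).
#' @param compound_names,descriptor_names optional dimension names
#'   (default: taken from `values`).
#' @return numeric matrix of class `descriptor_matrix`.
#' @export
descriptor_matrix <- function(values, compound_names = NULL,
                              descriptor_names = NULL) {
  x <- as.matrix(values)
  storage.mode(x) <- "double"
  if (!is.null(compound_names)) rownames(x) <- compound_names
  if (!is.null(descriptor_names)) colnames(x) <- descriptor_names
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("descriptor matrix needs compound and descriptor names",
         call. = FALSE)
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("compound and descriptor names must be unique", call. = FALSE)
  class(x) <- c("descriptor_matrix", class(x))
  x
}

#' Read a descriptor matrix from CSV
#'
#' First column `name`, remaining columns one per descriptor, header row with
#' the exact descriptor labels.
#'
#' @param path CSV file.
#' @return a [descriptor_matrix].
#' @export
read_descriptor_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1L], "name"))
    stop("descriptor CSV must have 'name' as its first column",
         call. = FALSE)
  descriptor_matrix(df[, -1L, drop = FALSE], compound_names = df$name)
}

#' Univariate pre-screen of descriptors
#'
#' Regresses the response on each descriptor alone and keeps those with
#' simple-regression r-squared at or above `r2_min` (default 0.1, the
#' screening rule of the automated procedure). Constant columns are skipped
#' with a warning. The result is a ranked table of single-descriptor
#' statistics (r2, q2, SE, F, p, SSE-like PC), the analogue of a published
#' univariate comparison table.
#'
#' @param matrix a [descriptor_matrix] (or any named numeric matrix).
#' @param response numeric vector aligned with the matrix rows.
#' @param r2_min keep threshold on univariate r-squared.
#' @return data frame ranked by decreasing r2 with a logical `kept` column;
#'   the kept descriptor names are in the `"kept"` attribute.
#' @export
univariate_screen <- function(matrix, response, r2_min = 0.1) {
  x <- as.matrix(matrix)
  stopifnot(nrow(x) == length(response))
  res <- lapply(colnames(x), function(nm) {
    col <- x[, nm]
    if (stats::sd(col) == 0) {
      warning("constant descriptor column skipped: ", nm, call. = FALSE)
      return(NULL)
    }
    f <- fit_ols(x[, nm, drop = FALSE], response)
    data.frame(descriptor = nm, r2 = f$r2, q2 = f$q2_loo, se = f$se,
               f_stat = f$f_stat, p = f$p_value,
               pc_sse = f$pc_amemiya[["sse_like"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    stop("no usable descriptor columns", call. = FALSE)
  out <- out[order(-out$r2), , drop = FALSE]
  rownames(out) <- NULL
  out$kept <- out$r2 >= r2_min
  attr(out, "kept") <- out$descriptor[out$kept]
  attr(out, "r2_min") <- r2_min
  out
}

# VIF of every column of x against the others (Inf for exact collinearity)
.vif_values <- function(x) {
  vapply(seq_len(ncol(x)), function(j) {
    yj <- x[, j]
    xj <- x[, -j, drop = FALSE]
    qrx <- qr(cbind(1, xj))
    r <- yj - qr.fitted(qrx, yj)
    sst <- sum((yj - mean(yj))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(r^2) / sst
    if (r2 >= 1 - .Machine$double.eps^0.5) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Variance-inflation-factor collinearity filter
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the r-squared of descriptor `j`
#' regressed on all other candidates. Descriptors are removed iteratively,
#' worst first, until all remaining VIFs are below `threshold`; simultaneous
#' thresholding would be order-dependent and is deliberately avoided. Exact
#' duplicates (infinite VIF) tie-break by removing the later-listed column.
#'
#' @param matrix candidate descriptors (>= 2 columns).
#' @param threshold VIF cut (default 5).
#' @return list with `kept` (names), `vif` (named vector for the kept set)
#'   and `removed` (data frame logging name, VIF at removal, step).
#' @export
vif_filter <- function(matrix, threshold = 5) {
  x <- as.matrix(matrix)
  if (ncol(x) < 2L)
    stop("VIF filtering needs at least 2 candidate descriptors",
         call. = FALSE)
  removed <- list()
  step <- 0L
  repeat {
    v <- .vif_values(x)
    names(v) <- colnames(x)
    if (all(v < threshold) || ncol(x) == 1L) break
    # worst first; on exact ties (duplicated columns) drop the later-listed
    worst <- max(v)
    j <- max(which(v == worst))
    step <- step + 1L
    removed[[step]] <- data.frame(descriptor = colnames(x)[j], vif = worst,
                                  step = step, stringsAsFactors = FALSE)
    x <- x[, -j, drop = FALSE]
  }
  list(kept = colnames(x), vif = v,
       removed = if (step > 0L) do.call(rbind, removed) else
         data.frame(descriptor = character(), vif = numeric(),
                    step = integer()))
}

#' Search multi-descriptor OLS models
#'
#' Enumerates descriptor subsets of size 1 to `max_vars` (exhaustively when
#' the candidate count is at most `enumerate_limit`, otherwise by greedy
#' forward selection), fits each with [fit_ols()], validates by leave-one-out
#' q-squared, and ranks by the objective (default q2; ties broken by lower SE
#' then fewer variables). With `exclusion_search = TRUE` each of the
#' `n_exclusion` top models is additionally refitted n times leaving out one
#' compound, and the single exclusion that most improves the objective is
#' reported alongside the full-sample fit.
#'
#' Candidates are expected to have passed [univariate_screen()] and
#' [vif_filter()] already.
#'
#' @param matrix candidate [descriptor_matrix].
#' @param response numeric vector aligned with the matrix rows.
#' @param max_vars largest subset size (1 to 5).
#' @param objective `"q2"` or `"r2"`.
#' @param exclusion_search try leaving out each single compound from the top
#'   models.
#' @param enumerate_limit largest candidate count for exhaustive enumeration.
#' @param n_exclusion how many top models get the exclusion scan.
#' @return object of class `stepwise_search`: a ranked list of models, each
#'   with `selected`, `summary` (`iam_ols`), `vif`, and (when searched)
#'   `excluded_compound` plus the corresponding `summary_excluded`.
#' @export
search_models <- function(matrix, response, max_vars = 5,
                          objective = c("q2", "r2"),
                          exclusion_search = FALSE, enumerate_limit = 20L,
                          n_exclusion = 10L) {
  objective <- match.arg(objective)
  x <- as.matrix(matrix)
  stopifnot(nrow(x) == length(response))
  if (ncol(x) == 0L) stop("empty candidate set", call. = FALSE)
  max_vars <- min(max_vars, ncol(x), 5L)
  obj_of <- function(f) if (objective == "q2") f$q2_loo else f$r2
  fit_subset <- function(sel, y = response, rows = seq_len(nrow(x))) {
    fit_ols(x[rows, sel, drop = FALSE], y[rows])
  }
  subsets <- list()
  if (ncol(x) <= enumerate_limit) {
    for (sz in seq_len(max_vars))
      subsets <- c(subsets, utils::combn(colnames(x), sz, simplify = FALSE))
  } else {
    # greedy forward: grow the best subset one descriptor at a time,
    # keeping every intermediate model in the ranking
    current <- character()
    for (sz in seq_len(max_vars)) {
      cands <- setdiff(colnames(x), current)
      scores <- vapply(cands, function(nm)
        obj_of(fit_subset(c(current, nm))), numeric(1))
      current <- c(current, cands[which.max(scores)])
      subsets[[sz]] <- current
    }
  }
  models <- lapply(subsets, function(sel) {
    f <- fit_subset(sel)
    vif <- if (length(sel) >= 2L)
      stats::setNames(.vif_values(x[, sel, drop = FALSE]), sel)
    else stats::setNames(1, sel)
    list(selected = sel, summary = f, vif = vif, excluded_compound = NULL)
  })
  ord <- order(-vapply(models, function(m) obj_of(m$summary), numeric(1)),
               vapply(models, function(m) m$summary$se, numeric(1)),
               vapply(models, function(m) length(m$selected), numeric(1)))
  models <- models[ord]
  if (exclusion_search) {
    n <- nrow(x)
    top <- seq_len(min(n_exclusion, length(models)))
    for (i in top) {
      sel <- models[[i]]$selected
      base <- obj_of(models[[i]]$summary)
      best <- list(gain = 0, name = NULL, fit = NULL)
      for (j in seq_len(n)) {
        fj <- tryCatch(fit_subset(sel, rows = setdiff(seq_len(n), j)),
                       error = function(e) NULL)
        if (is.null(fj)) next
        gain <- obj_of(fj) - base
        if (gain > best$gain)
          best <- list(gain = gain, name = rownames(x)[j], fit = fj)
      }
      if (!is.null(best$name)) {
        best$fit$excluded <- best$name
        models[[i]]$excluded_compound <- best$name
        models[[i]]$summary_excluded <- best$fit
      }
    }
    # re-rank the scanned models on their post-exclusion objective
    obj_final <- vapply(models, function(m)
      obj_of(if (!is.null(m$excluded_compound)) m$summary_excluded
             else m$summary), numeric(1))
    se_final <- vapply(models, function(m)
      (if (!is.null(m$excluded_compound)) m$summary_excluded
       else m$summary)$se, numeric(1))
    models <- models[order(-obj_final, se_final,
                           vapply(models, function(m) length(m$selected),
                                  numeric(1)))]
  }
  structure(list(models = models, objective = objective,
                 max_vars = max_vars,
                 exclusion_search = exclusion_search),
            class = "stepwise_search")
}

#' @export
print.stepwise_search <- function(x, n = 5L, ...) {
  cat(sprintf("Stepwise model search: %d model(s), objective = %s%s\n",
              length(x$models), x$objective,
              if (x$exclusion_search) ", with single-compound exclusion"
              else ""))
  for (i in seq_len(min(n, length(x$models)))) {
    m <- x$models[[i]]
    s <- if (!is.null(m$excluded_compound)) m$summary_excluded else m$summary
    cat(sprintf("%2d. [%s] r2 = %.3f, q2 = %.3f, SE = %.3f%s\n", i,
                paste(m$selected, collapse = " + "), s$r2, s$q2_loo, s$se,
                if (!is.null(m$excluded_compound))
                  paste0("  (Exc: ", m$excluded_compound, ")") else ""))
  }
  invisible(x)
}

#' Screen, filter and search in one call
#'
#' The full automated procedure: univariate pre-screen (drop descriptors
#' with r2 below `r2_min`), iterative VIF filter at `vif_threshold`, then
#' [search_models()] over the surviving candidates.
#'
#' @inheritParams search_models
#' @param r2_min univariate screening threshold (default 0.1).
#' @param vif_threshold collinearity cut (default 5).
#' @return a `stepwise_search` whose `"screen"` and `"vif"` attributes hold
#'   the intermediate screening table and VIF log.
#' @export
stepwise_qspr <- function(matrix, response, r2_min = 0.1, vif_threshold = 5,
                          max_vars = 5, objective = "q2",
                          exclusion_search = FALSE, ...) {
  screen <- univariate_screen(matrix, response, r2_min = r2_min)
  kept <- attr(screen, "kept")
  if (length(kept) == 0L)
    stop("no descriptor passed the univariate screen", call. = FALSE)
  vif <- NULL
  if (length(kept) >= 2L) {
    vif <- vif_filter(as.matrix(matrix)[, kept, drop = FALSE],
                      threshold = vif_threshold)
    kept <- vif$kept
  }
  out <- search_models(as.matrix(matrix)[, kept, drop = FALSE], response,
                       max_vars = max_vars, objective = objective,
                       exclusion_search = exclusion_search, ...)
  attr(out, "screen") <- screen
  attr(out, "vif") <- vif
  out
}
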