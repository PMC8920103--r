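#' @keywords internal
"_PACKAGE"

# Canonical column order of a compound table on disk. `delta_mg`, `delta_dd2`
# are optional extras carried by the packaged reference table.
.compound_cols <- c("name", "ionization_class", "clogkw_mg", "clogkw_dd2",
                    "explogp", "clogp_alogps", "clogp_marvin", "clogd74",
                    "logbb")
.numeric_cols <- setdiff(.compound_cols, c("name", "ionization_class"))
.extra_cols   <- c("delta_mg", "delta_dd2")

#' Construct and validate a compound table
#'
#' A `compound_table` is a data frame with one row per compound and the fixed
#' property schema used throughout the package: identity (`name`), ionization
#' class (`A` acid, `B` monobasic, `BB` bibasic, `N` neutral), calculated
#' phospholipophilicity on the two IAM phases (`clogkw_mg`, `clogkw_dd2`),
#' experimental and calculated octanol-water lipophilicity (`explogp`,
#' `clogp_alogps`, `clogp_marvin`), the calculated pH 7.4 distribution
#' coefficient for acids (`clogd74`), and the experimental brain/blood
#' partition `logbb`. Missing values are `NA`, never zero.
#'
#' @param df data frame holding at least the schema columns.
#' @param provenance free-text source tag kept as an attribute.
#' @return the validated table, classed `compound_table`.
#' @export
compound_table <- function(df, provenance = "user") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.compound_cols, names(df))
  if (length(missing_cols) > 0L)
    stop("compound table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- intersect(c(.compound_cols, .extra_cols), names(df))
  df <- df[, keep, drop = FALSE]
  df$name <- as.character(df$name)
  df$ionization_class <- as.character(df$ionization_class)
  for (col in intersect(c(.numeric_cols, .extra_cols), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  validate_compound_table(df)
  structure(df, provenance = provenance,
            class = c("compound_table", "data.frame"))
}

#' Validate compound-table invariants
#'
#' Checks (and errors on violation): non-empty unique names; ionization class
#' in `A`/`B`/`BB`/`N`; every class-A record carries `clogd74`; every non-acid
#' carries at least one of `explogp`, `clogp_marvin`.
#'
#' @param df data frame in the compound schema.
#' @return `df`, invisibly.
#' @export
validate_compound_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$name) | !nzchar(df$name)))
    stop("compound names must be non-empty", call. = FALSE)
  dup <- unique(df$name[duplicated(df$name)])
  if (length(dup) > 0L)
    stop("duplicate compound name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad_class <- !df$ionization_class %in% c("A", "B", "BB", "N")
  if (any(bad_class))
    stop("invalid ionization class for: ",
         paste(df$name[bad_class], collapse = ", "),
         " (must be one of A, B, BB, N)", call. = FALSE)
  acid_no_d <- df$ionization_class == "A" & is.na(df$clogd74)
  if (any(acid_no_d))
    stop("class-A (acid) record(s) without clogd74: ",
         paste(df$name[acid_no_d], collapse = ", "), call. = FALSE)
  no_lip <- df$ionization_class != "A" &
    is.na(df$explogp) & is.na(df$clogp_marvin)
  if (any(no_lip))
    stop("record(s) with neither explogp nor clogp_marvin: ",
         paste(df$name[no_lip], collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read a compound table from delimited text
#'
#' Expects a header row with the documented column names; unknown columns are
#' dropped (the reference table's printed `delta_mg`/`delta_dd2` columns are
#' retained). Empty cells become `NA`.
#'
#' @param path file to read.
#' @param sep field delimiter (default comma).
#' @param provenance source tag; defaults to the path.
#' @return a [compound_table].
#' @export
read_compound_table <- function(path, sep = ",", provenance = path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "", colClasses = NA)
  compound_table(df, provenance = provenance)
}

#' Write a compound table to delimited text
#'
#' Inverse of [read_compound_table()]: one header row, `NA` serialized as the
#' empty cell, fields quoted only when needed, full numeric precision (the
#' read/write round trip is the identity on every field).
#'
#' @param table a [compound_table].
#' @param path destination file.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "compound_table"))
  ok <- tryCatch({
    utils::write.table(as.data.frame(table), path, sep = sep, na = "",
                       row.names = FALSE, qmethod = "double")
    TRUE
  }, error = function(e) {
    stop("cannot write compound table to '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' The packaged 56-compound reference dataset
#'
#' Loads the merged compound/descriptor table shipped with the package:
#' 56 small molecules with in-silico IAM phospholipophilicity on the MG and
#' DD2 phases, experimental and calculated lipophilicity, pH 7.4 log D for the
#' acids, published excess descriptors (`delta_mg`, `delta_dd2`) and
#' experimental log BB, all at the published precision.
#'
#' One published cell is internally inconsistent: the isoflurane row has an
#' empty experimental log P, yet its published delta values on both phases
#' back-solve to a lipophilicity of 2.06 — the PubChem experimental log P for
#' isoflurane. A packaged errata file records that value; it is applied by
#' default so that the dataset is self-consistent. Set `apply_errata = FALSE`
#' for the table exactly as published.
#'
#' @param apply_errata apply the packaged errata (default `TRUE`).
#' @return a [compound_table] with 56 records.
#' @export
iam_dataset <- function(apply_errata = TRUE) {
  path <- system.file("extdata", "table1_table2_merged.csv",
                      package = "iamdelta", mustWork = TRUE)
  tab <- read_compound_table(path, provenance = "packaged reference table")
  if (apply_errata) {
    epath <- system.file("extdata", "table1_errata.csv",
                         package = "iamdelta", mustWork = TRUE)
    err <- utils::read.csv(epath, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(err))) {
      j <- match(err$name[i], tab$name)
      if (!is.na(j)) tab[[err$field[i]]][j] <- as.numeric(err$value[i])
    }
    attr(tab, "errata") <- err
    attr(tab, "provenance") <-
      "packaged reference table (errata applied)"
  }
  tab
}

#' Subset a compound table by log BB
#'
#' Keeps records whose `logbb` is strictly below `logbb_max` (records without
#' a `logbb` are never selected), then removes `exclude_names`. Order is
#' preserved. An exclusion name absent from the table raises a warning, not an
#' error.
#'
#' @param table a [compound_table].
#' @param logbb_max finite threshold; strict `<` comparison.
#' @param exclude_names character vector of compound names to drop.
#' @return the filtered [compound_table]; the applied exclusions are recorded
#'   in the `"excluded"` attribute.
#' @export
filter_subset <- function(table, logbb_max, exclude_names = character()) {
  stopifnot(inherits(table, "compound_table"), is.numeric(logbb_max),
            length(logbb_max) == 1L, !is.na(logbb_max))
  unknown <- setdiff(exclude_names, table$name)
  if (length(unknown) > 0L)
    warning("exclusion name(s) not in table: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  keep <- !is.na(table$logbb) & table$logbb < logbb_max &
    !(table$name %in% exclude_names)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(table, "provenance"),
            excluded = intersect(exclude_names, table$name),
            class = c("compound_table", "data.frame"))
}

#' @export
as.data.frame.compound_table <- function(x, ...) {
  attr(x, "provenance") <- NULL
  attr(x, "errata") <- NULL
  attr(x, "excluded") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("Compound table: %d record(s) [%s]\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  cls <- table(factor(x$ionization_class, levels = c("A", "B", "BB", "N")))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "),
      "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more row(s)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
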