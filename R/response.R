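#' Construct a drug response table
#'
#' @param records Data frame with columns `cell_id`, `drug_id`, `ln_ic50`
#'   (natural log of IC50 in micromolar) and optionally `source`
#'   (GDSC1/GDSC2/CHEMBL/SYNTHETIC).
#' @param dedup_stats Optional list of deduplication statistics.
#' @return A `response_table`.
#' @export
response_table <- function(records, dedup_stats = NULL) {
  stopifnot(all(c("cell_id", "drug_id", "ln_ic50") %in% names(records)))
  if (is.null(records$source)) records$source <- "SYNTHETIC"
  if (!all(is.finite(records$ln_ic50))) stop("ln_ic50 values must be finite")
  records <- records[, c("cell_id", "drug_id", "ln_ic50", "source")]
  rownames(records) <- NULL
  structure(list(records = records, dedup_stats = dedup_stats),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  r <- x$records
  cat("response_table:", nrow(r), "records,", length(unique(r$cell_id)),
      "cells,", length(unique(r$drug_id)), "drugs\n")
  if (!is.null(x$dedup_stats))
    cat("  duplicates seen:", x$dedup_stats$n_duplicates,
        "| groups averaged:", x$dedup_stats$n_groups_averaged,
        "| RMSD:", round(x$dedup_stats$rmsd, 4),
        "| PCC:", round(x$dedup_stats$pcc, 4), "\n")
  invisible(x)
}

#' Average duplicate (cell, drug) response measurements
#'
#' Collapses repeated measurements of the same cell/drug combination to their
#' arithmetic mean and records duplicate statistics: the number of records
#' involved in duplication, the number of groups averaged, the root mean
#' square deviation between duplicated values and their group means, and the
#' Pearson correlation between duplicated values and their (repeated) group
#' means.
#'
#' @param records Data frame or `response_table` with `cell_id`, `drug_id`,
#'   `ln_ic50` (and optional `source`).
#' @return A deduplicated `response_table` with `dedup_stats` populated.
#' @export
average_duplicates <- function(records) {
  if (inherits(records, "response_table")) records <- records$records
  if (is.null(records$source)) records$source <- "SYNTHETIC"
  key <- paste(records$cell_id, records$drug_id, sep = "\r")
  grp <- match(key, unique(key))
  n_per <- tabulate(grp)
  means <- as.vector(tapply(records$ln_ic50, grp, mean))
  dup_rows <- n_per[grp] > 1
  n_dup <- sum(dup_rows)
  if (n_dup > 0) {
    dev <- records$ln_ic50[dup_rows] - means[grp][dup_rows]
    rmsd <- sqrt(mean(dev^2))
    pcc <- if (stats::sd(records$ln_ic50[dup_rows]) == 0 ||
               stats::sd(means[grp][dup_rows]) == 0) 1
           else stats::cor(records$ln_ic50[dup_rows], means[grp][dup_rows])
  } else {
    rmsd <- 0; pcc <- 1
  }
  first <- !duplicated(grp)
  out <- data.frame(cell_id = records$cell_id[first],
                    drug_id = records$drug_id[first],
                    ln_ic50 = means,
                    source = records$source[first],
                    stringsAsFactors = FALSE)
  response_table(out, dedup_stats = list(
    n_duplicates = n_dup,
    n_groups_averaged = sum(n_per > 1),
    rmsd = rmsd, pcc = pcc))
}

#' Merge two GDSC response tables with GDSC2 priority
#'
#' Takes the union of (cell, drug) pairs; when a pair is present in both
#' releases the GDSC2 value wins (GDSC2's wider screening concentration
#' range yields more precise IC50 estimates).
#'
#' @param g1,g2 Deduplicated `response_table`s (GDSC1 and GDSC2).
#' @return A merged `response_table`; `source` records provenance.
#' @export
merge_gdsc <- function(g1, g2) {
  r1 <- g1$records; r2 <- g2$records
  k1 <- paste(r1$cell_id, r1$drug_id, sep = "\r")
  k2 <- paste(r2$cell_id, r2$drug_id, sep = "\r")
  if (anyDuplicated(k1) || anyDuplicated(k2))
    stop("merge_gdsc expects deduplicated tables; run average_duplicates() first")
  r1$source <- "GDSC1"; r2$source <- "GDSC2"
  keep1 <- !(k1 %in% k2)
  out <- rbind(r2, r1[keep1, ])
  response_table(out, dedup_stats = list(
    n_conflicts = sum(!keep1), n_from_gdsc1 = sum(keep1),
    n_from_gdsc2 = nrow(r2)))
}

#' Convert an external IC50 measurement to ln(IC50 uM)
#'
#' @param value Positive IC50 value(s).
#' @param unit Unit of `value`: `"nM"`, `"uM"` or `"M"`.
#' @return Natural log of the IC50 expressed in micromolar.
#' @export
convert_external_ic50 <- function(value, unit = c("uM", "nM", "M")) {
  unit <- match.arg(unit)
  if (any(value <= 0)) stop("IC50 values must be positive")
  um <- switch(unit, nM = value / 1e3, uM = value, M = value * 1e6)
  log(um)
}

#' Remove responses capped at the assay concentration limit
#'
#' Screens report an IC50 equal to the maximum tested concentration when the
#' true value lies beyond it; such right-censored records (raw IC50 exactly
#' equal to the cap) are removed before factor analyses.
#'
#' @param records `response_table` or data frame with `ln_ic50`.
#' @param cap_value Cap concentration in micromolar (e.g. 8).
#' @return Filtered `response_table`; the number removed is stored in
#'   `dedup_stats$n_capped_removed`.
#' @export
filter_capped <- function(records, cap_value) {
  if (inherits(records, "response_table")) records <- records$records
  stopifnot(cap_value > 0)
  capped <- abs(records$ln_ic50 - log(cap_value)) < 1e-12
  out <- records[!capped, , drop = FALSE]
  if (nrow(out) == 0L)
    out <- data.frame(cell_id = character(0), drug_id = character(0),
                      ln_ic50 = numeric(0), source = character(0))
  response_table(out, dedup_stats = list(n_capped_removed = sum(capped)))
}

#' Read a GDSC-dialect response CSV
#'
#' Expects columns for the cell identifier (`SANGER_MODEL_ID` or
#' `COSMIC_ID`), `DRUG_ID` and `LN_IC50`.
#'
#' @param path CSV file.
#' @param source `"GDSC1"` or `"GDSC2"`.
#' @return A raw (possibly duplicated) `response_table`.
#' @export
read_gdsc_csv <- function(path, source = c("GDSC2", "GDSC1")) {
  source <- match.arg(source)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cell_col <- intersect(c("SANGER_MODEL_ID", "COSMIC_ID"), names(df))[1]
  if (is.na(cell_col)) stop("no SANGER_MODEL_ID/COSMIC_ID column in ", path)
  stopifnot(all(c("DRUG_ID", "LN_IC50") %in% names(df)))
  response_table(data.frame(cell_id = as.character(df[[cell_col]]),
                            drug_id = as.character(df$DRUG_ID),
                            ln_ic50 = as.numeric(df$LN_IC50),
                            source = source, stringsAsFactors = FALSE))
}

#' Read a ChEMBL-dialect activity CSV
#'
#' Expects a pre-exported activity table with columns `molecule_id`,
#' `cell_id`, `standard_value`, `standard_units` and `standard_type`; rows
#' are filtered to `standard_type == "IC50"`, converted to ln(IC50 uM) and
#' non-positive values rejected.
#'
#' @param path CSV file.
#' @return List with `table` (a `response_table`) and `rejected` (data frame
#'   of rejected rows with a `reason` column).
#' @export
read_chembl_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("molecule_id", "cell_id", "standard_value",
                  "standard_units", "standard_type") %in% names(df)))
  df <- df[df$standard_type == "IC50", , drop = FALSE]
  unit_map <- c(nM = "nM", uM = "uM", "uM " = "uM", M = "M")
  bad_unit <- !(df$standard_units %in% names(unit_map))
  nonpos <- !is.na(df$standard_value) & df$standard_value <= 0
  reject <- bad_unit | nonpos | is.na(df$standard_value)
  rejected <- df[reject, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- ifelse(bad_unit[reject], "unknown unit",
                              "non-positive or missing value")
  df <- df[!reject, , drop = FALSE]
  ln <- mapply(function(v, u) convert_external_ic50(v, unit_map[[u]]),
               df$standard_value, df$standard_units)
  list(table = response_table(data.frame(
         cell_id = as.character(df$cell_id),
         drug_id = as.character(df$molecule_id),
         ln_ic50 = as.numeric(ln), source = "CHEMBL",
         stringsAsFactors = FALSE)),
       rejected = rejected)
}

#' Write a response table to the canonical internal TSV
#'
#' @param table A `response_table`.
#' @param path Output path.
#' @export
write_response_tsv <- function(table, path) {
  utils::write.table(table$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read the canonical internal response TSV
#'
#' @param path TSV with columns `cell_id`, `drug_id`, `ln_ic50`, `source`.
#' @return A `response_table`.
#' @export
read_response_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(cell_id = "character",
                                         drug_id = "character"))
  response_table(df)
}
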