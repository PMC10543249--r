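#' Read GWAS summary statistics
#'
#' Parses a delimited summary-statistics file (tab- or whitespace-separated,
#' with a header) into a data.frame of variant records, using a column-role
#' mapping so files with arbitrary column names and orders are supported.
#' Rows whose numeric fields (position, odds ratio, standard error, INFO)
#' do not parse are rejected and reported with their row numbers.
#'
#' @param path path to the summary-statistics file.
#' @param column_map named character vector mapping roles to column names in
#'   the file. Required roles: `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `odds_ratio`, `se`. Optional: `info`.
#' @return data.frame with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `odds_ratio`, `se`, `info` (NA when absent). Rejected
#'   rows are attached as `attr(x, "rejected")`, a data.frame with `row`
#'   (1-based data-row number) and `reason`.
#' @export
readSumstats <- function(path, column_map) {
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "odds_ratio", "se")
  missing_roles <- setdiff(required, names(column_map))
  if (length(missing_roles)) {
    stop("column_map is missing roles: ", paste(missing_roles, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("summary-statistics file has no data rows: ", path)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    stop("mapped columns absent from file: ", paste(missing_cols, collapse = ", "))
  }

  get_col <- function(role) raw[[column_map[[role]]]]
  n <- nrow(raw)
  rec <- data.frame(
    rsid = get_col("rsid"),
    chrom = normalizeChrom(get_col("chrom")),
    pos = suppressWarnings(as.numeric(get_col("pos"))),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    odds_ratio = suppressWarnings(as.numeric(get_col("odds_ratio"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    info = if ("info" %in% names(column_map)) {
      suppressWarnings(as.numeric(get_col("info")))
    } else NA_real_,
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, n)
  bad_num <- is.na(rec$pos) | is.na(rec$odds_ratio) | is.na(rec$se)
  reason[bad_num] <- "unparseable numeric field"
  has_info_col <- "info" %in% names(column_map)
  if (has_info_col) {
    # blank/NA INFO is allowed (kept as missing); only non-numeric text rejects
    info_txt <- trimws(get_col("info"))
    bad_info <- is.na(rec$info) & !(info_txt %in% c("", "NA", "na", ".", "NaN"))
    reason[bad_info & is.na(reason)] <- "unparseable INFO"
  }
  bad_pos <- !is.na(rec$pos) & rec$pos < 1
  reason[bad_pos & is.na(reason)] <- "position < 1"
  bad_or <- !is.na(rec$odds_ratio) & rec$odds_ratio <= 0
  reason[bad_or & is.na(reason)] <- "non-positive odds ratio"
  bad_se <- !is.na(rec$se) & rec$se <= 0
  reason[bad_se & is.na(reason)] <- "non-positive standard error"
  bad_alleles <- rec$effect_allele == rec$other_allele
  reason[bad_alleles & is.na(reason)] <- "identical alleles"

  keep <- is.na(reason)
  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Normalize chromosome labels
#'
#' Strips any "chr" prefix and upper-cases so "chr1"/"1" and "chrx"/"X"
#' unify; "M" is mapped to "MT".
#' @param chrom character vector of chromosome labels.
#' @return normalized character vector.
#' @export
normalizeChrom <- function(chrom) {
  out <- toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
  out[out == "M"] <- "MT"
  out
}

#' Quality-control filter for summary statistics
#'
#' Applies the standard pre-test filters in a fixed order so that the
#' per-rule removal counts are reproducible: (1) keep autosomes only,
#' (2) INFO imputation-quality filter, (3) remove strand-ambiguous alleles
#' (A/T or C/G pairs), (4) remove non-biallelic positions (several records
#' at one position with inconsistent allele pairs), (5) remove every record
#' carrying a duplicated rsID.
#'
#' @param records data.frame from [readSumstats()].
#' @param info_min INFO threshold (default 0.9).
#' @param info_mode `"keep_at_least"` (default) retains records with
#'   INFO >= `info_min` (records with missing INFO are retained);
#'   `"drop_above_literal"` removes records with INFO > `info_min`.
#' @param drop_ambiguous drop strand-ambiguous SNPs (default TRUE).
#' @param autosomes_only keep chromosomes 1-22 only (default TRUE).
#' @return list with `records` (filtered data.frame) and `report`, a
#'   data.frame of removal counts per rule in application order plus
#'   `n_input`/`n_output` attributes.
#' @export
qcFilter <- function(records, info_min = 0.9,
                     info_mode = c("keep_at_least", "drop_above_literal"),
                     drop_ambiguous = TRUE, autosomes_only = TRUE) {
  info_mode <- match.arg(info_mode)
  n_input <- nrow(records)
  counts <- c(non_autosomal = 0L, info = 0L, ambiguous = 0L,
              non_biallelic = 0L, duplicate_rsid = 0L)

  if (autosomes_only) {
    keep <- records$chrom %in% as.character(1:22)
    counts["non_autosomal"] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  if (nrow(records)) {
    if (info_mode == "keep_at_least") {
      drop <- !is.na(records$info) & records$info < info_min
    } else {
      drop <- !is.na(records$info) & records$info > info_min
    }
    counts["info"] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  if (drop_ambiguous && nrow(records)) {
    pair <- paste(pmin(records$effect_allele, records$other_allele),
                  pmax(records$effect_allele, records$other_allele))
    drop <- pair %in% c("A T", "C G")
    counts["ambiguous"] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  if (nrow(records)) {
    # non-biallelic at the summary level: >1 distinct allele pair at a position
    loc <- paste(records$chrom, records$pos)
    pair <- paste(pmin(records$effect_allele, records$other_allele),
                  pmax(records$effect_allele, records$other_allele))
    n_pairs <- tapply(pair, loc, function(x) length(unique(x)))
    bad_loc <- names(n_pairs)[n_pairs > 1L]
    drop <- loc %in% bad_loc
    counts["non_biallelic"] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  if (nrow(records)) {
    dup <- records$rsid %in% records$rsid[duplicated(records$rsid)]
    counts["duplicate_rsid"] <- sum(dup)
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  report <- data.frame(rule = names(counts), removed = as.integer(counts),
                       stringsAsFactors = FALSE)
  attr(report, "n_input") <- n_input
  attr(report, "n_output") <- nrow(records)
  stopifnot(sum(report$removed) == n_input - nrow(records))
  list(records = records, report = report)
}

#' Compute per-variant Z-scores
#'
#' The signed standardized effect z = ln(OR) / SE, oriented to the effect
#' allele. Stored in a `z` column on the records.
#'
#' @param records data.frame with `odds_ratio` and `se` columns.
#' @return the records with a `z` column added.
#' @export
computeZ <- function(records) {
  if (any(records$odds_ratio <= 0)) stop("odds ratios must be positive")
  if (any(records$se <= 0)) stop("standard errors must be positive")
  records$z <- log(records$odds_ratio) / records$se
  records
}
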