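#' Load a reference genotype panel from VCF
#'
#' Reads biallelic SNVs from a VCF into a dosage matrix (count of ALT
#' alleles, 0/1/2, NA for missing genotypes). Multi-allelic sites and
#' indels are skipped and counted. Works on plain-text or bgzipped VCFs.
#'
#' @param vcf_path path to the VCF.
#' @param region optional list(chrom =, start =, end =) restricting to a
#'   1-based inclusive interval.
#' @param sample_subset optional character vector of sample IDs, or path to
#'   a file with one sample ID per line.
#' @return list with `variants` (data.frame: chrom, pos, rsid, ref, alt),
#'   `dosage` (variants x samples integer matrix) and `skipped` (count of
#'   non-biallelic-SNV records).
#' @export
loadPanel <- function(vcf_path, region = NULL, sample_subset = NULL) {
  if (!file.exists(vcf_path)) stop("panel VCF not found: ", vcf_path)
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) stop("unreadable VCF: ", conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(list(variants = data.frame(chrom = character(0), pos = numeric(0),
                                      rsid = character(0), ref = character(0),
                                      alt = character(0)),
                dosage = matrix(integer(0), 0, 0), skipped = 0L))
  }
  fix$POS <- as.numeric(fix$POS)
  fix$CHROM <- normalizeChrom(fix$CHROM)

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    keep <- fix$CHROM == normalizeChrom(region$chrom) &
      fix$POS >= region$start & fix$POS <= region$end
  }
  bases <- c("A", "C", "G", "T")
  snv <- fix$REF %in% bases & fix$ALT %in% bases
  skipped <- sum(keep & !snv)
  keep <- keep & snv

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  if (!is.null(sample_subset)) {
    if (length(sample_subset) == 1L && file.exists(sample_subset)) {
      sample_subset <- readLines(sample_subset)
      sample_subset <- sample_subset[nzchar(sample_subset)]
    }
    missing_s <- setdiff(sample_subset, colnames(gt))
    if (length(missing_s)) {
      stop("samples absent from panel: ", paste(missing_s, collapse = ", "))
    }
    gt <- gt[, sample_subset, drop = FALSE]
  }

  dosage <- gtToDosage(gt)
  variants <- data.frame(chrom = fix$CHROM, pos = fix$POS, rsid = fix$ID,
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  rownames(dosage) <- variants$rsid
  list(variants = variants, dosage = dosage, skipped = skipped)
}

# "0/1", "1|0", "./." etc. -> ALT-allele count
gtToDosage <- function(gt) {
  clean <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0" = 0L, "1" = 1L)
  d <- map[clean]
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

#' Harmonize GWAS records for one gene against the panel
#'
#' Matches records to panel variants by (chromosome, position, allele pair).
#' If the GWAS effect allele equals the panel ALT (counted) allele the
#' Z-score is kept; if it equals the panel REF allele the sign is flipped;
#' incompatible allele pairs are dropped and counted. Position order is
#' preserved. Strand-complement rescue is deliberately not attempted:
#' ambiguous SNPs are removed upstream by [qcFilter()].
#'
#' @param assignment per-gene data.frame of records from [assignSnps()].
#' @param panel panel list from [loadPanel()].
#' @return list with `snps` (rsid, pos, effect_allele = panel ALT,
#'   other_allele = panel REF), `z` (oriented Z-scores), `panel_idx`
#'   (rows of `panel$variants`), and `counts` (matched, flipped, dropped).
#' @export
harmonizeGene <- function(assignment, panel) {
  chrom <- attr(assignment, "chrom")
  pv <- panel$variants
  on_chrom <- which(pv$chrom == chrom)
  key <- paste(pv$pos[on_chrom], pmin(pv$ref, pv$alt)[on_chrom],
               pmax(pv$ref, pv$alt)[on_chrom])
  gkey <- paste(assignment$pos,
                pmin(assignment$effect_allele, assignment$other_allele),
                pmax(assignment$effect_allele, assignment$other_allele))
  hit <- match(gkey, key)

  matched <- flipped <- 0L
  keep <- integer(0); zout <- numeric(0); pidx <- integer(0)
  for (i in seq_len(nrow(assignment))) {
    j <- hit[i]
    if (is.na(j)) next
    j <- on_chrom[j]
    zi <- assignment$z[i]
    if (assignment$effect_allele[i] == pv$alt[j]) {
      matched <- matched + 1L
    } else {
      zi <- -zi
      flipped <- flipped + 1L
    }
    keep <- c(keep, i); zout <- c(zout, zi); pidx <- c(pidx, j)
  }
  dropped <- nrow(assignment) - length(keep)
  snps <- data.frame(rsid = assignment$rsid[keep],
                     pos = assignment$pos[keep],
                     effect_allele = pv$alt[pidx],
                     other_allele = pv$ref[pidx],
                     stringsAsFactors = FALSE)
  list(snps = snps, z = zout, panel_idx = pidx,
       counts = list(matched = matched, flipped = flipped, dropped = dropped))
}

#' Pearson LD matrix from panel dosages
#'
#' Pairwise Pearson correlation of dosage vectors over non-missing samples
#' (pairwise-complete). Monomorphic variants (zero dosage variance) are
#' dropped and reported. The diagonal is set to exactly 1.
#'
#' @param dosage variants x samples dosage matrix (rows named by rsid).
#' @return list with `snp_ids`, `r` (correlation matrix) and
#'   `monomorphic` (ids of dropped zero-variance variants). When fewer than
#'   one polymorphic variant remains, `r` is a 0 x 0 matrix.
#' @export
computeLD <- function(dosage) {
  v <- apply(dosage, 1L, stats::var, na.rm = TRUE)
  poly <- which(!is.na(v) & v > 0)
  mono <- setdiff(rownames(dosage), rownames(dosage)[poly])
  d <- dosage[poly, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(list(snp_ids = character(0),
                r = matrix(numeric(0), 0, 0), monomorphic = mono))
  }
  r <- stats::cor(t(d), use = "pairwise.complete.obs")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  list(snp_ids = rownames(d), r = r, monomorphic = mono)
}

#' Prune one of each pair of perfectly correlated SNPs
#'
#' Greedy scan in position order: a SNP is removed when its |r| with any
#' earlier-position retained SNP reaches `r_max`; the earlier SNP is kept
#' (deterministic tie-break). Z-scores and LD rows/columns are removed
#' consistently and the result is re-checked. Idempotent.
#'
#' @param gene_set a [GeneSnpSet-class].
#' @param r_max absolute-correlation threshold treated as "perfect"
#'   (default 0.9999).
#' @return the pruned `GeneSnpSet`, or `NULL` when fewer than 2 SNPs
#'   survive (the gene is dropped; the reason is attached as
#'   `attr(, "drop_reason")` on the `NULL` via a condition message).
#' @export
prunePerfect <- function(gene_set, r_max = 0.9999) {
  r <- ldMatrix(gene_set)
  m <- nrow(r)
  keep <- 1L
  for (j in seq_len(m)[-1]) {
    if (all(abs(r[j, keep]) < r_max)) keep <- c(keep, j)
  }
  if (length(keep) < 2L) return(NULL)
  r2 <- r[keep, keep, drop = FALSE]
  stopifnot(max(abs(r2[upper.tri(r2)])) < r_max || length(keep) == 1L)
  prov <- gene_set@provenance
  prov$pruned <- (prov$pruned %||% 0L) + (m - length(keep))
  GeneSnpSet(geneId(gene_set), gene_set@chrom,
             snpInfo(gene_set)[keep, , drop = FALSE],
             zScores(gene_set)[keep], r2, prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build harmonized, pruned GeneSnpSets for all assignments
#'
#' Convenience chain: harmonize each gene's records against the panel,
#' estimate the LD matrix from panel dosages, prune perfect-LD pairs, and
#' drop genes that fall below 2 SNPs at any stage (with reasons).
#'
#' @param assignments named list from [assignSnps()].
#' @param panel panel list from [loadPanel()].
#' @param r_max pruning threshold passed to [prunePerfect()].
#' @return list with `gene_sets` (named list of [GeneSnpSet-class]) and
#'   `dropped` (data.frame gene_id, reason).
#' @export
makeGeneSets <- function(assignments, panel, r_max = 0.9999) {
  gene_sets <- list()
  dropped <- data.frame(gene_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_gene <- function(gid, why) {
    rbind(dropped, data.frame(gene_id = gid, reason = why,
                              stringsAsFactors = FALSE))
  }
  for (gid in names(assignments)) {
    asn <- assignments[[gid]]
    h <- harmonizeGene(asn, panel)
    if (length(h$z) < 2L) {
      dropped <- drop_gene(gid, "fewer than 2 SNPs after harmonization"); next
    }
    d <- panel$dosage[h$panel_idx, , drop = FALSE]
    rownames(d) <- h$snps$rsid   # key by the GWAS rsid for alignment
    ld <- computeLD(d)
    ok <- sort(match(ld$snp_ids, h$snps$rsid))
    if (length(ok) < 2L) {
      dropped <- drop_gene(gid, "fewer than 2 polymorphic SNPs in panel"); next
    }
    sel <- match(h$snps$rsid[ok], ld$snp_ids)
    gs <- GeneSnpSet(gid, attr(asn, "chrom"),
                     h$snps[ok, , drop = FALSE], h$z[ok],
                     ld$r[sel, sel, drop = FALSE],
                     provenance = c(h$counts,
                                    list(monomorphic = length(ld$monomorphic))))
    gs <- prunePerfect(gs, r_max = r_max)
    if (is.null(gs)) {
      dropped <- drop_gene(gid, "fewer than 2 SNPs after LD pruning"); next
    }
    gene_sets[[gid]] <- gs
  }
  list(gene_sets = gene_sets, dropped = dropped)
}
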