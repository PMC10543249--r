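#' GeneSnpSet: harmonized per-gene Z-scores with their LD matrix
#'
#' The unit consumed by all SNP-set tests: for one gene, the vector of
#' GWAS Z-scores (oriented to the panel's counted allele) together with the
#' LD correlation matrix `R` estimated from a reference genotype panel,
#' index-aligned SNP metadata, and provenance counters from harmonization
#' and pruning.
#'
#' @slot gene_id single gene identifier.
#' @slot chrom chromosome label (normalized, no "chr" prefix).
#' @slot snps data.frame with one row per SNP: `rsid`, `pos`,
#'   `effect_allele` (panel ALT, the counted allele), `other_allele`
#'   (panel REF), ordered by position.
#' @slot z numeric vector of Z-scores, aligned with `snps`.
#' @slot ld symmetric correlation matrix over the same SNPs, unit diagonal.
#' @slot provenance list of counters (e.g. `matched`, `flipped`, `dropped`,
#'   `monomorphic`, `pruned`).
#'
#' @name GeneSnpSet-class
#' @aliases GeneSnpSet-class
#' @exportClass GeneSnpSet
setClass("GeneSnpSet",
  representation(
    gene_id = "character",
    chrom = "character",
    snps = "data.frame",
    z = "numeric",
    ld = "matrix",
    provenance = "list"
  )
)

setValidity("GeneSnpSet", function(object) {
  m <- length(object@z)
  msgs <- character(0)
  if (length(object@gene_id) != 1L) msgs <- c(msgs, "gene_id must be length 1")
  if (m < 2L) msgs <- c(msgs, "a GeneSnpSet needs at least 2 SNPs")
  if (nrow(object@snps) != m) msgs <- c(msgs, "snps and z are not aligned")
  if (!all(dim(object@ld) == c(m, m))) {
    msgs <- c(msgs, "ld must be m x m")
  } else {
    r <- object@ld
    if (max(abs(r - t(r))) > 1e-8) msgs <- c(msgs, "ld is not symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msgs <- c(msgs, "ld diagonal is not 1")
    if (max(abs(r)) > 1 + 1e-8) msgs <- c(msgs, "ld entries outside [-1, 1]")
    ev <- eigen((r + t(r)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) msgs <- c(msgs, "ld is not positive semi-definite")
  }
  if (anyNA(object@z) || any(!is.finite(object@z))) {
    msgs <- c(msgs, "z must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSnpSet
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome label.
#' @param snps data.frame of SNP metadata (`rsid`, `pos`, `effect_allele`,
#'   `other_allele`), one row per SNP in position order.
#' @param z numeric Z-score vector aligned with `snps`.
#' @param ld LD correlation matrix over the same SNPs.
#' @param provenance optional list of bookkeeping counters.
#' @return a validated [GeneSnpSet-class] object.
#' @export
GeneSnpSet <- function(gene_id, chrom, snps, z, ld, provenance = list()) {
  ld <- as.matrix(ld)
  ld <- (ld + t(ld)) / 2
  diag(ld) <- 1
  dimnames(ld) <- list(snps$rsid, snps$rsid)
  new("GeneSnpSet",
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    snps = as.data.frame(snps), z = as.numeric(z), ld = ld,
    provenance = provenance
  )
}

#' @describeIn GeneSnpSet-class gene identifier
#' @param object,x a `GeneSnpSet`
#' @export
geneId <- function(x) x@gene_id

#' @describeIn GeneSnpSet-class Z-score vector
#' @export
zScores <- function(x) x@z

#' @describeIn GeneSnpSet-class LD correlation matrix
#' @export
ldMatrix <- function(x) x@ld

#' @describeIn GeneSnpSet-class SNP metadata table
#' @export
snpInfo <- function(x) x@snps

#' @describeIn GeneSnpSet-class number of SNPs (after any pruning)
#' @export
nSnps <- function(x) length(x@z)

setMethod("show", "GeneSnpSet", function(object) {
  cat("GeneSnpSet:", object@gene_id,
      sprintf("(chr%s, %d SNPs)\n", object@chrom, length(object@z)))
  cat("  z range: [", sprintf("%.3f", min(object@z)), ", ",
      sprintf("%.3f", max(object@z)), "]\n", sep = "")
  off <- object@ld[upper.tri(object@ld)]
  if (length(off)) {
    cat("  |r| off-diagonal max:", sprintf("%.3f", max(abs(off))), "\n")
  }
  if (length(object@provenance)) {
    cat("  provenance:",
        paste(names(object@provenance), unlist(object@provenance),
              sep = "=", collapse = ", "), "\n")
  }
})
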