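#' Load gene regions from BED or GTF
#'
#' Reads gene intervals (e.g. TSS-TES bodies) into a GRanges. BED input is
#' 0-based half-open and is converted by the reader to the internal 1-based
#' inclusive convention; GTF is already 1-based inclusive (only `gene`
#' features are used, falling back to all features when a GTF carries no
#' `gene` rows). Chromosome labels are normalized ("chr1" and "1" unify).
#'
#' @param path path to a BED4+ or GTF file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return GRanges named by gene id, with a `gene_id` metadata column.
#' @export
loadGenes <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)(\\.gz)?$", path, ignore.case = TRUE)) {
      "gtf"
    } else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- gr$name
    if (is.null(ids) || anyNA(ids)) stop("BED input must carry gene names (column 4)")
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    if (!is.null(gr$type) && any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    ids <- gr$gene_id
    if (is.null(ids) || anyNA(ids)) stop("GTF input must carry gene_id attributes")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate gene ids in annotation: ", paste(dup, collapse = ", "))
  }
  if (any(GenomicRanges::start(gr) > GenomicRanges::end(gr))) {
    stop("malformed gene interval (start > end) in ", path)
  }
  GenomeInfoDb::seqlevels(gr) <-
    normalizeChrom(GenomeInfoDb::seqlevels(gr))
  names(gr) <- ids
  gr$gene_id <- ids
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, "gene_id", drop = FALSE]
  gr
}

#' Assign QC-passed variants to genes by position
#'
#' A variant belongs to a gene iff it lies on the gene's chromosome with
#' start - padding <= pos <= end + padding (both ends inclusive). A variant
#' may belong to several overlapping genes. Genes with fewer than
#' `min_snps` member variants are dropped and reported.
#'
#' @param records data.frame of QC-passed records with `z` computed.
#' @param genes GRanges from [loadGenes()].
#' @param padding_bp symmetric flank added to each gene body (default 0).
#' @param min_snps minimum members for a gene to be kept (default 2).
#' @return list with `assignments` (named list of per-gene data.frames of
#'   member records, sorted by position then rsid, each carrying the gene's
#'   `chrom`, `start`, `end` as attributes) and `dropped`, a data.frame
#'   reporting genes removed for having fewer than `min_snps` members.
#' @export
assignSnps <- function(records, genes, padding_bp = 0, min_snps = 2) {
  if (!nrow(records)) stop("no records to assign")
  chroms <- union(unique(records$chrom), GenomeInfoDb::seqlevels(genes))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = factor(records$chrom, levels = chroms),
    ranges = IRanges::IRanges(start = records$pos, width = 1L)
  )
  genes2 <- genes
  GenomeInfoDb::seqlevels(genes2) <- chroms
  if (padding_bp > 0) {
    genes2 <- GenomicRanges::trim(suppressWarnings(genes2 + padding_bp))
  }
  hits <- GenomicRanges::findOverlaps(snp_gr, genes2, ignore.strand = TRUE)
  by_gene <- split(S4Vectors::queryHits(hits),
                   names(genes2)[S4Vectors::subjectHits(hits)])

  assignments <- list()
  dropped <- data.frame(gene_id = character(0), n_snps = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  for (gid in names(genes2)) {
    idx <- by_gene[[gid]]
    n <- length(idx)
    if (n < min_snps) {
      dropped <- rbind(dropped, data.frame(
        gene_id = gid, n_snps = n,
        reason = sprintf("fewer than %d SNPs", min_snps),
        stringsAsFactors = FALSE))
      next
    }
    mem <- records[idx, , drop = FALSE]
    mem <- mem[order(mem$pos, mem$rsid), , drop = FALSE]
    rownames(mem) <- NULL
    attr(mem, "gene_id") <- gid
    attr(mem, "chrom") <- as.character(GenomicRanges::seqnames(genes2[gid]))
    attr(mem, "start") <- GenomicRanges::start(genes[gid])
    attr(mem, "end") <- GenomicRanges::end(genes[gid])
    assignments[[gid]] <- mem
  }
  list(assignments = assignments, dropped = dropped)
}
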