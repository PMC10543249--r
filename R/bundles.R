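#' Write per-chromosome bundles of processed gene sets
#'
#' Persists harmonized, pruned gene sets as one directory per chromosome,
#' each holding a SNP table (`snps.tsv`: gene_id, rsid, pos, alleles, z)
#' and the LD matrices in long format (`ld.tsv`: gene_id, i, j, r; upper
#' triangle including the diagonal). Values are written with 17 significant
#' digits so a round trip reproduces them bit-exactly. A `manifest.tsv`
#' records per-chromosome gene/SNP counts and md5 checksums.
#'
#' @param gene_sets named list of [GeneSnpSet-class] objects.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
buildBundles <- function(gene_sets, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chroms <- vapply(gene_sets, function(g) g@chrom, character(1))
  manifest <- data.frame(chrom = character(0), n_genes = integer(0),
                         n_snps = integer(0), snps_md5 = character(0),
                         ld_md5 = character(0), stringsAsFactors = FALSE)
  fmt <- function(x) sprintf("%.17g", x)
  for (chr in sort(unique(chroms))) {
    sets <- gene_sets[chroms == chr]
    sets <- sets[order(names(sets))]
    cdir <- file.path(out_dir, paste0("chr", chr))
    dir.create(cdir, showWarnings = FALSE)
    snp_rows <- lapply(sets, function(g) {
      s <- snpInfo(g)
      data.frame(gene_id = geneId(g), rsid = s$rsid, pos = s$pos,
                 effect_allele = s$effect_allele,
                 other_allele = s$other_allele, z = fmt(zScores(g)),
                 stringsAsFactors = FALSE)
    })
    ld_rows <- lapply(sets, function(g) {
      r <- ldMatrix(g)
      idx <- which(upper.tri(r, diag = TRUE), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      data.frame(gene_id = geneId(g), i = idx[, 1], j = idx[, 2],
                 r = fmt(r[idx]), stringsAsFactors = FALSE)
    })
    snp_tab <- do.call(rbind, snp_rows)
    ld_tab <- do.call(rbind, ld_rows)
    sf <- file.path(cdir, "snps.tsv")
    lf <- file.path(cdir, "ld.tsv")
    utils::write.table(snp_tab, sf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ld_tab, lf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- rbind(manifest, data.frame(
      chrom = chr, n_genes = length(sets), n_snps = nrow(snp_tab),
      snps_md5 = unname(tools::md5sum(sf)), ld_md5 = unname(tools::md5sum(lf)),
      stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read per-chromosome bundles back into GeneSnpSets
#'
#' @param bundle_dir directory written by [buildBundles()].
#' @return named list of [GeneSnpSet-class] objects.
#' @export
readBundles <- function(bundle_dir) {
  mf <- file.path(bundle_dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv under ", bundle_dir)
  manifest <- utils::read.table(mf, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE,
                                colClasses = c(chrom = "character"))
  gene_sets <- list()
  for (k in seq_len(nrow(manifest))) {
    chr <- manifest$chrom[k]
    cdir <- file.path(bundle_dir, paste0("chr", chr))
    if (manifest$n_genes[k] == 0L) next
    snps <- utils::read.table(file.path(cdir, "snps.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    ld <- utils::read.table(file.path(cdir, "ld.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    for (gid in unique(snps$gene_id)) {
      s <- snps[snps$gene_id == gid, , drop = FALSE]
      e <- ld[ld$gene_id == gid, , drop = FALSE]
      m <- nrow(s)
      r <- matrix(0, m, m)
      r[cbind(e$i, e$j)] <- e$r
      r[cbind(e$j, e$i)] <- e$r
      gene_sets[[gid]] <- GeneSnpSet(
        gid, chr,
        data.frame(rsid = s$rsid, pos = s$pos,
                   effect_allele = s$effect_allele,
                   other_allele = s$other_allele, stringsAsFactors = FALSE),
        s$z, r)
    }
  }
  gene_sets
}
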