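# shared in-code fixtures

# write a small summary-statistics file; rows is a data.frame with columns
# SNP CHR BP A1 A2 OR SE INFO (any subset of optional ones)
write_sumstats_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

default_column_map <- c(rsid = "SNP", chrom = "CHR", pos = "BP",
                        effect_allele = "A1", other_allele = "A2",
                        odds_ratio = "OR", se = "SE", info = "INFO")

sumstats_fixture <- function() {
  data.frame(
    SNP = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    CHR = c("1", "chr2", "X", "3", "3"),
    BP = c(100L, 200L, 300L, 400L, 500L),
    A1 = c("A", "A", "C", "G", "A"),
    A2 = c("G", "T", "G", "C", "C"),
    OR = c(1.2, 0.8, 1.1, 1.05, 0.9),
    SE = c(0.1, 0.2, 0.1, 0.05, 0.12),
    INFO = c(0.95, 0.99, 0.92, 0.97, 0.5),
    stringsAsFactors = FALSE
  )
}

# records data.frame in the internal (post-read) layout
make_records <- function(rsid, chrom, pos, ea, oa, or_, se, info = NA_real_) {
  data.frame(rsid = rsid, chrom = as.character(chrom), pos = pos,
             effect_allele = ea, other_allele = oa, odds_ratio = or_,
             se = se, info = info, stringsAsFactors = FALSE)
}

# tiny deterministic GeneSnpSet
toy_gene_set <- function(z = c(1.2, -0.4, 2.1), r = 0.5,
                         gene_id = "TOY1", chrom = "1") {
  m <- length(z)
  R <- r^abs(outer(seq_len(m), seq_len(m), "-"))
  snps <- data.frame(rsid = paste0("rs", seq_len(m)),
                     pos = 100L * seq_len(m),
                     effect_allele = rep("A", m),
                     other_allele = rep("G", m),
                     stringsAsFactors = FALSE)
  GeneSnpSet(gene_id, chrom, snps, z, R)
}

# brute-force Monte-Carlo tail of a weighted chi-square sum
mc_quadform_tail <- function(q, w, n = 5e5, seed = 1) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- matrix(rnorm(n * length(w))^2, ncol = length(w)) %*% w
  mean(x > q)
}
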