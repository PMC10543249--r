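make_test_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "1\t100\tv1\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0",
    "1\t300\tv3\tA\tC,G\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "1\t400\tv4\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",
    "1\t500\tv5\tT\tC\t.\tPASS\t.\tGT\t1/1\t./.\t0/0"
  )
  writeLines(lines, path)
  path
}

test_that("VCF loading keeps biallelic SNVs, counts skips, decodes dosages", {
  panel <- loadPanel(make_test_vcf())
  expect_equal(panel$variants$rsid, c("v1", "v2", "v5"))
  expect_equal(panel$skipped, 2L)  # multiallelic + indel
  expect_equal(unname(panel$dosage["v1", ]), c(0L, 1L, 2L))
  expect_equal(unname(panel$dosage["v2", ]), c(1L, 1L, 0L))
  expect_equal(unname(panel$dosage["v5", ]), c(2L, NA_integer_, 0L))
})

test_that("region and sample subsets restrict the panel", {
  path <- make_test_vcf()
  reg <- loadPanel(path, region = list(chrom = "1", start = 150, end = 250))
  expect_equal(reg$variants$rsid, "v2")
  sub <- loadPanel(path, sample_subset = c("S1", "S3"))
  expect_equal(colnames(sub$dosage), c("S1", "S3"))
  expect_error(loadPanel(path, sample_subset = "S9"), "absent")
  empty <- loadPanel(path, region = list(chrom = "7", start = 1, end = 10))
  expect_equal(nrow(empty$variants), 0L)
})

test_that("harmonization keeps, flips or drops Z by allele orientation", {
  panel <- list(variants = data.frame(
    chrom = "1", pos = c(100, 200, 300),
    rsid = c("v1", "v2", "v3"),
    ref = c("G", "G", "A"), alt = c("A", "A", "C"),
    stringsAsFactors = FALSE))
  asn <- computeZ(make_records(
    c("rs1", "rs2", "rs3"), "1", c(100, 200, 300),
    ea = c("A", "G", "A"), oa = c("G", "A", "G"),
    or_ = exp(c(0.13, 0.13, 0.13)), se = 0.1))
  attr(asn, "chrom") <- "1"
  h <- harmonizeGene(asn, panel)
  expect_equal(h$snps$rsid, c("rs1", "rs2"))
  expect_equal(h$z, c(1.3, -1.3), tolerance = 1e-12)
  expect_equal(h$counts, list(matched = 1L, flipped = 1L, dropped = 1L))
})

test_that("LD is the Pearson correlation of dosages and matches a hand oracle", {
  d <- rbind(a = c(0, 1, 2, 1, 0, 2),
             b = c(2, 1, 0, 1, 2, 0),
             c = c(0, 1, 2, 2, 1, 0),
             mono = rep(1, 6))
  ld <- computeLD(d)
  expect_equal(ld$monomorphic, "mono")
  expect_equal(ld$r["a", "b"], -1)
  expect_equal(diag(ld$r), setNames(rep(1, 3), c("a", "b", "c")))
  # independent oracle: direct Pearson formula
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(ld$r["a", "c"], pearson(d["a", ], d["c", ]), tolerance = 1e-12)
  expect_equal(ld$r["b", "c"], pearson(d["b", ], d["c", ]), tolerance = 1e-12)
  ev <- eigen(ld$r, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("missing genotypes use pairwise-complete correlation", {
  d <- rbind(a = c(0, 1, 2, NA, 1), b = c(0, 1, 2, 2, NA))
  ld <- computeLD(d)
  expect_equal(ld$r["a", "b"], cor(c(0, 1, 2), c(0, 1, 2)))
})

test_that("perfect-LD pruning keeps the earliest SNP, prunes chains, is idempotent", {
  snps <- data.frame(rsid = paste0("s", 1:3), pos = c(10, 20, 30),
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  R_pair <- matrix(c(1, 1, 0.3, 1, 1, 0.3, 0.3, 0.3, 1), 3, 3)
  gs <- GeneSnpSet("G1", "1", snps, c(1, 2, 3), R_pair)
  pruned <- prunePerfect(gs)
  expect_equal(snpInfo(pruned)$rsid, c("s1", "s3"))
  expect_equal(zScores(pruned), c(1, 3))
  again <- prunePerfect(pruned)
  expect_equal(snpInfo(again), snpInfo(pruned))
  expect_equal(ldMatrix(again), ldMatrix(pruned))

  # chain r12 = r23 = 1 (hence r13 = 1): only the first SNP survives -> gene dropped
  R_chain <- matrix(1, 3, 3)
  gs_chain <- GeneSnpSet("G2", "1", snps, c(1, 1, 1), R_chain)
  expect_null(prunePerfect(gs_chain))

  # below threshold: untouched
  gs_ok <- toy_gene_set(r = 0.95)
  expect_equal(snpInfo(prunePerfect(gs_ok, r_max = 0.9999)),
               snpInfo(gs_ok))
})

test_that("bundles round-trip bit-exactly and are byte-stable across writes", {
  set.seed(7)
  gs1 <- toy_gene_set(z = rnorm(4), r = 0.6, gene_id = "GA", chrom = "1")
  gs2 <- toy_gene_set(z = rnorm(3), r = 0.2, gene_id = "GB", chrom = "2")
  sets <- list(GA = gs1, GB = gs2)
  d1 <- file.path(tempfile(), "b1")
  buildBundles(sets, d1)
  back <- readBundles(d1)
  expect_equal(sort(names(back)), c("GA", "GB"))
  expect_identical(zScores(back$GA), zScores(gs1))
  expect_identical(ldMatrix(back$GA), ldMatrix(gs1))
  expect_identical(snpInfo(back$GB)$pos, snpInfo(gs2)$pos)

  d2 <- file.path(tempfile(), "b2")
  buildBundles(sets, d2)
  for (f in c("chr1/snps.tsv", "chr1/ld.tsv", "chr2/snps.tsv", "chr2/ld.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("recoding panel alleles flips z and LD signs but not gene p-values", {
  set.seed(11)
  m <- 6
  panel <- simulatePanel(makeLD(list(type = "ar1", r = 0.5), m),
                         mafs = runif(m, 0.1, 0.5), n_samples = 300,
                         chrom = "1", positions = 100 * seq_len(m))
  z_alt <- as.vector(simulateZ(diag(m), 0, 1))
  se <- rep(0.1, m)
  asn <- computeZ(make_records(
    panel$variants$rsid, "1", panel$variants$pos,
    ea = panel$variants$alt, oa = panel$variants$ref,
    or_ = exp(z_alt * se), se = se))
  attr(asn, "chrom") <- "1"

  build <- function(pn) {
    h <- harmonizeGene(asn, pn)
    d <- pn$dosage[h$panel_idx, , drop = FALSE]
    rownames(d) <- h$snps$rsid
    ld <- computeLD(d)
    GeneSnpSet("G", "1", h$snps, h$z, ld$r)
  }
  g1 <- build(panel)
  # recode one variant: swap ref/alt, dosage -> 2 - dosage
  flip_idx <- 3L
  panel2 <- panel
  panel2$variants[flip_idx, c("ref", "alt")] <-
    panel$variants[flip_idx, c("alt", "ref")]
  panel2$dosage[flip_idx, ] <- 2L - panel$dosage[flip_idx, ]
  g2 <- build(panel2)

  sgn <- rep(1, m); sgn[flip_idx] <- -1
  expect_equal(zScores(g2), zScores(g1) * sgn, tolerance = 1e-12)
  expect_equal(ldMatrix(g2), ldMatrix(g1) * outer(sgn, sgn),
               tolerance = 1e-12, ignore_attr = TRUE)
  # the squared-sum statistic is orientation-free even for a partial recode
  expect_lt(abs(squaredSumTest(zScores(g2), ldMatrix(g2))$p -
                  squaredSumTest(zScores(g1), ldMatrix(g1))$p), 1e-10)

  # recoding EVERY variant: z fully negated, LD unchanged, all p identical
  panel3 <- panel
  panel3$variants[, c("ref", "alt")] <- panel$variants[, c("alt", "ref")]
  panel3$dosage <- 2L - panel$dosage
  g3 <- build(panel3)
  expect_equal(zScores(g3), -zScores(g1), tolerance = 1e-12)
  expect_equal(ldMatrix(g3), ldMatrix(g1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(abs(sumTest(zScores(g3), ldMatrix(g3))$p -
                  sumTest(zScores(g1), ldMatrix(g1))$p), 1e-10)
  expect_lt(abs(squaredSumTest(zScores(g3), ldMatrix(g3))$p -
                  squaredSumTest(zScores(g1), ldMatrix(g1))$p), 1e-10)
  expect_lt(abs(adaptiveTest(zScores(g3), ldMatrix(g3))$p -
                  adaptiveTest(zScores(g1), ldMatrix(g1))$p), 1e-10)
})
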