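#' Build an LD correlation matrix with a named structure
#'
#' AR(1): r_ij = r^|i-j|; block: equal-sized blocks with constant
#' within-block correlation and zero between; identity. The result is
#' validated as a correlation matrix (unit diagonal, PSD).
#'
#' @param structure list with `type` in `"ar1"`, `"block"`, `"identity"`
#'   and, as needed, `r` (and `size` for blocks).
#' @param m number of SNPs (>= 2).
#' @return m x m correlation matrix.
#' @export
makeLD <- function(structure, m) {
  stopifnot(m >= 2)
  type <- structure$type
  R <- switch(type,
    identity = diag(m),
    ar1 = {
      r <- structure$r
      if (abs(r) >= 1) stop("ar1 correlation must be in (-1, 1)")
      r^abs(outer(seq_len(m), seq_len(m), "-"))
    },
    block = {
      r <- structure$r
      size <- structure$size
      if (abs(r) >= 1) stop("block correlation must be in (-1, 1)")
      blk <- ceiling(seq_len(m) / size)
      R <- (outer(blk, blk, "==")) * r
      diag(R) <- 1
      R
    },
    stop("unknown LD structure type: ", type)
  )
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("requested structure is not positive semi-definite")
  R
}

#' Simulate correlated Z-score vectors
#'
#' Draws from MVN(delta, R) via a square-root factorization of R (with
#' diagonal jitter at most 1e-8 when needed). Reproducible by seed.
#'
#' @param R correlation matrix.
#' @param delta mean vector (recycled scalar allowed; 0 for the null).
#' @param n_reps number of draws.
#' @param seed optional RNG seed.
#' @return n_reps x m matrix of Z-vectors.
#' @export
simulateZ <- function(R, delta = 0, n_reps = 1, seed = NULL) {
  if (!is.null(seed)) {
    old_rng <- saveRNG()
    on.exit(restoreRNG(old_rng), add = TRUE)
    set.seed(seed)
  }
  m <- nrow(R)
  delta <- rep_len(delta, m)
  ch <- sqrtFactor(R)
  zs <- matrix(stats::rnorm(n_reps * m), n_reps, m) %*% ch
  sweep(zs, 2L, delta, "+")
}

# non-strand-ambiguous REF/ALT pairs to draw from
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Simulate a diploid reference panel
#'
#' Latent-Gaussian threshold model: per individual, two correlated
#' standard-normal vectors with correlation `R_target` are thresholded at
#' the upper-MAF quantile and summed to a {0, 1, 2} dosage. The realized
#' dosage correlation is attenuated relative to the latent target; the
#' pipeline (like its tests) always uses the realized panel LD, so the
#' attenuation is measured rather than corrected.
#'
#' @param R_target latent correlation matrix (m x m).
#' @param mafs per-variant minor-allele frequencies in (0, 0.5].
#' @param n_samples number of diploid individuals.
#' @param seed optional RNG seed.
#' @param vcf_path optional path: when given, a VCF 4.2 file with GT
#'   genotypes and per-variant non-ambiguous REF/ALT alleles is written.
#' @param chrom,positions,ids optional variant coordinates/names.
#' @return list with `variants` (chrom, pos, rsid, ref, alt), `dosage`
#'   (variants x samples) and `vcf_path` (NULL if not written).
#' @export
simulatePanel <- function(R_target, mafs, n_samples, seed = NULL,
                          vcf_path = NULL, chrom = "1", positions = NULL,
                          ids = NULL) {
  if (!is.null(seed)) {
    old_rng <- saveRNG()
    on.exit(restoreRNG(old_rng), add = TRUE)
    set.seed(seed)
  }
  m <- nrow(R_target)
  mafs <- rep_len(mafs, m)
  stopifnot(all(mafs > 0), all(mafs <= 0.5))
  ch <- sqrtFactor(R_target)
  thr <- stats::qnorm(1 - mafs)
  hap <- function() {
    lat <- matrix(stats::rnorm(n_samples * m), n_samples, m) %*% ch
    t(sweep(lat, 2L, thr, ">") * 1L)
  }
  dosage <- hap() + hap()
  pair_idx <- sample.int(nrow(.allele_pairs), m, replace = TRUE)
  if (is.null(positions)) positions <- seq_len(m) * 100L
  if (is.null(ids)) ids <- paste0("rs_sim_", seq_len(m))
  variants <- data.frame(chrom = as.character(chrom), pos = positions,
                         rsid = ids, ref = .allele_pairs[pair_idx, 1],
                         alt = .allele_pairs[pair_idx, 2],
                         stringsAsFactors = FALSE)
  rownames(dosage) <- ids
  colnames(dosage) <- paste0("S", seq_len(n_samples))
  if (!is.null(vcf_path)) {
    writePanelVcf(variants, dosage, vcf_path)
  }
  list(variants = variants, dosage = dosage, vcf_path = vcf_path)
}

#' Write a dosage matrix as a VCF 4.2 file
#'
#' @param variants data.frame with chrom, pos, rsid, ref, alt.
#' @param dosage variants x samples matrix of {0, 1, 2} ALT counts.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePanelVcf <- function(variants, dosage, path) {
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_map[dosage + 1L], nrow = nrow(dosage))
  gt[is.na(dosage)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=geneSAT synthetic panel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dosage)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$rsid[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate an end-to-end summary-statistics fixture
#'
#' Generates, per gene, panel genotypes under a latent AR(1)/block/identity
#' LD target, draws per-SNP Z-scores from MVN(delta, realized panel LD),
#' converts them to (OR, SE) pairs via OR = exp(z * se) with SE drawn in a
#' plausible range, randomly orients the reported effect allele to panel
#' ALT or REF (flipping the written Z accordingly), and writes the
#' pipeline's input dialects: a summary-statistics table, a gene BED, a
#' panel VCF and a ground-truth table (gene -> delta).
#'
#' @param sim list of study conditions: `seed`, `n_genes`, `m_per_gene`,
#'   `ld` (structure list for [makeLD()]), `delta` (per-gene scalar mean
#'   shift of every SNP Z; recycled; 0 for null genes), `panel_n`,
#'   `maf_range` (default c(0.05, 0.5)), `se_range` (default c(0.02, 0.08)).
#' @param out_dir directory to write `sumstats.tsv`, `genes.bed`,
#'   `panel.vcf`, `truth.tsv`.
#' @return list with the four file paths plus `truth` (data.frame) and
#'   `column_map` for [readSumstats()].
#' @export
simulateSumstats <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old_rng <- saveRNG()
  on.exit(restoreRNG(old_rng), add = TRUE)
  set.seed(sim$seed)
  n_genes <- sim$n_genes
  m <- sim$m_per_gene
  maf_range <- sim$maf_range %||% c(0.05, 0.5)
  se_range <- sim$se_range %||% c(0.02, 0.08)
  delta <- rep_len(sim$delta %||% 0, n_genes)
  R_target <- makeLD(sim$ld, m)

  ss_rows <- vector("list", n_genes)
  bed_rows <- character(n_genes)
  var_rows <- vector("list", n_genes)
  dos_rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    gid <- sprintf("GENE%03d", g)
    base <- (g - 1) * 100000 + 10000
    pos <- base + seq_len(m) * 150L
    ids <- sprintf("rs%d_%d", g, seq_len(m))
    mafs <- stats::runif(m, maf_range[1], maf_range[2])
    panel <- simulatePanel(R_target, mafs, sim$panel_n, chrom = "1",
                           positions = pos, ids = ids)
    ld <- computeLD(panel$dosage)
    keep <- match(ld$snp_ids, ids)
    z <- rep(NA_real_, m)
    if (length(keep) >= 1) {
      z[keep] <- as.vector(simulateZ(ld$r, delta = delta[g], n_reps = 1))
    }
    # monomorphic panel SNPs get an independent standard-normal Z
    mono <- which(is.na(z))
    z[mono] <- stats::rnorm(length(mono), mean = delta[g])
    se <- stats::runif(m, se_range[1], se_range[2])
    flip <- stats::runif(m) < 0.5
    eff <- ifelse(flip, panel$variants$ref, panel$variants$alt)
    oth <- ifelse(flip, panel$variants$alt, panel$variants$ref)
    z_out <- ifelse(flip, -z, z)
    ss_rows[[g]] <- data.frame(
      SNP = ids, CHR = "1", BP = pos, A1 = eff, A2 = oth,
      OR = sprintf("%.17g", exp(z_out * se)),
      SE = sprintf("%.17g", se),
      INFO = sprintf("%.4f", stats::runif(m, 0.92, 1)),
      stringsAsFactors = FALSE)
    bed_rows[g] <- paste("1", base - 1, base + (m + 1) * 150L, gid,
                         sep = "\t")
    var_rows[[g]] <- panel$variants
    dos_rows[[g]] <- panel$dosage
  }

  paths <- list(
    sumstats = file.path(out_dir, "sumstats.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    panel = file.path(out_dir, "panel.vcf"),
    truth = file.path(out_dir, "truth.tsv")
  )
  ss <- do.call(rbind, ss_rows)
  utils::write.table(ss, paths$sumstats, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(bed_rows, paths$genes)
  writePanelVcf(do.call(rbind, var_rows), do.call(rbind, dos_rows),
                paths$panel)
  truth <- data.frame(gene_id = sprintf("GENE%03d", seq_len(n_genes)),
                      delta = delta, stringsAsFactors = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(truth = truth,
                column_map = c(rsid = "SNP", chrom = "CHR", pos = "BP",
                               effect_allele = "A1", other_allele = "A2",
                               odds_ratio = "OR", se = "SE", info = "INFO")))
}

#' Simulate a negative-binomial count matrix
#'
#' Emulates a two-group RNA-seq design: per-gene baseline means drawn
#' log-uniformly, per-sample size multipliers, per-gene true log2 fold
#' changes applied to the case group, NB sampling at a common dispersion.
#'
#' @param de_params list with `n_per_group`, `true_lfc` (vector, recycled
#'   over genes), `dispersion` (> 0), and optional `size_multipliers`
#'   (per-sample, length 2 * n_per_group) and `base_mean_range`
#'   (default c(20, 500)).
#' @param n_genes number of genes.
#' @param seed optional RNG seed.
#' @return list with `counts` (genes x samples integer matrix), `condition`
#'   (factor, control then case) and `truth` (gene_id, base_mean, true_lfc).
#' @export
simulateCounts <- function(de_params, n_genes, seed = NULL) {
  if (!is.null(seed)) {
    old_rng <- saveRNG()
    on.exit(restoreRNG(old_rng), add = TRUE)
    set.seed(seed)
  }
  n <- de_params$n_per_group
  disp <- de_params$dispersion
  stopifnot(disp > 0, n >= 1)
  lfc <- rep_len(de_params$true_lfc, n_genes)
  rng <- de_params$base_mean_range %||% c(20, 500)
  sm <- de_params$size_multipliers %||% rep(1, 2 * n)
  stopifnot(length(sm) == 2 * n, all(sm > 0))
  base <- exp(stats::runif(n_genes, log(rng[1]), log(rng[2])))
  condition <- factor(rep(c("control", "case"), each = n),
                      levels = c("control", "case"))
  mu <- outer(base, sm)
  fc <- 2^lfc
  mu[, condition == "case"] <- mu[, condition == "case"] * fc
  counts <- matrix(stats::rnbinom(n_genes * 2 * n, mu = mu, size = 1 / disp),
                   nrow = n_genes)
  rownames(counts) <- sprintf("GENE%03d", seq_len(n_genes))
  colnames(counts) <- paste0(rep(c("ctrl_", "case_"), each = n),
                             seq_len(n))
  list(counts = counts, condition = condition,
       truth = data.frame(gene_id = rownames(counts), base_mean = base,
                          true_lfc = lfc, stringsAsFactors = FALSE))
}
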