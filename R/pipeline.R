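#' Read a pipeline configuration file
#'
#' The configuration is a single YAML document holding input paths
#' (discovery/replication summary statistics, gene annotation, panel VCF,
#' optional sample subset, count matrix, condition map), the column-role
#' map, QC parameters, test parameters (rho grid, seeds, Monte-Carlo
#' draws) and thresholds (family-wise, replication and DE alphas, all
#' 0.05 by default), plus an output directory.
#'
#' @param path YAML file path.
#' @return config list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  fillConfigDefaults(cfg)
}

fillConfigDefaults <- function(cfg) {
  defaults <- list(
    info_min = 0.9, info_mode = "keep_at_least",
    padding_bp = 0, min_snps = 2, r_max = 0.9999,
    alpha_fw = 0.05, alpha_replication = 0.05, alpha_de = 0.05,
    family_size = NULL, min_total_count = 10,
    genes_format = "auto"
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (a in c("alpha_fw", "alpha_replication", "alpha_de")) {
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1) stop(a, " must be in (0, 1)")
  }
  cfg
}

requireConfigPath <- function(cfg, field) {
  p <- cfg[[field]]
  if (is.null(p)) stop("configuration field '", field, "' is missing")
  if (!file.exists(p)) {
    stop("configuration field '", field, "' points to a missing file: ", p)
  }
  p
}

# shared sumstats -> pruned gene sets chain, with per-stage counters
processSumstats <- function(sumstats_path, cfg, genes, panel,
                            restrict_genes = NULL) {
  records <- readSumstats(sumstats_path, unlist(cfg$column_map))
  n_rejected <- nrow(attr(records, "rejected"))
  qc <- qcFilter(records, info_min = cfg$info_min, info_mode = cfg$info_mode)
  recs <- computeZ(qc$records)
  if (!is.null(restrict_genes)) genes <- genes[restrict_genes]
  asn <- assignSnps(recs, genes, padding_bp = cfg$padding_bp,
                    min_snps = cfg$min_snps)
  gs <- makeGeneSets(asn$assignments, panel, r_max = cfg$r_max)
  list(gene_sets = gs$gene_sets,
       counters = list(
         records_in = nrow(records) + n_rejected,
         records_rejected = n_rejected,
         records_qc_pass = nrow(recs),
         qc_report = qc$report,
         genes_in = length(genes),
         genes_dropped_assignment = nrow(asn$dropped),
         genes_dropped_harmonization = nrow(gs$dropped),
         genes_tested = length(gs$gene_sets)),
       dropped = rbind(
         asn$dropped[, c("gene_id", "reason")],
         gs$dropped))
}

#' Discovery-stage gene scan
#'
#' Full chain: read and QC the discovery summary statistics, compute
#' Z-scores, assign SNPs to genes, harmonize against the panel, estimate
#' and prune LD, build bundles, and run the three SNP-set tests per gene
#' with a Bonferroni threshold alpha_fw / genes-tested (or a configured
#' nominal family size). Every stage's counts are logged in the returned
#' manifest.
#'
#' @param config config list (see [readPipelineConfig()]); required fields:
#'   `discovery_sumstats`, `genes`, `panel_vcf`, `column_map`; optional
#'   `sample_subset`, `out_dir`, thresholds and QC parameters.
#' @return list with `scan` (from [geneScan()]), `gene_sets`, `manifest`
#'   (stage counters), `dropped` (gene-level report) and `threshold`.
#' @export
runDiscovery <- function(config) {
  cfg <- fillConfigDefaults(config)
  ss <- requireConfigPath(cfg, "discovery_sumstats")
  gp <- requireConfigPath(cfg, "genes")
  vp <- requireConfigPath(cfg, "panel_vcf")
  genes <- loadGenes(gp, format = cfg$genes_format)
  panel <- loadPanel(vp, sample_subset = cfg$sample_subset)
  proc <- processSumstats(ss, cfg, genes, panel)
  if (length(proc$gene_sets) == 0L) stop("no testable genes after processing")
  scan <- geneScan(proc$gene_sets, alpha_fw = cfg$alpha_fw,
                   family_size = cfg$family_size)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    buildBundles(proc$gene_sets, file.path(cfg$out_dir, "bundles"))
    writeTsv(scan$results, file.path(cfg$out_dir, "discovery_results.tsv"))
    writeTsv(scan$manhattan, file.path(cfg$out_dir, "manhattan.tsv"))
    writeTsv(proc$dropped, file.path(cfg$out_dir, "dropped_genes.tsv"))
    writeRunManifest(proc$counters, scan$threshold,
                     file.path(cfg$out_dir, "run_manifest.txt"))
  }
  list(scan = scan, gene_sets = proc$gene_sets, manifest = proc$counters,
       dropped = proc$dropped, threshold = scan$threshold)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

writeRunManifest <- function(counters, threshold, path) {
  lines <- c(
    sprintf("records_in\t%d", counters$records_in),
    sprintf("records_rejected\t%d", counters$records_rejected),
    sprintf("records_qc_pass\t%d", counters$records_qc_pass),
    sprintf("qc_%s\t%d", counters$qc_report$rule, counters$qc_report$removed),
    sprintf("genes_in\t%d", counters$genes_in),
    sprintf("genes_dropped_assignment\t%d", counters$genes_dropped_assignment),
    sprintf("genes_dropped_harmonization\t%d",
            counters$genes_dropped_harmonization),
    sprintf("genes_tested\t%d", counters$genes_tested),
    sprintf("bonferroni_threshold\t%.17g", threshold))
  writeLines(lines, path)
}

#' Replication stage
#'
#' Re-runs the adaptive test for the discovery-significant genes only,
#' against the replication summary statistics re-harmonized to the same
#' panel. A gene replicates iff its replication p-value is strictly below
#' the (unadjusted) replication alpha; genes that cannot be tested (absent
#' or with fewer than `min_snps` surviving SNPs in the replication data)
#' are flagged not-testable.
#'
#' @param discovery result list from [runDiscovery()].
#' @param config config list; requires `replication_sumstats` plus the
#'   discovery fields (`genes`, `panel_vcf`, `column_map`).
#' @return data.frame: gene_id, p_replication, testable, replicated.
#' @export
runReplication <- function(discovery, config) {
  cfg <- fillConfigDefaults(config)
  sig <- discovery$scan$results$gene_id[discovery$scan$results$significant]
  if (length(sig) == 0L) {
    stop("no discovery-significant genes to replicate")
  }
  rs <- requireConfigPath(cfg, "replication_sumstats")
  gp <- requireConfigPath(cfg, "genes")
  vp <- requireConfigPath(cfg, "panel_vcf")
  genes <- loadGenes(gp, format = cfg$genes_format)
  missing_genes <- setdiff(sig, names(genes))
  panel <- loadPanel(vp, sample_subset = cfg$sample_subset)
  proc <- processSumstats(rs, cfg, genes, panel,
                          restrict_genes = intersect(sig, names(genes)))
  out <- data.frame(gene_id = sig, p_replication = NA_real_,
                    testable = FALSE, replicated = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sig)) {
    g <- proc$gene_sets[[sig[i]]]
    if (is.null(g)) next
    at <- adaptiveTest(zScores(g), ldMatrix(g))
    out$p_replication[i] <- at$p
    out$testable[i] <- TRUE
    out$replicated[i] <- at$p < cfg$alpha_replication
  }
  if (!is.null(cfg$out_dir)) {
    writeTsv(out, file.path(cfg$out_dir, "replication_results.tsv"))
  }
  out
}

#' Differential-expression stage from files
#'
#' Reads a gene-by-sample count matrix (delimited text, genes in rows,
#' header of sample IDs) and a two-column sample/condition map, then runs
#' [deAnalysis()].
#'
#' @param config config list; requires `counts` and `condition_map` paths.
#' @return the [deAnalysis()] data.frame.
#' @export
runDE <- function(config) {
  cfg <- fillConfigDefaults(config)
  cp <- requireConfigPath(cfg, "counts")
  mp <- requireConfigPath(cfg, "condition_map")
  counts <- as.matrix(utils::read.table(cp, header = TRUE, sep = "\t",
                                        row.names = 1, check.names = FALSE))
  cmap <- utils::read.table(mp, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  idx <- match(colnames(counts), cmap[[1]])
  if (anyNA(idx)) stop("condition map is missing samples: ",
                       paste(colnames(counts)[is.na(idx)], collapse = ", "))
  condition <- cmap[[2]][idx]
  res <- deAnalysis(counts, condition, min_total = cfg$min_total_count,
                    alpha = cfg$alpha_de)
  if (!is.null(cfg$out_dir)) {
    writeTsv(res, file.path(cfg$out_dir, "de_results.tsv"))
  }
  res
}

#' Integrate discovery, replication and expression evidence
#'
#' Joins the three stages by gene id for the discovery-significant genes
#' and emits a gene-report table with three boolean flags
#' (discovery-significant, replicated, DE-significant) and their
#' conjunction, mirroring a discovery/replication/RNA-seq summary table.
#'
#' @param discovery result list from [runDiscovery()].
#' @param replication data.frame from [runReplication()].
#' @param de_results optional data.frame from [runDE()]/[deAnalysis()];
#'   when absent the DE flag is NA and the overall flag requires the first
#'   two only of the available evidence (reported as such).
#' @param config config list (for `out_dir`).
#' @return data.frame: gene_id, chrom, p_discovery, p_replication, lfc,
#'   p_de, p_de_adj, discovery_significant, replicated, de_significant,
#'   all_three.
#' @export
integrateResults <- function(discovery, replication, de_results = NULL,
                             config = list()) {
  cfg <- fillConfigDefaults(config)
  dres <- discovery$scan$results
  if (anyDuplicated(dres$gene_id)) stop("duplicate gene ids in discovery results")
  if (anyDuplicated(replication$gene_id)) {
    stop("duplicate gene ids in replication results")
  }
  if (!is.null(de_results) && anyDuplicated(de_results$gene_id)) {
    stop("duplicate gene ids in DE results")
  }
  sig <- dres[dres$significant, , drop = FALSE]
  ri <- match(sig$gene_id, replication$gene_id)
  rep_flag <- replication$replicated[ri]
  rep_flag[is.na(rep_flag)] <- FALSE
  out <- data.frame(
    gene_id = sig$gene_id, chrom = sig$chrom,
    p_discovery = sig$p_at,
    p_replication = replication$p_replication[ri],
    lfc = NA_real_, p_de = NA_real_, p_de_adj = NA_real_,
    discovery_significant = TRUE,
    replicated = rep_flag,
    de_significant = NA,
    stringsAsFactors = FALSE)
  if (!is.null(de_results)) {
    di <- match(sig$gene_id, de_results$gene_id)
    out$lfc <- de_results$lfc[di]
    out$p_de <- de_results$p[di]
    out$p_de_adj <- de_results$p_adj[di]
    de_flag <- de_results$significant[di]
    de_flag[is.na(de_flag)] <- FALSE
    out$de_significant <- de_flag
  }
  out$all_three <- out$discovery_significant & out$replicated &
    !is.na(out$de_significant) & out$de_significant
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeTsv(out, file.path(cfg$out_dir, "integrated_report.tsv"))
    passing <- out$gene_id[out$all_three]
    writeLines(c("Genes significant in all three analyses:",
                 if (length(passing)) passing else "(none)"),
               file.path(cfg$out_dir, "integrated_summary.txt"))
  }
  out
}

#' Run the full pipeline
#'
#' Discovery scan, replication filter, DE stage (when count inputs are
#' configured) and integration.
#'
#' @param config config list or YAML path.
#' @return list with `discovery`, `replication`, `de`, `report`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  discovery <- runDiscovery(config)
  replication <- runReplication(discovery, config)
  de <- if (!is.null(config$counts)) runDE(config) else NULL
  report <- integrateResults(discovery, replication, de, config)
  list(discovery = discovery, replication = replication, de = de,
       report = report)
}

#' Manhattan plot from a scan's Manhattan table
#'
#' @param manhattan data.frame from [geneScan()].
#' @param threshold Bonferroni threshold to draw as a horizontal line.
#' @return a ggplot object.
#' @export
plotManhattan <- function(manhattan, threshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  manhattan$chrom <- factor(manhattan$chrom,
                            levels = unique(manhattan$chrom))
  p <- ggplot2::ggplot(manhattan,
                       ggplot2::aes(x = pos, y = neg_log10_p,
                                    colour = chrom)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position", y = expression(-log[10](p))) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  }
  p
}
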