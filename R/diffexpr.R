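#' Filter genes with low total counts
#'
#' Keeps genes whose total count across all samples is at least
#' `min_total` (the usual pre-filter before dispersion estimation).
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param min_total minimum total count across samples (default 10).
#' @return list with `counts` (filtered matrix) and `dropped` (number of
#'   genes removed).
#' @export
filterLowCounts <- function(counts, min_total = 10) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  keep <- rowSums(counts) >= min_total
  list(counts = counts[keep, , drop = FALSE], dropped = sum(!keep))
}

#' Median-of-ratios size factors
#'
#' Per-gene geometric means over samples form a pseudo-reference; each
#' sample's factor is the median over (positively expressed) genes of
#' count / geometric mean, rescaled so the factors have geometric mean 1.
#'
#' @param counts non-negative matrix, genes x samples.
#' @return named positive numeric vector of per-sample size factors with
#'   geometric mean 1.
#' @export
sizeFactorsMedianRatio <- function(counts) {
  stopifnot(is.matrix(counts))
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no gene is expressed in all samples; supply a pseudo-reference ",
         "or filter samples")
  }
  sf <- apply(counts, 2L, function(col) {
    exp(stats::median(log(col[use]) - log_geo[use]))
  })
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Per-gene negative-binomial Wald tests
#'
#' Fits, per gene, an NB generalized linear model with log link,
#' log size factors as offset and a two-level condition (intercept +
#' case-vs-control), and reports the log2 fold change with its Wald
#' statistic and two-sided normal p-value. Dispersion comes from a pooled
#' within-condition method-of-moments estimate on normalized counts
#' (floored at 1e-8), or is fixed. This is a deliberately simplified
#' analog of shrinkage-based DE frameworks: no dispersion shrinkage,
#' outlier handling or LFC shrinkage.
#'
#' @param counts filtered count matrix, genes x samples.
#' @param condition factor or character vector per sample with levels
#'   `control`, `case` (case vs control is reported).
#' @param size_factors optional per-sample factors; computed by
#'   [sizeFactorsMedianRatio()] when omitted.
#' @param dispersion_mode `"per_gene_moments"` (default) or `"fixed"`.
#' @param fixed_alpha NB dispersion used when `dispersion_mode = "fixed"`.
#' @return data.frame with `gene_id`, `mean_norm_count`, `lfc` (log2),
#'   `lfc_se`, `wald`, `p` (NA with `converged = FALSE` on failure).
#' @export
nbWaldTest <- function(counts, condition, size_factors = NULL,
                       dispersion_mode = c("per_gene_moments", "fixed"),
                       fixed_alpha = NULL) {
  dispersion_mode <- match.arg(dispersion_mode)
  condition <- factor(as.character(condition), levels = c("control", "case"))
  if (anyNA(condition)) stop("condition labels must be 'control' or 'case'")
  if (nlevels(droplevels(condition)) < 2L) {
    stop("both conditions must be present")
  }
  if (dispersion_mode == "fixed" && is.null(fixed_alpha)) {
    stop("fixed_alpha required when dispersion_mode = 'fixed'")
  }
  if (is.null(size_factors)) size_factors <- sizeFactorsMedianRatio(counts)
  off <- log(size_factors)
  norm <- sweep(counts, 2L, size_factors, "/")
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))

  out <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    y <- counts[i, ]
    ny <- norm[i, ]
    alpha <- if (dispersion_mode == "fixed") {
      fixed_alpha
    } else {
      momentDispersion(ny, condition)
    }
    alpha <- max(alpha, 1e-8)
    fit <- tryCatch({
      suppressWarnings(stats::glm(
        y ~ condition, offset = off,
        family = MASS::negative.binomial(theta = 1 / alpha, link = "log")))
    }, error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      out[[i]] <- data.frame(gene_id = gene_ids[i],
                             mean_norm_count = mean(ny), lfc = NA_real_,
                             lfc_se = NA_real_, wald = NA_real_, p = NA_real_,
                             converged = FALSE, stringsAsFactors = FALSE)
      next
    }
    cf <- summary(fit)$coefficients
    beta <- cf["conditioncase", "Estimate"]
    se <- cf["conditioncase", "Std. Error"]
    wald <- beta / se
    out[[i]] <- data.frame(
      gene_id = gene_ids[i], mean_norm_count = mean(ny),
      lfc = beta / log(2), lfc_se = se / log(2), wald = wald,
      p = 2 * stats::pnorm(-abs(wald)), converged = TRUE,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# pooled within-condition method-of-moments NB dispersion on normalized
# counts: alpha = (pooled variance - mean) / mean^2, floored by the caller
momentDispersion <- function(ny, condition) {
  mu <- tapply(ny, condition, mean)
  ss <- sum((ny - mu[condition])^2)
  df <- length(ny) - nlevels(condition)
  v <- if (df > 0) ss / df else 0
  mbar <- mean(ny)
  if (mbar <= 0) return(1e-8)
  (v - mbar) / mbar^2
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' missing p-values are excluded from the family and returned as NA.
#'
#' @param pvals numeric vector of raw p-values (NA allowed).
#' @return adjusted p-values, order-aligned with the input.
#' @export
bhAdjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Fold change from a log2 fold change
#'
#' @param lfc log2 fold change.
#' @return multiplicative fold change `2^lfc`.
#' @export
foldChange <- function(lfc) 2^lfc

#' Full differential-expression stage
#'
#' Filter low-count genes, normalize by median-of-ratios, run per-gene NB
#' Wald tests and BH-adjust the converged p-values.
#'
#' @inheritParams nbWaldTest
#' @param min_total total-count filter threshold (default 10).
#' @param alpha adjusted-p significance level (default 0.05).
#' @return data.frame of [nbWaldTest()] columns plus `p_adj` and
#'   `significant`; `attr(, "dropped_low_count")` records the filter loss.
#' @export
deAnalysis <- function(counts, condition, min_total = 10,
                       dispersion_mode = "per_gene_moments",
                       fixed_alpha = NULL, alpha = 0.05) {
  flt <- filterLowCounts(counts, min_total = min_total)
  if (nrow(flt$counts) == 0L) {
    res <- data.frame(gene_id = character(0), mean_norm_count = numeric(0),
                      lfc = numeric(0), lfc_se = numeric(0),
                      wald = numeric(0), p = numeric(0),
                      converged = logical(0), p_adj = numeric(0),
                      significant = logical(0))
    attr(res, "dropped_low_count") <- flt$dropped
    return(res)
  }
  res <- nbWaldTest(flt$counts, condition,
                    dispersion_mode = dispersion_mode,
                    fixed_alpha = fixed_alpha)
  res$p_adj <- bhAdjust(res$p)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  attr(res, "dropped_low_count") <- flt$dropped
  res
}
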