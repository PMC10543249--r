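#' Sum (burden) test
#'
#' B = sum_j z_j; under the null B ~ Normal(0, 1'R1), so the two-sided
#' p-value is the 1-df chi-square tail of B^2 / (1'R1). Powerful when all
#' variants share a direction of effect.
#'
#' @param z Z-score vector.
#' @param R LD correlation matrix, aligned with `z`.
#' @return list with `B` and `p`.
#' @export
sumTest <- function(z, R) {
  s2 <- sum(R)
  if (s2 <= 0) stop("1'R1 <= 0: invalid correlation matrix")
  B <- sum(z)
  list(B = B, p = stats::pchisq(B^2 / s2, df = 1, lower.tail = FALSE))
}

#' Squared-sum (SKAT-type) test
#'
#' Q = sum_j z_j^2; the null is the weighted chi-square sum whose weights
#' are the eigenvalues of R. Powerful under mixed effect directions.
#'
#' @inheritParams sumTest
#' @return list with `Q`, `p`, and `method` used by the tail computation.
#' @export
squaredSumTest <- function(z, R) {
  lam <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  Q <- sum(z^2)
  pv <- quadFormPvalue(Q, lam)
  list(Q = Q, p = pv$p, method = pv$method)
}

# Eigenvalues of A_rho^{1/2} R A_rho^{1/2} for A_rho = (1-rho) I + rho J.
# A_rho^{1/2} has the closed form sqrt(1-rho) I + c J with
# c = (sqrt(1-rho+m*rho) - sqrt(1-rho)) / m.
rhoKernelEigen <- function(R, rho) {
  m <- nrow(R)
  a <- sqrt(1 - rho)
  cc <- (sqrt(1 - rho + m * rho) - a) / m
  rs <- rowSums(R)
  tot <- sum(rs)
  # B = (aI + cJ) R (aI + cJ) = a^2 R + a c (1 rs' + rs 1') + c^2 tot J
  B <- a^2 * R + a * cc * (outer(rep(1, m), rs) + outer(rs, rep(1, m))) +
    cc^2 * tot
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0)
}

# Square-root factor of R with diagonal jitter up to 1e-8 (Cholesky first,
# symmetric eigen square root as fallback).
sqrtFactor <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(R + diag(1e-8, nrow(R))), error = function(e) NULL)
  }
  if (!is.null(ch)) return(ch)
  es <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(es$values) < -1e-8) stop("R is not PSD beyond jitter tolerance")
  t(es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors)))
}

#' Adaptive minimum-p SNP-set test
#'
#' Scans the family Q_rho = (1-rho) Q + rho B^2 over a grid of rho in
#' [0, 1] (rho = 0 is the squared-sum test, rho = 1 the sum test), takes
#' the minimum per-rho p-value T, and computes the null probability that
#' the minimum is at most T for z ~ MVN(0, R). The default route is a
#' one-dimensional integration conditioning on the standardized burden
#' component u = 1'z / sqrt(1'R1), exact under the multivariate-normal
#' null: given u^2, the residual quadratic form is a non-central weighted
#' chi-square, and the joint survival is integrated over the 1-df density
#' of u^2. A Monte-Carlo estimator (square-root-factor MVN draws,
#' p-hat = (1 + #{T* <= T}) / (N + 1)) serves as cross-check and fallback
#' when integration diagnostics fail. Below T = 1e-4 the quantile and
#' survival evaluations use moment matching, and the result is clamped
#' into the Bonferroni/minimum-p sandwich [T, |grid| T].
#'
#' @inheritParams sumTest
#' @param rho_grid grid of rho values in [0, 1]; the default is quadratic,
#'   denser near 0 where the optimum typically lies.
#' @param method `"integration"` (default) or `"monte_carlo"`.
#' @param mc_draws Monte-Carlo sample size when used.
#' @param seed optional seed for the Monte-Carlo path.
#' @return list with `T` (minimum per-rho p), `p` (adaptive p-value),
#'   `p_rho` (per-rho p-values), `rho_grid`, `method` actually used
#'   (`"integration"` or `"monte_carlo"`), and `mc_draws` when relevant.
#' @export
adaptiveTest <- function(z, R,
                         rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25,
                                      0.36, 0.49, 0.64, 0.81, 1),
                         method = c("integration", "monte_carlo"),
                         mc_draws = 2e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(rho_grid >= 0), all(rho_grid <= 1))
  m <- length(z)
  R <- as.matrix(R)
  if (m == 1L) {
    # all statistics coincide for a single SNP
    p <- stats::pchisq(z^2 / R[1, 1], df = 1, lower.tail = FALSE)
    return(list(T = p, p = p, p_rho = rep(p, length(rho_grid)),
                rho_grid = rho_grid, method = "integration",
                mc_draws = NA_integer_))
  }
  Q <- sum(z^2)
  B <- sum(z)
  Qrho <- (1 - rho_grid) * Q + rho_grid * B^2
  lam_rho <- lapply(rho_grid, function(r) rhoKernelEigen(R, r))
  p_rho <- mapply(function(q, w) quadFormPvalue(q, w)$p, Qrho, lam_rho)
  Tmin <- min(p_rho)

  p_at <- NA_real_
  used <- method
  if (method == "integration") {
    p_at <- tryCatch(atIntegration(R, rho_grid, Tmin, lam_rho),
                     error = function(e) NA_real_)
    if (!is.finite(p_at) || p_at < 0 || p_at > 1 + 1e-6) {
      used <- "monte_carlo"
      warning("adaptive-test integration diagnostics failed; ",
              "falling back to Monte Carlo")
    }
  }
  if (used == "monte_carlo") {
    p_at <- atMonteCarlo(R, rho_grid, Tmin, lam_rho, mc_draws, seed)
  }
  # Bonferroni / min-p sandwich: the true adaptive p lies in [T, |grid| T]
  p_at <- min(max(p_at, Tmin), min(1, length(rho_grid) * Tmin))
  list(T = Tmin, p = p_at, p_rho = p_rho, rho_grid = rho_grid,
       method = used,
       mc_draws = if (used == "monte_carlo") as.integer(mc_draws) else NA_integer_)
}

# One-dimensional integration for the adaptive test, conditioning on the
# standardized burden u = 1'z / sqrt(1'R1), which is exact for
# z ~ MVN(0, R): with v = R1 and Sigma_e = R - v v' / (1'R1), the
# conditional law of z given u is Gaussian with mean v u / sqrt(1'R1) and
# covariance Sigma_e, so z'z | u^2 = x is a non-central weighted
# chi-square (weights eigen(Sigma_e), noncentralities proportional to x)
# plus the deterministic null-space shift. The event {T* > T} is
# {Q_rho < q_T(rho) for every rho}; for rho < 1 these are upper bounds on
# z'z, for rho = 1 a bound on x itself, and the joint survival integrates
# the conditional CDF at the binding bound over the 1-df density of x.
atIntegration <- function(R, rho_grid, Tmin, lam_rho = NULL) {
  m <- nrow(R)
  v <- as.vector(R %*% rep(1, m))
  s2 <- sum(v)
  if (s2 <= 0) stop("1'R1 <= 0")
  Sig_e <- R - outer(v, v) / s2
  es <- eigen((Sig_e + t(Sig_e)) / 2, symmetric = TRUE)
  lam_all <- pmax(es$values, 0)
  pos <- lam_all > 1e-10 * max(lam_all, 1)
  lam <- lam_all[pos]
  if (length(lam) == 0L) return(1)
  proj <- drop(crossprod(es$vectors, v))       # components of v in eigenbasis
  dcoef <- proj[pos]^2 / (s2 * lam)            # noncentrality per unit x
  shift_coef <- (sum(v^2) - sum(proj[pos]^2)) / s2  # null-space part per unit x

  # Deep in the tail the exact characteristic-function inversions are
  # expensive and the minimum-p region is governed by its Bonferroni
  # sandwich; moment-matched quantiles and survival curves are the
  # standard choice there and are used below 1e-4.
  far_tail <- Tmin < 1e-4
  is_burden <- rho_grid >= 1 - 1e-12
  qmin <- numeric(length(rho_grid))
  for (k in seq_along(rho_grid)) {
    qmin[k] <- if (is_burden[k]) {
      s2 * stats::qchisq(Tmin, df = 1, lower.tail = FALSE)
    } else {
      w_k <- if (is.null(lam_rho)) rhoKernelEigen(R, rho_grid[k]) else
        lam_rho[[k]]
      if (far_tail) liuQuantile(Tmin, w_k) else
        quadFormQuantile(Tmin, w_k, rel_tol = 1e-4, acc = 1e-7)
    }
  }
  xlim <- min(60, if (any(is_burden)) min(qmin[is_burden]) / s2 else Inf)
  if (xlim <= 0) return(1)
  rr <- rho_grid[!is_burden]
  qq <- qmin[!is_burden]

  G <- function(x) {
    # conditional probability that every rho < 1 constraint holds
    b <- min((qq - rr * s2 * x) / (1 - rr)) - shift_coef * x
    if (b <= 0) return(0)
    if (far_tail) return(1 - liuPvalueNC(b, lam, dcoef * x))
    1 - ncQuadFormSurvival(b, lam, dcoef * x, acc = 1e-6)
  }
  # G is smooth and monotone decreasing in x; tabulate + monotone spline
  nodes <- xlim * seq(0, 1, length.out = 21)^1.5
  Gvals <- vapply(nodes, G, numeric(1))
  Gvals <- rev(cummax(rev(pmin(pmax(Gvals, 0), 1))))
  Gspl <- stats::splinefun(nodes, Gvals, method = "hyman")
  integrand <- function(x) {
    pmin(pmax(Gspl(x), 0), 1) * stats::dchisq(x, df = 1)
  }
  int <- stats::integrate(integrand, 0, xlim, rel.tol = 1e-7,
                          abs.tol = 1e-10, subdivisions = 1000L)
  1 - int$value
}

# Monte-Carlo adaptive p: T* <= T iff some Q_rho exceeds the exact T-level
# quantile of its own null, so draws need no per-draw tail evaluations.
atMonteCarlo <- function(R, rho_grid, Tmin, lam_rho, n_draws, seed = NULL) {
  if (!is.null(seed)) {
    old_rng <- saveRNG()
    on.exit(restoreRNG(old_rng), add = TRUE)
    set.seed(seed)
  }
  thr <- vapply(lam_rho, function(w) quadFormQuantile(Tmin, w), numeric(1))
  ch <- sqrtFactor(R)
  m <- nrow(R)
  n_draws <- as.integer(n_draws)
  hits <- 0L
  block <- 50000L
  done <- 0L
  while (done < n_draws) {
    nb <- min(block, n_draws - done)
    zs <- matrix(stats::rnorm(nb * m), nb, m) %*% ch
    Q <- rowSums(zs^2)
    B <- rowSums(zs)
    any_hit <- rep(FALSE, nb)
    for (k in seq_along(rho_grid)) {
      any_hit <- any_hit |
        ((1 - rho_grid[k]) * Q + rho_grid[k] * B^2 >= thr[k])
    }
    hits <- hits + sum(any_hit)
    done <- done + nb
  }
  (1 + hits) / (n_draws + 1)
}

#' Bonferroni family-wise threshold
#'
#' @param alpha_fw family-wise error rate.
#' @param n_tests number of tests in the family.
#' @return per-test significance threshold `alpha_fw / n_tests`.
#' @export
bonferroniThreshold <- function(alpha_fw, n_tests) {
  stopifnot(alpha_fw > 0, alpha_fw < 1, n_tests >= 1)
  alpha_fw / n_tests
}

#' Genome-wide gene-based scan
#'
#' Runs the sum, squared-sum and adaptive tests for every gene set and
#' flags genes whose adaptive p-value falls under the Bonferroni threshold
#' alpha_fw / (number of genes tested), optionally overridden by a nominal
#' family size. Also emits a Manhattan-plot table (gene, chromosome,
#' midpoint position, -log10 p).
#'
#' @param gene_sets named list of [GeneSnpSet-class] objects (e.g. from
#'   [makeGeneSets()] or [readBundles()]).
#' @param alpha_fw family-wise error rate (default 0.05).
#' @param family_size optional nominal family size overriding the number
#'   of genes actually tested.
#' @param ... passed to [adaptiveTest()] (e.g. `rho_grid`, `method`).
#' @return list with `results` (data.frame: gene_id, chrom, m, B, Q, p_st,
#'   p_s2t, T, p_at, at_method, significant), `manhattan` (data.frame:
#'   gene_id, chrom, pos, neg_log10_p) and `threshold`.
#' @export
geneScan <- function(gene_sets, alpha_fw = 0.05, family_size = NULL, ...) {
  if (length(gene_sets) == 0L) stop("empty set of gene bundles")
  rows <- lapply(gene_sets, function(g) {
    z <- zScores(g)
    R <- ldMatrix(g)
    st <- sumTest(z, R)
    s2t <- squaredSumTest(z, R)
    at <- adaptiveTest(z, R, ...)
    data.frame(gene_id = geneId(g), chrom = g@chrom, m = nSnps(g),
               B = st$B, Q = s2t$Q, p_st = st$p, p_s2t = s2t$p,
               T = at$T, p_at = at$p, at_method = at$method,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  n_fam <- if (is.null(family_size)) nrow(results) else family_size
  threshold <- bonferroniThreshold(alpha_fw, n_fam)
  results$significant <- results$p_at < threshold
  mids <- vapply(gene_sets, function(g) {
    stats::median(range(snpInfo(g)$pos))
  }, numeric(1))
  manhattan <- data.frame(gene_id = results$gene_id, chrom = results$chrom,
                          pos = unname(mids[results$gene_id]),
                          neg_log10_p = -log10(results$p_at),
                          stringsAsFactors = FALSE)
  list(results = results, manhattan = manhattan, threshold = threshold)
}
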