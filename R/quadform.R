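#' Survival function of a weighted sum of 1-df chi-squares
#'
#' Computes P(sum_k w_k X_k > q) with X_k iid chi-square(1) — the
#' asymptotic null of quadratic forms z' A z in correlated Gaussians, with
#' weights the eigenvalues of the (kernel-weighted) LD matrix. The default
#' route is numerical inversion of the characteristic function (Imhof-type
#' oscillatory integral); when inversion fails to resolve the value, or
#' lands below `liu_floor` where cancellation dominates, a Liu-type
#' moment-matching approximation (matching skewness to a scaled
#' non-central chi-square) is used instead. When all weights are equal the
#' scaled chi-square closed form is exact and used directly.
#'
#' @param q non-negative quantile.
#' @param weights non-negative weights (eigenvalues); small negatives up to
#'   -1e-8 are clipped to 0, larger negatives are an error.
#' @param acc target absolute error of the inversion integral (default 1e-9).
#' @param liu_floor p-values below this from inversion are recomputed by
#'   moment matching, whose far tail is more stable (default 1e-12).
#' @return list with `p` (the survival probability, in (0, 1]) and
#'   `method`, one of `"exact"`, `"cf_inversion"`, `"moment_match"`.
#' @export
quadFormPvalue <- function(q, weights, acc = 1e-9, liu_floor = 1e-12) {
  if (!is.finite(q)) stop("q must be finite")
  if (min(weights) < -1e-8) stop("negative weight beyond tolerance")
  w <- pmax(weights, 0)
  w <- w[w > 0]
  if (length(w) == 0L) return(list(p = 1, method = "exact"))
  # relatively negligible components shift the distribution by O(1e-10 max)
  # but stretch the inversion's truncation range enormously; drop them
  w <- w[w > 1e-10 * max(w)]
  if (q <= 0) return(list(p = 1, method = "exact"))
  if (diff(range(w)) <= 1e-12 * max(w)) {
    # equal weights: exactly a scaled chi-square
    p <- stats::pchisq(q / w[1], df = length(w), lower.tail = FALSE)
    return(list(p = max(p, 1e-300), method = "exact"))
  }
  res <- imhofPvalue(q, w, acc = acc)
  if (!is.finite(res$p) || res$p <= 10 * res$err) {
    res <- imhofPvalue(q, w, acc = acc, grow = 4)
  }
  if (is.finite(res$p) && res$p > liu_floor && res$p > 10 * res$err &&
      res$p <= 1 + 1e-6) {
    list(p = min(res$p, 1), method = "cf_inversion")
  } else {
    list(p = liuPvalue(q, w), method = "moment_match")
  }
}

# Imhof's characteristic-function inversion for (possibly non-central)
# weighted chi-square sums:
#   P(Q > q) = 1/2 + (1/pi) Int_0^Inf sin(theta(u)) / (u rho(u)) du
#   theta(u) = 0.5 sum [atan(w_k u) + d_k w_k u / (1 + w_k^2 u^2)] - q u / 2
#   rho(u)   = prod (1 + w_k^2 u^2)^{1/4}
#              * exp(0.5 sum d_k w_k^2 u^2 / (1 + w_k^2 u^2))
# with d_k the noncentrality of the k-th 1-df component. The integrand is
# analytic with limit 0.5 (sum w_k (1 + d_k) - q) at u = 0, oscillates at
# frequency at most (q + sum w_k (1 + d_k))/2, and its amplitude decays
# like u^{-(1 + m/2)}; the alternating tail beyond a truncation point U is
# bounded by 8 g(U)/q for the central amplitude g, which also bounds the
# non-central case. A composite Simpson rule sized to the oscillation
# count evaluates it in one vectorized pass; halving the resolution on the
# same nodes provides the quadrature error estimate.
imhofPvalue <- function(q, w, acc = 1e-9, grow = 1, delta = 0) {
  central <- all(delta == 0)
  delta <- rep_len(delta, length(w))
  sw1 <- sum(w * (1 + delta))
  amp <- function(u) 1 / (u * exp(0.25 * sum(log1p(w^2 * u^2))))
  target <- pi * acc * q / 8
  U <- 4 / max(q, 1e-3)
  while (amp(U) > target && U < 1e6) U <- U * 1.6
  # keep at least 16 Simpson nodes per oscillation period within the node
  # budget; when that caps the truncation point the unresolved tail shows
  # up honestly in the returned error bound
  n_budget <- 2^16 * grow
  U <- min(U, (n_budget / 4) * 4 * pi / (q + sw1))
  periods <- U * (q + sw1) / (4 * pi)
  N <- 4L * max(64L, as.integer(ceiling(4 * periods))) + 1L
  u <- seq(0, U, length.out = N)
  uu <- u[-1]
  m <- length(w)
  wu <- outer(w, uu)
  wu2 <- wu * wu
  if (central) {
    theta <- 0.5 * .colSums(atan(wu), m, N - 1L) - 0.5 * q * uu
    lrho <- 0.25 * .colSums(log1p(wu2), m, N - 1L)
  } else {
    onep <- 1 + wu2
    theta <- 0.5 * (.colSums(atan(wu), m, N - 1L) +
                      .colSums(delta * wu / onep, m, N - 1L)) - 0.5 * q * uu
    lrho <- 0.25 * .colSums(log1p(wu2), m, N - 1L) +
      0.5 * .colSums(delta * wu2 / onep, m, N - 1L)
  }
  f <- c(0.5 * (sw1 - q), sin(theta) / (uu * exp(lrho)))
  simpson <- function(vals, h) {
    n <- length(vals)
    h / 3 * (vals[1] + vals[n] + 4 * sum(vals[seq(2, n - 1, 2)]) +
               2 * sum(vals[seq(3, n - 2, 2)]))
  }
  h <- U / (N - 1)
  S_fine <- simpson(f, h)
  S_coarse <- simpson(f[seq(1, N, 2)], 2 * h)
  err_quad <- abs(S_fine - S_coarse) / 15
  err_tail <- amp(U) * 8 / q
  list(p = 0.5 + S_fine / pi, err = (err_quad + err_tail) / pi)
}

# non-central survival with the same escalation/fallback policy as
# quadFormPvalue; clamped to [0, 1] for use as a distribution function
ncQuadFormSurvival <- function(q, w, delta, acc = 1e-8) {
  if (q <= 0) return(1)
  res <- imhofPvalue(q, w, acc = acc, delta = delta)
  if (!is.finite(res$p) || res$p <= 10 * res$err) {
    res <- imhofPvalue(q, w, acc = acc, grow = 4, delta = delta)
  }
  if (!is.finite(res$p) || res$p <= 10 * res$err) {
    res$p <- liuPvalueNC(q, w, delta)
  }
  min(max(res$p, 0), 1)
}

#' Liu moment-matching survival approximation
#'
#' Matches the first moments and skewness of the weighted chi-square sum to
#' a scaled non-central chi-square (Liu, Tang & Zhang 2009).
#'
#' @inheritParams quadFormPvalue
#' @return approximate survival probability.
#' @export
liuPvalue <- function(q, weights) {
  liuPvalueNC(q, weights, 0)
}

liuPvalueNC <- function(q, weights, delta) {
  w <- pmax(weights, 0)
  delta <- rep_len(delta, length(weights))[w > 0]
  w <- w[w > 0]
  c1 <- sum(w * (1 + delta))
  c2 <- sum(w^2 * (1 + 2 * delta))
  c3 <- sum(w^3 * (1 + 3 * delta))
  c4 <- sum(w^4 * (1 + 4 * delta))
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  muQ <- c1
  sigmaQ <- sqrt(2 * c2)
  tstar <- (q - muQ) / sigmaQ
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    a <- 1 / s1
    d <- 0
    l <- 1 / s1^2
  }
  muX <- l + d
  sigmaX <- sqrt(2) * a
  p <- stats::pchisq(tstar * sigmaX + muX, df = l, ncp = d,
                     lower.tail = FALSE)
  max(p, 1e-300)
}

# Liu-approximate upper quantile, used only to initialize the exact
# inversion in quadFormQuantile.
liuQuantile <- function(p_tail, weights) {
  w <- pmax(weights, 0)
  w <- w[w > 0]
  c1 <- sum(w); c2 <- sum(w^2); c3 <- sum(w^3); c4 <- sum(w^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    a <- 1 / s1
    d <- 0
    l <- 1 / s1^2
  }
  muX <- l + d
  sigmaX <- sqrt(2) * a
  x <- stats::qchisq(p_tail, df = l, ncp = d, lower.tail = FALSE)
  max((x - muX) / sigmaX * sqrt(2 * c2) + c1, 1e-12)
}

#' Exact upper quantile of a weighted chi-square sum
#'
#' Inverts [quadFormPvalue()]: returns q such that the survival
#' probability at q equals `p_tail`. A Liu moment-matching quantile seeds
#' a secant iteration on the log tail probability (the tail is close to
#' log-linear in q), with a bracketed bisection fallback.
#'
#' @param p_tail target tail probability in (0, 1).
#' @param weights non-negative weights.
#' @param rel_tol relative tolerance on the tail probability (default 1e-5).
#' @param acc inversion accuracy forwarded to [quadFormPvalue()].
#' @return the quantile.
#' @export
quadFormQuantile <- function(p_tail, weights, rel_tol = 1e-5, acc = 1e-9) {
  stopifnot(p_tail > 0, p_tail < 1)
  lp <- function(q) log(quadFormPvalue(q, weights, acc = acc)$p)
  ltarget <- log(p_tail)
  q0 <- liuQuantile(p_tail, weights)
  f0 <- lp(q0) - ltarget
  if (abs(f0) < rel_tol) return(q0)
  q1 <- q0 * if (f0 > 0) 1.1 else 0.9
  f1 <- lp(q1) - ltarget
  for (iter in 1:30) {
    if (abs(f1) < rel_tol) return(q1)
    if (f1 == f0) break
    q2 <- q1 - f1 * (q1 - q0) / (f1 - f0)
    if (!is.finite(q2) || q2 <= 0) break
    q0 <- q1; f0 <- f1
    q1 <- q2; f1 <- lp(q1) - ltarget
  }
  if (abs(f1) < 1e-3) return(q1)
  # bracketed fallback
  lo <- 1e-12
  hi <- sum(weights) + 10 * sqrt(2 * sum(weights^2))
  while (lp(hi) > ltarget) hi <- hi * 2
  stats::uniroot(function(q) lp(q) - ltarget, c(lo, hi), tol = 1e-10 * hi)$root
}
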