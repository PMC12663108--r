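# Independent oracles used to check the implementation. Each one is a
# deliberately naive, separately-coded route to the same quantity.

# forward transverse Mercator (Airy 1830, OSGB constants): lat/lon in
# degrees -> easting/northing. Standard forward series, coded
# independently of the package's inverse.
oracleOsgbForward <- function(lat_deg, lon_deg) {
  a <- 6377563.396; b <- 6356256.909; F0 <- 0.9996012717
  lat0 <- 49 * pi / 180; lon0 <- -2 * pi / 180
  E0 <- 400000; N0 <- -100000
  e2 <- 1 - (b / a)^2
  n <- (a - b) / (a + b)
  phi <- lat_deg * pi / 180; lam <- lon_deg * pi / 180
  sp <- sin(phi); cp <- cos(phi); tp <- tan(phi)
  nu <- a * F0 / sqrt(1 - e2 * sp^2)
  rho <- a * F0 * (1 - e2) * (1 - e2 * sp^2)^(-1.5)
  eta2 <- nu / rho - 1
  M <- b * F0 * (
    (1 + n + 5 / 4 * n^2 + 5 / 4 * n^3) * (phi - lat0) -
    (3 * n + 3 * n^2 + 21 / 8 * n^3) * sin(phi - lat0) * cos(phi + lat0) +
    (15 / 8 * n^2 + 15 / 8 * n^3) * sin(2 * (phi - lat0)) *
      cos(2 * (phi + lat0)) -
    (35 / 24 * n^3) * sin(3 * (phi - lat0)) * cos(3 * (phi + lat0)))
  I <- M + N0
  II <- nu / 2 * sp * cp
  III <- nu / 24 * sp * cp^3 * (5 - tp^2 + 9 * eta2)
  IIIA <- nu / 720 * sp * cp^5 * (61 - 58 * tp^2 + tp^4)
  IV <- nu * cp
  V <- nu / 6 * cp^3 * (nu / rho - tp^2)
  VI <- nu / 120 * cp^5 * (5 - 18 * tp^2 + tp^4 + 14 * eta2 -
                             58 * tp^2 * eta2)
  dl <- lam - lon0
  data.frame(
    easting = E0 + IV * dl + V * dl^3 + VI * dl^5,
    northing = I + II * dl^2 + III * dl^4 + IIIA * dl^6
  )
}

# Hardy-Weinberg exact test by full enumeration with explicit binomial
# coefficients (double precision; fine for the count ranges used here).
oracleHwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  n_minor <- 2 * min(nAA, naa) + nAa
  hs <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  pr <- vapply(hs, function(h) {
    na <- (n_minor - h) / 2
    nA <- n - h - na
    # multinomial count of genotype configurations x 2^h, normalized below
    exp(lgamma(n + 1) - lgamma(nA + 1) - lgamma(h + 1) - lgamma(na + 1) +
          h * log(2))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hs)] * (1 + 1e-12)])
}

# naive full-design least squares with model-based and HC2 covariance
oracleFitVariant <- function(g, E, y, C) {
  X1 <- cbind(1, C, g)                 # marginal model
  b1 <- solve(t(X1) %*% X1, t(X1) %*% y)
  r1 <- y - X1 %*% b1
  s2_1 <- sum(r1^2) / (nrow(X1) - ncol(X1))
  V1 <- s2_1 * solve(t(X1) %*% X1)
  X2 <- cbind(1, C, g, g * E)          # interaction model
  b2 <- solve(t(X2) %*% X2, t(X2) %*% y)
  r2 <- y - X2 %*% b2
  s2_2 <- sum(r2^2) / (nrow(X2) - ncol(X2))
  XtXi <- solve(t(X2) %*% X2)
  Vmod <- s2_2 * XtXi
  hat <- rowSums((X2 %*% XtXi) * X2)
  meat <- t(X2) %*% (X2 * as.vector(r2)^2 / (1 - hat))
  Vrob <- XtXi %*% meat %*% XtXi
  k <- ncol(X2)
  list(
    beta_marginal = b1[ncol(X1)], se_marginal = sqrt(V1[ncol(X1), ncol(X1)]),
    beta_g = b2[k - 1], beta_gxe = b2[k],
    se_g_model = sqrt(Vmod[k - 1, k - 1]), se_gxe_model = sqrt(Vmod[k, k]),
    cov_g_gxe_model = Vmod[k - 1, k],
    se_g_robust = sqrt(Vrob[k - 1, k - 1]), se_gxe_robust = sqrt(Vrob[k, k]),
    cov_g_gxe_robust = Vrob[k - 1, k]
  )
}

# exhaustive greedy clumping oracle on a precomputed r2 matrix
oracleClump <- function(p, r2mat, p_threshold, r2_threshold) {
  sig <- which(p < p_threshold)
  sig <- sig[order(p[sig])]
  leads <- integer()
  while (length(sig)) {
    leads <- c(leads, sig[1])
    keepers <- c()
    for (s in sig[-1])
      if (r2mat[sig[1], s] < r2_threshold) keepers <- c(keepers, s)
    sig <- keepers
  }
  leads
}

# two-sided exact binomial p at p0 = 0.5 by direct enumeration
oracleBinomTwoSided <- function(k, n) {
  pr <- choose(n, 0:n) / 2^n
  min(1, sum(pr[pr <= pr[k + 1] * (1 + 1e-9)]))
}
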