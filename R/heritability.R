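## LD score computation and LD score regression: univariate
## SNP-heritability, bivariate genetic correlation, and
## exposure-stratified heritability.
##
## Under a polygenic model, E[chi2_j] = 1 + (N h2 / M) * l_j (+ an
## intercept excess for confounding), where l_j is variant j's LD score.
## The slope of a weighted regression of chi2 on l therefore estimates
## h2 * N / M; uncertainty comes from a delete-one block jackknife over
## contiguous variant blocks.

#' In-sample LD scores
#'
#' \code{l_j} is the sum of bias-adjusted squared correlations
#' \code{r2 - (1 - r2)/(n - 2)} between variant j and all
#' same-chromosome variants within \code{window_variants} positions of
#' it (the self term, exactly 1, included). The adjustment makes
#' cross-terms of independent variants average zero, so independent
#' variants have expected score 1.
#'
#' @param g a \linkS4class{GenotypeData} with at least 50 samples.
#' @param window_variants flanking window size in variant count
#'   (default 200).
#' @return data.frame with \code{id} and \code{ldscore}, plus attributes
#'   \code{window_variants} and \code{n_ld}.
#' @export
computeLdScores <- function(g, window_variants = 200) {
  if (window_variants < 1) stop("window_variants must be >= 1")
  n <- nSamples(g)
  if (n < 50) stop("need at least 50 samples for LD scores")
  D <- dosage(g)
  vi <- variantInfo(g)
  m <- ncol(D)
  S <- scale(D)
  S[is.na(S)] <- 0
  sdev <- attr(S, "scaled:scale")
  ell <- rep(NA_real_, m)
  for (chr in unique(as.character(vi$chrom))) {
    jj <- which(as.character(vi$chrom) == chr)
    mc <- length(jj)
    ellc <- numeric(mc)
    chunk <- 512L
    for (a in seq(1, mc, by = chunk)) {
      bl <- a:min(a + chunk - 1L, mc)
      lo <- max(1L, min(bl) - window_variants)
      hi <- min(mc, max(bl) + window_variants)
      R <- crossprod(S[, jj[bl], drop = FALSE],
                     S[, jj[lo:hi], drop = FALSE]) / (n - 1)
      r2 <- R^2
      adj <- r2 - (1 - r2) / (n - 2)
      ## mask to the window around each focal variant
      off <- outer(bl, lo:hi, function(x, y) abs(x - y))
      adj[off > window_variants] <- 0
      ellc[bl] <- rowSums(adj)
    }
    ellc[sdev[jj] == 0] <- NA
    ell[jj] <- ellc
  }
  out <- data.frame(id = vi$id, ldscore = ell)
  attr(out, "window_variants") <- window_variants
  attr(out, "n_ld") <- n
  out
}

## weighted LS of y on x with intercept; returns c(intercept, slope)
.wls <- function(x, y, w) {
  sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sl <- sum(w * (x - mx) * (y - my)) / sum(w * (x - mx)^2)
  c(my - sl * mx, sl)
}

## two-step LDSC fit: heteroskedasticity weights 1/max(l,1), then
## reweight by the implied E[chi2]^2 and refit. Returns c(int, slope).
.ldscFit <- function(ell, y, n_eff, m) {
  w <- 1 / pmax(ell, 1)
  f1 <- .wls(ell, y, w)
  h1 <- max(f1[2], 0) * m / n_eff
  w2 <- 1 / (pmax(ell, 1) * (1 + n_eff * h1 * ell / m)^2)
  .wls(ell, y, w2)
}

#' SNP-heritability by LD score regression
#'
#' Regresses per-variant chi-square statistics on LD scores with a free
#' intercept, converts the slope to h2 via M/N, and estimates standard
#' errors by a delete-one block jackknife over \code{n_blocks}
#' contiguous variant blocks. Weights are the standard
#' heteroskedasticity weights \code{1/max(l, 1)} with one re-weighting
#' pass using the implied expected chi-square.
#'
#' @param chi2 per-variant chi-square statistics (typically
#'   \code{(beta_marginal/se_marginal)^2}), aligned with \code{ld}.
#' @param ld a \code{\link{computeLdScores}} table (or a numeric vector
#'   of LD scores).
#' @param n_gwas GWAS sample size.
#' @param m number of variants the heritability is spread over
#'   (defaults to \code{length(chi2)}).
#' @param n_blocks jackknife blocks (default 20).
#' @return a list of class \code{"LdscEstimate"}: \code{h2},
#'   \code{se_h2}, \code{intercept}, \code{se_intercept},
#'   \code{n_blocks}, \code{m}, \code{n_gwas}.
#' @export
ldscH2 <- function(chi2, ld, n_gwas, m = length(chi2), n_blocks = 20) {
  ell <- if (is.data.frame(ld)) ld$ldscore else ld
  ok <- is.finite(chi2) & is.finite(ell)
  chi2 <- chi2[ok]; ell <- ell[ok]
  mm <- length(chi2)
  if (mm < 10 * n_blocks)
    stop("too few variants (", mm, ") for ", n_blocks, " jackknife blocks")
  if (sd(ell) == 0) stop("LD scores are constant; slope not identifiable")
  full <- .ldscFit(ell, chi2, n_gwas, m)
  blk <- as.integer(cut(seq_len(mm), n_blocks))
  theta <- matrix(NA_real_, n_blocks, 2)
  for (b in seq_len(n_blocks)) {
    keep <- blk != b
    theta[b, ] <- .ldscFit(ell[keep], chi2[keep], n_gwas, m)
  }
  jk_se <- sqrt((n_blocks - 1) / n_blocks *
                  colSums(sweep(theta, 2, colMeans(theta))^2))
  structure(list(
    h2 = full[2] * m / n_gwas,
    se_h2 = jk_se[2] * m / n_gwas,
    intercept = full[1], se_intercept = jk_se[1],
    n_blocks = n_blocks, m = m, n_gwas = n_gwas
  ), class = "LdscEstimate")
}

#' @export
print.LdscEstimate <- function(x, ...) {
  cat(sprintf("LDSC: h2 = %.4f (se %.4f), intercept = %.3f (se %.3f); M = %d, N = %d\n",
              x$h2, x$se_h2, x$intercept, x$se_intercept, x$m, x$n_gwas))
  invisible(x)
}

#' Genetic correlation by bivariate LD score regression
#'
#' Regresses the z-score products of two traits on LD scores to
#' estimate their genetic covariance, divides by the geometric mean of
#' the univariate heritabilities, and jackknifes the whole pipeline over
#' contiguous variant blocks.
#'
#' @param z1,z2 per-variant z-scores (\code{beta/se}) of the two traits,
#'   aligned with \code{ld}.
#' @param ld LD score table or vector.
#' @param n1,n2 the two GWAS sample sizes.
#' @param m variant count (default \code{length(z1)}).
#' @param n_blocks jackknife blocks (default 20).
#' @return a list of class \code{"CrossTraitEstimate"}: \code{rg},
#'   \code{se_rg}, \code{gcov}, \code{gcov_intercept}, \code{h2_1},
#'   \code{h2_2}. Estimates beyond |1| are tolerated (flagged beyond
#'   1.25).
#' @export
ldscRg <- function(z1, z2, ld, n1, n2, m = length(z1), n_blocks = 20) {
  ell <- if (is.data.frame(ld)) ld$ldscore else ld
  ok <- is.finite(z1) & is.finite(z2) & is.finite(ell)
  z1 <- z1[ok]; z2 <- z2[ok]; ell <- ell[ok]
  mm <- length(z1)
  rg_of <- function(keep) {
    f1 <- .ldscFit(ell[keep], z1[keep]^2, n1, m)
    f2 <- .ldscFit(ell[keep], z2[keep]^2, n2, m)
    h1 <- f1[2] * m / n1; h2 <- f2[2] * m / n2
    fc <- .ldscFit(ell[keep], (z1 * z2)[keep], sqrt(n1 * n2), m)
    gcov <- fc[2] * m / sqrt(n1 * n2)
    c(h1 = h1, h2 = h2, gcov = gcov, gint = fc[1],
      rg = gcov / sqrt(h1 * h2))
  }
  full <- rg_of(rep(TRUE, mm))
  if (!is.finite(full["rg"]))
    stop("undefined genetic correlation: a heritability estimate is <= 0")
  blk <- as.integer(cut(seq_len(mm), n_blocks))
  th <- vapply(seq_len(n_blocks), function(b) rg_of(blk != b)["rg"],
               numeric(1))
  th <- th[is.finite(th)]
  se <- sqrt((length(th) - 1) / length(th) * sum((th - mean(th))^2))
  if (abs(full["rg"]) > 1.25)
    warning("genetic correlation estimate beyond 1.25: ",
            round(full["rg"], 3))
  structure(list(
    rg = unname(full["rg"]), se_rg = se, gcov = unname(full["gcov"]),
    gcov_intercept = unname(full["gint"]),
    h2_1 = unname(full["h1"]), h2_2 = unname(full["h2"]),
    n_blocks = n_blocks
  ), class = "CrossTraitEstimate")
}

#' @export
print.CrossTraitEstimate <- function(x, ...) {
  cat(sprintf("LDSC rg = %.3f (se %.3f); gcov = %.4g; h2 = %.3f / %.3f\n",
              x$rg, x$se_rg, x$gcov, x$h2_1, x$h2_2))
  invisible(x)
}

#' Exposure-stratified SNP-heritability
#'
#' Runs a marginal scan per stratum (phenotype re-standardized within
#' stratum), converts marginal statistics to chi-square and estimates
#' per-stratum heritability by \code{\link{ldscH2}} with the
#' stratum-specific sample size. LD scores are computed once from the
#' full genotype panel unless supplied.
#'
#' @inheritParams runStratified
#' @param ld optional precomputed \code{\link{computeLdScores}} table.
#' @param n_blocks jackknife blocks per stratum.
#' @param window_variants LD score window when \code{ld} is NULL.
#' @return data.frame with one row per stratum: \code{stratum},
#'   \code{n}, \code{h2}, \code{se}, \code{intercept}.
#' @export
stratifiedH2 <- function(g, cohort, spec = modelSpec(), strata,
                         ld = NULL, n_blocks = 20, min_stratum = 50,
                         window_variants = 200) {
  if (is.null(ld)) ld <- computeLdScores(g, window_variants)
  runs <- runStratified(g, cohort, spec, strata, min_stratum = min_stratum)
  out <- lapply(names(runs), function(lab) {
    r <- runs[[lab]]
    chi2 <- (r$beta_marginal / r$se_marginal)^2
    est <- ldscH2(chi2, ld$ldscore[match(r$variant_id, ld$id)],
                  n_gwas = attr(r, "n_stratum"), m = nrow(r),
                  n_blocks = n_blocks)
    data.frame(stratum = lab, n = attr(r, "n_stratum"),
               h2 = est$h2, se = est$se_h2, intercept = est$intercept)
  })
  do.call(rbind, out)
}
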