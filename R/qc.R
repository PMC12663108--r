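## Variant- and sample-level genotype quality control: missingness, minor
## allele frequency, Hardy-Weinberg exact test, imputation info score,
## heterozygosity outliers and KING-robust kinship pruning.

#' QC thresholds
#'
#' @param max_missing maximum missing fraction, applied to both variants
#'   and samples (default 0.02).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param min_hwe_p minimum Hardy-Weinberg exact-test p-value
#'   (default 1e-6).
#' @param min_info minimum imputation info score (default 0.8; variants
#'   with no info score pass this filter).
#' @param kinship_max KING-robust kinship at or above which one member of
#'   a pair is removed (default 0.0884, second-degree relatives).
#' @param het_sd heterozygosity-rate outlier cutoff in standard
#'   deviations from the cohort mean (default 6).
#' @return a list with class \code{"QcThresholds"}.
#' @export
qcThresholds <- function(max_missing = 0.02, min_maf = 0.01,
                         min_hwe_p = 1e-6, min_info = 0.8,
                         kinship_max = 0.0884, het_sd = 6) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 0.5,
            min_hwe_p >= 0, min_hwe_p <= 1,
            min_info >= 0, min_info <= 1,
            kinship_max > 0, het_sd > 0)
  structure(list(max_missing = max_missing, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, min_info = min_info,
                 kinship_max = kinship_max, het_sd = het_sd),
            class = "QcThresholds")
}

#' Hard genotype calls from dosages
#'
#' Rounds dosages to 0/1/2; dosages in (0.1, 0.9) or (1.1, 1.9) are too
#' uncertain to call and become \code{NA}. Hard calls are used for the
#' Hardy-Weinberg test, heterozygosity rates and KING kinship.
#'
#' @param d numeric vector or matrix of dosages in [0, 2].
#' @return integer vector/matrix of calls in \{0, 1, 2\} or \code{NA}.
#' @export
hardCalls <- function(d) {
  r <- round(d)
  r[abs(d - r) > 0.1] <- NA
  r
}

#' Hardy-Weinberg exact test
#'
#' Exact test conditioning on the minor-allele count: with allele counts
#' fixed, the probability of h heterozygotes is proportional to
#' \code{n! / (n_AA! h! n_aa!) * 2^h}; the p-value is the sum of
#' probabilities of all admissible heterozygote counts whose probability
#' does not exceed that of the observed count (standard, not mid-p).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return the exact p-value in (0, 1].
#' @examples
#' hweExactTest(99, 0, 1)  # 100/19900
#' @export
hweExactTest <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  n_minor <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  ## admissible heterozygote counts share the parity of the minor count
  h <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  ## log probability up to a constant: -log(nAA! h! naa!) + h log 2
  naa <- (n_minor - h) / 2
  nAA <- n - h - naa
  logp <- h * log(2) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- match(n_het, h)
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' KING-robust kinship coefficient
#'
#' Between-family estimator computed on shared non-missing hard calls:
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{2 N^{min}_{Aa}}
#'   + \frac12 - \frac{N^{(i)}_{Aa} + N^{(j)}_{Aa}}{4 N^{min}_{Aa}}}
#' where \eqn{N_{Aa,Aa}} counts sites heterozygous in both samples,
#' \eqn{N_{AA,aa}} opposite-homozygote sites, and
#' \eqn{N^{min}_{Aa}} the smaller of the two per-sample heterozygote
#' counts (over shared non-missing sites). A duplicate pair gives exactly
#' 0.5; unrelated samples about 0; parent-offspring about 0.25.
#'
#' @param gi,gj hard-call genotype vectors (0/1/2/NA) of equal length.
#' @param min_shared minimum shared non-missing sites (default 100).
#' @return the kinship estimate, or \code{NA} with a warning when neither
#'   sample has a heterozygous site among shared calls.
#' @export
kingKinship <- function(gi, gj, min_shared = 100) {
  stopifnot(length(gi) == length(gj))
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < min_shared)
    stop("fewer than ", min_shared, " shared non-missing sites")
  gi <- gi[ok]; gj <- gj[ok]
  n_het_i <- sum(gi == 1); n_het_j <- sum(gj == 1)
  n_min <- min(n_het_i, n_het_j)
  if (n_min == 0) {
    warning("no shared heterozygous sites; kinship undefined")
    return(NA_real_)
  }
  n_hh <- sum(gi == 1 & gj == 1)
  n_opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  (n_hh - 2 * n_opp) / (2 * n_min) + 0.5 -
    (n_het_i + n_het_j) / (4 * n_min)
}

## all-pairs KING on a hard-call matrix (samples x variants), by
## indicator-matrix products; returns a symmetric kinship matrix.
.kingMatrix <- function(H) {
  n <- nrow(H)
  M <- (!is.na(H)) * 1
  A <- (H == 1); A[is.na(A)] <- FALSE; A <- A * 1
  B0 <- (H == 0); B0[is.na(B0)] <- FALSE; B0 <- B0 * 1
  B2 <- (H == 2); B2[is.na(B2)] <- FALSE; B2 <- B2 * 1
  n_hh <- tcrossprod(A)
  n_opp <- tcrossprod(B0, B2) + tcrossprod(B2, B0)
  het_i <- tcrossprod(A, M)  # [i,j] = hets of i among shared sites with j
  n_min <- pmin(het_i, t(het_i))
  phi <- (n_hh - 2 * n_opp) / (2 * n_min) + 0.5 -
    (het_i + t(het_i)) / (4 * n_min)
  phi[n_min == 0] <- NA
  diag(phi) <- NA
  phi
}

#' Variant-level QC
#'
#' Filters are applied in the order info score, missingness, MAF, HWE;
#' the reason recorded is the first failing filter. MAF is the minor
#' allele frequency from mean dosage / 2; the HWE exact test runs on
#' hard calls.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param thresholds a \code{\link{qcThresholds}}.
#' @return data.frame with \code{id}, \code{keep} and \code{reason}
#'   (\code{NA} for kept variants).
#' @export
variantQc <- function(g, thresholds = qcThresholds()) {
  d <- dosage(g)
  vi <- variantInfo(g)
  m <- ncol(d)
  reason <- rep(NA_character_, m)
  info <- vi$info_score
  fail_info <- !is.na(info) & info < thresholds$min_info
  reason[fail_info] <- "info"
  missfrac <- colMeans(is.na(d))
  fail_miss <- is.na(reason) & missfrac > thresholds$max_missing
  reason[fail_miss] <- "missingness"
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- is.na(reason) & (is.nan(maf) | maf < thresholds$min_maf)
  reason[fail_maf] <- "maf"
  H <- hardCalls(d)
  for (j in which(is.na(reason))) {
    h <- H[, j]
    p <- hweExactTest(sum(h == 0, na.rm = TRUE), sum(h == 1, na.rm = TRUE),
                      sum(h == 2, na.rm = TRUE))
    if (p < thresholds$min_hwe_p) reason[j] <- "hwe"
  }
  data.frame(id = vi$id, keep = is.na(reason), reason = reason)
}

#' Sample-level QC
#'
#' Drops samples in three passes: (1) missingness above
#' \code{max_missing}; (2) heterozygosity-rate outliers more than
#' \code{het_sd} standard deviations from the mean of the samples
#' retained after pass 1; (3) for each remaining pair with KING kinship
#' at or above \code{kinship_max}, the member with the higher missingness
#' (ties: the later sample) is removed, greedily from the most related
#' pair down.
#'
#' @inheritParams variantQc
#' @param min_shared minimum shared sites for a kinship estimate.
#' @return data.frame with \code{id}, \code{keep}, \code{reason}.
#' @export
sampleQc <- function(g, thresholds = qcThresholds(), min_shared = 50) {
  d <- dosage(g)
  n <- nrow(d)
  if (n < 3) stop("sample QC requires at least 3 samples")
  ids <- sampleIds(g)
  reason <- rep(NA_character_, n)
  missfrac <- rowMeans(is.na(d))
  reason[missfrac > thresholds$max_missing] <- "missingness"
  H <- hardCalls(d)
  het <- rowSums(H == 1, na.rm = TRUE) / pmax(rowSums(!is.na(H)), 1)
  keep1 <- is.na(reason)
  mu <- mean(het[keep1]); s <- sd(het[keep1])
  if (is.finite(s) && s > 0) {
    out <- keep1 & abs(het - mu) > thresholds$het_sd * s
    reason[out] <- "heterozygosity"
  }
  alive <- which(is.na(reason))
  if (length(alive) >= 2) {
    phi <- .kingMatrix(H[alive, , drop = FALSE])
    shared <- tcrossprod((!is.na(H[alive, , drop = FALSE])) * 1)
    phi[shared < min_shared] <- NA
    repeat {
      mx <- suppressWarnings(max(phi, na.rm = TRUE))
      if (!is.finite(mx) || mx < thresholds$kinship_max) break
      ij <- which(phi == mx, arr.ind = TRUE)[1, ]
      a <- alive[ij[1]]; b <- alive[ij[2]]
      drop_local <- if (missfrac[a] > missfrac[b]) ij[1]
        else if (missfrac[b] > missfrac[a]) ij[2]
        else max(ij)  # tie: later sample order
      reason[alive[drop_local]] <- "kinship"
      phi[drop_local, ] <- NA; phi[, drop_local] <- NA
    }
  }
  data.frame(id = ids, keep = is.na(reason), reason = reason)
}

#' Apply full QC
#'
#' Runs sample QC, then variant QC on the retained samples, and returns
#' the filtered genotypes plus a report of removal counts per reason.
#' The procedure is deterministic and idempotent.
#'
#' @inheritParams variantQc
#' @param min_shared minimum shared sites for kinship estimates.
#' @return list with \code{genotypes} (filtered
#'   \linkS4class{GenotypeData}) and \code{report} (a list of removal
#'   counts and retained dimensions, class \code{"QcReport"}).
#' @export
applyQc <- function(g, thresholds = qcThresholds(), min_shared = 50) {
  sq <- sampleQc(g, thresholds, min_shared = min_shared)
  if (!any(sq$keep)) stop("all samples removed by QC")
  g2 <- g[sq$keep, ]
  vq <- variantQc(g2, thresholds)
  if (!any(vq$keep)) stop("all variants removed by QC")
  g3 <- g2[, vq$keep]
  count <- function(tab, what) sum(tab$reason == what, na.rm = TRUE)
  report <- structure(list(
    samples_in = nSamples(g), variants_in = nVariants(g),
    samples_removed = c(missingness = count(sq, "missingness"),
                        heterozygosity = count(sq, "heterozygosity"),
                        kinship = count(sq, "kinship")),
    variants_removed = c(info = count(vq, "info"),
                         missingness = count(vq, "missingness"),
                         maf = count(vq, "maf"),
                         hwe = count(vq, "hwe")),
    samples_kept = nSamples(g3), variants_kept = nVariants(g3),
    sample_table = sq, variant_table = vq
  ), class = "QcReport")
  list(genotypes = g3, report = report)
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QC report: %d/%d samples, %d/%d variants retained\n",
              x$samples_kept, x$samples_in, x$variants_kept, x$variants_in))
  cat("samples removed: ",
      paste(names(x$samples_removed), x$samples_removed,
            sep = "=", collapse = ", "), "\n")
  cat("variants removed:",
      paste(names(x$variants_removed), x$variants_removed,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
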