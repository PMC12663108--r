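## Post-GWAS: independent-variant selection (LD clumping and stepwise
## conditional regression), variance explained, replication statistics and
## genetic risk scores.

#' Greedy LD clumping of significant variants
#'
#' Sorts significant variants by ascending p (ties by chromosome, then
#' position), repeatedly takes the best remaining variant as a lead and
#' removes all remaining variants with squared dosage correlation
#' \code{>= r2_threshold} to it.
#'
#' @param results a \code{\link{runGweis}} result table.
#' @param ld_source a \linkS4class{GenotypeData} covering all significant
#'   variants (used only for LD).
#' @param p_field which p-value column to clump on (default
#'   \code{"p_joint"}).
#' @param p_threshold significance threshold (default 5e-8).
#' @param r2_threshold LD pruning threshold (default 0.1).
#' @return data.frame of lead variants (\code{variant_id}, \code{p}) with
#'   attributes \code{p_field} and \code{r2_threshold}; zero rows when
#'   nothing is significant.
#' @export
clumpLeads <- function(results, ld_source, p_field = "p_joint",
                       p_threshold = 5e-8, r2_threshold = 0.1) {
  p <- results[[p_field]]
  sig <- which(!is.na(p) & p < p_threshold)
  out <- data.frame(variant_id = character(), p = numeric())
  if (length(sig)) {
    ord <- sig[order(p[sig], results$chromosome[sig],
                     results$base_pair_location[sig])]
    ids <- results$variant_id[ord]
    vidx <- match(ids, variantInfo(ld_source)$id)
    if (anyNA(vidx))
      stop("ld_source lacks variants: ",
           paste(head(ids[is.na(vidx)], 5), collapse = ", "))
    D <- dosage(ld_source)[, vidx, drop = FALSE]
    remaining <- seq_along(ids)
    leads <- integer()
    while (length(remaining)) {
      lead <- remaining[1]
      leads <- c(leads, lead)
      remaining <- remaining[-1]
      if (length(remaining)) {
        r2 <- suppressWarnings(
          cor(D[, lead], D[, remaining, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        r2[is.na(r2)] <- 0
        remaining <- remaining[r2 < r2_threshold]
      }
    }
    out <- data.frame(variant_id = ids[leads], p = p[ord][leads])
  }
  attr(out, "p_field") <- p_field
  attr(out, "r2_threshold") <- r2_threshold
  out
}

#' Stepwise conditional variant selection
#'
#' Forward selection on individual-level data: at each step the
#' candidate with the smallest conditional p-value (marginal model with
#' all previously selected variants as extra covariates) is added while
#' that p-value is below \code{p_threshold}; after each addition, any
#' selected variant whose p-value in the joint fit rises above the
#' threshold is dropped. Candidates with LD r^2 above
#' \code{collinearity_r2} to any selected variant are skipped, and only
#' candidates on the same chromosome within \code{window_bp} of a
#' selected variant are treated as in LD with it.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param cohort cohort data.frame (see \code{\link{runGweis}}).
#' @param spec a \code{\link{modelSpec}}.
#' @param p_threshold selection threshold (default 5e-8).
#' @param window_bp LD window in base pairs (default 1e7).
#' @param collinearity_r2 candidates above this r^2 with a selected
#'   variant are never added (default 0.9).
#' @param max_steps safety cap on selected variants.
#' @return data.frame of selected variants with joint-model \code{beta},
#'   \code{se} and conditional \code{p} from the final joint fit; zero
#'   rows when nothing is significant.
#' @export
stepwiseConditionalSelection <- function(g, cohort, spec = modelSpec(),
                                         p_threshold = 5e-8,
                                         window_bp = 1e7,
                                         collinearity_r2 = 0.9,
                                         max_steps = 100) {
  ids <- sampleIds(g)
  idx <- match(ids, cohort$participant_id)
  if (anyNA(idx)) stop("cohort is missing participants")
  cohort <- cohort[idx, , drop = FALSE]
  n <- nrow(cohort)
  cb <- .covariateBasis(cohort, spec)
  y <- cohort$pheno_std
  D <- dosage(g)
  D[is.na(D)] <- 0  # replaced below by column means
  for (j in seq_len(ncol(D))) {
    gj <- dosage(g)[, j]
    if (anyNA(gj)) D[, j] <- ifelse(is.na(gj), mean(gj, na.rm = TRUE), gj)
  }
  vi <- variantInfo(g)
  selected <- integer()

  cond_fit <- function(sel) {
    ## joint fit of selected variants + covariates; returns beta/se/p
    X <- cbind(cb$Q, scale(D[, sel, drop = FALSE], scale = FALSE))
    qx <- qr(X)
    b <- qr.coef(qx, y)
    r <- qr.resid(qx, y)
    sig2 <- sum(r^2) / (n - qx$rank)
    unpiv <- order(qx$pivot)
    XtXinv <- chol2inv(qr.R(qx))[unpiv, unpiv, drop = FALSE]
    k <- length(sel)
    take <- ncol(cb$Q) + seq_len(k)
    se <- sqrt(sig2 * diag(XtXinv)[take])
    beta <- b[take]
    pv <- pchisq((beta / se)^2, 1, lower.tail = FALSE)
    list(beta = beta, se = se, p = pv)
  }

  for (step in seq_len(max_steps)) {
    ## residualize y and candidates on covariates + selected
    Xsel <- cbind(cb$Q, scale(D[, selected, drop = FALSE], scale = FALSE))
    qs <- qr(Xsel)
    yt <- qr.resid(qs, y)
    cand <- setdiff(seq_len(ncol(D)), selected)
    if (length(selected)) {
      drop_cand <- logical(length(cand))
      for (s in selected) {
        same <- vi$chrom[cand] == vi$chrom[s] &
          abs(vi$pos[cand] - vi$pos[s]) <= window_bp
        if (any(same)) {
          r2 <- suppressWarnings(
            cor(D[, s], D[, cand[same], drop = FALSE]))^2
          r2[is.na(r2)] <- 1
          drop_cand[same][r2 > collinearity_r2] <- TRUE
        }
      }
      cand <- cand[!drop_cand]
    }
    if (!length(cand)) break
    Gt <- qr.resid(qs, D[, cand, drop = FALSE])
    gg <- colSums(Gt^2)
    ok <- gg > n * 1e-12
    if (!any(ok)) break
    bj <- colSums(Gt * yt) / gg
    dfree <- n - qs$rank - 1
    sig2 <- (sum(yt^2) - bj^2 * gg) / dfree
    pj <- pchisq(bj^2 * gg / sig2, 1, lower.tail = FALSE)
    pj[!ok] <- 1
    best <- which.min(pj)
    if (pj[best] >= p_threshold) break
    selected <- c(selected, cand[best])
    ## backward pass
    repeat {
      if (length(selected) < 2) break
      f <- cond_fit(selected)
      worst <- which.max(f$p)
      if (f$p[worst] < p_threshold) break
      selected <- selected[-worst]
    }
  }
  if (!length(selected))
    return(data.frame(variant_id = character(), beta = numeric(),
                      se = numeric(), p = numeric()))
  f <- cond_fit(selected)
  data.frame(variant_id = vi$id[selected], beta = unname(f$beta),
             se = unname(f$se), p = unname(f$p))
}

#' Per-variant variance explained on a standardized trait
#'
#' For a standardized trait, a variant with per-allele effect beta and
#' effect-allele frequency f explains approximately
#' \code{2 * beta^2 * f * (1 - f)} of the variance.
#'
#' @param betas marginal effect estimates on the standardized trait.
#' @param freqs effect-allele frequencies, strictly inside (0, 1).
#' @return list with \code{per_variant} contributions and their
#'   \code{total}.
#' @export
varianceExplained <- function(betas, freqs) {
  stopifnot(length(betas) == length(freqs))
  if (any(freqs <= 0 | freqs >= 1))
    stop("frequencies must be strictly inside (0, 1)")
  pv <- 2 * betas^2 * freqs * (1 - freqs)
  list(per_variant = pv, total = sum(pv))
}

#' Sign concordance between discovery and replication effects
#'
#' Counts pairs with the same effect sign (pairs where either beta is
#' exactly zero are excluded) and tests against random signs with a
#' two-sided exact binomial test at p0 = 0.5; also reports the Pearson
#' correlation of the effect pairs with its two-sided p-value.
#'
#' @param discovery_betas,replication_betas paired effect estimates,
#'   matched on variant and effect allele.
#' @return list with \code{n_total}, \code{n_concordant}, \code{p_binom},
#'   \code{pearson_r}, \code{p_pearson}.
#' @export
signConcordanceTest <- function(discovery_betas, replication_betas) {
  stopifnot(length(discovery_betas) == length(replication_betas))
  ok <- !is.na(discovery_betas) & !is.na(replication_betas)
  if (!any(ok)) stop("no overlapping variants")
  d <- discovery_betas[ok]; r <- replication_betas[ok]
  nz <- d != 0 & r != 0
  k <- sum(sign(d[nz]) == sign(r[nz]))
  n <- sum(nz)
  p_binom <- if (n > 0) binom.test(k, n, p = 0.5)$p.value else NA_real_
  ct <- if (sum(ok) >= 3 && sd(d) > 0 && sd(r) > 0)
    cor.test(d, r) else NULL
  list(n_total = n, n_concordant = k, p_binom = p_binom,
       pearson_r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       p_pearson = if (is.null(ct)) NA_real_ else ct$p.value)
}

#' Genetic risk scores
#'
#' The marginal score of sample i is
#' \code{sum_j dosage_ij * beta_marginal_j}; the interaction-aware score
#' is \code{sum_j dosage_ij * (beta_g_j + cwduvb_i * beta_gxe_j)}, using
#' each participant's own exposure. Missing dosages are mean-imputed per
#' variant.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param weights data.frame with \code{variant_id},
#'   \code{effect_allele}, \code{beta_marginal}, \code{beta_g},
#'   \code{beta_gxe}.
#' @param exposure per-sample CW-D-UVB values aligned with the samples
#'   of \code{g}.
#' @return data.frame with \code{participant_id}, \code{marginal_score},
#'   \code{interaction_score}.
#' @export
buildRiskScores <- function(g, weights, exposure) {
  vi <- variantInfo(g)
  idx <- match(weights$variant_id, vi$id)
  if (anyNA(idx))
    stop("genotypes lack weight variants: ",
         paste(head(weights$variant_id[is.na(idx)], 5), collapse = ", "))
  if (any(weights$effect_allele != vi$alt[idx]))
    stop("effect allele mismatch for: ",
         paste(head(weights$variant_id[
           weights$effect_allele != vi$alt[idx]], 5), collapse = ", "))
  D <- dosage(g)[, idx, drop = FALSE]
  for (j in seq_len(ncol(D)))
    if (anyNA(D[, j])) D[is.na(D[, j]), j] <- mean(D[, j], na.rm = TRUE)
  stopifnot(length(exposure) == nrow(D))
  marginal <- as.vector(D %*% weights$beta_marginal)
  interaction <- as.vector(D %*% weights$beta_g) +
    exposure * as.vector(D %*% weights$beta_gxe)
  data.frame(participant_id = sampleIds(g),
             marginal_score = marginal, interaction_score = interaction)
}

#' Evaluate risk scores against raw 25OHD
#'
#' Fits raw 25OHD on each score adjusted for age and sex, and contrasts
#' mean 25OHD between the top and bottom score deciles.
#'
#' @param scores a \code{\link{buildRiskScores}} result.
#' @param cohort cohort data.frame with \code{participant_id},
#'   \code{pheno_raw}, \code{age}, \code{sex}.
#' @return data.frame with one row per score: \code{slope} (nmol/L per
#'   unit score), \code{se}, \code{p}, and
#'   \code{decile_diff} (top minus bottom decile mean 25OHD).
#' @export
evaluateRiskScores <- function(scores, cohort) {
  idx <- match(scores$participant_id, cohort$participant_id)
  if (anyNA(idx)) stop("cohort is missing scored participants")
  cohort <- cohort[idx, , drop = FALSE]
  out <- lapply(c("marginal_score", "interaction_score"), function(sc) {
    s <- scores[[sc]]
    if (sd(s) == 0) stop("constant score: ", sc)
    fit <- lm(cohort$pheno_raw ~ s + cohort$age + cohort$sex)
    cf <- summary(fit)$coefficients["s", ]
    dec <- as.integer(ceiling(10 * rank(s, ties.method = "first") /
                                length(s)))
    data.frame(score = sc, slope = cf[1], se = cf[2], p = cf[4],
               decile_diff = mean(cohort$pheno_raw[dec == 10]) -
                 mean(cohort$pheno_raw[dec == 1]))
  })
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}
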