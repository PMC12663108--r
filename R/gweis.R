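## Genome-wide gene-environment interaction engine.
##
## Two least-squares models per variant, on the standardized
## log-transformed phenotype y with covariates C (which include the
## exposure E):
##   marginal:     y ~ b_marginal * G + C
##   interaction:  y ~ b_G * G + b_GxE * (G x E) + C
## Tests: 1-df Wald on b_marginal (model-based SE), 1-df Wald on b_GxE
## and 2-df joint Wald on (b_G, b_GxE), the latter two with either
## model-based or HC0 sandwich covariance (default robust).
##
## The fast path residualizes y, G and GxE on the covariates once
## (Frisch-Waugh-Lovell); coefficients, model-based covariance blocks and
## the HC0 sandwich block computed on the residualized design are
## algebraically identical to the full-design quantities.

#' Model specification for the association scan
#'
#' @param covariates character vector of covariate column names in the
#'   cohort table. The exposure is always included as a covariate.
#' @param exposure name of the exposure column (default \code{"cwduvb"}).
#' @param se_type covariance used for the interaction and joint tests:
#'   \code{"robust"} (sandwich, default) or \code{"model"}. The
#'   marginal test always uses its model-based SE; both covariances are
#'   stored in the output either way.
#' @param hc_type flavour of the sandwich: \code{"HC2"} (default;
#'   leverage-corrected, well calibrated even when the exposure
#'   distribution is skewed and G x E rows carry high leverage),
#'   \code{"HC0"} or \code{"HC3"}.
#' @param significance_threshold genome-wide significance level
#'   (default 5e-8).
#' @return a list with class \code{"ModelSpec"}.
#' @export
modelSpec <- function(covariates = c("age", "sex", "vitd_supp",
                                     "fishoil_supp", paste0("pc", 1:10)),
                      exposure = "cwduvb",
                      se_type = c("robust", "model"),
                      hc_type = c("HC2", "HC0", "HC3"),
                      significance_threshold = 5e-8) {
  se_type <- match.arg(se_type)
  hc_type <- match.arg(hc_type)
  stopifnot(significance_threshold > 0, significance_threshold < 1)
  structure(list(covariates = union(covariates, exposure),
                 exposure = exposure, se_type = se_type,
                 hc_type = hc_type,
                 significance_threshold = significance_threshold),
            class = "ModelSpec")
}

#' Standardize the 25OHD phenotype
#'
#' Clamps raw concentrations at the assay lower limit of detection,
#' natural-log transforms, and z-scores against the analysis sample.
#'
#' @param raw numeric vector of 25OHD concentrations, nmol/L.
#' @param lod lower limit of detection (default 10 nmol/L).
#' @return standardized values with mean 0 and sd 1.
#' @export
preparePhenotype <- function(raw, lod = 10) {
  if (any(!is.finite(raw)))
    stop("non-finite phenotype values")
  x <- pmax(raw, lod)
  if (any(x <= 0)) stop("non-positive phenotype after clamping")
  lx <- log(x)
  s <- sd(lx)
  if (!is.finite(s) || s == 0) stop("constant phenotype")
  (lx - mean(lx)) / s
}

## covariate design: intercept + spec$covariates columns; returns thin-Q
.covariateBasis <- function(cohort, spec) {
  miss <- setdiff(spec$covariates, colnames(cohort))
  if (length(miss))
    stop("cohort lacks covariate columns: ", paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(cohort[, spec$covariates, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- c("(intercept)", spec$covariates)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  list(Q = qr.Q(qrX), p = ncol(X))
}

## per-variant fit on pre-residualized quantities.
## yt: residualized phenotype; g: raw dosage (mean-imputed); E exposure;
## Q covariate basis; p number of covariate columns (incl intercept).
.fitOne <- function(g, E, yt, Q, p, n, se_type, hc_type = "HC2") {
  gt <- g - Q %*% crossprod(Q, g)
  ge <- g * E
  get <- ge - Q %*% crossprod(Q, ge)
  gg <- sum(gt * gt)
  if (gg < n * 1e-12)
    return(NULL)  # constant dosage / collinear with covariates
  ## marginal model
  bm <- sum(gt * yt) / gg
  rm_ <- yt - bm * gt
  df_m <- n - p - 1
  sig2m <- sum(rm_^2) / df_m
  sem <- sqrt(sig2m / gg)
  ## interaction model
  Z <- cbind(gt, get)
  A <- crossprod(Z)
  detA <- A[1, 1] * A[2, 2] - A[1, 2]^2
  if (!is.finite(detA) || detA < (A[1, 1] * A[2, 2]) * 1e-12)
    return(NULL)  # GxE collinear with G given covariates
  Ainv <- matrix(c(A[2, 2], -A[1, 2], -A[1, 2], A[1, 1]), 2, 2) / detA
  b <- Ainv %*% crossprod(Z, yt)
  r <- yt - Z %*% b
  df_i <- n - p - 2
  sig2i <- sum(r^2) / df_i
  Vmod <- sig2i * Ainv
  r2w <- as.vector(r)^2
  if (hc_type != "HC0") {
    ## full-design leverage: covariate part + interaction-block part
    hii <- rowSums(Q^2) + as.vector(
      A[2, 2] * gt^2 - 2 * A[1, 2] * gt * get + A[1, 1] * get^2) / detA
    r2w <- r2w / (1 - hii)^(if (hc_type == "HC3") 2 else 1)
  }
  meat <- crossprod(Z * r2w, Z)
  Vrob <- Ainv %*% meat %*% Ainv
  V <- if (se_type == "robust") Vrob else Vmod
  p_marg <- pchisq((bm / sem)^2, df = 1, lower.tail = FALSE)
  p_int <- pchisq(b[2]^2 / V[2, 2], df = 1, lower.tail = FALSE)
  detV <- V[1, 1] * V[2, 2] - V[1, 2]^2
  w2 <- (b[1]^2 * V[2, 2] - 2 * b[1] * b[2] * V[1, 2] +
           b[2]^2 * V[1, 1]) / detV
  p_joint <- pchisq(w2, df = 2, lower.tail = FALSE)
  c(beta_marginal = bm, se_marginal = sem, p_marginal = p_marg,
    beta_g = b[1], beta_gxe = b[2],
    se_g_robust = sqrt(Vrob[1, 1]), se_gxe_robust = sqrt(Vrob[2, 2]),
    cov_g_gxe_robust = Vrob[1, 2],
    se_g_model = sqrt(Vmod[1, 1]), se_gxe_model = sqrt(Vmod[2, 2]),
    cov_g_gxe_model = Vmod[1, 2],
    p_int = p_int, p_joint = p_joint, joint_stat = w2)
}

#' Fit the marginal and interaction models for a single variant
#'
#' @param dosage_vec per-sample ALT dosages (missing values are
#'   mean-imputed).
#' @param cohort cohort data.frame with \code{pheno_std}, the exposure
#'   and all covariates in \code{spec}.
#' @param spec a \code{\link{modelSpec}}.
#' @return one-row data.frame with effect estimates, both covariance
#'   versions and the three p-values, or a zero-row data.frame with
#'   attribute \code{skip_reason} when the dosage is constant.
#' @export
fitVariant <- function(dosage_vec, cohort, spec = modelSpec()) {
  n <- nrow(cohort)
  stopifnot(length(dosage_vec) == n)
  cb <- .covariateBasis(cohort, spec)
  y <- cohort$pheno_std
  yt <- y - cb$Q %*% crossprod(cb$Q, y)
  g <- dosage_vec
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  E <- cohort[[spec$exposure]]
  r <- .fitOne(g, E, yt, cb$Q, cb$p, n, spec$se_type, spec$hc_type)
  if (is.null(r)) {
    out <- data.frame()
    attr(out, "skip_reason") <- "constant or collinear dosage"
    return(out)
  }
  cbind(data.frame(n = n, effect_allele_frequency = mean(g) / 2),
        as.data.frame(as.list(r)))
}

#' Genome-wide scan: marginal, interaction and joint tests
#'
#' Runs \code{\link{fitVariant}} for every variant via the residualize-
#' once fast path. Samples are aligned between genotypes and cohort by
#' \code{participant_id}.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param cohort cohort data.frame with \code{participant_id},
#'   \code{pheno_std}, exposure and covariates.
#' @param spec a \code{\link{modelSpec}}.
#' @param chunk_size variants processed per BLAS block (memory/speed
#'   trade-off only; results are identical).
#' @return data.frame with one row per variant: variant metadata,
#'   \code{n}, \code{effect_allele_frequency}, the estimates of both
#'   models, covariance entries and p-values, and a \code{status}
#'   column (\code{"ok"} or a skip reason).
#' @export
runGweis <- function(g, cohort, spec = modelSpec(), chunk_size = 512L) {
  ids <- sampleIds(g)
  idx <- match(ids, cohort$participant_id)
  if (anyNA(idx))
    stop("cohort is missing participants: ",
         paste(head(ids[is.na(idx)], 5), collapse = ", "))
  cohort <- cohort[idx, , drop = FALSE]
  n <- nrow(cohort)
  cb <- .covariateBasis(cohort, spec)
  y <- cohort$pheno_std
  yt <- as.vector(y - cb$Q %*% crossprod(cb$Q, y))
  E <- cohort[[spec$exposure]]
  D <- dosage(g)
  vi <- variantInfo(g)
  m <- ncol(D)
  cols <- c("beta_marginal", "se_marginal", "p_marginal", "beta_g",
            "beta_gxe", "se_g_robust", "se_gxe_robust", "cov_g_gxe_robust",
            "se_g_model", "se_gxe_model", "cov_g_gxe_model",
            "p_int", "p_joint", "joint_stat")
  res <- matrix(NA_real_, m, length(cols), dimnames = list(NULL, cols))
  eaf <- numeric(m)
  status <- rep("ok", m)
  yy <- sum(yt^2)
  df_m <- n - cb$p - 1
  df_i <- n - cb$p - 2
  h_cov <- rowSums(cb$Q^2)  # covariate-part leverage, shared by variants
  for (a in seq(1L, m, by = chunk_size)) {
    jj <- a:min(a + chunk_size - 1L, m)
    G <- D[, jj, drop = FALSE]
    if (anyNA(G)) {
      mu <- colMeans(G, na.rm = TRUE)
      nas <- which(is.na(G), arr.ind = TRUE)
      G[nas] <- mu[nas[, 2]]
    }
    eaf[jj] <- colMeans(G) / 2
    GE <- G * E
    ## residualize both blocks on the covariates in one BLAS pass each
    Gt <- G - cb$Q %*% crossprod(cb$Q, G)
    GEt <- GE - cb$Q %*% crossprod(cb$Q, GE)
    gg <- colSums(Gt^2)
    ok <- gg > n * 1e-12
    gy <- colSums(Gt * yt)
    ## marginal model
    bm <- gy / gg
    sig2m <- (yy - bm^2 * gg) / df_m
    sem <- sqrt(sig2m / gg)
    ## interaction model: per-variant 2x2 normal equations
    ee <- colSums(GEt^2)
    ge <- colSums(Gt * GEt)
    ey <- colSums(GEt * yt)
    detA <- gg * ee - ge^2
    ok <- ok & is.finite(detA) & detA > gg * ee * 1e-12
    b1 <- (ee * gy - ge * ey) / detA
    b2 <- (gg * ey - ge * gy) / detA
    R <- yt - sweep(Gt, 2, b1, "*") - sweep(GEt, 2, b2, "*")
    rss <- colSums(R^2)
    sig2i <- rss / df_i
    ## model-based covariance: sig2i * A^{-1}
    v11m <- sig2i * ee / detA
    v22m <- sig2i * gg / detA
    v12m <- -sig2i * ge / detA
    ## sandwich: A^{-1} (Z' diag(w) Z) A^{-1}, w = r^2 (HC0) or
    ## leverage-corrected r^2/(1-h) (HC2) / r^2/(1-h)^2 (HC3)
    R2 <- R^2
    if (spec$hc_type != "HC0") {
      H <- h_cov +
        (sweep(Gt^2, 2, ee, "*") - 2 * sweep(Gt * GEt, 2, ge, "*") +
           sweep(GEt^2, 2, gg, "*")) / rep(detA, each = n)
      R2 <- R2 / (1 - H)^(if (spec$hc_type == "HC3") 2 else 1)
    }
    m11 <- colSums(Gt^2 * R2)
    m22 <- colSums(GEt^2 * R2)
    m12 <- colSums(Gt * GEt * R2)
    ## A^{-1} rows: [ee, -ge; -ge, gg]/detA
    v11r <- (ee^2 * m11 - 2 * ee * ge * m12 + ge^2 * m22) / detA^2
    v22r <- (ge^2 * m11 - 2 * gg * ge * m12 + gg^2 * m22) / detA^2
    v12r <- (-ee * ge * m11 + (gg * ee + ge^2) * m12 - gg * ge * m22) /
      detA^2
    if (spec$se_type == "robust") {
      V11 <- v11r; V22 <- v22r; V12 <- v12r
    } else {
      V11 <- v11m; V22 <- v22m; V12 <- v12m
    }
    detV <- V11 * V22 - V12^2
    w2 <- (b1^2 * V22 - 2 * b1 * b2 * V12 + b2^2 * V11) / detV
    block <- cbind(
      beta_marginal = bm, se_marginal = sem,
      p_marginal = pchisq((bm / sem)^2, 1, lower.tail = FALSE),
      beta_g = b1, beta_gxe = b2,
      se_g_robust = sqrt(v11r), se_gxe_robust = sqrt(v22r),
      cov_g_gxe_robust = v12r,
      se_g_model = sqrt(v11m), se_gxe_model = sqrt(v22m),
      cov_g_gxe_model = v12m,
      p_int = pchisq(b2^2 / V22, 1, lower.tail = FALSE),
      p_joint = pchisq(w2, 2, lower.tail = FALSE),
      joint_stat = w2)
    block[!ok, ] <- NA_real_
    res[jj, ] <- block
    status[jj][!ok] <- "constant_dosage"
  }
  data.frame(
    chromosome = vi$chrom, base_pair_location = vi$pos,
    variant_id = vi$id, effect_allele = vi$alt, other_allele = vi$ref,
    effect_allele_frequency = eaf, n = n,
    as.data.frame(res), status = status,
    stringsAsFactors = FALSE
  )
}

#' Exposure quintile labels
#'
#' Assigns labels 1..5 by sample quantile boundaries; ties are broken by
#' stable rank order so that strata are near-equal even with heavily
#' tied exposures, and labels are invariant under monotone
#' transformations of the exposure.
#'
#' @param x numeric exposure vector, length >= 5.
#' @return integer labels in 1..5.
#' @export
exposureQuintiles <- function(x) {
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(5 * r / n))
}

#' Stratified genome-wide scans
#'
#' Runs an independent scan in each stratum with the phenotype
#' re-standardized (from \code{pheno_raw}) within stratum.
#'
#' @inheritParams runGweis
#' @param strata either a vector of stratum labels aligned with
#'   \code{cohort}, or one of \code{"bmi_category"},
#'   \code{"exposure_quintile"}, \code{"outdoors"} (the subset with
#'   \code{outdoors_hours >= 3}).
#' @param min_stratum minimum stratum size (default 50).
#' @return named list of per-stratum result data.frames, each with an
#'   attribute \code{n_stratum}.
#' @export
runStratified <- function(g, cohort, spec = modelSpec(), strata,
                          min_stratum = 50) {
  if (is.character(strata) && length(strata) == 1L) {
    strata <- switch(strata,
      bmi_category = cohort$bmi_category,
      exposure_quintile = exposureQuintiles(cohort[[spec$exposure]]),
      outdoors = ifelse(cohort$outdoors_hours >= 3, "outdoors3h", NA),
      stop("unknown stratification: ", strata))
  }
  stopifnot(length(strata) == nrow(cohort))
  labs <- sort(unique(strata[!is.na(strata)]))
  if (length(labs) == 0L) stop("no non-empty strata")
  out <- list()
  for (lab in labs) {
    keep <- !is.na(strata) & strata == lab
    if (sum(keep) < min_stratum)
      stop(sprintf("stratum '%s' has %d samples (< %d)",
                   lab, sum(keep), min_stratum))
    sub <- cohort[keep, , drop = FALSE]
    if (!is.null(sub$pheno_raw))
      sub$pheno_std <- preparePhenotype(sub$pheno_raw)
    else
      sub$pheno_std <- (sub$pheno_std - mean(sub$pheno_std)) /
        sd(sub$pheno_std)
    gi <- g[match(sub$participant_id, sampleIds(g)), ]
    r <- runGweis(gi, sub, spec)
    attr(r, "n_stratum") <- sum(keep)
    out[[as.character(lab)]] <- r
  }
  out
}
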