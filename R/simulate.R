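## Synthetic data with known ground truth: LD-structured genotype
## dosages, seasonal daily UVB grids, and 25OHD phenotypes generated from
## main genetic, exposure, GxE and covariate effects plus noise.

#' Simulation configuration
#'
#' @param seed integer seed; the same config always yields identical
#'   output. Genotypes are drawn block by block from block-derived seed
#'   streams, so increasing \code{n_variants} does not perturb earlier
#'   blocks.
#' @param n_samples,n_variants cohort dimensions.
#' @param maf_range ALT-allele frequencies are drawn uniformly from this
#'   range; the default [0.005, 0.5] keeps low-frequency (MAF < 0.05)
#'   variants in the spectrum while rarely producing monomorphic columns
#'   at desk-scale n.
#' @param ld_rho per-block latent AR(1) autocorrelation, in [0, 1); a
#'   vector is recycled across blocks, giving heterogeneous LD (and
#'   hence a spread of LD scores) along the genome.
#' @param block_size variants per LD block; blocks are independent.
#' @param n_causal_main,n_causal_gxe numbers of causal variants for main
#'   and interaction effects.
#' @param h2_target variance share of the main genetic component.
#' @param gxe_strength variance share of the interaction component
#'   (architecture \code{"interaction"} only).
#' @param architecture \code{"additive"} (no GxE),
#'   \code{"interaction"} (locus-specific GxE at its own causal set), or
#'   \code{"amplification"} (every main effect scaled by
#'   \code{1 + kappa * E_std}, so \code{beta_gxe = kappa * beta_g}).
#' @param kappa amplification slope.
#' @param exposure_share variance share of the exposure main effect
#'   (default 0.124, the share ambient UVB explains of 25OHD variance
#'   in UK cohorts).
#' @param covariate_effects named vector of effects (per SD of the
#'   covariate) for age, sex, vitd_supp, fishoil_supp on the latent
#'   scale.
#' @param mu_log,sigma_log location and scale used to map the latent
#'   standardized phenotype to raw 25OHD via
#'   \code{exp(mu_log + sigma_log * z)} (defaults give a right-skewed
#'   distribution with geometric mean 48 nmol/L).
#' @param lod assay lower limit of detection, nmol/L.
#' @return a list with class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1, n_samples = 1000, n_variants = 500,
                      maf_range = c(0.005, 0.5), ld_rho = 0.5,
                      block_size = 25, n_causal_main = 20,
                      n_causal_gxe = 10, h2_target = 0.15,
                      gxe_strength = 0.05,
                      architecture = c("additive", "interaction",
                                       "amplification"),
                      kappa = 0,
                      exposure_share = 0.124,
                      covariate_effects = c(age = -0.05, sex = 0.05,
                                            vitd_supp = 0.2,
                                            fishoil_supp = 0.1),
                      mu_log = log(48), sigma_log = 0.35, lod = 10) {
  architecture <- match.arg(architecture)
  stopifnot(all(ld_rho >= 0), all(ld_rho < 1),
            h2_target >= 0, h2_target < 1,
            gxe_strength >= 0, h2_target + gxe_strength <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, seed == round(seed))
  structure(as.list(environment()), class = "SimConfig")
}

## AR(1) latent-Gaussian haplotype block: n x L standard normal with
## lag-1 correlation rho, thresholded at qnorm(f) to give ALT alleles.
.haploBlock <- function(n, f, rho) {
  L <- length(f)
  Z <- matrix(rnorm(n * L), n, L)
  if (rho > 0 && L > 1) {
    for (k in 2:L) Z[, k] <- rho * Z[, k - 1] + sqrt(1 - rho^2) * Z[, k]
  }
  sweep(Z, 2, qnorm(f), "<") * 1
}

#' Simulate LD-structured genotype dosages
#'
#' Each haplotype is a latent standard-normal AR(1) series with
#' correlation \code{ld_rho} within blocks (independent across blocks),
#' thresholded at the allele-frequency quantile; the dosage is the sum
#' of two independent haplotypes, so Hardy-Weinberg equilibrium holds by
#' construction. Each block draws from its own seed stream derived from
#' \code{seed}, so earlier blocks are unchanged when variants are added.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{genotypes} (a \linkS4class{GenotypeData}),
#'   \code{blocks} (block index per variant) and \code{maf} (target ALT
#'   frequencies).
#' @export
simulateGenotypes <- function(config) {
  m <- config$n_variants; n <- config$n_samples
  bs <- config$block_size
  n_blocks <- ceiling(m / bs)
  D <- matrix(0, n, m)
  f_all <- numeric(m)
  block <- integer(m)
  rho_b <- rep_len(config$ld_rho, n_blocks)
  for (b in seq_len(n_blocks)) {
    jj <- ((b - 1) * bs + 1):min(b * bs, m)
    set.seed((config$seed %% 1000000L) * 2048L + b)
    f <- runif(length(jj), config$maf_range[1], config$maf_range[2])
    D[, jj] <- .haploBlock(n, f, rho_b[b]) +
      .haploBlock(n, f, rho_b[b])
    f_all[jj] <- f
    block[jj] <- b
  }
  variants <- data.frame(
    chrom = "1", pos = seq_len(m) * 5000L,
    id = sprintf("var%05d", seq_len(m)),
    ref = "A", alt = "G", info_score = NA_real_
  )
  g <- GenotypeData(D, variants,
                    sample_ids = sprintf("id%06d", seq_len(n)))
  list(genotypes = g, blocks = block, maf = f_all)
}

## seasonal shape: m(doy) in [0,1], 1 at the June solstice (doy 172)
.seasonShape <- function(doy) (1 + cos(2 * pi * (doy - 172) / 365.25)) / 2

## solve (trough, ratio) so that noise-free June and December monthly
## mean doses at the reference latitude equal the calibration targets
.calibrateSeason <- function(june_mean, december_mean) {
  mj <- .seasonShape(152:181)   # June
  md <- .seasonShape(c(335:365))  # December
  target <- june_mean / december_mean
  froot <- function(lr) mean(exp(lr * mj)) / mean(exp(lr * md)) - target
  lr <- uniroot(froot, c(log(2), log(1e4)), tol = 1e-12)$root
  trough <- december_mean / mean(exp(lr * md))
  list(log_ratio = lr, trough = trough)
}

#' Simulate a seasonal daily UVB dose grid
#'
#' Clear-sky dose is a seasonal exponential-of-cosine in day of year
#' peaking at the summer solstice, calibrated so that at the reference
#' latitude the noise-free June and December monthly mean doses equal
#' the London climatology (5.56 and 0.11 kJ/m^2, a ~50-fold annual
#' range). A linear latitude factor makes higher-latitude cells
#' uniformly dimmer; multiplicative lognormal day-to-day noise emulates
#' cloud variability.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param dates contiguous \code{Date} vector.
#' @param june_mean,december_mean calibration monthly means at
#'   \code{lat_ref}, kJ/m^2.
#' @param lat_ref,lat_slope reference latitude and fractional dimming
#'   per degree poleward of it.
#' @param cloud_sd sdlog of the lognormal noise (0 disables noise; the
#'   noise has mean 1).
#' @param seed seed for the noise draw.
#' @return a \linkS4class{DailyDoseGrid}.
#' @export
simulateUvbGrid <- function(grid, dates, june_mean = 5.56,
                            december_mean = 0.11, lat_ref = 51.5,
                            lat_slope = 0.04, cloud_sd = 0.3, seed = 1) {
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("empty date range")
  cal <- .calibrateSeason(june_mean, december_mean)
  doy <- as.integer(format(dates, "%j"))
  season <- cal$trough * exp(cal$log_ratio * .seasonShape(doy))
  lat_centers <- grid@lat_min + (seq_len(grid@n_lat) - 0.5) * grid@cell_size_deg
  latfac <- pmax(0.05, 1 - lat_slope * (lat_centers - lat_ref))
  ## cells latitude-major: column i*n_lon + j + 1
  cellfac <- rep(latfac, each = grid@n_lon)
  dose <- outer(season, cellfac)
  if (cloud_sd > 0) {
    set.seed(seed)
    noise <- matrix(rlnorm(length(dose), meanlog = -cloud_sd^2 / 2,
                           sdlog = cloud_sd), nrow(dose), ncol(dose))
    dose <- dose * noise
  }
  DailyDoseGrid(grid, dates, dose)
}

#' Simulate a cohort phenotype with known ground truth
#'
#' Generates a standardized latent phenotype
#' \deqn{z = \sum_j \beta_{G,j}\tilde g_j + \gamma E_{std} +
#'   \sum_j \beta_{GxE,j}\tilde g_j E_{std} + covariates + \epsilon}
#' with standardized dosages \eqn{\tilde g} and the exposure
#' standardized inside the generative model so variance-share
#' parameters are interpretable. Under
#' \code{architecture = "amplification"} the main effects are scaled by
#' \code{1 + kappa * E_std}, i.e. \code{beta_gxe = kappa * beta_g}.
#' Effects are scaled so the realized main-genetic variance share equals
#' \code{h2_target} (and the interaction share \code{gxe_strength}
#' under \code{"interaction"}). Raw 25OHD is
#' \code{exp(mu_log + sigma_log * z)} clamped at the assay LOD.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param exposures data.frame with \code{participant_id} and
#'   \code{cwduvb}, or a numeric vector aligned with the samples.
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{cohort} (analysis-ready data.frame including
#'   \code{pheno_raw}, \code{pheno_std}, covariates, \code{cwduvb},
#'   \code{bmi_category}, \code{outdoors_hours}) and \code{truth} (per
#'   variant \code{beta_g}, \code{beta_gxe}, causal flags; realized
#'   variance shares; per-sample generative components).
#' @export
simulateCohort <- function(g, exposures, config) {
  n <- nSamples(g); m <- nVariants(g)
  ids <- sampleIds(g)
  if (is.data.frame(exposures)) {
    idx <- match(ids, exposures$participant_id)
    if (anyNA(idx)) stop("exposures missing for some samples")
    E_raw <- exposures$cwduvb[idx]
  } else {
    stopifnot(length(exposures) == n)
    E_raw <- as.numeric(exposures)
  }
  E <- (E_raw - mean(E_raw)) / sd(E_raw)
  set.seed((config$seed %% 1000000L) * 2048L + 1500000L)
  ## covariates
  age <- runif(n, 40, 70)
  sex <- rbinom(n, 1, 0.5)
  vitd_supp <- rbinom(n, 1, 0.25)
  fishoil_supp <- rbinom(n, 1, 0.3)
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  bmi <- pmax(16, rnorm(n, 27, 4.5))
  outdoors_hours <- pmin(12, pmax(0, round(rnorm(n, 2.5, 1.8))))
  ce <- config$covariate_effects
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  cov_comp <- ce["age"] * zs(age) + ce["sex"] * zs(sex) +
    ce["vitd_supp"] * zs(vitd_supp) + ce["fishoil_supp"] * zs(fishoil_supp)

  D <- dosage(g)
  D[is.na(D)] <- 0
  sds <- apply(D, 2, sd)
  usable <- which(sds > 0)
  Gs <- scale(D[, usable, drop = FALSE])

  beta_g <- numeric(m); beta_gxe <- numeric(m)
  causal_main <- sample(usable, min(config$n_causal_main, length(usable)))
  b_raw <- rnorm(length(causal_main))
  Gmat <- Gs[, match(causal_main, usable), drop = FALSE]
  gen0 <- as.vector(Gmat %*% b_raw)
  sc <- if (config$h2_target > 0 && var(gen0) > 0)
    sqrt(config$h2_target / var(gen0)) else 0
  beta_g[causal_main] <- b_raw * sc
  gen <- gen0 * sc

  inter <- numeric(n)
  if (config$architecture == "interaction" && config$gxe_strength > 0) {
    causal_gxe <- sample(usable, min(config$n_causal_gxe, length(usable)))
    bx_raw <- rnorm(length(causal_gxe))
    ix0 <- as.vector(
      (Gs[, match(causal_gxe, usable), drop = FALSE] %*% bx_raw)) * E
    scx <- if (var(ix0) > 0) sqrt(config$gxe_strength / var(ix0)) else 0
    beta_gxe[causal_gxe] <- bx_raw * scx
    inter <- ix0 * scx
  } else if (config$architecture == "amplification" && config$kappa != 0) {
    beta_gxe[causal_main] <- config$kappa * beta_g[causal_main]
    inter <- config$kappa * gen * E
  }

  expo <- sqrt(config$exposure_share) * E
  used <- var(gen) + var(inter) + var(expo) + var(cov_comp)
  noise_sd <- sqrt(max(1 - used, 0.05))
  eps <- rnorm(n, 0, noise_sd)
  z <- gen + inter + expo + cov_comp + eps
  pheno_raw <- pmax(exp(config$mu_log + config$sigma_log * z), config$lod)

  bmi_category <- cut(bmi, c(18.5, 25, 30, Inf), right = FALSE,
                      labels = c("normal", "overweight", "obese"))
  cohort <- data.frame(
    participant_id = ids, pheno_raw = pheno_raw,
    pheno_std = preparePhenotype(pheno_raw, lod = config$lod),
    age = age, sex = sex, vitd_supp = vitd_supp,
    fishoil_supp = fishoil_supp, cwduvb = E_raw, pcs,
    bmi = bmi, bmi_category = as.character(bmi_category),
    outdoors_hours = outdoors_hours,
    stringsAsFactors = FALSE
  )
  truth <- list(
    variants = data.frame(id = variantInfo(g)$id, beta_g = beta_g,
                          beta_gxe = beta_gxe,
                          causal_main = beta_g != 0,
                          causal_gxe = beta_gxe != 0),
    realized_h2 = var(gen) / var(z),
    realized_gxe_share = var(inter) / var(z),
    components = data.frame(genetic = gen, interaction = inter,
                            exposure = expo, covariates = cov_comp,
                            noise = eps, z = z, E_std = E)
  )
  list(cohort = cohort, truth = truth)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates genotypes, a seasonal UVB grid, residences with sampling
#' dates, exposures, a phenotype table and the ground truth, writes
#' everything as plain TSV, and plants one QC failure of each kind: a
#' high-missingness variant, an all-heterozygote (HWE-violating)
#' variant, a duplicated sample and a heterozygosity outlier. The bundle
#' is byte-identical across runs with the same config.
#'
#' @param config a \code{\link{simConfig}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of written paths plus the in-memory
#'   objects.
#' @export
makeFixtureBundle <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateGenotypes(config)
  g <- sim$genotypes
  n <- nSamples(g); m <- nVariants(g)
  D <- dosage(g)
  set.seed((config$seed %% 1000000L) * 2048L + 900000L)
  ## planted QC failures (recorded in plants.tsv)
  v_miss <- m - 1L; v_hwe <- m
  D[sample(n, ceiling(0.05 * n)), v_miss] <- NA
  D[, v_hwe] <- 1
  s_dup <- n - 1L; s_het <- n - 2L
  D[s_dup, ] <- D[1L, ]
  het_targets <- sample(m - 2L, floor(0.6 * (m - 2L)))
  D[s_het, het_targets] <- 1
  g <- GenotypeData(D, variantInfo(g), sample_ids = sampleIds(g))

  grid <- GridSpec(lat_min = 50, lon_min = -4, cell_size_deg = 0.25,
                   n_lat = 16, n_lon = 16)
  dates <- seq(as.Date("2009-01-01"), as.Date("2010-06-30"), by = "day")
  dose_grid <- simulateUvbGrid(grid, dates, cloud_sd = 0.3,
                               seed = config$seed)
  sample_date <- sample(seq(as.Date("2009-06-01"), as.Date("2010-06-30"),
                            by = "day"), n, replace = TRUE)
  residences <- data.frame(
    participant_id = sampleIds(g),
    lat = runif(n, 50.05, 53.95), lon = runif(n, -3.95, -0.05),
    sample_date = sample_date
  )
  expo <- buildExposureTable(residences, dose_grid)
  sim_cohort <- simulateCohort(g, expo$exposure, config)
  cohort <- sim_cohort$cohort

  w <- function(x, file) {
    p <- file.path(out_dir, file)
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 10,
                                                   format = "g"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list(
    grid = writeDoseGrid(dose_grid, file.path(out_dir, "uvb_grid.tsv")),
    residences = w(residences, "residences.tsv"),
    exposure = w(expo$exposure, "exposure.tsv"),
    genotypes = writeGenotypeTsv(g, file.path(out_dir, "genotypes")),
    phenotype = w(cohort, "phenotype.tsv"),
    truth = w(sim_cohort$truth$variants, "truth.tsv"),
    plants = w(data.frame(
      kind = c("variant_missingness", "variant_hwe",
               "sample_duplicate", "sample_heterozygosity"),
      id = c(variantInfo(g)$id[c(v_miss, v_hwe)],
             sampleIds(g)[c(s_dup, s_het)])), "plants.tsv")
  )
  invisible(c(paths, list(genotypes_obj = g, cohort = cohort,
                          truth = sim_cohort$truth, grid = dose_grid)))
}

#' @importFrom stats uniroot
NULL
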