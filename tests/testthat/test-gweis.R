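test_that("phenotype preparation clamps at the LOD, log-transforms and z-scores", {
  set.seed(8)
  raw <- rlnorm(500, log(48), 0.35)
  z <- preparePhenotype(raw)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(order(z), order(raw))  # monotone
  # values below 10 nmol/L are treated as 10 before the log
  raw2 <- c(5, 10, raw)
  z2 <- preparePhenotype(raw2)
  expect_equal(z2[1], z2[2])
  expect_error(preparePhenotype(c(raw, NA)), "finite")
})

test_that("fitVariant agrees with a naive normal-equations oracle", {
  set.seed(9)
  n <- 200
  co <- makeSimpleCohort(n, seed = 9)
  g <- rbinom(n, 2, 0.35)
  spec <- modelSpec()
  fv <- fitVariant(g, co, spec)
  C <- as.matrix(co[, spec$covariates])
  orc <- oracleFitVariant(g, co$cwduvb, co$pheno_std, C)
  for (nm in names(orc))
    expect_equal(fv[[nm]], orc[[nm]], tolerance = 1e-8, label = nm)
})

test_that("fitVariant matches lm + sandwich HC2 as an independent cross-check", {
  set.seed(10)
  n <- 300
  co <- makeSimpleCohort(n, seed = 10)
  g <- rbinom(n, 2, 0.25)
  spec <- modelSpec()
  fv <- fitVariant(g, co, spec)
  dat <- cbind(co, g = g, ge = g * co$cwduvb)
  f <- as.formula(paste("pheno_std ~ g + ge +",
                        paste(spec$covariates, collapse = "+")))
  fit <- lm(f, data = dat)
  expect_equal(fv$beta_g, unname(coef(fit)["g"]), tolerance = 1e-10)
  expect_equal(fv$beta_gxe, unname(coef(fit)["ge"]), tolerance = 1e-10)
  Vr <- sandwich::vcovHC(fit, type = "HC2")
  expect_equal(fv$se_g_robust, sqrt(Vr["g", "g"]), tolerance = 1e-8)
  expect_equal(fv$se_gxe_robust, sqrt(Vr["ge", "ge"]), tolerance = 1e-8)
  expect_equal(fv$cov_g_gxe_robust, Vr["g", "ge"], tolerance = 1e-8)
})

test_that("orthogonalized dosage reduces the marginal fit to simple regression", {
  set.seed(11)
  n <- 400
  co <- makeSimpleCohort(n, seed = 11)
  spec <- modelSpec()
  X <- cbind(1, as.matrix(co[, spec$covariates]))
  g0 <- rnorm(n)
  g <- g0 - X %*% solve(crossprod(X), crossprod(X, g0))  # orthogonal to X
  g <- as.vector(g - min(g)); g <- g / max(g) * 2        # rescale into [0,2]
  g <- g - X %*% solve(crossprod(X), crossprod(X, g))    # re-orthogonalize
  fv <- fitVariant(as.vector(g), co, spec)
  simple <- sum(g * co$pheno_std) / sum(g^2)
  expect_equal(fv$beta_marginal, simple, tolerance = 1e-8)
})

test_that("the scan equals per-variant direct fits and is deterministic", {
  set.seed(12)
  g <- makeSimpleGenotypes(200, 50, maf = runif(50, 0.05, 0.5), seed = 12)
  co <- makeSimpleCohort(200, seed = 12)
  spec <- modelSpec()
  res <- runGweis(g, co, spec)
  expect_equal(nrow(res), 50)
  res2 <- runGweis(g, co, spec)
  expect_identical(res, res2)
  D <- dosage(g)
  fields <- c("beta_marginal", "se_marginal", "beta_g", "beta_gxe",
              "se_g_robust", "se_gxe_robust", "cov_g_gxe_robust",
              "se_g_model", "se_gxe_model", "cov_g_gxe_model")
  for (j in seq(1, 50, by = 7)) {
    fv <- fitVariant(D[, j], co, spec)
    expect_lt(max(abs(unlist(fv[fields]) - unlist(res[j, fields]))), 1e-8)
  }
})

test_that("the joint p-value is recomputable from the stored covariance", {
  g <- makeSimpleGenotypes(300, 20, maf = runif(20, 0.1, 0.5), seed = 13)
  co <- makeSimpleCohort(300, seed = 13)
  res <- runGweis(g, co)
  V11 <- res$se_g_robust^2; V22 <- res$se_gxe_robust^2
  V12 <- res$cov_g_gxe_robust
  w2 <- (res$beta_g^2 * V22 - 2 * res$beta_g * res$beta_gxe * V12 +
           res$beta_gxe^2 * V11) / (V11 * V22 - V12^2)
  expect_equal(pchisq(w2, 2, lower.tail = FALSE), res$p_joint,
               tolerance = 1e-12)
  expect_true(all(res$joint_stat >= 0))
  expect_true(all(res$p_int > 0 & res$p_int <= 1))
})

test_that("flipping the effect allele flips betas and keeps p-values", {
  g <- makeSimpleGenotypes(250, 10, maf = runif(10, 0.1, 0.5), seed = 14)
  co <- makeSimpleCohort(250, seed = 14)
  res <- runGweis(g, co)
  gflip <- GenotypeData(2 - dosage(g), variantInfo(g),
                        sample_ids = sampleIds(g))
  resf <- runGweis(gflip, co)
  expect_equal(resf$beta_marginal, -res$beta_marginal, tolerance = 1e-10)
  expect_equal(resf$beta_g, -res$beta_g, tolerance = 1e-10)
  expect_equal(resf$beta_gxe, -res$beta_gxe, tolerance = 1e-10)
  expect_equal(resf$p_marginal, res$p_marginal, tolerance = 1e-10)
  expect_equal(resf$p_int, res$p_int, tolerance = 1e-10)
  expect_equal(resf$p_joint, res$p_joint, tolerance = 1e-10)
  expect_equal(resf$effect_allele_frequency,
               1 - res$effect_allele_frequency, tolerance = 1e-12)
})

test_that("robust and model-based SEs agree under homoskedastic noise", {
  set.seed(17)
  n <- 5000
  # exposures from the actual seasonal dose model (bounded, realistic
  # skew) rather than a heavy-tailed stand-in
  spec_g <- GridSpec(51, -1, 0.25, 2, 2)
  grid <- simulateUvbGrid(spec_g, seq(as.Date("2009-01-01"),
                                      as.Date("2010-12-31"), "day"),
                          cloud_sd = 0.2, seed = 17)
  days <- seq(as.Date("2009-06-01"), as.Date("2010-05-31"), "day")
  res_tab <- data.frame(participant_id = as.character(seq_along(days)),
                        lat = 51.1, lon = -0.9, sample_date = days)
  by_day <- buildExposureTable(res_tab, grid)$exposure$cwduvb
  E <- by_day[sample(length(by_day), n, replace = TRUE)]
  co <- makeSimpleCohort(n, seed = 17, E = E)
  g <- makeSimpleGenotypes(n, 10, maf = runif(10, 0.1, 0.5), seed = 17)
  res <- runGweis(g, co)  # pheno is pure homoskedastic noise
  expect_lt(max(abs(res$se_g_robust / res$se_g_model - 1)), 0.1)
  expect_lt(max(abs(res$se_gxe_robust / res$se_gxe_model - 1)), 0.1)
})

test_that("constant dosages are skipped with a reason, not fatal", {
  g <- makeSimpleGenotypes(100, 3, maf = c(0.3, 0.3, 0.3), seed = 15)
  D <- dosage(g); D[, 2] <- 1
  g2 <- GenotypeData(D, variantInfo(g), sample_ids = sampleIds(g))
  res <- runGweis(g2, makeSimpleCohort(100, seed = 15))
  expect_equal(res$status, c("ok", "constant_dosage", "ok"))
  expect_true(is.na(res$beta_g[2]))
})

test_that("exposure quintiles are balanced, stable under ties and rank-invariant", {
  x <- rnorm(100)
  q <- exposureQuintiles(x)
  expect_equal(as.vector(table(q)), rep(20, 5))
  expect_equal(exposureQuintiles(exp(x)), q)  # monotone invariance
  # all-identical values: near-equal strata by rank
  q2 <- exposureQuintiles(rep(1, 103))
  expect_true(all(abs(table(q2) - 103 / 5) <= 1))
  expect_error(exposureQuintiles(1:3), "at least 5")
})

test_that("stratified runs re-standardize within stratum and partition n", {
  g <- makeSimpleGenotypes(300, 15, maf = runif(15, 0.1, 0.5), seed = 16)
  co <- makeSimpleCohort(300, seed = 16)
  # single stratum: identical to the plain scan
  one <- runStratified(g, co, strata = rep("all", 300), min_stratum = 10)
  plain <- runGweis(g, co)
  expect_equal(one$all$beta_g, plain$beta_g, tolerance = 1e-12)
  # quintiles: five tables whose sample sizes sum to n
  q <- runStratified(g, co, strata = "exposure_quintile", min_stratum = 10)
  expect_length(q, 5)
  expect_equal(sum(vapply(q, function(r) r$n[1], numeric(1))), 300)
  expect_error(runStratified(g, co, strata = rep(c("a", "b"), c(295, 5)),
                             min_stratum = 10), "stratum")
})
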