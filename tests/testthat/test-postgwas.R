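test_that("clumping keeps single significant variants and merges duplicates", {
  set.seed(20)
  g <- makeSimpleGenotypes(200, 5, maf = runif(5, 0.2, 0.5), seed = 20)
  D <- dosage(g); D[, 2] <- D[, 1]  # identical dosage columns 1 and 2
  g <- GenotypeData(D, variantInfo(g), sample_ids = sampleIds(g))
  res <- data.frame(
    chromosome = "1", base_pair_location = 1:5 * 1000,
    variant_id = variantInfo(g)$id,
    p_joint = c(1e-10, 1e-12, 0.5, 0.5, 0.5)
  )
  leads <- clumpLeads(res, g)
  expect_equal(leads$variant_id, "snp0002")  # the smaller p of the r2=1 pair
  res$p_joint <- c(1e-10, 0.5, 0.5, 0.5, 0.5)
  expect_equal(clumpLeads(res, g)$variant_id, "snp0001")
  res$p_joint <- rep(0.5, 5)
  expect_equal(nrow(clumpLeads(res, g)), 0)  # nothing significant: empty set
})

test_that("clumping matches an exhaustive greedy oracle on an LD-block fixture", {
  set.seed(21)
  n <- 400
  # three LD blocks of 4: within-block duplicates with noise, across free
  base <- sapply(1:3, function(i) rbinom(n, 2, 0.4))
  D <- matrix(0, n, 12)
  for (b in 1:3) for (k in 1:4) {
    col <- (b - 1) * 4 + k
    flip <- rbinom(n, 1, 0.08)
    D[, col] <- pmin(2, pmax(0, ifelse(flip == 1, 2 - base[, b], base[, b])))
  }
  g <- GenotypeData(D, data.frame(chrom = "1", pos = 1:12 * 1e5,
                                  id = sprintf("v%02d", 1:12),
                                  ref = "A", alt = "G"),
                    sample_ids = sprintf("s%04d", 1:n))
  p <- runif(12) * 1e-9
  res <- data.frame(chromosome = "1", base_pair_location = 1:12 * 1e5,
                    variant_id = sprintf("v%02d", 1:12), p_joint = p)
  leads <- clumpLeads(res, g, p_threshold = 5e-8, r2_threshold = 0.1)
  r2mat <- cor(D)^2
  oracle <- oracleClump(p, r2mat, 5e-8, 0.1)
  expect_equal(leads$variant_id, sprintf("v%02d", oracle))
  # invariant: pairwise r2 of leads below threshold
  li <- match(leads$variant_id, sprintf("v%02d", 1:12))
  if (length(li) > 1) {
    rr <- cor(D[, li])^2; diag(rr) <- 0
    expect_lt(max(rr), 0.1)
  }
  # every removed significant variant is in LD with at least one lead
  removed <- setdiff(1:12, li)
  expect_true(all(apply(r2mat[removed, li, drop = FALSE], 1, max) >= 0.1))
})

test_that("stepwise conditional selection recovers independent causals and
           collapses perfect LD", {
  set.seed(22)
  n <- 3000
  g <- makeSimpleGenotypes(n, 30, maf = runif(30, 0.2, 0.5), seed = 22)
  D <- dosage(g)
  D[, 10] <- D[, 5]  # perfect-LD copy of causal variant 5
  g <- GenotypeData(D, variantInfo(g), sample_ids = sampleIds(g))
  co <- makeSimpleCohort(n, seed = 22)
  # two causal variants in linkage equilibrium (5 and 20)
  y <- 0.25 * D[, 5] + 0.25 * D[, 20] + rnorm(n)
  co$pheno_std <- (y - mean(y)) / sd(y)
  sel <- stepwiseConditionalSelection(g, co)
  expect_setequal(intersect(sel$variant_id, c("snp0005", "snp0020")),
                  c("snp0005", "snp0020"))
  # exactly one of the r2 = 1 pair is selected
  expect_equal(length(intersect(sel$variant_id,
                                c("snp0005", "snp0010"))), 1)
  # final joint fit: all conditional p below threshold
  expect_true(all(sel$p < 5e-8))
})

test_that("stepwise selection returns an empty set on null genotypes", {
  set.seed(23)
  g <- makeSimpleGenotypes(500, 40, maf = runif(40, 0.1, 0.5), seed = 23)
  co <- makeSimpleCohort(500, seed = 23)
  sel <- stepwiseConditionalSelection(g, co)
  expect_equal(nrow(sel), 0)
})

test_that("variance explained follows 2 b^2 f (1-f) and matches empirical R2", {
  expect_equal(varianceExplained(0, 0.3)$total, 0)
  expect_equal(varianceExplained(0.1, 0.5)$total, 0.005, tolerance = 1e-12)
  expect_error(varianceExplained(0.1, 1), "inside")
  set.seed(24)
  n <- 10000; m <- 12
  f <- runif(m, 0.1, 0.5)
  D <- sapply(f, function(ff) rbinom(n, 2, ff))
  b <- rnorm(m, 0, 0.08)
  y <- as.vector(D %*% b) + rnorm(n)
  y <- (y - mean(y)) / sd(y)
  # marginal per-SNP estimates on the standardized trait
  bh <- sapply(seq_len(m), function(j) coef(lm(y ~ D[, j]))[2])
  ve <- varianceExplained(bh, colMeans(D) / 2)
  r2 <- summary(lm(y ~ D))$r.squared
  expect_lt(abs(ve$total - r2) / r2, 0.2)
})

test_that("sign concordance test equals exact binomial enumeration", {
  r <- signConcordanceTest(rep(1, 10), rep(1, 10))
  expect_equal(r$p_binom, 2^-9, tolerance = 1e-12)
  expect_equal(r$n_concordant, 10)
  mixed <- signConcordanceTest(c(rep(1, 5), rep(-1, 5)), rep(1, 10))
  expect_equal(mixed$p_binom, 1.0)
  set.seed(25)
  for (i in 1:20) {
    n <- sample(5:30, 1); k <- sample(0:n, 1)
    d <- c(rep(1, k), rep(1, n - k)); rep_ <- c(rep(1, k), rep(-1, n - k))
    out <- signConcordanceTest(d, rep_)
    expect_equal(out$p_binom, oracleBinomTwoSided(k, n), tolerance = 1e-9)
  }
  # zero betas are excluded from both counts
  z <- signConcordanceTest(c(0, 1, 1), c(1, 1, 1))
  expect_equal(z$n_total, 2)
  expect_error(signConcordanceTest(NA_real_, 1), "overlap")
})

test_that("sign concordance flip symmetries hold", {
  set.seed(26)
  d <- rnorm(40); r <- rnorm(40)
  a <- signConcordanceTest(d, r)
  b <- signConcordanceTest(d, -r)      # one cohort flipped
  expect_equal(b$n_concordant, a$n_total - a$n_concordant)
  c2 <- signConcordanceTest(-d, -r)    # both flipped: identical
  expect_equal(c2$p_binom, a$p_binom)
  expect_equal(c2$n_concordant, a$n_concordant)
})

test_that("risk scores match hand-computed values and are linear in weights", {
  D <- matrix(c(0, 1,
                2, 1,
                1, 0), nrow = 2)  # 2 samples x 3 variants
  g <- GenotypeData(D, data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                                  id = c("a", "b", "c"), ref = "A",
                                  alt = "G"),
                    sample_ids = c("p1", "p2"))
  w <- data.frame(variant_id = c("a", "b", "c"), effect_allele = "G",
                  beta_marginal = c(0.1, -0.2, 0.3),
                  beta_g = c(0.05, 0.1, -0.1),
                  beta_gxe = c(0.01, 0, 0.02))
  E <- c(2, 4)
  s <- buildRiskScores(g, w, E)
  # by hand: p1 marginal = 0*0.1 + 2*(-0.2) + 1*0.3 = -0.1
  expect_equal(s$marginal_score, c(-0.1, 0.1 - 0.2), tolerance = 1e-12)
  # p1 interaction = 0*(.05+2*.01) + 2*(.1+0) + 1*(-.1+2*.02) = 0.2 - 0.06
  expect_equal(s$interaction_score[1], 0.14, tolerance = 1e-12)
  expect_equal(s$interaction_score[2],
               1 * (0.05 + 4 * 0.01) + 1 * (0.1) + 0, tolerance = 1e-12)
  # zero weights give zero scores
  w0 <- w; w0[, 3:5] <- 0
  expect_equal(unlist(buildRiskScores(g, w0, E)[, 2:3]),
               setNames(rep(0, 4), NULL), ignore_attr = TRUE)
  # linearity
  w2 <- w; w2[, 3:5] <- 2 * w[, 3:5]
  s2 <- buildRiskScores(g, w2, E)
  expect_equal(s2$marginal_score, 2 * s$marginal_score, tolerance = 1e-12)
  expect_equal(s2$interaction_score, 2 * s$interaction_score,
               tolerance = 1e-12)
  # allele mismatch is an error
  wbad <- w; wbad$effect_allele[1] <- "T"
  expect_error(buildRiskScores(g, wbad, E), "allele")
})

test_that("risk score evaluation detects true scores and not permuted ones", {
  set.seed(27)
  cfg <- simConfig(seed = 27, n_samples = 3000, n_variants = 60,
                   n_causal_main = 15, h2_target = 0.2,
                   maf_range = c(0.1, 0.5))
  sim <- simulateGenotypes(cfg)
  sc <- simulateCohort(sim$genotypes, rlnorm(3000, 3, 0.5), cfg)
  truth <- sc$truth$variants
  w <- data.frame(variant_id = truth$id, effect_allele = "G",
                  beta_marginal = truth$beta_g, beta_g = truth$beta_g,
                  beta_gxe = truth$beta_gxe)
  s <- buildRiskScores(sim$genotypes, w, sc$cohort$cwduvb)
  ev <- evaluateRiskScores(s, sc$cohort)
  expect_true(all(ev$slope > 0))
  expect_true(all(ev$p < 0.05))
  # decile contrast sign equals slope sign
  expect_true(all(sign(ev$decile_diff) == sign(ev$slope)))
  # permuted score: slope within 2 SE of zero
  sperm <- s; sperm$marginal_score <- sample(s$marginal_score)
  sperm$interaction_score <- sample(s$interaction_score)
  evp <- evaluateRiskScores(sperm, sc$cohort)
  expect_true(all(abs(evp$slope) < 2.5 * evp$se + 1e-12))
})
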