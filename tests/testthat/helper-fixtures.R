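# Small fixtures built in code at test time.

# independent binomial genotypes (no LD), samples x variants
makeSimpleGenotypes <- function(n, m, maf = 0.3, seed = 1) {
  set.seed(seed)
  maf <- rep_len(maf, m)
  D <- sapply(maf, function(f) rbinom(n, 2, f))
  GenotypeData(
    D,
    data.frame(chrom = "1", pos = seq_len(m) * 1000L,
               id = sprintf("snp%04d", seq_len(m)), ref = "A", alt = "G",
               info_score = NA_real_),
    sample_ids = sprintf("s%04d", seq_len(n))
  )
}

# minimal analysis-ready cohort: null phenotype unless y is supplied
makeSimpleCohort <- function(n, seed = 1, y = NULL, E = NULL) {
  set.seed(seed + 5000)
  if (is.null(E)) E <- rlnorm(n, 3, 0.5)
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  raw <- if (is.null(y)) rlnorm(n, log(48), 0.35) else exp(log(48) + 0.35 * y)
  data.frame(
    participant_id = sprintf("s%04d", seq_len(n)),
    pheno_raw = pmax(raw, 10),
    pheno_std = preparePhenotype(pmax(raw, 10)),
    age = runif(n, 40, 70), sex = rbinom(n, 1, 0.5),
    vitd_supp = rbinom(n, 1, 0.25), fishoil_supp = rbinom(n, 1, 0.3),
    cwduvb = E, pcs
  )
}

# flat (constant-dose) grid over a small extent
makeConstantGrid <- function(value = 2, n_days = 400,
                             start = as.Date("2009-01-01")) {
  spec <- GridSpec(lat_min = 50, lon_min = -4, cell_size_deg = 0.25,
                   n_lat = 8, n_lon = 8)
  DailyDoseGrid(spec, seq(start, by = "day", length.out = n_days),
                matrix(value, n_days, 64))
}
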