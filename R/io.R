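## Plain-text readers and writers for the pipeline's external formats:
## long-format dose grids, residence tables, genotype dosage matrices
## (TSV or VCF), and GWAS-SSF-style summary statistics.

#' Read and write daily dose grids
#'
#' The grid file is TSV with columns
#' \code{date  lat_idx  lon_idx  dose_kjm2} (ISO-8601 dates, 0-based
#' cell indices, missing doses as empty fields), preceded by a header
#' block of \code{#key=value} lines giving the grid spec
#' (\code{lat_min}, \code{lon_min}, \code{cell_size_deg}, \code{n_lat},
#' \code{n_lon}). Days absent from the file are missing for all cells.
#'
#' @param path file path.
#' @return \code{readDoseGrid} returns a \linkS4class{DailyDoseGrid}.
#' @export
readDoseGrid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1)
    if (!startsWith(line, "#")) break
    hdr <- c(hdr, sub("^#\\s*", "", line))
  }
  kv <- strsplit(hdr, "=")
  vals <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                   vapply(kv, `[`, "", 1))
  spec <- GridSpec(vals["lat_min"], vals["lon_min"],
                   vals["cell_size_deg"], vals["n_lat"], vals["n_lon"])
  tab <- read.delim(path, comment.char = "#", na.strings = c("", "NA"),
                    colClasses = c("character", "integer", "integer",
                                   "numeric"))
  dates <- seq(as.Date(min(tab$date)), as.Date(max(tab$date)), by = "day")
  dose <- matrix(NA_real_, length(dates), spec@n_lat * spec@n_lon)
  row <- as.integer(as.Date(tab$date) - dates[1]) + 1L
  col <- tab$lat_idx * spec@n_lon + tab$lon_idx + 1L
  dose[cbind(row, col)] <- tab$dose_kjm2
  DailyDoseGrid(spec, dates, dose)
}

#' @param x a \linkS4class{DailyDoseGrid}.
#' @rdname readDoseGrid
#' @return \code{writeDoseGrid} returns \code{path} invisibly.
#' @export
writeDoseGrid <- function(x, path) {
  spec <- x@grid
  hdr <- sprintf("#%s=%s",
                 c("lat_min", "lon_min", "cell_size_deg", "n_lat", "n_lon"),
                 c(spec@lat_min, spec@lon_min, spec@cell_size_deg,
                   spec@n_lat, spec@n_lon))
  nd <- length(x@dates); nc <- ncol(x@dose)
  cells <- seq_len(nc) - 1L
  tab <- data.frame(
    date = rep(format(x@dates, "%Y-%m-%d"), nc),
    lat_idx = rep(cells %/% spec@n_lon, each = nd),
    lon_idx = rep(cells %% spec@n_lon, each = nd),
    dose_kjm2 = ifelse(is.na(as.vector(x@dose)), "",
                       formatC(as.vector(x@dose), digits = 8,
                               format = "g"))
  )
  writeLines(hdr, path)
  suppressWarnings(write.table(tab, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a residence table
#'
#' TSV with \code{participant_id}, \code{sample_date} and either
#' \code{easting}/\code{northing} (metres, OSGB) or
#' \code{lat}/\code{lon} (degrees).
#'
#' @param path file path.
#' @return data.frame with \code{sample_date} parsed as \code{Date}.
#' @export
readResidenceTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "sample_date")
  if (!all(need %in% colnames(tab)))
    stop("residence table needs columns: ", paste(need, collapse = ", "))
  if (!(all(c("lat", "lon") %in% colnames(tab)) ||
        all(c("easting", "northing") %in% colnames(tab))))
    stop("residence table needs lat/lon or easting/northing")
  tab$sample_date <- as.Date(tab$sample_date)
  tab
}

#' Write an exposure table
#'
#' @param x the \code{exposure} data.frame from
#'   \code{\link{buildExposureTable}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeExposureTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write genotype dosage matrices as TSV
#'
#' \code{writeGenotypeTsv} writes \code{<prefix>.dosage.tsv} (samples x
#' variants, first column \code{participant_id}, missing as empty
#' fields) and a variant-metadata sidecar \code{<prefix>.variants.tsv}
#' (\code{chrom pos id ref alt info_score}).
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param prefix output path prefix.
#' @return \code{writeGenotypeTsv}: the two paths, invisibly;
#'   \code{readGenotypeTsv}: a \linkS4class{GenotypeData}.
#' @export
writeGenotypeTsv <- function(g, prefix) {
  d <- dosage(g)
  df <- as.data.frame(
    matrix(ifelse(is.na(d), "", formatC(d, digits = 8, format = "g")),
           nrow(d), ncol(d)))
  colnames(df) <- variantInfo(g)$id
  df <- cbind(participant_id = sampleIds(g), df)
  p1 <- paste0(prefix, ".dosage.tsv")
  p2 <- paste0(prefix, ".variants.tsv")
  write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(variantInfo(g), p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(dosage = p1, variants = p2))
}

#' @rdname writeGenotypeTsv
#' @export
readGenotypeTsv <- function(prefix) {
  d <- read.delim(paste0(prefix, ".dosage.tsv"), check.names = FALSE,
                  na.strings = c("", "NA"))
  v <- read.delim(paste0(prefix, ".variants.tsv"),
                  colClasses = c(chrom = "character"))
  ids <- d$participant_id
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  GenotypeData(m, v, sample_ids = ids)
}

#' Read genotype dosages from a VCF
#'
#' Uses the \pkg{VariantAnnotation} parser; the \code{DS} FORMAT field
#' is preferred, otherwise dosages are derived from \code{GT} hard
#' calls. Requires \pkg{VariantAnnotation} to be installed.
#'
#' @param path VCF file path.
#' @return a \linkS4class{GenotypeData}.
#' @export
readGenotypeVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readGenotypeVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    d <- geno$DS  # variants x samples
    storage.mode(d) <- "double"
  } else if ("GT" %in% names(geno)) {
    gt <- geno$GT
    d <- matrix(NA_real_, nrow(gt), ncol(gt))
    d[gt %in% c("0/0", "0|0")] <- 0
    d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    d[gt %in% c("1/1", "1|1")] <- 2
  } else stop("VCF has neither DS nor GT")
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = names(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(as.list(VariantAnnotation::alt(vcf)),
                 function(a) as.character(a)[1], ""),
    info_score = NA_real_
  )
  GenotypeData(t(d), variants, sample_ids = colnames(d))
}

#' Read and write GWAS summary statistics
#'
#' TSV with the GWAS-SSF-compatible core columns produced by
#' \code{\link{runGweis}}.
#'
#' @param results a \code{\link{runGweis}} table.
#' @param path file path.
#' @return \code{writeSummaryStats}: \code{path} invisibly;
#'   \code{readSummaryStats}: a data.frame.
#' @export
writeSummaryStats <- function(results, path) {
  cols <- c("chromosome", "base_pair_location", "variant_id",
            "effect_allele", "other_allele", "effect_allele_frequency",
            "n", "beta_marginal", "se_marginal", "p_marginal", "beta_g",
            "beta_gxe", "se_g_robust", "se_gxe_robust",
            "cov_g_gxe_robust", "se_g_model", "se_gxe_model",
            "cov_g_gxe_model", "p_int", "p_joint")
  write.table(results[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeSummaryStats
#' @export
readSummaryStats <- function(path) {
  read.delim(path, colClasses = c(chromosome = "character"))
}
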