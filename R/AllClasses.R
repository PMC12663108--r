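#' @import methods
#' @importFrom stats complete.cases cor dnorm median pchisq pnorm qchisq
#'   qnorm quantile rbinom rlnorm rnorm runif sd var setNames binom.test
#'   cor.test lm coef vcov
#' @importFrom utils read.delim write.table head tail
NULL

#' Specification of a regular latitude/longitude grid
#'
#' Describes a quarter-degree-style latitude-by-longitude grid of the kind
#' used by gridded daily UVB dose products. Cells are half-open and anchored
#' at their lower-left (south-west) corner: cell \code{(i, j)} covers
#' \code{[lat_min + i*s, lat_min + (i+1)*s)} by
#' \code{[lon_min + j*s, lon_min + (j+1)*s)} with 0-based indices.
#'
#' @slot lat_min southern edge of the grid, degrees latitude.
#' @slot lon_min western edge of the grid, degrees longitude.
#' @slot cell_size_deg cell edge length in degrees (default 0.25).
#' @slot n_lat,n_lon number of rows (latitude) and columns (longitude).
#'
#' @export
setClass("GridSpec",
  representation(
    lat_min = "numeric", lon_min = "numeric",
    cell_size_deg = "numeric", n_lat = "integer", n_lon = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- NULL
  if (length(object@cell_size_deg) != 1L || object@cell_size_deg <= 0)
    msg <- c(msg, "cell_size_deg must be a single positive number")
  if (object@n_lat < 1L || object@n_lon < 1L)
    msg <- c(msg, "n_lat and n_lon must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @param lat_min,lon_min,cell_size_deg,n_lat,n_lon see slots.
#' @return \code{GridSpec} returns a \code{GridSpec} object.
#' @rdname GridSpec-class
#' @export
GridSpec <- function(lat_min, lon_min, cell_size_deg = 0.25, n_lat, n_lon) {
  new("GridSpec",
    lat_min = as.numeric(lat_min), lon_min = as.numeric(lon_min),
    cell_size_deg = as.numeric(cell_size_deg),
    n_lat = as.integer(n_lat), n_lon = as.integer(n_lon)
  )
}

#' Daily ambient UVB doses on a regular grid
#'
#' Holds daily vitamin-D-effective UVB doses (kJ/m^2) for every cell of a
#' \linkS4class{GridSpec} over a contiguous range of calendar days. The dose
#' matrix is days x cells with cells in row-major (latitude-major) order:
#' column \code{i * n_lon + j + 1} is cell \code{(i, j)}. Missing daily
#' values are \code{NA}; present values must be non-negative.
#'
#' @slot grid a \linkS4class{GridSpec}.
#' @slot dates contiguous \code{Date} vector, one entry per matrix row.
#' @slot dose numeric matrix, \code{length(dates)} x \code{n_lat*n_lon}.
#'
#' @seealso \code{\link{simulateUvbGrid}}, \code{\link{readDoseGrid}},
#'   \code{\link{buildExposureTable}}
#' @export
setClass("DailyDoseGrid",
  representation(grid = "GridSpec", dates = "Date", dose = "matrix")
)

setValidity("DailyDoseGrid", function(object) {
  msg <- NULL
  nc <- object@grid@n_lat * object@grid@n_lon
  if (ncol(object@dose) != nc)
    msg <- c(msg, sprintf("dose has %d columns, grid has %d cells",
                          ncol(object@dose), nc))
  if (nrow(object@dose) != length(object@dates))
    msg <- c(msg, "dose must have one row per date")
  if (length(object@dates) > 1L &&
      !all(diff(as.integer(object@dates)) == 1L))
    msg <- c(msg, "dates must be contiguous calendar days")
  if (any(object@dose < 0, na.rm = TRUE))
    msg <- c(msg, "doses must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' @param grid a \linkS4class{GridSpec}.
#' @param dates contiguous \code{Date} vector.
#' @param dose days x cells numeric matrix.
#' @return \code{DailyDoseGrid} returns a \code{DailyDoseGrid} object.
#' @rdname DailyDoseGrid-class
#' @export
DailyDoseGrid <- function(grid, dates, dose) {
  new("DailyDoseGrid", grid = grid, dates = as.Date(dates),
      dose = as.matrix(dose))
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells of %g deg, SW corner (%g, %g)\n",
    object@n_lat, object@n_lon, object@cell_size_deg,
    object@lat_min, object@lon_min))
})

setMethod("show", "DailyDoseGrid", function(object) {
  cat(sprintf(
    "DailyDoseGrid: %d days (%s .. %s) x %d cells; %.1f%% missing\n",
    length(object@dates), min(object@dates), max(object@dates),
    ncol(object@dose), 100 * mean(is.na(object@dose))))
  show(object@grid)
})

#' Sample-by-variant genotype dosages
#'
#' \code{GenotypeData} wraps a
#' \link[SummarizedExperiment]{SummarizedExperiment} carrying ALT-allele
#' dosages in assay \code{"dosage"} (variants as rows, samples as columns,
#' values in [0, 2] or \code{NA}) together with variant metadata in
#' \code{rowData} (\code{chrom}, \code{pos}, \code{id}, \code{ref},
#' \code{alt} and optional \code{info_score}).
#'
#' @slot se the underlying SummarizedExperiment.
#'
#' @seealso \code{\link{dosage}}, \code{\link{variantInfo}},
#'   \code{\link{sampleIds}}, \code{\link{simulateGenotypes}}
#' @export
setClass("GenotypeData", representation(se = "SummarizedExperiment"))

setValidity("GenotypeData", function(object) {
  msg <- NULL
  se <- object@se
  if (!"dosage" %in% SummarizedExperiment::assayNames(se))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(se, "dosage")
  if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  rd <- SummarizedExperiment::rowData(se)
  need <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("rowData lacks columns:", paste(miss, collapse = ", ")))
  if ("id" %in% colnames(rd) && anyDuplicated(rd$id))
    msg <- c(msg, "variant ids must be unique")
  if (all(c("chrom", "pos") %in% colnames(rd))) {
    bychrom <- split(rd$pos, as.character(rd$chrom))
    if (!all(vapply(bychrom, function(p) !is.unsorted(p), logical(1))))
      msg <- c(msg, "pos must be nondecreasing within chrom")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix of ALT dosages, samples x variants (the
#'   natural orientation of most text inputs; it is transposed into the
#'   variants x samples SummarizedExperiment layout internally).
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{id}, \code{ref}, \code{alt} and optionally \code{info_score}.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   rownames of \code{dosage}.
#'
#' @return a \linkS4class{GenotypeData}.
#' @examples
#' d <- matrix(c(0, 1, 2, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), NULL))
#' v <- data.frame(chrom = "1", pos = c(100L, 200L), id = c("v1", "v2"),
#'                 ref = "A", alt = "G")
#' g <- GenotypeData(d, v)
#' dim(dosage(g))
#' @export
GenotypeData <- function(dosage, variants, sample_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_len(nrow(dosage)))
  variants <- as.data.frame(variants)
  if (!"info_score" %in% colnames(variants)) variants$info_score <- NA_real_
  stopifnot(nrow(variants) == ncol(dosage))
  m <- t(dosage)
  dimnames(m) <- list(variants$id, sample_ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = m),
    rowData = S4Vectors::DataFrame(variants)
  )
  new("GenotypeData", se = se)
}

setMethod("show", "GenotypeData", function(object) {
  se <- object@se
  d <- SummarizedExperiment::assay(se, "dosage")
  cat(sprintf(
    "GenotypeData: %d samples x %d variants; %.2f%% missing dosages\n",
    ncol(se), nrow(se), 100 * mean(is.na(d))))
  rd <- SummarizedExperiment::rowData(se)
  cat(sprintf("chromosomes: %s\n",
              paste(unique(as.character(rd$chrom)), collapse = ", ")))
})
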