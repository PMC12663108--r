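#' Accessors for GenotypeData
#'
#' \code{dosage} returns the samples x variants dosage matrix (note the
#' orientation: internal storage is variants x samples),
#' \code{variantInfo} the variant metadata data.frame, \code{sampleIds}
#' the sample identifiers, and \code{nVariants}/\code{nSamples} the
#' dimensions.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @return see description.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname genotype-accessors
#' @export
setMethod("dosage", "GenotypeData", function(x) {
  t(SummarizedExperiment::assay(x@se, "dosage"))
})

#' @rdname genotype-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname genotype-accessors
#' @export
setMethod("variantInfo", "GenotypeData", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x@se))
})

#' @rdname genotype-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname genotype-accessors
#' @export
setMethod("sampleIds", "GenotypeData", function(x) colnames(x@se))

#' @rdname genotype-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname genotype-accessors
#' @export
setMethod("nVariants", "GenotypeData", function(x) nrow(x@se))

#' @rdname genotype-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname genotype-accessors
#' @export
setMethod("nSamples", "GenotypeData", function(x) ncol(x@se))

#' Subset a GenotypeData by samples and/or variants
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param i sample index (logical, integer or character).
#' @param j variant index (logical, integer or character variant ids).
#' @param ... ignored.
#' @param drop ignored; subsetting never drops dimensions.
#' @return a \linkS4class{GenotypeData}.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  se <- x@se
  if (!missing(j)) se <- se[j, , drop = FALSE]
  if (!missing(i)) se <- se[, i, drop = FALSE]
  new("GenotypeData", se = se)
})

#' Accessors for DailyDoseGrid
#'
#' @param x a \linkS4class{DailyDoseGrid}.
#' @return \code{gridSpec} the \linkS4class{GridSpec}, \code{gridDates}
#'   the date vector, \code{gridDose} the days x cells dose matrix.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "DailyDoseGrid", function(x) x@grid)

#' @rdname grid-accessors
#' @export
setGeneric("gridDates", function(x) standardGeneric("gridDates"))

#' @rdname grid-accessors
#' @export
setMethod("gridDates", "DailyDoseGrid", function(x) x@dates)

#' @rdname grid-accessors
#' @export
setGeneric("gridDose", function(x) standardGeneric("gridDose"))

#' @rdname grid-accessors
#' @export
setMethod("gridDose", "DailyDoseGrid", function(x) x@dose)
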