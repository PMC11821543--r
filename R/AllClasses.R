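#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData rowData
NULL

FREQ_CLASSES <- c("fixed", "polymorphic_known", "polymorphic_novel", "private")
SD_KINDS <- c("intrachromosomal", "interchromosomal", "both")

#' SDRegionCatalog: flattened SD regions with per-haplotype presence
#'
#' A container for a catalog of nonoverlapping segmental-duplication (SD)
#' regions on a common reference frame. Rows are regions (a
#' [GenomicRanges::GRanges] with frequency class, intra/inter kind and
#' reference-presence annotations), columns are haplotypes, and the single
#' `presence` assay holds the 0/1 haplotype presence matrix. Built with
#' [buildCatalog()].
#'
#' Region coordinates are stored 1-based inside the `GRanges` (Bioconductor
#' convention); all on-disk formats read and written by the package are
#' 0-based half-open (BED convention).
#'
#' @slot se A `RangedSummarizedExperiment` with assay `presence`.
#' @export
setClass("SDRegionCatalog", representation(se = "RangedSummarizedExperiment"))

setValidity("SDRegionCatalog", function(object) {
    se <- object@se
    msg <- character()
    if (!"presence" %in% SummarizedExperiment::assayNames(se))
        msg <- c(msg, "assay 'presence' is required")
    rr <- SummarizedExperiment::rowRanges(se)
    need <- c("freq_class", "kind", "in_reference", "haplotype_count",
              "sample_count")
    miss <- setdiff(need, colnames(S4Vectors::mcols(rr)))
    if (length(miss))
        msg <- c(msg, paste("missing rowRanges columns:",
                            paste(miss, collapse = ", ")))
    if (!length(msg)) {
        pres <- SummarizedExperiment::assay(se, "presence")
        if (!all(pres %in% c(0L, 1L)))
            msg <- c(msg, "presence entries must be 0/1")
        if (!identical(as.integer(rowSums(pres)),
                       as.integer(S4Vectors::mcols(rr)$haplotype_count)))
            msg <- c(msg, "haplotype_count must equal rowSums(presence)")
        if (!all(S4Vectors::mcols(rr)$freq_class %in% FREQ_CLASSES))
            msg <- c(msg, "invalid freq_class value")
        red <- GenomicRanges::reduce(rr, ignore.strand = TRUE)
        if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(rr)))
            msg <- c(msg, "regions must be pairwise nonoverlapping")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an SDRegionCatalog from regions and a presence matrix
#'
#' @param regions `GRanges` of nonoverlapping regions with metadata columns
#'   `freq_class`, `kind`, `in_reference`, `haplotype_count`, `sample_count`.
#' @param presence integer 0/1 matrix, regions x haplotypes, with haplotype
#'   ids as column names.
#' @param labels population labels data frame (see [readPopulationLabels()]),
#'   stored in the catalog metadata.
#' @return An [SDRegionCatalog-class] object.
#' @export
SDRegionCatalog <- function(regions, presence, labels = NULL) {
    stopifnot(length(regions) == nrow(presence))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(presence = presence), rowRanges = regions)
    if (!is.null(labels)) S4Vectors::metadata(se)$labels <- labels
    methods::new("SDRegionCatalog", se = se)
}

#' @describeIn SDRegionCatalog-class region `GRanges`
#' @param x,object An `SDRegionCatalog`.
#' @export
regions <- function(x) SummarizedExperiment::rowRanges(x@se)

#' @describeIn SDRegionCatalog-class 0/1 presence matrix (regions x haplotypes)
#' @export
presenceMatrix <- function(x) SummarizedExperiment::assay(x@se, "presence")

#' @describeIn SDRegionCatalog-class haplotype identifiers (column order)
#' @export
haplotypeIds <- function(x) colnames(SummarizedExperiment::assay(x@se, "presence"))

#' @describeIn SDRegionCatalog-class population label table stored at build time
#' @export
catalogLabels <- function(x) S4Vectors::metadata(x@se)$labels

setMethod("show", "SDRegionCatalog", function(object) {
    rr <- regions(object)
    cat("SDRegionCatalog with", length(rr), "regions x",
        ncol(presenceMatrix(object)), "haplotypes\n")
    cat("  union bp:", sum(GenomicRanges::width(rr)), "\n")
    tab <- table(factor(S4Vectors::mcols(rr)$freq_class, levels = FREQ_CLASSES))
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("length", "SDRegionCatalog", function(x) length(regions(x)))

#' CopyNumberExperiment: diploid copy numbers per unit and sample
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] extension holding a
#' diploid copy-number matrix (assay `cn`) for genes or gene families
#' (rows) across samples (columns). `metadata(x)$method` records whether the
#' values come from assembly paralog counting (`"assembly"`) or windowed
#' read depth (`"read_depth"`); `metadata(x)$unit` is `"gene"` or `"family"`.
#'
#' @export
setClass("CopyNumberExperiment", contains = "SummarizedExperiment")

setValidity("CopyNumberExperiment", function(object) {
    msg <- character()
    if (!"cn" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'cn' is required")
    else {
        cn <- SummarizedExperiment::assay(object, "cn")
        if (any(cn < 0, na.rm = TRUE)) msg <- c(msg, "negative copy number")
    }
    md <- S4Vectors::metadata(object)
    if (!isTRUE(md$unit %in% c("gene", "family")))
        msg <- c(msg, "metadata 'unit' must be 'gene' or 'family'")
    if (!isTRUE(md$method %in% c("assembly", "read_depth")))
        msg <- c(msg, "metadata 'method' must be 'assembly' or 'read_depth'")
    if (length(msg)) msg else TRUE
})

#' Construct a CopyNumberExperiment
#'
#' @param cn numeric matrix, units x samples (row/col names required).
#' @param unit `"gene"` or `"family"`.
#' @param method `"assembly"` or `"read_depth"`.
#' @param colData optional per-sample `DataFrame` (e.g. superpopulation).
#' @return A [CopyNumberExperiment-class].
#' @export
CopyNumberExperiment <- function(cn, unit, method, colData = NULL) {
    stopifnot(!is.null(rownames(cn)), !is.null(colnames(cn)))
    args <- list(assays = list(cn = cn))
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    S4Vectors::metadata(se)$unit <- unit
    S4Vectors::metadata(se)$method <- method
    methods::new("CopyNumberExperiment", se)
}

#' @describeIn CopyNumberExperiment-class the copy-number matrix
#' @param x A `CopyNumberExperiment`.
#' @export
copyNumber <- function(x) SummarizedExperiment::assay(x, "cn")

#' @describeIn CopyNumberExperiment-class estimation method
#' @export
cnMethod <- function(x) S4Vectors::metadata(x)$method

#' @describeIn CopyNumberExperiment-class unit of the rows (gene or family)
#' @export
cnUnit <- function(x) S4Vectors::metadata(x)$unit

setMethod("show", "CopyNumberExperiment", function(object) {
    cat("CopyNumberExperiment [", cnUnit(object), ", ", cnMethod(object),
        "]: ", nrow(object), " units x ", ncol(object), " samples\n", sep = "")
})

#' GCModel: per-GC-bin depth correction factors
#'
#' Fitted by [gcRecalibrate()] from a uniform-depth self sample; applying the
#' model divides window depth by the factor of its GC bin so that an unbiased
#' sample yields flat corrected depth.
#'
#' @slot breaks numeric vector of GC bin edges (after occupancy pooling).
#' @slot factor per-bin multiplicative depth factor (> 0).
#' @slot occupancy per-bin window counts.
#' @slot global_mean mean depth of the self sample used for fitting.
#' @export
setClass("GCModel", representation(breaks = "numeric", factor = "numeric",
                                   occupancy = "integer",
                                   global_mean = "numeric"))

setValidity("GCModel", function(object) {
    msg <- character()
    if (length(object@factor) != length(object@breaks) - 1L)
        msg <- c(msg, "need one factor per bin")
    if (any(object@factor <= 0)) msg <- c(msg, "factors must be positive")
    if (is.unsorted(object@breaks, strictly = TRUE))
        msg <- c(msg, "breaks must be strictly increasing")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GCModel", function(object) {
    cat("GCModel:", length(object@factor), "GC bins, factors in [",
        signif(min(object@factor), 3), ",", signif(max(object@factor), 3),
        "]\n")
})
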