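# Reference-divergent transcript filter and novel-gene counting for
# full-length isoform-sequencing alignments.

#' Gap-compressed alignment identity
#'
#' Conventional definition: matches over matches + mismatches + gap
#' openings, so a multi-base indel counts once.
#'
#' @param matches,mismatches,gap_openings nonnegative counts (vectorised).
#' @return identity fraction in `[0, 1]`.
#' @export
gapCompressedIdentity <- function(matches, mismatches, gap_openings) {
    if (any(matches < 0 | mismatches < 0 | gap_openings < 0))
        stop("counts must be nonnegative")
    if (any(matches + mismatches == 0))
        stop("identity undefined: no aligned bases")
    matches / (matches + mismatches + gap_openings)
}

#' Reference-divergent read filter
#'
#' A read supports a reference-divergent (novel) duplication when it aligns
#' to the haplotype assembly with identity strictly above `hap_threshold`
#' (99.9%) and to the reference with gap-compressed identity strictly below
#' `ref_threshold` (99.7%). A missing reference alignment counts as
#' identity 0.
#'
#' @param hap_identity identity to the best haplotype hit (plain identity).
#' @param ref_identity gap-compressed identity to the best reference hit
#'   (`NA` when absent).
#' @param hap_threshold,ref_threshold strict cutoffs (defaults 0.999, 0.997).
#' @return logical vector.
#' @export
referenceDivergent <- function(hap_identity, ref_identity,
                               hap_threshold = 0.999, ref_threshold = 0.997) {
    ref_identity[is.na(ref_identity)] <- 0
    hap_identity > hap_threshold & ref_identity < ref_threshold
}

#' Count novel genes per family, max over haplotypes
#'
#' Each family's count is the number of novel-gene predictions on the
#' haplotype carrying the most predictions for that family; the total is the
#' sum over families. Counting distinct `gene_id`s per (family, haplotype).
#'
#' @param predictions data.frame with columns `family_id, haplotype_id,
#'   gene_id`.
#' @return list with `per_family` (data.frame `family_id, haplotype_id,
#'   count`, the winning haplotype per family, ties broken by lexicographic
#'   haplotype id) and `total`.
#' @export
countNovelFamilies <- function(predictions) {
    if (!nrow(predictions))
        return(list(per_family = data.frame(family_id = character(),
                                            haplotype_id = character(),
                                            count = integer()), total = 0L))
    u <- unique(predictions[c("family_id", "haplotype_id", "gene_id")])
    cnt <- stats::aggregate(gene_id ~ family_id + haplotype_id, data = u,
                            FUN = length)
    names(cnt)[3] <- "count"
    cnt <- cnt[order(cnt$family_id, -cnt$count, cnt$haplotype_id), ,
               drop = FALSE]
    best <- cnt[!duplicated(cnt$family_id), , drop = FALSE]
    rownames(best) <- NULL
    list(per_family = best, total = sum(best$count))
}

#' Classify novel-gene loci against SD annotation
#'
#' A locus (reference frame) is `reference_sd` when it overlaps the
#' reference SD annotation by at least one base; otherwise
#' `haplotype_sd_only` when it lies inside any haplotype's SD region;
#' otherwise `unique`. Loci with missing coordinates are `unplaced`.
#'
#' @param loci data.frame `chrom, start, end` (NA coordinates = unplaced).
#' @param reference_sd data.frame `chrom, start, end` of reference SDs.
#' @param haplotype_sd data.frame `chrom, start, end` of SD regions seen in
#'   at least one haplotype (e.g. the catalog regions).
#' @return character vector of classes.
#' @export
classifyPredictionRegion <- function(loci, reference_sd, haplotype_sd) {
    cls <- rep("unplaced", nrow(loci))
    ok <- !(is.na(loci$chrom) | is.na(loci$start) | is.na(loci$end))
    if (!any(ok)) return(cls)
    gr <- .toGR(loci$chrom[ok], loci$start[ok], loci$end[ok])
    inRef <- if (nrow(reference_sd))
        IRanges::overlapsAny(gr, .toGR(reference_sd$chrom,
                                             reference_sd$start,
                                             reference_sd$end))
        else rep(FALSE, length(gr))
    inHap <- if (nrow(haplotype_sd))
        IRanges::overlapsAny(gr, .toGR(haplotype_sd$chrom,
                                             haplotype_sd$start,
                                             haplotype_sd$end))
        else rep(FALSE, length(gr))
    sub <- ifelse(inRef, "reference_sd",
                  ifelse(inHap, "haplotype_sd_only", "unique"))
    cls[ok] <- sub
    cls
}

#' Run the reference-divergent filter over an Iso-Seq alignment table
#'
#' Applies [gapCompressedIdentity()] to the reference-side counts,
#' [referenceDivergent()] to each read, and optionally restricts candidate
#' reads to rare duplications (families whose locus region is carried by at
#' most `max_carrier_haplotypes` haplotypes, when a catalog is supplied).
#'
#' @param alignments data.frame from [readIsoAlignments()].
#' @param catalog optional [SDRegionCatalog-class] used for the rare-region
#'   pre-filter and locus classification.
#' @param reference_sd data.frame of reference SD intervals.
#' @param max_carrier_haplotypes rare-duplication bound (default 10; `Inf`
#'   disables the pre-filter).
#' @return the alignment table with `ref_gc_identity`, `divergent`,
#'   `eligible`, `passing` and `in_sd` columns added.
#' @export
isoseqFilter <- function(alignments, catalog = NULL,
                         reference_sd = data.frame(chrom = character(),
                                                   start = integer(),
                                                   end = integer()),
                         max_carrier_haplotypes = 10) {
    al <- alignments
    al$ref_gc_identity <- ifelse(
        al$ref_matches + al$ref_mismatches == 0, 0,
        al$ref_matches /
            (al$ref_matches + al$ref_mismatches + al$ref_gap_openings))
    al$divergent <- referenceDivergent(al$hap_identity, al$ref_gc_identity)
    al$eligible <- TRUE
    hap_sd <- data.frame(chrom = character(), start = integer(),
                         end = integer())
    if (!is.null(catalog)) {
        rr <- regions(catalog)
        hap_sd <- .grDF(rr)
        if (is.finite(max_carrier_haplotypes)) {
            rare <- rr[S4Vectors::mcols(rr)$haplotype_count <=
                       max_carrier_haplotypes]
            if (length(rare)) {
                gr <- .toGR(al$locus_chrom, al$locus_start, al$locus_end)
                al$eligible <- IRanges::overlapsAny(gr, rare)
            } else al$eligible <- FALSE
        }
    }
    al$passing <- al$divergent & al$eligible
    loci <- data.frame(chrom = al$locus_chrom, start = al$locus_start,
                       end = al$locus_end)
    al$in_sd <- classifyPredictionRegion(loci, reference_sd, hap_sd)
    al
}
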