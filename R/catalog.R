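# Projection of assembly-frame intervals onto the reference, flattening to
# nonoverlapping regions, presence/frequency classification, accumulation.

#' Project an assembly-frame interval onto the reference through alignment blocks
#'
#' Blocks are gap-free 1-to-1 alignments; a forward block maps offsets
#' directly, a reverse block mirrors them within the block. Parts of the
#' query covered by no block are reported as unplaced lengths.
#'
#' @param chrom,start,end query interval (haplotype frame, 0-based half-open).
#' @param blocks data.frame of this haplotype's alignment blocks
#'   (see [readAlignmentBlocks()]); other haplotypes' rows are ignored if a
#'   `haplotype_id` is supplied.
#' @param haplotype_id optional haplotype id to subset `blocks`.
#' @return list with `projected` (data.frame `chrom, start, end` in reference
#'   frame) and `unplaced` (integer vector of uncovered lengths).
#' @export
projectInterval <- function(chrom, start, end, blocks, haplotype_id = NULL) {
    stopifnot(length(chrom) == 1, start < end)
    if (!is.null(haplotype_id))
        blocks <- blocks[blocks$haplotype_id == haplotype_id, , drop = FALSE]
    if (!chrom %in% blocks$hap_chrom)
        stop("interval on unknown haplotype chromosome: ", chrom)
    b <- blocks[blocks$hap_chrom == chrom & blocks$hap_start < end &
                blocks$hap_end > start, , drop = FALSE]
    proj <- data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
    covered <- IRanges::IRanges()
    if (nrow(b)) {
        os <- pmax(start, b$hap_start)
        oe <- pmin(end, b$hap_end)
        fwd <- b$strand == "+"
        ps <- ifelse(fwd, b$ref_start + (os - b$hap_start),
                     b$ref_start + (b$hap_end - oe))
        pe <- ifelse(fwd, b$ref_start + (oe - b$hap_start),
                     b$ref_start + (b$hap_end - os))
        proj <- data.frame(chrom = b$ref_chrom, start = as.integer(ps),
                           end = as.integer(pe), stringsAsFactors = FALSE)
        covered <- .toIR(os, oe)
    }
    gaps <- IRanges::setdiff(.toIR(start, end), covered)
    list(projected = proj, unplaced = IRanges::width(gaps))
}

#' Project both mates of every SD pair onto the reference
#'
#' @param pairs assembly-frame SD pair data.frame (see [readSDPairs()]).
#' @param blocks alignment-block data.frame for all haplotypes.
#' @return list with `intervals`: data.frame `haplotype_id, chrom, start, end,
#'   kind` (one row per projected fragment; both mates contribute, `kind` is
#'   `intrachromosomal`/`interchromosomal` from the originating pair) and
#'   `unplaced`: data.frame `haplotype_id, length` of unprojected fragments.
#' @export
projectPairs <- function(pairs, blocks) {
    kind <- ifelse(pairs$chrom_a == pairs$chrom_b,
                   "intrachromosomal", "interchromosomal")
    n <- nrow(pairs)
    mates <- rbind(
        data.frame(mate_id = seq_len(n), haplotype_id = pairs$haplotype_id,
                   chrom = pairs$chrom_a, start = pairs$start_a,
                   end = pairs$end_a, kind = kind, stringsAsFactors = FALSE),
        data.frame(mate_id = n + seq_len(n), haplotype_id = pairs$haplotype_id,
                   chrom = pairs$chrom_b, start = pairs$start_b,
                   end = pairs$end_b, kind = kind, stringsAsFactors = FALSE))
    known <- unique(blocks[c("haplotype_id", "hap_chrom")])
    bad <- !paste(mates$haplotype_id, mates$chrom) %in%
        paste(known$haplotype_id, known$hap_chrom)
    if (any(bad))
        stop("interval on unknown haplotype chromosome: ",
             mates$chrom[which(bad)[1]], " (", mates$haplotype_id[which(bad)[1]],
             ")")
    cand <- merge(mates, blocks, by.x = c("haplotype_id", "chrom"),
                  by.y = c("haplotype_id", "hap_chrom"))
    cand <- cand[cand$hap_start < cand$end & cand$hap_end > cand$start, ,
                 drop = FALSE]
    os <- pmax(cand$start, cand$hap_start)
    oe <- pmin(cand$end, cand$hap_end)
    fwd <- cand$strand == "+"
    ps <- ifelse(fwd, cand$ref_start + (os - cand$hap_start),
                 cand$ref_start + (cand$hap_end - oe))
    pe <- ifelse(fwd, cand$ref_start + (oe - cand$hap_start),
                 cand$ref_start + (cand$hap_end - os))
    intervals <- data.frame(haplotype_id = cand$haplotype_id,
                            chrom = cand$ref_chrom,
                            start = as.integer(ps), end = as.integer(pe),
                            kind = cand$kind, stringsAsFactors = FALSE)
    # unplaced: query length minus covered length (blocks are disjoint)
    covered <- rep(0L, 2L * n)
    if (nrow(cand)) {
        agg <- rowsum(oe - os, group = cand$mate_id)
        covered[as.integer(rownames(agg))] <- as.integer(agg[, 1])
    }
    unp_len <- (mates$end - mates$start) - covered
    keep <- unp_len > 0L
    unplaced <- data.frame(haplotype_id = mates$haplotype_id[keep],
                           length = unp_len[keep], stringsAsFactors = FALSE)
    rownames(intervals) <- NULL
    list(intervals = intervals, unplaced = unplaced)
}

#' Flatten intervals into nonoverlapping regions
#'
#' Set-theoretic union: overlapping or bookended intervals are merged, and the
#' total is the number of distinct bases covered.
#'
#' @param df data.frame with `chrom, start, end` (0-based half-open), or a
#'   `GRanges`.
#' @return list with `regions` (sorted data.frame `chrom, start, end`) and
#'   `total_bp`.
#' @export
flattenUnion <- function(df) {
    if (methods::is(df, "GRanges")) df <- .grDF(df)
    if (!nrow(df))
        return(list(regions = data.frame(chrom = character(),
                                         start = integer(), end = integer()),
                    total_bp = 0))
    gr <- .toGR(df$chrom, df$start, df$end)
    red <- GenomicRanges::reduce(GenomicRanges::sort(gr), ignore.strand = TRUE)
    out <- .grDF(red)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    list(regions = out, total_bp = sum(GenomicRanges::width(red)))
}

#' Haplotype presence over flattened regions
#'
#' A haplotype is present in a region when its SD bases cover at least
#' `coverage_threshold` of the region's length (inclusive).
#'
#' @param regions data.frame `chrom, start, end` of flattened regions.
#' @param intervals data.frame `haplotype_id, chrom, start, end` of projected
#'   per-haplotype SD intervals.
#' @param haplotype_ids character vector fixing the column order (the cohort);
#'   haplotypes in `intervals` but not here are an error.
#' @param coverage_threshold minimum covered fraction (default 0.5).
#' @return integer 0/1 matrix, regions x haplotypes.
#' @export
buildPresence <- function(regions, intervals, haplotype_ids,
                          coverage_threshold = 0.5) {
    unknown <- setdiff(unique(intervals$haplotype_id), haplotype_ids)
    if (length(unknown))
        stop("haplotype missing from cohort: ",
             paste(unknown, collapse = ", "))
    rgr <- .toGR(regions$chrom, regions$start, regions$end)
    pres <- matrix(0L, nrow = nrow(regions), ncol = length(haplotype_ids),
                   dimnames = list(NULL, haplotype_ids))
    for (hap in intersect(haplotype_ids, unique(intervals$haplotype_id))) {
        d <- intervals[intervals$haplotype_id == hap, , drop = FALSE]
        hgr <- GenomicRanges::reduce(.toGR(d$chrom, d$start, d$end))
        hits <- GenomicRanges::findOverlaps(rgr, hgr)
        if (!length(hits)) next
        ov <- GenomicRanges::pintersect(rgr[S4Vectors::queryHits(hits)],
                                        hgr[S4Vectors::subjectHits(hits)])
        cov <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits),
                      sum)
        idx <- as.integer(names(cov))
        frac <- as.numeric(cov) / GenomicRanges::width(rgr)[idx]
        pres[idx[frac >= coverage_threshold], hap] <- 1L
    }
    pres
}

#' Classify region haplotype frequency
#'
#' Frequency classes: `fixed` (present in all H haplotypes), `private`
#' (present in exactly one sample and absent from the reference),
#' `polymorphic_known` (in the reference, not fixed), `polymorphic_novel`
#' (not in the reference, present in two or more samples).
#'
#' @param haplotype_count carriers per region (integer vector).
#' @param sample_count distinct carrier samples per region.
#' @param in_reference logical: region overlaps the reference SD annotation.
#' @param H cohort size (number of haplotypes).
#' @return character vector of classes.
#' @export
classifyFrequency <- function(haplotype_count, sample_count, in_reference, H) {
    n <- length(haplotype_count)
    stopifnot(length(sample_count) == n, length(in_reference) == n)
    if (any(haplotype_count == 0 & !in_reference))
        stop("region with zero presence and not in reference should not exist")
    cls <- character(n)
    cls[haplotype_count == H] <- "fixed"
    rest <- haplotype_count < H
    cls[rest & in_reference] <- "polymorphic_known"
    cls[rest & !in_reference & sample_count == 1] <- "private"
    cls[rest & !in_reference & sample_count >= 2] <- "polymorphic_novel"
    if (any(cls == ""))
        stop("unclassifiable region (zero presence, in reference, H mismatch?)")
    cls
}

#' Build an SD region catalog from projected intervals
#'
#' Flattens all projected SD intervals to nonoverlapping regions, computes the
#' haplotype presence matrix, assigns intra/inter kind from the generating
#' pairs (regions touched by both kinds are tagged `both`), determines
#' reference presence against the reference SD annotation (>= `ref_threshold`
#' of the region covered) and classifies frequency.
#'
#' @param intervals data.frame `haplotype_id, chrom, start, end, kind` (from
#'   [projectPairs()], or reference-frame calls directly).
#' @param labels population label table ([readPopulationLabels()]).
#' @param reference_sd data.frame `chrom, start, end` of the reference SD
#'   annotation (may be empty).
#' @param coverage_threshold presence threshold (default 0.5).
#' @param ref_threshold fraction of a region that must overlap the reference
#'   annotation to count as known (default 0.5).
#' @return an [SDRegionCatalog-class].
#' @export
buildCatalog <- function(intervals, labels, reference_sd,
                         coverage_threshold = 0.5, ref_threshold = 0.5) {
    validateLabels(labels)
    haps <- labels$haplotype_id
    fl <- flattenUnion(intervals)
    reg <- fl$regions
    if (!nrow(reg)) stop("no SD intervals to catalog")
    pres <- buildPresence(reg, intervals, haps, coverage_threshold)
    rgr <- .toGR(reg$chrom, reg$start, reg$end)
    # intra/inter kind: which kinds of generating intervals overlap a region
    kind <- rep(NA_character_, nrow(reg))
    for (kk in c("intrachromosomal", "interchromosomal")) {
        d <- intervals[intervals$kind == kk, , drop = FALSE]
        if (!nrow(d)) next
        hit <- IRanges::overlapsAny(rgr, .toGR(d$chrom, d$start, d$end))
        kind[hit & is.na(kind)] <- kk
        kind[hit & !is.na(kind) & kind != kk] <- "both"
    }
    kind[is.na(kind)] <- "intrachromosomal"
    # reference presence by covered fraction
    in_ref <- rep(FALSE, nrow(reg))
    if (nrow(reference_sd)) {
        sgr <- GenomicRanges::reduce(
            .toGR(reference_sd$chrom, reference_sd$start, reference_sd$end))
        hits <- GenomicRanges::findOverlaps(rgr, sgr)
        if (length(hits)) {
            ov <- GenomicRanges::pintersect(rgr[S4Vectors::queryHits(hits)],
                                            sgr[S4Vectors::subjectHits(hits)])
            cov <- tapply(GenomicRanges::width(ov),
                          S4Vectors::queryHits(hits), sum)
            idx <- as.integer(names(cov))
            in_ref[idx] <- as.numeric(cov) /
                GenomicRanges::width(rgr)[idx] >= ref_threshold
        }
    }
    hap2samp <- stats::setNames(labels$sample_id, labels$haplotype_id)
    samp <- hap2samp[colnames(pres)]
    hcount <- as.integer(rowSums(pres))
    scount <- as.integer(apply(pres, 1L,
                               function(r) length(unique(samp[r == 1L]))))
    cls <- classifyFrequency(hcount, scount, in_ref, length(haps))
    S4Vectors::mcols(rgr) <- S4Vectors::DataFrame(
        freq_class = cls, kind = kind, in_reference = in_ref,
        haplotype_count = hcount, sample_count = scount)
    SDRegionCatalog(rgr, pres, labels = labels)
}

#' Accumulation curve of SD content
#'
#' Adds haplotypes one by one (default order: the non-African block, then the
#' African block) and reports, per added genome, the cumulative distinct SD bp
#' and the bp newly contributed, broken down by frequency class and
#' intra/inter kind. Regions with zero carriers (reference-only) never
#' contribute. The final cumulative total equals the catalog union bp over
#' carried regions regardless of ordering.
#'
#' @param catalog an [SDRegionCatalog-class].
#' @param ordering optional character vector: a permutation of the cohort's
#'   haplotype ids.
#' @return list with `curve` (data.frame per added haplotype: `haplotype_id`,
#'   `added_bp`, `cumulative_bp` plus `added_bp.<class>` and `added_bp.<kind>`
#'   columns), `mean_increment_bp` (mean added bp per genome after the first)
#'   and `slope_bp` (least-squares slope of cumulative bp on genome index).
#' @export
accumulationCurve <- function(catalog, ordering = NULL) {
    labels <- catalogLabels(catalog)
    haps <- haplotypeIds(catalog)
    if (is.null(ordering)) {
        if (is.null(labels)) ordering <- haps
        else {
            sup <- stats::setNames(labels$superpopulation,
                                   labels$haplotype_id)[haps]
            ordering <- c(haps[sup == "nonAFR"], haps[sup == "AFR"])
        }
    }
    if (!setequal(ordering, haps) || length(ordering) != length(haps))
        stop("ordering must be a permutation of the cohort haplotypes")
    pres <- presenceMatrix(catalog)[, ordering, drop = FALSE]
    rr <- regions(catalog)
    w <- GenomicRanges::width(rr)
    cls <- S4Vectors::mcols(rr)$freq_class
    kind <- S4Vectors::mcols(rr)$kind
    first <- apply(pres, 1L, function(r) {
        i <- which(r == 1L)
        if (length(i)) i[1] else NA_integer_
    })
    H <- length(ordering)
    added <- vapply(seq_len(H), function(i)
        sum(w[!is.na(first) & first == i]), numeric(1))
    curve <- data.frame(haplotype_id = ordering, added_bp = added,
                        cumulative_bp = cumsum(added))
    for (cc in FREQ_CLASSES)
        curve[[paste0("added_bp.", cc)]] <- vapply(seq_len(H), function(i)
            sum(w[!is.na(first) & first == i & cls == cc]), numeric(1))
    for (kk in SD_KINDS)
        curve[[paste0("added_bp.", kk)]] <- vapply(seq_len(H), function(i)
            sum(w[!is.na(first) & first == i & kind == kk]), numeric(1))
    fit <- stats::lm(cumulative_bp ~ seq_len(H), data = curve)
    list(curve = curve,
         mean_increment_bp = if (H > 1) mean(added[-1]) else 0,
         slope_bp = unname(stats::coef(fit)[2]))
}
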