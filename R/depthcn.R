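# Windowed read-depth copy number: window exclusion, GC recalibration,
# normalisation to diploid CN, per-gene medians, assembly-anchored
# adjustment, concordance.

#' Flag depth windows overlapping repeat annotation
#'
#' A window is excluded when more than `max_overlap` of its length (strictly)
#' overlaps tandem-repeat / low-complexity annotation.
#'
#' @param windows data.frame `chrom, start, end, ...` of depth windows.
#' @param repeats data.frame `chrom, start, end` of repeat annotation.
#' @param max_overlap maximum tolerated overlapping fraction (default 0.10).
#' @return `windows` with a logical `excluded` column added (or updated by OR
#'   with an existing one).
#' @export
excludeWindows <- function(windows, repeats, max_overlap = 0.10) {
    frac <- rep(0, nrow(windows))
    if (nrow(repeats)) {
        wgr <- .toGR(windows$chrom, windows$start, windows$end)
        rgr <- GenomicRanges::reduce(.toGR(repeats$chrom, repeats$start,
                                           repeats$end))
        hits <- GenomicRanges::findOverlaps(wgr, rgr)
        if (length(hits)) {
            ov <- GenomicRanges::pintersect(wgr[S4Vectors::queryHits(hits)],
                                            rgr[S4Vectors::subjectHits(hits)])
            cov <- tapply(GenomicRanges::width(ov),
                          S4Vectors::queryHits(hits), sum)
            idx <- as.integer(names(cov))
            frac[idx] <- as.numeric(cov) / GenomicRanges::width(wgr)[idx]
        }
    }
    flag <- frac > max_overlap
    windows$excluded <- if (is.null(windows$excluded)) flag
                        else windows$excluded | flag
    windows
}

#' Fit a GC depth-correction model from a uniform self sample
#'
#' The self sample emulates decomposing the reference into fixed-length
#' fragments and processing them as a perfectly matched, unbiased sample:
#' every window has true copy number 2, so any depth structure across GC is
#' bias. Windows are binned by GC fraction (`bin_width`); bins are pooled
#' with their right neighbours until each holds at least `min_occupancy`
#' windows, and each bin's factor is its mean depth over the global mean.
#'
#' @param self_depth data.frame `depth, gc` (+ optional logical `excluded`)
#'   for the self sample's windows.
#' @param bin_width GC bin width (default 0.01).
#' @param min_occupancy minimum windows per pooled bin (default 100).
#' @return a [GCModel-class].
#' @export
gcRecalibrate <- function(self_depth, bin_width = 0.01, min_occupancy = 100) {
    d <- self_depth
    if (!is.null(d$excluded)) d <- d[!d$excluded, , drop = FALSE]
    if (nrow(d) < min_occupancy)
        stop("not enough windows to fill a single GC bin")
    edges <- seq(0, 1, by = bin_width)
    if (edges[length(edges)] < 1) edges <- c(edges, 1)
    bin <- findInterval(d$gc, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(bin, nbins = length(edges) - 1L)
    # pool consecutive bins left-to-right until occupancy is met
    grp <- integer(length(counts))
    g <- 1L; acc <- 0L
    for (i in seq_along(counts)) {
        grp[i] <- g
        acc <- acc + counts[i]
        if (acc >= min_occupancy) { g <- g + 1L; acc <- 0L }
    }
    # fold an underfull trailing group into its predecessor
    if (g > 1L && any(grp == g) && sum(counts[grp == g]) < min_occupancy)
        grp[grp == g] <- g - 1L
    ngrp <- max(grp)
    lo <- vapply(seq_len(ngrp), function(k) min(which(grp == k)), integer(1))
    hi <- vapply(seq_len(ngrp), function(k) max(which(grp == k)), integer(1))
    breaks <- c(edges[lo], edges[hi[ngrp] + 1L])
    gbin <- grp[bin]
    occ <- tabulate(gbin, nbins = ngrp)
    if (any(occ == 0)) stop("empty GC bin after pooling")
    gmean <- mean(d$depth)
    if (gmean <= 0) stop("self sample has zero mean depth")
    fac <- as.numeric(tapply(d$depth, gbin, mean)) / gmean
    if (any(fac <= 0)) stop("nonpositive GC factor (zero-depth bin)")
    methods::new("GCModel", breaks = breaks, factor = fac,
                 occupancy = as.integer(occ), global_mean = gmean)
}

#' Apply a GC model: corrected depth
#' @param model a [GCModel-class].
#' @param depth,gc window depth and GC vectors.
#' @return depth divided by the factor of each window's GC bin.
#' @export
gcCorrect <- function(model, depth, gc) {
    bin <- findInterval(gc, model@breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    depth / model@factor[bin]
}

#' Per-window diploid copy number
#'
#' `CN = 2 * corrected_depth / baseline`, where the baseline is the mean
#' GC-corrected depth over non-excluded windows inside caller-supplied
#' copy-number-2 ("unique") regions. Excluded windows get `NA`.
#'
#' @param windows data.frame `chrom, start, end, depth, gc` (+ optional
#'   `excluded`).
#' @param model a [GCModel-class].
#' @param baseline_regions data.frame `chrom, start, end` of diploid unique
#'   regions, or `NULL` to pass `baseline` directly.
#' @param baseline mean corrected depth at CN 2 (computed from
#'   `baseline_regions` when `NULL`).
#' @return `windows` with columns `corrected_depth` and `cn` added.
#' @export
windowCN <- function(windows, model, baseline_regions = NULL,
                     baseline = NULL) {
    excl <- if (is.null(windows$excluded)) rep(FALSE, nrow(windows))
            else windows$excluded
    corr <- gcCorrect(model, windows$depth, windows$gc)
    if (is.null(baseline)) {
        if (is.null(baseline_regions))
            stop("need baseline_regions or baseline")
        wgr <- .toGR(windows$chrom, windows$start, windows$end)
        inb <- IRanges::overlapsAny(
            wgr, .toGR(baseline_regions$chrom, baseline_regions$start,
                       baseline_regions$end), type = "within")
        use <- inb & !excl
        if (!any(use)) stop("no usable baseline windows")
        baseline <- mean(corr[use])
    }
    if (!is.finite(baseline) || baseline <= 0)
        stop("baseline depth must be positive")
    windows$corrected_depth <- corr
    windows$cn <- 2 * corr / baseline
    windows$cn[excl] <- NA_real_
    windows
}

#' Gene copy number as the median of contained windows
#'
#' Only non-excluded windows fully contained within the gene span are used.
#'
#' @param genes data.frame `gene_id, chrom, start, end`.
#' @param windows window data.frame with `cn` (from [windowCN()]).
#' @return data.frame `gene_id, cn, n_windows`; genes with no usable window
#'   get `NA` and are counted in the `missing` attribute.
#' @export
geneCNFromWindows <- function(genes, windows) {
    ok <- !is.na(windows$cn)
    wgr <- .toGR(windows$chrom[ok], windows$start[ok], windows$end[ok])
    ggr <- .toGR(genes$chrom, genes$start, genes$end)
    hits <- GenomicRanges::findOverlaps(wgr, ggr, type = "within")
    cn <- rep(NA_real_, nrow(genes))
    nw <- integer(nrow(genes))
    if (length(hits)) {
        vals <- split(windows$cn[ok][S4Vectors::queryHits(hits)],
                      S4Vectors::subjectHits(hits))
        idx <- as.integer(names(vals))
        cn[idx] <- vapply(vals, stats::median, numeric(1))
        nw[idx] <- lengths(vals)
    }
    out <- data.frame(gene_id = genes$gene_id, cn = cn, n_windows = nw,
                      stringsAsFactors = FALSE)
    attr(out, "missing") <- sum(is.na(cn))
    out
}

#' Per-gene adjustment factors anchoring read depth to assembly copy number
#'
#' On a calibration sample with assembly copy number taken as ground truth,
#' `a_g = assembly_cn / read_depth_cn`. Genes needing more than a 50%
#' adjustment (`|a_g - 1| > 0.5`), or with zero read-depth CN against nonzero
#' assembly CN, are excluded. Multiplying the calibration sample's read-depth
#' values by retained `a_g` reproduces its assembly values exactly.
#'
#' @param read_depth_cn named numeric vector: read-depth CN per gene on the
#'   calibration sample.
#' @param assembly_cn named numeric vector: assembly CN per gene (ground
#'   truth), same genes.
#' @param max_adjustment exclusion bound on `|a_g - 1|` (default 0.5).
#' @return data.frame `gene_id, factor, excluded, reason`.
#' @export
calibrateAdjustment <- function(read_depth_cn, assembly_cn,
                                max_adjustment = 0.5) {
    genes <- intersect(names(read_depth_cn), names(assembly_cn))
    if (!length(genes)) stop("no shared genes between matrices")
    rd <- read_depth_cn[genes]
    as_ <- assembly_cn[genes]
    fac <- rep(NA_real_, length(genes))
    reason <- rep("", length(genes))
    zero <- (is.na(rd) | rd == 0)
    fac[!zero] <- as_[!zero] / rd[!zero]
    reason[zero & as_ > 0] <- "zero_read_depth"
    reason[zero & as_ == 0] <- "zero_both"
    fac[zero & as_ == 0] <- 1
    reason[!zero & abs(fac - 1) > max_adjustment] <- "over_adjustment"
    excluded <- reason != ""
    data.frame(gene_id = genes, factor = fac, excluded = excluded,
               reason = reason, row.names = NULL, stringsAsFactors = FALSE)
}

#' Coefficient of determination between assembly and read-depth copy number
#'
#' R-squared of the least-squares fit of read-depth CN on assembly CN over
#' all shared gene x sample entries.
#'
#' @param assembly,read_depth [CopyNumberExperiment-class] objects (or plain
#'   matrices) with shared row and column names.
#' @return R-squared.
#' @export
concordanceR2 <- function(assembly, read_depth) {
    a <- if (methods::is(assembly, "CopyNumberExperiment"))
        copyNumber(assembly) else assembly
    r <- if (methods::is(read_depth, "CopyNumberExperiment"))
        copyNumber(read_depth) else read_depth
    genes <- intersect(rownames(a), rownames(r))
    samps <- intersect(colnames(a), colnames(r))
    if (!length(genes) || !length(samps)) stop("no shared units/samples")
    x <- as.numeric(a[genes, samps])
    y <- as.numeric(r[genes, samps])
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0) stop("constant predictor: R2 undefined")
    summary(stats::lm(y ~ x))$r.squared
}
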