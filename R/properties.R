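# Pair orientation/dispersion classification, rarity bands, permutation
# tests and 2x2 enrichment.

#' Classify SD pairs by orientation and dispersion
#'
#' Same-chromosome gap is the inner distance between the mate intervals
#' (end of the left mate to start of the right mate, 0 when they touch or
#' overlap). Dispersion classes are mutually exclusive: `clustered`
#' (gap <= 1 Mb), `interspersed` (1 Mb < gap <= 50 Mb), `distant`
#' (gap > 50 Mb), `interchromosomal` (mates on different chromosomes; gap
#' undefined, `NA`).
#'
#' @param pairs SD pair data.frame (see [readSDPairs()]).
#' @param interspersed_bp lower gap bound for interspersed (default 1e6).
#' @param distant_bp lower gap bound for distant (default 5e7).
#' @return the input with added columns `gap_bp` and `dispersion`.
#' @export
classifyPairs <- function(pairs, interspersed_bp = 1e6, distant_bp = 5e7) {
    same <- pairs$chrom_a == pairs$chrom_b
    left_end <- pmin(pairs$end_a, pairs$end_b)
    right_start <- pmax(pairs$start_a, pairs$start_b)
    gap <- pmax(0, right_start - left_end)
    gap[!same] <- NA_real_
    disp <- rep("interchromosomal", nrow(pairs))
    disp[same & gap <= interspersed_bp] <- "clustered"
    disp[same & gap > interspersed_bp & gap <= distant_bp] <- "interspersed"
    disp[same & gap > distant_bp] <- "distant"
    pairs$gap_bp <- gap
    pairs$dispersion <- disp
    pairs$orientation_class <- ifelse(pairs$orientation == "+",
                                      "direct", "inverted")
    pairs
}

#' Rarity band of a carrier count
#'
#' Rare: carried by at most 5 haplotypes; common: 6-20; other: above 20.
#'
#' @param haplotype_count integer carrier counts (each in `[1, H]`).
#' @param H cohort size.
#' @return data.frame with `band` and `allele_frequency` (= count / H).
#' @export
rarityBand <- function(haplotype_count, H) {
    if (any(haplotype_count < 1 | haplotype_count > H))
        stop("carrier count outside [1, H]")
    band <- ifelse(haplotype_count <= 5, "rare",
                   ifelse(haplotype_count <= 20, "common", "other"))
    data.frame(band = band, allele_frequency = haplotype_count / H)
}

#' One-sided permutation test for a two-group location difference
#'
#' Statistic is the difference of group means (or medians), group A minus
#' group B. Labels are permuted `n_perm` times; the empirical P uses the
#' add-one estimator `P = (1 + #{permuted >= observed}) / (1 + n_perm)`,
#' counting in the direction of the alternative. With `alternative = "auto"`
#' the observed direction is tested (note: this selective one-sided P has
#' twice the nominal type-I error when used as a two-sided test; fix the
#' direction for a calibrated test).
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @param statistic `"mean"` or `"median"` difference.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (local to this call).
#' @param alternative `"auto"` (observed direction), `"greater"` (A > B) or
#'   `"less"`.
#' @return list with `p_value`, `observed`, `direction` (`"greater"` or
#'   `"less"`), `statistic`, `n_perm`.
#' @export
permutationCompare <- function(values_a, values_b,
                               statistic = c("mean", "median"),
                               n_perm = 10000, seed = 1,
                               alternative = c("auto", "greater", "less")) {
    statistic <- match.arg(statistic)
    alternative <- match.arg(alternative)
    if (!length(values_a) || !length(values_b))
        stop("both groups must be nonempty")
    if (n_perm < 100) stop("n_perm must be >= 100")
    fun <- if (statistic == "mean") mean else stats::median
    obs <- fun(values_a) - fun(values_b)
    dir <- switch(alternative, auto = if (obs >= 0) "greater" else "less",
                  alternative)
    pool <- c(values_a, values_b)
    na <- length(values_a)
    n <- length(pool)
    sgn <- if (dir == "greater") 1 else -1
    perm_stats <- local({
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old), add = TRUE)
        set.seed(seed)
        vapply(seq_len(n_perm), function(i) {
            idx <- sample.int(n, na)
            fun(pool[idx]) - fun(pool[-idx])
        }, numeric(1))
    })
    p <- (1 + sum(sgn * perm_stats >= sgn * obs)) / (1 + n_perm)
    list(p_value = p, observed = obs, direction = dir,
         statistic = statistic, n_perm = n_perm)
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}
.Random.seed_restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Proximity permutation test: are novel regions closer to known SDs than random?
#'
#' The statistic is the median distance from each novel region to the nearest
#' known SD. The null re-places every novel region uniformly at random on its
#' own chromosome, length-preserving and avoiding excluded layout intervals;
#' the one-sided empirical P (observed median smaller than random) uses the
#' add-one estimator.
#'
#' @param novel_regions data.frame `chrom, start, end` of novel regions.
#' @param known_sd data.frame `chrom, start, end` of the known SD annotation.
#' @param layout a `genome_layout` ([makeGenomeLayout()]).
#' @param n_perm number of random placements (default 1000).
#' @param seed RNG seed (local).
#' @return list with `p_value`, `observed_median_bp`, `n_perm`.
#' @export
proximityPermutation <- function(novel_regions, known_sd, layout,
                                 n_perm = 1000, seed = 1) {
    stopifnot(inherits(layout, "genome_layout"))
    if (!nrow(novel_regions)) stop("no novel regions")
    kgr <- .toGR(known_sd$chrom, known_sd$start, known_sd$end)
    lens <- novel_regions$end - novel_regions$start
    chroms <- novel_regions$chrom
    # allowed placement space per chromosome: [0, L - len] minus exclusions
    clens <- layout$chrom_lengths
    if (any(!chroms %in% names(clens)))
        stop("novel region on chromosome absent from layout")
    if (any(lens > clens[chroms]))
        stop("region longer than available placement space")
    dist_to_known <- function(chrom, start, end) {
        gr <- .toGR(chrom, start, end)
        d <- GenomicRanges::distanceToNearest(gr, kgr)
        out <- rep(Inf, length(gr))
        out[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
        out
    }
    obs <- stats::median(dist_to_known(chroms, novel_regions$start,
                                       novel_regions$end))
    excl <- layout$excluded
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    # all permutations in one batch: n_perm placements per region
    k <- length(lens)
    rep_chrom <- rep(chroms, n_perm)
    rep_len <- rep(lens, n_perm)
    s <- floor(stats::runif(k * n_perm) * (clens[rep_chrom] - rep_len + 1))
    if (nrow(excl)) {
        egr <- .toGR(excl$chrom, excl$start, excl$end)
        bad <- IRanges::overlapsAny(.toGR(rep_chrom, s, s + rep_len), egr)
        for (tries in seq_len(50)) {
            if (!any(bad)) break
            s[bad] <- floor(stats::runif(sum(bad)) *
                            (clens[rep_chrom[bad]] - rep_len[bad] + 1))
            bad[bad] <- IRanges::overlapsAny(
                .toGR(rep_chrom[bad], s[bad], s[bad] + rep_len[bad]), egr)
        }
        if (any(bad)) stop("could not place region outside exclusions")
    }
    d <- dist_to_known(rep_chrom, s, s + rep_len)
    perm <- vapply(split(d, rep(seq_len(n_perm), each = k)),
                   stats::median, numeric(1))
    p <- (1 + sum(perm <= obs)) / (1 + n_perm)
    list(p_value = p, observed_median_bp = obs, n_perm = n_perm)
}

#' 2x2 enrichment: sample odds ratio and Fisher exact P
#'
#' The point estimate is the sample odds ratio `ad / bc`; when any cell is
#' zero the Haldane-Anscombe correction (0.5 added to every cell) is applied
#' to the point estimate only and flagged. The two-sided P sums the
#' hypergeometric probabilities of all tables (at the observed margins) no
#' more likely than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list with `odds_ratio`, `p_value`, `corrected` (logical: zero-cell
#'   correction applied).
#' @export
enrichment2x2 <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(identical(dim(tab), c(2L, 2L)))
    if (any(tab < 0) || any(tab != round(tab)))
        stop("counts must be nonnegative integers")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("2x2 table has a zero margin")
    corrected <- any(tab == 0)
    tt <- if (corrected) tab + 0.5 else tab
    or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
    p <- stats::fisher.test(tab)$p.value
    list(odds_ratio = unname(or), p_value = p, corrected = corrected)
}
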