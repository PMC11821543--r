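# Assembly-based gene copy number: hit filtering, diploid counting,
# family aggregation, dispersion index, ranking.

#' Filter paralog alignment hits
#'
#' A hit is retained iff coverage > `min_coverage`, identity > `min_identity`
#' (both strict, matching the printed >60% / >90% cutoffs), it is not fully
#' contained in annotated repeat sequence (`repeat_overlap < 1`), its gene's
#' coding sequence is at least `min_cds_bp`, and - when the flank filter is
#' enabled - the nearest assembly break is at least `break_flank_bp` away.
#'
#' @param hits data.frame of hits (see [readParalogHits()]).
#' @param min_coverage,min_identity strict lower bounds (defaults 0.60, 0.90).
#' @param min_cds_bp minimum coding-sequence length (default 200).
#' @param break_flank_bp required distance to the nearest assembly break
#'   (default 30000); only applied when `flank_filter = TRUE`.
#' @param flank_filter logical; the flank filter is used for paralog-resolved
#'   reporting, not cohort totals (default `FALSE`).
#' @return list with `hits` (retained rows) and `rejected` (named counts per
#'   reason: coverage, identity, repeat, short_cds, near_break).
#' @export
filterHits <- function(hits, min_coverage = 0.60, min_identity = 0.90,
                       min_cds_bp = 200, break_flank_bp = 30000,
                       flank_filter = FALSE) {
    rej_cov <- !(hits$coverage > min_coverage)
    rej_idy <- !(hits$identity > min_identity)
    rej_rep <- hits$repeat_overlap >= 1.0
    rej_cds <- hits$cds_bp < min_cds_bp
    rej_brk <- if (flank_filter) hits$distance_to_break < break_flank_bp
               else rep(FALSE, nrow(hits))
    keep <- !(rej_cov | rej_idy | rej_rep | rej_cds | rej_brk)
    list(hits = hits[keep, , drop = FALSE],
         rejected = c(coverage = sum(rej_cov), identity = sum(rej_idy),
                      repeat_contained = sum(rej_rep),
                      short_cds = sum(rej_cds), near_break = sum(rej_brk)))
}

#' Diploid gene copy number from assembly paralog hits
#'
#' Counts retained hits per gene in each haplotype and sums the two
#' haplotypes of every sample into a diploid copy number. Genes whose extra
#' copies (per-haplotype count > 1) are confined to a single haplotype across
#' the whole cohort are flagged as putative assembly artefacts and, when
#' `exclude_single_haplotype = TRUE`, dropped from the matrix.
#'
#' @param hits retained hit data.frame (after [filterHits()]).
#' @param labels population label table; both haplotypes of every sample must
#'   be present in it.
#' @param gene_ids optional character vector fixing the gene universe (genes
#'   without hits get copy number 0).
#' @param exclude_single_haplotype drop flagged genes (default `TRUE`).
#' @return list with `cn` (a gene-level [CopyNumberExperiment-class]) and
#'   `flagged_genes` (character).
#' @export
assemblyCopyNumber <- function(hits, labels, gene_ids = NULL,
                               exclude_single_haplotype = TRUE) {
    validateLabels(labels)
    if (any(!hits$haplotype_id %in% labels$haplotype_id))
        stop("hit haplotype absent from labels")
    if (is.null(gene_ids)) gene_ids <- sort(unique(hits$gene_id))
    hap_ids <- labels$haplotype_id
    counts <- table(factor(hits$gene_id, levels = gene_ids),
                    factor(hits$haplotype_id, levels = hap_ids))
    counts <- matrix(as.integer(counts), nrow = length(gene_ids),
                     dimnames = list(gene_ids, hap_ids))
    multi <- counts > 1L
    flagged <- gene_ids[rowSums(multi) == 1L]
    samples <- unique(labels$sample_id)
    hap_of <- split(labels$haplotype_id, labels$sample_id)[samples]
    cn <- vapply(samples, function(s) rowSums(counts[, hap_of[[s]],
                                                     drop = FALSE]),
                 numeric(length(gene_ids)))
    dimnames(cn) <- list(gene_ids, samples)
    if (exclude_single_haplotype && length(flagged))
        cn <- cn[setdiff(gene_ids, flagged), , drop = FALSE]
    sup <- labels$superpopulation[match(colnames(cn),
                                        labels$sample_id)]
    cd <- S4Vectors::DataFrame(sample_id = colnames(cn),
                               superpopulation = sup)
    list(cn = CopyNumberExperiment(cn, unit = "gene", method = "assembly",
                                   colData = cd),
         flagged_genes = flagged)
}

#' Aggregate gene copy number to gene families
#'
#' Family copy number is the sum of member gene copy numbers in each sample.
#'
#' @param cn a gene-level [CopyNumberExperiment-class].
#' @param families data.frame with columns `gene_id, family_id`; families
#'   must partition the gene set of `cn`.
#' @return a family-level [CopyNumberExperiment-class].
#' @export
familyCopyNumber <- function(cn, families) {
    stopifnot(cnUnit(cn) == "gene")
    m <- copyNumber(cn)
    fam <- families$family_id[match(rownames(m), families$gene_id)]
    if (anyNA(fam)) stop("gene(s) without family assignment: ",
                         paste(utils::head(rownames(m)[is.na(fam)], 3),
                               collapse = ", "))
    agg <- rowsum(m, group = fam)
    CopyNumberExperiment(agg[order(rownames(agg)), , drop = FALSE],
                         unit = "family", method = cnMethod(cn),
                         colData = SummarizedExperiment::colData(cn))
}

#' Index of dispersion (variance over mean)
#'
#' Sample variance (n-1 denominator) of a copy-number vector divided by its
#' mean; undefined (error) when the mean is zero.
#'
#' @param values numeric vector of copy numbers across samples.
#' @return the dispersion index.
#' @export
dispersionIndex <- function(values) {
    m <- mean(values)
    if (m == 0) stop("dispersion index undefined: mean copy number is 0")
    stats::var(values) / m
}

#' Rank gene families by copy-number dispersion
#'
#' Families with mean diploid copy number above `min_mean_cn` are ranked by
#' dispersion index; the `top_k` most and least variable are returned, ties
#' broken by family id.
#'
#' @param cn a family-level [CopyNumberExperiment-class].
#' @param min_mean_cn eligibility threshold on mean CN (strict >, default 3).
#' @param top_k list length (default 25); if fewer families are eligible all
#'   are returned with a warning.
#' @return list with `table` (family, mean_cn, dispersion, eligible),
#'   `most_variable` and `least_variable` (character vectors of family ids).
#' @export
rankFamilies <- function(cn, min_mean_cn = 3.0, top_k = 25) {
    stopifnot(cnUnit(cn) == "family")
    m <- copyNumber(cn)
    mean_cn <- rowMeans(m)
    disp <- apply(m, 1, function(v)
        if (mean(v) == 0) NA_real_ else dispersionIndex(v))
    tab <- data.frame(family_id = rownames(m), mean_cn = mean_cn,
                      dispersion = disp,
                      eligible = mean_cn > min_mean_cn & !is.na(disp),
                      row.names = NULL, stringsAsFactors = FALSE)
    el <- tab[tab$eligible, , drop = FALSE]
    if (nrow(el) < top_k)
        warning("only ", nrow(el), " eligible families (top_k = ", top_k, ")")
    ordHi <- el$family_id[order(-el$dispersion, el$family_id)]
    ordLo <- el$family_id[order(el$dispersion, el$family_id)]
    list(table = tab,
         most_variable = utils::head(ordHi, top_k),
         least_variable = utils::head(ordLo, top_k))
}
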