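# Generator contracts: determinism, reader-valid outputs, configured
# effects, planted truth.

smallConfig <- function(...) {
    args <- list(n_afr_samples = 3, n_nonafr_samples = 2,
                 chrom_lengths = c(cA = 4e6, cB = 3e6),
                 n_intra_templates = 60, n_inter_templates = 20,
                 afr_intra_excess_bp = 3e4, n_families = 10, n_shifted = 3,
                 depth_samples = 4, iso_planted = 12, iso_background = 40)
    over <- list(...)
    args[names(over)] <- over
    do.call(simConfig, args)
}

test_that("the generator is byte-deterministic under a seed", {
    d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
    unlink(c(d1, d2), recursive = TRUE)
    for (d in c(d1, d2)) {
        co <- simulateCohort(smallConfig(), seed = 5)
        writeCohort(co, d, depth = simulateDepth(co),
                    isoseq = simulateIsoseq(co))
    }
    f1 <- list.files(d1, recursive = TRUE)
    f2 <- list.files(d2, recursive = TRUE)
    expect_identical(f1, f2)
    h1 <- tools::md5sum(file.path(d1, f1))
    h2 <- tools::md5sum(file.path(d2, f2))
    expect_identical(unname(h1), unname(h2))
    # a different seed changes the outputs
    co3 <- simulateCohort(smallConfig(), seed = 6)
    expect_false(identical(co3$pairs, simulateCohort(smallConfig(),
                                                     seed = 5)$pairs))
})

test_that("a 10-haplotype config yields 10 call sets and 5 samples, all reader-valid", {
    d <- file.path(tempdir(), "gen10")
    unlink(d, recursive = TRUE)
    co <- simulateCohort(smallConfig(), seed = 2)
    writeCohort(co, d, depth = simulateDepth(co),
                isoseq = simulateIsoseq(co))
    labels <- readPopulationLabels(file.path(d, "labels.tsv"))
    expect_equal(nrow(labels), 10L)
    expect_equal(length(unique(labels$sample_id)), 5L)
    pair_files <- list.files(file.path(d, "pairs"), full.names = TRUE)
    expect_length(pair_files, 10L)
    # every emitted file is accepted by the strict readers with no drops
    for (p in pair_files) {
        got <- readSDPairs(p, frame = "assembly",
                           chrom_names = names(co$config$chrom_lengths))
        expect_equal(attr(got, "dropped"), 0L)
    }
    blocks <- readAlignmentBlocks(file.path(d, "blocks.tsv"))
    expect_setequal(unique(blocks$haplotype_id), labels$haplotype_id)
    expect_gt(nrow(readBED(file.path(d, "reference_sd.bed"))), 0L)
    expect_gt(nrow(readParalogHits(file.path(d, "hits.tsv"))), 0L)
    expect_gt(nrow(readDepthWindows(file.path(d, "depth", "self.tsv"))), 0L)
    expect_gt(nrow(readIsoAlignments(file.path(d, "isoseq.tsv"))), 0L)
})

test_that("the African intrachromosomal excess matches the configured effect", {
    diffs <- vapply(1:20, function(s) {
        co <- simulateCohort(simConfig(), seed = s)
        cp <- classifyPairs(co$pairs)
        intra <- cp[cp$dispersion != "interchromosomal", ]
        bp <- tapply(2 * intra$length, intra$haplotype_id, sum)
        sup <- stats::setNames(co$labels$superpopulation,
                               co$labels$haplotype_id)[names(bp)]
        mean(bp[sup == "AFR"]) - mean(bp[sup == "nonAFR"])
    }, numeric(1))
    target <- simConfig()$afr_intra_excess_bp
    expect_lt(abs(mean(diffs) - target) / target, 0.2)
})

test_that("rare SD loci are longer and higher-identity than common ones", {
    co <- simulateCohort(simConfig(), seed = 4)
    t <- co$truth$templates
    rare <- t$carrier_count <= 5
    common <- t$carrier_count >= 6 & t$carrier_count <= 20
    cmp_len <- permutationCompare(t$length[rare], t$length[common],
                                  statistic = "median", n_perm = 10000,
                                  seed = 1)
    cmp_idy <- permutationCompare(t$identity[rare], t$identity[common],
                                  statistic = "median", n_perm = 10000,
                                  seed = 1)
    expect_lt(cmp_len$p_value, 0.01)
    expect_equal(cmp_len$direction, "greater")
    expect_lt(cmp_idy$p_value, 0.01)
})

test_that("depth simulation is flat at CN 2 and doubles at CN 4, recovering the GC curve", {
    co <- simulateCohort(smallConfig(), seed = 8)
    dp <- simulateDepth(co)
    # the self sample is exactly coverage * gc_bias: recalibration recovers
    # the planted curve within 5% per bin
    model <- gcRecalibrate(dp$self_depth)
    mid <- (utils::head(model@breaks, -1) + utils::tail(model@breaks, -1)) / 2
    curve <- SDPopGen:::.gcBias(mid)
    rel <- model@factor / (curve / mean(SDPopGen:::.gcBias(dp$self_depth$gc)))
    # narrow, well-populated bins track the planted curve within 5%; wide
    # pooled tail bins average over a broader GC span
    narrow <- diff(model@breaks) <= 0.015
    expect_gt(sum(narrow), 10)
    expect_true(all(abs(rel[narrow] - 1) < 0.05))
    # noisy samples: corrected CN near 2 outside genes, near truth inside
    s <- dp$sample_ids[1]
    w <- windowCN(dp$samples[[s]], model,
                  baseline_regions = dp$unique_regions)
    truth <- dp$truth_cn[, s]
    base <- truth == 2
    expect_lt(abs(mean(w$cn[base], na.rm = TRUE) - 2), 0.05)
    hi <- truth == 4
    if (any(hi))
        expect_lt(abs(mean(w$cn[hi], na.rm = TRUE) - 4) /
                  4, 0.15)
})

test_that("Iso-Seq simulation plants a perfectly separable divergent set", {
    co <- simulateCohort(smallConfig(), seed = 10)
    iso <- simulateIsoseq(co)
    al <- iso$alignments
    gci <- gapCompressedIdentity(al$ref_matches, al$ref_mismatches,
                                 al$ref_gap_openings)
    hit <- al$read_id[referenceDivergent(al$hap_identity, gci)]
    expect_setequal(hit, iso$truth$planted_reads)
    # zero planted reads yield zero passing reads
    co0 <- simulateCohort(smallConfig(iso_planted = 0), seed = 10)
    expect_error(iso0 <- simulateIsoseq(co0), NA)
    al0 <- iso0$alignments
    gci0 <- gapCompressedIdentity(al0$ref_matches, al0$ref_mismatches,
                                  al0$ref_gap_openings)
    expect_equal(sum(referenceDivergent(al0$hap_identity, gci0)), 0L)
})
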