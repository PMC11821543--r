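# Hit filtering, diploid counting, dispersion index, family ranking.
# (makeHit comes from helper-fixtures.R)

test_that("hit filtering applies every printed cutoff with correct strictness", {
    hits <- rbind(makeHit(coverage = 0.55),            # below coverage
                  makeHit(coverage = 0.60),            # boundary: rejected
                  makeHit(coverage = 0.601),           # kept
                  makeHit(identity = 0.89),            # below identity
                  makeHit(identity = 0.90),            # boundary: rejected
                  makeHit(identity = 0.901),           # kept
                  makeHit(cds_bp = 150L),              # short CDS
                  makeHit(cds_bp = 199L),              # below 200: rejected
                  makeHit(cds_bp = 200L),              # boundary: kept
                  makeHit(repeat_overlap = 1.0),       # fully in repeat
                  makeHit(repeat_overlap = 0.999))     # kept
    res <- filterHits(hits)
    expect_equal(nrow(res$hits), 4L)
    expect_equal(unname(res$rejected["coverage"]), 2L)
    expect_equal(unname(res$rejected["identity"]), 2L)
    expect_equal(unname(res$rejected["short_cds"]), 2L)
    expect_equal(unname(res$rejected["repeat_contained"]), 1L)
    # 30 kb assembly-break flank, only with the flank filter on
    brk <- rbind(makeHit(distance_to_break = 29999L),
                 makeHit(distance_to_break = 30000L))
    expect_equal(nrow(filterHits(brk)$hits), 2L)
    on <- filterHits(brk, flank_filter = TRUE)
    expect_equal(nrow(on$hits), 1L)
    expect_equal(on$hits$distance_to_break, 30000L)
})

test_that("hit filtering is idempotent and monotone in its thresholds", {
    set.seed(2)
    hits <- do.call(rbind, lapply(1:200, function(i)
        makeHit(coverage = stats::runif(1, 0.4, 1),
                identity = stats::runif(1, 0.85, 1),
                repeat_overlap = sample(c(stats::runif(1), 1), 1),
                cds_bp = sample(c(150L, 250L, 1200L), 1))))
    once <- filterHits(hits)
    twice <- filterHits(once$hits)
    expect_equal(once$hits, twice$hits)
    strict <- nrow(filterHits(hits, min_coverage = 0.7,
                              min_identity = 0.95)$hits)
    loose <- nrow(filterHits(hits, min_coverage = 0.5,
                             min_identity = 0.85)$hits)
    expect_lte(strict, nrow(once$hits))
    expect_gte(loose, nrow(once$hits))
})

test_that("assembly copy number sums haplotype hit counts into diploid values", {
    labels <- makeLabels(1, 1)   # AFR01, NON01
    hits <- rbind(makeHit(hap = "AFR01_h1"), makeHit(hap = "AFR01_h1"),
                  makeHit(hap = "AFR01_h2"), makeHit(hap = "AFR01_h2"),
                  makeHit(gene = "g2", hap = "NON01_h1"))
    res <- assemblyCopyNumber(hits, labels,
                              exclude_single_haplotype = FALSE)
    cn <- copyNumber(res$cn)
    expect_equal(cn["g1", "AFR01"], 4)
    expect_equal(cn["g1", "NON01"], 0)
    expect_equal(cn["g2", "AFR01"], 0)
    expect_equal(cn["g2", "NON01"], 1)
    # extra copies confined to one haplotype are flagged and excluded
    dup <- rbind(makeHit(gene = "g3", hap = "NON01_h2"),
                 makeHit(gene = "g3", hap = "NON01_h2"))
    res2 <- assemblyCopyNumber(rbind(hits, dup), labels)
    expect_equal(res2$flagged_genes, "g3")
    expect_false("g3" %in% rownames(copyNumber(res2$cn)))
    expect_error(assemblyCopyNumber(makeHit(hap = "XX_h1"), labels),
                 "absent from labels")
})

test_that("five-sample toy matrix equals the hand-computed counts", {
    labels <- makeLabels(2, 3)
    haps <- labels$haplotype_id
    set.seed(31)
    tab <- expand.grid(gene_id = c("gA", "gB", "gC"),
                       haplotype_id = haps, stringsAsFactors = FALSE)
    tab$n <- sample(0:3, nrow(tab), replace = TRUE)
    hits <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
        if (tab$n[i] > 0)
            do.call(rbind, replicate(tab$n[i],
                makeHit(tab$gene_id[i], tab$haplotype_id[i]),
                simplify = FALSE))))
    got <- copyNumber(assemblyCopyNumber(hits, labels,
                      exclude_single_haplotype = FALSE)$cn)
    hand <- sapply(unique(labels$sample_id), function(s) {
        hs <- labels$haplotype_id[labels$sample_id == s]
        sapply(c("gA", "gB", "gC"), function(g)
            sum(tab$n[tab$gene_id == g & tab$haplotype_id %in% hs]))
    })
    expect_equal(got[c("gA", "gB", "gC"), colnames(hand)], hand)
})

test_that("dispersion index is sample variance over mean with its scaling law", {
    expect_equal(dispersionIndex(c(4, 4, 4, 4)), 0)
    expect_equal(dispersionIndex(c(2, 4, 6)), 1)   # var 4, mean 4
    expect_error(dispersionIndex(c(0, 0)), "mean copy number is 0")
    set.seed(8)
    v <- stats::rpois(50, 5) + 1
    for (c in c(2, 7)) expect_equal(dispersionIndex(c * v),
                                    c * dispersionIndex(v))
    # agrees with a direct two-pass computation
    two_pass <- sum((v - mean(v))^2) / (length(v) - 1) / mean(v)
    expect_equal(dispersionIndex(v), two_pass, tolerance = 1e-12)
})

test_that("family aggregation conserves copy number and ranking follows the dispersion order", {
    labels <- makeLabels(2, 3)
    samples <- unique(labels$sample_id)
    set.seed(13)
    genes <- sprintf("g%02d", 1:30)
    fams <- data.frame(gene_id = genes,
                       family_id = rep(sprintf("F%02d", 1:10), each = 3))
    m <- matrix(stats::rpois(30 * 5, 4), 30, 5,
                dimnames = list(genes, samples))
    gcn <- CopyNumberExperiment(m, unit = "gene", method = "assembly")
    fcn <- familyCopyNumber(gcn, fams)
    fm <- copyNumber(fcn)
    for (s in samples)
        expect_equal(unname(fm[, s]),
                     unname(rowsum(m[, s], fams$family_id)[, 1]))
    rk <- rankFamilies(fcn, min_mean_cn = 3, top_k = 5)
    tab <- rk$table[rk$table$eligible, ]
    oracle <- tab$family_id[order(-tab$dispersion, tab$family_id)]
    expect_equal(rk$most_variable, utils::head(oracle, 5))
    expect_equal(rk$least_variable, utils::head(rev(oracle), 5))
    # mean CN at and below the threshold is excluded (strict > 3)
    low <- matrix(2.9, 1, 5, dimnames = list("Flow", samples))
    at <- matrix(3.0, 1, 5, dimnames = list("Fat", samples))
    cm <- CopyNumberExperiment(rbind(fm, low, at), unit = "family",
                               method = "assembly")
    rk2 <- suppressWarnings(rankFamilies(cm, top_k = 50))
    expect_false(rk2$table$eligible[rk2$table$family_id == "Flow"])
    expect_false(rk2$table$eligible[rk2$table$family_id == "Fat"])
    expect_warning(rankFamilies(fcn, top_k = 50), "eligible")
})
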