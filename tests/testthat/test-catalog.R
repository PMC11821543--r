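# Interval projection, union flattening, presence, frequency classes,
# accumulation.

test_that("interval projection matches a per-base brute-force oracle", {
    blocks <- blockRow(hap_chrom = "h1", hap_start = 5000L, hap_end = 6000L,
                       ref_start = 1000L, ref_end = 2000L)
    pr <- projectInterval("h1", 5100L, 5200L, blocks)
    expect_equal(pr$projected,
                 data.frame(chrom = "chr1", start = 1100L, end = 1200L))
    expect_length(pr$unplaced, 0L)

    # reverse strand mirrors offsets within the block
    rev <- blocks; rev$strand <- "-"
    pr2 <- projectInterval("h1", 5100L, 5200L, rev)
    expect_equal(pr2$projected,
                 data.frame(chrom = "chr1", start = 1800L, end = 1900L))

    # partial coverage: projected head plus unplaced remainder
    pr3 <- projectInterval("h1", 4900L, 5050L, blocks)
    expect_equal(pr3$projected,
                 data.frame(chrom = "chr1", start = 1000L, end = 1050L))
    expect_equal(pr3$unplaced, 100L)

    # brute force agreement on random intervals over a multi-block table
    set.seed(11)
    btab <- rbind(
        blockRow(hap_start = 0L, hap_end = 3000L, ref_start = 10000L,
                 ref_end = 13000L),
        blockRow(hap_start = 4000L, hap_end = 5000L, strand = "-",
                 ref_start = 20000L, ref_end = 21000L, id = "b2"),
        blockRow(hap_start = 5000L, hap_end = 9000L, ref_start = 40000L,
                 ref_end = 44000L, id = "b3"))
    for (rep in 1:25) {
        s <- sample(0:8900, 1); e <- s + sample(50:900, 1)
        pr <- projectInterval("h1", s, e, btab)
        oracle <- projectBases("h1", s, e, btab)
        got <- unlist(lapply(seq_len(nrow(pr$projected)), function(i)
            pr$projected$start[i]:(pr$projected$end[i] - 1L)))
        expect_setequal(got, oracle[!is.na(oracle)])
        expect_equal(sum(pr$unplaced), sum(is.na(oracle)))
    }
    expect_error(projectInterval("nope", 0L, 10L, btab),
                 "unknown haplotype chromosome")
})

test_that("projection is length-preserving and invertible on forward blocks", {
    blocks <- blockRow(hap_start = 2000L, hap_end = 9000L,
                       ref_start = 100000L, ref_end = 107000L)
    for (s in c(2000L, 3500L, 8000L)) {
        e <- s + 600L
        pr <- projectInterval("h1", s, e, blocks)
        expect_equal(sum(pr$projected$end - pr$projected$start), 600L)
        # back-project through the inverse block table
        inv <- blockRow(hap_chrom = "chr1", hap_start = 100000L,
                        hap_end = 107000L, ref_chrom = "h1",
                        ref_start = 2000L, ref_end = 9000L)
        back <- projectInterval("chr1", pr$projected$start,
                                pr$projected$end, inv)
        expect_equal(back$projected$start, s)
        expect_equal(back$projected$end, e)
    }
})

test_that("flattenUnion equals the per-base bit-vector oracle and handles edge cases", {
    fl <- flattenUnion(data.frame(chrom = "c", start = c(100, 150, 500),
                                  end = c(200, 300, 600)))
    expect_equal(fl$regions$start, c(100L, 500L))
    expect_equal(fl$regions$end, c(300L, 600L))
    expect_equal(fl$total_bp, 300)

    disjoint <- data.frame(chrom = "c", start = c(0, 1000),
                           end = c(10, 1010))
    expect_equal(flattenUnion(disjoint)$total_bp, 20)
    expect_equal(flattenUnion(disjoint)$regions$start, c(0L, 1000L))

    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer())
    expect_equal(flattenUnion(empty)$total_bp, 0)

    set.seed(5)
    for (rep in 1:20) {
        n <- sample(5:40, 1)
        s <- sample(0:9e4, n, replace = TRUE)
        e <- s + sample(1:5000, n, replace = TRUE)
        fl <- flattenUnion(data.frame(chrom = "c", start = s, end = e))
        expect_equal(fl$total_bp, unionBitOracle(s, e, 1e5))
        # output disjoint and sorted
        expect_true(all(diff(fl$regions$start) > 0))
        expect_true(all(utils::head(fl$regions$end, -1) <
                        utils::tail(fl$regions$start, -1)))
    }
})

test_that("presence respects the 50% coverage threshold inclusively", {
    regions <- data.frame(chrom = "c", start = 0L, end = 1000L)
    haps <- c("S1_h1", "S1_h2")
    iv <- function(e) data.frame(haplotype_id = "S1_h1", chrom = "c",
                                 start = 0L, end = e)
    expect_equal(buildPresence(regions, iv(600L), haps)[1, ], c(S1_h1 = 1L,
                                                                S1_h2 = 0L))
    expect_equal(unname(buildPresence(regions, iv(400L), haps)[1, "S1_h1"]), 0L)
    expect_equal(unname(buildPresence(regions, iv(500L), haps)[1, "S1_h1"]), 1L)
    expect_error(buildPresence(regions, data.frame(haplotype_id = "zz",
                                                   chrom = "c", start = 0L,
                                                   end = 10L), haps),
                 "missing from cohort")
})

test_that("frequency classification follows the pangenome rules", {
    # fixed: carried by every haplotype
    expect_equal(classifyFrequency(170L, 85L, TRUE, 170L), "fixed")
    # private: one sample, absent from the reference
    expect_equal(classifyFrequency(2L, 1L, FALSE, 170L), "private")
    expect_equal(classifyFrequency(1L, 1L, FALSE, 170L), "private")
    # novel polymorphic: >= 2 samples, not in reference
    expect_equal(classifyFrequency(3L, 3L, FALSE, 170L),
                 "polymorphic_novel")
    # known polymorphic: in reference and not fixed, even at one sample
    expect_equal(classifyFrequency(1L, 1L, TRUE, 170L),
                 "polymorphic_known")
    expect_error(classifyFrequency(0L, 0L, FALSE, 170L),
                 "should not exist")
    # classes partition any simulated catalog
    co <- simulateCohort(simConfig(n_afr_samples = 4, n_nonafr_samples = 5,
                                   n_intra_templates = 60,
                                   n_inter_templates = 20,
                                   afr_intra_excess_bp = 2e4,
                                   n_families = 10, n_shifted = 2),
                         seed = 3)
    proj <- projectPairs(co$pairs, co$blocks)
    ctl <- buildCatalog(proj$intervals, co$labels, co$reference_sd)
    cls <- S4Vectors::mcols(regions(ctl))$freq_class
    expect_true(all(cls %in% c("fixed", "polymorphic_known",
                               "polymorphic_novel", "private")))
    expect_equal(sum(table(cls)), length(ctl))
})

test_that("accumulation curve is monotone, ordering-invariant in total and matches the union", {
    cfg <- simConfig(n_afr_samples = 3, n_nonafr_samples = 2,
                     n_intra_templates = 50, n_inter_templates = 15,
                     afr_intra_excess_bp = 2e4, n_families = 8,
                     n_shifted = 2)
    co <- simulateCohort(cfg, seed = 9)
    proj <- projectPairs(co$pairs, co$blocks)
    ctl <- buildCatalog(proj$intervals, co$labels, co$reference_sd)
    acc <- accumulationCurve(ctl)
    expect_true(all(diff(acc$curve$cumulative_bp) >= 0))
    union_bp <- flattenUnion(regions(ctl))$total_bp
    expect_equal(utils::tail(acc$curve$cumulative_bp, 1), union_bp)
    # a different ordering changes the shape but not the final total
    set.seed(1)
    perm <- sample(haplotypeIds(ctl))
    acc2 <- accumulationCurve(ctl, ordering = perm)
    expect_equal(utils::tail(acc2$curve$cumulative_bp, 1), union_bp)
    expect_error(accumulationCurve(ctl, ordering = perm[-1]),
                 "permutation")
    # two identical haplotypes: the second adds nothing
    labels <- makeLabels(1, 1)
    iv <- do.call(rbind, lapply(labels$haplotype_id[1:2], function(h)
        data.frame(haplotype_id = h, chrom = "c", start = 0L, end = 5000L,
                   kind = "intrachromosomal")))
    ctl2 <- buildCatalog(iv, labels,
                         data.frame(chrom = "c", start = 0L, end = 5000L))
    acc3 <- accumulationCurve(ctl2,
                              ordering = labels$haplotype_id)
    expect_equal(acc3$curve$added_bp, c(5000, 0, 0, 0))
})
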