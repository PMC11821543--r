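# Window exclusion, GC recalibration, CN normalisation, gene medians,
# adjustment, concordance.

test_that("window exclusion uses a strict 10% repeat-overlap rule", {
    win <- data.frame(chrom = "c", start = c(0L, 1000L, 2000L),
                      end = c(1000L, 2000L, 3000L))
    reps <- data.frame(chrom = "c", start = c(0L, 1000L),
                       end = c(101L, 1100L))  # 10.1% and 10.0%
    out <- excludeWindows(win, reps)
    expect_equal(out$excluded, c(TRUE, FALSE, FALSE))
    none <- excludeWindows(win, reps[0, ])
    expect_false(any(none$excluded))
})

test_that("GC recalibration is the identity on unbiased input and recovers planted bias", {
    set.seed(4)
    n <- 20000
    gc <- stats::runif(n, 0.25, 0.75)
    flat <- data.frame(depth = rep(30, n), gc = gc)
    m0 <- gcRecalibrate(flat)
    expect_true(all(abs(m0@factor - 1) < 1e-12))
    # inflate depth by 1.2 in one GC band
    biased <- flat
    band <- gc >= 0.6 & gc < 0.7
    biased$depth[band] <- 36
    m1 <- gcRecalibrate(biased)
    mid <- (utils::head(m1@breaks, -1) + utils::tail(m1@breaks, -1)) / 2
    inband <- mid >= 0.6 & mid < 0.7
    expect_true(all(abs(m1@factor[inband] -
                        36 / mean(biased$depth)) < 0.01))
    # correcting the self sample flattens it: every bin within 1% of CN 2
    corr <- gcCorrect(m1, biased$depth, biased$gc)
    cn <- 2 * corr / mean(corr)
    for (k in seq_along(m1@factor)) {
        sel <- gc >= m1@breaks[k] & gc < m1@breaks[k + 1]
        expect_lt(abs(mean(cn[sel]) - 2), 0.02)
    }
    # fixed point: refitting on the corrected sample gives unit factors
    m2 <- gcRecalibrate(data.frame(depth = corr, gc = gc))
    expect_true(all(abs(m2@factor - 1) < 1e-6))
    expect_error(gcRecalibrate(flat[1:10, ]), "not enough windows")
})

test_that("window copy number normalises corrected depth against the diploid baseline", {
    set.seed(6)
    n <- 3000
    win <- data.frame(chrom = "c", start = seq(0L, by = 1000L,
                                               length.out = n))
    win$end <- win$start + 1000L
    win$gc <- stats::runif(n, 0.3, 0.7)
    win$depth <- 30
    win$depth[1:10] <- 60   # one CN-4 stretch
    model <- gcRecalibrate(data.frame(depth = rep(30, n), gc = win$gc))
    baseline_regions <- data.frame(chrom = "c", start = 10000L,
                                   end = max(win$end))
    out <- windowCN(win, model, baseline_regions = baseline_regions)
    expect_equal(out$cn[11], 2.0)
    expect_equal(out$cn[1], 4.0)
    # excluded windows carry no CN
    win$excluded <- c(TRUE, rep(FALSE, n - 1))
    out2 <- windowCN(win, model, baseline_regions = baseline_regions)
    expect_true(is.na(out2$cn[1]))
    expect_error(windowCN(win, model), "baseline")
})

test_that("gene CN is the median of fully contained windows only", {
    win <- data.frame(chrom = "c",
                      start = c(0L, 1000L, 2000L, 3000L, 4000L),
                      end = c(1000L, 2000L, 3000L, 4000L, 5000L),
                      cn = c(9, 2, 2, 4, 9))
    genes <- data.frame(gene_id = c("g1", "g2"),
                        chrom = "c", start = c(900L, 4500L),
                        end = c(4100L, 4900L))
    out <- geneCNFromWindows(genes, win)
    # windows [1000,2000),[2000,3000),[3000,4000) are inside g1; the
    # straddling first/last windows are not
    expect_equal(out$cn[1], 2)
    expect_equal(out$n_windows[1], 3L)
    # g2 contains no whole window: missing value, tallied
    expect_true(is.na(out$cn[2]))
    expect_equal(attr(out, "missing"), 1L)
    # single contained window passes through
    g3 <- data.frame(gene_id = "g3", chrom = "c", start = 2900L,
                     end = 4100L)
    expect_equal(geneCNFromWindows(g3, win)$cn, 4)
})

test_that("adjustment factors anchor read depth to assembly CN with the 50% exclusion", {
    rd <- c(gA = 3.2, gB = 2.5, gC = 4.0, gD = 0, gE = 0)
    as_ <- c(gA = 4.0, gB = 4.0, gC = 4.0, gD = 2.0, gE = 0)
    adj <- calibrateAdjustment(rd, as_)
    expect_equal(adj$factor[adj$gene_id == "gA"], 1.25)
    expect_false(adj$excluded[adj$gene_id == "gA"])
    expect_equal(adj$factor[adj$gene_id == "gB"], 1.6)
    expect_true(adj$excluded[adj$gene_id == "gB"])
    expect_equal(adj$factor[adj$gene_id == "gC"], 1.0)
    expect_equal(adj$reason[adj$gene_id == "gD"], "zero_read_depth")
    expect_equal(adj$reason[adj$gene_id == "gE"], "zero_both")
    # boundary: exactly 50% adjustment is retained (strict >)
    b <- calibrateAdjustment(c(g = 2), c(g = 3))
    expect_false(b$excluded)   # a_g = 1.5
    b2 <- calibrateAdjustment(c(g = 2), c(g = 3.002))
    expect_true(b2$excluded)   # a_g = 1.501
    # retained factors make the calibration sample exact
    keep <- adj[!adj$excluded & adj$reason == "", ]
    expect_equal(rd[keep$gene_id] * keep$factor, as_[keep$gene_id])
})

test_that("concordance R2 behaves on identical, noisy and degenerate input", {
    set.seed(12)
    a <- matrix(stats::rpois(200, 4) + 1, 20, 10,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("s%02d", 1:10)))
    expect_equal(suppressWarnings(concordanceR2(a, a)), 1.0)
    noisy <- a + matrix(stats::rnorm(200, 0, 0.2), 20, 10)
    expect_gt(concordanceR2(a, noisy), 0.9)
    indep <- matrix(stats::rnorm(200), 20, 10, dimnames = dimnames(a))
    expect_lt(concordanceR2(a, indep), 0.1)
    const <- matrix(2, 20, 10, dimnames = dimnames(a))
    expect_error(concordanceR2(const, a), "constant predictor")
})
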