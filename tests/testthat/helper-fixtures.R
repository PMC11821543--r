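# Fixture builders shared across the suite. All fixtures are generated in
# code; nothing is stored on disk.

# tiny label table: n_afr + n_non samples, two haplotypes each
makeLabels <- function(n_afr = 2, n_non = 3) {
    samples <- c(sprintf("AFR%02d", seq_len(n_afr)),
                 sprintf("NON%02d", seq_len(n_non)))
    sup <- rep(c("AFR", "nonAFR"), c(n_afr, n_non))
    data.frame(sample_id = rep(samples, each = 2),
               haplotype_id = paste0(rep(samples, each = 2), "_h",
                                     rep(1:2, length(samples))),
               superpopulation = rep(sup, each = 2),
               population = rep("POP", 2 * length(samples)),
               stringsAsFactors = FALSE)
}

writePairFile <- function(df, path = tempfile(fileext = ".tsv")) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

pairRow <- function(hap = "S1_h1", chrom_a = "chr1", start_a = 0L,
                    end_a = 2000L, chrom_b = "chr1", start_b = 10000L,
                    end_b = 12000L, orientation = "+", identity = 0.95) {
    data.frame(haplotype_id = hap, chrom_a = chrom_a, start_a = start_a,
               end_a = end_a, chrom_b = chrom_b, start_b = start_b,
               end_b = end_b, orientation = orientation,
               identity = identity, length = end_a - start_a,
               stringsAsFactors = FALSE)
}

blockRow <- function(hap = "S1_h1", hap_chrom = "h1", hap_start = 5000L,
                     hap_end = 6000L, strand = "+", ref_chrom = "chr1",
                     ref_start = 1000L, ref_end = 2000L, id = "b1") {
    data.frame(haplotype_id = hap, hap_chrom = hap_chrom,
               hap_start = hap_start, hap_end = hap_end, strand = strand,
               ref_chrom = ref_chrom, ref_start = ref_start,
               ref_end = ref_end, block_id = id, stringsAsFactors = FALSE)
}

# per-base brute-force projection oracle: maps one haplotype base through a
# block table, returns reference positions of covered bases (NA = unplaced)
projectBases <- function(chrom, start, end, blocks) {
    vapply(start:(end - 1L), function(pos) {
        hit <- blocks[blocks$hap_chrom == chrom & blocks$hap_start <= pos &
                      blocks$hap_end > pos, , drop = FALSE]
        if (!nrow(hit)) return(NA_integer_)
        b <- hit[1, ]
        if (b$strand == "+") b$ref_start + (pos - b$hap_start)
        else b$ref_start + (b$hap_end - 1L - pos)
    }, integer(1))
}

# per-base bit-vector union oracle (single chromosome, coords < max_bp)
unionBitOracle <- function(starts, ends, max_bp) {
    bits <- logical(max_bp)
    for (i in seq_along(starts))
        if (ends[i] > starts[i]) bits[(starts[i] + 1L):ends[i]] <- TRUE
    sum(bits)
}

# independent Mann-Whitney oracle: U by pair counting, P by enumeration
mwOracle <- function(a, b) {
    U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    pool <- c(a, b)
    n <- length(pool); na <- length(a)
    combs <- utils::combn(n, na)
    us <- apply(combs, 2, function(idx) {
        x <- pool[idx]; y <- pool[-idx]
        sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    })
    mu <- na * length(b) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p = p)
}

# exhaustive permutation-difference oracle (one-sided, >=)
permOracle <- function(a, b, fun = mean) {
    obs <- fun(a) - fun(b)
    pool <- c(a, b)
    n <- length(pool); na <- length(a)
    combs <- utils::combn(n, na)
    stats <- apply(combs, 2, function(idx) fun(pool[idx]) - fun(pool[-idx]))
    if (obs >= 0) mean(stats >= obs - 1e-12)
    else mean(stats <= obs + 1e-12)
}

# full hypergeometric two-sided (minimum-likelihood) Fisher oracle
fisherOracle <- function(tab) {
    a <- tab[1, 1]
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    lo <- max(0, k - n2); hi <- min(k, m)
    x <- lo:hi
    d <- stats::dhyper(x, m, n2, k)
    sum(d[d <= d[x == a] * (1 + 1e-7)])
}

makeHit <- function(gene = "g1", hap = "AFR01_h1", coverage = 0.8,
                    identity = 0.95, repeat_overlap = 0.2,
                    distance_to_break = 50000L, cds_bp = 1200L) {
    data.frame(gene_id = gene, haplotype_id = hap, chrom = "chr1",
               start = 0L, end = 10000L, coverage = coverage,
               identity = identity, repeat_overlap = repeat_overlap,
               distance_to_break = distance_to_break, cds_bp = cds_bp,
               stringsAsFactors = FALSE)
}

# minimal hand-built catalog
makeTinyCatalog <- function(counts = c(10L, 11L), H = 20L) {
    labels <- makeLabels(5, 5)
    haps <- labels$haplotype_id
    gr <- GenomicRanges::GRanges(c("chr1", "chr1"),
                                 IRanges::IRanges(c(1, 100001),
                                                  c(5000, 104000)))
    pres <- matrix(0L, 2, H, dimnames = list(NULL, haps))
    for (i in 1:2) pres[i, seq_len(counts[i])] <- 1L
    samp <- sub("_h[12]$", "", haps)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        freq_class = c("polymorphic_novel", "polymorphic_novel"),
        kind = c("intrachromosomal", "intrachromosomal"),
        in_reference = c(FALSE, FALSE),
        haplotype_count = counts,
        sample_count = vapply(1:2, function(i)
            length(unique(samp[pres[i, ] == 1L])), integer(1)))
    SDRegionCatalog(gr, pres, labels = labels)
}
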