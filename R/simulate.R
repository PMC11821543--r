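# Synthetic cohort generator: SD pair call sets in assembly frame with
# alignment blocks, reference SD annotation, gene-family copy-number truth
# with paralog hits, GC-biased windowed depth, and Iso-Seq alignment
# summaries - everything the pipeline consumes, plus ground truth.

.withSeed <- function(seed, expr) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    expr
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is designed for:
#' 85 samples (38 African, 47 non-African; 170 haplotypes), a 30 Mb toy
#' layout of three chromosomes, an SD frequency spectrum mixing fixed,
#' polymorphic (known and novel) and private regions, rare SDs drawn longer
#' and with higher identity than common ones, an African excess of
#' intrachromosomal SD content, a 2.0 inversion odds ratio of interspersed
#' over clustered pairs, gene families with African-shifted copy numbers,
#' and 30x GC-biased overdispersed window depth.
#'
#' @param seed default RNG seed used by the generator functions.
#' @param n_afr_samples,n_nonafr_samples cohort composition (38 / 47).
#' @param chrom_lengths named vector of toy chromosome lengths.
#' @param slot_bp placement grid unit for SD loci (one locus per slot).
#' @param n_intra_templates,n_inter_templates number of intra- and
#'   interchromosomal SD pair templates (each contributes two region loci).
#' @param frac_clustered fraction of intra templates placed < 1 Mb apart.
#' @param freq_spectrum named fractions over intended classes
#'   (fixed, polymorphic_known, polymorphic_novel, private); must sum to 1.
#' @param afr_intra_excess_bp target mean extra intrachromosomal SD bp per
#'   African haplotype (realised with African-only rare templates).
#' @param rare_meanlog,rare_sdlog,common_meanlog,common_sdlog log-normal
#'   length parameters for rare (carrier count <= 5) vs common SD loci.
#' @param p_inv_clustered inversion probability of clustered pair records.
#' @param or_interspersed inversion odds ratio of interspersed over
#'   clustered records (default 2.0).
#' @param n_families,genes_per_family,n_shifted,afr_shift,afr_higher_frac
#'   gene-family structure: family count, member-count range, number of
#'   population-shifted families, mean diploid copy shift, and the fraction
#'   of shifted families whose copy number is higher in African samples.
#' @param depth_samples,coverage,nb_size,window_bp read-depth simulation:
#'   number of sequenced samples, haploid-pair (diploid) coverage at CN 2,
#'   negative-binomial size (overdispersion; larger = closer to Poisson) and
#'   window width.
#' @param repeat_frac fraction of windows given > 10% repeat overlap.
#' @param gene_atten_frac,gene_atten_range fraction of genes with
#'   paralog-divergence depth attenuation and its range; a further small set
#'   gets attenuation strong enough to exceed the 50% adjustment bound.
#' @param iso_planted,iso_background Iso-Seq read counts (reference-divergent
#'   planted reads vs background reads violating a threshold).
#' @return a `sim_config` list.
#' @export
simConfig <- function(seed = 1,
                      n_afr_samples = 38, n_nonafr_samples = 47,
                      chrom_lengths = c(chrA = 12e6, chrB = 10e6,
                                        chrC = 8e6),
                      slot_bp = 10000,
                      n_intra_templates = 800, n_inter_templates = 250,
                      frac_clustered = 0.55,
                      freq_spectrum = c(fixed = 0.25,
                                        polymorphic_known = 0.35,
                                        polymorphic_novel = 0.25,
                                        private = 0.15),
                      afr_intra_excess_bp = 120e3,
                      rare_meanlog = log(6000), rare_sdlog = 0.35,
                      common_meanlog = log(2500), common_sdlog = 0.4,
                      p_inv_clustered = 0.2, or_interspersed = 2.0,
                      n_families = 50, genes_per_family = 1:4,
                      n_shifted = 10, afr_shift = 2.0,
                      afr_higher_frac = 0.8,
                      depth_samples = 20, coverage = 30, nb_size = 1500,
                      window_bp = 1000, repeat_frac = 0.04,
                      gene_atten_frac = 0.15,
                      gene_atten_range = c(0.75, 0.9),
                      iso_planted = 40, iso_background = 200) {
    stopifnot(abs(sum(freq_spectrum) - 1) < 1e-8, all(freq_spectrum >= 0),
              n_afr_samples > 0, n_nonafr_samples > 0)
    cfg <- as.list(environment())
    class(cfg) <- "sim_config"
    cfg
}

.simLabels <- function(cfg) {
    afr_pops <- c("YRI", "LWK", "GWD", "MSL", "ESN")
    non_pops <- c("CEU", "CHS", "PJL", "CLM", "JPT", "GBR")
    samples <- c(sprintf("AFR%03d", seq_len(cfg$n_afr_samples)),
                 sprintf("NON%03d", seq_len(cfg$n_nonafr_samples)))
    sup <- rep(c("AFR", "nonAFR"),
               c(cfg$n_afr_samples, cfg$n_nonafr_samples))
    pop <- c(rep_len(afr_pops, cfg$n_afr_samples),
             rep_len(non_pops, cfg$n_nonafr_samples))
    data.frame(sample_id = rep(samples, each = 2),
               haplotype_id = paste0(rep(samples, each = 2), "_h",
                                     rep(1:2, length(samples))),
               superpopulation = rep(sup, each = 2),
               population = rep(pop, each = 2), stringsAsFactors = FALSE)
}

.simBlocks <- function(cfg, haps) {
    cl <- cfg$chrom_lengths
    n <- length(haps)
    offs <- 1000L * (seq_len(n) %% 7L)
    do.call(rbind, lapply(seq_along(cl), function(ci) {
        ch <- names(cl)[ci]
        data.frame(haplotype_id = haps, hap_chrom = ch,
                   hap_start = offs, hap_end = offs + cl[[ci]],
                   strand = "+", ref_chrom = ch, ref_start = 0L,
                   ref_end = cl[[ci]],
                   block_id = paste0("blk_", ch, "_", haps),
                   stringsAsFactors = FALSE)
    }))
}

# carrier haplotype set for one template
.drawCarriers <- function(class, labels, H) {
    haps <- labels$haplotype_id
    switch(class,
        fixed = haps,
        private = {
            s <- sample(unique(labels$sample_id), 1L)
            hs <- labels$haplotype_id[labels$sample_id == s]
            if (stats::runif(1) < 0.5) hs else sample(hs, 1L)
        },
        polymorphic_known = {
            k <- min(H - 1L, 1L + stats::rnbinom(1L, size = 1, mu = 14))
            sample(haps, max(1L, k))
        },
        polymorphic_novel = {
            k <- min(H - 1L, 60L,
                     2L + stats::rnbinom(1L, size = 1.5, mu = 7))
            sample(haps, max(2L, k))
        })
}

#' Simulate a synthetic SD cohort
#'
#' Draws SD pair templates on a slot grid (two disjoint loci per template),
#' assigns each a carrier haplotype set from the configured frequency
#' spectrum, draws locus length and identity from rarity-dependent
#' distributions, adds African-only intrachromosomal templates until the
#' configured per-haplotype content excess is reached, emits per-carrier
#' pair records in assembly coordinates (with per-record inversion odds by
#' dispersion class) alongside the haplotype-to-reference alignment blocks,
#' and generates the gene-family copy-number truth with matching paralog
#' hits. Deterministic under `seed`.
#'
#' @param config a [simConfig()] list.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a `sd_cohort` list: `labels`, `layout`, `blocks`, `pairs`
#'   (assembly frame), `reference_sd`, `genes`, `families`, `hits`, and
#'   `truth` (region table with classes and carriers, pair template table,
#'   gene/family CN matrices, shifted family table).
#' @export
simulateCohort <- function(config = simConfig(), seed = config$seed) {
    cfg <- config
    .withSeed(seed, {
        labels <- .simLabels(cfg)
        haps <- labels$haplotype_id
        H <- length(haps)
        afr_haps <- labels$haplotype_id[labels$superpopulation == "AFR"]
        layout <- makeGenomeLayout(cfg$chrom_lengths)
        blocks <- .simBlocks(cfg, haps)

        cl <- cfg$chrom_lengths
        slots <- do.call(rbind, lapply(names(cl), function(ch)
            data.frame(chrom = ch,
                       start = seq(0, cl[[ch]] - cfg$slot_bp,
                                   by = cfg$slot_bp),
                       stringsAsFactors = FALSE)))
        free <- rep(TRUE, nrow(slots))
        pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
        pick_pair <- function(type) {
            for (try in 1:40) {
                avail <- which(free)
                if (length(avail) < 2L) return(NULL)
                i <- pick1(avail)
                cand <- which(free & slots$chrom == slots$chrom[i])
                d <- abs(slots$start[cand] - slots$start[i])
                cand <- switch(type,
                    clustered = cand[d > 0 & d <= 9e5],
                    interspersed = cand[d >= 1.2e6],
                    inter = which(free & slots$chrom != slots$chrom[i]))
                if (length(cand)) {
                    j <- pick1(cand)
                    free[c(i, j)] <<- FALSE
                    return(c(i, j))
                }
            }
            NULL
        }

        n_clu <- round(cfg$n_intra_templates * cfg$frac_clustered)
        n_int <- cfg$n_intra_templates - n_clu
        types <- c(rep("clustered", n_clu), rep("interspersed", n_int),
                   rep("inter", cfg$n_inter_templates))
        tmpl <- list()
        for (tt in types) {
            ij <- pick_pair(tt)
            if (is.null(ij)) next
            cls <- sample(names(cfg$freq_spectrum), 1L,
                          prob = cfg$freq_spectrum)
            carriers <- .drawCarriers(cls, labels, H)
            tmpl[[length(tmpl) + 1L]] <-
                list(type = tt, slot_a = ij[1], slot_b = ij[2],
                     in_reference = cls %in% c("fixed", "polymorphic_known"),
                     carriers = carriers)
        }
        # African-only intrachromosomal templates up to the target excess
        n_afr_h <- length(afr_haps)
        excess <- 0
        while (excess < cfg$afr_intra_excess_bp) {
            ij <- pick_pair(sample(c("clustered", "interspersed"), 1L))
            if (is.null(ij)) break
            k <- min(sample(5:20, 1L), n_afr_h)
            carriers <- sample(afr_haps, k)
            len <- min(max(1001, round(exp(stats::rnorm(
                1, cfg$rare_meanlog, cfg$rare_sdlog)))), cfg$slot_bp - 1000)
            tmpl[[length(tmpl) + 1L]] <-
                list(type = if (abs(slots$start[ij[1]] -
                                    slots$start[ij[2]]) > 1e6)
                         "interspersed" else "clustered",
                     slot_a = ij[1], slot_b = ij[2], in_reference = FALSE,
                     carriers = carriers, afr_only = TRUE, fixed_len = len)
            # both mates of an intra pair count toward intra content
            excess <- excess + 2 * len * k / n_afr_h
        }

        nT <- length(tmpl)
        counts <- vapply(tmpl, function(t) length(t$carriers), integer(1))
        rare <- counts <= 5
        lens <- ifelse(rare,
                       exp(stats::rnorm(nT, cfg$rare_meanlog, cfg$rare_sdlog)),
                       exp(stats::rnorm(nT, cfg$common_meanlog,
                                        cfg$common_sdlog)))
        lens <- pmin(pmax(round(lens), 1001), cfg$slot_bp - 1000)
        fixed <- vapply(tmpl, function(t)
            if (is.null(t$fixed_len)) NA_real_ else t$fixed_len, numeric(1))
        lens <- ifelse(is.na(fixed), lens, fixed)
        idy <- ifelse(rare, 0.985 + 0.014 * stats::rbeta(nT, 2, 2),
                      0.925 + 0.055 * stats::rbeta(nT, 2, 2))
        offA <- floor(stats::runif(nT, 10, cfg$slot_bp - lens - 10))
        offB <- floor(stats::runif(nT, 10, cfg$slot_bp - lens - 10))
        sa <- vapply(tmpl, `[[`, integer(1), "slot_a")
        sb <- vapply(tmpl, `[[`, integer(1), "slot_b")
        tdf <- data.frame(
            template_id = sprintf("T%04d", seq_len(nT)),
            type = vapply(tmpl, `[[`, character(1), "type"),
            chrom_a = slots$chrom[sa], start_a = slots$start[sa] + offA,
            chrom_b = slots$chrom[sb], start_b = slots$start[sb] + offB,
            length = lens, identity = idy,
            in_reference = vapply(tmpl, `[[`, logical(1), "in_reference"),
            carrier_count = counts, stringsAsFactors = FALSE)
        tdf$end_a <- tdf$start_a + tdf$length
        tdf$end_b <- tdf$start_b + tdf$length
        tdf$afr_only <- vapply(tmpl, function(t) isTRUE(t$afr_only),
                               logical(1))

        # per-carrier pair records in assembly coordinates
        hap_idx <- stats::setNames(seq_len(H), haps)
        offs <- 1000L * (hap_idx %% 7L)
        rec_t <- rep(seq_len(nT), counts)
        rec_h <- unlist(lapply(tmpl, `[[`, "carriers"), use.names = FALSE)
        odds_c <- cfg$p_inv_clustered / (1 - cfg$p_inv_clustered)
        p_inv_i <- cfg$or_interspersed * odds_c /
            (1 + cfg$or_interspersed * odds_c)
        p_inv <- c(clustered = cfg$p_inv_clustered,
                   interspersed = p_inv_i, inter = 0.25)[tdf$type[rec_t]]
        inv <- stats::runif(length(rec_t)) < p_inv
        jit <- stats::runif(length(rec_t), -0.001, 0.001)
        off_rec <- offs[rec_h]
        pairs <- data.frame(
            haplotype_id = rec_h,
            chrom_a = tdf$chrom_a[rec_t],
            start_a = tdf$start_a[rec_t] + off_rec,
            end_a = tdf$end_a[rec_t] + off_rec,
            chrom_b = tdf$chrom_b[rec_t],
            start_b = tdf$start_b[rec_t] + off_rec,
            end_b = tdf$end_b[rec_t] + off_rec,
            orientation = ifelse(inv, "-", "+"),
            identity = pmin(1, pmax(0.901, tdf$identity[rec_t] + jit)),
            length = tdf$length[rec_t],
            template_id = tdf$template_id[rec_t],
            stringsAsFactors = FALSE)

        ref_sd <- rbind(
            data.frame(chrom = tdf$chrom_a, start = tdf$start_a,
                       end = tdf$end_a)[tdf$in_reference, ],
            data.frame(chrom = tdf$chrom_b, start = tdf$start_b,
                       end = tdf$end_b)[tdf$in_reference, ])
        ref_sd <- ref_sd[order(ref_sd$chrom, ref_sd$start), , drop = FALSE]
        rownames(ref_sd) <- NULL

        # region-level truth: both loci, classified by the frequency rules
        hap2samp <- stats::setNames(labels$sample_id, labels$haplotype_id)
        scount <- vapply(tmpl, function(t)
            length(unique(hap2samp[t$carriers])), integer(1))
        tcls <- classifyFrequency(counts, scount, tdf$in_reference, H)
        regions_truth <- rbind(
            data.frame(chrom = tdf$chrom_a, start = tdf$start_a,
                       end = tdf$end_a, template_id = tdf$template_id,
                       mate = "a", stringsAsFactors = FALSE),
            data.frame(chrom = tdf$chrom_b, start = tdf$start_b,
                       end = tdf$end_b, template_id = tdf$template_id,
                       mate = "b", stringsAsFactors = FALSE))
        idx <- match(regions_truth$template_id, tdf$template_id)
        regions_truth$freq_class <- tcls[idx]
        regions_truth$carrier_count <- counts[idx]
        regions_truth$in_reference <- tdf$in_reference[idx]
        regions_truth$kind <- ifelse(tdf$type[idx] == "inter",
                                     "interchromosomal", "intrachromosomal")
        regions_truth <-
            regions_truth[order(regions_truth$chrom, regions_truth$start), ]
        rownames(regions_truth) <- NULL

        gene_truth <- .simGenes(cfg, labels)

        structure(list(config = cfg, seed = seed, labels = labels,
                       layout = layout, blocks = blocks, pairs = pairs,
                       reference_sd = ref_sd, genes = gene_truth$genes,
                       families = gene_truth$families,
                       hits = gene_truth$hits,
                       truth = list(templates = tdf,
                                    regions = regions_truth,
                                    template_carriers =
                                        lapply(tmpl, `[[`, "carriers"),
                                    gene_cn = gene_truth$gene_cn,
                                    family_cn = gene_truth$family_cn,
                                    shifted = gene_truth$shifted,
                                    attenuation = gene_truth$attenuation)),
                  class = "sd_cohort")
    })
}

.simGenes <- function(cfg, labels) {
    cl <- cfg$chrom_lengths
    haps <- labels$haplotype_id
    samples <- unique(labels$sample_id)
    nfam <- cfg$n_families
    sizes <- sample(cfg$genes_per_family, nfam, replace = TRUE)
    fam_ids <- sprintf("FAM%03d", seq_len(nfam))
    gene_fam <- rep(fam_ids, sizes)
    ngene <- length(gene_fam)
    gene_ids <- sprintf("G%04d", seq_len(ngene))
    gslots <- do.call(rbind, lapply(names(cl), function(ch)
        data.frame(chrom = ch, start = seq(0, cl[[ch]] - 30000, by = 30000),
                   stringsAsFactors = FALSE)))
    pick <- sample(nrow(gslots), ngene)
    glen <- sample(15000:25000, ngene, replace = TRUE)
    genes <- data.frame(gene_id = gene_ids, family_id = gene_fam,
                        chrom = gslots$chrom[pick],
                        start = gslots$start[pick] + 1000,
                        cds_bp = sample(c(1200L, 2400L, 900L), ngene,
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
    genes$end <- genes$start + glen
    # per-haplotype paralog counts
    volatile <- stats::runif(ngene) < 0.3
    lam <- ifelse(volatile, stats::runif(ngene, 0.3, 1.0),
                  stats::runif(ngene, 0.3, 0.8))
    hap_counts <- matrix(0L, ngene, length(haps),
                         dimnames = list(gene_ids, haps))
    for (g in seq_len(ngene)) {
        base <- if (volatile[g]) stats::rpois(length(haps), lam[g])
                else 1L + stats::rpois(length(haps), lam[g])
        hap_counts[g, ] <- pmin(base, 6L)
    }
    # population-shifted families: extra copies on the first member gene
    shifted_fams <- sample(fam_ids, cfg$n_shifted)
    n_hi <- round(cfg$n_shifted * cfg$afr_higher_frac)
    dir_afr <- c(rep(TRUE, n_hi), rep(FALSE, cfg$n_shifted - n_hi))
    afr_h <- labels$haplotype_id[labels$superpopulation == "AFR"]
    non_h <- labels$haplotype_id[labels$superpopulation == "nonAFR"]
    for (i in seq_along(shifted_fams)) {
        g <- which(gene_fam == shifted_fams[i])[1]
        tgt <- if (dir_afr[i]) afr_h else non_h
        hap_counts[g, tgt] <- pmin(hap_counts[g, tgt] +
            stats::rpois(length(tgt), cfg$afr_shift / 2), 6L)
    }
    shifted <- data.frame(family_id = shifted_fams,
                          direction = ifelse(dir_afr, "AFR_higher",
                                             "nonAFR_higher"),
                          stringsAsFactors = FALSE)
    # diploid truth
    hap_of <- split(labels$haplotype_id, labels$sample_id)[samples]
    gene_cn <- vapply(samples, function(s)
        rowSums(hap_counts[, hap_of[[s]], drop = FALSE]),
        numeric(ngene))
    dimnames(gene_cn) <- list(gene_ids, samples)
    family_cn <- rowsum(gene_cn, group = gene_fam)
    family_cn <- family_cn[order(rownames(family_cn)), , drop = FALSE]
    # paralog hits consistent with the truth
    tot <- sum(hap_counts)
    gi <- rep(rep(gene_ids, ncol(hap_counts)), as.integer(hap_counts))
    hi <- rep(rep(haps, each = ngene), as.integer(hap_counts))
    gidx <- match(gi, gene_ids)
    hits <- data.frame(
        gene_id = gi, haplotype_id = hi,
        chrom = genes$chrom[gidx],
        start = genes$start[gidx] +
            as.integer(stats::runif(tot, 0, 2000)),
        coverage = stats::runif(tot, 0.75, 1.0),
        identity = stats::runif(tot, 0.95, 0.999),
        repeat_overlap = stats::runif(tot, 0, 0.5),
        distance_to_break = sample(40000:200000, tot, replace = TRUE),
        cds_bp = genes$cds_bp[gidx], stringsAsFactors = FALSE)
    hits$end <- hits$start + (genes$end - genes$start)[gidx]
    hits <- hits[c("gene_id", "haplotype_id", "chrom", "start", "end",
                   "coverage", "identity", "repeat_overlap",
                   "distance_to_break", "cds_bp")]
    # gene-level depth attenuation (paralog divergence): most genes 1.0
    att <- rep(1, ngene)
    n_att <- round(ngene * cfg$gene_atten_frac)
    att_idx <- sample(ngene, n_att)
    att[att_idx] <- stats::runif(n_att, cfg$gene_atten_range[1],
                                 cfg$gene_atten_range[2])
    n_bad <- max(1L, round(ngene * 0.03))
    bad_idx <- sample(setdiff(seq_len(ngene), att_idx), n_bad)
    att[bad_idx] <- stats::runif(n_bad, 0.5, 0.62)
    attenuation <- data.frame(gene_id = gene_ids, attenuation = att,
                              stringsAsFactors = FALSE)
    list(genes = genes[c("gene_id", "family_id", "chrom", "start", "end",
                         "cds_bp")],
         families = genes[c("gene_id", "family_id")],
         hits = hits, gene_cn = gene_cn, family_cn = family_cn,
         shifted = shifted, attenuation = attenuation)
}

.gcBias <- function(gc) 0.6 + 0.4 * exp(-((gc - 0.45)^2) / (2 * 0.12^2))

#' Simulate windowed read depth conditioned on copy-number truth
#'
#' Tiles the layout with fixed windows, assigns each a GC fraction, plants
#' repeat annotation (a small fraction of windows with just-over-10%,
#' exactly-10% and heavy overlap), and draws per-sample window depth from a
#' negative-binomial model with mean
#' `coverage * (CN/2) * gc_bias(gc) * attenuation(gene)`; true CN is 2
#' outside gene spans and the sample's diploid gene CN inside them. A
#' noise-free uniform self sample (true CN 2 everywhere, no attenuation) is
#' emitted for GC recalibration, and the complement of the gene spans is
#' returned as the diploid baseline ("unique") region set.
#'
#' @param cohort an `sd_cohort` from [simulateCohort()].
#' @param seed RNG seed (default: cohort seed + 1).
#' @return list with `windows` (chrom, start, end, gc), `repeats`,
#'   `self_depth`, `samples` (named list of per-sample window tables with
#'   `depth`), `unique_regions`, `sample_ids`, and `truth_cn` (window x
#'   sample true copy number matrix).
#' @export
simulateDepth <- function(cohort, seed = cohort$seed + 1) {
    cfg <- cohort$config
    .withSeed(seed, {
        cl <- cfg$chrom_lengths
        win <- do.call(rbind, lapply(names(cl), function(ch)
            data.frame(chrom = ch,
                       start = seq(0, cl[[ch]] - cfg$window_bp,
                                   by = cfg$window_bp),
                       stringsAsFactors = FALSE)))
        win$end <- win$start + cfg$window_bp
        nw <- nrow(win)
        win$gc <- pmin(0.8, pmax(0.2,
            0.45 + 0.17 * sin(2 * pi * win$start / 777000) +
                stats::rnorm(nw, 0, 0.05)))
        # repeat annotation: heavy overlaps plus boundary cases
        n_rep <- round(nw * cfg$repeat_frac)
        ridx <- sample(nw, n_rep + 40)
        heavy <- ridx[seq_len(n_rep)]
        at_bound <- ridx[n_rep + 1:20]       # exactly 10%: retained
        over_bound <- ridx[n_rep + 21:40]    # 10.1%: excluded
        repeats <- rbind(
            data.frame(chrom = win$chrom[heavy], start = win$start[heavy],
                       end = win$start[heavy] +
                           round(0.3 * cfg$window_bp)),
            data.frame(chrom = win$chrom[at_bound],
                       start = win$start[at_bound],
                       end = win$start[at_bound] +
                           round(0.10 * cfg$window_bp)),
            data.frame(chrom = win$chrom[over_bound],
                       start = win$start[over_bound],
                       end = win$start[over_bound] +
                           round(0.101 * cfg$window_bp)))
        repeats <- repeats[order(repeats$chrom, repeats$start), ]
        rownames(repeats) <- NULL
        # sequenced subset: balanced AFR / non-AFR
        labels <- cohort$labels
        samples <- unique(labels$sample_id)
        sup <- labels$superpopulation[match(samples, labels$sample_id)]
        k <- cfg$depth_samples
        sample_ids <- c(utils::head(samples[sup == "AFR"], ceiling(k / 2)),
                        utils::head(samples[sup == "nonAFR"], floor(k / 2)))
        # true window CN per sample: 2 outside genes, gene CN inside
        genes <- cohort$genes
        wgr <- .toGR(win$chrom, win$start, win$end)
        ggr <- .toGR(genes$chrom, genes$start, genes$end)
        hit <- GenomicRanges::findOverlaps(wgr, ggr, type = "within")
        gene_of_win <- rep(NA_integer_, nw)
        gene_of_win[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
        att <- cohort$truth$attenuation$attenuation[
            match(genes$gene_id, cohort$truth$attenuation$gene_id)]
        truth_cn <- matrix(2, nw, length(sample_ids),
                           dimnames = list(NULL, sample_ids))
        ing <- !is.na(gene_of_win)
        for (s in sample_ids)
            truth_cn[ing, s] <-
                cohort$truth$gene_cn[genes$gene_id[gene_of_win[ing]], s]
        bias <- .gcBias(win$gc)
        att_w <- ifelse(ing, att[gene_of_win], 1)
        self_depth <- data.frame(win,
                                 depth = cfg$coverage * bias,
                                 stringsAsFactors = FALSE)
        draws <- lapply(sample_ids, function(s) {
            mu <- cfg$coverage * (truth_cn[, s] / 2) * bias * att_w
            d <- win
            d$depth <- stats::rnbinom(nw, mu = mu, size = cfg$nb_size)
            d
        })
        names(draws) <- sample_ids
        # baseline diploid regions: complement of gene spans
        ug <- lapply(names(cl), function(ch) {
            g <- genes[genes$chrom == ch, , drop = FALSE]
            ir <- IRanges::setdiff(IRanges::IRanges(1, cl[[ch]]),
                                   .toIR(g$start, g$end))
            data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
                       end = IRanges::end(ir), stringsAsFactors = FALSE)
        })
        list(windows = win, repeats = repeats, self_depth = self_depth,
             samples = draws, unique_regions = do.call(rbind, ug),
             sample_ids = sample_ids, truth_cn = truth_cn)
    })
}

#' Simulate Iso-Seq alignment summaries with a planted divergent set
#'
#' Planted reads exceed both reference-divergence thresholds (haplotype
#' identity > 99.9%, reference gap-compressed identity < 99.7%) and lie in
#' rare novel SD regions (<= 10 carriers); background reads violate at least
#' one threshold. The planted read ids are the ground truth.
#'
#' @param cohort an `sd_cohort`.
#' @param seed RNG seed (default: cohort seed + 2).
#' @return list with `alignments` (the Iso-Seq table) and `truth`
#'   (`planted_reads`, `family_counts` per (family, haplotype)).
#' @export
simulateIsoseq <- function(cohort, seed = cohort$seed + 2) {
    cfg <- cohort$config
    .withSeed(seed, {
        tr <- cohort$truth$regions
        rare_novel <- tr[!tr$in_reference & tr$carrier_count <= 10 &
                         tr$freq_class %in%
                             c("polymorphic_novel", "private"), ,
                         drop = FALSE]
        if (!nrow(rare_novel)) stop("no rare novel regions to plant reads in")
        n_fam <- min(8L, nrow(rare_novel))
        fams <- sprintf("NVF%02d", seq_len(n_fam))
        haps <- unique(cohort$labels$haplotype_id)
        npl <- cfg$iso_planted
        fam_of <- sample(fams, npl, replace = TRUE)
        # two candidate haplotypes per family so the max-per-haplotype
        # counting rule is exercised
        fam_haps <- stats::setNames(
            lapply(fams, function(f) sample(haps, 2L)), fams)
        hap_of <- vapply(fam_of, function(f)
            sample(fam_haps[[f]], 1L), character(1))
        loci <- rare_novel[sample(nrow(rare_novel), npl, replace = TRUE), ]
        mm <- sample(8:15, npl, replace = TRUE)
        go <- sample(1:3, npl, replace = TRUE)
        planted <- if (npl == 0L) data.frame(
            read_id = character(), haplotype_id = character(),
            family_id = character(), gene_id = character(),
            hap_identity = numeric(), ref_matches = integer(),
            ref_mismatches = integer(), ref_gap_openings = integer(),
            ref_gap_bases = integer(), locus_chrom = character(),
            locus_start = integer(), locus_end = integer(),
            stringsAsFactors = FALSE)
        else data.frame(
            read_id = sprintf("pl%04d", seq_len(npl)),
            haplotype_id = hap_of, family_id = fam_of,
            gene_id = paste0(fam_of, "_", hap_of, "_g",
                             stats::ave(seq_len(npl),
                                        paste(fam_of, hap_of),
                                        FUN = seq_along)),
            hap_identity = stats::runif(npl, 0.9992, 0.9999),
            ref_matches = 2000L, ref_mismatches = mm,
            ref_gap_openings = go,
            ref_gap_bases = go * sample(1:5, npl, replace = TRUE),
            locus_chrom = loci$chrom, locus_start = loci$start,
            locus_end = loci$end, stringsAsFactors = FALSE)
        nbg <- cfg$iso_background
        mode <- sample(1:3, nbg, replace = TRUE)
        hap_id_bg <- ifelse(mode == 1, stats::runif(nbg, 0.99, 0.9988),
                            stats::runif(nbg, 0.9992, 0.9999))
        mm_bg <- ifelse(mode >= 2, sample(0:2, nbg, replace = TRUE),
                        sample(8:15, nbg, replace = TRUE))
        anyw <- cohort$truth$regions
        bg_loci <- anyw[sample(nrow(anyw), nbg, replace = TRUE), ]
        background <- data.frame(
            read_id = sprintf("bg%04d", seq_len(nbg)),
            haplotype_id = sample(haps, nbg, replace = TRUE),
            family_id = "BGF00",
            gene_id = sprintf("bgg%04d", seq_len(nbg)),
            hap_identity = hap_id_bg,
            ref_matches = 2000L, ref_mismatches = mm_bg,
            ref_gap_openings = ifelse(mode >= 2, 0L,
                                      sample(1:3, nbg, replace = TRUE)),
            ref_gap_bases = 0L,
            locus_chrom = bg_loci$chrom, locus_start = bg_loci$start,
            locus_end = bg_loci$end, stringsAsFactors = FALSE)
        al <- rbind(planted, background)
        rownames(al) <- NULL
        fc <- countNovelFamilies(planted)
        list(alignments = al,
             truth = list(planted_reads = planted$read_id,
                          family_counts = fc))
    })
}

#' Write a simulated cohort (and optional depth / Iso-Seq sets) to disk
#'
#' Emits every on-disk format the pipeline readers consume: per-haplotype SD
#' pair TSVs under `pairs/`, alignment blocks, labels, the reference SD BED,
#' gene and family tables, paralog hits, truth tables, and (when given)
#' per-sample depth tables under `depth/` plus repeat/unique-region BEDs and
#' the Iso-Seq alignment table.
#'
#' @param cohort an `sd_cohort`.
#' @param dir output directory (created).
#' @param depth optional result of [simulateDepth()].
#' @param isoseq optional result of [simulateIsoseq()].
#' @return invisibly `dir`.
#' @export
writeCohort <- function(cohort, dir, depth = NULL, isoseq = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(dir, "pairs"), showWarnings = FALSE)
    .writeTSV(cohort$labels, file.path(dir, "labels.tsv"))
    .writeTSV(cohort$blocks, file.path(dir, "blocks.tsv"))
    writeBED(cohort$reference_sd, file.path(dir, "reference_sd.bed"))
    for (hap in unique(cohort$labels$haplotype_id)) {
        d <- cohort$pairs[cohort$pairs$haplotype_id == hap,
                          SD_PAIR_COLS, drop = FALSE]
        .writeTSV(d, file.path(dir, "pairs", paste0(hap, ".tsv")))
    }
    .writeTSV(cohort$genes, file.path(dir, "genes.tsv"))
    .writeTSV(cohort$families, file.path(dir, "families.tsv"))
    .writeTSV(cohort$hits, file.path(dir, "hits.tsv"))
    .writeTSV(cohort$truth$regions, file.path(dir, "truth_regions.tsv"))
    .writeTSV(data.frame(gene_id = rownames(cohort$truth$gene_cn),
                         cohort$truth$gene_cn, check.names = FALSE),
              file.path(dir, "truth_gene_cn.tsv"))
    .writeTSV(cohort$truth$shifted, file.path(dir, "truth_shifted.tsv"))
    if (!is.null(depth)) {
        dir.create(file.path(dir, "depth"), showWarnings = FALSE)
        .writeTSV(depth$self_depth, file.path(dir, "depth", "self.tsv"))
        for (s in depth$sample_ids)
            .writeTSV(depth$samples[[s]],
                      file.path(dir, "depth", paste0(s, ".tsv")))
        writeBED(depth$repeats, file.path(dir, "repeats.bed"))
        writeBED(depth$unique_regions, file.path(dir, "unique_regions.bed"))
    }
    if (!is.null(isoseq))
        .writeTSV(isoseq$alignments, file.path(dir, "isoseq.tsv"))
    invisible(dir)
}
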