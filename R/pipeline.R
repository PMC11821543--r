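# One-command orchestration: simulate -> catalog -> properties -> gene CN ->
# depth CN -> population differentiation -> Iso-Seq filter, with a
# consolidated, reproducible report.

.stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
}

#' Run the full SD analysis pipeline on a simulated cohort
#'
#' Simulates a cohort (writing every on-disk format), reads everything back
#' through the package readers, and runs all stages in dependency order:
#' region catalog with frequency classes and accumulation curve, pair
#' property statistics (orientation x dispersion, inversion enrichment,
#' rare-vs-common comparisons), assembly and read-depth gene copy number
#' with GC recalibration and adjustment, African vs non-African
#' differentiation with replication, and the reference-divergent Iso-Seq
#' filter. Reruns with the same seed and config reproduce the report
#' bit-exactly.
#'
#' @param config a [simConfig()].
#' @param out_dir output directory.
#' @param seed seed for the generator (default `config$seed`).
#' @param n_perm permutations for the property tests (default 1000).
#' @return a `RunReport`-style list of headline numbers (invisible copies on
#'   disk: `report.tsv` and `report.txt` under `out_dir`).
#' @export
runPipeline <- function(config = simConfig(), out_dir, seed = config$seed,
                        n_perm = 1000) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cohort <- .stage("simulate", {
        co <- simulateCohort(config, seed = seed)
        dp <- simulateDepth(co)
        iso <- simulateIsoseq(co)
        writeCohort(co, file.path(out_dir, "cohort"), depth = dp,
                    isoseq = iso)
        list(co = co, dp = dp, iso = iso)
    })
    cdir <- file.path(out_dir, "cohort")

    labels <- .stage("read", readPopulationLabels(file.path(cdir,
                                                            "labels.tsv")))
    blocks <- readAlignmentBlocks(file.path(cdir, "blocks.tsv"))
    ref_sd <- readBED(file.path(cdir, "reference_sd.bed"))
    pair_files <- list.files(file.path(cdir, "pairs"), full.names = TRUE)
    pair_sets <- lapply(pair_files, readSDPairs, frame = "assembly")
    pairs <- do.call(rbind, pair_sets)

    catalog <- .stage("catalog", {
        proj <- projectPairs(pairs, blocks)
        buildCatalog(proj$intervals, labels, ref_sd)
    })
    writeRegionCatalog(catalog, file.path(out_dir, "catalog"))
    acc <- accumulationCurve(catalog)
    .writeTSV(acc$curve, file.path(out_dir, "accumulation.tsv"))

    prop <- .stage("properties", {
        cp <- classifyPairs(pairs)
        same <- cp$dispersion %in% c("clustered", "interspersed")
        tab <- table(factor(cp$dispersion[same],
                            c("interspersed", "clustered")),
                     factor(cp$orientation_class[same],
                            c("inverted", "direct")))
        enr <- enrichment2x2(tab)
        rr <- regions(catalog)
        hc <- S4Vectors::mcols(rr)$haplotype_count
        band <- rarityBand(pmax(hc, 1L), length(haplotypeIds(catalog)))$band
        w <- GenomicRanges::width(rr)
        rare_vs_common <- if (any(band == "rare") && any(band == "common"))
            permutationCompare(w[band == "rare"], w[band == "common"],
                               statistic = "median", n_perm = n_perm,
                               seed = seed)
        else NULL
        novel <- .grDF(rr[S4Vectors::mcols(rr)$freq_class %in%
                          c("polymorphic_novel", "private")])
        prox <- if (nrow(novel) && nrow(ref_sd))
            proximityPermutation(novel, ref_sd, cohort$co$layout,
                                 n_perm = n_perm, seed = seed)
        else NULL
        list(pairs = cp, inversion = enr, rare_vs_common = rare_vs_common,
             proximity = prox,
             cell_counts = table(cp$dispersion, cp$orientation_class))
    })

    genecn <- .stage("genecn", {
        hits <- readParalogHits(file.path(cdir, "hits.tsv"))
        fh <- filterHits(hits)
        acn <- assemblyCopyNumber(fh$hits, labels)
        fams <- utils::read.delim(file.path(cdir, "families.tsv"))
        fcn <- familyCopyNumber(acn$cn, fams)
        rk <- rankFamilies(fcn)
        list(gene = acn, family = fcn, ranking = rk, rejected = fh$rejected)
    })
    .writeTSV(genecn$ranking$table, file.path(out_dir, "dispersion.tsv"))

    depthcn <- .stage("depthcn", {
        repeats <- readBED(file.path(cdir, "repeats.bed"))
        uniq <- readBED(file.path(cdir, "unique_regions.bed"))
        genes <- utils::read.delim(file.path(cdir, "genes.tsv"))
        self <- readDepthWindows(file.path(cdir, "depth", "self.tsv"))
        self <- excludeWindows(self, repeats)
        model <- gcRecalibrate(self)
        sample_ids <- cohort$dp$sample_ids
        rd <- vapply(sample_ids, function(s) {
            w <- readDepthWindows(file.path(cdir, "depth",
                                            paste0(s, ".tsv")))
            w <- excludeWindows(w, repeats)
            w <- windowCN(w, model, baseline_regions = uniq)
            geneCNFromWindows(genes, w)$cn
        }, numeric(nrow(genes)))
        rownames(rd) <- genes$gene_id
        asm <- copyNumber(genecn$gene$cn)
        shared <- intersect(rownames(rd), rownames(asm))
        calib <- calibrateAdjustment(rd[shared, 1],
                                     asm[shared, sample_ids[1]])
        keep <- calib$gene_id[!calib$excluded]
        adj <- rd[keep, , drop = FALSE] *
            calib$factor[match(keep, calib$gene_id)]
        sup <- labels$superpopulation[match(sample_ids, labels$sample_id)]
        rd_cn <- CopyNumberExperiment(
            adj, unit = "gene", method = "read_depth",
            colData = S4Vectors::DataFrame(sample_id = sample_ids,
                                           superpopulation = sup))
        r2 <- concordanceR2(asm[keep, sample_ids], adj)
        list(cn = rd_cn, model = model, adjustment = calib, r2 = r2)
    })

    popdiff <- .stage("popdiff", {
        fams <- utils::read.delim(file.path(cdir, "families.tsv"))
        rd_fam <- familyCopyNumber(depthcn$cn, fams)
        cnDifferentiation(genecn$family, labels, cn2 = rd_fam)
    })
    .writeTSV(popdiff$results, file.path(out_dir, "differentiation.tsv"))

    isores <- .stage("isofilter", {
        al <- readIsoAlignments(file.path(cdir, "isoseq.tsv"))
        flt <- isoseqFilter(al, catalog = catalog, reference_sd = ref_sd)
        pass <- flt[flt$passing & flt$family_id != "BGF00", , drop = FALSE]
        list(table = flt, counts = countNovelFamilies(pass))
    })

    rr <- regions(catalog)
    cls <- S4Vectors::mcols(rr)$freq_class
    w <- GenomicRanges::width(rr)
    report <- list(
        seed = seed,
        n_haplotypes = length(haplotypeIds(catalog)),
        n_regions = length(rr),
        union_bp = sum(w),
        union_bp_by_class = tapply(w, factor(cls, FREQ_CLASSES), sum,
                                   default = 0),
        class_counts = table(factor(cls, FREQ_CLASSES)),
        mean_increment_bp = acc$mean_increment_bp,
        inversion_or = prop$inversion$odds_ratio,
        inversion_p = prop$inversion$p_value,
        rare_vs_common_p = if (!is.null(prop$rare_vs_common))
            prop$rare_vs_common$p_value else NA,
        proximity_p = if (!is.null(prop$proximity))
            prop$proximity$p_value else NA,
        most_variable = genecn$ranking$most_variable,
        least_variable = genecn$ranking$least_variable,
        concordance_r2 = depthcn$r2,
        n_adjustment_excluded = sum(depthcn$adjustment$excluded),
        diff_summary = popdiff$summary,
        novel_gene_total = isores$counts$total)
    flat <- data.frame(
        key = c("seed", "n_haplotypes", "n_regions", "union_bp",
                paste0("union_bp.", FREQ_CLASSES),
                paste0("n_regions.", FREQ_CLASSES),
                "mean_increment_bp", "inversion_or", "inversion_p",
                "rare_vs_common_p", "proximity_p", "concordance_r2",
                "n_adjustment_excluded", "n_eligible_families",
                "n_significant_families", "n_afr_higher", "binomial_p",
                "novel_gene_total"),
        value = c(seed, report$n_haplotypes, report$n_regions,
                  report$union_bp, as.numeric(report$union_bp_by_class),
                  as.numeric(report$class_counts),
                  report$mean_increment_bp, report$inversion_or,
                  report$inversion_p, report$rare_vs_common_p,
                  report$proximity_p, report$concordance_r2,
                  report$n_adjustment_excluded,
                  popdiff$summary$n_eligible,
                  popdiff$summary$n_significant,
                  popdiff$summary$n_afr_higher,
                  popdiff$summary$binomial_p,
                  report$novel_gene_total))
    .writeTSV(flat, file.path(out_dir, "report.tsv"))
    txt <- c(sprintf("SD pipeline report (seed %d)", seed),
             sprintf("regions: %d spanning %.2f Mb", report$n_regions,
                     report$union_bp / 1e6),
             sprintf("classes: %s",
                     paste(names(report$class_counts),
                           as.integer(report$class_counts),
                           sep = "=", collapse = " ")),
             sprintf("inversion OR (interspersed vs clustered): %.2f (P=%.3g)",
                     report$inversion_or, report$inversion_p),
             sprintf("assembly/read-depth concordance R2: %.3f",
                     report$concordance_r2),
             sprintf("differentiated families: %d of %d eligible (%d AFR-higher, binomial P=%.3g)",
                     popdiff$summary$n_significant,
                     popdiff$summary$n_eligible,
                     popdiff$summary$n_afr_higher,
                     popdiff$summary$binomial_p),
             sprintf("novel genes (max-per-haplotype rule): %d",
                     report$novel_gene_total))
    writeLines(txt, file.path(out_dir, "report.txt"))
    invisible(report)
}
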