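# Readers/writers for the tab-separated formats the pipeline touches.
# All on-disk coordinates are 0-based half-open (BED convention); chromosome
# names are taken verbatim (no "chr" normalisation).

# 0-based half-open [start, end) -> IRanges (1-based closed) and back
.toIR <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)
.irStart0 <- function(ir) IRanges::start(ir) - 1L
.toGR <- function(chrom, start, end) {
    GenomicRanges::GRanges(chrom, .toIR(start, end))
}
.grDF <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
}

.readTSV <- function(path, col_names, what) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(col_names, names(df))
    if (length(miss))
        stop(what, " file ", path, " is missing columns: ",
             paste(miss, collapse = ", "))
    df
}

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

.checkIntervals <- function(df, start_col, end_col, path, what) {
    bad <- which(!(df[[start_col]] < df[[end_col]]))
    if (length(bad))
        stop("validation error in ", path, ": ", what, " has start >= end at ",
             "line(s) ", paste(utils::head(bad + 1L, 5), collapse = ", "))
    if (any(df[[start_col]] < 0))
        stop("validation error in ", path, ": negative coordinates")
    invisible(TRUE)
}

SD_PAIR_COLS <- c("haplotype_id", "chrom_a", "start_a", "end_a",
                  "chrom_b", "start_b", "end_b", "orientation",
                  "identity", "length")

#' Read a segmental-duplication pair call set
#'
#' Reads a 10-column tab-separated table of aligned duplication pairs (one row
#' per pairwise SD alignment: both mate intervals, orientation, identity and
#' length). Records failing the operational SD definition (identity > 0.90 and
#' length > 1 kb) are dropped and counted; malformed records are errors.
#'
#' @param path path to a TSV with columns `haplotype_id, chrom_a, start_a,
#'   end_a, chrom_b, start_b, end_b, orientation (+/-), identity, length`.
#' @param frame coordinate frame of the records, `"reference"` or
#'   `"assembly"`; recorded on the result, not interpreted here.
#' @param chrom_names optional character vector of known chromosome names;
#'   when given, unknown chromosomes are validation errors.
#' @return data.frame of validated pairs with attribute `dropped` (number of
#'   records failing the >90% / >1 kb definition) and `frame`.
#' @export
readSDPairs <- function(path, frame = c("reference", "assembly"),
                        chrom_names = NULL) {
    frame <- match.arg(frame)
    df <- .readTSV(path, SD_PAIR_COLS, "SD pair")
    df <- df[SD_PAIR_COLS]
    num <- c("start_a", "end_a", "start_b", "end_b", "identity", "length")
    for (cc in num) {
        v <- suppressWarnings(as.numeric(df[[cc]]))
        if (anyNA(v))
            stop("parse error in ", path, ": non-numeric '", cc, "' at line ",
                 which(is.na(v))[1] + 1L)
        df[[cc]] <- v
    }
    for (cc in c("start_a", "end_a", "start_b", "end_b", "length"))
        df[[cc]] <- as.integer(df[[cc]])
    if (!all(df$orientation %in% c("+", "-")))
        stop("validation error in ", path, ": orientation must be + or -")
    .checkIntervals(df, "start_a", "end_a", path, "mate A")
    .checkIntervals(df, "start_b", "end_b", path, "mate B")
    if (!is.null(chrom_names)) {
        unk <- setdiff(unique(c(df$chrom_a, df$chrom_b)), chrom_names)
        if (length(unk))
            stop("validation error in ", path, ": unknown chromosome(s) ",
                 paste(unk, collapse = ", "))
    }
    if (any(df$length != df$end_a - df$start_a))
        stop("validation error in ", path,
             ": length must equal end_a - start_a")
    keep <- df$identity > 0.90 & df$length > 1000L
    dropped <- sum(!keep)
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "dropped") <- dropped
    attr(df, "frame") <- frame
    df
}

BLOCK_COLS <- c("haplotype_id", "hap_chrom", "hap_start", "hap_end",
                "strand", "ref_chrom", "ref_start", "ref_end", "block_id")

#' Read haplotype-to-reference alignment blocks
#'
#' Blocks are gap-free 1-to-1 alignments: both sides must have equal length
#' and, within one haplotype, the haplotype-side intervals must not overlap.
#'
#' @param path TSV with columns `haplotype_id, hap_chrom, hap_start, hap_end,
#'   strand, ref_chrom, ref_start, ref_end, block_id`.
#' @return data.frame of validated blocks (all haplotypes in one table).
#' @export
readAlignmentBlocks <- function(path) {
    df <- .readTSV(path, BLOCK_COLS, "alignment block")
    df <- df[BLOCK_COLS]
    for (cc in c("hap_start", "hap_end", "ref_start", "ref_end"))
        df[[cc]] <- as.integer(df[[cc]])
    if (!all(df$strand %in% c("+", "-")))
        stop("validation error in ", path, ": strand must be + or -")
    .checkIntervals(df, "hap_start", "hap_end", path, "haplotype side")
    .checkIntervals(df, "ref_start", "ref_end", path, "reference side")
    if (any((df$hap_end - df$hap_start) != (df$ref_end - df$ref_start)))
        stop("validation error in ", path,
             ": blocks must have equal lengths on both sides")
    for (key in split(seq_len(nrow(df)),
                      paste(df$haplotype_id, df$hap_chrom))) {
        ir <- .toIR(df$hap_start[key], df$hap_end[key])
        if (sum(IRanges::width(IRanges::reduce(ir))) != sum(IRanges::width(ir)))
            stop("validation error in ", path, ": overlapping haplotype-side ",
                 "blocks for haplotype ", df$haplotype_id[key[1]])
    }
    df
}

#' Read population labels
#'
#' @param path TSV with columns `sample_id, haplotype_id, superpopulation,
#'   population`; `superpopulation` must be `AFR` or `nonAFR`; every sample
#'   must have exactly two haplotypes and every haplotype one sample.
#' @return data.frame of labels.
#' @export
readPopulationLabels <- function(path) {
    df <- .readTSV(path, c("sample_id", "haplotype_id", "superpopulation",
                           "population"), "labels")
    validateLabels(df)
    df
}

#' Validate a population label table
#' @param labels data.frame as returned by [readPopulationLabels()].
#' @return invisibly `TRUE`; stops on violation.
#' @export
validateLabels <- function(labels) {
    if (anyDuplicated(labels$haplotype_id))
        stop("validation error: haplotype mapped to more than one sample")
    per <- table(labels$sample_id)
    if (any(per != 2))
        stop("validation error: sample(s) without exactly two haplotypes: ",
             paste(names(per)[per != 2], collapse = ", "))
    if (!all(labels$superpopulation %in% c("AFR", "nonAFR")))
        stop("validation error: superpopulation must be AFR or nonAFR")
    invisible(TRUE)
}

#' Read a BED file (first 3+ columns) as a data.frame
#'
#' @param path BED path (no header; 0-based half-open).
#' @return data.frame with `chrom, start, end` (+ `name`, `score` if present).
#' @export
readBED <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    info <- file.info(path)
    if (info$size == 0)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE))
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(df)[1:3] <- c("chrom", "start", "end")
    if (ncol(df) >= 4) names(df)[4] <- "name"
    if (ncol(df) >= 5) names(df)[5] <- "score"
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    .checkIntervals(df, "start", "end", path, "BED interval")
    df
}

#' Write intervals as BED
#' @param df data.frame with `chrom, start, end` and optional further columns
#'   written as BED columns 4+.
#' @param path output path.
#' @export
writeBED <- function(df, path) {
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write an SD region catalog to disk
#'
#' Emits `<prefix>.bed` (BED5: chrom, start, end, frequency class, haplotype
#' count, sorted by chrom/start) and `<prefix>.presence.tsv` (region x
#' haplotype 0/1 matrix with a `region` id column). [readRegionCatalog()]
#' reproduces the content exactly.
#'
#' @param catalog an [SDRegionCatalog-class].
#' @param prefix output path prefix.
#' @return invisibly the two file paths.
#' @export
writeRegionCatalog <- function(catalog, prefix) {
    rr <- regions(catalog)
    df <- .grDF(rr)
    df$name <- as.character(S4Vectors::mcols(rr)$freq_class)
    df$score <- S4Vectors::mcols(rr)$haplotype_count
    df$kind <- as.character(S4Vectors::mcols(rr)$kind)
    df$in_reference <- as.integer(S4Vectors::mcols(rr)$in_reference)
    ord <- order(df$chrom, df$start, df$end)
    df <- df[ord, , drop = FALSE]
    bed <- paste0(prefix, ".bed")
    writeBED(df, bed)
    pres <- presenceMatrix(catalog)[ord, , drop = FALSE]
    mat <- cbind(data.frame(region = if (nrow(df))
                     paste0(df$chrom, ":", df$start, "-", df$end)
                 else character(0), stringsAsFactors = FALSE),
                 as.data.frame(pres))
    tsv <- paste0(prefix, ".presence.tsv")
    .writeTSV(mat, tsv)
    invisible(c(bed = bed, presence = tsv))
}

#' Read a catalog written by [writeRegionCatalog()]
#' @param prefix the prefix passed to [writeRegionCatalog()].
#' @return An [SDRegionCatalog-class] (labels metadata is not round-tripped).
#' @export
readRegionCatalog <- function(prefix) {
    bed <- readBED(paste0(prefix, ".bed"))
    pres <- utils::read.delim(paste0(prefix, ".presence.tsv"), sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(pres[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    if (!nrow(bed)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            freq_class = character(), kind = character(),
            in_reference = logical(), haplotype_count = integer(),
            sample_count = integer())
        return(SDRegionCatalog(gr, m))
    }
    names(bed)[4:7] <- c("freq_class", "haplotype_count", "kind",
                         "in_reference")
    gr <- .toGR(bed$chrom, bed$start, bed$end)
    hap2samp <- NULL
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        freq_class = bed$freq_class, kind = bed$kind,
        in_reference = as.logical(bed$in_reference),
        haplotype_count = as.integer(bed$haplotype_count),
        sample_count = as.integer(bed$haplotype_count))  # placeholder
    # recompute sample_count only if column names look like hap ids of form
    # <sample>_h<1|2>; otherwise keep haplotype_count
    samp <- sub("_h[12]$", "", colnames(m))
    if (!all(samp == colnames(m))) {
        sc <- apply(m, 1, function(r) length(unique(samp[r == 1L])))
        S4Vectors::mcols(gr)$sample_count <- as.integer(sc)
    }
    SDRegionCatalog(gr, m)
}

PARALOG_HIT_COLS <- c("gene_id", "haplotype_id", "chrom", "start", "end",
                      "coverage", "identity", "repeat_overlap",
                      "distance_to_break", "cds_bp")

#' Read paralog alignment hits
#' @param path TSV with columns `gene_id, haplotype_id, chrom, start, end,
#'   coverage, identity, repeat_overlap, distance_to_break, cds_bp`.
#' @return validated data.frame of hits.
#' @export
readParalogHits <- function(path) {
    df <- .readTSV(path, PARALOG_HIT_COLS, "paralog hit")
    for (cc in c("coverage", "identity", "repeat_overlap"))
        if (any(df[[cc]] < 0 | df[[cc]] > 1))
            stop("validation error in ", path, ": ", cc, " outside [0,1]")
    .checkIntervals(df, "start", "end", path, "hit interval")
    df
}

#' Read a per-sample windowed depth table
#' @param path TSV with columns `chrom, start, end, depth, gc`.
#' @return validated data.frame of windows.
#' @export
readDepthWindows <- function(path) {
    df <- .readTSV(path, c("chrom", "start", "end", "depth", "gc"), "depth")
    .checkIntervals(df, "start", "end", path, "window")
    if (any(df$gc < 0 | df$gc > 1))
        stop("validation error in ", path, ": gc outside [0,1]")
    if (any(df$depth < 0))
        stop("validation error in ", path, ": negative depth")
    df
}

ISO_COLS <- c("read_id", "haplotype_id", "family_id", "gene_id",
              "hap_identity", "ref_matches", "ref_mismatches",
              "ref_gap_openings", "ref_gap_bases",
              "locus_chrom", "locus_start", "locus_end")

#' Read Iso-Seq alignment summaries
#' @param path TSV with columns `read_id, haplotype_id, family_id, gene_id,
#'   hap_identity, ref_matches, ref_mismatches, ref_gap_openings,
#'   ref_gap_bases, locus_chrom, locus_start, locus_end`.
#' @return validated data.frame.
#' @export
readIsoAlignments <- function(path) {
    df <- .readTSV(path, ISO_COLS, "Iso-Seq alignment")
    if (any(df$hap_identity < 0 | df$hap_identity > 1))
        stop("validation error in ", path, ": hap_identity outside [0,1]")
    df
}

#' Describe a genome layout
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param excluded optional data.frame `chrom, start, end` of excluded
#'   intervals (e.g. acrocentric short-arm proxies, assembly gaps).
#' @return a `genome_layout` list with elements `chrom_lengths` and
#'   `excluded`.
#' @export
makeGenomeLayout <- function(chrom_lengths, excluded = NULL) {
    stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
    if (is.null(excluded))
        excluded <- data.frame(chrom = character(), start = integer(),
                               end = integer(), stringsAsFactors = FALSE)
    if (nrow(excluded)) {
        if (any(!excluded$chrom %in% names(chrom_lengths)))
            stop("excluded interval on unknown chromosome")
        if (any(excluded$start < 0) ||
            any(excluded$end > chrom_lengths[excluded$chrom]))
            stop("excluded interval outside chromosome bounds")
    }
    structure(list(chrom_lengths = chrom_lengths, excluded = excluded),
              class = "genome_layout")
}
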