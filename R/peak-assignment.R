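# Replicate validation of ChIP peak calls and >=100 bp assignment of
# validated peaks to gene bodies and flanking bins.

# put two GRanges on the union of their seqlevels so overlap queries do
# not churn on Seqinfo merging
unifySeqlevels <- function(a, b) {
    lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
    GenomeInfoDb::seqlevels(a) <- lv
    GenomeInfoDb::seqlevels(b) <- lv
    list(a, b)
}

#' Replicate-validated peak calls
#'
#' Keeps only peak calls validated by both replicates: each replicate-1
#' peak that overlaps at least `minConsensusOverlapBp` bases (default 1)
#' of some replicate-2 peak. Coordinates of a validated peak are the
#' replicate-1 call by default; `"intersect"`/`"union"` instead combine it
#' with the replicate-2 peak it overlaps most.
#'
#' @param rep1,rep2 GRanges of peak calls from the two replicates.
#' @param config an [AssignmentConfig] (fields `minConsensusOverlapBp`,
#'   `consensusCoordinates`).
#' @return GRanges of validated peaks, a subset of `rep1` (possibly with
#'   adjusted coordinates). An empty replicate yields an empty result with
#'   a warning.
#' @examples
#' r1 <- GenomicRanges::GRanges("chrI:101-300")
#' r2 <- GenomicRanges::GRanges("chrI:251-400")
#' replicateConsensus(r1, r2)   # keeps chrI:101-300
#' @export
replicateConsensus <- function(rep1, rep2, config = AssignmentConfig()) {
    if (length(rep1) == 0L || length(rep2) == 0L) {
        warning("empty replicate peak list; no validated peaks")
        return(rep1[0])
    }
    u <- unifySeqlevels(rep1, rep2)
    hits <- findOverlaps(u[[1]], u[[2]],
                         minoverlap = config@minConsensusOverlapBp,
                         ignore.strand = TRUE)
    q <- queryHits(hits); s <- subjectHits(hits)
    if (length(hits) == 0L) return(rep1[0])
    mode <- config@consensusCoordinates
    if (mode == "rep1")
        return(rep1[sort(unique(q))])
    # pick, per rep1 peak, the rep2 peak with the largest overlap
    ov <- overlapLength(rep1[q], rep2[s])
    best <- vapply(split(seq_along(q), q),
                   function(i) i[which.max(ov[i])], integer(1))
    qi <- q[best]; si <- s[best]
    out <- rep1[qi]
    if (mode == "intersect") {
        ns <- pmax(start(rep1[qi]), start(rep2[si]))
        ne <- pmin(end(rep1[qi]), end(rep2[si]))
    } else {
        ns <- pmin(start(rep1[qi]), start(rep2[si]))
        ne <- pmax(end(rep1[qi]), end(rep2[si]))
    }
    GenomicRanges::ranges(out) <- IRanges(ns, ne)
    out
}

#' Assign peaks to gene features
#'
#' Assigns each peak to every gene feature (gene body or one of the six
#' flanking bins, see [flankingRegions()]) it overlaps by at least
#' `minOverlapBp` bases (default 100). A peak may be assigned to several
#' features of one gene and to several genes; no exclusivity is imposed.
#'
#' @param peaks GRanges of (validated) peak calls; names are used as peak
#'   ids, else `peak_00001`-style ids are minted in input order.
#' @param genes GRanges with `gene_id`.
#' @param config an [AssignmentConfig].
#' @param chromLengths passed to [flankingRegions()].
#' @return data.frame with one row per assignment: columns peak_id,
#'   gene_id, feature (factor over the seven labels), overlap_bp.
#' @examples
#' g <- GenomicRanges::GRanges("chrI:5001-7000:+", gene_id = "g1")
#' p <- GenomicRanges::GRanges("chrI:5101-5400")
#' assignPeaks(p, g, chromLengths = c(chrI = 20000))
#' @export
assignPeaks <- function(peaks, genes, config = AssignmentConfig(),
                        chromLengths = NULL) {
    feats <- flankingRegions(genes, chromLengths)
    ids <- names(peaks)
    if (is.null(ids))
        ids <- sprintf("peak_%05d", seq_along(peaks))
    u <- unifySeqlevels(peaks, feats)
    hits <- findOverlaps(u[[1]], u[[2]], minoverlap = config@minOverlapBp,
                         ignore.strand = TRUE)
    q <- queryHits(hits); s <- subjectHits(hits)
    data.frame(
        peak_id = ids[q],
        gene_id = feats$gene_id[s],
        feature = feats$feature[s],
        overlap_bp = overlapLength(peaks[q], feats[s]),
        stringsAsFactors = FALSE)
}

#' Mean peak counts per hour bin and feature
#'
#' Per-gene assignment counts averaged within hour bins of the larval
#' stage clock - the machine-readable form of the "peaks flanking and
#' within regulated genes by phase" figure. Every gene of the oscillation
#' table enters its bin, contributing zeros for features without assigned
#' peaks; non-oscillating genes form their own `non_osc` bin.
#'
#' @param assignments data.frame from [assignPeaks()]. Genes appearing
#'   here but missing from `osc` raise an error listing the ids.
#' @param osc an [OscillationSet] defining the gene universe and bins
#'   (typically restricted to the regulated gene set).
#' @param clock a [MoltClock].
#' @return data.frame with columns hour_bin (factor `1`..`stageHours`,
#'   `non_osc`), feature (the seven labels plus `total`), mean_peaks,
#'   n_genes. Bins with no genes are omitted.
#' @export
peaksPerGeneByHour <- function(assignments, osc, clock = MoltClock()) {
    universe <- geneIds(osc)
    missing <- setdiff(unique(assignments$gene_id), universe)
    if (length(missing))
        stop("assigned gene(s) missing from the oscillation table: ",
             paste(missing, collapse = ", "))
    binLevels <- c(as.character(seq_len(stageHours(clock))), "non_osc")
    bin <- rep("non_osc", length(universe))
    oscMask <- isOscillatory(osc)
    bin[oscMask] <- as.character(hourBin(phases(osc)[oscMask], clock))
    bin <- factor(bin, levels = binLevels)
    featLevels <- c(flankLabels, "total")
    # per-gene per-feature counts, zero-filled over the whole universe
    cnt <- table(factor(assignments$gene_id, levels = universe),
                 factor(as.character(assignments$feature),
                        levels = flankLabels))
    cnt <- cbind(unclass(cnt), total = rowSums(cnt))
    nGenes <- as.integer(table(bin))
    keep <- nGenes > 0L
    means <- rowsum(cnt, group = bin)
    means <- means[binLevels[keep], , drop = FALSE] / nGenes[keep]
    out <- data.frame(
        hour_bin = factor(rep(rownames(means), times = ncol(means)),
                          levels = binLevels),
        feature = factor(rep(colnames(means), each = nrow(means)),
                         levels = featLevels),
        mean_peaks = as.vector(means),
        n_genes = rep(nGenes[keep], times = ncol(means)),
        stringsAsFactors = FALSE)
    out[order(out$hour_bin, out$feature), , drop = FALSE]
}
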