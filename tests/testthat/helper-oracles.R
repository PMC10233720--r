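# Independent brute-force oracles and small fixture builders.

library(GenomicRanges)

gr1 <- function(chrom, start, end, strand = "*") {
    GRanges(chrom, IRanges(start, end), strand = strand)
}

# per-base overlap count: the set of shared integer positions
bruteOverlap <- function(chromA, startA, endA, chromB, startB, endB) {
    if (chromA != chromB) return(0L)
    length(intersect(seq(startA, endA), seq(startB, endB)))
}

# independent re-derivation of the seven feature spans of one gene
# (1-based closed coordinates), as a named list of c(start, end);
# truncated at [1, chromLen], empty bins dropped
bruteFeatures <- function(start, end, strand, chromLen) {
    if (strand == "-") {
        up <- function(lo, hi) c(end + lo, end + hi)
        dn <- function(lo, hi) c(start - hi, start - lo)
    } else {
        up <- function(lo, hi) c(start - hi, start - lo)
        dn <- function(lo, hi) c(end + lo, end + hi)
    }
    feats <- list(
        up_3_5k = up(3001, 5000), up_1_3k = up(1001, 3000),
        up_0_1k = up(1, 1000), body = c(start, end),
        down_0_1k = dn(1, 1000), down_1_3k = dn(1001, 3000),
        down_3_5k = dn(3001, 5000))
    out <- list()
    for (nm in names(feats)) {
        s <- max(feats[[nm]][1], 1)
        e <- min(feats[[nm]][2], chromLen)
        if (s <= e) out[[nm]] <- c(s, e)
    }
    out
}

# triple loop over (peak, gene, feature) with per-base overlap counting
bruteAssign <- function(peaks, genes, chromLens, minOverlap) {
    rows <- list()
    for (pi in seq_along(peaks)) {
        pc <- as.character(seqnames(peaks))[pi]
        ps <- start(peaks)[pi]; pe <- end(peaks)[pi]
        for (gi in seq_along(genes)) {
            gc <- as.character(seqnames(genes))[gi]
            feats <- bruteFeatures(start(genes)[gi], end(genes)[gi],
                                   as.character(strand(genes))[gi],
                                   chromLens[[gc]])
            for (nm in names(feats)) {
                ov <- bruteOverlap(pc, ps, pe, gc, feats[[nm]][1],
                                   feats[[nm]][2])
                if (ov >= minOverlap)
                    rows[[length(rows) + 1L]] <- data.frame(
                        peak = pi, gene = genes$gene_id[gi], feature = nm,
                        overlap = ov, stringsAsFactors = FALSE)
            }
        }
    }
    if (length(rows) == 0L)
        return(data.frame(peak = integer(0), gene = character(0),
                          feature = character(0), overlap = integer(0)))
    df <- do.call(rbind, rows)
    df[order(df$peak, df$gene, df$feature), , drop = FALSE]
}

# brute-force body rescaling: sample the piecewise-constant per-base
# signal densely on the scaled axis, then average per window
bruteScaledBody <- function(v, nOut, samplesPerWindow = 2000) {
    L <- length(v)
    xs <- seq(0, L, length.out = nOut * samplesPerWindow + 1)
    mid <- (xs[-1] + xs[-length(xs)]) / 2
    vals <- v[pmin(floor(mid) + 1, L)]
    colMeans(matrix(vals, nrow = samplesPerWindow))
}

# signal track with given per-base values on one chromosome
makeTrack <- function(values, chrom = "chrI") {
    rl <- IRanges::RleList(S4Vectors::Rle(values))
    names(rl) <- chrom
    SignalTrack(rl)
}

# oscillation set with k oscillatory genes out of n (fixed phases)
makeOscSet <- function(n, k, phase = 180) {
    OscillationSet(sprintf("g%03d", seq_len(n)),
                   c(rep(phase, k), rep(NA, n - k)),
                   c(rep(1, k), rep(NA, n - k)),
                   c(rep(TRUE, k), rep(FALSE, n - k)))
}
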