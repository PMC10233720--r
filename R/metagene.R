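# TSS/TES-anchored, body-scaled average signal profiles.
#
# Each gene contributes a fixed grid of windows: flankBp of real genomic
# sequence upstream of the TSS, the body rescaled to bodyTargetBp, and
# flankBp downstream of the TES, averaged in windowBp windows (40 + 80 +
# 40 = 160 windows at the defaults). Body rescaling treats the per-base
# signal as a piecewise-constant function of position, stretches it to the
# target length and takes exact area-weighted window means, so constants
# are preserved and the body-wide mean is unchanged by scaling.

# exact window means of a piecewise-constant per-base signal stretched to
# nOut windows of the scaled axis; v is the per-base body signal
scaleBodySignal <- function(v, nOut, windowBp) {
    L <- length(v)
    cs <- c(0, cumsum(v))
    # integral of the step function over [0, x), x in base units
    intAt <- function(x) {
        i <- floor(x)
        cs[i + 1] + (x - i) * v[pmin(i + 1, L)] * (x > i)
    }
    # window w covers scaled interval [(w-1), w) * totalScaled/nOut, which
    # maps back to base coordinates by the factor L / (nOut * windowBp)
    edges <- seq(0, L, length.out = nOut + 1)
    (intAt(edges[-1]) - intAt(edges[-(nOut + 1)])) / diff(edges)
}

#' Per-gene scaled signal profile
#'
#' Signal profile of one gene on the scaled TSS-to-TES axis: fixed
#' `windowBp` genomic windows over the flanks, and area-weighted window
#' means of the body signal rescaled to `bodyTargetBp`. Minus-strand genes
#' are reversed so the axis always runs TSS to TES. Windows extending
#' past a chromosome boundary are `NA` (missing, not zero).
#'
#' @param track a [SignalTrack].
#' @param gene a length-1 GRanges (the gene body / CDS span).
#' @param config a [MetageneConfig].
#' @param chromLengths optional named vector bounding the right flank;
#'   positions beyond a stored signal but inside the chromosome count as
#'   signal 0.
#' @return numeric vector of per-window means (length
#'   `(2*flankBp + bodyTargetBp)/windowBp`), `NA` for clipped windows. A
#'   chromosome absent from the track yields an all-zero profile with a
#'   warning.
#' @export
geneProfile <- function(track, gene, config = MetageneConfig(),
                        chromLengths = NULL) {
    stopifnot(length(gene) == 1L, width(gene) >= 1L)
    chrom <- as.character(seqnames(gene))
    fl <- config@flankBp
    w <- config@windowBp
    gStart <- start(gene) - fl
    gEnd <- end(gene) + fl
    # clip at position 1 and (when known) the chromosome end
    chromLen <- if (!is.null(chromLengths) && chrom %in% names(chromLengths))
        chromLengths[[chrom]] else Inf
    qStart <- max(gStart, 1L)
    qEnd <- min(gEnd, chromLen)
    vals <- trackValues(track, chrom, qStart, qEnd)
    v <- rep(NA_real_, gEnd - gStart + 1)
    v[(qStart - gStart + 1):(qEnd - gStart + 1)] <- vals
    if (as.character(strand(gene)) == "-") v <- rev(v)
    nf <- fl / w
    nb <- config@bodyTargetBp / w
    L <- width(gene)
    upV <- v[seq_len(fl)]
    bodyV <- v[(fl + 1):(fl + L)]
    downV <- v[(fl + L + 1):(fl + L + fl)]
    winMeans <- function(x) colMeans(matrix(x, nrow = w))
    body <- if (anyNA(bodyV)) rep(NA_real_, nb) else
        scaleBodySignal(bodyV, nb, w)
    c(winMeans(upV), body, winMeans(downV))
}

#' Window-center positions of the scaled metagene axis
#'
#' @param config a [MetageneConfig].
#' @return numeric vector; 0 marks the TSS and `bodyTargetBp` the TES.
#' @export
metageneAxis <- function(config = MetageneConfig()) {
    (seq_len(nWindows(config)) - 0.5) * config@windowBp - config@flankBp
}

#' Aggregate per-gene profiles into a metagene profile
#'
#' Per-window mean over genes with a normal-approximation confidence
#' interval of the mean, `mean +/- z * sd / sqrt(n)`. Windows missing for
#' a gene (clipped at a chromosome boundary) are excluded from that
#' window's n. With a single contributing gene the interval degenerates to
#' the mean and the profile is flagged degenerate rather than failing.
#'
#' @param profiles a matrix (genes in rows, windows in columns), or a list
#'   of per-gene profile vectors from [geneProfile()].
#' @param config a [MetageneConfig].
#' @return a [MetageneProfile].
#' @examples
#' p <- rbind(rep(0, 160), rep(2, 160))
#' aggregateProfiles(p)   # mean 1 everywhere
#' @export
aggregateProfiles <- function(profiles, config = MetageneConfig()) {
    if (is.list(profiles)) profiles <- do.call(rbind, profiles)
    if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
    if (nrow(profiles) == 0L) stop("no profiles to aggregate")
    if (ncol(profiles) != nWindows(config))
        stop("profiles have ", ncol(profiles), " windows; config expects ",
             nWindows(config))
    n <- colSums(!is.na(profiles))
    mu <- colMeans(profiles, na.rm = TRUE)
    mu[n == 0L] <- NA_real_
    sd <- apply(profiles, 2, stats::sd, na.rm = TRUE)
    z <- stats::qnorm(1 - (1 - config@ciLevel) / 2)
    half <- z * sd / sqrt(n)
    half[n <= 1L] <- 0
    new("MetageneProfile", axisPos = metageneAxis(config), mean = mu,
        ciLow = mu - half, ciHigh = mu + half, n = as.integer(n),
        nGenes = nrow(profiles), degenerate = any(n == 1L))
}

#' Metagene profiles per phase class
#'
#' Builds one aggregated metagene profile per gene class: the three
#' oscillation phase classes (early/middle/late, from the oscillation
#' records), all genes, and the lowest-expressed 20 percent
#' ("no expression", requiring an `expression_percentile` gene column).
#' Empty classes are omitted with a warning.
#'
#' @param track a [SignalTrack].
#' @param genes GRanges with `gene_id` (and `expression_percentile` for
#'   the no_expression class).
#' @param osc an [OscillationSet]; phase classes are computed for its
#'   oscillatory genes. Genes absent from `osc` only contribute to the
#'   `all` and `no_expression` classes.
#' @param config a [MetageneConfig].
#' @param classes subset of `c("early", "middle", "late", "all",
#'   "no_expression")`.
#' @param chromLengths passed to [geneProfile()].
#' @return named list of [MetageneProfile] objects.
#' @export
profileByClass <- function(track, genes, osc, config = MetageneConfig(),
                           classes = c("early", "middle", "late", "all",
                                       "no_expression"),
                           chromLengths = NULL) {
    classes <- match.arg(classes, several.ok = TRUE)
    idx <- match(genes$gene_id, geneIds(osc))
    phase <- rep(NA_real_, length(genes))
    hit <- !is.na(idx)
    phase[hit] <- phases(osc)[idx[hit]]   # NA for non-oscillatory genes
    phaseClass <- as.character(classifyPhase(phase))
    members <- list()
    for (cl in classes) {
        members[[cl]] <- switch(cl,
            all = seq_along(genes),
            no_expression = {
                if (is.null(genes$expression_percentile))
                    stop("no_expression class needs expression_percentile")
                which(genes$expression_percentile < 20)
            },
            which(!is.na(phaseClass) & phaseClass == cl))
    }
    needed <- sort(unique(unlist(members)))
    prof <- matrix(NA_real_, nrow = length(genes), ncol = nWindows(config))
    for (i in needed)
        prof[i, ] <- geneProfile(track, genes[i], config, chromLengths)
    out <- list()
    for (cl in classes) {
        if (length(members[[cl]]) == 0L) {
            warning("class '", cl, "' is empty; omitted")
            next
        }
        out[[cl]] <- aggregateProfiles(prof[members[[cl]], , drop = FALSE],
                                       config)
    }
    out
}

#' Tidy table of class profiles
#'
#' @param profileList named list from [profileByClass()].
#' @return data.frame with columns class, window_index, axis_position,
#'   mean, ci_low, ci_high, n - sufficient to replot the metagene figure.
#' @export
metageneTable <- function(profileList) {
    rows <- lapply(names(profileList), function(cl)
        cbind(class = cl, as.data.frame(profileList[[cl]]),
              stringsAsFactors = FALSE))
    do.call(rbind, rows)
}
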