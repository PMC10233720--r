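#' @import methods
#' @importFrom S4Vectors DataFrame Rle
#' @importClassesFrom IRanges RleList
#' @importFrom IRanges RleList
NULL

# ---------------------------------------------------------------------------
# MoltClock
# ---------------------------------------------------------------------------

#' Molt-anchored developmental clock
#'
#' Maps oscillation phase (degrees of one larval-stage cycle) onto
#' developmental time within a larval stage. One full 360 degree cycle
#' corresponds to one larval stage (9 h by default, so 1 h = 40 degrees).
#' Lethargus (behavioral quiescence) starts at 45 degrees and ecdysis
#' (cuticle shedding) ends at 135 degrees; the adjusted larval-stage clock
#' starts at the end of ecdysis.
#'
#' @slot stageHours duration of one larval stage in hours.
#' @slot lethargusStartDeg phase at which lethargus begins (degrees).
#' @slot ecdysisEndDeg phase at which ecdysis ends (degrees); the origin of
#'   adjusted larval-stage time.
#'
#' @seealso [adjustedHour()], [hourBin()], [inMolt()]
#' @examples
#' clock <- MoltClock()
#' degPerHour(clock)   # 40
#' @name MoltClock-class
#' @rdname MoltClock
#' @exportClass MoltClock
setClass("MoltClock",
    representation(
        stageHours = "numeric",
        lethargusStartDeg = "numeric",
        ecdysisEndDeg = "numeric"
    ),
    prototype(stageHours = 9, lethargusStartDeg = 45, ecdysisEndDeg = 135)
)

setValidity("MoltClock", function(object) {
    msg <- character()
    if (length(object@stageHours) != 1L || !is.finite(object@stageHours) ||
        object@stageHours <= 0)
        msg <- c(msg, "stageHours must be a single positive number")
    if (!(0 <= object@lethargusStartDeg &&
          object@lethargusStartDeg < object@ecdysisEndDeg &&
          object@ecdysisEndDeg < 360))
        msg <- c(msg, "need 0 <= lethargusStartDeg < ecdysisEndDeg < 360")
    if (length(msg)) msg else TRUE
})

#' @param stageHours,lethargusStartDeg,ecdysisEndDeg see slots.
#' @return `MoltClock()` returns a MoltClock object.
#' @rdname MoltClock
#' @export
MoltClock <- function(stageHours = 9, lethargusStartDeg = 45,
                      ecdysisEndDeg = 135) {
    new("MoltClock", stageHours = stageHours,
        lethargusStartDeg = lethargusStartDeg,
        ecdysisEndDeg = ecdysisEndDeg)
}

#' @describeIn MoltClock degrees of phase per developmental hour
#'   (360 / stageHours; 40 at the defaults).
#' @param object,x a MoltClock.
#' @export
degPerHour <- function(object) 360 / object@stageHours

#' @describeIn MoltClock larval-stage duration in hours.
#' @export
stageHours <- function(object) object@stageHours

setMethod("show", "MoltClock", function(object) {
    cat(sprintf(
        "MoltClock: %g h stage (%g deg/h); lethargus %g deg, ecdysis end %g deg\n",
        object@stageHours, degPerHour(object),
        object@lethargusStartDeg, object@ecdysisEndDeg))
})

# ---------------------------------------------------------------------------
# OscillationSet
# ---------------------------------------------------------------------------

#' Per-gene oscillation annotations
#'
#' Container for per-gene oscillatory-expression annotations: a peak phase
#' in degrees of the larval-stage cycle, an amplitude (log2-scale fold
#' change in the published datasets this emulates), and an oscillatory
#' flag. Non-oscillatory genes carry `NA` phase and amplitude.
#'
#' @slot geneId character, unique gene identifiers.
#' @slot phaseDeg numeric in [0, 360) for oscillatory genes, `NA` otherwise.
#' @slot amplitude nonnegative numeric, `NA` for non-oscillatory genes.
#' @slot oscillatory logical.
#'
#' @examples
#' osc <- OscillationSet(c("a", "b"), c(178.11, NA), c(2.11, NA),
#'                       c(TRUE, FALSE))
#' phases(osc)
#' @name OscillationSet-class
#' @rdname OscillationSet
#' @exportClass OscillationSet
setClass("OscillationSet",
    representation(
        geneId = "character",
        phaseDeg = "numeric",
        amplitude = "numeric",
        oscillatory = "logical"
    )
)

setValidity("OscillationSet", function(object) {
    n <- length(object@geneId)
    msg <- character()
    if (length(object@phaseDeg) != n || length(object@amplitude) != n ||
        length(object@oscillatory) != n)
        msg <- c(msg, "all slots must have equal length")
    if (anyDuplicated(object@geneId))
        msg <- c(msg, "gene ids must be unique")
    if (anyNA(object@oscillatory))
        msg <- c(msg, "oscillatory flag must not be NA")
    osc <- object@oscillatory & !is.na(object@oscillatory)
    ph <- object@phaseDeg[osc]
    if (anyNA(ph) || any(ph < 0 | ph >= 360))
        msg <- c(msg, "oscillatory genes need phaseDeg in [0, 360)")
    am <- object@amplitude[osc]
    if (anyNA(am) || any(am < 0))
        msg <- c(msg, "oscillatory genes need amplitude >= 0")
    if (length(msg)) msg else TRUE
})

#' @param geneId,phaseDeg,amplitude,oscillatory see slots. Phase and
#'   amplitude of non-oscillatory genes are forced to `NA`.
#' @return `OscillationSet()` returns an OscillationSet.
#' @rdname OscillationSet
#' @export
OscillationSet <- function(geneId, phaseDeg, amplitude, oscillatory) {
    oscillatory <- as.logical(oscillatory)
    phaseDeg <- as.numeric(phaseDeg)
    amplitude <- as.numeric(amplitude)
    phaseDeg[!oscillatory] <- NA_real_
    amplitude[!oscillatory] <- NA_real_
    new("OscillationSet", geneId = as.character(geneId), phaseDeg = phaseDeg,
        amplitude = amplitude, oscillatory = oscillatory)
}

#' @describeIn OscillationSet gene identifiers.
#' @export
geneIds <- function(object) object@geneId

#' @describeIn OscillationSet peak phases in degrees (`NA` when not
#'   oscillatory).
#' @export
phases <- function(object) object@phaseDeg

#' @describeIn OscillationSet oscillation amplitudes (`NA` when not
#'   oscillatory).
#' @export
amplitudes <- function(object) object@amplitude

#' @describeIn OscillationSet logical oscillatory flags.
#' @export
isOscillatory <- function(object) object@oscillatory

#' @describeIn OscillationSet number of genes.
#' @export
setMethod("length", "OscillationSet", function(x) length(x@geneId))

#' @describeIn OscillationSet subset by index or gene id.
#' @param i index, logical mask or character vector of gene ids.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "OscillationSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) {
        idx <- match(i, x@geneId)
        if (anyNA(idx))
            stop("unknown gene ids: ", paste(i[is.na(idx)], collapse = ", "))
        i <- idx
    }
    initialize(x, geneId = x@geneId[i], phaseDeg = x@phaseDeg[i],
               amplitude = x@amplitude[i], oscillatory = x@oscillatory[i])
})

#' @describeIn OscillationSet coerce to a base data.frame with columns
#'   gene_id, phase_deg, amplitude, oscillatory.
#' @export
setMethod("as.data.frame", "OscillationSet", function(x, ...) {
    data.frame(gene_id = x@geneId, phase_deg = x@phaseDeg,
               amplitude = x@amplitude, oscillatory = x@oscillatory,
               stringsAsFactors = FALSE)
})

setMethod("show", "OscillationSet", function(object) {
    cat(sprintf("OscillationSet: %d genes, %d oscillatory (%.1f%%)\n",
                length(object), sum(object@oscillatory),
                100 * mean(object@oscillatory)))
})

# ---------------------------------------------------------------------------
# SignalTrack
# ---------------------------------------------------------------------------

#' Genome-wide signal track
#'
#' Per-chromosome run-length encoded signal, as read from a wiggle file.
#' The signal is defined everywhere: positions not covered by any wiggle
#' block have value 0, including positions beyond the last stored run.
#'
#' @slot cov an [S4Vectors::RleList] of per-chromosome signal values
#'   (1-based positions).
#'
#' @seealso [readWiggle()], [writeWiggle()], [trackValues()]
#' @name SignalTrack-class
#' @rdname SignalTrack
#' @exportClass SignalTrack
setClass("SignalTrack", representation(cov = "RleList"))

#' @param cov an RleList of per-chromosome values, or a
#'   [GenomicRanges::GRanges] with a `score` column (non-overlapping runs).
#' @return `SignalTrack()` returns a SignalTrack.
#' @rdname SignalTrack
#' @export
SignalTrack <- function(cov) {
    if (is(cov, "GRanges")) {
        if (is.null(cov$score))
            stop("GRanges input needs a 'score' metadata column")
        cov <- GenomicRanges::coverage(cov, weight = "score")
    }
    new("SignalTrack", cov = cov)
}

#' @describeIn SignalTrack chromosome names with stored signal.
#' @export
setMethod("seqnames", "SignalTrack", function(x) names(x@cov))

#' @describeIn SignalTrack length of the stored run vector per chromosome
#'   (signal beyond it is implicitly 0).
#' @export
trackLengths <- function(object) lengths(object@cov)

setMethod("show", "SignalTrack", function(object) {
    cat(sprintf("SignalTrack: %d chromosome(s) [%s]\n",
                length(object@cov),
                paste(utils::head(names(object@cov), 5), collapse = ", ")))
})

# ---------------------------------------------------------------------------
# Configuration objects
# ---------------------------------------------------------------------------

#' Peak-to-feature assignment configuration
#'
#' @slot minOverlapBp minimum peak/feature overlap in bp for an assignment
#'   (default 100).
#' @slot minConsensusOverlapBp minimum bp overlap for a peak to be validated
#'   by the other replicate (default 1; the source analyses state no
#'   threshold).
#' @slot consensusCoordinates coordinates kept for validated peaks:
#'   `"rep1"` (default), `"intersect"` (intersection with the
#'   best-overlapping replicate-2 peak) or `"union"` (union with it).
#'
#' @examples
#' AssignmentConfig()
#' @name AssignmentConfig-class
#' @rdname AssignmentConfig
#' @exportClass AssignmentConfig
setClass("AssignmentConfig",
    representation(
        minOverlapBp = "numeric",
        minConsensusOverlapBp = "numeric",
        consensusCoordinates = "character"
    ),
    prototype(minOverlapBp = 100, minConsensusOverlapBp = 1,
              consensusCoordinates = "rep1")
)

setValidity("AssignmentConfig", function(object) {
    msg <- character()
    if (object@minOverlapBp < 1)
        msg <- c(msg, "minOverlapBp must be >= 1")
    if (object@minConsensusOverlapBp < 1)
        msg <- c(msg, "minConsensusOverlapBp must be >= 1")
    if (!object@consensusCoordinates %in% c("rep1", "intersect", "union"))
        msg <- c(msg, "consensusCoordinates must be rep1, intersect or union")
    if (length(msg)) msg else TRUE
})

#' @param minOverlapBp,minConsensusOverlapBp,consensusCoordinates see slots.
#' @return `AssignmentConfig()` returns an AssignmentConfig.
#' @rdname AssignmentConfig
#' @export
AssignmentConfig <- function(minOverlapBp = 100, minConsensusOverlapBp = 1,
                             consensusCoordinates = "rep1") {
    new("AssignmentConfig", minOverlapBp = minOverlapBp,
        minConsensusOverlapBp = minConsensusOverlapBp,
        consensusCoordinates = consensusCoordinates)
}

#' Metagene profile configuration
#'
#' @slot bodyTargetBp length every gene body is rescaled to (default 2000).
#' @slot flankBp unscaled flank on each side of the body (default 1000).
#' @slot windowBp averaging window width on the scaled axis (default 25).
#' @slot ciLevel confidence level of the per-window interval of the mean
#'   (default 0.95).
#'
#' @examples
#' MetageneConfig()          # the 160-window default grid
#' @name MetageneConfig-class
#' @rdname MetageneConfig
#' @exportClass MetageneConfig
setClass("MetageneConfig",
    representation(
        bodyTargetBp = "numeric",
        flankBp = "numeric",
        windowBp = "numeric",
        ciLevel = "numeric"
    ),
    prototype(bodyTargetBp = 2000, flankBp = 1000, windowBp = 25,
              ciLevel = 0.95)
)

setValidity("MetageneConfig", function(object) {
    msg <- character()
    if (object@windowBp < 1)
        msg <- c(msg, "windowBp must be >= 1")
    if (object@bodyTargetBp %% object@windowBp != 0)
        msg <- c(msg, "bodyTargetBp must be divisible by windowBp")
    if (object@flankBp %% object@windowBp != 0)
        msg <- c(msg, "flankBp must be divisible by windowBp")
    if (!(object@ciLevel > 0 && object@ciLevel < 1))
        msg <- c(msg, "ciLevel must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' @param bodyTargetBp,flankBp,windowBp,ciLevel see slots.
#' @return `MetageneConfig()` returns a MetageneConfig.
#' @rdname MetageneConfig
#' @export
MetageneConfig <- function(bodyTargetBp = 2000, flankBp = 1000,
                           windowBp = 25, ciLevel = 0.95) {
    new("MetageneConfig", bodyTargetBp = bodyTargetBp, flankBp = flankBp,
        windowBp = windowBp, ciLevel = ciLevel)
}

nWindows <- function(config) {
    as.integer((2 * config@flankBp + config@bodyTargetBp) / config@windowBp)
}

# ---------------------------------------------------------------------------
# MetageneProfile
# ---------------------------------------------------------------------------

#' Aggregated metagene signal profile
#'
#' Mean signal with a confidence band over a TSS-to-TES scaled axis:
#' fixed-size flanks in real genomic bp around a gene body rescaled to a
#' common length, averaged in fixed windows over a gene set.
#'
#' @slot axisPos window-center positions on the scaled axis (bp; 0 = TSS,
#'   bodyTargetBp = TES, negative = upstream flank).
#' @slot mean,ciLow,ciHigh per-window mean signal and confidence bounds.
#' @slot n per-window number of contributing genes (windows clipped off a
#'   chromosome are excluded gene-wise).
#' @slot nGenes number of genes aggregated.
#' @slot degenerate TRUE when any window had n = 1 so its interval collapsed
#'   to the mean.
#'
#' @seealso [aggregateProfiles()], [profileByClass()]
#' @name MetageneProfile-class
#' @rdname MetageneProfile-class
#' @exportClass MetageneProfile
setClass("MetageneProfile",
    representation(
        axisPos = "numeric",
        mean = "numeric",
        ciLow = "numeric",
        ciHigh = "numeric",
        n = "integer",
        nGenes = "integer",
        degenerate = "logical"
    )
)

setValidity("MetageneProfile", function(object) {
    k <- length(object@axisPos)
    if (length(object@mean) != k || length(object@ciLow) != k ||
        length(object@ciHigh) != k || length(object@n) != k)
        return("axisPos, mean, ciLow, ciHigh and n must have equal length")
    ok <- stats::complete.cases(object@ciLow, object@mean, object@ciHigh)
    if (any(object@ciLow[ok] > object@mean[ok] + 1e-12) ||
        any(object@ciHigh[ok] < object@mean[ok] - 1e-12))
        return("need ciLow <= mean <= ciHigh")
    TRUE
})

setMethod("show", "MetageneProfile", function(object) {
    cat(sprintf(
        "MetageneProfile: %d windows, %d genes%s; mean signal %.4g-%.4g\n",
        length(object@axisPos), object@nGenes,
        if (object@degenerate) " (degenerate CI)" else "",
        min(object@mean, na.rm = TRUE), max(object@mean, na.rm = TRUE)))
})

#' @describeIn MetageneProfile-class coerce to a data.frame with columns
#'   window_index, axis_position, mean, ci_low, ci_high, n.
#' @param x a MetageneProfile.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "MetageneProfile", function(x, ...) {
    data.frame(window_index = seq_along(x@axisPos), axis_position = x@axisPos,
               mean = x@mean, ci_low = x@ciLow, ci_high = x@ciHigh, n = x@n,
               stringsAsFactors = FALSE)
})

# ---------------------------------------------------------------------------
# EnrichmentResult
# ---------------------------------------------------------------------------

#' Oscillation-enrichment test result
#'
#' One-degree-of-freedom chi-squared goodness-of-fit comparison of an
#' observed oscillatory count against a fixed genome-wide null proportion.
#'
#' @slot nTotal,nOscillatory gene-set size and oscillatory count.
#' @slot fraction nOscillatory / nTotal.
#' @slot nullProportion genome-wide oscillatory proportion under the null.
#' @slot statistic chi-squared statistic (1 df).
#' @slot pValue two-sided p-value.
#' @slot yates whether the continuity correction was applied.
#'
#' @seealso [chi2Enrichment()]
#' @name EnrichmentResult-class
#' @rdname EnrichmentResult-class
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
    representation(
        nTotal = "integer",
        nOscillatory = "integer",
        fraction = "numeric",
        nullProportion = "numeric",
        statistic = "numeric",
        pValue = "numeric",
        yates = "logical"
    )
)

setValidity("EnrichmentResult", function(object) {
    msg <- character()
    if (object@nOscillatory < 0 || object@nOscillatory > object@nTotal)
        msg <- c(msg, "need 0 <= nOscillatory <= nTotal")
    if (!(object@nullProportion > 0 && object@nullProportion < 1))
        msg <- c(msg, "nullProportion must be in (0, 1)")
    if (object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "pValue must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult: %d/%d oscillatory (%.1f%%) vs null %.0f%%\n  chi-squared = %.4g (1 df%s), p = %.3g\n",
        object@nOscillatory, object@nTotal, 100 * object@fraction,
        100 * object@nullProportion, object@statistic,
        if (object@yates) ", Yates-corrected" else "", object@pValue))
})

#' @describeIn EnrichmentResult-class one-row data.frame with columns
#'   n_total, n_oscillatory, percent, null_p, chi2, p_value.
#' @param x an EnrichmentResult.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "EnrichmentResult", function(x, ...) {
    data.frame(n_total = x@nTotal, n_oscillatory = x@nOscillatory,
               percent = round(100 * x@fraction), null_p = x@nullProportion,
               chi2 = x@statistic, p_value = x@pValue,
               stringsAsFactors = FALSE)
})
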