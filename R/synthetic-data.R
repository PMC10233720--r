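# Seeded generator of synthetic genomes, oscillation annotations,
# regulated-gene sets, replicate ChIP peak calls and signal tracks with
# the statistical structure the analysis assumes: a regulated subset
# enriched for oscillation, phases clustered around the regulator's peak,
# and promoter-proximal binding whose density decays with circular
# distance from the regulator phase.

#' Synthetic-data configuration
#'
#' Defaults define the standard simulated study: 900 genes of 0.4-2 kb on
#' three 2 Mb chromosomes (one gene per ~6.7 kb, close to the real
#' nematode genome's density); 15 percent of genes oscillate genome-wide
#' while 89 percent of a 265-gene regulated set does; regulated phases
#' cluster (von Mises) around the regulator reference phase 178.11
#' degrees; each oscillatory gene draws Poisson peak counts at rate
#' `peakRateAtZero * exp(-peakRateDecay * circularDistance(phase,
#' regulatorPhase + bindingPhaseLagDeg))` (non-oscillatory genes at
#' `peakRateFloor`), with peaks placed promoter-proximally (a fraction
#' near the TES); replicate 2 jitters and drops replicate-1 peaks; the
#' signal track sums triangular per-peak bumps plus truncated Gaussian
#' noise.
#'
#' @slot seed integer master seed; each generation stage derives its own
#'   stream (seed + a fixed stage offset) so later stages never perturb
#'   earlier draws.
#' @slot nChroms,chromLengthBp,nGenes,geneLengthMinBp,geneLengthMaxBp
#'   genome layout.
#' @slot pOscGenome,pOscRegulated,nRegulated oscillatory fractions and
#'   regulated-set size.
#' @slot regulatorPhaseDeg,regulatedPhaseOffsetDeg,phaseConcentration
#'   regulated-gene phase distribution (von Mises mean and kappa).
#' @slot bindingPhaseLagDeg lag of peak binding activity behind the
#'   regulator's mRNA peak, in degrees (default 17, about 25 min of a 9 h
#'   stage): protein accumulation and activity follow transcription, so
#'   binding density is maximal for genes peaking shortly after the
#'   regulator transcript.
#' @slot amplitudeLogMean,amplitudeLogSd lognormal amplitude parameters.
#' @slot peakRateAtZero,peakRateFloor,peakRateDecay,peakWidthBp,
#'   tesPeakFraction binding model.
#' @slot replicateJitterSd,replicateDropout replicate-2 perturbation.
#' @slot signalNoiseSd signal-track noise.
#'
#' @examples
#' SimConfig(seed = 1)
#' @name SimConfig-class
#' @rdname SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        seed = "numeric", nChroms = "numeric", chromLengthBp = "numeric",
        nGenes = "numeric", geneLengthMinBp = "numeric",
        geneLengthMaxBp = "numeric", pOscGenome = "numeric",
        pOscRegulated = "numeric", nRegulated = "numeric",
        regulatorPhaseDeg = "numeric", regulatedPhaseOffsetDeg = "numeric",
        bindingPhaseLagDeg = "numeric",
        phaseConcentration = "numeric", amplitudeLogMean = "numeric",
        amplitudeLogSd = "numeric", peakRateAtZero = "numeric",
        peakRateFloor = "numeric", peakRateDecay = "numeric",
        peakWidthBp = "numeric", tesPeakFraction = "numeric",
        replicateJitterSd = "numeric", replicateDropout = "numeric",
        signalNoiseSd = "numeric"
    ),
    prototype(
        seed = 1, nChroms = 3, chromLengthBp = 2e6, nGenes = 900,
        geneLengthMinBp = 400, geneLengthMaxBp = 2000, pOscGenome = 0.15,
        pOscRegulated = 0.89, nRegulated = 265, regulatorPhaseDeg = 178.11,
        regulatedPhaseOffsetDeg = 0, bindingPhaseLagDeg = 17,
        phaseConcentration = 1.5,
        amplitudeLogMean = 0.5, amplitudeLogSd = 0.35, peakRateAtZero = 4,
        peakRateFloor = 0.3, peakRateDecay = 0.05, peakWidthBp = 300,
        tesPeakFraction = 0.2, replicateJitterSd = 25,
        replicateDropout = 0.05, signalNoiseSd = 0.1
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    probs <- c(object@pOscGenome, object@pOscRegulated,
               object@replicateDropout, object@tesPeakFraction)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    rates <- c(object@peakRateAtZero, object@peakRateFloor,
               object@peakRateDecay, object@phaseConcentration,
               object@replicateJitterSd, object@signalNoiseSd)
    if (any(rates < 0))
        msg <- c(msg, "rates/spreads must be >= 0")
    if (object@nRegulated > object@nGenes)
        msg <- c(msg, "nRegulated must not exceed nGenes")
    if (object@geneLengthMinBp < 1 ||
        object@geneLengthMaxBp < object@geneLengthMinBp)
        msg <- c(msg, "need 1 <= geneLengthMinBp <= geneLengthMaxBp")
    if (abs(object@seed) >= 2^31 - 8)
        msg <- c(msg, "seed must be a 32-bit integer")
    if (length(msg)) msg else TRUE
})

#' @param seed master seed (mandatory to set for reproducibility).
#' @param ... any slot, by name, overriding its default.
#' @return `SimConfig()` returns a SimConfig.
#' @rdname SimConfig
#' @export
SimConfig <- function(seed = 1, ...) new("SimConfig", seed = seed, ...)

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: seed %d; %d genes on %d x %g bp chroms; p_osc %g (regulated %g, n=%d)\n",
        as.integer(object@seed), as.integer(object@nGenes),
        as.integer(object@nChroms), object@chromLengthBp, object@pOscGenome,
        object@pOscRegulated, as.integer(object@nRegulated)))
})

simConfigAsList <- function(config) {
    sl <- methods::slotNames("SimConfig")
    stats::setNames(lapply(sl, function(s) methods::slot(config, s)), sl)
}

# stage streams: genome=1, oscillation=2, peaks=3, replicate2=4, signal=5
withStream <- function(config, stage, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    set.seed(as.integer(config@seed) + stage)
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    expr
}

#' Circular distance between phases
#'
#' Shortest angular distance in degrees, in [0, 180].
#'
#' @param a,b phases in degrees.
#' @return numeric distances.
#' @export
circularDistance <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
}

# von Mises sampler (Best & Fisher rejection scheme); kappa ~ 0 falls
# back to the uniform circle
rvonmises <- function(n, muDeg, kappa) {
    if (kappa < 1e-8) return(stats::runif(n, 0, 360))
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    out <- numeric(0)
    while (length(out) < n) {
        m <- n - length(out)
        u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
        z <- cos(pi * u1)
        f <- (1 + r * z) / (r + z)
        cc <- kappa * (r - f)
        ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
        theta <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
        out <- c(out, theta)
    }
    (muDeg + out[seq_len(n)] * 180 / pi) %% 360
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes with uniform random gaps and strands on
#' `nChroms` chromosomes and assigns each gene an expression percentile
#' (a random permutation of evenly spaced ranks in [0, 100]).
#'
#' @param config a [SimConfig].
#' @return GRanges with `gene_id` and `expression_percentile` metadata and
#'   seqlengths set; identical config (seed included) gives identical
#'   output.
#' @export
simulateGenome <- function(config) {
    withStream(config, 1L, {
        nc <- as.integer(config@nChroms)
        chroms <- sprintf("chr%d", seq_len(nc))
        perChrom <- diff(round(seq(0, config@nGenes, length.out = nc + 1)))
        all <- list()
        gi <- 0L
        for (ci in seq_len(nc)) {
            n <- perChrom[ci]
            if (n == 0L) next
            len <- floor(stats::runif(n, config@geneLengthMinBp,
                                      config@geneLengthMaxBp + 1))
            free <- config@chromLengthBp - sum(len)
            if (free < 0)
                stop("cannot place ", n, " genes on a ",
                     config@chromLengthBp,
                     " bp chromosome; increase chromLengthBp")
            gaps <- diff(c(0, sort(stats::runif(n, 0, free))))
            starts <- floor(cumsum(gaps) + cumsum(c(0, len[-n]))) + 1
            all[[ci]] <- GRanges(
                factor(rep(chroms[ci], n), levels = chroms),
                IRanges(start = starts, width = len),
                strand = sample(c("+", "-"), n, replace = TRUE))
            gi <- gi + n
        }
        genes <- if (length(all)) do.call(c, all) else GRanges()
        GenomeInfoDb::seqlevels(genes) <- chroms
        if (length(genes)) {
            genes$gene_id <- sprintf("gene_%04d", seq_along(genes))
            ranks <- seq(0, 100, length.out = max(length(genes), 2))
            genes$expression_percentile <-
                sample(ranks[seq_along(genes)])
        } else {
            genes$gene_id <- character(0)
            genes$expression_percentile <- numeric(0)
        }
        seqlengths(genes) <- stats::setNames(
            rep(config@chromLengthBp, nc), chroms)
        genes
    })
}

#' Simulate oscillation annotations and a regulated gene set
#'
#' Draws a regulated subset of `nRegulated` genes; regulated genes are
#' oscillatory with probability `pOscRegulated`, background genes with
#' `pOscGenome`. Oscillatory regulated genes draw phases from a von Mises
#' distribution centered on `regulatorPhaseDeg + regulatedPhaseOffsetDeg`
#' with concentration `phaseConcentration`; background oscillatory phases
#' are uniform. Amplitudes are lognormal.
#'
#' @param config a [SimConfig].
#' @param genes GRanges from [simulateGenome()].
#' @return list with `osc` (an [OscillationSet] over all genes) and
#'   `regulated` (character vector of regulated gene ids).
#' @export
simulateOscillation <- function(config, genes) {
    if (config@nRegulated > length(genes))
        stop("nRegulated exceeds the number of genes")
    withStream(config, 2L, {
        ids <- genes$gene_id
        n <- length(ids)
        regulated <- sort(sample(ids, as.integer(config@nRegulated)))
        isReg <- ids %in% regulated
        pOsc <- ifelse(isReg, config@pOscRegulated, config@pOscGenome)
        osc <- stats::runif(n) < pOsc
        phase <- rep(NA_real_, n)
        regOsc <- isReg & osc
        bgOsc <- !isReg & osc
        phase[regOsc] <- rvonmises(
            sum(regOsc),
            (config@regulatorPhaseDeg +
                 config@regulatedPhaseOffsetDeg) %% 360,
            config@phaseConcentration)
        phase[bgOsc] <- stats::runif(sum(bgOsc), 0, 360)
        amp <- rep(NA_real_, n)
        amp[osc] <- stats::rlnorm(sum(osc), config@amplitudeLogMean,
                                  config@amplitudeLogSd)
        list(osc = OscillationSet(ids, phase, amp, osc),
             regulated = regulated)
    })
}

# strand-aware TSS/TES positions
tssOf <- function(genes) ifelse(as.character(strand(genes)) == "-",
                                end(genes), start(genes))
tesOf <- function(genes) ifelse(as.character(strand(genes)) == "-",
                                start(genes), end(genes))

#' Simulate replicate ChIP peak calls and a signal track
#'
#' Per-gene Poisson peak counts at a rate decaying exponentially with the
#' circular distance between the gene's peak phase and the regulator
#' reference phase (`peakRateFloor` for non-oscillatory genes). Peaks of
#' width ~ `peakWidthBp` center near the TSS (a `tesPeakFraction` near
#' the TES, mirroring the downstream enrichment seen in real binding
#' data). Replicate 2 is replicate 1 with Gaussian positional jitter and
#' independent dropout. The signal track is the sum of per-peak
#' triangular bumps plus nonnegative noise, on a 25 bp grid.
#'
#' @param config a [SimConfig].
#' @param genes GRanges from [simulateGenome()].
#' @param oscillation list from [simulateOscillation()].
#' @param signal build the signal track (set `FALSE` to skip the most
#'   expensive part when only peaks are needed).
#' @return list with GRanges `rep1` and `rep2` (named peaks with `score`)
#'   and `track` (a [SignalTrack], or `NULL` when `signal = FALSE`).
#' @export
simulateBinding <- function(config, genes, oscillation, signal = TRUE) {
    osc <- oscillation$osc
    stopifnot(identical(geneIds(osc), genes$gene_id))
    peaks <- withStream(config, 3L, {
        bindingPeakPhase <- (config@regulatorPhaseDeg +
                                 config@bindingPhaseLagDeg) %% 360
        dist <- circularDistance(phases(osc), bindingPeakPhase)
        rate <- ifelse(isOscillatory(osc),
                       config@peakRateAtZero *
                           exp(-config@peakRateDecay * dist),
                       config@peakRateFloor)
        nPeaks <- stats::rpois(length(genes), rate)
        gi <- rep(seq_along(genes), nPeaks)
        total <- sum(nPeaks)
        if (total == 0L) {
            GRanges()
        } else {
            atTes <- stats::runif(total) < config@tesPeakFraction
            anchor <- ifelse(atTes, tesOf(genes)[gi], tssOf(genes)[gi])
            center <- anchor + round(stats::rnorm(total, 0, 250))
            halfw <- round(config@peakWidthBp *
                               stats::runif(total, 0.8, 1.2) / 2)
            chrom <- as.character(seqnames(genes))[gi]
            chromLen <- seqlengths(genes)[chrom]
            s <- pmax(1, center - halfw)
            e <- pmin(chromLen, center + halfw)
            keep <- e > s
            p <- GRanges(chrom[keep], IRanges(s[keep], e[keep]))
            p$score <- round(stats::rgamma(sum(keep), shape = 2,
                                           scale = 5), 3)
            p <- sort(p)
            names(p) <- sprintf("peak_%05d", seq_along(p))
            p
        }
    })
    rep2 <- withStream(config, 4L, {
        if (length(peaks) == 0L) peaks else {
            shift <- round(stats::rnorm(length(peaks), 0,
                                        config@replicateJitterSd))
            keep <- stats::runif(length(peaks)) >= config@replicateDropout
            chromLen <- seqlengths(genes)[as.character(seqnames(peaks))]
            s <- pmax(1, start(peaks) + shift)
            e <- pmin(chromLen, end(peaks) + shift)
            ok <- keep & e > s
            p2 <- GRanges(as.character(seqnames(peaks))[ok],
                          IRanges(s[ok], e[ok]))
            p2$score <- peaks$score[ok]
            p2 <- sort(p2)
            names(p2) <- sprintf("peak_%05d", seq_along(p2))
            p2
        }
    })
    track <- NULL
    if (signal) track <- withStream(config, 5L, {
        step <- 25L
        covList <- lapply(seqlevels(genes), function(chrom) {
            len <- seqlengths(genes)[[chrom]]
            nwin <- as.integer(ceiling(len / step))
            centers <- (seq_len(nwin) - 0.5) * step
            v <- numeric(nwin)
            pk <- peaks[as.character(seqnames(peaks)) == chrom]
            for (i in seq_along(pk)) {
                c0 <- (start(pk)[i] + end(pk)[i]) / 2
                hw <- (end(pk)[i] - start(pk)[i]) / 2
                h <- pk$score[i] / 10
                lo <- max(1L, floor((c0 - hw) / step))
                hi <- min(nwin, ceiling((c0 + hw) / step))
                sl <- lo:hi
                v[sl] <- v[sl] + pmax(0, h * (1 - abs(centers[sl] - c0) / hw))
            }
            v <- pmax(0, v + stats::rnorm(nwin, 0, config@signalNoiseSd))
            v <- round(v, 4)
            widths <- rep(step, nwin)
            widths[nwin] <- len - step * (nwin - 1L)
            Rle(values = v, lengths = widths)
        })
        SignalTrack(methods::as(stats::setNames(covList, seqlevels(genes)),
                                "RleList"))
    })
    list(rep1 = peaks, rep2 = rep2, track = track)
}

#' Simulate a complete input bundle on disk
#'
#' Runs [simulateGenome()], [simulateOscillation()] and
#' [simulateBinding()] and writes every file the pipeline reads:
#' `genes.bed`, `expression.tsv`, `oscillation.tsv`, `regulated.tsv`,
#' `peaks_rep1.bed`, `peaks_rep2.bed`, `signal.wig` and a
#' `simconfig.json` sidecar with the full configuration. Output bytes are
#' a deterministic function of the config.
#'
#' @param config a [SimConfig].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
simulateAll <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    genes <- simulateGenome(config)
    oscillation <- simulateOscillation(config, genes)
    binding <- simulateBinding(config, genes, oscillation)
    paths <- c(
        genes = file.path(dir, "genes.bed"),
        expression = file.path(dir, "expression.tsv"),
        oscillation = file.path(dir, "oscillation.tsv"),
        regulated = file.path(dir, "regulated.tsv"),
        rep1 = file.path(dir, "peaks_rep1.bed"),
        rep2 = file.path(dir, "peaks_rep2.bed"),
        signal = file.path(dir, "signal.wig"),
        config = file.path(dir, "simconfig.json"))
    gb <- genes
    gb$name <- gb$gene_id
    gb$score <- 0
    gb$gene_id <- NULL
    gb$expression_percentile <- NULL
    writeBed(gb, paths[["genes"]])
    utils::write.table(
        data.frame(gene_id = genes$gene_id,
                   expression_percentile =
                       sprintf("%.6g", genes$expression_percentile)),
        paths[["expression"]], sep = "\t", quote = FALSE, row.names = FALSE)
    writeOscillations(oscillation$osc, paths[["oscillation"]])
    writeLines(c("gene_id", oscillation$regulated), paths[["regulated"]])
    writePeaks <- function(p, path) {
        if (length(p)) p$name <- names(p)
        writeBed(p, path)
    }
    writePeaks(binding$rep1, paths[["rep1"]])
    writePeaks(binding$rep2, paths[["rep2"]])
    writeWiggle(binding$track, paths[["signal"]])
    jsonlite::write_json(simConfigAsList(config), paths[["config"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(paths)
}
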