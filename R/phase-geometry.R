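# Circular-phase computation on the molt-anchored developmental clock.
# Phases are degrees of one larval-stage expression cycle, in [0, 360).

checkPhase <- function(phaseDeg) {
    bad <- !is.na(phaseDeg) & (phaseDeg < 0 | phaseDeg >= 360)
    if (any(bad))
        stop("phase must lie in [0, 360); got ",
             paste(utils::head(phaseDeg[bad], 3), collapse = ", "))
    invisible(phaseDeg)
}

#' Polar coordinates of oscillation records
#'
#' Converts peak phase and amplitude to cartesian coordinates,
#' x = amplitude * cos(phase) and y = amplitude * sin(phase), with phase in
#' degrees - the coordinates behind the radar/scatter representation of an
#' oscillatory transcriptome.
#'
#' @param phaseDeg phase(s) in [0, 360), or an [OscillationSet].
#' @param amplitude amplitude(s); ignored when `phaseDeg` is an
#'   OscillationSet.
#' @return data.frame with columns `x` and `y` (and `gene_id` for an
#'   OscillationSet). The vector norm of each row equals the amplitude.
#'   Non-oscillatory records (undefined phase) raise an error.
#' @examples
#' polarToCartesian(90, 4)          # (0, 4)
#' polarToCartesian(178.11, 2.11)   # (-2.1089, 0.0696)
#' @export
polarToCartesian <- function(phaseDeg, amplitude) {
    if (is(phaseDeg, "OscillationSet")) {
        osc <- phaseDeg
        if (!all(isOscillatory(osc)))
            stop("phase undefined for non-oscillatory gene(s): ",
                 paste(utils::head(geneIds(osc)[!isOscillatory(osc)], 5),
                       collapse = ", "))
        out <- polarToCartesian(phases(osc), amplitudes(osc))
        return(cbind(data.frame(gene_id = geneIds(osc),
                                stringsAsFactors = FALSE), out))
    }
    if (anyNA(phaseDeg) || anyNA(amplitude))
        stop("phase undefined (NA): record is not oscillatory")
    checkPhase(phaseDeg)
    rad <- phaseDeg * pi / 180
    data.frame(x = amplitude * cos(rad), y = amplitude * sin(rad))
}

#' Reference oscillation of the regulator
#'
#' The mRNA oscillation of the nuclear hormone receptor driving the
#' molting program: peak phase 178.11 degrees, amplitude 2.11 (from the
#' published oscillatory-transcriptome fit). Used as the reference phase
#' for binding-density decay and for the hour-2 consistency checks.
#'
#' @return list with elements `phaseDeg` and `amplitude`.
#' @export
regulatorReference <- function() list(phaseDeg = 178.11, amplitude = 2.11)

#' Adjusted larval-stage time
#'
#' Developmental hours since the start of the larval-stage clock, whose
#' origin is the end of ecdysis (135 degrees by default):
#' `((phaseDeg - ecdysisEndDeg) mod 360) / degPerHour`.
#'
#' @param phaseDeg phase(s) in [0, 360).
#' @param clock a [MoltClock].
#' @return hours in [0, stageHours).
#' @examples
#' adjustedHour(135)      # 0
#' adjustedHour(178.11)   # 1.078 -> hour bin 2
#' adjustedHour(95)       # 8
#' @export
adjustedHour <- function(phaseDeg, clock = MoltClock()) {
    checkPhase(phaseDeg)
    ((phaseDeg - clock@ecdysisEndDeg) %% 360) / degPerHour(clock)
}

#' @describeIn adjustedHour inverse mapping: the phase at a given adjusted
#'   hour (hours in [0, stageHours)).
#' @param hours adjusted larval-stage time in hours.
#' @export
phaseAtHour <- function(hours, clock = MoltClock()) {
    (clock@ecdysisEndDeg + hours * degPerHour(clock)) %% 360
}

#' Hour bin on the larval-stage clock
#'
#' Integer hour bin `floor(adjustedHour) + 1`, in `1:stageHours`. The
#' regulator reference phase (178.11 degrees) falls in bin 2: genes peaking
#' in the hour after the regulator's mRNA peak.
#'
#' @inheritParams adjustedHour
#' @return integer bins in `1:stageHours(clock)`.
#' @examples
#' hourBin(c(135, 178.11, 134.99))   # 1, 2, 9
#' @export
hourBin <- function(phaseDeg, clock = MoltClock()) {
    as.integer(floor(adjustedHour(phaseDeg, clock)) + 1)
}

#' Early/middle/late phase classes
#'
#' Tripartition of the cycle into three 120-degree (3-hour) classes
#' relative to the regulator's peak: early = [135, 255), middle =
#' [255, 360) plus [0, 15) (wrapping midnight), late = [15, 135).
#' Half-open bounds make the classes a partition of [0, 360); they
#' coincide with hour bins 1-3, 4-6 and 7-9.
#'
#' @param phaseDeg phase(s) in [0, 360); `NA` yields `NA`.
#' @return factor with levels early, middle, late.
#' @examples
#' classifyPhase(c(178.11, 300, 10, 15))   # early middle middle late
#' @export
classifyPhase <- function(phaseDeg) {
    checkPhase(phaseDeg)
    cls <- ifelse(is.na(phaseDeg), NA_character_,
           ifelse(phaseDeg >= 135 & phaseDeg < 255, "early",
           ifelse(phaseDeg >= 15 & phaseDeg < 135, "late", "middle")))
    factor(cls, levels = c("early", "middle", "late"))
}

#' Is a phase inside the molt?
#'
#' TRUE when the phase lies in the molt window, from the start of
#' lethargus (45 degrees) up to, but excluding, the end of ecdysis
#' (135 degrees).
#'
#' @inheritParams adjustedHour
#' @return logical vector.
#' @examples
#' inMolt(c(45, 90, 135))   # TRUE TRUE FALSE
#' @export
inMolt <- function(phaseDeg, clock = MoltClock()) {
    checkPhase(phaseDeg)
    phaseDeg >= clock@lethargusStartDeg & phaseDeg < clock@ecdysisEndDeg
}

#' Per-gene phase table
#'
#' The tidy per-gene table behind the polar/scatter phase figures:
#' cartesian coordinates, adjusted larval-stage hour, hour bin and phase
#' class for every gene. Non-oscillating genes are kept as an explicit
#' fourth class with `NA` coordinates and times, never dropped.
#'
#' @param osc an [OscillationSet].
#' @param clock a [MoltClock].
#' @return data.frame with columns gene_id, phase_deg, amplitude, x, y,
#'   adjusted_hour, hour_bin, phase_class (factor levels early, middle,
#'   late, non_oscillating), in_molt.
#' @export
phaseTable <- function(osc, clock = MoltClock()) {
    stopifnot(is(osc, "OscillationSet"))
    ph <- phases(osc)
    am <- amplitudes(osc)
    rad <- ph * pi / 180
    cls <- as.character(classifyPhase(ph))
    cls[!isOscillatory(osc)] <- "non_oscillating"
    data.frame(
        gene_id = geneIds(osc),
        phase_deg = ph,
        amplitude = am,
        x = am * cos(rad),
        y = am * sin(rad),
        adjusted_hour = ifelse(is.na(ph), NA_real_,
                               adjustedHour(ifelse(is.na(ph), 0, ph), clock)),
        hour_bin = ifelse(is.na(ph), NA_integer_,
                          hourBin(ifelse(is.na(ph), 0, ph), clock)),
        phase_class = factor(cls, levels = c("early", "middle", "late",
                                             "non_oscillating")),
        in_molt = ifelse(is.na(ph), NA,
                         inMolt(ifelse(is.na(ph), 0, ph), clock)),
        stringsAsFactors = FALSE)
}

#' Read and write oscillation annotation tables
#'
#' Tab-separated tables with header columns `gene_id`, `phase_deg`,
#' `amplitude`, `oscillatory`. Non-oscillatory rows may leave phase and
#' amplitude empty/NA.
#'
#' @param path TSV path.
#' @return `readOscillations` returns an [OscillationSet];
#'   `writeOscillations` returns `path` invisibly.
#' @export
readOscillations <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "phase_deg", "amplitude", "oscillatory")
    if (!all(need %in% names(tab)))
        stop("expected columns ", paste(need, collapse = ", "), " in ", path)
    OscillationSet(tab$gene_id, tab$phase_deg, tab$amplitude,
                   as.logical(tab$oscillatory))
}

#' @param osc an [OscillationSet] to write.
#' @rdname readOscillations
#' @export
writeOscillations <- function(osc, path) {
    tab <- as.data.frame(osc)
    tab$phase_deg <- ifelse(is.na(tab$phase_deg), "",
                            sprintf("%.6g", tab$phase_deg))
    tab$amplitude <- ifelse(is.na(tab$amplitude), "",
                            sprintf("%.6g", tab$amplitude))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a gene-set file
#'
#' One gene id per line, or a TSV whose first column (header `gene_id`)
#' holds the ids - the format of the regulated-gene list.
#'
#' @param path input path.
#' @return character vector of gene ids.
#' @export
readGeneSet <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !grepl("^#", lines)]
    ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
    if (length(ids) && ids[1L] == "gene_id") ids <- ids[-1L]
    unique(ids)
}
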