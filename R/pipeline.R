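# End-to-end orchestration: from annotation, oscillation, peak and signal
# files to the four analysis tables plus a reproducibility manifest.

pipeLog <- function(quiet, ...) if (!quiet) message(...)

fmtNum <- function(x) {
    if (is.numeric(x) && !is.integer(x))
        ifelse(is.na(x), "NA", sprintf("%.6g", x))
    else x
}

writeTsv <- function(df, path) {
    df[] <- lapply(df, fmtNum)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the full phase/binding analysis pipeline
#'
#' Reads gene annotations, oscillation annotations, the regulated gene
#' set, two replicates of peak calls and a signal track; then computes
#' (1) the per-gene phase table (polar coordinates, adjusted hours, hour
#' bins, phase classes), (2) replicate-validated peak assignments and
#' mean peak counts per hour bin and feature for the regulated genes,
#' (3) metagene signal profiles per phase class, and (4) the oscillation
#' enrichment test of the regulated set. Results are written as TSV plus
#' a JSON manifest (configuration, package version, input checksums),
#' atomically: on any stage failure partial outputs are removed.
#'
#' @param genesBed gene annotation (BED with ids in column 4, or GFF3).
#' @param oscillationTsv oscillation annotation TSV
#'   (see [readOscillations()]).
#' @param regulatedTsv regulated gene-set file (see [readGeneSet()]).
#' @param peaksRep1Bed,peaksRep2Bed replicate peak-call BED files.
#' @param signalWig wiggle signal track.
#' @param outDir output directory, created if needed.
#' @param expressionTsv optional gene expression-percentile TSV enabling
#'   the no_expression metagene class.
#' @param clock a [MoltClock].
#' @param assignConfig an [AssignmentConfig].
#' @param metaConfig a [MetageneConfig].
#' @param nullProportion genome-wide oscillatory null proportion.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with elements `phaseTable`, `assignments`,
#'   `peakCounts`, `metagene`, `enrichment` and `files` (paths written:
#'   phase_coordinates.tsv, peak_assignments.tsv,
#'   peak_counts_by_hour.tsv, metagene_profiles.tsv, enrichment.tsv,
#'   run_manifest.json).
#' @export
runPipeline <- function(genesBed, oscillationTsv, regulatedTsv,
                        peaksRep1Bed, peaksRep2Bed, signalWig, outDir,
                        expressionTsv = NULL, clock = MoltClock(),
                        assignConfig = AssignmentConfig(),
                        metaConfig = MetageneConfig(),
                        nullProportion = 0.20, quiet = FALSE) {
    inputs <- c(genes = genesBed, oscillation = oscillationTsv,
                regulated = regulatedTsv, peaks_rep1 = peaksRep1Bed,
                peaks_rep2 = peaksRep2Bed, signal = signalWig)
    if (!is.null(expressionTsv)) inputs["expression"] <- expressionTsv
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        stop("missing input file(s): ", paste(missing, collapse = ", "))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    outFiles <- file.path(outDir, c(
        phase = "phase_coordinates.tsv",
        assignments = "peak_assignments.tsv",
        counts = "peak_counts_by_hour.tsv",
        metagene = "metagene_profiles.tsv",
        enrichment = "enrichment.tsv",
        manifest = "run_manifest.json"))
    names(outFiles) <- c("phase", "assignments", "counts", "metagene",
                         "enrichment", "manifest")
    stage <- "read inputs"
    result <- tryCatch({
        pipeLog(quiet, "[phasePeak] reading inputs")
        genes <- readGenes(genesBed)
        if (!is.null(expressionTsv))
            genes <- readExpressionPercentiles(genes, expressionTsv)
        osc <- readOscillations(oscillationTsv)
        regulated <- readGeneSet(regulatedTsv)
        rep1 <- readBed(peaksRep1Bed)
        rep2 <- readBed(peaksRep2Bed)
        if (!is.null(rep1$name) && !anyDuplicated(rep1$name))
            names(rep1) <- rep1$name
        track <- readWiggle(signalWig)
        chromLengths <- trackLengths(track)
        sl <- seqlengths(genes)
        known <- !is.na(sl)
        chromLengths[names(sl)[known]] <- sl[known]

        stage <- "phase table"
        pipeLog(quiet, "[phasePeak] phase geometry")
        ptab <- phaseTable(osc, clock)

        stage <- "peak assignment"
        pipeLog(quiet, "[phasePeak] replicate consensus and assignment")
        validated <- replicateConsensus(rep1, rep2, assignConfig)
        assignments <- assignPeaks(validated, genes, assignConfig,
                                   chromLengths)
        regPresent <- intersect(regulated, geneIds(osc))
        regAssign <- assignments[assignments$gene_id %in% regPresent, ,
                                 drop = FALSE]
        counts <- peaksPerGeneByHour(regAssign, osc[regPresent], clock)

        stage <- "metagene profiles"
        pipeLog(quiet, "[phasePeak] metagene profiles")
        classes <- c("early", "middle", "late", "all")
        if (!is.null(genes$expression_percentile))
            classes <- c(classes, "no_expression")
        regGenes <- genes[genes$gene_id %in% regPresent]
        profGenes <- genes
        # early/middle/late are classes of the regulated oscillating set;
        # restrict the class membership accordingly by masking phases
        oscReg <- osc[regPresent]
        profiles <- c(
            profileByClass(track, regGenes, oscReg, metaConfig,
                           classes = intersect(classes,
                                               c("early", "middle", "late")),
                           chromLengths = chromLengths),
            profileByClass(track, profGenes, osc, metaConfig,
                           classes = intersect(classes,
                                               c("all", "no_expression")),
                           chromLengths = chromLengths))
        mtab <- metageneTable(profiles)

        stage <- "enrichment test"
        pipeLog(quiet, "[phasePeak] oscillation enrichment")
        enr <- enrichmentTest(regulated, osc, nullProportion)

        stage <- "write outputs"
        pipeLog(quiet, "[phasePeak] writing ", outDir)
        writeTsv(ptab, outFiles[["phase"]])
        writeTsv(assignments, outFiles[["assignments"]])
        writeTsv(counts, outFiles[["counts"]])
        writeTsv(mtab, outFiles[["metagene"]])
        writeTsv(as.data.frame(enr), outFiles[["enrichment"]])
        manifest <- list(
            package = "phasePeak",
            version = as.character(utils::packageVersion("phasePeak")),
            inputs = as.list(inputs),
            input_md5 = as.list(stats::setNames(
                unname(tools::md5sum(inputs)), names(inputs))),
            clock = list(stageHours = stageHours(clock),
                         lethargusStartDeg = clock@lethargusStartDeg,
                         ecdysisEndDeg = clock@ecdysisEndDeg),
            assignment = list(
                minOverlapBp = assignConfig@minOverlapBp,
                minConsensusOverlapBp = assignConfig@minConsensusOverlapBp,
                consensusCoordinates = assignConfig@consensusCoordinates),
            metagene = list(bodyTargetBp = metaConfig@bodyTargetBp,
                            flankBp = metaConfig@flankBp,
                            windowBp = metaConfig@windowBp,
                            ciLevel = metaConfig@ciLevel),
            nullProportion = nullProportion)
        jsonlite::write_json(manifest, outFiles[["manifest"]],
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        list(phaseTable = ptab, assignments = assignments,
             peakCounts = counts, metagene = profiles, enrichment = enr,
             files = outFiles)
    }, error = function(e) {
        unlink(outFiles)
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    })
    invisible(result)
}
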