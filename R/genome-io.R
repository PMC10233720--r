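#' @importFrom GenomicRanges GRanges strand strand<- mcols mcols<- seqnames
#'   start end width findOverlaps pintersect coverage
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Read a BED file of genomic intervals
#'
#' Reads BED3/BED6 (tab-separated, 0-based half-open) into a
#' [GenomicRanges::GRanges] (1-based closed, the Bioconductor convention;
#' a BED record `chrI 0 100` becomes `chrI:1-100`). Optional columns 4-6
#' become `name` and `score` metadata and the strand; strand is `*` when
#' absent or `.`.
#'
#' @param path path to a BED file. Lines starting with `track`, `browser`
#'   or `#` are skipped.
#' @return a GRanges with metadata columns `name` and `score` when present.
#' @details Malformed records (fewer than 3 columns, non-integer
#'   coordinates, empty or negative-length intervals) raise an error naming
#'   the offending line number.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chrI\t0\t100\tg1\t5\t+", bed)
#' readBed(bed)
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    lineNo <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) return(GRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols < 3L))
        stop("BED parse error at line ", lineNo[which(ncols < 3L)[1L]],
             ": fewer than 3 tab-separated columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    startTxt <- vapply(fields, `[[`, "", 2L)
    endTxt <- vapply(fields, `[[`, "", 3L)
    start0 <- suppressWarnings(as.numeric(startTxt))
    end0 <- suppressWarnings(as.numeric(endTxt))
    bad <- is.na(start0) | is.na(end0) | start0 != floor(start0) |
        end0 != floor(end0)
    if (any(bad))
        stop("BED parse error at line ", lineNo[which(bad)[1L]],
             ": non-integer coordinates")
    bad <- start0 < 0 | start0 >= end0
    if (any(bad))
        stop("BED parse error at line ", lineNo[which(bad)[1L]],
             ": need 0 <= start < end")
    strandTxt <- rep("*", length(lines))
    has6 <- ncols >= 6L
    strandTxt[has6] <- vapply(fields[has6], `[[`, "", 6L)
    strandTxt[!strandTxt %in% c("+", "-")] <- "*"
    gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end0),
                  strand = strandTxt)
    if (any(ncols >= 4L)) {
        nm <- rep(NA_character_, length(lines))
        nm[ncols >= 4L] <- vapply(fields[ncols >= 4L], `[[`, "", 4L)
        gr$name <- nm
    }
    if (any(ncols >= 5L)) {
        sc <- rep(NA_real_, length(lines))
        sc[ncols >= 5L] <-
            suppressWarnings(as.numeric(vapply(fields[ncols >= 5L],
                                               `[[`, "", 5L)))
        gr$score <- sc
    }
    gr
}

#' Write intervals to a BED file
#'
#' Emits BED6 when the GRanges carries strand or name/score metadata,
#' BED3 otherwise. Output is byte-stable for identical input.
#'
#' @param gr a GRanges; `name` and `score` metadata columns are used when
#'   present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
    chrom <- as.character(seqnames(gr))
    s0 <- start(gr) - 1L
    e0 <- end(gr)
    std <- as.character(strand(gr))
    plain <- all(std == "*") && is.null(gr$name) && is.null(gr$score)
    if (plain) {
        out <- sprintf("%s\t%d\t%d", chrom, s0, e0)
    } else {
        nm <- if (is.null(gr$name)) rep(".", length(gr)) else
            ifelse(is.na(gr$name), ".", gr$name)
        sc <- if (is.null(gr$score)) rep("0", length(gr)) else
            ifelse(is.na(gr$score), "0", sprintf("%.6g", gr$score))
        std[std == "*"] <- "."
        out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", chrom, s0, e0, nm, sc, std)
    }
    writeLines(out, path)
    invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' Convenience reader for gene annotations: BED input must carry gene ids
#' in column 4; GFF3 input (1-based inclusive, converted by rtracklayer)
#' uses `gene`-type records and their `ID`/`gene_id`/`Name` attribute.
#'
#' @param path annotation file; format inferred from the extension
#'   (`.bed` vs `.gff`/`.gff3`) unless `format` is given.
#' @param format `"bed"` or `"gff3"`.
#' @return GRanges with a `gene_id` metadata column (and
#'   `expression_percentile` if a BED score column is present - see
#'   [readExpressionPercentiles()] for the usual source).
#' @export
readGenes <- function(path, format = c("auto", "bed", "gff3")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE))
            "gff3" else "bed"
    if (format == "bed") {
        gr <- readBed(path)
        if (is.null(gr$name) || anyNA(gr$name))
            stop("gene BED needs ids in column 4")
        gr$gene_id <- gr$name
        gr$name <- NULL
        gr$score <- NULL
    } else {
        gr <- rtracklayer::import(path, format = "gff3")
        if ("type" %in% names(mcols(gr)) && any(gr$type == "gene"))
            gr <- gr[gr$type == "gene"]
        id <- gr$ID
        if (is.null(id)) id <- gr$gene_id
        if (is.null(id)) id <- gr$Name
        if (is.null(id)) stop("GFF3 gene records need ID/gene_id/Name")
        mcols(gr) <- NULL
        gr$gene_id <- as.character(id)
    }
    if (anyDuplicated(gr$gene_id))
        stop("duplicated gene ids in ", path)
    gr
}

#' Attach expression percentiles to gene models
#'
#' @param genes GRanges with `gene_id`.
#' @param path two-column TSV with header `gene_id  expression_percentile`
#'   (ranks in [0, 100]; the bottom 20 percent form the usual
#'   "no expression" reference set).
#' @return `genes` with an `expression_percentile` metadata column.
#' @export
readExpressionPercentiles <- function(genes, path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "expression_percentile") %in% names(tab)))
        stop("expected columns gene_id, expression_percentile in ", path)
    idx <- match(genes$gene_id, tab$gene_id)
    if (anyNA(idx))
        stop("genes missing from percentile table: ",
             paste(utils::head(genes$gene_id[is.na(idx)], 5), collapse = ", "))
    p <- tab$expression_percentile[idx]
    if (any(p < 0 | p > 100)) stop("percentiles must lie in [0, 100]")
    genes$expression_percentile <- p
    genes
}

# light pre-validation of wiggle headers; parsing itself is rtracklayer's
validateWiggleHeaders <- function(path) {
    lines <- readLines(path)
    heads <- grep("^[A-Za-z]", lines, value = TRUE)
    heads <- heads[!grepl("^(track|browser)", heads)]
    if (length(heads) == 0L)
        stop("wiggle parse error: no fixedStep/variableStep block in ", path)
    ok <- grepl("^(fixedStep|variableStep)\\b", heads)
    if (!all(ok))
        stop("wiggle parse error: unknown block header '",
             sub("\\s.*$", "", heads[!ok][1L]), "'")
    spans <- regmatches(heads, regexpr("span=-?[0-9]+", heads))
    if (length(spans)) {
        span <- as.integer(sub("span=", "", spans))
        if (any(span <= 0L))
            stop("wiggle parse error: span must be positive")
    }
    invisible(TRUE)
}

#' Read a wiggle signal track
#'
#' Parses fixedStep/variableStep wiggle (1-based; `span` honored) into a
#' [SignalTrack]. Uncovered positions have value 0.
#'
#' @param path path to a `.wig` file.
#' @return a [SignalTrack].
#' @examples
#' wig <- tempfile(fileext = ".wig")
#' writeLines(c("fixedStep chrom=chrI start=1 step=25 span=25", "1", "2"), wig)
#' trackValues(readWiggle(wig), "chrI", 1, 30)
#' @export
readWiggle <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    validateWiggleHeaders(path)
    gr <- rtracklayer::import(path, format = "wig")
    SignalTrack(gr)
}

#' Write a signal track as fixedStep wiggle
#'
#' Emits one fixedStep block per chromosome at a fixed step equal to the
#' span, covering position 1 to the end of the stored signal. Values are
#' exact for tracks constant within each step window (e.g. tracks built on
#' a matching grid); otherwise each line holds the window mean.
#'
#' @param track a [SignalTrack].
#' @param path output path.
#' @param stepBp window/step size in bp (default 25).
#' @return `path`, invisibly.
#' @export
writeWiggle <- function(track, path, stepBp = 25) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (chrom in names(track@cov)) {
        r <- track@cov[[chrom]]
        len <- length(r)
        if (len == 0L) next
        nwin <- ceiling(len / stepBp)
        # pad to a whole number of windows with zeros
        v <- c(as.numeric(r), numeric(nwin * stepBp - len))
        m <- matrix(v, nrow = stepBp)
        vals <- colMeans(m)
        writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                           chrom, stepBp, stepBp), con)
        writeLines(sprintf("%.6g", vals), con)
    }
    invisible(path)
}

#' Query signal values at single-base resolution
#'
#' @param track a [SignalTrack].
#' @param chrom chromosome name; if absent from the track, zeros are
#'   returned with a warning.
#' @param start,end 1-based inclusive range; positions beyond the stored
#'   signal return 0.
#' @return numeric vector of length `end - start + 1`.
#' @export
trackValues <- function(track, chrom, start, end) {
    stopifnot(start >= 1, end >= start)
    n <- end - start + 1
    if (!chrom %in% names(track@cov)) {
        warning("chromosome ", chrom, " absent from signal track; using 0")
        return(numeric(n))
    }
    r <- track@cov[[chrom]]
    len <- length(r)
    if (start > len) return(numeric(n))
    inEnd <- min(end, len)
    vals <- as.numeric(S4Vectors::window(r, start, inEnd))
    c(vals, numeric(end - inEnd))
}

#' Overlap length between two intervals
#'
#' Number of bases shared by two genomic intervals; 0 when they lie on
#' different chromosomes. Strand is ignored (overlap is strand-blind
#' throughout; strand only orients upstream/downstream).
#'
#' @param a,b GRanges of equal length (or length 1, recycled); overlap is
#'   computed pairwise.
#' @return integer vector of shared base counts.
#' @examples
#' a <- GenomicRanges::GRanges("chrI:201-400")
#' b <- GenomicRanges::GRanges("chrI:101-250")
#' overlapLength(a, b)   # 50
#' @export
overlapLength <- function(a, b) {
    if (length(a) != length(b)) {
        if (length(a) == 1L) a <- rep(a, length(b))
        else if (length(b) == 1L) b <- rep(b, length(a))
        else stop("a and b must have equal length (or length 1)")
    }
    same <- as.character(seqnames(a)) == as.character(seqnames(b))
    ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
    as.integer(ifelse(same, pmax(0L, ov), 0L))
}

flankLabels <- c("up_3_5k", "up_1_3k", "up_0_1k", "body",
                 "down_0_1k", "down_1_3k", "down_3_5k")

#' Flanking feature bins around gene bodies
#'
#' For each gene, the seven assignment features: the gene body plus 0-1 kb,
#' 1-3 kb and 3-5 kb bins up- and downstream. "Upstream" is strand-aware
#' (for minus-strand genes it lies at higher coordinates). Bins are
#' truncated at the chromosome boundaries and omitted entirely when
#' truncated to nothing. Neighboring genes' bins may overlap; no masking is
#' applied.
#'
#' @param genes GRanges with a `gene_id` metadata column.
#' @param chromLengths named vector of chromosome lengths; defaults to
#'   `seqlengths(genes)`. Chromosomes without a known length are truncated
#'   only at position 1. An error is raised if a gene body extends beyond
#'   its chromosome.
#' @return GRanges with metadata columns `gene_id` and `feature` (factor
#'   with levels up_3_5k, up_1_3k, up_0_1k, body, down_0_1k, down_1_3k,
#'   down_3_5k).
#' @examples
#' g <- GenomicRanges::GRanges("chrI:5001-7000:+", gene_id = "g1")
#' flankingRegions(g, c(chrI = 20000))
#' @export
flankingRegions <- function(genes, chromLengths = NULL) {
    if (is.null(genes$gene_id)) stop("genes need a gene_id metadata column")
    if (is.null(chromLengths)) chromLengths <- seqlengths(genes)
    chrom <- as.character(seqnames(genes))
    lenOf <- chromLengths[chrom]
    lenOf[is.na(lenOf)] <- Inf
    if (any(start(genes) < 1) || any(end(genes) > lenOf))
        stop("gene body outside chromosome bounds: ",
             paste(utils::head(
                 genes$gene_id[start(genes) < 1 | end(genes) > lenOf], 5),
                 collapse = ", "))
    minus <- as.character(strand(genes)) == "-"
    s <- start(genes); e <- end(genes)
    # offsets of (outer, inner) edges of each flank bin from the gene edge
    bins <- list(up_3_5k = c(5000, 3001), up_1_3k = c(3000, 1001),
                 up_0_1k = c(1000, 1))
    pieces <- list()
    for (lab in names(bins)) {
        off <- bins[[lab]]
        dlab <- sub("^up", "down", lab)
        # upstream of + genes / downstream of - genes: left of the start
        ls <- s - off[1]; le <- s - off[2]
        # downstream of + genes / upstream of - genes: right of the end
        rs <- e + off[2]; re <- e + off[1]
        pieces[[paste0(lab, ".L")]] <- data.frame(
            chrom = chrom, start = ls, end = le,
            gene_id = genes$gene_id, feature = ifelse(minus, dlab, lab),
            chromLen = as.numeric(lenOf), stringsAsFactors = FALSE)
        pieces[[paste0(lab, ".R")]] <- data.frame(
            chrom = chrom, start = rs, end = re,
            gene_id = genes$gene_id, feature = ifelse(minus, lab, dlab),
            chromLen = as.numeric(lenOf), stringsAsFactors = FALSE)
    }
    pieces$body <- data.frame(
        chrom = chrom, start = s, end = e, gene_id = genes$gene_id,
        feature = "body", chromLen = as.numeric(lenOf),
        stringsAsFactors = FALSE)
    df <- do.call(rbind, pieces)
    df$start <- pmax(df$start, 1)
    df$end <- pmin(df$end, df$chromLen)
    df <- df[df$start <= df$end, , drop = FALSE]
    out <- GRanges(df$chrom, IRanges(df$start, df$end))
    out$gene_id <- df$gene_id
    out$feature <- factor(df$feature, levels = flankLabels)
    ord <- order(match(out$gene_id, genes$gene_id), out$feature)
    out[ord]
}
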