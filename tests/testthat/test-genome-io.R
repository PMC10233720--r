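test_that("BED records convert to 1-based closed coordinates", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chrI\t0\t100",
                 "chrI\t200\t400\tpkA\t7.5\t-",
                 "chrII\t10\t12\tpkB\t1\t."), bed)
    gr <- readBed(bed)
    expect_equal(start(gr), c(1L, 201L, 11L))
    expect_equal(end(gr), c(100L, 400L, 12L))
    expect_equal(as.character(strand(gr)), c("*", "-", "*"))
    expect_equal(gr$name, c(NA, "pkA", "pkB"))
    expect_equal(gr$score, c(NA, 7.5, 1))
})

test_that("malformed BED lines raise errors naming the line", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chrI\t0\t100", "chrI\t100\t100"), bed)
    expect_error(readBed(bed), "line 2")
    writeLines(c("track name=x", "chrI\t1.5\t90"), bed)
    expect_error(readBed(bed), "line 2.*non-integer")
    writeLines("chrI\t100", bed)
    expect_error(readBed(bed), "3 tab-separated")
})

test_that("BED round-trips through write and read", {
    gr <- gr1("chrI", c(1, 500), c(100, 900), c("+", "-"))
    gr$name <- c("a", "b")
    gr$score <- c(1.25, 0)
    bed <- withr::local_tempfile(fileext = ".bed")
    writeBed(gr, bed)
    back <- readBed(bed)
    expect_equal(start(back), start(gr))
    expect_equal(end(back), end(gr))
    expect_equal(as.character(strand(back)), as.character(strand(gr)))
    expect_equal(back$name, gr$name)
    expect_equal(back$score, gr$score)
})

test_that("fixedStep and variableStep wiggle blocks are honored", {
    wig <- withr::local_tempfile(fileext = ".wig")
    writeLines(c("fixedStep chrom=chrI start=1 step=25 span=25",
                 "1", "2"), wig)
    tr <- readWiggle(wig)
    expect_equal(trackValues(tr, "chrI", 1, 25), rep(1, 25))
    expect_equal(trackValues(tr, "chrI", 26, 50), rep(2, 25))
    # uncovered positions read as 0
    expect_equal(trackValues(tr, "chrI", 51, 60), rep(0, 10))

    writeLines(c("variableStep chrom=chrII span=5", "11 3.0"), wig)
    tr2 <- readWiggle(wig)
    expect_equal(trackValues(tr2, "chrII", 11, 15), rep(3, 5))
    expect_equal(trackValues(tr2, "chrII", 10, 10), 0)
    expect_equal(trackValues(tr2, "chrII", 16, 16), 0)
})

test_that("wiggle parse errors are reported", {
    wig <- withr::local_tempfile(fileext = ".wig")
    writeLines(c("wibbleStep chrom=chrI start=1 step=25", "1"), wig)
    expect_error(readWiggle(wig), "unknown block header")
    writeLines(c("fixedStep chrom=chrI start=1 step=25 span=-5", "1"), wig)
    expect_error(readWiggle(wig), "span")
    writeLines("", wig)
    expect_error(readWiggle(wig), "no fixedStep/variableStep")
})

test_that("wiggle write/read round-trip reproduces covered values", {
    set.seed(42)
    vals <- round(stats::runif(40, 0, 10), 4)       # 40 windows of 25 bp
    tr <- makeTrack(rep(vals, each = 25))
    wig <- withr::local_tempfile(fileext = ".wig")
    writeWiggle(tr, wig, stepBp = 25)
    back <- readWiggle(wig)
    expect_equal(trackValues(back, "chrI", 1, 1000),
                 trackValues(tr, "chrI", 1, 1000))
})

test_that("overlapLength matches spec arithmetic and brute-force counts", {
    expect_equal(overlapLength(gr1("chrI", 1, 100), gr1("chrI", 51, 150)), 50L)
    expect_equal(overlapLength(gr1("chrI", 1, 100), gr1("chrI", 101, 200)), 0L)
    expect_equal(overlapLength(gr1("chrI", 201, 400), gr1("chrI", 101, 250)), 50L)
    expect_equal(overlapLength(gr1("chrI", 1, 100), gr1("chrII", 1, 100)), 0L)
    # strand is ignored
    expect_equal(overlapLength(gr1("chrI", 1, 100, "+"),
                               gr1("chrI", 50, 60, "-")), 11L)
    # exhaustive check against per-base counting for small coordinates
    spans <- expand.grid(s = 1:10, e = 1:12)
    spans <- spans[spans$s <= spans$e, ]
    for (i in seq_len(nrow(spans))) {
        a <- gr1("chrI", spans$s[i], spans$e[i])
        ov <- overlapLength(rep(a, nrow(spans)),
                            gr1("chrI", spans$s, spans$e))
        expected <- mapply(bruteOverlap, "chrI", spans$s[i], spans$e[i],
                           "chrI", spans$s, spans$e)
        expect_equal(ov, as.integer(expected))
    }
})

test_that("flanking bins follow strand and truncate at chromosome ends", {
    g <- gr1("chrI", 5001, 7000, "+")
    g$gene_id <- "g1"
    fr <- flankingRegions(g, c(chrI = 20000))
    pick <- function(lab) {
        r <- fr[fr$feature == lab]
        c(start(r), end(r))
    }
    expect_equal(pick("up_0_1k"), c(4001, 5000))
    expect_equal(pick("up_1_3k"), c(2001, 4000))
    expect_equal(pick("up_3_5k"), c(1, 2000))
    expect_equal(pick("body"), c(5001, 7000))
    expect_equal(pick("down_0_1k"), c(7001, 8000))
    expect_equal(pick("down_3_5k"), c(10001, 12000))

    # minus strand: upstream lies to the right
    strand(g) <- "-"
    frm <- flankingRegions(g, c(chrI = 20000))
    r <- frm[frm$feature == "up_0_1k"]
    expect_equal(c(start(r), end(r)), c(7001, 8000))
    r <- frm[frm$feature == "down_3_5k"]
    expect_equal(c(start(r), end(r)), c(1, 2000))

    # truncation: bins cut at position 1, empty bins omitted
    g2 <- gr1("chrI", 501, 900, "+")
    g2$gene_id <- "g2"
    fr2 <- flankingRegions(g2, c(chrI = 20000))
    r <- fr2[fr2$feature == "up_0_1k"]
    expect_equal(c(start(r), end(r)), c(1, 500))
    expect_false(any(fr2$feature %in% c("up_1_3k", "up_3_5k")))

    # gene body beyond the chromosome is an error
    expect_error(flankingRegions(g2, c(chrI = 800)), "outside chromosome")
})

test_that("flank bins of mirrored genes are mirror images", {
    L <- 30000
    set.seed(7)
    for (i in 1:20) {
        s <- sample(1000:20000, 1)
        e <- s + sample(200:3000, 1)
        g <- gr1("chrI", s, e, "+")
        g$gene_id <- "g"
        gm <- gr1("chrI", L - e + 1, L - s + 1, "-")
        gm$gene_id <- "g"
        f1 <- flankingRegions(g, c(chrI = L))
        f2 <- flankingRegions(gm, c(chrI = L))
        expect_equal(as.character(f1$feature), as.character(f2$feature))
        # mirror each + strand bin and compare
        expect_equal(start(f1), L - end(f2)[order(match(
            f2$feature, f1$feature))] + 1)
        expect_equal(end(f1), L - start(f2)[order(match(
            f2$feature, f1$feature))] + 1)
    }
})

test_that("gene annotations read from BED and GFF3 agree", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chrI\t0\t1000\tgA\t0\t+", "chrI\t5000\t5500\tgB\t0\t-"),
               bed)
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chrI\ttest\tgene\t1\t1000\t.\t+\t.\tID=gA",
                 "chrI\ttest\tgene\t5001\t5500\t.\t-\t.\tID=gB"), gff)
    gb <- readGenes(bed)
    gg <- readGenes(gff)
    expect_equal(start(gb), start(gg))
    expect_equal(end(gb), end(gg))
    expect_equal(gb$gene_id, gg$gene_id)
    expect_equal(as.character(strand(gb)), as.character(strand(gg)))
})
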