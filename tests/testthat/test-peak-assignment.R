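test_that("replicate consensus keeps rep1 peaks validated by rep2", {
    r1 <- gr1("chrI", 101, 300)
    r2 <- gr1("chrI", 251, 400)
    v <- replicateConsensus(r1, r2)
    expect_equal(c(start(v), end(v)), c(101, 300))
    # disjoint peaks are dropped
    expect_length(replicateConsensus(gr1("chrI", 101, 200),
                                     gr1("chrI", 301, 400)), 0)
    # identical replicate lists validate everything
    r <- gr1("chrI", c(1, 500, 900), c(100, 600, 1000))
    expect_equal(replicateConsensus(r, r), r)
    # empty input warns
    expect_warning(v0 <- replicateConsensus(r[0], r), "empty")
    expect_length(v0, 0)
})

test_that("consensus coordinate modes and idempotence behave", {
    r1 <- gr1("chrI", c(101, 700), c(300, 800))
    r2 <- gr1("chrI", c(251, 260), c(400, 290))
    ci <- AssignmentConfig(consensusCoordinates = "intersect")
    cu <- AssignmentConfig(consensusCoordinates = "union")
    vi <- replicateConsensus(r1, r2, ci)
    vu <- replicateConsensus(r1, r2, cu)
    # best-overlapping rep2 peak for rep1[1] is 251-400 (50 bp vs 31 bp)
    expect_equal(c(start(vi), end(vi)), c(251, 300))
    expect_equal(c(start(vu), end(vu)), c(101, 400))
    # rep1 mode: output subset of input, idempotent against rep2
    set.seed(3)
    s <- sort(sample(1:5000, 30))
    p1 <- gr1("chrI", s, s + sample(50:200, 30, replace = TRUE))
    s2 <- sort(sample(1:5000, 25))
    p2 <- gr1("chrI", s2, s2 + sample(50:200, 25, replace = TRUE))
    v <- replicateConsensus(p1, p2)
    expect_true(all(overlapLength(v, v) > 0))
    expect_true(length(v) <= length(p1))
    ov <- countOverlaps(v, p1, type = "equal")
    expect_true(all(ov >= 1))            # every validated peak is a rep1 peak
    expect_equal(replicateConsensus(v, p2), v)
})

test_that("peaks are assigned to features by the 100 bp overlap rule", {
    g <- gr1("chrI", 5001, 7000, "+")
    g$gene_id <- "g1"
    cl <- c(chrI = 20000)
    a <- assignPeaks(gr1("chrI", 5101, 5400), g, chromLengths = cl)
    expect_equal(nrow(a), 1)
    expect_equal(as.character(a$feature), "body")
    expect_equal(a$overlap_bp, 300L)
    # 99 bp overlap rejected, 100 bp accepted
    expect_equal(nrow(assignPeaks(gr1("chrI", 4902, 5099), g,
                                  chromLengths = cl)), 0)
    a100 <- assignPeaks(gr1("chrI", 4901, 5100), g, chromLengths = cl)
    expect_equal(nrow(a100), 2)          # 100 bp in up_0_1k and 100 in body
    # multi-assignment: 120 bp in the promoter bin and 110 bp in the body
    am <- assignPeaks(gr1("chrI", 4881, 5110), g, chromLengths = cl)
    expect_equal(sort(as.character(am$feature)), c("body", "up_0_1k"))
    expect_equal(am$overlap_bp[am$feature == "up_0_1k"], 120L)
    expect_equal(am$overlap_bp[am$feature == "body"], 110L)
})

test_that("assignments match the brute-force triple loop", {
    set.seed(11)
    for (rep in 1:200) {
        chromLens <- c(chrA = 3000L, chrB = 2500L)
        nGenes <- sample(1:8, 1)
        nPeaks <- sample(1:15, 1)
        minOv <- sample(c(5L, 10L, 25L), 1)
        gc <- sample(names(chromLens), nGenes, replace = TRUE)
        gs <- sample(100:2000, nGenes)
        genes <- gr1(gc, gs, gs + sample(20:400, nGenes, replace = TRUE),
                     sample(c("+", "-"), nGenes, replace = TRUE))
        genes$gene_id <- sprintf("g%02d", seq_len(nGenes))
        pc <- sample(names(chromLens), nPeaks, replace = TRUE)
        ps <- sample(1:2400, nPeaks)
        peaks <- gr1(pc, ps, ps + sample(10:300, nPeaks, replace = TRUE))
        peaks <- peaks[end(peaks) <= chromLens[as.character(seqnames(peaks))]]
        genes <- genes[end(genes) <= chromLens[as.character(seqnames(genes))]]
        if (length(genes) == 0L || length(peaks) == 0L) next
        got <- assignPeaks(peaks, genes,
                           AssignmentConfig(minOverlapBp = minOv),
                           chromLengths = chromLens)
        got$peak <- match(got$peak_id, sprintf("peak_%05d",
                                               seq_along(peaks)))
        got <- got[order(got$peak, got$gene_id,
                         as.character(got$feature)), ]
        want <- bruteAssign(peaks, genes, chromLens, minOv)
        expect_equal(nrow(got), nrow(want))
        if (nrow(want)) {
            expect_equal(got$peak, want$peak)
            expect_equal(got$gene_id, want$gene)
            expect_equal(as.character(got$feature), want$feature)
            expect_equal(got$overlap_bp, want$overlap)
        }
    }
})

test_that("raising the overlap threshold never adds assignments", {
    set.seed(21)
    s <- sample(1:20000, 40)
    peaks <- gr1("chrI", s, s + sample(50:500, 40, replace = TRUE))
    gs <- sample(1:18000, 10)
    genes <- gr1("chrI", gs, gs + sample(300:2000, 10, replace = TRUE),
                 sample(c("+", "-"), 10, replace = TRUE))
    genes$gene_id <- sprintf("g%02d", 1:10)
    cl <- c(chrI = 25000)
    last <- Inf
    for (m in c(1, 50, 100, 200, 400)) {
        n <- nrow(assignPeaks(peaks, genes,
                              AssignmentConfig(minOverlapBp = m),
                              chromLengths = cl))
        expect_lte(n, last)
        last <- n
    }
})

test_that("per-bin mean peak counts average over all genes in the bin", {
    # one gene in hour bin 2 with three body assignments
    osc1 <- OscillationSet("gA", 178.11, 2, TRUE)
    a1 <- data.frame(peak_id = c("p1", "p2", "p3"), gene_id = "gA",
                     feature = factor(rep("body", 3),
                                      levels = phasePeak:::flankLabels),
                     overlap_bp = 150L)
    t1 <- peaksPerGeneByHour(a1, osc1)
    expect_equal(t1$mean_peaks[t1$hour_bin == "2" & t1$feature == "body"], 3)
    expect_equal(t1$mean_peaks[t1$hour_bin == "2" & t1$feature == "total"], 3)

    # two genes in the same bin with body counts 1 and 3 -> mean 2
    osc2 <- OscillationSet(c("gA", "gB"), c(178, 180), c(1, 1), c(TRUE, TRUE))
    a2 <- data.frame(peak_id = sprintf("p%d", 1:4),
                     gene_id = c("gA", "gB", "gB", "gB"),
                     feature = factor(rep("body", 4),
                                      levels = phasePeak:::flankLabels),
                     overlap_bp = 150L)
    t2 <- peaksPerGeneByHour(a2, osc2)
    expect_equal(t2$mean_peaks[t2$hour_bin == "2" & t2$feature == "body"], 2)
    expect_equal(t2$n_genes[t2$hour_bin == "2"][1], 2L)

    # assignment-free genes count as zeros in their bin's denominator
    osc3 <- OscillationSet(c("gA", "gB", "gC"), c(178, 180, NA), c(1, 1, NA),
                           c(TRUE, TRUE, FALSE))
    t3 <- peaksPerGeneByHour(a1, osc3)
    expect_equal(t3$mean_peaks[t3$hour_bin == "2" & t3$feature == "body"],
                 1.5)
    expect_equal(t3$mean_peaks[t3$hour_bin == "non_osc" &
                               t3$feature == "total"], 0)

    # unknown assigned gene is an error listing the id
    expect_error(peaksPerGeneByHour(a1, osc1[0]), "gA")
})
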