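test_that("a constant track yields a flat profile at the constant", {
    tr <- makeTrack(rep(1, 30000))
    g <- gr1("chrI", 10001, 11500, "+")
    p <- geneProfile(tr, g)
    expect_length(p, 160)
    expect_equal(p, rep(1, 160))
    # strand makes no difference for a constant
    strand(g) <- "-"
    expect_equal(geneProfile(tr, g), rep(1, 160))
})

test_that("a 2 kb gene body reduces to direct 25 bp window means", {
    set.seed(5)
    vals <- stats::runif(30000)
    tr <- makeTrack(vals)
    g <- gr1("chrI", 10001, 12000, "+")
    p <- geneProfile(tr, g)
    direct <- colMeans(matrix(vals[10001:12000], nrow = 25))
    expect_equal(p[41:120], direct, tolerance = 1e-12)
    # flanks are plain genomic windows
    expect_equal(p[1:40], colMeans(matrix(vals[9001:10000], nrow = 25)))
    expect_equal(p[121:160], colMeans(matrix(vals[12001:13000], nrow = 25)))
})

test_that("body scaling stretches a half-on signal to half the windows", {
    vals <- numeric(30000)
    vals[10001:10500] <- 2             # first half of a 1 kb gene
    tr <- makeTrack(vals)
    g <- gr1("chrI", 10001, 11000, "+")
    p <- geneProfile(tr, g)
    body <- p[41:120]
    expect_equal(body[1:40], rep(2, 40))
    expect_equal(body[41:80], rep(0, 40))
})

test_that("scaled bodies match the brute-force dense resampler", {
    set.seed(9)
    for (rep in 1:25) {
        L <- sample(20:200, 1)
        v <- stats::rpois(L, 3) + stats::runif(L)
        vals <- numeric(5000)
        s <- 2000
        vals[s:(s + L - 1)] <- v
        tr <- makeTrack(vals)
        g <- gr1("chrI", s, s + L - 1, "+")
        body <- geneProfile(tr, g)[41:120]
        expect_equal(body, bruteScaledBody(v, 80), tolerance = 1e-3)
    }
})

test_that("scaling preserves the body-wide mean signal", {
    set.seed(13)
    for (L in c(237, 1000, 1999, 2000, 3741)) {
        v <- rep(stats::runif(ceiling(L / 50), 0, 5),
                 each = 50)[seq_len(L)]       # piecewise-constant
        vals <- c(numeric(1500), v, numeric(1500))
        tr <- makeTrack(vals)
        g <- gr1("chrI", 1501, 1500 + L, "+")
        body <- geneProfile(tr, g)[41:120]
        expect_equal(mean(body), mean(v), tolerance = 1e-6)
    }
})

test_that("minus-strand genes with mirrored signal give mirrored profiles", {
    set.seed(17)
    n <- 20000
    vals <- stats::runif(n)
    g <- gr1("chrI", 8001, 9200, "+")
    p1 <- geneProfile(makeTrack(vals), g)
    gm <- gr1("chrI", n - 9200 + 1, n - 8001 + 1, "-")
    p2 <- geneProfile(makeTrack(rev(vals)), gm)
    expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("windows clipped off the chromosome are missing, not zero", {
    tr <- makeTrack(rep(1, 5000))
    g <- gr1("chrI", 301, 800, "+")      # upstream flank reaches -700
    p <- geneProfile(tr, g)
    expect_true(all(is.na(p[1:28])))     # 700 bp / 25 clipped
    expect_equal(p[29:160], rep(1, 132))
    # a chromosome absent from the track warns and returns zeros
    g2 <- gr1("chrX", 2001, 3000, "+")
    expect_warning(p2 <- geneProfile(tr, g2), "chrX")
    expect_equal(p2, rep(0, 160))
})

test_that("aggregation averages windows and tracks per-window n", {
    p <- rbind(rep(0, 160), rep(2, 160))
    mp <- aggregateProfiles(p)
    expect_equal(mp@mean, rep(1, 160))
    expect_equal(mp@nGenes, 2L)
    expect_true(all(mp@ciLow <= mp@mean & mp@mean <= mp@ciHigh))
    # single profile: degenerate CI equal to the mean
    mp1 <- aggregateProfiles(rep(3, 160))
    expect_true(mp1@degenerate)
    expect_equal(mp1@ciLow, mp1@mean)
    # missing windows drop out of n
    p2 <- rbind(c(NA, rep(1, 159)), rep(3, 160))
    mp2 <- aggregateProfiles(p2)
    expect_equal(mp2@n[1:2], c(1L, 2L))
    expect_equal(mp2@mean[1], 3)
    expect_error(aggregateProfiles(matrix(0, 0, 160)), "no profiles")
})

test_that("normal-approximation intervals cover the true mean ~95%", {
    set.seed(29)
    nGenes <- 400
    trueMean <- 2
    covered <- logical(0)
    for (r in 1:10) {
        p <- matrix(stats::rnorm(nGenes * 160, trueMean, 1), nrow = nGenes)
        mp <- aggregateProfiles(p)
        covered <- c(covered,
                     mp@ciLow <= trueMean & trueMean <= mp@ciHigh)
    }
    expect_gt(mean(covered), 0.93)
    expect_lt(mean(covered), 0.97)
})

test_that("class profiles split genes by phase, expression and identity", {
    n <- 30000
    tr <- makeTrack(rep(2, n))
    starts <- seq(6001, by = 4000, length.out = 6)
    genes <- gr1("chrI", starts, starts + 999, "+")
    genes$gene_id <- sprintf("g%d", seq_along(genes))
    genes$expression_percentile <- c(5, 10, 50, 80, 90, 99)
    osc <- OscillationSet(genes$gene_id,
                          c(180, 200, 300, 100, NA, NA),
                          c(1, 1, 1, 1, NA, NA),
                          c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
    pr <- profileByClass(tr, genes, osc, chromLengths = c(chrI = n))
    # constant track: all classes give the same flat profile
    for (cl in names(pr)) expect_equal(pr[[cl]]@mean, rep(2, 160))
    expect_equal(pr$early@nGenes, 2L)    # phases 180 and 200
    expect_equal(pr$middle@nGenes, 1L)
    expect_equal(pr$late@nGenes, 1L)
    expect_equal(pr$all@nGenes, 6L)
    expect_equal(pr$no_expression@nGenes, 2L)  # percentiles 5 and 10
    # a single-gene class equals that gene's own profile
    expect_equal(pr$middle@mean,
                 geneProfile(tr, genes[3], chromLengths = c(chrI = n)))
    # empty classes are omitted with a warning
    expect_warning(
        pr2 <- profileByClass(tr, genes[5:6], osc,
                              classes = c("early", "all"),
                              chromLengths = c(chrI = n)),
        "empty")
    expect_named(pr2, "all")
})

test_that("promoter-biased binding separates early from silent genes", {
    # synthetic tracks with TSS-proximal bumps only for early-phase genes
    n <- 40000
    vals <- numeric(n)
    starts <- seq(6001, by = 6000, length.out = 6)
    genes <- gr1("chrI", starts, starts + 1499, "+")
    genes$gene_id <- sprintf("g%d", seq_along(genes))
    genes$expression_percentile <- c(90, 80, 70, 10, 5, 15)
    osc <- OscillationSet(genes$gene_id,
                          c(170, 200, 240, NA, NA, NA),
                          c(1, 1, 1, NA, NA, NA),
                          c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    for (i in 1:3)                        # bump over the promoter
        vals[(starts[i] - 300):(starts[i] + 100)] <- 5
    pr <- profileByClass(makeTrack(vals), genes, osc,
                         classes = c("early", "no_expression"),
                         chromLengths = c(chrI = n))
    tssWin <- which.min(abs(metageneAxis()))
    expect_gt(pr$early@mean[tssWin], pr$no_expression@mean[tssWin])
})

test_that("tidy metagene tables carry one row per class and window", {
    tr <- makeTrack(rep(1, 20000))
    g <- gr1("chrI", 8001, 9000, "+")
    g$gene_id <- "g1"
    osc <- OscillationSet("g1", 180, 1, TRUE)
    pr <- profileByClass(tr, g, osc, classes = c("early", "all"),
                         chromLengths = c(chrI = 20000))
    tab <- metageneTable(pr)
    expect_equal(nrow(tab), 2 * 160)
    expect_equal(unique(tab$class), c("early", "all"))
    expect_true(all(c("window_index", "axis_position", "mean", "ci_low",
                      "ci_high", "n") %in% names(tab)))
})
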