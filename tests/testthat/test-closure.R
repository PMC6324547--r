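gapAt <- function(g1, g2, scaffold = "chr1") {
    g <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(g1, g2))
    S4Vectors::mcols(g)$terminal <- FALSE
    S4Vectors::mcols(g)$L <- g2 - g1 + 1L
    g
}

test_that("tag pairs are retained strictly within the 1 +/- c ratio band", {
    gap <- gapAt(11001, 12000)
    # equal read/scaffold distances: r = 1, retained
    a <- rbind(anchorRow("r1", 501, 10001), anchorRow("r1", 2901, 12401))
    pr <- pairTags(gap, a, readLength = 5000, maxDeviation = 0.2)
    expect_identical(nrow(pr), 1L)
    expect_equal(pr$r, 1.0)
    # r = 1.25 with c = 0.2: outside the open interval
    b <- rbind(anchorRow("r1", 501, 10001), anchorRow("r1", 3501, 12401))
    expect_identical(nrow(pairTags(gapAt(11001, 12000), b, 5000, 0.2)), 0L)
    # r exactly 1 + c is rejected: the inequalities are strict
    d <- rbind(anchorRow("r1", 1, 10001), anchorRow("r1", 2401, 12001))
    r <- (2401 - 1) / (12001 - 10001)
    expect_equal(r, 1.2)
    expect_identical(nrow(pairTags(gapAt(11001, 12000), d, 5000, 0.2)), 0L)
    expect_identical(nrow(pairTags(gapAt(11001, 12000), d, 5000, 0.201)), 1L)
})

test_that("boundary support needs the tag-count threshold and the window", {
    gap <- gapAt(10001, 11000)
    param <- gapCloserParam()
    rl <- c(rA = 10000L)
    mk <- function(n, lastEnd = 9950L) {
        do.call(rbind, lapply(seq_len(n), function(i)
            anchorRow("rA", (i - 1) * 300 + 1,
                      lastEnd - 299L - (n - i) * 300L)))
    }
    # six anchors, nearest within the window: left side supported
    sup <- boundarySupport(gap, mk(6), rl, param)
    expect_identical(sup$side, "left")
    expect_identical(sup$tag_count, 6L)
    # four anchors fall short of the default threshold of five
    expect_identical(nrow(boundarySupport(gap, mk(4), rl, param)), 0L)
    # five anchors but the nearest one sits past the window
    far <- mk(5, lastEnd = 10000L - 1500L)
    expect_identical(nrow(boundarySupport(gap, far, rl, param)), 0L)
    # a terminal gap can only ever be supported on one side
    term <- gapAt(1, 1000)
    right <- do.call(rbind, lapply(1:5, function(i)
        anchorRow("rA", (i - 1) * 300 + 1, 1001 + (i - 1) * 300)))
    supT <- boundarySupport(term, right, rl, param)
    expect_identical(supT$side, "right")
})

test_that("extension measures read protrusion into the gap", {
    gap <- gapAt(10001, 11000)
    param <- gapCloserParam()
    # forward read, nearest anchor ends 100 bases before the gap,
    # 2600 read bases remain after the tag: extension 2500
    a <- do.call(rbind, lapply(1:5, function(i)
        anchorRow("rA", 2001 + (i - 1) * 300, 8401 + (i - 1) * 300)))
    # nearest anchor: p = 3201, ends at scaffold 9900
    sup <- boundarySupport(gap, a, c(rA = 6100L), param)
    expect_identical(sup$dist, 100L)
    expect_identical(sup$ext, (6100L - (3201L + 299L)) - 100L)
    expect_equal(sup$proportion, 1)
})

test_that("type-2 closures follow the printed N arithmetic", {
    param <- gapCloserParam()
    # under-spanned gap: N = L_C - (extL + extR)
    fx <- makeType2Fixture(L_C = 1000L, extL = 600L, extR = 300L, seed = 1)
    res <- closeGap(fx$gap, fx$anchors, fx$reads, param)
    expect_identical(res$type, 2L)
    expect_identical(res$inserted_N, 1000L - 600L - 300L)
    expect_identical(res$status, "partial")
    expect_identical(nchar(res$fill), 600L + 100L + 300L)
    # jointly spanning reads leave exactly the 100-N sentinel
    fx <- makeType2Fixture(L_C = 1000L, extL = 600L, extR = 500L, seed = 2)
    res <- closeGap(fx$gap, fx$anchors, fx$reads, param)
    expect_identical(res$inserted_N, 100L)
    # a side with zero extension contributes nothing
    fx <- makeType2Fixture(L_C = 1000L, extL = 0L, extR = 300L, seed = 3)
    res <- closeGap(fx$gap, fx$anchors, fx$reads, param)
    expect_identical(res$inserted_N, 700L)
    expect_identical(nchar(res$fill), 1000L)
})

test_that("type-2 N counts match the closed-form in randomized
           configurations", {
    param <- gapCloserParam()
    set.seed(77)
    n <- 1000L
    for (i in seq_len(n)) {
        L_C <- sample(150:2000, 1)
        extL <- sample(0:1500, 1)
        extR <- sample(0:1500, 1)
        slackL <- sample(0:200, 1)
        slackR <- sample(0:200, 1)
        if (extL + extR == 0L) extL <- 1L
        fx <- makeType2Fixture(L_C, extL, extR, slackL, slackR, seed = i)
        res <- closeGap(fx$gap, fx$anchors, fx$reads, param)
        expect_identical(res$type, 2L)
        if (extL + extR < L_C) {
            expect_identical(res$inserted_N, L_C - extL - extR)
            # with flush anchors this is exactly L(C) - (L(A)-p(a)+p(b))
            if (slackL == 0L && slackR == 0L)
                expect_identical(res$inserted_N,
                                 L_C - (fx$L_A - fx$pA_end +
                                        (fx$pB_start - 1L)))
            # partial fills preserve the locus length
            expect_identical(nchar(res$fill), res$y - res$x + 1L)
        } else {
            expect_identical(res$inserted_N, 100L)
        }
        expect_identical(nchar(gsub("[^N]", "", res$fill)),
                         res$inserted_N)
    }
})

test_that("type-3 closures fill from one side and pad with N", {
    param <- gapCloserParam()
    base <- makeType2Fixture(L_C = 1000L, extL = 400L, extR = 0L, seed = 5)
    # keep only the left-side read: single-flank support
    anchors <- base$anchors[base$anchors$read_id == "rA", , drop = FALSE]
    res <- closeGap(base$gap, anchors, base$reads, param)
    expect_identical(res$type, 3L)
    expect_identical(res$inserted_N, 600L)
    expect_identical(nchar(res$fill), res$y - res$x + 1L)
    # over-long extension is truncated to leave the 100-N sentinel
    base <- makeType2Fixture(L_C = 1000L, extL = 1200L, extR = 0L, seed = 6)
    anchors <- base$anchors[base$anchors$read_id == "rA", , drop = FALSE]
    res <- closeGap(base$gap, anchors, base$reads, param)
    expect_identical(res$inserted_N, 100L)
    expect_identical(nchar(res$fill) - 100L,
                     res$L_C - 100L + res$gap_start - res$x)
    # zero extension emits no edit
    base <- makeType2Fixture(L_C = 1000L, extL = 0L, extR = 0L, seed = 7)
    anchors <- base$anchors[base$anchors$read_id == "rA", , drop = FALSE]
    expect_null(closeGap(base$gap, anchors, base$reads, param))
})

test_that("a reverse-orientation spanning read restores truth through its
           reverse complement", {
    set.seed(21)
    truthSeq <- randomSeq(12000)
    asm <- truthSeq
    substr(asm, 5001, 5500) <- strrep("N", 500)
    assembly <- Biostrings::DNAStringSet(c(chr1 = asm))
    # the read covers the gap but is sequenced from the opposite strand
    fwd <- substr(truthSeq, 2001, 9000)
    reads <- Biostrings::DNAStringSet(c(rc1 = as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(fwd)))))
    run <- runGapCloser(assembly, reads,
                        param = gapCloserParam(iterations = 1))
    expect_identical(gapReport(run)$gap_type, "1")
    expect_identical(as.character(finalAssembly(run)[[1]]), truthSeq)
})

test_that("applyClosures edits exactly the replaced intervals", {
    asm <- Biostrings::DNAStringSet(c(s1 = paste0(randomSeq(50, seed = 31),
                                                  strrep("N", 10),
                                                  randomSeq(50))))
    # identity on zero results
    expect_identical(as.character(applyClosures(asm, NULL)),
                     as.character(asm))
    res <- data.frame(scaffold = "s1", gap_start = 51L, gap_end = 60L,
                      L_C = 10L, type = 1L, x = 46L, y = 65L,
                      fill = randomSeq(25), inserted_N = 0L, reads = "r",
                      status = "closed", stringsAsFactors = FALSE)
    out <- applyClosures(asm, res)
    s0 <- as.character(asm[[1]]); s1 <- as.character(out[[1]])
    expect_identical(substr(s1, 1, 45), substr(s0, 1, 45))
    expect_identical(substr(s1, 71, nchar(s1)), substr(s0, 66, nchar(s0)))
    expect_identical(totalN(out), 0L)
    # overlapping intervals are rejected
    res2 <- rbind(res, within(res, { x <- 60L; y <- 80L }))
    expect_error(applyClosures(asm, res2), "overlapping")
})

test_that("gap type precedence prefers a single spanning read", {
    # both flanks supported by rA and rB individually, but rS spans
    fx <- makeType2Fixture(L_C = 400L, extL = 100L, extR = 100L, seed = 9)
    span <- do.call(rbind, c(
        lapply(0:4, function(k) anchorRow("rS", 1L + k * 300L,
                                          1501L + k * 300L)),
        lapply(0:4, function(k) anchorRow("rS", 2101L + k * 300L,
                                          3601L + k * 300L))))
    reads <- c(fx$reads,
               Biostrings::DNAStringSet(c(rS = randomSeq(4000, seed = 10))))
    res <- closeGap(fx$gap, rbind(fx$anchors, span), reads,
                    gapCloserParam())
    expect_identical(res$type, 1L)
    expect_identical(res$reads, "rS")
    expect_identical(res$inserted_N, 0L)
})
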