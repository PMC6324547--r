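test_that("alignment coverage follows the (match + insert)/tag formula", {
    rec <- data.frame(match_len = c(240, 250, 0, 290),
                      insert_len = c(0, 20, 0, 40),
                      tag_len = 300)
    expect_equal(alignmentCoverage(rec), c(0.80, 0.90, 0, 1.10))
})

test_that("coverage filtering is inclusive at the threshold and idempotent", {
    rec <- data.frame(tag_id = c("t1", "t2", "t3"),
                      match_len = c(237, 240, 243), insert_len = 0,
                      tag_len = 300, stringsAsFactors = FALSE)
    kept <- filterByCoverage(rec, 0.80)
    expect_identical(kept$tag_id, c("t2", "t3"))   # 0.79 out, 0.80 in
    expect_identical(filterByCoverage(kept, 0.80)$tag_id, kept$tag_id)
    expect_identical(nrow(filterByCoverage(rec, 1.0)), 0L)
    # insertion-heavy coverage above 1 passes a one-sided filter
    over <- data.frame(tag_id = "t", match_len = 280, insert_len = 40,
                       tag_len = 300)
    expect_identical(nrow(filterByCoverage(over, 1.0)), 1L)
})

test_that("multiplicity classification separates unique and multi-mapped tags", {
    a <- rbind(anchorRow("r1", 1, 100), anchorRow("r1", 301, 500),
               anchorRow("r1", 301, 5000), anchorRow("r1", 301, 9000))
    cls <- classifyMultiplicity(a)
    expect_identical(cls$multiplicity[cls$p == 1], "type1")
    expect_identical(unique(cls$multiplicity[cls$p == 301]), "type2")
    expect_identical(sum(cls$multiplicity == "type2"), 3L)
})

test_that("orientation vote keeps the majority and removes ties", {
    mk <- function(strands) {
        do.call(rbind, lapply(seq_along(strands), function(i)
            anchorRow("r1", (i - 1) * 300 + 1, i * 1000,
                      strand = strands[i])))
    }
    expect_identical(nrow(orientationFilter(mk(c("+", "+", "+", "-")))), 3L)
    expect_identical(unique(orientationFilter(
        mk(c("+", "+", "+", "-")))$strand), "+")
    expect_identical(nrow(orientationFilter(mk(c("+", "+", "-", "-")))), 0L)
    expect_identical(nrow(orientationFilter(mk(rep("+", 4)))), 4L)
})

test_that("order filter keeps anchors collinear with the median reference", {
    # fully collinear: all kept
    a <- rbind(anchorRow("r1", 1, 101), anchorRow("r1", 301, 401),
               anchorRow("r1", 601, 701))
    expect_identical(nrow(orderFilter(a)), 3L)
    # median tag at p=301 is reference; the tag at 601 breaks the order
    b <- rbind(anchorRow("r1", 1, 101), anchorRow("r1", 301, 901),
               anchorRow("r1", 601, 501))
    kept <- orderFilter(b)
    expect_identical(sort(kept$p), c(1L, 301L))
    # two anchors with reversed scaffold order on the forward strand: both go
    d <- rbind(anchorRow("r1", 1, 900), anchorRow("r1", 301, 100))
    expect_identical(nrow(orderFilter(d)), 0L)
    # reverse-strand groups are consistent when anti-collinear
    e <- rbind(anchorRow("r1", 1, 900, strand = "-"),
               anchorRow("r1", 301, 100, strand = "-"))
    expect_identical(nrow(orderFilter(e)), 2L)
})

test_that("orientation and order filters are idempotent and leave strictly
           monotone anchors", {
    set.seed(11)
    for (i in 1:40) {
        g <- randomAnchorGroup()
        o1 <- orientationFilter(g)
        expect_identical(orientationFilter(o1), o1)
        k1 <- orderFilter(o1)
        expect_identical(orderFilter(k1), k1)
        if (nrow(k1) > 1L) {
            expect_identical(length(unique(k1$strand)), 1L)
            adj <- if (k1$strand[1] == "+") k1$pos else -k1$pos
            expect_true(all(diff(adj[order(k1$p)]) > 0))
        }
    }
})

test_that("filters agree with naive reference implementations on small
           groups", {
    set.seed(12)
    for (i in 1:200) {
        g <- randomAnchorGroup(maxN = 6L)
        expect_identical(orientationFilter(g), oracleOrientation(g))
        og <- orientationFilter(g)
        expect_identical(orderFilter(og), oracleOrder(og))
    }
})

test_that("multi-mapped tags are rescued only by a uniquely consistent
           candidate", {
    # retained unique neighbours at read offsets 301 and 901 on s1/+
    t1 <- rbind(anchorRow("nb", 301, 1401, scaffold = "s1"),
                anchorRow("nb", 901, 2001, scaffold = "s1"))
    t1$read_id <- "rX"
    # candidate loci for the tag at offset 601
    cand <- rbind(anchorRow("rX", 601, 1701, scaffold = "s1"),
                  anchorRow("rX", 601, 5001, scaffold = "s2",
                            strand = "-"))
    got <- rescueMultimapped(cand, t1, 0.2)
    expect_identical(nrow(got), 1L)
    expect_identical(got$pos, 1701L)
    expect_identical(got$scaffold, "s1")
    # no candidate on the neighbours' scaffold/orientation: none chosen
    off <- anchorRow("rX", 601, 5001, scaffold = "s2")
    expect_identical(nrow(rescueMultimapped(off, t1, 0.2)), 0L)
    # order-inconsistent candidate (scaffold position past both
    # neighbours) is rejected by the distance-ratio test
    bad <- anchorRow("rX", 601, 9001, scaffold = "s1")
    expect_identical(nrow(rescueMultimapped(bad, t1, 0.2)), 0L)
    # two equally consistent candidates tie, so none is chosen
    tie <- rbind(anchorRow("rX", 601, 1701, scaffold = "s1"),
                 anchorRow("rX", 601, 1702, scaffold = "s1"))
    expect_identical(nrow(rescueMultimapped(tie, t1, 0.2)), 0L)
})

test_that("the full filtration cascade composes the rounds", {
    # read r1: 3 consistent forward anchors plus one reverse outlier, and
    # a multi-mapped tag rescueable between the first two
    uniq <- rbind(anchorRow("r1", 1, 101), anchorRow("r1", 301, 401),
                  anchorRow("r1", 901, 1001),
                  anchorRow("r1", 1201, 5001, strand = "-"))
    multi <- rbind(anchorRow("r1", 601, 701),
                   anchorRow("r1", 601, 9001))
    aln <- rbind(uniq, multi)
    out <- filterTagAlignments(aln, gapCloserParam())
    expect_identical(sort(out$p), c(1L, 301L, 601L, 901L))
    expect_identical(out$pos[out$p == 601], 701L)
    expect_identical(unique(out$strand), "+")
})
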