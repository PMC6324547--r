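# Shared fixture builders and independent oracles.

randomSeq <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build an anchor data.frame row by row (columns as produced by
# filterTagAlignments, minus the filter metadata).
anchorRow <- function(read_id, p, pos, strand = "+", tag_len = 300L,
                      scaffold = "chr1") {
    data.frame(tag_id = paste0(read_id, "#", (p - 1L) %/% tag_len + 1L),
               read_id = read_id, index = (p - 1L) %/% tag_len + 1L,
               p = as.integer(p), tag_len = as.integer(tag_len),
               scaffold = scaffold, pos = as.integer(pos),
               end_pos = as.integer(pos + tag_len - 1L), strand = strand,
               match_len = as.numeric(tag_len), insert_len = 0,
               aln_span = as.numeric(tag_len), mapq = 60L,
               stringsAsFactors = FALSE)
}

anchorsDF <- function(...) do.call(rbind, list(...))

# A two-read type-2 scenario with controlled extensions and slacks.
# The scaffold is 3000 bp flank + L_C N + 3000 bp flank; read A anchors
# only the left flank (5 tags), read B only the right (5 tags).
makeType2Fixture <- function(L_C, extL, extR, slackL = 0L, slackR = 0L,
                             tagLen = 300L, seed = 1) {
    set.seed(seed)
    flank <- 3000L
    g1 <- flank + 1L
    g2 <- flank + L_C
    scaffold <- paste0(randomSeq(flank), strrep("N", L_C),
                       randomSeq(flank))
    L_A <- 5L * tagLen + slackL + extL + 50L
    L_B <- 5L * tagLen + slackR + extR + 50L
    readA <- randomSeq(L_A)
    readB <- randomSeq(L_B)
    # left anchors: nearest ends slackL bases before the gap
    pcA <- L_A - (tagLen - 1L) - slackL - extL
    endA <- g1 - 1L - slackL
    rowsA <- lapply(0:4, function(k)
        anchorRow("rA", pcA - k * tagLen, endA - tagLen + 1L - k * tagLen))
    # right anchors: nearest starts slackR bases after the gap
    pcB <- extR + slackR + 1L
    posB <- g2 + 1L + slackR
    rowsB <- lapply(0:4, function(k)
        anchorRow("rB", pcB + k * tagLen, posB + k * tagLen))
    anchors <- do.call(rbind, c(rowsA, rowsB))
    gap <- GenomicRanges::GRanges("chr1", IRanges::IRanges(g1, g2))
    S4Vectors::mcols(gap)$terminal <- FALSE
    S4Vectors::mcols(gap)$L <- L_C
    list(gap = gap,
         anchors = anchors,
         reads = Biostrings::DNAStringSet(c(rA = readA, rB = readB)),
         scaffold = Biostrings::DNAStringSet(c(chr1 = scaffold)),
         g1 = g1, g2 = g2, L_A = L_A, L_B = L_B,
         pA_end = pcA + tagLen - 1L, pB_start = pcB)
}

# Error-free end-to-end fixture: truth genome, gapped assembly, reads.
makeSmallWorld <- function(genomeLen = 50000L, nGaps = 4L,
                           lengthRange = c(200L, 1500L), coverage = 20,
                           sub = 0, ins = 0, del = 0, seed = 3L) {
    truth <- simulateGenome(genomeLen, seed = seed)
    gapped <- introduceGaps(truth$genome, n = nGaps,
                            lengthRange = lengthRange,
                            minSeparation = 6000L, seed = seed)
    reads <- simulateReads(truth$genome, coverage = coverage, sub = sub,
                           ins = ins, del = del, seed = seed)
    list(truth = truth, gapped = gapped, reads = reads)
}

totalN <- function(assembly) {
    sum(Biostrings::letterFrequency(assembly, "N"))
}
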