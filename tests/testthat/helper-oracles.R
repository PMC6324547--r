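# Deliberately naive reference implementations, written independently of
# the package code paths, used to cross-check the filtration rules and
# contiguity statistics.

# Orientation vote, one (read, scaffold) group at a time, by explicit
# counting.
oracleOrientation <- function(anchors) {
    out <- anchors[0, , drop = FALSE]
    for (rid in unique(anchors$read_id)) {
        for (sc in unique(anchors$scaffold)) {
            g <- anchors[anchors$read_id == rid &
                         anchors$scaffold == sc, , drop = FALSE]
            if (nrow(g) == 0L) next
            nf <- 0L; nr <- 0L
            for (i in seq_len(nrow(g))) {
                if (g$strand[i] == "+") nf <- nf + 1L else nr <- nr + 1L
            }
            if (nf == nr) next
            win <- if (nf > nr) "+" else "-"
            out <- rbind(out, g[g$strand == win, , drop = FALSE])
        }
    }
    out <- out[order(out$read_id, out$scaffold, out$p), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# Order consistency against the lower-median reference, explicit loops;
# reverse groups compare negated scaffold positions.
oracleOrder <- function(anchors) {
    out <- anchors[0, , drop = FALSE]
    for (rid in unique(anchors$read_id)) {
        for (sc in unique(anchors$scaffold)) {
            g <- anchors[anchors$read_id == rid &
                         anchors$scaffold == sc, , drop = FALSE]
            n <- nrow(g)
            if (n == 0L) next
            g <- g[order(g$p), , drop = FALSE]
            adj <- if (g$strand[1] == "+") g$pos else -g$pos
            if (n == 1L) {
                out <- rbind(out, g)
            } else if (n == 2L) {
                if (adj[2] > adj[1]) out <- rbind(out, g)
            } else {
                ref <- floor((n + 1) / 2)
                for (i in seq_len(n)) {
                    ok <- if (i == ref) TRUE
                          else if (i < ref) adj[i] < adj[ref]
                          else adj[i] > adj[ref]
                    if (ok) out <- rbind(out, g[i, , drop = FALSE])
                }
            }
        }
    }
    out <- out[order(out$read_id, out$scaffold, out$p), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# N50 by explicit sort-and-accumulate.
oracleN50 <- function(lengths) {
    if (length(lengths) == 0L) return(0L)
    lengths <- sort(lengths, decreasing = TRUE)
    half <- sum(lengths) / 2
    acc <- 0
    for (l in lengths) {
        acc <- acc + l
        if (acc >= half) return(as.integer(l))
    }
}

# Random anchor groups for the filter-equivalence property tests.
randomAnchorGroup <- function(maxN = 6L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n <- sample.int(maxN, 1L)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    p <- sort(sample.int(40L, n)) * 300L - 299L
    pos <- sample.int(20000L, n)
    do.call(rbind, lapply(seq_len(n), function(i)
        anchorRow("r1", p[i], pos[i], strand = strands[i])))
}
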