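# Gap classification and closure.
#
# All read coordinates are handled in a canonical forward frame: anchors of
# a reverse-orientation (read, scaffold) group are re-expressed on the
# reverse complement of the read (p' = L - p - tagLen + 2, 1-based), after
# which scaffold position grows with read offset for every group and a
# single set of interval formulas applies.

.canonicalP <- function(p, tagLen, strand, readLen) {
    ifelse(strand == "+", p, readLen - p - tagLen + 2L)
}

# Read sequence in the canonical frame of the group.
.canonicalRead <- function(reads, readId, strand) {
    s <- as.character(reads[[readId]])
    if (strand == "+") s else .revComp(s)
}

#' Collect per-side boundary support for a gap
#'
#' A read supports a gap flank when (i) it has at least \code{minTagCount}
#' retained anchors strictly on that flank (alignment end before the gap
#' for the left side, alignment start after it for the right side) and
#' (ii) its anchor nearest the gap lies within \code{boundaryWindow} bases
#' of the gap edge. For each supporting read the extension -- the number of
#' read bases protruding past the nearest anchor into the gap, after
#' orientation adjustment -- and the proportion of the gap it covers are
#' recorded.
#'
#' @param gap a length-1 \code{GRanges} row from [findGaps()].
#' @param anchors retained anchor \code{data.frame} (see
#'   [filterTagAlignments()]) for the gap's scaffold.
#' @param readLengths named integer vector of read lengths.
#' @param param a [GapCloserParam-class].
#' @return \code{data.frame} with one row per (read, side):
#'   columns \code{read_id, side, strand, tag_count, p_canon, pos,
#'   end_pos, dist, ext, proportion}, where \code{p_canon}/\code{pos}/
#'   \code{end_pos} describe the anchor nearest the gap and \code{dist} is
#'   the number of scaffold bases between that anchor and the gap edge.
#' @export
boundarySupport <- function(gap, anchors, readLengths,
                            param = gapCloserParam()) {
    s <- GenomicRanges::start(gap)
    e <- GenomicRanges::end(gap)
    W <- boundaryWindow(param)
    minCnt <- minTagCount(param)
    L_C <- e - s + 1L
    out <- list()
    if (nrow(anchors) == 0L) return(.emptySupport())
    for (g in split(anchors, anchors$read_id)) {
        rid <- g$read_id[1]
        strand <- g$strand[1]
        L_A <- unname(readLengths[rid])
        pc <- .canonicalP(g$p, g$tag_len, g$strand, L_A)
        left <- g$end_pos < s
        right <- g$pos > e
        if (any(left)) {
            i <- which(left)[which.max(g$end_pos[left])]
            dist <- s - 1L - g$end_pos[i]
            if (sum(left) >= minCnt && dist <= W) {
                ext <- (L_A - (pc[i] + g$tag_len[i] - 1L)) - dist
                out[[length(out) + 1L]] <- data.frame(
                    read_id = rid, side = "left", strand = strand,
                    tag_count = sum(left), p_canon = pc[i],
                    pos = g$pos[i], end_pos = g$end_pos[i], dist = dist,
                    ext = ext,
                    proportion = max(0, min(ext / L_C, 1)),
                    stringsAsFactors = FALSE)
            }
        }
        if (any(right)) {
            i <- which(right)[which.min(g$pos[right])]
            dist <- g$pos[i] - e - 1L
            if (sum(right) >= minCnt && dist <= W) {
                ext <- (pc[i] - 1L) - dist
                out[[length(out) + 1L]] <- data.frame(
                    read_id = rid, side = "right", strand = strand,
                    tag_count = sum(right), p_canon = pc[i],
                    pos = g$pos[i], end_pos = g$end_pos[i], dist = dist,
                    ext = ext,
                    proportion = max(0, min(ext / L_C, 1)),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (length(out) == 0L) return(.emptySupport())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.emptySupport <- function() {
    data.frame(read_id = character(), side = character(),
               strand = character(), tag_count = integer(),
               p_canon = integer(), pos = integer(), end_pos = integer(),
               dist = integer(), ext = integer(), proportion = numeric(),
               stringsAsFactors = FALSE)
}

#' Enumerate and filter cross-boundary tag pairs
#'
#' All pairs between a read's anchors on the left flank and its anchors on
#' the right flank of a gap are formed; a pair is retained iff the
#' read-distance to scaffold-distance ratio lies strictly within
#' \eqn{(1-c, 1+c)}, with read offsets taken in the canonical
#' (orientation-adjusted) frame so both distances are positive.
#'
#' @param gap a length-1 \code{GRanges} row.
#' @param readAnchors retained anchors of one read on the gap's scaffold.
#' @param readLength length of that read.
#' @param maxDeviation the tolerance \eqn{c}.
#' @return \code{data.frame} of retained pairs with the left/right anchor
#'   coordinates and the ratio \code{r}.
#' @export
pairTags <- function(gap, readAnchors, readLength, maxDeviation = 0.2) {
    s <- GenomicRanges::start(gap)
    e <- GenomicRanges::end(gap)
    g <- readAnchors
    pc <- .canonicalP(g$p, g$tag_len, g$strand, readLength)
    li <- which(g$end_pos < s)
    ri <- which(g$pos > e)
    if (length(li) == 0L || length(ri) == 0L)
        return(data.frame(pL = integer(), pR = integer(),
                          posL = integer(), posR = integer(),
                          endL = integer(), r = numeric()))
    grid <- expand.grid(i = li, j = ri)
    dp <- pc[grid$j] - pc[grid$i]
    dO <- g$pos[grid$j] - g$pos[grid$i]
    r <- dp / dO
    c <- maxDeviation
    keep <- r > 1 - c & r < 1 + c
    data.frame(pL = pc[grid$i][keep], pR = pc[grid$j][keep],
               posL = g$pos[grid$i][keep], posR = g$pos[grid$j][keep],
               endL = g$end_pos[grid$i][keep], r = r[keep])
}

# Deterministic support selection: largest proportion, then larger
# tag_count, then lexicographically smaller read id.
.selectSupport <- function(sup) {
    sup[order(-sup$proportion, -sup$tag_count, sup$read_id), ,
        drop = FALSE][1, , drop = FALSE]
}

.closureRow <- function(scaffold, s, e, type, x, y, fill, insN, reads,
                        status) {
    data.frame(scaffold = scaffold, gap_start = s, gap_end = e,
               L_C = e - s + 1L, type = type, x = x, y = y, fill = fill,
               inserted_N = insN, reads = reads, status = status,
               stringsAsFactors = FALSE)
}

#' Classify one gap and construct its closure
#'
#' Implements the three-type decision: (1) one read anchors both flanks
#' with at least one retained tag pair -- the gap is fully closed by the
#' read sequence between the two anchor tags nearest the boundaries;
#' (2) different reads anchor the two flanks -- each contributes its
#' protruding sequence and an N spacer of \eqn{L_C - (ext_L + ext_R)} is
#' left between them, or a 100-N sentinel when the two extensions jointly
#' span the gap; (3) only one flank is anchored -- the protruding sequence
#' fills from that side and \eqn{L_C - ext} N remain (over-long extensions
#' are truncated to leave a 100-N sentinel rather than fabricating an
#' unverified junction). A result is only emitted when it strictly reduces
#' the gap's N count.
#'
#' @param gap a length-1 \code{GRanges} row.
#' @param anchors retained anchors on the gap's scaffold.
#' @param reads \code{DNAStringSet} of long reads.
#' @param param a [GapCloserParam-class].
#' @return A one-row closure \code{data.frame} (columns \code{scaffold,
#'   gap_start, gap_end, L_C, type, x, y, fill, inserted_N, reads,
#'   status}), or \code{NULL} when the gap cannot be improved. \code{[x,y]}
#'   is the 1-based closed scaffold interval replaced by \code{fill}.
#' @export
closeGap <- function(gap, anchors, reads, param = gapCloserParam()) {
    scaffold <- as.character(GenomicRanges::seqnames(gap))
    s <- GenomicRanges::start(gap)
    e <- GenomicRanges::end(gap)
    L_C <- e - s + 1L
    readLengths <- stats::setNames(Biostrings::width(reads), names(reads))
    sup <- boundarySupport(gap, anchors, readLengths, param)
    if (nrow(sup) == 0L) return(NULL)
    supL <- sup[sup$side == "left", , drop = FALSE]
    supR <- sup[sup$side == "right", , drop = FALSE]

    ## -- type 1: a single read anchors both flanks ----------------------
    both <- intersect(supL$read_id, supR$read_id)
    if (length(both)) {
        byRead <- split(anchors, anchors$read_id)
        pairCount <- vapply(both, function(rid) {
            nrow(pairTags(gap, byRead[[rid]], readLengths[rid],
                          maxDeviation(param)))
        }, integer(1))
        cand <- both[pairCount > 0L]
        if (length(cand)) {
            ord <- order(-pairCount[cand], -readLengths[cand], cand)
            rid <- cand[ord[1]]
            pr <- pairTags(gap, byRead[[rid]], readLengths[rid],
                           maxDeviation(param))
            res <- .closeType1(scaffold, s, e, rid, pr,
                               byRead[[rid]]$strand[1],
                               byRead[[rid]]$tag_len[1], reads)
            if (!is.null(res)) return(res)
        }
    }

    ## -- type 2: two flanks anchored by different reads -----------------
    if (nrow(supL) && nrow(supR)) {
        selL <- .selectSupport(supL)
        selR <- .selectSupport(supR)
        if (selL$read_id == selR$read_id) {
            # a read may serve only one side; keep its better one
            if (selL$proportion >= selR$proportion) {
                supR <- supR[supR$read_id != selL$read_id, , drop = FALSE]
                if (nrow(supR)) selR <- .selectSupport(supR)
            } else {
                supL <- supL[supL$read_id != selR$read_id, , drop = FALSE]
                if (nrow(supL)) selL <- .selectSupport(supL)
            }
        }
        if (nrow(supL) && nrow(supR) && selL$read_id != selR$read_id) {
            res <- .closeType2(scaffold, s, e, selL, selR, reads, param)
            if (!is.null(res)) return(res)
        }
    }

    ## -- type 3: a single usable flank ----------------------------------
    rest <- rbind(supL, supR)
    if (nrow(rest) > 0L)
        return(.closeType3(scaffold, s, e, .selectSupport(rest), reads,
                           param))
    NULL
}

.closeType1 <- function(scaffold, s, e, rid, pairs, strand, tagLen,
                        reads) {
    # anchor pair: among paired tags, the left tag nearest the left edge
    # and the right tag nearest the right edge
    iL <- which.max(pairs$endL)
    iR <- which.min(pairs$posR)
    pL <- pairs$pL[iL]; endL <- pairs$endL[iL]
    pR <- pairs$pR[iR]; posR <- pairs$posR[iR]
    if (endL >= posR || pL + tagLen > pR) return(NULL)
    seq <- .canonicalRead(reads, rid, strand)
    fill <- substr(seq, pL + tagLen, pR - 1L)
    .closureRow(scaffold, s, e, 1L, endL + 1L, posR - 1L, fill, 0L, rid,
                "closed")
}

.closeType2 <- function(scaffold, s, e, selL, selR, reads, param) {
    L_C <- e - s + 1L
    tagLen <- tagLength(param)
    extL <- max(0L, selL$ext)
    extR <- max(0L, selR$ext)
    if (extL + extR <= 0L) return(NULL)
    if (extL > 0L) {
        x <- selL$end_pos + 1L
        seqA <- .canonicalRead(reads, selL$read_id, selL$strand)
        fillA <- substr(seqA, selL$p_canon + tagLen, nchar(seqA))
    } else {
        x <- s
        fillA <- ""
    }
    if (extR > 0L) {
        y <- selR$pos - 1L
        seqB <- .canonicalRead(reads, selR$read_id, selR$strand)
        fillB <- substr(seqB, 1L, selR$p_canon - 1L)
    } else {
        y <- e
        fillB <- ""
    }
    if (extL + extR < L_C) {
        nN <- L_C - extL - extR
    } else {
        if (L_C <= 100L) return(NULL)  # sentinel would not reduce N
        nN <- 100L
    }
    fill <- paste0(fillA, strrep("N", nN), fillB)
    .closureRow(scaffold, s, e, 2L, x, y, fill, nN,
                paste(selL$read_id, selR$read_id, sep = ","), "partial")
}

.closeType3 <- function(scaffold, s, e, sel, reads, param) {
    L_C <- e - s + 1L
    tagLen <- tagLength(param)
    if (sel$ext <= 0L) return(NULL)
    extUsed <- if (sel$ext >= L_C) L_C - 100L else sel$ext
    if (extUsed <= 0L) return(NULL)  # gap too short for a sentinel
    nN <- L_C - extUsed
    seq <- .canonicalRead(reads, sel$read_id, sel$strand)
    if (sel$side == "left") {
        used <- sel$dist + extUsed
        from <- sel$p_canon + tagLen
        fill <- paste0(substr(seq, from, from + used - 1L),
                       strrep("N", nN))
        x <- sel$end_pos + 1L
        y <- e
    } else {
        used <- sel$dist + extUsed
        fill <- paste0(strrep("N", nN),
                       substr(seq, sel$p_canon - used, sel$p_canon - 1L))
        x <- s
        y <- sel$pos - 1L
    }
    .closureRow(scaffold, s, e, 3L, x, y, fill, nN, sel$read_id,
                "partial")
}

#' Apply closure edits to an assembly
#'
#' Edits are applied right-to-left within each scaffold so that earlier
#' coordinates stay valid; replaced intervals must be pairwise disjoint.
#' Bases outside the replaced intervals are untouched and the scaffold
#' count and ids never change.
#'
#' @param assembly a named \code{DNAStringSet}.
#' @param results closure \code{data.frame} rows (see [closeGap()]).
#' @return The edited \code{DNAStringSet}.
#' @export
applyClosures <- function(assembly, results) {
    if (is.null(results) || nrow(results) == 0L) return(assembly)
    seqs <- as.character(assembly)
    for (sc in unique(results$scaffold)) {
        rs <- results[results$scaffold == sc, , drop = FALSE]
        rs <- rs[order(rs$x), , drop = FALSE]
        if (nrow(rs) > 1L && any(rs$x[-1] <= rs$y[-nrow(rs)]))
            .stopf("overlapping replaced intervals on scaffold %s", sc)
        seq <- seqs[[sc]]
        for (i in rev(seq_len(nrow(rs)))) {
            seq <- paste0(substr(seq, 1L, rs$x[i] - 1L), rs$fill[i],
                          substr(seq, rs$y[i] + 1L, nchar(seq)))
        }
        seqs[[sc]] <- seq
    }
    out <- DNAStringSet(seqs)
    names(out) <- names(assembly)
    out
}
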