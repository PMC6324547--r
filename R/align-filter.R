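#' Alignment coverage of tag alignments
#'
#' Coverage scores an alignment as (match base length + insert base
#' length) / tag length. Match bases are identical bases between tag and
#' scaffold; insert bases are bases inserted relative to the scaffold.
#' The value is a fraction that may exceed 1 for insertion-rich alignments;
#' it is deliberately not clamped and the retention filter is one-sided.
#'
#' @param alignments alignment \code{data.frame} (see
#'   [readTagAlignments()]).
#' @return Numeric vector of coverage values, one per record.
#' @examples
#' rec <- data.frame(match_len = 240, insert_len = 0, tag_len = 300)
#' alignmentCoverage(rec)  # 0.8
#' @export
alignmentCoverage <- function(alignments) {
    stopifnot(all(alignments$tag_len > 0))
    (alignments$match_len + alignments$insert_len) / alignments$tag_len
}

#' Retain alignments whose coverage meets the threshold
#'
#' Retention is inclusive: an alignment at exactly the threshold is kept.
#' Record order is preserved and the operation is idempotent.
#'
#' @param alignments alignment \code{data.frame}.
#' @param threshold minimum coverage in (0, 1].
#' @return The retained subset of \code{alignments}, with a
#'   \code{coverage} column added.
#' @export
filterByCoverage <- function(alignments, threshold = 0.80) {
    stopifnot(threshold > 0, threshold <= 1)
    alignments$coverage <- alignmentCoverage(alignments)
    out <- alignments[alignments$coverage >= threshold, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify tags by alignment multiplicity
#'
#' After coverage filtering, a tag with exactly one surviving locus is
#' unique ("type1"); a tag with two or more candidate loci (including
#' secondary/supplementary records) is multi-mapped ("type2") and can only
#' be used after rescue against neighbouring unique anchors. Tags with no
#' surviving locus are absent from the output.
#'
#' @param alignments coverage-filtered alignment \code{data.frame}.
#' @return The same rows with a \code{multiplicity} column
#'   (\code{"type1"}/\code{"type2"}).
#' @export
classifyMultiplicity <- function(alignments) {
    if (nrow(alignments) == 0L) {
        alignments$multiplicity <- character(0)
        return(alignments)
    }
    nloci <- table(alignments$tag_id)
    alignments$multiplicity <-
        as.vector(ifelse(nloci[alignments$tag_id] == 1L,
                         "type1", "type2"))
    alignments
}

# Apply fun to each (read_id, scaffold) group; rbind the results.
.perGroup <- function(anchors, fun) {
    if (nrow(anchors) == 0L) return(anchors)
    key <- paste(anchors$read_id, anchors$scaffold, sep = "\r")
    parts <- split(seq_len(nrow(anchors)), key)
    out <- lapply(parts, function(i) fun(anchors[i, , drop = FALSE]))
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out[order(out$read_id, out$scaffold, out$p), , drop = FALSE]
}

#' Orientation majority vote among unique anchors
#'
#' For each (read, scaffold) group of unique ("type1") anchors, the
#' alignment orientations are tallied. When one orientation has strictly
#' more anchors, only that orientation is retained; when the two counts are
#' equal, the whole group is considered error-prone and removed.
#'
#' @param anchors \code{data.frame} of type1 anchors.
#' @return The retained subset, sorted by read, scaffold and read offset.
#' @export
orientationFilter <- function(anchors) {
    .perGroup(anchors, function(g) {
        fwd <- sum(g$strand == "+")
        rev <- nrow(g) - fwd
        if (fwd == rev) return(g[0, , drop = FALSE])
        g[g$strand == (if (fwd > rev) "+" else "-"), , drop = FALSE]
    })
}

#' Order-consistency filter against a median reference tag
#'
#' Within each single-orientation (read, scaffold) group: with exactly two
#' anchors, both are kept iff their read order matches their
#' orientation-adjusted scaffold order, otherwise both are removed. With
#' three or more, the tag at the median read position (lower median for
#' even counts) is the reference and is always kept; every other anchor is
#' kept iff its read-order relative to the reference matches its scaffold
#' order relative to the reference. For reverse-orientation groups,
#' scaffold positions are compared after negation, so consistency means
#' anti-collinearity.
#'
#' @param anchors \code{data.frame} of orientation-filtered type1 anchors.
#' @return The retained subset; orientation-adjusted scaffold positions of
#'   the survivors are strictly monotone in read offset.
#' @export
orderFilter <- function(anchors) {
    .perGroup(anchors, function(g) {
        n <- nrow(g)
        if (n <= 1L) return(g)
        sgn <- if (g$strand[1] == "+") 1 else -1
        g <- g[order(g$p), , drop = FALSE]
        o <- sgn * g$pos
        if (n == 2L) {
            if (o[2] > o[1]) return(g)
            return(g[0, , drop = FALSE])
        }
        ref <- (n + 1L) %/% 2L
        keep <- vapply(seq_len(n), function(i) {
            if (i == ref) return(TRUE)
            if (i < ref) o[i] < o[ref] else o[i] > o[ref]
        }, logical(1))
        g[keep, , drop = FALSE]
    })
}

#' Rescue multi-mapped tags via neighbouring unique anchors
#'
#' For each multi-mapped ("type2") tag, its candidate loci are tested
#' against the nearest retained unique anchors of the same read on each
#' side (one side suffices at read ends): the candidate must lie on the
#' same scaffold with the same orientation as the neighbours, in the
#' correct relative order, and the read-distance / scaffold-distance ratio
#' to each neighbour must lie strictly within \eqn{(1-c, 1+c)}. When
#' exactly one candidate satisfies all criteria it is adopted as the tag's
#' anchor; ambiguity (zero or several survivors) leaves the tag unused.
#' Only unique anchors serve as neighbours; rescued tags do not rescue
#' others.
#'
#' @param type2 \code{data.frame} of candidate records of multi-mapped
#'   tags.
#' @param retained \code{data.frame} of retained unique anchors (post
#'   orientation and order filtering).
#' @param maxDeviation the tolerance \eqn{c}.
#' @return \code{data.frame} of chosen records (possibly 0 rows).
#' @export
rescueMultimapped <- function(type2, retained, maxDeviation = 0.2) {
    if (nrow(type2) == 0L || nrow(retained) == 0L)
        return(type2[0, , drop = FALSE])
    out <- vector("list", 0L)
    byReadT1 <- split(retained, retained$read_id)
    byTag <- split(type2, type2$tag_id)
    for (cand in byTag) {
        t1 <- byReadT1[[cand$read_id[1]]]
        if (is.null(t1) || nrow(t1) == 0L) next
        p0 <- cand$p[1]
        left <- t1[t1$p < p0, , drop = FALSE]
        right <- t1[t1$p > p0, , drop = FALSE]
        nbs <- rbind(
            if (nrow(left)) left[which.max(left$p), , drop = FALSE],
            if (nrow(right)) right[which.min(right$p), , drop = FALSE])
        if (is.null(nbs) || nrow(nbs) == 0L) next
        ok <- vapply(seq_len(nrow(cand)), function(i) {
            all(vapply(seq_len(nrow(nbs)), function(j) {
                .rescueConsistent(cand[i, ], nbs[j, ], maxDeviation)
            }, logical(1)))
        }, logical(1))
        if (sum(ok) == 1L)
            out[[length(out) + 1L]] <- cand[ok, , drop = FALSE]
    }
    if (length(out) == 0L) return(type2[0, , drop = FALSE])
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.rescueConsistent <- function(cand, nb, c) {
    if (cand$scaffold != nb$scaffold || cand$strand != nb$strand)
        return(FALSE)
    dO <- if (nb$strand == "+") cand$pos - nb$pos else nb$pos - cand$pos
    dp <- cand$p - nb$p
    if (dO == 0) return(FALSE)
    r <- dp / dO
    r > 0 && r > 1 - c && r < 1 + c
}

#' Run the full alignment filtration cascade
#'
#' Applies, in order: the coverage filter, multiplicity classification, the
#' orientation majority vote and the order-consistency filter on unique
#' anchors, and finally rescue of multi-mapped tags. The retained anchor
#' set drives gap classification and closure.
#'
#' @param alignments raw alignment \code{data.frame} (see
#'   [readTagAlignments()]).
#' @param param a [GapCloserParam-class].
#' @return \code{data.frame} of retained anchors with \code{coverage} and
#'   \code{multiplicity} columns.
#' @export
filterTagAlignments <- function(alignments, param = gapCloserParam()) {
    a <- filterByCoverage(alignments, minCoverage(param))
    a <- classifyMultiplicity(a)
    t1 <- a[a$multiplicity == "type1", , drop = FALSE]
    t2 <- a[a$multiplicity == "type2", , drop = FALSE]
    t1 <- orientationFilter(t1)
    t1 <- orderFilter(t1)
    resc <- rescueMultimapped(t2, t1, maxDeviation(param))
    out <- rbind(t1, resc)
    out <- out[order(out$read_id, out$scaffold, out$p), , drop = FALSE]
    rownames(out) <- NULL
    out
}
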