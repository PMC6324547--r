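# Truth-based evaluation of a gap-closing run, plus contiguity metrics.

#' Contig lengths of an assembly
#'
#' Contigs are maximal N-free runs; runs shorter than \code{minLength} are
#' dropped (the field commonly reports contigs >= 1000 bp; the default
#' here keeps everything).
#'
#' @param assembly a \code{DNAStringSet} or character vector of sequences.
#' @param minLength minimum contig length to keep.
#' @return Integer vector of contig lengths.
#' @export
contigLengths <- function(assembly, minLength = 1L) {
    seqs <- as.character(assembly)
    parts <- strsplit(seqs, "N+")
    lens <- unlist(lapply(parts, nchar), use.names = FALSE)
    lens <- lens[lens >= minLength]
    as.integer(lens)
}

#' N50 of a length multiset
#'
#' The largest length L such that sequences of length >= L together cover
#' at least half of the total.
#'
#' @param lengths integer vector of contig/scaffold lengths.
#' @return N50 as a single integer (0 for an empty input).
#' @examples
#' contigN50(c(8, 4, 4, 2))  # 4
#' @export
contigN50 <- function(lengths) {
    if (length(lengths) == 0L) return(0L)
    lengths <- sort(as.integer(lengths), decreasing = TRUE)
    as.integer(lengths[which(cumsum(as.numeric(lengths)) >=
                             sum(as.numeric(lengths)) / 2)[1]])
}

#' Score a closed assembly against simulation truth
#'
#' Each original gap locus is located in the closed assembly via unique
#' flanking sequence taken from the truth genome outside the maximal edit
#' radius (boundary window + tag length), so that coordinate shifts from
#' complete closures do not matter. Per gap the status is one of
#' \code{closed_exact} (locus byte-identical to truth),
#' \code{closed_diff} (N-free but different; an identity percentage is
#' computed by global pairwise alignment with unit scores, restricted to
#' alignment columns inside the original gap span), \code{partial}
#' (fewer N than the original gap), \code{open}, or \code{unlocated}
#' (flanks not found, counted as not closed).
#'
#' @param closed the closed assembly (\code{DNAStringSet}).
#' @param truthGenome the truth genome the fixture was derived from.
#' @param truth the truth \code{data.frame} from [introduceGaps()].
#' @param flank flank length used to locate loci.
#' @param editRadius how far outside the gap a closure may legitimately
#'   rewrite scaffold bases (boundary window + tag length for default
#'   parameters).
#' @param minContig minimum contig length for the N50 metrics.
#' @return list with \code{perGap} (a \code{data.frame} with
#'   \code{status} and \code{identity} per truth record) and
#'   \code{summary} (gaps, closed, closed rate, mean identity of closed
#'   loci, contig N50 of the closed assembly, misassembly count --
#'   closed loci below 90 percent identity -- and its ratio to contig
#'   N50).
#' @export
evaluateClosure <- function(closed, truthGenome, truth, flank = 300L,
                            editRadius = 1300L, minContig = 1L) {
    tseqs <- as.character(truthGenome)
    cseqs <- as.character(closed)
    D <- editRadius + flank
    status <- character(nrow(truth))
    identity <- rep(NA_real_, nrow(truth))
    for (i in seq_len(nrow(truth))) {
        sc <- truth$scaffold[i]
        s <- truth$start[i]; e <- truth$end[i]
        tseq <- tseqs[[sc]]
        # the evaluated region extends editRadius past the gap; locating
        # flanks sit just outside it, clamped at the sequence ends
        rs <- max(1L, s - editRadius)
        re <- min(nchar(tseq), e + editRadius)
        flL <- min(flank, rs - 1L)
        flR <- min(flank, nchar(tseq) - re)
        if (flL < 30L || flR < 30L) {
            status[i] <- "unlocated"  # too close to a sequence end
            next
        }
        lf <- substr(tseq, rs - flL, rs - 1L)
        rf <- substr(tseq, re + 1L, re + flR)
        lhits <- Biostrings::start(Biostrings::matchPattern(
            lf, Biostrings::DNAString(cseqs[[sc]])))
        rhits <- Biostrings::start(Biostrings::matchPattern(
            rf, Biostrings::DNAString(cseqs[[sc]])))
        loc <- .pickFlankPair(lhits, rhits, flL, flR,
                              (re + flR) - (rs - flL) + 1L)
        if (is.null(loc)) {
            status[i] <- "unlocated"
            next
        }
        region <- substr(cseqs[[sc]], loc[1] + flL, loc[2] - 1L)
        truthRegion <- substr(tseq, rs, re)
        nN <- .countN(region)
        if (region == truthRegion) {
            status[i] <- "closed_exact"
            identity[i] <- 100
        } else if (nN == 0L) {
            status[i] <- "closed_diff"
            identity[i] <- .gapIdentity(truthRegion, region,
                                        gapFrom = s - rs + 1L,
                                        gapTo = s - rs + (e - s + 1L))
        } else if (nN >= e - s + 1L) {
            status[i] <- "open"
        } else {
            status[i] <- "partial"
        }
    }
    perGap <- cbind(truth[, c("scaffold", "start", "end", "L", "origin")],
                    data.frame(status = status, identity = identity,
                               stringsAsFactors = FALSE))
    closedMask <- status %in% c("closed_exact", "closed_diff")
    n50 <- contigN50(contigLengths(closed, minContig))
    misass <- sum(closedMask & !is.na(identity) & identity < 90)
    list(perGap = perGap,
         summary = list(
             gaps = nrow(truth),
             closed = sum(closedMask),
             closed_rate = if (nrow(truth)) sum(closedMask) / nrow(truth)
                           else NA_real_,
             exact = sum(status == "closed_exact"),
             partial = sum(status == "partial"),
             open = sum(status %in% c("open", "unlocated")),
             mean_identity = if (any(closedMask))
                 mean(identity[closedMask]) else NA_real_,
             contig_N50 = n50,
             misassemblies = misass,
             misassembly_to_N50 = if (n50 > 0) misass / n50 else NA_real_))
}

# Choose the (left, right) flank hit pair with the span closest to the
# expected locus size; returns c(leftStart, rightStart) or NULL.
.pickFlankPair <- function(lhits, rhits, flankL, flankR, expected) {
    if (length(lhits) == 0L || length(rhits) == 0L) return(NULL)
    grid <- expand.grid(l = lhits, r = rhits)
    grid <- grid[grid$r > grid$l + flankL, , drop = FALSE]
    if (nrow(grid) == 0L) return(NULL)
    span <- grid$r + flankR - grid$l
    best <- which.min(abs(span - expected))
    c(grid$l[best], grid$r[best])
}

# Percent identity of `region` vs `truthRegion`, by global pairwise
# alignment with unit scores, counted only over alignment columns whose
# truth coordinate falls inside [gapFrom, gapTo] (the original gap span),
# so flank context does not inflate the estimate. Insertion columns are
# charged to the last consumed truth position.
.gapIdentity <- function(truthRegion, region, gapFrom, gapTo) {
    aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(region),
        subject = Biostrings::DNAString(truthRegion),
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 0, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    tpos <- cumsum(sa != "-")
    inGap <- tpos >= gapFrom & tpos <= gapTo
    cols <- sum(inGap)
    if (cols == 0L) return(NA_real_)
    100 * sum(inGap & pa == sa & pa != "-") / cols
}
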