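# Synthetic fixtures: genomes with planted repeats, gapped derivatives and
# error-bearing long reads, so the whole pipeline is testable without any
# external data.

.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv())
        }, add = TRUE)
        set.seed(as.integer(seed))
    }
    force(expr)
}

.randomBases <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with planted repeat copies
#'
#' Background bases are i.i.d. uniform over A/C/G/T; \code{repeatCopies}
#' exact copies of one random repeat unit are planted at non-overlapping
#' loci. Deterministic per seed.
#'
#' @param length genome length in bases.
#' @param repeatUnitLength length of the repeat unit.
#' @param repeatCopies number of planted copies (0 for none).
#' @param seed RNG seed.
#' @return list with \code{genome} (a named \code{DNAStringSet} with one
#'   sequence \code{"chr1"}) and \code{repeats} (a \code{GRanges} of the
#'   planted copies).
#' @export
simulateGenome <- function(length, repeatUnitLength = 500L,
                           repeatCopies = 0L, seed = 1L) {
    length <- as.integer(length)
    repeatUnitLength <- as.integer(repeatUnitLength)
    repeatCopies <- as.integer(repeatCopies)
    if (repeatCopies > 0L &&
        length < repeatCopies * (repeatUnitLength + 2L))
        .stopf("genome too short for the requested repeat packing")
    .withSeed(seed, {
        seq <- .randomBases(length)
        starts <- integer(0)
        if (repeatCopies > 0L) {
            unit <- .randomBases(repeatUnitLength)
            # rejection-sample non-overlapping placements; keep copies
            # away from the sequence ends so that a copy converted to a
            # gap always has anchorable flanks on both sides
            margin <- max(0L, min(2500L,
                (length - repeatCopies * (repeatUnitLength + 2L)) %/% 2L))
            tries <- 0L
            while (length(starts) < repeatCopies) {
                cand <- margin + sample.int(
                    length - repeatUnitLength - 2L * margin - 1L, 1L) + 1L
                if (all(abs(cand - starts) > repeatUnitLength)) {
                    starts <- c(starts, cand)
                } else if ((tries <- tries + 1L) > 10000L) {
                    .stopf("could not place %d repeat copies", repeatCopies)
                }
            }
            starts <- sort(starts)
            for (st in starts)
                substr(seq, st, st + repeatUnitLength - 1L) <- unit
        }
        genome <- DNAStringSet(stats::setNames(seq, "chr1"))
        repeats <- GenomicRanges::GRanges(
            seqnames = rep("chr1", length(starts)),
            ranges = IRanges::IRanges(
                start = starts,
                width = rep(repeatUnitLength, length(starts))))
        list(genome = genome, repeats = repeats)
    })
}

#' Derive a gapped assembly from a genome
#'
#' Two strategies: \code{"random"} replaces \code{n} non-overlapping
#' intervals (lengths uniform in \code{lengthRange}, at least
#' \code{minSeparation} bases apart and away from the sequence ends) with
#' N runs of identical length; \code{"repeat"} replaces every planted
#' repeat copy of at least \code{repeatMinLength} bases with an equal-length
#' N run, emulating repeat-derived gaps. Truth records allow exact
#' restoration.
#'
#' @param genome a named \code{DNAStringSet} (typically from
#'   [simulateGenome()]).
#' @param strategy \code{"random"} or \code{"repeat"}.
#' @param n number of random gaps.
#' @param lengthRange integer range of random gap lengths.
#' @param minSeparation minimum distance between gaps and to the sequence
#'   ends (random strategy).
#' @param repeats \code{GRanges} of planted repeats (repeat strategy).
#' @param repeatMinLength minimum repeat length converted to a gap.
#' @param seed RNG seed.
#' @return list with \code{assembly} (gapped \code{DNAStringSet}) and
#'   \code{truth}, a \code{data.frame} with columns \code{scaffold, start,
#'   end, L, origin, true_seq}.
#' @export
introduceGaps <- function(genome, strategy = c("random", "repeat"),
                          n = 20L, lengthRange = c(200L, 2000L),
                          minSeparation = 5000L, repeats = NULL,
                          repeatMinLength = 200L, seed = 1L) {
    strategy <- match.arg(strategy)
    seqs <- as.character(genome)
    truth <- list()
    if (strategy == "random") {
        .withSeed(seed, {
            # spread gaps over scaffolds proportionally to length
            G <- nchar(seqs)
            alloc <- diff(round(c(0, cumsum(G) / sum(G)) * n))
            for (k in seq_along(seqs)) {
                nk <- as.integer(alloc[k])
                if (nk == 0L) next
                lens <- sample(seq(lengthRange[1], lengthRange[2]), nk,
                               replace = TRUE)
                slack <- G[k] - sum(lens) - (nk + 1L) * minSeparation
                if (slack < 0L)
                    .stopf("gaps do not fit in scaffold %s", names(seqs)[k])
                cuts <- sort(sample.int(slack + 1L, nk, replace = TRUE)) - 1L
                starts <- minSeparation * seq_len(nk) +
                    c(0L, cumsum(lens))[seq_len(nk)] + cuts + 1L
                for (i in seq_len(nk)) {
                    st <- starts[i]; en <- st + lens[i] - 1L
                    truth[[length(truth) + 1L]] <- data.frame(
                        scaffold = names(seqs)[k], start = as.integer(st),
                        end = as.integer(en), L = as.integer(lens[i]),
                        origin = "random",
                        true_seq = substr(seqs[k], st, en),
                        stringsAsFactors = FALSE)
                    substr(seqs[k], st, en) <- strrep("N", lens[i])
                }
            }
        })
    } else {
        if (is.null(repeats))
            .stopf("repeat strategy needs the planted repeat coordinates")
        keep <- GenomicRanges::width(repeats) >= repeatMinLength
        reps <- repeats[keep]
        for (i in seq_along(reps)) {
            sc <- as.character(GenomicRanges::seqnames(reps[i]))
            st <- GenomicRanges::start(reps[i])
            en <- GenomicRanges::end(reps[i])
            truth[[length(truth) + 1L]] <- data.frame(
                scaffold = sc, start = st, end = en, L = en - st + 1L,
                origin = "repeat", true_seq = substr(seqs[sc], st, en),
                stringsAsFactors = FALSE)
            substr(seqs[sc], st, en) <- strrep("N", en - st + 1L)
        }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(scaffold = character(), start = integer(),
                   end = integer(), L = integer(), origin = character(),
                   true_seq = character(), stringsAsFactors = FALSE)
    truth <- truth[order(truth$scaffold, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    assembly <- DNAStringSet(seqs)
    names(assembly) <- names(genome)
    list(assembly = assembly, truth = truth)
}

#' Simulate long reads with a simple per-base error model
#'
#' Read lengths are log-normal (mean \code{meanLength}, log-sd
#' \code{sdLog}), clamped to \code{[minLength, genome length]}; start
#' positions are uniform; both strands are equiprobable. Errors are applied
#' per base: a base is deleted with probability \code{del}, substituted
#' (by a different base) with probability \code{sub}, and followed by a
#' random inserted base with probability \code{ins}. Expected total bases
#' are approximately \code{coverage} times the genome length.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param coverage target depth of coverage.
#' @param sub,ins,del per-base error probabilities.
#' @param meanLength mean read length in bases.
#' @param sdLog log-scale standard deviation of read length.
#' @param minLength minimum read length.
#' @param seed RNG seed.
#' @return A named \code{DNAStringSet} of reads
#'   (\code{"read1"}, \code{"read2"}, ...).
#' @export
simulateReads <- function(genome, coverage = 20, sub = 0, ins = 0,
                          del = 0, meanLength = 10000, sdLog = 0.3,
                          minLength = 1000, seed = 1L) {
    stopifnot(coverage > 0, sub >= 0, ins >= 0, del >= 0,
              sub + del < 1)
    seqs <- as.character(genome)
    G <- nchar(seqs)
    total <- sum(G)
    .withSeed(seed, {
        nReads <- max(1L, round(coverage * total / meanLength))
        # scaffold chosen proportionally to length
        sc <- sample(seq_along(seqs), nReads, replace = TRUE,
                     prob = G / total)
        lens <- round(stats::rlnorm(nReads,
                                    meanlog = log(meanLength) - sdLog^2 / 2,
                                    sdlog = sdLog))
        lens <- pmin(pmax(lens, minLength), G[sc])
        starts <- floor(stats::runif(nReads) * (G[sc] - lens + 1)) + 1
        revFlag <- stats::runif(nReads) < 0.5
        out <- character(nReads)
        for (i in seq_len(nReads)) {
            s <- substr(seqs[sc[i]], starts[i], starts[i] + lens[i] - 1)
            if (revFlag[i]) s <- .revComp(s)
            if (sub > 0 || ins > 0 || del > 0)
                s <- .mutate(s, sub, ins, del)
            out[i] <- s
        }
        reads <- DNAStringSet(out)
        names(reads) <- paste0("read", seq_len(nReads))
        reads
    })
}

.mutate <- function(seq, sub, ins, del) {
    alphabet <- c("A", "C", "G", "T")
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(ch)
    u <- stats::runif(n)
    isDel <- u < del
    isSub <- !isDel & u < del + sub
    if (any(isSub)) {
        shift <- sample.int(3L, sum(isSub), replace = TRUE)
        ch[isSub] <- alphabet[(match(ch[isSub], alphabet) + shift - 1L) %%
                              4L + 1L]
    }
    ch[isDel] <- ""
    insFlag <- stats::runif(n) < ins
    insCh <- character(n)
    if (any(insFlag))
        insCh[insFlag] <- sample(alphabet, sum(insFlag), replace = TRUE)
    paste(paste0(ch, insCh), collapse = "")
}

#' Write simulated reads to FASTA or FASTQ
#'
#' FASTQ output (chosen by a \code{.fq}/\code{.fastq} extension) uses a
#' constant placeholder quality; the gap-closing algorithm never reads
#' qualities.
#'
#' @param reads a named \code{DNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLongReads <- function(reads, path) {
    if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
        q <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
        Biostrings::writeXStringSet(reads, filepath = path,
                                    format = "fastq", qualities = q)
    } else {
        Biostrings::writeXStringSet(reads, filepath = path, width = 80L)
    }
    invisible(path)
}
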