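#' Read a draft assembly from FASTA
#'
#' Loads scaffolds, upper-cases the sequences and validates them against the
#' DNA-with-ambiguity alphabet used internally: only A, C, G, T and N are
#' accepted (soft-masked lowercase input is upper-cased, not treated
#' specially).
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return A named \code{DNAStringSet}, one element per record, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTNNNNACGT"), fa)
#' readAssembly(fa)
#' @export
readAssembly <- function(path) {
    if (!file.exists(path))
        .stopf("assembly file not found: %s", path)
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    if (length(x) == 0L)
        .stopf("no FASTA records in %s", path)
    # keep the id up to the first whitespace, as aligners do
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        .stopf("duplicate scaffold ids in %s: %s", path,
               paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    x <- DNAStringSet(toupper(x))
    bad <- Biostrings::alphabetFrequency(x, baseOnly = FALSE)
    extra <- colnames(bad)[!colnames(bad) %in% c("A", "C", "G", "T", "N")]
    if (any(bad[, extra, drop = FALSE] > 0))
        .stopf("non-ACGTN characters in %s", path)
    x
}

#' Read long reads from FASTA or FASTQ
#'
#' Format is chosen by extension (\code{.fq}/\code{.fastq}, optionally
#' \code{.gz}, read as FASTQ; anything else as FASTA). Qualities are
#' discarded: the algorithm is quality-agnostic.
#'
#' @param path path to the read file.
#' @return A named \code{DNAStringSet}.
#' @export
readLongReads <- function(path) {
    if (!file.exists(path))
        .stopf("read file not found: %s", path)
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
        "fastq" else "fasta"
    x <- Biostrings::readDNAStringSet(path, format = fmt)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        .stopf("duplicate read ids in %s", path)
    DNAStringSet(toupper(x))
}

#' Write an assembly to FASTA
#'
#' Records are written in input order, wrapped at 80 columns, so that
#' \code{readAssembly(writeAssembly(x))} round-trips the sequences exactly.
#'
#' @param assembly a named \code{DNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAssembly <- function(assembly, path) {
    if (length(assembly) == 0L)
        .stopf("refusing to write an empty assembly")
    Biostrings::writeXStringSet(assembly, filepath = path, width = 80L)
    invisible(path)
}

#' Discover gaps as maximal N runs
#'
#' Every maximal run of \code{N} of length at least \code{minGapLength} is
#' reported as a gap. Terminal runs (touching a scaffold end) are flagged:
#' they can only ever be closed from one side.
#'
#' @param assembly a named \code{DNAStringSet} (or a single scaffold as a
#'   length-1 set).
#' @param minGapLength minimum N-run length to report (default 1).
#' @return A \code{GRanges} (1-based, closed intervals) with metadata
#'   columns \code{terminal} (logical) and \code{L} (gap length).
#' @examples
#' asm <- Biostrings::DNAStringSet(c(s1 = "ACGTNNNNACGT"))
#' findGaps(asm)
#' @export
findGaps <- function(assembly, minGapLength = 1L) {
    stopifnot(minGapLength >= 1L)
    seqs <- as.character(assembly)
    ids <- names(assembly)
    if (is.null(ids))
        .stopf("assembly must be named")
    hits <- gregexpr("N+", seqs)
    res <- lapply(seq_along(seqs), function(i) {
        m <- hits[[i]]
        if (m[1] == -1L) return(NULL)
        st <- as.integer(m)
        w <- attr(m, "match.length")
        keep <- w >= minGapLength
        if (!any(keep)) return(NULL)
        st <- st[keep]; w <- w[keep]
        data.frame(scaffold = ids[i], start = st, end = st + w - 1L,
                   terminal = st == 1L | (st + w - 1L) == nchar(seqs[i]))
    })
    res <- do.call(rbind, res)
    if (is.null(res))
        return(GenomicRanges::GRanges(
            seqnames = character(), ranges = IRanges::IRanges(),
            terminal = logical(), L = integer()))
    gr <- GenomicRanges::GRanges(
        seqnames = res$scaffold,
        ranges = IRanges::IRanges(res$start, res$end))
    mcols(gr)$terminal <- res$terminal
    mcols(gr)$L <- res$end - res$start + 1L
    gr
}

#' Parse tag-to-scaffold alignments from SAM
#'
#' Reads a plain-text SAM file (both header sections required) of tag
#' alignments produced by an external aligner run on [writeTagsFasta()]
#' output. Secondary and supplementary records are kept as extra candidate
#' loci for multiplicity classification; unmapped records are dropped.
#'
#' The match base length is derived as (aligned \code{M/=/X} bases minus
#' mismatches), with mismatches taken from the \code{NM} tag as
#' \code{NM - inserted - deleted} bases, or counted from the \code{MD}
#' string when \code{NM} is absent. Records carrying neither are skipped
#' with a warning. The insert base length is the total of \code{I}
#' operations.
#'
#' @param path path to a SAM file.
#' @param tags the tag set the SAM was produced from (see [tileReads()]);
#'   used to recover read id, tag index and read offset from the query
#'   names.
#' @param scaffoldNames optional character vector of valid reference names;
#'   an alignment to any other name is an error.
#' @return A \code{data.frame} with one row per mapped record: columns
#'   \code{tag_id, read_id, index, p, tag_len, scaffold, pos, end_pos,
#'   strand, match_len, insert_len, aln_span, mapq}. \code{pos}/\code{end_pos}
#'   are the 1-based closed reference interval of the alignment;
#'   \code{p} is the 1-based offset of the tag in its read.
#' @export
readTagAlignments <- function(path, tags, scaffoldNames = NULL) {
    if (!file.exists(path))
        .stopf("SAM file not found: %s", path)
    bam <- Rsamtools::asBam(path,
        destination = tempfile(), overwrite = TRUE,
        indexDestination = FALSE)
    on.exit(unlink(bam), add = TRUE)
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
        tag = c("NM", "MD"))
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    flag <- b$flag
    mapped <- !bitwAnd(flag, 4L)
    if (!any(mapped)) return(.emptyAlignments())

    qname <- b$qname[mapped]
    rname <- as.character(b$rname)[mapped]
    pos <- b$pos[mapped]
    mapq <- b$mapq[mapped]
    cigar <- b$cigar[mapped]
    strand <- ifelse(bitwAnd(flag[mapped], 16L) > 0L, "-", "+")
    nm <- if (is.null(b$tag$NM)) rep(NA_integer_, sum(mapped))
          else b$tag$NM[mapped]
    md <- if (is.null(b$tag$MD)) rep(NA_character_, sum(mapped))
          else b$tag$MD[mapped]

    if (!is.null(scaffoldNames) && !all(rname %in% scaffoldNames))
        .stopf("alignment to unknown reference: %s",
               paste(unique(setdiff(rname, scaffoldNames)), collapse = ", "))

    mlen <- .cigarOpSum(cigar, c("M", "=", "X"))
    ilen <- .cigarOpSum(cigar, "I")
    dlen <- .cigarOpSum(cigar, c("D", "N"))

    mism <- rep(NA_real_, length(qname))
    hasNM <- !is.na(nm)
    mism[hasNM] <- nm[hasNM] - ilen[hasNM] - dlen[hasNM]
    needMD <- !hasNM & !is.na(md)
    if (any(needMD))
        mism[needMD] <- vapply(md[needMD], .mdSubstitutions, numeric(1))
    usable <- !is.na(mism)
    if (!all(usable))
        warning(sum(!usable),
                " SAM record(s) without NM or MD tag were skipped")

    tl <- .tagLookup(tags)
    idx <- match(qname, tl$tag_id)
    if (anyNA(idx[usable]))
        .stopf("SAM query names do not match the supplied tag set")

    keep <- usable
    data.frame(
        tag_id = qname[keep],
        read_id = tl$read_id[idx[keep]],
        index = tl$index[idx[keep]],
        p = tl$p[idx[keep]],
        tag_len = tl$tag_len[idx[keep]],
        scaffold = rname[keep],
        pos = pos[keep],
        end_pos = as.integer(pos[keep] + mlen[keep] + dlen[keep] - 1L),
        strand = strand[keep],
        match_len = pmax(mlen[keep] - mism[keep], 0),
        insert_len = ilen[keep],
        aln_span = mlen[keep] + dlen[keep],
        mapq = mapq[keep],
        stringsAsFactors = FALSE)
}

.emptyAlignments <- function() {
    data.frame(tag_id = character(), read_id = character(),
               index = integer(), p = integer(), tag_len = integer(),
               scaffold = character(), pos = integer(), end_pos = integer(),
               strand = character(), match_len = numeric(),
               insert_len = numeric(), aln_span = numeric(),
               mapq = integer(), stringsAsFactors = FALSE)
}

.tagLookup <- function(tags) {
    mc <- mcols(tags)
    data.frame(tag_id = names(tags),
               read_id = mc$read_id,
               index = mc$index,
               p = mc$p,
               tag_len = mc$tag_len,
               stringsAsFactors = FALSE)
}

#' Write the per-gap closure report as TSV
#'
#' A summary block (\code{# key<TAB>value} comment lines) precedes the
#' header: gaps closed, bases filled (gap N bases resolved) and contig N50
#' before and after closure. One data row per gap per iteration follows.
#'
#' @param report a report \code{data.frame} as held by a
#'   [GapCloserRun-class] (columns \code{scaffold_id, gap_start, gap_end,
#'   L_C, iteration, gap_type, status, fill_len, inserted_N,
#'   source_read_ids}).
#' @param path output path.
#' @param n50Before,n50After contig N50 of the assembly before/after the
#'   run.
#' @return \code{path}, invisibly.
#' @export
writeGapReport <- function(report, path, n50Before = NA, n50After = NA) {
    closed <- sum(report$status == "closed")
    filled <- sum(report$L_C[report$status != "open"] -
                  report$inserted_N[report$status != "open"])
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        sprintf("# gaps_closed\t%d", closed),
        sprintf("# bases_filled\t%d", as.integer(filled)),
        sprintf("# contig_N50_before\t%s", n50Before),
        sprintf("# contig_N50_after\t%s", n50After)), con)
    utils::write.table(report, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
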