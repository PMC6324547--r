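# Pluggable aligner contract.
#
# An aligner is a function(tags, assembly, param) returning the alignment
# data.frame of readTagAlignments(). Three modes are provided: a built-in
# exact-match aligner (adequate only for error-free fixtures), an external
# command (bwa mem, the field-standard choice for this task), and a
# precomputed SAM file.

#' Built-in exact-match test aligner
#'
#' Matches every tag (and its reverse complement) exactly against the
#' scaffolds with \code{Biostrings::matchPDict}. No mismatches or indels
#' are tolerated, so this mode is adequate only for error-free fixtures;
#' use [bwaAligner()] or a precomputed SAM for real reads. Every exact
#' locus is reported, so multi-mapping tags are classified correctly.
#'
#' @return An aligner function for [runGapCloser()].
#' @export
builtinAligner <- function() {
    function(tags, assembly, param) {
        if (length(tags) == 0L) return(.emptyAlignments())
        freq <- Biostrings::alphabetFrequency(tags, baseOnly = TRUE)
        clean <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE]) ==
            Biostrings::width(tags)
        tags <- tags[clean]
        if (length(tags) == 0L) return(.emptyAlignments())
        tl <- .tagLookup(tags)
        hits <- list()
        for (strand in c("+", "-")) {
            pd <- Biostrings::PDict(
                if (strand == "+") tags
                else reverseComplement(tags))
            for (sc in names(assembly)) {
                m <- Biostrings::matchPDict(pd, assembly[[sc]])
                st <- Biostrings::startIndex(m)
                nh <- lengths(st)
                if (sum(nh) == 0L) next
                i <- rep(seq_along(tags), nh)
                hits[[length(hits) + 1L]] <- data.frame(
                    tag_id = tl$tag_id[i], read_id = tl$read_id[i],
                    index = tl$index[i], p = tl$p[i],
                    tag_len = tl$tag_len[i], scaffold = sc,
                    pos = unlist(st, use.names = FALSE),
                    strand = strand, stringsAsFactors = FALSE)
            }
        }
        if (length(hits) == 0L) return(.emptyAlignments())
        out <- do.call(rbind, hits)
        out$end_pos <- out$pos + out$tag_len - 1L
        out$match_len <- as.numeric(out$tag_len)
        out$insert_len <- 0
        out$aln_span <- as.numeric(out$tag_len)
        out$mapq <- 60L
        out[, c("tag_id", "read_id", "index", "p", "tag_len", "scaffold",
                "pos", "end_pos", "strand", "match_len", "insert_len",
                "aln_span", "mapq")]
    }
}

#' External aligner via bwa mem
#'
#' Writes the tags and the current assembly to a temporary directory,
#' indexes the assembly and runs \code{bwa mem -a} (reporting all
#' alignments so multi-mapped tags keep their candidate loci), then parses
#' the SAM output. The \code{pacbio} preset tolerates the indel-rich error
#' profile of raw long reads.
#'
#' @param preset \code{"pacbio"} (default) or \code{"none"} for bwa's
#'   short-read defaults.
#' @param bwa path to the \code{bwa} executable.
#' @return An aligner function for [runGapCloser()].
#' @export
bwaAligner <- function(preset = c("pacbio", "none"), bwa = "bwa") {
    preset <- match.arg(preset)
    if (Sys.which(bwa) == "")
        .stopf("bwa executable not found on PATH")
    function(tags, assembly, param) {
        wd <- tempfile("bwa")
        dir.create(wd)
        on.exit(unlink(wd, recursive = TRUE), add = TRUE)
        asm <- file.path(wd, "assembly.fasta")
        tg <- file.path(wd, "tags.fasta")
        sam <- file.path(wd, "tags.sam")
        writeAssembly(assembly, asm)
        writeTagsFasta(tags, tg)
        st <- system2(bwa, c("index", asm), stdout = FALSE,
                      stderr = FALSE)
        if (st != 0L) .stopf("bwa index failed (exit %d)", st)
        args <- c("mem", "-a", "-t", as.character(param@threads))
        if (preset == "pacbio") args <- c(args, "-x", "pacbio")
        st <- system2(bwa, c(args, asm, tg), stdout = sam,
                      stderr = FALSE)
        if (st != 0L) .stopf("bwa mem failed (exit %d)", st)
        readTagAlignments(sam, tags, names(assembly))
    }
}

#' External aligner via an arbitrary command template
#'
#' The template must contain the placeholders \code{{tags.fasta}} and
#' \code{{assembly.fasta}}; it is run through \code{/bin/sh} and must print
#' SAM (with headers) on stdout.
#'
#' @param template command template string.
#' @return An aligner function for [runGapCloser()].
#' @export
commandAligner <- function(template) {
    stopifnot(grepl("{tags.fasta}", template, fixed = TRUE),
              grepl("{assembly.fasta}", template, fixed = TRUE))
    function(tags, assembly, param) {
        wd <- tempfile("aln")
        dir.create(wd)
        on.exit(unlink(wd, recursive = TRUE), add = TRUE)
        asm <- file.path(wd, "assembly.fasta")
        tg <- file.path(wd, "tags.fasta")
        sam <- file.path(wd, "tags.sam")
        writeAssembly(assembly, asm)
        writeTagsFasta(tags, tg)
        cmd <- gsub("{tags.fasta}", tg, template, fixed = TRUE)
        cmd <- gsub("{assembly.fasta}", asm, cmd, fixed = TRUE)
        st <- system2("/bin/sh", c("-c", shQuote(cmd)), stdout = sam)
        if (st != 0L) .stopf("aligner command failed (exit %d): %s", st,
                             template)
        readTagAlignments(sam, tags, names(assembly))
    }
}

#' Precomputed SAM as aligner
#'
#' Uses tag alignments computed outside the package. Because the file
#' cannot follow the assembly as it is edited, a pipeline run with this
#' mode performs a single iteration.
#'
#' @param path path to a SAM file of tag alignments.
#' @return An aligner function for [runGapCloser()].
#' @export
samAligner <- function(path) {
    if (!file.exists(path)) .stopf("SAM file not found: %s", path)
    f <- function(tags, assembly, param) {
        readTagAlignments(path, tags, names(assembly))
    }
    attr(f, "static") <- TRUE
    f
}
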