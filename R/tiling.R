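#' Fragment long reads into tiling paths of fixed-length tags
#'
#' Each read is cut into consecutive, non-overlapping tags of exactly
#' \code{tagLength} bases starting at its first base; the trailing remainder
#' shorter than one tag is discarded so that every tag has the same length
#' (the coverage formula's denominator assumes this). Reads shorter than
#' \code{tagLength} contribute no tags and are ignored downstream.
#'
#' @param reads a named \code{DNAStringSet} of long reads.
#' @param tagLength tag length in bases (>= 50; default 300).
#' @return A \code{DNAStringSet} of tags named \code{"<read_id>#<index>"}
#'   (index is 1-based along the read), with metadata columns
#'   \code{read_id}, \code{index}, \code{p} (1-based offset of the tag in
#'   its read) and \code{tag_len}.
#' @examples
#' reads <- Biostrings::DNAStringSet(c(r1 = paste(rep("ACGT", 250),
#'                                     collapse = "")))
#' tags <- tileReads(reads, 300)
#' length(tags)  # floor(1000 / 300) = 3
#' @export
tileReads <- function(reads, tagLength = 300L) {
    tagLength <- as.integer(tagLength)
    if (is.na(tagLength) || tagLength <= 0L)
        .stopf("tagLength must be a positive integer")
    if (tagLength < 50L)
        .stopf("tagLength must be >= 50")
    if (is.null(names(reads)))
        .stopf("reads must be named")
    n <- Biostrings::width(reads) %/% tagLength
    keep <- n > 0L
    reads <- reads[keep]
    n <- n[keep]
    if (length(reads) == 0L) {
        out <- DNAStringSet()
        mcols(out) <- DataFrame(read_id = character(), index = integer(),
                                p = integer(), tag_len = integer())
        return(out)
    }
    read_id <- rep(names(reads), n)
    index <- unlist(lapply(n, seq_len), use.names = FALSE)
    p <- (index - 1L) * tagLength + 1L
    out <- Biostrings::subseq(rep(reads, n), start = p,
                              width = tagLength)
    names(out) <- paste0(read_id, "#", index)
    mcols(out) <- DataFrame(read_id = read_id, index = index, p = p,
                            tag_len = tagLength)
    out
}

#' Write tags to FASTA for an external aligner
#'
#' Tag ids follow the \code{"<read_id>#<index>"} scheme, which
#' [readTagAlignments()] parses back. Read ids must therefore not contain
#' \code{"#"}.
#'
#' @param tags output of [tileReads()].
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeTagsFasta <- function(tags, path) {
    Biostrings::writeXStringSet(tags, filepath = path, width = 80L)
    invisible(path)
}
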