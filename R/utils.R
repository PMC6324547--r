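# Internal helpers shared across modules.

#' @importFrom Biostrings DNAStringSet reverseComplement letterFrequency
NULL

# Total number of bases under the given CIGAR operations, per record.
.cigarOpSum <- function(cigar, ops) {
    opl <- GenomicAlignments::explodeCigarOpLengths(cigar, ops = ops)
    vapply(opl, function(x) sum(as.numeric(x)), numeric(1))
}

# Reverse complement of plain character vectors.
.revComp <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

.countN <- function(x) {
    sum(letterFrequency(DNAStringSet(x), "N"))
}

# Substitutions in an MD tag: mismatch letters outside ^-prefixed deletions.
.mdSubstitutions <- function(md) {
    toks <- regmatches(md, gregexpr("\\^[A-Z]+|[A-Z]|[0-9]+", md))[[1]]
    sum(grepl("^[A-Z]$", toks))
}

# Deterministic sub-seed derivation (kept well below 2^31).
.subSeed <- function(seed, k) {
    (as.integer(seed) * 1009L + as.integer(k) * 9176L) %% 2147483L + 1L
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
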