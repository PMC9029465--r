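#' Read a FASTA file of nucleotide sequences
#'
#' Thin validating wrapper around [Biostrings::readDNAStringSet()].
#' Residues are uppercased (soft-masking is ignored) and restricted to
#' the alphabet {A, C, G, T, N}: any other character, an empty file, or
#' duplicated record identifiers raise an error naming the offending
#' record.
#'
#' @param path path to a (multi-record) FASTA file, wrapped or not.
#' @return A `DNAStringSet`, one element per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgtg"), fa)
#' readFastaDNA(fa)
#' @export
readFastaDNA <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    # read as raw strings first so an illegal character can be blamed on
    # its record rather than failing deep inside the DNA alphabet check
    raw <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
        error = function(e) stop("cannot parse FASTA '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (length(raw) == 0L)
        stop("FASTA file '", path, "' contains no records")
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids))
        stop("duplicate FASTA identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    txt <- toupper(as.character(raw))
    for (k in seq_along(txt)) {
        bad <- unique(strsplit(gsub("[ACGTN]", "", txt[k]), "")[[1]])
        if (length(bad))
            stop("record '", ids[k], "' contains base(s) outside the ",
                 "{A,C,G,T,N} alphabet: ", paste(bad, collapse = ", "))
    }
    set <- Biostrings::DNAStringSet(txt)
    names(set) <- ids
    set
}

.asDNAString <- function(x) {
    if (is(x, "DNAString")) return(x)
    if (is(x, "DNAStringSet")) {
        if (length(x) != 1L)
            stop("expected a single sequence, got ", length(x), " records")
        return(x[[1L]])
    }
    Biostrings::DNAString(toupper(as.character(x)))
}

#' Convert an absolute genomic position to a TSS-relative coordinate
#'
#' The TSS-relative axis is zero-free: the TSS base itself is +1, the
#' base immediately upstream is -1, and 0 is never produced.  Downstream
#' means "in the direction of transcription", so on the minus strand
#' downstream positions have *smaller* absolute coordinates than the TSS.
#'
#' With a minus-strand TSS at `t`: `rel = t - pos + 1` for `pos <= t`
#' (downstream) and `rel = t - pos` for `pos > t` (upstream).  With a
#' plus-strand TSS: `rel = pos - t + 1` downstream, `pos - t` upstream.
#'
#' @param position 1-based absolute coordinate(s), `>= 1`.  Vectorized.
#' @param tss a [StrandedLocus-class] (or [TssAnnotation-class]).
#' @return Integer TSS-relative coordinate(s); never 0.
#' @examples
#' tss <- strandedLocus("chr8", 27230845, "-")
#' absToRel(27226612, tss)   # +4234
#' absToRel(27237610, tss)   # -6765
#' absToRel(27230845, tss)   # +1 (the TSS base)
#' @seealso [relToAbs()] for the exact inverse.
#' @export
absToRel <- function(position, tss) {
    stopifnot(is(tss, "StrandedLocus"))
    position <- as.integer(position)
    if (any(is.na(position)) || any(position < 1L))
        stop("position must be >= 1")
    t <- tss@position
    if (tss@strand == "-")
        ifelse(position <= t, t - position + 1L, t - position)
    else
        ifelse(position >= t, position - t + 1L, position - t)
}

#' Convert a TSS-relative coordinate back to an absolute position
#'
#' Exact inverse of [absToRel()] for the same TSS.  `rel = 0` is a
#' contract violation on the zero-free axis and raises an error.
#'
#' @param rel nonzero TSS-relative coordinate(s).  Vectorized.
#' @param tss a [StrandedLocus-class].
#' @return Integer 1-based absolute coordinate(s).
#' @examples
#' tss <- strandedLocus("chr8", 27230845, "-")
#' relToAbs(4234, tss)    # 27226612
#' relToAbs(-6765, tss)   # 27237610
#' @export
relToAbs <- function(rel, tss) {
    stopifnot(is(tss, "StrandedLocus"))
    rel <- as.integer(rel)
    if (any(is.na(rel)) || any(rel == 0L))
        stop("rel must be a nonzero integer (no 0 exists on the TSS axis)")
    t <- tss@position
    if (tss@strand == "-")
        ifelse(rel > 0L, t - rel + 1L, t - rel)
    else
        ifelse(rel > 0L, t + rel - 1L, t + rel)
}

#' Extract a gene-sense analysis window around a TSS
#'
#' Slices the genome record over the TSS-relative window and returns the
#' sequence reading 5'->3' along the gene: for a minus-strand TSS this is
#' the reverse complement of the plus-strand slice.  Local base 1
#' corresponds to TSS-relative position `upstream(window)`; the window
#' spans `|upstream| + downstream` bases (no zero position exists).
#'
#' @param genome a `DNAString` (or single-record `DNAStringSet` or
#'   character) whose first base is absolute position 1.
#' @param tss a [StrandedLocus-class].
#' @param window an [AnalysisWindow-class].
#' @return A [WindowSequence-class] carrying the sequence and the
#'   local-to-genomic coordinate maps ([relPositions()], [absPositions()]).
#' @examples
#' g <- Biostrings::DNAString(paste(rep("ACGT", 30), collapse = ""))
#' ws <- extractWindow(g, strandedLocus("chrS", 51, "+"), analysisWindow(-10, 10))
#' length(windowSeq(ws))  # 20
#' @export
extractWindow <- function(genome, tss, window) {
    stopifnot(is(tss, "StrandedLocus"), is(window, "AnalysisWindow"))
    genome <- .asDNAString(genome)
    ends <- relToAbs(c(window@upstream, window@downstream), tss)
    lo <- min(ends); hi <- max(ends)
    if (lo < 1L || hi > length(genome))
        stop(sprintf(
            "window [%d..%d] exceeds the genome record (1..%d): overhang %d bp at the %s end",
            lo, hi, length(genome),
            max(0L, 1L - lo, hi - length(genome)),
            if (lo < 1L) "low" else "high"))
    slice <- Biostrings::subseq(genome, lo, hi)
    if (tss@strand == "-")
        slice <- Biostrings::reverseComplement(slice)
    new("WindowSequence", seq = slice, tss = .asLocus(tss), window = window)
}

# drop TssAnnotation extras so WindowSequence slots stay minimal
.asLocus <- function(tss) {
    if (is(tss, "TssAnnotation"))
        strandedLocus(tss@chrom, tss@position, tss@strand)
    else tss
}
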