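#' Map a transcription start site from an mRNA 5' anchor
#'
#' Locates the TSS on a genomic record by searching both strands for the
#' first `anchorLength` bases of the mRNA, allowing up to `maxMismatches`
#' mismatches.  The TSS is the genomic base pairing the mRNA's first
#' nucleotide; on the minus strand that is the highest absolute
#' coordinate of the placement.  This deterministic anchor search stands
#' in for an interactive full-transcript DNA/RNA alignment: the TSS is
#' defined solely by the transcript's first base, so aligning exons and
#' introns downstream of it adds nothing.
#'
#' Exactly one placement must exist: zero placements raise a "no anchor"
#' error and multiple placements raise an ambiguity error listing all of
#' them, because a single-position TSS claim presumes uniqueness.
#'
#' @param genome a `DNAString`/`DNAStringSet`/character genomic record
#'   (absolute position 1 = first base).
#' @param mrna the transcript sequence (same types accepted); only its
#'   first `anchorLength` bases are used.
#' @param anchorLength 5' anchor size in bases (default 30, a practical
#'   balance between placement uniqueness and 5'-end sequencing noise).
#' @param maxMismatches mismatch tolerance (default 0).
#' @param chrom chromosome label recorded in the annotation.
#' @return A [TssAnnotation-class].
#' @examples
#' sim <- simulateLocus(seed = 1, length = 3000, tssPosition = 1500,
#'                      strand = "+")
#' mr <- simulateMrna(sim$genome, sim$tss, exonLengths = 200)
#' mapTss(sim$genome, mr)
#' @export
mapTss <- function(genome, mrna, anchorLength = 30L, maxMismatches = 0L,
                   chrom = "chr") {
    genome <- .asDNAString(genome)
    mrnaName <- if (is(mrna, "DNAStringSet") && !is.null(names(mrna)))
        names(mrna)[1L] else "mrna"
    mrna <- .asDNAString(mrna)
    anchorLength <- as.integer(anchorLength)
    if (length(mrna) < anchorLength)
        stop("mRNA (", length(mrna), " nt) is shorter than the anchor (",
             anchorLength, " nt)")
    if (length(genome) < anchorLength)
        stop("genome record is shorter than the anchor")
    anchor <- Biostrings::subseq(mrna, 1L, anchorLength)

    fwd <- Biostrings::matchPattern(anchor, genome,
                                    max.mismatch = maxMismatches)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(anchor),
                                    genome, max.mismatch = maxMismatches)
    hits <- rbind(
        if (length(fwd)) data.frame(pos = BiocGenerics::start(fwd),
                                    strand = "+"),
        if (length(rev)) data.frame(pos = BiocGenerics::end(rev),
                                    strand = "-"))
    if (is.null(hits) || nrow(hits) == 0L)
        stop("no anchor: the mRNA 5' anchor (", anchorLength,
             " nt, <=", maxMismatches, " mismatches) was not found on ",
             "either strand")
    if (nrow(hits) > 1L)
        stop("ambiguous TSS: ", nrow(hits), " anchor placements found (",
             paste(sprintf("%s:%d:%s", chrom, hits$pos, hits$strand),
                   collapse = ", "), ")")

    mm <- .countMismatches(genome, anchor, hits$pos, hits$strand)
    new("TssAnnotation", chrom = chrom, position = as.integer(hits$pos),
        strand = hits$strand, sourceMrna = mrnaName,
        anchorLength = anchorLength, mismatches = mm)
}

.countMismatches <- function(genome, anchor, pos, strand) {
    w <- length(anchor)
    if (strand == "+") {
        seen <- Biostrings::subseq(genome, pos, pos + w - 1L)
    } else {
        seen <- Biostrings::reverseComplement(
            Biostrings::subseq(genome, pos - w + 1L, pos))
    }
    sum(strsplit(as.character(seen), "")[[1]] !=
        strsplit(as.character(anchor), "")[[1]])
}
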