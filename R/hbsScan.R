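#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Find occurrences of the HIF-binding-site core motif
#'
#' Scans a sequence for the conserved HBS core `ACGTG` (optionally the
#' relaxed `RCGTG`, i.e. allowing a G at the A0 position).  Matching is
#' exact for `ACGTG`; in `RCGTG` mode the IUPAC code in the pattern is
#' interpreted while the subject stays literal, so `N` in the sequence
#' never matches any motif position.
#'
#' Offsets are 1-based positions of the core's A0 base on the scanned
#' (sense) strand.  With `scanAntisense = TRUE`, occurrences of the core
#' on the reverse strand are also reported, at the offset of the sense
#' base that pairs the core's A0.
#'
#' @param seq `DNAString`/`DNAStringSet`/character to scan.
#' @param core `"ACGTG"` (default) or `"RCGTG"`.
#' @param scanAntisense also scan the reverse strand (default `FALSE`).
#' @return data.frame with columns `offset` (1-based A0 position) and
#'   `strand` (`"sense"`/`"antisense"`), ordered 5'->3'.
#' @examples
#' findCores("GAACGTGCCTGGC")       # one sense hit, A0 at position 3
#' findCores("ACGTGACGTG")          # A0 at 1 and 6; ACGTG cannot self-overlap
#' @export
findCores <- function(seq, core = "ACGTG", scanAntisense = FALSE) {
    seq <- .asDNAString(seq)
    core <- match.arg(toupper(core), c("ACGTG", "RCGTG"))
    pat <- Biostrings::DNAString(core)
    fixed <- if (core == "ACGTG") TRUE else "subject"
    hits <- data.frame(offset = integer(0), strand = character(0))
    f <- Biostrings::matchPattern(pat, seq, fixed = fixed)
    if (length(f))
        hits <- rbind(hits, data.frame(offset = BiocGenerics::start(f),
                                       strand = "sense"))
    if (isTRUE(scanAntisense)) {
        r <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                      seq, fixed = fixed)
        if (length(r))
            hits <- rbind(hits, data.frame(offset = BiocGenerics::end(r),
                                           strand = "antisense"))
    }
    hits[order(hits$offset, hits$strand == "antisense"), , drop = FALSE]
}

#' Annotate the G(-2)/C(+5) flanks of a core hit
#'
#' For a hit returned by [findCores()], records the bases at positions -2
#' and +5 relative to the core's A0 (in match orientation: for an
#' antisense hit the flanks are read on the reverse strand).  A flank
#' that falls outside the sequence is `NA` ("unknown") and sets the
#' low-context flag; unknown flanks count as absent when classifying.
#'
#' @param seq the scanned sequence.
#' @param offset 1-based A0 position (from [findCores()]).
#' @param strand `"sense"` or `"antisense"`.
#' @return One-row data.frame: `offset`, `strand`, `core` (matched 5-mer
#'   in match orientation), `flankMinus2`, `flankPlus5`, `hasGMinus2`,
#'   `hasCPlus5`, `confidence`, `lowContext`.
#' @examples
#' annotateFlanks("GAACGTGCCTGGC", 3, "sense")   # G(-2) and C(+5): HIGH
#' annotateFlanks("ACGTGC", 1, "sense")          # -2 flank unknown
#' @export
annotateFlanks <- function(seq, offset, strand = "sense") {
    seq <- .asDNAString(seq)
    offset <- as.integer(offset)
    chars <- strsplit(as.character(seq), "")[[1]]
    baseAt <- function(i) if (i >= 1L && i <= length(chars)) chars[i]
                          else NA_character_
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    if (strand == "sense") {
        coreSeq <- paste(chars[offset:(offset + 4L)], collapse = "")
        fm2 <- baseAt(offset - 2L)
        fp5 <- baseAt(offset + 5L)
    } else {
        coreSeq <- as.character(Biostrings::reverseComplement(
            Biostrings::subseq(seq, offset - 4L, offset)))
        fm2 <- unname(comp[baseAt(offset + 2L)])
        fp5 <- unname(comp[baseAt(offset - 5L)])
    }
    hasG <- !is.na(fm2) & fm2 == "G"
    hasC <- !is.na(fp5) & fp5 == "C"
    data.frame(offset = offset, strand = strand, core = coreSeq,
               flankMinus2 = fm2, flankPlus5 = fp5,
               hasGMinus2 = hasG, hasCPlus5 = hasC,
               confidence = classifyConfidence(hasG, hasC),
               lowContext = is.na(fm2) | is.na(fp5))
}

#' Classify HBS confidence from the flanking-nucleotide rule
#'
#' A candidate is `HIGH` probability when it carries the G(-2) and/or the
#' C(+5) flanking nucleotide (inclusive OR); otherwise it is `CORE_ONLY`.
#' `NA` (unknown) flanks count as absent.
#'
#' @param hasGMinus2,hasCPlus5 logical vectors.
#' @return Character vector, `"HIGH"` or `"CORE_ONLY"`.
#' @examples
#' classifyConfidence(TRUE, FALSE)   # "HIGH"
#' classifyConfidence(FALSE, FALSE)  # "CORE_ONLY"
#' @export
classifyConfidence <- function(hasGMinus2, hasCPlus5) {
    ifelse(isTRUE2(hasGMinus2) | isTRUE2(hasCPlus5), "HIGH", "CORE_ONLY")
}

isTRUE2 <- function(x) !is.na(x) & x

#' Scan a TSS-relative window for candidate HIF-binding sites
#'
#' Composes [extractWindow()] -> [findCores()] -> [annotateFlanks()] and
#' resolves each hit to TSS-relative and absolute genomic coordinates.
#' Candidates are labelled `#1, #2, ...` in 5'->3' window order and
#' tagged `UPSTREAM` (relative position <= -1) or `INTRAGENIC`.  By
#' default only the gene-sense strand of the window is scanned;
#' `scanAntisense = TRUE` adds reverse-strand occurrences.
#'
#' @param genome genomic record (`DNAString` etc., position 1 = abs 1).
#' @param tss a [StrandedLocus-class] or [TssAnnotation-class].
#' @param window an [AnalysisWindow-class].
#' @param scanAntisense scan both strands of the window (default `FALSE`).
#' @param core `"ACGTG"` (default) or `"RCGTG"`.
#' @return A `GRanges`, one range per candidate spanning the 5 matched
#'   genomic bases (strand = genomic strand of the match), with metadata
#'   columns `label`, `core`, `relPosition` (of the A0 base),
#'   `absPosition`, `flankMinus2`, `flankPlus5`, `hasGMinus2`,
#'   `hasCPlus5`, `confidence`, `location`, `lowContext`.
#' @examples
#' sim <- simulateLocus(seed = 2, length = 4000, tssPosition = 2000,
#'     strand = "-", planted = data.frame(rel = -500, gMinus2 = TRUE,
#'     cPlus5 = FALSE), window = analysisWindow(-1000, 1000))
#' scanRegion(sim$genome, sim$tss, sim$window)
#' @export
scanRegion <- function(genome, tss, window, scanAntisense = FALSE,
                       core = "ACGTG") {
    ws <- extractWindow(genome, tss, window)
    hits <- findCores(windowSeq(ws), core = core,
                      scanAntisense = scanAntisense)
    chrom <- ws@tss@chrom
    if (nrow(hits) == 0L)
        return(.emptyCandidates(chrom))
    ann <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i)
        annotateFlanks(windowSeq(ws), hits$offset[i], hits$strand[i])))
    rel <- relPositions(ws)[ann$offset]
    abs <- absPositions(ws)[ann$offset]
    geneStrand <- ws@tss@strand
    gStrand <- ifelse(ann$strand == "sense", geneStrand,
                      ifelse(geneStrand == "+", "-", "+"))
    start <- ifelse(gStrand == "+", abs, abs - 4L)
    end <- ifelse(gStrand == "+", abs + 4L, abs)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = gStrand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        label = paste0("#", seq_len(nrow(ann))),
        core = ann$core,
        relPosition = as.integer(rel),
        absPosition = as.integer(abs),
        flankMinus2 = ann$flankMinus2,
        flankPlus5 = ann$flankPlus5,
        hasGMinus2 = ann$hasGMinus2,
        hasCPlus5 = ann$hasCPlus5,
        confidence = ann$confidence,
        location = ifelse(rel <= -1L, "UPSTREAM", "INTRAGENIC"),
        lowContext = ann$lowContext)
    gr
}

.emptyCandidates <- function(chrom) {
    gr <- GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                                 strand = character(0))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        label = character(0), core = character(0),
        relPosition = integer(0), absPosition = integer(0),
        flankMinus2 = character(0), flankPlus5 = character(0),
        hasGMinus2 = logical(0), hasCPlus5 = logical(0),
        confidence = character(0), location = character(0),
        lowContext = logical(0))
    gr
}

#' Export HBS candidates to BED6, GFF3 or CSV
#'
#' BED6 uses 0-based half-open absolute coordinates over the 5 core bases
#' (candidate label and confidence in the name column, confidence also
#' encoded in the score: HIGH = 1000, CORE_ONLY = 500); GFF3 is 1-based
#' inclusive; CSV mirrors every candidate field and round-trips through
#' [readCandidates()].
#'
#' @param candidates a `GRanges` from [scanRegion()].
#' @param path output file path.
#' @param format `"csv"`, `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
exportCandidates <- function(candidates, path,
                             format = c("csv", "bed", "gff3")) {
    format <- match.arg(format)
    if (format == "csv") {
        df <- as.data.frame(candidates)
        utils::write.csv(df, path, row.names = FALSE)
    } else {
        gr <- candidates
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            name = paste0(sub("^#", "HBS", candidates$label), "_",
                          candidates$confidence),
            score = ifelse(candidates$confidence == "HIGH", 1000L, 500L))
        if (format == "gff3") {
            gr$type <- "protein_binding_site"
            gr$source <- "HBStools"
            gr$relPosition <- candidates$relPosition
            gr$confidence <- candidates$confidence
        }
        rtracklayer::export(gr, path,
                            format = if (format == "bed") "BED" else "GFF3")
    }
    invisible(path)
}

#' Read candidates back from a CSV written by [exportCandidates()]
#'
#' @param path CSV file path.
#' @return A `GRanges` equal (field by field) to the exported one.
#' @export
readCandidates <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df$seqnames,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    keep <- setdiff(names(df), c("seqnames", "start", "end", "width",
                                 "strand"))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[keep])
    gr
}
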