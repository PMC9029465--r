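#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importFrom BiocGenerics start end
NULL

.validStrand <- function(s) s %in% c("+", "-")

#' StrandedLocus: a single 1-based genomic position with strand
#'
#' A minimal strand-aware point locus, used to anchor the TSS-relative
#' coordinate axis.  Positions are 1-based and inclusive throughout the
#' package; conversion to 0-based half-open happens only at BED export.
#'
#' @slot chrom chromosome label, e.g. `"chr8"`
#' @slot position 1-based absolute coordinate (bp), `>= 1`
#' @slot strand `"+"` or `"-"`
#'
#' @seealso [strandedLocus()], [absToRel()], [relToAbs()]
#' @export
setClass("StrandedLocus",
    slots = c(chrom = "character", position = "integer", strand = "character"))

setValidity("StrandedLocus", function(object) {
    msg <- NULL
    if (length(object@position) != 1L || is.na(object@position) ||
        object@position < 1L)
        msg <- c(msg, "position must be a single integer >= 1")
    if (length(object@strand) != 1L || !.validStrand(object@strand))
        msg <- c(msg, "strand must be \"+\" or \"-\"")
    if (length(object@chrom) != 1L || is.na(object@chrom))
        msg <- c(msg, "chrom must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' Construct a StrandedLocus
#'
#' @param chrom chromosome label.
#' @param position 1-based absolute coordinate (bp).
#' @param strand `"+"`/`"-"` (also accepts `"plus"`/`"minus"`).
#' @return A [StrandedLocus-class] object.
#' @examples
#' tss <- strandedLocus("chr8", 27230845, "-")
#' @export
strandedLocus <- function(chrom, position, strand) {
    strand <- switch(as.character(strand),
        plus = "+", minus = "-", as.character(strand))
    new("StrandedLocus", chrom = as.character(chrom),
        position = as.integer(position), strand = strand)
}

#' TssAnnotation: a mapped transcription start site
#'
#' Extends [StrandedLocus-class] with provenance from the mRNA 5'-anchor
#' search that produced it: which transcript defined the TSS, how many
#' bases of its 5' end were used as the anchor, and how many mismatches
#' the unique placement carried.
#'
#' @slot sourceMrna identifier of the mRNA whose 5' end defines the TSS
#' @slot anchorLength number of 5' bases used as the search anchor
#' @slot mismatches mismatch count of the accepted placement
#' @seealso [mapTss()]
#' @export
setClass("TssAnnotation", contains = "StrandedLocus",
    slots = c(sourceMrna = "character", anchorLength = "integer",
              mismatches = "integer"))

setValidity("TssAnnotation", function(object) {
    if (length(object@mismatches) == 1L && !is.na(object@mismatches) &&
        object@mismatches < 0L) "mismatches must be >= 0" else TRUE
})

#' AnalysisWindow: TSS-relative scan bounds
#'
#' The zero-free TSS-relative axis puts the TSS base at +1 and the base
#' immediately upstream at -1; position 0 does not exist.  A window is
#' therefore a pair (upstream, downstream) with upstream <= -1 and
#' downstream >= +1, spanning |upstream| + downstream bases.
#'
#' @slot upstream negative TSS-relative bound (bp), e.g. -6765
#' @slot downstream positive TSS-relative bound (bp), e.g. +4234
#' @seealso [analysisWindow()], [extractWindow()]
#' @export
setClass("AnalysisWindow",
    slots = c(upstream = "integer", downstream = "integer"))

setValidity("AnalysisWindow", function(object) {
    msg <- NULL
    if (object@upstream > -1L) msg <- c(msg, "upstream must be <= -1")
    if (object@downstream < 1L) msg <- c(msg, "downstream must be >= +1")
    if (is.null(msg)) TRUE else msg
})

#' Construct an AnalysisWindow
#'
#' @param upstream negative TSS-relative bound (bp).
#' @param downstream positive TSS-relative bound (bp).
#' @return An [AnalysisWindow-class] object.
#' @examples
#' analysisWindow(-6765, 4234)
#' @export
analysisWindow <- function(upstream, downstream) {
    new("AnalysisWindow", upstream = as.integer(upstream),
        downstream = as.integer(downstream))
}

#' WindowSequence: an extracted gene-sense analysis window
#'
#' The result of [extractWindow()]: the window sequence read 5'->3' along
#' the gene (for a minus-strand TSS this is the reverse complement of the
#' plus-strand slice) together with the mapping from each local base to
#' its TSS-relative and absolute genomic coordinate.
#'
#' @slot seq the window sequence (gene-sense `DNAString`)
#' @slot tss the anchoring [StrandedLocus-class]
#' @slot window the [AnalysisWindow-class] that was extracted
#' @seealso [windowSeq()], [relPositions()], [absPositions()]
#' @export
setClass("WindowSequence",
    slots = c(seq = "DNAString", tss = "StrandedLocus",
              window = "AnalysisWindow"))

#' Trajectory: multi-frame coordinates over a fixed atom table
#'
#' An ordered set of coordinate frames (nm) over an immutable atom table.
#' Each atom carries a moiety tag derived deterministically from its
#' residue name: standard amino-acid three-letter codes map to PROTEIN,
#' DA/DC/DG/DT/DN to DNA, anything else to OTHER.
#'
#' @slot atoms data.frame with columns `atom_name`, `residue_name`,
#'   `residue_index`, `chain`, `moiety`
#' @slot coords numeric array `[atoms, 3, frames]`, coordinates in nm
#' @slot frameSpacing time per frame in ns (`NA` if unknown)
#' @seealso [readStructure()], [countContacts()], [calcRMSD()], [calcRMSF()]
#' @export
setClass("Trajectory",
    slots = c(atoms = "data.frame", coords = "array",
              frameSpacing = "numeric"))

setValidity("Trajectory", function(object) {
    msg <- NULL
    need <- c("atom_name", "residue_name", "residue_index", "chain", "moiety")
    if (!all(need %in% names(object@atoms)))
        msg <- c(msg, paste("atom table must have columns:",
                            paste(need, collapse = ", ")))
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
        msg <- c(msg, "coords must be an [atoms, 3, frames] array")
    else if (d[1] != nrow(object@atoms))
        msg <- c(msg, "coords rows must match the atom table")
    if (is.null(msg)) TRUE else msg
})

#' ContactSeries: per-frame contact counts with a trailing-window mean
#'
#' @slot counts per-frame atom-pair contact counts
#' @slot windowMean arithmetic mean over the trailing window
#' @slot window number of trailing frames averaged
#' @seealso [contactSeries()]
#' @export
setClass("ContactSeries",
    slots = c(counts = "numeric", windowMean = "numeric", window = "integer"))

setMethod("show", "StrandedLocus", function(object) {
    cat(sprintf("%s locus %s:%d:%s\n", class(object), object@chrom,
                object@position, object@strand))
    if (is(object, "TssAnnotation"))
        cat(sprintf("  TSS from mRNA '%s' (anchor %d bp, %d mismatch%s)\n",
                    object@sourceMrna, object@anchorLength,
                    object@mismatches,
                    if (object@mismatches == 1L) "" else "es"))
})

setMethod("show", "AnalysisWindow", function(object) {
    cat(sprintf("AnalysisWindow %+d..%+d (%d bp, zero-free TSS axis)\n",
                object@upstream, object@downstream,
                -object@upstream + object@downstream))
})

setMethod("show", "WindowSequence", function(object) {
    cat(sprintf("WindowSequence: %d bp gene-sense window %+d..%+d around %s:%d:%s\n",
                length(object@seq), object@window@upstream,
                object@window@downstream, object@tss@chrom,
                object@tss@position, object@tss@strand))
})

setMethod("show", "Trajectory", function(object) {
    mo <- table(object@atoms$moiety)
    cat(sprintf("Trajectory: %d atoms x %d frames (%s)%s\n",
                nrow(object@atoms), dim(object@coords)[3],
                paste(sprintf("%s=%d", names(mo), as.integer(mo)),
                      collapse = ", "),
                if (is.na(object@frameSpacing)) ""
                else sprintf(", %.3g ns/frame", object@frameSpacing)))
})

setMethod("show", "ContactSeries", function(object) {
    cat(sprintf("ContactSeries: %d frames, mean over last %d = %.6g\n",
                length(object@counts), object@window, object@windowMean))
})

# ---- accessors ----

#' Accessors for package classes
#'
#' `windowSeq`, `relPositions` and `absPositions` expose a
#' [WindowSequence-class]; `atomTable`, `nFrames`, `nAtoms` and
#' `frameCoords` expose a [Trajectory-class]; `contactCounts` and
#' `contactWindowMean` expose a [ContactSeries-class].
#'
#' @param x an object of the documented class.
#' @param i frame index for `frameCoords`.
#' @return `windowSeq`: a `DNAString`; `relPositions`/`absPositions`:
#'   integer vectors parallel to the window bases; `frameCoords`: an
#'   `[atoms, 3]` coordinate matrix in nm; the others: as named.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("windowSeq", function(x) standardGeneric("windowSeq"))
#' @rdname accessors
#' @export
setMethod("windowSeq", "WindowSequence", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("relPositions", function(x) standardGeneric("relPositions"))
#' @rdname accessors
#' @export
setMethod("relPositions", "WindowSequence", function(x) {
    u <- -x@window@upstream
    i <- seq_len(length(x@seq))
    as.integer(ifelse(i <= u, i - u - 1L, i - u))
})

#' @rdname accessors
#' @export
setGeneric("absPositions", function(x) standardGeneric("absPositions"))
#' @rdname accessors
#' @export
setMethod("absPositions", "WindowSequence", function(x)
    relToAbs(relPositions(x), x@tss))

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "Trajectory", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
    stopifnot(length(i) == 1L, i >= 1L, i <= dim(x@coords)[3])
    m <- x@coords[, , i, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    m
})

#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @rdname accessors
#' @export
setMethod("contactCounts", "ContactSeries", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("contactWindowMean", function(x) standardGeneric("contactWindowMean"))
#' @rdname accessors
#' @export
setMethod("contactWindowMean", "ContactSeries", function(x) x@windowMean)
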