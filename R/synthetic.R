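# run expr with a local, fully restored RNG state: generators never
# disturb (or depend on) the caller's random stream
.withSeed <- function(seed, expr) {
    glob <- globalenv()
    had <- exists(".Random.seed", envir = glob, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = glob) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = glob)
        else if (exists(".Random.seed", envir = glob, inherits = FALSE))
            rm(".Random.seed", envir = glob)
    })
    set.seed(seed)
    force(expr)
}

.senseIndex <- function(rel, tssIdx) {
    rel <- as.integer(rel)
    ifelse(rel > 0L, tssIdx + rel - 1L, tssIdx + rel)
}

#' Simulate a genomic locus with planted HBS cores and known truth
#'
#' Generates a uniform-composition random genome containing a TSS on the
#' chosen strand and plants `ACGTG` cores at the requested TSS-relative
#' positions with controlled G(-2)/C(+5) flanks.  Any accidental `ACGTG`
#' occurrence outside the planted sites (on the gene-sense strand, the
#' strand the default scan reads) is destroyed by single-base
#' substitution, so [scanRegion()] recovers exactly the planted
#' candidates.  Identical seed and parameters give a byte-identical
#' genome.
#'
#' @param seed integer RNG seed; all randomness flows from it.
#' @param length genome length in bp.
#' @param tssPosition TSS position in gene-sense coordinates (bases from
#'   the gene-sense 5' end; on the minus strand the absolute coordinate
#'   becomes `length - tssPosition + 1`).
#' @param strand `"+"` or `"-"` gene strand.
#' @param planted data.frame with columns `rel` (TSS-relative A0
#'   position, nonzero), `gMinus2`, `cPlus5` (logical flank choices), or
#'   `NULL` for no plants.  Core starts must be pairwise >= 8 bp apart
#'   and the 5 core bases inside `window`.
#' @param window an [AnalysisWindow-class] the plants must fit in.
#' @param chrom chromosome label for the generated record.
#' @return list with `genome` (named `DNAStringSet`), `tss`
#'   ([StrandedLocus-class]), `window`, and `truth` (data.frame `rel`,
#'   `gMinus2`, `cPlus5`, `confidence`, `location`).
#' @examples
#' sim <- simulateLocus(seed = 7, planted = data.frame(
#'     rel = c(-500, 120), gMinus2 = c(TRUE, FALSE),
#'     cPlus5 = c(FALSE, FALSE)))
#' scanRegion(sim$genome, sim$tss, sim$window)
#' @export
simulateLocus <- function(seed, length = 4000L, tssPosition = 2000L,
                          strand = c("+", "-"), planted = NULL,
                          window = analysisWindow(-1000, 1000),
                          chrom = "chrS") {
    strand <- match.arg(strand)
    length <- as.integer(length)
    tssIdx <- as.integer(tssPosition)
    stopifnot(is(window, "AnalysisWindow"), tssIdx >= 1L,
              tssIdx <= length)
    if (is.null(planted))
        planted <- data.frame(rel = integer(0), gMinus2 = logical(0),
                              cPlus5 = logical(0))
    stopifnot(all(c("rel", "gMinus2", "cPlus5") %in% names(planted)))
    if (any(planted$rel == 0L))
        stop("planted rel positions must be nonzero")
    idx <- .senseIndex(planted$rel, tssIdx)
    if (nrow(planted) > 1L) {
        o <- order(idx)
        if (any(diff(idx[o]) < 8L))
            stop("planted cores overlap: starts must be >= 8 bp apart")
        planted <- planted[o, , drop = FALSE]
        idx <- idx[o]
    }
    winLo <- tssIdx + window@upstream
    winHi <- tssIdx + window@downstream - 1L
    if (any(idx < pmax(1L, winLo)) || any(idx + 4L > pmin(length, winHi)))
        stop("planted core outside the analysis window or the genome")

    sense <- .withSeed(seed, {
        chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
        protected <- integer(0)
        for (k in seq_len(nrow(planted))) {
            i <- idx[k]
            chars[i:(i + 4L)] <- c("A", "C", "G", "T", "G")
            protected <- c(protected, i:(i + 4L))
            if (i - 2L >= 1L) {
                chars[i - 2L] <- if (planted$gMinus2[k]) "G"
                    else sample(c("A", "C", "T"), 1L)
                if (planted$gMinus2[k]) protected <- c(protected, i - 2L)
            }
            if (i + 5L <= length) {
                chars[i + 5L] <- if (planted$cPlus5[k]) "C"
                    else sample(c("A", "G", "T"), 1L)
                if (planted$cPlus5[k]) protected <- c(protected, i + 5L)
            }
        }
        .destroyAccidentalCores(chars, idx, protected)
    })
    genomeStr <- if (strand == "+") paste(sense, collapse = "")
        else as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(paste(sense, collapse = ""))))
    genome <- Biostrings::DNAStringSet(genomeStr)
    names(genome) <- chrom
    absTss <- if (strand == "+") tssIdx else length - tssIdx + 1L
    truth <- data.frame(
        rel = as.integer(planted$rel),
        gMinus2 = planted$gMinus2, cPlus5 = planted$cPlus5,
        confidence = as.character(
            classifyConfidence(planted$gMinus2, planted$cPlus5)),
        location = as.character(
            ifelse(planted$rel <= -1L, "UPSTREAM", "INTRAGENIC")))
    list(genome = genome, tss = strandedLocus(chrom, absTss, strand),
         window = window, truth = truth)
}

# substitute one non-protected base of every ACGTG whose A0 was not
# planted; iterate because a substitution can itself create a new core
.destroyAccidentalCores <- function(chars, plantedIdx, protected) {
    for (iter in 1:1000) {
        s <- paste(chars, collapse = "")
        hits <- gregexpr("ACGTG", s, fixed = TRUE)[[1]]
        hits <- hits[hits > 0 & !(hits %in% plantedIdx)]
        if (!length(hits)) return(chars)
        for (h in hits) {
            span <- h:(h + 4L)
            free <- setdiff(span, protected)
            if (!length(free))
                stop("cannot destroy accidental core at ", h,
                     ": all bases protected")
            p <- free[1]
            chars[p] <- if (chars[p] == "T") "A" else "T"
        }
    }
    stop("accidental-core destruction did not converge")
}

#' Simulate an mRNA whose 5' end marks the TSS
#'
#' Builds a spliced transcript from the gene-sense genome: exon 1 starts
#' exactly at the TSS base, so [mapTss()] recovers the planted TSS from
#' the transcript's 5' anchor regardless of downstream exon structure.
#' On a minus-strand gene the transcript is (by construction) the
#' reverse complement of the genomic exon slices.
#'
#' @param genome genomic record (e.g. from [simulateLocus()]).
#' @param tss a [StrandedLocus-class].
#' @param exonLengths exon lengths in bp, 5' to 3'.
#' @param intronLengths intron lengths between consecutive exons
#'   (default 100 bp each).
#' @return A named `DNAStringSet` with the single transcript.
#' @export
simulateMrna <- function(genome, tss, exonLengths,
                         intronLengths = NULL) {
    g <- .asDNAString(genome)
    exonLengths <- as.integer(exonLengths)
    if (is.null(intronLengths))
        intronLengths <- rep(100L, max(0L, length(exonLengths) - 1L))
    intronLengths <- as.integer(intronLengths)
    stopifnot(length(intronLengths) == length(exonLengths) - 1L ||
              length(exonLengths) == 1L)
    senseG <- if (tss@strand == "+") g
              else Biostrings::reverseComplement(g)
    tssIdx <- if (tss@strand == "+") tss@position
              else length(g) - tss@position + 1L
    starts <- tssIdx + c(0L, cumsum(exonLengths[-length(exonLengths)] +
                                    intronLengths))
    ends <- starts + exonLengths - 1L
    if (any(starts < 1L) || any(ends > length(senseG)))
        stop("exon(s) fall outside the genome record")
    mrna <- paste(vapply(seq_along(starts), function(k)
        as.character(Biostrings::subseq(senseG, starts[k], ends[k])),
        character(1)), collapse = "")
    out <- Biostrings::DNAStringSet(mrna)
    names(out) <- "synthetic_mrna"
    out
}

#' Simulate a ChIP-qPCR threshold-cycle table with known enrichment
#'
#' For each condition and replicate, the IgG control Ct is drawn as
#' `Normal(baseCt, noiseSd)` and the ChIP sample Ct as
#' `baseCt - log2(trueFold) + Normal(0, noiseSd)`, so at zero noise
#' [summarizeEnrichment()] returns the true folds exactly, and each Ct
#' unit of separation encodes one two-fold enrichment.
#'
#' @param seed integer RNG seed.
#' @param conditions character vector of condition names.
#' @param trueFold true fold enrichment per condition (recycled).
#' @param baseCt mean control threshold cycle (default 25).
#' @param noiseSd Gaussian Ct noise, in cycles (default 0.2, a typical
#'   replicate-to-replicate spread for SYBR assays).
#' @param replicates replicates per condition (default 3, reactions run
#'   in triplicate).
#' @param chipTarget,iggTarget target labels written into the table.
#' @return list with `table` (Ct records data.frame) and `truth`
#'   (`trueFold` named per condition, `baseCt`, `noiseSd`, `replicates`).
#' @examples
#' sim <- simulateCtTable(seed = 1, conditions = "hypoxia_12h",
#'                        trueFold = 35, noiseSd = 0, replicates = 3)
#' summarizeEnrichment(sim$table, "HBS1_ChIP", "IgG")
#' @export
simulateCtTable <- function(seed, conditions, trueFold, baseCt = 25,
                            noiseSd = 0.2, replicates = 3L,
                            chipTarget = "HBS1_ChIP", iggTarget = "IgG") {
    stopifnot(all(trueFold > 0), replicates >= 1L)
    trueFold <- rep_len(trueFold, length(conditions))
    replicates <- as.integer(replicates)
    tab <- .withSeed(seed, {
        rows <- lapply(seq_along(conditions), function(i) {
            igg <- baseCt + stats::rnorm(replicates, 0, noiseSd)
            chip <- baseCt - log2(trueFold[i]) +
                stats::rnorm(replicates, 0, noiseSd)
            data.frame(
                sample_id = sprintf("%s_rep%d", conditions[i],
                                    seq_len(replicates)),
                condition = conditions[i],
                target = rep(c(chipTarget, iggTarget),
                             each = replicates),
                replicate = rep(seq_len(replicates), 2L),
                ct = c(chip, igg))
        })
        do.call(rbind, rows)
    })
    list(table = tab,
         truth = list(trueFold = stats::setNames(trueFold, conditions),
                      baseCt = baseCt, noiseSd = noiseSd,
                      replicates = replicates))
}

#' Simulate a protein-DNA trajectory with a known contact schedule
#'
#' Builds a multi-frame [Trajectory-class] in which the number of
#' protein-DNA atom pairs within the 0.6 nm contact cutoff is exactly
#' `contactSchedule[f]` in frame `f`.  Protein atoms sit on a 2 nm grid;
#' each DNA atom has one protein partner and is placed 0.45 nm from it
#' when in contact and 1.0 nm away otherwise, so counts are robust to
#' the 0.001 A coordinate rounding of PDB files.  Optional oscillator
#' atoms (chain `"F"`, far from the interface) alternate +/- amplitude
#' about their rest position, realizing known per-atom RMSF values about
#' the mean structure when the frame count is even.
#'
#' Because each DNA atom engages a single partner, schedules are limited
#' to `min(nProtein, nDna)` contacts per frame; anything larger is
#' rejected as infeasible.
#'
#' @param seed integer RNG seed (controls the sub-angstrom placement
#'   jitter of the scaffold; pair distances are exact by construction).
#' @param nProtein,nDna number of protein / DNA atoms.
#' @param contactSchedule intended contact count per frame.
#' @param fluctuation amplitudes (nm) of extra oscillator atoms
#'   (default none).
#' @param frameSpacing optional ns per frame.
#' @return list with `trajectory` ([Trajectory-class]) and `truth`
#'   (`contactSchedule`, `fluctuation`, `nProtein`, `nDna`).
#' @examples
#' sim <- simulateTrajectory(seed = 1, nProtein = 10, nDna = 10,
#'                           contactSchedule = c(5, 5, 5, 9, 9))
#' contactCounts(contactSeries(sim$trajectory, 2))
#' @export
simulateTrajectory <- function(seed, nProtein = 10L, nDna = 10L,
                               contactSchedule = c(5L, 5L),
                               fluctuation = numeric(0),
                               frameSpacing = NA_real_) {
    nProtein <- as.integer(nProtein)
    nDna <- as.integer(nDna)
    sched <- as.integer(contactSchedule)
    nf <- length(sched)
    stopifnot(nProtein >= 1L, nDna >= 1L, nf >= 1L)
    if (any(sched < 0L) || any(sched > min(nProtein, nDna)))
        stop("infeasible contact schedule: counts must be in 0..",
             min(nProtein, nDna), " (one DNA atom per protein partner)")
    nOsc <- length(fluctuation)

    base <- .withSeed(seed, {
        jitter <- function(n) stats::runif(n, -0.05, 0.05)
        prot <- cbind(2 * seq_len(nProtein), jitter(nProtein),
                      jitter(nProtein))
        dnaPartner <- ((seq_len(nDna) - 1L) %% nProtein) + 1L
        osc <- if (nOsc) cbind(2 * seq_len(nOsc), 10 + jitter(nOsc),
                               jitter(nOsc)) else NULL
        list(prot = prot, dnaPartner = dnaPartner, osc = osc)
    })
    # distinct partners are required for exact counts; enforced by the
    # schedule cap, partners only recycle when nDna > nProtein and those
    # extra atoms are never scheduled into contact
    nAt <- nProtein + nDna + nOsc
    coords <- array(NA_real_, dim = c(nAt, 3L, nf))
    sign <- rep(c(1, -1), length.out = nf)
    for (f in seq_len(nf)) {
        m <- matrix(NA_real_, nAt, 3L)
        m[seq_len(nProtein), ] <- base$prot
        for (j in seq_len(nDna)) {
            p <- base$prot[base$dnaPartner[j], ]
            m[nProtein + j, ] <- if (j <= sched[f]) p + c(0.45, 0, 0)
                                 else p + c(0, 1.0, 0)
        }
        if (nOsc)
            m[nProtein + nDna + seq_len(nOsc), ] <-
                base$osc + cbind(0, 0, fluctuation * sign[f])
        coords[, , f] <- m
    }
    atoms <- data.frame(
        atom_name = c(rep("CA", nProtein), rep("C1'", nDna),
                      rep("CA", nOsc)),
        residue_name = c(rep("GLY", nProtein), rep("DA", nDna),
                         rep("GLY", nOsc)),
        residue_index = c(seq_len(nProtein), seq_len(nDna),
                          seq_len(nOsc)),
        chain = c(rep("P", nProtein), rep("D", nDna), rep("F", nOsc)),
        moiety = c(rep("PROTEIN", nProtein), rep("DNA", nDna),
                   rep("PROTEIN", nOsc)),
        stringsAsFactors = FALSE)
    traj <- new("Trajectory", atoms = atoms, coords = coords,
                frameSpacing = as.numeric(frameSpacing))
    list(trajectory = traj,
         truth = list(contactSchedule = sched, fluctuation = fluctuation,
                      nProtein = nProtein, nDna = nDna))
}

#' Write a Trajectory as a multi-MODEL PDB file
#'
#' Coordinates are converted from nm to Angstrom (x 10) and written as
#' standard fixed-width ATOM records, one MODEL/ENDMDL block per frame.
#' Output is deterministic: the same trajectory always produces a
#' byte-identical file.
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readStructure()] for the inverse.
#' @export
writeTrajectoryPdb <- function(traj, path) {
    stopifnot(is(traj, "Trajectory"))
    at <- traj@atoms
    nf <- nFrames(traj)
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (f in seq_len(nf)) {
        writeLines(sprintf("MODEL     %4d", f), con)
        xyz <- frameCoords(traj, f) * 10   # nm -> Angstrom
        writeLines(sprintf(
            "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            seq_len(nrow(at)), at$atom_name, at$residue_name, at$chain,
            at$residue_index, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0), con)
        writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

#' Serialize / read generator ground truth as plain-text key-value pairs
#'
#' `writeTruth` flattens a truth list (scalars, vectors, data.frames)
#' into `key<TAB>value` lines, vectors comma-joined, data.frame columns
#' as `name.column` keys; `readTruth` parses them back (numeric where
#' possible).  The format is deliberately trivial so truth files stay
#' human-readable next to their datasets.
#'
#' @param truth a named list (e.g. `simulateLocus(...)$truth`).
#' @param path output/input file path.
#' @return `writeTruth`: `path` invisibly; `readTruth`: a named list.
#' @export
writeTruth <- function(truth, path) {
    if (is.data.frame(truth)) truth <- as.list(truth)
    flat <- .flattenTruth(truth, prefix = NULL)
    writeLines(vapply(names(flat), function(k)
        paste0(k, "\t", paste(flat[[k]], collapse = ",")),
        character(1)), path)
    invisible(path)
}

.flattenTruth <- function(x, prefix) {
    out <- list()
    for (nm in names(x)) {
        key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
        v <- x[[nm]]
        if (is.data.frame(v) || is.list(v))
            out <- c(out, .flattenTruth(as.list(v), key))
        else if (!is.null(names(v)))
            out <- c(out, .flattenTruth(as.list(v), key))
        else out[[key]] <- v
    }
    out
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- list()
    for (p in parts) {
        vals <- strsplit(p[2], ",", fixed = TRUE)[[1]]
        num <- suppressWarnings(as.numeric(vals))
        log <- vals %in% c("TRUE", "FALSE")
        out[[p[1]]] <- if (!anyNA(num)) num
            else if (all(log)) as.logical(vals) else vals
    }
    out
}
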