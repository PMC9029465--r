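.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.DNA3 <- c("DA", "DC", "DG", "DT", "DN")

#' Moiety classification of residue names
#'
#' Standard amino-acid three-letter codes map to `PROTEIN`,
#' deoxyribonucleotide codes (`DA`/`DC`/`DG`/`DT`/`DN`) to `DNA`,
#' anything else to `OTHER`.
#'
#' @param residueName character vector of residue names.
#' @return Character vector of `"PROTEIN"`, `"DNA"`, `"OTHER"`.
#' @examples
#' moietyOf(c("ASP", "DA", "HOH"))
#' @export
moietyOf <- function(residueName) {
    rn <- toupper(trimws(residueName))
    ifelse(rn %in% .AA3, "PROTEIN", ifelse(rn %in% .DNA3, "DNA", "OTHER"))
}

#' Read a (multi-MODEL) PDB file into a Trajectory
#'
#' Parses a PDB file via [bio3d::read.pdb()]; a file without MODEL
#' records is a single frame.  Angstrom coordinates are converted to nm
#' (x 0.1), atom order is preserved, and each atom is tagged with its
#' moiety (see [moietyOf()]).  Models with differing atom counts are a
#' structural error naming the offending model.
#'
#' @param path PDB file path.
#' @param frameSpacing optional time per frame in ns.
#' @return A [Trajectory-class].
#' @export
readStructure <- function(path, frameSpacing = NA_real_) {
    if (!file.exists(path))
        stop("PDB file not found: ", path)
    lines <- readLines(path)
    isAtom <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(isAtom))
        stop("no ATOM/HETATM records in '", path, "'")
    badCoord <- which(isAtom &
        !grepl("^.{30}[ 0-9.+-]{8}[ 0-9.+-]{8}[ 0-9.+-]{8}", lines))
    if (length(badCoord))
        stop("unparseable ATOM record at line ", badCoord[1], " of '",
             path, "'")
    modelStarts <- grep("^MODEL", lines)
    if (length(modelStarts) > 1L) {
        # per-model atom counts, so a mismatch can name its model
        grp <- findInterval(which(isAtom), modelStarts)
        counts <- tabulate(grp, nbins = length(modelStarts))
        if (length(unique(counts[counts > 0])) > 1L) {
            ref <- counts[1]
            badModel <- which(counts != ref)[1]
            stop("model ", badModel, " has ", counts[badModel],
                 " atoms but model 1 has ", ref)
        }
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz)))
        xyz <- matrix(xyz, nrow = 1L)
    nFrame <- nrow(xyz)
    nAtom <- ncol(xyz) / 3L
    atoms <- data.frame(
        atom_name = trimws(pdb$atom$elety),
        residue_name = trimws(pdb$atom$resid),
        residue_index = as.integer(pdb$atom$resno),
        chain = as.character(pdb$atom$chain),
        moiety = moietyOf(pdb$atom$resid),
        stringsAsFactors = FALSE)
    coords <- array(NA_real_, dim = c(nAtom, 3L, nFrame))
    for (f in seq_len(nFrame))
        coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) * 0.1
    new("Trajectory", atoms = atoms, coords = coords,
        frameSpacing = as.numeric(frameSpacing))
}

.resolveGroup <- function(traj, group) {
    if (is.character(group) && length(group) == 1L &&
        group %in% c("PROTEIN", "DNA", "OTHER"))
        which(traj@atoms$moiety == group)
    else if (is.logical(group)) which(group)
    else as.integer(group)
}

#' Count protein-DNA atom-pair contacts in one frame
#'
#' Number of atom pairs (one from each group) within `cutoff` of each
#' other (inclusive: a pair at exactly the cutoff counts, so results are
#' bit-reproducible on constructed inputs).  Uses a cell-list spatial
#' grid; by construction it returns exactly the same count as a full
#' O(n^2) distance scan.
#'
#' @param traj a [Trajectory-class].
#' @param frame frame index.
#' @param cutoff contact distance in nm (default 0.6).
#' @param groupA,groupB atom selections: a moiety name (`"PROTEIN"`,
#'   `"DNA"`, `"OTHER"`), a logical mask, or atom indices.  Defaults:
#'   all PROTEIN vs all DNA atoms.
#' @return Non-negative integer contact count.
#' @examples
#' sim <- simulateTrajectory(seed = 1, nProtein = 4, nDna = 4,
#'                           contactSchedule = c(2, 3))
#' countContacts(sim$trajectory, 1)   # 2
#' @export
countContacts <- function(traj, frame, cutoff = 0.6, groupA = "PROTEIN",
                          groupB = "DNA") {
    stopifnot(is(traj, "Trajectory"), cutoff > 0)
    ia <- .resolveGroup(traj, groupA)
    ib <- .resolveGroup(traj, groupB)
    if (length(ia) == 0L || length(ib) == 0L)
        stop("empty atom group: groupA has ", length(ia),
             " atoms, groupB has ", length(ib))
    if (length(intersect(ia, ib)))
        stop("groups must be disjoint")
    xyz <- frameCoords(traj, frame)
    .cellListCount(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE],
                   cutoff)
}

# cell-list neighbour search: bin group-B atoms into cubic cells of edge
# `cutoff`; for each group-A atom only the 27 surrounding cells are
# examined.  Distances are compared as squares against cutoff^2, the
# same arithmetic a brute-force scan uses, so counts agree exactly.
.cellListCount <- function(A, B, cutoff) {
    origin <- pmin(apply(A, 2, min), apply(B, 2, min))
    ca <- floor(sweep(A, 2, origin) / cutoff)
    cb <- floor(sweep(B, 2, origin) / cutoff)
    keyB <- paste(cb[, 1], cb[, 2], cb[, 3])
    bIndex <- split(seq_len(nrow(B)), keyB)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    cut2 <- cutoff^2
    total <- 0L
    for (i in seq_len(nrow(A))) {
        keys <- paste(offs[, 1] + ca[i, 1], offs[, 2] + ca[i, 2],
                      offs[, 3] + ca[i, 3])
        cand <- unlist(bIndex[keys], use.names = FALSE)
        if (length(cand)) {
            d2 <- (B[cand, 1] - A[i, 1])^2 + (B[cand, 2] - A[i, 2])^2 +
                  (B[cand, 3] - A[i, 3])^2
            total <- total + sum(d2 <= cut2)
        }
    }
    as.integer(total)
}

#' Per-frame contact counts with a trailing-window mean
#'
#' Applies [countContacts()] to every frame and averages the last
#' `trailingWindow` frames — the usual way to summarize an
#' interface once a simulation has equilibrated (e.g. a mean contact
#' count over the final nanoseconds).
#'
#' @inheritParams countContacts
#' @param trailingWindow number of trailing frames to average
#'   (`<=` number of frames).
#' @return A [ContactSeries-class].
#' @export
contactSeries <- function(traj, trailingWindow, cutoff = 0.6,
                          groupA = "PROTEIN", groupB = "DNA") {
    nf <- nFrames(traj)
    trailingWindow <- as.integer(trailingWindow)
    if (trailingWindow < 1L || trailingWindow > nf)
        stop("trailingWindow must be in 1..", nf)
    counts <- vapply(seq_len(nf), function(f)
        countContacts(traj, f, cutoff, groupA, groupB), integer(1))
    tail <- counts[(nf - trailingWindow + 1L):nf]
    new("ContactSeries", counts = as.numeric(counts),
        windowMean = mean(tail), window = trailingWindow)
}

#' Residue-level contact map for one frame
#'
#' Aggregates in-cutoff atom pairs by (chain, residue) on each side.
#' The table total always equals [countContacts()] for the same frame
#' and parameters.
#'
#' @inheritParams countContacts
#' @return data.frame with columns `chainA`, `residueA`, `residueNameA`,
#'   `chainB`, `residueB`, `residueNameB`, `pairs`; zero rows when no
#'   pair is within the cutoff.
#' @export
residueContactMap <- function(traj, frame, cutoff = 0.6,
                              groupA = "PROTEIN", groupB = "DNA") {
    stopifnot(is(traj, "Trajectory"), cutoff > 0)
    ia <- .resolveGroup(traj, groupA)
    ib <- .resolveGroup(traj, groupB)
    if (length(ia) == 0L || length(ib) == 0L)
        stop("empty atom group: groupA has ", length(ia),
             " atoms, groupB has ", length(ib))
    xyz <- frameCoords(traj, frame)
    A <- xyz[ia, , drop = FALSE]
    B <- xyz[ib, , drop = FALSE]
    cut2 <- cutoff^2
    rows <- list()
    at <- traj@atoms
    for (i in seq_along(ia)) {
        d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
              (B[, 3] - A[i, 3])^2
        hit <- which(d2 <= cut2)
        if (length(hit))
            rows[[length(rows) + 1L]] <- data.frame(
                chainA = at$chain[ia[i]],
                residueA = at$residue_index[ia[i]],
                residueNameA = at$residue_name[ia[i]],
                chainB = at$chain[ib[hit]],
                residueB = at$residue_index[ib[hit]],
                residueNameB = at$residue_name[ib[hit]])
    }
    if (!length(rows))
        return(data.frame(chainA = character(0), residueA = integer(0),
                          residueNameA = character(0),
                          chainB = character(0), residueB = integer(0),
                          residueNameB = character(0), pairs = integer(0)))
    all <- do.call(rbind, rows)
    agg <- stats::aggregate(list(pairs = rep(1L, nrow(all))),
                            by = all, FUN = sum)
    agg[order(agg$chainA, agg$residueA, agg$chainB, agg$residueB), ,
        drop = FALSE]
}

#' Optimal rigid (Kabsch) superposition
#'
#' Least-squares rotation + translation of `P` onto `Q` via SVD of the
#' covariance matrix, with the usual determinant correction so the
#' result is a proper rotation (no reflection).
#'
#' @param P,Q `[n, 3]` coordinate matrices with matched rows.
#' @return `P` rigidly transformed onto `Q`.
#' @export
kabsch <- function(P, Q) {
    stopifnot(all(dim(P) == dim(Q)), ncol(P) == 3L)
    cp <- colMeans(P); cq <- colMeans(Q)
    Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
    s <- svd(crossprod(Pc, Qc))
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    sweep(Pc %*% t(R), 2, cq, "+")
}

#' Root-mean-square deviation between two frames
#'
#' RMS displacement (nm) of the selected atoms between a frame and a
#' reference frame.  With `superpose = TRUE` (default) an optimal
#' least-squares rigid superposition ([kabsch()]) is applied first, so a
#' rigid rotation+translation of the same structure gives 0; with
#' `superpose = FALSE` the raw displacements are used.
#'
#' @param traj a [Trajectory-class].
#' @param frame frame index to measure.
#' @param reference reference frame index (default 1).
#' @param selection atom indices/logical mask/moiety name (default: all
#'   atoms).
#' @param superpose apply Kabsch superposition first (default `TRUE`).
#' @return RMSD in nm.
#' @export
calcRMSD <- function(traj, frame, reference = 1L, selection = NULL,
                     superpose = TRUE) {
    stopifnot(is(traj, "Trajectory"))
    sel <- if (is.null(selection)) seq_len(nAtoms(traj))
           else .resolveGroup(traj, selection)
    if (length(sel) == 0L)
        stop("empty selection")
    P <- frameCoords(traj, frame)[sel, , drop = FALSE]
    Q <- frameCoords(traj, reference)[sel, , drop = FALSE]
    if (isTRUE(superpose))
        P <- kabsch(P, Q)
    sqrt(mean(rowSums((P - Q)^2)))
}

#' Root-mean-square fluctuation over a trailing window
#'
#' Per-atom RMS displacement (nm) from a reference structure over the
#' last `trailingWindow` frames.  The reference is either the window's
#' mean structure (`"mean"`, the standard definition) or the first frame
#' of the window (`"first"`, the displacement-from-starting-structure
#' reading); no superposition is applied.  Per-residue values are means
#' over each residue's atoms.
#'
#' @param traj a [Trajectory-class].
#' @param trailingWindow number of trailing frames used (`>= 2`).
#' @param reference `"mean"` (default) or `"first"`.
#' @param per `"atom"` (default) or `"residue"`.
#' @return Numeric vector of fluctuations in nm; for `per = "residue"`,
#'   named `chain:residue_index` in atom-table order.
#' @export
calcRMSF <- function(traj, trailingWindow = nFrames(traj),
                     reference = c("mean", "first"),
                     per = c("atom", "residue")) {
    stopifnot(is(traj, "Trajectory"))
    reference <- match.arg(reference)
    per <- match.arg(per)
    nf <- nFrames(traj)
    trailingWindow <- as.integer(trailingWindow)
    if (trailingWindow < 2L || trailingWindow > nf)
        stop("trailingWindow must be in 2..", nf)
    idx <- (nf - trailingWindow + 1L):nf
    cube <- traj@coords[, , idx, drop = FALSE]
    n <- dim(cube)[1]
    ref <- apply(cube, c(1, 2), mean)
    if (reference == "first") {
        ref <- cube[, , 1, drop = FALSE]
        dim(ref) <- dim(ref)[1:2]
    }
    dev2 <- vapply(seq_along(idx), function(k) {
        m <- cube[, , k, drop = FALSE]
        dim(m) <- dim(m)[1:2]
        rowSums((m - ref)^2)
    }, numeric(n))
    dev2 <- matrix(dev2, nrow = n)
    rmsf <- sqrt(rowMeans(dev2))
    if (per == "atom") return(rmsf)
    key <- paste0(traj@atoms$chain, ":", traj@atoms$residue_index)
    out <- tapply(rmsf, factor(key, levels = unique(key)), mean)
    stats::setNames(as.numeric(out), names(out))
}
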