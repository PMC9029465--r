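# shared fixtures and independent oracles

writeTempFasta <- function(..., file = tempfile(fileext = ".fa")) {
    writeLines(unlist(list(...)), file)
    file
}

# the six protein-DNA docking fragments printed for the mouse gene,
# keyed by model number; models 1/4/5 carry G(-2) and/or C(+5)
modelFragments <- c(
    "1" = "GAACGTGCCTGGC",
    "2" = "AACATACGTGGTCTT",
    "3" = "AACCAACGTGTTCGT",
    "4" = "TGGACGTGCTCTGTG",
    "5" = "TGGCCAACGTGCTGCGCGCAC",
    "6" = "TCCCACGTGAAGG")

# O(n^2) enumeration oracle for pair contacts (independent of the
# package's cell-list pruning)
bruteContacts <- function(A, B, cutoff) {
    cut2 <- cutoff^2
    total <- 0L
    for (i in seq_len(nrow(A))) {
        d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
              (B[, 3] - A[i, 3])^2
        total <- total + sum(d2 <= cut2)
    }
    total
}

# build a one-or-more-frame Trajectory directly from coordinate matrices
makeTrajectory <- function(protCoords, dnaCoords, frames = NULL) {
    np <- nrow(protCoords); nd <- nrow(dnaCoords)
    atoms <- data.frame(
        atom_name = c(rep("CA", np), rep("C1'", nd)),
        residue_name = c(rep("GLY", np), rep("DA", nd)),
        residue_index = c(seq_len(np), seq_len(nd)),
        chain = c(rep("P", np), rep("D", nd)),
        moiety = c(rep("PROTEIN", np), rep("DNA", nd)),
        stringsAsFactors = FALSE)
    if (is.null(frames)) frames <- list(rbind(protCoords, dnaCoords))
    coords <- array(NA_real_, dim = c(np + nd, 3L, length(frames)))
    for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
    new("Trajectory", atoms = atoms, coords = coords,
        frameSpacing = NA_real_)
}

# GRanges candidates -> plain comparable data.frame
candidateFrame <- function(gr) {
    d <- as.data.frame(gr)
    d$seqnames <- as.character(d$seqnames)
    d$strand <- as.character(d$strand)
    rownames(d) <- NULL
    d
}

randomDnaString <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = "")
}
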