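test_that("PDB reading converts to nm, assigns moieties, preserves order", {
    pdb <- tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  CA  ASP A  24       1.000   2.000   3.000  1.00  0.00",
        "ATOM      2  C1' DA  C  10       7.000   2.000   3.000  1.00  0.00",
        "END"), pdb)
    tr <- readStructure(pdb)
    expect_equal(nFrames(tr), 1L)
    expect_equal(nAtoms(tr), 2L)
    expect_equal(atomTable(tr)$moiety, c("PROTEIN", "DNA"))
    expect_equal(frameCoords(tr, 1)[1, ], c(0.1, 0.2, 0.3))  # A -> nm
    expect_equal(moietyOf(c("ASP", "DA", "HOH")),
                 c("PROTEIN", "DNA", "OTHER"))
})

test_that("models with differing atom counts are a structural error naming the model", {
    sim <- simulateTrajectory(seed = 1, nProtein = 2, nDna = 2,
                              contactSchedule = c(1, 1, 1))
    pdb <- tempfile(fileext = ".pdb")
    writeTrajectoryPdb(sim$trajectory, pdb)
    lines <- readLines(pdb)
    drop <- which(grepl("^ATOM", lines))[6]   # second atom of model 2
    writeLines(lines[-drop], pdb)
    expect_error(readStructure(pdb), "model 2 has 3 atoms")
})

test_that("contact counting respects the inclusive 0.6 nm cutoff", {
    near <- makeTrajectory(matrix(c(0, 0, 0), 1),
                           matrix(c(0.5, 0, 0), 1))
    expect_equal(countContacts(near, 1), 1L)
    far <- makeTrajectory(matrix(c(0, 0, 0), 1),
                          matrix(c(0.7, 0, 0), 1))
    expect_equal(countContacts(far, 1), 0L)
    at <- makeTrajectory(matrix(c(0, 0, 0), 1),
                         matrix(c(0.6, 0, 0), 1))
    expect_equal(countContacts(at, 1), 1L)   # boundary pair counts
    expect_error(countContacts(far, 1, groupA = "OTHER"), "empty")
})

test_that("grid contact counts equal the brute-force enumeration", {
    set.seed(7)
    A <- matrix(runif(150, 0, 3), ncol = 3)
    B <- matrix(runif(150, 0, 3), ncol = 3)
    tr <- makeTrajectory(A, B)
    expect_equal(countContacts(tr, 1), bruteContacts(A, B, 0.6))
    # sparse and dense packings
    for (s in 1:20) {
        set.seed(400 + s)
        box <- if (s %% 2 == 0) 1.2 else 6
        A <- matrix(runif(90, 0, box), ncol = 3)
        B <- matrix(runif(90, 0, box), ncol = 3)
        tr <- makeTrajectory(A, B)
        for (cut in c(0.3, 0.6, 1.1))
            expect_equal(countContacts(tr, 1, cutoff = cut),
                         bruteContacts(A, B, cut))
    }
})

test_that("contact counts are monotone in cutoff and symmetric in groups", {
    set.seed(19)
    A <- matrix(runif(120, 0, 2.5), ncol = 3)
    B <- matrix(runif(120, 0, 2.5), ncol = 3)
    tr <- makeTrajectory(A, B)
    cuts <- c(0.2, 0.4, 0.6, 0.9, 1.5)
    counts <- vapply(cuts, function(ct) countContacts(tr, 1, ct),
                     integer(1))
    expect_true(all(diff(counts) >= 0L))
    expect_equal(countContacts(tr, 1, 0.6, "DNA", "PROTEIN"),
                 countContacts(tr, 1, 0.6, "PROTEIN", "DNA"))
})

test_that("contact series reproduces engineered schedules and window means", {
    sim <- simulateTrajectory(seed = 4, nProtein = 10, nDna = 10,
                              contactSchedule = c(5, 5, 5, 9, 9))
    cs <- contactSeries(sim$trajectory, 2)
    expect_equal(contactCounts(cs), c(5, 5, 5, 9, 9))
    expect_equal(contactWindowMean(cs), 9)
    full <- contactSeries(sim$trajectory, 5)
    expect_equal(contactWindowMean(full), mean(c(5, 5, 5, 9, 9)))
    expect_error(contactSeries(sim$trajectory, 6), "trailingWindow")
})

test_that("residue contact map totals equal the pair count", {
    pdb <- tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  OD1 ASP A  24       0.000   0.000   0.000  1.00  0.00",
        "ATOM      2  N3  DT  C  10       4.000   0.000   0.000  1.00  0.00",
        "END"), pdb)
    tr <- readStructure(pdb)
    m <- residueContactMap(tr, 1)
    expect_equal(nrow(m), 1L)
    expect_equal(m$pairs, 1L)
    expect_equal(m$residueNameA, "ASP")
    expect_equal(m$chainB, "C")

    for (s in 1:5) {
        set.seed(600 + s)
        A <- matrix(runif(60, 0, 2), ncol = 3)
        B <- matrix(runif(60, 0, 2), ncol = 3)
        tr <- makeTrajectory(A, B)
        m <- residueContactMap(tr, 1)
        expect_equal(sum(m$pairs), countContacts(tr, 1))
    }
    farA <- matrix(c(0, 0, 0), 1); farB <- matrix(c(5, 5, 5), 1)
    expect_equal(nrow(residueContactMap(makeTrajectory(farA, farB), 1)),
                 0L)
})

test_that("RMSD: identity, rigid-motion invariance, and the d/sqrt(N) case", {
    set.seed(23)
    P <- matrix(runif(60, 0, 3), ncol = 3)
    tr <- makeTrajectory(P[1:10, ], P[11:20, ],
                         frames = list(P, P))
    expect_equal(calcRMSD(tr, 2, 1), 0)

    th <- 0.9
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3)
    moved <- P %*% R + matrix(rep(c(1.2, -0.4, 2), each = 20), ncol = 3)
    tr2 <- makeTrajectory(P[1:10, ], P[11:20, ], frames = list(P, moved))
    expect_lt(calcRMSD(tr2, 2, 1), 1e-9)
    expect_gt(calcRMSD(tr2, 2, 1, superpose = FALSE), 1)

    # 4 atoms, one displaced by 0.2 nm, no superposition -> 0.2/sqrt(4)
    Q <- matrix(0, 4, 3); Q2 <- Q; Q2[1, 1] <- 0.2
    tr3 <- makeTrajectory(Q[1:2, ], Q[3:4, ], frames = list(Q, Q2))
    expect_equal(calcRMSD(tr3, 2, 1, superpose = FALSE), 0.1)
})

test_that("superposed RMSD never exceeds raw RMSD", {
    set.seed(29)
    for (k in 1:20) {
        P <- matrix(runif(36, 0, 3), ncol = 3)
        Q <- P + matrix(rnorm(36, 0, 0.3), ncol = 3)
        tr <- makeTrajectory(P[1:6, ], P[7:12, ], frames = list(P, Q))
        expect_lte(calcRMSD(tr, 2, 1),
                   calcRMSD(tr, 2, 1, superpose = FALSE) + 1e-12)
    }
})

test_that("Kabsch superposition agrees with an independent reference implementation", {
    set.seed(31)
    P <- matrix(runif(45, 0, 2), ncol = 3)
    Q <- P + matrix(rnorm(45, 0, 0.25), ncol = 3)
    tr <- makeTrajectory(P[1:8, ], P[9:15, ], frames = list(P, Q))
    ours <- calcRMSD(tr, 2, 1)
    # bio3d works in Angstrom and rounds its result to 3 decimals
    theirs <- bio3d::rmsd(as.vector(t(P)) * 10, as.vector(t(Q)) * 10,
                          fit = TRUE) / 10
    expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("RMSF closed forms: static zeros and oscillator amplitudes", {
    sim <- simulateTrajectory(seed = 2, nProtein = 3, nDna = 3,
                              contactSchedule = rep(2, 6))
    expect_equal(calcRMSF(sim$trajectory), rep(0, 6))

    a <- 0.15
    osc <- simulateTrajectory(seed = 2, nProtein = 3, nDna = 3,
                              contactSchedule = rep(2, 6),
                              fluctuation = a)
    rf <- calcRMSF(osc$trajectory, reference = "mean")
    expect_equal(rf, c(rep(0, 6), a))

    # first-frame reference: cross-check against direct per-frame math
    rfFirst <- calcRMSF(osc$trajectory, reference = "first")
    cube <- sapply(1:6, function(f)
        frameCoords(osc$trajectory, f)[7, 3])
    oracle <- sqrt(mean((cube - cube[1])^2))
    expect_equal(rfFirst[7], oracle)
    expect_equal(oracle, a * sqrt(2))

    perRes <- calcRMSF(osc$trajectory, per = "residue")
    expect_equal(unname(perRes[names(perRes) == "F:1"]), a)
    expect_error(calcRMSF(sim$trajectory, trailingWindow = 1),
                 "trailingWindow")
})
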