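test_that("core search finds all ACGTG occurrences in order", {
    h <- findCores(modelFragments[["1"]])
    expect_equal(h$offset, 3L)          # A0 at base 3 of GAACGTGCCTGGC
    expect_equal(h$strand, "sense")
    expect_equal(nrow(findCores("AAAAAA")), 0L)
    expect_equal(findCores("ACGTGACGTG")$offset, c(1L, 6L))
})

test_that("antisense hits are reported at the sense base pairing A0", {
    # CACGT on the sense strand is ACGTG read on the reverse strand,
    # with A0 pairing the final T
    h <- findCores("TTCACGTTT", scanAntisense = TRUE)
    expect_equal(h$offset, 7L)
    expect_equal(h$strand, "antisense")
    a <- annotateFlanks("TTCACGTTT", 7L, "antisense")
    expect_equal(a$core, "ACGTG")
})

test_that("sense-only scan of a sequence equals antisense-only scan of its reverse complement", {
    set.seed(13)
    for (k in 1:20) {
        s <- randomDnaString(300)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        sense <- findCores(s)$offset
        anti <- findCores(rc, scanAntisense = TRUE)
        anti <- anti$offset[anti$strand == "antisense"]
        expect_equal(sort(301L - anti), sort(sense))
    }
})

test_that("enabling antisense never removes candidates", {
    set.seed(17)
    for (k in 1:10) {
        s <- randomDnaString(400)
        expect_gte(nrow(findCores(s, scanAntisense = TRUE)),
                   nrow(findCores(s)))
    }
})

test_that("RCGTG mode adds G0 cores but N never matches", {
    h <- findCores("AAGCGTGAA", core = "RCGTG")
    expect_equal(h$offset, 3L)
    expect_equal(nrow(findCores("AAGCGTGAA")), 0L)      # strict mode
    expect_equal(nrow(findCores("AANCGTGAA", core = "RCGTG")), 0L)
    expect_equal(nrow(findCores("ACGTN")), 0L)
})

test_that("flank annotation matches the printed fragments' classes", {
    expected <- data.frame(
        model = 1:6,
        m2 = c("G", "A", "C", "G", "C", "C"),
        p5 = c("C", "G", "T", "C", "C", "A"),
        conf = c("HIGH", "CORE_ONLY", "CORE_ONLY", "HIGH", "HIGH",
                 "CORE_ONLY"))
    for (i in 1:6) {
        frag <- modelFragments[[as.character(i)]]
        h <- findCores(frag)
        expect_equal(nrow(h), 1L, info = paste("model", i))
        a <- annotateFlanks(frag, h$offset, h$strand)
        expect_equal(a$flankMinus2, expected$m2[i])
        expect_equal(a$flankPlus5, expected$p5[i])
        expect_equal(a$confidence, expected$conf[i])
        expect_false(a$lowContext)
    }
})

test_that("flanks outside the sequence are unknown, count as absent, and flag low context", {
    a <- annotateFlanks("ACGTGC", 1L, "sense")
    expect_true(is.na(a$flankMinus2))
    expect_true(a$lowContext)
    expect_equal(a$confidence, "HIGH")   # C(+5) present
    b <- annotateFlanks("ACGTGA", 1L, "sense")
    expect_true(is.na(b$flankMinus2))
    expect_equal(b$confidence, "CORE_ONLY")
    expect_true(b$lowContext)
})

test_that("the high-probability rule is an inclusive OR", {
    expect_equal(classifyConfidence(TRUE, TRUE), "HIGH")
    expect_equal(classifyConfidence(TRUE, FALSE), "HIGH")
    expect_equal(classifyConfidence(FALSE, TRUE), "HIGH")
    expect_equal(classifyConfidence(FALSE, FALSE), "CORE_ONLY")
    expect_equal(classifyConfidence(NA, FALSE), "CORE_ONLY")
})

test_that("scanRegion resolves coordinates, confidence, location and labels", {
    sim <- simulateLocus(seed = 2, length = 12000, tssPosition = 6000,
        strand = "-",
        planted = data.frame(rel = c(-2186, 120, 4000),
                             gMinus2 = c(TRUE, FALSE, FALSE),
                             cPlus5 = c(FALSE, TRUE, FALSE)),
        window = analysisWindow(-3000, 4100))
    gr <- scanRegion(sim$genome, sim$tss, sim$window)
    expect_equal(gr$relPosition, c(-2186L, 120L, 4000L))
    expect_equal(gr$confidence, c("HIGH", "HIGH", "CORE_ONLY"))
    expect_equal(gr$location, c("UPSTREAM", "INTRAGENIC", "INTRAGENIC"))
    expect_equal(gr$label, c("#1", "#2", "#3"))
    expect_equal(gr$absPosition, relToAbs(gr$relPosition, sim$tss))
    # empty window scan
    sim0 <- simulateLocus(seed = 3, length = 2000, tssPosition = 1001)
    expect_equal(length(scanRegion(sim0$genome, sim0$tss, sim0$window)),
                 0L)
})

test_that("every reported core re-extracts as ACGTG from the genome", {
    for (s in c(21, 22)) {
        st <- if (s %% 2 == 0) "+" else "-"
        sim <- simulateLocus(seed = s, length = 8000, tssPosition = 4000,
            strand = st,
            planted = data.frame(rel = c(-900, -12, 33, 700),
                                 gMinus2 = c(TRUE, FALSE, TRUE, FALSE),
                                 cPlus5 = c(FALSE, TRUE, TRUE, FALSE)),
            window = analysisWindow(-1500, 1500))
        gr <- scanRegion(sim$genome, sim$tss, sim$window,
                         scanAntisense = TRUE)
        g <- sim$genome[[1]]
        for (i in seq_along(gr)) {
            sub <- Biostrings::subseq(g, BiocGenerics::start(gr)[i],
                                      BiocGenerics::end(gr)[i])
            if (as.character(GenomicRanges::strand(gr))[i] == "-")
                sub <- Biostrings::reverseComplement(sub)
            expect_equal(as.character(sub), "ACGTG")
        }
    }
})

test_that("BED export is 0-based half-open over the 5 core bases", {
    # plus-strand gene: A0 at absolute 101
    simP <- simulateLocus(seed = 31, length = 300, tssPosition = 100,
        strand = "+",
        planted = data.frame(rel = 2, gMinus2 = TRUE, cPlus5 = FALSE),
        window = analysisWindow(-50, 80))
    grP <- scanRegion(simP$genome, simP$tss, simP$window)
    expect_equal(grP$absPosition, 101L)
    bed <- tempfile(fileext = ".bed")
    exportCandidates(grP, bed, "bed")
    f <- strsplit(readLines(bed)[1], "\t")[[1]]
    expect_equal(as.integer(f[2:3]), c(100L, 105L))
    expect_equal(f[6], "+")

    # minus-strand gene: A0 at absolute 200, core spans 196..200
    simM <- simulateLocus(seed = 32, length = 400, tssPosition = 201,
        strand = "-",
        planted = data.frame(rel = 1, gMinus2 = FALSE, cPlus5 = TRUE),
        window = analysisWindow(-50, 50))
    grM <- scanRegion(simM$genome, simM$tss, simM$window)
    expect_equal(grM$absPosition, 200L)
    exportCandidates(grM, bed, "bed")
    f <- strsplit(readLines(bed)[1], "\t")[[1]]
    expect_equal(as.integer(f[2:3]), c(195L, 200L))
    expect_equal(f[6], "-")
})

test_that("GFF3 export keeps 1-based inclusive coordinates", {
    sim <- simulateLocus(seed = 35, length = 500, tssPosition = 250,
        strand = "+",
        planted = data.frame(rel = 10, gMinus2 = TRUE, cPlus5 = TRUE),
        window = analysisWindow(-100, 100))
    gr <- scanRegion(sim$genome, sim$tss, sim$window)
    gff <- tempfile(fileext = ".gff3")
    exportCandidates(gr, gff, "gff3")
    ln <- grep("^[^#]", readLines(gff), value = TRUE)[1]
    f <- strsplit(ln, "\t")[[1]]
    expect_equal(as.integer(f[4:5]),
                 c(BiocGenerics::start(gr), BiocGenerics::end(gr)))
})

test_that("candidates round-trip through CSV unchanged", {
    sim <- simulateLocus(seed = 36, length = 3000, tssPosition = 1500,
        strand = "-",
        planted = data.frame(rel = c(-300, 40), gMinus2 = c(TRUE, FALSE),
                             cPlus5 = c(FALSE, FALSE)),
        window = analysisWindow(-800, 800))
    gr <- scanRegion(sim$genome, sim$tss, sim$window)
    csv <- tempfile(fileext = ".csv")
    exportCandidates(gr, csv, "csv")
    back <- readCandidates(csv)
    expect_equal(candidateFrame(back), candidateFrame(gr))
})
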