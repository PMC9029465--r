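---
title: "Finding HIF-1 binding sites around a TSS, and quantifying the evidence"
author: "HBStools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding HIF-1 binding sites around a TSS, and quantifying the evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HBStools)
```

# The problem

Hypoxia-inducible factor 1 (HIF-1) transactivates genes by binding
hypoxia-response elements, whose functional heart is a short conserved
HIF-binding site (HBS). The minimal HBS core is the pentamer
5'-ACGTG-3' (more generally RCGTG), and two flanking nucleotides — a G
two bases 5' of the core's A0 and a C five bases 3' of it — are known
to raise the probability that HIF-1 actually binds. Because functional
HBSs can sit far upstream of a promoter or inside the transcribed
region, the natural search space is a window around the transcription
start site (TSS), expressed in TSS-relative coordinates.

HBStools implements that search as a reusable pipeline: a strand-aware
TSS-relative coordinate system, TSS mapping from an mRNA 5' end, core
scanning with flank classification, ChIP-qPCR quantification of binding
evidence, and protein–DNA interface metrics for structural follow-up.
Seeded generators produce synthetic inputs with exact ground truth for
every stage.

# The coordinate system

The TSS-relative axis is **zero-free**: the TSS base is +1, the base
immediately upstream is −1, and 0 never occurs. This is the unique
convention consistent with describing a minus-strand region bounded by
absolute positions 27,237,610 and 27,226,612 around a TSS at 27,230,845
as running from −6765 to +4234: `27230845 − 27226612 + 1 = 4234` and
`27230845 − 27237610 = −6765`.

```{r coords}
tss <- strandedLocus("chr8", 27230845, "-")
absToRel(c(27226612, 27237610, 27230845), tss)
```

On the minus strand "downstream" means *decreasing* absolute
coordinate; `absToRel()`/`relToAbs()` are exact inverses, and
`extractWindow()` returns the window sequence reading 5'→3' along the
gene (the reverse complement of the plus-strand slice for a
minus-strand TSS), together with per-base relative and absolute
coordinate maps. Internally everything is 1-based inclusive;
0-based half-open coordinates appear only in BED export.

# TSS mapping

`mapTss()` finds the TSS as the unique placement (either strand) of the
mRNA's first `anchorLength` bases, defaulting to a 30-mer with zero
mismatches. A full spliced transcript alignment would be overkill: the
TSS is defined solely by the transcript's first base, so only the 5'
anchor matters. Thirty bases put random collisions at ~4^-30 per
position while tolerating nothing by default; both knobs are exposed
for noisy 5' ends. Zero placements and multiple placements are errors —
a single-position TSS presumes uniqueness, and silently picking one of
several placements would manufacture a wrong answer.

# Scanning and classification

`scanRegion()` composes window extraction, core search
(`findCores()`, exact ACGTG by default; an optional RCGTG mode
interprets the IUPAC R in the pattern while keeping the subject
literal, so N in the sequence never matches), flank annotation and
classification:

* a candidate's **position is its A0 base** (the package's convention;
  position reports in the literature rarely say which core base they
  index);
* confidence is **HIGH** when G(−2) and/or C(+5) is present — an
  inclusive OR — and **CORE_ONLY** otherwise; flanks falling outside
  the sequence are unknown, count as absent, and set a low-context
  flag;
* candidates are labelled #1, #2, … in 5'→3' window order and tagged
  UPSTREAM (relative position ≤ −1) or INTRAGENIC.

By default only the gene-sense strand is scanned; `scanAntisense =
TRUE` adds reverse-strand cores, reported at the sense base pairing the
core's A0. Sense-only is the default because a sense-oriented window
analysis is the common reading of published HBS lists; the flag makes
the alternative explicit rather than silent.

```{r scan}
sim <- simulateLocus(seed = 7, length = 8000, tssPosition = 4000,
    strand = "-",
    planted = data.frame(rel = c(-2186, 120), gMinus2 = c(TRUE, FALSE),
                         cPlus5 = c(TRUE, TRUE)),
    window = analysisWindow(-3000, 3000))
scanRegion(sim$genome, sim$tss, sim$window)
```

# ChIP-qPCR quantification

Binding evidence from chromatin immunoprecipitation is quantified as
fold enrichment over the non-immune IgG control,
`2^(IgG Ct − sample Ct)`, and expression as delta-delta-Ct fold change,
`2^−((Ct_target − Ct_ref) − (Ct_target,cal − Ct_ref,cal))`.
Amplification efficiency is fixed at 2 (perfect doubling) by default —
the usual assumption when primer efficiencies are near 100% — with an
`efficiency` parameter for assays where a standard curve says
otherwise.

`summarizeEnrichment()`/`summarizeExpression()` average replicate Cts
*before* exponentiation for the point estimate (standard ΔΔCt
practice, and the geometric-mean estimator on the fold scale) and use
per-replicate fold values only for dispersion, reported as mean ± SEM.
A condition missing a required role is a structured error; a single
replicate reports SEM as `NA`, never 0. Normality testing and ANOVA
are deliberately out of scope — the tidy per-condition output drops
straight into any stats package.

# Protein–DNA interface metrics

`readStructure()` parses (multi-MODEL) PDB files via bio3d, converts Å
to nm, and tags each atom's moiety from its residue name. Contacts are
**atom pairs** — not residue pairs — within a cutoff, default 0.6 nm,
the conventional maximum distance for effective amino-acid–nucleotide
interactions. The comparison is inclusive (≤): "within" is ambiguous
at the boundary, the boundary set has measure zero for real data, and
inclusiveness makes constructed tests bit-exact. Counting uses a
cell-list grid over cubic cells of edge `cutoff` (only the 27
neighbouring cells of an atom can hold partners) and compares squared
distances against `cutoff²` with the same arithmetic a brute-force scan
uses, so the two agree exactly, not just statistically.
`residueContactMap()` aggregates the same pairs by (chain, residue);
its total always equals the pair count. No periodic-boundary handling
is applied: inputs are treated as whole molecules in open space.

`calcRMSD()` applies an optimal least-squares rigid superposition
(Kabsch, via SVD with the determinant correction against reflections)
before taking RMS displacements, so a rigidly moved copy scores 0;
`superpose = FALSE` gives raw displacements. `calcRMSF()` measures
per-atom RMS displacement over a trailing window, against either the
window-mean structure (`"mean"`, the standard definition and the
default) or the window's first frame (`"first"`, the
"displacement from the starting structure" reading found in the
literature); both are exposed because the two definitions differ by up
to √2 on an oscillating atom and published methods sections often do
not say which was used. Per-residue values are means over each
residue's atoms.

# What the generators emulate — and what they do not

`simulateLocus()` draws a uniform-composition background, plants ACGTG
cores at requested TSS-relative offsets with controlled flanks, and
**destroys** any accidental sense-strand ACGTG elsewhere by single-base
substitution (iterating, since a substitution can create a new core).
Destruction rather than rejection sampling keeps generation O(length)
and makes the truth table exact: a scan recovers precisely the planted
candidates. Plants must start ≥ 8 bp apart so core+flank footprints
never collide. The background is uniform — real promoters are not
(ACGTG density is CpG-sensitive), so passing recovery tests
demonstrates correctness of the scanner, not calling performance on
real chromatin.

`simulateCtTable()` draws the control Ct as Normal(baseCt, noiseSd) and
the ChIP Ct as `baseCt − log2(trueFold)` plus the same noise, defaults
baseCt 25, noiseSd 0.2 cycles, triplicate reactions — typical SYBR
qPCR behaviour near 100% efficiency. It does not simulate
amplification curves, efficiency drift, or outlier wells.

`simulateTrajectory()` realizes an exact per-frame contact schedule:
protein atoms on a 2 nm grid, each DNA atom placed 0.45 nm from its
single protein partner when in contact and 1.0 nm away otherwise, so
counts survive the 0.001 Å rounding of PDB files. One partner per DNA
atom caps schedules at `min(nProtein, nDna)` contacts per frame;
larger schedules are rejected as infeasible. Optional oscillator atoms
alternate ± amplitude about a rest position far from the interface,
giving RMSF exactly equal to the amplitude about the mean structure
when the frame count is even (for odd counts the alternating mean is
offset by amplitude/n). There is no physics here — no force field, no
thermostat — only geometry constructed to make analysis code provably
correct.

All generator randomness flows from one explicit seed, and the
caller's RNG state is saved and restored, so identical calls are
byte-identical and never perturb surrounding code.

# Numerical and testing choices

* Recovery properties are exercised on 200 random 3 kb loci
  (window −800..+800, up to three plants each) — small enough that the
  full suite runs in well under a minute, large enough to cover both
  strands, empty loci, and every confidence/location combination.
* The qPCR bias check averages 500 seeded simulations at noise sd 0.2
  and n = 6, where the analytic sampling error of the mean log2
  estimate is ~0.005, an order of magnitude below the 0.05 acceptance
  band.
* Contact-grid equivalence runs 100 seeded 50+50-atom configurations
  across box sizes 1–8 nm, spanning dense to sparse packings.
* Kabsch RMSD is cross-checked against bio3d's independent fitted RMSD
  (which rounds to 3 decimals in Å, hence a 1e-3 comparison tolerance).

# Limitations

The scanner implements the core+flank rule only; it does not model
position-weight matrices, chromatin accessibility, conservation, or
ChIP-seq peak support, and genome-wide it would (correctly) report the
vast excess of RCGTG occurrences that are never bound in vivo. The
qPCR module assumes a shared efficiency across targets. The structure
module measures geometry on whatever frames it is given; it neither
generates nor validates dynamics.
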