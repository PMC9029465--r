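# HBStools

Discovery and quantification of HIF-1 binding sites (HBSs) around a
transcription start site, for regulatory genomicists studying
hypoxia-inducible transcription. The package covers the three
computational legs such a study stands on:

1. **Sequence prediction** — a strand-aware, zero-free TSS-relative
   coordinate system (TSS = +1, upstream base = −1, no 0), TSS mapping
   from an mRNA 5′ anchor, and a scanner for the minimal HBS core
   5′-A⁰CGTG-3′ that classifies each hit by the flanking-nucleotide
   rule: candidates carrying G⁻² and/or C⁺⁵ relative to A⁰ are
   high-probability HBSs, core-only hits are not. Export to BED6,
   GFF3 and CSV.
2. **ChIP-qPCR quantification** — fold enrichment over a non-immune
   IgG control, `2^(Ct_IgG − Ct_sample)`, and ΔΔCt relative expression,
   `2^−ΔΔCt`, with replicate-aware summaries (mean ± SEM).
3. **Structural interface metrics** — on multi-MODEL PDB structures:
   protein–DNA atom-pair contacts within an inclusive 0.6 nm cutoff
   (cell-list accelerated, provably equal to brute force), residue
   contact maps, Kabsch-superposed RMSD and trailing-window RMSF.

Seeded generators (`simulateLocus`, `simulateMrna`, `simulateCtTable`,
`simulateTrajectory`) produce synthetic inputs with serialized ground
truth, so the whole pipeline is testable without any downloads.

## Worked example

Scan a synthetic minus-strand locus carrying a planted upstream
enhancer-like site at −2186 and an intragenic site at +120:

```r
library(HBStools)

sim <- simulateLocus(seed = 7, length = 8000, tssPosition = 4000,
    strand = "-",
    planted = data.frame(rel = c(-2186, 120),
                         gMinus2 = c(TRUE, FALSE),
                         cPlus5 = c(TRUE, TRUE)),
    window = analysisWindow(-3000, 3000))
scanRegion(sim$genome, sim$tss, sim$window)
#> GRanges object with 2 ranges and 11 metadata columns:
#>       seqnames    ranges strand |  label   core relPosition absPosition
#>   [1]     chrS 6183-6187      - |     #1  ACGTG       -2186        6187
#>   [2]     chrS 3878-3882      - |     #2  ACGTG         120        3882
#>       flankMinus2 flankPlus5 hasGMinus2 hasCPlus5 confidence   location
#>   [1]           G          C       TRUE      TRUE       HIGH   UPSTREAM
#>   [2]           C          C      FALSE      TRUE       HIGH INTRAGENIC
```

Both planted cores are recovered at exactly their TSS-relative
positions; the −2186 site is UPSTREAM (an enhancer-compatible
position), and both are HIGH because each carries at least one of the
G⁻²/C⁺⁵ flanks. The ranges are the 5 genomic bases of each core
(minus strand: A⁰ at the high coordinate).

Quantify ChIP enrichment from a simulated Ct table (true folds 6 and
35, Ct noise sd 0.2, six replicates):

```r
ct <- simulateCtTable(seed = 11, conditions = c("normoxia", "hypoxia_12h"),
                      trueFold = c(6, 35), noiseSd = 0.2, replicates = 6)
summarizeEnrichment(ct$table, "HBS1_ChIP", "IgG")
#>     condition n fold_enrichment       sem
#> 1    normoxia 6         5.60840 0.4784303
#> 2 hypoxia_12h 6        34.81419 1.0911363
```

The estimates recover the generating folds within ~1 SEM. Contact
counting reproduces an engineered per-frame schedule exactly:

```r
tj <- simulateTrajectory(seed = 3, nProtein = 20, nDna = 20,
                         contactSchedule = c(12, 14, 18, 18, 18))
contactSeries(tj$trajectory, 2)
#> ContactSeries: 5 frames, mean over last 2 = 18
```

## Package tour

| Area | Functions |
| --- | --- |
| Coordinates | `strandedLocus`, `analysisWindow`, `absToRel`, `relToAbs`, `extractWindow` |
| TSS | `mapTss` |
| Scanning | `findCores`, `annotateFlanks`, `classifyConfidence`, `scanRegion`, `exportCandidates`, `readCandidates` |
| qPCR | `foldEnrichment`, `relativeExpression`, `readCtTable`, `summarizeEnrichment`, `summarizeExpression` |
| Structure | `readStructure`, `countContacts`, `contactSeries`, `residueContactMap`, `calcRMSD`, `calcRMSF`, `kabsch`, `writeTrajectoryPdb` |
| Synthetic data | `simulateLocus`, `simulateMrna`, `simulateCtTable`, `simulateTrajectory`, `writeTruth`, `readTruth` |

The methods vignette (`vignettes/hbs-discovery.Rmd`) documents the
model, the parameter defaults and why, the generators' scope, and known
limitations.
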