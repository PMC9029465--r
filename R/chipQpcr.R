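#' ChIP-qPCR fold enrichment from threshold cycles
#'
#' Fold enrichment of a ChIP sample over the non-immune IgG control:
#' `efficiency^(iggCt - sampleCt)`, i.e. `2^(IgG Ct - sample Ct)` at the
#' default perfect-doubling efficiency.  Each Ct unit corresponds to one
#' doubling of template at 100% amplification efficiency.
#'
#' @param sampleCt threshold cycle(s) of the ChIP sample.
#' @param iggCt threshold cycle(s) of the IgG control.
#' @param efficiency amplification base (default 2, perfect doubling).
#' @return Positive fold enrichment, vectorized.
#' @examples
#' foldEnrichment(25, 30)   # 32
#' foldEnrichment(30, 25)   # 1/32, depletion
#' @export
foldEnrichment <- function(sampleCt, iggCt, efficiency = 2) {
    stopifnot(all(is.finite(sampleCt)), all(is.finite(iggCt)),
              efficiency > 1)
    efficiency^(iggCt - sampleCt)
}

#' Delta-delta-Ct relative expression
#'
#' Fold change of a target gene, normalized to a reference (housekeeping)
#' gene and expressed relative to a calibrator condition:
#' `efficiency^-((targetCt - refCt) - (calTargetCt - calRefCt))`.
#'
#' @param targetCt,refCt sample threshold cycles (target / housekeeping).
#' @param calTargetCt,calRefCt calibrator-condition threshold cycles.
#' @param efficiency amplification base (default 2).
#' @return Positive fold change, vectorized; 1 when the sample equals the
#'   calibrator.
#' @examples
#' relativeExpression(22, 20, 24, 20)   # delta-Ct 2 vs 4 -> fold 4
#' @export
relativeExpression <- function(targetCt, refCt, calTargetCt, calRefCt,
                               efficiency = 2) {
    stopifnot(all(is.finite(c(targetCt, refCt, calTargetCt, calRefCt))),
              efficiency > 1)
    efficiency^(-((targetCt - refCt) - (calTargetCt - calRefCt)))
}

#' Read and validate a Ct table
#'
#' Expects CSV columns `sample_id`, `condition`, `target`, `replicate`,
#' `ct`; every Ct must be finite and positive.
#'
#' @param path CSV file path.
#' @return data.frame of Ct records.
#' @export
readCtTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    .checkCtTable(df)
    df
}

.checkCtTable <- function(df) {
    need <- c("sample_id", "condition", "target", "replicate", "ct")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("Ct table is missing column(s): ", paste(miss, collapse = ", "))
    if (any(!is.finite(df$ct)) || any(df$ct <= 0))
        stop("all Ct values must be finite and > 0")
    invisible(df)
}

.roleCts <- function(df, condition, target, role) {
    rows <- df[df$condition == condition & df$target == target, ,
               drop = FALSE]
    if (nrow(rows) == 0L)
        stop("missing role ", role, " for condition ", condition)
    rows[order(rows$replicate), ]
}

#' Summarize per-condition ChIP-qPCR enrichment
#'
#' For each condition, the point estimate is computed from replicate-mean
#' Cts, `efficiency^(mean IgG Ct - mean ChIP Ct)` (Cts are averaged
#' before exponentiation, standard delta-Ct practice); dispersion comes
#' from per-replicate fold values, with SEM = sd/sqrt(n).  A condition
#' lacking either role is a structured error; with a single replicate the
#' SEM is reported as `NA`, not 0.
#'
#' @param table data.frame of Ct records (see [readCtTable()]).
#' @param chipTarget target name of the ChIP sample rows.
#' @param iggTarget target name of the non-immune IgG rows.
#' @param efficiency amplification base (default 2).
#' @return data.frame with one row per condition: `condition`, `n`,
#'   `fold_enrichment`, `sem`.
#' @examples
#' tab <- simulateCtTable(seed = 1, conditions = "hypoxia_12h",
#'                        trueFold = 35, noiseSd = 0, replicates = 3)
#' summarizeEnrichment(tab$table, "HBS1_ChIP", "IgG")
#' @export
summarizeEnrichment <- function(table, chipTarget, iggTarget,
                                efficiency = 2) {
    .checkCtTable(table)
    conds <- unique(table$condition)
    res <- lapply(conds, function(cond) {
        chip <- .roleCts(table, cond, chipTarget, "chip_target")
        igg <- .roleCts(table, cond, iggTarget, "igg")
        point <- efficiency^(mean(igg$ct) - mean(chip$ct))
        n <- min(nrow(chip), nrow(igg))
        folds <- efficiency^(igg$ct[seq_len(n)] - chip$ct[seq_len(n)])
        data.frame(condition = cond, n = n, fold_enrichment = point,
                   sem = if (n > 1L) stats::sd(folds) / sqrt(n)
                         else NA_real_)
    })
    do.call(rbind, res)
}

#' Summarize per-condition relative expression (delta-delta-Ct)
#'
#' Point estimates use replicate-mean Cts per (condition, target); the
#' calibrator condition therefore gets fold change exactly 1.  Dispersion
#' uses per-replicate delta-Ct values against the calibrator's mean
#' delta-Ct.
#'
#' @param table data.frame of Ct records.
#' @param geneTarget target gene name (e.g. `"b3AR"`).
#' @param housekeepingTarget reference gene name (e.g. `"Rpl13a"`).
#' @param calibrator condition used as the expression baseline.
#' @param efficiency amplification base (default 2).
#' @return data.frame: `condition`, `n`, `fold_change`, `sem`.
#' @export
summarizeExpression <- function(table, geneTarget, housekeepingTarget,
                                calibrator, efficiency = 2) {
    .checkCtTable(table)
    if (!calibrator %in% table$condition)
        stop("calibrator condition '", calibrator, "' not in table")
    calGene <- .roleCts(table, calibrator, geneTarget, "gene")
    calRef <- .roleCts(table, calibrator, housekeepingTarget,
                       "housekeeping")
    calDelta <- mean(calGene$ct) - mean(calRef$ct)
    conds <- unique(table$condition)
    res <- lapply(conds, function(cond) {
        gene <- .roleCts(table, cond, geneTarget, "gene")
        ref <- .roleCts(table, cond, housekeepingTarget, "housekeeping")
        point <- efficiency^(-((mean(gene$ct) - mean(ref$ct)) - calDelta))
        n <- min(nrow(gene), nrow(ref))
        folds <- efficiency^(-((gene$ct[seq_len(n)] - ref$ct[seq_len(n)]) -
                               calDelta))
        data.frame(condition = cond, n = n, fold_change = point,
                   sem = if (n > 1L) stats::sd(folds) / sqrt(n)
                         else NA_real_)
    })
    do.call(rbind, res)
}
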