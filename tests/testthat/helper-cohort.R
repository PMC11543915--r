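suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
})

# small three-lineage cohort shared by several test files; built once per run
threeTypeSpec <- function(ids = c("ref", "query"), n_cells = c(400, 400),
                          seed = 1, n_genes = 600, lfc = 2,
                          batch_shift_sd = 0.1) {
  cohortSpec(ids, n_cells = n_cells,
             compositions = rep(list(c(EPI_ICM = 0.3, PE_I = 0.2,
                                       TE = 0.5)), length(ids)),
             n_genes = n_genes, marker_log_fold_change = lfc,
             intermediate_fraction = 0, batch_shift_sd = batch_shift_sd,
             seed = seed)
}

normalizedCohort <- function(spec) {
  lapply(generateCohort(spec), function(d) logNormalize(qcFilter(d)$dataset))
}

primaryTruth <- function(ds) {
  tt <- trueType(ds)
  tt[tt %in% c("PE_I", "PE_II")] <- "PE"
  tt[tt == "intermediate_EPI_TE"] <- "unknown"
  tt
}

countsOf <- function(ds) as.matrix(assay(ds, "counts"))

# tiny deterministic ExpressionDataset from a dense matrix
toyDataset <- function(m, platform = "umi", id = "toy", ...) {
  ExpressionDataset(m, dataset_id = id, platform = platform, ...)
}
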