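#' @importFrom stats rnorm rlnorm rnbinom rbeta runif rbinom median
NULL

.CELL_TYPES <- c("EPI_ICM", "PE_I", "PE_II", "TE", "intermediate_EPI_TE")
.MT_GENES <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6",
                             "CO3", "ND3", "ND4L", "ND4", "ND5", "ND6",
                             "CYB"))

#' Composition archetypes
#'
#' Named cell-type proportion vectors for the three composition archetypes
#' observed across embryo models: \code{"balanced"} (blastocyst-like,
#' TE-majority), \code{"epi_enriched"} and \code{"pe_enriched"}. A fraction
#' \code{intermediate_fraction} of cells is carved out for
#' EPI/TE-intermediate cells, the remainder rescaled.
#'
#' @param archetype one of \code{"balanced"}, \code{"epi_enriched"},
#'   \code{"pe_enriched"}.
#' @param intermediate_fraction proportion in [0,1) of intermediate cells.
#' @return named numeric vector over the five cell types, summing to 1.
#' @export
archetypeComposition <- function(archetype = c("balanced", "epi_enriched",
                                               "pe_enriched"),
                                 intermediate_fraction = 0.05) {
  archetype <- match.arg(archetype)
  base <- switch(archetype,
    balanced     = c(EPI_ICM = 0.25, PE_I = 0.10, PE_II = 0.05, TE = 0.60),
    epi_enriched = c(EPI_ICM = 0.60, PE_I = 0.05, PE_II = 0.05, TE = 0.30),
    pe_enriched  = c(EPI_ICM = 0.15, PE_I = 0.25, PE_II = 0.30, TE = 0.30))
  comp <- c(base * (1 - intermediate_fraction),
            intermediate_EPI_TE = intermediate_fraction)
  comp
}

#' Specify a synthetic multi-dataset cohort
#'
#' Defines the study conditions for \code{\link{generateCohort}}: a set of
#' datasets of differing size and platform (UMI counts vs TPM), planted cell
#' types with marker-gene overexpression, per-cell mitochondrial fractions
#' and a fraction of intermediate cells interpolating the epiblast and
#' trophectoderm programs.
#'
#' @param dataset_ids character vector of unique dataset names.
#' @param platforms \code{"umi"} or \code{"tpm"}, recycled to the number of
#'   datasets.
#' @param n_cells integer cells per dataset, recycled.
#' @param compositions either a list of named proportion vectors over the
#'   cell types (one per dataset), or \code{NULL} to derive them from
#'   \code{archetypes}.
#' @param archetypes character vector of archetype names, recycled; used
#'   when \code{compositions} is \code{NULL}.
#' @param n_genes total number of genes (must cover all marker genes).
#' @param marker_log_fold_change natural-log inflation of marker-gene means
#'   within their lineage (default 2).
#' @param intermediate_fraction proportion of intermediate cells used when
#'   building compositions from archetypes.
#' @param mito_fraction_params \code{c(mean, dispersion)} of the Beta-like
#'   per-cell mitochondrial fraction; concentration is \code{1/dispersion}.
#' @param dropout_rate Bernoulli zero-inflation probability applied after
#'   sampling (default 0; negative-binomial counts are already zero-rich).
#' @param batch_shift_sd sd of a per-dataset log-normal gene-level shift.
#' @param dispersion negative-binomial gene-level dispersion (default 0.3).
#' @param mean_depth mean library size for UMI cells.
#' @param simulate_mito_genes if \code{TRUE}, a designated "MT-" gene block
#'   is inflated so each cell's realized mitochondrial share matches its
#'   drawn \code{mito_fraction}, exercising the QC filter path end-to-end.
#' @param seed integer cohort seed; per-dataset sub-seeds are
#'   \code{seed + dataset index}.
#' @return an object of class \code{CohortSpec} (a validated list).
#' @export
cohortSpec <- function(dataset_ids, platforms = "umi", n_cells = 500,
                       compositions = NULL, archetypes = "balanced",
                       n_genes = 2000, marker_log_fold_change = 2,
                       intermediate_fraction = 0.05,
                       mito_fraction_params = c(mean = 0.05,
                                                dispersion = 0.02),
                       dropout_rate = 0, batch_shift_sd = 0.1,
                       dispersion = 0.3, mean_depth = 8000,
                       simulate_mito_genes = FALSE, seed = 1) {
  n <- length(dataset_ids)
  if (n < 1L || anyDuplicated(dataset_ids))
    stop("dataset_ids must be non-empty and unique")
  platforms <- rep_len(platforms, n)
  n_cells <- rep_len(as.integer(n_cells), n)
  archetypes <- rep_len(archetypes, n)
  if (is.null(compositions)) {
    compositions <- lapply(archetypes, archetypeComposition,
                           intermediate_fraction = intermediate_fraction)
  } else {
    compositions <- lapply(compositions, function(comp) {
      full <- setNames(numeric(length(.CELL_TYPES)), .CELL_TYPES)
      bad <- setdiff(names(comp), .CELL_TYPES)
      if (length(bad))
        stop("unknown cell types in composition: ", paste(bad, collapse = ", "))
      full[names(comp)] <- comp
      full
    })
    archetypes <- rep_len("custom", n)
  }
  for (comp in compositions) {
    if (any(comp < 0)) stop("composition proportions must be non-negative")
    if (abs(sum(comp) - 1) > 1e-9)
      stop("composition must sum to 1 (got ", sum(comp), ")")
  }
  panel <- defaultMarkerPanel()
  marker_genes <- unique(unlist(markerSets(panel), use.names = FALSE))
  n_required <- length(marker_genes) +
    if (simulate_mito_genes) length(.MT_GENES) else 0L
  if (n_genes < n_required)
    stop("n_genes (", n_genes, ") smaller than total marker count (",
         n_required, ")")
  if (!all(platforms %in% c("umi", "tpm")))
    stop("platforms must be 'umi' or 'tpm'")
  stopifnot(all(n_cells > 0), marker_log_fold_change >= 0,
            intermediate_fraction >= 0, intermediate_fraction < 1,
            dropout_rate >= 0, dropout_rate < 1, batch_shift_sd >= 0,
            dispersion > 0)
  structure(list(
    dataset_ids = dataset_ids, platforms = platforms, n_cells = n_cells,
    compositions = compositions, archetypes = archetypes, n_genes = n_genes,
    marker_log_fold_change = marker_log_fold_change,
    intermediate_fraction = intermediate_fraction,
    mito_fraction_params = mito_fraction_params,
    dropout_rate = dropout_rate, batch_shift_sd = batch_shift_sd,
    dispersion = dispersion, mean_depth = mean_depth,
    simulate_mito_genes = simulate_mito_genes, seed = as.integer(seed)),
    class = "CohortSpec")
}

# gene universe and per-type expression programs shared by all datasets
.cohortPrograms <- function(spec) {
  panel <- markerSets(defaultMarkerPanel())
  marker_genes <- unique(unlist(panel, use.names = FALSE))
  mt <- if (spec$simulate_mito_genes) .MT_GENES else character()
  n_bg <- spec$n_genes - length(marker_genes) - length(mt)
  genes <- c(marker_genes, mt,
             if (n_bg > 0) sprintf("GENE%05d", seq_len(n_bg)))
  lambda <- setNames(rlnorm(length(genes), meanlog = 0, sdlog = 1), genes)
  lfc <- spec$marker_log_fold_change
  # lineage programs: markers inflated by exp(lfc) within their lineage;
  # AMN markers ride along with the PE_II program
  program_markers <- list(
    EPI_ICM = panel$EPI_ICM,
    PE_I    = panel$PE,
    PE_II   = c(panel$PE, panel$AMN),
    TE      = panel$TE)
  programs <- vapply(names(program_markers), function(tp) {
    p <- lambda
    p[program_markers[[tp]]] <- p[program_markers[[tp]]] * exp(lfc)
    p
  }, numeric(length(genes)))
  rownames(programs) <- genes
  list(genes = genes, programs = programs, mt_genes = mt)
}

#' Generate a synthetic cohort
#'
#' Draws one \linkS4class{ExpressionDataset} per dataset in the spec. UMI
#' datasets contain non-negative integer counts from a negative-binomial
#' model (gene-level dispersion \code{spec$dispersion}) with per-lineage
#' marker mean inflation of \code{exp(marker_log_fold_change)}; TPM datasets
#' contain non-negative reals rescaled so each cell sums to 1e6. Cells carry
#' \code{true_type}, \code{dataset_id} and \code{mito_fraction}; intermediate
#' cells mix the epiblast and trophectoderm programs with a weight uniform
#' on (0,1), recorded in \code{mixture_weight}. Identical spec and seed give
#' byte-identical output; the caller's RNG state is preserved.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return named list of \linkS4class{ExpressionDataset}.
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  withr::with_seed(spec$seed, {
    shared <- .cohortPrograms(spec)
    out <- vector("list", length(spec$dataset_ids))
    names(out) <- spec$dataset_ids
    for (i in seq_along(spec$dataset_ids)) {
      set.seed(spec$seed + i)
      out[[i]] <- .generateDataset(spec, i, shared)
    }
    out
  })
}

.generateDataset <- function(spec, i, shared) {
  n_cells <- spec$n_cells[i]
  platform <- spec$platforms[i]
  genes <- shared$genes
  progs <- shared$programs

  # per-dataset batch shift on gene means
  shift <- exp(rnorm(length(genes), 0, spec$batch_shift_sd))
  progs <- progs * shift
  progs <- sweep(progs, 2, colSums(progs), "/")

  comp <- spec$compositions[[i]]
  types <- sample(names(comp), n_cells, replace = TRUE, prob = comp)
  w <- rep(NA_real_, n_cells)
  is_int <- types == "intermediate_EPI_TE"
  w[is_int] <- runif(sum(is_int))

  # per-cell relative expression program (genes x cells)
  P <- progs[, ifelse(is_int, "EPI_ICM", types), drop = FALSE]
  if (any(is_int))
    P[, is_int] <- P[, is_int, drop = FALSE] * rep(w[is_int],
                                                   each = length(genes)) +
      progs[, "TE"] %o% (1 - w[is_int])

  mp <- spec$mito_fraction_params
  conc <- 1 / mp[["dispersion"]]
  mito_f <- rbeta(n_cells, mp[["mean"]] * conc, (1 - mp[["mean"]]) * conc)
  if (spec$simulate_mito_genes) {
    mt_idx <- match(shared$mt_genes, genes)
    mt_share <- colSums(P[mt_idx, , drop = FALSE])
    P[mt_idx, ] <- sweep(P[mt_idx, , drop = FALSE], 2,
                         mito_f / mt_share, "*")
    P[-mt_idx, ] <- sweep(P[-mt_idx, , drop = FALSE], 2,
                          (1 - mito_f) / (1 - mt_share), "*")
  }

  if (platform == "umi") {
    depth <- rlnorm(n_cells, log(spec$mean_depth), 0.3)
    mu <- sweep(P, 2, depth, "*")
    x <- matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
                nrow = length(genes))
  } else {
    noise <- matrix(rlnorm(length(genes) * n_cells, 0, 0.5),
                    nrow = length(genes))
    x <- P * noise * 1e6
  }
  if (spec$dropout_rate > 0) {
    keep <- matrix(runif(length(x)) >= spec$dropout_rate, nrow = nrow(x))
    x <- x * keep
  }
  if (platform == "tpm") {
    tot <- colSums(x)
    if (any(tot == 0)) stop("TPM cell with zero total generated")
    x <- sweep(x, 2, 1e6 / tot, "*")
  }
  dimnames(x) <- list(genes,
                      sprintf("%s_cell%05d", spec$dataset_ids[i],
                              seq_len(n_cells)))
  ExpressionDataset(Matrix::Matrix(x, sparse = (platform == "umi")),
                    dataset_id = spec$dataset_ids[i], platform = platform,
                    mito_fraction = mito_f, true_type = types,
                    extra_coldata = data.frame(mixture_weight = w))
}

#' Report realized marker log-fold-changes in a generated cohort
#'
#' For each scored lineage, reports the natural-log ratio of mean
#' depth-normalized marker expression in-lineage versus out-of-lineage,
#' averaged over the lineage's markers. Serves as ground truth in recovery
#' tests. Lineage-to-cell mapping: EPI_ICM -> EPI_ICM cells; PE -> PE_I and
#' PE_II; TE -> TE; AMN -> PE_II (amnion markers ride with the PE_II
#' program). Lineages without in- or out-of-lineage cells are flagged
#' missing, not errored.
#'
#' @param cohort list of \linkS4class{ExpressionDataset} from
#'   \code{\link{generateCohort}}.
#' @return data.frame with columns lineage, realized_lfc, n_in, n_out,
#'   missing.
#' @export
plantedMarkerReport <- function(cohort) {
  panel <- markerSets(defaultMarkerPanel())
  lineage_cells <- list(EPI_ICM = "EPI_ICM", PE = c("PE_I", "PE_II"),
                        TE = "TE", AMN = "PE_II")
  mats <- lapply(cohort, function(ds) {
    m <- assay(ds, "counts")
    sweep_div <- Matrix::t(Matrix::t(m) / Matrix::colSums(m))
    sweep_div
  })
  norm <- do.call(cbind, mats)
  types <- unlist(lapply(cohort, trueType), use.names = FALSE)
  res <- lapply(names(lineage_cells), function(lin) {
    markers <- intersect(panel[[lin]], rownames(norm))
    inc <- types %in% lineage_cells[[lin]]
    outc <- !inc & types != "intermediate_EPI_TE"
    if (!any(inc) || !any(outc) || !length(markers))
      return(data.frame(lineage = lin, realized_lfc = NA_real_,
                        n_in = sum(inc), n_out = sum(outc), missing = TRUE))
    m_in <- Matrix::rowMeans(norm[markers, inc, drop = FALSE])
    m_out <- Matrix::rowMeans(norm[markers, outc, drop = FALSE])
    eff <- log(m_in) - log(m_out)
    data.frame(lineage = lin, realized_lfc = mean(eff), n_in = sum(inc),
               n_out = sum(outc), missing = FALSE)
  })
  do.call(rbind, res)
}

#' Write / read a cohort on disk
#'
#' UMI datasets are written as a 10x-style MTX triplet (matrix.mtx,
#' barcodes.tsv, features.tsv) in a per-dataset directory; TPM datasets as a
#' dense TSV. Truth labels go to \code{truth.tsv} (cell_id, dataset_id,
#' true_type) and the spec round-trips through \code{spec.yaml}.
#'
#' @param cohort list of \linkS4class{ExpressionDataset}.
#' @param spec the generating \code{\link{cohortSpec}}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in cohort) {
    sub <- file.path(dir, datasetId(ds))
    writeDataset(ds, sub)
  }
  truth <- do.call(rbind, lapply(cohort, function(ds) {
    data.frame(cell_id = colnames(ds), dataset_id = datasetId(ds),
               true_type = trueType(ds))
  }))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeCohortSpec(spec, file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' @rdname writeCohort
#' @param path file path for the YAML spec.
#' @export
writeCohortSpec <- function(spec, path) {
  lst <- unclass(spec)
  lst$compositions <- lapply(lst$compositions, as.list)
  lst$mito_fraction_params <- as.list(lst$mito_fraction_params)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohortSpec <- function(path) {
  lst <- yaml::read_yaml(path)
  cohortSpec(
    dataset_ids = unlist(lst$dataset_ids),
    platforms = unlist(lst$platforms),
    n_cells = unlist(lst$n_cells),
    compositions = lapply(lst$compositions, unlist),
    n_genes = lst$n_genes,
    marker_log_fold_change = lst$marker_log_fold_change,
    intermediate_fraction = lst$intermediate_fraction,
    mito_fraction_params = unlist(lst$mito_fraction_params),
    dropout_rate = lst$dropout_rate, batch_shift_sd = lst$batch_shift_sd,
    dispersion = lst$dispersion, mean_depth = lst$mean_depth,
    simulate_mito_genes = lst$simulate_mito_genes, seed = lst$seed)
}
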