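#' @import methods
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assays assayNames colData rowData
#'   colData<- rowData<- assay<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' ExpressionDataset: one study's expression matrix with per-cell metadata
#'
#' A thin extension of \linkS4class{SingleCellExperiment} representing a
#' single dataset (study) in a cross-study comparison: a genes-by-cells
#' matrix in the \code{"counts"} assay (UMI counts for droplet data, TPM for
#' plate-based data), plus required per-cell metadata columns
#' \code{dataset_id}, \code{platform}, \code{n_features},
#' \code{total_counts} and \code{mito_fraction}, and optionally
#' \code{true_type} for simulated data with known ground truth.
#'
#' Validity requires non-negative matrix entries, unique cell and gene
#' identifiers, and \code{n_features}/\code{total_counts} to equal values
#' recomputed from the matrix. For TPM data that has not yet been
#' QC-filtered, per-cell sums must equal 1e6 within a relative tolerance of
#' 1e-3.
#'
#' @export
setClass("ExpressionDataset", contains = "SingleCellExperiment")

.REQUIRED_COLDATA <- c("dataset_id", "platform", "n_features",
                       "total_counts", "mito_fraction")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  m <- assay(object, "counts")
  vals <- if (inherits(m, "sparseMatrix")) m@x else m
  if (length(vals) && (any(!is.finite(vals)) || min0(m) < 0))
    msg <- c(msg, "matrix entries must be non-negative and finite")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "cell_ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene_ids must be unique")
  missing_cd <- setdiff(.REQUIRED_COLDATA, colnames(colData(object)))
  if (length(missing_cd)) {
    msg <- c(msg, paste0("missing colData columns: ",
                         paste(missing_cd, collapse = ", ")))
  } else if (ncol(object) > 0) {
    nf <- Matrix::colSums(m > 0)
    tc <- Matrix::colSums(m)
    if (!isTRUE(all(nf == colData(object)$n_features)))
      msg <- c(msg, "n_features does not match the matrix")
    if (max(abs(tc - colData(object)$total_counts)) > 1e-6 * max(1, max(tc)))
      msg <- c(msg, "total_counts does not match the matrix")
    mf <- colData(object)$mito_fraction
    if (any(mf < 0 | mf > 1)) msg <- c(msg, "mito_fraction must lie in [0,1]")
    plat <- unique(colData(object)$platform)
    if (!all(plat %in% c("umi", "tpm")))
      msg <- c(msg, "platform must be 'umi' or 'tpm'")
    if (identical(plat, "tpm") && !isTRUE(metadata(object)$qc_filtered)) {
      if (max(abs(tc - 1e6)) > 1e-3 * 1e6)
        msg <- c(msg, "pre-filter TPM cells must sum to 1e6 (rel. tol 1e-3)")
    }
  }
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimum of a dense or sparse matrix, treating an empty matrix as 0
min0 <- function(m) {
  if (length(m) == 0) return(0)
  if (inherits(m, "sparseMatrix")) min(0, min(m@x %||% 0)) else min(m)
}

#' Construct an ExpressionDataset
#'
#' @param counts genes-by-cells matrix (dense or \pkg{Matrix} sparse);
#'   non-negative. UMI counts or TPM values depending on \code{platform}.
#' @param dataset_id single string naming the dataset.
#' @param platform \code{"umi"} or \code{"tpm"}.
#' @param mito_fraction numeric vector in [0,1], one per cell; defaults to 0.
#' @param true_type optional character vector of ground-truth cell types.
#' @param extra_coldata optional data.frame of further per-cell covariates.
#' @param qc_filtered logical; set \code{TRUE} for matrices that already went
#'   through QC (relaxes the TPM sum-to-1e6 invariant).
#' @return an \linkS4class{ExpressionDataset}.
#' @export
ExpressionDataset <- function(counts, dataset_id, platform = c("umi", "tpm"),
                              mito_fraction = NULL, true_type = NULL,
                              extra_coldata = NULL, qc_filtered = FALSE) {
  platform <- match.arg(platform)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("%s_cell%04d", dataset_id, seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (is.null(mito_fraction)) mito_fraction <- rep(0, ncol(counts))
  cd <- DataFrame(
    dataset_id = rep(dataset_id, ncol(counts)),
    platform = rep(platform, ncol(counts)),
    n_features = as.integer(Matrix::colSums(counts > 0)),
    total_counts = as.numeric(Matrix::colSums(counts)),
    mito_fraction = as.numeric(mito_fraction),
    row.names = colnames(counts))
  if (!is.null(true_type)) cd$true_type <- true_type
  if (!is.null(extra_coldata)) cd <- cbind(cd, DataFrame(extra_coldata))
  sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd)
  metadata(sce)$qc_filtered <- isTRUE(qc_filtered)
  new("ExpressionDataset", sce)
}

#' @rdname ExpressionDataset
#' @param x an ExpressionDataset.
#' @export
datasetId <- function(x) unique(colData(x)$dataset_id)

#' @rdname ExpressionDataset
#' @export
platformType <- function(x) unique(colData(x)$platform)

#' @rdname ExpressionDataset
#' @export
trueType <- function(x) colData(x)$true_type

setMethod("show", "ExpressionDataset", function(object) {
  cat(sprintf("ExpressionDataset '%s' (%s): %d genes x %d cells\n",
              datasetId(object), platformType(object),
              nrow(object), ncol(object)))
  cat(sprintf("  assays: %s; qc_filtered: %s\n",
              paste(assayNames(object), collapse = ", "),
              isTRUE(metadata(object)$qc_filtered)))
})

#' MarkerPanel: lineage -> positive marker genes
#'
#' Houses the curated lineage marker table used for annotation and module
#' scoring. \code{defaultMarkerPanel()} returns the literature-procured
#' panel for pre- and peri-implantation lineages (epiblast/ICM, primitive
#' endoderm, trophectoderm, amnion, extravillous cytotrophoblast,
#' syncytiotrophoblast).
#'
#' @slot sets named list of character vectors (lineage -> marker symbols).
#' @export
setClass("MarkerPanel", representation(sets = "list"))

setValidity("MarkerPanel", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "lineage names must be present and unique")
  dup <- vapply(object@sets, anyDuplicated, 1L) > 0
  if (any(dup))
    msg <- c(msg, paste0("duplicate genes within lineage(s): ",
                         paste(names(object@sets)[dup], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname MarkerPanel-class
#' @param sets named list of character vectors.
#' @export
MarkerPanel <- function(sets) new("MarkerPanel", sets = sets)

#' @rdname MarkerPanel-class
#' @export
defaultMarkerPanel <- function() {
  MarkerPanel(list(
    EPI_ICM = c("SUSD2", "NANOG", "KLF17", "FGF4", "BMP2", "LAMA4"),
    PE      = c("GATA4", "PDGFRA", "SOX17", "GATA6"),
    TE      = c("GATA3", "TACSTD2", "FABP3"),
    AMN     = c("BAMBI", "COL5A1", "ISL1", "KCNMA1", "KRT19", "PODXL", "VTCN1"),
    EVT     = c("CSH1", "CSH2", "DLX5", "DLX6", "ERBB2", "HLA-G", "KRT7",
                "MMP2", "RXRA"),
    STB     = c("CGB1", "CGB2", "CGB5", "CGB7", "CGB8", "ERVFRD-1", "ESRRG",
                "FOXO6", "MAFK", "PSG3", "TBX3", "TCL6")))
}

#' @rdname MarkerPanel-class
#' @param x a MarkerPanel.
#' @export
markerSets <- function(x) x@sets

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel with %d lineages:\n", length(object@sets)))
  for (nm in names(object@sets))
    cat(sprintf("  %s (%d): %s\n", nm, length(object@sets[[nm]]),
                paste(object@sets[[nm]], collapse = ", ")))
})

#' ModuleScoreTable: per-cell module scores
#'
#' Cell-by-module matrix of lineage module scores with a variant tag
#' (\code{"raw"}, \code{"minmax"} or \code{"zscaled_by_dataset"}), the
#' dataset of origin of every cell, and scoring provenance (panel hash,
#' number of expression bins, number of control genes, seed).
#'
#' @slot scores numeric matrix, cells x modules.
#' @slot dataset character, dataset id per cell.
#' @slot variant character scalar.
#' @slot provenance list.
#' @export
setClass("ModuleScoreTable",
         representation(scores = "matrix", dataset = "character",
                        variant = "character", provenance = "list"))

setValidity("ModuleScoreTable", function(object) {
  msg <- character()
  if (length(object@dataset) != nrow(object@scores))
    msg <- c(msg, "one dataset id per row (cell) required")
  if (!object@variant %in% c("raw", "minmax", "zscaled_by_dataset"))
    msg <- c(msg, "unknown variant tag")
  if (length(msg)) msg else TRUE
})

#' @rdname ModuleScoreTable-class
#' @param x a ModuleScoreTable.
#' @export
moduleScores <- function(x) x@scores

#' @rdname ModuleScoreTable-class
#' @export
scoreVariant <- function(x) x@variant

#' @rdname ModuleScoreTable-class
#' @export
scoreDataset <- function(x) x@dataset

setMethod("show", "ModuleScoreTable", function(object) {
  cat(sprintf("ModuleScoreTable (%s): %d cells x %d modules [%s]\n",
              object@variant, nrow(object@scores), ncol(object@scores),
              paste(colnames(object@scores), collapse = ", ")))
})

#' AnnotationTable: per-cell labels from three annotators plus consensus
#'
#' @slot labels data.frame with columns cell_id, dataset_id,
#'   annotator_cluster, annotator_cell, annotator_ref, consensus.
#' @export
setClass("AnnotationTable", representation(labels = "data.frame"))

setValidity("AnnotationTable", function(object) {
  need <- c("cell_id", "dataset_id", "annotator_cluster", "annotator_cell",
            "annotator_ref", "consensus")
  missing <- setdiff(need, colnames(object@labels))
  if (length(missing))
    return(paste0("missing columns: ", paste(missing, collapse = ", ")))
  lab <- object@labels
  ok <- mapply(function(a, b, c, cons) {
    base <- sub("^PE_(I|II)$", "PE", cons)
    cons == "unknown" || sum(c(a, b, c) == base) >= 2 ||
      sum(c(a, b, c) == cons) >= 2
  }, lab$annotator_cluster, lab$annotator_cell, lab$annotator_ref,
     lab$consensus)
  if (!all(ok))
    return("consensus must be held by >= 2 annotators or be 'unknown'")
  TRUE
})

#' @rdname AnnotationTable-class
#' @param labels the label data.frame.
#' @export
AnnotationTable <- function(labels) new("AnnotationTable", labels = labels)

#' @rdname AnnotationTable-class
#' @param x an AnnotationTable.
#' @export
annotationLabels <- function(x) x@labels

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d cells\n", nrow(object@labels)))
  print(table(object@labels$consensus))
})

#' DistanceMatrix: symmetric dataset-by-dataset distances
#'
#' @slot mat symmetric numeric matrix (NA where undefined).
#' @slot metric one of \code{"jsd"}, \code{"pcd"}, \code{"ks_mean"},
#'   \code{"euclidean"}.
#' @slot defined logical matrix, validity mask (FALSE where the entry is
#'   undefined, e.g. PCD pairs with too few shared clusters).
#' @slot info list of metric-specific provenance.
#' @export
setClass("DistanceMatrix",
         representation(mat = "matrix", metric = "character",
                        defined = "matrix", info = "list"))

setValidity("DistanceMatrix", function(object) {
  m <- object@mat
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  d <- m[object@defined]
  if (length(d) && max(abs(m - t(m)), na.rm = TRUE) > 1e-12)
    msg <- c(msg, "matrix must be symmetric")
  if (!object@metric %in% c("jsd", "pcd", "ks_mean", "euclidean"))
    msg <- c(msg, "unknown metric tag")
  if (length(msg)) msg else TRUE
})

DistanceMatrixObj <- function(mat, metric, defined = NULL, info = list()) {
  if (is.null(defined)) defined <- !is.na(mat)
  new("DistanceMatrix", mat = mat, metric = metric, defined = defined,
      info = info)
}

#' @rdname DistanceMatrix-class
#' @param x a DistanceMatrix.
#' @export
distanceMatrix <- function(x) x@mat

#' @rdname DistanceMatrix-class
#' @export
distanceMetric <- function(x) x@metric

#' @rdname DistanceMatrix-class
#' @export
definedMask <- function(x) x@defined

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix [%s]: %d x %d (%d undefined entries)\n",
              object@metric, nrow(object@mat), ncol(object@mat),
              sum(!object@defined)))
})
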