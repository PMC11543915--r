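#' @importFrom stats lm.fit sd var cor prcomp p.adjust wilcox.test
NULL

#' Pseudo-log normalization
#'
#' UMI data: \code{ln(1 + count * scale_factor / cell_total)} (default
#' scale factor 1e4); TPM data: \code{ln(1 + tpm)}. Cell totals must be
#' strictly positive — zero-total cells should have been removed by QC.
#' The result is stored in the \code{"logcounts"} assay.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param scale_factor UMI depth-normalization target.
#' @return \code{ds} with a \code{"logcounts"} assay added.
#' @export
logNormalize <- function(ds, scale_factor = 1e4) {
  m <- assay(ds, "counts")
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stop("cell(s) with total 0 encountered; run qcFilter first")
  if (platformType(ds) == "umi") {
    if (inherits(m, "CsparseMatrix")) {
      fac <- scale_factor / tot
      x <- m
      x@x <- log1p(m@x * rep.int(fac, diff(m@p)))
    } else {
      x <- log1p(sweep(as.matrix(m), 2, scale_factor / tot, "*"))
    }
  } else {
    x <- m
    if (inherits(m, "CsparseMatrix")) x@x <- log1p(m@x)
    else x <- log1p(as.matrix(m))
  }
  assay(ds, "logcounts") <- x
  ds
}

.logcounts <- function(x) {
  if (is(x, "ExpressionDataset")) {
    if (!"logcounts" %in% assayNames(x))
      stop("run logNormalize() first")
    assay(x, "logcounts")
  } else x
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: a degree-2 polynomial trend of
#' log(variance) on log(mean) is fit over all expressed genes and genes are
#' ranked by their residual from the trend. Constant genes are never
#' selected.
#'
#' @param x normalized matrix (genes x cells) or an
#'   \linkS4class{ExpressionDataset} with logcounts.
#' @param n_top number of genes to return (default 3000); if fewer genes
#'   are available all are returned with a warning.
#' @return character vector of gene names, ranked most to least variable.
#' @export
selectVariableGenes <- function(x, n_top = 3000) {
  m <- .logcounts(x)
  mu <- as.numeric(Matrix::rowMeans(m))
  v <- .rowVars(m, mu)
  expressed <- mu > 0 & v > 0
  if (sum(expressed) < 10)
    stop("fewer than 10 expressed genes; variance trend unfittable")
  lm_mu <- log(mu[expressed])
  lm_v <- log(v[expressed])
  fit <- lm.fit(cbind(1, lm_mu, lm_mu^2), lm_v)
  resid <- setNames(fit$residuals, rownames(m)[expressed])
  ranked <- names(sort(resid, decreasing = TRUE))
  if (n_top > length(ranked)) {
    warning("only ", length(ranked), " expressed genes available; ",
            "returning all")
    n_top <- length(ranked)
  }
  ranked[seq_len(n_top)]
}

.rowVars <- function(m, mu = Matrix::rowMeans(m)) {
  n <- ncol(m)
  if (n < 2) return(rep(0, nrow(m)))
  as.numeric(Matrix::rowMeans(m^2) - mu^2) * n / (n - 1)
}

#' Regress out technical covariates
#'
#' Per gene, ordinary least squares of the normalized values on the given
#' covariates (spike-in fraction, feature/count totals, cell-cycle scores,
#' ...); residuals are z-scored per gene and clipped at +/-10. Collinear
#' covariates are dropped (later duplicates) with a warning. With no (or
#' all-zero) covariates this reduces to plain per-gene z-scoring.
#'
#' @param x normalized matrix or \linkS4class{ExpressionDataset}.
#' @param covariates data.frame of per-cell covariates (may be empty).
#' @param clip residual z-score clip value.
#' @return dense matrix of clipped, z-scored residuals (genes x cells).
#' @export
residualizeCovariates <- function(x, covariates = NULL, clip = 10) {
  m <- as.matrix(.logcounts(x))
  n <- ncol(m)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    if (any(!vapply(covariates, function(col) all(is.finite(col)), TRUE)))
      stop("covariates must be finite")
    X <- cbind(X, as.matrix(covariates))
  }
  if (n < ncol(X) + 2)
    stop("need at least 2 more cells than covariates")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping collinear covariate(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  fit <- lm.fit(X, t(m))
  res <- t(as.matrix(fit$residuals))
  mu <- rowMeans(res)
  s <- sqrt(.rowVars(res, mu))
  # a residual sd at numerical-noise scale relative to the input row means
  # a perfect fit, not real variation to be rescaled
  floor_s <- 1e-10 * pmax(sqrt(.rowVars(m)), 1)
  degenerate <- s <= floor_s
  z <- (res - mu) / ifelse(degenerate, 1, s)
  z[degenerate, ] <- 0
  dimnames(z) <- dimnames(m)
  pmin(pmax(z, -clip), clip)
}

#' Bin-matched module score
#'
#' Per-cell score of a gene set against expression-matched random controls:
#' genes are binned into \code{n_bins} equal-frequency bins by across-cell
#' average expression (ties broken by gene index); for each set gene,
#' \code{n_ctrl} control genes are sampled from its bin (without
#' replacement, or with replacement when the bin is smaller than
#' \code{n_ctrl}); the score of a cell is the mean expression of the set
#' genes minus the mean expression over all sampled control genes. Sampling
#' is seeded; identical inputs and seed give bitwise-identical scores.
#'
#' @param x normalized matrix (genes x cells) or
#'   \linkS4class{ExpressionDataset}.
#' @param gene_set character vector of gene names; absent genes are dropped
#'   with a warning, an empty intersection is an error.
#' @param n_bins,n_ctrl binning and control-sampling parameters.
#' @param seed integer seed for the control draw.
#' @param set_name label used in error messages.
#' @return numeric per-cell score vector.
#' @export
moduleScore <- function(x, gene_set, n_bins = 25, n_ctrl = 100, seed = 0,
                        set_name = "gene set") {
  m <- .logcounts(x)
  present <- intersect(gene_set, rownames(m))
  if (!length(present))
    stop("no genes of '", set_name, "' are present in the matrix")
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present), " gene(s) of '", set_name,
            "' absent from the matrix; dropped")
  bins <- .expressionBins(m, n_bins)
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(present, function(g) {
      members <- which(bins == bins[g])
      sample(members, n_ctrl, replace = length(members) < n_ctrl)
    }), use.names = FALSE)
  })
  marker_mean <- Matrix::colMeans(m[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(m[ctrl, , drop = FALSE])
  as.numeric(marker_mean - ctrl_mean)
}

# equal-frequency bins of genes by average expression, ties by gene index
.expressionBins <- function(m, n_bins) {
  avg <- as.numeric(Matrix::rowMeans(m))
  ord <- order(avg, seq_along(avg))
  bin_of_rank <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bins <- integer(length(ord))
  bins[ord] <- bin_of_rank
  names(bins) <- rownames(m)
  bins
}

#' Score all modules of a marker panel
#'
#' @param x normalized matrix or \linkS4class{ExpressionDataset}; for plain
#'   matrices supply \code{dataset} ids per cell.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param dataset per-cell dataset ids (inferred from an
#'   ExpressionDataset).
#' @inheritParams moduleScore
#' @return a \linkS4class{ModuleScoreTable} (variant \code{"raw"}).
#' @export
scoreModules <- function(x, panel = defaultMarkerPanel(), dataset = NULL,
                         n_bins = 25, n_ctrl = 100, seed = 0) {
  m <- .logcounts(x)
  if (is.null(dataset)) {
    dataset <- if (is(x, "ExpressionDataset"))
      as.character(colData(x)$dataset_id)
    else rep("dataset", ncol(m))
  }
  sets <- markerSets(panel)
  scores <- vapply(names(sets), function(nm) {
    moduleScore(m, sets[[nm]], n_bins = n_bins, n_ctrl = n_ctrl,
                seed = seed, set_name = nm)
  }, numeric(ncol(m)))
  rownames(scores) <- colnames(m)
  new("ModuleScoreTable", scores = scores, dataset = dataset,
      variant = "raw",
      provenance = list(panel_hash = .hashObject(sets), n_bins = n_bins,
                        n_ctrl = n_ctrl, seed = seed))
}

.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Min-max normalization to [0, 1]
#'
#' \code{(x - min) / (max - min)} over the full (integrated) scope of the
#' vector; a constant input maps to all zeros.
#'
#' @param x numeric vector.
#' @return vector in [0, 1].
#' @export
minmaxScale <- function(x) {
  stopifnot(length(x) >= 1)
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' @rdname minmaxScale
#' @param mst a \linkS4class{ModuleScoreTable} (raw variant); each module
#'   column is min-max normalized across all cells of the integrated set.
#' @export
minmaxModuleScores <- function(mst) {
  s <- apply(moduleScores(mst), 2, minmaxScale)
  dimnames(s) <- dimnames(moduleScores(mst))
  methods::initialize(mst, scores = s, variant = "minmax")
}

#' Z-scale module scores per dataset
#'
#' Within each dataset and module, subtract the mean and divide by the
#' standard deviation, so each score is scaled separately by the mean and
#' variance for each dataset. A zero-variance module within a dataset
#' becomes all zeros, with a warning. Every dataset must have at least two
#' cells.
#'
#' @param mst a \linkS4class{ModuleScoreTable}.
#' @return a \linkS4class{ModuleScoreTable} (variant
#'   \code{"zscaled_by_dataset"}).
#' @export
zscaleByDataset <- function(mst) {
  s <- moduleScores(mst)
  ds <- scoreDataset(mst)
  if (any(table(ds) < 2)) stop("every dataset needs >= 2 cells")
  out <- s
  for (d in unique(ds)) {
    idx <- ds == d
    mu <- colMeans(s[idx, , drop = FALSE])
    sig <- apply(s[idx, , drop = FALSE], 2, sd)
    if (any(sig == 0))
      warning("zero-variance module(s) in dataset ", d, ": ",
              paste(colnames(s)[sig == 0], collapse = ", "))
    out[idx, ] <- sweep(sweep(s[idx, , drop = FALSE], 2, mu, "-"), 2,
                        ifelse(sig > 0, sig, 1), "/")
    out[idx, sig == 0] <- 0
  }
  methods::initialize(mst, scores = out, variant = "zscaled_by_dataset")
}

#' Write a ModuleScoreTable as TSV (+ JSON provenance sidecar)
#'
#' @param mst a \linkS4class{ModuleScoreTable}.
#' @param path TSV path; the sidecar goes to \code{<path>.json}.
#' @export
writeModuleScores <- function(mst, path) {
  tab <- data.frame(cell_id = rownames(moduleScores(mst)),
                    dataset_id = scoreDataset(mst),
                    moduleScores(mst), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(mst@provenance, list(variant = scoreVariant(mst))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
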