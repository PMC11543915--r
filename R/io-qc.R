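#' @importFrom utils read.delim write.table
#' @importFrom stats density quantile setNames
NULL

#' Read an expression dataset from disk
#'
#' Supports the 10x-style MTX triplet (Matrix Market coordinate file plus
#' \code{barcodes.tsv} and \code{features.tsv}, genes in rows) and dense TSV
#' (header row of cell IDs, first column gene IDs). Per-cell
#' \code{n_features} and \code{total_counts} are recomputed from the matrix.
#' The mitochondrial fraction is taken from an optional
#' \code{cell_metadata.tsv} (columns cell_id, mito_fraction, ...) next to
#' the matrix, and otherwise computed from genes with an "MT-" prefix.
#'
#' @param path directory (mtx_triplet) or file (dense_tsv).
#' @param format \code{"mtx_triplet"} or \code{"dense_tsv"}.
#' @param platform \code{"umi"} or \code{"tpm"}.
#' @param dataset_id dataset name; defaults to the basename of \code{path}.
#' @return an \linkS4class{ExpressionDataset}.
#' @export
readDataset <- function(path, format = c("mtx_triplet", "dense_tsv"),
                        platform = c("umi", "tpm"), dataset_id = NULL) {
  format <- match.arg(format)
  platform <- match.arg(platform)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[a-z]+$", "", basename(path))
  if (format == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
    for (f in c(mtx, bc, ft))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    barcodes <- readLines(bc)
    features <- read.delim(ft, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (length(barcodes) != ncol(m))
      stop("dimension mismatch: ", bc, " has ", length(barcodes),
           " barcodes but matrix has ", ncol(m), " columns")
    if (nrow(features) != nrow(m))
      stop("dimension mismatch: ", ft, " has ", nrow(features),
           " features but matrix has ", nrow(m), " rows")
    rownames(m) <- features[[1]]
    colnames(m) <- barcodes
    m <- methods::as(m, "CsparseMatrix")
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE)
    m <- as.matrix(tab)
  }
  if (min0(m) < 0)
    stop("negative entries in matrix read from ", path)
  meta_file <- file.path(if (format == "mtx_triplet") path
                         else dirname(path), "cell_metadata.tsv")
  mito <- NULL
  true_type <- NULL
  if (file.exists(meta_file)) {
    meta <- read.delim(meta_file, stringsAsFactors = FALSE)
    meta <- meta[match(colnames(m), meta$cell_id), , drop = FALSE]
    mito <- meta$mito_fraction
    true_type <- meta$true_type
  }
  if (is.null(mito)) {
    mt <- grepl("^MT-", rownames(m))
    tot <- Matrix::colSums(m)
    mito <- if (any(mt)) as.numeric(Matrix::colSums(m[mt, , drop = FALSE]) /
                                    pmax(tot, 1)) else rep(0, ncol(m))
  }
  ExpressionDataset(m, dataset_id = dataset_id, platform = platform,
                    mito_fraction = mito, true_type = true_type)
}

#' Write an expression dataset to disk
#'
#' UMI data go to a 10x-style MTX triplet in directory \code{path}; TPM data
#' to a dense TSV \code{matrix.tsv} in \code{path}. A
#' \code{cell_metadata.tsv} with mito fractions (and truth labels when
#' present) is written alongside.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param path output directory.
#' @return \code{path}, invisibly.
#' @export
writeDataset <- function(ds, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- assay(ds, "counts")
  if (platformType(ds) == "umi") {
    Matrix::writeMM(methods::as(m, "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
    write.table(data.frame(id = rownames(m), symbol = rownames(m)),
                file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    tab <- as.data.frame(as.matrix(m), check.names = FALSE)
    write.table(cbind(gene = rownames(m), tab),
                file.path(path, "matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- data.frame(cell_id = colnames(ds),
                     mito_fraction = colData(ds)$mito_fraction)
  if (!is.null(trueType(ds))) meta$true_type <- trueType(ds)
  write.table(meta, file.path(path, "cell_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse transcript isoforms to gene level
#'
#' Sums the values of transcripts mapping to the same gene ID, per cell, and
#' substitutes display symbols when the map provides them (otherwise the
#' stable gene ID is retained). Transcripts absent from the map are dropped
#' with a logged count, not errored — annotation version mismatches are
#' routine.
#'
#' @param m transcripts-by-cells matrix with transcript IDs as row names.
#' @param map data.frame with columns \code{transcript_id},
#'   \code{gene_id} and optionally \code{symbol}.
#' @return gene-by-cells matrix; attributes \code{dropped_transcripts}
#'   (count) and \code{gene_ids} (stable IDs backing each row).
#' @export
collapseIsoforms <- function(m, map) {
  idx <- match(rownames(m), map$transcript_id)
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    message(dropped, " transcript(s) absent from the map were dropped")
    m <- m[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  gene <- map$gene_id[idx]
  g <- rowsum(as.matrix(m), group = gene, reorder = TRUE)
  gene_ids <- rownames(g)
  if (!is.null(map$symbol)) {
    sym <- map$symbol[match(gene_ids, map$gene_id)]
    display <- ifelse(is.na(sym) | sym == "", gene_ids, sym)
    rownames(g) <- make.unique(display)
  }
  structure(g, dropped_transcripts = dropped, gene_ids = gene_ids)
}

#' Density-inflection threshold for outlier filtering
#'
#' Locates the minimum of a Gaussian-kernel density estimate of
#' \code{log10(values + 1)} between the two highest density modes —
#' analogous to knee-inflection filtering of barcode count distributions.
#' Only prominent modes (at least 5\% of the main peak's density) count,
#' and the secondary mode must lie on the flagged side of the main mode
#' (below it for \code{side = "lower"}, above for \code{"upper"}).
#' Unimodal input falls back to a configured quantile (default 0.01 for
#' \code{side = "lower"}, 0.99 for \code{"upper"}); fewer than \code{min_n}
#' values or an all-identical sample also take the fallback path, with a
#' warning. Bandwidth follows Silverman's rule on the log scale.
#'
#' @param values positive reals.
#' @param side \code{"lower"} (flag values below) or \code{"upper"}.
#' @param fallback_quantile quantile used on the fallback path.
#' @param min_n minimum sample size for density estimation.
#' @return threshold on the original scale, with attribute \code{method}
#'   (\code{"density_inflection"} or \code{"fallback_quantile"}).
#' @export
densityInflectionThreshold <- function(values, side = c("lower", "upper"),
                                       fallback_quantile = NULL,
                                       min_n = 50) {
  side <- match.arg(side)
  if (is.null(fallback_quantile))
    fallback_quantile <- if (side == "lower") 0.01 else 0.99
  fallback <- function()
    structure(as.numeric(quantile(values, fallback_quantile)),
              method = "fallback_quantile")
  if (length(values) < min_n) {
    warning("fewer than ", min_n, " values; using quantile fallback")
    return(fallback())
  }
  lv <- log10(values + 1)
  if (max(lv) - min(lv) < 1e-12) {
    warning("all values identical; using quantile fallback")
    return(fallback())
  }
  d <- density(lv, bw = "nrd0")
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  # only prominent modes count (>= 5% of the main peak), so KDE shoulder
  # wiggles do not masquerade as a second population
  peaks <- peaks[y[peaks] >= 0.05 * max(y)]
  if (length(peaks) < 2) return(fallback())
  main <- peaks[which.max(y[peaks])]
  side_peaks <- if (side == "lower") peaks[peaks < main]
                else peaks[peaks > main]
  if (!length(side_peaks)) return(fallback())
  second <- side_peaks[which.max(y[side_peaks])]
  between <- seq(min(main, second), max(main, second))
  valley <- between[which.min(y[between])]
  # a genuine antimode separates two populations; shallow KDE wiggles on a
  # unimodal sample do not qualify
  if (y[valley] >= 0.5 * min(y[main], y[second])) return(fallback())
  structure(10^d$x[valley] - 1, method = "density_inflection")
}

#' Quality-control filtering
#'
#' Applies, in order: (1) removal of genes detected (value > 0) in fewer
#' than \code{min_cells_per_gene} cells; then cell filters on the
#' gene-filtered matrix: (2) cells with fewer than
#' \code{min_features_per_cell} detected genes, (3) cells with mitochondrial
#' fraction strictly above \code{mito_threshold}, and (4) for UMI data only,
#' cells outside density-inflection thresholds on total counts (the count
#' filter is provably skipped for TPM, whose cells all sum to ~1e6). All
#' boundaries follow a literal "fewer than" reading: strictly below the
#' minimum is removed, exactly at it is retained; a mito fraction of exactly
#' the threshold is retained.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param min_cells_per_gene,min_features_per_cell,mito_threshold filter
#'   parameters (defaults 10, 100, 0.20).
#' @param reiterate if \code{TRUE}, re-apply the rule set until a fixed
#'   point (the gene-detection filter may cascade after cell removal); the
#'   first pass's count thresholds are reused, which makes re-iteration
#'   convergent.
#' @param count_thresholds optional \code{c(lower, upper)} total-count
#'   thresholds to use instead of recomputing density inflections (e.g. to
#'   re-apply a previous run's thresholds).
#' @return list with \code{dataset} (filtered \linkS4class{ExpressionDataset},
#'   \code{metadata(.)$qc_filtered = TRUE}) and \code{report} (a
#'   \code{QCReport} list: thresholds used, counts removed per rule,
#'   retained dimensions; removed + retained equals input dimensions on both
#'   axes).
#' @export
qcFilter <- function(ds, min_cells_per_gene = 10,
                     min_features_per_cell = 100, mito_threshold = 0.20,
                     reiterate = FALSE, count_thresholds = NULL) {
  input_dim <- dim(ds)
  pass <- .qcPass(ds, min_cells_per_gene, min_features_per_cell,
                  mito_threshold, count_thresholds)
  if (reiterate) {
    # the count thresholds from the first pass are reused so re-iteration
    # converges: only the gene-detection filter may cascade
    fixed_thr <- c(pass$report$thresholds$count_lower,
                   pass$report$thresholds$count_upper)
    repeat {
      nxt <- .qcPass(pass$dataset, min_cells_per_gene,
                     min_features_per_cell, mito_threshold, fixed_thr)
      for (rule in names(nxt$report$removed))
        pass$report$removed[[rule]] <- pass$report$removed[[rule]] +
          nxt$report$removed[[rule]]
      done <- identical(dim(nxt$dataset), dim(pass$dataset))
      pass$dataset <- nxt$dataset
      if (done) break
    }
  }
  pass$report$input_dim <- input_dim
  pass$report$retained_dim <- dim(pass$dataset)
  class(pass$report) <- "QCReport"
  pass
}

.qcPass <- function(ds, min_cells_per_gene, min_features_per_cell,
                    mito_threshold, count_thresholds = NULL) {
  m <- assay(ds, "counts")
  platform <- platformType(ds)
  removed <- list(genes_min_cells = 0L, cells_min_features = 0L,
                  cells_mito = 0L, cells_count_low = 0L,
                  cells_count_high = 0L)
  thresholds <- list(min_cells_per_gene = min_cells_per_gene,
                     min_features_per_cell = min_features_per_cell,
                     mito_threshold = mito_threshold,
                     count_lower = NA_real_, count_upper = NA_real_,
                     count_filter = if (platform == "umi") "applied"
                                    else "skipped")

  detected_in <- Matrix::rowSums(m > 0)
  keep_genes <- detected_in >= min_cells_per_gene
  removed$genes_min_cells <- sum(!keep_genes)
  m <- m[keep_genes, , drop = FALSE]

  nf <- Matrix::colSums(m > 0)
  tc <- Matrix::colSums(m)
  mito <- colData(ds)$mito_fraction
  alive <- rep(TRUE, ncol(m))

  fail <- nf < min_features_per_cell
  removed$cells_min_features <- sum(fail & alive)
  alive <- alive & !fail
  if (!any(alive)) stop("all cells removed by rule: min features per cell")

  fail <- mito > mito_threshold
  removed$cells_mito <- sum(fail & alive)
  alive <- alive & !fail
  if (!any(alive)) stop("all cells removed by rule: mitochondrial fraction")

  if (platform == "umi") {
    if (is.null(count_thresholds)) {
      lo <- suppressWarnings(
        densityInflectionThreshold(tc[alive], side = "lower"))
      hi <- suppressWarnings(
        densityInflectionThreshold(tc[alive], side = "upper"))
    } else {
      lo <- count_thresholds[1]
      hi <- count_thresholds[2]
    }
    thresholds$count_lower <- as.numeric(lo)
    thresholds$count_upper <- as.numeric(hi)
    fail_lo <- tc < as.numeric(lo)
    fail_hi <- tc > as.numeric(hi)
    removed$cells_count_low <- sum(fail_lo & alive)
    alive <- alive & !fail_lo
    removed$cells_count_high <- sum(fail_hi & alive)
    alive <- alive & !fail_hi
    if (!any(alive)) stop("all cells removed by rule: count thresholds")
  }

  m <- m[, alive, drop = FALSE]
  cd <- colData(ds)[alive, , drop = FALSE]
  out <- ExpressionDataset(
    m, dataset_id = datasetId(ds), platform = platform,
    mito_fraction = cd$mito_fraction, true_type = cd$true_type,
    extra_coldata = as.data.frame(
      cd[, setdiff(colnames(cd), .REQUIRED_COLDATA) |>
           setdiff("true_type"), drop = FALSE]),
    qc_filtered = TRUE)
  list(dataset = out,
       report = list(thresholds = thresholds, removed = removed))
}

#' @rdname qcFilter
#' @param report a \code{QCReport}.
#' @param path JSON output path.
#' @export
writeQCReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
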