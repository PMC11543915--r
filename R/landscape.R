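#' @importFrom igraph cluster_louvain membership
NULL

#' Baseline joint transcriptomic landscape
#'
#' Builds a shared-gene PCA embedding across datasets as an
#' integration-agnostic baseline: variable genes are ranked per dataset,
#' combined by cross-dataset median rank and cut to the top
#' \code{n_genes} genes shared by all datasets; expression is z-scaled per
#' gene within each dataset; cells are concatenated and projected onto the
#' first \code{n_pcs} principal components. Component signs are fixed by
#' making each component's largest-magnitude loading positive, so the
#' embedding is deterministic.
#'
#' @param datasets list of log-normalized \linkS4class{ExpressionDataset}s
#'   (>= 2).
#' @param n_pcs number of principal components (typically 10-15).
#' @param n_genes size of the shared variable-gene universe (default 2000).
#' @return list with \code{coords} (cells x n_pcs), \code{dataset} (id per
#'   cell), \code{genes}, \code{rotation} and \code{var_explained}.
#' @export
jointEmbed <- function(datasets, n_pcs = 12, n_genes = 2000) {
  stopifnot(length(datasets) >= 2)
  mats <- lapply(datasets, .logcounts)
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) < 100)
    stop("shared gene universe < 100 genes")
  rank_mats <- vapply(mats, function(m) {
    hvg <- suppressWarnings(selectVariableGenes(m, n_top = nrow(m)))
    r <- match(shared, hvg)
    r[is.na(r)] <- length(shared) + 1
    r
  }, numeric(length(shared)))
  med_rank <- apply(rank_mats, 1, median)
  ord <- order(med_rank, seq_along(shared))
  genes <- shared[ord][seq_len(min(n_genes, length(shared)))]

  blocks <- lapply(mats, function(m) t(.rowZscore(m[genes, , drop = FALSE])))
  X <- do.call(rbind, blocks)           # cells x genes
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  # PCA via eigen-decomposition of the gene-gene cross-product (genes <<
  # cells for joint landscapes)
  cp <- crossprod(Xc) / (nrow(Xc) - 1)
  eig <- eigen(cp, symmetric = TRUE)
  n_pcs <- min(n_pcs, ncol(Xc))
  rot <- eig$vectors[, seq_len(n_pcs), drop = FALSE]
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  rownames(rot) <- genes
  colnames(rot) <- paste0("PC", seq_len(n_pcs))
  coords <- Xc %*% rot
  rownames(coords) <- unlist(lapply(mats, colnames), use.names = FALSE)
  ev <- pmax(eig$values, 0)
  list(coords = coords,
       dataset = rep(vapply(datasets, datasetId, ""),
                     vapply(datasets, ncol, 1L)),
       genes = genes, rotation = rot,
       var_explained = ev[seq_len(n_pcs)] / sum(ev))
}

#' Graph-based clustering of the joint landscape
#'
#' Shared-nearest-neighbor graph on the embedding (Jaccard-weighted, via
#' \pkg{scran}) followed by seeded Louvain community detection at the given
#' resolution (default 2.0, chosen to detect less abundant cell types in
#' small datasets). Cluster ids are relabeled by decreasing size,
#' contiguous from 0.
#'
#' @param embedding result of \code{\link{jointEmbed}}, or a cells x dims
#'   coordinate matrix (then supply \code{dataset}).
#' @param resolution modularity resolution (default 2.0).
#' @param k_neighbors neighbors for the SNN graph (default 20).
#' @param seed integer seed for the community detection.
#' @param dataset per-cell dataset ids when \code{embedding} is a matrix.
#' @return a \code{ClusterAssignment}: data.frame with columns
#'   \code{cell_id}, \code{dataset_id}, \code{cluster}, and a
#'   \code{provenance} attribute.
#' @export
graphCluster <- function(embedding, resolution = 2.0, k_neighbors = 20,
                         seed = 0, dataset = NULL) {
  if (is.list(embedding) && !is.null(embedding$coords)) {
    coords <- embedding$coords
    if (is.null(dataset)) dataset <- embedding$dataset
  } else coords <- as.matrix(embedding)
  if (is.null(dataset)) dataset <- rep("dataset", nrow(coords))
  if (nrow(coords) < k_neighbors + 1)
    stop("need at least k_neighbors + 1 cells")
  g <- scran::buildSNNGraph(coords, k = k_neighbors, transposed = TRUE,
                            type = "jaccard")
  comm <- withr::with_seed(seed,
    cluster_louvain(g, resolution = resolution))
  memb <- as.integer(membership(comm))
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  cluster <- unname(relabel[as.character(memb)])
  structure(data.frame(cell_id = rownames(coords) %||%
                         as.character(seq_len(nrow(coords))),
                       dataset_id = dataset, cluster = cluster),
            provenance = list(method = "snn_louvain",
                              resolution = resolution,
                              k_neighbors = k_neighbors,
                              n_dims = ncol(coords), seed = seed))
}

#' Per-dataset cluster distributions
#'
#' For each dataset, the proportion vector over the global cluster id
#' range: number of cells in each cluster divided by the dataset's total
#' cell count (zeros where the dataset is absent from a cluster).
#'
#' @param assignment a \code{ClusterAssignment} data.frame (columns
#'   \code{dataset_id}, \code{cluster}).
#' @return matrix datasets x clusters of proportions, rows summing to 1.
#' @export
clusterDistributions <- function(assignment) {
  stopifnot(all(c("dataset_id", "cluster") %in% colnames(assignment)))
  clusters <- sort(unique(assignment$cluster))
  datasets <- unique(assignment$dataset_id)
  mat <- t(vapply(datasets, function(d) {
    cl <- assignment$cluster[assignment$dataset_id == d]
    tabulate(factor(cl, levels = clusters),
             nbins = length(clusters)) / length(cl)
  }, numeric(length(clusters))))
  dimnames(mat) <- list(datasets, as.character(clusters))
  mat
}

# Kullback-Leibler sum with 0 * log 0 := 0
.klTerms <- function(p, m, logf) {
  nz <- p > 0
  sum(p[nz] * logf(p[nz] / m[nz]))
}

#' Jensen-Shannon distance matrix between cluster distributions
#'
#' Pairwise Jensen-Shannon divergence with natural logarithm and
#' \code{0 log 0 := 0} (the default unit of the reference implementation);
#' entries lie in [0, ln 2]. \code{mode = "metric"} instead returns the
#' square root of the base-2 divergence, a metric in [0, 1] satisfying the
#' triangle inequality.
#'
#' @param distributions datasets x clusters proportion matrix, rows summing
#'   to 1 (within 1e-6).
#' @param mode \code{"divergence"} (default) or \code{"metric"}.
#' @return a \linkS4class{DistanceMatrix} with metric tag \code{"jsd"}.
#' @export
jsdMatrix <- function(distributions, mode = c("divergence", "metric")) {
  mode <- match.arg(mode)
  p <- as.matrix(distributions)
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("distribution row(s) do not sum to 1")
  logf <- if (mode == "metric") log2 else log
  n <- nrow(p)
  out <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    m <- (p[i, ] + p[j, ]) / 2
    d <- 0.5 * .klTerms(p[i, ], m, logf) + 0.5 * .klTerms(p[j, ], m, logf)
    if (mode == "metric") d <- sqrt(pmax(d, 0))
    out[i, j] <- out[j, i] <- d
  }
  DistanceMatrixObj(out, "jsd", info = list(mode = mode))
}

#' Pearson-correlation distance matrix on shared clusters
#'
#' Per dataset pair, the proportion vectors are restricted to clusters with
#' strictly positive proportion in both datasets; the Pearson correlation
#' of the restricted vectors is mapped to a distance
#' \code{PCD = (1 - cor) / 2} in [0, 1]. Pairs with fewer than
#' \code{min_shared} shared clusters, or zero variance on either restricted
#' vector, are undefined: masked with a warning, not errored.
#'
#' @inheritParams jsdMatrix
#' @param min_shared minimum number of shared clusters (default 3).
#' @return a \linkS4class{DistanceMatrix} with metric tag \code{"pcd"} and
#'   a validity mask for undefined entries.
#' @export
pcdMatrix <- function(distributions, min_shared = 3) {
  p <- as.matrix(distributions)
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("distribution row(s) do not sum to 1")
  n <- nrow(p)
  out <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  defined <- matrix(TRUE, n, n, dimnames = dimnames(out))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    shared <- p[i, ] > 0 & p[j, ] > 0
    if (sum(shared) < min_shared || var(p[i, shared]) == 0 ||
        var(p[j, shared]) == 0) {
      out[i, j] <- out[j, i] <- NA_real_
      defined[i, j] <- defined[j, i] <- FALSE
    } else {
      r <- cor(p[i, shared], p[j, shared])
      out[i, j] <- out[j, i] <- (1 - r) / 2
    }
  }
  if (!all(defined))
    warning(sum(!defined[upper.tri(defined)]),
            " pair(s) undefined (fewer than ", min_shared,
            " shared clusters or zero variance); masked")
  DistanceMatrixObj(out, "pcd", defined = defined,
                    info = list(min_shared = min_shared))
}

#' PCA of cluster distributions
#'
#' Centered principal component analysis of the dataset x cluster
#' proportion matrix; returns the first two components (signs fixed by the
#' largest-loading convention) and their explained-variance fractions.
#'
#' @inheritParams jsdMatrix
#' @return list with \code{coords} (datasets x 2) and
#'   \code{var_explained}.
#' @export
pcaOfDistributions <- function(distributions) {
  p <- as.matrix(distributions)
  if (nrow(p) < 3) stop("need >= 3 datasets")
  pc <- prcomp(p, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- rot[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = coords, var_explained = ve[seq_len(k)])
}

#' Order datasets by hierarchical clustering of a distance matrix
#'
#' Average-linkage agglomeration on the (symmetric) distance matrix;
#' masked/undefined entries are imputed with the maximum defined value,
#' with a warning. Returns the leaf order for heatmap display and an
#' optional flat cut.
#'
#' @param dm a \linkS4class{DistanceMatrix} (or plain symmetric matrix).
#' @param k optional number of flat groups.
#' @return list with \code{order}, \code{hclust}, \code{groups} and
#'   \code{newick}.
#' @export
orderByClustering <- function(dm, k = NULL) {
  m <- if (is(dm, "DistanceMatrix")) distanceMatrix(dm) else as.matrix(dm)
  if (any(is.na(m))) {
    warning("undefined entries imputed with the maximum defined distance")
    m[is.na(m)] <- max(m, na.rm = TRUE)
  }
  hc <- hclust(stats::as.dist(m), method = "average")
  groups <- if (!is.null(k)) cutree(hc, k = k) else NULL
  list(order = hc$labels[hc$order], hclust = hc, groups = groups,
       newick = .hclustNewick(hc))
}

#' Read / write cluster assignments
#'
#' TSV with columns cell_id, dataset_id, cluster — the pluggable interface
#' through which externally computed (e.g. integrated) cluster assignments
#' enter the distribution/distance analyses.
#'
#' @param path TSV path.
#' @export
readClusterAssignment <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "dataset_id", "cluster")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stop("cluster assignment file lacks column(s): ",
         paste(missing, collapse = ", "))
  tab$cluster <- as.integer(tab$cluster)
  tab
}

#' @rdname readClusterAssignment
#' @param assignment a \code{ClusterAssignment} data.frame.
#' @export
writeClusterAssignment <- function(assignment, path) {
  write.table(assignment, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a DistanceMatrix as square TSV plus JSON sidecar
#'
#' @param dm a \linkS4class{DistanceMatrix}.
#' @param path TSV path; sidecar goes to \code{<path>.json}.
#' @export
writeDistanceMatrix <- function(dm, path) {
  write.table(distanceMatrix(dm), path, sep = "\t", quote = FALSE,
              col.names = NA)
  jsonlite::write_json(c(list(metric = distanceMetric(dm)), dm@info),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
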