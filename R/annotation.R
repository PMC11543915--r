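#' @importFrom stats aggregate
NULL

# per-gene z-score across cells (genes x cells in, dense out);
# zero-variance genes become all zeros
.rowZscore <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  s <- sqrt(.rowVars(m, mu))
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

# specificity weight per gene: 1/sqrt(number of lineages listing it)
.markerWeights <- function(panel) {
  sets <- markerSets(panel)
  all_genes <- unlist(sets, use.names = FALSE)
  counts <- table(all_genes)
  setNames(1 / sqrt(as.numeric(counts)), names(counts))
}

#' Cluster-level marker annotation
#'
#' First of the three annotators: per-gene z-scores across cells are
#' combined, per cluster and lineage, as the sum over the cluster's cells
#' of the z-scored marker expression weighted by marker specificity
#' (\code{1/sqrt(number of lineages listing the gene)}). Each cluster is
#' labeled by the argmax lineage, or \code{"unknown"} when its top score is
#' below \code{cluster size / 4}; clusters with fewer than 3 cells are
#' labeled unknown with a warning. All cells inherit their cluster's label.
#'
#' @param x normalized matrix (genes x cells) or
#'   \linkS4class{ExpressionDataset} with logcounts.
#' @param clusters per-cell cluster ids.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param unknown_divisor the score threshold is cluster size divided by
#'   this (default 4).
#' @return character vector of per-cell labels.
#' @export
annotateClusterMarkers <- function(x, clusters, panel = defaultMarkerPanel(),
                                   unknown_divisor = 4) {
  m <- .logcounts(x)
  stopifnot(length(clusters) == ncol(m), length(markerSets(panel)) > 0)
  z <- .rowZscore(m)
  w <- .markerWeights(panel)
  sets <- markerSets(panel)
  # lineage score per cell: sum over markers of weighted z
  cell_scores <- vapply(names(sets), function(lin) {
    genes <- intersect(sets[[lin]], rownames(z))
    if (!length(genes)) return(rep(0, ncol(z)))
    colSums(z[genes, , drop = FALSE] * w[genes])
  }, numeric(ncol(m)))
  cl <- as.character(clusters)
  labels <- setNames(rep("unknown", length(unique(cl))), unique(cl))
  for (c_id in unique(cl)) {
    idx <- cl == c_id
    if (sum(idx) < 3) {
      warning("cluster ", c_id, " has < 3 cells; labeled unknown")
      next
    }
    tot <- colSums(cell_scores[idx, , drop = FALSE])
    if (max(tot) >= sum(idx) / unknown_divisor)
      labels[c_id] <- names(sets)[which.max(tot)]
  }
  unname(labels[cl])
}

#' Per-cell marker annotation with a margin rule
#'
#' Second annotator, a high-specificity per-cell rule: each cell's lineage
#' score is the mean of z-scored marker expression; the cell is labeled by
#' the argmax lineage only when the top score exceeds the runner-up by at
#' least \code{margin_cutoff} and is positive, otherwise \code{"unknown"}.
#'
#' @inheritParams annotateClusterMarkers
#' @param margin_cutoff minimum top-minus-second score margin (default
#'   0.25).
#' @return character vector of per-cell labels.
#' @export
annotateCellMarkers <- function(x, panel = defaultMarkerPanel(),
                                margin_cutoff = 0.25) {
  m <- .logcounts(x)
  stopifnot(length(markerSets(panel)) > 0)
  z <- .rowZscore(m)
  sets <- markerSets(panel)
  scores <- vapply(names(sets), function(lin) {
    genes <- intersect(sets[[lin]], rownames(z))
    if (!length(genes)) return(rep(-Inf, ncol(z)))
    colMeans(z[genes, , drop = FALSE])
  }, numeric(ncol(m)))
  apply(scores, 1, function(s) {
    ord <- order(s, decreasing = TRUE)
    if (s[ord[1]] > 0 && (s[ord[1]] - s[ord[2]]) >= margin_cutoff)
      names(sets)[ord[1]] else "unknown"
  })
}

#' Reference-based annotation by centroid correlation
#'
#' Third annotator: per reference label, a centroid of per-gene mean
#' expression over that label's cells is built on the genes that best
#' separate the reference labels (top between-centroid variance, so shared
#' background expression does not swamp the label signal); each query cell
#' is assigned the label of the centroid
#' with the highest Spearman correlation, or \code{"unknown"} when the top
#' correlation does not exceed the median correlation by
#' \code{delta_cutoff}.
#'
#' @param query,reference normalized matrices (genes x cells) or
#'   \linkS4class{ExpressionDataset}s with logcounts.
#' @param ref_labels character labels for the reference cells (>= 2 labels,
#'   each with >= 3 cells).
#' @param delta_cutoff minimum top-minus-median correlation (default 0.05).
#' @param n_var number of label-discriminating genes used; default 10 per
#'   reference label (at least 30) — a small, concentrated signature keeps
#'   the correlation margins sharp.
#' @return character vector of per-query-cell labels.
#' @export
annotateByReference <- function(query, reference, ref_labels,
                                delta_cutoff = 0.05, n_var = NULL) {
  qm <- .logcounts(query)
  rm_ <- .logcounts(reference)
  tab <- table(ref_labels)
  if (length(tab) < 2 || any(tab < 3))
    stop("reference needs >= 2 labels with >= 3 cells each")
  if (is.null(n_var)) n_var <- max(30, 10 * length(tab))
  shared <- intersect(rownames(qm), rownames(rm_))
  if (length(shared) < 50)
    stop("gene intersection between query and reference < 50")
  centroids_all <- vapply(names(tab), function(lab) {
    rowMeans(as.matrix(rm_[shared, ref_labels == lab, drop = FALSE]))
  }, numeric(length(shared)))
  # rank genes by how much they separate the reference labels; correlating
  # on all genes lets shared background expression swamp the label signal
  disc <- apply(centroids_all, 1, var)
  genes <- shared[order(disc, decreasing = TRUE)][
    seq_len(min(n_var, length(shared)))]
  centroids <- centroids_all[genes, , drop = FALSE]
  cors <- suppressWarnings(
    cor(as.matrix(qm[genes, , drop = FALSE]), centroids,
        method = "spearman"))
  cors[is.na(cors)] <- -1
  apply(cors, 1, function(r) {
    if ((max(r) - median(r)) < delta_cutoff) "unknown"
    else colnames(cors)[which.max(r)]
  })
}

#' Majority-vote consensus of three annotators
#'
#' Per cell, the label held by at least two of the three annotators
#' (\code{"unknown"} counts as a label); a three-way disagreement yields
#' \code{"unknown"}.
#'
#' @param labels_a,labels_b,labels_c equal-length character vectors.
#' @return character vector of consensus labels.
#' @export
consensusVote <- function(labels_a, labels_b, labels_c) {
  stopifnot(length(labels_a) == length(labels_b),
            length(labels_b) == length(labels_c))
  mapply(function(a, b, c) {
    if (a == b || a == c) a
    else if (b == c) b
    else "unknown"
  }, labels_a, labels_b, labels_c, USE.NAMES = FALSE)
}

#' Run all three annotators and take the consensus
#'
#' @inheritParams annotateClusterMarkers
#' @inheritParams annotateByReference
#' @param cell_ids,dataset_ids identifiers carried into the table.
#' @return an \linkS4class{AnnotationTable}.
#' @export
consensusAnnotation <- function(x, clusters, reference, ref_labels,
                                panel = defaultMarkerPanel(),
                                margin_cutoff = 0.25, delta_cutoff = 0.05,
                                cell_ids = NULL, dataset_ids = NULL) {
  m <- .logcounts(x)
  if (is.null(cell_ids)) cell_ids <- colnames(m)
  if (is.null(dataset_ids)) {
    dataset_ids <- if (is(x, "ExpressionDataset"))
      as.character(colData(x)$dataset_id) else rep("dataset", ncol(m))
  }
  a <- annotateClusterMarkers(m, clusters, panel)
  b <- annotateCellMarkers(m, panel, margin_cutoff)
  c_ <- annotateByReference(m, reference, ref_labels, delta_cutoff)
  AnnotationTable(data.frame(
    cell_id = cell_ids, dataset_id = dataset_ids,
    annotator_cluster = a, annotator_cell = b, annotator_ref = c_,
    consensus = consensusVote(a, b, c_)))
}

#' Refine primitive-endoderm subtypes by cluster membership
#'
#' PE cells falling in the designated subtype-II clusters are relabeled
#' \code{"PE_II"}; all other PE cells become \code{"PE_I"}. Non-PE labels
#' are unchanged.
#'
#' @param labels per-cell consensus labels.
#' @param clusters per-cell cluster ids.
#' @param subtype2_clusters vector of cluster ids defining subtype II.
#' @return relabeled character vector.
#' @export
refinePESubtypes <- function(labels, clusters, subtype2_clusters) {
  stopifnot(length(labels) == length(clusters))
  is_pe <- labels == "PE"
  labels[is_pe] <- ifelse(clusters[is_pe] %in% subtype2_clusters,
                          "PE_II", "PE_I")
  labels
}

#' Wilcoxon rank-sum marker genes between groups
#'
#' For each group versus the rest: a two-sided Wilcoxon rank-sum test
#' (normal approximation with tie correction) per gene, a natural-log fold
#' change \code{ln(mean(expm1(in)) + 1) - ln(mean(expm1(rest)) + 1)}, and
#' Benjamini-Hochberg adjustment within each group's gene list.
#' Mitochondrial and ribosomal genes (and any further patterns) are removed
#' before testing.
#'
#' @param x normalized (log1p) matrix or \linkS4class{ExpressionDataset}.
#' @param groups per-cell group labels (>= 2 groups, each >= 3 cells).
#' @param exclusions regular expressions of genes to exclude
#'   (defaults: \code{"^MT-"}, \code{"^RPS"}, \code{"^RPL"}).
#' @return data.frame with columns gene, group, statistic, avg_logFC,
#'   p_val, p_val_adj, and attribute \code{excluded_genes} (count).
#' @export
rankSumMarkers <- function(x, groups,
                           exclusions = c("^MT-", "^RPS", "^RPL")) {
  m <- as.matrix(.logcounts(x))
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 3)) stop("every group needs >= 3 cells")
  excl <- Reduce(`|`, lapply(exclusions, grepl, x = rownames(m)),
                 accumulate = FALSE, init = rep(FALSE, nrow(m)))
  n_excl <- sum(excl)
  m <- m[!excl, , drop = FALSE]
  res <- lapply(names(tab), function(g) {
    inc <- groups == g
    stats_per_gene <- t(apply(m, 1, function(v) {
      x1 <- v[inc]; x2 <- v[!inc]
      if (max(v) == min(v)) {
        c(W = length(x1) * length(x2) / 2, p = 1)
      } else {
        wt <- suppressWarnings(
          wilcox.test(x1, x2, exact = FALSE, correct = FALSE))
        p <- wt$p.value
        c(W = unname(wt$statistic), p = if (is.na(p)) 1 else p)
      }
    }))
    lfc <- log(rowMeans(expm1(m[, inc, drop = FALSE])) + 1) -
      log(rowMeans(expm1(m[, !inc, drop = FALSE])) + 1)
    data.frame(gene = rownames(m), group = g,
               statistic = stats_per_gene[, "W"],
               avg_logFC = as.numeric(lfc),
               p_val = stats_per_gene[, "p"],
               p_val_adj = p.adjust(stats_per_gene[, "p"], method = "BH"),
               row.names = NULL)
  })
  structure(do.call(rbind, res), excluded_genes = n_excl)
}

#' Write an AnnotationTable as TSV
#'
#' @param at an \linkS4class{AnnotationTable}.
#' @param path output TSV path.
#' @export
writeAnnotationTable <- function(at, path) {
  write.table(annotationLabels(at), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
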