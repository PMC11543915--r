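#' @importFrom stats chisq.test hclust cutree dist as.dendrogram
NULL

.PRIMARY_TYPES <- c("EPI_ICM", "PE", "TE")

#' Tabulate per-dataset cell-type composition
#'
#' Counts consensus labels per dataset over the primary cell types
#' (EPI_ICM, PE, TE), optionally adding an \code{unknown} column. PE
#' subtypes are pooled into PE for the primary table (subtype-resolved
#' tables via \code{pool_pe = FALSE}); labels outside the primary types are
#' folded into \code{unknown}. Datasets with zero qualifying cells are
#' retained as zero rows, with a warning.
#'
#' @param annotations an \linkS4class{AnnotationTable} or a data.frame with
#'   columns \code{dataset_id} and \code{consensus}.
#' @param source_map named character vector mapping dataset id to source
#'   (e.g. blastocyst, nPSC, EPSC, fibroblast); every dataset needs one.
#' @param include_unknown include non-annotated cells as a fourth column.
#' @param pool_pe pool PE_I / PE_II into PE.
#' @return a \code{CompositionTable}: list with \code{counts}
#'   (dataset x type integer matrix), \code{source} (per dataset) and
#'   \code{include_unknown}.
#' @export
compositionTable <- function(annotations, source_map,
                             include_unknown = FALSE, pool_pe = TRUE) {
  lab <- if (is(annotations, "AnnotationTable"))
    annotationLabels(annotations) else annotations
  stopifnot(all(c("dataset_id", "consensus") %in% colnames(lab)))
  missing_src <- setdiff(unique(lab$dataset_id), names(source_map))
  if (length(missing_src))
    stop("no source for dataset(s): ", paste(missing_src, collapse = ", "))
  cons <- lab$consensus
  if (pool_pe) cons[cons %in% c("PE_I", "PE_II")] <- "PE"
  types <- if (pool_pe) .PRIMARY_TYPES else
    c("EPI_ICM", "PE_I", "PE_II", "TE")
  cons[!cons %in% types] <- "unknown"
  lev <- if (include_unknown) c(types, "unknown") else types
  datasets <- unique(lab$dataset_id)
  counts <- t(vapply(datasets, function(d) {
    tabulate(factor(cons[lab$dataset_id == d & cons %in% lev],
                    levels = lev), nbins = length(lev))
  }, integer(length(lev))))
  dimnames(counts) <- list(datasets, lev)
  zero <- rowSums(counts) == 0
  if (any(zero))
    warning("dataset(s) with zero qualifying cells retained as zero rows: ",
            paste(datasets[zero], collapse = ", "))
  structure(list(counts = counts,
                 source = unname(source_map[datasets]),
                 include_unknown = include_unknown),
            class = "CompositionTable")
}

#' Chi-squared association of composition with source
#'
#' Groups the composition table's datasets by source (rows = sources,
#' columns = cell types), then applies the Pearson chi-squared test without
#' continuity correction, with expected counts from the row/column
#' marginals. With 4 sources the annotated-only (3-type) table has df = 6
#' and the with-unknown (4-type) table df = 9.
#'
#' @param ct a \code{CompositionTable} from \code{\link{compositionTable}},
#'   or a plain counts matrix whose rows are already sources.
#' @return an \code{AssociationResult}: list with \code{statistic},
#'   \code{df}, \code{p_value} and \code{expected}.
#' @export
chiSquaredAssociation <- function(ct) {
  tab <- if (inherits(ct, "CompositionTable"))
    rowsum(ct$counts, group = ct$source) else as.matrix(ct)
  tab <- as.matrix(tab)
  empty_r <- rowSums(tab) == 0
  empty_c <- colSums(tab) == 0
  if (any(empty_r) || any(empty_c))
    stop("empty marginal category; remove empty row(s)/column(s): ",
         paste(c(rownames(tab)[empty_r], colnames(tab)[empty_c]),
               collapse = ", "))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table needs >= 2 rows and >= 2 columns")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 expected = ht$expected),
            class = "AssociationResult")
}

#' Hierarchical clustering of dataset compositions
#'
#' Agglomerative clustering of row-normalized proportion vectors
#' (average linkage on euclidean distances by default), with an optional
#' flat cut at \code{k} groups.
#'
#' @param ct a \code{CompositionTable} or a dataset x type counts matrix.
#' @param k number of flat groups (optional; must not exceed the number of
#'   datasets).
#' @param linkage hclust agglomeration method.
#' @param metric distance metric for \code{\link[stats]{dist}}.
#' @return list with \code{hclust}, \code{order} (leaf order),
#'   \code{groups} (cut at \code{k}, or NULL) and \code{newick}.
#' @export
clusterCompositions <- function(ct, k = NULL, linkage = "average",
                                metric = "euclidean") {
  counts <- if (inherits(ct, "CompositionTable")) ct$counts else
    as.matrix(ct)
  if (nrow(counts) < 3) stop("need >= 3 datasets")
  props <- counts / pmax(rowSums(counts), 1)
  hc <- hclust(dist(props, method = metric), method = linkage)
  groups <- NULL
  if (!is.null(k)) {
    if (k > nrow(counts)) stop("k exceeds the number of datasets")
    groups <- cutree(hc, k = k)
  }
  list(hclust = hc, order = hc$labels[hc$order], groups = groups,
       newick = .hclustNewick(hc))
}

.hclustNewick <- function(hc) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}

#' Write composition artifacts
#'
#' @param ct a \code{CompositionTable}.
#' @param path TSV output path.
#' @export
writeCompositionTable <- function(ct, path) {
  tab <- data.frame(dataset_id = rownames(ct$counts), source = ct$source,
                    ct$counts, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCompositionTable
#' @param res an \code{AssociationResult}.
#' @export
writeAssociationResult <- function(res, path) {
  jsonlite::write_json(list(statistic = res$statistic, df = res$df,
                            p_value = res$p_value),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
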