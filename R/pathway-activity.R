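#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line — name, description, then genes,
#' tab-separated. Set names must be unique and sets non-empty.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  if (any(lengths(sets) == 0)) stop("empty gene set(s) in ", path)
  sets
}

#' AUC recovery score of a gene set per cell
#'
#' Ranks each cell's genes by decreasing expression (ties broken by one
#' seeded random permutation of the gene order, the dominant tie case
#' being zero-expression genes) and scores the recovery of set genes within
#' the top \code{K = ceiling(top_fraction * n_genes)} ranks:
#' \code{raw = sum_k hits(k)} for k = 1..K, normalized by
#' \code{sum_k min(k, |set|)} so a perfect top ranking scores 1.
#'
#' @param x expression matrix (genes x cells; any monotone transform of
#'   expression gives the same result) or \linkS4class{ExpressionDataset}.
#' @param gene_set character vector; at least one member must be present.
#' @param top_fraction fraction of top-ranked genes integrated (default
#'   0.05).
#' @param seed seed for the tie-breaking permutation.
#' @param set_name label used in error messages.
#' @return numeric per-cell AUC in [0, 1].
#' @export
aucActivity <- function(x, gene_set, top_fraction = 0.05, seed = 0,
                        set_name = "gene set") {
  m <- if (is(x, "ExpressionDataset")) assay(x, "counts") else x
  n_genes <- nrow(m)
  K <- ceiling(top_fraction * n_genes)
  if (K < 2) stop("top_fraction yields fewer than 2 top ranks")
  set_idx <- which(rownames(m) %in% gene_set)
  if (!length(set_idx))
    stop("no genes of '", set_name, "' are present in the matrix")
  s <- length(set_idx)
  denom <- sum(pmin(seq_len(K), s))
  tiebreak <- withr::with_seed(seed, sample.int(n_genes))
  m <- as.matrix(m)
  vapply(seq_len(ncol(m)), function(ci) {
    ord <- order(-m[, ci], tiebreak)
    ranks <- integer(n_genes)
    ranks[ord] <- seq_len(n_genes)
    r <- ranks[set_idx]
    sum(pmax(K - r + 1L, 0L)) / denom
  }, numeric(1))
}

#' Score a gene-set collection across cells
#'
#' @param x expression matrix or \linkS4class{ExpressionDataset}.
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{readGMT}}).
#' @inheritParams aucActivity
#' @return a \code{PathwayActivityTable}: cells x sets matrix of AUC values
#'   with attributes \code{top_fraction} and \code{seed}.
#' @export
pathwayActivity <- function(x, gene_sets, top_fraction = 0.05, seed = 0) {
  m <- if (is(x, "ExpressionDataset")) assay(x, "counts") else x
  scores <- vapply(names(gene_sets), function(nm) {
    aucActivity(m, gene_sets[[nm]], top_fraction = top_fraction,
                seed = seed, set_name = nm)
  }, numeric(ncol(m)))
  rownames(scores) <- colnames(m)
  structure(scores, top_fraction = top_fraction, seed = seed,
            class = c("PathwayActivityTable", class(scores)))
}

#' Aggregate activity scores by group
#'
#' Arithmetic mean of per-cell AUC scores per (group, set); one or two
#' grouping vectors may be supplied (e.g. dataset and cell type).
#' Grouping-level combinations without cells are emitted as missing
#' (\code{NA}), not zero.
#'
#' @param activity cells x sets matrix (e.g. from
#'   \code{\link{pathwayActivity}}).
#' @param grouping factor/character vector, or data.frame of up to two
#'   such vectors, one entry per cell.
#' @return groups x sets matrix of means (NA for empty groups); for
#'   two-way grouping, row names are \code{<g1>.<g2>} over the full level
#'   grid.
#' @export
aggregateActivity <- function(activity, grouping) {
  a <- as.matrix(activity)
  if (is.data.frame(grouping)) {
    stopifnot(ncol(grouping) <= 2)
    fs <- lapply(grouping, function(g) if (is.factor(g)) g else factor(g))
    grp <- interaction(fs, drop = FALSE, sep = ".")
  } else {
    grp <- if (is.factor(grouping)) grouping else factor(grouping)
  }
  stopifnot(length(grp) == nrow(a))
  out <- matrix(NA_real_, nlevels(grp), ncol(a),
                dimnames = list(levels(grp), colnames(a)))
  present <- levels(grp)[levels(grp) %in% as.character(grp)]
  for (g in present)
    out[g, ] <- colMeans(a[grp == g, , drop = FALSE])
  out
}

#' Write an activity table as TSV
#'
#' @param activity cells-or-groups x sets matrix.
#' @param path output TSV path.
#' @param id_column name of the first column (default "cell_id").
#' @export
writeActivityTable <- function(activity, path, id_column = "cell_id") {
  tab <- data.frame(rownames(activity), as.matrix(activity),
                    check.names = FALSE)
  colnames(tab)[1] <- id_column
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
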