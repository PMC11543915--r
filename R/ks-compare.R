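#' Two-sample Kolmogorov-Smirnov statistic
#'
#' \code{D = sup_t |F_x(t) - F_y(t)|}, computed exactly over the pooled
#' sorted values; ties are handled by evaluating both empirical CDFs at
#' every pooled point.
#'
#' @param sample_x,sample_y non-empty numeric vectors.
#' @return D in [0, 1].
#' @export
ksStatistic <- function(sample_x, sample_y) {
  if (!length(sample_x) || !length(sample_y))
    stop("both samples must be non-empty")
  sx <- sort(sample_x)
  sy <- sort(sample_y)
  pooled <- sort(c(sx, sy))
  fx <- findInterval(pooled, sx) / length(sx)
  fy <- findInterval(pooled, sy) / length(sy)
  max(abs(fx - fy))
}

#' Bootstrapped KS distance matrix between dataset score distributions
#'
#' Per iteration, \code{subsample_size} scores are drawn per dataset (with
#' replacement) and the full pairwise KS matrix is computed; the result is
#' the element-wise mean over iterations. The subsample size defaults to
#' the smallest dataset's cell count, controlling for unequal dataset
#' sizes. Within an iteration the same per-dataset draw is used against all
#' partners, enforcing exact symmetry; the diagonal is the self-resampling
#' distance (computed against a second, independent draw of the same
#' dataset) — a useful O(n^-1/2) null scale, deliberately not zeroed.
#'
#' @param mst a \linkS4class{ModuleScoreTable} (use the
#'   \code{"zscaled_by_dataset"} variant so location/scale differences
#'   between datasets are removed first), or a data.frame with columns
#'   \code{dataset_id} and \code{score}.
#' @param module module (column) name to compare; ignored for data.frame
#'   input.
#' @param n_iterations bootstrap iterations (default 1000).
#' @param subsample_size draw size; \code{NULL} = smallest dataset.
#' @param with_replacement sampling mode (default TRUE).
#' @param seed integer seed; identical inputs and seed give bitwise
#'   identical results.
#' @return a \code{BootstrapKSResult}: list with \code{matrix} (a
#'   \linkS4class{DistanceMatrix}, metric \code{"ks_mean"}), \code{module},
#'   \code{n_iterations}, \code{subsample_size}, \code{with_replacement},
#'   \code{seed}.
#' @export
bootstrapKSMatrix <- function(mst, module = NULL, n_iterations = 1000,
                              subsample_size = NULL,
                              with_replacement = TRUE, seed = 0) {
  by_ds <- .scoresByDataset(mst, module)
  sizes <- lengths(by_ds)
  if (any(sizes < 2)) stop("every dataset needs >= 2 cells")
  if (is.null(subsample_size)) subsample_size <- min(sizes)
  if (subsample_size < 2) stop("subsample_size must be >= 2")
  n <- length(by_ds)
  acc <- matrix(0, n, n, dimnames = list(names(by_ds), names(by_ds)))
  withr::with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      draws <- lapply(by_ds, sample, size = subsample_size,
                      replace = with_replacement)
      extra <- lapply(by_ds, sample, size = subsample_size,
                      replace = with_replacement)
      for (i in seq_len(n)) {
        acc[i, i] <- acc[i, i] + ksStatistic(draws[[i]], extra[[i]])
        for (j in seq_len(n)) if (j > i) {
          d <- ksStatistic(draws[[i]], draws[[j]])
          acc[i, j] <- acc[i, j] + d
          acc[j, i] <- acc[j, i] + d
        }
      }
    }
  })
  avg <- acc / n_iterations
  structure(list(matrix = DistanceMatrixObj(avg, "ks_mean",
                   info = list(module = module %||% "score",
                               n_iterations = n_iterations,
                               subsample_size = subsample_size,
                               seed = seed)),
                 module = module %||% "score",
                 n_iterations = n_iterations,
                 subsample_size = subsample_size,
                 with_replacement = with_replacement, seed = seed),
            class = "BootstrapKSResult")
}

.scoresByDataset <- function(mst, module) {
  if (is(mst, "ModuleScoreTable")) {
    if (is.null(module))
      stop("supply the module name to compare")
    if (!module %in% colnames(moduleScores(mst)))
      stop("unknown module: ", module)
    split(moduleScores(mst)[, module], scoreDataset(mst))
  } else {
    stopifnot(all(c("dataset_id", "score") %in% colnames(mst)))
    split(mst$score, mst$dataset_id)
  }
}

#' Subsample-size sensitivity of the bootstrapped KS distances
#'
#' Reruns \code{\link{bootstrapKSMatrix}} at each subsample size and
#' reports, against the reference-size matrix: the element-wise difference
#' matrix, its Frobenius norm, and the Spearman rank correlation of
#' off-diagonal distances. At the reference size with the same seed the
#' difference is exactly zero and the rank correlation 1.
#'
#' @inheritParams bootstrapKSMatrix
#' @param sizes subsample sizes to test (default 100, 400, 800, 1000,
#'   1500).
#' @param reference_size size of the reference matrix; \code{NULL} =
#'   smallest dataset's cell count.
#' @return a \code{SensitivityReport}: list with \code{reference_size},
#'   \code{reference} matrix, and per size \code{matrices},
#'   \code{differences}, \code{frobenius_norms},
#'   \code{rank_correlations}.
#' @export
ksSensitivity <- function(mst, module = NULL,
                          sizes = c(100, 400, 800, 1000, 1500),
                          reference_size = NULL, n_iterations = 1000,
                          seed = 0) {
  by_ds <- .scoresByDataset(mst, module)
  if (is.null(reference_size)) reference_size <- min(lengths(by_ds))
  ref <- bootstrapKSMatrix(mst, module, n_iterations = n_iterations,
                           subsample_size = reference_size, seed = seed)
  refm <- distanceMatrix(ref$matrix)
  off <- upper.tri(refm)
  per_size <- lapply(sizes, function(s) {
    res <- bootstrapKSMatrix(mst, module, n_iterations = n_iterations,
                             subsample_size = s, seed = seed)
    m <- distanceMatrix(res$matrix)
    diffm <- m - refm
    list(matrix = m, difference = diffm,
         frobenius_norm = sqrt(sum(diffm^2)),
         rank_correlation = cor(m[off], refm[off], method = "spearman"))
  })
  names(per_size) <- as.character(sizes)
  structure(list(sizes = sizes, reference_size = reference_size,
                 reference = refm,
                 matrices = lapply(per_size, `[[`, "matrix"),
                 differences = lapply(per_size, `[[`, "difference"),
                 frobenius_norms = vapply(per_size, `[[`,
                                          numeric(1), "frobenius_norm"),
                 rank_correlations = vapply(per_size, `[[`,
                                            numeric(1), "rank_correlation"),
                 n_iterations = n_iterations, seed = seed),
            class = "SensitivityReport")
}

#' Write a SensitivityReport as JSON (matrices embedded)
#'
#' @param report a \code{SensitivityReport}.
#' @param path JSON output path.
#' @export
writeSensitivityReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
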