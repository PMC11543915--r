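test_that("cluster-level annotation matches the weighted-score oracle", {
  set.seed(60)
  panel <- defaultMarkerPanel()
  genes <- unique(unlist(markerSets(panel)))
  n_per <- 30
  clusters <- rep(1:3, each = n_per)
  m <- matrix(rnorm(length(genes) * 90, 2, 0.2), nrow = length(genes),
              dimnames = list(genes, paste0("c", 1:90)))
  m[markerSets(panel)$EPI_ICM, clusters == 1] <-
    m[markerSets(panel)$EPI_ICM, clusters == 1] + 3
  m[markerSets(panel)$PE, clusters == 2] <-
    m[markerSets(panel)$PE, clusters == 2] + 3
  m[markerSets(panel)$TE, clusters == 3] <-
    m[markerSets(panel)$TE, clusters == 3] + 3
  labels <- annotateClusterMarkers(m, clusters, panel)
  expect_identical(unique(labels[clusters == 1]), "EPI_ICM")
  expect_identical(unique(labels[clusters == 2]), "PE")
  expect_identical(unique(labels[clusters == 3]), "TE")

  # independent recomputation of the weighted-sum argmax per cluster
  z <- t(scale(t(m)))
  w <- 1 / sqrt(table(unlist(markerSets(panel))))
  for (cl in 1:3) {
    scores <- vapply(markerSets(panel), function(gs) {
      sum(z[gs, clusters == cl] * as.numeric(w[gs]))
    }, numeric(1))
    expect_identical(unique(labels[clusters == cl]),
                     names(which.max(scores)))
  }
})

test_that("weak clusters and tiny clusters are labeled unknown", {
  set.seed(61)
  panel <- defaultMarkerPanel()
  genes <- unique(unlist(markerSets(panel)))
  m <- matrix(rnorm(length(genes) * 40, 2, 0.2), nrow = length(genes),
              dimnames = list(genes, paste0("c", 1:40)))
  labels <- annotateClusterMarkers(m, rep(1, 40), panel)
  expect_identical(unique(labels), "unknown")  # all z-scores ~ 0

  expect_warning(
    lab2 <- annotateClusterMarkers(m, c(rep(1, 38), 2, 2), panel),
    "< 3 cells")
  expect_identical(unique(lab2[39:40]), "unknown")
})

test_that("per-cell margin rule matches a brute-force recomputation", {
  set.seed(62)
  panel <- defaultMarkerPanel()
  genes <- c(unique(unlist(markerSets(panel))), paste0("bg", 1:30))
  n <- 100
  m <- matrix(exp(rnorm(length(genes) * n)), nrow = length(genes),
              dimnames = list(genes, paste0("c", 1:n)))
  labels <- annotateCellMarkers(m, panel, margin_cutoff = 0.25)

  z <- t(scale(t(m)))
  oracle <- vapply(seq_len(n), function(ci) {
    s <- vapply(markerSets(panel), function(gs) mean(z[gs, ci]), numeric(1))
    ord <- order(s, decreasing = TRUE)
    if (s[ord[1]] > 0 && s[ord[1]] - s[ord[2]] >= 0.25)
      names(s)[ord[1]] else "unknown"
  }, character(1))
  expect_identical(unname(labels), unname(oracle))
})

test_that("margin-rule corner cases: clear margin wins, ties are unknown", {
  panel <- MarkerPanel(list(A = c("gA1", "gA2"), B = c("gB1", "gB2")))
  m <- rbind(gA1 = c(5, 3, 1), gA2 = c(5, 3, 1),
             gB1 = c(1, 3, 5), gB2 = c(1, 3, 5),
             bg1 = c(2, 2.1, 2), bg2 = c(2, 2, 2.1))
  colnames(m) <- c("cellA", "tied", "cellB")
  labels <- annotateCellMarkers(m, panel)
  expect_identical(unname(labels),
                   c("A", "unknown", "B"))
})

test_that("reference annotation recovers labels and flags shuffled cells", {
  # query drawn from the same lineage programs as the reference
  spec <- threeTypeSpec(c("ref", "query"), c(500, 300), seed = 1,
                        batch_shift_sd = 0)
  nds <- normalizedCohort(spec)
  truth <- lapply(nds, primaryTruth)
  qm <- as.matrix(assay(nds$query, "logcounts"))
  labels <- annotateByReference(qm, nds$ref, truth$ref)
  expect_gte(mean(labels == truth$query), 0.9)

  # a query cell identical to a reference centroid self-matches
  rm_ <- as.matrix(assay(nds$ref, "logcounts"))
  centroid <- rowMeans(rm_[, truth$ref == "TE"])
  fake <- cbind(qm[, 1:5], TEcentroid = centroid)
  lab2 <- annotateByReference(fake, nds$ref, truth$ref)
  expect_identical(unname(lab2["TEcentroid"]), "TE")

  # gene-shuffled cells decorrelate from every centroid; their labels must
  # agree with a direct recomputation of the correlation-margin rule, and
  # unknowns become far more frequent than on intact cells
  set.seed(64)
  shuffled <- qm[, 1:50]
  for (i in seq_len(50)) shuffled[, i] <- sample(shuffled[, i])
  lab3 <- annotateByReference(shuffled, nds$ref, truth$ref)

  tabs <- sort(unique(truth$ref))
  cents <- sapply(tabs, function(l)
    rowMeans(rm_[, truth$ref == l, drop = FALSE]))
  disc_genes <- rownames(cents)[order(apply(cents, 1, var),
                                      decreasing = TRUE)][1:30]
  oracle <- apply(shuffled[disc_genes, ], 2, function(v) {
    r <- apply(cents[disc_genes, ], 2, cor, x = v, method = "spearman")
    if (max(r) - median(r) < 0.05) "unknown" else names(which.max(r))
  })
  expect_identical(unname(lab3), unname(oracle))
  expect_gt(mean(lab3 == "unknown"), mean(labels == "unknown") + 0.2)
})

test_that("reference annotation validates its inputs", {
  m <- matrix(rnorm(200), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  expect_error(annotateByReference(m, m, rep(c("A", "B"), each = 5)),
               "intersection")
  big <- matrix(rnorm(60 * 10), nrow = 60,
                dimnames = list(paste0("g", 1:60), paste0("c", 1:10)))
  expect_error(annotateByReference(big, big, c(rep("A", 8), "B", "B")),
               ">= 3 cells")
})

test_that("majority vote resolves 2-of-3, punts on full disagreement", {
  expect_identical(
    consensusVote(c("EPI_ICM", "EPI_ICM", "unknown"),
                  c("EPI_ICM", "PE", "unknown"),
                  c("TE", "TE", "PE")),
    c("EPI_ICM", "unknown", "unknown"))
  expect_identical(consensusVote("unknown", "unknown", "PE"), "unknown")
})

test_that("PE refinement relabels only PE cells by cluster membership", {
  labels <- c("PE", "PE", "TE", "EPI_ICM", "PE")
  clusters <- c(7, 2, 7, 7, 30)
  out <- refinePESubtypes(labels, clusters,
                          subtype2_clusters = c(7, 30, 24, 11, 14, 23, 8,
                                                9, 18, 13, 4, 31))
  expect_identical(out, c("PE_II", "PE_I", "TE", "EPI_ICM", "PE_II"))
})

test_that("rank-sum statistics match exact enumeration and null behavior", {
  # complete separation, n = 10 vs 10: U statistic is exactly 100
  g1 <- rnorm(10, 10, 0.1)
  g2 <- rnorm(10, 0, 0.1)
  m <- rbind(sep = c(g1, g2), flat = rep(1, 20),
             noise = rnorm(20))
  colnames(m) <- paste0("c", 1:20)
  groups <- rep(c("hi", "lo"), each = 10)
  deg <- rankSumMarkers(m, groups, exclusions = character())
  sep_hi <- deg[deg$gene == "sep" & deg$group == "hi", ]
  expect_equal(sep_hi$statistic, 100)
  flat <- deg[deg$gene == "flat" & deg$group == "hi", ]
  expect_equal(flat$p_val, 1, tolerance = 1e-6)
  expect_true(all(deg$p_val_adj >= deg$p_val - 1e-12))
})

test_that("mito and ribosomal genes are excluded from DEG testing", {
  set.seed(65)
  m <- matrix(rnorm(5 * 12), nrow = 5,
              dimnames = list(c("MT-ND1", "RPS4", "RPL3", "GATA4", "NANOG"),
                              paste0("c", 1:12)))
  deg <- rankSumMarkers(m, rep(c("A", "B"), each = 6))
  expect_identical(sort(unique(deg$gene)), c("GATA4", "NANOG"))
  expect_identical(attr(deg, "excluded_genes"), 3L)
})

test_that("a planted DE gene surfaces in the top ranks", {
  set.seed(66)
  n <- 200
  m <- matrix(exp(rnorm(200 * 2 * n, 0, 0.5)), nrow = 200,
              dimnames = list(paste0("g", 1:200), paste0("c", 1:(2 * n))))
  groups <- rep(c("A", "B"), each = n)
  m["g7", groups == "A"] <- m["g7", groups == "A"] * 4
  lm_ <- log1p(m)
  deg <- rankSumMarkers(lm_, groups, exclusions = character())
  degA <- deg[deg$group == "A", ]
  top10 <- degA$gene[order(degA$p_val_adj)][1:10]
  expect_true("g7" %in% top10)
  expect_gt(degA$avg_logFC[degA$gene == "g7"], 0.5)
})

test_that("label permutation yields a calibrated rank-sum null", {
  set.seed(67)
  n_genes <- 1000
  m <- matrix(rnorm(n_genes * 100), nrow = n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("c", 1:100)))
  groups <- sample(rep(c("A", "B"), each = 50))
  deg <- rankSumMarkers(m, groups, exclusions = character())
  frac <- mean(deg$p_val[deg$group == "A"] < 0.05)
  expect_lte(frac, 0.07)
})

test_that("raising cutoffs never decreases the number of unknowns", {
  spec <- threeTypeSpec(c("ref", "query"), c(300, 200), seed = 2)
  nds <- normalizedCohort(spec)
  qm <- as.matrix(assay(nds$query, "logcounts"))
  truth_ref <- primaryTruth(nds$ref)
  n_unknown_margin <- vapply(c(0, 0.25, 0.8, 2), function(cut) {
    sum(annotateCellMarkers(qm, margin_cutoff = cut) == "unknown")
  }, numeric(1))
  expect_true(all(diff(n_unknown_margin) >= 0))
  n_unknown_delta <- vapply(c(0, 0.05, 0.2, 0.5), function(cut) {
    sum(annotateByReference(qm, nds$ref, truth_ref,
                            delta_cutoff = cut) == "unknown")
  }, numeric(1))
  expect_true(all(diff(n_unknown_delta) >= 0))
})

test_that("consensus annotation table satisfies its validity contract", {
  spec <- threeTypeSpec(c("ref", "query"), c(300, 200), seed = 3)
  nds <- normalizedCohort(spec)
  emb <- jointEmbed(nds, n_pcs = 8)
  cl <- graphCluster(emb, resolution = 1.0, seed = 1)
  qm <- as.matrix(assay(nds$query, "logcounts"))
  truth_ref <- primaryTruth(nds$ref)
  at <- consensusAnnotation(
    qm, cl$cluster[match(colnames(qm), cl$cell_id)],
    reference = nds$ref, ref_labels = truth_ref,
    dataset_ids = rep("query", ncol(qm)))
  expect_s4_class(at, "AnnotationTable")
  lab <- annotationLabels(at)
  agree <- mapply(function(a, b, c, cons) {
    cons == "unknown" | sum(c(a, b, c) == cons) >= 2
  }, lab$annotator_cluster, lab$annotator_cell, lab$annotator_ref,
     lab$consensus)
  expect_true(all(agree))
})
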