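test_that("duplicate datasets land on identical embedding coordinates", {
  spec <- threeTypeSpec("one", 150, seed = 80, n_genes = 300)
  ds <- normalizedCohort(spec)[[1]]
  m <- assay(ds, "counts")
  twin_a <- logNormalize(toyDataset(m, id = "twinA"))
  twin_b <- logNormalize(toyDataset(m, id = "twinB"))
  emb <- jointEmbed(list(twin_a, twin_b), n_pcs = 6)
  n <- ncol(m)
  expect_equal(unname(emb$coords[seq_len(n), ]),
               unname(emb$coords[n + seq_len(n), ]), tolerance = 1e-8)
  # explained variance is non-increasing across components
  expect_true(all(diff(emb$var_explained) <= 1e-12))
})

test_that("the joint landscape separates planted lineages", {
  spec <- threeTypeSpec(c("a", "b"), c(250, 250), seed = 81, n_genes = 500)
  nds <- normalizedCohort(spec)
  # embedding gene budget proportionate to the 500-gene fixture
  emb <- jointEmbed(nds, n_pcs = 10, n_genes = 200)
  truth <- unlist(lapply(nds, primaryTruth), use.names = FALSE)
  sil <- cluster::silhouette(as.integer(factor(truth)),
                             dist(emb$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.2)
})

test_that("joint embedding validates the shared gene universe", {
  m1 <- matrix(rpois(60 * 30, 3), nrow = 60,
               dimnames = list(paste0("g", 1:60), paste0("a", 1:30)))
  m2 <- matrix(rpois(60 * 30, 3), nrow = 60,
               dimnames = list(paste0("h", 1:60), paste0("b", 1:30)))
  d1 <- logNormalize(toyDataset(m1, id = "d1"))
  d2 <- logNormalize(toyDataset(m2, id = "d2"))
  expect_error(jointEmbed(list(d1, d2)), "< 100")
})

test_that("graph clustering resolves well-separated blobs deterministically", {
  set.seed(82)
  blob1 <- matrix(rnorm(200 * 5, 0), ncol = 5)
  blob2 <- matrix(rnorm(200 * 5, 8), ncol = 5)
  coords <- rbind(blob1, blob2)
  rownames(coords) <- paste0("c", 1:400)
  truth <- rep(1:2, each = 200)
  cl <- graphCluster(coords, resolution = 0.5, k_neighbors = 15, seed = 1)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[truth == 1])), 1)
  expect_equal(length(unique(cl$cluster[truth == 2])), 1)

  # low resolution merges, high resolution splits at least as much
  lo <- graphCluster(coords, resolution = 0.01, k_neighbors = 15, seed = 1)
  hi <- graphCluster(coords, resolution = 5, k_neighbors = 15, seed = 1)
  expect_lte(length(unique(lo$cluster)), 2)
  expect_gte(length(unique(hi$cluster)), 2)

  cl2 <- graphCluster(coords, resolution = 0.5, k_neighbors = 15, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(graphCluster(coords[1:10, ], k_neighbors = 20),
               "k_neighbors")
})

test_that("cluster distributions are per-dataset proportion vectors", {
  asg <- data.frame(cell_id = paste0("c", 1:13),
                    dataset_id = c(rep("a", 3), rep("b", 10)),
                    cluster = c(0, 0, 0, rep(0, 2), rep(1, 3), rep(2, 5)))
  d <- clusterDistributions(asg)
  expect_equal(unname(d["a", ]), c(1, 0, 0))
  expect_equal(unname(d["b", ]), c(0.2, 0.3, 0.5))

  set.seed(83)
  asg2 <- data.frame(cell_id = paste0("x", 1:500),
                     dataset_id = sample(c("p", "q"), 500, replace = TRUE),
                     cluster = sample(0:6, 500, replace = TRUE))
  d2 <- clusterDistributions(asg2)
  for (ds in c("p", "q")) {
    sub <- asg2$cluster[asg2$dataset_id == ds]
    oracle <- vapply(0:6, function(k) sum(sub == k) / length(sub),
                     numeric(1))
    expect_equal(unname(d2[ds, ]), oracle)
  }
})

test_that("Jensen-Shannon distances match closed forms", {
  p <- rbind(a = c(0.5, 0.5), b = c(0.5, 0.5), c = c(1, 0), d = c(0, 1),
             e = c(0.25, 0.75))
  dm <- jsdMatrix(p)
  m <- distanceMatrix(dm)
  expect_equal(m["a", "b"], 0)
  expect_equal(m["c", "d"], log(2), tolerance = 1e-12)
  expect_equal(m["a", "e"], 0.0338, tolerance = 1e-4 / 0.0338)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_error(jsdMatrix(rbind(c(0.5, 0.6))), "sum to 1")
})

test_that("metric-mode JSD satisfies the triangle inequality", {
  set.seed(84)
  for (i in 1:1000) {
    p <- matrix(rgamma(12, 1), 3)
    p <- p / rowSums(p)
    m <- distanceMatrix(jsdMatrix(p, mode = "metric"))
    expect_lte(m[1, 2], m[1, 3] + m[2, 3] + 1e-12)
  }
})

test_that("PCD restricts to shared clusters and masks degenerate pairs", {
  p <- rbind(a = c(0.6, 0.3, 0.1), b = c(0.1, 0.3, 0.6))
  dm <- pcdMatrix(p)
  expect_equal(distanceMatrix(dm)["a", "b"], 0.9868,
               tolerance = 1e-4 / 0.9868)

  same <- rbind(a = c(0.2, 0.5, 0.3), b = c(0.2, 0.5, 0.3))
  expect_equal(distanceMatrix(pcdMatrix(same))["a", "b"], 0)

  # pair sharing only 2 of 5 clusters is undefined and masked
  p2 <- rbind(a = c(0.4, 0, 0.3, 0, 0.3),
              b = c(0.5, 0.2, 0.3, 0, 0))
  expect_warning(dm2 <- pcdMatrix(p2), "masked")
  expect_true(is.na(distanceMatrix(dm2)["a", "b"]))
  expect_false(definedMask(dm2)["a", "b"])
})

test_that("distribution PCA is degenerate on identical rows and ordered", {
  p <- matrix(rep(c(0.2, 0.3, 0.5), each = 4), nrow = 4)
  rownames(p) <- paste0("d", 1:4)
  res <- pcaOfDistributions(p)
  expect_lt(max(abs(res$coords)), 1e-12)

  set.seed(85)
  q <- matrix(rgamma(40, 1), 8)
  q <- q / rowSums(q)
  rownames(q) <- paste0("d", 1:8)
  r2 <- pcaOfDistributions(q)
  expect_true(all(diff(r2$var_explained) <= 1e-12))
  expect_lte(sum(r2$var_explained), 1 + 1e-12)
})

test_that("clustering order recovers block structure and is permutation-equivariant", {
  m <- matrix(0.8, 6, 6)
  m[1:3, 1:3] <- 0.1
  m[4:6, 4:6] <- 0.1
  diag(m) <- 0
  dimnames(m) <- list(paste0("d", 1:6), paste0("d", 1:6))
  res <- orderByClustering(m, k = 2)
  pos <- match(paste0("d", 1:6), res$order)
  expect_true(max(pos[1:3]) < min(pos[4:6]) ||
                min(pos[1:3]) > max(pos[4:6]))
  expect_equal(unname(res$groups[1:3]), rep(res$groups[["d1"]], 3))

  perm <- c(4, 1, 6, 2, 5, 3)
  res_p <- orderByClustering(m[perm, perm], k = 2)
  grp <- res$groups[res$order]
  grp_p <- res_p$groups[res$order]
  expect_true(all(table(grp, grp_p)[table(grp, grp_p) > 0] == 3))
})

test_that("masked distances are imputed with a warning before ordering", {
  m <- matrix(c(0, 0.2, NA, 0.2, 0, 0.5, NA, 0.5, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(res <- orderByClustering(m), "imputed")
  expect_length(res$order, 3)
})

test_that("cluster assignments round-trip through TSV", {
  asg <- data.frame(cell_id = paste0("c", 1:6),
                    dataset_id = rep(c("x", "y"), 3),
                    cluster = c(0, 1, 1, 0, 2, 2))
  f <- tempfile(fileext = ".tsv")
  writeClusterAssignment(asg, f)
  back <- readClusterAssignment(f)
  expect_equal(back$cluster, asg$cluster)
  expect_equal(clusterDistributions(back), clusterDistributions(asg))
  cat("cell_id\tdataset_id\n", file = f)
  expect_error(readClusterAssignment(f), "lacks column")
})
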