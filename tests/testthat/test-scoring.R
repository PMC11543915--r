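test_that("pseudo-log normalization follows the stated formulas", {
  m <- matrix(c(10, 30,
                0, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ds <- toyDataset(m, platform = "umi")
  nm <- as.matrix(assay(logNormalize(ds, scale_factor = 1e4), "logcounts"))
  expect_equal(nm["g1", "c1"], log(1 + 10 * 1e4 / 10))  # cell total 10
  expect_equal(nm["g2", "c1"], 0)                       # log1p(0)
  expect_equal(nm["g1", "c2"], log(1 + 30 * 1e4 / 35))
  expect_equal(nm["g2", "c2"], log(1 + 5 * 1e4 / 35))

  tpm <- matrix(c(1e6, 0), nrow = 2,
                dimnames = list(c("g1", "g2"), "c1"))
  tds <- toyDataset(tpm, platform = "tpm")
  tn <- as.matrix(assay(logNormalize(tds), "logcounts"))
  expect_equal(tn["g1", "c1"], log(1 + 1e6))

  zero <- toyDataset(matrix(c(1, 0), 1, 2,
                            dimnames = list("g", c("a", "b"))))
  expect_error(logNormalize(zero), "total 0")
})

test_that("a two-component cell normalizes to the worked values", {
  m <- matrix(c(10, 30), nrow = 2,
              dimnames = list(c("g1", "g2"), "c1"))
  nm <- as.matrix(assay(logNormalize(toyDataset(m), 1e4), "logcounts"))
  expect_equal(unname(nm[, 1]), c(log(1 + 2500), log(1 + 7500)))
})

test_that("variable-gene selection recovers planted high-variance genes", {
  set.seed(30)
  n_cells <- 200
  # background genes span a range of means with a common log-scale noise
  # level; planted genes carry 10x the variance at comparable means
  mu_bg <- runif(2000, 0.5, 3)
  mu_hv <- runif(50, 0.5, 3)
  bg <- matrix(rnorm(2000 * n_cells, mu_bg, 0.3), nrow = 2000)
  planted <- matrix(rnorm(50 * n_cells, mu_hv, 0.3 * sqrt(10)), nrow = 50)
  m <- pmax(rbind(bg, planted), 0.01)
  rownames(m) <- c(paste0("bg", 1:2000), paste0("hv", 1:50))
  colnames(m) <- paste0("c", seq_len(n_cells))
  top100 <- selectVariableGenes(m, n_top = 100)
  expect_gte(sum(grepl("^hv", top100)), 45)

  # constant genes are never selected
  m2 <- rbind(m, const = rep(3, n_cells))
  expect_false("const" %in% selectVariableGenes(m2, n_top = nrow(m2) - 1))

  expect_warning(all_back <- selectVariableGenes(m[1:60, ], n_top = 1000),
                 "returning all")
  expect_lte(length(all_back), 60)
})

test_that("covariate residualization matches the closed-form OLS oracle", {
  set.seed(31)
  n_cells <- 100
  covs <- data.frame(a = rnorm(n_cells), b = rnorm(n_cells),
                     c = rnorm(n_cells), d = rnorm(n_cells),
                     e = rnorm(n_cells))
  m <- matrix(rnorm(40 * n_cells), nrow = 40,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:n_cells)))
  out <- residualizeCovariates(m, covs)

  X <- cbind(1, as.matrix(covs))
  H <- solve(t(X) %*% X) %*% t(X)
  for (g in c("g1", "g17", "g40")) {
    beta <- H %*% m[g, ]
    r <- m[g, ] - as.numeric(X %*% beta)
    z <- (r - mean(r)) / sd(r)
    expect_equal(unname(out[g, ]), unname(pmin(pmax(z, -10), 10)),
                 tolerance = 1e-8)
  }
})

test_that("residualization degenerate cases behave as specified", {
  set.seed(32)
  m <- matrix(rnorm(10 * 30), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:30)))
  # all-zero covariate: dropped as collinear, result is plain z-scoring
  expect_warning(out <- residualizeCovariates(m, data.frame(z = rep(0, 30))),
                 "collinear")
  plain <- t(scale(t(m)))
  expect_equal(unname(out), unname(plain), tolerance = 1e-10,
               ignore_attr = TRUE)

  # gene exactly linear in a covariate: residuals all zero
  cov <- data.frame(a = rnorm(30))
  m2 <- m
  m2["g1", ] <- 2 * cov$a + 5
  out2 <- residualizeCovariates(m2, cov)
  expect_true(all(out2["g1", ] == 0))
})

test_that("module score is zero when all genes are identical", {
  m <- matrix(2, nrow = 30, ncol = 8,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:8)))
  s <- moduleScore(m, c("g1", "g5"), n_bins = 5, n_ctrl = 10, seed = 1)
  expect_equal(s, rep(0, 8))
})

test_that("module score equals a step-by-step independent re-derivation", {
  set.seed(40)
  m <- matrix(exp(rnorm(30 * 20)), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:20)))
  gene_set <- c("g3", "g11", "g27")
  n_bins <- 5; n_ctrl <- 4; seed <- 99
  s <- moduleScore(m, gene_set, n_bins = n_bins, n_ctrl = n_ctrl,
                   seed = seed)

  # oracle: recompute equal-frequency bins (ties by index) and replay the
  # seeded control draw gene by gene
  avg <- rowMeans(m)
  ord <- order(avg, seq_along(avg))
  bins <- integer(30)
  bins[ord] <- ceiling(seq_len(30) / (30 / n_bins))
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      members <- which(bins == bins[match(g, rownames(m))])
      sample(members, n_ctrl, replace = length(members) < n_ctrl)
    }))
  })
  oracle <- colMeans(m[gene_set, ]) - colMeans(m[ctrl, ])
  expect_identical(s, unname(as.numeric(oracle)))
})

test_that("single-bin module score uses the full gene pool as controls", {
  set.seed(41)
  m <- matrix(exp(rnorm(25 * 10)), nrow = 25,
              dimnames = list(paste0("g", 1:25), paste0("c", 1:10)))
  s <- moduleScore(m, rownames(m), n_bins = 1, n_ctrl = 7, seed = 5)
  ctrl <- withr::with_seed(5, {
    unlist(lapply(seq_len(25), function(i) sample(1:25, 7, replace = FALSE)))
  })
  oracle <- colMeans(m) - colMeans(m[ctrl, ])
  expect_identical(s, unname(as.numeric(oracle)))
})

test_that("module score is invariant to per-cell constant shifts", {
  set.seed(42)
  m <- matrix(exp(rnorm(40 * 12)), nrow = 40,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:12)))
  s1 <- moduleScore(m, c("g2", "g8"), n_bins = 4, n_ctrl = 10, seed = 3)
  m2 <- m
  m2[, 5] <- m2[, 5] + 7.3
  s2 <- moduleScore(m2, c("g2", "g8"), n_bins = 4, n_ctrl = 10, seed = 3)
  expect_equal(s2[5], s1[5], tolerance = 1e-12)
})

test_that("module scoring is bitwise reproducible under a fixed seed", {
  set.seed(43)
  m <- matrix(exp(rnorm(50 * 15)), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:15)))
  s1 <- moduleScore(m, c("g1", "g9", "g33"), seed = 11)
  s2 <- moduleScore(m, c("g1", "g9", "g33"), seed = 11)
  expect_identical(s1, s2)
  expect_warning(moduleScore(m, c("g1", "nope"), seed = 1), "absent")
  expect_error(moduleScore(m, c("none1", "none2"), seed = 1,
                           set_name = "ghost"), "ghost")
})

test_that("matching lineages attain the top module score on synthetic data", {
  spec <- cohortSpec("rec", n_cells = 1600, n_genes = 600,
                     compositions = list(c(EPI_ICM = 1 / 3, PE_I = 1 / 3,
                                           TE = 1 / 3)),
                     intermediate_fraction = 0, seed = 50)
  nd <- normalizedCohort(spec)[[1]]
  mst <- scoreModules(nd, seed = 1)
  truth <- primaryTruth(nd)
  s <- moduleScores(mst)
  for (lin in c("EPI_ICM", "PE", "TE")) {
    means <- tapply(s[, lin], truth, mean)
    expect_identical(names(which.max(means)), lin)
  }
})

test_that("min-max normalization spans [0, 1] and degrades gracefully", {
  expect_equal(minmaxScale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmaxScale(rep(3, 5)), rep(0, 5))
  set.seed(44)
  x <- rnorm(100)
  mm <- minmaxScale(x)
  expect_equal(range(mm), c(0, 1))
})

test_that("per-dataset z-scaling centers and scales each dataset slice", {
  set.seed(45)
  s <- matrix(rnorm(60), ncol = 2,
              dimnames = list(paste0("c", 1:30), c("m1", "m2")))
  ds <- rep(c("A", "B"), each = 15)
  mst <- new("ModuleScoreTable", scores = s, dataset = ds, variant = "raw",
             provenance = list())
  z <- zscaleByDataset(mst)
  zs <- moduleScores(z)
  for (d in c("A", "B")) for (mod in c("m1", "m2")) {
    expect_lt(abs(mean(zs[ds == d, mod])), 1e-6)
    expect_lt(abs(sd(zs[ds == d, mod]) - 1), 1e-6)
  }
  # hand-computed example
  hand <- (s[ds == "A", "m1"] - mean(s[ds == "A", "m1"])) /
    sd(s[ds == "A", "m1"])
  expect_equal(unname(zs[ds == "A", "m1"]), unname(hand))

  # affine invariance: a * x + b with a > 0 gives identical z-scores
  s2 <- s
  s2[ds == "A", ] <- 3.7 * s2[ds == "A", ] + 2
  mst2 <- new("ModuleScoreTable", scores = s2, dataset = ds,
              variant = "raw", provenance = list())
  expect_equal(moduleScores(zscaleByDataset(mst2)), zs, tolerance = 1e-12)
})

test_that("scoreModules assembles a table with provenance and variants", {
  spec <- threeTypeSpec("tab", 150, seed = 46, n_genes = 300)
  nd <- normalizedCohort(spec)[[1]]
  mst <- scoreModules(nd, n_bins = 10, n_ctrl = 20, seed = 2)
  expect_s4_class(mst, "ModuleScoreTable")
  expect_identical(scoreVariant(mst), "raw")
  expect_identical(colnames(moduleScores(mst)),
                   names(markerSets(defaultMarkerPanel())))
  mm <- minmaxModuleScores(mst)
  expect_identical(scoreVariant(mm), "minmax")
  expect_true(all(moduleScores(mm) >= 0 & moduleScores(mm) <= 1))
  f <- tempfile(fileext = ".tsv")
  writeModuleScores(mst, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(back$EPI_ICM, unname(moduleScores(mst)[, "EPI_ICM"]))
  expect_true(file.exists(paste0(f, ".json")))
})
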