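test_that("normalization standardizes, is magnitude-blind, and tags constants", {
  withr::with_seed(2, p <- runif(20, 0, 1))
  z <- normalize_qisp(p)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_false(attr(z, "degenerate"))
  expect_equal(as.numeric(normalize_qisp(5 * p)), as.numeric(z))

  zc <- normalize_qisp(rep(0.7, 20))
  expect_equal(as.numeric(zc), rep(0, 20))
  expect_true(attr(zc, "degenerate"))
})

test_that("Pearson distance: self 0, anticorrelated 2, affine-invariant", {
  withr::with_seed(4, a <- runif(20))
  expect_equal(pearson_distance(a, a), 0)
  expect_equal(pearson_distance(a, -a), 2)
  expect_equal(pearson_distance(a, 3 * a + 7), 0)
  expect_error(pearson_distance(a, rep(1, 20)), "zero-variance")
})

test_that("identical profiles merge first at height zero; leaves equal genes", {
  withr::with_seed(6, base <- runif(20))
  m <- rbind(g1 = base, g2 = base, g3 = -base + 2 * mean(base))
  tree <- hierarchical_cluster(m)
  expect_equal(length(tree$labels), 3)
  expect_equal(tree$height[1], 0)
  first <- tree$merge[1, ]
  expect_setequal(tree$labels[-first], c("g1", "g2"))
})

test_that("average-linkage merge heights match a naive O(n^3) oracle", {
  withr::with_seed(9, m <- matrix(runif(8 * 20), 8, 20))
  rownames(m) <- sprintf("g%d", 1:8)
  tree <- hierarchical_cluster(m, linkage = "average")
  d <- as.dist(1 - cor(t(m[order(rownames(m)), ])))
  expect_equal(sort(tree$height), naive_average_linkage_heights(d))
})

test_that("cut_clusters covers the trivial cuts and validates k", {
  withr::with_seed(10, m <- matrix(runif(6 * 20), 6, 20))
  rownames(m) <- sprintf("g%d", 1:6)
  tree <- hierarchical_cluster(m)
  expect_equal(unname(cut_clusters(tree, 6)), 1:6)
  expect_equal(unname(cut_clusters(tree, 1)), rep(1L, 6))
  expect_error(cut_clusters(tree, 0), "between 1 and")
  expect_error(cut_clusters(tree, 7), "between 1 and")
  # labels are numbered by first appearance in label order
  lab <- cut_clusters(tree, 3)
  expect_equal(unique(unname(lab)), sort(unique(unname(lab))))
})

test_that("three planted archetypes form monophyletic clades and are recovered at k = 3", {
  truth <- generate_truth_profiles(
    30, c(vz_peak = 1 / 3, iz_peak = 1 / 3, cp_peak = 1 / 3), seed = 14)
  m <- truth_profile_matrix(truth)
  withr::with_seed(15, noisy <- m + matrix(rnorm(length(m), 0, 0.02), nrow(m)))
  noisy <- pmax(noisy, 0)
  tree <- hierarchical_cluster(t(apply(noisy, 1, normalize_qisp)))
  lab <- cut_clusters(tree, 3)
  acc <- permutation_accuracy(lab[truth$genes$gene_id], truth$genes$archetype)
  expect_equal(acc, 1.0)
})

test_that("cluster recovery stays above 95% across 20 seeds at 10% profile noise", {
  accs <- vapply(1:20, function(s) {
    truth <- generate_truth_profiles(
      60, c(vz_peak = 1 / 3, iz_peak = 1 / 3, cp_peak = 1 / 3),
      seed = 2000 + s)
    m <- truth_profile_matrix(truth)
    amp <- max(m)
    withr::with_seed(3000 + s,
      noisy <- pmax(m + matrix(rnorm(length(m), 0, 0.1 * amp), nrow(m)), 0))
    cl <- cluster_qisps(noisy, k = 3)
    lab <- setNames(cl$labels$cluster, cl$labels$gene_id)
    permutation_accuracy(lab[truth$genes$gene_id], truth$genes$archetype)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("zone map validates its partition and assign_zone uses the peak", {
  zm <- zone_map()
  expect_equal(assign_zone(archetype_profile(archetype_spec("p", 5, 2, 1)), zm),
               "deep")
  expect_equal(assign_zone(archetype_profile(archetype_spec("p", 12, 2, 1)), zm),
               "middle")
  expect_equal(assign_zone(archetype_profile(archetype_spec("p", 18, 2, 1)), zm),
               "upper")
  # exact tie between bins 10 and 11 resolves superficially -> middle
  tie <- rep(0, 20); tie[10] <- 1; tie[11] <- 1
  expect_equal(assign_zone(tie, zm), "middle")
  expect_equal(assign_zone(rep(0.2, 20), zm), "unassigned")
  expect_error(zone_map(deep = 1:10, middle = 11:14, upper = 16:20),
               "partition")
  expect_error(zone_map(deep = 2:10, middle = c(1, 11:15), upper = 16:20),
               "contiguous")
})

test_that("zone assignment agrees with a brute-force argmax check per cluster", {
  truth <- generate_truth_profiles(
    45, c(vz_peak = 1 / 3, iz_peak = 1 / 3, cp_peak = 1 / 3), seed = 31)
  cl <- cluster_qisps(truth_profile_matrix(truth), k = 3)
  zm <- zone_map()
  for (c_id in rownames(cl$centroids)) {
    peak <- max(which(cl$centroids[c_id, ] == max(cl$centroids[c_id, ])))
    want <- if (peak <= 10) "deep" else if (peak <= 15) "middle" else "upper"
    expect_equal(unname(cl$zone_of_cluster[c_id]), want)
  }
})

test_that("zone composition arithmetic reports half-up integer percentages", {
  zones <- rep(c("deep", "middle", "upper"), c(44, 49, 224))
  gs <- group_summary(zones)
  expect_equal(gs$n, c(44L, 49L, 224L))
  expect_equal(gs$pct[gs$zone == "deep"], 14L)
  expect_equal(gs$pct[gs$zone == "upper"], 71L)
  expect_equal(gs$pct_1dp[gs$zone == "middle"], 15.5)
  expect_lte(abs(sum(gs$pct) - 100), 1)
})

test_that("group_summary percentage sums stay within 1 of 100 on random splits", {
  withr::with_seed(41, {
    for (i in 1:10) {
      zones <- sample(c("deep", "middle", "upper"), sample(10:400, 1),
                      replace = TRUE)
      expect_lte(abs(sum(group_summary(zones)$pct) - 100), 1)
    }
  })
  expect_error(group_summary(character()), "no genes")
})

test_that("end-to-end scale/shift invariance of cluster label and zone", {
  truth <- generate_truth_profiles(
    30, c(vz_peak = 1 / 3, iz_peak = 1 / 3, cp_peak = 1 / 3), seed = 51)
  m <- truth_profile_matrix(truth)
  cl1 <- cluster_qisps(m, k = 3)
  m2 <- m
  m2[4, ] <- 7.3 * m2[4, ] + 0.9  # positive affine transform of one gene
  cl2 <- cluster_qisps(m2, k = 3)
  expect_equal(cl1$labels$cluster, cl2$labels$cluster)
  expect_equal(cl1$labels$zone, cl2$labels$zone)
})

test_that("degenerate profiles are excluded with NA cluster and unassigned zone", {
  truth <- generate_truth_profiles(10, c(cp_peak = 1), seed = 61)
  m <- rbind(truth_profile_matrix(truth), flatgene = rep(0.5, 20))
  suppressMessages(cl <- cluster_qisps(m, k = 2))
  row <- cl$labels[cl$labels$gene_id == "flatgene", ]
  expect_true(is.na(row$cluster))
  expect_equal(row$zone, "unassigned")
  expect_equal(sum(!is.na(cl$labels$cluster)), 10)
})

test_that("annotation subsetting is a case-insensitive substring filter", {
  anno <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    term = c("receptor activity", "synapse", "synaptic transmission",
             "kinase", "Receptor binding"))
  genes <- paste0("g", 5:1)
  expect_equal(subset_by_annotation(genes, anno, "receptor"), c("g5", "g1"))
  expect_equal(subset_by_annotation(genes, anno, "synap"), c("g3", "g2"))
  expect_equal(subset_by_annotation(genes, anno, "nuclear"), character())
})

test_that("cluster trees export to parseable Newick with merge-height branch lengths", {
  truth <- generate_truth_profiles(12, c(vz_peak = 0.5, cp_peak = 0.5), seed = 71)
  cl <- cluster_qisps(truth_profile_matrix(truth), k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(cl, path)
  phy <- ape::read.tree(path)
  expect_equal(sort(phy$tip.label), sort(cl$labels$gene_id))
})
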