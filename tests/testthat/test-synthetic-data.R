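test_that("truth generation apportions archetypes exactly and peaks land in zone", {
  truth <- generate_truth_profiles(
    60, c(vz_peak = 1 / 3, iz_peak = 1 / 3, cp_peak = 1 / 3), seed = 1)
  counts <- table(truth$genes$archetype)
  expect_equal(unname(counts[c("vz_peak", "iz_peak", "cp_peak")]),
               rep(20L, 3), ignore_attr = TRUE)

  m <- truth_profile_matrix(truth)
  zone_bins <- list(vz_peak = 1:10, iz_peak = 11:15, cp_peak = 16:20)
  for (i in seq_len(nrow(m))) {
    arch <- truth$genes$archetype[i]
    expect_true(which.max(m[i, ]) %in% zone_bins[[arch]],
                label = paste("argmax of", truth$genes$gene_id[i], "in", arch))
  }
})

test_that("flat archetype is constant and regeneration is bit-for-bit", {
  t1 <- generate_truth_profiles(1, c(flat = 1), seed = 3)
  p <- truth_profile_matrix(t1)[1, ]
  expect_true(all(p == p[1]))

  t2 <- generate_truth_profiles(25, c(dual_peak = 0.5, flat = 0.5), seed = 99)
  t3 <- generate_truth_profiles(25, c(dual_peak = 0.5, flat = 0.5), seed = 99)
  expect_identical(t2, t3)
  t4 <- generate_truth_profiles(25, c(dual_peak = 0.5, flat = 0.5), seed = 100)
  expect_false(identical(t2$profiles, t4$profiles))
})

test_that("deep_invalid profiles, and only they, have noise-free deep ratio > 1", {
  truth <- generate_truth_profiles(100, c(deep_invalid = 0.1, cp_peak = 0.9),
                                   seed = 7)
  m <- truth_profile_matrix(truth)
  ratios <- apply(m, 1, brute_deep_ratio)
  expect_identical(sum(ratios > 1), 10L)
  expect_setequal(truth$genes$gene_id[ratios > 1],
                  truth$genes$gene_id[truth$genes$archetype == "deep_invalid"])

  # every built-in archetype respects the construction invariant
  for (nm in names(default_archetypes())) {
    p <- archetype_profile(default_archetypes()[[nm]])
    r <- brute_deep_ratio(p)
    if (nm == "deep_invalid") {
      expect_gt(r, 1)
    } else {
      expect_lte(r, 1)
    }
  }
})

test_that("generator rejects bad mixes", {
  expect_error(generate_truth_profiles(10, c(nonsense = 1), seed = 1),
               "unknown archetype")
  expect_error(generate_truth_profiles(10, c(vz_peak = 1.2, cp_peak = -0.2),
                                       seed = 1),
               "non-negative")
  expect_error(generate_truth_profiles(10, c(vz_peak = 0.6, cp_peak = 0.6),
                                       seed = 1),
               "sum to 1")
})

test_that("flat zero profile renders to uniform white and zero densities", {
  rp <- render_params(background_level = 0, illumination_gradient = 0,
                      noise_sd = 0)
  r <- render_ish_image(rep(0, 20), rp, seed = 1)
  expect_true(all(r$image == 255))
  q <- extract_qisp(r$image, r$roi, "zero")
  expect_equal(q$raw, rep(0, 20))
  expect_equal(q$smoothed, rep(0, 20))
})

test_that("impulse profile renders exactly one dark band of wall_span/20 rows", {
  rp <- render_params(background_level = 0, illumination_gradient = 0,
                      noise_sd = 0, wall_span_px = 200)
  p <- rep(0, 20); p[10] <- 1
  r <- render_ish_image(p, rp, seed = 1)
  dark_rows <- which(apply(r$image, 1, min) == 0)
  expect_length(dark_rows, 200 / 20)
  expect_equal(dark_rows, seq(min(dark_rows), length.out = 10))
  # the dark band spans exactly the band width in columns
  dark_cols <- which(apply(r$image, 2, min) == 0)
  expect_length(dark_cols, rp$band_width_px)
})

test_that("rendered pixel values clamp to the bit depth range", {
  rp <- render_params(background_level = 0.5, noise_sd = 0.5, bit_depth = 8)
  r <- render_ish_image(rep(0.9, 20), rp, seed = 2)
  expect_true(all(r$image >= 0 & r$image <= 255))
  rp16 <- render_params(noise_sd = 0, bit_depth = 16)
  r16 <- render_ish_image(rep(0.5, 20), rp16, seed = 2)
  expect_true(all(r16$image >= 0 & r16$image <= 65535))
})

test_that("dual-peak rendering round-trips with peaks within 1 sROI", {
  p <- archetype_profile(default_archetypes()$dual_peak)
  true_peaks <- c(5, 17)
  sm <- extract_from_profile(p, render_params(noise_sd = 0.02), seed = 3)
  got <- c(which.max(sm[1:10]), 10 + which.max(sm[11:20]))
  expect_true(all(abs(got - true_peaks) <= 1))
})

test_that("rendering is deterministic under seed", {
  rp <- render_params(noise_sd = 0.03)
  p <- archetype_profile(default_archetypes()$iz_peak)
  expect_identical(render_ish_image(p, rp, seed = 5)$image,
                   render_ish_image(p, rp, seed = 5)$image)
  expect_false(identical(render_ish_image(p, rp, seed = 5)$image,
                         render_ish_image(p, rp, seed = 6)$image))
})

test_that("zero jitter yields pixel-identical replicates", {
  rp <- render_params(noise_sd = 0)
  p <- archetype_profile(default_archetypes()$cp_peak)
  reps <- generate_replicates(
    p, 3, jitter = list(axis_shift_px = 0, rotation_deg = 0,
                        amplitude_scale_sd = 0),
    render = rp, seed = 4)
  expect_identical(reps[[1]]$image, reps[[2]]$image)
  expect_identical(reps[[2]]$image, reps[[3]]$image)
  expect_identical(reps[[1]]$roi, reps[[3]]$roi)
})

test_that("jittered replicates keep the extracted peak within 2 sROIs of truth", {
  p <- archetype_profile(default_archetypes()$iz_peak)
  reps <- generate_replicates(p, 5, render = render_params(), seed = 11)
  imgs <- vapply(reps, function(r) {
    q <- extract_qisp(r$image, r$roi, "g")
    which.max(qisp_vector(q))
  }, numeric(1))
  expect_true(all(abs(imgs - 12) <= 2))
})

test_that("amplitude-only jitter changes magnitude but keeps Pearson r near 1", {
  rp <- render_params(noise_sd = 0)
  p <- archetype_profile(default_archetypes()$cp_peak)
  reps <- generate_replicates(
    p, 2, jitter = list(axis_shift_px = 0, rotation_deg = 0,
                        amplitude_scale_sd = 0.2),
    render = rp, seed = 8)
  v1 <- qisp_vector(extract_qisp(reps[[1]]$image, reps[[1]]$roi, "a"))
  v2 <- qisp_vector(extract_qisp(reps[[2]]$image, reps[[2]]$roi, "b"))
  expect_false(isTRUE(all.equal(max(v1), max(v2), tolerance = 1e-3)))
  expect_gt(cor(v1, v2), 0.995)
})

test_that("archetype separability: peaks recovered within 1 sROI at low noise", {
  truth <- generate_truth_profiles(
    60, c(vz_peak = 1 / 3, iz_peak = 1 / 3, cp_peak = 1 / 3), seed = 21)
  m <- truth_profile_matrix(truth)
  rp <- render_params(noise_sd = 0.02)
  hits <- vapply(seq_len(nrow(m)), function(i) {
    sm <- extract_from_profile(m[i, ], rp, seed = 300 + i)
    abs(which.max(sm) - which.max(m[i, ])) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("expression generator: null effects, planted folds, control baseline", {
  truth <- generate_truth_profiles(20, c(cp_peak = 1), seed = 2)
  truth$genes$log2fc <- rep(0, 20)
  em <- generate_expression_matrix(truth, replicate_sd = 0, n_controls = 0,
                                   seed = 5)
  m <- as.matrix(em$expression[-1])
  grp <- em$samples$group
  expect_equal(rowMeans(m[, grp == "gfp_pos"]),
               rowMeans(m[, grp == "gfp_neg"]))

  truth$genes$log2fc <- rep(log2(4), 20)
  em4 <- generate_expression_matrix(truth, replicate_sd = 0, n_controls = 0,
                                    seed = 5)
  sc <- screen_genes(em4$expression, em4$samples, "gfp_pos", "gfp_neg",
                     threshold = 7, fold_cutoff = 3)
  expect_equal(unique(sc$fold), 4)
  expect_length(screen_hits(sc, "up"), 20)

  em_c <- generate_expression_matrix(truth, n_controls = 10, seed = 5)
  ctrl_vals <- unlist(em_c$expression[
    em_c$expression$gene_id %in% em_c$controls, -1])
  se <- 0.7 / sqrt(length(ctrl_vals))
  expect_lt(abs(mean(ctrl_vals) - 5.5), 3 * se)
})

test_that("expression generation is deterministic under seed", {
  truth <- generate_truth_profiles(10, c(iz_peak = 1), seed = 3)
  e1 <- generate_expression_matrix(truth, seed = 9)
  e2 <- generate_expression_matrix(truth, seed = 9)
  expect_identical(e1, e2)
})
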