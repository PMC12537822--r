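test_that("colocalization partitions matched and unmatched spots", {
  set.seed(1)
  pts <- data.frame(y = runif(40, 0, 100), x = runif(40, 0, 100))
  same <- colocalization(pts, pts, 2)
  expect_equal(same$colocalized_fraction, 1)
  expect_equal(same$false_positive_rate, 0)
  expect_equal(same$false_negative_rate, 0)

  far <- data.frame(y = pts$y + 500, x = pts$x)
  disj <- colocalization(pts, far, 2)
  expect_equal(disj$n_colocalized, 0)
  expect_equal(disj$false_positive_rate, 1)
  expect_equal(disj$false_negative_rate, 1)
})

test_that("a planted 90/5/5 overlap structure is recovered exactly", {
  set.seed(2)
  shared <- data.frame(y = runif(90, 10, 490), x = runif(90, 10, 490))
  ref_only <- data.frame(y = runif(5, 510, 590), x = runif(5, 10, 90))
  test_only <- data.frame(y = runif(5, 510, 590), x = runif(5, 510, 590))
  reference <- rbind(shared, ref_only)
  test <- rbind(shared + rnorm(180, 0, 0.2), test_only)
  rep <- colocalization(reference, test, 2)
  expect_equal(rep$n_colocalized, 90)
  expect_equal(rep$false_positive_rate, 5 / 95)
  expect_equal(rep$false_negative_rate, 5 / 95)
  expect_gt(rep$colocalized_fraction, 0.9)
})

test_that("swapping reference and test swaps the two error rates", {
  set.seed(3)
  a <- data.frame(y = runif(30, 0, 50), x = runif(30, 0, 50))
  b <- data.frame(y = runif(22, 0, 50), x = runif(22, 0, 50))
  f <- colocalization(a, b, 3)
  r <- colocalization(b, a, 3)
  expect_equal(f$n_colocalized, r$n_colocalized)
  expect_equal(f$false_positive_rate, r$false_negative_rate)
  expect_equal(f$false_negative_rate, r$false_positive_rate)
})

test_that("retention ratios track the simulated stripping chemistry", {
  cfg <- sim_config(ny = 96, nx = 96, seed = 2, residual_fraction = 0.05)
  ser <- simulate_hybridize_cleave_series(cfg, 15, 10)
  ret <- retention_series(ser, mean(ser$background))
  expect_equal(nrow(ret), 15)
  expect_true(all(abs(ret$hyb_ratio - 10) < 1))
  expect_false(any(ret$below_floor))

  # post-cleave equal to background gives residual ratio 1
  one <- retention_series(data.frame(round = 1, post_hyb_mean = 1000,
                                     post_cleave_mean = 100), 100)
  expect_equal(one$cleave_ratio, 1)
  expect_equal(nrow(one), 1)
  expect_error(retention_series(one, 0), class = "spotcode_input_error")
})

test_that("nucleus distances are signed and match the analytic disk", {
  mask <- matrix(0L, 64, 64)
  yy <- row(mask) - 1; xx <- col(mask) - 1
  mask[(yy - 32)^2 + (xx - 32)^2 <= 100] <- 1L   # disk R = 10 at (32, 32)

  # boundary spot: distance 0
  bpix <- spotcode:::mask_boundary(mask)[1, ]
  d0 <- distance_to_nucleus(data.frame(y = bpix[1] - 1, x = bpix[2] - 1), mask)
  expect_equal(d0$distances, 0)

  # center of the disk: -R within pixel discretization
  dc <- distance_to_nucleus(data.frame(y = 32, x = 32), mask)
  expect_lt(abs(dc$distances - (-10)), 1)

  # planted annulus at distance d outside: mean recovered within a pixel
  set.seed(4)
  th <- runif(60, 0, 2 * pi)
  ann <- data.frame(y = 32 + 16 * sin(th), x = 32 + 16 * cos(th))
  da <- distance_to_nucleus(ann, mask)
  expect_lt(abs(mean(da$distances) - 6), 1)

  expect_error(distance_to_nucleus(ann, matrix(0L, 8, 8)),
               class = "spotcode_input_error")
})

test_that("signed distances agree with the brute-force boundary scan", {
  set.seed(5)
  mask <- matrix(0L, 48, 48)
  yy <- row(mask) - 1; xx <- col(mask) - 1
  mask[(yy - 20)^2 + (xx - 25)^2 <= 64] <- 1L
  mask[(yy - 38)^2 / 4 + (xx - 12)^2 <= 25] <- 1L   # second, elliptic nucleus
  pts <- data.frame(y = runif(25, 0, 47), x = runif(25, 0, 47))
  got <- distance_to_nucleus(pts, mask)$distances
  want <- sapply(seq_len(25), function(i)
    oracle_nucleus_distance(pts$y[i], pts$x[i], mask))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("depth profiles integrate to one and find planted structure", {
  set.seed(6)
  # uniform depths: flat profile over the central 80% of the grid
  unif <- kde_depth_profile(runif(500), rep("u", 500))
  dx <- diff(unif$grid[1:2])
  expect_equal(sum(unif$density[, 1]) * dx, 1, tolerance = 0.01)
  central <- unif$density[unif$grid >= 0.1 & unif$grid <= 0.9, 1]
  expect_lt(max(central) / min(central), 1.3)

  # concentrated band: mode within 0.02 of the planted depth
  band <- kde_depth_profile(pmin(pmax(rnorm(400, 0.3, 0.02), 0), 1),
                            rep("L4", 400))
  expect_lt(abs(band$modes[["L4"]] - 0.3), 0.02)
  expect_equal(sum(band$density[, 1]) * dx, 1, tolerance = 0.01)

  expect_warning(kde_depth_profile(c(0.5, runif(10)),
                                   c("lonely", rep("u", 10))), "lonely")
  expect_error(kde_depth_profile(c(1.4, 0.5), c("a", "a")),
               class = "spotcode_input_error")
})

test_that("laminar bands yield ordered, separated KDE modes", {
  set.seed(7)
  centers <- c(0.15, 0.4, 0.6, 0.85)
  depths <- unlist(lapply(centers, function(m)
    pmin(pmax(rnorm(200, m, 0.04), 0), 1)))
  types <- rep(paste0("L", 1:4), each = 200)
  prof <- kde_depth_profile(depths, types)
  modes <- prof$modes[paste0("L", 1:4)]
  expect_true(all(diff(modes) > 0))
  expect_true(all(abs(modes - centers) < 0.02))
  # every per-type profile integrates to one
  dx <- diff(prof$grid[1:2])
  for (k in 1:4)
    expect_equal(sum(prof$density[, k]) * dx, 1, tolerance = 0.01)
})

test_that("normalized depth spans the two reference polylines", {
  edge <- cbind(c(0, 0), c(0, 100))       # horizontal line y = 0
  deep <- cbind(c(50, 50), c(0, 100))     # horizontal line y = 50
  cells <- data.frame(y = c(0, 12.5, 25, 50), x = c(10, 20, 30, 40))
  d <- normalize_depth(cells, edge, deep)
  expect_equal(d, c(0, 0.25, 0.5, 1))
})

test_that("cell-type frequencies sum to one over typed cells", {
  regions <- data.frame(label = 1:5, centroid_y = 1:5, centroid_x = 1:5,
                        code = "11",
                        cell_type = c("a", "a", "b", NA, "a"))
  atlas <- cell_atlas(regions)
  tf <- type_frequencies(atlas)
  expect_equal(sum(tf$frequency), 1)
  expect_equal(tf$n[tf$cell_type == "a"], 3)
  expect_equal(atlas$n_untyped, 1)

  solo <- cell_atlas(data.frame(label = 1, centroid_y = 0, centroid_x = 0,
                                code = "11", cell_type = "a"))
  expect_equal(type_frequencies(solo)$frequency, 1)

  none <- cell_atlas(regions[4, ])
  expect_error(type_frequencies(none), class = "spotcode_input_error")
})

test_that("tissue-scene frequencies are recovered within the multinomial CI", {
  cb <- assign_panel(build_codebook(3, 2, 6, seed = 2),
                     data.frame(cell_type = rep(paste0("t", 1:6), each = 10),
                                gene = paste0("g", 1:60)))
  freqs <- c(t1 = 0.4, t2 = 0.2, t3 = 0.1, t4 = 0.1, t5 = 0.1, t6 = 0.1)
  cfg <- sim_config(ny = 420, nx = 420, seed = 45)
  sim <- simulate_tissue(cfg, cb, 170, freqs)
  dm <- decode_masks(normalize_channels(register_stack(sim$stack)$stack),
                     sim$mask, cb)
  tf <- type_frequencies(dm$atlas)
  n <- sum(tf$n)
  for (ty in tf$cell_type) {
    ci <- stats::qbinom(c(0.005, 0.995), n, freqs[[ty]]) / n
    expect_gte(tf$frequency[tf$cell_type == ty], ci[1])
    expect_lte(tf$frequency[tf$cell_type == ty], ci[2])
  }
})

test_that("group comparison reports means, sds and a t statistic", {
  set.seed(8)
  a <- rnorm(50, 10, 2); b <- rnorm(50, 12, 2)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$mean_a, mean(a))
  expect_equal(cmp$sd_b, sd(b))
  expect_lt(cmp$p.value, 0.01)
})
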