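sine_regressor <- function(duration = 600, dt = 0.5, f = 0.01) {
  t <- seq(0, duration, dt)
  tibble::tibble(time = t, value = sin(2 * pi * f * t))
}

test_that("voxelwise regression recovers regional coefficients at SNR 5", {
  reg <- sine_regressor()
  # signal sd = 2 * sd(sin) = 1.41; noise sd 0.28 -> SNR ~ 5
  spec <- coupling_spec(seed = 31, noise_sd = 0.28, ar1_coef = 0.3)
  sb <- sim_bold_volume(spec, reg, grid_shape = c(10, 10, 8), n_regions = 2,
                        region_beta_map = c("1" = 0, "2" = 2), tr_s = 1.45)
  map <- voxelwise_regression(sb$vol, reg)
  agg <- regional_aggregate(map$beta, NULL, sb$parc)
  expect_lt(abs(agg$beta[agg$region == 1]), 0.05)
  expect_equal(agg$beta[agg$region == 2], 2, tolerance = 0.05)
})

test_that("a noiseless proportional volume returns the coefficient exactly", {
  reg <- sine_regressor(duration = 120)
  spec <- coupling_spec(seed = 1, noise_sd = 0)
  sb <- sim_bold_volume(spec, reg, grid_shape = c(4, 4, 4), n_regions = 2,
                        region_beta_map = c("1" = 3, "2" = 3),
                        tr_s = 1.45, drift_sd = 0)
  map <- voxelwise_regression(sb$vol, reg)
  expect_equal(as.vector(map$beta), rep(3, 64), tolerance = 1e-9)
})

test_that("beta is equivariant under regressor rescaling", {
  reg <- sine_regressor(duration = 300)
  spec <- coupling_spec(seed = 32, noise_sd = 0.3)
  sb <- sim_bold_volume(spec, reg, grid_shape = c(6, 6, 4), n_regions = 2,
                        region_beta_map = c("1" = 1, "2" = 2), tr_s = 1.45)
  b1 <- voxelwise_regression(sb$vol, reg)$beta
  reg10 <- reg
  reg10$value <- reg$value * 10
  b10 <- voxelwise_regression(sb$vol, reg10)$beta
  expect_equal(b10, b1 / 10, tolerance = 1e-9)
  const <- reg
  const$value <- 1
  expect_error(voxelwise_regression(sb$vol, const), "constant regressor")
})

test_that("under the null about 0.5% of voxels pass p < 0.005", {
  reg <- sine_regressor()
  fracs <- vapply(c(41, 42), function(s) {
    spec <- coupling_spec(seed = s, noise_sd = 0.5, ar1_coef = 0)
    sb <- sim_bold_volume(spec, reg, grid_shape = c(12, 12, 10),
                          n_regions = 2,
                          region_beta_map = c("1" = 0, "2" = 0),
                          tr_s = 1.45, drift_sd = 0)
    map <- voxelwise_regression(sb$vol, reg)
    mean(map$p < 0.005, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(fracs), 0.001)
  expect_lt(mean(fracs), 0.012)
})

test_that("cluster-extent thresholds behave monotonically and reproducibly", {
  mask <- array(TRUE, c(14, 14, 12))
  vd <- c(3.4, 3.4, 6)
  a <- mc_cluster_threshold(mask, vd, 7, voxel_p = 0.01, n_iter = 200,
                            seed = 5)
  b <- mc_cluster_threshold(mask, vd, 7, voxel_p = 0.001, n_iter = 200,
                            seed = 5)
  expect_lte(b$k_voxels, a$k_voxels)
  a2 <- mc_cluster_threshold(mask, vd, 7, voxel_p = 0.01, n_iter = 200,
                             seed = 5)
  expect_identical(a$max_sizes, a2$max_sizes)
  expect_equal(a$k_mm3, a$k_voxels * prod(vd))

  white <- mc_cluster_threshold(mask, vd, vd, voxel_p = 0.005, n_iter = 200,
                                seed = 6)
  expect_lte(white$k_voxels, 3)
  expect_error(
    mc_cluster_threshold(array(TRUE, c(3, 3, 3)), vd, 40, n_iter = 200,
                         seed = 1),
    "too small"
  )
  expect_error(mc_cluster_threshold(mask, vd, 7, n_iter = 100), "at least 200")
  expect_error(mc_cluster_threshold(mask, vd, 1), "at least the voxel size")
})

test_that("cluster labelling uses face adjacency", {
  flag <- array(FALSE, c(4, 4, 4))
  flag[1, 1, 1] <- TRUE
  flag[2, 1, 1] <- TRUE    # face neighbour
  flag[4, 4, 4] <- TRUE    # far voxel
  flag[3, 2, 1] <- TRUE
  flag[2, 2, 2] <- TRUE    # only diagonal contact: separate cluster
  lab <- bercouple:::label_clusters(flag)
  expect_equal(sort(lab$sizes), c(1, 1, 1, 2))
})

test_that("regional aggregation computes voxel percentages by definition", {
  labels <- array(0L, c(5, 2, 1))
  labels[1:5, 1, 1] <- 1L
  labels[1:5, 2, 1] <- 2L
  parc <- parcellation(labels)
  beta <- array(seq_len(10) / 10, c(5, 2, 1))
  sig <- array(FALSE, c(5, 2, 1))
  sig[1:3, 1, 1] <- TRUE   # 3 of 5 voxels in region 1
  sig[1:5, 2, 1] <- TRUE   # all of region 2
  agg <- regional_aggregate(beta, sig, parc)
  expect_equal(agg$voxel_beta_pct, c(60, 100))
  expect_equal(agg$beta, c(mean(beta[1:5, 1, 1]), mean(beta[1:5, 2, 1])))
})

test_that("voxel percentage is monotone in the voxel threshold", {
  reg <- sine_regressor(duration = 300)
  spec <- coupling_spec(seed = 35, noise_sd = 0.5)
  sb <- sim_bold_volume(spec, reg, grid_shape = c(8, 8, 6), n_regions = 2,
                        region_beta_map = c("1" = 0.5, "2" = 1), tr_s = 1.45)
  map <- voxelwise_regression(sb$vol, reg)
  pcts <- vapply(c(0.05, 0.005, 0.0005), function(p) {
    sig <- cluster_correct(map, voxel_p = p, k_voxels = 1)
    mean(regional_aggregate(map$beta, sig, sb$parc)$voxel_beta_pct)
  }, numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("group regional tests flag true effects and not the null", {
  set.seed(50)
  n_sub <- 20
  regional <- purrr::map_dfr(seq_len(n_sub), function(s) {
    tibble::tibble(
      subject = s,
      region = 1:12,
      beta = c(rnorm(11, 0, 0.5), rnorm(1, 1, 0.5))
    )
  })
  g <- group_regional_test(regional, "beta")
  expect_true(g$significant[g$region == 12])
  expect_lte(sum(g$significant[g$region != 12]), 1)

  ident <- tibble::tibble(subject = rep(1:4, each = 2),
                          region = rep(1:2, 4), beta = 1)
  gi <- group_regional_test(ident, "beta")
  expect_true(all(gi$degenerate))
})

test_that("seed connectivity finds shared-drive regions and not noise", {
  t <- seq(0, 600, 0.5)
  reg <- tibble::tibble(time = t, value = sin(2 * pi * 0.01 * t))
  spec <- coupling_spec(seed = 36, noise_sd = 0.28, ar1_coef = 0.3)
  sb <- sim_bold_volume(spec, reg, grid_shape = c(8, 8, 6), n_regions = 3,
                        region_beta_map = c("1" = 1.5, "2" = 1.5, "3" = 0),
                        tr_s = 1.45)
  conn <- seed_connectivity_map(sb$vol, sb$parc, seed_region = 1)
  z <- conn$regional$fisher_z
  expect_equal(which.max(z), 1)
  expect_gt(z[2], atanh(0.5))
  expect_lt(abs(z[3]), 0.25)
})

test_that("CVR recovery under the CO2 block paradigm", {
  par <- sim_co2_paradigm(seed = 77, baseline_petco2 = 40)
  petco2 <- tibble::tibble(time = par$target$time,
                           value = par$target$approach)
  # signal sd ~ 0.2 * sd(petco2) ~ 0.5%; noise 0.1% -> SNR ~ 5
  spec <- coupling_spec(seed = 37, noise_sd = 0.1, ar1_coef = 0.3)
  sb <- sim_bold_volume(spec, petco2, grid_shape = c(8, 8, 6), n_regions = 2,
                        region_beta_map = c("1" = 0.2, "2" = 0), tr_s = 1.45)
  cm <- cvr_map(sb$vol, petco2, parc = sb$parc)
  expect_equal(cm$regional$cvr[1], 0.2, tolerance = 0.02 / 0.2)
  expect_lt(abs(cm$regional$cvr[2]), 0.02)
  # unit change mmHg -> kPa scales CVR reciprocally
  kpa <- petco2
  kpa$value <- petco2$value * 0.1333
  cm2 <- cvr_map(sb$vol, kpa, parc = sb$parc)
  expect_equal(cm2$regional$cvr[1], cm$regional$cvr[1] / 0.1333,
               tolerance = 1e-9)
})

test_that("the lag scan recovers an injected hemodynamic lag", {
  t <- seq(0, 600, 0.5)
  reg <- tibble::tibble(time = t, value = sin(2 * pi * 0.01 * t))
  spec <- coupling_spec(seed = 38, coupling_lag_s = 4, noise_sd = 0.3)
  sb <- sim_bold_volume(spec, reg, grid_shape = c(6, 6, 4), n_regions = 2,
                        region_beta_map = c("1" = 1, "2" = 1), tr_s = 1.45)
  scan <- scan_regressor_lag(sb$vol, reg, lags_s = 0:8)
  expect_equal(scan$best_lag_s, 4, tolerance = 1.01)
})

test_that("jaccard index handles the edge cases", {
  expect_equal(jaccard_index(1:3, 1:3), 1)
  expect_equal(jaccard_index(1:2, 2:3), 1 / 3)
  expect_equal(jaccard_index(integer(0), integer(0)), 1)
  expect_equal(jaccard_index(1, integer(0)), 0)
})
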