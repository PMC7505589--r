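#' Voxelwise regression of percent-BOLD change on a physiological regressor
#'
#' For every in-mask voxel, ordinary least squares of the BOLD time series
#' on `[intercept, linear drift, regressor]`. The regression coefficient of
#' the regressor term — percent BOLD change per unit regressor — is
#' returned together with its t statistic and two-sided p-value. The
#' regressor is linearly interpolated to the frame mid-times; no response
#' function is convolved in, so metrics can be compared on an equal
#' footing.
#'
#' @param vol A [volume_series()].
#' @param regressor Tibble (time, value).
#' @param lag_s Shift applied to the regressor before resampling (s).
#'
#' @return Object of class `stat_map`: list with 3D arrays `beta`, `t`,
#'   `p`, the `mask`, degrees of freedom `df` and frame count `n_frames`.
#' @export
voxelwise_regression <- function(vol, regressor, lag_s = 0) {
  stopifnot(inherits(vol, "volume_series"))
  dims <- dim(vol$data)
  n_t <- dims[4]
  frame_times <- (seq_len(n_t) - 0.5) * vol$tr_s
  reg <- approx(regressor$time, regressor$value,
                xout = frame_times - lag_s, rule = 1)$y
  use_t <- which(is.finite(reg))
  if (length(use_t) < 30) abort("regressor must overlap at least 30 frames")
  reg <- reg[use_t]
  if (sd(reg) == 0) abort("constant regressor")
  tt <- frame_times[use_t] - mean(frame_times[use_t])
  x <- cbind(1, tt, reg)
  xtxi <- solve(crossprod(x))
  hat <- x %*% xtxi

  y <- matrix(vol$data, prod(dims[1:3]), n_t)[, use_t, drop = FALSE]
  vox <- which(as.vector(vol$mask))
  y <- y[vox, , drop = FALSE]
  b <- y %*% hat
  resid <- y - b %*% t(x)
  df <- length(use_t) - 3
  s2 <- rowSums(resid^2) / df
  se <- sqrt(s2 * xtxi[3, 3])
  t_stat <- b[, 3] / se
  p <- 2 * pt(-abs(t_stat), df = df)

  to_arr <- function(v) {
    a <- array(NA_real_, dims[1:3])
    a[vox] <- v
    a
  }
  structure(
    list(beta = to_arr(b[, 3]), t = to_arr(t_stat), p = to_arr(p),
         mask = vol$mask, df = df, n_frames = length(use_t)),
    class = "stat_map"
  )
}

# 6-connectivity cluster sizes of a logical 3D array; returns the sizes and
# a label array.
label_clusters <- function(flag) {
  dims <- dim(flag)
  idx <- which(flag)
  labels <- array(0L, dims)
  if (length(idx) == 0) return(list(sizes = integer(0), labels = labels))
  coords <- arrayInd(idx, dims)
  key <- function(m) (m[, 3] - 1) * dims[1] * dims[2] +
    (m[, 2] - 1) * dims[1] + m[, 1]
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = lookup)
  visited <- logical(length(idx))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  sizes <- integer(0)
  lab <- 0L
  for (i in seq_along(idx)) {
    if (visited[i]) next
    lab <- lab + 1L
    queue <- i
    visited[i] <- TRUE
    count <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      count <- count + 1L
      labels[idx[cur]] <- lab
      cc <- coords[cur, ]
      for (k in 1:6) {
        nb <- cc + offs[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        nb_lin <- as.character((nb[3] - 1) * dims[1] * dims[2] +
                                 (nb[2] - 1) * dims[1] + nb[1])
        j <- lookup[[nb_lin]]
        if (!is.null(j) && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    sizes <- c(sizes, count)
  }
  list(sizes = sizes, labels = labels)
}

gaussian_smooth_3d <- function(arr, sigma_vox) {
  dims <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 0.05) next
    r <- max(1L, ceiling(3 * s))
    if (2 * r + 1 > dims[axis]) abort("mask too small for smoothing kernel")
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    others <- setdiff(1:3, axis)
    m <- apply(arr, others, function(v) {
      vp <- c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1]))
      as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
    })
    arr <- aperm(array(m, c(dims[axis], dims[others])),
                 order(c(axis, others)))
  }
  arr
}

#' Monte Carlo cluster-extent threshold
#'
#' Estimates the minimum cluster size (face-adjacent, 6-connectivity) such
#' that clusters of voxels individually exceeding the `voxel_p` threshold
#' occur with family-wise probability at most `alpha` under a smooth
#' Gaussian null. Each iteration smooths a white-noise field to the stated
#' smoothness, standardizes it within the mask, thresholds two-sided at
#' `voxel_p`, and records the largest surviving cluster; the threshold is
#' the smallest extent whose exceedance frequency is at most `alpha`.
#'
#' @param mask 3D logical array.
#' @param voxel_dims_mm Voxel dimensions (mm).
#' @param smoothness_fwhm_mm Assumed spatial smoothness (FWHM, mm) of the
#'   noise; must be at least the voxel size.
#' @param voxel_p Per-voxel two-sided probability threshold (default 0.005).
#' @param alpha Corrected family-wise level (default 0.05).
#' @param n_iter Monte Carlo iterations (>= 200; default 2000).
#' @param seed Integer seed.
#'
#' @return List: `k_voxels` (minimum significant extent), `k_mm3`,
#'   `max_sizes` (null distribution of largest cluster sizes).
#' @export
mc_cluster_threshold <- function(mask, voxel_dims_mm, smoothness_fwhm_mm,
                                 voxel_p = 0.005, alpha = 0.05,
                                 n_iter = 2000, seed = 1L) {
  if (n_iter < 200) abort("n_iter must be at least 200")
  if (any(smoothness_fwhm_mm < min(voxel_dims_mm))) {
    abort("smoothness must be at least the voxel size")
  }
  dims <- dim(mask)
  sigma_vox <- rep(smoothness_fwhm_mm, length.out = 3) /
    (2 * sqrt(2 * log(2))) / voxel_dims_mm
  zc <- qnorm(1 - voxel_p / 2)
  in_mask <- which(mask)
  max_sizes <- integer(n_iter)
  withr::with_seed(substream_seed(seed, "cluster"), {
    for (i in seq_len(n_iter)) {
      field <- gaussian_smooth_3d(array(rnorm(prod(dims)), dims), sigma_vox)
      v <- field[in_mask]
      z <- (field - mean(v)) / sd(v)
      flag <- array(FALSE, dims)
      flag[in_mask] <- abs(z[in_mask]) > zc
      sz <- label_clusters(flag)$sizes
      max_sizes[i] <- if (length(sz)) max(sz) else 0L
    }
  })
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  list(
    k_voxels = k,
    k_mm3 = k * prod(voxel_dims_mm),
    max_sizes = max_sizes
  )
}

#' Apply voxel and cluster-extent thresholds to a stat map
#'
#' @param map A [voxelwise_regression()] `stat_map`.
#' @param voxel_p Per-voxel two-sided threshold.
#' @param k_voxels Minimum cluster extent from [mc_cluster_threshold()].
#' @return 3D logical array of voxels surviving both thresholds.
#' @export
cluster_correct <- function(map, voxel_p = 0.005, k_voxels = 1L) {
  flag <- !is.na(map$p) & map$p < voxel_p
  lab <- label_clusters(flag)
  keep <- which(lab$sizes >= k_voxels)
  out <- array(FALSE, dim(flag))
  out[lab$labels %in% keep & flag] <- TRUE
  out
}

#' Regional aggregation of a beta map
#'
#' Averages the regression coefficient over the voxels of each parcellation
#' region, and reports the percentage of region voxels whose association
#' survived cluster correction (the `voxel_beta_pct` map).
#'
#' @param beta_map 3D array of coefficients (e.g. `stat_map$beta`).
#' @param sig_mask 3D logical array of cluster-corrected significant voxels
#'   (or `NULL` for none).
#' @param parc A [parcellation()].
#'
#' @return Tibble: `region`, `name`, `n_voxels`, `beta`, `n_sig`,
#'   `voxel_beta_pct`, `empty`.
#' @export
regional_aggregate <- function(beta_map, sig_mask, parc) {
  stopifnot(inherits(parc, "parcellation"))
  if (!identical(dim(beta_map), dim(parc$labels))) abort("shape mismatch")
  if (is.null(sig_mask)) sig_mask <- array(FALSE, dim(beta_map))
  lab <- as.vector(parc$labels)
  purrr::map_dfr(seq_len(nrow(parc$regions)), function(i) {
    id <- parc$regions$region[i]
    vox <- which(lab == id)
    vals <- beta_map[vox]
    vals <- vals[is.finite(vals)]
    tibble(
      region = id,
      name = parc$regions$name[i],
      n_voxels = length(vox),
      beta = if (length(vals)) mean(vals) else NA_real_,
      n_sig = sum(sig_mask[vox], na.rm = TRUE),
      voxel_beta_pct = if (length(vox)) 100 * sum(sig_mask[vox],
                                                  na.rm = TRUE) / length(vox)
                       else NA_real_,
      empty = length(vals) == 0
    )
  })
}

#' Group one-sample test over regional statistics
#'
#' One-sample t-test against zero of a per-subject regional field (regional
#' beta, voxel percentage, Fisher z, CVR, ...), with Benjamini-Hochberg FDR
#' correction across regions.
#'
#' @param regional Long tibble with columns `subject`, `region`, and the
#'   tested field.
#' @param field Name of the tested column (default `"beta"`).
#' @param q FDR level (default 0.05).
#'
#' @return Tibble per region: `region`, `n`, `mean`, `t`, `p`, `p_adj`,
#'   `significant`, `degenerate`.
#' @export
group_regional_test <- function(regional, field = "beta", q = 0.05) {
  if (!field %in% names(regional)) abort(paste0("unknown field '", field, "'"))
  per_region <- regional |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n = sum(is.finite(.data[[field]])),
      mean = mean(.data[[field]], na.rm = TRUE),
      s = sd(.data[[field]], na.rm = TRUE),
      .groups = "drop"
    )
  if (any(per_region$n < 2)) {
    warn("some regions observed in fewer than 2 subjects; tests skipped there")
  }
  res <- per_region |>
    mutate(
      degenerate = .data$n < 2 | .data$s == 0,
      t = ifelse(.data$degenerate, NA_real_,
                 .data$mean / (.data$s / sqrt(.data$n))),
      p = ifelse(.data$degenerate, NA_real_,
                 2 * pt(-abs(.data$t), df = .data$n - 1))
    )
  ok <- which(!res$degenerate)
  res$p_adj <- NA_real_
  res$significant <- FALSE
  if (length(ok)) {
    fdr <- bh_fdr(res$p[ok], q = q)
    res$p_adj[ok] <- fdr$p_adj
    res$significant[ok] <- fdr$reject
  }
  select(res, "region", "n", "mean", "t", "p", "p_adj",
         "significant", "degenerate")
}

#' Seed-based connectivity map
#'
#' Linearly detrends and low-pass filters (default 0.03 Hz) every in-mask
#' voxel series, averages the filtered series over the seed region, and
#' correlates that seed series with every voxel. Correlations are converted
#' to Fisher z and averaged per region.
#'
#' @param vol A [volume_series()].
#' @param parc A [parcellation()].
#' @param seed_region Region label used as the seed.
#' @param fc_hz Low-pass cutoff (Hz, default 0.03).
#'
#' @return List: `z_map` (3D array of Fisher z), `regional` (tibble
#'   `region`, `name`, `fisher_z`), `seed_region`.
#' @export
seed_connectivity_map <- function(vol, parc, seed_region, fc_hz = 0.03) {
  stopifnot(inherits(vol, "volume_series"), inherits(parc, "parcellation"))
  dims <- dim(vol$data)
  n_t <- dims[4]
  y <- matrix(vol$data, prod(dims[1:3]), n_t)
  vox <- which(as.vector(vol$mask))
  fs <- 1 / vol$tr_s
  # remove per-voxel linear drift (projection), then zero-phase low-pass
  tt <- seq_len(n_t)
  x <- cbind(1, tt - mean(tt))
  proj <- x %*% solve(crossprod(x)) %*% t(x)
  yd <- y[vox, , drop = FALSE] - y[vox, , drop = FALSE] %*% t(proj)
  yf <- t(apply(yd, 1, butter_lowpass_zerophase, fc_hz = fc_hz, fs_hz = fs))
  seed_vox <- which(as.vector(parc$labels) == seed_region)
  seed_rows <- match(seed_vox, vox)
  seed_rows <- seed_rows[!is.na(seed_rows)]
  if (length(seed_rows) == 0) abort("seed region is empty")
  seed_series <- colMeans(yf[seed_rows, , drop = FALSE])
  if (sd(seed_series) == 0) abort("seed series is constant")
  r <- as.numeric(cor(t(yf), seed_series))
  z <- fisher_z(r)
  z_map <- array(NA_real_, dims[1:3])
  z_map[vox] <- z
  regional <- regional_aggregate(z_map, NULL, parc) |>
    select("region", "name", fisher_z = "beta")
  list(z_map = z_map, regional = regional, seed_region = seed_region)
}

#' Cerebrovascular reactivity map from a CO2 challenge
#'
#' Voxelwise regression of percent BOLD change on the end-tidal CO2 series
#' recorded during an exogenous CO2 block paradigm. The coefficient is the
#' CVR in percent BOLD per mmHg; regional means are reported alongside.
#'
#' @param vol A [volume_series()].
#' @param petco2 Tibble (time, value) of end-tidal CO2 (mmHg).
#' @param parc Optional [parcellation()] for regional means.
#' @param lag_s Regressor lag (s).
#'
#' @return List: `map` (`stat_map`; beta in percent/mmHg), `regional`
#'   (tibble with `cvr` per region, when `parc` given).
#' @export
cvr_map <- function(vol, petco2, parc = NULL, lag_s = 0) {
  map <- voxelwise_regression(vol, petco2, lag_s = lag_s)
  regional <- NULL
  if (!is.null(parc)) {
    regional <- regional_aggregate(map$beta, NULL, parc) |>
      select("region", "name", cvr = "beta")
  }
  list(map = map, regional = regional)
}

#' Scan a grid of regressor lags
#'
#' Optional helper for choosing the regressor-to-frame lag: for each
#' candidate lag the regressor is resampled to the (shifted) frame
#' mid-times and the mean squared correlation with the in-mask voxel
#' series is evaluated; the lag maximizing it is returned. The default
#' analysis applies no lag.
#'
#' @param vol A [volume_series()].
#' @param regressor Tibble (time, value).
#' @param lags_s Candidate lags in seconds (default 0-10 s in 1-s steps).
#' @return List: `best_lag_s` and the tibble `profile` (lag_s, mean_r2).
#' @export
scan_regressor_lag <- function(vol, regressor, lags_s = 0:10) {
  stopifnot(inherits(vol, "volume_series"))
  dims <- dim(vol$data)
  frame_times <- (seq_len(dims[4]) - 0.5) * vol$tr_s
  y <- matrix(vol$data, prod(dims[1:3]), dims[4])[as.vector(vol$mask), ,
                                                  drop = FALSE]
  mean_r2 <- vapply(lags_s, function(l) {
    reg <- approx(regressor$time, regressor$value,
                  xout = frame_times - l, rule = 1)$y
    ok <- is.finite(reg)
    if (sum(ok) < 30 || sd(reg[ok]) == 0) return(NA_real_)
    r <- as.numeric(cor(t(y[, ok, drop = FALSE]), reg[ok]))
    mean(r^2)
  }, numeric(1))
  list(
    best_lag_s = lags_s[which.max(mean_r2)],
    profile = tibble(lag_s = lags_s, mean_r2 = mean_r2)
  )
}

#' Jaccard index of two region sets
#'
#' Overlap measure used to compare the set of regions significantly coupled
#' to a gas metric with the seed-connectivity region set.
#'
#' @param a,b Vectors of region labels.
#' @return `|a intersect b| / |a union b|` (1 when both are empty).
#' @export
jaccard_index <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}
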