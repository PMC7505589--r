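#' Configuration of the TCD session pipeline
#'
#' Collects all parameters of the transcranial-Doppler pipeline with the
#' study defaults: 10-minute records, 5-s breaths, 13 simulated subjects,
#' 1-s analysis grid, 0.03 Hz low-pass, 100 red-noise surrogates. Unknown
#' keys passed through [read_run_config()] are rejected here.
#'
#' @param seed Master integer seed for every stochastic component.
#' @param simulate Generate synthetic subjects (`TRUE`) or read the trace
#'   files below (`FALSE`, single subject).
#' @param n_subjects Number of simulated subjects.
#' @param duration_s,breath_period_s,sample_rate_hz Gas-record geometry.
#' @param tcd_sample_rate_hz,heart_rate_hz Velocity-record geometry.
#' @param dt_s Uniform analysis grid spacing (s).
#' @param lowpass_hz Low-pass cutoff applied to the hemodynamic series in
#'   the filtered correlation pass.
#' @param n_surrogates,alpha Red-noise significance settings.
#' @param max_lag_s Gas-delay search window.
#' @param baseline_s Opening baseline window for the percent-change series.
#' @param spec_args Named list of [coupling_spec()] overrides.
#' @param gas_file,resp_file,velocity_file Input traces for
#'   `simulate = FALSE`.
#' @param out_dir Optional output directory; the resolved config, tables and
#'   a run log are written there.
#' @return A validated list of class `tcd_config`.
#' @export
tcd_config <- function(seed = 1L,
                       simulate = TRUE,
                       n_subjects = 13L,
                       duration_s = 600,
                       breath_period_s = 5,
                       sample_rate_hz = 20,
                       tcd_sample_rate_hz = 100,
                       heart_rate_hz = 1.1,
                       dt_s = 1,
                       lowpass_hz = 0.03,
                       n_surrogates = 100L,
                       alpha = 0.05,
                       max_lag_s = 15,
                       baseline_s = 30,
                       spec_args = list(),
                       gas_file = NULL,
                       resp_file = NULL,
                       velocity_file = NULL,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "tcd_config")
}

#' Configuration of the MRI session pipeline
#'
#' Study defaults: 20 simulated subjects, 16^3 grid parcellated into 8
#' slabs of which regions 1-3 form the "DMN-like" coupled set (region 1 is
#' the precuneus-like seed), TR 1.45 s, voxel p < 0.005 with Monte Carlo
#' cluster correction at alpha 0.05, 10 subjects with a CO2 challenge, and
#' a per-subject CO2-modulation gain drawn from N(0, co2_gain_sd) to
#' emulate inter-individual variability of the CO2 coupling.
#'
#' @inheritParams tcd_config
#' @param tr_s Repetition time (s).
#' @param grid_shape,n_regions Synthetic volume geometry.
#' @param coupled_regions Region labels truly coupled to bER.
#' @param beta_ber True percent-BOLD change per unit bER in coupled regions.
#' @param voxel_p,alpha,cluster_iters,smoothness_fwhm_mm Cluster-correction
#'   settings.
#' @param seed_region Seed parcel for the connectivity map.
#' @param co2_gain_sd SD of the per-subject CO2-modulation gain.
#' @param include_cvr Run the CO2-challenge CVR arm.
#' @param n_co2_subjects Subjects in the CVR arm.
#' @param cvr_truth True CVR (percent/mmHg) in gray-matter-like regions.
#' @param include_rvt Compute the RVT-BOLD coherence profile.
#' @param drift_sd SD of per-voxel drift slopes in the simulation.
#' @param bold_file,parc_file,petco2_file Inputs for `simulate = FALSE`.
#' @return A validated list of class `mri_config`.
#' @export
mri_config <- function(seed = 1L,
                       simulate = TRUE,
                       n_subjects = 20L,
                       duration_s = 600,
                       breath_period_s = 5,
                       sample_rate_hz = 20,
                       tr_s = 1.45,
                       grid_shape = c(16L, 16L, 16L),
                       n_regions = 8L,
                       coupled_regions = 1:3,
                       beta_ber = 10,
                       dt_s = 1,
                       voxel_p = 0.005,
                       alpha = 0.05,
                       cluster_iters = 200L,
                       smoothness_fwhm_mm = 7,
                       seed_region = 1L,
                       lowpass_hz = 0.03,
                       n_surrogates = 100L,
                       max_lag_s = 15,
                       co2_gain_sd = 0.5,
                       include_cvr = TRUE,
                       n_co2_subjects = 10L,
                       cvr_truth = 0.2,
                       include_rvt = TRUE,
                       drift_sd = 0.002,
                       spec_args = list(),
                       gas_file = NULL,
                       resp_file = NULL,
                       bold_file = NULL,
                       parc_file = NULL,
                       petco2_file = NULL,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "mri_config")
}

subject_spec <- function(config, s) {
  args <- config$spec_args
  args$seed <- (substream_seed(config$seed, "subject") + 131 * s) %% 2147483647
  do.call(coupling_spec, args)
}

# Run one stage, recording failures by name instead of aborting the run.
run_stage <- function(errors_env, stage, expr) {
  tryCatch(expr, error = function(e) {
    errors_env$errors[[stage]] <- conditionMessage(e)
    NULL
  })
}

process_gas_record <- function(gas, resp, config) {
  corrected <- correct_gas_delay(gas, resp, max_lag_s = config$max_lag_s)
  phases <- detect_breath_phases(corrected)
  table <- compute_rge_metrics(corrected, phases)
  list(
    table = table,
    lag_s = attr(corrected, "lag_s"),
    rvt = compute_rvt(resp),
    series = purrr::map(
      rlang::set_names(c("ber", "d_po2", "d_pco2", "pet_co2", "pet_o2")),
      ~ breath_series_to_uniform(table, .x, dt_s = config$dt_s)
    )
  )
}

join_on_time <- function(a, b) {
  m <- dplyr::inner_join(a, b, by = "time", suffix = c("_x", "_y"))
  m[stats::complete.cases(m), ]
}

#' Run the TCD session pipeline
#'
#' End-to-end orchestration of the transcranial-Doppler analysis: gas-line
#' delay correction, breath-table extraction, beat-resolved percent-change
#' velocity series, Pearson/Fisher correlations of every gas metric with
#' the velocity series (with and without the 0.03 Hz low-pass on the
#' hemodynamic series), paired comparisons of Fisher z scores against the
#' bER reference, and wavelet coherence with red-noise significance and
#' group-averaged quadrant TAC profiles for bER, the PO2 excursion and the
#' PCO2 excursion.
#'
#' @param config A [tcd_config()].
#' @return A list of class `tcd_report`; see the vignette for the layout.
#' @export
run_tcd_pipeline <- function(config = tcd_config()) {
  stopifnot(inherits(config, "tcd_config"))
  ee <- new.env()
  ee$errors <- list()
  metrics <- c("ber", "d_po2", "d_pco2", "pet_co2", "pet_o2")
  wtc_metrics <- c("ber", "d_po2", "d_pco2")
  n_sub <- if (config$simulate) config$n_subjects else 1L

  correlations <- list()
  tac <- rlang::set_names(vector("list", length(wtc_metrics)), wtc_metrics)
  for (m in wtc_metrics) tac[[m]] <- list()
  subject_detail <- NULL

  for (s in seq_len(n_sub)) {
    spec <- subject_spec(config, s)
    if (config$simulate) {
      sim <- sim_gas_exchange(spec, duration_s = config$duration_s,
                              breath_period_s = config$breath_period_s,
                              sample_rate_hz = config$sample_rate_hz)
      gas <- sim$gas
      resp <- sim$resp
      vel <- sim_cbfv(spec, sim$modulator, duration_s = config$duration_s,
                      sample_rate_hz = config$tcd_sample_rate_hz,
                      heart_rate_hz = config$heart_rate_hz)$trace
    } else {
      gas <- run_stage(ee, "read_gas", read_trace(config$gas_file))
      resp <- run_stage(ee, "read_resp", read_trace(config$resp_file))
      vel <- run_stage(ee, "read_velocity", {
        if (is.null(config$velocity_file) ||
            !file.exists(config$velocity_file)) {
          abort("velocity file missing")
        }
        read_trace(config$velocity_file)
      })
      if (is.null(gas) || is.null(resp)) break
    }

    gp <- run_stage(ee, "gas_metrics", process_gas_record(gas, resp, config))
    if (is.null(gp)) next
    if (s == 1) subject_detail <- gp

    if (is.null(vel)) next
    cb <- run_stage(ee, "cbfv", {
      beats <- detect_beats(despike_velocity(vel))
      beat_mean_delta_cbfv(vel, beats, baseline_s = config$baseline_s)
    })
    if (is.null(cb)) next
    cbfv_u <- breath_series_to_uniform(cb, "delta_cbfv", dt_s = config$dt_s,
                                       time_col = "beat_onset")
    cbfv_f <- lowpass_cutoff(cbfv_u, fc_hz = config$lowpass_hz)

    for (m in metrics) {
      for (filt in c(FALSE, TRUE)) {
        pair <- join_on_time(gp$series[[m]], if (filt) cbfv_f else cbfv_u)
        cr <- correlate_series(pair$value_x, pair$value_y)
        correlations[[length(correlations) + 1]] <- tibble(
          subject = s, metric = m, filtered = filt,
          r = cr$r, z = cr$z, n = cr$n, p = cr$p
        )
      }
    }
    for (m in wtc_metrics) {
      pair <- join_on_time(gp$series[[m]], cbfv_u)
      res <- wavelet_coherence(
        tibble(time = pair$time, value = pair$value_x),
        tibble(time = pair$time, value = pair$value_y)
      )
      res <- rednoise_significance(res, n_surrogates = config$n_surrogates,
                                   alpha = config$alpha,
                                   seed = spec$seed + match(m, wtc_metrics))
      tac[[m]][[length(tac[[m]]) + 1]] <- time_averaged_coherence(res)
      if (s == 1 && m == "ber") subject_detail$wtc_ber <- res
    }
  }

  correlations <- bind_rows(correlations)
  paired <- NULL
  group_tac <- NULL
  if (nrow(correlations) > 0 && n_sub >= 2) {
    paired <- purrr::map_dfr(
      setdiff(metrics, "ber"),
      function(m) {
        purrr::map_dfr(c(FALSE, TRUE), function(filt) {
          zr <- correlations$z[correlations$metric == "ber" &
                                 correlations$filtered == filt]
          zo <- correlations$z[correlations$metric == m &
                                 correlations$filtered == filt]
          cbind(tibble(metric = m, filtered = filt),
                paired_z_comparison(zr, zo))
        })
      }
    )
    group_tac <- purrr::map(tac, function(profiles) {
      if (length(profiles) >= 2) group_mean_tac(profiles) else NULL
    })
  }

  report <- structure(
    list(
      config = config,
      n_subjects = n_sub,
      correlations = correlations,
      paired = paired,
      group_tac = group_tac,
      subject_detail = subject_detail,
      errors = ee$errors
    ),
    class = "tcd_report"
  )
  if (!is.null(config$out_dir)) write_tcd_outputs(report, config$out_dir)
  report
}

write_run_log <- function(dir, seed) {
  writeLines(c(
    paste0("bercouple ", as.character(utils::packageVersion("bercouple"))),
    paste0("R ", R.version.string),
    paste0("seed ", seed),
    paste0("date ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), file.path(dir, "run_log.txt"))
}

write_tcd_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  write_run_log(dir, report$config$seed)
  if (!is.null(report$subject_detail)) {
    write_trace(report$subject_detail$table,
                file.path(dir, "breath_table.tsv"))
  }
  if (nrow(report$correlations) > 0) {
    write_trace(report$correlations, file.path(dir, "correlations.tsv"))
  }
  if (!is.null(report$paired)) {
    write_trace(report$paired, file.path(dir, "paired_z.tsv"))
  }
  if (!is.null(report$group_tac)) {
    purrr::iwalk(report$group_tac, function(tbl, m) {
      if (!is.null(tbl)) {
        write_trace(tbl, file.path(dir, paste0("group_tac_", m, ".tsv")))
      }
    })
  }
  invisible(dir)
}

#' @export
print.tcd_report <- function(x, ...) {
  cat("<tcd_report> ", x$n_subjects, " subject(s)\n", sep = "")
  if (nrow(x$correlations) > 0) {
    summ <- x$correlations |>
      group_by(.data$metric, .data$filtered) |>
      summarise(mean_z = mean(.data$z), .groups = "drop") |>
      arrange(.data$filtered, dplyr::desc(.data$mean_z))
    cat("  group mean Fisher z (unfiltered then 0.03 Hz low-pass):\n")
    print(as.data.frame(summ), row.names = FALSE)
  }
  if (length(x$errors)) {
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the MRI session pipeline
#'
#' Orchestrates the imaging analysis: per-subject breath tables and gas
#' regressors, voxelwise regression of percent BOLD change on bER and the
#' gas excursions, Monte Carlo cluster-extent correction, regional beta and
#' voxel-percentage statistics, group one-sample tests with FDR correction,
#' seed-based connectivity from the precuneus-like seed parcel, optional
#' CO2-challenge CVR mapping, and an optional RVT-BOLD coherence profile.
#'
#' @param config An [mri_config()].
#' @return A list of class `mri_report`.
#' @export
run_mri_pipeline <- function(config = mri_config()) {
  stopifnot(inherits(config, "mri_config"))
  ee <- new.env()
  ee$errors <- list()
  metrics <- c("ber", "d_po2", "d_pco2")

  if (!config$simulate) {
    return(run_mri_single(config, ee))
  }

  dims <- config$grid_shape
  mask <- array(TRUE, dims)
  cluster <- run_stage(ee, "cluster_threshold", mc_cluster_threshold(
    mask, voxel_dims_mm = c(3.4, 3.4, 6),
    smoothness_fwhm_mm = config$smoothness_fwhm_mm,
    voxel_p = config$voxel_p, alpha = config$alpha,
    n_iter = config$cluster_iters, seed = config$seed
  ))
  k_vox <- if (is.null(cluster)) 1L else cluster$k_voxels

  region_beta <- rlang::set_names(rep(0, config$n_regions),
                                  as.character(seq_len(config$n_regions)))
  region_beta[as.character(config$coupled_regions)] <- config$beta_ber

  regional <- list()
  rvt_profiles <- list()
  parc <- NULL
  subject_detail <- NULL
  for (s in seq_len(config$n_subjects)) {
    spec <- subject_spec(config, s)
    withr::with_seed(spec$seed + 17L, {
      g_s <- rnorm(1, 0, config$co2_gain_sd)
    })
    sim <- sim_gas_exchange(spec, duration_s = config$duration_s,
                            breath_period_s = config$breath_period_s,
                            sample_rate_hz = config$sample_rate_hz,
                            co2_mod_gain = g_s)
    gp <- run_stage(ee, "gas_metrics", process_gas_record(sim$gas, sim$resp,
                                                          config))
    if (is.null(gp)) next
    bold <- sim_bold_volume(spec, sim$drive, grid_shape = dims,
                            n_regions = config$n_regions,
                            region_beta_map = region_beta,
                            tr_s = config$tr_s, drift_sd = config$drift_sd)
    parc <- bold$parc

    row <- NULL
    for (m in metrics) {
      map <- voxelwise_regression(bold$vol, gp$series[[m]])
      sig <- cluster_correct(map, voxel_p = config$voxel_p, k_voxels = k_vox)
      agg <- regional_aggregate(map$beta, sig, parc)
      cols <- tibble(
        region = agg$region,
        beta = agg$beta,
        voxel_beta_pct = agg$voxel_beta_pct
      )
      names(cols)[2:3] <- paste0(c("beta_", "voxelpct_"), m)
      row <- if (is.null(row)) cols else left_join(row, cols, by = "region")
    }
    conn <- run_stage(ee, "connectivity", seed_connectivity_map(
      bold$vol, parc, config$seed_region, fc_hz = config$lowpass_hz
    ))
    if (!is.null(conn)) {
      row <- left_join(row, select(conn$regional, "region", "fisher_z"),
                       by = "region")
    }
    row$subject <- s
    regional[[s]] <- row
    if (s == 1) {
      subject_detail <- list(breath_table = gp$table, lag_s = gp$lag_s,
                             truth = bold$truth)
    }

    if (config$include_rvt && s <= min(10L, config$n_subjects) &&
        nrow(gp$rvt) > 2) {
      prof <- run_stage(ee, "rvt_coherence", {
        dmn <- colMeans(matrix(bold$vol$data, prod(dims),
                               dim(bold$vol$data)[4])[
          which(as.vector(parc$labels) %in% config$coupled_regions), ,
          drop = FALSE])
        frame_times <- (seq_along(dmn) - 0.5) * config$tr_s
        rvt_u <- breath_series_to_uniform(gp$rvt, "rvt",
                                          dt_s = config$dt_s,
                                          time_col = "time")
        bold_u <- tibble(
          time = rvt_u$time,
          value = approx(frame_times, dmn, xout = rvt_u$time, rule = 1)$y
        )
        pair <- join_on_time(rvt_u, bold_u)
        res <- wavelet_coherence(
          tibble(time = pair$time, value = pair$value_x),
          tibble(time = pair$time, value = pair$value_y)
        )
        res <- rednoise_significance(res,
                                     n_surrogates = config$n_surrogates,
                                     seed = spec$seed + 23L)
        time_averaged_coherence(res)
      })
      if (!is.null(prof)) rvt_profiles[[length(rvt_profiles) + 1]] <- prof
    }
  }
  regional <- bind_rows(regional)

  group <- purrr::map(
    rlang::set_names(c(paste0("beta_", metrics), "fisher_z")),
    function(f) {
      if (f %in% names(regional)) {
        group_regional_test(regional, field = f, q = 0.05)
      } else {
        NULL
      }
    }
  )
  voxel_pct_group <- regional |>
    tidyr::pivot_longer(dplyr::starts_with("voxelpct_"),
                        names_to = "metric", names_prefix = "voxelpct_",
                        values_to = "pct") |>
    group_by(.data$metric, .data$region) |>
    summarise(mean_pct = mean(.data$pct), .groups = "drop")

  cvr_regional <- NULL
  cvr_group <- NULL
  if (config$include_cvr) {
    cvr_truth_map <- rlang::set_names(
      rep(c(config$cvr_truth, 0),
          c(config$n_regions - 2, 2)),
      as.character(seq_len(config$n_regions))
    )
    cvr_rows <- list()
    for (s in seq_len(min(config$n_co2_subjects, config$n_subjects))) {
      spec <- subject_spec(config, 1000L + s)
      par <- sim_co2_paradigm(seed = spec$seed, baseline_petco2 = 40)
      petco2 <- tibble(time = par$target$time, value = par$target$approach)
      bold <- sim_bold_volume(spec, petco2, grid_shape = dims,
                              n_regions = config$n_regions,
                              region_beta_map = cvr_truth_map,
                              tr_s = config$tr_s,
                              drift_sd = config$drift_sd)
      cm <- cvr_map(bold$vol, petco2, parc = bold$parc)
      cvr_rows[[s]] <- mutate(cm$regional, subject = s)
    }
    cvr_regional <- bind_rows(cvr_rows)
    cvr_group <- group_regional_test(cvr_regional, field = "cvr", q = 0.05)
  }

  report <- structure(
    list(
      config = config,
      regional = regional,
      group = group,
      voxel_pct_group = voxel_pct_group,
      cluster_k = k_vox,
      cvr_regional = cvr_regional,
      cvr_group = cvr_group,
      rvt_group_tac = if (length(rvt_profiles) >= 2) {
        group_mean_tac(rvt_profiles)
      } else {
        NULL
      },
      parc = parc,
      subject_detail = subject_detail,
      errors = ee$errors
    ),
    class = "mri_report"
  )
  if (!is.null(config$out_dir)) write_mri_outputs(report, config$out_dir)
  report
}

# Single-subject file-input MRI run: regression and connectivity only.
run_mri_single <- function(config, ee) {
  vol <- read_volume(config$bold_file)
  parc <- read_parcellation(config$parc_file)
  gas <- read_trace(config$gas_file)
  resp <- read_trace(config$resp_file)
  gp <- process_gas_record(gas, resp, config)
  maps <- purrr::map(
    rlang::set_names(c("ber", "d_po2", "d_pco2")),
    ~ voxelwise_regression(vol, gp$series[[.x]])
  )
  conn <- seed_connectivity_map(vol, parc, config$seed_region,
                                fc_hz = config$lowpass_hz)
  cvr <- NULL
  if (!is.null(config$petco2_file)) {
    cvr <- cvr_map(vol, read_trace(config$petco2_file), parc = parc)
  }
  structure(
    list(config = config, maps = maps, connectivity = conn, cvr = cvr,
         breath_table = gp$table, errors = ee$errors),
    class = "mri_report"
  )
}

write_mri_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  write_run_log(dir, report$config$seed)
  if (!is.null(report$regional)) {
    write_trace(report$regional, file.path(dir, "regional_stats.tsv"))
  }
  purrr::iwalk(report$group, function(tbl, f) {
    if (!is.null(tbl)) {
      write_trace(tbl, file.path(dir, paste0("group_", f, ".tsv")))
    }
  })
  if (!is.null(report$cvr_group)) {
    write_trace(report$cvr_group, file.path(dir, "group_cvr.tsv"))
  }
  invisible(dir)
}

#' @export
print.mri_report <- function(x, ...) {
  cat("<mri_report>\n")
  if (!is.null(x$cluster_k)) {
    cat("  cluster-extent threshold:", x$cluster_k, "voxels\n")
  }
  if (!is.null(x$group)) {
    for (f in names(x$group)) {
      g <- x$group[[f]]
      if (!is.null(g)) {
        cat("  ", f, ": ", sum(g$significant), "/", nrow(g),
            " regions FDR-significant\n", sep = "")
      }
    }
  }
  invisible(x)
}
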