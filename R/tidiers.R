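#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a wavelet coherence result
#'
#' One row per time-scale cell with the coherence, phase, COI status and
#' (when computed) red-noise significance.
#'
#' @param x A `coherence_result`.
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.coherence_result <- function(x, ...) {
  j_n <- length(x$periods)
  n <- length(x$time)
  out <- tibble(
    time = rep(x$time, each = j_n),
    period_s = rep(x$periods, n),
    freq_hz = rep(1 / x$periods, n),
    coherence = as.vector(x$coherence),
    phase = as.vector(x$phase),
    in_coi = as.vector(outer(x$periods, x$coi, `<=`))
  )
  out$significant <- if (is.null(x$sig_mask)) NA else as.vector(x$sig_mask)
  out
}

#' @rdname tidy.coherence_result
#' @export
glance.coherence_result <- function(x, ...) {
  incoi <- outer(x$periods, x$coi, `<=`)
  tibble(
    n_time = length(x$time),
    n_scales = length(x$periods),
    dt_s = x$dt,
    min_period_s = min(x$periods),
    max_period_s = max(x$periods),
    n_surrogates = x$n_surrogates,
    frac_incoi_significant = if (is.null(x$sig_mask)) NA_real_ else {
      mean(x$sig_mask[incoi])
    }
  )
}

#' Tidiers for correlation results and reports
#'
#' `corr_result` objects are already tidy one-row tibbles; `tidy()` returns
#' them unchanged and `glance()` is an alias. For a `tcd_report`, `tidy()`
#' returns the long per-subject correlation table and `glance()` one row of
#' group-level summaries.
#'
#' @param x Object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.corr_result <- function(x, ...) as_tibble(x)

#' @rdname tidy.corr_result
#' @export
glance.corr_result <- function(x, ...) as_tibble(x)

#' @rdname tidy.corr_result
#' @export
tidy.tcd_report <- function(x, ...) x$correlations

#' @rdname tidy.corr_result
#' @export
glance.tcd_report <- function(x, ...) {
  summ <- x$correlations |>
    filter(!.data$filtered) |>
    group_by(.data$metric) |>
    summarise(mean_z = mean(.data$z), .groups = "drop")
  tibble(
    n_subjects = x$n_subjects,
    mean_z_ber = summ$mean_z[summ$metric == "ber"],
    mean_z_d_po2 = summ$mean_z[summ$metric == "d_po2"],
    mean_z_d_pco2 = summ$mean_z[summ$metric == "d_pco2"],
    n_errors = length(x$errors)
  )
}

#' @rdname tidy.corr_result
#' @export
tidy.mri_report <- function(x, ...) x$regional

#' @rdname tidy.corr_result
#' @export
glance.mri_report <- function(x, ...) {
  count_sig <- function(g) if (is.null(g)) NA_integer_ else sum(g$significant)
  tibble(
    n_subjects = x$config$n_subjects,
    cluster_k = x$cluster_k %||% NA_integer_,
    n_sig_beta_ber = count_sig(x$group$beta_ber),
    n_sig_beta_d_pco2 = count_sig(x$group$beta_d_pco2),
    n_sig_connectivity = count_sig(x$group$fisher_z),
    n_errors = length(x$errors)
  )
}
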