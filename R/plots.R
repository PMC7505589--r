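#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_ribbon
#'   scale_y_continuous scale_fill_viridis_c labs theme_minimal geom_tile
#'   facet_wrap geom_point
NULL

#' Plot a wavelet coherence result
#'
#' Squared coherence as a time-period raster (log period axis), with the
#' cone of influence drawn as a line; cells below the COI line are
#' edge-affected. When significance has been computed, significant cells
#' are outlined by an overlaid translucent layer.
#'
#' @param object A `coherence_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coherence_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$time, y = .data$period_s)) +
    geom_raster(aes(fill = .data$coherence)) +
    geom_line(
      data = tibble(time = object$time, coi = object$coi),
      aes(x = .data$time, y = .data$coi),
      inherit.aes = FALSE, linetype = 2, colour = "white"
    ) +
    scale_y_continuous(trans = "log2") +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "time (s)", y = "Fourier period (s)",
         fill = expression(R^2)) +
    theme_minimal()
  if (!is.null(object$sig_mask)) {
    p <- p + geom_point(
      data = df[df$significant & df$in_coi, ],
      size = 0.1, alpha = 0.25, colour = "white"
    )
  }
  p
}

#' Plot a quadrant-resolved TAC profile
#'
#' Time-averaged coherence against frequency, one line per phase-lag
#' quadrant (in-phase 0 +/- pi/2, anti-phase pi +/- pi/2).
#'
#' @param object A `tac_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tac_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("freq_hz", "tac_inphase", "tac_antiphase")],
    -"freq_hz", names_to = "quadrant", names_prefix = "tac_",
    values_to = "tac"
  )
  ggplot(df, aes(x = .data$freq_hz, y = .data$tac,
                 colour = .data$quadrant)) +
    geom_line() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "frequency (Hz)", y = "time-averaged coherence") +
    theme_minimal()
}

#' Plot a group TAC profile with its SEM ribbon
#'
#' @param group_tac Output of [group_mean_tac()].
#' @return A ggplot.
#' @export
plot_group_tac <- function(group_tac) {
  df <- bind_rows(
    tibble(freq_hz = group_tac$freq_hz, quadrant = "inphase",
           mean = group_tac$mean_inphase, sem = group_tac$sem_inphase),
    tibble(freq_hz = group_tac$freq_hz, quadrant = "antiphase",
           mean = group_tac$mean_antiphase, sem = group_tac$sem_antiphase)
  )
  ggplot(df, aes(x = .data$freq_hz, y = .data$mean,
                 colour = .data$quadrant, fill = .data$quadrant)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem),
                alpha = 0.25, colour = NA) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "time-averaged coherence") +
    theme_minimal()
}

#' Plot an axial slice of a stat map
#'
#' @param object A `stat_map`.
#' @param slice Axial (third-axis) slice index; defaults to the middle.
#' @param what Which array to show: `"beta"`, `"t"` or `"p"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stat_map <- function(object, slice = NULL, what = "beta", ...) {
  arr <- object[[what]]
  if (is.null(slice)) slice <- ceiling(dim(arr)[3] / 2)
  sl <- arr[, , slice]
  df <- tibble(
    x = rep(seq_len(nrow(sl)), ncol(sl)),
    y = rep(seq_len(ncol(sl)), each = nrow(sl)),
    value = as.vector(sl)
  )
  ggplot(df, aes(.data$x, .data$y, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(fill = what, title = paste0("slice z = ", slice)) +
    theme_minimal()
}

#' Plot per-breath gas-exchange metrics over time
#'
#' @param table A breath table from [compute_rge_metrics()].
#' @param fields Metrics to show.
#' @return A ggplot with one facet per metric.
#' @export
plot_breath_table <- function(table,
                              fields = c("ber", "d_po2", "d_pco2",
                                         "pet_o2", "pet_co2")) {
  df <- tidyr::pivot_longer(
    table[table$valid, c("t_end_exp", fields)],
    -"t_end_exp", names_to = "metric", values_to = "value"
  )
  ggplot(df, aes(.data$t_end_exp, .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "time of end expiration (s)", y = NULL) +
    theme_minimal()
}
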