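#' Plot shell profiles of a prepared analysis
#'
#' Signal power, noise power and `D_obs` as functions of resolution.
#'
#' @param object a `cryodock_prepared`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cryodock_prepared
#' @export
autoplot.cryodock_prepared <- function(object, ...) {
  sh <- object$shells
  df <- tidyr::pivot_longer(
    dplyr::transmute(sh, s = (.data$s_min + .data$s_max) / 2,
                     `Sigma_S` = .data$sigma_s, `Sigma_E` = .data$sigma_e,
                     D_obs = .data$d_obs),
    -"s", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "inverse resolution s (1/A)", y = NULL,
                  title = "Half-map signal/noise analysis") +
    ggplot2::theme_minimal()
}

#' Directional signal and noise profiles
#'
#' Signal and noise power along cones around the x, y and z axes of the
#' reconstruction, on a log scale: noise profiles should nearly coincide
#' when the noise is close to isotropic, while the signal profiles separate
#' according to the anisotropy of the map.
#'
#' @param prepared a `cryodock_prepared`.
#' @return A ggplot object.
#' @export
plot_axis_profiles <- function(prepared) {
  df <- tidyr::pivot_longer(prepared$axes, c("sigma_s", "sigma_e"),
                            names_to = "quantity", values_to = "power")
  df$quantity <- ifelse(df$quantity == "sigma_s", "signal", "noise")
  ggplot2::ggplot(df, ggplot2::aes(.data$s_mid, .data$power,
                                   colour = .data$axis,
                                   linetype = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "inverse resolution s (1/A)", y = "power",
                  colour = "axis", linetype = NULL,
                  title = "Directional signal and noise power") +
    ggplot2::theme_minimal()
}

#' Plot per-shell LLG contributions
#'
#' @param object a `cryodock_llg` from [total_llg()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cryodock_llg
#' @export
autoplot.cryodock_llg <- function(object, ...) {
  sh <- object$shells
  ggplot2::ggplot(sh, ggplot2::aes((.data$s_min + .data$s_max) / 2,
                                   .data$llg)) +
    ggplot2::geom_col(width = 0.01) +
    ggplot2::labs(x = "inverse resolution s (1/A)",
                  y = "LLG contribution",
                  title = sprintf("Total LLG = %.1f", object$total)) +
    ggplot2::theme_minimal()
}

#' Plot shell information and expected LLG
#'
#' @param object a `cryodock_info` from [info_report()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cryodock_info
#' @export
autoplot.cryodock_info <- function(object, ...) {
  sh <- object$shells
  df <- tidyr::pivot_longer(
    dplyr::transmute(sh, s = (.data$s_min + .data$s_max) / 2,
                     eLLG_rot = .data$ellg_rot, eLLG_tra = .data$ellg_tra,
                     bits = .data$bits),
    -"s", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "inverse resolution s (1/A)", y = NULL,
                  title = "Expected LLG and information per shell") +
    ggplot2::theme_minimal()
}
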