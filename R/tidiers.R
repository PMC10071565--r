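#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a refined signal model
#'
#' One row per resolution bin: bin bounds, the refined multiplier and its
#' restraint weight.
#'
#' @param x a `cryodock_signal_model`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy cryodock_signal_model
#' @export
tidy.cryodock_signal_model <- function(x, ...) {
  dplyr::mutate(x$bins, mult = exp(.data$log_mult))
}

#' One-row summary of a refined signal model
#'
#' @param x a `cryodock_signal_model`.
#' @param ... unused.
#' @return A one-row tibble with the overall scale, the tensor diagonal
#'   and anisotropy, the log-likelihood and convergence code.
#' @method glance cryodock_signal_model
#' @export
glance.cryodock_signal_model <- function(x, ...) {
  ev <- eigen(x$beta, symmetric = TRUE, only.values = TRUE)$values
  tibble::tibble(
    a0 = x$a0,
    beta_xx = x$beta[1, 1], beta_yy = x$beta[2, 2], beta_zz = x$beta[3, 3],
    beta_aniso = max(ev) - min(ev),
    logLik = x$value, convergence = x$convergence, n_bins = nrow(x$bins)
  )
}

#' Tidy an LLG report
#'
#' @param x a `cryodock_llg`.
#' @param ... unused.
#' @return The per-shell LLG tibble.
#' @method tidy cryodock_llg
#' @export
tidy.cryodock_llg <- function(x, ...) x$shells

#' One-row summary of an LLG report
#'
#' @param x a `cryodock_llg`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance cryodock_llg
#' @export
glance.cryodock_llg <- function(x, ...) {
  tibble::tibble(
    llg = x$total, correlation = x$correlation, scale = x$scale,
    offset = x$offset, factor = x$factor, n_terms = x$n_terms,
    delta = x$delta
  )
}

#' Tidy an information report
#'
#' @param x a `cryodock_info`.
#' @param ... unused.
#' @return The per-shell tibble.
#' @method tidy cryodock_info
#' @export
tidy.cryodock_info <- function(x, ...) x$shells

#' One-row summary of an information report
#'
#' @param x a `cryodock_info`.
#' @param ... unused.
#' @return A one-row tibble with totals.
#' @method glance cryodock_info
#' @export
glance.cryodock_info <- function(x, ...) {
  tibble::tibble(
    ellg_rot = x$totals$ellg_rot, ellg_tra = x$totals$ellg_tra,
    bits = x$totals$bits, factor = x$factor,
    f_completeness = x$f_completeness, delta = x$delta
  )
}

#' Tidy a docking result
#'
#' @param x a `cryodock_dock`.
#' @param ... unused.
#' @return A one-row tibble with the refined pose parameters and score.
#' @method tidy cryodock_dock
#' @export
tidy.cryodock_dock <- function(x, ...) {
  tibble::tibble(
    angle_x = x$pose$angles[1], angle_y = x$pose$angles[2],
    angle_z = x$pose$angles[3],
    shift_x = x$pose$shift[1], shift_y = x$pose$shift[2],
    shift_z = x$pose$shift[3],
    cell_scale = x$pose$scale, delta = x$delta, llg = x$llg,
    solved = x$solved
  )
}

#' Tidy a prepared analysis
#'
#' @param x a `cryodock_prepared`.
#' @param ... unused.
#' @return The per-shell summary tibble.
#' @method tidy cryodock_prepared
#' @export
tidy.cryodock_prepared <- function(x, ...) x$shells

#' One-row summary of a prepared analysis
#'
#' @param x a `cryodock_prepared`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance cryodock_prepared
#' @export
glance.cryodock_prepared <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$terms), d_min = 1 / max(x$terms$s),
    mean_d_obs = mean(x$terms$d_obs),
    oversampling = x$oversampling$factor,
    n_warnings = length(x$warnings)
  )
}
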