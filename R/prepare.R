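#' Signal/noise analysis of a half-map pair
#'
#' End-to-end error analysis of two unfiltered, unmasked half-maps,
#' optionally restricted to a soft-edged spherical subvolume: Fourier
#' transforms, local maximum-likelihood noise and signal estimates, the
#' refined anisotropic signal model, the hybrid signal estimate, per-term
#' `D_obs`, normalised averaged coefficients and docking map coefficients.
#' This is the map-preparation step run before any docking search.
#'
#' @param half1,half2 [map_grid()] objects (or paths to MRC maps).
#' @param resolution high-resolution limit (A); `NULL` keeps everything to
#'   the Nyquist sphere.
#' @param sphere_centre,sphere_radius optional subvolume sphere (A).
#' @param bins resolution bins for the signal-model refinement.
#' @param target_count approximate local-neighbourhood size.
#' @param best reference spectral power curve.
#' @param ordered_volume volume (A^3) of the ordered region used for the
#'   oversampling correction; defaults to the subvolume sphere if given,
#'   otherwise the whole box (factor 1, i.e. no correction).
#' @param sigma_a_params list with `f` and `delta` used only for the
#'   likelihood-weighted docking coefficient set.
#' @return Object of class `cryodock_prepared`: `terms` (tibble with
#'   `h, k, l, s, f1, f2, f_mean, sigma_s_loc, sigma_s_model, sigma_s,
#'   sigma_e, cc, d_obs, e_mean` and grid attributes), `signal_model`,
#'   `oversampling` (list), `shells` (per-shell summary tibble), `axes`
#'   (axis-cone profile tibble), and `warnings`.
#' @export
prepare_halfmaps <- function(half1, half2, resolution = NULL,
                             sphere_centre = NULL, sphere_radius = NULL,
                             bins = 40, target_count = 100,
                             best = best_curve(), ordered_volume = NULL,
                             sigma_a_params = list(f = 1, delta = 1)) {
  if (is.character(half1)) half1 <- read_map(half1)
  if (is.character(half2)) half2 <- read_map(half2)
  if (!identical(dim(half1$values), dim(half2$values)))
    stop("half-maps have different grids")
  warnings <- character(0)
  if (identical(half1$values, half2$values)) {
    warnings <- c(warnings, paste(
      "half-maps are identical: noise power cannot be estimated",
      "(were the half-maps averaged or duplicated?)"))
    warning(warnings[length(warnings)])
  }
  if (!is.null(sphere_radius)) {
    if (is.null(sphere_centre))
      sphere_centre <- (dim(half1$values) / 2 + half1$origin) * half1$voxel
    half1 <- extract_sphere(half1, sphere_centre, sphere_radius)
    half2 <- extract_sphere(half2, sphere_centre, sphere_radius)
  }
  t1 <- map_to_fourier(half1, resolution)
  t2 <- map_to_fourier(half2, resolution)
  a <- ft_attrs(t1)
  keep <- t1$s > 0  # the origin term carries no docking information
  t1 <- set_ft_attrs(t1[keep, ], a)
  t2 <- set_ft_attrs(t2[keep, ], a)
  # filtered-input check: shell power of the half-map difference
  bid10 <- resolution_bins(t1$s, 10)
  dpow <- tapply(Mod(t1$f - t2$f)^2, bid10, mean)
  tpow <- tapply((Mod(t1$f)^2 + Mod(t2$f)^2) / 2, bid10, mean)
  if (any(dpow < 1e-8 * tpow)) {
    warnings <- c(warnings, paste(
      "half-map difference power collapses in at least one resolution",
      "shell: input looks filtered; the error model requires unfiltered,",
      "unmasked half-maps"))
    warning(warnings[length(warnings)])
  }
  fld <- local_variance_field(t1, t2, target_count = target_count)
  sm <- refine_signal_model(t1, t2, fld$sigma_e, best = best, bins = bins)
  ss_loc <- fld$sigma_s_loc
  ss_hyb <- hybrid_sigma_s(ss_loc, sm$fitted, fld$cc)
  se_floor <- 1e-10 * mean(Mod(t1$f)^2 + Mod(t2$f)^2) / 2
  se <- pmax(fld$sigma_e, se_floor)
  f_mean <- (t1$f + t2$f) / 2
  nd <- normalize_terms(f_mean, ss_hyb, se, floor = se_floor)
  # E-value calibration: neighbourhood averaging inflates the local signal
  # estimate in steeply falling regions, so the raw normaliser leaves
  # |E_mean|^2 below one exactly where the weights are largest, which in
  # turn inflates the refined model error Delta and couples into the cell
  # scale. A smooth correction restores the defining unit mean-square
  # property of the E-values. The effective per-term denominator is kept
  # so model coefficients can be normalised by the very same field, which
  # cancels its speckle-tracking structure term by term.
  cal <- smooth_shell_scale(t1$s, Mod(nd$e_mean)^2)
  nd$e_mean <- nd$e_mean / cal
  denom <- sqrt(pmax(ss_hyb, 0) + se / 2) * cal
  terms <- tibble::tibble(
    h = t1$h, k = t1$k, l = t1$l, s = t1$s,
    f1 = t1$f, f2 = t2$f, f_mean = f_mean,
    sigma_s_loc = ss_loc, sigma_s_model = sm$fitted,
    sigma_s = ss_hyb, sigma_e = se, cc = fld$cc,
    d_obs = nd$d_obs, e_mean = nd$e_mean, denom = denom
  )
  terms <- set_ft_attrs(terms, a)
  box_volume <- prod(a$cell)
  if (is.null(ordered_volume)) {
    ordered_volume <- if (!is.null(sphere_radius))
      min(4 / 3 * pi * sphere_radius^3, box_volume) else box_volume
  }
  over <- list(ordered_volume = ordered_volume, box_volume = box_volume,
               factor = oversampling_factor(ordered_volume, box_volume))
  structure(
    list(terms = terms, signal_model = sm, oversampling = over,
         shells = shell_summary(terms, 10), axes = axis_profiles(terms),
         sigma_a_params = sigma_a_params, warnings = warnings),
    class = "cryodock_prepared"
  )
}

# Per-shell means of the estimated fields.
shell_summary <- function(terms, shells = 10) {
  bid <- resolution_bins(terms$s, shells)
  dplyr::summarise(
    dplyr::group_by(dplyr::mutate(terms, bin = bid), .data$bin),
    s_min = min(.data$s), s_max = max(.data$s), n = dplyr::n(),
    sigma_s = mean(.data$sigma_s), sigma_e = mean(.data$sigma_e),
    cc = mean(.data$cc), d_obs = mean(.data$d_obs),
    e2 = mean(Mod(.data$e_mean)^2),
    .groups = "drop"
  )
}

# Directional profiles: shell means of signal and noise power restricted to
# cones around the x, y and z axes (both hemispheres).
axis_profiles <- function(terms, shells = 10, half_angle = 25) {
  cosmin <- cos(half_angle * pi / 180)
  a <- ft_attrs(terms)
  hc <- cbind(terms$h / a$cell[1], terms$k / a$cell[2], terms$l / a$cell[3])
  u <- abs(hc / pmax(terms$s, 1e-12))
  bid <- resolution_bins(terms$s, shells)
  purrr::map_dfr(1:3, function(ax) {
    sel <- u[, ax] >= cosmin & terms$s > 0
    dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(axis = c("x", "y", "z")[ax], bin = bid[sel],
                       s = terms$s[sel], sigma_s = terms$sigma_s[sel],
                       sigma_e = terms$sigma_e[sel]),
        .data$axis, .data$bin),
      s_mid = stats::median(.data$s), n = dplyr::n(),
      sigma_s = mean(.data$sigma_s), sigma_e = mean(.data$sigma_e),
      .groups = "drop"
    )
  })
}

#' @export
print.cryodock_prepared <- function(x, ...) {
  a <- ft_attrs(x$terms)
  cat(sprintf("<cryodock_prepared> %d terms, box %.1f A, d_min %.2f A\n",
              nrow(x$terms), a$cell[1], 1 / max(x$terms$s)))
  cat(sprintf("  oversampling factor %.4g; mean D_obs %.3f\n",
              x$oversampling$factor, mean(x$terms$d_obs)))
  print(x$shells)
  invisible(x)
}

#' Docking coefficient sets from prepared data
#'
#' Convenience wrapper building the centroid and likelihood-weighted
#' coefficient sets from a prepared object (see
#' [docking_coefficients()]).
#'
#' @param prepared a `cryodock_prepared` object.
#' @param f_completeness,delta `sigma_A` parameters for the likelihood set;
#'   defaults from `prepared$sigma_a_params`.
#' @return List of two [fourier_terms]: `centroid`, `likelihood`.
#' @export
prepared_coefficients <- function(prepared,
                                  f_completeness = NULL, delta = NULL) {
  p <- prepared$sigma_a_params
  if (is.null(f_completeness)) f_completeness <- p$f
  if (is.null(delta)) delta <- p$delta
  t <- prepared$terms
  sa <- sigma_a(f_completeness, delta, t$s)
  docking_coefficients(t, t$e_mean, t$d_obs, sa)
}
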