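#' Single-term log-likelihood gain
#'
#' Gain in log-likelihood of an observed normalised map coefficient given a
#' model coefficient, relative to an uninformative model (`sigma_A = 0`).
#' With `x = D_obs * sigma_A`, the conditional distribution of `E_mean`
#' given `E_C` is complex normal with mean `x E_C` and variance `1 - x^2`,
#' so
#' `LLG = -log(1 - x^2) - x^2 (E^2 + E_C^2) / (1 - x^2)
#'        + 2 x E E_C cos(dphi) / (1 - x^2)`
#' where `E`, `E_C` are amplitudes and `dphi` the phase difference. Exactly
#' zero when `sigma_A = 0`; maximal in `dphi` at zero phase difference.
#'
#' @param e_mean_amp amplitude of the observed normalised coefficient.
#' @param e_c_amp amplitude of the normalised model coefficient.
#' @param delta_phi phase difference (radians).
#' @param d_obs per-term map quality in `[0, 1)`.
#' @param sigma_a per-term model quality in `[0, 1)`.
#' @return Per-term LLG values.
#' @export
llg_term <- function(e_mean_amp, e_c_amp, delta_phi, d_obs, sigma_a) {
  x <- d_obs * sigma_a
  if (any(x >= 1)) stop("d_obs * sigma_a must be < 1")
  v <- 1 - x^2
  -log(v) - x^2 * (e_mean_amp^2 + e_c_amp^2) / v +
    2 * x * e_mean_amp * e_c_amp * cos(delta_phi) / v
}

# Inner join of data and model coefficients on hkl; errors if misaligned.
# Model sets computed directly on the data's term layout are row-aligned
# already and skip the join.
join_terms <- function(data, mf) {
  if (nrow(mf) == nrow(data) &&
      identical(mf$h, data$h) && identical(mf$k, data$k) &&
      identical(mf$l, data$l)) {
    j <- data
    j$e_c <- mf$e_c
    return(j)
  }
  j <- dplyr::inner_join(data, mf[, c("h", "k", "l", "e_c")],
                         by = c("h", "k", "l"))
  if (nrow(j) != nrow(data) || nrow(j) != nrow(mf))
    stop("data and model term sets are misaligned on hkl")
  j
}

#' Total log-likelihood gain of a model against prepared data
#'
#' Sums the per-term LLG over all Fourier terms and applies the
#' oversampling correction. Also reports the equivalent decomposition into
#' a correlation part (the single term that changes under translation), a
#' quadratic scale part and an offset, and verifies that the two routes
#' agree.
#'
#' @param data tibble with columns `h, k, l, s, e_mean, d_obs` (e.g. the
#'   `terms` element of [prepare_halfmaps()]).
#' @param mf model coefficients from [model_to_efc()].
#' @param sigma_a_model per-term `sigma_A`; either a numeric vector aligned
#'   with `data`, or `NULL` to compute it from `f_completeness` and `delta`.
#' @param f_completeness model completeness fraction used when
#'   `sigma_a_model` is `NULL`.
#' @param delta r.m.s. coordinate error (A) used when `sigma_a_model` is
#'   `NULL` (default 1.0, the typical refined value range being roughly
#'   0.8--1.2 A).
#' @param factor oversampling correction factor in (0, 1].
#' @param shells number of resolution shells for the per-shell report.
#' @return Object of class `cryodock_llg`: `total`, `correlation`, `scale`,
#'   `offset`, `factor`, per-shell tibble, and the inputs used.
#' @export
total_llg <- function(data, mf, sigma_a_model = NULL, f_completeness = 1,
                      delta = 1.0, factor = 1, shells = 10) {
  j <- join_terms(data, mf)
  sa <- if (is.null(sigma_a_model)) sigma_a(f_completeness, delta, j$s)
  else sigma_a_model
  x <- j$d_obs * sa
  if (any(x >= 1)) stop("d_obs * sigma_a must be < 1")
  E <- Mod(j$e_mean); Ec <- Mod(j$e_c)
  dphi <- Arg(j$e_mean) - Arg(j$e_c)
  terms <- llg_term(E, Ec, dphi, j$d_obs, sa)
  v <- 1 - x^2
  corr <- sum(2 * x / v * Re(j$e_mean * Conj(j$e_c)))
  scale_part <- -sum(x^2 * (E^2 + Ec^2) / v)
  offset <- -sum(log(v))
  tot <- sum(terms)
  if (abs((corr + scale_part + offset) - tot) >
      1e-8 * max(1, abs(tot)))
    stop("internal inconsistency between LLG sum and its decomposition")
  shell_tbl <- NULL
  if (shells > 0) {
    bid <- resolution_bins(j$s, shells)
    shell_tbl <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(bin = bid, s = j$s, llg = terms),
                      .data$bin),
      s_min = min(.data$s), s_max = max(.data$s), n = dplyr::n(),
      llg = factor * sum(.data$llg), .groups = "drop"
    )
  }
  structure(
    list(total = factor * tot, correlation = factor * corr,
         scale = factor * scale_part, offset = factor * offset,
         factor = factor, shells = shell_tbl, n_terms = nrow(j),
         delta = if (is.null(sigma_a_model)) delta else NA_real_,
         f_completeness = f_completeness),
    class = "cryodock_llg"
  )
}

#' @export
print.cryodock_llg <- function(x, ...) {
  cat(sprintf("<cryodock_llg> total LLG = %.2f over %d terms (correction %.4g)\n",
              x$total, x$n_terms, x$factor))
  cat(sprintf("  correlation %.2f + scale %.2f + offset %.2f\n",
              x$correlation, x$scale, x$offset))
  invisible(x)
}

#' Quasi-uniform orientation grid
#'
#' Deterministic quasi-uniform sample of rotations: axes from a Fibonacci
#' hemisphere and rotation angles in a uniform ladder, sized so that
#' neighbouring orientations differ by roughly `step_deg`. The identity
#' rotation is always first; ties in later scoring are broken by grid
#' order. For a model of radius `R` docked against data to resolution
#' `d_min`, a step of about `2 asin(d_min / (4 R))` radians keeps the
#' highest-resolution features within half a Fourier feature of their
#' correct position between neighbouring grid points.
#'
#' @param step_deg angular step in degrees.
#' @return List of 3x3 rotation matrices.
#' @export
orientation_grid <- function(step_deg) {
  stopifnot(step_deg > 0)
  n_ang <- max(1, ceiling(360 / step_deg))
  angs <- seq(0, 360 - 360 / n_ang, by = 360 / n_ang)
  n_ax <- max(1, ceiling(2 * 180^2 / (pi * step_deg^2)))
  i <- seq_len(n_ax) - 0.5
  phi <- acos(i / n_ax)               # polar angle on the upper hemisphere
  theta <- pi * (1 + sqrt(5)) * i
  axes <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  rots <- list(diag(3))
  for (ai in seq_len(n_ax)) {
    u <- axes[ai, ]
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    for (ang in angs[angs > 0]) {
      th <- ang * pi / 180
      rots[[length(rots) + 1]] <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
  }
  rots
}

#' Recommended orientation step for a model and resolution
#'
#' @param d_min high-resolution limit (A).
#' @param model_radius model radius of gyration-scale extent (A).
#' @return Step in degrees.
#' @export
orientation_step <- function(d_min, model_radius) {
  2 * asin(min(1, d_min / (4 * model_radius))) * 180 / pi
}

#' Amplitude-only rotation target
#'
#' Scores model orientations against the data using only Fourier
#' amplitudes, since phases carry no information about orientation until a
#' position is chosen. Each term contributes a Rice-likelihood gain in
#' which `D_obs` downweights unreliable terms, exactly as the observational
#' error parameter does in the crystallographic likelihood rotation target
#' on intensities. Scores are invariant to any translation of the model by
#' construction.
#'
#' @param data tibble with `h, k, l, s, e_mean, d_obs` columns and
#'   [fourier_terms] attributes.
#' @param model atom tibble or coordinate matrix.
#' @param orientations list of 3x3 rotation matrices (e.g.
#'   [orientation_grid()]).
#' @param f_completeness,delta `sigma_A` parameters.
#' @param width Gaussian atom width (A).
#' @param factor oversampling correction factor.
#' @return Tibble of orientations ranked by score: columns `orientation`
#'   (index into `orientations`), `score`, and the rotation angles.
#' @export
rotation_score <- function(data, model, orientations, f_completeness = 1,
                           delta = 1.0, width = 1.5, factor = 1) {
  if (length(orientations) == 0) stop("empty orientation grid")
  coords <- if (is.matrix(model)) model else cbind(model$x, model$y, model$z)
  com <- colMeans(coords)
  sa <- sigma_a(f_completeness, delta, data$s)
  x <- data$d_obs * sa
  v <- 1 - x^2
  E <- Mod(data$e_mean)
  scores <- vapply(seq_along(orientations), function(i) {
    rot <- sweep(sweep(coords, 2, com) %*% t(orientations[[i]]), 2, com, "+")
    mf <- model_to_efc(rot, data, width = width)
    Ec <- Mod(mf$e_c)
    z <- 2 * x * E * Ec / v
    sum(-log(v) - (x^2 * (E^2 + Ec^2)) / v +
          log(besselI(z, 0, expon.scaled = TRUE)) + z)
  }, numeric(1))
  out <- tibble::tibble(
    orientation = seq_along(orientations),
    score = factor * scores
  )
  dplyr::arrange(out, dplyr::desc(.data$score), .data$orientation)
}

#' Exact FFT translation search
#'
#' The LLG as a function of model translation is a correlation function:
#' only the term `sum 2x/(1-x^2) Re(E_mean Conj(E_C))` changes under
#' translation, and a translation by `t` multiplies `E_C` by
#' `exp(-2 pi i h.t)`. The LLG on the full grid of voxel translations is
#' therefore computed exactly with a single FFT plus a
#' translation-independent constant.
#'
#' @param data tibble with `h, k, l, s, e_mean, d_obs` and [fourier_terms]
#'   attributes.
#' @param mf model coefficients from [model_to_efc()] at the orientation
#'   being searched (zero shift).
#' @param f_completeness,delta,sigma_a_model `sigma_A` specification as in
#'   [total_llg()].
#' @param factor oversampling correction factor.
#' @return List: `grid` (3D array of LLG over voxel translations), `best`
#'   (tibble with the top translation in A and its LLG), `constant`.
#' @export
translation_search_fft <- function(data, mf, sigma_a_model = NULL,
                                   f_completeness = 1, delta = 1.0,
                                   factor = 1) {
  a <- ft_attrs(data)
  j <- join_terms(data, mf)
  sa <- if (is.null(sigma_a_model)) sigma_a(f_completeness, delta, j$s)
  else sigma_a_model
  x <- j$d_obs * sa
  v <- 1 - x^2
  E <- Mod(j$e_mean); Ec <- Mod(j$e_c)
  G <- (2 * x / v) * j$e_mean * Conj(j$e_c)
  # the full-array transform counts each Friedel pair twice but
  # self-conjugate (Nyquist) terms once; pre-double the latter so the grid
  # is exactly twice the half-set sum everywhere
  d <- ft_attrs(data)$ngrid
  self <- (2 * j$h) %% d[1] == 0 & (2 * j$k) %% d[2] == 0 &
    (2 * j$l) %% d[3] == 0
  vals <- G
  vals[self] <- 2 * Re(G[self])
  garr <- ft_full_array(set_ft_attrs(j, ft_attrs(data)), vals)
  Cgrid <- Re(stats::fft(garr, inverse = TRUE)) / 2
  const <- sum(-log(v) - x^2 * (E^2 + Ec^2) / v)
  grid <- factor * (Cgrid + const)
  imax <- which.max(grid)
  iv <- arrayInd(imax, dim(grid)) - 1
  tvox <- ifelse(iv >= a$ngrid / 2, iv - a$ngrid, iv)
  best <- tibble::tibble(
    tx = tvox[1] * a$voxel, ty = tvox[2] * a$voxel, tz = tvox[3] * a$voxel,
    llg = grid[imax]
  )
  list(grid = grid, best = best, constant = factor * const,
       voxel = a$voxel, ngrid = a$ngrid)
}

#' Rigid-body refinement of a docked pose
#'
#' Maximises the total LLG over the pose parameters: three rotation
#' perturbations about the model centre of mass, three translations, the
#' effective model error `delta` (through `sigma_A`) and the cell scale
#' factor. Rotations about the centre of mass keep the rotation and
#' translation parameters nearly orthogonal at the optimum. A quasi-Newton
#' optimiser with numeric gradients is used; `delta` is bounded to
#' `[0.1, 3]` A and the cell scale to `[0.9, 1.1]`.
#'
#' @param data tibble with `h, k, l, s, e_mean, d_obs` and [fourier_terms]
#'   attributes.
#' @param model atom tibble or coordinate matrix (pre-pose coordinates).
#' @param pose0 starting [pose()] (from the rotation/translation search).
#' @param delta0 starting r.m.s. model error (A).
#' @param refine character vector naming the parameter groups to refine:
#'   any of `"rot"`, `"trans"`, `"delta"`, `"scale"`.
#' @param f_completeness completeness used in `sigma_A`.
#' @param width Gaussian atom width (A).
#' @param factor oversampling correction factor.
#' @param max_iter optimiser iteration cap.
#' @return List with the refined `pose`, `delta`, final `llg`, the
#'   starting LLG, the optimiser path (`llg_path`) and convergence info.
#' @export
refine_pose <- function(data, model, pose0 = pose(), delta0 = 1.0,
                        refine = c("rot", "trans", "delta", "scale"),
                        f_completeness = 1, width = 1.5, factor = 1,
                        max_iter = 200) {
  coords <- if (is.matrix(model)) model else cbind(model$x, model$y, model$z)
  com <- colMeans(coords)
  par_full <- c(pose0$angles, pose0$shift, delta0, pose0$scale)
  names(par_full) <- c("ax", "ay", "az", "tx", "ty", "tz", "delta", "scale")
  free <- c(rep("rot" %in% refine, 3), rep("trans" %in% refine, 3),
            "delta" %in% refine, "scale" %in% refine)
  lower_full <- c(rep(-Inf, 6), 0.1, 0.9)
  upper_full <- c(rep(Inf, 6), 3.0, 1.1)
  path <- numeric(0)
  objective <- function(pfree) {
    par <- par_full
    par[free] <- pfree
    pp <- pose(angles = par[1:3], shift = par[4:6], scale = par[8])
    mf <- model_to_efc(coords, data, p = pp, width = width, com = com)
    ll <- total_llg(data, mf, f_completeness = f_completeness,
                    delta = par[7], factor = factor, shells = 0)
    path <<- c(path, ll$total)
    -ll$total
  }
  opt <- stats::optim(par_full[free], objective, method = "L-BFGS-B",
                      lower = lower_full[free], upper = upper_full[free],
                      control = list(maxit = max_iter, factr = 1e9,
                                     parscale = c(0.5, 0.5, 0.5, 0.3, 0.3,
                                                  0.3, 0.1, 0.005)[free]))
  par <- par_full
  par[free] <- opt$par
  final_pose <- pose(angles = par[1:3], shift = par[4:6], scale = par[8])
  list(pose = final_pose, delta = unname(par[7]), llg = -opt$value,
       llg_start = path[1], llg_path = cummax(path),
       convergence = opt$convergence, message = opt$message,
       counts = opt$counts, com = com)
}
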