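#' Expected translation LLG per Fourier term
#'
#' Probability-weighted average of the per-term LLG over the conditional
#' distribution of the model coefficient given the data. With
#' `x = D_obs * sigma_A`, the cross terms involving correlated squared
#' amplitudes average out (their expected contribution is zero when the
#' squared amplitudes are uncorrelated with the quadratic weights), leaving
#' the closed form `eLLG_tra = -log(1 - x^2)`: the mutual information, in
#' nats, between two x-correlated complex normal coefficients.
#'
#' @param d_obs per-term map quality in `[0, 1)`.
#' @param sigma_a per-term model quality in `[0, 1)` (default 1).
#' @return Expected LLG per term (nats).
#' @export
ellg_tra_term <- function(d_obs, sigma_a = 1) {
  x <- d_obs * sigma_a
  if (any(x < 0 | x >= 1)) stop("d_obs * sigma_a must lie in [0, 1)")
  -log1p(-x^2)
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch).
gauss_legendre01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = (e$values + 1) / 2, weights = e$vectors[1, ]^2)
}

# log I0, switching to the asymptotic expansion where besselI would
# over- or underflow.
ln_i0 <- function(z) {
  out <- numeric(length(z))
  big <- z > 5e4
  if (any(!big)) {
    zb <- z[!big]
    out[!big] <- log(besselI(zb, 0, expon.scaled = TRUE)) + zb
  }
  if (any(big)) {
    zb <- z[big]
    out[big] <- zb - 0.5 * log(2 * pi * zb) + log1p(1 / (8 * zb))
  }
  out
}

# E[ln I0(2 x E Ec / (1 - x^2))] for amplitudes of x-correlated unit complex
# normals, minus the remaining terms of the amplitude mutual information.
# Two quadratures are used: a tensor-product grid over both amplitudes
# (accurate at small and moderate x, where the joint density is broad) and
# a ridge-adapted factorisation Ec ~ Rayleigh, E | Ec ~ Rice (accurate as
# x -> 1, where the density concentrates on a diagonal ridge of width
# sqrt(1 - x^2)).
ellg_rot_quad_grid <- function(x, n_nodes = 160, amax = 7.5) {
  gl <- gauss_legendre01(n_nodes)
  a <- gl$nodes * amax
  w <- gl$weights * amax
  ww <- outer(w, w)
  aa <- outer(a, a)
  a2 <- outer(a^2, a^2, "+")
  vapply(x, function(xi) {
    v <- 1 - xi^2
    lnI0 <- ln_i0(2 * xi * aa / v)
    dens <- (4 / v) * aa * exp(lnI0 - a2 / v)
    wgt <- ww * dens
    sum(wgt * lnI0) / sum(wgt) - log(v) - 2 * xi^2 / v
  }, numeric(1))
}

ellg_rot_quad_ridge <- function(x, n_nodes = 140, cmax = 6, umax = 8) {
  gl <- gauss_legendre01(n_nodes)
  cg <- gl$nodes * cmax
  wc <- gl$weights * cmax
  ug <- (gl$nodes * 2 - 1) * umax
  wu <- gl$weights * 2 * umax
  vapply(x, function(xi) {
    v <- 1 - xi^2
    sd <- sqrt(v / 2)
    e <- outer(sd * ug, xi * cg, "+")     # observed amplitude nodes
    pos <- e > 0
    c2 <- matrix(cg, n_nodes, n_nodes, byrow = TRUE)
    z <- 2 * xi * pmax(e, 0) * c2 / v
    lnI0 <- ln_i0(z)
    dim(lnI0) <- dim(z)
    lg <- log(pmax(2 * e, 1e-300) / v) - (e^2 + (xi * c2)^2) / v +
      lnI0 + log(2 * c2) - c2^2
    wgt <- outer(wu * sd, wc) * exp(lg)
    wgt[!pos] <- 0
    e_lni0 <- sum(ifelse(wgt > 0, wgt * lnI0, 0))
    norm <- sum(wgt)
    e_lni0 / norm - log(v) - 2 * xi^2 / v
  }, numeric(1))
}

ellg_rot_one <- function(x) {
  out <- numeric(length(x))
  lo <- x < 0.05
  mid <- x >= 0.05 & x <= 0.9
  hi <- x > 0.9 & x <= 1 - 1e-6
  xhi <- x > 1 - 1e-6
  out[lo] <- x[lo]^4 / 2 - (2 / 3) * x[lo]^6
  if (any(mid)) out[mid] <- ellg_rot_quad_grid(x[mid])
  if (any(hi)) out[hi] <- ellg_rot_quad_ridge(x[hi])
  if (any(xhi)) {
    # beyond x = 1 - 1e-6 the quadrature cancels catastrophically, but the
    # mutual information has reached its asymptotic slope of
    # -log(1 - x^2) / 2; anchor the asymptote at the switch point
    x0 <- 1 - 1e-6
    v0 <- 1 - x0^2
    anchor <- ellg_rot_quad_ridge(x0)
    out[xhi] <- anchor - 0.5 * (log1p(-x[xhi]^2) - log(v0))
  }
  out
}

#' Expected rotation LLG per Fourier term
#'
#' Expected per-term LLG of the amplitude-only rotation target for a map
#' without symmetry (the crystallographic P1 case). This is the mutual
#' information between the amplitudes of two `x`-correlated complex normal
#' coefficients (`x = D_obs * sigma_A`): a series `x^4/2 - (2/3) x^6 + ...`
#' for small `x`, evaluated by quadrature otherwise. Because amplitudes
#' discard the phase, this never exceeds [ellg_tra_term()]; at small `x` it
#' is quartic while the translation eLLG is quadratic, which is why small
#' subvolumes pay a far higher price in the rotation search than in the
#' translation search.
#'
#' @inheritParams ellg_tra_term
#' @return Expected rotation LLG per term (nats).
#' @export
ellg_rot_term <- function(d_obs, sigma_a = 1) {
  x <- d_obs * sigma_a
  if (any(x < 0 | x >= 1)) stop("d_obs * sigma_a must lie in [0, 1)")
  n_quad <- sum(x >= 0.05)
  if (n_quad <= 64) return(ellg_rot_one(x))
  # long vectors: evaluate the smooth ratio eLLG_rot / x^4 on a reference
  # grid once and spline-interpolate; relative accuracy is preserved at
  # every scale because the ratio varies slowly
  xg <- seq(0.05, max(min(max(x), 1 - 1e-10), 0.0501), length.out = 128)
  rg <- ellg_rot_one(xg) / xg^4
  sp <- stats::splinefun(xg, rg, method = "natural")
  out <- x^4 / 2 - (2 / 3) * x^6
  big <- x >= 0.05
  out[big] <- sp(x[big]) * x[big]^4
  # phases only ever add information: interpolation error must not push the
  # amplitude-only score past the full-coefficient bound
  pmin(out, -log1p(-x^2))
}

#' Information gained about one Fourier term
#'
#' Kullback-Leibler divergence from the prior to the posterior distribution
#' of the true coefficient given the reconstruction; equivalently the eLLG
#' a perfect model (`sigma_A = 1`) would achieve:
#' `D_KL = -ln(1 - D_obs^2)` nats. `D_obs = 1` means infinite information
#' and is reported as an overflow (capped at `1 - 1e-9`).
#'
#' @param d_obs per-term map quality in `[0, 1]`.
#' @return Tibble with columns `nats` and `bits` (`bits = nats / ln 2`).
#' @export
dkl_term <- function(d_obs) {
  if (any(d_obs < 0 | d_obs > 1)) stop("d_obs must lie in [0, 1]")
  if (any(d_obs == 1))
    warning("d_obs = 1 implies infinite information; capped at 1 - 1e-9")
  d <- pmin(d_obs, 1 - 1e-9)
  nats <- -log1p(-d^2)
  tibble::tibble(nats = nats, bits = nats / log(2))
}

#' Map half-map FSC to the single-term map quality
#'
#' The correlation of the averaged map to the true map (`FSC_ref`, the
#' shell-level analogue of `D_obs`) relates to the half-map FSC by
#' `D_obs^2 = 2 FSC / (1 + FSC)`.
#'
#' @param fsc half-map Fourier shell correlation in `[0, 1)`.
#' @return `D_obs` values.
#' @export
dobs_from_fsc <- function(fsc) {
  if (any(fsc < 0 | fsc >= 1)) stop("fsc must lie in [0, 1)")
  sqrt(2 * fsc / (1 + fsc))
}

#' Map the single-term map quality to half-map FSC
#'
#' Inverse of [dobs_from_fsc()]: `FSC = D_obs^2 / (2 - D_obs^2)`.
#'
#' @param d_obs map quality in `[0, 1)`.
#' @return FSC values.
#' @export
fsc_from_dobs <- function(d_obs) d_obs^2 / (2 - d_obs^2)

#' Fourier shell information
#'
#' Information, in bits, gained by a resolution shell with half-map FSC
#' `fsc` and `K` effective independent Fourier terms:
#' `FSI = K log2((1 + FSC) / (1 - FSC))`. Substituting the half-map FSC
#' implied by a common per-term `D_obs` makes this exactly
#' `K` times [dkl_term()] in bits, so the shell measure and the per-term
#' information measure agree whenever `D_obs` is uniform over the shell;
#' the per-term form is the more general, since anisotropy and preferred
#' orientations spread `D_obs` within a shell.
#'
#' @param fsc half-map FSC in `[0, 1)`.
#' @param K effective number of independent terms in the shell (>= 1);
#'   usually the raw term count times the oversampling factor.
#' @return Shell information in bits.
#' @export
fsi_shell <- function(fsc, K) {
  if (any(fsc < 0 | fsc >= 1)) stop("fsc must lie in [0, 1)")
  if (any(K < 1)) stop("K must be >= 1")
  K * log2((1 + fsc) / (1 - fsc))
}

#' Filter Fourier terms by information gain
#'
#' Drops terms whose individual information gain falls below a threshold
#' (default 0.01 bit), so later likelihood evaluations skip terms that
#' cannot influence the score. The oversampling correction is applied to
#' the per-term information before thresholding by default (exposed as a
#' flag, since the correction is uniform and simply rescales the threshold).
#'
#' @param terms a [fourier_terms] tibble (or any tibble with hkl columns).
#' @param d_obs per-term map quality aligned with `terms`.
#' @param threshold_bits information threshold in bits (default 0.01).
#' @param factor oversampling correction factor.
#' @param after_correction apply `factor` to the per-term information
#'   before comparing with the threshold (default `TRUE`).
#' @return List: `terms` (the surviving subset, attributes preserved),
#'   `kept`, `n_dropped`, `discarded_bits` (total information discarded).
#' @export
filter_by_information <- function(terms, d_obs, threshold_bits = 0.01,
                                  factor = 1, after_correction = TRUE) {
  bits <- dkl_term(d_obs)$bits * if (after_correction) factor else 1
  keep <- bits >= threshold_bits
  out <- terms[keep, , drop = FALSE]
  out <- set_ft_attrs(out, ft_attrs(terms))
  list(terms = out, kept = which(keep), n_dropped = sum(!keep),
       discarded_bits = sum(bits[!keep]) *
         if (after_correction) 1 else factor)
}

#' Per-shell information and expected-LLG planning report
#'
#' Summarises prepared half-map data into resolution shells: effective
#' independent term count, mean `D_obs`, the equivalent half-map FSC, the
#' expected rotation and translation LLGs for a model of the given quality,
#' and the shell information in bits. Totals carry the oversampling
#' correction.
#'
#' @param data tibble with `s` and `d_obs` columns ([prepare_halfmaps()]
#'   `terms`).
#' @param f_completeness,delta model quality entering `sigma_A`; use the
#'   defaults (perfect model) for pure information content.
#' @param factor oversampling correction factor.
#' @param shells number of equal-count resolution shells.
#' @return Object of class `cryodock_info`: per-shell tibble and totals.
#' @export
info_report <- function(data, f_completeness = 1, delta = 0, factor = 1,
                        shells = 10) {
  use <- data$s > 0
  sa <- sigma_a(f_completeness, delta, data$s[use])
  d <- pmin(data$d_obs[use], 1 - 1e-9)
  per <- tibble::tibble(
    s = data$s[use],
    d_obs = d,
    ellg_rot = ellg_rot_term(d, sa),
    ellg_tra = ellg_tra_term(d, sa),
    bits = dkl_term(d)$bits
  )
  bid <- resolution_bins(per$s, shells)
  tbl <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(per, bin = bid), .data$bin),
    s_min = min(.data$s), s_max = max(.data$s),
    n = dplyr::n(), K = factor * dplyr::n(),
    d_obs = mean(.data$d_obs),
    fsc = fsc_from_dobs(mean(.data$d_obs)),
    ellg_rot = factor * sum(.data$ellg_rot),
    ellg_tra = factor * sum(.data$ellg_tra),
    bits = factor * sum(.data$bits),
    .groups = "drop"
  )
  structure(
    list(shells = tbl,
         totals = list(ellg_rot = factor * sum(per$ellg_rot),
                       ellg_tra = factor * sum(per$ellg_tra),
                       bits = factor * sum(per$bits)),
         factor = factor, f_completeness = f_completeness, delta = delta),
    class = "cryodock_info"
  )
}

#' @export
print.cryodock_info <- function(x, ...) {
  cat(sprintf("<cryodock_info> totals (corrected by %.4g):\n", x$factor))
  cat(sprintf("  eLLG_rot %.3f, eLLG_tra %.3f, information %.1f bits\n",
              x$totals$ellg_rot, x$totals$ellg_tra, x$totals$bits))
  print(x$shells)
  invisible(x)
}
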