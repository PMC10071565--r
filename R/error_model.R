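#' Bivariate complex-normal log-likelihood of a half-map term pair
#'
#' Matching Fourier terms from two half-maps share the true signal and carry
#' independent noise, so their joint density is a bivariate complex normal
#' with covariance `Sigma_S + Sigma_E` on the diagonal and `Sigma_S` off the
#' diagonal. This returns the log joint density; it is the building block
#' both of the local maximum-likelihood variance estimators and of the
#' anisotropic signal-model refinement.
#'
#' @param f1,f2 complex coefficients (vectorised).
#' @param sigma_s signal power (may be zero).
#' @param sigma_e noise power (must be positive).
#' @return Log density values.
#' @export
bivariate_loglik <- function(f1, f2, sigma_s, sigma_e) {
  det <- sigma_e * (2 * sigma_s + sigma_e)
  if (any(sigma_e <= 0) || any(det <= 0) || any(sigma_s + sigma_e <= 0))
    stop("covariance matrix is not positive definite")
  quad <- ((sigma_s + sigma_e) * (Mod(f1)^2 + Mod(f2)^2) -
             2 * sigma_s * Re(f1 * Conj(f2))) / det
  -2 * log(pi) - log(det) - quad
}

# Linear indices of each stored term in the full 3D Fourier array.
ft_index <- function(terms) {
  d <- ft_attrs(terms)$ngrid
  1 + (terms$h %% d[1]) + d[1] * ((terms$k %% d[2]) + d[2] * (terms$l %% d[3]))
}

# Friedel-expanded neighbourhood of a term: all stored terms (and mates)
# within an index-space sphere of the given radius around centre_hkl.
ft_neighbourhood <- function(terms1, terms2, centre_hkl, radius) {
  full1 <- friedel_expand(terms1)
  full2 <- friedel_expand(terms2)
  d2 <- (full1$h - centre_hkl[1])^2 + (full1$k - centre_hkl[2])^2 +
    (full1$l - centre_hkl[3])^2
  sel <- d2 <= radius^2 + 1e-9
  list(f1 = full1$f[sel], f2 = full2$f[sel])
}

#' Local maximum-likelihood variance estimates for one neighbourhood
#'
#' Analytic maximisers of the summed bivariate complex-normal log-likelihood
#' over a sphere of terms in index space around a central term: the signal
#' power is the mean real part of `F1 * Conj(F2)` (an unnormalised
#' correlation of the half-map terms) and the noise power is half the mean
#' squared magnitude of the half-map difference. The raw signal estimate may
#' be negative; it is kept as is here (flooring happens downstream, where
#' physical non-negativity matters).
#'
#' @param terms1,terms2 aligned [fourier_terms] for the two half-maps.
#' @param centre_hkl integer triplet at the neighbourhood centre.
#' @param radius_terms neighbourhood radius in index units.
#' @param n_min minimum number of terms required (default 20).
#' @return List with `sigma_s`, `sigma_e` and the neighbourhood size `n`.
#' @export
local_ml_variances <- function(terms1, terms2, centre_hkl, radius_terms,
                               n_min = 20) {
  nb <- ft_neighbourhood(terms1, terms2, centre_hkl, radius_terms)
  n <- length(nb$f1)
  if (n < n_min) stop("neighbourhood holds ", n, " terms; need >= ", n_min)
  list(
    sigma_s = mean(Re(nb$f1 * Conj(nb$f2))),
    sigma_e = mean(Mod(nb$f1 - nb$f2)^2) / 2,
    n = n
  )
}

#' Local Fourier sphere correlation
#'
#' Real part of the normalised complex correlation of the two half-map term
#' sets over the same neighbourhood as [local_ml_variances()], clipped to
#' `[-1, 1]`. Used to decide, per term, how much to trust the local signal
#' estimate relative to the smooth anisotropic signal model.
#'
#' @inheritParams local_ml_variances
#' @return Correlation in `[-1, 1]`.
#' @export
sphere_cc <- function(terms1, terms2, centre_hkl, radius_terms) {
  nb <- ft_neighbourhood(terms1, terms2, centre_hkl, radius_terms)
  p1 <- sum(Mod(nb$f1)^2); p2 <- sum(Mod(nb$f2)^2)
  if (p1 <= 0 || p2 <= 0) stop("zero-power neighbourhood")
  max(-1, min(1, sum(Re(nb$f1 * Conj(nb$f2))) / sqrt(p1 * p2)))
}

# Smallest index-space radius whose lattice sphere holds >= target offsets.
neighbourhood_radius <- function(target_count = 100) {
  for (r in 1:8) {
    g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
    if (sum(g$x^2 + g$y^2 + g$z^2 <= r^2 + 1e-9) >= target_count) return(r)
  }
  8
}

#' Local variance and correlation fields over all terms
#'
#' Evaluates the analytic local maximum-likelihood estimators of signal and
#' noise power, and the local Fourier sphere correlation, at every stored
#' term simultaneously. Neighbourhood means over index-space spheres are
#' computed by FFT convolution on the full (Friedel-expanded) grid, so each
#' neighbourhood automatically includes Friedel mates and the cost is
#' independent of the neighbourhood size.
#'
#' @param terms1,terms2 aligned [fourier_terms] for the two half-maps.
#' @param radius neighbourhood radius in index units; by default the
#'   smallest radius holding at least `target_count` terms.
#' @param target_count approximate neighbourhood size used to pick the
#'   default radius (default 100).
#' @return A tibble aligned with `terms1`: columns `sigma_s_loc`,
#'   `sigma_e`, `cc`, `n_nbr`.
#' @export
local_variance_field <- function(terms1, terms2, radius = NULL,
                                 target_count = 100) {
  stopifnot(nrow(terms1) == nrow(terms2))
  if (is.null(radius)) radius <- neighbourhood_radius(target_count)
  idx <- ft_index(terms1)
  conv <- sphere_mean_operator(terms1, radius)
  X <- Re(terms1$f * Conj(terms2$f))
  Y <- Mod(terms1$f - terms2$f)^2 / 2
  P1 <- Mod(terms1$f)^2
  P2 <- Mod(terms2$f)^2
  sx <- conv(X); sy <- conv(Y); sp1 <- conv(P1); sp2 <- conv(P2)
  cc <- sx / sqrt(pmax(sp1 * sp2, 1e-300))
  tibble::tibble(
    sigma_s_loc = sx,
    sigma_e = sy,
    cc = pmin(1, pmax(-1, cc)),
    n_nbr = attr(conv, "counts")
  )
}

# Returns a function computing, for a per-term real field, the mean over
# the index-space sphere neighbourhood of every stored term (via FFT
# convolution on the Friedel-expanded grid). The neighbourhood counts are
# attached as an attribute.
sphere_mean_operator <- function(terms, radius) {
  a <- ft_attrs(terms)
  d <- a$ngrid
  idx <- ft_index(terms)
  scatter <- function(vals) {
    # real, Friedel-even fields: value identical at both mates
    Re(ft_full_array(terms, complex(real = vals, imaginary = 0)))
  }
  off <- -radius:radius
  kx <- outer(outer(off^2, off^2, "+"), off^2, "+") <= radius^2 + 1e-9
  K <- array(0, dim = d)
  K[(off %% d[1]) + 1, (off %% d[2]) + 1, (off %% d[3]) + 1] <-
    K[(off %% d[1]) + 1, (off %% d[2]) + 1, (off %% d[3]) + 1] + kx
  FK <- stats::fft(K)
  conv3 <- function(A)
    Re(stats::fft(stats::fft(A) * FK, inverse = TRUE)) / prod(d)
  cnt <- pmax(conv3(scatter(rep(1, nrow(terms)))), 1e-9)
  out <- function(vals) {
    sm <- conv3(scatter(vals))
    (sm / cnt)[idx]
  }
  attr(out, "counts") <- round(cnt[idx])
  out
}

# Smooth multiplicative amplitude normaliser: a low-df smoothing spline fit
# to shell log powers in log-s coordinates (so the strongly curved low-s
# region is resolved). Dividing coefficients by this gives unit local
# mean-square amplitude without bin-to-bin ripple; ripple matters because a
# rippled envelope moving under the cell-scale parameter can lock onto
# structure in the other envelope and bias the refined scale.
smooth_shell_scale <- function(s, power, bins = 40, df = 10) {
  use <- s > 0 & power > 0 & is.finite(power)
  nb <- min(bins, max(5, sum(use) %/% 100))
  if (sum(use) < 50) return(rep(sqrt(max(mean(power[use]), 1e-300)),
                                length(s)))
  bid <- resolution_bins(s[use], nb)
  shell <- tapply(power[use], bid, mean)
  smid <- tapply(s[use], bid, stats::median)
  ok <- is.finite(log(shell))
  if (sum(ok) < 4) {
    return(rep(sqrt(max(mean(power[use]), 1e-300)), length(s)))
  }
  sp <- stats::smooth.spline(log(smid[ok]), log(shell[ok]),
                             df = min(df, sum(ok) - 1))
  exp(stats::predict(sp, log(pmax(s, min(smid))))$y / 2)
}

# Equal-count resolution bins; returns integer bin ids and a bin table.
resolution_bins <- function(s, bins) {
  ok <- s > 0
  qs <- stats::quantile(s[ok], probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE)
  qs[1] <- -Inf; qs[bins + 1] <- Inf
  qs <- cummax(qs + seq_along(qs) * 1e-12)  # guard against ties
  id <- findInterval(s, qs, rightmost.closed = TRUE)
  id[id < 1] <- 1L; id[id > bins] <- as.integer(bins)
  id
}

#' Refine the anisotropic signal model
#'
#' Fits the smooth parametric description of the signal power
#' `Sigma_S(h) = A0^2 exp(-h*' beta_A h*/2) x m_bin x B(s)`, where `beta_A`
#' is a symmetric anisotropic tensor (A^2), `B(s)` is the reference spectral
#' power curve and the `m_bin` are binwise multipliers whose logarithms are
#' weakly restrained to zero (more weakly at low resolution, where true
#' spectra vary most between structures). The parameters maximise the summed
#' bivariate complex-normal log-likelihood of the half-map term pairs, with
#' the noise power field held fixed at its local estimate.
#'
#' @param terms1,terms2 aligned [fourier_terms] for the two half-maps.
#' @param sigma_e per-term noise power (from [local_variance_field()]).
#' @param best reference power curve; default [best_curve()].
#' @param bins number of equal-count resolution bins (default 20, >= 5).
#' @param restraint_base restraint weight on squared log-multipliers in the
#'   lowest-resolution bin; the weight rises linearly by a factor of 4
#'   towards the highest bin.
#' @param max_terms refinement uses at most this many terms, taken as a
#'   deterministic stride subsample across the whole set (the log-likelihood
#'   is reweighted so totals refer to the full set); parameter estimates are
#'   essentially unchanged while cost drops accordingly.
#' @param smooth_weight optional weight of a second-difference penalty on
#'   the log multipliers across neighbouring bins (default 0). Useful as an
#'   extra stabiliser when the reference curve is known to match the data
#'   closely; with a mismatched reference the multipliers need genuine
#'   curvature to correct its shape, so the penalty is off by default.
#' @param max_iter iteration cap for the quasi-Newton optimiser.
#' @return An object of class `cryodock_signal_model` with elements `a0`,
#'   `beta` (3x3), `bins` (tibble), `best`, `fitted` (per-term Sigma_S for
#'   the input terms), `convergence` and `value`.
#' @export
refine_signal_model <- function(terms1, terms2, sigma_e, best = best_curve(),
                                bins = 40, restraint_base = 1,
                                smooth_weight = 0,
                                max_terms = Inf, max_iter = 2000) {
  stopifnot(bins >= 5)
  a <- ft_attrs(terms1)
  use <- which(terms1$s > 0)
  wt <- 1
  if (length(use) > max_terms) {
    stride <- ceiling(length(use) / max_terms)
    sub <- use[seq(1, length(use), by = stride)]
    wt <- length(use) / length(sub)
    use <- sub
  }
  s <- terms1$s[use]
  sv <- cbind(terms1$h[use] / a$cell[1], terms1$k[use] / a$cell[2],
              terms1$l[use] / a$cell[3])
  P <- (Mod(terms1$f)^2 + Mod(terms2$f)^2)[use]
  C <- Re(terms1$f * Conj(terms2$f))[use]
  se <- pmax(sigma_e[use], 1e-10 * mean(P) / 2)
  bid <- resolution_bins(s, bins)
  bstat <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bid, s = s), .data$bin),
    s_min = min(.data$s), s_max = max(.data$s), n = dplyr::n(),
    .groups = "drop"
  )
  w_b <- restraint_base * (1 + 3 * (bstat$bin - 1) / (bins - 1))
  bs <- best(s)
  # parameters: a = log A0; 6 tensor components; log multipliers per bin
  q_of <- function(beta6) {
    sv[, 1]^2 * beta6[1] + sv[, 2]^2 * beta6[2] + sv[, 3]^2 * beta6[3] +
      2 * (sv[, 1] * sv[, 2] * beta6[4] + sv[, 1] * sv[, 3] * beta6[5] +
             sv[, 2] * sv[, 3] * beta6[6])
  }
  sig_of <- function(par) {
    # cap the exponent: a wild tensor trial step must yield a finite
    # objective, not break the line search
    exp(pmin(2 * par[1] - 0.5 * q_of(par[2:7]) + par[7 + bid], 300)) * bs
  }
  # second-difference operator over the ordered bins (curvature penalty)
  D2 <- if (bins >= 3) {
    m <- matrix(0, bins - 2, bins)
    m[cbind(1:(bins - 2), 1:(bins - 2))] <- 1
    m[cbind(1:(bins - 2), 2:(bins - 1))] <- -2
    m[cbind(1:(bins - 2), 3:bins)] <- 1
    m
  } else matrix(0, 0, bins)
  fn <- function(par) {
    ss <- sig_of(par)
    det <- se * (2 * ss + se)
    ll <- -log(det) - ((ss + se) * P - 2 * ss * C) / det
    lm <- par[8:(7 + bins)]
    val <- -wt * sum(ll) + sum(w_b * par[7 + bstat$bin]^2) +
      smooth_weight * sum((D2 %*% lm)^2)
    if (!is.finite(val)) val <- 1e300
    val
  }
  gr <- function(par) {
    ss <- sig_of(par)
    det <- se * (2 * ss + se)
    u <- (ss + se) * P - 2 * ss * C
    dll_dss <- -2 * se / det - ((P - 2 * C) * det - u * 2 * se) / det^2
    g_ss <- -dll_dss  # gradient of the negated log-likelihood wrt Sigma_S
    gpar <- numeric(length(par))
    gpar[1] <- sum(g_ss * 2 * ss)
    gpar[2] <- sum(g_ss * (-0.5 * sv[, 1]^2) * ss)
    gpar[3] <- sum(g_ss * (-0.5 * sv[, 2]^2) * ss)
    gpar[4] <- sum(g_ss * (-0.5 * sv[, 3]^2) * ss)
    gpar[5] <- sum(g_ss * (-sv[, 1] * sv[, 2]) * ss)
    gpar[6] <- sum(g_ss * (-sv[, 1] * sv[, 3]) * ss)
    gpar[7] <- sum(g_ss * (-sv[, 2] * sv[, 3]) * ss)
    gm <- rowsum(g_ss * ss, bid)
    gpar[7 + as.integer(rownames(gm))] <- gm[, 1]
    gpar <- wt * gpar
    gpar[7 + bstat$bin] <- gpar[7 + bstat$bin] + 2 * w_b * par[7 + bstat$bin]
    lm <- par[8:(7 + bins)]
    gpar[8:(7 + bins)] <- gpar[8:(7 + bins)] +
      2 * smooth_weight * as.vector(crossprod(D2, D2 %*% lm))
    gpar
  }
  # initial overall scale from the strongest (lowest-resolution) quartile
  lowq <- s <= stats::quantile(s, 0.25)
  a0_init <- 0.5 * log(max(mean(C[lowq]) / mean(bs[lowq]), 1e-6 * mean(P)))
  par0 <- c(a0_init, rep(0, 6), rep(0, bins))
  lower <- c(-Inf, rep(-Inf, 6), rep(-4, bins))
  upper <- c(Inf, rep(Inf, 6), rep(4, bins))
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter, factr = 1e7,
                                     parscale = c(0.5, rep(50, 6),
                                                  rep(0.3, bins))))
  par <- opt$par
  if (opt$convergence != 0)
    warning("signal-model refinement did not converge (code ",
            opt$convergence, "): ", opt$message)
  # parameter order: par[2:4] diagonal, par[5:7] off-diagonal xy, xz, yz
  beta <- matrix(0, 3, 3)
  diag(beta) <- par[2:4]
  beta[1, 2] <- beta[2, 1] <- par[5]
  beta[1, 3] <- beta[3, 1] <- par[6]
  beta[2, 3] <- beta[3, 2] <- par[7]
  bt <- tibble::tibble(
    bin = bstat$bin, s_min = bstat$s_min, s_max = bstat$s_max, n = bstat$n,
    log_mult = par[7 + bstat$bin], weight = w_b
  )
  out <- structure(
    list(a0 = exp(par[1]), beta = beta, bins = bt, best = best,
         convergence = opt$convergence,
         value = -opt$value, counts = opt$counts, cell = a$cell),
    class = "cryodock_signal_model"
  )
  out$fitted <- predict(out, terms1)
  out
}

#' Predict model signal power at arbitrary Fourier indices
#'
#' @param object a `cryodock_signal_model`.
#' @param terms a [fourier_terms] tibble (columns `h`, `k`, `l`, `s`).
#' @param ... unused.
#' @return Numeric vector of predicted Sigma_S values.
#' @export
predict.cryodock_signal_model <- function(object, terms, ...) {
  sv <- cbind(terms$h / object$cell[1], terms$k / object$cell[2],
              terms$l / object$cell[3])
  q <- rowSums((sv %*% object$beta) * sv)
  # piecewise-constant multiplier looked up by resolution
  edges <- c(-Inf, object$bins$s_max)
  edges[length(edges)] <- Inf
  bid <- findInterval(terms$s, edges, rightmost.closed = TRUE)
  bid <- pmin(pmax(bid, 1), nrow(object$bins))
  object$a0^2 * exp(-0.5 * q + object$bins$log_mult[bid]) * object$best(terms$s)
}

#' @export
print.cryodock_signal_model <- function(x, ...) {
  cat("<cryodock_signal_model>\n")
  cat(sprintf("  A0 = %.4g; beta_A diagonal = (%.3g, %.3g, %.3g) A^2\n",
              x$a0, x$beta[1, 1], x$beta[2, 2], x$beta[3, 3]))
  cat(sprintf("  %d resolution bins; multipliers in [%.3g, %.3g]\n",
              nrow(x$bins), exp(min(x$bins$log_mult)),
              exp(max(x$bins$log_mult))))
  cat(sprintf("  log-likelihood %.6g (convergence code %d)\n",
              x$value, x$convergence))
  invisible(x)
}

#' Hybrid signal-power estimate
#'
#' Blends the assumption-free local estimate of signal power with the smooth
#' anisotropic-model estimate. The weight on the local estimate is a
#' logistic sigmoid of the local Fourier sphere correlation, so the local
#' estimate dominates where the half-maps agree well and the model estimate
#' takes over where the local correlation (and hence the reliability of the
#' local estimate) is low. The result is floored at zero.
#'
#' @param local local signal-power estimates (may be negative).
#' @param model model signal-power estimates (non-negative).
#' @param cc local Fourier sphere correlation per term.
#' @param steepness sigmoid steepness (default 9).
#' @param k0 sigmoid midpoint as a fraction of `cc_ref` (default 0.95), so
#'   that even terms with a high local correlation keep some weight on the
#'   anisotropic model.
#' @param cc_ref reference correlation defining the sigmoid midpoint
#'   `k0 * cc_ref` (default 1).
#' @return Non-negative hybrid signal power, between the two estimates
#'   before flooring.
#' @export
hybrid_sigma_s <- function(local, model, cc, steepness = 9, k0 = 0.95,
                           cc_ref = 1) {
  w <- stats::plogis(steepness * (cc - k0 * cc_ref))
  pmax(w * local + (1 - w) * model, 0)
}

#' Single-term map quality D_obs
#'
#' The complex correlation between the normalised averaged map coefficient
#' and the (unknown) true coefficient. Averaging the two half-maps halves
#' the noise variance, giving
#' `D_obs = sqrt(Sigma_S / (Sigma_S + Sigma_E / 2))`: one when the noise
#' vanishes, zero when the signal vanishes. It plays the same role for a
#' single Fourier term as FSC_ref does for a resolution shell.
#'
#' @param sigma_s signal power (floored at 0).
#' @param sigma_e noise power (floored at `floor`).
#' @param floor noise-power floor keeping likelihoods finite.
#' @return `D_obs` in `[0, 1]`.
#' @export
compute_dobs <- function(sigma_s, sigma_e, floor = 1e-30) {
  ss <- pmax(sigma_s, 0)
  se <- pmax(sigma_e, floor)
  sqrt(ss / (ss + se / 2))
}

#' Normalised averaged map coefficients
#'
#' E-values of the averaged half-map coefficients:
#' `E_mean = F_mean / sqrt(Sigma_S + Sigma_E / 2)`, so that the mean squared
#' amplitude is one over any region where the variance fields are accurate.
#'
#' @param f_mean complex averaged coefficients `(F1 + F2) / 2`.
#' @param sigma_s,sigma_e per-term power estimates.
#' @param floor noise-power floor.
#' @return List with complex `e_mean` and `d_obs`.
#' @export
normalize_terms <- function(f_mean, sigma_s, sigma_e, floor = 1e-30) {
  ss <- pmax(sigma_s, 0)
  se <- pmax(sigma_e, floor)
  denom <- sqrt(ss + se / 2)
  if (any(denom <= 0)) stop("vanishing normaliser")
  list(e_mean = f_mean / denom, d_obs = compute_dobs(sigma_s, sigma_e, floor))
}

#' Map coefficients for docking
#'
#' Builds the two weighted coefficient sets used for docking. The centroid
#' set, `D_obs * E_mean`, is the expected value of the true sharpened map
#' coefficient and gives the map with minimum error from the true sharpened
#' map. The likelihood set additionally carries the correlation weights of
#' the LLG target, `2 x / (1 - x^2)` with `x = D_obs * sigma_A`, so that the
#' correlation of this map with a sharpened model map is proportional to the
#' LLG (up to translation-independent terms).
#'
#' @param terms a [fourier_terms] tibble giving hkl layout (used for map
#'   synthesis downstream).
#' @param e_mean normalised averaged coefficients.
#' @param d_obs per-term `D_obs`.
#' @param sigma_a per-term `sigma_A`; required for the likelihood set.
#' @return List of two [fourier_terms] tibbles: `centroid` and `likelihood`.
#' @export
docking_coefficients <- function(terms, e_mean, d_obs, sigma_a = NULL) {
  a <- ft_attrs(terms)
  mk <- function(vals) {
    as_fourier_terms(
      tibble::tibble(h = terms$h, k = terms$k, l = terms$l,
                     f = vals, s = terms$s),
      cell = a$cell, ngrid = a$ngrid, voxel = a$voxel, origin = a$origin
    )
  }
  out <- list(centroid = mk(d_obs * e_mean))
  if (!is.null(sigma_a)) {
    x <- d_obs * sigma_a
    if (any(x >= 1)) stop("d_obs * sigma_a must be < 1")
    out$likelihood <- mk(2 * x / (1 - x^2) * e_mean)
  }
  out
}
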