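test_that("bivariate log-likelihood matches an explicit complex-normal density", {
  f1 <- 1.2 + 0.7i; f2 <- -0.4 + 1.1i
  ss <- 1.7; se <- 0.6
  # independent limit: factorises into two univariate complex normals
  ll0 <- bivariate_loglik(f1, f2, 0, se)
  uni <- function(f, v) -log(pi * v) - Mod(f)^2 / v
  expect_equal(ll0, uni(f1, se) + uni(f2, se), tolerance = 1e-10)
  # generic case: explicit 2x2 complex determinant/inverse
  S <- matrix(c(ss + se, ss, ss, ss + se), 2, 2)
  z <- c(f1, f2)
  ll_oracle <- -2 * log(pi) - log(Re(det(S))) -
    Re(Conj(z) %*% solve(S, z))[1]
  expect_equal(bivariate_loglik(f1, f2, ss, se), ll_oracle,
               tolerance = 1e-10)
  # change of variables: scaling F by c and powers by c^2
  cc <- 2.7
  expect_equal(bivariate_loglik(cc * f1, cc * f2, cc^2 * ss, cc^2 * se),
               bivariate_loglik(f1, f2, ss, se) - 2 * log(cc^2),
               tolerance = 1e-10)
  expect_error(bivariate_loglik(f1, f2, 1, 0), "positive definite")
})

test_that("local ML estimators are the analytic maximisers", {
  set.seed(3)
  n <- 50
  ss <- 2.3; se <- 0.9
  T <- rcnorm(n, ss)
  f1 <- T + rcnorm(n, se); f2 <- T + rcnorm(n, se)
  s_hat <- mean(Re(f1 * Conj(f2)))
  e_hat <- mean(Mod(f1 - f2)^2) / 2
  nll <- function(p) -sum(bivariate_loglik(f1, f2, p[1], exp(p[2])))
  o <- stats::optim(c(max(s_hat / 2, 0.1), log(2 * e_hat)), nll,
                    method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 1000))
  expect_lt(abs(o$par[1] - s_hat) / abs(s_hat), 1e-6)
  expect_lt(abs(exp(o$par[2]) - e_hat) / e_hat, 1e-6)
})

test_that("single-neighbourhood estimators handle degenerate half-sets", {
  m <- map_grid(array(rnorm(12^3), dim = c(12, 12, 12)), voxel = 1)
  t1 <- map_to_fourier(m)
  # identical half-maps: zero noise, signal = mean power
  est <- local_ml_variances(t1, t1, centre_hkl = c(2, 1, 3),
                            radius_terms = 3)
  expect_equal(est$sigma_e, 0)
  nb <- cryodock:::ft_neighbourhood(t1, t1, c(2, 1, 3), 3)
  expect_equal(est$sigma_s, mean(Mod(nb$f1)^2))
  expect_equal(sphere_cc(t1, t1, c(2, 1, 3), 3), 1)
  # anticorrelated: negative raw signal estimate
  t2 <- t1; t2$f <- -t1$f
  est2 <- local_ml_variances(t1, t2, c(2, 1, 3), 3)
  expect_equal(est2$sigma_s, -mean(Mod(nb$f1)^2))
  expect_error(local_ml_variances(t1, t1, c(2, 1, 3), 1), "need >=")
})

test_that("sphere correlation tracks a known mixing weight", {
  set.seed(8)
  n <- 1000
  # independent noise-only: |CC| below the 3/sqrt(n) sampling bound
  a <- rcnorm(n); b <- rcnorm(n)
  cc0 <- sum(Re(a * Conj(b))) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
  expect_lt(abs(cc0), 3 / sqrt(n))
  # shared signal with weight w: expected CC = w^2/(w^2 + v)
  w <- 0.8; v <- 0.5
  T <- rcnorm(n)
  f1 <- w * T + rcnorm(n, v); f2 <- w * T + rcnorm(n, v)
  cc <- sum(Re(f1 * Conj(f2))) / sqrt(sum(Mod(f1)^2) * sum(Mod(f2)^2))
  expected <- w^2 / (w^2 + v)
  expect_lt(abs(cc - expected), 3 / sqrt(n))
})

test_that("local variance field agrees with per-neighbourhood estimators", {
  set.seed(4)
  m1 <- map_grid(array(rnorm(16^3), dim = c(16, 16, 16)), voxel = 1)
  m2 <- map_grid(array(rnorm(16^3), dim = c(16, 16, 16)), voxel = 1)
  t1 <- map_to_fourier(m1); t2 <- map_to_fourier(m2)
  fld <- local_variance_field(t1, t2, radius = 3)
  i <- which(t1$h == 3 & t1$k == -2 & t1$l == 4)
  ref <- local_ml_variances(t1, t2, c(3, -2, 4), 3)
  expect_equal(fld$sigma_s_loc[i], ref$sigma_s, tolerance = 1e-8)
  expect_equal(fld$sigma_e[i], ref$sigma_e, tolerance = 1e-8)
  expect_equal(fld$cc[i], sphere_cc(t1, t2, c(3, -2, 4), 3),
               tolerance = 1e-8)
  expect_equal(fld$n_nbr[i], ref$n)
})

test_that("signal-model refinement recovers matched-family parameters", {
  set.seed(42)
  m0 <- map_grid(array(0, dim = c(48, 48, 48)), voxel = 1.2)
  ft <- map_to_fourier(m0)
  bc <- best_curve()
  sigs <- 25 * bc(ft$s)
  sige <- rep(0.5, nrow(ft))
  T <- rcnorm(nrow(ft), sigs)
  t1 <- ft; t1$f <- T + rcnorm(nrow(ft), sige)
  t2 <- ft; t2$f <- T + rcnorm(nrow(ft), sige)
  sm <- refine_signal_model(t1, t2, sige, bins = 20)
  expect_equal(sm$convergence, 0)
  expect_equal(sm$a0^2, 25, tolerance = 0.05)
  # isotropic truth (beta = 0): recovered tensor close to zero
  expect_lt(max(abs(sm$beta)), 2)
  # multipliers within 10% of one
  expect_lt(max(abs(sm$bins$log_mult)), log(1.1))
  g <- glance(sm)
  expect_equal(g$convergence, 0)
  expect_lt(g$beta_aniso, 3)
  expect_equal(nrow(tidy(sm)), 20)
})

test_that("refinement recovers an imposed prolate tensor", {
  set.seed(43)
  m0 <- map_grid(array(0, dim = c(48, 48, 48)), voxel = 1.2)
  ft <- map_to_fourier(m0)
  cell <- rep(48 * 1.2, 3)
  hc <- cbind(ft$h / cell[1], ft$k / cell[2], ft$l / cell[3])
  btrue <- diag(c(10, 10, 90))
  sigs <- 25 * exp(-rowSums((hc %*% btrue) * hc) / 2) * best_curve()(ft$s)
  sige <- rep(0.5, nrow(ft))
  T <- rcnorm(nrow(ft), sigs)
  t1 <- ft; t1$f <- T + rcnorm(nrow(ft), sige)
  t2 <- ft; t2$f <- T + rcnorm(nrow(ft), sige)
  sm <- refine_signal_model(t1, t2, sige)
  aniso_true <- 90 - 10
  aniso_fit <- sm$beta[3, 3] - sm$beta[1, 1]
  expect_lt(abs(aniso_fit - aniso_true) / aniso_true, 0.15)
})

test_that("noise-only refinement is prior-dominated and stable", {
  set.seed(44)
  m0 <- map_grid(array(0, dim = c(32, 32, 32)), voxel = 1.2)
  ft <- map_to_fourier(m0)
  sige <- rep(0.5, nrow(ft))
  t1 <- ft; t1$f <- rcnorm(nrow(ft), sige)
  t2 <- ft; t2$f <- rcnorm(nrow(ft), sige)
  sm <- refine_signal_model(t1, t2, sige)
  expect_equal(sm$convergence, 0)
  # predicted signal is a small fraction of the noise over essentially all
  # data terms; the handful of lowest-resolution terms (and the origin) sit
  # where the tensor extrapolates with almost no data to constrain it
  on_data <- t1$s > 0
  expect_lt(stats::quantile(sm$fitted[on_data], 0.99),
            0.05 * mean(sige))
  expect_lt(stats::median(sm$fitted[on_data]), 1e-6 * mean(sige))
  # multipliers stay near the prior; none diverge
  expect_lt(mean(abs(sm$bins$log_mult)), 0.1)
  expect_lt(max(abs(sm$bins$log_mult)), 1)
})

test_that("hybrid signal estimate blends by local correlation", {
  # cc <= 0: model estimate dominates
  expect_equal(hybrid_sigma_s(10, 2, 0), 2, tolerance = 2e-3)
  expect_equal(hybrid_sigma_s(10, 2, -0.5), 2, tolerance = 1e-4)
  # cc = 1: weight of the local estimate is at its maximum
  w1 <- stats::plogis(9 * (1 - 0.95))
  expect_equal(hybrid_sigma_s(10, 2, 1), w1 * 10 + (1 - w1) * 2)
  # monotone in cc, bounded by the two estimates, floored at zero
  ccs <- seq(-1, 1, by = 0.01)
  out <- hybrid_sigma_s(10, 2, ccs)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= 2 - 1e-12 & out <= 10 + 1e-12))
  expect_true(all(hybrid_sigma_s(-5, 1, ccs) >= 0))
})

test_that("D_obs hits its closed-form limits", {
  expect_equal(compute_dobs(2, 0), 1)
  expect_equal(compute_dobs(0, 1), 0)
  expect_equal(compute_dobs(1, 2), 1 / sqrt(2))
  expect_equal(compute_dobs(-3, 1), 0)  # floored negative signal
})

test_that("normalisation gives unit shells, zero maps to zero, scale invariance", {
  set.seed(9)
  n <- 4000
  ss <- 3; se <- 1
  f <- rcnorm(n, ss + se / 2)
  nd <- normalize_terms(f, rep(ss, n), rep(se, n))
  expect_lt(abs(mean(Mod(nd$e_mean)^2) - 1), 3 / sqrt(n))
  expect_equal(normalize_terms(0 + 0i, 1, 1)$e_mean, 0 + 0i)
  # doubling both half-maps: powers x4, coefficients x2 => E, D unchanged
  nd2 <- normalize_terms(2 * f, rep(4 * ss, n), rep(4 * se, n))
  expect_equal(nd2$e_mean, nd$e_mean, tolerance = 1e-12)
  expect_equal(nd2$d_obs, nd$d_obs, tolerance = 1e-12)
})

test_that("docking coefficient sets obey their limiting forms", {
  m <- map_grid(array(rnorm(8^3), dim = c(8, 8, 8)), voxel = 1)
  ft <- map_to_fourier(m)
  e <- ft$f / sqrt(mean(Mod(ft$f)^2))
  ones <- rep(1 - 1e-9, nrow(ft))
  co1 <- docking_coefficients(ft, e, ones, sigma_a = rep(0.5, nrow(ft)))
  expect_equal(co1$centroid$f, ones * e)
  zeros <- rep(0, nrow(ft))
  co0 <- docking_coefficients(ft, e, zeros, sigma_a = rep(0.5, nrow(ft)))
  expect_true(all(Mod(co0$centroid$f) == 0))
  expect_true(all(Mod(co0$likelihood$f) == 0))
  expect_error(docking_coefficients(ft, e, ones, sigma_a = rep(1.5, nrow(ft))),
               "< 1")
})

test_that("likelihood-map correlation is proportional to the LLG correlation term", {
  # the likelihood-weighted map is built so that its (Fourier-space)
  # correlation with a model map reproduces the translation-dependent part
  # of the LLG; verify across random poses
  fx <- dock_fixture()
  data <- fx$data
  sa <- sigma_a(1, 1, data$s)
  co <- docking_coefficients(data, data$e_mean, data$d_obs, sa)
  set.seed(10)
  diffs <- sapply(1:5, function(i) {
    p <- pose(angles = runif(3, -20, 20), shift = runif(3, -4, 4))
    mf <- model_to_efc(fx$coords, data, p = p)
    ll <- total_llg(data, mf, delta = 1, shells = 0)
    map_corr <- sum(Re(co$likelihood$f * Conj(mf$e_c)))
    (ll$correlation - map_corr) / max(1, abs(ll$correlation))
  })
  expect_lt(max(abs(diffs)), 1e-8)
})

test_that("scale equivariance holds through the prepared pipeline fields", {
  set.seed(12)
  m1 <- map_grid(array(rnorm(16^3), dim = c(16, 16, 16)), voxel = 1)
  m2 <- map_grid(array(rnorm(16^3), dim = c(16, 16, 16)), voxel = 1)
  t1 <- map_to_fourier(m1); t2 <- map_to_fourier(m2)
  f1 <- local_variance_field(t1, t2)
  t1c <- t1; t1c$f <- 3 * t1$f
  t2c <- t2; t2c$f <- 3 * t2$f
  f2 <- local_variance_field(t1c, t2c)
  expect_equal(f2$sigma_s_loc, 9 * f1$sigma_s_loc, tolerance = 1e-10)
  expect_equal(f2$sigma_e, 9 * f1$sigma_e, tolerance = 1e-10)
  expect_equal(f2$cc, f1$cc, tolerance = 1e-10)
})
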