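test_that("expected rotation LLG is quartic at small argument", {
  expect_equal(ellg_rot_term(0), 0)
  r <- ellg_rot_term(0.02) / ellg_rot_term(0.01)
  expect_lt(abs(r - 16) / 16, 0.001)
})

test_that("expected translation LLG has its closed form and Monte-Carlo check", {
  expect_equal(ellg_tra_term(0), 0)
  expect_equal(ellg_tra_term(0.6, 0.5), -log(1 - 0.09), tolerance = 1e-12)
  # Monte-Carlo: average realized LLG when the model is drawn from the
  # conditional given the data equals the closed form
  x <- 0.55
  set.seed(19)
  n <- 4e5
  ec <- rcnorm(n)
  em <- x * ec + rcnorm(n, 1 - x^2)
  vals <- llg_term(Mod(em), Mod(ec), Arg(em) - Arg(ec),
                   d_obs = rep(x, n), sigma_a = 1)
  mc_se <- stats::sd(vals) / sqrt(n)
  expect_lt(abs(mean(vals) - ellg_tra_term(x)), 3 * mc_se)
})

test_that("rotation eLLG matches a Monte-Carlo estimate of the amplitude target", {
  x <- 0.6
  set.seed(23)
  n <- 4e5
  ec <- rcnorm(n)
  em <- x * ec + rcnorm(n, 1 - x^2)
  E <- Mod(em); Ec <- Mod(ec)
  v <- 1 - x^2
  z <- 2 * x * E * Ec / v
  vals <- -log(v) - (E^2 + x^2 * Ec^2) / v + E^2 +
    log(besselI(z, 0, expon.scaled = TRUE)) + z
  mc_se <- stats::sd(vals) / sqrt(n)
  expect_lt(abs(mean(vals) - ellg_rot_term(x)), 3 * mc_se)
})

test_that("volume trade-off: rotation eLLG halves, translation eLLG holds", {
  set.seed(29)
  d <- runif(2000, 0.001, 0.02)
  f1 <- 0.01
  tot_rot_1 <- sum(ellg_rot_term(d, sqrt(f1)))
  tot_tra_1 <- sum(ellg_tra_term(d, sqrt(f1)))
  # doubling the subvolume: completeness halves, term count doubles
  d2 <- c(d, d)
  tot_rot_2 <- sum(ellg_rot_term(d2, sqrt(f1 / 2)))
  tot_tra_2 <- sum(ellg_tra_term(d2, sqrt(f1 / 2)))
  expect_equal(tot_rot_2 / tot_rot_1, 0.5, tolerance = 1e-3)
  expect_equal(tot_tra_2 / tot_tra_1, 1, tolerance = 1e-3)
})

test_that("information gain identities hold", {
  expect_equal(dkl_term(0)$bits, 0)
  d <- seq(0, 0.99, by = 0.01)
  dk <- dkl_term(d)
  expect_equal(dk$nats, ellg_tra_term(d, 1), tolerance = 1e-14)
  expect_equal(dk$bits, dk$nats / log(2), tolerance = 1e-14)
  expect_warning(dkl_term(1), "infinite")
  # 2D quadrature of the per-term KL integral over the complex plane,
  # for a representative coefficient with |E_mean| = 1
  dd <- 0.7
  g <- seq(-6, 6, by = 0.01)
  v <- 1 - dd^2
  re <- outer(g, rep(1, length(g))); im <- t(re)
  post <- exp(-((re - dd)^2 + im^2) / v) / (pi * v)
  prior <- exp(-(re^2 + im^2)) / pi
  kl <- sum(post * log(post / prior)) * 0.01^2
  expect_equal(kl, -log(1 - dd^2), tolerance = 1e-4)
})

test_that("Fourier shell information matches the per-term form", {
  expect_equal(fsi_shell(0, 10), 0)
  fscs <- seq(0.1, 0.9, by = 0.1)
  lhs <- fsi_shell(fscs, 7)
  rhs <- 7 * dkl_term(dobs_from_fsc(fscs))$bits
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  expect_equal(fsi_shell(0.5, 10), 2 * fsi_shell(0.5, 5))
  # round trip of the half-map FSC / D_obs mapping
  expect_equal(fsc_from_dobs(dobs_from_fsc(fscs)), fscs, tolerance = 1e-12)
  expect_error(fsi_shell(1, 5), "fsc")
})

test_that("translation eLLG dominates rotation eLLG everywhere", {
  g <- c(seq(0.001, 0.999, by = 0.001), 1 - 10^-seq(4, 9))
  rot <- ellg_rot_term(g)
  tra <- ellg_tra_term(g)
  expect_true(all(rot >= 0))
  expect_true(all(tra >= rot))
  expect_true(all(diff(ellg_rot_term(seq(0, 0.99, by = 0.01))) > 0))
  expect_true(all(diff(dkl_term(seq(0, 0.99, by = 0.01))$bits) > 0))
})

test_that("information filter reproduces a brute-force cut", {
  fx <- default_prepared()
  d <- fx$terms$d_obs
  fl <- filter_by_information(fx$terms, d, threshold_bits = 0.01)
  brute <- which(-log1p(-pmin(d, 1 - 1e-9)^2) / log(2) >= 0.01)
  expect_equal(fl$kept, brute)
  expect_equal(nrow(fl$terms) + fl$n_dropped, nrow(fx$terms))
  # degenerate cases
  fl0 <- filter_by_information(fx$terms, rep(0, nrow(fx$terms)))
  expect_equal(nrow(fl0$terms), 0)
  fl1 <- filter_by_information(fx$terms, rep(0.9, nrow(fx$terms)))
  expect_equal(nrow(fl1$terms), nrow(fx$terms))
  # correction factor shifts the effective threshold
  fl2 <- filter_by_information(fx$terms, d, threshold_bits = 0.01,
                               factor = 0.5)
  fl3 <- filter_by_information(fx$terms, d, threshold_bits = 0.02)
  expect_equal(fl2$kept, fl3$kept)
})

test_that("realized LLG at the true model matches the expected LLG", {
  # synthetic Fourier data with known per-term quality: over replicates,
  # the realized total LLG at sigma_A = 1 fluctuates around the eLLG total
  set.seed(37)
  n <- 20000
  d <- runif(n, 0.05, 0.9)
  etot <- sum(ellg_tra_term(d))
  reps <- sapply(1:20, function(i) {
    ec <- rcnorm(n)
    em <- d * ec + rcnorm(n, 1 - d^2)
    sum(llg_term(Mod(em), Mod(ec), Arg(em) - Arg(ec), d, 1))
  })
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - etot), 3 * se)
})

test_that("info report aggregates shells and totals coherently", {
  fx <- default_prepared()
  ir <- info_report(fx$terms, factor = 0.5)
  expect_equal(sum(tidy(ir)$bits), glance(ir)$bits, tolerance = 1e-9)
  expect_true(all(tidy(ir)$ellg_tra >= tidy(ir)$ellg_rot))
  expect_equal(glance(ir)$factor, 0.5)
  # all reported quantities non-negative
  expect_true(all(as.matrix(tidy(ir)[, c("ellg_rot", "ellg_tra", "bits")]) >= 0))
})
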