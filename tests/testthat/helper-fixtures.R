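# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# complex-normal draws with variance v (per complex value)
rcnorm <- function(n, v = 1) {
  complex(real = stats::rnorm(n, 0, sqrt(v / 2)),
          imaginary = stats::rnorm(n, 0, sqrt(v / 2)))
}

# The default study fixture: 64^3 half-map pair with anisotropic signal and
# directional noise, plus its prepared analysis.
default_fixture <- function() {
  fixture("default64", function() {
    spec <- synthetic_spec()
    tm <- generate_true_map(spec)
    hm <- simulate_half_maps(tm, spec)
    list(spec = spec, tm = tm, hm = hm)
  })
}

default_prepared <- function() {
  fixture("default64_prep", function() {
    fx <- default_fixture()
    suppressWarnings(prepare_halfmaps(fx$hm$half1, fx$hm$half2))
  })
}

# Signal-dominated docking fixture: milder anisotropy (so the isotropic
# model-error family nearly contains the truth) and low noise; 48^3 for
# speed. The true orientation/translation are off-grid on purpose.
dock_fixture <- function() {
  fixture("dock48", function() {
    spec <- synthetic_spec(n_grid = 48, voxel = 1.2, n_atoms = 200,
                           cluster_radius = 14, beta = diag(c(20, 30, 40)),
                           noise_scale = 0.3, seed = 11)
    tm <- generate_true_map(spec)
    hm <- simulate_half_maps(tm, spec)
    prep <- suppressWarnings(prepare_halfmaps(hm$half1, hm$half2))
    fl <- filter_by_information(prep$terms, prep$terms$d_obs)
    list(spec = spec, tm = tm, hm = hm, prep = prep, data = fl$terms,
         coords = tm$truth$atoms)
  })
}

# truth-aligned rows of a prepared term table
match_truth <- function(prep_terms, truth_terms) {
  match(paste(prep_terms$h, prep_terms$k, prep_terms$l),
        paste(truth_terms$h, truth_terms$k, truth_terms$l))
}

# overall rotation angle (degrees) of a rotation matrix
rotation_angle_deg <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
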