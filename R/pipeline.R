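#' Run configuration
#'
#' Validated bundle of inputs and options for the command-level pipelines.
#' The configuration (with a hash) is embedded in every report for
#' provenance, so a run can be reproduced exactly.
#'
#' @param halfmap1,halfmap2 paths to the two half-maps (MRC), or
#'   [map_grid()] objects.
#' @param model path to a PDB/mmCIF model, or an atom tibble (for docking).
#' @param sphere_centre,sphere_radius optional subvolume sphere (A).
#' @param resolution high-resolution limit (A) or `NULL`.
#' @param bins resolution bins for signal refinement.
#' @param threshold_bits information filter threshold (bits).
#' @param step_deg orientation grid step for the rotation search (degrees).
#' @param n_orientations number of top orientations carried into the
#'   translation search.
#' @param seed integer seed for any stochastic step.
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   file output.
#' @return A validated list of class `cryodock_config`.
#' @export
cryodock_config <- function(halfmap1, halfmap2, model = NULL,
                            sphere_centre = NULL, sphere_radius = NULL,
                            resolution = NULL, bins = 40,
                            threshold_bits = 0.01, step_deg = 24,
                            n_orientations = 5, seed = 1, out_dir = NULL) {
  for (p in list(halfmap1, halfmap2)) {
    if (is.character(p) && !file.exists(p))
      stop("half-map file not found: ", p)
  }
  if (is.character(model) && !file.exists(model))
    stop("model file not found: ", model)
  if (!is.null(resolution) && resolution <= 0) stop("invalid resolution")
  if (threshold_bits < 0) stop("invalid information threshold")
  if (step_deg <= 0 || step_deg > 60) stop("step_deg must be in (0, 60]")
  cfg <- list(halfmap1 = halfmap1, halfmap2 = halfmap2, model = model,
              sphere_centre = sphere_centre, sphere_radius = sphere_radius,
              resolution = resolution, bins = bins,
              threshold_bits = threshold_bits, step_deg = step_deg,
              n_orientations = n_orientations, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "cryodock_config"
  cfg
}

config_fingerprint <- function(cfg) {
  slim <- cfg[!names(cfg) %in% "out_dir"]
  slim <- lapply(slim, function(x) if (inherits(x, "map_grid"))
    list(dim = dim(x$values), voxel = x$voxel, sum = sum(x$values)) else x)
  rlang::hash(slim)
}

report_header <- function(cfg) {
  list(
    package = "cryodock",
    version = as.character(utils::packageVersion("cryodock")),
    config_hash = config_fingerprint(cfg),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
}

#' Prepare half-maps and write an analysis report
#'
#' Command-level wrapper around [prepare_halfmaps()]: runs the full error
#' analysis, writes the two docking coefficient sets (as MRC maps and as
#' tabular text), per-shell and per-axis profiles of signal and noise
#' power, and a JSON report embedding the configuration hash.
#'
#' @param cfg a [cryodock_config()].
#' @return The `cryodock_prepared` object, invisibly, with the report under
#'   `$report`.
#' @export
run_prepare <- function(cfg) {
  prep <- prepare_halfmaps(
    cfg$halfmap1, cfg$halfmap2, resolution = cfg$resolution,
    sphere_centre = cfg$sphere_centre, sphere_radius = cfg$sphere_radius,
    bins = cfg$bins
  )
  co <- prepared_coefficients(prep)
  report <- c(report_header(cfg), list(
    n_terms = nrow(prep$terms),
    d_min = 1 / max(prep$terms$s),
    oversampling = prep$oversampling,
    mean_d_obs = mean(prep$terms$d_obs),
    shells = prep$shells,
    axis_profiles = prep$axes,
    signal_model = list(
      a0 = prep$signal_model$a0,
      beta = prep$signal_model$beta,
      log_multipliers = prep$signal_model$bins$log_mult
    ),
    warnings = prep$warnings
  ))
  prep$report <- report
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "prepare_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_map(fourier_to_map(co$centroid),
              file.path(cfg$out_dir, "map_centroid.mrc"))
    write_map(fourier_to_map(co$likelihood),
              file.path(cfg$out_dir, "map_likelihood.mrc"))
    write_terms_table(co$centroid,
                      file.path(cfg$out_dir, "coefficients_centroid.tsv"))
    write_terms_table(co$likelihood,
                      file.path(cfg$out_dir, "coefficients_likelihood.tsv"))
    utils::write.table(prep$shells, file.path(cfg$out_dir, "shells.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(prep$axes, file.path(cfg$out_dir, "axis_profiles.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(prep)
}

#' Write placed model coordinates as PDB
#'
#' @param coords n x 3 coordinate matrix (A).
#' @param path output path.
#' @param elem element symbols (recycled).
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(coords, path, elem = "C") {
  n <- nrow(coords)
  bio3d::write.pdb(
    file = path, xyz = as.vector(t(coords)),
    resno = seq_len(n), resid = rep("GLY", n),
    elety = rep("CA", n), chain = rep("A", n),
    o = rep(1, n), b = rep(0, n), elesy = rep(elem, length.out = n)
  )
  invisible(path)
}

#' Dock a model into prepared half-map data
#'
#' Full docking pipeline: information filter, amplitude-only rotation
#' search on a quasi-uniform orientation grid, exact FFT translation search
#' for the top orientations, then rigid-body refinement (rotation,
#' translation, model error `delta` and cell scale) from the best
#' candidates. Reports the final pose, its LLG, and the expected-LLG and
#' information totals used to judge the search.
#'
#' @param cfg a [cryodock_config()] with a `model`.
#' @param prepared optionally a precomputed `cryodock_prepared` (skips the
#'   error analysis).
#' @return List of class `cryodock_dock`: `pose`, `orientation` (3x3
#'   pre-rotation applied before the pose), `coords` (placed model), `llg`,
#'   `delta`, `report`.
#' @export
run_dock <- function(cfg, prepared = NULL) {
  if (is.null(cfg$model)) stop("docking requires a model")
  if (is.null(prepared)) prepared <- run_prepare(cfg)
  model <- if (is.character(cfg$model)) read_model(cfg$model) else cfg$model
  coords <- if (is.matrix(model)) model else cbind(model$x, model$y, model$z)
  over <- prepared$oversampling$factor
  fl <- filter_by_information(prepared$terms, prepared$terms$d_obs,
                              threshold_bits = cfg$threshold_bits,
                              factor = over)
  data <- fl$terms
  if (nrow(data) < 100)
    stop("fewer than 100 informative Fourier terms after filtering; ",
         "no docking search is possible")
  info <- info_report(data, factor = over)
  grid <- orientation_grid(cfg$step_deg)
  rs <- rotation_score(data, coords, grid, delta = 1, factor = over)
  top <- utils::head(rs, cfg$n_orientations)
  com <- colMeans(coords)
  cands <- purrr::map(top$orientation, function(oi) {
    rot <- sweep(sweep(coords, 2, com) %*% t(grid[[oi]]), 2, com, "+")
    mf <- model_to_efc(rot, data)
    ts <- translation_search_fft(data, mf, delta = 1, factor = over)
    list(orientation = oi, shift = c(ts$best$tx, ts$best$ty, ts$best$tz),
         llg = ts$best$llg)
  })
  ord <- order(-purrr::map_dbl(cands, "llg"))
  best <- NULL
  n_refine <- min(3, length(cands))
  for (ci in ord[seq_len(n_refine)]) {
    cand <- cands[[ci]]
    rot <- sweep(sweep(coords, 2, com) %*% t(grid[[cand$orientation]]),
                 2, com, "+")
    rp <- refine_pose(data, rot, pose0 = pose(shift = cand$shift),
                      delta0 = 1, factor = over)
    if (is.null(best) || rp$llg > best$rp$llg)
      best <- list(cand = cand, rp = rp, rot_coords = rot)
  }
  rp <- best$rp
  placed <- apply_pose(best$rot_coords, rp$pose, com)
  # null calibration: is the score plausibly above noise?
  null_sd <- sqrt(2 * info$totals$ellg_tra)
  solved <- rp$llg > 3 * null_sd
  report <- c(report_header(cfg), list(
    n_terms_used = nrow(data), n_filtered = fl$n_dropped,
    discarded_bits = fl$discarded_bits,
    information_bits = info$totals$bits,
    ellg_rot = info$totals$ellg_rot, ellg_tra = info$totals$ellg_tra,
    rotation_top = utils::head(rs, 10),
    llg = rp$llg, delta = rp$delta, cell_scale = rp$pose$scale,
    pose_angles = rp$pose$angles, pose_shift = rp$pose$shift,
    orientation_index = best$cand$orientation,
    llg_null_threshold = 3 * null_sd, solved = solved
  ))
  out <- structure(
    list(pose = rp$pose, orientation = grid[[best$cand$orientation]],
         coords = placed, llg = rp$llg, delta = rp$delta,
         solved = solved, report = report, rotation_scores = rs,
         prepared = prepared),
    class = "cryodock_dock"
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "dock_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_model_pdb(placed, file.path(cfg$out_dir, "placed_model.pdb"))
  }
  out
}

#' @export
print.cryodock_dock <- function(x, ...) {
  cat(sprintf("<cryodock_dock> LLG %.1f (delta %.2f A, cell scale %.4f)%s\n",
              x$llg, x$delta, x$pose$scale,
              if (x$solved) "" else "  [below noise threshold]"))
  print(x$pose)
  invisible(x)
}

#' Simulate a synthetic half-map fixture to files
#'
#' Generates the default-style synthetic half-map pair and writes the two
#' MRC half-maps, the atom model as PDB, and the ground truth (per-shell)
#' as JSON.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory.
#' @return List with file paths, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tm <- generate_true_map(spec)
  hm <- simulate_half_maps(tm, spec)
  p1 <- file.path(out_dir, "half1.mrc")
  p2 <- file.path(out_dir, "half2.mrc")
  pm <- file.path(out_dir, "model.pdb")
  pj <- file.path(out_dir, "ground_truth.json")
  write_map(hm$half1, p1)
  write_map(hm$half2, p2)
  write_model_pdb(tm$truth$atoms, pm)
  tt <- hm$truth$terms
  bid <- resolution_bins(tt$s, 10)
  gt <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      bin = bid, s = tt$s, sigma_s = hm$truth$sigma_s,
      sigma_e = hm$truth$sigma_e, d_obs = hm$truth$d_obs), .data$bin),
    s_min = min(.data$s), s_max = max(.data$s),
    sigma_s = mean(.data$sigma_s), sigma_e = mean(.data$sigma_e),
    d_obs = mean(.data$d_obs), .groups = "drop")
  jsonlite::write_json(
    list(seed = spec$seed, n_grid = spec$n_grid, voxel = spec$voxel,
         n_atoms = spec$n_atoms, beta = spec$beta,
         noise_scale = spec$noise_scale, shells = gt),
    pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(half1 = p1, half2 = p2, model = pm, truth = pj))
}
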