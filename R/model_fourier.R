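#' Model quality sigma_A
#'
#' Complex correlation between normalised model and true coefficients,
#' combining model completeness `f` (the fraction of the ordered scattering
#' accounted for by the model) with coordinate error. Assuming the errors of
#' all atoms are drawn from one 3D Gaussian with r.m.s. radial magnitude
#' `delta` (A), the phase-scrambling factor is the characteristic function
#' of that Gaussian, giving
#' `sigma_A = sqrt(f) * exp(-2 pi^2 delta^2 s^2 / 3)`:
#' `sqrt(f)` at `delta = 0`, log-linear in `s^2` with slope proportional to
#' `-delta^2` otherwise.
#'
#' @param f completeness fraction in (0, 1].
#' @param delta r.m.s. radial coordinate error (A), >= 0.
#' @param s inverse resolution (1/A), vectorised.
#' @return `sigma_A` values in (0, 1].
#' @export
sigma_a <- function(f, delta, s) {
  stopifnot(f > 0, f <= 1, delta >= 0)
  sqrt(f) * exp(-2 * pi^2 * delta^2 * s^2 / 3)
}

#' Read an atomic model
#'
#' Reads a PDB or mmCIF file and returns an atom tibble with coordinates in
#' angstroms, occupancies and element symbols.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @return Tibble with columns `x`, `y`, `z`, `occ`, `elem`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("cannot read model file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
  else bio3d::read.pdb(path)
  at <- pdb$atom
  occ <- at$o
  occ[is.na(occ)] <- 1
  tibble::tibble(x = at$x, y = at$y, z = at$z, occ = occ,
                 elem = ifelse(is.na(at$elesy) | at$elesy == "",
                               substr(trimws(at$elety), 1, 1), at$elesy))
}

#' Rigid-body pose
#'
#' A pose is parameterised for well-behaved refinement: three sequential
#' perturbation rotations about orthogonal x, y and z axes through the
#' model's centre of mass (degrees), a translation (A) and a cell scale
#' factor applied to coordinates about the centre of mass, which absorbs
#' voxel-size error in the map. Rotating about the centre of mass keeps the
#' rotation and translation parameters close to orthogonal near an optimum.
#'
#' @param angles rotation perturbations about x, y, z (degrees).
#' @param shift translation (A).
#' @param scale cell scale factor (default 1; bounds `[0.9, 1.1]` are
#'   enforced during refinement).
#' @return An object of class `cryodock_pose`.
#' @export
pose <- function(angles = c(0, 0, 0), shift = c(0, 0, 0), scale = 1) {
  stopifnot(length(angles) == 3, length(shift) == 3, length(scale) == 1)
  structure(list(angles = as.numeric(angles), shift = as.numeric(shift),
                 scale = as.numeric(scale)),
            class = "cryodock_pose")
}

#' @export
print.cryodock_pose <- function(x, ...) {
  cat(sprintf("<pose> angles (deg): %.3f %.3f %.3f; shift (A): %.3f %.3f %.3f; scale %.5f\n",
              x$angles[1], x$angles[2], x$angles[3],
              x$shift[1], x$shift[2], x$shift[3], x$scale))
  invisible(x)
}

#' Rotation matrix of sequential x, y, z rotations
#'
#' @param angles rotations about x, then y, then z, in degrees.
#' @return 3x3 rotation matrix (applied to column coordinate vectors).
#' @export
rotation_xyz <- function(angles) {
  a <- angles * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# Apply a pose to coordinates (n x 3 matrix) about the given centre of mass.
apply_pose <- function(coords, p, com) {
  rel <- sweep(coords, 2, com)
  rot <- rel %*% t(rotation_xyz(p$angles))
  sweep(rot * p$scale, 2, com + p$shift, "+")
}

#' Normalised model Fourier coefficients for a posed model
#'
#' Synthesises a Gaussian-atom density for the model under the given pose
#' (rotation about the centre of mass, then cell scaling about the centre
#' of mass) on the grid of the supplied term set, transforms it, and
#' applies the translation analytically as a Fourier-space phase shift
#' (exact, and free of resampling error). Coefficients are extracted at the
#' term set's hkl indices and normalised so shell means of `|E_C|^2` are
#' one.
#'
#' @param model atom tibble from [read_model()] (columns `x`, `y`, `z`,
#'   optionally `occ`), or an n x 3 coordinate matrix.
#' @param terms a [fourier_terms] tibble defining grid, box and hkl layout.
#' @param p a [pose()].
#' @param width Gaussian atom width (A).
#' @param bins resolution bins used for normalisation.
#' @param com centre of mass used for the rotation; defaults to the mean
#'   atom position before posing.
#' @return A tibble `h, k, l, s, e_c` (complex normalised coefficients)
#'   with attributes `com` and `pose`.
#' @export
model_to_efc <- function(model, terms, p = pose(), width = 1.5, bins = 40,
                         com = NULL) {
  a <- ft_attrs(terms)
  coords <- if (is.matrix(model)) model else cbind(model$x, model$y, model$z)
  occ <- if (!is.matrix(model) && !is.null(model$occ)) model$occ
  else rep(1, nrow(coords))
  if (is.null(com)) com <- colMeans(coords)
  rel <- sweep(coords, 2, com)
  rot <- rel %*% t(rotation_xyz(p$angles)) * p$scale
  placed <- sweep(rot, 2, com, "+")  # translation handled in Fourier space
  box <- a$cell
  # the translation is a Fourier-space phase shift and therefore periodic;
  # only the synthesised (rotated/scaled) coordinates must stay in the box
  lo <- (a$origin) * a$voxel
  if (any(sweep(placed, 2, lo) < 0) || any(sweep(placed, 2, lo + box) > 0))
    stop("model atoms fall outside the box after posing")
  dens <- gaussian_density(placed, a$ngrid, a$voxel, width,
                           origin = a$origin, weights = occ)
  F <- stats::fft(dens)
  fc <- as.vector(F)[ft_index(terms)]
  phase <- exp(-2i * pi * (terms$h * p$shift[1] / box[1] +
                             terms$k * p$shift[2] / box[2] +
                             terms$l * p$shift[3] / box[3]))
  fc <- fc * phase
  if ("denom" %in% names(terms)) {
    # prepared data supply their effective per-term normaliser; dividing
    # the model by the same field cancels its speckle-tracking structure
    # term by term (the local signal estimates follow the realised
    # spectrum of the very structure being modelled), leaving only a
    # smooth residual handled by the unit rescale below
    fc <- fc / terms[["denom"]]
  }
  # smooth ripple-free normaliser giving |E_C|^2 unit local mean
  norm <- smooth_shell_scale(terms$s, Mod(fc)^2, bins = bins)
  norm[!is.finite(norm) | norm <= 0] <- Inf  # zero-power data give E_C = 0
  out <- tibble::tibble(h = terms$h, k = terms$k, l = terms$l,
                        s = terms$s, e_c = fc / norm)
  attr(out, "com") <- com
  attr(out, "pose") <- p
  out
}
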