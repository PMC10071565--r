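#' Map grid container
#'
#' A `map_grid` holds real voxel values on a 3D grid together with the
#' geometry needed to interpret them: the cubic voxel size in angstroms and
#' the origin offset (in voxels) of the first stored voxel relative to the
#' coordinate frame of the full reconstruction. The box is treated as a P1
#' cell with orthogonal axes; voxel `[1,1,1]` sits at `origin * voxel`
#' angstroms.
#'
#' @param values numeric 3D array of voxel values (x fastest, as stored).
#' @param voxel voxel size in angstroms (cubic; a single positive number).
#' @param origin origin offset in voxels (length-3 numeric, may be fractional).
#' @return An object of class `map_grid`.
#' @export
map_grid <- function(values, voxel, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!is.numeric(voxel) || length(voxel) != 1 || !is.finite(voxel) || voxel <= 0)
    stop("voxel size must be a single positive number")
  if (any(dim(values) < 2)) stop("grid dimensions must be >= 2 per axis")
  if (!all(is.finite(values))) stop("map values must be finite")
  structure(
    list(values = values, voxel = voxel, origin = as.numeric(origin)),
    class = "map_grid"
  )
}

#' @export
print.map_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<map_grid> %d x %d x %d voxels, %.4g A/voxel (box %.4g x %.4g x %.4g A)\n",
    d[1], d[2], d[3], x$voxel, d[1] * x$voxel, d[2] * x$voxel, d[3] * x$voxel
  ))
  cat(sprintf("  origin (voxels): %g %g %g; value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Box edge lengths of a map in angstroms
#' @param map a `map_grid`.
#' @return numeric length-3 vector of box edges (A).
#' @export
map_cell <- function(map) dim(map$values) * map$voxel

#' Read an MRC/CCP4 map
#'
#' Reads a mode-2 (32-bit float) MRC/CCP4 map file. Values are taken as
#' stored: no filtering, masking or rescaling is applied, since the error
#' model requires unfiltered, unmasked half-maps. Maps with anisotropic
#' voxel sizes are rejected (resampling would silently change the error
#' model); a non-cubic box only triggers a warning. Axis order must be the
#' standard x-fastest (MAPC,MAPR,MAPS = 1,2,3).
#'
#' @param path path to the map file.
#' @return A [map_grid()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("cannot read map file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_flt <- readBin(con, "double", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  if (any(nxyz <= 0) || any(nxyz > 4096) || !(mode %in% c(0, 1, 2)))
    stop("not a readable MRC map (unsupported header or big-endian file): ", path)
  if (mode != 2) stop("only mode 2 (float) MRC maps are supported")
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_flt[11:13]
  mapcrs <- hdr_int[17:19]
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("only x-fastest axis order (MAPC,MAPR,MAPS = 1,2,3) is supported")
  nsymbt <- hdr_int[24]
  origin_ang <- hdr_flt[50:52]
  vox <- cella / mxyz
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop("invalid cell/sampling in MRC header")
  if (diff(range(vox)) > 1e-4 * mean(vox))
    stop("anisotropic voxel sizes are not supported (map would need resampling)")
  if (length(unique(nxyz)) > 1)
    warning("map box is not cubic (", paste(nxyz, collapse = " x "), " voxels)")
  seek(con, 1024 + nsymbt)
  n <- prod(nxyz)
  vals <- readBin(con, "double", n = n, size = 4, endian = "little")
  if (length(vals) < n) stop("map file truncated: ", path)
  voxel <- mean(vox)
  origin <- nstart + origin_ang / voxel
  map_grid(array(vals, dim = nxyz), voxel = voxel, origin = origin)
}

#' Write an MRC/CCP4 map (mode 2)
#'
#' @param map a [map_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "map_grid"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  vals <- as.vector(map$values)
  wi(d)                          # NX NY NZ
  wi(2)                          # MODE
  wi(round(map$origin))          # NXSTART..NZSTART
  wi(d)                          # MX MY MZ
  wf(d * map$voxel)              # CELLA
  wf(c(90, 90, 90))              # CELLB
  wi(c(1, 2, 3))                 # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))  # DMIN DMAX DMEAN
  wi(1)                          # ISPG
  wi(0)                          # NSYMBT
  wi(rep(0L, 25))                # EXTRA (words 25..49)
  wf((map$origin - round(map$origin)) * map$voxel)  # ORIGIN (A), words 50..52
  writeChar("MAP ", con, nchars = 4, eos = NULL)    # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(vals))            # RMS
  wi(0)                          # NLABL
  writeBin(raw(800), con)        # labels
  wf(vals)
  invisible(path)
}

#' Extract a soft-edged spherical subvolume
#'
#' Cuts a cubic box just enclosing a sphere (plus padding) out of a larger
#' map and applies a cosine taper to zero at the sphere surface, so that the
#' subvolume spectrum is not contaminated by a hard edge. If the sphere
#' covers the whole box (every corner inside the sphere) the map is returned
#' unchanged.
#'
#' @param map a [map_grid()].
#' @param centre sphere centre in angstroms (length 3), in the map frame
#'   (i.e. including the origin offset).
#' @param radius sphere radius in angstroms.
#' @param pad padding in voxels added around the sphere (default 2).
#' @param taper cosine taper width in voxels (default 3); the taper runs
#'   inward from the sphere surface.
#' @return A [map_grid()] holding the tapered subvolume, with its origin set
#'   so coordinates remain consistent with the parent map.
#' @export
extract_sphere <- function(map, centre, radius, pad = 2, taper = 3) {
  stopifnot(inherits(map, "map_grid"), length(centre) == 3, radius > 0)
  d <- dim(map$values)
  vx <- map$voxel
  # voxel-centre coordinates (A) along each axis in the parent frame
  ax <- lapply(1:3, function(i) (map$origin[i] + seq_len(d[i]) - 1) * vx)
  corners <- as.matrix(expand.grid(
    ax[[1]][c(1, d[1])], ax[[2]][c(1, d[2])], ax[[3]][c(1, d[3])]
  ))
  if (all(sqrt(colSums((t(corners) - centre)^2)) <= radius)) {
    return(map)  # sphere covers the whole box: identity
  }
  half <- ceiling(radius / vx) + pad
  ic <- round(centre / vx - map$origin) + 1  # nearest voxel index of centre
  lo <- ic - half
  hi <- ic + half
  if (any(lo < 1) || any(hi > d))
    stop("sphere (plus padding) extends outside the map box")
  sub <- map$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  nd <- dim(sub)
  new_origin <- map$origin + (lo - 1)
  gx <- (new_origin[1] + seq_len(nd[1]) - 1) * vx - centre[1]
  gy <- (new_origin[2] + seq_len(nd[2]) - 1) * vx - centre[2]
  gz <- (new_origin[3] + seq_len(nd[3]) - 1) * vx - centre[3]
  r <- sqrt(outer(outer(gx^2, gy^2, "+"), gz^2, "+"))
  tw <- taper * vx
  w <- ifelse(r <= radius - tw, 1,
              ifelse(r >= radius, 0, 0.5 * (1 + cos(pi * (r - (radius - tw)) / tw))))
  map_grid(sub * w, voxel = vx, origin = new_origin)
}

#' Oversampling correction factor
#'
#' The Fourier transform of a reconstruction computed in a box much larger
#' than the particle is oversampled, so neighbouring Fourier terms are
#' correlated. Total log-likelihood gains, expected LLGs and information
#' sums are corrected by the ratio of the volume required to contain the
#' ordered particle to the volume of the box.
#'
#' @param ordered_volume volume of the ordered region (A^3).
#' @param box_volume volume of the reconstruction box (A^3).
#' @return The correction factor in (0, 1].
#' @export
oversampling_factor <- function(ordered_volume, box_volume) {
  if (!(ordered_volume > 0)) stop("ordered_volume must be positive")
  if (ordered_volume > box_volume)
    stop("ordered_volume exceeds box_volume")
  ordered_volume / box_volume
}
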