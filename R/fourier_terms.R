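#' Fourier term sets
#'
#' A Fourier term set is a tibble with one row per Fourier term of a map:
#' integer Miller-style indices `h`, `k`, `l` (cycles per box edge), the
#' complex coefficient `f` and the inverse resolution `s = |h*|` in 1/A.
#' Only one member of each Friedel pair is stored (Hermitian half); the
#' geometry of the parent grid travels along as attributes (`cell`, `ngrid`,
#' `voxel`, `origin`).
#'
#' The forward transform convention is `F(h) = sum_x rho(x) exp(-2 pi i h.x)`
#' with `x` fractional in the box, i.e. base R's [stats::fft()] applied to
#' the voxel array. Phases therefore refer to the first stored voxel; the
#' map origin offset is honoured when converting model coordinates to
#' fractional coordinates.
#'
#' @name fourier_terms
NULL

ft_attrs <- function(terms) {
  attrs <- attributes(terms)
  attrs[c("cell", "ngrid", "voxel", "origin", "hermitian")]
}

set_ft_attrs <- function(x, attrs) {
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- unique(c("fourier_terms", class(x)))
  x
}

#' Construct a Fourier term set from a tibble
#'
#' @param tbl tibble with integer columns `h`, `k`, `l`, complex column `f`
#'   and numeric column `s`.
#' @param cell box edge lengths (A), length 3.
#' @param ngrid grid sampling per axis (voxels), length 3.
#' @param voxel voxel size (A).
#' @param origin origin offset in voxels.
#' @return The tibble with class `fourier_terms` and grid attributes set.
#' @export
as_fourier_terms <- function(tbl, cell, ngrid, voxel = cell[1] / ngrid[1],
                             origin = c(0, 0, 0)) {
  stopifnot(all(c("h", "k", "l", "f", "s") %in% names(tbl)))
  if (anyDuplicated(tbl[, c("h", "k", "l")]) > 0)
    stop("duplicate hkl indices in term set")
  set_ft_attrs(tibble::as_tibble(tbl),
               list(cell = as.numeric(cell), ngrid = as.integer(ngrid),
                    voxel = voxel, origin = as.numeric(origin),
                    hermitian = TRUE))
}

#' Fourier transform of a map
#'
#' Computes the discrete Fourier transform of a map and returns the
#' Hermitian-half set of terms, optionally cut at a resolution limit. With
#' `resolution = NULL` every term is kept (including self-conjugate Nyquist
#' terms) and the transform is exactly invertible by [fourier_to_map()].
#'
#' @param map a [map_grid()].
#' @param resolution high-resolution limit in angstroms, or `NULL` for no
#'   cut. Must be at least twice the voxel size (Nyquist).
#' @return A [fourier_terms] tibble.
#' @export
map_to_fourier <- function(map, resolution = NULL) {
  stopifnot(inherits(map, "map_grid"))
  d <- dim(map$values)
  cell <- d * map$voxel
  if (!is.null(resolution) && resolution < 2 * map$voxel)
    stop("resolution limit is beyond Nyquist (2 x voxel size)")
  F <- stats::fft(map$values)
  n1 <- rep(0:(d[1] - 1), times = d[2] * d[3])
  n2 <- rep(rep(0:(d[2] - 1), each = d[1]), times = d[3])
  n3 <- rep(0:(d[3] - 1), each = d[1] * d[2])
  m1 <- (d[1] - n1) %% d[1]
  m2 <- (d[2] - n2) %% d[2]
  m3 <- (d[3] - n3) %% d[3]
  keep <- (n3 < m3) | (n3 == m3 & (n2 < m2 | (n2 == m2 & n1 <= m1)))
  h <- n1 - d[1] * (n1 >= d[1] / 2)
  k <- n2 - d[2] * (n2 >= d[2] / 2)
  l <- n3 - d[3] * (n3 >= d[3] / 2)
  s <- sqrt((h / cell[1])^2 + (k / cell[2])^2 + (l / cell[3])^2)
  if (!is.null(resolution)) keep <- keep & (s <= 1 / resolution + 1e-12)
  tbl <- tibble::tibble(
    h = as.integer(h[keep]), k = as.integer(k[keep]), l = as.integer(l[keep]),
    f = as.vector(F)[keep], s = s[keep]
  )
  as_fourier_terms(tbl, cell = cell, ngrid = d, voxel = map$voxel,
                   origin = map$origin)
}

# Scatter a per-term complex vector into the full (Friedel-expanded) 3D
# Fourier array of the parent grid. Self-conjugate terms are forced real.
ft_full_array <- function(terms, values = terms$f) {
  a <- ft_attrs(terms)
  d <- a$ngrid
  arr <- array(complex(real = 0, imaginary = 0), dim = d)
  n1 <- terms$h %% d[1]; n2 <- terms$k %% d[2]; n3 <- terms$l %% d[3]
  m1 <- (d[1] - n1) %% d[1]; m2 <- (d[2] - n2) %% d[2]; m3 <- (d[3] - n3) %% d[3]
  idx <- 1 + n1 + d[1] * (n2 + d[2] * n3)
  midx <- 1 + m1 + d[1] * (m2 + d[2] * m3)
  self <- idx == midx
  arr[midx] <- Conj(values)
  arr[idx] <- values
  if (any(self)) arr[idx[self]] <- complex(real = Re(values[self]), imaginary = 0)
  arr
}

#' Inverse Fourier transform to a map
#'
#' Expands a Hermitian-half term set to the full grid by Friedel symmetry
#' and inverse-transforms it. Terms absent from the set are treated as zero.
#'
#' @param terms a [fourier_terms] tibble.
#' @param values optional complex vector to transform in place of `terms$f`
#'   (one entry per row), e.g. weighted docking coefficients.
#' @return A [map_grid()].
#' @export
fourier_to_map <- function(terms, values = terms$f) {
  a <- ft_attrs(terms)
  arr <- ft_full_array(terms, values)
  vals <- Re(stats::fft(arr, inverse = TRUE)) / prod(a$ngrid)
  map_grid(vals, voxel = a$voxel, origin = a$origin)
}

# Both Friedel mates of each stored term as a plain tibble (h,k,l,f,s).
# The origin term and self-conjugate Nyquist terms (h = -N/2 on the torus)
# appear once.
friedel_expand <- function(terms, cols = "f") {
  d <- ft_attrs(terms)$ngrid
  if (is.null(d)) d <- rep(2L * max(abs(c(terms$h, terms$k, terms$l))) + 2L, 3)
  mates <- terms
  mates$h <- -terms$h; mates$k <- -terms$k; mates$l <- -terms$l
  for (cc in cols) mates[[cc]] <- Conj(mates[[cc]])
  self <- (2 * terms$h) %% d[1] == 0 & (2 * terms$k) %% d[2] == 0 &
    (2 * terms$l) %% d[3] == 0
  dplyr::bind_rows(terms, mates[!self, , drop = FALSE])
}

#' Export a term set as a tabular text file
#'
#' Writes `h k l re im s` columns as tab-separated text for debugging or
#' interchange.
#'
#' @param terms a [fourier_terms] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_terms_table <- function(terms, path) {
  out <- data.frame(h = terms$h, k = terms$k, l = terms$l,
                    re = Re(terms$f), im = Im(terms$f), s = terms$s)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
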