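#' 3D local binary pattern maps
#'
#' For every voxel, intensities are sampled by trilinear interpolation at 42
#' points on a sphere of the given radius (an icosphere: the icosahedron
#' subdivided once), the binary pattern `neighbor > center` is projected on
#' the real spherical-harmonic basis, and the per-level energies form the
#' level-1 and level-2 maps. The third map is the excess kurtosis of the raw
#' (un-binarized) neighbor-minus-center differences; zero-variance
#' neighborhoods map to 0, so a flat field yields a kurtosis map that is
#' identically 0. Volume borders are handled by mirror padding. The filter
#' is invariant to adding a global constant to the image, and the harmonic
#' energies are approximately rotation-invariant.
#'
#' @param image a [ct_volume()], isotropically resampled.
#' @param radius sphere radius in mm (default 1).
#' @return An object of class `ln_lbp_maps`: list with `m1`, `m2`, `k`
#'   ([ct_volume()] maps on the source grid), `radius` and the sampling
#'   direction matrix.
#' @export
lbp3d_maps <- function(image, radius = 1) {
  sp <- image$spacing
  if (radius < min(sp) / 2) {
    rlang::abort("LBP radius smaller than half a voxel.",
                 class = "lnrad_bad_parameter")
  }
  dirs <- icosphere42()
  Y <- sh_basis(dirs)                      # 42 x 8 (l=1: 3 cols, l=2: 5 cols)
  n_s <- nrow(dirs)
  offs <- sweep(dirs * radius, 2, sp, "/") # voxel-unit offsets
  pad <- ceiling(max(abs(offs))) + 1L
  ap <- mirror_pad(image$voxels, pad)
  d <- dim(image$voxels)
  center <- image$voxels
  # accumulate SH coefficients and difference moments across the 42 samples
  c_lm <- vector("list", ncol(Y))
  for (m in seq_len(ncol(Y))) c_lm[[m]] <- array(0, d)
  s1 <- array(0, d); s2 <- array(0, d); s3 <- array(0, d); s4 <- array(0, d)
  for (jdir in seq_len(n_s)) {
    nb <- trilinear_shift(ap, pad, offs[jdir, ], d)
    s <- (nb > center) * 1
    for (m in seq_len(ncol(Y))) c_lm[[m]] <- c_lm[[m]] + s * Y[jdir, m]
    dd <- nb - center
    s1 <- s1 + dd; s2 <- s2 + dd^2; s3 <- s3 + dd^3; s4 <- s4 + dd^4
  }
  w <- 4 * pi / n_s
  m1 <- array(0, d); m2 <- array(0, d)
  for (m in 1:3) m1 <- m1 + (w * c_lm[[m]])^2
  for (m in 4:8) m2 <- m2 + (w * c_lm[[m]])^2
  mu <- s1 / n_s
  v <- s2 / n_s - mu^2
  m4c <- (s4 - 4 * mu * s3 + 6 * mu^2 * s2 - 4 * mu^3 * s1 + n_s * mu^4) / n_s
  k <- array(0, d)
  okv <- v > 1e-12
  k[okv] <- m4c[okv] / v[okv]^2 - 3
  structure(list(m1 = ct_volume(m1, sp, image$origin),
                 m2 = ct_volume(m2, sp, image$origin),
                 k = ct_volume(k, sp, image$origin),
                 radius = radius, directions = dirs),
            class = "ln_lbp_maps")
}

#' First-order features of the LBP maps inside a mask
#'
#' The 18 first-order statistics of each of the three LBP maps restricted to
#' the mask, prefixed `lbp-m1_`, `lbp-m2_` and `lbp-k_` (54 features).
#' Entropy/Uniformity discretization uses the map-scale bin width `w`.
#'
#' @param maps an `ln_lbp_maps` object.
#' @param mask a [ct_mask()] on the same grid.
#' @param w bin width for the entropy/uniformity discretization of the map
#'   values (maps are dimensionless; default 0.05).
#' @return named numeric vector of 54 features.
#' @export
lbp_firstorder <- function(maps, mask, w = 0.05) {
  vv <- voxel_volume(mask)
  out <- c(
    first_order_features(mask_values(maps$m1, mask), w = w, voxel_volume = vv,
                         prefix = "lbp-m1_"),
    first_order_features(mask_values(maps$m2, mask), w = w, voxel_volume = vv,
                         prefix = "lbp-m2_"),
    first_order_features(mask_values(maps$k, mask), w = w, voxel_volume = vv,
                         prefix = "lbp-k_")
  )
  out
}

lbp_names <- function() {
  c(firstorder_names("lbp-m1_"), firstorder_names("lbp-m2_"),
    firstorder_names("lbp-k_"))
}

# 42-vertex icosphere: icosahedron vertices + normalized edge midpoints
icosphere42 <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  # edges = vertex pairs at the minimal pairwise distance
  d2 <- as.matrix(stats::dist(v))^2
  dmin <- min(d2[d2 > 1e-9])
  mids <- NULL
  for (i in 1:11) for (j in (i + 1):12) {
    if (abs(d2[i, j] - dmin) < 1e-6) {
      m <- (v[i, ] + v[j, ]) / 2
      mids <- rbind(mids, m / sqrt(sum(m^2)))
    }
  }
  rbind(v, mids)
}

# real spherical harmonics l = 1 (3) and l = 2 (5), orthonormal on the sphere
sh_basis <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(
    sqrt(3 / (4 * pi)) * x,
    sqrt(3 / (4 * pi)) * y,
    sqrt(3 / (4 * pi)) * z,
    0.5 * sqrt(15 / pi) * x * y,
    0.5 * sqrt(15 / pi) * y * z,
    0.5 * sqrt(15 / pi) * x * z,
    0.25 * sqrt(15 / pi) * (x^2 - y^2),
    0.25 * sqrt(5 / pi) * (3 * z^2 - 1))
}

mirror_pad <- function(a, pad) {
  d <- dim(a)
  ix <- mirror_index(seq(-pad, d[1] - 1 + pad), d[1]) + 1L
  iy <- mirror_index(seq(-pad, d[2] - 1 + pad), d[2]) + 1L
  iz <- mirror_index(seq(-pad, d[3] - 1 + pad), d[3]) + 1L
  a[ix, iy, iz, drop = FALSE]
}

# value of padded array at (voxel index + fractional offset), trilinear;
# constant offset for all voxels -> weighted sum of 8 integer-shifted views
trilinear_shift <- function(ap, pad, off, d) {
  f <- floor(off)
  t <- off - f
  out <- array(0, d)
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    wgt <- (if (bx) t[1] else 1 - t[1]) *
      (if (by) t[2] else 1 - t[2]) *
      (if (bz) t[3] else 1 - t[3])
    if (wgt == 0) next
    sx <- pad + f[1] + bx; sy <- pad + f[2] + by; sz <- pad + f[3] + bz
    out <- out + wgt * ap[(1 + sx):(d[1] + sx),
                          (1 + sy):(d[2] + sy),
                          (1 + sz):(d[3] + sz)]
  }
  out
}
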