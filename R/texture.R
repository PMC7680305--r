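#' Gray-level texture matrices of a discretized VOI
#'
#' Computes the five texture-matrix families from a fixed-bin-width
#' discretized VOI: GLCM (13 unique 3D directions at distance 1,
#' symmetrized), GLRLM (same 13 directions), GLSZM and GLDM
#' (26-connectivity), and NGTDM (26-neighborhood). Directional families are
#' kept per direction; their features are averaged over directions
#' downstream, the common aggregation for 3D radiomics.
#'
#' @param disc an `ln_discretized` VOI from [discretize_fixed_bin_width()].
#' @return An object of class `ln_texture_matrices`: a list with `glcm`
#'   (list of 13 normalized symmetric matrices), `glrlm` (list of 13
#'   count matrices), `glszm`, `gldm` (count matrices), `ngtdm` (list with
#'   `p`, `s`, gray levels), `n_bins` and `n_voxels`.
#' @export
texture_matrices <- function(disc) {
  g <- disc$bins
  ng <- disc$n_bins
  np <- sum(!is.na(g))
  dirs <- texture_directions()
  glcm <- lapply(dirs, function(d) glcm_one(g, d, ng))
  glrlm <- lapply(dirs, function(d) glrlm_one(g, d, ng))
  structure(list(glcm = glcm, glrlm = glrlm,
                 glszm = glszm_matrix(g, ng),
                 gldm = gldm_matrix(g, ng),
                 ngtdm = ngtdm_stats(g, ng),
                 n_bins = ng, n_voxels = np),
            class = "ln_texture_matrices")
}

# the 13 unique direction vectors of the 26-neighborhood (positive half-space)
texture_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0]
    length(nz) > 0 && nz[length(nz)] > 0  # last nonzero positive -> one per axis pair
  })
  d <- d[keep, , drop = FALSE]
  lapply(seq_len(nrow(d)), function(i) unname(d[i, ]))
}

all_neighbor_offsets <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
}

# overlapping (center, neighbor) views of array `g` along offset `d`
shifted_views <- function(g, d) {
  dm <- dim(g)
  rng <- function(n, off) {
    a <- max(1, 1 + off); b <- min(n, n + off)
    list(center = (a - off):(b - off), nb = a:b)
  }
  r1 <- rng(dm[1], d[1]); r2 <- rng(dm[2], d[2]); r3 <- rng(dm[3], d[3])
  if (length(r1$center) < 1 || length(r2$center) < 1 || length(r3$center) < 1) {
    return(NULL)
  }
  list(center = g[r1$center, r2$center, r3$center, drop = FALSE],
       nb = g[r1$nb, r2$nb, r3$nb, drop = FALSE])
}

glcm_one <- function(g, d, ng) {
  v <- shifted_views(g, d)
  P <- matrix(0, ng, ng)
  if (!is.null(v)) {
    ok <- !is.na(v$center) & !is.na(v$nb)
    if (any(ok)) {
      a <- v$center[ok]; b <- v$nb[ok]
      counts <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
      P <- matrix(counts, ng, ng, byrow = TRUE)
      P <- P + t(P)
    }
  }
  s <- sum(P)
  if (s > 0) P / s else P
}

glrlm_one <- function(g, d, ng) {
  dm <- dim(g)
  idx <- arrayInd(seq_along(g), dm) - 1L
  # step count along the line: direction components are in {-1, 0, 1}, so
  # any active axis advances by exactly one per step
  ax <- which(d != 0)[1]
  s <- idx[, ax] * d[ax]
  # line anchor: project back s steps; packs uniquely with a radix bounded
  # by the total index sum
  M <- sum(dm) + 2L
  key <- (idx[, 1] - s * d[1] + M) +
    (2L * M + 1L) * ((idx[, 2] - s * d[2] + M) +
                       (2L * M + 1L) * (idx[, 3] - s * d[3] + M))
  ord <- order(key, s)
  gg <- as.vector(g)[ord]
  kk <- key[ord]
  ts <- s[ord]
  n <- length(gg)
  same <- c(FALSE, kk[-1] == kk[-n] & ts[-1] == ts[-n] + 1L &
              !is.na(gg[-1]) & !is.na(gg[-n]) & gg[-1] == gg[-n])
  run_id <- cumsum(!same)
  keep <- !is.na(gg)
  if (!any(keep)) return(matrix(0, ng, 1))
  rl <- tapply(run_id[keep], run_id[keep], length)
  rg <- tapply(gg[keep], run_id[keep], function(x) x[1])
  lmax <- max(rl)
  P <- matrix(0, ng, lmax)
  for (i in seq_along(rl)) P[rg[i], rl[i]] <- P[rg[i], rl[i]] + 1
  P
}

glszm_matrix <- function(g, ng) {
  zones <- connected_zones(g)
  if (nrow(zones) == 0) return(matrix(0, ng, 1))
  smax <- max(zones$size)
  P <- matrix(0, ng, smax)
  for (i in seq_len(nrow(zones))) {
    P[zones$gray[i], zones$size[i]] <- P[zones$gray[i], zones$size[i]] + 1
  }
  P
}

# 26-connected components of equal gray level
connected_zones <- function(g) {
  dm <- dim(g)
  visited <- array(FALSE, dm)
  offs <- all_neighbor_offsets()
  in_mask <- which(!is.na(g))
  res_gray <- integer(0)
  res_size <- integer(0)
  for (seed in in_mask) {
    if (visited[seed]) next
    gray <- g[seed]
    stack <- seed
    visited[seed] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      ci <- arrayInd(cur, dm)
      nb <- sweep(offs, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dm[1] * (nb[, 2] - 1L) + dm[1] * dm[2] * (nb[, 3] - 1L)
      lin <- lin[!visited[lin] & !is.na(g[lin]) & g[lin] == gray]
      if (length(lin) > 0) {
        visited[lin] <- TRUE
        stack <- c(stack, lin)
      }
    }
    res_gray <- c(res_gray, gray)
    res_size <- c(res_size, size)
  }
  data.frame(gray = res_gray, size = res_size)
}

gldm_matrix <- function(g, ng, alpha = 0) {
  offs <- all_neighbor_offsets()
  dep <- array(0L, dim(g))
  for (r in seq_len(nrow(offs))) {
    v <- shifted_views(g, offs[r, ])
    if (is.null(v)) next
    add <- !is.na(v$center) & !is.na(v$nb) & abs(v$nb - v$center) <= alpha
    idx <- shifted_index_ranges(dim(g), offs[r, ])
    dep[idx$i, idx$j, idx$k] <- dep[idx$i, idx$j, idx$k] + add
  }
  inm <- !is.na(g)
  dmax <- max(dep[inm]) + 1L
  P <- matrix(0, ng, dmax)
  tab <- table(factor(g[inm], levels = 1:ng), factor(dep[inm], levels = 0:(dmax - 1)))
  P[, ] <- as.numeric(tab)
  P
}

shifted_index_ranges <- function(dm, d) {
  rng <- function(n, off) {
    a <- max(1, 1 + off); b <- min(n, n + off)
    (a - off):(b - off)
  }
  list(i = rng(dm[1], d[1]), j = rng(dm[2], d[2]), k = rng(dm[3], d[3]))
}

ngtdm_stats <- function(g, ng) {
  offs <- all_neighbor_offsets()
  nsum <- array(0, dim(g))
  ncnt <- array(0L, dim(g))
  for (r in seq_len(nrow(offs))) {
    v <- shifted_views(g, offs[r, ])
    if (is.null(v)) next
    idx <- shifted_index_ranges(dim(g), offs[r, ])
    ok <- !is.na(v$nb)
    vv <- v$nb
    vv[!ok] <- 0
    nsum[idx$i, idx$j, idx$k] <- nsum[idx$i, idx$j, idx$k] + vv
    ncnt[idx$i, idx$j, idx$k] <- ncnt[idx$i, idx$j, idx$k] + ok
  }
  use <- !is.na(g) & ncnt > 0
  gi <- g[use]
  abar <- nsum[use] / ncnt[use]
  nv <- sum(use)
  n_i <- tabulate(gi, nbins = ng)
  s_i <- vapply(1:ng, function(i) sum(abs(i - abar[gi == i])), numeric(1))
  list(p = n_i / nv, s = s_i, n = n_i, n_v = nv, levels = 1:ng)
}

#' Texture features from gray-level matrices
#'
#' The 74 canonical texture features: 23 GLCM (the standard 24 minus the
#' SumAverage duplicate of JointAverage), 16 GLRLM, 16 GLSZM, 14 GLDM and
#' 5 NGTDM, each per its IBSI formula. Directional families (GLCM, GLRLM)
#' are computed per direction and averaged. Features undefined on
#' degenerate (e.g. single-gray-level) VOIs return their documented
#' fallback: correlation-type features 1, everything else 0.
#'
#' @param mats an `ln_texture_matrices` object from [texture_matrices()].
#' @return named numeric vector of 74 features.
#' @export
texture_features <- function(mats) {
  gl <- rowMeans(vapply(mats$glcm, glcm_features_one, numeric(23)))
  rl <- rowMeans(vapply(mats$glrlm, function(P) glrlm_features_one(P, mats$n_voxels),
                        numeric(16)))
  sz <- glszm_features_one(mats$glszm, mats$n_voxels)
  gd <- gldm_features_one(mats$gldm)
  nt <- ngtdm_features_one(mats$ngtdm)
  c(stats::setNames(gl, paste0("glcm_", names(gl))),
    stats::setNames(rl, paste0("glrlm_", names(rl))),
    stats::setNames(sz, paste0("glszm_", names(sz))),
    stats::setNames(gd, paste0("gldm_", names(gd))),
    stats::setNames(nt, paste0("ngtdm_", names(nt))))
}

texture_names <- function() {
  c(paste0("glcm_", names(glcm_features_one(matrix(1)))),
    paste0("glrlm_", names(glrlm_features_one(matrix(1), 1))),
    paste0("glszm_", names(glszm_features_one(matrix(1), 1))),
    paste0("gldm_", names(gldm_features_one(matrix(1)))),
    paste0("ngtdm_", names(ngtdm_features_one(list(p = 1, s = 0, n = 1,
                                                   n_v = 1, levels = 1)))))
}

glcm_features_one <- function(P) {
  eps <- 2.2e-16
  ng <- nrow(P)
  i <- matrix(1:ng, ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(i * P)
  muy <- sum(j * P)
  sigx <- sqrt(sum((i - mux)^2 * P))
  sigy <- sqrt(sum((j - muy)^2 * P))
  # diagonal-sum / difference marginals
  ks <- 2:(2 * ng)
  pxy_sum <- vapply(ks, function(k) sum(P[i + j == k]), numeric(1))
  kd <- 0:(ng - 1)
  pxy_diff <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  da <- sum(kd * pxy_diff)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxpy + eps))
  hxy2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sigx > 0 && sigy > 0) (sum(i * j * P) - mux * muy) / (sigx * sigy) else 1
  mcc <- glcm_mcc(P, px, py)
  offdiag <- i != j
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxy_diff[pxy_diff > 0] * log2(pxy_diff[pxy_diff > 0])),
    DifferenceVariance = sum((kd - da)^2 * pxy_diff),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[offdiag] / (i - j)[offdiag]^2),
    MaximumProbability = max(P),
    MCC = mcc,
    SumEntropy = -sum(pxy_sum[pxy_sum > 0] * log2(pxy_sum[pxy_sum > 0])),
    SumSquares = sum((i - mux)^2 * P))
}

glcm_mcc <- function(P, px, py) {
  ng <- nrow(P)
  if (ng < 2) return(1)
  keep <- px > 0
  if (sum(keep) < 2) return(1)
  Pk <- P[keep, keep, drop = FALSE]
  pxk <- px[keep]
  pyk <- py[keep]
  # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k))
  Q <- matrix(0, sum(keep), sum(keep))
  for (k in seq_len(sum(keep))) {
    if (pyk[k] <= 0) next
    Q <- Q + outer(Pk[, k] / pxk, Pk[, k]) / pyk[k]
  }
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  if (length(ev) < 2) return(1)
  sqrt(pmax(0, ev[2]))
}

rlm_style_features <- function(P, np, size_name, names_prefixless = TRUE) {
  ng <- nrow(P)
  nl <- ncol(P)
  i <- matrix(1:ng, ng, nl)
  l <- matrix(1:nl, ng, nl, byrow = TRUE)
  nr <- sum(P)
  if (nr == 0) {
    z <- rep(0, 16)
    return(z)
  }
  p <- P / nr
  mu_i <- sum(i * p)
  mu_l <- sum(l * p)
  c(sum(P / l^2) / nr,                 # short emphasis
    sum(P * l^2) / nr,                 # long emphasis
    sum(rowSums(P)^2) / nr,            # gray level non-uniformity
    sum(rowSums(P)^2) / nr^2,          # ... normalized
    sum(colSums(P)^2) / nr,            # size non-uniformity
    sum(colSums(P)^2) / nr^2,          # ... normalized
    nr / np,                           # percentage
    sum((i - mu_i)^2 * p),             # gray level variance
    sum((l - mu_l)^2 * p),             # size variance
    -sum(p[p > 0] * log2(p[p > 0])),   # entropy
    sum(P / i^2) / nr,                 # low gray level emphasis
    sum(P * i^2) / nr,                 # high gray level emphasis
    sum(P / (i^2 * l^2)) / nr,
    sum(P * i^2 / l^2) / nr,
    sum(P * l^2 / i^2) / nr,
    sum(P * i^2 * l^2) / nr)
}

glrlm_features_one <- function(P, np) {
  stats::setNames(rlm_style_features(P, np),
                  c("ShortRunEmphasis", "LongRunEmphasis",
                    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                    "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                    "RunPercentage", "GrayLevelVariance", "RunVariance",
                    "RunEntropy", "LowGrayLevelRunEmphasis",
                    "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                    "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                    "LongRunHighGrayLevelEmphasis"))
}

glszm_features_one <- function(P, np) {
  stats::setNames(rlm_style_features(P, np),
                  c("SmallAreaEmphasis", "LargeAreaEmphasis",
                    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                    "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                    "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                    "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                    "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                    "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
                    "LargeAreaHighGrayLevelEmphasis"))
}

gldm_features_one <- function(P) {
  ng <- nrow(P)
  nd <- ncol(P)
  i <- matrix(1:ng, ng, nd)
  jd <- matrix(1:nd, ng, nd, byrow = TRUE)  # dependence size = k + 1
  nz <- sum(P)
  if (nz == 0) return(stats::setNames(rep(0, 14), gldm_feature_names()))
  p <- P / nz
  mu_i <- sum(i * p)
  mu_j <- sum(jd * p)
  stats::setNames(
    c(sum(P / jd^2) / nz,
      sum(P * jd^2) / nz,
      sum(rowSums(P)^2) / nz,
      sum(colSums(P)^2) / nz,
      sum(colSums(P)^2) / nz^2,
      sum((i - mu_i)^2 * p),
      sum((jd - mu_j)^2 * p),
      -sum(p[p > 0] * log2(p[p > 0])),
      sum(P / i^2) / nz,
      sum(P * i^2) / nz,
      sum(P / (i^2 * jd^2)) / nz,
      sum(P * i^2 / jd^2) / nz,
      sum(P * jd^2 / i^2) / nz,
      sum(P * i^2 * jd^2) / nz),
    gldm_feature_names())
}

gldm_feature_names <- function() {
  c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "GrayLevelVariance",
    "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis")
}

ngtdm_features_one <- function(ng) {
  p <- ng$p
  s <- ng$s
  nv <- ng$n_v
  lev <- ng$levels
  act <- p > 0
  ngp <- sum(act)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp <= 1) {
    return(stats::setNames(c(coarseness, 0, 0, 0, 0),
                           c("Coarseness", "Contrast", "Busyness",
                             "Complexity", "Strength")))
  }
  ia <- lev[act]; pa <- p[act]; sa <- s[act]
  dif2 <- outer(ia, ia, function(a, b) (a - b)^2)
  contrast <- sum(outer(pa, pa) * dif2) / (ngp * (ngp - 1)) * sum(sa) / nv
  bus_den <- sum(abs(outer(ia * pa, ia * pa, "-")))
  busyness <- if (bus_den > 0) sum(pa * sa) / bus_den else 0
  compl_mat <- abs(outer(ia, ia, "-")) *
    (outer(pa * sa, pa * sa, "+")) / outer(pa, pa, "+")
  complexity <- sum(compl_mat) / nv
  str_den <- sum(sa)
  strength <- if (str_den > 0) sum(outer(pa, pa, "+") * dif2) / str_den else 0
  stats::setNames(c(coarseness, contrast, busyness, complexity, strength),
                  c("Coarseness", "Contrast", "Busyness", "Complexity",
                    "Strength"))
}
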