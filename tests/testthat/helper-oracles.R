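# independent brute-force oracles: direct enumeration over voxels, kept
# deliberately naive and separate from the package's vectorized code paths

oracle_directions <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    nz <- v[v != 0]
    if (nz[length(nz)] > 0) out[[length(out) + 1]] <- v
  }
  out
}

oracle_glcm <- function(bins, d, n_bins) {
  dm <- dim(bins)
  P <- matrix(0, n_bins, n_bins)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    a <- bins[i, j, k]
    if (is.na(a)) next
    ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
    if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] || kk < 1 || kk > dm[3]) next
    b <- bins[ii, jj, kk]
    if (is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  if (sum(P) > 0) P / sum(P) else P
}

oracle_runs <- function(bins, d) {
  # enumerate maximal runs along direction d by walking every line
  dm <- dim(bins)
  runs <- list()
  seen <- array(FALSE, dm)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    a <- bins[i, j, k]
    if (is.na(a)) next
    # only start at a line head: predecessor missing or different
    pi <- i - d[1]; pj <- j - d[2]; pk <- k - d[3]
    pred <- if (pi >= 1 && pi <= dm[1] && pj >= 1 && pj <= dm[2] &&
                pk >= 1 && pk <= dm[3]) bins[pi, pj, pk] else NA
    if (!is.na(pred) && pred == a) next
    len <- 1
    ci <- i + d[1]; cj <- j + d[2]; ck <- k + d[3]
    while (ci >= 1 && ci <= dm[1] && cj >= 1 && cj <= dm[2] &&
           ck >= 1 && ck <= dm[3] && !is.na(bins[ci, cj, ck]) &&
           bins[ci, cj, ck] == a) {
      len <- len + 1
      ci <- ci + d[1]; cj <- cj + d[2]; ck <- ck + d[3]
    }
    runs[[length(runs) + 1]] <- c(gray = a, len = len)
  }
  do.call(rbind, runs)
}

oracle_glrlm <- function(bins, d, n_bins) {
  runs <- oracle_runs(bins, d)
  lmax <- max(runs[, "len"])
  P <- matrix(0, n_bins, lmax)
  for (r in seq_len(nrow(runs))) {
    P[runs[r, "gray"], runs[r, "len"]] <- P[runs[r, "gray"], runs[r, "len"]] + 1
  }
  P
}

oracle_neighbors26 <- function(dm, i, j, k) {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ii <- i + dx; jj <- j + dy; kk <- k + dz
    if (ii >= 1 && ii <= dm[1] && jj >= 1 && jj <= dm[2] &&
        kk >= 1 && kk <= dm[3]) {
      out <- rbind(out, c(ii, jj, kk))
    }
  }
  out
}

oracle_glszm <- function(bins, n_bins) {
  dm <- dim(bins)
  lab <- array(0L, dm)
  next_lab <- 0L
  sizes <- integer(0); grays <- integer(0)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (is.na(bins[i, j, k]) || lab[i, j, k] > 0) next
    next_lab <- next_lab + 1L
    g <- bins[i, j, k]
    queue <- matrix(c(i, j, k), 1)
    lab[i, j, k] <- next_lab
    sz <- 0L
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      sz <- sz + 1L
      nb <- oracle_neighbors26(dm, cur[1], cur[2], cur[3])
      for (r in seq_len(NROW(nb))) {
        x <- nb[r, ]
        if (lab[x[1], x[2], x[3]] == 0 && !is.na(bins[x[1], x[2], x[3]]) &&
            bins[x[1], x[2], x[3]] == g) {
          lab[x[1], x[2], x[3]] <- next_lab
          queue <- rbind(queue, x)
        }
      }
    }
    sizes <- c(sizes, sz); grays <- c(grays, g)
  }
  P <- matrix(0, n_bins, max(sizes))
  for (z in seq_along(sizes)) P[grays[z], sizes[z]] <- P[grays[z], sizes[z]] + 1
  P
}

oracle_gldm <- function(bins, n_bins) {
  dm <- dim(bins)
  recs <- NULL
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    g <- bins[i, j, k]
    if (is.na(g)) next
    nb <- oracle_neighbors26(dm, i, j, k)
    dep <- 0L
    for (r in seq_len(NROW(nb))) {
      b <- bins[nb[r, 1], nb[r, 2], nb[r, 3]]
      if (!is.na(b) && b == g) dep <- dep + 1L
    }
    recs <- rbind(recs, c(g, dep))
  }
  P <- matrix(0, n_bins, max(recs[, 2]) + 1L)
  for (r in seq_len(nrow(recs))) {
    P[recs[r, 1], recs[r, 2] + 1L] <- P[recs[r, 1], recs[r, 2] + 1L] + 1
  }
  P
}

oracle_ngtdm <- function(bins, n_bins) {
  dm <- dim(bins)
  s <- numeric(n_bins); n_i <- integer(n_bins); nv <- 0L
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    g <- bins[i, j, k]
    if (is.na(g)) next
    nb <- oracle_neighbors26(dm, i, j, k)
    vals <- c()
    for (r in seq_len(NROW(nb))) {
      b <- bins[nb[r, 1], nb[r, 2], nb[r, 3]]
      if (!is.na(b)) vals <- c(vals, b)
    }
    if (length(vals) == 0) next
    nv <- nv + 1L
    n_i[g] <- n_i[g] + 1L
    s[g] <- s[g] + abs(g - mean(vals))
  }
  list(p = n_i / nv, s = s, n = n_i, n_v = nv, levels = 1:n_bins)
}

# exact two-sample Wilcoxon p by full enumeration of group assignments
oracle_wilcoxon_exact <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(abs(ws - mean(ws)) >= abs(w_obs - mean(ws)) - 1e-9)
}
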