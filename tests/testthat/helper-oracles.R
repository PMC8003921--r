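# Independent brute-force oracles used to cross-check the compiled kernels.
# They share no code with the implementation paths they verify.

# 26-connected component count/sizes by plain R breadth-first search
oracle_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  }
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, d)
      nx <- co[1] + offs$dx
      ny <- co[2] + offs$dy
      nz <- co[3] + offs$dz
      ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
      lin <- nx[ok] + d[1] * (ny[ok] - 1) + d[1] * d[2] * (nz[ok] - 1)
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- nextlab
      queue <- c(queue, lin)
    }
  }
  lab
}

# local box mean with mirrored padding, direct windowed computation
oracle_local_mean <- function(x, radius) {
  d <- dim(x)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  out <- array(0, d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1])) {
        win <- x[refl((i - radius[1]):(i + radius[1]), d[1]),
                 refl((j - radius[2]):(j + radius[2]), d[2]),
                 refl((k - radius[3]):(k + radius[3]), d[3])]
        out[i, j, k] <- mean(win)
      }
  out
}

# analytic chord length of a centred spherical shell (r1, r2] along a ray
# from the centre: full thickness when the direction is outside the cap
oracle_shell_chord <- function(dir, r1, r2, cap_axis = NULL,
                               cap_half_angle = 0) {
  if (!is.null(cap_axis) && cap_half_angle > 0) {
    cosang <- sum(dir * cap_axis) / sqrt(sum(dir^2))
    if (cosang >= cos(cap_half_angle)) return(0)
  }
  r2 - r1
}

# nearest-seed geodesic assignment inside a mask via igraph shortest paths
oracle_geodesic_labels <- function(mask, seed_idx, seed_lab, spacing) {
  d <- dim(mask)
  vox <- which(mask)
  id <- integer(prod(d))
  id[vox] <- seq_along(vox)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  co <- arrayInd(vox, d)
  edges <- NULL
  wts <- NULL
  for (r in seq_len(nrow(offs))) {
    nx <- co[, 1] + offs[r, 1]
    ny <- co[, 2] + offs[r, 2]
    nz <- co[, 3] + offs[r, 3]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    lin <- nx[ok] + d[1] * (ny[ok] - 1) + d[1] * d[2] * (nz[ok] - 1)
    ok2 <- mask[lin]
    from <- id[vox[ok]][ok2]
    to <- id[lin[ok2]]
    keep <- from < to
    edges <- rbind(edges, cbind(from[keep], to[keep]))
    w <- sqrt(sum((offs[r, ] * spacing)^2))
    wts <- c(wts, rep(w, sum(keep)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  dmat <- igraph::distances(g, v = id[seed_idx])
  assign_lab <- seed_lab[apply(dmat, 2, which.min)]
  out <- array(0L, d)
  out[vox] <- assign_lab
  out
}
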