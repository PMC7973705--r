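# Brute-force geometric oracles, independent of the package's BVH kernels.

# closest point on one triangle via plane projection + edge clamping
oracle_closest_on_triangle <- function(p, a, b, c) {
  n <- pracma_cross(b - a, c - a)
  nn <- sum(n^2)
  seg <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d^2)
    t <- min(max(t, 0), 1)
    u + t * d
  }
  if (nn < 1e-30) {  # degenerate: best of the three edges
    cands <- rbind(seg(p, a, b), seg(p, b, c), seg(p, c, a))
    return(cands[which.min(rowSums(sweep(cands, 2, p)^2)), ])
  }
  q <- p - sum((p - a) * n) / nn * n   # projection into the plane
  # barycentric coordinates of q
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(q)
  cands <- rbind(seg(p, a, b), seg(p, b, c), seg(p, c, a))
  cands[which.min(rowSums(sweep(cands, 2, p)^2)), ]
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# exhaustive minimization over every triangle of the mesh
oracle_closest_point <- function(mesh, p) {
  best <- NULL
  bestd <- Inf
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    q <- oracle_closest_on_triangle(p, mesh$vertices[f[1], ],
                                    mesh$vertices[f[2], ],
                                    mesh$vertices[f[3], ])
    d <- sqrt(sum((q - p)^2))
    if (d < bestd) { bestd <- d; best <- q }
  }
  list(point = best, distance = bestd)
}

# exhaustive Moller-Trumbore over every triangle (independent R code)
oracle_ray <- function(mesh, o, d, t_min = 0, t_max = Inf) {
  best <- Inf
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    a <- mesh$vertices[f[1], ]; b <- mesh$vertices[f[2], ]
    cc <- mesh$vertices[f[3], ]
    e1 <- b - a; e2 <- cc - a
    pv <- pracma_cross(d, e2)
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) next
    tv <- o - a
    u <- sum(tv * pv) / det
    if (u < 0 || u > 1) next
    qv <- pracma_cross(tv, e1)
    v <- sum(d * qv) / det
    if (v < 0 || u + v > 1) next
    t <- sum(e2 * qv) / det
    if (t > t_min && t < t_max && t < best) best <- t
  }
  if (is.finite(best)) best else NA_real_
}

# 26-connectivity voxel components through igraph (independent of the C++ BFS)
oracle_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  lin <- which(mask)
  n <- nrow(idx)
  edges <- NULL
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  linmap <- array(0L, d)
  linmap[lin] <- seq_len(n)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(idx, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_id <- linmap[nb[ok, , drop = FALSE]]
    src <- seq_len(n)[ok]
    keep <- nb_id > 0
    edges <- rbind(edges, cbind(src[keep], nb_id[keep]))
  }
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out <- array(0L, d)
  out[lin] <- memb
  out
}

# a deterministic random triangle soup for oracle comparisons
random_triangle_soup <- function(n_tri = 50, seed = 7) {
  set.seed(seed)
  centres <- matrix(runif(3 * n_tri, -10, 10), ncol = 3)
  verts <- NULL
  for (i in seq_len(n_tri))
    verts <- rbind(verts, sweep(matrix(runif(9, -3, 3), 3), 2, centres[i, ], "+"))
  surface_mesh(verts, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE))
}
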