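# Independent oracles used across the suite. These deliberately avoid the
# package's compiled kernels: plain-R arithmetic only.

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

rotation_matrix <- function(angle, axis = rand_unit()) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

cross_ref <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Reference pair potential evaluated with explicit cross products and
# internal renormalization of the polarity arguments.
V_ref <- function(xi, xj, p_i, p_j, q_i, q_j, li, lj, beta = 5, expo = 1) {
  p_i <- p_i / sqrt(sum(p_i^2)); p_j <- p_j / sqrt(sum(p_j^2))
  q_i <- q_i / sqrt(sum(q_i^2)); q_j <- q_j / sqrt(sum(q_j^2))
  d <- xj - xi
  r <- sqrt(sum(d^2))
  rh <- d / r
  S1 <- sum(cross_ref(p_i, rh) * cross_ref(p_j, rh))
  S2 <- sum(cross_ref(p_i, q_i) * cross_ref(p_j, q_j))
  S3 <- sum(cross_ref(q_i, rh) * cross_ref(q_j, rh))
  l <- (li + lj) / 2
  S <- l[1] * S1 + l[2] * S2 + l[3] * S3
  if (expo == 1) exp(-r) - S * exp(-r / beta)
  else exp(-r^4) - S * exp(-(r / beta)^4)
}

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    e <- rep(0, length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# O(N^3) midpoint criterion: the definitive line-of-sight neighbor oracle.
brute_force_los <- function(pos) {
  N <- nrow(pos)
  out <- matrix(integer(0), 0, 2)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    m <- (pos[i, ] + pos[j, ]) / 2
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    dk <- sqrt(rowSums(sweep(pos, 2, m)^2))
    dk[c(i, j)] <- Inf
    if (all(dk > r / 2)) out <- rbind(out, c(i, j))
  }
  out
}

# Brute-force Delaunay adjacency by the empty-circumsphere property over all
# point quadruples (generic position assumed).
delaunay_brute <- function(pos) {
  N <- nrow(pos)
  adj <- matrix(FALSE, N, N)
  quads <- utils::combn(N, 4)
  for (c4 in seq_len(ncol(quads))) {
    q <- quads[, c4]
    A <- 2 * (pos[q[2:4], ] - matrix(pos[q[1], ], 3, 3, byrow = TRUE))
    b <- rowSums(pos[q[2:4], ]^2) - sum(pos[q[1], ]^2)
    ctr <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(ctr)) next
    rad <- sqrt(sum((pos[q[1], ] - ctr)^2))
    d <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
    if (all(d[-q] > rad - 1e-9))
      for (a in 1:3) for (b2 in (a + 1):4) adj[q[a], q[b2]] <- TRUE
  }
  which(adj, arr.ind = TRUE)
}

edges_matrix <- function(graph) {
  cbind(graph$i, graph$j)
}

# Spherical shell with a Gaussian dimple of depth `depth` pushed toward the
# center around the south pole; AB polarity stays along the undeformed
# outward normal so the dimple bottom tilts toward its neighbors.
dimple_shell <- function(n = 400, depth = 3, width = 0.5) {
  st <- make_hollow_sphere(n)
  pos <- positions(st)
  R <- sqrt(sum(pos[1, ]^2))
  rhat <- pos / R
  ang <- acos(pmin(1, pmax(-1, -rhat[, 3]))) # angle from south pole
  fac <- 1 - (depth / R) * exp(-(ang / width)^2)
  cell_state(pos * fac, ab = rhat)
}
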