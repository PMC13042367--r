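# Independent brute-force oracles and fixture builders used across the
# suite. Oracles are deliberately written scalar-and-loop style, separate
# from the vectorised implementation paths they check.

# scalar dihedral via explicit rotation-free geometry (atan2 of projected
# components, computed with plain arithmetic)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  ub2 <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * ub2)
  atan2(y, x) * 180 / pi
}

oracle_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# brute-force linear scan over bin edges (distance map conventions)
oracle_bin_scan <- function(x, edges, periodic, catchall_at) {
  if (is.na(x)) return(catchall_at)
  if (periodic) x <- ((x + 180) %% 360) - 180
  n_in <- length(edges) - 1L
  for (k in seq_len(n_in)) {
    hi_ok <- if (!periodic && edges[1] == 0 && k == n_in) x <= edges[k + 1]
             else x < edges[k + 1]
    if (x >= edges[k] && hi_ok) return(k)
  }
  if (x < edges[1]) return(1L)
  catchall_at
}

# scalar decay-and-smooth update (Eq-style brute force): explicit loops,
# explicit kernel, reflection / wrap handled bin by bin
oracle_update <- function(p, s_idx, sigma, periodic, threshold = 0.5) {
  if (max(p) >= threshold) return(p)
  q <- p
  q[s_idx] <- q[s_idx] - 0.5 * q[s_idx]
  q <- q / sum(q)
  if (sigma == 0) return(q)
  n <- length(q) - 1L
  r <- min(n - 1L, max(1L, ceiling(4 * sigma)))
  w <- exp(-(-r:r)^2 / (2 * sigma^2)); w <- w / sum(w)
  out <- numeric(n)
  for (src in 1:n) {
    for (k in -r:r) {
      tgt <- src + k
      if (periodic) tgt <- ((tgt - 1) %% n) + 1
      else {
        if (tgt < 1) tgt <- 1 - tgt
        if (tgt > n) tgt <- 2 * n + 1 - tgt
      }
      out[tgt] <- out[tgt] + w[k + r + 1] * q[src]
    }
  }
  res <- c(out, q[n + 1])
  res / sum(res)
}

# brute-force max-abs-change scan over (map, pair, bin)
oracle_max_change <- function(G1, G2) {
  biggest <- 0
  for (m in c("dist", "omega", "theta", "phi")) {
    a <- G1[[m]]; b <- G2[[m]]
    for (i in seq_len(dim(a)[1]))
      for (j in seq_len(dim(a)[2]))
        for (k in seq_len(dim(a)[3]))
          biggest <- max(biggest, abs(a[i, j, k] - b[i, j, k]))
  }
  biggest
}

# quartile filter oracle with explicit linear-interpolation quartiles
oracle_energy_filter <- function(e) {
  qq <- function(p) {
    n <- length(e); s <- sort(e)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  thr <- qq(0.75) + (qq(0.75) - qq(0.25))
  which(e <= thr)
}

# superposition RMSD oracle: quaternion grid search with refinement
oracle_rmsd <- function(A, B, levels = 4, n0 = 12) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  rmsd_for <- function(q) {
    R <- quat_rot(q)
    sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
  }
  set.seed(1234)
  best_q <- NULL; best <- Inf
  cand <- rbind(diag(4), matrix(stats::rnorm(4 * 200), ncol = 4))
  for (i in seq_len(nrow(cand))) {
    v <- rmsd_for(cand[i, ])
    if (v < best) { best <- v; best_q <- cand[i, ] }
  }
  width <- 0.5
  for (lev in seq_len(levels * 3)) {
    cand <- sweep(matrix(stats::rnorm(4 * 60, sd = width), ncol = 4), 2,
                  best_q, `+`)
    for (i in seq_len(nrow(cand))) {
      v <- rmsd_for(cand[i, ])
      if (v < best) { best <- v; best_q <- cand[i, ] }
    }
    width <- width / 2.5
  }
  best
}

# random valid backbone from random torsions
random_backbone <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  build_backbone(stats::runif(L, -170, -40), stats::runif(L, -70, 170))
}

# small deterministic two-state fixture shared by several tests
hinge_fixture <- function() {
  spec <- toy_spec("hinge")
  states <- make_toy_states(spec)
  list(spec = spec, A = states[[1]], B = states[[2]],
       G = mix_geometries(states))
}
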