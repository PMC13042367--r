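# Binning, pair-geometry computation, discretization and smoothing.

test_that("binning scheme has the stated structure", {
  b <- geometry_binning()
  expect_equal(b$dist$n_bins, 37L)
  expect_equal(b$omega$n_bins, 25L)
  expect_equal(b$theta$n_bins, 25L)
  expect_equal(b$phi$n_bins, 13L)
  for (m in c("dist", "omega", "theta", "phi")) {
    expect_true(all(diff(b[[m]]$edges) > 0))
    expect_equal(length(unique(round(diff(b[[m]]$edges), 12))), 1L)
  }
  expect_true(b$omega$periodic && b$theta$periodic)
  expect_false(b$dist$periodic || b$phi$periodic)
})

test_that("pair geometries match construction and are symmetric where due", {
  # two residues with CBs placed a known distance apart
  st <- random_backbone(6, seed = 3)
  st$xyz[5, ] <- c(0, 0, 0)      # CB of residue 1
  st$xyz[10, ] <- c(5, 0, 0)     # CB of residue 2
  g <- compute_pair_geometries(st)
  expect_equal(g$d[1, 2], 5.0)
  expect_identical(g$d, t(g$d))
  expect_identical(g$omega, t(g$omega))
  expect_true(all(is.na(diag(g$d))))
  expect_true(all(g$phi[!is.na(g$phi)] >= 0 & g$phi[!is.na(g$phi)] <= 180))
  expect_true(all(g$omega[!is.na(g$omega)] >= -180 &
                  g$omega[!is.na(g$omega)] < 180))
})

test_that("pair geometries agree with the scalar geometry oracle", {
  set.seed(11)
  for (rep in 1:20) {
    st <- random_backbone(8)
    N <- bb_atom(st, "N"); CA <- bb_atom(st, "CA"); CB <- bb_atom(st, "CB")
    g <- compute_pair_geometries(st)
    for (pair in list(c(1, 5), c(2, 7), c(8, 3))) {
      i <- pair[1]; j <- pair[2]
      expect_equal(g$d[i, j], sqrt(sum((CB[i, ] - CB[j, ])^2)),
                   tolerance = 1e-9)
      expect_equal(g$omega[i, j],
                   oracle_dihedral(CA[i, ], CB[i, ], CB[j, ], CA[j, ]),
                   tolerance = 1e-6)
      expect_equal(g$theta[i, j],
                   oracle_dihedral(N[i, ], CA[i, ], CB[i, ], CB[j, ]),
                   tolerance = 1e-6)
      expect_equal(g$phi[i, j], oracle_angle(CA[i, ], CB[i, ], CB[j, ]),
                   tolerance = 1e-6)
    }
  }
})

test_that("ideal helix geometries match the atom-by-atom oracle", {
  st <- build_backbone(rep(-57, 10), rep(-47, 10))
  N <- bb_atom(st, "N"); CA <- bb_atom(st, "CA"); CB <- bb_atom(st, "CB")
  g <- compute_pair_geometries(st)
  for (i in 1:9) {
    j <- i + 1L
    expect_equal(g$theta[i, j],
                 oracle_dihedral(N[i, ], CA[i, ], CB[i, ], CB[j, ]),
                 tolerance = 1e-9)
    expect_equal(g$phi[i, j], oracle_angle(CA[i, ], CB[i, ], CB[j, ]),
                 tolerance = 1e-9)
  }
})

test_that("discretization follows the stated edges and no-contact rule", {
  b <- geometry_binning()
  expect_equal(bin_index(5.0, b$dist), 7L)   # 2.0 + 0.5k edges: [5.0, 5.5) is bin 7
  expect_equal(bin_index(2.0, b$dist), 1L)
  expect_equal(bin_index(19.99, b$dist), 36L)
  expect_equal(bin_index(25.0, b$dist), 37L)  # catch-all
  expect_equal(bin_index(-180, b$omega), 1L)
  expect_equal(bin_index(179.99, b$omega), 24L)
  expect_equal(bin_index(180, b$omega), 1L)   # wraps
  expect_equal(bin_index(0, b$phi), 1L)
  expect_equal(bin_index(180, b$phi), 12L)    # closed right edge
  expect_error(bin_index(NaN, b$dist), "non-finite")
  expect_error(bin_index(Inf, b$phi), "non-finite")
})

test_that("bin indices agree with a brute-force edge scan on random draws", {
  b <- geometry_binning()
  set.seed(99)
  d <- c(runif(250, 0, 25), runif(50, 19.9, 20.1))
  ang <- runif(300, -200, 200)
  ph <- runif(300, 0, 180)
  expect_equal(bin_index(d, b$dist),
               vapply(d, oracle_bin_scan, integer(1), edges = b$dist$edges,
                      periodic = FALSE, catchall_at = 37L))
  expect_equal(bin_index(ang, b$omega),
               vapply(ang, oracle_bin_scan, integer(1), edges = b$omega$edges,
                      periodic = TRUE, catchall_at = 25L))
  expect_equal(bin_index(ph, b$phi),
               vapply(ph, oracle_bin_scan, integer(1), edges = b$phi$edges,
                      periodic = FALSE, catchall_at = 13L))
})

test_that("discretize + compute yields valid one-hot distributions", {
  st <- random_backbone(12, seed = 5)
  G <- discretize(compute_pair_geometries(st), sequence = st$sequence)
  expect_s3_class(G, "geom_distributions")
  expect_silent(validate_geometries(G))
  # one-hot: every pair has exactly one unit entry
  M <- matrix(G$dist, 144, 37)
  expect_true(all(apply(M, 1, max) == 1))
  # diagonal is catch-all everywhere
  for (m in c("dist", "omega", "theta", "phi"))
    for (i in 1:12)
      expect_equal(G[[m]][i, i, dim(G[[m]])[3]], 1)
})

test_that("far pairs land in the catch-all bin of all four maps", {
  st <- build_backbone(rep(-120, 30), rep(130, 30))  # extended, ends far apart
  g <- compute_pair_geometries(st)
  expect_gt(g$d[1, 30], 20)
  G <- discretize(g)
  expect_equal(G$dist[1, 30, 37], 1)
  expect_equal(G$omega[1, 30, 25], 1)
  expect_equal(G$theta[1, 30, 25], 1)
  expect_equal(G$phi[1, 30, 13], 1)
})

test_that("smoothing conserves mass, respects the catch-all, matches kernel", {
  p <- c(rep(0, 36), 0); p[10] <- 0.8; p[37] <- 0.2
  expect_identical(smooth_probability(p, 0), p)
  q <- smooth_probability(p, 1)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  expect_equal(q[37], 0.2, tolerance = 1e-12)   # catch-all untouched
  # interior one-hot matches the discretised Gaussian kernel directly
  r <- ceiling(4)
  w <- exp(-(-r:r)^2 / 2); w <- w / sum(w)
  expect_equal(q[(10 - r):(10 + r)], 0.8 * w, tolerance = 1e-12)
  expect_error(smooth_probability(p, -1), "sigma")
})

test_that("periodic smoothing is equivariant under cyclic shifts", {
  set.seed(2)
  p <- runif(24); p <- c(p / sum(p) * 0.9, 0.1)
  q <- smooth_probability(p, 1.5, periodic = TRUE)
  for (shift in c(3, 11)) {
    ps <- c(p[seq_len(24)][((seq_len(24) - 1 + shift) %% 24) + 1], p[25])
    qs <- smooth_probability(ps, 1.5, periodic = TRUE)
    expect_equal(qs[seq_len(24)],
                 q[seq_len(24)][((seq_len(24) - 1 + shift) %% 24) + 1],
                 tolerance = 1e-12)
  }
})

test_that("glycine gets a virtual CB at the stated bond length", {
  st <- build_backbone(rep(-57, 5), rep(-47, 5), sequence = "AAGAA")
  ca <- bb_atom(st, "CA"); cb <- bb_atom(st, "CB")
  expect_equal(sqrt(sum((cb[3, ] - ca[3, ])^2)), 1.522, tolerance = 1e-9)
})

test_that("geometry validation rejects malformed distributions", {
  st <- random_backbone(6, seed = 8)
  G <- discretize(compute_pair_geometries(st))
  bad <- G
  bad$dist[1, 2, ] <- bad$dist[1, 2, ] * 2
  expect_error(validate_geometries(bad), "sums to")
  bad2 <- G
  bad2$dist[1, 2, ] <- 0; bad2$dist[1, 2, 3] <- 1   # asymmetric
  expect_error(validate_geometries(bad2), "symmetric")
})
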