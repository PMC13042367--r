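# Pairwise backbone geometries: for residues i, j the Cb-Cb distance d,
# dihedrals omega (CAi-CBi-CBj-CAj) and theta (Ni-CAi-CBi-CBj), and the
# planar angle phi (CAi-CBi-CBj). d and omega are symmetric in (i, j);
# theta and phi are directional.

.row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}
.row_norm <- function(u) sqrt(rowSums(u^2))

#' Dihedral angles for rows of four point matrices
#'
#' @param p1,p2,p3,p4 (n x 3) matrices; each row defines one dihedral.
#' @return angles in degrees in [-180, 180); \code{NA} where the
#'   construction is degenerate (collinear triplets).
#' @export
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .row_cross(b1, b2)
  n2 <- .row_cross(b2, b3)
  m1 <- .row_cross(n1, b2 / pmax(.row_norm(b2), 1e-300))
  x <- rowSums(n1 * n2)
  y <- -rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ang[ang >= 180] <- ang[ang >= 180] - 360
  ang[.row_norm(n1) < 1e-7 | .row_norm(n2) < 1e-7] <- NA_real_
  ang
}

#' Planar angles for rows of three point matrices
#'
#' @param p1,p2,p3 (n x 3) matrices; angle at \code{p2}.
#' @return angles in degrees in [0, 180]; \code{NA} where degenerate.
#' @export
angle_points <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- .row_norm(u); nv <- .row_norm(v)
  cs <- rowSums(u * v) / (nu * nv)
  cs <- pmin(1, pmax(-1, cs))
  ang <- acos(cs) * 180 / pi
  ang[nu < 1e-7 | nv < 1e-7] <- NA_real_
  ang
}

#' Compute pairwise geometry maps from a backbone structure
#'
#' Virtual CB atoms are used as stored in the structure (the builder and
#' PDB reader construct them for glycine). The diagonal is undefined
#' (\code{NA}); symmetric maps (\code{d}, \code{omega}) are computed on the
#' upper triangle and mirrored so symmetry is exact.
#'
#' @param structure a \code{backbone} object.
#' @return a list of four (L x L) matrices \code{d}, \code{omega},
#'   \code{theta}, \code{phi} of class \code{pair_geometry}.
#' @export
compute_pair_geometries <- function(structure) {
  L <- n_residues(structure)
  N  <- bb_atom(structure, "N")
  CA <- bb_atom(structure, "CA")
  CB <- bb_atom(structure, "CB")

  d <- as.matrix(stats::dist(CB))
  diag(d) <- NA_real_

  # all ordered pairs i != j for the directional maps
  ii <- rep(seq_len(L), each = L)
  jj <- rep(seq_len(L), times = L)
  off <- ii != jj
  io <- ii[off]; jo <- jj[off]

  th <- matrix(NA_real_, L, L)
  ph <- matrix(NA_real_, L, L)
  th[cbind(io, jo)] <- dihedral_points(N[io, , drop = FALSE], CA[io, , drop = FALSE],
                                       CB[io, , drop = FALSE], CB[jo, , drop = FALSE])
  ph[cbind(io, jo)] <- angle_points(CA[io, , drop = FALSE], CB[io, , drop = FALSE],
                                    CB[jo, , drop = FALSE])

  om <- matrix(NA_real_, L, L)
  ut <- which(upper.tri(om), arr.ind = TRUE)
  iu <- ut[, 1]; ju <- ut[, 2]
  vals <- dihedral_points(CA[iu, , drop = FALSE], CB[iu, , drop = FALSE],
                          CB[ju, , drop = FALSE], CA[ju, , drop = FALSE])
  om[ut] <- vals
  om[cbind(ju, iu)] <- vals

  structure(list(d = d, omega = om, theta = th, phi = ph),
            class = "pair_geometry")
}

#' Discretize geometry maps into one-hot distributions
#'
#' Each defined residue pair receives a one-hot probability vector per map.
#' Pairs with d at or beyond 20 Angstrom ("no contact"), the diagonal, and
#' pairs whose angle is undefined (degenerate construction) receive the
#' catch-all bin. NaN or infinite values are an error.
#'
#' @param geoms a \code{pair_geometry} list (from
#'   [compute_pair_geometries()]).
#' @param binning a [geometry_binning()] object.
#' @param sequence optional sequence to attach to the result.
#' @return a \code{geom_distributions} object (see
#'   [geometry_distributions()]).
#' @export
discretize <- function(geoms, binning = geometry_binning(), sequence = NULL) {
  idx <- discretize_indices(geoms, binning)
  L <- nrow(geoms$d)
  onehot <- function(ind, nb) {
    arr <- array(0, dim = c(L, L, nb))
    flat <- cbind(rep(seq_len(L), L), rep(seq_len(L), each = L))
    arr[cbind(flat[, 1], flat[, 2], as.vector(ind))] <- 1
    arr
  }
  geometry_distributions(
    dist  = onehot(idx$dist,  binning$dist$n_bins),
    omega = onehot(idx$omega, binning$omega$n_bins),
    theta = onehot(idx$theta, binning$theta$n_bins),
    phi   = onehot(idx$phi,   binning$phi$n_bins),
    sequence = sequence, binning = binning
  )
}

# Bin-index matrices (L x L) for all four maps; the no-contact rule
# (d >= 20 A) forces the catch-all bin of every map for that pair.
discretize_indices <- function(geoms, binning = geometry_binning()) {
  L <- nrow(geoms$d)
  di <- matrix(bin_index(geoms$d, binning$dist, "distance"), L, L)
  oi <- matrix(bin_index(geoms$omega, binning$omega, "omega"), L, L)
  ti <- matrix(bin_index(geoms$theta, binning$theta, "theta"), L, L)
  pi_ <- matrix(bin_index(geoms$phi, binning$phi, "phi"), L, L)
  far <- di == binning$dist$n_bins
  oi[far] <- binning$omega$n_bins
  ti[far] <- binning$theta$n_bins
  pi_[far] <- binning$phi$n_bins
  list(dist = di, omega = oi, theta = ti, phi = pi_)
}

#' Gaussian smoothing of a binned probability vector
#'
#' Smooths the in-range bins with a discretised Gaussian kernel (unit = one
#' bin), using circular wrap-around for periodic maps and reflection at the
#' boundaries otherwise. The terminal catch-all bin is categorical: it is
#' excluded from the convolution, keeps its mass, and never receives leaked
#' mass. The output is renormalised to the input's total mass.
#'
#' @param p probability vector (last element the catch-all unless
#'   \code{has_catchall = FALSE}).
#' @param sigma kernel width in bins; \code{0} returns the input unchanged.
#' @param periodic wrap the in-range bins circularly.
#' @param has_catchall whether the last element is a catch-all bin.
#' @return smoothed probability vector of the same length.
#' @export
smooth_probability <- function(p, sigma, periodic = FALSE, has_catchall = TRUE) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(p)
  n <- length(p) - if (has_catchall) 1L else 0L
  S <- smoothing_matrix(n, sigma, periodic)
  q <- p
  inr <- seq_len(n)
  q[inr] <- as.vector(S %*% p[inr])
  tot <- sum(p)
  if (tot > 0) q <- q * (tot / sum(q))
  q
}

#' Smoothing operator matrix for in-range bins
#'
#' @param n number of in-range bins.
#' @param sigma Gaussian width in bins.
#' @param periodic circular (TRUE) or reflecting (FALSE) boundary.
#' @return an (n x n) mass-conserving matrix \code{S}; smoothing is
#'   \code{S \%*\% p}.
#' @export
smoothing_matrix <- function(n, sigma, periodic = FALSE) {
  if (sigma <= 0) return(diag(n))
  r <- min(n - 1L, max(1L, ceiling(4 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (src in seq_len(n)) {
    for (k in seq(-r, r)) {
      tgt <- src + k
      if (periodic) {
        tgt <- ((tgt - 1L) %% n) + 1L
      } else {
        if (tgt < 1L) tgt <- 1L - tgt              # reflect at the edge
        if (tgt > n) tgt <- 2L * n + 1L - tgt
      }
      if (tgt >= 1L && tgt <= n)
        S[tgt, src] <- S[tgt, src] + w[k + r + 1L]
    }
  }
  S
}

#' Smooth every per-pair distribution of a geometry set
#'
#' @param G a \code{geom_distributions} object.
#' @param sigma Gaussian width in bins.
#' @return smoothed \code{geom_distributions}.
#' @export
smooth_geometries <- function(G, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(G)
  b <- G$binning
  for (m in GEOM_MAPS) {
    nb <- b[[m]]$n_bins
    n_in <- b[[m]]$n_in
    S <- smoothing_matrix(n_in, sigma, b[[m]]$periodic)
    L <- dim(G[[m]])[1]
    M <- matrix(G[[m]], L * L, nb)
    M[, seq_len(n_in)] <- M[, seq_len(n_in), drop = FALSE] %*% t(S)
    rs <- rowSums(M)
    M <- M / ifelse(rs > 0, rs, 1)
    G[[m]] <- array(M, dim = c(L, L, nb))
  }
  G
}

GEOM_MAPS <- c("dist", "omega", "theta", "phi")

#' Construct and validate a set of geometry distributions
#'
#' Container for the four (L x L x K) probability arrays. Validation checks
#' that every per-pair vector is non-negative and sums to one (1e-6), and
#' that the \code{dist} and \code{omega} maps are symmetric in (i, j).
#'
#' @param dist,omega,theta,phi (L x L x K) probability arrays with
#'   K = 37, 25, 25, 13 respectively.
#' @param sequence optional one-letter sequence of length L.
#' @param binning a [geometry_binning()] object.
#' @param validate run invariant checks.
#' @return object of class \code{geom_distributions}.
#' @export
geometry_distributions <- function(dist, omega, theta, phi, sequence = NULL,
                                   binning = geometry_binning(),
                                   validate = TRUE) {
  L <- dim(dist)[1]
  if (is.null(sequence)) sequence <- rep("A", L)
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  G <- structure(list(dist = dist, omega = omega, theta = theta, phi = phi,
                      sequence = sequence, binning = binning),
                 class = "geom_distributions")
  if (validate) validate_geometries(G)
  G
}

#' Validate geometry-distribution invariants
#' @param G a \code{geom_distributions} object.
#' @param tol normalisation tolerance.
#' @return \code{G}, invisibly; errors describe the offending map and pair.
#' @export
validate_geometries <- function(G, tol = 1e-6) {
  L <- dim(G$dist)[1]
  for (m in GEOM_MAPS) {
    a <- G[[m]]
    if (!identical(dim(a)[1:2], c(L, L)))
      stop("map ", m, " has inconsistent dimensions")
    expected <- G$binning[[m]]$n_bins
    if (dim(a)[3] != expected)
      stop(sprintf("map %s has %d bins, expected %d", m, dim(a)[3], expected))
    if (any(a < -tol)) stop("map ", m, " has negative probabilities")
    s <- apply(a, c(1, 2), sum)
    bad <- which(abs(s - 1) > tol, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("map %s: pair (%d, %d) sums to %.8f, not 1",
                   m, bad[1, 1], bad[1, 2], s[bad[1, 1], bad[1, 2]]))
  }
  for (m in c("dist", "omega")) {
    a <- G[[m]]
    ta <- aperm(a, c(2, 1, 3))
    if (max(abs(a - ta)) > tol)
      stop("map ", m, " is not symmetric in (i, j)")
  }
  invisible(G)
}
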