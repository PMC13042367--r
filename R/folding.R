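# Restraint-based coarse-grained folding. Geometry distributions become
# per-pair spline potentials of negative log probability ratios; folding
# minimizes the weighted restraint + physical energy in Cartesian backbone
# coordinates with L-BFGS, in two stages with the stage-specific restraint
# weights, starting from a seeded random-torsion chain.

#' Folding configuration
#'
#' Stage-1 restraint weights default to AtomPair 5.0, Dihedral 4.0,
#' Angle 4.0 with steric 1.0, backbone-regularity 1.0 and
#' omega-planarity 0.5; stage 2 re-minimizes with AtomPair 4.0,
#' Dihedral 1.0, Angle 1.0 (physical weights unchanged). The optimizer is
#' capped at \code{max_iter} L-BFGS iterations per stage with
#' projected-gradient tolerance \code{tol}.
#'
#' @param stage1,stage2 named weight lists (see defaults).
#' @param max_iter L-BFGS iteration cap per stage (default 1000).
#' @param tol convergence tolerance (default 1e-4).
#' @param gate minimum contact probability (1 - no-contact mass) for a pair
#'   to be restrained (default 0.05).
#' @param eps floor added to probabilities inside the log ratio
#'   (default 1e-4).
#' @param seed base random seed for chain initialisation.
#' @return object of class \code{folding_config}.
#' @export
folding_config <- function(stage1 = list(pair = 5.0, dihedral = 4.0, angle = 4.0,
                                         steric = 1.0, breg = 1.0, omegator = 0.5),
                           stage2 = list(pair = 4.0, dihedral = 1.0, angle = 1.0,
                                         steric = 1.0, breg = 1.0, omegator = 0.5),
                           max_iter = 1000L, tol = 1e-4, gate = 0.05,
                           eps = 1e-4, seed = 1L) {
  stopifnot(all(unlist(stage1) >= 0), all(unlist(stage2) >= 0),
            max_iter >= 1, tol > 0, eps > 0)
  structure(list(stage1 = stage1, stage2 = stage2,
                 max_iter = as.integer(max_iter), tol = tol, gate = gate,
                 eps = eps, seed = as.integer(seed)),
            class = "folding_config")
}

# Physical-term force constants and derived ideal CB frame constants.
# The CB angle/improper targets are computed once from the virtual-CB
# construction itself so an ideally built chain scores ~0.
folding_params <- function(weights) {
  cbg <- cb_frame_constants()
  list(w_pair = weights$pair, w_dih = weights$dihedral, w_ang = weights$angle,
       w_steric = weights$steric, w_breg = weights$breg,
       w_omegator = weights$omegator,
       kbond = 100, kang = 20, kimpr = 20, komega = 10,
       krep = 10, rep_rmin = 3.0,
       ideal = ideal_geometry(),
       t_cb = cbg$t_cb, a_NCACB = cbg$a_NCACB, a_CCACB = cbg$a_CCACB)
}

cb_frame_constants <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bb <- build_backbone(phi = c(-57, -57, -57), psi = c(-47, -47, -47))
    N <- bb_atom(bb, "N")[2, , drop = FALSE]
    CA <- bb_atom(bb, "CA")[2, , drop = FALSE]
    C <- bb_atom(bb, "C")[2, , drop = FALSE]
    CB <- bb_atom(bb, "CB")[2, , drop = FALSE]
    cache <<- list(
      t_cb = dihedral_points(N, C, CA, CB),
      a_NCACB = angle_points(N, CA, CB),
      a_CCACB = angle_points(C, CA, CB)
    )
    cache
  }
})

#' Build restraint potentials from geometry distributions
#'
#' For every residue pair whose contact probability (one minus the
#' no-contact mass) reaches the gate, the in-range distance distribution
#' becomes a cubic-spline potential of
#' \code{-log((p + eps) / (p_ref + eps))} over the bin centers, with the
#' terminal in-range bin's probability as the reference, anchoring the
#' potential to zero at the no-contact boundary. Orientation potentials
#' (omega, theta dihedrals; phi angle) are built only for gated pairs,
#' with a uniform reference. Symmetric classes (distance, omega) are built
#' once per unordered pair; theta and phi in both directions. Periodic
#' classes are padded beyond the wrap so the spline covers the full circle.
#'
#' @param G a \code{geom_distributions} object.
#' @param config a [folding_config()].
#' @return object of class \code{restraints}: per class, pair indices,
#'   spline knots \code{x}, values \code{y} and second derivatives
#'   \code{y2}; plus the sequence length.
#' @export
build_potentials <- function(G, config = folding_config()) {
  b <- G$binning
  L <- dim(G$dist)[1]
  eps <- config$eps
  nb_d <- b$dist$n_bins
  contact <- 1 - G$dist[, , nb_d]
  ut <- which(upper.tri(contact) & contact >= config$gate, arr.ind = TRUE)
  gate_mat <- matrix(FALSE, L, L)
  gate_mat[ut] <- TRUE
  gate_mat <- gate_mat | t(gate_mat)

  pot <- list(L = L)

  if (nrow(ut)) {
    # distance: reference = probability of the terminal in-range bin, so the
    # potential is zero at the no-contact boundary (and beyond it) and a
    # half-contact pair keeps a genuine well at its contact distance
    P <- matrix(G$dist, L * L, nb_d)[ut[, 1] + (ut[, 2] - 1L) * L, , drop = FALSE]
    pref <- P[, b$dist$n_in]
    y <- -log((P[, seq_len(b$dist$n_in), drop = FALSE] + eps) /
              (pref + eps))
    pot$dist <- spline_class(ut, b$dist$centers, y)

    # omega: symmetric, once per unordered pair
    pot$omega <- dihedral_class(G$omega, ut, b$omega, eps)
    # theta, phi: directional, both orders
    both <- rbind(ut, ut[, 2:1, drop = FALSE])
    pot$theta <- dihedral_class(G$theta, both, b$theta, eps)

    nb_p <- b$phi$n_bins
    Pp <- matrix(G$phi, L * L, nb_p)[both[, 1] + (both[, 2] - 1L) * L, , drop = FALSE]
    inr <- seq_len(b$phi$n_in)
    mass <- rowSums(Pp[, inr, drop = FALSE])
    yp <- -log((Pp[, inr, drop = FALSE] + eps) / (mass / b$phi$n_in + eps))
    pot$phi <- spline_class(both, b$phi$centers, yp)
  }
  structure(pot, class = "restraints")
}

# spline potentials for a periodic dihedral map: uniform reference over the
# in-range mass, padded by 4 bins on each side across the wrap
dihedral_class <- function(arr, pairs, map, eps, pad = 4L) {
  L <- dim(arr)[1]
  nb <- map$n_bins
  inr <- seq_len(map$n_in)
  P <- matrix(arr, L * L, nb)[pairs[, 1] + (pairs[, 2] - 1L) * L, , drop = FALSE]
  mass <- rowSums(P[, inr, drop = FALSE])
  y <- -log((P[, inr, drop = FALSE] + eps) / (mass / map$n_in + eps))
  n <- map$n_in
  left <- (n - pad + 1L):n
  right <- 1L:pad
  y_ext <- cbind(y[, left, drop = FALSE], y, y[, right, drop = FALSE])
  x_ext <- c(map$centers[left] - 360, map$centers, map$centers[right] + 360)
  spline_class(pairs, x_ext, y_ext)
}

spline_class <- function(pairs, x, y) {
  list(pairs = matrix(as.integer(pairs), ncol = 2),
       x = x, y = y, y2 = cpp_spline_y2(x, y))
}

#' Evaluate a restraint spline at arbitrary geometry values
#'
#' Utility for inspection and testing: evaluates the stored spline of one
#' restraint class at given x values (cubic between knots, linear beyond).
#'
#' @param cls one class entry of a \code{restraints} object (e.g.
#'   \code{pot$dist}).
#' @param row restraint row index.
#' @param t numeric values (Angstrom or degrees).
#' @return spline values at \code{t}.
#' @export
eval_restraint <- function(cls, row, t) {
  spline_value(cls$x, cls$y[row, ], cls$y2[row, ], t)
}

# Direct R-side spline evaluation (mirrors the C++ evaluator)
spline_value <- function(x, y, y2, t) {
  n <- length(x)
  sapply(t, function(tt) {
    if (tt <= x[1]) {
      h <- x[2] - x[1]
      d <- (y[2] - y[1]) / h - h / 6 * (2 * y2[1] + y2[2])
      return(y[1] + d * (tt - x[1]))
    }
    if (tt >= x[n]) {
      h <- x[n] - x[n - 1]
      d <- (y[n] - y[n - 1]) / h + h / 6 * (y2[n - 1] + 2 * y2[n])
      return(y[n] + d * (tt - x[n]))
    }
    k <- min(max(1L, findInterval(tt, x)), n - 1L)
    h <- x[k + 1] - x[k]
    A <- (x[k + 1] - tt) / h; B <- 1 - A
    A * y[k] + B * y[k + 1] +
      ((A^3 - A) * y2[k] + (B^3 - B) * y2[k + 1]) * h^2 / 6
  })
}

#' Physical (restraint-free) energy of a backbone structure
#'
#' Sum of soft-sphere steric repulsion over non-bonded atom pairs
#' (residue separation at least 2), harmonic deviations from ideal bond
#' lengths, angles and impropers, and the peptide-bond planarity penalty
#' (weight 0.5). Non-negative; numerically zero for an ideally built,
#' clash-free chain.
#'
#' @param structure a \code{backbone} object.
#' @return scalar energy with attribute \code{"terms"} (named breakdown).
#' @export
physical_energy <- function(structure) {
  par <- folding_params(list(pair = 0, dihedral = 0, angle = 0,
                             steric = 1, breg = 1, omegator = 0.5))
  r <- cpp_energy(as.vector(t(structure$xyz)), n_residues(structure),
                  list(), par, FALSE)
  structure(r$energy, terms = r$terms)
}

# random-torsion chain initialisation: phi in the L-amino-acid half plane,
# psi unrestricted
random_torsion_chain <- function(L, sequence) {
  phi <- stats::runif(L, -180, 0)
  psi <- stats::runif(L, -180, 180)
  build_backbone(phi, psi, sequence = sequence)
}

#' Fold restraint potentials into a backbone structure
#'
#' Two-stage quasi-Newton (L-BFGS) minimization of the weighted restraint
#' plus physical energy in Cartesian backbone coordinates, starting from a
#' seeded random-torsion chain. Stage 1 uses the stage-1 weights; stage 2
#' re-minimizes the result with the stage-2 weights. A non-finite result
#' triggers one retry with a derived seed, then an error.
#'
#' @param potentials a \code{restraints} object (see [build_potentials()]).
#' @param sequence one-letter sequence of length L.
#' @param config a [folding_config()].
#' @param seed random seed for the torsion initialisation.
#' @param init optional \code{backbone} used as the starting conformation
#'   (warm start) instead of a random-torsion chain; used by the iterative
#'   sampler so that successive minimizations continue from the previous
#'   structure.
#' @return \code{list(structure =, energy =)} where energy is the final
#'   stage-2 total (attribute \code{"terms"} gives the breakdown).
#' @export
fold <- function(potentials, sequence, config = folding_config(),
                 seed = config$seed, init = NULL) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  L <- length(sequence)
  if (!is.null(potentials$L) && potentials$L != L)
    stop("potentials were built for a different sequence length")
  for (attempt in 1:2) {
    use_seed <- if (attempt == 1L) seed else seed + 1000003L
    set.seed(use_seed)
    start <- if (is.null(init) || attempt > 1L)
      random_torsion_chain(L, sequence) else init
    x0 <- as.vector(t(start$xyz))
    res <- tryCatch({
      x1 <- minimize_stage(x0, L, potentials, config$stage1, config)
      x2 <- minimize_stage(x1, L, potentials, config$stage2, config)
      par2 <- folding_params(config$stage2)
      e <- cpp_energy(x2, L, potentials, par2, FALSE)
      if (!is.finite(e$energy)) stop("non-finite energy after minimization")
      list(structure = backbone(sequence, matrix(x2, ncol = 3, byrow = TRUE),
                                validate = FALSE),
           energy = structure(e$energy, terms = e$terms))
    }, error = function(err) err)
    if (!inherits(res, "error")) return(res)
    if (attempt == 2L)
      stop("folding failed after retry: ", conditionMessage(res))
  }
}

minimize_stage <- function(x0, L, potentials, weights, config) {
  par <- folding_params(weights)
  fn <- function(x) cpp_energy(x, L, potentials, par, FALSE)$energy
  gr <- function(x) cpp_energy(x, L, potentials, par, TRUE)$grad
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_iter,
                                     factr = 1e7, pgtol = config$tol))
  opt$par
}

#' Fold an ensemble of independently seeded structures
#'
#' Runs \code{n_runs} independent folds (distinct derived seeds) of the
#' same potentials, emulating repeated restrained energy minimization with
#' random initialisation.
#'
#' @param potentials a \code{restraints} object.
#' @param sequence one-letter sequence.
#' @param config a [folding_config()].
#' @param n_runs number of independent folds (default 50).
#' @param seed base seed; run k uses a seed derived deterministically.
#' @return an [ensemble()] with per-structure energies.
#' @export
fold_ensemble <- function(potentials, sequence, config = folding_config(),
                          n_runs = 50L, seed = config$seed) {
  stopifnot(n_runs >= 1)
  set.seed(seed)
  seeds <- if (n_runs == 1L) seed else sample.int(.Machine$integer.max, n_runs)
  models <- vector("list", n_runs)
  energies <- numeric(n_runs)
  for (k in seq_len(n_runs)) {
    r <- fold(potentials, sequence, config, seed = seeds[k])
    models[[k]] <- r$structure
    energies[k] <- as.numeric(r$energy)
  }
  ensemble(sequence, models, energies)
}

#' Create a folding engine for the sampler
#'
#' Returns a closure \code{function(G, seed, init)} that builds restraint
#' potentials from the geometry distributions and folds them (optionally
#' warm-started from \code{init}), as required by [run_sampling()].
#'
#' @param sequence one-letter sequence.
#' @param config a [folding_config()].
#' @return folding closure.
#' @export
make_folder <- function(sequence, config = folding_config()) {
  force(sequence); force(config)
  function(G, seed, init = NULL) {
    pot <- build_potentials(G, config)
    fold(pot, sequence, config, seed = seed, init = init)
  }
}
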