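# Synthetic toy proteins and multi-modal geometry mixtures. Two-state
# fixtures emulate proteins with significant conformational change
# (inter-state Ca RMSD above 6 Angstrom): a compact helical-hairpin domain
# carries a C-terminal helix arm whose orientation is switched between two
# packed, clash-free poses by rotating the hinge backbone torsions. Mixing
# the smoothed one-hot geometries of the states gives the multi-peaked
# per-pair distributions that drive the decay-and-smooth sampler.

#' Specification of a toy structure fixture
#'
#' @param topology \code{"hinge"} (two-state: helical hairpin domain plus
#'   a swinging C-terminal helix arm), \code{"helix"} (single ideal
#'   helix) or \code{"helix-hairpin"} (single-state hairpin).
#' @param L sequence length (at least 20; at least 36 for
#'   \code{"hinge"}; default 44 for \code{"hinge"}, 30 otherwise).
#' @param hinge hinge residue index (interior; defaults to \code{L - 16}
#'   for \code{"hinge"} so the arm is 16 residues, mid-chain otherwise).
#' @param angle hinge rotation scale (degrees) distinguishing state A
#'   from state B (default 60, which swings the arm by well over the
#'   6 Angstrom inter-state RMSD threshold).
#' @param seed random seed (reserved for perturbed variants).
#' @return object of class \code{toy_spec}.
#' @export
toy_spec <- function(topology = c("hinge", "helix", "helix-hairpin"),
                     L = NULL, hinge = NULL, angle = 60, seed = 1L) {
  topology <- match.arg(topology)
  if (is.null(L)) L <- if (topology == "hinge") 44L else 30L
  L <- as.integer(L)
  if (L < 20L) stop("toy fixtures require L >= 20")
  if (topology == "hinge" && L < 36L) stop("hinge fixtures require L >= 36")
  if (is.null(hinge)) hinge <- if (topology == "hinge") L - 16L else L %/% 2L
  if (hinge <= 2L || hinge >= L - 1L) stop("hinge index must be interior")
  structure(list(topology = topology, L = L, hinge = as.integer(hinge),
                 angle = angle, seed = as.integer(seed)),
            class = "toy_spec")
}

toy_sequence <- function(spec) {
  s <- rep("A", spec$L)
  if (spec$topology %in% c("hinge", "helix-hairpin")) s[spec$hinge] <- "G"
  s
}

# base torsions: helical everywhere, with a 3-residue loop splitting the
# N-terminal region into a hairpin for the hinge and helix-hairpin
# topologies
toy_torsions <- function(spec) {
  L <- spec$L
  phi <- rep(-57, L); psi <- rep(-47, L)
  if (spec$topology == "helix-hairpin") {
    loop <- spec$hinge + (-1L:1L)
    phi[loop] <- c(-80, -120, -100)
    psi[loop] <- c(100, 140, 120)
  }
  if (spec$topology == "hinge") {
    n1 <- (spec$hinge - 4L) %/% 2L
    loop <- n1 + (1L:3L)
    phi[loop] <- c(-80, -120, -100)
    psi[loop] <- c(100, 140, 120)
  }
  list(phi = phi, psi = psi)
}

#' Generate toy reference states
#'
#' Builds ideal-geometry backbones (helices at phi = -57, psi = -47
#' degrees; loops from fixed non-helical torsions). For the two-state
#' \code{"hinge"} topology the chain is a helical hairpin domain followed
#' by a helix arm, and the two states differ only in the hinge residue's
#' backbone torsions: (phi, psi) = (-10 angle / 6, 80 - 4 angle / 6) for
#' state A and (+10 angle / 6, 80 + 4 angle / 6) for state B, a
#' symmetric rotation of the arm between two packed poses on either side
#' of the domain. The construction retries with a larger angle if either
#' state has steric clashes or the inter-state Ca RMSD does not exceed
#' 6 Angstrom.
#'
#' @param spec a [toy_spec()].
#' @return list of \code{backbone} structures (length 1, or 2 for
#'   \code{"hinge"}).
#' @export
make_toy_states <- function(spec) {
  tor <- toy_torsions(spec)
  seqc <- toy_sequence(spec)
  if (spec$topology != "hinge")
    return(list(build_backbone(tor$phi, tor$psi, sequence = seqc)))
  ang <- spec$angle
  for (attempt in 1:6) {
    mk <- function(sgn) {
      phi <- tor$phi; psi <- tor$psi
      phi[spec$hinge] <- sgn * ang * 10 / 6
      psi[spec$hinge] <- 80 + sgn * ang * 4 / 6
      build_backbone(phi, psi, sequence = seqc)
    }
    A <- mk(-1); B <- mk(+1)
    clash <- function(st) unname(attr(physical_energy(st), "terms")["steric"])
    if (clash(A) < 2 && clash(B) < 2 && kabsch_rmsd(A, B) > 6)
      return(list(A, B))
    ang <- ang + 13
  }
  stop("could not build a clash-free two-state hinge with RMSD > 6 A")
}

#' Mix state geometries into multi-modal distributions
#'
#' Each state's pairwise geometries are one-hot discretised, smoothed with
#' a Gaussian of width \code{sigma} bins, and combined as a weighted sum:
#' pairs that differ between states become multi-peaked, while pairs
#' identical across states stay sharp and unimodal (stable under the
#' decay-and-smooth update for the default sigma).
#'
#' @param states list of \code{backbone} structures sharing one sequence.
#' @param weights mixture weights (normalised; default uniform).
#' @param sigma smoothing width in bins (default 0.75, which keeps
#'   state-invariant pairs above the 0.5 stability threshold).
#' @return a \code{geom_distributions} object.
#' @export
mix_geometries <- function(states, weights = NULL, sigma = 0.75) {
  K <- length(states)
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (length(weights) != K) stop("weights and states length mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  weights <- weights / sum(weights)
  seqc <- states[[1]]$sequence
  for (s in states)
    if (!identical(s$sequence, seqc)) stop("states must share one sequence")
  binning <- geometry_binning()
  parts <- lapply(states, function(s) {
    smooth_geometries(discretize(compute_pair_geometries(s), binning,
                                 sequence = seqc), sigma)
  })
  mix <- parts[[1]]
  for (m in GEOM_MAPS) {
    acc <- weights[1] * parts[[1]][[m]]
    if (K > 1) for (k in 2:K) acc <- acc + weights[k] * parts[[k]][[m]]
    mix[[m]] <- acc
  }
  validate_geometries(mix)
  mix
}
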