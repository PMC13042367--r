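# Ensemble evaluation metrics: optimal-superposition RMSD, TM-score,
# ensemble recall / mean-structure RMSD, pairwise diversity, RMSF,
# ensemble order parameters, RDC alignment-tensor fits and Q-factors,
# cross-entropy geometry loss, and restraint-based residue masks.
# All RMSD/TM computations use Ca atoms restricted to the supplied mask.

get_ca <- function(x) {
  if (inherits(x, "backbone")) bb_atom(x, "CA")
  else as.matrix(x)
}

resolve_mask <- function(mask, L) {
  if (is.null(mask)) rep(TRUE, L)
  else { stopifnot(length(mask) == L); as.logical(mask) }
}

# optimal rotation (Kabsch via SVD) aligning centred P onto centred Q
kabsch_rotation <- function(Pc, Qc) {
  C <- crossprod(Pc, Qc)
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# rigid transform of P (full set) fitted on masked rows onto Q's masked rows
superpose_onto <- function(P, Q, mask) {
  cp <- colMeans(P[mask, , drop = FALSE])
  cq <- colMeans(Q[mask, , drop = FALSE])
  R <- kabsch_rotation(sweep(P[mask, , drop = FALSE], 2, cp),
                       sweep(Q[mask, , drop = FALSE], 2, cq))
  list(R = R, cp = cp, cq = cq,
       coords = sweep(sweep(P, 2, cp) %*% t(R), 2, cq, `+`))
}

#' Optimal-superposition (Kabsch) RMSD between two structures
#'
#' Minimal least-squares Ca RMSD over all rigid transforms, computed by
#' singular value decomposition of the covariance of the masked,
#' centred coordinates (proper rotations only).
#'
#' @param A,B \code{backbone} objects or (L x 3) Ca coordinate matrices.
#' @param mask logical length-L residue mask (default all).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B, mask = NULL) {
  P <- get_ca(A); Q <- get_ca(B)
  if (nrow(P) != nrow(Q)) stop("structures have different residue counts")
  mask <- resolve_mask(mask, nrow(P))
  if (sum(mask) < 3L) stop("at least 3 masked residues are required")
  Pc <- sweep(P[mask, , drop = FALSE], 2, colMeans(P[mask, , drop = FALSE]))
  Qc <- sweep(Q[mask, , drop = FALSE], 2, colMeans(Q[mask, , drop = FALSE]))
  R <- kabsch_rotation(Pc, Qc)
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

#' TM-score between two conformations of the same protein
#'
#' Standard TM-score with identity alignment and
#' \code{d0 = 1.24 (L - 15)^(1/3) - 1.8} (floored at 0.5 Angstrom;
#' sequences of 15 or fewer residues use the floor directly), maximised
#' over superpositions seeded from contiguous windows (full, half,
#' quarter length and all 7-residue windows) with iterative refinement on
#' the close-residue subset. Normalised by the masked length.
#'
#' @param A,B \code{backbone} objects or Ca matrices.
#' @param mask logical residue mask.
#' @return score in (0, 1], with attribute \code{"d0"}.
#' @export
tm_score <- function(A, B, mask = NULL) {
  P <- get_ca(A); Q <- get_ca(B)
  if (nrow(P) != nrow(Q)) stop("structures have different residue counts")
  mask <- resolve_mask(mask, nrow(P))
  P <- P[mask, , drop = FALSE]; Q <- Q[mask, , drop = FALSE]
  n <- nrow(P)
  if (n < 4L) stop("at least 4 masked residues are required")
  d0 <- if (n > 15L) max(0.5, 1.24 * (n - 15)^(1 / 3) - 1.8) else 0.5

  score_of <- function(sub) {
    sup <- superpose_onto(P, Q, sub)
    di <- sqrt(rowSums((sup$coords - Q)^2))
    list(score = mean(1 / (1 + (di / d0)^2)), di = di)
  }
  best <- 0
  win_lengths <- unique(pmax(4L, c(n, floor(n / 2), floor(n / 4), 7L)))
  for (Lw in win_lengths) {
    starts <- if (Lw == 7L) seq_len(n - Lw + 1L)
              else unique(c(seq(1L, n - Lw + 1L, by = max(1L, Lw %/% 2)), n - Lw + 1L))
    for (s in starts) {
      sub <- rep(FALSE, n); sub[s:(s + Lw - 1L)] <- TRUE
      for (it in 1:20) {
        r <- score_of(sub)
        if (r$score > best) best <- r$score
        cut <- d0 + 1
        repeat {
          nxt <- r$di < cut
          if (sum(nxt) >= 4L) break
          cut <- cut + 0.5
        }
        if (identical(nxt, sub)) break
        sub <- nxt
      }
    }
  }
  structure(min(best, 1), d0 = d0)
}

#' Ensemble-recall RMSD
#'
#' Mean, over the reference models, of the minimum Ca RMSD between that
#' reference model and any predicted conformer: a coverage ("recall")
#' measure of how well the predicted ensemble reaches every reference
#' state.
#'
#' @param predicted,reference [ensemble()] objects with a common sequence
#'   length.
#' @param mask logical residue mask.
#' @return RMSD in Angstrom.
#' @export
rmsd_rec <- function(predicted, reference, mask = NULL) {
  if (!n_models(predicted)) stop("predicted ensemble is empty")
  mins <- vapply(reference$models, function(ref) {
    min(vapply(predicted$models, function(p) kabsch_rmsd(ref, p, mask),
               numeric(1)))
  }, numeric(1))
  mean(mins)
}

#' Iteratively superpose an ensemble onto its mean conformation
#'
#' Alternates between superposing every model onto the current mean (over
#' masked Ca) and recomputing the mean, until the mean moves less than
#' \code{tol} (max displacement).
#'
#' @param ens an [ensemble()].
#' @param mask logical residue mask used for fitting.
#' @param tol convergence tolerance in Angstrom (default 1e-6).
#' @return list with \code{mean} (L x 3 mean Ca coordinates), \code{ca}
#'   (list of aligned Ca matrices), \code{transforms} (per-model R, cp,
#'   cq) and \code{iterations}.
#' @export
superpose_ensemble <- function(ens, mask = NULL, tol = 1e-6) {
  cas <- lapply(ens$models, get_ca)
  L <- nrow(cas[[1]])
  mask <- resolve_mask(mask, L)
  if (sum(mask) < 3L) stop("at least 3 masked residues are required")
  ref <- cas[[1]]
  transforms <- NULL
  for (it in 1:200) {
    sup <- lapply(cas, function(P) superpose_onto(P, ref, mask))
    aligned <- lapply(sup, `[[`, "coords")
    m <- Reduce(`+`, aligned) / length(aligned)
    shift <- max(abs(m - ref))
    ref <- m
    transforms <- sup
    if (shift < tol) break
  }
  list(mean = ref, ca = lapply(transforms, `[[`, "coords"),
       transforms = lapply(transforms, function(s) s[c("R", "cp", "cq")]),
       iterations = it)
}

#' Mean RMSD to the reference mean conformation
#'
#' Mean Ca RMSD of every predicted conformer to the coordinate-average
#' reference conformation (the reference ensemble is first iteratively
#' superposed onto its converged mean).
#'
#' @inheritParams rmsd_rec
#' @return RMSD in Angstrom.
#' @export
rmsd_mean <- function(predicted, reference, mask = NULL) {
  if (!n_models(predicted)) stop("predicted ensemble is empty")
  m <- superpose_ensemble(reference, mask)$mean
  mean(vapply(predicted$models, function(p) kabsch_rmsd(p, m, mask),
              numeric(1)))
}

#' Mean pairwise RMSD within an ensemble (diversity)
#'
#' @param ens an [ensemble()] with at least two models.
#' @param mask logical residue mask.
#' @return mean Ca RMSD over all unordered model pairs, Angstrom.
#' @export
pairwise_diversity <- function(ens, mask = NULL) {
  n <- n_models(ens)
  if (n < 2L) stop("diversity requires at least 2 structures")
  tot <- 0; cnt <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    tot <- tot + kabsch_rmsd(ens$models[[a]], ens$models[[b]], mask)
    cnt <- cnt + 1
  }
  tot / cnt
}

#' Per-residue root mean square fluctuation
#'
#' The ensemble is iteratively superposed onto its mean over the masked
#' residues; RMSF at residue j is the root-mean-square deviation of its Ca
#' position from the ensemble-mean position.
#'
#' @param ens an [ensemble()] with at least two models.
#' @param mask logical residue mask used for superposition.
#' @return numeric vector of per-residue RMSF (Angstrom), all residues.
#' @export
rmsf <- function(ens, mask = NULL) {
  if (n_models(ens) < 2L) stop("RMSF requires at least 2 structures")
  sup <- superpose_ensemble(ens, mask)
  dev2 <- lapply(sup$ca, function(P) rowSums((P - sup$mean)^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}

#' Amide N-H unit vectors by geometric hydrogen placement
#'
#' The amide hydrogen of residue i (i >= 2, non-proline) is placed in the
#' C(i-1)-N-CA plane, opposite the bisector of the C(i-1)-N-CA angle, at
#' an N-H distance of 1.01 Angstrom. Residue 1 and prolines are undefined
#' (\code{NA} rows).
#'
#' @param structure a \code{backbone} object.
#' @return (L x 3) matrix of unit N-H vectors (NA rows where undefined).
#' @export
place_amide_vectors <- function(structure) {
  L <- n_residues(structure)
  N <- bb_atom(structure, "N"); CA <- bb_atom(structure, "CA")
  C <- bb_atom(structure, "C")
  mu <- matrix(NA_real_, L, 3)
  for (i in 2:L) {
    if (structure$sequence[i] == "P") next
    u1 <- C[i - 1, ] - N[i, ]; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- CA[i, ] - N[i, ];    u2 <- u2 / sqrt(sum(u2^2))
    h <- -(u1 + u2)
    nh <- sqrt(sum(h^2))
    if (nh < 1e-8) next
    mu[i, ] <- h / nh
  }
  mu
}

#' Ensemble generalized order parameters
#'
#' S2 for residue j is the squared norm of the ensemble-averaged amide
#' N-H unit vector over all conformers: 1 for a direction identical in
#' every model, 0 for fully disordered directions. The ensemble is first
#' superposed into a common frame (iterative fit onto the mean over the
#' masked residues).
#'
#' @param ens an [ensemble()].
#' @param mask logical residue mask used for superposition.
#' @return per-residue S2 in [0, 1]; \code{NA} where the N-H vector is
#'   undefined in any model (residue 1, prolines).
#' @export
s2_ensemble <- function(ens, mask = NULL) {
  sup <- superpose_ensemble(ens, mask)
  mus <- mapply(function(model, tr) {
    mu <- place_amide_vectors(model)
    mu %*% t(tr$R)                      # rotate vectors into common frame
  }, ens$models, sup$transforms, SIMPLIFY = FALSE)
  avg <- Reduce(`+`, mus) / length(mus)
  s2 <- rowSums(avg^2)
  s2[!stats::complete.cases(avg)] <- NA_real_
  pmin(s2, 1)
}

#' Fit an RDC alignment tensor to an ensemble and compute the Q-factor
#'
#' Least-squares fit of the five independent elements of the symmetric
#' traceless alignment tensor to experimental H-N residual dipolar
#' couplings, using ensemble-averaged direction-cosine products of the
#' amide bond vectors (one shared tensor across all conformers). The
#' Q-factor is RMS(D_exp - D_calc) / RMS(D_exp).
#'
#' @param ens an [ensemble()].
#' @param rdc data frame with columns \code{residue} and \code{coupling}
#'   (Hz); see [read_rdc_table()].
#' @param mask logical residue mask used for the common-frame
#'   superposition.
#' @return list with \code{tensor} (3 x 3 symmetric traceless matrix),
#'   \code{elements} (the five fitted coefficients), \code{q}, and
#'   \code{d_calc}.
#' @export
fit_tensor_and_q <- function(ens, rdc, mask = NULL) {
  stopifnot(all(c("residue", "coupling") %in% names(rdc)))
  if (anyDuplicated(rdc$residue)) stop("duplicate residue indices in RDC table")
  L <- length(ens$sequence)
  if (any(rdc$residue < 1 | rdc$residue > L)) stop("RDC residue index out of range")
  sup <- superpose_ensemble(ens, mask)
  mus <- mapply(function(model, tr) place_amide_vectors(model) %*% t(tr$R),
                ens$models, sup$transforms, SIMPLIFY = FALSE)
  basis_one <- function(mu) {
    cbind(mu[, 1]^2 - mu[, 3]^2, mu[, 2]^2 - mu[, 3]^2,
          2 * mu[, 1] * mu[, 2], 2 * mu[, 1] * mu[, 3], 2 * mu[, 2] * mu[, 3])
  }
  Bavg <- Reduce(`+`, lapply(mus, basis_one)) / length(mus)
  rows <- rdc$residue
  ok <- stats::complete.cases(Bavg[rows, , drop = FALSE])
  if (sum(ok) < 5L)
    stop("need at least 5 RDC records on residues with defined amide vectors")
  X <- Bavg[rows[ok], , drop = FALSE]
  y <- rdc$coupling[ok]
  sv <- svd(X)
  if (min(sv$d) < 1e-10 * max(sv$d))
    stop("rank-deficient design: fewer than 5 independent bond orientations")
  coef <- solve(crossprod(X), crossprod(X, y))[, 1]
  d_calc <- as.vector(X %*% coef)
  q <- sqrt(mean((y - d_calc)^2)) / sqrt(mean(y^2))
  A <- matrix(c(coef[1], coef[3], coef[4],
                coef[3], coef[2], coef[5],
                coef[4], coef[5], -coef[1] - coef[2]), 3, 3)
  list(tensor = A, elements = coef, q = q, d_calc = d_calc,
       residues = rows[ok])
}

#' Minimum cross-entropy loss of predicted geometries over conformations
#'
#' For each candidate conformation, the mean cross-entropy between the
#' predicted per-pair geometry distributions and the conformation's
#' one-hot geometries is computed over all residue pairs and all four
#' maps, scaled by 1 / (4 N^2); the minimum over conformations is
#' returned. Predicted probabilities are floored at \code{eps} inside the
#' log.
#'
#' @param predicted a \code{geom_distributions} object.
#' @param conformations an [ensemble()] (or list of \code{backbone}s).
#' @param eps probability floor (default 1e-8).
#' @return scalar loss, with attribute \code{"which"} (argmin index).
#' @export
nmr_min_loss <- function(predicted, conformations, eps = 1e-8) {
  models <- if (inherits(conformations, "ensemble")) conformations$models
            else conformations
  if (!length(models)) stop("no conformations supplied")
  L <- dim(predicted$dist)[1]
  b <- predicted$binning
  losses <- vapply(models, function(S) {
    if (n_residues(S) != L) stop("conformation length mismatch")
    idx <- discretize_indices(compute_pair_geometries(S), b)
    tot <- 0
    for (m in GEOM_MAPS) {
      P <- matrix(predicted[[m]], L * L, b[[m]]$n_bins)
      p_hit <- P[cbind(seq_len(L * L), as.vector(idx[[m]]))]
      tot <- tot + sum(-log(pmax(p_hit, eps)))
    }
    tot / (4 * L^2)
  }, numeric(1))
  structure(min(losses), which = which.min(losses))
}

#' Well-restrained residue mask from an NOE restraint pair list
#'
#' A residue is well restrained iff it participates in at least two
#' restraints whose sequence separation |i - j| is at least 2
#' (non-sequential contacts).
#'
#' @param restraint_pairs two-column matrix or data frame of residue index
#'   pairs (1-based).
#' @param L sequence length.
#' @return logical vector of length L with attribute
#'   \code{"provenance" = "well-restrained"}.
#' @export
well_restrained_mask <- function(restraint_pairs, L) {
  rp <- as.matrix(restraint_pairs)[, 1:2, drop = FALSE]
  storage.mode(rp) <- "integer"
  if (nrow(rp) && (any(rp < 1L) || any(rp > L)))
    stop("restraint index out of range [1, L]")
  count <- integer(L)
  if (nrow(rp)) {
    keep <- abs(rp[, 1] - rp[, 2]) >= 2L
    for (r in which(keep)) {
      count[rp[r, 1]] <- count[rp[r, 1]] + 1L
      count[rp[r, 2]] <- count[rp[r, 2]] + 1L
    }
  }
  structure(count >= 2L, provenance = "well-restrained")
}

#' Conformational-diversity predicate for an ensemble
#'
#' TRUE iff the minimum pairwise TM-score is strictly below 0.8 or the
#' maximum pairwise Ca RMSD strictly exceeds 6 Angstrom (significant
#' conformational heterogeneity). The pairwise TM-score is symmetrised as
#' min(TM(a, b), TM(b, a)).
#'
#' @param ens an [ensemble()] with at least two models.
#' @param mask logical residue mask.
#' @param tm_cutoff,rmsd_cutoff thresholds (defaults 0.8 and 6).
#' @return logical scalar.
#' @export
diversity_predicate <- function(ens, mask = NULL, tm_cutoff = 0.8,
                                rmsd_cutoff = 6) {
  n <- n_models(ens)
  if (n < 2L) stop("diversity predicate requires at least 2 structures")
  min_tm <- Inf; max_rmsd <- -Inf
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    tm <- min(as.numeric(tm_score(ens$models[[a]], ens$models[[b]], mask)),
              as.numeric(tm_score(ens$models[[b]], ens$models[[a]], mask)))
    min_tm <- min(min_tm, tm)
    max_rmsd <- max(max_rmsd, kabsch_rmsd(ens$models[[a]], ens$models[[b]], mask))
  }
  (min_tm < tm_cutoff) || (max_rmsd > rmsd_cutoff)
}
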