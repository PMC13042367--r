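# Heuristic iterative sampling: fold the current geometry distributions,
# then decay each unstable per-pair distribution at the bin realised by the
# folded structure, renormalise and Gaussian-smooth. Stable distributions
# (L-inf norm at or above the stability threshold) are kept bit-identical,
# so sharp geometries are exact fixed points of the update.

#' Sampler configuration
#'
#' @param stability_threshold L-inf norm at or above which a per-pair
#'   distribution is considered stable and left untouched (default 0.5).
#' @param tol convergence tolerance on the maximum absolute per-bin change
#'   over all pairs and maps (default 0.01).
#' @param sigma Gaussian smoothing width in bins applied after each decay
#'   (default 1 bin).
#' @param max_iter iteration cap per chain (default 200).
#' @param seed base random seed.
#' @param chains number of independent seeded sampling chains; their
#'   histories are concatenated (default 1).
#' @return object of class \code{sampler_config}.
#' @export
sampler_config <- function(stability_threshold = 0.5, tol = 0.01, sigma = 1.0,
                           max_iter = 200L, seed = 1L, chains = 1L) {
  stopifnot(stability_threshold > 0, stability_threshold <= 1,
            tol > 0, sigma >= 0, max_iter >= 1, chains >= 1)
  structure(list(stability_threshold = stability_threshold, tol = tol,
                 sigma = sigma, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), chains = as.integer(chains)),
            class = "sampler_config")
}

#' Decay-and-smooth update of one per-pair distribution
#'
#' If \code{max(p) >= stability_threshold} the input is returned unchanged
#' (bit-identical). Otherwise half of the probability mass at the bin
#' realised by the current structure is removed
#' (\code{p - 0.5 * p * s_onehot}), the vector is renormalised, and then
#' Gaussian-smoothed.
#'
#' @param p probability vector (normalised, catch-all last).
#' @param s_onehot one-hot vector of the realised bin, same length.
#' @param config a [sampler_config()].
#' @param periodic whether the map is angular-periodic (for smoothing).
#' @return updated probability vector.
#' @export
update_distribution <- function(p, s_onehot, config = sampler_config(),
                                periodic = FALSE) {
  if (length(p) != length(s_onehot))
    stop("distribution and one-hot lengths differ")
  if (max(p) >= config$stability_threshold) return(p)
  q <- p - 0.5 * p * s_onehot
  q <- q / sum(q)
  smooth_probability(q, config$sigma, periodic = periodic)
}

# Vectorised update of all pairs of all four maps, given the (L x L)
# realised-bin index matrices of the current structure.
update_geometries <- function(G, idx, config) {
  b <- G$binning
  L <- dim(G$dist)[1]
  for (m in GEOM_MAPS) {
    nb <- b[[m]]$n_bins
    n_in <- b[[m]]$n_in
    M <- matrix(G[[m]], L * L, nb)
    unstable <- which(apply(M, 1L, max) < config$stability_threshold)
    if (length(unstable)) {
      U <- M[unstable, , drop = FALSE]
      k <- as.vector(idx[[m]])[unstable]
      sel <- cbind(seq_along(unstable), k)
      U[sel] <- 0.5 * U[sel]
      U <- U / rowSums(U)
      if (config$sigma > 0) {
        S <- smoothing_matrix(n_in, config$sigma, b[[m]]$periodic)
        U[, seq_len(n_in)] <- U[, seq_len(n_in), drop = FALSE] %*% t(S)
        U <- U / rowSums(U)
      }
      M[unstable, ] <- U
      G[[m]] <- array(M, dim = c(L, L, nb))
    }
  }
  G
}

#' Convergence check between two geometry-distribution sets
#'
#' TRUE iff the maximum absolute per-bin change over all pairs and all four
#' maps (an L-inf norm) is strictly below \code{tol}.
#'
#' @param G_prev,G_next \code{geom_distributions} of identical shape.
#' @param tol tolerance (default 0.01).
#' @return logical scalar, with attribute \code{"delta"} holding the max
#'   change.
#' @export
check_convergence <- function(G_prev, G_next, tol = 0.01) {
  delta <- 0
  for (m in GEOM_MAPS) {
    if (!identical(dim(G_prev[[m]]), dim(G_next[[m]])))
      stop("shape mismatch in map ", m)
    delta <- max(delta, max(abs(G_prev[[m]] - G_next[[m]])))
  }
  structure(delta < tol, delta = delta)
}

#' Create a sampler state
#'
#' Bundles the current iteration index, geometry distributions, latest
#' structure and energy, the history of all visited structures, and the
#' convergence flag.
#'
#' @param G current \code{geom_distributions}.
#' @param structure latest folded \code{backbone}.
#' @param energy its energy.
#' @return object of class \code{sampler_state}.
#' @export
sampler_state <- function(G, structure, energy) {
  structure(list(n = 0L, G = G, S = structure, energy = as.numeric(energy),
                 history = list(list(structure = structure,
                                     energy = as.numeric(energy))),
                 converged = FALSE),
            class = "sampler_state")
}

#' @export
print.sampler_state <- function(x, ...) {
  cat(sprintf("<sampler_state> iteration %d, %d structure(s), converged: %s\n",
              x$n, length(x$history), x$converged))
  invisible(x)
}

#' One iteration of the decay-and-smooth sampler
#'
#' Computes the one-hot geometries realised by the current structure,
#' applies the decay-and-smooth update to every unstable per-pair
#' distribution of every map, then generates the next conformation by
#' restrained minimization: one run continued from the current structure
#' and one from a fresh seeded random chain, keeping whichever reaches the
#' lower energy (randomised initialisation with local continuation). The
#' new structure is appended to the history; the convergence flag records
#' whether the distribution change fell below \code{config$tol}. A folding
#' failure aborts the step, returning the prior state unchanged with an
#' \code{"error"} attribute.
#'
#' @param state a [sampler_state()].
#' @param folder folding engine \code{function(G, seed, init)}; see
#'   [make_folder()].
#' @param config a [sampler_config()].
#' @param seed seed for this step's cold fold (default derived from
#'   \code{config$seed} and the iteration index).
#' @return the updated \code{sampler_state}.
#' @export
sampling_step <- function(state, folder, config = sampler_config(),
                          seed = NULL) {
  if (is.null(seed)) seed <- (config$seed + 7919L * (state$n + 1L)) %% .Machine$integer.max
  idx <- discretize_indices(compute_pair_geometries(state$S), state$G$binning)
  G_next <- update_geometries(state$G, idx, config)
  conv <- check_convergence(state$G, G_next, config$tol)
  res <- tryCatch({
    warm <- folder(G_next, seed, init = state$S)
    cold <- folder(G_next, seed)
    if (as.numeric(warm$energy) <= as.numeric(cold$energy)) warm else cold
  }, error = function(e) e)
  if (inherits(res, "error")) {
    attr(state, "error") <- conditionMessage(res)
    return(state)
  }
  state$n <- state$n + 1L
  state$G <- G_next
  state$S <- res$structure
  state$energy <- as.numeric(res$energy)
  state$history[[state$n + 1L]] <- list(structure = res$structure,
                                        energy = as.numeric(res$energy))
  state$converged <- isTRUE(conv)
  attr(state, "delta") <- attr(conv, "delta")
  state
}

#' Run the iterative decay-and-smooth sampler
#'
#' Starting from geometry distributions \code{G0}, folds an initial
#' structure from a random chain, then iterates [sampling_step()] --
#' suppressing the realised geometry of the latest structure in every
#' unstable per-pair distribution and re-minimizing -- until the
#' distributions converge (max change below \code{config$tol}) or the
#' iteration cap is reached (warning, not an error). All structures
#' visited are collected, with their energies, into the returned ensemble.
#' With \code{config$chains} greater than 1, independent seeded chains are
#' run and their histories concatenated.
#'
#' @param G0 initial \code{geom_distributions}.
#' @param folder a folding engine: \code{function(G, seed, init)}
#'   returning \code{list(structure =, energy =)}; see [make_folder()].
#' @param config a [sampler_config()].
#' @return an [ensemble()] with per-structure energies; attribute
#'   \code{"trace"} is a data frame with chain, iteration, energy and the
#'   distribution change of each step.
#' @export
run_sampling <- function(G0, folder, config = sampler_config()) {
  validate_geometries(G0)
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max, config$chains)
  models <- list(); energies <- numeric(0)
  trace <- list()
  for (ch in seq_len(config$chains)) {
    set.seed(chain_seeds[ch])
    fold_seeds <- sample.int(.Machine$integer.max, config$max_iter + 1L)
    s0 <- folder(G0, fold_seeds[1L])
    state <- sampler_state(G0, s0$structure, s0$energy)
    trace[[length(trace) + 1L]] <-
      data.frame(chain = ch, iteration = 0L, energy = state$energy,
                 delta = NA_real_, converged = FALSE)
    for (n in seq_len(config$max_iter)) {
      nxt <- sampling_step(state, folder, config, seed = fold_seeds[n + 1L])
      if (!is.null(attr(nxt, "error"))) {
        warning(sprintf("chain %d: folding failed at iteration %d (%s); chain stopped",
                        ch, n, attr(nxt, "error")))
        break
      }
      state <- nxt
      trace[[length(trace) + 1L]] <-
        data.frame(chain = ch, iteration = n, energy = state$energy,
                   delta = attr(state, "delta"), converged = state$converged)
      if (state$converged) break
    }
    if (!state$converged && config$max_iter > 1L)
      warning(sprintf("chain %d reached the iteration cap (%d) without convergence",
                      ch, config$max_iter))
    models <- c(models, lapply(state$history, `[[`, "structure"))
    energies <- c(energies, vapply(state$history, `[[`, numeric(1), "energy"))
  }
  ens <- ensemble(G0$sequence, models, energies)
  attr(ens, "trace") <- do.call(rbind, trace)
  ens
}

#' Filter energetic outliers from an ensemble
#'
#' Retains exactly the structures whose energy is at most
#' Q3 + (Q3 - Q1), with quartiles computed by linear interpolation
#' (\code{stats::quantile} type 7). Ensembles with fewer than four members
#' are returned unchanged with a warning.
#'
#' @param ens an [ensemble()] with finite energies.
#' @return the filtered ensemble; attribute \code{"threshold"} holds the
#'   energy cutoff.
#' @export
energy_filter <- function(ens) {
  e <- ens$energies
  if (is.null(e) || !all(is.finite(e))) stop("ensemble must carry finite energies")
  if (length(e) < 4L) {
    warning("fewer than 4 structures; energy filter skipped")
    return(ens)
  }
  q <- stats::quantile(e, c(0.25, 0.75), names = FALSE, type = 7)
  thr <- q[2] + (q[2] - q[1])
  keep <- which(e <= thr)
  out <- ensemble(ens$sequence, ens$models[keep], e[keep])
  attr(out, "threshold") <- thr
  out
}

#' Construct a conformational ensemble
#'
#' @param sequence shared one-letter sequence.
#' @param models list of \code{backbone} structures.
#' @param energies optional numeric vector of per-structure energies.
#' @return object of class \code{ensemble}.
#' @export
ensemble <- function(sequence, models, energies = NULL) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (!length(models)) stop("ensemble must contain at least one structure")
  L <- length(sequence)
  for (k in seq_along(models))
    if (n_residues(models[[k]]) != L)
      stop(sprintf("model %d has %d residues, expected %d",
                   k, n_residues(models[[k]]), L))
  if (!is.null(energies) && length(energies) != length(models))
    stop("energies and models length mismatch")
  structure(list(sequence = sequence, models = models, energies = energies),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d models, %d residues\n",
              length(x$models), length(x$sequence)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens an [ensemble()].
#' @return integer count.
#' @export
n_models <- function(ens) length(ens$models)
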