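# Backbone structures: per residue N, CA, C, O, CB coordinates plus sequence.
# Coordinates are stored as a (5L x 3) matrix, atoms in residue-major order.

BB_ATOMS <- c("N", "CA", "C", "O", "CB")

#' Ideal backbone geometry constants
#'
#' Bond lengths (Angstrom) and bond angles (degrees) of the idealised
#' backbone used both by the chain builder and by the harmonic
#' backbone-regularity terms of the physical energy, so that an ideally
#' built chain has (numerically) zero bonded energy.
#'
#' @return named list of bond lengths \code{b_*} and angles \code{a_*}.
#' @export
ideal_geometry <- function() {
  list(
    b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_CACB = 1.522,
    a_NCAC = 111.0, a_CACN = 116.2, a_CNCA = 121.7,
    a_CACO = 120.8, a_OCN = 123.0
  )
}

#' Construct a backbone structure object
#'
#' @param sequence one-letter amino-acid string or character vector (length L).
#' @param xyz numeric (5L x 3) coordinate matrix, atoms ordered
#'   N, CA, C, O, CB within each residue.
#' @param validate check invariants (finite coordinates, CA-CA spacing).
#' @return object of class \code{backbone}.
#' @export
backbone <- function(sequence, xyz, validate = TRUE) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  L <- length(sequence)
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != 5L * L || ncol(xyz) != 3L)
    stop(sprintf("xyz must be a (%d x 3) matrix for L = %d", 5L * L, L))
  obj <- structure(list(sequence = sequence, xyz = xyz), class = "backbone")
  if (validate) validate_backbone(obj)
  obj
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %d residues: %s%s\n", n_residues(x),
              paste(utils::head(x$sequence, 20L), collapse = ""),
              if (n_residues(x) > 20L) "..." else ""))
  invisible(x)
}

#' Number of residues in a backbone or ensemble
#' @param x a \code{backbone} or \code{ensemble} object.
#' @return integer residue count.
#' @export
n_residues <- function(x) {
  if (inherits(x, "ensemble")) length(x$sequence)
  else length(x$sequence)
}

#' Extract the coordinates of one backbone atom type
#'
#' @param x a \code{backbone} object.
#' @param atom one of \code{"N"}, \code{"CA"}, \code{"C"}, \code{"O"},
#'   \code{"CB"}.
#' @return (L x 3) coordinate matrix.
#' @export
bb_atom <- function(x, atom) {
  k <- match(atom, BB_ATOMS)
  if (is.na(k)) stop("unknown backbone atom: ", atom)
  L <- n_residues(x)
  x$xyz[(seq_len(L) - 1L) * 5L + k, , drop = FALSE]
}

#' Validate backbone invariants
#'
#' Checks that all coordinates are finite and that consecutive CA-CA
#' distances lie in the 2.8--4.2 Angstrom window (cis/trans peptide
#' tolerance).
#'
#' @param x a \code{backbone} object.
#' @param strict error (default) rather than warn on CA-CA violations.
#' @return \code{x}, invisibly.
#' @export
validate_backbone <- function(x, strict = TRUE) {
  if (!all(is.finite(x$xyz))) stop("backbone has non-finite coordinates")
  ca <- bb_atom(x, "CA")
  if (nrow(ca) > 1L) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
    bad <- which(d < 2.8 | d > 4.2)
    if (length(bad)) {
      msg <- sprintf("CA-CA distance out of [2.8, 4.2] A at %d position(s), e.g. %.2f A after residue %d",
                     length(bad), d[bad[1]], bad[1])
      if (strict) stop(msg) else warning(msg)
    }
  }
  invisible(x)
}

# NeRF placement: position atom D given A-B-C, |CD|, angle BCD (deg),
# torsion ABCD (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build a backbone from torsion angles
#'
#' Places N, CA, C by natural-extension (NeRF) using ideal bond lengths and
#' angles, then adds the carbonyl O in the peptide plane and a virtual CB by
#' the tetrahedral construction from N, CA, C. The first phi and the last
#' psi/omega only affect terminal atom placement.
#'
#' @param phi,psi numeric vectors of length L (degrees).
#' @param omega peptide-bond torsions, length L (last unused) or scalar;
#'   default 180 (trans).
#' @param sequence one-letter sequence (defaults to poly-alanine).
#' @return a \code{backbone} object.
#' @export
build_backbone <- function(phi, psi, omega = 180, sequence = NULL) {
  L <- length(phi)
  if (length(psi) != L) stop("phi and psi must have equal length")
  if (length(omega) == 1L) omega <- rep(omega, L)
  if (is.null(sequence)) sequence <- rep("A", L)
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  ig <- ideal_geometry()

  n  <- matrix(0, L, 3); ca <- matrix(0, L, 3); cc <- matrix(0, L, 3)
  n[1, ]  <- c(0, 0, 0)
  ca[1, ] <- c(ig$b_NCA, 0, 0)
  th <- ig$a_NCAC * pi / 180
  cc[1, ] <- ca[1, ] + ig$b_CAC * c(-cos(th), sin(th), 0)
  for (i in 2:L) {
    n[i, ]  <- place_atom(n[i - 1, ], ca[i - 1, ], cc[i - 1, ],
                          ig$b_CN, ig$a_CACN, psi[i - 1])
    ca[i, ] <- place_atom(ca[i - 1, ], cc[i - 1, ], n[i, ],
                          ig$b_NCA, ig$a_CNCA, omega[i - 1])
    cc[i, ] <- place_atom(cc[i - 1, ], n[i, ], ca[i, ],
                          ig$b_CAC, ig$a_NCAC, phi[i])
  }
  o <- matrix(0, L, 3)
  for (i in 1:L)
    o[i, ] <- place_atom(n[i, ], ca[i, ], cc[i, ], ig$b_CO, ig$a_CACO,
                         psi[i] + 180)
  cb <- virtual_cb(n, ca, cc)

  xyz <- matrix(0, 5L * L, 3)
  for (i in 1:L) {
    xyz[(i - 1L) * 5L + 1L, ] <- n[i, ]
    xyz[(i - 1L) * 5L + 2L, ] <- ca[i, ]
    xyz[(i - 1L) * 5L + 3L, ] <- cc[i, ]
    xyz[(i - 1L) * 5L + 4L, ] <- o[i, ]
    xyz[(i - 1L) * 5L + 5L, ] <- cb[i, ]
  }
  backbone(sequence, xyz)
}

#' Virtual CB placement from backbone N, CA, C
#'
#' Standard tetrahedral construction of the beta-carbon position from the
#' backbone frame (used for glycine and for idealised chain building),
#' rescaled to an exact CA-CB bond length of 1.522 Angstrom.
#'
#' @param n,ca,c (L x 3) coordinate matrices (single rows accepted).
#' @return (L x 3) matrix of CB coordinates.
#' @export
virtual_cb <- function(n, ca, c) {
  n <- rbind(n); ca <- rbind(ca); c <- rbind(c)
  b <- ca - n
  cv <- c - ca
  a <- cbind(b[, 2] * cv[, 3] - b[, 3] * cv[, 2],
             b[, 3] * cv[, 1] - b[, 1] * cv[, 3],
             b[, 1] * cv[, 2] - b[, 2] * cv[, 1])
  raw <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cv
  len <- sqrt(rowSums(raw^2))
  ca + (ideal_geometry()$b_CACB / len) * raw
}
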