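#' Binning scheme for pairwise backbone geometries
#'
#' Defines the discretization used for the four per-pair geometry maps:
#' the Cb-Cb distance \code{d}, the dihedrals \code{omega} and \code{theta},
#' and the planar angle \code{phi}. Distances are binned in 36 uniform
#' 0.5-Angstrom bins over [2, 20) plus a terminal catch-all ("no contact")
#' bin; \code{omega} and \code{theta} in 24 periodic 15-degree bins over
#' [-180, 180) plus a catch-all; \code{phi} in 12 non-periodic 15-degree
#' bins over [0, 180] plus a catch-all. The catch-all bin is always the
#' last index and is categorical: it never takes part in smoothing.
#'
#' @return An object of class \code{geometry_binning}: a named list with one
#'   entry per map (\code{dist}, \code{omega}, \code{theta}, \code{phi}),
#'   each holding \code{edges}, \code{centers}, \code{n_bins} (including the
#'   catch-all), \code{n_in} (in-range bins) and a \code{periodic} flag.
#' @export
geometry_binning <- function() {
  mk <- function(edges, periodic) {
    list(
      edges    = edges,
      centers  = (edges[-1] + edges[-length(edges)]) / 2,
      n_in     = length(edges) - 1L,
      n_bins   = length(edges),       # in-range bins + catch-all
      periodic = periodic
    )
  }
  structure(list(
    dist  = mk(seq(2, 20, by = 0.5),     periodic = FALSE),
    omega = mk(seq(-180, 180, by = 15),  periodic = TRUE),
    theta = mk(seq(-180, 180, by = 15),  periodic = TRUE),
    phi   = mk(seq(0, 180, by = 15),     periodic = FALSE)
  ), class = "geometry_binning")
}

#' Map geometry values to bin indices
#'
#' Vectorised lookup of the bin index for a vector of geometry values under
#' one map of the binning scheme. \code{NA} values (undefined geometry, e.g.
#' degenerate dihedrals or the matrix diagonal) map to the catch-all bin;
#' distances at or beyond the last edge map to the catch-all bin; angular
#' values are wrapped into the map's domain first.
#'
#' @param x numeric vector of geometry values (Angstrom or degrees).
#' @param map one entry of [geometry_binning()] (e.g. \code{$dist}).
#' @param map_name name used in error messages.
#' @return integer vector of 1-based bin indices (catch-all = \code{n_bins}).
#' @export
bin_index <- function(x, map, map_name = "geometry") {
  bad <- is.nan(x) | is.infinite(x)
  if (any(bad)) {
    stop(sprintf("non-finite %s value at position(s) %s", map_name,
                 paste(utils::head(which(bad), 5L), collapse = ", ")))
  }
  idx <- rep(map$n_bins, length(x))       # default: catch-all
  ok <- !is.na(x)
  v <- x[ok]
  if (map$periodic) {
    # wrap into [-180, 180)
    v <- ((v + 180) %% 360) - 180
    k <- findInterval(v, map$edges, rightmost.closed = FALSE)
    k[k > map$n_in] <- map$n_in
    k[k < 1L] <- 1L
  } else if (map$edges[1] == 0) {         # phi: [0, 180], right edge closed
    k <- findInterval(v, map$edges, rightmost.closed = TRUE)
    k[k < 1L] <- 1L
    k[k > map$n_in] <- map$n_in
  } else {                                # distance: clamp short, catch-all far
    k <- findInterval(v, map$edges)
    k[k < 1L] <- 1L                       # d < first edge: first bin
    k[k > map$n_in] <- map$n_bins         # d >= last edge: no-contact
  }
  idx[ok] <- k
  as.integer(idx)
}
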