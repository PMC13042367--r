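# Readers and writers: multi-model backbone PDB files, the geometry
# container, and the plain-text RDC / restraint tables. Residue numbering
# is 1-based and contiguous internally.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)

#' Write an ensemble as a multi-model PDB file
#'
#' Standard MODEL/ENDMDL records with fixed-width ATOM fields for the five
#' backbone atoms per residue (glycine CB is written as a virtual atom).
#' Per-model energies, when present, are emitted as
#' \code{REMARK 250 ENERGY} lines inside each model block.
#'
#' @param ens an [ensemble()] (a single \code{backbone} is promoted).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  if (inherits(ens, "backbone")) ens <- ensemble(ens$sequence, list(ens))
  con <- file(path, "w")
  on.exit(close(con))
  L <- length(ens$sequence)
  res3 <- AA3[ens$sequence]
  res3[is.na(res3)] <- "UNK"
  for (mdl in seq_along(ens$models)) {
    writeLines(sprintf("MODEL     %4d", mdl), con)
    if (!is.null(ens$energies))
      writeLines(sprintf("REMARK 250 ENERGY %.6f", ens$energies[mdl]), con)
    xyz <- ens$models[[mdl]]$xyz
    serial <- 0L
    lines <- character(5L * L)
    for (i in seq_len(L)) {
      for (k in seq_along(BB_ATOMS)) {
        serial <- serial + 1L
        p <- xyz[(i - 1L) * 5L + k, ]
        lines[serial] <- sprintf(
          "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", BB_ATOMS[k]), " ", res3[i], "A", i, " ",
          p[1], p[2], p[3], 1.00, 0.00, substr(BB_ATOMS[k], 1, 1))
      }
    }
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model backbone PDB file into an ensemble
#'
#' Parses ATOM records of a single chain (the first encountered); models
#' are delimited by MODEL/ENDMDL (a single-model file yields an ensemble
#' of size 1). All models must share the same sequence and atom
#' complement; insertion codes are rejected. Missing CB atoms (glycine)
#' are reconstructed virtually; energies are read from
#' \code{REMARK 250 ENERGY} lines when present.
#'
#' @param path PDB file path.
#' @return an [ensemble()].
#' @export
read_ensemble_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  model_breaks <- grepl("^MODEL", lines)
  models_raw <- list()
  energies <- numeric(0)
  if (any(model_breaks)) {
    starts <- which(model_breaks)
    ends <- which(grepl("^ENDMDL", lines))
    if (length(ends) < length(starts)) stop("unterminated MODEL block")
    for (k in seq_along(starts)) {
      blk <- lines[starts[k]:ends[k]]
      models_raw[[k]] <- blk[grepl("^ATOM  ", blk)]
      en <- blk[grepl("^REMARK 250 ENERGY", blk)]
      energies[k] <- if (length(en)) as.numeric(sub(".*ENERGY +", "", en[1])) else NA_real_
    }
  } else {
    models_raw[[1]] <- lines[grepl("^ATOM  ", lines)]
    energies <- NA_real_
  }
  parse_model <- function(atoms, k) {
    if (!length(atoms)) stop("model ", k, " contains no ATOM records")
    icode <- substr(atoms, 27, 27)
    if (any(icode != " "))
      stop("insertion codes are not supported (model ", k, ")")
    chain <- substr(atoms, 22, 22)
    atoms <- atoms[chain == chain[1]]
    name <- trimws(substr(atoms, 13, 16))
    resno <- as.integer(substr(atoms, 23, 26))
    res3 <- trimws(substr(atoms, 18, 20))
    x <- as.numeric(substr(atoms, 31, 38))
    y <- as.numeric(substr(atoms, 39, 46))
    z <- as.numeric(substr(atoms, 47, 54))
    keep <- name %in% BB_ATOMS
    name <- name[keep]; resno <- resno[keep]; res3 <- res3[keep]
    xyz_in <- cbind(x[keep], y[keep], z[keep])
    resids <- unique(resno)
    Lm <- length(resids)
    remap <- match(resno, resids)
    seqc <- character(Lm)
    xyz <- matrix(NA_real_, 5L * Lm, 3)
    for (r in seq_len(Lm)) {
      rows <- which(remap == r)
      seqc[r] <- if (res3[rows[1]] %in% names(AA1)) AA1[[res3[rows[1]]]] else "X"
      for (rr in rows) {
        k2 <- match(name[rr], BB_ATOMS)
        xyz[(r - 1L) * 5L + k2, ] <- xyz_in[rr, ]
      }
    }
    # reconstruct missing virtual CBs
    for (r in seq_len(Lm)) {
      if (anyNA(xyz[(r - 1L) * 5L + 5L, ])) {
        xyz[(r - 1L) * 5L + 5L, ] <- virtual_cb(xyz[(r - 1L) * 5L + 1L, , drop = FALSE],
                                                xyz[(r - 1L) * 5L + 2L, , drop = FALSE],
                                                xyz[(r - 1L) * 5L + 3L, , drop = FALSE])
      }
    }
    if (anyNA(xyz))
      stop("model ", k, " is missing backbone atoms")
    backbone(seqc, xyz, validate = FALSE)
  }
  models <- mapply(parse_model, models_raw, seq_along(models_raw),
                   SIMPLIFY = FALSE)
  seqc <- models[[1]]$sequence
  for (k in seq_along(models)) {
    if (n_residues(models[[k]]) != length(seqc))
      stop("model ", k, " has a different residue count")
    if (!identical(models[[k]]$sequence, seqc))
      stop("model ", k, " has a different sequence")
  }
  ensemble(seqc, models, if (all(is.na(energies))) NULL else energies)
}

GEOM_CONTAINER_VERSION <- "1.0"

#' Write geometry distributions to a container file
#'
#' Serialises the four named probability arrays (\code{dist} L x L x 37,
#' \code{omega}/\code{theta} L x L x 25, \code{phi} L x L x 13) plus the
#' sequence and a format version tag into a single binary container
#' (R serialisation, version 2, platform independent).
#'
#' @param G a \code{geom_distributions} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_geometry_container <- function(G, path) {
  validate_geometries(G)
  payload <- list(version = GEOM_CONTAINER_VERSION,
                  sequence = paste(G$sequence, collapse = ""),
                  dist = G$dist, omega = G$omega, theta = G$theta,
                  phi = G$phi)
  saveRDS(payload, path, version = 2)
  invisible(path)
}

#' Read geometry distributions from a container file
#'
#' Shapes and per-pair normalisation are validated on load; a truncated or
#' malformed file is a clean error.
#'
#' @param path container path (see [write_geometry_container()]).
#' @return a \code{geom_distributions} object.
#' @export
read_geometry_container <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("unreadable geometry container: ",
                                               conditionMessage(e)))
  need <- c("version", "sequence", "dist", "omega", "theta", "phi")
  if (!is.list(payload) || !all(need %in% names(payload)))
    stop("geometry container is missing required arrays")
  geometry_distributions(payload$dist, payload$omega, payload$theta,
                         payload$phi, sequence = payload$sequence)
}

#' Read a whitespace-delimited RDC table
#'
#' Two columns: residue index and experimental H-N coupling (Hz);
#' \code{#} starts a comment.
#'
#' @param path file path.
#' @return data frame with columns \code{residue}, \code{coupling}.
#' @export
read_rdc_table <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("residue", "coupling"))
  d$residue <- as.integer(d$residue)
  d
}

#' Read a plain-text restraint pair list
#'
#' Two columns of 1-based residue indices; \code{#} starts a comment.
#'
#' @param path file path.
#' @return integer matrix with two columns.
#' @export
read_restraint_pairs <- function(path) {
  d <- utils::read.table(path, comment.char = "#")[, 1:2]
  m <- as.matrix(d)
  storage.mode(m) <- "integer"
  colnames(m) <- c("i", "j")
  m
}
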