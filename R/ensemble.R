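#' @importFrom stats rnorm runif sd quantile lm resid coef fft dnorm pnorm
#' @importFrom utils read.delim write.table
NULL

# Backbone atom names used throughout; side chains are ignored.
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) 180 - ((180 - x) %% 360)

#' Construct a conformational ensemble
#'
#' A `conformation_ensemble` holds, for one peptide, the backbone dihedral
#' angles of every conformation and (optionally) the backbone coordinates.
#' Angles are in degrees within (-180, 180]. Undefined angles (phi of the
#' first residue; psi and omega of the last residue) are `NA`. The omega
#' angle stored at residue i is the peptide-bond torsion CA(i)-C(i)-N(i+1)-
#' CA(i+1), i.e. the bond *following* residue i; the prolyl bond preceding a
#' proline at position j is therefore `omega[, j - 1]`.
#'
#' @param phi,psi,omega numeric matrices `[conformation x residue]`, degrees.
#' @param residue_names character vector of 3-letter residue codes.
#' @param peptide_name label for the peptide.
#' @param coords optional list (one element per conformation) of arrays with
#'   dim `c(n_residues, 4, 3)`; atom dimension named N, CA, C, O.
#' @return an object of class `conformation_ensemble`.
#' @export
conformation_ensemble <- function(phi, psi, omega, residue_names,
                                  peptide_name = "peptide", coords = NULL) {
  phi <- as.matrix(phi); psi <- as.matrix(psi); omega <- as.matrix(omega)
  n_conf <- nrow(phi); n_res <- ncol(phi)
  stopifnot(length(residue_names) == n_res,
            all(dim(psi) == c(n_conf, n_res)),
            all(dim(omega) == c(n_conf, n_res)))
  for (m in list(phi, psi, omega)) {
    v <- m[!is.na(m)]
    if (length(v) && (any(v <= -180) || any(v > 180)))
      stop("angles must lie in (-180, 180]; wrap with wrap_angle()")
  }
  if (!all(is.na(phi[, 1]))) stop("phi of residue 1 must be NA")
  if (!all(is.na(psi[, n_res]))) stop("psi of the last residue must be NA")
  if (!all(is.na(omega[, n_res]))) stop("omega of the last residue must be NA")
  if (!is.null(coords)) {
    stopifnot(length(coords) == n_conf)
    for (cc in coords)
      stopifnot(all(dim(cc) == c(n_res, 4L, 3L)))
  }
  structure(list(peptide_name = peptide_name,
                 n_conformations = n_conf, n_residues = n_res,
                 residue_names = toupper(residue_names),
                 phi = phi, psi = psi, omega = omega, coords = coords),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("Conformational ensemble '%s': %d conformations x %d residues (%s)\n",
              x$peptide_name, x$n_conformations, x$n_residues,
              paste0(rle(x$residue_names)$values, collapse = "-")))
  cat(sprintf("  coordinates: %s\n", if (is.null(x$coords)) "absent" else "present"))
  invisible(x)
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Vectorised signed torsion for matrices of points (rows = quadruples).
torsion_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(.cross3(n1, n2) * b2) / nb2
  bad <- rowSums(n1^2) < 1e-14 | rowSums(n2^2) < 1e-14
  ang <- wrap_angle(atan2(y, x) * 180 / pi)
  ang[bad] <- NA_real_
  ang
}

#' Signed backbone torsion angle of four points
#'
#' IUPAC sign convention: looking down the p2 -> p3 bond, a positive angle is
#' a clockwise rotation of p4 relative to p1. An ideal right-handed
#' alpha-helix built from this convention has phi close to -57 degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom).
#' @return torsion angle in degrees within (-180, 180].
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  pts <- rbind(p1, p2, p3, p4)
  if (!all(is.finite(pts))) stop("all points must be finite")
  if (min(sqrt(rowSums(diff(pts)^2))) < 1e-9)
    stop("consecutive points coincide; torsion undefined")
  ang <- unname(torsion_rows(rbind(p1), rbind(p2), rbind(p3), rbind(p4)))
  if (is.na(ang)) stop("collinear points; torsion undefined")
  ang
}

# phi/psi/omega matrices from a coords list. Returns list(phi, psi, omega).
dihedrals_from_coords <- function(coords) {
  n_conf <- length(coords)
  n_res <- dim(coords[[1]])[1]
  phi <- psi <- omega <- matrix(NA_real_, n_conf, n_res)
  for (k in seq_len(n_conf)) {
    cc <- coords[[k]]
    N <- cc[, "N", , drop = FALSE]; dim(N) <- c(n_res, 3)
    CA <- cc[, "CA", , drop = FALSE]; dim(CA) <- c(n_res, 3)
    C <- cc[, "C", , drop = FALSE]; dim(C) <- c(n_res, 3)
    if (n_res >= 2) {
      i <- 2:n_res
      phi[k, i] <- torsion_rows(C[i - 1, , drop = FALSE], N[i, , drop = FALSE],
                                CA[i, , drop = FALSE], C[i, , drop = FALSE])
      j <- 1:(n_res - 1)
      psi[k, j] <- torsion_rows(N[j, , drop = FALSE], CA[j, , drop = FALSE],
                                C[j, , drop = FALSE], N[j + 1, , drop = FALSE])
      omega[k, j] <- torsion_rows(CA[j, , drop = FALSE], C[j, , drop = FALSE],
                                  N[j + 1, , drop = FALSE], CA[j + 1, , drop = FALSE])
    }
  }
  list(phi = phi, psi = psi, omega = omega)
}

#' Read a multi-model PDB file into an ensemble
#'
#' Reads MODEL/ENDMDL blocks (or a single unnumbered structure) of a
#' single-chain peptide. Backbone atoms N, CA, C are required per residue; O
#' is retained when present and reconstructed later if absent. Models missing
#' any required backbone atom are skipped with a warning.
#'
#' @param path path to a PDB file.
#' @param peptide_name optional label; defaults to the file name.
#' @return a [conformation_ensemble] with coordinates and dihedrals.
#' @export
read_multimodel_pdb <- function(path, peptide_name = basename(path)) {
  lines <- readLines(path)
  atom <- grepl("^ATOM  ", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (max(model_id) == 0) model_id <- rep(1L, length(lines))
  al <- lines[atom]
  amod <- model_id[atom]
  if (!length(al)) stop("no ATOM records found in ", path)
  name <- trimws(substr(al, 13, 16))
  chain <- substr(al, 22, 22)
  resno <- as.integer(substr(al, 23, 26))
  resnm <- trimws(substr(al, 18, 20))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  chains <- unique(chain)
  if (length(chains) > 1)
    stop("multiple chains found: ", paste(chains, collapse = ", "))
  keep <- name %in% BACKBONE_ATOMS
  name <- name[keep]; resno <- resno[keep]; resnm <- resnm[keep]
  amod <- amod[keep]; x <- x[keep]; y <- y[keep]; z <- z[keep]
  residues <- sort(unique(resno))
  n_res <- length(residues)
  res_index <- match(resno, residues)
  residue_names <- character(n_res)
  residue_names[res_index] <- resnm
  coords <- list()
  skipped <- 0L
  for (m in sort(unique(amod))) {
    sel <- amod == m
    arr <- array(NA_real_, c(n_res, 4, 3),
                 dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
    arr[cbind(rep(res_index[sel], 3),
              rep(match(name[sel], BACKBONE_ATOMS), 3),
              rep(1:3, each = sum(sel)))] <- c(x[sel], y[sel], z[sel])
    if (anyNA(arr[, c("N", "CA", "C"), ])) {
      skipped <- skipped + 1L
      next
    }
    coords[[length(coords) + 1L]] <- arr
  }
  if (skipped > 0L)
    warning(skipped, " model(s) skipped: missing backbone atoms")
  if (!length(coords)) stop("no usable models in ", path)
  dih <- dihedrals_from_coords(coords)
  conformation_ensemble(dih$phi, dih$psi, dih$omega, residue_names,
                        peptide_name = peptide_name, coords = coords)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Intended for fixtures and interoperability checks; analysis results are
#' written as tables, not PDB.
#'
#' @param ens a [conformation_ensemble] with coordinates.
#' @param path output path.
#' @export
write_multimodel_pdb <- function(ens, path) {
  if (is.null(ens$coords)) stop("ensemble has no coordinates")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (k in seq_len(ens$n_conformations)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    cc <- ens$coords[[k]]
    for (i in seq_len(ens$n_residues)) {
      for (a in BACKBONE_ATOMS) {
        if (anyNA(cc[i, a, ])) next
        serial <- serial + 1L
        writeLines(sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                           serial %% 100000L, a, ens$residue_names[i], i,
                           cc[i, a, 1], cc[i, a, 2], cc[i, a, 3]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a plain dihedral table
#'
#' TSV with header columns `conformation`, `residue_index`, `residue_name`,
#' `phi`, `psi`, `omega`. Residue indices are 1-based and must be contiguous
#' within each conformation. Angles outside (-180, 180] are wrapped; literal
#' `NA` denotes an undefined angle.
#'
#' @param path path to the TSV file.
#' @param peptide_name optional label.
#' @return a [conformation_ensemble] without coordinates.
#' @export
read_dihedral_table <- function(path, peptide_name = basename(path)) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c("integer", "integer", "character",
                                 "character", "character", "character"))
  need <- c("conformation", "residue_index", "residue_name", "phi", "psi", "omega")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  parse_angle <- function(s, col) {
    out <- rep(NA_real_, length(s))
    ok <- is.na(s) | s == "NA"
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!ok & is.na(v))
    if (length(bad))
      stop(sprintf("unparseable %s value '%s' at data line %d", col, s[bad[1]],
                   bad[1]))
    out[!ok] <- wrap_angle(v[!ok])
    out
  }
  confs <- sort(unique(d$conformation))
  n_res <- length(unique(d$residue_index))
  for (k in confs) {
    ri <- d$residue_index[d$conformation == k]
    if (!identical(sort(ri), seq_len(n_res)))
      stop("residue indices not contiguous 1..", n_res, " in conformation ", k)
  }
  ord <- order(d$conformation, d$residue_index)
  d <- d[ord, ]
  phi <- matrix(parse_angle(d$phi, "phi"), length(confs), n_res, byrow = TRUE)
  psi <- matrix(parse_angle(d$psi, "psi"), length(confs), n_res, byrow = TRUE)
  omg <- matrix(parse_angle(d$omega, "omega"), length(confs), n_res, byrow = TRUE)
  residue_names <- d$residue_name[seq_len(n_res)]
  conformation_ensemble(phi, psi, omg, residue_names, peptide_name = peptide_name)
}

fmt_angle <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))

#' Write an ensemble as a dihedral table
#'
#' Deterministic TSV output (fixed column order, fixed float formatting,
#' trailing newline) so files are byte-comparable across runs.
#'
#' @param ens a [conformation_ensemble].
#' @param path output path.
#' @export
write_dihedral_table <- function(ens, path) {
  n <- ens$n_residues
  rows <- character(ens$n_conformations * n)
  idx <- 1L
  for (k in seq_len(ens$n_conformations)) {
    rows[idx:(idx + n - 1L)] <- sprintf("%d\t%d\t%s\t%s\t%s\t%s",
      k, seq_len(n), ens$residue_names,
      fmt_angle(ens$phi[k, ]), fmt_angle(ens$psi[k, ]), fmt_angle(ens$omega[k, ]))
    idx <- idx + n
  }
  writeLines(c("conformation\tresidue_index\tresidue_name\tphi\tpsi\tomega", rows),
             path)
  invisible(path)
}

#' Write analysis products as deterministic tables
#'
#' Writes region labels, motif instances or correlation profiles to TSV with
#' fixed column order and float formatting; byte-identical across repeated
#' calls on the same input.
#'
#' @param x a region label matrix, motif instance table, or correlation
#'   profile.
#' @param ens the [conformation_ensemble] the product was derived from (used
#'   for dimension checks); may be `NULL` for profiles.
#' @param path output path.
#' @export
write_annotations <- function(x, ens = NULL, path) {
  if (inherits(x, "region_labels")) {
    if (!is.null(ens) &&
        !all(dim(x$labels) == c(ens$n_conformations, ens$n_residues)))
      stop("label matrix dimensions do not match the ensemble")
    lab <- x$labels
    n <- ncol(lab)
    rows <- character(nrow(lab) * n)
    idx <- 1L
    for (k in seq_len(nrow(lab))) {
      rows[idx:(idx + n - 1L)] <- sprintf("%d\t%d\t%s", k, seq_len(n),
                                          ifelse(is.na(lab[k, ]), "NA", lab[k, ]))
      idx <- idx + n
    }
    writeLines(c("conformation\tresidue_index\tregion", rows), path)
  } else if (is.data.frame(x) && all(c("type", "start", "end") %in% names(x))) {
    if (!is.null(ens) && nrow(x) && max(x$end) > ens$n_residues)
      stop("motif span exceeds ensemble size")
    header <- "conformation\ttype\tstart\tend\tlength\tisolated\tmin_len"
    if (nrow(x) == 0) { writeLines(header, path); return(invisible(path)) }
    rows <- sprintf("%d\t%s\t%d\t%d\t%d\t%s\t%d", x$conformation, x$type,
                    x$start, x$end, x$length,
                    ifelse(is.na(x$isolated), "NA", as.character(x$isolated)),
                    x$min_len)
    writeLines(c(header, rows), path)
  } else if (inherits(x, "correlation_profile")) {
    rows <- sprintf("%d\t%.6f\t%s\t%d", x$r, x$value,
                    ifelse(is.na(x$se), "NA", sprintf("%.6f", x$se)), x$n_pairs)
    writeLines(c("r\tvalue\tse\tn_pairs", rows), path)
  } else {
    stop("unsupported annotation object of class ", paste(class(x), collapse = "/"))
  }
  invisible(path)
}
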