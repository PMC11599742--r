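# Membrane coordinate frame: a unit normal, a z-origin at the bilayer median
# and hydrophobic-hydrophilic boundary depths. The boundaries of the
# reference entries come from external hydrophobic-boundary calculations and
# are accepted as input; a transparent slab estimator is provided as a
# fallback for synthetic structures.

# Kyte-Doolittle hydropathy; residues with positive values count as
# hydrophobic in the slab estimator.
KYTE_DOOLITTLE <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5, MSE = 1.9
)

#' Assign a membrane coordinate frame
#'
#' The frame consists of a unit membrane normal, a z-origin placed at the
#' bilayer median (the midpoint of the hydrophobic--hydrophilic boundaries),
#' and the two boundary depths relative to that origin. The normal defaults
#' to the principal axis of the helical C-alpha atoms (the axis of smallest
#' moment of inertia of a seven-helix bundle is the bilayer normal).
#'
#' If `boundaries` is `NULL` they are estimated by sliding a 24--36 Angstrom
#' slab along the normal and maximising the count of hydrophobic minus polar
#' residues (Kyte--Doolittle > 0 defining hydrophobic) whose C-alpha lies
#' inside the slab.
#'
#' @param structure an `mr_structure`.
#' @param boundaries numeric length-2 `(lower, upper)` giving the boundary
#'   positions along the normal (same projection coordinate as
#'   `xyz %*% normal`), or `NULL` to estimate.
#' @param normal optional membrane normal (unit vector enforced internally).
#' @return An object of class `membrane_frame`: `normal`, `z_origin`,
#'   `z_lower` (< 0), `z_upper` (> 0).
#' @export
assign_frame <- function(structure, boundaries = NULL, normal = NULL) {
  n <- normal %||% membrane_normal(structure)
  n <- n / sqrt(sum(n^2))
  if (!is.null(boundaries)) {
    stopifnot(length(boundaries) == 2L)
    if (boundaries[1L] >= boundaries[2L]) {
      stop2("invalid_boundaries", "z_lower must be below z_upper")
    }
  } else {
    boundaries <- estimate_boundaries(structure, n)
  }
  origin <- mean(boundaries)
  out <- list(normal = n, z_origin = origin,
              z_lower = boundaries[1L] - origin,
              z_upper = boundaries[2L] - origin)
  class(out) <- "membrane_frame"
  out
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf(
    "<membrane_frame> normal (%.3f, %.3f, %.3f), origin %.2f A, boundaries [%.2f, %.2f] A (thickness %.1f A)\n",
    x$normal[1L], x$normal[2L], x$normal[3L], x$z_origin,
    x$z_lower, x$z_upper, x$z_upper - x$z_lower))
  invisible(x)
}

#' Membrane normal of a helix bundle
#'
#' Principal axis (largest-variance direction, equivalently smallest moment
#' of inertia) of the helical C-alpha atoms; falls back to all C-alpha atoms
#' when no helix annotation is present. The sign is fixed deterministically
#' (positive component along +z, ties broken by +x then +y).
#'
#' @param structure an `mr_structure`.
#' @return Unit length-3 vector.
#' @export
membrane_normal <- function(structure) {
  a <- structure$atoms
  ca <- a[a$atom == "CA" & !a$het & a$resname %in% STANDARD_AA, , drop = FALSE]
  if (nrow(structure$helix)) {
    h <- structure$helix
    keep <- rep(FALSE, nrow(ca))
    for (i in seq_len(nrow(h))) {
      keep <- keep | (ca$chain == h$chain[i] & ca$resno >= h$start[i] &
                        ca$resno <= h$end[i])
    }
    if (sum(keep) >= 3L) ca <- ca[keep, , drop = FALSE]
  }
  if (nrow(ca) < 3L) {
    stop2("insufficient_data", "need at least 3 C-alpha atoms for a normal")
  }
  xyz <- atom_xyz(ca)
  cv <- stats::cov(xyz)
  ev <- eigen(cv, symmetric = TRUE)
  n <- ev$vectors[, 1L]
  for (k in c(3L, 1L, 2L)) {
    if (abs(n[k]) > 1e-12) {
      if (n[k] < 0) n <- -n
      break
    }
  }
  n
}

# Slab estimator for the hydrophobic belt: maximise
# (#hydrophobic - #polar) residue C-alphas inside a slab of width 24-36 A.
estimate_boundaries <- function(structure, normal) {
  a <- structure$atoms
  ca <- a[a$atom == "CA" & !a$het & a$resname %in% STANDARD_AA, , drop = FALSE]
  n_res <- nrow(ca)
  if (n_res < 50L) {
    stop2("insufficient_data",
          "boundary estimation needs >= 50 protein residues, got %d", n_res)
  }
  t <- as.vector(atom_xyz(ca) %*% normal)
  kd <- KYTE_DOOLITTLE[ca$resname]
  kd[is.na(kd)] <- 0
  hydro <- kd > 0
  centers <- seq(min(t), max(t), by = 0.5)
  best <- c(score = -Inf, lo = NA_real_, hi = NA_real_)
  for (w in seq(24, 36, by = 1)) {
    for (cc in centers) {
      lo <- cc - w / 2; hi <- cc + w / 2
      inside <- t >= lo & t <= hi
      score <- sum(hydro & inside) - sum(!hydro & inside)
      if (score > best["score"]) best <- c(score = score, lo = lo, hi = hi)
    }
  }
  c(best[["lo"]], best[["hi"]])
}

#' Bilayer depths of atoms
#'
#' Depth = projection of the atom position on the membrane normal minus the
#' z-origin; zero is the bilayer median, negative values are below it.
#'
#' @param atoms atom table, coordinate matrix or `mr_structure`.
#' @param frame a `membrane_frame`.
#' @return Numeric vector of depths in Angstrom.
#' @export
depths_of <- function(atoms, frame) {
  xyz <- if (inherits(atoms, "mr_structure")) atom_xyz(atoms$atoms)
         else as_xyz_matrix(atoms)
  as.vector(xyz %*% frame$normal) - frame$z_origin
}

#' Transfer a membrane frame through a rigid transform
#'
#' When a structure is moved by a rigid transform, co-transforming its frame
#' preserves every atom's depth exactly.
#'
#' @param frame a `membrane_frame`.
#' @param transform a `rigid_transform`.
#' @return The transformed `membrane_frame`.
#' @export
transform_frame <- function(frame, transform) {
  n2 <- as.vector(transform$rotation %*% frame$normal)
  frame$z_origin <- frame$z_origin + sum(n2 * transform$translation)
  frame$normal <- n2
  frame
}
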