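# Rigid-body superposition. Two independent solvers are provided: the Kabsch
# SVD method (production path) and the Horn quaternion method (used as a
# cross-check); both minimise the least-squares RMSD over a
# correspondence-ordered atom pairing.

new_transform <- function(rotation, translation, rmsd = NA_real_) {
  out <- list(rotation = rotation, translation = translation, rmsd = rmsd)
  class(out) <- "rigid_transform"
  out
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    return(unname(x))
  }
  atom_xyz(x)
}

#' Kabsch superposition
#'
#' Computes the proper rigid transform (rotation + translation) minimising
#' the RMSD between correspondence-ordered atom sets, mapping `mobile` onto
#' `reference`.
#'
#' @param reference,mobile n x 3 coordinate matrices or atom tables with
#'   equal row counts (n >= 3, non-collinear).
#' @return A list of class `rigid_transform` with `rotation` (3 x 3,
#'   determinant +1), `translation` (length 3) and `rmsd` (Angstrom) over the
#'   input correspondence after transformation.
#' @seealso [quaternion_superpose()] for the independent solver.
#' @export
kabsch_superpose <- function(reference, mobile) {
  R <- as_xyz_matrix(reference)
  M <- as_xyz_matrix(mobile)
  check_superposable(R, M)
  cr <- colMeans(R)
  cm <- colMeans(M)
  Rc <- sweep(R, 2L, cr)
  Mc <- sweep(M, 2L, cm)
  H <- crossprod(Mc, Rc)           # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - as.vector(rot %*% cm)
  out <- structure(list(rotation = rot, translation = trans, rmsd = NA_real_),
                   class = "rigid_transform")
  fitted <- apply_transform(out, M)
  out$rmsd <- sqrt(mean(rowSums((fitted - R)^2)))
  out
}

#' Quaternion superposition (independent solver)
#'
#' Horn's closed-form quaternion method: the optimal rotation is recovered
#' from the principal eigenvector of the 4 x 4 key matrix built from the
#' coordinate cross-covariance. Kept algorithmically independent of
#' [kabsch_superpose()] so the two can validate each other.
#'
#' @inheritParams kabsch_superpose
#' @return Same structure as [kabsch_superpose()].
#' @export
quaternion_superpose <- function(reference, mobile) {
  R <- as_xyz_matrix(reference)
  M <- as_xyz_matrix(mobile)
  check_superposable(R, M)
  cr <- colMeans(R)
  cm <- colMeans(M)
  Rc <- sweep(R, 2L, cr)
  Mc <- sweep(M, 2L, cm)
  S <- crossprod(Mc, Rc)  # S[i,j] = sum mobile_i * ref_j
  K <- matrix(0, 4L, 4L)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1L]
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  rot <- matrix(c(
    w*w + x*x - y*y - z*z, 2*(x*y - w*z),         2*(x*z + w*y),
    2*(x*y + w*z),         w*w - x*x + y*y - z*z, 2*(y*z - w*x),
    2*(x*z - w*y),         2*(y*z + w*x),         w*w - x*x - y*y + z*z
  ), 3L, 3L, byrow = TRUE)
  trans <- cr - as.vector(rot %*% cm)
  out <- structure(list(rotation = rot, translation = trans, rmsd = NA_real_),
                   class = "rigid_transform")
  fitted <- apply_transform(out, M)
  out$rmsd <- sqrt(mean(rowSums((fitted - R)^2)))
  out
}

check_superposable <- function(R, M) {
  if (nrow(R) != nrow(M)) {
    stop2("underdetermined_superposition",
          "atom sets differ in length (%d vs %d)", nrow(R), nrow(M))
  }
  if (nrow(R) < 3L) {
    stop2("underdetermined_superposition",
          "need at least 3 correspondence atoms, got %d", nrow(R))
  }
  for (X in list(R, M)) {
    Xc <- sweep(X, 2L, colMeans(X))
    if (sum(svd(Xc)$d > 1e-8) < 2L) {
      stop2("underdetermined_superposition",
            "degenerate (collinear) atom set")
    }
  }
  invisible(TRUE)
}

#' Apply a rigid transform
#'
#' @param transform a `rigid_transform`.
#' @param x an n x 3 matrix, atom table or `mr_structure`.
#' @return Object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "mr_structure")) {
    xyz <- apply_transform(transform, atom_xyz(x$atoms))
    x$atoms$x <- xyz[, 1L]; x$atoms$y <- xyz[, 2L]; x$atoms$z <- xyz[, 3L]
    return(x)
  }
  if (is.data.frame(x)) {
    xyz <- apply_transform(transform, atom_xyz(x))
    x$x <- xyz[, 1L]; x$y <- xyz[, 2L]; x$z <- xyz[, 3L]
    return(x)
  }
  sweep(x %*% t(transform$rotation), 2L, -transform$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rot <- t(transform$rotation)
  structure(list(rotation = rot,
                 translation = -as.vector(rot %*% transform$translation),
                 rmsd = NA_real_),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n rotation:\n")
  print(round(x$rotation, 6))
  cat(" translation:", paste(round(x$translation, 4), collapse = ", "), "\n")
  if (!is.na(x$rmsd)) cat(sprintf(" rmsd: %.4f A\n", x$rmsd))
  invisible(x)
}

#' Backbone + retinal correspondence between two structures
#'
#' Builds the atom pairing used to align microbial rhodopsins: backbone
#' N, CA, C, O atoms of residue numbers shared between the two structures,
#' plus retinal atoms with shared names. Chains are paired by shared chain
#' identifier; if none is shared, the first protein chain of each structure
#' is paired.
#'
#' @param a,b `mr_structure` objects containing protein (and ideally RET).
#' @return A list with `ref_idx` and `mob_idx`, row indices into `a$atoms`
#'   and `b$atoms` in correspondence order, plus `n_backbone`, `n_retinal`.
#' @export
pair_backbone_retinal <- function(a, b) {
  pa <- partition_structure(a)
  pb <- partition_structure(b)
  chains_a <- unique(pa$protein$chain)
  chains_b <- unique(pb$protein$chain)
  shared <- intersect(chains_a, chains_b)
  pairs <- if (length(shared)) cbind(shared, shared)
           else cbind(chains_a[1L], chains_b[1L])
  bb <- c("N", "CA", "C", "O")
  ref_idx <- integer(0); mob_idx <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    aa <- a$atoms; ba <- b$atoms
    sel_a <- which(!aa$het & aa$chain == pairs[k, 1L] & aa$atom %in% bb &
                     aa$resname %in% STANDARD_AA)
    sel_b <- which(!ba$het & ba$chain == pairs[k, 2L] & ba$atom %in% bb &
                     ba$resname %in% STANDARD_AA)
    key_a <- paste(aa$resno[sel_a], aa$insert[sel_a], aa$atom[sel_a])
    key_b <- paste(ba$resno[sel_b], ba$insert[sel_b], ba$atom[sel_b])
    common <- intersect(key_a, key_b)
    ref_idx <- c(ref_idx, sel_a[match(common, key_a)])
    mob_idx <- c(mob_idx, sel_b[match(common, key_b)])
  }
  n_backbone <- length(ref_idx)
  # retinal: first RET residue in each, matched by atom name
  n_ret <- 0L
  if (nrow(pa$retinal) && nrow(pb$retinal)) {
    ra <- pa$retinal; rb <- pb$retinal
    ka <- residue_keys(ra); kb <- residue_keys(rb)
    ra <- ra[ka == ka[1L], , drop = FALSE]
    rb <- rb[kb == kb[1L], , drop = FALSE]
    common <- intersect(ra$atom, rb$atom)
    # match back to full-table row indices
    idx_a <- which(residue_keys(a$atoms) == residue_keys(ra)[1L])
    idx_b <- which(residue_keys(b$atoms) == residue_keys(rb)[1L])
    ref_idx <- c(ref_idx, idx_a[match(common, a$atoms$atom[idx_a])])
    mob_idx <- c(mob_idx, idx_b[match(common, b$atoms$atom[idx_b])])
    n_ret <- length(common)
  }
  if (length(ref_idx) == 0L) {
    stop2("empty_correspondence", "no shared residues between structures")
  }
  list(ref_idx = ref_idx, mob_idx = mob_idx,
       n_backbone = n_backbone, n_retinal = n_ret)
}

#' Helical C-alpha RMSD between two structures
#'
#' Restricts the correspondence to C-alpha atoms inside helix ranges (the
#' reference structure's deposited HELIX annotations by default), superposes
#' by the Kabsch method, and reports the RMSD over the same atoms.
#'
#' @param a,b `mr_structure` objects.
#' @param helix_ranges data frame (`chain`, `start`, `end`); defaults to
#'   `a$helix`.
#' @param superpose if `FALSE` the RMSD is evaluated in the given frames
#'   without aligning first.
#' @return RMSD in Angstrom, with the number of atoms as attribute `"n"`.
#' @export
helical_rmsd <- function(a, b, helix_ranges = NULL, superpose = TRUE) {
  h <- helix_ranges %||% a$helix
  if (is.null(h) || nrow(h) == 0L) {
    stop2("empty_correspondence", "no helix ranges available")
  }
  in_helix <- function(atoms) {
    keep <- rep(FALSE, nrow(atoms))
    for (i in seq_len(nrow(h))) {
      keep <- keep | (atoms$chain == h$chain[i] &
                        atoms$resno >= h$start[i] & atoms$resno <= h$end[i])
    }
    keep & atoms$atom == "CA" & !atoms$het & atoms$resname %in% STANDARD_AA
  }
  aa <- a$atoms[in_helix(a$atoms), , drop = FALSE]
  ba <- b$atoms[in_helix(b$atoms), , drop = FALSE]
  key_a <- paste(aa$chain, aa$resno, aa$insert)
  key_b <- paste(ba$chain, ba$resno, ba$insert)
  common <- intersect(key_a, key_b)
  if (length(common) == 0L) {
    stop2("empty_correspondence", "no shared helical residues")
  }
  A <- atom_xyz(aa[match(common, key_a), , drop = FALSE])
  B <- atom_xyz(ba[match(common, key_b), , drop = FALSE])
  r <- if (superpose) {
    kabsch_superpose(A, B)$rmsd
  } else {
    sqrt(mean(rowSums((B - A)^2)))
  }
  attr(r, "n") <- length(common)
  r
}
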