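#' Expand a structure by symmetry operators
#'
#' Applies a list of rigid transforms (or generates the C3 rotations about a
#' given axis) to a structure, producing an assembly in which each generated
#' copy receives fresh chain identifiers.
#'
#' @param structure an `mr_structure`.
#' @param ops list of `rigid_transform` objects. The identity need not be
#'   included; copies are generated for every supplied op.
#' @param point_symmetry alternatively, `"C3"` to generate rotations of 120
#'   and 240 degrees about `axis` through `origin`.
#' @param axis,origin axis direction and a point on the axis for
#'   `point_symmetry` (defaults: z axis through the coordinate origin).
#' @return An `mr_structure` whose atom count is the original times the
#'   number of copies (original + generated).
#' @export
expand_assembly <- function(structure, ops = NULL, point_symmetry = NULL,
                            axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  if (is.null(ops) && is.null(point_symmetry)) {
    stop2("assembly_unavailable",
          "no symmetry operators supplied and none derivable")
  }
  if (!is.null(point_symmetry)) {
    stopifnot(identical(point_symmetry, "C3"))
    ops <- lapply(c(2, 4) * pi / 3, function(th) {
      rot <- rotation_about_axis(axis, th)
      new_transform(rot, as.vector(origin - rot %*% origin))
    })
  }
  base_chains <- unique(structure$atoms$chain)
  used <- base_chains
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)), used)
  atoms_out <- structure$atoms
  helix_out <- structure$helix
  for (op in ops) {
    if (is_identity_transform(op)) next
    copy <- apply_transform(op, structure)$atoms
    map <- pool[seq_along(base_chains)]
    if (length(map) < length(base_chains)) {
      stop2("assembly_unavailable", "ran out of chain identifiers")
    }
    pool <- setdiff(pool, map)
    names(map) <- base_chains
    copy$chain <- unname(map[copy$chain])
    atoms_out <- rbind(atoms_out, copy)
    if (nrow(structure$helix)) {
      h <- structure$helix
      h$chain <- unname(map[h$chain])
      helix_out <- rbind(helix_out, h)
    }
  }
  rownames(atoms_out) <- NULL
  new_structure(atoms_out, entry_id = structure$entry_id, helix = helix_out)
}

is_identity_transform <- function(op, tol = 1e-12) {
  max(abs(op$rotation - diag(3))) < tol && max(abs(op$translation)) < tol
}

# Rotation matrix about a (not necessarily unit) axis by angle theta.
rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(theta); s_ <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    c_ + ux^2 * (1 - c_),      ux*uy*(1 - c_) - uz*s_,   ux*uz*(1 - c_) + uy*s_,
    uy*ux*(1 - c_) + uz*s_,    c_ + uy^2 * (1 - c_),     uy*uz*(1 - c_) - ux*s_,
    uz*ux*(1 - c_) - uy*s_,    uz*uy*(1 - c_) + ux*s_,   c_ + uz^2 * (1 - c_)
  ), 3L, 3L, byrow = TRUE)
}
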