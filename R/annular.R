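# Annular-shell analysis: nearest lipid-to-protein-surface distances, shell
# extraction at a distance cutoff, and location classification of lipids in
# oligomeric assemblies.

#' Nearest-protein-atom distance for each query atom
#'
#' For every query (lipid) atom, the distance to the nearest target
#' (protein) atom. The production path uses a uniform spatial grid (cell
#' list) with an expanding ring search; `method = "brute"` is the exhaustive
#' O(N*M) oracle. The two paths evaluate the winning atom pair with
#' identical floating-point arithmetic, so their results are bit-identical.
#'
#' @param query_xyz,target_xyz n x 3 coordinate matrices (or atom tables).
#' @param method `"grid"` or `"brute"`.
#' @param cell_size grid cell edge in Angstrom.
#' @return Numeric vector: for each query row, the nearest-target distance.
#' @export
nearest_distances <- function(query_xyz, target_xyz,
                              method = c("grid", "brute"), cell_size = 4) {
  method <- match.arg(method)
  Q <- as_xyz_matrix(query_xyz)
  T_ <- as_xyz_matrix(target_xyz)
  if (nrow(Q) == 0L || nrow(T_) == 0L) {
    stop2("empty_input", "empty atom set in nearest_distances")
  }
  if (method == "brute") {
    return(vapply(seq_len(nrow(Q)), function(i) {
      sqrt(min(point_dist2(Q[i, ], T_)))
    }, numeric(1L)))
  }
  # cell list over targets
  lo <- apply(T_, 2L, min)
  ci <- matrix(as.integer(floor(sweep(T_, 2L, lo) / cell_size)), ncol = 3L)
  dims <- as.integer(apply(ci, 2L, max)) + 1L
  cell_id <- ci[, 1L] + dims[1L] * (ci[, 2L] + dims[2L] * ci[, 3L])
  cells <- split(seq_len(nrow(T_)), cell_id)
  vapply(seq_len(nrow(Q)), function(i) {
    q <- Q[i, ]
    qc <- as.integer(floor((q - lo) / cell_size))
    # ring radius beyond which every grid cell has been visited
    r_cover <- max(pmax(abs(qc), abs(qc - (dims - 1L))))
    best2 <- Inf
    r <- 0L
    repeat {
      idx <- ring_cell_indices(qc, r, dims)
      if (length(idx)) {
        cand <- unlist(cells[as.character(idx)], use.names = FALSE)
        if (length(cand)) {
          d2 <- point_dist2(q, T_[cand, , drop = FALSE])
          m <- min(d2)
          if (m < best2) best2 <- m
        }
      }
      # cells in ring r+1 are at least r * cell_size away from q
      if ((is.finite(best2) && best2 <= (r * cell_size)^2) || r >= r_cover) {
        break
      }
      r <- r + 1L
    }
    sqrt(best2)
  }, numeric(1L))
}

# Linearised ids of grid cells in the Chebyshev ring of radius r around qc,
# clipped to the grid extent. qc may lie outside the grid.
ring_cell_indices <- function(qc, r, dims) {
  rng <- function(k) {
    lo <- max(0L, qc[k] - r); hi <- min(dims[k] - 1L, qc[k] + r)
    if (lo > hi) integer(0) else seq.int(lo, hi)
  }
  xs <- rng(1L); ys <- rng(2L); zs <- rng(3L)
  if (!length(xs) || !length(ys) || !length(zs)) return(integer(0))
  g <- expand.grid(x = xs, y = ys, z = zs)
  if (r > 0L) {
    cheb <- pmax(abs(g$x - qc[1L]), abs(g$y - qc[2L]), abs(g$z - qc[3L]))
    g <- g[cheb == r, , drop = FALSE]
  }
  as.integer(g$x + dims[1L] * (g$y + dims[2L] * g$z))
}

#' Lipid-to-protein-surface distance summary
#'
#' For each heavy atom of a lipid selection, the distance to the nearest
#' protein heavy atom, summarised as mean and standard deviation. This is
#' the statistic used to compare how tightly native and non-native lipid
#' chains pack against the protein's hydrophobic surface.
#'
#' The "surface" target set is all protein heavy atoms by default; set
#' `apolar_only = TRUE` to restrict it to carbon and sulfur atoms.
#'
#' @param lipid_atoms atom table of the lipid selection (hydrogens ignored).
#' @param protein_atoms atom table of the protein (hydrogens ignored).
#' @param apolar_only restrict the target surface to C and S atoms.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param method passed to [nearest_distances()].
#' @return An object of class `distance_summary`: `n_atoms`, `per_atom`
#'   (named by atom labels), `mean`, `sd`.
#' @export
nearest_surface_distances <- function(lipid_atoms, protein_atoms,
                                      apolar_only = FALSE,
                                      sd_type = c("sample", "population"),
                                      method = "grid") {
  sd_type <- match.arg(sd_type)
  la <- heavy_atoms(lipid_atoms)
  pa <- heavy_atoms(protein_atoms)
  if (apolar_only) pa <- pa[pa$element %in% c("C", "S"), , drop = FALSE]
  if (nrow(la) == 0L || nrow(pa) == 0L) {
    stop2("empty_input", "empty lipid or protein atom set")
  }
  d <- nearest_distances(atom_xyz(la), atom_xyz(pa), method = method)
  names(d) <- paste0(la$resname, la$resno, "/", la$atom)
  n <- length(d)
  s <- if (n < 2L) 0 else {
    if (sd_type == "sample") stats::sd(d)
    else sqrt(mean((d - mean(d))^2))
  }
  out <- list(n_atoms = n, per_atom = d, mean = mean(d), sd = s,
              sd_type = sd_type, apolar_only = apolar_only)
  class(out) <- "distance_summary"
  out
}

#' @export
print.distance_summary <- function(x, digits = 2, ...) {
  cat(sprintf("nearest-surface distance: %.*f +/- %.*f A over %d lipid atoms%s\n",
              digits, x$mean, digits, x$sd, x$n_atoms,
              if (x$apolar_only) " (apolar surface)" else ""))
  invisible(x)
}

#' Extract the annular lipid shell
#'
#' A lipid residue belongs to the shell if at least one of its heavy atoms
#' lies within `cutoff` (inclusive) of any protein heavy atom of the named
#' protomer chains. The 5 Angstrom default delimits the first (annular)
#' lipid layer.
#'
#' @param structure an `mr_structure`.
#' @param protomer_chains chain identifiers of the protomer(s); default all
#'   protein chains.
#' @param cutoff shell cutoff in Angstrom (> 0, boundary inclusive).
#' @param dictionary lipid dictionary.
#' @return An object of class `shell_result` with `cutoff` and `members`, a
#'   data frame (one row per member lipid residue, sorted by minimum
#'   distance) with columns `chain`, `resname`, `resno`, `insert`,
#'   `lipid_class`, `min_distance`, `n_atoms_within`.
#' @export
extract_shell <- function(structure, protomer_chains = NULL, cutoff = 5,
                          dictionary = lipid_dictionary()) {
  stopifnot(cutoff > 0)
  part <- partition_structure(structure, dictionary)
  prot <- heavy_atoms(part$protein)
  if (!is.null(protomer_chains)) {
    missing_ch <- setdiff(protomer_chains, unique(prot$chain))
    if (length(missing_ch)) {
      stop2("unknown_chain", "no protein atoms in chain(s): %s",
            paste(missing_ch, collapse = ", "))
    }
    prot <- prot[prot$chain %in% protomer_chains, , drop = FALSE]
  }
  lip <- heavy_atoms(part$lipid)
  members <- data.frame(chain = character(), resname = character(),
                        resno = integer(), insert = character(),
                        lipid_class = character(), min_distance = numeric(),
                        n_atoms_within = integer(), stringsAsFactors = FALSE)
  if (nrow(lip) && nrow(prot)) {
    d <- nearest_distances(atom_xyz(lip), atom_xyz(prot))
    key <- residue_keys(lip)
    for (k in unique(key)) {
      idx <- which(key == k)
      dmin <- min(d[idx])
      if (dmin <= cutoff) {
        members <- rbind(members, data.frame(
          chain = lip$chain[idx[1L]], resname = lip$resname[idx[1L]],
          resno = lip$resno[idx[1L]], insert = lip$insert[idx[1L]],
          lipid_class = component_class(lip$resname[idx[1L]], dictionary),
          min_distance = dmin,
          n_atoms_within = sum(d[idx] <= cutoff),
          stringsAsFactors = FALSE))
      }
    }
    members <- members[order(members$min_distance), , drop = FALSE]
    rownames(members) <- NULL
  }
  out <- list(cutoff = cutoff, members = members)
  class(out) <- "shell_result"
  out
}

#' @export
print.shell_result <- function(x, ...) {
  cat(sprintf("annular shell at %.1f A: %d lipid residue%s\n", x$cutoff,
              nrow(x$members), if (nrow(x$members) == 1L) "" else "s"))
  if (nrow(x$members)) print(x$members, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.shell_result <- function(x, ...) x$members

#' Classify the location of a lipid within an oligomeric assembly
#'
#' Labels a lipid residue as
#'
#' * `inner_compartment`: contacts >= 2 protomers and its centroid,
#'   projected on the membrane plane, falls inside the polygon of protomer
#'   centroids (the central cavity along the symmetry axis);
#' * `inter_protomer`: contacts >= 2 protomers outside that polygon
#'   (crevices fastening adjacent protomers together);
#' * `peripheral`: contacts fewer than 2 protomers.
#'
#' A protomer counts as contacted when any of its protein heavy atoms lies
#' within `contact_cutoff` of a lipid heavy atom.
#'
#' @param lipid_atoms atom table of one lipid residue.
#' @param structure the assembly (`mr_structure`) with >= 2 protomer chains.
#' @param frame a `membrane_frame` for the assembly.
#' @param contact_cutoff contact distance in Angstrom (default 4.5).
#' @param dictionary lipid dictionary.
#' @return A list of class `location_label`: `label`,
#'   `contacting_protomers`, `axis_distance` (Angstrom, in-plane distance of
#'   the lipid centroid from the protomer-centroid average).
#' @export
classify_location <- function(lipid_atoms, structure, frame,
                              contact_cutoff = 4.5,
                              dictionary = lipid_dictionary()) {
  part <- partition_structure(structure, dictionary)
  prot <- heavy_atoms(part$protein)
  chains <- sort(unique(prot$chain))
  la <- heavy_atoms(lipid_atoms)
  if (nrow(la) == 0L) stop2("empty_input", "lipid residue has no heavy atoms")
  if (length(chains) < 2L) {
    warn2("monomeric_assembly",
          "assembly has fewer than 2 protomers; labelling peripheral")
    out <- list(label = "peripheral", contacting_protomers = character(0),
                axis_distance = NA_real_)
    class(out) <- "location_label"
    return(out)
  }
  contacting <- chains[vapply(chains, function(ch) {
    pxyz <- atom_xyz(prot[prot$chain == ch, , drop = FALSE])
    min(nearest_distances(atom_xyz(la), pxyz)) <= contact_cutoff
  }, logical(1L))]
  # in-plane projection basis orthogonal to the membrane normal
  basis <- plane_basis(frame$normal)
  proj <- function(xyz) {
    cbind(as.vector(xyz %*% basis$u), as.vector(xyz %*% basis$v))
  }
  cent_l <- proj(matrix(colMeans(atom_xyz(la)), 1L, 3L))
  cents_p <- t(vapply(chains, function(ch) {
    colMeans(atom_xyz(prot[prot$chain == ch, , drop = FALSE]))
  }, numeric(3L)))
  cents_2d <- proj(cents_p)
  axis_dist <- sqrt(sum((cent_l - colMeans(cents_2d))^2))
  label <- if (length(contacting) >= 2L &&
               point_in_convex_polygon(cent_l, cents_2d)) {
    "inner_compartment"
  } else if (length(contacting) >= 2L) {
    "inter_protomer"
  } else {
    "peripheral"
  }
  out <- list(label = label, contacting_protomers = contacting,
              axis_distance = axis_dist)
  class(out) <- "location_label"
  out
}

#' @export
print.location_label <- function(x, ...) {
  cat(sprintf("location: %s (contacts: %s; in-plane axis distance %.2f A)\n",
              x$label,
              if (length(x$contacting_protomers))
                paste(x$contacting_protomers, collapse = ",") else "none",
              x$axis_distance))
  invisible(x)
}

# Orthonormal basis {u, v} of the plane orthogonal to n.
plane_basis <- function(n) {
  n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2L] * u[3L] - n[3L] * u[2L],
         n[3L] * u[1L] - n[1L] * u[3L],
         n[1L] * u[2L] - n[2L] * u[1L])
  list(u = u, v = v)
}

# Point-in-convex-polygon test (2D); vertices need not be ordered, the
# convex hull is taken first. Boundary counts as inside.
point_in_convex_polygon <- function(p, vertices, tol = 1e-9) {
  hull <- grDevices::chull(vertices[, 1L], vertices[, 2L])
  vs <- vertices[hull, , drop = FALSE]
  m <- nrow(vs)
  if (m < 3L) {
    # degenerate polygon: treat as segment/point, inside iff within tol
    return(FALSE)
  }
  sgn <- 0
  for (i in seq_len(m)) {
    a <- vs[i, ]; b <- vs[if (i == m) 1L else i + 1L, ]
    cr <- (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
    if (abs(cr) < tol) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}
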