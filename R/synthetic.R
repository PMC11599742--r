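# Synthetic membrane-protein scenes: idealized seven-helix bundles (optionally
# C3 trimers) with planted annular lipid chains and noble-gas atoms, plus the
# ground truth needed to test every pipeline stage without real data.
#
# Geometry conventions: the protomer axis is vertical (z); helices are ideal
# alpha-helical C-alpha spirals (rise 1.5 A per residue, 100 degrees per
# residue, spiral radius 2.3 A) with approximate backbone N/C/O positions and
# a C-beta pseudo-atom for the side chain. Residue identities are hydrophobic
# inside the declared membrane belt and polar outside, so the slab boundary
# estimator sees a realistic hydropathy profile.

HELIX_RISE <- 1.5
HELIX_TWIST <- 100 * pi / 180
HELIX_SPIRAL_R <- 2.3
BUNDLE_R <- 8.5        # helix axes from the protomer axis
TRIMER_R <- 15         # protomer axes from the C3 axis
PROTOMER_PHASE <- 3 * pi / 180  # helix-wheel rotation about the protomer
                                # axis; sets the width of the trimer's inner
                                # compartment relative to the contact cutoff
HYDROPHOBIC_CYCLE <- c("LEU", "ILE", "VAL", "PHE", "ALA", "MET")
POLAR_CYCLE <- c("SER", "LYS", "ASP", "GLN", "ASN", "THR")

#' Specify a synthetic membrane-protein scene
#'
#' A `scene_spec` fully determines a scene: the same spec (including seed)
#' always builds identical coordinates.
#'
#' @param seed integer RNG seed.
#' @param n_helices helices per protomer (default 7).
#' @param helix_length residues per helix (default 24).
#' @param trimer build a C3-symmetric trimer (chains A, B, C)?
#' @param boundaries hydrophobic--hydrophilic boundary z-values in Angstrom
#'   (default `c(-16, 16)`); the bilayer median sits at their midpoint.
#' @param lipids list of lipid placements; each element a list with fields
#'   `class` (`"linear_acyl"` or `"archaeal_diphytanyl"`), `location`
#'   (`"peripheral"`, `"inner_compartment"`, `"inter_protomer"`), `d0`
#'   (target nearest-surface distance, Angstrom, > 2.8), `jitter`
#'   (per-atom Gaussian sigma, Angstrom), `branched` (logical),
#'   `n_carbons` (default 16).
#' @param gas noble-gas depth mixture: list with `weights` (sum 1), `means`,
#'   `sds` (Angstrom) and `n` atoms, or `NULL` for none.
#' @param lipid_depth_mixture optional mixture spec (same fields as `gas`
#'   plus `d0`, default 4) planting short lipid fragments whose depths are
#'   drawn from the mixture -- used to emulate the depth concentration of
#'   annular lipid atoms.
#' @return A validated list of class `scene_spec`.
#' @export
scene_spec <- function(seed = 1L, n_helices = 7L, helix_length = 24L,
                       trimer = FALSE, boundaries = c(-16, 16),
                       lipids = list(), gas = NULL,
                       lipid_depth_mixture = NULL) {
  stopifnot(length(boundaries) == 2L, boundaries[1L] < boundaries[2L],
            n_helices >= 3L, helix_length >= 4L)
  for (lp in lipids) {
    stopifnot(!is.null(lp$location), !is.null(lp$d0))
    if (lp$d0 <= 2.8) {
      stop2("invalid_scene_spec",
            "lipid target distance d0 must exceed the 2.8 A contact radius")
    }
    if (lp$location == "inter_protomer" && !trimer) {
      stop2("invalid_scene_spec",
            "inter_protomer placement requires a trimer scene")
    }
    if (lp$location == "inner_compartment" && !trimer) {
      stop2("invalid_scene_spec",
            "inner_compartment placement requires a trimer scene")
    }
  }
  for (mx in list(gas, lipid_depth_mixture)) {
    if (!is.null(mx)) {
      stopifnot(length(mx$weights) == length(mx$means),
                length(mx$means) == length(mx$sds), mx$n >= 1)
      if (abs(sum(mx$weights) - 1) > 1e-9) {
        stop2("invalid_scene_spec", "mixture weights must sum to 1")
      }
    }
  }
  out <- list(seed = as.integer(seed), n_helices = as.integer(n_helices),
              helix_length = as.integer(helix_length), trimer = trimer,
              boundaries = as.numeric(boundaries), lipids = lipids,
              gas = gas, lipid_depth_mixture = lipid_depth_mixture)
  class(out) <- "scene_spec"
  out
}

#' Ideal lipid chain geometry
#'
#' Builds an ideal hydrocarbon chain along +z: backbone carbons with 1.27 A
#' rise and alternating 0.44 A lateral offset (C-C bond 1.54 A, 1-3 distance
#' 2.54 A), with methyl branch carbons every 4th backbone carbon when
#' `branched` (the phytanyl pattern).
#'
#' @param n_carbons backbone carbons (>= 2).
#' @param branched add methyl branches every 4th carbon?
#' @return Matrix (n x 3) of carbon coordinates with rownames `C1..` /
#'   `CM..` (branch methyls).
#' @export
make_lipid_chain <- function(n_carbons = 16L, branched = FALSE) {
  stopifnot(n_carbons >= 2L)
  j <- seq_len(n_carbons)
  xyz <- cbind(x = 0.44 * (j %% 2L), y = 0, z = 1.27 * (j - 1L))
  rownames(xyz) <- paste0("C", j)
  if (branched) {
    at <- seq(3L, n_carbons - 1L, by = 4L)
    if (length(at)) {
      br <- cbind(x = xyz[at, 1L], y = 1.53, z = xyz[at, 3L])
      rownames(br) <- paste0("CM", seq_along(at))
      xyz <- rbind(xyz, br)
    }
  }
  xyz
}

#' Build a synthetic scene
#'
#' Constructs the protein bundle (trimer if requested), plants the lipids at
#' their target nearest-surface distances, samples gas atoms from the depth
#' mixture, and returns the structure together with the ground truth.
#'
#' Placement: peripheral and inter-protomer lipid chains are first placed
#' tangent to the bundle surface and then each carbon is moved along the
#' direction away from its nearest protein heavy atom until its
#' nearest-surface distance equals `d0` exactly (so with zero jitter every
#' atom, and hence the residue minimum, sits at `d0`); per-atom Gaussian
#' jitter is added afterwards. Inner-compartment lipids stay on the C3 axis
#' (their achieved minimum distance, set by the trimer geometry, is recorded
#' in the ground truth instead).
#'
#' @param spec a [scene_spec()].
#' @return List of class `mr_scene`: `structure` (an `mr_structure`),
#'   `frame` (the ground-truth `membrane_frame`), `truth` (list with lipid
#'   table, gas depths and mixture component assignments), `spec`.
#' @export
build_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  prot <- build_protomer(spec)
  structure_one <- new_structure(prot$atoms, entry_id = "SYN1",
                                 helix = prot$helix)
  scene_structure <- if (spec$trimer) {
    moved <- translate_structure(structure_one, c(TRIMER_R, 0, 0))
    expand_assembly(moved, point_symmetry = "C3")
  } else {
    structure_one
  }
  frame <- assign_frame(scene_structure, boundaries = spec$boundaries,
                        normal = c(0, 0, 1))
  prot_heavy <- heavy_atoms(
    partition_structure(scene_structure)$protein)
  prot_xyz <- atom_xyz(prot_heavy)

  lipid_rows <- NULL
  truth_lipids <- data.frame(resname = character(), resno = integer(),
                             location = character(), d0_target = numeric(),
                             d0_achieved = numeric(), jitter = numeric(),
                             branched = logical(), stringsAsFactors = FALSE)
  resno_next <- 1001L
  for (lp in spec$lipids) {
    n_c <- lp$n_carbons %||% 16L
    branched <- isTRUE(lp$branched)
    jitter <- lp$jitter %||% 0
    resname <- if (identical(lp$class, "archaeal_diphytanyl") || branched)
      "L2P" else "LFA"
    chain_xyz <- make_lipid_chain(n_c, branched)
    placed <- place_lipid(chain_xyz, lp$location, lp$d0, prot_xyz, spec)
    if (jitter > 0) {
      placed$xyz <- placed$xyz +
        matrix(stats::rnorm(length(placed$xyz), sd = jitter), ncol = 3L)
    }
    d_ach <- min(nearest_distances(placed$xyz, prot_xyz, method = "brute"))
    lipid_rows <- rbind(lipid_rows, data.frame(
      chain = "A", resname = resname, resno = resno_next, insert = "",
      atom = rownames(placed$xyz), element = "C",
      x = placed$xyz[, 1L], y = placed$xyz[, 2L], z = placed$xyz[, 3L],
      occ = 1, b = 0, het = TRUE, hydrogen = FALSE,
      stringsAsFactors = FALSE))
    truth_lipids <- rbind(truth_lipids, data.frame(
      resname = resname, resno = resno_next, location = lp$location,
      d0_target = lp$d0, d0_achieved = d_ach, jitter = jitter,
      branched = branched, stringsAsFactors = FALSE))
    resno_next <- resno_next + 1L
  }

  frag_truth <- NULL
  if (!is.null(spec$lipid_depth_mixture)) {
    mx <- spec$lipid_depth_mixture
    frag <- plant_depth_fragments(mx, prot_xyz, spec, resno_start = resno_next)
    lipid_rows <- rbind(lipid_rows, frag$atoms)
    frag_truth <- frag$truth
    resno_next <- resno_next + nrow(frag$truth)
  }

  gas_rows <- NULL
  gas_truth <- NULL
  if (!is.null(spec$gas)) {
    mx <- spec$gas
    comp <- sample.int(length(mx$weights), mx$n, replace = TRUE,
                       prob = mx$weights)
    depth <- stats::rnorm(mx$n, mean = mx$means[comp], sd = mx$sds[comp])
    ang <- stats::runif(mx$n, 0, 2 * pi)
    r_surf <- BUNDLE_R + HELIX_SPIRAL_R + 3
    cx <- if (spec$trimer) TRIMER_R else 0
    gas_rows <- data.frame(
      chain = "A", resname = "AR", resno = 2000L + seq_len(mx$n), insert = "",
      atom = "AR", element = "AR",
      x = cx + r_surf * cos(ang), y = r_surf * sin(ang),
      z = depth + frame$z_origin,
      occ = 1, b = 0, het = TRUE, hydrogen = FALSE, stringsAsFactors = FALSE)
    gas_truth <- list(depths = depth, component = comp, mixture = mx)
  }

  atoms <- rbind(scene_structure$atoms, lipid_rows, gas_rows)
  rownames(atoms) <- NULL
  out_structure <- new_structure(atoms, entry_id = scene_structure$entry_id,
                                 helix = scene_structure$helix)
  out <- list(structure = out_structure, frame = frame,
              truth = list(lipids = truth_lipids, fragments = frag_truth,
                           gas = gas_truth, boundaries = spec$boundaries),
              spec = spec)
  class(out) <- "mr_scene"
  out
}

#' @export
print.mr_scene <- function(x, ...) {
  cat(sprintf("<mr_scene seed %d> %s%s, %d planted lipids, %s gas atoms\n",
              x$spec$seed, if (x$spec$trimer) "trimer" else "monomer",
              sprintf(" (%d helices x %d residues)", x$spec$n_helices,
                      x$spec$helix_length),
              nrow(x$truth$lipids),
              if (is.null(x$truth$gas)) "no" else length(x$truth$gas$depths)))
  invisible(x)
}

# -- internal scene construction ---------------------------------------------

.protomer_cache <- new.env(parent = emptyenv())

# Protomer construction is deterministic (no RNG), so cache by geometry key.
build_protomer <- function(spec) {
  key <- paste(spec$n_helices, spec$helix_length,
               paste(spec$boundaries, collapse = ","), sep = "|")
  if (!is.null(.protomer_cache[[key]])) return(.protomer_cache[[key]])
  out <- build_protomer_impl(spec)
  .protomer_cache[[key]] <- out
  out
}

build_protomer_impl <- function(spec) {
  L <- spec$helix_length
  nh <- spec$n_helices
  z_span <- (L - 1L) * HELIX_RISE
  z0 <- -z_span / 2
  belt <- spec$boundaries
  atoms <- NULL
  helix <- NULL
  for (k in seq_len(nh) - 1L) {
    phi <- 2 * pi * k / nh + PROTOMER_PHASE
    hx <- BUNDLE_R * cos(phi); hy <- BUNDLE_R * sin(phi)
    up <- k %% 2L == 0L
    i <- seq_len(L)
    zz <- z0 + (i - 1L) * HELIX_RISE
    if (!up) zz <- rev(zz)
    th <- (i - 1L) * HELIX_TWIST + phi
    ca <- cbind(hx + HELIX_SPIRAL_R * cos(th),
                hy + HELIX_SPIRAL_R * sin(th), zz)
    # local helix tangent for backbone pseudo-atoms
    tvec <- rbind(ca[2L, ] - ca[1L, ],
                  ca[pmin(i + 1L, L)[-c(1L, L)] + 0L, ] -
                    ca[pmax(i - 1L, 1L)[-c(1L, L)], ],
                  ca[L, ] - ca[L - 1L, ])
    tvec <- tvec / sqrt(rowSums(tvec^2))
    # radial direction from the helix axis (for O) and from the protomer
    # axis (for C-beta)
    rad_h <- cbind(cos(th), sin(th), 0)
    cb_dir <- ca - cbind(0, 0, zz)
    cb_norm <- sqrt(rowSums(cb_dir^2))
    cb_dir <- cb_dir / ifelse(cb_norm > 1e-9, cb_norm, 1)
    resno <- k * 100L + i
    depth_in_belt <- zz >= belt[1L] & zz <= belt[2L]
    resname <- ifelse(depth_in_belt,
                      HYDROPHOBIC_CYCLE[(i - 1L) %% length(HYDROPHOBIC_CYCLE) + 1L],
                      POLAR_CYCLE[(i - 1L) %% length(POLAR_CYCLE) + 1L])
    for (nm in c("N", "CA", "C", "O", "CB")) {
      pos <- switch(nm,
        N = ca - 0.75 * tvec,
        CA = ca,
        C = ca + 0.75 * tvec,
        O = ca + 0.75 * tvec + 1.23 * rad_h,
        CB = ca + 1.5 * cb_dir)
      atoms <- rbind(atoms, data.frame(
        chain = "A", resname = resname, resno = resno, insert = "",
        atom = nm, element = substr(nm, 1L, 1L),
        x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
        occ = 1, b = 0, het = FALSE, hydrogen = FALSE,
        stringsAsFactors = FALSE))
    }
    helix <- rbind(helix, data.frame(chain = "A", start = min(resno),
                                     end = max(resno),
                                     stringsAsFactors = FALSE))
  }
  # retinal: a short polyene arc inside the bundle at mid-membrane height
  n_ret <- 12L
  dth <- 1.4 / 4.0
  th <- (seq_len(n_ret) - 1L) * dth
  ret <- data.frame(
    chain = "A", resname = "RET", resno = 900L, insert = "",
    atom = paste0("C", seq_len(n_ret)), element = "C",
    x = 4.0 * cos(th), y = 4.0 * sin(th), z = 0.5,
    occ = 1, b = 0, het = TRUE, hydrogen = FALSE, stringsAsFactors = FALSE)
  atoms <- rbind(atoms, ret)
  atoms <- atoms[order(atoms$resno, method = "radix"), , drop = FALSE]
  rownames(atoms) <- NULL
  list(atoms = atoms, helix = helix)
}

translate_structure <- function(structure, shift) {
  structure$atoms$x <- structure$atoms$x + shift[1L]
  structure$atoms$y <- structure$atoms$y + shift[2L]
  structure$atoms$z <- structure$atoms$z + shift[3L]
  structure
}

# Initial placement + per-atom distance calibration for one lipid chain.
place_lipid <- function(chain_xyz, location, d0, prot_xyz, spec) {
  cx <- if (spec$trimer) TRIMER_R else 0
  surface_r <- BUNDLE_R + HELIX_SPIRAL_R + 1.5
  pos0 <- switch(location,
    peripheral = {
      ang <- stats::runif(1L, 0, 2 * pi)
      r <- surface_r + d0 + 2
      c(cx + r * cos(ang), r * sin(ang), 0)
    },
    inner_compartment = c(0, 0, 0),
    inter_protomer = {
      r <- TRIMER_R
      c(r * cos(pi / 3), r * sin(pi / 3), 0)
    },
    stop2("invalid_scene_spec", "unknown lipid location '%s'", location)
  )
  # centre the chain vertically on the membrane median, stand it upright
  xyz <- chain_xyz
  xyz[, 3L] <- xyz[, 3L] - mean(range(xyz[, 3L]))
  if (location == "inner_compartment") {
    # centroid exactly on the C3 axis so the three protomers are seen
    # near-symmetrically
    xyz[, 1L] <- xyz[, 1L] - mean(xyz[, 1L])
    xyz[, 2L] <- xyz[, 2L] - mean(xyz[, 2L])
    return(list(xyz = sweep(xyz, 2L, -pos0)))
  }
  xyz <- sweep(xyz, 2L, -pos0)
  axis_center <- if (location == "inter_protomer") c(0, 0) else c(cx, 0)
  calibrate_atoms(xyz, prot_xyz, d0, axis_center)
}

# Calibrate each atom independently so that its nearest-protein distance
# equals d0: 1-D bisection along the atom's outward horizontal ray (away
# from `axis_center`). Atoms do not interact, so a single pass is exact.
calibrate_atoms <- function(xyz, prot_xyz, d0, axis_center,
                            tol = 1e-12) {
  for (i in seq_len(nrow(xyz))) {
    p <- xyz[i, ]
    # the ray is horizontal, so protein atoms further than d0 + 6 A away in
    # z can never be the nearest once the atom sits near its target
    # distance; restricting to this slab leaves the root of f unchanged
    slab <- abs(prot_xyz[, 3L] - p[3L]) <= d0 + 6
    targets <- if (any(slab)) prot_xyz[slab, , drop = FALSE] else prot_xyz
    nearest_of <- function(q) sqrt(min(point_dist2(q, targets)))
    u <- c(p[1L] - axis_center[1L], p[2L] - axis_center[2L], 0)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) u <- c(1, 0, 0) else u <- u / nu
    f <- function(t) nearest_of(p + t * u) - d0
    f0 <- f(0)
    if (abs(f0) <= tol) next
    # bracket a sign change along the ray
    step <- if (f0 < 0) 1 else -1
    t_hi <- 0
    found <- FALSE
    for (k in seq_len(200L)) {
      t_new <- t_hi + step
      if (sign(f(t_new)) != sign(f0)) { found <- TRUE; break }
      t_hi <- t_new
    }
    if (!found) {
      stop2("placement_failure",
            "cannot bracket target distance %.2f A for lipid atom %d", d0, i)
    }
    lo <- min(t_hi, t_hi + step); hi <- max(t_hi, t_hi + step)
    flo <- f(lo)
    for (k in seq_len(200L)) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) <= tol) { lo <- hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    t_star <- (lo + hi) / 2
    if (abs(f(t_star)) > max(10 * tol, 1e-9)) {
      stop2("placement_failure",
            "distance calibration did not converge for lipid atom %d", i)
    }
    xyz[i, ] <- p + t_star * u
  }
  list(xyz = xyz)
}

# Short lipid fragments at mixture-drawn depths (annular depth profile).
plant_depth_fragments <- function(mx, prot_xyz, spec, resno_start) {
  d0 <- mx$d0 %||% 4
  comp <- sample.int(length(mx$weights), mx$n, replace = TRUE,
                     prob = mx$weights)
  depth <- stats::rnorm(mx$n, mean = mx$means[comp], sd = mx$sds[comp])
  ang <- stats::runif(mx$n, 0, 2 * pi)
  # fragments need a protein surface at their height: truncate the mixture
  # to the helix bundle's z-extent (the depth profile only admits atoms
  # within the boundaries anyway)
  z_max <- (spec$helix_length - 1L) * HELIX_RISE / 2 - 2
  keep <- abs(depth) <= z_max
  comp <- comp[keep]; depth <- depth[keep]; ang <- ang[keep]
  n_keep <- length(depth)
  cx <- if (spec$trimer) TRIMER_R else 0
  surface_r <- BUNDLE_R + HELIX_SPIRAL_R + 1.5
  atoms <- NULL
  mid <- mean(spec$boundaries)
  for (i in seq_len(n_keep)) {
    frag <- make_lipid_chain(3L)
    frag[, 3L] <- frag[, 3L] - mean(range(frag[, 3L]))
    pos0 <- c(cx + (surface_r + d0) * cos(ang[i]),
              (surface_r + d0) * sin(ang[i]),
              depth[i] + mid)
    frag <- sweep(frag, 2L, -pos0)
    # fragments only need to pass the proximity filter, so a loose distance
    # tolerance suffices (planted-d0 lipids use the exact default)
    frag <- calibrate_atoms(frag, prot_xyz, d0, c(cx, 0), tol = 1e-6)$xyz
    atoms <- rbind(atoms, data.frame(
      chain = "A", resname = "LFA", resno = resno_start + i - 1L,
      insert = "", atom = rownames(frag), element = "C",
      x = frag[, 1L], y = frag[, 2L], z = frag[, 3L],
      occ = 1, b = 0, het = TRUE, hydrogen = FALSE, stringsAsFactors = FALSE))
  }
  list(atoms = atoms,
       truth = data.frame(resno = resno_start + seq_len(n_keep) - 1L,
                          depth = depth, component = comp))
}

#' Write a scene fixture
#'
#' Writes the scene as a PDB file plus a JSON ground-truth sidecar
#' (`<path>.json`). Both writers are deterministic: the same spec always
#' produces byte-identical files.
#'
#' @param scene an `mr_scene` from [build_scene()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(scene, path) {
  write_structure_pdb(scene$structure, path)
  truth <- list(
    seed = scene$spec$seed,
    trimer = scene$spec$trimer,
    boundaries = scene$truth$boundaries,
    frame = list(normal = scene$frame$normal,
                 z_origin = scene$frame$z_origin,
                 z_lower = scene$frame$z_lower,
                 z_upper = scene$frame$z_upper),
    lipids = scene$truth$lipids,
    gas_depths = scene$truth$gas$depths %||% numeric(0))
  jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
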