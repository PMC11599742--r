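# Bilayer-depth profiles: distributions of lipid carbon and noble-gas atom
# positions along the membrane normal, and mode (peak) detection.

#' Lipid carbon atoms proximal to the protein
#'
#' Selects lipid carbon atoms whose nearest protein heavy atom lies within
#' `proximity_cutoff` and whose bilayer depth falls inside the
#' hydrophobic--hydrophilic boundaries. These are the atoms that enter the
#' lipid depth profile.
#'
#' @param structure an `mr_structure`.
#' @param frame a `membrane_frame`.
#' @param proximity_cutoff Angstrom (default 5, the annular-shell cutoff).
#' @param dictionary lipid dictionary.
#' @return Atom table of the admitted lipid carbons with an extra `depth`
#'   column.
#' @export
proximal_lipid_atoms <- function(structure, frame, proximity_cutoff = 5,
                                 dictionary = lipid_dictionary()) {
  part <- partition_structure(structure, dictionary)
  lip <- heavy_atoms(part$lipid)
  lip <- lip[lip$element == "C", , drop = FALSE]
  prot <- heavy_atoms(part$protein)
  if (nrow(lip) == 0L || nrow(prot) == 0L) {
    lip$depth <- numeric(0)
    return(lip)
  }
  d <- nearest_distances(atom_xyz(lip), atom_xyz(prot))
  depth <- depths_of(lip, frame)
  keep <- d <= proximity_cutoff & depth >= frame$z_lower &
    depth <= frame$z_upper
  out <- lip[keep, , drop = FALSE]
  out$depth <- depth[keep]
  rownames(out) <- NULL
  out
}

#' Bilayer depth histogram
#'
#' Bins atom depths into uniform bins spanning the boundary interval
#' `[z_lower, z_upper]` of the frame. Depths outside the boundaries are
#' excluded (the profile only counts atoms within the hydrophobic belt).
#' An empty depth list yields an all-zero histogram, not an error.
#'
#' @param depths numeric vector of depths (Angstrom), e.g. from
#'   [depths_of()] or the `depth` column of [proximal_lipid_atoms()].
#' @param frame a `membrane_frame` supplying the boundaries.
#' @param bin_width bin width in Angstrom (> 0; default 2).
#' @param smoothing_window moving-average window (bins) used for the mode
#'   detection stored in the result.
#' @return Object of class `depth_histogram`: `bin_edges`, `bin_centers`,
#'   `counts`, `n_total`, `boundaries_applied`, `modes`.
#' @export
depth_histogram <- function(depths, frame, bin_width = 2,
                            smoothing_window = 3) {
  stopifnot(bin_width > 0)
  n_bins <- max(1L, as.integer(ceiling(
    (frame$z_upper - frame$z_lower) / bin_width - 1e-9)))
  edges <- frame$z_lower + bin_width * seq.int(0L, n_bins)
  keep <- depths >= frame$z_lower & depths <= frame$z_upper
  d <- depths[keep]
  # bin index: left-closed bins, last bin right-closed
  idx <- pmin(n_bins, as.integer(floor((d - frame$z_lower) / bin_width)) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  out <- list(bin_edges = edges,
              bin_centers = (edges[-1L] + edges[-length(edges)]) / 2,
              counts = counts, n_total = length(d),
              boundaries_applied = TRUE, modes = numeric(0))
  class(out) <- "depth_histogram"
  out$modes <- detect_modes(out, smoothing_window = smoothing_window)
  out
}

#' @export
print.depth_histogram <- function(x, ...) {
  cat(sprintf("<depth_histogram> %d atoms in %d bins over [%.1f, %.1f] A\n",
              x$n_total, length(x$counts), min(x$bin_edges), max(x$bin_edges)))
  if (length(x$modes)) {
    cat("  modes at depth:", paste(sprintf("%.1f", x$modes), collapse = ", "),
        "A\n")
  }
  invisible(x)
}

#' Detect modes of a depth histogram
#'
#' Local maxima of the moving-average-smoothed counts. At the histogram ends
#' the averaging window shrinks symmetrically. Plateau maxima resolve to the
#' lower depth; all-zero histograms yield an empty mode list. Modes are
#' returned as bin-center depths, sorted ascending.
#'
#' @param histogram a `depth_histogram`.
#' @param smoothing_window odd window length in bins (1 = no smoothing).
#' @return Numeric vector of mode depths (Angstrom).
#' @export
detect_modes <- function(histogram, smoothing_window = 3) {
  counts <- histogram$counts
  n <- length(counts)
  stopifnot(n >= 1L, smoothing_window >= 1L, smoothing_window %% 2L == 1L)
  if (all(counts == 0L)) return(numeric(0))
  h <- (smoothing_window - 1L) %/% 2L
  s <- vapply(seq_len(n), function(i) {
    mean(counts[max(1L, i - h):min(n, i + h)])
  }, numeric(1L))
  modes <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L  # plateau [i, j]
    left_lower <- i == 1L || s[i - 1L] < s[i]
    right_lower <- j == n || s[j + 1L] < s[i]
    if (left_lower && right_lower && s[i] > 0) {
      modes <- c(modes, i)  # tie within plateau -> lower depth
    }
    i <- j + 1L
  }
  sort(histogram$bin_centers[modes])
}

#' Serialize a depth histogram
#'
#' @param histogram a `depth_histogram`.
#' @param path output path; `.json` writes JSON with metadata, anything else
#'   a two-column TSV (`bin_center`, `count`).
#' @return `path`, invisibly.
#' @export
write_histogram <- function(histogram, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(bin_edges = histogram$bin_edges, counts = histogram$counts,
           n_total = histogram$n_total, modes = histogram$modes,
           boundaries_applied = histogram$boundaries_applied),
      path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.table(
      data.frame(bin_center = histogram$bin_centers,
                 count = histogram$counts),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
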