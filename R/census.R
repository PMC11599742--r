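# Per-protomer lipid censuses and derived lipid budgets.

#' Per-protomer lipid census of a structure
#'
#' Counts modeled lipid fragments (one HET residue classified to a lipid
#' class = one fragment) per lipid class and divides by the number of
#' protomers using exact rational arithmetic, matching the convention of
#' reporting lipid contents "per one protomer" (e.g. a trimer with two
#' glycolipids reports 2/3). Residues of the non-lipid classes
#' (`small_amphiphile_or_cryo`, unknown codes) are tallied separately under
#' `other`.
#'
#' @param structure an `mr_structure`.
#' @param dictionary lipid dictionary.
#' @param n_protomers number of protomers the counts are normalised by
#'   (>= 1); defaults to the number of protein chains.
#' @return Object of class `census_row`: `entry_id`, `n_protomers`,
#'   `per_class_total` (integer vector by lipid class),
#'   `per_class_per_protomer` (character vector of exact rationals),
#'   `total_lipid_fragments`, `other_residues` (named counts).
#' @export
lipid_census <- function(structure, dictionary = lipid_dictionary(),
                         n_protomers = NULL) {
  part <- partition_structure(structure, dictionary)
  if (is.null(n_protomers)) {
    n_protomers <- max(1L, length(unique(part$protein$chain)))
  }
  if (n_protomers < 1L) {
    stop2("invalid_protomer_count", "n_protomers must be >= 1")
  }
  totals <- as.integer(part$counts)
  names(totals) <- names(part$counts)
  lipid_cls <- lipid_like_classes()
  totals <- totals[lipid_cls]
  per_prot <- vapply(totals, function(k) format_rational(k, n_protomers),
                     character(1L))
  oh <- part$other_het
  oh <- oh[!oh$resname %in% WATER_RES, , drop = FALSE]
  other <- if (nrow(oh)) {
    res <- unique(oh[, c("chain", "resno", "insert", "resname")])
    tab <- table(res$resname)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  out <- list(entry_id = structure$entry_id,
              n_protomers = as.integer(n_protomers),
              per_class_total = totals,
              per_class_per_protomer = per_prot,
              total_lipid_fragments = sum(totals),
              other_residues = other)
  class(out) <- "census_row"
  out
}

#' @export
print.census_row <- function(x, ...) {
  cat(sprintf("lipid census for %s (%d protomer%s): %d lipid fragment%s\n",
              x$entry_id, x$n_protomers, if (x$n_protomers == 1L) "" else "s",
              x$total_lipid_fragments,
              if (x$total_lipid_fragments == 1L) "" else "s"))
  nz <- x$per_class_total[x$per_class_total > 0]
  for (cl in names(nz)) {
    cat(sprintf("  %-26s %3d total  (%s per protomer)\n", cl, nz[[cl]],
                x$per_class_per_protomer[[cl]]))
  }
  if (length(x$other_residues)) {
    cat("  other het residues:",
        paste(sprintf("%s x%d", names(x$other_residues), x$other_residues),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.census_row <- function(x, ...) {
  data.frame(entry_id = x$entry_id,
             lipid_class = names(x$per_class_total),
             total = as.integer(x$per_class_total),
             per_protomer = unname(x$per_class_per_protomer),
             n_protomers = x$n_protomers,
             stringsAsFactors = FALSE)
}

#' Lipid budget for a trimer prediction
#'
#' How many lipid molecules to place when generating a full trimer model:
#' the per-protomer fragment count observed crystallographically, plus the
#' extra molecule(s) per protomer that consistently occupy the retinal
#' binding site in generated models, times three protomers.
#'
#' @param per_protomer observed lipid fragments per protomer (>= 0).
#' @param extra_per_protomer additional molecules per protomer (default 1,
#'   the retinal-site molecule).
#' @param n_protomers protomers in the assembly (default 3, a trimer).
#' @return Integer count of molecules.
#' @examples
#' trimer_lipid_budget(28)  # 87
#' @export
trimer_lipid_budget <- function(per_protomer, extra_per_protomer = 1,
                                n_protomers = 3) {
  stopifnot(per_protomer >= 0, extra_per_protomer >= 0, n_protomers >= 1)
  as.integer(n_protomers * (per_protomer + extra_per_protomer))
}
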