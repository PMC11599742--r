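#' Partition a structure into protein / retinal / lipid / solvent / other
#'
#' Residues are assigned to exactly one of five disjoint sets:
#'
#' * `protein`: standard amino-acid residues in ATOM records;
#' * `retinal`: residue `RET` (the chromophore);
#' * `solvent`: waters (`HOH`, `WAT`, `DOD`);
#' * `lipid`: HET residues whose component code classifies to a lipid class
#'   other than `unknown` or `small_amphiphile_or_cryo`;
#' * `other_het`: everything else (cryoprotectants, unknown codes, ions).
#'
#' @param structure an `mr_structure`.
#' @param dictionary lipid dictionary from [lipid_dictionary()].
#' @return An object of class `mr_partition`: a list of atom tables
#'   `protein`, `retinal`, `lipid`, `solvent`, `other_het` plus a `counts`
#'   table of residue counts per lipid class.
#' @export
partition_structure <- function(structure, dictionary = lipid_dictionary()) {
  a <- structure$atoms
  cls <- component_class(a$resname, dictionary)
  is_protein <- !a$het & a$resname %in% STANDARD_AA
  is_ret <- !is_protein & a$resname == "RET"
  is_solvent <- !is_protein & !is_ret & a$resname %in% WATER_RES
  is_lipid <- !is_protein & !is_ret & !is_solvent &
    cls %in% lipid_like_classes()
  is_other <- !(is_protein | is_ret | is_solvent | is_lipid)
  lipid <- a[is_lipid, , drop = FALSE]
  lipid_res <- unique(lipid[, c("chain", "resno", "insert", "resname")])
  lipid_res$lipid_class <- component_class(lipid_res$resname, dictionary)
  counts <- table(factor(lipid_res$lipid_class, levels = lipid_classes()))
  out <- list(protein = a[is_protein, , drop = FALSE],
              retinal = a[is_ret, , drop = FALSE],
              lipid = lipid,
              solvent = a[is_solvent, , drop = FALSE],
              other_het = a[is_other, , drop = FALSE],
              lipid_residues = lipid_res,
              counts = counts)
  class(out) <- "mr_partition"
  out
}

#' @export
print.mr_partition <- function(x, ...) {
  n_res <- function(df) if (nrow(df) == 0L) 0L else
    nrow(unique(df[, c("chain", "resno", "insert", "resname")]))
  cat(sprintf(paste0("<mr_partition> protein %d atoms | retinal %d | ",
                     "lipid %d atoms in %d residues | solvent %d | other %d\n"),
              nrow(x$protein), nrow(x$retinal), nrow(x$lipid),
              n_res(x$lipid), nrow(x$solvent), nrow(x$other_het)))
  nz <- x$counts[x$counts > 0]
  if (length(nz)) {
    cat("  lipid classes:",
        paste(sprintf("%s=%d", names(nz), as.integer(nz)), collapse = ", "),
        "\n")
  }
  invisible(x)
}
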