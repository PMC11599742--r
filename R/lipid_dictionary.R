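#' The lipid chemical-component dictionary
#'
#' Crystallographers model lipid and amphiphile fragments in membrane-protein
#' entries under three-letter chemical-component codes (for example `OLC` for
#' monoolein or `L2P` for the diphytanyl core of the archaeal glycolipid
#' S-TGA-1). At least 39 such codes occur across the microbial-rhodopsin
#' entries this package was built around; the shipped dictionary assigns each
#' one a lipid class. Classes:
#'
#' * `archaeal_diphytanyl` -- methyl-branched isoprenoid (phytanyl) chains,
#'   the hallmark of archaeal lipids;
#' * `linear_acyl` -- unbranched chains of bacterial lipids, host lipids
#'   (e.g. monoolein) or detergent tails;
#' * `carotenoid`, `isoprenoid_squalene` -- auxiliary native hydrophobic
#'   molecules;
#' * `detergent`, `sugar_headgroup_fragment`, `small_amphiphile_or_cryo` --
#'   non-lipid or headgroup-only components counted separately;
#' * `unknown` -- any code absent from the dictionary.
#'
#' @param extra optional data frame (or path to a TSV file) with columns
#'   `code`, `lipid_class`, `display_name` providing user extensions or
#'   overrides; overriding entries win over the shipped table.
#' @return A data frame with columns `code`, `lipid_class`, `display_name`,
#'   `source` (`"paper_list"` for shipped rows, `"user_extension"` otherwise).
#' @examples
#' dict <- lipid_dictionary()
#' nrow(dict) >= 39
#' @export
lipid_dictionary <- function(extra = NULL) {
  path <- system.file("extdata", "lipid_components.tsv", package = "annulipid")
  dict <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!is.null(extra)) {
    if (is_string(extra)) {
      extra <- utils::read.delim(extra, stringsAsFactors = FALSE,
                                 colClasses = "character")
    }
    stopifnot(all(c("code", "lipid_class") %in% names(extra)))
    extra$display_name <- extra$display_name %||% extra$code
    extra$source <- "user_extension"
    extra <- extra[, c("code", "lipid_class", "display_name", "source")]
    bad <- !extra$lipid_class %in% lipid_classes()
    if (any(bad)) {
      stop2("invalid_lipid_class", "unknown lipid_class in extension: %s",
            paste(unique(extra$lipid_class[bad]), collapse = ", "))
    }
    dict <- dict[!dict$code %in% extra$code, , drop = FALSE]
    dict <- rbind(dict, extra)
  }
  dict[order(dict$code), , drop = FALSE]
}

#' @rdname lipid_dictionary
#' @export
lipid_classes <- function() {
  c("archaeal_diphytanyl", "linear_acyl", "carotenoid", "isoprenoid_squalene",
    "detergent", "sugar_headgroup_fragment", "small_amphiphile_or_cryo",
    "unknown")
}

# Classes whose residues count as lipids in partitions and censuses.
lipid_like_classes <- function() {
  setdiff(lipid_classes(), c("unknown", "small_amphiphile_or_cryo"))
}

#' Classify a chemical-component code
#'
#' Looks up a three-letter component code in the lipid dictionary. Codes not
#' in the dictionary classify as `unknown` (never an error); malformed
#' identifiers (wrong length, non-alphanumeric) raise an
#' `invalid_identifier` error.
#'
#' @param code a 3-character uppercase alphanumeric component identifier.
#' @param dictionary a dictionary from [lipid_dictionary()].
#' @return A one-row list with fields `code`, `lipid_class`, `display_name`,
#'   `source`.
#' @examples
#' classify_component("L2P")$lipid_class  # "archaeal_diphytanyl"
#' classify_component("ZZZ")$lipid_class  # "unknown"
#' @export
classify_component <- function(code, dictionary = lipid_dictionary()) {
  if (!is_string(code) || nchar(code) != 3L || !grepl("^[A-Z0-9]{3}$", code)) {
    stop2("invalid_identifier",
          "component code must be 3 uppercase alphanumeric characters, got %s",
          deparse(code)[1L])
  }
  i <- match(code, dictionary$code)
  if (is.na(i)) {
    return(list(code = code, lipid_class = "unknown",
                display_name = code, source = "unlisted"))
  }
  as.list(dictionary[i, c("code", "lipid_class", "display_name", "source")])
}

# Vectorised class lookup for residue-name vectors; unlisted -> "unknown".
component_class <- function(codes, dictionary = lipid_dictionary()) {
  cls <- dictionary$lipid_class[match(codes, dictionary$code)]
  cls[is.na(cls)] <- "unknown"
  cls
}

#' Detect chain branching in a modeled residue
#'
#' Archaeal lipid chains are methyl-branched (phytanyl), bacterial and host
#' acyl chains are linear; the distinction is visible directly in the carbon
#' skeleton of a modeled fragment. Carbon--carbon bonds are inferred by a
#' distance threshold between carbon centres (default 1.9 Angstrom: covers
#' the 1.53 Angstrom C-C bond with refinement noise while excluding 1-3
#' neighbours at >= 2.5 Angstrom). A carbon bonded to three or more other
#' carbons is a branch point.
#'
#' @param residue_atoms atom table with `x`, `y`, `z` and either an `element`
#'   column or an `atom` (atom-name) column from which elements are inferred.
#' @param bond_cutoff C-C bond distance threshold in Angstrom.
#' @return A list of class `chain_geometry` with `n_carbons`,
#'   `n_branch_points` and `verdict` (`"branched"`, `"linear"` or
#'   `"undetermined"` for fragments of fewer than 4 carbons).
#' @export
detect_branching <- function(residue_atoms, bond_cutoff = 1.9) {
  stopifnot(nrow(residue_atoms) >= 1L)
  el <- residue_atoms$element
  if (is.null(el) || anyNA(el) || any(!nzchar(el))) {
    warn2("element_inference_required",
          "missing element records; inferring elements from atom names")
    inferred <- infer_element(residue_atoms$atom)
    if (is.null(el)) el <- inferred
    fix <- is.na(el) | !nzchar(el)
    el[fix] <- inferred[fix]
  }
  carbons <- toupper(el) == "C"
  xyz <- atom_xyz(residue_atoms)[carbons, , drop = FALSE]
  n <- nrow(xyz)
  if (n < 4L) {
    return(structure(list(n_carbons = n, n_branch_points = 0L,
                          verdict = "undetermined"),
                     class = "chain_geometry"))
  }
  d <- as.matrix(stats::dist(xyz))
  bonded <- d <= bond_cutoff
  diag(bonded) <- FALSE
  degree <- rowSums(bonded)
  n_branch <- sum(degree >= 3L)
  structure(list(n_carbons = n, n_branch_points = as.integer(n_branch),
                 verdict = if (n_branch >= 1L) "branched" else "linear"),
            class = "chain_geometry")
}

#' @export
print.chain_geometry <- function(x, ...) {
  cat(sprintf("chain geometry: %s (%d carbons, %d branch point%s)\n",
              x$verdict, x$n_carbons, x$n_branch_points,
              if (x$n_branch_points == 1L) "" else "s"))
  invisible(x)
}

# PDB-style element inference from an atom name: strip digits and primes,
# then take the leading alphabetic token; two-letter elements relevant to
# this domain are recognised explicitly.
infer_element <- function(atom_names) {
  two_letter <- c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "CU", "SE",
                  "AR", "KR", "XE", "CD", "NI", "CO")
  vapply(atom_names, function(nm) {
    stripped <- gsub("[0-9']", "", toupper(trimws(nm)))
    if (!nzchar(stripped)) return(NA_character_)
    if (stripped %in% two_letter) return(stripped)
    substr(stripped, 1L, 1L)
  }, character(1L), USE.NAMES = FALSE)
}
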