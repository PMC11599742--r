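# Structure reading/writing. Parsing of the standard formats is delegated to
# bio3d (read.pdb / read.cif); this module normalises the result into a plain
# atom table and applies the altloc and model-selection policies.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE")
WATER_RES <- c("HOH", "WAT", "DOD")

#' Read a crystal structure
#'
#' Reads a PDB or mmCIF file into a `mr_structure` object: an atom table plus
#' helix annotations. Policies applied on read:
#'
#' * alternate locations are resolved to a single conformer per atom, keeping
#'   the highest occupancy (ties go to altloc `"A"`, then alphabetical);
#' * only the first model of a multi-model file is kept (with a warning);
#' * hydrogen atoms are retained but flagged; all geometric analyses in this
#'   package use heavy atoms only.
#'
#' @param path path to the coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param entry_id optional entry identifier; defaults to the file base name.
#' @return An object of class `mr_structure` with elements `entry_id`,
#'   `atoms` (data frame with columns `chain`, `resname`, `resno`, `insert`,
#'   `atom`, `element`, `x`, `y`, `z`, `occ`, `b`, `het`, `hydrogen`) and
#'   `helix` (data frame `chain`, `start`, `end`, possibly empty).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           entry_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop2("format_error", "file not found: %s", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (format == "pdb") {
    n_models <- length(grep("^MODEL ", readLines(path, warn = FALSE)))
    if (n_models > 1L) {
      warn2("multi_model", "%s contains %d models; keeping the first only",
            path, n_models)
    }
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE)
    ),
    error = function(e) stop2("format_error", "cannot parse %s as %s: %s",
                              path, format, conditionMessage(e))
  )
  atoms <- normalize_bio3d_atoms(pdb$atom)
  helix <- helix_table(pdb)
  new_structure(atoms, entry_id = entry_id %||%
                  toupper(sub("\\.[^.]*$", "", basename(path))),
                helix = helix)
}

#' Construct a structure object from an atom table
#'
#' @param atoms atom table (see [read_structure()] for the columns).
#' @param entry_id entry identifier string.
#' @param helix optional helix-range data frame (`chain`, `start`, `end`).
#' @return An `mr_structure`.
#' @export
new_structure <- function(atoms, entry_id = "XXXX", helix = NULL) {
  needed <- c("chain", "resname", "resno", "insert", "atom", "element",
              "x", "y", "z", "occ", "b", "het", "hydrogen")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop2("format_error", "atom table lacks columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop2("format_error", "non-finite coordinates in atom table")
  }
  rownames(atoms) <- NULL
  structure(list(entry_id = entry_id, atoms = atoms,
                 helix = helix %||% data.frame(chain = character(),
                                               start = integer(),
                                               end = integer())),
            class = "mr_structure")
}

#' @export
print.mr_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<mr_structure %s>  %d atoms, %d chains (%s), %d residues\n",
              x$entry_id, nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              nrow(unique(a[, c("chain", "resno", "insert", "resname")]))))
  het <- sort(table(a$resname[a$het & !a$resname %in% WATER_RES]),
              decreasing = TRUE)
  if (length(het)) {
    cat("  het residues:",
        paste(sprintf("%s x%d", names(het),
                      as.integer(tapply(a$resno[a$het], a$resname[a$het],
                                        function(r) length(unique(r)))[names(het)])),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# bio3d atom data frame -> canonical atom table, resolving altlocs.
normalize_bio3d_atoms <- function(df) {
  el <- toupper(trimws(df$elesy))
  bad <- is.na(el) | !nzchar(el)
  if (any(bad)) el[bad] <- infer_element(df$elety[bad])
  atoms <- data.frame(
    chain = ifelse(is.na(df$chain), " ", as.character(df$chain)),
    resname = toupper(trimws(as.character(df$resid))),
    resno = as.integer(df$resno),
    insert = ifelse(is.na(df$insert), "", as.character(df$insert)),
    atom = trimws(as.character(df$elety)),
    element = el,
    x = as.numeric(df$x), y = as.numeric(df$y), z = as.numeric(df$z),
    occ = ifelse(is.na(df$o), 1, as.numeric(df$o)),
    b = ifelse(is.na(df$b), 0, as.numeric(df$b)),
    het = df$type == "HETATM",
    hydrogen = toupper(trimws(ifelse(bad, el, df$elesy))) %in% c("H", "D"),
    alt = ifelse(is.na(df$alt), "", as.character(df$alt)),
    stringsAsFactors = FALSE
  )
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  atoms <- resolve_altlocs(atoms)
  atoms$alt <- NULL
  rownames(atoms) <- NULL
  atoms
}

# Keep one conformer per (chain, resno, insert, resname, atom name):
# highest occupancy wins, ties resolved to altloc "A" then alphabetical.
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname,
               atoms$atom, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  # order: by key, then decreasing occupancy, then altloc ("" sorts first,
  # then "A" etc.); first row per key is retained
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  atoms <- atoms[keep, , drop = FALSE]
  # restore original file order
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

helix_table <- function(pdb) {
  h <- pdb$helix
  if (is.null(h) || length(h$start) == 0L) {
    return(data.frame(chain = character(), start = integer(), end = integer()))
  }
  data.frame(chain = as.character(h$chain),
             start = as.integer(h$start),
             end = as.integer(h$end),
             stringsAsFactors = FALSE)
}

#' Write a structure to a PDB file
#'
#' Deterministic fixed-width PDB writer (used for synthetic fixtures).
#' Coordinates are written to 3 decimals, occupancy and B to 2; helix
#' annotations are written as HELIX records so they survive a round trip.
#'
#' @param structure an `mr_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- character(0)
  h <- structure$helix
  if (nrow(h)) {
    lines <- c(lines, vapply(seq_len(nrow(h)), function(i) {
      sprintf("HELIX  %3d %3s ALA %s %4d  ALA %s %4d  1 %29d",
              i, sprintf("%3d", i), h$chain[i], h$start[i], h$chain[i],
              h$end[i], h$end[i] - h$start[i] + 1L)
    }, character(1L)))
  }
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  # PDB atom-name column convention: names of 1-3 characters whose element
  # symbol is a single letter start in column 14
  name_field <- vapply(a$atom, function(nm) {
    if (nchar(nm) >= 4L) substr(nm, 1L, 4L) else sprintf(" %-3s", nm)
  }, character(1L), USE.NAMES = FALSE)
  atom_lines <- sprintf(
    "%s%5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, (seq_len(nrow(a)) - 1L) %% 99999L + 1L, name_field, " ",
    a$resname, a$chain, a$resno,
    ifelse(nzchar(a$insert), a$insert, " "),
    a$x, a$y, a$z, a$occ, a$b, a$element)
  lines <- c(lines, atom_lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write an atom table as TSV
#'
#' @param structure an `mr_structure` or atom table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_atom_tsv <- function(structure, path) {
  atoms <- if (inherits(structure, "mr_structure")) structure$atoms else structure
  utils::write.table(atoms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Residue-level split helper: list of atom tables keyed by residue.
residue_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname, sep = "\r")
}

residue_label <- function(atoms) {
  paste0(atoms$resname, " ", atoms$resno,
         ifelse(nzchar(atoms$insert), atoms$insert, ""),
         " (chain ", atoms$chain, ")")
}
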