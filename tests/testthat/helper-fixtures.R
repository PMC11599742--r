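# Shared fixtures: tiny hand-written structures and generated scenes.

# A minimal PDB text: two ALA residues, a retinal, a monoolein fragment,
# glycerol and a water.
mini_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.432   7.339  -4.803  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      12.432   8.339  -5.503  1.00  0.00           O",
    "ATOM      5  N   ALA A   2      13.104   7.234  -3.654  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2      13.839   8.271  -2.947  1.00  0.00           C",
    "ATOM      7  C   ALA A   2      14.632   7.739  -1.803  1.00  0.00           C",
    "ATOM      8  O   ALA A   2      14.532   6.539  -1.503  1.00  0.00           O",
    "HETATM    9  C1  RET A 300       5.000   5.000   0.000  1.00 10.00           C",
    "HETATM   10  C2  RET A 300       6.400   5.000   0.000  1.00 10.00           C",
    "HETATM   11  C1  OLC A 401       1.000   2.000   3.000  1.00 10.00           C",
    "HETATM   12  C2  OLC A 401       1.000   2.000   4.400  1.00 10.00           C",
    "HETATM   13  C1  GOL A 402       9.000   9.000   9.000  1.00 10.00           C",
    "HETATM   14  O   HOH A 501       5.000   5.000   5.000  1.00 10.00           O",
    "END")
}

write_mini_pdb <- function(path = tempfile(fileext = ".pdb"),
                           lines = mini_pdb_lines()) {
  writeLines(lines, path)
  path
}

# Serialize an mr_structure atom table as a minimal mmCIF file (format-parity
# oracle; the package itself only writes PDB).
write_mini_cif <- function(structure, path = tempfile(fileext = ".cif")) {
  a <- structure$atoms
  head <- c(
    "data_SYN", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- sprintf(
    "%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), a$element, a$atom,
    a$resname, a$chain, a$resno, a$x, a$y, a$z, a$occ, a$b,
    a$resno, a$resname, a$chain, a$atom)
  writeLines(c(head, rows, "#"), path)
  path
}

# A small trimer scene with one lipid of each location class.
standard_trimer_scene <- function(seed = 11L, jitter = 0) {
  build_scene(scene_spec(
    seed = seed, trimer = TRUE,
    lipids = list(
      list(class = "linear_acyl", location = "peripheral", d0 = 4.0,
           jitter = jitter),
      list(class = "archaeal_diphytanyl", location = "inner_compartment",
           d0 = 4.0, branched = TRUE),
      list(class = "linear_acyl", location = "inter_protomer", d0 = 4.0,
           jitter = jitter))))
}

# Atom table for one residue of the scene.
scene_residue <- function(scene, resno) {
  a <- scene$structure$atoms
  a[a$resno == resno & a$het, , drop = FALSE]
}

# Bare atom table builder for hand-made cases.
atom_row <- function(x, y, z, atom = "C1", element = "C", resname = "OLC",
                     resno = 1L, chain = "A", het = TRUE) {
  data.frame(chain = chain, resname = resname, resno = as.integer(resno),
             insert = "", atom = atom, element = element,
             x = x, y = y, z = z, occ = 1, b = 0, het = het,
             hydrogen = element %in% c("H", "D"), stringsAsFactors = FALSE)
}

random_rigid_transform <- function() {
  ax <- stats::rnorm(3)
  annulipid:::rotation_about_axis(ax, stats::runif(1, 0, 2 * pi))
}

# Local mirror of public PDB entries used by the reference comparisons;
# populate tests/testthat/pdb_entries/ with the deposited coordinate files
# to run them.
pdb_entry_path <- function(id) {
  testthat::test_path("pdb_entries", paste0(toupper(id), ".pdb"))
}
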