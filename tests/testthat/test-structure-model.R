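test_that("minimal PDB files parse into structures", {
  tf <- write_mini_pdb(lines = mini_pdb_lines()[2])  # single ATOM record
  s <- read_structure(tf)
  expect_s3_class(s, "mr_structure")
  expect_identical(nrow(s$atoms), 1L)
  expect_identical(s$atoms$atom, "CA")
  expect_equal(s$atoms$x, 11.639)

  s2 <- read_structure(write_mini_pdb())
  expect_identical(nrow(s2$atoms), 14L)
  expect_error(read_structure(tempfile()), class = "format_error")
})

test_that("alternate locations resolve to the highest-occupancy conformer, ties to A", {
  lines <- c(
    "ATOM      1  CA AALA A   1      10.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1      20.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1      30.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1      40.000   0.000   0.000  0.50  0.00           C",
    "END")
  s <- read_structure(write_mini_pdb(lines = lines))
  expect_identical(nrow(s$atoms), 2L)
  # highest occupancy wins for CA (conformer B)
  expect_equal(s$atoms$x[s$atoms$atom == "CA"], 20)
  # occupancy tie resolves to altloc A for CB
  expect_equal(s$atoms$x[s$atoms$atom == "CB"], 30)
})

test_that("multi-model files keep the first model with a warning", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1      10.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1      99.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END")
  expect_warning(s <- read_structure(write_mini_pdb(lines = lines)),
                 class = "multi_model")
  expect_identical(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 10)
})

test_that("the same content parses identically from PDB and mmCIF", {
  scene <- build_scene(scene_spec(
    seed = 21L,
    lipids = list(list(class = "linear_acyl", location = "peripheral",
                       d0 = 4.0)),
    gas = list(weights = 1, means = 0, sds = 4, n = 20)))
  pdb_path <- tempfile(fileext = ".pdb")
  write_structure_pdb(scene$structure, pdb_path)
  s_pdb <- read_structure(pdb_path)
  s_cif <- read_structure(write_mini_cif(s_pdb), format = "cif")
  expect_identical(nrow(s_pdb$atoms), nrow(s_cif$atoms))
  expect_equal(atom_xyz(s_pdb$atoms), atom_xyz(s_cif$atoms))
  p1 <- partition_structure(s_pdb)
  p2 <- partition_structure(s_cif)
  for (set in c("protein", "retinal", "lipid", "solvent", "other_het")) {
    expect_identical(nrow(p1[[set]]), nrow(p2[[set]]))
  }
})

test_that("writing and reparsing preserves names and coordinates to PDB precision", {
  scene <- standard_trimer_scene(seed = 3L)
  tf <- tempfile(fileext = ".pdb")
  write_structure_pdb(scene$structure, tf)
  s2 <- read_structure(tf)
  a1 <- scene$structure$atoms
  expect_identical(nrow(s2$atoms), nrow(a1))
  expect_identical(s2$atoms$atom, a1$atom)
  expect_identical(s2$atoms$resname, a1$resname)
  expect_equal(atom_xyz(s2$atoms), round(atom_xyz(a1), 3), tolerance = 1e-12)
  expect_identical(nrow(s2$helix), nrow(scene$structure$helix))
})

test_that("partition is a disjoint cover with the documented class rules", {
  s <- read_structure(write_mini_pdb())
  p <- partition_structure(s)
  sets <- list(p$protein, p$retinal, p$lipid, p$solvent, p$other_het)
  expect_identical(sum(vapply(sets, nrow, integer(1))), nrow(s$atoms))
  # pairwise disjoint on atom identity
  keys <- lapply(sets, function(df) {
    paste(df$chain, df$resno, df$atom)
  })
  all_keys <- unlist(keys)
  expect_false(anyDuplicated(all_keys) > 0)
  # retinal is its own set, never a lipid
  expect_identical(unique(p$retinal$resname), "RET")
  expect_false("RET" %in% p$lipid$resname)
  # glycerol (cryoprotectant class) is not a lipid
  expect_true("GOL" %in% p$other_het$resname)
  expect_false("GOL" %in% p$lipid$resname)
  expect_true("OLC" %in% p$lipid$resname)
  # scene with planted lipids: every planted residue lands in the lipid set
  scene <- standard_trimer_scene(seed = 5L)
  ps <- partition_structure(scene$structure)
  expect_identical(
    sort(unique(ps$lipid$resno)), sort(scene$truth$lipids$resno))
})

test_that("the selection grammar expands the printed atom lists", {
  # the 32-atom glycolipid selection
  expanded <- parse_selection(
    "chain A and resname L2P and resnum 270 and name O2+C2+C3+C12-C21+C41-C45+C47-C60")
  expect_length(expanded$names, 32L)
  expect_length(parse_selection("name C12-C21")$names, 10L)
  expect_error(parse_selection("chain"), class = "parse_error")
  expect_error(parse_selection("name C12-O21"), class = "parse_error")
  expect_error(parse_selection("bogus A"), class = "parse_error")
  expect_error(parse_selection("resnum abc"), class = "parse_error")
})

test_that("selection is monotone and empty results are flagged", {
  scene <- standard_trimer_scene(seed = 5L)
  s <- scene$structure
  n_all <- nrow(select_atoms(s, "chain A"))
  n_more <- nrow(select_atoms(s, "chain A and resname LEU"))
  n_even_more <- nrow(select_atoms(s, "chain A and resname LEU and name CA"))
  expect_lte(n_more, n_all)
  expect_lte(n_even_more, n_more)
  expect_warning(out <- select_atoms(s, "resname QQQ"),
                 class = "empty_selection")
  expect_identical(nrow(out), 0L)
  # planted lipid is addressable by the grammar
  lip <- select_atoms(s, sprintf("resname L2P and resnum %d",
                                 scene$truth$lipids$resno[2]))
  expect_gt(nrow(lip), 0L)
})

test_that("assembly expansion scales atoms, renames chains, and is exactly symmetric", {
  scene <- build_scene(scene_spec(seed = 2L))
  s <- scene$structure
  tri <- expand_assembly(s, point_symmetry = "C3")
  expect_identical(nrow(tri$atoms), 3L * nrow(s$atoms))
  expect_identical(sort(unique(tri$atoms$chain)), c("A", "B", "C"))
  # identity op leaves the structure unchanged
  idop <- annulipid:::new_transform(diag(3), c(0, 0, 0))
  same <- expand_assembly(s, ops = list(idop))
  expect_identical(nrow(same$atoms), nrow(s$atoms))
  expect_error(expand_assembly(s), class = "assembly_unavailable")
  # protomer-vs-protomer superposition recovers the symmetry exactly
  ca_a <- tri$atoms[tri$atoms$chain == "A" & tri$atoms$atom == "CA", ]
  ca_b <- tri$atoms[tri$atoms$chain == "B" & tri$atoms$atom == "CA", ]
  expect_lt(kabsch_superpose(atom_xyz(ca_a), atom_xyz(ca_b))$rmsd, 1e-6)
})
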