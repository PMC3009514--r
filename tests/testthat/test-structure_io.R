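test_that("read_structure types chains and resolves altlocs", {
  pdb <- c(
    "ATOM      1  CA  ALA B   1      11.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  P     G A   5       1.000   2.000   3.000  1.00  0.00           P",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  m <- read_structure(f)
  expect_s3_class(m, "StructureModel")
  expect_equal(nrow(m$atoms), 2)
  expect_setequal(m$chains$polymer_class, c("protein", "rna"))
  expect_equal(m$chains$polymer_class[m$chains$chain == "A"], "rna")

  pdb_alt <- c(
    "ATOM      1  CA AALA B   1      11.000  10.000  10.000  0.60  0.00           C",
    "ATOM      2  CA BALA B   1      12.000  10.000  10.000  0.40  0.00           C",
    "END")
  writeLines(pdb_alt, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), 1)
  expect_equal(m2$atoms$x, 11)  # highest occupancy kept

  # the winner is chosen by occupancy, not altloc letter
  pdb_alt2 <- sub("0.60", "0.30", pdb_alt, fixed = TRUE)
  writeLines(pdb_alt2, f)
  m3 <- read_structure(f)
  expect_equal(nrow(m3$atoms), 1)
  expect_equal(m3$atoms$x, 12)

  writeLines(c("ATOM      1  CA  ALA B   1      11.000", "END"), f)
  expect_error(read_structure(f), "line 1")
})

test_that("mmCIF files load with the same typing rules", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_TOY", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA B 1 1 ? 11.000 10.000 10.000 1.00 0.00 ? 1 ALA B CA 1",
    "ATOM 2 P P . G A 2 1 ? 1.000 2.000 3.000 1.00 0.00 ? 5 G A P 1"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2)
  expect_setequal(m$chains$polymer_class, c("protein", "rna"))
  expect_equal(m$atoms$resno[m$atoms$name == "P"], 5)  # author numbering
})

test_that("hydrogens and waters are dropped at load", {
  pdb <- c(
    "ATOM      1  CA  ALA B   1      11.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  H   ALA B   1      11.500  10.000  10.000  1.00  0.00           H",
    "HETATM    3  O   HOH W   1       5.000   5.000   5.000  1.00  0.00           O",
    "ATOM      4  P     G A   5       1.000   2.000   3.000  1.00  0.00           P",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  m <- read_structure(f)
  expect_equal(sort(m$atoms$name), c("CA", "P"))
})

test_that("rna_atom_group partitions backbone names 3 + 9, rest base", {
  phosphate <- c("P", "OP1", "OP2")
  ribose <- c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")
  expect_equal(rna_atom_group(phosphate), rep("phosphate", 3))
  expect_equal(rna_atom_group(ribose), rep("ribose", 9))
  expect_equal(rna_atom_group(c("N3", "C8", "O6", "N9")), rep("base", 4))
  # legacy spellings normalize into the same partition
  expect_equal(rna_atom_group(c("O1P", "O2P", "C1*", "O2*")),
               c("phosphate", "phosphate", "ribose", "ribose"))
})

test_that("SASA matches closed forms and is monotone under burial", {
  iso <- toy_model(atom_row("O", "O", 0, 0, 0, "B", 1, "ALA"))
  a <- compute_sasa(iso)
  expect_equal(a, 4 * pi * (1.52 + 1.5)^2, tolerance = 1e-12)

  # two identical C atoms 2 A apart: analytic spherical caps within 2%
  two <- toy_model(atom_row(c("C1", "C2"), "C", c(0, 2), 0, 0, "B", 1:2,
                            "ALA"))
  a2 <- compute_sasa(two)
  expect_equal(a2[1], two_sphere_exposed(1.7 + 1.5, 2), tolerance = 0.02)
  expect_equal(a2[2], a2[1], tolerance = 1e-9)

  # atom enclosed in a tight cage has zero accessible area
  grid <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  cage <- toy_model(atom_row(paste0("C", seq_len(27)), "C", grid$x, grid$y,
                             grid$z, "B", seq_len(27), "ALA"))
  expect_equal(compute_sasa(cage)[14], 0)  # center atom of the 3x3x3 cage

  expect_warning(compute_sasa(toy_model(atom_row("X", "XX", 0, 0, 0, "B",
                                                 1, "ALA"))),
                 "unknown element")
})

test_that("surface_atoms is monotone in the threshold", {
  set.seed(7)
  n <- 10
  m <- toy_model(atom_row(paste0("C", 1:n), "C", runif(n, 0, 6),
                          runif(n, 0, 6), runif(n, 0, 6), "B", 1:n, "ALA"))
  sasa <- compute_sasa(m)
  sizes <- vapply(c(0, 1, 5, 20, 50, 120),
                  function(th) length(surface_atoms(sasa,
                    surface_params(surface_sasa_min = th))), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(length(surface_atoms(sasa * 0)), 0)
})

test_that("write/read round-trip preserves atoms to 3 decimals", {
  sc <- make_tetraloop_scene(synthetic_spec(seed = 11, n_tetraloops = 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sc$model, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atoms), nrow(sc$model$atoms))
  expect_equal(back$atoms$name, sc$model$atoms$name)
  expect_equal(back$atoms$x, round(sc$model$atoms$x, 3))
  expect_equal(back$atoms$z, round(sc$model$atoms$z, 3))
})
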