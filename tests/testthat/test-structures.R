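test_that("read_structure parses a minimal PDB and round-trips identity", {
  p <- write_tiny_pdb(c(
    pdb_line("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 1.458, 0, 0),
    pdb_line("ATOM", 3, "C", "ALA", "A", 1, 2.0, 1.3, 0)))
  s <- read_structure(p)
  expect_s3_class(s, "allo_structure")
  expect_equal(nrow(s$atoms), 3)
  expect_equal(length(polymer_residues(s)), 1)
  expect_equal(s$atoms$element, c("N", "C", "C"))
  expect_equal(s$atoms$vdw, c(1.55, 1.70, 1.70))
})

test_that("water and buffer compounds never enter ligand_groups", {
  p <- write_tiny_pdb(c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line("HETATM", 2, "O", "HOH", "A", 90, 9, 9, 9, element = "O"),
    pdb_line("HETATM", 3, "S", "SO4", "A", 91, 5, 5, 5, element = "S"),
    pdb_line("HETATM", 4, "C1", "XYZ", "A", 92, 7, 7, 7, element = "C")))
  s <- read_structure(p)
  expect_length(s$ligand_groups, 1)
  expect_match(s$ligand_groups, "XYZ")
})

test_that("write/read round-trip preserves helix coordinates to 1e-3 A", {
  h <- make_helix_structure(12, "poly-A", id = "rt")
  p <- tempfile(fileext = ".pdb")
  write_pdb(h, p)
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), nrow(h$atoms))
  expect_equal(s$atoms$name, h$atoms$name)
  expect_equal(s$atoms$x, h$atoms$x, tolerance = 1e-3)
  expect_equal(s$atoms$y, h$atoms$y, tolerance = 1e-3)
  expect_equal(s$atoms$z, h$atoms$z, tolerance = 1e-3)
})

test_that("mmCIF atom_site parsing matches the PDB parse", {
  h <- make_helix_structure(5, "poly-A", id = "cif")
  a <- h$atoms
  cif <- c("data_cif", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "auth_atom_id", "auth_comp_id",
                                   "auth_asym_id", "auth_seq_id",
                                   "Cartn_x", "Cartn_y", "Cartn_z",
                                   "occupancy")),
           sprintf("%s %d %s %s %s %s %d %.3f %.3f %.3f %.2f",
                   "ATOM", a$serial, a$element, a$name, a$res_name, a$chain,
                   a$res_seq, a$x, a$y, a$z, a$occupancy))
  p <- tempfile(fileext = ".cif")
  writeLines(cif, p)
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), nrow(a))
  expect_equal(s$atoms$x, a$x, tolerance = 1e-3)
  expect_equal(s$atoms$res_seq, a$res_seq)
})

test_that("altloc collapse keeps the highest-occupancy conformer", {
  p <- write_tiny_pdb(c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, altloc = "B"),
    pdb_line("ATOM", 3, "N", "ALA", "A", 1, 1, 1, 1, element = "N")))
  s <- read_structure(p)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9)
})

test_that("unknown elements fall back to the default radius with a warning", {
  atoms <- mk_atoms(c(0, 0, 0), element = "XX")
  expect_warning(s <- mk_structure(atoms), "unknown element")
  expect_equal(s$atoms$vdw, 1.70)
})

test_that("strip_group removes exactly the named group and is invertible", {
  fx <- plant_modulator(make_helix_structure(10, "poly-A", id = "sg"), 4:5)
  key <- fx$ligand_groups[1]
  n_lig <- nrow(group_atoms(fx, key))
  apo <- strip_group(fx, key)
  expect_length(apo$ligand_groups, 0)
  expect_equal(nrow(apo$atoms), nrow(fx$atoms) - n_lig)
  # re-adding the stripped atoms reproduces the original atom set
  readd <- rbind(apo$atoms, group_atoms(fx, key))
  ord <- function(a) a[order(a$serial), c("name", "x", "y", "z")]
  expect_equal(ord(readd), ord(fx$atoms), ignore_attr = TRUE)
  expect_error(strip_group(apo, key), "not a ligand group")
})

test_that("min_heavy_distance matches toy values and the brute-force oracle", {
  a1 <- mk_atoms(c(0, 0, 0))
  expect_equal(min_heavy_distance(a1, a1), 0)
  a2 <- mk_atoms(c(3, 4, 0))
  expect_equal(min_heavy_distance(a1, a2), 5.0)
  for (seed in 1:5) {
    set.seed(seed)
    A <- mk_atoms(rnorm(30, sd = 5))
    B <- mk_atoms(rnorm(30, sd = 5))
    d <- min_heavy_distance(A, B)
    expect_equal(d, oracle_min_dist(cbind(A$x, A$y, A$z),
                                    cbind(B$x, B$y, B$z)))
    expect_equal(d, min_heavy_distance(B, A)) # symmetry
  }
  expect_error(min_heavy_distance(mk_atoms(c(0, 0, 0), element = "H"), a1),
               "empty heavy-atom set")
})

test_that("centroid matches arithmetic mean and is translation-equivariant", {
  expect_equal(centroid(mk_atoms(c(1, 2, 3))), c(1, 2, 3))
  expect_equal(centroid(mk_atoms(c(1, 0, 0, -1, 0, 0))), c(0, 0, 0))
  set.seed(7)
  X <- matrix(rnorm(15), 5, 3)
  a <- mk_atoms(as.vector(t(X)))
  expect_equal(centroid(a), colMeans(X))
  t0 <- c(4, -2, 11)
  at <- a; at$x <- at$x + t0[1]; at$y <- at$y + t0[2]; at$z <- at$z + t0[3]
  expect_equal(centroid(at), centroid(a) + t0)
  expect_error(centroid(a[0, ]), "empty atom set")
})

test_that("pick_modulator honours the heavy-atom minimum and buffer list", {
  fx <- plant_modulator(make_helix_structure(10, "poly-A", id = "pm"), 4:5)
  expect_match(pick_modulator(fx), "LIG")
  # small hetero group below the 6-heavy-atom rule is not picked
  small <- mk_atoms(c(50, 0, 0, 51, 0, 0), name = c("C1", "C2"),
                    res_name = "XYZ", res_seq = 99, is_hetero = TRUE)
  s <- mk_structure(rbind(make_helix_structure(6, "poly-A")$atoms[, names(small)],
                          small))
  expect_true(is.na(pick_modulator(s)))
})
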