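test_that("generated structures round-trip through PDB format", {
  toys <- gen_toy_structures(separation = 20)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toys$helix_pair, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$atoms), nrow(toys$helix_pair$atoms))
  # atoms come back in file order with coordinates to 3 decimals
  expect_equal(back$atoms$elety, toys$helix_pair$atoms$elety)
  expect_equal(back$atoms$chain, toys$helix_pair$atoms$chain)
  expect_equal(back$atoms$x, toys$helix_pair$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$z, toys$helix_pair$atoms$z, tolerance = 1e-3)
})

test_that("only the first model of a multi-model file is read", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atom <- function(i, x, res) sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    i, res, x, 0, 0)
  writeLines(c("MODEL     1", atom(1, 0, 1), atom(2, 3.8, 2), "ENDMDL",
               "MODEL     2", atom(1, 50, 1), atom(2, 53.8, 2), "ENDMDL",
               "END"), path)
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x, c(0, 3.8))
})

test_that("altloc conformers collapse to the highest occupancy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "END"), path)
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 5.0)
})

test_that("strip_to_chain keeps one chain and removes waters", {
  toys <- gen_toy_structures(separation = 10)
  a <- strip_to_chain(toys$helix_pair, "A")
  expect_true(all(a$atoms$chain == "A"))
  expect_equal(nrow(a$atoms),
               sum(toys$helix_pair$atoms$chain == "A"))
  # single-chain input is unchanged
  again <- strip_to_chain(a, "A")
  expect_equal(nrow(again$atoms), nrow(a$atoms))
  expect_error(strip_to_chain(a, "Z"), "chain not present")
  # waters on the kept chain are removed
  wet <- a
  wet$atoms <- rbind(wet$atoms, data.frame(
    chain = "A", resno = 999, icode = "", resid = "HOH", elety = "O",
    element = "O", x = 0, y = 0, z = 0, type = "ATOM"))
  expect_equal(nrow(strip_to_chain(wet, "A")$atoms), nrow(a$atoms))
})

test_that("foreign contacts match the all-pairs distance oracle", {
  far <- gen_toy_structures(separation = 50)$helix_pair
  near <- gen_toy_structures(separation = 8)$helix_pair
  for (r in c(1, 5, 9)) {
    expect_false(has_foreign_contact(far, "A", r))
    expect_equal(has_foreign_contact(near, "A", r, cutoff = 5),
                 min_foreign_distance(near, "A", r) <= 5)
  }
  expect_error(has_foreign_contact(far, "A", 999), "not found")
})

test_that("a cross-chain atom pair just inside the cutoff triggers", {
  # two single-atom chains at exactly 4.99 apart
  atoms <- data.frame(
    chain = c("A", "B"), resno = c(1, 1), icode = "",
    resid = "ALA", elety = "CA", element = "C",
    x = c(0, 4.99), y = 0, z = 0, type = "ATOM",
    stringsAsFactors = FALSE)
  s <- structure(list(atoms = atoms, model = 1L), class = "pdb_structure")
  expect_true(has_foreign_contact(s, "A", 1, cutoff = 5))
  s$atoms$x[2] <- 5.01
  expect_false(has_foreign_contact(s, "A", 1, cutoff = 5))
})

test_that("water and same-chain ligands follow the contact rules", {
  base <- data.frame(
    chain = "A", resno = 1, icode = "", resid = "ALA", elety = "CA",
    element = "C", x = 0, y = 0, z = 0, type = "ATOM",
    stringsAsFactors = FALSE)
  wat <- data.frame(chain = "A", resno = 2, icode = "", resid = "HOH",
                    elety = "O", element = "O", x = 3, y = 0, z = 0,
                    type = "HETATM", stringsAsFactors = FALSE)
  lig <- data.frame(chain = "A", resno = 3, icode = "", resid = "ZNX",
                    elety = "ZN", element = "ZN", x = 3, y = 0, z = 0,
                    type = "HETATM", stringsAsFactors = FALSE)
  s_w <- structure(list(atoms = rbind(base, wat), model = 1L),
                   class = "pdb_structure")
  s_l <- structure(list(atoms = rbind(base, lig), model = 1L),
                   class = "pdb_structure")
  # a water 3 A away never counts; a same-chain non-water HETATM does
  expect_false(has_foreign_contact(s_w, "A", 1))
  expect_true(has_foreign_contact(s_l, "A", 1))
})

test_that("contact detection is monotone in the cutoff", {
  s <- gen_toy_structures(separation = 9)$helix_pair
  cutoffs <- c(2, 4, 6, 8, 10, 14)
  for (r in c(1, 6, 12)) {
    hits <- vapply(cutoffs, function(cc) has_foreign_contact(s, "A", r, cc),
                   logical(1))
    expect_true(all(diff(as.integer(hits)) >= 0))
  }
})
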