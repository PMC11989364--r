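test_that("a hand-written tripeptide loads with the expected hierarchy", {
  m <- load_structure(fixture_tripeptide())
  rt <- residue_table(m)
  expect_equal(nrow(rt), 3L)
  expect_equal(unique(rt$chain), "A")
  expect_equal(rt$resname, c("ALA", "GLY", "ALA"))
  # ALA: N,CA,C,O,CB all heavy; GLY has no side-chain heavy atoms
  expect_equal(rt$n_heavy, c(5L, 4L, 5L))
  expect_equal(rt$n_sidechain_heavy, c(1L, 0L, 1L))
  # sum of per-residue heavy atoms equals the heavy-atom total
  expect_equal(sum(rt$n_heavy), sum(!m$atoms$is_hydrogen))
})

test_that("altloc resolution keeps the highest-occupancy copy", {
  lines <- c(pdb_line(serial = 1, name = "CA", resno = 1),
             pdb_line(serial = 2, name = "CB", alt = "A", resno = 1,
                      x = 1.0, occ = 0.6),
             pdb_line(serial = 3, name = "CB", alt = "B", resno = 1,
                      x = 2.0, occ = 0.4))
  m <- load_structure(write_pdb_fixture(lines))
  cb <- m$atoms[m$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 1.0)
  # reversed occupancies flip the winner
  lines2 <- c(pdb_line(serial = 1, name = "CA", resno = 1),
              pdb_line(serial = 2, name = "CB", alt = "A", resno = 1,
                       x = 1.0, occ = 0.3),
              pdb_line(serial = 3, name = "CB", alt = "B", resno = 1,
                       x = 2.0, occ = 0.7))
  m2 <- load_structure(write_pdb_fixture(lines2))
  expect_equal(m2$atoms$x[m2$atoms$elety == "CB"], 2.0)
})

test_that("model_index selects the requested MODEL block", {
  mk <- function(x) c(pdb_line(serial = 1, name = "CA", resno = 1, x = x),
                      pdb_line(serial = 2, name = "CA", resno = 2, x = x + 3.8))
  lines <- c("MODEL        1", mk(0), "ENDMDL",
             "MODEL        2", mk(50), "ENDMDL")
  path <- write_pdb_fixture(lines)
  expect_equal(load_structure(path, model_index = 1)$atoms$x[1], 0)
  expect_equal(load_structure(path, model_index = 2)$atoms$x[1], 50)
  expect_error(load_structure(path, model_index = 3), "out of range")
})

test_that("load errors name the problem for unreadable input", {
  expect_error(load_structure(tempfile()), "not found")
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA", "END"), bad)
  expect_error(load_structure(bad), "line 1")
  empty <- write_pdb_fixture("REMARK nothing here")
  expect_error(load_structure(empty), "no ATOM/HETATM")
})

test_that("curation strips waters and hetero residues per flags", {
  path <- fixture_multichain_hetero()
  m <- load_structure(path)
  cur <- curate(m)
  expect_false(any(cur$atoms$resid %in% c("HOH", "GNP", "MG")))
  expect_equal(nrow(residue_table(cur)), 6L)
  # keep_chains restriction
  a_only <- curate(m, keep_chains = "A")
  expect_equal(unique(a_only$atoms$chain), "A")
  expect_error(curate(m, keep_chains = c("A", "Z")), "available")
  # waters retained when drop_waters = FALSE (hetero still removed)
  keepw <- curate(m, drop_waters = FALSE)
  expect_equal(sum(keepw$atoms$resid == "HOH"), 5L)
  expect_false(any(keepw$atoms$resid %in% c("GNP", "MG")))
})

test_that("curation is idempotent and logs its steps", {
  m <- curate(load_structure(fixture_multichain_hetero()))
  m2 <- curate(m)
  expect_identical(m$atoms, m2$atoms)
  expect_true(length(m$curation_log) >= 2)
})

test_that("residue ordering is stable across repeated loads", {
  path <- fixture_multichain_hetero()
  rt1 <- residue_table(curate(load_structure(path)))
  rt2 <- residue_table(curate(load_structure(path)))
  expect_identical(rt1, rt2)
  expect_equal(rt1$chain, rep(c("A", "B", "C"), each = 2))
})

test_that("residues without a C-alpha are dropped with a warning", {
  lines <- c(pdb_line(serial = 1, name = "CA", resno = 1),
             pdb_line(serial = 2, name = "CB", resno = 2, x = 4))
  m <- load_structure(write_pdb_fixture(lines))
  expect_warning(cur <- curate(m), "C-alpha")
  expect_equal(nrow(residue_table(cur)), 1L)
})
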