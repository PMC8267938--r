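test_that("read_pdb parses ATOM records with exact coordinates", {
  txt <- c(pdb_atom_line(1, "N", "ALA", "A", 1, 1.234, -5.678, 9.000, "N"),
           pdb_atom_line(2, "CA", "ALA", "A", 1, 2.000, 0.125, -3.500, "C"))
  s <- read_pdb(text = txt)
  expect_s3_class(s, "MolecularStructure")
  expect_equal(nrow(s), 2L)
  expect_equal(s$x, c(1.234, 2.000))
  expect_equal(s$y, c(-5.678, 0.125))
  expect_equal(s$z, c(9.000, -3.500))
  expect_equal(s$element, c("N", "C"))
  expect_equal(s$mass, element_mass(c("N", "C")))
  expect_equal(s$resno, c(1L, 1L))
})

test_that("malformed coordinate fields raise an error naming the line", {
  good <- pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0)
  bad <- good
  substr(bad, 31, 38) <- " 1.2.3.4"
  expect_error(read_pdb(text = c(good, bad)), "line 2")
  blank <- good
  substr(blank, 39, 46) <- "        "
  expect_error(read_pdb(text = blank), "line 1")
})

test_that("alternate locations keep the highest occupancy, ties favour A", {
  txt <- c(
    pdb_atom_line(1, "CA", "SER", "A", 7, 0, 0, 0, "C", altloc = "A", occupancy = 0.4),
    pdb_atom_line(2, "CA", "SER", "A", 7, 1, 0, 0, "C", altloc = "B", occupancy = 0.6),
    pdb_atom_line(3, "OG", "SER", "A", 7, 2, 0, 0, "O", altloc = "A", occupancy = 0.5),
    pdb_atom_line(4, "OG", "SER", "A", 7, 3, 0, 0, "O", altloc = "B", occupancy = 0.5))
  s <- read_pdb(text = txt)
  expect_equal(nrow(s), 2L)
  expect_equal(s$x, c(1, 2))  # B wins on occupancy; A wins the tie
})

test_that("elements are inferred from atom names when columns 77-78 are blank", {
  lines <- c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
             pdb_atom_line(2, "1HB", "GLY", "A", 1, 1, 0, 0, "H"),
             "ATOM      3 ZN    ZN A   2       2.000   0.000   0.000  1.00  0.00")
  # strip the element columns from the first two as well
  lines[1:2] <- substr(lines[1:2], 1, 66)
  s <- read_pdb(text = lines)
  expect_equal(s$element, c("C", "H", "ZN"))
  expect_true(all(s$mass > 0))
})

test_that("multi-model PDB becomes a trajectory sharing the first topology", {
  mk <- function(model, dx) c(sprintf("MODEL     %4d", model),
                              pdb_atom_line(1, "CA", "GLY", "A", 1, dx, 0, 0),
                              pdb_atom_line(2, "CA", "GLY", "A", 2, dx + 1, 0, 0),
                              "ENDMDL")
  tr <- read_pdb(text = c(mk(1, 0), mk(2, 5), mk(3, -2)), model_policy = "all")
  expect_s3_class(tr, "Trajectory")
  expect_equal(n_frames(tr), 3L)
  expect_equal(tr$coords[1, 1, ], c(0, 5, -2))
  s <- read_pdb(text = c(mk(1, 0), mk(2, 5)), model_policy = "first")
  expect_s3_class(s, "MolecularStructure")

  bad <- c(mk(1, 0), "MODEL        2",
           pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0), "ENDMDL")
  expect_error(read_pdb(text = bad, model_policy = "all"), "topology mismatch")
})

test_that("PDB and XYZ round-trips preserve coordinates and atom order", {
  set.seed(11)
  top <- make_structure(matrix(rnorm(30, sd = 8), 10, 3),
                        atom_name = c("CA", "CB"), element = c("C", "C"),
                        resno = rep(1:5, each = 2))
  frames <- lapply(1:5, function(i) matrix(rnorm(30, sd = 8), 10, 3))
  tr <- make_trajectory(top, frames)

  txt <- write_pdb(tr)
  expect_equal(sum(grepl("^MODEL", txt)), 5L)
  back <- read_pdb(text = txt, model_policy = "all")
  expect_equal(n_frames(back), 5L)
  expect_lt(max(abs(back$coords - tr$coords)), 5e-4)
  expect_equal(back$topology$atom_name, top$atom_name)
  # read-write-read is idempotent
  again <- read_pdb(text = write_pdb(back), model_policy = "all")
  expect_identical(again$coords, back$coords)

  xtxt <- write_xyz(tr)
  xback <- read_xyz(text = xtxt, topology = top)
  expect_identical(round(xback$coords, 6), round(tr$coords, 6))
  again_x <- read_xyz(text = write_xyz(xback), topology = top)
  expect_identical(again_x$coords, xback$coords)
})

test_that("single-frame single-atom trajectory writes one MODEL block", {
  top <- make_structure(matrix(c(1, 2, 3), 1, 3))
  tr <- trajectory(top, coords(top))
  txt <- write_pdb(tr)
  expect_equal(sum(grepl("^MODEL", txt)), 0L)   # single model: no MODEL card
  txt2 <- write_pdb(make_trajectory(top, list(coords(top), coords(top))))
  expect_equal(sum(grepl("^MODEL", txt2)), 2L)
  expect_error(write_pdb(trajectory(
    make_structure(matrix(0, 1, 3), atom_name = "TOOLONG"), matrix(0, 1, 3))),
    "field width")
})

test_that("selection resolution is deterministic and class-aware", {
  xyz <- matrix(rnorm(300), 100, 3)
  s <- make_structure(xyz, resno = 1:100)
  sel <- resolve_selection(s, selection_spec(resno = 42:48))
  expect_length(sel, 7L)
  expect_identical(sel, resolve_selection(s, selection_spec(resno = 42:48)))
  expect_length(resolve_selection(s, selection_spec(resno = 500:510)), 0L)

  phe <- make_phe(183)
  side <- resolve_selection(phe, selection_spec(resno = 183, class = "sidechain"))
  expect_setequal(phe$atom_name[side],
                  c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  bb <- resolve_selection(phe, selection_spec(class = "backbone"))
  expect_setequal(phe$atom_name[bb], c("N", "CA", "C", "O"))
})

test_that("HETATM records are excluded from protein selections by default", {
  txt <- c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
           pdb_atom_line(2, "ZN", "ZN", "A", 500, 1, 1, 1, "ZN", record = "HETATM"))
  s <- read_pdb(text = txt)
  expect_length(resolve_selection(s, selection_spec()), 1L)
  expect_length(resolve_selection(s, selection_spec(include_het = TRUE)), 2L)
})

test_that("every element in the packaged fixture resolves to a positive mass", {
  s <- read_pdb(system.file("extdata", "smyd3_crystal_synthetic.pdb",
                            package = "mdscape"))
  expect_true(all(s$mass > 0))
  expect_true(all(is.finite(coords(s))))
  # (chain, resno, atom_name) unique after altloc resolution
  expect_false(anyDuplicated(paste(s$chain, s$resno, s$atom_name)) > 0)
})
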