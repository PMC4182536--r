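# Multi-model PDB / GRO parsing, writing, frame selection, region lookup.

pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     altloc = " ", occ = 1) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, sprintf(" %-3s", name), altloc, resname, chain, resid,
          x, y, z, occ, 0, substr(name, 1, 1))
}

write_two_model_fixture <- function(path) {
  lines <- c(
    "MODEL        1",
    pdb_line(1, "N", "ALA", "A", 1, 1.000, 2.000, 3.000),
    pdb_line(2, "CA", "ALA", "A", 1, 2.500, 2.000, 3.000),
    pdb_line(3, "C", "ALA", "A", 1, 4.000, 2.000, 3.000),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "N", "ALA", "A", 1, 1.100, 2.100, 3.100),
    pdb_line(2, "CA", "ALA", "A", 1, 2.600, 2.100, 3.100),
    pdb_line(3, "C", "ALA", "A", 1, 4.100, 2.100, 3.100),
    "ENDMDL", "END")
  writeLines(lines, path)
  path
}

test_that("multi-model PDB reading converts angstrom to nm and keeps models", {
  path <- write_two_model_fixture(withr::local_tempfile(fileext = ".pdb"))
  tr <- read_multimodel_pdb(path)
  expect_equal(n_frames(tr), 2L)
  expect_equal(n_atoms(tr), 3L)
  # fixture values / 10: unit conversion is exact
  expect_equal(tr$coords[1, , 1], c(0.1, 0.2, 0.3))
  expect_equal(tr$coords[3, , 2], c(0.41, 0.21, 0.31))
  expect_equal(tr$topology$element, c("N", "C", "C"))
  expect_gt(min(tr$topology$mass), 0)
})

test_that("a file without MODEL records is one implicit model", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
               pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0), "END"), path)
  tr <- read_multimodel_pdb(path)
  expect_equal(n_frames(tr), 1L)
  expect_equal(n_atoms(tr), 2L)
})

test_that("altloc resolves to highest occupancy, ties to first record", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "SER", "A", 1, 1, 0, 0, altloc = "A", occ = 0.4),
    pdb_line(2, "CA", "SER", "A", 1, 2, 0, 0, altloc = "B", occ = 0.6),
    pdb_line(3, "CB", "SER", "A", 1, 3, 0, 0, altloc = "A", occ = 0.5),
    pdb_line(4, "CB", "SER", "A", 1, 4, 0, 0, altloc = "B", occ = 0.5),
    "END"), path)
  tr <- read_multimodel_pdb(path)
  expect_equal(n_atoms(tr), 2L)
  expect_equal(tr$coords[1, 1, 1], 0.2)  # occupancy 0.6 wins
  expect_equal(tr$coords[2, 1, 1], 0.3)  # tie: first encountered wins
})

test_that("malformed records and inconsistent models are loud errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
               "ATOM      2  CA  ALA A   2        bad   0.000   0.000"), path)
  expect_error(read_multimodel_pdb(path), "line 2")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
               "ENDMDL", "MODEL        2",
               pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
               pdb_line(2, "CA", "ALA", "A", 2, 1, 0, 0),
               "ENDMDL"), path2)
  expect_error(read_multimodel_pdb(path2), "inconsistent atom counts")
})

test_that("write + read round-trips coordinates, names, chains and resids", {
  gen <- generate_dimer_trajectory(
    default_plant_spec("bound", seed = 4, n_frames = 10))
  tr <- gen$trajectory
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, path)
  back <- read_multimodel_pdb(path)
  expect_equal(n_frames(back), 10L)
  expect_lte(max(abs(back$coords - tr$coords)), 1e-4)
  expect_identical(back$topology$chain, tr$topology$chain)
  expect_identical(back$topology$resid, tr$topology$resid)
  expect_identical(back$topology$name, tr$topology$name)
  # idempotence: a second write/read cycle reproduces coordinates exactly
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(back, path2)
  again <- read_multimodel_pdb(path2)
  expect_identical(again$coords, back$coords)
})

test_that("written PDB agrees with an independent reader (bio3d)", {
  skip_if_not_installed("bio3d")
  fr <- build_ideal_backbone("ASTL", -57, -47)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(trajectory(fr$atoms, fr$coords), path)
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_equal(xyz / 10, fr$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(pdb$atom$resid[1], "ALA")
})

test_that("writer refuses what PDB fixed-width fields cannot hold", {
  fr <- point_frame(matrix(0, 1, 3))
  expect_error(write_multimodel_pdb(trajectory(fr$atoms[0, ],
                                               fr$coords[0, , drop = FALSE]),
                                    tempfile()))
  at <- atom_table(1, "CA", "ALA", 10000, "A")
  tr <- trajectory(at, matrix(0, 1, 3))
  expect_error(write_multimodel_pdb(tr, tempfile()), "resid")
})

test_that("GRO reading takes nm coordinates and ignores velocities", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "two atoms",
    "    2",
    "    1ALA      N    1   0.000   0.000   0.000",
    "    1ALA     CA    2   1.000   0.000   0.000",
    "   5.0   5.0   5.0"), path)
  fr <- read_gro(path)
  expect_equal(sqrt(sum((fr$coords[2, ] - fr$coords[1, ])^2)), 1)
  # with velocity columns: same coordinates
  path2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "two atoms",
    "    2",
    "    1ALA      N    1   0.000   0.000   0.000  0.1000  0.2000  0.3000",
    "    1ALA     CA    2   1.000   0.000   0.000 -0.1000 -0.2000 -0.3000",
    "   5.0   5.0   5.0"), path2)
  expect_identical(read_gro(path2)$coords, fr$coords)
  path3 <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("bad", "    1", "    1ALA      N    1   0.0",
               "   5.0   5.0   5.0"), path3)
  expect_error(read_gro(path3), "column widths")
})

test_that("frame selection matches the 50-ps ensemble sampling convention", {
  at <- atom_table(1, "CA", "ALA", 1, "A")
  nfr <- 3001L  # 0..150000 ps at 50 ps spacing
  tr <- trajectory(at, array(0, c(1, 3, nfr)), times = (0:3000) * 50)
  # the last 50 ns sampled every 50 ps: 1001 snapshots
  sel <- select_frames(tr, 100000, 150000, 50)
  expect_equal(n_frames(sel), 1001L)
  expect_equal(sel$times[1], 100000)
  expect_equal(sel$times[1001], 150000)
  # stride equal to native spacing keeps every frame in the window
  expect_equal(n_frames(select_frames(tr, 0, 150000, 50)), 3001L)
  # selecting twice with nested windows equals selecting once
  a <- select_frames(select_frames(tr, 50000, 150000, 50), 100000, 140000, 50)
  b <- select_frames(tr, 100000, 140000, 50)
  expect_identical(a$times, b$times)
  expect_error(select_frames(tr, 2e5, 3e5, 50), "empty")
  expect_error(select_frames(tr, 100, 50, 50), "t_start")
})

test_that("regions resolve to their atoms with strict errors", {
  fr <- dimerlens:::.jd_fold(dimerlens:::.jd_sequence())
  tr <- trajectory(fr$atoms, fr$coords)
  hp <- region_spec("hairpin", "A", 31, 62)
  idx <- resolve_region(tr, hp)
  expect_equal(sort(unique(tr$topology$resid[idx])), 31:62)
  expect_length(unique(tr$topology$resid[idx]), 32L)
  one <- resolve_region(tr, region_spec("w87", "A", 87, 87))
  expect_true(all(tr$topology$resid[one] == 87))
  expect_error(region_spec("bad", "A", 62, 31), "first_resid")
  expect_error(resolve_region(tr, region_spec("x", "Q", 1, 5)), "chain")
})
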