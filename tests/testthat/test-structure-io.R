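# PDB parsing/writing and CASP QA (QMODE) exchange formats.

minimal_pdb <- paste(
  "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
  "END", sep = "\n")

test_that("minimal one-atom PDB parses into a one-residue structure", {
  s <- read_pdb(minimal_pdb)
  expect_s3_class(s, "structure3d")
  expect_equal(chain_ids(s), "A")
  expect_equal(length(residue_keys(s)), 1L)
  expect_equal(s$atoms$x, 11.104)
})

test_that("PDB round-trip is stable and preserves coordinates and order", {
  spec <- decoy_spec("A1B1", chain_length = 6, seed = 2)
  s <- make_reference(spec)
  txt1 <- write_pdb(s)
  s2 <- read_pdb(txt1)
  txt2 <- write_pdb(s2)
  expect_identical(txt1, txt2)           # idempotent after first pass
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(chain_ids(s2), chain_ids(s))
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 5e-4)
  expect_equal(s2$atoms$y, s$atoms$y, tolerance = 5e-4)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 5e-4)
})

test_that("altloc filtering keeps blank and 'A' records only", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CB BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  s <- read_pdb(txt)
  # hand count: CA(1) + CB altloc A + CA(2) = 3 atoms retained
  expect_equal(nrow(s$atoms), 3L)
  cb <- s$atoms[s$atoms$atom == "CB", ]
  expect_equal(cb$x, 1.0)
})

test_that("hydrogens, HETATM and later MODELs are dropped", {
  txt <- paste(
    "MODEL     1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   ALA A   1       0.500   0.000   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       9.000   0.000   0.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL     2",
    "ATOM      4  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END", sep = "\n")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$atom, "CA")
})

test_that("malformed ATOM records raise errors naming the line", {
  bad <- paste(
    "ATOM      1  CA  ALA A   1      xx.xxx   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  expect_error(read_pdb(bad), "line 1")
  expect_error(read_pdb("REMARK nothing\nEND"), "no ATOM records")
})

test_that("B-factor annotation follows the score*100 convention", {
  s <- read_pdb(minimal_pdb)
  key <- residue_keys(s)
  txt <- write_pdb(s, track = new_track(key, 0.852), scale = 100)
  expect_match(txt, " 85.20", fixed = TRUE)
  txt1 <- write_pdb(s, track = new_track(key, 1.0), scale = 1)
  expect_match(txt1, "  1.00          ", fixed = TRUE)
  # unscored residues serialize as 0.00; absent track preserves input b
  txt0 <- write_pdb(s, track = new_track(key, NA_real_))
  expect_match(txt0, "  0.00           C", fixed = TRUE)
  expect_identical(write_pdb(s), write_pdb(read_pdb(write_pdb(s))))
})

test_that("annotation never changes coordinate fields", {
  spec <- decoy_spec("A2", chain_length = 5, seed = 3)
  s <- make_reference(spec)
  tr <- new_track(residue_keys(s), 0.5)
  plain <- strsplit(write_pdb(s), "\n")[[1]]
  annot <- strsplit(write_pdb(s, track = tr), "\n")[[1]]
  expect_identical(substr(plain, 31, 54), substr(annot, 31, 54))
})

test_that("track referencing an absent residue is an error", {
  s <- read_pdb(minimal_pdb)
  bad <- new_track(c(residue_keys(s), "Z|9|"), 0.5)
  expect_error(write_pdb(s, track = bad), "absent")
})

test_that("bio3d independently parses coordinates we write", {
  skip_if_not_installed("bio3d")
  spec <- decoy_spec("A3", chain_length = 6, seed = 4)
  s <- make_reference(spec)
  f <- tempfile(fileext = ".pdb")
  write_pdb_file(s, f)
  ext <- bio3d::read.pdb(f)
  expect_equal(nrow(ext$atom), nrow(s$atoms))
  expect_equal(ext$atom$x, s$atoms$x, tolerance = 5e-4)
  expect_equal(ext$atom$chain, s$atoms$chain)
  expect_equal(ext$atom$resno, s$atoms$resno)
})

test_that("QMODE2 formats one record per model with X for unscored", {
  keys <- c("A|1|", "A|2|", "A|3|")
  res <- list(list(model = "model1", global = 0.5,
                   track = new_track(keys, c(0.5, 0.25, NA))))
  txt <- write_qmode2("T1234", res, keys)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1:4], c("PFRMAT QA", "TARGET T1234", "MODEL 1",
                             "QMODE 2"))
  expect_equal(lines[5], "model1 0.500 0.50 0.25 X")
  expect_equal(lines[6], "END")
})

test_that("45-residue tracks wrap at 20 values per line", {
  keys <- sprintf("A|%d|", 1:45)
  res <- list(list(model = "m", global = 1,
                   track = new_track(keys, rep(0.5, 45))))
  txt <- write_qmode2("T0", res, keys)
  body <- setdiff(strsplit(txt, "\n")[[1]],
                  c("PFRMAT QA", "TARGET T0", "MODEL 1", "QMODE 2", "END"))
  expect_equal(length(body), 3L)
  nvals <- vapply(strsplit(body, " "), length, 0L)
  expect_equal(nvals, c(22L, 20L, 5L))   # name + global + 20, 20, 5
})

test_that("QMODE2 read/write round-trips and second write is identical", {
  keys <- sprintf("A|%d|", 1:25)
  set.seed(42)
  res <- list(
    list(model = "m1", global = 0.81,
         track = new_track(keys, round(runif(25), 2))),
    list(model = "m2", global = 0.33,
         track = new_track(keys, c(rep(NA, 5), round(runif(20), 2))))
  )
  txt <- write_qmode2("T9", res, keys)
  rec <- read_qmode2(txt)
  expect_equal(rec$target, "T9")
  expect_equal(length(rec$models), 2L)
  expect_equal(rec$models[[1]]$global, 0.81)
  expect_equal(rec$models[[1]]$local, unname(as.numeric(res[[1]]$track)))
  expect_true(all(is.na(rec$models[[2]]$local[1:5])))
  # rebuild from the parsed record: byte-identical second pass
  res2 <- lapply(rec$models, function(m)
    list(model = m$model, global = m$global,
         track = new_track(keys, m$local)))
  expect_identical(write_qmode2("T9", res2, keys), txt)
})

test_that("QMODE read validates format and score range", {
  expect_error(read_qmode("PFRMAT QA\nTARGET T\nm1 0.5\nEND"), "QMODE")
  expect_error(
    read_qmode("PFRMAT QA\nTARGET T\nMODEL 1\nQMODE 2\nm1 1.500 0.50\nEND"),
    "range")
  r1 <- read_qmode("PFRMAT QA\nTARGET T\nMODEL 1\nQMODE 1\nm1 0.500\nEND")
  expect_equal(r1$mode, 1L)
  expect_equal(r1$models[[1]]$global, 0.5)
})
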