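test_that("synthetic tetramer round-trips through PDB with hemes and classes", {
  topo <- synthetic_topology("bovine")
  tmp <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(topo$model,
                       matrix(t(as.matrix(topo$model$atoms[, c("x", "y", "z")])),
                              nrow = 1), tmp)
  m <- read_structure(tmp, chain_classes = topo$map$chains)
  expect_length(m$hemes, 4L)
  expect_equal(sum(m$chains$subunit_class == "alpha"), 2L)
  expect_equal(sum(m$chains$subunit_class == "beta"), 2L)
  expect_equal(nrow(m$atoms), nrow(topo$model$atoms))
  ## coordinates survive to PDB precision (1e-3 A = 1e-4 nm)
  expect_lt(max(abs(as.matrix(m$atoms[, c("x", "y", "z")]) -
                    as.matrix(topo$model$atoms[, c("x", "y", "z")]))), 1e-4)
})

test_that("a heme lacking its iron is rejected with the chain named", {
  topo <- synthetic_topology("bovine")
  atoms <- topo$model$atoms
  atoms <- atoms[!(atoms$chain == "C" & atoms$elety == "FE"), ]
  expect_error(structure_model(atoms), "chain C")
  ## and a heme with a missing pyrrole nitrogen likewise
  atoms2 <- topo$model$atoms
  atoms2 <- atoms2[!(atoms2$chain == "B" & atoms2$elety == "NB"), ]
  expect_error(structure_model(atoms2), "pyrrole")
})

test_that("mini-pocket fixture parses to one heme with four pyrrole N", {
  path <- system.file("extdata", "minipocket.pdb", package = "hemegating")
  m <- read_structure(path)
  expect_length(m$hemes, 1L)
  expect_length(m$hemes[[1]]$pyrrole, 4L)
  ## expectation derived from the fixture text itself
  lines <- readLines(path)
  n_pyr <- sum(grepl("^HETATM", lines) &
               substr(lines, 13, 16) %in% c(" NA ", " NB ", " NC ", " ND "))
  expect_equal(length(m$hemes[[1]]$pyrrole), n_pyr)
})

test_that("resolve_site finds atoms and validates residue identity", {
  topo <- synthetic_topology("bovine")
  model <- topo$model; map <- topo$map
  e7 <- resolve_site(model, map, "alpha", "E7", "NE2", chain = "A")
  expect_s3_class(e7, "atom_ref")
  expect_equal(attr(e7, "resname"), "HIS")
  expect_equal(attr(e7, "resno"), map$sites$alpha$E7$resid)
  ## deterministic: same query, same atom
  expect_identical(as.integer(e7),
                   as.integer(resolve_site(model, map, "alpha", "E7", "NE2",
                                           chain = "A")))
  ## E11 CA resolves to the mapped residue index
  e11 <- resolve_site(model, map, "alpha", "E11", "CA", chain = "C")
  expect_equal(attr(e11, "resno"), map$sites$alpha$E11$resid)
  ## a trout-style map expecting TrpCE4 fails loudly on a bovine
  ## structure carrying PheCE4
  trout_map <- synthetic_topology("trout")$map
  expect_error(resolve_site(model, trout_map, "alpha", "CE4", "CG",
                            chain = "A"),
               "residue-name mismatch")
  expect_error(resolve_site(model, map, "alpha", "ZZ9", "CA", chain = "A"),
               "not mapped")
  expect_error(resolve_site(model, map, "alpha", "E7", "XX", chain = "A"),
               "absent")
})

test_that("trajectory I/O round-trips and validates atom counts", {
  topo <- synthetic_topology("bovine")
  n <- nrow(topo$model$atoms)
  base <- as.vector(t(as.matrix(topo$model$atoms[, c("x", "y", "z")])))
  set.seed(42)
  xyz <- matrix(rep(base, each = 10), nrow = 10) +
    matrix(stats::rnorm(10 * 3 * n, sd = 0.01), nrow = 10)
  tmp <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(topo$model, xyz, tmp)
  tr <- read_trajectory(topo$model, tmp, frame_spacing = 0.2)
  expect_equal(tr$n_frames, 10L)
  expect_lt(max(abs(tr$xyz - xyz)), 1e-3)   # format precision bound
  expect_equal(tr$times, 0.2 * (0:9))
  ## wrong atom count is a structured failure
  small <- synthetic_topology("trout")$model
  expect_error(read_trajectory(small, tmp), "atom-count mismatch")
  expect_error(read_trajectory(topo$model, tempfile(fileext = ".xtc")),
               "no such file")
})

test_that("multi-model PDB frame count follows its MODEL records", {
  topo <- synthetic_topology("bovine")
  base <- as.vector(t(as.matrix(topo$model$atoms[, c("x", "y", "z")])))
  xyz <- matrix(rep(base, each = 3), nrow = 3)
  tmp <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(topo$model, xyz, tmp)
  n_models <- sum(grepl("^MODEL", readLines(tmp)))
  tr <- read_trajectory(topo$model, tmp)
  expect_equal(tr$n_frames, n_models)
  expect_equal(tr$n_frames, 3L)
})

test_that("site maps survive a YAML round trip", {
  map <- synthetic_topology("trout")$map
  tmp <- tempfile(fileext = ".yaml")
  write_site_map(map, tmp)
  m2 <- read_site_map(tmp)
  expect_equal(m2$species, map$species)
  expect_equal(m2$chains, map$chains)
  expect_equal(m2$sites$alpha$CE4$resname, "TRP")
  expect_equal(m2$sites$alpha$E7$resid, map$sites$alpha$E7$resid)
})

test_that("TSV export is deterministic and carries its header block", {
  tr <- const_trace(0.45, n = 12)
  f1 <- tempfile(); f2 <- tempfile()
  write_trace_tsv(tr, f1, header = list(species = "synthetic"))
  write_trace_tsv(tr, f2, header = list(species = "synthetic"))
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_true(any(grepl("^# species: synthetic", lines)))
  tab <- utils::read.delim(f1, comment.char = "#")
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$value_nm, rep(0.45, 12))
})
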