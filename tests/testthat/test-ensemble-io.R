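test_that("multi-model PDB files round-trip through write and read", {
  ref <- make_toy_rna(2, seed = 7)
  spec <- fixture_spec(n_models = 3, n_sites = 5, n_bulk_waters = 0, seed = 5)
  ens <- make_solvent_ensemble(ref, spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  back <- standardize_species(read_ensemble(path))
  expect_length(back$models, 3L)
  for (m in 1:3) {
    a <- ens$models[[m]]; b <- back$models[[m]]
    expect_equal(nrow(b), nrow(a))
    expect_equal(b$residue_index, a$residue_index)
    expect_equal(b$species, a$species)
    expect_equal(b$atom_name, a$atom_name)
    expect_lt(max(abs(coords_of(b) - coords_of(a))), 1e-3 + 1e-9)
  }
  # a second round trip is exact: the writer's 3-decimal grid is stable
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(back, path2)
  again <- standardize_species(read_ensemble(path2))
  expect_identical(lapply(again$models, coords_of), lapply(back$models, coords_of))
})

test_that("a file without MODEL records reads as a one-model ensemble", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P     G A   1       1.000   2.000   3.000  1.00 10.00           P",
    "ATOM      2  C4'   G A   1       2.000   2.500   3.000  1.00 10.00           C",
    "HETATM    3  O   HOH A 101       5.000   5.000   5.000  1.00 20.00           O",
    "END"), path)
  ens <- read_ensemble(path)
  expect_length(ens$models, 1L)
  expect_equal(nrow(ens$models[[1]]), 3L)
  expect_equal(ens$models[[1]]$atom_name, c("P", "C4'", "O"))
})

test_that("mmCIF and PDB serializations of the same coordinates agree", {
  ref <- make_toy_rna(2, seed = 7)
  spec <- fixture_spec(n_models = 2, n_sites = 4, n_bulk_waters = 0, seed = 5)
  ens <- make_solvent_ensemble(ref, spec)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_ensemble(ens, pdb)
  write_cif_fixture(ens, cif)
  a <- standardize_species(read_ensemble(pdb))
  b <- standardize_species(read_ensemble(cif))
  expect_length(b$models, length(a$models))
  for (m in seq_along(a$models)) {
    expect_equal(b$models[[m]]$species, a$models[[m]]$species)
    expect_equal(b$models[[m]]$residue_index, a$models[[m]]$residue_index)
    expect_lt(max(abs(coords_of(b$models[[m]]) - coords_of(a$models[[m]]))), 1e-3 + 1e-9)
  }
})

test_that("unreadable or empty coordinate files raise informative errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_ensemble(empty), "no ATOM/HETATM")
  unbalanced <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1",
               "ATOM      1  P     G A   1       1.000   2.000   3.000  1.00 10.00           P"),
             unbalanced)
  expect_error(read_ensemble(unbalanced), "MODEL/ENDMDL")
  badcif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site.id", "_atom_site.type_symbol",
               "1 O extra_token"), badcif)
  expect_error(read_ensemble(badcif), "malformed|atom_site")
})

test_that("species standardization maps residue codes and is idempotent", {
  at <- data.frame(
    element = c("P", "Mg", "O", "N", "Na"),
    atom_name = c("P", "MG", "O", "N1", "NA"),
    residue_name = c("G", "MG", "SPM", "HOH", "NA"),
    residue_index = 1:5, chain_id = "A",
    x = 0, y = 0, z = as.numeric(1:5), b_factor = 0,
    stringsAsFactors = FALSE)
  std <- standardize_species(at)
  expect_equal(std$species, c("RNA", "Mg2+", "water", "water", "Na+"))
  expect_identical(standardize_species(std), std)
  # configurable mapping
  custom <- standardize_species(at, map = c(SPM = "K+", G = "RNA"))
  expect_equal(custom$species[3], "K+")
})

test_that("solvent trimming is inclusive at the cutoff, keyed on water oxygens", {
  rna <- data.frame(element = "P", atom_name = "P", residue_name = "G",
                    residue_index = 1L, chain_id = "A", x = 0, y = 0, z = 0,
                    b_factor = 0, stringsAsFactors = FALSE)
  wat <- function(d, idx) data.frame(
    element = "O", atom_name = "O", residue_name = "HOH",
    residue_index = idx, chain_id = "S", x = d, y = 0, z = 0,
    b_factor = 0, stringsAsFactors = FALSE)
  model <- standardize_species(rbind(rna, wat(4.9, 101L), wat(5.0, 102L), wat(6.0, 103L)))
  trimmed <- trim_solvent(model, cutoff = 5.0)
  expect_equal(trimmed$residue_index[trimmed$species == "water"], c(101L, 102L))
  # idempotent, never grows
  expect_identical(trim_solvent(trimmed), trimmed)
  expect_lte(nrow(trim_solvent(model)), nrow(model))
  # hydrogens follow their water oxygen
  h <- data.frame(element = "H", atom_name = "H1", residue_name = "HOH",
                  residue_index = 103L, chain_id = "S", x = 4.0, y = 0, z = 0,
                  b_factor = 0, stringsAsFactors = FALSE)
  m2 <- standardize_species(rbind(rna, wat(6.0, 103L), h))
  expect_equal(sum(trim_solvent(m2)$species == "water"), 0L)
  # no RNA at all is an error
  expect_error(trim_solvent(standardize_species(wat(3, 1L))), "no RNA")
})

test_that("alternate locations keep the highest-occupancy copy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P  AG A   1       1.000   0.000   0.000  0.40 10.00           P",
    "ATOM      2  P  BG A   1       2.000   0.000   0.000  0.60 10.00           P",
    "ATOM      3  C4'AG A   1       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  C4'BG A   1       4.000   0.000   0.000  0.50 10.00           C",
    "END"), path)
  m <- read_ensemble(path)$models[[1]]
  expect_equal(nrow(m), 2L)
  expect_equal(m$x[m$atom_name == "P"], 2.0)    # higher occupancy wins
  expect_equal(m$x[m$atom_name == "C4'"], 3.0)  # tie: first encountered wins
})

test_that("insertion codes are rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P     G A   1A      1.000   2.000   3.000  1.00 10.00           P",
    "END"), path)
  expect_error(read_ensemble(path), "insertion")
})

test_that("ensemble size limits and reference reading are enforced", {
  ref <- make_toy_rna(2, seed = 7)
  expect_error(cryoshell:::new_solvent_ensemble(list()), "zero models")
  path <- withr::local_tempfile(fileext = ".pdb")
  spec <- fixture_spec(n_models = 2, n_sites = 3, n_bulk_waters = 0, seed = 5)
  write_ensemble(make_solvent_ensemble(ref, spec), path)
  expect_warning(rr <- read_reference(path, excluded_residues = "2"), "using the first")
  expect_true(all(rr$atoms$species == "RNA"))
  expect_equal(rr$excluded_residues, 2L)
  expect_equal(parse_residue_ranges("63-65,229,231-232"), c(63L, 64L, 65L, 229L, 231L, 232L))
})
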