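test_that("minimal PDB parses with size-based partner assignment", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdbAtomLine(3, "CA", "SER", "B", 1, 0, 4, 0),
    "END"), f)
  m <- readModel(f)
  expect_s4_class(m, "StructureModel")
  expect_equal(sort(unique(residueKeys(m))), c("A:1", "A:2", "B:1"))
  expect_equal(partnerMap(m), c(A = "receptor", B = "ligand"))
})

test_that("homodimer tie-break makes the alphabetically first chain receptor", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdbAtomLine(1, "CA", "ALA", "B", 1, 0, 0, 0),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 5, 0, 0),
    "END"), f)
  m <- readModel(f)
  expect_equal(partnerMap(m)[["A"]], "receptor")
  expect_equal(partnerMap(m)[["B"]], "ligand")
})

test_that("hydrogens are kept but non-heavy and invisible to contacts", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "HB1", "ALA", "A", 1, 1, 0, 0, element = "H"),
    pdbAtomLine(3, "CA", "GLY", "B", 1, 20, 0, 0),
    # only the hydrogen of B:1 is close to A:1
    pdbAtomLine(4, "HA", "GLY", "B", 1, 2, 0, 0, element = "H"),
    "END"), f)
  m <- readModel(f)
  a <- atoms(m)
  expect_equal(sum(!a$isHeavy), 2L)
  expect_length(contacts(contactFingerprint(m)), 0)
})

test_that("malformed coordinate fields raise an error naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  good <- pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0)
  bad <- sub("   0.000", "  0.x00 ", pdbAtomLine(2, "CA", "GLY", "B", 1, 0, 0, 0))
  writeLines(c(good, bad, "END"), f)
  expect_error(readModel(f), "line 2|malformed")
})

test_that("missing files and empty structures are rejected", {
  expect_error(readModel(file.path(tempdir(), "nope.pdb")), "cannot read")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), f)
  expect_error(readModel(f), "no ATOM records")
})

test_that("alternate locations resolve to the highest occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.3, alt = "A"),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.7, alt = "B"),
    pdbAtomLine(3, "CA", "GLY", "B", 1, 1, 0, 0),
    "END"), f)
  m <- readModel(f)
  a <- atoms(m)
  caA1 <- a[a$chain == "A" & a$elety == "CA", ]
  expect_equal(nrow(caA1), 1L)
  expect_equal(unname(unlist(caA1[, c("x", "y", "z")])), c(9, 9, 9))
})

test_that("explicit receptor chains are honored and validated", {
  m <- toyModel(data.frame(chain = c("A", "B", "C"), resno = 1,
                           x = c(0, 5, 10), y = 0, z = 0),
                partnerOf = c(A = "receptor", B = "ligand", C = "ligand"))
  m2 <- assignPartners(m, receptorChains = c("A", "B"))
  expect_equal(partnerMap(m2), c(A = "receptor", B = "receptor", C = "ligand"))
  expect_error(assignPartners(m, receptorChains = "Z"), "not present")
  expect_error(assignPartners(m, receptorChains = c("A", "B", "C")),
               "no ligand")
})

test_that("round-trip through PDB preserves keys, elements and coordinates", {
  native <- makeNative(complexSpec(seed = 3))
  for (mod in list(native, transformModel(native, angle = 1.1))) {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeModel(mod, f)
    back <- readModel(f, modelId = modelId(mod))
    expect_equal(residueKeys(back), residueKeys(mod))
    expect_equal(atoms(back)$elesy, atoms(mod)$elesy)
    expect_equal(as.matrix(atoms(back)[, c("x", "y", "z")]),
                 as.matrix(atoms(mod)[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("insertion codes survive a round trip", {
  m <- toyModel(data.frame(chain = c("A", "A", "B"), resno = c(52, 52, 1),
                           insert = c("", "A", ""),
                           x = c(0, 2, 4), y = 0, z = 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeModel(m, f)
  back <- readModel(f)
  expect_setequal(unique(residueKeys(back)), c("A:52", "A:52A", "B:1"))
})

test_that("residue numbers beyond PDB fixed columns are rejected", {
  m <- toyModel(data.frame(chain = c("A", "B"), resno = c(10000, 1),
                           x = c(0, 5), y = 0, z = 0))
  expect_error(writeModel(m, withr::local_tempfile(fileext = ".pdb")),
               "9999")
})

test_that("harmonization aligns offset numbering onto shared keys", {
  native <- makeNative(complexSpec(receptorLength = 30, ligandLength = 15,
                                   axisSeparation = 9, seed = 5))
  shifted <- native
  a <- atoms(shifted)
  a$resno[a$chain == "B"] <- a$resno[a$chain == "B"] + 5L
  shifted <- initialize(shifted, modelId = "shifted", atoms = a)
  ens <- harmonizeNumbering(new("ModelEnsemble",
                                models = list(native, shifted)))
  expect_true(isHarmonized(ens))
  keys <- lapply(models(ens), function(m) sort(unique(residueKeys(m))))
  expect_identical(keys[[1]], keys[[2]])
  # coordinates untouched
  expect_identical(atoms(models(ens)[[2]])[, c("x", "y", "z")],
                   atoms(shifted)[, c("x", "y", "z")])
})

test_that("harmonization is idempotent on a consistent ensemble", {
  sim <- smallScenario(seed = 2, nModels = 6)
  once <- harmonizeNumbering(sim$ensemble)
  twice <- harmonizeNumbering(once)
  for (i in seq_along(models(once))) {
    expect_identical(atoms(models(twice)[[i]]), atoms(models(once)[[i]]))
    expect_identical(partnerMap(models(twice)[[i]]),
                     partnerMap(models(once)[[i]]))
  }
})

test_that("chains below the identity threshold stay in separate groups", {
  # two unrelated random sequences: identity far below 70%
  m1 <- makeNative(complexSpec(receptorLength = 30, ligandLength = 15,
                               axisSeparation = 9, seed = 7))
  m2 <- makeNative(complexSpec(receptorLength = 30, ligandLength = 15,
                               axisSeparation = 9, seed = 8))
  m2 <- initialize(m2, modelId = "other")
  expect_warning(
    ens <- harmonizeNumbering(new("ModelEnsemble",
                                  models = list(m1, m2))),
    "own group")
  # chain ids must differ between the groups after harmonization
  ch1 <- unique(atoms(models(ens)[[1]])$chain)
  ch2 <- unique(atoms(models(ens)[[2]])$chain)
  expect_length(intersect(ch1, ch2), 0)
})

test_that("readEnsemble loads a directory of models", {
  sim <- smallScenario(seed = 3, nModels = 5)
  dir <- withr::local_tempdir()
  writeEnsemble(sim$ensemble, dir)
  ens <- readEnsemble(dir)
  expect_length(models(ens), 5)
  expect_false(isHarmonized(ens))
  expect_error(readEnsemble(withr::local_tempdir()), "no PDB files")
})
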