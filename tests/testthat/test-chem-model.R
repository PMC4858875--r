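# Molecule parsing, hydrogen completion and proton equivalence classes.

methaneSDF <- function(path) {
  writeLines(c(
    "methane", "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END", "$$$$"), path)
  path
}

test_that("readSDF parses V2000 records faithfully", {
  f <- methaneSDF(tempfile(fileext = ".sdf"))
  mols <- readSDF(f)
  expect_length(mols, 1L)
  expect_equal(atomCount(mols[[1]]), 5L)
  expect_equal(nrow(bondTable(mols[[1]])), 4L)
  expect_equal(molId(mols[[1]]), "methane")

  # two records preserve file order
  f2 <- tempfile(fileext = ".sdf")
  writeLines(c(readLines(f),
               sub("methane", "methane2", readLines(f))), f2)
  mols2 <- readSDF(f2)
  expect_length(mols2, 2L)
  expect_equal(vapply(mols2, molId, character(1)), c("methane", "methane2"))

  empty <- tempfile(fileext = ".sdf")
  file.create(empty)
  expect_length(readSDF(empty), 0L)
})

test_that("readSDF round-trips writeSDF including formal charges", {
  acetate <- mkMol(c("C", "C", "O", "O"), c(1, 2, 2), c(2, 3, 4),
                   c(1, 2, 1), charges = c(0L, 0L, 0L, -1L), id = "acetate")
  f <- tempfile(fileext = ".sdf")
  writeSDF(list(acetate, fixBenzene()), f)
  back <- readSDF(f)
  expect_length(back, 2L)
  expect_equal(atomTable(back[[1]]), atomTable(acetate))
  expect_equal(bondTable(back[[1]]), bondTable(acetate))
  expect_equal(atomTable(back[[2]])$symbol, atomTable(fixBenzene())$symbol)
})

test_that("readSDF enforces record-level contracts", {
  bad <- tempfile(fileext = ".sdf")
  writeLines(c(
    "bad", "", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  3  1  0",
    "M  END", "$$$$"), bad)
  expect_error(readSDF(bad), "record 1.*outside 1\\.\\.2")

  v3 <- tempfile(fileext = ".sdf")
  writeLines(c("v3", "", "",
               "  0  0  0  0  0  0  0  0  0  0999 V3000",
               "M  END", "$$$$"), v3)
  expect_error(readSDF(v3), "V3000")

  garbled <- tempfile(fileext = ".sdf")
  writeLines(c("g", "", "", "not a counts line", "M  END", "$$$$"), garbled)
  expect_error(readSDF(garbled), "record 1.*counts line")
})

test_that("disconnected records keep the largest component with a warning", {
  salt <- tempfile(fileext = ".sdf")
  writeLines(c(
    "salt", "", "",
    "  4  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 Cl  0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0",
    "M  END", "$$$$"), salt)
  expect_warning(mols <- readSDF(salt), "disconnected")
  expect_equal(atomCount(mols[[1]]), 3L)
  expect_equal(atomTable(mols[[1]])$symbol, c("C", "C", "C"))
})

test_that("readSDF agrees with the ChemmineR reader on atoms and bonds", {
  skip_if_not_installed("ChemmineR")
  f <- tempfile(fileext = ".sdf")
  writeSDF(list(fixEthanol(), fixAnisole(), fixMethylAcetate()), f)
  mine <- readSDF(f)
  theirs <- suppressWarnings(ChemmineR::read.SDFset(f))
  for (i in seq_along(mine)) {
    ab <- ChemmineR::atomblock(theirs[[i]])
    bb <- ChemmineR::bondblock(theirs[[i]])
    expect_equal(atomCount(mine[[i]]), nrow(ab))
    expect_equal(atomTable(mine[[i]])$symbol,
                 gsub("_.*", "", rownames(ab)))
    b <- bondTable(mine[[i]])
    expect_equal(b[order(b$from, b$to), c("from", "to", "order")],
                 data.frame(from = as.integer(bb[, 1]),
                            to = as.integer(bb[, 2]),
                            order = as.integer(bb[, 3]))[
                   order(bb[, 1], bb[, 2]), ],
                 ignore_attr = TRUE)
  }
})

test_that("completeHydrogens reaches standard valences and is idempotent", {
  eth <- completeHydrogens(mkMol(c("C", "C", "O"), c(1, 2), c(2, 3), c(1, 1)))
  expect_equal(atomCount(eth), 9L)                       # 3 heavy + 6 H
  expect_equal(sum(atomTable(eth)$symbol == "H"), 6L)
  expect_equal(completeHydrogens(eth), eth)              # idempotent
  m <- fixMethane()
  expect_equal(completeHydrogens(m), m)                  # explicit H preserved

  # formal charge changes valence: ammonium gets 4 H, alkoxide O none
  ammonium <- completeHydrogens(mkMol("N", integer(0), integer(0), integer(0),
                                      charges = 1L))
  expect_equal(sum(atomTable(ammonium)$symbol == "H"), 4L)
  alkox <- completeHydrogens(mkMol(c("C", "O"), 1, 2, 1, charges = c(0L, -1L)))
  expect_equal(sum(atomTable(alkox)$symbol == "H"), 3L)  # only the carbon

  # aromatic carbons count 1.5 per ring bond: one H each on benzene
  expect_equal(sum(atomTable(fixBenzene())$symbol == "H"), 6L)
})

test_that("completeHydrogens rejects over-valent atoms", {
  penta <- mkMol(c("C", "C", "C", "C", "C", "C"),
                 rep(1, 5), 2:6, rep(1, 5))
  expect_error(completeHydrogens(penta), "valence error: atom 1")
})

test_that("proton classes match symmetry on reference molecules", {
  expect_equal(lengths(protonClasses(fixBenzene())), 6L)
  expect_equal(lengths(protonClasses(fixMethane())), 4L)
  expect_equal(lengths(protonClasses(fixEthanol())), c(3L, 2L, 1L))
  # propane: the two methyls are exchanged by an automorphism -> one class
  expect_equal(lengths(protonClasses(fixPropane())), c(6L, 2L))
  # anisole: OCH3, 2 ortho, 2 meta, 1 para
  expect_setequal(lengths(protonClasses(fixAnisole())), c(3L, 2L, 2L, 1L))
})

test_that("proton classes equal brute-force automorphism orbits", {
  for (fix in list(fixMethane(), fixEthanol(), fixPropane(), fixBenzene(),
                   fixToluene(), fixAnisole(), fixMethylFormate(),
                   fixMethylAcetate())) {
    expect_true(samePartition(protonClasses(fix), oracleProtonOrbits(fix)),
                label = paste("orbits of", molId(fix)))
  }
})

test_that("class partition is invariant under atom relabelling", {
  withr::local_seed(42)
  for (mol in list(fixEthanol(), fixToluene(), fixMethylAcetate())) {
    cl <- protonClasses(mol)
    for (rep_ in 1:5) {
      perm <- sample(atomCount(mol))
      pm <- permuteMolecule(mol, perm)
      clP <- protonClasses(pm$mol)
      mapped <- lapply(cl, function(g) sort(pm$newIndex[g]))
      mapped <- mapped[order(vapply(mapped, min, integer(1)))]
      expect_true(samePartition(clP, mapped))
    }
  }
})

test_that("class sizes always sum to the hydrogen count", {
  mols <- genMolecules(15, seed = 7)
  for (mol in mols) {
    cl <- protonClasses(mol)
    expect_equal(sum(lengths(cl)), sum(atomTable(mol)$symbol == "H"))
  }
})
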