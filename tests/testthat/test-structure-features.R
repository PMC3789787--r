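test_that("minimum ligand distance is the closest heavy-atom pair", {
  atoms <- rbind(
    atom_row(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_row(2, "FE", "HEM", "A", 90, 3, 0, 0, elesy = "FE", het = TRUE))
  m <- make_model(atoms)
  expect_equal(minLigandDistance(m, 1, "heme"), 3.0)

  atoms2 <- rbind(
    atom_row(1, "CA", "ALA", "A", 1, 5, 0, 0),
    atom_row(2, "CB", "ALA", "A", 1, 2, 0, 0),
    atom_row(3, "FE", "HEM", "A", 90, 0, 0, 0, elesy = "FE", het = TRUE))
  expect_equal(minLigandDistance(make_model(atoms2), 1, "heme"), 2.0)

  expect_error(minLigandDistance(m, 7, "heme"), "not present")
  expect_error(minLigandDistance(m, 1, "plp"), "plp")
})

test_that("ligand distances match a brute-force all-pairs scan", {
  f <- simulateStructure(60, ligand_xyz = list(heme = c(12, 3, 40),
                                               plp = c(-8, 5, 10)),
                         path = withr::local_tempfile(fileext = ".pdb"))
  m <- readStructure(f)
  for (p in c(1, 17, 30, 55)) {
    expect_equal(minLigandDistance(m, p, "heme"),
                 brute_min_distance(m, p, "heme"), tolerance = 1e-9)
    expect_equal(minLigandDistance(m, p, "plp"),
                 brute_min_distance(m, p, "plp"), tolerance = 1e-9)
  }
})

test_that("same-chain scope restricts the ligand search", {
  atoms <- rbind(
    atom_row(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_row(2, "FE", "HEM", "A", 90, 8, 0, 0, elesy = "FE", het = TRUE),
    atom_row(3, "FE", "HEM", "B", 90, 2, 0, 0, elesy = "FE", het = TRUE))
  m <- make_model(atoms)
  expect_equal(minLigandDistance(m, 1, "heme", scope = "all_chains"), 2.0)
  expect_equal(minLigandDistance(m, 1, "heme", scope = "same_chain"), 8.0)
})

test_that("isolated-atom SASA matches the closed-form sphere area", {
  # selenium: vdW 1.9, probe 1.4 -> 4*pi*3.3^2
  atoms <- atom_row(1, "SE", "MSE", "A", 1, 0, 0, 0, elesy = "SE")
  m <- make_model(atoms)
  area <- solventAccessibility(m, 1, relative = FALSE)
  expect_equal(area, 4 * pi * 3.3^2, tolerance = 0.01)

  # an atom enclosed by an octahedral shell of occluders has zero area
  shell <- do.call(rbind, lapply(seq_len(6), function(i) {
    d <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0),
               c(0, -2, 0), c(0, 0, 2), c(0, 0, -2))[i, ]
    atom_row(i + 1, "C", "ALA", "A", 2, d[1], d[2], d[3])
  }))
  enclosed <- make_model(rbind(atom_row(1, "C", "ALA", "A", 1, 0, 0, 0),
                               shell))
  expect_equal(solventAccessibility(enclosed, 1, relative = FALSE), 0)
  expect_error(solventAccessibility(
    make_model(atom_row(1, "X", "ALA", "A", 1, 0, 0, 0, elesy = "XX")), 1),
    "radius")
})

test_that("helix interior residues are more buried than the termini", {
  f <- simulateStructure(30, ligand_xyz = list(heme = c(50, 50, 50),
                                               plp = c(60, 60, 60)),
                         path = withr::local_tempfile(fileext = ".pdb"))
  m <- readStructure(f)
  expect_lt(solventAccessibility(m, 15), solventAccessibility(m, 1))
  expect_lt(solventAccessibility(m, 15), solventAccessibility(m, 30))
})

test_that("absolute residue SASA agrees with an independent implementation", {
  # Reference values computed once with biotite's Shrake-Rupley
  # (960 points, probe 1.4, identical vdW radii) on this deterministic
  # 20-residue helix, protein atoms only.
  f <- simulateStructure(20, ligand_xyz = list(heme = c(50, 50, 50),
                                               plp = c(60, 60, 60)),
                         path = withr::local_tempfile(fileext = ".pdb"))
  m <- readStructure(f)
  reference <- c(`1` = 119.92, `5` = 65.94, `10` = 66.82, `15` = 65.95,
                 `20` = 122.18)
  for (p in names(reference)) {
    mine <- solventAccessibility(m, as.integer(p), relative = FALSE)
    expect_lt(abs(mine / reference[[p]] - 1), 0.05)
  }
})

test_that("distances and SASA are invariant under rigid-body motion", {
  f <- simulateStructure(25, path = withr::local_tempfile(fileext = ".pdb"))
  m <- readStructure(f)
  mt <- rigid_transform(m, seed = 9)
  for (p in c(2, 12, 24)) {
    expect_equal(minLigandDistance(m, p, "heme"),
                 minLigandDistance(mt, p, "heme"), tolerance = 1e-6)
    expect_equal(solventAccessibility(m, p),
                 solventAccessibility(mt, p), tolerance = 1e-6)
    expect_equal(meanBfactor(m, p), meanBfactor(mt, p))
  }
})

test_that("secondary structure uses records first, dihedral windows as fallback", {
  f <- simulateStructure(30, path = withr::local_tempfile(fileext = ".pdb"))
  m <- readStructure(f)
  expect_true(secondaryStructure(m, 10))

  # records present but not covering a residue -> loop
  m2 <- m
  m2@helix <- data.frame(chain = "A", start = 1L, end = 20L)
  expect_false(secondaryStructure(m2, 25))

  # no records: ideal helix dihedrals classify interior residues as regular
  f3 <- simulateStructure(30, helix_record = FALSE,
                          path = withr::local_tempfile(fileext = ".pdb"))
  m3 <- readStructure(f3)
  expect_length(m3@helix$start, 0)
  for (p in 2:29) expect_true(secondaryStructure(m3, p))
})

test_that("B-factors average per residue and recover planted profiles", {
  atoms <- rbind(atom_row(1, "N", "ALA", "A", 1, 0, 0, 0, b = 10),
                 atom_row(2, "CA", "ALA", "A", 1, 1.5, 0, 0, b = 20),
                 atom_row(3, "C", "ALA", "A", 1, 3, 0, 0, b = 30),
                 atom_row(4, "CA", "ALA", "A", 2, 6, 0, 0, b = 15))
  m <- make_model(atoms)
  expect_equal(meanBfactor(m, 1), 20.0)
  expect_equal(meanBfactor(m, 2), 15.0)

  prof <- seq(10, 34, length.out = 25)
  f <- simulateStructure(25, bfactor_profile = prof,
                         path = withr::local_tempfile(fileext = ".pdb"))
  m2 <- readStructure(f)
  got <- vapply(1:25, function(p) meanBfactor(m2, p), numeric(1))
  expect_equal(got, prof, tolerance = 0.005)  # PDB B column prints 2 dp
})

test_that("the feature table maps 44 residues and leaves 7 substitutions out", {
  panel <- loadTable1()
  f <- simulateStructure(321, path = withr::local_tempfile(fileext = ".pdb"))
  m <- readStructure(f, offset = 64L)  # file residue 1 = NP position 65
  ft <- featureTable(m, panel, n_points = 120)
  expect_equal(attr(ft, "n_mapped"), 44L)
  expect_equal(attr(ft, "n_unmapped"), 7L)
  expect_true(all(is.na(ft$rsa[!ft$mapped])))
  expect_true(all(!is.na(ft$dist_heme[ft$mapped])))

  empty <- new("VariantPanel",
               records = variantRecords(panel)[0, ],
               growth = growthResults(panel)[0, ])
  expect_equal(nrow(featureTable(m, empty)), 0L)
})
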