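test_that("hand-written PDB fragments parse with residue annotation intact", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLU A 885      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  GLU A 885      11.400  10.000  10.000  1.00  0.00           C",
    "ATOM      3  OE2 GLU A 885      12.000  11.200  10.500  1.00  0.00           O",
    "END"), pdb)
  mol <- read_structure(pdb, "pdb")
  expect_s3_class(mol, "molecule3d")
  expect_equal(nrow(mol$atoms), 3L)
  # author numbering preserved verbatim
  expect_equal(unique(mol$atoms$residue_number), 885L)
  expect_equal(unique(mol$atoms$residue_name), "GLU")
  expect_equal(mol$atoms$atom_name, c("N", "CA", "OE2"))
})

test_that("PDB with HETATM ligand splits into receptor and ligand, waters stripped", {
  cx <- make_toy_complex(complex_spec(list(
    hb_contact(919, "CYS", 2.9)), seed = 1))
  pdb <- tempfile(fileext = ".pdb")
  write_pdb_complex(cx, pdb)
  # append a water record
  lines <- readLines(pdb)
  end <- grep("^END", lines)[1]
  wat <- "HETATM 9999  O   HOH A 500      50.000  50.000  50.000  1.00  0.00           O"
  writeLines(c(lines[seq_len(end - 1)], wat, lines[end:length(lines)]), pdb)
  cx2 <- read_structure(pdb, "pdb", strip_water = TRUE)
  expect_s3_class(cx2, "plcomplex")
  expect_equal(sort(unique(cx2$receptor$atoms$residue_number)), 919L)
  expect_false(any(cx2$ligand$atoms$residue_name == "HOH"))
  # geometry survives the fixed-column round trip to ~1e-3 Angstrom
  expect_equal(coords(cx2$ligand), coords(cx$ligand), tolerance = 1e-3)
})

test_that("SDF benzene reads as six aromatic carbons with aromatic bonds", {
  sdf <- tempfile(fileext = ".sdf")
  write_sdf(benzene_mol(), sdf)
  mol <- read_structure(sdf, "sdf")
  expect_equal(sum(mol$atoms$element == "C"), 6L)
  expect_true(all(mol$atoms$is_aromatic[mol$atoms$element == "C"]))
  expect_equal(sum(mol$bonds$order == "ar"), 6L)
})

test_that("truncated SDF (no M END) raises a parse error", {
  sdf <- tempfile(fileext = ".sdf")
  writeLines(c("mol", "  test", "", "  1  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0"), sdf)
  expect_error(read_structure(sdf, "sdf"), "M  END")
})

test_that("SMILES without an embedding request is rejected for lack of coordinates", {
  smi <- tempfile(fileext = ".smi")
  writeLines("c1ccccc1", smi)
  expect_error(read_structure(smi, "smiles3d"), "coordinates")
})

test_that("SDF writer round-trips multi-record libraries through ChemmineR", {
  m <- ref_model()
  mols <- list(make_matching_ligand(m, 1, name = "a"),
               make_matching_ligand(m, 2, name = "b"))
  sdf <- tempfile(fileext = ".sdf")
  write_sdf(mols, sdf)
  back <- read_sdf_library(sdf)
  expect_equal(names(back), c("a", "b"))
  expect_equal(coords(back$a), coords(mols[[1]]), tolerance = 1e-3)
  expect_equal(back$b$bonds$order, mols[[2]]$bonds$order)
})

test_that("binding-site extraction uses an inclusive distance boundary", {
  lig <- toy_mol("lig", "C", rbind(c(0, 0, 0)))
  rec <- toy_mol("rec", c("C", "C", "C"),
                 rbind(c(9.5, 0, 0), c(10.5, 0, 0), c(0, 0, 0)),
                 resname = c("LEU", "VAL", "GLY"),
                 resnum = c(1L, 2L, 3L), chain = "A")
  cx <- pl_complex(rec, lig)
  site <- extract_binding_site(cx, radius = 10)
  expect_true(1L %in% site$residues$number)   # 9.5 A in
  expect_false(2L %in% site$residues$number)  # 10.5 A out
  # radius 0 keeps only coincident residues
  site0 <- extract_binding_site(cx, radius = 0)
  expect_equal(site0$residues$number, 3L)
  # boundary exactly at the radius is included
  site_eq <- extract_binding_site(cx, radius = 9.5)
  expect_true(1L %in% site_eq$residues$number)
})

test_that("binding-site extraction demands a ligand", {
  rec <- toy_mol("rec", "C", rbind(c(0, 0, 0)), resname = "GLY",
                 resnum = 1L, chain = "A")
  lig <- toy_mol("lig", "C", rbind(c(1, 0, 0)))
  cx <- pl_complex(rec, lig)
  cx$ligand$atoms <- cx$ligand$atoms[0, ]
  expect_error(extract_binding_site(cx, 10), "ligand")
})

test_that("pharmacophore JSON round-trip is the identity", {
  m <- ref_model()
  path <- tempfile(fileext = ".json")
  write_pharmacophore(m, path)
  m2 <- read_pharmacophore(path)
  expect_equal(feature_kinds(m2), feature_kinds(m))
  for (k in seq_along(m$features)) {
    expect_equal(m2$features[[k]]$centroid, m$features[[k]]$centroid,
                 tolerance = 1e-12)
    expect_equal(m2$features[[k]]$tolerance, m$features[[k]]$tolerance)
  }
  expect_lt(max(abs(m2$distance_matrix - m$distance_matrix)), 1e-9)
  expect_equal(m2$selectivity, m$selectivity, tolerance = 1e-12)
  # projected points survive too
  mp <- pharmacophore_model(list(
    pharmacophore_feature("HBD", c(0, 0, 0), projection = c(0, 0, 2.9)),
    pharmacophore_feature("HBA", c(4, 0, 0), projection = c(4, 0, -2.9)),
    pharmacophore_feature("HyP", c(2, 3, 0))))
  write_pharmacophore(mp, path)
  mp2 <- read_pharmacophore(path)
  expect_equal(mp2$features[[1]]$projection, c(0, 0, 2.9), tolerance = 1e-12)
})

test_that("unknown feature kinds and empty models are rejected", {
  path <- tempfile(fileext = ".json")
  writeLines('{"features": [{"kind": "XYZ", "centroid": [0,0,0], "tolerance": 1.6}]}',
             path)
  expect_error(read_pharmacophore(path), "XYZ")
  expect_error(pharmacophore_model(list()), "features")
  expect_error(write_pharmacophore(structure(list(), class = "list"),
                                   tempfile()))
})

test_that("molecule construction enforces its invariants", {
  expect_error(toy_mol("bad", "C", rbind(c(NA, 0, 0))), "finite")
  expect_error(molecule3d("dup", data.frame(
    serial = c(1, 1), element = "C", x = 0, y = 0, z = c(0, 1))), "unique")
  expect_error(toy_mol("selfbond", c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                       bonds = data.frame(i = 1, j = 1, order = "1")),
               "self-bonds")
  expect_error(toy_mol("badidx", "C", rbind(c(0, 0, 0)),
                       bonds = data.frame(i = 1, j = 5, order = "1")),
               "valid atom indices")
  expect_error(molecule3d("empty", data.frame(serial = integer(0),
                                              element = character(0),
                                              x = numeric(0), y = numeric(0),
                                              z = numeric(0))), "at least one")
})

test_that("pocket definitions validate front/back subsets and defaults", {
  expect_error(pocket_definition(
    residues = data.frame(chain = "A", number = 1, name = "GLY"),
    front = data.frame(chain = "A", number = 2, name = "ALA")),
    "subsets")
  pk <- vegfr2_pocket()
  expect_setequal(pk$front_residues$number, c(917L, 919L))
  expect_setequal(pk$back_residues$number, c(885L, 1046L))
})
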