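test_that("perception applies the documented donor/acceptor/hydrophobe rules", {
  # methanol-like fragment: one HBD and one HBA, both on the oxygen
  fs <- perceive_ligand_features(methanol_mol())
  kinds <- feature_kinds(fs)
  expect_equal(sum(kinds == "HBD"), 1L)
  expect_equal(sum(kinds == "HBA"), 1L)
  o_pos <- c(1.43, 0, 0)
  for (f in fs$features[kinds != "HyP"])
    expect_equal(f$centroid, o_pos, tolerance = 1e-12)

  # benzene: exactly one hydrophobe at the ring centroid
  fs2 <- perceive_ligand_features(benzene_mol(center = c(1, 2, 3)))
  expect_equal(feature_kinds(fs2), "HyP")
  expect_equal(fs2$features[[1]]$centroid, c(1, 2, 3), tolerance = 1e-9)

  # protonated amine: donor yes, acceptor no
  amine <- toy_mol("ammonium", c("N", "H", "H", "H", "C"),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(-0.5, 0.87, 0),
                         c(-0.5, -0.87, 0), c(0, 0, 1.49)),
                   bonds = data.frame(i = c(1, 1, 1, 1), j = 2:5, order = "1"),
                   charge = c(1L, 0L, 0L, 0L, 0L))
  kinds3 <- feature_kinds(perceive_ligand_features(amine))
  expect_true("HBD" %in% kinds3)
  expect_false("HBA" %in% kinds3)
})

test_that("donor perception demands hydrogens unless inference is requested", {
  bare_o <- toy_mol("bare", c("C", "O"), rbind(c(0, 0, 0), c(1.43, 0, 0)),
                    bonds = data.frame(i = 1, j = 2, order = "1"))
  expect_error(perceive_ligand_features(bare_o), "hydrogens")
  fs <- perceive_ligand_features(bare_o, infer_h = TRUE)
  expect_true("HBD" %in% feature_kinds(fs))  # inferred O-H
  # carbon-only molecules need no hydrogens
  expect_silent(perceive_ligand_features(benzene_mol()))
})

test_that("perception is invariant under rigid-body motion", {
  m <- ref_model()
  lig <- make_matching_ligand(m, seed = 31)
  fs <- perceive_ligand_features(lig)
  rng <- kp_rng(99)
  for (rep in 1:5) {
    R <- random_rotation(rng)
    tr <- 10 * rng$norm(3)
    fs2 <- perceive_ligand_features(transform_molecule(lig, R, tr))
    expect_equal(feature_kinds(fs2), feature_kinds(fs))
    for (k in seq_along(fs$features))
      expect_equal(fs2$features[[k]]$centroid,
                   as.numeric(R %*% fs$features[[k]]$centroid + tr),
                   tolerance = 1e-9)
  }
})

test_that("complementary perception images the pocket onto the ligand side", {
  # lone backbone carbonyl facing the ligand -> exactly one HBD with the
  # acceptor as projected point
  lig <- toy_mol("lig", "C", rbind(c(0, 0, 0)))
  rec <- toy_mol("rec", c("O", "C"), rbind(c(4, 0, 0), c(5.23, 0, 0)),
                 resname = "GLY", resnum = 10L, chain = "A")
  rec$atoms$atom_name <- c("O", "C")
  cx <- pl_complex(rec, lig)
  fs <- perceive_complementary_features(cx, extract_binding_site(cx, 10))
  expect_equal(feature_kinds(fs), "HBD")
  expect_equal(fs$features[[1]]$projection, c(4, 0, 0))
  expect_equal(fs$features[[1]]$centroid, c(4 - 2.9, 0, 0), tolerance = 1e-9)

  # pure-glycine pocket: no hydrophobes
  expect_false("HyP" %in% feature_kinds(fs))
})

test_that("a planted kinase-like pocket yields the 2xHBD/2xHyP/1xHBA composition", {
  spec <- complex_spec(list(
    hb_contact(917, "GLU", 2.8, donor_side = "ligand", atom = "O"),
    hb_contact(919, "CYS", 2.9, donor_side = "receptor"),
    hb_contact(885, "GLU", 2.6, donor_side = "ligand"),
    pi_contact("alkyl_alkyl", 889, "LEU", 4.5),
    pi_contact("alkyl_alkyl", 1035, "LEU", 4.8)), seed = 2)
  cx <- make_toy_complex(spec)
  fs <- perceive_complementary_features(cx, extract_binding_site(cx, 10))
  kinds <- feature_kinds(fs)
  # the key composition is achievable as a sub-multiset
  expect_gte(sum(kinds == "HBD"), 2L)
  expect_gte(sum(kinds == "HyP"), 2L)
  expect_gte(sum(kinds == "HBA"), 1L)
})

test_that("model enumeration matches subset-counting combinatorics", {
  feats <- lapply(1:5, function(k)
    pharmacophore_feature(c("HBD", "HBD", "HBA", "HyP", "HyP")[k],
                          c(4 * k, (k %% 2) * 3, 0)))
  fs <- structure(list(owner = "toy", features = feats), class = "feature_set")
  expect_length(enumerate_models(fs, 5, 5), 1L)
  expect_length(enumerate_models(fs, 4, 5), choose(5, 4) + choose(5, 5))
  expect_length(enumerate_models(fs, 3, 5),
                choose(5, 3) + choose(5, 4) + choose(5, 5))
  # brute-force subset count oracle on 7 features
  feats7 <- lapply(1:7, function(k)
    pharmacophore_feature(c("HBD", "HBA", "HyP")[(k %% 3) + 1],
                          c(5 * k, 2.5 * (k %% 3), (k %% 2) * 4)))
  fs7 <- structure(list(owner = "toy7", features = feats7),
                   class = "feature_set")
  cent <- t(vapply(feats7, function(f) f$centroid, numeric(3)))
  dm <- as.matrix(dist(cent))
  count_oracle <- 0L
  for (k in 4:5) for (s in combn(7, k, simplify = FALSE)) {
    sub <- dm[s, s]
    if (all(sub[upper.tri(sub)] >= 2)) count_oracle <- count_oracle + 1L
  }
  expect_length(enumerate_models(fs7, 4, 5), count_oracle)
})

test_that("features closer than the minimum spacing are never co-selected", {
  feats <- list(
    pharmacophore_feature("HBD", c(0, 0, 0)),
    pharmacophore_feature("HBA", c(1, 0, 0)),   # 1 A from the first
    pharmacophore_feature("HyP", c(5, 0, 0)),
    pharmacophore_feature("HyP", c(5, 5, 0)))
  fs <- structure(list(owner = "close", features = feats),
                  class = "feature_set")
  models <- enumerate_models(fs, 3, 4)
  for (m in models) {
    cent <- t(vapply(m$features, function(f) f$centroid, numeric(3)))
    expect_false(all(c("0 0 0", "1 0 0") %in% apply(cent, 1, paste,
                                                    collapse = " ")))
  }
})

test_that("enumeration warns and returns empty below the feature minimum", {
  fs <- structure(list(owner = "tiny", features = list(
    pharmacophore_feature("HBD", c(0, 0, 0)),
    pharmacophore_feature("HBA", c(5, 0, 0)))), class = "feature_set")
  expect_warning(out <- enumerate_models(fs, 3, 5), "fewer")
  expect_length(out, 0L)
})

test_that("selectivity scoring is deterministic, additive and spread-sensitive", {
  m <- ref_model()
  expect_identical(selectivity_score(m), selectivity_score(m))
  # every 5-feature model outranks each of its 4-feature submodels
  for (drop in 1:5) {
    sub <- pharmacophore_model(m$features[-drop])
    expect_gt(m$selectivity, sub$selectivity)
  }
  # wider spread scores higher at equal composition
  tight <- pharmacophore_model(lapply(1:5, function(k)
    pharmacophore_feature(feature_kinds(m)[k],
                          c(2.5 * k, 0, 0))))
  wide <- pharmacophore_model(lapply(1:5, function(k)
    pharmacophore_feature(feature_kinds(m)[k],
                          c(4 * k, 0, 0))))
  expect_gt(wide$selectivity, tight$selectivity)
})

test_that("every 5-feature model outranks every 4-feature model from the same pool", {
  # pocket-scale feature pool mirroring the selected-model composition
  feats <- list(
    pharmacophore_feature("HBD", c(0, 0, 0)),
    pharmacophore_feature("HyP", c(3.5, 1, -0.5)),
    pharmacophore_feature("HyP", c(5.5, -0.8, 1.2)),
    pharmacophore_feature("HBA", c(7.5, -1.5, 1)),
    pharmacophore_feature("HBD", c(9, 1, 0.5)),
    pharmacophore_feature("HBA", c(4.5, -3, -1)))
  fs <- structure(list(owner = "pool", features = feats),
                  class = "feature_set")
  models <- enumerate_models(fs, 4, 5)
  n_feats <- vapply(models, function(m) length(m$features), 0L)
  sel <- vapply(models, function(m) m$selectivity, 0)
  expect_gt(min(sel[n_feats == 5]), max(sel[n_feats == 4]))
  # and the returned ranking is selectivity-descending
  expect_equal(sel, sort(sel, decreasing = TRUE))
})

test_that("feature and model constructors enforce invariants", {
  expect_error(pharmacophore_feature("HyP", c(0, 0, 0),
                                     projection = c(1, 1, 1)), "projection")
  expect_error(pharmacophore_feature("HBD", c(0, 0, 0), tolerance = 0),
               "tolerance")
  two <- list(pharmacophore_feature("HBD", c(0, 0, 0)),
              pharmacophore_feature("HBA", c(4, 0, 0)))
  expect_error(pharmacophore_model(two), "between 3 and 7")
  m <- ref_model()
  dm <- m$distance_matrix
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  # triangle inequality holds for centroid-derived distances
  n <- nrow(dm)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-9)
})
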