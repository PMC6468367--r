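test_that("planted hydrogen bonds are recovered at their exact distances", {
  spec <- complex_spec(list(
    hb_contact(1046, "ASP", 2.9, donor_side = "receptor", measure = "heavy"),
    hb_contact(917, "GLU", 1.9, donor_side = "ligand",
               measure = "hydrogen", atom = "O"),
    hb_contact(885, "GLU", 2.1, donor_side = "ligand",
               measure = "hydrogen")), seed = 8)
  hb <- detect_hbonds(make_toy_complex(spec))
  expect_equal(nrow(hb), 3L)
  expect_true(all(hb$category == "hydrogen_bond"))
  expect_true(all(hb$donor_side != "n/a"))
  expect_true(all(hb$distance > 0))
  d1046 <- hb[hb$residue_number == 1046, ]
  expect_equal(d1046$distance, 2.9, tolerance = 1e-6)
  expect_equal(d1046$donor_side, "receptor")
  # hydrogen-measured contacts report both conventions
  d917 <- hb[hb$residue_number == 917, ]
  expect_equal(d917$h_distance, 1.9, tolerance = 1e-6)
  expect_lt(d917$distance, 3.0)
  d885 <- hb[hb$residue_number == 885, ]
  expect_equal(d885$h_distance, 2.1, tolerance = 1e-6)
  expect_gte(d885$angle, 120)
})

test_that("pairs beyond the heavy-atom cutoff yield no hydrogen bond", {
  near <- make_toy_complex(complex_spec(list(
    hb_contact(1046, "ASP", 2.9, measure = "heavy")), seed = 4))
  expect_equal(nrow(detect_hbonds(near)), 1L)
  far <- make_toy_complex(complex_spec(list(
    hb_contact(1046, "ASP", 3.2, measure = "heavy")), seed = 4))
  expect_equal(nrow(detect_hbonds(far)), 0L)
})

test_that("planted aromatic and hydrophobic contacts classify correctly", {
  cases <- list(
    list(pi_contact("pi_pi_stacked", 1026, "HIS", 4.6), "pi_pi_stacked"),
    list(pi_contact("pi_pi_T", 1047, "PHE", 4.8), "pi_pi_T"),
    list(pi_contact("pi_cation", 868, "LYS", 3.1), "pi_cation"),
    list(pi_contact("pi_sigma", 1035, "LEU", 3.5), "pi_sigma"),
    list(pi_contact("pi_alkyl", 848, "VAL", 5.0), "pi_alkyl"),
    list(pi_contact("sulfur_x", 840, "LEU", 3.2), "sulfur_x"),
    list(pi_contact("alkyl_alkyl", 889, "LEU", 4.9), "alkyl_alkyl"))
  for (cs in cases) {
    cx <- make_toy_complex(complex_spec(list(cs[[1]]), seed = 6))
    rec <- detect_pi_interactions(cx)
    hit <- rec[rec$category == cs[[2]], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$distance, cs[[1]]$distance, tolerance = 1e-6)
    expect_equal(hit$residue_number, cs[[1]]$residue$number)
  }
  # a lone parallel stack is the only record of its complex
  lone <- detect_pi_interactions(make_toy_complex(complex_spec(
    list(pi_contact("pi_pi_stacked", 1026, "HIS", 4.6)), seed = 2)))
  expect_equal(nrow(lone), 1L)
  expect_equal(lone$category, "pi_pi_stacked")
  expect_equal(lone$angle, 0, tolerance = 1e-6)
})

test_that("detectors are invariant under rigid-body motion of the complex", {
  spec <- complex_spec(list(
    hb_contact(919, "CYS", 2.9),
    pi_contact("pi_pi_stacked", 1026, "HIS", 4.6),
    pi_contact("pi_alkyl", 848, "VAL", 4.6)), seed = 9)
  cx <- make_toy_complex(spec)
  base_hb <- detect_hbonds(cx)
  base_pi <- detect_pi_interactions(cx)
  rng <- kp_rng(123)
  for (k in 1:5) {
    cxT <- transform_complex(cx, random_rotation(rng), 15 * rng$norm(3))
    hbT <- detect_hbonds(cxT)
    piT <- detect_pi_interactions(cxT)
    expect_equal(hbT$distance, base_hb$distance, tolerance = 1e-9)
    expect_equal(sort(piT$category), sort(base_pi$category))
    expect_equal(piT$distance[order(piT$category)],
                 base_pi$distance[order(base_pi$category)], tolerance = 1e-9)
  }
})

test_that("van der Waals contacts respect the cutoff and the exclusivity rule", {
  cx <- make_toy_complex(complex_spec(list(
    pi_contact("vdw_contact", 922, "GLY", 3.8),
    pi_contact("vdw_contact", 920, "LYS", 4.5),
    hb_contact(919, "CYS", 2.9)), seed = 3))
  hb <- detect_hbonds(cx)
  vdw <- detect_vdw_contacts(cx, exclude = hb)
  expect_true(922L %in% vdw$number)            # inside 4 A
  expect_false(920L %in% vdw$number)           # 4.5 A is out
  expect_false(919L %in% vdw$number)           # already hydrogen-bonded
  expect_equal(vdw$min_distance[vdw$number == 922L], 3.8, tolerance = 1e-6)
  # without the exclusion the H-bonded residue appears
  vdw_all <- detect_vdw_contacts(cx)
  expect_true(919L %in% vdw_all$number)
})

test_that("category assignment is exclusive per pair with documented precedence", {
  cx <- make_toy_complex(complex_spec(list(
    hb_contact(919, "CYS", 2.9),
    pi_contact("pi_pi_stacked", 1026, "HIS", 4.6)), seed = 13))
  row <- interaction_table(cx)
  recs <- rbind(row$hbonds, row$pi)
  key <- paste(recs$receptor_atom, recs$ligand_atom)
  expect_false(anyDuplicated(key) > 0)
  # residues carrying records never reappear in the vdW column
  expect_false(any(paste(row$vdw$number, row$vdw$name) %in%
                     paste(recs$residue_number, recs$residue_name)))
})

test_that("back-to-front verdict follows the front/back truth table", {
  mk_rec <- function(numbers, names) {
    do.call(rbind, lapply(seq_along(numbers), function(k) {
      data.frame(category = "hydrogen_bond", chain = "A",
                 residue_number = numbers[k], residue_name = names[k],
                 receptor_atom = "x", ligand_atom = "y", distance = 2.5,
                 h_distance = NA_real_, angle = NA_real_,
                 donor_side = "receptor", stringsAsFactors = FALSE)
    }))
  }
  front <- list(c(917L, "GLU"), c(919L, "CYS"))
  back <- list(c(885L, "GLU"), c(1046L, "ASP"))
  for (fmask in 0:3) for (bmask in 0:3) {
    sel_f <- front[which(bitwAnd(fmask, 1:2) > 0)]
    sel_b <- back[which(bitwAnd(bmask, 1:2) > 0)]
    sel <- c(sel_f, sel_b)
    recs <- if (length(sel))
      mk_rec(as.integer(vapply(sel, `[`, "", 1)),
             vapply(sel, `[`, "", 2))
    else mk_rec(integer(0), character(0))
    if (is.null(recs)) recs <- mk_rec(123L, "GLY")[0, ]
    v <- classify_type2(recs)
    expect_identical(v$is_back_to_front,
                     length(sel_f) > 0 && length(sel_b) > 0)
    expect_equal(nrow(v$front_hbonds), length(sel_f))
    expect_equal(nrow(v$back_hbonds), length(sel_b))
  }
  expect_error(classify_type2(mk_rec(919L, "CYS"),
                              pocket_definition(radius = 10)),
               "front and back")
})

test_that("an apolar ligand in a polar pocket gives no hydrogen bonds", {
  cx <- make_toy_complex(complex_spec(list(
    pi_contact("pi_alkyl", 848, "VAL", 4.6)), seed = 21))
  expect_equal(nrow(detect_hbonds(cx)), 0L)
  row <- interaction_table(cx)
  expect_false(row$verdict$is_back_to_front)
  expect_equal(as.data.frame(row)$n_hbonds, 0L)
})

test_that("a full planted pose reproduces its three-column interaction row", {
  spec <- complex_spec(list(
    hb_contact(885, "GLU", 2.1, donor_side = "ligand", measure = "hydrogen"),
    hb_contact(917, "GLU", 1.9, donor_side = "ligand",
               measure = "hydrogen", atom = "O"),
    hb_contact(919, "CYS", 1.9, donor_side = "receptor",
               measure = "hydrogen"),
    hb_contact(1046, "ASP", 2.0, donor_side = "ligand",
               measure = "hydrogen", atom = "O"),
    pi_contact("pi_alkyl", 840, "LEU", 4.8),
    pi_contact("pi_alkyl", 848, "VAL", 4.2),
    pi_contact("vdw_contact", 888, "ILE", 3.8),
    pi_contact("vdw_contact", 892, "ILE", 3.6),
    pi_contact("vdw_contact", 899, "VAL", 3.9)), seed = 11)
  row <- interaction_table(make_toy_complex(spec))
  tab <- as.data.frame(row)
  expect_equal(tab$n_hbonds, 4L)
  expect_equal(tab$n_pi, 2L)
  expect_equal(tab$n_vdw, 3L)
  expect_true(tab$back_to_front)
  # H-distance reporting style mirrors the conventional table format
  expect_match(tab$hydrogen_bonds, "Glu885:OE2-.* \\(2\\.1\\)")
  expect_match(tab$hydrogen_bonds, "Cys919:N-.* \\(1\\.9\\)")
})

test_that("every reported contact distance lies inside its category window", {
  co <- interaction_cutoffs()
  # distances printed for the reference pose and the seven hit poses
  printed <- list(
    hydrogen_bond = c(2.6, 2.8, 2.9, 2.9, 2.1, 1.9, 1.9, 2.0, 1.9, 1.8,
                      1.9, 1.9, 2.1, 2.8, 2.1, 2.8, 2.1, 2.6, 2.6, 2.6,
                      2.0, 2.2, 2.4, 2.9, 1.9, 1.9, 2.5, 2.2),
    pi_alkyl = c(5.0, 5.4, 4.3, 4.6, 4.8, 3.6, 4.4, 4.8, 5.0, 4.2, 4.9,
                 4.1, 5.1, 4.9, 4.2, 5.1, 4.8, 4.8, 5.1, 4.2, 5.3, 4.9,
                 4.4, 5.4, 4.3, 4.6, 5.3, 4.2, 4.3, 5.2),
    pi_cation = c(4.3, 3.1, 3.5),
    pi_sigma = c(3.5, 3.5, 3.7, 2.7, 2.6, 2.8),
    pi_pi_stacked = c(5.1, 4.6),
    pi_pi_T = c(4.8),
    sulfur_x = c(3.2),
    alkyl_alkyl = c(4.9, 4.5))
  window <- c(hydrogen_bond = co$hbond_heavy, pi_alkyl = co$pi_alkyl,
              pi_cation = co$pi_cation, pi_sigma = co$pi_sigma,
              pi_pi_stacked = co$pi_pi_stacked, pi_pi_T = co$pi_pi_T,
              sulfur_x = co$sulfur_x, alkyl_alkyl = co$alkyl_alkyl)
  for (cat in names(printed)) {
    expect_true(all(printed[[cat]] <= window[[cat]]),
                info = paste("window violated for", cat))
    expect_true(all(printed[[cat]] > 0))
  }
})
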