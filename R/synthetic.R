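# orthonormal basis completing a unit vector u
.orthobasis <- function(u) {
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w1 <- ref - sum(ref * u) * u
  w1 <- w1 / sqrt(sum(w1^2))
  list(u = u, w1 = w1, w2 = c(u[2] * w1[3] - u[3] * w1[2],
                              u[3] * w1[1] - u[1] * w1[3],
                              u[1] * w1[2] - u[2] * w1[1]))
}

.unit3 <- function(rng) {
  repeat {
    v <- rng$norm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# --- chemical group builders -------------------------------------------
# each returns list(atoms = data.frame(element, x, y, z, formal_charge,
# is_aromatic), bonds = data.frame(i, j, order)) with local indices

.grp_atoms <- function(el, xyz, charge = 0L, aromatic = FALSE) {
  data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             formal_charge = charge, is_aromatic = aromatic,
             stringsAsFactors = FALSE)
}

# methyl hydrogens on carbon at `c_pos`, bond direction to parent `n`
.methyl_h <- function(c_pos, n, basis) {
  t(vapply(0:2, function(k) {
    th <- 2 * pi * k / 3
    d <- -n / 3 + sqrt(8) / 3 * (cos(th) * basis$w1 + sin(th) * basis$w2)
    c_pos + 1.09 * d / sqrt(sum(d^2))
  }, numeric(3)))
}

# hydroxymethyl: HBD (and incidental HBA) at the oxygen, placed at `t`
.grp_hydroxyl <- function(t, u) {
  b <- .orthobasis(u)
  o <- t
  ho <- t + 0.96 * b$u
  c_ <- t - 1.43 * b$u
  hs <- .methyl_h(c_, b$u, b)
  atoms <- .grp_atoms(c("O", "H", "C", "H", "H", "H"),
                      rbind(o, ho, c_, hs))
  bonds <- data.frame(i = c(1L, 1L, 3L, 3L, 3L), j = c(2L, 3L, 4L, 5L, 6L),
                      order = "1", stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = bonds)
}

# dimethyl ether: pure HBA at the oxygen placed at `t`, methyls on the
# side away from `u`
.grp_ether <- function(t, u) {
  b <- .orthobasis(u)
  half <- 55.5 * pi / 180
  e1 <- -cos(half) * b$u + sin(half) * b$w1
  e2 <- -cos(half) * b$u - sin(half) * b$w1
  c1 <- t + 1.43 * e1
  c2 <- t + 1.43 * e2
  h1 <- .methyl_h(c1, -e1, .orthobasis(e1))
  h2 <- .methyl_h(c2, -e2, .orthobasis(e2))
  atoms <- .grp_atoms(c("O", "C", "C", rep("H", 6)), rbind(t, c1, c2, h1, h2))
  bonds <- data.frame(i = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
                      j = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
                      order = "1", stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = bonds)
}

# benzene ring: HyP at the centroid `t`, ring plane normal to `n`
.grp_benzene <- function(t, n) {
  b <- .orthobasis(n)
  th <- 2 * pi * (0:5) / 6
  cpos <- t(vapply(th, function(a) t + 1.39 * (cos(a) * b$w1 + sin(a) * b$w2),
                   numeric(3)))
  hpos <- t(vapply(th, function(a) t + 2.47 * (cos(a) * b$w1 + sin(a) * b$w2),
                   numeric(3)))
  atoms <- .grp_atoms(c(rep("C", 6), rep("H", 6)), rbind(cpos, hpos),
                      aromatic = c(rep(TRUE, 6), rep(FALSE, 6)))
  bonds <- rbind(
    data.frame(i = 1:6, j = c(2:6, 1L), order = "ar", stringsAsFactors = FALSE),
    data.frame(i = 1:6, j = 7:12, order = "1", stringsAsFactors = FALSE))
  list(atoms = atoms, bonds = bonds)
}

# methylammonium: HBD without any acceptor character (N positively
# charged), used by kind-violation decoys
.grp_ammonium <- function(t, u) {
  b <- .orthobasis(u)
  hs <- t(vapply(0:2, function(k) {
    th <- 2 * pi * k / 3
    d <- b$u / 3 + sqrt(8) / 3 * (cos(th) * b$w1 + sin(th) * b$w2)
    t + 1.02 * d / sqrt(sum(d^2))
  }, numeric(3)))
  c_ <- t - 1.49 * b$u
  hc <- .methyl_h(c_, b$u, b)
  atoms <- .grp_atoms(c("N", "H", "H", "H", "C", "H", "H", "H"),
                      rbind(t, hs, c_, hc),
                      charge = c(1L, rep(0L, 7)))
  bonds <- data.frame(i = c(1L, 1L, 1L, 1L, 5L, 5L, 5L),
                      j = c(2L, 3L, 4L, 5L, 6L, 7L, 8L),
                      order = "1", stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = bonds)
}

# isobutane-like aliphatic cluster: HyP-capable carbon cluster at `t`
.grp_alkyl <- function(t, u) {
  b <- .orthobasis(u)
  dirs <- t(vapply(0:2, function(k) {
    th <- 2 * pi * k / 3
    d <- -b$u / 3 + sqrt(8) / 3 * (cos(th) * b$w1 + sin(th) * b$w2)
    d / sqrt(sum(d^2))
  }, numeric(3)))
  cs <- sweep(1.53 * dirs, 2, t, "+")
  atoms <- .grp_atoms(c("C", "C", "C", "C", "H"),
                      rbind(t, cs, t + 1.09 * b$u))
  bonds <- data.frame(i = c(1L, 1L, 1L, 1L), j = c(2L, 3L, 4L, 5L),
                      order = "1", stringsAsFactors = FALSE)
  # give each substituent carbon three hydrogens for complete valence
  for (k in 1:3) {
    hb <- .methyl_h(cs[k, ], -dirs[k, ], .orthobasis(dirs[k, ]))
    base <- nrow(atoms)
    atoms <- rbind(atoms, .grp_atoms(rep("H", 3), hb))
    bonds <- rbind(bonds, data.frame(i = k + 1L, j = base + 1:3,
                                     order = "1", stringsAsFactors = FALSE))
  }
  list(atoms = atoms, bonds = bonds)
}

.assemble_mol <- function(name, groups, residue = NULL) {
  atoms <- NULL; bonds <- NULL; offset <- 0L
  for (g in groups) {
    b <- g$bonds
    if (nrow(b)) { b$i <- b$i + offset; b$j <- b$j + offset }
    atoms <- rbind(atoms, g$atoms)
    bonds <- rbind(bonds, b)
    offset <- nrow(atoms)
  }
  atoms$serial <- seq_len(nrow(atoms))
  if (!is.null(residue)) {
    atoms$residue_name <- residue$name
    atoms$residue_number <- residue$number
    atoms$chain_id <- residue$chain
  }
  molecule3d(name, atoms, bonds)
}

.group_for_kind <- function(kind, t, u) {
  switch(kind,
         HBD = .grp_hydroxyl(t, u),
         HBA = .grp_ether(t, u),
         HyP = .grp_benzene(t, u))
}

#' Generate a ligand that matches a pharmacophore model by construction
#'
#' Places one valence-complete chemical group per model feature — a
#' hydroxymethyl for HBD, a dimethyl ether for HBA, a benzene ring for
#' HyP — so that the perceived feature centroid falls exactly on the
#' model centroid. With `jitter > 0` each group is displaced by a random
#' vector of length at most `jitter` (so the post-hoc superposition RMSD
#' is bounded by `jitter`), drawn from the package's own deterministic
#' stream: the output is a pure function of `(model, seed, jitter)`.
#'
#' @param model a `pharmacophore_model` (at most 7 features).
#' @param seed integer seed.
#' @param jitter nonnegative displacement bound in Angstrom.
#' @param name molecule name.
#' @return a `molecule3d`.
#' @export
make_matching_ligand <- function(model, seed, jitter = 0,
                                 name = paste0("synlig", seed)) {
  stopifnot(inherits(model, "pharmacophore_model"), jitter >= 0)
  if (length(model$features) > 7L)
    stop("models with more than 7 features are unsupported")
  rng <- kp_rng(seed)
  groups <- lapply(model$features, function(f) {
    u <- .unit3(rng)
    t <- f$centroid
    if (jitter > 0) t <- t + jitter * rng$unif(1) * .unit3(rng)
    .group_for_kind(f$kind, t, u)
  })
  .assemble_mol(name, groups)
}

#' Generate a ligand guaranteed not to match a model
#'
#' Two violation modes. `"distance"` keeps one group per feature but
#' dilates all group positions about their mean so that every pairwise
#' distance exceeds every model distance window by more than 3 Angstrom
#' beyond the combined tolerances — no injective assignment can be
#' feasible. `"kind"` removes one feature kind entirely (HBA when the
#' model has one, else HBD, else HyP); donors are built as protonated
#' methylammonium groups so no incidental acceptor survives.
#'
#' @inheritParams make_matching_ligand
#' @param violation `"distance"` or `"kind"`.
#' @return a `molecule3d` for which [map_ligand()] returns
#'   `matched = FALSE`.
#' @export
make_decoy_ligand <- function(model, seed, violation = c("distance", "kind"),
                              name = paste0("decoy", seed)) {
  stopifnot(inherits(model, "pharmacophore_model"))
  violation <- match.arg(violation)
  rng <- kp_rng(seed)
  cent <- t(vapply(model$features, function(f) f$centroid, numeric(3)))
  kinds <- feature_kinds(model)
  if (violation == "distance") {
    dm <- model$distance_matrix
    d <- dm[upper.tri(dm)]
    tol <- vapply(model$features, function(f) f$tolerance, 0)
    k <- (max(d) + 2 * max(tol) + 3.001) / min(d)
    mid <- colMeans(cent)
    cent <- sweep(k * sweep(cent, 2, mid), 2, mid, "+")
    groups <- lapply(seq_along(kinds), function(i)
      .group_for_kind(kinds[i], cent[i, ], .unit3(rng)))
  } else {
    drop <- if ("HBA" %in% kinds) "HBA" else if ("HBD" %in% kinds) "HBD" else "HyP"
    keep <- which(kinds != drop)
    if (!length(keep)) {
      groups <- list(.grp_ether(cent[1, ], .unit3(rng)))
    } else {
      groups <- lapply(keep, function(i) {
        u <- .unit3(rng)
        if (kinds[i] == "HBD") .grp_ammonium(cent[i, ], u)
        else .group_for_kind(kinds[i], cent[i, ], u)
      })
    }
  }
  .assemble_mol(name, groups)
}

#' Specification for a planted screening library
#'
#' @param D library size; @param A number of actives; `planted_Ht` /
#'   `planted_Ha` the hit counts a screen of the generated library must
#'   produce; `seed` the generator seed.
#' @param A,planted_Ht,planted_Ha,seed see above.
#' @return object of class `library_spec`.
#' @export
library_spec <- function(D, A, planted_Ht, planted_Ha, seed = 1L) {
  v <- c(D = D, A = A, Ht = planted_Ht, Ha = planted_Ha)
  if (any(v < 0) || any(v != round(v)))
    stop("library spec counts must be nonnegative integers")
  if (A > D) stop("infeasible spec: A > D")
  if (planted_Ht > D) stop("infeasible spec: planted_Ht > D")
  if (planted_Ha > planted_Ht) stop("infeasible spec: planted_Ha > planted_Ht")
  if (planted_Ha > A) stop("infeasible spec: planted_Ha > A")
  if (planted_Ht - planted_Ha > D - A)
    stop("infeasible spec: more inactive hits than inactives")
  structure(list(D = as.integer(D), A = as.integer(A),
                 planted_Ht = as.integer(planted_Ht),
                 planted_Ha = as.integer(planted_Ha),
                 seed = as.integer(seed)),
            class = "library_spec")
}

#' Generate a labelled library with planted confusion counts
#'
#' Builds `planted_Ha` actives and `planted_Ht - planted_Ha` inactives as
#' matching ligands (jittered within tolerance), and the remaining
#' `A - planted_Ha` actives and the rest of the inactives as guaranteed
#' decoys, then shuffles the record order with the seeded stream.
#' Screening the library against `model` under default tolerances yields
#' exactly the planted counts.
#'
#' @param model a `pharmacophore_model`.
#' @param spec a [library_spec()].
#' @param jitter coordinate jitter for the matching ligands (Angstrom);
#'   small enough that matching is preserved.
#' @return a labelled `screening_library`.
#' @export
make_library <- function(model, spec, jitter = 0.15) {
  stopifnot(inherits(model, "pharmacophore_model"),
            inherits(spec, "library_spec"))
  rng <- kp_rng(spec$seed)
  n <- spec$D
  sub_seed <- function(k) (as.numeric(spec$seed) * 10007 + 7919 * k) %% 2147483629 + 1
  roles <- c(rep("match_active", spec$planted_Ha),
             rep("match_inactive", spec$planted_Ht - spec$planted_Ha),
             rep("decoy_active", spec$A - spec$planted_Ha),
             rep("decoy_inactive", spec$D - spec$A -
                   (spec$planted_Ht - spec$planted_Ha)))
  mols <- vector("list", n)
  labels <- logical(n)
  for (k in seq_len(n)) {
    nm <- sprintf("mol%04d", k)
    mols[[k]] <- switch(roles[k],
      match_active = ,
      match_inactive = make_matching_ligand(model, sub_seed(k),
                                            jitter = jitter, name = nm),
      decoy_active = ,
      decoy_inactive = make_decoy_ligand(
        model, sub_seed(k),
        violation = if (k %% 2L == 0L) "distance" else "kind", name = nm))
    labels[k] <- roles[k] %in% c("match_active", "decoy_active")
  }
  ord <- rng$perm(n)
  screening_library(mols[ord], labels[ord])
}

# --- planted-contact complexes -----------------------------------------

#' Specification for a planted-contact complex
#'
#' @param contacts list of contacts; each a list with `category` (an
#'   interaction class), `residue` (list with `chain`, `number`, `name`),
#'   `distance` (Angstrom), and for hydrogen bonds optionally
#'   `donor_side` (`"receptor"` or `"ligand"`, default `"receptor"`) and
#'   `measure` (`"heavy"` or `"hydrogen"`; default heavy for distances >=
#'   2.5, hydrogen below).
#' @param seed integer seed.
#' @param ligand_name name stamped on the generated ligand.
#' @return object of class `complex_spec`.
#' @export
complex_spec <- function(contacts, seed = 1L, ligand_name = "PLNT") {
  ok_cat <- c("hydrogen_bond", "pi_pi_stacked", "pi_pi_T", "pi_cation",
              "pi_sigma", "pi_alkyl", "alkyl_alkyl", "sulfur_x",
              "vdw_contact")
  contacts <- lapply(seq_along(contacts), function(k) {
    ct <- contacts[[k]]
    if (is.null(ct$category) || !ct$category %in% ok_cat)
      stop("contact ", k, ": unknown category '", ct$category, "'")
    if (is.null(ct$distance) || ct$distance <= 0)
      stop("contact ", k, ": distance must be positive")
    if (is.null(ct$residue))
      ct$residue <- list(chain = "A", number = 100L + k, name = "LEU")
    ct$residue$number <- as.integer(ct$residue$number)
    ct$residue$name <- toupper(ct$residue$name)
    if (is.null(ct$donor_side)) ct$donor_side <- "receptor"
    if (is.null(ct$measure))
      ct$measure <- if (ct$distance >= 2.5) "heavy" else "hydrogen"
    ct
  })
  structure(list(contacts = contacts, seed = as.integer(seed),
                 ligand_name = ligand_name), class = "complex_spec")
}

# receptor fragment helpers; all take the contact anchor (ligand-side
# point), the outward unit vector u and in-plane vectors, and return the
# fragment with PDB-style atom names
.res_fragment <- function(els, names_, xyz, res, charge = 0L,
                          aromatic = FALSE, bonds = NULL) {
  at <- .grp_atoms(els, xyz, charge = charge, aromatic = aromatic)
  at$atom_name <- names_
  list(atoms = at, bonds = if (is.null(bonds))
    data.frame(i = integer(0), j = integer(0), order = character(0))
    else bonds, residue = res)
}

.assemble_receptor <- function(frags) {
  atoms <- NULL; bonds <- NULL; offset <- 0L
  for (f in frags) {
    a <- f$atoms
    a$residue_name <- f$residue$name
    a$residue_number <- f$residue$number
    a$chain_id <- f$residue$chain
    b <- f$bonds
    if (nrow(b)) { b$i <- b$i + offset; b$j <- b$j + offset }
    atoms <- rbind(atoms, a)
    bonds <- rbind(bonds, b)
    offset <- nrow(atoms)
  }
  atoms$serial <- seq_len(nrow(atoms))
  molecule3d("pocket", atoms, bonds)
}

#' Generate a mini protein-ligand complex with planted contacts
#'
#' Builds a toy pocket of amino-acid fragments around a multi-group
#' ligand so that every requested contact realises its planted distance
#' exactly (to floating-point precision). Contacts are laid out in
#' separate angular sectors on a 10 Angstrom circle so they cannot
#' cross-talk under the default detection cutoffs.
#'
#' @param spec a [complex_spec()].
#' @return a `plcomplex`.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "complex_spec"))
  contacts <- spec$contacts
  n <- length(contacts)
  if (n > 12L) stop("geometrically infeasible spec: more than 12 contacts")
  for (ct in contacts)
    if (ct$distance > 8) stop("geometrically infeasible spec: planted ",
                              "distance ", ct$distance, " exceeds 8 Angstrom")
  rng <- kp_rng(spec$seed)
  R <- 10
  lig_groups <- list()
  rec_frags <- list()
  nsec <- max(n, 3L)
  for (k in seq_len(max(n, 0L))) {
    ct <- contacts[[k]]
    phi <- 2 * pi * (k - 1) / nsec
    u <- c(cos(phi), sin(phi), 0)
    b <- .orthobasis(u)   # b$w1, b$w2 span the plane normal to u
    anchor <- R * u
    d <- ct$distance
    res <- ct$residue
    add_lig <- function(g) lig_groups[[length(lig_groups) + 1L]] <<- g
    add_rec <- function(f) rec_frags[[length(rec_frags) + 1L]] <<- f
    if (ct$category == "hydrogen_bond") {
      if (ct$measure == "hydrogen" && d > 2.2)
        stop("geometrically infeasible spec: hydrogen-measured H-bond ",
             "distance ", d, " cannot satisfy the <3 Angstrom heavy-atom ",
             "and >=120 degree angle criteria")
      if (ct$donor_side == "receptor") {
        # ligand ether acceptor at the anchor; receptor N-H donor outward
        add_lig(.grp_ether(anchor, u))
        if (ct$measure == "heavy") {
          npos <- anchor + d * u
          hpos <- npos - 1.0 * u
        } else if (d + 1.0 < 2.95) {
          # collinear N-H...A: heavy-atom distance d + 1 stays below 3
          npos <- anchor + (d + 1.0) * u
          hpos <- anchor + d * u
        } else {
          # bend: |N - A| = 2.9, |H - A| = d, |N - H| = 1
          x <- (d^2 + 2.9^2 - 1) / (2 * 2.9)
          y <- sqrt(max(0, d^2 - x^2))
          npos <- anchor + 2.9 * u
          hpos <- anchor + x * u + y * b$w1
        }
        ca <- npos + 1.47 * u
        add_rec(.res_fragment(c("N", "H", "C"), c("N", "HN", "CA"),
                              rbind(npos, hpos, ca), res,
                              bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L),
                                                 order = "1",
                                                 stringsAsFactors = FALSE)))
      } else {
        # ligand hydroxyl donor at the anchor; receptor acceptor outward
        add_lig(.grp_hydroxyl(anchor, u))
        hpos <- anchor + 0.96 * u
        if (ct$measure == "heavy") {
          apos <- anchor + d * u
        } else if (0.96 + d < 2.999) {
          # collinear O-H...A keeps the heavy-atom distance below 3
          apos <- anchor + (0.96 + d) * u
        } else {
          # bend the bond: |A - O| = 2.9, |A - H| = d, O at anchor,
          # H at anchor + 0.96 u
          xa <- (2.9^2 - d^2 + 0.96^2) / (2 * 0.96)
          ya <- sqrt(max(0, 2.9^2 - xa^2))
          apos <- anchor + xa * u + ya * b$w1
        }
        if (res$name %in% c("GLU", "ASP") &&
            !(identical(ct$atom, "O"))) {
          pre <- if (res$name == "GLU") "OE" else "OD"
          cd <- apos + 1.25 * u
          o1 <- cd + 1.25 * b$w1
          add_rec(.res_fragment(c("O", "C", "O"),
                                c(paste0(pre, "2"),
                                  if (res$name == "GLU") "CD" else "CG",
                                  paste0(pre, "1")),
                                rbind(apos, cd, o1), res))
        } else {
          cpos <- apos + 1.23 * u
          add_rec(.res_fragment(c("O", "C"), c("O", "C"),
                                rbind(apos, cpos), res))
        }
      }
    } else if (ct$category %in% c("pi_pi_stacked", "pi_pi_T")) {
      add_lig(.grp_benzene(anchor, u))
      cen <- anchor + d * u
      normal <- if (ct$category == "pi_pi_stacked") u else b$w1
      rb <- .orthobasis(normal)
      ring_n <- if (res$name == "HIS") 5L else 6L
      rad <- if (ring_n == 5L) 1.17 else 1.39
      th <- 2 * pi * (seq_len(ring_n) - 1) / ring_n
      rpos <- t(vapply(th, function(a)
        cen + rad * (cos(a) * rb$w1 + sin(a) * rb$w2), numeric(3)))
      nm <- if (ring_n == 5L) c("CG", "ND1", "CE1", "NE2", "CD2")
            else c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      el <- ifelse(startsWith(nm, "N"), "N", "C")
      rb_bonds <- data.frame(i = seq_len(ring_n),
                             j = c(seq_len(ring_n)[-1], 1L),
                             order = "ar", stringsAsFactors = FALSE)
      add_rec(.res_fragment(el, nm, rpos, res, aromatic = TRUE,
                            bonds = rb_bonds))
    } else if (ct$category == "pi_cation") {
      add_lig(.grp_benzene(anchor, u))
      npos <- anchor + d * u
      add_rec(.res_fragment(c("N", "C"), c("NZ", "CE"),
                            rbind(npos, npos + 1.49 * u), res,
                            charge = c(1L, 0L)))
    } else if (ct$category == "pi_sigma") {
      add_lig(.grp_benzene(anchor, u))
      cpos <- anchor + d * u
      hpos <- cpos - 1.09 * u
      cg <- cpos + 1.52 * u
      cd2 <- cg + 1.52 * b$w1
      add_rec(.res_fragment(c("C", "H", "C", "C"),
                            c("CD1", "HD1", "CG", "CD2"),
                            rbind(cpos, hpos, cg, cd2), res,
                            bonds = data.frame(i = c(1L, 1L, 3L),
                                               j = c(2L, 3L, 4L),
                                               order = "1",
                                               stringsAsFactors = FALSE)))
    } else if (ct$category == "pi_alkyl") {
      if (d <= 4.0)
        stop("geometrically infeasible spec: pi_alkyl below the pi_sigma ",
             "window would need a C-H aimed at the ring; use pi_sigma")
      add_lig(.grp_benzene(anchor, u))
      cpos <- anchor + d * u
      cg <- cpos + 1.52 * u
      cd2 <- cg + 1.52 * b$w1
      add_rec(.res_fragment(c("C", "C", "C"), c("CD1", "CG", "CD2"),
                            rbind(cpos, cg, cd2), res,
                            bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L),
                                               order = "1",
                                               stringsAsFactors = FALSE)))
    } else if (ct$category == "alkyl_alkyl") {
      g <- .grp_alkyl(anchor, u)
      add_lig(g)
      cpos <- anchor + d * u
      cg <- cpos + 1.52 * u
      cd2 <- cg + 1.52 * b$w1
      add_rec(.res_fragment(c("C", "C", "C"), c("CD1", "CG", "CD2"),
                            rbind(cpos, cg, cd2), res,
                            bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L),
                                               order = "1",
                                               stringsAsFactors = FALSE)))
    } else if (ct$category == "sulfur_x") {
      # ligand thioether sulfur at the anchor, partner carbon outward
      b2 <- .orthobasis(u)
      c1 <- anchor - 1.81 * (0.5 * u + 0.866 * b2$w1)
      c2 <- anchor - 1.81 * (0.5 * u - 0.866 * b2$w1)
      at <- .grp_atoms(c("S", "C", "C"), rbind(anchor, c1, c2))
      add_lig(list(atoms = at,
                   bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L),
                                      order = "1", stringsAsFactors = FALSE)))
      add_rec(.res_fragment("C", "CB", rbind(anchor + d * u), res))
    } else if (ct$category == "vdw_contact") {
      at <- .grp_atoms(c("C", "H", "H", "H", "H"),
                       rbind(anchor,
                             .methyl_h(anchor, u, .orthobasis(u)),
                             anchor + 1.09 * u))
      add_lig(list(atoms = at,
                   bonds = data.frame(i = rep(1L, 4), j = 2:5, order = "1",
                                      stringsAsFactors = FALSE)))
      add_rec(.res_fragment("C", "CB", rbind(anchor + d * u), res))
    }
  }
  if (!length(lig_groups)) {
    # contact-free complex: a bare methane ligand and one distant glycine
    lig_groups <- list(list(
      atoms = .grp_atoms(c("C", "H", "H", "H", "H"),
                         rbind(c(0, 0, 0), .methyl_h(c(0, 0, 0), c(0, 0, 1),
                                                     .orthobasis(c(0, 0, 1))),
                               c(0, 0, 1.09))),
      bonds = data.frame(i = rep(1L, 4), j = 2:5, order = "1",
                         stringsAsFactors = FALSE)))
    rec_frags <- list(.res_fragment(c("N", "C", "C", "O"),
                                    c("N", "CA", "C", "O"),
                                    rbind(c(20, 0, 0), c(21.5, 0, 0),
                                          c(22.5, 1, 0), c(23.7, 1, 0)),
                                    list(chain = "A", number = 1L,
                                         name = "GLY")))
  }
  pl_complex(receptor = .assemble_receptor(rec_frags),
             ligand = .assemble_mol(spec$ligand_name, lig_groups))
}
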