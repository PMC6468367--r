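# default geometric windows for contact classification (Angstrom /
# degrees). Chosen to bracket the distance ranges conventionally reported
# for each class (pi-alkyl ~3.6-5.4, pi-cation ~3.1-4.3, pi-pi stacked
# ~4.6-5.1, pi-pi T ~4.8, pi-sigma ~2.6-3.7, sulfur-X ~3.2); all
# overridable per call.
.default_cutoffs <- list(
  hbond_heavy = 3.0, hbond_angle = 120,
  pi_pi_stacked = 5.5, pi_pi_stacked_angle = 30,
  pi_pi_T = 6.0, pi_pi_T_angle = c(60, 120),
  pi_cation = 6.0, pi_sigma = 4.0, pi_alkyl = 5.5,
  alkyl_alkyl = 5.5, sulfur_x = 3.6, vdw = 4.0)

#' Default interaction-geometry cutoffs
#' @return named list of distance (Angstrom) and angle (degrees) windows.
#' @export
interaction_cutoffs <- function() .default_cutoffs

.res_title <- function(name, number) {
  paste0(substr(toupper(name), 1, 1),
         tolower(substr(name, 2, nchar(name))), number)
}

.atom_label <- function(mol, i) {
  a <- mol$atoms
  if (!is.null(a$atom_name) && !is.na(a$atom_name[i]) && nzchar(a$atom_name[i]))
    a$atom_name[i]
  else paste0(a$element[i], a$serial[i])
}

.empty_records <- function() {
  data.frame(category = character(0), chain = character(0),
             residue_number = integer(0), residue_name = character(0),
             receptor_atom = character(0), ligand_atom = character(0),
             distance = numeric(0), h_distance = numeric(0),
             angle = numeric(0), donor_side = character(0),
             stringsAsFactors = FALSE)
}

.record <- function(category, rec_mol, rec_i, lig_label, distance,
                    h_distance = NA_real_, angle = NA_real_,
                    donor_side = "n/a", rec_label = NULL) {
  a <- rec_mol$atoms
  data.frame(category = category, chain = a$chain_id[rec_i],
             residue_number = a$residue_number[rec_i],
             residue_name = a$residue_name[rec_i],
             receptor_atom = if (is.null(rec_label))
               paste0(.res_title(a$residue_name[rec_i], a$residue_number[rec_i]),
                      ":", .atom_label(rec_mol, rec_i))
             else rec_label,
             ligand_atom = lig_label, distance = distance,
             h_distance = h_distance, angle = angle,
             donor_side = donor_side, stringsAsFactors = FALSE)
}

# polar atoms (donor heavy atom with its explicit hydrogens, acceptors)
# of a ligand-side molecule, from connectivity
.ligand_polar <- function(mol) {
  a <- mol$atoms
  adj <- .adjacency(mol)
  donors <- list()
  for (i in which(a$element %in% c("N", "O", "S"))) {
    hs <- adj[[i]][a$element[adj[[i]]] == "H"]
    if (length(hs)) donors[[length(donors) + 1L]] <- list(heavy = i, h = hs)
  }
  list(donors = donors, acceptors = which(a$element %in% c("N", "O")))
}

# receptor polar atoms: residue/atom-name table, augmented with explicit
# hydrogens through bonds when the receptor carries them
.receptor_polar_h <- function(rec) {
  polar <- .receptor_polar(rec)
  adj <- .adjacency(rec)
  a <- rec$atoms
  donors <- lapply(polar$donors, function(i) {
    hs <- adj[[i]][a$element[adj[[i]]] == "H"]
    list(heavy = i, h = hs)
  })
  list(donors = donors, acceptors = polar$acceptors)
}

.angle_at <- function(p_mid, p1, p2) {
  u <- p1 - p_mid; v <- p2 - p_mid
  cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Detect protein-ligand hydrogen bonds
#'
#' Emits one record per donor-acceptor pair whose heavy-atom D...A
#' distance is below `heavy_cutoff` and, when the donor hydrogen is
#' explicit, whose D-H...A angle (measured at the hydrogen) is at least
#' `angle_min`. Records always carry the heavy-atom distance and, when a
#' hydrogen is explicit, also the H...A distance — reported interaction
#' tables conventionally mix both conventions.
#'
#' @param cplx a `plcomplex`.
#' @param heavy_cutoff heavy-atom distance cutoff in Angstrom (default 3,
#'   i.e. "hydrogen bonds < 3 Angstrom").
#' @param angle_min minimum D-H...A angle in degrees when H is explicit.
#' @return data frame of interaction records (possibly empty).
#' @export
detect_hbonds <- function(cplx, heavy_cutoff = 3.0, angle_min = 120) {
  stopifnot(inherits(cplx, "plcomplex"))
  rec <- cplx$receptor; lig <- cplx$ligand
  rxyz <- coords(rec); lxyz <- coords(lig)
  rp <- .receptor_polar_h(rec)
  lp <- .ligand_polar(lig)
  out <- list()
  emit <- function(...) out[[length(out) + 1L]] <<- .record(...)
  check_pair <- function(d_heavy, d_pos, hs, h_xyz_of, a_pos) {
    # returns list(ok, h_distance, angle)
    if (sqrt(sum((d_pos - a_pos)^2)) >= heavy_cutoff)
      return(list(ok = FALSE))
    if (!length(hs))
      return(list(ok = TRUE, h_distance = NA_real_, angle = NA_real_))
    best <- NULL
    for (h in hs) {
      hp <- h_xyz_of(h)
      ang <- .angle_at(hp, d_pos, a_pos)
      if (ang >= angle_min) {
        hd <- sqrt(sum((hp - a_pos)^2))
        if (is.null(best) || hd < best$h_distance)
          best <- list(ok = TRUE, h_distance = hd, angle = ang)
      }
    }
    if (is.null(best)) list(ok = FALSE) else best
  }
  # receptor donor -> ligand acceptor
  for (d in rp$donors) {
    dp <- rxyz[d$heavy, ]
    for (ai in lp$acceptors) {
      ap <- lxyz[ai, ]
      r <- check_pair(NULL, dp, d$h, function(h) rxyz[h, ], ap)
      if (r$ok)
        emit("hydrogen_bond", rec, d$heavy, .atom_label(lig, ai),
             distance = sqrt(sum((dp - ap)^2)), h_distance = r$h_distance,
             angle = r$angle, donor_side = "receptor")
    }
  }
  # ligand donor -> receptor acceptor
  for (d in lp$donors) {
    dp <- lxyz[d$heavy, ]
    for (ai in rp$acceptors) {
      ap <- rxyz[ai, ]
      r <- check_pair(NULL, dp, d$h, function(h) lxyz[h, ], ap)
      if (r$ok)
        emit("hydrogen_bond", rec, ai, .atom_label(lig, d$heavy),
             distance = sqrt(sum((dp - ap)^2)), h_distance = r$h_distance,
             angle = r$angle, donor_side = "ligand")
    }
  }
  if (!length(out)) return(.empty_records())
  do.call(rbind, out)
}

# ring perception for interaction geometry: explicit aromatic bonds when
# present, else residue-template rings for standard aromatic sidechains
.interaction_rings <- function(mol, receptor = FALSE) {
  rings <- .aromatic_rings(mol)
  if (!length(rings) && receptor) {
    templates <- list(
      PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
      TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
      HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
      TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                 c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")))
    a <- mol$atoms
    nm <- if (!is.null(a$atom_name)) a$atom_name else a$element
    key <- paste(a$chain_id, a$residue_number, a$residue_name)
    for (res_key in unique(key[a$residue_name %in% names(templates)])) {
      rows <- which(key == res_key)
      for (tpl in templates[[a$residue_name[rows[1]]]]) {
        hit <- rows[match(tpl, nm[rows])]
        if (!anyNA(hit)) rings[[length(rings) + 1L]] <- hit
      }
    }
  }
  xyz <- coords(mol)
  lapply(rings, function(idx) {
    pts <- xyz[idx, , drop = FALSE]
    cen <- colMeans(pts)
    sv <- svd(sweep(pts, 2, cen))
    list(atoms = idx, centroid = cen, normal = sv$v[, 3],
         rms_out_of_plane = sqrt(mean((sweep(pts, 2, cen) %*% sv$v[, 3])^2)))
  })
}

.plane_angle <- function(n1, n2) {
  cosv <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(pmin(1, cosv)) * 180 / pi
}

# cationic centers: formally positive atoms plus LYS:NZ / ARG:CZ on a
# receptor read without charges
.cation_atoms <- function(mol, receptor = FALSE) {
  a <- mol$atoms
  idx <- which(a$formal_charge > 0L & a$element != "H")
  if (receptor) {
    nm <- if (!is.null(a$atom_name)) a$atom_name else a$element
    idx <- union(idx, which((a$residue_name == "LYS" & nm == "NZ") |
                              (a$residue_name == "ARG" & nm == "CZ")))
  }
  idx
}

# aliphatic hydrophobic carbons: members of contiguous carbon clusters
# (>= min_size, no attached heteroatom); the interacting unit of alkyl
# and pi-alkyl contacts
.alkyl_atoms <- function(mol, min_size = 2L) {
  unlist(.carbon_clusters(mol, min_size = min_size))
}

#' Detect aromatic-ring-mediated and hydrophobic contacts
#'
#' Geometric classification over ring centroids, ring normals and atom
#' positions:
#' \itemize{
#'   \item `pi_pi_stacked`: ring-ring centroid distance within the window
#'     and interplanar angle <= 30 degrees;
#'   \item `pi_pi_T`: centroid distance within window, interplanar angle
#'     60-120 degrees;
#'   \item `pi_cation`: cationic center to ring centroid;
#'   \item `pi_sigma`: aliphatic C-H carbon whose hydrogen points at the
#'     ring, carbon-to-centroid within window;
#'   \item `pi_alkyl`: aliphatic cluster carbon (or Cys/Met sulfur) to
#'     ring centroid;
#'   \item `alkyl_alkyl`: closest aliphatic-cluster carbon pair per
#'     residue;
#'   \item `sulfur_x`: divalent sulfur to an electron-rich partner atom.
#' }
#' Classes are mutually exclusive per (receptor unit, ligand unit) pair,
#' with the precedence given by the order above; hydrogen bonds (detected
#' separately) outrank all of them in [interaction_table()].
#'
#' @param cplx a `plcomplex`.
#' @param cutoffs named list overriding [interaction_cutoffs()] entries.
#' @return data frame of interaction records.
#' @export
detect_pi_interactions <- function(cplx, cutoffs = list()) {
  stopifnot(inherits(cplx, "plcomplex"))
  co <- utils::modifyList(.default_cutoffs, cutoffs)
  rec <- cplx$receptor; lig <- cplx$ligand
  rxyz <- coords(rec); lxyz <- coords(lig)
  r_rings <- .interaction_rings(rec, receptor = TRUE)
  l_rings <- .interaction_rings(lig)
  ra <- rec$atoms; la <- lig$atoms
  rnm <- if (!is.null(ra$atom_name)) ra$atom_name else ra$element
  out <- list()
  used <- character(0)
  pair_key <- function(ru, lu) paste(ru, lu, sep = "|")
  emit <- function(key, ...) {
    if (key %in% used) return(invisible())
    used <<- c(used, key)
    out[[length(out) + 1L]] <<- .record(...)
  }
  lig_ring_label <- function(k) paste0("ring", k)
  # --- pi-pi ---
  for (ri in seq_along(r_rings)) for (li in seq_along(l_rings)) {
    rr <- r_rings[[ri]]; lr <- l_rings[[li]]
    d <- sqrt(sum((rr$centroid - lr$centroid)^2))
    ang <- .plane_angle(rr$normal, lr$normal)
    key <- pair_key(paste0("rring", ri), paste0("lring", li))
    anchor <- rr$atoms[1]
    if (d <= co$pi_pi_stacked && ang <= co$pi_pi_stacked_angle) {
      emit(key, "pi_pi_stacked", rec, anchor, lig_ring_label(li), d,
           angle = ang,
           rec_label = paste0(.res_title(ra$residue_name[anchor],
                                         ra$residue_number[anchor]), ":ring"))
    } else if (d <= co$pi_pi_T && ang >= co$pi_pi_T_angle[1] &&
               (180 - ang) >= (180 - co$pi_pi_T_angle[2])) {
      emit(key, "pi_pi_T", rec, anchor, lig_ring_label(li), d, angle = ang,
           rec_label = paste0(.res_title(ra$residue_name[anchor],
                                         ra$residue_number[anchor]), ":ring"))
    }
  }
  # --- pi-cation (either side's cation vs the other side's ring) ---
  for (ci in .cation_atoms(lig)) for (ri in seq_along(r_rings)) {
    rr <- r_rings[[ri]]
    d <- sqrt(sum((lxyz[ci, ] - rr$centroid)^2))
    if (d <= co$pi_cation) {
      anchor <- rr$atoms[1]
      emit(pair_key(paste0("rring", ri), paste0("latom", ci)),
           "pi_cation", rec, anchor, .atom_label(lig, ci), d,
           rec_label = paste0(.res_title(ra$residue_name[anchor],
                                         ra$residue_number[anchor]), ":ring"))
    }
  }
  for (ci in .cation_atoms(rec, receptor = TRUE)) for (li in seq_along(l_rings)) {
    lr <- l_rings[[li]]
    d <- sqrt(sum((rxyz[ci, ] - lr$centroid)^2))
    if (d <= co$pi_cation)
      emit(pair_key(paste0("ratom", ci), paste0("lring", li)),
           "pi_cation", rec, ci, lig_ring_label(li), d)
  }
  # --- pi-sigma / pi-alkyl: receptor aliphatic carbon (or Cys/Met S)
  #     against ligand rings, and symmetrically ---
  radj <- .adjacency(rec); ladj <- .adjacency(lig)
  h_points_at <- function(xyz, adj, elements, i, target) {
    hs <- adj[[i]][elements[adj[[i]]] == "H"]
    if (!length(hs)) return(FALSE)
    u <- target - xyz[i, ]
    any(vapply(hs, function(h) {
      v <- xyz[h, ] - xyz[i, ]
      sum(u * v) / sqrt(sum(u^2) * sum(v^2)) > 0.6
    }, TRUE))
  }
  r_alkyl <- .alkyl_atoms(rec)
  r_sulfur <- which(ra$element == "S")
  l_alkyl <- .alkyl_atoms(lig)
  l_sulfur <- which(la$element == "S")
  for (li in seq_along(l_rings)) {
    cen <- l_rings[[li]]$centroid
    for (i in c(r_alkyl, r_sulfur)) {
      d <- sqrt(sum((rxyz[i, ] - cen)^2))
      key <- pair_key(paste0("ratom", i), paste0("lring", li))
      if (ra$element[i] == "C" && d <= co$pi_sigma &&
          h_points_at(rxyz, radj, ra$element, i, cen)) {
        emit(key, "pi_sigma", rec, i, lig_ring_label(li), d)
      } else if (d <= co$pi_alkyl) {
        emit(key, "pi_alkyl", rec, i, lig_ring_label(li), d)
      }
    }
  }
  for (ri in seq_along(r_rings)) {
    rr <- r_rings[[ri]]
    anchor <- rr$atoms[1]
    rl <- paste0(.res_title(ra$residue_name[anchor],
                            ra$residue_number[anchor]), ":ring")
    for (i in c(l_alkyl, l_sulfur)) {
      d <- sqrt(sum((lxyz[i, ] - rr$centroid)^2))
      key <- pair_key(paste0("rring", ri), paste0("latom", i))
      if (la$element[i] == "C" && d <= co$pi_sigma &&
          h_points_at(lxyz, ladj, la$element, i, rr$centroid)) {
        emit(key, "pi_sigma", rec, anchor, .atom_label(lig, i), d,
             rec_label = rl)
      } else if (d <= co$pi_alkyl) {
        emit(key, "pi_alkyl", rec, anchor, .atom_label(lig, i), d,
             rec_label = rl)
      }
    }
  }
  # --- alkyl-alkyl: closest aliphatic pair per residue ---
  if (length(r_alkyl) && length(l_alkyl)) {
    rkey <- paste(ra$chain_id[r_alkyl], ra$residue_number[r_alkyl],
                  ra$residue_name[r_alkyl])
    for (res in unique(rkey)) {
      ridx <- r_alkyl[rkey == res]
      dmat <- outer(ridx, l_alkyl, Vectorize(function(i, j)
        sqrt(sum((rxyz[i, ] - lxyz[j, ])^2))))
      if (min(dmat) <= co$alkyl_alkyl) {
        w <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        i <- ridx[w[1]]; j <- l_alkyl[w[2]]
        emit(pair_key(paste0("ratom", i), paste0("latom", j)),
             "alkyl_alkyl", rec, i, .atom_label(lig, j), min(dmat))
      }
    }
  }
  # --- sulfur-X: divalent sulfur to electron-rich partner ---
  for (i in l_sulfur) {
    heavy_nb <- sum(la$element[ladj[[i]]] != "H")
    if (heavy_nb > 2L) next
    d2 <- sqrt(colSums((t(rxyz) - lxyz[i, ])^2))
    cand <- which(d2 <= co$sulfur_x & ra$element != "H")
    if (length(cand)) {
      j <- cand[which.min(d2[cand])]
      emit(pair_key(paste0("ratom", j), paste0("latom", i)),
           "sulfur_x", rec, j, .atom_label(lig, i), d2[j])
    }
  }
  for (i in r_sulfur) {
    d2 <- sqrt(colSums((t(lxyz) - rxyz[i, ])^2))
    cand <- which(d2 <= co$sulfur_x & la$element %in% c("N", "O", "S"))
    if (length(cand)) {
      j <- cand[which.min(d2[cand])]
      emit(pair_key(paste0("ratom", i), paste0("latom", j)),
           "sulfur_x", rec, i, .atom_label(lig, j), d2[j])
    }
  }
  if (!length(out)) return(.empty_records())
  do.call(rbind, out)
}

#' Detect residual van der Waals contact residues
#'
#' Residues with at least one heavy atom within `cutoff` of a ligand
#' heavy atom that do not already carry a hydrogen-bond or pi-class
#' record.
#'
#' @param cplx a `plcomplex`.
#' @param cutoff heavy-atom distance cutoff (Angstrom).
#' @param exclude data frame of records (e.g. from [detect_hbonds()] and
#'   [detect_pi_interactions()]) whose residues are excluded.
#' @return data frame with columns chain, number, name, min_distance.
#' @export
detect_vdw_contacts <- function(cplx, cutoff = 4.0, exclude = NULL) {
  stopifnot(inherits(cplx, "plcomplex"))
  ra <- cplx$receptor$atoms
  rxyz <- coords(cplx$receptor)
  la <- cplx$ligand$atoms
  lxyz <- coords(cplx$ligand)[la$element != "H", , drop = FALSE]
  heavy <- which(ra$element != "H")
  mind <- vapply(heavy, function(i)
    sqrt(min(colSums((t(lxyz) - rxyz[i, ])^2))), 0)
  key <- paste(ra$chain_id[heavy], ra$residue_number[heavy], ra$residue_name[heavy])
  res_min <- tapply(mind, key, min)
  keep <- names(res_min)[res_min <= cutoff]
  if (!is.null(exclude) && nrow(exclude)) {
    excl <- unique(paste(exclude$chain, exclude$residue_number,
                         exclude$residue_name))
    keep <- setdiff(keep, excl)
  }
  if (!length(keep))
    return(data.frame(chain = character(0), number = integer(0),
                      name = character(0), min_distance = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keep, " "))
  out <- data.frame(chain = parts[, 1], number = as.integer(parts[, 2]),
                    name = parts[, 3], min_distance = unname(res_min[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$number), , drop = FALSE]
}

#' Back-to-front type-II binding verdict
#'
#' Partitions hydrogen-bond records by front- versus back-pocket residue
#' membership. A pose binds back-to-front — the type-II kinase-inhibitor
#' signature of engaging the hinge (front) and the allosteric back pocket
#' simultaneously — iff both partitions are nonempty.
#'
#' @param records data frame of interaction records (only
#'   `hydrogen_bond` rows are considered).
#' @param pocket a `pocket_definition` with nonempty front and back sets,
#'   e.g. [vegfr2_pocket()].
#' @return object of class `type2_verdict`: `front_hbonds`,
#'   `back_hbonds` (record subsets) and `is_back_to_front`.
#' @export
classify_type2 <- function(records, pocket = vegfr2_pocket()) {
  stopifnot(inherits(pocket, "pocket_definition"))
  if (nrow(pocket$front_residues) == 0L || nrow(pocket$back_residues) == 0L)
    stop("pocket must define nonempty front and back residue sets")
  hb <- records[records$category == "hydrogen_bond", , drop = FALSE]
  memb <- function(set) paste(hb$residue_number, toupper(hb$residue_name)) %in%
    paste(set$number, set$name)
  front <- hb[memb(pocket$front_residues), , drop = FALSE]
  back <- hb[memb(pocket$back_residues), , drop = FALSE]
  structure(list(front_hbonds = front, back_hbonds = back,
                 is_back_to_front = nrow(front) >= 1L && nrow(back) >= 1L),
            class = "type2_verdict")
}

#' @export
print.type2_verdict <- function(x, ...) {
  cat(sprintf("<type2_verdict> front H-bonds %d, back H-bonds %d -> back-to-front: %s\n",
              nrow(x$front_hbonds), nrow(x$back_hbonds),
              x$is_back_to_front))
  invisible(x)
}

#' Full interaction table for one protein-ligand pose
#'
#' Runs all detectors with the documented precedence (hydrogen bonds
#' outrank pi classes outrank van der Waals) and assembles one row in the
#' conventional three-column shape — hydrogen bonds with distances,
#' pi/alkyl partners, van der Waals partners — plus the back-to-front
#' verdict.
#'
#' @param cplx a `plcomplex`.
#' @param pocket a `pocket_definition` with front/back sets.
#' @param cutoffs named list overriding [interaction_cutoffs()].
#' @param distance_style which distance to print for hydrogen bonds with
#'   explicit hydrogens: `"hydrogen"` (H...A, the common reporting style)
#'   or `"heavy"` (D...A).
#' @return object of class `interaction_row`; `as.data.frame()` yields a
#'   one-row table with formatted columns.
#' @export
interaction_table <- function(cplx, pocket = vegfr2_pocket(),
                              cutoffs = list(),
                              distance_style = c("hydrogen", "heavy")) {
  distance_style <- match.arg(distance_style)
  co <- utils::modifyList(.default_cutoffs, cutoffs)
  hb <- detect_hbonds(cplx, heavy_cutoff = co$hbond_heavy,
                      angle_min = co$hbond_angle)
  pi_rec <- detect_pi_interactions(cplx, cutoffs = cutoffs)
  # hydrogen bonds outrank pi records on the same residue atom pair
  if (nrow(pi_rec) && nrow(hb)) {
    dup <- paste(pi_rec$receptor_atom, pi_rec$ligand_atom) %in%
      paste(hb$receptor_atom, hb$ligand_atom)
    pi_rec <- pi_rec[!dup, , drop = FALSE]
  }
  all_rec <- rbind(hb, pi_rec)
  vdw <- detect_vdw_contacts(cplx, cutoff = co$vdw, exclude = all_rec)
  verdict <- classify_type2(all_rec, pocket)
  structure(list(compound = cplx$ligand$name, hbonds = hb, pi = pi_rec,
                 vdw = vdw, verdict = verdict,
                 distance_style = distance_style),
            class = "interaction_row")
}

#' @export
as.data.frame.interaction_row <- function(x, ...) {
  hb <- x$hbonds
  hb_str <- if (nrow(hb)) {
    d <- if (x$distance_style == "hydrogen")
      ifelse(is.na(hb$h_distance), hb$distance, hb$h_distance)
    else hb$distance
    paste(sprintf("%s-%s (%.1f)", hb$receptor_atom, hb$ligand_atom, d),
          collapse = "; ")
  } else ""
  pi_res <- unique(.res_title(x$pi$residue_name, x$pi$residue_number))
  vdw_res <- .res_title(x$vdw$name, x$vdw$number)
  data.frame(compound = x$compound,
             hydrogen_bonds = hb_str,
             n_hbonds = nrow(hb),
             pi_partners = paste(pi_res, collapse = ", "),
             n_pi = nrow(x$pi),
             vdw_partners = paste(vdw_res, collapse = ", "),
             n_vdw = nrow(x$vdw),
             back_to_front = x$verdict$is_back_to_front,
             stringsAsFactors = FALSE)
}

#' @export
print.interaction_row <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}
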