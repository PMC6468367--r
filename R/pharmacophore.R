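#' Pharmacophore feature
#'
#' One abstract chemical feature of a 3D pharmacophore: a hydrogen-bond
#' donor (HBD), hydrogen-bond acceptor (HBA) or hydrophobic point (HyP),
#' with a spherical matching tolerance. Donor/acceptor features may carry
#' a projected point — the position of the hydrogen-bonding partner atom
#' that defines the bond direction.
#'
#' @param kind one of `"HBD"`, `"HBA"`, `"HyP"`.
#' @param centroid numeric length-3 position (Angstrom).
#' @param projection optional length-3 projected point; only meaningful
#'   for HBD/HBA features.
#' @param tolerance sphere radius in Angstrom (> 0). Defaults follow
#'   common pharmacophore practice: 1.6 for polar features, 1.7 for
#'   hydrophobes.
#' @param source_atoms optional integer indices of the atoms that gave
#'   rise to the feature in its parent molecule.
#' @return object of class `pharmacophore_feature`.
#' @export
pharmacophore_feature <- function(kind, centroid, projection = NULL,
                                  tolerance = if (kind == "HyP") 1.7 else 1.6,
                                  source_atoms = integer(0)) {
  kind <- match.arg(kind, c("HBD", "HBA", "HyP"))
  centroid <- as.numeric(centroid)
  stopifnot(length(centroid) == 3L, all(is.finite(centroid)))
  if (!is.null(projection)) {
    if (kind == "HyP") stop("projection points apply only to HBD/HBA features")
    projection <- as.numeric(projection)
    stopifnot(length(projection) == 3L, all(is.finite(projection)))
  }
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("feature tolerance must be > 0")
  structure(list(kind = kind, centroid = centroid, projection = projection,
                 tolerance = tolerance,
                 source_atoms = as.integer(source_atoms)),
            class = "pharmacophore_feature")
}

#' Assemble a pharmacophore model from features
#'
#' @param features list of [pharmacophore_feature()] (3 to 7 of them).
#' @param selectivity optional precomputed selectivity score; computed
#'   with [selectivity_score()] when omitted.
#' @param provenance free-text note on where the model came from.
#' @return object of class `pharmacophore_model` with the symmetric
#'   interfeature distance matrix over feature centroids.
#' @export
pharmacophore_model <- function(features, selectivity = NULL,
                                provenance = "") {
  if (!length(features) || !all(vapply(features, inherits, TRUE,
                                       "pharmacophore_feature")))
    stop("features must be a nonempty list of pharmacophore_feature")
  n <- length(features)
  if (n < 3L || n > 7L)
    stop("a pharmacophore model must have between 3 and 7 features, got ", n)
  cent <- t(vapply(features, function(f) f$centroid, numeric(3)))
  dm <- as.matrix(stats::dist(cent))
  dimnames(dm) <- NULL
  m <- structure(list(features = features, distance_matrix = dm,
                      selectivity = NA_real_, provenance = provenance),
                 class = "pharmacophore_model")
  m$selectivity <- if (is.null(selectivity)) selectivity_score(m) else selectivity
  m
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  kinds <- vapply(x$features, function(f) f$kind, "")
  cat(sprintf("<pharmacophore_model> %d features [%s], selectivity %.2f\n",
              length(kinds), paste(kinds, collapse = ", "), x$selectivity))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Feature kinds of a model or feature set
#' @param x a `pharmacophore_model` or `feature_set`.
#' @return character vector of kinds.
#' @export
feature_kinds <- function(x) vapply(x$features, function(f) f$kind, "")

#' Heuristic selectivity score of a model
#'
#' A deterministic rarity-weighted score used to rank enumerated models:
#' each feature contributes a kind prior (HBD 2.0, HBA 2.0, HyP 1.5) plus
#' 0.1 x the model's mean interfeature centroid distance in Angstrom.
#' Larger means more selective. This is an openly documented heuristic —
#' it is not, and does not emulate, any proprietary vendor score; only its
#' ordering properties (more features and wider spread rank higher) are
#' relied upon.
#'
#' @param model a `pharmacophore_model`.
#' @return numeric score.
#' @export
selectivity_score <- function(model) {
  stopifnot(inherits(model, "pharmacophore_model"))
  priors <- c(HBD = 2.0, HBA = 2.0, HyP = 1.5)
  kinds <- feature_kinds(model)
  dm <- model$distance_matrix
  mean_d <- mean(dm[upper.tri(dm)])
  sum(priors[kinds]) + 0.1 * length(kinds) * mean_d
}

# ---- feature perception -------------------------------------------------

# simple cycles of aromatic bonds, size 3..7, deduplicated by atom set
.aromatic_rings <- function(mol) {
  b <- mol$bonds
  ar <- b[b$order == "ar", , drop = FALSE]
  if (nrow(ar) == 0L) return(list())
  verts <- sort(unique(c(ar$i, ar$j)))
  adj <- lapply(seq_len(nrow(mol$atoms)), function(i) integer(0))
  for (k in seq_len(nrow(ar))) {
    adj[[ar$i[k]]] <- c(adj[[ar$i[k]]], ar$j[k])
    adj[[ar$j[k]]] <- c(adj[[ar$j[k]]], ar$i[k])
  }
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(ar))) {
    u <- ar$i[k]; v <- ar$j[k]
    # BFS from v to u avoiding the (u, v) edge gives the smallest ring
    # through this bond
    prev <- integer(nrow(mol$atoms)); prev[] <- 0L
    prev[v] <- -1L
    queue <- v
    found <- FALSE
    while (length(queue) && !found) {
      w <- queue[1]; queue <- queue[-1]
      for (x in adj[[w]]) {
        if (w == v && x == u) next
        if (prev[x] == 0L) {
          prev[x] <- w
          if (x == u) { found <- TRUE; break }
          queue <- c(queue, x)
        }
      }
    }
    if (!found) next
    path <- u
    w <- u
    while (prev[w] > 0L) { w <- prev[w]; path <- c(path, w) }
    path <- c(path, v)[!duplicated(c(path, v))]
    if (length(path) < 3L || length(path) > 7L) next
    key <- paste(sort(path), collapse = "-")
    if (!key %in% seen) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- sort(path) }
  }
  rings
}

# connected clusters (single/any bonds) of aliphatic carbons whose
# neighbours are only carbon or hydrogen; clusters of >= 3 are hydrophobic
.carbon_clusters <- function(mol, min_size = 3L) {
  a <- mol$atoms
  adj <- .adjacency(mol)
  ok <- a$element == "C" & !a$is_aromatic
  for (i in which(ok)) {
    nb <- adj[[i]]
    if (length(nb) && any(!a$element[nb] %in% c("C", "H"))) ok[i] <- FALSE
  }
  idx <- which(ok)
  if (!length(idx)) return(list())
  comp <- integer(nrow(a))
  cur <- 0L
  for (s in idx) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      w <- queue[1]; queue <- queue[-1]
      for (x in adj[[w]]) if (ok[x] && comp[x] == 0L) { comp[x] <- cur; queue <- c(queue, x) }
    }
  }
  out <- split(which(comp > 0L), comp[comp > 0L])
  Filter(function(cl) length(cl) >= min_size, unname(out))
}

#' Perceive pharmacophore features of a 3D ligand
#'
#' Fixed, documented perception chemistry:
#' \itemize{
#'   \item HBD at every N, O or S bearing at least one hydrogen (explicit,
#'     or inferred from standard valences when `infer_h = TRUE`);
#'   \item HBA at every O not positively charged, and at every N with an
#'     available lone pair — not positively charged, not amide-like (N
#'     single-bonded to a carbonyl carbon), and for aromatic N only the
#'     pyridine type (two ring neighbours, no hydrogen);
#'   \item HyP at the centroid of every aromatic ring and of every
#'     connected cluster of three or more aliphatic carbons with no
#'     attached heteroatom.
#' }
#'
#' @param mol a `molecule3d` with 3D coordinates.
#' @param infer_h infer implicit hydrogens from standard valences when the
#'   molecule carries none explicitly. Donor perception requires
#'   hydrogens: with heteroatoms present, no explicit hydrogens and
#'   `infer_h = FALSE`, an error is raised.
#' @param tol_polar,tol_hyp feature tolerances (Angstrom) stamped on the
#'   perceived features.
#' @return object of class `feature_set`.
#' @export
perceive_ligand_features <- function(mol, infer_h = FALSE,
                                     tol_polar = 1.6, tol_hyp = 1.7) {
  stopifnot(inherits(mol, "molecule3d"))
  a <- mol$atoms
  adj <- .adjacency(mol)
  has_h <- any(a$element == "H")
  het <- a$element %in% c("N", "O", "S")
  if (!has_h && any(het) && !infer_h)
    stop("no hydrogens present: donor perception needs explicit hydrogens ",
         "or infer_h = TRUE")
  imp_h <- if (infer_h && !has_h) .implicit_h(mol) else rep(0L, nrow(a))
  n_h <- vapply(seq_len(nrow(a)), function(i) {
    sum(a$element[adj[[i]]] == "H") + imp_h[i]
  }, 0L)
  feats <- list()
  add <- function(f) feats[[length(feats) + 1L]] <<- f
  pos <- coords(mol)
  # donors
  for (i in which(het & n_h > 0L))
    add(pharmacophore_feature("HBD", pos[i, ], tolerance = tol_polar,
                              source_atoms = i))
  # acceptors
  is_amide_n <- function(i) {
    for (cn in adj[[i]]) {
      if (a$element[cn] != "C") next
      bk <- mol$bonds[(mol$bonds$i == cn | mol$bonds$j == cn) &
                        mol$bonds$order == "2", , drop = FALSE]
      other <- ifelse(bk$i == cn, bk$j, bk$i)
      if (any(a$element[other] == "O")) return(TRUE)
    }
    FALSE
  }
  for (i in which(a$element == "O")) {
    if (a$formal_charge[i] > 0L) next
    add(pharmacophore_feature("HBA", pos[i, ], tolerance = tol_polar,
                              source_atoms = i))
  }
  for (i in which(a$element == "N")) {
    if (a$formal_charge[i] > 0L) next
    heavy_deg <- sum(a$element[adj[[i]]] != "H")
    if (a$is_aromatic[i]) {
      if (heavy_deg == 2L && n_h[i] == 0L)
        add(pharmacophore_feature("HBA", pos[i, ], tolerance = tol_polar,
                                  source_atoms = i))
    } else if (heavy_deg + n_h[i] <= 3L && !is_amide_n(i)) {
      add(pharmacophore_feature("HBA", pos[i, ], tolerance = tol_polar,
                                source_atoms = i))
    }
  }
  # hydrophobes: aromatic ring centroids, then aliphatic carbon clusters
  for (ring in .aromatic_rings(mol))
    add(pharmacophore_feature("HyP", colMeans(pos[ring, , drop = FALSE]),
                              tolerance = tol_hyp, source_atoms = ring))
  for (cl in .carbon_clusters(mol))
    add(pharmacophore_feature("HyP", colMeans(pos[cl, , drop = FALSE]),
                              tolerance = tol_hyp, source_atoms = cl))
  structure(list(owner = mol$name, features = feats), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  k <- feature_kinds(x)
  cat(sprintf("<feature_set> %s: %d features (%s)\n", x$owner, length(k),
              paste(sprintf("%s=%d", names(table(k)), table(k)), collapse = ", ")))
  invisible(x)
}

# receptor polar-atom roles by residue/atom name (PDB conventions,
# explicit hydrogens not required)
.protein_donor_atoms <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = "NE2", TRP = "NE1")
.protein_acceptor_atoms <- list(
  backbone = "O",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = "ND1")
.hydrophobic_residues <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET",
                           "PRO", "TRP")

.receptor_polar <- function(rec) {
  a <- rec$atoms
  nm <- if (!is.null(a$atom_name)) a$atom_name else a$element
  res <- a$residue_name
  is_don <- (nm == "N" & res != "PRO")
  is_acc <- (nm == "O")
  for (i in seq_len(nrow(a))) {
    d <- .protein_donor_atoms[[res[i]]]
    if (!is.null(d) && nm[i] %in% d) is_don[i] <- TRUE
    ac <- .protein_acceptor_atoms[[res[i]]]
    if (!is.null(ac) && nm[i] %in% ac) is_acc[i] <- TRUE
  }
  list(donors = which(is_don), acceptors = which(is_acc), atom_name = nm)
}

#' Perceive receptor-complementary features inside a binding site
#'
#' Builds the ligand-side feature image of the pocket: opposite every
#' receptor hydrogen-bond acceptor a donor (HBD) feature is placed 2.9
#' Angstrom along the direction toward the ligand, with the acceptor atom
#' as projected point; symmetrically an HBA feature opposite every
#' receptor donor; and a HyP feature at the sidechain-carbon centroid of
#' every hydrophobic site residue facing the ligand.
#'
#' @param cplx a `plcomplex`.
#' @param site a `pocket_definition` with a nonempty residue set, e.g.
#'   from [extract_binding_site()].
#' @param hbond_length donor/acceptor projection distance (Angstrom).
#' @param face_cutoff maximum sidechain-centroid-to-ligand distance for a
#'   hydrophobic cluster to count as facing the ligand (Angstrom).
#' @param tol_polar,tol_hyp tolerances stamped on emitted features.
#' @return a `feature_set` in the ligand's coordinate frame.
#' @export
perceive_complementary_features <- function(cplx, site, hbond_length = 2.9,
                                            face_cutoff = 8,
                                            tol_polar = 1.6, tol_hyp = 1.7) {
  stopifnot(inherits(cplx, "plcomplex"), inherits(site, "pocket_definition"))
  if (nrow(site$residues) == 0L) stop("binding site has no residues")
  rec <- cplx$receptor
  a <- rec$atoms
  in_site <- paste(a$residue_number, toupper(a$residue_name)) %in%
    paste(site$residues$number, site$residues$name)
  lig_xyz <- coords(cplx$ligand)
  rec_xyz <- coords(rec)
  toward_ligand <- function(p) {
    d2 <- colSums((t(lig_xyz) - p)^2)
    u <- lig_xyz[which.min(d2), ] - p
    u / sqrt(sum(u^2))
  }
  polar <- .receptor_polar(rec)
  feats <- list()
  add <- function(f) feats[[length(feats) + 1L]] <<- f
  for (i in intersect(polar$acceptors, which(in_site))) {
    p <- rec_xyz[i, ]
    add(pharmacophore_feature("HBD", p + hbond_length * toward_ligand(p),
                              projection = p, tolerance = tol_polar,
                              source_atoms = i))
  }
  for (i in intersect(polar$donors, which(in_site))) {
    p <- rec_xyz[i, ]
    add(pharmacophore_feature("HBA", p + hbond_length * toward_ligand(p),
                              projection = p, tolerance = tol_polar,
                              source_atoms = i))
  }
  nm <- polar$atom_name
  hyd <- which(in_site & a$residue_name %in% .hydrophobic_residues &
                 a$element == "C" & !nm %in% c("N", "CA", "C", "OXT"))
  if (length(hyd)) {
    key <- paste(a$chain_id[hyd], a$residue_number[hyd], a$residue_name[hyd])
    for (cl in split(hyd, key)) {
      cen <- colMeans(rec_xyz[cl, , drop = FALSE])
      mind <- sqrt(min(colSums((t(lig_xyz) - cen)^2)))
      if (mind <= face_cutoff)
        add(pharmacophore_feature("HyP", cen, tolerance = tol_hyp,
                                  source_atoms = cl))
    }
  }
  structure(list(owner = cplx$ligand$name, features = feats),
            class = "feature_set")
}

#' Enumerate candidate pharmacophore models from a feature set
#'
#' All feature subsets with size in `[min_n, max_n]` whose centroids are
#' pairwise at least `min_spacing` apart become candidate models, ranked
#' by [selectivity_score()] descending; ties are broken by feature count
#' descending, then by the lexicographic sorted kind string.
#'
#' @param fs a `feature_set`.
#' @param min_n,max_n subset size bounds (3 <= min_n <= max_n <= 7).
#' @param min_spacing minimum pairwise centroid separation (Angstrom).
#' @param provenance provenance stamped on each model.
#' @return list of `pharmacophore_model`, best first; empty (with a
#'   warning) when fewer than `min_n` features are available.
#' @export
enumerate_models <- function(fs, min_n = 4L, max_n = 5L, min_spacing = 2,
                             provenance = fs$owner) {
  stopifnot(inherits(fs, "feature_set"))
  if (min_n < 3L || min_n > max_n || max_n > 7L)
    stop("require 3 <= min_n <= max_n <= 7")
  nf <- length(fs$features)
  if (nf < min_n) {
    warning("only ", nf, " features available, fewer than min_n = ", min_n)
    return(list())
  }
  cent <- t(vapply(fs$features, function(f) f$centroid, numeric(3)))
  dm <- as.matrix(stats::dist(cent))
  models <- list()
  for (k in seq(min_n, min(max_n, nf))) {
    subsets <- utils::combn(nf, k, simplify = FALSE)
    for (s in subsets) {
      sub <- dm[s, s]
      if (any(sub[upper.tri(sub)] < min_spacing)) next
      models[[length(models) + 1L]] <-
        pharmacophore_model(fs$features[s], provenance = provenance)
    }
  }
  if (!length(models)) return(models)
  sel <- vapply(models, function(m) m$selectivity, 0)
  cnt <- vapply(models, function(m) length(m$features), 0L)
  kindstr <- vapply(models, function(m)
    paste(sort(feature_kinds(m)), collapse = ","), "")
  models[order(-sel, -cnt, kindstr)]
}
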