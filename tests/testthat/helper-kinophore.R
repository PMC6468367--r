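# shared fixtures and independent oracles for the test suite

# a random rotation matrix drawn from the package's deterministic stream
# (Rodrigues' formula on a random axis/angle)
random_rotation <- function(rng) {
  ax <- rng$norm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- 2 * pi * rng$unif(1)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# independent brute-force mapping oracle: enumerates every injective
# kind-compatible assignment without pruning, checks the pairwise window
# directly and superposes with an SVD written out locally
oracle_map <- function(model, fs) {
  m_kinds <- feature_kinds(model)
  l_kinds <- vapply(fs$features, function(f) f$kind, "")
  m_cent <- t(vapply(model$features, function(f) f$centroid, numeric(3)))
  l_cent <- t(vapply(fs$features, function(f) f$centroid, numeric(3)))
  tol <- vapply(model$features, function(f) f$tolerance, 0)
  dm <- model$distance_matrix
  nm <- length(m_kinds)
  rmsd_of <- function(a, b) {
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    sv <- svd(crossprod(ac, bc))
    d <- sign(det(sv$v %*% t(sv$u)))
    sqrt(max(0, (sum(ac^2) + sum(bc^2) -
                   2 * (sv$d[1] + sv$d[2] + d * sv$d[3])) / nrow(a)))
  }
  best <- Inf
  found <- FALSE
  recurse <- function(assign) {
    step <- length(assign) + 1L
    if (step > nm) {
      lc <- l_cent[assign, , drop = FALSE]
      for (i in seq_len(nm - 1L)) for (j in seq(i + 1L, nm)) {
        if (abs(sqrt(sum((lc[i, ] - lc[j, ])^2)) - dm[i, j]) >
            tol[i] + tol[j]) return(invisible())
      }
      found <<- TRUE
      best <<- min(best, rmsd_of(m_cent, lc))
      return(invisible())
    }
    for (li in which(l_kinds == m_kinds[step])) {
      if (li %in% assign) next
      recurse(c(assign, li))
    }
    invisible()
  }
  recurse(integer(0))
  list(matched = found, rmsd = if (found) best else NA_real_)
}

# Mann-Whitney pair-counting AUC oracle (ties count one half)
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# bare coordinate molecule for geometry-level tests
toy_mol <- function(name, el, xyz, bonds = NULL, charge = 0L,
                    aromatic = FALSE, resname = "", resnum = NA,
                    chain = "") {
  molecule3d(name, data.frame(
    serial = seq_along(el), element = el,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    formal_charge = charge, is_aromatic = aromatic,
    residue_name = resname, residue_number = resnum, chain_id = chain,
    stringsAsFactors = FALSE), bonds = bonds)
}

# methanol-like fragment: C-O-H plus methyl hydrogens
methanol_mol <- function() {
  toy_mol("methanol", c("C", "O", "H", "H", "H", "H"),
          rbind(c(0, 0, 0), c(1.43, 0, 0), c(1.79, 0.9, 0),
                c(-0.5, 0.9, 0), c(-0.5, -0.9, 0.3), c(-0.5, 0, -1)),
          bonds = data.frame(i = c(1, 2, 1, 1, 1), j = c(2, 3, 4, 5, 6),
                             order = "1"))
}

benzene_mol <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                        with_h = FALSE) {
  th <- 2 * pi * (0:5) / 6
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normal / sqrt(sum(normal^2))
  w1 <- ref - sum(ref * u) * u; w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(u[2] * w1[3] - u[3] * w1[2], u[3] * w1[1] - u[1] * w1[3],
          u[1] * w1[2] - u[2] * w1[1])
  cpos <- t(vapply(th, function(a) center + 1.39 * (cos(a) * w1 + sin(a) * w2),
                   numeric(3)))
  el <- rep("C", 6)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = "ar")
  if (with_h) {
    hpos <- t(vapply(th, function(a) center + 2.47 * (cos(a) * w1 + sin(a) * w2),
                     numeric(3)))
    cpos <- rbind(cpos, hpos)
    el <- c(el, rep("H", 6))
    bonds <- rbind(bonds, data.frame(i = 1:6, j = 7:12, order = "1"))
  }
  toy_mol("benzene", el, cpos, bonds = bonds,
          aromatic = el == "C")
}

# the five-feature reference model used across tests
ref_model <- function() vegfr2_reference_model()

# planted-contact spec helpers
hb_contact <- function(number, name, distance, donor_side = "receptor",
                       measure = NULL, atom = NULL) {
  ct <- list(category = "hydrogen_bond",
             residue = list(chain = "A", number = number, name = name),
             distance = distance, donor_side = donor_side)
  if (!is.null(measure)) ct$measure <- measure
  if (!is.null(atom)) ct$atom <- atom
  ct
}

pi_contact <- function(category, number, name, distance) {
  list(category = category,
       residue = list(chain = "A", number = number, name = name),
       distance = distance)
}
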