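# fixed atom-contribution table for the logP estimate: element-level
# octanol/water contributions in the spirit of atom-additive schemes
# (aromatic carbon enriched relative to aliphatic, heteroatoms negative).
# Documented constants; not fitted inside this package.
.logp_contrib <- c(
  C_aromatic = 0.16, C_aliphatic = 0.14, H = 0.12,
  N = -0.60, O = -0.40, S = 0.25, P = -0.20,
  F = 0.42, Cl = 0.65, Br = 0.86, I = 1.05)

#' Lipinski Rule-of-5 profile of a molecule
#'
#' Computes the five descriptors and applies the rules as strict
#' inequalities by default: molecular weight < 500 Da, logP < 5, hydrogen
#' bond donors < 5, acceptors < 10, rotatable bonds < 10.
#'
#' Conventions: molecular weight is the sum of standard atomic weights
#' over all atoms, with implicit hydrogens (inferred from standard
#' valences) counted when the structure carries no explicit ones; logP is
#' a fixed atom-additive estimate over the documented element
#' contribution table; donors are counted as N-H/O-H hydrogens; acceptors
#' use the classic Lipinski N + O count; rotatable bonds are non-ring
#' single bonds between two non-terminal heavy atoms, amide C-N excluded.
#'
#' @param mol a `molecule3d` with complete valences (explicit hydrogens,
#'   or inferable ones).
#' @param strict apply all five rules as strict `<` (default). With
#'   `strict = FALSE` the classic non-strict `<=` thresholds are used.
#' @return object of class `ro5_profile` with fields `mw`, `logp`,
#'   `hbd`, `hba`, `rotatable`, `violations` (character vector of failed
#'   rule names) and `passes`.
#' @export
ro5_profile <- function(mol, strict = TRUE) {
  stopifnot(inherits(mol, "molecule3d"))
  a <- mol$atoms
  unknown <- setdiff(unique(a$element), names(.atomic_weights))
  if (length(unknown))
    stop("cannot profile molecule with element(s) of unknown weight: ",
         paste(unknown, collapse = ", "))
  adj <- .adjacency(mol)
  has_h <- any(a$element == "H")
  imp_h <- if (has_h) rep(0L, nrow(a)) else .implicit_h(mol)
  n_h <- vapply(seq_len(nrow(a)), function(i) {
    sum(a$element[adj[[i]]] == "H") + imp_h[i]
  }, 0L)
  mw <- sum(.atomic_weights[a$element]) + sum(imp_h) * .atomic_weights[["H"]]
  contrib_key <- ifelse(a$element == "C",
                        ifelse(a$is_aromatic, "C_aromatic", "C_aliphatic"),
                        a$element)
  contrib <- .logp_contrib[contrib_key]
  contrib[is.na(contrib)] <- 0
  logp <- sum(contrib) + (sum(imp_h)) * .logp_contrib[["H"]]
  hbd <- sum(n_h[a$element %in% c("N", "O")])
  hba <- sum(a$element %in% c("N", "O"))
  rotatable <- .count_rotatable(mol, adj)
  lim <- function(x, cut) if (strict) x < cut else x <= cut
  rules <- c(mw = lim(mw, 500), logp = lim(logp, 5), hbd = lim(hbd, 5),
             hba = lim(hba, 10), rotatable = lim(rotatable, 10))
  violations <- names(rules)[!rules]
  structure(list(mw = unname(mw), logp = unname(logp), hbd = hbd, hba = hba,
                 rotatable = rotatable, violations = violations,
                 passes = length(violations) == 0L),
            class = "ro5_profile")
}

#' @export
print.ro5_profile <- function(x, ...) {
  cat(sprintf("<ro5_profile> MW %.1f Da | logP %.2f | HBD %d | HBA %d | RotB %d -> %s\n",
              x$mw, x$logp, x$hbd, x$hba, x$rotatable,
              if (x$passes) "passes" else
                paste("violates:", paste(x$violations, collapse = ", "))))
  invisible(x)
}

# rotatable bonds: single-order bonds whose removal disconnects the graph
# (i.e. non-ring; ring bonds are exactly the non-bridges), both endpoints
# heavy with heavy-degree >= 2, amide C-N excluded
.count_rotatable <- function(mol, adj = .adjacency(mol)) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  a <- mol$atoms
  heavy_deg <- vapply(seq_len(nrow(a)), function(i)
    sum(a$element[adj[[i]]] != "H"), 0L)
  g <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
  if (igraph::vcount(g) < nrow(a))
    g <- igraph::add_vertices(g, nrow(a) - igraph::vcount(g))
  bridge_ids <- igraph::bridges(g)
  is_bridge <- rep(FALSE, nrow(b))
  if (length(bridge_ids)) {
    be <- igraph::ends(g, bridge_ids)
    bkey <- paste(pmin(be[, 1], be[, 2]), pmax(be[, 1], be[, 2]))
    is_bridge <- paste(pmin(b$i, b$j), pmax(b$i, b$j)) %in% bkey
  }
  is_amide <- function(i, j) {
    # C-N single bond where the carbon bears a double-bonded oxygen
    for (p in list(c(i, j), c(j, i))) {
      ci <- p[1]; ni <- p[2]
      if (a$element[ci] != "C" || a$element[ni] != "N") next
      dbl <- b[(b$i == ci | b$j == ci) & b$order == "2", , drop = FALSE]
      other <- ifelse(dbl$i == ci, dbl$j, dbl$i)
      if (any(a$element[other] == "O")) return(TRUE)
    }
    FALSE
  }
  cnt <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != "1" || !is_bridge[k]) next
    i <- b$i[k]; j <- b$j[k]
    if (a$element[i] == "H" || a$element[j] == "H") next
    if (heavy_deg[i] < 2L || heavy_deg[j] < 2L) next
    if (is_amide(i, j)) next
    cnt <- cnt + 1L
  }
  cnt
}

#' Filter a screening library by drug-likeness
#'
#' Retains, in order, the records whose molecules pass [ro5_profile()];
#' the profile is attached to every retained record.
#'
#' @param lib a `screening_library`.
#' @param strict passed to [ro5_profile()].
#' @return the filtered `screening_library`.
#' @export
filter_druglike <- function(lib, strict = TRUE) {
  stopifnot(inherits(lib, "screening_library"))
  if (length(lib$records) == 0L) stop("cannot filter an empty library")
  keep <- list()
  for (r in lib$records) {
    p <- ro5_profile(r$mol, strict = strict)
    if (p$passes) {
      r$ro5 <- p
      keep[[length(keep) + 1L]] <- r
    }
  }
  structure(list(records = keep), class = "screening_library")
}
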