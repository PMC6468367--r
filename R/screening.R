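#' Optimal rigid-superposition RMSD of paired points
#'
#' Kabsch algorithm: both point sets are centered, the optimal rotation is
#' obtained from the SVD of the covariance matrix (with reflection
#' correction), and the residual root-mean-square deviation is returned.
#'
#' @param a,b numeric n x 3 matrices of paired coordinates (Angstrom).
#' @return the minimal RMSD (Angstrom) over all rigid-body motions.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3L, ncol(b) == 3L, nrow(a) == nrow(b), nrow(a) >= 1L)
  n <- nrow(a)
  if (n == 1L) return(0)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(ac, bc)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- sv$d
  msd <- (sum(ac^2) + sum(bc^2) - 2 * (s[1] + s[2] + d * s[3])) / n
  sqrt(max(0, msd))
}

#' Map a 3D ligand onto a pharmacophore model
#'
#' Searches injective, kind-compatible assignments of perceived ligand
#' features to model features. An assignment is feasible when every
#' pairwise ligand-feature centroid distance agrees with the model's
#' interfeature distance within the sum of the two model features'
#' tolerances. All model features must be matched (no partial mappings).
#' Among feasible assignments the one with minimal RMSD after optimal
#' rigid superposition of corresponding centroids is returned; exact RMSD
#' ties are broken by lexicographic assignment order so results are
#' bit-for-bit reproducible. The fit score is
#' `max(0, 1 - rmsd / mean model tolerance)`, in `[0, 1]`.
#'
#' Matching is single-conformer: the ligand is taken as given and only
#' rigid-body freedom is considered; conformer generation is the caller's
#' concern.
#'
#' @param model a `pharmacophore_model`.
#' @param mol a `molecule3d` with 3D coordinates, or a precomputed
#'   `feature_set`.
#' @param infer_h passed to [perceive_ligand_features()] when `mol` is a
#'   molecule.
#' @return object of class `match_result`: fields `matched`, `assignment`
#'   (model feature index -> ligand feature index), `rmsd`, `fit`.
#' @export
map_ligand <- function(model, mol, infer_h = TRUE) {
  stopifnot(inherits(model, "pharmacophore_model"))
  fs <- if (inherits(mol, "feature_set")) mol
        else perceive_ligand_features(mol, infer_h = infer_h)
  m_kinds <- feature_kinds(model)
  l_kinds <- vapply(fs$features, function(f) f$kind, "")
  nm <- length(m_kinds)
  no_match <- structure(list(matched = FALSE, assignment = integer(0),
                             rmsd = NA_real_, fit = 0), class = "match_result")
  cand <- lapply(m_kinds, function(k) which(l_kinds == k))
  if (any(vapply(cand, length, 0L) == 0L)) return(no_match)
  m_cent <- t(vapply(model$features, function(f) f$centroid, numeric(3)))
  l_cent <- t(vapply(fs$features, function(f) f$centroid, numeric(3)))
  tol <- vapply(model$features, function(f) f$tolerance, 0)
  dm <- model$distance_matrix
  dl <- as.matrix(stats::dist(l_cent))
  # search model features in order of fewest candidates; report assignments
  # in original feature order
  ord <- order(vapply(cand, length, 0L))
  best <- NULL
  best_rmsd <- Inf
  assign <- integer(nm)
  used <- rep(FALSE, ncol(dl))
  recurse <- function(step) {
    if (step > nm) {
      r <- kabsch_rmsd(m_cent, l_cent[assign, , drop = FALSE])
      # strict < keeps the lexicographically first assignment on exact ties
      if (r < best_rmsd - 1e-12) {
        best_rmsd <<- r
        best <<- assign
      }
      return(invisible())
    }
    mi <- ord[step]
    for (li in cand[[mi]]) {
      if (used[li]) next
      ok <- TRUE
      for (prev in seq_len(step - 1L)) {
        mj <- ord[prev]
        if (abs(dl[li, assign[mj]] - dm[mi, mj]) > tol[mi] + tol[mj]) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign[mi] <<- li
      used[li] <<- TRUE
      recurse(step + 1L)
      used[li] <<- FALSE
      assign[mi] <<- 0L
    }
    invisible()
  }
  recurse(1L)
  if (is.null(best)) return(no_match)
  structure(list(matched = TRUE, assignment = best, rmsd = best_rmsd,
                 fit = max(0, 1 - best_rmsd / mean(tol))),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$matched)
    cat(sprintf("<match_result> matched, rmsd %.4f A, fit %.4f\n",
                x$rmsd, x$fit))
  else cat("<match_result> no feasible mapping\n")
  invisible(x)
}

#' Construct a screening library
#'
#' @param mols list of `molecule3d` (names taken from the molecules when
#'   the list is unnamed).
#' @param labels optional logical activity labels (TRUE = active), one per
#'   molecule; NA when unknown.
#' @return object of class `screening_library`: a list of records, each
#'   with `mol`, `name`, `label`, `score`, `matched`.
#' @export
screening_library <- function(mols, labels = NULL) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  stopifnot(length(mols) >= 1L)
  nms <- names(mols)
  if (is.null(nms)) nms <- vapply(mols, function(m) m$name, "")
  if (anyDuplicated(nms)) stop("library molecule names must be unique")
  if (is.null(labels)) labels <- rep(NA, length(mols))
  stopifnot(length(labels) == length(mols))
  recs <- lapply(seq_along(mols), function(k) {
    list(mol = mols[[k]], name = nms[k], label = as.logical(labels[k]),
         score = NA_real_, matched = NA)
  })
  structure(list(records = recs), class = "screening_library")
}

#' @export
length.screening_library <- function(x) length(x$records)

#' @export
print.screening_library <- function(x, ...) {
  lab <- vapply(x$records, function(r) r$label, TRUE)
  cat(sprintf("<screening_library> %d molecules (%d labelled active)\n",
              length(x$records), sum(lab, na.rm = TRUE)))
  invisible(x)
}

#' Summarize a screening library as a data frame
#' @param x a `screening_library`.
#' @param ... unused.
#' @return data frame with name, label, matched, score columns.
#' @export
as.data.frame.screening_library <- function(x, ...) {
  data.frame(
    name = vapply(x$records, function(r) r$name, ""),
    label = vapply(x$records, function(r) r$label, TRUE),
    matched = vapply(x$records, function(r) as.logical(r$matched), TRUE),
    score = vapply(x$records, function(r) r$score, 0),
    stringsAsFactors = FALSE)
}

#' Screen a library against a pharmacophore model
#'
#' Every record is mapped with [map_ligand()] and scored by fit; the hit
#' list contains the matched records sorted by fit descending, ties by
#' name.
#'
#' @param model a `pharmacophore_model`.
#' @param lib a `screening_library`.
#' @param infer_h passed to feature perception.
#' @return list with `library` (the scored `screening_library`) and
#'   `hits` (data frame: name, label, rmsd, fit, best first).
#' @export
screen_library <- function(model, lib, infer_h = TRUE) {
  stopifnot(inherits(lib, "screening_library"))
  if (length(lib$records) == 0L) stop("cannot screen an empty library")
  rows <- vector("list", length(lib$records))
  for (k in seq_along(lib$records)) {
    r <- lib$records[[k]]
    mr <- map_ligand(model, r$mol, infer_h = infer_h)
    lib$records[[k]]$matched <- mr$matched
    lib$records[[k]]$score <- mr$fit
    rows[[k]] <- data.frame(name = r$name, label = r$label,
                            matched = mr$matched,
                            rmsd = if (mr$matched) mr$rmsd else NA_real_,
                            fit = mr$fit, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  hits <- tab[tab$matched, , drop = FALSE]
  hits <- hits[order(-hits$fit, hits$name), , drop = FALSE]
  rownames(hits) <- NULL
  list(library = lib, hits = hits)
}
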