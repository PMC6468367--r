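#' Read a molecular structure file
#'
#' Reads PDB (fixed-column, via \pkg{bio3d}), SDF V2000 (via
#' \pkg{ChemmineR}), MOL2 (via \pkg{bio3d}) or SMILES. A PDB file whose
#' HETATM records contain a non-water ligand is returned as a
#' [pl_complex()]; otherwise a single [molecule3d()] is returned. For
#' SMILES input 3D coordinates must be generated explicitly
#' (`embed = TRUE`, requires the OpenBabel `obabel` executable on the
#' PATH); without them matching and interaction geometry are undefined.
#'
#' @param path file path.
#' @param format one of `"pdb"`, `"sdf"`, `"mol2"`, `"smiles3d"`; guessed
#'   from the file extension when omitted.
#' @param strip_water drop water residues (HOH/WAT/DOD) from PDB input.
#' @param chain optional chain selector for PDB polymer records; defaults
#'   to the first chain present.
#' @param embed for `smiles3d`, generate 3D coordinates with OpenBabel.
#' @return a `molecule3d`, or a `plcomplex` for PDB files with a ligand.
#' @export
read_structure <- function(path, format = NULL, strip_water = TRUE,
                           chain = NULL, embed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", ent = "pdb", sdf = "sdf", mol = "sdf",
                     mol2 = "mol2", smi = "smiles3d", smiles = "smiles3d",
                     stop("cannot guess format from extension of ", path))
  }
  format <- match.arg(format, c("pdb", "sdf", "mol2", "smiles3d"))
  switch(format,
         pdb = .read_pdb_structure(path, strip_water, chain),
         sdf = .read_sdf_molecule(path),
         mol2 = .read_mol2_molecule(path),
         smiles3d = .read_smiles3d(path, embed))
}

.read_pdb_structure <- function(path, strip_water, chain) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported; found in ", path)
  # altloc: keep the highest-occupancy alternative per atom site
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$resid, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  if (strip_water) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms left after filtering in ", path)
  ele <- at$elesy
  if (is.null(ele) || all(is.na(ele) | ele == ""))
    ele <- bio3d::atom2ele(at$elety)
  ele <- sub("^([A-Za-z])([a-z]?).*$", "\\1\\2", ele)
  ele[is.na(ele) | ele == ""] <- bio3d::atom2ele(at$elety[is.na(ele) | ele == ""])
  as_mol <- function(rows, name) {
    a <- at[rows, , drop = FALSE]
    molecule3d(name, data.frame(
      serial = a$eleno, element = ele[rows], x = a$x, y = a$y, z = a$z,
      formal_charge = 0L, is_aromatic = FALSE,
      residue_name = a$resid, residue_number = a$resno,
      chain_id = ifelse(is.na(a$chain), "", a$chain),
      atom_name = a$elety, stringsAsFactors = FALSE))
  }
  poly <- which(at$type == "ATOM")
  het <- which(at$type == "HETATM")
  if (length(poly)) {
    chains <- unique(at$chain[poly])
    sel <- if (is.null(chain)) chains[1] else chain
    poly <- poly[at$chain[poly] %in% sel]
  }
  if (length(het) == 0L) {
    if (length(poly) == 0L) stop("no usable records in ", path)
    return(as_mol(poly, basename(path)))
  }
  if (length(poly) == 0L) return(as_mol(het, basename(path)))
  # the ligand is the largest HETATM residue group
  grp <- paste(at$chain[het], at$resno[het], at$resid[het])
  main <- names(which.max(table(grp)))
  lig <- het[grp == main]
  pl_complex(receptor = as_mol(poly, paste0(basename(path), ":receptor")),
             ligand = as_mol(lig, at$resid[lig[1]]))
}

.read_sdf_molecule <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^M  END", lines)))
    stop("SDF parse error in ", path, ": no 'M  END' terminator found ",
         "within ", length(lines), " line(s)")
  sdfs <- ChemmineR::read.SDFset(path)
  .sdf_to_mol(sdfs[[1]], name = ChemmineR::sdfid(sdfs)[1])
}

.sdf_to_mol <- function(sdf, name = "mol") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  bonds <- NULL
  aromatic <- rep(FALSE, nrow(ab))
  if (!is.null(bb) && nrow(bb) > 0) {
    type <- as.integer(bb[, 3])
    order <- as.character(type)
    order[type == 4] <- "ar"
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = order, stringsAsFactors = FALSE)
    arom_atoms <- unique(c(bonds$i[order == "ar"], bonds$j[order == "ar"]))
    aromatic[arom_atoms] <- TRUE
  }
  molecule3d(name, data.frame(
    serial = seq_along(el), element = el,
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    formal_charge = 0L, is_aromatic = aromatic, stringsAsFactors = FALSE),
    bonds = bonds)
}

#' Read a multi-record SDF file as a list of molecules
#'
#' @param path SDF file path.
#' @return named list of `molecule3d`.
#' @export
read_sdf_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^M  END", lines)))
    stop("SDF parse error in ", path, ": no 'M  END' terminator found")
  sdfs <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfs)
  out <- lapply(seq_along(sdfs), function(k) .sdf_to_mol(sdfs[[k]], ids[k]))
  names(out) <- ids
  out
}

.read_mol2_molecule <- function(path) {
  m <- bio3d::read.mol2(path)
  at <- m$atom
  el <- sub("\\..*$", "", at$elena)
  bonds <- NULL
  if (!is.null(m$bond) && nrow(m$bond) > 0) {
    order <- as.character(m$bond$type)
    order[order %in% c("ar", "am")] <- c(ar = "ar", am = "1")[order[order %in% c("ar", "am")]]
    bonds <- data.frame(i = m$bond$origin, j = m$bond$target,
                        order = order, stringsAsFactors = FALSE)
  }
  aromatic <- rep(FALSE, nrow(at))
  if (!is.null(bonds)) {
    arom <- unique(c(bonds$i[bonds$order == "ar"], bonds$j[bonds$order == "ar"]))
    aromatic[arom] <- TRUE
  }
  molecule3d(basename(path), data.frame(
    serial = at$eleno, element = el, x = at$x, y = at$y, z = at$z,
    formal_charge = round(ifelse(is.na(at$charge), 0, at$charge)),
    is_aromatic = aromatic, stringsAsFactors = FALSE), bonds = bonds)
}

.read_smiles3d <- function(path, embed) {
  if (!embed)
    stop("SMILES input carries no 3D coordinates; pass embed = TRUE ",
         "to generate them with OpenBabel")
  if (Sys.which("obabel") == "")
    stop("embed = TRUE requires the 'obabel' executable on the PATH")
  out <- tempfile(fileext = ".sdf")
  status <- system2("obabel", c(shQuote(path), "--gen3d", "-osdf",
                                paste0("-O", shQuote(out))),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out))
    stop("OpenBabel failed to embed 3D coordinates for ", path)
  .read_sdf_molecule(out)
}

#' Write molecules to an SDF V2000 file
#'
#' Emits a standard V2000 connection table per molecule (aromatic bonds as
#' type 4). Files written here read back identically through any V2000
#' reader; the test suite round-trips them through \pkg{ChemmineR}.
#'
#' @param mols a `molecule3d` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    a <- mol$atoms
    b <- mol$bonds
    writeLines(c(mol$name, "  kinophore", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nrow(b)) {
      type <- b$order
      type[type == "ar"] <- "4"
      writeLines(sprintf("%3d%3d%3d  0", b$i, b$j, as.integer(type)), con)
    }
    chg <- which(a$formal_charge != 0L)
    for (k in chg)
      writeLines(sprintf("M  CHG  1 %3d %3d", k, a$formal_charge[k]), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Write a protein-ligand complex as a PDB file
#'
#' @param cplx a `plcomplex`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_complex <- function(cplx, path) {
  r <- cplx$receptor$atoms
  l <- cplx$ligand$atoms
  lig_name <- ifelse(l$residue_name == "", "LIG", l$residue_name)
  lig_num <- ifelse(is.na(l$residue_number), 1L, l$residue_number)
  atom_name <- function(a, fallback) {
    if (!is.null(a$atom_name)) a$atom_name else fallback
  }
  bio3d::write.pdb(
    file = path,
    xyz = c(t(as.matrix(rbind(r[, c("x", "y", "z")], l[, c("x", "y", "z")])))),
    type = c(rep("ATOM", nrow(r)), rep("HETATM", nrow(l))),
    resno = c(r$residue_number, lig_num),
    resid = c(r$residue_name, lig_name),
    eleno = seq_len(nrow(r) + nrow(l)),
    elety = c(atom_name(r, paste0(r$element, seq_len(nrow(r)))),
              atom_name(l, paste0(l$element, seq_len(nrow(l))))),
    chain = c(ifelse(r$chain_id == "", "A", r$chain_id),
              ifelse(l$chain_id == "", "A", l$chain_id)),
    elesy = c(r$element, l$element))
  invisible(path)
}

#' Define a binding pocket
#'
#' @param residues data frame with columns `chain`, `number`, `name`
#'   identifying pocket residues (may be empty when only front/back sets
#'   matter).
#' @param radius pocket radius in Angstrom (> 0).
#' @param front,back data frames (same columns) naming the front- and
#'   back-pocket key residues; must be subsets of `residues` when
#'   `residues` is nonempty.
#' @return object of class `pocket_definition`.
#' @export
pocket_definition <- function(residues = NULL, radius = 10,
                              front = NULL, back = NULL) {
  if (!is.numeric(radius) || radius < 0)
    stop("pocket radius must be a nonnegative number")
  norm_res <- function(x) {
    if (is.null(x) || NROW(x) == 0L)
      return(data.frame(chain = character(0), number = integer(0),
                        name = character(0), stringsAsFactors = FALSE))
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    stopifnot(all(c("chain", "number", "name") %in% names(x)))
    x$number <- as.integer(x$number)
    x$name <- toupper(x$name)
    x[, c("chain", "number", "name")]
  }
  residues <- norm_res(residues)
  front <- norm_res(front)
  back <- norm_res(back)
  key <- function(d) paste(d$number, d$name)
  if (nrow(residues)) {
    if (!all(key(front) %in% key(residues)) || !all(key(back) %in% key(residues)))
      stop("front/back residues must be subsets of the pocket residue set")
  }
  structure(list(radius = radius, residues = residues,
                 front_residues = front, back_residues = back),
            class = "pocket_definition")
}

#' Default VEGFR-2 front/back pocket residues
#'
#' The type-II classifier's convention for the VEGFR-2 kinase domain
#' (author numbering): the front (adenine) pocket is defined by Glu917 and
#' Cys919 and the allosteric back pocket by Glu885 and Asp1046.
#'
#' @param chain chain identifier to stamp on the residue records.
#' @return a `pocket_definition` carrying only front/back sets.
#' @export
vegfr2_pocket <- function(chain = "A") {
  front <- data.frame(chain = chain, number = c(917L, 919L),
                      name = c("GLU", "CYS"), stringsAsFactors = FALSE)
  back <- data.frame(chain = chain, number = c(885L, 1046L),
                     name = c("GLU", "ASP"), stringsAsFactors = FALSE)
  pocket_definition(residues = rbind(front, back), radius = 10,
                    front = front, back = back)
}

#' Extract the binding-site residues around a bound ligand
#'
#' A residue belongs to the site iff any of its atoms lies within
#' `radius` (inclusive) of any ligand atom — the conventional inclusive
#' reading of a "within 10 Angstrom" site definition.
#'
#' @param cplx a `plcomplex` with at least one ligand atom.
#' @param radius site radius in Angstrom (default 10).
#' @return a `pocket_definition` whose `residues` lists the site.
#' @export
extract_binding_site <- function(cplx, radius = 10) {
  stopifnot(inherits(cplx, "plcomplex"))
  if (nrow(cplx$ligand$atoms) < 1L) stop("complex has no ligand atoms")
  rec <- cplx$receptor$atoms
  lig_xyz <- coords(cplx$ligand)
  rec_xyz <- coords(cplx$receptor)
  mind <- apply(rec_xyz, 1, function(p) {
    sqrt(min(colSums((t(lig_xyz) - p)^2)))
  })
  keep <- mind <= radius
  res <- unique(data.frame(chain = rec$chain_id[keep],
                           number = rec$residue_number[keep],
                           name = rec$residue_name[keep],
                           stringsAsFactors = FALSE))
  rownames(res) <- NULL
  pocket_definition(residues = res, radius = radius)
}

#' Serialize a pharmacophore model to JSON
#'
#' The on-disk form is a small documented JSON dialect (feature kinds,
#' centroids, optional projected points, tolerances, the interfeature
#' distance matrix, the selectivity score and a provenance string), kept
#' diffable and round-trip exact to well below 1e-9 Angstrom.
#'
#' @param model a `pharmacophore_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore_model"))
  obj <- list(
    format = "kinophore-pharmacophore-1",
    provenance = model$provenance,
    selectivity = model$selectivity,
    features = lapply(model$features, function(f) {
      list(kind = f$kind, centroid = f$centroid,
           projection = if (is.null(f$projection)) NULL else f$projection,
           tolerance = f$tolerance)
    }),
    distance_matrix = model$distance_matrix)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- lapply(obj$features, function(f) {
    kind <- as.character(f$kind)
    if (!kind %in% c("HBD", "HBA", "HyP"))
      stop("unknown pharmacophore feature kind '", kind, "' in ", path)
    pharmacophore_feature(
      kind = kind, centroid = as.numeric(unlist(f$centroid)),
      projection = if (is.null(f$projection)) NULL else as.numeric(unlist(f$projection)),
      tolerance = as.numeric(f$tolerance))
  })
  pharmacophore_model(feats,
                      selectivity = if (is.null(obj$selectivity)) NULL else as.numeric(obj$selectivity),
                      provenance = if (is.null(obj$provenance)) "" else as.character(obj$provenance))
}
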