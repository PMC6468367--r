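#' Packaged five-feature reference pharmacophore model
#'
#' A fixed five-feature model — two hydrogen-bond donors, one acceptor
#' and two hydrophobes — laid out with the topology of a type-II kinase
#' site query: one donor addressing the back pocket, the
#' acceptor/donor pair addressing the hinge, hydrophobes spanning the
#' gatekeeper region between them. Coordinates are synthetic package
#' constants (no crystal structure is shipped); the model's role is to
#' give every pipeline stage a deterministic default query.
#'
#' @return a `pharmacophore_model`.
#' @export
vegfr2_reference_model <- function() {
  pharmacophore_model(list(
    pharmacophore_feature("HBD", c(0.0, 0.0, 0.0)),
    pharmacophore_feature("HyP", c(3.5, 1.0, -0.5)),
    pharmacophore_feature("HyP", c(5.5, -0.8, 1.2)),
    pharmacophore_feature("HBA", c(7.5, -1.5, 1.0)),
    pharmacophore_feature("HBD", c(9.0, 1.0, 0.5))),
    provenance = "kinophore reference model (synthetic coordinates)")
}

#' Assemble and validate a pipeline configuration
#'
#' @param seed integer master seed for every stochastic stage.
#' @param model a `pharmacophore_model`, a pharmacophore JSON path, or
#'   NULL for [vegfr2_reference_model()].
#' @param library either a list/`library_spec` with counts `D`, `A`,
#'   `planted_Ht`, `planted_Ha` (synthetic library), or an SDF file path.
#' @param labels_csv optional CSV (columns `name`, `active`) labelling an
#'   SDF library.
#' @param validate run decoy-set validation (requires labels).
#' @param jitter coordinate jitter for synthetic libraries (Angstrom).
#' @param ro5_strict strict (`<`) Rule-of-5 inequalities.
#' @param poses optional list of `plcomplex` poses, or a directory of
#'   PDB complex files, to profile after screening. Docked poses are
#'   consumed, never produced: docking is outside the package's scope.
#' @param pocket a `pocket_definition` with front/back sets.
#' @param out_dir optional output directory for report files.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, model = NULL, library = NULL,
                            labels_csv = NULL, validate = TRUE,
                            jitter = 0.15, ro5_strict = TRUE,
                            poses = NULL, pocket = vegfr2_pocket(),
                            out_dir = NULL) {
  if (is.character(model) && !file.exists(model))
    stop("model file not found: ", model)
  if (is.character(library) && !file.exists(library))
    stop("library file not found: ", library)
  if (!is.null(labels_csv) && !file.exists(labels_csv))
    stop("labels file not found: ", labels_csv)
  if (is.character(poses) && !dir.exists(poses))
    stop("pose directory not found: ", poses)
  if (!is.numeric(jitter) || jitter < 0) stop("jitter must be >= 0")
  stopifnot(inherits(pocket, "pocket_definition"))
  structure(list(seed = as.integer(seed), model = model, library = library,
                 labels_csv = labels_csv, validate = isTRUE(validate),
                 jitter = jitter, ro5_strict = isTRUE(ro5_strict),
                 poses = poses, pocket = pocket, out_dir = out_dir),
            class = "pipeline_config")
}

.load_pipeline_model <- function(model) {
  if (is.null(model)) return(vegfr2_reference_model())
  if (inherits(model, "pharmacophore_model")) return(model)
  read_pharmacophore(model)
}

.load_pipeline_library <- function(config, model) {
  lib <- config$library
  if (is.null(lib)) stop("pipeline startup: no library configured")
  if (inherits(lib, "screening_library")) return(lib)
  if (is.character(lib)) {
    mols <- read_sdf_library(lib)
    labels <- rep(NA, length(mols))
    if (!is.null(config$labels_csv)) {
      tab <- utils::read.csv(config$labels_csv, stringsAsFactors = FALSE)
      labels <- as.logical(tab$active[match(names(mols), tab$name)])
    }
    return(screening_library(mols, labels))
  }
  if (inherits(lib, "library_spec") || is.list(lib)) {
    spec <- if (inherits(lib, "library_spec")) lib
    else library_spec(lib$D, lib$A, lib$planted_Ht, lib$planted_Ha,
                      seed = if (is.null(lib$seed)) config$seed else lib$seed)
    return(make_library(model, spec, jitter = config$jitter))
  }
  stop("pipeline startup: unrecognized library configuration")
}

.load_pipeline_poses <- function(poses) {
  if (is.null(poses)) return(list())
  if (is.character(poses)) {
    files <- sort(list.files(poses, pattern = "\\.pdb$", full.names = TRUE))
    out <- lapply(files, read_structure, format = "pdb")
    ok <- vapply(out, inherits, TRUE, "plcomplex")
    return(out[ok])
  }
  poses
}

#' Run the screening funnel end to end
#'
#' Executes the stages in their canonical order — load/generate the
#' library, (optionally) validate the model against it, map every ligand,
#' apply the Rule-of-5 gate, profile any supplied docked poses and apply
#' the back-to-front verdict — and reports a funnel summary plus
#' machine-readable artefacts. Two runs with an identical configuration
#' (including seed) produce byte-identical reports.
#'
#' @param config a [pipeline_config()], or a YAML file path holding its
#'   fields.
#' @return a `pipeline_report` list: `funnel` (named stage counts),
#'   `hits`, `validation`, `interactions` (per-pose table),
#'   `config` (fully resolved, sufficient to re-execute the run).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    y$pocket <- if (is.null(y$pocket)) vegfr2_pocket() else
      pocket_definition(residues = NULL, front = as.data.frame(y$pocket$front),
                        back = as.data.frame(y$pocket$back))
    config <- do.call(pipeline_config, y)
  }
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "model"
  report <- tryCatch({
    model <- .load_pipeline_model(config$model)
    stage <- "library"
    lib <- .load_pipeline_library(config, model)
    validation <- NULL
    if (config$validate) {
      stage <- "validation"
      labels <- vapply(lib$records, function(r) r$label, TRUE)
      if (!anyNA(labels)) validation <- validate_model(model, lib)
    }
    stage <- "screening"
    sc <- screen_library(model, lib)
    matched_names <- sc$hits$name
    matched_lib <- structure(list(records = Filter(
      function(r) r$name %in% matched_names, sc$library$records)),
      class = "screening_library")
    stage <- "druglikeness"
    surv <- if (length(matched_lib$records))
      filter_druglike(matched_lib, strict = config$ro5_strict)
    else matched_lib
    stage <- "interaction_profile"
    poses <- .load_pipeline_poses(config$poses)
    rows <- lapply(poses, interaction_table, pocket = config$pocket)
    itab <- if (length(rows)) do.call(rbind, lapply(rows, as.data.frame))
    else NULL
    n_b2f <- if (is.null(itab)) 0L else sum(itab$back_to_front)
    funnel <- c(input = length(lib$records),
                mapped = nrow(sc$hits),
                ro5_pass = length(surv$records),
                poses_profiled = length(poses),
                back_to_front = n_b2f)
    list(funnel = funnel, hits = sc$hits,
         ro5_survivors = vapply(surv$records, function(r) r$name, ""),
         validation = validation, interactions = itab,
         config = config)
  }, error = function(e) {
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) .write_pipeline_outputs(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> funnel:\n")
  for (nm in names(x$funnel)) cat(sprintf("  %-15s %d\n", nm, x$funnel[[nm]]))
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

.config_as_list <- function(config) {
  list(seed = config$seed,
       model = if (is.character(config$model)) config$model else "inline",
       library = if (is.character(config$library)) config$library
       else if (inherits(config$library, "library_spec") ||
                is.list(config$library)) unclass(config$library)
       else "inline",
       labels_csv = config$labels_csv, validate = config$validate,
       jitter = config$jitter, ro5_strict = config$ro5_strict,
       poses = if (is.character(config$poses)) config$poses
       else if (is.null(config$poses)) NULL else "inline",
       pocket = list(front = config$pocket$front_residues,
                     back = config$pocket$back_residues))
}

.write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(funnel = as.list(report$funnel),
         run_record = .config_as_list(report$config)),
    file.path(out_dir, "funnel.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(report$hits, file.path(out_dir, "hits.csv"),
                   row.names = FALSE)
  if (!is.null(report$validation)) {
    v <- report$validation
    jsonlite::write_json(list(counts = unclass(v$counts), raw = v$raw,
                              display = v$display),
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(report$interactions))
    utils::write.csv(report$interactions,
                     file.path(out_dir, "interactions.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}
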