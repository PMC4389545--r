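#' Default run configuration
#'
#' Every tolerance and scale of the pipeline in one serializable list. The
#' configuration round-trips losslessly through JSON ([write_config()] /
#' [read_config()]).
#'
#' @param root_seed root integer seed; all per-stage/per-subject seeds are
#'   derived from it by stable hashing.
#' @param ... overrides of any default field.
#' @return a `agetpl_config` list.
#' @export
default_config <- function(root_seed = 1L, ...) {
  cfg <- list(
    root_seed = as.integer(root_seed),
    out_dir = "agetpl_run",
    schemes = c("five_year", "ten_year"),
    groups = NULL,                 # NULL = all groups of the first scheme
    n_per_group = 3L,
    grid_shape = c(48L, 48L, 48L),
    voxel_size = 8 / 3,
    noise_sigma = 5,
    bias_amplitude = 0,
    shape_jitter = 1,
    backend = "demons",            # registration backend choice
    harness_backend = "rigid",     # prior mapping in evaluation
    schedule_plan = list(c(10, 0, 0), c(10, 10, 0), c(10, 10, 10)),
    rms_tol = 0.05,
    max_iter = 3L,
    inv_tol = 0.2,
    em_tol = 1e-6,
    em_max_iter = 200L,
    include_reference = TRUE)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "agetpl_config")
}

validate_config <- function(cfg) {
  if (!cfg$backend %in% "demons")
    stop("unknown registration backend: ", cfg$backend)
  if (!cfg$harness_backend %in% c("rigid", "deformable"))
    stop("unknown harness backend: ", cfg$harness_backend)
  if (!all(cfg$schemes %in% c("five_year", "ten_year", "multi_year")))
    stop("unknown scheme in config")
  invisible(cfg)
}

#' @rdname default_config
#' @param cfg a config list.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  if (is.matrix(cfg$schedule_plan))
    cfg$schedule_plan <- lapply(seq_len(nrow(cfg$schedule_plan)),
                                function(i) cfg$schedule_plan[i, ])
  cfg$root_seed <- as.integer(cfg$root_seed)
  cfg
}

pipeline_log <- function(...) message(sprintf(...))

#' Run the full synthetic pipeline
#'
#' Executes phantom generation, preprocessing, prior-free segmentation,
#' template + prior construction, and the evaluation reports, writing the
#' template library and TSV reports under `cfg$out_dir`. Re-running with the
#' same configuration reproduces all TSV outputs byte for byte.
#'
#' @param cfg an `agetpl_config` from [default_config()].
#' @return invisibly, a list with the cohort, library, and report paths.
#' @export
run_pipeline <- function(cfg = default_config()) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <<- c(manifest, name)
    path
  }

  groups <- make_age_groups(cfg$schemes[1])
  if (!is.null(cfg$groups)) groups <- groups[groups$label %in% cfg$groups, ]
  pipeline_log("pipeline: generating %d x %d phantoms (seed %d)",
               nrow(groups), cfg$n_per_group, cfg$root_seed)
  cohort <- make_cohort(groups, cfg$n_per_group,
                        seed = derive_seed(cfg$root_seed, "phantom"),
                        grid_shape = cfg$grid_shape, voxel_size = cfg$voxel_size,
                        noise_sigma = cfg$noise_sigma,
                        bias_amplitude = cfg$bias_amplitude,
                        shape_jitter = cfg$shape_jitter)

  pipeline_log("pipeline: preprocessing %d subjects", length(cohort))
  for (i in seq_along(cohort)) {
    pp <- preprocess_subject(cohort[[i]]$brain, atlas = NULL,
                             correct_bias_field = cfg$bias_amplitude > 0)
    cohort[[i]]$brain <- pp$normalized
    cohort[[i]]$norm_scale <- pp$scale
    cohort[[i]]$pve_image <- pp$pve
  }

  pipeline_log("pipeline: building template library (%s)",
               paste(cfg$schemes, collapse = ", "))
  library <- withCallingHandlers(
    build_prior_library(cohort, schemes = cfg$schemes,
                        schedule_plan = cfg$schedule_plan,
                        rms_tol = cfg$rms_tol, max_iter = cfg$max_iter,
                        include_reference = cfg$include_reference),
    warning = function(w) { pipeline_log("pipeline: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  write_library(library, file.path(cfg$out_dir, "library"))
  manifest <- c(manifest, "library")

  paths <- list()
  fy_ok <- !is.null(library$library$five_year)
  ty_ok <- !is.null(library$library$ten_year)
  have_groups <- function(case) {
    fy <- make_age_groups("five_year"); ty <- make_age_groups("ten_year")
    g5 <- fy$label[age_group_index(case$spec$age, fy)]
    g10 <- ty$label[age_group_index(case$spec$age, ty)]
    !is.null(library$library$five_year[[g5]]) &&
      (!ty_ok || !is.null(library$library$ten_year[[g10]]))
  }
  if (fy_ok && ty_ok && cfg$include_reference && all(vapply(cohort, have_groups, logical(1)))) {
    pipeline_log("pipeline: running variant harness")
    recs <- run_variant_harness(lapply(cohort, function(x) {
      x$reference <- x$truth_pve; x
    }), library, backend = cfg$harness_backend)
    paths$dice <- emit(recs, "dice_records.tsv")
  } else pipeline_log("pipeline: variant harness skipped (library incomplete)")

  pipeline_log("pipeline: volumetric report")
  vols <- do.call(rbind, lapply(cohort, function(case) {
    fy <- make_age_groups("five_year")
    g5 <- fy$label[age_group_index(case$spec$age, fy)]
    entry <- library$library$five_year[[g5]]
    pve <- if (!is.null(entry)) {
      pri <- warp_priors_to_subject(entry$priors_image, entry$template,
                                    case$brain, backend = cfg$harness_backend)
      segment_em(case$brain, case$brain_mask, priors_as_pve(pri),
                 seg_config("a_posteriori"))$pve
    } else case$pve_image
    tv <- tissue_volumes(pve)
    vv <- prod(voxel_size(case$inner_skull_mask))
    data.frame(subject_id = case$id, age = case$spec$age,
               om = tv[["om"]], gm = tv[["gm"]], wm = tv[["wm"]],
               gm_wm = tv[["gm_wm"]],
               inner_skull = sum(case$inner_skull_mask$data > 0) * vv)
  }))
  paths$volumes <- emit(vols, "volumes.tsv")

  demo <- summarize_cohort(data.frame(age = vapply(cohort, function(x) x$spec$age, numeric(1))))
  paths$demographics <- emit(demo, "demographics.tsv")

  jsonlite::write_json(list(outputs = manifest, config = unclass(cfg)),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  pipeline_log("pipeline: done (%s)", cfg$out_dir)
  invisible(list(cohort = cohort, library = library, paths = paths,
                 volumes = vols))
}

#' Write a template/prior library to a directory tree
#'
#' Layout: `{scheme}/{age_label}/{template.nii.gz, prior_{om,gm,wm}_{image,reference}.nii.gz, meta.json}`.
#' @param library an `agetpl_library`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_library <- function(library, dir) {
  for (scheme in names(library$library)) {
    for (label in names(library$library[[scheme]])) {
      entry <- library$library[[scheme]][[label]]
      d <- file.path(dir, scheme, label)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_volume(entry$template, file.path(d, "template.nii.gz"))
      for (cl in PVE_CLASSES) {
        write_volume(entry$priors_image[[cl]],
                     file.path(d, sprintf("prior_%s_image.nii.gz", cl)))
        if (!is.null(entry$priors_reference))
          write_volume(entry$priors_reference[[cl]],
                       file.path(d, sprintf("prior_%s_reference.nii.gz", cl)))
      }
      jsonlite::write_json(list(scheme = scheme, label = label,
                                n = length(entry$ages), ages = entry$ages,
                                rms = entry$result$iterations$rms),
                           file.path(d, "meta.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' Command-line interface
#'
#' Subcommands: `phantom` (write a phantom cohort), `segment`, `register`,
#' `pipeline` (full run from a JSON config), `config` (print defaults).
#' Invoked by the `inst/cli/agetpl` Rscript wrapper.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
agetpl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: agetpl <command> [--key value ...]",
    "  phantom   --ages 20-24,85-89 --n 2 --seed 1 --out DIR [--grid 48 --voxel 2.67]",
    "  segment   --in brain.nii.gz [--mask mask.nii.gz] --out DIR",
    "  register  --moving a.nii.gz --fixed b.nii.gz --schedule 50x50x50 --out DIR",
    "  pipeline  --config cfg.json | --out DIR [--seed 1]",
    "  config    [--out cfg.json]", sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  switch(cmd,
    phantom = {
      groups <- lapply(strsplit(opts$ages %||% "20-24", ",")[[1]], function(s)
        as.numeric(strsplit(s, "-")[[1]]))
      gs <- as.integer(opts$grid %||% 64)
      cohort <- make_cohort(groups, as.integer(opts$n %||% 1),
                            seed = as.integer(opts$seed %||% 1),
                            grid_shape = rep(gs, 3),
                            voxel_size = as.numeric(opts$voxel %||% 2))
      for (case in cohort)
        write_phantom(case, file.path(opts$out %||% "phantoms", case$id))
    },
    segment = {
      vol <- read_volume(opts$`in`)
      m <- vol$data > 0
      mask <- as_volume(array(as.numeric(m), dim(vol$data)), vol$affine)
      res <- segment_em(vol, mask)
      dir.create(opts$out %||% ".", recursive = TRUE, showWarnings = FALSE)
      for (cl in PVE_CLASSES)
        write_volume(res$pve[[cl]],
                     file.path(opts$out %||% ".", sprintf("pve_%s.nii.gz", cl)))
      write_volume(classify_hard(res$pve),
                   file.path(opts$out %||% ".", "labels.nii.gz"), "uint8")
    },
    register = {
      mov <- read_volume(opts$moving); fix <- read_volume(opts$fixed)
      sched <- as.numeric(strsplit(opts$schedule %||% "50x50x50", "x")[[1]])
      field <- register_deformable(mov, fix, sched)
      dir.create(opts$out %||% ".", recursive = TRUE, showWarnings = FALSE)
      write_field_nifti(field$forward, field$grid$affine,
                        file.path(opts$out %||% ".", "warp.nii.gz"))
      write_field_nifti(field$inverse, field$grid$affine,
                        file.path(opts$out %||% ".", "inverse_warp.nii.gz"))
      write.table(field$pre_affine$matrix,
                  file.path(opts$out %||% ".", "affine.txt"),
                  row.names = FALSE, col.names = FALSE)
    },
    pipeline = {
      cfg <- if (!is.null(opts$config)) read_config(opts$config) else
        default_config(root_seed = as.integer(opts$seed %||% 1),
                       out_dir = opts$out %||% "agetpl_run")
      if (!is.null(opts$out)) cfg$out_dir <- opts$out
      run_pipeline(cfg)
    },
    config = {
      cfg <- default_config()
      if (is.null(opts$out)) {
        cat(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, pretty = TRUE,
                             null = "null"), "\n")
      } else write_config(cfg, opts$out)
    },
    { cat(usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else { opts[[key]] <- args[i + 1]; i <- i + 2L }
  }
  opts
}
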