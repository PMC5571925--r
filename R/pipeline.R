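#' Full radiomic feature vector of one lesion
#'
#' Computes the complete named feature set used throughout the pipeline:
#' `suv_max`, `suv_peak`, `suv_mean` (SUV), `mtv` (mL), `tlg` (mL*SUV), the
#' six heterogeneity features, and the three shape features. Texture
#' features require at least one voxel pair and shape meshing at least 8
#' voxels; unavailable features are `NA`.
#'
#' @inheritParams suv_basic
#' @param settings list of feature settings: `G` (grey levels),
#'   `quantization` (`"minmax"`/`"fixed_width"`), `bin_width`,
#'   `suvpeak_mode`, `shape_mode`.
#' @return Named numeric vector of 14 features.
#' @export
lesion_features <- function(vol, mask, settings = feature_settings()) {
  basics <- suv_basic(vol, mask)
  peak <- tryCatch(suv_peak(vol, mask, mode = settings$suvpeak_mode),
                   error = function(e) NA_real_)
  mt <- mtv_tlg(vol, mask)
  tex <- tryCatch(
    texture_features(vol, mask, G = settings$G, method = settings$quantization,
                     bin_width = settings$bin_width),
    error = function(e) c(homogeneity = NA_real_, entropy = NA_real_,
                          dissimilarity = NA_real_, hgre = NA_real_,
                          zlnu = NA_real_, szhge = NA_real_))
  shp <- shape_features(mask, mode = settings$shape_mode)
  c(suv_max = unname(basics["suv_max"]), suv_peak = peak,
    suv_mean = unname(basics["suv_mean"]), mt, tex, shp)
}

#' Feature extraction settings
#' @param G grey levels for quantization.
#' @param quantization quantization method.
#' @param bin_width bin width for fixed-width quantization, SUV.
#' @param suvpeak_mode see [suv_peak()].
#' @param shape_mode see [shape_elongation()].
#' @return A settings list.
#' @export
feature_settings <- function(G = 64L, quantization = "minmax", bin_width = 0.25,
                             suvpeak_mode = "max_over_centers",
                             shape_mode = "box3d") {
  list(G = as.integer(G), quantization = quantization, bin_width = bin_width,
       suvpeak_mode = suvpeak_mode, shape_mode = shape_mode)
}

#' Study run configuration
#'
#' Bundles the per-patient input manifest with every tunable setting of the
#' pipeline. The manifest has one row per patient: image paths per
#' timepoint (`post_image` may be `NA`: such patients join baseline-only
#' analyses and are excluded from delta analyses with a logged reason),
#' optional mask paths, the seed voxel and the background reference SUV.
#'
#' @param manifest data.frame with columns `id`, `baseline_image`,
#'   `post_image`, `baseline_mask`, `post_mask`, `seed_x`, `seed_y`,
#'   `seed_z`, `background`.
#' @param out_dir output directory for the run products.
#' @param cohort_csv optional path to the clinical table (survival
#'   endpoints, grades, covariates), joined by `id`.
#' @param features a [feature_settings()] list.
#' @param segmentation a [segmentation_params()].
#' @param stats list: `endpoints`, `candidates` (covariates screened; NULL
#'   means all baseline features plus clinical covariates),
#'   `inclusion_alpha`, `dichotomize`.
#' @param seed global RNG seed of the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest, out_dir, cohort_csv = NULL,
                       features = feature_settings(),
                       segmentation = segmentation_params(),
                       stats = list(endpoints = c("pfs", "os"),
                                    candidates = NULL,
                                    inclusion_alpha = 0.10,
                                    dichotomize = FALSE),
                       seed = 1L) {
  manifest <- as.data.frame(manifest)
  need <- c("id", "baseline_image", "seed_x", "seed_y", "seed_z", "background")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) stopf("manifest lacks columns: %s", paste(missing, collapse = ", "))
  if (nrow(manifest) == 0L) stopf("empty manifest")
  for (opt in c("post_image", "baseline_mask", "post_mask")) {
    if (!opt %in% names(manifest)) manifest[[opt]] <- NA_character_
  }
  structure(list(manifest = manifest, out_dir = out_dir,
                 cohort_csv = cohort_csv, features = features,
                 segmentation = segmentation, stats = stats,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read and write run configurations as YAML
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `path` invisibly; `read_run_config` returns the config.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$manifest <- lapply(seq_len(nrow(config$manifest)), function(i) {
    as.list(config$manifest[i, ])
  })
  x$segmentation <- unclass(x$segmentation)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  manifest <- do.call(rbind, lapply(x$manifest, function(r) {
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  run_config(manifest, out_dir = x$out_dir, cohort_csv = x$cohort_csv,
             features = do.call(feature_settings, x$features),
             segmentation = do.call(segmentation_params, x$segmentation),
             stats = x$stats, seed = x$seed)
}

mask_for_timepoint <- function(vol, mask_path, seed_voxel, background, segp) {
  if (!is.na(mask_path) && nzchar(mask_path)) {
    m <- read_lesion_mask(mask_path)
    check_aligned(vol, m)
    return(list(mask = m, flag = "supplied_mask"))
  }
  m <- adaptive_segment(vol, seed_voxel, background, segp)
  list(mask = m, flag = "adaptive_segment")
}

#' Extract features for one patient of a run
#'
#' Reads the patient's images, obtains the VOI (supplied mask if present,
#' otherwise adaptive segmentation; a non-delineable post-therapy lesion
#' falls back to the baseline VOI), and computes the per-timepoint feature
#' vectors plus percent deltas. A fallback VOI whose mean uptake does not
#' exceed the background reference is treated as complete metabolic
#' disappearance: `mtv = 0`, `tlg = 0`, flagged `no_residual_uptake`
#' (driving `delta_tlg` to -100).
#'
#' @param config a [run_config()].
#' @param patient one row of the manifest (or a patient `id`).
#' @return List with `baseline`, `post` (named feature vectors or `NULL`),
#'   `deltas`, and `flags` (character).
#' @export
extract_features <- function(config, patient) {
  if (is.character(patient)) {
    patient <- config$manifest[config$manifest$id == patient, ]
    if (nrow(patient) != 1L) stopf("patient id not found in manifest")
  }
  seedv <- c(patient$seed_x, patient$seed_y, patient$seed_z)
  bg <- patient$background
  flags <- character(0)

  vol_b <- read_suv_volume(patient$baseline_image, "baseline")
  mb <- mask_for_timepoint(vol_b, patient$baseline_mask, seedv, bg,
                           config$segmentation)
  flags <- c(flags, paste0("baseline:", mb$flag))
  fv_b <- lesion_features(vol_b, mb$mask, config$features)

  fv_p <- NULL
  deltas <- NULL
  if (is.na(patient$post_image) || !nzchar(patient$post_image)) {
    flags <- c(flags, "no_post_image")
    message(sprintf("[%s] no post-CHT image: baseline-only analyses", patient$id))
  } else {
    vol_p <- read_suv_volume(patient$post_image, "post_cht")
    mp <- tryCatch(
      mask_for_timepoint(vol_p, patient$post_mask, seedv, bg, config$segmentation),
      petsarc_not_delineable = function(e) {
        list(mask = fallback_voi(mb$mask, vol_p), flag = "fallback_voi")
      })
    flags <- c(flags, paste0("post:", mp$flag))
    fv_p <- lesion_features(vol_p, mp$mask, config$features)
    if (mp$flag == "fallback_voi" &&
        unname(suv_basic(vol_p, mp$mask)["suv_mean"]) <= bg) {
      fv_p["mtv"] <- 0
      fv_p["tlg"] <- 0
      flags <- c(flags, "no_residual_uptake")
    }
    deltas <- delta_percent(fv_b, fv_p)
  }
  list(baseline = fv_b, post = fv_p, deltas = deltas, flags = flags)
}

#' Simulate a complete synthetic study on disk
#'
#' Generates a survival cohort, renders one phantom response pair per
#' patient as NIfTI image files (a fraction of patients, as in real
#' practice, lack the post-chemotherapy study), links the simulated
#' histologic grade to the metabolic response (responders draw larger
#' uptake and volume reductions), and writes the cohort CSV plus a ready
#' [run_config()].
#'
#' @param out_dir directory to create the study in.
#' @param n_patients cohort size.
#' @param seed global seed; every random choice derives from it.
#' @param grid_shape,spacing phantom grid geometry.
#' @param post_fraction fraction of patients with a post-CHT study.
#' @param noise_sd intra-lesion noise SD, SUV.
#' @param cspec optional [cohort_spec()] override (its `n_patients` and
#'   `seed` are replaced by this function's arguments).
#' @return The [run_config()] of the simulated study.
#' @export
simulate_study <- function(out_dir, n_patients = 60L, seed = 1L,
                           grid_shape = c(36L, 36L, 36L), spacing = c(2, 2, 2),
                           post_fraction = 0.7, noise_sd = 0.1,
                           cspec = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  if (is.null(cspec)) cspec <- cohort_spec()
  cspec$n_patients <- as.integer(n_patients)
  cspec$seed <- as.integer(seed)
  cohort <- generate_cohort(cspec)
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort_csv(cohort, cohort_path)

  background <- 0.8
  # reference uptake for segmentation and PERCIST: background mean plus a
  # two-sigma noise margin, as a reference-region reading would give
  background_ref <- background + 2 * (noise_sd / 2)
  rows <- with_seed(seed + 1L, {
    lapply(seq_len(n_patients), function(i) {
      # lesion geometry: elongation covariate drives the long axis
      r0 <- stats::runif(1, 7, 11)
      el <- min(cohort$elongation[i], 2.2)
      semi <- c(r0 * el, r0, r0 * stats::runif(1, 0.9, 1.1))
      ctr <- (grid_shape + 1) / 2 + stats::runif(3, -1, 1)
      spec <- phantom_spec(
        grid_shape = grid_shape, spacing = spacing,
        background_suv = background, background_noise_sd = noise_sd / 2,
        lesion_center = ctr, semi_axes = semi,
        lesion_suv = max(cohort$suv_max[i], 2.5 * background),
        texture_pattern = list(type = "blobs", count = 4L,
                               amplitude = 0.25 * cohort$suv_max[i]),
        noise_sd = noise_sd, seed = seed + 100L + i)
      has_post <- stats::runif(1) < post_fraction
      responder <- cohort$salzer_kuntschik_grade[i] <= 3L
      u_scale <- if (responder) stats::runif(1, 0.05, 0.45) else stats::runif(1, 0.55, 1.05)
      v_scale <- if (responder) stats::runif(1, 0.15, 0.6) else stats::runif(1, 0.6, 1.1)
      pair <- generate_response_pair(spec, uptake_scale = u_scale,
                                     volume_scale = v_scale)
      bpath <- file.path(img_dir, sprintf("%s_baseline.nii.gz", cohort$id[i]))
      write_suv_volume(pair$baseline$volume, bpath)
      ppath <- NA_character_
      if (has_post) {
        ppath <- file.path(img_dir, sprintf("%s_post.nii.gz", cohort$id[i]))
        write_suv_volume(pair$post$volume, ppath)
      }
      data.frame(id = cohort$id[i], baseline_image = bpath, post_image = ppath,
                 baseline_mask = NA_character_, post_mask = NA_character_,
                 seed_x = round(ctr[1]), seed_y = round(ctr[2]),
                 seed_z = round(ctr[3]), background = background_ref,
                 stringsAsFactors = FALSE)
    })
  })
  manifest <- do.call(rbind, rows)
  config <- run_config(manifest, out_dir = out_dir, cohort_csv = cohort_path,
                       seed = seed)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  config
}

#' Run the end-to-end study
#'
#' Orchestrates the full analysis for every patient of the manifest:
#' feature extraction at both timepoints, percent deltas, PERCIST and
#' histologic response labels, and the Cox prognostic screen. Per-patient
#' failures are logged and do not abort the remaining patients. Writes
#' `features.csv`, `deltas.csv`, `response.csv`, `prognostics.csv` and
#' `run_manifest.json` (settings + package version + seed) into the
#' configured output directory; the run is deterministic under a fixed
#' configuration, so a rerun reproduces the outputs byte for byte.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the output paths and the assembled tables.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (!is.null(config$cohort_csv)) read_cohort_csv(config$cohort_csv) else NULL

  feat_rows <- list(); delta_rows <- list(); resp_rows <- list(); errors <- list()
  for (i in seq_len(nrow(config$manifest))) {
    pat <- config$manifest[i, ]
    ex <- tryCatch(extract_features(config, pat), error = function(e) e)
    if (inherits(ex, "error")) {
      message(sprintf("[%s] failed: %s", pat$id, conditionMessage(ex)))
      errors[[pat$id]] <- conditionMessage(ex)
      next
    }
    feat_rows[[length(feat_rows) + 1L]] <-
      data.frame(id = pat$id, timepoint = "baseline", t(ex$baseline),
                 stringsAsFactors = FALSE)
    if (!is.null(ex$post)) {
      feat_rows[[length(feat_rows) + 1L]] <-
        data.frame(id = pat$id, timepoint = "post_cht", t(ex$post),
                   stringsAsFactors = FALSE)
      delta_rows[[length(delta_rows) + 1L]] <-
        data.frame(id = pat$id, t(ex$deltas),
                   flags = paste(ex$flags, collapse = ";"),
                   stringsAsFactors = FALSE)
      resp_rows[[length(resp_rows) + 1L]] <- data.frame(
        id = pat$id,
        percist = percist_classify(ex$baseline[["suv_peak"]],
                                   ex$post[["suv_peak"]], pat$background),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(feat_rows)) stopf("no patient could be processed")
  features <- do.call(rbind, feat_rows)
  deltas <- if (length(delta_rows)) do.call(rbind, delta_rows) else NULL
  response <- if (length(resp_rows)) do.call(rbind, resp_rows) else NULL
  if (!is.null(response) && !is.null(cohort) &&
      "salzer_kuntschik_grade" %in% names(cohort)) {
    gr <- cohort$salzer_kuntschik_grade[match(response$id, cohort$id)]
    response$histologic <- ifelse(is.na(gr), NA_character_, histologic_responder(gr))
  }

  prognostics <- NULL
  if (!is.null(cohort) && all(c("pfs_days", "pfs_event") %in% names(cohort))) {
    base <- features[features$timepoint == "baseline", ]
    joined <- merge(cohort, base[, setdiff(names(base), "timepoint")], by = "id",
                    suffixes = c("_clinical", ""))
    cands <- config$stats$candidates
    if (is.null(cands)) {
      cands <- c("elongation", "sphericity", "compactness", "suv_max",
                 "suv_peak", "suv_mean", "mtv", "tlg", "homogeneity",
                 "entropy", "dissimilarity", "hgre", "zlnu", "szhge",
                 intersect(c("lung_metastasis", "bone_metastasis"), names(joined)))
      cands <- intersect(cands, names(joined))
    }
    keep <- vapply(cands, function(cv) {
      x <- joined[[cv]][stats::complete.cases(joined[[cv]])]
      ok <- length(unique(x)) > 1L
      if (!ok) message(sprintf("covariate '%s' skipped: constant", cv))
      ok
    }, logical(1))
    prognostics <- prognostic_screen(
      joined, cands[keep], endpoints = config$stats$endpoints,
      inclusion_alpha = config$stats$inclusion_alpha %||% 0.10,
      dichotomize = isTRUE(config$stats$dichotomize))
  }

  paths <- list(features = file.path(config$out_dir, "features.csv"),
                deltas = file.path(config$out_dir, "deltas.csv"),
                response = file.path(config$out_dir, "response.csv"),
                prognostics = file.path(config$out_dir, "prognostics.csv"),
                manifest = file.path(config$out_dir, "run_manifest.json"))
  utils::write.csv(features, paths$features, row.names = FALSE)
  if (!is.null(deltas)) utils::write.csv(deltas, paths$deltas, row.names = FALSE)
  if (!is.null(response)) utils::write.csv(response, paths$response, row.names = FALSE)
  if (!is.null(prognostics)) utils::write.csv(prognostics, paths$prognostics,
                                              row.names = FALSE)
  manifest_json <- list(
    package = "petsarc",
    version = as.character(utils::packageVersion("petsarc")),
    seed = config$seed,
    features = config$features,
    segmentation = unclass(config$segmentation),
    stats = config$stats,
    n_patients = nrow(config$manifest),
    n_processed = length(unique(features$id)),
    errors = errors
  )
  jsonlite::write_json(manifest_json, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, features = features, deltas = deltas,
                 response = response, prognostics = prognostics,
                 errors = errors))
}
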