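#' Pipeline configuration
#'
#' Reads and validates the pipeline configuration from YAML or JSON (or
#' an R list). Unknown top-level keys are rejected; missing sections get
#' package defaults.
#'
#' @param x Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) {
    x <- if (grepl("\\.ya?ml$", x)) yaml::read_yaml(x) else
      jsonlite::read_json(x, simplifyVector = TRUE)
  }
  stopifnot(is.list(x))
  known <- c("paths", "optics", "preprocess", "design", "space", "group",
             "simulate", "seed")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(known, collapse = ", "), call. = FALSE)
  cfg <- list(
    paths = x$paths %||% list(),
    optics = utils::modifyList(list(wavelengths = c(695, 830),
                                    distance = 3, age = 25), x$optics %||% list()),
    preprocess = do.call(preprocess_config, x$preprocess %||% list()),
    design = utils::modifyList(
      list(conditions = c("congruent", "incongruent"),
           basis = c("canonical", "derivative"),
           contrast = list(incongruent.canonical = 1,
                           congruent.canonical = -1),
           chromophore = "hbo"),
      x$design %||% list()),
    space = match.arg(x$space %||% "both", c("2d", "3d", "both")),
    group = utils::modifyList(list(alpha = 0.05, method = "rft"),
                              x$group %||% list()),
    simulate = utils::modifyList(
      list(N = 21, n_freq = 80, n_rare = 20, isi_range = c(9, 12),
           active_channels = c("CH24", "CH36", "CH47"),
           effect = c(congruent = 1, incongruent = 1),
           sigma_w = 0.3, sigma_b = 0.5, rho = 0.3),
      x$simulate %||% list()),
    seed = x$seed %||% 1L)
  if (!(cfg$group$alpha > 0 && cfg$group$alpha < 1))
    stop("group alpha must lie in (0, 1)", call. = FALSE)
  if (!cfg$group$method %in% c("rft", "bonferroni"))
    stop("group method must be rft or bonferroni", call. = FALSE)
  if (cfg$simulate$N < 2) stop("simulate N must be >= 2", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    class(x) <- NULL
  }
  x
}

provenance_record <- function(cfg, out_dir, extra = list()) {
  cfg <- strip_classes(cfg)
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  rec <- c(list(package = "nirstopo",
                version = as.character(utils::packageVersion("nirstopo")),
                config = unclass(cfg),
                config_checksum = sum(utf8ToInt(js)) %% 1e9,
                r_version = R.version.string),
           extra)
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes per-subject hemoglobin TSVs and event TSVs, the probe layout,
#' the ground-truth record (JSON) and a provenance record into
#' `out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, the list of subject file paths.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  cfg <- pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$simulate
  layout <- default_probe_layout(separation = cfg$optics$distance)
  truth <- simulation_truth(active_channels = sim$active_channels,
                            effect_size = sim$effect,
                            sigma_w = sim$sigma_w, sigma_b = sim$sigma_b,
                            rho = sim$rho, seed = cfg$seed)
  grp <- simulate_group(truth, layout, N = sim$N, n_freq = sim$n_freq,
                        n_rare = sim$n_rare, isi_range = sim$isi_range,
                        seed = cfg$seed)
  files <- list()
  for (s in grp$subjects) {
    hb_path <- file.path(out_dir, paste0(s$subject_id, "_hb.tsv"))
    ev_path <- file.path(out_dir, paste0(s$subject_id, "_events.tsv"))
    write_hb_table(s$hb, hb_path)
    write_events(s$events, ev_path)
    files[[s$subject_id]] <- list(hb = hb_path, events = ev_path)
  }
  write_layout(layout, file.path(out_dir, "layout.tsv"))
  write_truth(truth, file.path(out_dir, "truth.json"))
  provenance_record(cfg, out_dir, list(stage = "simulate"))
  message("simulated ", length(files), " subjects into ", out_dir)
  invisible(files)
}

#' Apply the temporal filter chain to design regressors
#'
#' Runs the linear part of the preprocessing chain (band-stop, DCT
#' high-pass projection, anti-aliased decimation; motion correction is
#' data-driven and excluded) on design-matrix columns, so the model sees
#' the same filters as the data.
#'
#' @param X M x L regressor matrix at the acquisition rate.
#' @param fs Acquisition sampling rate, Hz.
#' @param config A [preprocess_config()].
#' @return Filtered, decimated regressor matrix.
#' @export
filter_design <- function(X, fs, config = preprocess_config()) {
  X <- as.matrix(X)
  if (ncol(X) == 0) {
    keep <- seq(1, nrow(X), by = round(fs / config$target_fs))
    return(X[keep, , drop = FALSE])
  }
  wrap <- hb_series(X, X, fs, paste0("reg", seq_len(ncol(X))))
  wrap <- bandstop_physio(wrap, config$stopbands, config$filter_order)
  wrap <- dct_highpass(wrap, config$hp_cutoff)$hb
  wrap <- downsample_hb(wrap, config$target_fs)
  out <- wrap$hbo
  colnames(out) <- colnames(X)
  out
}

#' First-level channel contrasts from a preprocessed-ready series
#'
#' Runs the within-subject chain on one subject: temporal preprocessing,
#' design construction (canonical HRF and optionally its temporal
#' derivative), an initial OLS fit whose residuals give the global AR(1)
#' coefficient, a prewhitened refit, and the requested contrast.
#'
#' @param hb An [hb_series()].
#' @param events An [event_table()].
#' @param contrast Named contrast vector over design columns.
#' @param preprocess A [preprocess_config()] (or `NULL` to skip
#'   preprocessing).
#' @param basis HRF basis set.
#' @param conditions Declared condition labels.
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param subject_id Subject label.
#' @return List: `contrast` (`channel_contrast`), `fit` (`glm_fit`),
#'   `ar1` (`ar1_model`), `segments`.
#' @export
first_level_pipeline <- function(hb, events, contrast,
                                 preprocess = preprocess_config(),
                                 basis = c("canonical", "derivative"),
                                 conditions = NULL,
                                 chromophore = "hbo",
                                 subject_id = NA_character_) {
  segments <- NULL
  if (!is.null(preprocess)) {
    # filter data and model alike: the temporal filters are part of the
    # whitening-style filter matrix applied to both sides of the GLM, so
    # the task regressors receive the same band-stop, high-pass and
    # decimation as the data (otherwise the mismatch shrinks the
    # estimates)
    des0 <- build_design(events, nrow(hb$hbo), hb$fs, basis = basis,
                         conditions = conditions, add_constant = FALSE)
    pp <- preprocess_hb(hb, preprocess)
    hb <- pp$hb
    segments <- pp$segments
    Xf <- filter_design(des0$X, des0$fs, preprocess)
    des <- des0
    des$X <- cbind(Xf, constant = 1)
    des$column_names <- colnames(des$X)
    des$fs <- hb$fs
  } else {
    des <- build_design(events, nrow(hb$hbo), hb$fs, basis = basis,
                        conditions = conditions)
  }
  fit0 <- fit_glm(hb, des, S = NULL, chromophore = chromophore)
  ar1 <- estimate_ar1(fit0$residuals)
  S <- whitening_matrix(ar1, nrow(hb$hbo))
  fit <- fit_glm(hb, des, S = S, chromophore = chromophore)
  con <- contrast_channels(fit, contrast, subject_id = subject_id)
  list(contrast = con, fit = fit, ar1 = ar1, segments = segments)
}

#' Run the first level for all subjects and write contrast images
#'
#' For each subject: read data and events, run
#' [first_level_pipeline()], build the scalp geometry from the layout,
#' and write the 2D (NIfTI) and/or 3D (GIfTI) contrast images plus a
#' channel contrast TSV. Failures are isolated per subject and
#' re-raised together at the end.
#'
#' @param cfg A [pipeline_config()].
#' @param data_dir Directory produced by [cmd_simulate()] (or matching
#'   its naming scheme: `<sub>_hb.tsv`, `<sub>_events.tsv`,
#'   `layout.tsv`).
#' @param out_dir Output directory.
#' @return Invisibly, a data.frame of written image paths.
#' @export
cmd_first_level <- function(cfg, data_dir, out_dir) {
  cfg <- pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- read_layout(file.path(data_dir, "layout.tsv"))
  hb_files <- sort(Sys.glob(file.path(data_dir, "*_hb.tsv")))
  if (!length(hb_files)) stop("no *_hb.tsv files in ", data_dir,
                              call. = FALSE)
  proj <- project_channels_sphere(layout)
  xy <- project_channels_disc(proj)
  grid <- scalp_grid2d(64)
  mesh <- make_canonical_mesh(4, radius = proj$head_radius)
  mask2d <- make_search_mask(grid, xy, 30)
  mask3d <- make_search_mask(mesh, proj, 30)
  contrast <- unlist(cfg$design$contrast)
  rows <- list(); errors <- character()
  for (f in hb_files) {
    sid <- sub("_hb\\.tsv$", "", basename(f))
    res <- tryCatch({
      ev_file <- file.path(data_dir, paste0(sid, "_events.tsv"))
      if (!file.exists(ev_file)) stop("missing events file: ", ev_file)
      hb <- read_hb_table(f)
      ev <- read_events(ev_file)
      fl <- first_level_pipeline(hb, ev, contrast,
                                 preprocess = cfg$preprocess,
                                 basis = cfg$design$basis,
                                 conditions = cfg$design$conditions,
                                 chromophore = cfg$design$chromophore,
                                 subject_id = sid)
      out <- list(subject = sid)
      write_contrast_table(fl$contrast,
                           file.path(out_dir, paste0(sid, "_contrast.tsv")))
      if (cfg$space %in% c("2d", "both")) {
        img <- contrast_image_2d(fl$contrast, xy, grid, fwhm = 14,
                                 mask = mask2d, subject_id = sid)
        p <- file.path(out_dir, paste0(sid, "_contrast_grid2d.nii"))
        write_image(img, p); out$nii <- p
      }
      if (cfg$space %in% c("3d", "both")) {
        img <- contrast_image_mesh(fl$contrast, proj, mesh, m = 4,
                                   mask = mask3d, subject_id = sid)
        p <- file.path(out_dir, paste0(sid, "_contrast_mesh3d.gii"))
        write_image(img, p); out$gii <- p
      }
      out
    }, error = function(e) {
      errors <<- c(errors, paste0(sid, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[sid]] <- res
  }
  write_gifti_surface(mesh, file.path(out_dir, "scalp_mesh.surf.gii"))
  provenance_record(cfg, out_dir, list(stage = "first_level",
                                       subjects = names(rows)))
  if (length(errors))
    stop("first level failed for ", length(errors), " subject(s):\n",
         paste(errors, collapse = "\n"), call. = FALSE)
  invisible(do.call(rbind, lapply(rows, function(r)
    data.frame(subject = r$subject,
               nii = r$nii %||% NA, gii = r$gii %||% NA))))
}

#' Group-level inference on first-level images
#'
#' Reads the per-subject contrast images of one space, runs the
#' random-effects fit with the chosen multiple-comparison correction,
#' and writes the results table, the group T map, and provenance.
#'
#' @param cfg A [pipeline_config()].
#' @param image_dir Directory with `cmd_first_level()` outputs.
#' @param out_dir Output directory.
#' @param space `"2d"` or `"3d"` (default from config; `both` runs 2d).
#' @return The `inference_result`, invisibly.
#' @export
cmd_group <- function(cfg, image_dir, out_dir, space = NULL) {
  cfg <- pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(space)) space <- if (cfg$space == "3d") "3d" else "2d"
  if (space == "2d") {
    files <- sort(Sys.glob(file.path(image_dir, "*_grid2d.nii")))
    geometry <- NULL
    images <- lapply(files, function(f)
      read_image(f, subject_id = sub("_contrast_grid2d\\.nii$", "",
                                     basename(f))))
  } else {
    files <- sort(Sys.glob(file.path(image_dir, "*_mesh3d.gii")))
    geometry <- read_gifti_surface(file.path(image_dir,
                                             "scalp_mesh.surf.gii"))
    images <- lapply(files, function(f)
      read_image(f, geometry,
                 subject_id = sub("_contrast_mesh3d\\.gii$", "",
                                  basename(f))))
  }
  if (length(images) < 2) stop("need >= 2 contrast images in one space",
                               call. = FALSE)
  if (cfg$group$method == "bonferroni") {
    cons <- sort(Sys.glob(file.path(image_dir, "*_contrast.tsv")))
    W <- do.call(rbind, lapply(cons, function(f)
      utils::read.delim(f)$w))
    colnames(W) <- utils::read.delim(cons[1])$channel
    inf <- run_group_inference(method = "bonferroni", channel_w = W,
                               alpha = cfg$group$alpha)
  } else {
    inf <- run_group_inference(images, alpha = cfg$group$alpha,
                               method = "rft")
    tmap <- contrast_image(inf$fit$space, ifelse(inf$fit$mask, inf$fit$T, NA),
                           inf$fit$mask, images[[1]]$geometry, "group")
    ext <- if (space == "2d") "group_T.nii" else "group_T.gii"
    write_image(tmap, file.path(out_dir, ext))
  }
  write_results_table(inf, file.path(out_dir, "results.tsv"))
  provenance_record(cfg, out_dir, list(stage = "group", space = space,
                                       n_images = length(images)))
  invisible(inf)
}
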