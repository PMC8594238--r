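#' Default pipeline run configuration
#'
#' Nested parameter blocks for the simulate/measure/analyze pipeline.
#' Any subset can be overridden from a YAML file ([read_run_config()]);
#' unknown keys are rejected.
#'
#' Blocks: `seed` (master seed; every stage derives substreams from it),
#' `out_dir`, `phantom` (`n_eyes`, `modality`, `overrides` applied onto
#' [phantom_config()]), `cohort` (`design`: `"rvo"`, `"dr"` or
#' `"none"`), `roi` ([build_iris_rois()] parameters), `binarize`
#' ([binarize_config()] parameters), `measure` (`n_replicates`,
#' `input_dir`, `auto_landmarks`), `analyze` (`input_csv`,
#' `correction`), `log_level` (`"quiet"`, `"info"` or `"debug"`).
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "octairis_out",
    phantom = list(n_eyes = 3L, modality = "iris", overrides = list()),
    cohort = list(design = "rvo"),
    roi = list(half_height = 150, span = 150, mode = "nested"),
    binarize = list(method = "otsu", tophat_radius = 0,
                    adaptive_window = 31L, adaptive_offset = 10,
                    min_object_px = 4L, threshold_jitter_sd = 0),
    measure = list(n_replicates = 3L, input_dir = NULL,
                   auto_landmarks = FALSE),
    analyze = list(input_csv = NULL, correction = "none"),
    log_level = "info"
  ), class = "run_config")
}

check_config_keys <- function(user, template, path = "") {
  unknown <- setdiff(names(user), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        nm != "overrides" && is.list(user[[nm]]))
      check_config_keys(user[[nm]], template[[nm]],
                        paste0(path, nm, "."))
  }
  invisible(user)
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file, validates it against the schema of
#' [default_run_config()] (unknown keys are an error), and merges it
#' onto the defaults.
#'
#' @param path YAML file path; `NULL` returns the defaults
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  check_config_keys(user, cfg)
  out <- modifyList(cfg, user)
  class(out) <- "run_config"
  out
}

log_msg <- function(config, level, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  want <- levels[[match.arg(config$log_level, names(levels))]]
  if (levels[[level]] <= want && want > 0)
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

manifest_entry <- function(path) {
  list(path = basename(path), md5 = unname(tools::md5sum(path)))
}

#' Simulate phantom eyes and a cohort table to disk
#'
#' Writes one phantom angiogram (PNG) and landmark JSON per simulated
#' eye, a simulated cohort CSV, and a manifest JSON recording the master
#' seed and an MD5 checksum per file: rerunning with the same seed
#' reproduces identical checksums.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()])
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config = default_run_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out) || file.access(out, 2L) != 0L)
    stop("output directory is not writable: ", out, call. = FALSE)
  files <- list()
  n_eyes <- config$phantom$n_eyes
  if (n_eyes == 0L) {
    warning("phantom.n_eyes = 0: no phantom eyes simulated",
            call. = FALSE)
  }
  for (i in seq_len(n_eyes)) {
    base <- phantom_config(modality = config$phantom$modality)
    overrides <- config$phantom$overrides
    overrides$seed <- substream_seed(config$seed, i)
    overrides$modality <- config$phantom$modality
    cfg <- do.call(phantom_config, modifyList(
      base[setdiff(names(base), "modality")], overrides))
    ph <- if (config$phantom$modality == "iris")
      generate_iris_phantom(cfg) else generate_macula_phantom(cfg)
    img_path <- file.path(out, sprintf("eye_%03d.png", i))
    write_angiogram(ph$image, img_path)
    files <- c(files, list(manifest_entry(img_path)))
    if (!is.null(ph$landmarks)) {
      lm_path <- file.path(out, sprintf("eye_%03d_landmarks.json", i))
      write_landmarks(ph$landmarks, lm_path)
      files <- c(files, list(manifest_entry(lm_path)))
    }
    log_msg(config, "debug", "wrote ", img_path)
  }
  design_name <- config$cohort$design
  if (identical(design_name, "none")) {
    cohort <- generate_cohort(design_rvo_cohort(config$seed))[0, ]
    warning("cohort.design = \"none\": writing an empty cohort table",
            call. = FALSE)
  } else {
    design <- switch(design_name,
      rvo = design_rvo_cohort(config$seed),
      dr = design_dr_cohort(config$seed),
      stop("unknown cohort design: ", design_name, call. = FALSE))
    cohort <- generate_cohort(design)
  }
  cohort_path <- file.path(out, "cohort.csv")
  write_cohort_csv(cohort, cohort_path)
  files <- c(files, list(manifest_entry(cohort_path)))
  manifest <- list(seed = config$seed,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   n_eyes = n_eyes, files = files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg(config, "info", "simulated ", n_eyes, " eye(s) and ",
          nrow(cohort), " cohort record(s) into ", out)
  invisible(manifest)
}

#' Measure VAD/VSD for every simulated eye on disk
#'
#' Reads each `eye_*.png` in the input directory with its landmark JSON
#' (or automatic detection when `measure.auto_landmarks` is set), runs
#' [measure_eye()], and writes `metrics.csv` with one row per eye,
#' segment and replicate plus averaged rows (`replicate = "mean"`).
#'
#' @param config a `run_config`
#' @return The metrics data.frame, invisibly.
#' @export
run_measure <- function(config = default_run_config()) {
  in_dir <- config$measure$input_dir
  if (is.null(in_dir)) in_dir <- config$out_dir
  imgs <- sort(list.files(in_dir, pattern = "^eye_[0-9]+\\.png$",
                          full.names = TRUE))
  if (length(imgs) == 0L)
    stop("no eye_*.png images found in ", in_dir, call. = FALSE)
  bcfg <- do.call(binarize_config, config$binarize)
  modality <- config$phantom$modality
  all_rows <- list()
  for (path in imgs) {
    sid <- sub("\\.png$", "", basename(path))
    img <- tryCatch(read_angiogram(path, modality = modality),
                    error = function(e)
                      stop("failed to read image file ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    lm <- NULL
    if (modality == "iris") {
      lm_path <- file.path(in_dir, paste0(sid, "_landmarks.json"))
      if (file.exists(lm_path)) {
        lm <- read_landmarks(lm_path)
      } else if (isTRUE(config$measure$auto_landmarks)) {
        lm <- locate_landmarks(img)
      } else {
        stop("missing landmark file for ", basename(path),
             " (enable measure.auto_landmarks for automatic detection)",
             call. = FALSE)
      }
    }
    pm <- measure_eye(img, lm, n_replicates = config$measure$n_replicates,
                      config = bcfg,
                      half_height = config$roi$half_height,
                      span = config$roi$span, mode = config$roi$mode,
                      seed = config$seed)
    rep_rows <- data.frame(subject_id = sid, eye = img$eye,
                           pm$replicates, stringsAsFactors = FALSE)
    mean_rows <- data.frame(subject_id = sid, eye = img$eye,
                            segment = pm$summary$segment,
                            replicate = "mean",
                            vad = pm$summary$vad, vsd = pm$summary$vsd,
                            stringsAsFactors = FALSE)
    rep_rows$replicate <- as.character(rep_rows$replicate)
    all_rows <- c(all_rows, list(rep_rows, mean_rows))
    log_msg(config, "debug", "measured ", sid)
  }
  metrics <- do.call(rbind, all_rows)
  out_path <- file.path(config$out_dir, "metrics.csv")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(metrics, out_path, row.names = FALSE)
  log_msg(config, "info", "wrote ", out_path, " (", nrow(metrics),
          " rows)")
  invisible(metrics)
}

#' Analyze a cohort table into comparison and segment-trend reports
#'
#' Reads a cohort CSV (wide format with a `group` column, as written by
#' [run_simulate()]), computes the group-comparison report and, when the
#' iris segment metrics are present, the per-segment deviation summary;
#' writes `report.csv` (full precision), `report.md` (formatted) and
#' `segments.csv`.
#'
#' @param config a `run_config`
#' @return A list with `report` and (possibly `NULL`) `segments`,
#'   invisibly.
#' @export
run_analyze <- function(config = default_run_config()) {
  path <- config$analyze$input_csv
  if (is.null(path)) path <- file.path(config$out_dir, "cohort.csv")
  cohort <- read_cohort_csv(path)
  if (nrow(cohort) == 0L)
    stop("cohort CSV is empty: ", path, call. = FALSE)
  if (!"group" %in% names(cohort))
    stop("cohort CSV has no `group` column: ", path, call. = FALSE)
  report <- group_comparison_report(
    cohort, correction = config$analyze$correction)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$raw, file.path(config$out_dir, "report.csv"),
            row.names = FALSE)
  writeLines(report_markdown(report),
             file.path(config$out_dir, "report.md"))
  segments <- NULL
  segs <- c("one_third", "two_thirds", "full")
  if (all(c(paste0("iris_vad_", segs), paste0("iris_vsd_", segs)) %in%
            names(cohort))) {
    segments <- segment_deviation_summary(cohort)
    write.csv(segments, file.path(config$out_dir, "segments.csv"),
              row.names = FALSE)
  }
  log_msg(config, "info", "analysis reports written to ",
          config$out_dir)
  invisible(list(report = report, segments = segments))
}
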