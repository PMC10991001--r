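#' Create a validation project
#'
#' A project is a directory that collects recordings, the poster
#' configuration, processing parameters and results, mirroring the
#' import - annotate - process - export workflow. Each recording moves
#' through the statuses `not_imported`, `imported`, `episodes_annotated`,
#' `dq_computed`, in that order only.
#'
#' @param path Project directory (created; must not already contain a
#'   project).
#' @param poster A `poster_spec` (stored as `poster.json`).
#' @param mode `"pose_estimated"` or `"fixed_distance"`.
#' @param assumed_distance Assumed perpendicular viewing distance, mm.
#' @param params A `classifier_params`.
#' @return The project path, invisibly.
#' @export
project_init <- function(path, poster = default_poster(),
                         mode = c("pose_estimated", "fixed_distance"),
                         assumed_distance = poster$assumed_distance,
                         params = classifier_params()) {
  mode <- match.arg(mode)
  if (file.exists(file.path(path, "config.json"))) {
    stop("project already exists at ", path, call. = FALSE)
  }
  dir.create(file.path(path, "recordings"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "results"), showWarnings = FALSE)
  save_poster(poster, file.path(path, "poster.json"))
  cfg <- list(mode = mode, assumed_distance_mm = assumed_distance,
              classifier = unclass(params))
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(structure(list(), names = character(0)),
                       file.path(path, "status.json"), auto_unbox = TRUE)
  invisible(path)
}

read_project_config <- function(path) {
  cfgp <- file.path(path, "config.json")
  if (!file.exists(cfgp)) stop("not a project directory: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
  cfg$poster <- load_poster(file.path(path, "poster.json"))
  cfg$params <- do.call(classifier_params, as.list(cfg$classifier))
  cfg
}

read_status <- function(path) {
  st <- jsonlite::read_json(file.path(path, "status.json"), simplifyVector = TRUE)
  if (is.null(names(st))) st <- structure(list(), names = character(0))
  st
}

write_status <- function(path, st) {
  jsonlite::write_json(as.list(st), file.path(path, "status.json"),
                       auto_unbox = TRUE)
}

#' Recording statuses of a project
#'
#' @param path Project directory.
#' @return data.frame with `recording` and `status`.
#' @export
project_status <- function(path) {
  st <- read_status(path)
  data.frame(recording = names(st),
             status = unlist(st, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Import recordings into a project
#'
#' Copies interchange-format recording directories into the project and
#' validates them on the way in. A malformed recording is reported and
#' skipped; the others proceed. Re-importing an already imported recording
#' is idempotent.
#'
#' @param path Project directory.
#' @param recording_dirs Character vector of recording directories.
#' @return data.frame with `recording`, `imported` (logical) and `error`
#'   (message or `NA`).
#' @export
project_import <- function(path, recording_dirs) {
  cfg <- read_project_config(path)  # also validates the project
  st <- read_status(path)
  res <- data.frame(recording = basename(recording_dirs), imported = FALSE,
                    error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(recording_dirs)) {
    name <- basename(recording_dirs[i])
    ok <- tryCatch({
      rec <- read_recording(recording_dirs[i])  # validation happens here
      dest <- file.path(path, "recordings", name)
      write_recording(rec, dest)
      TRUE
    }, error = function(e) {
      res$error[i] <<- conditionMessage(e)
      FALSE
    })
    if (ok) {
      res$imported[i] <- TRUE
      if (is.null(st[[name]]) || st[[name]] == "not_imported") {
        st[[name]] <- "imported"
      }
    }
  }
  write_status(path, st)
  res
}

#' Annotate the validation episodes of an imported recording
#'
#' Replaces the recording's episode table with the given annotations
#' (a data.frame or a CSV with columns `start_ms`, `end_ms`, `label`) and
#' advances its status.
#'
#' @param path Project directory.
#' @param name Recording name (as imported).
#' @param episodes data.frame or CSV path.
#' @return The project path, invisibly.
#' @export
project_annotate <- function(path, name, episodes) {
  st <- read_status(path)
  if (is.null(st[[name]])) {
    stop("recording '", name, "' has not been imported; run project_import first",
         call. = FALSE)
  }
  if (is.character(episodes)) episodes <- utils::read.csv(episodes)
  rec_dir <- file.path(path, "recordings", name)
  rec <- read_recording(rec_dir)
  rec <- recording(rec$gaze, rec$markers, episodes, rec$calibration, rec$meta)
  write_recording(rec, rec_dir)
  if (st[[name]] == "imported") st[[name]] <- "episodes_annotated"
  write_status(path, st)
  invisible(path)
}

#' Process annotated recordings
#'
#' Runs the full data-quality chain (gaze mapping, fixation classification,
#' target matching, accuracy/precision/data loss/gaze range) for each
#' validation episode of the named recordings and stores per-target result
#' rows under `results/`, together with a provenance log (poster file hash,
#' mode, parameter values).
#'
#' @param path Project directory.
#' @param names Recording names; default all annotated recordings.
#' @return Named list of `episode_dq_list` results, invisibly.
#' @export
project_process <- function(path, names = NULL) {
  cfg <- read_project_config(path)
  st <- read_status(path)
  if (is.null(names)) {
    names <- names(st)[unlist(st) %in% c("episodes_annotated", "dq_computed")]
  }
  out <- list()
  for (name in names) {
    if (is.null(st[[name]])) {
      stop("recording '", name, "' has not been imported", call. = FALSE)
    }
    if (st[[name]] == "imported") {
      stop("recording '", name,
           "' has no episode annotations; run project_annotate first",
           call. = FALSE)
    }
    rec <- read_recording(file.path(path, "recordings", name))
    mode <- cfg$mode
    if (mode == "pose_estimated" && is.null(rec$calibration)) {
      mode <- "fixed_distance"
      warning("recording '", name,
              "' has no calibration; falling back to fixed_distance mode",
              call. = FALSE)
    }
    dq <- compute_data_quality(rec, cfg$poster, mode = mode,
                               assumed_distance = cfg$assumed_distance_mm,
                               params = cfg$params)
    out[[name]] <- dq
    rows <- summarize_data_quality(stats::setNames(list(dq), name))
    utils::write.csv(rows, file.path(path, "results", paste0(name, ".csv")),
                     row.names = FALSE)
    log <- list(recording = name, mode = mode,
                poster_md5 = unname(tools::md5sum(file.path(path, "poster.json"))),
                assumed_distance_mm = cfg$assumed_distance_mm,
                classifier = cfg$classifier,
                processed_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(log, file.path(path, "results", paste0(name, ".log.json")),
                         auto_unbox = TRUE, digits = NA)
    st[[name]] <- "dq_computed"
  }
  write_status(path, st)
  invisible(out)
}

#' Export a project summary
#'
#' Concatenates the per-target result rows of all processed recordings into
#' one summary CSV; with `average_over_targets` the measures are averaged
#' over the matched targets of each recording x episode first.
#'
#' @param path Project directory.
#' @param out_csv Output CSV path (default `summary.csv` in the project).
#' @param average_over_targets Average over targets (default FALSE).
#' @return The summary data.frame, invisibly.
#' @export
project_export <- function(path, out_csv = file.path(path, "summary.csv"),
                           average_over_targets = FALSE) {
  st <- read_status(path)
  done <- names(st)[unlist(st) == "dq_computed"]
  if (!length(done)) stop("no processed recordings to export", call. = FALSE)
  rows <- do.call(rbind, lapply(done, function(name) {
    utils::read.csv(file.path(path, "results", paste0(name, ".csv")))
  }))
  if (average_over_targets) {
    key <- interaction(rows$recording, rows$episode, drop = TRUE)
    agg <- lapply(split(rows, key), function(g) {
      data.frame(recording = g$recording[1], episode = g$episode[1],
                 target_id = "mean",
                 accuracy_deg = mean(g$accuracy_deg, na.rm = TRUE),
                 rms_s2s_deg = mean(g$rms_s2s_deg, na.rm = TRUE),
                 std_deg = mean(g$std_deg, na.rm = TRUE),
                 data_loss_percent = g$data_loss_percent[1],
                 gaze_range_h_deg = g$gaze_range_h_deg[1],
                 gaze_range_v_deg = g$gaze_range_v_deg[1],
                 viewing_distance_mm = mean(g$viewing_distance_mm, na.rm = TRUE),
                 mode = g$mode[1], n_samples = sum(g$n_samples),
                 n_unmatched = g$n_unmatched[1])
    })
    rows <- do.call(rbind, agg)
    rownames(rows) <- NULL
  }
  utils::write.csv(rows, out_csv, row.names = FALSE)
  invisible(rows)
}
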