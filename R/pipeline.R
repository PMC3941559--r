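#' Pipeline configuration
#'
#' Collects the knobs shared by the pipeline stages. Defaults follow the
#' measurement protocol: 13 mm adhesive markers, Tiffeneau screening at
#' 0.80, user-supplied support-surface baseline, threshold-based detector.
#'
#' @param marker_diameter_mm Physical marker diameter used for scale
#'   calibration, mm.
#' @param tiffeneau_threshold FEV1/FVC ratio below which a subject is
#'   excluded.
#' @param axis_direction Craniocaudal direction of the image x axis.
#' @param baseline_y_px Image row of the support surface when not given
#'   per-frame (manual-coordinate input); `NULL` means it must come from
#'   the input files.
#' @param fvc_lower_limit Optional FVC lower limit (l) flagging possible
#'   restriction; `NULL` disables it.
#' @param detector Detection backend (only `"threshold"` is provided).
#' @param out_dir Output directory for pipeline products.
#' @param seed Integer RNG seed for stages that sample.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(marker_diameter_mm = 13,
                            tiffeneau_threshold = 0.80,
                            axis_direction = c("x_increasing_caudal",
                                               "x_decreasing_caudal"),
                            baseline_y_px = NULL,
                            fvc_lower_limit = NULL,
                            detector = "threshold",
                            out_dir = ".",
                            seed = 1L) {
  axis_direction <- match.arg(axis_direction)
  if (marker_diameter_mm <= 0 || tiffeneau_threshold <= 0)
    stop_usage("thresholds must be positive")
  structure(list(marker_diameter_mm = marker_diameter_mm,
                 tiffeneau_threshold = tiffeneau_threshold,
                 axis_direction = axis_direction,
                 baseline_y_px = baseline_y_px,
                 fvc_lower_limit = fvc_lower_limit,
                 detector = detector, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration file (YAML), with overrides
#'
#' File values replace the defaults; anything in `overrides` (e.g. parsed
#' command-line flags) wins over the file.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list of settings taking precedence.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_usage(sprintf("config file not found: %s", path))
    vals <- yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_usage(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, vals)
}

log_jsonl <- function(logfile, event, ...) {
  if (is.null(logfile)) return(invisible(NULL))
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                package = "photoresp",
                version = as.character(utils::packageVersion("photoresp")),
                event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = logfile,
      append = TRUE, sep = "")
  invisible(NULL)
}

volumes_row <- function(subject_id, phase, vol, mobility = NA_real_) {
  data.frame(subject_id = subject_id, phase = phase,
             UT_l = vol[["UT"]], LT_l = vol[["LT"]], TT_l = vol[["TT"]],
             UA_l = vol[["UA"]], LA_l = vol[["LA"]], TA_l = vol[["TA"]],
             thoracoabdominal_l = vol[["thoracoabdominal"]],
             mobility_l = mobility, stringsAsFactors = FALSE)
}

write_volumes_csv <- function(volumes, path) {
  out <- volumes
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 2)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Simulate a complete study fixture set
#'
#' Generates a synthetic assessment cohort and writes everything the
#' measurement pipeline consumes: a subject table with spirometry, paired
#' expiration/inspiration frames (8-bit grayscale PNG), a frame index with
#' per-frame support-surface baselines, and the ground-truth marker
#' coordinates and volumes.
#'
#' Defaults reproduce the reference study's screening composition: 50
#' assessed adolescents of whom 7 show a Tiffeneau index below 0.80 and 3
#' a restrictive pattern (low FVC), leaving 40 analyzable. Retained
#' subjects' measured FVC is bounded to the analyzed cohort's observed
#' range; restrictive subjects get FVC in 1.2-1.8 l so a 2.0 l lower
#' limit separates them.
#'
#' @param out_dir Output directory (created if missing).
#' @param n Number of subjects assessed.
#' @param seed Master integer seed; the whole fixture set is a
#'   deterministic function of it.
#' @param n_obstruction,n_restriction Number of subjects given an
#'   obstructive (Tiffeneau < 0.80) or restrictive (low FVC) spirometry
#'   pattern; defaults keep the reference study's 7:3:40 composition,
#'   scaled proportionally when `n` differs from 50.
#' @param noise_sd Gaussian pixel noise SD for the rendered frames
#'   (8-bit gray levels).
#' @param write_frames Render and write PNG frames (disable for fast
#'   coordinate-only fixtures).
#' @return Invisibly, a list with `subjects` (data frame including
#'   spirometry and true mobility), `truth_markers`, `truth_volumes`,
#'   `frames_index` and the file `paths`.
#' @export
simulate_breathing_cohort <- function(out_dir, n = 50, seed = 1,
                                      n_obstruction = round(7 * n / 50),
                                      n_restriction = round(3 * n / 50),
                                      noise_sd = 0, write_frames = TRUE) {
  if (n < 1) stop_usage("n must be >= 1")
  if (n_obstruction + n_restriction > n)
    stop_usage("more flagged subjects than subjects")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_data(sprintf("cannot create directory %s", out_dir))
  logfile <- file.path(out_dir, "pipeline_log.jsonl")

  subjects <- sample_cohort(n, seed = seed)
  status <- rep("retained", n)
  pick <- with_rng(seed, sample.int(n, n_obstruction + n_restriction))
  status[pick[seq_len(n_obstruction)]] <- "obstruction"
  if (n_restriction > 0)
    status[pick[n_obstruction + seq_len(n_restriction)]] <- "restriction"

  seeds <- child_seeds(seed + 1L, 4L * n)
  sub_rows <- list(); mk_rows <- list(); vol_rows <- list(); idx_rows <- list()
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    mob <- sample_mobility(s, rng_seed = seeds[4 * i - 3])
    kt <- make_kinematics(s, mob, rng_seed = seeds[4 * i - 2])
    spiro <- switch(status[i],
      retained    = sample_spirometry(s, mob, rng_seed = seeds[4 * i - 1]),
      obstruction = sample_spirometry(s, mob, rng_seed = seeds[4 * i - 1],
                                      tiffeneau_range = c(0.60, 0.78)),
      restriction = sample_spirometry(s, mob, rng_seed = seeds[4 * i - 1],
                                      fvc_range = c(1.2, 1.8)))
    sub_rows[[i]] <- cbind(subjects_to_df(list(s)),
                           data.frame(FEV1_l = spiro$FEV1, FVC_l = spiro$FVC,
                                      PEF_l_s = spiro$PEF, DI_l = spiro$DI,
                                      true_mobility_l = kt$true_mobility,
                                      status = status[i]))
    for (ph in c("expiration", "inspiration")) {
      ms <- if (ph == "expiration") kt$marker_exp else kt$marker_insp
      mk_rows[[length(mk_rows) + 1]] <-
        data.frame(subject_id = s$subject_id, phase = ph, landmark = ms$landmark,
                   x_cm = ms$x_cm, y_cm = ms$y_cm, stringsAsFactors = FALSE)
      vol <- if (ph == "expiration") kt$true_volumes_exp else kt$true_volumes_insp
      vol_rows[[length(vol_rows) + 1]] <-
        volumes_row(s$subject_id, ph, vol,
                    mobility = if (ph == "inspiration") kt$true_mobility else NA_real_)
      if (write_frames) {
        fr <- render_frame(kt, ph, s, noise_sd = noise_sd,
                           rng_seed = seeds[4 * i] + (ph == "inspiration"))
        file <- file.path(out_dir, sprintf("%s_%s.png", s$subject_id, ph))
        write_frame_png(fr, file)
        idx_rows[[length(idx_rows) + 1]] <-
          data.frame(subject_id = s$subject_id, phase = ph,
                     file = basename(file), baseline_y_px = fr$baseline_y_px,
                     stringsAsFactors = FALSE)
      }
    }
  }
  subjects_df <- do.call(rbind, sub_rows)
  truth_markers <- do.call(rbind, mk_rows)
  truth_volumes <- do.call(rbind, vol_rows)
  frames_index <- if (write_frames) do.call(rbind, idx_rows) else NULL

  paths <- list(subjects = file.path(out_dir, "subjects.csv"),
                truth_markers = file.path(out_dir, "truth_markers.csv"),
                truth_volumes = file.path(out_dir, "truth_volumes.csv"),
                frames_index = file.path(out_dir, "frames_index.csv"))
  write.csv(subjects_df, paths$subjects, row.names = FALSE, quote = FALSE)
  write.csv(truth_markers, paths$truth_markers, row.names = FALSE, quote = FALSE)
  write_volumes_csv(truth_volumes, paths$truth_volumes)
  if (write_frames)
    write.csv(frames_index, paths$frames_index, row.names = FALSE, quote = FALSE)
  log_jsonl(logfile, "simulate", n = n, seed = seed, noise_sd = noise_sd,
            n_obstruction = n_obstruction, n_restriction = n_restriction,
            out_dir = out_dir)
  invisible(list(subjects = subjects_df, truth_markers = truth_markers,
                 truth_volumes = truth_volumes, frames_index = frames_index,
                 subject_specs = subjects, paths = paths))
}

markers_from_frame <- function(path, baseline_y_px, config) {
  det <- detect_markers(path)
  cal <- calibrate(det, reference_diameter_mm = config$marker_diameter_mm)
  assign_landmarks(det, cal, baseline_y_px = baseline_y_px,
                   axis_direction = config$axis_direction)
}

markers_from_coords <- function(rows, baseline_y_px, config) {
  cal <- calibrate(data.frame(diameter = rows$diameter_px),
                   reference_diameter_mm = config$marker_diameter_mm)
  det <- data.frame(center_x = rows$x_px, center_y = rows$y_px,
                    diameter = rows$diameter_px, circularity = 1)
  assign_landmarks(det, cal, baseline_y_px = baseline_y_px,
                   axis_direction = config$axis_direction)
}

#' Measure compartment volumes for a cohort
#'
#' Runs the measurement chain (detect markers, calibrate scale, label
#' landmarks, build compartments, extrude, pair phases) for every subject,
#' from rendered/recorded frames or from pre-digitized marker coordinates.
#'
#' @param input Either a frame-index CSV (columns `subject_id`, `phase`,
#'   `file`, `baseline_y_px`; `file` relative to the index's directory)
#'   or a manual-coordinate CSV (columns `subject_id`, `phase`,
#'   `landmark`, `x_px`, `y_px`, `diameter_px`, optionally
#'   `baseline_y_px`).
#' @param subjects_csv Subject table CSV with columns `subject_id` and
#'   `thorax_cm` (extrusion depth per subject).
#' @param config A [pipeline_config].
#' @param out_dir Directory for `volumes.csv` and the run log; `NULL`
#'   skips writing.
#' @return List with `volumes` (data frame, one row per subject and
#'   phase, spec columns `UT_l` ... `mobility_l`) and `errors` (data
#'   frame of per-subject failures, zero rows on full success).
#' @export
measure_cohort <- function(input, subjects_csv, config = pipeline_config(),
                           out_dir = NULL) {
  if (!file.exists(input)) stop_usage(sprintf("input not found: %s", input))
  if (!file.exists(subjects_csv)) stop_usage(sprintf("subject table not found: %s", subjects_csv))
  subjects <- read.csv(subjects_csv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "thorax_cm") %in% names(subjects)))
    stop_data("subject table must have subject_id and thorax_cm columns")

  hdr <- names(read.csv(input, nrows = 1, stringsAsFactors = FALSE))
  mode <- if (all(c("file", "baseline_y_px") %in% hdr)) "frames"
          else if (all(c("landmark", "x_px", "y_px", "diameter_px") %in% hdr)) "coords"
          else stop_data("input CSV is neither a frame index nor a marker-coordinate table")
  tab <- if (mode == "coords") read_marker_coordinates(input)
         else read.csv(input, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop_usage("empty input table")
  base_dir <- dirname(input)

  vol_rows <- list(); err_rows <- list()
  for (sid in unique(tab$subject_id)) {
    res <- tryCatch({
      srow <- subjects[subjects$subject_id == sid, , drop = FALSE]
      if (nrow(srow) != 1) stop_data(sprintf("subject %s missing from subject table", sid))
      phases <- list()
      for (ph in c("expiration", "inspiration")) {
        rows <- tab[tab$subject_id == sid & tab$phase == ph, , drop = FALSE]
        if (nrow(rows) == 0)
          stop_data(sprintf("subject %s: missing %s phase", sid, ph))
        ms <- if (mode == "frames") {
          markers_from_frame(file.path(base_dir, rows$file[1]),
                             rows$baseline_y_px[1], config)
        } else {
          bl <- if ("baseline_y_px" %in% names(rows)) rows$baseline_y_px[1]
                else config$baseline_y_px
          if (is.null(bl) || !is.finite(bl))
            stop_data(sprintf("subject %s: no support-surface baseline available", sid))
          rows <- rows[match(LANDMARKS, rows$landmark), , drop = FALSE]
          if (any(is.na(rows$x_px)))
            stop_data(sprintf("subject %s: incomplete landmark set for %s", sid, ph))
          markers_from_coords(rows, bl, config)
        }
        phases[[ph]] <- markers_to_volumes(ms, srow$thorax_cm)
      }
      bp <- pair_breath(phases$expiration, phases$inspiration)
      rbind(volumes_row(sid, "expiration", bp$expiration),
            volumes_row(sid, "inspiration", bp$inspiration, mobility = bp$mobility))
    }, photoresp_error = function(e) e)
    if (inherits(res, "photoresp_error")) {
      err_rows[[length(err_rows) + 1]] <-
        data.frame(subject_id = sid, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else vol_rows[[length(vol_rows) + 1]] <- res
  }
  volumes <- if (length(vol_rows)) do.call(rbind, vol_rows) else
    volumes_row("x", "expiration", compartment_volumes(0, 0, 0, 0))[0, ]
  errors <- if (length(err_rows)) do.call(rbind, err_rows) else
    data.frame(subject_id = character(0), error = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volumes_csv(volumes, file.path(out_dir, "volumes.csv"))
    if (nrow(errors))
      write.csv(errors, file.path(out_dir, "measure_errors.csv"), row.names = FALSE)
    log_jsonl(file.path(out_dir, "pipeline_log.jsonl"), "measure",
              input = input, mode = mode, n_subjects = length(unique(tab$subject_id)),
              n_failed = nrow(errors))
  }
  list(volumes = volumes, errors = errors)
}

#' Predict spirometric outcomes and validate against measurements
#'
#' Applies the reference FVC and DI equations to each subject's height,
#' thorax length and measured mobility. When measured spirometry is
#' present the validation layer is added: Tiffeneau screening, Pearson
#' correlation table between photogrammetric and spirometric measures,
#' Bland-Altman agreement of predictions vs measurements, and a refit of
#' the model form on the retained subjects.
#'
#' @param volumes Volumes data frame from [measure_cohort()] (or the path
#'   of a volumes CSV). Must contain `mobility_l` on inspiration rows.
#' @param subjects Subject table data frame or CSV path; needs
#'   `subject_id`, `height_m`, `thorax_cm`, and for validation the
#'   spirometry columns `FEV1_l`, `FVC_l`, `PEF_l_s`, `DI_l`.
#' @param config A [pipeline_config].
#' @param out_dir Directory for the report files (predictions.csv,
#'   correlations.csv, bland_altman.csv, refit model JSONs, plots);
#'   `NULL` skips writing.
#' @return List with `predictions`, `screening`, `correlations`,
#'   `bland_altman` (list for FVC and DI), and `refit` (list of
#'   `mobility_model`s), the validation members `NULL` when spirometry is
#'   absent or the retained cohort is too small.
#' @export
predict_and_validate <- function(volumes, subjects, config = pipeline_config(),
                                 out_dir = NULL) {
  if (is.character(volumes)) volumes <- read.csv(volumes, stringsAsFactors = FALSE)
  if (is.character(subjects)) subjects <- read.csv(subjects, stringsAsFactors = FALSE)
  if (!"mobility_l" %in% names(volumes))
    stop_data("volumes table lacks the mobility_l column")
  need <- c("subject_id", "height_m", "thorax_cm")
  if (!all(need %in% names(subjects)))
    stop_data(sprintf("subject table needs columns: %s", paste(need, collapse = ", ")))

  insp <- volumes[volumes$phase == "inspiration" & is.finite(volumes$mobility_l), ,
                  drop = FALSE]
  d <- merge(subjects, insp[, c("subject_id", "mobility_l")], by = "subject_id")
  if (nrow(d) == 0) stop_data("no subjects with measured mobility")

  have_spiro <- all(c("FEV1_l", "FVC_l") %in% names(d))
  d$screening <- if (have_spiro)
    screen_cohort(d, threshold = config$tiffeneau_threshold,
                  fvc_lower_limit = config$fvc_lower_limit) else "retained"
  d$FVC_pred_l <- predict_fvc(d$height_m, d$thorax_cm, d$mobility_l)
  d$DI_pred_l <- predict_di(d$height_m, d$thorax_cm, d$mobility_l)

  ret <- d[d$screening == "retained", , drop = FALSE]
  correlations <- NULL; ba <- NULL; refit <- NULL
  if (!have_spiro) {
    message("no spirometry columns: prediction-only mode, validation skipped")
  } else if (nrow(ret) < 3) {
    warning("fewer than 3 retained subjects: validation skipped", call. = FALSE)
  } else {
    exp_v <- volumes[volumes$phase == "expiration", , drop = FALSE]
    insp_v <- volumes[volumes$phase == "inspiration", , drop = FALSE]
    photo <- merge(ret[, c("subject_id", "mobility_l")],
                   merge(exp_v, insp_v, by = "subject_id",
                         suffixes = c("_exp", "_insp")), by = "subject_id")
    pcols <- c(setdiff(grep("_l_(exp|insp)$", names(photo), value = TRUE),
                       c("mobility_l_exp", "mobility_l_insp")), "mobility_l")
    scols <- intersect(c("FEV1_l", "FVC_l", "PEF_l_s", "DI_l"), names(ret))
    sp <- ret[match(photo$subject_id, ret$subject_id), scols, drop = FALSE]
    correlations <- correlation_table(photo[, pcols, drop = FALSE], sp)
    ba <- list(FVC = bland_altman(ret$FVC_pred_l, ret$FVC_l))
    if ("DI_l" %in% names(ret)) ba$DI <- bland_altman(ret$DI_pred_l, ret$DI_l)
    if (nrow(ret) >= 5) {
      refit <- list(FVC = fit_mobility_model(ret$FVC_l, ret, outcome_name = "FVC"))
      if ("DI_l" %in% names(ret))
        refit$DI <- fit_mobility_model(ret$DI_l, ret, outcome_name = "DI")
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(d, file.path(out_dir, "predictions.csv"), row.names = FALSE)
    if (!is.null(correlations))
      write.csv(round(correlations, 3), file.path(out_dir, "correlations.csv"))
    if (!is.null(ba)) {
      ba_df <- do.call(rbind, lapply(names(ba), function(nm)
        data.frame(outcome = nm, bias_l = ba[[nm]]$bias, sd_diff_l = ba[[nm]]$sd_diff,
                   ULA_l = ba[[nm]]$ULA, LLA_l = ba[[nm]]$LLA,
                   bias_p_value = ba[[nm]]$bias_p_value, n = ba[[nm]]$n)))
      write.csv(ba_df, file.path(out_dir, "bland_altman.csv"), row.names = FALSE)
      for (nm in names(ba)) {
        grDevices::png(file.path(out_dir, sprintf("bland_altman_%s.png", nm)),
                       width = 640, height = 520)
        plot(ba[[nm]], main = sprintf("Bland-Altman: predicted vs measured %s", nm))
        dev.off()
      }
    }
    if (!is.null(refit))
      for (nm in names(refit))
        model_to_json(refit[[nm]], file.path(out_dir, sprintf("refit_%s.json", nm)))
    log_jsonl(file.path(out_dir, "pipeline_log.jsonl"), "predict_validate",
              n = nrow(d), n_retained = nrow(ret), validated = !is.null(ba))
  }
  list(predictions = d, screening = d$screening, correlations = correlations,
       bland_altman = ba, refit = refit)
}
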