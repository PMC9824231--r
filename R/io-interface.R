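#' Parse a movement code
#'
#' Movement recordings are labelled `joint-movement-orientation-index`, e.g.
#' `"K-FLEX-FR-1"` for knee-flexion-frontal-recording 1. The parser accepts
#' the dialect variants that occur in practice — Portuguese joint initials
#' (`Q` hip, `J` knee, `C` elbow, `O` shoulder), `FLE`/`FLX` for `FLEX`,
#' `ADB` for `ABD`, `INL` for `IN` — and canonicalizes them; unknown tokens
#' are rejected. The index is optional (movement-level labels such as
#' `"K-FLEX-FR"` are valid).
#'
#' @param text A single code string.
#' @return An object of class `movement_code` with fields `joint` (K/H/E/S),
#'   `joint_name`, `movement` (FLEX/ABD), `orientation` (FR/IN) and `index`
#'   (integer or NA). `format()` re-serializes it canonically.
#' @examples
#' parse_movement_code("K-FLEX-FR-1")
#' format(parse_movement_code("Q-ADB-INL-2"))  # canonicalized to "H-ABD-IN-2"
#' @export
parse_movement_code <- function(text) {
  if (inherits(text, "movement_code")) return(text)
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  tok <- strsplit(toupper(trimws(text)), "-", fixed = TRUE)[[1]]
  if (length(tok) < 3 || length(tok) > 4) {
    kv_stop("kv_parse_error", "movement code '%s' is not joint-movement-orientation[-index]", text)
  }
  joints <- c(K = "K", J = "K", H = "H", Q = "H", E = "E", C = "E", S = "S", O = "S")
  movements <- c(FLEX = "FLEX", FLE = "FLEX", FLX = "FLEX", ABD = "ABD", ADB = "ABD")
  orientations <- c(FR = "FR", IN = "IN", INL = "IN")
  joint <- joints[tok[1]]
  movement <- movements[tok[2]]
  orientation <- orientations[tok[3]]
  if (is.na(joint)) kv_stop("kv_parse_error", "unknown joint token '%s' in '%s'", tok[1], text)
  if (is.na(movement)) kv_stop("kv_parse_error", "unknown movement token '%s' in '%s'", tok[2], text)
  if (is.na(orientation)) kv_stop("kv_parse_error", "unknown orientation token '%s' in '%s'", tok[3], text)
  index <- NA_integer_
  if (length(tok) == 4) {
    index <- suppressWarnings(as.integer(tok[4]))
    if (is.na(index)) kv_stop("kv_parse_error", "recording index '%s' is not an integer", tok[4])
  }
  names(joint) <- names(movement) <- names(orientation) <- NULL
  joint_names <- c(K = "knee", H = "hip", E = "elbow", S = "shoulder")
  structure(list(joint = joint, joint_name = unname(joint_names[joint]),
                 movement = movement, orientation = orientation, index = index),
            class = "movement_code")
}

#' @export
format.movement_code <- function(x, ...) {
  base <- paste(x$joint, x$movement, x$orientation, sep = "-")
  if (is.na(x$index)) base else paste(base, x$index, sep = "-")
}

#' @export
print.movement_code <- function(x, ...) {
  cat(sprintf("<movement_code> %s (%s %s, %s)\n", format(x), x$joint_name,
              tolower(x$movement),
              if (x$orientation == "FR") "frontal to sensor" else "inclined 30 deg"))
  invisible(x)
}

#' Recording availability accounting
#'
#' Counts lost and analyzed recordings from an availability grid — one row
#' per recording code, one column per volunteer, cells `"o"` (analyzed) or
#' `"x"` (lost; a loss in any sensor invalidates the whole recording) — and
#' derives the loss percentage and the number of analyzed executions
#' (analyzed recordings times repetitions per recording).
#'
#' @param grid Data frame whose first column is the recording code and whose
#'   remaining columns hold `"o"`/`"x"` cells.
#' @param repetitions_per_recording Executions per analyzed recording
#'   (default 5).
#' @return List with `total`, `lost`, `analyzed`, `percent_lost`,
#'   `executions`.
#' @export
loss_accounting <- function(grid, repetitions_per_recording = 5) {
  cells <- as.matrix(grid[, -1, drop = FALSE])
  if (any(is.na(cells)) || !all(cells %in% c("o", "x"))) {
    kv_stop("kv_bad_grid", "availability grid cells must all be 'o' or 'x'")
  }
  total <- length(cells)
  lost <- sum(cells == "x")
  analyzed <- total - lost
  list(total = total, lost = lost, analyzed = analyzed,
       percent_lost = 100 * lost / total,
       executions = analyzed * repetitions_per_recording)
}

#' Bundled reference tables from a published validation study
#'
#' Reference results of a published validation study that compared four
#' markerless tracking streams (Astra, Intel RealSense, Kinect V2 and
#' MediaPipe pose estimation, the latter two applied to the Kinect colour
#' stream) against a marker-based optical motion-capture system across
#' twelve monoplanar movements. Available tables: per-movement median
#' absolute errors (`"median_ae"`), upper-limb RMS of the absolute error
#' (`"rms_upper"`), per-movement Pearson correlations (`"pearson"`), and
#' the recording availability grid (`"availability"`). The numbers are the
#' study's published per-movement values; the group aggregates derivable
#' from them are recomputed by [aggregate_report()], not stored.
#'
#' @param name Which table to load.
#' @return A data frame.
#' @export
reference_table <- function(name = c("median_ae", "rms_upper", "pearson",
                                     "availability")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".csv"),
                      package = "kinovalid", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

## long form of a reference value table for aggregate_report()
reference_long <- function(name) {
  df <- reference_table(name)
  sensors <- setdiff(names(df), c("movement", "limb"))
  out <- do.call(rbind, lapply(sensors, function(s) {
    data.frame(movement = df$movement, limb = df$limb, sensor = s,
               value = df[[s]])
  }))
  names(out)[4] <- "median_ae"
  out
}

#' Write / read a skeleton stream as CSV with a JSON sidecar
#'
#' The CSV holds the long-format stream (`frame`, `time_s`, `joint`, `x_m`,
#' `y_m`, `z_m`); the sidecar `<path>.json` records the sampling rate,
#' movement code and source so a stream round-trips losslessly.
#'
#' @param stream A [skeleton_stream()].
#' @param path CSV file path.
#' @return `write_skeleton_stream()` returns `path` invisibly;
#'   `read_skeleton_stream()` returns the [skeleton_stream()].
#' @export
write_skeleton_stream <- function(stream, path) {
  stopifnot(inherits(stream, "skeleton_stream"))
  write.csv(as.data.frame(stream), path, row.names = FALSE)
  meta <- list(rate = attr(stream, "rate"),
               movement_code = attr(stream, "movement_code"),
               source = attr(stream, "source"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_skeleton_stream
#' @export
read_skeleton_stream <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  skeleton_stream(df, rate = meta$rate %||% NA_real_,
                  movement_code = meta$movement_code %||% NA_character_,
                  source = meta$source %||% NA_character_)
}

#' Write / read an angle series as CSV
#'
#' Columns `frame`, `time_s`, `angle_deg`, `valid_flag`; the sampling rate
#' travels in a JSON sidecar like the skeleton streams.
#'
#' @param series An [angle_series()].
#' @param path CSV file path.
#' @export
write_angle_series <- function(series, path) {
  stopifnot(inherits(series, "angle_series"))
  out <- data.frame(frame = series$frame, time_s = series$time_s,
                    angle_deg = series$angle_deg, valid_flag = series$valid)
  write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(list(rate = attr(series, "rate"),
                            movement_code = attr(series, "movement_code"),
                            source = attr(series, "source")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_angle_series
#' @export
read_angle_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  angle_series(ifelse(df$valid_flag, df$angle_deg, NA_real_),
               rate = meta$rate %||% NA_real_, time_s = df$time_s,
               valid = df$valid_flag,
               movement_code = meta$movement_code %||% NA_character_,
               source = meta$source %||% NA_character_)
}

#' Default synthetic-study configuration
#'
#' Mirrors the validation study's design: twelve movement-orientation
#' combinations (knee/hip/elbow/shoulder flexion and abduction, each facing
#' the sensors and inclined 30 degrees), two recordings per combination,
#' five volunteers, four sensor streams at 30 Hz against a 180 Hz
#' reference, five repetitions per recording. Two of the sensor streams go
#' through the 2D-landmark-plus-depth back-projection path (as the sensors
#' without a free skeleton SDK did); the other two deliver 3D joints
#' directly.
#'
#' @param n_volunteers,n_recordings Study size knobs.
#' @param position_noise_sd Landmark noise SD in metres (all sensors).
#' @param dropout_probability Per-recording outright-loss probability.
#' @param max_start_offset Upper bound of the uniform per-stream start
#'   offset, seconds.
#' @param amplitude,frequency,n_repetitions,baseline_angle Motion script
#'   parameters shared by all recordings.
#' @param seed Integer seed fixing all randomness of the run.
#' @return A configuration list for [run_pipeline()].
#' @export
default_config <- function(n_volunteers = 5, n_recordings = 2,
                           position_noise_sd = 0.005,
                           dropout_probability = 0.15,
                           max_start_offset = 1,
                           amplitude = 60, frequency = 0.5,
                           n_repetitions = 5, baseline_angle = 10,
                           seed = 1L) {
  combos <- c("K-FLEX-FR", "K-FLEX-IN", "H-ABD-FR", "H-ABD-IN",
              "H-FLEX-FR", "H-FLEX-IN", "E-FLEX-FR", "E-FLEX-IN",
              "S-ABD-FR", "S-ABD-IN", "S-FLEX-FR", "S-FLEX-IN")
  list(
    movements = combos,
    n_recordings = n_recordings,
    n_volunteers = n_volunteers,
    sensors = list(
      kinect = list(path = "direct", noise_sd = position_noise_sd),
      mediapipe = list(path = "direct", noise_sd = position_noise_sd),
      astra = list(path = "depth_overlay", noise_sd = position_noise_sd),
      realsense = list(path = "depth_overlay", noise_sd = position_noise_sd)
    ),
    gold_rate = 180, sensor_rate = 30,
    dropout_probability = dropout_probability,
    max_start_offset = max_start_offset,
    amplitude = amplitude, frequency = frequency,
    n_repetitions = n_repetitions, baseline_angle = baseline_angle,
    subject_distance = 2.5,
    tolerance = 90,
    max_gap = 5,
    seed = seed
  )
}

#' Read a run configuration from a YAML file
#'
#' Convenience wrapper: fields present in the file override the
#' [default_config()] defaults.
#'
#' @param path YAML file path.
#' @return A configuration list for [run_pipeline()].
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    kv_stop("kv_bad_config", "reading YAML configurations requires the 'yaml' package")
  }
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg[names(user)] <- user
  cfg
}

## rebuild a skeleton stream from per-frame 2D landmarks + depth records
lift_landmarks_to_stream <- function(landmarks, depth, intrinsics, template_rate,
                                     movement_code, source) {
  frames <- sort(unique(landmarks$frame))
  rows <- lapply(frames, function(f) {
    lm <- landmarks[landmarks$frame == f, ]
    dp <- depth[depth$frame == f, ]
    w <- overlay_depth(lm[, c("joint", "xp", "yp")],
                       dp[, c("u", "v", "z_m")], intrinsics)
    ok <- w$valid
    if (!any(ok)) return(NULL)
    data.frame(frame = f, time_s = lm$time_s[1], joint = w$joint[ok],
               x_m = w$xw[ok], y_m = w$yw[ok], z_m = w$zw[ok])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) kv_stop("kv_empty_series", "no landmark could be lifted to 3D")
  skeleton_stream(df, rate = template_rate, movement_code = movement_code,
                  source = source)
}

## per-execution error medians: windows of half a period around each peak
execution_medians <- function(errors, peaks, period_samples) {
  h <- floor(period_samples / 2)
  vapply(peaks, function(p) {
    median(errors[max(1, p - h):min(length(errors), p + h)])
  }, numeric(1))
}

#' Run the full synthetic validation pipeline
#'
#' Orchestrates the whole analysis on generated data: for every volunteer,
#' movement and recording index, ground-truth trajectories are sampled at
#' the reference and sensor rates with independent start offsets, posed
#' into skeletons, rendered through the virtual camera (with the
#' depth-overlay back-projection path for the sensors configured so),
#' converted to angle series, gap-filled, smoothed, and synchronized to the
#' reference by movement peaks. Failed recordings (dropouts, unfillable
#' gaps, peak-count mismatches) are marked lost in the availability grid
#' rather than aborting the run. Agreement statistics are then aggregated
#' into a validation report.
#'
#' @param config A configuration list, see [default_config()].
#' @param intrinsics Virtual camera intrinsics.
#' @return An object of class `validation_report`: `per_recording` and
#'   `per_movement` tables, `summary` / `rms_summary` / `pearson_summary`
#'   group aggregations (with clinical classification on the error
#'   summary), `rank` tests, the `availability` grid, `loss` accounting and
#'   the echoed `config`.
#' @export
run_pipeline <- function(config = default_config(),
                         intrinsics = default_intrinsics()) {
  with_preserved_rng(config$seed, run_pipeline_impl(config, intrinsics))
}

run_pipeline_impl <- function(config, intrinsics) {
  template <- default_skeleton_template()
  recordings <- expand.grid(index = seq_len(config$n_recordings),
                            movement = config$movements,
                            volunteer = seq_len(config$n_volunteers),
                            stringsAsFactors = FALSE)
  sensor_names <- names(config$sensors)

  per_recording <- list()
  avail <- list()
  exec_rows <- list()

  for (i in seq_len(nrow(recordings))) {
    combo <- recordings$movement[i]
    code <- sprintf("%s-%d", combo, recordings$index[i])
    vol <- recordings$volunteer[i]
    rec_label <- list(recording = code, volunteer = vol)

    mark_lost <- function(reason) {
      avail[[length(avail) + 1]] <<- c(rec_label, analyzed = FALSE, reason = reason)
    }

    if (runif(1) < config$dropout_probability) {
      mark_lost("dropped recording")
      next
    }

    prof <- movement_profile(combo)
    orientation <- if (parse_movement_code(combo)$orientation == "IN") 30 else 0
    script <- motion_script(code, amplitude = config$amplitude,
                            frequency = config$frequency,
                            n_repetitions = config$n_repetitions,
                            baseline_angle = config$baseline_angle)
    request <- angle_request(prof$proximal, prof$distal, prof$plane,
                             tolerance = config$tolerance)

    result <- tryCatch({
      gold_off <- runif(1, 0, config$max_start_offset)
      gold_traj <- generate_angle_trajectory(script, config$gold_rate, gold_off)
      gold_stream <- forward_kinematics(template, gold_traj, combo,
                                        root_position = c(0, 0, config$subject_distance))
      gold_ang <- compute_angle_series(gold_stream, request, prof$limb_group)
      gold_sm <- smooth_series(fill_gaps(gold_ang, config$max_gap),
                               default_filter_spec(config$gold_rate))

      smoothed <- list()
      for (sn in sensor_names) {
        scfg <- config$sensors[[sn]]
        off <- runif(1, 0, config$max_start_offset)
        traj <- generate_angle_trajectory(script, config$sensor_rate, off)
        truth <- forward_kinematics(template, traj, combo,
                                    root_position = c(0, 0, config$subject_distance))
        sim <- simulation_config(gold_rate = config$gold_rate,
                                 sensor_rate = config$sensor_rate,
                                 position_noise_sd = scfg$noise_sd,
                                 start_offset = off,
                                 dropout_probability = 0,
                                 camera_orientation = orientation,
                                 subject_distance = config$subject_distance)
        rendered <- render_sensor_stream(truth, sim, intrinsics, source = sn)
        stream <- if (identical(scfg$path, "depth_overlay")) {
          lift_landmarks_to_stream(rendered$landmarks, rendered$depth,
                                   intrinsics, config$sensor_rate, code, sn)
        } else {
          rendered$stream
        }
        ang <- compute_angle_series(stream, request, prof$limb_group)
        smoothed[[sn]] <- smooth_series(fill_gaps(ang, config$max_gap),
                                        default_filter_spec(config$sensor_rate))
      }

      aligned <- synchronize(smoothed, gold_sm)
      peaks <- attr(aligned, "peaks")
      period <- if (length(peaks) > 1) median(diff(peaks)) else {
        config$gold_rate / config$frequency
      }

      rows <- lapply(sensor_names, function(sn) {
        err <- absolute_error(aligned[[sn]], aligned$gold)
        pb <- pearson_band(aligned[[sn]], aligned$gold)
        exec_rows[[length(exec_rows) + 1]] <<- data.frame(
          recording = code, volunteer = vol, sensor = sn,
          execution = seq_along(peaks),
          median_ae = execution_medians(err, peaks, period))
        data.frame(recording = code, volunteer = vol, movement = combo,
                   limb = prof$limb_group, sensor = sn,
                   median_ae = median(err), sd_ae = sd(err),
                   rms_ae = rms_error(err), pearson_r = pb$r)
      })
      do.call(rbind, rows)
    }, kv_error = function(e) {
      mark_lost(conditionMessage(e))
      NULL
    })

    if (!is.null(result)) {
      avail[[length(avail) + 1]] <- c(rec_label, analyzed = TRUE, reason = "")
      per_recording[[length(per_recording) + 1]] <- result
    }
  }

  if (length(per_recording) == 0) {
    kv_stop("kv_empty_series", "every recording of the run was lost")
  }
  per_recording <- do.call(rbind, per_recording)
  avail <- do.call(rbind, lapply(avail, as.data.frame))
  executions <- do.call(rbind, exec_rows)

  # per movement x sensor: pooled medians / RMS, mean of per-recording r
  per_movement <- do.call(rbind, lapply(
    split(per_recording,
          list(per_recording$movement, per_recording$sensor), drop = TRUE),
    function(g) data.frame(movement = g$movement[1], limb = g$limb[1],
                           sensor = g$sensor[1],
                           median_ae = median(g$median_ae),
                           rms_ae = mean(g$rms_ae),
                           pearson_r = mean(g$pearson_r))))
  rownames(per_movement) <- NULL

  summary <- aggregate_report(per_movement, "median_ae")
  summary$classification <- mapply(function(m, s) {
    as.character(classify_error(m, if (is.na(s)) 0 else s))
  }, summary$mean, summary$sd)
  rms_summary <- aggregate_report(per_movement, "rms_ae")
  pearson_summary <- aggregate_report(per_movement, "pearson_r")
  pearson_summary$band <- as.character(correlation_band(pearson_summary$mean))

  # rank tests blocked on executions, paired across sensors
  exec_wide <- do.call(cbind, lapply(sensor_names, function(sn) {
    sub <- executions[executions$sensor == sn, ]
    sub <- sub[order(sub$recording, sub$volunteer, sub$execution), ]
    sub$median_ae
  }))
  colnames(exec_wide) <- sensor_names
  rank <- if (length(sensor_names) >= 3) rank_tests(exec_wide) else NULL

  grid <- availability_grid(avail)
  loss <- loss_accounting(grid, config$n_repetitions)

  structure(list(per_recording = per_recording, per_movement = per_movement,
                 summary = summary, rms_summary = rms_summary,
                 pearson_summary = pearson_summary, rank = rank,
                 availability = grid, loss = loss, log = avail,
                 config = config),
            class = "validation_report")
}

## long availability records -> wide o/x grid (recording x volunteer)
availability_grid <- function(avail) {
  recs <- unique(avail$recording)
  vols <- sort(unique(avail$volunteer))
  grid <- data.frame(recording = recs, stringsAsFactors = FALSE)
  for (v in vols) {
    col <- vapply(recs, function(rc) {
      row <- avail$recording == rc & avail$volunteer == v
      if (!any(row)) "x" else if (isTRUE(avail$analyzed[row][1])) "o" else "x"
    }, character(1))
    grid[[paste0("volunteer_", v)]] <- col
  }
  grid
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  recordings: %d analyzed / %d lost (%.2f%%), %d executions\n",
              x$loss$analyzed, x$loss$lost, x$loss$percent_lost, x$loss$executions))
  cat("  median absolute error (mean +/- SD of per-movement medians):\n")
  s <- x$summary[x$summary$group == "all", ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %-10s %5.2f +/- %4.2f deg  [%s]\n",
                s$sensor[i], s$mean[i], s$sd[i], s$classification[i]))
  }
  if (!is.null(x$rank)) {
    cat(sprintf("  Friedman chi-squared = %.2f, p = %.3g %s\n",
                x$rank$friedman$statistic, x$rank$friedman$p.value,
                x$rank$friedman$tier))
  }
  invisible(x)
}
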