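# Track tables are plain tibbles with columns
#   track_id, t_min, x_um, y_um, z_um
# (times in minutes post-fertilization, positions in micrometres).

TRACK_COLS <- c("track_id", "t_min", "x_um", "y_um", "z_um")

#' Validate a track table
#'
#' Checks the required columns, finiteness of positions, and that times are
#' strictly increasing within every track. Used internally by all
#' track-consuming functions; exported for explicit checking.
#'
#' @param tracks A data frame with columns `track_id`, `t_min`, `x_um`,
#'   `y_um`, `z_um`.
#' @return `tracks`, invisibly, if valid; otherwise an error naming the
#'   offending columns or track ids.
#' @export
validate_tracks <- function(tracks) {
  if (!is.data.frame(tracks)) abort("`tracks` must be a data frame.")
  missing_cols <- setdiff(TRACK_COLS, names(tracks))
  if (length(missing_cols) > 0) {
    abort(paste0("track table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  pos <- as.matrix(tracks[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(pos)) || !all(is.finite(tracks$t_min))) {
    abort("track table contains non-finite times or positions.")
  }
  dup_t <- tracks |>
    dplyr::arrange(.data$track_id, .data$t_min) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(bad = any(diff(.data$t_min) <= 0), .groups = "drop") |>
    dplyr::filter(.data$bad)
  if (nrow(dup_t) > 0) {
    abort(paste0("non-increasing times within track(s): ",
                 paste(head(dup_t$track_id, 10), collapse = ", ")))
  }
  invisible(tracks)
}

#' Read and write track tables
#'
#' Track tables are tab- or comma-delimited text with a header line naming
#' the columns `track_id, t_min, x_um, y_um, z_um`; lines starting with `#`
#' are comments (the writer records the units there). The round trip
#' `write_tracks()` then `read_tracks()` is lossless. Malformed rows (wrong
#' field count, unparseable numbers) are reported with their line numbers.
#'
#' @param path File path.
#' @param tracks Track table to write.
#' @param delim Field delimiter; `read_tracks` auto-detects tab vs comma
#'   from the header when `NULL`.
#' @return `read_tracks` returns a tibble sorted by `track_id`, `t_min`;
#'   `write_tracks` returns `path` invisibly.
#' @export
read_tracks <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(delim)) {
    hdr <- readLines(path, n = 10L)
    hdr <- hdr[!startsWith(hdr, "#")][1]
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  # parsing problems are surfaced as errors below, not as readr warnings
  df <- suppressWarnings(readr::read_delim(path, delim = delim, comment = "#",
                          col_types = readr::cols(
                            track_id = readr::col_integer(),
                            t_min = readr::col_double(),
                            x_um = readr::col_double(),
                            y_um = readr::col_double(),
                            z_um = readr::col_double()),
                          progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0("malformed rows in ", path, " at line(s): ",
                 paste(head(unique(probs$row), 10), collapse = ", ")))
  }
  missing_cols <- setdiff(TRACK_COLS, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df |>
    dplyr::select(dplyr::all_of(TRACK_COLS)) |>
    dplyr::arrange(.data$track_id, .data$t_min)
  validate_tracks(df)
  df
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path, delim = "\t") {
  validate_tracks(tracks)
  con <- file(path, "w")
  writeLines("# tissuetectonics track table: t_min in minutes, x_um/y_um/z_um in micrometres",
             con)
  close(con)
  readr::write_delim(tracks[TRACK_COLS], path, delim = delim, append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

#' Infer the acquisition interval of a track table
#'
#' The modal positive time step between consecutive samples of the same
#' track; 2 minutes in the imaging protocol this package targets.
#'
#' @param tracks Track table.
#' @return Frame interval in minutes.
#' @export
track_frame_interval <- function(tracks) {
  d <- tracks |>
    dplyr::arrange(.data$track_id, .data$t_min) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(dt = .data$t_min - dplyr::lag(.data$t_min)) |>
    dplyr::ungroup()
  dts <- d$dt[is.finite(d$dt) & d$dt > 0]
  if (length(dts) == 0) return(2)
  as.numeric(names(sort(table(dts), decreasing = TRUE))[1])
}

# mutual nearest-neighbour matching between two point sets; returns an
# integer vector idx of length nrow(A): idx[i] = matched row of B or NA.
mutual_nn_match <- function(A, B, max_disp) {
  if (nrow(A) == 0 || nrow(B) == 0) return(rep(NA_integer_, nrow(A)))
  # squared distances (dense; frame sizes here are a few thousand)
  D2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  nn_ab <- max.col(-D2, ties.method = "first")
  nn_ba <- max.col(-t(D2), ties.method = "first")
  i <- seq_len(nrow(A))
  mutual <- nn_ba[nn_ab] == i
  d <- sqrt(pmax(0, D2[cbind(i, nn_ab)]))
  ok <- mutual & d <= max_disp
  ifelse(ok, nn_ab, NA_integer_)
}

#' Link per-frame detections into tracks by mutual nearest neighbours
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames: a
#' detection in frame `t` is linked to a detection in frame `t+1` iff each
#' is the other's nearest neighbour and their distance does not exceed
#' `max_disp`. Unmatched detections start new tracks; tracks with no match
#' terminate (a detection that reappears later gets a new id). Ties are
#' resolved deterministically by row order (smaller id).
#'
#' @param detections Either a tibble with columns `t_min`, `x_um`, `y_um`,
#'   `z_um` (split into frames by `t_min`) or a list of per-frame data
#'   frames each carrying those position columns and a constant `t_min`.
#'   Extra columns are carried through to the output.
#' @param max_disp Maximum link distance, micrometres. Default (`NULL`):
#'   3x the median per-frame displacement estimated from a first linking
#'   pass with an unbounded threshold.
#' @return Track table (tibble) with assigned `track_id` plus any
#'   passthrough columns of the input.
#' @export
link_nearest_neighbor <- function(detections, max_disp = NULL) {
  if (is.data.frame(detections)) {
    if (!all(c("t_min", "x_um", "y_um", "z_um") %in% names(detections))) {
      abort("detections need columns t_min, x_um, y_um, z_um.")
    }
    frames <- split(detections, detections$t_min)
    frames <- frames[order(as.numeric(names(frames)))]
  } else if (is.list(detections)) {
    frames <- detections
  } else {
    abort("`detections` must be a data frame or a list of per-frame data frames.")
  }
  if (length(frames) < 2) abort("linking needs at least 2 frames.")
  frames <- lapply(frames, tibble::as_tibble)
  if (is.null(max_disp)) {
    first_pass <- link_frames(frames, Inf)
    disp <- first_pass$disp
    max_disp <- if (length(disp) > 0) 3 * median(disp) else Inf
  }
  link_frames(frames, max_disp)$tracks
}

# core linking; returns tracks plus the link displacement sample
link_frames <- function(frames, max_disp) {
  n_frames <- length(frames)
  pos <- lapply(frames, function(f) as_xyz_matrix(f))
  # per-frame vector of track ids
  ids <- vector("list", n_frames)
  next_id <- 1L
  n0 <- nrow(frames[[1]])
  ids[[1]] <- seq_len(n0); next_id <- n0 + 1L
  disp <- numeric(0)
  for (k in seq_len(n_frames - 1)) {
    A <- pos[[k]]; B <- pos[[k + 1]]
    if (nrow(A) == 0 || nrow(B) == 0) {
      warn(sprintf("empty frame at index %d: all tracks terminate.", k + (nrow(A) == 0)))
    }
    m <- mutual_nn_match(A, B, max_disp)
    idsB <- rep(NA_integer_, nrow(B))
    linked <- which(!is.na(m))
    idsB[m[linked]] <- ids[[k]][linked]
    if (length(linked) > 0) {
      disp <- c(disp, sqrt(rowSums((B[m[linked], , drop = FALSE] -
                                      A[linked, , drop = FALSE])^2)))
    }
    new_rows <- which(is.na(idsB))
    if (length(new_rows) > 0) {
      idsB[new_rows] <- next_id + seq_along(new_rows) - 1L
      next_id <- next_id + length(new_rows)
    }
    ids[[k + 1]] <- idsB
  }
  out <- dplyr::bind_rows(lapply(seq_len(n_frames), function(k) {
    dplyr::mutate(frames[[k]], track_id = ids[[k]], .before = 1)
  })) |>
    dplyr::arrange(.data$track_id, .data$t_min)
  list(tracks = out, disp = disp)
}

#' Per-cell velocities from tracks
#'
#' Finite-difference velocities at the acquisition interval: central
#' differences in the track interior, one-sided at the ends. A sample
#' flanked by a gap (missing neighbour at one frame interval) falls back to
#' the one-sided difference on the intact side; if neither neighbour is at
#' one frame interval the velocity is missing (`NA`). Single-point tracks
#' are dropped (count reported via a message).
#'
#' @param tracks Track table.
#' @param frame_interval Acquisition interval in minutes; default 2 (the
#'   imaging interval), or inferred with [track_frame_interval()] when
#'   `NULL`.
#' @param max_speed Optional plausibility bound, micrometres/min; faster
#'   samples are flagged (`speed_flag`), never dropped.
#' @return Tibble `track_id, t_min, x_um, y_um, z_um, vx, vy, vz,
#'   speed_flag` with velocities in micrometres/min.
#' @export
compute_velocities <- function(tracks, frame_interval = 2, max_speed = Inf) {
  validate_tracks(tracks)
  if (is.null(frame_interval)) frame_interval <- track_frame_interval(tracks)
  dt <- frame_interval
  single <- tracks |>
    dplyr::count(.data$track_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(single) > 0) {
    inform(sprintf("dropping %d single-point track(s).", nrow(single)))
  }
  out <- tracks |>
    dplyr::arrange(.data$track_id, .data$t_min) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::mutate(
      dt_prev = .data$t_min - dplyr::lag(.data$t_min),
      dt_next = dplyr::lead(.data$t_min) - .data$t_min,
      prev_ok = !is.na(.data$dt_prev) & abs(.data$dt_prev - dt) < 1e-9,
      next_ok = !is.na(.data$dt_next) & abs(.data$dt_next - dt) < 1e-9,
      vx = fd_velocity(.data$x_um, .data$prev_ok, .data$next_ok, dt),
      vy = fd_velocity(.data$y_um, .data$prev_ok, .data$next_ok, dt),
      vz = fd_velocity(.data$z_um, .data$prev_ok, .data$next_ok, dt)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::all_of(c("dt_prev", "dt_next", "prev_ok", "next_ok")))
  speed <- sqrt(out$vx^2 + out$vy^2 + out$vz^2)
  out$speed_flag <- is.finite(speed) & speed > max_speed
  out
}

# finite-difference along one coordinate given neighbour availability
fd_velocity <- function(x, prev_ok, next_ok, dt) {
  xl <- dplyr::lag(x); xn <- dplyr::lead(x)
  dplyr::case_when(
    prev_ok & next_ok ~ (xn - xl) / (2 * dt),
    next_ok ~ (xn - x) / dt,
    prev_ok ~ (x - xl) / dt,
    TRUE ~ NA_real_
  )
}

#' Cell counts per frame
#'
#' Number of distinct tracks detected at each time point.
#'
#' @param tracks Track table.
#' @return Tibble `t_min`, `n_cells`, sorted by time.
#' @export
count_cells_per_frame <- function(tracks) {
  validate_tracks(tracks)
  tracks |>
    dplyr::distinct(.data$track_id, .data$t_min) |>
    dplyr::count(.data$t_min, name = "n_cells") |>
    dplyr::arrange(.data$t_min)
}
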