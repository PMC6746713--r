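#' Construct a raw typing session
#'
#' A typing session is all key events between one keyboard launch and its
#' subsequent close. Events carry press/release timestamps in epoch
#' milliseconds and either per-key pixel coordinates (portrait orientation,
#' origin top-left) or, in privacy mode, a precomputed inter-key distance
#' series in millimetres; never both.
#'
#' @param subject_id,session_id Identifiers (coerced to character).
#' @param start_time Keyboard launch time, epoch milliseconds; must be at or
#'   before the first key press.
#' @param events Data frame with columns `press`, `release` (epoch ms),
#'   `x`, `y` (pixels, or `NA` in privacy mode) and `is_delete` (logical).
#' @param screen_density_x,screen_density_y Screen pixel densities (pixels
#'   per inch) along the portrait x/y axes; must be positive.
#' @param app_name Optional application name (kept as metadata, unused by the
#'   pipeline).
#' @param distances_mm Optional numeric vector of inter-key distances (mm) of
#'   length `nrow(events) - 1`; exclusive with per-event coordinates.
#'
#' @return An object of class `raw_typing_session`.
#' @export
typing_session <- function(subject_id, session_id, start_time, events,
                           screen_density_x, screen_density_y,
                           app_name = NULL, distances_mm = NULL) {
  events <- tibble::as_tibble(events)
  s <- structure(
    list(
      subject_id = as.character(subject_id),
      session_id = as.character(session_id),
      start_time = as.numeric(start_time),
      app_name = if (is.null(app_name) || is.na(app_name[1])) NULL else as.character(app_name),
      events = events,
      screen_density_x = as.numeric(screen_density_x),
      screen_density_y = as.numeric(screen_density_y),
      distances_mm = if (is.null(distances_mm)) NULL else as.numeric(distances_mm)
    ),
    class = "raw_typing_session"
  )
  validate_session(s)
}

#' Validate a raw typing session
#'
#' Checks the structural invariants: strictly increasing press and release
#' timestamp sequences, release >= press per key, positive screen densities,
#' non-negative coordinates, and that exactly one of per-event coordinates or
#' a distance series of length N-1 is present.
#'
#' @param session A `raw_typing_session`.
#' @return The session, invisibly unchanged, or an error.
#' @export
validate_session <- function(session) {
  ev <- session$events
  req <- c("press", "release", "is_delete")
  miss <- setdiff(req, names(ev))
  if (length(miss) > 0) {
    stop("session '", session$session_id, "': events missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(ev)
  if (n == 0) stop("session '", session$session_id, "': no events", call. = FALSE)
  if (any(ev$release < ev$press)) {
    stop("session '", session$session_id, "': release before press", call. = FALSE)
  }
  if (n > 1) {
    if (any(diff(ev$press) <= 0)) {
      stop("session '", session$session_id,
           "': press timestamps not strictly increasing", call. = FALSE)
    }
    if (any(diff(ev$release) <= 0)) {
      stop("session '", session$session_id,
           "': release timestamps not strictly increasing", call. = FALSE)
    }
  }
  if (session$screen_density_x <= 0 || session$screen_density_y <= 0) {
    stop("session '", session$session_id, "': screen densities must be > 0",
         call. = FALSE)
  }
  has_xy <- all(c("x", "y") %in% names(ev)) && !all(is.na(ev$x))
  has_d <- !is.null(session$distances_mm)
  if (has_xy && has_d) {
    stop("session '", session$session_id,
         "': both coordinates and distances_mm present (exclusive fields)",
         call. = FALSE)
  }
  if (!has_xy && !has_d) {
    stop("session '", session$session_id,
         "': neither coordinates nor distances_mm present", call. = FALSE)
  }
  if (has_xy && any(stats::na.omit(c(ev$x, ev$y)) < 0)) {
    stop("session '", session$session_id, "': negative pixel coordinates",
         call. = FALSE)
  }
  if (has_d && length(session$distances_mm) != n - 1) {
    stop("session '", session$session_id, "': distances_mm length must be N-1",
         call. = FALSE)
  }
  invisible(session)
}

#' @export
print.raw_typing_session <- function(x, ...) {
  cat(sprintf("<raw_typing_session> subject %s session %s: %d events (%s)\n",
              x$subject_id, x$session_id, nrow(x$events),
              if (is.null(x$distances_mm)) "coordinates" else "privacy mode"))
  invisible(x)
}

session_has_coords <- function(session) is.null(session$distances_mm)

#' Write typing sessions to disk
#'
#' Serialises a list of sessions as JSON Lines (one session per line, the
#' canonical format) or as a flat per-event CSV. With `privacy = TRUE`,
#' per-key pixel coordinates are replaced by the locally computed inter-key
#' distance series so the keys pressed cannot be recovered.
#'
#' @param sessions List of `raw_typing_session` objects.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @param privacy Replace coordinates with `distances_mm` (JSONL only)?
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path, format = c("jsonl", "csv"),
                           privacy = FALSE) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(sessions, function(s) {
      ev <- s$events
      if (privacy && session_has_coords(s)) {
        rec_events <- lapply(seq_len(nrow(ev)), function(i) list(
          p = ev$press[i], r = ev$release[i], del = ev$is_delete[i]))
        dist_out <- compute_distances(s)
      } else {
        rec_events <- lapply(seq_len(nrow(ev)), function(i) list(
          p = ev$press[i], r = ev$release[i],
          x = if (session_has_coords(s)) ev$x[i] else NULL,
          y = if (session_has_coords(s)) ev$y[i] else NULL,
          del = ev$is_delete[i]))
        dist_out <- s$distances_mm
      }
      rec <- list(
        subject_id = s$subject_id, session_id = s$session_id,
        start_time = s$start_time, app_name = s$app_name,
        screen_density_x = s$screen_density_x,
        screen_density_y = s$screen_density_y,
        events = rec_events, distances_mm = dist_out)
      jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
    }, character(1))
    writeLines(lines, path)
  } else {
    rows <- dplyr::bind_rows(lapply(sessions, function(s) {
      if (!session_has_coords(s)) {
        stop("CSV events dialect requires per-event coordinates", call. = FALSE)
      }
      tibble::tibble(
        subject_id = s$subject_id, session_id = s$session_id,
        start_time = s$start_time,
        press_ms = s$events$press, release_ms = s$events$release,
        x = s$events$x, y = s$events$y, is_delete = s$events$is_delete)
    }))
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

parse_jsonl_session <- function(line, lineno) {
  rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(rec)) return(NULL) # malformed JSON: rejected, counted by caller
  req <- c("subject_id", "session_id", "start_time",
           "screen_density_x", "screen_density_y", "events")
  for (f in req) {
    if (is.null(rec[[f]])) {
      stop("line ", lineno, ": missing required field '", f, "'", call. = FALSE)
    }
  }
  ev <- rec$events
  if (is.data.frame(ev)) {
    events <- tibble::tibble(
      press = as.numeric(ev$p), release = as.numeric(ev$r),
      x = if ("x" %in% names(ev)) as.numeric(ev$x) else NA_real_,
      y = if ("y" %in% names(ev)) as.numeric(ev$y) else NA_real_,
      is_delete = as.logical(ev$del))
  } else {
    stop("line ", lineno, ": missing required field 'events'", call. = FALSE)
  }
  typing_session(
    subject_id = rec$subject_id, session_id = rec$session_id,
    start_time = rec$start_time, events = events,
    screen_density_x = rec$screen_density_x,
    screen_density_y = rec$screen_density_y,
    app_name = rec$app_name,
    distances_mm = if (is.null(rec$distances_mm) || all(is.na(rec$distances_mm)))
      NULL else rec$distances_mm)
}

#' Read typing sessions from disk
#'
#' Reads the JSONL session format (canonical) or the per-event CSV dialect.
#' Sessions come back grouped by subject and with events ordered by press
#' time. Lines that are not parseable JSON are rejected and counted (see the
#' `n_rejected` attribute); schema violations (missing required fields,
#' non-monotone timestamps) raise errors identifying the line or session.
#'
#' @param path Input file path.
#' @param format `"jsonl"` or `"csv"`.
#' @param screen_density_x,screen_density_y Densities (ppi) to attach to
#'   sessions read from CSV, which does not carry them.
#' @return List of `raw_typing_session`, with attribute `n_rejected`.
#' @export
read_sessions <- function(path, format = c("jsonl", "csv"),
                          screen_density_x = 420, screen_density_y = 420) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sessions <- list()
    rejected <- 0L
    for (i in seq_along(lines)) {
      s <- parse_jsonl_session(lines[[i]], i)
      if (is.null(s)) rejected <- rejected + 1L else sessions[[length(sessions) + 1L]] <- s
    }
    if (rejected > 0) {
      message("read_sessions: rejected ", rejected, " malformed line(s)")
    }
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    req <- c("subject_id", "session_id", "start_time", "press_ms",
             "release_ms", "x", "y", "is_delete")
    miss <- setdiff(req, names(df))
    if (length(miss) > 0) {
      stop("CSV missing required field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    rejected <- 0L
    sessions <- lapply(split(df, df$session_id), function(g) {
      g <- g[order(g$press_ms), , drop = FALSE]
      typing_session(
        subject_id = g$subject_id[1], session_id = g$session_id[1],
        start_time = g$start_time[1],
        events = tibble::tibble(
          press = g$press_ms, release = g$release_ms,
          x = g$x, y = g$y, is_delete = as.logical(g$is_delete)),
        screen_density_x = screen_density_x,
        screen_density_y = screen_density_y)
    })
    names(sessions) <- NULL
  }
  # group by subject, events already validated ordered by press
  ord <- order(vapply(sessions, function(s) s$subject_id, character(1)),
               vapply(sessions, function(s) s$start_time, numeric(1)))
  sessions <- sessions[ord]
  attr(sessions, "n_rejected") <- rejected
  sessions
}

#' Read cohort metadata
#'
#' Reads the cohort metadata CSV (`subject_id,phq1..phq9,age,gender,education`)
#' and scores the PHQ-9 items.
#'
#' @param path CSV path.
#' @return Tibble with one row per subject, the nine items, `phq9_score`,
#'   and demographics.
#' @export
read_cohort <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  item_cols <- paste0("phq", 1:9)
  miss <- setdiff(c("subject_id", item_cols), names(df))
  if (length(miss) > 0) {
    stop("cohort CSV missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$phq9_score <- vapply(seq_len(nrow(df)), function(i) {
    score_phq9(as.integer(unlist(df[i, item_cols])))
  }, numeric(1))
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Write cohort metadata
#'
#' @param cohort Tibble with `subject_id`, `phq1..phq9`, `age`, `gender`,
#'   `education` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("subject_id", paste0("phq", 1:9), "age", "gender", "education")
  write.csv(cohort[, intersect(cols, names(cohort))], path, row.names = FALSE)
  invisible(path)
}
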