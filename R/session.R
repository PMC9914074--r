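#' Reading sessions: raw multi-read, multi-cycle sensor data
#'
#' A reading session is the raw sensor record for one candidate excretion
#' event: for each detection cycle (default 3) and each channel, one or more
#' absolute reads taken at nearby moments (default 2). Collections of
#' sessions travel as a long-format data frame with columns `session_id`,
#' `cycle`, `channel`, `read_index`, `value` and optionally `true_label`
#' (the generating event for labelled/simulated data, `NA` otherwise).
#'
#' @param session_id identifier.
#' @param reads data frame with columns `cycle`, `channel`, `read_index`,
#'   `value`.
#' @param true_label optional event label (see [event_labels()]).
#' @return a validated sessions data frame (one session).
#' @export
reading_session <- function(session_id, reads, true_label = NA) {
  reads$session_id <- session_id
  reads$true_label <- if (is.na(true_label)) NA_character_
                      else as_event_label(true_label)
  validate_sessions(reads[c("session_id", "cycle", "channel", "read_index",
                            "value", "true_label")])
}

#' @rdname reading_session
#' @param sessions a long-format sessions data frame.
#' @return `validate_sessions()` returns the data frame (with `true_label`
#'   added as `NA` if absent), or stops with an informative error.
#' @export
validate_sessions <- function(sessions) {
  required <- c("session_id", "cycle", "channel", "read_index", "value")
  missing <- setdiff(required, names(sessions))
  if (length(missing)) {
    stop("sessions are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"true_label" %in% names(sessions)) sessions$true_label <- NA_character_
  if (nrow(sessions) == 0L) stop("no sessions", call. = FALSE)
  bad <- !sessions$channel %in% sensor_channels()
  if (any(bad)) {
    stop("unknown channel(s) at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(unique(sessions$channel[bad]), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(sessions$value) || anyNA(sessions$value)) {
    stop("sessions column 'value' must be numeric and non-missing",
         call. = FALSE)
  }
  lab <- sessions$true_label
  if (any(!is.na(lab))) {
    sessions$true_label[!is.na(lab)] <- as_event_label(lab[!is.na(lab)])
  }
  # every session/cycle must carry at least one read per channel
  for (sid in unique(sessions$session_id)) {
    s <- sessions[sessions$session_id == sid, ]
    tab <- table(s$cycle, s$channel)
    if (ncol(tab) < 3L || any(tab == 0L)) {
      stop(sprintf("session '%s' lacks reads for some cycle x channel", sid),
           call. = FALSE)
    }
  }
  sessions
}

#' Read and write session CSV files
#'
#' Sessions are exchanged as plain CSV in the long dialect
#' `session_id,cycle,channel,read_index,value,true_label`.
#'
#' @param path file path.
#' @return `read_sessions()` returns a validated sessions data frame;
#'   `write_sessions()` returns `path` invisibly.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sessions(d)
}

#' @rdname read_sessions
#' @param sessions a sessions data frame.
#' @export
write_sessions <- function(sessions, path) {
  sessions <- validate_sessions(sessions)
  utils::write.csv(sessions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# split a sessions data frame into a named list of single-session frames,
# preserving first-appearance order
split_sessions <- function(sessions) {
  ids <- unique(sessions$session_id)
  stats::setNames(lapply(ids, function(i) sessions[sessions$session_id == i, ]),
                  ids)
}
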