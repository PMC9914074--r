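#' Preprocess a reading session into per-cycle excursions
#'
#' Cleans the raw reads and reduces them to one excursion triple per cycle:
#' per channel, reads farther than `mad_threshold` scaled median absolute
#' deviations from the session median are discarded as obviously
#' unreasonable (never discarding every read of a cycle: if all of a
#' cycle's reads are flagged, the one closest to the session median is
#' kept); the surviving reads are averaged within each cycle and converted
#' to excursions with [compute_deltas()].
#'
#' @param session a single-session data frame (see [reading_session()]).
#' @param basis a [detection_basis()].
#' @return a list with `deltas` (cycles x channels matrix of excursions) and
#'   `dropped` (audit data frame of discarded reads).
#' @export
preprocess_session <- function(session, basis) {
  session <- validate_sessions(session)
  if (length(unique(session$session_id)) != 1L) {
    stop("preprocess_session() expects a single session", call. = FALSE)
  }
  thr <- basis$mad_threshold
  keep <- rep(TRUE, nrow(session))
  for (ch in sensor_channels()) {
    i <- which(session$channel == ch)
    v <- session$value[i]
    med <- stats::median(v)
    s <- stats::mad(v) # scaled MAD (consistent with a normal sd)
    if (s > 0) keep[i[abs(v - med) > thr * s]] <- FALSE
    # never empty a cycle x channel cell
    for (cy in unique(session$cycle[i])) {
      j <- i[session$cycle[i] == cy]
      if (!any(keep[j])) keep[j[which.min(abs(session$value[j] - med))]] <- TRUE
    }
  }
  kept <- session[keep, ]
  cycles <- sort(unique(session$cycle))
  deltas <- t(vapply(cycles, function(cy) {
    s <- kept[kept$cycle == cy, ]
    reading <- vapply(sensor_channels(),
                      function(ch) mean(s$value[s$channel == ch]), 0)
    compute_deltas(reading, basis)
  }, numeric(3)))
  rownames(deltas) <- cycles
  colnames(deltas) <- sensor_channels()
  list(deltas = deltas, dropped = session[!keep, ])
}

# session-mean excursions (single effective reading), used by the direct
# baseline classifier
session_mean_deltas <- function(session, basis) {
  reading <- vapply(sensor_channels(), function(ch) {
    mean(session$value[session$channel == ch])
  }, 0)
  compute_deltas(reading, basis)
}

#' Detect an excretion event from one reading session
#'
#' The full evidence-fusion flow: the session is preprocessed into per-cycle
#' excursions; within each cycle the three sensor mass functions M1
#' (temperature), M2 (humidity) and M3 (ammonia) are built with
#' [build_bpa()] and fused with Dempster's rule; the per-cycle results are
#' then fused across cycles and the event with the highest fused mass is the
#' decision. All mass functions are epsilon-floored ([floor_mass()]) before
#' combination so total conflict cannot occur in the pipeline.
#'
#' @param session a single-session data frame.
#' @param basis a [detection_basis()].
#' @return an object of class `detection_result`: list with `session_id`,
#'   `decided`, `final` (fused [mass_function()]), `cycles` (per-cycle fused
#'   masses), `bpas` (per-cycle list of per-channel masses), and `dropped`
#'   (preprocessing audit).
#' @export
detect_event <- function(session, basis) {
  pp <- tryCatch(preprocess_session(session, basis), error = function(e) {
    stop(sprintf("session '%s': %s", session$session_id[1],
                 conditionMessage(e)), call. = FALSE)
  })
  ncy <- nrow(pp$deltas)
  bpas <- vector("list", ncy)
  cycle_masses <- vector("list", ncy)
  for (cy in seq_len(ncy)) {
    ms <- lapply(sensor_channels(), function(ch) {
      floor_mass(build_bpa(pp$deltas[cy, ch], ch, basis))
    })
    names(ms) <- sensor_channels()
    bpas[[cy]] <- ms
    cycle_masses[[cy]] <- ds_fuse(unname(ms))
  }
  final <- ds_fuse(lapply(cycle_masses, floor_mass))
  structure(list(session_id = session$session_id[1],
                 decided = ds_decide(final), final = final,
                 cycles = cycle_masses, bpas = bpas, dropped = pp$dropped),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection result> session %s -> %s\n", x$session_id,
              toupper(x$decided)))
  cat("  final "); print(x$final)
  for (i in seq_along(x$cycles)) {
    cat(sprintf("  cycle %d ", i)); print(x$cycles[[i]])
  }
  if (nrow(x$dropped)) cat("  reads dropped:", nrow(x$dropped), "\n")
  invisible(x)
}

#' Detect events for a collection of sessions
#'
#' Runs both the fused pipeline ([detect_event()]) and the direct threshold
#' baseline ([direct_classify()] on the session-mean excursions) on every
#' session.
#'
#' @param sessions a sessions data frame.
#' @param basis a [detection_basis()].
#' @return data frame with one row per session: `session_id`, `true_label`,
#'   `fused`, `direct`, and the final fused masses `m_A`..`m_D`.
#' @export
detect_sessions <- function(sessions, basis) {
  per <- split_sessions(validate_sessions(sessions))
  rows <- lapply(per, function(s) {
    r <- detect_event(s, basis)
    cbind(data.frame(session_id = s$session_id[1],
                     true_label = s$true_label[1],
                     fused = r$decided,
                     direct = direct_classify(session_mean_deltas(s, basis),
                                              basis),
                     stringsAsFactors = FALSE),
          as.data.frame(r$final))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare evidence fusion with the direct threshold baseline
#'
#' Scores the fused pipeline and the direct classifier against the true
#' labels of a labelled session collection and runs McNemar's paired
#' chi-square test on the discordant pairs.
#'
#' @param sessions a sessions data frame with `true_label` set.
#' @param basis a [detection_basis()].
#' @return a [comparison_report()] object.
#' @export
compare_with_baseline <- function(sessions, basis) {
  preds <- detect_sessions(sessions, basis)
  if (all(is.na(preds$true_label))) {
    stop("compare_with_baseline() needs labelled sessions", call. = FALSE)
  }
  preds <- preds[!is.na(preds$true_label), ]
  comparison_report(truth = preds$true_label, fused = preds$fused,
                    direct = preds$direct)
}
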