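#' Packaged bench-trial fixture
#'
#' Ten bench trials of the assembled device: absolute humidity, temperature
#' and ammonia readings together with the event printed by the on-device
#' fusion algorithm, and a flag marking the single trial whose printed
#' result was annotated as an identification error.
#'
#' @return data frame with columns `num`, `humidity`, `temperature`,
#'   `ammonia`, `result` (event label) and `error` (logical).
#' @examples
#' t2 <- load_table2()
#' t2[1, ]
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2.csv", package = "dsnurse")
  if (path == "") stop("packaged fixture table2.csv not found", call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) != 10L ||
      !isTRUE(all.equal(unlist(d[1, c("humidity", "temperature", "ammonia")]),
                        c(humidity = 65.9, temperature = 20.6, ammonia = 3.0)))) {
    stop("packaged fixture table2.csv is corrupted", call. = FALSE)
  }
  d$result <- as_event_label(d$result)
  d
}

#' Convert the bench-trial fixture to reading sessions
#'
#' Each trial becomes a one-cycle, single-read session of absolute
#' readings. The trials record absolute values; interpreting them requires
#' an environment baseline, which is a property of the room the bench test
#' was run in and therefore a configuration input, not part of the fixture.
#'
#' @param table2 the fixture (defaults to [load_table2()]).
#' @return a sessions data frame (10 sessions, `true_label` unset).
#' @export
table2_sessions <- function(table2 = load_table2()) {
  out <- do.call(rbind, lapply(seq_len(nrow(table2)), function(i) {
    data.frame(session_id = sprintf("T2-%02d", table2$num[i]),
               cycle = 1L,
               channel = sensor_channels(),
               read_index = 1L,
               value = as.numeric(table2[i, c("temperature", "humidity",
                                              "ammonia")]),
               true_label = NA_character_,
               stringsAsFactors = FALSE)
  }))
  validate_sessions(out)
}

#' Summary of the packaged bench trials
#'
#' @return list with `n` trials, `errors` (count of trials whose printed
#'   result was marked wrong) and `accuracy` (percent of trials identified
#'   correctly by the on-device fusion).
#' @examples
#' table2_report() # 10 trials, 1 error, 90% accuracy
#' @export
table2_report <- function() {
  t2 <- load_table2()
  list(n = nrow(t2), errors = sum(t2$error),
       accuracy = 100 * mean(!t2$error))
}
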