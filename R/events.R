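#' Event labels for the excretion frame
#'
#' The device distinguishes four care events: `"urine"` (code A), `"stool"`
#' (code B), `"both"` (urine and stool, code C) and `"none"` (no detection,
#' code D). On the frame of discernment \{u, s, n\} (urine present, stool
#' present, nothing) these correspond to the focal sets A = \{u\}, B = \{s\},
#' C = \{u, s\} and D = \{n\}; C behaves as the union of A and B, so A and B
#' each intersect C while D is disjoint from all others.
#'
#' @return `event_labels()` returns the four labels in canonical A, B, C, D
#'   order. `event_codes()` returns the corresponding one-letter codes.
#' @examples
#' event_labels()
#' as_event_label("C")
#' @export
event_labels <- function() c("urine", "stool", "both", "none")

#' @rdname event_labels
#' @export
event_codes <- function() c(urine = "A", stool = "B", both = "C", none = "D")

#' @rdname event_labels
#' @param x character vector of labels or one-letter codes (case-insensitive).
#' @return `as_event_label()` returns a character vector of canonical labels.
#' @export
as_event_label <- function(x) {
  x <- tolower(as.character(x))
  codes <- c(a = "urine", b = "stool", c = "both", d = "none")
  out <- ifelse(x %in% names(codes), codes[x], x)
  bad <- !out %in% event_labels()
  if (any(bad)) {
    stop("unknown event label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

# Decision preference when masses (or votes) tie: prefer the event triggering
# the most complete cleaning action (both > stool > urine > none).
severity_order <- function() c("both", "stool", "urine", "none")

# index of `labels` in severity order, for tie-breaking via which.max
.severity_idx <- function() match(severity_order(), event_labels())
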