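#' Detection basis: interval thresholds and environment for event sensing
#'
#' The detection basis holds everything the detector needs to turn absolute
#' sensor readings into evidence: the per-channel, per-event excursion
#' intervals (relative to the indoor environment), the environment baselines,
#' the sensor noise model and the derived membership softness.
#'
#' The default intervals are the device's calibrated detection table
#' (excursions above the indoor baseline):
#' \tabular{lccc}{
#'   \tab stool \tab urine \tab both \cr
#'   temperature (degC) \tab (0.5, 2) \tab (1.8, Inf) \tab (0, 1) \cr
#'   humidity (\%RH) \tab (5, 12) \tab (20, Inf) \tab (12, 20) \cr
#'   ammonia (ppm) \tab (1, 2) \tab (2, Inf) \tab (1, 2) \cr
#' }
#' "none" corresponds to excursions near 0 on every channel. Printed interval
#' bounds are treated as half-open: a value exactly on a shared boundary
#' belongs to the class above it (e.g. an ammonia excursion of exactly 2 ppm
#' counts as urine), and an excursion of exactly 0 belongs to "none".
#'
#' @param intervals nested list `channel -> event -> c(lo, hi)` (hi may be
#'   `Inf`). Defaults to the table above.
#' @param baseline named numeric: indoor `temperature` (degC), `humidity`
#'   (\%RH) and ambient `ammonia` (ppm) used as the reference point.
#' @param sensor_noise named numeric: per-channel standard deviation of a
#'   single sensor read (defaults reflect the installed DHT22
#'   temperature/humidity and GM-802B ammonia sensors).
#' @param reads_per_cycle number of reads averaged within one detection
#'   cycle; used to derive the default membership softness.
#' @param softness named numeric membership softness per channel, or `NULL`
#'   to derive it as `2 * sensor_noise / sqrt(reads_per_cycle)` (a two-sigma
#'   uncertainty band on the per-cycle averaged reading). Set to 0 for crisp
#'   interval memberships.
#' @param none_halfwidth named numeric half-width of the "none" neighbourhood
#'   around 0 used by the direct threshold classifier; defaults to the
#'   smallest positive interval bound of each channel.
#' @param bpa_alloc `"consonant"` (default) or `"proportional"`; see
#'   [build_bpa()].
#' @param mad_threshold robust outlier threshold used by [preprocess_session()].
#' @return an object of class `detection_basis`.
#' @seealso [build_bpa()], [direct_classify()], [read_basis()]
#' @export
detection_basis <- function(intervals = default_intervals(),
                            baseline = c(temperature = 22, humidity = 40,
                                         ammonia = 0),
                            sensor_noise = c(temperature = 0.4, humidity = 4,
                                             ammonia = 0.6),
                            reads_per_cycle = 2,
                            softness = NULL,
                            none_halfwidth = NULL,
                            bpa_alloc = c("consonant", "proportional"),
                            mad_threshold = 3) {
  bpa_alloc <- match.arg(bpa_alloc)
  chs <- sensor_channels()
  stopifnot(all(chs %in% names(intervals)))
  for (ch in chs) {
    for (ev in c("urine", "stool", "both")) {
      iv <- intervals[[ch]][[ev]]
      if (length(iv) != 2L || !is.numeric(iv) || iv[1] >= iv[2]) {
        stop(sprintf("invalid interval for %s/%s", ch, ev), call. = FALSE)
      }
    }
  }
  baseline <- .named_channels(baseline, "baseline")
  sensor_noise <- .named_channels(sensor_noise, "sensor_noise")
  if (any(sensor_noise < 0)) stop("sensor_noise must be >= 0", call. = FALSE)
  if (is.null(softness)) {
    softness <- 2 * sensor_noise / sqrt(reads_per_cycle)
  } else {
    if (length(softness) == 1L) softness <- rep(softness, 3)
    softness <- .named_channels(softness, "softness")
  }
  if (is.null(none_halfwidth)) {
    none_halfwidth <- vapply(chs, function(ch) {
      los <- vapply(c("urine", "stool", "both"),
                    function(ev) intervals[[ch]][[ev]][1], 0)
      min(los[los > 0])
    }, 0)
  } else {
    none_halfwidth <- .named_channels(none_halfwidth, "none_halfwidth")
  }
  structure(list(intervals = intervals, baseline = baseline,
                 sensor_noise = sensor_noise,
                 reads_per_cycle = reads_per_cycle,
                 softness = softness, none_halfwidth = none_halfwidth,
                 bpa_alloc = bpa_alloc, mad_threshold = mad_threshold),
            class = "detection_basis")
}

#' @rdname detection_basis
#' @export
default_intervals <- function() {
  list(
    temperature = list(stool = c(0.5, 2), urine = c(1.8, Inf), both = c(0, 1)),
    humidity    = list(stool = c(5, 12),  urine = c(20, Inf),  both = c(12, 20)),
    ammonia     = list(stool = c(1, 2),   urine = c(2, Inf),   both = c(1, 2))
  )
}

#' @rdname detection_basis
#' @export
sensor_channels <- function() c("temperature", "humidity", "ammonia")

.named_channels <- function(x, what) {
  chs <- sensor_channels()
  if (is.null(names(x))) {
    if (length(x) != 3L) stop(what, " needs 3 values", call. = FALSE)
    names(x) <- chs
  }
  if (!all(chs %in% names(x))) {
    stop(what, " must name channels ", paste(chs, collapse = ", "),
         call. = FALSE)
  }
  x[chs]
}

#' @export
print.detection_basis <- function(x, ...) {
  cat("<detection basis>\n")
  for (ch in sensor_channels()) {
    iv <- x$intervals[[ch]]
    cat(sprintf("  %-11s stool (%g, %g)  urine (%g, %g)  both (%g, %g)\n",
                ch, iv$stool[1], iv$stool[2], iv$urine[1], iv$urine[2],
                iv$both[1], iv$both[2]))
  }
  cat(sprintf("  baseline: %s\n",
              paste(sprintf("%s=%g", names(x$baseline), x$baseline),
                    collapse = ", ")))
  cat(sprintf("  softness: %s  (bpa_alloc=%s)\n",
              paste(sprintf("%.3g", x$softness), collapse = "/"), x$bpa_alloc))
  invisible(x)
}

#' Channel excursions above the environment baseline
#'
#' Subtracts the configured indoor baseline from an absolute reading triple.
#' The ammonia excursion is floored at 0 because absolute concentrations
#' cannot fall below the ambient level that defines the reference.
#'
#' @param reading named (or A,B,C-ordered) numeric: absolute `temperature`
#'   (degC), `humidity` (\%RH), `ammonia` (ppm).
#' @param basis a [detection_basis()] with baselines.
#' @return named numeric of excursions `temperature`, `humidity`, `ammonia`.
#' @examples
#' b <- detection_basis(baseline = c(temperature = 15.1, humidity = 22.9,
#'                                   ammonia = 0))
#' compute_deltas(c(16.1, 27.9, 1.0), b)
#' @export
compute_deltas <- function(reading, basis) {
  stopifnot(inherits(basis, "detection_basis"))
  reading <- .named_channels(reading, "reading")
  if (anyNA(basis$baseline)) {
    stop("detection basis has no environment baseline configured", call. = FALSE)
  }
  d <- reading - basis$baseline
  d[["ammonia"]] <- max(0, d[["ammonia"]])
  d
}

# Smoothed interval membership: the indicator of (lo, hi) convolved with a
# Gaussian kernel of width w, rescaled to peak at 1. w = 0 gives the crisp
# half-open indicator (lo inclusive unless lo == 0, which "none" owns).
.smooth_box <- function(d, lo, hi, w) {
  if (w <= 0) {
    inside <- if (lo == 0) d > lo else d >= lo
    if (is.finite(hi)) inside <- inside & d < hi
    return(as.numeric(inside))
  }
  v <- stats::pnorm((d - lo) / w) -
    if (is.finite(hi)) stats::pnorm((d - hi) / w) else 0
  mid <- if (is.finite(hi)) (lo + hi) / 2 else lo + 8 * w
  vmax <- stats::pnorm((mid - lo) / w) -
    if (is.finite(hi)) stats::pnorm((mid - hi) / w) else 0
  v / vmax
}

#' Per-event membership of one channel excursion
#'
#' Scores how compatible one channel's excursion is with each of the four
#' events, in \[0, 1\]. Event intervals use a Gaussian-smoothed indicator
#' whose softness defaults to twice the standard deviation of the per-cycle
#' averaged reading, so the soft boundary band matches the measurement
#' uncertainty; "none" uses a Gaussian peak at 0 of the same width. With
#' softness 0 the memberships are crisp half-open interval indicators and
#' "none" is the indicator of an exactly-zero excursion.
#'
#' @param delta scalar excursion for `channel` (from [compute_deltas()]).
#' @param channel one of [sensor_channels()].
#' @param basis a [detection_basis()].
#' @return named numeric `urine`, `stool`, `both`, `none`, each in \[0, 1\].
#' @export
channel_membership <- function(delta, channel, basis) {
  channel <- match.arg(channel, sensor_channels())
  iv <- basis$intervals[[channel]]
  w <- basis$softness[[channel]]
  mu_none <- if (w <= 0) as.numeric(delta == 0) else exp(-delta^2 / (2 * w^2))
  c(urine = .smooth_box(delta, iv$urine[1], iv$urine[2], w),
    stool = .smooth_box(delta, iv$stool[1], iv$stool[2], w),
    both  = .smooth_box(delta, iv$both[1], iv$both[2], w),
    none  = mu_none)
}

#' Basic probability assignment from one channel's excursion
#'
#' Converts interval memberships into a mass function, the per-sensor
#' evidence that enters Dempster fusion (M1 = temperature, M2 = humidity,
#' M3 = ammonia).
#'
#' Two allocation schemes are available. The default, `"consonant"`, respects
#' the set structure of the frame: because "both" is the union \{u, s\},
#' evidence that is equally compatible with a singleton and with "both" is
#' ambiguous between them and is assigned to the union; only the
#' singleton-exclusive excess max(0, mu_singleton - mu_both) supports the
#' singleton. This matches the canonical consonant mass induced by nested
#' focal sets and is what allows the fused decision to recover the "both"
#' event (under plain proportional allocation, Dempster's rule transfers all
#' shared stool/both evidence to stool and "both" can never win).
#' `"proportional"` simply normalizes the raw memberships.
#'
#' If every membership is below 1e-9 the full mass goes to "none".
#'
#' @inheritParams channel_membership
#' @return a [mass_function()].
#' @examples
#' b <- detection_basis(softness = 0) # crisp memberships
#' build_bpa(25, "humidity", b)  # certainty on urine
#' build_bpa(0, "temperature", b) # all mass on none
#' @export
build_bpa <- function(delta, channel, basis) {
  mu <- channel_membership(delta, channel, basis)
  m <- if (basis$bpa_alloc == "consonant") {
    c(max(0, mu[["urine"]] - mu[["both"]]),
      max(0, mu[["stool"]] - mu[["both"]]),
      mu[["both"]], mu[["none"]])
  } else {
    c(mu[["urine"]], mu[["stool"]], mu[["both"]], mu[["none"]])
  }
  if (sum(m) < 1e-9) m <- c(0, 0, 0, 1)
  mass_function(m / sum(m))
}

# crisp per-channel vote sets for the direct classifier
.channel_votes <- function(delta, channel, basis) {
  iv <- basis$intervals[[channel]]
  hw <- basis$none_halfwidth[[channel]]
  inside <- function(lohi) {
    lo <- lohi[1]; hi <- lohi[2]
    ok <- if (lo == 0) delta > lo else delta >= lo
    if (is.finite(hi)) ok <- ok && delta < hi
    ok
  }
  c(urine = inside(iv$urine), stool = inside(iv$stool),
    both = inside(iv$both), none = abs(delta) < hw)
}

#' Direct threshold classification (no evidence fusion)
#'
#' The traditional single-table baseline: each channel votes for every event
#' whose excursion interval contains the observed excursion ("none" votes
#' when the excursion is within its near-zero neighbourhood); the event with
#' the most channel votes wins. Ties are broken in severity order
#' both > stool > urine > none; if no interval matches on any channel the
#' result is "none".
#'
#' @param deltas named numeric excursions (see [compute_deltas()]).
#' @param basis a [detection_basis()].
#' @return one of `event_labels()`.
#' @examples
#' b <- detection_basis()
#' direct_classify(c(1.0, 8, 1.5), b) # "stool"
#' direct_classify(c(2.5, 25, 3), b)  # "urine"
#' @export
direct_classify <- function(deltas, basis) {
  deltas <- .named_channels(deltas, "deltas")
  votes <- rowSums(vapply(sensor_channels(),
                          function(ch) .channel_votes(deltas[[ch]], ch, basis),
                          numeric(4)))
  if (all(votes == 0)) return("none")
  idx <- .severity_idx()
  severity_order()[which.max(votes[idx])]
}

#' Read and write a detection basis as YAML
#'
#' The YAML layout mirrors the basis: `channels: <channel>: <event>: [lo, hi]`
#' (use `.inf` for unbounded sides), environment baselines under
#' `environment:`, and optional `sensor_noise`, `softness`, `none_halfwidth`,
#' `reads_per_cycle`, `bpa_alloc`, `mad_threshold`. The packaged default is
#' `system.file("extdata", "table1.yaml", package = "dsnurse")`.
#'
#' @param path file path.
#' @return `read_basis()` returns a [detection_basis()].
#' @export
read_basis <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$channels)) stop("basis YAML lacks 'channels'", call. = FALSE)
  intervals <- lapply(y$channels, function(ch) {
    lapply(ch, function(iv) {
      iv <- as.numeric(iv)
      if (is.na(iv[2])) iv[2] <- Inf
      iv
    })
  })
  env <- y$environment
  args <- list(intervals = intervals)
  if (!is.null(env)) args$baseline <- unlist(env)[sensor_channels()]
  for (f in c("sensor_noise", "softness", "none_halfwidth")) {
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  }
  for (f in c("reads_per_cycle", "bpa_alloc", "mad_threshold")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(detection_basis, args)
}

#' @rdname read_basis
#' @param basis a [detection_basis()] to serialize.
#' @return `write_basis()` returns `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "detection_basis"))
  y <- list(
    channels = lapply(basis$intervals, function(ch) lapply(ch, as.list)),
    environment = as.list(basis$baseline),
    sensor_noise = as.list(basis$sensor_noise),
    softness = as.list(basis$softness),
    none_halfwidth = as.list(basis$none_halfwidth),
    reads_per_cycle = basis$reads_per_cycle,
    bpa_alloc = basis$bpa_alloc,
    mad_threshold = basis$mad_threshold
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
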