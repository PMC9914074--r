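# Generic subset-lattice Dempster combination over the frame {u, s, n},
# independent of the package's closed-form implementation. Subsets are coded
# as bitmasks u=1, s=2, n=4; the excretion focal sets are A={u}=1, B={s}=2,
# C={u,s}=3, D={n}=4.

event_masks <- c(urine = 1L, stool = 2L, both = 3L, none = 4L)

# mass_function -> vector over the 7 non-empty subsets (index = bitmask)
to_lattice <- function(m) {
  v <- numeric(7)
  v[event_masks] <- unclass(m)
  v
}

lattice_combine <- function(v1, v2) {
  out <- numeric(7)
  conflict <- 0
  for (i in which(v1 > 0)) {
    for (j in which(v2 > 0)) {
      x <- bitwAnd(i, j)
      p <- v1[i] * v2[j]
      if (x == 0L) conflict <- conflict + p else out[x] <- out[x] + p
    }
  }
  K <- 1 - conflict
  if (K <= 0) stop("total conflict")
  out / K
}

oracle_combine <- function(m1, m2) {
  v <- lattice_combine(to_lattice(m1), to_lattice(m2))
  mass_function(v[event_masks])
}

oracle_conflict <- function(m1, m2) {
  v1 <- to_lattice(m1); v2 <- to_lattice(m2)
  conflict <- 0
  for (i in which(v1 > 0)) for (j in which(v2 > 0)) {
    if (bitwAnd(i, j) == 0L) conflict <- conflict + v1[i] * v2[j]
  }
  1 - conflict
}

# uniform draw from the 4-simplex
random_mass <- function() {
  mass_function(diff(c(0, sort(stats::runif(3)), 1)))
}

# a small deterministic session builder: one value per cycle x channel,
# replicated over `reads` identical reads
make_session <- function(id, values, true_label = NA, reads = 1L) {
  # values: matrix cycles x 3 (temperature, humidity, ammonia), absolute
  rows <- do.call(rbind, lapply(seq_len(nrow(values)), function(cy) {
    do.call(rbind, lapply(seq_len(reads), function(rd) {
      data.frame(cycle = cy, channel = sensor_channels(), read_index = rd,
                 value = as.numeric(values[cy, ]), stringsAsFactors = FALSE)
    }))
  }))
  reading_session(id, rows, true_label = true_label)
}
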