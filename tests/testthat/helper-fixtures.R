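# Shared fixtures and independent oracles, all built in code at test time.

# A fast, deterministic trial configuration for unit tests.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, laps_per_subject = 1,
                                 lap_duration = 20, seed = 42), list(...))
  do.call(sim_config, args)
}

# Noise-free strictly periodic configuration (the separable limit).
clean_config <- function(...) {
  args <- utils::modifyList(list(n_subjects = 1, laps_per_subject = 1,
                                 lap_duration = 30, noise_sd_accel = 0,
                                 noise_sd_gyro = 0, cycle_duration_sd = 0,
                                 downhill_fraction = 0, subject_style_sd = 0,
                                 seed = 7), list(...))
  do.call(sim_config, args)
}

# Random valid event list fully inside a window of `dur` seconds, built on
# a 100 Hz grid so the binary encoding round-trips exactly.
rand_event_list <- function(dur = 10, effector = "pole", rate = 100) {
  n_ev <- sample(0:6, 1)
  if (n_ev == 0) return(event_list(effector = effector))
  k <- sort(sample(0:(dur * rate - 2), 2 * n_ev))
  while (any(diff(k) == 0)) k <- sort(sample(0:(dur * rate - 2), 2 * n_ev))
  event_list(k / rate, rep(c("ON", "OFF"), n_ev), effector)
}

# Independent run-enumeration oracle for the block filter (R, rle-based).
oracle_filter <- function(x, max_gap = 20L, min_block = 30L) {
  x <- as.integer(x)
  if (length(x) == 0L) return(x)
  r <- rle(x)
  n <- length(r$values)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (r$values[i] == 0L && r$values[i - 1L] == 1L &&
          r$values[i + 1L] == 1L && r$lengths[i] < max_gap)
        r$values[i] <- 1L
    }
  }
  y <- inverse.rle(r)
  r2 <- rle(y)
  r2$values[r2$values == 1L & r2$lengths <= min_block] <- 0L
  inverse.rle(r2)
}

# Brute-force nearest-reference attribution oracle: every ML event picks the
# reference event with minimal |dt| (tie -> earlier reference); per reference
# the closest attributed ML event pairs (tie -> earlier ML), surplus counts
# extra, unattributed references count missed.
oracle_match <- function(mt, rt) {
  n_ml <- length(mt); n_ref <- length(rt)
  if (n_ref == 0L || n_ml == 0L)
    return(list(pairs = cbind(ref = numeric(0), ml = numeric(0)),
                missed = n_ref, extra = 0L))
  attr_of <- vapply(mt, function(m) {
    d <- abs(m - rt)
    which(d == min(d))[1L]
  }, 0L)
  pairs <- NULL; missed <- 0L; extra <- 0L
  for (i in seq_len(n_ref)) {
    js <- which(attr_of == i)
    if (!length(js)) { missed <- missed + 1L; next }
    d <- abs(mt[js] - rt[i])
    j <- js[which(d == min(d))[1L]]
    pairs <- rbind(pairs, c(ref = rt[i], ml = mt[j]))
    extra <- extra + length(js) - 1L
  }
  list(pairs = pairs, missed = missed, extra = extra)
}

# All binary sequences of length n as rows (n <= 20).
all_binary <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}
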