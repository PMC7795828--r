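# Independent oracles the implementation is checked against. These are
# deliberately written as direct, non-incremental computations.

# set Jaccard via explicit bit vectors
jaccard_bitvec <- function(a, b, n_slots = 48) {
  va <- logical(n_slots); va[a + 1L] <- TRUE
  vb <- logical(n_slots); vb[b + 1L] <- TRUE
  if (!any(va | vb)) return(1)
  sum(va & vb) / sum(va | vb)
}

# batch pattern slots by explicit run enumeration over the full window
batch_pattern_slots <- function(slots, n_slots, theta, phi) {
  counts <- tabulate(slots + 1L, nbins = n_slots)
  n <- length(slots)
  sth <- n * theta / n_slots
  cs <- ifelse(counts >= sth, counts, 0)
  keep <- integer(0)
  i <- 1L
  while (i <= n_slots) {
    if (cs[i] > 0) {
      j <- i
      while (j < n_slots && cs[j + 1L] > 0) j <- j + 1L
      if (sum(cs[i:j]) >= phi * n) keep <- c(keep, (i:j) - 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  keep
}

# dense-grid Mamdani pipeline coded from scratch (own interpolation, own grid)
mamdani_oracle <- function(fis, sens, sim, step = 0.01) {
  interp <- function(mf, x) {
    y <- numeric(length(x))
    nx <- length(mf$x)
    inside <- x >= mf$x[1] & x <= mf$x[nx]
    for (i in which(inside)) {
      j <- findInterval(x[i], mf$x, all.inside = TRUE)
      x0 <- mf$x[j]; x1 <- mf$x[j + 1L]
      y[i] <- mf$mu[j] + (mf$mu[j + 1L] - mf$mu[j]) * (x[i] - x0) / (x1 - x0)
    }
    y
  }
  grid <- seq(fis$drift$range[1], fis$drift$range[2], by = step)
  agg <- numeric(length(grid))
  for (r in seq_len(nrow(fis$rules))) {
    act <- min(interp(fis$sensitivity$terms[[fis$rules$sensitivity[r]]], sens),
               interp(fis$similarity$terms[[fis$rules$similarity[r]]], sim))
    if (act <= 0) next
    agg <- pmax(agg, pmin(act, interp(fis$drift$terms[[fis$rules$drift[r]]], grid)))
  }
  if (all(agg == 0)) return(NA_real_)
  sum(grid * agg) / sum(agg)
}

# construct a sociability_pattern with a prescribed slot set
make_pattern <- function(slots, context = "ALL", grid = slot_grid(0.5)) {
  state <- context_counter(context, grid)
  if (length(slots)) state <- update_counts(state, slots)
  extract_pattern(state, miner_params(grid, theta = 0, phi = 0),
                  extracted_at = as.Date("2013-04-01"))
}

# events placed at given hour offsets on a date (UTC, conversation type)
events_at <- function(date, hours) {
  start <- as.POSIXct(as.Date(date), tz = "UTC") + hours * 3600
  data.frame(activity_type = rep("conversation", length(hours)),
             start = start, end = start + 120,
             cas_explicit = I(rep(list(character(0)), length(hours))),
             stringsAsFactors = FALSE)
}
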