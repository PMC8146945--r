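# Independent brute-force oracles, deliberately written as plain R loops so
# they share no code path with the package implementation.

# local seeded evaluation (tests only)
with_seed <- function(seed, code) { set.seed(seed); force(code) }

# Step Forward recurrence, straight from its definition.
oracle_sf_encode <- function(x, thr, b0 = x[1]) {
  s <- integer(length(x))
  B <- b0
  for (n in seq_along(x)) {
    if (x[n] - B > thr) { s[n] <- 1L; B <- B + thr }
    else if (B - x[n] > thr) { s[n] <- -1L; B <- B - thr }
  }
  list(spikes = s, baseline_final = B)
}

# Event-list LIF + nearest-spike STDP simulation on a dense weight matrix.
# Semantics mirrored from the documented rules, not from the C++ code:
#  - leak exp(-1/tau_m) for non-refractory neurons, refractory hold at reset
#  - spikes delivered one step after firing
#  - input spike injects sign * v_thr * k_in
#  - fire at v >= v_thr; refractory blocks refrac steps
#  - STDP on strictly earlier spikes only; magnitude updates, fixed sign
oracle_lif_stdp <- function(n, edges, raster, imap, lif, stdp = NULL,
                            passes = 1L, v0 = rep(0, n)) {
  W <- matrix(0, n, n)
  SGN <- matrix(1L, n, n)
  for (r in seq_len(nrow(edges))) {
    W[edges$i[r], edges$j[r]] <- edges$w[r]
    SGN[edges$i[r], edges$j[r]] <- edges$sign[r]
  }
  has_edge <- matrix(FALSE, n, n)
  has_edge[cbind(edges$i, edges$j)] <- TRUE
  v <- v0; last_fire <- rep(-1, n); next_ok <- rep(0, n)
  prev_fired <- integer(0)
  fired_log <- list()
  T_ <- ncol(raster)
  learn <- !is.null(stdp)
  upd <- function(i, j, dmag) {
    mag <- abs(W[i, j]) + dmag
    if (mag < 0) mag <- 0
    if (SGN[i, j] < 0) W[i, j] <<- max(-mag, stdp$w_min)
    else W[i, j] <<- min(mag, stdp$w_max)
  }
  for (p in seq_len(passes)) for (t in seq_len(T_)) {
    g <- (p - 1) * T_ + (t - 1)
    for (i in 1:n) {
      if (g >= next_ok[i]) v[i] <- v[i] * exp(-1 / lif$tau_m)
      else v[i] <- lif$v_reset
    }
    for (f in prev_fired) for (j in which(has_edge[f, ]))
      if (g >= next_ok[j]) v[j] <- v[j] + W[f, j]
    for (ch in seq_len(nrow(raster))) {
      s <- raster[ch, t]
      if (s != 0 && g >= next_ok[imap[ch]])
        v[imap[ch]] <- v[imap[ch]] + s * lif$v_thr * lif$k_in
    }
    fired <- which(v >= lif$v_thr & g >= next_ok)
    if (learn) for (jn in fired) {
      for (k in which(has_edge[, jn]))
        if (last_fire[k] >= 0 && last_fire[k] < g)
          upd(k, jn, stdp$a_plus * exp(-(g - last_fire[k]) / stdp$tau_plus))
      for (m in which(has_edge[jn, ]))
        if (last_fire[m] >= 0 && last_fire[m] < g)
          upd(jn, m, -stdp$a_minus * exp(-(g - last_fire[m]) / stdp$tau_minus))
    }
    for (i in fired) {
      last_fire[i] <- g; v[i] <- lif$v_reset; next_ok[i] <- g + lif$refrac
      fired_log[[length(fired_log) + 1]] <- c(g + 1, i)
    }
    prev_fired <- fired
  }
  fired_df <- if (length(fired_log))
    as.data.frame(do.call(rbind, fired_log)) else data.frame(V1 = integer(),
                                                             V2 = integer())
  names(fired_df) <- c("step", "neuron")
  list(W = W, fired = fired_df)
}

# Raster container around a plain matrix, for driving the reservoir directly.
raw_raster <- function(spikes, rate = 256, condition = "toy") {
  structure(list(spikes = spikes, rate = rate,
                 params = encoder_params(), montage = NULL,
                 condition = condition),
            class = "snn_spike_raster")
}

# Tiny deterministic reservoir with explicit edges.
toy_model <- function(n, edges, imap, lif = lif_params(),
                      coords = cbind(seq_len(n) * 10, 0, 0),
                      inhibitory = rep(FALSE, n)) {
  structure(list(grid = neuron_grid(coords, source = "toy"),
                 edges = edges, inhibitory = inhibitory,
                 input_map = imap, lif = lif,
                 swc = swc_params(), seed = 0L),
            class = "snn_reservoir")
}
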