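# 3D spiking reservoir: input mapping, small-world initialization, and leaky
# integrate-and-fire dynamics.

#' Small-world connectivity parameters
#'
#' Pairs within `r_frac * d_max` of each other (d_max = grid diameter) are
#' connected with probability `exp(-d^2 / lambda^2)`, `lambda` = half the
#' connection radius, so the connection probability decays with distance and
#' is zero beyond the radius. Weights are drawn uniformly on (0, w_init];
#' a fraction `p_inh` of neurons is inhibitory and their outgoing weights are
#' negative.
#'
#' @param r_frac connection radius as a fraction of the grid diameter.
#' @param w_init maximum initial weight magnitude.
#' @param p_inh fraction of inhibitory neurons.
#' @return `snn_swc_params` list.
#' @export
swc_params <- function(r_frac = 0.25, w_init = 0.2, p_inh = 0.2) {
  stopifnot(r_frac > 0, r_frac <= 1, w_init > 0, p_inh >= 0, p_inh < 1)
  structure(list(r_frac = r_frac, w_init = w_init, p_inh = p_inh),
            class = "snn_swc_params")
}

#' Leaky integrate-and-fire parameters
#'
#' All in simulation time steps (one step = one sample of the 256 Hz input).
#'
#' @param tau_m membrane time constant (steps).
#' @param v_thr firing threshold.
#' @param v_reset reset potential.
#' @param refrac refractory period (steps): a neuron that fires at step g
#'   cannot fire again before g + refrac.
#' @param k_in input gain: an input spike of sign s injects `s * v_thr * k_in`
#'   into its mapped neuron (k_in >= 1 forces firing on a positive spike).
#' @return `snn_lif_params` list.
#' @export
lif_params <- function(tau_m = 10, v_thr = 1, v_reset = 0, refrac = 2,
                       k_in = 1.2) {
  stopifnot(tau_m > 0, v_thr > 0, refrac >= 0, k_in > 0)
  structure(list(tau_m = tau_m, v_thr = v_thr, v_reset = v_reset,
                 refrac = refrac, k_in = k_in),
            class = "snn_lif_params")
}

#' Map montage channels to their nearest grid neurons
#'
#' Each channel is assigned the Euclidean-nearest neuron; when two channels
#' compete for one neuron, the later channel takes its next-nearest free
#' neuron, keeping the map injective.
#'
#' @param montage an `snn_montage` with positions in grid space.
#' @param grid an `snn_neuron_grid`.
#' @return Named integer vector: neuron index per channel label.
#' @export
map_inputs <- function(montage, grid) {
  n_ch <- length(montage$labels)
  if (n_ch > grid$n) stop("more channels than neurons in the grid")
  pos <- montage$positions
  taken <- logical(grid$n)
  out <- integer(n_ch)
  for (c in seq_len(n_ch)) {
    d2 <- colSums((t(grid$coords) - pos[c, ])^2)
    ord <- order(d2)
    pick <- ord[!taken[ord]][1]
    taken[pick] <- TRUE
    out[c] <- pick
  }
  names(out) <- montage$labels
  out
}

#' Initialize a reservoir with small-world connectivity
#'
#' @param grid an `snn_neuron_grid`.
#' @param swc [swc_params()].
#' @param seed integer seed (connection draws, weights, inhibitory set).
#' @param lif [lif_params()].
#' @param montage optional montage; when given, the input map is built here.
#' @return `snn_reservoir` object: grid, `edges` data.frame (`i`, `j`, `w`,
#'   sorted by (i, j)), `inhibitory` logical per neuron, `input_map`, `lif`,
#'   `swc`, `seed`.
#' @export
#' @examples
#' res <- init_small_world(synthetic_grid(5), seed = 1)
#' nrow(res$edges)
init_small_world <- function(grid, swc = swc_params(), seed = 1L,
                             lif = lif_params(), montage = NULL) {
  stopifnot(inherits(grid, "snn_neuron_grid"))
  co <- grid$coords
  n <- grid$n
  d <- as.matrix(stats::dist(co))
  d_max <- max(d)
  radius <- swc$r_frac * d_max
  lambda <- radius / 2
  with_seed(seed, {
    inhib <- runif(n) < swc$p_inh
    cand <- which(d > 0 & d <= radius, arr.ind = TRUE)  # ordered pairs
    # deterministic order: by source then target
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    p <- exp(-(d[cand]^2) / lambda^2)
    keep <- runif(nrow(cand)) < p
    cand <- cand[keep, , drop = FALSE]
    w <- runif(nrow(cand), min = 0, max = swc$w_init)
    w[w == 0] <- swc$w_init                      # open interval (0, w_init]
    w <- ifelse(inhib[cand[, 1]], -w, w)
  })
  edges <- data.frame(i = cand[, 1], j = cand[, 2], w = w)
  input_map <- if (!is.null(montage)) map_inputs(montage, grid) else NULL
  structure(list(grid = grid, edges = edges, inhibitory = inhib,
                 input_map = input_map, lif = lif, swc = swc,
                 seed = as.integer(seed)),
            class = "snn_reservoir")
}

#' @export
print.snn_reservoir <- function(x, ...) {
  cat(sprintf("<snn_reservoir> %d neurons, %d connections (%.1f%% inhibitory neurons)\n",
              x$grid$n, nrow(x$edges), 100 * mean(x$inhibitory)))
  invisible(x)
}

#' Reservoir weight matrix
#'
#' @param model an `snn_reservoir` (or trained model).
#' @return Dense N x N matrix, `W[i, j]` = weight of connection i -> j.
#' @export
reservoir_weights <- function(model) {
  if (inherits(model, "snn_trained_model")) model <- model$model
  W <- matrix(0, model$grid$n, model$grid$n)
  W[cbind(model$edges$i, model$edges$j)] <- model$edges$w
  W
}

# Fixed excitatory(+1)/inhibitory(-1) sign per edge, from the source neuron.
edge_signs <- function(model) {
  if (!is.null(model$inhibitory))
    ifelse(model$inhibitory[model$edges$i], -1L, 1L)
  else
    ifelse(model$edges$w < 0, -1L, 1L)
}

.check_compat <- function(model, raster) {
  if (is.null(model$input_map))
    stop("reservoir has no input map; build it with a montage or map_inputs()")
  if (nrow(raster$spikes) != length(model$input_map))
    stop("raster channel count does not match the reservoir input map")
}

#' Run leaky integrate-and-fire dynamics
#'
#' Drives the reservoir with a spike raster: per step, potentials leak by
#' `exp(-1/tau_m)`, spikes fired in the previous step deliver their
#' connection weights, input spikes inject `sign * v_thr * k_in` at their
#' mapped neurons, and any neuron at or above threshold fires, resets, and
#' enters its refractory period.
#'
#' @param model an `snn_reservoir`.
#' @param raster an `snn_spike_raster`.
#' @param steps number of input samples to use (default: all).
#' @param record_potentials keep the full potential trace (small models
#'   only).
#' @param v0 optional initial potentials.
#' @return `snn_spike_activity`: list with `fired` (data.frame `step`,
#'   `neuron`, 1-based), `n_steps`, and optionally `potentials`.
#' @export
run_dynamics <- function(model, raster, steps = ncol(raster$spikes),
                         record_potentials = FALSE, v0 = NULL) {
  .check_compat(model, raster)
  if (steps > ncol(raster$spikes)) stop("steps exceeds raster length")
  sp <- raster$spikes[, seq_len(steps), drop = FALSE]
  res <- lif_stdp_core(model$grid$n,
                       model$edges$i - 1L, model$edges$j - 1L, model$edges$w,
                       edge_signs(model), sp, model$input_map - 1L,
                       model$lif$tau_m, model$lif$v_thr, model$lif$v_reset,
                       model$lif$refrac, model$lif$k_in,
                       FALSE, 0, 0, 1, 1, -1, 1, 1L,
                       record_potentials,
                       v0 %||% numeric(model$grid$n))
  act <- list(fired = data.frame(step = res$fired_step + 1L,
                                 neuron = res$fired_neuron + 1L),
              n_steps = steps)
  if (record_potentials) act$potentials <- res$potentials
  structure(act, class = "snn_spike_activity")
}
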