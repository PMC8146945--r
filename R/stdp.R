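# Spike-timing-dependent plasticity, interleaved with the LIF dynamics.

#' STDP parameters
#'
#' Nearest-spike rule: when a neuron fires, each incoming connection whose
#' source fired dt steps earlier is potentiated by
#' `a_plus * exp(-dt / tau_plus)`, and each outgoing connection whose target
#' fired dt steps earlier is depressed by `a_minus * exp(-dt / tau_minus)`.
#' Only strictly earlier spikes count (simultaneous spikes cause no update).
#' Updates act on the weight magnitude — inhibitory connections mirror the
#' rule — and magnitudes are clipped to `[0, w_max]` (signed weights to
#' `[w_min, 0]` for inhibitory, `[0, w_max]` for excitatory sources).
#'
#' @param a_plus,a_minus potentiation / depression amplitudes (>= 0).
#' @param tau_plus,tau_minus decay constants (time steps, > 0).
#' @param w_min,w_max signed weight bounds (w_min < w_max).
#' @param passes training passes over the data (>= 1).
#' @return `snn_stdp_params` list.
#' @export
stdp_params <- function(a_plus = 0.01, a_minus = 0.01,
                        tau_plus = 10, tau_minus = 10,
                        w_min = -1, w_max = 1, passes = 1L) {
  stopifnot(a_plus >= 0, a_minus >= 0, tau_plus > 0, tau_minus > 0,
            w_min < w_max, passes >= 1)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_min = w_min, w_max = w_max,
                 passes = as.integer(passes)),
            class = "snn_stdp_params")
}

#' Train a reservoir with STDP
#'
#' Runs the LIF dynamics on the raster and updates connection weights at each
#' postsynaptic/presynaptic firing per the nearest-spike STDP rule. STDP only
#' modifies existing connections; the sparsity pattern is preserved.
#'
#' @param model an `snn_reservoir`.
#' @param raster an `snn_spike_raster`.
#' @param params [stdp_params()].
#' @param steps input samples to train on (default: all).
#' @return `snn_trained_model`: list with `model` (reservoir with updated
#'   edge weights), `trained_on` condition tag, `activity` summary (firing
#'   count, steps), and `params`.
#' @export
stdp_train <- function(model, raster, params = stdp_params(),
                       steps = ncol(raster$spikes)) {
  .check_compat(model, raster)
  if (steps > ncol(raster$spikes)) stop("steps exceeds raster length")
  sp <- raster$spikes[, seq_len(steps), drop = FALSE]
  res <- lif_stdp_core(model$grid$n,
                       model$edges$i - 1L, model$edges$j - 1L, model$edges$w,
                       edge_signs(model), sp, model$input_map - 1L,
                       model$lif$tau_m, model$lif$v_thr, model$lif$v_reset,
                       model$lif$refrac, model$lif$k_in,
                       TRUE, params$a_plus, params$a_minus,
                       params$tau_plus, params$tau_minus,
                       params$w_min, params$w_max,
                       params$passes, FALSE, numeric(model$grid$n))
  trained <- model
  trained$edges$w <- res$w
  structure(list(model = trained,
                 trained_on = raster$condition,
                 activity = list(n_fired = length(res$fired_step),
                                 n_steps = steps * params$passes),
                 params = params),
            class = "snn_trained_model")
}

#' @export
print.snn_trained_model <- function(x, ...) {
  cat(sprintf("<snn_trained_model> condition = %s, %d connections, %d firings\n",
              x$trained_on, nrow(x$model$edges), x$activity$n_fired))
  invisible(x)
}

#' Train one model per condition from a shared initial reservoir
#'
#' Every condition's model starts from an identical copy of the same seeded
#' initial reservoir, so that differences between trained models are
#' attributable to the data alone. Each recording is encoded (optionally with
#' per-channel threshold optimization) and trained independently.
#'
#' @param recordings list of [eeg_recording()]s (typically
#'   `make_study_fixture(...)$recordings`); all must share montage labels and
#'   rate.
#' @param base the shared initial `snn_reservoir`.
#' @param enc [encoder_params()].
#' @param params [stdp_params()].
#' @return Named list of `snn_trained_model`, one per condition.
#' @export
train_condition_models <- function(recordings, base,
                                   enc = encoder_params(optimize = TRUE),
                                   params = stdp_params()) {
  labels <- lapply(recordings, function(r) rownames(r$data))
  rates <- vapply(recordings, function(r) r$rate, numeric(1))
  if (length(unique(lapply(labels, paste, collapse = ","))) != 1L)
    stop("recordings have mixed montages")
  if (length(unique(rates)) != 1L) stop("recordings have mixed rates")
  out <- lapply(recordings, function(rec) {
    stdp_train(base, sf_encode(rec, enc), params)
  })
  names(out) <- vapply(recordings, function(r) as.character(r$condition),
                       character(1))
  out
}
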