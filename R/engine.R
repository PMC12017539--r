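#' Simulate the column
#'
#' Time-stepped integration of the full network at fixed step `dt` (default
#' 0.1 ms). Each step accrues binned background Poisson deliveries, delivers
#' the previous step's spikes through the synapse table (one-step implicit
#' latency; the model has no explicit axonal delays), advances the gating
#' dynamics, evaluates the total synaptic current including the protocol's DC
#' epochs, and advances the membranes with spike detection, reset and
#' refractoriness. All neurons start at rest with zero gating. The run is a
#' pure function of (network, protocol, seed, dt): repeating it reproduces
#' every spike bit-identically.
#'
#' @param column A `cortical_column`.
#' @param protocol A `stimulus_protocol` (default: spontaneous).
#' @param duration Simulated time, ms.
#' @param dt Step size, ms.
#' @param seed Master integer seed; background and target-selection
#'   substreams are derived from it.
#' @param record_voltage `FALSE`, `TRUE` (all neurons) or an integer vector
#'   of neuron ids whose membrane potential is sampled.
#' @param voltage_every_ms Voltage sampling period, ms (default 1).
#' @param latency_ms Spike transmission latency, ms (default 0.1: one step at
#'   the default resolution; kept fixed under step-size refinement).
#' @return Object of class `simulation_record`: `spikes` (data frame
#'   `neuron_id`, `group`, `time_ms`), `voltage` (matrix time x neuron or
#'   `NULL`), `voltage_t`, `config` (full provenance echo).
#' @export
run_simulation <- function(column, protocol = make_state_protocol("spontaneous"),
                           duration = 3000, dt = 0.1, seed = 1,
                           record_voltage = FALSE, voltage_every_ms = 1,
                           latency_ms = 0.1) {
  stopifnot(dt > 0, duration >= dt)
  n <- column$N_total
  pars <- column$params[column$pops$group]
  per_group <- function(f) rep(vapply(pars, f, numeric(1)), column$pops$n)
  kin <- column$kinetics
  ep <- resolve_epochs(column, protocol, seed, duration)
  rec_ids <- if (isTRUE(record_voltage)) seq_len(n)
             else if (is.numeric(record_voltage)) as.integer(record_voltage)
             else integer(0)
  n_steps <- as.integer(round(duration / dt))
  res <- with_seed(substream_seed(seed, "background"), {
    cpp_run_column(n_steps, dt,
                   per_group(function(p) p$V_rest),
                   per_group(function(p) p$V_th),
                   per_group(function(p) p$C_m),
                   per_group(function(p) p$g_L),
                   per_group(function(p) p$tau_ref),
                   per_group(function(p) p$nu_bg) * dt / 1000,
                   column$csr$AMPA$ptr, column$csr$AMPA$post, column$csr$AMPA$w,
                   column$csr$NMDA$ptr, column$csr$NMDA$post, column$csr$NMDA$w,
                   column$csr$GABA$ptr, column$csr$GABA$post, column$csr$GABA$w,
                   kin$tau_AMPA, kin$tau_NMDA_decay, kin$tau_NMDA_rise,
                   kin$alpha, kin$tau_GABA, kin$Mg,
                   kin$g_AMPA, kin$g_NMDA, kin$g_GABA, kin$V_E,
                   ep$on, ep$off, ep$amp, as.integer(ep$ptr),
                   as.integer(ep$ids - 1L),
                   as.integer(rec_ids - 1L),
                   as.integer(round(voltage_every_ms / dt)),
                   max(1L, as.integer(round(latency_ms / dt))))
  })
  grp <- neuron_groups(column)
  spikes <- data.frame(neuron_id = res$spike_id,
                       group = grp[res$spike_id],
                       time_ms = res$spike_t,
                       stringsAsFactors = FALSE)
  voltage <- NULL
  if (length(rec_ids)) {
    voltage <- res$voltage
    colnames(voltage) <- rec_ids
  }
  structure(list(
    spikes = spikes,
    voltage = voltage,
    voltage_t = if (length(rec_ids)) res$voltage_t else NULL,
    V_final = res$V_final,
    config = list(seed = seed, dt = dt, duration = duration,
                  protocol = protocol, N_total = n,
                  n_per_group = stats::setNames(column$pops$n,
                                                column$pops$group),
                  network_seed = column$seed,
                  provenance = column$provenance)),
    class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  cat("<simulation_record> ", x$config$duration, " ms, ",
      nrow(x$spikes), " spikes from ", x$config$N_total, " neurons\n",
      sep = "")
  cat("  protocol: ", x$config$protocol$name, "; seed ", x$config$seed,
      "; dt ", x$config$dt, " ms\n", sep = "")
  invisible(x)
}

#' @export
summary.simulation_record <- function(object, ...) {
  w <- c(0, object$config$duration)
  data.frame(group = names(object$config$n_per_group),
             n = as.integer(object$config$n_per_group),
             rate_hz = as.numeric(mean_rates(object, w)),
             row.names = NULL)
}

#' Raster plot of a simulation
#'
#' @param x A `simulation_record`.
#' @param groups Groups to show (default all, canonical order).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.simulation_record <- function(x, groups = column_groups(), ...) {
  sp <- x$spikes[x$spikes$group %in% groups, ]
  graphics::plot(sp$time_ms, sp$neuron_id, pch = ".", cex = 0.8,
                 xlab = "time (ms)", ylab = "neuron",
                 main = paste("raster:", x$config$protocol$name), ...)
  invisible(x)
}
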