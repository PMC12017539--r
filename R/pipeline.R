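#' Perturbation experiment plan
#'
#' Fixes everything a perturbation sweep needs: the state and its drive
#' amplitude, the perturbation amplitude, the categorisation threshold, the
#' master seed, and the timing (state onset, settling margin, matched
#' baseline/post windows). The default timing gives each simulation a 3 s
#' baseline window after a 1 s settling margin, then a 3 s post-perturbation
#' window.
#'
#' @param state State name (see [make_state_protocol()]).
#' @param state_amplitude State-drive amplitude, pA.
#' @param perturb_amplitude Perturbation amplitude, pA (may be negative).
#' @param threshold Categorisation threshold, percent.
#' @param master_seed Integer master seed shared by every member simulation.
#' @param state_onset State-drive onset, ms.
#' @param settle Settling margin between state onset and the baseline
#'   window, ms.
#' @param window Length of the (equal) baseline and post windows, ms.
#' @param dt Integration step, ms.
#' @param n_realizations Number of seeded network/noise realizations
#'   (matrices are computed per realization; > 1 reports mean and SD).
#' @return Object of class `experiment_plan`.
#' @export
experiment_plan <- function(state = "spontaneous", state_amplitude = 150,
                            perturb_amplitude = 30, threshold = 20,
                            master_seed = 1, state_onset = 700,
                            settle = 1000, window = 3000, dt = 0.1,
                            n_realizations = 1) {
  stopifnot(window > 0, settle >= 0, is.finite(perturb_amplitude))
  structure(list(state = state, state_amplitude = state_amplitude,
                 perturb_amplitude = perturb_amplitude, threshold = threshold,
                 master_seed = master_seed, state_onset = state_onset,
                 settle = settle, window = window, dt = dt,
                 n_realizations = n_realizations),
            class = "experiment_plan")
}

plan_times <- function(plan) {
  t_base <- plan$state_onset + plan$settle
  t_pert <- t_base + plan$window
  list(baseline = c(t_base, t_pert),
       post = c(t_pert, t_pert + plan$window),
       t_pert = t_pert,
       duration_state = t_pert,
       duration_full = t_pert + plan$window)
}

#' Establish a state and measure baseline rates
#'
#' Simulates the plan's state drive alone and returns the per-group mean
#' rates over the baseline window (after the settling margin).
#'
#' @param plan An [experiment_plan()].
#' @param column A `cortical_column`.
#' @return List with `rates` (all 17 groups), `record`.
#' @export
run_state <- function(plan, column) {
  tt <- plan_times(plan)
  protocol <- make_state_protocol(plan$state, amplitude = plan$state_amplitude,
                                  t_on = plan$state_onset)
  rec <- run_simulation(column, protocol, duration = tt$duration_state,
                        dt = plan$dt, seed = plan$master_seed)
  list(rates = stats::setNames(mean_rates(rec, tt$baseline), column_groups()),
       record = rec)
}

#' Full 16-population perturbation sweep
#'
#' One state-only simulation plus one simulation per perturbable group: the
#' state drive is established, a DC perturbation is added to the whole group
#' after a settled baseline period, and mean rates are measured over the
#' measurement window. Every member simulation uses the same master seed
#' (identical background and target-selection streams), so the unperturbed
#' run evaluated over the *same* window is the exact counterfactual baseline:
#' rate changes are attributable to the perturbation alone, and a
#' perturbation amplitude of 0 yields an exactly zero matrix.
#'
#' @param plan An [experiment_plan()].
#' @param column A `cortical_column`.
#' @return A `response_matrix` (see [response_matrix()]); its categorical
#'   view is available via [categorize()].
#' @export
perturbation_sweep <- function(plan, column) {
  tt <- plan_times(plan)
  state_protocol <- make_state_protocol(plan$state,
                                        amplitude = plan$state_amplitude,
                                        t_on = plan$state_onset)
  g <- perturbable_groups()
  base_rec <- run_simulation(column, state_protocol,
                             duration = tt$duration_full,
                             dt = plan$dt, seed = plan$master_seed)
  baseline <- stats::setNames(mean_rates(base_rec, tt$post, groups = g), g)
  perturbed <- vector("list", length(g))
  names(perturbed) <- g
  for (y in g) {
    protocol <- add_perturbation(state_protocol, y,
                                 amplitude = plan$perturb_amplitude,
                                 t_on = tt$t_pert,
                                 t_off = tt$post[2])
    rec <- run_simulation(column, protocol, duration = tt$duration_full,
                          dt = plan$dt, seed = plan$master_seed)
    perturbed[[y]] <- stats::setNames(mean_rates(rec, tt$post, groups = g), g)
  }
  response_matrix(baseline, perturbed, threshold = plan$threshold)
}

#' Marked-change counts across state-drive strengths
#'
#' Runs one perturbation sweep per state-drive amplitude and reports how
#' many response-matrix entries are marked (beyond the threshold) and which
#' fraction of them are increases. The default amplitude grid is 14 evenly
#' spaced values spanning 0-400 pA.
#'
#' @param family State family: `"ff"` (feedforward drive varied), `"fb"`
#'   (layer-5 feedback drive varied), `"ff_fixed_fb_varying"` or
#'   `"fb_fixed_ff_varying"` (combined state with one drive fixed at the
#'   plan's `state_amplitude`).
#' @param amplitudes Amplitude grid, pA.
#' @param plan An [experiment_plan()].
#' @param column A `cortical_column`.
#' @return Data frame `amplitude`, `n_marked`, `positive_fraction`; the
#'   response matrices as attribute `"matrices"`.
#' @export
condition_sweep <- function(family = c("ff", "fb", "ff_fixed_fb_varying",
                                       "fb_fixed_ff_varying"),
                            amplitudes = seq(0, 400, length.out = 14),
                            plan, column) {
  family <- match.arg(family)
  if (!length(amplitudes)) stop("amplitude list must be nonempty")
  state <- switch(family, ff = "ff", fb = "fb_L5",
                  ff_fixed_fb_varying = "ff_fb", fb_fixed_ff_varying = "ff_fb")
  mats <- vector("list", length(amplitudes))
  rows <- vector("list", length(amplitudes))
  for (i in seq_along(amplitudes)) {
    p <- plan
    p$state <- state
    p$state_amplitude <- amplitudes[i]
    mats[[i]] <- perturbation_sweep(p, column)
    cm <- count_marked(categorize(mats[[i]]))
    rows[[i]] <- data.frame(amplitude = amplitudes[i],
                            n_marked = cm[["n_marked"]],
                            positive_fraction = cm[["positive_fraction"]])
  }
  out <- do.call(rbind, rows)
  attr(out, "matrices") <- mats
  out
}

#' Marked-change counts over perturbation amplitudes and thresholds
#'
#' One perturbation sweep per amplitude in the plan's state; each sweep's
#' percent-change matrix is categorised at every threshold, yielding a
#' (amplitude x threshold) surface of marked-change counts. Counts are
#' non-increasing in the threshold at fixed amplitude.
#'
#' @param plan An [experiment_plan()].
#' @param column A `cortical_column`.
#' @param amplitudes Perturbation amplitudes, pA (default the signed grid
#'   -40..40 excluding 0).
#' @param thresholds Percent thresholds (default 5..200).
#' @return Integer matrix amplitudes x thresholds; the sweeps as attribute
#'   `"matrices"`.
#' @export
amplitude_threshold_scan <- function(plan, column,
                                     amplitudes = c(-40, -30, -20, -10,
                                                    10, 20, 30, 40),
                                     thresholds = c(5, 10, 20, 30, 40, 50,
                                                    70, 80, 90, 100, 150,
                                                    200)) {
  stopifnot(all(thresholds > 0))
  out <- matrix(0L, length(amplitudes), length(thresholds),
                dimnames = list(amplitude = amplitudes,
                                threshold = thresholds))
  mats <- vector("list", length(amplitudes))
  for (i in seq_along(amplitudes)) {
    p <- plan
    p$perturb_amplitude <- amplitudes[i]
    mats[[i]] <- perturbation_sweep(p, column)
    for (j in seq_along(thresholds)) {
      cm <- count_marked(categorize(mats[[i]], threshold = thresholds[j]))
      out[i, j] <- as.integer(cm[["n_marked"]])
    }
  }
  attr(out, "matrices") <- mats
  out
}
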