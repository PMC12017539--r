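#' Sample a reproducible fraction of a population
#'
#' Uniform sampling without replacement of `round(fraction * n)` neurons of
#' one group; the same (group, fraction, seed) always returns the same set,
#' independently of the caller's RNG state.
#'
#' @param column A `cortical_column`.
#' @param group Group label.
#' @param fraction Proportion in \[0, 1\].
#' @param seed Integer seed.
#' @return Sorted integer vector of global neuron ids.
#' @export
select_fraction <- function(column, group, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  ids <- group_ids(column, group)
  size <- round(fraction * length(ids))
  if (size == 0) return(integer(0))
  if (size == length(ids)) return(ids)
  sort(with_seed(seed, sample(ids, size)))
}

#' Background Poisson spike trains
#'
#' Independent homogeneous Poisson trains, one private generator per neuron,
#' at each group's background rate. This is the event-time view of the drive
#' that the engine applies in per-step binned form to the background AMPA
#' channel.
#'
#' @param column A `cortical_column`.
#' @param duration Train length, ms.
#' @param seed Integer seed.
#' @return List (length `N_total`) of spike-time vectors, ms.
#' @export
background_trains <- function(column, duration, seed) {
  stopifnot(duration > 0)
  rates <- vapply(neuron_groups(column),
                  function(g) column$params[[g]]$nu_bg, numeric(1))
  with_seed(seed, {
    lapply(rates, function(nu) {
      k <- stats::rpois(1, nu * duration / 1000)
      sort(stats::runif(k, 0, duration))
    })
  })
}

new_protocol <- function(epochs, name = "custom") {
  structure(list(name = name, epochs = epochs), class = "stimulus_protocol")
}

empty_epochs <- function() {
  data.frame(target_group = character(0), fraction = numeric(0),
             amplitude = numeric(0), t_on = numeric(0), t_off = numeric(0),
             stringsAsFactors = FALSE)
}

#' State-drive stimulation protocols
#'
#' Constructs the DC-current protocols that put the column into its named
#' states. All state drives inject `amplitude` (default 150 pA) into 25% of
#' the pyramidal cells and 5% of the PV cells of the driven layer(s):
#' feedforward (`ff`) drives layer 4; the feedback variants drive layer 5
#' (`fb_L5`), layer 2/3 (`fb_L23`), layers 2/3+5 (`fb_L23_L5`), layer 6
#' (`fb_L6`) or layers 2/3+5+6 (`fb_L23_L5_L6`); `ff_fb` combines the
#' feedforward drive (onset 500 ms) with the layer-5 feedback drive (onset
#' 1100 ms); `spontaneous` has no epochs. Epochs last until the end of the
#' simulation.
#'
#' @param name State name.
#' @param amplitude DC amplitude, pA.
#' @param t_on Drive onset, ms (single-drive states; default 700).
#' @param t_on_ff,t_on_fb Onsets of the combined state's two drives, ms.
#' @param e_fraction,pv_fraction Targeted fractions of the E and PV groups.
#' @return A `stimulus_protocol`.
#' @export
make_state_protocol <- function(name = c("spontaneous", "ff", "fb_L5",
                                         "fb_L23", "fb_L23_L5", "fb_L6",
                                         "fb_L23_L5_L6", "ff_fb"),
                                amplitude = 150, t_on = 700,
                                t_on_ff = 500, t_on_fb = 1100,
                                e_fraction = 0.25, pv_fraction = 0.05) {
  name <- match.arg(name)
  stopifnot(amplitude >= 0)
  layer_epochs <- function(layers, on) {
    do.call(rbind, lapply(layers, function(l) {
      data.frame(target_group = paste0(c("E", "PV"), l),
                 fraction = c(e_fraction, pv_fraction),
                 amplitude = amplitude, t_on = on, t_off = Inf,
                 stringsAsFactors = FALSE)
    }))
  }
  ep <- switch(name,
    spontaneous  = empty_epochs(),
    ff           = layer_epochs("4", t_on),
    fb_L5        = layer_epochs("5", t_on),
    fb_L23       = layer_epochs("23", t_on),
    fb_L23_L5    = layer_epochs(c("23", "5"), t_on),
    fb_L6        = layer_epochs("6", t_on),
    fb_L23_L5_L6 = layer_epochs(c("23", "5", "6"), t_on),
    ff_fb        = rbind(layer_epochs("4", t_on_ff),
                         layer_epochs("5", t_on_fb)))
  new_protocol(ep, name)
}

#' Append a single-group perturbation epoch
#'
#' Adds a DC epoch delivering `amplitude` (default 30 pA; negative values
#' allowed) to the whole named group, starting at `t_on` and lasting through
#' `t_off`. The layer-1 VIP group is not perturbable: response matrices are
#' 16x16 over the complete-layer groups.
#'
#' @param base A `stimulus_protocol`.
#' @param group One of [perturbable_groups()].
#' @param amplitude Perturbation current, pA (may be negative).
#' @param t_on,t_off Epoch window, ms.
#' @param fraction Targeted fraction of the group (default 1: the whole
#'   group).
#' @return The extended `stimulus_protocol`.
#' @export
add_perturbation <- function(base, group, amplitude = 30, t_on = 0,
                             t_off = Inf, fraction = 1) {
  if (!group %in% perturbable_groups())
    stop("group ", group, " is not perturbable: the layer-1 VIP group is ",
         "excluded from the 16x16 perturbation design")
  stopifnot(t_off > t_on)
  ep <- rbind(base$epochs,
              data.frame(target_group = group, fraction = fraction,
                         amplitude = amplitude, t_on = t_on, t_off = t_off,
                         stringsAsFactors = FALSE))
  new_protocol(ep, paste0(base$name, "+", group))
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol> ", x$name, ": ", nrow(x$epochs), " epoch(s)\n",
      sep = "")
  if (nrow(x$epochs)) print(x$epochs, row.names = FALSE)
  invisible(x)
}

# resolve epochs to neuron id sets; epoch target seeds depend only on the
# epoch index and group, so a protocol prefix resolves identically whether or
# not later epochs (perturbations) are present
resolve_epochs <- function(column, protocol, seed, duration) {
  ep <- protocol$epochs
  if (nrow(ep) == 0)
    return(list(on = integer(0), off = integer(0), amp = numeric(0),
                ptr = 0L, ids = integer(0)))
  ids <- vector("list", nrow(ep))
  for (i in seq_len(nrow(ep))) {
    s <- substream_seed(seed, paste0("targets:", ep$target_group[i]), i)
    ids[[i]] <- select_fraction(column, ep$target_group[i], ep$fraction[i], s)
  }
  t_off <- pmin(ep$t_off, duration)
  list(on = ep$t_on, off = t_off, amp = ep$amplitude,
       ptr = cumsum(c(0L, lengths(ids))), ids = unlist(ids))
}
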