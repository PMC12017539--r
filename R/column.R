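#' Build a cortical column network
#'
#' Instantiates the 17 populations, realizes the neuron-to-neuron synapses
#' from the group matrices (with probability correction, size-invariant
#' weights and the AMPA/NMDA receptor split) and precomputes the adjacency
#' structure used by the simulation engine. The connectivity stream is
#' derived from `seed`, so the same (bundle, N_total, seed) always yields a
#' bit-identical network.
#'
#' @param bundle A [column_bundle()] (e.g. [synthetic_bundle()]).
#' @param N_total Total number of neurons (default 5000).
#' @param seed Master integer seed; the connectivity substream is derived
#'   from it.
#' @param lognormal Draw individual synaptic weights from a lognormal
#'   distribution (mean = SD = the projection's uniform weight).
#' @param lesion_inhibition Remove all GABA synapses (inhibitory-output
#'   lesion) while keeping interneurons in the network.
#' @return Object of class `cortical_column`.
#' @export
build_column <- function(bundle, N_total = 5000, seed = 1,
                         lognormal = FALSE, lesion_inhibition = FALSE) {
  params_table <- split(bundle$cell_params, bundle$cell_params$group)
  params_table <- lapply(params_table, function(r)
    cell_type_params(r$group, r$V_rest, r$V_th, r$C_m, r$g_L, r$tau_ref,
                     r$nu_bg))
  pops <- build_populations(bundle$fractions, N_total, params_table)
  syn <- realize_connectivity(pops, bundle$spec,
                              seed = substream_seed(seed, "connectivity"))
  if (lognormal)
    syn <- lognormalize_weights(syn, substream_seed(seed, "lognormal"))
  if (lesion_inhibition)
    syn <- lesion_inhibitory_output(syn)
  structure(list(pops = pops, params = params_table, synapses = syn,
                 kinetics = synapse_kinetics(Mg = bundle$globals$Mg),
                 globals = bundle$globals, seed = seed,
                 provenance = bundle$provenance,
                 csr = build_csr(syn, N_total),
                 N_total = N_total),
            class = "cortical_column")
}

# compressed row (by presynaptic neuron) adjacency per receptor, 0-based
build_csr <- function(syn, n) {
  per <- function(rc) {
    rows <- syn[syn$receptor == rc, , drop = FALSE]
    o <- order(rows$pre)
    rows <- rows[o, ]
    counts <- tabulate(rows$pre, nbins = n)
    list(ptr = as.integer(cumsum(c(0L, counts))),
         post = as.integer(rows$post - 1L),
         w = as.numeric(rows$weight))
  }
  list(AMPA = per("AMPA"), NMDA = per("NMDA"), GABA = per("GABA"))
}

# global neuron ids of one group
group_ids <- function(column, group) {
  i <- match(group, column$pops$group)
  if (is.na(i)) stop("unknown group: ", group)
  seq.int(column$pops$first_id[i], length.out = column$pops$n[i])
}

# group label of each neuron id
neuron_groups <- function(column) {
  rep(column$pops$group, column$pops$n)
}

#' @export
print.cortical_column <- function(x, ...) {
  cat("<cortical_column> ", x$N_total, " neurons, ",
      nrow(x$synapses), " synapses (", x$provenance, ")\n", sep = "")
  tab <- table(x$synapses$receptor)
  cat("  receptors: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.cortical_column <- function(object, ...) {
  pops <- object$pops
  deg <- tabulate(object$synapses$post, nbins = object$N_total)
  pops$mean_in_degree <- vapply(seq_len(nrow(pops)), function(i) {
    ids <- seq.int(pops$first_id[i], length.out = pops$n[i])
    mean(deg[ids])
  }, numeric(1))
  pops
}
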