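#' Canonical cell-group labels of the column
#'
#' The column contains 17 cell groups: VIP interneurons in layer 1 and four
#' cell types (pyramidal E, PV, SST and VIP interneurons) in each of layers
#' 2/3, 4, 5 and 6. All matrix interfaces (probability, strength, width,
#' response matrices) use this fixed layer-major order.
#'
#' @return Character vector of the 17 group labels.
#' @export
column_groups <- function() {
  c("VIP1",
    "E23", "PV23", "SST23", "VIP23",
    "E4",  "PV4",  "SST4",  "VIP4",
    "E5",  "PV5",  "SST5",  "VIP5",
    "E6",  "PV6",  "SST6",  "VIP6")
}

#' Groups eligible for perturbation (all except layer-1 VIP)
#'
#' Response matrices are 16x16: the lone layer-1 group is excluded both as a
#' perturbation target and as an observed population.
#'
#' @return Character vector of 16 group labels.
#' @export
perturbable_groups <- function() {
  setdiff(column_groups(), "VIP1")
}

# cell type ("E","PV","SST","VIP") of each group label
group_type <- function(groups = column_groups()) {
  sub("[0-9/]+$", "", groups)
}

# layer label ("1","23","4","5","6") of each group
group_layer <- function(groups = column_groups()) {
  sub("^[A-Z]+", "", groups)
}

is_excitatory_group <- function(groups = column_groups()) {
  group_type(groups) == "E"
}

#' Default population fractions of the synthetic column
#'
#' Fraction of the total neuron count assigned to each of the 17 groups. Each
#' complete layer (2/3, 4, 5, 6) is 85% pyramidal and 15% interneurons, with
#' the interneuron mass split between PV, SST and VIP in layer-specific
#' proportions (PV-dominated in layers 4-6, VIP-rich in layer 2/3); layer 1
#' holds a small all-VIP population.
#'
#' @return Named numeric vector over [column_groups()] summing to 1.
#' @export
default_fractions <- function() {
  layer_share <- c("1" = 0.02, "23" = 0.28, "4" = 0.25, "5" = 0.17, "6" = 0.28)
  inh_split <- list( # shares of the 15% interneuron mass: PV, SST, VIP
    "23" = c(PV = 0.40, SST = 0.30, VIP = 0.30),
    "4"  = c(PV = 0.55, SST = 0.35, VIP = 0.10),
    "5"  = c(PV = 0.50, SST = 0.40, VIP = 0.10),
    "6"  = c(PV = 0.55, SST = 0.40, VIP = 0.05))
  g <- column_groups()
  fr <- numeric(length(g))
  names(fr) <- g
  fr["VIP1"] <- layer_share["1"]
  for (ly in c("23", "4", "5", "6")) {
    fr[paste0("E", ly)] <- layer_share[ly] * 0.85
    for (tp in c("PV", "SST", "VIP")) {
      fr[paste0(tp, ly)] <- layer_share[ly] * 0.15 * inh_split[[ly]][tp]
    }
  }
  fr
}

# deterministic sub-stream seed derivation: one master seed spawns named
# streams (connectivity, background, target selection, ...) so runs are
# bit-identical while a single stream can be varied independently
substream_seed <- function(master, name, index = 0L) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes))
  as.integer((as.double(master) %% 65536 * 48271 + h * 1009 + index * 7919) %%
               2147483647)
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
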