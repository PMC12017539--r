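#' Group-level connectivity specification
#'
#' Holds the three 17x17 group-level matrices (connection probabilities `P`,
#' synaptic strengths `S` in mV, Gaussian connection widths `sigma` in µm)
#' together with the global coupling `G` (1/mV), the AMPA/NMDA receptor split
#' and the column radii used by the probability correction. Rows index the
#' presynaptic group, columns the postsynaptic group, in canonical order
#' ([column_groups()]). The strength matrix carries 288 defined entries: the
#' layer-1 self-projection (VIP1 to VIP1) is undefined and stored as `NA`
#' (treated as zero strength).
#'
#' @param P 17x17 probability matrix in \[0, 1\].
#' @param S 17x17 strength matrix, mV (VIP1->VIP1 may be `NA`).
#' @param sigma 17x17 Gaussian width matrix, µm (positive wherever `P > 0`).
#' @param G Global coupling factor, 1/mV.
#' @param nmda_fraction Fraction of excitatory contacts targeting NMDA
#'   receptors (AMPA receives the complement).
#' @param R Column radius of the simulated network, µm.
#' @param R0 Reference radius at which the probabilities were measured, µm.
#' @return Object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(P, S, sigma, G = 5, nmda_fraction = 0.2,
                              R = 125, R0 = 75) {
  g <- column_groups()
  for (nm in c("P", "S", "sigma")) {
    m <- get(nm)
    if (!is.matrix(m) || !identical(dim(m), c(17L, 17L)))
      stop(nm, " must be a 17x17 matrix")
    if (is.null(rownames(m)) || !identical(rownames(m), g) ||
        !identical(colnames(m), g))
      stop(nm, " must carry the canonical group labels on rows and columns")
  }
  if (anyNA(P) || any(P < 0 | P > 1))
    stop("probabilities must lie in [0, 1] with no missing entries")
  if (any(is.na(S) & !(row(S) == 1 & col(S) == 1)))
    stop("only the VIP1->VIP1 strength may be undefined")
  if (any(sigma[P > 0] <= 0, na.rm = TRUE))
    stop("sigma must be positive wherever P > 0")
  if (G <= 0) stop("G must be positive")
  if (nmda_fraction < 0 || nmda_fraction > 1)
    stop("nmda_fraction must lie in [0, 1]")
  if (R <= 0 || R0 <= 0) stop("radii must be positive")
  structure(list(P = P, S = S, sigma = sigma, G = G,
                 nmda_fraction = nmda_fraction, R = R, R0 = R0),
            class = "connectivity_spec")
}

#' Number of defined entries in the strength matrix
#'
#' The probability interface carries all 17x17 = 289 group pairs; the
#' strength interface defines 16x16 + 16x2 = 288 of them, the layer-1
#' self-projection being absent.
#'
#' @param spec A [connectivity_spec()].
#' @return Integer count of non-missing strength entries.
#' @export
defined_strengths <- function(spec) {
  sum(!is.na(spec$S))
}

#' Partition neurons into the 17 populations
#'
#' Converts target fractions into integer group sizes by largest-remainder
#' rounding (ties broken by canonical group order) so that the counts sum
#' exactly to `N_total`; any group left empty by rounding is topped up from
#' the largest group so that every population is non-empty.
#'
#' @param fractions Named numeric vector over [column_groups()] summing to 1.
#' @param N_total Total neuron count (>= 17).
#' @param params_table Named list of [cell_type_params()], one per group.
#' @return A data frame with one row per group: `group`, `n`, `first_id`
#'   (1-based index of the group's first neuron in the global ordering).
#' @export
build_populations <- function(fractions, N_total, params_table) {
  g <- column_groups()
  stopifnot(N_total >= 17)
  if (!all(g %in% names(fractions)))
    stop("fractions must cover all 17 canonical groups")
  fractions <- fractions[g]
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("population fractions must sum to 1 (got ", sum(fractions), ")")
  if (!all(g %in% names(params_table)))
    stop("params_table must cover all 17 canonical groups")
  target <- fractions * N_total
  n <- floor(target)
  rem <- N_total - sum(n)
  if (rem > 0) {
    ord <- order(-(target - n), seq_along(g)) # largest remainder, canonical ties
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  while (any(n == 0)) {
    n[which.max(n)] <- max(n) - 1
    n[which(n == 0)[1]] <- 1
  }
  data.frame(group = g, n = as.integer(n),
             first_id = cumsum(c(1L, as.integer(n)))[seq_along(g)],
             stringsAsFactors = FALSE)
}

#' Disk-uniform connection-probability correction
#'
#' Group-level probabilities measured over a reference column of radius `R0`
#' with a Gaussian lateral profile `A exp(-r^2/sigma^2)` are translated into
#' the uniform probability over the simulated column of radius `R`:
#' `P_new = p_rep (R0^2/R^2) (1 - exp(-R^2/sigma^2)) / (1 - exp(-R0^2/sigma^2))`.
#' For flat profiles (`sigma -> Inf`) the correction vanishes; for narrow
#' profiles it approaches `p_rep R0^2 / R^2`. The result is clamped to
#' \[0, 1\].
#'
#' @param p_rep Reported probability in \[0, 1\] (vectorised).
#' @param sigma Gaussian width, µm (vectorised).
#' @param R Simulated column radius, µm.
#' @param R0 Reference radius, µm.
#' @return Corrected probability in \[0, 1\].
#' @export
correct_probability <- function(p_rep, sigma, R = 125, R0 = 75) {
  if (any(p_rep < 0 | p_rep > 1, na.rm = TRUE))
    stop("p_rep must lie in [0, 1]")
  if (any(sigma <= 0, na.rm = TRUE) || R <= 0 || R0 <= 0)
    stop("sigma and radii must be positive")
  ratio <- -expm1(-(R / sigma)^2) / -expm1(-(R0 / sigma)^2)
  ratio[!is.finite(ratio)] <- (R / R0)^2 # flat-profile (sigma -> Inf) limit
  pmin(1, pmax(0, p_rep * (R0 / R)^2 * ratio))
}

#' Size-invariant synaptic weight
#'
#' Dimensionless weight of every realized synapse between two groups:
#' `w = G * ws / (N_send * p)`, so the *expected* summed weight onto a target
#' neuron from a source group, `N_send * p * w = G * ws`, is independent of
#' network size.
#'
#' @param G Global coupling, 1/mV.
#' @param ws Group-level strength, mV.
#' @param N_send Size of the sending population.
#' @param p Connection probability actually used to realize the projection.
#' @return Dimensionless weight.
#' @export
compute_weight <- function(G, ws, N_send, p) {
  stopifnot(N_send >= 1)
  if (any(p == 0 & ws != 0))
    stop("connection declared (ws != 0) but impossible (p = 0)")
  ifelse(ws == 0, 0, G * ws / (N_send * p))
}

# Bernoulli-realize one ordered group pair for one receptor channel.
# Returns integer matrix with columns pre, post (global ids).
draw_pairs <- function(n_pre, n_post, first_pre, first_post, p, self_pair) {
  m <- n_pre * n_post
  if (p <= 0 || m == 0) return(cbind(pre = integer(0), post = integer(0)))
  k <- stats::rbinom(1, m, p)
  if (k == 0) return(cbind(pre = integer(0), post = integer(0)))
  idx <- sample.int(m, k) - 1L
  pre <- idx %% n_pre + 1L
  post <- idx %/% n_pre + 1L
  if (self_pair) {
    keep <- pre != post # no autapses
    pre <- pre[keep]; post <- post[keep]
  }
  cbind(pre = pre + first_pre - 1L, post = post + first_post - 1L)
}

#' Realize neuron-to-neuron connectivity
#'
#' Draws every ordered neuron pair independently (Bernoulli) for each receptor
#' channel. Excitatory projections are split over the two glutamatergic
#' channels: contacts targeting AMPA receptors are drawn with probability
#' `p * (1 - nmda_fraction)` and NMDA contacts independently with
#' `p * nmda_fraction`; inhibitory projections are drawn once for GABA.
#' Probabilities are first passed through [correct_probability()] using the
#' per-projection Gaussian widths; weights follow [compute_weight()] with the
#' corrected probability. Self-connections are excluded; at most one synapse
#' exists per (pre, post, receptor) triple. Fully reproducible under `seed`.
#'
#' @param pops Population table from [build_populations()].
#' @param spec A [connectivity_spec()].
#' @param seed Integer seed for the connectivity stream.
#' @param correct Apply the probability correction (default `TRUE`).
#' @return A `synapse_table` data frame with columns `pre`, `post`,
#'   `receptor` (factor: AMPA/NMDA/GABA) and `weight`.
#' @export
realize_connectivity <- function(pops, spec, seed, correct = TRUE) {
  g <- column_groups()
  if (!all(g %in% pops$group))
    stop("population table must cover all groups named in P")
  pops <- pops[match(g, pops$group), ]
  exc <- is_excitatory_group(g)
  out <- vector("list", 17 * 17 * 2)
  k <- 0L
  with_seed(seed, {
    for (a in seq_along(g)) {
      for (b in seq_along(g)) {
        p <- spec$P[a, b]
        ws <- spec$S[a, b]
        if (is.na(ws)) ws <- 0
        if (p <= 0 || ws == 0) next
        if (correct)
          p <- correct_probability(p, spec$sigma[a, b], spec$R, spec$R0)
        if (p <= 0) next
        w <- compute_weight(spec$G, ws, pops$n[a], p)
        self <- a == b
        if (exc[a]) {
          channels <- list(AMPA = p * (1 - spec$nmda_fraction),
                           NMDA = p * spec$nmda_fraction)
        } else {
          channels <- list(GABA = p)
        }
        for (rc in names(channels)) {
          pr <- draw_pairs(pops$n[a], pops$n[b], pops$first_id[a],
                           pops$first_id[b], channels[[rc]], self)
          if (nrow(pr) == 0) next
          k <- k + 1L
          out[[k]] <- data.frame(pre = pr[, "pre"], post = pr[, "post"],
                                 receptor = rc, weight = w,
                                 stringsAsFactors = FALSE)
        }
      }
    }
  })
  tab <- if (k == 0) {
    data.frame(pre = integer(0), post = integer(0),
               receptor = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, out[seq_len(k)])
  tab$receptor <- factor(tab$receptor, levels = c("AMPA", "NMDA", "GABA"))
  class(tab) <- c("synapse_table", "data.frame")
  tab
}

#' Replace uniform projection weights by lognormal draws
#'
#' Each nonzero weight is replaced by an independent lognormal draw whose
#' arithmetic mean equals the original weight and whose arithmetic standard
#' deviation equals that mean (so `sdlog^2 = ln 2` and
#' `meanlog = ln(mean) - ln(2)/2`). Zero weights, receptor labels and
#' topology are untouched.
#'
#' @param table A `synapse_table`.
#' @param seed Integer seed.
#' @return The table with resampled weights.
#' @export
lognormalize_weights <- function(table, seed) {
  if (any(table$weight < 0)) stop("weights must be non-negative")
  nz <- table$weight > 0
  sdlog <- sqrt(log(2))
  with_seed(seed, {
    table$weight[nz] <- stats::rlnorm(sum(nz),
                                      meanlog = log(table$weight[nz]) - log(2) / 2,
                                      sdlog = sdlog)
  })
  table
}

#' Silence all inhibitory output
#'
#' Removes every GABA synapse from the table while leaving the excitatory
#' rows (and hence the inhibitory neurons' own inputs and spiking) intact:
#' interneurons keep firing but their signals no longer reach any target.
#'
#' @param table A `synapse_table`.
#' @return The table without GABA rows.
#' @export
lesion_inhibitory_output <- function(table) {
  out <- table[table$receptor != "GABA", , drop = FALSE]
  rownames(out) <- NULL
  out
}
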