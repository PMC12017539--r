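#' Assemble a column bundle
#'
#' A bundle collects everything needed to build a column: the three 17x17
#' group matrices, the per-group cell-parameter table (including background
#' rates), the population fractions and the global constants. Validation is
#' total: the first offending entry is named in the error.
#'
#' @param P,S,sigma 17x17 labelled matrices (probabilities, strengths in mV,
#'   Gaussian widths in µm).
#' @param cell_params Data frame with columns `group`, `V_rest`, `V_th`,
#'   `C_m`, `g_L`, `tau_ref`, `nu_bg`, one row per group.
#' @param fractions Named numeric vector of population fractions.
#' @param globals List with elements `G`, `nmda_fraction`, `R`, `R0`, `dt`,
#'   `Mg`.
#' @param provenance `"synthetic"` or `"user-supplied"`.
#' @return Object of class `column_bundle`.
#' @export
column_bundle <- function(P, S, sigma, cell_params, fractions,
                          globals = list(G = 5, nmda_fraction = 0.2,
                                         R = 125, R0 = 75, dt = 0.1, Mg = 1),
                          provenance = "user-supplied") {
  spec <- connectivity_spec(P, S, sigma, G = globals$G,
                            nmda_fraction = globals$nmda_fraction,
                            R = globals$R, R0 = globals$R0)
  g <- column_groups()
  need <- c("group", "V_rest", "V_th", "C_m", "g_L", "tau_ref", "nu_bg")
  if (!all(need %in% names(cell_params)))
    stop("cell_params must carry columns ", paste(need, collapse = ", "))
  missing <- setdiff(g, cell_params$group)
  if (length(missing))
    stop("cell_params is missing group ", missing[1])
  cell_params <- cell_params[match(g, cell_params$group), ]
  for (i in seq_len(nrow(cell_params))) { # constructor validates each row
    r <- cell_params[i, ]
    cell_type_params(r$group, r$V_rest, r$V_th, r$C_m, r$g_L,
                     r$tau_ref, r$nu_bg)
  }
  if (!all(g %in% names(fractions)))
    stop("fractions must be named over the 17 canonical groups")
  structure(list(P = P, S = S, sigma = sigma, cell_params = cell_params,
                 fractions = fractions[g], globals = globals,
                 provenance = provenance, spec = spec),
            class = "column_bundle")
}

#' @export
print.column_bundle <- function(x, ...) {
  cat("<column_bundle> (", x$provenance, ")\n", sep = "")
  cat("  17 groups; mean connection probability ",
      round(mean(x$P), 4), "\n", sep = "")
  cat("  G = ", x$globals$G, " /mV, NMDA fraction ",
      x$globals$nmda_fraction, ", radii ", x$globals$R, "/", x$globals$R0,
      " um\n", sep = "")
  invisible(x)
}

# deterministic motif override helper
set_entry <- function(m, pre, post, value) {
  m[pre, post] <- value
  m
}

#' Seeded synthetic column bundle
#'
#' Generates a self-contained, reproducible stand-in for the experimentally
#' constrained connectivity: probabilities in \[0, 0.3\] with stronger
#' within-layer than across-layer coupling, strengths in \[0.1, 2\] mV,
#' Gaussian widths in \[50, 300\] µm, physiological leaky integrate-and-fire
#' parameters per cell type, and background rates placing the column in a
#' low-rate, inhibition-dominated asynchronous regime. On top of the seeded
#' base matrices a fixed set of canonical microcircuit motifs is imposed:
#' a feedforward excitatory chain out of layer 4, recruitment of translaminar
#' inhibition by layer-5 pyramidal cells, layer-6 projections onto PV cells
#' of other layers, and VIP->SST disinhibition. The same seed always returns
#' an identical bundle.
#'
#' @param seed Integer seed.
#' @param regime `"sparse"` (default) or `"dense"` (probabilities scaled by
#'   1.5, clamped to 1).
#' @return A [column_bundle()] with provenance `"synthetic"`.
#' @export
synthetic_bundle <- function(seed = 1, regime = c("sparse", "dense")) {
  regime <- match.arg(regime)
  g <- column_groups()
  tp <- group_type(g)
  ly <- group_layer(g)
  n <- length(g)
  base <- with_seed(substream_seed(seed, "bundle"), {
    P <- matrix(stats::runif(n * n, 0.01, 0.05), n, n, dimnames = list(g, g))
    S <- matrix(stats::runif(n * n, 0.10, 0.50), n, n, dimnames = list(g, g))
    sg <- matrix(stats::runif(n * n, 50, 300), n, n, dimnames = list(g, g))
    within <- outer(ly, ly, "==")
    P[within] <- stats::runif(sum(within), 0.06, 0.12)
    list(P = P, S = S, sigma = sg)
  })
  P <- base$P; S <- base$S; sigma <- base$sigma

  put <- function(pre, post, p, s) {
    P[pre, post] <<- p
    S[pre, post] <<- s
  }
  for (l in c("23", "4", "5", "6")) { # within-layer microcircuit
    E <- paste0("E", l); PV <- paste0("PV", l)
    SST <- paste0("SST", l); VIP <- paste0("VIP", l)
    put(E, E, 0.10, 0.50)
    put(E, PV, 0.15, 1.00); put(E, SST, 0.10, 0.80); put(E, VIP, 0.08, 0.60)
    put(PV, E, 0.20, 1.50); put(PV, PV, 0.15, 1.00)
    put(SST, E, 0.15, 1.00); put(SST, PV, 0.10, 0.80); put(SST, VIP, 0.10, 0.80)
    put(VIP, SST, 0.15, 1.20)
  }
  # feedforward chain out of layer 4
  put("E4", "E23", 0.12, 1.00)
  put("E23", "E5", 0.08, 0.60); put("E23", "E6", 0.05, 0.40)
  put("E4", "E5", 0.06, 0.50); put("E4", "E6", 0.06, 0.50)
  # layer-5 pyramids recruit inhibition across layers (top-down motif)
  for (l in c("23", "4", "6")) {
    put("E5", paste0("PV", l), 0.10, 1.20)
    put("E5", paste0("SST", l), 0.08, 1.00)
    put("E5", paste0("E", l), 0.02, 0.20)
  }
  # layer-6 translaminar inhibition via PV cells
  for (l in c("23", "4", "5")) put("E6", paste0("PV", l), 0.06, 0.80)
  # layer-1 VIP disinhibition of SST cells
  put("VIP1", "SST23", 0.08, 0.80)
  put("VIP1", "SST5", 0.08, 0.80)

  S["VIP1", "VIP1"] <- NA # the one undefined strength (288 defined entries)
  if (regime == "dense") P <- pmin(P * 1.5, 1)

  type_params <- list( # per cell type: V_rest, V_th, C_m, g_L, tau_ref, nu_bg
    E   = c(-75, -50, 180, 9.0, 2, 1950),
    PV  = c(-72, -48,  90, 9.0, 1, 2000),
    SST = c(-65, -45, 110, 5.5, 2, 1000),
    VIP = c(-68, -42,  70, 4.4, 1, 1100))
  cp <- do.call(rbind, lapply(seq_along(g), function(i) {
    v <- type_params[[tp[i]]]
    data.frame(group = g[i], V_rest = v[1], V_th = v[2], C_m = v[3],
               g_L = v[4], tau_ref = v[5], nu_bg = v[6],
               stringsAsFactors = FALSE)
  }))
  column_bundle(P, S, sigma, cp, default_fractions(),
                provenance = "synthetic")
}

read_matrix_csv <- function(path, what) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  g <- column_groups()
  if (!identical(dim(m), c(17L, 17L)))
    stop(what, " file ", path, " must be 17x17 (got ",
         paste(dim(m), collapse = "x"), ")")
  if (!identical(rownames(m), g))
    stop(what, " file ", path, ": row labels must be the canonical groups; ",
         "first mismatch at row ", which(rownames(m) != g)[1])
  if (!identical(colnames(m), g))
    stop(what, " file ", path, ": column labels must be the canonical groups")
  bad <- which(!is.na(m) & !is.finite(m))
  if (length(bad))
    stop(what, " file ", path, ": non-numeric or non-finite cell at ",
         rownames(m)[row(m)[bad[1]]], " -> ", colnames(m)[col(m)[bad[1]]])
  m
}

#' Read a column bundle from disk
#'
#' Expects a directory holding `P.csv`, `S.csv`, `sigma.csv` (17x17 labelled
#' matrices, rows = presynaptic group), `cell_params.csv` (per-group table)
#' and `globals.yaml`. Every file is validated; errors name the offending
#' entry.
#'
#' @param dir Directory path.
#' @param provenance Provenance tag recorded on the bundle.
#' @return A [column_bundle()].
#' @export
read_bundle <- function(dir, provenance = "user-supplied") {
  P <- read_matrix_csv(file.path(dir, "P.csv"), "probability")
  bad <- which(P < 0 | P > 1)
  if (length(bad))
    stop("probability outside [0, 1] at ",
         rownames(P)[row(P)[bad[1]]], " -> ", colnames(P)[col(P)[bad[1]]],
         " (", P[bad[1]], ")")
  S <- read_matrix_csv(file.path(dir, "S.csv"), "strength")
  sigma <- read_matrix_csv(file.path(dir, "sigma.csv"), "width")
  cp <- utils::read.csv(file.path(dir, "cell_params.csv"),
                        stringsAsFactors = FALSE)
  gl <- yaml::read_yaml(file.path(dir, "globals.yaml"))
  fr <- unlist(gl$fractions)
  gl$fractions <- NULL
  column_bundle(P, S, sigma, cp, fr, globals = gl, provenance = provenance)
}

#' Write a column bundle to disk
#'
#' Inverse of [read_bundle()]; writing then reading reproduces the bundle
#' exactly (up to provenance).
#'
#' @param bundle A [column_bundle()].
#' @param dir Directory path (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$P, file.path(dir, "P.csv"))
  utils::write.csv(bundle$S, file.path(dir, "S.csv"))
  utils::write.csv(bundle$sigma, file.path(dir, "sigma.csv"))
  utils::write.csv(bundle$cell_params, file.path(dir, "cell_params.csv"),
                   row.names = FALSE)
  gl <- bundle$globals
  gl$fractions <- as.list(bundle$fractions)
  yaml::write_yaml(gl, file.path(dir, "globals.yaml"))
  invisible(dir)
}

#' Write spikes to CSV
#'
#' @param record A `simulation_record`.
#' @param path Output file; header `neuron_id,group,time_ms`.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(record, path) {
  utils::write.csv(record$spikes[, c("neuron_id", "group", "time_ms")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a labelled matrix to CSV at full precision
#'
#' @param m Matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  df <- cbind(group = rownames(m), df)
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix_csv()]
#'
#' @param path CSV file.
#' @return Matrix with dimnames.
#' @export
read_matrix_out <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a run provenance file
#'
#' Records the seeds, step size, protocol and invocation so a run can be
#' reproduced bit-identically.
#'
#' @param info Named list.
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(info, path) {
  yaml::write_yaml(info, path)
  invisible(path)
}
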