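# Shared fixtures, built once per test run. Two synthetic columns are used:
# a 2000-neuron column for network-level statistics and state signatures, and
# a 800-neuron column for the sweep determinism checks.

fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env))
    assign(name, builder(), envir = fixture_env)
  get(name, envir = fixture_env)
}

test_bundle <- function() get_fixture("bundle", function() synthetic_bundle(7))

test_column <- function() get_fixture("column", function()
  build_column(test_bundle(), N_total = 2000, seed = 11))

mini_column <- function() get_fixture("mini", function()
  build_column(test_bundle(), N_total = 800, seed = 11))

# short-timescale plan used for sweep tests
mini_plan <- function(...) {
  experiment_plan(master_seed = 3, state_onset = 100, settle = 200,
                  window = 400, ...)
}

# a connectivity spec with exactly one nonzero projection between two named
# groups, with correction disabled by a flat profile (huge sigma)
make_pair_spec <- function(pre, post, p, ws = 0.5, G = 5) {
  g <- column_groups()
  P <- matrix(0, 17, 17, dimnames = list(g, g))
  S <- matrix(0, 17, 17, dimnames = list(g, g))
  sg <- matrix(100, 17, 17, dimnames = list(g, g))
  P[pre, post] <- p
  S[pre, post] <- ws
  S["VIP1", "VIP1"] <- NA
  connectivity_spec(P, S, sg, G = G)
}

# populations with chosen sizes for two groups and 1 neuron elsewhere
make_pair_pops <- function(pre, post, n_pre, n_post) {
  g <- column_groups()
  n <- rep(1L, 17)
  n[match(pre, g)] <- n_pre
  if (post != pre) n[match(post, g)] <- n_post
  data.frame(group = g, n = n,
             first_id = cumsum(c(1L, n))[1:17],
             stringsAsFactors = FALSE)
}

# single isolated neuron column: one neuron per group, no synapses, chosen
# parameters on one group, zero background
lone_neuron_column <- function(V_rest = -70, V_th = -50, C_m = 200, g_L = 10,
                               tau_ref = 2, nu_bg = 0, Mg = 1) {
  b <- synthetic_bundle(1)
  b$P[] <- 0
  b$cell_params$nu_bg[] <- 0
  b$cell_params[b$cell_params$group == "E23",
                c("V_rest", "V_th", "C_m", "g_L", "tau_ref", "nu_bg")] <-
    list(V_rest, V_th, C_m, g_L, tau_ref, nu_bg)
  b$globals$Mg <- Mg
  bundle <- column_bundle(b$P, b$S, b$sigma, b$cell_params, b$fractions,
                          b$globals, provenance = "synthetic")
  build_column(bundle, N_total = 17, seed = 1)
}

# DC protocol injecting a constant current into the E23 singleton
dc_protocol <- function(amplitude, t_on = 0, t_off = Inf) {
  add_perturbation(make_state_protocol("spontaneous"), "E23",
                   amplitude = amplitude, t_on = t_on, t_off = t_off)
}
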