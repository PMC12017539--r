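test_that("population rounding is exact, proportional and non-empty", {
  fr <- default_fractions()
  params <- setNames(vector("list", 17), column_groups())
  pops <- build_populations(fr, 5000, params)
  expect_identical(sum(pops$n), 5000L)
  expect_true(all(pops$n >= 1))
  # every complete layer is ~85% pyramidal
  for (l in c("23", "4", "5", "6")) {
    in_layer <- pops$group %in% paste0(c("E", "PV", "SST", "VIP"), l)
    e_frac <- pops$n[pops$group == paste0("E", l)] / sum(pops$n[in_layer])
    expect_equal(e_frac, 0.85, tolerance = 0.005)
  }
  # doubling the size doubles every group within rounding
  pops2 <- build_populations(fr, 10000, params)
  expect_true(all(abs(pops2$n - 2 * pops$n) <= 1))
  # all mass on one group
  fr1 <- setNames(c(1, rep(0, 16)), column_groups())
  pops1 <- build_populations(fr1, 100, params)
  expect_identical(pops1$n[pops1$group == "VIP1"], 100L - 16L)
  expect_error(build_populations(fr * 2, 100, params), "sum to 1")
})

test_that("probability correction has the flat and narrow profile limits", {
  p <- 0.2
  expect_identical(correct_probability(0, 100), 0)
  # flat profile: correction vanishes
  expect_equal(correct_probability(p, 1e6), p, tolerance = 1e-6)
  expect_equal(correct_probability(p, Inf), p)
  # narrow profile at the reference radii: (75/125)^2 = 0.36
  expect_equal(correct_probability(p, 1e-3), 0.36 * p, tolerance = 1e-9)
  # monotone increasing in sigma and bounded
  sig <- c(50, 75, 100, 150, 200, 300, 1000)
  v <- correct_probability(p, sig)
  expect_true(all(diff(v) > 0))
  v_wide <- correct_probability(p, c(sig, 1e4, 1e6))
  expect_true(all(v_wide >= 0.36 * p & v_wide <= p))
  expect_error(correct_probability(0.5, -1), "positive")
})

test_that("size-invariant weight follows w = G ws / (N_send p)", {
  expect_equal(compute_weight(5, 0.5, 100, 0.1), 0.25)
  expect_equal(compute_weight(5, 0.5, 200, 0.1),
               compute_weight(5, 0.5, 100, 0.1) / 2)
  expect_identical(compute_weight(5, 0, 100, 0.1), 0)
  expect_error(compute_weight(5, 0.5, 100, 0), "impossible")
  # expected summed input N p w = G ws is constant across network sizes
  for (N in c(2500, 5000, 10000)) {
    expect_equal(N * 0.1 * compute_weight(5, 0.7, N, 0.1), 5 * 0.7)
  }
})

test_that("realized connectivity matches Bernoulli expectation and the receptor split", {
  pops <- make_pair_pops("E23", "E4", 200, 200)
  spec <- make_pair_spec("E23", "E4", p = 0.5)
  tab <- realize_connectivity(pops, spec, seed = 5, correct = FALSE)
  m <- 200 * 200
  n_ampa <- sum(tab$receptor == "AMPA")
  n_nmda <- sum(tab$receptor == "NMDA")
  # binomial 99% bounds around 0.8*0.5*m and 0.2*0.5*m
  for (chk in list(c(n_ampa, 0.4), c(n_nmda, 0.1))) {
    expect_lt(abs(chk[1] - chk[2] * m), 2.58 * sqrt(m * chk[2] * (1 - chk[2])))
  }
  # weight identical on every row: G ws / (N p)
  expect_true(all(tab$weight == 5 * 0.5 / (200 * 0.5)))
  # p = 1 inhibitory pair: complete bipartite graph in GABA rows
  popsI <- make_pair_pops("PV4", "E4", 30, 40)
  specI <- make_pair_spec("PV4", "E4", p = 1)
  tabI <- realize_connectivity(popsI, specI, seed = 5, correct = FALSE)
  expect_identical(nrow(tabI), 30L * 40L)
  expect_true(all(tabI$receptor == "GABA"))
  # p = 1 self pair excludes autapses
  popsS <- make_pair_pops("PV4", "PV4", 30, 30)
  specS <- make_pair_spec("PV4", "PV4", p = 1)
  tabS <- realize_connectivity(popsS, specS, seed = 5, correct = FALSE)
  expect_identical(nrow(tabS), 30L * 29L)
  expect_true(all(tabS$pre != tabS$post))
  # p = 0 everywhere: empty table; reproducibility under seed
  expect_identical(nrow(realize_connectivity(pops,
    make_pair_spec("E23", "E4", p = 0.5, ws = 0), seed = 1)), 0L)
  expect_identical(realize_connectivity(pops, spec, seed = 5),
                   realize_connectivity(pops, spec, seed = 5))
})

test_that("Dale-type receptor segregation holds on a full synthetic column", {
  col <- test_column()
  tab <- col$synapses
  grp <- rep(col$pops$group, col$pops$n)
  pre_exc <- grepl("^E", grp[tab$pre])
  expect_true(all(pre_exc[tab$receptor %in% c("AMPA", "NMDA")]))
  expect_true(all(!pre_exc[tab$receptor == "GABA"]))
  expect_true(all(tab$pre != tab$post))
  expect_true(all(is.finite(tab$weight) & tab$weight >= 0))
})

test_that("per-pair realized counts stay within 4 sigma of expectation", {
  col <- test_column()
  b <- test_bundle()
  tab <- col$synapses
  grp <- rep(col$pops$group, col$pops$n)
  e_groups <- paste0("E", c("23", "4", "5", "6")) # the groups with n >= 100
  for (pre in e_groups) for (post in e_groups) {
    n_pre <- col$pops$n[col$pops$group == pre]
    n_post <- col$pops$n[col$pops$group == post]
    p <- correct_probability(b$P[pre, post], b$sigma[pre, post])
    ws <- b$S[pre, post]
    if (is.na(ws) || ws == 0 || p == 0) next
    m <- n_pre * n_post - (pre == post) * n_pre
    got <- sum(grp[tab$pre] == pre & grp[tab$post] == post)
    expect_lt(abs(got - m * p), 4 * sqrt(m * p * (1 - p)) + 1)
  }
})

test_that("lognormal weights keep the projection mean and unit CV", {
  tab <- data.frame(pre = seq_len(1e5), post = 1L, receptor = "AMPA",
                    weight = 0.4)
  out <- lognormalize_weights(tab, seed = 9)
  expect_equal(mean(out$weight), 0.4, tolerance = 0.02)
  expect_equal(sd(out$weight) / mean(out$weight), 1, tolerance = 0.05)
  # zero weights and topology untouched
  tab$weight[1:10] <- 0
  out <- lognormalize_weights(tab, seed = 9)
  expect_true(all(out$weight[1:10] == 0))
  expect_identical(out$pre, tab$pre)
})

test_that("inhibitory-output lesion removes exactly the GABA rows", {
  col <- test_column()
  les <- lesion_inhibitory_output(col$synapses)
  expect_identical(sum(les$receptor == "GABA"), 0L)
  expect_identical(sum(les$receptor == "AMPA"),
                   sum(col$synapses$receptor == "AMPA"))
  # excitatory-only table passes through unchanged
  exc <- col$synapses[col$synapses$receptor != "GABA", ]
  rownames(exc) <- NULL
  expect_identical(lesion_inhibitory_output(exc), exc)
})

test_that("strength interface carries 288 defined entries out of 289", {
  spec <- test_bundle()$spec
  expect_identical(length(spec$P), 289L)
  expect_identical(defined_strengths(spec), 288L)
  expect_true(is.na(spec$S["VIP1", "VIP1"]))
})
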