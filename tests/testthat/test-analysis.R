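# minimal hand-built record for rate arithmetic
fake_record <- function(spikes, n_per_group, duration = 3000) {
  structure(list(spikes = spikes,
                 config = list(duration = duration,
                               n_per_group = n_per_group)),
            class = "simulation_record")
}

test_that("group mean rates are spikes / (n * window)", {
  npg <- c(E23 = 100, E4 = 50)
  sp <- data.frame(neuron_id = rep(1:10, 60), group = "E23",
                   time_ms = runif(600, 0, 3000))
  rec <- fake_record(sp, npg)
  r <- mean_rates(rec, c(0, 3000), groups = names(npg))
  expect_equal(r[[1]], 600 / 100 / 3)
  expect_equal(r[[2]], 0)
  expect_error(mean_rates(rec, c(100, 100)), "empty")
})

test_that("sliding-window rate traces are centred and conserve spike mass", {
  npg <- c(E23 = 20)
  sp <- data.frame(neuron_id = 1, group = "E23", time_ms = 1000)
  rec <- fake_record(sp, npg, duration = 2000)
  tr <- rate_trace(rec, "E23", window_ms = 100, step_ms = 10)
  # a single spike yields a boxcar bump of area 1/n centred on the spike
  expect_true(all(tr$rate_hz[abs(tr$time_ms - 1000) < 50] > 0))
  expect_true(all(tr$rate_hz[abs(tr$time_ms - 1000) > 60] == 0))
  expect_equal(sum(tr$rate_hz) * 10 / 1000, 1 / 20, tolerance = 1e-9)
  # a step increase becomes visible half a window before onset
  sp2 <- data.frame(neuron_id = 1:1000, group = "E23",
                    time_ms = runif(1000, 1000, 2000))
  tr2 <- rate_trace(fake_record(sp2, npg, 2000), "E23", 100, 10)
  expect_true(all(tr2$rate_hz[tr2$time_ms < 940] == 0))
  expect_gt(tr2$rate_hz[tr2$time_ms == 960], 0)
})

test_that("ISI irregularity: periodic trains give 0, Poisson trains give 1", {
  periodic <- data.frame(neuron_id = 1, group = "E23",
                         time_ms = seq(0, 2999, by = 10))
  rec <- fake_record(periodic, c(E23 = 1))
  expect_equal(isi_cv(rec, "E23")$mean, 0)
  set.seed(4)
  pois <- data.frame(neuron_id = 1, group = "E23",
                     time_ms = cumsum(rexp(10000, rate = 1)))
  rec <- fake_record(pois, c(E23 = 1), duration = max(pois$time_ms))
  expect_equal(isi_cv(rec, "E23")$mean, 1, tolerance = 0.02)
  # neurons with < 3 spikes are excluded
  two <- data.frame(neuron_id = c(1, 1), group = "E23", time_ms = c(1, 2))
  expect_true(is.na(isi_cv(fake_record(two, c(E23 = 1)), "E23")$mean))
})

test_that("voltage synchrony: identical traces 1, independent traces ~ N^-1/2, shared fraction sqrt(rho)", {
  set.seed(8)
  t_n <- 2000
  v <- rnorm(t_n)
  expect_equal(synchrony_chi(cbind(v, v, v)), 1, tolerance = 1e-12)
  indep <- matrix(rnorm(t_n * 100), t_n, 100)
  expect_equal(synchrony_chi(indep), 0.1, tolerance = 0.35)
  # traces sharing a fraction rho of their variance give chi ~ sqrt(rho)
  rho <- 0.4
  shared <- rnorm(t_n)
  mixed <- sapply(1:200, function(i)
    sqrt(rho) * shared + sqrt(1 - rho) * rnorm(t_n))
  expect_equal(synchrony_chi(mixed), sqrt(rho), tolerance = 0.05)
  expect_warning(chi0 <- synchrony_chi(matrix(1, 10, 3)), "undefined")
  expect_true(is.na(chi0))
})

test_that("Welch spectrum finds an injected tone and is flat for constants", {
  fs_step <- 10 # ms
  t <- seq(0, 19999, by = fs_step)
  tone <- sin(2 * pi * 10 * t / 1000)
  ps <- power_spectrum(tone, step_ms = fs_step)
  expect_equal(ps$freq_hz[which.max(ps$power)], 10, tolerance = 0.05)
  flat <- power_spectrum(rep(3.2, 1000), step_ms = 10)
  expect_true(all(flat$power < 1e-20))
  expect_error(power_spectrum(rep(1, 10), step_ms = 10), "shorter")
})

test_that("response matrices encode percent change with flagged zero baselines", {
  g <- perturbable_groups()
  base <- setNames(rep(1, 16), g)
  base["SST4"] <- 2
  base["VIP6"] <- 0
  pert <- setNames(lapply(g, function(y) {
    r <- base
    r["E23"] <- 1.22   # +22%
    r["SST4"] <- 1.5   # -25%
    r
  }), g)
  rm <- response_matrix(base, pert)
  expect_equal(unname(rm$values["E5", "E23"]), 22)
  expect_equal(unname(rm$values["E5", "SST4"]), -25)
  expect_true(all(rm$undefined[, "VIP6"]))
  expect_true(all(is.na(rm$values[, "VIP6"])))
  # perturbed == baseline -> all zeros
  rm0 <- response_matrix(base, setNames(lapply(g, function(y) base), g))
  expect_true(all(rm0$values[!is.na(rm0$values)] == 0))
  # categorisation is invariant under uniform rate rescaling
  pert2 <- lapply(pert, function(r) r * 3)
  rm2 <- response_matrix(base * 3, pert2)
  expect_identical(categorize(rm), categorize(rm2))
})

test_that("threshold categorisation uses strict 20% exceedance", {
  m <- matrix(c(25, 10, -30, 20, -20, 0), 2, 3)
  cat_m <- categorize(m, threshold = 20)
  expect_identical(as.vector(cat_m), c(1L, 0L, -1L, 0L, 0L, 0L))
  # undefined entries become 0 but stay flagged
  m[1, 1] <- NA
  cat_m <- categorize(m, threshold = 20)
  expect_identical(cat_m[1, 1], 0L)
  expect_true(attr(cat_m, "undefined")[1, 1])
})

test_that("categorical comparison reproduces the full transition rule table", {
  # exhaustive 3x3 rule table: white on agreement, red toward increase,
  # green toward decrease
  expected <- rbind("-1" = c("white", "red", "red"),
                    "0" = c("green", "white", "red"),
                    "1" = c("green", "green", "white"))
  colnames(expected) <- c("-1", "0", "1")
  for (a in c(-1L, 0L, 1L)) for (b in c(-1L, 0L, 1L)) {
    got <- compare_categorical(matrix(a), matrix(b))[1, 1]
    expect_identical(got, expected[as.character(a), as.character(b)])
  }
  expect_error(compare_categorical(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("numeric differences report signed pp changes and sign flips", {
  A <- matrix(c(50, 5, 0), 1, 3)
  B <- matrix(c(30, -5, 0), 1, 3)
  nd <- numeric_difference(A, B)
  expect_equal(as.vector(nd$difference), c(-20, -10, 0))
  expect_identical(as.vector(nd$sign_flip), c(FALSE, TRUE, FALSE))
  same <- numeric_difference(A, A)
  expect_true(all(same$difference == 0) && !any(same$sign_flip))
})

test_that("marked-change counting matches brute force and handles extremes", {
  expect_equal(count_marked(matrix(0L, 16, 16))[["n_marked"]], 0)
  full <- matrix(1L, 16, 16)
  expect_equal(count_marked(full)[["n_marked"]], 240)
  m <- matrix(0L, 4, 4)
  m[1, 2] <- 1L; m[2, 1] <- 1L; m[3, 4] <- 1L; m[4, 1] <- -1L; m[1, 3] <- -1L
  cm <- count_marked(m)
  expect_equal(cm[["n_marked"]], 5)
  expect_equal(cm[["positive_fraction"]], 0.6)
  # brute-force oracle equivalence on random matrices
  set.seed(12)
  for (i in 1:20) {
    v <- matrix(runif(64, -60, 60), 8, 8)
    cat_m <- categorize(v, threshold = 20)
    off <- cat_m; diag(off) <- 0L
    brute <- sum(abs(v) > 20 & row(v) != col(v))
    expect_equal(count_marked(cat_m)[["n_marked"]], brute)
  }
})

test_that("Frobenius distance satisfies the norm axioms", {
  set.seed(3)
  A <- matrix(rnorm(64), 8, 8)
  expect_equal(frobenius_distance(A, A), 0)
  B <- A; B[2, 5] <- A[2, 5] + 7
  expect_equal(frobenius_distance(A, B), 7)
  for (i in 1:20) {
    X <- matrix(rnorm(64), 8, 8); Y <- matrix(rnorm(64), 8, 8)
    Z <- matrix(rnorm(64), 8, 8)
    expect_equal(frobenius_distance(X, Y), frobenius_distance(Y, X))
    expect_lte(frobenius_distance(X, Z),
               frobenius_distance(X, Y) + frobenius_distance(Y, Z) + 1e-12)
    expect_gte(frobenius_distance(X, Y), 0)
  }
  # pairwise table is symmetric with a zero diagonal
  pw <- pairwise_frobenius(list(a = A, b = B, c = A + 1))
  expect_identical(pw, t(pw))
  expect_true(all(diag(pw) == 0))
})
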