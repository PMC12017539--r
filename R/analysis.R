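#' Per-group mean firing rates
#'
#' Group mean rate = total spikes of the group in the window divided by
#' (group size x window length).
#'
#' @param record A `simulation_record`.
#' @param window Numeric `c(t0, t1)`, ms; spikes with `t0 <= t < t1` count.
#' @param groups Groups to report (default all).
#' @return Named numeric vector, spikes/s.
#' @export
mean_rates <- function(record, window, groups = column_groups()) {
  if (window[2] <= window[1]) stop("empty rate window")
  sp <- record$spikes
  sel <- sp$time_ms >= window[1] & sp$time_ms < window[2]
  counts <- table(factor(sp$group[sel], levels = groups))
  n <- record$config$n_per_group[groups]
  as.numeric(counts) / n / ((window[2] - window[1]) / 1000)
}

#' Sliding-window population rate trace
#'
#' Population rate of one group estimated in a centred sliding window: the
#' value at time `t` counts spikes in `[t - window/2, t + window/2)`. The
#' centred convention means a step input shows in the trace up to half a
#' window before its onset.
#'
#' @param record A `simulation_record`.
#' @param group Group label.
#' @param window_ms Integration window, ms (default 100).
#' @param step_ms Trace sampling step, ms.
#' @return Data frame with `time_ms` and `rate_hz`.
#' @export
rate_trace <- function(record, group, window_ms = 100, step_ms = 10) {
  stopifnot(window_ms >= step_ms)
  tmax <- record$config$duration
  times <- seq(0, tmax, by = step_ms)
  st <- record$spikes$time_ms[record$spikes$group == group]
  n <- record$config$n_per_group[[group]]
  counts <- vapply(times, function(t)
    sum(st >= t - window_ms / 2 & st < t + window_ms / 2), numeric(1))
  data.frame(time_ms = times, rate_hz = counts / n / (window_ms / 1000))
}

#' Inter-spike-interval irregularity (CV of ISI)
#'
#' Coefficient of variation (SD over mean) of each neuron's inter-spike
#' intervals; neurons with fewer than 3 spikes are excluded (two intervals
#' are the minimum for a dispersion estimate). A perfectly periodic train
#' gives 0, a Poisson train 1.
#'
#' @param record A `simulation_record`.
#' @param group Group label.
#' @param window Optional `c(t0, t1)` restriction, ms.
#' @return List with `per_neuron` (named numeric) and `mean`.
#' @export
isi_cv <- function(record, group, window = NULL) {
  sp <- record$spikes[record$spikes$group == group, ]
  if (!is.null(window))
    sp <- sp[sp$time_ms >= window[1] & sp$time_ms < window[2], ]
  cvs <- vapply(split(sp$time_ms, sp$neuron_id), function(ts) {
    if (length(ts) < 3) return(NA_real_)
    isi <- diff(sort(ts))
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  cvs <- cvs[!is.na(cvs)]
  list(per_neuron = cvs,
       mean = if (length(cvs)) mean(cvs) else NA_real_)
}

#' Voltage-based population synchrony
#'
#' Golomb-Rinzel synchrony measure on membrane-potential traces:
#' `chi^2 = Var_t(mean_i V_i) / mean_i(Var_t V_i)`, returned as `chi` in
#' \[0, 1\]. Identical traces give 1; N independent traces scale as
#' `N^(-1/2)`.
#'
#' @param voltage Matrix, time samples x neurons (>= 2 columns).
#' @return `chi`, or `NA` with a warning when the traces carry no variance.
#' @export
synchrony_chi <- function(voltage) {
  if (ncol(voltage) < 2) stop("need at least 2 voltage traces")
  vi <- apply(voltage, 2, stats::var)
  if (all(vi == 0)) {
    warning("zero-variance voltage traces: synchrony undefined")
    return(NA_real_)
  }
  chi2 <- stats::var(rowMeans(voltage)) / mean(vi)
  sqrt(max(0, min(1, chi2)))
}

#' Welch power spectrum of a rate trace
#'
#' Mean-removed Welch periodogram: Hann-windowed segments (default 1 s) with
#' 50% overlap, averaged. Frequencies in Hz given the trace sampling step.
#'
#' @param trace Data frame from [rate_trace()] or a numeric vector.
#' @param step_ms Sampling period when `trace` is a bare vector, ms.
#' @param segment_ms Segment length, ms.
#' @param overlap Fractional segment overlap.
#' @return Data frame with `freq_hz` and `power` (f > 0 only).
#' @export
power_spectrum <- function(trace, step_ms = NULL, segment_ms = 1000,
                           overlap = 0.5) {
  if (is.data.frame(trace)) {
    step_ms <- diff(trace$time_ms[1:2])
    x <- trace$rate_hz
  } else x <- as.numeric(trace)
  if (is.null(step_ms)) stop("step_ms required for a bare numeric trace")
  x <- x - mean(x)
  nseg <- round(segment_ms / step_ms)
  if (length(x) < nseg)
    stop("trace shorter than one spectral segment (", nseg, " samples)")
  hop <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1)) # Hann
  pw <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    pw <- pw + Mod(stats::fft(seg))^2
  }
  pw <- pw / length(starts) / sum(w^2) * (step_ms / 1000)
  freq <- seq(0, nseg - 1) / nseg / (step_ms / 1000)
  keep <- seq(2, floor(nseg / 2) + 1)
  data.frame(freq_hz = freq[keep], power = pw[keep])
}

#' Assemble a perturbation response matrix
#'
#' Entry (Y, X) is the percent change of population X's mean rate caused by
#' the perturbation of population Y:
#' `100 * (rate_X_perturbed(Y) - rate_X_baseline) / rate_X_baseline`.
#' Entries with zero baseline are undefined and flagged (never silently 0);
#' the diagonal (the perturbed group observing itself) is flagged excluded.
#'
#' @param baseline Named numeric vector of baseline rates over the 16
#'   perturbable groups.
#' @param perturbed Named list mapping each perturbed group to its named
#'   vector of post-perturbation rates.
#' @param threshold Categorisation threshold, percent (default 20).
#' @return Object of class `response_matrix`: `values` (16x16, rows =
#'   perturbed group Y, columns = observed group X), `undefined` mask,
#'   `baseline`, `perturbed`, `threshold`.
#' @export
response_matrix <- function(baseline, perturbed, threshold = 20) {
  g <- perturbable_groups()
  if (!all(g %in% names(baseline)))
    stop("baseline must cover the 16 perturbable groups")
  if (!all(g %in% names(perturbed)))
    stop("perturbed rates must cover the 16 perturbed groups")
  vals <- matrix(NA_real_, 16, 16, dimnames = list(perturbed = g, observed = g))
  undef <- matrix(FALSE, 16, 16, dimnames = dimnames(vals))
  for (y in g) {
    post <- perturbed[[y]][g]
    base <- baseline[g]
    zero <- base == 0
    vals[y, !zero] <- 100 * (post[!zero] - base[!zero]) / base[!zero]
    undef[y, zero] <- TRUE
  }
  structure(list(values = vals, undefined = undef,
                 baseline = baseline[g], perturbed = perturbed,
                 threshold = threshold),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> 16x16 percent changes, threshold ", x$threshold,
      "%\n", sep = "")
  cat("  marked changes (off-diagonal): ",
      count_marked(categorize(x))["n_marked"], "; undefined entries: ",
      sum(x$undefined), "\n", sep = "")
  invisible(x)
}

as_values <- function(m) {
  if (inherits(m, "response_matrix")) m$values else m
}

#' Threshold categorisation of a response matrix
#'
#' Maps percent changes to +1 (increase beyond the threshold), -1 (decrease
#' beyond the threshold) or 0 (change within the threshold, boundary
#' inclusive). Undefined entries map to 0 and stay flagged via the
#' `"undefined"` attribute.
#'
#' @param matrix A `response_matrix` or plain numeric matrix.
#' @param threshold Percent threshold (default: the matrix's own, else 20).
#' @return Integer matrix in \{-1, 0, 1\} with attribute `undefined`.
#' @export
categorize <- function(matrix, threshold = NULL) {
  if (is.null(threshold))
    threshold <- if (inherits(matrix, "response_matrix")) matrix$threshold else 20
  stopifnot(threshold > 0)
  v <- as_values(matrix)
  undef <- if (inherits(matrix, "response_matrix")) matrix$undefined
           else is.na(v)
  cat_m <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  cat_m[!is.na(v) & v > threshold] <- 1L
  cat_m[!is.na(v) & v < -threshold] <- -1L
  cat_m[undef] <- 0L
  attr(cat_m, "undefined") <- undef
  cat_m
}

#' Categorical comparison of two states
#'
#' Entrywise transition algebra between two categorical matrices (state A to
#' state B): `white` when the categories agree; `red` for the transitions
#' 0->+1, -1->0 and -1->+1 (shift toward increase); `green` for +1->-1,
#' +1->0 and 0->-1 (shift toward decrease).
#'
#' @param A,B Categorical matrices from [categorize()], same shape.
#' @return Character matrix in \{"white", "red", "green"\}.
#' @export
compare_categorical <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("categorical matrices differ in shape")
  out <- matrix("white", nrow(A), ncol(A), dimnames = dimnames(A))
  out[B > A] <- "red"
  out[B < A] <- "green"
  out
}

#' Numeric difference between two response matrices
#'
#' Entrywise `B - A` in percentage points, plus a mask of the entries whose
#' percent change flipped sign between the two states.
#'
#' @param A,B `response_matrix` objects or numeric matrices, same shape.
#' @return List with `difference` (matrix, pp) and `sign_flip` (logical
#'   matrix).
#' @export
numeric_difference <- function(A, B) {
  a <- as_values(A); b <- as_values(B)
  if (!identical(dim(a), dim(b))) stop("matrices differ in shape")
  list(difference = b - a,
       sign_flip = !is.na(a) & !is.na(b) & (sign(a) * sign(b) < 0))
}

#' Count marked changes in a categorical matrix
#'
#' Number of nonzero off-diagonal entries (the perturbed group observing
#' itself is excluded), plus the fraction of the marked changes that are
#' increases.
#'
#' @param cat_matrix Matrix from [categorize()].
#' @return Named numeric vector `n_marked`, `positive_fraction`.
#' @export
count_marked <- function(cat_matrix) {
  off <- cat_matrix
  diag(off) <- 0L
  n_pos <- sum(off == 1L)
  n_neg <- sum(off == -1L)
  n <- n_pos + n_neg
  c(n_marked = n,
    positive_fraction = if (n > 0) n_pos / n else NA_real_)
}

#' Frobenius distance between two matrices
#'
#' `||A - B||_F`, the square root of the summed squared entrywise
#' differences. Entries masked (NA) in either matrix are excluded from both.
#'
#' @param A,B Numeric matrices (or `response_matrix` objects) of one shape.
#' @return Non-negative scalar.
#' @export
frobenius_distance <- function(A, B) {
  a <- as_values(A); b <- as_values(B)
  if (!identical(dim(a), dim(b))) stop("matrices differ in shape")
  d <- a - b
  sqrt(sum(d[!is.na(d)]^2))
}

#' Pairwise Frobenius distance table
#'
#' @param matrices Named list of matrices (or `response_matrix` objects).
#' @return Symmetric labelled matrix of pairwise distances.
#' @export
pairwise_frobenius <- function(matrices) {
  k <- length(matrices)
  out <- matrix(0, k, k, dimnames = list(names(matrices), names(matrices)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) out[i, j] <- out[j, i] <-
        frobenius_distance(matrices[[i]], matrices[[j]])
  }
  out
}
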