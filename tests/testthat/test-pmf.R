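truth_dw <- function(x) 10 * (x - 1)^2 * (x - 2)^2
dw_centers <- seq(0.275, by = 0.05, length.out = 50)

test_that("window extraction walks successive spacing multiples", {
  rc <- seq(0, 2.45, length.out = 200)
  w <- extract_windows(rc, spacing = 0.05)
  expect_identical(nrow(w), 50L)        # floor(2.45/0.05) + 1
  expect_equal(w$center, seq(0, 2.45, by = 0.05))
  expect_identical(w$frame[1], 1L)
  # non-monotone series: first crossing wins, backtracks are ignored
  rc2 <- c(0, 0.03, 0.06, 0.04, 0.02, 0.08, 0.12)
  w2 <- extract_windows(rc2, spacing = 0.05, n_windows = 3)
  expect_equal(w2$center, c(0, 0.05, 0.10))
  expect_equal(w2$frame, c(1L, 3L, 7L))
  # window cap respected; too-short span errors
  expect_identical(nrow(extract_windows(rc, spacing = 0.05,
                                        n_windows = 10)), 10L)
  expect_error(extract_windows(c(0, 0.01, 0.02), spacing = 0.05), "span")
  # descending pulls work too
  w3 <- extract_windows(seq(3, 1, length.out = 50), spacing = 0.5)
  expect_equal(w3$center, c(3, 2.5, 2, 1.5, 1))
  expect_equal(formals(extract_windows)$spacing, 0.05)
})

test_that("biased sampling matches harmonic-oscillator moments", {
  kT <- 0.0083144621 * 323
  flat <- function(x) rep(0, length(x))
  win <- sample_biased_synthetic(flat, centers = c(1, 2), k = 1000,
                                 n = 20000, seed = 3)
  for (w in win) {
    se_mean <- sd(w$samples) / sqrt(length(w$samples))
    expect_lt(abs(mean(w$samples) - w$center), 3 * se_mean)
    v <- var(w$samples)
    se_var <- v * sqrt(2 / (length(w$samples) - 1))
    expect_lt(abs(v - kT / 1000), 3 * se_var)
    expect_true(w$sane)
  }
  # harmonic truth: product of two Gaussians has closed-form moments
  a <- 500; m <- 1.5
  harm <- function(x) a / 2 * (x - m)^2
  wh <- sample_biased_synthetic(harm, centers = 1.2, k = 1000, n = 20000,
                                seed = 4)[[1]]
  prec <- (a + 1000) / kT
  mu <- (a * m + 1000 * 1.2) / (a + 1000)
  expect_lt(abs(mean(wh$samples) - mu), 3 * sd(wh$samples) / sqrt(20000))
  expect_lt(abs(var(wh$samples) - 1 / prec),
            3 * var(wh$samples) * sqrt(2 / 19999))
  # identical seed -> identical samples
  w2 <- sample_biased_synthetic(harm, centers = 1.2, k = 1000, n = 100,
                                seed = 4)[[1]]
  w3 <- sample_biased_synthetic(harm, centers = 1.2, k = 1000, n = 100,
                                seed = 4)[[1]]
  expect_identical(w2$samples, w3$samples)
  expect_error(sample_biased_synthetic(function(x) rep(Inf, length(x)),
                                       centers = 1, n = 100), "not finite")
})

test_that("one-window WHAM reduces to Boltzmann inversion of the histogram", {
  set.seed(5)
  # near-zero bias: WHAM must reproduce -kT log(histogram) up to a constant
  smp <- rnorm(50000, 1, 0.15)
  win <- list(umbrella_window(1, 1e-8, smp))
  prof <- wham_1d(win)
  kT <- 0.0083144621 * 323
  h <- hist(smp, breaks = c(prof$xi - diff(prof$xi)[1] / 2,
                            max(prof$xi) + diff(prof$xi)[1] / 2),
            plot = FALSE)
  Wref <- -kT * log(h$counts)
  Wref <- Wref - min(Wref[is.finite(Wref)])
  sel <- is.finite(Wref) & !is.na(prof$W)
  expect_lt(max(abs(prof$W[sel] - Wref[sel])), 1e-6)
})

test_that("WHAM recovers a double well and is gauge invariant", {
  win <- sample_biased_synthetic(truth_dw, centers = dw_centers, k = 1000,
                                 n = 2000, seed = 6)
  prof <- wham_1d(win)
  expect_true(prof$converged)
  expect_equal(min(prof$W, na.rm = TRUE), 0)
  sel <- !is.na(prof$W)
  Wt <- truth_dw(prof$xi); Wt <- Wt - min(Wt[sel])
  expect_lt(sqrt(mean((prof$W[sel] - Wt[sel])^2)), 0.7)
  # gauge: a constant added to the potential leaves the profile unchanged
  win2 <- sample_biased_synthetic(function(x) truth_dw(x) + 25,
                                  centers = dw_centers, k = 1000,
                                  n = 2000, seed = 6)
  prof2 <- wham_1d(win2, grid = prof$xi)
  both <- !is.na(prof$W) & !is.na(prof2$W)
  expect_equal(prof2$W[both], prof$W[both], tolerance = 1e-4)
  # non-overlapping windows are rejected
  wfar <- list(umbrella_window(0, 1000, rnorm(100, 0, 0.01)),
               umbrella_window(2, 1000, rnorm(100, 2, 0.01)))
  expect_error(wham_1d(wfar), "non-overlapping")
})

test_that("Bayesian bootstrap SDs behave like a statistical error", {
  win <- sample_biased_synthetic(truth_dw, centers = dw_centers, k = 1000,
                                 n = 500, seed = 7)
  # single replicate: zero SD by construction
  b1 <- bayesian_bootstrap_pmf(win, n_boot = 1, seed = 8)
  expect_true(all(b1$sd[!is.na(b1$sd)] == 0))
  # identical seeds give identical SDs
  b2 <- bayesian_bootstrap_pmf(win, n_boot = 10, seed = 9)
  b3 <- bayesian_bootstrap_pmf(win, n_boot = 10, seed = 9)
  expect_identical(b2$sd, b3$sd)
  # quadrupling the data roughly halves the SD
  win4 <- sample_biased_synthetic(truth_dw, centers = dw_centers, k = 1000,
                                  n = 2000, seed = 7)
  b4 <- bayesian_bootstrap_pmf(win4, n_boot = 10, seed = 9)
  mid <- !is.na(b2$sd) & !is.na(b4$sd) & b2$sd > 0
  ratio <- median(b2$sd[mid] / b4$sd[mid])
  expect_gt(ratio, 2 * 0.7)
  expect_lt(ratio, 2 * 1.3)
})

test_that("K_d from a square well matches the analytic integral", {
  kT <- 0.0083144621 * 323
  xi <- seq(0.0025, 1.5, by = 0.005)
  W <- ifelse(xi < 0.5, 0, 40)      # well depth 40 kJ/mol, width 0.5 nm
  prof <- structure(list(xi = xi, W = W, sd = NULL, temperature = 323,
                         n_windows = 1), class = "pmf_profile")
  kd <- estimate_kd(prof)
  I_analytic <- 0.5 * exp(40 / kT)
  expect_lt(abs(kd$kd_M - 1.660539 / I_analytic) / (1.660539 / I_analytic),
            0.01)
  expect_match(kd$convention, "standard state")
  # the estimate lands in the sub-micromolar regime typical of lipid sites
  expect_lt(kd$kd_M, 1e-5)
  # flat profile: the pure standard-state ratio over the chosen range
  prof0 <- structure(list(xi = xi, W = rep(0, length(xi)), sd = NULL,
                          temperature = 323, n_windows = 1),
                     class = "pmf_profile")
  kd0 <- estimate_kd(prof0, bound_range = c(0, 0.5))
  # bin centres inside [0, 0.5] span 0.0025..0.4975: the integral is 0.495 nm
  expect_equal(kd0$kd_M, 1.660539 / 0.495, tolerance = 1e-6)
  expect_error(estimate_kd(prof0), "unsampled")
  # deeper well, same shape -> strictly smaller K_d
  prof2 <- prof; prof2$W <- ifelse(xi < 0.5, 0, 50)
  expect_lt(estimate_kd(prof2)$kd_M, kd$kd_M)
})

test_that("K_d decreases strictly with well depth for random well shapes", {
  set.seed(12)
  xi <- seq(0.0025, 2, by = 0.005)
  for (i in 1:20) {
    w0 <- 0.2 + runif(1, 0, 0.5)
    shape <- exp(-((xi - 0.3) / w0)^2)
    depths <- sort(runif(2, 5, 60))
    kds <- vapply(depths, function(D) {
      prof <- structure(list(xi = xi, W = D - D * shape, sd = NULL,
                             temperature = 323, n_windows = 1),
                        class = "pmf_profile")
      estimate_kd(prof)$kd_M
    }, 0)
    expect_lt(kds[2], kds[1])
  }
})

test_that("paper-style umbrella defaults are wired through", {
  w <- umbrella_window(0.5, samples = rnorm(100, 0.5, 0.05))
  expect_equal(w$force_constant, 1000)
  expect_equal(formals(wham_1d)$temperature, 323)
  expect_equal(formals(sample_biased_synthetic)$k, 1000)
})
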