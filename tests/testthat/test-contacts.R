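test_that("minimum-image distances are correct", {
  expect_equal(min_image(0.3, 10), 0.3)
  # beads at x = 0.1 and 9.9 in a 10 nm box are 0.2 nm apart
  expect_equal(abs(min_image(0.1 - 9.9, 10)), 0.2)
  expect_equal(abs(min_image(5, 10)), 5)   # half-box separation is ambiguous
})

test_that("COM distance series match a brute-force recomputation", {
  set.seed(202)
  nf <- 40; nl <- 5
  x <- matrix(runif(nf * nl, -6, 6), nf, nl)
  y <- matrix(runif(nf * nl, -6, 6), nf, nl)
  z <- matrix(runif(nf * nl, -3, 3), nf, nl)
  rec <- receptor_model(data.frame(residue_id = 1:3, bead = "BB", helix = 1L,
                                   x = c(0, 1, -1), y = c(0, 0.5, 0.2),
                                   z = c(-1, 0.5, 1)))
  traj <- make_test_traj(x, y, z, box = c(12, 12, 10), receptor = rec)
  ds <- com_distance_series(traj)
  for (p in seq_len(nrow(ds$pairs))) {
    li <- ds$pairs$lipid_id[p]; ri <- ds$pairs$residue_id[p]
    for (f in c(1, 17, 40)) {
      dx <- x[f, li] - rec$beads$x[ri]; dx <- dx - 12 * round(dx / 12)
      dy <- y[f, li] - rec$beads$y[ri]; dy <- dy - 12 * round(dy / 12)
      dz <- z[f, li] - rec$beads$z[ri]
      expect_equal(ds$dist[f, p], sqrt(dx^2 + dy^2 + dz^2), tolerance = 1e-9)
    }
  }
  expect_error(com_distance_series(traj, lipid_ids = integer()),
               "zero particles")
})

test_that("dual-cutoff detector reproduces hand-run examples", {
  # event opens below 0.55, survives excursions up to 1.4, closes beyond it
  ev <- detect_contact_events(c(0.60, 0.50, 0.80, 1.00, 1.50),
                              times_ns = 0:4)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$t_start_ns, 1)
  expect_equal(ev$t_end_ns, 4)
  expect_equal(ev$duration_ns, 3)
  expect_false(ev$censored)

  expect_identical(nrow(detect_contact_events(rep(0.56, 10))), 0L)

  # rattling suppression: 1.20 <= 1.4 does not terminate the contact
  ev2 <- detect_contact_events(c(0.50, 1.20, 0.50, 1.50), times_ns = 0:3)
  expect_identical(nrow(ev2), 1L)
  expect_equal(ev2$duration_ns, 3)

  # open at trajectory end: censored at the final frame time
  ev3 <- detect_contact_events(c(0.9, 0.5, 0.6), times_ns = c(0, 2, 4))
  expect_identical(nrow(ev3), 1L)
  expect_true(ev3$censored)
  expect_equal(ev3$t_end_ns, 4)

  expect_error(detect_contact_events(c(0.5, 0.6), times_ns = c(0, 1),
                                     lower = 1.5, upper = 1.4))
  expect_error(detect_contact_events(c(0.5, 0.6, 0.7),
                                     times_ns = c(0, 1, 3)), "stride")
})

test_that("detector equals the brute-force automaton on random series", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(5:120, 1)
    d <- runif(n, 0.2, 2.0)
    times <- seq(0, by = 1, length.out = n)
    got <- detect_contact_events(d, times_ns = times)
    want <- brute_dual_cutoff(d, times)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$t_start_ns, want$t_start)
      expect_equal(got$t_end_ns, want$t_end)
      expect_identical(got$censored, want$censored == 1)
    }
  }
})

test_that("event count is non-increasing in the upper cutoff", {
  set.seed(304)
  for (i in 1:50) {
    d <- runif(150, 0.2, 2.0)
    uppers <- seq(0.6, 1.8, by = 0.2)
    counts <- vapply(uppers, function(u)
      nrow(detect_contact_events(d, lower = 0.55, upper = u)), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("duration profiles pool events and exclude censored from means", {
  ev <- data.frame(residue_id = c(1L, 1L, 1L, 2L), species = "PIP2",
                   duration_ns = c(2, 4, 100, 3),
                   censored = c(FALSE, FALSE, TRUE, FALSE),
                   run = c(1L, 2L, 1L, 1L))
  p <- residue_duration_profile(ev)
  r1 <- p[p$residue_id == 1L, ]
  expect_equal(r1$mean_ns, 3)          # censored 100 excluded
  expect_identical(r1$n_events, 2L)
  expect_identical(r1$n_censored, 1L)
  expect_equal(p$mean_ns[p$residue_id == 2L], 3)
  pr <- attr(p, "per_repeat")
  expect_equal(pr$mean_ns[pr$residue_id == 1 & pr$run == 1], 2)
  expect_equal(pr$mean_ns[pr$residue_id == 1 & pr$run == 2], 4)
  # single event of 3 ns
  p1 <- residue_duration_profile(data.frame(residue_id = 1L, species = "GM3",
                                            duration_ns = 3, censored = FALSE))
  expect_equal(p1$mean_ns, 3)
  expect_identical(p1$n_events, 1L)
})

test_that("profile maxima sit on the designed anchor residues", {
  run <- quick_binding_run(seed = 55, total_us = 4)
  ev <- contact_events(run$trajectory, species = c("PIP2", "GM3"))
  prof <- residue_duration_profile(ev)
  for (s in run$system$sites) {
    psp <- prof[prof$species == s$species, ]
    expect_true(psp$residue_id[which.max(psp$mean_ns)] %in% s$anchor_residues)
  }
})

test_that("first-shell occupancy counts constructed molecules exactly", {
  rec <- receptor_model(data.frame(residue_id = 1:2, bead = "BB", helix = 1L,
                                   x = 0, y = 0, z = c(-1, 1)))
  # 3 molecules inside the 1 nm shell, 2 outside
  x <- matrix(c(0.4, 0.5, -0.3, 3.0, 4.0), 1, 5)
  y <- matrix(0, 1, 5)
  z <- matrix(c(1.2, 0.8, -1.1, 1, -1), 1, 5)
  traj <- make_test_traj(x, y, z, species = rep("POPC", 5), receptor = rec)
  occ <- first_shell_series(traj)
  expect_identical(unname(occ$POPC), 3L)
  # far-away species give an all-zero series
  traj2 <- make_test_traj(x + 5, y + 5, z, species = rep("GM3", 5),
                          receptor = rec)
  expect_true(all(first_shell_series(traj2)$GM3 == 0L))
  expect_error(first_shell_series(traj, species = "PIP2"), "absent")
})

test_that("equilibration detection finds plateaus and rejects drifts", {
  set.seed(404)
  # stationary Poisson series: equilibrated from the first block
  s1 <- rpois(800, 10)
  t1 <- seq(0, by = 10, length.out = 800)   # 8 us at 10 ns
  expect_lte(estimate_equilibration(s1, times_ns = t1), 400)
  # step at 3 us (mean 5 -> 15): estimate in [2.8, 3.4] us with 0.4 us blocks
  s2 <- c(rpois(300, 5), rpois(500, 15))
  eq <- estimate_equilibration(s2, times_ns = t1)
  expect_gte(eq, 2800)
  expect_lte(eq, 3400)
  # monotone drift: no plateau
  s3 <- seq(0, 100, length.out = 800) + rnorm(800, 0, 0.5)
  expect_error(estimate_equilibration(s3, times_ns = t1),
               class = "lipidkinetics_no_plateau")
  expect_error(estimate_equilibration(rpois(5, 3)), "10 blocks")
})
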