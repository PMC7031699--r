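test_that("synthetic receptor geometry supports the designed sites", {
  sys <- synthetic_binding_system(n_sites = 9)
  rb <- sys$receptor$beads
  expect_identical(length(sys$sites), 9L)
  expect_true(max(rb$z) > 0 && min(rb$z) < 0)
  rc <- residue_coms(sys$receptor)
  for (s in sys$sites) {
    expect_true(all(s$anchor_residues %in% rb$residue_id))
    # every anchor residue is within the tether reach (< lower cutoff)
    a <- rc[match(s$anchor_residues, rc$residue_id), ]
    zmid <- if (s$leaflet == "upper") 2 else -2
    d <- sqrt((a$x - s$anchor_point[1])^2 + (a$y - s$anchor_point[2])^2 +
              (a$z - zmid)^2)
    expect_true(all(d < 0.45))
  }
  # anchor points of distinct sites in the same leaflet are beyond the upper
  # cutoff of each other, so a bound lipid cannot hold a contact elsewhere
  for (lf in c("upper", "lower")) {
    pts <- t(vapply(Filter(function(s) s$leaflet == lf, sys$sites),
                    `[[`, numeric(2), "anchor_point"))
    if (nrow(pts) > 1) expect_gt(min(dist(pts)), 1.4)
  }
})

test_that("receptor_model rejects broken inputs", {
  expect_error(receptor_model(data.frame(residue_id = c(1, 3), bead = "BB",
                                         x = 0, y = 0, z = c(-1, 1))),
               "contiguous")
  expect_error(receptor_model(data.frame(residue_id = 1:2, bead = "BB",
                                         x = 0, y = 0, z = c(1, 2))),
               "span both leaflets")
  expect_error(binding_site_spec(1, integer(), c(0, 0), species = "PIP2",
                                 k_off_true = 5, leaflet = "lower"))
})

test_that("zero lipids give receptor-only frames and an empty ledger", {
  sys <- synthetic_binding_system(n_sites = 2, n_helices = 4,
                                  species = c("PIP2", "GM3"))
  cfg <- system_config(box_nm = c(10, 10, 10), stride_ns = 10,
                       total_time_us = 0.1, seed = 1)
  res <- simulate_membrane_trajectory(default_composition(), sys$receptor,
                                      list(), cfg, n_upper = 0, n_lower = 0)
  expect_identical(nrow(res$ledger), 0L)
  expect_identical(nrow(res$trajectory$lipids), 0L)
  expect_identical(n_frames(res$trajectory), 11L)
})

test_that("initial molecule counts follow the composition exactly", {
  run <- quick_binding_run(seed = 5, total_us = 0.05)
  counts <- table(run$trajectory$lipids$species,
                  run$trajectory$lipids$leaflet0)
  rc <- realize_counts(default_composition(), 20, 20)
  for (sp in names(rc$upper))
    expect_identical(unname(counts[sp, "upper"]), as.integer(rc$upper[[sp]]))
  for (sp in names(rc$lower))
    expect_identical(unname(counts[sp, "lower"]), as.integer(rc$lower[[sp]]))
})

test_that("identical seed and config give bit-identical trajectories", {
  a <- quick_binding_run(seed = 11, total_us = 0.3)
  b <- quick_binding_run(seed = 11, total_us = 0.3)
  expect_identical(a$trajectory$x, b$trajectory$x)
  expect_identical(a$trajectory$z, b$trajectory$z)
  expect_identical(a$ledger, b$ledger)
  c2 <- quick_binding_run(seed = 12, total_us = 0.3)
  expect_false(identical(a$trajectory$x, c2$trajectory$x))
})

test_that("coordinates stay wrapped and lipids respect the exclusion zone", {
  run <- quick_binding_run(seed = 3, total_us = 0.3)
  tr <- run$trajectory
  expect_true(all(abs(tr$x) <= tr$box_nm[1] / 2 + 1e-9))
  expect_true(all(abs(tr$y) <= tr$box_nm[2] / 2 + 1e-9))
  # unbound lipids never enter the receptor hard core (bound ones are
  # tethered at the anchors, inside it)
  bound_at <- matrix(FALSE, n_frames(tr), nrow(tr$lipids))
  for (i in seq_len(nrow(run$ledger))) {
    ev <- run$ledger[i, ]
    fr <- which(tr$times_ns / 1000 >= ev$t_on_us &
                tr$times_ns / 1000 <= ev$t_off_us + 1e-3)
    bound_at[fr, ev$lipid_id] <- TRUE
  }
  r2 <- tr$x^2 + tr$y^2
  expect_true(all(r2[!bound_at] >= (2.6 - 1e-9)^2))
})

test_that("ledger residence times are exponential with the designed rate", {
  # single high-duty site, k_off = 10/us: mean residence 0.1 us
  sys <- synthetic_binding_system(n_sites = 1, species = "PIP2", k_off = 10,
                                  k_on = 500, capture_radius = 2.5,
                                  n_helices = 4)
  cfg <- system_config(box_nm = c(10, 10, 10), stride_ns = 1,
                       total_time_us = 130, seed = 21)
  res <- simulate_membrane_trajectory(default_composition(), sys$receptor,
                                      sys$sites, cfg, n_upper = 12,
                                      n_lower = 12, exclusion_radius = 2.6)
  d <- ledger_to_reference_durations(res$ledger)[["1"]]
  expect_gt(length(d), 1000)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.1), 3 * se)
  ks <- suppressWarnings(ks.test(d, "pexp", rate = 10))
  expect_gt(ks$p.value, 0.01)
  # ledger invariants
  expect_true(all(res$ledger$t_off_us > res$ledger$t_on_us))
  for (l in unique(res$ledger$lipid_id)) {
    ev <- res$ledger[res$ledger$lipid_id == l, ]
    ev <- ev[order(ev$t_on_us), ]
    if (nrow(ev) > 1)
      expect_true(all(ev$t_on_us[-1] >= ev$t_off_us[-nrow(ev)] - 1e-12))
  }
})

test_that("ledger durations and simple arithmetic agree", {
  led <- data.frame(lipid_id = 1L, site_id = 1L, t_on_us = 1.0,
                    t_off_us = 1.4, censored = FALSE)
  expect_equal(ledger_to_reference_durations(led)[["1"]], 0.4)
  expect_identical(ledger_to_reference_durations(led[0, ]), list())
})

test_that("detected events match the ground-truth ledger one-to-one", {
  # saturating k_on and padded exclusion: detection endpoints must sit within
  # one frame stride of the ledger transitions
  sys <- synthetic_binding_system(n_sites = 2, species = c("PIP2", "GM3"),
                                  k_off = c(6, 10), k_on = 5000,
                                  capture_radius = 1.7, n_helices = 4)
  cfg <- system_config(box_nm = c(10, 10, 10), stride_ns = 1,
                       total_time_us = 8, seed = 33)
  res <- simulate_membrane_trajectory(default_composition(), sys$receptor,
                                      sys$sites, cfg, n_upper = 15,
                                      n_lower = 15, exclusion_radius = 2.6)
  for (si in 1:2) {
    s <- sys$sites[[si]]
    led <- res$ledger[res$ledger$site_id == si, ]
    ev <- contact_events(res$trajectory, species = s$species,
                         residue_ids = s$anchor_residues[1])
    ev <- ev[order(ev$t_start_ns), ]
    led <- led[order(led$t_on_us), ]
    expect_identical(nrow(ev), nrow(led))
    expect_true(all(abs(ev$t_start_ns - led$t_on_us * 1000) <= 1 + 1e-9))
    expect_true(all(abs(ev$t_end_ns - led$t_off_us * 1000) <= 1 + 1e-9))
    expect_identical(ev$censored, led$censored)
  }
})

test_that("binding events accumulate roughly linearly with simulated time", {
  n_ev <- vapply(c(3, 6), function(T) {
    sys <- synthetic_binding_system(n_sites = 1, species = "PIP2", k_off = 9,
                                    k_on = 500, capture_radius = 2.5,
                                    n_helices = 4)
    cfg <- system_config(box_nm = c(10, 10, 10), stride_ns = 1,
                         total_time_us = T, seed = 77)
    res <- simulate_membrane_trajectory(default_composition(), sys$receptor,
                                        sys$sites, cfg, n_upper = 30,
                                        n_lower = 30, exclusion_radius = 2.6)
    sum(!res$ledger$censored)
  }, 0)
  expect_gt(n_ev[2] / n_ev[1], 1.6)
  expect_lt(n_ev[2] / n_ev[1], 2.4)
})

test_that("cholesterol flips leaflet and other species never do", {
  run <- quick_binding_run(seed = 9, total_us = 5)
  tr <- run$trajectory
  chol <- which(tr$lipids$species == "CHOL")
  other <- which(tr$lipids$species != "CHOL")
  flips <- vapply(seq_len(ncol(tr$z)), function(i)
    any(sign(tr$z[-1, i]) != sign(tr$z[-nrow(tr$z), i])), TRUE)
  expect_true(any(flips[chol]))
  expect_false(any(flips[other]))
})
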