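test_that("leaflet assignment follows head-group z and only cholesterol flips", {
  # two lipids per leaflet plus one cholesterol that crosses mid-trajectory
  nf <- 10
  z <- cbind(rep(2, nf), rep(2, nf), rep(-2, nf), rep(-2, nf),
             c(rep(2, 5), rep(-2, 5)))
  x <- matrix(runif(nf * 5, -4, 4), nf, 5); y <- matrix(0, nf, 5)
  traj <- make_test_traj(x, y, z,
                         species = c("POPC", "GM3", "PIP2", "POPS", "CHOL"))
  expect_identical(assign_leaflets(traj, 1),
                   c("upper", "upper", "lower", "lower", "upper"))
  lab6 <- assign_leaflets(traj, 6)
  expect_identical(lab6[5], "lower")        # cholesterol relabelled
  expect_identical(lab6[1:4], c("upper", "upper", "lower", "lower"))
  # a non-cholesterol species is never relabelled, even if its z moved
  z2 <- z; z2[, 1] <- c(rep(2, 5), rep(-2, 5))
  traj2 <- make_test_traj(x, y, z2,
                          species = c("POPC", "GM3", "PIP2", "POPS", "CHOL"))
  expect_identical(assign_leaflets(traj2, 6)[1], "upper")
})

test_that("periodic Voronoi areas: square lattice and conservation", {
  pts <- as.matrix(expand.grid(c(2.5, 7.5), c(2.5, 7.5)))
  a <- periodic_voronoi_areas(pts, c(10, 10))
  expect_equal(a, rep(25, 4))
  expect_error(periodic_voronoi_areas(pts[1:2, ], c(10, 10)), "at least 3")

  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:60, 1)
    p <- cbind(runif(n, 0, 13), runif(n, 0, 9))
    a <- periodic_voronoi_areas(p, c(13, 9))
    expect_lt(abs(sum(a) - 13 * 9) / (13 * 9), 1e-6)
    expect_true(all(a > 0))
  }
})

test_that("voronoi_apl resolves representative beads and conserves box area", {
  run <- quick_binding_run(seed = 23, total_us = 0.05, n_per_leaflet = 25)
  apl <- voronoi_apl(run$trajectory, frame = 10)
  box <- apl$box_area_nm2
  for (lf in c("upper", "lower")) {
    tot <- sum(apl$lipids$area_nm2[apl$lipids$leaflet == lf]) +
      apl$receptor_area_nm2[[lf]]
    expect_lt(abs(tot - box) / box, 1e-6)
  }
  expect_true(all(apl$lipids$area_nm2 > 0))
  expect_true(all(c("species", "leaflet", "mean_nm2", "sd_nm2") %in%
                  names(apl$summary)))
  # the receptor occupies a nonzero in-plane area in both leaflets
  expect_gt(apl$receptor_area_nm2[["upper"]], 0)
  expect_gt(apl$receptor_area_nm2[["lower"]], 0)
})

test_that("representative-bead rules follow the species class", {
  # glycerophospholipid: GL1/GL2 midpoint; sphingolipid: AM1/AM2; sterol: ROH
  tpl <- lipidkinetics:::.bead_templates()
  off <- lipidkinetics:::.rep_offset("POPC")
  gl <- tpl$POPC[tpl$POPC$bead %in% c("GL1", "GL2"), ]
  expect_equal(off, c(mean(gl$dx), mean(gl$dy), mean(gl$dz)))
  offs <- lipidkinetics:::.rep_offset("PSM")
  am <- tpl$PSM[tpl$PSM$bead %in% c("AM1", "AM2"), ]
  expect_equal(offs, c(mean(am$dx), mean(am$dy), mean(am$dz)))
  offc <- lipidkinetics:::.rep_offset("CHOL")
  expect_equal(offc, unlist(tpl$CHOL[tpl$CHOL$bead == "ROH",
                                     c("dx", "dy", "dz")], use.names = FALSE))
})

test_that("2D density maps conserve molecule-frames and add over species", {
  # single static molecule: all mass in one cell of value 1/(cell area)
  traj <- make_test_traj(matrix(1.3, 4, 1), matrix(-2.1, 4, 1),
                         matrix(2, 4, 1), species = "GM3")
  m <- density_map_2d(traj, "GM3", grid_spacing = 0.5)
  expect_identical(sum(m$values > 0), 1L)
  expect_equal(max(m$values), 1 / 0.25)
  # integral: sum(density) * cell area * frames = molecule-frames
  run <- quick_binding_run(seed = 29, total_us = 0.1, n_per_leaflet = 15)
  sp <- c("POPC", "CHOL")
  cell <- 0.5^2
  for (s in sp) {
    mm <- density_map_2d(run$trajectory, s, grid_spacing = 0.5)
    nmol <- sum(run$trajectory$lipids$species == s)
    expect_equal(sum(mm$values) * cell * mm$n_frames,
                 nmol * n_frames(run$trajectory))
  }
  # additivity: species maps sum to the pooled map
  m1 <- density_map_2d(run$trajectory, "POPC", grid_spacing = 0.5)
  m2 <- density_map_2d(run$trajectory, "CHOL", grid_spacing = 0.5)
  m12 <- density_map_2d(run$trajectory, c("POPC", "CHOL"), grid_spacing = 0.5)
  expect_equal(m1$values + m2$values, m12$values)
  expect_error(density_map_2d(run$trajectory, "POPC", frames = integer()),
               "empty analysis window")
})

test_that("density maps are translation-equivariant with the periodic box", {
  set.seed(31)
  nf <- 20; nl <- 12
  x <- matrix(runif(nf * nl, -5, 5), nf, nl)
  y <- matrix(runif(nf * nl, -5, 5), nf, nl)
  z <- matrix(2, nf, nl)
  traj <- make_test_traj(x, y, z, species = rep("GM3", nl))
  m <- density_map_2d(traj, "GM3", grid_spacing = 0.5)
  # shift by exactly two grid cells with periodic wrap
  shift <- 1.0
  trj2 <- make_test_traj(min_image(x + shift, 10), y, z,
                         species = rep("GM3", nl))
  m2 <- density_map_2d(trj2, "GM3", grid_spacing = 0.5)
  nx <- nrow(m$values)
  rolled <- m$values[((seq_len(nx) - 1 - 2) %% nx) + 1, ]
  expect_equal(m2$values, rolled)
})

test_that("surface RDF of a homogeneous in-plane ideal gas is flat", {
  set.seed(37)
  nf <- 400; nl <- 150
  rec <- receptor_model(data.frame(
    residue_id = 1:14, bead = "BB", helix = rep(1:7, 2),
    x = rep(1.3 * cos(2 * pi * (0:6) / 7), 2),
    y = rep(1.3 * sin(2 * pi * (0:6) / 7), 2),
    z = rep(c(-2, 2), each = 7)))
  x <- matrix(runif(nf * nl, -6, 6), nf, nl)
  y <- matrix(runif(nf * nl, -6, 6), nf, nl)
  z <- matrix(rep(c(-2, 2), length.out = nl), nf, nl, byrow = TRUE)
  traj <- make_test_traj(x, y, z, box = c(12, 12, 10),
                         species = rep("POPC", nl), receptor = rec)
  g <- surface_rdf(traj, "POPC", bin_width = 0.2, mc_seed = 99)
  sel <- g$r_mid > 2 & !is.na(g$g)
  expect_lt(mean(abs(g$g[sel] - 1)), 0.05)
  expect_true(all(g$g >= 0, na.rm = TRUE))
  expect_error(surface_rdf(traj, "PIP2"), "absent")
  # downstream first-shell default is 1 nm
  expect_equal(formals(first_shell_series)$shell_radius, 1.0)
})
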