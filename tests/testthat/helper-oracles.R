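# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately written as plain loops, independent of the
# package's vectorized implementations.

# literal two-state automaton for the dual-cutoff scheme
brute_dual_cutoff <- function(d, times, lower = 0.55, upper = 1.4) {
  events <- list()
  open <- FALSE
  t_open <- NA_real_
  for (i in seq_along(d)) {
    if (!open) {
      if (d[i] < lower) {
        open <- TRUE
        t_open <- times[i]
      }
    } else if (d[i] > upper) {
      events[[length(events) + 1L]] <-
        c(t_start = t_open, t_end = times[i], censored = 0)
      open <- FALSE
    }
  }
  if (open)
    events[[length(events) + 1L]] <-
      c(t_start = t_open, t_end = times[length(times)], censored = 1)
  if (length(events) == 0L)
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      censored = numeric()))
  as.data.frame(do.call(rbind, events))
}

# Pearson correlation written out exactly as the definition
brute_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# hand-assembled trajectory object for geometric tests
make_test_traj <- function(x, y, z, box = c(10, 10, 10), species = NULL,
                           receptor = NULL, stride_ns = 1) {
  nf <- nrow(x); nl <- ncol(x)
  if (is.null(species)) species <- rep("POPC", nl)
  if (is.null(receptor))
    receptor <- receptor_model(data.frame(
      residue_id = 1:2, bead = "BB", helix = 1L,
      x = 0, y = 0, z = c(-1, 1)))
  structure(list(times_ns = (seq_len(nf) - 1) * stride_ns,
                 stride_ns = stride_ns, box_nm = box,
                 lipids = data.frame(lipid_id = seq_len(nl),
                                     species = species,
                                     leaflet0 = ifelse(z[1, ] >= 0,
                                                       "upper", "lower"),
                                     stringsAsFactors = FALSE),
                 x = x, y = y, z = z, receptor = receptor,
                 species = default_species(), leaflet_z = 2.0),
            class = "cg_trajectory")
}

# small fast synthetic binding run shared by several tests
quick_binding_run <- function(seed = 42, total_us = 2, n_sites = 2,
                              k_off = c(6, 12), species = c("PIP2", "GM3"),
                              k_on = 500, capture = 1.7, excl = 2.6,
                              n_per_leaflet = 20, box = c(10, 10, 10),
                              stride_ns = 1) {
  sys <- synthetic_binding_system(n_sites = n_sites, species = species,
                                  k_off = k_off, k_on = k_on,
                                  capture_radius = capture, n_helices = 4)
  cfg <- system_config(box_nm = box, stride_ns = stride_ns,
                       total_time_us = total_us, seed = seed)
  res <- simulate_membrane_trajectory(default_composition(), sys$receptor,
                                      sys$sites, cfg,
                                      n_upper = n_per_leaflet,
                                      n_lower = n_per_leaflet,
                                      exclusion_radius = excl)
  c(res, list(system = sys, config = cfg))
}
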