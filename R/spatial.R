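# Spatial lipid statistics: leaflet assignment, surface-referenced RDFs,
# 2D in-plane density maps, and Voronoi-tessellation area per lipid with
# periodic boundaries and receptor beads.

# representative-bead offset (relative to the COM) for a species
.rep_offset <- function(species_name) {
  tpl <- .bead_templates()[[species_name]]
  reg <- default_species()[[species_name]]
  rule <- if (!is.null(reg)) reg$bead_rule else "named-bead:COM"
  if (is.null(tpl)) return(c(0, 0, 0))
  pick <- switch(rule,
                 "glycerol-midpoint" = c("GL1", "GL2"),
                 "sphingosine-midpoint" = c("AM1", "AM2"),
                 "hydroxyl-bead" = "ROH",
                 sub("^named-bead:", "", rule))
  rows <- tpl[tpl$bead %in% pick, , drop = FALSE]
  if (nrow(rows) == 0L) return(c(0, 0, 0))
  c(mean(rows$dx), mean(rows$dy), mean(rows$dz))
}

#' Assign lipids to leaflets
#'
#' A molecule's leaflet is the sign of its head-group bead z relative to the
#' instantaneous membrane midplane (the median z of all lipid representative
#' beads in the frame). Cholesterol -- the only species expected to flip-flop
#' -- is re-evaluated at the requested frame; all other species keep their
#' frame-1 label.
#'
#' @param traj A `cg_trajectory`.
#' @param frame Frame index (default 1).
#' @return Character vector (`"upper"`/`"lower"`), one entry per lipid.
#' @export
assign_leaflets <- function(traj, frame = 1L) {
  lab_at <- function(f) {
    rep_z <- head_z <- numeric(nrow(traj$lipids))
    for (i in seq_len(nrow(traj$lipids))) {
      sp <- traj$lipids$species[i]
      off <- .rep_offset(sp)
      tpl <- .bead_templates()[[sp]]
      hdz <- if (is.null(tpl)) 0 else tpl$dz[1]
      sgn <- if (traj$z[f, i] >= 0) 1 else -1
      rep_z[i] <- traj$z[f, i] + sgn * off[3]
      head_z[i] <- traj$z[f, i] + sgn * hdz
    }
    mid <- stats::median(rep_z)
    if (all(abs(rep_z - mid) < 1e-9))
      stop("degenerate geometry: all representative beads coplanar with the midplane")
    ifelse(head_z > mid, "upper", "lower")
  }
  lab <- lab_at(1L)
  if (frame != 1L) {
    chol <- traj$lipids$species == "CHOL"
    if (any(chol)) lab[chol] <- lab_at(frame)[chol]
  }
  lab
}

#' Surface-referenced radial distribution function
#'
#' The distribution of lipid COM distances to the receptor surface (minimum
#' distance to any receptor bead). Because the accessible in-plane area of a
#' distance shell around an irregular protein cross-section has no closed
#' form, shell areas are estimated by Monte Carlo per leaflet; the histogram
#' is normalized by shell area times the bulk (whole-box) species density so
#' that g tends to 1 far from the protein.
#'
#' @param traj A `cg_trajectory`.
#' @param species Lipid species.
#' @param bin_width Bin width, nm (default 0.1).
#' @param r_max Largest distance (default just under half the smallest
#'   in-plane box edge); must be below that bound.
#' @param frames Frame indices to use (default all).
#' @param n_mc Monte-Carlo samples per leaflet for shell areas (default 1e5).
#' @param mc_seed Optional seed for the shell-area sampling.
#' @return Object of class `surface_rdf`: `r_mid`, `g`, `species`,
#'   `bin_width`, `meta` (bulk densities and shell areas).
#' @export
surface_rdf <- function(traj, species, bin_width = 0.1, r_max = NULL,
                        frames = NULL, n_mc = 1e5, mc_seed = NULL) {
  Lx <- traj$box_nm[1]; Ly <- traj$box_nm[2]
  if (is.null(r_max)) r_max <- min(Lx, Ly) / 2 - bin_width
  stopifnot(r_max < min(Lx, Ly) / 2)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  li <- which(traj$lipids$species == species)
  if (length(li) == 0L) stop("species absent: ", species)
  if (!is.null(mc_seed)) set.seed(mc_seed)
  rb <- traj$receptor$beads
  breaks <- seq(0, r_max, by = bin_width)
  nbin <- length(breaks) - 1L

  surf_dist <- function(px, py, pz) {
    d <- rep(Inf, length(px))
    for (b in seq_len(nrow(rb))) {
      dx <- min_image(px - rb$x[b], Lx)
      dy <- min_image(py - rb$y[b], Ly)
      dz <- pz - rb$z[b]
      d <- pmin(d, dx * dx + dy * dy + dz * dz)
    }
    sqrt(d)
  }

  obs <- numeric(nbin); expd <- numeric(nbin)
  meta <- list()
  for (leaf in c(1, -1)) {
    zsel <- traj$z[frames, li, drop = FALSE]
    inleaf <- sign(zsel) == leaf
    if (!any(inleaf)) next
    zplane <- mean(zsel[inleaf])
    dlist <- numeric(0)
    for (j in seq_along(li)) {
      f <- frames[inleaf[, j]]
      if (length(f) == 0L) next
      dlist <- c(dlist, surf_dist(traj$x[f, li[j]], traj$y[f, li[j]],
                                  traj$z[f, li[j]]))
    }
    h <- graphics::hist(dlist[dlist < r_max], breaks = breaks, plot = FALSE)
    mcx <- runif(n_mc, -Lx / 2, Lx / 2); mcy <- runif(n_mc, -Ly / 2, Ly / 2)
    md <- surf_dist(mcx, mcy, rep(zplane, n_mc))
    hm <- graphics::hist(md[md < r_max], breaks = breaks, plot = FALSE)
    shell_area <- hm$counts / n_mc * Lx * Ly
    rho <- sum(inleaf) / length(frames) / (Lx * Ly)  # molecules per nm^2
    obs <- obs + h$counts / length(frames)
    expd <- expd + rho * shell_area
    meta[[if (leaf > 0) "upper" else "lower"]] <-
      list(bulk_density = rho, shell_area = shell_area, z_plane = zplane)
  }
  g <- ifelse(expd > 0, obs / expd, NA_real_)
  structure(list(r_mid = breaks[-1] - bin_width / 2, g = g, species = species,
                 bin_width = bin_width, meta = meta,
                 n_frames = length(frames)),
            class = "surface_rdf")
}

#' @export
print.surface_rdf <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf("Surface RDF for %s: %d bins to %.2f nm; peak g = %.2f at %.2f nm\n",
              x$species, length(x$g), max(x$r_mid) + x$bin_width / 2,
              x$g[pk], x$r_mid[pk]))
  invisible(x)
}

#' @export
plot.surface_rdf <- function(x, ...) {
  graphics::plot(x$r_mid, x$g, type = "l",
                 xlab = "distance to receptor surface (nm)", ylab = "g(r)",
                 main = x$species, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Two-dimensional in-plane lipid density map
#'
#' Time-averaged COM number density of a species on an xy grid, per leaflet.
#' The receptor is static in these trajectories, so maps are already in the
#' receptor frame.
#'
#' @param traj A `cg_trajectory`.
#' @param species Lipid species (or vector of species, pooled).
#' @param leaflet `"upper"`, `"lower"` or `"both"`.
#' @param grid_spacing Requested grid spacing, nm; the effective spacing
#'   divides the box edge exactly.
#' @param frames Frame indices (default all).
#' @return Object of class `density_map_2d`: `x_edges`, `y_edges`, `values`
#'   (molecules per nm^2, averaged over frames), `n_frames`, `species`,
#'   `leaflet`.
#' @export
density_map_2d <- function(traj, species, leaflet = c("both", "upper", "lower"),
                           grid_spacing = 0.5, frames = NULL) {
  leaflet <- match.arg(leaflet)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) == 0L) stop("empty analysis window")
  Lx <- traj$box_nm[1]; Ly <- traj$box_nm[2]
  nx <- max(1L, round(Lx / grid_spacing)); ny <- max(1L, round(Ly / grid_spacing))
  sx <- Lx / nx; sy <- Ly / ny
  li <- which(traj$lipids$species %in% species)
  if (length(li) == 0L) stop("species absent")
  counts <- matrix(0, nx, ny)
  for (i in li) {
    x <- traj$x[frames, i]; y <- traj$y[frames, i]; z <- traj$z[frames, i]
    keep <- switch(leaflet, both = rep(TRUE, length(z)),
                   upper = z > 0, lower = z < 0)
    if (!any(keep)) next
    ix <- pmin(nx, floor((min_image(x[keep], Lx) + Lx / 2) / sx) + 1L)
    iy <- pmin(ny, floor((min_image(y[keep], Ly) + Ly / 2) / sy) + 1L)
    for (p in seq_along(ix)) counts[ix[p], iy[p]] <- counts[ix[p], iy[p]] + 1
  }
  structure(list(x_edges = seq(-Lx / 2, Lx / 2, length.out = nx + 1),
                 y_edges = seq(-Ly / 2, Ly / 2, length.out = ny + 1),
                 values = counts / (length(frames) * sx * sy),
                 n_frames = length(frames), species = species,
                 leaflet = leaflet),
            class = "density_map_2d")
}

#' Write a 2D density map as plain-text matrix + JSON metadata
#' @param map A `density_map_2d`.
#' @param matrix_path Output path for the density matrix (whitespace-separated).
#' @param meta_path Output path for the JSON metadata (grid origin, spacing,
#'   species, leaflet, frame count).
#' @export
write_density_map <- function(map, matrix_path, meta_path) {
  utils::write.table(map$values, matrix_path, row.names = FALSE,
                     col.names = FALSE)
  meta <- list(origin_nm = c(map$x_edges[1], map$y_edges[1]),
               spacing_nm = c(diff(map$x_edges[1:2]), diff(map$y_edges[1:2])),
               species = map$species, leaflet = map$leaflet,
               n_frames = map$n_frames)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(matrix_path)
}

#' @export
plot.density_map_2d <- function(x, ...) {
  graphics::image(x = x$x_edges, y = x$y_edges, z = x$values,
                  xlab = "x (nm)", ylab = "y (nm)", useRaster = TRUE, ...)
  invisible(x)
}

# Sutherland-Hodgman clip of a convex polygon by the half-plane
# {q : (q - m) . nrm <= 0}
.clip_halfplane <- function(poly, mx, my, nx, ny) {
  s <- (poly[, 1] - mx) * nx + (poly[, 2] - my) * ny
  inside <- s <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(NULL)
  n <- nrow(poly)
  out <- matrix(NA_real_, n + 2L, 2L)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      k <- k + 1L; out[k, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

#' Areas of periodic 2D Voronoi cells
#'
#' Voronoi cell area of each generating point in a periodic rectangle,
#' computed by half-plane clipping against the 3x3 tiling of periodic images
#' (exact for cells that do not span half the box). The central cells tile
#' the box, so the areas sum to the box area.
#'
#' @param pts n x 2 matrix of points (any representative; wrapped into the
#'   box internally).
#' @param box_xy Box edges `c(Lx, Ly)`.
#' @return Numeric vector of cell areas (nm^2).
#' @export
periodic_voronoi_areas <- function(pts, box_xy) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 generating points")
  Lx <- box_xy[1]; Ly <- box_xy[2]
  px <- min_image(pts[, 1], Lx); py <- min_image(pts[, 2], Ly)
  sh <- expand.grid(ox = c(-Lx, 0, Lx), oy = c(-Ly, 0, Ly))
  ix <- rep(px, times = 9L) + rep(sh$ox, each = n)
  iy <- rep(py, times = 9L) + rep(sh$oy, each = n)
  H <- max(Lx, Ly)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (ix - px[i])^2 + (iy - py[i])^2
    ord <- order(d2)
    poly <- cbind(px[i] + c(-H, H, H, -H), py[i] + c(-H, -H, H, H))
    maxr2 <- 2 * H * H
    for (j in ord) {
      if (d2[j] < 1e-18) next          # the point itself
      if (d2[j] > 4 * maxr2) break     # bisector cannot reach the cell
      mx <- (px[i] + ix[j]) / 2; my <- (py[i] + iy[j]) / 2
      poly <- .clip_halfplane(poly, mx, my, ix[j] - px[i], iy[j] - py[i])
      if (is.null(poly)) break
      maxr2 <- max((poly[, 1] - px[i])^2 + (poly[, 2] - py[i])^2)
    }
    if (is.null(poly) || nrow(poly) < 3L) {
      areas[i] <- 0
    } else {
      xs <- poly[, 1]; ys <- poly[, 2]
      areas[i] <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
    }
  }
  areas
}

#' Voronoi-tessellation area per lipid
#'
#' Per leaflet, tessellates the lipid representative points (glycerol
#' midpoint for glycerophospholipids, sphingosine midpoint for sphingolipids,
#' the hydroxyl bead for cholesterol) together with the xy projections of the
#' receptor beads lying in that leaflet's z slab (between the bilayer
#' midplane and the leaflet midplane), under periodic boundaries. A lipid's
#' APL is its cell area; receptor cell areas are reported separately.
#'
#' @param traj A `cg_trajectory`.
#' @param frame Frame index.
#' @param include_receptor Include receptor beads as generators (default
#'   TRUE).
#' @return Object of class `voronoi_apl`: `lipids` (per-lipid areas),
#'   `summary` (mean +/- SD per species x leaflet), `receptor_area_nm2` per
#'   leaflet, `box_area_nm2`.
#' @export
voronoi_apl <- function(traj, frame = 1L, include_receptor = TRUE) {
  Lx <- traj$box_nm[1]; Ly <- traj$box_nm[2]
  lab <- assign_leaflets(traj, frame)
  rb <- traj$receptor$beads
  out <- list(); rec_area <- c(upper = 0, lower = 0)
  for (leaf in c("upper", "lower")) {
    idx <- which(lab == leaf)
    if (length(idx) == 0L) next
    off <- t(vapply(traj$lipids$species[idx], .rep_offset, numeric(3)))
    ptx <- traj$x[frame, idx] + off[, 1]
    pty <- traj$y[frame, idx] + off[, 2]
    zmid <- mean(traj$z[frame, idx])
    pts <- cbind(ptx, pty)
    n_lip <- length(idx)
    if (include_receptor && nrow(rb) > 0) {
      slab <- if (leaf == "upper") rb$z >= 0 & rb$z <= max(zmid, 0)
              else rb$z <= 0 & rb$z >= min(zmid, 0)
      if (any(slab)) {
        # beads stacked on the same axis project to one generating point
        proj <- unique(round(cbind(rb$x[slab], rb$y[slab]), 9))
        pts <- rbind(pts, proj)
      }
    }
    if (nrow(pts) < 3L)
      stop("fewer than 3 generating points in the ", leaf, " leaflet")
    areas <- periodic_voronoi_areas(pts, c(Lx, Ly))
    out[[leaf]] <- data.frame(lipid_id = traj$lipids$lipid_id[idx],
                              species = traj$lipids$species[idx],
                              leaflet = leaf, area_nm2 = areas[seq_len(n_lip)],
                              stringsAsFactors = FALSE)
    rec_area[leaf] <- sum(areas[-seq_len(n_lip)])
  }
  lipids <- do.call(rbind, out)
  rownames(lipids) <- NULL
  smry <- aggregate(area_nm2 ~ species + leaflet, data = lipids,
                    FUN = function(a) c(mean = mean(a), sd = stats::sd(a),
                                        n = length(a)))
  smry <- do.call(data.frame, smry)
  names(smry) <- c("species", "leaflet", "mean_nm2", "sd_nm2", "n")
  structure(list(lipids = lipids, summary = smry,
                 receptor_area_nm2 = rec_area, box_area_nm2 = Lx * Ly,
                 frame = frame),
            class = "voronoi_apl")
}

#' @export
print.voronoi_apl <- function(x, ...) {
  cat("Voronoi area per lipid (frame ", x$frame, "):\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  receptor area: upper %.1f nm^2, lower %.1f nm^2 (box %.1f nm^2)\n",
              x$receptor_area_nm2[["upper"]], x$receptor_area_nm2[["lower"]],
              x$box_area_nm2))
  invisible(x)
}
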