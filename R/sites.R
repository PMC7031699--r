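# Binding-site identification from duration profiles, bead-density pose
# scoring, and lipid-interplay correlation.

#' Expand lipid COMs to bead coordinates for one frame
#'
#' Beads are placed at fixed species-template offsets around the COM
#' (mirrored in z for lower-leaflet molecules), so the bead COM equals the
#' stored molecule COM exactly.
#'
#' @param traj A `cg_trajectory`.
#' @param frame Frame index.
#' @param lipid_idx Row indices into `traj$lipids` (default all).
#' @return data.frame `lipid_id`, `species`, `bead`, `x`, `y`, `z`.
#' @export
lipid_bead_coords <- function(traj, frame, lipid_idx = NULL) {
  if (is.null(lipid_idx)) lipid_idx <- seq_len(nrow(traj$lipids))
  tpl <- .bead_templates()
  out <- vector("list", length(lipid_idx))
  for (j in seq_along(lipid_idx)) {
    i <- lipid_idx[j]
    sp <- traj$lipids$species[i]
    tp <- tpl[[sp]]
    if (is.null(tp))
      tp <- data.frame(bead = "COM", dx = 0, dy = 0, dz = 0)
    sgn <- if (traj$z[frame, i] >= 0) 1 else -1
    out[[j]] <- data.frame(lipid_id = traj$lipids$lipid_id[i], species = sp,
                           bead = tp$bead,
                           x = traj$x[frame, i] + tp$dx,
                           y = traj$y[frame, i] + tp$dy,
                           z = traj$z[frame, i] + sgn * tp$dz,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Identify lipid binding sites from a duration profile
#'
#' Residues whose mean interaction duration (for a given species) reaches the
#' threshold become nodes; nodes whose residue COMs lie within
#' `adjacency_radius` are connected; connected components with at least two
#' members are sites, ranked by their maximum member duration. The default
#' threshold is 3x the profile-wide median positive duration (scale-free).
#'
#' @param profile A `duration_profile`.
#' @param receptor The `receptor_model` the profile refers to.
#' @param duration_threshold Minimum mean duration (ns); default
#'   `3 * median(positive mean durations)`.
#' @param adjacency_radius Residue-residue connection distance, nm.
#' @param min_size Minimum component size (default 2).
#' @return List of `lipid_binding_site` objects (fields `site_id`,
#'   `residues`, `species`, `mean_ns`, `max_ns`, `n_events`), ordered by
#'   decreasing maximum duration. Empty list if nothing passes the threshold.
#' @export
identify_sites <- function(profile, receptor, duration_threshold = NULL,
                           adjacency_radius = 1.0, min_size = 2L) {
  if (nrow(profile) == 0L) return(list())
  if (!all(profile$residue_id %in% receptor$beads$residue_id))
    stop("profile and receptor do not share residue ids")
  if (is.null(duration_threshold)) {
    pos <- profile$mean_ns[profile$n_events > 0 & profile$mean_ns > 0]
    if (length(pos) == 0L) return(list())
    duration_threshold <- 3 * stats::median(pos)
  }
  rc <- residue_coms(receptor)
  sites <- list()
  for (sp in unique(profile$species)) {
    p <- profile[profile$species == sp & profile$n_events > 0 &
                 !is.na(profile$mean_ns) &
                 profile$mean_ns >= duration_threshold, ]
    if (nrow(p) < min_size) next
    co <- rc[match(p$residue_id, rc$residue_id), c("x", "y", "z")]
    d <- as.matrix(stats::dist(co))
    adj <- d <= adjacency_radius
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    for (cmp in unique(memb)) {
      ids <- p$residue_id[memb == cmp]
      if (length(ids) < min_size) next
      rows <- p[memb == cmp, ]
      sites[[length(sites) + 1L]] <- structure(
        list(site_id = NA_integer_, residues = sort(ids), species = sp,
             mean_ns = stats::weighted.mean(rows$mean_ns, rows$n_events),
             max_ns = max(rows$mean_ns), n_events = sum(rows$n_events)),
        class = "lipid_binding_site")
    }
  }
  if (length(sites) == 0L) return(list())
  ord <- order(-vapply(sites, `[[`, 0, "max_ns"))
  sites <- sites[ord]
  for (i in seq_along(sites)) sites[[i]]$site_id <- i
  sites
}

#' @export
print.lipid_binding_site <- function(x, ...) {
  cat(sprintf("Binding site %s (%s): residues %s; mean %.1f ns, max %.1f ns, %d events\n",
              x$site_id, x$species, paste(x$residues, collapse = ","),
              x$mean_ns, x$max_ns, x$n_events))
  invisible(x)
}

#' Score bound poses by bead distribution density
#'
#' Selects the frames in which a lipid of the species is bound at the site
#' (COM within `inclusion_radius` of the site's basic residues -- of each of
#' them in `"intersection"` mode, of any in `"union"` mode), accumulates a 3D
#' voxel histogram per bead index over the selected poses, and scores each
#' pose by the sum over its beads of the density at the bead position. Poses
#' are ranked by decreasing score; ties break toward the lower frame index.
#'
#' @param traj A `cg_trajectory`.
#' @param site A `lipid_binding_site` or `binding_site_spec` (or integer
#'   residue ids).
#' @param species Lipid species to score.
#' @param inclusion_radius Bound-pose inclusion radius, nm (default 1.0).
#' @param basic_residues Residue ids defining the site's basic set; defaults
#'   to the receptor's basic residues within the site, falling back to all
#'   site residues.
#' @param mode `"intersection"` (within the radius of all basic residues, as
#'   the rule is stated) or `"union"`.
#' @param voxel_nm Density grid voxel edge, nm (default 0.1).
#' @return data.frame of class `pose_scores`: `frame`, `lipid_id`, `score`,
#'   `rank`.
#' @export
score_poses <- function(traj, site, species, inclusion_radius = 1.0,
                        basic_residues = NULL,
                        mode = c("intersection", "union"), voxel_nm = 0.1) {
  mode <- match.arg(mode)
  residues <- if (is.list(site)) {
    if (!is.null(site$residues)) site$residues else site$anchor_residues
  } else as.integer(site)
  if (is.null(basic_residues)) {
    basic_residues <- intersect(residues, traj$receptor$basic_residues)
    if (length(basic_residues) == 0L) basic_residues <- residues
  }
  rc <- residue_coms(traj$receptor)
  bc <- rc[match(basic_residues, rc$residue_id), ]
  li <- which(traj$lipids$species == species)
  if (length(li) == 0L) stop("no lipids of species ", species)
  nf <- n_frames(traj)

  sel_frame <- integer(0); sel_lip <- integer(0)
  for (i in li) {
    within <- matrix(FALSE, nf, nrow(bc))
    for (b in seq_len(nrow(bc))) {
      dx <- min_image(traj$x[, i] - bc$x[b], traj$box_nm[1])
      dy <- min_image(traj$y[, i] - bc$y[b], traj$box_nm[2])
      dz <- traj$z[, i] - bc$z[b]
      within[, b] <- dx^2 + dy^2 + dz^2 <= inclusion_radius^2
    }
    ok <- if (mode == "intersection") rowSums(within) == nrow(bc)
          else rowSums(within) > 0
    sel_frame <- c(sel_frame, which(ok))
    sel_lip <- c(sel_lip, rep(i, sum(ok)))
  }
  if (length(sel_frame) == 0L) stop("no bound frames at this site")

  tpl <- .bead_templates()[[species]]
  if (is.null(tpl)) tpl <- data.frame(bead = "COM", dx = 0, dy = 0, dz = 0)
  nb <- nrow(tpl)
  n_sel <- length(sel_frame)
  bx <- by <- bz <- matrix(NA_real_, n_sel, nb)
  for (p in seq_len(n_sel)) {
    i <- sel_lip[p]; f <- sel_frame[p]
    sgn <- if (traj$z[f, i] >= 0) 1 else -1
    bx[p, ] <- traj$x[f, i] + tpl$dx
    by[p, ] <- traj$y[f, i] + tpl$dy
    bz[p, ] <- traj$z[f, i] + sgn * tpl$dz
  }
  margin <- 1.0
  ox <- min(bx) - margin; oy <- min(by) - margin; oz <- min(bz) - margin
  ix <- floor((bx - ox) / voxel_nm); iy <- floor((by - oy) / voxel_nm)
  iz <- floor((bz - oz) / voxel_nm)
  score <- numeric(n_sel)
  for (b in seq_len(nb)) {
    key <- paste(ix[, b], iy[, b], iz[, b])
    cnt <- table(key)
    dens <- as.numeric(cnt[key]) / (n_sel * voxel_nm^3)
    score <- score + dens
  }
  ord <- order(-score, sel_frame)
  out <- data.frame(frame = sel_frame, lipid_id = traj$lipids$lipid_id[sel_lip],
                    score = score)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("pose_scores", "data.frame")
  out
}

#' Representative (top-scoring) bound pose
#' @param scores A `pose_scores` data.frame.
#' @return The frame id of the rank-1 pose.
#' @export
representative_pose <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0L) stop("no scored poses")
  scores$frame[scores$rank == 1L][1L]
}

#' Pearson correlation of interaction durations
#'
#' The sample Pearson correlation computed exactly from its definition:
#' sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2)
#' sum((y - mean(y))^2)). Inputs are the per-repeat mean interaction
#' durations of two cohabiting lipid species.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, nonzero variance).
#' @return The correlation in `[-1, 1]`.
#' @export
duration_pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  cx <- x - mean(x); cy <- y - mean(y)
  sx <- sum(cx^2); sy <- sum(cy^2)
  if (sx == 0 || sy == 0)
    stop("undefined correlation: zero variance in an input")
  sum(cx * cy) / sqrt(sx * sy)
}

#' Lipid-interplay correlation matrix
#'
#' Pairwise [duration_pcc()] of per-repeat mean interaction durations across
#' species. Pairs with |PCC| at or above `annotate_threshold` are annotated
#' as synergistic (positive) or competing (negative).
#'
#' @param repeat_means Matrix or data.frame, one row per simulation repeat,
#'   one column per species.
#' @param annotate_threshold |PCC| annotation threshold (default 0.5).
#' @return Object of class `interplay_matrix`: the symmetric correlation
#'   matrix with an `"interplay"` attribute (data.frame of annotated pairs).
#' @export
interplay_matrix <- function(repeat_means, annotate_threshold = 0.5) {
  m <- as.matrix(repeat_means)
  sp <- colnames(m)
  k <- ncol(m)
  out <- matrix(NA_real_, k, k, dimnames = list(sp, sp))
  pairs <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        out[i, j] <- if (stats::sd(m[, i]) > 0) 1 else NA_real_
        next
      }
      r <- tryCatch(duration_pcc(m[, i], m[, j]), error = function(e) NA_real_)
      out[i, j] <- r
      if (i < j && !is.na(r) && abs(r) >= annotate_threshold)
        pairs[[length(pairs) + 1L]] <- data.frame(
          species_x = sp[i], species_y = sp[j], pcc = r,
          interplay = if (r > 0) "synergistic" else "competing",
          stringsAsFactors = FALSE)
    }
  }
  attr(out, "interplay") <- if (length(pairs) > 0) do.call(rbind, pairs)
    else data.frame(species_x = character(), species_y = character(),
                    pcc = numeric(), interplay = character())
  class(out) <- c("interplay_matrix", class(out))
  out
}

#' @export
print.interplay_matrix <- function(x, ...) {
  cat("Lipid interplay (Pearson correlation of interaction durations):\n")
  print(round(unclass(x), 3))
  ann <- attr(x, "interplay")
  if (nrow(ann) > 0) {
    cat("annotated pairs (|PCC| >= threshold):\n")
    for (i in seq_len(nrow(ann)))
      cat(sprintf("  %s / %s: %.2f (%s)\n", ann$species_x[i], ann$species_y[i],
                  ann$pcc[i], ann$interplay[i]))
  }
  invisible(x)
}
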