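# Receptor bead model and designed binding sites for the synthetic generator.

#' Construct a receptor bead model
#'
#' A static coarse-grained receptor: one or more beads per residue, residues
#' grouped into transmembrane helices. The bead set must span both leaflets in
#' z and residue ids must be unique (per bead group) and contiguous.
#'
#' @param beads data.frame with columns `residue_id`, `bead`, `helix`,
#'   `x`, `y`, `z` (nm, receptor axis at the box centre, bilayer midplane at
#'   z = 0).
#' @param basic_residues Integer residue ids flagged cationic (e.g. the
#'   arginines/lysines of anionic-lipid sites).
#' @param helix_spans Optional named list of `c(first, last)` residue-id
#'   intervals labelling TM helices.
#' @return An object of class `receptor_model`.
#' @export
receptor_model <- function(beads, basic_residues = integer(),
                           helix_spans = NULL) {
  stopifnot(all(c("residue_id", "bead", "x", "y", "z") %in% names(beads)))
  ids <- sort(unique(beads$residue_id))
  if (!identical(ids, seq(min(ids), max(ids))))
    stop("residue ids must be contiguous")
  if (max(beads$z) <= 0 || min(beads$z) >= 0)
    stop("receptor beads must span both leaflets in z")
  if (!all(basic_residues %in% ids))
    stop("basic_residues outside the receptor")
  structure(list(beads = beads,
                 basic_residues = as.integer(basic_residues),
                 helix_spans = helix_spans),
            class = "receptor_model")
}

#' Per-residue centres of mass of a receptor
#' @param receptor A `receptor_model`.
#' @return data.frame `residue_id`, `x`, `y`, `z` (equal-weight bead COM).
#' @export
residue_coms <- function(receptor) {
  b <- receptor$beads
  agg <- aggregate(b[c("x", "y", "z")], by = list(residue_id = b$residue_id),
                   FUN = mean)
  agg[order(agg$residue_id), ]
}

#' Specify a designed lipid binding site
#'
#' @param site_id Integer/character site label.
#' @param anchor_residues Residue ids whose COMs the tethered lipid stays
#'   within the contact lower cutoff of.
#' @param anchor_point xy position (nm) of the tether.
#' @param capture_radius Radius (nm) within which an unbound eligible lipid is
#'   exposed to the binding hazard.
#' @param species Lipid species bound by the site.
#' @param k_on Binding hazard per eligible in-range lipid, per microsecond.
#' @param k_off_true True unbinding hazard, per microsecond (the regime of
#'   interest is 2-14 per microsecond).
#' @param leaflet `"upper"` or `"lower"`.
#' @return An object of class `binding_site_spec`.
#' @export
binding_site_spec <- function(site_id, anchor_residues, anchor_point,
                              capture_radius = 0.8, species, k_on = 300,
                              k_off_true, leaflet) {
  stopifnot(k_on > 0, k_off_true > 0, length(anchor_residues) >= 1,
            length(anchor_point) == 2L, leaflet %in% c("upper", "lower"))
  structure(list(site_id = site_id,
                 anchor_residues = as.integer(anchor_residues),
                 anchor_point = as.numeric(anchor_point),
                 capture_radius = capture_radius, species = species,
                 k_on = k_on, k_off_true = k_off_true, leaflet = leaflet),
            class = "binding_site_spec")
}

#' Build a synthetic multi-helix receptor with designed binding sites
#'
#' Helices are placed on a ring of the given radius; each carries residues on
#' a regular z grid spanning the bilayer. A designed site replaces the
#' leaflet-depth residues of its helix with a triplet of anchor residues
#' stacked 0.3 nm apart around the leaflet midplane, so a lipid tethered at
#' the anchor point stays within the contact lower cutoff of all three while
#' residues above/below never come that close. With the default ring radius
#' the anchor points of neighbouring helices are > 1.4 nm apart, so a bound
#' lipid is beyond the upper cutoff of every other site's residues.
#'
#' @param n_sites Number of designed sites (at most `2 * n_helices`).
#' @param species Character vector (recycled) of site species.
#' @param k_off True unbinding rates per site, per microsecond.
#' @param k_on Binding hazard, per microsecond.
#' @param capture_radius Site capture radius, nm.
#' @param n_helices Number of helices.
#' @param ring_radius Helix ring radius, nm.
#' @param z_step Residue z spacing on each helix, nm.
#' @param leaflet_z |z| of the leaflet midplanes, nm.
#' @return List with `receptor` (a [receptor_model()]), `sites` (list of
#'   [binding_site_spec()]), and `design` (named list: designed member-residue
#'   ids per site, the ground truth for site-recovery checks).
#' @export
synthetic_binding_system <- function(n_sites = 9,
                                     species = c("PIP2", "GM3", "PIP2", "GM3",
                                                 "CHOL", "CHOL", "PIP2", "GM3",
                                                 "CHOL"),
                                     k_off = seq(2, 14, length.out = n_sites),
                                     k_on = 300, capture_radius = 0.8,
                                     n_helices = 7, ring_radius = 2.0,
                                     z_step = 0.6, leaflet_z = 2.0) {
  stopifnot(n_sites <= 2 * n_helices)
  species <- rep_len(species, n_sites)
  k_off <- rep_len(k_off, n_sites)
  # alternate lower/upper leaflet slots around the ring
  slot_helix <- ((seq_len(n_sites) - 1L) %% n_helices) + 1L
  slot_leaflet <- rep(c("lower", "upper"), length.out = n_sites)
  # species must live in the right leaflet: PIP2/POPS/DOPS lower, GM3/PSM upper
  lower_only <- c("PIP2", "POPS", "DOPS")
  upper_only <- c("GM3", "PSM")
  slot_leaflet[species %in% lower_only] <- "lower"
  slot_leaflet[species %in% upper_only] <- "upper"
  # avoid two sites landing on the same (helix, leaflet) slot
  key <- paste(slot_helix, slot_leaflet)
  while (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    slot_helix[i] <- (slot_helix[i] %% n_helices) + 1L
    key <- paste(slot_helix, slot_leaflet)
  }

  angles <- 2 * pi * (seq_len(n_helices) - 1) / n_helices
  hx <- ring_radius * cos(angles)
  hy <- ring_radius * sin(angles)
  z_base <- seq(-3, 3, by = z_step)

  rows <- list()
  anchor_of <- vector("list", n_sites)
  for (h in seq_len(n_helices)) {
    z <- z_base
    anchors_here <- list()
    for (s in which(slot_helix == h)) {
      sgn <- if (slot_leaflet[s] == "lower") -1 else 1
      az <- sgn * leaflet_z + c(-0.3, 0, 0.3)
      # drop grid residues that would sit inside the anchor contact shell
      z <- z[abs(z - sgn * leaflet_z) > 0.7]
      z <- c(z, az)
      anchors_here[[as.character(s)]] <- az
    }
    z <- sort(z)
    df <- data.frame(residue_id = NA_integer_, bead = "BB", helix = h,
                     x = hx[h], y = hy[h], z = z, stringsAsFactors = FALSE)
    rows[[h]] <- df
    for (s in names(anchors_here))
      anchor_of[[as.integer(s)]] <- list(helix = h, z = anchors_here[[s]])
  }
  beads <- do.call(rbind, rows)
  beads$residue_id <- seq_len(nrow(beads))

  sites <- vector("list", n_sites)
  design <- vector("list", n_sites)
  basic <- integer()
  for (s in seq_len(n_sites)) {
    h <- anchor_of[[s]]$helix
    az <- anchor_of[[s]]$z
    ids <- beads$residue_id[beads$helix == h & round(beads$z, 6) %in% round(az, 6)]
    sites[[s]] <- binding_site_spec(
      site_id = s, anchor_residues = ids, anchor_point = c(hx[h], hy[h]),
      capture_radius = capture_radius, species = species[s], k_on = k_on,
      k_off_true = k_off[s],
      leaflet = slot_leaflet[s])
    design[[s]] <- ids
    if (species[s] == "PIP2") basic <- c(basic, ids)
  }
  names(design) <- paste0("site", seq_len(n_sites))

  spans <- split(beads$residue_id, beads$helix)
  helix_spans <- lapply(spans, range)
  names(helix_spans) <- paste0("TM", seq_along(helix_spans))

  list(receptor = receptor_model(beads, basic_residues = basic,
                                 helix_spans = helix_spans),
       sites = sites, design = design)
}

#' @export
print.receptor_model <- function(x, ...) {
  cat("Receptor bead model: ", nrow(x$beads), " beads, ",
      length(unique(x$beads$residue_id)), " residues, ",
      length(x$helix_spans), " helices, ",
      length(x$basic_residues), " basic residues\n", sep = "")
  invisible(x)
}
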