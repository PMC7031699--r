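# k_off estimation: mono-exponential fit N(t) = A * exp(-k_off * t) to the
# distribution of continuous-contact durations.

#' Fit k_off to a sample of interaction durations
#'
#' Histograms the (uncensored) durations and fits the mono-exponential decay
#' N(t) = A exp(-k_off t) by weighted nonlinear least squares (Poisson
#' weights, Levenberg-Marquardt). The closed-form exponential rate 1/mean is
#' reported alongside as a cross-check, and a case-resampling bootstrap gives
#' the confidence interval.
#'
#' @param durations_ns Uncensored contact durations in ns.
#' @param bin_width_ns Histogram bin width; default `max(durations)/30`.
#' @param density `"counts"` (default) fits raw bin counts; `"pdf"` fits the
#'   normalized density (identical k_off, different A).
#' @param n_boot Bootstrap resamples for the CI (default 200).
#' @param min_events Minimum number of durations required (default 50).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `koff_fit` with elements `A`, `k_off_us`
#'   (per microsecond), `ci_us`, `n_events`, `residual_norm`,
#'   `rate_from_mean_us`, `bin_width_ns`.
#' @export
fit_koff <- function(durations_ns, bin_width_ns = NULL,
                     density = c("counts", "pdf"), n_boot = 200,
                     min_events = 50, conf = 0.95) {
  density <- match.arg(density)
  durations_ns <- durations_ns[is.finite(durations_ns)]
  n <- length(durations_ns)
  if (n < min_events)
    stop("too few events for a k_off fit: ", n, " < ", min_events)
  if (stats::sd(durations_ns) < .Machine$double.eps * max(durations_ns))
    stop("degenerate fit: all durations identical")
  if (is.null(bin_width_ns)) bin_width_ns <- max(durations_ns) / 30

  fit_once <- function(dur) {
    breaks <- seq(0, max(dur) + bin_width_ns, by = bin_width_ns)
    h <- graphics::hist(dur, breaks = breaks, plot = FALSE)
    y <- h$counts
    if (density == "pdf") y <- y / (length(dur) * bin_width_ns)
    tc <- h$mids
    scale <- if (density == "pdf") length(dur) * bin_width_ns else 1
    w <- 1 / pmax(h$counts, 1)
    k0 <- 1 / mean(dur)
    fit <- minpack.lm::nlsLM(y ~ A * exp(-k * tc),
                             start = list(A = max(y), k = k0),
                             weights = w,
                             lower = c(0, .Machine$double.eps),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    # Poisson variance from the model, not the observed counts: weights from
    # observed counts over-pull sparse tail bins and bias k_off upward
    for (pass in 1:2) {
      w <- 1 / pmax(stats::predict(fit) * scale, 1)
      fit <- minpack.lm::nlsLM(y ~ A * exp(-k * tc),
                               start = as.list(stats::coef(fit)),
                               weights = w,
                               lower = c(0, .Machine$double.eps),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
    }
    stats::coef(fit)
  }
  cf <- fit_once(durations_ns)
  ks <- rep(NA_real_, n_boot)
  if (n_boot > 1) {
    for (b in seq_len(n_boot)) {
      res <- try(fit_once(sample(durations_ns, n, replace = TRUE)),
                 silent = TRUE)
      if (!inherits(res, "try-error")) ks[b] <- res[["k"]] * 1000
    }
  }
  alpha <- (1 - conf) / 2
  ci <- if (all(is.na(ks))) c(NA_real_, NA_real_) else
    stats::quantile(ks, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  # the point estimate must lie in its own interval
  ci <- range(c(ci, cf[["k"]] * 1000), na.rm = TRUE)

  breaks <- seq(0, max(durations_ns) + bin_width_ns, by = bin_width_ns)
  h <- graphics::hist(durations_ns, breaks = breaks, plot = FALSE)
  y <- h$counts
  if (density == "pdf") y <- y / (n * bin_width_ns)
  resid <- y - cf[["A"]] * exp(-cf[["k"]] * h$mids)

  structure(list(A = unname(cf[["A"]]),
                 k_off_us = unname(cf[["k"]]) * 1000,
                 ci_us = ci, conf = conf, n_events = n,
                 residual_norm = sqrt(sum(resid^2)),
                 rate_from_mean_us = 1000 / mean(durations_ns),
                 bin_width_ns = bin_width_ns, density = density),
            class = "koff_fit")
}

#' @export
print.koff_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential k_off fit: k_off = %.3g /us (%d%% CI %.3g-%.3g), A = %.3g, n = %d\n",
              x$k_off_us, round(100 * (x$conf %||% 0.95)), x$ci_us[1],
              x$ci_us[2], x$A, x$n_events))
  cat(sprintf("  1/mean cross-check: %.3g /us\n", x$rate_from_mean_us))
  invisible(x)
}

#' @export
coef.koff_fit <- function(object, ...) {
  c(A = object$A, k_off_us = object$k_off_us)
}

#' Evaluate the fitted decay curve
#' @param object A `koff_fit`.
#' @param t_ns Times (ns) at which to evaluate N(t).
#' @param ... Unused.
#' @export
predict.koff_fit <- function(object, t_ns = 0, ...) {
  object$A * exp(-object$k_off_us / 1000 * t_ns)
}

#' k_off of a binding site from its strongest residues
#'
#' Following the per-site analysis, selects the residue(s) with the largest
#' mean interaction duration within the site (top 1 by default) and fits
#' k_off on their pooled durations.
#'
#' @param profile A `duration_profile`.
#' @param site A [binding_site_spec()], a `lipid_binding_site` from
#'   [identify_sites()], or an integer vector of residue ids.
#' @param events The event data.frame the profile was built from.
#' @param species Restrict to this species (defaults to the site's species if
#'   it carries one).
#' @param top Number of strongest residues to pool (default 1).
#' @param ... Passed to [fit_koff()].
#' @return A `koff_fit`.
#' @export
site_koff <- function(profile, site, events, species = NULL, top = 1L, ...) {
  residues <- if (inherits(site, "binding_site_spec")) site$anchor_residues
              else if (inherits(site, "lipid_binding_site")) site$residues
              else as.integer(site)
  if (is.null(species) && is.list(site) && !is.null(site$species))
    species <- site$species
  if (length(residues) == 0L) stop("site has no residues")
  p <- profile[profile$residue_id %in% residues & profile$n_events > 0, ]
  if (!is.null(species)) p <- p[p$species %in% species, ]
  if (nrow(p) == 0L) stop("site has zero events")
  p <- p[order(-p$mean_ns), ]
  pick <- p$residue_id[seq_len(min(top, nrow(p)))]
  sel <- events$residue_id %in% pick & !events$censored
  if (!is.null(species)) sel <- sel & events$species %in% species
  fit_koff(events$duration_ns[sel], ...)
}
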