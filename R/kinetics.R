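#' Avogadro's number (1/mol)
#' @export
N_AVOGADRO <- 6.02214076e23

PS_PER_S <- 1e12

#' Percentile bootstrap confidence interval
#'
#' Resamples the event-level observations with replacement, re-applies the
#' estimator, and returns the percentile interval. Seeded and reproducible.
#'
#' @param x numeric vector of events (durations or waiting times).
#' @param statistic function of a resampled vector returning one number.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param level confidence level in (0, 1).
#' @param seed integer seed.
#' @return numeric `c(low, high)`; `c(NA, NA)` (with a warning) when fewer
#'   than two events are available.
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 10000L,
                         level = 0.95, seed = 1L) {
  stopifnot(n_boot >= 100L, level > 0, level < 1)
  n <- length(x)
  if (n < 2L) {
    warning("fewer than 2 events: confidence interval undefined")
    return(c(NA_real_, NA_real_))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  stats <- if (identical(statistic, mean)) {
    colMeans(matrix(x[idx], nrow = n))
  } else {
    apply(idx, 2L, function(i) statistic(x[i]))
  }
  alpha <- (1 - level) / 2
  unname(stats::quantile(stats, c(alpha, 1 - alpha), names = FALSE,
                         type = 7))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.rate_estimate <- function(kind, site, value, units, n_events, ci, level) {
  structure(list(kind = kind, site = site, value = value, units = units,
                 n_events = n_events, ci_low = ci[1], ci_high = ci[2],
                 ci_level = level),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s(%s) = %.4g %s  [%.4g, %.4g] (%d%% CI, n = %d events)\n",
              x$kind, x$site, x$value, x$units,
              x$ci_low, x$ci_high, round(100 * x$ci_level), x$n_events))
  invisible(x)
}

#' Dissociation rate constant by direct counting
#'
#' `k_off = 1 / mean survival time`: the reciprocal of the mean duration of
#' the maximal bound runs for the site, converted to 1/s. Boundary-censored
#' dwells are included by default (the plain direct-counting estimator
#' pools every observed run); set `include_censored = FALSE` to drop them.
#'
#' @param dwells a `dwell_table` from [extract_dwells()].
#' @param site `"SITE_A"` or `"SITE_B"`.
#' @param include_censored include dwells truncated by a replica boundary.
#' @param level,n_boot,seed bootstrap CI controls (see [bootstrap_ci()]).
#' @return a `rate_estimate` (units 1/s).
#' @export
estimate_koff <- function(dwells, site = c("SITE_A", "SITE_B"),
                          include_censored = TRUE, level = 0.95,
                          n_boot = 10000L, seed = 1L) {
  site <- match.arg(site)
  d <- dwells$duration[dwells$state == site &
                         (include_censored | !dwells$censored)]
  if (length(d) == 0L)
    stop("no ", site, " binding events observed: k_off is undefined")
  ## percentile CI of the mean maps through the monotone transform
  ## k_off = 1/mean with the bounds swapped
  ci <- if (length(d) >= 2L)
    sort(PS_PER_S / bootstrap_ci(d, mean, n_boot, level, seed)) else {
      warning("single event: confidence interval undefined")
      c(NA_real_, NA_real_)
    }
  .rate_estimate("k_off", site, PS_PER_S / mean(d), "1/s", length(d), ci,
                 level)
}

#' Association rate constant by direct counting
#'
#' `k_on = (N_Av * v_eff) / t_on` in 1/(M s), where `t_on` is the mean
#' unbound waiting time behind the site's association events and `v_eff`
#' the effective volume (box minus protein) in litres. The effective
#' concentration of the single intramolecular partner,
#' `C_eff = 1 / (N_Av * v_eff)`, is reported alongside, so that
#' `k_on * C_eff = 1 / t_on` is the observed pseudo-first-order rate.
#'
#' @param dwells a `dwell_table`.
#' @param site `"SITE_A"` or `"SITE_B"`.
#' @param volume a `volume_model` from [compute_effective_volume()], or a
#'   single number taken as `v_eff` in litres.
#' @param scope waiting-time scope, see [unbound_intervals()].
#' @param level,n_boot,seed bootstrap CI controls.
#' @return a `rate_estimate` (units 1/(M s)) with extra fields `t_on_ps`,
#'   `v_eff_L` and `c_eff_M`.
#' @export
estimate_kon <- function(dwells, site = c("SITE_A", "SITE_B"), volume,
                         scope = c("to_event", "open_only"), level = 0.95,
                         n_boot = 10000L, seed = 1L) {
  site <- match.arg(site)
  veff_L <- if (inherits(volume, "volume_model")) volume$v_eff_L
  else as.numeric(volume)
  if (!is.finite(veff_L) || veff_L <= 0)
    stop("effective volume must be positive")
  w <- unbound_intervals(dwells, site, scope = match.arg(scope))
  if (length(w) == 0L)
    stop("no ", site, " association events observed: k_on is undefined")
  kon_from_mean_ps <- function(m) N_AVOGADRO * veff_L / (m / PS_PER_S)
  ci <- if (length(w) >= 2L)
    sort(kon_from_mean_ps(bootstrap_ci(w, mean, n_boot, level, seed))) else {
      warning("single waiting interval: confidence interval undefined")
      c(NA_real_, NA_real_)
    }
  out <- .rate_estimate("k_on", site, kon_from_mean_ps(mean(w)), "1/(M s)",
                        length(w), ci, level)
  out$t_on_ps <- mean(w)
  out$v_eff_L <- veff_L
  out$c_eff_M <- 1 / (N_AVOGADRO * veff_L)
  out
}

## van der Waals radii (Angstrom) for the elements seen in protein heavy
## atoms plus hydrogen; unknown elements fall back to carbon.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Effective volume: simulation box minus protein
#'
#' The protein volume is estimated by van-der-Waals-sphere voxelisation: a
#' cubic grid (default spacing 0.5 Angstrom) spans the molecule, and every
#' voxel whose center lies inside any atom's vdW sphere contributes
#' `spacing^3`. The estimate is averaged over at most `max_frames` evenly
#' spaced frames. `v_eff = box - protein` is reported in Angstrom^3 and
#' litres (1 A^3 = 1e-27 L).
#'
#' @param ens an [ensemble]. Its `box_volume` is used unless `box_volume`
#'   is supplied here.
#' @param box_volume box volume override, Angstrom^3.
#' @param spacing voxel grid spacing, Angstrom.
#' @param max_frames maximum number of frames averaged over.
#' @return a `volume_model`: box, protein and effective volumes (A^3), plus
#'   `v_eff_L`.
#' @export
compute_effective_volume <- function(ens, box_volume = NULL, spacing = 0.5,
                                     max_frames = 100L) {
  stopifnot(inherits(ens, "ensemble"), spacing > 0)
  if (is.null(box_volume)) {
    if (is.null(ens$box_volume))
      stop("no box volume in the ensemble and no override given")
    box_volume <- mean(ens$box_volume)
  }
  nf <- n_frames(ens)
  frames <- unique(round(seq(1L, nf, length.out = min(max_frames, nf))))
  radii <- .VDW_RADII[ens$atoms$element]
  radii[is.na(radii)] <- .VDW_RADII[["C"]]
  vols <- vapply(frames, function(f)
    .voxel_volume(ens$xyz[f, ], radii, spacing), numeric(1))
  protein <- mean(vols)
  if (protein >= box_volume)
    stop("protein volume (", round(protein), " A^3) >= box volume (",
         round(box_volume), " A^3)")
  veff <- box_volume - protein
  structure(list(box_volume_A3 = box_volume, protein_volume_A3 = protein,
                 v_eff_A3 = veff, v_eff_L = veff * 1e-27,
                 method = sprintf("vdW voxelisation, %.2f A grid, %d frames",
                                  spacing, length(frames))),
            class = "volume_model")
}

#' @export
print.volume_model <- function(x, ...) {
  cat(sprintf(
    "Volume model (%s)\n  box %.4g A^3, protein %.4g A^3, v_eff %.4g A^3 (%.4g L)\n",
    x$method, x$box_volume_A3, x$protein_volume_A3, x$v_eff_A3, x$v_eff_L))
  invisible(x)
}

## Voxelised union-of-spheres volume for one frame (flat xyz vector).
.voxel_volume <- function(frame_xyz, radii, spacing) {
  n <- length(frame_xyz) %/% 3L
  px <- frame_xyz[3L * seq_len(n) - 2L]
  py <- frame_xyz[3L * seq_len(n) - 1L]
  pz <- frame_xyz[3L * seq_len(n)]
  rmax <- max(radii)
  gx <- seq(min(px) - rmax, max(px) + rmax + spacing, by = spacing)
  gy <- seq(min(py) - rmax, max(py) + rmax + spacing, by = spacing)
  gz <- seq(min(pz) - rmax, max(pz) + rmax + spacing, by = spacing)
  inside <- array(FALSE, c(length(gx), length(gy), length(gz)))
  for (a in seq_len(n)) {
    r <- radii[a]
    ix <- which(abs(gx - px[a]) <= r)
    iy <- which(abs(gy - py[a]) <= r)
    iz <- which(abs(gz - pz[a]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - px[a])^2
    dy2 <- (gy[iy] - py[a])^2
    dz2 <- (gz[iz] - pz[a])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    inside[ix, iy, iz] <- inside[ix, iy, iz] | (d2 <= r^2)
  }
  sum(inside) * spacing^3
}
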