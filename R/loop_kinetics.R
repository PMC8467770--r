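#' Fit loop-binding kinetics by direct counting
#'
#' The package's central estimator. From a classified per-frame state
#' sequence (or directly from an ensemble plus region definitions) it
#' extracts bound dwells and unbound waiting intervals and estimates, for
#' each binding site, the dissociation rate constant
#' `k_off = 1 / mean survival time` and — when an effective volume is
#' available — the association rate constant
#' `k_on = (N_Av * v_eff) / t_on`, each with a percentile-bootstrap
#' confidence interval over events.
#'
#' @param x a [state_sequence], a `dwell_table`, or an [ensemble] (in which
#'   case `regions` is required and frames are classified first).
#' @param regions a `region_set`; only used when `x` is an ensemble.
#' @param config an [analysis_config]; supplies the classification cutoffs,
#'   bootstrap replicate count, CI level and seed.
#' @param volume a `volume_model`, or a number taken as `v_eff` in litres,
#'   or `NULL` to skip `k_on`.
#' @param include_censored include boundary-censored dwells in the mean
#'   survival time (default TRUE; the plain direct-counting estimator).
#' @param ton_scope waiting-time scope for `k_on`, see
#'   [unbound_intervals()].
#' @return an object of class `loop_kinetics`: a list with `rates` (a
#'   data.frame of estimates), `estimates` (the underlying `rate_estimate`
#'   objects), `dwells`, `states`, `volume` and the call.
#' @seealso [estimate_koff()], [estimate_kon()], [simulate.loop_kinetics()]
#' @examples
#' s <- state_sequence(rep(c("OPEN", "SITE_A", "SITE_A", "OPEN", "SITE_B"),
#'                         40), frame_interval = 200)
#' fit <- loop_kinetics(s, volume = 6e-22)
#' coef(fit)
#' confint(fit)
#' @export
loop_kinetics <- function(x, regions = NULL, config = analysis_config(),
                          volume = NULL, include_censored = TRUE,
                          ton_scope = c("to_event", "open_only")) {
  cl <- match.call()
  ton_scope <- match.arg(ton_scope)
  states <- NULL
  if (inherits(x, "ensemble")) {
    if (is.null(regions))
      stop("classifying an ensemble requires a region_set")
    states <- classify_frames(x, regions, config)
    dwells <- extract_dwells(states)
    if (is.null(volume) && !is.null(x$box_volume))
      volume <- compute_effective_volume(x)
  } else if (inherits(x, "state_sequence")) {
    states <- x
    dwells <- extract_dwells(states)
  } else if (inherits(x, "dwell_table")) {
    dwells <- x
  } else stop("x must be an ensemble, state_sequence or dwell_table")

  ests <- list()
  for (site in c("SITE_A", "SITE_B")) {
    n_bound <- sum(dwells$state == site)
    if (n_bound >= 1L) {
      ests[[paste0("koff_", site)]] <- estimate_koff(
        dwells, site, include_censored = include_censored,
        level = config$ci_level, n_boot = config$bootstrap_replicates,
        seed = config$seed)
    }
    if (!is.null(volume) &&
        length(unbound_intervals(dwells, site, ton_scope)) >= 1L) {
      ests[[paste0("kon_", site)]] <- estimate_kon(
        dwells, site, volume, scope = ton_scope, level = config$ci_level,
        n_boot = config$bootstrap_replicates, seed = config$seed + 1L)
    }
  }
  rates <- do.call(rbind, lapply(ests, function(e)
    data.frame(kind = e$kind, site = e$site, value = e$value,
               units = e$units, n_events = e$n_events, ci_low = e$ci_low,
               ci_high = e$ci_high, ci_level = e$ci_level,
               stringsAsFactors = FALSE)))
  structure(list(rates = rates, estimates = ests, dwells = dwells,
                 states = states,
                 volume = if (inherits(volume, "volume_model")) volume
                 else if (!is.null(volume))
                   list(v_eff_L = as.numeric(volume), method = "override"),
                 include_censored = include_censored,
                 ton_scope = ton_scope, config = config, call = cl),
            class = "loop_kinetics")
}

#' @export
print.loop_kinetics <- function(x, digits = 4, ...) {
  cat("Loop binding kinetics (direct counting)\n\n")
  if (is.null(x$rates)) {
    cat("  no binding events observed\n")
    return(invisible(x))
  }
  df <- x$rates
  df$value <- signif(df$value, digits)
  df$ci_low <- signif(df$ci_low, digits)
  df$ci_high <- signif(df$ci_high, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.loop_kinetics <- function(object, ...) {
  d <- object$dwells
  per_state <- do.call(rbind, lapply(levels(factor(d$state)), function(s) {
    dd <- d[d$state == s, ]
    data.frame(state = s, n_events = nrow(dd),
               mean_dwell_ps = mean(dd$duration),
               median_dwell_ps = stats::median(dd$duration),
               total_time_ps = sum(dd$duration),
               n_censored = sum(dd$censored))
  }))
  out <- list(rates = object$rates, dwell_summary = per_state,
              volume = object$volume,
              n_replicas = length(unique(d$replica)),
              frame_interval = attr(d, "frame_interval"))
  class(out) <- "summary.loop_kinetics"
  out
}

#' @export
print.summary.loop_kinetics <- function(x, ...) {
  cat("Dwell-time summary (", x$n_replicas, " replica(s), dt = ",
      x$frame_interval, " ps):\n", sep = "")
  print(x$dwell_summary, row.names = FALSE)
  cat("\nRate estimates:\n")
  if (!is.null(x$rates)) print(x$rates, row.names = FALSE)
  if (!is.null(x$volume) && !is.null(x$volume$v_eff_L))
    cat(sprintf("\nEffective volume: %.4g L (C_eff = %.4g M)\n",
                x$volume$v_eff_L, 1 / (N_AVOGADRO * x$volume$v_eff_L)))
  invisible(x)
}

#' @export
coef.loop_kinetics <- function(object, ...) {
  if (is.null(object$rates)) return(numeric(0))
  stats::setNames(object$rates$value,
                  paste(object$rates$kind, object$rates$site, sep = "."))
}

#' @export
confint.loop_kinetics <- function(object, parm, level, ...) {
  r <- object$rates
  ci <- cbind(r$ci_low, r$ci_high)
  rownames(ci) <- paste(r$kind, r$site, sep = ".")
  colnames(ci) <- paste0(100 * c((1 - r$ci_level[1]) / 2,
                                 1 - (1 - r$ci_level[1]) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Simulate state sequences from a fitted kinetics model
#'
#' Draws new three-state trajectories from the continuous-time Markov
#' chain implied by the fitted rates: the fitted `k_off` per site, and
#' pseudo-first-order association rates `1 / t_on` recovered from the
#' observed waiting times. Useful for parametric-bootstrap checks of the
#' direct-counting estimator.
#'
#' @param object a fitted `loop_kinetics`.
#' @param nsim number of replicas to simulate.
#' @param seed integer seed.
#' @param n_frames frames per simulated replica (default: frames per
#'   replica of the fitted data).
#' @param ... unused.
#' @return a [state_sequence].
#' @export
simulate.loop_kinetics <- function(object, nsim = 1, seed = NULL,
                                   n_frames = NULL, ...) {
  cf <- coef(object)
  need <- c("k_off.SITE_A", "k_off.SITE_B")
  if (!all(need %in% names(cf)))
    stop("simulation requires fitted k_off for both sites")
  d <- object$dwells
  ton_A <- mean(unbound_intervals(d, "SITE_A", object$ton_scope))
  ton_B <- mean(unbound_intervals(d, "SITE_B", object$ton_scope))
  if (!is.finite(ton_A) || !is.finite(ton_B))
    stop("simulation requires observed association events for both sites")
  dt <- attr(d, "frame_interval")
  if (is.null(n_frames)) {
    tab <- table(d$replica)
    n_frames <- round(sum(d$duration) / dt / length(tab))
  }
  p <- ctmc_params(k_on_A = PS_PER_S / ton_A, k_on_B = PS_PER_S / ton_B,
                   k_off_A = cf[["k_off.SITE_A"]],
                   k_off_B = cf[["k_off.SITE_B"]],
                   frame_interval = dt, n_frames = n_frames,
                   n_replicas = nsim,
                   seed = if (is.null(seed)) 1L else as.integer(seed))
  simulate_ctmc(p)$states
}

#' Rate-constant plot with confidence intervals
#'
#' @param x a `loop_kinetics` fit.
#' @param which `"k_off"`, `"k_on"` or both.
#' @param ... passed to [graphics::barplot].
#' @export
plot.loop_kinetics <- function(x, which = c("k_off", "k_on"), ...) {
  r <- x$rates[x$rates$kind %in% which, ]
  if (nrow(r) == 0L) stop("no rates of the requested kind in the fit")
  old <- graphics::par(mfrow = c(1, length(unique(r$kind))))
  on.exit(graphics::par(old))
  for (k in unique(r$kind)) {
    rk <- r[r$kind == k, ]
    bp <- graphics::barplot(rk$value, names.arg = rk$site, log = "y",
                            ylab = paste0(k, " (", rk$units[1], ")"),
                            ylim = range(rk$value, rk$ci_low, rk$ci_high,
                                         na.rm = TRUE), ...)
    graphics::arrows(bp, rk$ci_low, bp, rk$ci_high, angle = 90, code = 3,
                     length = 0.06)
  }
  invisible(x)
}

#' Residual diagnostics for the exponential dwell model
#'
#' Direct counting models dwell durations as exponential. The method
#' returns, per bound state, the standardised exponential quantile
#' residuals `d / mean(d) - 1`; systematic structure indicates
#' non-exponential (e.g. multi-pathway) unbinding.
#'
#' @param object a `loop_kinetics` fit.
#' @param ... unused.
#' @return data.frame with `state`, `duration` and `residual`.
#' @export
residuals.loop_kinetics <- function(object, ...) {
  d <- object$dwells[object$dwells$state %in% c("SITE_A", "SITE_B"), ]
  if (nrow(d) == 0L) return(data.frame(state = character(0),
                                       duration = numeric(0),
                                       residual = numeric(0)))
  res <- unlist(lapply(split(d$duration, d$state, drop = TRUE),
                       function(x) x / mean(x) - 1), use.names = FALSE)
  data.frame(state = d$state[order(d$state)],
             duration = d$duration[order(d$state)], residual = res)
}
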