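#' State-sequence container
#'
#' Per-frame labels from the three-state alphabet OPEN / SITE_A / SITE_B at
#' a fixed frame interval, with replica ids retained so dwell extraction
#' treats replica boundaries as hard breaks.
#'
#' @param labels character or factor vector with values in
#'   `c("OPEN", "SITE_A", "SITE_B")`.
#' @param frame_interval frame spacing, ps.
#' @param replica integer vector (contiguous per replica); default all 1.
#' @return an object of class `state_sequence`.
#' @export
state_sequence <- function(labels, frame_interval, replica = NULL) {
  lv <- c("OPEN", "SITE_A", "SITE_B")
  labels <- as.character(labels)
  if (!all(labels %in% lv))
    stop("labels outside the {OPEN, SITE_A, SITE_B} alphabet: ",
         paste(unique(setdiff(labels, lv)), collapse = ", "))
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (is.null(replica)) replica <- rep.int(1L, length(labels))
  if (length(replica) != length(labels))
    stop("replica vector length != number of frames")
  structure(list(labels = factor(labels, levels = lv),
                 frame_interval = as.numeric(frame_interval),
                 replica = as.integer(replica)),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  n <- length(x$labels)
  cat("State sequence:", n, "frames @", x$frame_interval, "ps,",
      length(unique(x$replica)), "replica(s)\n")
  occ <- table(x$labels) / n
  cat("  occupancy:", paste(sprintf("%s %.3f", names(occ), occ),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Classify frames into open / site-A bound / site-B bound
#'
#' A frame is bound to a site when at least `min_contact_residues` loop
#' residues are each in contact (minimum atom-atom distance at most
#' `atom_contact_cutoff`, heavy atoms by default) with at least one residue
#' of that site. If both sites qualify simultaneously, the site with the
#' larger contacting-residue count wins; an exact tie keeps the previous
#' frame's bound label (hysteresis), or OPEN at the start of a replica.
#'
#' @param ens an [ensemble].
#' @param regions a `region_set`.
#' @param config an [analysis_config] (uses `atom_contact_cutoff`,
#'   `min_contact_residues`, `include_hydrogens`).
#' @param keep_counts logical; attach the per-frame contact-residue counts.
#' @return a [state_sequence] (with a `counts` element when requested).
#' @export
classify_frames <- function(ens, regions, config = analysis_config(),
                            keep_counts = FALSE) {
  stopifnot(inherits(ens, "ensemble"), inherits(regions, "region_set"))
  cut2 <- config$atom_contact_cutoff^2
  nf <- n_frames(ens)
  counts <- list()
  for (site in c("siteA", "siteB")) {
    site_atoms <- .region_atoms(regions, site, config$include_hydrogens)
    cnt <- integer(nf)
    for (r in as.character(regions$loop)) {
      idx <- regions$atom_idx$loop[[r]]
      if (config$include_hydrogens)
        idx <- c(idx, regions$hydrogen_idx$loop[[r]])
      cnt <- cnt + (.min_dist2_sets(ens$xyz, idx, site_atoms) <= cut2)
    }
    counts[[site]] <- cnt
  }
  thr <- config$min_contact_residues
  a <- counts$siteA; b <- counts$siteB
  lab <- rep.int("OPEN", nf)
  lab[a >= thr & (b < thr | a > b)] <- "SITE_A"
  lab[b >= thr & (a < thr | b > a)] <- "SITE_B"
  ## exact dual-qualifying ties: inherit the previous bound label within the
  ## replica, OPEN otherwise
  ties <- which(a >= thr & b >= thr & a == b)
  for (f in ties) {
    prev <- if (f > 1L && ens$replica[f - 1L] == ens$replica[f])
      lab[f - 1L] else "OPEN"
    lab[f] <- if (prev %in% c("SITE_A", "SITE_B")) prev else "OPEN"
  }
  out <- state_sequence(lab, ens$frame_interval, ens$replica)
  if (keep_counts) out$counts <- data.frame(siteA = a, siteB = b)
  out
}

#' Extract dwell (survival) and unbound intervals
#'
#' One event per maximal constant-label run within a replica, for all three
#' labels (bound dwells and OPEN intervals alike). Runs touching a
#' replica's first or last frame are flagged censored: their true duration
#' is only bounded below. Durations are `run length x frame_interval`.
#'
#' @param states a [state_sequence].
#' @return a `dwell_table`: data.frame with columns `state`, `replica`,
#'   `start`, `end` (frame indices into the concatenated sequence),
#'   `duration` (ps) and `censored`; attribute `frame_interval`.
#' @export
extract_dwells <- function(states) {
  stopifnot(inherits(states, "state_sequence"))
  lab <- as.character(states$labels)
  if (length(lab) == 0L) stop("empty state sequence")
  dt <- states$frame_interval
  out <- vector("list", length(unique(states$replica)))
  k <- 0L
  for (rep_id in unique(states$replica)) {
    sel <- which(states$replica == rep_id)
    r <- rle(lab[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- k + 1L
    out[[k]] <- data.frame(
      state = r$values, replica = rep_id,
      start = sel[1L] + starts - 1L, end = sel[1L] + ends - 1L,
      duration = r$lengths * dt,
      censored = starts == 1L | ends == length(sel),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, frame_interval = dt,
            class = c("dwell_table", "data.frame"))
}

#' Total bound time per site
#'
#' @param dwells a `dwell_table`.
#' @return named numeric (ps) for SITE_A and SITE_B.
#' @export
total_bound_time <- function(dwells) {
  vapply(c("SITE_A", "SITE_B"), function(s)
    sum(dwells$duration[dwells$state == s]), numeric(1))
}

#' Per-site unbound waiting intervals
#'
#' The waiting time behind each association event: for site X, the maximal
#' interval of non-X labels that terminates when an X dwell begins. Time
#' spent bound to the other site counts as waiting (switchable to OPEN-only
#' time via `scope`). Trailing intervals that never terminate in an X entry
#' before the replica ends are right-censored and excluded.
#'
#' @param dwells a `dwell_table`.
#' @param site `"SITE_A"` or `"SITE_B"`.
#' @param scope `"to_event"` (default; full non-X interval) or
#'   `"open_only"` (only the OPEN portion of the interval).
#' @return numeric vector of waiting times, ps (possibly length 0).
#' @export
unbound_intervals <- function(dwells, site = c("SITE_A", "SITE_B"),
                              scope = c("to_event", "open_only")) {
  site <- match.arg(site)
  scope <- match.arg(scope)
  waits <- numeric(0)
  for (rep_id in unique(dwells$replica)) {
    d <- dwells[dwells$replica == rep_id, ]
    acc <- 0
    for (i in seq_len(nrow(d))) {
      if (d$state[i] == site) {
        if (acc > 0) waits <- c(waits, acc)
        acc <- 0
      } else if (scope == "to_event" || d$state[i] == "OPEN") {
        acc <- acc + d$duration[i]
      }
    }
    ## the trailing accumulator never terminated in a binding event:
    ## right-censored, dropped
  }
  waits
}
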