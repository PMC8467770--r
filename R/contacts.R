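## Internal coordinate helpers. The ensemble xyz matrix is frames x (3N):
## column 3a-2 is atom a's x, 3a-1 its y, 3a its z.

## Per-frame geometric center (unweighted mean) of an atom set: n_frames x 3.
.center_frames <- function(xyz, idx) {
  cbind(rowMeans(xyz[, 3L * idx - 2L, drop = FALSE]),
        rowMeans(xyz[, 3L * idx - 1L, drop = FALSE]),
        rowMeans(xyz[, 3L * idx, drop = FALSE]))
}

## Per-frame squared distance from a moving point (n_frames x 3) to each
## atom in `idx`, minimised over the set.
.min_dist2_point_set <- function(xyz, pt, idx) {
  out <- rep.int(Inf, nrow(xyz))
  for (a in idx) {
    d2 <- (xyz[, 3L * a - 2L] - pt[, 1L])^2 +
          (xyz[, 3L * a - 1L] - pt[, 2L])^2 +
          (xyz[, 3L * a] - pt[, 3L])^2
    out <- pmin(out, d2)
  }
  out
}

## Per-frame minimum squared distance between two atom sets.
.min_dist2_sets <- function(xyz, idx_a, idx_b) {
  out <- rep.int(Inf, nrow(xyz))
  for (a in idx_a) {
    ax <- xyz[, 3L * a - 2L]; ay <- xyz[, 3L * a - 1L]; az <- xyz[, 3L * a]
    for (b in idx_b) {
      d2 <- (ax - xyz[, 3L * b - 2L])^2 + (ay - xyz[, 3L * b - 1L])^2 +
            (az - xyz[, 3L * b])^2
      out <- pmin(out, d2)
    }
  }
  out
}

#' Loop-center contact-ratio profile
#'
#' For every frame the geometric center of the loop's heavy atoms is
#' computed; a contact with residue i is declared when the distance from
#' that center to residue i is at most the cutoff, and the contact ratio is
#' the fraction of frames in which the contact is present. One profile is
#' reported per cutoff. Residues belonging to the loop itself (plus,
#' optionally, `exclude_neighbors` sequence neighbours on either side) are
#' excluded from the target set, since contacts trivially persist near the
#' loop in primary sequence.
#'
#' @param ens an [ensemble].
#' @param regions a `region_set` from [resolve_regions()].
#' @param cutoffs center-to-residue cutoff distances, Angstrom.
#' @param endpoint residue endpoint for the distance: `"center"` (geometric
#'   center of the residue's heavy atoms, symmetric with the loop-center
#'   definition; the default) or `"nearest"` (nearest heavy atom).
#' @param exclude_neighbors integer k: also drop residues within k of the
#'   loop in residue numbering. Default 0 (drop the loop only).
#' @return a `contact_profile`: data.frame with `resno` and one ratio column
#'   per cutoff (named `r<cutoff>`), with attributes `cutoffs` and
#'   `n_frames`.
#' @export
loop_center_contact_profile <- function(ens, regions,
                                        cutoffs = c(6.5, 8.0, 12.0),
                                        endpoint = c("center", "nearest"),
                                        exclude_neighbors = 0L) {
  stopifnot(inherits(ens, "ensemble"), inherits(regions, "region_set"),
            all(cutoffs > 0), n_frames(ens) >= 1L)
  endpoint <- match.arg(endpoint)
  loop_atoms <- .region_atoms(regions, "loop")
  if (length(loop_atoms) == 0L) stop("empty loop selection")
  ctr <- .center_frames(ens$xyz, loop_atoms)

  atoms <- ens$atoms
  targets <- sort(unique(atoms$resno[atoms$heavy]))
  drop <- regions$loop
  if (exclude_neighbors > 0L)
    drop <- unique(c(drop, outer(regions$loop,
                                 seq_len(exclude_neighbors) %o% c(-1L, 1L),
                                 `+`)))
  targets <- setdiff(targets, drop)
  cutoffs <- sort(as.numeric(cutoffs))
  cut2 <- cutoffs^2

  ratios <- matrix(NA_real_, length(targets), length(cutoffs))
  for (i in seq_along(targets)) {
    idx <- which(atoms$resno == targets[i] & atoms$heavy)
    d2 <- if (endpoint == "center") {
      rc <- .center_frames(ens$xyz, idx)
      (ctr[, 1] - rc[, 1])^2 + (ctr[, 2] - rc[, 2])^2 + (ctr[, 3] - rc[, 3])^2
    } else {
      .min_dist2_point_set(ens$xyz, ctr, idx)
    }
    ratios[i, ] <- vapply(cut2, function(c2) mean(d2 <= c2), numeric(1))
  }
  out <- data.frame(resno = targets, ratios)
  names(out) <- c("resno", paste0("r", cutoffs))
  structure(out, cutoffs = cutoffs, n_frames = n_frames(ens),
            endpoint = endpoint, class = c("contact_profile", "data.frame"))
}

#' @export
plot.contact_profile <- function(x, ...) {
  cutoffs <- attr(x, "cutoffs")
  cols <- grDevices::hcl.colors(length(cutoffs), "Dark 3")
  graphics::matplot(x$resno, as.matrix(x[, -1, drop = FALSE]), type = "l",
                    lty = 1, col = cols, xlab = "residue",
                    ylab = "contact ratio", ...)
  graphics::legend("topright", legend = paste0(cutoffs, " A"), lty = 1,
                   col = cols, bty = "n")
  invisible(x)
}

#' Residue-residue contact map
#'
#' Entry (i, j) is the fraction of (masked) frames in which the minimum
#' atom-atom distance between loop residue i and target residue j is at
#' most `cutoff` (4.5 Angstrom by default, heavy atoms only unless
#' `include_hydrogens`). A frame mask restricts the denominator, e.g. to the
#' frames classified in one bound state for state-conditioned maps.
#'
#' @param ens an [ensemble].
#' @param loop_res,target_res residue id vectors.
#' @param cutoff atom-pair cutoff, Angstrom.
#' @param frame_mask logical vector of length `n_frames(ens)`; default all
#'   frames. Must select at least one frame.
#' @param include_hydrogens logical; include hydrogens in the pair distance.
#' @return a `residue_contact_map`: list with `ratio` (|loop| x |target|
#'   matrix), `loop_contacts` (n_masked x |target| matrix counting, per
#'   frame, how many loop residues contact each target residue), `cutoff`,
#'   `n_frames` (the mask size, i.e. the ratio denominator).
#' @export
residue_contact_map <- function(ens, loop_res, target_res, cutoff = 4.5,
                                frame_mask = NULL,
                                include_hydrogens = FALSE) {
  stopifnot(inherits(ens, "ensemble"), cutoff > 0)
  if (is.null(frame_mask)) frame_mask <- rep.int(TRUE, n_frames(ens))
  if (length(frame_mask) != n_frames(ens))
    stop("frame_mask length != number of frames")
  if (!any(frame_mask)) stop("empty frame mask: no frames selected")
  atoms <- ens$atoms
  sel <- function(r) which(atoms$resno == r &
                             (atoms$heavy | include_hydrogens))
  xyz <- ens$xyz[frame_mask, , drop = FALSE]
  nm <- nrow(xyz)
  cut2 <- cutoff^2
  ratio <- matrix(0, length(loop_res), length(target_res),
                  dimnames = list(loop_res, target_res))
  counts <- matrix(0L, nm, length(target_res))
  for (j in seq_along(target_res)) {
    jdx <- sel(target_res[j])
    if (length(jdx) == 0L)
      stop("target residue ", target_res[j], " not found in topology")
    for (i in seq_along(loop_res)) {
      idx <- sel(loop_res[i])
      if (length(idx) == 0L)
        stop("loop residue ", loop_res[i], " not found in topology")
      hit <- .min_dist2_sets(xyz, idx, jdx) <= cut2
      ratio[i, j] <- mean(hit)
      counts[, j] <- counts[, j] + hit
    }
  }
  structure(list(ratio = ratio, loop_contacts = counts,
                 loop_res = loop_res, target_res = target_res,
                 cutoff = cutoff, n_frames = nm),
            class = "residue_contact_map")
}

#' @export
print.residue_contact_map <- function(x, ...) {
  cat("Residue-residue contact map: ", length(x$loop_res), " loop x ",
      length(x$target_res), " target residues, cutoff ", x$cutoff,
      " A, ", x$n_frames, " frames\n", sep = "")
  print(round(x$ratio, 3))
  invisible(x)
}

#' @export
plot.residue_contact_map <- function(x, ...) {
  graphics::image(seq_along(x$target_res), seq_along(x$loop_res),
                  t(x$ratio), axes = FALSE, xlab = "site residue",
                  ylab = "loop residue",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, seq_along(x$target_res), x$target_res)
  graphics::axis(2, seq_along(x$loop_res), x$loop_res, las = 1)
  graphics::box()
  invisible(x)
}

#' Per-site-residue contact ratio
#'
#' For each target (site) residue j, the fraction of the map's masked frames
#' in which at least one loop residue contacts j. A frame in which several
#' loop residues touch j counts once. With a state mask (e.g. the frames in
#' the site-B bound form) this reproduces the state-conditioned per-residue
#' contact ratios of the reference analysis.
#'
#' @param map a `residue_contact_map`.
#' @return named numeric vector, one ratio per target residue.
#' @export
per_site_residue_ratio <- function(map) {
  stopifnot(inherits(map, "residue_contact_map"))
  r <- colMeans(map$loop_contacts >= 1L)
  names(r) <- map$target_res
  r
}
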