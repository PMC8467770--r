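#' Structural ensemble container
#'
#' An `ensemble` bundles a topology (atom table) with per-frame heavy-atom
#' coordinates sampled at a fixed time interval. Coordinates follow the
#' bio3d convention: one row per frame, columns `(x1, y1, z1, x2, ...)` in
#' Angstrom. Frames from independent trajectories (replicas) are
#' concatenated, and the replica id of every frame is retained so that
#' downstream dwell extraction never joins runs across two independent
#' trajectories.
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `resno`, `resid`,
#'   `chain`, `element`, `heavy` (logical).
#' @param xyz numeric matrix, `n_frames x (3 * n_atoms)`.
#' @param frame_interval time between stored frames, ps. Must be positive.
#' @param replica integer vector of length `n_frames`; frames of one replica
#'   must be contiguous.
#' @param box_volume optional per-frame box volume, Angstrom^3 (recycled if
#'   length 1).
#' @param source character label(s) recording where the frames came from.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(atoms, xyz, frame_interval, replica = NULL,
                     box_volume = NULL, source = "in-memory") {
  xyz <- as.matrix(xyz)
  n_atoms <- nrow(atoms)
  if (ncol(xyz) != 3L * n_atoms)
    stop("coordinate matrix has ", ncol(xyz), " columns but topology has ",
         n_atoms, " atoms (expected ", 3L * n_atoms, " columns)")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("frame_interval must be a single positive number (ps)")
  n_frames <- nrow(xyz)
  if (is.null(replica)) replica <- rep.int(1L, n_frames)
  replica <- as.integer(replica)
  if (length(replica) != n_frames)
    stop("replica vector length != number of frames")
  if (any(duplicated(rle(replica)$values)))
    stop("frames of one replica must be contiguous")
  if (!is.null(box_volume)) {
    box_volume <- rep_len(as.numeric(box_volume), n_frames)
    if (any(box_volume <= 0)) stop("box_volume must be positive")
  }
  required <- c("eleno", "elety", "resno", "resid", "chain", "element", "heavy")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  structure(
    list(atoms = atoms, xyz = xyz, frame_interval = as.numeric(frame_interval),
         replica = replica, box_volume = box_volume, source = source),
    class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("Structural ensemble:", n_frames(x), "frames,", nrow(x$atoms), "atoms (",
      sum(x$atoms$heavy), "heavy ),", length(unique(x$replica)), "replica(s)\n")
  cat("  frame interval:", x$frame_interval, "ps; total time:",
      n_frames(x) * x$frame_interval / 1000, "ns\n")
  if (!is.null(x$box_volume))
    cat("  mean box volume:", format(mean(x$box_volume)), "A^3\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x an `ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(x) nrow(x$xyz)

## Derive the chemical element from a PDB atom name: strip leading digits
## and primes, then take the leading alpha run's first character. Good enough
## for protein heavy/hydrogen discrimination (no metals in scope).
.element_from_elety <- function(elety) {
  e <- toupper(sub("^[0-9']*", "", elety))
  first <- substr(e, 1L, 1L)
  ifelse(first == "H", "H", first)
}

#' Load a topology plus one or more trajectories
#'
#' Reads a PDB topology and concatenates DCD trajectory frames in input
#' order. Each trajectory file becomes one replica; replica boundaries are
#' recorded so no dwell can silently span two independent trajectories.
#' Hydrogens are flagged (not removed) so that contact analyses can restrict
#' themselves to heavy atoms.
#'
#' @param topology_path path to a PDB file.
#' @param trajectory_paths character vector of DCD file paths (XTC is not
#'   supported; convert upstream).
#' @param frame_interval time between stored frames, ps.
#' @param box_volume optional box volume override, Angstrom^3.
#' @return an [ensemble].
#' @export
load_ensemble <- function(topology_path, trajectory_paths, frame_interval,
                          box_volume = NULL) {
  if (length(trajectory_paths) == 0L)
    stop("no trajectory files given")
  bad <- grepl("\\.xtc$", trajectory_paths, ignore.case = TRUE)
  if (any(bad))
    stop("XTC trajectories are not supported; convert to DCD first: ",
         paste(trajectory_paths[bad], collapse = ", "))
  pdb <- bio3d::read.pdb(topology_path)
  at <- pdb$atom
  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety, resno = at$resno, resid = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    stringsAsFactors = FALSE)
  atoms$element <- .element_from_elety(atoms$elety)
  atoms$heavy <- atoms$element != "H"
  n_atoms <- nrow(atoms)

  xyz_list <- vector("list", length(trajectory_paths))
  replica <- integer(0)
  for (i in seq_along(trajectory_paths)) {
    tr <- bio3d::read.dcd(trajectory_paths[i], verbose = FALSE)
    tr <- unclass(tr)
    if (ncol(tr) != 3L * n_atoms)
      stop("atom-count mismatch: trajectory '", trajectory_paths[i], "' has ",
           ncol(tr) / 3, " atoms, topology has ", n_atoms)
    xyz_list[[i]] <- tr
    replica <- c(replica, rep.int(i, nrow(tr)))
  }
  ensemble(atoms, do.call(rbind, xyz_list), frame_interval, replica,
           box_volume = box_volume,
           source = c(topology = topology_path, trajectory_paths))
}

#' Write a CHARMM-format DCD trajectory
#'
#' Minimal single-precision little-endian DCD writer (no unit-cell records).
#' The output is readable by [bio3d::read.dcd] and by the usual MD analysis
#' stacks.
#'
#' @param xyz numeric matrix, `n_frames x (3 * n_atoms)` (bio3d layout).
#' @param path output file path.
#' @param frame_interval frame spacing, ps (stored in the header as the
#'   CHARMM `delta` field in AKMA-adjacent units; informational only).
#' @return `path`, invisibly.
#' @export
write_dcd <- function(xyz, path, frame_interval = 1) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3L != 0L) stop("xyz column count must be a multiple of 3")
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) %/% 3L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  ## header record: "CORD" + 20-int control block; slot 10 holds the time
  ## step as a float, slot 20 a nonzero CHARMM version so readers take the
  ## CHARMM branch.
  wi(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  wi(c(n_frames, 1L, 1L, n_frames, 0L, 0L, 0L, 0L, 0L))
  wf(frame_interval)
  wi(c(0L, rep.int(0L, 8L), 24L))
  wi(84L)
  ## title record
  title <- formatC("Synthetic trajectory written by loopkin", width = -80L)
  wi(80L + 4L)
  wi(1L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  wi(80L + 4L)
  ## atom-count record
  wi(4L); wi(n_atoms); wi(4L)
  ## per-frame x, y, z records
  xi <- seq.int(1L, by = 3L, length.out = n_atoms)
  for (f in seq_len(n_frames)) {
    fr <- xyz[f, ]
    for (off in 0:2) {
      wi(4L * n_atoms); wf(fr[xi + off]); wi(4L * n_atoms)
    }
  }
  invisible(path)
}
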