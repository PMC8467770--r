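## Shared fixtures and independent brute-force oracles. The oracles work on
## plain 3-column coordinate matrices with explicit double/triple loops so
## they stay independent of the package's vectorised implementations.

## Minimal in-memory ensemble: one single-atom residue per entry of `resno`,
## coordinates given per frame as a list of n_atoms x 3 matrices.
make_point_ensemble <- function(resno, frames, frame_interval = 200,
                                replica = NULL, box_volume = NULL,
                                elety = "CA") {
  atoms <- data.frame(
    eleno = seq_along(resno), elety = elety, resno = as.integer(resno),
    resid = "ALA", chain = "A", element = .elem_of(elety),
    heavy = .elem_of(elety) != "H", stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  ensemble(atoms, xyz, frame_interval, replica = replica,
           box_volume = box_volume)
}

.elem_of <- function(elety) {
  e <- toupper(sub("^[0-9']*", "", elety))
  ifelse(substr(e, 1, 1) == "H", "H", substr(e, 1, 1))
}

## Random-coordinate fixture: n_res single-atom residues, n_frames frames.
random_point_ensemble <- function(n_res, n_frames, seed, spread = 12) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f)
    matrix(stats::runif(n_res * 3, -spread, spread), ncol = 3))
  make_point_ensemble(seq_len(n_res), frames)
}

## Frame f of an ensemble as an n_atoms x 3 matrix.
frame_coords <- function(ens, f) matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)

## Oracle 1: naive loop-center contact profile. Double loop over frames and
## target residues; geometric centers by explicit colMeans.
naive_profile <- function(ens, loop_ids, cutoffs, exclude = loop_ids) {
  targets <- sort(setdiff(unique(ens$atoms$resno[ens$atoms$heavy]), exclude))
  counts <- matrix(0, length(targets), length(cutoffs))
  for (f in seq_len(n_frames(ens))) {
    m <- frame_coords(ens, f)
    lsel <- ens$atoms$resno %in% loop_ids & ens$atoms$heavy
    ctr <- colMeans(m[lsel, , drop = FALSE])
    for (i in seq_along(targets)) {
      rsel <- ens$atoms$resno == targets[i] & ens$atoms$heavy
      rc <- colMeans(m[rsel, , drop = FALSE])
      d <- sqrt(sum((ctr - rc)^2))
      for (k in seq_along(cutoffs))
        if (d <= cutoffs[k]) counts[i, k] <- counts[i, k] + 1
    }
  }
  list(resno = targets, ratio = counts / n_frames(ens))
}

## Oracle 2: naive residue-residue contact map (min over all atom pairs).
naive_map <- function(ens, loop_ids, target_ids, cutoff,
                      mask = rep(TRUE, n_frames(ens))) {
  out <- matrix(0, length(loop_ids), length(target_ids))
  nmask <- sum(mask)
  for (f in which(mask)) {
    m <- frame_coords(ens, f)
    for (i in seq_along(loop_ids)) {
      ai <- which(ens$atoms$resno == loop_ids[i] & ens$atoms$heavy)
      for (j in seq_along(target_ids)) {
        aj <- which(ens$atoms$resno == target_ids[j] & ens$atoms$heavy)
        dmin <- Inf
        for (a in ai) for (b in aj)
          dmin <- min(dmin, sqrt(sum((m[a, ] - m[b, ])^2)))
        if (dmin <= cutoff) out[i, j] <- out[i, j] + 1
      }
    }
  }
  out / nmask
}

## Small default CTMC for state-level tests (fast, many events).
test_ctmc <- function(seed = 42, n_frames = 500L, n_replicas = 2L) {
  ctmc_params(k_on_A = 5e8, k_on_B = 5e8, k_off_A = 5e8, k_off_B = 1e9,
              frame_interval = 200, n_frames = n_frames,
              n_replicas = n_replicas, seed = seed)
}

## Hand-buildable dwell table.
make_dwells <- function(states, durations, replica = 1L,
                        censored = FALSE, dt = 200) {
  n <- length(states)
  structure(data.frame(state = states, replica = rep_len(replica, n),
                       start = NA_integer_, end = NA_integer_,
                       duration = durations,
                       censored = rep_len(censored, n),
                       stringsAsFactors = FALSE),
            frame_interval = dt, class = c("dwell_table", "data.frame"))
}
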