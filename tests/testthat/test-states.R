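## Coordinate builder for classification tests: a fixed scaffold with two
## 3-residue pockets and a 4-residue loop whose residues can be placed "in"
## either pocket (within 4.5 A) or far away.
pocket_frame <- function(nA, nB) {
  pocketA <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))        # res 11-13
  pocketB <- rbind(c(0, 40, 0), c(3, 40, 0), c(6, 40, 0))     # res 21-23
  loop <- matrix(NA_real_, 4, 3)                              # res 1-4
  for (i in 1:4) {
    loop[i, ] <- if (i <= nA) pocketA[min(i, 3), ] + c(0, 2, 0)
    else if (i <= nA + nB) pocketB[min(i - nA, 3), ] + c(0, -2, 0)
    else c(50, -50, 50) + 5 * i
  }
  rbind(loop, pocketA, pocketB)
}

pocket_ensemble <- function(frames, replica = NULL) {
  make_point_ensemble(c(1:4, 11:13, 21:23), frames, replica = replica)
}

pocket_regions <- function(ens)
  resolve_regions(ens, loop = 1:4, siteA = 11:13, siteB = 21:23)

test_that("three-state rule: >=3 contacting loop residues bind a site", {
  ens <- pocket_ensemble(list(pocket_frame(3, 0),   # 3 in A -> SITE_A
                              pocket_frame(2, 2),   # 2 and 2 -> OPEN
                              pocket_frame(0, 3),   # 3 in B -> SITE_B
                              pocket_frame(0, 0),   # none -> OPEN
                              pocket_frame(4, 0)))  # 4 in A -> SITE_A
  st <- classify_frames(ens, pocket_regions(ens), keep_counts = TRUE)
  expect_equal(as.character(st$labels),
               c("SITE_A", "OPEN", "SITE_B", "OPEN", "SITE_A"))
  expect_equal(st$counts$siteA, c(3L, 2L, 0L, 0L, 4L))
  expect_equal(st$counts$siteB, c(0L, 2L, 3L, 0L, 0L))
})

test_that("dual-qualifying frames resolve by larger count, ties by hysteresis", {
  ## both sites engaged: construct a 6-residue loop so counts (4, 3) and
  ## (3, 3) are possible simultaneously
  frame_dual <- function(nA, nB) {
    pocketA <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
    pocketB <- rbind(c(0, 40, 0), c(3, 40, 0), c(6, 40, 0))
    loop <- matrix(NA_real_, 7, 3)
    for (i in 1:7) {
      loop[i, ] <- if (i <= nA) pocketA[min(i, 3), ] + c(0, 2, 0)
      else if (i <= nA + nB) pocketB[min(i - nA, 3), ] + c(0, -2, 0)
      else c(80, -80, 80) + 5 * i
    }
    rbind(loop, pocketA, pocketB)
  }
  ens <- make_point_ensemble(c(1:7, 11:13, 21:23),
                             list(frame_dual(4, 3),    # larger count: A
                                  frame_dual(3, 4),    # larger count: B
                                  frame_dual(3, 3),    # tie -> previous (B)
                                  frame_dual(0, 0),    # OPEN
                                  frame_dual(3, 3)))   # tie, prev OPEN
  reg <- resolve_regions(ens, loop = 1:7, siteA = 11:13, siteB = 21:23)
  st <- classify_frames(ens, reg)
  expect_equal(as.character(st$labels),
               c("SITE_A", "SITE_B", "SITE_B", "OPEN", "OPEN"))
})

test_that("tie at a replica start cannot inherit across the boundary", {
  f_tie <- pocket_frame(2, 2)  # not a tie above threshold; build explicit
  frame_dual <- function() {
    pocketA <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
    pocketB <- rbind(c(0, 40, 0), c(3, 40, 0), c(6, 40, 0))
    loop <- rbind(pocketA + rep(c(0, 2, 0), each = 3),
                  pocketB - rep(c(0, 2, 0), each = 3))
    rbind(loop, pocketA, pocketB)
  }
  ens <- make_point_ensemble(c(1:6, 11:13, 21:23),
                             list(frame_dual(), frame_dual()),
                             replica = c(1L, 2L))
  reg <- resolve_regions(ens, loop = 1:6, siteA = 11:13, siteB = 21:23)
  st <- classify_frames(ens, reg)
  ## both frames are 3-3 ties at the start of their replica -> OPEN
  expect_equal(as.character(st$labels), c("OPEN", "OPEN"))
})

test_that("dwell extraction: hand-enumerated runs, censoring, boundaries", {
  st <- state_sequence(c("OPEN", "SITE_A", "SITE_A", "OPEN", "SITE_A",
                         "OPEN"), frame_interval = 200)
  d <- extract_dwells(st)
  a <- d[d$state == "SITE_A", ]
  expect_equal(nrow(a), 2L)
  expect_equal(a$duration, c(400, 200))
  expect_false(any(a$censored))
  ## flanking OPEN runs touch the sequence ends -> censored
  o <- d[d$state == "OPEN", ]
  expect_equal(o$censored, c(TRUE, FALSE, TRUE))

  ## all OPEN -> no bound events
  d0 <- extract_dwells(state_sequence(rep("OPEN", 5), 200))
  expect_equal(sum(d0$state != "OPEN"), 0L)

  ## a run crossing a replica boundary splits into two censored events
  st2 <- state_sequence(c("OPEN", "SITE_B", "SITE_B", "SITE_B", "SITE_B",
                          "OPEN"), 200, replica = rep(1:2, each = 3))
  d2 <- extract_dwells(st2)
  b <- d2[d2$state == "SITE_B", ]
  expect_equal(nrow(b), 2L)
  expect_equal(b$replica, 1:2)
  expect_true(all(b$censored))
  expect_equal(b$duration, c(400, 400))
})

test_that("dwell tables reconstruct the label sequence and conserve time", {
  sim <- simulate_ctmc(test_ctmc(seed = 13))
  st <- sim$states
  d <- extract_dwells(st)
  ## reconstruction: events + gaps reproduce the labels exactly
  rebuilt <- character(length(st$labels))
  for (i in seq_len(nrow(d)))
    rebuilt[d$start[i]:d$end[i]] <- d$state[i]
  expect_identical(rebuilt, as.character(st$labels))
  ## per replica, total event time = frames x dt
  for (r in unique(st$replica))
    expect_equal(sum(d$duration[d$replica == r]),
                 sum(st$replica == r) * st$frame_interval)
})

test_that("raising the contact-residue threshold never adds bound time", {
  spec <- toy_system_spec(test_ctmc(seed = 77, n_frames = 300L,
                                    n_replicas = 2L))
  syn <- synthesize_ensemble(spec)
  reg <- resolve_regions(syn$ensemble, syn$regions$loop, syn$regions$siteA,
                         syn$regions$siteB)
  bound_time <- sapply(1:5, function(thr) {
    st <- classify_frames(syn$ensemble, reg,
                          analysis_config(min_contact_residues = thr))
    sum(total_bound_time(extract_dwells(st)))
  })
  expect_true(all(diff(bound_time) <= 0))
})

test_that("unbound intervals: per-site waiting times and censoring", {
  ## replica: O O A O B A  (dt = 100 ps)
  st <- state_sequence(c("OPEN", "OPEN", "SITE_A", "OPEN", "SITE_B",
                         "SITE_A"), 100)
  d <- extract_dwells(st)
  ## site A: leading 200 ps wait, then O+B = 200 ps wait
  expect_equal(unbound_intervals(d, "SITE_A"), c(200, 200))
  ## open-only scope drops the time spent bound to B
  expect_equal(unbound_intervals(d, "SITE_A", scope = "open_only"),
               c(200, 100))
  ## site B: one wait (O O A O = 400 ps); trailing A not counted
  expect_equal(unbound_intervals(d, "SITE_B"), 400)
  ## no event ever -> no waits
  expect_length(unbound_intervals(extract_dwells(
    state_sequence(rep("OPEN", 4), 100)), "SITE_B"), 0L)
})
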