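test_that("k_off equals the reciprocal mean survival time exactly", {
  d <- make_dwells(rep("SITE_A", 3), c(400, 800, 1200))
  est <- estimate_koff(d, "SITE_A", n_boot = 100)
  expect_identical(est$value, 1e12 / 800)   # 1.25e9 1/s, machine precision
  expect_identical(est$units, "1/s")
  expect_identical(est$n_events, 3L)

  ## single event of duration t -> k_off = 1/t
  d1 <- make_dwells("SITE_B", 500)
  expect_warning(e1 <- estimate_koff(d1, "SITE_B", n_boot = 100), "single")
  expect_identical(e1$value, 1e12 / 500)

  ## no events for a site is an explicit error, never k_off = 0
  expect_error(estimate_koff(d, "SITE_B"), "no SITE_B")
})

test_that("censored dwells can be excluded from the survival mean", {
  d <- make_dwells(rep("SITE_A", 3), c(400, 800, 1200),
                   censored = c(TRUE, FALSE, FALSE))
  incl <- estimate_koff(d, "SITE_A", n_boot = 100)
  excl <- estimate_koff(d, "SITE_A", include_censored = FALSE,
                        n_boot = 100)
  expect_identical(incl$value, 1e12 / 800)
  expect_identical(excl$value, 1e12 / 1000)
  expect_identical(excl$n_events, 2L)
})

test_that("k_on dimensional arithmetic and linearity in v_eff", {
  ## t_on = 100 ns, v_eff = 6e-22 L -> k_on = N_Av * v_eff / t_on
  st <- state_sequence(c(rep("OPEN", 500), "SITE_A"), frame_interval = 200)
  d <- extract_dwells(st)
  expect_equal(unbound_intervals(d, "SITE_A"), 1e5)  # 100 ns in ps
  expect_warning(est <- estimate_kon(d, "SITE_A", volume = 6.0e-22,
                                     n_boot = 100), "single")
  expect_equal(est$value, 6.02214076e23 * 6.0e-22 / 1e-7)
  expect_identical(est$units, "1/(M s)")
  ## doubling v_eff doubles k_on at fixed t_on
  expect_warning(est2 <- estimate_kon(d, "SITE_A", volume = 1.2e-21,
                                      n_boot = 100), "single")
  expect_equal(est2$value, 2 * est$value)
  ## pseudo-first-order sanity: k_on * C_eff = 1 / t_on
  expect_equal(est$value * est$c_eff_M, 1e7)
  ## errors
  expect_error(estimate_kon(d, "SITE_B", volume = 6e-22), "no SITE_B")
  expect_error(estimate_kon(d, "SITE_A", volume = -1), "positive")
})

test_that("bootstrap CI: degeneracy, determinism, and bracket invariant", {
  ## identical durations -> zero-width CI at 2e9 1/s
  d <- make_dwells(rep("SITE_A", 3), c(500, 500, 500))
  est <- estimate_koff(d, "SITE_A", n_boot = 200, seed = 4)
  expect_identical(c(est$ci_low, est$ci_high), c(2e9, 2e9))

  ## fixed seed -> bit-identical CI on rerun
  x <- rexp(50, 1 / 800)
  ci_a <- bootstrap_ci(x, mean, n_boot = 500, seed = 11)
  ci_b <- bootstrap_ci(x, mean, n_boot = 500, seed = 11)
  expect_identical(ci_a, ci_b)
  expect_false(identical(ci_a, bootstrap_ci(x, mean, n_boot = 500,
                                            seed = 12)))
  expect_true(ci_a[1] <= mean(x) && mean(x) <= ci_a[2])

  ## < 2 events: CI undefined and flagged
  expect_warning(ci1 <- bootstrap_ci(1, mean, n_boot = 100), "fewer than 2")
  expect_true(all(is.na(ci1)))

  ## generic statistic path agrees with the fast mean path
  ci_gen <- bootstrap_ci(x, function(v) mean(v), n_boot = 500, seed = 11)
  expect_equal(ci_gen, ci_a)
})

test_that("point estimate lies inside its own bootstrap CI on CTMC data", {
  sim <- simulate_ctmc(test_ctmc(seed = 21, n_frames = 1500L))
  d <- extract_dwells(sim$states)
  for (site in c("SITE_A", "SITE_B")) {
    est <- estimate_koff(d, site, n_boot = 500, seed = 2)
    expect_true(est$ci_low <= est$value && est$value <= est$ci_high)
    expect_gt(est$value, 0)
  }
})

test_that("voxelised volume matches the closed-form sphere and refines", {
  ## single carbon sphere (vdW radius 1.7 A) in a 1000 A^3 box vs the
  ## closed form (4/3) pi r^3, at a grid fine against the radius
  atoms <- data.frame(eleno = 1L, elety = "X", resno = 1L, resid = "SPH",
                      chain = "A", element = "C", heavy = TRUE)
  ens <- ensemble(atoms, matrix(c(0.13, 0.07, -0.11), 1), 200,
                  box_volume = 1000)
  vm <- compute_effective_volume(ens, spacing = 0.25)
  v_true <- 4 / 3 * pi * 1.7^3
  expect_lt(abs(vm$protein_volume_A3 - v_true) / v_true, 0.02)
  expect_equal(vm$box_volume_A3 - vm$protein_volume_A3, vm$v_eff_A3)
  expect_equal(vm$v_eff_L, vm$v_eff_A3 * 1e-27)

  ## grid refinement on the toy scaffold: halving the default 0.5 A
  ## spacing moves the estimate by < 2%
  spec <- toy_system_spec(test_ctmc(seed = 3, n_frames = 20L,
                                    n_replicas = 1L))
  toy <- synthesize_ensemble(spec)$ensemble
  v1 <- compute_effective_volume(toy, spacing = 0.5,
                                 max_frames = 5)$protein_volume_A3
  v2 <- compute_effective_volume(toy, spacing = 0.25,
                                 max_frames = 5)$protein_volume_A3
  expect_lt(abs(v1 - v2) / v2, 0.02)

  ## overlapping spheres: union, not sum
  atoms2 <- rbind(atoms, transform(atoms, eleno = 2L))
  ens2 <- ensemble(atoms2, matrix(c(0, 0, 0, 0.5, 0, 0), 1), 200,
                   box_volume = 1000)
  v_two <- compute_effective_volume(ens2, spacing = 0.25)$protein_volume_A3
  expect_lt(v_two, 2 * v_true)
  expect_gt(v_two, v_true)

  ## missing box volume without override is an error
  ens_nb <- ensemble(atoms, matrix(c(0, 0, 0), 1), 200)
  expect_error(compute_effective_volume(ens_nb), "box volume")
})

test_that("loop_kinetics fit object: methods and invariants", {
  sim <- simulate_ctmc(test_ctmc(seed = 31, n_frames = 1500L))
  cfg <- analysis_config(bootstrap_replicates = 500, seed = 8)
  fit <- loop_kinetics(sim$states, config = cfg, volume = 5e-22)
  expect_s3_class(fit, "loop_kinetics")
  cf <- coef(fit)
  expect_setequal(names(cf), c("k_off.SITE_A", "k_off.SITE_B",
                               "k_on.SITE_A", "k_on.SITE_B"))
  expect_true(all(cf > 0))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= cf[rownames(ci)] &
                    cf[rownames(ci)] <= ci[, 2]))
  ## deterministic refit
  fit2 <- loop_kinetics(sim$states, config = cfg, volume = 5e-22)
  expect_identical(coef(fit2), cf)
  expect_output(print(fit), "k_off")
  s <- summary(fit)
  expect_output(print(s), "Dwell-time summary")
  r <- residuals(fit)
  expect_equal(as.numeric(tapply(r$residual, r$state, mean)), c(0, 0),
               tolerance = 1e-12)
  ## simulate() round-trip produces a valid sequence at the same dt
  ss <- simulate(fit, nsim = 2, seed = 3, n_frames = 200)
  expect_s3_class(ss, "state_sequence")
  expect_equal(length(ss$labels), 400L)
  expect_equal(ss$frame_interval, 200)
})

test_that("discretisation bias stays below 5% at dt <= dwell_mean / 20", {
  ## both sites unbind at 1e9 1/s (1 ns mean dwell = 20 frames at 50 ps);
  ## pooling the two equal-rate sites sharpens the bias estimate
  p_fine <- ctmc_params(2.5e8, 2.5e8, 1e9, 1e9, frame_interval = 50,
                        n_frames = 100000L, n_replicas = 3L, seed = 99)
  d <- extract_dwells(simulate_ctmc(p_fine)$states)
  durs <- d$duration[d$state %in% c("SITE_A", "SITE_B")]
  expect_gt(length(durs), 2000)
  koff_hat <- 1e12 / mean(durs)
  expect_lt(abs(koff_hat - 1e9) / 1e9, 0.05)

  ## the same physics sampled at dt = dwell_mean is strongly biased:
  ## sub-frame events vanish and unsampled open gaps merge dwells
  p_coarse <- ctmc_params(2.5e8, 2.5e8, 1e9, 1e9, frame_interval = 1000,
                          n_frames = 5000L, n_replicas = 3L, seed = 99)
  dc <- extract_dwells(simulate_ctmc(p_coarse)$states)
  durs_c <- dc$duration[dc$state %in% c("SITE_A", "SITE_B")]
  koff_coarse <- 1e12 / mean(durs_c)
  expect_gt(abs(koff_coarse - 1e9) / 1e9, 0.2)
})
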