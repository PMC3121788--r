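test_that("ensemble builder hits the embedded-fraction target reproducibly", {
  m <- build_nucleoid_ensemble(1000, mean_kbp = 42, cv = 0.1,
                               embedded_target = 0.02, seed = 11)
  ef <- embedded_fraction(m)
  expect_gte(ef, 0.018)
  expect_lte(ef, 0.022)
  expect_equal(mean(m$loops$total_bp) / 1000, 42, tolerance = 0.02)
  # footprints split equally between anchors
  expect_equal(m$loops$mar_left_bp, m$loops$mar_right_bp)
  # zero target
  m0 <- build_nucleoid_ensemble(50, embedded_target = 0, seed = 2)
  expect_equal(embedded_fraction(m0), 0)
  expect_true(all(m0$loops$mar_left_bp == 0))
  # determinism: same seed, identical loop tables
  expect_identical(build_nucleoid_ensemble(200, seed = 5)$loops,
                   build_nucleoid_ensemble(200, seed = 5)$loops)
  expect_false(identical(build_nucleoid_ensemble(200, seed = 5)$loops,
                         build_nucleoid_ensemble(200, seed = 6)$loops))
})

test_that("invalid generator parameters are rejected", {
  expect_error(build_nucleoid_ensemble(10, embedded_target = 1), "embedded_target")
  expect_error(build_nucleoid_ensemble(10, embedded_target = 0.7), "embedded_target")
  expect_error(build_nucleoid_ensemble(10, mean_kbp = -1), "mean_kbp")
  expect_error(accessibility_profile(k0 = -1), "k0")
  expect_error(accessibility_profile(alpha = -0.5), "alpha")
})

test_that("analytic attached fraction matches the uniform-hazard closed form", {
  prof <- accessibility_profile(k0 = 2e-5, alpha = 0)
  lp <- list(total_bp = 20000, mar_left_bp = 0, mar_right_bp = 0)
  for (t in c(1, 5, 20, 60)) {
    kL <- 2e-5 * 20000 * t
    closed <- (2 / kL) * (1 - exp(-kL)) - exp(-kL)
    expect_equal(analytic_attached_fraction(lp, prof, t), closed, tolerance = 1e-6)
  }
  expect_equal(analytic_attached_fraction(lp, prof, 0), 1)
  expect_error(analytic_attached_fraction(lp, prof, -1), ">= 0")
})

test_that("simulated digestion matches brute-force enumeration at unit hazard mass", {
  # independent oracle for a uniform-hazard loop discretized into 10
  # segments: enumerate which segments contain cuts (each independently
  # with probability 1 - exp(-Lambda/10)); within a cut segment the cut
  # positions are iid uniform with Poisson-conditional count, so the
  # expected extreme positions are exact:
  #   E[min | >=1 cut] = a + w * c,  E[max | >=1 cut] = a + w * (1 - c),
  #   c = E[1/(N+1) | N >= 1],  N ~ Poisson(Lambda/10)
  lambda <- 1
  mu <- lambda / 10
  p_seg <- 1 - exp(-mu)
  cc <- ((1 - exp(-mu)) / mu - exp(-mu)) / (1 - exp(-mu))
  a <- (0:9) / 10; w <- 0.1
  ev <- 0
  for (mask in 0:1023) {
    bits <- as.integer(intToBits(mask)[1:10])
    pr <- prod(ifelse(bits == 1, p_seg, 1 - p_seg))
    cut <- which(bits == 1)
    att <- if (length(cut) == 0) 1
    else if (length(cut) == 1) 1 - w * (1 - 2 * cc)
    else (a[cut[1]] + w * cc) + 1 - (a[cut[length(cut)]] + w * (1 - cc))
    ev <- ev + pr * att
  }
  # the segment decomposition is exact for a uniform hazard: the
  # enumeration must agree with the closed form
  closed <- (2 / lambda) * (1 - exp(-lambda)) - exp(-lambda)
  expect_equal(ev, closed, tolerance = 1e-12)
  m <- single_loop_model(total_bp = 1000, mar_bp = 0, k0 = 1e-3, alpha = 0)
  cfg <- simulation_config(timepoints_min = c(0, 1), n_nucleoids = 500,
                           n_replicates = 20, seed = 31)
  sim <- simulate_digestion(m, cfg)
  mc <- sim$replicate_pct["t1", ] / 100
  se <- stats::sd(mc) / sqrt(length(mc))
  expect_lte(abs(mean(mc) - ev), 3 * se)
})

test_that("Monte-Carlo digestion agrees with the analytic oracle over a grid", {
  for (k0 in c(3e-5, 1e-4)) {
    for (alpha in c(0, 2)) {
      m <- single_loop_model(k0 = k0, alpha = alpha, seed = 3)
      cfg <- simulation_config(n_nucleoids = 500, n_replicates = 8, seed = 13)
      sim <- simulate_digestion(m, cfg)
      ana <- analytic_attached_fraction(m$loops[1, ], m$profile, cfg$timepoints_min)
      for (j in seq_along(cfg$timepoints_min)[-1]) {
        reps <- sim$replicate_pct[j, ] / 100
        se <- stats::sd(reps) / sqrt(length(reps))
        expect_lte(abs(mean(reps) - ana[j]), 3 * se + 1e-12)
      }
    }
  }
})

test_that("digestion respects trivial limits", {
  m <- single_loop_model(k0 = 0)
  cfg <- simulation_config(n_nucleoids = 50, n_replicates = 2, seed = 1)
  sim <- simulate_digestion(m, cfg)
  expect_true(all(sim$timecourse$pct_attached == 100))
  m2 <- single_loop_model()
  sim2 <- simulate_digestion(m2, cfg)
  expect_equal(sim2$timecourse$pct_attached[1], 100)
  expect_error(simulation_config(timepoints_min = c(0, 5, -3)), "increasing")
  empty <- single_loop_model()
  empty$loops <- empty$loops[0, ]
  expect_error(simulate_digestion(empty, cfg), "no loops")
})

test_that("every simulated course is non-increasing with the embedded floor", {
  set.seed(99)
  for (i in 1:20) {
    emb <- runif(1, 0, 0.1)
    m <- build_nucleoid_ensemble(3, mean_kbp = runif(1, 5, 60), cv = 0.1,
                                 embedded_target = emb,
                                 profile = accessibility_profile(10^runif(1, -5.5, -3.5),
                                                                 runif(1, 0, 3)),
                                 seed = i)
    cfg <- simulation_config(n_nucleoids = 30, n_replicates = 2, seed = i)
    sim <- simulate_digestion(m, cfg)
    for (r in seq_len(ncol(sim$replicate_pct))) {
      course <- sim$replicate_pct[, r]
      expect_true(all(diff(course) <= 1e-9))
      expect_true(all(course >= 100 * embedded_fraction(m) - 1e-9))
    }
  }
})

test_that("survival decreases with arc distance from the NM (gradient ordering)", {
  m <- single_loop_model()
  d <- c(0.05, 0.15, 0.25, 0.35, 0.45)
  amps <- amplicon_table(paste0("a", seq_along(d)), rep("L1", length(d)),
                         start_bp = round(d * 42000) - 100, length_bp = 200,
                         model = m)
  p <- analytic_amplicon_survival(m, amps, c(5, 15, 30, 60))
  for (j in seq_len(ncol(p))) expect_true(all(diff(p[, j]) <= 1e-12))
  # empirically, from the simulated detection fractions
  cfg <- simulation_config(n_nucleoids = 5000, n_replicates = 1, seed = 8)
  sc <- simulate_amplicon_detection(m, amps, cfg)
  fr <- attr(sc, "fractions")[, "t5", 1]
  expect_true(all(diff(fr) <= 0.02))  # Monte-Carlo jitter allowance
})

test_that("amplicon detection honours hazard-free footprints and thresholds", {
  m <- single_loop_model(mar_bp = 500, k0 = 3e-4)
  cfg <- simulation_config(n_nucleoids = 2000, n_replicates = 3, seed = 21)
  inside <- amplicon_table("mar_amp", "L1", start_bp = 50, length_bp = 254, model = m)
  sc <- simulate_amplicon_detection(m, inside, cfg)
  expect_true(all(sc$detected))
  # k0 = 0: everything detected everywhere
  m0 <- single_loop_model(k0 = 0)
  apex0 <- amplicon_table("apex", "L1", start_bp = 20900, length_bp = 200, model = m0)
  expect_true(all(simulate_amplicon_detection(m0, apex0, cfg)$detected))
  # apex amplicon under strong digestion: analytic survival far below
  # threshold at 15 min implies negatives at 15, 30 and 60 min
  apex <- amplicon_table("apex", "L1", start_bp = 20900, length_bp = 200, model = m)
  p15 <- analytic_amplicon_survival(m, apex, 15)[1, 1]
  expect_lt(p15, cfg$detection_threshold / 10)
  sc2 <- simulate_amplicon_detection(m, apex, cfg)
  late <- sc2[sc2$timepoint_min >= 15, ]
  expect_true(all(!late$detected))
  # dangling loop id
  bad <- amplicon_table("x", "nope", 0, 100)
  expect_error(simulate_amplicon_detection(m, bad, cfg), "not in model")
})

test_that("identical seeds give identical simulations", {
  m <- single_loop_model()
  cfg <- simulation_config(n_nucleoids = 200, n_replicates = 2, seed = 77)
  s1 <- simulate_digestion(m, cfg)
  s2 <- simulate_digestion(m, cfg)
  expect_identical(s1$replicate_pct, s2$replicate_pct)
  amps <- amplicon_table("a", "L1", 10000, 254, model = m)
  expect_identical(simulate_amplicon_detection(m, amps, cfg),
                   simulate_amplicon_detection(m, amps, cfg))
})

test_that("cut records summarize the realized cut process", {
  m <- single_loop_model(seed = 4)
  cfg <- simulation_config(timepoints_min = c(0, 5, 15), n_nucleoids = 20,
                           n_replicates = 2, seed = 4)
  sim <- simulate_digestion(m, cfg, keep_cut_records = TRUE)
  rec <- sim$cut_records
  expect_equal(nrow(rec), 2 * 2 * 20)  # replicates x windows x nucleoids
  with_cuts <- rec[rec$n_cuts > 0, ]
  expect_true(all(with_cuts$min_pos <= with_cuts$max_pos))
  fl <- m$loops$mar_left_bp / m$loops$total_bp
  expect_true(all(with_cuts$min_pos >= fl))
  expect_true(all(with_cuts$max_pos <= 1 - fl))
})
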