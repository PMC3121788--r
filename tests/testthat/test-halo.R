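test_that("halo radius converts to loop size by hand arithmetic", {
  expect_equal(loop_size_from_halo(0), 0)
  expect_equal(round(loop_size_from_halo(7.141), 1), 42.0)
  expect_equal(round(loop_size_from_halo(6.122), 1), 36.0)
  expect_error(loop_size_from_halo(-1), ">= 0")
})

test_that("halo conversion is linear and strictly monotone", {
  r <- seq(0.5, 12, by = 0.5)
  kbp <- loop_size_from_halo(r)
  expect_true(all(diff(kbp) > 0))
  expect_equal(loop_size_from_halo(2 * r), 2 * kbp)
  expect_equal(loop_size_from_halo(r[1] + r[2]), kbp[1] + kbp[2])
})

test_that("noise-free halo simulation inverts the conversion exactly", {
  m <- build_nucleoid_ensemble(300, mean_kbp = 42, embedded_target = 0, seed = 6)
  h <- simulate_halo_radii(m, n = 50, noise_cv = 0, seed = 1)
  expect_equal(stats::sd(h$halo_radius_um), 0)
  expect_equal(loop_size_from_halo(h$halo_radius_um[1]),
               mean(m$loops$free_bp) / 1000)
  # configured 42 kbp free DNA gives R = 7.14 um at zero noise
  flat <- single_loop_model(total_bp = 42000, mar_bp = 0)
  h42 <- simulate_halo_radii(flat, n = 5, noise_cv = 0, seed = 1)
  expect_equal(round(h42$halo_radius_um[1], 2), 7.14)
  expect_error(simulate_halo_radii(m, n = 0), "n must be >= 1")
  expect_error(simulate_halo_radii(m, n = 10, noise_cv = -0.1), "noise_cv")
})

test_that("noisy halo round trip recovers the mean within the delta-method bound", {
  m <- build_nucleoid_ensemble(300, mean_kbp = 42, embedded_target = 0, seed = 6)
  cv <- 0.08; n <- 200
  h <- simulate_halo_radii(m, n = n, noise_cv = cv, seed = 42)
  est <- loop_size_estimate(h)
  truth <- mean(m$loops$free_bp) / 1000
  expect_lt(abs(est$mean_kbp - truth) / truth, 2 * cv / sqrt(n))
  expect_equal(est$n, n)
})

test_that("measurement summaries match a two-pass brute-force computation", {
  same <- halo_measurements("x", rep(9, 5), rep(10, 5), rep(7, 5))
  s <- summarize_measurements(same)
  expect_true(all(s$sd == 0))
  tri <- halo_measurements("x", c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(summarize_measurements(tri)$mean, rep(2, 3))
  expect_equal(summarize_measurements(tri)$sd, rep(1, 3))
  set.seed(12)
  x <- halo_measurements("r", runif(100, 5, 15), runif(100, 5, 15), runif(100, 2, 9))
  s2 <- summarize_measurements(x)
  for (j in 1:3) {
    v <- x[[j]]
    mu <- sum(v) / length(v)
    expect_equal(s2$mean[j], mu)
    expect_equal(s2$sd[j], sqrt(sum((v - mu)^2) / (length(v) - 1)))
  }
  expect_error(summarize_measurements(halo_measurements("x", 1, 1, 1)), "n >= 2")
  expect_error(halo_measurements("x", -1, 1, 1), "> 0")
})

test_that("Student's t-test matches the hand-worked pooled formula", {
  a <- c(5.1, 4.9, 5.6, 4.7, 5.2)
  b <- c(4.2, 4.5, 3.9, 4.8, 4.1)
  res <- students_t_test(a, b)
  # frozen from the manual pooled-variance computation
  expect_equal(round(res$t_statistic, 4), 3.6515)
  expect_equal(round(res$p_value, 4), 0.0065)
  expect_equal(res$degrees_of_freedom, 8)
  expect_true(res$significant)  # alpha = 0.01
  # symmetry and identity
  swapped <- students_t_test(b, a)
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(swapped$t_statistic, -res$t_statistic)
  idn <- students_t_test(a, a)
  expect_equal(idn$t_statistic, 0)
  expect_equal(idn$p_value, 1)
  expect_false(idn$significant)
  # degenerate zero-variance samples
  z <- students_t_test(rep(2, 3), rep(2, 4))
  expect_equal(z$t_statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(students_t_test(1, c(1, 2)), "n >= 2")
})

test_that("significance flips exactly at p < alpha", {
  a <- c(5.1, 4.9, 5.6, 4.7, 5.2)
  b <- c(4.2, 4.5, 3.9, 4.8, 4.1)
  p <- students_t_test(a, b)$p_value
  expect_true(students_t_test(a, b, alpha = p * 1.0001)$significant)
  expect_false(students_t_test(a, b, alpha = p)$significant)
  expect_false(students_t_test(a, b, alpha = p * 0.9999)$significant)
})

test_that("Welch variant is available and differs under unequal variances", {
  set.seed(3)
  a <- rnorm(20, 0, 1); b <- rnorm(8, 1, 4)
  pooled <- students_t_test(a, b, variant = "pooled")
  welch <- students_t_test(a, b, variant = "welch")
  expect_false(isTRUE(all.equal(pooled$degrees_of_freedom,
                                welch$degrees_of_freedom)))
})

test_that("NM resilience reflects the NM/nucleus diameter ratio", {
  s <- halo_measurements("x", rep(10, 4), rep(11, 4), rep(7, 4))
  r <- nm_resilience(s)
  expect_equal(r$ratio, 1.1)
  expect_true(r$resilient)
  eq <- halo_measurements("x", rep(10, 4), rep(10, 4), rep(7, 4))
  expect_false(nm_resilience(eq)$resilient)
  expect_equal(nm_resilience(eq)$ratio, 1)
  # synthetic set with configured NM > nucleus
  m <- build_nucleoid_ensemble(100, seed = 8)
  h <- simulate_halo_radii(m, 50, noise_cv = 0.03, seed = 9,
                           nucleus_mean_um = 10, nm_mean_um = 11)
  expect_true(nm_resilience(h)$resilient)
})

test_that("group mean ordering of radii is preserved in loop-size estimates", {
  # radii ordered as P7 < P540 < P0 < P80 must give ordered size estimates
  set.seed(5)
  means <- c(P7 = 6.1, P540 = 6.9, P0 = 7.1, P80 = 7.5)
  ests <- vapply(names(means), function(g) {
    r <- means[[g]] * (1 + rnorm(50, 0, 0.01))
    loop_size_estimate(halo_measurements(g, rep(10, 50), rep(11, 50), r))$mean_kbp
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})
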