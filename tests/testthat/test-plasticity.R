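test_that("protein synthesis threshold follows the neuromodulator level", {
  expect_equal(protein_threshold(0), 1000)
  expect_equal(protein_threshold(0.06), 1 / 0.061)
  expect_equal(protein_threshold(0.06), 16.393, tolerance = 1e-4)
  expect_equal(protein_threshold(0.18), 5.5249, tolerance = 1e-4)
  expect_error(protein_threshold(-0.1), "non-negative")
})

test_that("calcium decays exponentially and jumps on pre/post spikes", {
  p <- model_params()
  c0 <- 2
  n <- 500
  cc <- c0
  for (k in seq_len(n)) cc <- calcium_step(cc, p)
  expect_equal(cc, c0 * exp(-n * p$dt / p$tau_c), tolerance = 1e-10)
  expect_equal(calcium_step(0, p, n_pre = 1), 0.6)      # presynaptic jump
  expect_equal(calcium_step(0, p, n_post = 1), 0.1655)  # postsynaptic jump
  expect_equal(calcium_step(0, p, n_pre = 1, n_post = 1), 0.7655)
})

test_that("early-phase weight has the three calcium-dependent fixed points", {
  p <- model_params()
  # c < theta_d: relaxation to h_0 at rate 0.1/tau_h
  h <- 8
  n <- 10000
  for (k in seq_len(n)) h <- early_phase_step(h, 0, p, noise = 0)
  h_pred <- p$h_0 + (8 - p$h_0) * exp(-0.1 * n * p$dt / p$tau_h)
  expect_equal(h, h_pred, tolerance = 1e-6)
  # sustained c > theta_p: potentiation fixed point ~ 2 h_0
  fp_ltp <- (0.1 * p$h_0 + 10 * p$gamma_p) / (0.1 + p$gamma_p + p$gamma_d)
  h <- p$h_0
  for (k in 1:40000) h <- early_phase_step(h, 5, p, noise = 0)
  expect_equal(h, fp_ltp, tolerance = 1e-6)
  expect_equal(fp_ltp, 8.401, tolerance = 1e-4)
  expect_equal(fp_ltp, 2 * p$h_0, tolerance = 2e-4)
  # sustained theta_d < c < theta_p: depression fixed point ~ 0
  fp_ltd <- 0.1 * p$h_0 / (0.1 + p$gamma_d)
  h <- p$h_0
  for (k in 1:40000) h <- early_phase_step(h, 2, p, noise = 0, dt = 0.002)
  expect_equal(h, fp_ltd, tolerance = 1e-4)
  expect_equal(fp_ltd, 0.00134, tolerance = 1e-2)
  # clipping keeps h within [0, 10] mV even under extreme noise
  expect_equal(early_phase_step(9.9, 5, p, noise = 5000), 10)
  expect_equal(early_phase_step(0.1, 2, p, noise = -5000), 0)
})

test_that("tagging is a threshold on the early-phase deviation", {
  p <- model_params()
  expect_false(tag_indicator(p$h_0, p))
  expect_true(tag_indicator(2 * p$h_0, p))            # |dev| = 4.2 > 0.840149
  expect_false(tag_indicator(p$h_0 - 0.5, p))         # 0.5 < theta_tag
  expect_equal(tag_indicator(2 * p$h_0, p, sign = TRUE), 1L)
  expect_equal(tag_indicator(p$h_0 - 1, p, sign = TRUE), -1L)
  expect_equal(tag_indicator(p$h_0, p, sign = TRUE), 0L)
})

test_that("protein pool decays with a ~42 min half-life and saturates at alpha", {
  p <- model_params()
  pp <- 1
  n <- 5000
  dt <- 1  # coarse steps are fine for tau_p = 3600 s
  for (k in seq_len(n)) pp <- protein_step(pp, 0, 0, p, dt = dt)
  expect_equal(pp, exp(-n * dt / p$tau_p), tolerance = 1e-3)
  half_life <- p$tau_p * log(2)
  expect_equal(half_life / 60, 60 * log(2), tolerance = 1e-12)  # ~41.6 min
  pp <- 0
  for (k in 1:80000) pp <- protein_step(pp, 2000, 0, p, dt = dt)
  expect_equal(pp, p$alpha_p, tolerance = 1e-6)
})

test_that("late phase integrates toward its bounds only when gated", {
  p <- model_params()
  # p = 0: frozen
  expect_equal(late_phase_step(0.3, 2 * p$h_0, 0, p), 0.3)
  # LTP tag, p = 1: z(60 min) = 1 - 1/e
  z <- 0
  dt <- 0.5
  for (k in seq_len(3600 / dt)) z <- late_phase_step(z, 2 * p$h_0, 1, p, dt = dt)
  expect_equal(z, 1 - exp(-1), tolerance = 1e-3)
  # LTD tag, p = 1: z(t) = -0.5 (1 - exp(-t/tau_z))
  z <- 0
  for (k in seq_len(1800 / dt)) z <- late_phase_step(z, 0, 1, p, dt = dt)
  expect_equal(z, -0.5 * (1 - exp(-0.5)), tolerance = 1e-3)
  # untagged: frozen even with protein available
  expect_equal(late_phase_step(0.2, p$h_0 + 0.5, 1, p), 0.2)
})

test_that("late phase and protein respect gating and bounds on random paths", {
  p <- model_params()
  set.seed(99)
  for (rep in 1:20) {
    h <- runif(1, 0, 10)
    z <- runif(1, -0.5, 1)
    pp <- runif(1, 0, 1)
    s <- runif(1, 0, 30)
    nm <- sample(c(0, 0.05, 0.2), 1)
    for (k in 1:50) {
      z_new <- late_phase_step(z, h, pp, p, dt = 10)
      if (!tag_indicator(h, p) || pp == 0) expect_identical(z_new, z)
      expect_true(z_new >= -0.5 && z_new <= 1)
      pp <- protein_step(pp, s, nm, p, dt = 10)
      expect_true(pp >= 0 && pp <= p$alpha_p)
      z <- z_new
    }
  }
})

test_that("total weight combines early and late phase on the percent scale", {
  p <- model_params()
  tw <- total_weight(p$h_0, 0, p)
  expect_equal(tw$w, 4.20075)
  expect_equal(tw$percent, 100)
  expect_equal(total_weight(2 * p$h_0, 1, p)$percent, 300)
  expect_equal(total_weight(p$h_0, 0.5, p)$percent, 150)
})

test_that("tag lifetime under pure decay matches the logarithmic formula", {
  p <- model_params()
  lt <- tag_lifetime(2 * p$h_0, p)
  expect_equal(lt, p$tau_h / 0.1 * log(p$h_0 / p$theta_tag))
  expect_equal(lt, 6884 * log(5), tolerance = 1e-4)   # ~3.08 h
  expect_equal(lt / 3600, 3.08, tolerance = 1e-3)
  expect_equal(tag_lifetime(p$h_0 + 0.5, p), 0)       # never tagged
  # consistency: decaying h for that long lands exactly on the threshold
  h_end <- p$h_0 + (2 * p$h_0 - p$h_0) * exp(-0.1 * lt / p$tau_h)
  expect_equal(h_end - p$h_0, p$theta_tag, tolerance = 1e-10)
})

test_that("neuromodulator schedules evaluate piecewise and gate the late phase", {
  nm <- nm_schedule(0.12, onset_min = 30, duration_min = 60)
  expect_equal(nm_at(nm, 0), 0)
  expect_equal(nm_at(nm, 11.1 + 30 * 60), 0.12)
  expect_equal(nm_at(nm, 11.1 + 89 * 60), 0.12)
  expect_equal(nm_at(nm, 11.1 + 91 * 60), 0)
  nmc <- nm_constant(0.12)
  expect_equal(nm_at(nmc, c(0, 1e5)), c(0.12, 0.12))
  nmax <- nm_schedule(0.12, onset_min = 0, duration_min = "max")
  expect_equal(nm_at(nmax, c(5, 12, 1e5)), c(0, 0.12, 0.12))
  expect_error(nm_schedule(-1), "level >= 0")
})

test_that("fast-forward matches fine-step integration of the gap dynamics", {
  p <- model_params()
  h0 <- p$h_0
  h <- c(2 * h0, h0 + 1.2, h0 - 1.5, h0 + 0.2, h0)
  z <- c(0, 0.2, -0.1, 0, 0)
  post <- 1:5
  pp <- numeric(8)
  nm <- nm_schedule(0.2, onset_min = 1, duration_min = 2)
  ff <- fast_forward(h, z, pp, post, 8, 11.6, 11.6 + 300, nm, p, dt_ff = 0.1)
  fine <- fine_consolidation(h, z, pp, post, 8, 11.6, 11.6 + 300, nm, p,
                             dt = 0.005)
  expect_equal(ff$h, fine$h, tolerance = 1e-6)
  expect_lt(max(abs(ff$z - fine$z)), 1e-4)
  expect_lt(max(abs(ff$p - fine$p)), 1e-4)
  # a schedule that starts only after every tag has vanished leaves the
  # late phase untouched
  nm_late <- nm_schedule(1, onset_min = 300, duration_min = "max")
  ff2 <- fast_forward(h, z, pp, post, 8, 11.6, 11.6 + 8 * 3600, nm_late, p)
  expect_equal(ff2$z, z)
  expect_error(fast_forward(h, z, pp, post, 8, 10, 5, nm, p), "precede")
})
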