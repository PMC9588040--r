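test_that("pattern completion coefficient covers its analytic limits", {
  # perfect completion: non-stimulated assembly matches stimulated, no
  # control activity
  expect_equal(pattern_completion_q(c(10, 10, 10, 10, 0, 0),
                                    1:2, 3:4, 5:6), 1)
  # no completion: non-stimulated assembly at control level
  expect_equal(pattern_completion_q(c(10, 10, 4, 4, 4, 4),
                                    1:2, 3:4, 5:6), 0)
  expect_equal(pattern_completion_q(c(10, 10, 6, 6, 2, 2),
                                    1:2, 3:4, 5:6), 0.4)
  # invariance under uniform rate rescaling
  set.seed(1)
  r <- runif(30, 0, 20)
  q1 <- pattern_completion_q(r, 1:5, 6:10, 11:30)
  q2 <- pattern_completion_q(7 * r, 1:5, 6:10, 11:30)
  expect_equal(q1, q2)
  expect_warning(q0 <- pattern_completion_q(c(0, 0, 1, 1), 1:2, 3, 4),
                 "undefined")
  expect_true(is.na(q0))
})

test_that("rate mutual information matches a brute-force joint histogram", {
  # 4-neuron toy, computed by explicit probability tables
  a <- c(2, 2, 4, 6)
  b <- c(0, 0, 4, 4)
  ent <- function(x) {
    p <- as.numeric(table(x)) / length(x)
    -sum(p * log2(p))
  }
  joint <- -sum(as.numeric(table(paste(a, b))) / 4 *
                log2(as.numeric(table(paste(a, b))) / 4))
  expect_equal(rate_mutual_information(a, b), ent(a) + ent(b) - joint)
  expect_equal(rate_mutual_information(a, b), 1)  # computed by hand
  # identical distributions: MI equals the entropy
  expect_equal(rate_mutual_information(a, a), ent(a))
  # a constant recall vector carries no information
  expect_equal(rate_mutual_information(a, c(3, 3, 3, 3)), 0)
  expect_error(rate_mutual_information(a, b[1:3]), "same neurons")
})

test_that("mutual information is symmetric, non-negative and bounded", {
  set.seed(2)
  ent <- function(x) {
    p <- as.numeric(table(x)) / length(x)
    -sum(p * log2(p))
  }
  for (k in 1:20) {
    a <- sample(seq(0, 10, by = 2), 40, replace = TRUE)
    b <- sample(seq(0, 10, by = 2), 40, replace = TRUE)
    mi <- rate_mutual_information(a, b)
    expect_equal(mi, rate_mutual_information(b, a))
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(ent(a), ent(b)) + 1e-12)
  }
})

test_that("PCA dimensionality counts components to the variance criterion", {
  # rank-1: all neurons share one temporal profile at varying amplitude
  profile <- sin(seq_len(100) / 7)
  m1 <- outer(seq(0.5, 3, length.out = 20), profile)
  expect_equal(pca_dimensionality(m1, 0.7), 1L)
  # full variance: dimensionality equals the rank of the centered matrix
  set.seed(3)
  basis <- matrix(rnorm(3 * 100), 3, 100)
  m3 <- matrix(runif(30 * 3), 30, 3) %*% basis
  expect_equal(pca_dimensionality(m3, 1), qr(scale(m3, scale = FALSE))$rank)
  # iid noise: matches a direct covariance eigenvalue computation
  mn <- matrix(rnorm(50 * 100), 50, 100)
  ev <- eigen(cov(mn), symmetric = TRUE, only.values = TRUE)$values
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.7)[1]
  expect_equal(pca_dimensionality(mn, 0.7,
                                  neurons_as_samples = FALSE), k_oracle)
  # row permutations leave the dimensionality unchanged
  expect_equal(pca_dimensionality(mn, 0.7),
               pca_dimensionality(mn[sample(50), ], 0.7))
  # degenerate inputs
  expect_equal(pca_dimensionality(matrix(0, 5, 10)), 0L)
  expect_equal(pca_dimensionality(matrix(1, 5, 10)), 0L)
})

test_that("spike-time stability scores matching bins per learning spike", {
  m <- matrix(0L, 3, 100)
  m[1, c(3, 10, 40)] <- 1L
  r <- matrix(0L, 3, 100)
  r[1, c(10, 40, 77)] <- 1L
  expect_equal(spike_time_stability(m, r), 2 / 3)
  expect_equal(spike_time_stability(m, m), 1)
  r2 <- matrix(0L, 3, 100); r2[1, c(50, 60, 70)] <- 1L
  expect_equal(spike_time_stability(m, r2), 0)
  # per-neuron scores: zero-spike neurons are excluded / NA
  s <- spike_time_stability(m, r, per_neuron = TRUE)
  expect_equal(s, c(2 / 3, NA, NA))
  expect_true(is.na(spike_time_stability(matrix(0L, 2, 10),
                                         matrix(0L, 2, 10))))
})

test_that("bin shuffling preserves counts and matches the chance level", {
  set.seed(4)
  bins <- matrix(rbinom(200 * 100, 1, 0.08), 200, 100)
  sh <- shuffle_raster(bins, seed = 1)
  expect_equal(rowSums(sh), rowSums(bins))
  expect_false(identical(sh, bins))
  expect_identical(shuffle_raster(bins, seed = 1), sh)
  # expected stability of an independently shuffled pair: for a neuron
  # with k learning and m recall spikes the match count is
  # hypergeometric with mean k m / 100
  k <- 12; m <- 9; nb <- 100
  learn <- matrix(0L, 1, nb); learn[1, 1:k] <- 1L
  recall <- matrix(0L, 1, nb); recall[1, 1:m] <- 1L
  n_rep <- 1000
  set.seed(5)
  scores <- vapply(seq_len(n_rep), function(i) {
    spike_time_stability(shuffle_raster(learn), shuffle_raster(recall))
  }, numeric(1))
  mu <- m / nb                                   # (k m / nb) / k
  v_match <- k * (m / nb) * (1 - m / nb) * (nb - k) / (nb - 1)
  se <- sqrt(v_match / k^2 / n_rep)
  expect_lt(abs(mean(scores) - mu), 3 * se)
})

test_that("stability-weight correlation is a guarded Spearman coefficient", {
  stab <- c(0.1, 0.2, 0.3, 0.5, 0.9)
  w <- c(1, 2, 5, 7, 20)
  expect_equal(stability_weight_correlation(stab, w), 1)
  expect_equal(stability_weight_correlation(stab, -w), -1)
  # toy set against the explicit rank formula (no ties)
  w2 <- c(3, 1, 10, 2, 8)
  d <- rank(stab) - rank(w2)
  rho <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
  expect_equal(stability_weight_correlation(stab, w2), rho)
  expect_error(stability_weight_correlation(c(0.1, NA, NA, NA),
                                            c(1, 2, 3, 4)), "fewer than 3")
  # independent (permuted) weights: near-zero correlation on average
  set.seed(6)
  rhos <- vapply(1:200, function(i) {
    stability_weight_correlation(runif(30), runif(30))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("random-walk targets start at 1 with unit-variance increments", {
  y <- gaussian_random_walk(100, seed = 7)
  expect_equal(length(y), 100)
  expect_equal(y[1], 1)
  expect_identical(y, gaussian_random_walk(100, seed = 7))
  set.seed(8)
  incs <- unlist(lapply(1:200, function(i) diff(gaussian_random_walk(50))))
  expect_equal(var(incs), 1, tolerance = 0.05)
  # Var(y[i] - y[0]) = i - 1 increments
  endpoints <- vapply(1:2000, function(s) {
    gaussian_random_walk(51, seed = 10000 + s)[51] - 1
  }, numeric(1))
  expect_equal(var(endpoints), 50, tolerance = 0.15 * 50)
})

test_that("ridge readout equals the penalised normal equations", {
  set.seed(9)
  segs <- lapply(1:4, function(i) matrix(rbinom(10 * 100, 1, 0.2), 10, 100))
  y <- gaussian_random_walk(100, seed = 11)
  alpha <- 0.1
  fit <- fit_ridge_readout(segs, y, p_out = 1, alpha_ridge = alpha)
  # oracle: closed-form solve on the explicitly assembled design
  X <- cbind(do.call(rbind, lapply(segs, t)), 1)
  w_oracle <- solve(t(X) %*% X + alpha * diag(ncol(X)), t(X) %*% rep(y, 4))
  expect_equal(fit$weights, as.numeric(w_oracle), tolerance = 1e-10)
  pred <- X[301:400, ] %*% w_oracle
  r2_oracle <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r2, r2_oracle, tolerance = 1e-12)
  # interpolation limit: a target realisable as a linear readout of the
  # raster is fit perfectly as alpha -> 0 (identical segments keep the
  # repeated-target problem consistent)
  w_true <- rnorm(11)
  segs_consistent <- rep(segs[1], 4)
  y_lin <- as.numeric(cbind(t(segs[[1]]), 1) %*% w_true)
  fit0 <- fit_ridge_readout(segs_consistent, y_lin, p_out = 1,
                            alpha_ridge = 1e-10)
  expect_gt(fit0$r2, 0.999)
  # shrinkage limit: weights vanish and the fit degenerates
  fit_inf <- fit_ridge_readout(segs, y, p_out = 1, alpha_ridge = 1e9)
  expect_lt(max(abs(fit_inf$weights)), 1e-3)
  expect_lte(fit_inf$r2, 0)
  expect_error(fit_ridge_readout(segs, y, p_out = 0.001), "empty")
})

test_that("readout subsampling has the stated design width and seeding", {
  set.seed(10)
  segs <- lapply(1:4, function(i) matrix(rbinom(150 * 100, 1, 0.15), 150, 100))
  y <- gaussian_random_walk(100, seed = 12)
  fit <- fit_ridge_readout(segs, y, p_out = 0.3, neuron_pool = 1:150,
                           seed = 3)
  expect_equal(length(fit$neurons), round(0.3 * 150))
  expect_equal(length(fit$weights), 45 + 1)   # subsample plus intercept
  fit2 <- fit_ridge_readout(segs, y, p_out = 0.3, neuron_pool = 1:150,
                            seed = 3)
  expect_identical(fit$neurons, fit2$neurons)
  # connectivity curve: same seed reproduces the table; R2 tends to grow
  # with the sampled fraction (checked loosely at the extremes)
  cur <- readout_connectivity_curve(segs, p_out_grid = c(0.1, 0.5, 1),
                                    n_targets = 5, seed = 2)
  cur2 <- readout_connectivity_curve(segs, p_out_grid = c(0.1, 0.5, 1),
                                     n_targets = 5, seed = 2)
  expect_equal(cur, cur2)
  expect_gt(cur$r2[cur$p_out == 1], cur$r2[cur$p_out == 0.1] - 0.05)
})

test_that("mean core input weight aggregates outgoing late-phase weights", {
  p <- model_params(N_e = 5, N_i = 0, assembly_size = 2, p_c = 1)
  topo <- build_network(p, seed = 1)
  ee <- ee_synapses(topo)
  z <- numeric(length(ee))
  cls <- classify_synapses(topo)
  z[cls == "outgoing"] <- 0.5
  w <- core_input_weight(topo, z)
  expect_true(all(is.na(w[1:2])))          # core neurons excluded
  expect_equal(w[3:5], rep(0.5, 3))
})
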