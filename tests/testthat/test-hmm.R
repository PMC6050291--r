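test_that("single-state Poisson likelihood has the closed form", {
  m <- hmm_model(matrix(c(1, 1), 1, 2), matrix(1, 1, 1))
  ll <- loglikelihood(m, matrix(c(0, 0), 1, 2))
  expect_equal(ll, -2, tolerance = 1e-12)
})

test_that("forward likelihood equals exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:12) {
    K <- sample(2:3, 1)
    Tn <- sample(2:6, 1)
    A <- matrix(rexp(K * K), K); A <- A / rowSums(A)
    means <- matrix(runif(2 * K, 0, 6), K)
    pi <- rexp(K); pi <- pi / sum(pi)
    m <- hmm_model(means, A, pi)
    counts <- matrix(rpois(2 * Tn, 3), Tn)
    expect_equal(loglikelihood(m, counts), enumerate_loglik(m, counts),
                 tolerance = 1e-10)
  }
})

test_that("appending a frame cannot raise loglik above the emission bound", {
  m <- hmm_model(rbind(c(5, 1), c(1, 5)),
                 matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  set.seed(14)
  counts <- matrix(rpois(20, 3), 10)
  ll_n <- loglikelihood(m, counts[1:9, ])
  ll_n1 <- loglikelihood(m, counts)
  best_emit <- max(lambdaswitch:::emission_logprob(m, counts[10, ,
                                                             drop = FALSE]))
  expect_lte(ll_n1, ll_n + best_emit + 1e-10)
})

test_that("EM recovers a single-state mean and never decreases loglik", {
  m <- hmm_model(matrix(c(5, 5), 1, 2), matrix(1, 1, 1))
  cfg <- generator_config(emission_means = m$means, dwell_means = 10,
                          stationary_targets = 1, trace_length = 3000)
  tr <- simulate_lineage(cfg, m, seed = 2)
  fit <- fit_em(tr, 1, n_restarts = 2, seed = 3)
  se <- sqrt(5 / 3000)
  expect_lt(max(abs(fit$model$means - 5)), 3 * se)
  expect_true(all(diff(fit$loglik_path) > -1e-8))
})

test_that("EM loglik is monotone on multi-state data and rows normalize", {
  ds <- simulate_dataset(generator_config(n_lineages = 10,
                                          trace_length = 60), seed = 9)
  fit <- fit_em(ds, 3, n_restarts = 3, seed = 5)
  expect_true(all(diff(fit$loglik_path) > -1e-8))
  expect_lt(max(abs(rowSums(fit$model$A) - 1)), 1e-10)
  expect_lt(abs(sum(fit$model$pi) - 1), 1e-10)
})

test_that("viterbi equals per-frame argmax for well-separated states", {
  m <- hmm_model(rbind(c(0.2, 10), c(10, 0.2)),
                 matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE))
  counts <- rbind(c(0, 9), c(1, 11), c(12, 0), c(9, 1), c(0, 8))
  dec <- viterbi(m, counts)
  argmax <- apply(lambdaswitch:::emission_logprob(m, counts), 1, which.max)
  expect_identical(dec$states, as.integer(argmax))
  expect_identical(dec$states, c(1L, 1L, 2L, 2L, 1L))
})

test_that("ties break toward the lower state index", {
  m <- hmm_model(rbind(c(3, 3), c(3, 3)), matrix(0.5, 2, 2))
  dec <- viterbi(m, matrix(rpois(10, 3), 5))
  expect_true(all(dec$states == 1L))
})

test_that("viterbi path beats all enumerated paths", {
  set.seed(77)
  for (rep in 1:6) {
    K <- sample(2:3, 1)
    A <- matrix(rexp(K * K), K); A <- A / rowSums(A)
    m <- hmm_model(matrix(runif(2 * K, 0, 6), K), A)
    counts <- matrix(rpois(10, 3), 5)
    dec <- viterbi(m, counts)
    oracle <- enumerate_viterbi(m, counts)
    expect_equal(dec$states, unname(oracle$path))
  }
})

test_that("viterbi path probability >= pointwise posterior argmax path", {
  m <- table1_model()
  tr <- simulate_lineage(generator_config(trace_length = 40), m, seed = 4)
  counts <- cbind(tr$cro_count, tr$ci_count)
  dec <- viterbi(m, counts)
  logp_path <- function(p) {
    lb <- emission_logprob(m, counts)
    lp <- log(m$pi[p[1]]) + lb[1, p[1]]
    for (t in 2:length(p)) lp <- lp + log(m$A[p[t - 1], p[t]]) + lb[t, p[t]]
    lp
  }
  argmax_path <- apply(dec$posterior, 1, which.max)
  expect_gte(logp_path(dec$states), logp_path(argmax_path) - 1e-10)
})

test_that("four-state fit recovers the generator parameters", {
  cfg <- generator_config()
  m <- table1_model()
  ds <- simulate_dataset(cfg, m, seed = 101)
  fit <- fit_em(ds, 4, n_restarts = 6, seed = 7)
  perm <- match_states(fit$model$means, m$means)
  fitted <- fit$model$means[perm, ]
  expect_true(all(abs(fitted - m$means) <=
                    pmax(0.1 * m$means, 0.25)))
  # stationary distribution of the fitted chain matches decoded frequencies
  dec <- decode_traces(fit$model, ds)
  freq <- tabulate(unlist(lapply(dec, `[[`, "states")), 4)
  freq <- freq / sum(freq)
  pis <- stationary_distribution(fit$model$A)
  ess <- sum(freq) # correlated frames: allow a generous band
  expect_lt(max(abs(pis - freq)), 0.05)
})

test_that("model selection picks K = 1 for single-state data", {
  m <- hmm_model(matrix(c(3, 2), 1, 2), matrix(1, 1, 1))
  cfg <- generator_config(emission_means = m$means, dwell_means = 10,
                          stationary_targets = 1, trace_length = 800)
  tr <- simulate_lineage(cfg, m, seed = 6)
  sel <- select_model(tr, 1:3, n_restarts = 2, seed = 8)
  expect_identical(sel$K_bic, 1L)
  expect_identical(sel$K_histmatch, 1L)
  expect_error(select_model(tr, integer(0)), "non-empty")
})

test_that("dwell times follow the stated arithmetic and censoring rules", {
  dec <- structure(list(
    states = c(1L, 1L, 1L, 2L, 2L),
    posterior = matrix(NA_real_, 5, 2),
    segments = data.frame(state = c(1L, 2L), start = c(1L, 4L),
                          length = c(3L, 2L),
                          censored_left = c(TRUE, FALSE),
                          censored_right = c(FALSE, TRUE)),
    frame_interval = 5), class = "decoded_trace")
  all_dw <- dwell_times(dec, policy = "all")
  expect_equal(all_dw$mean_dwell_min, c(15, 10))
  # default policy drops censored runs: nothing remains here
  unc <- dwell_times(dec)
  expect_true(all(unc$n_occurrences == 0))
  expect_true(all(is.na(unc$mean_dwell_min)))
})

test_that("decoded dwell matches the geometric closed form", {
  m <- hmm_model(rbind(c(0, 12), c(12, 0)),
                 matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  p <- simulate_state_path(m, 2e4, seed = 3)
  counts <- cbind(rpois(2e4, m$means[p, 1]), rpois(2e4, m$means[p, 2]))
  dec <- viterbi(m, counts)
  dw <- dwell_times(dec, policy = "exit_rate")
  # oracle: geometric mean run length 1/(1 - 0.9) frames = 50 min
  for (k in 1:2) {
    n <- dw$n_occurrences[dw$state == k]
    expect_lt(abs(dw$mean_dwell_min[dw$state == k] - 50), 3 * 50 / sqrt(n))
  }
})

test_that("transition time constants: arithmetic, NAs, closed form", {
  dec <- structure(list(
    states = rep(c(1L, 2L), 10),
    posterior = NULL,
    segments = data.frame(state = rep(c(1L, 2L), 10),
                          start = seq(1, 20),
                          length = rep(1L, 20),
                          censored_left = c(TRUE, rep(FALSE, 19)),
                          censored_right = c(rep(FALSE, 19), TRUE)),
    frame_interval = 5), class = "decoded_trace")
  tt <- transition_time_constants(dec, K = 3)
  expect_equal(tt$tau[1, 2], 10 * 5 / 10)   # 50 min in 1, 10 switches 1->2
  expect_true(is.na(tt$tau[1, 3]))
  expect_identical(tt$n_switches[1, 3], 0L)

  # simulation from a known A: tau_ij ~ frame_interval / A_ij
  m <- hmm_model(rbind(c(0, 12), c(12, 0)),
                 matrix(c(0.92, 0.08, 0.04, 0.96), 2, byrow = TRUE))
  p <- simulate_state_path(m, 4e4, seed = 9)
  counts <- cbind(rpois(4e4, m$means[p, 1]), rpois(4e4, m$means[p, 2]))
  tt2 <- transition_time_constants(viterbi(m, counts))
  for (i in 1:2) {
    j <- 3 - i
    expected <- 5 / m$A[i, j]
    n <- tt2$n_switches[i, j]
    expect_lt(abs(tt2$tau[i, j] - expected), 3 * expected / sqrt(n))
  }
  # consistency: 1/dwell_exit = sum_j 1/tau_ij
  dw <- dwell_times(viterbi(m, counts), policy = "exit_rate")
  for (i in 1:2) {
    expect_equal(1 / dw$mean_dwell_min[dw$state == i],
                 sum(1 / tt2$tau[i, -i], na.rm = TRUE), tolerance = 1e-9)
  }
})

test_that("predicted histogram matches theory and long simulations", {
  m1 <- hmm_model(matrix(c(2, 3), 1, 2), matrix(1, 1, 1))
  ph <- predicted_histogram(m1, max_count = 20)
  expect_equal(sum(ph$prob), 1, tolerance = 1e-12)
  expect_equal(ph$prob[3, 4], dpois(2, 2) * dpois(3, 3), tolerance = 1e-12)

  m <- table1_model()
  ph4 <- predicted_histogram(m, max_count = 14)
  expect_equal(sum(ph4$prob), 1, tolerance = 1e-10)
  p <- simulate_state_path(m, 1e6, seed = 12)
  counts <- cbind(rpois(1e6, m$means[p, 1]), rpois(1e6, m$means[p, 2]))
  emp <- histogram2d(data.frame(cro_count = counts[, 1],
                                ci_count = counts[, 2]), 14)
  tv <- sum(abs(emp$prob - ph4$prob)) / 2
  expect_lt(tv, 0.01)
})

test_that("model round-trips through the flat text format", {
  m <- table1_model()
  path <- tempfile(fileext = ".txt")
  write_model_file(m, path)
  m2 <- read_model_file(path)
  expect_equal(m2$means, m$means, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(m2$A, m$A, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(m2$pi, m$pi, tolerance = 1e-10)
})
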