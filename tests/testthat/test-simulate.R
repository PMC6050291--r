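test_that("state paths are deterministic and respect the chain", {
  m <- table1_model()
  p1 <- simulate_state_path(m, 500, seed = 7)
  p2 <- simulate_state_path(m, 500, seed = 7)
  expect_identical(as.integer(p1), as.integer(p2))
  # identity transition matrix freezes the start state
  mi <- hmm_model(m$means, diag(4), pi = c(0, 0, 1, 0))
  expect_true(all(simulate_state_path(mi, 50, seed = 1) == 3L))
})

test_that("long paths match the stationary distribution of the chain", {
  m <- table1_model()
  n <- 1e5
  p <- simulate_state_path(m, n, seed = 11)
  freq <- tabulate(p, 4) / n
  # oracle: stationary distribution from power iteration
  P <- m$A
  for (i in 1:12) P <- P %*% P
  target <- unname(P[1, ])
  se <- sqrt(target * (1 - target) / n)
  # dwell correlation inflates the error of frame fractions; 3 s.e. on the
  # effective sample size n / (2 * mean dwell in frames)
  ess <- n / (2 * mean(1 / (1 - diag(m$A))))
  expect_true(all(abs(freq - target) <
                    3 * sqrt(target * (1 - target) / ess)))
  # empirical dwell of each state matches frame_interval / (1 - A_kk)
  runs <- rle(as.integer(p))
  for (k in 1:4) {
    lens <- runs$lengths[runs$values == k]
    lens <- lens[-c(1, length(lens))]  # crude decensoring
    expected <- 1 / (1 - m$A[k, k])
    expect_lt(abs(mean(lens) - expected),
              3 * expected / sqrt(length(lens)) + 0.05)
  }
})

test_that("zero emission means give all-zero counts", {
  cfg <- generator_config(emission_means = matrix(0, 4, 2),
                          trace_length = 50)
  tr <- simulate_lineage(cfg, seed = 3)
  expect_true(all(tr$cro_count == 0) && all(tr$ci_count == 0))
})

test_that("single-state lineage reproduces the configured Cro mean", {
  m <- hmm_model(matrix(c(5.2, 0), 1, 2), matrix(1, 1, 1))
  cfg <- generator_config(emission_means = m$means, dwell_means = 10,
                          stationary_targets = 1, trace_length = 1e4)
  tr <- simulate_lineage(cfg, m, seed = 5)
  se <- sqrt(5.2 / 1e4)
  expect_lt(abs(mean(tr$cro_count) - 5.2), 3 * se)
  expect_true(all(tr$ci_count == 0))
})

test_that("lineage structure is valid: times, ages, divisions", {
  cfg <- generator_config(trace_length = 200)
  tr <- simulate_lineage(cfg, seed = 13)
  expect_equal(diff(tr$time_min), rep(5, 199))
  expect_true(all(tr$cell_age > 0 & tr$cell_age <= 1))
  expect_true(all(diff(tr$cell_id) %in% c(0L, 1L)))
  # division flags sit on the last frame of each cell
  div_frames <- which(tr$division_flag == 1)
  expect_true(all(tr$cell_id[pmin(div_frames + 1, 200)] ==
                    tr$cell_id[div_frames] + 1 |
                    div_frames == 200))
})

test_that("inter-division times recover the 71 +/- 22 min cell cycle", {
  cfg <- generator_config(n_lineages = 94, trace_length = 69)
  ds <- simulate_dataset(cfg, seed = 17)
  gaps <- unlist(lapply(ds, function(tr) diff(which(tr$division_flag == 1))))
  expect_gt(length(gaps), 300)
  mean_cycle <- mean(gaps) * 5
  expect_lt(abs(mean_cycle - 71), 3 * sd(gaps * 5) / sqrt(length(gaps)))
})

test_that("maturation lag preserves means and broadens per-state spread", {
  m <- two_state_model(0.98)
  base <- generator_config(emission_means = m$means,
                           dwell_means = c(250, 250),
                           stationary_targets = c(0.5, 0.5),
                           trace_length = 2e4)
  mat <- base; mat$maturation_mean <- 7
  tr0 <- simulate_lineage(base, m, seed = 23)
  tr1 <- simulate_lineage(mat, m, seed = 23)
  # long-run flux conservation: per-channel means unchanged
  expect_lt(abs(mean(tr1$cro_count) - mean(tr0$cro_count)),
            4 * sd(tr0$cro_count) / sqrt(nrow(tr0)))
  # conditional on the true state, the lag mixes high and low frames and
  # strictly inflates the spread (it cannot reduce it)
  v0 <- var(tr0$cro_count[tr0$true_state == 1])
  v1 <- var(tr1$cro_count[tr1$true_state == 1])
  expect_gt(v1, v0)
})

test_that("detection efficiency thins counts binomially", {
  m <- hmm_model(matrix(c(8, 8), 1, 2), matrix(1, 1, 1))
  cfg <- generator_config(emission_means = m$means, dwell_means = 10,
                          stationary_targets = 1, trace_length = 5e3,
                          detection_efficiency = 0.5)
  tr <- simulate_lineage(cfg, m, seed = 31)
  expect_lt(abs(mean(tr$cro_count) - 4), 3 * sqrt(4 / 5e3))
})

test_that("datasets are reproducible, seeded per lineage, sized correctly", {
  cfg <- generator_config(n_lineages = 94, trace_length = 69)
  d1 <- simulate_dataset(cfg, seed = 1)
  d2 <- simulate_dataset(cfg, seed = 1)
  d3 <- simulate_dataset(cfg, seed = 2)
  expect_identical(attr(d1, "n_frames"), 94L * 69L)
  expect_true(abs(attr(d1, "n_frames") - 6453) < 100)
  expect_identical(d1[[10]]$cro_count, d2[[10]]$cro_count)
  expect_false(identical(d1[[10]]$cro_count, d3[[10]]$cro_count))
  empty <- simulate_dataset(generator_config(n_lineages = 0), seed = 1)
  expect_length(empty, 0)
})

test_that("snapshot population pins to expected classes", {
  # model pinned to [L,H]: every cell classifies CI-only
  cfg <- generator_config()
  mLH <- hmm_model(matrix(c(0, 4.7), 1, 2), matrix(1, 1, 1))
  snapLH <- simulate_snapshot_population(cfg, mLH, n_cells = 200, seed = 3)
  cls <- classify_population(snapLH$ci_total, snapLH$cro_total)
  expect_true(mean(cls == "CI-only") > 0.97)
  # pinned [H,H] with equal means: median ratio near 0.5
  mHH <- hmm_model(matrix(c(4.6, 4.6), 1, 2), matrix(1, 1, 1))
  snapHH <- simulate_snapshot_population(cfg, mHH, n_cells = 500, seed = 4)
  r <- snapHH$ci_total / (snapHH$ci_total + snapHH$cro_total)
  expect_lt(abs(median(r) - 0.5), 0.03)
  # full four-state model occupies all four classes at n = 2000; for
  # cycle-integrated totals "little CI or Cro" means ~1 molecule per frame,
  # so the low-total cutoff is scaled accordingly (function default stays 2)
  snap <- simulate_snapshot_population(cfg, table1_model(), 2000, seed = 5)
  cls4 <- classify_population(snap$ci_total, snap$cro_total, low_total = 20)
  expect_setequal(unique(cls4), c("CI-only", "Cro-only", "both", "low-low"))
})
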