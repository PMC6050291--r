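#' Simulate a hidden state path
#'
#' Samples a Markov chain from the model's transition matrix, starting from
#' its initial distribution. Deterministic for a fixed seed.
#'
#' @param model a [hmm_model()].
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @return integer vector of 1-based state indices with attributes
#'   `frame_interval` and class `state_path`.
#' @export
simulate_state_path <- function(model, n_frames, seed = 1L) {
  assert_that(n_frames >= 1, "n_frames must be at least 1")
  validate_stochastic(model$A)
  set.seed(seed)
  path <- integer(n_frames)
  path[1] <- sample.int(model$K, 1, prob = model$pi)
  if (n_frames > 1) {
    u <- runif(n_frames - 1)
    cumA <- t(apply(model$A, 1, cumsum))
    for (t in 2:n_frames) {
      path[t] <- findInterval(u[t - 1], cumA[path[t - 1], ],
                              left.open = TRUE) + 1L
    }
  }
  structure(path, frame_interval = model$frame_interval, class = "state_path")
}

# sample cell-cycle lengths (minutes): normal truncated below at one frame
sample_cell_cycles <- function(n, mean, sd, frame_interval) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= frame_interval
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# draw counts for one channel given the state path
draw_channel_counts <- function(path, means, family, size) {
  lam <- means[path]
  if (family == "poisson") rpois(length(path), lam)
  else rnbinom_mu(length(path), lam, size)
}

rnbinom_mu <- function(n, mu, size) {
  out <- integer(n)
  pos <- mu > 0
  out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = size)
  out
}

# displace each molecule's detection frame by an exponential maturation lag;
# production times are uniform within their frame. Molecules maturing after
# the last frame are lost (negligible for lags << trace length).
apply_maturation <- function(counts, maturation_mean, frame_interval) {
  n_frames <- length(counts)
  total <- sum(counts)
  if (total == 0) return(counts)
  prod_frame <- rep.int(seq_len(n_frames), counts)
  t_prod <- (prod_frame - 1 + runif(total)) * frame_interval
  t_det <- t_prod + rexp(total, rate = 1 / maturation_mean)
  f_det <- floor(t_det / frame_interval) + 1
  f_det <- f_det[f_det <= n_frames]
  out <- tabulate(f_det, nbins = n_frames)
  storage.mode(out) <- "integer"
  out
}

#' Simulate one cell-lineage production trace
#'
#' Draws a hidden production-state path, emits per-frame newly produced
#' (Cro, CI) molecule counts from the state's count distribution, and lays
#' dividing cell cycles (truncated normal lengths) over the frames. Division
#' does not reset the hidden state: the production state is a promoter
#' configuration that daughters inherit, and counts are per cell, so no
#' partitioning is applied. Optional fluorophore-maturation lag displaces
#' each molecule's detection frame; optional detection inefficiency thins
#' counts binomially.
#'
#' @param config a [generator_config()].
#' @param model a [hmm_model()]; defaults to the model implied by `config`.
#' @param seed integer seed.
#' @param lineage_id identifier stored in the trace.
#' @return a `lineage_trace`: a data.frame with columns `lineage_id`,
#'   `frame`, `time_min`, `cell_id`, `cell_age`, `division_flag`,
#'   `cro_count`, `ci_count`, `true_state`, and attribute `frame_interval`.
#' @export
simulate_lineage <- function(config, model = default_switch_model(config),
                             seed = config$rng_seed, lineage_id = 1L) {
  n <- config$trace_length
  path <- simulate_state_path(model, n, seed = seed)
  # simulate_state_path seeds the RNG; everything below continues the stream
  cro <- draw_channel_counts(path, model$means[, 1], model$family, model$size)
  ci <- draw_channel_counts(path, model$means[, 2], model$family, model$size)
  if (config$maturation_mean > 0) {
    cro <- apply_maturation(cro, config$maturation_mean, config$frame_interval)
    ci <- apply_maturation(ci, config$maturation_mean, config$frame_interval)
  }
  if (config$detection_efficiency < 1) {
    cro <- rbinom(n, cro, config$detection_efficiency)
    ci <- rbinom(n, ci, config$detection_efficiency)
  }
  # cell cycles: sample generously, then cut to the trace length
  n_cycles_max <- ceiling(n * config$frame_interval / config$cell_cycle_mean) + 10
  lens_min <- sample_cell_cycles(n_cycles_max, config$cell_cycle_mean,
                                 config$cell_cycle_sd, config$frame_interval)
  lens_frames <- pmax(1, round(lens_min / config$frame_interval))
  while (sum(lens_frames) < n) {
    extra <- sample_cell_cycles(10, config$cell_cycle_mean,
                                config$cell_cycle_sd, config$frame_interval)
    lens_min <- c(lens_min, extra)
    lens_frames <- c(lens_frames,
                     pmax(1, round(extra / config$frame_interval)))
  }
  cell_id <- integer(n); age <- numeric(n); division <- integer(n)
  pos <- 0; cid <- 0
  for (m in lens_frames) {
    cid <- cid + 1
    within <- seq_len(min(m, n - pos))
    cell_id[pos + within] <- cid
    age[pos + within] <- within / m
    if (pos + m <= n) division[pos + m] <- 1L
    pos <- pos + m
    if (pos >= n) break
  }
  out <- data.frame(lineage_id = lineage_id, frame = seq_len(n),
                    time_min = seq_len(n) * config$frame_interval,
                    cell_id = cell_id, cell_age = age,
                    division_flag = division,
                    cro_count = as.integer(cro), ci_count = as.integer(ci),
                    true_state = as.integer(path))
  attr(out, "frame_interval") <- config$frame_interval
  class(out) <- c("lineage_trace", "data.frame")
  out
}

#' Simulate a collection of independent lineages
#'
#' Each lineage uses a seed derived from the root seed with [derive_seed()],
#' so the collection is reproducible and lineages are independent.
#'
#' @inheritParams simulate_lineage
#' @return a `trace_set`: list of `lineage_trace` objects with attributes
#'   `config`, `seed`, `n_frames`.
#' @export
simulate_dataset <- function(config, model = default_switch_model(config),
                             seed = config$rng_seed) {
  traces <- lapply(seq_len(config$n_lineages), function(i) {
    simulate_lineage(config, model, seed = derive_seed(seed, i),
                     lineage_id = i)
  })
  structure(traces, config = config, seed = as.integer(seed),
            n_frames = sum(vapply(traces, nrow, 0L)),
            frame_interval = config$frame_interval,
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d lineages, %d frames, frame interval %g min\n",
              length(x), attr(x, "n_frames") %||% sum(vapply(x, nrow, 0L)),
              attr(x, "frame_interval") %||% NA))
  invisible(x)
}

#' Simulate a steady-state snapshot population
#'
#' Stand-in for integrated-fluorescence snapshot measurements: each cell
#' accumulates its production over one sampled cell cycle, giving per-cell
#' (Cro, CI) totals suitable for the ratio classifier
#' [classify_population()].
#'
#' @inheritParams simulate_lineage
#' @param n_cells number of cells (>= 1).
#' @return data.frame with columns `cell_id`, `cro_total`, `ci_total`.
#' @export
simulate_snapshot_population <- function(config,
                                         model = default_switch_model(config),
                                         n_cells, seed = config$rng_seed) {
  assert_that(n_cells >= 1, "n_cells must be at least 1")
  set.seed(seed)
  lens <- sample_cell_cycles(n_cells, config$cell_cycle_mean,
                             config$cell_cycle_sd, config$frame_interval)
  frames <- pmax(1, round(lens / config$frame_interval))
  seeds <- vapply(seq_len(n_cells), function(i) derive_seed(seed, i), 0L)
  cro <- integer(n_cells); ci <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    path <- simulate_state_path(model, frames[i], seed = seeds[i])
    cro[i] <- sum(draw_channel_counts(path, model$means[, 1],
                                      model$family, model$size))
    ci[i] <- sum(draw_channel_counts(path, model$means[, 2],
                                     model$family, model$size))
  }
  data.frame(cell_id = seq_len(n_cells), cro_total = cro, ci_total = ci)
}
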