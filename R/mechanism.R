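#' Mechanistic simulation of the switch by operator occupancy
#'
#' Runs an exact stochastic (Gillespie) simulation over the discrete
#' occupancy states of O_R1/O_R2/O_R3 (each free, CI-bound or Cro-bound).
#' P_R transcribes cro only while O_R1 and O_R2 are both repressor-free;
#' P_RM transcribes cI only while O_R3 is free. Transcripts live an
#' exponential ~1.5 min and are translated in bursts; translation events are
#' binned into imaging frames as newly produced molecules, mirroring
#' photobleach-interval counting. Binding propensities scale with the free
#' repressor copy number, closing the mutual-repression feedback, and
#' `adiabaticity_scale` multiplies all binding/unbinding rates: large values
#' give the classic fast-equilibrating (adiabatic) bistable regime, small
#' values the slow-binding (non-adiabatic) regime in which the [L,L] and
#' [H,H] production states emerge.
#'
#' @param mconfig a [mechanism_config()].
#' @param duration simulated time in minutes.
#' @param seed integer seed.
#' @param frame_interval imaging interval in minutes.
#' @return a `lineage_trace`-style data.frame with per-frame `cro_count`,
#'   `ci_count` and the operator occupancy code at frame start
#'   (`occ_code`, base-3 digits O_R1, O_R2, O_R3: 0 free, 1 CI, 2 Cro).
#'   Attribute `truncated` reports whether the event cap was hit.
#' @export
simulate_promoter_mechanism <- function(mconfig, duration, seed = mconfig$rng_seed,
                                        frame_interval = 5) {
  assert_that(duration >= frame_interval,
              "duration must cover at least one frame")
  set.seed(seed)
  res <- gillespie_switch(mconfig$kon_ci, mconfig$kon_cro,
                          mconfig$koff_ci, mconfig$koff_cro,
                          mconfig$k_tx_r, mconfig$k_tx_rm,
                          mconfig$mrna_lifetime, mconfig$burst_size,
                          mconfig$dilution, mconfig$adiabaticity_scale,
                          duration, frame_interval,
                          mconfig$p_ci0, mconfig$p_cro0, 5e7)
  n <- length(res$cro_counts)
  out <- data.frame(lineage_id = 1L, frame = seq_len(n),
                    time_min = seq_len(n) * frame_interval,
                    cell_id = 1L, cell_age = NA_real_,
                    division_flag = 0L,
                    cro_count = res$cro_counts, ci_count = res$ci_counts,
                    occ_code = res$occ_frame)
  attr(out, "frame_interval") <- frame_interval
  attr(out, "truncated") <- isTRUE(res$truncated)
  attr(out, "n_events") <- res$n_events
  class(out) <- c("lineage_trace", "data.frame")
  out
}

#' Pool several mechanistic runs into one frame table
#'
#' Convenience wrapper running independent trajectories (derived seeds) and
#' concatenating their frames, e.g. to estimate quadrant occupancies of the
#' production histogram in a given adiabaticity regime.
#'
#' @inheritParams simulate_promoter_mechanism
#' @param n_runs number of independent trajectories.
#' @param burn_in_frames frames dropped from the start of each run.
#' @return a `trace_set`.
#' @export
simulate_mechanism_ensemble <- function(mconfig, duration, n_runs,
                                        seed = mconfig$rng_seed,
                                        frame_interval = 5,
                                        burn_in_frames = 0) {
  traces <- lapply(seq_len(n_runs), function(i) {
    tr <- simulate_promoter_mechanism(mconfig, duration,
                                      seed = derive_seed(seed, i),
                                      frame_interval = frame_interval)
    tr$lineage_id <- i
    if (burn_in_frames > 0) tr <- tr[tr$frame > burn_in_frames, , drop = FALSE]
    class(tr) <- c("lineage_trace", "data.frame")
    tr
  })
  structure(traces, n_frames = sum(vapply(traces, nrow, 0L)),
            frame_interval = frame_interval, seed = as.integer(seed),
            class = "trace_set")
}

#' Quadrant occupancy of a bivariate production table
#'
#' Fraction of frames in each quadrant of the (Cro, CI) count plane, with
#' "high" meaning at least `threshold` molecules produced in the frame.
#'
#' @param traces a `trace_set`, `lineage_trace` or data.frame with
#'   `cro_count`, `ci_count`.
#' @param threshold count defining a high-production frame (default 2).
#' @return named numeric vector over `c("LL","HL","LH","HH")`, summing to 1.
#' @export
quadrant_fractions <- function(traces, threshold = 2) {
  df <- as_frame_table(traces)
  hi_cro <- df$cro_count >= threshold
  hi_ci <- df$ci_count >= threshold
  n <- nrow(df)
  c(LL = sum(!hi_cro & !hi_ci), HL = sum(hi_cro & !hi_ci),
    LH = sum(!hi_cro & hi_ci), HH = sum(hi_cro & hi_ci)) / n
}

# normalize the various trace containers to one data.frame of frames
as_frame_table <- function(traces) {
  if (inherits(traces, "trace_set")) {
    do.call(rbind, lapply(traces, as.data.frame))
  } else if (is.data.frame(traces)) {
    traces
  } else if (is.list(traces)) {
    do.call(rbind, lapply(traces, as.data.frame))
  } else stop("unsupported trace container", call. = FALSE)
}
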