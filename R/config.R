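#' Generator configuration for synthetic production traces
#'
#' Bundles and validates every tunable of the lineage-trace generator. The
#' defaults reproduce the experimental design the analysis assumes: a 5-min
#' imaging interval with photobleaching between frames (so each frame counts
#' newly produced molecules), four production states \code{[L,L]},
#' \code{[H,L]}, \code{[L,H]}, \code{[H,H]} with per-frame emission means
#' (0,0), (5.2,0), (0,4.7), (4.5,4.7) molecules for (Cro, CI), state dwell
#' times of 7, 36, 127 and 47 minutes, stationary frame fractions
#' 391:1733:3145:3069, and cell cycles of 71 +/- 22 min (truncated normal).
#'
#' @param frame_interval imaging interval in minutes.
#' @param n_lineages number of independent cell lineages.
#' @param trace_length frames per lineage.
#' @param cell_cycle_mean,cell_cycle_sd cell-cycle length distribution
#'   (minutes); lengths are truncated below at one frame.
#' @param emission_means K x 2 matrix of per-state mean molecules produced
#'   per frame, columns \code{(cro, ci)}.
#' @param dwell_means per-state mean dwell times in minutes (may be `Inf`).
#' @param stationary_targets optional per-state stationary frame fractions
#'   (must sum to 1).
#' @param maturation_mean mean fluorophore maturation lag in minutes;
#'   0 disables the lag.
#' @param detection_efficiency probability in (0, 1] that a produced
#'   molecule is detected (binomial thinning).
#' @param rng_seed integer root seed recorded with the configuration.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(frame_interval = 5,
                             n_lineages = 94,
                             trace_length = 69,
                             cell_cycle_mean = 71,
                             cell_cycle_sd = 22,
                             emission_means = default_emission_means(),
                             dwell_means = c(7, 36, 127, 47),
                             stationary_targets = c(391, 1733, 3145, 3069) / 8338,
                             maturation_mean = 0,
                             detection_efficiency = 1,
                             rng_seed = 1L) {
  emission_means <- as.matrix(emission_means)
  assert_that(frame_interval > 0, "frame_interval must be positive")
  assert_that(n_lineages >= 0, "n_lineages must be non-negative")
  assert_that(trace_length >= 1 || n_lineages == 0,
              "trace_length must be at least 1")
  assert_that(cell_cycle_mean > 0, "cell_cycle_mean must be positive")
  assert_that(cell_cycle_sd >= 0, "cell_cycle_sd must be non-negative")
  assert_that(ncol(emission_means) == 2,
              "emission_means must have two columns (cro, ci)")
  assert_that(all(emission_means >= 0), "emission means must be >= 0")
  assert_that(length(dwell_means) == nrow(emission_means),
              "dwell_means must have one entry per state")
  assert_that(all(dwell_means >= frame_interval),
              "dwell means must be at least one frame interval")
  if (!is.null(stationary_targets)) {
    assert_that(length(stationary_targets) == nrow(emission_means),
                "stationary_targets must have one entry per state")
    assert_that(abs(sum(stationary_targets) - 1) < 1e-8,
                "stationary_targets must sum to 1")
    assert_that(all(stationary_targets >= 0),
                "stationary_targets must be non-negative")
  }
  assert_that(maturation_mean >= 0, "maturation_mean must be >= 0")
  assert_that(detection_efficiency > 0 && detection_efficiency <= 1,
              "detection_efficiency must be in (0, 1]")
  cfg <- list(frame_interval = frame_interval, n_lineages = n_lineages,
              trace_length = trace_length, cell_cycle_mean = cell_cycle_mean,
              cell_cycle_sd = cell_cycle_sd, emission_means = emission_means,
              dwell_means = dwell_means,
              stationary_targets = stationary_targets,
              maturation_mean = maturation_mean,
              detection_efficiency = detection_efficiency,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Default per-state production means of the four-state switch
#'
#' Rows are the production states \code{[L,L]}, \code{[H,L]}, \code{[L,H]},
#' \code{[H,H]}; columns are mean newly produced (Cro, CI) molecules per
#' 5-min frame.
#' @return a 4 x 2 numeric matrix.
#' @export
default_emission_means <- function() {
  m <- rbind(LL = c(0.0, 0.0), HL = c(5.2, 0.0),
             LH = c(0.0, 4.7), HH = c(4.5, 4.7))
  colnames(m) <- c("cro", "ci")
  m
}

#' Configuration of the mechanistic operator-occupancy simulator
#'
#' Parameters of the exact stochastic (Gillespie) simulation of repressor
#' binding at the three right operators. Binding propensities are
#' per-molecule rate constants multiplied by the current free repressor copy
#' number, which closes the mutual-repression feedback; `adiabaticity_scale`
#' multiplies all binding and unbinding rates and interpolates between the
#' slow-binding (non-adiabatic) and fast-binding (adiabatic) regimes.
#'
#' Defaults are illustrative, not fitted: transcription/translation rates are
#' set so a fully active promoter yields the observed per-frame production
#' means (5.2 Cro, 4.7 CI per 5 min), the mRNA lifetime is 1.5 min, and
#' dilution matches a 71-min doubling time.
#'
#' @param kon_ci,kon_cro per-operator binding rate constants for CI and Cro
#'   at (O_R1, O_R2, O_R3), in 1/min per free molecule.
#' @param koff_ci,koff_cro unbinding rates (1/min).
#' @param k_tx_r,k_tx_rm transcription initiation rates of P_R (cro) and
#'   P_RM (cI) when unobstructed (1/min).
#' @param mrna_lifetime mean mRNA lifetime in minutes.
#' @param burst_size mean proteins translated per mRNA.
#' @param dilution first-order protein dilution rate (1/min).
#' @param adiabaticity_scale multiplier on all binding/unbinding rates.
#' @param p_ci0,p_cro0 initial free protein copy numbers.
#' @param rng_seed integer seed recorded with the configuration.
#' @return an object of class `mechanism_config`.
#' @export
mechanism_config <- function(kon_ci = c(8e-4, 8e-4, 2e-5),
                             kon_cro = c(5e-5, 5e-5, 8e-4),
                             koff_ci = 0.005, koff_cro = 0.01,
                             k_tx_r = 0.8, k_tx_rm = 0.723,
                             mrna_lifetime = 1.5, burst_size = 1.3,
                             dilution = log(2) / 71,
                             adiabaticity_scale = 1,
                             p_ci0 = 0, p_cro0 = 0,
                             rng_seed = 1L) {
  rates <- c(kon_ci, kon_cro, koff_ci, koff_cro, k_tx_r, k_tx_rm,
             burst_size, dilution, adiabaticity_scale)
  assert_that(all(rates >= 0), "all rates must be >= 0")
  assert_that(length(kon_ci) == 3 && length(kon_cro) == 3,
              "binding rates must be given per operator (length 3)")
  assert_that(mrna_lifetime > 0, "mRNA lifetime must be positive")
  cfg <- list(kon_ci = kon_ci, kon_cro = kon_cro, koff_ci = koff_ci,
              koff_cro = koff_cro, k_tx_r = k_tx_r, k_tx_rm = k_tx_rm,
              mrna_lifetime = mrna_lifetime, burst_size = burst_size,
              dilution = dilution, adiabaticity_scale = adiabaticity_scale,
              p_ci0 = as.integer(p_ci0), p_cro0 = as.integer(p_cro0),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "mechanism_config"
  cfg
}
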