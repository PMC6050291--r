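#' Hidden Markov model of bivariate production counts
#'
#' Container for a K-state HMM whose emissions are, per state, independent
#' counts in the two reporter channels (Cro, CI). The default emission
#' family is Poisson per channel; a negative-binomial family with a shared
#' dispersion is available for overdispersed data.
#'
#' @param means K x 2 matrix of per-state emission means, columns
#'   \code{(cro, ci)} in molecules per frame.
#' @param A K x K row-stochastic per-frame transition matrix.
#' @param pi initial state distribution (defaults to the stationary
#'   distribution of `A`).
#' @param frame_interval frame interval in minutes.
#' @param family `"poisson"` or `"nbinom"`.
#' @param size negative-binomial size (dispersion) parameter, shared across
#'   states and channels; ignored for the Poisson family.
#' @return an object of class `switch_hmm`.
#' @export
hmm_model <- function(means, A, pi = NULL, frame_interval = 5,
                      family = c("poisson", "nbinom"), size = 10) {
  family <- match.arg(family)
  means <- as.matrix(means)
  K <- nrow(means)
  assert_that(K >= 1, "need at least one state")
  assert_that(ncol(means) == 2, "means must have two columns (cro, ci)")
  assert_that(all(means >= 0), "emission means must be >= 0")
  if (K == 1) A <- matrix(1, 1, 1)
  validate_stochastic(A)
  assert_that(nrow(A) == K, "transition matrix size must match means")
  if (is.null(pi)) pi <- stationary_distribution(A)
  assert_that(length(pi) == K && abs(sum(pi) - 1) < 1e-6 && all(pi >= 0),
              "pi must be a probability vector over the states")
  m <- list(K = K, means = means, A = A, pi = pi / sum(pi),
            frame_interval = frame_interval, family = family, size = size)
  class(m) <- "switch_hmm"
  m
}

#' The default four-state production model of the lambda switch
#'
#' States \code{[L,L]}, \code{[H,L]}, \code{[L,H]}, \code{[H,H]} with
#' per-frame (Cro, CI) emission means (0,0), (5.2,0), (0,4.7), (4.5,4.7),
#' dwell times (7, 36, 127, 47) min, and stationary frame fractions
#' 391:1733:3145:3069. The transition matrix is calibrated with
#' [build_transition_matrix()].
#'
#' @param config a [generator_config()]; its emission means, dwell means,
#'   stationary targets and frame interval define the model.
#' @return a `switch_hmm`.
#' @export
default_switch_model <- function(config = generator_config()) {
  targets <- config$stationary_targets
  if (is.null(targets)) {
    # without targets, fall back to the dwell-consistent chain with
    # uniform off-diagonal splits
    diagA <- 1 - config$frame_interval / config$dwell_means
    K <- length(config$dwell_means)
    A <- diag(diagA, K)
    for (k in seq_len(K)) A[k, -k] <- (1 - diagA[k]) / (K - 1)
    return(hmm_model(config$emission_means, A,
                     frame_interval = config$frame_interval))
  }
  tm <- build_transition_matrix(config$dwell_means, targets,
                                config$frame_interval)
  hmm_model(config$emission_means, tm$A, pi = tm$stationary,
            frame_interval = config$frame_interval)
}

#' @export
print.switch_hmm <- function(x, ...) {
  cat(sprintf("switch_hmm: %d states, %s emissions, frame interval %g min\n",
              x$K, x$family, x$frame_interval))
  tab <- cbind(round(x$means, 3), diag = round(diag(x$A), 4),
               pi = round(x$pi, 4))
  rownames(tab) <- state_labels(x$means)
  print(tab)
  invisible(x)
}

#' Name production states from their emission means
#'
#' Each channel is called high (`H`) when its fitted mean exceeds half the
#' largest mean of that channel across states, low (`L`) otherwise; labels
#' are `[Cro, CI]` pairs such as `"HL"`.
#'
#' @param means K x 2 matrix of emission means, columns `(cro, ci)`.
#' @return a character vector of labels.
#' @export
state_labels <- function(means) {
  means <- as.matrix(means)
  lab <- function(v) {
    thr <- max(v) / 2
    ifelse(v > thr & max(v) > 0, "H", "L")
  }
  paste0(lab(means[, 1]), lab(means[, 2]))
}

# per-frame log emission probabilities: T x K matrix
emission_logprob <- function(model, counts) {
  counts <- as.matrix(counts)
  K <- model$K
  out <- matrix(0, nrow(counts), K)
  for (k in seq_len(K)) {
    if (model$family == "poisson") {
      out[, k] <- dpois(counts[, 1], model$means[k, 1], log = TRUE) +
        dpois(counts[, 2], model$means[k, 2], log = TRUE)
    } else {
      out[, k] <- dnbinom(counts[, 1], mu = max(model$means[k, 1], 1e-8),
                          size = model$size, log = TRUE) +
        dnbinom(counts[, 2], mu = max(model$means[k, 2], 1e-8),
                size = model$size, log = TRUE)
    }
  }
  # lambda == 0 makes dpois(0, 0) = 1 and dpois(k > 0, 0) = 0 (log -Inf),
  # which the scaled recursions handle
  out
}
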