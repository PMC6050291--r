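#' Per-state dwell-time statistics from decoded traces
#'
#' A dwell is a maximal run of consecutive frames decoded in one state;
#' its duration is (run length) x frame interval. Three censoring policies
#' are available for runs that touch a trace end or a filtered-segment
#' boundary, where the true dwell is only partially observed:
#' \describe{
#'   \item{`"uncensored"`}{(default) exclude runs touching either end;
#'     unbiased only when dwells are much shorter than traces.}
#'   \item{`"all"`}{include every run.}
#'   \item{`"exit_rate"`}{total decoded time in the state divided by the
#'     number of observed exits from it; the maximum-likelihood rate
#'     estimator under geometric dwells, robust to censoring and the
#'     recommended policy when dwells are comparable to the trace length.}
#' }
#'
#' @param decoded a [viterbi()] result or list of them.
#' @param frame_interval minutes per frame (default: taken from `decoded`).
#' @param policy censoring policy (see above).
#' @return data.frame with one row per visited state: `state`,
#'   `n_occurrences` (runs used), `n_frames`, `mean_dwell_min`, `se_min`.
#'   States never visited are absent.
#' @export
dwell_times <- function(decoded, frame_interval = NULL,
                        policy = c("uncensored", "all", "exit_rate")) {
  policy <- match.arg(policy)
  dec <- if (inherits(decoded, "decoded_trace")) list(decoded) else decoded
  if (is.null(frame_interval)) {
    frame_interval <- dec[[1]]$frame_interval %||% 5
  }
  segs <- do.call(rbind, lapply(dec, `[[`, "segments"))
  states <- sort(unique(segs$state))
  rows <- lapply(states, function(s) {
    runs <- segs[segs$state == s, , drop = FALSE]
    n_frames <- sum(runs$length)
    if (policy == "exit_rate") {
      n_exit <- sum(!runs$censored_right)
      if (n_exit == 0) {
        return(data.frame(state = s, n_occurrences = 0L,
                          n_frames = n_frames,
                          mean_dwell_min = NA_real_, se_min = NA_real_))
      }
      m <- n_frames * frame_interval / n_exit
      return(data.frame(state = s, n_occurrences = n_exit,
                        n_frames = n_frames, mean_dwell_min = m,
                        se_min = m / sqrt(n_exit)))
    }
    if (policy == "uncensored") {
      runs <- runs[!runs$censored_left & !runs$censored_right, , drop = FALSE]
    }
    if (nrow(runs) == 0) {
      return(data.frame(state = s, n_occurrences = 0L, n_frames = n_frames,
                        mean_dwell_min = NA_real_, se_min = NA_real_))
    }
    d <- runs$length * frame_interval
    data.frame(state = s, n_occurrences = nrow(runs), n_frames = n_frames,
               mean_dwell_min = mean(d),
               se_min = if (nrow(runs) > 1) sd(d) / sqrt(nrow(runs))
                        else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transition time constants between decoded states
#'
#' tau_ij = (total decoded time in state i) / (number of observed i -> j
#' switches): the mean occupancy time of i per i -> j transition, the
#' inverse of the i -> j switching rate. Pairs without observed switches
#' are reported as `NA` with a zero count. By construction
#' `1 / sum_j (1/tau_ij)` equals the exit-rate dwell time of state i.
#'
#' @param decoded a [viterbi()] result or list of them.
#' @param frame_interval minutes per frame (default: from `decoded`).
#' @param K number of states (default: largest decoded label).
#' @return list with `tau` (K x K matrix, minutes, `NA` diagonal),
#'   `n_switches` (K x K integer matrix), `time_in_state` (minutes).
#' @export
transition_time_constants <- function(decoded, frame_interval = NULL,
                                      K = NULL) {
  dec <- if (inherits(decoded, "decoded_trace")) list(decoded) else decoded
  if (is.null(frame_interval)) {
    frame_interval <- dec[[1]]$frame_interval %||% 5
  }
  if (is.null(K)) K <- max(vapply(dec, function(d) max(d$states), 0L))
  n_sw <- matrix(0L, K, K)
  time_in <- numeric(K)
  for (d in dec) {
    segs <- d$segments
    time_in_d <- tabulate(rep(segs$state, segs$length), nbins = K)
    time_in <- time_in + time_in_d * frame_interval
    # switches: consecutive runs within the same decoded segment block.
    # Runs were emitted per independent segment; a censored_right = FALSE
    # run is followed by the next run in the same chain.
    for (i in seq_len(nrow(segs) - 1)) {
      if (!segs$censored_right[i]) {
        n_sw[segs$state[i], segs$state[i + 1]] <-
          n_sw[segs$state[i], segs$state[i + 1]] + 1L
      }
    }
  }
  tau <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i != j && n_sw[i, j] > 0) tau[i, j] <- time_in[i] / n_sw[i, j]
  }
  list(tau = tau, n_switches = n_sw, time_in_state = time_in)
}

#' Transition time constants implied by a transition matrix
#'
#' Analytic counterpart of [transition_time_constants()]: per frame spent in
#' state i the expected number of i -> j switches is A_ij, so
#' tau_ij = frame_interval / A_ij.
#'
#' @param model a `switch_hmm`.
#' @return K x K matrix of minutes (`NA` diagonal and impossible pairs).
#' @export
tau_from_model <- function(model) {
  if (inherits(model, "switch_hmm_fit")) model <- model$model
  tau <- model$frame_interval / model$A
  diag(tau) <- NA_real_
  tau[model$A == 0] <- NA_real_
  tau
}

#' Kinetics summary of a fitted model and its decoded traces
#'
#' Mirrors the per-state table of the analysis: mean production per
#' channel, frames, dwell time with standard error, occurrences, plus the
#' pairwise transition time-constant matrix.
#'
#' @param fit a `switch_hmm_fit` (or `switch_hmm`).
#' @param traces the traces to decode.
#' @param dwell_policy censoring policy for [dwell_times()].
#' @return a `kinetics_summary`: list with `states` (data.frame state,
#'   label, mean_cro, mean_ci, n_frames, dwell_min, dwell_se, occurrences),
#'   `tau` (matrix), `tau_model` (matrix from the fitted A), `n_switches`.
#' @export
kinetics_summary <- function(fit, traces,
                             dwell_policy = c("uncensored", "all",
                                              "exit_rate")) {
  dwell_policy <- match.arg(dwell_policy)
  model <- if (inherits(fit, "switch_hmm_fit")) fit$model else fit
  decoded <- decode_traces(model, traces)
  dw <- dwell_times(decoded, policy = dwell_policy)
  tt <- transition_time_constants(decoded, K = model$K)
  labels <- state_labels(model$means)
  states <- data.frame(state = seq_len(model$K), label = labels,
                       mean_cro = model$means[, 1],
                       mean_ci = model$means[, 2],
                       n_frames = 0L, dwell_min = NA_real_,
                       dwell_se = NA_real_, occurrences = 0L)
  for (i in seq_len(nrow(dw))) {
    s <- dw$state[i]
    states$n_frames[s] <- dw$n_frames[i]
    states$dwell_min[s] <- dw$mean_dwell_min[i]
    states$dwell_se[s] <- dw$se_min[i]
    states$occurrences[s] <- dw$n_occurrences[i]
  }
  structure(list(states = states, tau = tt$tau,
                 tau_model = tau_from_model(model),
                 n_switches = tt$n_switches,
                 dwell_policy = dwell_policy),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat("Per-state production and dwell statistics",
      sprintf("(dwell policy: %s)\n", x$dwell_policy))
  df <- x$states
  df$mean_cro <- round(df$mean_cro, 2); df$mean_ci <- round(df$mean_ci, 2)
  df$dwell_min <- round(df$dwell_min, 1); df$dwell_se <- round(df$dwell_se, 1)
  print(df, row.names = FALSE)
  cat("\nTransition time constants tau_ij (min, decoded):\n")
  print(round(x$tau, 1))
  invisible(x)
}

#' Match fitted states to reference states by emission means
#'
#' Finds the permutation of fitted states minimizing the total Euclidean
#' distance between fitted and reference emission-mean pairs (exhaustive
#' over permutations; intended for small K).
#'
#' @param fitted_means,reference_means K x 2 matrices.
#' @return integer permutation `p` such that fitted state `p[k]` matches
#'   reference state `k`.
#' @export
match_states <- function(fitted_means, reference_means) {
  K <- nrow(reference_means)
  assert_that(nrow(fitted_means) == K, "state counts differ")
  perms <- permutations(K)
  cost <- apply(perms, 1, function(p) {
    sum((fitted_means[p, , drop = FALSE] - reference_means)^2)
  })
  perms[which.min(cost), ]
}

permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}
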