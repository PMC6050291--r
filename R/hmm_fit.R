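# --- observation plumbing ---------------------------------------------------

# Normalize traces into observation segments: a list of integer T x 2 count
# matrices plus bookkeeping. A `segment` column (from young-cell filtering)
# breaks the Markov chain; cell divisions do not.
as_segments <- function(traces) {
  trs <- if (inherits(traces, "trace_set") || (is.list(traces) &&
             !is.data.frame(traces))) traces else list(traces)
  segs <- list()
  for (li in seq_along(trs)) {
    tr <- trs[[li]]
    if (is.matrix(tr)) tr <- data.frame(cro_count = tr[, 1], ci_count = tr[, 2])
    sid <- if ("segment" %in% names(tr)) tr$segment else rep(1L, nrow(tr))
    for (s in unique(sid)) {
      rows <- which(sid == s)
      segs[[length(segs) + 1]] <- list(
        counts = cbind(cro = as.integer(tr$cro_count[rows]),
                       ci = as.integer(tr$ci_count[rows])),
        trace = li, segment = s, rows = rows)
    }
  }
  segs
}

# --- likelihood -------------------------------------------------------------

#' Log-likelihood of traces under an HMM
#'
#' Scaled forward recursion; the per-frame emission probability is the
#' product of the two channels' count pmfs given the state. Segments (and
#' separate traces) are treated as independent chains, each starting from
#' the model's initial distribution.
#'
#' @param model a [hmm_model()].
#' @param traces a `trace_set`, single trace, data.frame or T x 2 count
#'   matrix.
#' @return the total log-likelihood (scalar). `-Inf` (with a warning) when
#'   some frame is impossible under every state.
#' @export
loglikelihood <- function(model, traces) {
  segs <- as_segments(traces)
  assert_that(length(segs) > 0, "no observations")
  ll <- 0
  for (sg in segs) {
    fb <- hmm_forward_backward(emission_logprob(model, sg$counts),
                               model$A, model$pi, FALSE)
    if (isTRUE(fb$degenerate)) {
      warning("a frame has zero emission probability under every state")
      return(-Inf)
    }
    ll <- ll + fb$loglik
  }
  ll
}

# --- Baum-Welch -------------------------------------------------------------

#' Fit a K-state HMM by Baum-Welch EM
#'
#' Multi-restart expectation-maximization over all trace segments. Emission
#' means are initialized by k-means on the pooled (cro, ci) counts (later
#' restarts perturb the centers), the transition matrix starts sticky
#' (diagonal 0.9), and the best non-degenerate restart is returned. The EM
#' objective is monotone non-decreasing; a restart in which some state's
#' expected occupancy falls below one frame is flagged degenerate and
#' excluded if any clean restart exists.
#'
#' @param traces observations (see [loglikelihood()]).
#' @param K number of states.
#' @param n_restarts number of EM restarts (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param seed integer seed; restart r uses `derive_seed(seed, r)`.
#' @param frame_interval minutes per frame for the fitted model.
#' @param family emission family, `"poisson"` (default) or `"nbinom"`.
#' @return a `switch_hmm_fit`: list with `model` (a `switch_hmm`), `loglik`,
#'   `loglik_path`, `converged`, `n_iter`, `restarts` (data.frame of restart
#'   scores and degeneracy flags), `n_frames`.
#' @export
fit_em <- function(traces, K, n_restarts = 10, tol = 1e-6, max_iter = 500,
                   seed = 1L, frame_interval = NULL,
                   family = c("poisson", "nbinom")) {
  family <- match.arg(family)
  assert_that(K >= 1, "K must be at least 1")
  segs <- as_segments(traces)
  assert_that(length(segs) > 0, "need at least one trace")
  if (is.null(frame_interval)) {
    frame_interval <- attr(traces, "frame_interval") %||% 5
  }
  pooled <- do.call(rbind, lapply(segs, `[[`, "counts"))
  n_frames <- nrow(pooled)
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, r))
    init <- init_params(pooled, K, jitter = r > 1)
    fits[[r]] <- em_once(segs, init, K, tol, max_iter, frame_interval, family)
  }
  scores <- vapply(fits, `[[`, 0, "loglik")
  degen <- vapply(fits, `[[`, TRUE, "degenerate")
  usable <- if (any(!degen)) which(!degen) else seq_len(n_restarts)
  best <- usable[which.max(scores[usable])]
  out <- fits[[best]]
  out$restarts <- data.frame(restart = seq_len(n_restarts), loglik = scores,
                             degenerate = degen, selected =
                               seq_len(n_restarts) == best)
  out$n_frames <- n_frames
  class(out) <- "switch_hmm_fit"
  out
}

init_params <- function(pooled, K, jitter = FALSE) {
  if (K == 1) {
    centers <- matrix(colMeans(pooled), 1, 2)
  } else {
    km <- tryCatch(
      suppressWarnings(kmeans(pooled + matrix(runif(length(pooled), 0, 1e-3),
                                              nrow(pooled)), K, nstart = 3)),
      error = function(e) NULL)
    centers <- if (!is.null(km)) km$centers
               else pooled[sample.int(nrow(pooled), K), , drop = FALSE]
  }
  centers <- pmax(centers, 0)
  if (jitter) {
    centers <- centers * matrix(runif(length(centers), 0.5, 1.5),
                                nrow(centers))
    centers <- centers + matrix(runif(length(centers), 0, 0.5),
                                nrow(centers))
  }
  A <- matrix(0.1 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.9 else 1
  list(means = pmax(centers, 1e-4), A = A, pi = rep(1 / K, K))
}

em_once <- function(segs, init, K, tol, max_iter, frame_interval, family) {
  means <- init$means; A <- init$A; pi <- init$pi
  size <- 10
  ll_path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    model <- hmm_model(means, A, pi, frame_interval, family, size)
    gsum <- matrix(0, K, 1)
    gxsum <- matrix(0, K, 2)
    xisum <- matrix(0, K, K)
    g1sum <- numeric(K)
    ll <- 0
    bad <- FALSE
    for (sg in segs) {
      fb <- hmm_forward_backward(emission_logprob(model, sg$counts),
                                 A, pi, TRUE)
      if (isTRUE(fb$degenerate)) { bad <- TRUE; break }
      ll <- ll + fb$loglik
      gsum <- gsum + matrix(colSums(fb$gamma), K)
      gxsum <- gxsum + t(fb$gamma) %*% sg$counts
      xisum <- xisum + fb$xi_sum
      g1sum <- g1sum + fb$gamma[1, ]
    }
    if (bad) {
      return(list(model = model, loglik = -Inf, loglik_path = ll_path,
                  converged = FALSE, n_iter = iter, degenerate = TRUE))
    }
    ll_path <- c(ll_path, ll)
    if (is.finite(ll_old) &&
        (ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    means <- pmax(gxsum / as.vector(gsum), 1e-6)
    means[!is.finite(means)] <- 1e-6
    rs <- rowSums(xisum)
    for (k in seq_len(K)) {
      A[k, ] <- if (rs[k] > 0) xisum[k, ] / rs[k]
                else { row <- rep(0, K); row[k] <- 1; row }
    }
    pi <- g1sum / sum(g1sum)
    if (family == "nbinom") {
      size <- estimate_nb_size(segs, means, gsum, gxsum)
    }
  }
  model <- hmm_model(means, A, pi, frame_interval, family, size)
  degenerate <- any(gsum < 1)
  list(model = model, loglik = ll_path[length(ll_path)],
       loglik_path = ll_path, converged = converged,
       n_iter = length(ll_path), degenerate = degenerate)
}

# crude shared-dispersion estimate by method of moments on pooled residuals
estimate_nb_size <- function(segs, means, gsum, gxsum) {
  pooled <- do.call(rbind, lapply(segs, `[[`, "counts"))
  m <- colMeans(pooled); v <- apply(pooled, 2, var)
  excess <- max(mean((v - m) / pmax(m^2, 1e-8)), 1e-3)
  min(1 / excess, 1e4)
}

#' @export
print.switch_hmm_fit <- function(x, ...) {
  cat(sprintf("switch_hmm_fit: K = %d, loglik = %.2f, %s after %d iterations\n",
              x$model$K, x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(x$model)
  invisible(x)
}

# --- model selection --------------------------------------------------------

#' Select the number of production states
#'
#' Fits an HMM for each K in `K_range` and scores the fits two ways:
#' `bic` = -2 logL + p log(n) with p = K^2 + 2K - 1 free parameters, and
#' `histmatch` = total-variation distance between the model's stationary
#' predicted 2D production histogram and the observed one. The BIC rule
#' picks the minimum; the histogram-match rule picks the smallest K whose
#' distance is within `hist_margin` (default 1.2x) of the best distance,
#' a parsimony margin that stops indistinguishable refits from inflating K.
#'
#' @param traces observations.
#' @param K_range integer vector of candidate state counts.
#' @param criterion which rule decides `K_selected`: `"bic"` (default) or
#'   `"histmatch"`; both scores are always reported.
#' @param n_restarts EM restarts per K (default 5).
#' @param max_count histogram truncation for the histogram-match score.
#' @param hist_margin multiplicative parsimony margin (default 1.2).
#' @param seed integer seed.
#' @param ... passed to [fit_em()].
#' @return list with `K_selected`, `K_bic`, `K_histmatch`, `scores`
#'   (data.frame K, loglik, n_params, bic, tv_distance), `fits`.
#' @export
select_model <- function(traces, K_range, criterion = c("bic", "histmatch"),
                         n_restarts = 5, max_count = 14, hist_margin = 1.2,
                         seed = 1L, ...) {
  criterion <- match.arg(criterion)
  assert_that(length(K_range) > 0, "K_range must be non-empty")
  obs_hist <- histogram2d(traces, max_count)
  n <- obs_hist$n_frames
  fits <- list(); rows <- list()
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- fit_em(traces, K, n_restarts = n_restarts,
                  seed = derive_seed(seed, 1000 + K), ...)
    p <- K^2 + 2 * K - 1
    pred <- predicted_histogram(fit$model, max_count)
    tv <- sum(abs(pred$prob - obs_hist$prob)) / 2
    fits[[as.character(K)]] <- fit
    rows[[i]] <- data.frame(K = K, loglik = fit$loglik, n_params = p,
                            bic = -2 * fit$loglik + p * log(n),
                            tv_distance = tv)
  }
  scores <- do.call(rbind, rows)
  K_bic <- scores$K[which.min(scores$bic)]
  ok <- scores$tv_distance <= hist_margin * min(scores$tv_distance)
  K_hist <- min(scores$K[ok])
  list(K_selected = if (criterion == "bic") K_bic else K_hist,
       K_bic = K_bic, K_histmatch = K_hist, scores = scores, fits = fits)
}

# --- decoding ---------------------------------------------------------------

#' Viterbi decoding of a trace
#'
#' Maximum-a-posteriori state path (ties broken toward the lower state
#' index) plus forward-backward posterior state probabilities, per segment.
#' Segments are decoded independently; segment boundaries and trace ends
#' set the censoring flags of the segment table.
#'
#' @param model a `switch_hmm` (or `switch_hmm_fit`).
#' @param trace a single trace (data.frame / `lineage_trace` / T x 2
#'   matrix).
#' @return a `decoded_trace`: list with `states` (per-frame integer path),
#'   `posterior` (T x K matrix), `segments` (data.frame state, start,
#'   length, censored_left, censored_right), `frame_interval`.
#' @export
viterbi <- function(model, trace) {
  if (inherits(model, "switch_hmm_fit")) model <- model$model
  segs <- as_segments(trace)
  n_total <- sum(vapply(segs, function(s) nrow(s$counts), 0L))
  states <- integer(n_total)
  post <- matrix(NA_real_, n_total, model$K)
  seg_rows <- list()
  off <- 0
  for (sg in segs) {
    logB <- emission_logprob(model, sg$counts)
    path <- hmm_viterbi_path(logB, model$A, model$pi)
    fb <- hmm_forward_backward(logB, model$A, model$pi, TRUE)
    Tn <- length(path)
    states[off + seq_len(Tn)] <- path
    if (!isTRUE(fb$degenerate)) post[off + seq_len(Tn), ] <- fb$gamma
    runs <- rle(path)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    seg_rows[[length(seg_rows) + 1]] <- data.frame(
      state = runs$values, start = off + starts, length = runs$lengths,
      censored_left = starts == 1, censored_right = ends == Tn)
    off <- off + Tn
  }
  structure(list(states = states, posterior = post,
                 segments = do.call(rbind, seg_rows),
                 frame_interval = model$frame_interval),
            class = "decoded_trace")
}

#' Decode every trace of a set
#'
#' @param model a `switch_hmm` or `switch_hmm_fit`.
#' @param traces a `trace_set`.
#' @return list of [viterbi()] results.
#' @export
decode_traces <- function(model, traces) {
  trs <- if (inherits(traces, "trace_set") || (is.list(traces) &&
             !is.data.frame(traces))) traces else list(traces)
  lapply(trs, function(tr) viterbi(model, tr))
}

# --- predicted histogram ----------------------------------------------------

#' Stationary predicted 2D production histogram of a model
#'
#' Closed form, no sampling: P(c, i) = sum_k pi~_k pmf_k(c) pmf_k(i) with
#' pi~ the stationary distribution of the transition matrix, on the same
#' truncated grid as [histogram2d()] (tail mass pooled into the top bin).
#'
#' @param model a `switch_hmm`.
#' @param max_count top bin (default 14).
#' @return a `prod_hist2d` (with `n_frames = 0`, it is a model quantity).
#' @export
predicted_histogram <- function(model, max_count = 14) {
  if (inherits(model, "switch_hmm_fit")) model <- model$model
  pis <- stationary_distribution(model$A)
  if (any(!is.finite(pis)) || abs(sum(pis) - 1) > 1e-6) {
    stop("transition matrix has no unique stationary distribution",
         call. = FALSE)
  }
  grid <- 0:max_count
  pmf <- function(lam) {
    p <- dpois(grid, lam)
    p[length(p)] <- p[length(p)] + ppois(max_count, lam, lower.tail = FALSE)
    p
  }
  P <- matrix(0, max_count + 1, max_count + 1,
              dimnames = list(cro = grid, ci = grid))
  for (k in seq_len(model$K)) {
    if (model$family == "poisson") {
      pc <- pmf(model$means[k, 1]); pi_ <- pmf(model$means[k, 2])
    } else {
      pc <- dnbinom(grid, mu = max(model$means[k, 1], 1e-8), size = model$size)
      pc[length(pc)] <- pc[length(pc)] + max(0, 1 - sum(pc))
      pi_ <- dnbinom(grid, mu = max(model$means[k, 2], 1e-8), size = model$size)
      pi_[length(pi_)] <- pi_[length(pi_)] + max(0, 1 - sum(pi_))
    }
    P <- P + pis[k] * outer(pc, pi_)
  }
  structure(list(prob = P, counts = NULL, n_frames = 0L,
                 max_count = max_count), class = "prod_hist2d")
}
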