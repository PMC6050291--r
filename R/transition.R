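#' Build a per-frame transition matrix from dwell times and targets
#'
#' Calibrates the hidden-chain transition matrix from observable summaries:
#' the diagonal is fixed by the geometric mean dwell time of each state,
#' \eqn{dwell_k = \Delta t / (1 - A_{kk})}, and the off-diagonal entries are
#' solved by non-negative least squares so that the chain's stationary
#' distribution matches `stationary_targets`, with ties broken toward a
#' uniform split of each row's off-diagonal mass.
#'
#' @param dwell_means per-state mean dwell times in minutes (`Inf` allowed,
#'   giving an absorbing state).
#' @param stationary_targets target stationary frame fractions (sum to 1).
#' @param frame_interval frame interval in minutes.
#' @return a list with elements `A` (row-stochastic matrix), `stationary`
#'   (achieved stationary distribution), `dwell_means`, `frame_interval`.
#' @export
build_transition_matrix <- function(dwell_means, stationary_targets,
                                    frame_interval = 5) {
  K <- length(dwell_means)
  assert_that(K >= 2, "need at least two states")
  assert_that(length(stationary_targets) == K,
              "stationary_targets must match dwell_means in length")
  assert_that(all(dwell_means >= frame_interval),
              "dwell means must be at least one frame interval")
  assert_that(abs(sum(stationary_targets) - 1) < 1e-8,
              "stationary_targets must sum to 1")
  pi0 <- stationary_targets
  diagA <- ifelse(is.infinite(dwell_means), 1, 1 - frame_interval / dwell_means)
  r <- 1 - diagA                      # per-frame exit probability
  flow <- pi0 * r                     # stationary exit flux per state
  # transportation feasibility with a forbidden diagonal: each state's
  # outflow must be absorbable by the others' outflows
  bad <- which(flow > sum(flow) - flow + 1e-12)
  if (length(bad)) {
    stop(sprintf(
      "infeasible stationary targets: state %d requires more outflow (%g) than all other states can return (%g)",
      bad[1], flow[bad[1]], sum(flow) - flow[bad[1]]), call. = FALSE)
  }
  A <- diag(diagA, K)
  if (sum(flow) > 0) {
    Fm <- solve_flow_ls(flow, K)
    off <- Fm / pi0                   # A_kj = F_kj / pi_k
    off[pi0 == 0, ] <- 0
    A <- A + off
    # states with zero stationary mass but finite dwell still need a valid
    # row: split the exit mass uniformly (their row cannot affect pi)
    for (k in which(pi0 == 0 & r > 0)) {
      A[k, -k] <- r[k] / (K - 1)
    }
  }
  # renormalize rows against numerical drift
  A <- A / rowSums(A)
  dimnames(A) <- list(names(dwell_means), names(dwell_means))
  list(A = A, stationary = stationary_distribution(A),
       dwell_means = dwell_means, frame_interval = frame_interval)
}

# Solve for the stationary flow matrix F (zero diagonal, F_kj >= 0) with
# row sums and column sums both equal to `flow`, minimizing the squared
# distance to a uniform split of each row. Equality-constrained quadratic
# program with identity Hessian, solved by KKT elimination plus an active
# set on the non-negativity bounds.
solve_flow_ls <- function(flow, K) {
  idx <- which(upper.tri(matrix(0, K, K)) | lower.tri(matrix(0, K, K)),
               arr.ind = TRUE)
  n <- nrow(idx)
  u <- flow[idx[, 1]] / (K - 1)       # tie-break target: uniform row split
  # constraints: row sums (K) and column sums (K, one redundant -> drop last)
  C <- matrix(0, 2 * K - 1, n)
  d <- c(flow, flow[-K])
  for (e in seq_len(n)) {
    C[idx[e, 1], e] <- 1
    if (idx[e, 2] < K) C[K + idx[e, 2], e] <- 1
  }
  active <- rep(FALSE, n)
  for (iter in seq_len(n + 1)) {
    free <- !active
    Cf <- C[, free, drop = FALSE]
    # drop linearly dependent constraint rows (e.g. K = 2 degeneracy)
    qrC <- qr(t(Cf))
    rows <- qrC$pivot[seq_len(qrC$rank)]
    Cf <- Cf[rows, , drop = FALSE]
    df <- d[rows]
    # KKT: x_free = u_free + Cf' lambda ; Cf x_free = d
    M <- Cf %*% t(Cf)
    rhs <- df - Cf %*% u[free]
    lam <- tryCatch(solve(M, rhs), error = function(e) qr.solve(M, rhs))
    x <- numeric(n)
    x[free] <- u[free] + as.vector(t(Cf) %*% lam)
    if (all(x >= -1e-10)) {
      x[x < 0] <- 0
      if (max(abs(C %*% x - d)) > 1e-7)
        stop("no non-negative off-diagonal solution found", call. = FALSE)
      Fm <- matrix(0, K, K)
      Fm[idx] <- x
      return(Fm)
    }
    active[which.min(x)] <- TRUE
  }
  stop("no non-negative off-diagonal solution found", call. = FALSE)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Computed from the left eigenvector of eigenvalue 1.
#'
#' @param A row-stochastic matrix.
#' @return a probability vector.
#' @export
stationary_distribution <- function(A) {
  validate_stochastic(A)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8)) {
    # defensive fallback: power iteration from uniform
    v <- rep(1 / nrow(A), nrow(A))
    for (j in 1:10000) {
      v2 <- as.vector(v %*% A)
      conv <- max(abs(v2 - v)) < 1e-14
      v <- v2
      if (conv) break
    }
  }
  pmax(v, 0) / sum(pmax(v, 0))
}

validate_stochastic <- function(A, tol = 1e-8) {
  assert_that(is.matrix(A) && nrow(A) == ncol(A),
              "transition matrix must be square")
  assert_that(all(A >= -tol), "transition matrix entries must be >= 0")
  assert_that(max(abs(rowSums(A) - 1)) < tol,
              "transition matrix rows must sum to 1")
  invisible(TRUE)
}
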