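# shared fixtures, all built in code

table1_config <- function(...) generator_config(...)

table1_model <- function() default_switch_model(generator_config())

# small two-state model with well-separated channels
two_state_model <- function(p_stay = 0.9) {
  hmm_model(rbind(c(5, 0), c(0, 5)),
            matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2, 2,
                   byrow = TRUE))
}

# --- independent oracles ----------------------------------------------------

# brute-force HMM log-likelihood by explicit enumeration of all state paths
enumerate_loglik <- function(model, counts) {
  K <- model$K
  Tn <- nrow(counts)
  logB <- matrix(NA_real_, Tn, K)
  for (k in seq_len(K)) {
    logB[, k] <- dpois(counts[, 1], model$means[k, 1], log = TRUE) +
      dpois(counts[, 2], model$means[k, 2], log = TRUE)
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  total <- -Inf
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    lp <- log(model$pi[p[1]]) + logB[1, p[1]]
    if (Tn > 1) {
      for (t in 2:Tn) lp <- lp + log(model$A[p[t - 1], p[t]]) + logB[t, p[t]]
    }
    total <- max(total, lp) + log1p(exp(min(total, lp) - max(total, lp)))
  }
  total
}

# best path and its log-probability by enumeration
enumerate_viterbi <- function(model, counts) {
  K <- model$K
  Tn <- nrow(counts)
  logB <- matrix(NA_real_, Tn, K)
  for (k in seq_len(K)) {
    logB[, k] <- dpois(counts[, 1], model$means[k, 1], log = TRUE) +
      dpois(counts[, 2], model$means[k, 2], log = TRUE)
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- -Inf; best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    lp <- log(model$pi[p[1]]) + logB[1, p[1]]
    if (Tn > 1) {
      for (t in 2:Tn) lp <- lp + log(model$A[p[t - 1], p[t]]) + logB[t, p[t]]
    }
    if (lp > best + 1e-12) { best <- lp; best_path <- p }
  }
  list(logp = best, path = best_path)
}

# exact minimax barrier by threshold connectivity: the bottleneck height is
# the smallest level t such that {U <= t} connects a to b (8-neighborhood).
# Independent of the Dijkstra-style search used by the package.
threshold_minimax <- function(U, a, b) {
  levels <- sort(unique(as.vector(U)))
  levels <- levels[levels >= max(U[a[1], a[2]], U[b[1], b[2]])]
  for (t in levels) {
    open <- U <= t
    if (flood_connected(open, a, b)) return(t)
  }
  Inf
}

flood_connected <- function(open, a, b) {
  nr <- nrow(open); nc <- ncol(open)
  seen <- matrix(FALSE, nr, nc)
  stack <- list(a)
  seen[a[1], a[2]] <- TRUE
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (cur[1] == b[1] && cur[2] == b[2]) return(TRUE)
    for (dr in -1:1) for (dc in -1:1) {
      r <- cur[1] + dr; c <- cur[2] + dc
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          open[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        stack[[length(stack) + 1]] <- c(r, c)
      }
    }
  }
  FALSE
}

# exhaustive simple-path minimax on tiny grids (DFS), a second oracle
dfs_minimax <- function(U, a, b) {
  nr <- nrow(U); nc <- ncol(U)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  rec <- function(r, c, cur) {
    cur <- max(cur, U[r, c])
    if (cur >= best) return()
    if (r == b[1] && c == b[2]) { best <<- cur; return() }
    visited[r, c] <<- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && !visited[r2, c2]) {
        rec(r2, c2, cur)
      }
    }
    visited[r, c] <<- FALSE
  }
  rec(a[1], a[2], -Inf)
  best
}

# label landscape basins by their (cro, ci) quadrant
basin_quadrant <- function(basins, threshold = 2) {
  paste0(ifelse(basins$cro >= threshold, "H", "L"),
         ifelse(basins$ci >= threshold, "H", "L"))
}
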