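#' 2D production-count histogram
#'
#' Joint distribution of (Cro, CI) molecules newly produced per frame,
#' pooled over all frames of all traces. Unit-width integer bins from 0 to
#' `max_count`; counts beyond `max_count` are pooled into the top bin.
#'
#' @param traces a `trace_set`, `lineage_trace` or data.frame with
#'   `cro_count` and `ci_count` columns.
#' @param max_count top bin (default 14).
#' @return a `prod_hist2d`: list with `prob` ((max_count+1) square matrix,
#'   rows = Cro count, columns = CI count), `counts`, `n_frames`,
#'   `max_count`.
#' @export
histogram2d <- function(traces, max_count = 14) {
  df <- as_frame_table(traces)
  assert_that(!is.null(df) && nrow(df) > 0, "no frames to histogram")
  cro <- pmin(df$cro_count, max_count)
  ci <- pmin(df$ci_count, max_count)
  counts <- matrix(0L, max_count + 1, max_count + 1,
                   dimnames = list(cro = 0:max_count, ci = 0:max_count))
  tab <- table(factor(cro, levels = 0:max_count),
               factor(ci, levels = 0:max_count))
  counts[] <- as.integer(tab)
  structure(list(prob = counts / nrow(df), counts = counts,
                 n_frames = nrow(df), max_count = max_count),
            class = "prod_hist2d")
}

#' Potential landscape U = -ln P of a production histogram
#'
#' Empty bins are regularized with a pseudocount (default half a count per
#' bin, Jeffreys-style) so the potential is finite everywhere; the surface
#' is shifted so its minimum is zero.
#'
#' @param hist a [histogram2d()] or [predicted_histogram()] result.
#' @param pseudocount added to every bin, in units of counts (default 0.5).
#' @return a `potential_landscape`: list with `U` (matrix, natural-log
#'   units), `prob`, `pseudocount`, `n_frames`, `max_count`.
#' @export
potential <- function(hist, pseudocount = 0.5) {
  stopifnot(inherits(hist, "prod_hist2d"))
  if (pseudocount <= 0 && any(hist$prob == 0)) {
    stop("pseudocount must be positive when empty bins are present",
         call. = FALSE)
  }
  n <- max(hist$n_frames, 1)
  U <- -log(hist$prob + pseudocount / n)
  U <- U - min(U)
  structure(list(U = U, prob = hist$prob, pseudocount = pseudocount,
                 n_frames = hist$n_frames, max_count = hist$max_count),
            class = "potential_landscape")
}

#' Refine a landscape grid by spline interpolation
#'
#' Tensor-product interpolating cubic splines (rows, then columns); values
#' at the original nodes are preserved exactly. `factor = 1` returns the
#' input grid.
#'
#' @param landscape a `potential_landscape` (or bare matrix).
#' @param factor integer refinement factor (>= 1).
#' @return a list with `U` (refined matrix), `x`, `y` (bin coordinates of
#'   the refined grid, in original bin units).
#' @export
interpolate_landscape <- function(landscape, factor = 4) {
  U <- if (inherits(landscape, "potential_landscape")) landscape$U
       else as.matrix(landscape)
  assert_that(factor >= 1 && factor == round(factor),
              "factor must be a positive integer")
  nr <- nrow(U); nc <- ncol(U)
  x0 <- seq_len(nr) - 1; y0 <- seq_len(nc) - 1
  if (factor == 1 || nr < 2 || nc < 2) {
    return(list(U = U, x = x0, y = y0, factor = factor))
  }
  xr <- seq(0, nr - 1, by = 1 / factor)
  yr <- seq(0, nc - 1, by = 1 / factor)
  tmp <- matrix(0, length(xr), nc)
  for (j in seq_len(nc)) {
    tmp[, j] <- spline(x0, U[, j], xout = xr, method = "fmm")$y
  }
  out <- matrix(0, length(xr), length(yr))
  for (i in seq_len(length(xr))) {
    out[i, ] <- spline(y0, tmp[i, ], xout = yr, method = "fmm")$y
  }
  list(U = out, x = xr, y = yr, factor = factor)
}

#' Basins, saddles and minimax barriers of a potential landscape
#'
#' Basins are strict local minima of the grid (8-neighborhood), kept when
#' they hold at least `min_prob` of the probability mass (a production state
#' must be supported by a non-negligible fraction of frames) and survive a
#' persistence filter: a minimum whose minimax barrier to any deeper
#' minimum is below `min_depth` is treated as sampling noise and merged.
#'
#' The pairwise barrier is a minimax path statistic on the grid graph:
#' `barrier[i, j]` is the minimum over all 8-connected paths from basin i to
#' basin j of the maximum potential along the path, minus `U` at basin i
#' (the climb out of i on the easiest route). `saddle[i, j]` is the
#' absolute height of that bottleneck, so
#' `barrier[i, j] + U_i = barrier[j, i] + U_j = saddle[i, j]`.
#'
#' @param landscape a `potential_landscape`, an [interpolate_landscape()]
#'   result, or a bare matrix of potentials.
#' @param min_depth persistence threshold in natural-log units (default
#'   0.5).
#' @param min_prob minimum probability mass of a basin bin (default 0.001);
#'   only applied when probabilities are available.
#' @return list with `basins` (data.frame row, col, cro, ci, U, prob),
#'   `barriers` (matrix), `saddles` (matrix of absolute bottleneck
#'   heights), `n_basins`. A flat landscape yields zero basins.
#' @export
find_basins_and_saddles <- function(landscape, min_depth = 0.5,
                                    min_prob = 0.001) {
  if (inherits(landscape, "potential_landscape")) {
    U <- landscape$U; P <- landscape$prob
    x <- seq_len(nrow(U)) - 1; y <- seq_len(ncol(U)) - 1
  } else if (is.list(landscape) && !is.null(landscape$U)) {
    U <- landscape$U; P <- landscape$prob
    x <- landscape$x %||% (seq_len(nrow(U)) - 1)
    y <- landscape$y %||% (seq_len(ncol(U)) - 1)
  } else {
    U <- as.matrix(landscape); P <- NULL
    x <- seq_len(nrow(U)) - 1; y <- seq_len(ncol(U)) - 1
  }
  assert_that(all(is.finite(U)), "potential grid must be finite")
  mins <- local_minima(U)
  if (!is.null(P) && nrow(mins)) {
    mins <- mins[P[as.matrix(mins[, c("row", "col")])] >= min_prob, ,
                 drop = FALSE]
  }
  if (nrow(mins) > 1) {
    # persistence filter: merge shallow minima into deeper ones
    mins <- mins[order(mins$U), , drop = FALSE]
    keep <- rep(TRUE, nrow(mins))
    for (i in seq_len(nrow(mins))[-1]) {
      deeper <- which(keep & mins$U < mins$U[i])
      if (!length(deeper)) next
      s <- min(vapply(deeper, function(j) {
        minimax_barrier(U, c(mins$row[i], mins$col[i]),
                        c(mins$row[j], mins$col[j]))
      }, 0))
      if (s - mins$U[i] < min_depth) keep[i] <- FALSE
    }
    mins <- mins[keep, , drop = FALSE]
  }
  nb <- nrow(mins)
  barriers <- saddles <- matrix(NA_real_, nb, nb)
  if (nb > 1) {
    for (i in seq_len(nb)) {
      bn <- minimax_from(U, c(mins$row[i], mins$col[i]))
      for (j in seq_len(nb)) {
        if (i == j) next
        saddles[i, j] <- bn[mins$row[j], mins$col[j]]
        barriers[i, j] <- saddles[i, j] - mins$U[i]
      }
    }
  }
  basins <- data.frame(row = mins$row, col = mins$col,
                       cro = x[mins$row], ci = y[mins$col], U = mins$U,
                       prob = if (!is.null(P))
                         P[as.matrix(mins[, c("row", "col")])]
                       else rep(NA_real_, nrow(mins)))
  rownames(basins) <- NULL
  list(basins = basins, barriers = barriers, saddles = saddles,
       n_basins = nb)
}

# strict local minima under the 8-neighborhood
local_minima <- function(U) {
  nr <- nrow(U); nc <- ncol(U)
  out <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rr <- max(1, r - 1):min(nr, r + 1)
      cc <- max(1, c - 1):min(nc, c + 1)
      nb <- U[rr, cc]
      if (sum(nb < U[r, c]) == 0 && sum(nb == U[r, c]) == 1) {
        out[[length(out) + 1]] <- c(r, c, U[r, c])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(row = integer(0), col = integer(0), U = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(row = as.integer(m[, 1]), col = as.integer(m[, 2]), U = m[, 3])
}

# minimax (widest-path) Dijkstra over the 8-connected grid graph:
# bn[v] = min over paths s -> v of the max potential along the path
minimax_from <- function(U, source) {
  nr <- nrow(U); nc <- ncol(U)
  n <- nr * nc
  bn <- rep(Inf, n)
  done <- rep(FALSE, n)
  id <- function(r, c) (c - 1L) * nr + r
  bn[id(source[1], source[2])] <- U[source[1], source[2]]
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, bn))
    if (!is.finite(bn[u])) break
    done[u] <- TRUE
    r <- ((u - 1L) %% nr) + 1L
    c <- ((u - 1L) %/% nr) + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- id(r2, c2)
      nd <- max(bn[u], U[r2, c2])
      if (nd < bn[v]) bn[v] <- nd
    }
  }
  matrix(bn, nr, nc)
}

minimax_barrier <- function(U, a, b) {
  minimax_from(U, a)[b[1], b[2]]
}
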