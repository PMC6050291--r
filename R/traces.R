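#' Assemble lineage traces from a per-frame count table
#'
#' Builds a `trace_set` from a flat table of per-frame counts. When a
#' `colony_id` column is present, exactly one lineage per colony is retained
#' (seeded uniform choice), mirroring the one-trace-per-microcolony rule
#' that avoids double counting sister lineages. Lineages with missing
#' (non-contiguous) frames are dropped with a message.
#'
#' @param table data.frame with columns `lineage_id`, `frame`, `cro_count`,
#'   `ci_count` and optionally `colony_id`, `time_min`, `cell_id`,
#'   `cell_age`, `division_flag`, `true_state`.
#' @param frame_interval minutes between frames (default 5; used to fill in
#'   `time_min` when absent).
#' @param seed seed for the per-colony lineage choice.
#' @return a `trace_set`; the chosen seed is stored in its `seed` attribute.
#' @export
assemble_traces <- function(table, frame_interval = 5, seed = 1L) {
  if (nrow(table) == 0) {
    return(structure(list(), n_frames = 0L, frame_interval = frame_interval,
                     seed = as.integer(seed), class = "trace_set"))
  }
  assert_that(all(c("lineage_id", "frame", "cro_count", "ci_count") %in%
                    names(table)),
              "table must have lineage_id, frame, cro_count, ci_count")
  if ("colony_id" %in% names(table)) {
    set.seed(seed)
    keep_ids <- unlist(lapply(split(table$lineage_id, table$colony_id),
                              function(ids) {
                                u <- unique(ids)
                                u[sample.int(length(u), 1)]
                              }))
    table <- table[table$lineage_id %in% keep_ids, , drop = FALSE]
  }
  traces <- lapply(split(table, table$lineage_id), function(df) {
    df <- df[order(df$frame), , drop = FALSE]
    if (nrow(df) > 1 && any(diff(df$frame) != 1)) {
      message(sprintf("dropping lineage %s: missing frames",
                      df$lineage_id[1]))
      return(NULL)
    }
    if (!"time_min" %in% names(df)) df$time_min <- df$frame * frame_interval
    rownames(df) <- NULL
    attr(df, "frame_interval") <- frame_interval
    class(df) <- c("lineage_trace", "data.frame")
    df
  })
  traces <- traces[!vapply(traces, is.null, TRUE)]
  structure(unname(traces), n_frames = sum(vapply(traces, nrow, 0L)),
            frame_interval = frame_interval, seed = as.integer(seed),
            class = "trace_set")
}

#' Restrict traces to young cells
#'
#' Keeps only frames with `cell_age <= age_cutoff` (age as a fraction of the
#' current cell cycle). Retained frames are tagged with a `segment` index:
#' consecutive surviving frames share a segment, and downstream dwell/HMM
#' analysis treats segment boundaries as chain breaks so that statistics
#' never bridge removed frames.
#'
#' @param traces a `trace_set`.
#' @param age_cutoff maximum cell age kept (default 0.4).
#' @return a `trace_set` with a `segment` column added.
#' @export
filter_young_cells <- function(traces, age_cutoff = 0.4) {
  out <- lapply(traces, function(tr) {
    assert_that("cell_age" %in% names(tr), "traces must carry cell_age")
    keep <- which(tr$cell_age <= age_cutoff)
    df <- tr[keep, , drop = FALSE]
    if (nrow(df)) {
      brk <- c(TRUE, diff(keep) != 1)
      df$segment <- cumsum(brk)
    } else df$segment <- integer(0)
    rownames(df) <- NULL
    attr(df, "frame_interval") <- attr(tr, "frame_interval")
    class(df) <- c("lineage_trace", "data.frame")
    df
  })
  structure(out, n_frames = sum(vapply(out, nrow, 0L)),
            frame_interval = attr(traces, "frame_interval"),
            age_cutoff = age_cutoff, class = "trace_set")
}

#' Classify cells by their CI/(CI + Cro) copy-number ratio
#'
#' Cells with fewer than `low_total` molecules in total form the `low-low`
#' class (little CI or Cro). Otherwise the ratio r = CI / (CI + Cro)
#' assigns `CI-only` (r >= r_hi), `Cro-only` (r <= r_lo) or `both`.
#'
#' @param ci_total,cro_total non-negative per-cell totals (vectorized).
#' @param r_hi,r_lo ratio thresholds (defaults 0.8 / 0.2).
#' @param low_total minimum total molecule count for ratio classification;
#'   set to 0 to reproduce a pure three-class ratio scheme.
#' @return character vector over \{"CI-only","Cro-only","both","low-low"\}.
#' @export
classify_population <- function(ci_total, cro_total, r_hi = 0.8, r_lo = 0.2,
                                low_total = 2) {
  assert_that(all(ci_total >= 0) && all(cro_total >= 0),
              "totals must be non-negative")
  total <- ci_total + cro_total
  out <- rep("both", length(total))
  r <- ifelse(total > 0, ci_total / total, NA_real_)
  out[!is.na(r) & r >= r_hi] <- "CI-only"
  out[!is.na(r) & r <= r_lo] <- "Cro-only"
  out[total < low_total] <- "low-low"
  out
}

#' Population class percentages with binomial standard errors
#'
#' @param snapshot data.frame with `ci_total` and `cro_total` columns (as
#'   produced by [simulate_snapshot_population()]).
#' @param r_hi,r_lo,low_total thresholds passed to [classify_population()].
#' @return a `population_summary`: data.frame of class, n, percent, se,
#'   with attributes `n_cells` and `thresholds`.
#' @export
population_percentages <- function(snapshot, r_hi = 0.8, r_lo = 0.2,
                                   low_total = 2) {
  assert_that(nrow(snapshot) >= 1, "need at least one cell")
  cls <- classify_population(snapshot$ci_total, snapshot$cro_total,
                             r_hi, r_lo, low_total)
  lev <- c("CI-only", "Cro-only", "both", "low-low")
  n <- vapply(lev, function(l) sum(cls == l), 0L)
  N <- nrow(snapshot)
  p <- n / N
  out <- data.frame(class = lev, n = n, percent = 100 * p,
                    se = 100 * sqrt(p * (1 - p) / N))
  rownames(out) <- NULL
  attr(out, "n_cells") <- N
  attr(out, "thresholds") <- c(r_hi = r_hi, r_lo = r_lo, low_total = low_total)
  class(out) <- c("population_summary", "data.frame")
  out
}

#' Co-expression summary of two mRNA species
#'
#' Fraction of cells with at least one molecule of each species, plus the
#' per-cell means, all with standard errors.
#'
#' @param counts_a,counts_b non-negative integer per-cell counts.
#' @return list with `fraction_both` (+ `fraction_both_se`), `mean_a`,
#'   `mean_a_se`, `mean_b`, `mean_b_se`, `n_cells`.
#' @export
coexpression_summary <- function(counts_a, counts_b) {
  assert_that(length(counts_a) > 0 && length(counts_a) == length(counts_b),
              "need equal-length, non-empty count vectors")
  assert_that(all(counts_a >= 0) && all(counts_b >= 0),
              "counts must be non-negative")
  n <- length(counts_a)
  both <- counts_a >= 1 & counts_b >= 1
  p <- mean(both)
  list(fraction_both = p,
       fraction_both_se = sqrt(p * (1 - p) / n),
       mean_a = mean(counts_a), mean_a_se = sd(counts_a) / sqrt(n),
       mean_b = mean(counts_b), mean_b_se = sd(counts_b) / sqrt(n),
       n_cells = n)
}

#' Write a trace set to a tab-separated file
#'
#' One row per frame; all lineages concatenated. The format round-trips
#' through [read_traces()].
#'
#' @param traces a `trace_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- as_frame_table(traces)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace set from a tab-separated file
#'
#' @param path file written by [write_traces()] (or any TSV with columns
#'   `lineage_id`, `frame`, `cro_count`, `ci_count`).
#' @param frame_interval minutes between frames.
#' @return a `trace_set`.
#' @export
read_traces <- function(path, frame_interval = 5) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  traces <- lapply(split(df, df$lineage_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    rownames(tr) <- NULL
    attr(tr, "frame_interval") <- frame_interval
    class(tr) <- c("lineage_trace", "data.frame")
    tr
  })
  structure(unname(traces), n_frames = nrow(df),
            frame_interval = frame_interval, class = "trace_set")
}
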