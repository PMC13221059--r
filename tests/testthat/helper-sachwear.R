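# Shared test utilities.

# Independent brute-force Kendall's W, computed straight from definitions:
# mid-ranks by counting, per-rater tie terms by tabulating duplicates, S by
# explicit summation. Deliberately avoids rank() and the package's own code
# path so it can serve as an oracle.
oracle_w <- function(scores) {
  m <- nrow(scores); n <- ncol(scores)
  ranks <- matrix(0, m, n)
  for (j in 1:m) {
    for (i in 1:n) {
      v <- scores[j, i]
      n_less <- sum(scores[j, ] < v)
      n_eq <- sum(scores[j, ] == v)
      ranks[j, i] <- n_less + (n_eq + 1) / 2   # mid-rank by definition
    }
  }
  S <- 0
  mean_rank_sum <- m * (n + 1) / 2
  for (i in 1:n) S <- S + (sum(ranks[, i]) - mean_rank_sum)^2
  T <- 0
  for (j in 1:m) {
    for (v in unique(scores[j, ])) {
      t_k <- sum(scores[j, ] == v)
      T <- T + t_k^3 - t_k
    }
  }
  denom <- m^2 * (n^3 - n) - m * T
  if (denom <= 0) return(list(W = NA_real_, S = S, T = T))
  list(W = 12 * S / denom, S = S, T = T)
}

# Random raters x items ordinal score matrix with frequent ties.
rand_scores <- function(m, n, levels = 0:9) {
  matrix(sample(levels, m * n, replace = TRUE), nrow = m)
}

# Build a small panel directly from per-rater cell matrices.
panel_from_cells <- function(cell_list_by_rater, foot_ids = NULL,
                             scale = "original", session = 1L) {
  grids <- list()
  for (rid in names(cell_list_by_rater)) {
    per_foot <- cell_list_by_rater[[rid]]
    for (fid in names(per_foot)) {
      grids[[length(grids) + 1L]] <- score_grid(
        per_foot[[fid]], foot_id = fid, rater_id = rid, session = session,
        scale = scale)
    }
  }
  rating_panel(grids)
}

# Consensus scoreability mask of a simulated panel's ground truth.
truth_mask <- function(panel) {
  truth <- attr(panel, "truth")
  masks <- vapply(truth, function(tr) !is.na(tr$true_grid$cells),
                  matrix(TRUE, panel$rows, panel$cols))
  matrix(apply(masks, c(1, 2), mean) >= 0.5, panel$rows, panel$cols)
}

# Keep only some raters of a panel (dropout contrasts).
subset_raters <- function(panel, rater_ids) {
  rating_panel(unname(Filter(function(g) g$rater_id %in% rater_ids,
                             panel$grids)))
}
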