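#' Average (mid-rank) ranks of an ordinal score vector
#'
#' Tied values share the mean of the ranks they span, the standard
#' prerequisite of the tie-corrected concordance coefficient. Ranks always
#' sum to n(n+1)/2.
#'
#' @param scores Numeric vector without `NA`.
#' @return Numeric rank vector of the same length.
#' @export
average_ranks <- function(scores) {
  if (length(scores) == 0L) stop("cannot rank an empty vector")
  if (anyNA(scores)) stop("scores must not contain NA (exclude first)")
  rank(scores, ties.method = "average")
}

#' Tie-correction term for one rater
#'
#' `T_j = sum_k (t_k^3 - t_k)` over the groups of tied values in one rater's
#' score vector; the per-rater terms are summed over raters and subtracted
#' (times m) in the denominator of Kendall's W.
#'
#' @param scores Numeric vector without `NA`.
#' @return The correction term (0 when all values are distinct).
#' @export
tie_correction <- function(scores) {
  if (anyNA(scores)) stop("scores must not contain NA (exclude first)")
  t_k <- table(scores)
  sum(t_k^3 - t_k)
}

concordance_result <- function(W = NA_real_, S = NA_real_, T = NA_real_,
                               m = NA_integer_, n = NA_integer_,
                               chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                               excluded_items = 0L, undefined_reason = NA_character_) {
  structure(list(W = W, S = S, T = T, m = m, n = n, chi2 = chi2, df = df,
                 p = p, excluded_items = as.integer(excluded_items),
                 undefined_reason = undefined_reason),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  if (!is.na(x$undefined_reason)) {
    cat(sprintf("<concordance: undefined (%s), m=%s n=%s, %d excluded>\n",
                x$undefined_reason, x$m, x$n, x$excluded_items))
  } else {
    cat(sprintf(
      "<concordance: W=%.3f (%s), m=%d n=%d, S=%.1f T=%.0f, chi2=%.2f df=%d p=%.3g>\n",
      x$W, categorize_agreement(x$W), x$m, x$n, x$S, x$T, x$chi2, x$df, x$p))
  }
  invisible(x)
}

#' Is a concordance result defined?
#' @param x A `concordance_result`.
#' @return `TRUE` if W could be computed.
#' @export
is_defined <- function(x) {
  stopifnot(inherits(x, "concordance_result"))
  is.na(x$undefined_reason)
}

#' Tie-corrected Kendall's coefficient of concordance
#'
#' Measures agreement among m raters ranking n items (0 = no agreement,
#' 1 = identical rankings). Each rater's scores are converted to average
#' ranks; with `R_i` the rank sum of item i,
#' `S = sum_i (R_i - m(n+1)/2)^2`, `T = sum_j T_j` the summed per-rater tie
#' corrections ([tie_correction()]), and
#' `W = 12 S / (m^2 (n^3 - n) - m T)`.
#' The companion large-sample test statistic is `chi2 = m (n - 1) W` on
#' `n - 1` degrees of freedom.
#'
#' The result is undefined (with a machine-readable reason, never a silent
#' zero) when fewer than 3 items or 2 raters survive, or when the
#' denominator is non-positive (each rater assigning a single constant
#' score).
#'
#' @param scores m x n numeric matrix, raters in rows, items in columns,
#'   no `NA` (exclude incomplete items first).
#' @return A `concordance_result`.
#' @examples
#' kendalls_w(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, 1, 3, 4)))
#' @export
kendalls_w <- function(scores) {
  if (!is.matrix(scores)) stop("`scores` must be a raters x items matrix")
  if (anyNA(scores)) stop("scores must not contain NA (exclude items first)")
  m <- nrow(scores); n <- ncol(scores)
  if (m < 2L) return(concordance_result(m = m, n = n,
                                        undefined_reason = "insufficient_raters"))
  if (n < 3L) return(concordance_result(m = m, n = n,
                                        undefined_reason = "insufficient_items"))
  ranks <- t(apply(scores, 1, average_ranks))
  R_i <- colSums(ranks)
  S <- sum((R_i - m * (n + 1) / 2)^2)
  T <- sum(apply(scores, 1, tie_correction))
  denom <- m^2 * (n^3 - n) - m * T
  if (denom <= 0) {
    return(concordance_result(S = S, T = T, m = m, n = n,
                              undefined_reason = "degenerate_ties"))
  }
  W <- 12 * S / denom
  chi2 <- m * (n - 1) * W
  df <- n - 1L
  concordance_result(W = W, S = S, T = T, m = m, n = n, chi2 = chi2, df = df,
                     p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

panel_scale_for <- function(panel, scale) {
  if (is.null(scale)) return(panel)
  scale <- as_wear_scale(scale)
  if (scale$name == panel$scale$name) return(panel)
  if (panel$scale$name == "original" && scale$name == "modified") {
    return(collapse_panel(panel))
  }
  stop("cannot analyse a modified-scale panel on the original scale")
}

panel_score_array <- function(panel, session) {
  feet <- panel$feet; raters <- panel$raters
  arr <- array(NA_integer_,
               dim = c(length(raters), length(feet), panel$rows, panel$cols))
  for (j in seq_along(raters)) {
    for (i in seq_along(feet)) {
      g <- panel_grid(panel, feet[i], raters[j], session)
      if (is.null(g)) {
        stop(sprintf("panel is missing foot %s / rater %s / session %d",
                     feet[i], raters[j], session))
      }
      arr[j, i, , ] <- g$cells
    }
  }
  arr
}

#' Per-cell interobserver concordance across feet
#'
#' For each grid cell, asks "do raters agree which feet are more or less
#' worn at this cell?": items are the feet, and Kendall's W is computed over
#' the raters' scores for that cell. Feet where any rater recorded `NA` in
#' the cell are excluded listwise, keeping the item set identical across
#' raters; if fewer than 3 feet survive the cell's result is undefined.
#'
#' No multiple-testing adjustment is applied across cells; per-cell W and p
#' values are reported raw.
#'
#' @param panel A [rating_panel()] (one grid per rater per foot at
#'   `session`).
#' @param scale Optional scale to analyse on; an original-scale panel can be
#'   collapsed on the fly with `scale = "modified"`.
#' @param session Session to analyse (default 1).
#' @return A `cell_concordance` object; see [concordance_df()] and
#'   [w_matrix()].
#' @export
per_cell_concordance <- function(panel, scale = NULL, session = 1L) {
  stopifnot(inherits(panel, "rating_panel"))
  if (length(panel$raters) < 2L) stop("per-cell concordance needs at least 2 raters")
  panel <- panel_scale_for(panel, scale)
  arr <- panel_score_array(panel, session)
  n_feet <- length(panel$feet)
  res <- vector("list", panel$rows * panel$cols)
  dim(res) <- c(panel$rows, panel$cols)
  for (r in seq_len(panel$rows)) {
    for (c in seq_len(panel$cols)) {
      scores <- arr[, , r, c, drop = TRUE]
      if (is.null(dim(scores))) scores <- matrix(scores, nrow = dim(arr)[1])
      keep <- colSums(is.na(scores)) == 0L
      excl <- sum(!keep)
      sub <- scores[, keep, drop = FALSE]
      out <- if (ncol(sub) < 3L) {
        concordance_result(m = nrow(scores), n = ncol(sub),
                           excluded_items = excl,
                           undefined_reason = "insufficient_items")
      } else {
        w <- kendalls_w(sub)
        w$excluded_items <- excl
        w
      }
      res[[r, c]] <- out
    }
  }
  structure(list(results = res, rows = panel$rows, cols = panel$cols,
                 m = length(panel$raters), n_feet = n_feet,
                 scale = panel$scale$name),
            class = "cell_concordance")
}

#' @export
print.cell_concordance <- function(x, ...) {
  wm <- w_matrix(x)
  cat(sprintf("<cell_concordance: %dx%d cells, %d raters, %d feet; %d defined, mean W %.3f>\n",
              x$rows, x$cols, x$m, x$n_feet, sum(!is.na(wm)),
              mean(wm, na.rm = TRUE)))
  invisible(x)
}

#' Extract the matrix of W values from a per-cell analysis
#'
#' @param x A `cell_concordance` from [per_cell_concordance()].
#' @return rows x cols numeric matrix; undefined cells are `NA`.
#' @export
w_matrix <- function(x) {
  stopifnot(inherits(x, "cell_concordance"))
  matrix(vapply(x$results, function(r) r$W, numeric(1)), x$rows, x$cols)
}

#' Per-foot interobserver concordance across cells
#'
#' For one foot, asks "do raters agree which regions of this foot are more
#' or less worn?": items are the foot's grid cells that are `NA`-free across
#' all raters (cells any rater marked `NA` are excluded listwise).
#'
#' @param panel A [rating_panel()].
#' @param foot_id One foot id, or `NULL` for all feet.
#' @param scale,session As in [per_cell_concordance()].
#' @return A `concordance_result` for one foot, or a named list of them for
#'   all feet.
#' @export
per_foot_concordance <- function(panel, foot_id = NULL, scale = NULL,
                                 session = 1L) {
  stopifnot(inherits(panel, "rating_panel"))
  if (length(panel$raters) < 2L) stop("per-foot concordance needs at least 2 raters")
  panel <- panel_scale_for(panel, scale)
  if (is.null(foot_id)) {
    out <- lapply(panel$feet, function(f)
      per_foot_concordance(panel, f, scale = NULL, session = session))
    names(out) <- panel$feet
    return(out)
  }
  if (!foot_id %in% panel$feet) {
    stop(sprintf("unknown foot id: %s", foot_id))
  }
  scores <- t(vapply(panel$raters, function(rid) {
    g <- panel_grid(panel, foot_id, rid, session)
    if (is.null(g)) stop(sprintf("panel is missing foot %s / rater %s / session %d",
                                 foot_id, rid, session))
    as.vector(g$cells)
  }, numeric(panel$rows * panel$cols)))
  keep <- colSums(is.na(scores)) == 0L
  excl <- sum(!keep)
  sub <- scores[, keep, drop = FALSE]
  if (ncol(sub) < 3L) {
    return(concordance_result(m = nrow(scores), n = ncol(sub),
                              excluded_items = excl,
                              undefined_reason = "insufficient_items"))
  }
  w <- kendalls_w(sub)
  w$excluded_items <- excl
  w
}

#' The five agreement categories for Kendall's W
#'
#' @return Data frame with `label`, `lo`, `hi`: poor/slight (0-0.20), fair
#'   (0.21-0.40), moderate (0.41-0.60), good/substantial (0.61-0.80),
#'   excellent (0.81-1.00). Implemented as half-open bins at the midpoints
#'   of the printed gaps (0.205, 0.405, ...), so every W lands in exactly
#'   one bin and any value at a printed bound keeps its printed label.
#' @export
agreement_categories <- function() {
  data.frame(
    label = c("poor/slight", "fair", "moderate", "good/substantial", "excellent"),
    lo = c(0, 0.205, 0.405, 0.605, 0.805),
    hi = c(0.205, 0.405, 0.605, 0.805, 1),
    stringsAsFactors = FALSE
  )
}

#' Categorize agreement strength
#'
#' @param W Numeric vector of concordance values in `[0, 1]`; `NA`
#'   (undefined) propagates.
#' @return Character vector of category labels (see
#'   [agreement_categories()]).
#' @examples
#' categorize_agreement(c(0.45, 1, 0))
#' @export
categorize_agreement <- function(W) {
  if (any(!is.na(W) & (W < 0 | W > 1))) stop("W must lie in [0, 1]")
  cats <- agreement_categories()
  idx <- findInterval(W, c(cats$lo, Inf), rightmost.closed = FALSE)
  idx[!is.na(W) & W >= 1] <- nrow(cats)
  cats$label[pmin(idx, nrow(cats))]
}

#' Intraobserver cell-level agreement counts
#'
#' For one rater who re-scored feet in repeat sessions, counts per cell how
#' many (foot, session-pair) comparisons gave identical scores — the
#' repeatability measure behind intraobserver heatmaps. Comparisons where
#' both sessions recorded `NA` are excluded by default (set
#' `count_na_agreement = TRUE` to count them as agreements); an `NA` against
#' a numeric score counts as a comparison that disagrees.
#'
#' @param panel A [rating_panel()].
#' @param rater_id Rater with >= 2 sessions on at least one foot.
#' @param count_na_agreement Treat NA-vs-NA as agreement? Default `FALSE`.
#' @return A `cell_agreement` object: matrices `counts` (agreements; `NA`
#'   where no comparison was possible) and `comparisons`.
#' @export
intraobserver_agreement <- function(panel, rater_id, count_na_agreement = FALSE) {
  stopifnot(inherits(panel, "rating_panel"))
  if (!rater_id %in% panel$raters) stop(sprintf("unknown rater id: %s", rater_id))
  counts <- matrix(0L, panel$rows, panel$cols)
  comps <- matrix(0L, panel$rows, panel$cols)
  any_pair <- FALSE
  for (f in panel$feet) {
    ses <- Filter(function(s) !is.null(panel_grid(panel, f, rater_id, s)),
                  panel$sessions)
    if (length(ses) < 2L) next
    pairs <- utils::combn(ses, 2, simplify = FALSE)
    for (pr in pairs) {
      any_pair <- TRUE
      a <- panel_grid(panel, f, rater_id, pr[1])$cells
      b <- panel_grid(panel, f, rater_id, pr[2])$cells
      both_na <- is.na(a) & is.na(b)
      one_na <- xor(is.na(a), is.na(b))
      eq <- !is.na(a) & !is.na(b) & a == b
      compared <- if (count_na_agreement) !logical(length(a)) else !both_na
      dim(compared) <- dim(a)
      agree <- eq | (count_na_agreement & both_na)
      comps <- comps + compared
      counts <- counts + (agree & compared)
    }
  }
  if (!any_pair) {
    stop(sprintf("rater %s has no foot scored in two or more sessions", rater_id))
  }
  counts[comps == 0L] <- NA_integer_
  structure(list(counts = counts, comparisons = comps, rater_id = rater_id),
            class = "cell_agreement")
}

#' @export
print.cell_agreement <- function(x, ...) {
  cat(sprintf("<cell_agreement: rater %s, %d cells compared, mean agreement %.2f>\n",
              x$rater_id, sum(x$comparisons > 0),
              mean((x$counts / x$comparisons)[x$comparisons > 0], na.rm = TRUE)))
  invisible(x)
}

#' Count discordant item pairs between two score vectors
#'
#' Pairs (i, j) ranked in strictly opposite order by the two vectors. Used
#' to verify that collapsing the scale never creates new disagreement.
#'
#' @param a,b Equal-length numeric vectors without `NA`.
#' @return Integer count.
#' @export
discordant_pairs <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (anyNA(a) || anyNA(b)) stop("vectors must not contain NA")
  da <- sign(outer(a, a, "-"))
  db <- sign(outer(b, b, "-"))
  sum(da * db < 0) / 2
}

#' Count tied pairs within a score vector
#'
#' @param v Numeric vector without `NA`.
#' @return Number of unordered pairs with equal values.
#' @export
tied_pairs <- function(v) {
  if (anyNA(v)) stop("vector must not contain NA")
  t_k <- table(v)
  sum(choose(t_k, 2))
}

#' Flatten concordance results to a data frame
#'
#' @param x A `cell_concordance` (per-cell) or a list of
#'   `concordance_result`s keyed by foot id (per-foot).
#' @return Data frame with one row per cell (`row`, `col`) or per foot
#'   (`foot_id`) and columns `W`, `S`, `T`, `m`, `n`, `chi2`, `df`, `p`,
#'   `category`, `excluded_items`, `undefined_reason`.
#' @export
concordance_df <- function(x) {
  one <- function(res) {
    data.frame(W = res$W, S = res$S, T = res$T, m = res$m, n = res$n,
               chi2 = res$chi2, df = res$df, p = res$p,
               category = if (is.na(res$W)) NA_character_ else categorize_agreement(res$W),
               excluded_items = res$excluded_items,
               undefined_reason = res$undefined_reason,
               stringsAsFactors = FALSE)
  }
  if (inherits(x, "cell_concordance")) {
    idx <- expand.grid(row = seq_len(x$rows), col = seq_len(x$cols))
    out <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k)
      one(x$results[[idx$row[k], idx$col[k]]])))
    cbind(idx, out)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "concordance_result"))) {
    out <- do.call(rbind, lapply(x, one))
    cbind(data.frame(foot_id = names(x), stringsAsFactors = FALSE), out,
          row.names = NULL)
  } else if (inherits(x, "concordance_result")) {
    one(x)
  } else {
    stop("unsupported input to concordance_df()")
  }
}
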