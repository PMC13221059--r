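test_that("average ranks use mid-ranks and always sum to n(n+1)/2", {
  expect_equal(average_ranks(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(average_ranks(c(5, 5, 2)), c(2.5, 2.5, 1))
  expect_equal(average_ranks(c(7, 7, 7, 7)), c(2.5, 2.5, 2.5, 2.5))
  expect_error(average_ranks(numeric(0)), "empty")
  expect_error(average_ranks(c(1, NA)), "NA")
  set.seed(7)
  for (i in 1:20) {
    v <- sample(0:5, 8, replace = TRUE)
    expect_equal(sum(average_ranks(v)), 8 * 9 / 2)
  }
})

test_that("tie correction sums t^3 - t over tie groups", {
  expect_equal(tie_correction(c(1, 2, 3)), 0)
  expect_equal(tie_correction(c(5, 5, 2)), 6)    # 2^3 - 2
  expect_equal(tie_correction(c(7, 7, 7, 7)), 60)  # 4^3 - 4
  expect_equal(tie_correction(c(1, 1, 2, 2, 2)), 6 + 24)
})

test_that("kendalls_w handles perfect agreement, reversal and ties", {
  # identical rankings, no ties
  w1 <- kendalls_w(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(1, 3, 5, 9)))
  expect_equal(w1$W, 1)
  expect_equal(w1$chi2, 3 * 3 * 1)
  # identical score vectors including ties: the tie correction must make W 1
  v <- c(2, 2, 5, 7, 7, 7)
  w2 <- kendalls_w(rbind(v, v, v))
  expect_equal(w2$W, 1, tolerance = 1e-12)
  expect_gt(w2$T, 0)
  # two raters in exact reversal: all rank sums equal, S = 0
  w3 <- kendalls_w(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(w3$W, 0)
  expect_equal(w3$S, 0)
})

test_that("undefined results carry machine-readable reasons", {
  w <- kendalls_w(rbind(c(1, 2), c(2, 1)))
  expect_false(is_defined(w))
  expect_equal(w$undefined_reason, "insufficient_items")
  # every rater assigns one constant value: denominator is zero
  w2 <- kendalls_w(rbind(c(4, 4, 4, 4), c(7, 7, 7, 7)))
  expect_false(is_defined(w2))
  expect_equal(w2$undefined_reason, "degenerate_ties")
  w3 <- kendalls_w(matrix(1:4, nrow = 1))
  expect_equal(w3$undefined_reason, "insufficient_raters")
  expect_error(kendalls_w(rbind(c(1, NA, 2), c(1, 2, 3))), "NA")
})

test_that("kendalls_w matches the brute-force oracle on random tied data", {
  set.seed(101)
  for (i in 1:60) {
    m <- sample(2:5, 1); n <- sample(3:8, 1)
    sc <- rand_scores(m, n)
    ref <- oracle_w(sc)
    got <- kendalls_w(sc)
    if (is.na(ref$W)) {
      expect_false(is_defined(got))
    } else {
      expect_equal(got$W, ref$W, tolerance = 1e-12)
      expect_equal(got$S, ref$S, tolerance = 1e-12)
      expect_equal(got$T, ref$T)
      expect_true(got$W >= 0 && got$W <= 1)
    }
  }
})

test_that("kendalls_w agrees with an established implementation", {
  skip_if_not_installed("vegan")
  set.seed(55)
  for (i in 1:10) {
    sc <- rand_scores(3, 6)
    got <- kendalls_w(sc)
    if (!is_defined(got)) next
    ref <- vegan::kendall.global(t(sc))$Concordance_analysis
    expect_equal(got$W, unname(ref["W", 1]), tolerance = 1e-10)
    expect_equal(got$chi2, unname(ref["Chi2", 1]), tolerance = 1e-10)
  }
})

test_that("per-cell concordance excludes NA feet listwise", {
  a <- matrix(c(1L, 2L, 3L, 4L), 2, 2)
  feet <- paste0("F", 1:5)
  cells <- lapply(1:5, function(i) matrix(as.integer(i), 2, 2) + a)
  names(cells) <- feet
  # two identical raters everywhere -> W = 1 in every cell
  p <- panel_from_cells(list(R1 = cells, R2 = cells))
  cc <- per_cell_concordance(p)
  expect_true(all(w_matrix(cc) == 1))

  # rater 2 records NA for cell R1C1 of every foot -> that cell undefined
  cells2 <- lapply(cells, function(m) { m[1, 1] <- NA_integer_; m })
  p2 <- panel_from_cells(list(R1 = cells, R2 = cells2))
  cc2 <- per_cell_concordance(p2)
  r11 <- cc2$results[[1, 1]]
  expect_false(is_defined(r11))
  expect_equal(r11$excluded_items, 5L)
  expect_true(all(w_matrix(cc2)[-1] == 1, na.rm = TRUE))

  expect_error(per_cell_concordance(panel_from_cells(list(R1 = cells))),
               "at least 2 raters")
})

test_that("per-foot concordance ranks cells within one foot", {
  cells <- matrix(c(1L, 3L, 5L, 7L, 2L, 6L), 2, 3)
  p <- panel_from_cells(list(
    R1 = list(F1 = cells, F2 = cells + 1L),
    R2 = list(F1 = cells, F2 = cells + 1L)))
  r <- per_foot_concordance(p, "F1")
  expect_equal(r$W, 1)
  expect_equal(r$n, 6)

  # one rater scored everything NA on F1: no cells survive
  na_cells <- matrix(NA_integer_, 2, 3)
  p2 <- panel_from_cells(list(
    R1 = list(F1 = cells, F2 = cells),
    R2 = list(F1 = na_cells, F2 = cells)))
  r2 <- per_foot_concordance(p2, "F1")
  expect_false(is_defined(r2))
  expect_equal(r2$excluded_items, 6L)
  expect_error(per_foot_concordance(p2, "nope"), "unknown foot")

  all_feet <- per_foot_concordance(p)
  expect_named(all_feet, c("F1", "F2"))
  df <- concordance_df(all_feet)
  expect_equal(df$W, c(1, 1))
})

test_that("agreement categories match the published bins", {
  expect_equal(categorize_agreement(0.45), "moderate")
  expect_equal(categorize_agreement(1.0), "excellent")
  expect_equal(categorize_agreement(0.0), "poor/slight")
  expect_equal(categorize_agreement(c(0.20, 0.21)), c("poor/slight", "fair"))
  expect_equal(categorize_agreement(0.61), "good/substantial")
  # values in the printed gaps go to the lower bin below the midpoint
  expect_equal(categorize_agreement(0.204), "poor/slight")
  expect_equal(categorize_agreement(0.205), "fair")
  expect_true(is.na(categorize_agreement(NA)))
  expect_error(categorize_agreement(1.2), "0, 1")
  bins <- agreement_categories()
  expect_equal(bins$lo[1], 0)
  expect_equal(bins$hi[5], 1)
  expect_true(all(bins$lo[-1] == bins$hi[-5]))  # bins cover [0,1] w/o overlap
})

test_that("intraobserver agreement counts identical repeat scores per cell", {
  cells <- matrix(c(1L, 2L, 3L, 4L, 5L, 6L), 2, 3)
  feet <- paste0("F", 1:5)
  s1 <- lapply(setNames(feet, feet), function(f) cells)
  p <- rating_panel(c(
    lapply(feet, function(f) score_grid(cells, f, "R1", session = 1)),
    lapply(feet, function(f) score_grid(cells, f, "R1", session = 2))))
  am <- intraobserver_agreement(p, "R1")
  expect_true(all(am$counts == 5))

  # one cell of one foot changed in the repeat: that cell drops to 4
  cells_b <- cells; cells_b[2, 3] <- 1L
  p2 <- rating_panel(c(
    lapply(feet, function(f) score_grid(cells, f, "R1", session = 1)),
    lapply(feet[-1], function(f) score_grid(cells, f, "R1", session = 2)),
    list(score_grid(cells_b, "F1", "R1", session = 2))))
  am2 <- intraobserver_agreement(p2, "R1")
  expect_equal(am2$counts[2, 3], 4L)
  expect_true(all(am2$counts[-6] == 5))

  # NA-vs-NA excluded by default, counted when configured
  cna <- cells; cna[1, 1] <- NA_integer_
  p3 <- rating_panel(list(score_grid(cna, "F1", "R1", session = 1),
                          score_grid(cna, "F1", "R1", session = 2)))
  am3 <- intraobserver_agreement(p3, "R1")
  expect_true(is.na(am3$counts[1, 1]))
  expect_equal(am3$comparisons[1, 1], 0L)
  am4 <- intraobserver_agreement(p3, "R1", count_na_agreement = TRUE)
  expect_equal(am4$counts[1, 1], 1L)

  expect_error(intraobserver_agreement(
    rating_panel(list(score_grid(cells, "F1", "R1"))), "R1"),
    "two or more sessions")
  expect_error(intraobserver_agreement(p3, "R9"), "unknown rater")
})

test_that("discordant pairs are counted and never increase under collapse", {
  expect_equal(discordant_pairs(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(discordant_pairs(c(1, 2), c(2, 1)), 1)
  expect_error(discordant_pairs(1:3, 1:4), "equal length")
  set.seed(77)
  for (i in 1:100) {
    a <- sample(0:9, 10, replace = TRUE)
    b <- sample(0:9, 10, replace = TRUE)
    expect_lte(discordant_pairs(collapse_score(a), collapse_score(b)),
               discordant_pairs(a, b))
  }
})

test_that("W stays in [0, 1] over randomized panels", {
  set.seed(31)
  for (i in 1:30) {
    sc <- rand_scores(sample(2:4, 1), sample(4:10, 1), levels = 0:5)
    w <- kendalls_w(sc)
    if (is_defined(w)) expect_true(w$W >= 0 && w$W <= 1 + 1e-12)
  }
})

test_that("concordance_df flattens per-cell results with categories", {
  cells <- lapply(setNames(1:4, paste0("F", 1:4)),
                  function(i) matrix(as.integer(i %% 3 + 1), 2, 2))
  p <- panel_from_cells(list(R1 = cells, R2 = cells))
  df <- concordance_df(per_cell_concordance(p))
  expect_equal(nrow(df), 4)
  expect_true(all(c("row", "col", "W", "S", "T", "m", "n", "chi2", "df", "p",
                    "category", "excluded_items", "undefined_reason")
                  %in% names(df)))
  expect_true(all(df$category[!is.na(df$W)] == "excellent"))
})
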