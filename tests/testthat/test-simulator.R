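test_that("synthetic outlines are deterministic and sized to spec", {
  o1 <- make_foot_outline(200, 0.5, seed = 3)
  o2 <- make_foot_outline(200, 0.5, seed = 3)
  expect_identical(o1$vertices, o2$vertices)
  expect_false(identical(o1$vertices, make_foot_outline(200, 0.5, seed = 4)$vertices))
  bb_w <- diff(range(o1$vertices[, 1]))
  bb_h <- diff(range(o1$vertices[, 2]))
  expect_equal(bb_h, 200, tolerance = 1)
  expect_equal(bb_w, 100, tolerance = 1)
  expect_error(make_foot_outline(-10, 0.5), "positive")
  expect_error(make_foot_outline(200, 1.2), "width_ratio")
})

test_that("the keel bump is anchored to the heel, not scaled with the foot", {
  short <- make_wear_field(make_foot_outline(180, 0.45, seed = 1), seed = 1)
  long <- make_wear_field(make_foot_outline(260, 0.45, seed = 1), seed = 1)
  # toe is at y = 0, heel at y = length; keel centre sits keel_offset from heel
  d_short <- 180 - short$keel_center[2]
  d_long <- 260 - long$keel_center[2]
  expect_equal(d_short, d_long, tolerance = 1)
  # hence relatively nearer the toe in the shorter foot
  expect_lt(short$keel_center[2] / 180, long$keel_center[2] / 260)
})

test_that("wear field components behave analytically", {
  o <- make_foot_outline(200, 0.45, seed = 2)
  flat <- make_wear_field(o, list(keel_amplitude = 0, edge_amplitude = 0,
                                  noise_sd = 0, baseline = 2), seed = 1)
  xs <- runif(50, -40, 40); ys <- runif(50, 0, 200)
  expect_true(all(flat$intensity(xs, ys) == 2))

  keel <- make_wear_field(o, list(edge_amplitude = 0, noise_sd = 0), seed = 1)
  at_keel <- keel$intensity(keel$keel_center[1], keel$keel_center[2])
  expect_true(all(at_keel >= keel$intensity(xs, ys)))

  edge <- make_wear_field(o, list(keel_amplitude = 0, noise_sd = 0,
                                  edge_amplitude = 3, edge_width = 10), seed = 1)
  cen <- poly_centroid(o$vertices)
  near_edge <- o$vertices * 0.98 + matrix(cen, nrow(o$vertices), 2, byrow = TRUE) * 0.02
  band_mean <- mean(edge$intensity(near_edge[, 1], near_edge[, 2]))
  interior_mean <- edge$intensity(cen[1], cen[2])
  expect_gt(band_mean, interior_mean)
  expect_error(make_wear_field(o, list(keel_amplitude = -1)), "amplitudes")
})

test_that("render_true_grid bins mean intensity and applies the NA rule", {
  o <- make_foot_outline(200, 0.45, seed = 6)
  p <- fit_grid(o)
  low <- make_wear_field(o, list(keel_amplitude = 0, edge_amplitude = 0,
                                 noise_sd = 0, baseline = 0.01), seed = 1)
  g <- render_true_grid(low, p, thresholds = 1:8)
  expect_true(all(g$cells[!is.na(g$cells)] == 1))  # used foot floors at 1
  # NA pattern equals the 50% coverage rule
  expect_identical(is.na(g$cells), !apply_na_rule(cell_coverage(o, p)))

  high <- make_wear_field(o, list(keel_amplitude = 0, edge_amplitude = 0,
                                  noise_sd = 0, baseline = 99), seed = 1)
  g2 <- render_true_grid(high, p, thresholds = 1:8)
  expect_true(all(g2$cells[!is.na(g2$cells)] == 9))
  g3 <- render_true_grid(high, p, scale = "modified", thresholds = 1:4)
  expect_true(all(g3$cells[!is.na(g3$cells)] == 5))

  # a field increasing along the foot gives non-decreasing scores down rows
  ramp <- low
  ramp$intensity <- function(x, y) y / 25
  ramp$design_max <- 8
  g4 <- render_true_grid(ramp, p)
  for (cc in 1:10) {
    col <- g4$cells[, cc]
    expect_true(all(diff(col[!is.na(col)]) >= 0))
  }
  expect_error(render_true_grid(low, p, thresholds = c(1, 2)), "thresholds")
  expect_error(render_true_grid(low, p, thresholds = rep(1, 8)), "increasing")
})

test_that("the identity rater reproduces the truth; bias shifts interior levels", {
  o <- make_foot_outline(210, 0.46, seed = 8)
  p <- fit_grid(o)
  f <- make_wear_field(o, seed = 8)
  truth <- render_true_grid(f, p)
  same <- simulate_rater(f, o, p, identity_rater(), seed = 42)
  expect_identical(same$cells, truth$cells)

  biased <- simulate_rater(f, o, p, rater_model(bias = 1, noise_sd = 0,
                                                lapse_rate = 0), seed = 42)
  interior <- !is.na(truth$cells) & truth$cells < 9
  expect_true(all(biased$cells[interior] == truth$cells[interior] + 1L))
  expect_true(all(biased$cells[!is.na(truth$cells) & truth$cells == 9] == 9L))
})

test_that("misaligned raters disagree with truth mostly at the border", {
  o <- make_foot_outline(220, 0.44, seed = 10)
  p <- fit_grid(o)
  f <- make_wear_field(o, seed = 10)
  truth <- render_true_grid(f, p)
  cls <- classify_cells(!is.na(truth$cells))
  shifted <- simulate_rater(
    f, o, p, rater_model(noise_sd = 0, lapse_rate = 0, shift = c(0.5, 0.5)),
    seed = 1)
  dis <- (is.na(truth$cells) != is.na(shifted$cells)) |
    (!is.na(truth$cells) & !is.na(shifted$cells) & truth$cells != shifted$cells)
  border_rate <- mean(dis[cls == "border"], na.rm = TRUE)
  interior_rate <- mean(dis[cls == "interior"], na.rm = TRUE)
  expect_gt(border_rate, interior_rate)
})

test_that("panels are reproducible and extend without disturbing old streams", {
  cfg <- sim_config(n_feet = 3, m_raters = 2, sessions = 2, seed = 21)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_scores_csv(p1, f1); write_scores_csv(p2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical export
  expect_equal(length(p1$grids), 3 * 2 * 2)
  expect_equal(p1$sessions, 1:2)

  # adding a rater re-uses the same per-foot streams: G1/G2 grids unchanged
  models2 <- default_rater_models(2, cfg$seed)
  models3 <- c(models2, list(rater_model(noise_sd = 2)))
  cfg3 <- sim_config(n_feet = 3, m_raters = 3, sessions = 2, seed = 21)
  p3 <- simulate_panel(cfg3, models3)
  for (f in p1$feet) {
    for (r in c("G1", "G2")) {
      expect_identical(panel_grid(p3, f, r, 1)$cells,
                       panel_grid(p1, f, r, 1)$cells)
    }
  }
})

test_that("identity raters give W = 1 wherever defined", {
  cfg <- sim_config(n_feet = 6, m_raters = 3, seed = 5)
  p <- simulate_panel(cfg, replicate(3, identity_rater(), simplify = FALSE))
  wm <- w_matrix(per_cell_concordance(p))
  expect_true(all(wm[!is.na(wm)] == 1))
  pf <- per_foot_concordance(p)
  expect_true(all(vapply(pf, function(r) !is_defined(r) || r$W == 1,
                         logical(1))))
})

test_that("averaged true wear is highest at the keel and high along edges", {
  cfg <- sim_config(n_feet = 50, m_raters = 1, seed = 99)
  p <- simulate_panel(cfg, list(identity_rater()))
  truth <- attr(p, "truth")
  mean_wear <- Reduce(`+`, lapply(truth, function(tr) {
    m <- tr$true_grid$cells
    m[is.na(m)] <- 0   # treat outside-foot as 0 for the average pattern
    m
  })) / length(truth)
  mask <- truth_mask(p)
  cls <- classify_cells(mask)
  keel_rows <- 4:10   # rows containing the keel bump across foot sizes
  keel_cells <- mean_wear[keel_rows, 4:7]
  interior_nonkeel <- mean_wear[cls == "interior"][
    !(row(mean_wear)[cls == "interior"] %in% keel_rows)]
  expect_gt(max(keel_cells), max(interior_nonkeel, na.rm = TRUE))
  border_mean <- mean(mean_wear[cls == "border"], na.rm = TRUE)
  # elevated edge wear relative to interior cells away from the keel
  expect_gt(border_mean, mean(interior_nonkeel, na.rm = TRUE) * 0.8)
})

test_that("mean concordance decreases with rater noise", {
  mean_w <- function(noise) {
    cfg <- sim_config(n_feet = 10, m_raters = 3, seed = 303)
    models <- lapply(1:3, function(j)
      rater_model(noise_sd = noise, lapse_rate = 0,
                  shift = c(0.05 * j, -0.05 * j)))
    mean(w_matrix(per_cell_concordance(simulate_panel(cfg, models))),
         na.rm = TRUE)
  }
  ws <- vapply(c(0, 0.5, 1, 2), mean_w, numeric(1))
  expect_true(all(diff(ws) <= 0.02))  # non-increasing up to simulation jitter
  expect_lt(ws[4], ws[1])
})
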