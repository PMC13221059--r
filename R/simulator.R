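# Synthetic feet, wear fields and noisy ordinal raters. Every reliability
# statistic in the package is exercised against panels from this module, so
# simulation is first-class, seeded and fully deterministic.

# Deterministic sub-seed derivation: one stream per (foot, rater, session),
# derived from the master seed by counter, so adding raters or sessions never
# perturbs existing feet. Kept < 2^31 (R integers are 32-bit).
sub_seed <- function(master, counter) {
  as.integer(((master %% 2147483647) * 48271 + counter * 1299721) %% 2147483629)
}

#' Generate a synthetic left-foot plantar outline
#'
#' A foot-like simple polygon: wider forefoot, arched medial edge, narrower
#' rounded heel, with small seeded shape perturbations so no two feet are
#' identical. The toe is at y = 0, the heel at y = `length_px`; the bounding
#' box is `length_px` tall and `width_ratio * length_px` wide (within 1 px).
#'
#' @param length_px Toe-heel length in px (> 0).
#' @param width_ratio Bounding-box width as a fraction of length, in (0, 1).
#' @param seed Integer seed; the same seed gives identical vertices.
#' @param n_side Vertices per side (resolution of the outline).
#' @return A left-oriented [foot_outline()].
#' @export
make_foot_outline <- function(length_px, width_ratio = 0.43, seed = 1L,
                              n_side = 36L) {
  if (length_px <= 0) stop("length_px must be positive")
  if (width_ratio <= 0 || width_ratio >= 1) stop("width_ratio must be in (0, 1)")
  t <- seq(0, 1, length.out = n_side)
  base <- 0.52 + 0.48 * exp(-((t - 0.24) / 0.26)^2) -
    0.18 * exp(-((t - 0.62) / 0.16)^2)
  cap <- (1 - (2 * t - 1)^8)^0.45
  f_lat <- 1 + 0.06 * exp(-((t - 0.30) / 0.30)^2)
  f_med <- 1 - 0.10 * exp(-((t - 0.60) / 0.18)^2)
  pert <- withr::with_seed(seed, {
    amps <- matrix(stats::rnorm(6, 0, 0.02), 2, 3)
    phs <- matrix(stats::runif(6, 0, 2 * pi), 2, 3)
    vapply(1:2, function(side) {
      rowSums(vapply(1:3, function(k)
        amps[side, k] * sin(2 * pi * k * t + phs[side, k]), numeric(length(t))))
    }, numeric(length(t)))
  })
  hw_med <- pmax(base * cap * f_med * (1 + pert[, 1]), 0)
  hw_lat <- pmax(base * cap * f_lat * (1 + pert[, 2]), 0)
  y <- t * length_px
  x_med <- -hw_med; x_lat <- hw_lat
  target_w <- width_ratio * length_px
  sc <- target_w / (max(x_lat) - min(x_med))
  x_med <- x_med * sc; x_lat <- x_lat * sc
  # lateral side toe -> heel, then medial side heel -> toe; tips are single
  # vertices (width 0 at t = 0, 1)
  verts <- rbind(
    cbind(x_lat[-c(1, n_side)], y[-c(1, n_side)]),
    c(x_lat[n_side], y[n_side]),
    cbind(rev(x_med[-c(1, n_side)]), rev(y[-c(1, n_side)])),
    c(x_med[1], y[1])
  )
  foot_outline(verts, side = "left")
}

# Minimum distance from each point to the polygon boundary.
dist_to_boundary <- function(pts, verts) {
  n <- nrow(verts)
  vn <- rbind(verts[-1, , drop = FALSE], verts[1, , drop = FALSE])
  px <- pts[, 1]; py <- pts[, 2]
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    ax <- verts[i, 1]; ay <- verts[i, 2]
    bx <- vn[i, 1]; by <- vn[i, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx^2 + dy^2
    tt <- if (L2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * dx + (py - ay) * dy) / L2, 0), 1)
    d2 <- (px - (ax + tt * dx))^2 + (py - (ay + tt * dy))^2
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Construct a continuous ground-truth wear field over a foot
#'
#' Wear intensity is modelled as a baseline plus a Gaussian bump under the
#' distal end of the keel plus an elevated band along the foot edge —
#' reproducing the pattern of worn SACH feet, where wear is highest under
#' the distal keel and around the outer edge — plus optional smooth spatial
#' noise. The keel is anchored a fixed distance from the heel, so its bump
#' sits relatively closer to the toes in shorter feet (feet of different
#' sizes share the same keel).
#'
#' @param outline A [foot_outline()].
#' @param params Named list overriding defaults: `baseline` (1),
#'   `keel_amplitude` (6), `keel_radius` (30 px), `keel_offset` (140 px from
#'   the heel along the foot axis), `edge_amplitude` (3), `edge_width`
#'   (12 px), `noise_sd` (0.4), `noise_scale` (40 px correlation length).
#'   Amplitudes are in the same arbitrary intensity units as `baseline`.
#' @param seed Seed for the spatial noise component.
#' @return A `wear_field`: the domain outline, parameters, an `intensity(x,
#'   y)` vectorised evaluator (clamped at 0), the keel centre, and
#'   `design_max = baseline + keel_amplitude + edge_amplitude`, the range
#'   over which score thresholds are spread by default.
#' @export
make_wear_field <- function(outline, params = list(), seed = 1L) {
  stopifnot(inherits(outline, "foot_outline"))
  p <- utils::modifyList(list(
    baseline = 1, keel_amplitude = 6, keel_radius = 30, keel_offset = 140,
    edge_amplitude = 3, edge_width = 12, noise_sd = 0.4, noise_scale = 40
  ), params)
  if (p$keel_amplitude < 0 || p$edge_amplitude < 0) stop("amplitudes must be >= 0")
  if (p$keel_radius <= 0 || p$edge_width <= 0) stop("radius and width must be > 0")
  ax <- fit_grid(outline, rows = 1L, cols = 1L)
  axes <- placement_axes(ax)
  len <- ax$cell_height; wid <- ax$cell_width
  keel_center <- ax$origin + max(len - p$keel_offset, 0.2 * len) * axes$u +
    (wid / 2) * axes$w
  K <- 8L
  wave <- withr::with_seed(seed, list(
    theta = stats::runif(K, 0, 2 * pi),
    lambda = stats::runif(K, 0.7, 1.5) * p$noise_scale,
    phi = stats::runif(K, 0, 2 * pi)
  ))
  verts <- outline$vertices
  intensity <- function(x, y) {
    v <- p$baseline +
      p$keel_amplitude *
        exp(-((x - keel_center[1])^2 + (y - keel_center[2])^2) /
              (2 * p$keel_radius^2))
    if (p$edge_amplitude > 0) {
      d <- dist_to_boundary(cbind(x, y), verts)
      v <- v + p$edge_amplitude * pmax(0, 1 - d / p$edge_width)
    }
    if (p$noise_sd > 0) {
      ns <- 0
      for (k in seq_len(K)) {
        ns <- ns + cos(2 * pi * (x * cos(wave$theta[k]) + y * sin(wave$theta[k])) /
                         wave$lambda[k] + wave$phi[k])
      }
      v <- v + p$noise_sd * sqrt(2 / K) * ns
    }
    pmax(v, 0)
  }
  structure(list(domain = outline, params = p, intensity = intensity,
                 keel_center = keel_center,
                 design_max = p$baseline + p$keel_amplitude + p$edge_amplitude),
            class = "wear_field")
}

#' @export
print.wear_field <- function(x, ...) {
  cat(sprintf("<wear_field: baseline %.1f, keel bump %.1f @ (%.0f, %.0f), edge band %.1f, noise sd %.2f>\n",
              x$params$baseline, x$params$keel_amplitude, x$keel_center[1],
              x$keel_center[2], x$params$edge_amplitude, x$params$noise_sd))
  invisible(x)
}

default_thresholds <- function(field, n_levels) {
  field$design_max * seq_len(n_levels - 1L) / n_levels
}

# Mean field intensity per cell, by a samples x samples quadrature grid.
cell_mean_intensity <- function(field, p, samples = 4L) {
  s <- samples
  off <- (seq_len(s) - 0.5) / s
  rr <- rep(seq_len(p$rows), times = p$cols)
  cc <- rep(seq_len(p$cols), each = p$rows)
  oa <- as.vector(outer(off, rep(1, s)))    # within-cell a offsets
  ob <- as.vector(outer(rep(1, s), off))    # within-cell b offsets
  a_pts <- (matrix(rr - 1, nrow = length(rr), ncol = s * s) +
              matrix(oa, nrow = length(rr), ncol = s * s, byrow = TRUE)) * p$cell_height
  b_pts <- (matrix(cc - 1, nrow = length(cc), ncol = s * s) +
              matrix(ob, nrow = length(cc), ncol = s * s, byrow = TRUE)) * p$cell_width
  ax <- placement_axes(p)
  x <- p$origin[1] + a_pts * ax$u[1] + b_pts * ax$w[1]
  y <- p$origin[2] + a_pts * ax$u[2] + b_pts * ax$w[2]
  vals <- field$intensity(as.vector(x), as.vector(y))
  mi <- rowMeans(matrix(vals, nrow = length(rr)))
  matrix(mi, p$rows, p$cols)
}

#' Discretize a wear field into a noise-free score grid
#'
#' The ground-truth scoring of a simulated foot: per scoreable cell the mean
#' field intensity is binned into an ordinal level by strictly increasing
#' thresholds; cells failing the 50%-fill rule are `NA`. Used feet score on
#' levels 1 and up (0 is reserved for unused feet).
#'
#' @param field A [make_wear_field()].
#' @param placement A [grid_placement()].
#' @param scale Scale to score on.
#' @param thresholds Increasing numeric vector, one fewer than the number of
#'   numeric levels; default equally spaced over `(0, design_max)`.
#' @param foot_id,rater_id,session Metadata for the resulting grid.
#' @param samples Quadrature points per cell side.
#' @return A [score_grid()].
#' @export
render_true_grid <- function(field, placement, scale = "original",
                             thresholds = NULL, foot_id = "sim",
                             rater_id = "truth", session = 1L, samples = 4L) {
  stopifnot(inherits(field, "wear_field"), inherits(placement, "grid_placement"))
  scale <- as_wear_scale(scale)
  levels_used <- scale$levels[scale$levels >= 1L]  # used foot: no 0
  if (is.null(thresholds)) {
    thresholds <- default_thresholds(field, length(levels_used))
  }
  if (length(thresholds) != length(levels_used) - 1L) {
    stop(sprintf("need %d thresholds for %d levels, got %d",
                 length(levels_used) - 1L, length(levels_used),
                 length(thresholds)))
  }
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  mask <- apply_na_rule(cell_coverage(field$domain, placement))
  mi <- cell_mean_intensity(field, placement, samples)
  lev <- levels_used[1L + findInterval(as.vector(mi), thresholds)]
  cells <- matrix(as.integer(lev), placement$rows, placement$cols)
  cells[!mask] <- NA_integer_
  score_grid(cells, foot_id = foot_id, rater_id = rater_id, session = session,
             scale = scale, used = TRUE)
}

#' Describe a (possibly imperfect) rater
#'
#' @param bias Signed score offset added before rounding.
#' @param noise_sd Gaussian score noise, in level units (humans mis-score by
#'   adjacent levels, so noise acts on the level scale, not on intensity).
#' @param shift Grid misalignment, fractions of a cell `(rows, cols)`
#'   direction — expressed in cell units so a rater's placement error scales
#'   with foot size.
#' @param rotation Grid misalignment rotation, radians about the grid
#'   centre.
#' @param lapse_rate Probability a cell gets a uniformly random level.
#' @return A `rater_model`.
#' @export
rater_model <- function(bias = 0, noise_sd = 0.5, shift = c(0, 0),
                        rotation = 0, lapse_rate = 0.01) {
  stopifnot(noise_sd >= 0, lapse_rate >= 0, lapse_rate <= 1,
            length(shift) == 2L)
  structure(list(bias = bias, noise_sd = noise_sd, shift = as.numeric(shift),
                 rotation = rotation, lapse_rate = lapse_rate),
            class = "rater_model")
}

#' The identity rater (no bias, noise, misalignment or lapses)
#' @return A `rater_model` that reproduces [render_true_grid()] exactly.
#' @export
identity_rater <- function() {
  rater_model(bias = 0, noise_sd = 0, shift = c(0, 0), rotation = 0,
              lapse_rate = 0)
}

perturb_placement <- function(p, model) {
  ax <- placement_axes(p)
  center <- p$origin + (p$rows * p$cell_height / 2) * ax$u +
    (p$cols * p$cell_width / 2) * ax$w
  rot <- p$rotation + model$rotation
  u2 <- c(cos(rot), sin(rot)); w2 <- c(-u2[2], u2[1])
  origin <- center - (p$rows * p$cell_height / 2) * u2 -
    (p$cols * p$cell_width / 2) * w2 +
    model$shift[1] * p$cell_height * u2 + model$shift[2] * p$cell_width * w2
  grid_placement(origin, rot, p$cell_height, p$cell_width, p$rows, p$cols)
}

#' Simulate one rater scoring one foot
#'
#' The rater places the grid with their own misalignment (re-deriving their
#' own NA mask from the shifted grid, so border disagreement includes
#' NA-vs-score conflicts — the dominant error mode at foot edges), reads the
#' true level in each scoreable cell, then perturbs it:
#' `clamp(round(level + bias + N(0, noise_sd)))`, replaced with a uniformly
#' random level with probability `lapse_rate`.
#'
#' @param field A [make_wear_field()].
#' @param outline The foot's outline (normally `field$domain`).
#' @param true_placement The reference [grid_placement()] from [fit_grid()].
#' @param model A [rater_model()].
#' @param scale Scale to score on.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param thresholds,samples Passed to [render_true_grid()].
#' @param foot_id,rater_id,session Metadata for the resulting grid.
#' @return A [score_grid()].
#' @export
simulate_rater <- function(field, outline, true_placement, model,
                           scale = "original", seed = 1L, thresholds = NULL,
                           foot_id = "sim", rater_id = "rater", session = 1L,
                           samples = 4L) {
  stopifnot(inherits(model, "rater_model"))
  scale <- as_wear_scale(scale)
  pl <- perturb_placement(true_placement, model)
  g <- render_true_grid(field, pl, scale = scale, thresholds = thresholds,
                        foot_id = foot_id, rater_id = rater_id,
                        session = session, samples = samples)
  levels_used <- scale$levels[scale$levels >= 1L]
  cells <- g$cells
  idx <- which(!is.na(cells))
  if (length(idx)) {
    withr::with_seed(seed, {
      noisy <- cells[idx] + model$bias
      if (model$noise_sd > 0) {
        noisy <- noisy + stats::rnorm(length(idx), 0, model$noise_sd)
      }
      noisy <- pmin(pmax(round(noisy), min(levels_used)), max(levels_used))
      if (model$lapse_rate > 0) {
        lapse <- stats::runif(length(idx)) < model$lapse_rate
        noisy[lapse] <- sample(levels_used, sum(lapse), replace = TRUE)
      }
      cells[idx] <- as.integer(noisy)
    })
  }
  g$cells <- cells
  g
}

#' Simulation configuration
#'
#' Defaults mirror the reliability-study design the package targets: 48
#' feet scored by 4 rater groups on a 20x10 grid, foot lengths 180--260 px
#' with width 38--48% of length, original 0--9 scale.
#'
#' @param n_feet,m_raters,sessions Panel dimensions (all >= 1).
#' @param rows,cols Grid size.
#' @param foot_length_range Min/max toe-heel length in px.
#' @param width_ratio_range Min/max bounding-box width as fraction of
#'   length.
#' @param scale Scoring scale.
#' @param seed Master seed; fixes the full output stream.
#' @param field_params Overrides passed to [make_wear_field()].
#' @return A `sim_config`.
#' @export
sim_config <- function(n_feet = 48L, m_raters = 4L, sessions = 1L,
                       rows = 20L, cols = 10L,
                       foot_length_range = c(180, 260),
                       width_ratio_range = c(0.38, 0.48),
                       scale = "original", seed = 1L, field_params = list()) {
  stopifnot(n_feet >= 1, m_raters >= 1, sessions >= 1, rows >= 1, cols >= 1)
  structure(list(n_feet = as.integer(n_feet), m_raters = as.integer(m_raters),
                 sessions = as.integer(sessions), rows = as.integer(rows),
                 cols = as.integer(cols),
                 foot_length_range = foot_length_range,
                 width_ratio_range = width_ratio_range,
                 scale = as_wear_scale(scale), seed = as.integer(seed),
                 field_params = field_params),
            class = "sim_config")
}

#' Default panel of rater models
#'
#' One model per rater with no bias, 0.5-level score noise, a fixed
#' misalignment drawn once per rater (uniform within a quarter cell, plus up
#' to 2 degrees of rotation) and a 1% lapse rate — illustrative novice-rater
#' error magnitudes.
#'
#' @param m_raters Number of raters.
#' @param seed Seed for the per-rater misalignment draws.
#' @return List of [rater_model()]s.
#' @export
default_rater_models <- function(m_raters, seed = 1L) {
  lapply(seq_len(m_raters), function(j) {
    withr::with_seed(sub_seed(seed, 900000L + j), {
      rater_model(bias = 0, noise_sd = 0.5,
                  shift = stats::runif(2, -0.25, 0.25),
                  rotation = stats::runif(1, -2, 2) * pi / 180,
                  lapse_rate = 0.01)
    })
  })
}

#' Simulate a full multi-rater, multi-session rating panel
#'
#' Generates `n_feet` synthetic feet (outline, wear field, fitted grid) and
#' has every rater score every foot in every session. Each (foot, rater,
#' session) draws from its own RNG stream derived from the master seed, so
#' the panel is byte-reproducible and adding raters or sessions never
#' changes existing feet.
#'
#' @param cfg A [sim_config()].
#' @param rater_models List of `m_raters` [rater_model()]s; default
#'   [default_rater_models()].
#' @return A [rating_panel()]; the per-foot ground truth (outline, field,
#'   placement, true grid) is attached as `attr(panel, "truth")`.
#' @export
simulate_panel <- function(cfg, rater_models = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(rater_models)) {
    rater_models <- default_rater_models(cfg$m_raters, cfg$seed)
  }
  if (length(rater_models) != cfg$m_raters) {
    stop("need one rater model per rater")
  }
  grids <- list()
  truth <- list()
  for (i in seq_len(cfg$n_feet)) {
    foot_id <- sprintf("F%03d", i)
    dims <- withr::with_seed(sub_seed(cfg$seed, i * 1000L), c(
      stats::runif(1, cfg$foot_length_range[1], cfg$foot_length_range[2]),
      stats::runif(1, cfg$width_ratio_range[1], cfg$width_ratio_range[2])
    ))
    outline <- make_foot_outline(dims[1], dims[2],
                                 seed = sub_seed(cfg$seed, i * 1000L + 1L))
    field <- make_wear_field(outline, cfg$field_params,
                             seed = sub_seed(cfg$seed, i * 1000L + 2L))
    placement <- fit_grid(outline, cfg$rows, cfg$cols)
    truth[[foot_id]] <- list(
      outline = outline, field = field, placement = placement,
      true_grid = render_true_grid(field, placement, scale = cfg$scale,
                                   foot_id = foot_id))
    for (j in seq_len(cfg$m_raters)) {
      rater_id <- sprintf("G%d", j)
      for (s in seq_len(cfg$sessions)) {
        grids[[length(grids) + 1L]] <- simulate_rater(
          field, outline, placement, rater_models[[j]], scale = cfg$scale,
          seed = sub_seed(cfg$seed, i * 1000L + j * 20L + s),
          foot_id = foot_id, rater_id = rater_id, session = s)
      }
    }
  }
  panel <- rating_panel(grids)
  attr(panel, "truth") <- truth
  panel
}
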