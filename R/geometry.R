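# Polygon primitives -----------------------------------------------------
#
# Coverage fractions need exact cell-by-outline intersection areas. Cells are
# rectangles (convex), so a Sutherland-Hodgman half-plane clip of the outline
# against each cell edge, followed by the shoelace formula, is exact for
# simple polygons (bridging edges produced on non-convex subjects have zero
# area). All clips are vectorised over vertices.

#' Polygon area and centroid
#'
#' Shoelace-formula helpers for working with outline vertex matrices.
#'
#' @param xy n x 2 vertex matrix (closed polygon, no repeated last vertex).
#' @return `poly_area()`: the enclosed area; `poly_centroid()`: the (x, y)
#'   area centroid.
#' @export
poly_area <- function(xy) abs(poly_signed_area(xy))

poly_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @rdname poly_area
#' @export
poly_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Covariance of the uniform measure over the polygon's interior (about its
# area centroid); its leading eigenvector is the outline's length axis.
poly_covariance <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cen <- poly_centroid(xy)
  sxx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  syy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  m <- matrix(c(sxx / a - cen[1]^2, sxy / a - cen[1] * cen[2],
                sxy / a - cen[1] * cen[2], syy / a - cen[2]^2), 2, 2)
  m
}

# Keep the part of `xy` with nx*x + ny*y <= d.
clip_halfplane <- function(xy, nx, ny, d) {
  n <- nrow(xy)
  if (n == 0L) return(xy)
  x <- xy[, 1]; y <- xy[, 2]
  f <- nx * x + ny * y - d
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  fn <- c(f[-1], f[1])
  ins <- f <= 0; insn <- fn <= 0
  cross <- xor(ins, insn)
  tt <- ifelse(cross, f / (f - fn), 0)
  px <- x + tt * (xn - x); py <- y + tt * (yn - y)
  keep <- as.vector(rbind(ins, cross))
  out_x <- as.vector(rbind(x, px))[keep]
  out_y <- as.vector(rbind(y, py))[keep]
  cbind(out_x, out_y, deparse.level = 0)
}

poly_self_intersects <- function(xy) {
  n <- nrow(xy)
  seg <- cbind(xy, rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]))
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # skip edges sharing a vertex
    if (length(js) == 0L) next
    if (any(segments_cross(seg[i, ], seg[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

segments_cross <- function(s1, s2) {
  # s1: length-4 (x1,y1,x2,y2); s2: matrix of segments
  o <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  d1 <- o(s1[1], s1[2], s1[3], s1[4], s2[, 1], s2[, 2])
  d2 <- o(s1[1], s1[2], s1[3], s1[4], s2[, 3], s2[, 4])
  d3 <- o(s2[, 1], s2[, 2], s2[, 3], s2[, 4], s1[1], s1[2])
  d4 <- o(s2[, 1], s2[, 2], s2[, 3], s2[, 4], s1[3], s1[4])
  d1 * d2 < 0 & d3 * d4 < 0
}

# Foot outlines -----------------------------------------------------------

#' Construct a foot outline polygon
#'
#' The plantar outline of a foot as a closed simple polygon in image
#' coordinates (pixels). Reliability analyses assume all feet are
#' left-oriented; right-foot photographs are mirrored first
#' ([mirror_outline()]).
#'
#' @param vertices Numeric n x 2 matrix (or data frame) of (x, y) vertices,
#'   in order, without a repeated closing vertex.
#' @param side `"left"` or `"right"`.
#' @return A `foot_outline` object.
#' @export
foot_outline <- function(vertices, side = c("left", "right")) {
  side <- match.arg(side)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("an outline needs an n x 2 matrix with at least 3 vertices")
  }
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (poly_area(vertices) <= 0) stop("outline has zero area")
  if (poly_self_intersects(vertices)) stop("outline polygon self-intersects")
  structure(list(vertices = vertices, closed = TRUE, side = side,
                 mirrored = FALSE),
            class = "foot_outline")
}

#' @export
print.foot_outline <- function(x, ...) {
  cat(sprintf("<foot_outline: %d vertices, side %s%s, area %.1f px^2>\n",
              nrow(x$vertices), x$side,
              if (isTRUE(x$mirrored)) " (mirrored)" else "",
              poly_area(x$vertices)))
  invisible(x)
}

#' Mirror a right-foot outline to left orientation
#'
#' Reflects x coordinates about the outline's bounding-box midline, so a
#' right foot can be scored with the left-foot grid convention. The result
#' carries `mirrored = TRUE` so score grids derived from it can record
#' `side = "mirrored_right"`.
#'
#' @param o A [foot_outline()] with `side = "right"`.
#' @return A left-oriented `foot_outline`.
#' @export
mirror_outline <- function(o) {
  stopifnot(inherits(o, "foot_outline"))
  if (o$side == "left") {
    warning("outline is already left-oriented; returning it unchanged")
    return(o)
  }
  mid <- (min(o$vertices[, 1]) + max(o$vertices[, 1])) / 2
  v <- o$vertices
  v[, 1] <- 2 * mid - v[, 1]
  out <- o
  out$vertices <- v
  out$side <- "left"
  out$mirrored <- TRUE
  out
}

# Grid placement ----------------------------------------------------------

#' Create a grid placement directly
#'
#' A `grid_placement` maps the unit scoring grid onto image coordinates:
#' `origin` is the toe-medial corner of cell R1C1, `rotation` the direction
#' (radians) of the row axis (toe to heel), and `cell_height`/`cell_width`
#' the cell extents along and across that axis.
#'
#' @param origin Numeric (x, y).
#' @param rotation Radians.
#' @param cell_height,cell_width Positive cell extents in px.
#' @param rows,cols Grid dimensions.
#' @return A `grid_placement` object.
#' @export
grid_placement <- function(origin, rotation, cell_height, cell_width,
                           rows = 20L, cols = 10L) {
  stopifnot(cell_height > 0, cell_width > 0, rows >= 1, cols >= 1)
  structure(list(origin = as.numeric(origin), rotation = as.numeric(rotation),
                 cell_height = cell_height, cell_width = cell_width,
                 rows = as.integer(rows), cols = as.integer(cols)),
            class = "grid_placement")
}

#' @export
print.grid_placement <- function(x, ...) {
  cat(sprintf("<grid_placement: %dx%d cells of %.2f x %.2f px, rotation %.1f deg>\n",
              x$rows, x$cols, x$cell_height, x$cell_width,
              x$rotation * 180 / pi))
  invisible(x)
}

placement_axes <- function(p) {
  u <- c(cos(p$rotation), sin(p$rotation))   # row axis, toe -> heel
  w <- c(-u[2], u[1])                        # column axis, C1 edge -> Ccols edge
  list(u = u, w = w)
}

# Outline vertices in grid-frame coordinates: a along rows, b along columns.
grid_frame_coords <- function(o, p) {
  ax <- placement_axes(p)
  v <- sweep(o$vertices, 2, p$origin)
  cbind(v %*% ax$u, v %*% ax$w)
}

#' Fit the scoring grid to a foot outline
#'
#' Scales and rotates the rows x cols grid so its long axis spans the
#' outline's principal (toe-heel) axis and its cells tile the outline's
#' oriented bounding box: rows partition foot length, columns partition
#' width, mimicking how the grid is aligned over a plantar photograph.
#'
#' The principal axis is the leading eigenvector of the outline's
#' second-moment (area covariance) tensor. The toe end is taken as the wider
#' half of the outline (the forefoot is wider than the heel); pass
#' `toe = "flip"` to override. Row 1 sits at the toe, column 1 at the
#' grid-frame edge obtained by rotating the toe-to-heel axis 90 degrees
#' counterclockwise (the medial edge of a left foot in standard plantar
#' image orientation).
#'
#' @param o A left-oriented [foot_outline()].
#' @param rows,cols Grid dimensions (default 20 x 10, i.e. 200 cells).
#' @param toe `"auto"` (wider half is the toe) or `"flip"`.
#' @return A [grid_placement()].
#' @export
fit_grid <- function(o, rows = 20L, cols = 10L, toe = c("auto", "flip")) {
  stopifnot(inherits(o, "foot_outline"))
  toe <- match.arg(toe)
  if (poly_area(o$vertices) <= 0) stop("degenerate outline: zero area")
  cen <- poly_centroid(o$vertices)
  ev <- eigen(poly_covariance(o$vertices), symmetric = TRUE)
  u <- ev$vectors[, 1]                      # length axis
  v <- sweep(o$vertices, 2, cen)
  a <- as.vector(v %*% u)
  amid <- (min(a) + max(a)) / 2
  # area of the half at low a (toward -u)
  low <- clip_halfplane(v, u[1], u[2], amid)
  area_low <- if (nrow(low) >= 3) poly_area(low) else 0
  wider_low <- area_low >= poly_area(o$vertices) / 2
  if (!wider_low) u <- -u                   # toe (wider half) at low a
  if (toe == "flip") u <- -u
  w <- c(-u[2], u[1])
  a <- as.vector(v %*% u)
  b <- as.vector(v %*% w)
  len <- max(a) - min(a); wid <- max(b) - min(b)
  if (len <= 0 || wid <= 0) stop("degenerate outline: zero extent")
  origin <- cen + min(a) * u + min(b) * w
  grid_placement(origin = origin, rotation = atan2(u[2], u[1]),
                 cell_height = len / rows, cell_width = wid / cols,
                 rows = rows, cols = cols)
}

#' Corner coordinates of one grid cell
#'
#' @param p A [grid_placement()].
#' @param row,col 1-based cell indices.
#' @return 4 x 2 matrix of corner (x, y), counterclockwise.
#' @export
cell_polygon <- function(p, row, col) {
  stopifnot(row >= 1, row <= p$rows, col >= 1, col <= p$cols)
  ax <- placement_axes(p)
  a0 <- (row - 1) * p$cell_height; a1 <- row * p$cell_height
  b0 <- (col - 1) * p$cell_width;  b1 <- col * p$cell_width
  corners <- rbind(c(a0, b0), c(a1, b0), c(a1, b1), c(a0, b1))
  t(apply(corners, 1, function(ab) p$origin + ab[1] * ax$u + ab[2] * ax$w))
}

#' Fraction of each grid cell covered by the foot
#'
#' For every cell, the exact area of (cell intersect outline) divided by the
#' cell's area, computed by half-plane clipping. This is the quantity the
#' 50%-fill rule thresholds ([apply_na_rule()]).
#'
#' @param o A [foot_outline()].
#' @param p A [grid_placement()].
#' @return rows x cols numeric matrix of fractions in `[0, 1]`.
#' @export
cell_coverage <- function(o, p) {
  stopifnot(inherits(o, "foot_outline"), inherits(p, "grid_placement"))
  fr <- grid_frame_coords(o, p)
  h <- p$cell_height; w <- p$cell_width
  out <- matrix(0, p$rows, p$cols)
  for (cc in seq_len(p$cols)) {
    strip <- clip_halfplane(fr, 0, 1, cc * w)          # b <= c*w
    strip <- clip_halfplane(strip, 0, -1, -(cc - 1) * w)  # b >= (c-1)*w
    if (nrow(strip) < 3L) next
    for (rr in seq_len(p$rows)) {
      cell <- clip_halfplane(strip, 1, 0, rr * h)
      cell <- clip_halfplane(cell, -1, 0, -(rr - 1) * h)
      if (nrow(cell) >= 3L) out[rr, cc] <- poly_area(cell) / (h * w)
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Apply the 50%-fill scoreability rule
#'
#' Cells at least half filled by the foot (or by its reconstructed outline,
#' when parts are missing) receive numerical scores; all others are NA. The
#' threshold comparison is inclusive: coverage of exactly 0.5 is scoreable.
#'
#' @param cov Coverage matrix from [cell_coverage()].
#' @param threshold Fraction in (0, 1]; default 0.5.
#' @return Logical matrix, `TRUE` = scoreable.
#' @export
apply_na_rule <- function(cov, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  cov >= threshold
}

#' Classify scoreable cells as border or interior
#'
#' A border cell is scoreable but has at least one 4-neighbour (or the grid
#' edge) that is not scoreable — the cells where the edge effect degrades
#' agreement.
#'
#' @param mask Logical scoreability matrix (from [apply_na_rule()]).
#' @return Character matrix: `"border"`, `"interior"`, or `NA` for
#'   non-scoreable cells.
#' @export
classify_cells <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  out <- matrix(NA_character_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      nb <- c(pad[r, c + 1], pad[r + 2, c + 1], pad[r + 1, c], pad[r + 1, c + 2])
      out[r, c] <- if (all(nb)) "interior" else "border"
    }
  }
  out
}
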