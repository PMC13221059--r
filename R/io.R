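#' Cell labels of the form "RxCy"
#'
#' Cells are addressed by 1-based row/column labels like `"R5C7"` (row 5,
#' column 7), with row 1 at the toe and column 1 at the medial edge of a
#' left foot.
#'
#' @param row,col 1-based indices (vectorised).
#' @return Character vector of labels.
#' @export
cell_label <- function(row, col) sprintf("R%dC%d", as.integer(row), as.integer(col))

#' Parse a cell label
#'
#' @param label Character vector of `"RxCy"` labels.
#' @param rows,cols Grid bounds for range checking (default 20 x 10).
#' @return Data frame with integer columns `row`, `col`.
#' @examples
#' parse_cell_label("R5C7")
#' @export
parse_cell_label <- function(label, rows = 20L, cols = 10L) {
  m <- regmatches(label, regexec("^R([0-9]+)C([0-9]+)$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("malformed cell label: %s (expected RxCy)", label[bad][1]))
  }
  row <- vapply(m, function(x) as.integer(x[2]), integer(1))
  col <- vapply(m, function(x) as.integer(x[3]), integer(1))
  oob <- row < 1L | row > rows | col < 1L | col > cols
  if (any(oob)) {
    stop(sprintf("cell label %s is out of range for a %dx%d grid",
                 label[oob][1], rows, cols))
  }
  data.frame(row = row, col = col)
}

#' Write a rating panel to long-format CSV
#'
#' One row per cell: columns `foot_id`, `rater_id`, `session`, `cell`
#' ("RxCy"), `score` (level or `"NA"`), `scale`, `side`, `used`. This is
#' the package's interchange schema; [read_scores_csv()] inverts it
#' losslessly.
#'
#' @param panel A [rating_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(panel, path) {
  stopifnot(inherits(panel, "rating_panel"))
  rows <- lapply(panel$grids, function(g) {
    idx <- expand.grid(row = seq_len(g$rows), col = seq_len(g$cols))
    data.frame(
      foot_id = g$foot_id, rater_id = g$rater_id, session = g$session,
      cell = cell_label(idx$row, idx$col),
      score = ifelse(is.na(g$cells[cbind(idx$row, idx$col)]), "NA",
                     as.character(g$cells[cbind(idx$row, idx$col)])),
      scale = g$scale$name, side = g$side, used = g$used,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rating panel from long-format CSV
#'
#' Expects the schema written by [write_scores_csv()] (`side` and `used`
#' are optional, defaulting to `"left"` and `TRUE`). `"NA"` scores
#' (case-insensitive) mark cells outside the foot. Grid dimensions are
#' inferred from the largest cell label unless given. Duplicate (foot,
#' rater, session, cell) records and incomplete grids are errors.
#'
#' @param path CSV path.
#' @param rows,cols Grid dimensions; `NULL` to infer.
#' @return A [rating_panel()].
#' @export
read_scores_csv <- function(path, rows = NULL, cols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  need <- c("foot_id", "rater_id", "session", "cell", "score", "scale")
  if (!all(need %in% names(df))) {
    stop(sprintf("score CSV is missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  sc <- unique(tolower(df$scale))
  if (length(sc) != 1L || !sc %in% c("original", "modified")) {
    stop(sprintf("unknown or mixed scale tag: %s", paste(sc, collapse = ", ")))
  }
  if (is.null(rows) || is.null(cols)) {
    rc <- parse_cell_label(df$cell, rows = .Machine$integer.max,
                           cols = .Machine$integer.max)
    rows <- max(rc$row); cols <- max(rc$col)
  } else {
    rc <- parse_cell_label(df$cell, rows = rows, cols = cols)
  }
  key <- paste(df$foot_id, df$rater_id, df$session, df$cell, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop(sprintf("duplicate record for foot %s, rater %s, session %s, cell %s",
                 d[1], d[2], d[3], d[4]))
  }
  score <- suppressWarnings(as.integer(df$score))
  not_na_marker <- toupper(trimws(df$score)) != "NA"
  if (any(not_na_marker & is.na(score))) {
    stop(sprintf("unparseable score value: %s",
                 df$score[not_na_marker & is.na(score)][1]))
  }
  gk <- paste(df$foot_id, df$rater_id, df$session, sep = "\r")
  grids <- lapply(split(seq_len(nrow(df)), gk), function(ii) {
    sub <- df[ii, ]
    sub_rc <- rc[ii, ]
    have <- cell_label(sub_rc$row, sub_rc$col)
    all_cells <- cell_label(rep(seq_len(rows), cols),
                            rep(seq_len(cols), each = rows))
    missing <- setdiff(all_cells, have)
    if (length(missing)) {
      stop(sprintf("grid for foot %s / rater %s / session %s is missing cell(s): %s",
                   sub$foot_id[1], sub$rater_id[1], sub$session[1],
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
    cells <- matrix(NA_integer_, rows, cols)
    cells[cbind(sub_rc$row, sub_rc$col)] <- score[ii]
    side <- if ("side" %in% names(sub)) sub$side[1] else "left"
    used <- if ("used" %in% names(sub)) toupper(sub$used[1]) %in% c("TRUE", "1") else TRUE
    score_grid(cells, foot_id = sub$foot_id[1], rater_id = sub$rater_id[1],
               session = as.integer(sub$session[1]), scale = tolower(sub$scale[1]),
               side = side, used = used)
  })
  rating_panel(unname(grids))
}

#' Outline JSON I/O
#'
#' Outlines are stored as a JSON object with a `vertices` array of `[x, y]`
#' pairs and a `side` tag.
#'
#' @param o A [foot_outline()].
#' @param path JSON path.
#' @return `write_outline_json()` returns `path` invisibly;
#'   `read_outline_json()` returns a `foot_outline`.
#' @export
write_outline_json <- function(o, path) {
  stopifnot(inherits(o, "foot_outline"))
  jsonlite::write_json(list(vertices = unname(apply(o$vertices, 1, c,
                                                    simplify = FALSE)),
                            side = o$side),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_outline_json
#' @export
read_outline_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- j$vertices
  if (is.list(v)) v <- do.call(rbind, v)
  foot_outline(v, side = if (is.null(j$side)) "left" else j$side)
}

#' Grid placement JSON I/O
#'
#' @param p A [grid_placement()].
#' @param path JSON path.
#' @return `write_placement_json()` returns `path` invisibly;
#'   `read_placement_json()` returns a `grid_placement`.
#' @export
write_placement_json <- function(p, path) {
  stopifnot(inherits(p, "grid_placement"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_placement_json
#' @export
read_placement_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_placement(j$origin, j$rotation, j$cell_height, j$cell_width,
                 j$rows, j$cols)
}

#' Simulation config JSON I/O
#'
#' @param cfg A [sim_config()].
#' @param path JSON path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x$scale <- cfg$scale$name
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- sim_config()
  for (f in c("n_feet", "m_raters", "sessions", "rows", "cols",
              "foot_length_range", "width_ratio_range", "scale", "seed",
              "field_params")) {
    if (is.null(j[[f]])) {
      j[[f]] <- if (f == "scale") defaults$scale$name else defaults[[f]]
    }
  }
  sim_config(n_feet = j$n_feet, m_raters = j$m_raters, sessions = j$sessions,
             rows = j$rows, cols = j$cols,
             foot_length_range = j$foot_length_range,
             width_ratio_range = j$width_ratio_range, scale = j$scale,
             seed = j$seed, field_params = as.list(j$field_params))
}
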