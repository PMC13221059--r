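#' Ordinal wear scales for plantar-surface scoring
#'
#' Two ordinal rubrics are used to score wear in each grid cell of the
#' plantar surface of a SACH prosthetic foot: the `original` 0--9 scale,
#' whose levels track progressive exposure of the two nylon reinforcement
#' sheets moulded into the sole, and the `modified` (minimalist) 0--5 scale,
#' which trades resolution for applicability to foot designs without nylon
#' sheets. `NA` is a distinct marker meaning the cell lies outside the foot
#' (even a pristine foot would not occupy it); it is never a numeric level.
#'
#' @param name `"original"` or `"modified"`.
#' @return A `wear_scale` object: list with `name`, integer `levels`
#'   (0:9 or 0:5) and a named character vector `descriptions`.
#' @examples
#' wear_scale("original")$levels
#' wear_scale("modified")$descriptions[["4"]]
#' @export
wear_scale <- function(name = c("original", "modified")) {
  name <- match.arg(name)
  if (name == "original") {
    levels <- 0:9
    descriptions <- c(
      "0" = "No wear (newly manufactured, not yet used)",
      "1" = "No observable wear",
      "2" = "First layer of nylon exposed",
      "3" = "Second layer of nylon exposed",
      "4" = "0%-33% of rubber under nylon exposed",
      "5" = "34%-66% of rubber under nylon exposed",
      "6" = "67%-99% of rubber under nylon exposed",
      "7" = "100% of rubber under nylon exposed",
      "8" = "Portions of rubber missing",
      "9" = "Portions of foot completely missing"
    )
  } else {
    levels <- 0:5
    descriptions <- c(
      "0" = "No wear (newly manufactured, not yet used)",
      "1" = "No observable wear",
      "2" = "Wear present, but minimal (e.g., surface scratches, small gouges, or texture altered)",
      "3" = "Wear present, and significant/advanced (e.g., deep scratches/gouges or visible changes in foot height)",
      "4" = "Portions of the foot are missing, beyond scratches/gouges, but the cell still contains portions of foot",
      "5" = "Cell should be occupied by the foot but is not due to foot fracture or extreme wear"
    )
  }
  structure(list(name = name, levels = levels, descriptions = descriptions),
            class = "wear_scale")
}

#' @export
print.wear_scale <- function(x, ...) {
  cat(sprintf("<wear_scale: %s, levels %d-%d>\n", x$name,
              min(x$levels), max(x$levels)))
  invisible(x)
}

as_wear_scale <- function(scale) {
  if (inherits(scale, "wear_scale")) return(scale)
  if (is.character(scale) && length(scale) == 1L) return(wear_scale(scale))
  stop("`scale` must be a wear_scale object or \"original\"/\"modified\"")
}

#' Export a rubric as a level/description table
#'
#' @param scale A `wear_scale` or its name.
#' @param path Optional CSV path; if given the table is written there.
#' @return A data frame with columns `level` (character, includes `"NA"`)
#'   and `description`, invisibly if `path` is given.
#' @export
rubric_table <- function(scale = "original", path = NULL) {
  scale <- as_wear_scale(scale)
  df <- data.frame(
    level = c(names(scale$descriptions), "NA"),
    description = c(unname(scale$descriptions),
                    "Even if all portions of the foot were present, no portion of the foot would occupy this cell"),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Collapse original-scale scores to the modified scale
#'
#' The minimalist 0--5 scale is a many-to-one coarsening of the 0--9 scale:
#' 0 and 1 are unchanged, 2--3 become 2, 4--7 become 3, 8 becomes 4 and 9
#' becomes 5. `NA` (cell outside the foot) propagates. The mapping is
#' monotone, so two raters who agreed on a cell before collapsing still agree
#' after: collapsing can only merge levels, never create new disagreement.
#'
#' @param s Integer vector of original-scale levels (0--9) and/or `NA`.
#' @return Integer vector of modified-scale levels (0--5) and/or `NA`.
#' @examples
#' collapse_score(c(0, 1, 2, 3, 4, 7, 8, 9, NA))
#' @export
collapse_score <- function(s) {
  if (length(s) == 0L) return(integer(0))
  num <- !is.na(s)
  v <- s[num]
  if (!is.numeric(s) && !all(is.na(s))) stop("invalid score: non-numeric input")
  if (any(v != as.integer(v) | v < 0 | v > 9)) {
    bad <- v[v != as.integer(v) | v < 0 | v > 9][1]
    stop(sprintf("invalid score: %s is not an original-scale level (0-9)", format(bad)))
  }
  map <- c(0L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 5L)  # index by level + 1
  out <- rep(NA_integer_, length(s))
  out[num] <- map[as.integer(v) + 1L]
  out
}
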