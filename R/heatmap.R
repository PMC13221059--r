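#' Export a per-cell matrix as a heatmap image plus a numeric CSV
#'
#' Renders a rows x cols cell matrix in the orientation of the scoring grid
#' (row 1 / toe at the top, column 1 / medial edge at the left) and writes
#' both a PNG image and a CSV holding the matrix values exactly as given
#' (no rendering-side rounding); `NA`/undefined cells are written as `NA`
#' in the CSV and drawn in a distinct grey.
#'
#' @param m rows x cols matrix: mean wear levels (`kind = "mean_wear"`),
#'   per-cell W (`"W"`), category labels or W values to bin
#'   (`"category"`), or intraobserver agreement counts
#'   (`"agreement_count"`).
#' @param path Output path; the `.png` and `.csv` extensions are applied to
#'   its base name.
#' @param kind One of `"mean_wear"`, `"W"`, `"category"`,
#'   `"agreement_count"`.
#' @param title Optional plot title.
#' @return Named character vector with the `png` and `csv` paths,
#'   invisibly.
#' @export
write_heatmap <- function(m, path,
                          kind = c("mean_wear", "W", "category", "agreement_count"),
                          title = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(m))
  base <- sub("\\.(png|csv)$", "", path)
  png_path <- paste0(base, ".png")
  csv_path <- paste0(base, ".csv")
  utils::write.table(m, csv_path, sep = ",", row.names = FALSE,
                     col.names = paste0("C", seq_len(ncol(m))), na = "NA")
  df <- data.frame(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  if (kind == "category") {
    lab <- if (is.character(m)) as.vector(m) else categorize_agreement(as.vector(m))
    df$value <- factor(lab, levels = agreement_categories()$label)
  }
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.2) +
    ggplot2::scale_y_reverse(breaks = pretty(seq_len(nrow(m)))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (medial to lateral)", y = "row (toe to heel)",
                  title = title, fill = switch(kind,
                    mean_wear = "mean wear", W = "Kendall's W",
                    category = "agreement", agreement_count = "same-score count")) +
    ggplot2::theme_minimal()
  gg <- gg + if (kind == "category") {
    ggplot2::scale_fill_manual(
      values = c("poor/slight" = "#d73027", "fair" = "#fc8d59",
                 "moderate" = "#fee08b", "good/substantial" = "#91cf60",
                 "excellent" = "#1a9850"),
      na.value = "grey60", drop = FALSE)
  } else {
    ggplot2::scale_fill_viridis_c(na.value = "grey60")
  }
  ggplot2::ggsave(png_path, gg, width = 4.5, height = 7, dpi = 150)
  invisible(c(png = png_path, csv = csv_path))
}
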