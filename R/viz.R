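# Diagnostic graphics: Van Krevelen scatter (O/C on x, H/C on y), DBE
# distributions, per-class range bars, DBE boxplots and a 3D
# H/C--O/C--DBE view. Coordinate mapping is pure (and unit-tested) and kept
# separate from rendering.

# fixed 20-class palette so figures are reproducible; recycled if a KB
# carries more classes
.class_palette <- function(classes) {
  base_cols <- c(
    "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd", "#8c564b",
    "#e377c2", "#7f7f7f", "#bcbd22", "#17becf", "#aec7e8", "#ffbb78",
    "#98df8a", "#ff9896", "#c5b0d5", "#c49c94", "#f7b6d2", "#c7c7c7",
    "#dbdb8d", "#9edae5"
  )
  classes <- sort(unique(classes))
  stats::setNames(rep(base_cols, length.out = length(classes)), classes)
}

.label_col <- function(data) {
  if ("top1_class" %in% names(data)) "top1_class"
  else if ("true_class" %in% names(data)) "true_class"
  else if ("class" %in% names(data)) "class"
  else NULL
}

#' Van Krevelen plot coordinates
#'
#' Pure coordinate mapping for the Van Krevelen diagram: x = O/C, y = H/C
#' (the conventional axis orientation). Rows with undefined ratios are
#' excluded and counted in the `excluded_count` attribute.
#'
#' @param data Annotated table with `hc` and `oc` columns (e.g. from
#'   [classify_table()]); a class label column (`top1_class`, `true_class`
#'   or `class`) is used when present, `"unclassified"` otherwise.
#' @return Tibble with `oc, hc, dbe, class, carbon`; attribute
#'   `excluded_count` gives the number of dropped rows.
#' @export
#' @examples
#' vk_points(classify_table(tibble::tibble(formula = "C15H10O7")))
vk_points <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("hc", "oc")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("input lacks required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  lab <- .label_col(data)
  cls <- if (is.null(lab)) rep("unclassified", nrow(data)) else data[[lab]]
  cls[is.na(cls)] <- "unclassified"
  out <- tibble::tibble(
    oc = data$oc, hc = data$hc,
    dbe = if ("dbe" %in% names(data)) data$dbe else NA_real_,
    class = cls,
    carbon = if ("c" %in% names(data)) data$c else NA_integer_
  )
  keep <- is.finite(out$oc) & is.finite(out$hc)
  excluded <- sum(!keep)
  out <- out[keep, ]
  attr(out, "excluded_count") <- excluded
  out
}

#' Per-class DBE histogram counts
#'
#' Bins DBE values per class label. The default bin width of 0.5 resolves
#' the half-integer DBE values of protonated single-nitrogen alkaloids; at
#' width 1.0 a value is assigned to its bin by the floor rule (6.5 falls in
#' \[6, 7)). Total counts are preserved (rows with missing DBE excluded and
#' counted).
#'
#' @param data Table with a `dbe` column; class labels as in [vk_points()].
#' @param bin_width 0.5 (default) or 1.0.
#' @return Tibble with `class, bin, n` where `bin` is the bin's left edge;
#'   attribute `excluded_count`.
#' @export
dbe_distribution <- function(data, bin_width = 0.5) {
  stopifnot(is.data.frame(data))
  if (!"dbe" %in% names(data)) stop("input lacks a 'dbe' column", call. = FALSE)
  if (!bin_width %in% c(0.5, 1.0)) stop("bin_width must be 0.5 or 1.0", call. = FALSE)
  lab <- .label_col(data)
  cls <- if (is.null(lab)) rep("all", nrow(data)) else data[[lab]]
  cls[is.na(cls)] <- "unclassified"
  keep <- is.finite(data$dbe)
  excluded <- sum(!keep)
  bins <- floor(data$dbe[keep] / bin_width) * bin_width
  out <- tibble::tibble(class = cls[keep], bin = bins) |>
    dplyr::count(.data$class, .data$bin, name = "n") |>
    dplyr::arrange(.data$class, .data$bin)
  attr(out, "excluded_count") <- excluded
  out
}

#' Van Krevelen diagram
#'
#' Scatter of H/C against O/C, colored by class.
#'
#' @param data Annotated table (see [vk_points()]).
#' @param point_size Point size.
#' @return A ggplot object.
#' @export
plot_van_krevelen <- function(data, point_size = 2) {
  pts <- vk_points(data)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$oc, y = .data$hc, colour = .data$class)) +
    ggplot2::geom_point(size = point_size, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = .class_palette(pts$class)) +
    ggplot2::labs(x = "O/C atomic ratio", y = "H/C atomic ratio",
                  colour = "class", title = "Van Krevelen diagram") +
    ggplot2::theme_minimal()
}

#' DBE distribution plot
#'
#' Per-class bar chart of compound counts by DBE bin.
#'
#' @param data Annotated table with a `dbe` column.
#' @param bin_width See [dbe_distribution()].
#' @return A ggplot object.
#' @export
plot_dbe_distribution <- function(data, bin_width = 0.5) {
  counts <- dbe_distribution(data, bin_width)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$bin, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col(position = "dodge", width = bin_width * 0.9) +
    ggplot2::scale_fill_manual(values = .class_palette(counts$class)) +
    ggplot2::labs(x = "DBE", y = "number of compounds", fill = "class",
                  title = "DBE distribution") +
    ggplot2::theme_minimal()
}

#' H/C and O/C range bars for a knowledge base
#'
#' One horizontal bar per class and ratio axis, spanning the class window --
#' the at-a-glance view of which classes converge in Van Krevelen space.
#'
#' @param kb A `vk_kb` knowledge base.
#' @return A ggplot object.
#' @export
plot_class_ranges <- function(kb = default_kb()) {
  long <- tidy(kb)
  long <- long[long$axis %in% c("hc", "oc"), ]
  long$axis <- factor(ifelse(long$axis == "hc", "H/C", "O/C"), levels = c("H/C", "O/C"))
  ggplot2::ggplot(long, ggplot2::aes(y = .data$class, colour = .data$axis)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$min, xmax = .data$max),
                            linewidth = 3, position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::scale_colour_manual(values = c("H/C" = "#1f77b4", "O/C" = "#ff7f0e")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "atomic ratio", y = NULL, colour = NULL,
                  title = "Class H/C and O/C windows") +
    ggplot2::theme_minimal()
}

#' DBE boxplot by class
#'
#' Boxplot of DBE per class label; quartiles use linear interpolation
#' (the default type-7 quantile rule).
#'
#' @param data Annotated table with a `dbe` column.
#' @return A ggplot object.
#' @export
plot_dbe_box <- function(data) {
  lab <- .label_col(data)
  cls <- if (is.null(lab)) rep("all", nrow(data)) else data[[lab]]
  cls[is.na(cls)] <- "unclassified"
  df <- tibble::tibble(class = cls, dbe = data$dbe)
  df <- df[is.finite(df$dbe), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$dbe, fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = .class_palette(df$class)) +
    ggplot2::labs(x = NULL, y = "DBE", title = "DBE by class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render a diagnostic figure to file
#'
#' Dispatches on `kind` and writes PNG or SVG according to the file
#' extension. Layout is deterministic given identical inputs.
#'
#' @param data Annotated table (or a `vk_kb` for `kind = "range_bars"`).
#' @param kind One of `"vk"`, `"dbe_hist"`, `"range_bars"`, `"box"`,
#'   `"vk3d"`.
#' @param path Output path ending in `.png` or `.svg`.
#' @param width,height Device size in inches.
#' @param bin_width Bin width for `"dbe_hist"`.
#' @return `path`, invisibly.
#' @export
render <- function(data, kind = c("vk", "dbe_hist", "range_bars", "box", "vk3d"),
                   path, width = 7, height = 5, bin_width = 0.5) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg")) {
    stop("unsupported output extension '.", ext, "'; use .png or .svg", call. = FALSE)
  }
  open_dev <- function() {
    if (ext == "png") {
      grDevices::png(path, width = width, height = height, units = "in", res = 150)
    } else {
      grDevices::svg(path, width = width, height = height)
    }
  }
  if (kind == "vk3d") {
    if (!requireNamespace("lattice", quietly = TRUE)) {
      stop("the 'lattice' package is required for 3D plots", call. = FALSE)
    }
    pts <- vk_points(data)
    pts <- pts[is.finite(pts$dbe), ]
    pal <- .class_palette(pts$class)
    open_dev()
    on.exit(grDevices::dev.off(), add = TRUE)
    print(lattice::cloud(
      dbe ~ oc * hc, data = pts, groups = pts$class,
      par.settings = list(superpose.symbol = list(col = pal, pch = 16)),
      auto.key = list(space = "right"),
      xlab = "O/C", ylab = "H/C", zlab = "DBE"
    ))
    return(invisible(path))
  }
  p <- switch(kind,
    vk = plot_van_krevelen(data),
    dbe_hist = plot_dbe_distribution(data, bin_width = bin_width),
    range_bars = {
      if (!inherits(data, "vk_kb")) stop("kind 'range_bars' needs a vk_kb object", call. = FALSE)
      plot_class_ranges(data)
    },
    box = plot_dbe_box(data)
  )
  open_dev()
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

#' Autoplot method for a knowledge base
#'
#' @param object A `vk_kb`.
#' @param ... Unused.
#' @return A ggplot object (class range bars).
#' @method autoplot vk_kb
#' @export
autoplot.vk_kb <- function(object, ...) plot_class_ranges(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
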