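#' Red/green classification overlay as an RGB array
#'
#' Renders a grayscale channel with object outlines colored red
#' (positive labels) or green (all other labels), mirroring the
#' classification displays of the original workflow.
#'
#' @param channel Numeric background matrix in \[0, 1\].
#' @param labels Integer label matrix.
#' @param positive_labels Integer vector of labels drawn in red.
#' @return An H x W x 3 numeric array in \[0, 1\].
#' @export
classification_overlay <- function(channel, labels, positive_labels) {
  assert_intensity_matrix(channel, "channel")
  rgb <- array(rep(channel, 3), dim = c(nrow(channel), ncol(channel), 3))
  bnd <- boundary_mask(labels)
  pos <- bnd & (labels %in% positive_labels)
  neg <- bnd & !pos
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  r[pos] <- 1; g[pos] <- 0; b[pos] <- 0
  r[neg] <- 0; g[neg] <- 1; b[neg] <- 0
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  rgb
}

# ggplot of a channel with outlines and optional per-object text.
overlay_plot <- function(channel, labels, table, color_by = NULL,
                         label_col = NULL, title = NULL, digits = 3) {
  h <- nrow(channel); w <- ncol(channel)
  bg <- tibble(
    row = rep(seq_len(h) - 1, times = w),
    col = rep(seq_len(w) - 1, each = h),
    intensity = as.numeric(channel)
  )
  bnd <- which(boundary_mask(labels))
  outline <- tibble(
    row = ((bnd - 1L) %% h),
    col = ((bnd - 1L) %/% h),
    label = labels[bnd]
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = bg,
                         ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
  if (nrow(outline)) {
    if (!is.null(color_by)) {
      outline$positive <- outline$label %in% table$label[table[[color_by]]]
      p <- p + ggplot2::geom_point(
        data = outline,
        ggplot2::aes(x = .data$col, y = .data$row, colour = .data$positive),
        size = 0.1) +
        ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "green3"),
                                     guide = "none")
    } else {
      p <- p + ggplot2::geom_point(data = outline,
                                   ggplot2::aes(x = .data$col, y = .data$row),
                                   colour = "yellow", size = 0.1)
    }
  }
  if (!is.null(label_col) && nrow(table)) {
    txt <- table
    txt$text <- if (label_col == "number") {
      seq_len(nrow(txt))  # consecutive object numbering
    } else {
      round(txt[[label_col]], digits)
    }
    p <- p + ggplot2::geom_text(
      data = txt,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row,
                   label = .data$text),
      colour = "cyan", size = 2.4)
  }
  if (!is.null(title)) p <- p + ggplot2::ggtitle(title)
  p
}

#' Write the full overlay set for a pipeline result
#'
#' Writes (a) per-nucleus mean-intensity annotation images for SOX10 and
#' EdU, (b) red/green classification overlays for SOX10 positivity and
#' for EdU positivity within SOX10-positive nuclei, and (c)
#' count-annotated images (consecutive object numbering) for real cells,
#' Schwann cells and proliferating Schwann cells.  Classification
#' overlays are written directly as RGB PNGs; annotation images are
#' rendered with ggplot2.
#'
#' @param result A [run_pipeline()] result.
#' @param image The [cyto_image()] the result was computed from.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
render_overlays <- function(result, image, out_dir) {
  stopifnot(inherits(result, "cyto_result"), inherits(image, "cyto_image"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  obj <- result$objects
  nl <- result$nuclei_labels
  bl <- result$body_labels
  written <- character(0)
  put_png <- function(arr, name) {
    path <- file.path(out_dir, name)
    png::writePNG(arr, path)
    written <<- c(written, path)
  }
  put_plot <- function(p, name) {
    path <- file.path(out_dir, name)
    ggplot2::ggsave(path, p, width = 6, height = 6, dpi = 150)
    written <<- c(written, path)
  }
  pos_sox <- obj$label[obj$is_sox10_pos]
  pos_edu <- obj$label[obj$is_edu_pos]
  put_png(classification_overlay(image$channels$SOX10, nl, pos_sox),
          "sox10_classification.png")
  # EdU classification within the SOX10+ subset only
  nl_sox <- nl
  nl_sox[!nl_sox %in% obj$label[obj$is_sox10_pos]] <- 0L
  put_png(classification_overlay(image$channels$EdU, nl_sox, pos_edu),
          "edu_classification.png")
  put_plot(overlay_plot(image$channels$SOX10, nl, obj,
                        label_col = "mean_SOX10",
                        title = "Mean SOX10 intensity per real nucleus"),
           "sox10_intensity.png")
  put_plot(overlay_plot(image$channels$EdU, nl, obj,
                        label_col = "mean_EdU",
                        title = "Mean EdU intensity per real nucleus"),
           "edu_intensity.png")
  real <- obj[obj$has_intact_body, , drop = FALSE]
  put_plot(overlay_plot(image$channels$VIME, bl, real, label_col = "number",
                        title = sprintf("Real cells: %d", nrow(real))),
           "real_cells.png")
  scs <- real[real$is_sox10_pos, , drop = FALSE]
  put_plot(overlay_plot(image$channels$SOX10, nl, scs, label_col = "number",
                        title = sprintf("SOX10+ real cells: %d", nrow(scs))),
           "sc_count.png")
  prolif <- real[real$is_edu_pos, , drop = FALSE]
  put_plot(overlay_plot(image$channels$EdU, nl, prolif, label_col = "number",
                        title = sprintf("SOX10+/EdU+ real cells: %d", nrow(prolif))),
           "proliferating_count.png")
  invisible(written)
}

#' Plot a pipeline result
#'
#' ggplot overlay of a chosen channel with nucleus outlines colored by a
#' classification flag and optional consecutive numbering.
#'
#' @param object A [run_pipeline()] result.
#' @param image The [cyto_image()] it was computed from.
#' @param channel Channel to use as background (default `"SOX10"`).
#' @param color_by Flag column for the red/green outline coloring
#'   (default `"is_sox10_pos"`).
#' @param number Draw consecutive object numbers (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_result <- function(object, image, channel = "SOX10",
                                 color_by = "is_sox10_pos", number = FALSE,
                                 ...) {
  overlay_plot(image$channels[[channel]], object$nuclei_labels,
               object$objects, color_by = color_by,
               label_col = if (number) "number" else NULL,
               title = sprintf("%s / %s", channel, color_by))
}
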