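# Radar-chart rendering: ggplot2 objects for interactive use and PNG
# export, and a direct SVG serializer whose geometry is byte-deterministic
# and structurally testable (polygon vertices, axis labels, point counts).

profile_palette <- c("#1b6ca8", "#c0392b", "#1e8449", "#8e44ad", "#b7950b",
                     "#117a65", "#a04000", "#2c3e50")

# Normalize the profiles argument: a named list of axis-value vectors.
as_profile_list <- function(profiles) {
  if (inherits(profiles, "vox_axis_values") || (is.numeric(profiles) &&
      !is.list(profiles))) {
    profiles <- list(profile = profiles)
  }
  if (length(profiles) == 0) {
    stop("at least one profile is required", call. = FALSE)
  }
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- paste0("profile_", seq_along(profiles))
  }
  profiles
}

check_overlays <- function(n, max_overlays) {
  if (n > max_overlays) {
    warning("plotting ", n, " profiles exceeds the readability limit of ",
            max_overlays, "; overlapping displays are hard to compare",
            call. = FALSE)
  }
}

#' Radar chart of one or more language profiles
#'
#' Draws the four operant axes at right angles, one closed polygon per
#' profile, optionally the circumscribing property-space circle, and —
#' for a single profile only — its centroid marked "c" (overlapping
#' displays prohibit centroid plotting).
#'
#' @param profiles One [axis_values()] object or a named list of them.
#' @param config A [radar_config()].
#' @param show_centroid Mark the centroid (single profile only).
#' @param show_property_circle Draw the circle of radius `C`; on by
#'   default when `C` is configured.
#' @param max_overlays Soft readability limit; exceeding it warns but
#'   still plots.
#' @return A ggplot object.
#' @examples
#' plot_radar(vox_fixture("fig4"), radar_config(12))
#' @export
plot_radar <- function(profiles, config = radar_config(),
                       show_centroid = TRUE,
                       show_property_circle = !is.null(config$property_radius),
                       max_overlays = 5) {
  profiles <- as_profile_list(profiles)
  check_overlays(length(profiles), max_overlays)
  plps <- lapply(profiles, build_profile, config = config)
  lim <- plot_limit(plps, config)
  n <- config$n_axes
  axes <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- axis_direction(i, n)
    data.frame(label = config$axis_order[i], xend = lim * d[1],
               yend = lim * d[2])
  }))
  poly <- do.call(rbind, lapply(names(plps), function(nm) {
    v <- plps[[nm]]$vertices
    data.frame(profile = nm, x = v[, "x"], y = v[, "y"])
  }))
  poly$profile <- factor(poly$profile, levels = names(plps))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = axes, colour = "grey55",
                          ggplot2::aes(x = 0, y = 0, xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::geom_text(data = axes, size = 3.4, colour = "grey25",
                       ggplot2::aes(x = 1.12 * .data$xend,
                                    y = 1.12 * .data$yend,
                                    label = .data$label)) +
    ggplot2::geom_polygon(data = poly, alpha = 0.15, linewidth = 0.7,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$profile,
                                       fill = .data$profile)) +
    ggplot2::scale_colour_manual(values = rep_len(profile_palette,
                                                  length(plps))) +
    ggplot2::scale_fill_manual(values = rep_len(profile_palette,
                                                length(plps))) +
    ggplot2::coord_fixed(xlim = c(-1.25, 1.25) * lim,
                         ylim = c(-1.25, 1.25) * lim) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = if (length(plps) > 1) "right" else "none")
  if (show_property_circle && !is.null(config$property_radius)) {
    t <- seq(0, 2 * pi, length.out = 181)
    circ <- data.frame(x = config$property_radius * cos(t),
                       y = config$property_radius * sin(t))
    p <- p + ggplot2::geom_path(data = circ, colour = "grey40",
                                linetype = "dashed",
                                ggplot2::aes(x = .data$x, y = .data$y))
  }
  if (show_centroid && length(plps) == 1) {
    ctr <- plp_centroid(plps[[1]])
    if (!anyNA(ctr)) {
      cdat <- data.frame(x = ctr[["x"]], y = ctr[["y"]])
      p <- p +
        ggplot2::geom_point(data = cdat, size = 1.6,
                            ggplot2::aes(x = .data$x, y = .data$y)) +
        ggplot2::geom_text(data = cdat, label = "c", fontface = "italic",
                           nudge_x = 0.05 * lim, nudge_y = 0.05 * lim,
                           ggplot2::aes(x = .data$x, y = .data$y))
    }
  }
  p
}

plot_limit <- function(plps, config) {
  vmax <- max(c(0, vapply(plps, function(p) max(p$values), numeric(1))))
  lim <- if (!is.null(config$property_radius)) config$property_radius
         else vmax
  if (lim <= 0) lim <- 1
  lim
}

#' First-moment-of-area time series plot
#'
#' Line graph of `Q` over age for a longitudinal series, for examining
#' level, trend, and variability. Timepoints at or before
#' `baseline_until` are joined by a dashed segment to mark a presumed
#' pre-assessment trajectory.
#'
#' @param series A `vox_series` from [longitudinal_series()].
#' @param baseline_until Optional age (years) ending the dashed baseline
#'   segment.
#' @return A ggplot object.
#' @export
plot_q_timeseries <- function(series, baseline_until = NULL) {
  stopifnot(inherits(series, "vox_series"))
  d <- data.frame(age = series$ages, Q = series$table$Q)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$Q))
  if (!is.null(baseline_until) && any(d$age <= baseline_until)) {
    base <- d[d$age <= baseline_until, ]
    p <- p + ggplot2::geom_line(data = base, linetype = "dashed")
    rest <- d[d$age >= max(base$age), ]
    if (nrow(rest) > 1) p <- p + ggplot2::geom_line(data = rest)
  } else if (nrow(d) > 1) {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Age (years)", y = "First moment of area (Q)") +
    ggplot2::theme_classic()
}

# ---- deterministic SVG serialization ----------------------------------

fmt_num <- function(x) sprintf("%.4f", x)

svg_header <- function(width, height) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>',
            width, height))
}

#' Render a radar chart to SVG or PNG
#'
#' The SVG path serializes the chart geometry directly (axes, polygons,
#' property circle, centroid, text labels), so output bytes are fully
#' determined by the input and the polygon coordinates in the document
#' are the profile vertices under the affine plot transform. PNG output
#' rasterizes the [plot_radar()] ggplot.
#'
#' @inheritParams plot_radar
#' @param file Output path ending in `.svg` or `.png`.
#' @param width,height Canvas size in pixels.
#' @return `file`, invisibly.
#' @examples
#' \donttest{
#' render_radar(vox_fixture("fig4"), radar_config(12),
#'              file.path(tempdir(), "fig4.svg"))
#' }
#' @export
render_radar <- function(profiles, config = radar_config(), file,
                         show_centroid = TRUE,
                         show_property_circle = !is.null(config$property_radius),
                         max_overlays = 5, width = 480, height = 480) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    p <- plot_radar(profiles, config, show_centroid = show_centroid,
                    show_property_circle = show_property_circle,
                    max_overlays = max_overlays)
    grDevices::png(file, width = width, height = height, res = 96)
    on.exit(grDevices::dev.off())
    print(p)
    return(invisible(file))
  }
  profiles <- as_profile_list(profiles)
  check_overlays(length(profiles), max_overlays)
  plps <- lapply(profiles, build_profile, config = config)
  lim <- plot_limit(plps, config)
  margin <- 40
  span <- min(width, height) - 2 * margin
  s <- span / (2 * lim)                      # world units -> pixels
  cx0 <- width / 2
  cy0 <- height / 2
  tx <- function(x) cx0 + s * x
  ty <- function(y) cy0 - s * y
  out <- svg_header(width, height)
  if (show_property_circle && !is.null(config$property_radius)) {
    out <- c(out, sprintf(
      '<circle class="property-space" cx="%s" cy="%s" r="%s" fill="none" stroke="grey" stroke-dasharray="4 3"/>',
      fmt_num(cx0), fmt_num(cy0), fmt_num(s * config$property_radius)))
  }
  n <- config$n_axes
  for (i in seq_len(n)) {
    d <- axis_direction(i, n)
    out <- c(out, sprintf(
      '<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888888"/>',
      fmt_num(cx0), fmt_num(cy0), fmt_num(tx(lim * d[1])),
      fmt_num(ty(lim * d[2]))),
      sprintf('<text class="axis-label" x="%s" y="%s" text-anchor="middle" font-size="12">%s</text>',
              fmt_num(tx(1.12 * lim * d[1])),
              fmt_num(ty(1.12 * lim * d[2]) + 4), config$axis_order[i]))
  }
  for (j in seq_along(plps)) {
    v <- plps[[j]]$vertices
    pts <- paste(fmt_num(tx(v[, "x"])), fmt_num(ty(v[, "y"])),
                 sep = ",", collapse = " ")
    col <- rep_len(profile_palette, length(plps))[j]
    out <- c(out, sprintf(
      '<polygon class="plp" data-label="%s" points="%s" fill="%s" fill-opacity="0.15" stroke="%s" stroke-width="1.5"/>',
      names(plps)[j], pts, col, col))
  }
  if (show_centroid && length(plps) == 1) {
    ctr <- plp_centroid(plps[[1]])
    if (!anyNA(ctr)) {
      out <- c(out, sprintf(
        '<circle class="centroid" cx="%s" cy="%s" r="3" fill="black"/>',
        fmt_num(tx(ctr[["x"]])), fmt_num(ty(ctr[["y"]]))),
        sprintf('<text class="centroid-label" x="%s" y="%s" font-style="italic" font-size="12">c</text>',
                fmt_num(tx(ctr[["x"]]) + 6), fmt_num(ty(ctr[["y"]]) - 6)))
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, file)
  invisible(file)
}

#' Render the Q time series to SVG or PNG
#'
#' The SVG path serializes one `q-point` circle per timepoint plus the
#' connecting polyline (dashed over the baseline segment), giving a
#' structurally testable, deterministic document. PNG output rasterizes
#' [plot_q_timeseries()].
#'
#' @inheritParams plot_q_timeseries
#' @param file Output path ending in `.svg` or `.png`.
#' @param width,height Canvas size in pixels.
#' @return `file`, invisibly.
#' @export
render_q_timeseries <- function(series, file, baseline_until = NULL,
                                width = 560, height = 360) {
  stopifnot(inherits(series, "vox_series"))
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    grDevices::png(file, width = width, height = height, res = 96)
    on.exit(grDevices::dev.off())
    print(plot_q_timeseries(series, baseline_until))
    return(invisible(file))
  }
  age <- series$ages
  q <- series$table$Q
  margin <- 50
  xr <- range(age)
  yr <- range(c(0, q))
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(0, 1)
  tx <- function(x) margin + (x - xr[1]) / diff(xr) * (width - 2 * margin)
  ty <- function(y) height - margin - (y - yr[1]) / diff(yr) *
    (height - 2 * margin)
  out <- svg_header(width, height)
  out <- c(out, sprintf(
    '<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
    fmt_num(margin), fmt_num(height - margin), fmt_num(width - margin),
    fmt_num(height - margin)), sprintf(
    '<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
    fmt_num(margin), fmt_num(margin), fmt_num(margin),
    fmt_num(height - margin)),
    sprintf('<text class="axis-title" x="%s" y="%s" text-anchor="middle" font-size="12">Age (years)</text>',
            fmt_num(width / 2), fmt_num(height - 12)),
    sprintf('<text class="axis-title" x="14" y="%s" text-anchor="middle" font-size="12" transform="rotate(-90 14 %s)">First moment of area (Q)</text>',
            fmt_num(height / 2), fmt_num(height / 2)))
  if (length(age) > 1) {
    seg_line <- function(idx, dashed) {
      if (length(idx) < 2) return(character())
      pts <- paste(fmt_num(tx(age[idx])), fmt_num(ty(q[idx])),
                   sep = ",", collapse = " ")
      sprintf('<polyline class="q-line%s" points="%s" fill="none" stroke="#1b6ca8" stroke-width="1.5"%s/>',
              if (dashed) " baseline" else "", pts,
              if (dashed) ' stroke-dasharray="5 4"' else "")
    }
    if (!is.null(baseline_until) && any(age <= baseline_until)) {
      base_idx <- which(age <= baseline_until)
      rest_idx <- max(base_idx):length(age)
      out <- c(out, seg_line(base_idx, TRUE), seg_line(rest_idx, FALSE))
    } else {
      out <- c(out, seg_line(seq_along(age), FALSE))
    }
  }
  out <- c(out, sprintf(
    '<circle class="q-point" cx="%s" cy="%s" r="3.5" fill="#1b6ca8"/>',
    fmt_num(tx(age)), fmt_num(ty(q))))
  out <- c(out, "</svg>")
  writeLines(out, file)
  invisible(file)
}
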