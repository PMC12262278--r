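# Module visualization: a 45-degree rotated upper-triangle contact heatmap
# over the module span, significant contacts marked as open diamonds, and an
# arc plot of the module's edges underneath, with arcs incident to a
# highlighted bin drawn in a distinct color. The layout is deterministic.

#' Plot a chromatin interaction module
#'
#' Writes a triangle heatmap + arc plot image for one module. Counts are
#' colored on a log1p scale with a perceptually uniform palette. The device
#' is chosen from the file extension (.pdf, .png or .svg).
#'
#' @param records contact records covering the module span (plus flank).
#' @param module one-row slice of a `chromatin_modules` table.
#' @param net the interaction network the module was detected in.
#' @param out output image path.
#' @param resolution bin width in bp; defaults to the network's attribute.
#' @param significant optional significant-contact table to mark with
#'   diamonds.
#' @param highlight optional bin start whose incident arcs are emphasized.
#' @param flank flank around the span, in bins (default 5).
#' @return the output path, invisibly, with attributes `n_arcs` and
#'   `n_highlighted`.
#' @export
plot_module <- function(records, module, net, out, resolution = NULL,
                        significant = NULL, highlight = NULL, flank = 5L) {
  resolution <- resolution %||% igraph::graph_attr(net, "resolution")
  if (is.null(resolution)) stop("resolution is required")
  module <- as.data.frame(module)
  stopifnot(nrow(module) == 1L)
  if (min(records$start1) > module$span_start ||
      max(records$start2) + resolution < module$span_end)
    stop("records do not cover the module span")
  x0 <- module$span_start - flank * resolution
  x1 <- module$span_end + flank * resolution
  rec <- records[records$start1 >= x0 & records$start2 + resolution <= x1, ,
                 drop = FALSE]

  # module edges from the induced subgraph
  nodes <- as.character(
    as.numeric(igraph::V(net)$name)[
      as.numeric(igraph::V(net)$name) >= module$span_start &
        as.numeric(igraph::V(net)$name) < module$span_end])
  sub <- igraph::induced_subgraph(net, intersect(nodes,
                                                 igraph::V(net)$name))
  edges <- igraph::ends(sub, igraph::E(sub), names = TRUE)
  n_arcs <- nrow(edges)
  hi <- if (is.null(highlight)) rep(FALSE, n_arcs) else
    (as.numeric(edges[, 1L]) == highlight |
       as.numeric(edges[, 2L]) == highlight)

  ext <- tolower(tools::file_ext(out))
  switch(ext,
         pdf = grDevices::pdf(out, width = 9, height = 7),
         png = grDevices::png(out, width = 900, height = 700),
         svg = grDevices::svg(out, width = 9, height = 7),
         stop("unsupported image format: .", ext))
  on.exit(grDevices::dev.off(), add = TRUE)

  span_w <- x1 - x0
  ymax <- span_w / 2
  ymin <- -0.6 * ymax
  graphics::plot.new()
  graphics::plot.window(xlim = c(x0, x1), ylim = c(ymin, ymax), asp = NA)
  graphics::title(main = sprintf("%s  %s:%s-%s", module$module_id,
                                 module$chrom,
                                 format(module$span_start, big.mark = ","),
                                 format(module$span_end, big.mark = ",")),
                  xlab = sprintf("%s position (bp)", module$chrom))
  graphics::axis(1)

  # rotated heatmap: pixel (s1, s2) -> diamond centered at
  # ((s1+s2)/2 + res/2, (s2-s1)/2)
  if (nrow(rec) > 0L) {
    pal <- grDevices::hcl.colors(101, "viridis")
    lv <- log1p(rec$count)
    ci <- 1 + round(100 * lv / max(lv))
    h <- resolution / 2
    for (r in seq_len(nrow(rec))) {
      cx <- (rec$start1[r] + rec$start2[r]) / 2 + h
      cy <- (rec$start2[r] - rec$start1[r]) / 2
      graphics::polygon(cx + c(-h, 0, h, 0), cy + c(0, h, 0, -h),
                        col = pal[ci[r]], border = NA)
    }
  }

  # significant contacts as open diamonds
  if (!is.null(significant) && nrow(significant) > 0L) {
    ss <- significant[significant$start1 >= x0 &
                        significant$start2 + resolution <= x1, , drop = FALSE]
    graphics::points((ss$start1 + ss$start2) / 2 + resolution / 2,
                     (ss$start2 - ss$start1) / 2,
                     pch = 5, cex = 0.5, col = "black")
  }

  # arcs below the baseline; highlighted arcs on top in a distinct color
  draw_arc <- function(a, b, col, lwd) {
    mid <- (a + b) / 2
    rad <- abs(b - a) / 2
    t <- seq(0, pi, length.out = 60)
    graphics::lines(mid + rad * cos(t), -0.5 * rad * sin(t) * (abs(ymin) /
                                                                ymax) * 2,
                    col = col, lwd = lwd)
  }
  if (n_arcs > 0L) {
    ord <- order(hi)  # plain arcs first
    for (e in ord) {
      a <- as.numeric(edges[e, 1L]) + resolution / 2
      b <- as.numeric(edges[e, 2L]) + resolution / 2
      draw_arc(a, b, col = if (hi[e]) "goldenrod2" else "grey60",
               lwd = if (hi[e]) 1.6 else 0.6)
    }
  }
  graphics::abline(h = 0, col = "grey30")

  structure(invisible(out), n_arcs = n_arcs, n_highlighted = sum(hi))
}
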