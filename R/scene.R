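# Minimal retained-mode renderer shared by the GAP and LAP plots.
#
# Figures are first assembled as a "scene" (an ordered list of rect /
# line / text primitives in a top-left-origin coordinate system), then
# emitted either as hand-written SVG -- which makes SVG output
# byte-for-byte deterministic, with no timestamps or device state -- or
# drawn onto a pdf()/png() graphics device.  PNG output maps one scene
# unit to one pixel, so canvas dimensions are exact pixel dimensions.

new_scene <- function(width, height, background = "#FFFFFF") {
  sc <- list(width = width, height = height, elements = list())
  scene_rect(sc, 0, 0, width, height, background, class = "canvas-bg")
}

scene_add <- function(sc, el) {
  sc$elements[[length(sc$elements) + 1L]] <- el
  sc
}

scene_rect <- function(sc, x, y, w, h, fill, stroke = NA, class = NULL) {
  scene_add(sc, list(type = "rect", x = x, y = y, w = w, h = h,
                     fill = fill, stroke = stroke, class = class))
}

scene_line <- function(sc, x1, y1, x2, y2, stroke, width = 1, class = NULL) {
  scene_add(sc, list(type = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                     stroke = stroke, lwd = width, class = class))
}

scene_text <- function(sc, x, y, label, size = 12, anchor = "start",
                       rotate = 0, fill = "#000000", class = NULL) {
  scene_add(sc, list(type = "text", x = x, y = y, label = label,
                     size = size, anchor = anchor, rotate = rotate,
                     fill = fill, class = class))
}

emit_scene <- function(sc, out_path, format) {
  switch(format,
    svg = write_scene_svg(sc, out_path),
    pdf = {
      grDevices::pdf(out_path, width = sc$width / 96, height = sc$height / 96,
                     useDingbats = FALSE)
      on.exit(grDevices::dev.off(), add = TRUE)
      draw_scene_device(sc)
    },
    png = {
      grDevices::png(out_path, width = sc$width, height = sc$height,
                     res = 96, type = "cairo")
      on.exit(grDevices::dev.off(), add = TRUE)
      draw_scene_device(sc)
    },
    stop_usage(sprintf("unsupported output format '%s'", format))
  )
  invisible(out_path)
}

fmt_num <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_attr <- function(name, value) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) return("")
  sprintf(' %s="%s"', name, value)
}

write_scene_svg <- function(sc, path) {
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" ',
      'viewBox="0 0 %s %s" font-family="Helvetica, Arial, sans-serif">'),
      fmt_num(sc$width), fmt_num(sc$height),
      fmt_num(sc$width), fmt_num(sc$height))
  )
  body <- vapply(sc$elements, function(el) {
    cls <- svg_attr("class", el$class)
    switch(el$type,
      rect = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s%s/>',
                     fmt_num(el$x), fmt_num(el$y), fmt_num(el$w),
                     fmt_num(el$h), el$fill,
                     svg_attr("stroke", el$stroke), cls),
      line = sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s/>',
                     fmt_num(el$x1), fmt_num(el$y1), fmt_num(el$x2),
                     fmt_num(el$y2), el$stroke, fmt_num(el$lwd), cls),
      text = {
        anchor <- switch(el$anchor, start = NULL, middle = "middle",
                         end = "end")
        transform <- if (el$rotate != 0) {
          sprintf("rotate(%s %s %s)", fmt_num(-el$rotate),
                  fmt_num(el$x), fmt_num(el$y))
        }
        sprintf('<text x="%s" y="%s" font-size="%s" fill="%s"%s%s%s>%s</text>',
                fmt_num(el$x), fmt_num(el$y), fmt_num(el$size), el$fill,
                svg_attr("text-anchor", anchor),
                svg_attr("transform", transform), cls,
                xml_escape(el$label))
      })
  }, character(1L))
  writeLines(c(out, body, "</svg>"), path)
  invisible(path)
}

# Base-graphics backend.  One scene unit maps to 1/96 inch; font sizes are
# interpreted as CSS-like pixels (1 px = 0.75 pt).
draw_scene_device <- function(sc) {
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, sc$width), ylim = c(sc$height, 0))
  for (el in sc$elements) {
    switch(el$type,
      rect = graphics::rect(el$x, el$y + el$h, el$x + el$w, el$y,
                            col = el$fill,
                            border = if (is.na(el$stroke)) NA else el$stroke),
      line = graphics::segments(el$x1, el$y1, el$x2, el$y2,
                                col = el$stroke, lwd = el$lwd),
      text = {
        adj <- switch(el$anchor, start = 0, middle = 0.5, end = 1)
        graphics::text(el$x, el$y, labels = el$label,
                       adj = c(adj, 0.35), srt = el$rotate, col = el$fill,
                       cex = el$size * 0.75 / 12)
      })
  }
  invisible(NULL)
}
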