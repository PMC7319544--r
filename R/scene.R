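# Minimal retained-mode drawing layer. Figures are assembled as a list of
# primitives ("scene") and then painted either to a hand-written SVG
# (byte-deterministic, structurally inspectable: every primitive carries a
# class attribute and optional data-* attributes) or to a PNG device.
# Scene coordinates are pixels at 96 dpi with the y axis pointing down.

new_scene <- function(width, height) {
  env <- new.env(parent = emptyenv())
  env$width <- width
  env$height <- height
  env$elements <- list()
  class(env) <- "snv_scene"
  env
}

scene_add <- function(scene, el) {
  scene$elements[[length(scene$elements) + 1L]] <- el
  invisible(scene)
}

sc_rect <- function(scene, x, y, w, h, fill, class = NULL, opacity = NULL,
                    data = NULL) {
  scene_add(scene, list(kind = "rect", x = x, y = y, w = w, h = h,
                        fill = fill, class = class, opacity = opacity,
                        data = data))
}

sc_line <- function(scene, x1, y1, x2, y2, stroke, width = 1,
                    class = NULL, opacity = NULL, data = NULL) {
  scene_add(scene, list(kind = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                        stroke = stroke, width = width, class = class,
                        opacity = opacity, data = data))
}

sc_polyline <- function(scene, xs, ys, stroke, width = 1.5, class = NULL,
                        opacity = NULL) {
  scene_add(scene, list(kind = "polyline", xs = xs, ys = ys,
                        stroke = stroke, width = width, class = class,
                        opacity = opacity))
}

sc_circle <- function(scene, cx, cy, r, stroke = "#000000", fill = "none",
                      width = 1, class = NULL) {
  scene_add(scene, list(kind = "circle", cx = cx, cy = cy, r = r,
                        stroke = stroke, fill = fill, width = width,
                        class = class))
}

# Arc path between two baseline points (half ellipse) or circle chord.
sc_path <- function(scene, d, stroke, width = 1, class = NULL,
                    opacity = NULL, data = NULL, fill = "none") {
  scene_add(scene, list(kind = "path", d = d, stroke = stroke,
                        width = width, class = class, opacity = opacity,
                        data = data, fill = fill))
}

sc_text <- function(scene, x, y, label, size = 11, anchor = "middle",
                    fill = "#000000", class = NULL) {
  scene_add(scene, list(kind = "text", x = x, y = y, label = label,
                        size = size, anchor = anchor, fill = fill,
                        class = class))
}

fmt_num <- function(v) {
  out <- sprintf("%.3f", v)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_attrs <- function(el) {
  a <- character(0L)
  if (!is.null(el$class)) a <- c(a, sprintf('class="%s"', el$class))
  if (!is.null(el$opacity)) {
    a <- c(a, sprintf('opacity="%s"', fmt_num(el$opacity)))
  }
  if (!is.null(el$data)) {
    for (k in names(el$data)) {
      a <- c(a, sprintf('data-%s="%s"', k, el$data[[k]]))
    }
  }
  if (length(a) > 0L) paste0(" ", paste(a, collapse = " ")) else ""
}

svg_element <- function(el) {
  extra <- svg_attrs(el)
  switch(el$kind,
    rect = sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
      fmt_num(el$x), fmt_num(el$y), fmt_num(el$w), fmt_num(el$h),
      el$fill, extra),
    line = sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s/>',
      fmt_num(el$x1), fmt_num(el$y1), fmt_num(el$x2), fmt_num(el$y2),
      el$stroke, fmt_num(el$width), extra),
    polyline = sprintf(
      '<polyline points="%s" fill="none" stroke="%s" stroke-width="%s"%s/>',
      paste(sprintf("%s,%s", vapply(el$xs, fmt_num, ""),
                    vapply(el$ys, fmt_num, "")), collapse = " "),
      el$stroke, fmt_num(el$width), extra),
    circle = sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="%s"%s/>',
      fmt_num(el$cx), fmt_num(el$cy), fmt_num(el$r), el$fill, el$stroke,
      fmt_num(el$width), extra),
    path = sprintf(
      '<path d="%s" fill="%s" stroke="%s" stroke-width="%s"%s/>',
      el$d, el$fill, el$stroke, fmt_num(el$width), extra),
    text = sprintf(
      '<text x="%s" y="%s" font-size="%s" text-anchor="%s" fill="%s" font-family="Helvetica, Arial, sans-serif"%s>%s</text>',
      fmt_num(el$x), fmt_num(el$y), fmt_num(el$size), el$anchor, el$fill,
      extra, xml_escape(el$label)),
    stop("unknown primitive kind ", el$kind)
  )
}

scene_to_svg <- function(scene, path) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            scene$width, scene$height, scene$width, scene$height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
            scene$width, scene$height),
    vapply(scene$elements, svg_element, character(1L)),
    "</svg>"
  )
  # write with fixed LF endings for byte determinism across platforms
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

scene_to_png <- function(scene, path, dpi = 300) {
  scale <- dpi / 96
  grDevices::png(path, width = round(scene$width * scale),
                 height = round(scene$height * scale), units = "px")
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, scene$width),
                        ylim = c(scene$height, 0), asp = 1)
  graphics::rect(0, scene$height, scene$width, 0, col = "#ffffff",
                 border = NA)
  for (el in scene$elements) {
    op_alpha <- if (is.null(el$opacity)) 1 else el$opacity
    switch(el$kind,
      rect = graphics::rect(el$x, el$y + el$h, el$x + el$w, el$y,
                            col = alpha_col(el$fill, op_alpha), border = NA),
      line = graphics::segments(el$x1, el$y1, el$x2, el$y2,
                                col = alpha_col(el$stroke, op_alpha),
                                lwd = el$width * scale),
      polyline = graphics::lines(el$xs, el$ys,
                                 col = alpha_col(el$stroke, op_alpha),
                                 lwd = el$width * scale),
      circle = {
        th <- seq(0, 2 * pi, length.out = 181L)
        graphics::lines(el$cx + el$r * cos(th), el$cy + el$r * sin(th),
                        col = el$stroke, lwd = el$width * scale)
      },
      path = draw_path_png(el, op_alpha, scale),
      text = graphics::text(el$x, el$y, labels = el$label,
                            col = el$fill, cex = el$size / 11 * scale,
                            adj = switch(el$anchor, start = 0,
                                         middle = 0.5, end = 1))
    )
  }
  invisible(path)
}

alpha_col <- function(col, alpha) {
  if (is.null(alpha) || alpha >= 1) return(col)
  v <- grDevices::col2rgb(col) / 255
  grDevices::rgb(v[1L], v[2L], v[3L], alpha = max(0, alpha))
}

# PNG fallback renderer for the two path shapes the figures use:
# elliptical arcs ("M x1 y1 A rx ry 0 0 s x2 y2") and quadratic chords
# ("M x1 y1 Q cx cy x2 y2").
draw_path_png <- function(el, alpha, scale) {
  toks <- strsplit(trimws(el$d), "[ ,]+")[[1L]]
  col <- alpha_col(el$stroke, alpha)
  if (toks[[4L]] == "A") {
    x1 <- as.numeric(toks[[2L]]); y1 <- as.numeric(toks[[3L]])
    rx <- as.numeric(toks[[5L]]); ry <- as.numeric(toks[[6L]])
    sweep <- as.numeric(toks[[9L]])
    x2 <- as.numeric(toks[[10L]]); y2 <- as.numeric(toks[[11L]])
    cx <- (x1 + x2) / 2
    th <- seq(pi, 0, length.out = 91L)
    ys <- if (sweep == 1) y1 - ry * sin(th) else y1 + ry * sin(th)
    graphics::lines(cx - rx * cos(th), ys, col = col, lwd = el$width * scale)
  } else if (toks[[4L]] == "Q") {
    x1 <- as.numeric(toks[[2L]]); y1 <- as.numeric(toks[[3L]])
    cx <- as.numeric(toks[[5L]]); cy <- as.numeric(toks[[6L]])
    x2 <- as.numeric(toks[[7L]]); y2 <- as.numeric(toks[[8L]])
    t <- seq(0, 1, length.out = 61L)
    graphics::lines((1 - t)^2 * x1 + 2 * t * (1 - t) * cx + t^2 * x2,
                    (1 - t)^2 * y1 + 2 * t * (1 - t) * cy + t^2 * y2,
                    col = col, lwd = el$width * scale)
  }
}

write_scene <- function(scene, out, spec) {
  files <- character(0L)
  if ("svg" %in% spec$formats) {
    f <- paste0(out, ".svg")
    scene_to_svg(scene, f)
    files <- c(files, f)
  }
  if ("png" %in% spec$formats) {
    f <- paste0(out, ".png")
    scene_to_png(scene, f, dpi = spec$dpi)
    files <- c(files, f)
  }
  files
}
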