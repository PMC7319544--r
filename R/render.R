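#' Rendering options for all figure types
#'
#' @param formats Subset of `c("png", "svg")`.
#' @param dpi Raster resolution for PNG output (>= 72; default 300).
#' @param tick_interval Axis tick spacing in nt (default 10).
#' @param mutation_marks 1-based positions highlighted with red guide
#'   lines / boundary marks.
#' @param threshold Entries with `|value|` below this are not drawn as
#'   chords/arcs (legibility; default 1e-3).
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(formats = c("png", "svg"), dpi = 300L,
                        tick_interval = 10L, mutation_marks = integer(0L),
                        threshold = 1e-3) {
  formats <- match.arg(formats, c("png", "svg"), several.ok = TRUE)
  if (dpi < 72) snv_stop("dpi must be at least 72")
  if (tick_interval < 1) snv_stop("tick_interval must be >= 1")
  structure(
    list(formats = formats, dpi = as.integer(dpi),
         tick_interval = as.integer(tick_interval),
         mutation_marks = as.integer(mutation_marks),
         threshold = threshold),
    class = "render_spec"
  )
}

# 0 -> white, 1 -> black
grey_fill <- function(v) {
  g <- pmin(pmax(1 - v, 0), 1)
  grDevices::rgb(g, g, g)
}

# symmetric diverging map: blue (negative) / white (0) / red (positive)
diverging_fill <- function(v, limit) {
  t <- pmin(abs(v) / limit, 1)
  ifelse(v < 0,
         grDevices::rgb(1 - t, 1 - t, 1),
         grDevices::rgb(1, 1 - t, 1 - t))
}

# color limit for differential panels: +-max|delta| floored at +-0.1 so
# near-null results are not amplified into saturated colors
diff_limit <- function(delta) max(max(abs(delta)), 0.1)

tick_positions <- function(n, interval) {
  if (n < interval) return(integer(0L))
  seq.int(interval, n, by = interval)
}

RED <- "#cc0000"
BLUE <- "#2166ac"

as_matrix_values <- function(matrix) {
  if (inherits(matrix, "bp_matrix")) matrix$P else as.matrix(matrix)
}

heatmap_scene <- function(M, spec, differential) {
  n <- nrow(M)
  margin <- 46
  plot_px <- 520
  cs <- plot_px / n
  W <- margin + plot_px + 14L
  sc <- new_scene(round(W), round(W))
  px <- function(j) margin + (j - 1) * cs  # column j -> x
  py <- function(i) margin + (i - 1) * cs  # row i -> y
  limit <- if (differential) diff_limit(M) else 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- M[i, j]
      if (v == 0) next
      fill <- if (differential) diverging_fill(v, limit) else grey_fill(v)
      sc_rect(sc, px(j), py(i), cs, cs, fill = fill, class = "cell",
              data = list(i = i, j = j))
    }
  }
  frame_col <- "#333333"
  sc_line(sc, margin, margin, margin + plot_px, margin, frame_col,
          class = "frame")
  sc_line(sc, margin, margin + plot_px, margin + plot_px, margin + plot_px,
          frame_col, class = "frame")
  sc_line(sc, margin, margin, margin, margin + plot_px, frame_col,
          class = "frame")
  sc_line(sc, margin + plot_px, margin, margin + plot_px, margin + plot_px,
          frame_col, class = "frame")
  for (t in tick_positions(n, spec$tick_interval)) {
    xc <- px(t) + cs / 2
    sc_line(sc, xc, margin + plot_px, xc, margin + plot_px + 5, frame_col,
            class = "tick")
    sc_text(sc, xc, margin + plot_px + 16, as.character(t), size = 9,
            class = "tick-label")
    yc <- py(t) + cs / 2
    sc_line(sc, margin - 5, yc, margin, yc, frame_col, class = "tick")
    sc_text(sc, margin - 8, yc + 3, as.character(t), size = 9,
            anchor = "end", class = "tick-label")
  }
  for (p in spec$mutation_marks) {
    xc <- px(p) + cs / 2
    yc <- py(p) + cs / 2
    sc_line(sc, xc, margin, xc, margin + plot_px, RED, width = 1,
            class = "mutation-guide", opacity = 0.8,
            data = list(position = p))
    sc_line(sc, margin, yc, margin + plot_px, yc, RED, width = 1,
            class = "mutation-guide", opacity = 0.8,
            data = list(position = p))
  }
  sc
}

#' Render a probability heatmap
#'
#' Grayscale heatmap of a base-pair probability matrix (0 maps to white,
#' 1 to black), axes ticked every `tick_interval` nt with 1-based labels,
#' and full-length red guide lines at each mutation position on both
#' axes. Pass the output of [combined_triangle_matrix()] to get the
#' wildtype ensemble in the upper and the mutant in the lower triangle.
#'
#' @param matrix `bp_matrix` or plain matrix with values in `[0, 1]`.
#' @param spec A `render_spec`.
#' @param out Output path prefix (extensions are appended per format).
#' @return Character vector of files written.
#' @export
render_heatmap <- function(matrix, spec = render_spec(), out) {
  M <- as_matrix_values(matrix)
  if (min(M) < 0 || max(M) > 1) {
    snv_stop("probability heatmap values must lie in [0, 1]")
  }
  write_scene(heatmap_scene(M, spec, differential = FALSE), out, spec)
}

#' Render a differential heatmap
#'
#' Diverging colormap for a difference matrix: blue for negative entries
#' (pairs weakened by the mutation), red for positive (strengthened),
#' white at zero. The color scale is symmetric about 0 with limit
#' `max(|delta|)`, floored at 0.1.
#'
#' @param delta Difference matrix in `[-1, 1]` (from [diff_matrix()]).
#' @inheritParams render_heatmap
#' @return Character vector of files written.
#' @export
render_diff_heatmap <- function(delta, spec = render_spec(), out) {
  M <- as_matrix_values(delta)
  if (min(M) < -1 || max(M) > 1) {
    snv_stop("difference values must lie in [-1, 1]")
  }
  write_scene(heatmap_scene(M, spec, differential = TRUE), out, spec)
}

#' Render a circular (chord) plot
#'
#' The sequence is laid out clockwise on a circle starting with the 5'
#' end at the bottom slightly left of center. Every matrix entry above
#' the plot threshold becomes one chord whose opacity is proportional to
#' `|value|`; in differential mode (any negative entry) chords are blue
#' for weakened and red for strengthened pairs. The mutation positions
#' are marked in red on the boundary and the mutation code is annotated.
#'
#' @param matrix `bp_matrix` or plain matrix (probabilities or
#'   differences).
#' @param mutation_code Optional code string annotated next to the
#'   boundary mark.
#' @inheritParams render_heatmap
#' @return Character vector of files written.
#' @export
render_circular <- function(matrix, spec = render_spec(), out,
                            mutation_code = NULL) {
  M <- as_matrix_values(matrix)
  n <- nrow(M)
  differential <- min(M) < 0
  size <- 560
  c0 <- size / 2
  r <- size / 2 - 60
  sc <- new_scene(size, size)
  # position i sits at angle 100 deg + clockwise progression (y-down
  # coordinates), i.e. 5' bottom slight-left, then clockwise
  ang <- function(i) (100 + 360 * (i - 0.5) / n) * pi / 180
  pxy <- function(i, rad) c(c0 + rad * cos(ang(i)), c0 + rad * sin(ang(i)))
  sc_circle(sc, c0, c0, r, stroke = "#333333", width = 1.2,
            class = "backbone")
  limit <- if (differential) diff_limit(M) else 1
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- M[i, j]
      if (abs(v) < spec$threshold) next
      a <- pxy(i, r); b <- pxy(j, r)
      col <- if (!differential) "#000000" else if (v < 0) BLUE else RED
      d <- sprintf("M %s %s Q %s %s %s %s", fmt_num(a[1L]), fmt_num(a[2L]),
                   fmt_num(c0), fmt_num(c0), fmt_num(b[1L]), fmt_num(b[2L]))
      sc_path(sc, d, stroke = col, width = 1.4, class = "chord",
              opacity = min(1, abs(v) / limit),
              data = list(i = i, j = j))
    }
  }
  for (t in tick_positions(n, spec$tick_interval)) {
    a <- pxy(t, r); b <- pxy(t, r + 7)
    sc_line(sc, a[1L], a[2L], b[1L], b[2L], "#333333", class = "tick")
    lab <- pxy(t, r + 20)
    sc_text(sc, lab[1L], lab[2L] + 3, as.character(t), size = 9,
            class = "tick-label")
  }
  # 5' label just outside position 1
  lab5 <- pxy(1, r + 32)
  sc_text(sc, lab5[1L], lab5[2L], "5'", size = 11, class = "end-label")
  for (p in spec$mutation_marks) {
    a <- pxy(p, r - 6); b <- pxy(p, r + 12)
    sc_line(sc, a[1L], a[2L], b[1L], b[2L], RED, width = 2.4,
            class = "mutation-mark", data = list(position = p))
  }
  if (!is.null(mutation_code) && length(spec$mutation_marks) > 0L) {
    lab <- pxy(spec$mutation_marks[1L], r + 36)
    sc_text(sc, lab[1L], lab[2L], mutation_code, size = 11, fill = RED,
            class = "mutation-label")
  }
  write_scene(sc, out, spec)
}

#' Render a wildtype/mutant arc diagram
#'
#' The sequence is a horizontal baseline; wildtype pairs are drawn as
#' arcs above it and mutant pairs as arcs below it, with opacity
#' proportional to probability. Arcs never cross the baseline. Mutation
#' positions are marked in red on the baseline.
#'
#' @param wt,mut `bp_matrix` objects of equal size.
#' @inheritParams render_heatmap
#' @return Character vector of files written.
#' @export
render_arc_diagram <- function(wt, mut, spec = render_spec(), out) {
  Pw <- as_matrix_values(wt)
  Pm <- as_matrix_values(mut)
  if (nrow(Pw) != nrow(Pm)) snv_stop("matrix sizes differ")
  n <- nrow(Pw)
  W <- 700; H <- 420
  margin <- 40
  y0 <- H / 2
  dx <- (W - 2 * margin) / max(1, n - 1)
  xp <- function(i) margin + (i - 1) * dx
  sc <- new_scene(W, H)
  sc_line(sc, margin, y0, W - margin, y0, "#333333", width = 1.4,
          class = "baseline")
  max_ry <- y0 - 24
  add_arcs <- function(P, above, cls) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        v <- P[i, j]
        if (v < spec$threshold) next
        rx <- (xp(j) - xp(i)) / 2
        ry <- min(max_ry, rx)
        sweep <- if (above) 1 else 0
        d <- sprintf("M %s %s A %s %s 0 0 %d %s %s",
                     fmt_num(xp(i)), fmt_num(y0), fmt_num(rx), fmt_num(ry),
                     sweep, fmt_num(xp(j)), fmt_num(y0))
        sc_path(sc, d, stroke = "#000000", width = 1.4, class = cls,
                opacity = min(1, v), data = list(i = i, j = j))
      }
    }
  }
  add_arcs(Pw, above = TRUE, cls = "arc-wt")
  add_arcs(Pm, above = FALSE, cls = "arc-mut")
  for (t in tick_positions(n, spec$tick_interval)) {
    sc_line(sc, xp(t), y0 - 3, xp(t), y0 + 3, "#333333", class = "tick")
    sc_text(sc, xp(t), y0 + 16, as.character(t), size = 9,
            class = "tick-label")
  }
  sc_text(sc, margin - 14, y0 + 4, "5'", size = 11, class = "end-label")
  sc_text(sc, margin - 24, 24, "WT", size = 11, anchor = "start",
          class = "panel-label")
  sc_text(sc, margin - 24, H - 14, "mutant", size = 11, anchor = "start",
          class = "panel-label")
  for (p in spec$mutation_marks) {
    sc_line(sc, xp(p), y0 - 8, xp(p), y0 + 8, RED, width = 2.4,
            class = "mutation-mark", data = list(position = p))
  }
  write_scene(sc, out, spec)
}

#' Render the combined accessibility track
#'
#' Wildtype and mutant per-position unpaired probabilities on a shared
#' 1-based axis, plus the blue difference curve (wildtype minus mutant;
#' negative values mean the position is more accessible in the mutant).
#' Probability curves live in `[0, 1]`; the difference curve uses the
#' same axis extended to `[-1, 1]`. Mutation positions are marked with
#' red vertical lines.
#'
#' @param wt,mut `accessibility_profile` objects of equal length.
#' @param acc_delta Difference track from [accessibility_delta()]
#'   (recomputed when `NULL`).
#' @inheritParams render_heatmap
#' @return Character vector of files written.
#' @export
render_accessibility <- function(wt, mut, acc_delta = NULL,
                                 spec = render_spec(), out) {
  stopifnot(inherits(wt, "accessibility_profile"),
            inherits(mut, "accessibility_profile"))
  if (wt$n != mut$n) snv_stop("profile lengths differ")
  if (is.null(acc_delta)) acc_delta <- accessibility_delta(wt, mut)
  n <- wt$n
  W <- 700; H <- 380
  ml <- 50; mr <- 16; mt <- 18; mb <- 40
  pw <- W - ml - mr; ph <- H - mt - mb
  xp <- function(i) ml + (i - 1) / max(1, n - 1) * pw
  yp <- function(v) mt + (1 - (v + 1) / 2) * ph  # v in [-1, 1]
  sc <- new_scene(W, H)
  frame_col <- "#333333"
  sc_line(sc, ml, mt, ml, mt + ph, frame_col, class = "frame")
  sc_line(sc, ml, mt + ph, ml + pw, mt + ph, frame_col, class = "frame")
  sc_line(sc, ml, yp(0), ml + pw, yp(0), "#bbbbbb", class = "zero-line")
  for (v in c(-1, -0.5, 0, 0.5, 1)) {
    sc_line(sc, ml - 4, yp(v), ml, yp(v), frame_col, class = "tick")
    sc_text(sc, ml - 7, yp(v) + 3, fmt_num(v), size = 9, anchor = "end",
            class = "tick-label")
  }
  for (t in tick_positions(n, spec$tick_interval)) {
    sc_line(sc, xp(t), mt + ph, xp(t), mt + ph + 4, frame_col,
            class = "tick")
    sc_text(sc, xp(t), mt + ph + 16, as.character(t), size = 9,
            class = "tick-label")
  }
  for (p in spec$mutation_marks) {
    sc_line(sc, xp(p), mt, xp(p), mt + ph, RED, width = 1.2,
            class = "mutation-mark", opacity = 0.8,
            data = list(position = p))
  }
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  xs <- vapply(seq_len(n), xp, numeric(1L))
  sc_polyline(sc, xs, yp(clamp01(wt$pu)), "#000000", class = "curve-wt")
  sc_polyline(sc, xs, yp(clamp01(mut$pu)), "#e08214", class = "curve-mut")
  sc_polyline(sc, xs, yp(pmin(pmax(acc_delta, -1), 1)), BLUE,
              class = "curve-delta")
  sc_text(sc, ml + 8, mt + 12, "WT", size = 10, anchor = "start",
          class = "legend")
  sc_text(sc, ml + 40, mt + 12, "mutant", size = 10, anchor = "start",
          fill = "#e08214", class = "legend")
  sc_text(sc, ml + 100, mt + 12, "WT - mut", size = 10, anchor = "start",
          fill = BLUE, class = "legend")
  write_scene(sc, out, spec)
}
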