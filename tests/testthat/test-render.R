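library(xml2)

svg_nodes <- function(path, class) {
  doc <- read_xml(path)
  xml_find_all(doc, sprintf("//*[@class='%s']", class))
}

worked_matrices <- function() {
  m <- mod_uniform()
  wt <- validate_sequence("GAAAC", "wt")
  mut <- validate_sequence("AAAAC", "mut")
  list(wt = wt, mut = mut,
       bw = pair_probabilities_global(wt, m),
       bm = pair_probabilities_global(mut, m),
       aw = accessibility_profile(wt, m),
       am = accessibility_profile(mut, m))
}

test_that("heatmaps produce the requested formats with guides and ticks", {
  w <- worked_matrices()
  M <- combined_triangle_matrix(w$bw, w$bm)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "combined")
  spec <- render_spec(formats = c("png", "svg"), tick_interval = 2,
                      mutation_marks = 1L)
  files <- render_heatmap(M, spec, out)
  expect_setequal(files, paste0(out, c(".png", ".svg")))
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))
  svg <- paste0(out, ".svg")
  # red guide lines on both axes at the mutation position
  guides <- svg_nodes(svg, "mutation-guide")
  expect_length(guides, 2L)
  expect_true(all(xml_attr(guides, "data-position") == "1"))
  # 1-based tick labels at the configured interval
  labels <- xml_text(svg_nodes(svg, "tick-label"))
  expect_true(all(c("2", "4") %in% labels))
  # the darkest cell is the wildtype (1,5) entry
  cells <- svg_nodes(svg, "cell")
  expect_gt(length(cells), 0)
  is15 <- xml_attr(cells, "data-i") == "1" & xml_attr(cells, "data-j") == "5"
  expect_true(any(is15))
  grey <- function(node) {
    strtoi(substr(xml_attr(node, "fill"), 2, 3), base = 16L)
  }
  fills <- vapply(seq_along(cells), function(k) grey(cells[[k]]), 0)
  expect_equal(min(fills), fills[which(is15)])
})

test_that("SVG output is byte-deterministic", {
  w <- worked_matrices()
  dir <- withr::local_tempdir()
  spec <- render_spec(formats = "svg", mutation_marks = 1L)
  f1 <- render_heatmap(w$bw, spec, file.path(dir, "a"))
  f2 <- render_heatmap(w$bw, spec, file.path(dir, "b"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c1 <- render_circular(w$bw$P, spec, file.path(dir, "c1"), "G1A")
  c2 <- render_circular(w$bw$P, spec, file.path(dir, "c2"), "G1A")
  expect_identical(readBin(c1, "raw", file.size(c1)),
                   readBin(c2, "raw", file.size(c2)))
})

test_that("differential heatmap colors by sign, symmetric about zero", {
  w <- worked_matrices()
  delta <- diff_matrix(w$bw, w$bm)
  dir <- withr::local_tempdir()
  spec <- render_spec(formats = "svg")
  f <- render_diff_heatmap(delta, spec, file.path(dir, "diff"))
  cells <- svg_nodes(f, "cell")
  fills <- xml_attr(cells, "fill")
  # delta(1,5) < 0: blue cell means blue channel stronger than red
  rgbv <- function(hex) strtoi(c(substr(hex, 2, 3), substr(hex, 4, 5),
                                 substr(hex, 6, 7)), base = 16L)
  for (hex in fills) {
    v <- rgbv(hex)
    expect_gt(v[3], v[1])  # all entries here are weakenings
  }
  # negated input swaps blue for red exactly
  f2 <- render_diff_heatmap(-delta, spec, file.path(dir, "diffneg"))
  fills2 <- xml_attr(svg_nodes(f2, "cell"), "fill")
  swap <- function(hex) {
    v <- rgbv(hex)
    grDevices::rgb(v[3], v[2], v[1], maxColorValue = 255)
  }
  expect_identical(toupper(fills2),
                   unname(toupper(vapply(fills, swap, ""))))
  # all-zero delta renders no colored cells (all-white panel)
  f3 <- render_diff_heatmap(matrix(0, 5, 5), spec, file.path(dir, "null"))
  expect_length(svg_nodes(f3, "cell"), 0L)
  expect_error(render_diff_heatmap(matrix(2, 2, 2), spec,
                                   file.path(dir, "bad")), "\\[-1, 1\\]")
})

test_that("circular plots draw one chord per above-threshold entry", {
  w <- worked_matrices()
  dir <- withr::local_tempdir()
  spec <- render_spec(formats = "svg", tick_interval = 2,
                      mutation_marks = 1L)
  f <- render_circular(w$bw$P, spec, file.path(dir, "circ"), "G1A")
  chords <- svg_nodes(f, "chord")
  expect_length(chords, sum(w$bw$P[upper.tri(w$bw$P)] >= spec$threshold))
  expect_equal(xml_attr(chords[[1]], "data-i"), "1")
  expect_equal(xml_attr(chords[[1]], "data-j"), "5")
  expect_length(svg_nodes(f, "mutation-mark"), 1L)
  expect_equal(xml_text(svg_nodes(f, "mutation-label")), "G1A")
  # zero matrix: a circle with no chords
  f0 <- render_circular(matrix(0, 5, 5), spec, file.path(dir, "zero"))
  expect_length(svg_nodes(f0, "chord"), 0L)
  expect_length(svg_nodes(f0, "backbone"), 1L)
})

test_that("arc diagrams keep wildtype above and mutant below the baseline", {
  w <- worked_matrices()
  dir <- withr::local_tempdir()
  spec <- render_spec(formats = "svg", mutation_marks = 1L)
  f <- render_arc_diagram(w$bw, w$bm, spec, file.path(dir, "arcs"))
  expect_length(svg_nodes(f, "arc-wt"), 1L)   # single WT pair
  expect_length(svg_nodes(f, "arc-mut"), 0L)  # mutant unstructured
  # sweep flags: WT arcs bulge up (sweep 1), mutant arcs down (sweep 0)
  d <- xml_attr(svg_nodes(f, "arc-wt")[[1]], "d")
  expect_match(d, " 0 0 1 ")
  f2 <- render_arc_diagram(w$bw, w$bw, spec, file.path(dir, "mirror"))
  expect_length(svg_nodes(f2, "arc-wt"), 1L)
  expect_length(svg_nodes(f2, "arc-mut"), 1L)
  dm <- xml_attr(svg_nodes(f2, "arc-mut")[[1]], "d")
  expect_match(dm, " 0 0 0 ")
})

test_that("accessibility track plots both curves and the blue delta", {
  w <- worked_matrices()
  dir <- withr::local_tempdir()
  spec <- render_spec(formats = c("svg", "png"), tick_interval = 2,
                      mutation_marks = 1L)
  files <- render_accessibility(w$aw, w$am, NULL, spec,
                                file.path(dir, "acc"))
  expect_length(files, 2L)
  svg <- grep("svg$", files, value = TRUE)
  for (cls in c("curve-wt", "curve-mut", "curve-delta")) {
    expect_length(svg_nodes(svg, cls), 1L)
  }
  expect_length(svg_nodes(svg, "mutation-mark"), 1L)
  # identical profiles: delta curve is the flat zero line
  f2 <- render_accessibility(w$aw, w$aw, NULL, render_spec(formats = "svg"),
                             file.path(dir, "null"))
  pts <- xml_attr(svg_nodes(f2, "curve-delta")[[1]], "points")
  ys <- unique(vapply(strsplit(strsplit(pts, " ")[[1]], ","),
                      `[[`, "", 2L))
  expect_length(ys, 1L)
})
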