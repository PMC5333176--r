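# Pair builders: a reference chain and a perturbed copy, already in the
# same frame (assume-aligned), with full correspondence by construction.
aligned_pair_scene <- function(ref, other, mode = "superposed",
                               config = layout_config()) {
  corr <- correspond(ref, other, max_dist = 1e6)
  ca <- multi_align(ref, list(other), list(corr))
  build_scene(ca, mode = mode, config = config)
}

test_that("sse_axis endpoints and direction come from first/last CA", {
  ch <- protein_chain("ax", "A",
                      data.frame(res_id = as.character(1:4), name = "ALA"),
                      rbind(c(0, 0, 0), c(0, 0, 3), c(0, 0, 6), c(0, 0, 9)),
                      data.frame(kind = "HELIX", start = 0, end = 3))
  ax <- sse_axis(ch, "H1")
  expect_equal(ax$direction, c(0, 0, 1))
  expect_true(ax$defined)
  # random element equals independent normalization
  set.seed(8)
  big <- build_chain(chain_spec("C2 E6 C2"))
  ax2 <- sse_axis(big, "E1")
  v <- big$ca[8L, ] - big$ca[3L, ]
  expect_equal(ax2$direction, v / sqrt(sum(v^2)), tolerance = 1e-12)
  # one-residue element: undefined direction
  tiny <- protein_chain("t", "A", data.frame(res_id = "1", name = "ALA"),
                        rbind(c(1, 2, 3)),
                        data.frame(kind = "HELIX", start = 0, end = 0))
  expect_false(sse_axis(tiny, "H1")$defined)
})

test_that("glyph_length uses 3D extent for beads, residue count for coils", {
  ch <- protein_chain("len", "A",
                      data.frame(res_id = as.character(1:2), name = "ALA"),
                      rbind(c(0, 0, 0), c(3, 4, 0)),
                      data.frame(kind = "SHEET", start = 0, end = 1))
  cfg <- layout_config(scale = 1)
  expect_equal(glyph_length(ch, "E1", cfg), 5)       # 3-4-5 triangle
  cfg4 <- layout_config(scale = 4)
  expect_equal(glyph_length(ch, "E1", cfg4), 20)

  # 10-residue ideal helix: 9 rises of 1.5 A along the axis plus a 180-degree
  # radial phase offset of 2 x 2.3 A between the endpoint CAs
  helix <- build_chain(chain_spec("H10"))
  expect_equal(glyph_length(helix, "H1", cfg),
               sqrt(13.5^2 + 4.6^2), tolerance = 1e-9)

  coil <- build_chain(chain_spec("C7"))
  expect_equal(glyph_length(coil, "C1", cfg), 7 * cfg$coil_per_residue)
  # degenerate 1-residue element floors at the minimum
  tiny <- protein_chain("t", "A", data.frame(res_id = "1", name = "ALA"),
                        rbind(c(0, 0, 0)),
                        data.frame(kind = "HELIX", start = 0, end = 0))
  expect_equal(glyph_length(tiny, "H1", cfg), cfg$min_glyph_length)
})

test_that("glyph_angle magnitude, sign and symmetry behave", {
  mk <- function(v) list(start = c(0, 0, 0), end = v,
                         direction = v / sqrt(sum(v^2)), defined = TRUE)
  expect_equal(glyph_angle(mk(c(1, 0, 0)), mk(c(1, 0, 0))), 0)
  expect_equal(abs(glyph_angle(mk(c(1, 0, 0)), mk(c(0, 1, 0)))), 90)
  expect_equal(abs(glyph_angle(mk(c(1, 0, 0)), mk(c(-1, 0, 0)))), 180)
  # sign: counterclockwise rotation in the viewing plane is positive,
  # and swapping arguments flips it
  expect_equal(glyph_angle(mk(c(1, 0, 0)), mk(c(1, 1, 0))), 45)
  expect_equal(glyph_angle(mk(c(1, 1, 0)), mk(c(1, 0, 0))), -45)
  # random pairs: magnitude equals the arccos-dot oracle
  set.seed(12)
  for (i in 1:25) {
    u <- rnorm(3); v <- rnorm(3)
    got <- glyph_angle(mk(u), mk(v))
    want <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) *
      180 / pi
    expect_equal(abs(got), want, tolerance = 1e-9)
    expect_equal(glyph_angle(mk(v), mk(u)), -got, tolerance = 1e-9)
  }
  und <- list(direction = rep(NA_real_, 3), defined = FALSE)
  expect_warning(a <- glyph_angle(und, mk(c(1, 0, 0))), "undefined")
  expect_equal(a, 0)
})

test_that("glyph_shift projects the centroid displacement into the local frame", {
  ref <- build_chain(chain_spec("C2 H10 C2"), source_id = "ref")
  cfg <- layout_config(scale = 4)
  expect_equal(glyph_shift(ref, "H1", ref, "H1", cfg), c(0, 0))
  # translation along the element's own axis appears as (2 * scale, 0)
  ax <- sse_axis(ref, "H1")
  moved <- ref
  idx <- (3:12)
  moved$ca[idx, ] <- sweep(moved$ca[idx, , drop = FALSE], 2L,
                           2 * ax$direction, "+")
  expect_equal(glyph_shift(ref, "H1", moved, "H1", cfg), c(2 * 4, 0),
               tolerance = 1e-9)
  # random displacement equals the independent frame-projection oracle
  set.seed(3)
  for (i in 1:10) {
    d <- rnorm(3)
    m2 <- ref
    m2$ca[idx, ] <- sweep(m2$ca[idx, , drop = FALSE], 2L, d, "+")
    got <- glyph_shift(ref, "H1", m2, "H1", cfg)
    xhat <- ax$direction
    yhat <- c(-xhat[2L], xhat[1L], 0)    # z cross x, for an in-plane axis
    yhat <- yhat / sqrt(sum(yhat^2))
    expect_equal(got, c(sum(d * xhat), sum(d * yhat)) * 4, tolerance = 1e-9)
  }
})

test_that("self-comparison collapses to identity glyphs", {
  ref <- build_chain(chain_spec("C2 H10 C3 E6 C2 H8 C2"), source_id = "id")
  sc <- aligned_pair_scene(ref, ref)
  beads <- sc$glyphs[sc$glyphs$kind %in% c("HELIX", "SHEET"), ]
  expect_equal(max(abs(beads$angle_deg)), 0, tolerance = 1e-9)
  expect_equal(max(abs(beads$shift_x)), 0, tolerance = 1e-9)
  expect_equal(max(abs(beads$shift_y)), 0, tolerance = 1e-9)
  # both tracks coincide column-anchor by column-anchor
  for (cc in unique(beads$column)) {
    xs <- beads$x[beads$column == cc]
    expect_equal(max(xs) - min(xs), 0, tolerance = 1e-9)
  }
})

test_that("known rotation and in-frame shift are recovered exactly", {
  ref <- build_chain(chain_spec("C2 H10 C3 E6 C2 H10 C2"), source_id = "gt")
  cfg <- layout_config(scale = 4)
  for (theta in c(5, 15, 30, 60)) {
    a <- 1.7; b <- -2.4
    pert <- perturb(ref,
                    rotations = list(H2 = list(theta = theta)),
                    translations = list(H2 = list(along = a, across = b)))
    sc <- aligned_pair_scene(ref, pert, config = cfg)
    g <- sc$glyphs[sc$glyphs$track == 2L & !is.na(sc$glyphs$sse_id) &
                     sc$glyphs$sse_id == "H2", ]
    expect_equal(g$angle_deg, theta, tolerance = 1e-6)
    expect_equal(g$shift_x, a * 4, tolerance = 1e-6)
    expect_equal(g$shift_y, b * 4, tolerance = 1e-6)
    others <- sc$glyphs[sc$glyphs$track == 2L &
                          sc$glyphs$kind %in% c("HELIX", "SHEET") &
                          sc$glyphs$sse_id != "H2", ]
    expect_equal(max(abs(others$angle_deg)), 0, tolerance = 1e-6)
    expect_equal(max(abs(c(others$shift_x, others$shift_y))), 0,
                 tolerance = 1e-6)
  }
})

test_that("gap slots become fixed-width zero-angle glyphs", {
  ref <- build_chain(chain_spec("C1 H6 C1 E4 C1"), source_id = "ref")
  del <- perturb(ref, delete = "E1"); del$source_id <- "del"
  sc <- aligned_pair_scene(ref, del)
  gaps <- sc$glyphs[sc$glyphs$kind == "GAP", ]
  expect_equal(nrow(gaps), 1L)
  expect_equal(gaps$angle_deg, 0)
  expect_equal(gaps$length, sc$config$gap_width)
  expect_equal(gaps$x, sc$anchors[gaps$column + 1L])
})

test_that("visible range restricts glyphs but not the navigation strip", {
  ref <- build_chain(chain_spec("C1 H4 C1 E3 C1 H4 C1 E3 C1 H4 C1"),
                     source_id = "rng")
  corr <- correspond(ref, ref)
  ca <- multi_align(ref, list(ref), list(corr))
  sc <- build_scene(ca, range = c(1L, 3L))
  cols <- sc$glyphs$column[!is.na(sc$glyphs$column)]
  expect_true(all(cols >= 1L & cols < 3L))
  expect_equal(max(sc$nav$to), column_count(ca))
  expect_error(build_scene(ca, range = c(3L, 3L)), "range")
  expect_error(build_scene(ca, range = c(-1L, 2L)), "range")
})

test_that("juxtaposed tracks are stacked by row height", {
  ref <- build_chain(chain_spec("C1 H5 C1"), source_id = "st")
  c2 <- ref; c2$source_id <- "b"
  c3 <- ref; c3$source_id <- "c"
  ca <- multi_align(ref, list(c2, c3),
                    list(correspond(ref, c2), correspond(ref, c3)))
  cfg <- layout_config(row_height = 40)
  sc <- build_scene(ca, mode = "juxtaposed", config = cfg)
  ys <- vapply(1:3, function(tk) {
    unique(sc$glyphs$y[sc$glyphs$track == tk &
                         sc$glyphs$kind == "HELIX"])[1L]
  }, numeric(1))
  expect_equal(ys, c(0, 40, 80))
  sup <- build_scene(ca, mode = "superposed", config = cfg)
  expect_equal(unique(sup$glyphs$y[sup$glyphs$kind == "HELIX"]), 0)
})

test_that("scene JSON carries full glyph geometry", {
  ref <- build_chain(chain_spec("C1 H5 C1"), source_id = "js")
  ca <- multi_align(ref, list(ref), list(correspond(ref, ref)))
  js <- jsonlite::fromJSON(scene_to_json(build_scene(ca)))
  expect_equal(js$mode, "superposed")
  expect_true(all(c("track", "sse_id", "x", "angle_deg", "length") %in%
                    names(js$glyphs)))
})
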