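#' Rendering parameters
#'
#' @param palette Character vector of per-chain colors; cycled when there
#'   are more chains than colors.
#' @param stroke_width Glyph stroke width.
#' @param opacity Per-track opacity in superposed mode.
#' @param gap_fill Fill of the gray gap rectangles in the tracks.
#' @param nav_gap_fill Fill of gap segments on the navigation strip.
#' @param highlight Optional sse id drawn in the highlight color.
#' @param highlight_color Color used for the highlighted element.
#' @param font Font family for labels.
#' @param margin Outer margin in layout units.
#' @return Named list of class `ssemap_render_config`.
#' @export
render_config <- function(palette = c("#1f77b4", "#ff7f0e", "#2ca02c",
                                      "#d62728", "#9467bd", "#8c564b",
                                      "#e377c2", "#7f7f7f"),
                          stroke_width = 2, opacity = 0.65,
                          gap_fill = "#bdbdbd", nav_gap_fill = "#000000",
                          highlight = NULL, highlight_color = "#00a651",
                          font = "sans-serif", margin = 20) {
  structure(list(palette = palette, stroke_width = stroke_width,
                 opacity = opacity, gap_fill = gap_fill,
                 nav_gap_fill = nav_gap_fill, highlight = highlight,
                 highlight_color = highlight_color, font = font,
                 margin = margin),
            class = "ssemap_render_config")
}

num <- function(x) sprintf("%.3f", x)

# sinusoid path approximating a helix spiral, from (0,0) to (len,0)
helix_path <- function(len, amp = 5, wavelength = 10) {
  n <- max(8L, ceiling(len / wavelength * 8L))
  xs <- seq(0, len, length.out = n + 1L)
  ys <- amp * sin(xs / wavelength * 2 * pi)
  paste0("M ", paste(paste(num(xs), num(ys)), collapse = " L "))
}

# arrow polygon for a strand, from (0,0) to (len,0)
sheet_points <- function(len, half = 3.5, head = 7) {
  hd <- min(head, len * 0.6)
  pts <- rbind(c(0, -half), c(len - hd, -half), c(len - hd, -half * 2),
               c(len, 0), c(len - hd, half * 2), c(len - hd, half),
               c(0, half))
  paste(apply(pts, 1L, function(p) paste(num(p[1L]), num(p[2L]))),
        collapse = " ")
}

svg_el <- function(tag, attrs, body = NULL) {
  a <- paste(sprintf('%s="%s"', names(attrs), unlist(attrs)), collapse = " ")
  if (is.null(body)) sprintf("<%s %s/>", tag, a)
  else sprintf("<%s %s>%s</%s>", tag, a, body, tag)
}

render_glyph <- function(g, color, cfg) {
  hl <- !is.null(cfg$highlight) && !is.na(g$sse_id) &&
    identical(g$sse_id, cfg$highlight)
  col <- if (hl) cfg$highlight_color else color
  attrs_common <- list(class = paste0("glyph ", tolower(g$kind)),
                       `data-sse` = if (is.na(g$sse_id)) "gap" else g$sse_id)
  body <- switch(
    g$kind,
    HELIX = svg_el("path", c(attrs_common, list(
      d = helix_path(g$length), fill = "none", stroke = col,
      `stroke-width` = num(cfg$stroke_width)))),
    SHEET = svg_el("polygon", c(attrs_common, list(
      points = sheet_points(g$length), fill = col, stroke = "none"))),
    COIL = svg_el("line", c(attrs_common, list(
      x1 = num(0), y1 = num(0), x2 = num(g$length), y2 = num(0),
      stroke = col, `stroke-width` = num(cfg$stroke_width)))),
    GAP = svg_el("rect", c(attrs_common, list(
      x = num(0), y = num(-5), width = num(g$length), height = num(10),
      fill = cfg$gap_fill, stroke = "none"))))
  svg_el("g",
         list(transform = sprintf("translate(%s %s) rotate(%s)",
                                  num(g$x), num(g$y), num(g$angle_deg))),
         body)
}

#' Render a scene to SVG
#'
#' Deterministic text output: identical scene + config give byte-identical
#' SVG. Helices are sinusoid paths, sheets arrow polygons, coils lines, GAP
#' slots gray rectangles. In superposed mode all tracks share one baseline
#' and are drawn with partial opacity; in juxtaposed mode they are stacked,
#' reference on top. The navigation strip (one line per chain, black
#' segments for gaps, interrupted at polymer breaks) sits below the panel.
#'
#' @param scene A `Scene` from [build_scene()].
#' @param config A [render_config()].
#' @return SVG document as a single string.
#' @export
render_svg <- function(scene, config = render_config()) {
  cfg <- config
  g <- scene$glyphs
  m <- cfg$margin
  xmax <- if (nrow(g)) max(g$x + g$length) else 100
  ymin <- if (nrow(g)) min(g$y) - 15 else -15
  ymax <- if (nrow(g)) max(g$y) + 15 else 15
  nav_tracks <- unique(scene$nav$track)
  nav_h <- 8 * length(nav_tracks) + 10
  width <- xmax + 2 * m
  height <- (ymax - ymin) + nav_h + 2 * m + 10

  tracks <- sort(unique(g$track))
  parts <- character(0)
  for (tk in tracks) {
    color <- cfg$palette[((tk - 1L) %% length(cfg$palette)) + 1L]
    gg <- g[g$track == tk, , drop = FALSE]
    body <- paste(vapply(seq_len(nrow(gg)), function(i) {
      render_glyph(gg[i, ], color, cfg)
    }, character(1)), collapse = "")
    op <- if (scene$mode == "superposed") cfg$opacity else 1
    parts <- c(parts, svg_el("g", list(
      class = "track", `data-track` = tk, opacity = num(op)), body))
  }

  # navigation strip in column units mapped linearly to the panel width
  ncol_ <- max(scene$nav$to)
  colx <- function(cc) cc / max(ncol_, 1L) * xmax
  navy0 <- (ymax - ymin) + 20
  nav_parts <- character(0)
  for (i in seq_len(nrow(scene$nav))) {
    s <- scene$nav[i, ]
    y <- navy0 + (s$track - 1L) * 8
    color <- cfg$palette[((s$track - 1L) %% length(cfg$palette)) + 1L]
    if (s$kind == "chain") {
      nav_parts <- c(nav_parts, svg_el("line", list(
        class = "nav chain", x1 = num(colx(s$from)), y1 = num(y),
        x2 = num(colx(s$to)), y2 = num(y), stroke = color,
        `stroke-width` = "3")))
    } else if (s$kind == "gap") {
      nav_parts <- c(nav_parts, svg_el("rect", list(
        class = "nav gap", x = num(colx(s$from)), y = num(y - 2),
        width = num(colx(s$to) - colx(s$from)), height = "4",
        fill = cfg$nav_gap_fill)))
    } else {
      nav_parts <- c(nav_parts, svg_el("rect", list(
        class = "nav break", x = num(colx(s$from) - 1), y = num(y - 3),
        width = "2", height = "6", fill = "#ffffff", stroke = "none")))
    }
  }

  body <- paste0(
    svg_el("g", list(transform = sprintf("translate(%s %s)", num(m),
                                         num(m - ymin))),
           paste(parts, collapse = "")),
    svg_el("g", list(class = "navstrip",
                     transform = sprintf("translate(%s %s)", num(m),
                                         num(m - ymin))),
           paste(nav_parts, collapse = "")))
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                        'width="%s" height="%s" viewBox="0 0 %s %s" ',
                        'font-family="%s">'),
                 num(width), num(height), num(width), num(height), cfg$font),
         body, "</svg>\n")
}

#' Stack several rendered panels into one SVG document
#'
#' Used by the CLI's `--mode both` to emit the superposed and juxtaposed
#' panels in a single file.
#'
#' @param svgs List of SVG document strings from [render_svg()].
#' @return One SVG document string.
#' @export
svg_stack <- function(svgs) {
  dims <- lapply(svgs, function(s) {
    w <- as.numeric(sub('.*<svg[^>]* width="([0-9.]+)".*', "\\1", s))
    h <- as.numeric(sub('.*height="([0-9.]+)".*', "\\1", s))
    c(w, h)
  })
  width <- max(vapply(dims, `[`, numeric(1), 1L))
  height <- sum(vapply(dims, `[`, numeric(1), 2L))
  y <- 0
  parts <- character(0)
  for (i in seq_along(svgs)) {
    inner <- sub('^.*?<svg[^>]*>', "", svgs[[i]])
    inner <- sub("</svg>\\s*$", "", inner)
    parts <- c(parts, svg_el("g", list(
      transform = sprintf("translate(0 %s)", num(y))), inner))
    y <- y + dims[[i]][2L]
  }
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
                 num(width), num(height), num(width), num(height)),
         paste(parts, collapse = ""), "</svg>\n")
}
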