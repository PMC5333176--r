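#' Layout parameters
#'
#' Geometry knobs for the 2D map. Units are abstract layout units; `scale`
#' converts Angstrom to layout units for helix/sheet glyph lengths and
#' shifts, coils are drawn per residue (their 3D extent is conformation
#' noise, not signal), and `gap_width` is the fixed width of the gray gap
#' rectangle.
#'
#' @param scale Layout units per Angstrom (default 4).
#' @param coil_per_residue Units of line per coil residue (default 2).
#' @param spacing Horizontal padding between consecutive columns (default 3).
#' @param gap_width Width of a GAP rectangle (default 8).
#' @param min_glyph_length Floor for degenerate (1-residue) elements
#'   (default 2).
#' @param row_height Vertical distance between tracks in juxtaposed mode
#'   (default 40).
#' @param angle_mode `"space3d"` (default): angle magnitude measured between
#'   the 3D direction vectors, sign from the viewing-axis component of their
#'   cross product; `"projected"`: both directions projected to the viewing
#'   (xy) plane first.
#' @return Named list of class `ssemap_layout_config`.
#' @export
layout_config <- function(scale = 4, coil_per_residue = 2, spacing = 3,
                          gap_width = 8, min_glyph_length = 2,
                          row_height = 40,
                          angle_mode = c("space3d", "projected")) {
  structure(list(scale = scale, coil_per_residue = coil_per_residue,
                 spacing = spacing, gap_width = gap_width,
                 min_glyph_length = min_glyph_length,
                 row_height = row_height,
                 angle_mode = match.arg(angle_mode)),
            class = "ssemap_layout_config")
}

#' Axis of a secondary-structure element
#'
#' Start and end are the CA positions of the element's first and last
#' residue; the direction is their normalized difference. A one-residue
#' element has a zero-length axis and an undefined direction (`defined =
#' FALSE`); downstream angles default to 0 for it.
#'
#' @param chain A `ProteinChain`.
#' @param sse_id Id of one of its SSEs.
#' @return List with `start`, `end` (length-3 points), `direction` (unit
#'   vector or `NA`s) and `defined` (logical).
#' @export
sse_axis <- function(chain, sse_id) {
  idx <- sse_rows_idx(chain, sse_id)
  p0 <- chain$ca[idx[1L], ]
  p1 <- chain$ca[idx[length(idx)], ]
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len < 1e-12) {
    return(list(start = p0, end = p1, direction = rep(NA_real_, 3L),
                defined = FALSE))
  }
  list(start = p0, end = p1, direction = v / len, defined = TRUE)
}

#' Glyph length of an element
#'
#' Helix and sheet glyphs take their length from 3D: the Euclidean distance
#' between first and last CA, times `scale`. Coil glyphs are drawn per
#' residue (`coil_per_residue` units each). Degenerate elements are floored
#' at `min_glyph_length`.
#'
#' @param chain A `ProteinChain`.
#' @param sse_id Id of one of its SSEs.
#' @param config A [layout_config()].
#' @return Length in layout units.
#' @export
glyph_length <- function(chain, sse_id, config = layout_config()) {
  r <- sse_row(chain, sse_id)
  nres <- r$end - r$start + 1L
  len <- if (r$kind == "COIL") {
    nres * config$coil_per_residue
  } else {
    ax <- sse_axis(chain, sse_id)
    sqrt(sum((ax$end - ax$start)^2)) * config$scale
  }
  max(len, config$min_glyph_length)
}

#' Signed angle between two element axes
#'
#' Magnitude is the 3D angle between the unit directions — the value of
#' `acos(clamp(dot))`, computed as `atan2(|cross|, dot)` for stability near
#' 0 and 180 — in `[0, 180]` degrees; the sign is taken from the
#' z-component (viewing axis of the superposed frame) of `ref_dir x
#' other_dir`, so an element rotated counterclockwise in the viewing plane
#' gets a positive angle. With `mode = "projected"` both directions are
#' first projected onto the xy plane.
#'
#' @param ref_axis,other_axis Axes from [sse_axis()].
#' @param mode `"space3d"` or `"projected"`.
#' @return Signed angle in degrees, in (-180, 180].
#' @export
glyph_angle <- function(ref_axis, other_axis, mode = "space3d") {
  if (!isTRUE(ref_axis$defined) || !isTRUE(other_axis$defined)) {
    warning("undefined axis direction; angle defaults to 0")
    return(0)
  }
  u <- ref_axis$direction
  v <- other_axis$direction
  if (mode == "projected") {
    u[3L] <- 0; v[3L] <- 0
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < 1e-12 || nv < 1e-12) {
      warning("direction parallel to viewing axis; angle defaults to 0")
      return(0)
    }
    u <- u / nu; v <- v / nv
  }
  # atan2(|u x v|, u . v): same value as acos of the clamped dot product
  # but numerically stable near 0 and 180 degrees
  cr <- c(u[2L] * v[3L] - u[3L] * v[2L],
          u[3L] * v[1L] - u[1L] * v[3L],
          u[1L] * v[2L] - u[2L] * v[1L])
  ang <- atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
  cz <- cr[3L]
  s <- if (cz < 0) -1 else 1
  a <- s * ang
  if (a <= -180) a <- a + 360
  a
}

# Local 2D frame of a reference element: x along its direction, y chosen in
# the viewing plane; the third (discarded) axis completes the right-handed
# frame. Falls back to world-y when the direction is parallel to world-z.
ref_local_frame <- function(ref_axis) {
  xhat <- ref_axis$direction
  up <- c(0, 0, 1)
  yh <- c(up[2L] * xhat[3L] - up[3L] * xhat[2L],
          up[3L] * xhat[1L] - up[1L] * xhat[3L],
          up[1L] * xhat[2L] - up[2L] * xhat[1L])
  if (sqrt(sum(yh^2)) < 1e-9) {
    up <- c(0, 1, 0)
    yh <- c(up[2L] * xhat[3L] - up[3L] * xhat[2L],
            up[3L] * xhat[1L] - up[1L] * xhat[3L],
            up[1L] * xhat[2L] - up[2L] * xhat[1L])
  }
  yhat <- yh / sqrt(sum(yh^2))
  list(x = xhat, y = yhat)
}

#' 2D shift between corresponding elements
#'
#' The 3D displacement between the centroids of the two elements is
#' expressed in the reference element's local frame (x along the reference
#' direction, y perpendicular in the viewing plane); the component along the
#' third axis is discarded ("ignore the Z coordinate"), and the remaining
#' (along, across) pair, scaled to layout units, is the offset of the
#' aligned glyph relative to its reference glyph anchor.
#'
#' @param ref Reference `ProteinChain`; `other` must be superposed onto it.
#' @param ref_sse,other_sse Ids of the corresponding elements.
#' @param other Superposed `ProteinChain`.
#' @param config A [layout_config()].
#' @return Numeric length-2 (along, across) offset in layout units.
#' @export
glyph_shift <- function(ref, ref_sse, other, other_sse,
                        config = layout_config()) {
  ax <- sse_axis(ref, ref_sse)
  d <- sse_centroid(other, other_sse) - sse_centroid(ref, ref_sse)
  if (!ax$defined) return(c(0, 0))
  fr <- ref_local_frame(ax)
  c(sum(d * fr$x), sum(d * fr$y)) * config$scale
}

#' Build the 2D scene for a column alignment
#'
#' Reference glyphs are laid collinearly left to right in column order
#' (anchors separated by glyph lengths, inter-column spacing and the
#' reference's own coil runs); every aligned chain's matched glyph sits at
#' its column's reference anchor plus its [glyph_shift()], rotated by its
#' [glyph_angle()] about the glyph start; unmatched elements sit straight at
#' their column anchor; GAP slots become gray rectangles. The navigation
#' strip spans the full column range regardless of the zoom window.
#'
#' @param col_align A `ColumnAlignment` whose gapped chains carry
#'   `ProteinChain`s with coordinates (all superposed onto the reference).
#' @param mode `"superposed"` (all tracks on one baseline) or `"juxtaposed"`
#'   (track k offset vertically by `k * row_height`).
#' @param range Optional visible column window `c(from, to)` (0-based,
#'   half-open); glyphs outside are dropped, the navigation strip is not.
#' @param config A [layout_config()].
#' @return A `Scene`: list with `glyphs` (data.frame: `track`, `source_id`,
#'   `column`, `sse_id`, `kind`, `x`, `y`, `angle_deg`, `shift_x`,
#'   `shift_y`, `length`), `nav` (data.frame of strip segments), `anchors`
#'   (column anchor x positions), `mode`, `range`, `config`.
#' @export
build_scene <- function(col_align, mode = c("superposed", "juxtaposed"),
                        range = NULL, config = layout_config()) {
  mode <- match.arg(mode)
  ncol_ <- column_count(col_align)
  if (!is.null(range)) {
    range <- as.integer(range)
    if (length(range) != 2L || range[1L] < 0L || range[2L] > ncol_ ||
        range[1L] >= range[2L]) {
      stop("empty or invalid visible column range")
    }
  }
  gapped <- col_align$gapped
  ref_g <- gapped[[col_align$ref_index]]
  ref <- ref_g$chain
  if (is.null(ref)) stop("scene construction needs chains with coordinates")

  # reference coil run (in residues) following each of its beads
  rb <- chain_beads(ref)
  coil_after <- function(bead_id) {
    k <- match(bead_id, ref$sses$sse_id)
    if (!is.na(k) && k < nrow(ref$sses) && ref$sses$kind[k + 1L] == "COIL") {
      ref$sses$sse_id[k + 1L]
    } else NA_character_
  }

  # column anchors from the reference track
  anchors <- numeric(ncol_)
  widths <- numeric(ncol_)
  x <- 0
  # leading reference coil, if any
  lead <- if (nrow(ref$sses) && ref$sses$kind[1L] == "COIL") {
    glyph_length(ref, ref$sses$sse_id[1L], config)
  } else 0
  x <- x + lead
  for (cc in seq_len(ncol_)) {
    slot <- ref_g$slots[cc]
    w <- if (is.na(slot)) config$gap_width else glyph_length(ref, slot, config)
    anchors[cc] <- x
    widths[cc] <- w
    x <- x + w + config$spacing
    if (!is.na(slot)) {
      co <- coil_after(slot)
      if (!is.na(co)) x <- x + glyph_length(ref, co, config)
    }
  }

  glyphs <- list()
  add <- function(track, source_id, column, sse_id, kind, gx, gy,
                  angle, sx, sy, len) {
    glyphs[[length(glyphs) + 1L]] <<- data.frame(
      track = track, source_id = source_id, column = column,
      sse_id = sse_id, kind = kind, x = gx, y = gy, angle_deg = angle,
      shift_x = sx, shift_y = sy, length = len, stringsAsFactors = FALSE)
  }

  for (tk in seq_along(gapped)) {
    g <- gapped[[tk]]
    ch <- g$chain
    ty <- if (mode == "juxtaposed") (tk - 1L) * config$row_height else 0
    is_ref <- tk == col_align$ref_index
    prev_bead <- NA_character_
    for (cc in seq_len(ncol_)) {
      slot <- g$slots[cc]
      if (is.na(slot)) {
        add(tk, ch$source_id, cc - 1L, NA_character_, "GAP",
            anchors[cc], ty, 0, 0, 0, config$gap_width)
        next
      }
      kind <- sse_row(ch, slot)$kind
      len <- glyph_length(ch, slot, config)
      if (is_ref) {
        add(tk, ch$source_id, cc - 1L, slot, kind,
            anchors[cc], ty, 0, 0, 0, len)
      } else {
        ref_slot <- ref_g$slots[cc]
        if (!is.na(ref_slot)) {
          rax <- sse_axis(ref, ref_slot)
          oax <- sse_axis(ch, slot)
          ang <- if (rax$defined && oax$defined) {
            glyph_angle(rax, oax, config$angle_mode)
          } else 0
          sh <- glyph_shift(ref, ref_slot, ch, slot, config)
          add(tk, ch$source_id, cc - 1L, slot, kind,
              anchors[cc] + sh[1L], ty + sh[2L], ang, sh[1L], sh[2L], len)
        } else {
          add(tk, ch$source_id, cc - 1L, slot, kind,
              anchors[cc], ty, 0, 0, 0, len)
        }
      }
      # coil connector after this bead (own chain's tiling)
      k <- match(slot, ch$sses$sse_id)
      if (!is.na(k) && k < nrow(ch$sses) && ch$sses$kind[k + 1L] == "COIL" &&
          cc < ncol_) {
        cid <- ch$sses$sse_id[k + 1L]
        add(tk, ch$source_id, NA_integer_, cid, "COIL",
            anchors[cc] + widths[cc], ty, 0, 0, 0,
            glyph_length(ch, cid, config))
      }
      prev_bead <- slot
    }
  }
  glyphs <- do.call(rbind, glyphs)
  rownames(glyphs) <- NULL

  nav <- build_nav(col_align)

  if (!is.null(range)) {
    keep <- is.na(glyphs$column) | (glyphs$column >= range[1L] &
                                      glyphs$column < range[2L])
    glyphs <- glyphs[keep, , drop = FALSE]
    rownames(glyphs) <- NULL
  }

  structure(list(glyphs = glyphs, nav = nav, anchors = anchors,
                 widths = widths, mode = mode,
                 range = range %||% c(0L, ncol_), config = config),
            class = "Scene")
}

# Navigation strip: per chain, runs of chain/gap columns partitioning
# [0, column_count); polymer breaks are zero-width markers at the column of
# the first bead after the break.
build_nav <- function(col_align) {
  ncol_ <- column_count(col_align)
  out <- list()
  for (tk in seq_along(col_align$gapped)) {
    g <- col_align$gapped[[tk]]
    kinds <- ifelse(is.na(g$slots), "gap", "chain")
    r <- rle(kinds)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    out[[length(out) + 1L]] <- data.frame(
      track = tk,
      source_id = if (is.null(g$chain)) "sse-seq" else g$chain$source_id,
      kind = r$values, from = starts, to = ends, stringsAsFactors = FALSE)
    ch <- g$chain
    if (!is.null(ch) && length(ch$segment_breaks)) {
      for (br in ch$segment_breaks) {
        after <- which(!is.na(g$slots) &
                         vapply(g$slots, function(s) {
                           !is.na(s) && sse_row(ch, s)$start >= br
                         }, logical(1)))
        col <- if (length(after)) after[1L] - 1L else ncol_
        out[[length(out) + 1L]] <- data.frame(
          track = tk, source_id = ch$source_id, kind = "break",
          from = col, to = col, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.Scene <- function(x, ...) {
  cat(sprintf("Scene (%s): %d glyphs, %d tracks, columns [%d, %d)\n",
              x$mode, nrow(x$glyphs), length(unique(x$glyphs$track)),
              x$range[1L], x$range[2L]))
  invisible(x)
}

#' Serialize a scene to JSON
#'
#' Full glyph geometry plus navigation strip, for inspection and testing.
#'
#' @param scene A `Scene`.
#' @return JSON text.
#' @export
scene_to_json <- function(scene) {
  jsonlite::toJSON(
    list(mode = scene$mode,
         range = as.integer(scene$range),
         anchors = scene$anchors,
         glyphs = scene$glyphs,
         nav = scene$nav),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
}
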