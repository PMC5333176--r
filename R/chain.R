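# Secondary-structure kinds used throughout the package.
SSE_KINDS <- c("HELIX", "SHEET", "COIL")

#' Construct a protein chain
#'
#' A `ProteinChain` is the unit of comparison: an ordered list of residues
#' (CA coordinates only) completely tiled by secondary-structure elements
#' (SSEs). Helices and strands are the "beads" that take part in alignment
#' and glyph layout; coil runs fill every position between them.
#'
#' @param source_id Label for the structure the chain came from (PDB id,
#'   frame label, generator tag).
#' @param chain_id Chain identifier; concatenated multi-chain proteins get a
#'   compound id such as `"A+B"`.
#' @param residues `data.frame` with columns `res_id` (author residue number
#'   with insertion code, as character), `name` (3-letter code) and
#'   optionally `chain` (per-residue author chain id).
#' @param ca Numeric matrix, one row per residue, columns x/y/z in Angstrom.
#' @param sses `data.frame` with columns `kind` (`"HELIX"`, `"SHEET"`,
#'   `"COIL"`), `start`, `end` (0-based inclusive residue indices) and
#'   optionally `sse_id`; must tile `0:(n-1)` without gaps or overlap. If
#'   `NULL`, the whole chain becomes one coil.
#' @param segment_breaks Integer vector of residue indices at which the
#'   polymer is discontinuous (the break lies *before* each listed index).
#' @return An object of class `ProteinChain`.
#' @export
protein_chain <- function(source_id, chain_id, residues, ca,
                          sses = NULL, segment_breaks = integer()) {
  ca <- as.matrix(ca)
  storage.mode(ca) <- "double"
  dimnames(ca) <- NULL
  n <- nrow(ca)
  if (n == 0L) stop("empty structure: chain has no residues")
  if (ncol(ca) != 3L || any(!is.finite(ca))) {
    stop("ca must be an n x 3 matrix of finite coordinates")
  }
  residues <- as.data.frame(residues, stringsAsFactors = FALSE)
  if (nrow(residues) != n) stop("residues and ca disagree on residue count")
  if (is.null(residues$chain)) residues$chain <- chain_id
  residues$res_id <- as.character(residues$res_id)
  residues$seq_index <- seq_len(n) - 1L
  rownames(residues) <- NULL

  if (is.null(sses)) {
    sses <- data.frame(kind = "COIL", start = 0L, end = n - 1L,
                       stringsAsFactors = FALSE)
  }
  sses <- normalize_sses(sses, n)
  segment_breaks <- sort(unique(as.integer(segment_breaks)))
  if (any(segment_breaks < 1L | segment_breaks > n - 1L)) {
    stop("segment_breaks must lie strictly inside the residue index range")
  }
  structure(
    list(source_id = as.character(source_id),
         chain_id = as.character(chain_id),
         residues = residues, ca = ca, sses = sses,
         segment_breaks = segment_breaks),
    class = "ProteinChain")
}

# Validate, sort, coil-fill and label an SSE table so that it tiles 0:(n-1).
normalize_sses <- function(sses, n) {
  sses <- as.data.frame(sses, stringsAsFactors = FALSE)
  sses$kind <- toupper(as.character(sses$kind))
  if (!all(sses$kind %in% SSE_KINDS)) {
    stop("unknown SSE kind: ", paste(setdiff(sses$kind, SSE_KINDS), collapse = ", "))
  }
  sses$start <- as.integer(sses$start)
  sses$end <- as.integer(sses$end)
  if (any(sses$start > sses$end)) stop("SSE with start > end")
  if (any(sses$start < 0L) || any(sses$end > n - 1L)) {
    stop("SSE indices outside residue range")
  }
  sses <- sses[order(sses$start), , drop = FALSE]
  # overlap check on the explicit records
  if (nrow(sses) > 1L &&
      any(sses$start[-1L] <= sses$end[-nrow(sses)])) {
    stop("overlapping SSEs")
  }
  # fill uncovered stretches with coil
  filled <- list()
  cursor <- 0L
  for (k in seq_len(nrow(sses))) {
    if (sses$start[k] > cursor) {
      filled[[length(filled) + 1L]] <-
        data.frame(kind = "COIL", start = cursor, end = sses$start[k] - 1L,
                   stringsAsFactors = FALSE)
    }
    filled[[length(filled) + 1L]] <- sses[k, c("kind", "start", "end")]
    cursor <- sses$end[k] + 1L
  }
  if (cursor <= n - 1L) {
    filled[[length(filled) + 1L]] <-
      data.frame(kind = "COIL", start = cursor, end = n - 1L,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  # merge adjacent coil runs (they arise from coil filling and from bead
  # deletion); adjacent helices/sheets stay separate elements
  if (nrow(out) > 1L) {
    merged <- out[1L, , drop = FALSE]
    for (k in 2L:nrow(out)) {
      last <- nrow(merged)
      if (out$kind[k] == "COIL" && merged$kind[last] == "COIL" &&
          out$start[k] == merged$end[last] + 1L) {
        merged$end[last] <- out$end[k]
      } else {
        merged <- rbind(merged, out[k, , drop = FALSE])
      }
    }
    out <- merged
    rownames(out) <- NULL
  }
  if (sum(out$end - out$start + 1L) != n) stop("SSEs do not tile the chain")
  prefix <- c(HELIX = "H", SHEET = "E", COIL = "C")[out$kind]
  counts <- stats::ave(seq_len(nrow(out)), out$kind, FUN = seq_along)
  out$sse_id <- paste0(prefix, counts)
  out[, c("sse_id", "kind", "start", "end")]
}

#' @export
print.ProteinChain <- function(x, ...) {
  beads <- x$sses[x$sses$kind != "COIL", , drop = FALSE]
  cat(sprintf("ProteinChain %s/%s: %d residues, %d SSEs (%d helix/sheet)\n",
              x$source_id, x$chain_id, nrow(x$ca), nrow(x$sses), nrow(beads)))
  if (length(x$segment_breaks)) {
    cat("  segment breaks at:", paste(x$segment_breaks, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of residues in a chain
#' @param chain A `ProteinChain`.
#' @return Integer residue count.
#' @export
n_residues <- function(chain) nrow(chain$ca)

#' Helix/sheet elements of a chain
#'
#' Returns the SSE table restricted to HELIX and SHEET rows ("beads"), the
#' only elements that take part in correspondence and gap alignment.
#'
#' @param chain A `ProteinChain`.
#' @return `data.frame` subset of `chain$sses`.
#' @export
chain_beads <- function(chain) {
  out <- chain$sses[chain$sses$kind != "COIL", , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Look up one SSE row by id; errors if absent.
sse_row <- function(chain, sse_id) {
  k <- match(sse_id, chain$sses$sse_id)
  if (is.na(k)) stop("no SSE with id '", sse_id, "' in chain ", chain$source_id)
  chain$sses[k, , drop = FALSE]
}

# Residue indices (1-based row numbers into chain$ca) of one SSE.
sse_rows_idx <- function(chain, sse_id) {
  r <- sse_row(chain, sse_id)
  (r$start:r$end) + 1L
}

#' Construct a trajectory
#'
#' A `Trajectory` is an ordered set of frames of the *same* chain: identical
#' residue counts and author residue ids, while SSE tilings may differ from
#' frame to frame (helix ends fray, short elements vanish).
#'
#' @param frames List of `ProteinChain` objects.
#' @param frame_labels Optional character labels, defaults to the frames'
#'   `source_id`s.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(frames, frame_labels = NULL) {
  if (length(frames) < 1L) stop("trajectory needs at least one frame")
  n <- n_residues(frames[[1L]])
  ids <- frames[[1L]]$residues$res_id
  for (f in seq_along(frames)) {
    if (n_residues(frames[[f]]) != n ||
        !identical(frames[[f]]$residues$res_id, ids)) {
      stop("inconsistent residue numbering: frame ", f,
           " does not match frame 1")
    }
  }
  if (is.null(frame_labels)) {
    frame_labels <- vapply(frames, function(x) x$source_id, character(1))
  }
  structure(list(frames = frames, frame_labels = as.character(frame_labels)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d residues\n",
              length(x$frames), n_residues(x$frames[[1L]])))
  invisible(x)
}

# Replace a chain's SSE tiling from a per-residue kind vector.
retile_chain <- function(chain, kinds) {
  stopifnot(length(kinds) == n_residues(chain))
  runs <- rle(kinds)
  end <- cumsum(runs$lengths)
  start <- end - runs$lengths + 1L
  sses <- data.frame(kind = runs$values, start = start - 1L, end = end - 1L,
                     stringsAsFactors = FALSE)
  chain$sses <- normalize_sses(sses, n_residues(chain))
  chain
}

# Per-residue kind vector from a chain's SSE tiling.
residue_kinds <- function(chain) {
  kinds <- character(n_residues(chain))
  for (k in seq_len(nrow(chain$sses))) {
    kinds[(chain$sses$start[k]:chain$sses$end[k]) + 1L] <- chain$sses$kind[k]
  }
  kinds
}
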