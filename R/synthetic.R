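# Ideal-geometry constants (textbook stereochemistry). These shape fixtures
# only, never the algorithms.
HELIX_RISE <- 1.5        # A per residue along the helix axis
HELIX_TWIST <- 100       # degrees per residue
HELIX_RADIUS <- 2.3      # A, CA distance from the axis
STRAND_RISE <- 3.5       # A per residue for an extended strand
COIL_RISE <- 3.0         # A per residue for connector coils
BLOCK_SPACING <- 3.8     # A between consecutive blocks

#' Specify a synthetic chain
#'
#' @param blocks Either a `data.frame` with columns `kind`, `n` or a compact
#'   string such as `"C2 H10 C3 E5 C2"` (kind letter H/E/C + residue count).
#' @param origin 3D origin of the first residue.
#' @param seed Integer seed recorded on the spec (generation itself is
#'   deterministic; the seed feeds perturbation noise).
#' @return A `ChainSpec` list.
#' @export
chain_spec <- function(blocks, origin = c(0, 0, 0), seed = 1L) {
  if (is.character(blocks)) {
    toks <- strsplit(trimws(blocks), "[ ,]+")[[1L]]
    kind <- c(H = "HELIX", E = "SHEET", C = "COIL")[substr(toks, 1L, 1L)]
    n <- as.integer(substring(toks, 2L))
    if (anyNA(kind) || anyNA(n)) stop("cannot parse block string: ", blocks)
    blocks <- data.frame(kind = unname(kind), n = n, stringsAsFactors = FALSE)
  }
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  if (any(blocks$n < 1L)) stop("every block needs at least 1 residue")
  structure(list(blocks = blocks, origin = as.numeric(origin),
                 seed = as.integer(seed)),
            class = "ChainSpec")
}

#' Build an ideal synthetic chain
#'
#' Helices are ideal alpha-helical CA traces (rise 1.5 A/residue, 100
#' degrees/residue twist, radius 2.3 A), strands extended traces (3.5
#' A/residue with a small alternating pleat), coils gently waved connectors
#' (3.0 A/residue). Blocks are laid out left to right along +x with a fixed
#' inter-block spacing; construction is fully deterministic.
#'
#' @param spec A [chain_spec()].
#' @param source_id Label for the chain.
#' @return A `ProteinChain` whose SSE tiling matches the blocks.
#' @export
build_chain <- function(spec, source_id = "synthetic") {
  blocks <- spec$blocks
  coords <- list()
  sses <- list()
  cursor <- 0
  res_at <- 0L
  for (k in seq_len(nrow(blocks))) {
    n <- blocks$n[k]
    kind <- blocks$kind[k]
    i <- seq_len(n) - 1L
    local <- switch(kind,
      HELIX = cbind(HELIX_RISE * i,
                    HELIX_RADIUS * cos(i * HELIX_TWIST * pi / 180),
                    HELIX_RADIUS * sin(i * HELIX_TWIST * pi / 180)),
      SHEET = cbind(STRAND_RISE * i, 0.9 * (-1)^i, rep(0, n)),
      COIL = cbind(COIL_RISE * i, 1.1 * sin(i * 0.9), 0.7 * cos(i * 1.3)))
    local[, 1L] <- local[, 1L] + cursor
    coords[[k]] <- local
    sses[[k]] <- data.frame(kind = kind, start = res_at, end = res_at + n - 1L,
                            stringsAsFactors = FALSE)
    cursor <- cursor + switch(kind, HELIX = HELIX_RISE, SHEET = STRAND_RISE,
                              COIL = COIL_RISE) * (n - 1L) + BLOCK_SPACING
    res_at <- res_at + n
  }
  ca <- do.call(rbind, coords)
  ca <- sweep(ca, 2L, spec$origin, "+")
  n_total <- nrow(ca)
  protein_chain(source_id = source_id, chain_id = "A",
                residues = data.frame(res_id = as.character(seq_len(n_total)),
                                      name = "ALA", chain = "A",
                                      stringsAsFactors = FALSE),
                ca = ca, sses = do.call(rbind, sses))
}

# Rotation matrix for angle theta (degrees) about unit axis.
rotation_about <- function(theta_deg, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  K <- matrix(c(0, -axis[3L], axis[2L],
                axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

#' Perturb a synthetic chain with known ground truth
#'
#' Applies rigid per-SSE rotations/translations, optional isotropic Gaussian
#' coordinate noise, and SSE deletions (the deleted element's residues are
#' relabelled coil, producing a missing-counterpart case). The perturbation
#' actually applied is attached as `attr(, "ground_truth")` so tests can
#' close the loop from construction to recovered layout parameters.
#'
#' Rotations pivot about the SSE *centroid* by default: the 2D shift read
#' off by the layout is centroid-based, so a centroid pivot keeps "rotate by
#' theta, shift by (a, b)" exactly recoverable as two independent
#' parameters. `pivot = "start"` is available for hinge-like motions.
#'
#' @param chain A `ProteinChain`.
#' @param rotations Named list: `sse_id -> list(theta, axis, pivot)` with
#'   `theta` in degrees, `axis` a 3-vector (default world z), `pivot`
#'   `"centroid"` (default) or `"start"`.
#' @param translations Named list: `sse_id -> 3-vector` in Angstrom, or
#'   `sse_id -> list(along, across)` interpreted in the element's local
#'   frame (see [glyph_shift()]).
#' @param sigma Standard deviation (A) of iid Gaussian noise added to every
#'   CA coordinate.
#' @param delete Character vector of sse ids to relabel as coil.
#' @param seed Integer seed for the noise.
#' @return The perturbed `ProteinChain` with a `ground_truth` attribute
#'   (list with `rotations`, `translations`, `sigma`, `deleted`).
#' @export
perturb <- function(chain, rotations = list(), translations = list(),
                    sigma = 0, delete = character(), seed = 1L) {
  out <- chain
  for (id in names(rotations)) {
    rot <- rotations[[id]]
    theta <- rot$theta %||% rot[[1L]]
    axis <- rot$axis %||% c(0, 0, 1)
    pivot_kind <- rot$pivot %||% "centroid"
    idx <- sse_rows_idx(out, id)
    pivot <- if (pivot_kind == "start") out$ca[idx[1L], ] else
      colMeans(out$ca[idx, , drop = FALSE])
    R <- rotation_about(theta, axis)
    out$ca[idx, ] <- sweep(sweep(out$ca[idx, , drop = FALSE], 2L, pivot) %*%
                             t(R), 2L, pivot, "+")
  }
  for (id in names(translations)) {
    tr <- translations[[id]]
    idx <- sse_rows_idx(out, id)
    d <- if (is.list(tr)) {
      fr <- ref_local_frame(sse_axis(chain, id))
      tr$along * fr$x + tr$across * fr$y
    } else as.numeric(tr)
    out$ca[idx, ] <- sweep(out$ca[idx, , drop = FALSE], 2L, d, "+")
  }
  if (sigma > 0) {
    set.seed(seed)
    out$ca <- out$ca + matrix(stats::rnorm(length(out$ca), 0, sigma),
                              nrow = nrow(out$ca))
  }
  if (length(delete)) {
    kinds <- residue_kinds(out)
    for (id in delete) {
      idx <- sse_rows_idx(chain, id)
      kinds[idx] <- "COIL"
    }
    out <- retile_chain(out, kinds)
  }
  attr(out, "ground_truth") <- list(rotations = rotations,
                                    translations = translations,
                                    sigma = sigma, deleted = delete)
  out
}

#' Generate a synthetic trajectory
#'
#' Frame f applies to each flexible element an independent rotation drawn
#' uniformly in +/- its amplitude (about the element centroid, axis z), and
#' each droppable short element vanishes (is relabelled coil) independently
#' with its stated probability. All frames share residue numbering; the
#' realized per-frame draws are attached as `attr(, "ground_truth")`.
#'
#' @param chain Base `ProteinChain`.
#' @param n_frames Number of frames (>= 2).
#' @param flexibility Named numeric vector: `sse_id -> angular amplitude`
#'   in degrees.
#' @param p_drop Named numeric vector: `sse_id -> per-frame disappearance
#'   probability`.
#' @param seed Integer seed.
#' @return A `Trajectory` with ground-truth attribute (list with `angles`
#'   (frames x flexible SSEs matrix) and `dropped` (frames x droppable SSEs
#'   logical matrix)).
#' @export
make_trajectory <- function(chain, n_frames, flexibility = numeric(),
                            p_drop = numeric(), seed = 1L) {
  if (n_frames < 2L) stop("a trajectory needs at least 2 frames")
  set.seed(seed)
  flex_ids <- names(flexibility)
  drop_ids <- names(p_drop)
  angles <- matrix(0, n_frames, length(flex_ids),
                   dimnames = list(NULL, flex_ids))
  dropped <- matrix(FALSE, n_frames, length(drop_ids),
                    dimnames = list(NULL, drop_ids))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    rots <- list()
    for (id in flex_ids) {
      a <- stats::runif(1L, -flexibility[[id]], flexibility[[id]])
      angles[f, id] <- a
      rots[[id]] <- list(theta = a)
    }
    del <- character(0)
    for (id in drop_ids) {
      if (stats::runif(1L) < p_drop[[id]]) {
        dropped[f, id] <- TRUE
        del <- c(del, id)
      }
    }
    fr <- perturb(chain, rotations = rots, delete = del, sigma = 0)
    attr(fr, "ground_truth") <- NULL
    fr$source_id <- sprintf("%s#%d", chain$source_id, f)
    frames[[f]] <- fr
  }
  tr <- trajectory(frames, sprintf("t%d", seq_len(n_frames)))
  attr(tr, "ground_truth") <- list(angles = angles, dropped = dropped)
  tr
}

#' Worked greedy-step instance (two chains, crossing correspondence)
#'
#' The canonical worked example for one greedy step: the tails of two
#' chains, A = (sheet j, sheet x, helix y, helix m) and B = (helix s,
#' sheet t), where spatially j pairs with t and m pairs with s (the
#' correspondence crosses). Searching A to B for j skips one element
#' (n_gap = 1); searching B to A for s skips three (m_gap = 3); the greedy
#' step therefore inserts one gap into A before j, opposite s. Synthetic
#' centroids are provided so that these pairs are the unique nearest
#' same-kind matches.
#'
#' @return List with `a`, `b` (bead tables with `sse_id`, `kind`, `cx`
#'   centroid x; centroids lie on the x axis) and `corr` (a
#'   `CorrespondenceMap`).
#' @export
fig9_instance <- function() {
  a <- data.frame(sse_id = c("j", "x", "y", "m"),
                  kind = c("SHEET", "SHEET", "HELIX", "HELIX"),
                  cx = c(10, 50, 60, 30), stringsAsFactors = FALSE)
  b <- data.frame(sse_id = c("s", "t"),
                  kind = c("HELIX", "SHEET"),
                  cx = c(29.5, 10.5), stringsAsFactors = FALSE)
  corr <- new_correspondence(data.frame(
    ref_sse = c("j", "m"), other_sse = c("t", "s"),
    dist = c(0.5, 0.5), stringsAsFactors = FALSE))
  list(a = a, b = b, corr = corr)
}

#' Ambiguous instance where the greedy aligner inserts unnecessary gaps
#'
#' Two same-type candidates lie (near-)equidistant from an element of the
#' other chain while the suffixes differ, so the spatially nearest
#' correspondence crosses; the greedy walk then commits to the locally
#' cheapest pair and pays for it later with redundant gaps, while the
#' dynamic program does not. On this instance greedy inserts 6 gaps, the
#' optimum is 4.
#'
#' @return List with `a`, `b` (bead tables) and `corr` (crossing
#'   `CorrespondenceMap`).
#' @export
fig10_instance <- function() {
  a <- data.frame(sse_id = c("a1", "x1", "x2", "a2", "a3"),
                  kind = "HELIX",
                  cx = c(0, 200, 210, 100, 110), stringsAsFactors = FALSE)
  b <- data.frame(sse_id = c("b1", "b2", "b3"),
                  kind = "HELIX",
                  cx = c(100.4, 110.4, 0.4), stringsAsFactors = FALSE)
  corr <- new_correspondence(data.frame(
    ref_sse = c("a1", "a2", "a3"), other_sse = c("b3", "b1", "b2"),
    dist = c(0.4, 0.4, 0.4), stringsAsFactors = FALSE))
  list(a = a, b = b, corr = corr)
}
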