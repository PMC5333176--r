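# A gapped chain: the chain's helix/sheet elements in order, interleaved
# with GAP slots (NA) so that corresponding elements share columns with the
# partner chain(s). Coils are never gapped or matched; they are drawn as
# connectors between bead columns.
new_gapped_chain <- function(chain, slots) {
  structure(list(chain = chain, slots = as.character(slots)),
            class = "GappedChain")
}

#' @export
print.GappedChain <- function(x, ...) {
  cat(sprintf("GappedChain %s: [%s]\n",
              if (is.null(x$chain)) "<sse-seq>" else x$chain$source_id,
              paste(ifelse(is.na(x$slots), "-", x$slots), collapse = " ")))
  invisible(x)
}

#' Number of columns of a gapped chain or column alignment
#' @param x A `GappedChain` or `ColumnAlignment`.
#' @return Integer column count.
#' @export
column_count <- function(x) {
  if (inherits(x, "ColumnAlignment")) return(length(x$gapped[[1L]]$slots))
  length(x$slots)
}

#' Remove GAP slots
#' @param x A `GappedChain`.
#' @return Character vector of sse ids in original order.
#' @export
strip_gaps <- function(x) x$slots[!is.na(x$slots)]

#' Count GAP slots of a gapped chain
#' @param x A `GappedChain`.
#' @return Integer.
#' @export
gap_count <- function(x) sum(is.na(x$slots))

# Accept a ProteinChain or a bead table (data.frame with sse_id, kind).
as_bead_table <- function(x) {
  if (inherits(x, "ProteinChain")) return(chain_beads(x))
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(df$sse_id) || is.null(df$kind)) {
    stop("SSE sequence needs sse_id and kind columns")
  }
  df
}

#' Greedy pairwise gap insertion
#'
#' The core column-building step: walks two bead sequences with one pointer
#' each, starting before the first element. Each step searches forward for
#' the counterpart of A's next element among B's remaining elements
#' (counting the `n_gap` elements of B that would have to be skipped) and
#' symmetrically for B's next element in A (`m_gap`). The cheaper search
#' wins: its skip count of gap slots is inserted into the *other* chain just
#' before the current element (each skipped element gets its own column
#' opposite a GAP), the found pair is placed in a shared column, and both
#' pointers advance past it. Ties (`n_gap == m_gap`) insert into A. An
#' element with no reachable counterpart occupies a fresh column opposite a
#' GAP and its pointer advances by one. When one sequence is exhausted the
#' other's remaining elements are matched against trailing GAP slots.
#'
#' Greedy means locally cheapest: with a non-crossing correspondence the
#' result is gap-optimal, but when the correspondence crosses (two plausible
#' nearest candidates, cf. [fig10_instance()]) the algorithm can insert
#' unnecessary gaps; [optimal_pair()] is the exact reference.
#'
#' @param A,B `ProteinChain`s or bead tables (`data.frame` with `sse_id`,
#'   `kind`); A is the first-listed (reference-side) sequence.
#' @param corr `CorrespondenceMap` between A (ref side) and B (other side).
#' @return List with `a`, `b` (two `GappedChain`s of equal column count) and
#'   `decisions`, a `data.frame` with one row per step: `a_next`, `b_next`,
#'   `n_gap`, `m_gap` (NA when the search failed), `chosen_side`
#'   (`"A"`/`"B"`/`"none"`) and `gaps_inserted`.
#' @export
greedy_pair <- function(A, B, corr) {
  a <- as_bead_table(A)
  b <- as_bead_table(B)
  pairs <- corr$pairs
  if (nrow(pairs)) {
    bad <- !(pairs$ref_sse %in% a$sse_id) | !(pairs$other_sse %in% b$sse_id)
    if (any(bad)) stop("correspondence references unknown SSE ids")
    kk <- a$kind[match(pairs$ref_sse, a$sse_id)] !=
      b$kind[match(pairs$other_sse, b$sse_id)]
    if (any(kk)) stop("correspondence pairs elements of different kinds")
  }
  a2b <- stats::setNames(pairs$other_sse, pairs$ref_sse)
  b2a <- stats::setNames(pairs$ref_sse, pairs$other_sse)

  nA <- nrow(a); nB <- nrow(b)
  ia <- 1L; ib <- 1L
  slotsA <- character(0); slotsB <- character(0)
  dec <- list()
  push <- function(sa, sb) {
    slotsA <<- c(slotsA, sa)
    slotsB <<- c(slotsB, sb)
  }
  record <- function(a_next, b_next, n_gap, m_gap, side, gaps) {
    dec[[length(dec) + 1L]] <<- data.frame(
      a_next = a_next, b_next = b_next,
      n_gap = n_gap, m_gap = m_gap,
      chosen_side = side, gaps_inserted = gaps,
      stringsAsFactors = FALSE)
  }

  repeat {
    if (ia > nA && ib > nB) break
    if (ia > nA) {                        # fill end of A with gaps
      k <- nB - ib + 1L
      for (j in ib:nB) push(NA_character_, b$sse_id[j])
      record(NA_character_, b$sse_id[ib], NA_integer_, NA_integer_, "A", k)
      break
    }
    if (ib > nB) {                        # fill end of B with gaps
      k <- nA - ia + 1L
      for (i in ia:nA) push(a$sse_id[i], NA_character_)
      record(a$sse_id[ia], NA_character_, NA_integer_, NA_integer_, "B", k)
      break
    }
    # forward searches
    pa <- unname(a2b[a$sse_id[ia]])       # counterpart of A's next, in B
    n_gap <- NA_integer_
    if (!is.na(pa)) {
      pos <- match(pa, b$sse_id)
      if (pos >= ib) n_gap <- pos - ib
    }
    pb <- unname(b2a[b$sse_id[ib]])       # counterpart of B's next, in A
    m_gap <- NA_integer_
    if (!is.na(pb)) {
      pos <- match(pb, a$sse_id)
      if (pos >= ia) m_gap <- pos - ia
    }

    if (is.na(n_gap) && is.na(m_gap)) {
      # A's next is unmatched: fresh column opposite a gap in B
      push(a$sse_id[ia], NA_character_)
      record(a$sse_id[ia], b$sse_id[ib], NA_integer_, NA_integer_, "B", 1L)
      ia <- ia + 1L
    } else if (!is.na(n_gap) && (is.na(m_gap) || n_gap <= m_gap)) {
      # insert n_gap gaps into A, the skipped B elements keep their columns
      if (n_gap > 0L) for (j in ib:(ib + n_gap - 1L)) push(NA_character_, b$sse_id[j])
      push(a$sse_id[ia], b$sse_id[ib + n_gap])
      record(a$sse_id[ia], b$sse_id[ib],
             n_gap, m_gap,
             if (n_gap > 0L) "A" else "none", n_gap)
      ia <- ia + 1L
      ib <- ib + n_gap + 1L
    } else {
      # insert m_gap gaps into B, skipped A elements keep their columns
      if (m_gap > 0L) for (i in ia:(ia + m_gap - 1L)) push(a$sse_id[i], NA_character_)
      push(a$sse_id[ia + m_gap], b$sse_id[ib])
      record(a$sse_id[ia], b$sse_id[ib],
             n_gap, m_gap, "B", m_gap)
      ia <- ia + m_gap + 1L
      ib <- ib + 1L
    }
  }
  decisions <- if (length(dec)) do.call(rbind, dec) else
    data.frame(a_next = character(), b_next = character(),
               n_gap = integer(), m_gap = integer(),
               chosen_side = character(), gaps_inserted = integer(),
               stringsAsFactors = FALSE)
  list(a = new_gapped_chain(if (inherits(A, "ProteinChain")) A else NULL, slotsA),
       b = new_gapped_chain(if (inherits(B, "ProteinChain")) B else NULL, slotsB),
       decisions = decisions)
}

#' Gap-optimal pairwise alignment (dynamic programming oracle)
#'
#' Exact counterpart of [greedy_pair()]: minimizes the total number of
#' inserted GAP slots over all alignments in which a column may hold two
#' elements only if the correspondence pairs them. Since every realized pair
#' saves exactly two gaps, this is equivalent to realizing the largest
#' non-crossing subset of the correspondence. Ties are broken towards
#' matching early and placing gaps as far left as possible, so the output is
#' deterministic.
#'
#' @inheritParams greedy_pair
#' @return List with `a` and `b`, two `GappedChain`s of equal column count.
#' @export
optimal_pair <- function(A, B, corr) {
  a <- as_bead_table(A)
  b <- as_bead_table(B)
  pairs <- corr$pairs
  a2b <- stats::setNames(pairs$other_sse, pairs$ref_sse)
  nA <- nrow(a); nB <- nrow(b)
  # cost[i+1, j+1]: min gaps aligning a[1..i] with b[1..j]
  cost <- matrix(0L, nA + 1L, nB + 1L)
  move <- matrix(0L, nA + 1L, nB + 1L)   # 1 match, 2 gap-in-B (advance A), 3 gap-in-A (advance B)
  cost[, 1L] <- 0:nA
  cost[1L, ] <- 0:nB
  move[-1L, 1L] <- 2L
  move[1L, -1L] <- 3L
  for (i in seq_len(nA)) {
    partner <- unname(a2b[a$sse_id[i]])
    for (j in seq_len(nB)) {
      bc <- cost[i, j + 1L] + 1L; bm <- 2L
      if (cost[i + 1L, j] + 1L < bc) { bc <- cost[i + 1L, j] + 1L; bm <- 3L }
      if (!is.na(partner) && partner == b$sse_id[j] && cost[i, j] <= bc) {
        bc <- cost[i, j]; bm <- 1L
      }
      cost[i + 1L, j + 1L] <- bc
      move[i + 1L, j + 1L] <- bm
    }
  }
  i <- nA; j <- nB
  sa <- character(0); sb <- character(0)
  while (i > 0L || j > 0L) {
    mv <- move[i + 1L, j + 1L]
    if (mv == 1L) {
      sa <- c(a$sse_id[i], sa); sb <- c(b$sse_id[j], sb); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      sa <- c(a$sse_id[i], sa); sb <- c(NA_character_, sb); i <- i - 1L
    } else {
      sa <- c(NA_character_, sa); sb <- c(b$sse_id[j], sb); j <- j - 1L
    }
  }
  list(a = new_gapped_chain(if (inherits(A, "ProteinChain")) A else NULL, sa),
       b = new_gapped_chain(if (inherits(B, "ProteinChain")) B else NULL, sb))
}

#' Multi-chain column alignment against one reference
#'
#' The pairwise algorithm is reference-centric: each comparison chain is
#' greedy-paired with the reference independently, then the per-pair gap
#' positions in the reference are merged into one master column sequence (at
#' every inter-bead position the master carries the maximum number of gap
#' columns any pair needed there) and every chain is re-projected onto the
#' master columns. Corresponding elements end up in shared columns across
#' all chains.
#'
#' @param ref Reference `ProteinChain`.
#' @param others List of superposed `ProteinChain`s.
#' @param corrs List of `CorrespondenceMap`s, one per element of `others`,
#'   each against `ref`.
#' @return A `ColumnAlignment`: list with `gapped` (list of `GappedChain`,
#'   reference first), `ref_index = 1`, and `pair_results` (the raw
#'   [greedy_pair()] outputs, for logging).
#' @export
multi_align <- function(ref, others, corrs) {
  if (length(others) != length(corrs)) stop("need one correspondence per chain")
  rb <- chain_beads(ref)
  nR <- nrow(rb)
  results <- vector("list", length(others))
  # gaps_before[[c]][p+1]: gap columns pair c inserted before ref bead p+1
  gaps_before <- matrix(0L, nrow = length(others), ncol = nR + 1L)
  inserted <- vector("list", length(others))  # other-chain slots at each position
  for (c in seq_along(others)) {
    g <- greedy_pair(ref, others[[c]], corrs[[c]])
    results[[c]] <- g
    pos <- 0L
    ins <- vector("list", nR + 1L)
    for (k in seq_along(g$a$slots)) {
      if (is.na(g$a$slots[k])) {
        gaps_before[c, pos + 1L] <- gaps_before[c, pos + 1L] + 1L
        ins[[pos + 1L]] <- c(ins[[pos + 1L]], g$b$slots[k])
      } else {
        pos <- pos + 1L
      }
    }
    inserted[[c]] <- ins
  }
  master <- if (length(others)) apply(gaps_before, 2L, max) else rep(0L, nR + 1L)

  # project each chain onto master columns
  matched_slot <- function(g, bead_id) {
    k <- which(!is.na(g$a$slots) & g$a$slots == bead_id)
    g$b$slots[k]
  }
  gapped <- vector("list", length(others) + 1L)
  ref_slots <- character(0)
  for (p in 0:nR) {
    ref_slots <- c(ref_slots, rep(NA_character_, master[p + 1L]))
    if (p < nR) ref_slots <- c(ref_slots, rb$sse_id[p + 1L])
  }
  gapped[[1L]] <- new_gapped_chain(ref, ref_slots)
  for (c in seq_along(others)) {
    slots <- character(0)
    for (p in 0:nR) {
      own <- inserted[[c]][[p + 1L]]
      pad <- master[p + 1L] - length(own)
      slots <- c(slots, own, rep(NA_character_, pad))
      if (p < nR) slots <- c(slots, matched_slot(results[[c]], rb$sse_id[p + 1L]))
    }
    gapped[[c + 1L]] <- new_gapped_chain(others[[c]], slots)
  }
  structure(list(gapped = gapped, ref_index = 1L, pair_results = results),
            class = "ColumnAlignment")
}

#' @export
print.ColumnAlignment <- function(x, ...) {
  cat(sprintf("ColumnAlignment: %d chains x %d columns\n",
              length(x$gapped), column_count(x)))
  for (g in x$gapped) print(g)
  invisible(x)
}

#' Column alignment of molecular-dynamics frames via a union chain
#'
#' Frames of a trajectory share residue numbering, so elements are
#' identified across frames by overlap: same-kind elements whose residue
#' intervals share at least one position are the same aggregated element
#' (changes happen at SSE ends; very short elements may vanish entirely in
#' some frames). One artificial chain holding one representative per
#' aggregated element, ordered by residue position, is built, every frame is
#' greedy-paired against it (receiving a GAP wherever the artificial chain
#' has an element the frame lacks), and the artificial chain is dropped from
#' the result.
#'
#' @param traj A `Trajectory`.
#' @return A `ColumnAlignment` over the frames (first frame as reference),
#'   with the artificial chain available as `attr(, "union_chain")` (a bead
#'   table with columns `sse_id`, `kind`, `start`, `end`).
#' @export
md_union <- function(traj) {
  frames <- traj$frames
  beads <- lapply(frames, chain_beads)
  all <- do.call(rbind, Map(function(b, f) {
    if (nrow(b)) cbind(b, frame = f) else NULL
  }, beads, seq_along(frames)))
  if (is.null(all) || nrow(all) == 0L) stop("trajectory contains no helix/sheet elements")

  # union-find over same-kind, interval-overlapping elements
  parent <- seq_len(nrow(all))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(all) - 1L)) {
    for (j in (i + 1L):nrow(all)) {
      if (all$kind[i] == all$kind[j] &&
          all$start[i] <= all$end[j] && all$start[j] <= all$end[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(nrow(all)), find, integer(1))
  # a frame contributing two elements to one group keeps only the first;
  # later ones become singleton groups of their own
  for (g in unique(root)) {
    idx <- which(root == g)
    dupf <- idx[duplicated(all$frame[idx])]
    root[dupf] <- dupf
  }

  groups <- unique(root)
  gstart <- vapply(groups, function(g) min(all$start[root == g]), integer(1))
  gend <- vapply(groups, function(g) max(all$end[root == g]), integer(1))
  ord <- order(gstart, gend)
  groups <- groups[ord]
  union_tab <- data.frame(
    sse_id = paste0("U", seq_along(groups)),
    kind = all$kind[groups],
    start = gstart[ord], end = gend[ord],
    stringsAsFactors = FALSE)

  gapped <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    idx <- which(all$frame == f)
    pairs <- data.frame(
      ref_sse = union_tab$sse_id[match(root[idx], groups)],
      other_sse = all$sse_id[idx],
      stringsAsFactors = FALSE)
    pairs <- pairs[!is.na(pairs$ref_sse), , drop = FALSE]
    g <- greedy_pair(union_tab, frames[[f]], new_correspondence(pairs))
    gapped[[f]] <- g$b
  }
  structure(list(gapped = gapped, ref_index = 1L, pair_results = NULL),
            class = "ColumnAlignment",
            union_chain = union_tab)
}

#' Export a column alignment as a TSV matrix
#'
#' Rows are chains, columns are alignment columns, cells hold the sse id or
#' `"-"` for a GAP.
#'
#' @param ca A `ColumnAlignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_columns_tsv <- function(ca, path) {
  rows <- vapply(ca$gapped, function(g) {
    paste(ifelse(is.na(g$slots), "-", g$slots), collapse = "\t")
  }, character(1))
  labels <- vapply(ca$gapped, function(g) {
    if (is.null(g$chain)) "sse-seq" else g$chain$source_id
  }, character(1))
  header <- paste(c("chain", paste0("col", seq_len(column_count(ca)))),
                  collapse = "\t")
  writeLines(c(header, paste(labels, rows, sep = "\t")), path)
  invisible(path)
}
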