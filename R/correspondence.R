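#' Centroid of a secondary-structure element
#'
#' Arithmetic mean of the CA coordinates of the element's residues, the
#' reference point used for spatial SSE matching.
#'
#' @param chain A `ProteinChain`.
#' @param sse_id Id of one of its SSEs.
#' @return Numeric length-3 point.
#' @export
sse_centroid <- function(chain, sse_id) {
  colMeans(chain$ca[sse_rows_idx(chain, sse_id), , drop = FALSE])
}

# Centroid matrix for a bead table.
bead_centroids <- function(chain, beads = chain_beads(chain)) {
  t(vapply(beads$sse_id, function(id) sse_centroid(chain, id), numeric(3)))
}

#' Match secondary-structure elements between superposed chains
#'
#' Decides which helices/strands of `other` correspond to which of `ref`,
#' from spatial distance and type: among same-kind pairs whose centroid
#' distance does not exceed `max_dist`, the order-consistent (non-crossing)
#' matching with the largest number of pairs, and among those the smallest
#' total centroid distance, is found by dynamic programming over the two
#' bead sequences. Coils never take part.
#'
#' `other` must already be superposed onto `ref`; distances are measured in
#' the shared frame.
#'
#' @param ref Reference `ProteinChain`.
#' @param other Superposed `ProteinChain`.
#' @param max_dist Distance cutoff in Angstrom beyond which two elements are
#'   never considered the same (default 8).
#' @return A `CorrespondenceMap`: list with `pairs` (`data.frame` of
#'   `ref_sse`, `other_sse`, `dist`, ordered along the reference) and
#'   `max_dist`.
#' @export
correspond <- function(ref, other, max_dist = 8) {
  br <- chain_beads(ref)
  bo <- chain_beads(other)
  n <- nrow(br)
  m <- nrow(bo)
  if (n == 0L || m == 0L) {
    return(new_correspondence(empty_pairs(), max_dist))
  }
  cr <- bead_centroids(ref, br)
  co <- bead_centroids(other, bo)
  d2 <- outer(rowSums(cr^2), rowSums(co^2), "+") - 2 * cr %*% t(co)
  dist <- sqrt(pmax(d2, 0))
  ok <- outer(br$kind, bo$kind, "==") & dist <= max_dist

  # DP maximizing (pairs, -total distance) lexicographically
  INF <- sum(dist) + 1
  np <- matrix(0L, n + 1L, m + 1L)
  cost <- matrix(0, n + 1L, m + 1L)
  move <- matrix(0L, n + 1L, m + 1L)     # 1 = match, 2 = skip ref, 3 = skip other
  for (i in seq_len(n)) move[i + 1L, 1L] <- 2L
  for (j in seq_len(m)) move[1L, j + 1L] <- 3L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # candidates: (pairs, cost, move)
      bp <- np[i, j + 1L]; bc <- cost[i, j + 1L]; bm <- 2L
      if (np[i + 1L, j] > bp ||
          (np[i + 1L, j] == bp && cost[i + 1L, j] < bc)) {
        bp <- np[i + 1L, j]; bc <- cost[i + 1L, j]; bm <- 3L
      }
      if (ok[i, j]) {
        mp <- np[i, j] + 1L
        mc <- cost[i, j] + dist[i, j]
        if (mp > bp || (mp == bp && mc < bc)) {
          bp <- mp; bc <- mc; bm <- 1L
        }
      }
      np[i + 1L, j + 1L] <- bp
      cost[i + 1L, j + 1L] <- bc
      move[i + 1L, j + 1L] <- bm
    }
  }
  i <- n; j <- m
  ri <- integer(0); oj <- integer(0)
  while (i > 0L || j > 0L) {
    mv <- move[i + 1L, j + 1L]
    if (mv == 1L) {
      ri <- c(i, ri); oj <- c(j, oj); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) i <- i - 1L else j <- j - 1L
  }
  pairs <- if (length(ri)) {
    data.frame(ref_sse = br$sse_id[ri], other_sse = bo$sse_id[oj],
               dist = dist[cbind(ri, oj)], stringsAsFactors = FALSE)
  } else empty_pairs()
  new_correspondence(pairs, max_dist)
}

empty_pairs <- function() {
  data.frame(ref_sse = character(), other_sse = character(),
             dist = numeric(), stringsAsFactors = FALSE)
}

#' Build a correspondence map from explicit pairs
#'
#' Low-level constructor used by the alignment machinery and by tests that
#' need a hand-specified (possibly crossing) correspondence, e.g. the
#' worked greedy examples.
#'
#' @param pairs `data.frame` with columns `ref_sse`, `other_sse` and
#'   optionally `dist`.
#' @param max_dist Threshold recorded on the map.
#' @return A `CorrespondenceMap`.
#' @export
new_correspondence <- function(pairs, max_dist = Inf) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    if (anyDuplicated(pairs$ref_sse) || anyDuplicated(pairs$other_sse)) {
      stop("correspondence must be injective in both coordinates")
    }
    if (is.null(pairs$dist)) pairs$dist <- NA_real_
  } else pairs <- empty_pairs()
  structure(list(pairs = pairs, max_dist = max_dist),
            class = "CorrespondenceMap")
}

#' @export
print.CorrespondenceMap <- function(x, ...) {
  cat(sprintf("CorrespondenceMap: %d pairs (max_dist = %g A)\n",
              nrow(x$pairs), x$max_dist))
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Export a correspondence map as TSV
#'
#' Columns `ref_sse_id`, `other_sse_id`, `distance_A`.
#'
#' @param corr A `CorrespondenceMap`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_correspondence_tsv <- function(corr, path) {
  df <- corr$pairs
  names(df) <- c("ref_sse_id", "other_sse_id", "distance_A")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
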