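# Fixtures and independent oracles, all built in code.

# -- PDB text ---------------------------------------------------------------

# Hand-formatted ATOM line (independent of write_pdb).
atom_line <- function(serial, resname, chain, resseq, x, y, z, icode = " ",
                      name = " CA ", altloc = " ") {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, name, altloc, resname, chain, resseq, icode, x, y, z)
}

helix_line <- function(serial, chain, from, to) {
  sprintf("HELIX  %3d %3s ALA %1s %4d  ALA %1s %4d  1%30s%6d",
          serial, sprintf("H%02d", serial), chain, from, chain, to, "",
          to - from + 1L)
}

sheet_line <- function(serial, chain, from, to) {
  sprintf("SHEET  %3d %3s 1 ALA %1s%4d  ALA %1s%4d  0",
          serial, sprintf("S%02d", serial), chain, from, chain, to)
}

# 5-residue single-chain PDB with an optional helix annotation.
mini_pdb <- function(helix = NULL, chain = "A") {
  atoms <- vapply(1:5, function(i) {
    atom_line(i, "ALA", chain, i, i * 3.8, (i %% 2) * 1.0, 0.3 * i)
  }, character(1))
  c(if (!is.null(helix)) helix_line(1L, chain, helix[1L], helix[2L]),
    atoms, "END")
}

# DSSP text for a chain: one row per residue, given one-letter codes.
dssp_text <- function(chain, codes) {
  if (length(codes) == 1L) codes <- strsplit(codes, "")[[1L]]
  hdr <- "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"
  rows <- vapply(seq_along(codes), function(i) {
    resseq <- suppressWarnings(as.integer(gsub("[^0-9-]", "",
                                               chain$residues$res_id[i])))
    sprintf("%5d%5d %1s %1s  %1s", i, resseq, chain$residues$chain[i],
            "A", codes[i])
  }, character(1))
  c("==== Secondary Structure Definition (synthetic fixture) ====", hdr, rows)
}

# -- random generators ------------------------------------------------------

random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# Random bead-sequence pair with a MONOTONE type-consistent correspondence
# (the regime where the greedy aligner is provably gap-optimal).
random_monotone_instance <- function(seed, max_n = 10L) {
  set.seed(seed)
  nA <- sample.int(max_n, 1L)
  nB <- sample.int(max_n, 1L)
  a <- data.frame(sse_id = paste0("a", seq_len(nA)),
                  kind = sample(c("HELIX", "SHEET"), nA, replace = TRUE),
                  stringsAsFactors = FALSE)
  b <- data.frame(sse_id = paste0("b", seq_len(nB)),
                  kind = sample(c("HELIX", "SHEET"), nB, replace = TRUE),
                  stringsAsFactors = FALSE)
  k <- sample.int(min(nA, nB) + 1L, 1L) - 1L
  ia <- sort(sample.int(nA, k))
  ib <- sort(sample.int(nB, k))
  keep <- a$kind[ia] == b$kind[ib]
  pairs <- data.frame(ref_sse = a$sse_id[ia[keep]],
                      other_sse = b$sse_id[ib[keep]],
                      stringsAsFactors = FALSE)
  list(a = a, b = b, corr = new_correspondence(pairs))
}

# Random instance with an arbitrary (possibly crossing) injective
# correspondence, for testing the optimal aligner against brute force.
random_crossing_instance <- function(seed, max_n = 8L) {
  set.seed(seed)
  nA <- sample.int(max_n, 1L)
  nB <- sample.int(max_n, 1L)
  a <- data.frame(sse_id = paste0("a", seq_len(nA)), kind = "HELIX",
                  stringsAsFactors = FALSE)
  b <- data.frame(sse_id = paste0("b", seq_len(nB)), kind = "HELIX",
                  stringsAsFactors = FALSE)
  k <- sample.int(min(nA, nB) + 1L, 1L) - 1L
  ia <- sample.int(nA, k)            # unsorted: crossings allowed
  ib <- sample.int(nB, k)
  pairs <- data.frame(ref_sse = a$sse_id[ia], other_sse = b$sse_id[ib],
                      stringsAsFactors = FALSE)
  list(a = a, b = b, corr = new_correspondence(pairs))
}

# -- independent oracles ----------------------------------------------------

# Exhaustive maximum non-crossing subset of a correspondence, as index
# pairs. Minimum total gaps of any alignment is nA + nB - 2 * max_k.
oracle_min_gaps <- function(a, b, corr) {
  if (nrow(corr$pairs) == 0L) return(nrow(a) + nrow(b))
  pi <- match(corr$pairs$ref_sse, a$sse_id)
  pj <- match(corr$pairs$other_sse, b$sse_id)
  np <- length(pi)
  best <- 0L
  for (mask in 0:(2^np - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1L)) > 0L)
    if (length(sel) <= best) next
    ii <- pi[sel]; jj <- pj[sel]
    ord <- order(ii)
    if (!is.unsorted(jj[ord], strictly = TRUE)) best <- length(sel)
  }
  nrow(a) + nrow(b) - 2L * best
}

# Exhaustive order-consistent matching between two bead tables maximizing
# pair count, then minimizing total centroid distance.
oracle_best_matching <- function(ref, other, max_dist) {
  br <- chain_beads(ref)
  bo <- chain_beads(other)
  cr <- t(vapply(br$sse_id, function(id) sse_centroid(ref, id), numeric(3)))
  co <- t(vapply(bo$sse_id, function(id) sse_centroid(other, id), numeric(3)))
  n <- nrow(br); m <- nrow(bo)
  best <- list(k = -1L, cost = Inf, pairs = NULL)
  recurse <- function(i, j, k, cost, acc) {
    if (i > n || j > m) {
      if (k > best$k || (k == best$k && cost < best$cost)) {
        best <<- list(k = k, cost = cost, pairs = acc)
      }
      return(invisible())
    }
    recurse(i + 1L, j, k, cost, acc)               # skip ref i
    recurse(i, j + 1L, k, cost, acc)               # skip other j
    d <- sqrt(sum((cr[i, ] - co[j, ])^2))
    if (br$kind[i] == bo$kind[j] && d <= max_dist) {
      recurse(i + 1L, j + 1L, k + 1L, cost + d,
              rbind(acc, c(i, j)))
    }
  }
  recurse(1L, 1L, 0L, 0, NULL)
  best
}

# -- misc -------------------------------------------------------------------

total_gaps <- function(res) gap_count(res$a) + gap_count(res$b)

full_self_corr <- function(chain) {
  beads <- chain_beads(chain)
  new_correspondence(data.frame(ref_sse = beads$sse_id,
                                other_sse = beads$sse_id,
                                stringsAsFactors = FALSE))
}

expect_tiles <- function(chain) {
  expect_equal(sum(chain$sses$end - chain$sses$start + 1L), n_residues(chain))
  expect_true(all(diff(chain$sses$start) > 0))
}
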