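test_that("greedy step reproduces the worked two-chain example", {
  f <- fig9_instance()
  g <- greedy_pair(f$a, f$b, f$corr)
  d1 <- g$decisions[1L, ]
  expect_equal(d1$n_gap, 1L)            # one element skipped in B to reach t
  expect_equal(d1$m_gap, 3L)            # three skipped in A to reach m
  expect_equal(d1$chosen_side, "A")     # one gap into A, before j
  expect_equal(d1$gaps_inserted, 1L)
  expect_equal(g$a$slots, c(NA, "j", "x", "y", "m"))
  expect_equal(g$b$slots, c("s", "t", NA, NA, NA))
  # the DP oracle inserts the same total on this instance
  o <- optimal_pair(f$a, f$b, f$corr)
  expect_equal(total_gaps(g), total_gaps(o))
})

test_that("identical chains align with zero gaps", {
  ch <- build_chain(chain_spec("C1 H6 C2 E4 C1 H5 C2"))
  g <- greedy_pair(ch, ch, full_self_corr(ch))
  expect_equal(total_gaps(g), 0L)
  expect_equal(column_count(g$a), nrow(chain_beads(ch)))
  expect_true(all(g$decisions$gaps_inserted == 0L))
})

test_that("trailing unmatched elements get end-fill gaps", {
  a <- data.frame(sse_id = c("h1", "e1", "h2", "h3"),
                  kind = c("HELIX", "SHEET", "HELIX", "HELIX"))
  b <- data.frame(sse_id = c("p1", "p2"), kind = c("HELIX", "SHEET"))
  corr <- new_correspondence(data.frame(ref_sse = c("h1", "e1"),
                                        other_sse = c("p1", "p2")))
  g <- greedy_pair(a, b, corr)
  expect_equal(g$b$slots, c("p1", "p2", NA, NA))
  expect_equal(gap_count(g$b), 2L)
  expect_equal(gap_count(g$a), 0L)
})

test_that("gapped chains preserve order and share columns (property)", {
  for (seed in 1:60) {
    inst <- random_monotone_instance(seed)
    g <- greedy_pair(inst$a, inst$b, inst$corr)
    expect_equal(strip_gaps(g$a), inst$a$sse_id, info = paste("seed", seed))
    expect_equal(strip_gaps(g$b), inst$b$sse_id, info = paste("seed", seed))
    expect_equal(column_count(g$a), column_count(g$b))
    # every correspondence pair ends up in a shared column
    for (k in seq_len(nrow(inst$corr$pairs))) {
      ca <- which(!is.na(g$a$slots) & g$a$slots == inst$corr$pairs$ref_sse[k])
      cb <- which(!is.na(g$b$slots) & g$b$slots == inst$corr$pairs$other_sse[k])
      expect_equal(ca, cb, info = paste("seed", seed, "pair", k))
    }
  }
})

test_that("greedy equals the optimum on monotone instances", {
  for (seed in 1:200) {
    inst <- random_monotone_instance(seed)
    g <- greedy_pair(inst$a, inst$b, inst$corr)
    o <- optimal_pair(inst$a, inst$b, inst$corr)
    expect_equal(total_gaps(g), total_gaps(o), info = paste("seed", seed))
  }
})

test_that("optimal_pair equals exhaustive search, greedy never beats it", {
  for (seed in 1:40) {
    inst <- random_crossing_instance(seed)
    o <- optimal_pair(inst$a, inst$b, inst$corr)
    expect_equal(total_gaps(o), oracle_min_gaps(inst$a, inst$b, inst$corr),
                 info = paste("seed", seed))
    expect_equal(strip_gaps(o$a), inst$a$sse_id)
    expect_equal(strip_gaps(o$b), inst$b$sse_id)
    g <- greedy_pair(inst$a, inst$b, inst$corr)
    expect_gte(total_gaps(g), total_gaps(o))
  }
})

test_that("the ambiguous-candidates instance defeats greedy but not the DP", {
  f <- fig10_instance()
  g <- greedy_pair(f$a, f$b, f$corr)
  o <- optimal_pair(f$a, f$b, f$corr)
  expect_gt(total_gaps(g), total_gaps(o))  # the documented greedy failure
  expect_equal(total_gaps(o), oracle_min_gaps(f$a, f$b, f$corr))
})

test_that("greedy rejects malformed correspondences", {
  a <- data.frame(sse_id = "h1", kind = "HELIX")
  b <- data.frame(sse_id = "e1", kind = "SHEET")
  expect_error(greedy_pair(a, b, new_correspondence(
    data.frame(ref_sse = "h1", other_sse = "e1"))), "different kinds")
  expect_error(greedy_pair(a, b, new_correspondence(
    data.frame(ref_sse = "h1", other_sse = "zz"))), "unknown SSE")
})

test_that("multi_align shares master columns across chains", {
  ref <- build_chain(chain_spec("C1 H6 C1 E4 C1 H5 C1 E4 C1 H6 C1"),
                     source_id = "ref")
  # two exact copies: no gaps anywhere
  ca0 <- multi_align(ref, list(ref, ref),
                     list(full_self_corr(ref), full_self_corr(ref)))
  expect_equal(column_count(ca0), nrow(chain_beads(ref)))
  expect_equal(sum(vapply(ca0$gapped, gap_count, integer(1))), 0L)

  # one chain missing the 3rd bead, another missing the 5th
  del3 <- perturb(ref, delete = "H2")    # 3rd bead
  del5 <- perturb(ref, delete = "H3")    # 5th bead
  del3$source_id <- "d3"; del5$source_id <- "d5"
  ca1 <- multi_align(ref, list(del3, del5),
                     list(correspond(ref, del3), correspond(ref, del5)))
  expect_equal(gap_count(ca1$gapped[[1L]]), 0L)
  expect_equal(which(is.na(ca1$gapped[[2L]]$slots)), 3L)
  expect_equal(which(is.na(ca1$gapped[[3L]]$slots)), 5L)

  # randomized deletions across 4 chains: every correspondence pair shares
  # its master column with the reference
  set.seed(99)
  beads <- chain_beads(ref)$sse_id
  others <- lapply(1:4, function(i) {
    x <- perturb(ref, delete = sample(beads, sample(0:2, 1L)))
    x$source_id <- paste0("c", i)
    x
  })
  corrs <- lapply(others, function(o) correspond(ref, o))
  ca2 <- multi_align(ref, others, corrs)
  refslots <- ca2$gapped[[1L]]$slots
  for (i in seq_along(others)) {
    gi <- ca2$gapped[[i + 1L]]$slots
    expect_equal(length(gi), length(refslots))
    for (k in seq_len(nrow(corrs[[i]]$pairs))) {
      expect_equal(which(!is.na(refslots) &
                           refslots == corrs[[i]]$pairs$ref_sse[k]),
                   which(!is.na(gi) & gi == corrs[[i]]$pairs$other_sse[k]))
    }
  }
})

test_that("multi_align allocates master gap columns for insertions", {
  ref <- build_chain(chain_spec("C1 H6 C1 E4 C1"), source_id = "ref")
  # an "insertion": the other chain has an extra helix the reference lacks
  other <- build_chain(chain_spec("C1 H6 C1 H5 C1 E4 C1"), source_id = "ins")
  # correspondence by construction: H1<->H1, E1<->E1 (other's H2 unmatched)
  corr <- new_correspondence(data.frame(ref_sse = c("H1", "E1"),
                                        other_sse = c("H1", "E1")))
  ca <- multi_align(ref, list(other), list(corr))
  expect_equal(column_count(ca), 3L)
  expect_equal(ca$gapped[[1L]]$slots, c("H1", NA, "E1"))
  expect_equal(ca$gapped[[2L]]$slots, c("H1", "H2", "E1"))
})

test_that("md_union aggregates per-interval elements across frames", {
  # base: three beads a (H), b (E), c (H); frames differ by deletion
  base <- build_chain(chain_spec("C1 H5 C2 E4 C2 H6 C1"), source_id = "md")
  f1 <- perturb(base, delete = "H2"); f1$source_id <- "f1"   # {a, b}
  f2 <- perturb(base, delete = "E1"); f2$source_id <- "f2"   # {a, c}
  f3 <- base; f3$source_id <- "f3"                           # {a, b, c}
  ca <- md_union(trajectory(list(f1, f2, f3)))
  uni <- attr(ca, "union_chain")
  expect_equal(nrow(uni), 3L)
  expect_equal(uni$kind, c("HELIX", "SHEET", "HELIX"))
  expect_equal(column_count(ca), 3L)
  expect_equal(is.na(ca$gapped[[1L]]$slots), c(FALSE, FALSE, TRUE))
  expect_equal(is.na(ca$gapped[[2L]]$slots), c(FALSE, TRUE, FALSE))
  expect_equal(is.na(ca$gapped[[3L]]$slots), c(FALSE, FALSE, FALSE))

  # identical frames: no gaps
  ca2 <- md_union(trajectory(list(f3, f3, f3)))
  expect_equal(sum(vapply(ca2$gapped, gap_count, integer(1))), 0L)
})

test_that("md_union tracks an intermittently vanishing short helix", {
  base <- build_chain(chain_spec("C2 H8 C2 H2 C2 E5 C2"), source_id = "md2")
  traj <- make_trajectory(base, 10L, p_drop = c(H2 = 0.5), seed = 123L)
  gt <- attr(traj, "ground_truth")
  ca <- md_union(traj)
  uni <- attr(ca, "union_chain")
  expect_equal(column_count(ca), 3L)
  # the short helix appears exactly once in the union chain
  h2 <- chain_beads(base)[2L, ]
  hits <- which(uni$kind == "HELIX" & uni$start <= h2$end & uni$end >= h2$start)
  expect_length(hits, 1L)
  col <- hits[1L]
  missing_frames <- which(gt$dropped[, "H2"])
  expect_gt(length(missing_frames), 0L)
  expect_lt(length(missing_frames), 10L)
  for (f in 1:10) {
    expect_equal(is.na(ca$gapped[[f]]$slots[col]), f %in% missing_frames,
                 info = paste("frame", f))
  }
})

test_that("column alignments export as a TSV matrix", {
  ref <- build_chain(chain_spec("C1 H6 C1 E4 C1"), source_id = "ref")
  del <- perturb(ref, delete = "E1"); del$source_id <- "del"
  ca <- multi_align(ref, list(del), list(correspond(ref, del)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_columns_tsv(ca, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(dim(tab), c(2L, 1L + column_count(ca)))
  expect_equal(tab$col2, c("E1", "-"))
})
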