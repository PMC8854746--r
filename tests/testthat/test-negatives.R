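test_that("random sampling excludes positives and is exhaustive when forced", {
  pos <- data.frame(lnc = c("L1", "L1", "L2"), prot = c("P1", "P2", "P1"),
                    stringsAsFactors = FALSE)
  out <- sample_random(c("L1", "L2"), c("P1", "P2"), pos, count = 1L,
                       seed = 1L)
  expect_equal(out, data.frame(lnc = "L2", prot = "P2",
                               stringsAsFactors = FALSE))
  expect_error(sample_random(c("L1", "L2"), c("P1", "P2"), pos, count = 2L),
               "only 1 candidate")
})

test_that("random sampling is deterministic and duplicate-free", {
  pos <- random_edges(10, 10, 30, seed = 1L)
  ls <- sprintf("L%02d", 1:10); ps <- sprintf("P%02d", 1:10)
  s1 <- sample_random(ls, ps, pos, count = 20L, seed = 5L)
  s2 <- sample_random(ls, ps, pos, count = 20L, seed = 5L)
  s3 <- sample_random(ls, ps, pos, count = 20L, seed = 6L)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  key <- function(df) paste(df$lnc, df$prot)
  expect_equal(anyDuplicated(key(s1)), 0L)
  expect_length(intersect(key(s1), key(pos)), 0L)
  expect_equal(nrow(s1), 20L)
})

test_that("subcellular eligibility is compartment disjointness", {
  loc <- list(L1 = "nucleus", L2 = c("nucleus", "cytoplasm"),
              P1 = "nucleus", P2 = c("cytoplasm", "membrane"),
              P3 = "ribosome")
  pos <- data.frame(lnc = "L1", prot = "P3", stringsAsFactors = FALSE)
  # brute-force disjointness over the 2 x 3 grid
  expected <- character()
  for (l in c("L1", "L2")) {
    for (p in c("P1", "P2", "P3")) {
      if (length(intersect(loc[[l]], loc[[p]])) == 0L &&
          !(l == "L1" && p == "P3")) {
        expected <- c(expected, paste(l, p))
      }
    }
  }
  got <- sample_subcellular(loc, c("L1", "L2"), c("P1", "P2", "P3"), pos,
                            count = length(expected), seed = 2L)
  expect_setequal(paste(got$lnc, got$prot), expected)
  # shared-compartment pair is never eligible
  expect_false("L1 P1" %in% expected)
  # missing annotation is an error
  expect_error(sample_subcellular(loc, c("L1", "LX"), "P1", pos, 1L),
               "LX")
  # no eligible pair -> diagnostic error
  loc2 <- list(L1 = "nucleus", P1 = "nucleus")
  expect_error(sample_subcellular(loc2, "L1", "P1",
                                  data.frame(lnc = character(),
                                             prot = character()), 1L),
               "no compartment-disjoint")
})

test_that("subcellular eligibility equals brute force on a random fixture", {
  set.seed(8)
  comps <- c("nuc", "cyt", "mem", "rib")
  ls <- paste0("L", 1:4); ps <- paste0("P", 1:4)
  loc <- lapply(setNames(c(ls, ps), c(ls, ps)),
                function(i) sample(comps, sample.int(2, 1)))
  brute <- character()
  for (l in ls) for (p in ps) {
    if (length(intersect(loc[[l]], loc[[p]])) == 0L) {
      brute <- c(brute, paste(l, p))
    }
  }
  got <- lpiembed:::eligible_subcellular(loc, ls, ps)
  expect_setequal(gsub("\r", " ", got), brute)
})

test_that("bipartite shortest-path distances match a BFS oracle", {
  # hand path: L1-P1-L2-P2
  prior <- data.frame(lnc = c("L1", "L2", "L2"),
                      prot = c("P1", "P1", "P2"), stringsAsFactors = FALSE)
  d <- interaction_distances(prior)
  expect_equal(d["L1", "P1"], 1)
  expect_equal(d["L1", "P2"], 3)
  # random 30-node fixture vs plain-R BFS for all pairs
  prior2 <- random_edges(18, 12, 30, seed = 9L)
  d2 <- interaction_distances(prior2)
  for (l in rownames(d2)) {
    oracle <- bfs_distance(prior2$lnc, prior2$prot, l, colnames(d2))
    expect_equal(unname(d2[l, ]), unname(oracle))
  }
  # all finite lncRNA-protein distances are odd
  finite <- d2[is.finite(d2)]
  expect_true(all(finite %% 2 == 1))
})

test_that("distance bands select the right candidates and exclude positives", {
  prior <- data.frame(lnc = c("L1", "L2", "L2", "L3"),
                      prot = c("P1", "P1", "P2", "P3"),
                      stringsAsFactors = FALSE)
  cand3 <- distance_candidates(prior, 3L, 3L)
  expect_true("L1" %in% cand3$lnc[cand3$prot == "P2"])
  # distance-1 pairs (positives) are excluded by min > 1
  expect_false(any(paste(cand3$lnc, cand3$prot) %in%
                     paste(prior$lnc, prior$prot)))
  # unreachable pairs (L3/P3 component) never qualify for bounded specs
  expect_false(any(cand3$lnc == "L3" & cand3$prot != "P3"))
  expect_error(negative_spec("distance", distance_min = 1L,
                             distance_max = 3L), "distance_min")

  out <- sample_by_distance(prior, "Distance_3", count = nrow(cand3),
                            seed = 1L)
  expect_setequal(paste(out$lnc, out$prot), paste(cand3$lnc, cand3$prot))
  expect_error(sample_by_distance(prior, "Distance_3", count = 99L),
               "99 requested")
})

test_that("Distance_3, Distance_5, Distance_7 candidate sets are nested", {
  for (seed in 1:20) {
    prior <- random_edges(12, 8, sample(15:35, 1), seed = seed)
    key <- function(df) paste(df$lnc, df$prot)
    c3 <- key(distance_candidates(prior, 3L, 3L))
    c5 <- key(distance_candidates(prior, 2L, 5L))
    c7 <- key(distance_candidates(prior, 2L, 7L))
    expect_true(all(c3 %in% c5))
    expect_true(all(c5 %in% c7))
  }
})

test_that("sample_negatives dispatches all strategies with balanced counts", {
  p <- small_planted()
  pos <- p$interactions
  n <- nrow(pos)
  for (strat in list("random", "subcellular", "Distance_7")) {
    got <- sample_negatives(negative_spec(strat), p$lnc_ids, p$prot_ids,
                            pos, seed = 3L,
                            localization = p$localization)
    expect_equal(nrow(got), n)
    expect_length(intersect(paste(got$lnc, got$prot),
                            paste(pos$lnc, pos$prot)), 0L)
    expect_equal(anyDuplicated(paste(got$lnc, got$prot)), 0L)
  }
})
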