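# a small fixed heterogeneous network used across walk tests:
# interactions L1-P1, L1-P2, L2-P1, L3-P2; similarity L1-L2, P1-P2
walk_fixture <- function() {
  inter <- data.frame(lnc = c("L1", "L1", "L2", "L3"),
                      prot = c("P1", "P2", "P1", "P2"),
                      stringsAsFactors = FALSE)
  lnc_sim <- lpiembed:::new_similarity_graph(
    data.frame(u = "L1", v = "L2", weight = 1, stringsAsFactors = FALSE),
    "lncRNA", "jaccard")
  prot_sim <- lpiembed:::new_similarity_graph(
    data.frame(u = "P1", v = "P2", weight = 1, stringsAsFactors = FALSE),
    "protein", "jaccard")
  assemble_network(inter, lnc_sim, prot_sim)
}

test_that("scheme constructor enforces cyclability and parses strings", {
  s <- metapath_scheme("LPLPL")
  expect_equal(s$name, "LPLPL")
  expect_equal(s$types[1], "lncRNA")
  expect_equal(length(s$types), 5L)
  expect_error(metapath_scheme("LP"), "same type")
  expect_error(metapath_scheme("LXL"), "only contain")
  s2 <- metapath_scheme("LLPPLL")
  expect_equal(s2$types[2], "lncRNA")
})

test_that("transition distribution is uniform over admissible neighbours", {
  g <- walk_fixture()
  d <- transition_distribution(g, "L1", "protein")
  expect_equal(sort(names(d)), c("P1", "P2"))
  expect_equal(unname(d), c(0.5, 0.5))

  # node with 4 protein neighbours -> 0.25 each
  star <- assemble_network(data.frame(
    lnc = "L0", prot = paste0("P", 1:4), stringsAsFactors = FALSE))
  ds <- transition_distribution(star, "L0", "protein")
  expect_equal(unname(ds), rep(0.25, 4))

  # required type with no admissible neighbour -> empty map
  expect_length(transition_distribution(star, "L0", "lncRNA"), 0L)
  expect_length(transition_distribution(g, "L3", "lncRNA"), 0L)
})

test_that("transition distributions match exhaustive enumeration on a toy net", {
  g <- walk_fixture()
  vn <- igraph::V(g)$name
  vt <- igraph::V(g)$ntype
  ends <- igraph::ends(g, igraph::E(g))
  et <- igraph::E(g)$etype
  for (node in vn) {
    for (required in c("lncRNA", "protein")) {
      cur_type <- vt[match(node, vn)]
      klass <- if (cur_type == required) {
        c("lnc_sim", "prot_sim")
      } else {
        "interaction"
      }
      nbrs <- character()
      for (e in seq_len(nrow(ends))) {
        if (!et[e] %in% klass) next
        if (ends[e, 1] == node) nbrs <- c(nbrs, ends[e, 2])
        if (ends[e, 2] == node) nbrs <- c(nbrs, ends[e, 1])
      }
      nbrs <- unique(nbrs[vt[match(nbrs, vn)] == required])
      d <- transition_distribution(g, node, required)
      expect_setequal(names(d), nbrs)
      if (length(nbrs) > 0L) {
        expect_equal(unname(d), rep(1 / length(nbrs), length(nbrs)))
        expect_equal(sum(d), 1)
      }
    }
  }
})

test_that("walks on a star graph are forced and exactly walk_length long", {
  star <- assemble_network(data.frame(
    lnc = "L0", prot = paste0("P", 1:4), stringsAsFactors = FALSE))
  corpus <- generate_walks(star, "LPLPL", num_walks = 5L, walk_length = 5L,
                           seed = 2L)
  expect_length(corpus, 5L)
  for (w in unclass(corpus)) {
    expect_length(w, 5L)
    expect_equal(w[c(1, 3, 5)], rep("L0", 3))
    expect_true(all(w[c(2, 4)] %in% paste0("P", 1:4)))
  }
})

test_that("every walk's type sequence is a prefix of the cycled scheme", {
  net <- {
    p <- small_planted()
    assemble_network(p$interactions)
  }
  vt <- setNames(igraph::V(net)$ntype, igraph::V(net)$name)
  for (scheme in c("LPLPL", "LLPPLL")) {
    s <- metapath_scheme(scheme)
    cyc <- function(i) s$types[((i - 1L) %% (length(s$types) - 1L)) + 1L]
    corpus <- generate_walks(net, scheme, num_walks = 2L, walk_length = 11L,
                             seed = 3L)
    for (w in unclass(corpus)) {
      expect_equal(unname(vt[w]), vapply(seq_along(w), cyc, ""))
    }
  }
})

test_that("walk corpora are deterministic in the seed", {
  net <- assemble_network(small_planted()$interactions)
  c1 <- generate_walks(net, "LPLPL", num_walks = 3L, walk_length = 20L,
                       seed = 9L)
  c2 <- generate_walks(net, "LPLPL", num_walks = 3L, walk_length = 20L,
                       seed = 9L)
  expect_identical(unclass(c1), unclass(c2))
  c3 <- generate_walks(net, "LPLPL", num_walks = 3L, walk_length = 20L,
                       seed = 10L)
  expect_false(identical(unclass(c1), unclass(c3)))
})

test_that("dead-ended walks are truncated and single-node walks dropped", {
  # L1-P1 plus isolated L2: LPLPL from L2 dies immediately (dropped);
  # LLPPLL from L1 dies at the first L->L step after one node (dropped)
  inter <- data.frame(lnc = "L1", prot = "P1", stringsAsFactors = FALSE)
  net <- assemble_network(inter, extra_nodes = list(lnc = "L2",
                                                    prot = character()))
  lplpl <- generate_walks(net, "LPLPL", num_walks = 4L, walk_length = 5L,
                          seed = 1L)
  expect_length(lplpl, 4L)  # only L1 yields walks; L2's are dropped
  expect_true(all(vapply(unclass(lplpl), length, 0L) == 5L))
  llppll <- generate_walks(net, "LLPPLL", num_walks = 4L, walk_length = 6L,
                           seed = 1L)
  expect_length(llppll, 0L)
})

test_that("walks never traverse held-out test interaction edges", {
  p <- small_planted()
  ds <- build_dataset(p$interactions, lncRNAs = p$lnc_ids,
                      proteins = p$prot_ids, strategy = "random",
                      repeats = 3L, seed = 21L)
  for (r in 1:3) {
    train_pos <- dataset_part(ds, r, "train", label = 1L)
    test_pos <- dataset_part(ds, r, "test", label = 1L)
    net <- assemble_network(train_pos)
    for (scheme in c("LPLPL", "LLPPLL")) {
      corpus <- generate_walks(net, scheme, num_walks = 3L,
                               walk_length = 20L, seed = r)
      expect_identical(check_no_leak(corpus, test_pos), 0L)
    }
  }
  # and the check itself detects a planted violation
  fake <- structure(list(c("Lx", "Px")), class = "walk_corpus")
  expect_error(check_no_leak(fake, data.frame(lnc = "Lx", prot = "Px")),
               "leak|test edges")
})

test_that("empirical bigram frequencies match the exact transition law", {
  g <- walk_fixture()
  corpus <- generate_walks(g, "LPLPL", num_walks = 400L, walk_length = 40L,
                           seed = 13L)
  # count transitions out of L1 at L->P steps (positions 1,3,5,...)
  counts <- c(P1 = 0, P2 = 0)
  n_from_l1 <- 0
  for (w in unclass(corpus)) {
    for (i in seq_len(length(w) - 1L)) {
      if (i %% 2L == 1L && w[i] == "L1") {
        n_from_l1 <- n_from_l1 + 1
        counts[w[i + 1L]] <- counts[w[i + 1L]] + 1
      }
    }
  }
  d <- transition_distribution(g, "L1", "protein")
  for (nb in names(d)) {
    p_hat <- counts[[nb]]
    se <- sqrt(n_from_l1 * d[[nb]] * (1 - d[[nb]]))
    expect_lt(abs(p_hat - n_from_l1 * d[[nb]]), 3 * se + 1e-9)
  }
})
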