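#' Train skip-gram node embeddings on a walk corpus
#'
#' Walks are treated as sentences of node-id tokens and fed to a skip-gram
#' model with negative sampling (single-threaded, seeded, so results are
#' reproducible bit-for-bit on one platform). Every node appearing in at
#' least one walk gets a learned vector; nodes listed in `all_nodes` but
#' absent from the corpus get the zero vector (counted and reported via a
#' message).
#'
#' @param corpus a `walk_corpus`.
#' @param dim embedding dimension (default 64).
#' @param window context window half-width (default 5).
#' @param epochs training epochs (default 5).
#' @param negative negative samples per context pair (default 5).
#' @param alpha initial learning rate (default 0.025).
#' @param seed integer seed.
#' @param all_nodes optional character vector of node ids that must appear in
#'   the output (zero-vector fallback for those missing from the corpus).
#' @return Numeric matrix, one row per node id (rownames), `dim` columns.
#' @export
train_embeddings <- function(corpus, dim = 64L, window = 5L, epochs = 5L,
                             negative = 5L, alpha = 0.025, seed = 1L,
                             all_nodes = NULL) {
  walks <- unclass(corpus)
  walks <- walks[lengths(walks) >= 2L]
  if (length(walks) == 0L) stop("empty walk corpus", call. = FALSE)
  dim <- check_count(dim, "dim", min = 2L)
  vocab <- unique(unlist(walks, use.names = FALSE))
  iwalks <- lapply(walks, function(w) match(w, vocab))
  emb <- sgns_train_cpp(iwalks, length(vocab), dim, as.integer(window),
                        as.integer(epochs), as.integer(negative), alpha,
                        as.integer(seed))
  rownames(emb) <- vocab
  if (!is.null(all_nodes)) {
    missing <- setdiff(all_nodes, vocab)
    if (length(missing) > 0L) {
      message(length(missing),
              " node(s) absent from all walks; zero-vector fallback")
      zeros <- matrix(0, nrow = length(missing), ncol = dim,
                      dimnames = list(missing, NULL))
      emb <- rbind(emb, zeros)
    }
    emb <- emb[all_nodes, , drop = FALSE]
  }
  emb
}

#' Embed one heterogeneous network with meta-path walks + skip-gram
#'
#' Runs each scheme over the network, pools the corpora, and trains one
#' skip-gram model, yielding a `dim`-vector per node.
#'
#' @param network a `hetero_network`.
#' @param schemes list of scheme strings or `metapath_scheme`s
#'   (default `list("LPLPL", "LLPPLL")`).
#' @param dim,window,epochs,negative,alpha,seed passed to
#'   [train_embeddings()]; `num_walks`/`walk_length` to [generate_walks()].
#' @param num_walks walks per start node.
#' @param walk_length nodes per walk.
#' @return Numeric matrix: all network nodes x `dim`.
#' @export
embed_network <- function(network, schemes = list("LPLPL", "LLPPLL"),
                          dim = 64L, num_walks = 10L, walk_length = 80L,
                          window = 5L, epochs = 5L, negative = 5L,
                          alpha = 0.025, seed = 1L) {
  corpora <- lapply(seq_along(schemes), function(i) {
    generate_walks(network, schemes[[i]], num_walks = num_walks,
                   walk_length = walk_length, seed = seed + i - 1L)
  })
  corpus <- do.call(concat_corpora, corpora)
  train_embeddings(corpus, dim = dim, window = window, epochs = epochs,
                   negative = negative, alpha = alpha, seed = seed,
                   all_nodes = igraph::V(network)$name)
}

#' Splice per-network embeddings into one node feature vector
#'
#' Concatenates, per node, its vector from the Jaccard-similarity network
#' (first) and from the alignment-similarity network (second), giving a
#' `2 * d` feature vector. A node missing from one matrix contributes a zero
#' block for that half.
#'
#' @param emb_kjnet node embedding matrix from the KJNet network.
#' @param emb_kbnet node embedding matrix from the KBNet network.
#' @return Numeric matrix: union of node ids x `2 * d`.
#' @export
splice_node_features <- function(emb_kjnet, emb_kbnet) {
  stopifnot(is.matrix(emb_kjnet), is.matrix(emb_kbnet))
  d1 <- ncol(emb_kjnet); d2 <- ncol(emb_kbnet)
  if (d1 != d2) stop("embedding dimension mismatch: ", d1, " vs ", d2,
                     call. = FALSE)
  nodes <- union(rownames(emb_kjnet), rownames(emb_kbnet))
  out <- matrix(0, nrow = length(nodes), ncol = 2L * d1,
                dimnames = list(nodes, NULL))
  in1 <- intersect(nodes, rownames(emb_kjnet))
  in2 <- intersect(nodes, rownames(emb_kbnet))
  out[in1, seq_len(d1)] <- emb_kjnet[in1, , drop = FALSE]
  out[in2, d1 + seq_len(d2)] <- emb_kbnet[in2, , drop = FALSE]
  out
}

#' Pair feature vectors for candidate lncRNA-protein pairs
#'
#' Per pair, the lncRNA node feature followed by the protein node feature.
#' With 128-dim spliced node features this yields the 256-dim pair
#' representation used by the classifier.
#'
#' @param node_feats numeric matrix of node features (rownames = node ids).
#' @param pairs data.frame with columns `lnc` and `prot` (an optional `label`
#'   column is carried through).
#' @return A `pair_feature_set`: numeric matrix, one row per pair (rownames
#'   `lnc|prot`), with attributes `pairs` (the input data.frame) and `labels`
#'   (or NULL).
#' @export
pair_features <- function(node_feats, pairs) {
  pairs_df <- as_pair_df(pairs, "pairs")
  missing <- setdiff(unique(c(pairs_df$lnc, pairs_df$prot)),
                     rownames(node_feats))
  if (length(missing) > 0L) {
    bad_i <- which(pairs_df$lnc %in% missing | pairs_df$prot %in% missing)[1L]
    stop(sprintf("no node feature for pair (%s, %s)",
                 pairs_df$lnc[bad_i], pairs_df$prot[bad_i]), call. = FALSE)
  }
  x <- cbind(node_feats[pairs_df$lnc, , drop = FALSE],
             node_feats[pairs_df$prot, , drop = FALSE])
  rownames(x) <- paste(pairs_df$lnc, pairs_df$prot, sep = "|")
  labels <- if (is.data.frame(pairs) && "label" %in% names(pairs)) {
    as.integer(pairs$label)
  }
  structure(x, class = c("pair_feature_set", "matrix", "array"),
            pairs = pairs_df, labels = labels)
}

#' @export
print.pair_feature_set <- function(x, ...) {
  cat(sprintf("<pair_feature_set> %d pair(s) x %d feature(s)%s\n",
              nrow(x), ncol(x),
              if (!is.null(attr(x, "labels"))) ", labelled" else ""))
  invisible(x)
}
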