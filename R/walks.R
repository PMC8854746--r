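#' Define a meta-path scheme
#'
#' A scheme is an ordered sequence of node types constraining admissible
#' random-walk steps, written as a string of `L` (lncRNA) and `P` (protein),
#' e.g. `"LPLPL"` or `"LLPPLL"`. The first and last type must match so the
#' scheme can cycle for walks longer than the literal scheme. Steps between
#' different types traverse interaction edges; steps between equal types
#' traverse similarity edges.
#'
#' @param types a string such as `"LPLPL"`, or a character vector of
#'   `"lncRNA"`/`"protein"` types.
#' @param name optional scheme name; defaults to the compact string.
#' @return A `metapath_scheme` object.
#' @export
metapath_scheme <- function(types, name = NULL) {
  if (is.character(types) && length(types) == 1L && !grepl("lnc", types)) {
    letters_ <- strsplit(toupper(types), "")[[1]]
    if (!all(letters_ %in% c("L", "P"))) {
      stop("scheme string may only contain 'L' and 'P'", call. = FALSE)
    }
    types <- ifelse(letters_ == "L", "lncRNA", "protein")
    if (is.null(name)) name <- paste(letters_, collapse = "")
  }
  if (!all(types %in% c("lncRNA", "protein"))) {
    stop("types must be 'lncRNA' or 'protein'", call. = FALSE)
  }
  if (length(types) < 2L) stop("scheme needs length >= 2", call. = FALSE)
  if (types[1L] != types[length(types)]) {
    stop("scheme must start and end with the same type (cyclable)",
         call. = FALSE)
  }
  if (is.null(name)) {
    name <- paste(ifelse(types == "lncRNA", "L", "P"), collapse = "")
  }
  structure(list(types = types, name = name), class = "metapath_scheme")
}

#' @export
print.metapath_scheme <- function(x, ...) {
  cat(sprintf("<metapath_scheme> %s (%s)\n", x$name,
              paste(x$types, collapse = "-")))
  invisible(x)
}

# typed adjacency: for each vertex, its neighbours via interaction edges and
# via similarity edges, as 1-based vertex indices
typed_adjacency <- function(network) {
  et <- igraph::E(network)$etype
  ends <- igraph::ends(network, igraph::E(network), names = FALSE)
  n <- igraph::vcount(network)
  adj_int <- vector("list", n)
  adj_sim <- vector("list", n)
  for (i in seq_len(n)) {
    adj_int[[i]] <- integer()
    adj_sim[[i]] <- integer()
  }
  is_int <- et == "interaction"
  add <- function(adj, a, b) {
    for (k in seq_along(a)) {
      adj[[a[k]]] <- c(adj[[a[k]]], b[k])
      adj[[b[k]]] <- c(adj[[b[k]]], a[k])
    }
    adj
  }
  adj_int <- add(adj_int, ends[is_int, 1L], ends[is_int, 2L])
  adj_sim <- add(adj_sim, ends[!is_int, 1L], ends[!is_int, 2L])
  # drop parallel duplicates, sort for reproducible sampling order
  adj_int <- lapply(adj_int, function(v) sort(unique(v)))
  adj_sim <- lapply(adj_sim, function(v) sort(unique(v)))
  list(interaction = adj_int, similarity = adj_sim)
}

#' Transition distribution of the meta-path walk at one node
#'
#' Under the meta-path constraint, the walker moves uniformly over the
#' neighbours of the current node whose type equals the required next type
#' and whose connecting edge class is admissible for the step (interaction
#' edges between different types, similarity edges within a type); all other
#' nodes get probability 0. An empty result signals a dead end.
#'
#' @param network a `hetero_network`.
#' @param current node id (name) of the current node.
#' @param required_type `"lncRNA"` or `"protein"`: the type required at the
#'   next step.
#' @param edge_class `"auto"` (infer from the type pair), `"interaction"` or
#'   `"similarity"`.
#' @return Named numeric vector of probabilities over admissible next nodes
#'   (sums to 1), or an empty numeric vector at a dead end.
#' @export
transition_distribution <- function(network, current,
                                    required_type = c("lncRNA", "protein"),
                                    edge_class = c("auto", "interaction",
                                                   "similarity")) {
  required_type <- match.arg(required_type)
  edge_class <- match.arg(edge_class)
  vnames <- igraph::V(network)$name
  if (!current %in% vnames) stop("node not in network: ", current,
                                 call. = FALSE)
  cur_type <- igraph::V(network)$ntype[match(current, vnames)]
  if (edge_class == "auto") {
    edge_class <- if (cur_type == required_type) "similarity" else
      "interaction"
  }
  adj <- typed_adjacency(network)
  idx <- match(current, vnames)
  cand <- adj[[edge_class]][[idx]]
  cand <- cand[igraph::V(network)$ntype[cand] == required_type]
  if (length(cand) == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(rep(1 / length(cand), length(cand)), vnames[cand])
}

#' Generate meta-path constrained random walks
#'
#' For every node whose type matches the scheme start, `num_walks` walks are
#' started. The scheme cycles (exploiting first type == last type) until the
#' walk reaches `walk_length` nodes or a dead end; dead-ended walks are kept
#' if they have at least 2 nodes, else discarded. Deterministic given `seed`.
#'
#' @param network a `hetero_network`; it must have been assembled from
#'   training interactions only (held-out test edges removed).
#' @param scheme a `metapath_scheme` or a scheme string such as `"LPLPL"`.
#' @param num_walks walks per start node (default 10).
#' @param walk_length nodes per walk (default 80).
#' @param seed integer seed.
#' @return A `walk_corpus`: list of character-vector walks, with attributes
#'   recording scheme name, num_walks, walk_length and seed.
#' @export
generate_walks <- function(network, scheme, num_walks = 10L,
                           walk_length = 80L, seed = 1L) {
  if (!inherits(scheme, "metapath_scheme")) scheme <- metapath_scheme(scheme)
  num_walks <- check_count(num_walks, "num_walks")
  walk_length <- check_count(walk_length, "walk_length", min = 2L)
  if (walk_length < length(scheme$types)) {
    stop("`walk_length` must be >= scheme length", call. = FALSE)
  }
  vtypes <- igraph::V(network)$ntype
  vnames <- igraph::V(network)$name
  if (!scheme$types[1L] %in% vtypes) {
    stop("scheme start type absent from network", call. = FALSE)
  }
  adj <- typed_adjacency(network)
  type_code <- ifelse(vtypes == "lncRNA", 1L, 2L)
  scheme_code <- ifelse(scheme$types == "lncRNA", 1L, 2L)
  raw <- metapath_walks_cpp(adj$interaction, adj$similarity, type_code,
                            scheme_code, num_walks, walk_length,
                            as.integer(seed))
  walks <- lapply(raw, function(w) vnames[w])
  structure(walks, class = "walk_corpus", scheme = scheme$name,
            num_walks = num_walks, walk_length = walk_length, seed = seed)
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("<walk_corpus> %d walk(s), scheme=%s, %d tokens\n",
              length(x), attr(x, "scheme"),
              sum(lengths(unclass(x)))))
  invisible(x)
}

#' Concatenate walk corpora
#'
#' Used to pool the corpora of several meta-path schemes over one network
#' before embedding training.
#'
#' @param ... `walk_corpus` objects.
#' @return A `walk_corpus` containing all walks, scheme names joined by `+`.
#' @export
concat_corpora <- function(...) {
  corpora <- list(...)
  stopifnot(all(vapply(corpora, inherits, TRUE, "walk_corpus")))
  walks <- do.call(c, lapply(corpora, unclass))
  structure(walks, class = "walk_corpus",
            scheme = paste(vapply(corpora, attr, "", "scheme"),
                           collapse = "+"),
            num_walks = NA_integer_, walk_length = NA_integer_,
            seed = NA_integer_)
}

#' Write a walk corpus as whitespace-delimited token lines
#'
#' @param corpus a `walk_corpus`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(unclass(corpus), paste, "", collapse = " "), path)
  invisible(path)
}

#' Assert that no walk traverses a held-out test interaction edge
#'
#' Scans every consecutive bigram in the corpus; a bigram equal to a test
#' lncRNA-protein pair (in either order) is a label leak.
#'
#' @param corpus a `walk_corpus`.
#' @param test_edges data.frame (`lnc`, `prot`) of held-out test positives.
#' @return Invisibly the number of violations (0 on success); errors if any
#'   violation is found.
#' @export
check_no_leak <- function(corpus, test_edges) {
  test_edges <- as_pair_df(test_edges, "test_edges")
  bad_keys <- c(pair_key(test_edges$lnc, test_edges$prot),
                pair_key(test_edges$prot, test_edges$lnc))
  n_viol <- 0L
  for (w in unclass(corpus)) {
    if (length(w) < 2L) next
    bigr <- pair_key(w[-length(w)], w[-1L])
    n_viol <- n_viol + sum(bigr %in% bad_keys)
  }
  if (n_viol > 0L) {
    stop(n_viol, " walk step(s) traverse held-out test edges", call. = FALSE)
  }
  invisible(n_viol)
}
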