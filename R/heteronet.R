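pair_key <- function(lnc, prot) paste(lnc, prot, sep = "\r")

as_pair_df <- function(x, what = "pairs") {
  if (is.data.frame(x)) {
    if (all(c("lnc", "prot") %in% names(x))) {
      return(data.frame(lnc = as.character(x$lnc),
                        prot = as.character(x$prot),
                        stringsAsFactors = FALSE))
    }
    stop(what, " must have columns `lnc` and `prot`", call. = FALSE)
  }
  stop(what, " must be a data.frame with columns `lnc` and `prot`",
       call. = FALSE)
}

#' Split positive and negative pairs into train/test partitions
#'
#' Each repeat draws an independent uniform partition, stratified by class
#' label so positives and negatives both keep the requested train fraction.
#' Deterministic given `seed`.
#'
#' @param positives data.frame of interacting pairs (`lnc`, `prot`).
#' @param negatives data.frame of non-interacting pairs (`lnc`, `prot`).
#' @param ratio train fraction, in (0, 1); default 0.9 (a 9:1 split).
#' @param repeats number of independent repeats; default 3.
#' @param seed integer seed.
#' @return An `interaction_dataset`: data.frame with columns `lnc`, `prot`,
#'   `label` (1/0), `rep`, `part` ("train"/"test"); attributes record ratio,
#'   repeats and seed.
#' @export
split_dataset <- function(positives, negatives, ratio = 0.9, repeats = 3L,
                          seed = 1L) {
  positives <- as_pair_df(positives, "positives")
  negatives <- as_pair_df(negatives, "negatives")
  check_scalar_number(ratio, "ratio", 0, 1)
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)",
                                     call. = FALSE)
  repeats <- check_count(repeats, "repeats")
  if (nrow(positives) < 10L || nrow(negatives) < 10L) {
    stop("need at least 10 pairs per class to split", call. = FALSE)
  }
  if (length(intersect(pair_key(positives$lnc, positives$prot),
                       pair_key(negatives$lnc, negatives$prot))) > 0L) {
    stop("positives and negatives overlap", call. = FALSE)
  }
  split_one <- function(df, label, rep_i) {
    n <- nrow(df)
    n_train <- round(n * ratio)
    n_train <- max(1L, min(n - 1L, n_train))
    idx <- sample.int(n, n_train)
    part <- rep("test", n)
    part[idx] <- "train"
    data.frame(lnc = df$lnc, prot = df$prot, label = label, rep = rep_i,
               part = part, stringsAsFactors = FALSE)
  }
  out <- local_seed(seed, {
    do.call(rbind, lapply(seq_len(repeats), function(r) {
      rbind(split_one(positives, 1L, r), split_one(negatives, 0L, r))
    }))
  })
  rownames(out) <- NULL
  structure(out, ratio = ratio, repeats = repeats, seed = seed,
            class = c("interaction_dataset", "data.frame"))
}

#' Extract one partition of one repeat from an interaction dataset
#'
#' @param dataset an `interaction_dataset`.
#' @param rep repeat index.
#' @param part `"train"` or `"test"`.
#' @param label optional label filter (1 or 0).
#' @return data.frame with columns `lnc`, `prot`, `label`.
#' @export
dataset_part <- function(dataset, rep = 1L, part = c("train", "test"),
                         label = NULL) {
  part <- match.arg(part)
  out <- dataset[dataset$rep == rep & dataset$part == part, , drop = FALSE]
  if (!is.null(label)) out <- out[out$label == label, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("lnc", "prot", "label")]
}

#' Assemble a typed heterogeneous lncRNA-protein network
#'
#' Merges training interaction edges with optional lncRNA-lncRNA and
#' protein-protein similarity graphs into one typed multigraph. The variant
#' tag is inferred from the similarity provenance: `KNet` (interactions
#' only), `KJNet` (interactions + Jaccard similarities) or `KBNet`
#' (interactions + alignment similarities). Test-partition interaction edges
#' must never be passed in; callers assemble from training interactions only.
#'
#' @param train_interactions data.frame (`lnc`, `prot`) of training positives.
#' @param lnc_sim optional `similarity_graph` with node_type `"lncRNA"`.
#' @param prot_sim optional `similarity_graph` with node_type `"protein"`.
#' @param extra_nodes optional list with character vectors `lnc` and `prot`
#'   of ids to retain even when isolated (so held-out nodes keep a slot and
#'   receive fallback embeddings rather than vanishing).
#' @return A `hetero_network`: an igraph with vertex attribute `ntype`
#'   ("lncRNA"/"protein"), edge attributes `etype` ("interaction"/"lnc_sim"/
#'   "prot_sim") and `weight`, plus a `variant` graph attribute.
#' @export
assemble_network <- function(train_interactions, lnc_sim = NULL,
                             prot_sim = NULL, extra_nodes = NULL) {
  inter <- as_pair_df(train_interactions, "train_interactions")
  check_sim <- function(g, type, arg) {
    if (is.null(g)) return(invisible(NULL))
    if (!inherits(g, "similarity_graph")) {
      stop("`", arg, "` must be a similarity_graph", call. = FALSE)
    }
    if (attr(g, "node_type") != type) {
      stop("`", arg, "` has node_type ", attr(g, "node_type"),
           ", expected ", type, call. = FALSE)
    }
  }
  check_sim(lnc_sim, "lncRNA", "lnc_sim")
  check_sim(prot_sim, "protein", "prot_sim")

  lnc_ids <- unique(c(inter$lnc,
                      if (!is.null(lnc_sim)) c(lnc_sim$u, lnc_sim$v),
                      if (!is.null(extra_nodes)) extra_nodes$lnc))
  prot_ids <- unique(c(inter$prot,
                       if (!is.null(prot_sim)) c(prot_sim$u, prot_sim$v),
                       if (!is.null(extra_nodes)) extra_nodes$prot))
  check_namespaces(lnc_ids, prot_ids)

  prov <- c(if (!is.null(lnc_sim)) attr(lnc_sim, "provenance"),
            if (!is.null(prot_sim)) attr(prot_sim, "provenance"))
  variant <- if (length(prov) == 0L) {
    "KNet"
  } else if (all(prov == "jaccard")) {
    "KJNet"
  } else if (all(prov == "alignment")) {
    "KBNet"
  } else {
    "mixed"
  }

  edges <- rbind(
    data.frame(u = inter$lnc, v = inter$prot, etype = "interaction",
               weight = 1, stringsAsFactors = FALSE),
    if (!is.null(lnc_sim) && nrow(lnc_sim) > 0L) {
      data.frame(u = lnc_sim$u, v = lnc_sim$v, etype = "lnc_sim",
                 weight = lnc_sim$weight, stringsAsFactors = FALSE)
    },
    if (!is.null(prot_sim) && nrow(prot_sim) > 0L) {
      data.frame(u = prot_sim$u, v = prot_sim$v, etype = "prot_sim",
                 weight = prot_sim$weight, stringsAsFactors = FALSE)
    }
  )
  vertices <- data.frame(
    name = c(lnc_ids, prot_ids),
    ntype = c(rep("lncRNA", length(lnc_ids)),
              rep("protein", length(prot_ids))),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  g <- igraph::set_graph_attr(g, "variant", variant)
  class(g) <- c("hetero_network", class(g))
  g
}

#' @export
print.hetero_network <- function(x, ...) {
  nt <- igraph::V(x)$ntype
  et <- igraph::E(x)$etype
  cat(sprintf(
    "<hetero_network> variant=%s | %d lncRNA, %d protein | %s\n",
    igraph::graph_attr(x, "variant"),
    sum(nt == "lncRNA"), sum(nt == "protein"),
    paste(sprintf("%s=%d", names(table(et)), as.integer(table(et))),
          collapse = ", ")
  ))
  invisible(x)
}

#' Node ids of one type in a heterogeneous network
#'
#' @param network a `hetero_network`.
#' @param type `"lncRNA"` or `"protein"`.
#' @return Character vector of node ids.
#' @export
network_nodes <- function(network, type = c("lncRNA", "protein")) {
  type <- match.arg(type)
  igraph::V(network)$name[igraph::V(network)$ntype == type]
}
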