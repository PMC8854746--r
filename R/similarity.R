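#' Jaccard similarity between two sets
#'
#' `|a intersect b| / |a union b|`; defined as 0 when both sets are empty.
#'
#' @param a,b character vectors (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Association sets from training interactions
#'
#' For each lncRNA, the set of proteins it interacts with; for each protein,
#' the set of lncRNAs. Built from training-partition interactions only, so
#' the resulting similarities cannot leak held-out test edges.
#'
#' @param edges data.frame with columns `lnc` and `prot` (training positives).
#' @return List with named lists `lnc` (lncRNA id -> protein ids) and
#'   `prot` (protein id -> lncRNA ids).
#' @export
association_sets <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("lnc", "prot") %in% names(edges)))
  list(
    lnc = lapply(split(edges$prot, edges$lnc), unique),
    prot = lapply(split(edges$lnc, edges$prot), unique)
  )
}

new_similarity_graph <- function(edges, node_type, provenance) {
  stopifnot(is.data.frame(edges),
            all(c("u", "v", "weight") %in% names(edges)))
  structure(
    edges[, c("u", "v", "weight"), drop = FALSE],
    node_type = node_type,
    provenance = provenance,
    class = c("similarity_graph", "data.frame")
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %s / %s: %d edge(s)\n",
              attr(x, "node_type"), attr(x, "provenance"), nrow(x)))
  if (nrow(x) > 0L) print.data.frame(head(x, 10L))
  invisible(x)
}

#' Build a Jaccard similarity graph over one node type
#'
#' Two nodes are connected when the Jaccard similarity of their association
#' sets exceeds the threshold (strict `>`). Defaults follow the network
#' construction rules: threshold 0.5 for lncRNA-lncRNA edges, 0 for
#' protein-protein edges.
#'
#' @param assoc output of [association_sets()].
#' @param node_type `"lncRNA"` or `"protein"`.
#' @param threshold edge threshold in `[0, 1]`; `NULL` picks the default for
#'   the node type (0.5 for lncRNA, 0 for protein).
#' @param strict if `TRUE` (default) an edge requires similarity strictly
#'   greater than the threshold; if `FALSE`, greater-or-equal.
#' @return A `similarity_graph`: data.frame of undirected edges `u`, `v` with
#'   `weight` equal to the Jaccard similarity.
#' @export
build_jaccard_graph <- function(assoc, node_type = c("lncRNA", "protein"),
                                threshold = NULL, strict = TRUE) {
  node_type <- match.arg(node_type)
  sets <- if (node_type == "lncRNA") assoc$lnc else assoc$prot
  if (is.null(threshold)) threshold <- if (node_type == "lncRNA") 0.5 else 0
  check_scalar_number(threshold, "threshold", 0, 1)
  ids <- names(sets)
  n <- length(ids)
  us <- character(); vs <- character(); ws <- numeric()
  if (n >= 2L) {
    # invert: for each partner, which nodes carry it -- candidate pairs are
    # only those sharing at least one partner (others have similarity 0)
    memb <- split(rep(ids, lengths(sets)), unlist(sets, use.names = FALSE))
    cand <- new.env(hash = TRUE)
    for (grp in memb) {
      grp <- sort(unique(grp))
      if (length(grp) < 2L) next
      for (i in seq_len(length(grp) - 1L)) {
        for (j in seq((i + 1L), length(grp))) {
          assign(paste(grp[i], grp[j], sep = "\r"), TRUE, envir = cand)
        }
      }
    }
    pairs <- ls(cand)
    if (threshold == 0 && !strict) {
      # similarity-0 pairs qualify under >= 0: enumerate all pairs
      pairs <- unlist(lapply(seq_len(n - 1L), function(i) {
        paste(pmin(ids[i], ids[(i + 1L):n]), pmax(ids[i], ids[(i + 1L):n]),
              sep = "\r")
      }))
    }
    for (key in pairs) {
      uv <- strsplit(key, "\r", fixed = TRUE)[[1]]
      s <- jaccard(sets[[uv[1L]]], sets[[uv[2L]]])
      ok <- if (strict) s > threshold else s >= threshold
      if (ok) {
        us <- c(us, uv[1L]); vs <- c(vs, uv[2L]); ws <- c(ws, s)
      }
    }
  }
  edges <- data.frame(u = us, v = vs, weight = ws, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  new_similarity_graph(edges, node_type, "jaccard")
}

#' Build an alignment similarity graph from BLAST-style hits
#'
#' An undirected edge (u, v) is present when the minimum e-value over the two
#' orientations (u as query, v as query) is below the cutoff (strict `<`).
#' Defaults follow the network construction rules: cutoff 1e-3 for
#' lncRNA-lncRNA edges, 1e-2 for protein-protein edges. The edge weight is
#' `-log10(min e-value)` capped at 300 (walks ignore weights; the weight is
#' informational).
#'
#' @param hits data.frame as returned by [read_blast_tabular()].
#' @param node_type `"lncRNA"` or `"protein"`.
#' @param evalue_cutoff positive cutoff; `NULL` picks the default for the node
#'   type (1e-3 for lncRNA, 1e-2 for protein).
#' @param node_ids optional character vector of valid ids of this type; hits
#'   mentioning other ids raise an error.
#' @param require_both if `TRUE`, both orientations must pass the cutoff
#'   (max-stringency rule) instead of either.
#' @return A `similarity_graph` with `provenance = "alignment"`.
#' @export
build_alignment_graph <- function(hits, node_type = c("lncRNA", "protein"),
                                  evalue_cutoff = NULL, node_ids = NULL,
                                  require_both = FALSE) {
  node_type <- match.arg(node_type)
  stopifnot(is.data.frame(hits),
            all(c("query", "subject", "evalue") %in% names(hits)))
  if (is.null(evalue_cutoff)) {
    evalue_cutoff <- if (node_type == "lncRNA") 1e-3 else 1e-2
  }
  check_scalar_number(evalue_cutoff, "evalue_cutoff", min = 0)
  if (evalue_cutoff <= 0) stop("`evalue_cutoff` must be > 0", call. = FALSE)
  if (!is.null(node_ids)) {
    bad <- setdiff(unique(c(hits$query, hits$subject)), node_ids)
    if (length(bad) > 0L) {
      stop("alignment hit ids not of type ", node_type, ": ",
           paste(head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  empty <- data.frame(u = character(), v = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(new_similarity_graph(empty, node_type,
                                                    "alignment"))
  u <- pmin(hits$query, hits$subject)
  v <- pmax(hits$query, hits$subject)
  key <- paste(u, v, sep = "\r")
  if (require_both) {
    # both orientations must be present and pass; compare the worst e-value
    orient <- ifelse(hits$query < hits$subject, "f", "r")
    ef <- tapply(ifelse(orient == "f", hits$evalue, Inf), key, min)
    er <- tapply(ifelse(orient == "r", hits$evalue, Inf), key, min)
    eff <- pmax(ef, er[names(ef)])
  } else {
    eff <- tapply(hits$evalue, key, min)
  }
  keep <- eff < evalue_cutoff
  keys <- names(eff)[keep]
  uv <- strsplit(keys, "\r", fixed = TRUE)
  w <- pmin(-log10(pmax(eff[keep], 1e-300)), 300)
  edges <- data.frame(
    u = vapply(uv, `[[`, "", 1L),
    v = vapply(uv, `[[`, "", 2L),
    weight = as.numeric(w),
    stringsAsFactors = FALSE
  )
  if (nrow(edges) > 0L) edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  new_similarity_graph(edges, node_type, "alignment")
}

#' Write a similarity graph as a weighted TSV edge list
#'
#' Columns: u, v, weight, provenance.
#'
#' @param graph a `similarity_graph`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_similarity_graph <- function(graph, path) {
  stopifnot(inherits(graph, "similarity_graph"))
  prov <- attr(graph, "provenance")
  lines <- paste(graph$u, graph$v,
                 formatC(graph$weight, digits = 6L, format = "g"),
                 prov, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
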