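#' Specify a negative-sampling strategy
#'
#' Three strategies produce non-interacting lncRNA-protein pairs for class-0
#' training examples: uniform random pairing, subcellular-localization
#' incompatibility (molecules sharing no compartment), and shortest-path
#' distance in the prior interaction network. The distance strategy has three
#' named variants: `Distance_3` (distance exactly 3), `Distance_5` (greater
#' than 1 and at most 5) and `Distance_7` (greater than 1 and at most 7).
#'
#' @param strategy `"random"`, `"subcellular"`, `"distance"`, or one of the
#'   shorthands `"Distance_3"`, `"Distance_5"`, `"Distance_7"`.
#' @param distance_min,distance_max integer bounds for the distance strategy;
#'   `distance_min` must exceed 1 (distance-1 pairs are the positives).
#' @param count number of pairs to draw.
#' @param seed integer seed.
#' @return A `negative_spec` list.
#' @export
negative_spec <- function(strategy = c("random", "subcellular", "distance",
                                       "Distance_3", "Distance_5",
                                       "Distance_7"),
                          distance_min = NULL, distance_max = NULL,
                          count = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "Distance_3") {
    strategy <- "distance"; distance_min <- 3L; distance_max <- 3L
  } else if (strategy == "Distance_5") {
    strategy <- "distance"; distance_min <- 2L; distance_max <- 5L
  } else if (strategy == "Distance_7") {
    strategy <- "distance"; distance_min <- 2L; distance_max <- 7L
  }
  if (strategy == "distance") {
    distance_min <- check_count(distance_min, "distance_min", min = 2L)
    distance_max <- check_count(distance_max, "distance_max",
                                min = distance_min)
  }
  if (!is.null(count)) count <- check_count(count, "count")
  structure(list(strategy = strategy, distance_min = distance_min,
                 distance_max = distance_max, count = count,
                 seed = as.integer(seed)),
            class = "negative_spec")
}

sample_pairs_keys <- function(keys, count, seed) {
  if (count > length(keys)) {
    stop(sprintf("requested %d negative pairs but only %d candidates exist",
                 count, length(keys)), call. = FALSE)
  }
  chosen <- local_seed(seed, sample(keys, count))
  parts <- strsplit(chosen, "\r", fixed = TRUE)
  data.frame(lnc = vapply(parts, `[[`, "", 1L),
             prot = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Random-pairing negative sampling
#'
#' Uniform sample without replacement from all lncRNA-protein pairs that are
#' not known positives.
#'
#' @param lncRNAs,proteins character vectors of candidate node ids.
#' @param positives data.frame (`lnc`, `prot`) of known interactions.
#' @param count number of pairs.
#' @param seed integer seed.
#' @return data.frame with columns `lnc`, `prot`.
#' @export
sample_random <- function(lncRNAs, proteins, positives, count, seed = 1L) {
  positives <- as_pair_df(positives, "positives")
  count <- check_count(count, "count")
  all_keys <- as.vector(outer(lncRNAs, proteins, pair_key))
  pos_keys <- pair_key(positives$lnc, positives$prot)
  sample_pairs_keys(setdiff(all_keys, pos_keys), count, seed)
}

#' Subcellular-localization negative sampling
#'
#' Under the assumption that molecules never found in the same compartment
#' cannot interact, candidate negatives are pairs whose compartment sets are
#' disjoint; positives are excluded.
#'
#' @param localization named list: molecule id -> compartment labels (as from
#'   [read_localization()]).
#' @param lncRNAs,proteins character vectors of candidate node ids.
#' @param positives data.frame (`lnc`, `prot`).
#' @param count number of pairs.
#' @param seed integer seed.
#' @return data.frame with columns `lnc`, `prot`.
#' @export
sample_subcellular <- function(localization, lncRNAs, proteins, positives,
                               count, seed = 1L) {
  positives <- as_pair_df(positives, "positives")
  count <- check_count(count, "count")
  missing <- setdiff(c(lncRNAs, proteins), names(localization))
  if (length(missing) > 0L) {
    stop("no localization annotation for: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  eligible <- eligible_subcellular(localization, lncRNAs, proteins)
  pos_keys <- pair_key(positives$lnc, positives$prot)
  keys <- setdiff(eligible, pos_keys)
  if (length(keys) == 0L) {
    stop(sprintf(paste0("no compartment-disjoint candidate pairs ",
                        "(%d lncRNAs x %d proteins, %d positives excluded)"),
                 length(lncRNAs), length(proteins), length(pos_keys)),
         call. = FALSE)
  }
  sample_pairs_keys(keys, count, seed)
}

# keys of compartment-disjoint (lncRNA, protein) pairs
eligible_subcellular <- function(localization, lncRNAs, proteins) {
  keys <- character()
  for (l in lncRNAs) {
    cl <- localization[[l]]
    ok <- vapply(proteins,
                 function(p) length(intersect(cl, localization[[p]])) == 0L,
                 TRUE)
    if (any(ok)) keys <- c(keys, pair_key(l, proteins[ok]))
  }
  keys
}

#' Shortest-path distances between lncRNAs and proteins in the prior network
#'
#' Breadth-first-search distances over the unweighted bipartite graph of
#' prior (training) interactions. In a bipartite graph every finite
#' lncRNA-protein distance is odd; pairs in different components have
#' distance `Inf`.
#'
#' @param prior_positives data.frame (`lnc`, `prot`) of prior interactions.
#' @param lncRNAs,proteins node ids to include (defaults: all endpoint ids).
#' @return Numeric matrix of distances, lncRNAs x proteins.
#' @export
interaction_distances <- function(prior_positives, lncRNAs = NULL,
                                  proteins = NULL) {
  prior <- as_pair_df(prior_positives, "prior_positives")
  if (is.null(lncRNAs)) lncRNAs <- unique(prior$lnc)
  if (is.null(proteins)) proteins <- unique(prior$prot)
  check_namespaces(lncRNAs, proteins)
  vertices <- data.frame(name = c(lncRNAs, proteins),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(u = prior$lnc, v = prior$prot, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vertices
  )
  d <- igraph::distances(g, v = lncRNAs, to = proteins)
  d
}

#' Distance-based negative sampling
#'
#' Candidates are lncRNA-protein pairs whose shortest-path distance `d` in
#' the prior interaction network satisfies
#' `distance_min <= d <= distance_max`. Distance-1 pairs (the positives
#' themselves) are excluded by requiring `distance_min > 1`; unreachable
#' pairs (infinite distance) never qualify for bounded specs.
#'
#' @param prior_positives data.frame (`lnc`, `prot`) of prior interactions
#'   (training positives only, so held-out labels cannot leak).
#' @param spec a `negative_spec` with `strategy = "distance"` (or a shorthand
#'   name accepted by [negative_spec()]).
#' @param lncRNAs,proteins node ids to consider (defaults: prior endpoints).
#' @param count number of pairs; overrides `spec$count`.
#' @param seed integer seed; overrides `spec$seed`.
#' @return data.frame with columns `lnc`, `prot`.
#' @export
sample_by_distance <- function(prior_positives, spec, lncRNAs = NULL,
                               proteins = NULL, count = NULL, seed = NULL) {
  if (is.character(spec)) spec <- negative_spec(spec)
  stopifnot(inherits(spec, "negative_spec"))
  if (spec$strategy != "distance") {
    stop("spec strategy must be 'distance'", call. = FALSE)
  }
  count <- check_count(if (is.null(count)) spec$count else count, "count")
  if (is.null(seed)) seed <- spec$seed
  cand <- distance_candidates(prior_positives, spec$distance_min,
                              spec$distance_max, lncRNAs, proteins)
  if (nrow(cand) < count) {
    stop(sprintf(paste0("only %d pair(s) at distance in [%d, %d] but %d ",
                        "requested"),
                 nrow(cand), spec$distance_min, spec$distance_max, count),
         call. = FALSE)
  }
  sample_pairs_keys(pair_key(cand$lnc, cand$prot), count, seed)
}

#' Enumerate distance-band candidate pairs
#'
#' @inheritParams sample_by_distance
#' @param distance_min,distance_max inclusive distance bounds.
#' @return data.frame with columns `lnc`, `prot`, `distance`.
#' @export
distance_candidates <- function(prior_positives, distance_min, distance_max,
                                lncRNAs = NULL, proteins = NULL) {
  d <- interaction_distances(prior_positives, lncRNAs, proteins)
  idx <- which(d >= distance_min & d <= distance_max & is.finite(d),
               arr.ind = TRUE)
  out <- data.frame(lnc = rownames(d)[idx[, 1L]],
                    prot = colnames(d)[idx[, 2L]],
                    distance = d[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$lnc, out$prot), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw negatives under any strategy
#'
#' Dispatches to [sample_random()], [sample_subcellular()] or
#' [sample_by_distance()] according to the spec.
#'
#' @param spec a `negative_spec` (or strategy name string).
#' @param lncRNAs,proteins candidate node ids.
#' @param positives data.frame (`lnc`, `prot`) to exclude; also the prior
#'   network for the distance strategy.
#' @param count number of pairs; defaults to `nrow(positives)` (balanced
#'   classes).
#' @param seed integer seed; overrides `spec$seed`.
#' @param localization named list of compartment labels (required for the
#'   subcellular strategy).
#' @return data.frame with columns `lnc`, `prot`.
#' @export
sample_negatives <- function(spec, lncRNAs, proteins, positives,
                             count = NULL, seed = NULL, localization = NULL) {
  if (is.character(spec)) spec <- negative_spec(spec)
  if (is.null(count)) count <- nrow(as_pair_df(positives, "positives"))
  if (is.null(seed)) seed <- spec$seed
  switch(spec$strategy,
    random = sample_random(lncRNAs, proteins, positives, count, seed),
    subcellular = {
      if (is.null(localization)) {
        stop("subcellular strategy requires `localization`", call. = FALSE)
      }
      sample_subcellular(localization, lncRNAs, proteins, positives, count,
                         seed)
    },
    distance = sample_by_distance(positives, spec, lncRNAs, proteins,
                                  count = count, seed = seed)
  )
}
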