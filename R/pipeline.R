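#' Default pipeline configuration
#'
#' Central place for the tunable knobs of the full prediction pipeline.
#' `network.variant` selects the ablation: `"KNet"` (interaction edges
#' only), `"KJNet"` (+ Jaccard similarity), `"KBNet"` (+ alignment
#' similarity) or `"full"` (KJNet and KBNet embedded independently and
#' spliced).
#'
#' @param ... overrides for any default, using the dotted key names below.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    split.ratio = 0.9,
    split.repeats = 3L,
    split.seed = 1L,
    network.variant = "full",
    negatives.strategy = "subcellular",
    walk.num_walks = 10L,
    walk.length = 80L,
    walk.schemes = c("LPLPL", "LLPPLL"),
    embed.dim = 64L,
    embed.window = 5L,
    embed.epochs = 5L,
    embed.negative = 5L,
    embed.seed = 1L,
    svm.C = 1,
    svm.gamma = "scale",
    jaccard.lnc_threshold = 0.5,
    jaccard.prot_threshold = 0,
    evalue.lnc_cutoff = 1e-3,
    evalue.prot_cutoff = 1e-2
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys match [pipeline_config()] (dotted or nested form).
#'
#' @param path path to a YAML config file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files requires the 'yaml' package", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (k in names(raw)) {
    if (is.list(raw[[k]])) {
      for (k2 in names(raw[[k]])) {
        flat[[paste(k, k2, sep = ".")]] <- raw[[k]][[k2]]
      }
    } else {
      flat[[k]] <- raw[[k]]
    }
  }
  do.call(pipeline_config, flat)
}

#' Build a labelled, partitioned interaction dataset
#'
#' Per repeat: positives are split into train/test at `ratio`; negatives
#' (equal in number to the positives, for balanced classes) are drawn fresh
#' under the chosen strategy and split at the same ratio. For the distance
#' strategy, shortest-path distances are computed on the repeat's *training*
#' positives only, and any candidate that coincides with a known positive
#' (train or test) is excluded so labels stay consistent.
#'
#' @param positives data.frame (`lnc`, `prot`) of all known interactions.
#' @param lncRNAs,proteins candidate node ids (defaults: positive endpoints).
#' @param strategy a `negative_spec` or strategy name (default
#'   `"subcellular"` when `localization` is given, else `"random"`).
#' @param localization named list of compartment labels (for the
#'   subcellular strategy).
#' @param ratio train fraction (default 0.9).
#' @param repeats number of repeats (default 3).
#' @param seed integer seed.
#' @return An `interaction_dataset` (see [split_dataset()]).
#' @export
build_dataset <- function(positives, lncRNAs = NULL, proteins = NULL,
                          strategy = NULL, localization = NULL,
                          ratio = 0.9, repeats = 3L, seed = 1L) {
  positives <- as_pair_df(positives, "positives")
  if (is.null(lncRNAs)) lncRNAs <- unique(positives$lnc)
  if (is.null(proteins)) proteins <- unique(positives$prot)
  if (is.null(strategy)) {
    strategy <- if (!is.null(localization)) "subcellular" else "random"
  }
  spec <- if (is.character(strategy)) negative_spec(strategy) else strategy
  stopifnot(inherits(spec, "negative_spec"))
  repeats <- check_count(repeats, "repeats")
  n_pos <- nrow(positives)
  if (n_pos < 10L) stop("need at least 10 positive pairs", call. = FALSE)
  pos_keys <- pair_key(positives$lnc, positives$prot)

  split_idx <- function(n, r_seed) {
    n_train <- max(1L, min(n - 1L, round(n * ratio)))
    local_seed(r_seed, sample.int(n, n_train))
  }

  reps <- lapply(seq_len(repeats), function(r) {
    base <- seed * 1000L + r
    tr <- split_idx(n_pos, base)
    train_pos <- positives[tr, , drop = FALSE]
    test_pos <- positives[-tr, , drop = FALSE]

    negs <- if (spec$strategy == "distance") {
      cand <- distance_candidates(train_pos, spec$distance_min,
                                  spec$distance_max, lncRNAs, proteins)
      keys <- setdiff(pair_key(cand$lnc, cand$prot), pos_keys)
      if (length(keys) < n_pos) {
        stop(sprintf(
          "only %d distance-band candidate(s) for %d negatives (repeat %d)",
          length(keys), n_pos, r), call. = FALSE)
      }
      sample_pairs_keys(keys, n_pos, base + 500L)
    } else {
      sample_negatives(spec, lncRNAs, proteins, positives, count = n_pos,
                       seed = base + 500L, localization = localization)
    }
    tr_n <- split_idx(n_pos, base + 900L)
    part_pos <- rep("test", n_pos); part_pos[tr] <- "train"
    part_neg <- rep("test", n_pos); part_neg[tr_n] <- "train"
    rbind(
      data.frame(lnc = positives$lnc, prot = positives$prot, label = 1L,
                 rep = r, part = part_pos, stringsAsFactors = FALSE),
      data.frame(lnc = negs$lnc, prot = negs$prot, label = 0L, rep = r,
                 part = part_neg, stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  structure(out, ratio = ratio, repeats = repeats, seed = seed,
            strategy = spec$strategy,
            class = c("interaction_dataset", "data.frame"))
}

# similarity graphs for one repeat's training positives
repeat_networks <- function(train_pos, variant, lnc_hits, prot_hits,
                            extra_nodes, cfg) {
  jac <- function() {
    assoc <- association_sets(train_pos)
    list(
      lnc = build_jaccard_graph(assoc, "lncRNA",
                                threshold = cfg$jaccard.lnc_threshold),
      prot = build_jaccard_graph(assoc, "protein",
                                 threshold = cfg$jaccard.prot_threshold)
    )
  }
  aln <- function() {
    list(
      lnc = build_alignment_graph(lnc_hits, "lncRNA",
                                  evalue_cutoff = cfg$evalue.lnc_cutoff),
      prot = build_alignment_graph(prot_hits, "protein",
                                   evalue_cutoff = cfg$evalue.prot_cutoff)
    )
  }
  switch(variant,
    KNet = list(assemble_network(train_pos, extra_nodes = extra_nodes)),
    KJNet = {
      j <- jac()
      list(assemble_network(train_pos, j$lnc, j$prot,
                            extra_nodes = extra_nodes))
    },
    KBNet = {
      a <- aln()
      list(assemble_network(train_pos, a$lnc, a$prot,
                            extra_nodes = extra_nodes))
    },
    full = {
      j <- jac(); a <- aln()
      list(assemble_network(train_pos, j$lnc, j$prot,
                            extra_nodes = extra_nodes),
           assemble_network(train_pos, a$lnc, a$prot,
                            extra_nodes = extra_nodes))
    },
    stop("unknown network variant: ", variant, call. = FALSE)
  )
}

#' Run one train/evaluate repeat of the full pipeline
#'
#' Assembles the heterogeneous network(s) from the training positives,
#' embeds them with meta-path walks + skip-gram, splices node features
#' (full variant), builds pair features, trains the RBF-SVM on the training
#' pairs and evaluates on the held-out test pairs. Walks can never traverse
#' a held-out edge because held-out positives are not part of the assembled
#' network.
#'
#' @param train_pos,train_neg data.frames (`lnc`, `prot`) of training pairs.
#' @param test data.frame (`lnc`, `prot`, `label`) of held-out pairs.
#' @param lnc_hits,prot_hits alignment-hit tables (needed for KBNet/full).
#' @param config list from [pipeline_config()].
#' @param seed integer seed for walks/embedding.
#' @return An `evaluation_report` with an extra `node_features` attribute
#'   (dimensions only).
#' @export
run_repeat <- function(train_pos, train_neg, test, lnc_hits = NULL,
                       prot_hits = NULL, config = pipeline_config(),
                       seed = 1L) {
  cfg <- config
  train_pos <- as_pair_df(train_pos, "train_pos")
  train_neg <- as_pair_df(train_neg, "train_neg")
  stopifnot(is.data.frame(test), all(c("lnc", "prot", "label") %in%
                                       names(test)))
  variant <- cfg$network.variant
  if (variant %in% c("KBNet", "full") &&
      (is.null(lnc_hits) || is.null(prot_hits))) {
    stop("variant ", variant, " needs alignment hit tables", call. = FALSE)
  }
  extra_nodes <- list(
    lnc = unique(c(train_pos$lnc, train_neg$lnc, test$lnc)),
    prot = unique(c(train_pos$prot, train_neg$prot, test$prot))
  )
  nets <- repeat_networks(train_pos, variant, lnc_hits, prot_hits,
                          extra_nodes, cfg)
  all_nodes <- unique(unlist(lapply(nets, function(g) igraph::V(g)$name)))
  embs <- lapply(seq_along(nets), function(i) {
    emb <- embed_network(
      nets[[i]], schemes = as.list(cfg$walk.schemes),
      dim = cfg$embed.dim, num_walks = cfg$walk.num_walks,
      walk_length = cfg$walk.length, window = cfg$embed.window,
      epochs = cfg$embed.epochs, negative = cfg$embed.negative,
      seed = seed + (i - 1L) * 97L
    )
    # align row universe across networks
    miss <- setdiff(all_nodes, rownames(emb))
    if (length(miss) > 0L) {
      emb <- rbind(emb, matrix(0, length(miss), ncol(emb),
                               dimnames = list(miss, NULL)))
    }
    emb[all_nodes, , drop = FALSE]
  })
  node_feats <- if (length(embs) == 2L) {
    splice_node_features(embs[[1L]], embs[[2L]])
  } else {
    embs[[1L]]
  }
  train_pairs <- rbind(
    data.frame(lnc = train_pos$lnc, prot = train_pos$prot, label = 1L,
               stringsAsFactors = FALSE),
    data.frame(lnc = train_neg$lnc, prot = train_neg$prot, label = 0L,
               stringsAsFactors = FALSE)
  )
  x_train <- pair_features(node_feats, train_pairs)
  x_test <- pair_features(node_feats, test)
  clf <- train_classifier(x_train, C = cfg$svm.C, gamma = cfg$svm.gamma,
                          seed = seed)
  pred <- predict(clf, x_test)
  rep_ <- evaluate_predictions(test$label, pred$label, pred$score)
  rep_$dims <- c(embed = ncol(embs[[1L]]), node = ncol(node_feats),
                 pair = ncol(x_train))
  rep_
}

#' Cross-repeat evaluation of the full pipeline
#'
#' Runs [run_repeat()] for every repeat in the dataset and reports
#' per-repeat metrics plus their mean (the headline numbers).
#'
#' @param dataset an `interaction_dataset` (from [build_dataset()] or
#'   [split_dataset()]).
#' @param lnc_hits,prot_hits alignment-hit tables (for KBNet/full variants).
#' @param config list from [pipeline_config()].
#' @param seed integer base seed for walks/embedding (per-repeat seeds are
#'   derived from it).
#' @return List with `per_repeat` (list of `evaluation_report`s) and `mean`
#'   (named vector: PRE, REC, SPE, ACC, MCC, F1, AUC averaged over repeats).
#' @export
cross_repeat_evaluate <- function(dataset, lnc_hits = NULL, prot_hits = NULL,
                                  config = pipeline_config(), seed = 1L) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  repeats <- attr(dataset, "repeats")
  reports <- lapply(seq_len(repeats), function(r) {
    tryCatch(
      run_repeat(
        train_pos = dataset_part(dataset, r, "train", label = 1L),
        train_neg = dataset_part(dataset, r, "train", label = 0L),
        test = dataset_part(dataset, r, "test"),
        lnc_hits = lnc_hits, prot_hits = prot_hits, config = config,
        seed = seed + (r - 1L) * 1009L
      ),
      error = function(e) {
        stop("repeat ", r, ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  per_metric <- vapply(reports, function(rp) c(rp$metrics, AUC = rp$auc),
                       numeric(7L))
  list(per_repeat = reports,
       mean = rowMeans(per_metric),
       per_repeat_metrics = t(per_metric))
}
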