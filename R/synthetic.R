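#' Specify a planted-block synthetic benchmark
#'
#' Nodes of both types are assigned to `k_blocks` blocks; interactions occur
#' with probability `p_within` when lncRNA and protein share a block and
#' `p_between` otherwise. Similarity edges (emitted as synthetic alignment
#' hits) connect same-type pairs within a block and, with flip probability
#' `sim_noise`, across blocks. Blocks double as subcellular compartments, so
#' cross-block pairs are compartment-disjoint — the ground truth that the
#' localization-based negative sampling assumes.
#'
#' @param n_lnc number of lncRNAs (default 150).
#' @param n_prot number of proteins (default 30).
#' @param k_blocks number of planted blocks (default 3).
#' @param p_within interaction probability within a block (default 0.6).
#' @param p_between interaction probability across blocks (default 0.02).
#' @param sim_noise probability that a similarity edge flips block membership
#'   (default 0.05).
#' @param seed integer seed.
#' @return A `planted_network_spec` list.
#' @export
planted_network_spec <- function(n_lnc = 150L, n_prot = 30L, k_blocks = 3L,
                                 p_within = 0.6, p_between = 0.02,
                                 sim_noise = 0.05, seed = 1L) {
  n_lnc <- check_count(n_lnc, "n_lnc")
  n_prot <- check_count(n_prot, "n_prot")
  k_blocks <- check_count(k_blocks, "k_blocks")
  if (k_blocks > min(n_lnc, n_prot)) {
    stop("k_blocks must not exceed min(n_lnc, n_prot)", call. = FALSE)
  }
  check_scalar_number(p_within, "p_within", 0, 1)
  check_scalar_number(p_between, "p_between", 0, 1)
  if (p_between >= p_within) {
    stop("p_between must be < p_within", call. = FALSE)
  }
  check_scalar_number(sim_noise, "sim_noise", 0, 1)
  structure(list(n_lnc = n_lnc, n_prot = n_prot, k_blocks = k_blocks,
                 p_within = p_within, p_between = p_between,
                 sim_noise = sim_noise, seed = as.integer(seed)),
            class = "planted_network_spec")
}

# synthetic alignment hits for same-type pairs: a "hit" pair gets a strong
# e-value, others none; within-block pairs hit with prob 1 - sim_noise,
# cross-block pairs with prob sim_noise
synth_hits <- function(ids, blocks, sim_noise) {
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(query = character(), subject = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(n, 2L)
  same <- blocks[ids[pairs[1L, ]]] == blocks[ids[pairs[2L, ]]]
  p_hit <- ifelse(same, 1 - sim_noise, sim_noise)
  hit <- stats::runif(ncol(pairs)) < p_hit
  if (!any(hit)) {
    return(data.frame(query = character(), subject = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  ev <- 10^(-stats::runif(sum(hit), 10, 50))
  data.frame(query = ids[pairs[1L, hit]],
             subject = ids[pairs[2L, hit]],
             evalue = ev,
             bitscore = round(-log10(ev) * 2, 1L),
             stringsAsFactors = FALSE)
}

#' Generate a planted-block lncRNA-protein benchmark
#'
#' Deterministic given the spec's seed. Produces everything a pipeline run
#' needs: interactions, synthetic alignment-hit tables for both node types,
#' a localization table (one compartment per block) and the ground-truth
#' block assignment.
#'
#' @param spec a `planted_network_spec`.
#' @return List with `interactions` (data.frame `lnc`, `prot`), `lnc_hits`
#'   and `prot_hits` (alignment-hit data.frames), `localization` (named list
#'   id -> compartment), `blocks` (named integer vector over all node ids),
#'   and the `spec`.
#' @export
generate_planted_network <- function(spec) {
  stopifnot(inherits(spec, "planted_network_spec"))
  local_seed(spec$seed, {
    lnc_ids <- sprintf("L%03d", seq_len(spec$n_lnc))
    prot_ids <- sprintf("P%03d", seq_len(spec$n_prot))
    # round-robin assignment guarantees every block holds both node types
    lnc_block <- ((seq_len(spec$n_lnc) - 1L) %% spec$k_blocks) + 1L
    prot_block <- ((seq_len(spec$n_prot) - 1L) %% spec$k_blocks) + 1L
    lnc_block <- sample(lnc_block)
    prot_block <- sample(prot_block)
    blocks <- stats::setNames(c(lnc_block, prot_block),
                              c(lnc_ids, prot_ids))

    grid <- expand.grid(lnc = lnc_ids, prot = prot_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    same <- blocks[grid$lnc] == blocks[grid$prot]
    p <- ifelse(same, spec$p_within, spec$p_between)
    keep <- stats::runif(nrow(grid)) < p
    interactions <- grid[keep, , drop = FALSE]
    rownames(interactions) <- NULL
    if (nrow(interactions) == 0L) {
      stop("spec produced an empty positive set", call. = FALSE)
    }

    lnc_hits <- synth_hits(lnc_ids, blocks, spec$sim_noise)
    prot_hits <- synth_hits(prot_ids, blocks, spec$sim_noise)

    localization <- as.list(stats::setNames(
      sprintf("compartment_%d", blocks), names(blocks)))

    list(interactions = interactions, lnc_hits = lnc_hits,
         prot_hits = prot_hits, localization = localization,
         blocks = blocks, lnc_ids = lnc_ids, prot_ids = prot_ids,
         spec = spec)
  })
}

#' Generate block-structured synthetic sequences
#'
#' One random ancestor sequence per block; each member is a point-mutated
#' copy of its block's ancestor, so within-block sequence identity exceeds
#' between-block identity.
#'
#' @param blocks named integer vector: id -> block (as from
#'   [generate_planted_network()], possibly subset to one node type).
#' @param length sequence length (default 200).
#' @param alphabet character vector of residues (default `c("A","C","G","T")`).
#' @param mutation_rate per-site mutation probability in `[0, 0.5]`
#'   (default 0.1).
#' @param seed integer seed.
#' @return Named character vector of sequences (a FASTA map).
#' @export
generate_sequences <- function(blocks, length = 200L,
                               alphabet = c("A", "C", "G", "T"),
                               mutation_rate = 0.1, seed = 1L) {
  check_scalar_number(mutation_rate, "mutation_rate", 0, 0.5)
  length <- check_count(length, "length")
  local_seed(seed, {
    ks <- sort(unique(blocks))
    ancestors <- lapply(ks, function(k) {
      sample(alphabet, length, replace = TRUE)
    })
    names(ancestors) <- as.character(ks)
    seqs <- vapply(names(blocks), function(id) {
      s <- ancestors[[as.character(blocks[[id]])]]
      mut <- stats::runif(length) < mutation_rate
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(ch) {
          sample(setdiff(alphabet, ch), 1L)
        }, "")
      }
      paste(s, collapse = "")
    }, "")
    seqs
  })
}

#' Toy identity-based alignment scorer (synthetic stand-in for BLAST)
#'
#' Scores every unordered pair of equal-length sequences by Hamming identity
#' and converts identity into a pseudo e-value:
#' `evalue = 10^(-(identity - baseline) * scale)`, so identity at or below
#' the random-match baseline maps to e-values >= 1 (never passing the graph
#' cutoffs) and near-identical sequences map to very small e-values. It is a
#' monotone toy score for exercising the alignment-similarity path, not an
#' alignment statistic.
#'
#' @param seqs named character vector of equal-length sequences.
#' @param baseline expected identity of unrelated sequences (default 0.25,
#'   uniform nucleotides).
#' @param scale steepness of the identity-to-e-value map (default 40).
#' @return data.frame with columns `query`, `subject`, `evalue`, `bitscore`.
#' @export
identity_hits <- function(seqs, baseline = 0.25, scale = 40) {
  n <- length(seqs)
  stopifnot(n >= 2L, length(unique(nchar(seqs))) == 1L)
  ids <- names(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  pairs <- utils::combn(n, 2L)
  ident <- apply(pairs, 2L, function(ij) {
    mean(mat[ij[1L], ] == mat[ij[2L], ])
  })
  ev <- 10^(-(ident - baseline) * scale)
  data.frame(query = ids[pairs[1L, ]], subject = ids[pairs[2L, ]],
             evalue = ev, bitscore = round(ident * 100, 1L),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture directory
#'
#' Emits `edges.tsv`, `lnc.fasta`, `prot.fasta`, `localization.tsv` and
#' `truth.json` (block assignment and generator settings) for a planted
#' benchmark.
#'
#' @param spec a `planted_network_spec`.
#' @param dir output directory (created if absent).
#' @param seq_length synthetic sequence length.
#' @param mutation_rate per-site mutation rate for the sequences.
#' @return Invisibly, the generated network list.
#' @export
write_fixture_dir <- function(spec, dir, seq_length = 200L,
                              mutation_rate = 0.1) {
  net <- generate_planted_network(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(net$interactions, file.path(dir, "edges.tsv"))
  lnc_seqs <- generate_sequences(net$blocks[net$lnc_ids],
                                 length = seq_length,
                                 mutation_rate = mutation_rate,
                                 seed = spec$seed + 1L)
  prot_seqs <- generate_sequences(net$blocks[net$prot_ids],
                                  length = seq_length,
                                  mutation_rate = mutation_rate,
                                  seed = spec$seed + 2L)
  write_fasta(lnc_seqs, file.path(dir, "lnc.fasta"))
  write_fasta(prot_seqs, file.path(dir, "prot.fasta"))
  write_localization(net$localization, file.path(dir, "localization.tsv"))
  jsonlite::write_json(
    list(blocks = as.list(net$blocks), spec = unclass(spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(net)
}
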