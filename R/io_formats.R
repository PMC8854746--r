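#' Read a two-column interaction edge list
#'
#' Each non-comment line holds at least two tab-separated fields: a lncRNA
#' identifier and a protein identifier. Duplicate pairs are collapsed to the
#' first occurrence, preserving first-seen order. Lines starting with `#` are
#' skipped.
#'
#' @param path path to a TSV file.
#' @return A data.frame with character columns `lnc` and `prot`, one row per
#'   unique interaction.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty edge list: ", path, call. = FALSE)
    return(data.frame(lnc = character(), prot = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    stop(sprintf("malformed edge line %d: expected >= 2 tab-separated fields",
                 bad), call. = FALSE)
  }
  lnc <- vapply(parts, `[[`, "", 1L)
  prot <- vapply(parts, `[[`, "", 2L)
  check_ids(lnc, "lncRNA id")
  check_ids(prot, "protein id")
  dup <- duplicated(paste(lnc, prot, sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) collapsed")
  }
  data.frame(lnc = lnc[!dup], prot = prot[!dup], stringsAsFactors = FALSE)
}

#' Write an interaction edge list
#'
#' @param edges data.frame with columns `lnc` and `prot`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(is.data.frame(edges), all(c("lnc", "prot") %in% names(edges)))
  writeLines(paste(edges$lnc, edges$prot, sep = "\t"), path)
  invisible(path)
}

#' Read pairwise alignment hits in BLAST tabular format
#'
#' Parses the 12-column tab-separated `outfmt 6` dialect (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore). Only the
#' query id, subject id, e-value and bitscore are retained. Self-hits
#' (query == subject) are dropped, and multiple HSPs for the same ordered pair
#' are collapsed to the one with the minimum e-value.
#'
#' @param path path to a BLAST tabular file.
#' @return A data.frame with columns `query`, `subject`, `evalue`, `bitscore`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  empty <- data.frame(query = character(), subject = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(keep)) return(empty)
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L)) {
    bad <- idx[which(nf < 12L)[1L]]
    stop(sprintf("malformed BLAST tabular line %d: expected 12 columns", bad),
         call. = FALSE)
  }
  query <- vapply(parts, `[[`, "", 1L)
  subject <- vapply(parts, `[[`, "", 2L)
  ev_raw <- vapply(parts, `[[`, "", 11L)
  bs_raw <- vapply(parts, `[[`, "", 12L)
  evalue <- suppressWarnings(as.numeric(ev_raw))
  bitscore <- suppressWarnings(as.numeric(bs_raw))
  if (anyNA(evalue)) {
    bad <- idx[which(is.na(evalue))[1L]]
    stop(sprintf("non-numeric e-value at line %d", bad), call. = FALSE)
  }
  if (any(evalue < 0)) {
    bad <- idx[which(evalue < 0)[1L]]
    stop(sprintf("negative e-value at line %d", bad), call. = FALSE)
  }
  self <- query == subject
  if (any(self)) message(sum(self), " self-hit(s) dropped")
  hits <- data.frame(query = query[!self], subject = subject[!self],
                     evalue = evalue[!self], bitscore = bitscore[!self],
                     stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  # best HSP per ordered pair: minimum e-value, its bitscore
  ord <- order(hits$query, hits$subject, hits$evalue, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(paste(hits$query, hits$subject, sep = "\r"))
  hits <- hits[first, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.fasta_alphabets <- list(
  nt = c(strsplit("ACGTUNRYSWKMBDHV", "")[[1]]),
  aa = c(strsplit("ACDEFGHIKLMNPQRSTVWYBXZJUO*", "")[[1]])
)

#' Read a FASTA file into a named character vector
#'
#' Identifiers are the header token up to the first whitespace; sequences are
#' uppercased. Duplicate identifiers and characters outside the IUPAC
#' nucleotide or amino-acid alphabets raise errors.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"auto"`, `"nt"` or `"aa"`; with `"auto"` a sequence is
#'   accepted if it fits either alphabet.
#' @return Named character vector of uppercased sequences.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nt", "aa")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("[[:space:]].*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  allowed <- switch(alphabet,
    nt = .fasta_alphabets$nt,
    aa = .fasta_alphabets$aa,
    auto = union(.fasta_alphabets$nt, .fasta_alphabets$aa)
  )
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L) {
      stop(sprintf("record '%s' contains invalid characters: %s",
                   ids[i], paste(bad, collapse = "")), call. = FALSE)
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a subcellular localization table
#'
#' TSV with two columns: molecule id and compartment label; a molecule may
#' appear on several lines, one per compartment.
#'
#' @param path path to the TSV file.
#' @return Named list mapping molecule id to a character vector of unique
#'   compartment labels.
#' @export
read_localization <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  if (!any(keep)) return(structure(list(), names = character()))
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    stop(sprintf("malformed localization line %d: expected 2 columns", bad),
         call. = FALSE)
  }
  id <- vapply(parts, `[[`, "", 1L)
  comp <- vapply(parts, `[[`, "", 2L)
  loc <- lapply(split(comp, id), unique)
  loc[unique(id)]
}

#' Write a subcellular localization table
#'
#' @param loc named list mapping molecule id to compartment labels.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_localization <- function(loc, path) {
  stopifnot(is.list(loc), !is.null(names(loc)))
  id <- rep(names(loc), lengths(loc))
  comp <- unlist(loc, use.names = FALSE)
  writeLines(paste(id, comp, sep = "\t"), path)
  invisible(path)
}

#' Write a node embedding table
#'
#' One line per node: id then coordinates, tab-separated, 6 significant
#' digits. A header line records the dimension as `dim=<d>`.
#'
#' @param emb numeric matrix with one row per node; rownames are node ids.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_embeddings <- function(emb, path) {
  if (is.list(emb) && !is.data.frame(emb)) {
    lens <- lengths(emb)
    if (length(unique(lens)) > 1L) stop("ragged vectors", call. = FALSE)
    emb <- do.call(rbind, emb)
  }
  stopifnot(is.matrix(emb), is.numeric(emb))
  if (nrow(emb) > 0L && is.null(rownames(emb))) {
    stop("embedding matrix must have rownames (node ids)", call. = FALSE)
  }
  header <- sprintf("dim=%d", ncol(emb))
  if (nrow(emb) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  vals <- apply(emb, 1L, function(v) {
    paste(formatC(v, digits = 6L, format = "g"), collapse = "\t")
  })
  writeLines(c(header, paste(rownames(emb), vals, sep = "\t")), path)
  invisible(path)
}

#' Read a node embedding table written by [write_embeddings()]
#'
#' @param path path to the embedding TSV.
#' @return Numeric matrix with node ids as rownames.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^dim=\\d+$", lines[1L])) {
    stop("missing 'dim=' header in ", path, call. = FALSE)
  }
  d <- as.integer(sub("^dim=", "", lines[1L]))
  body <- lines[-1L][nzchar(lines[-1L])]
  if (length(body) == 0L) {
    return(matrix(numeric(), nrow = 0L, ncol = d))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != d + 1L)) {
    stop("embedding row does not match header dimension", call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  if (d == 1L) m <- matrix(m, ncol = 1L)
  rownames(m) <- ids
  m
}
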