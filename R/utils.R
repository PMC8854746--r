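#' @useDynLib lpiembed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict sd var
#' @importFrom utils head
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps package functions deterministic without
# clobbering the user's random stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_ids <- function(ids, name) {
  if (!is.character(ids) || anyNA(ids) || any(!nzchar(ids)) ||
      any(grepl("[[:space:]]", ids))) {
    stop(sprintf("`%s` must be non-empty strings without whitespace", name),
         call. = FALSE)
  }
  invisible(ids)
}

#' Check that lncRNA and protein identifier namespaces are disjoint
#'
#' Typed heterogeneous graphs need unambiguous node typing, so one run must
#' never use the same identifier for both a lncRNA and a protein.
#'
#' @param lnc_ids character vector of lncRNA identifiers.
#' @param prot_ids character vector of protein identifiers.
#' @return Invisibly `TRUE`; errors listing offending ids otherwise.
#' @export
check_namespaces <- function(lnc_ids, prot_ids) {
  clash <- intersect(unique(lnc_ids), unique(prot_ids))
  if (length(clash) > 0L) {
    stop("lncRNA and protein identifier namespaces overlap: ",
         paste(head(clash, 5L), collapse = ", "),
         if (length(clash) > 5L) ", ..." else "", call. = FALSE)
  }
  invisible(TRUE)
}
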