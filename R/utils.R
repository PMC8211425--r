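#' @keywords internal
"_PACKAGE"

expit <- stats::plogis
logit <- stats::qlogis

## probabilities are kept strictly inside (0,1) before any logit
.PROB_EPS <- 1e-6

clip_prob <- function(p, eps = .PROB_EPS) pmin(pmax(p, eps), 1 - eps)

#' Derive a reproducible sub-stream seed from a global seed and a label
#'
#' Deterministic 32-bit mix of an integer seed and a character label, used to
#' give each pipeline stage (and each gene in a per-gene batch) its own
#' random-number stream while remaining reproducible from a single global
#' seed and invariant to batch order.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the stream (stage or gene id).
#' @return a non-negative integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(label)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

## run expr with a local RNG state seeded by `seed` (NULL = leave RNG alone)
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Split a numeric vector at its median into low/high groups
#'
#' Values strictly greater than the median are labelled `"high"`, all others
#' (including values exactly at the median) `"low"`. This is the dichotomy
#' used both for immune/stromal score groups and for gene-expression
#' exposures, so a single tie rule applies everywhere.
#'
#' @param x numeric vector, length >= 2.
#' @return factor with levels `c("low", "high")`, same length as `x`.
#' @examples
#' split_by_median(c(1, 2, 3, 4))
#' split_by_median(c(5, 5, 1, 9))  # only 9 is "high"
#' @export
split_by_median <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L, all(is.finite(x)))
  if (max(x) == min(x)) {
    stop("all values identical: median split is degenerate")
  }
  m <- stats::median(x)
  factor(ifelse(x > m, "high", "low"), levels = c("low", "high"))
}

## simple FNV-1a hash of a character string, for run manifests
fnv1a <- function(s) {
  h <- 2166136261
  for (k in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), k)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## log2 counts-per-million on a genes x samples count matrix
#' Log2 counts-per-million normalization
#'
#' @param counts non-negative genes x samples matrix.
#' @param prior pseudocount added after CPM scaling (default 1).
#' @return matrix of `log2(cpm + prior)` values, same dimnames.
#' @export
log2_cpm <- function(counts, prior = 1) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  log2(sweep(counts, 2, lib / 1e6, "/") + prior)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
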