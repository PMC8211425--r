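#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Single-sample rank-based gene-set enrichment score
#'
#' For one sample's expression profile, genes are ranked by expression
#' (highest expression = highest rank) and walked in decreasing order. The
#' in-set cumulative distribution climbs by `rank^weight_exponent`
#' (normalized over the set) at in-set genes; the out-of-set ECDF climbs by
#' `1/(N - m)` at the others. The score is the sum over all positions of the
#' difference between the two cumulative curves — positive when set members
#' concentrate among highly expressed genes. Because only ranks enter, the
#' score is invariant under strictly monotone transforms of the expression
#' values.
#'
#' @param expression named numeric vector of one sample's expression over
#'   the full gene universe (>= 2 genes).
#' @param set character vector of gene ids; must be a non-empty strict
#'   subset of `names(expression)`.
#' @param weight_exponent exponent applied to the ranks (default 0.25).
#' @return numeric enrichment score.
#' @export
ssgsea_score <- function(expression, set, weight_exponent = 0.25) {
  stopifnot(is.numeric(expression), length(expression) >= 2L,
            !is.null(names(expression)))
  set <- unique(set)
  in_set <- names(expression) %in% set
  m <- sum(in_set)
  if (m == 0L) stop("gene set does not intersect the expression universe")
  if (m == length(expression)) stop("gene set equals the full gene universe")
  r <- rank(expression, ties.method = "average")
  ord <- order(expression, decreasing = TRUE)
  w <- r^weight_exponent
  step_in <- ifelse(in_set, w, 0)[ord]
  step_in <- step_in / sum(step_in)
  step_out <- ifelse(in_set, 0, 1 / (length(expression) - m))[ord]
  sum(cumsum(step_in) - cumsum(step_out))
}

#' Immune, stromal and combined enrichment scores per sample
#'
#' Normalizes counts to log2(CPM + 1) and computes [ssgsea_score()] per
#' sample for the immune and stromal signatures; the combined score is their
#' sum, in the manner of ESTIMATE-style tumor-microenvironment scoring.
#' Signature genes absent from the count matrix are dropped with a warning.
#'
#' @param counts genes x samples count matrix.
#' @param immune,stromal character vectors of signature gene ids.
#' @param weight_exponent passed to [ssgsea_score()].
#' @return data.frame: `sample_id`, `immune_score`, `stromal_score`,
#'   `estimate_score` (= immune + stromal, exactly).
#' @export
estimate_scores <- function(counts, immune, stromal, weight_exponent = 0.25) {
  stopifnot(is.matrix(counts))
  keep_set <- function(set, label) {
    hit <- intersect(set, rownames(counts))
    if (length(hit) == 0L) stop(label, " signature does not intersect measured genes")
    if (length(hit) < length(set)) {
      warning(sprintf("%d %s signature gene(s) not measured; dropped",
                      length(set) - length(hit), label))
    }
    hit
  }
  immune <- keep_set(immune, "immune")
  stromal <- keep_set(stromal, "stromal")
  expr <- log2_cpm(counts)
  imm <- apply(expr, 2, ssgsea_score, set = immune,
               weight_exponent = weight_exponent)
  str <- apply(expr, 2, ssgsea_score, set = stromal,
               weight_exponent = weight_exponent)
  data.frame(sample_id = colnames(counts),
             immune_score = unname(imm),
             stromal_score = unname(str),
             estimate_score = unname(imm + str),
             stringsAsFactors = FALSE)
}
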