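#' Read a gene-level count matrix from TSV or MatrixMarket
#'
#' TSV layout: first column gene id, remaining columns one per sample.
#' MatrixMarket (`.mtx`) input requires companion `<stem>.genes.txt` and
#' `<stem>.samples.txt` files with one id per line.
#'
#' @param path file path.
#' @return integer matrix, genes x samples, with dimnames.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix_readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".genes.txt"))
    colnames(m) <- readLines(paste0(stem, ".samples.txt"))
  } else {
    df <- read_tsv(path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  if (any(m < 0)) stop("negative counts in ", path)
  storage.mode(m) <- "integer"
  m
}

## thin indirection so the Matrix dependency stays optional
Matrix_readMM <- function(path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("reading MatrixMarket input requires the Matrix package")
  }
  Matrix::readMM(path)
}

#' Read a clinical covariate table
#'
#' @param path TSV path with a header row.
#' @param column_map optional named character vector mapping canonical names
#'   (`sample_id`, `vital_status`, `os_time`, `sample_type`, ...) to the
#'   file's column names.
#' @param time_unit `"years"` or `"days"`; `os_time` is converted to years.
#' @return data.frame with canonical column names.
#' @export
read_clinical <- function(path, column_map = NULL,
                          time_unit = c("years", "days")) {
  time_unit <- match.arg(time_unit)
  df <- read_tsv(path)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("mapped column not found: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  if (!"sample_id" %in% names(df)) stop("clinical table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in clinical table")
  if ("os_time" %in% names(df) && time_unit == "days") {
    df$os_time <- df$os_time / 365.25
  }
  df
}

#' Define the binary mortality outcome at a follow-up horizon
#'
#' Y = 1 for patients who died before the horizon; Y = 0 for patients with
#' overall-survival time at or beyond the horizon (whatever their final
#' vital status: a death after the horizon still means the patient survived
#' the horizon); patients alive with follow-up shorter than the horizon are
#' excluded as outcome-indeterminate, as are patients with missing survival
#' time.
#'
#' @param clinical data.frame with `sample_id`, `vital_status`
#'   (`"alive"`/`"dead"`) and `os_time` in years.
#' @param horizon_years follow-up horizon (default 3).
#' @return list with `y` (named 0/1 integer vector over retained samples)
#'   and `excluded` (data.frame of `sample_id`, `reason`).
#' @export
define_outcome <- function(clinical, horizon_years = 3) {
  stopifnot(all(c("sample_id", "vital_status", "os_time") %in% names(clinical)),
            horizon_years > 0)
  t <- clinical$os_time
  if (any(!is.na(t) & t < 0)) stop("negative overall-survival time")
  dead <- clinical$vital_status == "dead"
  reason <- rep(NA_character_, nrow(clinical))
  reason[is.na(t)] <- "missing os_time"
  reason[!is.na(t) & !dead & t < horizon_years] <-
    "alive with follow-up shorter than horizon"
  keep <- is.na(reason)
  y <- ifelse(t[keep] >= horizon_years, 0L, 1L)  # dead & t<h is the only Y=1
  names(y) <- clinical$sample_id[keep]
  excluded <- data.frame(sample_id = clinical$sample_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  list(y = y, excluded = excluded)
}

#' Build the analysis cohort from clinical and count data
#'
#' Retains samples present in both tables, keeps primary tumors only, then
#' applies the outcome definition of [define_outcome()] at the configured
#' horizon. Sample ordering is made consistent across all outputs. Every
#' dropped sample is itemized with a reason.
#'
#' @param clinical clinical data.frame (see [read_clinical()]).
#' @param counts genes x samples count matrix.
#' @param horizon_years outcome horizon in years.
#' @return list with `clinical`, `counts`, `y` (named outcome vector) and
#'   `exclusions` (data.frame `sample_id`, `reason`).
#' @export
filter_samples <- function(clinical, counts, horizon_years = 3) {
  stopifnot(is.matrix(counts))
  exclusions <- data.frame(sample_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  note <- function(ids, why) {
    if (length(ids)) rbind(exclusions,
                           data.frame(sample_id = ids, reason = why,
                                      stringsAsFactors = FALSE))
    else exclusions
  }
  in_both <- intersect(clinical$sample_id, colnames(counts))
  exclusions <- note(setdiff(clinical$sample_id, colnames(counts)),
                     "no expression data")
  exclusions <- note(setdiff(colnames(counts), clinical$sample_id),
                     "no clinical data")
  cl <- clinical[match(in_both, clinical$sample_id), , drop = FALSE]
  if ("sample_type" %in% names(cl)) {
    rec <- cl$sample_id[cl$sample_type != "primary"]
    exclusions <- note(rec, "recurrent tumor sample")
    cl <- cl[cl$sample_type == "primary", , drop = FALSE]
  }
  out <- define_outcome(cl, horizon_years)
  exclusions <- rbind(exclusions, out$excluded)
  keep <- names(out$y)
  if (length(keep) == 0L) stop("no samples survive the cohort filters")
  cl <- cl[match(keep, cl$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  list(clinical = cl,
       counts = counts[, keep, drop = FALSE],
       y = out$y,
       exclusions = exclusions)
}
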