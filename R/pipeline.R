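#' Configuration for the full discovery pipeline
#'
#' Collects every tunable of the cohort -> scoring -> differential
#' expression -> screening -> confounder selection -> targeted estimation
#' flow. Inputs may be in-memory objects (count matrix, clinical data.frame,
#' signature list) or file paths (TSV / GMT); a YAML file with the same
#' field names can be loaded via [load_pipeline_config()].
#'
#' @param counts genes x samples count matrix, or path to a counts TSV.
#' @param clinical clinical data.frame, or path to a clinical TSV.
#' @param signatures named list with `immune` and `stromal` gene-id vectors,
#'   or path to a GMT file containing sets named `immune` and `stromal`.
#' @param out_dir run directory for all artifacts.
#' @param horizon_years outcome horizon (default 3).
#' @param time_unit survival-time unit in the clinical table.
#' @param column_map optional clinical column mapping, see
#'   [read_clinical()].
#' @param clinical_covariates clinical columns entered into screening; by
#'   default every column other than the identifier/outcome fields.
#' @param de_lfc_cut,de_fdr_cut,de_filter_rule differential-expression
#'   thresholds and low-count filter rule.
#' @param de_shrink_weight dispersion-shrinkage weight, see
#'   [nb_wald_test()].
#' @param screen_alpha univariate screening threshold.
#' @param covsel_threshold,covsel_engine confounder-selection settings.
#' @param sl_library,v_folds,g_bounds,sl_control targeted-estimation
#'   settings.
#' @param confounders_override optional character vector (or per-gene named
#'   list) of adjustment-set names that bypasses confounder selection.
#' @param validation optional list with `expr` (samples x genes matrix) and
#'   `labels` (0/1) for external validation, plus optional `alias_map`.
#' @param seed global integer seed; all stage streams derive from it.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts, clinical, signatures, out_dir,
                            horizon_years = 3,
                            time_unit = "years",
                            column_map = NULL,
                            clinical_covariates = NULL,
                            de_lfc_cut = 1.5, de_fdr_cut = 0.05,
                            de_filter_rule = "all_below",
                            de_shrink_weight = 0.5,
                            screen_alpha = 0.05,
                            covsel_threshold = 0.1, covsel_engine = "lrt",
                            sl_library = c("glm", "glm_interaction",
                                           "glmnet", "xgboost",
                                           "random_forest"),
                            v_folds = 10L,
                            g_bounds = c(0.025, 0.975),
                            sl_control = list(),
                            confounders_override = NULL,
                            validation = NULL,
                            seed = 1L) {
  stopifnot(screen_alpha >= 0, screen_alpha <= 1,
            de_fdr_cut > 0, de_fdr_cut <= 1, de_lfc_cut >= 0,
            covsel_threshold > 0, covsel_threshold < 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose fields mirror [pipeline_config()] arguments
#'   (file paths for `counts`, `clinical`, `signatures`).
#' @return a `"pipeline_config"`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

## resolve in-memory-or-path inputs
resolve_inputs <- function(cfg) {
  counts <- if (is.character(cfg$counts)) read_counts(cfg$counts) else cfg$counts
  clinical <- if (is.character(cfg$clinical)) {
    read_clinical(cfg$clinical, cfg$column_map, cfg$time_unit)
  } else cfg$clinical
  sigs <- if (is.character(cfg$signatures)) read_gmt(cfg$signatures)
          else cfg$signatures
  if (!all(c("immune", "stromal") %in% names(sigs))) {
    stop("signatures must provide sets named 'immune' and 'stromal'")
  }
  list(counts = counts, clinical = clinical, signatures = sigs)
}

stage_paths <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  list(clinical = file.path(dir, "cohort_clinical.tsv"),
       counts = file.path(dir, "cohort_counts.tsv"),
       outcome = file.path(dir, "outcome.tsv"),
       exclusions = file.path(dir, "exclusions.tsv"),
       scores = file.path(dir, "scores.tsv"),
       de_immune = file.path(dir, "de_immune.tsv"),
       de_stromal = file.path(dir, "de_stromal.tsv"),
       degs = file.path(dir, "degs_shared.tsv"),
       screening = file.path(dir, "screening.tsv"),
       exposures = file.path(dir, "exposures.tsv"),
       candidates = file.path(dir, "candidates.tsv"),
       covsel = file.path(dir, "covsel.json"),
       tmle = file.path(dir, "tmle.tsv"),
       validation = file.path(dir, "validation.json"),
       manifest = file.path(dir, "manifest.json"))
}

read_stage_path <- function(path, what) {
  if (!file.exists(path)) {
    stop("missing upstream artifact for this stage: ", basename(path),
         " (", what, ")")
  }
  path
}

read_stage <- function(path, what) read_tsv(read_stage_path(path, what))

#' @rdname run_pipeline
#' @export
stage_cohort <- function(cfg) {
  p <- stage_paths(cfg$out_dir)
  inp <- resolve_inputs(cfg)
  coh <- filter_samples(inp$clinical, inp$counts, cfg$horizon_years)
  write_tsv(coh$clinical, p$clinical)
  write_tsv(data.frame(gene_id = rownames(coh$counts), coh$counts,
                       check.names = FALSE), p$counts)
  write_tsv(data.frame(sample_id = names(coh$y), y = coh$y), p$outcome)
  write_tsv(coh$exclusions, p$exclusions)
  invisible(coh)
}

#' @rdname run_pipeline
#' @export
stage_scores <- function(cfg) {
  p <- stage_paths(cfg$out_dir)
  sigs <- resolve_inputs(cfg)$signatures
  counts <- read_counts(read_stage_path(p$counts, "cohort counts"))
  sc <- estimate_scores(counts, sigs$immune, sigs$stromal)
  write_tsv(sc, p$scores)
  invisible(sc)
}

#' @rdname run_pipeline
#' @export
stage_de <- function(cfg) {
  p <- stage_paths(cfg$out_dir)
  counts <- read_counts(read_stage_path(p$counts, "cohort counts"))
  sc <- read_stage(p$scores, "scores")
  filtered <- filter_low_counts(counts, cfg$de_filter_rule)
  run_one <- function(score) {
    grp <- split_by_median(score)
    nb_wald_test(filtered, grp, cfg$de_shrink_weight)
  }
  de_imm <- run_one(sc$immune_score)
  de_str <- run_one(sc$stromal_score)
  write_tsv(de_imm, p$de_immune)
  write_tsv(de_str, p$de_stromal)
  degs <- shared_degs(select_degs(de_imm, cfg$de_lfc_cut, cfg$de_fdr_cut),
                      select_degs(de_str, cfg$de_lfc_cut, cfg$de_fdr_cut))
  write_tsv(degs, p$degs)
  invisible(degs)
}

#' @rdname run_pipeline
#' @export
stage_screen <- function(cfg) {
  p <- stage_paths(cfg$out_dir)
  counts <- read_counts(read_stage_path(p$counts, "cohort counts"))
  clinical <- read_stage(p$clinical, "cohort clinical")
  outcome <- read_stage(p$outcome, "outcome")
  degs <- read_stage(p$degs, "shared DEGs")
  y <- stats::setNames(outcome$y, outcome$sample_id)
  covars <- cfg$clinical_covariates %||%
    setdiff(names(clinical),
            c("sample_id", "vital_status", "os_time", "sample_type"))
  scr <- screen_candidates(degs$gene, counts, clinical, covars, y,
                           cfg$screen_alpha)
  write_tsv(scr$results, p$screening)
  write_tsv(data.frame(sample_id = rownames(scr$exposures), scr$exposures,
                       check.names = FALSE), p$exposures)
  write_tsv(data.frame(variable = c(scr$candidate_genes,
                                    scr$candidate_clinical),
                       kind = rep(c("gene", "clinical"),
                                  c(length(scr$candidate_genes),
                                    length(scr$candidate_clinical)))),
            p$candidates)
  invisible(scr)
}

## assemble the covariate pool: candidate-gene exposures + screened clinical
covariate_pool <- function(cfg, p) {
  cand <- read_stage(p$candidates, "candidates")
  genes <- cand$variable[cand$kind == "gene"]
  clin_vars <- cand$variable[cand$kind == "clinical"]
  expo <- read_stage(p$exposures, "exposures")
  clinical <- read_stage(p$clinical, "cohort clinical")
  pool <- expo[, intersect(genes, names(expo)), drop = FALSE]
  for (v in clin_vars) {
    xv <- clinical[[v]][match(expo$sample_id, clinical$sample_id)]
    if (is.character(xv)) xv <- factor(xv)
    pool[[v]] <- xv
  }
  rownames(pool) <- expo$sample_id
  list(genes = genes, clin_vars = clin_vars, pool = pool,
       exposures = as.matrix(expo[, intersect(genes, names(expo)),
                                  drop = FALSE]))
}

#' @rdname run_pipeline
#' @export
stage_covsel <- function(cfg) {
  p <- stage_paths(cfg$out_dir)
  cp <- covariate_pool(cfg, p)
  outcome <- read_stage(p$outcome, "outcome")
  y <- outcome$y
  sets <- list()
  for (gene in cp$genes) {
    cands <- c(setdiff(cp$genes, gene), cp$clin_vars)
    cs <- select_confounders(cp$pool, y, cp$pool[[gene]], cands,
                             threshold = cfg$covsel_threshold,
                             engine = cfg$covsel_engine)
    sets[[gene]] <- list(gene = gene, V = cs$V, W = cs$W,
                         steps_V = cs$steps_V, steps_W = cs$steps_W)
  }
  jsonlite::write_json(sets, p$covsel, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sets)
}

#' @rdname run_pipeline
#' @export
stage_tmle <- function(cfg) {
  p <- stage_paths(cfg$out_dir)
  cp <- covariate_pool(cfg, p)
  outcome <- read_stage(p$outcome, "outcome")
  y <- outcome$y
  if (!is.null(cfg$confounders_override)) {
    ov <- cfg$confounders_override
    sets <- if (is.list(ov)) ov else
      stats::setNames(rep(list(ov), length(cp$genes)), cp$genes)
  } else {
    raw <- jsonlite::read_json(p$covsel, simplifyVector = TRUE)
    sets <- lapply(raw, function(s) unlist(s$W) %||% character())
    names(sets) <- vapply(raw, `[[`, "", "gene")
  }
  res <- run_per_gene(cp$genes, cp$exposures, cp$pool, y, sets,
                      seed = derive_seed(cfg$seed, "tmle"),
                      q_learners = cfg$sl_library,
                      g_learners = cfg$sl_library,
                      v_folds = cfg$v_folds,
                      g_bounds = cfg$g_bounds,
                      sl_control = cfg$sl_control)
  write_tsv(res$table, p$tmle)
  invisible(res)
}

#' @rdname run_pipeline
#' @export
stage_validate <- function(cfg) {
  if (is.null(cfg$validation)) return(invisible(NULL))
  p <- stage_paths(cfg$out_dir)
  v <- cfg$validation
  rep <- validation_report(v$expr, v$labels, v$alias_map)
  jsonlite::write_json(list(per_gene = rep$per_gene, combined = rep$combined),
                       p$validation, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes cohort construction, immune/stromal scoring, two
#' differential-expression contrasts with the shared-DEG intersection,
#' univariate screening, per-gene confounder selection, and per-gene
#' targeted estimation (plus optional external validation), writing every
#' stage's table into the run directory together with a machine-readable
#' manifest (configuration hash, seed, per-stage record counts). Each
#' `stage_*` function is independently runnable against the artifacts the
#' previous stage wrote, and a full run is byte-identical to running the
#' stages one by one with the same configuration.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the final targeted-estimation table and
#'   the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- stage_paths(cfg$out_dir)
  counts_stage <- function(f, name) {
    tryCatch(f(cfg), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  coh <- counts_stage(stage_cohort, "cohort")
  sc <- counts_stage(stage_scores, "scores")
  degs <- counts_stage(stage_de, "de")
  scr <- counts_stage(stage_screen, "screen")
  sets <- counts_stage(stage_covsel, "covsel")
  tm <- counts_stage(stage_tmle, "tmle")
  val <- counts_stage(stage_validate, "validate")
  manifest <- list(
    package_version = as.character(utils::packageVersion("tmecausal")),
    seed = cfg$seed,
    config_hash = fnv1a(paste(utils::capture.output(utils::str(
      cfg[setdiff(names(cfg), c("counts", "clinical", "validation"))])),
      collapse = "\n")),
    n_samples = length(coh$y),
    n_excluded = nrow(coh$exclusions),
    n_shared_degs = nrow(degs),
    n_candidate_genes = length(scr$candidate_genes),
    n_tmle_fits = nrow(tm$table))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(tmle = tm$table, manifest = manifest))
}
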