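#' Read a tab-delimited expression matrix
#'
#' Expected layout: header line of sample IDs, first column of probe IDs,
#' numeric cells. Ragged rows, duplicate identifiers and non-numeric cells
#' are rejected with the offending line or identifier named.
#'
#' @param path file path.
#' @return Probe-by-sample numeric matrix with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged row at line %d of %s",
                 which(nf != nf[1])[1], path), call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  probe_ids <- df[[1]]
  if (anyDuplicated(probe_ids))
    stop(sprintf("duplicate probe ID: %s",
                 probe_ids[duplicated(probe_ids)][1]), call. = FALSE)
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop(sprintf("duplicate sample ID: %s",
                 sample_ids[duplicated(sample_ids)][1]), call. = FALSE)
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(probe_ids, sample_ids))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at line %d, sample '%s'",
                 bad[1] + 1L, sample_ids[bad[2]]), call. = FALSE)
  }
  vals
}

#' Write a tab-delimited expression matrix
#'
#' @param x probe-by-sample numeric matrix with dimnames.
#' @param path destination path.
#' @param id_column header name of the probe-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "probe_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited sample-annotation table
#'
#' @param path file path; must contain at least `sample_id`, `cohort` and
#'   `ctdna_status` columns.
#' @return Data frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", "ctdna_status")
  if (!all(need %in% names(df)))
    stop(sprintf("annotation file missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicate sample ID: %s",
                 df$sample_id[duplicated(df$sample_id)][1]), call. = FALSE)
  df
}

#' Write a sample-annotation table
#' @param x annotation data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: term ID, description, then member genes, all
#' tab-separated. Duplicate members within a line are collapsed with a
#' warning; lines with fewer than three fields are rejected with their line
#' number.
#'
#' @param path file path.
#' @return Object of class `"gmt"`: `terms` (named list of member vectors)
#'   and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list(); descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i),
           call. = FALSE)
    id <- fields[1]
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate member(s) collapsed in term '%s'", id))
      members <- unique(members)
    }
    terms[[id]] <- members
    descriptions[id] <- fields[2]
  }
  structure(list(terms = terms, descriptions = descriptions), class = "gmt")
}

#' Write gene sets in GMT format
#' @param gmt a `"gmt"` object or named list of member vectors.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gmt, path) {
  if (!inherits(gmt, "gmt"))
    gmt <- structure(list(terms = gmt,
                          descriptions = stats::setNames(names(gmt),
                                                         names(gmt))),
                     class = "gmt")
  lines <- vapply(names(gmt$terms), function(id)
    paste(c(id, gmt$descriptions[[id]], gmt$terms[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a fitted classifier to JSON
#' @param model a `"ctdna_classifier"`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(selected_probe_ids = model$selected_probe_ids,
              weights = as.list(model$decision_rule$weights),
              intercept = model$decision_rule$intercept,
              standardization = lapply(model$standardization, as.list),
              loocv_trace = model$loocv_trace,
              loocv_accuracy = model$loocv_accuracy,
              training_accuracy = model$training_accuracy,
              majority_class = model$majority_class,
              svm = unclass(model$svm))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' End-to-end pipeline configuration
#'
#' @param sim a [simulation_config()] describing the synthetic study (used
#'   when no expression files are supplied).
#' @param expression_paths,annotation_path optional paths to per-cohort
#'   expression matrices and a pooled annotation file; when given they are
#'   loaded instead of simulating. The last cohort is the validation set.
#' @param alpha candidate threshold for [rank_candidate_probes()].
#' @param meta_model `"DL"` or `"FE"`.
#' @param svm an [svm_config()].
#' @param max_probes cap on selected probes.
#' @param gmt_path optional GMT file for enrichment of the candidate genes.
#' @param probe_gene_map optional two-column data frame (probe_id, gene)
#'   mapping probes to gene symbols for enrichment.
#' @param enrich_mode `"ease"` or `"standard"`.
#' @param seed integer seed overriding `sim$seed`.
#' @param out_dir optional output directory; when set, all artifacts are
#'   written there.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            expression_paths = NULL, annotation_path = NULL,
                            alpha = 0.010, meta_model = "DL",
                            svm = svm_config(), max_probes = Inf,
                            gmt_path = NULL, probe_gene_map = NULL,
                            enrich_mode = "ease",
                            seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(sim = sim, expression_paths = expression_paths,
              annotation_path = annotation_path, alpha = alpha,
              meta_model = meta_model, svm = svm, max_probes = max_probes,
              gmt_path = gmt_path, probe_gene_map = probe_gene_map,
              enrich_mode = enrich_mode, out_dir = out_dir)
  for (p in c(cfg$expression_paths, cfg$annotation_path, cfg$gmt_path))
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input file not found: %s", p), call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

load_cohorts <- function(cfg) {
  ann <- read_annotations(cfg$annotation_path)
  lapply(cfg$expression_paths, function(p) {
    expr <- read_expression(p)
    sub <- ann[match(colnames(expr), ann$sample_id), , drop = FALSE]
    if (any(is.na(sub$sample_id)))
      stop(sprintf("samples of %s missing from annotations", p),
           call. = FALSE)
    new_cohort_study(expr, sub, unique(sub$cohort)[1])
  })
}

#' Run the full ctDNA-detectability pipeline
#'
#' Simulates (or loads) the cohorts, ranks candidate probes on the training
#' cohorts (all but the last), builds the classifier by sequential forward
#' selection, predicts the validation cohort, computes contingency tables
#' and diagnostic metrics for both sets, tests the call/ctDNA association
#' (chi-square when margins allow, Fisher otherwise), compares
#' recurrence-free survival between predicted groups in the combined cohort,
#' and (when a GMT file is configured) runs over-representation analysis of
#' the candidate genes. With `out_dir` set, every artifact is written as
#' TSV/JSON together with a run log (seed, configuration, package version).
#'
#' @param config a [pipeline_config()].
#' @return List: `cohorts`, `truth` (NULL for loaded data), `ranking`,
#'   `model`, `validation_calls`, `tables`, `metrics`, `association`,
#'   `survival`, `enrichment` (optional).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$expression_paths)) {
    sim <- simulate_study(config$sim)
    cohorts <- sim$cohorts
    truth <- sim$truth
  } else {
    cohorts <- load_cohorts(config)
    truth <- NULL
  }
  if (length(cohorts) < 2L)
    stop("pipeline: need at least one training and one validation cohort",
         call. = FALSE)
  training <- cohorts[-length(cohorts)]
  validation <- cohorts[[length(cohorts)]]

  ranking <- rank_candidate_probes(training, alpha = config$alpha,
                                   meta_model = config$meta_model)
  if (nrow(ranking$candidates) == 0L)
    stop("pipeline: ranking produced no candidate probes", call. = FALSE)
  model <- sequential_forward_select(ranking, training, svm = config$svm,
                                     max_probes = config$max_probes)
  val_calls <- stats::predict(model, validation)

  train_truth <- unlist(lapply(training,
                               function(co) co$annotations$ctdna_status))
  ct_train <- contingency_table(model$training_calls, train_truth)
  ct_val <- contingency_table(val_calls, validation$annotations$ctdna_status)
  assoc <- lapply(list(training = ct_train, validation = ct_val), function(ct) {
    tab <- matrix(c(ct$tn, ct$fn, ct$fp, ct$tp), nrow = 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      c(pearson_chi2(tab), test = "chi-square")
    else list(statistic = NA_real_, p = fisher_exact(tab), test = "fisher")
  })

  ann_all <- do.call(rbind, lapply(cohorts, `[[`, "annotations"))
  calls_all <- c(model$training_calls, val_calls)
  calls_all <- calls_all[ann_all$sample_id]
  grp_pos <- calls_all == 1L
  surv_res <- list(
    km_positive = if (any(grp_pos)) km_curve(ann_all$rfs_months[grp_pos],
                                             ann_all$rfs_event[grp_pos]) else NULL,
    km_negative = if (any(!grp_pos)) km_curve(ann_all$rfs_months[!grp_pos],
                                              ann_all$rfs_event[!grp_pos]) else NULL,
    logrank = if (any(grp_pos) && any(!grp_pos) && sum(ann_all$rfs_event) > 0)
      logrank_test(ann_all$rfs_months[grp_pos], ann_all$rfs_event[grp_pos],
                   ann_all$rfs_months[!grp_pos], ann_all$rfs_event[!grp_pos])
    else NULL)

  enrichment <- NULL
  if (!is.null(config$gmt_path)) {
    gmt <- read_gmt(config$gmt_path)
    query <- ranking$candidates$probe_id
    if (!is.null(config$probe_gene_map)) {
      m <- config$probe_gene_map
      query <- unique(m[[2]][match(query, m[[1]])])
      query <- query[!is.na(query)]
    }
    enrichment <- hypergeom_enrich(query, gmt, mode = config$enrich_mode)
  }

  result <- list(cohorts = cohorts, truth = truth, ranking = ranking,
                 model = model, validation_calls = val_calls,
                 tables = list(training = ct_train, validation = ct_val),
                 metrics = list(training = diagnostic_metrics(ct_train),
                                validation = diagnostic_metrics(ct_val)),
                 association = assoc, survival = surv_res,
                 enrichment = enrichment)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  for (co in result$cohorts)
    write_expression(co$expr, out(sprintf("expression_%s.tsv",
                                          co$cohort_label)))
  ann_all <- do.call(rbind, lapply(result$cohorts, `[[`, "annotations"))
  write_annotations(ann_all, out("annotations.tsv"))
  if (!is.null(result$truth))
    jsonlite::write_json(lapply(unclass(result$truth), function(x)
      if (is.numeric(x) || is.character(x)) as.list(x) else x),
      out("truth.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(result$ranking$candidates, out("ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_model(result$model, out("model.json"))
  utils::write.table(
    data.frame(sample_id = names(result$validation_calls),
               call = as.integer(result$validation_calls)),
    out("validation_calls.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  metrics <- lapply(result$metrics, unclass)
  jsonlite::write_json(list(tables = lapply(result$tables, unclass),
                            metrics = metrics,
                            association = result$association),
                       out("metrics.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$enrichment))
    utils::write.table(result$enrichment, out("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  log <- list(seed = config$sim$seed,
              alpha = config$alpha, meta_model = config$meta_model,
              svm = unclass(config$svm), max_probes = config$max_probes,
              package_version = as.character(
                utils::packageVersion("ctdnasig")),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE)
  invisible(NULL)
}
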