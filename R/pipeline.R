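# End-to-end orchestration of the synthetic-data-driven pipeline. Each stage
# writes its artifact plus a JSON provenance stanza embedding the exact
# configuration and seed used, so every output is re-derivable from
# inputs + config alone.

#' Default pipeline configuration
#'
#' Returns the full stage-parameter list the pipeline runs on, with the study
#' conditions as defaults: a 104-patient cohort with four binary clinical
#' covariates and per-phenotype Poisson counts, a three-class single-cell
#' matrix with epithelial/mesenchymal/immune/ribosomal panel structure,
#' ribosomal-gene depression in mesenchymal-like cells, dropout, the 10-gene
#' EMT panel, and the exhaustive cross-validated model selection over the
#' four candidate predictors with the grade/lymph-node pair excluded.
#'
#' @param seed global integer seed; all stage streams derive from it.
#' @return nested list of stage parameters (class `ctc_runconfig`).
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(
      n_patients = 104L,
      predictor_prevalences = c(cT234 = 0.55, cNpos = 0.4,
                                grade3 = 0.3, lobular = 0.15),
      true_log_irr = rbind(
        eCTC = c(cT234 = 0, cNpos = log(14.12), grade3 = 0, lobular = -2),
        emCTC = c(cT234 = log(1.57), cNpos = log(2.37), grade3 = 0,
                  lobular = log(0.08)),
        mCTC = c(cT234 = log(2.22), cNpos = log(2.85), grade3 = 0,
                 lobular = log(0.34))
      ),
      baseline_log_rate = c(eCTC = log(0.1), emCTC = log(0.15),
                            mCTC = log(0.5))
    ),
    model_selection = list(
      candidates = c("cT234", "cNpos", "grade3", "lobular"),
      exclusions = list(c("grade3", "cNpos")),
      k = 10L, reps = 500L,
      # tolerate sporadic resampling-induced separation (up to 10% of folds)
      max_failed_folds = 500L
    ),
    cells = list(
      n_cells_per_class = c(eCTC = 15L, mCTC = 15L, WBC = 20L),
      n_genes = 600L,
      mean_shift_log2 = list(
        eCTC = list(epithelial = 3, immune = -4),
        mCTC = list(mesenchymal = 3, ribosomal = -2, immune = -4),
        WBC = list(immune = 4)
      ),
      dispersion = 0.5,
      dropout_rate = 0.3
    ),
    classify = list(expr_threshold = 4, min_genes = 100L),
    deg = list(alpha = 0.05, lfc_threshold = 1, fdr_correct = FALSE)
  ), class = "ctc_runconfig")
}

# Default single-cell gene panels for the simulated matrix: the EMT scoring
# panel genes double as the epithelial/mesenchymal panels so score recovery
# is testable; immune markers include the classifier defaults.
default_cell_panels <- function() {
  emt <- emt_gene_panel()
  list(
    epithelial = emt$epithelial,
    mesenchymal = emt$mesenchymal,
    immune = c("PTPRC", "PECAM1", "CD3E", "CD14", "MS4A1", "NKG7"),
    ribosomal = c(sprintf("RPL%d", 1:20), sprintf("RPS%d", 1:20))
  )
}

provenance <- function(cfg, stage) {
  list(
    stage = stage,
    package = "ctcemt",
    version = as.character(utils::packageVersion("ctcemt")),
    seed = cfg$seed,
    config = cfg,
    config_hash = config_hash(cfg)
  )
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Run the synthetic-data pipeline end to end
#'
#' Executes the requested stages in order — `simulate` (cohort + expression
#' matrix), `classify_cells`, `emt_score`, `deg`, `model_select` — each
#' writing its artifact (CSV/TSV) and a JSON report with a provenance stanza
#' into `out_dir`. A stage failure aborts with the failing stage named;
#' artifacts already written are retained.
#'
#' @param config a [default_run_config()] (possibly modified) or a path to a
#'   YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run, in pipeline order.
#' @return invisibly, a list of in-memory stage results and artifact paths.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = "results",
                         stages = c("simulate", "classify_cells", "emt_score",
                                    "deg", "model_select")) {
  if (is.character(config) && length(config) == 1L) {
    config <- utils::modifyList(default_run_config(), yaml::read_yaml(config))
    class(config) <- "ctc_runconfig"
  }
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  seeds <- stream_seeds(config$seed, 2L)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("simulate" %in% stages) {
    res$simulate <- run_stage("simulate", {
      cc <- config$cohort
      cfg <- cohort_config(cc$n_patients, cc$predictor_prevalences,
                           cc$true_log_irr, cc$baseline_log_rate,
                           seed = seeds[1])
      cohort <- generate_cohort(cfg)
      utils::write.csv(cohort$cohort, file.path(out_dir, "cohort.csv"),
                       row.names = FALSE)
      write_report(list(provenance = provenance(config, "simulate"),
                        truth = list(
                          true_log_irr = cfg$true_log_irr,
                          baseline_log_rate = cfg$baseline_log_rate)),
                   file.path(out_dir, "cohort_truth.json"))

      ce <- config$cells
      sim_cfg <- cellsim_config(
        n_cells_per_class = ce$n_cells_per_class,
        n_genes = ce$n_genes,
        panel_genes = default_cell_panels(),
        mean_shift_log2 = lapply(ce$mean_shift_log2, unlist),
        dispersion = ce$dispersion,
        dropout_rate = ce$dropout_rate,
        seed = seeds[2]
      )
      expr <- generate_expression(sim_cfg)
      write_matrix(expr$counts, file.path(out_dir, "expression.tsv"), "tsv")
      utils::write.csv(
        data.frame(cell_id = names(expr$cell_class),
                   true_class = unname(expr$cell_class)),
        file.path(out_dir, "cell_truth.csv"), row.names = FALSE)
      list(cohort = cohort, expression = expr)
    })
  }

  expr <- res$simulate$expression
  if (is.null(expr) && any(c("classify_cells", "emt_score", "deg") %in% stages)) {
    stop("pipeline stage `classify_cells` failed: no simulated expression; ",
         "run the simulate stage first", call. = FALSE)
  }

  if ("classify_cells" %in% stages) {
    res$classify_cells <- run_stage("classify_cells", {
      cfg <- classifier_config(expr_threshold = config$classify$expr_threshold,
                               min_genes = config$classify$min_genes)
      qc <- qc_filter(expr$counts, cfg)
      counts <- expr$counts[, qc$keep, drop = FALSE]
      # protein panel booleans derived from the simulated truth labels
      truth <- expr$cell_class[colnames(counts)]
      panel <- data.frame(
        epcam = truth == "eCTC", ecad = FALSE,
        csvim = truth == "mCTC", mcam = FALSE,
        cd45 = truth == "WBC", cd31 = FALSE
      )
      norm <- size_factor_normalize(counts)
      labels <- classify_origin(panel, norm$normalized, cfg)
      out <- data.frame(cell_id = colnames(counts), label = labels)
      utils::write.csv(out, file.path(out_dir, "cell_labels.csv"),
                       row.names = FALSE)
      write_report(list(provenance = provenance(config, "classify_cells"),
                        n_input = ncol(expr$counts),
                        n_retained = ncol(counts),
                        n_rejected = nrow(qc$log),
                        label_counts = as.list(table(labels))),
                   file.path(out_dir, "classify_report.json"))
      list(labels = out, qc = qc, normalized = norm)
    })
  }

  if ("emt_score" %in% stages) {
    res$emt_score <- run_stage("emt_score", {
      keep <- res$classify_cells$qc$keep
      counts <- expr$counts[, keep, drop = FALSE]
      scored <- emt_classify(counts)
      utils::write.csv(scored, file.path(out_dir, "emt_scores.csv"),
                       row.names = FALSE)
      write_report(list(provenance = provenance(config, "emt_score"),
                        q1 = attr(classify_by_quartiles(scored$score), "q1"),
                        q3 = attr(classify_by_quartiles(scored$score), "q3"),
                        class_counts = as.list(table(scored$class))),
                   file.path(out_dir, "emt_report.json"))
      scored
    })
  }

  if ("deg" %in% stages) {
    res$deg <- run_stage("deg", {
      norm <- res$classify_cells$normalized$normalized
      labels <- res$classify_cells$labels
      cfg <- deg_config(alpha = config$deg$alpha,
                        lfc_threshold = config$deg$lfc_threshold,
                        fdr_correct = config$deg$fdr_correct)
      kept <- exclude_marker_genes(norm, cfg$excluded_panels)
      a <- labels$cell_id[labels$label == "tCTC"]
      b <- labels$cell_id[labels$label == "tNC"]
      degs <- deg_call(kept$matrix, a, b, cfg)
      utils::write.table(degs, file.path(out_dir, "deg_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_report(list(provenance = provenance(config, "deg"),
                        n_down = sum(degs$call == "down"),
                        n_up = sum(degs$call == "up"),
                        n_excluded = sum(kept$log$n_removed)),
                   file.path(out_dir, "deg_report.json"))
      degs
    })
  }

  if ("model_select" %in% stages) {
    res$model_select <- run_stage("model_select", {
      cohort <- if (!is.null(res$simulate)) {
        res$simulate$cohort$cohort
      } else {
        utils::read.csv(file.path(out_dir, "cohort.csv"))
      }
      ms <- config$model_selection
      sel <- run_model_selection(cohort, ms$candidates, ms$exclusions,
                                 k = ms$k, reps = ms$reps, seed = config$seed,
                                 max_failed_folds = ms$max_failed_folds %||% 0)
      utils::write.table(sel$selection$ranking,
                         file.path(out_dir, "model_ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_report(list(provenance = provenance(config, "model_select"),
                        winner = spec_label(sel$selection$winner),
                        irr = sel$irr,
                        overall_r2 = sel$r2$overall_r2,
                        per_response_r2 = as.list(sel$r2$per_response_r2),
                        partial_r2 = sel$r2$partial_r2),
                   file.path(out_dir, "model_report.json"))
      sel
    })
  }

  invisible(res)
}
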