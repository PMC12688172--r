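# Cell-origin classification (true CTC / potential normal cell / true normal
# cell) from combined protein-panel and transcript evidence, plus per-cell
# quality filters.

#' Configuration for cell-origin classification and QC
#'
#' @param immune_endo_markers immune/endothelial transcript markers whose
#'   expression disqualifies a protein-positive cell from being a true CTC.
#'   The default ships the hematopoietic (PTPRC, encoding CD45) and
#'   endothelial (PECAM1, encoding CD31) markers; extend the list to match
#'   the lineage panel in use — it is provenance, not a constant.
#' @param expr_threshold expression level at or above which a marker counts
#'   as expressed (default 4, applied to normalized expression).
#' @param min_genes minimum number of detected genes per cell to pass QC
#'   (default 800, inclusive).
#' @param min_housekeeping minimum number of detected housekeeping genes
#'   (out of EEF1A1, ACTB, GAPDH) for a usable transcriptome (default 2).
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(immune_endo_markers = c("PTPRC", "PECAM1"),
                              expr_threshold = 4,
                              min_genes = 800L,
                              min_housekeeping = 2L) {
  stopifnot(length(immune_endo_markers) >= 1L,
            expr_threshold > 0, min_genes > 0, min_housekeeping > 0)
  structure(
    list(immune_endo_markers = immune_endo_markers,
         expr_threshold = expr_threshold,
         min_genes = as.integer(min_genes),
         min_housekeeping = as.integer(min_housekeeping)),
    class = "classifier_config"
  )
}

#' Classify captured cells into tCTC / pNC / tNC
#'
#' Combines the immunofluorescence protein panel a cell was picked on with
#' its transcript-level marker expression:
#' * `tCTC` (true CTC): protein CTC-positive (epithelial and/or mesenchymal
#'   marker present, CD45/CD31 absent) and every configured
#'   immune/endothelial transcript marker below the expression threshold;
#' * `pNC` (potential normal cell): protein CTC-positive but at least one
#'   marker at or above the threshold;
#' * `tNC` (true normal cell): protein panel negative for both epithelial and
#'   mesenchymal markers — the protein rule dominates regardless of
#'   transcript levels.
#'
#' A panel that is cancer-marker positive *and* CD45/CD31 positive is
#' contradictory and raises an error.
#'
#' @param panel data frame of per-cell protein booleans (`epcam`, `ecad`,
#'   `csvim`, `mcam`, `cd45`, `cd31`; a `dapi` column, if present, is treated
#'   like an exclusion marker).
#' @param expr normalized expression: a named numeric vector (one cell) or a
#'   genes x cells matrix. Markers absent from `expr` count as 0.
#' @param cfg a [classifier_config()].
#' @return factor of labels (`tCTC`, `pNC`, `tNC`), one per cell.
#' @export
classify_origin <- function(panel, expr, cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  if (is.logical(panel) && !is.null(names(panel))) {
    panel <- as.data.frame(as.list(panel))
  }
  if (is.numeric(expr) && is.null(dim(expr))) {
    expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), NULL))
  }
  if (nrow(panel) != ncol(expr)) {
    stop("`panel` rows and `expr` columns must correspond one-to-one")
  }
  for (f in c("epcam", "ecad", "csvim", "mcam", "cd45", "cd31")) {
    if (!f %in% names(panel)) stop("panel is missing field `", f, "`")
  }
  epi <- panel$epcam | panel$ecad
  mes <- panel$csvim | panel$mcam
  excl <- panel$cd45 | panel$cd31
  if (!is.null(panel$dapi)) excl <- excl | panel$dapi

  contradictory <- (epi | mes) & excl
  if (any(contradictory)) {
    stop("contradictory panel(s) (cancer marker with CD45/CD31/DAPI) at cell ",
         paste(which(contradictory), collapse = ", "))
  }

  markers <- cfg$immune_endo_markers
  marker_expr <- matrix(0, nrow = length(markers), ncol = ncol(expr),
                        dimnames = list(markers, colnames(expr)))
  present <- intersect(markers, rownames(expr))
  marker_expr[present, ] <- as.matrix(expr)[present, , drop = FALSE]
  marker_high <- colSums(marker_expr >= cfg$expr_threshold) > 0

  labels <- ifelse(!(epi | mes), "tNC",
                   ifelse(marker_high, "pNC", "tCTC"))
  factor(labels, levels = c("tCTC", "pNC", "tNC"))
}

#' Filter cells on the minimum-detected-genes QC rule
#'
#' Retains cells expressing at least `min_genes` genes (count > 0), the
#' "good-quality transcriptome" rule; the boundary is inclusive, so a cell
#' with exactly `min_genes` detected genes is retained.
#'
#' @param counts count matrix (genes x cells) or a named vector of per-cell
#'   detected-gene numbers.
#' @param cfg a [classifier_config()].
#' @return list with `keep` (logical per cell), `retained` (cell names) and
#'   `log` (data frame of rejected cells with `n_genes_detected` and
#'   `reason`).
#' @export
qc_filter <- function(counts, cfg = classifier_config()) {
  if (is.matrix(counts) || inherits(counts, "Matrix")) {
    detected <- colSums(as.matrix(counts) > 0)
  } else {
    detected <- counts
  }
  cells <- names(detected) %||% paste0("cell", seq_along(detected))
  keep <- detected >= cfg$min_genes
  list(
    keep = stats::setNames(keep, cells),
    retained = cells[keep],
    log = data.frame(
      cell_id = cells[!keep],
      n_genes_detected = as.integer(detected[!keep]),
      reason = rep(sprintf("fewer than %d genes detected", cfg$min_genes),
                   sum(!keep)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

#' Housekeeping-gene quality rule
#'
#' A cell's transcriptome is usable when at least `min_housekeeping` of the
#' three housekeeping genes (EEF1A1, ACTB, GAPDH) are detected.
#'
#' @param detected logical vector of length 3 (one cell) or a cells x 3
#'   logical matrix / data frame of per-gene detection flags.
#' @param cfg a [classifier_config()].
#' @return logical, one value per cell.
#' @export
housekeeping_pass <- function(detected, cfg = classifier_config()) {
  if (is.data.frame(detected)) detected <- as.matrix(detected)
  if (is.null(dim(detected))) detected <- matrix(detected, nrow = 1)
  if (ncol(detected) != 3L) {
    stop("`detected` must have one flag per housekeeping gene (3)")
  }
  if (!is.logical(detected) || anyNA(detected)) {
    stop("`detected` must be TRUE/FALSE with no missing values")
  }
  rowSums(detected) >= cfg$min_housekeeping
}
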