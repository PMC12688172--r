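# Per-cell EMT scoring on fixed epithelial/mesenchymal gene panels and
# quartile-based phenotype classes.

#' EMT gene panel
#'
#' The default panel follows the established single-cell CTC EMT signature:
#' three mesenchymal genes (FN1, CDH2, SERPINE1) and seven epithelial genes
#' (KRT5, KRT7, KRT8, KRT18, KRT19, EPCAM, CDH1), ten genes in total — the
#' score's denominator.
#'
#' @param mesenchymal,epithelial disjoint gene-symbol vectors.
#' @return object of class `emt_panel` with fields `mesenchymal`,
#'   `epithelial`, `n_total`.
#' @export
emt_gene_panel <- function(
    mesenchymal = c("FN1", "CDH2", "SERPINE1"),
    epithelial = c("KRT5", "KRT7", "KRT8", "KRT18", "KRT19", "EPCAM", "CDH1")) {
  if (length(intersect(mesenchymal, epithelial)) > 0L) {
    stop("mesenchymal and epithelial panels must be disjoint")
  }
  if (length(mesenchymal) == 0L || length(epithelial) == 0L) {
    stop("both panels must be non-empty")
  }
  structure(
    list(mesenchymal = mesenchymal, epithelial = epithelial,
         n_total = length(mesenchymal) + length(epithelial)),
    class = "emt_panel"
  )
}

#' Reads-per-million normalization
#'
#' Scales each cell (column) to a library size of one million:
#' `RPM(g, c) = count(g, c) / total(c) * 1e6`.
#'
#' @param counts numeric matrix, genes x cells, with per-cell totals > 0.
#' @return matrix of the same shape whose column sums are all `1e6`.
#' @export
rpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  zero <- totals <= 0
  if (any(zero)) {
    bad <- colnames(counts)[zero] %||% which(zero)
    stop("cell(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Per-cell EMT score
#'
#' For each cell, sums `log10(RPM + 1)` over the mesenchymal panel (`m_sum`)
#' and over the epithelial panel (`e_sum`); the score is
#' `(m_sum - e_sum) / n_total` with `n_total` the panel size (10 by default).
#' Positive scores indicate mesenchymal character. Panel genes absent from
#' the matrix contribute an RPM of 0 and raise a warning (they may have been
#' filtered upstream).
#'
#' @param rpm RPM-normalized matrix (genes x cells), e.g. from
#'   [rpm_normalize()].
#' @param panel an [emt_gene_panel()].
#' @return data frame with `cell_id`, `m_sum`, `e_sum`, `score`.
#' @export
emt_score <- function(rpm, panel = emt_gene_panel()) {
  stopifnot(inherits(panel, "emt_panel"))
  rpm <- as.matrix(rpm)
  missing <- setdiff(c(panel$mesenchymal, panel$epithelial), rownames(rpm))
  if (length(missing) > 0L) {
    warning("panel gene(s) absent from matrix, scored as RPM 0: ",
            paste(missing, collapse = ", "))
  }
  panel_sum <- function(genes) {
    present <- intersect(genes, rownames(rpm))
    if (length(present) == 0L) return(rep(0, ncol(rpm)))
    colSums(log10(rpm[present, , drop = FALSE] + 1))
  }
  m_sum <- panel_sum(panel$mesenchymal)
  e_sum <- panel_sum(panel$epithelial)
  data.frame(
    cell_id = colnames(rpm) %||% paste0("cell", seq_len(ncol(rpm))),
    m_sum = m_sum, e_sum = e_sum,
    score = (m_sum - e_sum) / panel$n_total,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Assign EMT phenotype classes by score quartiles
#'
#' Computes the first and third quartiles of the score distribution of the
#' population being classified and labels cells strictly below Q1 as `eCTC`,
#' strictly above Q3 as `mCTC`, and the rest `intermediate`. Quartiles use
#' linear interpolation between order statistics (plotting position
#' `(k - 1)/(n - 1)`, `stats::quantile` type 7) by default; the convention is
#' an argument because different conventions can shift tail membership by one
#' cell. Constant scores degenerate to everything `intermediate`.
#'
#' @param scores numeric vector of EMT scores (at least 4 cells).
#' @param quantile_type quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation of order statistics).
#' @return factor with levels `eCTC`, `intermediate`, `mCTC`, plus attributes
#'   `q1`, `q3` and `quantile_type` recording the cutpoints used.
#' @export
classify_by_quartiles <- function(scores, quantile_type = 7) {
  if (length(scores) < 4L) stop("need at least 4 cells to form quartiles")
  if (anyNA(scores)) stop("scores must not contain NA")
  q <- stats::quantile(scores, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  cls <- rep("intermediate", length(scores))
  cls[scores < q[1]] <- "eCTC"
  cls[scores > q[2]] <- "mCTC"
  structure(
    factor(cls, levels = c("eCTC", "intermediate", "mCTC")),
    q1 = q[1], q3 = q[2], quantile_type = quantile_type
  )
}

#' Score and classify a count matrix in one step
#'
#' Convenience wrapper: RPM-normalize raw counts, compute per-cell EMT
#' scores, and attach quartile classes.
#'
#' @param counts raw count matrix, genes x cells.
#' @param panel an [emt_gene_panel()].
#' @param quantile_type see [classify_by_quartiles()].
#' @return the [emt_score()] data frame with an extra `class` column.
#' @export
emt_classify <- function(counts, panel = emt_gene_panel(), quantile_type = 7) {
  scores <- emt_score(rpm_normalize(counts), panel)
  scores$class <- classify_by_quartiles(scores$score, quantile_type)
  scores
}
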