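# Median-of-ratios size-factor normalization and rule-based differential
# expression calling between cell groups, with erythroid/platelet marker
# exclusion and optional FDR correction.

#' Configuration for rule-based differential-expression calling
#'
#' @param alpha significance level for the per-gene test (default 0.05).
#' @param lfc_threshold absolute log2 fold-change cutoff; genes at or beyond
#'   `-lfc_threshold` / `+lfc_threshold` with a significant test are called
#'   down / up (default 1).
#' @param fdr_correct apply Benjamini-Hochberg correction across all tested
#'   genes and gate calls on the adjusted p-value (default `FALSE`; turn on
#'   for validation-style analyses).
#' @param excluded_panels named list of gene vectors to strip before testing
#'   (defaults to the bundled erythroid and platelet panels, see
#'   [default_marker_panels()]).
#' @param pseudocount added inside both the log transform of the test input
#'   and the median fold change (default 1).
#' @param var_equal use the classical equal-variance Student t-test
#'   (default `TRUE`); `FALSE` switches to Welch.
#' @return object of class `deg_config`.
#' @export
deg_config <- function(alpha = 0.05, lfc_threshold = 1, fdr_correct = FALSE,
                       excluded_panels = default_marker_panels(),
                       pseudocount = 1, var_equal = TRUE) {
  stopifnot(alpha > 0, alpha < 1, lfc_threshold > 0, pseudocount > 0)
  structure(
    list(alpha = alpha, lfc_threshold = lfc_threshold,
         fdr_correct = fdr_correct, excluded_panels = excluded_panels,
         pseudocount = pseudocount, var_equal = var_equal),
    class = "deg_config"
  )
}

#' Bundled erythroid (RBC) and platelet (PLT) exclusion panels
#'
#' High-background erythroid and platelet transcripts are removed before
#' differential-expression testing. The bundled lists are synthetic
#' stand-ins sized like the published Human Protein Atlas clusters (138
#' erythroid, 173 platelet genes): a core of genuine marker symbols (HBB,
#' GYPA, PF4, PPBP, ...) padded with clearly synthetic `RBCSYN`/`PLTSYN`
#' symbols. Replace them with the real cluster lists for analyses of real
#' data.
#'
#' @return named list with elements `RBC` and `PLT` (character vectors of
#'   gene symbols).
#' @export
default_marker_panels <- function() {
  read_panel <- function(file) {
    path <- system.file("extdata", file, package = "ctcemt")
    if (!nzchar(path)) stop("bundled panel not found: ", file)
    read_gene_panel(path)
  }
  list(
    RBC = read_panel("rbc_panel_synthetic.txt"),
    PLT = read_panel("plt_panel_synthetic.txt")
  )
}

#' Median-of-ratios size-factor normalization
#'
#' Computes one size factor per cell as the median, over reference genes, of
#' the ratio of the cell's count to the gene's geometric mean across cells;
#' normalized counts are raw counts divided by the cell's size factor.
#' Reference genes are genes with nonzero counts in every cell; when none
#' exist (heavy dropout), the procedure falls back to genes nonzero in at
#' least half the cells, taking each gene's geometric mean over its positive
#' counts, and says so via a message.
#'
#' @param counts count matrix, genes x cells, at least 2 cells.
#' @return list with `normalized` (matrix), `size_factors` (numeric per
#'   cell), `n_reference_genes` and `fallback` (logical).
#' @export
size_factor_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 cells")
  log_counts <- log(counts)
  log_geomeans <- rowMeans(log_counts)
  reference <- is.finite(log_geomeans)
  fallback <- FALSE
  if (!any(reference)) {
    fallback <- TRUE
    frac_nonzero <- rowMeans(counts > 0)
    reference <- frac_nonzero >= 0.5
    if (!any(reference)) {
      stop("no gene is nonzero in at least half the cells; cannot normalize")
    }
    message("no gene nonzero in every cell; falling back to median-of-ratios ",
            "over ", sum(reference), " genes nonzero in >= 50% of cells")
    log_geomeans <- apply(log_counts, 1, function(lc) mean(lc[is.finite(lc)]))
    size_factors <- apply(counts, 2, function(cnts) {
      ratios <- (log(cnts) - log_geomeans)[reference & cnts > 0]
      if (length(ratios) == 0L) stop("a cell shares no counts with the reference set")
      exp(stats::median(ratios))
    })
  } else {
    size_factors <- apply(counts, 2, function(cnts) {
      exp(stats::median((log(cnts) - log_geomeans)[reference]))
    })
  }
  list(
    normalized = sweep(counts, 2, size_factors, "/"),
    size_factors = size_factors,
    n_reference_genes = sum(reference),
    fallback = fallback
  )
}

#' Remove marker-panel genes from a matrix
#'
#' Strips rows whose gene symbol belongs to any of the given panels (e.g.
#' high-background erythroid and platelet transcripts) and logs how many
#' genes each panel removed.
#'
#' @param mat matrix with gene rownames.
#' @param panels named list of gene vectors.
#' @return list with `matrix` (rows removed) and `log` (data frame: `panel`,
#'   `n_removed`).
#' @export
exclude_marker_genes <- function(mat, panels = default_marker_panels()) {
  stopifnot(!is.null(rownames(mat)))
  removed_by <- lapply(panels, function(genes) intersect(rownames(mat), genes))
  drop <- unique(unlist(removed_by, use.names = FALSE))
  list(
    matrix = mat[!(rownames(mat) %in% drop), , drop = FALSE],
    log = data.frame(
      panel = names(panels),
      n_removed = lengths(removed_by),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

#' Rule-based differential-expression calls between two cell groups
#'
#' Per gene: a two-sided t-test (equal-variance Student by default) on
#' `log2(normalized + pseudocount)` between the groups, and a median fold
#' change `log2((median_A + pc) / (median_B + pc))` of normalized expression.
#' A gene is called `down` when `log2FC <= -lfc_threshold` and significant,
#' `up` when `log2FC >= lfc_threshold` and significant, else `unchanged`.
#' Significance gates on the raw p-value, or the Benjamini-Hochberg adjusted
#' one when `fdr_correct` is on. Marker exclusion
#' ([exclude_marker_genes()]) is expected to have been applied already.
#' Genes with zero variance in both groups have an undefined test
#' (`p_value = NA`), are flagged, and stay `unchanged`.
#'
#' @param norm normalized matrix (genes x cells), e.g.
#'   `size_factor_normalize(...)$normalized`.
#' @param group_a,group_b column names or indices of the two groups
#'   (>= 2 cells each); fold changes are A over B.
#' @param cfg a [deg_config()].
#' @return data frame with `gene`, `p_value`, `adjusted_p`, `log2fc`, `call`
#'   (factor: down/up/unchanged), `flagged`.
#' @export
deg_call <- function(norm, group_a, group_b, cfg = deg_config()) {
  stopifnot(inherits(cfg, "deg_config"))
  a <- as.matrix(norm[, group_a, drop = FALSE])
  b <- as.matrix(norm[, group_b, drop = FALSE])
  if (ncol(a) < 2L || ncol(b) < 2L) stop("both groups need >= 2 cells")
  pc <- cfg$pseudocount
  la <- log2(a + pc)
  lb <- log2(b + pc)

  genes <- rownames(norm) %||% paste0("gene", seq_len(nrow(norm)))
  p <- rep(NA_real_, nrow(norm))
  flagged <- rep(FALSE, nrow(norm))
  for (g in seq_len(nrow(norm))) {
    xa <- la[g, ]
    xb <- lb[g, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      flagged[g] <- TRUE
      next
    }
    p[g] <- stats::t.test(xa, xb, var.equal = cfg$var_equal)$p.value
  }

  log2fc <- log2((apply(a, 1, stats::median) + pc) /
                   (apply(b, 1, stats::median) + pc))
  adjusted_p <- if (cfg$fdr_correct) stats::p.adjust(p, "BH") else NA_real_
  gate <- if (cfg$fdr_correct) adjusted_p else p
  significant <- !is.na(gate) & gate < cfg$alpha

  call <- rep("unchanged", nrow(norm))
  call[significant & log2fc <= -cfg$lfc_threshold] <- "down"
  call[significant & log2fc >= cfg$lfc_threshold] <- "up"

  data.frame(
    gene = genes,
    p_value = p,
    adjusted_p = adjusted_p,
    log2fc = log2fc,
    call = factor(call, levels = c("down", "up", "unchanged")),
    flagged = flagged,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
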