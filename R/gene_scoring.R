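# The scoring cascade turning model metrics and importances into prioritized
# gene lists: CMPS -> PWIS -> GPS (per dataset, top 1%) and the
# log-appearance-weighted DSS / HGS aggregates.

#' Composite Model Performance Score
#'
#' The mean of the six normalized metrics. AUC, accuracy, F1, precision and
#' recall are natively 0-1 and used as-is; kappa is mapped (kappa + 1)/2 by
#' default so the score does not depend on which other models were evaluated.
#' A min-max alternative across the supplied model set is available behind
#' `kappa_norm = "minmax"`.
#'
#' @param metrics named numeric vector (or one-row data.frame) with
#'   `auc accuracy f1 precision recall kappa`.
#' @param kappa_norm `"affine"` (default, (kappa+1)/2) or `"minmax"`
#'   (requires `kappa_range`).
#' @param kappa_range numeric length-2, only for `"minmax"`.
#' @return the CMPS in \[0, 1\].
#' @export
composite_model_performance <- function(metrics,
                                        kappa_norm = c("affine", "minmax"),
                                        kappa_range = NULL) {
  kappa_norm <- match.arg(kappa_norm)
  if (is.data.frame(metrics)) metrics <- unlist(metrics[1, , drop = TRUE])
  need <- c("auc", "accuracy", "f1", "precision", "recall", "kappa")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("missing metric(s): ", paste(miss, collapse = ", "))
  kappa01 <- if (kappa_norm == "affine") {
    (as.numeric(metrics[["kappa"]]) + 1) / 2
  } else {
    stopifnot(length(kappa_range) == 2, diff(kappa_range) > 0)
    (as.numeric(metrics[["kappa"]]) - kappa_range[1]) / diff(kappa_range)
  }
  mean(c(as.numeric(metrics[need[1:5]]), kappa01))
}

#' Performance-Weighted Importance Score
#'
#' A gene's raw model importance multiplied by the reporting model's CMPS.
#'
#' @param raw_importance non-negative importance value(s).
#' @param cmps the model's Composite Model Performance Score.
#' @return `raw_importance * cmps`.
#' @export
performance_weighted_importance <- function(raw_importance, cmps) {
  stopifnot(all(raw_importance >= 0), all(cmps >= 0))
  raw_importance * cmps
}

#' Per-dataset gene prioritization with a top-1% cut
#'
#' A gene's Gene Prioritization Score is the sum of its PWIS values over all
#' (pathway, model) records within the dataset. Genes are ranked in
#' descending GPS; `ceiling(top_frac * n_genes)` genes (at least 1) are
#' retained. Ties break by appearance count, then gene symbol.
#'
#' @param records data.frame with columns `gene` and `pwis` (one row per
#'   gene x pathway x model record within one dataset).
#' @param top_frac retained fraction (default 0.01).
#' @return data.frame `gene gps hits rank retained` sorted by rank.
#' @export
gene_prioritization <- function(records, top_frac = 0.01) {
  stopifnot(all(c("gene", "pwis") %in% names(records)))
  gps <- tapply(records$pwis, records$gene, sum)
  hits <- tapply(records$pwis, records$gene, length)
  out <- data.frame(gene = names(gps), gps = as.numeric(gps),
                    hits = as.integer(hits), stringsAsFactors = FALSE)
  out <- out[order(-out$gps, -out$hits, out$gene), ]
  out$rank <- seq_len(nrow(out))
  n_keep <- max(1L, ceiling(top_frac * nrow(out)))
  out$retained <- out$rank <= n_keep
  rownames(out) <- NULL
  out
}

#' Dataset-Specific Score
#'
#' `dss(g) = sum(pwis) * ln(1 + freq)` within one dataset, where `freq`
#' counts the gene's (pathway, model) appearances. The `+1` inside the log
#' keeps a single-hit gene's factor at ln 2 rather than zero, so a potent
#' specialist gene can still top the ranking.
#'
#' @param records data.frame with `gene` and `pwis` for one dataset.
#' @return data.frame `gene dss sum_pwis freq rank` sorted by rank.
#' @export
dataset_specific_score <- function(records) {
  s <- tapply(records$pwis, records$gene, sum)
  f <- tapply(records$pwis, records$gene, length)
  out <- data.frame(gene = names(s), sum_pwis = as.numeric(s),
                    freq = as.integer(f),
                    dss = as.numeric(s) * log1p(as.integer(f)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$dss, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("gene", "dss", "sum_pwis", "freq", "rank")]
}

#' Holistic Gene Score across all datasets
#'
#' `hgs(g) = sum(pwis over every dataset/pathway/model) * ln(1 + total_hits)`
#' where `total_hits` counts all appearances. Same `+1` convention as
#' [dataset_specific_score()].
#'
#' @param records data.frame with `gene` and `pwis` pooled across datasets.
#' @return data.frame `gene hgs sum_pwis total_hits rank` sorted by rank.
#' @export
holistic_score <- function(records) {
  s <- tapply(records$pwis, records$gene, sum)
  f <- tapply(records$pwis, records$gene, length)
  out <- data.frame(gene = names(s), sum_pwis = as.numeric(s),
                    total_hits = as.integer(f),
                    hgs = as.numeric(s) * log1p(as.integer(f)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hgs, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("gene", "hgs", "sum_pwis", "total_hits", "rank")]
}

#' Build PWIS records from pathway evaluation results
#'
#' Convenience assembler: takes per-pathway [evaluate_pathway()] outputs for
#' one dataset and flattens them into the `gene / pwis` record table the
#' scoring functions consume. Each top model contributes one record per gene
#' it scored, with PWIS = normalized importance x the model's CMPS.
#'
#' @param pathway_results named list (pathway -> [evaluate_pathway()] output).
#' @param dataset_id label attached to every record.
#' @return data.frame `dataset pathway model gene raw_importance cmps pwis`.
#' @export
pwis_records <- function(pathway_results, dataset_id = "dataset") {
  rows <- list()
  for (pw in names(pathway_results)) {
    res <- pathway_results[[pw]]
    cmps_by_model <- setNames(
      vapply(seq_len(nrow(res$metrics)), function(i)
        composite_model_performance(res$metrics[i, ]), numeric(1)),
      res$metrics$model)
    for (mod in names(res$importances)) {
      imp <- res$importances[[mod]]
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = dataset_id, pathway = pw, model = mod,
        gene = names(imp), raw_importance = as.numeric(imp),
        cmps = cmps_by_model[[mod]],
        pwis = performance_weighted_importance(as.numeric(imp),
                                               cmps_by_model[[mod]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
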