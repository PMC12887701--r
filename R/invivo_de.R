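# Two-group differential expression with empirical-Bayes-moderated
# statistics, DEG calling, and the multi-parametric target ranking.

# Moment-matched scaled-F prior (d0, s0^2) for the residual variances:
# e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2) has mean log(s0^2) +
# digamma(d0/2) - log(d0/2) and variance trigamma(d_g/2) + trigamma(d0/2),
# so d0 solves trigamma(d0/2) = var(e) - trigamma(d_g/2).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2) return(list(d0 = 1e6, s02 = mean(s2[ok], na.rm = TRUE)))
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    # degenerate spread (e.g. all residual variances equal): no positive
    # prior-df solution; shrink everything to the common variance
    message("log-variance spread below the sampling floor; ",
            "using the heavy-shrinkage limit d0 = 1e6")
    return(list(d0 = 1e6, s02 = exp(mean(log(s2[ok])))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of trigamma on (0, Inf)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Two-group differential expression with a moderated t-statistic
#'
#' Fits a per-gene two-group linear model on log2-scale expression,
#' stabilizes the residual variances with an empirical-Bayes scaled-F prior
#' fitted by moment matching, and reports moderated t-statistics on
#' `d0 + d_g` degrees of freedom with Benjamini-Hochberg adjusted p-values.
#' Linear-scale input is auto-detected (any value > 30 suggests linear) and
#' log2(x + 1)-transformed with a message. Genes with zero residual variance
#' in both groups are reported with `p = 1` and flagged.
#'
#' @param mat genes x samples matrix.
#' @param groups data.frame (`sample`, `group`) or a vector aligned with the
#'   columns; the `"model"`/first level is the treatment group.
#' @param prior_d0 override the fitted prior df (e.g. 0 disables moderation
#'   and reproduces the ordinary pooled t).
#' @return data.frame of class `de_table`: `gene log2fc fc_mvsc t p fdr
#'   s2_g s2_post overall_variance zero_var`, plus attributes `d0`, `s02`.
#' @export
differential_expression <- function(mat, groups, prior_d0 = NULL) {
  grp <- if (is.data.frame(groups)) {
    stopifnot(all(colnames(mat) %in% groups$sample))
    groups$group[match(colnames(mat), groups$sample)]
  } else as.character(groups)
  lv <- unique(grp)
  stopifnot(length(lv) == 2)
  # treat "model" (or the first level encountered) as the treatment group
  trt <- if ("model" %in% lv) "model" else lv[1]
  is_t <- grp == trt
  n1 <- sum(is_t); n0 <- sum(!is_t)
  if (n1 < 2 || n0 < 2) stop("need >= 2 samples per group")
  if (max(mat, na.rm = TRUE) > 30) {
    message("input looks linear-scale; applying log2(x + 1)")
    linmat <- mat
    mat <- log2(mat + 1)
  } else {
    linmat <- 2^mat
  }
  m1 <- rowMeans(mat[, is_t, drop = FALSE])
  m0 <- rowMeans(mat[, !is_t, drop = FALSE])
  log2fc <- m1 - m0
  fc_mvsc <- rowMeans(linmat[, is_t, drop = FALSE]) /
    rowMeans(linmat[, !is_t, drop = FALSE])
  ss1 <- matrixStats::rowVars(mat[, is_t, drop = FALSE]) * (n1 - 1)
  ss0 <- matrixStats::rowVars(mat[, !is_t, drop = FALSE]) * (n0 - 1)
  dg <- n1 + n0 - 2
  s2 <- (ss1 + ss0) / dg
  zero_var <- s2 <= 0

  if (is.null(prior_d0)) {
    prior <- fit_variance_prior(s2, dg)
  } else {
    prior <- list(d0 = prior_d0,
                  s02 = if (prior_d0 > 0) mean(s2[!zero_var]) else 0)
  }
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (d0 == 0) s2 else (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  tmod <- log2fc / se
  df_total <- if (is.finite(d0)) d0 + dg else Inf
  p <- 2 * pt(-abs(tmod), df = df_total)
  p[zero_var] <- 1
  tmod[zero_var] <- NA_real_
  if (any(zero_var))
    message(sum(zero_var), " gene(s) with zero residual variance: p set to 1")
  out <- data.frame(gene = rownames(mat), log2fc = log2fc,
                    fc_mvsc = fc_mvsc, t = tmod, p = p,
                    fdr = p.adjust(p, "BH"), s2_g = s2, s2_post = s2_post,
                    overall_variance = matrixStats::rowVars(mat),
                    zero_var = zero_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  class(out) <- c("de_table", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' DEG iff `p < p_thresh` and `|log2fc| > lfc_thresh` (both strict).
#'
#' @param de a `de_table` from [differential_expression()].
#' @param p_thresh uncorrected p-value gate (default 0.05).
#' @param lfc_thresh absolute log2 fold-change gate (default 1.0).
#' @return list with `degs` (subset of the table), `n_up`, `n_down`.
#' @export
call_degs <- function(de, p_thresh = 0.05, lfc_thresh = 1.0) {
  hit <- de$p < p_thresh & abs(de$log2fc) > lfc_thresh
  degs <- de[hit, , drop = FALSE]
  rownames(degs) <- NULL
  list(degs = degs, n_up = sum(degs$log2fc > 0),
       n_down = sum(degs$log2fc < 0))
}

#' Multi-parametric Comprehensive Score target ranking
#'
#' Ranks each gene on three axes — chemical connectivity (distinct
#' interacting chemicals), expression modulation (|log2 fold change|) and
#' biological variance (overall variance) — each descending with averaged
#' ties (rank 1 = largest), and sums the three ranks. Lower total = better;
#' final ordering breaks ties by gene symbol.
#'
#' @param genes character vector of genes to rank (typically the DEG set).
#' @param chem_edges chemical-gene edge table supplying connectivity
#'   (genes absent from it get connectivity 0).
#' @param de the `de_table` supplying fold changes and variances.
#' @return data.frame `gene connectivity log2fc fc_mvsc overall_variance
#'   rank_connectivity rank_foldchange rank_variance comprehensive_score`
#'   sorted by ascending score.
#' @export
comprehensive_score <- function(genes, chem_edges, de) {
  idx <- match(genes, de$gene)
  stopifnot(!anyNA(idx))
  e <- dedup_edges(chem_edges)
  conn <- vapply(genes, function(g)
    length(unique(e$chemical_name[e$gene_symbol == g])), integer(1))
  out <- data.frame(gene = genes, connectivity = conn,
                    log2fc = de$log2fc[idx], fc_mvsc = de$fc_mvsc[idx],
                    overall_variance = de$overall_variance[idx],
                    stringsAsFactors = FALSE)
  out$rank_connectivity <- rank_desc(out$connectivity)
  out$rank_foldchange <- rank_desc(abs(out$log2fc))
  out$rank_variance <- rank_desc(out$overall_variance)
  out$comprehensive_score <- out$rank_connectivity + out$rank_foldchange +
    out$rank_variance
  out <- out[order(out$comprehensive_score, out$gene), ]
  rownames(out) <- NULL
  out
}
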