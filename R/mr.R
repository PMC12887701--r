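# Two-sample Mendelian randomization: instrument selection, harmonization,
# IVW and MR-Egger estimation, and the sensitivity / qualification suite.
#
# Conventions used throughout:
#   * Wald ratio b_i = beta_out / beta_exp with first-order (delta) SE
#     se_out / |beta_exp|; equivalently IVW weight w_i = (beta_exp/se_out)^2.
#   * Random-effects flavor is multiplicative: the fixed-effect SE is scaled
#     by sqrt(max(1, Q/(k-1))) and never deflated below the fixed-effect SE.

#' Select independent instruments by p-value threshold and LD clumping
#'
#' Greedy clumping: candidates below `p_thresh` are sorted by ascending
#' p-value; a SNP is retained iff its squared correlation with every
#' already-retained SNP lying within `window_kb` of it is below `r2_thresh`.
#' SNPs farther apart than the window are never pruned against each other.
#'
#' @param gwas exposure summary table (`snp`, `chr`, `pos`, `pval`, ...).
#' @param ld square matrix of squared correlations with SNP ids as dimnames;
#'   must cover all candidate SNPs.
#' @param p_thresh genome-wide significance threshold (default 5e-8).
#' @param r2_thresh LD pruning threshold on r-squared (default 0.001).
#' @param window_kb clumping window in kilobases (default 1000).
#' @return character vector of retained SNP ids (empty, with a message, when
#'   no candidate reaches significance).
#' @export
select_instruments <- function(gwas, ld, p_thresh = 5e-8, r2_thresh = 0.001,
                               window_kb = 1000) {
  cand <- gwas[gwas$pval < p_thresh, , drop = FALSE]
  if (nrow(cand) == 0L) {
    message("no instruments: no SNP reaches the significance threshold")
    return(character())
  }
  if (!all(cand$snp %in% rownames(ld)))
    stop("LD matrix does not cover all candidate SNPs")
  cand <- cand[order(cand$pval), , drop = FALSE]
  kept <- character()
  for (i in seq_len(nrow(cand))) {
    s <- cand$snp[i]
    near <- kept[norm_chr(cand$chr[i]) ==
                   norm_chr(gwas$chr[match(kept, gwas$snp)]) &
                 abs(cand$pos[i] - gwas$pos[match(kept, gwas$snp)]) <=
                   window_kb * 1000]
    if (!length(near) || all(ld[s, near] < r2_thresh)) kept <- c(kept, s)
  }
  kept
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")
.is_palindromic <- function(ea, oa) .complement[ea] == oa

#' Harmonize exposure and outcome summary statistics to shared effect alleles
#'
#' Aligns the outcome record to the exposure's effect allele: the outcome
#' beta is sign-flipped (and its EAF complemented) when its effect allele
#' equals the exposure's other allele, including the strand-complement case
#' for non-palindromic SNPs. Palindromic (A/T, C/G) SNPs are dropped when
#' either study's EAF falls inside the ambiguity window; unmatched SNPs are
#' dropped with a logged reason.
#'
#' @param exposure,outcome summary tables sharing a `snp` column.
#' @param eaf_ambiguity length-2 numeric window; palindromic SNPs whose EAF
#'   falls strictly inside it (either study) are dropped. Default
#'   `c(0.42, 0.58)`.
#' @return data.frame of harmonized pairs (`snp_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `n_exp`, `n_out`,
#'   `palindromic`, `flipped`) with attribute `"dropped"` recording removals.
#' @export
harmonize <- function(exposure, outcome, eaf_ambiguity = c(0.42, 0.58)) {
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared)) {
    message("no overlap: exposure and outcome share no SNPs")
    out <- data.frame(snp_id = character())
    attr(out, "dropped") <- data.frame(snp = character(), reason = character())
    return(out)
  }
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]
  pal <- unname(.is_palindromic(ex$ea, ex$oa))
  direct <- ou$ea == ex$ea & ou$oa == ex$oa
  swapped <- ou$ea == ex$oa & ou$oa == ex$ea
  strand_direct <- !pal & ou$ea == unname(.complement[ex$ea]) &
    ou$oa == unname(.complement[ex$oa])
  strand_swapped <- !pal & ou$ea == unname(.complement[ex$oa]) &
    ou$oa == unname(.complement[ex$ea])
  flipped <- swapped | strand_swapped
  matched <- direct | swapped | strand_direct | strand_swapped
  ambiguous <- function(f) f > eaf_ambiguity[1] & f < eaf_ambiguity[2]
  pal_drop <- matched & pal & (ambiguous(ex$eaf) | ambiguous(ou$eaf))
  keep <- matched & !pal_drop
  out <- data.frame(
    snp_id = shared[keep],
    beta_exp = ex$beta[keep], se_exp = ex$se[keep],
    beta_out = ifelse(flipped[keep], -ou$beta[keep], ou$beta[keep]),
    se_out = ou$se[keep],
    eaf_exp = ex$eaf[keep],
    eaf_out = ifelse(flipped[keep], 1 - ou$eaf[keep], ou$eaf[keep]),
    n_exp = ex$n[keep], n_out = ou$n[keep],
    palindromic = pal[keep], flipped = flipped[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(
    snp = shared[!keep],
    reason = ifelse(pal_drop[!keep], "palindromic, ambiguous EAF",
                    "allele mismatch"),
    stringsAsFactors = FALSE)
  out
}

.ivw_weights <- function(pairs) (pairs$beta_exp / pairs$se_out)^2

#' Inverse-variance-weighted MR estimate (multiplicative random effects)
#'
#' Per-SNP Wald ratios `beta_out/beta_exp` are combined with first-order
#' weights `(beta_exp/se_out)^2`. The fixed-effect SE `1/sqrt(sum(w))` is
#' inflated by `sqrt(max(1, Q/(k-1)))`, so the random-effects SE never drops
#' below the fixed-effect SE. The two-sided p-value uses the normal
#' approximation; the odds-ratio scale reports `exp(beta_hat)` with a 95% CI.
#'
#' @param pairs harmonized pairs from [harmonize()] (>= 2 rows; SNPs with
#'   `beta_exp == 0` are excluded with a warning).
#' @return list of class `mr_estimate` with `method`, `beta_hat`, `se_hat`,
#'   `pval`, `or_`, `ci_low`, `ci_high`, `nsnp`, `q_stat`, plus the
#'   untruncated fixed-effect `se_fixed`/`pval_fixed` (the random-effects
#'   p-value is conservative by construction, never anticonservative, because
#'   the SE inflation factor is floored at 1).
#' @export
mr_ivw <- function(pairs) {
  bad <- pairs$beta_exp == 0
  if (any(bad)) {
    warning(sum(bad), " SNP(s) with zero exposure beta excluded")
    pairs <- pairs[!bad, , drop = FALSE]
  }
  k <- nrow(pairs)
  if (k < 2) stop("IVW requires >= 2 usable instruments")
  b <- pairs$beta_out / pairs$beta_exp
  w <- .ivw_weights(pairs)
  beta_hat <- sum(w * b) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (b - beta_hat)^2)
  se_hat <- se_fixed * sqrt(max(1, q / (k - 1)))
  structure(list(method = "IVW", beta_hat = beta_hat, se_hat = se_hat,
                 pval = 2 * pnorm(-abs(beta_hat / se_hat)),
                 se_fixed = se_fixed,
                 pval_fixed = 2 * pnorm(-abs(beta_hat / se_fixed)),
                 or_ = exp(beta_hat),
                 ci_low = exp(beta_hat - 1.96 * se_hat),
                 ci_high = exp(beta_hat + 1.96 * se_hat),
                 nsnp = k, q_stat = q),
            class = "mr_estimate")
}

#' MR-Egger regression (slope, intercept, pleiotropy test)
#'
#' Weighted linear regression of outcome betas on exposure betas with a free
#' intercept and weights `1/se_out^2`, after orienting every pair so that
#' `beta_exp >= 0` (removes the sign indeterminacy of the intercept). A
#' non-zero intercept indicates directional pleiotropy. Standard errors use a
#' multiplicative overdispersion factor bounded below at 1, consistent with
#' the IVW random-effects flavor; p-values are on t(k-2).
#'
#' @param pairs harmonized pairs (>= 3 rows).
#' @return list of class `mr_egger` with the slope as an `mr_estimate` plus
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(pairs) {
  k <- nrow(pairs)
  if (k < 3) stop("Egger requires >=3 instruments")
  sgn <- ifelse(pairs$beta_exp < 0, -1, 1)
  x <- pairs$beta_exp * sgn
  y <- pairs$beta_out * sgn
  w <- 1 / pairs$se_out^2
  fit <- stats::lm.wfit(cbind(intercept = 1, slope = x), y, w)
  rss <- sum(w * fit$residuals^2)
  phi <- max(1, rss / (k - 2))
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, x) * sqrt(w))))
  ses <- sqrt(diag(xtx_inv) * phi)
  slope <- fit$coefficients[["slope"]]
  intercept <- fit$coefficients[["intercept"]]
  pt2 <- function(est, se) 2 * pt(-abs(est / se), df = k - 2)
  est <- structure(list(method = "Egger", beta_hat = slope, se_hat = ses[2],
                        pval = pt2(slope, ses[2]),
                        or_ = exp(slope),
                        ci_low = exp(slope - 1.96 * ses[2]),
                        ci_high = exp(slope + 1.96 * ses[2]),
                        nsnp = k, q_stat = NA_real_),
                   class = "mr_estimate")
  structure(list(estimate = est, intercept = intercept,
                 intercept_se = ses[1],
                 intercept_p = pt2(intercept, ses[1])),
            class = "mr_egger")
}

#' Cochran's Q heterogeneity statistic for IVW
#'
#' `Q = sum(w_i * (b_i - beta_hat)^2)` over the per-SNP Wald ratios, referred
#' to a chi-square upper tail on `k - 1` degrees of freedom.
#'
#' @param pairs harmonized pairs (>= 2 rows).
#' @param ivw_beta optional pooled estimate; recomputed when missing.
#' @return list with `q_stat`, `q_df`, `q_p`.
#' @export
cochran_q <- function(pairs, ivw_beta = NULL) {
  k <- nrow(pairs)
  if (k < 2) stop("Cochran's Q requires >= 2 instruments")
  b <- pairs$beta_out / pairs$beta_exp
  w <- .ivw_weights(pairs)
  if (is.null(ivw_beta)) ivw_beta <- sum(w * b) / sum(w)
  q <- sum(w * (b - ivw_beta)^2)
  list(q_stat = q, q_df = k - 1L, q_p = pchisq(q, k - 1, lower.tail = FALSE))
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Recomputes the IVW estimate with each instrument removed in turn and flags
#' SNPs whose removal either moves the estimate by more than one fixed-effect
#' SE or carries the IVW p-value across the 0.05 boundary.
#'
#' @param pairs harmonized pairs (>= 3 rows).
#' @return data.frame with one row per instrument: `snp_id`, `beta_hat`,
#'   `se_hat`, `pval`, `delta_beta`, `influential`.
#' @export
leave_one_out <- function(pairs) {
  k <- nrow(pairs)
  if (k < 3) stop("leave-one-out requires >= 3 instruments")
  full <- mr_ivw(pairs)
  se_fixed <- full$se_hat / sqrt(max(1, full$q_stat / (k - 1)))
  rows <- lapply(seq_len(k), function(i) {
    est <- mr_ivw(pairs[-i, , drop = FALSE])
    data.frame(snp_id = pairs$snp_id[i], beta_hat = est$beta_hat,
               se_hat = est$se_hat, pval = est$pval,
               delta_beta = est$beta_hat - full$beta_hat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$influential <- abs(out$delta_beta) > se_fixed |
    ((out$pval < 0.05) != (full$pval < 0.05))
  out
}

#' Radial-MR outlier detection via per-SNP Q contributions
#'
#' Each instrument's contribution `Q_i = w_i * (b_i - beta_hat)^2` is
#' compared with a chi-square(1) upper quantile at level `alpha`
#' (Bonferroni-divided by the number of instruments when `bonferroni`).
#' Flagged SNPs are reported, not silently removed.
#'
#' @param pairs harmonized pairs (>= 3 rows).
#' @param alpha nominal level (default 0.05).
#' @param bonferroni divide `alpha` by the instrument count (default TRUE).
#' @return character vector of flagged SNP ids, with attribute `"q_i"`.
#' @export
radial_outliers <- function(pairs, alpha = 0.05, bonferroni = TRUE) {
  k <- nrow(pairs)
  if (k < 3) stop("radial outlier detection requires >= 3 instruments")
  b <- pairs$beta_out / pairs$beta_exp
  w <- .ivw_weights(pairs)
  beta_hat <- sum(w * b) / sum(w)
  q_i <- w * (b - beta_hat)^2
  thr <- qchisq(if (bonferroni) alpha / k else alpha, df = 1,
                lower.tail = FALSE)
  out <- pairs$snp_id[q_i > thr]
  attr(out, "q_i") <- setNames(q_i, pairs$snp_id)
  out
}

#' Steiger directionality filter
#'
#' For each instrument the variance explained in each trait is estimated as
#' `r2 = t^2 / (t^2 + n - 2)` with `t = beta/se` (default), or from the
#' allele frequency as `2*p*(1-p)*beta^2` when `method = "eaf"`. Instruments
#' explaining more variance in the outcome than in the exposure are removed
#' to guard against reverse causation.
#'
#' @param pairs harmonized pairs carrying `n_exp`/`n_out` (or supply them).
#' @param n_exp,n_out sample sizes; taken from `pairs` when missing.
#' @param method `"tstat"` (default) or `"eaf"`.
#' @return list with `retained` (pairs subset), `removed` (SNP ids) and the
#'   per-SNP `r2` table.
#' @export
steiger_filter <- function(pairs, n_exp = NULL, n_out = NULL,
                           method = c("tstat", "eaf")) {
  method <- match.arg(method)
  if (is.null(n_exp)) n_exp <- pairs$n_exp
  if (is.null(n_out)) n_out <- pairs$n_out
  if (is.null(n_exp) || anyNA(n_exp))
    stop("missing sample size for the exposure dataset")
  if (is.null(n_out) || anyNA(n_out))
    stop("missing sample size for the outcome dataset")
  if (method == "tstat") {
    t_exp <- pairs$beta_exp / pairs$se_exp
    t_out <- pairs$beta_out / pairs$se_out
    r2_exp <- t_exp^2 / (t_exp^2 + n_exp - 2)
    r2_out <- t_out^2 / (t_out^2 + n_out - 2)
  } else {
    r2_exp <- 2 * pairs$eaf_exp * (1 - pairs$eaf_exp) * pairs$beta_exp^2
    r2_out <- 2 * pairs$eaf_out * (1 - pairs$eaf_out) * pairs$beta_out^2
  }
  remove <- r2_out > r2_exp
  list(retained = pairs[!remove, , drop = FALSE],
       removed = pairs$snp_id[remove],
       r2 = data.frame(snp_id = pairs$snp_id, r2_exp = r2_exp,
                       r2_out = r2_out, removed = remove,
                       stringsAsFactors = FALSE))
}

#' Full sensitivity report for one harmonized pair set
#'
#' Bundles the Egger intercept test, Cochran's Q, leave-one-out table,
#' radial outliers and (optionally) the Steiger-removed set.
#'
#' @param pairs harmonized pairs (>= 3 rows for the full suite).
#' @param steiger optional result of [steiger_filter()].
#' @return list of class `sensitivity_report`.
#' @export
sensitivity_suite <- function(pairs, steiger = NULL) {
  eg <- mr_egger(pairs)
  q <- cochran_q(pairs)
  structure(list(egger_intercept = eg$intercept,
                 egger_intercept_p = eg$intercept_p,
                 q_stat = q$q_stat, q_df = q$q_df, q_p = q$q_p,
                 loo_table = leave_one_out(pairs),
                 radial_outliers = as.character(radial_outliers(pairs)),
                 steiger_removed = if (is.null(steiger)) character()
                                   else steiger$removed),
            class = "sensitivity_report")
}

#' Apply the three-criterion qualification rule
#'
#' An exposure-outcome association qualifies iff (1) the IVW p-value is
#' below 0.05, (2) the Egger intercept p-value exceeds 0.05 (no directional
#' pleiotropy), and (3) the Cochran's Q p-value exceeds 0.05 (no
#' heterogeneity). All three sub-verdicts are recorded.
#'
#' @param estimate an IVW `mr_estimate`.
#' @param sensitivity a `sensitivity_report`.
#' @param exposure,outcome trait identifiers.
#' @param direction `"forward"` or `"reverse"`.
#' @param source_id optional identifier of the originating analysis.
#' @param alpha significance level for all three criteria (default 0.05).
#' @return list of class `qualified_association`.
#' @export
qualify <- function(estimate, sensitivity, exposure = NA_character_,
                    outcome = NA_character_,
                    direction = c("forward", "reverse"),
                    source_id = NA_character_, alpha = 0.05) {
  direction <- match.arg(direction)
  crit <- c(ivw_significant = estimate$pval < alpha,
            no_pleiotropy = sensitivity$egger_intercept_p > alpha,
            no_heterogeneity = sensitivity$q_p > alpha)
  structure(list(exposure = exposure, outcome = outcome,
                 direction = direction, source_id = source_id,
                 estimate = estimate, sensitivity = sensitivity,
                 criteria = crit, qualified = all(crit)),
            class = "qualified_association")
}

#' Run the full MR workflow on one exposure/outcome summary pair
#'
#' Instrument selection, harmonization, optional Steiger filtering, IVW,
#' and the sensitivity suite, ending in the three-criterion verdict.
#'
#' @param exposure,outcome summary tables (`snp chr pos ea oa eaf beta se
#'   pval n`).
#' @param ld LD matrix covering the exposure SNPs.
#' @param exposure_id,outcome_id,source_id trait / source labels.
#' @param direction `"forward"` or `"reverse"`.
#' @param p_thresh,r2_thresh,window_kb instrument-selection thresholds.
#' @param steiger apply Steiger filtering before estimation (default TRUE).
#' @param exclude_region optional `"chr:start-end"` string; instruments in
#'   the region are dropped (by default no region is excluded, so e.g. the
#'   APOE locus is retained).
#' @return a `qualified_association`, or `NULL` (with a message) when fewer
#'   than 3 instruments survive.
#' @export
mr_run <- function(exposure, outcome, ld, exposure_id = "exposure",
                   outcome_id = "outcome",
                   direction = c("forward", "reverse"),
                   source_id = NA_character_, p_thresh = 5e-8,
                   r2_thresh = 0.001, window_kb = 1000, steiger = TRUE,
                   exclude_region = NULL) {
  direction <- match.arg(direction)
  instruments <- select_instruments(exposure, ld, p_thresh, r2_thresh,
                                    window_kb)
  if (!is.null(exclude_region)) {
    m <- regmatches(exclude_region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", exclude_region))[[1]]
    if (length(m) != 4) stop("exclude_region must look like 'chr:start-end'")
    idx <- match(instruments, exposure$snp)
    drop <- norm_chr(exposure$chr[idx]) == norm_chr(m[2]) &
      exposure$pos[idx] >= as.numeric(m[3]) &
      exposure$pos[idx] <= as.numeric(m[4])
    instruments <- instruments[!drop]
  }
  if (length(instruments) < 3) {
    message("fewer than 3 instruments for ", exposure_id, " -> ", outcome_id)
    return(NULL)
  }
  pairs <- harmonize(exposure[exposure$snp %in% instruments, , drop = FALSE],
                     outcome)
  if (nrow(pairs) < 3) {
    message("fewer than 3 harmonized pairs for ", exposure_id, " -> ",
            outcome_id)
    return(NULL)
  }
  st <- NULL
  if (steiger) {
    st <- steiger_filter(pairs)
    pairs <- st$retained
    if (nrow(pairs) < 3) {
      message("fewer than 3 instruments after Steiger filtering for ",
              exposure_id, " -> ", outcome_id)
      return(NULL)
    }
  }
  est <- mr_ivw(pairs)
  sens <- sensitivity_suite(pairs, steiger = st)
  qa <- qualify(est, sens, exposure_id, outcome_id, direction, source_id)
  qa$instruments <- pairs$snp_id
  qa
}
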