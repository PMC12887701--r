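# Shared fixture builders. Everything is generated in code; nothing binary.

# harmonized-pair table straight from Wald ratios and ratio SEs
# (beta_exp = 1 makes ratio = beta_out and ratio SE = se_out)
pairs_from_ratios <- function(ratios, ratio_ses, n = 1e5) {
  data.frame(snp_id = sprintf("s%02d", seq_along(ratios)),
             beta_exp = 1, se_exp = 0.01,
             beta_out = ratios, se_out = ratio_ses,
             eaf_exp = 0.3, eaf_out = 0.3,
             n_exp = n, n_out = n,
             palindromic = FALSE, flipped = FALSE,
             stringsAsFactors = FALSE)
}

# generic harmonized-pair builder
make_pairs <- function(beta_exp, beta_out, se_out, se_exp = 0.01, n = 1e5) {
  data.frame(snp_id = sprintf("s%02d", seq_along(beta_exp)),
             beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out,
             eaf_exp = 0.3, eaf_out = 0.3,
             n_exp = n, n_out = n,
             palindromic = FALSE, flipped = FALSE,
             stringsAsFactors = FALSE)
}

# summary-stat row builder for harmonize() tests
gwas_row <- function(snp, ea, oa, beta, eaf = 0.3, se = 0.01, n = 1e5,
                     chr = "1", pos = 1000) {
  data.frame(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

# tiny gene-set collection as a plain named list
tiny_sets <- function(...) {
  sets <- list(...)
  lapply(sets, function(s) { attr(s, "domain") <- "BP"; s })
}

# simulate a full exposure->outcome MR input and harmonize it
sim_harmonized <- function(seed, n_instruments = 30, beta_causal = 0, ...) {
  p <- simulate_gwas_pair(gwas_sim_config(n_instruments = n_instruments,
                                          beta_causal = beta_causal,
                                          seed = seed, ...))
  harmonize(p$exposure, p$outcome)
}
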