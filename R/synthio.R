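# Seeded generators producing every input the pipeline consumes, with planted
# ground truth written alongside the data. All randomness flows from the
# single `seed` field of each call; identical seeds give identical output.

#' Configuration for a simulated two-sample GWAS pair
#'
#' Describes the generative model for one exposure/outcome summary-statistic
#' pair. Per instrument j, a true standardized effect gamma_j on the exposure
#' is drawn uniformly on `gamma_range` with random sign; the true effect on
#' the outcome is `(beta_causal + N(0, het_sd)) * gamma_j + pleiotropy_mean`.
#' Estimated betas add sampling noise with standard error
#' `1 / sqrt(2 * maf * (1 - maf) * n)` (standardized-trait approximation,
#' which makes Steiger r-squared exact under this model). Directional
#' pleiotropy (`pleiotropy_mean != 0`) violates the InSIDE assumption by
#' construction, giving the Egger intercept test a usable alternative.
#'
#' @param n_instruments number of instruments (SNPs), at least 2.
#' @param beta_causal causal effect of exposure on outcome.
#' @param pleiotropy_mean mean direct SNP-to-outcome effect (directional
#'   pleiotropy intercept analog).
#' @param het_sd standard deviation of per-SNP causal-effect noise.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param maf_range length-2 numeric in (0, 0.5], minor-allele frequency range.
#' @param ld_block_size SNPs per LD block (1 = fully independent panel).
#' @param ld_r2 within-block squared correlation, in \[0, 1\].
#' @param gamma_range magnitude range for the true instrument effects on the
#'   standardized exposure scale; defaults keep instruments genome-wide
#'   significant at the default sample size.
#' @param seed integer seed.
#' @return a validated `gwas_sim_config` list.
#' @export
gwas_sim_config <- function(n_instruments = 50, beta_causal = 0,
                            pleiotropy_mean = 0, het_sd = 0,
                            n_exposure = 100000, n_outcome = 100000,
                            maf_range = c(0.1, 0.5), ld_block_size = 1,
                            ld_r2 = 0, gamma_range = c(0.03, 0.08),
                            seed = 1L) {
  if (!is.numeric(n_instruments) || n_instruments < 2)
    stop_cfg("n_instruments", "must be >= 2")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_cfg("maf_range", "must be an increasing pair in (0, 0.5]")
  if (!is.numeric(ld_r2) || ld_r2 < 0 || ld_r2 > 1)
    stop_cfg("ld_r2", "must lie in [0, 1]")
  if (ld_block_size < 1) stop_cfg("ld_block_size", "must be >= 1")
  if (het_sd < 0) stop_cfg("het_sd", "must be >= 0")
  if (n_exposure < 2 || n_outcome < 2)
    stop_cfg("n_exposure/n_outcome", "sample sizes must be >= 2")
  structure(list(
    n_instruments = as.integer(n_instruments), beta_causal = beta_causal,
    pleiotropy_mean = pleiotropy_mean, het_sd = het_sd,
    n_exposure = n_exposure, n_outcome = n_outcome, maf_range = maf_range,
    ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
    gamma_range = gamma_range, seed = as.integer(seed)
  ), class = "gwas_sim_config")
}

#' Simulate an exposure/outcome GWAS summary-statistic pair
#'
#' @param cfg a [gwas_sim_config()].
#' @return list with `exposure` and `outcome` summary tables (columns
#'   `snp chr pos ea oa eaf beta se pval n`), the block-diagonal `ld` matrix
#'   of squared correlations, and `truth` (per-SNP gamma, alpha, beta_causal).
#' @export
simulate_gwas_pair <- function(cfg) {
  stopifnot(inherits(cfg, "gwas_sim_config"))
  withr::with_seed(cfg$seed, {
    m <- cfg$n_instruments
    snp <- sprintf("rs%06d", seq_len(m))
    # one block per ld_block_size SNPs, blocks spaced 2 Mb apart so clumping
    # windows separate them; within-block SNPs 1 kb apart
    block <- (seq_len(m) - 1L) %/% cfg$ld_block_size
    pos <- 1L + block * 2000000L + ((seq_len(m) - 1L) %% cfg$ld_block_size) * 1000L
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    # effect alleles are coded as the exposure-increasing allele, so true
    # instrument effects are positive; directional pleiotropy then acts on
    # the oriented scale and is visible to the Egger intercept
    gamma <- runif(m, cfg$gamma_range[1], cfg$gamma_range[2])
    alpha <- rep(cfg$pleiotropy_mean, m)
    slope <- cfg$beta_causal + if (cfg$het_sd > 0) rnorm(m, 0, cfg$het_sd) else 0
    beta_out_true <- slope * gamma + alpha

    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome)
    beta_exp <- gamma + rnorm(m, 0, se_exp)
    beta_out <- beta_out_true + rnorm(m, 0, se_out)

    alleles <- cbind(sample(c("A", "C", "G", "T"), m, replace = TRUE), "")
    alleles[, 2] <- vapply(alleles[, 1], function(a)
      sample(setdiff(c("A", "C", "G", "T"), a), 1L), character(1))

    mk <- function(beta, se, n) data.frame(
      snp = snp, chr = "1", pos = pos, ea = alleles[, 1], oa = alleles[, 2],
      eaf = maf, beta = beta, se = se,
      pval = 2 * pnorm(-abs(beta / se)), n = n,
      stringsAsFactors = FALSE)

    ld <- diag(1, m)
    if (cfg$ld_block_size > 1L) {
      same <- outer(block, block, "==")
      ld[same] <- cfg$ld_r2
      diag(ld) <- 1
    }
    dimnames(ld) <- list(snp, snp)

    list(exposure = mk(beta_exp, se_exp, cfg$n_exposure),
         outcome = mk(beta_out, se_out, cfg$n_outcome),
         ld = ld,
         truth = data.frame(snp = snp, gamma = gamma, alpha = alpha,
                            beta_causal = cfg$beta_causal,
                            stringsAsFactors = FALSE))
  })
}

#' Specification for a simulated trait panel with planted causal modules
#'
#' @param modules named (or unnamed) list of character vectors; each vector is
#'   a group of trait names forming one planted module.
#' @param intra_edge_prob,inter_edge_prob probability that an ordered trait
#'   pair within / between modules carries a true causal link.
#' @param effect_size causal beta for true links.
#' @param n_instruments instruments per simulated GWAS pair.
#' @param n_sample GWAS sample size for each trait.
#' @param seed integer seed.
#' @return a validated `trait_panel_spec` list.
#' @export
trait_panel_spec <- function(modules, intra_edge_prob = 0.9,
                             inter_edge_prob = 0.05, effect_size = 0.2,
                             n_instruments = 20, n_sample = 100000,
                             seed = 1L) {
  traits <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(traits)) stop_cfg("modules", "trait names must be unique")
  if (intra_edge_prob < inter_edge_prob)
    warning("intra_edge_prob < inter_edge_prob: planted structure will not be recoverable")
  if (length(modules) == 1L && inter_edge_prob > 0)
    warning("single-module spec: inter_edge_prob has no effect")
  structure(list(modules = modules, intra_edge_prob = intra_edge_prob,
                 inter_edge_prob = inter_edge_prob, effect_size = effect_size,
                 n_instruments = as.integer(n_instruments),
                 n_sample = n_sample, seed = as.integer(seed)),
            class = "trait_panel_spec")
}

#' Simulate a panel of trait pairs with planted causal links
#'
#' Draws, for every ordered pair of distinct traits, a Bernoulli "true link"
#' indicator (probability `intra_edge_prob` within a module,
#' `inter_edge_prob` between modules) and simulates a two-sample GWAS pair
#' with causal effect `effect_size` (true link) or 0 (no link).
#'
#' @param spec a [trait_panel_spec()].
#' @param keep_data if `FALSE`, only the truth tables are materialized (the
#'   per-pair GWAS simulations are skipped); useful when a test needs the
#'   planted graph but not the summary statistics.
#' @return list with `pairs` (named list of [simulate_gwas_pair()] outputs,
#'   names `"exposure->outcome"`), `truth_edges` (planted directed links),
#'   and `module_table` (trait, module id).
#' @export
simulate_trait_panel <- function(spec, keep_data = TRUE) {
  stopifnot(inherits(spec, "trait_panel_spec"))
  traits <- unlist(spec$modules, use.names = FALSE)
  mod_of <- rep(seq_along(spec$modules), lengths(spec$modules))
  names(mod_of) <- traits
  grid <- expand.grid(exposure = traits, outcome = traits,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$exposure != grid$outcome, , drop = FALSE]
  grid <- grid[order(grid$exposure, grid$outcome), , drop = FALSE]
  rownames(grid) <- NULL
  intra <- mod_of[grid$exposure] == mod_of[grid$outcome]
  p_link <- ifelse(intra, spec$intra_edge_prob, spec$inter_edge_prob)
  planted <- withr::with_seed(spec$seed, rbinom(nrow(grid), 1L, p_link) == 1L)

  pairs <- NULL
  if (keep_data) {
    pairs <- lapply(seq_len(nrow(grid)), function(i) {
      cfg <- gwas_sim_config(
        n_instruments = spec$n_instruments,
        beta_causal = if (planted[i]) spec$effect_size else 0,
        n_exposure = spec$n_sample, n_outcome = spec$n_sample,
        seed = child_seed(spec$seed, i))
      simulate_gwas_pair(cfg)
    })
    names(pairs) <- paste0(grid$exposure, "->", grid$outcome)
  }
  truth_edges <- grid[planted, , drop = FALSE]
  truth_edges$beta <- rep(spec$effect_size, nrow(truth_edges))
  rownames(truth_edges) <- NULL
  list(pairs = pairs,
       truth_edges = truth_edges,
       module_table = data.frame(trait = traits, module = unname(mod_of[traits]),
                                 stringsAsFactors = FALSE))
}

#' Specification for a simulated expression cohort
#'
#' @param n_cases,n_controls sample counts (>= 2 each).
#' @param n_genes number of genes in the matrix.
#' @param active_sets character vector of gene-set names carrying signal.
#' @param effect_shift mean case/control difference, in units of `noise_sd`.
#' @param noise_sd within-group standard deviation.
#' @param seed integer seed.
#' @export
expr_sim_spec <- function(n_cases = 50, n_controls = 50, n_genes = 500,
                          active_sets = character(), effect_shift = 2,
                          noise_sd = 1, seed = 1L) {
  if (n_cases < 2 || n_controls < 2)
    stop_cfg("n_cases/n_controls", "need >= 2 samples per group")
  if (effect_shift < 0) stop_cfg("effect_shift", "must be >= 0")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_genes = as.integer(n_genes),
                 active_sets = active_sets, effect_shift = effect_shift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expr_sim_spec")
}

#' Simulate an expression matrix with planted pathway-restricted signal
#'
#' Genes belonging to the named `active_sets` have their case-group mean
#' shifted by `effect_shift * noise_sd`; all other genes are exchangeable
#' between groups.
#'
#' @param spec an [expr_sim_spec()].
#' @param gene_sets named list of character vectors (gene sets over the gene
#'   universe `g00001 ... g<n_genes>`), e.g. from [simulate_gene_sets()].
#' @return list with `matrix` (genes x samples), `labels` (data.frame
#'   `sample`, `label` with levels case/control), and `truth` (signal genes).
#' @export
simulate_expression <- function(spec, gene_sets = list()) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  unknown <- setdiff(spec$active_sets, names(gene_sets))
  if (length(unknown))
    stop("unknown active set name(s): ", paste(unknown, collapse = ", "))
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  signal <- intersect(genes, unique(unlist(gene_sets[spec$active_sets])))
  n <- spec$n_cases + spec$n_controls
  withr::with_seed(spec$seed, {
    x <- matrix(rnorm(spec$n_genes * n, 0, spec$noise_sd), spec$n_genes, n)
    rownames(x) <- genes
    colnames(x) <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
                     sprintf("ctrl_%03d", seq_len(spec$n_controls)))
    if (length(signal))
      x[signal, seq_len(spec$n_cases)] <-
        x[signal, seq_len(spec$n_cases)] + spec$effect_shift * spec$noise_sd
    list(matrix = x,
         labels = data.frame(
           sample = colnames(x),
           label = rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
           stringsAsFactors = FALSE),
         truth = data.frame(gene = signal, stringsAsFactors = FALSE))
  })
}

#' Simulate a named gene-set collection over the synthetic gene universe
#'
#' Convenience generator of disjoint or overlapping sets over the
#' `g00001 ...` universe used by [simulate_expression()].
#'
#' @param n_genes size of the gene universe.
#' @param set_sizes named integer vector: one set per element.
#' @param overlap if `TRUE` sets are drawn with replacement across sets
#'   (so they may overlap); otherwise disjoint.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
simulate_gene_sets <- function(n_genes, set_sizes, overlap = FALSE, seed = 1L) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  stopifnot(all(set_sizes <= n_genes))
  withr::with_seed(seed, {
    if (overlap) {
      out <- lapply(set_sizes, function(k) sort(sample(genes, k)))
    } else {
      stopifnot(sum(set_sizes) <= n_genes)
      pool <- sample(genes)
      out <- vector("list", length(set_sizes))
      at <- 0L
      for (i in seq_along(set_sizes)) {
        out[[i]] <- sort(pool[(at + 1L):(at + set_sizes[i])])
        at <- at + set_sizes[i]
      }
      names(out) <- names(set_sizes)
    }
    out
  })
}

#' Simulate a chemical-gene interaction edge list with planted hubs
#'
#' Planted hub chemicals receive the requested distinct-gene degrees;
#' background chemicals draw degrees uniformly from `background_degrees`.
#' Every edge carries an interaction-action label.
#'
#' @param n_chemicals total chemicals (hubs included).
#' @param n_genes size of the target-gene universe (`g00001 ...`).
#' @param hub_spec named integer vector: planted hub name -> degree.
#' @param seed integer seed.
#' @param background_degrees integer vector of degrees for non-hub chemicals.
#' @return list with `edges` (data.frame `chemical_name chemical_id
#'   gene_symbol action`) and `truth_hubs` (data.frame `chemical`, `degree`).
#' @export
simulate_chem_edges <- function(n_chemicals, n_genes, hub_spec = integer(),
                                seed = 1L, background_degrees = 1:3) {
  if (any(hub_spec > n_genes))
    stop("hub degree exceeds n_genes: ",
         paste(names(hub_spec)[hub_spec > n_genes], collapse = ", "))
  if (length(hub_spec) > n_chemicals)
    stop("more planted hubs than chemicals")
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_bg <- n_chemicals - length(hub_spec)
  chems <- c(names(hub_spec),
             if (n_bg > 0) sprintf("bgchem_%03d", seq_len(n_bg)))
  if (n_chemicals == 0L)
    return(list(edges = data.frame(chemical_name = character(),
                                   chemical_id = character(),
                                   gene_symbol = character(),
                                   action = character(),
                                   stringsAsFactors = FALSE),
                truth_hubs = data.frame(chemical = character(),
                                        degree = integer())))
  withr::with_seed(seed, {
    degs <- c(unname(hub_spec),
              if (n_bg > 0) sample(background_degrees, n_bg, replace = TRUE))
    actions <- c("activation", "inhibition", "binding", "other")
    edges <- do.call(rbind, lapply(seq_along(chems), function(i) {
      tg <- sample(genes, degs[i])
      data.frame(chemical_name = chems[i],
                 chemical_id = sprintf("MESH:%06d", i),
                 gene_symbol = tg,
                 action = sample(actions, degs[i], replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rownames(edges) <- NULL
    list(edges = edges,
         truth_hubs = data.frame(chemical = names(hub_spec),
                                 degree = unname(as.integer(hub_spec)),
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate a model-vs-control expression matrix with planted fold changes
#'
#' Values are on the log2 scale. Planted differentially expressed genes have
#' their model-group mean shifted by the requested log2 fold change; truth
#' records the planted direction and the linear-scale fold change implied by
#' the group means.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (>= 2; per-gene variance is undefined
#'   below that).
#' @param deg_spec data.frame with columns `gene` (indices into the gene
#'   universe or gene names) and `lfc` (planted log2 fold change), or an
#'   empty data.frame for an all-null matrix.
#' @param seed integer seed.
#' @param noise_sd within-group SD on the log2 scale.
#' @param base_mean baseline log2 expression level.
#' @return list with `matrix` (genes x samples, log2 scale), `groups`
#'   (data.frame `sample`, `group` model/control) and `truth` (gene, planted
#'   lfc, linear fold change, direction).
#' @export
simulate_invivo <- function(n_genes, n_per_group, deg_spec = NULL, seed = 1L,
                            noise_sd = 0.5, base_mean = 6) {
  if (n_per_group < 2)
    stop("n_per_group must be >= 2 (per-gene variance undefined otherwise)")
  genes <- sprintf("mgene%05d", seq_len(n_genes))
  if (is.null(deg_spec) || NROW(deg_spec) == 0L)
    deg_spec <- data.frame(gene = character(), lfc = numeric())
  deg_genes <- if (is.numeric(deg_spec$gene)) genes[deg_spec$gene] else as.character(deg_spec$gene)
  stopifnot(all(deg_genes %in% genes))
  withr::with_seed(seed, {
    n <- 2L * n_per_group
    x <- matrix(rnorm(n_genes * n, base_mean, noise_sd), n_genes, n)
    rownames(x) <- genes
    colnames(x) <- c(sprintf("model_%02d", seq_len(n_per_group)),
                     sprintf("control_%02d", seq_len(n_per_group)))
    if (length(deg_genes))
      x[deg_genes, seq_len(n_per_group)] <-
        x[deg_genes, seq_len(n_per_group)] + deg_spec$lfc
    truth <- data.frame(gene = deg_genes, lfc = deg_spec$lfc,
                        fold_change = 2^deg_spec$lfc,
                        direction = ifelse(deg_spec$lfc > 0, "up", "down"),
                        stringsAsFactors = FALSE)
    list(matrix = x,
         groups = data.frame(sample = colnames(x),
                             group = rep(c("model", "control"),
                                         each = n_per_group),
                             stringsAsFactors = FALSE),
         truth = truth)
  })
}
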