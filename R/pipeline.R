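# Orchestration: configuration with the published default thresholds, the
# end-to-end synthetic demonstration run, and its manifest.

#' Pipeline run configuration
#'
#' Every threshold defaults to its published value: genome-wide significance
#' 5e-8, clumping r2 < 0.001 within 1000 kb, the 0.05 qualification trio,
#' 50 kb gene-mapping flank, enrichment FDR 0.05 with 5-2000 set-size
#' bounds, ANOVA-F 0.01, 10-fold CV, top 5 models, top 1% genes, top 5 hub
#' chemicals, and DEG gates p < 0.05 with |log2FC| > 1.
#'
#' @param seed master seed; all stage seeds derive from it via
#'   [child_seed()].
#' @param stages character vector of stage names to run (default: all, in
#'   order).
#' @param ... overrides for any threshold listed above (see the field names
#'   in the returned object).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, stages = c(
                         "synthio", "mr", "network", "enrichment", "ml",
                         "scoring", "chem", "invivo"), ...) {
  cfg <- list(
    seed = as.integer(seed), stages = stages,
    p_thresh = 5e-8, r2_thresh = 0.001, window_kb = 1000,
    qualify_alpha = 0.05, flank_kb = 50,
    fdr_thresh = 0.05, set_min = 5, set_max = 2000,
    f_alpha = 0.01, cv_folds = 10, top_models = 5, top_frac = 0.01,
    top_hubs = 5, deg_p = 0.05, deg_lfc = 1.0,
    # synthetic-demo sizes (chosen so the full run stays well inside a
    # 10-minute single-CPU budget; see the methods vignette)
    demo_modules = list(metabolic = c("T2D", "Obesity", "Hypertension"),
                        neuro = c("AD", "Dementia", "VaD")),
    demo_n_instruments = 20, demo_n_sample = 100000,
    demo_effect_size = 0.25,
    demo_n_cases = 40, demo_n_controls = 40, demo_n_genes = 300,
    demo_effect_shift = 1.5, demo_ntree = 60,
    demo_n_chemicals = 20, demo_hub_degree = 12,
    demo_invivo_genes = 1000, demo_invivo_degs = 60,
    demo_invivo_n = 3, demo_invivo_lfc = 2)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

write_stage <- function(dir, stage, files) {
  d <- file.path(dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Run the full synthetic demonstration pipeline
#'
#' Executes all eight stages in order on synthetic data with planted ground
#' truth: data generation, bidirectional MR over every trait pair, trait
#' network and module filtering, enrichment, pathway-restricted ML,
#' gene scoring, chemical hub networks, and in vivo DE with the
#' comprehensive target ranking. Stage outputs are written as TSV/JSON under
#' `out_dir`; a manifest records seeds, stage status and input digests. Any
#' stage failure marks the stage failed and skips the stages that depend on
#' it.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the per-stage results and the manifest.
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("nexuslipid_"),
                    quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[nexuslipid] ", ...)
  manifest <- list(package_version = as.character(utils::packageVersion("nexuslipid")),
                   seed = config$seed, stages = list())
  state <- list()
  mark <- function(stage, status) {
    manifest$stages[[stage]] <<- list(status = status)
  }
  run_stage <- function(stage, deps, fun) {
    if (!stage %in% config$stages) { mark(stage, "toggled off"); return() }
    missing_dep <- deps[!deps %in% names(state)]
    if (length(missing_dep)) {
      mark(stage, paste0("skipped: missing input from ",
                         paste(missing_dep, collapse = ", ")))
      say(stage, ": skipped (missing ", paste(missing_dep, collapse = ", "),
          ")")
      return()
    }
    say("stage ", stage)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      mark(stage, paste0("failed: ", conditionMessage(res)))
      say(stage, " FAILED: ", conditionMessage(res))
    } else {
      state[[stage]] <<- res
      mark(stage, "completed")
    }
  }

  run_stage("synthio", character(), function() {
    d <- write_stage(out_dir, "synthio")
    panel <- simulate_trait_panel(trait_panel_spec(
      config$demo_modules, intra_edge_prob = 0.9, inter_edge_prob = 0.05,
      effect_size = config$demo_effect_size,
      n_instruments = config$demo_n_instruments,
      n_sample = config$demo_n_sample, seed = child_seed(config$seed, 1)))
    gene_sets <- simulate_gene_sets(config$demo_n_genes,
      set_sizes = c(lipid_transport = 25, glucose_homeostasis = 25,
                    synapse_organization = 25, inflammatory_response = 25),
      seed = child_seed(config$seed, 2))
    expr <- simulate_expression(expr_sim_spec(
      n_cases = config$demo_n_cases, n_controls = config$demo_n_controls,
      n_genes = config$demo_n_genes, active_sets = "lipid_transport",
      effect_shift = config$demo_effect_shift,
      seed = child_seed(config$seed, 3)), gene_sets)
    chem <- simulate_chem_edges(config$demo_n_chemicals, config$demo_n_genes,
      hub_spec = c(valproate_like = config$demo_hub_degree,
                   pyrene_like = config$demo_hub_degree - 2L),
      seed = child_seed(config$seed, 4))
    deg_spec <- data.frame(
      gene = seq_len(config$demo_invivo_degs),
      lfc = rep(c(config$demo_invivo_lfc, -config$demo_invivo_lfc),
                length.out = config$demo_invivo_degs))
    invivo <- simulate_invivo(config$demo_invivo_genes, config$demo_invivo_n,
                              deg_spec, seed = child_seed(config$seed, 5))
    write_truth_json(list(truth_edges = panel$truth_edges,
                          modules = panel$module_table,
                          signal_genes = expr$truth$gene,
                          hubs = chem$truth_hubs,
                          invivo_degs = invivo$truth),
                     file.path(d, "truth.json"))
    write_expression_tsv(expr$matrix, file.path(d, "expression.tsv"))
    write.table(expr$labels, file.path(d, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(chem$edges, file.path(d, "chem_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_expression_tsv(invivo$matrix, file.path(d, "invivo_matrix.tsv"))
    list(panel = panel, gene_sets = gene_sets, expr = expr, chem = chem,
         invivo = invivo)
  })

  run_stage("mr", "synthio", function() {
    d <- write_stage(out_dir, "mr")
    panel <- state$synthio$panel
    qa <- lapply(names(panel$pairs), function(nm) {
      p <- panel$pairs[[nm]]
      traits <- strsplit(nm, "->", fixed = TRUE)[[1]]
      mr_run(p$exposure, p$outcome, p$ld, exposure_id = traits[1],
             outcome_id = traits[2], direction = "forward",
             source_id = "demo", p_thresh = config$p_thresh,
             r2_thresh = config$r2_thresh, window_kb = config$window_kb)
    })
    qa <- qa[!vapply(qa, is.null, logical(1))]
    est <- do.call(rbind, lapply(qa, function(a) data.frame(
      exposure = a$exposure, outcome = a$outcome, beta = a$estimate$beta_hat,
      se = a$estimate$se_hat, pval = a$estimate$pval, or_ = a$estimate$or_,
      ci_low = a$estimate$ci_low, ci_high = a$estimate$ci_high,
      nsnp = a$estimate$nsnp, egger_intercept_p = a$sensitivity$egger_intercept_p,
      q_p = a$sensitivity$q_p, qualified = a$qualified,
      stringsAsFactors = FALSE)))
    write.table(est, file.path(d, "estimates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    qa
  })

  run_stage("network", "mr", function() {
    d <- write_stage(out_dir, "network")
    qa <- state$mr
    graph <- build_trait_graph(qa)
    modules <- detect_modules(graph, seed = child_seed(config$seed, 10))
    core <- core_relationships(graph, modules)
    fwd <- do.call(rbind, lapply(qa, function(a) if (a$qualified)
      data.frame(exposure = a$exposure, outcome = a$outcome,
                 source_id = a$source_id, direction = a$direction,
                 stringsAsFactors = FALSE)))
    fwd$instruments <- lapply(qa[vapply(qa, `[[`, logical(1), "qualified")],
                              `[[`, "instruments")
    filt <- filter_bidirectional(fwd, fwd[0, ], core)
    freq <- snp_frequency(filt$forward)
    write.table(data.frame(trait = names(modules), module = modules),
                file.path(d, "modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(core, file.path(d, "core_relationships.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(freq, file.path(d, "snp_frequency.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(graph = graph, modules = modules, core = core, filtered = filt,
         freq = freq)
  })

  run_stage("enrichment", "synthio", function() {
    d <- write_stage(out_dir, "enrichment")
    sets <- state$synthio$gene_sets
    # query: the planted signal genes plus background noise, emulating the
    # mapped-gene list emerging from the genetic arm
    truth_genes <- state$synthio$expr$truth$gene
    query <- unique(c(truth_genes,
                      withr::with_seed(child_seed(config$seed, 20),
                        sample(sprintf("g%05d", seq_len(config$demo_n_genes)),
                               10))))
    filtered <- filter_gene_sets(sets, min_size = config$set_min,
                                 max_size = config$set_max)
    res <- enrich(query, filtered, fdr_thresh = config$fdr_thresh)
    write.table(res, file.path(d, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res
  })

  run_stage("ml", c("synthio", "enrichment"), function() {
    d <- write_stage(out_dir, "ml")
    enr <- state$enrichment
    sig_sets <- enr$set_name[enr$significant]
    if (!length(sig_sets)) sig_sets <- enr$set_name[which.min(enr$p)]
    expr <- state$synthio$expr
    suite <- default_model_suite(ntree = config$demo_ntree)
    results <- lapply(sig_sets, function(pw) {
      feats <- intersect(state$synthio$gene_sets[[pw]], rownames(expr$matrix))
      x <- t(expr$matrix[feats, , drop = FALSE])
      evaluate_pathway(x, expr$labels$label, suite, k = config$cv_folds,
                       seed = child_seed(config$seed, 30),
                       top_n = config$top_models, f_alpha = config$f_alpha)
    })
    names(results) <- sig_sets
    metrics <- do.call(rbind, lapply(sig_sets, function(pw)
      data.frame(pathway = pw, results[[pw]]$metrics,
                 stringsAsFactors = FALSE)))
    write.table(metrics, file.path(d, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results
  })

  run_stage("scoring", "ml", function() {
    d <- write_stage(out_dir, "scoring")
    rec <- pwis_records(state$ml, dataset_id = "demo_cohort")
    prio <- gene_prioritization(rec, top_frac = config$top_frac)
    dss <- dataset_specific_score(rec)
    hgs <- holistic_score(rec)
    write.table(prio, file.path(d, "gene_prioritization.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(hgs, file.path(d, "holistic_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(records = rec, prioritization = prio, dss = dss, hgs = hgs)
  })

  run_stage("chem", c("synthio", "scoring"), function() {
    d <- write_stage(out_dir, "chem")
    edges <- state$synthio$chem$edges
    # prioritized set: top-ranked genes from the scoring cascade, padded
    # with the planted signal genes so hub recovery is well-posed
    prio <- union(state$scoring$prioritization$gene[
                    state$scoring$prioritization$retained],
                  state$synthio$expr$truth$gene)
    hubs <- hub_chemicals(edges, prio, top_n = config$top_hubs)
    sub <- edges[edges$chemical_name %in% hubs$chemical, , drop = FALSE]
    comm <- chem_communities(sub, seed = child_seed(config$seed, 40))
    integrated <- integrate_bipartite(list(demo_cohort = sub))
    write.table(hubs, file.path(d, "hubs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(integrated$convergence, file.path(d, "convergence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(hubs = hubs, communities = comm, integrated = integrated)
  })

  run_stage("invivo", "synthio", function() {
    d <- write_stage(out_dir, "invivo")
    iv <- state$synthio$invivo
    de <- differential_expression(iv$matrix, iv$groups)
    degs <- call_degs(de, p_thresh = config$deg_p,
                      lfc_thresh = config$deg_lfc)
    chem_edges <- simulate_chem_edges(
      8, nrow(iv$matrix),
      hub_spec = c(chem_a = 40L, chem_b = 30L, chem_c = 20L),
      seed = child_seed(config$seed, 50))$edges
    chem_edges$gene_symbol <- sub("^g", "mgene",
                                  chem_edges$gene_symbol)
    ranking <- comprehensive_score(degs$degs$gene, chem_edges, de)
    write.table(de, file.path(d, "de.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_truth_json(list(n_up = degs$n_up, n_down = degs$n_down,
                          n_deg = nrow(degs$degs)),
                     file.path(d, "deg_summary.json"))
    write.table(ranking, file.path(d, "target_ranking.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(de = de, degs = degs, ranking = ranking)
  })

  manifest$completed <- sum(vapply(manifest$stages, function(s)
    identical(s$status, "completed"), logical(1)))
  write_truth_json(manifest, file.path(out_dir, "manifest.json"))
  say("done: ", manifest$completed, "/", length(manifest$stages),
      " stages completed; outputs in ", out_dir)
  invisible(list(state = state, manifest = manifest, out_dir = out_dir))
}

#' One-call synthetic demonstration
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return see [run_all()].
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("nexuslipid_demo_"),
                     quiet = FALSE) {
  run_all(run_config(seed = seed), out_dir = out_dir, quiet = quiet)
}
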