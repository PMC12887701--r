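# Trait-level causal graph, Walktrap modules, core relationships, the
# bidirectional filter, instrument frequency prioritization and positional
# gene mapping.

#' Build the trait-level causal graph from forward qualified associations
#'
#' One directed edge per qualified exposure-outcome pair; duplicate pairs
#' from different sources collapse into a single edge whose `weight` counts
#' the parallel qualified results. Unqualified inputs contribute nothing.
#'
#' @param associations list of `qualified_association` objects, or a
#'   data.frame with columns `exposure`, `outcome`, `qualified` (optional
#'   `beta`, `pval`, `source_id`).
#' @return an [igraph::graph] (directed) with edge attributes `weight`,
#'   `beta`, `pval`, `sources`.
#' @export
build_trait_graph <- function(associations) {
  df <- if (is.data.frame(associations)) associations else
    do.call(rbind, lapply(associations, function(a) data.frame(
      exposure = a$exposure, outcome = a$outcome,
      beta = a$estimate$beta_hat, pval = a$estimate$pval,
      source_id = a$source_id, qualified = a$qualified,
      stringsAsFactors = FALSE)))
  if (is.null(df) || nrow(df) == 0L || !any(df$qualified)) {
    warning("no qualified associations: returning an empty graph")
    return(igraph::make_empty_graph(directed = TRUE))
  }
  df <- df[df$qualified, , drop = FALSE]
  stopifnot(all(df$exposure != df$outcome))
  key <- paste(df$exposure, df$outcome, sep = "\r")
  agg <- do.call(rbind, lapply(split(df, key), function(d) data.frame(
    exposure = d$exposure[1], outcome = d$outcome[1],
    weight = nrow(d),
    beta = d$beta[which.min(d$pval)][1],
    pval = min(d$pval),
    sources = paste(unique(d$source_id), collapse = ";"),
    stringsAsFactors = FALSE)))
  igraph::graph_from_data_frame(agg, directed = TRUE)
}

#' Detect trait modules with the Walktrap algorithm
#'
#' The directed causal graph is projected to its weighted undirected form
#' (parallel qualified results accumulate into edge weight) and partitioned
#' by short-random-walk agglomeration with the modularity-maximizing cut.
#' Isolated nodes become singleton modules. Walktrap is deterministic given
#' the graph, but a seed is fixed anyway for igraph internals.
#'
#' @param graph a directed trait graph from [build_trait_graph()].
#' @param walk_steps random-walk length (default 4).
#' @param seed integer seed.
#' @param weighted use edge weights (default TRUE).
#' @return named integer vector: trait -> module id (1-based).
#' @export
detect_modules <- function(graph, walk_steps = 4, seed = 1L, weighted = TRUE) {
  if (igraph::vcount(graph) == 0L)
    return(setNames(integer(), character()))
  und <- igraph::as_undirected(graph, mode = "collapse",
                               edge.attr.comb = list(weight = "sum",
                                                     "ignore"))
  wt <- if (weighted && "weight" %in% igraph::edge_attr_names(und))
    igraph::E(und)$weight else NULL
  memb <- withr::with_seed(seed, {
    cl <- igraph::cluster_walktrap(und, weights = wt, steps = walk_steps)
    igraph::membership(cl)
  })
  out <- as.integer(memb)
  names(out) <- names(memb)
  # renumber to consecutive 1-based ids in first-appearance order
  out[] <- match(out, unique(out))
  out
}

#' Core network relationships: edges whose endpoints share a module
#'
#' @param graph directed trait graph.
#' @param modules named module assignment covering all graph nodes
#'   (from [detect_modules()]).
#' @return data.frame `exposure`, `outcome`, `module_id`.
#' @export
core_relationships <- function(graph, modules) {
  el <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(el) == 0L)
    return(data.frame(exposure = character(), outcome = character(),
                      module_id = integer()))
  stopifnot(all(c(el$from, el$to) %in% names(modules)))
  same <- modules[el$from] == modules[el$to]
  data.frame(exposure = el$from[same], outcome = el$to[same],
             module_id = unname(modules[el$from[same]]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bidirectional network-informed filter
#'
#' Forward results are retained iff their (exposure, outcome) pair belongs to
#' the core set; reverse results iff their pair exactly inverts a core
#' forward relationship.
#'
#' @param forward,reverse data.frames with `exposure`, `outcome` columns
#'   (any extra columns pass through).
#' @param core core relationship set from [core_relationships()].
#' @return list with `forward` and `reverse` retained subsets, each annotated
#'   with `module_id`.
#' @export
filter_bidirectional <- function(forward, reverse, core) {
  key <- function(e, o) paste(e, o, sep = "\r")
  ck <- key(core$exposure, core$outcome)
  pick <- function(df, inverted) {
    if (is.null(df) || nrow(df) == 0L) {
      df <- df[0, , drop = FALSE]
      df$module_id <- integer()
      return(df)
    }
    k <- if (inverted) key(df$outcome, df$exposure) else
      key(df$exposure, df$outcome)
    hit <- match(k, ck)
    out <- df[!is.na(hit), , drop = FALSE]
    out$module_id <- core$module_id[hit[!is.na(hit)]]
    rownames(out) <- NULL
    out
  }
  list(forward = pick(forward, inverted = FALSE),
       reverse = pick(reverse, inverted = TRUE))
}

#' Instrument frequency across module-supported relationships
#'
#' Counts, separately within each (source id, direction) stratum, the number
#' of distinct retained causal relationships in which each SNP served as an
#' instrument. Rankings break ties by SNP id.
#'
#' @param results data.frame with one row per retained relationship,
#'   columns `exposure`, `outcome`, `source_id`, `direction`, and a
#'   list-column `instruments` of SNP-id character vectors.
#' @return data.frame `snp_id`, `source_id`, `direction`, `frequency`,
#'   sorted by descending frequency then SNP id within each stratum.
#' @export
snp_frequency <- function(results) {
  if (is.null(results) || nrow(results) == 0L)
    return(data.frame(snp_id = character(), source_id = character(),
                      direction = character(), frequency = integer()))
  rows <- lapply(seq_len(nrow(results)), function(i) {
    snps <- unique(results$instruments[[i]])
    if (!length(snps)) return(NULL)
    data.frame(snp_id = snps, source_id = results$source_id[i],
               direction = results$direction[i], stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  agg <- aggregate(list(frequency = rep(1L, nrow(long))),
                   by = long[c("snp_id", "source_id", "direction")], FUN = sum)
  agg <- agg[order(agg$source_id, agg$direction, -agg$frequency, agg$snp_id), ]
  rownames(agg) <- NULL
  agg[c("snp_id", "source_id", "direction", "frequency")]
}

#' Map SNPs to their nearest gene within a flanking window
#'
#' SNP positions are 1-based points; annotation intervals follow the BED
#' convention (0-based half-open). Distance is 0 when the SNP lies inside a
#' gene, otherwise the gap to the nearest boundary; the minimum-distance gene
#' is assigned iff that distance is at most `flank_kb * 1000` (boundary
#' inclusive). Chromosome names are normalized ("chr1" == "1"). Ties are
#' broken by smaller start coordinate, then gene symbol.
#'
#' @param snps data.frame with `snp`, `chr`, `pos` (1-based).
#' @param annotation data.frame with `chr`, `start`, `end`, `gene`
#'   (BED4, 0-based half-open; see [read_bed4()]).
#' @param flank_kb flanking window in kb (default 50).
#' @return data.frame `snp`, `gene`, `distance` (NA gene for unmapped SNPs).
#' @export
map_genes <- function(snps, annotation, flank_kb = 50) {
  stopifnot(all(annotation$start < annotation$end))
  ann_chr <- norm_chr(annotation$chr)
  max_gap <- flank_kb * 1000
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    p0 <- snps$pos[i] - 1L            # convert 1-based point to 0-based
    on_chr <- annotation[ann_chr == norm_chr(snps$chr[i]), , drop = FALSE]
    if (nrow(on_chr) == 0L)
      return(data.frame(snp = snps$snp[i], gene = NA_character_,
                        distance = NA_real_, stringsAsFactors = FALSE))
    inside <- p0 >= on_chr$start & p0 < on_chr$end
    d <- ifelse(inside, 0,
                pmax(on_chr$start - p0, p0 - (on_chr$end - 1L), 0))
    ord <- order(d, on_chr$start, on_chr$gene)
    best <- ord[1]
    if (d[best] <= max_gap)
      data.frame(snp = snps$snp[i], gene = on_chr$gene[best],
                 distance = d[best], stringsAsFactors = FALSE)
    else
      data.frame(snp = snps$snp[i], gene = NA_character_,
                 distance = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unique/shared SNP membership across named causal pathways
#'
#' Computes, for every SNP appearing in any of the named sets, the exact
#' combination of pathways containing it, plus per-combination counts
#' (upset-style).
#'
#' @param snp_sets named list (>= 2 entries) of SNP-id character vectors.
#' @return list with `membership` (data.frame `snp`, `combination`) and
#'   `counts` (data.frame `combination`, `n`, `degree`).
#' @export
shared_snp_analysis <- function(snp_sets) {
  stopifnot(length(snp_sets) >= 2, !is.null(names(snp_sets)))
  all_snps <- sort(unique(unlist(snp_sets)))
  inmat <- vapply(snp_sets, function(s) all_snps %in% s,
                  logical(length(all_snps)))
  if (length(all_snps) == 1L) inmat <- matrix(inmat, nrow = 1,
                                              dimnames = list(NULL, names(snp_sets)))
  combo <- apply(inmat, 1, function(r)
    paste(names(snp_sets)[r], collapse = "&"))
  membership <- data.frame(snp = all_snps, combination = combo,
                           stringsAsFactors = FALSE)
  counts <- as.data.frame(table(combination = combo),
                          stringsAsFactors = FALSE)
  names(counts)[2] <- "n"
  counts$degree <- lengths(strsplit(counts$combination, "&", fixed = TRUE))
  counts <- counts[order(-counts$n, counts$combination), ]
  rownames(counts) <- NULL
  list(membership = membership, counts = counts)
}
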