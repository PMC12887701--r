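# Hub-chemical identification, Louvain community structure, and
# cross-disease convergence on prioritized genes from CTD-style edge lists.

dedup_edges <- function(edges) {
  unique(edges[c("chemical_name", "chemical_id", "gene_symbol", "action")])
}

#' Identify hub chemicals against a prioritized gene set
#'
#' Degree counts distinct prioritized genes (a chemical with several actions
#' on one gene has degree 1 for it). Chemicals are sorted by descending
#' degree with ties broken by ascending name; the top `top_n` are returned
#' with contiguous ranks from 1.
#'
#' @param edges chemical-gene edge table
#'   (`chemical_name chemical_id gene_symbol action`).
#' @param prioritized non-empty character vector of prioritized genes.
#' @param top_n hubs to return (default 5).
#' @return data.frame `chemical degree rank` (empty, with a warning, when no
#'   chemical touches the prioritized set).
#' @export
hub_chemicals <- function(edges, prioritized, top_n = 5) {
  stopifnot(length(prioritized) > 0)
  e <- dedup_edges(edges)
  e <- e[e$gene_symbol %in% prioritized, , drop = FALSE]
  if (nrow(e) == 0L) {
    warning("no chemical interacts with the prioritized gene set")
    return(data.frame(chemical = character(), degree = integer(),
                      rank = integer()))
  }
  deg <- tapply(e$gene_symbol, e$chemical_name,
                function(g) length(unique(g)))
  out <- data.frame(chemical = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$chemical), , drop = FALSE]
  out <- head(out, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Louvain communities on a chemical-gene interaction graph
#'
#' The bipartite edge set (typically restricted to hubs and their targets)
#' is treated as a simple undirected graph; Louvain modularity maximization
#' is run with a fixed seed and sorted node order, making the partition
#' deterministic.
#'
#' @param edges chemical-gene edge table.
#' @param seed integer seed.
#' @param resolution Louvain resolution parameter (default 1).
#' @return named integer vector node -> community id (1-based), with a
#'   `"modularity"` attribute.
#' @export
chem_communities <- function(edges, seed = 1L, resolution = 1) {
  e <- dedup_edges(edges)
  stopifnot(nrow(e) > 0)
  el <- unique(data.frame(from = e$chemical_name, to = e$gene_symbol,
                          stringsAsFactors = FALSE))
  el <- el[order(el$from, el$to), ]
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)
  out <- as.integer(memb)
  names(out) <- names(memb)
  out[] <- match(out, unique(out))
  attr(out, "modularity") <- max(igraph::modularity(cl))
  out
}

#' Integrate per-disease hub networks into one bipartite graph
#'
#' Unions the edges of every disease context's selected chemicals, keeping
#' edge provenance, and counts for each gene the number of distinct selected
#' chemicals targeting it (convergence). A chemical selected in several
#' diseases is counted once per gene.
#'
#' @param disease_edges named list: disease -> edge table restricted to that
#'   disease's selected (hub) chemicals.
#' @return list with `edges` (unified edge table with a `diseases`
#'   provenance column) and `convergence` (data.frame `gene`, `n_chemicals`
#'   sorted descending; genes untouched by any selected chemical are absent).
#' @export
integrate_bipartite <- function(disease_edges) {
  stopifnot(length(disease_edges) >= 1, !is.null(names(disease_edges)))
  long <- do.call(rbind, lapply(names(disease_edges), function(d) {
    e <- dedup_edges(disease_edges[[d]])
    if (nrow(e) == 0L) return(NULL)
    e$disease <- d
    e
  }))
  key <- paste(long$chemical_name, long$gene_symbol, long$action, sep = "\r")
  prov <- tapply(long$disease, key, function(d)
    paste(sort(unique(d)), collapse = ";"))
  uni <- long[!duplicated(key), c("chemical_name", "chemical_id",
                                  "gene_symbol", "action")]
  uni$diseases <- as.character(prov[key[!duplicated(key)]])
  uni <- uni[order(uni$chemical_name, uni$gene_symbol, uni$action), ]
  rownames(uni) <- NULL
  cg <- unique(uni[c("chemical_name", "gene_symbol")])
  conv <- tapply(cg$chemical_name, cg$gene_symbol,
                 function(ch) length(unique(ch)))
  convergence <- data.frame(gene = names(conv),
                            n_chemicals = as.integer(conv),
                            stringsAsFactors = FALSE)
  convergence <- convergence[order(-convergence$n_chemicals,
                                   convergence$gene), ]
  rownames(convergence) <- NULL
  list(edges = uni, convergence = convergence)
}
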