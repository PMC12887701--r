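# Hypergeometric over-representation of gene lists against a GMT collection
# with Benjamini-Hochberg FDR control.

#' Read a GMT gene-set collection
#'
#' Tab-separated `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are deduplicated with a warning. The description field
#' doubles as a free domain tag (BP/CC/MF/HPO or anything else).
#'
#' @param path path to a GMT file.
#' @return named list of class `gene_set_collection`; each element is a
#'   character vector of member genes with a `"domain"` attribute.
#' @export
load_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": need name, description and >=1 gene")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1], "' deduplicated")
      genes <- unique(genes)
    }
    attr(genes, "domain") <- f[2]
    out[[f[1]]] <- genes
  }
  structure(out, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors (optionally with a `"domain"`
#'   attribute per set).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    dom <- attr(sets[[nm]], "domain")
    paste(c(nm, if (is.null(dom)) "na" else dom, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter a gene-set collection to the usable size range
#'
#' Set sizes are counted after intersection with the background; sets with
#' fewer than `min_size` or more than `max_size` surviving members are
#' dropped (bounds inclusive: 5 and 2000 are retained by default).
#'
#' @param sets named list of gene sets.
#' @param background character vector of background genes (NULL = no
#'   intersection).
#' @param min_size,max_size inclusive size bounds (defaults 5 and 2000).
#' @return the filtered named list.
#' @export
filter_gene_sets <- function(sets, background = NULL, min_size = 5,
                             max_size = 2000) {
  sizes <- vapply(sets, function(s)
    length(if (is.null(background)) s else intersect(s, background)),
    integer(1))
  sets[sizes >= min_size & sizes <= max_size]
}

#' Hypergeometric over-representation test across a gene-set collection
#'
#' For each set, `p = P(X >= k)` under Hypergeometric(N, K, n) where N is the
#' background size, K the set size, n the query size and k the overlap (all
#' counts after intersection with the background). Benjamini-Hochberg
#' adjustment runs across all tested sets; sets are flagged significant at
#' `fdr < fdr_thresh`.
#'
#' When no background is supplied it defaults to the union of all genes
#' across the (filtered) collection; query genes outside the background are
#' dropped before counting.
#'
#' @param query character vector of query genes.
#' @param collection named list of gene sets (pre-filter with
#'   [filter_gene_sets()] to apply the 5-2000 size bounds).
#' @param background optional background gene vector.
#' @param fdr_thresh significance threshold on the adjusted p (default 0.05).
#' @return data.frame `set_name domain N K n k p fdr significant`, ordered
#'   by ascending p.
#' @export
enrich <- function(query, collection, background = NULL, fdr_thresh = 0.05) {
  if (is.null(background)) background <- unique(unlist(collection))
  background <- unique(background)
  query <- unique(intersect(query, background))
  empty <- data.frame(set_name = character(), domain = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p = numeric(), fdr = numeric(),
                      significant = logical())
  if (!length(query)) {
    warning("empty query after background intersection")
    return(empty)
  }
  if (!length(collection)) return(empty)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], background)
    K <- length(members)
    k <- length(intersect(query, members))
    # upper tail P(X >= k): survival function evaluated at k - 1
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    dom <- attr(collection[[nm]], "domain")
    data.frame(set_name = nm, domain = if (is.null(dom)) NA_character_ else dom,
               N = N, K = K, n = n, k = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_thresh
  out <- out[order(out$p, out$set_name), ]
  rownames(out) <- NULL
  out
}
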