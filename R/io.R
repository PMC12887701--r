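# Plain-text readers/writers for the pipeline's interchange formats:
# GWAS summary TSV, LD TSV, expression + label TSV, BED4 annotation,
# CTD-style chemical-gene edge TSV, and JSON truth files.

#' Read / write a GWAS summary-statistics TSV
#'
#' Header `snp chr pos ea oa eaf beta se pval n`; positions are 1-based.
#'
#' @param path file path.
#' @return data.frame with the columns above.
#' @export
read_gwas_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chr = "character"))
  need <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("GWAS TSV missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' @rdname read_gwas_tsv
#' @param gwas summary table to write.
#' @export
write_gwas_tsv <- function(gwas, path) {
  write.table(gwas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an LD matrix TSV (square, SNP ids as header)
#'
#' @param path file path.
#' @return square numeric matrix of squared correlations.
#' @export
read_ld_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  stopifnot(nrow(m) == ncol(m))
  m
}

#' @rdname read_ld_tsv
#' @param ld matrix to write.
#' @export
write_ld_tsv <- function(ld, path) {
  write.table(ld, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED4 gene annotation (0-based half-open intervals)
#'
#' Columns `chr start end gene`, no header.
#'
#' @param path file path.
#' @return data.frame `chr`, `start`, `end`, `gene`.
#' @export
read_bed4 <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chr", "start", "end", "gene"),
                   colClasses = c("character", "integer", "integer",
                                  "character"))
  stopifnot(all(df$start < df$end))
  df
}

#' Read / write an expression matrix TSV (genes x samples)
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_expression_tsv
#' @param mat matrix to write.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample/label TSV
#'
#' @param path file path.
#' @return data.frame with the file's two columns.
#' @export
read_labels_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2)
  df
}

#' Read a CTD-style chemical-gene edge TSV
#'
#' Accepts either the package's native header
#' (`chemical_name chemical_id gene_symbol action`) or CTD export column
#' names (`ChemicalName ChemicalID GeneSymbol InteractionActions`).
#'
#' @param path file path.
#' @return data.frame `chemical_name chemical_id gene_symbol action`.
#' @export
read_chem_edges_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ctd <- c(ChemicalName = "chemical_name", ChemicalID = "chemical_id",
           GeneSymbol = "gene_symbol", InteractionActions = "action")
  hit <- names(df) %in% names(ctd)
  names(df)[hit] <- ctd[names(df)[hit]]
  need <- c("chemical_name", "chemical_id", "gene_symbol", "action")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("chemical edge TSV missing column(s): ",
         paste(missing, collapse = ", "))
  df[need]
}

#' Write an R object as pretty JSON (truth files, manifests)
#'
#' @param x object to serialize.
#' @param path output path.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
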