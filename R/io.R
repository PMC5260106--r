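# Plain-text readers/writers for the dialects the CLI speaks.  Everything is
# TSV/CSV/JSON so outputs stay diffable.

#' Read a drug label table
#'
#' Expects a TSV with columns `id` and `class`, where class is one of
#' `effective`, `ineffective`, `aging_gene`.
#'
#' @param path path to the labels TSV.
#' @return A [label_set()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path))
    stop_fmt("rwrscreen_io_error", "labels file not found: %s", path)
  tab <- read.delim(path, colClasses = "character")
  if (!all(c("id", "class") %in% names(tab)))
    stop_fmt("rwrscreen_format_error",
             "labels file needs columns 'id' and 'class'")
  bad <- setdiff(unique(tab$class), c("effective", "ineffective",
                                      "aging_gene"))
  if (length(bad))
    stop_fmt("rwrscreen_format_error", "unknown label class: %s", bad[1])
  label_set(tab$id[tab$class == "effective"],
            tab$id[tab$class == "ineffective"],
            tab$id[tab$class == "aging_gene"])
}

#' Write a drug label table
#' @param labels a [label_set()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  tab <- data.frame(
    id = c(labels$effective_drugs, labels$ineffective_drugs,
           labels$aging_genes),
    class = c(rep("effective", length(labels$effective_drugs)),
              rep("ineffective", length(labels$ineffective_drugs)),
              rep("aging_gene", length(labels$aging_genes))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a bipartite network
#'
#' Writes `<prefix>.tsv` (columns `drug`, `protein`, `weight`, full float
#' precision) plus a `<prefix>.json` sidecar recording node order, so
#' [read_network()] round-trips exactly.
#'
#' @param net a `bipartite_network`.
#' @param prefix output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_network <- function(net, prefix) {
  m <- length(net$drug_ids)
  idx <- Matrix::which(net$A != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] <= m & idx[, 2] > m, , drop = FALSE]
  edges <- data.frame(drug = net$drug_ids[idx[, 1]],
                      protein = net$protein_ids[idx[, 2] - m],
                      weight = sprintf("%.17g", net$A[idx]))
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  write.table(edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(drug_ids = net$drug_ids,
                            protein_ids = net$protein_ids),
                       json, pretty = TRUE)
  invisible(c(tsv, json))
}

#' Load a serialized bipartite network
#' @param prefix path prefix used by [write_network()].
#' @return The `bipartite_network`.
#' @export
read_network <- function(prefix) {
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  if (!file.exists(tsv) || !file.exists(json))
    stop_fmt("rwrscreen_io_error", "network files not found at prefix %s",
             prefix)
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  edges <- read.delim(tsv, colClasses = c("character", "character",
                                          "numeric"))
  drug_ids <- as.character(side$drug_ids)
  protein_ids <- as.character(side$protein_ids)
  m <- length(drug_ids); n <- length(protein_ids)
  i <- match(edges$drug, drug_ids)
  j <- m + match(edges$protein, protein_ids)
  if (anyNA(i) || anyNA(j))
    stop_fmt("rwrscreen_format_error",
             "edge references a node missing from the sidecar")
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(edges$weight, 2), dims = c(m + n, m + n),
                            dimnames = rep(list(c(drug_ids, protein_ids)), 2))
  new_bipartite_network(drug_ids, protein_ids, A)
}

#' Read a chemical attribute matrix
#'
#' CSV whose first column is the drug id and remaining columns are numeric
#' attributes (descriptors and/or fingerprint bits).
#'
#' @param path CSV path.
#' @return Numeric matrix with drug ids as rownames.
#' @export
read_attributes <- function(path) {
  if (!file.exists(path))
    stop_fmt("rwrscreen_io_error", "attribute file not found: %s", path)
  tab <- read.csv(path, check.names = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop_fmt("rwrscreen_format_error", "non-numeric attribute column")
  rownames(mat) <- ids
  mat
}

#' Write a chemical attribute matrix
#' @param mat numeric matrix with drug id rownames.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_attributes <- function(mat, path) {
  df <- data.frame(drug_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square similarity matrix as CSV
#' @param sim a `similarity_matrix`.
#' @param path output CSV path (header row and first column are drug ids).
#' @return Invisibly, `path`.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(drug_id = sim$ids, sim$S, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square similarity matrix CSV
#' @param path CSV written by [write_similarity()].
#' @param kind provenance tag to attach (default `"integrated"`).
#' @return A `similarity_matrix`.
#' @export
read_similarity <- function(path, kind = "integrated") {
  mat <- read_attributes(path)
  new_similarity_matrix(rownames(mat), mat, kind)
}
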