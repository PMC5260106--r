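#' Column dialect for interaction tables
#'
#' Describes how columns of a chemical-protein interaction TSV map onto the
#' five evidence channels, and the scale scores are printed on.  The default
#' matches the STITCH `protein_chemical.links.detailed` layout, whose integer
#' scores run 0-1000; internally all scores live in \[0, 1\].
#'
#' @param drug,protein column names holding the drug and protein identifiers.
#' @param experimental,database,textmining,predicted,combined column names of
#'   the per-channel confidence scores and the integrated score.
#' @param scale divisor applied to raw scores (1000 for STITCH dumps, 1 for
#'   tables already on the unit interval).
#' @return A named list of class `interaction_dialect`.
#' @export
interaction_dialect <- function(drug = "chemical", protein = "protein",
                                experimental = "experimental",
                                database = "database",
                                textmining = "textmining",
                                predicted = "prediction",
                                combined = "combined_score",
                                scale = 1000) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(list(drug = drug, protein = protein,
                 experimental = experimental, database = database,
                 textmining = textmining, predicted = predicted,
                 combined = combined, scale = scale),
            class = "interaction_dialect")
}

channel_names <- c("experimental", "database", "textmining",
                   "predicted", "combined")

# Collapse duplicate (drug, protein) rows to the per-channel maximum,
# preserving first-appearance order of pairs.  Conservative and idempotent.
collapse_duplicates <- function(records) {
  key <- paste(records$drug_id, records$protein_id, sep = "\r")
  if (!anyDuplicated(key)) return(records)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  idx <- match(key, key[first])
  for (ch in channel_names) {
    out[[ch]] <- as.numeric(tapply(records[[ch]], idx, max)[as.character(seq_len(nrow(out)))])
  }
  rownames(out) <- NULL
  out
}

#' Read a drug-protein interaction table
#'
#' Reads a TSV of weighted drug-protein interactions, rescales the per-channel
#' confidence scores to \[0, 1\] according to the dialect, and collapses
#' duplicate (drug, protein) rows to the per-channel maximum.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect an [interaction_dialect()].
#' @return A data frame with columns `drug_id`, `protein_id`, `experimental`,
#'   `database`, `textmining`, `predicted`, `combined`, one row per retained
#'   (drug, protein) pair.
#' @export
read_interactions <- function(path, dialect = interaction_dialect()) {
  if (!file.exists(path))
    stop_fmt("rwrscreen_io_error", "interaction file not found: %s", path)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  needed <- unlist(dialect[c("drug", "protein", channel_names)])
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop_fmt("rwrscreen_format_error",
             "missing required column(s): %s", paste(missing, collapse = ", "))
  n <- nrow(raw)
  rec <- data.frame(drug_id = raw[[dialect$drug]],
                    protein_id = raw[[dialect$protein]],
                    stringsAsFactors = FALSE)
  if (n > 0 && (any(!nzchar(rec$drug_id)) || any(!nzchar(rec$protein_id))))
    stop_fmt("rwrscreen_format_error", "empty drug or protein identifier")
  for (ch in channel_names) {
    v <- suppressWarnings(as.numeric(raw[[dialect[[ch]]]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop_fmt("rwrscreen_format_error",
               "unparseable %s score at line %d", ch, bad[1] + 1L)
    v <- v / dialect$scale
    if (n > 0 && (min(v) < 0 || max(v) > 1))
      stop_fmt("rwrscreen_format_error",
               "%s score outside [0,1] after rescaling by %g",
               ch, dialect$scale)
    rec[[ch]] <- v
  }
  collapse_duplicates(rec)
}

#' Keep interactions with experimental or curated-database evidence
#'
#' Retains exactly the records whose experimental or database channel score is
#' strictly above `threshold` (default 0, i.e. any such evidence at all);
#' text mining or computational prediction alone is not sufficient.
#'
#' @param records interaction data frame as from [read_interactions()].
#' @param threshold minimum (exclusive) evidence score; default 0.
#' @return The filtered data frame, input order preserved.
#' @export
filter_high_confidence <- function(records, threshold = 0) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  keep <- records$experimental > threshold | records$database > threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map interaction proteins through an ortholog table
#'
#' Replaces each record's protein by its orthologs in the target organism,
#' keeping only ortholog pairs supported by at least `min_methods` orthology
#' prediction methods.  A protein with several qualifying orthologs expands
#' into several records (scores copied); a protein with none drops out.
#' Duplicates created by many-to-one mapping are max-collapsed per channel.
#'
#' @param records interaction data frame.
#' @param orthologs data frame with columns `source_protein`,
#'   `target_protein`, `n_methods`.
#' @param min_methods minimum number of supporting methods (default 2).
#' @return The remapped interaction data frame.
#' @export
map_orthologs <- function(records, orthologs, min_methods = 2L) {
  stopifnot(is_count(min_methods), min_methods >= 1)
  stopifnot(all(c("source_protein", "target_protein", "n_methods") %in%
                  names(orthologs)))
  ok <- orthologs[orthologs$n_methods >= min_methods, , drop = FALSE]
  if (nrow(records) == 0L || nrow(ok) == 0L)
    return(records[0, , drop = FALSE])
  hits <- merge(cbind(records, .row = seq_len(nrow(records))),
                ok[c("source_protein", "target_protein")],
                by.x = "protein_id", by.y = "source_protein")
  if (nrow(hits) == 0L) return(records[0, , drop = FALSE])
  hits <- hits[order(hits$.row, hits$target_protein), , drop = FALSE]
  out <- data.frame(drug_id = hits$drug_id, protein_id = hits$target_protein,
                    stringsAsFactors = FALSE)
  for (ch in channel_names) out[[ch]] <- hits[[ch]]
  collapse_duplicates(out)
}

#' Build the weighted drug-protein bipartite network
#'
#' Assembles a symmetric nonnegative affinity matrix A over drugs and
#' proteins from an interaction table.  If whitelists are given, a record is
#' kept when its drug *or* its protein is whitelisted; node order is
#' first-appearance order with all drugs before all proteins.
#'
#' @param records interaction data frame (already filtered/mapped).
#' @param drug_whitelist,protein_whitelist optional character vectors of
#'   identifiers; `NULL` means no restriction on that side.
#' @param weight_channel which score weights the edges: `"combined"`
#'   (default), `"experimental"` or `"database"`.
#' @return A `bipartite_network`: list with `drug_ids`, `protein_ids`, and
#'   the sparse symmetric affinity matrix `A` (drugs first).
#' @export
build_network <- function(records, drug_whitelist = NULL,
                          protein_whitelist = NULL,
                          weight_channel = c("combined", "experimental",
                                             "database")) {
  weight_channel <- match.arg(weight_channel)
  if (!is.null(drug_whitelist) || !is.null(protein_whitelist)) {
    keep <- records$drug_id %in% (drug_whitelist %||% character(0)) |
      records$protein_id %in% (protein_whitelist %||% character(0))
    records <- records[keep, , drop = FALSE]
  }
  records <- records[records[[weight_channel]] > 0, , drop = FALSE]
  if (nrow(records) == 0L)
    stop_fmt("rwrscreen_build_error",
             "no interactions survive selection; cannot build network")
  records <- collapse_duplicates(records)
  drug_ids <- unique(records$drug_id)
  protein_ids <- unique(records$protein_id)
  m <- length(drug_ids); n <- length(protein_ids)
  i <- match(records$drug_id, drug_ids)
  j <- m + match(records$protein_id, protein_ids)
  w <- records[[weight_channel]]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(m + n, m + n),
                            dimnames = rep(list(c(drug_ids, protein_ids)), 2))
  new_bipartite_network(drug_ids, protein_ids, A)
}

new_bipartite_network <- function(drug_ids, protein_ids, A) {
  structure(list(drug_ids = drug_ids, protein_ids = protein_ids,
                 A = methods::as(A, "CsparseMatrix")),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d drugs, %d proteins, %d edges\n",
              length(x$drug_ids), length(x$protein_ids),
              Matrix::nnzero(x$A) / 2))
  invisible(x)
}

#' Number of nodes in a bipartite network
#' @param net a `bipartite_network`.
#' @return Integer node count (drugs + proteins).
#' @export
n_nodes <- function(net) length(net$drug_ids) + length(net$protein_ids)

node_ids <- function(net) c(net$drug_ids, net$protein_ids)

# Validate the structural invariants of a bipartite network; used by tests
# and by the synthetic generator.
#' Check bipartite-network invariants
#'
#' Asserts symmetry, nonnegativity and bipartiteness (no drug-drug or
#' protein-protein edge) of the affinity matrix.
#'
#' @param net a `bipartite_network`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_network <- function(net) {
  A <- net$A
  m <- length(net$drug_ids)
  if (!isTRUE(all.equal(max(abs(A - Matrix::t(A))), 0)))
    stop_fmt("rwrscreen_validation_error", "affinity matrix not symmetric")
  if (any(A@x < 0))
    stop_fmt("rwrscreen_validation_error", "negative edge weight")
  idx <- Matrix::which(A != 0, arr.ind = TRUE)
  same_side <- (idx[, 1] <= m) == (idx[, 2] <= m)
  if (any(same_side))
    stop_fmt("rwrscreen_validation_error",
             "edge within one side of the bipartition")
  invisible(TRUE)
}

#' Keep the largest connected component
#'
#' Drops small disconnected subnetworks, returning the subnetwork induced by
#' the single largest connected component.  Ties are broken in favour of the
#' component containing the smallest node index.  Afterwards every node has
#' degree > 0.
#'
#' @param net a `bipartite_network`.
#' @return The pruned `bipartite_network` (relative node order preserved).
#' @export
prune_components <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$A, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    first_node <- vapply(best, function(cid) min(which(comp$membership == cid)),
                         integer(1))
    best <- best[which.min(first_node)]
  }
  keep <- which(comp$membership == best)
  m <- length(net$drug_ids)
  new_bipartite_network(net$drug_ids[keep[keep <= m]],
                        net$protein_ids[keep[keep > m] - m],
                        net$A[keep, keep, drop = FALSE])
}

#' Row-stochastic transition matrix of the walk
#'
#' Computes T = D^-1 A where D is the diagonal degree matrix,
#' D(i,i) = sum_j A(i,j).  Every row of T sums to 1; all entries are
#' nonnegative.  A column-stochastic variant T = A D^-1 is available for
#' users expecting per-column probability conservation.
#'
#' @param net a `bipartite_network` with every node of positive degree
#'   (guaranteed after [prune_components()]).
#' @param normalization `"row"` (default) or `"column"`.
#' @return A `transition_matrix`: list with sparse matrix `T`, the node
#'   registries, and the normalization used.
#' @export
transition_matrix <- function(net, normalization = c("row", "column")) {
  normalization <- match.arg(normalization)
  deg <- Matrix::rowSums(net$A)
  if (any(deg == 0)) {
    bad <- node_ids(net)[which(deg == 0)[1]]
    stop_fmt("rwrscreen_validation_error",
             "node '%s' has zero degree; prune the network first", bad)
  }
  Dinv <- Matrix::Diagonal(x = 1 / deg)
  T <- if (normalization == "row") Dinv %*% net$A else net$A %*% Dinv
  dimnames(T) <- dimnames(net$A)
  structure(list(T = methods::as(T, "CsparseMatrix"),
                 drug_ids = net$drug_ids, protein_ids = net$protein_ids,
                 normalization = normalization),
            class = "transition_matrix")
}
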