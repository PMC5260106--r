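#' Seed label sets for the two walks
#'
#' Bundles the identifiers of known effective drugs, known ineffective drugs
#' and (optionally) phenotype-associated proteins.  Proteins coding for
#' aging-related genes join the *effective* walk's seed set; the ineffective
#' walk is seeded by ineffective drugs only.
#'
#' @param effective_drugs,ineffective_drugs character vectors of drug ids.
#' @param aging_genes optional character vector of protein ids.
#' @return A `label_set`.
#' @export
label_set <- function(effective_drugs, ineffective_drugs,
                      aging_genes = character(0)) {
  effective_drugs <- unique(as.character(effective_drugs))
  ineffective_drugs <- unique(as.character(ineffective_drugs))
  aging_genes <- unique(as.character(aging_genes))
  if (length(intersect(effective_drugs, ineffective_drugs)))
    stop_fmt("rwrscreen_validation_error",
             "a drug cannot be both effective and ineffective")
  if (length(effective_drugs) + length(aging_genes) == 0L)
    stop_fmt("rwrscreen_validation_error", "effective seed set is empty")
  if (length(ineffective_drugs) == 0L)
    stop_fmt("rwrscreen_validation_error", "ineffective seed set is empty")
  structure(list(effective_drugs = effective_drugs,
                 ineffective_drugs = ineffective_drugs,
                 aging_genes = aging_genes),
            class = "label_set")
}

#' Build the two-column label matrix
#'
#' Column 1 marks ineffective seed drugs, column 2 marks effective seed drugs
#' together with any aging-gene proteins.  Each column is then normalized to
#' a probability distribution, giving the walks' restart distributions.
#'
#' @param net a `bipartite_network`.
#' @param labels a [label_set()]; every id must be a node of `net`.
#' @return A `label_matrix`: list with indicator matrix `L` and
#'   column-normalized `L_norm`, rows in network node order.
#' @export
build_label_matrix <- function(net, labels) {
  ids <- node_ids(net)
  seeds <- c(labels$effective_drugs, labels$ineffective_drugs,
             labels$aging_genes)
  absent <- setdiff(seeds, ids)
  if (length(absent))
    stop_fmt("rwrscreen_validation_error",
             "seed id(s) not in network: %s",
             paste(utils::head(absent, 5), collapse = ", "))
  if (length(setdiff(labels$aging_genes, net$protein_ids)))
    stop_fmt("rwrscreen_validation_error",
             "aging-gene seed is not a protein node")
  L <- matrix(0, nrow = length(ids), ncol = 2,
              dimnames = list(ids, c("ineffective", "effective")))
  L[labels$ineffective_drugs, 1] <- 1
  L[c(labels$effective_drugs, labels$aging_genes), 2] <- 1
  cs <- colSums(L)
  if (any(cs == 0))
    stop_fmt("rwrscreen_validation_error",
             "label column '%s' has no seeds; normalization undefined",
             colnames(L)[cs == 0][1])
  structure(list(L = L, L_norm = sweep(L, 2, cs, "/")),
            class = "label_matrix")
}

#' Run the two restarting random walks
#'
#' Iterates P(t+1) = (1 - alpha) T P(t) + alpha L' from P(0) = L' until the
#' L1 change between successive iterates falls below `epsilon`.  The two
#' columns of the stationary matrix P* are the arrival probabilities of the
#' walks restarted at the ineffective and effective seed distributions.
#'
#' @param tm a [transition_matrix()].
#' @param lm a [build_label_matrix()] result on the same network.
#' @param alpha restart probability in (0, 1]; unstated in the underlying
#'   method, default 0.5 (see the methods vignette).
#' @param epsilon convergence tolerance on the summed L1 change (default 1e-9).
#' @param max_iter iteration cap; exceeding it is an error, never silent.
#' @param pseudocount passed to [f_ratio()] for the stored odds vector.
#' @return A `propagation_result`: list with `P_star`, `f_ratio`,
#'   `iterations`, `residual` and the parameters used.
#' @export
propagate <- function(tm, lm, alpha = 0.5, epsilon = 1e-9,
                      max_iter = 10000L, pseudocount = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is_count(max_iter), max_iter >= 1)
  Lp <- lm$L_norm
  if (nrow(Lp) != nrow(tm$T))
    stop_fmt("rwrscreen_validation_error",
             "label matrix and transition matrix sizes differ")
  P <- Lp
  TT <- tm$T
  for (it in seq_len(max_iter)) {
    P_new <- as.matrix((1 - alpha) * (TT %*% P)) + alpha * Lp
    residual <- sum(abs(P_new - P))
    P <- P_new
    if (residual < epsilon) {
      dimnames(P) <- dimnames(Lp)
      return(structure(list(P_star = P,
                            f_ratio = f_ratio_from(P, pseudocount),
                            iterations = it, residual = residual,
                            alpha = alpha, epsilon = epsilon),
                       class = "propagation_result"))
    }
  }
  stop_fmt("rwrscreen_convergence_error",
           "no convergence after %d iterations (last L1 residual %.3e)",
           max_iter, residual)
}

#' Closed-form stationary solution (dense oracle)
#'
#' Solves the fixed point of the restart iteration directly:
#' P* = alpha (I - (1 - alpha) T)^-1 L'.  Intended as an exact oracle for
#' small networks; guarded to at most 2000 nodes.
#'
#' @inheritParams propagate
#' @return The dense stationary matrix P* (|V| x 2).
#' @export
solve_stationary_direct <- function(tm, lm, alpha = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  nv <- nrow(tm$T)
  if (nv > 2000)
    stop_fmt("rwrscreen_validation_error",
             "direct solve guarded to 2000 nodes (got %d)", nv)
  M <- diag(nv) - (1 - alpha) * as.matrix(tm$T)
  P <- alpha * solve(M, lm$L_norm)
  dimnames(P) <- dimnames(lm$L_norm)
  P
}

f_ratio_from <- function(P, pseudocount = 0) {
  if (pseudocount < 0)
    stop_fmt("rwrscreen_validation_error", "pseudocount must be >= 0")
  f <- (P[, 2] + pseudocount) / (P[, 1] + pseudocount)
  f[is.nan(f)] <- 0  # 0/0 policy; x/0 stays +Inf
  f
}

#' F-ratio odds score
#'
#' F(i) = P*(i, effective) / P*(i, ineffective), optionally smoothed by a
#' pseudocount added to both probabilities.  With pseudocount 0 the division
#' policy is: 0/0 -> 0 and x/0 -> +Inf for x > 0.
#'
#' @param result a `propagation_result` (or a bare P* matrix).
#' @param pseudocount nonnegative smoothing constant (default 0).
#' @return Named numeric vector of odds, one per node.
#' @export
f_ratio <- function(result, pseudocount = 0) {
  P <- if (inherits(result, "propagation_result")) result$P_star else result
  f_ratio_from(P, pseudocount)
}

#' Threshold classification of F-ratios
#'
#' A node is called effective iff its F-ratio strictly exceeds `theta`.
#'
#' @param f named F-ratio vector.
#' @param theta positive decision threshold.
#' @return Named character vector, `"effective"` or `"ineffective"`.
#' @export
classify_effective <- function(f, theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
  setNames(ifelse(f > theta, "effective", "ineffective"), names(f))
}

#' Rank nodes by F-ratio
#'
#' Descending F-ratio; ties broken lexicographically by node id so the
#' ranking is deterministic across runs and platforms.
#'
#' @param f named F-ratio vector.
#' @return Data frame with columns `node_id`, `f_ratio`, `rank`.
#' @export
rank_nodes <- function(f) {
  ord <- order(-f, names(f))
  data.frame(node_id = names(f)[ord], f_ratio = unname(f[ord]),
             rank = seq_along(f), stringsAsFactors = FALSE)
}
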