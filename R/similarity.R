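#' Drop attributes constant across all drugs
#'
#' Removes every attribute column whose value is identical for all drugs in
#' the collection; such columns carry no information for cosine similarity.
#'
#' @param profiles numeric matrix, rows = drugs (rownames are drug ids),
#'   columns = chemical attributes (descriptors and/or fingerprint bits).
#' @return The matrix with constant columns removed.
#' @export
remove_constant_attributes <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  constant <- apply(profiles, 2, function(col) all(col == col[1]))
  if (all(constant))
    stop_fmt("rwrscreen_validation_error",
             "all attributes are constant; no informative features remain")
  profiles[, !constant, drop = FALSE]
}

new_similarity_matrix <- function(ids, S, kind) {
  dimnames(S) <- list(ids, ids)
  structure(list(ids = ids, S = S, kind = kind),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d drugs\n", x$kind, length(x$ids)))
  invisible(x)
}

#' Chemical similarity: cosine of attribute vectors
#'
#' S(i,j) = sum_k c_ik c_jk / (||c_i|| ||c_j||).  Raw descriptors can be
#' negative, so chemical cosine lives in \[-1, 1\]; it is floored at 0 only
#' when fed to [integrate_similarities()] or [to_distance()].  A drug with an
#' all-zero attribute vector has undefined cosine; its similarities are set
#' to 0 with a warning.
#'
#' @param profiles numeric matrix, rows = drugs with rownames.
#' @return A `similarity_matrix` of kind `"chemical"`.
#' @export
cosine_similarity <- function(profiles) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  nrm <- sqrt(rowSums(profiles^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sprintf("zero-norm attribute vector for: %s; similarities set to 0",
                    paste(rownames(profiles)[zero], collapse = ", ")))
    nrm[zero] <- 1
  }
  S <- tcrossprod(profiles / nrm)
  S[zero, ] <- 0
  S[, zero] <- 0
  diag(S)[!zero] <- 1
  new_similarity_matrix(rownames(profiles), S, "chemical")
}

#' Target-sharing similarity: Jaccard over target sets
#'
#' S(i,j) = |t_i intersect t_j| / |t_i union t_j| over the binary
#' target-protein vectors of two drugs; a pair of drugs that both target
#' nothing gets similarity 0.
#'
#' @param profiles binary matrix, rows = drugs with rownames, columns =
#'   proteins; entries must be 0/1.
#' @return A `similarity_matrix` of kind `"target"`.
#' @export
target_jaccard <- function(profiles) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  if (!all(profiles %in% c(0, 1)))
    stop_fmt("rwrscreen_validation_error",
             "target profiles must be binary 0/1")
  inter <- tcrossprod(profiles)
  sz <- rowSums(profiles)
  uni <- outer(sz, sz, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  diag(S)[sz > 0] <- 1
  new_similarity_matrix(rownames(profiles), S, "target")
}

#' Integrate similarity measures by noisy-OR
#'
#' S(i,j) = 1 - prod_n (1 - S_n(i,j)): the combined similarity is dominated
#' by the strongest evidence channel and never below any single one.
#' Components are clipped to \[0, 1\] first (negative chemical cosines are
#' floored at 0).
#'
#' @param matrices list of `similarity_matrix` objects over the same drugs
#'   in the same order.
#' @return A `similarity_matrix` of kind `"integrated"`.
#' @export
integrate_similarities <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  ids <- matrices[[1]]$ids
  for (m in matrices) {
    if (!inherits(m, "similarity_matrix") || !identical(m$ids, ids))
      stop_fmt("rwrscreen_validation_error",
               "similarity matrices must share the same drug ordering")
  }
  comp <- lapply(matrices, function(m) pmin(pmax(m$S, 0), 1))
  S <- 1 - Reduce(`*`, lapply(comp, function(x) 1 - x))
  new_similarity_matrix(ids, S, "integrated")
}

#' Similarity to distance
#'
#' D = 1 - S elementwise, with a zero diagonal; used by the k-nearest
#' neighbour baseline.  Entries must already lie in \[0, 1\] (clip chemical
#' cosine via [integrate_similarities()] or `pmax(S, 0)` first).
#'
#' @param sim a `similarity_matrix` (or bare matrix) with entries in \[0, 1\].
#' @return A symmetric distance matrix with zero diagonal.
#' @export
to_distance <- function(sim) {
  S <- if (inherits(sim, "similarity_matrix")) sim$S else sim
  if (min(S) < 0 || max(S) > 1)
    stop_fmt("rwrscreen_validation_error",
             "similarity entries outside [0,1]; clip before converting")
  D <- 1 - S
  diag(D) <- 0
  D
}
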