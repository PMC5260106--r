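#' Specification of a synthetic screening world
#'
#' Parameters of the planted-module generator.  Proteins are split into
#' modules assigned alternately to the effective and the ineffective side;
#' drugs of a class attach to proteins of their side with probability
#' `p_within` and to the other side with `p_between`, so effective drugs
#' share target neighbourhoods — the structural premise that makes label
#' propagation work.  Edge confidences are uniform in `weight_range`
#' (default 0.15-1, mirroring interaction databases that drop scores below
#' their low-confidence cutoff).
#'
#' @param n_effective_drugs,n_ineffective_drugs seed drugs per class
#'   (defaults 20 and 200: positives are rare in real screens).
#' @param n_candidate_drugs unlabeled drugs, split evenly between
#'   effective-like and ineffective-like ground truth (default 100).
#' @param n_proteins protein count (default 500).
#' @param n_modules number of protein modules (default 2).
#' @param p_within,p_between attachment probabilities; `p_within > p_between`
#'   is required for planted structure (defaults 0.1 and 0.01).
#' @param weight_range length-2 numeric in (0, 1\].
#' @param attr_dim total chemical attributes: half continuous descriptors,
#'   half fingerprint bits (default 100).
#' @param class_shift separation between the class mean attribute vectors in
#'   noise-sd units (default 2: separable but overlapping).
#' @param noise_sd descriptor noise standard deviation (default 1).
#' @param seed integer seed; every draw flows through it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_effective_drugs = 20L, n_ineffective_drugs = 200L,
                           n_candidate_drugs = 100L, n_proteins = 500L,
                           n_modules = 2L, p_within = 0.1, p_between = 0.01,
                           weight_range = c(0.15, 1), attr_dim = 100L,
                           class_shift = 2, noise_sd = 1, seed = 0L) {
  spec <- list(n_effective_drugs = n_effective_drugs,
               n_ineffective_drugs = n_ineffective_drugs,
               n_candidate_drugs = n_candidate_drugs,
               n_proteins = n_proteins, n_modules = n_modules,
               p_within = p_within, p_between = p_between,
               weight_range = as.numeric(weight_range), attr_dim = attr_dim,
               class_shift = class_shift, noise_sd = noise_sd,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(is_count(n_effective_drugs), n_effective_drugs >= 1,
              is_count(n_ineffective_drugs), n_ineffective_drugs >= 1,
              is_count(n_candidate_drugs), n_candidate_drugs >= 0,
              is_count(n_proteins), n_proteins >= 2,
              is_count(n_modules), n_modules >= 1,
              p_within > p_between, p_within <= 1, p_between >= 0,
              length(weight_range) == 2, weight_range[1] <= weight_range[2],
              weight_range[1] > 0, weight_range[2] <= 1,
              is_count(attr_dim), attr_dim >= 2,
              class_shift >= 0, noise_sd > 0)
  })
  structure(spec, class = "synthetic_spec")
}

synthetic_drug_classes <- function(spec) {
  nc_eff <- spec$n_candidate_drugs %/% 2
  nc_ineff <- spec$n_candidate_drugs - nc_eff
  list(seeds = c(setNames(rep("effective", spec$n_effective_drugs),
                          sprintf("E%03d", seq_len(spec$n_effective_drugs))),
                 setNames(rep("ineffective", spec$n_ineffective_drugs),
                          sprintf("I%03d", seq_len(spec$n_ineffective_drugs)))),
       candidates = c(setNames(rep("effective", nc_eff),
                               sprintf("CE%03d", seq_len(nc_eff))),
                      setNames(rep("ineffective", nc_ineff),
                               sprintf("CI%03d", seq_len(nc_ineff)))))
}

#' Generate a planted-module bipartite network with labels
#'
#' Draws edges per the spec, builds and prunes the network to its largest
#' connected component, and returns the surviving seed labels and the hidden
#' ground truth of the surviving candidates.  Deterministic given the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `network` (`bipartite_network`), `labels`
#'   ([label_set()] of surviving seeds) and `truth` (named character vector:
#'   surviving candidate id -> planted class).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cls <- synthetic_drug_classes(spec)
  drug_class <- c(cls$seeds, cls$candidates)
  protein_ids <- sprintf("P%04d", seq_len(spec$n_proteins))
  protein_side <- c("effective", "ineffective")[
    (seq_len(spec$n_proteins) - 1L) %% spec$n_modules %% 2L + 1L]
  records <- local_seed(spec$seed, {
    m <- length(drug_class); n <- spec$n_proteins
    pmat <- matrix(spec$p_between, m, n)
    pmat[outer(drug_class, protein_side, "==")] <- spec$p_within
    hit <- which(matrix(runif(m * n), m, n) < pmat, arr.ind = TRUE)
    w <- runif(nrow(hit), spec$weight_range[1], spec$weight_range[2])
    data.frame(drug_id = names(drug_class)[hit[, 1]],
               protein_id = protein_ids[hit[, 2]],
               experimental = w, database = 0, textmining = 0, predicted = 0,
               combined = w, stringsAsFactors = FALSE)
  })
  if (nrow(records) == 0L)
    stop_fmt("rwrscreen_build_error",
             "no edges drawn; increase p_within or network size")
  net <- prune_components(build_network(records, weight_channel = "combined"))
  eff <- intersect(names(cls$seeds)[cls$seeds == "effective"], net$drug_ids)
  ineff <- intersect(names(cls$seeds)[cls$seeds == "ineffective"],
                     net$drug_ids)
  if (length(eff) == 0L || length(ineff) == 0L)
    stop_fmt("rwrscreen_build_error",
             "a seed class vanished after pruning; increase p_within")
  truth <- cls$candidates[intersect(names(cls$candidates), net$drug_ids)]
  list(network = net, labels = label_set(eff, ineff), truth = truth)
}

#' Generate chemical and target profiles with planted class structure
#'
#' Continuous descriptors follow a symmetric location model: the effective
#' class mean sits at +class_shift/2 and the ineffective at -class_shift/2
#' per dimension (shared `noise_sd`), so the class means differ by
#' `class_shift`.  Fingerprint bits are Bernoulli with logit +/-
#' class_shift/2 around even odds.  `class_shift = 0` gives no structure.
#' Target profiles are read directly off the generated network.
#'
#' @param classes named character vector drug id -> class
#'   (`"effective"`/`"ineffective"`), e.g. `c(labels-as-vector, truth)`.
#' @param spec a [synthetic_spec()].
#' @param network optional `bipartite_network` from [generate_network()];
#'   when given, binary target profiles for these drugs are extracted.
#' @return List with `chemical` (drugs x attr_dim numeric matrix) and
#'   `target` (drugs x proteins binary matrix, or `NULL`).
#' @export
generate_profiles <- function(classes, spec, network = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), !is.null(names(classes)))
  n <- length(classes)
  d_desc <- ceiling(spec$attr_dim / 2)
  d_fp <- spec$attr_dim - d_desc
  sgn <- ifelse(classes == "effective", 0.5, -0.5)
  chem <- local_seed(spec$seed + 1L, {
    desc <- matrix(rnorm(n * d_desc, sd = spec$noise_sd), n, d_desc) +
      sgn * spec$class_shift
    fp <- if (d_fp > 0)
      matrix(rbinom(n * d_fp, 1L, plogis(rep(sgn * spec$class_shift, d_fp))),
             n, d_fp)
    else matrix(0, n, 0)
    cbind(desc, fp)
  })
  dimnames(chem) <- list(names(classes),
                         c(sprintf("desc%03d", seq_len(d_desc)),
                           sprintf("fp%03d", seq_len(d_fp))))
  target <- NULL
  if (!is.null(network)) {
    present <- intersect(names(classes), network$drug_ids)
    m <- length(network$drug_ids)
    target <- as.matrix(network$A[match(present, network$drug_ids),
                                  m + seq_along(network$protein_ids),
                                  drop = FALSE] != 0) * 1
    dimnames(target) <- list(present, network$protein_ids)
  }
  list(chemical = chem, target = target)
}
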