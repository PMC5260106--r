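# Fixture builders shared across test files.  Everything is built in code;
# no binary data.

# Interaction data frame from a compact edge description.
make_records <- function(drug, protein, experimental = 0, database = 0,
                         textmining = 0, predicted = 0, combined = NULL) {
  n <- length(drug)
  rec <- data.frame(drug_id = drug, protein_id = protein,
                    experimental = rep_len(experimental, n),
                    database = rep_len(database, n),
                    textmining = rep_len(textmining, n),
                    predicted = rep_len(predicted, n),
                    stringsAsFactors = FALSE)
  rec$combined <- if (is.null(combined))
    pmax(rec$experimental, rec$database, rec$textmining, rec$predicted)
  else rep_len(combined, n)
  rec
}

# Bipartite network straight from an edge list (already "high confidence").
make_network <- function(drug, protein, weight = 1) {
  build_network(make_records(drug, protein, experimental = rep_len(weight,
                                                                   length(drug))),
                weight_channel = "combined")
}

# Hand-rolled label matrix for testing propagate() without label_set's
# drug/protein bookkeeping (both walks are independent columns).
make_label_matrix <- function(net, ineffective, effective) {
  ids <- c(net$drug_ids, net$protein_ids)
  L <- matrix(0, length(ids), 2, dimnames = list(ids, c("ineffective",
                                                        "effective")))
  L[ineffective, 1] <- 1
  L[effective, 2] <- 1
  structure(list(L = L, L_norm = sweep(L, 2, colSums(L), "/")),
            class = "label_matrix")
}

# Mirrored two-module fixture: the map sigma (e<->i, ce<->ci, pe<->pi,
# c0 fixed) is a network automorphism exchanging the two seed sets.
mirror_fixture <- function() {
  net <- make_network(
    drug = c("e", "ce", "c0", "c0", "ci", "i"),
    protein = c("pe", "pe", "pe", "pi", "pi", "pi"))
  sigma <- c(e = "i", i = "e", ce = "ci", ci = "ce", pe = "pi", pi = "pe",
             c0 = "c0")
  list(net = net, sigma = sigma,
       labels = label_set("e", "i"))
}

# Small random synthetic world (|V| <= ~60) for oracle comparisons.
small_spec <- function(seed) {
  synthetic_spec(n_effective_drugs = 3, n_ineffective_drugs = 6,
                 n_candidate_drugs = 6, n_proteins = 40, p_within = 0.35,
                 p_between = 0.05, seed = seed)
}

run_propagation <- function(world, alpha = 0.5, ...) {
  tm <- transition_matrix(world$network)
  lm <- build_label_matrix(world$network, world$labels)
  list(tm = tm, lm = lm, res = propagate(tm, lm, alpha = alpha, ...))
}
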