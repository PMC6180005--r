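# Hand-built fixtures and independent oracles used across the suite.

# --- tiny OBO fixtures ------------------------------------------------------

# chain: A is_a P is_a R (root); nc(P) = nc(R) = 1
chain_obo <- c(
  "format-version: 1.2",
  "data-version: fixture/chain",
  "",
  "[Term]", "id: GO:0000003", "name: A", "namespace: biological_process",
  "is_a: GO:0000002 ! P",
  "",
  "[Term]", "id: GO:0000002", "name: P", "namespace: biological_process",
  "is_a: GO:0000001 ! R",
  "",
  "[Term]", "id: GO:0000001", "name: R", "namespace: biological_process"
)

# diamond with asymmetric children counts:
#   A is_a B, A is_a C, B is_a D, C is_a D, X is_a B
#   nc(B) = 2, nc(C) = 1, nc(D) = 2
diamond_obo <- c(
  "format-version: 1.2",
  "",
  "[Term]", "id: GO:0000010", "name: A", "namespace: biological_process",
  "is_a: GO:0000011", "is_a: GO:0000012",
  "",
  "[Term]", "id: GO:0000011", "name: B", "namespace: biological_process",
  "is_a: GO:0000013",
  "",
  "[Term]", "id: GO:0000012", "name: C", "namespace: biological_process",
  "is_a: GO:0000013",
  "",
  "[Term]", "id: GO:0000013", "name: D", "namespace: biological_process",
  "",
  "[Term]", "id: GO:0000014", "name: X", "namespace: biological_process",
  "is_a: GO:0000011"
)

# mixed relations, alt id, obsolete term, and a second namespace
mixed_obo <- c(
  "format-version: 1.2",
  "data-version: fixture/mixed",
  "",
  "[Term]", "id: GO:0000100", "name: bp root", "namespace: biological_process",
  "",
  "[Term]", "id: GO:0000101", "name: bp mid", "namespace: biological_process",
  "alt_id: GO:0000199",
  "is_a: GO:0000100",
  "",
  "[Term]", "id: GO:0000102", "name: bp leaf", "namespace: biological_process",
  "is_a: GO:0000101",
  "relationship: part_of GO:0000100",
  "",
  "[Term]", "id: GO:0000103", "name: bp reg", "namespace: biological_process",
  "relationship: positively_regulates GO:0000101",
  "is_a: GO:0000100",
  "",
  "[Term]", "id: GO:0000150", "name: mf root", "namespace: molecular_function",
  "",
  "[Term]", "id: GO:0000151", "name: mf leaf", "namespace: molecular_function",
  "is_a: GO:0000150",
  "",
  "[Term]", "id: GO:0000160", "name: gone", "namespace: biological_process",
  "is_obsolete: true"
)

# three-level tree for IC tests: root -> mid1, mid2; mid1 -> leaf1, leaf2
ic_obo <- c(
  "format-version: 1.2",
  "",
  "[Term]", "id: GO:0000200", "name: root", "namespace: biological_process",
  "",
  "[Term]", "id: GO:0000201", "name: mid1", "namespace: biological_process",
  "is_a: GO:0000200",
  "",
  "[Term]", "id: GO:0000202", "name: mid2", "namespace: biological_process",
  "is_a: GO:0000200",
  "",
  "[Term]", "id: GO:0000203", "name: leaf1", "namespace: biological_process",
  "is_a: GO:0000201",
  "",
  "[Term]", "id: GO:0000204", "name: leaf2", "namespace: biological_process",
  "is_a: GO:0000201"
)

# --- independent oracles ----------------------------------------------------

# S-values by exhaustive upward path enumeration: S(t) is the maximum over
# all descending paths t -> ... -> target of the product of edge weights.
# Completely independent of the dynamic program in ancestor_graph().
oracle_s_values <- function(ontology, target, config = gogo_config()) {
  nodes <- go_ancestors(ontology, target, config$relations, include_self = TRUE,
                        same_namespace = !config$cross_namespace)
  best <- stats::setNames(rep(0, length(nodes)), nodes)
  best[target] <- 1
  walk <- function(node, prod) {
    ps <- go_parents(ontology, node, config$relations)
    for (r in seq_len(nrow(ps))) {
      p <- ps$parent[r]
      if (!(p %in% nodes)) next
      w <- edge_weight(ontology, p, ps$relation[r], config)
      np <- prod * w
      if (np > best[[p]]) best[p] <<- np
      walk(p, np)
    }
  }
  walk(target, 1)
  best
}

oracle_term_similarity <- function(ontology, a, b, config = gogo_config()) {
  sa <- oracle_s_values(ontology, a, config)
  sb <- oracle_s_values(ontology, b, config)
  common <- intersect(names(sa), names(sb))
  if (length(common) == 0L) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# propagated corpus counts by brute-force descendant enumeration
oracle_propagated_counts <- function(ontology, raw_counts, relations = c("is_a", "part_of")) {
  vapply(ontology$terms$id, function(t) {
    below <- go_descendants(ontology, t, relations, include_self = TRUE)
    sum(raw_counts[intersect(names(raw_counts), below)])
  }, numeric(1))
}

# net similarity of an exemplar subset: preferences of the exemplars plus
# each remaining point's similarity to its best exemplar
ap_net_similarity <- function(S, pref, ex_idx) {
  n <- nrow(S)
  rest <- setdiff(seq_len(n), ex_idx)
  sum(rep(pref, length(ex_idx))) +
    sum(apply(S[rest, ex_idx, drop = FALSE], 1L, max))
}

# globally optimal exemplar subset by enumeration (tiny n only)
ap_oracle_best_net <- function(S, pref) {
  n <- nrow(S)
  best <- -Inf
  for (size in seq_len(n)) {
    for (ex in utils::combn(n, size, simplify = FALSE)) {
      v <- ap_net_similarity(S, pref, ex)
      if (v > best) best <- v
    }
  }
  best
}

# per-gene confusion counts by explicit double loop over ordered pairs
oracle_pair_counts <- function(ref, pred) {
  genes <- names(ref)
  out <- data.frame(gene = genes, tp = 0L, tn = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i == j) next
      sr <- ref[[i]] == ref[[j]]
      sp <- pred[[genes[i]]] == pred[[genes[j]]]
      if (sr && sp) out$tp[i] <- out$tp[i] + 1L
      else if (!sr && !sp) out$tn[i] <- out$tn[i] + 1L
      else if (!sr && sp) out$fp[i] <- out$fp[i] + 1L
      else out$fn[i] <- out$fn[i] + 1L
    }
  }
  out
}

# Block-structured similarity matrix with planted groups. A small
# deterministic symmetric perturbation keeps gene profiles distinct:
# exactly duplicated rows are a degenerate input for affinity propagation
# (message passing cannot pick an exemplar among identical points; the
# reference sklearn implementation fails on them the same way).
block_sim_matrix <- function(sizes, within = 0.9, between = 0.1, wobble = 0.01) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- matrix(between, n, n)
  m[outer(lab, lab, "==")] <- within
  pert <- outer(seq_len(n), seq_len(n), function(i, j) sin(7 * i + 13 * j))
  pert <- (pert + t(pert)) / 2
  m <- m + wobble * pert
  diag(m) <- 1
  ids <- sprintf("g%02d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  attr(m, "labels") <- stats::setNames(lab, ids)
  m
}
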