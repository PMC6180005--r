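# GOGO / Wang semantic similarity on the GO DAG.
#
# Both measures propagate an S-value from a target term up through its
# ancestor graph: S_A(A) = 1 and, for an ancestor t, the maximum over its
# children t' (within the ancestor graph) of w_e * S_A(t'). They differ
# only in the edge weight w_e. Wang uses a fixed constant per relation
# type; GOGO uses
#
#     w_e = 1 / (c + nc(t)) + d
#
# where nc(t) is the number of direct children of the PARENT term t in the
# full ontology, so that broad ancestors with many children pass on less
# semantic contribution — the same qualitative behaviour as information
# content, without needing an annotation corpus. With d capped at 0.4
# (is_a) and nc >= 1, keeping every weight in (0, 1] requires c >= 0.67.

#' Configuration for term-level semantic similarity
#'
#' @param method `"GOGO"` (children-count-aware edge weights, the default)
#'   or `"WANG"` (fixed per-relation weights).
#' @param c positive constant in the GOGO edge weight `1/(c + nc) + d`;
#'   must be at least 0.67 so that weights stay in (0, 1] (the default is
#'   this minimum, which is also where the measure correlates best with
#'   established methods).
#' @param d_weights named numeric: per-relation contribution constants,
#'   default `is_a` 0.4, `part_of` 0.3, `regulates` 0.2.
#' @param relations relation subset used for ancestor traversal and
#'   children counting. The plain measure uses `is_a` + `part_of`; the
#'   "regulates" variant adds the regulates relation.
#' @param wang_weights named numeric used when `method = "WANG"`; defaults
#'   to the conventional 0.8 (`is_a`) / 0.6 (`part_of`), with 0.7 for
#'   `regulates` when that relation is traversed.
#' @param cross_namespace allow ancestor traversal to cross namespace
#'   boundaries (off by default: similarity is computed per ontology).
#' @param unsafe_c skip the `c >= 0.67` validation (weights above 1 become
#'   possible; only for experimentation).
#' @return an object of class `semsim_config`.
#' @examples
#' cfg <- gogo_config()                    # GOGO over is_a + part_of
#' cfg_reg <- gogo_config(relations = c("is_a", "part_of", "regulates"))
#' wang <- gogo_config(method = "WANG")
#' @export
gogo_config <- function(method = c("GOGO", "WANG"),
                        c = 0.67,
                        d_weights = c(is_a = 0.4, part_of = 0.3, regulates = 0.2),
                        relations = c("is_a", "part_of"),
                        wang_weights = c(is_a = 0.8, part_of = 0.6, regulates = 0.7),
                        cross_namespace = FALSE,
                        unsafe_c = FALSE) {
  method <- match.arg(method)
  relations <- match.arg(relations, GO_RELATIONS, several.ok = TRUE)
  if (!unsafe_c && method == "GOGO" && c < 0.67) {
    stop("c must be >= 0.67 so that every edge weight lies in (0, 1]; ",
         "set unsafe_c = TRUE to override")
  }
  if (c <= 0) stop("c must be positive")
  stopifnot(all(relations %in% names(d_weights)))
  if (any(d_weights <= 0) || any(d_weights >= 1)) stop("d_weights must lie in (0, 1)")
  if (method == "WANG") {
    stopifnot(all(relations %in% names(wang_weights)))
    if (any(wang_weights <= 0) || any(wang_weights >= 1)) {
      stop("wang_weights must lie in (0, 1)")
    }
  }
  structure(list(method = method, c = c, d_weights = d_weights,
                 relations = relations, wang_weights = wang_weights,
                 cross_namespace = cross_namespace),
            class = "semsim_config")
}

#' @export
print.semsim_config <- function(x, ...) {
  cat("Semantic similarity configuration\n")
  cat("  method:    ", x$method, "\n", sep = "")
  cat("  relations: ", paste(x$relations, collapse = " + "), "\n", sep = "")
  if (x$method == "GOGO") {
    cat("  c:         ", x$c, "\n", sep = "")
    cat("  d:         ",
        paste(sprintf("%s=%g", names(x$d_weights), x$d_weights), collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  weights:   ",
        paste(sprintf("%s=%g", names(x$wang_weights), x$wang_weights), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of direct children of a term
#'
#' Counts distinct direct children of `term` in the full ontology via the
#' given relations (not restricted to any ancestor graph).
#'
#' @inheritParams go_parents
#' @param term a term identifier.
#' @return non-negative integer.
#' @export
children_count <- function(ontology, term, relations = c("is_a", "part_of")) {
  length(unique(go_children(ontology, term, relations)$child))
}

#' Edge weight for semantic-contribution propagation
#'
#' For the GOGO method the weight of an edge into parent term `parent` is
#' `1/(c + nc(parent)) + d(relation)`, with `nc` the parent's direct child
#' count in the full ontology over the configured relations. For the Wang
#' method the weight is the configured per-relation constant.
#'
#' @inheritParams children_count
#' @param parent the parent (ancestor-side) term of the edge.
#' @param relation the edge's relation type.
#' @param config a [gogo_config].
#' @return a weight in (0, 1].
#' @export
edge_weight <- function(ontology, parent, relation, config = gogo_config()) {
  if (!relation %in% config$relations) {
    stop("relation '", relation, "' is not in the configured relation set")
  }
  w <- if (config$method == "GOGO") {
    nc <- children_count(ontology, parent, config$relations)
    1 / (config$c + nc) + config$d_weights[[relation]]
  } else {
    config$wang_weights[[relation]]
  }
  if (w <= 0 || w > 1) {
    stop("edge weight ", format(w), " outside (0, 1]; invalid c/d configuration")
  }
  w
}

#' Ancestor graph of a term with its S-values
#'
#' Builds the DAG induced by a term and all its ancestors over the
#' configured relations, then computes each node's S-value — the semantic
#' contribution of that ancestor to the target term, i.e. the maximum over
#' descending paths of the product of edge weights — by dynamic programming
#' in topological order (children before parents).
#'
#' @inheritParams edge_weight
#' @param term the target term (primary, non-obsolete).
#' @return an object of class `ancestor_graph` with elements `target`,
#'   `nodes`, `edges` (child/parent/relation/weight), and `s_values`
#'   (named numeric, `s_values[term] == 1`).
#' @export
ancestor_graph <- function(ontology, term, config = gogo_config()) {
  term <- go_resolve(ontology, term)
  nodes <- go_ancestors(ontology, term, config$relations, include_self = TRUE,
                        same_namespace = !config$cross_namespace)

  keep <- ontology$edges$child %in% nodes & ontology$edges$parent %in% nodes &
    ontology$edges$relation %in% config$relations
  edges <- ontology$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL

  # per-parent weights; nc is counted in the full ontology
  wts <- numeric(nrow(edges))
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      wts[i] <- edge_weight(ontology, edges$parent[i], edges$relation[i], config)
    }
  }
  edges$weight <- wts

  s <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  s[term] <- 1
  pending <- setdiff(nodes, term)
  while (length(pending)) {
    progressed <- FALSE
    for (t in pending) {
      rows <- which(edges$parent == t)
      ch <- edges$child[rows]
      if (any(is.na(s[ch]))) next
      s[t] <- max(edges$weight[rows] * s[ch])
      pending <- setdiff(pending, t)
      progressed <- TRUE
    }
    if (!progressed) stop("ancestor graph of ", term, " is not a DAG")
  }

  structure(list(target = term, nodes = nodes, edges = edges, s_values = s),
            class = "ancestor_graph")
}

#' @export
print.ancestor_graph <- function(x, ...) {
  cat("Ancestor graph of ", x$target, ": ", length(x$nodes), " terms, ",
      nrow(x$edges), " edges, SV = ", format(semantic_value(x), digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Semantic value of a term
#'
#' The sum of S-values over the term's ancestor graph. It is at least 1,
#' with equality exactly when the term is its namespace root.
#'
#' @param g an [ancestor_graph].
#' @return positive real.
#' @export
semantic_value <- function(g) {
  sum(g$s_values)
}

#' Create a memoisation cache for ancestor graphs
#'
#' Gene-level similarity evaluates the same terms' ancestor graphs many
#' times; passing one cache environment through repeated
#' [term_similarity()] calls avoids recomputing them. A cache is only
#' valid for one (ontology, configuration) pairing; results are identical
#' with or without it.
#'
#' @return an empty environment to pass as `cache`.
#' @export
new_semsim_cache <- function() new.env(parent = emptyenv())

.ancestor_graph_cached <- function(ontology, term, config, cache = NULL) {
  if (is.null(cache)) return(ancestor_graph(ontology, term, config))
  g <- cache[[term]]
  if (is.null(g)) {
    g <- ancestor_graph(ontology, term, config)
    cache[[term]] <- g
  }
  g
}

#' Semantic similarity between two GO terms
#'
#' The S-values of the common ancestors of the two terms, summed from both
#' sides and normalised by the two semantic values:
#' `sum over t in T_A intersect T_B of (S_A(t) + S_B(t)) / (SV(A) + SV(B))`.
#' Symmetric, equal to 1 for identical terms, and 0 only when the terms
#' share no ancestor.
#'
#' @inheritParams edge_weight
#' @param a,b term identifiers; must share a namespace unless the
#'   configuration allows cross-namespace traversal.
#' @param cache optional environment from [new_semsim_cache()] memoising
#'   ancestor graphs across calls (results are unaffected).
#' @return similarity in \[0, 1\].
#' @examples
#' ont <- simulate_ontology(fixture_spec(n_terms = 20, seed = 1))
#' ids <- ont$terms$id
#' term_similarity(ont, ids[5], ids[9])
#' @export
term_similarity <- function(ontology, a, b, config = gogo_config(), cache = NULL) {
  a <- go_resolve(ontology, a); b <- go_resolve(ontology, b)
  if (!config$cross_namespace &&
      ontology$terms[a, "namespace"] != ontology$terms[b, "namespace"]) {
    stop("terms ", a, " and ", b, " are in different namespaces")
  }
  ga <- .ancestor_graph_cached(ontology, a, config, cache)
  gb <- .ancestor_graph_cached(ontology, b, config, cache)
  common <- intersect(ga$nodes, gb$nodes)
  if (length(common) == 0L) return(0)
  sum(ga$s_values[common] + gb$s_values[common]) /
    (semantic_value(ga) + semantic_value(gb))
}

#' Pairwise term similarity matrix
#'
#' @inheritParams term_similarity
#' @param terms character vector of term identifiers (one namespace).
#' @return symmetric numeric matrix with unit diagonal, dimnames = terms.
#' @export
term_sim_matrix <- function(ontology, terms, config = gogo_config()) {
  terms <- go_resolve(ontology, terms)
  n <- length(terms)
  cache <- new_semsim_cache()
  m <- diag(1, n)
  dimnames(m) <- list(terms, terms)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- term_similarity(ontology, terms[i], terms[j], config, cache)
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  m
}
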