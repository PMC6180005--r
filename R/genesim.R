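# Mixing term-level similarities into gene-level functional similarity.
#
# Given the pairwise similarity matrix between the two genes' term sets,
# five mixing strategies are supported:
#   Avg — grand mean over all m x n pairs
#   Max — grand maximum
#   ABM — pooled best-match average: row-wise and column-wise maxima summed
#         and divided by m + n (the default)
#   BMA — mean of the two directional best-match averages
#   BMM — maximum of the two directional best-match averages

GENE_SIM_STRATEGIES <- c("ABM", "BMA", "BMM", "Avg", "Max")

#' Similarity between one GO term and a gene
#'
#' The best match of `go` against the gene's annotated terms:
#' `max_i S(go, go_i)`.
#'
#' @param ontology a [go_ontology].
#' @param go a term identifier.
#' @param terms the gene's annotated terms (non-empty, same namespace as
#'   `go`).
#' @param config a [gogo_config].
#' @param cache optional [new_semsim_cache()] environment.
#' @return similarity in \[0, 1\].
#' @export
term_to_gene_similarity <- function(ontology, go, terms, config = gogo_config(),
                                    cache = NULL) {
  if (length(terms) == 0L) stop("the gene has no annotated terms")
  max(vapply(terms, function(t) term_similarity(ontology, go, t, config, cache),
             numeric(1)))
}

# strategy arithmetic on a precomputed m x n term-pair similarity matrix
.mix_strategies <- function(m) {
  row_best <- apply(m, 1L, max)
  col_best <- apply(m, 2L, max)
  c(ABM = (sum(row_best) + sum(col_best)) / (nrow(m) + ncol(m)),
    BMA = (mean(row_best) + mean(col_best)) / 2,
    BMM = max(mean(row_best), mean(col_best)),
    Avg = mean(m),
    Max = max(m))
}

#' Functional similarity between two genes
#'
#' @inheritParams term_to_gene_similarity
#' @param terms1,terms2 the two genes' annotated terms (non-empty, one
#'   namespace).
#' @param strategy one of `"ABM"` (default), `"BMA"`, `"BMM"`, `"Avg"`,
#'   `"Max"`.
#' @return similarity in \[0, 1\], symmetric in the two genes.
#' @examples
#' ont <- simulate_ontology(fixture_spec(n_terms = 25, seed = 2))
#' ids <- ont$terms$id
#' gene_similarity(ont, ids[3:5], ids[c(4, 8)])
#' @export
gene_similarity <- function(ontology, terms1, terms2,
                            strategy = c("ABM", "BMA", "BMM", "Avg", "Max"),
                            config = gogo_config(), cache = NULL) {
  strategy <- match.arg(strategy)
  if (length(terms1) == 0L || length(terms2) == 0L) {
    stop("both genes must have at least one annotated term")
  }
  terms1 <- go_resolve(ontology, terms1)
  terms2 <- go_resolve(ontology, terms2)
  ns <- unique(ontology$terms[c(terms1, terms2), "namespace"])
  if (length(ns) > 1L && !config$cross_namespace) {
    stop("gene term sets span namespaces: ", paste(ns, collapse = ", "))
  }
  if (is.null(cache)) cache <- new_semsim_cache()
  m <- matrix(0, length(terms1), length(terms2))
  for (i in seq_along(terms1)) {
    for (j in seq_along(terms2)) {
      m[i, j] <- term_similarity(ontology, terms1[i], terms2[j], config, cache)
    }
  }
  unname(.mix_strategies(m)[strategy])
}

#' Pairwise gene functional-similarity matrix
#'
#' Genes without any annotated term in the requested namespace are excluded
#' (and reported via the `"excluded"` attribute); the matrix covers the
#' remaining genes with a unit diagonal.
#'
#' @inheritParams gene_similarity
#' @param annotations a [go_annotations].
#' @param genes character vector of gene identifiers.
#' @param namespace the ontology to compute in (`"BPO"`, `"CCO"`, `"MFO"`,
#'   or a synthetic namespace label).
#' @return symmetric numeric matrix with `dimnames` = retained genes and
#'   attributes `"excluded"` (character vector), `"namespace"` and
#'   `"strategy"`.
#' @export
gene_sim_matrix <- function(ontology, annotations, genes, namespace,
                            strategy = c("ABM", "BMA", "BMM", "Avg", "Max"),
                            config = gogo_config()) {
  strategy <- match.arg(strategy)
  if (length(genes) == 0L) stop("gene list is empty")
  namespace <- go_namespace(namespace)
  tsets <- lapply(genes, function(g) gene_terms(annotations, g, namespace))
  names(tsets) <- genes
  excluded <- genes[lengths(tsets) == 0L]
  kept <- setdiff(genes, excluded)
  if (length(kept) == 0L) {
    stop("no gene has annotated terms in namespace ", namespace)
  }
  cache <- new_semsim_cache()
  n <- length(kept)
  m <- diag(1, n)
  dimnames(m) <- list(kept, kept)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- gene_similarity(ontology, tsets[[kept[i]]], tsets[[kept[j]]],
                             strategy, config, cache)
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  attr(m, "excluded") <- excluded
  attr(m, "namespace") <- namespace
  attr(m, "strategy") <- strategy
  m
}
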