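# Seeded generators for synthetic ontologies and clustered annotation
# sets, so the whole pipeline — parsing, similarity, clustering,
# evaluation — is testable without downloading a GO release.

#' Specification for synthetic fixtures
#'
#' @param n_terms terms per namespace, including the root.
#' @param max_depth maximum term depth below the root.
#' @param branching minimum number of depth-1 terms hung off the root;
#'   also shapes the breadth of the DAG.
#' @param relation_mix named probabilities over `is_a`, `part_of`,
#'   `regulates` used when typing edges; a term's primary (connecting)
#'   edge is always `is_a` or `part_of` so every term stays reachable from
#'   the root without the regulates relation.
#' @param extra_parent_prob probability that a term receives a second
#'   parent, creating diamonds and multi-path ancestries.
#' @param n_genes total genes to simulate.
#' @param terms_per_gene length-2 integer range of annotations per gene.
#' @param n_clusters number of planted gene clusters.
#' @param within_cluster_term_overlap probability in \[0, 1\] that a gene's
#'   annotation is drawn from its cluster's home subtree rather than
#'   uniformly; 1 plants cleanly separated clusters, 0 plants none.
#' @param namespaces namespace label(s); one independent DAG is generated
#'   per namespace.
#' @param seed integer seed; identical specs yield identical fixtures.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 60L, max_depth = 5L, branching = 3,
                         relation_mix = c(is_a = 0.7, part_of = 0.25, regulates = 0.05),
                         extra_parent_prob = 0.25,
                         n_genes = 12L, terms_per_gene = c(3L, 6L),
                         n_clusters = 3L, within_cluster_term_overlap = 1,
                         namespaces = "BPO", seed = 1L) {
  stopifnot(n_terms >= 1L, max_depth >= 1L, branching >= 1)
  if (abs(sum(relation_mix) - 1) > 1e-9) stop("relation_mix must sum to 1")
  if (any(relation_mix < 0)) stop("relation_mix probabilities must be non-negative")
  stopifnot(n_terms >= n_clusters, n_clusters >= 1L,
            within_cluster_term_overlap >= 0, within_cluster_term_overlap <= 1,
            length(terms_per_gene) == 2L, terms_per_gene[1L] <= terms_per_gene[2L])
  if (n_terms > 1L && 1L + ceiling(branching) > n_terms) {
    stop("n_terms too small for the requested branching")
  }
  structure(list(n_terms = as.integer(n_terms), max_depth = as.integer(max_depth),
                 branching = branching, relation_mix = relation_mix,
                 extra_parent_prob = extra_parent_prob,
                 n_genes = as.integer(n_genes),
                 terms_per_gene = as.integer(terms_per_gene),
                 n_clusters = as.integer(n_clusters),
                 within_cluster_term_overlap = within_cluster_term_overlap,
                 namespaces = namespaces, seed = as.integer(seed)),
            class = "fixture_spec")
}

# sample() treats a length-1 numeric vector as 1:x; this never does
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  expr
}

#' Generate a synthetic ontology DAG
#'
#' Builds one single-root DAG per namespace, acyclic by construction
#' (every parent of a new term already exists), with typed edges and a mix
#' of single- and multi-parent terms. The result serialises to OBO via
#' [write_obo()] and re-parses to an identical graph.
#'
#' @param spec a [fixture_spec].
#' @return a [go_ontology] with `spec$n_terms * length(spec$namespaces)`
#'   terms.
#' @export
simulate_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    primary_mix <- spec$relation_mix[c("is_a", "part_of")]
    primary_mix <- primary_mix / sum(primary_mix)
    ids_all <- character(); names_all <- character(); ns_all <- character()
    e_child <- e_parent <- e_rel <- character()
    counter <- 0L
    for (nsp in spec$namespaces) {
      ids <- sprintf("GO:%07d", counter + seq_len(spec$n_terms))
      counter <- counter + spec$n_terms
      depth <- integer(spec$n_terms)
      subtree <- integer(spec$n_terms)  # depth-1 ancestor along the primary path
      depth[1L] <- 0L  # ids[1] is the namespace root
      subtree[1L] <- 0L
      n_level1 <- min(spec$n_terms - 1L, ceiling(spec$branching))
      for (i in seq_len(spec$n_terms)[-1L]) {
        if (i <= 1L + n_level1) {
          pi <- 1L
          rel <- "is_a"
          subtree[i] <- i
        } else {
          # two-stage choice — a depth-1 subtree uniformly, then a parent
          # inside it — keeps the subtrees comparably sized
          st <- .sample1(1L + seq_len(n_level1))
          eligible <- which(subtree[seq_len(i - 1L)] == st &
                              depth[seq_len(i - 1L)] < spec$max_depth)
          if (length(eligible) == 0L) {
            eligible <- which(depth[seq_len(i - 1L)] < spec$max_depth)[-1L]
          }
          if (length(eligible) == 0L) eligible <- 1L
          pi <- .sample1(eligible)
          rel <- sample(names(primary_mix), 1L, prob = primary_mix)
          subtree[i] <- subtree[pi]
        }
        depth[i] <- depth[pi] + 1L
        e_child <- c(e_child, ids[i]); e_parent <- c(e_parent, ids[pi])
        e_rel <- c(e_rel, rel)
        # extra parents stay inside the primary depth-1 subtree, so the
        # subtrees below different depth-1 terms share ancestry only at
        # the root (real GO also has cross-branch links; see the vignette)
        if (stats::runif(1L) < spec$extra_parent_prob) {
          others <- setdiff(
            which(depth[seq_len(i - 1L)] < spec$max_depth &
                    subtree[seq_len(i - 1L)] == subtree[i]), pi)
          if (length(others)) {
            pj <- .sample1(others)
            rel2 <- sample(names(spec$relation_mix), 1L, prob = spec$relation_mix)
            e_child <- c(e_child, ids[i]); e_parent <- c(e_parent, ids[pj])
            e_rel <- c(e_rel, rel2)
          }
        }
      }
      ids_all <- c(ids_all, ids)
      names_all <- c(names_all, paste0("synthetic term ", ids))
      ns_all <- c(ns_all, rep(nsp, spec$n_terms))
    }
    terms <- data.frame(id = ids_all, name = names_all, namespace = ns_all,
                        stringsAsFactors = FALSE)
    edges <- unique(data.frame(child = e_child, parent = e_parent, relation = e_rel,
                               stringsAsFactors = FALSE))
    go_ontology(terms, edges, release_date = "synthetic",
                relations = GO_RELATIONS)
  })
}

#' Generate clustered genes with matching annotations and reference labels
#'
#' Each planted cluster is assigned a "home" depth-1 subtree of the first
#' namespace; its genes draw each annotation from the home subtree with
#' probability `within_cluster_term_overlap` and uniformly from the whole
#' namespace otherwise. Home subtrees are restricted to terms reachable
#' from exactly one home, so at overlap 1 the clusters share ancestry only
#' through the root. Synthetic EC numbers share their first two levels
#' within a cluster, for EC-matched noise selection.
#'
#' @param spec a [fixture_spec].
#' @param ontology the ontology from [simulate_ontology()] (or any
#'   [go_ontology] with at least `spec$n_clusters` depth-1 terms).
#' @return list with `annotations` (a [go_annotations]) and `reference`
#'   (a [reference_pathway] with synthetic EC numbers).
#' @export
simulate_clustered_genes <- function(spec, ontology) {
  stopifnot(inherits(spec, "fixture_spec"))
  nsp <- spec$namespaces[1L]
  root <- go_roots(ontology, c("is_a", "part_of"), nsp)
  level1 <- go_children(ontology, root, c("is_a", "part_of"))$child
  level1 <- unique(level1)
  if (length(level1) < spec$n_clusters) {
    stop("ontology has ", length(level1), " depth-1 terms but ",
         spec$n_clusters, " planted clusters were requested")
  }
  desc <- lapply(level1, function(h)
    go_descendants(ontology, h, c("is_a", "part_of"), include_self = TRUE))
  names(desc) <- level1

  .with_seed(spec$seed + 1L, {
    # homes = the depth-1 terms with the most exclusively-owned descendants
    counts_excl <- vapply(level1, function(h) {
      others <- unlist(desc[setdiff(level1, h)], use.names = FALSE)
      length(setdiff(desc[[h]], others))
    }, integer(1))
    homes <- level1[order(-counts_excl)][seq_len(spec$n_clusters)]
    pure <- lapply(homes, function(h) {
      others <- unlist(desc[setdiff(level1, h)], use.names = FALSE)
      setdiff(desc[[h]], others)
    })
    names(pure) <- homes
    core_size <- spec$terms_per_gene[2L] + 2L
    if (any(lengths(pure) < core_size)) {
      stop("within_cluster_term_overlap cannot be honoured: a home subtree has ",
           "fewer exclusive terms (", min(lengths(pure)), ") than a cluster's ",
           "core annotation pool needs (", core_size, ")")
    }
    # genes of a cluster share a small core annotation pool, the way
    # pathway members share most of their experimental GO annotations,
    # without being annotation-identical
    core <- lapply(pure, function(p) {
      if (length(p) == core_size) p else sample(p, core_size)
    })
    all_terms <- setdiff(
      ontology$terms$id[ontology$terms$namespace == go_namespace(nsp)], root)

    cluster_of <- rep(seq_len(spec$n_clusters), length.out = spec$n_genes)
    cluster_of <- sort(cluster_of)
    genes <- sprintf("GENE%03d", seq_len(spec$n_genes))
    rec_gene <- rec_term <- character()
    seen_sets <- character()
    for (gi in seq_len(spec$n_genes)) {
      k <- cluster_of[gi]
      home_pool <- core[[homes[k]]]
      # annotation-identical genes are both unrealistic and degenerate for
      # exemplar-based clustering, so duplicate term sets are redrawn
      for (attempt in 1:50) {
        n_t <- .sample1(seq(spec$terms_per_gene[1L], spec$terms_per_gene[2L]))
        terms_g <- character()
        while (length(terms_g) < n_t) {
          from_home <- stats::runif(1L) < spec$within_cluster_term_overlap
          pool <- if (from_home) home_pool else all_terms
          pool <- setdiff(pool, terms_g)
          if (length(pool) == 0L) break
          terms_g <- c(terms_g, .sample1(pool))
        }
        key <- paste(sort(terms_g), collapse = "|")
        if (!(key %in% seen_sets)) break
      }
      seen_sets <- c(seen_sets, key)
      rec_gene <- c(rec_gene, rep(genes[gi], length(terms_g)))
      rec_term <- c(rec_term, terms_g)
    }
    records <- data.frame(gene = rec_gene, term = rec_term,
                          evidence = "IDA",
                          namespace = ontology$terms[rec_term, "namespace"],
                          stringsAsFactors = FALSE)
    ann <- go_annotations(records, ontology)
    ec <- sprintf("%d.%d.1.%d", cluster_of, cluster_of, seq_len(spec$n_genes))
    ref <- reference_pathway(genes, paste0("C", cluster_of), ec)
    list(annotations = ann, reference = ref)
  })
}

#' Write an annotation set as simple TSV (gene, semicolon-joined terms)
#' @param annotations a [go_annotations].
#' @param path file to write, or `NULL` to return the lines.
#' @return the TSV lines, invisibly when written to a file.
#' @export
write_annotations_tsv <- function(annotations, path = NULL) {
  by_gene <- split(annotations$records$term, annotations$records$gene)
  lines <- vapply(names(by_gene), function(g) {
    paste0(g, "\t", paste(sort(unique(by_gene[[g]])), collapse = ";"))
  }, "")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  unname(lines)
}

#' Write a reference pathway as TSV (gene, cluster, EC)
#' @param reference a [reference_pathway].
#' @param path file to write, or `NULL` to return the lines.
#' @return the TSV lines, invisibly when written to a file.
#' @export
write_reference_tsv <- function(reference, path = NULL) {
  lines <- vapply(seq_len(nrow(reference)), function(i) {
    paste(c(reference$gene[i], reference$cluster[i],
            if (!is.na(reference$ec[i])) reference$ec[i]), collapse = "\t")
  }, "")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
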