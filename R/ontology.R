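GO_RELATIONS <- c("is_a", "part_of", "regulates")

GO_NAMESPACES <- c(
  biological_process = "BPO",
  cellular_component = "CCO",
  molecular_function = "MFO"
)

#' Normalise an ontology namespace label
#'
#' Accepts either the long OBO namespace strings (`biological_process`,
#' `cellular_component`, `molecular_function`) or the short codes used
#' throughout this package (`BPO`, `CCO`, `MFO`) and returns the short code.
#' Unrecognised labels are returned unchanged, which allows synthetic
#' ontologies to use their own namespace names.
#'
#' @param x character vector of namespace labels.
#' @return character vector of the same length.
#' @export
go_namespace <- function(x) {
  out <- unname(GO_NAMESPACES[x])
  ifelse(is.na(out), x, out)
}

#' Construct a validated GO ontology graph
#'
#' The container for a typed GO DAG: terms carry a name and a namespace,
#' edges are directed child-to-parent links typed with one of the
#' relations `is_a`, `part_of` or `regulates`. Alternative identifiers and
#' obsolete identifiers are kept alongside so that annotation files citing
#' them can still be resolved.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @param alt_ids named character vector mapping alternative identifier to
#'   primary identifier.
#' @param obsolete character vector of retired identifiers.
#' @param release_date free-text release metadata from the OBO header.
#' @param relations the relation types the graph was restricted to.
#' @return an object of class `go_ontology`.
#' @export
go_ontology <- function(terms, edges, alt_ids = character(), obsolete = character(),
                        release_date = NA_character_, relations = GO_RELATIONS) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in% names(terms)))
  if (nrow(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  terms$namespace <- go_namespace(terms$namespace)
  if (anyDuplicated(terms$id)) {
    stop("duplicate term identifiers: ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  bad_rel <- setdiff(unique(edges$relation), GO_RELATIONS)
  if (length(bad_rel)) stop("unknown relation type(s): ", paste(bad_rel, collapse = ", "))
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown)) {
    stop("edge endpoint(s) are not primary terms: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (length(obsolete) && any(c(edges$child, edges$parent) %in% obsolete)) {
    stop("edges may not touch obsolete terms")
  }
  if (length(alt_ids)) {
    bad_alt <- setdiff(unname(alt_ids), terms$id)
    if (length(bad_alt)) {
      stop("alt_id target(s) missing from terms: ", paste(bad_alt, collapse = ", "))
    }
  }
  rownames(terms) <- terms$id
  ont <- structure(
    list(terms = terms,
         edges = edges,
         alt_ids = alt_ids,
         obsolete = unique(obsolete),
         release_date = release_date,
         relations = relations),
    class = "go_ontology")
  ont <- .go_index(ont)
  .go_check_acyclic(ont)
  ont
}

# row-index lookups by child and by parent, rebuilt whenever edges change
.go_index <- function(ont) {
  e <- ont$edges
  ont$.by_child <- split(seq_len(nrow(e)), factor(e$child, levels = ont$terms$id))
  ont$.by_parent <- split(seq_len(nrow(e)), factor(e$parent, levels = ont$terms$id))
  ont
}

# Kahn's algorithm over the full edge set; cycles make the peel stall
.go_check_acyclic <- function(ont) {
  n <- nrow(ont$terms)
  if (n == 0L) return(invisible(TRUE))
  ids <- ont$terms$id
  out_deg <- tabulate(match(ont$edges$child, ids), nbins = n)
  by_parent <- ont$.by_parent
  queue <- which(out_deg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ri in by_parent[[v]]) {
      ci <- match(ont$edges$child[ri], ids)
      out_deg[ci] <- out_deg[ci] - 1L
      if (out_deg[ci] == 0L) queue <- c(queue, ci)
    }
  }
  if (seen != n) stop("cycle detected in the ontology graph")
  invisible(TRUE)
}

#' @export
print.go_ontology <- function(x, ...) {
  ns <- table(x$terms$namespace)
  rel <- table(x$edges$relation)
  cat("GO ontology graph\n")
  cat("  release:   ", ifelse(is.na(x$release_date), "<unknown>", x$release_date), "\n", sep = "")
  cat("  terms:     ", nrow(x$terms), " (",
      paste(sprintf("%s: %d", names(ns), as.integer(ns)), collapse = ", "), ")\n", sep = "")
  cat("  edges:     ", nrow(x$edges), " (",
      paste(sprintf("%s: %d", names(rel), as.integer(rel)), collapse = ", "), ")\n", sep = "")
  cat("  alt ids:   ", length(x$alt_ids), "\n", sep = "")
  cat("  obsolete:  ", length(x$obsolete), "\n", sep = "")
  invisible(x)
}

#' Resolve term identifiers to primary identifiers
#'
#' Maps alternative identifiers to their primary identifier and checks that
#' the result is a known, non-obsolete term.
#'
#' @param ontology a [go_ontology].
#' @param ids character vector of GO identifiers.
#' @param strict error on unresolvable identifiers (default) rather than
#'   returning `NA` for them.
#' @return character vector of primary identifiers.
#' @export
go_resolve <- function(ontology, ids, strict = TRUE) {
  out <- ids
  is_alt <- out %in% names(ontology$alt_ids)
  out[is_alt] <- unname(ontology$alt_ids[out[is_alt]])
  known <- out %in% ontology$terms$id
  if (!all(known)) {
    if (strict) {
      bad <- unique(ids[!known])
      stop("unknown or obsolete term identifier(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    out[!known] <- NA_character_
  }
  out
}

# edge rows whose relation is in `relations`
.rel_rows <- function(rows, ont, relations) {
  rows[ont$edges$relation[rows] %in% relations]
}

#' Direct parents of a term
#' @inheritParams go_resolve
#' @param id a single term identifier.
#' @param relations relation subset to traverse.
#' @return data.frame with columns `parent`, `relation`.
#' @export
go_parents <- function(ontology, id, relations = ontology$relations) {
  id <- go_resolve(ontology, id)
  rows <- .rel_rows(ontology$.by_child[[id]], ontology, relations)
  data.frame(parent = ontology$edges$parent[rows],
             relation = ontology$edges$relation[rows],
             stringsAsFactors = FALSE)
}

#' Direct children of a term
#' @inheritParams go_parents
#' @return data.frame with columns `child`, `relation`.
#' @export
go_children <- function(ontology, id, relations = ontology$relations) {
  id <- go_resolve(ontology, id)
  rows <- .rel_rows(ontology$.by_parent[[id]], ontology, relations)
  data.frame(child = ontology$edges$child[rows],
             relation = ontology$edges$relation[rows],
             stringsAsFactors = FALSE)
}

#' All ancestors of a term by upward closure
#'
#' @inheritParams go_parents
#' @param include_self include `id` itself in the result.
#' @param same_namespace stop the traversal at namespace boundaries
#'   (the default; cross-namespace `part_of` links exist in the full GO but
#'   similarity is computed per namespace).
#' @return character vector of ancestor identifiers.
#' @export
go_ancestors <- function(ontology, id, relations = ontology$relations,
                         include_self = FALSE, same_namespace = TRUE) {
  id <- go_resolve(ontology, id)
  ns <- ontology$terms[id, "namespace"]
  seen <- character()
  frontier <- id
  while (length(frontier)) {
    nxt <- character()
    for (t in frontier) {
      rows <- .rel_rows(ontology$.by_child[[t]], ontology, relations)
      p <- unique(ontology$edges$parent[rows])
      if (same_namespace) p <- p[ontology$terms[p, "namespace"] == ns]
      nxt <- c(nxt, setdiff(p, seen))
    }
    nxt <- setdiff(unique(nxt), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (include_self) unique(c(id, seen)) else setdiff(seen, id)
}

#' All descendants of a term by downward closure
#' @inheritParams go_ancestors
#' @return character vector of descendant identifiers.
#' @export
go_descendants <- function(ontology, id, relations = ontology$relations,
                           include_self = FALSE, same_namespace = TRUE) {
  id <- go_resolve(ontology, id)
  ns <- ontology$terms[id, "namespace"]
  seen <- character()
  frontier <- id
  while (length(frontier)) {
    nxt <- character()
    for (t in frontier) {
      rows <- .rel_rows(ontology$.by_parent[[t]], ontology, relations)
      ch <- unique(ontology$edges$child[rows])
      if (same_namespace) ch <- ch[ontology$terms[ch, "namespace"] == ns]
      nxt <- c(nxt, setdiff(ch, seen))
    }
    nxt <- setdiff(unique(nxt), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (include_self) unique(c(id, seen)) else setdiff(seen, id)
}

#' Root term(s) of the ontology
#'
#' A root is a term with no parent via the given relations inside its own
#' namespace.
#' @inheritParams go_parents
#' @param namespace optionally restrict to one namespace.
#' @return character vector of root identifiers.
#' @export
go_roots <- function(ontology, relations = ontology$relations, namespace = NULL) {
  ids <- ontology$terms$id
  if (!is.null(namespace)) {
    ids <- ids[ontology$terms$namespace == go_namespace(namespace)]
  }
  has_parent <- vapply(ids, function(t) {
    rows <- .rel_rows(ontology$.by_child[[t]], ontology, relations)
    p <- ontology$edges$parent[rows]
    any(ontology$terms[p, "namespace"] == ontology$terms[t, "namespace"])
  }, logical(1))
  ids[!has_parent]
}

#' Depth of terms below their namespace root
#'
#' Depth is the minimum number of edges from the namespace root, with the
#' root at depth 0, computed by breadth-first search downward from the root
#' over the given relations.
#'
#' @inheritParams go_parents
#' @param namespace the namespace whose root to measure from.
#' @return named integer vector, `NA` for terms unreachable from the root.
#' @export
go_depths <- function(ontology, namespace, relations = ontology$relations) {
  namespace <- go_namespace(namespace)
  root <- go_roots(ontology, relations, namespace)
  if (length(root) != 1L) {
    stop("namespace ", namespace, " has ", length(root), " roots; expected 1")
  }
  ids <- ontology$terms$id[ontology$terms$namespace == namespace]
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[root] <- 0L
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- character()
    for (t in frontier) {
      ch <- go_children(ontology, t, relations)$child
      ch <- ch[ch %in% ids]
      new <- ch[is.na(depth[ch])]
      depth[new] <- d
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  depth
}
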