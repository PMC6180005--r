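# Corpus-based information content and the Resnik / Lin baselines.
#
# IC(f) = -log P(f), where P(f) is the probability that an annotation in
# the corpus falls on f or any of its descendants. Propagated counts are
# obtained by crediting each annotation occurrence to the annotated term
# and every ancestor of it, which counts each occurrence exactly once per
# ancestor even when the DAG offers several upward paths.

#' Information content from an annotation corpus
#'
#' Counts annotation occurrences per term, propagates them to ancestors,
#' and converts the propagated frequency into information content
#' `IC = -log(propagated / namespace total)` using the natural logarithm.
#' The namespace total is the propagated count at the namespace root, so
#' the root's IC is 0. Terms never seen in the corpus (directly or below)
#' get `NA` IC and are flagged rather than assigned infinite content.
#'
#' @param ontology a [go_ontology].
#' @param corpus a [go_annotations] whose terms resolve in `ontology`.
#' @param relations relation subset for ancestor propagation.
#' @return an object of class `corpus_counts`: a list with `table` (a
#'   data.frame of id, namespace, raw_count, propagated_count, ic) and the
#'   `relations` used.
#' @export
compute_ic <- function(ontology, corpus, relations = c("is_a", "part_of")) {
  ids <- ontology$terms$id
  raw <- stats::setNames(integer(length(ids)), ids)
  occ <- table(corpus$records$term)
  raw[names(occ)] <- as.integer(occ)

  prop <- stats::setNames(numeric(length(ids)), ids)
  annotated <- names(raw)[raw > 0L]
  for (t in annotated) {
    up <- go_ancestors(ontology, t, relations, include_self = TRUE)
    prop[up] <- prop[up] + raw[[t]]
  }

  ns <- ontology$terms$namespace
  ic <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (nsp in unique(ns)) {
    root <- go_roots(ontology, relations, nsp)
    total <- if (length(root)) sum(prop[root]) else 0
    if (total == 0) {
      warning("no corpus annotations in namespace ", nsp, "; its ICs are undefined")
      next
    }
    in_ns <- ns == nsp & prop > 0
    ic[in_ns] <- -log(prop[in_ns] / total)
  }

  structure(list(table = data.frame(id = ids, namespace = ns,
                                    raw_count = unname(raw),
                                    propagated_count = unname(prop),
                                    ic = unname(ic),
                                    stringsAsFactors = FALSE,
                                    row.names = ids),
                 relations = relations),
            class = "corpus_counts")
}

#' @export
print.corpus_counts <- function(x, ...) {
  cat("Corpus term counts: ", sum(x$table$raw_count), " occurrences over ",
      sum(x$table$raw_count > 0), " terms; IC defined for ",
      sum(!is.na(x$table$ic)), "/", nrow(x$table), " terms\n", sep = "")
  invisible(x)
}

.ic_of <- function(counts, term) counts$table[term, "ic"]

.mica_ic <- function(counts, ontology, a, b) {
  rel <- counts$relations
  anc_a <- go_ancestors(ontology, a, rel, include_self = TRUE)
  anc_b <- go_ancestors(ontology, b, rel, include_self = TRUE)
  common <- intersect(anc_a, anc_b)
  if (length(common) == 0L) return(0)
  ics <- counts$table[common, "ic"]
  ics <- ics[!is.na(ics)]
  if (length(ics) == 0L) return(0)
  max(ics)
}

#' Resnik similarity: IC of the most informative common ancestor
#'
#' @param counts a [compute_ic] result.
#' @param ontology the companion [go_ontology].
#' @param a,b term identifiers in one namespace.
#' @return non-negative real; 0 when the terms share no (informative)
#'   common ancestor.
#' @export
resnik_similarity <- function(counts, ontology, a, b) {
  a <- go_resolve(ontology, a); b <- go_resolve(ontology, b)
  .mica_ic(counts, ontology, a, b)
}

#' Lin similarity: normalised shared information content
#'
#' `2 * IC(MICA) / (IC(a) + IC(b))`. When both query ICs are zero there is
#' no information to share and the similarity is defined as 0 (with a
#' warning).
#'
#' @inheritParams resnik_similarity
#' @return similarity in \[0, 1\].
#' @export
lin_similarity <- function(counts, ontology, a, b) {
  a <- go_resolve(ontology, a); b <- go_resolve(ontology, b)
  ia <- .ic_of(counts, a); ib <- .ic_of(counts, b)
  if (is.na(ia) || is.na(ib)) stop("IC undefined for ", a, " or ", b)
  if (ia + ib == 0) {
    warning("both query terms have zero IC; Lin similarity defined as 0")
    return(0)
  }
  2 * .mica_ic(counts, ontology, a, b) / (ia + ib)
}

#' Relationship between a term's children count and its information content
#'
#' Groups the terms of each namespace by their number of direct children,
#' averages IC within each group, drops groups with more than
#' `max_children` children (extreme, near-zero-IC points), and correlates
#' `log(average IC)` with the children count. A strong negative correlation
#' is what motivates using the children count as a corpus-free stand-in
#' for IC.
#'
#' @inheritParams compute_ic
#' @param counts a [compute_ic] result.
#' @param max_children drop groups with children count above this (default
#'   100).
#' @return a data.frame (one row per namespace) with columns `namespace`,
#'   `n_groups`, `spearman`, `pearson`, plus attribute `"groups"` holding
#'   the grouped table.
#' @export
children_ic_correlation <- function(ontology, counts, max_children = 100,
                                    relations = counts$relations) {
  tab <- counts$table
  nc <- vapply(tab$id, function(t) children_count(ontology, t, relations), integer(1))
  out <- list(); groups_all <- list()
  for (nsp in unique(tab$namespace)) {
    in_ns <- tab$namespace == nsp & !is.na(tab$ic)
    if (!any(in_ns)) next
    grp <- stats::aggregate(list(avg_ic = tab$ic[in_ns]),
                            by = list(nc = nc[in_ns]), FUN = mean)
    grp <- grp[grp$nc <= max_children, , drop = FALSE]
    grp$log_avg_ic <- ifelse(grp$avg_ic > 0, log(grp$avg_ic), NA_real_)
    usable <- grp[is.finite(grp$log_avg_ic), , drop = FALSE]
    if (nrow(usable) < 3L) {
      stop("namespace ", nsp, " has fewer than 3 children-count groups with ",
           "positive average IC; correlation undefined")
    }
    pear <- if (stats::sd(usable$log_avg_ic) == 0 || stats::sd(usable$nc) == 0) {
      warning("zero variance in namespace ", nsp, "; Pearson correlation undefined")
      NA_real_
    } else {
      stats::cor(usable$nc, usable$log_avg_ic, method = "pearson")
    }
    spear <- suppressWarnings(stats::cor(usable$nc, usable$log_avg_ic,
                                         method = "spearman"))
    out[[nsp]] <- data.frame(namespace = nsp, n_groups = nrow(usable),
                             spearman = spear, pearson = pear,
                             stringsAsFactors = FALSE)
    usable$namespace <- nsp
    groups_all[[nsp]] <- usable
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "groups") <- do.call(rbind, groups_all)
  res
}
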