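# Evaluating a gene clustering against a reference pathway with the
# Matthews correlation coefficient, computed per gene from pairwise
# cluster co-membership, plus noise-gene injection and the pair-sampling
# utilities used for method comparisons.

#' Reference pathway (true clusters) container
#'
#' @param genes character vector of gene identifiers.
#' @param clusters parallel vector of reference cluster labels.
#' @param ec optional parallel vector of Enzyme Commission numbers
#'   (dot-separated, at least two levels) or `NA`.
#' @return an object of class `reference_pathway`: data.frame with columns
#'   `gene`, `cluster`, `ec`.
#' @export
reference_pathway <- function(genes, clusters, ec = NULL) {
  stopifnot(length(genes) == length(clusters))
  if (anyDuplicated(genes)) stop("duplicate genes in reference pathway")
  if (is.null(ec)) ec <- rep(NA_character_, length(genes))
  ok <- is.na(ec) | vapply(strsplit(ec, ".", fixed = TRUE), length, integer(1)) >= 2L
  if (!all(ok)) stop("EC numbers must have at least two dot-separated levels")
  structure(data.frame(gene = genes, cluster = as.character(clusters), ec = ec,
                       stringsAsFactors = FALSE),
            class = c("reference_pathway", "data.frame"))
}

#' Read a reference pathway from TSV (gene, cluster label, optional EC)
#' @param source path to a TSV file, or a character vector of its lines.
#' @return a [reference_pathway].
#' @export
read_reference_pathway <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE),
           use.names = FALSE)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 2L)) stop("reference pathway rows need gene<TAB>cluster")
  reference_pathway(vapply(f, `[`, "", 1L), vapply(f, `[`, "", 2L),
                    ec = vapply(f, function(z) if (length(z) >= 3L) z[3L] else NA_character_, ""))
}

#' Matthews correlation coefficient from a 2x2 confusion matrix
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the value
#' defined as 0 whenever a factor of the denominator is zero.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return real in \[-1, 1\].
#' @examples
#' mcc_score(2, 2, 1, 1)  # (4 - 1) / sqrt(81) = 1/3
#' @export
mcc_score <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Evaluate a clustering against a reference pathway
#'
#' Noise genes, if any, are appended to the reference as one extra cluster
#' containing only them. For every gene the other genes are scanned: a pair
#' in the same reference cluster and the same predicted cluster is a true
#' positive; same reference but split prediction, a false negative;
#' different reference but merged prediction, a false positive; different
#' in both, a true negative. Each gene then gets an MCC from its counts;
#' clusters are scored by the mean over their genes, and the overall score
#' is the mean of the per-cluster averages.
#'
#' @param predicted an `ap_clustering` or a named vector gene -> predicted
#'   cluster label covering all evaluated genes.
#' @param reference a [reference_pathway].
#' @param noise_genes character vector of injected outside genes (possibly
#'   empty).
#' @return an object of class `mcc_report`: list with `per_gene`
#'   (data.frame gene, cluster, tp, tn, fp, fn, mcc), `per_cluster`
#'   (data.frame cluster, n_genes, avg_mcc) and `overall`.
#' @export
evaluate_clustering <- function(predicted, reference, noise_genes = character()) {
  if (inherits(predicted, "ap_clustering")) predicted <- predicted$clusters
  if (length(intersect(reference$gene, noise_genes))) {
    stop("noise genes overlap the reference pathway")
  }
  ref <- stats::setNames(reference$cluster, reference$gene)
  if (length(noise_genes)) {
    ref[noise_genes] <- ".noise"
  }
  genes <- names(ref)
  missing <- setdiff(genes, names(predicted))
  if (length(missing)) {
    stop("predicted clustering is missing gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  extra <- setdiff(names(predicted), genes)
  if (length(extra)) {
    stop("predicted clustering contains gene(s) outside reference + noise: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  pred <- predicted[genes]
  n <- length(genes)

  same_ref <- outer(ref, ref, "==")
  same_pred <- outer(pred, pred, "==")
  diag(same_ref) <- NA
  diag(same_pred) <- NA
  tp <- rowSums(same_ref & same_pred, na.rm = TRUE)
  fn <- rowSums(same_ref & !same_pred, na.rm = TRUE)
  fp <- rowSums(!same_ref & same_pred, na.rm = TRUE)
  tn <- rowSums(!same_ref & !same_pred, na.rm = TRUE)
  mcc <- mapply(mcc_score, tp, tn, fp, fn)

  per_gene <- data.frame(gene = genes, cluster = unname(ref),
                         tp = unname(tp), tn = unname(tn),
                         fp = unname(fp), fn = unname(fn),
                         mcc = unname(mcc), stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(avg_mcc = per_gene$mcc),
                          by = list(cluster = per_gene$cluster), FUN = mean)
  sizes <- stats::aggregate(list(n_genes = per_gene$mcc),
                            by = list(cluster = per_gene$cluster), FUN = length)
  per_cluster <- merge(sizes, agg, by = "cluster")
  structure(list(per_gene = per_gene, per_cluster = per_cluster,
                 overall = mean(per_cluster$avg_mcc)),
            class = "mcc_report")
}

#' @export
print.mcc_report <- function(x, ...) {
  cat("MCC evaluation over ", nrow(x$per_gene), " genes, ",
      nrow(x$per_cluster), " reference cluster(s)\n", sep = "")
  for (i in seq_len(nrow(x$per_cluster))) {
    cat(sprintf("  %-12s n=%2d  avg MCC = %.3f\n", x$per_cluster$cluster[i],
                x$per_cluster$n_genes[i], x$per_cluster$avg_mcc[i]))
  }
  cat(sprintf("  overall avg MCC = %.3f\n", x$overall))
  invisible(x)
}

.ec_top2 <- function(ec) {
  vapply(strsplit(ec, ".", fixed = TRUE),
         function(z) paste(z[1:2], collapse = "."), "")
}

#' Select noise genes to add to a reference pathway
#'
#' Draws `round-half-up(fraction * pathway size)` genes from the pool
#' (genes outside the pathway). In `"random"` mode the draw is uniform
#' without replacement. In `"ec_matched"` mode each reference cluster
#' receives candidates whose first two Enzyme Commission levels match some
#' member of that cluster (e.g. a 2.6.x.x candidate matches a cluster
#' containing EC 2.6.1.28), with the per-cluster quota proportional to
#' cluster size and the remainder given to the largest cluster.
#'
#' @param reference a [reference_pathway] (EC numbers required for
#'   `"ec_matched"`).
#' @param pool character vector of candidate gene identifiers, disjoint
#'   from the pathway genes.
#' @param pool_ec named character vector gene -> EC number for the pool
#'   (required in `"ec_matched"` mode).
#' @param fraction how many genes to add, relative to pathway size
#'   (default 0.5, i.e. 10 pathway genes gain 5 noise genes).
#' @param mode `"random"` or `"ec_matched"`.
#' @param seed integer seed; the same seed reproduces the same selection.
#' @return character vector of selected noise genes.
#' @export
inject_noise_genes <- function(reference, pool, pool_ec = NULL, fraction = 0.5,
                               mode = c("random", "ec_matched"), seed = 1L) {
  mode <- match.arg(mode)
  if (fraction <= 0) stop("fraction must be positive")
  if (length(intersect(reference$gene, pool))) {
    stop("pool must be disjoint from the reference pathway genes")
  }
  n_add <- floor(fraction * nrow(reference) + 0.5)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  if (mode == "random") {
    if (length(pool) < n_add) {
      stop("pool has ", length(pool), " genes but ", n_add, " are needed (short by ",
           n_add - length(pool), ")")
    }
    return(sample(pool, n_add))
  }

  if (is.null(pool_ec) || any(is.na(reference$ec))) {
    stop("ec_matched mode needs EC numbers for the pool and every reference gene")
  }
  cl_sizes <- table(reference$cluster)
  quota <- floor(n_add * as.numeric(cl_sizes) / nrow(reference))
  names(quota) <- names(cl_sizes)
  rem <- n_add - sum(quota)
  if (rem > 0L) {
    largest <- names(cl_sizes)[which.max(cl_sizes)]
    quota[largest] <- quota[largest] + rem
  }
  chosen <- character()
  for (cl in names(quota)) {
    if (quota[[cl]] == 0L) next
    cl_ec2 <- unique(.ec_top2(reference$ec[reference$cluster == cl]))
    eligible <- setdiff(pool[.ec_top2(pool_ec[pool]) %in% cl_ec2], chosen)
    if (length(eligible) < quota[[cl]]) {
      stop("cluster ", cl, " needs ", quota[[cl]], " EC-matched noise genes but only ",
           length(eligible), " are eligible (short by ", quota[[cl]] - length(eligible), ")")
    }
    chosen <- c(chosen, sample(eligible, quota[[cl]]))
  }
  chosen
}

#' Sample random term pairs, optionally above a Wang-similarity threshold
#'
#' Uniformly samples unordered term pairs within one namespace; when
#' `min_wang_sim` is given, pairs are rejection-sampled until `n` of them
#' have Wang similarity at or above the threshold.
#'
#' @param ontology a [go_ontology].
#' @param n number of pairs wanted.
#' @param namespace namespace to sample in.
#' @param min_wang_sim numeric threshold or `NULL` for plain uniform pairs.
#' @param config configuration for the Wang screening similarity (its
#'   `method` is forced to `"WANG"`).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget (default `200 * n`).
#' @return data.frame with columns `a`, `b` (and `wang_sim` when screened).
#' @export
sample_term_pairs <- function(ontology, n, namespace, min_wang_sim = NULL,
                              config = gogo_config(method = "WANG"), seed = 1L,
                              max_attempts = 200L * n) {
  stopifnot(n >= 1L)
  namespace <- go_namespace(namespace)
  ids <- ontology$terms$id[ontology$terms$namespace == namespace]
  if (length(ids) < 2L) stop("namespace ", namespace, " has fewer than 2 terms")
  config$method <- "WANG"
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  cache <- new_semsim_cache()
  seen <- character()
  a_out <- b_out <- character(); w_out <- numeric()
  attempts <- 0L
  while (length(a_out) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not find ", n, " qualifying pairs in ", max_attempts,
           " attempts (acceptance rate ",
           sprintf("%.3f", length(a_out) / attempts), ")")
    }
    p <- sort(sample(ids, 2L))
    key <- paste(p, collapse = "|")
    if (key %in% seen) next
    if (!is.null(min_wang_sim)) {
      w <- term_similarity(ontology, p[1L], p[2L], config, cache)
      if (w < min_wang_sim) next
      w_out <- c(w_out, w)
    }
    seen <- c(seen, key)
    a_out <- c(a_out, p[1L]); b_out <- c(b_out, p[2L])
  }
  out <- data.frame(a = a_out, b = b_out, stringsAsFactors = FALSE)
  if (!is.null(min_wang_sim)) out$wang_sim <- w_out
  out
}

#' Sample sibling term pairs at a fixed depth
#'
#' Siblings share at least one direct parent; depth is the minimum edge
#' count from the namespace root (root = 0), and both members of a pair
#' must sit at the requested depth.
#'
#' @inheritParams sample_term_pairs
#' @param depth required depth of both terms.
#' @param relations relation subset for parent and depth computation.
#' @return data.frame with columns `a`, `b`.
#' @export
sample_sibling_pairs <- function(ontology, depth, n, namespace,
                                 relations = c("is_a", "part_of"), seed = 1L) {
  stopifnot(depth >= 1L, n >= 1L)
  namespace <- go_namespace(namespace)
  depths <- go_depths(ontology, namespace, relations)
  at_depth <- names(depths)[!is.na(depths) & depths == depth]
  pairs <- list()
  for (t in at_depth) {
    parents <- go_parents(ontology, t, relations)$parent
    for (p in parents) {
      sibs <- go_children(ontology, p, relations)$child
      sibs <- sibs[sibs %in% at_depth & sibs > t]
      for (s2 in sibs) pairs[[paste(t, s2, sep = "|")]] <- c(t, s2)
    }
  }
  if (length(pairs) < n) {
    stop("only ", length(pairs), " sibling pairs available at depth ", depth,
         " (needed ", n, ")")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sel <- sample(length(pairs), n)
  out <- do.call(rbind, pairs[sel])
  data.frame(a = out[, 1L], b = out[, 2L], stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation matrix between similarity methods
#'
#' Evaluates each provider on a shared list of term pairs and correlates
#' the resulting similarity vectors.
#'
#' @param pairs data.frame with columns `a`, `b` (at least 3 rows).
#' @param methods named list of functions `f(a, b) -> similarity`.
#' @return symmetric correlation matrix with unit diagonal; a method with
#'   zero variance over the pairs gets `NA` correlations (with a warning).
#' @export
method_correlation_matrix <- function(pairs, methods) {
  stopifnot(nrow(pairs) >= 3L, length(methods) >= 2L)
  vals <- vapply(methods, function(f) {
    mapply(f, pairs$a, pairs$b, USE.NAMES = FALSE)
  }, numeric(nrow(pairs)))
  sds <- apply(vals, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("method(s) with zero variance over the pairs: ",
            paste(colnames(vals)[sds == 0], collapse = ", "))
  }
  m <- suppressWarnings(stats::cor(vals))
  diag(m) <- 1
  m
}
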