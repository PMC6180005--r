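# High-level runners: parse inputs, compute, write TSV. The command-line
# script in inst/scripts/gogo.R is a thin dispatcher over these, so shell
# runs and library calls produce identical output.

#' Assemble and validate a run configuration
#'
#' @param method `"GOGO"`, `"GOGO_regulates"` (adds the regulates relation)
#'   or `"WANG"`.
#' @param c GOGO edge-weight constant (>= 0.67).
#' @param strategy gene-level mixing strategy (default `"ABM"`).
#' @param namespace namespace(s) to compute in; `NULL` means every
#'   namespace present in the ontology.
#' @param ap an [ap_config] for clustering runs.
#' @param seed top-level integer seed; all randomness in a run flows from
#'   it.
#' @return a list with a validated `semsim_config` under `$semsim` plus the
#'   remaining settings.
#' @export
run_config <- function(method = c("GOGO", "GOGO_regulates", "WANG"),
                       c = 0.67, strategy = "ABM", namespace = NULL,
                       ap = ap_config(), seed = 1L) {
  method <- match.arg(method)
  semsim <- switch(method,
    GOGO = gogo_config(method = "GOGO", c = c),
    GOGO_regulates = gogo_config(method = "GOGO", c = c,
                                 relations = c("is_a", "part_of", "regulates")),
    WANG = gogo_config(method = "WANG"))
  strategy <- match.arg(strategy, GENE_SIM_STRATEGIES)
  ap$seed <- as.integer(seed)
  list(semsim = semsim, strategy = strategy, namespace = namespace,
       ap = ap, seed = as.integer(seed))
}

.read_pair_lines <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE),
           use.names = FALSE)
  }
  lines[nzchar(trimws(lines))]
}

#' Compute similarities for a file of term pairs
#'
#' Input: one `GO:XXXXXXX GO:YYYYYYY` pair per line (whitespace- or
#' tab-separated). Output rows carry the full-precision similarity and a
#' 3-decimal display column. Unresolvable terms produce an error row; under
#' `strict` they abort the run instead.
#'
#' @param ontology a [go_ontology].
#' @param pairs_file path to the pair file, or a character vector of lines.
#' @param config a [run_config()].
#' @param out optional path for the TSV output.
#' @param strict abort on the first bad row (default `FALSE`).
#' @return data.frame with columns `a`, `b`, `namespace`, `similarity`,
#'   `display`, `error`.
#' @export
run_term_sim <- function(ontology, pairs_file, config = run_config(),
                         out = NULL, strict = FALSE) {
  lines <- .read_pair_lines(pairs_file)
  cache <- new_semsim_cache()
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    res <- if (length(f) != 2L) {
      simpleError(paste0("line ", i, ": expected two terms"))
    } else {
      tryCatch({
        s <- term_similarity(ontology, f[1L], f[2L], config$semsim, cache)
        ns <- ontology$terms[go_resolve(ontology, f[1L]), "namespace"]
        list(s = s, ns = ns)
      }, error = function(e) e)
    }
    if (inherits(res, "error")) {
      if (strict) stop("term-sim failed at line ", i, ": ", conditionMessage(res))
      rows[[i]] <- data.frame(a = f[1L], b = if (length(f) >= 2L) f[2L] else NA,
                              namespace = NA, similarity = NA_real_,
                              display = NA_character_,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(a = f[1L], b = f[2L], namespace = res$ns,
                              similarity = res$s,
                              display = sprintf("%.3f", res$s),
                              error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  result <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.table(result, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}

#' Pairwise gene functional similarity for a gene annotation file
#'
#' @inheritParams run_term_sim
#' @param annotations a [go_annotations] or a path/lines parseable by
#'   [parse_annotations()].
#' @param genes optional subset of genes (default: all annotated genes).
#' @param out_dir optional directory; one `gene_sim_<ns>.tsv` per
#'   namespace is written there, plus `excluded_<ns>.txt` when genes were
#'   excluded.
#' @return named list per namespace: the similarity matrix (with its
#'   `"excluded"` attribute).
#' @export
run_gene_sim <- function(ontology, annotations, config = run_config(),
                         genes = NULL, out_dir = NULL) {
  if (!inherits(annotations, "go_annotations")) {
    annotations <- parse_annotations(annotations, ontology)
  }
  if (is.null(genes)) genes <- sort(unique(annotations$records$gene))
  nss <- config$namespace
  if (is.null(nss)) nss <- sort(unique(annotations$records$namespace))
  out <- list()
  for (ns in go_namespace(nss)) {
    m <- tryCatch(
      gene_sim_matrix(ontology, annotations, genes, ns, config$strategy,
                      config$semsim),
      error = function(e) e)
    if (inherits(m, "error")) {
      warning("namespace ", ns, ": ", conditionMessage(m))
      next
    }
    out[[ns]] <- m
    if (!is.null(out_dir)) {
      utils::write.table(
        data.frame(gene = rownames(m), as.data.frame(m), check.names = FALSE),
        file.path(out_dir, paste0("gene_sim_", ns, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(attr(m, "excluded"))) {
        writeLines(attr(m, "excluded"),
                   file.path(out_dir, paste0("excluded_", ns, ".txt")))
      }
    }
  }
  if (length(out) == 0L) stop("no namespace yielded a gene similarity matrix")
  out
}

#' Cluster genes and, when a reference is given, score the clustering
#'
#' @inheritParams run_gene_sim
#' @param namespace single namespace to cluster in (defaults to the first
#'   configured or available one).
#' @param reference optional [reference_pathway] (or TSV path) of true
#'   clusters; triggers MCC evaluation.
#' @param noise_fraction optional fraction of noise genes to inject from
#'   the annotated genes outside the reference.
#' @param noise_mode `"random"` or `"ec_matched"` (needs `pool_ec`).
#' @param pool_ec named EC vector for the pool in EC-matched mode.
#' @param out_dir optional directory for `clusters.tsv` and
#'   `mcc_per_gene.tsv`.
#' @return list with `similarity`, `clustering`, and (when a reference is
#'   supplied) `noise_genes` and `mcc`.
#' @export
run_cluster <- function(ontology, annotations, config = run_config(),
                        namespace = NULL, reference = NULL,
                        noise_fraction = NULL, noise_mode = "random",
                        pool_ec = NULL, out_dir = NULL) {
  if (!inherits(annotations, "go_annotations")) {
    annotations <- parse_annotations(annotations, ontology)
  }
  if (is.character(reference)) reference <- read_reference_pathway(reference)
  if (is.null(namespace)) {
    namespace <- if (!is.null(config$namespace)) config$namespace[1L] else
      sort(unique(annotations$records$namespace))[1L]
  }
  genes <- if (!is.null(reference)) reference$gene else
    sort(unique(annotations$records$gene))

  noise <- character()
  if (!is.null(reference) && !is.null(noise_fraction)) {
    pool <- setdiff(sort(unique(annotations$records$gene)), reference$gene)
    if (length(pool) == 0L) stop("no annotated genes outside the reference to draw noise from")
    noise <- inject_noise_genes(reference, pool, pool_ec = pool_ec,
                                fraction = noise_fraction, mode = noise_mode,
                                seed = config$seed)
    genes <- c(genes, noise)
  }

  m <- gene_sim_matrix(ontology, annotations, genes, namespace,
                       config$strategy, config$semsim)
  cl <- affinity_propagation(m, config$ap)
  res <- list(similarity = m, clustering = cl)
  if (!is.null(reference)) {
    kept <- rownames(m)
    ref_kept <- reference[reference$gene %in% kept, , drop = FALSE]
    res$noise_genes <- intersect(noise, kept)
    res$mcc <- evaluate_clustering(cl, ref_kept, res$noise_genes)
  }
  if (!is.null(out_dir)) {
    df <- as.data.frame(cl)
    utils::write.table(df, file.path(out_dir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(res$mcc)) {
      utils::write.table(res$mcc$per_gene, file.path(out_dir, "mcc_per_gene.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (requireNamespace("jsonlite", quietly = TRUE)) {
        jsonlite::write_json(
          list(overall = res$mcc$overall, per_cluster = res$mcc$per_cluster,
               converged = cl$converged, n_noise = length(res$noise_genes)),
          file.path(out_dir, "mcc_summary.json"), auto_unbox = TRUE, digits = NA)
      }
    }
  }
  res
}
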