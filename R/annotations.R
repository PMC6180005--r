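# Gene -> GO term annotation sets, read from GAF 2.x or a simple TSV
# dialect (gene<TAB>GO:ID;GO:ID;...[<TAB>evidence]).

#' Experimental evidence codes
#'
#' The evidence codes commonly used to keep only experimentally supported
#' annotations: EXP, IDA, IPI, IMP, IGI, IEP.
#' @export
EXPERIMENTAL_EVIDENCE <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

.GAF_ASPECT <- c(P = "BPO", F = "MFO", C = "CCO")

#' Construct an annotation set
#'
#' @param records data.frame with columns `gene`, `term`, `evidence`,
#'   `namespace`; terms must be primary identifiers of `ontology`.
#' @param ontology the companion [go_ontology].
#' @param evidence_filter the evidence-code filter that produced the records
#'   (empty means unfiltered).
#' @param n_unknown_dropped number of rows dropped because their term did not
#'   resolve in the ontology.
#' @return an object of class `go_annotations`.
#' @export
go_annotations <- function(records, ontology, evidence_filter = character(),
                           n_unknown_dropped = 0L) {
  stopifnot(is.data.frame(records),
            all(c("gene", "term", "evidence", "namespace") %in% names(records)))
  bad <- setdiff(unique(records$term), ontology$terms$id)
  if (length(bad)) {
    stop("annotation term(s) are not primary terms of the ontology: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  records <- unique(records)
  rownames(records) <- NULL
  structure(list(records = records,
                 evidence_filter = evidence_filter,
                 n_unknown_dropped = n_unknown_dropped),
            class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat("GO annotation set\n")
  cat("  genes:       ", length(unique(x$records$gene)), "\n", sep = "")
  cat("  annotations: ", nrow(x$records), "\n", sep = "")
  if (length(x$evidence_filter)) {
    cat("  evidence:    ", paste(x$evidence_filter, collapse = ", "), "\n", sep = "")
  }
  if (x$n_unknown_dropped > 0L) {
    cat("  dropped (unknown terms): ", x$n_unknown_dropped, "\n", sep = "")
  }
  invisible(x)
}

#' Read gene annotations from GAF 2.x or simple TSV
#'
#' GAF rows with a `NOT` qualifier are dropped, evidence codes outside
#' `evidence_filter` are dropped (an empty filter keeps everything), and
#' rows whose GO identifier does not resolve — directly or through an
#' alternative identifier — are dropped with a warning giving the count.
#'
#' @param source path to the annotation file, or a character vector of lines.
#' @param ontology a [go_ontology] used to resolve and namespace the terms.
#' @param evidence_filter character vector of allowed evidence codes, e.g.
#'   [EXPERIMENTAL_EVIDENCE]; empty keeps all rows.
#' @param format `"auto"` (sniff GAF by its `!gaf-version` header or column
#'   count), `"gaf"`, or `"tsv"`.
#' @param gaf_gene_column which GAF column names the gene: the DB object
#'   symbol (default, e.g. SGD gene names) or the DB object id.
#' @return a [go_annotations].
#' @export
parse_annotations <- function(source, ontology, evidence_filter = character(),
                              format = c("auto", "gaf", "tsv"),
                              gaf_gene_column = c("symbol", "id")) {
  format <- match.arg(format)
  gaf_gene_column <- match.arg(gaf_gene_column)
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE),
           use.names = FALSE)
  }
  is_comment <- startsWith(lines, "!")
  if (format == "auto") {
    format <- if (any(grepl("^!gaf-version", lines))) "gaf" else {
      first <- lines[!is_comment & nzchar(lines)][1L]
      if (!is.na(first) && length(strsplit(first, "\t", fixed = TRUE)[[1L]]) >= 15L)
        "gaf" else "tsv"
    }
  }
  body_idx <- which(!is_comment & nzchar(lines))

  gene <- term <- evidence <- character()
  if (format == "gaf") {
    gcol <- if (gaf_gene_column == "symbol") 3L else 2L
    for (i in body_idx) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 9L) stop("unreadable GAF line ", i, ": expected >= 15 columns")
      quals <- strsplit(f[4L], "|", fixed = TRUE)[[1L]]
      if ("NOT" %in% quals) next
      gene <- c(gene, f[gcol]); term <- c(term, f[5L]); evidence <- c(evidence, f[7L])
    }
  } else {
    for (i in body_idx) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 2L || !nzchar(f[1L])) {
        stop("unreadable annotation line ", i, ": expected gene<TAB>GO:ID;...")
      }
      terms_i <- strsplit(f[2L], ";", fixed = TRUE)[[1L]]
      terms_i <- trimws(terms_i[nzchar(trimws(terms_i))])
      ev <- if (length(f) >= 3L && nzchar(f[3L])) f[3L] else NA_character_
      gene <- c(gene, rep(f[1L], length(terms_i)))
      term <- c(term, terms_i)
      evidence <- c(evidence, rep(ev, length(terms_i)))
    }
  }

  if (length(evidence_filter)) {
    keep <- !is.na(evidence) & evidence %in% evidence_filter
    gene <- gene[keep]; term <- term[keep]; evidence <- evidence[keep]
  }
  resolved <- go_resolve(ontology, term, strict = FALSE)
  n_unknown <- sum(is.na(resolved))
  if (n_unknown > 0L) {
    warning(n_unknown, " annotation row(s) referenced unknown terms and were dropped")
  }
  keep <- !is.na(resolved)
  records <- data.frame(gene = gene[keep], term = resolved[keep],
                        evidence = evidence[keep],
                        namespace = ontology$terms[resolved[keep], "namespace"],
                        stringsAsFactors = FALSE)
  if (nrow(records) == 0L) warning("annotation set is empty after filtering")
  go_annotations(records, ontology, evidence_filter, n_unknown)
}

#' Annotated terms of one gene
#'
#' @param annotations a [go_annotations].
#' @param gene a gene identifier.
#' @param namespace optional namespace restriction (`"BPO"`, `"CCO"`,
#'   `"MFO"`, or a synthetic namespace label).
#' @return character vector of term identifiers (possibly empty).
#' @export
gene_terms <- function(annotations, gene, namespace = NULL) {
  r <- annotations$records
  keep <- r$gene == gene
  if (!is.null(namespace)) keep <- keep & r$namespace == go_namespace(namespace)
  sort(unique(r$term[keep]))
}
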