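# OBO 1.2 flat-file reader and writer.
#
# Only the stanza fields this package needs are interpreted: id, name,
# namespace, alt_id, is_a, relationship, is_obsolete. The regulates
# sub-relations positively_regulates / negatively_regulates are collapsed
# onto a single "regulates" type, matching how a single contribution
# constant is assigned to that relation.

.OBO_SUBRELATIONS <- c(positively_regulates = "regulates",
                       negatively_regulates = "regulates",
                       regulates = "regulates",
                       part_of = "part_of")

#' Parse an OBO 1.2 ontology file
#'
#' Reads a GO release in OBO 1.2 format into a [go_ontology], keeping only
#' the requested relation types. Obsolete terms are excluded from the graph
#' but recorded, and alternative identifiers are kept in a lookup table.
#'
#' @param source path to an OBO file, or a character vector of its lines.
#' @param relations relation subset to keep, from
#'   `c("is_a", "part_of", "regulates")`; `regulates` includes its
#'   positively/negatively sub-relations.
#' @return a validated [go_ontology].
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: biological_process", "is_a: GO:0000001 ! root", "",
#'          "[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process")
#' ont <- parse_obo(obo)
#' go_parents(ont, "GO:0000002")
#' @export
parse_obo <- function(source, relations = c("is_a", "part_of", "regulates")) {
  relations <- match.arg(relations, GO_RELATIONS, several.ok = TRUE)
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE),
           use.names = FALSE)
  }

  stanza_starts <- grep("^\\[", lines)
  header_end <- if (length(stanza_starts)) stanza_starts[1L] - 1L else length(lines)
  release_date <- NA_character_
  for (h in seq_len(header_end)) {
    if (grepl("^data-version:", lines[h])) {
      release_date <- sub("^data-version:\\s*", "", lines[h])
      break
    }
    if (grepl("^date:", lines[h]) && is.na(release_date)) {
      release_date <- sub("^date:\\s*", "", lines[h])
    }
  }

  term_starts <- stanza_starts[lines[stanza_starts] == "[Term]"]
  bounds <- c(stanza_starts, length(lines) + 1L)

  ids <- names <- namespaces <- character()
  obsolete <- character()
  alt_from <- alt_to <- character()
  e_child <- e_parent <- e_rel <- character()

  for (s in term_starts) {
    end <- bounds[which(bounds > s)[1L]] - 1L
    body <- lines[(s + 1L):end]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    colon <- regexpr(": ", body, fixed = TRUE)
    if (any(colon < 0L & nzchar(body))) {
      bad <- which(colon < 0L)[1L]
      stop("malformed OBO line ", s + bad, ": '", body[bad], "'")
    }
    keys <- substr(body, 1L, colon - 1L)
    vals <- substring(body, colon + 2L)

    id <- vals[keys == "id"][1L]
    if (is.na(id)) stop("term stanza starting at line ", s, " has no id")
    if (any(keys == "is_obsolete") && tolower(vals[keys == "is_obsolete"][1L]) == "true") {
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    names <- c(names, if (any(keys == "name")) vals[keys == "name"][1L] else NA_character_)
    namespaces <- c(namespaces,
                    if (any(keys == "namespace")) vals[keys == "namespace"][1L] else NA_character_)

    alts <- vals[keys == "alt_id"]
    alt_from <- c(alt_from, alts)
    alt_to <- c(alt_to, rep(id, length(alts)))

    if ("is_a" %in% relations) {
      isa <- sub("\\s*!.*$", "", vals[keys == "is_a"])
      e_child <- c(e_child, rep(id, length(isa)))
      e_parent <- c(e_parent, isa)
      e_rel <- c(e_rel, rep("is_a", length(isa)))
    }
    rel_lines <- vals[keys == "relationship"]
    if (length(rel_lines)) {
      rel_lines <- sub("\\s*!.*$", "", rel_lines)
      parts <- strsplit(trimws(rel_lines), "\\s+")
      for (p in parts) {
        if (length(p) < 2L) stop("malformed relationship line in stanza for ", id)
        rtype <- .OBO_SUBRELATIONS[p[1L]]
        if (is.na(rtype) || !(rtype %in% relations)) next
        e_child <- c(e_child, id)
        e_parent <- c(e_parent, p[2L])
        e_rel <- c(e_rel, unname(rtype))
      }
    }
  }

  # drop edges whose parent is obsolete or undeclared (defensive for
  # hand-built fixtures; full releases do not produce these)
  keep <- e_parent %in% ids
  if (any(!keep)) {
    unknown <- setdiff(unique(e_parent[!keep]), obsolete)
    if (length(unknown)) {
      stop("edge(s) reference unknown term(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    e_child <- e_child[keep]; e_parent <- e_parent[keep]; e_rel <- e_rel[keep]
  }

  terms <- data.frame(id = ids, name = names, namespace = namespaces,
                      stringsAsFactors = FALSE)
  edges <- unique(data.frame(child = e_child, parent = e_parent, relation = e_rel,
                             stringsAsFactors = FALSE))
  alt_ids <- stats::setNames(alt_to, alt_from)
  alt_ids <- alt_ids[!(names(alt_ids) %in% ids)]
  go_ontology(terms, edges, alt_ids = alt_ids, obsolete = obsolete,
              release_date = release_date, relations = relations)
}

#' Serialise an ontology to OBO 1.2 text
#'
#' Writes the term and typed-edge content of a [go_ontology] as OBO 1.2
#' stanzas; parsing the result back yields an identical graph.
#'
#' @param ontology a [go_ontology].
#' @param path optional file to write to; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`) the character vector
#'   of OBO lines.
#' @export
write_obo <- function(ontology, path = NULL) {
  long_ns <- stats::setNames(names(GO_NAMESPACES), unname(GO_NAMESPACES))
  out <- c("format-version: 1.2")
  if (!is.na(ontology$release_date)) {
    out <- c(out, paste0("data-version: ", ontology$release_date))
  }
  alt_by_primary <- if (length(ontology$alt_ids)) {
    split(names(ontology$alt_ids), unname(ontology$alt_ids))
  } else list()
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$id[i]
    ns <- ontology$terms$namespace[i]
    ns_out <- if (ns %in% names(long_ns)) long_ns[[ns]] else ns
    stanza <- c("", "[Term]", paste0("id: ", id),
                paste0("name: ", ontology$terms$name[i]),
                paste0("namespace: ", ns_out))
    for (a in alt_by_primary[[id]]) stanza <- c(stanza, paste0("alt_id: ", a))
    rows <- ontology$.by_child[[id]]
    for (r in rows) {
      parent <- ontology$edges$parent[r]
      rel <- ontology$edges$relation[r]
      stanza <- c(stanza, if (rel == "is_a") paste0("is_a: ", parent)
                  else paste0("relationship: ", rel, " ", parent))
    }
    out <- c(out, stanza)
  }
  for (ob in ontology$obsolete) {
    out <- c(out, "", "[Term]", paste0("id: ", ob), "is_obsolete: true")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
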