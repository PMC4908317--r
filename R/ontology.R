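#' Construct an ontology DAG
#'
#' A minimal Gene-Ontology-style directed acyclic graph: terms with a
#' namespace (e.g. `C`, `P`, `F`) and child-to-parent edges (`is_a` and
#' `part_of` are treated identically). Validation enforces acyclicity, no
#' cross-namespace edges, and exactly one root (parentless term) per
#' namespace.
#'
#' @param terms data frame with columns `id`, `name`, `namespace`.
#' @param edges data frame with columns `child`, `parent`.
#' @return an object of class `slimppi_go_dag`.
#' @export
go_dag <- function(terms, edges) {
  terms <- as.data.frame(terms)
  edges <- as.data.frame(edges)
  if (anyDuplicated(terms$id)) {
    slimppi_abort("slimppi_duplicate_id", "duplicate term ids")
  }
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing) > 0) {
    slimppi_abort("slimppi_unknown_term",
                  sprintf("edge terms not declared: %s",
                          paste(missing, collapse = ", ")))
  }
  ns <- stats::setNames(terms$namespace, terms$id)
  if (nrow(edges) > 0 && any(ns[edges$child] != ns[edges$parent])) {
    slimppi_abort("slimppi_config_error", "cross-namespace edges are not allowed")
  }
  # Kahn topological check
  indeg <- table(factor(edges$parent, levels = terms$id))
  queue <- terms$id[indeg == 0]
  seen <- 0L
  indeg <- as.list(indeg)
  children_of_parent <- split(edges$child, edges$parent)
  parents_of_child <- split(edges$parent, edges$child)
  while (length(queue) > 0) {
    t <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (p in parents_of_child[[t]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != nrow(terms)) {
    slimppi_abort("slimppi_config_error", "ontology graph contains a cycle")
  }
  has_parent <- terms$id %in% edges$child
  roots <- terms$id[!has_parent]
  root_ns <- ns[roots]
  if (anyDuplicated(root_ns) || !setequal(unique(terms$namespace), root_ns)) {
    slimppi_abort("slimppi_config_error",
                  "each namespace must have exactly one root term")
  }
  structure(list(terms = terms, edges = edges,
                 roots = stats::setNames(roots, root_ns)),
            class = "slimppi_go_dag")
}

#' @export
print.slimppi_go_dag <- function(x, ...) {
  cat(sprintf("ontology DAG: %d terms, %d edges, namespaces: %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(sort(unique(x$terms$namespace)), collapse = ", ")))
  invisible(x)
}

# Per-namespace structural index: ancestor/descendant closures via
# topological sweeps. Terms are small per namespace, so plain R lists are
# adequate.
namespace_index <- function(dag, namespace) {
  ids <- dag$terms$id[dag$terms$namespace == namespace]
  if (length(ids) == 0) {
    slimppi_abort("slimppi_empty_ontology",
                  sprintf("namespace '%s' has no terms", namespace))
  }
  ed <- dag$edges[dag$edges$child %in% ids, , drop = FALSE]
  parents <- split(ed$parent, factor(ed$child, levels = ids))
  children <- split(ed$child, factor(ed$parent, levels = ids))
  # order with all children before their parents
  n_children_left <- lengths(children)
  queue <- ids[n_children_left == 0]
  order_up <- character(0)
  remaining <- as.list(n_children_left)
  parent_count <- lapply(parents, length)
  # count how many children of each parent have been emitted
  emitted <- stats::setNames(rep(0L, length(ids)), ids)
  while (length(queue) > 0) {
    t <- queue[[1]]; queue <- queue[-1]
    order_up <- c(order_up, t)
    for (p in parents[[t]]) {
      emitted[p] <- emitted[p] + 1L
      if (emitted[p] == length(children[[p]])) queue <- c(queue, p)
    }
  }
  desc <- stats::setNames(vector("list", length(ids)), ids)
  for (t in order_up) {
    desc[[t]] <- unique(c(t, unlist(desc[children[[t]]], use.names = FALSE)))
  }
  anc <- stats::setNames(vector("list", length(ids)), ids)
  for (t in rev(order_up)) {
    anc[[t]] <- unique(c(t, unlist(anc[parents[[t]]], use.names = FALSE)))
  }
  list(ids = ids, parents = parents, children = children,
       desc = desc, ancplus = anc, root = unname(dag$roots[namespace]))
}

#' Topological information content of ontology terms
#'
#' The structure-only information content used to partition the ontology:
#' \deqn{ICT(t) = -\ln\big(|\mathrm{desc}(t) \cup \{t\}|\; /\; n\big)}
#' with \eqn{n} the number of terms in the namespace. The root scores 0 and
#' leaves score maximally (\eqn{-\ln(1/n)}).
#'
#' @param dag a `slimppi_go_dag`.
#' @param namespace namespace label.
#' @return named numeric vector over the namespace's terms.
#' @export
topology_information_content <- function(dag, namespace) {
  idx <- namespace_index(dag, namespace)
  n <- length(idx$ids)
  ict <- vapply(idx$ids, function(t) -log(length(idx$desc[[t]]) / n), numeric(1))
  names(ict) <- idx$ids
  ict
}

#' Precomputed index for topologically clustered semantic similarity
#'
#' Builds everything [tcss_similarity()] needs for one namespace and cutoff:
#' the namespace is cut at terms whose topological information content
#' reaches the cutoff (a sub-graph root is such a term whose parents all
#' fall below the cutoff; its sub-graph is the root plus its descendants),
#' leaving a meta-graph of the below-cutoff terms plus the sub-graph roots.
#' Within each graph, annotation-frequency information content
#' \eqn{-\ln(n_t/n_{root})} (true-path propagated protein counts) is
#' normalised by the graph's maximum, so every graph spans `[0, 1]`.
#'
#' @param dag a `slimppi_go_dag`.
#' @param annotations data frame with columns `protein_id`, `term_id`, and
#'   optionally `evidence_code` (used for filtering) and `namespace`
#'   (ignored; the term's DAG namespace governs).
#' @param namespace namespace label.
#' @param cutoff topological-IC cutoff (> 0); the published defaults per
#'   ontology are 2.4 (cellular component), 3.5 (biological process) and
#'   3.3 (molecular function).
#' @param evidence_exclude evidence codes dropped before counting
#'   (default `"IEA"`, electronic annotations).
#' @return an object of class `slimppi_tcss_index`.
#' @export
tcss_index <- function(dag, annotations, namespace, cutoff,
                       evidence_exclude = "IEA") {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    slimppi_abort("slimppi_config_error", "TCSS cutoff must be > 0")
  }
  idx <- namespace_index(dag, namespace)
  ann <- as.data.frame(annotations)
  if (!is.null(ann$evidence_code) && length(evidence_exclude) > 0) {
    ann <- ann[!(ann$evidence_code %in% evidence_exclude), , drop = FALSE]
  }
  ann <- ann[ann$term_id %in% dag$terms$id, c("protein_id", "term_id")]
  unknown <- setdiff(unique(as.data.frame(annotations)$term_id), dag$terms$id)
  if (length(unknown) > 0) {
    slimppi_abort("slimppi_unknown_term",
                  sprintf("annotation terms absent from the DAG: %s",
                          paste(unknown, collapse = ", ")))
  }
  ann <- ann[ann$term_id %in% idx$ids, , drop = FALSE]
  direct <- lapply(split(ann$term_id, ann$protein_id), unique)

  counts <- stats::setNames(rep(0L, length(idx$ids)), idx$ids)
  for (terms_p in direct) {
    prop <- unique(unlist(idx$ancplus[terms_p], use.names = FALSE))
    counts[prop] <- counts[prop] + 1L
  }

  n <- length(idx$ids)
  ict <- vapply(idx$ids, function(t) -log(length(idx$desc[[t]]) / n), numeric(1))
  names(ict) <- idx$ids
  above <- idx$ids[ict >= cutoff]
  sub_roots <- above[vapply(above, function(t) {
    ps <- idx$parents[[t]]
    length(ps) == 0 || all(ict[ps] < cutoff)
  }, logical(1))]
  members <- lapply(sub_roots, function(r) idx$desc[[r]])
  names(members) <- sub_roots
  # term -> sub-graph roots containing it
  membership <- stats::setNames(vector("list", length(idx$ids)), idx$ids)
  for (r in sub_roots) {
    for (t in members[[r]]) membership[[t]] <- c(membership[[t]], r)
  }
  meta_terms <- union(idx$ids[ict < cutoff], sub_roots)

  norm_ica <- function(member_ids, root_id) {
    out <- stats::setNames(rep(NA_real_, length(member_ids)), member_ids)
    root_count <- counts[root_id]
    if (root_count == 0) return(out)
    ok <- member_ids[counts[member_ids] > 0]
    vals <- -log(counts[ok] / root_count)
    mx <- max(vals)
    out[ok] <- if (mx == 0) 0 else vals / mx
    out
  }
  graph_ica <- lapply(sub_roots, function(r) norm_ica(members[[r]], r))
  names(graph_ica) <- sub_roots
  meta_ica <- norm_ica(meta_terms, idx$root)

  structure(list(
    namespace = namespace, cutoff = cutoff, ns = idx,
    ict = ict, counts = counts, direct = direct,
    sub_roots = sub_roots, members = members, membership = membership,
    meta_terms = meta_terms, graph_ica = graph_ica, meta_ica = meta_ica
  ), class = "slimppi_tcss_index")
}

tcss_term_pair <- function(index, s, t) {
  ns <- index$ns
  if (!(s %in% ns$ids) || !(t %in% ns$ids)) {
    slimppi_abort("slimppi_unknown_term",
                  sprintf("term(s) absent from namespace '%s'", index$namespace))
  }
  ca <- intersect(ns$ancplus[[s]], ns$ancplus[[t]])
  shared <- intersect(index$membership[[s]], index$membership[[t]])
  best <- -Inf
  if (length(shared) > 0) {
    for (r in shared) {
      vals <- index$graph_ica[[r]][intersect(ca, index$members[[r]])]
      vals <- vals[!is.na(vals)]
      if (length(vals) > 0) best <- max(best, vals)
    }
  } else {
    vals <- index$meta_ica[intersect(ca, index$meta_terms)]
    vals <- vals[!is.na(vals)]
    if (length(vals) > 0) best <- max(best, vals)
  }
  if (!is.finite(best)) 0 else min(max(best, 0), 1)
}

#' Topologically clustered GO semantic similarity of two proteins
#'
#' Semantic similarity designed for interaction prediction: the most
#' informative common ancestor of each annotated term pair is scored with
#' annotation-frequency information content normalised *within* the
#' ontology sub-graph the pair falls in (see [tcss_index()]); term pairs
#' that share no sub-graph are scored in the meta-graph. The protein-pair
#' score aggregates over all direct annotation term pairs, by maximum
#' (default) or best-match average.
#'
#' Two proteins annotated only to the same minimally-annotated leaf score
#' 1; proteins whose only common ancestor is the namespace root score 0.
#'
#' @param a,b protein identifiers.
#' @param dag,annotations,namespace,cutoff,evidence_exclude used to build
#'   the index when `index` is `NULL`; see [tcss_index()].
#' @param index a prebuilt `slimppi_tcss_index` (recommended when scoring
#'   many pairs).
#' @param aggregate `"max"` (default) or `"bma"` (best-match average).
#' @return similarity in `[0, 1]`.
#' @export
tcss_similarity <- function(a, b, dag = NULL, annotations = NULL,
                            namespace = NULL, cutoff = NULL,
                            evidence_exclude = "IEA", index = NULL,
                            aggregate = c("max", "bma")) {
  aggregate <- match.arg(aggregate)
  if (is.null(index)) {
    index <- tcss_index(dag, annotations, namespace, cutoff, evidence_exclude)
  }
  ta <- index$direct[[a]]
  tb <- index$direct[[b]]
  if (is.null(ta) || length(ta) == 0 || is.null(tb) || length(tb) == 0) {
    missing <- c(a, b)[c(is.null(ta) || length(ta) == 0,
                         is.null(tb) || length(tb) == 0)]
    slimppi_abort("slimppi_missing_annotation",
                  sprintf("protein(s) not annotated in namespace '%s': %s",
                          index$namespace, paste(missing, collapse = ", ")))
  }
  simmat <- matrix(0, length(ta), length(tb))
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      simmat[i, j] <- tcss_term_pair(index, ta[i], tb[j])
    }
  }
  if (aggregate == "max") {
    max(simmat)
  } else {
    (mean(apply(simmat, 1, max)) + mean(apply(simmat, 2, max))) / 2
  }
}

#' Read / write a minimal OBO ontology file
#'
#' Supports the subset of OBO used here: `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a`, and `relationship: part_of` lines (both edge types
#' are treated identically).
#'
#' @param path file path.
#' @return a `slimppi_go_dag`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- list()
  edges <- list()
  cur <- NULL
  flush <- function(cur) {
    if (!is.null(cur) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        id = cur$id, name = cur$name %||% cur$id,
        namespace = cur$namespace %||% "default", stringsAsFactors = FALSE)
      for (p in cur$parents) {
        edges[[length(edges) + 1L]] <<- data.frame(
          child = cur$id, parent = p, stringsAsFactors = FALSE)
      }
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(cur)
      cur <- list(parents = character(0))
    } else if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "namespace:")) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(strsplit(sub("^is_a:", "", ln), "!", fixed = TRUE)[[1]][1])
      cur$parents <- c(cur$parents, tgt)
    } else if (startsWith(ln, "relationship: part_of")) {
      tgt <- trimws(strsplit(sub("^relationship: part_of", "", ln),
                             "!", fixed = TRUE)[[1]][1])
      cur$parents <- c(cur$parents, tgt)
    }
  }
  flush(cur)
  go_dag(do.call(rbind, terms), if (length(edges) > 0) do.call(rbind, edges)
         else data.frame(child = character(0), parent = character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_obo
#' @param dag a `slimppi_go_dag`.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  parents <- split(dag$edges$parent, dag$edges$child)
  for (k in seq_len(nrow(dag$terms))) {
    t <- dag$terms[k, ]
    writeLines(c("", "[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace)), con)
    for (p in parents[[t$id]]) {
      writeLines(sprintf("is_a: %s ! %s", p, p), con)
    }
  }
  invisible(path)
}

#' Read / write protein annotations (GAF-like)
#'
#' Tab-separated columns: `protein_id`, `term_id`, `evidence_code`,
#' `namespace`.
#'
#' @param path file path.
#' @return data frame of annotations.
#' @export
read_annotations <- function(path) {
  utils::read.delim(path, comment.char = "#", header = FALSE,
                    col.names = c("protein_id", "term_id", "evidence_code",
                                  "namespace"),
                    stringsAsFactors = FALSE)
}

#' @rdname read_annotations
#' @param annotations data frame of annotations.
#' @export
write_annotations <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# protein_id\tterm_id\tevidence_code\tnamespace", con)
  writeLines(sprintf("%s\t%s\t%s\t%s", annotations$protein_id,
                     annotations$term_id, annotations$evidence_code,
                     annotations$namespace), con)
  invisible(path)
}
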