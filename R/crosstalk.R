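#' Build the pathway-crosstalk network for a pair of adjacent exams
#'
#' Nodes are the pathways nominally enriched at either exam of the pair.
#' An edge joins two distinct pathways when one is enriched at the first
#' exam, the other at the second (either orientation; undirected semantics),
#' and their member sets share at least one functional gene — sharing only
#' non-functional genes is not crosstalk. An edge is flagged
#' `both_enriched_both_times` when both endpoints are enriched at both exams
#' (the persistent subnetworks). A pathway enriched at both exams appears as
#' a persistent node, not as a self-loop.
#'
#' @param enrich Enrichment table from [enrich_all()], covering (at least)
#'   both exams of `time_pair`; tables from several exams can be
#'   `rbind`-ed.
#' @param db The `"pathway_db"` providing pathway memberships.
#' @param truth_genes Non-empty character vector of functional gene ids (the
#'   sharing currency). For real data without simulation truth, a caller may
#'   pass BH-significant genes instead — a documented fallback, not the
#'   reference behavior.
#' @param time_pair Character vector of two adjacent exam labels, e.g.
#'   `c("T1", "T2")` or `c("T2", "T3")`.
#' @return A list of class `"crosstalk_network"` with `nodes` (data frame:
#'   `pathway_id`, `enriched_at` — comma-joined exam labels over all exams
#'   present in `enrich`, `category` — enrichment pattern within the pair),
#'   `edges` (data frame: `from`, `to`, `time_pair`,
#'   `shared_functional_genes` (comma-joined), `both_enriched_both_times`)
#'   and `time_pair`.
#' @export
build_crosstalk <- function(enrich, db, truth_genes, time_pair) {
  if (length(time_pair) != 2L)
    stop("'time_pair' must name exactly two exams")
  if (!all(time_pair %in% enrich$trait))
    stop("enrichment table lacks exam(s): ",
         paste(setdiff(time_pair, enrich$trait), collapse = ", "))
  if (length(truth_genes) == 0L)
    stop("'truth_genes' must be non-empty")

  enr_at <- function(pw, tr) {
    any(enrich$pathway_id == pw & enrich$trait == tr & enrich$enriched_at_nominal)
  }
  t1 <- time_pair[1]; t2 <- time_pair[2]
  all_tr <- unique(enrich$trait)
  cand <- unique(enrich$pathway_id[enrich$enriched_at_nominal &
                                     enrich$trait %in% time_pair])
  cand <- sort(cand)

  e1 <- vapply(cand, enr_at, TRUE, tr = t1)
  e2 <- vapply(cand, enr_at, TRUE, tr = t2)
  nodes <- data.frame(
    pathway_id = cand,
    enriched_at = vapply(cand, function(pw)
      paste(all_tr[vapply(all_tr, function(tr) enr_at(pw, tr), TRUE)],
            collapse = ","), ""),
    category = ifelse(e1 & e2, "enriched_both",
                      ifelse(e1, paste0("enriched_", t1), paste0("enriched_", t2))),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL

  edges <- data.frame(from = character(), to = character(),
                      time_pair = character(),
                      shared_functional_genes = character(),
                      both_enriched_both_times = logical(),
                      stringsAsFactors = FALSE)
  if (length(cand) >= 2L) {
    pairs <- utils::combn(cand, 2L)
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1, i]; b <- pairs[2, i]
      ## one endpoint enriched at t1, the other at t2, in either orientation
      linked <- (enr_at(a, t1) && enr_at(b, t2)) ||
                (enr_at(b, t1) && enr_at(a, t2))
      if (!linked) next
      shared <- intersect(intersect(db[[a]]$genes, db[[b]]$genes), truth_genes)
      if (length(shared) == 0L) next
      edges <- rbind(edges, data.frame(
        from = a, to = b,
        time_pair = paste(time_pair, collapse = "->"),
        shared_functional_genes = paste(sort(shared), collapse = ","),
        both_enriched_both_times = enr_at(a, t1) && enr_at(a, t2) &&
          enr_at(b, t1) && enr_at(b, t2),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(nodes = nodes, edges = edges, time_pair = time_pair),
            class = "crosstalk_network")
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat(sprintf("Pathway crosstalk network %s: %d node(s), %d edge(s)\n",
              paste(x$time_pair, collapse = "->"), nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    if (nrow(net$edges)) net$edges else
      data.frame(from = character(), to = character()),
    directed = FALSE, vertices = net$nodes)
  igraph::graph_attr(g, "time_pair") <- paste(net$time_pair, collapse = "->")
  g
}

#' Export a crosstalk network to GraphML or SIF
#'
#' GraphML carries all node and edge attributes (loadable by Cytoscape and
#' igraph); SIF carries the topology with the time-pair as the relation
#' label, one edge per line, plus one line per isolated node.
#'
#' @param net A `"crosstalk_network"`.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "crosstalk_network"))
  if (format == "graphml") {
    g <- .as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    rel <- paste(net$time_pair, collapse = "_")
    lines <- character()
    if (nrow(net$edges))
      lines <- sprintf("%s\tcrosstalk_%s\t%s", net$edges$from, rel, net$edges$to)
    isolated <- setdiff(net$nodes$pathway_id, c(net$edges$from, net$edges$to))
    lines <- c(lines, isolated)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a GraphML crosstalk export back into a network object
#'
#' Round-trip companion of [export_network()] for verification and reuse.
#'
#' @param path GraphML file written by [export_network()].
#' @return A `"crosstalk_network"`.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(g, "vertices")
  ed <- igraph::as_data_frame(g, "edges")
  nodes <- data.frame(pathway_id = vd$name,
                      enriched_at = vd$enriched_at,
                      category = vd$category, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  tp <- strsplit(igraph::graph_attr(g, "time_pair"), "->", fixed = TRUE)[[1]]
  if (nrow(ed)) {
    edges <- data.frame(from = ed$from, to = ed$to, time_pair = ed$time_pair,
                        shared_functional_genes = ed$shared_functional_genes,
                        both_enriched_both_times = as.logical(ed$both_enriched_both_times),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        time_pair = character(),
                        shared_functional_genes = character(),
                        both_enriched_both_times = logical(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, time_pair = tp),
            class = "crosstalk_network")
}
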