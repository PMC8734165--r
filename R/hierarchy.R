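#' Concept hierarchy (MeSH-style is-a edges)
#'
#' A set of `(parent, child)` concept-ID edges, where parents are broader
#' (hypernym) concepts. The structure must be acyclic; ancestor queries take
#' the transitive closure of the edges.
#'
#' @param edges Tibble or data frame with columns `parent`, `child`, or `NULL`
#'   for an empty hierarchy.
#'
#' @return A `krc_hierarchy` object.
#' @export
krc_hierarchy <- function(edges = NULL) {
  if (is.null(edges)) edges <- tibble(parent = character(), child = character())
  edges <- distinct(as_tibble(edges)[, c("parent", "child")])
  h <- structure(list(edges = edges), class = "krc_hierarchy")
  if (hierarchy_has_cycle(h)) abort("concept hierarchy contains a cycle")
  h
}

#' @export
print.krc_hierarchy <- function(x, ...) {
  cat(sprintf("<krc_hierarchy> %d edge(s), %d concept(s)\n", nrow(x$edges),
              length(unique(c(x$edges$parent, x$edges$child)))))
  invisible(x)
}

hierarchy_has_cycle <- function(h) {
  edges <- h$edges
  nodes <- unique(c(edges$parent, edges$child))
  while (length(nodes)) {
    sinks <- nodes[!nodes %in% edges$parent]
    if (!length(sinks)) return(TRUE)
    nodes <- setdiff(nodes, sinks)
    edges <- edges[!edges$child %in% sinks, ]
  }
  FALSE
}

#' Transitive ancestors of a concept
#'
#' @param hierarchy A [krc_hierarchy()].
#' @param concept_id A concept ID.
#' @return Character vector of all (transitive) hypernym concept IDs.
#' @export
hierarchy_ancestors <- function(hierarchy, concept_id) {
  stopifnot(inherits(hierarchy, "krc_hierarchy"))
  e <- hierarchy$edges
  anc <- character(0)
  frontier <- concept_id
  while (length(frontier)) {
    parents <- setdiff(unique(e$parent[e$child %in% frontier]), anc)
    anc <- c(anc, parents)
    frontier <- parents
  }
  anc
}
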