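# Optimal minimum spanning network among haplotypes: the union of all
# minimum spanning trees of the complete Hamming-distance graph, so every
# co-minimal ("alternative") connection is retained alongside a backbone MST.

#' Build an optimal minimum spanning haplotype network
#'
#' Computes Hamming distances (mutational steps) between haplotypes on the
#' retained sites and keeps every edge that occurs in at least one minimum
#' spanning tree of the complete graph (a Kruskal sweep over weight classes:
#' an edge belongs to some MST iff its endpoints are in different components
#' of the strictly-lighter subgraph). Edges in every MST are marked as
#' backbone; the rest are flagged as alternative connections. Haplotype
#' frequencies are attached to the nodes for rendering and do not alter the
#' topology.
#'
#' @param table A [collapse_haplotypes()] result with at least 2 haplotypes.
#' @return Object of class `haplotype_network`: `nodes` (data.frame with
#'   haplotype index, total count and per-population counts), `edges`
#'   (data.frame `from`, `to`, `steps`, `alternative`), `mst_weight` (total
#'   weight of any one MST).
#' @examples
#' a <- aligned_sample_set("A", c(x = "AAT", y = "ACT", z = "GCT"))
#' net <- build_msn(collapse_haplotypes(a))
#' net$edges
#' @export
build_msn <- function(table) {
  H <- length(table$haplotypes)
  if (H < 2L) stop("need at least 2 haplotypes")
  hm <- do.call(rbind, strsplit(table$haplotypes, "", fixed = TRUE))
  D <- hap_hamming(hm)

  # Kruskal sweep with a union-find over weight classes
  parent <- seq_len(H)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[pairs]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  edges <- data.frame(from = integer(0), to = integer(0), steps = numeric(0),
                      alternative = logical(0))
  mst_weight <- 0
  for (wc in unique(w)) {
    in_class <- which(w == wc)
    cand <- integer(0)
    roots <- matrix(0L, 0L, 2L)
    for (k in in_class) {
      ri <- find(pairs[k, 1L]); rj <- find(pairs[k, 2L])
      if (ri != rj) {
        cand <- c(cand, k)
        roots <- rbind(roots, c(min(ri, rj), max(ri, rj)))
      }
    }
    if (length(cand) == 0L) next
    # mandatory (in every MST) iff the edge is a bridge in the multigraph of
    # contracted components; with igraph, bridges() on the component graph
    comp_ids <- unique(as.vector(roots))
    g <- igraph::graph_from_edgelist(
      matrix(match(as.vector(roots), comp_ids), ncol = 2L), directed = FALSE)
    br <- igraph::bridges(g)
    mandatory <- rep(FALSE, length(cand))
    mandatory[as.integer(br)] <- TRUE
    # count one MST's contribution: number of component merges this class
    n_merge <- 0L
    for (m in seq_along(cand)) {
      k <- cand[m]
      ri <- find(pairs[k, 1L]); rj <- find(pairs[k, 2L])
      if (ri != rj) { parent[ri] <- rj; n_merge <- n_merge + 1L }
      edges <- rbind(edges, data.frame(from = pairs[k, 1L], to = pairs[k, 2L],
                                       steps = wc,
                                       alternative = !mandatory[m]))
    }
    mst_weight <- mst_weight + n_merge * wc
  }
  nodes <- data.frame(haplotype = seq_len(H),
                      total = rowSums(table$counts))
  nodes <- cbind(nodes, as.data.frame(table$counts))
  structure(list(nodes = nodes, edges = edges, mst_weight = mst_weight,
                 haplotypes = table$haplotypes),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Haplotype network: ", nrow(x$nodes), " haplotypes, ",
      nrow(x$edges), " edges (", sum(x$edges$alternative),
      " alternative); MST weight ", x$mst_weight, "\n", sep = "")
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#'
#' @param net A [build_msn()] result.
#' @return An undirected `igraph` graph with `steps`/`alternative` edge
#'   attributes and `total` node counts (for export, e.g. with
#'   `igraph::write_graph(g, file, format = "graphml")`).
#' @export
msn_igraph <- function(net) {
  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, c("from", "to")]),
                                   directed = FALSE)
  igraph::E(g)$steps <- net$edges$steps
  igraph::E(g)$alternative <- net$edges$alternative
  igraph::V(g)$total <- net$nodes$total
  g
}

#' Write the network edge list as TSV
#'
#' @param net A [build_msn()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_msn_tsv <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
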