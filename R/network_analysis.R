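# Binary-partition modularity of the hit network vs random and GO-term
# partitions.

asUndirectedGraph <- function(network) {
  if (inherits(network, "HitNetwork")) asIgraph(network) else network
}

#' Generalized modularity of a binary partition
#'
#' Computes `Q = sum_c [ e_c/m - gamma * (d_c/(2m))^2 ]` over the two sets
#' of a binary partition (a node subset and its complement), where `e_c`
#' is the number of intra-set edges, `d_c` the total degree of the set,
#' `m` the edge count and `gamma` the resolution parameter.  This is the
#' standard generalized-modularity definition used by common graph
#' libraries; the implementation delegates to igraph.  Edges are
#' unweighted.
#'
#' @param network a [HitNetwork-class] or an undirected igraph graph.
#' @param node_set character (or vertex-name) vector: the partition's set
#'   S; the complement is taken within the network's nodes.
#' @param resolution resolution gamma (default 0.81).
#' @return numeric Q.
#' @export
modularityScore <- function(network, node_set, resolution = 0.81) {
  g <- asUndirectedGraph(network)
  if (igraph::ecount(g) == 0) stop("modularity undefined: network has no edges")
  nodes <- igraph::V(g)$name
  node_set <- unique(node_set)
  stopifnot(all(node_set %in% nodes))
  if (!length(node_set) || length(node_set) >= length(nodes))
    stop("partition set must be non-empty and proper")
  membership <- ifelse(nodes %in% node_set, 1L, 2L)
  igraph::modularity(g, membership, resolution = resolution)
}

#' Null distribution of Q over random size-matched partitions
#'
#' Draws `n_reps` uniform node subsets of the given size (without
#' replacement within each subset) and returns their modularity scores.
#'
#' @param network a [HitNetwork-class] or igraph graph.
#' @param size subset size (must be < node count).
#' @param n_reps number of random partitions (default 1000).
#' @param seed integer seed.
#' @param resolution resolution gamma.
#' @return numeric vector of `n_reps` Q values.
#' @export
randomPartitionNull <- function(network, size, n_reps = 1000, seed = 1L,
                                resolution = 0.81) {
  g <- asUndirectedGraph(network)
  nodes <- igraph::V(g)$name
  if (size >= length(nodes)) stop("size must be smaller than the node count")
  stopifnot(size >= 1, n_reps >= 1)
  set.seed(seed)
  vapply(seq_len(n_reps), function(i)
    modularityScore(g, sample(nodes, size), resolution = resolution),
    numeric(1))
}

#' Modularity of GO-term-defined partitions
#'
#' One binary partition per term annotated (within the network's nodes) to
#' strictly more than `min_proteins` proteins: the term's annotated
#' proteins vs the rest.
#'
#' @param network a [HitNetwork-class] or igraph graph.
#' @param store a closed [AnnotationStore-class].
#' @param min_proteins strict lower bound on per-term protein count within
#'   the network (default 400, scaled down for small networks).
#' @param resolution resolution gamma.
#' @return named numeric vector, term -> Q (empty if no term qualifies).
#' @export
termPartitions <- function(network, store, min_proteins = 400,
                           resolution = 0.81) {
  g <- asUndirectedGraph(network)
  nodes <- igraph::V(g)$name
  a <- store@assignments
  a <- a[a$protein_id %in% nodes, c("protein_id", "term_id")]
  a <- unique(a)
  counts <- table(a$term_id)
  terms <- names(counts)[counts > min_proteins & counts < length(nodes)]
  if (!length(terms)) {
    message("no term qualifies for partitioning")
    return(setNames(numeric(), character()))
  }
  vapply(terms, function(t)
    modularityScore(g, a$protein_id[a$term_id == t], resolution = resolution),
    numeric(1))
}
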