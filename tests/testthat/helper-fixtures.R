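# Small in-code fixtures shared across test files.

# diamond DAG: root -> X -> Z, root -> Y -> W -> Z; depth(Z) = 3
diamondGraph <- function() {
  puffin:::makeOntologyGraph(
    term_ids = c("root", "X", "Y", "W", "Z"),
    namespace = c(root = "biological_process", X = "biological_process",
                  Y = "biological_process", W = "biological_process",
                  Z = "biological_process"),
    parent_list = list(root = character(), X = "root", Y = "root",
                       W = "Y", Z = c("X", "W")))
}

# linear chain root -> c1 -> ... -> c<n>
chainGraph <- function(n) {
  ids <- c("root", paste0("c", seq_len(n)))
  ns <- setNames(rep("biological_process", n + 1), ids)
  par <- c(list(root = character()),
           setNames(as.list(ids[-length(ids)]), ids[-1]))
  puffin:::makeOntologyGraph(ids, ns, par)
}

# random single-namespace DAG with <= n terms; term 1 is the root and
# every later term picks parents among earlier terms
randomDag <- function(n, seed) {
  set.seed(seed)
  ids <- paste0("t", seq_len(n))
  par <- list(t1 = character())
  for (i in 2:n) {
    k <- sample(min(i - 1, 2), 1)
    par[[ids[i]]] <- sample(ids[seq_len(i - 1)], k)
  }
  puffin:::makeOntologyGraph(ids, setNames(rep("biological_process", n), ids),
                             par)
}

# independent depth oracle: enumerate the lengths of ALL root-to-term
# paths by walking every parent chain, and take the maximum
allPathLengths <- function(graph, term) {
  p <- graph@parents[[term]]
  if (!length(p)) return(0L)
  unlist(lapply(p, function(q) 1L + allPathLengths(graph, q)))
}

# independent closure oracle: breadth-first reachability over parents
reachAncestors <- function(graph, terms) {
  seen <- character()
  frontier <- terms
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(graph@parents[frontier])), seen)
  }
  seen
}

# a small annotation store on the diamond graph
diamondStore <- function(graph = diamondGraph()) {
  closeStore(newAnnotationStore(data.frame(
    protein_id = c("p1", "p2", "p3"),
    term_id = c("Z", "X", "root"))), graph)
}

# two disjoint triangles: Q of the triangle partition is 1 - 0.5 * gamma
twoTriangles <- function() {
  new("HitNetwork", nodes = letters[1:6],
      edges = data.frame(
        protein_a = c("a", "b", "a", "d", "e", "d"),
        protein_b = c("b", "c", "c", "e", "f", "f"),
        predicted_depth = 7),
      hitCutoff = 6)
}

# tiny deterministic hit-set fixture: query q with two hits
tinyHitSet <- function() {
  list(query = "q",
       hits = data.frame(hit_id = c("h1", "h2"),
                         tm = c(0.6, 0.8), rmsd = c(2, 1)),
       annotations = list(c("X", "root"), c("X", "Z", "root")))
}

# memoized small strong-preset pipeline run shared by the heavier tests
.puffin_test_cache <- new.env(parent = emptyenv())
smallStrongRun <- function() {
  if (is.null(.puffin_test_cache$run)) {
    sim <- simulateData(syntheticConfig("strong", seed = 42,
                                        n_proteins = 120, n_terms = 120))
    .puffin_test_cache$sim <- sim
    .puffin_test_cache$run <- runPipeline(sim, num_trees = 120, seed = 42)
  }
  list(sim = .puffin_test_cache$sim, run = .puffin_test_cache$run)
}
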