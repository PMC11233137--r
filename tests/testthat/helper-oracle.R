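# Brute-force oracles used by several test files.
#
# The pedigree-tracing oracle reconstructs, independently of the simplify
# algorithm, the reduced marginal tree of a set of samples at any genomic
# position directly from the raw (unsimplified) edge table: it stabs the
# edges at the position to get the full pedigree's parent array, walks each
# sample to its root, marks the nodes that are MRCAs of at least two
# samples, and links each retained node to its nearest retained ancestor.

raw_parent_at <- function(tables, x) {
  e <- tables$edges
  parent <- rep(-1L, nrow(tables$nodes))
  cover <- e$left <= x & e$right > x
  parent[e$child[cover] + 1L] <- e$parent[cover]
  parent
}

path_to_root <- function(parent, u) {
  path <- integer(0)
  while (u >= 0) {
    path <- c(path, u)
    u <- parent[u + 1L]
  }
  path
}

# reduced tree at position x: list(retained = sorted input node ids,
# parent = named map input node -> nearest retained ancestor input id or -1)
oracle_reduced_tree <- function(tables, samples, x) {
  parent <- raw_parent_at(tables, x)
  paths <- lapply(samples, function(s) path_to_root(parent, s))
  times <- tables$nodes$time_gen
  # among common ancestors the MRCA is the youngest (largest birth generation)
  mrcas <- integer(0)
  ns <- length(samples)
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      common <- intersect(paths[[i]], paths[[j]])
      if (length(common) > 0)
        mrcas <- c(mrcas, common[which.max(times[common + 1L])][1])
    }
  }
  retained <- sort(unique(c(samples, mrcas)))
  red_parent <- sapply(retained, function(u) {
    anc <- path_to_root(parent, u)[-1]
    hit <- anc[anc %in% retained]
    if (length(hit) == 0) -1L else hit[1]
  })
  list(retained = retained, parent = stats::setNames(as.integer(red_parent),
                                                     retained))
}

# a random tiny pedigree simulation returning raw tables
random_raw_history <- function(n_ind = 8, n_gen = 5, L = 100, rho = 0.02,
                               seed = NULL) {
  p <- population("p", time = 1, N = n_ind)
  m <- compile_model(p, generation_time = 1, direction = "forward",
                     simulation_length = n_gen - 1)
  run_simulation(m, sequence_length = L, recombination_rate = rho, seed = seed,
                 simplify_interval = 1e9, simplify_output = FALSE)$tables
}

# genotype matrix computed by a slow per-site tree walk in pure R
oracle_genotypes <- function(tables, sample_nodes) {
  sapply(seq_len(nrow(tables$sites)), function(s) {
    x <- tables$sites$pos[s]
    parent <- raw_parent_at(tables, x)
    node <- tables$mutations$node[tables$mutations$site == tables$sites$id[s]]
    vapply(sample_nodes, function(u) {
      as.integer(node %in% path_to_root(parent, u))
    }, 1L)
  })
}
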