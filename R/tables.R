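#' Succinct genealogy tables
#'
#' The primary output of [run_simulation()]: a set of linked tables encoding
#' the correlated genealogies of the sampled genomes along a recombining
#' `[0, L)` genome (positions are 0-based, intervals half-open).
#'
#' * `nodes`: one row per genome copy — `id`, birth generation `time_gen`,
#'   `time` in the user's units, `pop`, owning sampled individual `ind`
#'   (NA otherwise), `sample` flag, location `x`, `y`.
#' * `individuals`: one row per sampled (named) diploid — `id`, `name`,
#'   `pop`, `time`, `x`, `y`, node pair `node1`/`node2`.
#' * `edges`: inheritance intervals `left`, `right`, `parent`, `child`.
#' * `sites` / `mutations`: infinite-sites mutations overlaid on the
#'   genealogy (`A` ancestral, `T` derived; one mutation per site).
#'
#' @name gen_tables
NULL

empty_sites <- function()
  tibble::tibble(id = integer(0), pos = numeric(0), ancestral = character(0))
empty_mutations <- function()
  tibble::tibble(site = integer(0), node = integer(0), derived = character(0))

new_gen_tables <- function(nodes, individuals, edges, sites, mutations, L,
                           direction, generation_time, T0) {
  structure(list(nodes = nodes, individuals = individuals, edges = edges,
                 sites = sites, mutations = mutations, L = L,
                 direction = direction, generation_time = generation_time,
                 T0 = T0),
            class = "gen_tables")
}

#' @export
print.gen_tables <- function(x, ...) {
  cat(sprintf(
    "<genealogy tables> L = %g bp | %d nodes (%d samples), %d edges, %d sites\n",
    x$L, nrow(x$nodes), sum(x$nodes$sample), nrow(x$edges), nrow(x$sites)))
  invisible(x)
}

tables_time_from_gen <- function(tables, gen) {
  if (tables$direction == "forward")
    tables$T0 + (gen - 1) * tables$generation_time
  else
    tables$T0 - (gen - 1) * tables$generation_time
}

resolve_sample_nodes <- function(tables, samples) {
  if (is.character(samples)) {
    i <- match(samples, tables$individuals$name)
    if (anyNA(i))
      stop("unknown individual(s): ",
           paste(samples[is.na(i)], collapse = ", "), call. = FALSE)
    as.integer(rbind(tables$individuals$node1[i], tables$individuals$node2[i]))
  } else {
    samples <- as.integer(samples)
    if (any(samples < 0 | samples >= nrow(tables$nodes)))
      stop("unknown node id in sample set", call. = FALSE)
    samples
  }
}

#' Simplify genealogy tables to a sample set
#'
#' Reduces the tables to the ancestry of the given samples: the output
#' contains exactly those sample nodes (renumbered first, order preserved)
#' plus, per genomic interval, only the ancestors that are most recent
#' common ancestors of at least two samples on that interval; unary
#' ancestors are removed. The marginal trees restricted to the samples are
#' unchanged, and overlaid mutations are carried through (mutations whose
#' lineage is no longer ancestral to any sample are dropped).
#'
#' @param tables A [gen_tables] object.
#' @param samples Individual names (each contributing its two nodes) or
#'   0-based node ids; default: all sample-flagged nodes.
#' @return A simplified [gen_tables] object; the attribute `"node_map"`
#'   gives the 0-based input-to-output node mapping (-1 = dropped).
#' @export
simplify_tables <- function(tables, samples = NULL) {
  sample_nodes <- if (is.null(samples)) {
    as.integer(rbind(tables$individuals$node1, tables$individuals$node2))
  } else resolve_sample_nodes(tables, samples)
  if (length(sample_nodes) == 0) stop("empty sample set", call. = FALSE)

  res <- simplify_cpp(nrow(tables$nodes), tables$nodes$time_gen,
                      tables$edges$left, tables$edges$right,
                      tables$edges$parent, tables$edges$child,
                      sample_nodes, tables$L,
                      tables$mutations$node, tables$sites$pos[tables$mutations$site + 1L])

  inp <- res$node_input + 1L
  old <- tables$nodes[inp, ]
  # individuals kept: those whose two nodes are both among the requested samples
  ind_ids <- tables$individuals$id[tables$individuals$node1 %in% sample_nodes &
                                   tables$individuals$node2 %in% sample_nodes]
  ind <- tables$individuals[tables$individuals$id %in% ind_ids, ]
  ind_newid <- stats::setNames(seq_len(nrow(ind)) - 1L, ind$id)
  map <- res$node_map
  nodes <- tibble::tibble(
    id = seq_along(inp) - 1L,
    time_gen = old$time_gen,
    time = old$time,
    pop = old$pop,
    ind = ifelse(!is.na(old$ind) & old$ind %in% ind_ids,
                 ind_newid[as.character(old$ind)], NA_integer_),
    sample = (seq_along(inp) - 1L) < length(sample_nodes),
    x = old$x, y = old$y)
  ind$node1 <- map[ind$node1 + 1L]
  ind$node2 <- map[ind$node2 + 1L]
  ind$id <- unname(ind_newid[as.character(ind$id)])
  edges <- tibble::tibble(left = res$edge_l, right = res$edge_r,
                          parent = res$edge_parent, child = res$edge_child)
  keep_mut <- res$mut_map >= 0
  mutations <- tables$mutations[keep_mut, ]
  mutations$node <- res$mut_map[keep_mut]
  sites_kept <- sort(unique(mutations$site))
  site_newid <- match(mutations$site, sites_kept) - 1L
  sites <- tables$sites[tables$sites$id %in% sites_kept, ]
  sites$id <- seq_len(nrow(sites)) - 1L
  mutations$site <- site_newid
  ord <- order(sites$pos)
  # sites stay position-sorted (they are already, but renumber defensively)
  sites <- sites[ord, ]
  sites$id <- seq_len(nrow(sites)) - 1L

  out <- new_gen_tables(nodes = nodes, individuals = ind, edges = edges,
                        sites = sites, mutations = mutations, L = tables$L,
                        direction = tables$direction,
                        generation_time = tables$generation_time, T0 = tables$T0)
  attr(out, "node_map") <- res$node_map
  out
}

#' Overlay neutral mutations on a genealogy
#'
#' Drops mutations on each edge with a Poisson count of mean
#' `mu * span_bp * branch_length_generations` and positions uniform on the
#' edge's genomic span (integer base pairs). Collisions with existing sites
#' are redrawn, so every site carries exactly one mutation (infinite-sites
#' approximation); ancestral state is `"A"`, derived `"T"`.
#'
#' @param tables A [gen_tables] object.
#' @param mu Per-bp, per-generation mutation rate.
#' @return The tables with `sites` and `mutations` filled in.
#' @export
overlay_mutations <- function(tables, mu) {
  stopifnot(mu >= 0)
  if (mu == 0 || nrow(tables$edges) == 0) return(tables)
  e <- tables$edges
  span <- e$right - e$left
  blen <- tables$nodes$time_gen[e$child + 1L] - tables$nodes$time_gen[e$parent + 1L]
  counts <- stats::rpois(nrow(e), mu * span * blen)
  tot <- sum(counts)
  if (tot == 0) return(tables)
  edge_of <- rep(seq_len(nrow(e)), counts)
  pos <- floor(stats::runif(tot, e$left[edge_of], e$right[edge_of]))
  taken <- tables$sites$pos
  repeat {
    dup <- duplicated(pos) | pos %in% taken
    if (!any(dup)) break
    pos[dup] <- floor(stats::runif(sum(dup), e$left[edge_of[dup]], e$right[edge_of[dup]]))
  }
  new_sites <- tibble::tibble(id = NA_integer_, pos = pos, ancestral = "A")
  new_muts <- tibble::tibble(site = NA_integer_, node = e$child[edge_of], derived = "T")
  sites <- dplyr::bind_rows(tables$sites, new_sites)
  muts <- dplyr::bind_rows(tables$mutations,
                           dplyr::mutate(new_muts, site = nrow(tables$sites) +
                                           seq_len(nrow(new_muts)) - 1L))
  ord <- order(sites$pos)
  remap <- integer(nrow(sites))
  remap[ord] <- seq_len(nrow(sites)) - 1L
  muts$site <- remap[muts$site + 1L]
  sites <- sites[ord, ]
  sites$id <- seq_len(nrow(sites)) - 1L
  muts <- muts[order(muts$site), ]
  tables$sites <- sites
  tables$mutations <- muts
  tables
}

#' Marginal trees of a genealogy
#'
#' Splits the genome at the sorted distinct edge endpoints and reconstructs
#' one tree per interval (indexed from 1). Each tree is a parent array over
#' the node ids, with -1 marking roots.
#'
#' @param tables A [gen_tables] object.
#' @return List of `marginal_tree` objects with elements `interval`
#'   (`c(left, right)`), `parent` (0-based parent per node, -1 = none) and
#'   `index`.
#' @export
iterate_trees <- function(tables) {
  e <- tables$edges
  bps <- sort(unique(c(0, e$left, e$right, tables$L)))
  n <- nrow(tables$nodes)
  lapply(seq_len(length(bps) - 1), function(i) {
    a <- bps[i]; b <- bps[i + 1]
    parent <- rep(-1L, n)
    cover <- e$left <= a & e$right >= b
    parent[e$child[cover] + 1L] <- e$parent[cover]
    structure(list(interval = c(a, b), parent = parent, index = i),
              class = "marginal_tree")
  })
}

#' @export
print.marginal_tree <- function(x, ...) {
  cat(sprintf("<marginal tree #%d> interval [%g, %g), %d nodes\n",
              x$index, x$interval[1], x$interval[2], sum(x$parent >= 0) + 1))
  invisible(x)
}

#' Serialize genealogy tables to a directory of TSV files
#'
#' Writes `nodes.tsv`, `individuals.tsv`, `edges.tsv`, `sites.tsv`,
#' `mutations.tsv` and a `manifest.yaml` (sequence length, time direction
#' and units) with a stable column order and fixed number formatting, so
#' identical tables always produce byte-identical files.
#'
#' @param tables A [gen_tables] object.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_tables <- function(tables, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  wr <- function(df, f) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
    utils::write.table(df, file.path(path, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(tables$nodes, "nodes.tsv")
  wr(tables$individuals, "individuals.tsv")
  wr(tables$edges, "edges.tsv")
  wr(tables$sites, "sites.tsv")
  wr(tables$mutations, "mutations.tsv")
  yaml::write_yaml(list(format = "popscape-tables-1", L = tables$L,
                        direction = tables$direction,
                        generation_time = tables$generation_time,
                        T0 = tables$T0),
                   file.path(path, "manifest.yaml"))
  invisible(path)
}

#' Load genealogy tables written by [write_tables()]
#' @param path Directory containing the TSV files and manifest.
#' @return A [gen_tables] object.
#' @export
read_tables <- function(path) {
  manifest <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  if (!identical(manifest$format, "popscape-tables-1"))
    stop("'", path, "' does not contain serialized genealogy tables", call. = FALSE)
  rd <- function(f, types) {
    df <- utils::read.table(file.path(path, f), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "", comment.char = "")
    for (nm in names(types)) {
      cast <- switch(types[[nm]], int = as.integer, dbl = as.numeric,
                     chr = as.character, lgl = as.logical)
      df[[nm]] <- cast(df[[nm]])
    }
    tibble::as_tibble(df)
  }
  nodes <- rd("nodes.tsv", list(id = "int", time_gen = "dbl", time = "dbl",
                                pop = "chr", ind = "int", sample = "lgl",
                                x = "dbl", y = "dbl"))
  ind <- rd("individuals.tsv", list(id = "int", name = "chr", pop = "chr",
                                    time = "dbl", x = "dbl", y = "dbl",
                                    node1 = "int", node2 = "int"))
  edges <- rd("edges.tsv", list(left = "dbl", right = "dbl",
                                parent = "int", child = "int"))
  sites <- rd("sites.tsv", list(id = "int", pos = "dbl", ancestral = "chr"))
  muts <- rd("mutations.tsv", list(site = "int", node = "int", derived = "chr"))
  new_gen_tables(nodes = nodes, individuals = ind, edges = edges,
                 sites = sites, mutations = muts,
                 L = manifest$L, direction = manifest$direction,
                 generation_time = manifest$generation_time, T0 = manifest$T0)
}
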