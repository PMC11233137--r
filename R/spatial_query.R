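#' Annotated node table of a genealogy
#'
#' One row per node with its owning individual's name (for sampled nodes),
#' population, time in user units, location and sample flag.
#'
#' @param tables A [gen_tables] object.
#' @return A tibble.
#' @export
nodes_table <- function(tables) {
  nd <- tables$nodes
  nm <- rep(NA_character_, nrow(nd))
  has <- !is.na(nd$ind)
  nm[has] <- tables$individuals$name[nd$ind[has] + 1L]
  tibble::tibble(node_id = nd$id, name = nm, pop = nd$pop, time = nd$time,
                 time_gen = nd$time_gen, x = nd$x, y = nd$y, sample = nd$sample)
}

#' Annotated edge table of a genealogy
#'
#' One row per edge with the genomic interval and both endpoint locations
#' and times, ready for plotting ancestry segments on a map.
#'
#' @param tables A [gen_tables] object.
#' @return A tibble.
#' @export
edges_table <- function(tables) {
  e <- tables$edges
  nd <- tables$nodes
  tibble::tibble(
    parent = e$parent, child = e$child, left = e$left, right = e$right,
    parent_time = nd$time[e$parent + 1L], child_time = nd$time[e$child + 1L],
    parent_x = nd$x[e$parent + 1L], parent_y = nd$y[e$parent + 1L],
    child_x = nd$x[e$child + 1L], child_y = nd$y[e$child + 1L])
}

#' Spatio-temporal ancestry of one sampled individual
#'
#' Walks the inheritance edges transitively up from each of the individual's
#' two sample nodes across all genomic intervals, emitting one record per
#' (ancestor, maximal genomic interval). Only ancestors recorded in the
#' tables appear — after simplification these are marginal-tree MRCAs, so
#' intermediate ancestors along simplified-away edges are unknown.
#'
#' @param tables A [gen_tables] object.
#' @param name Sampled individual name.
#' @return A tibble with one row per ancestry record: focal `name`, `chrom`
#'   (1 or 2), focal node and location, `ancestor` node, genomic interval
#'   `left`/`right`, ancestor `time`, and ancestor location `anc_x`/`anc_y`.
#' @export
ancestors_of <- function(tables, name) {
  i <- match(name, tables$individuals$name)
  if (is.na(i)) stop("unknown individual '", name, "'", call. = FALSE)
  e <- tables$edges
  nd <- tables$nodes
  out <- list()
  for (chrom in 1:2) {
    focal <- if (chrom == 1) tables$individuals$node1[i] else tables$individuals$node2[i]
    # queue of (node, left, right) genome segments to trace upward
    qn <- focal; ql <- 0; qr <- tables$L
    found_n <- integer(0); found_l <- numeric(0); found_r <- numeric(0)
    while (length(qn) > 0) {
      nn <- integer(0); nl <- numeric(0); nr <- numeric(0)
      for (k in seq_along(qn)) {
        hit <- which(e$child == qn[k] & e$right > ql[k] & e$left < qr[k])
        if (length(hit) == 0) next
        l <- pmax(e$left[hit], ql[k]); r <- pmin(e$right[hit], qr[k])
        nn <- c(nn, e$parent[hit]); nl <- c(nl, l); nr <- c(nr, r)
      }
      found_n <- c(found_n, nn); found_l <- c(found_l, nl); found_r <- c(found_r, nr)
      qn <- nn; ql <- nl; qr <- nr
    }
    if (length(found_n) == 0) next
    df <- tibble::tibble(ancestor = found_n, left = found_l, right = found_r)
    df <- dplyr::arrange(df, .data$ancestor, .data$left)
    # merge adjacent intervals of the same ancestor into maximal records
    merged <- dplyr::group_by(df, .data$ancestor)
    merged <- dplyr::mutate(merged,
      brk = cumsum(c(1, (.data$left[-1] > .data$right[-dplyr::n()])[seq_len(dplyr::n() - 1)])))
    merged <- dplyr::summarise(dplyr::group_by(merged, .data$ancestor, .data$brk),
                               left = min(.data$left), right = max(.data$right),
                               .groups = "drop")
    out[[chrom]] <- tibble::tibble(
      name = name, chrom = chrom, focal_node = focal,
      x = nd$x[focal + 1L], y = nd$y[focal + 1L],
      ancestor = merged$ancestor, left = merged$left, right = merged$right,
      time = nd$time[merged$ancestor + 1L],
      anc_x = nd$x[merged$ancestor + 1L], anc_y = nd$y[merged$ancestor + 1L])
  }
  if (length(out) == 0)
    return(tibble::tibble(name = character(0), chrom = integer(0),
                          focal_node = integer(0), x = numeric(0), y = numeric(0),
                          ancestor = integer(0), left = numeric(0),
                          right = numeric(0), time = numeric(0),
                          anc_x = numeric(0), anc_y = numeric(0)))
  dplyr::bind_rows(out)
}

#' Export a marginal tree as Newick text
#'
#' Leaves are labelled `"{name}_1"` / `"{name}_2"` for the two genome copies
#' of each sampled individual (unnamed nodes get `"n{id}"`); branch lengths
#' are in the user's time units. Intervals whose genealogy has several roots
#' yield a forest: one Newick string per root.
#'
#' @param tree A `marginal_tree` from [iterate_trees()].
#' @param tables The [gen_tables] object the tree came from.
#' @return Character vector of Newick strings (typically length 1).
#' @export
to_newick <- function(tree, tables) {
  parent <- tree$parent
  n <- length(parent)
  nd <- tables$nodes
  in_tree <- parent >= 0
  in_tree[parent[in_tree] + 1L] <- TRUE
  children <- split(which(parent >= 0) - 1L, parent[parent >= 0])
  labels <- rep(NA_character_, n)
  has <- !is.na(nd$ind)
  lab12 <- ifelse(nd$id[has] == tables$individuals$node1[nd$ind[has] + 1L], 1L, 2L)
  labels[has] <- sprintf("%s_%d", tables$individuals$name[nd$ind[has] + 1L], lab12)
  labels[is.na(labels)] <- sprintf("n%d", nd$id[is.na(labels)])
  glen <- tables$generation_time

  # guard against cycles in a corrupt parent array
  seen <- logical(n)
  build <- function(u) {
    if (seen[u + 1L]) stop("cyclic parent array in marginal tree", call. = FALSE)
    seen[u + 1L] <<- TRUE
    ch <- children[[as.character(u)]]
    if (is.null(ch) || length(ch) == 0) return(labels[u + 1L])
    sub <- vapply(ch, function(c) {
      blen <- (nd$time_gen[c + 1L] - nd$time_gen[u + 1L]) * glen
      sprintf("%s:%.10g", build(c), blen)
    }, "")
    sprintf("(%s)%s", paste(sub, collapse = ","), labels[u + 1L])
  }
  roots <- which(in_tree & parent < 0) - 1L
  roots <- roots[vapply(as.character(roots), function(r)
    !is.null(children[[r]]), TRUE)]
  if (length(roots) == 0) stop("tree has no internal structure", call. = FALSE)
  vapply(roots, function(r) paste0(build(r), ";"), "")
}
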