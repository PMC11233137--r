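#' @keywords internal
#' @noRd
set_nodes <- function(tables, set) {
  if (length(set) == 0) stop("empty sample set", call. = FALSE)
  resolve_sample_nodes(tables, set)
}

# derived-allele counts per site for each sample set; a single C++ tree sweep
# when the sets are disjoint, one sweep per set otherwise
derived_counts <- function(tables, sets) {
  n <- nrow(tables$nodes)
  if (nrow(tables$sites) == 0)
    return(list(counts = matrix(0L, 0, length(sets)),
                sizes = vapply(sets, function(s) length(set_nodes(tables, s)), 1L)))
  mut_node <- integer(nrow(tables$sites))
  mut_node[tables$mutations$site + 1L] <- tables$mutations$node
  nodes_by_set <- lapply(sets, set_nodes, tables = tables)
  sizes <- unname(lengths(nodes_by_set))
  all_nodes <- unlist(nodes_by_set)
  nocol <- rep(-1L, n)
  if (anyDuplicated(all_nodes) == 0) {
    set_id <- rep(-1L, n)
    for (k in seq_along(nodes_by_set)) set_id[nodes_by_set[[k]] + 1L] <- k - 1L
    res <- site_descent_cpp(n, tables$edges$left, tables$edges$right,
                            tables$edges$parent, tables$edges$child,
                            tables$sites$pos, mut_node,
                            set_id, length(sets), FALSE, nocol, 0L)
    counts <- res$counts
  } else {
    counts <- matrix(0L, nrow(tables$sites), length(sets))
    for (k in seq_along(nodes_by_set)) {
      set_id <- rep(-1L, n)
      set_id[nodes_by_set[[k]] + 1L] <- 0L
      res <- site_descent_cpp(n, tables$edges$left, tables$edges$right,
                              tables$edges$parent, tables$edges$child,
                              tables$sites$pos, mut_node,
                              set_id, 1L, FALSE, nocol, 0L)
      counts[, k] <- res$counts[, 1]
    }
  }
  list(counts = counts, sizes = sizes)
}

#' Nucleotide diversity (mean pairwise difference per site)
#'
#' For each sample set, the mean number of per-site differences over all
#' pairs of its sample genomes, divided by the sequence length.
#'
#' @param tables A [gen_tables] object with overlaid mutations.
#' @param sets A character vector of sampled individual names (one set), or
#'   a named list of such vectors.
#' @return A tibble with columns `set` and `diversity`.
#' @export
diversity <- function(tables, sets) {
  if (!is.list(sets)) sets <- list(set = sets)
  dc <- derived_counts(tables, sets)
  pi_ <- vapply(seq_along(sets), function(k) {
    n <- dc$sizes[k]
    if (n < 2) stop("diversity needs at least 2 sample genomes", call. = FALSE)
    d <- dc$counts[, k]
    sum(2 * d * (n - d) / (n * (n - 1))) / tables$L
  }, 1.0)
  tibble::tibble(set = names(sets), diversity = pi_)
}

#' Pairwise divergence between two sample sets
#'
#' Mean per-site difference over all cross pairs (one genome from each set),
#' divided by the sequence length.
#'
#' @inheritParams diversity
#' @param set1,set2 Character vectors of sampled individual names.
#' @param names Labels for the output (default `"x"`, `"y"`).
#' @return A tibble with columns `x`, `y`, `divergence`.
#' @export
divergence <- function(tables, set1, set2, names = c("x", "y")) {
  if (length(intersect(set1, set2)) > 0)
    warning("sample sets overlap; divergence computed anyway", call. = FALSE)
  dc <- derived_counts(tables, list(a = set1, b = set2))
  n1 <- dc$sizes[1]; n2 <- dc$sizes[2]
  d1 <- dc$counts[, 1]; d2 <- dc$counts[, 2]
  dxy <- sum(d1 * (n2 - d2) + (n1 - d1) * d2) / (n1 * n2) / tables$L
  tibble::tibble(x = names[1], y = names[2], divergence = dxy)
}

#' Patterson's f4 statistic
#'
#' Mean over sites of `(p_A - p_B)(p_C - p_D)` where `p` is the derived
#' allele frequency in each sample set; no bias correction is applied. Zero
#' in expectation under a correct admixture-free population topology.
#'
#' @inheritParams diversity
#' @param A,B,C,D Character vectors of sampled individual names.
#' @return A one-row tibble with column `f4`.
#' @export
f4 <- function(tables, A, B, C, D) {
  dc <- derived_counts(tables, list(A = A, B = B, C = C, D = D))
  if (nrow(dc$counts) == 0) return(tibble::tibble(f4 = 0))
  p <- sweep(dc$counts, 2, dc$sizes, "/")
  tibble::tibble(f4 = mean((p[, 1] - p[, 2]) * (p[, 3] - p[, 4])))
}

#' f4-ratio estimate of an admixture proportion
#'
#' Estimates the ancestry proportion `alpha` that population `X` derives
#' from a source related to `B`, as
#' `alpha = f4(A, O; X, C) / f4(A, O; B, C)`,
#' where `A` is a sister of the source lineage `B`, `C` an unadmixed
#' reference on the recipient side, and `O` an outgroup.
#'
#' @inheritParams diversity
#' @param X,A,B,C,O Character vectors of sampled individual names.
#' @return A one-row tibble with column `alpha`.
#' @export
f4_ratio <- function(tables, X, A, B, C, O) {
  num <- f4(tables, A, O, X, C)$f4
  den <- f4(tables, A, O, B, C)$f4
  if (abs(den) < 1e-12)
    stop("uninformative f4-ratio configuration: denominator f4 is ~0", call. = FALSE)
  tibble::tibble(alpha = num / den)
}

#' Allele frequency spectrum of a sample set
#'
#' Counts of sites by derived-allele count `i` among the `2n` sampled
#' genomes of the set (`i = 1 .. 2n-1`); with `polarised = FALSE` the
#' spectrum is folded (`xi_i + xi_{2n-i}` for `i < n`, `xi_n` kept as is).
#'
#' @inheritParams diversity
#' @param set Character vector of sampled individual names.
#' @param polarised Keep ancestral/derived polarization (default) or fold.
#' @return Named integer vector of counts.
#' @export
afs <- function(tables, set, polarised = TRUE) {
  dc <- derived_counts(tables, list(set = set))
  n2 <- dc$sizes[1]
  d <- dc$counts[, 1]
  xi <- tabulate(d[d > 0 & d < n2], nbins = n2 - 1)
  names(xi) <- seq_len(n2 - 1)
  if (polarised) return(xi)
  half <- floor(n2 / 2)
  folded <- vapply(seq_len(half), function(i)
    if (i == n2 - i) xi[i] else xi[i] + xi[n2 - i], 1L)
  names(folded) <- seq_len(half)
  folded
}

#' Names of the sampled individuals of a population
#'
#' @param tables A [gen_tables] object.
#' @param pop Population name.
#' @return Character vector of individual names, in sampling order.
#' @export
individuals_of <- function(tables, pop) {
  tables$individuals$name[tables$individuals$pop == pop]
}

#' Per-individual expected heterozygosity
#'
#' For each sampled individual, the per-site probability that its two
#' genome copies differ: the number of sites at which the individual is
#' heterozygous, divided by the sequence length. Local mating depresses it,
#' because a spatially structured population makes an individual's two
#' genomes coalesce quickly.
#'
#' @param tables A [gen_tables] object with overlaid mutations.
#' @param individuals Character vector of sampled individual names.
#' @return A tibble with columns `name`, `pop` and `heterozygosity`.
#' @export
heterozygosity <- function(tables, individuals) {
  i <- match(individuals, tables$individuals$name)
  if (anyNA(i))
    stop("unknown individual(s): ",
         paste(individuals[is.na(i)], collapse = ", "), call. = FALSE)
  sub <- simplify_tables(tables, individuals)
  g <- genotype_matrix(sub)
  n <- length(individuals)
  het <- vapply(seq_len(n), function(k)
    sum(g[, 2 * k - 1] != g[, 2 * k]) / tables$L, 1.0)
  tibble::tibble(name = individuals,
                 pop = tables$individuals$pop[i],
                 heterozygosity = het)
}
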