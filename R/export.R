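# 0/1 genotypes per sample node (columns ordered individual-major:
# ind1 node1, ind1 node2, ind2 node1, ...)
genotype_matrix <- function(tables) {
  ind <- tables$individuals
  if (nrow(ind) == 0) stop("no sampled individuals in the tables", call. = FALSE)
  if (anyNA(ind$node1) || anyNA(ind$node2))
    stop("an individual does not have exactly 2 sample nodes", call. = FALSE)
  cols <- as.integer(rbind(ind$node1, ind$node2))
  n <- nrow(tables$nodes)
  col_id <- rep(-1L, n)
  col_id[cols + 1L] <- seq_along(cols) - 1L
  mut_node <- integer(nrow(tables$sites))
  mut_node[tables$mutations$site + 1L] <- tables$mutations$node
  res <- site_descent_cpp(n, tables$edges$left, tables$edges$right,
                          tables$edges$parent, tables$edges$child,
                          tables$sites$pos, mut_node,
                          rep(-1L, n), 0L, TRUE, col_id, length(cols))
  res$geno
}

#' Export genotypes to VCF
#'
#' Writes a VCFv4.2 file with one phased diploid GT column per sampled
#' individual (column header = individual name), chromosome `"1"`, 1-based
#' positions, ancestral state as REF and derived as ALT, sites sorted by
#' position. Output is deterministic given the tables.
#'
#' @param tables A [gen_tables] object with overlaid mutations.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(tables, path) {
  g <- genotype_matrix(tables)
  ind <- tables$individuals
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popscape",
    sprintf("##contig=<ID=1,length=%d>", as.integer(tables$L)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind$name), collapse = "\t"))
  n_ind <- nrow(ind)
  gt <- matrix("", nrow(tables$sites), n_ind)
  for (j in seq_len(n_ind))
    gt[, j] <- sprintf("%d|%d", g[, 2 * j - 1], g[, 2 * j])
  rows <- sprintf("1\t%d\t%s\t%s\t%s\t.\t.\t.\tGT\t%s",
                  as.integer(tables$sites$pos) + 1L,
                  sprintf("site_%d", as.integer(tables$sites$pos) + 1L),
                  tables$sites$ancestral,
                  tables$mutations$derived[order(tables$mutations$site)],
                  apply(gt, 1, paste, collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Export genotypes to EIGENSTRAT
#'
#' Writes `{prefix}.geno` (one line per site, one character per individual:
#' derived-allele count 0/1/2), `{prefix}.snp` (site id, chromosome "1",
#' genetic position 0.0, 1-based physical position, ancestral and derived
#' alleles) and `{prefix}.ind` (name, "U", population label).
#'
#' @param tables A [gen_tables] object with overlaid mutations.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(tables, prefix) {
  g <- genotype_matrix(tables)
  ind <- tables$individuals
  n_ind <- nrow(ind)
  counts <- g[, seq(1, 2 * n_ind, by = 2), drop = FALSE] +
    g[, seq(2, 2 * n_ind, by = 2), drop = FALSE]
  geno_lines <- apply(counts, 1, paste, collapse = "")
  writeLines(geno_lines, paste0(prefix, ".geno"))
  derived <- tables$mutations$derived[order(tables$mutations$site)]
  writeLines(sprintf("site_%d\t1\t0.0\t%d\t%s\t%s",
                     as.integer(tables$sites$pos) + 1L,
                     as.integer(tables$sites$pos) + 1L,
                     tables$sites$ancestral, derived),
             paste0(prefix, ".snp"))
  writeLines(sprintf("%s\tU\t%s", ind$name, ind$pop), paste0(prefix, ".ind"))
  invisible(prefix)
}
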