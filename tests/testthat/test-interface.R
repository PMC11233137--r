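mutated_sim <- function(seed = 2) {
  raw <- random_raw_history(n_ind = 6, n_gen = 6, L = 5000, rho = 0.002,
                            seed = seed)
  set.seed(seed + 500)
  overlay_mutations(simplify_tables(raw), 2e-4)
}

test_that("VCF export follows the v4.2 conventions", {
  tb <- mutated_sim()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(tb, f)
  lines <- readLines(f)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  header <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  expect_identical(header[10:length(header)], tb$individuals$name)
  rows <- read.table(f, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character")
  rows$V2 <- as.integer(rows$V2)
  expect_identical(nrow(rows), nrow(tb$sites))
  expect_true(all(rows$V1 == "1"))
  # POS is 1-based: table position 0 would print as 1
  expect_identical(rows$V2, as.integer(tb$sites$pos) + 1L)
  expect_true(all(diff(rows$V2) > 0))
  expect_true(all(rows$V4 == "A") && all(rows$V5 == "T"))
  expect_true(all(grepl("^[01]\\|[01]$", as.matrix(rows[, 10:ncol(rows)]))))
  # allele counts per site from the VCF equal the AFS recomputed from tables
  gt <- as.matrix(rows[, 10:ncol(rows)])
  ac <- rowSums(matrix(as.integer(unlist(strsplit(gt, "\\|"))),
                       nrow = nrow(gt) * ncol(gt) / 1, byrow = TRUE))
  ac <- vapply(seq_len(nrow(gt)), function(i)
    sum(as.integer(unlist(strsplit(gt[i, ], "\\|")))), 1L)
  xi <- afs(tb, tb$individuals$name)
  n2 <- 2L * nrow(tb$individuals)
  expect_identical(unname(xi), tabulate(ac[ac > 0 & ac < n2], n2 - 1))
})

test_that("EIGENSTRAT export is consistent with the VCF genotypes", {
  tb <- mutated_sim(seed = 4)
  pre <- file.path(withr::local_tempdir(), "panel")
  write_eigenstrat(tb, pre)
  geno <- readLines(paste0(pre, ".geno"))
  snp <- read.table(paste0(pre, ".snp"), stringsAsFactors = FALSE)
  ind <- read.table(paste0(pre, ".ind"), stringsAsFactors = FALSE)
  expect_identical(length(geno), nrow(tb$sites))
  expect_true(all(nchar(geno) == nrow(tb$individuals)))
  expect_identical(ind$V1, tb$individuals$name)
  expect_true(all(ind$V2 == "U"))
  expect_identical(ind$V3, tb$individuals$pop)
  expect_identical(snp$V2, rep(1L, nrow(snp)))
  expect_identical(snp$V4, as.integer(tb$sites$pos) + 1L)
  # geno digits are derived-allele counts 0/1/2; no missing data ever
  digits <- do.call(rbind, lapply(strsplit(geno, ""), as.integer))
  expect_true(all(digits %in% 0:2))
  # cross-format: per-site geno sums equal twice the VCF alt frequencies'
  # numerators (i.e. the VCF allele count)
  f <- withr::local_tempfile()
  write_vcf(tb, f)
  rows <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  gt <- as.matrix(rows[, 10:ncol(rows)])
  ac <- vapply(seq_len(nrow(gt)), function(i)
    sum(as.integer(unlist(strsplit(gt[i, ], "\\|")))), 1L)
  expect_identical(unname(rowSums(digits)), as.numeric(ac))
  # homozygous-derived columns show as "2"
  hom <- which(digits == 2, arr.ind = TRUE)
  if (nrow(hom) > 0) {
    i <- hom[1, 1]; j <- hom[1, 2]
    expect_identical(substr(geno[i], j, j), "2")
  }
})

test_that("the command-line interface drives compile, simulate, stats and export", {
  root <- withr::local_tempdir()
  bundle <- file.path(root, "bundle")
  script <- file.path(root, "model.R")
  writeLines(c(
    "library(popscape)",
    "a <- population('a', time = 1, N = 30)",
    "b <- population('b', time = 10, N = 30, parent = a)",
    "model <- compile_model(list(a, b), generation_time = 1,",
    "                       simulation_length = 29)"), script)
  expect_identical(popscape_cli(c("compile", "--script", script,
                                  "--out", bundle)), 0L)
  expect_true(file.exists(file.path(bundle, "manifest.yaml")))

  # simulate twice with one seed: identical digests; different seed differs
  t1 <- file.path(root, "t1"); t2 <- file.path(root, "t2"); t3 <- file.path(root, "t3")
  args <- function(out, seed)
    c("simulate", "--bundle", bundle, "--sequence-length", "10000",
      "--recombination-rate", "1e-6", "--mutation-rate", "1e-5",
      "--seed", seed, "--out", out)
  expect_identical(popscape_cli(args(t1, "7")), 0L)
  expect_identical(popscape_cli(args(t2, "7")), 0L)
  expect_identical(popscape_cli(args(t3, "8")), 0L)
  for (f in list.files(t1))
    expect_identical(unname(tools::md5sum(file.path(t1, f))),
                     unname(tools::md5sum(file.path(t2, f))))
  expect_false(identical(unname(tools::md5sum(file.path(t1, "edges.tsv"))),
                         unname(tools::md5sum(file.path(t3, "edges.tsv")))))

  # stats to stdout
  out <- capture.output(code <- popscape_cli(c(
    "stats", "--tables", t1, "--stat", "diversity",
    "--sets", "a=a_1,a_2,a_3;b=b_1,b_2,b_3")))
  expect_identical(code, 0L)
  expect_match(out[1], "set\tdiversity")
  expect_identical(length(out), 3L)

  # export
  vcf <- file.path(root, "out.vcf")
  expect_identical(popscape_cli(c("export", "--tables", t1, "--format", "vcf",
                                  "--out", vcf)), 0L)
  expect_identical(readLines(vcf, n = 1), "##fileformat=VCFv4.2")
  nwk <- file.path(root, "out.nwk")
  expect_identical(popscape_cli(c("export", "--tables", t1, "--format", "newick",
                                  "--out", nwk, "--tree", "1")), 0L)
  expect_match(readLines(nwk)[1], ";$")

  # failures: unknown flags, missing files, invalid bundles
  expect_identical(suppressMessages(popscape_cli(c("frobnicate"))), 1L)
  expect_identical(suppressMessages(popscape_cli(c("simulate", "--bundle",
                                                   file.path(root, "nope")))), 1L)
  # an event referring to an unknown population is named in the message
  writeLines(c(
    "library(popscape)",
    "a <- population('a', time = 1, N = 30)",
    "model <- tryCatch(compile_model(list(a), list(resize('ghost', 5, 10)),",
    "  generation_time = 1, direction = 'forward', simulation_length = 20),",
    "  error = function(e) stop(conditionMessage(e)))"), script)
  msgs <- capture.output(code <- popscape_cli(c("compile", "--script", script,
                                                "--out", bundle)),
                         type = "message")
  expect_identical(code, 1L)
  expect_match(paste(msgs, collapse = " "), "ghost")
})

test_that("tidy, glance and autoplot methods expose the result objects", {
  m <- example2_model(competition = 0, N = 20, length = 10, radius = 50,
                      mating = 100, dispersal = 10)
  sim <- run_simulation(m, 1e4, recombination_rate = 1e-6,
                        mutation_rate = 1e-5, seed = 6)
  g <- glance(sim$tables)
  expect_identical(g$samples, 2L * g$individuals)
  expect_identical(g$L, 1e4)
  td <- tidy(sim$tables)
  expect_identical(nrow(td), g$nodes)
  expect_s3_class(tidy(sim), "tbl_df")
  expect_s3_class(glance(sim), "tbl_df")
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(m$world), "ggplot")
  expect_s3_class(plot_map(m), "ggplot")
})
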