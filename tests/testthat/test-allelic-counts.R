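# A tiny hand-built locus: one contig, two genes, three informative SNPs.
tiny_locus <- function() {
  ref <- c(c1 = paste(rep("ACGTT", 40), collapse = ""))  # 200 bp
  inf <- data.frame(contig = "c1", pos = c(20, 30, 120),
                    parent = c("maternal", "maternal", "paternal"),
                    parent_allele = c("G", "C", "A"),
                    other_allele = NA, stringsAsFactors = FALSE)
  inf$other_allele <- substring(ref, inf$pos, inf$pos)
  maternal <- apply_snps(ref, inf[inf$parent == "maternal", ])
  paternal <- apply_snps(ref, inf[inf$parent == "paternal", ])
  models <- data.frame(contig = "c1", start = c(10L, 110L),
                       end = c(60L, 160L), gene_id = c("gA", "gB"))
  list(ref = ref, inf = inf, maternal = maternal, paternal = paternal,
       models = models)
}

test_that("reads are assigned to the single exactly-matching parent", {
  L <- tiny_locus()
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    library_id = "lib1",
    seq = c(substr(L$maternal[[1]], 15, 44),   # covers both maternal SNPs
            substr(L$paternal[[1]], 111, 140), # covers the paternal SNP
            substr(L$ref[[1]], 61, 90),        # no informative SNP
            paste(rep("N", 30), collapse = "")),  # matches nothing
    stringsAsFactors = FALSE)
  asn <- assign_reads(reads, L$maternal, L$paternal, L$inf)
  expect_equal(asn$read_id, c("r1", "r2"))
  expect_equal(asn$parent, c("maternal", "paternal"))
  expect_equal(asn$snps_covered, c("c1:20,c1:30", "c1:120"))
  audit <- attr(asn, "audit")
  expect_equal(unname(audit["assigned"]), 2L)
  expect_equal(unname(audit["matches_both"]), 1L)
  expect_equal(unname(audit["unmatched"]), 1L)
  expect_equal(sum(audit[c("assigned", "matches_both", "ambiguous",
                           "unmatched", "too_long")]), nrow(reads))

  # swapping the genome labels swaps the assignments exactly
  swapped <- assign_reads(reads, L$paternal, L$maternal, L$inf)
  expect_equal(swapped$read_id, asn$read_id)
  expect_equal(swapped$parent, c("paternal", "maternal"))
})

test_that("a read spanning two SNPs of one gene counts once at gene level", {
  L <- tiny_locus()
  reads <- data.frame(
    read_id = c("r1", "r2", "r3"),
    library_id = "lib1",
    seq = c(substr(L$maternal[[1]], 15, 44),  # both SNPs of gA
            substr(L$maternal[[1]], 25, 54),  # SNP c1:30 of gA only
            substr(L$paternal[[1]], 111, 140)),
    stringsAsFactors = FALSE)
  asn <- assign_reads(reads, L$maternal, L$paternal, L$inf)
  ct <- count_by_snp(asn, L$models)
  snp <- ct$snp[order(ct$snp$snp_id), ]
  expect_equal(snp$snp_id, c("c1:120", "c1:20", "c1:30"))
  expect_equal(snp$maternal, c(0L, 1L, 2L))
  expect_equal(snp$paternal, c(1L, 0L, 0L))
  gene <- ct$gene[order(ct$gene$gene_id), ]
  expect_equal(gene$maternal, c(2L, 0L))   # r1 deduplicated within gA
  expect_equal(gene$paternal, c(0L, 1L))
  expect_equal(gene$n_snps, c(2L, 1L))
  # without deduplication the gene totals are the SNP-row sums
  nodedup <- count_by_snp(asn, L$models, dedup = FALSE)
  expect_equal(nodedup$gene$maternal[nodedup$gene$gene_id == "gA"], 3L)

  # empty assignments and intergenic-only SNPs give empty tables
  expect_equal(nrow(count_by_snp(asn[0, ], L$models)$snp), 0)
  intergenic <- data.frame(contig = "c1", start = 190L, end = 200L,
                           gene_id = "gC")
  expect_equal(nrow(count_by_snp(asn, intergenic)$snp), 0)
  # overlapping gene models are rejected
  expect_error(count_by_snp(asn, data.frame(
    contig = "c1", start = c(0L, 20L), end = c(30L, 60L),
    gene_id = c("g1", "g2"))), "overlap")
})

test_that("error-free library assignment matches read-level truth fully", {
  cfg <- sim_config(n_genes = 6, n_families = 1, directions = "initial",
                    workers_per_colony = 4, genome_contig_length = 6000,
                    mean_allelic_depth = 15, seed = 11)
  ss <- simulate_sequences(cfg, make_design(cfg))
  queen <- select_queen_homalt(filter_snps(ss$queen_records))
  drone <- filter_snps(ss$drone_records)
  uq <- unique_snps(queen, drone)
  inf <- rbind(uq$a_unique, uq$b_unique)
  # the decoy records never survive the filter chain
  expect_equal(sort(inf$pos), sort(ss$informative_truth$pos))
  mg <- apply_snps(ss$reference, uq$a_unique)
  pg <- apply_snps(ss$reference, uq$b_unique)
  asn <- assign_reads(ss$reads, mg, pg, inf)
  m <- merge(asn[c("read_id", "parent")],
             ss$read_truth[c("read_id", "parent")], by = "read_id")
  expect_equal(nrow(m), nrow(asn))
  expect_true(all(m$parent.x == m$parent.y))
})

test_that("zero-maternal SNP removal equals a brute-force scan", {
  tab <- data.frame(
    gene_id = "g1",
    snp_id = rep(c("s1", "s2"), each = 3),
    library_id = rep(c("l1", "l2", "l3"), 2),
    maternal = c(3L, 0L, 5L, 2L, 1L, 4L),
    paternal = c(1L, 6L, 2L, 0L, 2L, 1L))
  out <- drop_zero_maternal_snps(tab)
  expect_equal(unique(out$snp_id), "s2")   # s1 hit zero in l2, dropped everywhere
  expect_identical(drop_zero_maternal_snps(out), out)  # idempotent

  sim <- small_sim(n_genes = 25, seed = 77, mean_allelic_depth = 12)
  got <- drop_zero_maternal_snps(sim$counts)
  libs <- unique(sim$counts$library_id)
  ok <- vapply(split(sim$counts, sim$counts$snp_id), function(s)
    sum(s$maternal > 0) == length(libs), TRUE)
  expect_setequal(unique(got$snp_id), names(ok)[ok])
})

test_that("the gene universe needs two SNPs and presence in all crosses", {
  d <- make_design(sim_config(n_genes = 1))
  libs <- d$library_id
  mk_rows <- function(gene, snps, libs)
    expand.grid(snp_id = snps, library_id = libs,
                stringsAsFactors = FALSE) |>
      transform(gene_id = gene, maternal = 2L, paternal = 2L)
  one_snp <- mk_rows("g1", "g1_s1", libs)
  full <- mk_rows("g2", c("g2_s1", "g2_s2", "g2_s3"), libs)
  # g3 is absent from one colony (one family x direction cell)
  drop_libs <- libs[d$colony != d$colony[1]]
  partial <- mk_rows("g3", c("g3_s1", "g3_s2"), drop_libs)
  tab <- rbind(one_snp, full, partial)
  expect_equal(gene_universe(tab, d), "g2")

  # brute-force predicate agreement on a simulated table
  sim <- small_sim(n_genes = 30, seed = 15, mean_allelic_depth = 6)
  uni <- gene_universe(sim$counts, sim$design)
  cell <- paste(sim$design$family, sim$design$direction)
  lib_cell <- setNames(cell, sim$design$library_id)
  expected <- vapply(split(sim$counts, sim$counts$gene_id), function(s) {
    s <- s[s$maternal + s$paternal > 0, ]
    length(unique(s$snp_id)) >= 2 &&
      length(unique(lib_cell[s$library_id])) == 4
  }, TRUE)
  expect_equal(uni, sort(names(expected)[expected]))

  no_cell <- sim$design[sim$design$direction == "initial", ]
  expect_error(gene_universe(sim$counts, no_cell), "cell")
})

test_that("zero paternal totals become one, and only those", {
  gv <- data.frame(gene_id = c("g1", "g2", "g3"), library_id = "l1",
                   maternal = c(40L, 40L, 7L), paternal = c(0L, 7L, 0L))
  out <- substitute_paternal_zero(gv)
  expect_equal(out$paternal, c(1L, 7L, 1L))
  expect_equal(out$maternal, gv$maternal)
  expect_equal(attr(out, "substituted"), c(1L, 3L))

  sim <- small_sim(n_genes = 20, seed = 19, mean_allelic_depth = 8)
  gvs <- aggregate_to_genes(sim$counts)
  subbed <- substitute_paternal_zero(gvs)
  expect_equal(length(attr(subbed, "substituted")),
               sum(gvs$paternal == 0))
})
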