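test_that("the design crosses families, directions, workers and tissues", {
  d <- make_design(sim_config(n_genes = 1))
  expect_equal(nrow(d), 64)
  expect_equal(length(unique(d$colony)), 4)
  # per colony: 4 reproductive (2 dominant + 2 subordinate) and 4 sterile
  # workers, each with a head and an abdomen library
  for (col in unique(d$colony)) {
    dc <- d[d$colony == col, ]
    expect_equal(nrow(dc), 16)
    workers <- dc[!duplicated(dc$worker_id), ]
    expect_equal(as.vector(table(workers$status)[c("reproductive", "sterile")]),
                 c(4L, 4L))
    expect_equal(sort(as.vector(table(workers$worker_type))), c(2L, 2L, 2L, 2L))
    expect_equal(as.vector(table(dc$tissue)), c(8L, 8L))
  }
  # 32 libraries per reproductive state
  expect_equal(as.vector(table(d$status)), c(32L, 32L))

  d1 <- make_design(sim_config(n_genes = 1, n_families = 1,
                               directions = "initial"))
  expect_equal(nrow(d1), 16)
})

test_that("status is a deterministic function of worker type", {
  d <- make_design(sim_config(n_genes = 1))
  expect_true(all(d$status[d$worker_type %in%
                             c("dominant_rep", "subordinate_rep")] ==
                    "reproductive"))
  expect_true(all(d$status[d$worker_type %in% c("nurse", "forager")] ==
                    "sterile"))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(frac_maternal = 0.6, frac_paternal = 0.5),
               "frac")
  expect_error(sim_config(overdispersion_rho = 1), "rho")
  expect_error(sim_config(maternal_prop_imprinted = 1), "prop")
  expect_error(sim_config(n_snps_per_gene = list(mean = 1, min = 2)),
               "min")
})

test_that("identical seed and config reproduce identical artifacts", {
  a <- small_sim(n_genes = 10, seed = 9)
  b <- small_sim(n_genes = 10, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- small_sim(n_genes = 10, seed = 10)
  expect_false(identical(a$counts, c$counts))
})

test_that("counts conserve depth and truth matches the class fractions", {
  sim <- small_sim(n_genes = 60, seed = 4)
  expect_true(all(sim$counts$maternal >= 0 & sim$counts$paternal >= 0))
  # gene totals equal the sum of the multinomially split SNP rows
  gv <- aggregate_to_genes(sim$counts)
  by_gene <- tapply(sim$counts$maternal + sim$counts$paternal,
                    paste(sim$counts$gene_id, sim$counts$library_id), sum)
  expect_equal(as.vector(by_gene[paste(gv$gene_id, gv$library_id)]),
               gv$maternal + gv$paternal)
  expect_equal(sum(sim$truth$true_class == "MATERNAL"), 3)
  expect_equal(sum(sim$truth$true_class == "PATERNAL"), 3)
  # biallelic and lineage genes carry 0.5 under parental coding
  expect_true(all(sim$truth$true_maternal_prop[
    sim$truth$true_class %in% c("BIALLELIC", "LINEAGE_A", "LINEAGE_B")] ==
      0.5))
})

test_that("deep null counts concentrate at one half", {
  cfg <- sim_config(n_genes = 2, frac_maternal = 0, frac_paternal = 0,
                    frac_lineage = 0, overdispersion_rho = 0,
                    mean_allelic_depth = 1e6, nb_dispersion = 0, seed = 2)
  sim <- simulate_allelic_counts(cfg)
  gv <- aggregate_to_genes(sim$counts)
  frac <- sum(gv$maternal) / sum(gv$maternal + gv$paternal)
  expect_lt(abs(frac - 0.5), 0.002)
})

test_that("lineage genes flip their maternal proportion between directions", {
  cfg <- sim_config(n_genes = 40, frac_maternal = 0, frac_paternal = 0,
                    frac_lineage = 0.5, mean_allelic_depth = 400,
                    overdispersion_rho = 0, seed = 31)
  sim <- simulate_allelic_counts(cfg)
  gv <- merge(aggregate_to_genes(sim$counts), sim$design)
  for (cls in c("LINEAGE_A", "LINEAGE_B")) {
    genes <- sim$truth$gene_id[sim$truth$true_class == cls]
    sub <- gv[gv$gene_id %in% genes, ]
    prop <- tapply(sub$maternal / (sub$maternal + sub$paternal),
                   sub$direction, mean)
    expect_true((prop[["initial"]] - 0.5) * (prop[["reciprocal"]] - 0.5) < 0)
    # symmetric magnitude on the logit scale, within Monte Carlo error
    lg <- function(p) log(p / (1 - p))
    expect_lt(abs(lg(prop[["initial"]]) + lg(prop[["reciprocal"]])), 0.15)
  }
})

test_that("imprinted genes recover their true proportion at depth", {
  cfg <- sim_config(n_genes = 30, frac_maternal = 1, frac_paternal = 0,
                    frac_lineage = 0, mean_allelic_depth = 200, seed = 13)
  sim <- simulate_allelic_counts(cfg)
  gv <- aggregate_to_genes(sim$counts)
  grand <- sum(gv$maternal) / sum(gv$maternal + gv$paternal)
  expect_gt(grand, 0.85)
  expect_lt(grand, 0.95)
})

test_that("beta-binomial variance matches the intraclass parameterisation", {
  set.seed(5)
  n <- 400L; rho <- 0.1; p <- 0.5
  draws <- rbetabinom(rep(n, 20000), p, rho)
  ratio <- var(draws) / (n * p * (1 - p))
  expect_lt(abs(ratio - (1 + (n - 1) * rho)) / (1 + (n - 1) * rho), 0.05)
  # rho = 0 reduces to binomial
  draws0 <- rbetabinom(rep(n, 20000), p, 0)
  expect_lt(abs(var(draws0) / (n * p * (1 - p)) - 1), 0.05)
})

test_that("sequence simulation plants recoverable structure", {
  cfg <- sim_config(n_genes = 5, n_families = 1, directions = "initial",
                    workers_per_colony = 4, genome_contig_length = 5000,
                    mean_allelic_depth = 15, seed = 21)
  ss <- simulate_sequences(cfg, make_design(cfg))
  expect_equal(nchar(ss$reference[[1]]), 5000)
  expect_equal(nrow(ss$gene_models), 5)
  # haplotypes differ from the reference exactly at the planted SNPs
  ref <- strsplit(ss$reference[[1]], "")[[1]]
  mat <- strsplit(ss$maternal_haplotype[[1]], "")[[1]]
  expect_equal(which(ref != mat),
               sort(ss$informative_truth$pos[
                 ss$informative_truth$parent == "maternal"]))
  # a read spanning a maternal-unique SNP came from the maternal haplotype
  m_snp <- ss$informative_truth[ss$informative_truth$parent == "maternal", ][1, ]
  rt <- ss$read_truth
  covering <- rt[rt$start <= m_snp$pos &
                   rt$start + cfg$read_length - 1 >= m_snp$pos &
                   rt$parent == "maternal", ]
  expect_gt(nrow(covering), 0)
  rd <- merge(covering[1, ], ss$reads)
  offset <- m_snp$pos - rd$start + 1
  expect_equal(substr(rd$seq, offset, offset), m_snp$alt)
  # contig too short for the requested genes is a configuration error
  expect_error(simulate_sequences(
    sim_config(n_genes = 50, genome_contig_length = 1000)), "contig")
})
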