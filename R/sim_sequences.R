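#' Simulate a sequence-level reciprocal-cross fixture
#'
#' Generates a reference contig, non-overlapping gene models, parental
#' variant records, the two offspring haplotypes and error-free fixed
#' length reads with per-read parent-of-origin truth, so the whole
#' variant-filtering / read-assignment path can be exercised without
#' external data.
#'
#' The queen (mother) is diploid and the drone (father) haploid.  Each
#' genic informative site is carried by exactly one parent
#' (queen hom-alt or drone alt).  Intergenic decoy records are planted to
#' exercise the filter chain: queen heterozygous sites, low-quality and
#' low-coverage calls, and sites shared by both parents — none of which
#' may survive to the informative SNP set.  Reads are drawn uniformly
#' within gene bodies from the maternal or paternal haplotype according to
#' the gene's true class (lineage genes flip with cross direction), so a
#' read's parent of origin is known by construction.
#'
#' @param config A [sim_config()] object; `genome_contig_length` must
#'   accommodate `n_genes` non-overlapping genes of `gene_length` bases.
#' @param design Design table; defaults to [make_design(config)].
#' @return A list of class `"poe_seq_sim"` with elements `reference`
#'   (named character vector), `queen_records`, `drone_records` (SNP
#'   record tables including decoys), `gene_models` (0-based half-open),
#'   `informative_truth` (the genic informative SNPs actually planted),
#'   `maternal_haplotype`, `paternal_haplotype`, `reads` (`read_id`,
#'   `library_id`, `seq`), `read_truth` (`read_id`, `library_id`,
#'   `gene_id`, `parent`, `start` 1-based), `truth` (per-gene classes),
#'   and `design`.
#' @export
simulate_sequences <- function(config, design = make_design(config)) {
  validate_sim_config(config)
  validate_design(design)
  L <- config$genome_contig_length
  glen <- config$gene_length
  rlen <- config$read_length
  if (rlen > glen)
    stop("read_length must not exceed gene_length", call. = FALSE)
  gap <- 50L
  need <- config$n_genes * (glen + gap) + gap
  if (need > L)
    stop("configuration error: contig length ", L, " cannot hold ",
         config$n_genes, " non-overlapping genes of ", glen, " bases",
         call. = FALSE)

  set.seed(gene_seed(config$seed, -2L))
  bases <- c("A", "C", "G", "T")
  ref_chars <- sample(bases, L, replace = TRUE)
  contig <- "contig1"

  # non-overlapping gene placement with a fixed intergenic gap
  starts0 <- gap + (seq_len(config$n_genes) - 1L) * (glen + gap)
  truth <- sim_truth(config)
  gene_models <- data.frame(contig = contig, start = starts0,
                            end = starts0 + glen, gene_id = truth$gene_id,
                            stringsAsFactors = FALSE)

  # genic informative SNPs, each unique to one parent
  snp_rows <- list()
  for (g in seq_len(config$n_genes)) {
    k <- truth$n_snps[g]
    pos <- sort(sample(seq.int(starts0[g] + 1L, starts0[g] + glen), k))
    ref_a <- ref_chars[pos]
    alt_a <- vapply(ref_a, function(b) sample(setdiff(bases, b), 1), "")
    snp_rows[[g]] <- data.frame(
      contig = contig, pos = pos, gene_id = truth$gene_id[g],
      ref = ref_a, alt = alt_a,
      parent = sample(c("maternal", "paternal"), k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  snp_truth <- do.call(rbind, snp_rows)
  rownames(snp_truth) <- NULL

  mk_rec <- function(df, genotype, ploidy, qual = NULL) {
    n <- nrow(df)
    if (n == 0) return(NULL)
    depth <- 8L + stats::rpois(n, 6)
    snp_records(df$contig, df$pos, df$ref, df$alt,
                qual %||% round(runif(n, 30, 60), 1), depth,
                if (genotype == "het") pmax(2L, depth %/% 2L) else depth,
                genotype, ploidy)
  }
  q_inf <- snp_truth[snp_truth$parent == "maternal", , drop = FALSE]
  d_inf <- snp_truth[snp_truth$parent == "paternal", , drop = FALSE]

  # intergenic decoys: shared sites, queen het sites, low-quality calls
  intergenic <- setdiff(seq_len(L), unlist(Map(seq.int, starts0 + 1L,
                                               starts0 + glen)))
  dec_pos <- sample(intergenic, 12L)
  dec <- data.frame(contig = contig, pos = dec_pos,
                    ref = ref_chars[dec_pos],
                    alt = vapply(ref_chars[dec_pos],
                                 function(b) sample(setdiff(bases, b), 1),
                                 ""), stringsAsFactors = FALSE)
  shared <- dec[1:4, ]; het <- dec[5:8, ]; lowq <- dec[9:12, ]

  queen_records <- rbind(
    mk_rec(q_inf, "hom_alt", 2L),
    mk_rec(shared, "hom_alt", 2L),
    mk_rec(het, "het", 2L),
    mk_rec(lowq, "hom_alt", 2L, qual = round(runif(4, 2, 19), 1)))
  drone_records <- rbind(
    mk_rec(d_inf, "hom_alt", 1L),
    mk_rec(shared, "hom_alt", 1L))
  queen_records <- queen_records[order(queen_records$contig,
                                       queen_records$pos), ]
  drone_records <- drone_records[order(drone_records$contig,
                                       drone_records$pos), ]
  rownames(queen_records) <- rownames(drone_records) <- NULL

  reference <- setNames(paste(ref_chars, collapse = ""), contig)
  maternal_hap <- apply_snps(reference,
    data.frame(contig = q_inf$contig, pos = q_inf$pos,
               parent_allele = q_inf$alt, stringsAsFactors = FALSE))
  paternal_hap <- apply_snps(reference,
    data.frame(contig = d_inf$contig, pos = d_inf$pos,
               parent_allele = d_inf$alt, stringsAsFactors = FALSE))

  # error-free reads drawn inside gene bodies from the true haplotype
  reads <- list(); read_truth <- list()
  for (g in seq_len(config$n_genes)) {
    tg <- truth[g, ]
    p <- switch(tg$true_class,
                LINEAGE_A = ifelse(design$direction == "initial",
                                   config$maternal_prop_imprinted,
                                   1 - config$maternal_prop_imprinted),
                LINEAGE_B = ifelse(design$direction == "initial",
                                   1 - config$maternal_prop_imprinted,
                                   config$maternal_prop_imprinted),
                rep(tg$true_maternal_prop, nrow(design)))
    for (i in seq_len(nrow(design))) {
      n_reads <- stats::rpois(1, config$mean_allelic_depth)
      if (n_reads == 0) next
      parent <- ifelse(runif(n_reads) < p[i], "maternal", "paternal")
      start1 <- starts0[g] + 1L +
        sample.int(glen - rlen + 1L, n_reads, replace = TRUE) - 1L
      hap <- ifelse(parent == "maternal", maternal_hap[[contig]],
                    paternal_hap[[contig]])
      seqs <- substring(hap, start1, start1 + rlen - 1L)
      rid <- sprintf("%s_%s_r%04d", design$library_id[i], tg$gene_id,
                     seq_len(n_reads))
      reads[[length(reads) + 1L]] <- data.frame(
        read_id = rid, library_id = design$library_id[i], seq = seqs,
        stringsAsFactors = FALSE)
      read_truth[[length(read_truth) + 1L]] <- data.frame(
        read_id = rid, library_id = design$library_id[i],
        gene_id = tg$gene_id, parent = parent, start = start1,
        stringsAsFactors = FALSE)
    }
  }

  res <- list(reference = reference, queen_records = queen_records,
              drone_records = drone_records, gene_models = gene_models,
              informative_truth = snp_truth,
              maternal_haplotype = maternal_hap,
              paternal_haplotype = paternal_hap,
              reads = do.call(rbind, reads),
              read_truth = do.call(rbind, read_truth),
              truth = truth, design = design)
  class(res) <- "poe_seq_sim"
  res
}

#' @method print poe_seq_sim
#' @export
print.poe_seq_sim <- function(x, ...) {
  cat("Sequence-level reciprocal-cross fixture\n")
  cat(sprintf("  contig of %d bp; %d genes; %d informative SNPs; %d reads\n",
              nchar(x$reference[[1]]), nrow(x$gene_models),
              nrow(x$informative_truth),
              if (is.null(x$reads)) 0L else nrow(x$reads)))
  invisible(x)
}
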