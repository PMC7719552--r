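#' Pipeline run configuration
#'
#' Bundles a simulation config (or paths to user-supplied inputs) with
#' every stage threshold.  Defaults are the analysis constants of the
#' reciprocal-cross study: POE calls at q < 0.05 with proportion > 0.6 /
#' < 0.4, SNP filters of quality 20, coverage 5 and 2 alternate
#' observations, a minimum of 2 SNPs per gene, DE at q < 0.01 with a
#' 10-count floor, GO enrichment at q < 0.05 and RBH orthologs at
#' e-value <= 1e-3.  Thresholds are validated before any computation.
#'
#' @param sim A [sim_config()] for synthetic runs, or `NULL` when
#'   `counts`/`design` paths are given.
#' @param counts,design Optional paths to a SNP-level count TSV and a
#'   design TSV for user data.
#' @param read_level Run the sequence-level path (simulate reads, filter
#'   variants, build alternate genomes, assign reads) instead of
#'   consuming count-level draws directly.
#' @param q_poe,prop_hi,prop_lo,q_de,q_go Stage significance thresholds.
#' @param min_snps,snp_qual,snp_depth,alt_obs,de_min_total,rbh_evalue
#'   Stage filter constants.
#' @param seed Optional override of the simulation seed.
#' @param out_dir Output directory for tables and the run summary.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(), counts = NULL, design = NULL,
                       read_level = FALSE, q_poe = 0.05, prop_hi = 0.6,
                       prop_lo = 0.4, q_de = 0.01, q_go = 0.05,
                       min_snps = 2, snp_qual = 20, snp_depth = 5,
                       alt_obs = 2, de_min_total = 10, rbh_evalue = 1e-3,
                       seed = NULL, out_dir = tempfile("poeseq_run_")) {
  cfg <- list(sim = sim, counts = counts, design = design,
              read_level = isTRUE(read_level), q_poe = q_poe,
              prop_hi = prop_hi, prop_lo = prop_lo, q_de = q_de,
              q_go = q_go, min_snps = min_snps, snp_qual = snp_qual,
              snp_depth = snp_depth, alt_obs = alt_obs,
              de_min_total = de_min_total, rbh_evalue = rbh_evalue,
              seed = seed, out_dir = out_dir)
  for (th in c("q_poe", "q_de", "q_go")) {
    v <- cfg[[th]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop("validation error: ", th, " must lie in (0, 1]", call. = FALSE)
  }
  if (!(cfg$prop_lo < 0.5 && 0.5 < cfg$prop_hi && cfg$prop_hi <= 1 &&
        cfg$prop_lo >= 0))
    stop("validation error: need 0 <= prop_lo < 0.5 < prop_hi <= 1",
         call. = FALSE)
  for (th in c("min_snps", "snp_qual", "snp_depth", "alt_obs",
               "de_min_total", "rbh_evalue"))
    if (cfg[[th]] < 0)
      stop("validation error: ", th, " must be non-negative",
           call. = FALSE)
  if (is.null(sim) && (is.null(counts) || is.null(design)))
    stop("supply either a sim config or counts + design paths",
         call. = FALSE)
  if (!is.null(sim)) {
    validate_sim_config(sim)
    if (!is.null(seed)) cfg$sim$seed <- as.integer(seed)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full parent-of-origin analysis pipeline
#'
#' Executes every stage in order — simulation (count- or read-level),
#' variant filtering and alternate-genome construction, read assignment
#' and counting (read-level path), the universe and count filters, the
#' per-status POE model, per-tissue differential expression, and the
#' downstream set statistics — and writes all tables plus a
#' machine-readable JSON summary to `config$out_dir`.  When the input is
#' synthetic, truth-recovery metrics (per-class sensitivity, false
#' discovery among parent calls) are included.  With a fixed seed the
#' summary is byte-identical across runs.
#'
#' The zero-maternal SNP guard is applied on the read-level path, where
#' a miscalled queen genotype can masquerade as paternal signal; the
#' count-level simulator draws counts directly from known genotypes, so
#' the guard is skipped there (at desk-scale depth it would mostly
#' remove genuinely paternal-biased genes).
#'
#' @param config A [run_config()].
#' @return (Invisibly) the summary list, of class `"poe_run"`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    cfg <- config$sim
    design <- make_design(cfg)
    if (config$read_level) {
      seq_sim <- stage("simulate", simulate_sequences(cfg, design))
      queen <- stage("variant_prep", select_queen_homalt(
        filter_snps(seq_sim$queen_records, config$snp_qual,
                    config$snp_depth, config$alt_obs)))
      drone <- stage("variant_prep", filter_snps(
        seq_sim$drone_records, config$snp_qual, config$snp_depth,
        config$alt_obs))
      uq <- stage("variant_prep", unique_snps(queen, drone))
      informative <- rbind(uq$a_unique, uq$b_unique)
      m_genome <- stage("variant_prep",
                        apply_snps(seq_sim$reference, uq$a_unique))
      p_genome <- stage("variant_prep",
                        apply_snps(seq_sim$reference, uq$b_unique))
      assignments <- stage("allelic_counts", assign_reads(
        seq_sim$reads, m_genome, p_genome, informative))
      counted <- stage("allelic_counts",
                       count_by_snp(assignments, seq_sim$gene_models))
      snp_table <- stage("allelic_counts",
                         drop_zero_maternal_snps(counted$snp,
                                                 design$library_id))
      truth <- seq_sim$truth
    } else {
      sim <- stage("simulate", simulate_allelic_counts(cfg, design))
      snp_table <- sim$counts
      truth <- sim$truth
    }
  } else {
    snp_table <- stage("load", read_tsv_table(config$counts))
    design <- stage("load", read_tsv_table(config$design))
  }
  validate_design(design)

  universe <- stage("allelic_counts",
                    gene_universe(snp_table, design, config$min_snps))
  gv <- stage("allelic_counts", substitute_paternal_zero(
    aggregate_to_genes(snp_table[snp_table$gene_id %in% universe, ,
                                 drop = FALSE])))

  fits <- list()
  for (st in c("reproductive", "sterile")) {
    fits[[st]] <- stage("poe_inference", poe(
      gv, design, status = st, q_thresh = config$q_poe,
      prop_hi = config$prop_hi, prop_lo = config$prop_lo))
    write_tsv_table(fits[[st]]$calls,
                    file.path(out_dir, paste0("poe_", st, ".tsv")))
  }

  # total allelic depth as the expression proxy for the DE stage
  expr <- stage("diffexpr", {
    gvall <- aggregate_to_genes(snp_table)
    libs <- design$library_id
    m <- matrix(0L, length(unique(gvall$gene_id)), length(libs),
                dimnames = list(sort(unique(gvall$gene_id)), libs))
    m[cbind(gvall$gene_id, gvall$library_id)] <-
      gvall$maternal + gvall$paternal
    m
  })
  de <- list()
  for (t in unique(design$tissue)) {
    sel <- design$tissue == t
    de[[t]] <- stage("diffexpr", de_test(
      expr[, design$library_id[sel], drop = FALSE], design[sel, ],
      min_total = config$de_min_total, q_thresh = config$q_de))
    write_tsv_table(de[[t]], file.path(out_dir, paste0("de_", t, ".tsv")))
  }

  summary <- stage("set_stats",
                   run_summary(fits, de, universe, truth, config))
  write_tsv_table(snp_table, file.path(out_dir, "snp_counts.tsv"))
  write_tsv_table(gv, file.path(out_dir, "gene_counts.tsv"))
  write_tsv_table(design, file.path(out_dir, "design.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(summary) <- "poe_run"
  invisible(summary)
}

run_summary <- function(fits, de, universe, truth, config) {
  lab <- lapply(fits, function(f) f$calls$label)
  counts <- lapply(lab, function(l)
    as.list(table(factor(l, levels = c("MATERNAL", "PATERNAL",
                                       "LINEAGE_A", "LINEAGE_B",
                                       "BIALLELIC")))))
  gof <- lapply(counts, function(ct) {
    mp <- c(ct$MATERNAL, ct$PATERNAL)
    if (sum(mp) == 0) return(list(statistic = NA, p = NA))
    g <- chisq_gof_equal(mp)
    list(statistic = g$statistic, p = g$p)
  })
  tab <- rbind(c(counts$reproductive$MATERNAL,
                 counts$reproductive$PATERNAL),
               c(counts$sterile$MATERNAL, counts$sterile$PATERNAL))
  indep <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    list(statistic = NA, p = NA)
  else chisq_independence_2x2(tab)[c("statistic", "p")]

  mat_lists <- lapply(fits, function(f)
    f$calls$gene_id[f$calls$label == "MATERNAL"])
  ov <- overlap_test(mat_lists$reproductive, mat_lists$sterile, universe)

  out <- list(
    n_universe = length(universe),
    labels = counts,
    chisq_gof = gof,
    chisq_independence = indep,
    maternal_overlap = ov,
    de = lapply(de, function(d)
      list(n_tested = nrow(d), n_significant = sum(d$significant),
           n_up_reproductive = sum(d$significant &
                                     d$direction_of_change ==
                                     "up_reproductive"))),
    thresholds = config[c("q_poe", "prop_hi", "prop_lo", "q_de",
                          "min_snps")])
  if (!is.null(truth)) {
    out$recovery <- lapply(fits, function(f)
      recovery_metrics(f$calls, truth))
  }
  out
}

# Sensitivity per true class and false discovery among parent calls,
# judged against the simulator truth table.
recovery_metrics <- function(calls, truth) {
  m <- merge(calls[c("gene_id", "label")],
             truth[c("gene_id", "true_class")], by = "gene_id")
  sens <- function(cls) {
    n <- sum(m$true_class == cls)
    if (n == 0) return(NA)
    sum(m$true_class == cls & m$label == cls) / n
  }
  parent_call <- m$label %in% c("MATERNAL", "PATERNAL")
  fdr <- if (any(parent_call))
    mean(m$true_class[parent_call] != m$label[parent_call]) else 0
  lineage_leak <- sum(parent_call &
                        m$true_class %in% c("LINEAGE_A", "LINEAGE_B"))
  list(sensitivity_maternal = sens("MATERNAL"),
       sensitivity_paternal = sens("PATERNAL"),
       parent_call_fdr = fdr, lineage_leakage = lineage_leak)
}

#' @method print poe_run
#' @export
print.poe_run <- function(x, ...) {
  cat("Parent-of-origin pipeline summary\n")
  cat(sprintf("  universe: %d genes\n", x$n_universe))
  for (st in names(x$labels)) {
    l <- x$labels[[st]]
    cat(sprintf("  %s: %d maternal, %d paternal, %d lineage, %d biallelic\n",
                st, l$MATERNAL, l$PATERNAL, l$LINEAGE_A + l$LINEAGE_B,
                l$BIALLELIC))
  }
  cat(sprintf("  maternal-list overlap: %d genes, p = %.3g\n",
              x$maternal_overlap$overlap, x$maternal_overlap$p))
  invisible(x)
}
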