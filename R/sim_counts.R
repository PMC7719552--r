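#' Beta-binomial sampler parameterised by intraclass correlation
#'
#' Draws `length(size)` counts with success probability `prob` and
#' intraclass correlation `rho`; `rho = 0` reduces to pure binomial
#' sampling.  The marginal variance is `n p (1-p) (1 + (n-1) rho)`.
#'
#' @param size Integer vector of trial counts.
#' @param prob Success probability (scalar or vector).
#' @param rho Intraclass correlation in `[0, 1)`.
#' @return Integer vector of successes, one per element of `size`.
#' @export
rbetabinom <- function(size, prob, rho = 0) {
  stopifnot(rho >= 0, rho < 1, all(prob > 0 & prob < 1))
  if (rho == 0) return(rbinom(length(size), size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p_i <- rbeta(length(size), a, b)
  rbinom(length(size), size, p_i)
}

#' Simulate per-SNP allelic counts with known truth
#'
#' For every gene and library the total allelic depth is drawn from a
#' negative binomial whose mean is scaled by the library size factor and,
#' for genes designated differentially expressed, by a reproductive-status
#' fold change.  The maternal count is beta-binomial around the gene's true
#' maternal proportion: imprinted genes keep their proportion in both cross
#' directions, lineage (subspecies) genes flip it between directions, and
#' biallelic genes sit at 0.5.  Counts are then split across the gene's
#' informative SNPs by an equal-probability multinomial, so per SNP and
#' library maternal + paternal counts conserve the allelic depth assigned
#' to that SNP.
#'
#' @param config A [sim_config()] object.
#' @param design Design table from [make_design()] (or a subset of one).
#' @return A list of class `"poe_sim"`:
#'   \describe{
#'     \item{counts}{SNP-level `data.frame` (`gene_id`, `snp_id`,
#'       `library_id`, `maternal`, `paternal`).}
#'     \item{truth}{Per-gene truth (`gene_id`, `true_class`,
#'       `true_maternal_prop`, `de_status`, `n_snps`).}
#'     \item{design}{The design used.}
#'   }
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 42)
#' sim <- simulate_allelic_counts(cfg, make_design(cfg))
#' head(sim$counts)
#' table(sim$truth$true_class)
#' @export
simulate_allelic_counts <- function(config, design = make_design(config)) {
  validate_sim_config(config)
  validate_design(design)
  if (nrow(design) == 0) stop("design is empty", call. = FALSE)

  truth <- sim_truth(config)
  n_lib <- nrow(design)
  reproductive <- design$status == "reproductive"
  size_factor <- design$size_factor %||% rep(1, n_lib)

  out <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    set.seed(gene_seed(config$seed, g))
    tg <- truth[g, ]
    k <- tg$n_snps

    mu <- config$nb_mean * size_factor
    if (tg$de_status == "up") {
      mu[reproductive] <- mu[reproductive] * 2^config$status_log2fc
    } else if (tg$de_status == "down") {
      mu[reproductive] <- mu[reproductive] * 2^(-config$status_log2fc)
    }
    depth <- if (config$nb_dispersion > 0) {
      rnbinom(n_lib, mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(n_lib, mu)
    }

    p <- rep(tg$true_maternal_prop, n_lib)
    if (tg$true_class == "LINEAGE_A") {
      p <- ifelse(design$direction == "initial",
                  config$maternal_prop_imprinted,
                  1 - config$maternal_prop_imprinted)
    } else if (tg$true_class == "LINEAGE_B") {
      p <- ifelse(design$direction == "initial",
                  1 - config$maternal_prop_imprinted,
                  config$maternal_prop_imprinted)
    }
    maternal <- rbetabinom(depth, p, config$overdispersion_rho)
    paternal <- depth - maternal

    # multinomial split of each library's reads over the gene's SNPs
    m_split <- vapply(maternal, function(m)
      rmultinom(1, m, rep(1 / k, k))[, 1], integer(k))
    p_split <- vapply(paternal, function(m)
      rmultinom(1, m, rep(1 / k, k))[, 1], integer(k))
    if (k == 1) {
      m_split <- matrix(m_split, nrow = 1)
      p_split <- matrix(p_split, nrow = 1)
    }

    out[[g]] <- data.frame(
      gene_id = tg$gene_id,
      snp_id = rep(paste0(tg$gene_id, "_snp", seq_len(k)), times = n_lib),
      library_id = rep(design$library_id, each = k),
      maternal = as.vector(m_split),
      paternal = as.vector(p_split),
      stringsAsFactors = FALSE)
  }

  res <- list(counts = do.call(rbind, out), truth = truth, design = design)
  class(res) <- "poe_sim"
  res
}

# Internal: draw gene classes, true proportions, DE status and SNP counts.
sim_truth <- function(config) {
  set.seed(gene_seed(config$seed, -1L))
  n <- config$n_genes
  gene_id <- sprintf("gene%04d", seq_len(n))

  n_m <- round(config$frac_maternal * n)
  n_p <- round(config$frac_paternal * n)
  n_l <- round(config$frac_lineage * n)
  classes <- c(rep("MATERNAL", n_m), rep("PATERNAL", n_p),
               rep(c("LINEAGE_A", "LINEAGE_B"), length.out = n_l),
               rep("BIALLELIC", n - n_m - n_p - n_l))
  classes <- sample(classes)

  pi <- config$maternal_prop_imprinted
  prop <- ifelse(classes == "MATERNAL", pi,
                 ifelse(classes == "PATERNAL", 1 - pi, 0.5))

  n_up <- round(config$frac_de_up * n)
  n_dn <- round(config$frac_de_down * n)
  de <- sample(c(rep("up", n_up), rep("down", n_dn),
                 rep("none", n - n_up - n_dn)))

  snp_cfg <- config$n_snps_per_gene
  n_snps <- snp_cfg$min + stats::rpois(n, snp_cfg$mean - snp_cfg$min)

  data.frame(gene_id = gene_id, true_class = classes,
             true_maternal_prop = prop, de_status = de, n_snps = n_snps,
             stringsAsFactors = FALSE)
}

#' @method print poe_sim
#' @export
print.poe_sim <- function(x, ...) {
  cat("Simulated reciprocal-cross allelic counts\n")
  cat(sprintf("  %d genes x %d libraries; %d SNP-level rows\n",
              nrow(x$truth), nrow(x$design), nrow(x$counts)))
  print(table(x$truth$true_class))
  invisible(x)
}

#' Collapse a SNP-level allelic count table to the gene level
#'
#' Sums maternal and paternal counts over a gene's SNPs per library and
#' records the number of contributing SNPs.  This is the correct gene view
#' for count-level simulations, where every simulated read covers exactly
#' one SNP; for read-level data see [count_by_snp()], which can deduplicate
#' reads spanning several SNPs.
#'
#' @param counts SNP-level `data.frame` with `gene_id`, `snp_id`,
#'   `library_id`, `maternal`, `paternal`.
#' @return Gene-level `data.frame` (`gene_id`, `library_id`, `maternal`,
#'   `paternal`, `n_snps`).
#' @export
aggregate_to_genes <- function(counts) {
  stopifnot(all(c("gene_id", "snp_id", "library_id", "maternal",
                  "paternal") %in% names(counts)))
  if (nrow(counts) == 0)
    return(data.frame(gene_id = character(), library_id = character(),
                      maternal = integer(), paternal = integer(),
                      n_snps = integer(), stringsAsFactors = FALSE))
  key <- list(gene_id = counts$gene_id, library_id = counts$library_id)
  agg <- aggregate(counts[c("maternal", "paternal")], key, sum)
  nsnp <- aggregate(list(n_snps = counts$snp_id), key,
                    function(s) length(unique(s)))
  out <- merge(agg, nsnp, by = c("gene_id", "library_id"), sort = TRUE)
  out[order(out$gene_id, out$library_id), , drop = FALSE]
}
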