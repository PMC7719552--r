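#' Configuration for the reciprocal-cross simulator
#'
#' Builds and validates the parameter set used by [make_design()],
#' [simulate_allelic_counts()] and [simulate_sequences()].  Defaults encode
#' the study design the simulator emulates: two replicate families, each
#' crossed in both directions (four colonies), eight workers per colony —
#' two dominant reproductives, two subordinate reproductives, two nurses and
#' two foragers — with head and abdomen libraries per worker, i.e. 64
#' RNA-seq libraries in total, 32 per reproductive status.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_snps_per_gene List with elements `mean` and `min`: per-gene
#'   informative-SNP counts are drawn as `min + Poisson(mean - min)`.
#' @param genome_contig_length Length (bases) of the single simulated contig
#'   used by [simulate_sequences()].
#' @param n_families Number of replicate families (sibling crosses).
#' @param directions Character vector of cross directions simulated; subset
#'   of `c("initial", "reciprocal")`.
#' @param workers_per_colony Workers sequenced per colony (multiple of 4 so
#'   the four behavioural types are balanced).
#' @param tissues Tissues dissected per worker.
#' @param mean_allelic_depth Mean allelic (SNP-covering) read depth per gene
#'   per library; the negative binomial mean `nb_mean`.
#' @param maternal_prop_imprinted True maternal expression proportion of
#'   simulated imprinted genes (paternally expressed genes use its
#'   complement; lineage genes use it for the favoured subspecies).
#' @param frac_maternal,frac_paternal,frac_lineage Fractions of genes with
#'   maternal, paternal, and lineage (subspecies) expression bias; must sum
#'   to at most 1, remainder is biallelic.  Lineage genes are split evenly
#'   between the two subspecies.
#' @param overdispersion_rho Beta-binomial intraclass correlation in
#'   `[0, 1)`; 0 gives pure binomial sampling.
#' @param nb_dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`) of total allelic depth.
#' @param status_log2fc Log2 fold change (reproductive vs sterile) applied
#'   to the total expression of genes designated differentially expressed.
#' @param frac_de_up,frac_de_down Fractions of genes up-/down-regulated in
#'   reproductive workers.
#' @param read_length Read length (bases) for [simulate_sequences()].
#' @param gene_length Gene span (bases) for [simulate_sequences()].
#' @param seed Root seed; every simulator draw is derived from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' nrow(make_design(cfg))  # 64
#' @export
sim_config <- function(n_genes = 500,
                       n_snps_per_gene = list(mean = 5, min = 2),
                       genome_contig_length = 50000L,
                       n_families = 2L,
                       directions = c("initial", "reciprocal"),
                       workers_per_colony = 8L,
                       tissues = c("head", "abdomen"),
                       mean_allelic_depth = 50,
                       maternal_prop_imprinted = 0.9,
                       frac_maternal = 0.05,
                       frac_paternal = 0.05,
                       frac_lineage = 0.05,
                       overdispersion_rho = 0.05,
                       nb_dispersion = 0.2,
                       status_log2fc = 2,
                       frac_de_up = 0.05,
                       frac_de_down = 0.05,
                       read_length = 90L,
                       gene_length = 600L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_snps_per_gene = n_snps_per_gene,
    genome_contig_length = as.integer(genome_contig_length),
    n_families = as.integer(n_families),
    directions = match.arg(directions, c("initial", "reciprocal"),
                           several.ok = TRUE),
    workers_per_colony = as.integer(workers_per_colony),
    tissues = match.arg(tissues, c("head", "abdomen"), several.ok = TRUE),
    mean_allelic_depth = mean_allelic_depth,
    nb_mean = mean_allelic_depth,
    maternal_prop_imprinted = maternal_prop_imprinted,
    frac_maternal = frac_maternal,
    frac_paternal = frac_paternal,
    frac_lineage = frac_lineage,
    overdispersion_rho = overdispersion_rho,
    nb_dispersion = nb_dispersion,
    status_log2fc = status_log2fc,
    frac_de_up = frac_de_up,
    frac_de_down = frac_de_down,
    read_length = as.integer(read_length),
    gene_length = as.integer(gene_length),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_families >= 1,
            cfg$workers_per_colony >= 1,
            cfg$genome_contig_length >= 1)
  if (cfg$workers_per_colony %% 4L != 0L)
    stop("workers_per_colony must be a multiple of 4 ",
         "(balanced behavioural types)", call. = FALSE)
  fr <- c(cfg$frac_maternal, cfg$frac_paternal, cfg$frac_lineage)
  if (any(fr < 0) || sum(fr) > 1)
    stop("frac_maternal + frac_paternal + frac_lineage must lie in [0, 1]",
         call. = FALSE)
  if (cfg$maternal_prop_imprinted <= 0 || cfg$maternal_prop_imprinted >= 1)
    stop("maternal_prop_imprinted must lie in (0, 1)", call. = FALSE)
  if (cfg$overdispersion_rho < 0 || cfg$overdispersion_rho >= 1)
    stop("overdispersion_rho must lie in [0, 1)", call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$nb_mean <= 0) stop("mean_allelic_depth must be > 0", call. = FALSE)
  if (!is.list(cfg$n_snps_per_gene) ||
      is.null(cfg$n_snps_per_gene$mean) || is.null(cfg$n_snps_per_gene$min))
    stop("n_snps_per_gene must be list(mean =, min =)", call. = FALSE)
  if (cfg$n_snps_per_gene$min < 1 ||
      cfg$n_snps_per_gene$mean < cfg$n_snps_per_gene$min)
    stop("n_snps_per_gene: need mean >= min >= 1", call. = FALSE)
  if (any(cfg$frac_de_up < 0, cfg$frac_de_down < 0,
          cfg$frac_de_up + cfg$frac_de_down > 1))
    stop("DE fractions must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' @method print sim_config
#' @export
print.sim_config <- function(x, ...) {
  n_col <- x$n_families * length(x$directions)
  n_lib <- n_col * x$workers_per_colony * length(x$tissues)
  cat("Reciprocal-cross simulation config\n")
  cat(sprintf("  %d genes; %d famil%s x %d direction(s) = %d colonies; %d libraries\n",
              x$n_genes, x$n_families,
              if (x$n_families == 1) "y" else "ies",
              length(x$directions), n_col, n_lib))
  cat(sprintf("  classes: %.0f%% maternal, %.0f%% paternal, %.0f%% lineage (prop %.2f)\n",
              100 * x$frac_maternal, 100 * x$frac_paternal,
              100 * x$frac_lineage, x$maternal_prop_imprinted))
  cat(sprintf("  depth NB(mean %.0f, disp %.2f); beta-binomial rho %.2f; seed %d\n",
              x$nb_mean, x$nb_dispersion, x$overdispersion_rho, x$seed))
  invisible(x)
}
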