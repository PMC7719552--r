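#' Build the library design table for a reciprocal-cross experiment
#'
#' One row per RNA-seq library.  Families and cross directions are fully
#' crossed into colonies; each colony contributes `workers_per_colony`
#' workers split equally among the four behavioural types (dominant
#' reproductive, subordinate reproductive, nurse, forager), and each worker
#' yields one library per tissue.  Reproductive status is a deterministic
#' function of worker type.  Age and weight are standard-normal nuisance
#' covariates consumed only by the differential expression stage; a
#' log-normal per-library size factor models library-size variation.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `library_id`, `colony`, `family`,
#'   `direction`, `tissue`, `worker_id`, `worker_type`, `status`, `age`,
#'   `weight`, `size_factor`.
#' @examples
#' d <- make_design(sim_config(n_genes = 10))
#' table(d$status, d$tissue)
#' @export
make_design <- function(config) {
  validate_sim_config(config)
  families <- LETTERS[seq_len(config$n_families)]
  types <- c("dominant_rep", "subordinate_rep", "nurse", "forager")
  per_type <- config$workers_per_colony %/% 4L

  rows <- list()
  for (fam in families) {
    for (dir in config$directions) {
      colony <- paste0(fam, "_", dir)
      worker_type <- rep(types, each = per_type)
      worker_id <- paste0(colony, "_w", seq_len(config$workers_per_colony))
      for (t in config$tissues) {
        rows[[length(rows) + 1L]] <- data.frame(
          library_id = paste0(worker_id, "_", t),
          colony = colony, family = fam, direction = dir, tissue = t,
          worker_id = worker_id, worker_type = worker_type,
          stringsAsFactors = FALSE)
      }
    }
  }
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  design$status <- ifelse(design$worker_type %in%
                            c("dominant_rep", "subordinate_rep"),
                          "reproductive", "sterile")

  set.seed(gene_seed(config$seed, 0L))
  workers <- unique(design$worker_id)
  age <- setNames(rnorm(length(workers)), workers)
  weight <- setNames(rnorm(length(workers)), workers)
  design$age <- unname(age[design$worker_id])
  design$weight <- unname(weight[design$worker_id])
  design$size_factor <- exp(rnorm(nrow(design), 0, 0.15))
  design
}

# Internal: check a design covers every family x direction cell and has the
# columns the inference stages rely on.
validate_design <- function(design,
                            required = c("library_id", "colony", "family",
                                         "direction", "tissue",
                                         "worker_type", "status")) {
  miss <- setdiff(required, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cells <- table(design$family, design$direction)
  if (any(cells == 0))
    stop("design lacks libraries for some family x direction cell",
         call. = FALSE)
  invisible(design)
}
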