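#' Fit the parent-of-origin expression model over a gene universe
#'
#' The central model of the package.  For each gene, maternal vs paternal
#' allelic totals are fit with a quasibinomial logistic regression
#' ([fit_gene()]) over the selected libraries; intercept p-values are
#' Benjamini-Hochberg corrected across the analyzed universe; the
#' conservative hierarchical maternal proportion is computed
#' ([conservative_proportion()]); and each gene is classified as
#' maternally expressed, paternally expressed, lineage biased or
#' biallelic ([classify_gene()]).
#'
#' Analyses are run per reproductive status by default (factors: cross
#' direction and family), mirroring separate reproductive and sterile
#' gene lists; `status = "joint"` fits all libraries with reproductive
#' status as an additional factor.
#'
#' @param gene_counts Gene-level count table (`gene_id`, `library_id`,
#'   `maternal`, `paternal`), universe-filtered and with the
#'   paternal-zero substitution applied (see [gene_universe()],
#'   [substitute_paternal_zero()]).
#' @param design Design table covering the libraries.
#' @param status `"reproductive"`, `"sterile"`, or `"joint"`.
#' @param q_thresh,prop_hi,prop_lo Classification thresholds.
#' @return An object of class `"poe"`: a list with `calls` (per-gene
#'   report), `beta` (gene x coefficient matrix), `status`, `thresholds`,
#'   `n_libraries`, `excluded` (non-converged gene ids).
#' @examples
#' cfg <- sim_config(n_genes = 30, seed = 7)
#' sim <- simulate_allelic_counts(cfg)
#' gv <- substitute_paternal_zero(aggregate_to_genes(sim$counts))
#' fit <- poe(gv, sim$design, status = "reproductive")
#' summary(fit)
#' @export
poe <- function(gene_counts, design,
                status = c("reproductive", "sterile", "joint"),
                q_thresh = 0.05, prop_hi = 0.6, prop_lo = 0.4) {
  status <- match.arg(status)
  validate_design(design)
  stopifnot(all(c("gene_id", "library_id", "maternal", "paternal") %in%
                  names(gene_counts)))
  if (q_thresh <= 0 || q_thresh > 1)
    stop("q_thresh must lie in (0, 1]", call. = FALSE)
  if (!(prop_lo < 0.5 && 0.5 < prop_hi && prop_hi <= 1 && prop_lo >= 0))
    stop("need 0 <= prop_lo < 0.5 < prop_hi <= 1", call. = FALSE)

  if (status == "joint") {
    d <- design
    factors <- c("direction", "family", "status")
  } else {
    d <- design[design$status == status, , drop = FALSE]
    factors <- c("direction", "family")
  }
  counts <- gene_counts[gene_counts$library_id %in% d$library_id, ,
                        drop = FALSE]
  rownames(d) <- d$library_id

  genes <- sort(unique(counts$gene_id))
  idx <- split(seq_len(nrow(counts)), counts$gene_id)

  fits <- vector("list", length(genes)); names(fits) <- genes
  props <- vector("list", length(genes)); names(props) <- genes
  excluded <- character()
  for (g in genes) {
    rows <- counts[idx[[g]], , drop = FALSE]
    dg <- d[rows$library_id, , drop = FALSE]
    f <- tryCatch(fit_gene(rows$maternal, rows$paternal, dg, factors),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      excluded <- c(excluded, g)
      next
    }
    fits[[g]] <- f
    props[[g]] <- conservative_proportion(rows$maternal, rows$paternal, dg)
  }
  genes <- setdiff(genes, excluded)
  if (length(excluded))
    message(length(excluded), " gene(s) excluded (fit failure)")

  p <- vapply(fits[genes], `[[`, 0, "p_intercept")
  q <- bh_adjust(p)
  disp <- vapply(fits[genes], `[[`, 0, "dispersion")
  mprop <- vapply(props[genes], `[[`, 0, "mean_maternal_prop")

  colonies <- sort(unique(d$colony))
  pc <- matrix(unlist(lapply(props[genes],
                             function(x) x$per_colony_prop[colonies])),
               ncol = length(colonies), byrow = TRUE,
               dimnames = list(genes, paste0("prop_", colonies)))
  dirs <- sort(unique(d$direction))
  pd <- matrix(unlist(lapply(props[genes],
                             function(x) x$per_direction_prop[dirs])),
               ncol = length(dirs), byrow = TRUE,
               dimnames = list(genes, paste0("prop_", dirs)))

  label <- vapply(genes, function(g)
    classify_gene(q[[g]], props[[g]]$mean_maternal_prop,
                  props[[g]]$per_colony_prop,
                  props[[g]]$per_direction_prop,
                  q_thresh, prop_hi, prop_lo), "")

  coef_names <- unique(unlist(lapply(fits[genes],
                                     function(f) names(f$beta))))
  beta <- matrix(NA_real_, length(genes), length(coef_names),
                 dimnames = list(genes, coef_names))
  for (g in genes) beta[g, names(fits[[g]]$beta)] <- fits[[g]]$beta

  calls <- data.frame(
    gene_id = genes,
    beta0 = if (length(genes)) beta[, "(Intercept)"] else numeric(),
    dispersion = disp, p = p, q = q, mean_maternal_prop = mprop,
    stringsAsFactors = FALSE)
  calls <- cbind(calls, pc, pd)
  calls$label <- unname(label)
  rownames(calls) <- NULL

  structure(list(calls = calls, beta = beta, status = status,
                 thresholds = c(q = q_thresh, prop_hi = prop_hi,
                                prop_lo = prop_lo),
                 n_libraries = nrow(d), design = d,
                 excluded = excluded),
            class = "poe")
}

#' @rdname poe
#' @param table SNP-level allelic count table; collapsed to genes,
#'   universe-filtered and zero-substituted before fitting.
#' @param min_snps Minimum SNPs per gene for the universe.
#' @export
run_poe <- function(table, design,
                    status = c("reproductive", "sterile", "joint"),
                    q_thresh = 0.05, prop_hi = 0.6, prop_lo = 0.4,
                    min_snps = 2) {
  universe <- gene_universe(table, design, min_snps = min_snps)
  gv <- aggregate_to_genes(table[table$gene_id %in% universe, ,
                                 drop = FALSE])
  gv <- substitute_paternal_zero(gv)
  poe(gv, design, status = status, q_thresh = q_thresh,
      prop_hi = prop_hi, prop_lo = prop_lo)
}

#' @method print poe
#' @export
print.poe <- function(x, ...) {
  cat(sprintf("Parent-of-origin expression fit (%s workers)\n", x$status))
  cat(sprintf("  %d genes over %d libraries; thresholds q<%.2g, prop >%.2g / <%.2g\n",
              nrow(x$calls), x$n_libraries, x$thresholds[["q"]],
              x$thresholds[["prop_hi"]], x$thresholds[["prop_lo"]]))
  print(table(factor(x$calls$label,
                     levels = c("MATERNAL", "PATERNAL", "LINEAGE_A",
                                "LINEAGE_B", "BIALLELIC"))))
  invisible(x)
}

#' @method summary poe
#' @export
summary.poe <- function(object, ...) {
  cls <- object$calls
  out <- list(
    status = object$status,
    n_genes = nrow(cls),
    n_libraries = object$n_libraries,
    label_counts = table(factor(cls$label,
                                levels = c("MATERNAL", "PATERNAL",
                                           "LINEAGE_A", "LINEAGE_B",
                                           "BIALLELIC"))),
    n_significant = sum(cls$q < object$thresholds[["q"]], na.rm = TRUE),
    n_extreme_maternal = sum(cls$label == "MATERNAL" &
                               cls$mean_maternal_prop > 0.9),
    excluded = object$excluded,
    top = head(cls[order(cls$q), ], 10))
  class(out) <- "summary.poe"
  out
}

#' @method print summary.poe
#' @export
print.summary.poe <- function(x, ...) {
  cat(sprintf("POE analysis, %s workers: %d genes, %d libraries\n",
              x$status, x$n_genes, x$n_libraries))
  cat(sprintf("  significant at q threshold: %d; maternal calls with prop > 0.9: %d\n",
              x$n_significant, x$n_extreme_maternal))
  print(x$label_counts)
  cat("Top genes by q:\n")
  print(x$top[c("gene_id", "beta0", "dispersion", "q",
                "mean_maternal_prop", "label")], digits = 3)
  invisible(x)
}

#' @method coef poe
#' @export
coef.poe <- function(object, ...) object$beta

#' Maternal-proportion plot of a POE fit
#'
#' Plots each gene's conservative maternal expression proportion against
#' its gene index, coloured by classification, with the decision
#' thresholds drawn — the classic view in which maternally expressed
#' genes sit above 0.6 and paternally expressed genes below 0.4.
#'
#' @param x A `"poe"` object.
#' @param ... Passed to [graphics::plot()].
#' @method plot poe
#' @export
plot.poe <- function(x, ...) {
  cls <- x$calls
  col <- c(MATERNAL = "deeppink3", PATERNAL = "dodgerblue3",
           LINEAGE_A = "darkorange2", LINEAGE_B = "goldenrod3",
           BIALLELIC = "grey60")[cls$label]
  plot(seq_len(nrow(cls)), cls$mean_maternal_prop, col = col, pch = 16,
       cex = 0.6, xlab = "gene index", ylab = "maternal proportion",
       ylim = c(0, 1),
       main = sprintf("Parent-of-origin expression (%s)", x$status), ...)
  abline(h = c(x$thresholds[["prop_lo"]], 0.5, x$thresholds[["prop_hi"]]),
         lty = c(2, 1, 2), col = "grey40")
  legend("topright", legend = names(table(cls$label)), pch = 16, cex = 0.7,
         col = c(MATERNAL = "deeppink3", PATERNAL = "dodgerblue3",
                 LINEAGE_A = "darkorange2", LINEAGE_B = "goldenrod3",
                 BIALLELIC = "grey60")[names(table(cls$label))])
  invisible(x)
}
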