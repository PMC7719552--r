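#' Median-of-ratios library size factors
#'
#' For each library, the size factor is the median over genes of the
#' ratio of the library's count to the gene's geometric mean across
#' libraries, computed over genes with all-positive counts.  Identical
#' libraries therefore get factors of exactly 1, and doubling one
#' library's counts doubles its factor relative to the others.
#'
#' @param counts Integer matrix, genes x libraries.
#' @return Positive numeric vector, one factor per library.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene has positive counts in every library; ",
         "supply deeper data or a pseudo-reference fallback", call. = FALSE)
  geo <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
  apply(counts[all_pos, , drop = FALSE], 2, function(cl) median(cl / geo))
}

#' Reproductive-vs-sterile differential expression (simplified NB test)
#'
#' A deliberately simple negative binomial stage: genes with fewer than
#' `min_total` counts are removed; per gene a method-of-moments
#' dispersion is estimated from normalized counts; an NB log-linear model
#' with `log(size factor)` offset is fit with reproductive status and the
#' requested covariates; and the status coefficient is Wald-tested, with
#' Benjamini-Hochberg correction across tested genes.  No dispersion
#' shrinkage, no independent filtering — tissues are analysed separately
#' by subsetting before the call.
#'
#' @param counts Integer matrix, genes x libraries (one tissue).
#' @param design Design rows matching the columns of `counts`.
#' @param covariates Design columns entering besides `status`; columns
#'   constant over the libraries are dropped.
#' @param min_total Minimum total count for a gene to be tested.
#' @param q_thresh Significance threshold on the BH-adjusted p.
#' @return `data.frame` with `gene_id`, `log2_fold_change` (reproductive
#'   vs sterile), `p`, `q`, `significant`, `direction_of_change`.
#' @export
de_test <- function(counts, design,
                    covariates = c("family", "direction", "age", "weight"),
                    min_total = 10, q_thresh = 0.01) {
  counts <- as.matrix(counts)
  stopifnot(nrow(design) == ncol(counts))
  if (!all(c("reproductive", "sterile") %in% design$status))
    stop("design must contain both reproductive and sterile libraries",
         call. = FALSE)

  keep <- rowSums(counts) >= min_total
  counts <- counts[keep, , drop = FALSE]

  sf <- size_factors(counts)
  dat <- data.frame(status = factor(design$status,
                                    levels = c("sterile", "reproductive")))
  for (cv in covariates) {
    v <- design[[cv]]
    if (is.numeric(v)) {
      if (stats::sd(v) > 0) dat[[cv]] <- v
    } else if (length(unique(v)) >= 2) {
      dat[[cv]] <- factor(v, levels = sort(unique(v)))
    }
  }
  X <- model.matrix(stats::reformulate(names(dat)), dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; aliased column(s): ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]],
               collapse = ", "), call. = FALSE)

  norm <- sweep(counts, 2, sf, "/")
  mu_hat <- rowMeans(norm)
  var_hat <- apply(norm, 1, var)
  disp <- pmax((var_hat - mu_hat) / mu_hat^2, 1e-8)

  res <- lapply(seq_len(nrow(counts)), function(i) {
    dat$y <- counts[i, ]
    fit <- tryCatch(suppressWarnings(glm(
      stats::reformulate(setdiff(names(dat), "y"), response = "y"),
      family = MASS::negative.binomial(theta = 1 / disp[i]),
      data = dat, offset = log(sf),
      control = glm.control(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(c(lfc = NA_real_, p = NA_real_))
    est <- coef(fit)[["statusreproductive"]]
    se <- sqrt(summary(fit, dispersion = 1)$cov.unscaled[
      "statusreproductive", "statusreproductive"])
    z <- est / se
    c(lfc = est / log(2), p = 2 * pnorm(-abs(z)))
  })
  res <- do.call(rbind, res)

  out <- data.frame(gene_id = rownames(counts),
                    log2_fold_change = res[, "lfc"],
                    p = res[, "p"], stringsAsFactors = FALSE)
  out <- out[!is.na(out$p), , drop = FALSE]
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_thresh
  out$direction_of_change <- ifelse(out$log2_fold_change > 0,
                                    "up_reproductive", "up_sterile")
  rownames(out) <- NULL
  out
}
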