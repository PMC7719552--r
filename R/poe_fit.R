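#' Per-gene quasibinomial logistic regression of allelic counts
#'
#' Fits maternal vs paternal read counts with a binomial GLM (logit link,
#' iteratively reweighted least squares) and quasi-likelihood inference:
#' the Pearson overdispersion estimate scales the standard errors and the
#' intercept is tested against 0 on a t reference with the residual
#' degrees of freedom.  Design factors enter with sum-to-zero (effects)
#' coding, so the intercept is the grand-mean logit of the maternal
#' proportion and its test asks whether the gene deviates from the
#' expected 0.5 allelic proportion.
#'
#' @param maternal,paternal Integer count vectors, one entry per library.
#' @param design Design rows matching the counts (same order).
#' @param factors Design columns entering as fixed factors; factors
#'   constant over the supplied libraries are dropped automatically.
#' @return A list: `beta` (named coefficients, logit scale), `se`
#'   (dispersion-scaled standard errors), `dispersion` (Pearson
#'   chi-squared / residual df), `p_intercept` (two-sided t-test p),
#'   `df_residual`, `converged`.
#' @examples
#' d <- make_design(sim_config(n_genes = 1))
#' f <- fit_gene(rep(30, 64), rep(30, 64), d)
#' f$beta[["(Intercept)"]]  # 0: perfectly biallelic
#' @export
fit_gene <- function(maternal, paternal,
                     design, factors = c("direction", "family")) {
  n <- length(maternal)
  stopifnot(length(paternal) == n, nrow(design) == n)
  if (sum(maternal + paternal > 0) < 2)
    stop("need at least two libraries with positive allelic totals",
         call. = FALSE)

  dat <- data.frame(maternal = maternal, paternal = paternal)
  used <- character()
  for (f in factors) {
    lev <- sort(unique(design[[f]]))
    if (length(lev) >= 2) {
      dat[[f]] <- factor(design[[f]], levels = lev)
      used <- c(used, f)
    }
  }
  form <- if (length(used))
    stats::reformulate(used, response = "cbind(maternal, paternal)")
  else cbind(maternal, paternal) ~ 1
  ctr <- setNames(rep(list("contr.sum"), length(used)), used)

  fit <- suppressWarnings(glm(
    form, family = quasibinomial(), data = dat,
    contrasts = if (length(used)) ctr else NULL,
    control = glm.control(epsilon = 1e-12, maxit = 100)))
  if (fit$df.residual <= 0)
    stop("saturated design: no residual degrees of freedom", call. = FALSE)

  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  dispersion <- pearson / fit$df.residual
  beta <- coef(fit)
  # unscaled covariance, then quasi-likelihood scaling
  cov_u <- summary(fit, dispersion = 1)$cov.unscaled
  se <- sqrt(diag(cov_u) * dispersion)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = fit$df.residual)
  # degenerate perfect fit (dispersion 0): the effect is exactly its
  # estimate; a zero coefficient carries no evidence against 0.5
  bad <- !is.finite(pval)
  pval[bad] <- ifelse(abs(beta[bad]) < 1e-8, 1, 0)

  list(beta = beta, se = se, dispersion = dispersion,
       p_intercept = unname(pval["(Intercept)"]),
       df_residual = fit$df.residual, converged = fit$converged)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector in `[0, 1]` (`NA`s are passed through).
#' @return BH-adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Conservatively averaged maternal expression proportion
#'
#' Computes the per-library maternal proportion maternal/(maternal +
#' paternal) and averages it hierarchically — libraries within a tissue,
#' tissues within a worker type, worker types within a colony, and the
#' colony means across the family-by-direction cells with equal weight —
#' so that no colony, worker type or tissue dominates through unbalanced
#' library counts.
#'
#' @param maternal,paternal Count vectors, one entry per library.
#' @param design Matching design rows (`colony`, `direction`,
#'   `worker_type`, `tissue`).
#' @return List: `mean_maternal_prop`, `per_colony_prop` (named),
#'   `per_direction_prop` (named).
#' @export
conservative_proportion <- function(maternal, paternal, design) {
  total <- maternal + paternal
  keep <- total > 0
  d <- design[keep, , drop = FALSE]
  prop <- maternal[keep] / total[keep]

  colonies <- sort(unique(design$colony))
  missing <- setdiff(colonies, unique(d$colony))
  if (length(missing))
    stop("no allelic data for colony cell(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  lvl3 <- aggregate(list(prop = prop),
                    list(colony = d$colony, worker_type = d$worker_type,
                         tissue = d$tissue), mean)
  lvl2 <- aggregate(list(prop = lvl3$prop),
                    list(colony = lvl3$colony,
                         worker_type = lvl3$worker_type), mean)
  lvl1 <- aggregate(list(prop = lvl2$prop), list(colony = lvl2$colony),
                    mean)
  per_colony <- setNames(lvl1$prop, lvl1$colony)

  dir_of <- setNames(design$direction, design$colony)
  dir_of <- dir_of[!duplicated(names(dir_of))]
  per_direction <- tapply(per_colony, dir_of[names(per_colony)], mean)
  per_direction <- setNames(as.vector(per_direction),
                            dimnames(per_direction)[[1]])

  list(mean_maternal_prop = mean(per_colony),
       per_colony_prop = per_colony,
       per_direction_prop = per_direction[!is.na(per_direction)])
}

#' Classify a gene's allelic expression pattern
#'
#' Applies the significance-plus-proportion rule: a gene is maternally
#' (paternally) expressed when its BH-corrected p-value is below
#' `q_thresh`, its conservative mean maternal proportion exceeds
#' `prop_hi` (falls below `prop_lo`), and every colony shows the bias on
#' the same side of 0.5 — i.e. the deviation holds in both cross
#' directions and both replicate families.  Lineage (subspecies) bias is
#' the alternative pattern in which the favoured allele follows the
#' genetic background: after recoding the maternal proportion to the
#' lineage-A allele proportion (identity in the initial cross, complement
#' in the reciprocal), a lineage gene exceeds `prop_hi` (or falls below
#' `prop_lo`) in both directions.  Everything else is biallelic.
#'
#' @param q BH-adjusted p-value of the intercept test.
#' @param mean_prop Conservative mean maternal proportion.
#' @param per_colony_prop Named per-colony proportions.
#' @param per_direction_prop Named per-direction proportions
#'   (`initial`, `reciprocal`).
#' @param q_thresh,prop_hi,prop_lo Decision thresholds (0.05, 0.6, 0.4).
#' @return One of `"MATERNAL"`, `"PATERNAL"`, `"LINEAGE_A"`,
#'   `"LINEAGE_B"`, `"BIALLELIC"`.
#' @export
classify_gene <- function(q, mean_prop, per_colony_prop,
                          per_direction_prop, q_thresh = 0.05,
                          prop_hi = 0.6, prop_lo = 0.4) {
  if (is.na(q) || q >= q_thresh) return("BIALLELIC")
  if (mean_prop > prop_hi && all(per_colony_prop > 0.5)) return("MATERNAL")
  if (mean_prop < prop_lo && all(per_colony_prop < 0.5)) return("PATERNAL")
  if (all(c("initial", "reciprocal") %in% names(per_direction_prop))) {
    lineage_a <- c(per_direction_prop[["initial"]],
                   1 - per_direction_prop[["reciprocal"]])
    if (all(lineage_a > prop_hi)) return("LINEAGE_A")
    if (all(lineage_a < prop_lo)) return("LINEAGE_B")
  }
  "BIALLELIC"
}
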