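# Independent oracles, written separately from the package implementation.

# Textbook IRLS for a binomial logit GLM with quasi-likelihood inference:
# X is the model matrix, successes m, failures f.  Returns coefficients,
# Pearson dispersion and two-sided t-test p-values.
irls_oracle <- function(X, m, f, tol = 1e-13, maxit = 200) {
  n <- m + f
  y <- m / n
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- n * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    XtW <- t(X * W)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  df <- length(y) - ncol(X)
  pearson <- sum(n * (y - mu)^2 / (mu * (1 - mu)))
  dispersion <- pearson / df
  W <- n * mu * (1 - mu)
  cov_u <- solve(t(X * W) %*% X)
  se <- sqrt(diag(cov_u) * dispersion)
  tval <- beta / se
  list(beta = unname(beta), se = unname(se), dispersion = dispersion,
       p = unname(2 * pt(-abs(tval), df = df)))
}

# Exhaustive upper-tail hypergeometric probability by direct enumeration
# of the pmf (counts of ways to choose i marked and n - i unmarked).
hyper_tail_oracle <- function(k, K, N, n) {
  i <- 0:n
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(pmf[i >= k])
}

# Naive double-loop reciprocal-best-hit resolution.
rbh_oracle <- function(ab, ba, max_evalue = 1e-3) {
  pick <- function(h) {
    h <- h[h$evalue <= max_evalue, , drop = FALSE]
    out <- list()
    for (q in unique(h$query)) {
      hq <- h[h$query == q, , drop = FALSE]
      hq <- hq[hq$evalue == min(hq$evalue), , drop = FALSE]
      hq <- hq[hq$score == max(hq$score), , drop = FALSE]
      out[[q]] <- sort(hq$subject)[1]
    }
    out
  }
  fa <- pick(ab); fb <- pick(ba)
  pairs <- list()
  for (a in names(fa)) {
    b <- fa[[a]]
    if (!is.null(fb[[b]]) && identical(fb[[b]], a))
      pairs[[a]] <- data.frame(gene_a = a, gene_b = b,
                               stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, pairs)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random SNP record table for filter tests.
random_snp_records <- function(n, seed) {
  set.seed(seed)
  depth <- sample(0:20, n, replace = TRUE)
  snp_records(contig = sample(c("c1", "c2"), n, replace = TRUE),
              pos = sample(1e5, n), ref = sample(c("A", "C"), n, TRUE),
              alt = sample(c("G", "T"), n, TRUE),
              qual = round(runif(n, 0, 60), 1), depth = depth,
              alt_obs = pmin(depth, sample(0:10, n, replace = TRUE)),
              genotype = sample(c("hom_alt", "het"), n, TRUE),
              ploidy = 2L)
}

# Small count-level simulation shared across tests.
small_sim <- function(n_genes = 40, seed = 101, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
  simulate_allelic_counts(cfg, make_design(cfg))
}
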