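balanced_design <- make_design(sim_config(n_genes = 1))

test_that("a perfectly balanced gene has zero intercept and p of one", {
  f <- fit_gene(rep(30L, 64), rep(30L, 64), balanced_design)
  expect_equal(unname(f$beta[["(Intercept)"]]), 0)
  expect_equal(f$p_intercept, 1)
})

test_that("the intercept-only fit equals the pooled-proportion logit", {
  d <- balanced_design[1:4, ]  # one colony: direction and family constant
  m <- c(90L, 85L, 92L, 88L); p <- c(10L, 15L, 8L, 12L)
  f <- fit_gene(m, p, d)
  pooled <- sum(m) / sum(m + p)
  expect_equal(unname(f$beta[["(Intercept)"]]), log(pooled / (1 - pooled)),
               tolerance = 1e-8)
  # and the whole fit matches the independent IRLS oracle
  o <- irls_oracle(matrix(1, 4, 1), m, p)
  expect_equal(unname(f$beta), o$beta, tolerance = 1e-8)
  expect_equal(f$dispersion, o$dispersion, tolerance = 1e-8)
  expect_equal(f$p_intercept, o$p[1], tolerance = 1e-6)
})

test_that("quasibinomial fits equal the brute-force IRLS oracle", {
  set.seed(42)
  for (i in 1:20) {
    n_lib <- sample(c(16L, 32L), 1)
    d <- balanced_design[sample(64, n_lib), ]
    tot <- 10L + stats::rpois(n_lib, 40)
    m <- rbetabinom(tot, runif(1, 0.2, 0.8), 0.05)
    m <- pmin(pmax(m, 1L), tot - 1L)
    f <- fit_gene(m, tot - m, d)
    X <- model.matrix(~ direction + family,
                      data.frame(direction = factor(d$direction),
                                 family = factor(d$family)),
                      contrasts.arg = list(direction = "contr.sum",
                                           family = "contr.sum"))
    o <- irls_oracle(X, m, tot - m)
    expect_equal(unname(f$beta), unname(o$beta), tolerance = 1e-8)
    expect_equal(f$p_intercept, o$p[1], tolerance = 1e-6)
  }
})

test_that("degenerate designs are refused", {
  d <- balanced_design[1:2, ]
  expect_error(fit_gene(c(0L, 0L), c(0L, 0L), d), "positive")
  expect_error(fit_gene(c(5L), c(5L), balanced_design[1:1, ]),
               "positive|saturated")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.02, 0.7, 0.04, 0.2)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("the conservative proportion is a nested, colony-weighted mean", {
  d <- balanced_design[balanced_design$status == "reproductive", ]
  m <- rep(70L, nrow(d)); p <- rep(30L, nrow(d))
  cp <- conservative_proportion(m, p, d)
  expect_equal(cp$mean_maternal_prop, 0.7)
  expect_equal(unname(cp$per_direction_prop), c(0.7, 0.7))

  # colonies at 0.9, 0.9, 0.9 and 0.5 average to 0.8 with equal weights
  colonies <- sort(unique(d$colony))
  m2 <- ifelse(d$colony == colonies[4], 50L, 90L)
  p2 <- ifelse(d$colony == colonies[4], 50L, 10L)
  cp2 <- conservative_proportion(m2, p2, d)
  expect_equal(cp2$mean_maternal_prop, 0.8)
  expect_equal(unname(cp2$per_colony_prop[colonies]), c(0.9, 0.9, 0.9, 0.5))

  # unbalanced library counts: hierarchical mean equals a brute-force
  # nested group-by average and differs from the naive pooled mean
  set.seed(2)
  keep <- sort(c(sample(which(d$tissue == "head"), 14),
                 which(d$tissue == "abdomen")))
  du <- d[keep, ]
  mu <- 20L + stats::rpois(nrow(du), 30)
  pu <- 10L + stats::rpois(nrow(du), 20)
  got <- conservative_proportion(mu, pu, du)
  prop <- mu / (mu + pu)
  l3 <- aggregate(prop, list(du$colony, du$worker_type, du$tissue), mean)
  l2 <- aggregate(l3$x, list(l3[[1]], l3[[2]]), mean)
  l1 <- aggregate(l2$x, list(l2[[1]]), mean)
  expect_equal(got$mean_maternal_prop, mean(l1$x), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(got$mean_maternal_prop, mean(prop))))

  other <- which(d$colony != d$colony[1])[1]
  expect_error(conservative_proportion(
    c(0L, 5L), c(0L, 5L), d[c(1, other), ]), "colony")
})

test_that("classification applies the q-and-proportion rule with consistency", {
  pc <- c(a = 0.62, b = 0.66, c = 0.7, d = 0.61)
  pd <- c(initial = 0.65, reciprocal = 0.65)
  expect_equal(classify_gene(0.04, 0.65, pc, pd), "MATERNAL")
  expect_equal(classify_gene(0.06, 0.65, pc, pd), "BIALLELIC")  # fails q
  expect_equal(classify_gene(0.04, 0.55, pc, pd), "BIALLELIC")  # fails prop
  # one colony on the wrong side of 0.5 vetoes the parent call
  expect_equal(classify_gene(0.04, 0.65, c(pc[1:3], d = 0.45), pd),
               "BIALLELIC")
  expect_equal(classify_gene(0.04, 0.35, 1 - pc, 1 - pd), "PATERNAL")
  # direction-straddling bias is lineage, never a parent call
  lin <- c(initial = 0.8, reciprocal = 0.2)
  expect_equal(classify_gene(0.01, 0.5, c(a = 0.8, b = 0.8, c = 0.2,
                                          d = 0.2), lin), "LINEAGE_A")
  expect_equal(classify_gene(0.01, 0.5, c(a = 0.2, b = 0.2, c = 0.8,
                                          d = 0.8),
                             c(initial = 0.2, reciprocal = 0.8)),
               "LINEAGE_B")
})

test_that("maternal and paternal calls swap under column exchange", {
  sim <- small_sim(n_genes = 40, seed = 23)
  gv <- substitute_paternal_zero(aggregate_to_genes(sim$counts))
  fit <- poe(gv, sim$design, status = "reproductive")
  flipped <- gv
  flipped$maternal <- gv$paternal
  flipped$paternal <- gv$maternal
  fit2 <- poe(flipped, sim$design, status = "reproductive")
  m1 <- fit$calls$gene_id[fit$calls$label == "MATERNAL"]
  p2 <- fit2$calls$gene_id[fit2$calls$label == "PATERNAL"]
  expect_gt(length(m1), 0)
  expect_setequal(m1, p2)
  # note: the paternal-zero substitution is deliberately asymmetric, so
  # equality of q is only expected where no substitution occurred
  clean <- gv$gene_id[tapply(pmin(gv$maternal, gv$paternal) > 0,
                             gv$gene_id, all)[gv$gene_id]]
  both <- merge(fit$calls, fit2$calls, by = "gene_id")
  both <- both[both$gene_id %in% clean, ]
  expect_equal(both$q.x, both$q.y, tolerance = 1e-10)
})

test_that("the fitted model recovers planted imprinting", {
  sim <- small_sim(n_genes = 80, seed = 5)
  fit <- run_poe(sim$counts, sim$design, status = "reproductive")
  m <- merge(fit$calls[c("gene_id", "label")],
             sim$truth[c("gene_id", "true_class")])
  for (cls in c("MATERNAL", "PATERNAL")) {
    planted <- m$true_class == cls
    expect_gt(sum(planted), 0)
    expect_gte(mean(m$label[planted] == cls), 0.75)
  }
  expect_equal(sum(m$label %in% c("MATERNAL", "PATERNAL") &
                     !m$true_class %in% c("MATERNAL", "PATERNAL")), 0)
})

test_that("power increases with the planted maternal proportion", {
  sens <- vapply(c(0.6, 0.75, 0.9), function(prop) {
    cfg <- sim_config(n_genes = 40, frac_maternal = 1, frac_paternal = 0,
                      frac_lineage = 0, maternal_prop_imprinted = prop,
                      seed = 303)
    sim <- simulate_allelic_counts(cfg)
    gv <- substitute_paternal_zero(aggregate_to_genes(sim$counts))
    fit <- poe(gv, sim$design, status = "reproductive")
    mean(fit$calls$label == "MATERNAL")
  }, 0)
  expect_true(all(diff(sens) >= 0))
  expect_gte(sens[3], 0.9)
})

test_that("joint and per-status fits expose the expected factors", {
  sim <- small_sim(n_genes = 10, seed = 29)
  gv <- substitute_paternal_zero(aggregate_to_genes(sim$counts))
  joint <- poe(gv, sim$design, status = "joint")
  expect_true(any(grepl("status", colnames(coef(joint)))))
  expect_equal(joint$n_libraries, 64)
  rep_fit <- poe(gv, sim$design, status = "reproductive")
  expect_false(any(grepl("status", colnames(coef(rep_fit)))))
  expect_equal(rep_fit$n_libraries, 32)
  s <- summary(rep_fit)
  expect_s3_class(s, "summary.poe")
  expect_equal(sum(s$label_counts), nrow(rep_fit$calls))
})
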