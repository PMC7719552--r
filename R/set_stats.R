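#' Hypergeometric term enrichment of a study gene set
#'
#' For each annotation term, tests whether the study set contains more
#' term-annotated genes than expected under sampling without replacement
#' from the background: upper-tail hypergeometric probability of
#' observing at least `k` annotated genes when `K` of the `N` background
#' genes carry the term and `n` were drawn.  BH correction across terms.
#'
#' @param study Character vector, a subset of `background`.
#' @param background Character vector, the gene universe.
#' @param annot Named list mapping gene id to a character vector of term
#'   ids (may be partial over the universe).
#' @param q_thresh Threshold stored in the `enriched` column.
#' @return `data.frame` with `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `enriched`, ordered by `p`.
#' @export
hypergeom_enrichment <- function(study, background, annot,
                                 q_thresh = 0.05) {
  study <- unique(study); background <- unique(background)
  if (!all(study %in% background))
    stop("study set must be a subset of the background", call. = FALSE)
  empty <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE)
  if (length(study) == 0) return(empty)

  annot <- annot[names(annot) %in% background]
  gene_terms <- lapply(annot, unique)
  terms <- sort(unique(unlist(gene_terms)))
  if (length(terms) == 0) return(empty)

  N <- length(background); n <- length(study)
  in_study <- names(gene_terms) %in% study
  rows <- lapply(terms, function(t) {
    has <- vapply(gene_terms, function(x) t %in% x, TRUE)
    K <- sum(has); k <- sum(has & in_study)
    data.frame(term = t, k = k, K = K, n = n, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$enriched <- out$q < q_thresh
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail probability that two lists drawn from a common universe
#' share at least the observed number of genes.
#'
#' @param list_a,list_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return List with `overlap` (count) and `p`.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  universe <- unique(universe)
  if (!all(list_a %in% universe) || !all(list_b %in% universe))
    stop("gene lists must be subsets of the universe", call. = FALSE)
  ov <- length(intersect(list_a, list_b))
  p <- phyper(ov - 1, length(list_a),
              length(universe) - length(list_a), length(list_b),
              lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Chi-squared goodness of fit against equal category counts
#'
#' Pearson test of a two-category count vector against a 50/50 split,
#' e.g. maternal vs paternal gene counts within one reproductive status.
#'
#' @param counts Length-2 non-negative count vector.
#' @return List with `statistic`, `df` (1) and `p`.
#' @export
chisq_gof_equal <- function(counts) {
  stopifnot(length(counts) == 2, all(counts >= 0))
  if (sum(counts) == 0) stop("total count is zero", call. = FALSE)
  ht <- suppressWarnings(chisq.test(counts, p = c(0.5, 0.5)))
  list(statistic = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Chi-squared test of independence on a 2x2 table
#'
#' Pearson test with the Yates continuity correction (|ad - bc| reduced
#' by N/2 and floored at zero before squaring), e.g. maternal/paternal
#' counts by reproductive status.
#'
#' @param table 2x2 non-negative count matrix with positive margins.
#' @return List with `statistic`, `df` (1) and `p`.
#' @export
chisq_independence_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has a zero margin", call. = FALSE)
  ht <- suppressWarnings(chisq.test(table, correct = TRUE))
  list(statistic = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Upper-tail chi-squared probability
#'
#' @param statistic Non-negative test statistic.
#' @param df Positive integer degrees of freedom.
#' @return The upper-tail probability.
#' @examples
#' chisq_pvalue(1.3804, 1)  # 0.24
#' @export
chisq_pvalue <- function(statistic, df) {
  if (df <= 0) stop("df must be positive", call. = FALSE)
  stopifnot(statistic >= 0)
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Reciprocal-best-hit ortholog mapping from tabular hit files
#'
#' For each query the best hit is kept (lowest e-value, ties broken by
#' highest score then lexicographic subject id) subject to
#' `evalue <= max_evalue`; a gene pair is an ortholog when the two best
#' hits designate each other.  Consumes outfmt-6-style columns.
#'
#' @param hits_ab,hits_ba `data.frame`s with columns `query`, `subject`,
#'   `evalue`, `score` (A vs B and B vs A searches).
#' @param max_evalue Maximum e-value for a hit to be considered.
#' @return One-to-one `data.frame` (`gene_a`, `gene_b`) sorted by
#'   `gene_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, max_evalue = 1e-3) {
  best <- function(h, label) {
    req <- c("query", "subject", "evalue", "score")
    miss <- which(!stats::complete.cases(h[intersect(req, names(h))]))
    if (!all(req %in% names(h)) || length(miss))
      stop("malformed hit table ", label,
           if (length(miss)) paste0(" at line ", miss[1]) else
             ": missing columns", call. = FALSE)
    h <- h[h$evalue <= max_evalue, , drop = FALSE]
    h <- h[order(h$query, h$evalue, -h$score, h$subject), , drop = FALSE]
    h <- h[!duplicated(h$query), , drop = FALSE]
    setNames(h$subject, h$query)
  }
  ab <- best(hits_ab, "A->B")
  ba <- best(hits_ba, "B->A")
  mutual <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  out <- data.frame(gene_a = mutual, gene_b = unname(ab[mutual]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}
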