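#' @title Per-locus population-genetic summaries and exact tests
#'
#' @description
#' Summaries over reference adults: number of alleles (Na), observed
#' heterozygosity (Ho), Nei's unbiased expected heterozygosity
#' He = (2n/(2n-1)) (1 - sum p_i^2), and Monte-Carlo exact tests for
#' Hardy-Weinberg equilibrium (conditional on allele counts) and for
#' genotypic linkage disequilibrium (G statistic under permutation).
#' @name popgen_stats
NULL

#' Summary statistics for one locus
#'
#' @param g two-column integer matrix of genotypes (0 = missing), or a
#'   data.frame plus `locus`
#' @param locus locus name when `g` is a data.frame
#' @return list: `locus`, `n`, `Na`, `Ho`, `He`
#' @export
summarize_locus <- function(g, locus = NULL) {
  if (is.data.frame(g)) g <- geno_at(g, locus)
  g <- g[!is_missing_pair(g), , drop = FALSE]
  n <- nrow(g)
  if (n < 2) stop("summarize_locus needs >= 2 genotyped individuals")
  alleles <- as.vector(g)
  p <- as.numeric(table(alleles)) / (2 * n)
  Na <- length(p)
  Ho <- mean(g[, 1] != g[, 2])
  He <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  list(locus = locus %||% NA_character_, n = n, Na = Na, Ho = Ho, He = He)
}

# log conditional probability of a genotype table given its allele counts
# (Levene 1949): log P = log n! + h log 2 + sum log c_a! - sum log n_gg! - log (2n)!
log_hwe_table_prob <- function(g) {
  n <- nrow(g)
  h <- sum(g[, 1] != g[, 2])
  ac <- table(as.vector(g))
  gc <- table(paste(g[, 1], g[, 2]))
  lgamma(n + 1) + h * log(2) + sum(lgamma(as.numeric(ac) + 1)) -
    sum(lgamma(as.numeric(gc) + 1)) - lgamma(2 * n + 1)
}

#' Monte-Carlo exact test for Hardy-Weinberg equilibrium
#'
#' Probability-based exact test: the statistic is the conditional probability
#' of the observed genotype table given the allele counts; the null is
#' sampled by randomly re-pairing the observed allele multiset. The p-value
#' uses the add-one convention `(1 + #extreme) / (n_reps + 1)`.
#'
#' @param g two-column genotype matrix or data.frame (+ `locus`)
#' @param locus locus name when `g` is a data.frame
#' @param n_reps Monte-Carlo replicates (default 10000)
#' @param seed RNG seed
#' @return list: `statistic` (log table probability), `df` (NA), `p`,
#'   `n_permutations`
#' @export
hwe_test <- function(g, locus = NULL, n_reps = 10000, seed = NULL) {
  if (is.data.frame(g)) g <- geno_at(g, locus)
  g <- g[!is_missing_pair(g), , drop = FALSE]
  n <- nrow(g)
  pool <- as.vector(g)
  if (length(unique(pool)) < 2) {
    return(list(statistic = 0, df = NA_integer_, p = 1.0, n_permutations = 0L))
  }
  stopifnot(n >= 5)
  if (!is.null(seed)) set.seed(seed)
  obs <- log_hwe_table_prob(g)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    perm <- sample(pool)
    gp <- canonicalize_pair(perm[seq_len(n)], perm[n + seq_len(n)])
    if (log_hwe_table_prob(gp) <= obs + 1e-9) hits <- hits + 1L
  }
  list(statistic = obs, df = NA_integer_, p = (1 + hits) / (n_reps + 1),
       n_permutations = n_reps)
}

g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- tab > 0
  2 * sum(tab[keep] * log(tab[keep] / e[keep]))
}

#' Permutation test for genotypic linkage disequilibrium
#'
#' G (log-likelihood-ratio) statistic on the two-locus genotype contingency
#' table; the null distribution is generated by shuffling one locus'
#' genotypes across individuals (phase-free, genotypic-level test).
#'
#' @param g1,g2 two-column genotype matrices for the two loci (same rows)
#' @param n_reps permutation replicates
#' @param seed RNG seed
#' @return list: `statistic` (G), `df`, `p`, `n_permutations`, `flag`
#' @export
ld_test <- function(g1, g2, n_reps = 10000, seed = NULL) {
  keep <- !is_missing_pair(g1) & !is_missing_pair(g2)
  g1 <- g1[keep, , drop = FALSE]
  g2 <- g2[keep, , drop = FALSE]
  f1 <- paste(g1[, 1], g1[, 2], sep = "/")
  f2 <- paste(g2[, 1], g2[, 2], sep = "/")
  if (length(unique(f1)) < 2 || length(unique(f2)) < 2) {
    return(list(statistic = 0, df = 0L, p = 1.0, n_permutations = 0L,
                flag = "insufficient_variation"))
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- g_statistic(table(f1, f2))
  hits <- 0L
  for (r in seq_len(n_reps)) {
    if (g_statistic(table(f1, sample(f2))) >= obs - 1e-12) hits <- hits + 1L
  }
  df <- (length(unique(f1)) - 1L) * (length(unique(f2)) - 1L)
  list(statistic = obs, df = df, p = (1 + hits) / (n_reps + 1),
       n_permutations = n_reps, flag = NA_character_)
}

#' Bonferroni significance flags
#'
#' @param p vector of p-values
#' @param alpha family-wise error rate
#' @return logical vector: `p <= alpha / length(p)`
#' @export
bonferroni <- function(p, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (!length(p)) return(logical(0))
  p <= alpha / length(p)
}

#' Per-locus summary table for a sample of individuals
#'
#' Mirrors the usual per-species diversity table: n, Na, Ho, He and the
#' Monte-Carlo exact HWE p-value per locus. Loci with fewer than 2 genotyped
#' individuals are excluded with a warning.
#'
#' @param x individuals data.frame
#' @param loci loci to summarize (default: all found)
#' @param n_reps Monte-Carlo replicates for the HWE test
#' @param seed RNG seed
#' @export
popgen_summary <- function(x, loci = NULL, n_reps = 10000, seed = NULL) {
  loci <- loci %||% infer_loci(x)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (loc in loci) {
    g <- geno_at(x, loc)
    g <- g[!is_missing_pair(g), , drop = FALSE]
    if (nrow(g) < 2) {
      warning("locus ", loc, ": fewer than 2 genotyped individuals, excluded")
      next
    }
    s <- summarize_locus(g)
    hw <- if (s$Na >= 2 && s$n >= 5) hwe_test(g, n_reps = n_reps)$p else 1.0
    rows[[loc]] <- data.frame(locus = loc, n = s$n, Na = s$Na, Ho = s$Ho,
                              He = s$He, p_hwe = hw, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
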