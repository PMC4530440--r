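#' @title Power to detect multiple paternity (PrDM-style)
#'
#' @description
#' Monte-Carlo estimation of the probability that a polyandrous litter is
#' recognized as such by the minimal paternal-allele count: parents are drawn
#' from Hardy-Weinberg proportions at the panel's allele frequencies, embryos
#' by Mendelian transmission with sires sampled according to the scenario's
#' skew, and a replicate counts as detected when at least one locus shows
#' three or more (minimally resolved) paternal alleles — the same criterion
#' the empirical pipeline applies, so power statements and data flags are
#' mutually consistent.
#' @name detection_power
NULL

#' Construct a power scenario
#'
#' @param n_sires number of fathers (>= 2)
#' @param skew breeding-success proportions, one per sire, summing to 1
#' @param litter_size number of embryos sampled
#' @export
power_scenario <- function(n_sires, skew, litter_size) {
  stopifnot(n_sires >= 2, length(skew) == n_sires,
            abs(sum(skew) - 1) < 1e-6, all(skew > 0), litter_size >= 1)
  structure(list(n_sires = as.integer(n_sires), skew = skew,
                 litter_size = as.integer(litter_size)),
            class = "power_scenario")
}

#' The four standard mating scenarios
#'
#' Two or three sires, with equal success or the conventional skewed splits
#' (66.7/33.3 and 57/28.5/14.5).
#' @param litter_size litter size applied to each scenario
#' @export
default_scenarios <- function(litter_size) {
  list(
    "2 males (50:50)" = power_scenario(2, c(0.5, 0.5), litter_size),
    "2 males (66.7:33.3)" = power_scenario(2, c(0.667, 0.333), litter_size),
    "3 males (33.3:33.3:33.3)" = power_scenario(3, rep(1 / 3, 3), litter_size),
    "3 males (57:28.5:14.5)" = power_scenario(3, c(0.57, 0.285, 0.145), litter_size)
  )
}

# Vectorized replicate simulation of the per-locus minimum paternal-allele
# count, for R replicates at once. Returns a logical vector: detected
# (some locus reached >= 3) per replicate.
simulate_detection <- function(freqs, n_sires, skew, litter_size, n_reps,
                               mother = NULL, loci = NULL) {
  loci <- loci %||% names(freqs)
  n <- litter_size
  R <- n_reps
  detected <- rep(FALSE, R)
  # sire index per embryo x replicate (shared across loci: one mating event)
  fidx <- matrix(sample.int(n_sires, n * R, replace = TRUE, prob = skew), n, R)
  for (l in loci) {
    al <- as.integer(names(freqs[[l]]$freq))
    p <- as.numeric(freqs[[l]]$freq)
    A <- length(al)
    if (A < 2) next
    idx <- seq_len(A)
    if (!is.null(mother) && !is.null(mother[[l]])) {
      m1 <- rep(match(mother[[l]][1], al), R)
      m2 <- rep(match(mother[[l]][2], al), R)
      if (anyNA(m1) || anyNA(m2)) stop("mother allele absent from frequency table at ", l)
    } else {
      m1 <- sample(idx, R, replace = TRUE, prob = p)
      m2 <- sample(idx, R, replace = TRUE, prob = p)
    }
    # father alleles: n_sires x R each
    F1 <- matrix(sample(idx, n_sires * R, replace = TRUE, prob = p), n_sires, R)
    F2 <- matrix(sample(idx, n_sires * R, replace = TRUE, prob = p), n_sires, R)
    repcol <- rep(seq_len(R), each = n)
    fi <- cbind(as.vector(fidx), repcol)
    coin <- stats::runif(n * R) < 0.5
    pat <- ifelse(coin, F1[fi], F2[fi])
    mcoin <- stats::runif(n * R) < 0.5
    mat <- ifelse(mcoin, m1[repcol], m2[repcol])
    Mlo <- pmin(m1, m2)[repcol]
    Mhi <- pmax(m1, m2)[repcol]
    elo <- pmin(pat, mat)
    ehi <- pmax(pat, mat)
    amb <- elo != ehi & elo == Mlo & ehi == Mhi
    # observer's determined paternal allele (NA when ambiguous)
    e1m <- elo == Mlo | elo == Mhi
    detal <- ifelse(amb, NA_integer_, ifelse(e1m, ehi, elo))
    # distinct determined alleles per replicate
    pres <- matrix(FALSE, A, R)
    ok <- !is.na(detal)
    pres[cbind(detal[ok], repcol[ok])] <- TRUE
    ndet <- colSums(pres)
    ambany <- colSums(matrix(amb, n, R)) > 0
    hitM <- pres[cbind(pmin(m1, m2), seq_len(R))] | pres[cbind(pmax(m1, m2), seq_len(R))]
    mincount <- ndet + as.integer(ambany & !hitM)
    detected <- detected | (mincount >= 3)
  }
  detected
}

#' Probability of detecting multiple mating
#'
#' @param scenario a [power_scenario()]
#' @param freqs `allele_freqs` for the locus panel
#' @param n_reps Monte-Carlo replicates (default 10000)
#' @param seed RNG seed
#' @param mother optional fixed mother genotype (named list locus -> c(a1, a2));
#'   when NULL the mother is drawn from HWE each replicate
#' @return list: `p_detect`, `mc_se` (= sqrt(p(1-p)/n_reps)), `n_reps`, `seed`
#' @export
prdm <- function(scenario, freqs, n_reps = 10000, seed = NULL, mother = NULL) {
  stopifnot(inherits(scenario, "power_scenario"))
  if (!is.null(seed)) set.seed(seed)
  na <- vapply(freqs, function(f) length(f$freq), 0L)
  if (all(na <= 2)) {
    warning("panel has no locus with more than 2 alleles; detection impossible")
    return(list(p_detect = 0, mc_se = 0, n_reps = n_reps, seed = seed))
  }
  det <- simulate_detection(freqs, scenario$n_sires, scenario$skew,
                            scenario$litter_size, n_reps, mother = mother)
  p <- mean(det)
  list(p_detect = p, mc_se = sqrt(p * (1 - p) / n_reps),
       n_reps = n_reps, seed = seed)
}

#' Power table across scenarios and litter sizes
#'
#' @param freqs `allele_freqs`
#' @param litter_sizes integer vector (table columns)
#' @param scenarios either NULL (the four [default_scenarios()]) or a list of
#'   `list(n_sires, skew)` entries (table rows)
#' @param n_reps,seed Monte-Carlo control
#' @return numeric matrix of detection percentages (scenario x litter size)
#' @export
power_table <- function(freqs, litter_sizes, scenarios = NULL,
                        n_reps = 10000, seed = NULL) {
  stopifnot(length(litter_sizes) >= 1)
  if (is.null(scenarios)) {
    proto <- default_scenarios(litter_sizes[1])
    scenarios <- lapply(proto, function(s) list(n_sires = s$n_sires, skew = s$skew))
  }
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, length(scenarios), length(litter_sizes),
                dimnames = list(names(scenarios), as.character(litter_sizes)))
  for (i in seq_along(scenarios)) {
    for (j in seq_along(litter_sizes)) {
      sc <- power_scenario(scenarios[[i]]$n_sires, scenarios[[i]]$skew,
                           litter_sizes[j])
      suppressWarnings(
        out[i, j] <- 100 * prdm(sc, freqs, n_reps = n_reps)$p_detect)
    }
  }
  out
}
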