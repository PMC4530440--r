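#' @title Minimum-sire parentage reconstruction
#'
#' @description
#' With a known mother and unsampled fathers, the maternal contribution is
#' subtracted from each embryo genotype: when exactly one embryo allele can be
#' maternal the other is an obligate (determined) paternal allele; when the
#' embryo shares both alleles with a heterozygous mother the paternal allele
#' is ambiguous between the mother's two alleles. Because all embryos of a
#' litter share one mother, every ambiguous paternal-candidate set equals the
#' mother's allele pair, which keeps the minimum paternal-allele count and the
#' per-father feasibility checks exact and cheap. A litter showing three or
#' more (minimally resolved) paternal alleles at any locus is polyandrous; the
#' minimum number of sires is the smallest k for which an assignment of
#' embryos to k father genotypes is Mendel-consistent at every locus,
#' enumerated exhaustively with likelihood-ranked solutions.
#' @name paternity_inference
NULL

# Per-locus, per-embryo paternal constraints for one litter.
# det[e, l]   = determined paternal allele (NA when ambiguous / missing / incompatible)
# amb[e, l]   = paternal allele ambiguous between the mother's two alleles
# geno[e, l]  = embryo genotyped at l (and mother genotyped)
# incompat[e, l] = embryo carries no allele the mother could have transmitted
paternal_constraints <- function(litter, loci = NULL) {
  loci <- loci %||% intersect(infer_loci(litter$mother), infer_loci(litter$embryos))
  keep <- vapply(loci, function(l) {
    !is_missing_pair(geno_at(litter$mother, l))
  }, TRUE)
  loci <- loci[keep]
  emb <- litter$embryos
  ne <- nrow(emb)
  nl <- length(loci)
  det <- matrix(NA_integer_, ne, nl, dimnames = list(emb$sample_id, loci))
  amb <- matrix(FALSE, ne, nl, dimnames = dimnames(det))
  geno <- matrix(FALSE, ne, nl, dimnames = dimnames(det))
  incompat <- matrix(FALSE, ne, nl, dimnames = dimnames(det))
  mother <- list()
  for (j in seq_len(nl)) {
    l <- loci[j]
    M <- as.integer(geno_at(litter$mother, l)[1, ])
    mother[[l]] <- M
    g <- geno_at(emb, l)
    ok <- !is_missing_pair(g)
    geno[, j] <- ok
    for (i in which(ok)) {
      e1 <- g[i, 1]; e2 <- g[i, 2]
      in1 <- e1 %in% M; in2 <- e2 %in% M
      if (e1 == e2) {
        if (in1) det[i, j] <- e1 else incompat[i, j] <- TRUE
      } else if (in1 && in2) {
        amb[i, j] <- TRUE                 # mother heterozygous, embryo = mother
      } else if (in1) {
        det[i, j] <- e2
      } else if (in2) {
        det[i, j] <- e1
      } else {
        incompat[i, j] <- TRUE
      }
    }
  }
  mismatch <- rownames(det)[rowSums(incompat) >= 2]
  list(loci = loci, mother = mother, emb_ids = emb$sample_id,
       det = det, amb = amb, geno = geno, incompat = incompat,
       mismatched_embryos = mismatch)
}

#' Deduce paternal alleles for a litter
#'
#' Subtracts the maternal contribution per embryo per locus and summarizes:
#' obligate paternal alleles (not carriable by the mother), all determined
#' paternal alleles, the number of ambiguous embryos, and the minimum number
#' of distinct paternal alleles over all resolutions of the ambiguity.
#' Embryos incompatible with the mother at two or more loci are flagged
#' `maternal_mismatch` and excluded.
#'
#' @param litter a `litter` object
#' @param loci loci to use (default: all with a genotyped mother)
#' @return a `paternal_summary`: `per_locus` data.frame (with list columns
#'   `obligate`, `determined`), `mismatched_embryos`, and the raw constraints
#' @export
deduce_paternal_alleles <- function(litter, loci = NULL) {
  pc <- paternal_constraints(litter, loci)
  keep <- !(pc$emb_ids %in% pc$mismatched_embryos)
  rows <- lapply(seq_along(pc$loci), function(j) {
    l <- pc$loci[j]
    M <- pc$mother[[l]]
    dets <- pc$det[keep, j]
    D <- sort(unique(dets[!is.na(dets)]))
    namb <- sum(pc$amb[keep, j])
    counted <- sum(!is.na(dets)) + namb
    minc <- if (counted == 0) {
      NA_integer_
    } else {
      as.integer(length(D) + (namb > 0 && !any(D %in% M)))
    }
    data.frame(locus = l,
               obligate = I(list(setdiff(D, M))),
               determined = I(list(D)),
               n_ambiguous = namb,
               min_paternal_count = minc,
               stringsAsFactors = FALSE)
  })
  structure(list(per_locus = do.call(rbind, rows),
                 mother = pc$mother,
                 mismatched_embryos = pc$mismatched_embryos,
                 constraints = pc),
            class = "paternal_summary")
}

#' Flag a litter as polyandrous
#'
#' TRUE when at least one locus carries three or more paternal alleles under
#' the minimal (conservative) resolution of ambiguous embryos.
#' @param summary a `paternal_summary` from [deduce_paternal_alleles()]
#' @export
flag_polyandry <- function(summary) {
  any(summary$per_locus$min_paternal_count >= 3, na.rm = TRUE)
}

# HWE prior of an unordered father genotype c(a, b) at a locus
hwe_genotype_prior <- function(freqs, locus, g) {
  if (is.null(freqs[[locus]])) return(if (g[1] == g[2]) 1 else 2)
  p <- allele_freq_of(freqs, locus, g)
  if (g[1] == g[2]) p[1]^2 else 2 * p[1] * p[2]
}

# candidate father genotypes at one locus for one group of embryos, plus
# their weights prior(g) * prod over embryos of transmission probability
father_locus_options <- function(R, has_amb, M, pool, group_det, n_amb, freqs, locus) {
  opts <- list()
  if (length(R) == 2) {
    opts <- list(sort(R))
  } else if (length(R) == 1) {
    if (has_amb && !(R %in% M)) {
      opts <- lapply(unique(M), function(m) sort(c(R, m)))
    } else {
      opts <- lapply(pool, function(x) sort(c(R, x)))
    }
  } else {
    if (has_amb) {
      opts <- list()
      for (m in unique(M)) for (x in pool) opts[[length(opts) + 1L]] <- sort(c(m, x))
    } else {
      w <- pool[1]  # wildcard: homozygote for the most frequent allele
      opts <- list(c(w, w))
    }
  }
  opts <- unique(opts)
  wts <- vapply(opts, function(g) {
    tr <- 1
    if (length(group_det)) {
      tr <- prod(((g[1] == group_det) + (g[2] == group_det)) / 2)
    }
    if (n_amb > 0) {
      tr <- tr * (((g[1] %in% M) + (g[2] %in% M)) / 2)^n_amb
    }
    hwe_genotype_prior(freqs, locus, g) * tr
  }, 0)
  keep <- wts > 0
  list(genotypes = opts[keep], weights = wts[keep])
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Reconstruct the minimum number of sires for a litter
#'
#' Exhaustive search: the smallest k (up to `max_k`) is found for which the
#' embryos can be partitioned among k father genotypes that are
#' Mendel-consistent with every embryo at every locus; all consistent
#' partitions at that k are enumerated (depth-first with symmetry breaking),
#' and for each partition all father multilocus genotypes restricted to the
#' litter's paternal-candidate alleles (plus a homozygous-completion wildcard
#' at the most frequent population allele). Solutions are ranked by
#' `prior(fathers under HWE) x Mendelian transmission likelihood`, normalized
#' over the full enumerated set. A solution is a (fathers, embryo-assignment)
#' pair; assignments differing only in which of two equally compatible
#' fathers an embryo goes to are distinct solutions, as in GERUD-style
#' reporting.
#'
#' @param litter a `litter` object (embryos flagged `maternal_mismatch` are
#'   dropped automatically)
#' @param freqs `allele_freqs` for the HWE father-genotype prior
#' @param max_k largest number of sires to consider
#' @param max_solutions cap on reported solutions; `1` gives the fastest
#'   minimum-k determination (first consistent partition wins)
#' @param expand_cap per-partition cap on explicit genotype combinations;
#'   larger partitions report only their best combination
#' @param max_nodes search-node budget before the enumeration is flagged
#'   truncated
#' @param loci loci to use
#' @return a `sire_solutions` object; `$k` is the minimum sire count,
#'   `$solutions` the ranked solutions (fathers, assignment, skew,
#'   `relative_probability`), `$skew_string` the assigned-embryo skew of the
#'   best solution. `$unresolved` is TRUE when no k <= `max_k` fits.
#' @export
min_sires <- function(litter, freqs, max_k = 4, max_solutions = 1000,
                      expand_cap = 200, max_nodes = 1e6, loci = NULL) {
  ps <- deduce_paternal_alleles(litter, loci)
  pc <- ps$constraints
  keep <- which(!(pc$emb_ids %in% pc$mismatched_embryos))
  if (!length(keep)) stop("no embryos available for reconstruction")
  loci <- pc$loci
  nl <- length(loci)
  det <- pc$det[keep, , drop = FALSE]
  amb <- pc$amb[keep, , drop = FALSE]
  ids <- pc$emb_ids[keep]
  ne <- length(ids)
  M <- pc$mother

  # per-locus candidate allele pool, most frequent population allele first
  pool <- lapply(seq_len(nl), function(j) {
    l <- loci[j]
    cand <- unique(stats::na.omit(det[, j]))
    if (any(amb[, j])) cand <- union(cand, M[[l]])
    w <- if (!is.null(freqs[[l]])) top_allele(freqs, l) else
      if (length(cand)) cand[1] else M[[l]][1]
    unique(c(w, sort(cand)))
  })
  names(pool) <- loci

  if (nl == 0) stop("no informative locus for reconstruction")

  # most-constrained embryos first for pruning; every embryo is treated as
  # distinct and each set partition is enumerated exactly once (fathers
  # canonically numbered by first use: restricted-growth order)
  richness <- rowSums(!is.na(det))
  order_emb <- order(-richness)

  kmin <- max(1L, max(c(1L, ceiling(ps$per_locus$min_paternal_count / 2)), na.rm = TRUE))
  partition_cap <- max(50L, max_solutions)

  nodes <- 0L
  truncated_search <- FALSE

  search_k <- function(k) {
    partitions <- list()
    assign_vec <- integer(ne)
    fdet <- rep(list(rep(list(integer(0)), nl)), k)
    famb <- matrix(FALSE, k, nl)
    fn <- integer(k)
    done <- FALSE

    feasible_add <- function(f, e) {
      for (j in seq_len(nl)) {
        d <- det[e, j]
        if (!is.na(d)) {
          D <- fdet[[f]][[j]]
          if (!(d %in% D)) {
            if (length(D) >= 2) return(NULL)
            D <- c(D, d)
          }
          if (length(D) == 2 && (famb[f, j] || amb[e, j]) &&
              !any(D %in% M[[loci[j]]])) return(NULL)
          fdet[[f]][[j]] <<- D
        } else if (amb[e, j]) {
          D <- fdet[[f]][[j]]
          if (length(D) == 2 && !any(D %in% M[[loci[j]]])) return(NULL)
          famb[f, j] <<- TRUE
        }
      }
      TRUE
    }

    dfs <- function(i, open) {
      if (done) return()
      nodes <<- nodes + 1L
      if (nodes > max_nodes) { truncated_search <<- TRUE; done <<- TRUE; return() }
      if (i > ne) {
        if (open == k) {
          partitions[[length(partitions) + 1L]] <<- assign_vec
          if (length(partitions) >= partition_cap) done <<- TRUE
        }
        return()
      }
      if (ne - i + 1L < k - open) return()   # cannot open all k fathers
      e <- order_emb[i]
      hi <- min(open + 1L, k)
      for (f in seq_len(hi)) {
        saved_det <- fdet; saved_amb <- famb
        ok <- feasible_add(f, e)
        if (!is.null(ok)) {
          assign_vec[i] <<- f
          fn[f] <<- fn[f] + 1L
          dfs(i + 1L, max(open, f))
          fn[f] <<- fn[f] - 1L
        }
        fdet <<- saved_det; famb <<- saved_amb
        if (done) return()
      }
    }
    dfs(1L, 0L)
    partitions
  }

  partitions <- NULL
  k_found <- NA_integer_
  for (k in kmin:max_k) {
    if (k > ne) break
    p <- search_k(k)
    if (length(p)) { partitions <- p; k_found <- k; break }
    if (truncated_search) break
  }
  if (is.na(k_found)) {
    return(structure(list(unresolved = TRUE, max_k = max_k, k = NA_integer_,
                          solutions = list(), n_embryos = ne,
                          mismatched_embryos = pc$mismatched_embryos,
                          truncated_search = truncated_search,
                          summary = ps),
                     class = "sire_solutions"))
  }
  k <- k_found

  # ---- score partitions and enumerate explicit solutions ----
  solutions <- list()
  part_logW <- numeric(length(partitions))
  truncated_expand <- FALSE

  for (pi in seq_along(partitions)) {
    av <- partitions[[pi]]                      # father index per DFS position
    logmult <- 0                                # labeled enumeration: exact
    # per father x locus genotype options
    opt <- vector("list", k)
    logW <- logmult
    feasible <- TRUE
    for (f in seq_len(k)) {
      grp <- order_emb[av == f]
      opt[[f]] <- vector("list", nl)
      for (j in seq_len(nl)) {
        l <- loci[j]
        dets <- det[grp, j]
        dets <- dets[!is.na(dets)]
        R <- sort(unique(dets))
        namb <- sum(amb[grp, j])
        o <- father_locus_options(R, namb > 0, M[[l]], pool[[j]],
                                  dets, namb, freqs, l)
        if (!length(o$weights)) { feasible <- FALSE; break }
        opt[[f]][[j]] <- o
        logW <- logW + log(sum(o$weights))
      }
      if (!feasible) break
    }
    if (!feasible) { part_logW[pi] <- -Inf; next }
    part_logW[pi] <- logW

    n_comb <- prod(vapply(opt, function(of) prod(lengths(lapply(of, `[[`, "weights"))), 0))
    # map DFS assignment back to embryo ids (original order)
    assignment <- stats::setNames(integer(ne), ids)
    assignment[order_emb] <- av
    skew <- tabulate(assignment, k)

    emit <- function(choice) {
      fathers <- vector("list", k)
      logp <- logmult
      for (f in seq_len(k)) {
        gm <- matrix(NA_integer_, nl, 2, dimnames = list(loci, c("a1", "a2")))
        for (j in seq_len(nl)) {
          o <- opt[[f]][[j]]
          ci <- choice[[f]][j]
          gm[j, ] <- o$genotypes[[ci]]
          logp <- logp + log(o$weights[ci])
        }
        fathers[[f]] <- gm
      }
      solutions[[length(solutions) + 1L]] <<- list(
        k = k, fathers = fathers, assignment = assignment,
        skew = skew, log_prob = logp, log_mult = logmult)
    }

    if (n_comb <= expand_cap) {
      # full cross-product over per-father per-locus genotype choices
      idx <- rep(list(NULL), k)
      rec <- function(f, choice) {
        if (f > k) { emit(choice); return() }
        counts <- lengths(lapply(opt[[f]], `[[`, "weights"))
        grid <- as.matrix(expand.grid(lapply(counts, seq_len)))
        for (r in seq_len(nrow(grid))) {
          choice[[f]] <- grid[r, ]
          rec(f + 1L, choice)
        }
      }
      rec(1L, idx)
    } else {
      truncated_expand <- TRUE
      best <- lapply(opt, function(of) vapply(of, function(o) which.max(o$weights), 0L))
      emit(best)
    }
  }

  total_log <- logsumexp(part_logW)
  ord <- order(vapply(solutions, `[[`, 0, "log_prob"), decreasing = TRUE)
  solutions <- solutions[ord]
  if (length(solutions) > max_solutions) {
    solutions <- solutions[seq_len(max_solutions)]
    truncated_expand <- TRUE
  }
  for (s in seq_along(solutions)) {
    solutions[[s]]$relative_probability <- exp(solutions[[s]]$log_prob - total_log)
  }

  # embryos whose assignment differs across equally-best solutions
  unassigned <- character(0)
  if (length(solutions) > 1) {
    best_lp <- solutions[[1]]$log_prob
    tied <- Filter(function(s) s$log_prob >= best_lp - 1e-9, solutions)
    if (length(tied) > 1) {
      amat <- vapply(tied, `[[`, solutions[[1]]$assignment, "assignment")
      vary <- apply(amat, 1, function(r) length(unique(r)) > 1)
      unassigned <- ids[vary]
    }
  }
  best <- solutions[[1]]
  keep_assigned <- !(names(best$assignment) %in% unassigned)
  skew_assigned <- tabulate(best$assignment[keep_assigned], k)

  structure(list(
    unresolved = FALSE, k = k, solutions = solutions,
    n_embryos = ne, mismatched_embryos = pc$mismatched_embryos,
    unassigned_embryos = unassigned,
    skew_assigned = skew_assigned,
    skew_string = paste(skew_assigned, collapse = ":"),
    total_log_lik = total_log,
    n_partitions = length(partitions),
    truncated_search = truncated_search,
    truncated_solutions = truncated_expand,
    summary = ps), class = "sire_solutions")
}

#' @export
print.sire_solutions <- function(x, ...) {
  if (isTRUE(x$unresolved)) {
    cat("unresolved: no consistent solution with k <=", x$max_k, "\n")
    return(invisible(x))
  }
  cat("minimum sires:", x$k, " (", length(x$solutions), "solutions,",
      x$n_partitions, "partitions)\n")
  cat("best skew:", x$skew_string,
      sprintf(" relative probability %.3g\n", x$solutions[[1]]$relative_probability))
  invisible(x)
}

#' Mendelian segregation test for a monandrous litter
#'
#' For each locus at which the single reconstructed father is heterozygous,
#' counts of embryos inheriting each paternal allele are tested against the
#' expected 1:1 ratio (chi-square, 1 df, no continuity correction); per-locus
#' p-values are combined with Fisher's method (-2 sum log p, chi-square with
#' 2m df).
#'
#' @param litter a `litter` object
#' @param sires a `sire_solutions` with `k == 1`
#' @return list: `chi2`, `df`, `p`, `per_locus` data.frame; `df = 0` and
#'   `p = NA` when no locus is informative
#' @export
mendelian_segregation_test <- function(litter, sires) {
  stopifnot(inherits(sires, "sire_solutions"), !isTRUE(sires$unresolved))
  if (sires$k != 1) stop("segregation test applies to monandrous litters (k = 1)")
  father <- sires$solutions[[1]]$fathers[[1]]
  pc <- sires$summary$constraints
  keep <- !(pc$emb_ids %in% pc$mismatched_embryos)
  rows <- list()
  for (j in seq_along(pc$loci)) {
    l <- pc$loci[j]
    g <- father[l, ]
    if (g[1] == g[2]) next                       # homozygous father: uninformative
    counts <- c(0L, 0L)
    for (i in which(keep)) {
      d <- pc$det[i, j]
      if (!is.na(d)) {
        if (d == g[1]) counts[1] <- counts[1] + 1L
        else if (d == g[2]) counts[2] <- counts[2] + 1L
      } else if (pc$amb[i, j]) {
        hit <- intersect(pc$mother[[l]], g)
        if (length(hit) == 1) {
          counts[which(g == hit)[1]] <- counts[which(g == hit)[1]] + 1L
        }
      }
    }
    n <- sum(counts)
    if (n < 1) next
    chi2 <- (counts[1] - counts[2])^2 / n
    p <- stats::pchisq(chi2, 1, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = l, allele_a = g[1], allele_b = g[2],
      n_a = counts[1], n_b = counts[2], chi2 = chi2, p = p,
      stringsAsFactors = FALSE)
  }
  per_locus <- do.call(rbind, rows)
  if (is.null(per_locus) || nrow(per_locus) == 0) {
    return(list(chi2 = NA_real_, df = 0L, p = NA_real_, per_locus = per_locus,
                note = "no informative locus"))
  }
  chi2 <- -2 * sum(log(per_locus$p))
  df <- 2L * nrow(per_locus)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       per_locus = per_locus)
}

compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (x in 0:n) {
    sub <- compositions(n - x, k - 1)
    out[[length(out) + 1L]] <- cbind(x, sub)
  }
  do.call(rbind, out)
}

#' Exact test for paternity skew
#'
#' Tests the embryo counts per sire against equal contributions: exact
#' two-sided binomial (minimum-likelihood ordering) for two sires, exact
#' multinomial for three or more (full enumeration up to n = 30, Monte Carlo
#' beyond).
#'
#' @param counts integer vector of embryos per sire (length >= 2)
#' @param n_reps Monte-Carlo replicates for large multinomial cases
#' @param seed RNG seed for the Monte-Carlo branch
#' @return list: `counts`, `statistic` (probability of the observed split),
#'   `p`, `test_name`
#' @export
skew_test <- function(counts, n_reps = 1e5, seed = NULL) {
  k <- length(counts)
  n <- sum(counts)
  stopifnot(k >= 2, n >= 1)
  if (k == 2) {
    dens <- stats::dbinom(0:n, n, 0.5)
    obs <- dens[counts[1] + 1]
    p <- sum(dens[dens <= obs * (1 + 1e-7)])
    return(list(counts = counts, statistic = obs, p = min(p, 1),
                test_name = "exact_binomial"))
  }
  logp_of <- function(x) lgamma(n + 1) - sum(lgamma(x + 1)) + n * log(1 / k)
  obs_lp <- logp_of(counts)
  if (n <= 30) {
    comp <- compositions(n, k)
    lps <- apply(comp, 1, logp_of)
    p <- sum(exp(lps[lps <= obs_lp + 1e-9]))
    return(list(counts = counts, statistic = exp(obs_lp), p = min(p, 1),
                test_name = "exact_multinomial"))
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(n_reps, n, rep(1 / k, k))
  lps <- apply(draws, 2, logp_of)
  p <- (1 + sum(lps <= obs_lp + 1e-9)) / (n_reps + 1)
  list(counts = counts, statistic = exp(obs_lp), p = p,
       test_name = "mc_multinomial")
}

# drop embryos (e.g. hybrids) from a litter before reconstruction
drop_embryos <- function(litter, ids) {
  if (!length(ids)) return(litter)
  litter$embryos <- litter$embryos[!(litter$embryos$sample_id %in% ids), , drop = FALSE]
  litter
}

#' One study-report row for a litter
#'
#' @param litter a `litter` object
#' @param species species label of the litter (from the diagnostic calls)
#' @param sires `sire_solutions` for the litter
#' @param skew_res result of [skew_test()] (polyandrous litters), or NULL
#' @param segr_res result of [mendelian_segregation_test()] (monandrous), or NULL
#' @param n_excluded embryos excluded before reconstruction (hybrids etc.)
#' @export
litter_report <- function(litter, species, sires, skew_res = NULL,
                          segr_res = NULL, n_excluded = 0L) {
  polyandrous <- !isTRUE(sires$unresolved) && sires$k >= 2
  data.frame(
    mother_id = litter$mother$sample_id,
    species = species,
    tl_mm = litter$mother$tl_mm %||% NA_real_,
    n_embryos = nrow(litter$embryos),
    n_excluded = n_excluded + length(sires$mismatched_embryos),
    polyandrous = polyandrous,
    k = if (isTRUE(sires$unresolved)) NA_integer_ else sires$k,
    skew = if (isTRUE(sires$unresolved)) NA_character_ else sires$skew_string,
    best_prob = if (isTRUE(sires$unresolved)) NA_real_ else
      sires$solutions[[1]]$relative_probability,
    n_unassigned = if (isTRUE(sires$unresolved)) NA_integer_ else
      length(sires$unassigned_embryos),
    p_skew = if (is.null(skew_res)) NA_real_ else skew_res$p,
    p_segregation = if (is.null(segr_res)) NA_real_ else segr_res$p,
    stringsAsFactors = FALSE
  )
}

#' Run the full paternity stage over a list of litters
#'
#' For every litter: paternal-allele deduction, polyandry flag, minimum-sire
#' reconstruction, then a skew test (k >= 2) or the Mendelian segregation
#' test (k = 1). Hybrid embryos can be excluded (but the litter is kept).
#'
#' @param litters list of `litter` objects (from [build_litters()])
#' @param freqs `allele_freqs`
#' @param species named character: species label per mother id (optional)
#' @param exclude_embryos ids of embryos to drop before reconstruction
#' @param max_k,max_solutions passed to [min_sires()]
#' @param loci loci used for reconstruction (default: the loci of `freqs`,
#'   i.e. the polymorphic panel; diagnostic loci stay out of paternity)
#' @param seed RNG seed (Monte-Carlo skew branch)
#' @return list: `report` (one row per litter), `details` (per-litter list of
#'   the stage objects)
#' @export
analyze_litters <- function(litters, freqs, species = NULL,
                            exclude_embryos = character(0),
                            max_k = 4, max_solutions = 200,
                            loci = names(freqs), seed = NULL) {
  rows <- list()
  details <- list()
  for (mid in names(litters)) {
    lit0 <- litters[[mid]]
    lit <- drop_embryos(lit0, exclude_embryos)
    n_excl <- nrow(lit0$embryos) - nrow(lit$embryos)
    sires <- min_sires(lit, freqs, max_k = max_k, max_solutions = max_solutions,
                       loci = intersect(loci, infer_loci(lit$mother)))
    skew_res <- segr_res <- NULL
    if (!isTRUE(sires$unresolved)) {
      if (sires$k >= 2) {
        sk <- sires$skew_assigned
        if (sum(sk) >= 1) skew_res <- skew_test(sk, seed = seed)
      } else {
        segr_res <- mendelian_segregation_test(lit, sires)
      }
    }
    sp <- if (!is.null(species) && mid %in% names(species)) species[[mid]] else NA_character_
    rows[[mid]] <- litter_report(lit, sp, sires, skew_res, segr_res, n_excl)
    details[[mid]] <- list(sires = sires, skew_test = skew_res,
                           segregation = segr_res)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report, details = details)
}
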