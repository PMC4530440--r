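# Builders for tiny in-code fixtures and the independent oracles used by the
# derived-value tests. Oracles deliberately use different algorithms from the
# package (inclusion-exclusion / full enumeration).

# one-row individual with genotypes given as list(locus = c(a1, a2))
make_ind <- function(id, role, genotypes, mother_id = NA_character_,
                     species_hint = NA_character_, tl_mm = NA_real_) {
  base <- data.frame(sample_id = id, role = role, mother_id = mother_id,
                     species_hint = species_hint, tl_mm = tl_mm,
                     stringsAsFactors = FALSE)
  for (l in names(genotypes)) {
    g <- sort(as.integer(genotypes[[l]]))
    if (any(g == 0L)) g <- c(0L, 0L)
    base[[paste0(l, "_1")]] <- g[1]
    base[[paste0(l, "_2")]] <- g[2]
  }
  base
}

# rbind individuals, filling absent locus columns with 0
make_table <- function(...) {
  rows <- list(...)
  cols <- unique(unlist(lapply(rows, colnames)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, colnames(r))) {
      r[[cc]] <- if (grepl("_[12]$", cc)) 0L else NA
    }
    r[, cols]
  })
  do.call(rbind, rows)
}

make_litter <- function(mother, embryos) {
  structure(list(mother = mother, embryos = embryos), class = "litter")
}

# litter from compact genotype lists
quick_litter <- function(mother_geno, embryo_genos, id = "M1") {
  mom <- make_ind(id, "mother", mother_geno)
  embs <- do.call(make_table, lapply(seq_along(embryo_genos), function(i) {
    make_ind(sprintf("%sE%02d", id, i), "embryo", embryo_genos[[i]],
             mother_id = id)
  }))
  make_litter(mom, embs)
}

uniform_freqs <- function(loci_alleles, n = 100L) {
  allele_freqs(lapply(loci_alleles, function(al) {
    stats::setNames(rep(1 / length(al), length(al)), al)
  }), n = n)
}

# ---- independent minimum-sire oracle -------------------------------------
# Inclusion-exclusion over father-genotype subsets: for a set G of candidate
# multilocus genotypes, the total likelihood of all surjective assignments of
# embryos to a k-subset S is sum over T subseteq S of (-1)^(|S|-|T|)
# prod_e sum_{g in T} W[e, g]; W[e, g] is the embryo's Mendelian transmission
# weight. Completely different algorithm from the package's partition DFS.
oracle_min_sires <- function(litter, freqs, max_k = 3) {
  loci <- intersect(litterkin::infer_loci(litter$mother),
                    litterkin::infer_loci(litter$embryos))
  M <- lapply(loci, function(l) {
    as.integer(litter$mother[, paste0(l, c("_1", "_2"))])
  })
  names(M) <- loci
  ne <- nrow(litter$embryos)
  # candidate paternal sets per embryo x locus
  cand <- list()
  for (l in loci) {
    cl <- list()
    for (i in seq_len(ne)) {
      e <- as.integer(litter$embryos[i, paste0(l, c("_1", "_2"))])
      inM <- e %in% M[[l]]
      cl[[i]] <- if (e[1] == e[2]) {
        if (inM[1]) e[1] else stop("oracle fixture incompatible with mother")
      } else if (all(inM)) M[[l]] else if (inM[1]) e[2] else if (inM[2]) e[1] else
        stop("oracle fixture incompatible with mother")
    }
    cand[[l]] <- cl
  }
  # per-locus pool: determined alleles, mother pair if any ambiguity, wildcard
  pool <- lapply(loci, function(l) {
    dets <- unlist(Filter(function(x) length(x) == 1, cand[[l]]))
    ambp <- if (any(vapply(cand[[l]], length, 0L) == 2)) M[[l]] else integer(0)
    f <- freqs[[l]]$freq
    w <- as.integer(names(f)[which.max(f)])
    unique(c(w, sort(unique(c(dets, ambp)))))
  })
  names(pool) <- loci
  pairs <- lapply(pool, function(p) {
    idx <- expand.grid(i = seq_along(p), j = seq_along(p))
    idx <- idx[idx$i <= idx$j, ]
    cbind(p[idx$i], p[idx$j])
  })
  fr_of <- function(l, a) {
    f <- freqs[[l]]$freq[as.character(a)]
    f[is.na(f)] <- 1 / (2 * freqs[[l]]$n + 2)
    unname(f)
  }
  # multilocus genotypes = cross product of per-locus pairs
  grid <- expand.grid(lapply(pairs, function(p) seq_len(nrow(p))))
  G <- nrow(grid)
  prior <- rep(1, G)
  W <- matrix(1, ne, G)
  for (li in seq_along(loci)) {
    l <- loci[li]
    pg <- pairs[[l]][grid[[li]], , drop = FALSE]
    het <- pg[, 1] != pg[, 2]
    prior <- prior * fr_of(l, pg[, 1]) * fr_of(l, pg[, 2]) * ifelse(het, 2, 1)
    for (i in seq_len(ne)) {
      cc <- cand[[l]][[i]]
      W[i, ] <- W[i, ] * (((pg[, 1] %in% cc) + (pg[, 2] %in% cc)) / 2)
    }
  }
  # a father only has to cover its own embryos; feasibility is handled by the
  # surjective subset sums, so keep every genotype with positive prior
  keep <- prior > 0
  prior <- prior[keep]; W <- W[, keep, drop = FALSE]
  G <- sum(keep)

  surj_mass <- function(S) {  # total over surjective assignments, labeled
    kk <- length(S)
    tot <- 0
    for (m in seq_len(2^kk) - 1L) {
      T <- S[bitwAnd(m, 2^(seq_len(kk) - 1L)) > 0]
      if (!length(T)) next
      s <- prod(rowSums(W[, T, drop = FALSE]))
      tot <- tot + (-1)^(kk - length(T)) * s
    }
    tot * prod(prior[S])
  }
  best_labeled <- function(S) {
    kk <- length(S)
    asg <- as.matrix(expand.grid(rep(list(seq_len(kk)), ne)))
    asg <- asg[apply(asg, 1, function(a) length(unique(a)) == kk), , drop = FALSE]
    if (!nrow(asg)) return(0)
    mx <- 0
    for (r in seq_len(nrow(asg))) {
      w <- prod(W[cbind(seq_len(ne), S[asg[r, ]])])
      if (w > mx) mx <- w
    }
    mx * prod(prior[S])
  }
  for (k in 1:max_k) {
    subsets <- utils::combn(G, k)
    masses <- apply(subsets, 2, surj_mass)
    if (any(masses > 1e-300)) {
      total <- sum(masses)
      nz <- which(masses > 1e-300)
      best <- max(vapply(nz, function(ci) best_labeled(subsets[, ci]), 0))
      return(list(k = k, total = total, best_labeled = best))
    }
  }
  list(k = NA_integer_, total = 0, best_labeled = 0)
}

# ---- exact single-locus PrDM oracle --------------------------------------
# Full enumeration of (mother, fathers, per-embryo sire/transmission) for one
# locus; detection = >= 3 minimally resolved paternal alleles.
oracle_min_count <- function(M, emb) {
  det <- integer(0); namb <- 0L
  for (i in seq_len(nrow(emb))) {
    e <- sort(emb[i, ])
    inM <- e %in% M
    if (e[1] == e[2]) det <- c(det, e[1])
    else if (all(inM)) namb <- namb + 1L
    else det <- c(det, if (inM[1]) e[2] else e[1])
  }
  D <- unique(det)
  length(D) + as.integer(namb > 0 && !any(D %in% M))
}

oracle_prdm_1locus <- function(alleles, p, skew, n_emb) {
  stopifnot(length(skew) == 2)
  gt <- expand.grid(i = seq_along(alleles), j = seq_along(alleles))
  gt <- gt[gt$i <= gt$j, ]
  gprob <- p[gt$i] * p[gt$j] * ifelse(gt$i == gt$j, 1, 2)
  # per-embryo outcome code 0..7: sire, paternal allele coin, maternal coin
  outc <- as.matrix(expand.grid(rep(list(0:7), n_emb)))
  sire <- outc %/% 4 + 1
  pc <- (outc %/% 2) %% 2 + 1
  mc <- outc %% 2 + 1
  wout <- apply(matrix(skew[sire], nrow(outc)), 1, prod) * 0.25^n_emb
  total <- 0
  for (mi in seq_len(nrow(gt))) {
    M <- c(alleles[gt$i[mi]], alleles[gt$j[mi]])
    for (f1 in seq_len(nrow(gt))) for (f2 in seq_len(nrow(gt))) {
      Fs <- rbind(c(alleles[gt$i[f1]], alleles[gt$j[f1]]),
                  c(alleles[gt$i[f2]], alleles[gt$j[f2]]))
      pcfg <- gprob[mi] * gprob[f1] * gprob[f2]
      pat <- matrix(Fs[cbind(as.vector(sire), as.vector(pc))], nrow(outc))
      mat <- matrix(M[mc], nrow(outc))
      det <- vapply(seq_len(nrow(outc)), function(r) {
        oracle_min_count(M, cbind(pat[r, ], mat[r, ])) >= 3
      }, TRUE)
      total <- total + pcfg * sum(wout[det])
    }
  }
  total
}
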