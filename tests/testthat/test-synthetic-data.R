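test_that("geometric frequency profiles hit the target diversity", {
  spec <- poly_panel_spec <- litterkin:::poly_panel_spec()
  for (sp in c("A", "B")) {
    fr <- default_polymorphic_panel(sp)
    tab <- spec[[sp]]
    n <- if (sp == "A") 136 else 117
    for (i in seq_len(nrow(tab))) {
      p <- fr[[tab$locus[i]]]$freq
      expect_length(p, tab$Na[i])
      he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      expect_equal(he, tab$He[i], tolerance = 1e-6)
    }
  }
})

test_that("simulated adults follow HWE at the configured frequencies", {
  set.seed(4)
  n <- 10000
  # diallelic 0.7/0.3 check on a custom panel via draw_genotypes
  fr <- allele_freqs(list(L = c("100" = 0.7, "102" = 0.3)))
  g <- litterkin:::draw_genotypes(fr, n)
  hom1 <- mean(g$L_1 == 100 & g$L_2 == 100)
  het <- mean(g$L_1 != g$L_2)
  hom2 <- mean(g$L_1 == 102 & g$L_2 == 102)
  expect_lt(max(abs(c(hom1, het, hom2) - c(0.49, 0.42, 0.09))), 0.02)

  ad <- simulate_adults(50, "A")
  # fixed diagnostic locus: all homozygous for the species allele
  expect_true(all(ad$Gg4_1 == 198 & ad$Gg4_2 == 198))
  # other-species-only loci are missing
  expect_true(all(ad$MaND5_1 == 0 & ad$Mh29_1 == 0))
  expect_true(all(ad$Gg22_1 > 0))
})

test_that("simulate_litter is Mendelian and respects skew", {
  set.seed(6)
  mom <- simulate_adults(1, "B", role = "mother")
  dads <- list(simulate_adults(1, "B", prefix = "d1"),
               simulate_adults(1, "B", prefix = "d2"))
  sim <- simulate_litter(mom, dads, c(0.667, 0.333), 400)
  emb <- sim$litter$embryos
  for (l in names(default_polymorphic_panel("B"))) {
    mg <- litterkin:::geno_at(mom, l)[1, ]
    for (i in seq_len(nrow(emb))) {
      eg <- as.integer(emb[i, paste0(l, c("_1", "_2"))])
      dg <- litterkin:::geno_at(dads[[sim$sire_of[i]]], l)[1, ]
      expect_true(any(eg %in% mg) && any(eg %in% dg))
    }
  }
  expect_lt(abs(mean(sim$sire_of == 1) - 0.667), 0.08)
  # degenerate skew: single sire gets everything
  sim1 <- simulate_litter(mom, dads[1], 1, 20)
  expect_true(all(sim1$sire_of == 1))
})

test_that("same seed gives identical studies; truth sidecar is consistent", {
  cfg <- sim_config(seed = 33, n_adults = c(A = 20, B = 20),
                    n_litters = c(A = 3, B = 2), f = 0.5)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  for (mid in names(s1$truth$litters)) {
    tr <- s1$truth$litters[[mid]]
    expect_equal(sum(tr$sire_counts) + length(tr$hybrid_embryos), tr$n_embryos)
    expect_equal(tr$polyandrous, tr$n_sires >= 2)
  }
  # litter sizes inside the configured species ranges
  sz <- vapply(s1$truth$litters, `[[`, 0, "n_embryos")
  sp <- vapply(s1$truth$litters, `[[`, "", "species")
  expect_true(all(sz[sp == "A"] >= 3 & sz[sp == "A"] <= 18))
  expect_true(all(sz[sp == "B"] >= 9 & sz[sp == "B"] <= 35))
})

test_that("f = 0 studies contain no polyandrous litter, and truth bounds hold", {
  cfg <- sim_config(seed = 21, n_adults = c(A = 40, B = 10),
                    n_litters = c(A = 8, B = 0), f = 0)
  st <- simulate_study(cfg)
  lits <- build_litters(st$table)
  fr <- suppressWarnings(estimate_allele_frequencies(
    st$table[st$table$role == "adult" & st$table$species_hint == "A", ],
    names(default_polymorphic_panel("A"))))
  for (mid in names(lits)) {
    ps <- deduce_paternal_alleles(lits[[mid]], names(fr))
    expect_false(flag_polyandry(ps))
    est <- min_sires(lits[[mid]], fr, max_solutions = 1)
    expect_lte(est$k, st$truth$litters[[mid]]$n_sires)
  }
})

test_that("hybrid embryos land where configured and are detected", {
  cfg <- sim_config(seed = 14, n_adults = c(A = 20, B = 20),
                    n_litters = c(A = 1, B = 2), f = 0,
                    hybrid_litters = data.frame(species = "B", litter = 1,
                                                n_hybrid = 2))
  st <- simulate_study(cfg)
  truth_h <- unlist(lapply(st$truth$litters, `[[`, "hybrid_embryos"))
  expect_length(truth_h, 2)
  calls <- classify_species(st$table)
  expect_setequal(calls$sample_id[calls$label == "hybrid"], truth_h)
})

test_that("scoring error switch perturbs genotypes at roughly the set rate", {
  set.seed(99)
  fr <- default_polymorphic_panel("A")
  g0 <- litterkin:::draw_genotypes(fr, 2000)
  g1 <- litterkin:::apply_scoring_error(g0, fr, 0.02)
  cols <- names(g0)
  rate <- mean(as.matrix(g0[cols]) != as.matrix(g1[cols]))
  # a hit can be invisible (same allele redrawn) or swap order, so observed
  # change rate is below 2 x 0.02 but well above 0
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.05)
})
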