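test_that("paternal alleles are deduced by maternal subtraction", {
  # mother 155/157; three obligate paternal alleles
  lit <- quick_litter(list(L = c(155, 157)),
                      list(list(L = c(157, 161)), list(L = c(157, 163)),
                           list(L = c(155, 165))))
  ps <- deduce_paternal_alleles(lit)
  pl <- ps$per_locus
  expect_setequal(pl$obligate[[1]], c(161, 163, 165))
  expect_equal(pl$n_ambiguous, 0L)
  expect_equal(pl$min_paternal_count, 3L)
  # an embryo sharing both alleles with the mother is ambiguous
  amb1 <- quick_litter(list(L = c(155, 157)), list(list(L = c(155, 157))))
  pa <- deduce_paternal_alleles(amb1)$per_locus
  expect_equal(pa$n_ambiguous, 1L)
  expect_equal(pa$min_paternal_count, 1L)
  expect_length(pa$obligate[[1]], 0)

  # obligates {161, 163} miss both maternal alleles, so the ambiguous embryo
  # forces a third paternal allele
  lit2 <- quick_litter(list(L = c(155, 157)),
                       list(list(L = c(157, 161)), list(L = c(155, 163)),
                            list(L = c(155, 157))))
  expect_equal(deduce_paternal_alleles(lit2)$per_locus$min_paternal_count, 3L)
  # ... unless an obligate allele is one of the mother's
  lit3 <- quick_litter(list(L = c(155, 157)),
                       list(list(L = c(155, 155)), list(L = c(161, 157)),
                            list(L = c(155, 157))))
  # determined: 155 (maternal-carried) and 161; ambiguous hits 155
  expect_equal(deduce_paternal_alleles(lit3)$per_locus$min_paternal_count, 2L)
})

test_that("maternal-mismatch embryos are flagged and excluded", {
  lit <- quick_litter(list(L1 = c(100, 102), L2 = c(200, 202)),
                      list(list(L1 = c(100, 104), L2 = c(200, 204)),
                           list(L1 = c(110, 112), L2 = c(210, 212))))
  ps <- deduce_paternal_alleles(lit)
  expect_equal(ps$mismatched_embryos, "M1E02")
  expect_setequal(ps$per_locus$obligate[[1]], 104)
})

test_that("flag_polyandry applies the three-allele rule conservatively", {
  two <- quick_litter(list(L = c(1, 2)),
                      list(list(L = c(1, 3)), list(L = c(2, 4))))
  expect_false(flag_polyandry(deduce_paternal_alleles(two)))
  three <- quick_litter(list(L = c(1, 2)),
                        list(list(L = c(1, 3)), list(L = c(2, 4)),
                             list(L = c(1, 5))))
  expect_true(flag_polyandry(deduce_paternal_alleles(three)))
  # obligate {3,4} + ambiguous-only embryos: ambiguity resolves to 3 or 4? no -
  # ambiguous candidates are the mother's alleles; {3,4} miss them, so count 3
  amb <- quick_litter(list(L = c(1, 2)),
                      list(list(L = c(1, 3)), list(L = c(2, 4)),
                           list(L = c(1, 2))))
  expect_true(flag_polyandry(deduce_paternal_alleles(amb)))
  # but when one obligate IS maternal, the ambiguous embryo is covered
  amb2 <- quick_litter(list(L = c(1, 2)),
                       list(list(L = c(1, 1)), list(L = c(2, 4)),
                            list(L = c(1, 2))))
  expect_false(flag_polyandry(deduce_paternal_alleles(amb2)))
})

test_that("min_sires handles the simple bound cases", {
  fr <- uniform_freqs(list(L = c(1:6)))
  one <- quick_litter(list(L = c(1, 2)),
                      list(list(L = c(1, 3)), list(L = c(2, 3))))
  m1 <- min_sires(one, fr)
  expect_equal(m1$k, 1L)
  expect_equal(sum(vapply(m1$solutions, `[[`, 0, "relative_probability")), 1,
               tolerance = 1e-9)
  # 5 obligate paternal alleles force at least ceil(5/2) = 3 sires
  five <- quick_litter(list(L = c(1, 2)),
                       list(list(L = c(1, 3)), list(L = c(1, 4)),
                            list(L = c(1, 5)), list(L = c(2, 6)),
                            list(L = c(1, 1))))
  # determined alleles 3,4,5,6,1 -> 5 distinct
  ps <- deduce_paternal_alleles(five)
  expect_equal(ps$per_locus$min_paternal_count, 5L)
  m3 <- min_sires(five, fr)
  expect_equal(m3$k, 3L)
  expect_true(all(vapply(m3$solutions, function(s) sum(s$skew), 0) == 5))
})

test_that("min_sires matches the inclusion-exclusion oracle on small litters", {
  set.seed(101)
  n_checked <- 0
  agree_k <- 0
  shapes <- list(list(nl = 3, na = 2), list(nl = 2, na = 3), list(nl = 1, na = 4))
  for (rep in 1:220) {
    shp <- shapes[[(rep %% 3) + 1]]
    loci <- paste0("L", seq_len(shp$nl))
    alleles <- lapply(loci, function(l) 100L + 2L * seq_len(shp$na))
    names(alleles) <- loci
    fr <- allele_freqs(lapply(alleles, function(al) {
      w <- stats::runif(length(al), 0.2, 1); stats::setNames(w / sum(w), al)
    }), n = 50L)
    draw_geno <- function() lapply(alleles, function(al)
      al[sample.int(length(al), 2, TRUE)])
    k_true <- sample(1:2, 1)
    mom_g <- draw_geno()
    dads <- replicate(k_true, draw_geno(), simplify = FALSE)
    ne <- sample(2:5, 1)
    sire <- sample.int(k_true, ne, TRUE)
    embs <- lapply(seq_len(ne), function(i) {
      lapply(loci, function(l) {
        c(mom_g[[l]][sample.int(2, 1)], dads[[sire[i]]][[l]][sample.int(2, 1)])
      }) |> stats::setNames(loci)
    })
    lit <- quick_litter(mom_g, embs, id = paste0("T", rep))
    est <- min_sires(lit, fr, max_k = 3, max_solutions = 5000,
                     expand_cap = 5000)
    orc <- oracle_min_sires(lit, fr, max_k = 3)
    expect_equal(est$k, orc$k, info = paste("litter", rep))
    expect_equal(est$total_log_lik, log(orc$total), tolerance = 1e-9,
                 info = paste("total, litter", rep))
    best_lab <- max(vapply(est$solutions, function(s)
      exp(s$log_prob - s$log_mult), 0))
    expect_equal(best_lab, orc$best_labeled, tolerance = 1e-9,
                 info = paste("best, litter", rep))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 220)
})

test_that("min_sires is sound on simulated litters", {
  set.seed(55)
  frA <- default_polymorphic_panel("A")
  n_mono <- 0; n_poly <- 0
  for (rep in 1:60) {
    mom <- simulate_adults(1, "A", prefix = paste0("sm", rep), role = "mother")
    k_true <- sample(1:3, 1)
    dads <- lapply(seq_len(k_true), function(j)
      simulate_adults(1, "A", prefix = paste0("sf", rep, "_", j)))
    sim <- simulate_litter(mom, dads, rep(1 / k_true, k_true), 12)
    est <- min_sires(sim$litter, frA, max_solutions = 1,
                     loci = names(frA))
    expect_false(isTRUE(est$unresolved))
    expect_lte(est$k, k_true)        # never overcount the true sire number
    if (k_true == 1) {
      expect_equal(est$k, 1L)        # monandry is never inflated
      expect_false(flag_polyandry(deduce_paternal_alleles(sim$litter,
                                                          names(frA))))
      n_mono <- n_mono + 1
    } else n_poly <- n_poly + 1
  }
  expect_gt(n_mono, 5); expect_gt(n_poly, 5)
})

test_that("2-sire litters at the default panel are usually detected", {
  set.seed(77)
  frA <- default_polymorphic_panel("A")
  hits <- replicate(100, {
    mom <- simulate_adults(1, "A", role = "mother")
    dads <- list(simulate_adults(1, "A", prefix = "f1"),
                 simulate_adults(1, "A", prefix = "f2"))
    sim <- simulate_litter(mom, dads, c(0.5, 0.5), 9)
    flag_polyandry(deduce_paternal_alleles(sim$litter, names(frA)))
  })
  expect_gte(mean(hits), 0.90)
})

test_that("Mendelian segregation test and Fisher combination", {
  # analytic check: 7 loci each with p = 0.5 combine to chi2 = -14 ln 0.5
  p7 <- rep(0.5, 7)
  chi2 <- -2 * sum(log(p7))
  expect_equal(chi2, 9.704, tolerance = 1e-3)
  expect_equal(stats::pchisq(chi2, 14, lower.tail = FALSE), 0.7835,
               tolerance = 1e-3)

  # a 1-sire litter: father het at L1 with a 5:5 split -> chi2 = 0, p = 1
  set.seed(30)
  mom <- make_ind("M", "mother", list(L1 = c(1, 2), L2 = c(5, 6)))
  embs <- do.call(make_table, lapply(1:10, function(i) {
    pat <- if (i <= 5) 3 else 4       # father 3/4 at L1, 7/7 at L2
    make_ind(paste0("e", i), "embryo",
             list(L1 = c(c(1, 2)[1 + i %% 2], pat), L2 = c(5, 7)),
             mother_id = "M")
  }))
  lit <- make_litter(mom, embs)
  fr <- uniform_freqs(list(L1 = 1:4, L2 = 5:8))
  ms <- min_sires(lit, fr)
  expect_equal(ms$k, 1L)
  seg <- mendelian_segregation_test(lit, ms)
  l1 <- seg$per_locus[seg$per_locus$locus == "L1", ]
  expect_equal(c(l1$n_a, l1$n_b), c(5L, 5L))
  expect_equal(l1$chi2, 0)
  expect_equal(l1$p, 1)
  # father homozygous at L2: uninformative, so df = 2 * 1
  expect_equal(seg$df, 2L)
  expect_equal(seg$p, 1)
})

test_that("skew_test exact p-values", {
  expect_equal(skew_test(c(3, 3))$p, 1.0)
  expect_equal(skew_test(c(17, 1))$p, 2 * (1 + 18) / 2^18, tolerance = 1e-12)
  expect_equal(skew_test(c(1, 17))$p, skew_test(c(17, 1))$p)
  r <- skew_test(c(4, 3, 2))
  expect_equal(r$test_name, "exact_multinomial")
  expect_gt(r$p, 0.5)
  expect_lte(r$p, 1)
  # independent check of the multinomial tail by direct enumeration
  n <- 9
  obs <- stats::dmultinom(c(4, 3, 2), prob = rep(1 / 3, 3))
  enum <- 0
  for (a in 0:n) for (b in 0:(n - a)) {
    d <- stats::dmultinom(c(a, b, n - a - b), prob = rep(1 / 3, 3))
    if (d <= obs * (1 + 1e-7)) enum <- enum + d
  }
  expect_equal(r$p, enum, tolerance = 1e-9)
  # large-n Monte-Carlo branch agrees roughly with a smaller exact case
  mc <- skew_test(c(25, 8, 2), seed = 1)
  expect_equal(mc$test_name, "mc_multinomial")
  expect_lt(mc$p, 0.05)
})

test_that("analyze_litters produces a coherent report", {
  set.seed(202)
  cfg <- sim_config(seed = 9, n_adults = c(A = 50, B = 10),
                    n_litters = c(A = 6, B = 0), f = 0.5,
                    sire_dist = c("2" = 1))
  st <- simulate_study(cfg)
  x <- st$table
  lits <- build_litters(x)
  ad <- x[x$role == "adult" & x$species_hint == "A", ]
  fr <- suppressWarnings(estimate_allele_frequencies(
    ad, names(default_polymorphic_panel("A"))))
  res <- analyze_litters(lits, fr)
  rep <- res$report
  expect_equal(nrow(rep), 6)
  expect_equal(sum(rep$n_embryos),
               sum(vapply(lits, function(l) nrow(l$embryos), 0)))
  for (mid in rep$mother_id) {
    expect_lte(rep$k[rep$mother_id == mid],
               st$truth$litters[[mid]]$n_sires)
    if (rep$polyandrous[rep$mother_id == mid]) {
      sk <- as.integer(strsplit(rep$skew[rep$mother_id == mid], ":")[[1]])
      expect_equal(sum(sk) + rep$n_unassigned[rep$mother_id == mid],
                   rep$n_embryos[rep$mother_id == mid])
      expect_false(is.na(rep$p_skew[rep$mother_id == mid]))
    } else {
      expect_false(is.na(rep$p_segregation[rep$mother_id == mid]) &&
                   rep$k[rep$mother_id == mid] == 1)
    }
  }
})
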