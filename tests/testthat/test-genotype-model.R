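test_that("read_genotype_table parses, canonicalizes and flags errors", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,role,mother_id,species_hint,tl_mm,McaB5_1,McaB5_2",
    "M1,mother,,A,1400,157,155",
    "E1,embryo,M1,,,155,157",
    "E2,embryo,M1,,,0,0"
  ), tf)
  x <- read_genotype_table(tf)
  expect_equal(infer_loci(x), "McaB5")
  # canonical order allele1 <= allele2, applied to both input orders
  expect_equal(unname(unlist(x[x$sample_id == "M1", c("McaB5_1", "McaB5_2")])),
               c(155L, 157L))
  expect_equal(unname(unlist(x[x$sample_id == "E1", c("McaB5_1", "McaB5_2")])),
               c(155L, 157L))
  expect_equal(unname(unlist(x[x$sample_id == "E2", c("McaB5_1", "McaB5_2")])),
               c(0L, 0L))
  expect_equal(x$mother_id[x$sample_id == "E1"], "M1")

  # unknown locus column is a hard error naming the column
  expect_error(read_genotype_table(tf, loci = "Mh9"), "McaB5")

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,role,mother_id,species_hint,tl_mm,McaB5_1,McaB5_2",
               "E9,embryo,M1,,,155.5,157"), tf2)
  expect_error(read_genotype_table(tf2), "E9")
})

test_that("genotype table round-trips through write/read", {
  set.seed(42)
  x <- simulate_adults(15, "A")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(x, tf)
  y <- read_genotype_table(tf)
  loci <- infer_loci(x)
  expect_identical(y[, locus_columns(loci)], x[, locus_columns(loci)])
  expect_identical(y$sample_id, x$sample_id)
})

test_that("build_litters groups embryos under mothers and rejects orphans", {
  m1 <- make_ind("M1", "mother", list(L = c(1, 2)))
  m2 <- make_ind("M2", "mother", list(L = c(3, 4)))
  e <- function(id, mom) make_ind(id, "embryo", list(L = c(1, 3)), mother_id = mom)
  # interleaved rows still group correctly
  x <- make_table(m1, e("a", "M2"), e("b", "M1"), m2, e("c", "M2"), e("d", "M1"),
                  e("f", "M1"))
  lits <- build_litters(x)
  expect_named(lits, c("M1", "M2"))
  expect_setequal(lits$M1$embryos$sample_id, c("b", "d", "f"))
  expect_setequal(lits$M2$embryos$sample_id, c("a", "c"))

  bad <- make_table(m1, e("z", "NOPE"))
  expect_error(build_litters(bad), "NOPE")
  # embryo pointing at a non-mother role
  ad <- make_ind("AD", "adult", list(L = c(1, 1)))
  expect_error(build_litters(make_table(m1, ad, e("z", "AD"))), "non-mother")
})

test_that("estimate_allele_frequencies counts alleles correctly", {
  i1 <- make_ind("a", "adult", list(L = c(155, 155)))
  i2 <- make_ind("b", "adult", list(L = c(155, 157)))
  fr <- estimate_allele_frequencies(make_table(i1, i2))
  expect_equal(fr$L$freq, c("155" = 0.75, "157" = 0.25))
  expect_equal(fr$L$n, 2L)

  mono <- make_table(i1, i1)
  expect_equal(estimate_allele_frequencies(mono)$L$freq, c("155" = 1))

  # 117 individuals, 2 heterozygous carriers of a rare allele
  rows <- c(replicate(115, make_ind(paste0("h", runif(1)), "adult",
                                    list(L = c(200, 200))), simplify = FALSE),
            replicate(2, make_ind(paste0("x", runif(1)), "adult",
                                  list(L = c(200, 204))), simplify = FALSE))
  fr <- estimate_allele_frequencies(do.call(make_table, rows))
  expect_equal(unname(fr$L$freq["204"]), 2 / 234)

  # all-missing locus dropped with warning
  i3 <- make_ind("c", "adult", list(L = c(1, 2), Z = c(0, 0)))
  expect_warning(fr <- estimate_allele_frequencies(make_table(i3, i3)), "Z")
  expect_null(fr$Z)
})

test_that("allele frequency recovery on a large HWE sample", {
  set.seed(7)
  p <- c("150" = 0.55, "152" = 0.3, "154" = 0.15)
  al <- as.integer(names(p))
  a1 <- al[sample.int(3, 10000, TRUE, prob = p)]
  a2 <- al[sample.int(3, 10000, TRUE, prob = p)]
  tab <- data.frame(sample_id = paste0("i", 1:10000), role = "adult",
                    mother_id = NA, species_hint = NA, tl_mm = NA,
                    L_1 = pmin(a1, a2), L_2 = pmax(a1, a2))
  fr <- estimate_allele_frequencies(tab)
  expect_lt(max(abs(fr$L$freq[names(p)] - p)), 0.02)
})

test_that("GenePop export is well-formed and round-trips", {
  i1 <- make_ind("ind1", "adult", list(L = c(155, 157)), species_hint = "A")
  i2 <- make_ind("ind2", "adult", list(L = c(0, 0)), species_hint = "B")
  x <- make_table(i1, i2)
  tf <- withr::local_tempfile(fileext = ".gen")
  map <- write_genepop(x, tf)
  lines <- readLines(tf)
  expect_equal(lines[2], "L")
  expect_true(any(grepl("^ind1 ,  001002$", lines)))
  expect_true(any(grepl("^ind2 ,  000000$", lines)))
  expect_equal(map$L, c("155" = 1, "157" = 2))

  set.seed(3)
  big <- simulate_adults(20, "A")
  tf2 <- withr::local_tempfile(fileext = ".gen")
  map2 <- write_genepop(big, tf2)
  back <- read_genepop(tf2)
  loci <- infer_loci(big)
  expect_setequal(back$sample_id, big$sample_id)
  for (l in loci) {
    inv <- as.integer(names(map2[[l]]))
    for (i in seq_len(nrow(big))) {
      r <- which(back$sample_id == big$sample_id[i])
      orig <- c(big[[paste0(l, "_1")]][i], big[[paste0(l, "_2")]][i])
      code <- c(back[[paste0(l, "_1")]][r], back[[paste0(l, "_2")]][r])
      got <- if (any(code == 0L)) c(0L, 0L) else sort(inv[code])
      expect_identical(got, sort(orig))
    }
  }
})
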