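#' @title Synthetic two-species study generator
#'
#' @description
#' Generates complete synthetic studies with the statistical structure the
#' analysis assumes: two reproductively isolated species, each with a
#' reference sample of adults genotyped at a 6-locus diagnostic panel and 7
#' species-usable polymorphic loci (allele counts and heterozygosities shaped
#' like the published reference panel for the two smooth-hounds); pregnant
#' females whose litter sizes grow with body size; litters sired by 1-3
#' fathers with configurable skew; optionally F1-hybrid embryos fathered by a
#' male of the other species. Genotyping is error-free by default
#' (`error_rate = 0`), matching the re-genotyping check of the motivating
#' study; per-allele mis-scoring can be switched on.
#' @name synthetic_data
NULL

# geometric allele-frequency profile p_i ~ r^i solving sum p^2 = target
geometric_freqs <- function(Na, sum_p2) {
  if (Na == 1) return(1)
  if (sum_p2 <= 1 / Na + 1e-12) return(rep(1 / Na, Na))
  f <- function(r) {
    p <- r^(0:(Na - 1)); p <- p / sum(p); sum(p^2) - sum_p2
  }
  r <- stats::uniroot(f, c(1e-6, 1 - 1e-9), tol = 1e-12)$root
  p <- r^(0:(Na - 1))
  p / sum(p)
}

# published-shaped reference: locus, alleles and unbiased He per species
poly_panel_spec <- function() {
  list(
    A = data.frame(   # larger species; 7 usable loci, n = 136 reference adults
      locus = c("MaD2X", "McaB5", "McaB35", "Mh9", "Mh25", "Gg22", "MaFYP"),
      Na = c(5L, 9L, 13L, 3L, 6L, 12L, 5L),
      He = c(0.675, 0.814, 0.831, 0.579, 0.218, 0.788, 0.544),
      base = c(180L, 150L, 200L, 120L, 160L, 240L, 140L),
      step = c(2L, 4L, 4L, 2L, 2L, 3L, 4L),
      stringsAsFactors = FALSE),
    B = data.frame(   # blackspotted species; n = 117 reference adults
      locus = c("MaD2X", "McaB5", "McaB35", "Mh9", "Mh25", "MaND5", "Mh29"),
      Na = c(3L, 2L, 3L, 3L, 4L, 5L, 4L),
      He = c(0.530, 0.017, 0.315, 0.526, 0.659, 0.686, 0.620),
      base = c(180L, 150L, 200L, 120L, 160L, 210L, 170L),
      step = c(2L, 4L, 4L, 2L, 2L, 3L, 2L),
      stringsAsFactors = FALSE)
  )
}

#' Default polymorphic locus panel for one species
#'
#' Builds the species' 7-locus `allele_freqs` with allele counts and
#' heterozygosities shaped like the published smooth-hound reference samples
#' (the geometric frequency profile is the design choice; only Na and He are
#' matched). Frequencies target the gene diversity implied by the printed
#' unbiased He at the reference sample size.
#'
#' @param species `"A"` or `"B"`
#' @param n reference sample size recorded in the object (defaults to the
#'   published 136 / 117)
#' @return an `allele_freqs` object
#' @export
default_polymorphic_panel <- function(species = c("A", "B"), n = NULL) {
  species <- match.arg(species)
  spec <- poly_panel_spec()[[species]]
  n <- n %||% if (species == "A") 136L else 117L
  out <- list()
  for (i in seq_len(nrow(spec))) {
    sum_p2 <- 1 - spec$He[i] * (2 * n - 1) / (2 * n)
    p <- geometric_freqs(spec$Na[i], sum_p2)
    alleles <- spec$base[i] + spec$step[i] * (0:(spec$Na[i] - 1))
    out[[spec$locus[i]]] <- stats::setNames(p, alleles)
  }
  allele_freqs(out, n = n)
}

# within-species genotype structure of the diagnostic loci: named allele
# frequency vectors per locus per species (alleles as in the default panel)
diag_panel_freqs <- function() {
  list(
    A = list(Gg4 = c("198" = 1), Gg20 = c("280" = 1), MaTJ5 = c("159" = 1),
             Mca33 = c("194" = 0.6, "200" = 0.4),
             McaB26 = c("224" = 0.5, "229" = 0.5), Mh1 = c("203" = 1)),
    B = list(Gg4 = c("199" = 1), Gg20 = c("281" = 0.7, "282" = 0.3),
             MaTJ5 = c("157" = 1), Mca33 = c("197" = 1),
             McaB26 = c("224" = 1), Mh1 = c("201" = 0.9, "205" = 0.1))
  )
}

#' Simulation configuration
#'
#' Defaults state the emulated study: reference samples of 136 / 117 adults,
#' 19 / 13 litters, total lengths uniform on the published within-species
#' ranges (A: 1210-1630 mm, B: 1100-1410 mm), litter sizes increasing
#' linearly with length across the species' observed range (A: 3-18,
#' B: 9-35), multiple-mating frequency `f = 0.5`, polyandrous litters sired
#' by 2 fathers (prob 0.9) or 3 (prob 0.1) with equal expected success.
#'
#' @param seed RNG seed (mandatory for reproducible studies)
#' @param species character vector of species to simulate
#' @param n_adults,n_litters named integer vectors per species
#' @param f multiple-mating frequency in `[0, 1]`
#' @param sire_dist named numeric: probability of 2, 3, ... sires given
#'   polyandry
#' @param skew list: skew proportions per sire count (names "2", "3", ...)
#' @param tl_range,size_range named lists per species: c(min, max)
#' @param size_noise_sd SD of the Gaussian jitter on litter size before
#'   rounding/clamping
#' @param hybrid_litters optional data.frame `species`, `litter`, `n_hybrid`:
#'   sire that many embryos of litter index `litter` by an other-species male
#' @param error_rate per-allele mis-scoring probability (default 0)
#' @export
sim_config <- function(seed = 1L,
                       species = c("A", "B"),
                       n_adults = c(A = 136L, B = 117L),
                       n_litters = c(A = 19L, B = 13L),
                       f = 0.5,
                       sire_dist = c("2" = 0.9, "3" = 0.1),
                       skew = list("2" = c(0.5, 0.5), "3" = rep(1 / 3, 3)),
                       tl_range = list(A = c(1210, 1630), B = c(1100, 1410)),
                       size_range = list(A = c(3L, 18L), B = c(9L, 35L)),
                       size_noise_sd = 2,
                       hybrid_litters = NULL,
                       error_rate = 0) {
  stopifnot(f >= 0, f <= 1, abs(sum(sire_dist) - 1) < 1e-9, error_rate >= 0)
  structure(list(seed = seed, species = species, n_adults = n_adults,
                 n_litters = n_litters, f = f, sire_dist = sire_dist,
                 skew = skew, tl_range = tl_range, size_range = size_range,
                 size_noise_sd = size_noise_sd,
                 hybrid_litters = hybrid_litters, error_rate = error_rate),
            class = "sim_config")
}

# full panel (diagnostic + polymorphic) allele frequencies for one species
species_panel_freqs <- function(species) {
  poly <- default_polymorphic_panel(species)
  diag <- diag_panel_freqs()[[species]]
  all <- c(lapply(diag, function(f) list(freq = f, n = 200L)),
           unclass(poly))
  structure(all, class = "allele_freqs")
}

# draw one diploid genotype per locus under HWE; returns named integer vector
# over locus columns
draw_genotypes <- function(freqs, n) {
  cols <- list()
  for (l in names(freqs)) {
    al <- as.integer(names(freqs[[l]]$freq))
    p <- as.numeric(freqs[[l]]$freq)
    a1 <- al[sample.int(length(al), n, replace = TRUE, prob = p)]
    a2 <- al[sample.int(length(al), n, replace = TRUE, prob = p)]
    cp <- canonicalize_pair(a1, a2)
    cols[[paste0(l, "_1")]] <- cp[, 1]
    cols[[paste0(l, "_2")]] <- cp[, 2]
  }
  as.data.frame(cols, check.names = FALSE)
}

apply_scoring_error <- function(g, freqs, error_rate) {
  if (error_rate <= 0) return(g)
  for (l in names(freqs)) {
    al <- as.integer(names(freqs[[l]]$freq))
    for (col in locus_columns(l)) {
      hit <- stats::runif(nrow(g)) < error_rate & g[[col]] != 0L
      if (any(hit)) g[[col]][hit] <- al[sample.int(length(al), sum(hit), replace = TRUE)]
    }
    cp <- canonicalize_pair(g[[paste0(l, "_1")]], g[[paste0(l, "_2")]])
    g[[paste0(l, "_1")]] <- cp[, 1]
    g[[paste0(l, "_2")]] <- cp[, 2]
  }
  g
}

# all locus columns any species uses, in fixed order
all_locus_names <- function() {
  c(names(diag_panel_freqs()$A),
    unique(c(poly_panel_spec()$A$locus, poly_panel_spec()$B$locus)))
}

blank_geno_cols <- function(n) {
  cols <- lapply(locus_columns(all_locus_names()), function(x) rep(0L, n))
  names(cols) <- locus_columns(all_locus_names())
  as.data.frame(cols, check.names = FALSE)
}

#' Simulate reference adults for one species
#'
#' Genotypes drawn independently per locus under HWE at the species panel
#' frequencies; loci private to the other species are missing (0).
#'
#' @param n number of adults
#' @param species `"A"` or `"B"`
#' @param prefix id prefix
#' @param role role to record
#' @export
simulate_adults <- function(n, species, prefix = paste0(species, "ad"),
                            role = "adult") {
  freqs <- species_panel_freqs(species)
  g <- draw_genotypes(freqs, n)
  base <- data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
                     role = role,
                     mother_id = NA_character_,
                     species_hint = species,
                     tl_mm = NA_real_,
                     stringsAsFactors = FALSE)
  out <- cbind(base, blank_geno_cols(n))
  out[, colnames(g)] <- g
  out
}

#' Simulate a litter by Mendelian transmission
#'
#' Each embryo samples a father according to `skew`, then one allele from
#' each parent uniformly per locus. Loci missing in a parent are missing in
#' the embryo.
#'
#' @param mother one-row individuals data.frame
#' @param fathers list of one-row data.frames (unsampled males)
#' @param skew sire proportions, summing to 1
#' @param n litter size
#' @param prefix embryo id prefix
#' @return list: `litter` (a `litter` object), `sire_of` (named sire index)
#' @export
simulate_litter <- function(mother, fathers, skew, n,
                            prefix = paste0(mother$sample_id, "e")) {
  stopifnot(abs(sum(skew) - 1) < 1e-9, length(skew) == length(fathers))
  loci <- infer_loci(mother)
  sire <- sample.int(length(fathers), n, replace = TRUE, prob = skew)
  emb <- data.frame(sample_id = sprintf("%s%02d", prefix, seq_len(n)),
                    role = "embryo",
                    mother_id = mother$sample_id,
                    species_hint = mother$species_hint,
                    tl_mm = NA_real_,
                    stringsAsFactors = FALSE)
  emb <- cbind(emb, blank_geno_cols(n))
  for (l in loci) {
    mg <- geno_at(mother, l)[1, ]
    mat <- if (any(mg == 0L)) rep(0L, n) else mg[1 + (stats::runif(n) < 0.5)]
    pat <- vapply(sire, function(s) {
      fg <- geno_at(fathers[[s]], l)[1, ]
      if (any(fg == 0L)) 0L else fg[1 + (stats::runif(1) < 0.5)]
    }, 0L)
    cp <- canonicalize_pair(ifelse(mat == 0L | pat == 0L, 0L, mat),
                            ifelse(mat == 0L | pat == 0L, 0L, pat))
    emb[[paste0(l, "_1")]] <- cp[, 1]
    emb[[paste0(l, "_2")]] <- cp[, 2]
  }
  lit <- structure(list(mother = mother, embryos = emb), class = "litter")
  list(litter = lit, sire_of = stats::setNames(sire, emb$sample_id))
}

#' Simulate a complete two-species study
#'
#' Adults, mothers and litters for each configured species, with a
#' ground-truth sidecar for recovery tests. Mothers' total lengths are
#' uniform within the species range; litter size follows a linear
#' length-fecundity link with Gaussian jitter, clamped to the species range.
#'
#' @param config a [sim_config()]
#' @param out_dir optional directory: writes `genotypes.tsv` and `truth.json`
#' @return list: `table` (all individuals), `truth` (per-litter sire counts,
#'   sire assignment, hybrid embryo ids, true f)
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tabs <- list()
  truth <- list(f = config$f, litters = list())
  for (sp in config$species) {
    freqs <- species_panel_freqs(sp)
    other <- setdiff(c("A", "B"), sp)
    adults <- simulate_adults(config$n_adults[[sp]], sp)
    tabs[[length(tabs) + 1L]] <- adults
    nl <- config$n_litters[[sp]]
    tlr <- config$tl_range[[sp]]
    szr <- config$size_range[[sp]]
    for (i in seq_len(nl)) {
      mother <- simulate_adults(1, sp, prefix = sprintf("%sm%02d", sp, i),
                                role = "mother")
      mother$sample_id <- sprintf("%sm%02d", sp, i)
      tl <- stats::runif(1, tlr[1], tlr[2])
      mother$tl_mm <- round(tl)
      mu <- szr[1] + (szr[2] - szr[1]) * (tl - tlr[1]) / (tlr[2] - tlr[1])
      n_emb <- as.integer(min(szr[2], max(szr[1],
                round(mu + stats::rnorm(1, 0, config$size_noise_sd)))))
      polyandrous <- stats::runif(1) < config$f
      k <- if (polyandrous) {
        as.integer(names(config$sire_dist))[
          sample.int(length(config$sire_dist), 1, prob = config$sire_dist)]
      } else 1L
      skew <- if (k == 1) 1 else config$skew[[as.character(k)]]
      fathers <- lapply(seq_len(k), function(j)
        simulate_adults(1, sp, prefix = sprintf("%sf%02d_%d", sp, i, j)))
      sim <- simulate_litter(mother, fathers, skew, n_emb)
      emb <- sim$litter$embryos
      sire_of <- sim$sire_of
      hybrid_ids <- character(0)
      hl <- config$hybrid_litters
      if (!is.null(hl)) {
        hit <- hl[hl$species == sp & hl$litter == i, , drop = FALSE]
        if (nrow(hit)) {
          nh <- min(hit$n_hybrid[1], n_emb)
          hsire <- simulate_adults(1, other, prefix = sprintf("%shyb%02d", sp, i))
          hsim <- simulate_litter(mother, list(hsire), 1, nh,
                                  prefix = sprintf("%sh%02d", mother$sample_id, i))
          hemb <- hsim$litter$embryos
          repl <- seq_len(nh)
          hemb$sample_id <- emb$sample_id[repl]
          emb[repl, ] <- hemb
          sire_of[repl] <- NA_integer_
          hybrid_ids <- emb$sample_id[repl]
        }
      }
      if (config$error_rate > 0) {
        emb <- apply_scoring_error(emb, freqs, config$error_rate)
      }
      tabs[[length(tabs) + 1L]] <- mother
      tabs[[length(tabs) + 1L]] <- emb
      truth$litters[[mother$sample_id]] <- list(
        species = sp, n_embryos = n_emb, n_sires = k,
        polyandrous = polyandrous,
        sire_counts = as.integer(tabulate(sire_of[!is.na(sire_of)], k)),
        sire_of = as.list(sire_of),
        hybrid_embryos = hybrid_ids)
    }
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotype_table(table, file.path(out_dir, "genotypes.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(table = table, truth = truth))
}
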