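#' @title End-to-end study pipeline
#'
#' @description
#' Orchestrates identification, per-species population-genetic summaries,
#' litter-by-litter paternity reconstruction, detection-power tables, and
#' the Bayesian multiple-mating frequency estimate into one reproducible
#' run. Species are analysed separately after diagnosis; hybrid and
#' maternal-mismatch embryos are excluded from paternity inference but kept
#' in the calls table. Per-species allele frequencies come from classified
#' adults only. All randomness flows from one root seed, split per stage.
#' @name pipeline_cli
NULL

#' Run the full analysis pipeline
#'
#' @param genotypes individuals data.frame, or path to a genotype table
#' @param panel diagnostic panel (default the shipped 6-locus panel)
#' @param seed root seed; per-stage seeds are derived from it
#' @param max_k maximum sires considered per litter
#' @param power_reps Monte-Carlo replicates for power / per-litter d_i
#'   (0 skips the power table)
#' @param power_sizes named list of litter-size grids per species label for
#'   the power table (default: range of observed litter sizes)
#' @param freq_source `"adults"` (default) or `"all"`: individuals used for
#'   allele-frequency estimation
#' @param out_dir optional output directory for TSV/JSON artifacts
#' @return a `study_report` list: `calls`, `flags`, `popgen`, `litters`
#'   (report + details), `power`, `fmm`, `species_summary`, `meta`
#' @export
run_pipeline <- function(genotypes, panel = default_diagnostic_panel(),
                         seed = 1L, max_k = 4, power_reps = 2000,
                         power_sizes = NULL, freq_source = "adults",
                         out_dir = NULL) {
  x <- if (is.character(genotypes)) read_genotype_table(genotypes) else genotypes
  seeds <- split_seed(seed, c("popgen", "paternity", "power", "fmm"))

  calls <- classify_species(x, panel)
  label <- stats::setNames(calls$label, calls$sample_id)
  litters_all <- build_litters(x)

  flags <- list()
  for (mid in names(litters_all)) {
    fl <- check_family_consistency(litters_all[[mid]], calls)
    if (nrow(fl)) flags[[mid]] <- cbind(mother_id = mid, fl)
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(mother_id = character(0), embryo_id = character(0),
               flag = character(0))
  rownames(flags) <- NULL
  hybrid_embryos <- flags$embryo_id[flags$flag == "hybrid_offspring"]

  diag_loci <- panel$locus
  poly_loci <- setdiff(infer_loci(x), diag_loci)

  report <- list(calls = calls, flags = flags, popgen = list(),
                 litters = list(), power = list(), fmm = list(),
                 species_summary = list(),
                 meta = list(seed = seed, stage_seeds = as.list(seeds),
                             max_k = max_k, power_reps = power_reps,
                             n_individuals = nrow(x)))

  for (sp in c("A", "B")) {
    adults <- x[x$role == "adult" & label[x$sample_id] == sp, , drop = FALSE]
    members <- if (freq_source == "adults") adults else
      x[label[x$sample_id] == sp, , drop = FALSE]
    if (!nrow(members)) next
    freqs <- suppressWarnings(estimate_allele_frequencies(members, poly_loci))
    if (nrow(adults) >= 5) {
      set.seed(seeds[["popgen"]])
      report$popgen[[sp]] <- suppressWarnings(
        popgen_summary(adults, poly_loci, n_reps = min(2000, power_reps * 2)))
    }
    mids <- names(litters_all)[label[names(litters_all)] == sp]
    if (!length(mids)) next
    lits <- litters_all[mids]
    pat <- analyze_litters(lits, freqs, species = stats::setNames(rep(sp, length(mids)), mids),
                           exclude_embryos = hybrid_embryos,
                           max_k = max_k, seed = seeds[["paternity"]])
    report$litters[[sp]] <- pat
    report$species_summary[[sp]] <- summarize_species(pat$report)

    if (power_reps > 0) {
      sizes <- if (!is.null(power_sizes)) power_sizes[[sp]] else {
        rng <- range(pat$report$n_embryos)
        unique(round(seq(rng[1], rng[2], length.out = min(4, diff(rng) + 1))))
      }
      set.seed(seeds[["power"]])
      report$power[[sp]] <- power_table(freqs, sizes, n_reps = power_reps)

      set.seed(seeds[["fmm"]])
      d <- vapply(mids, function(mid) {
        lit <- drop_embryos(lits[[mid]], hybrid_embryos)
        litter_detection_power(lit, freqs, n_reps = power_reps)$p_detect
      }, 0)
      detected <- pat$report$polyandrous
      d[detected & d == 0] <- 1 / power_reps  # MC floor: observed implies d > 0
      report$fmm[[sp]] <- fmm_estimate(detected, d)
    }
  }

  class(report) <- "study_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report:", x$meta$n_individuals, "individuals\n")
  cat("calls:", paste(names(table(x$calls$label)), table(x$calls$label),
                      sep = "=", collapse = ", "), "\n")
  for (sp in names(x$species_summary)) {
    s <- x$species_summary[[sp]]
    cat(sprintf("species %s: %d litters, %d polyandrous (%.0f%%)",
                sp, s$n_litters, s$n_polyandrous, s$polyandry_pct))
    if (!is.null(x$fmm[[sp]])) {
      cat(sprintf(", fmm mode %.2f", x$fmm[[sp]]$mode))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write pipeline artifacts to a directory
#' @param report a `study_report`
#' @param out_dir output directory (created if needed)
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(x, file.path(out_dir, f), sep = "\t",
                                           row.names = FALSE, quote = FALSE)
  tsv(report$calls, "species_calls.tsv")
  tsv(report$flags, "family_flags.tsv")
  for (sp in names(report$popgen)) tsv(report$popgen[[sp]],
                                       paste0("popgen_", sp, ".tsv"))
  for (sp in names(report$litters)) tsv(report$litters[[sp]]$report,
                                        paste0("litters_", sp, ".tsv"))
  summary <- list(species_summary = report$species_summary,
                  fmm = lapply(report$fmm, function(f)
                    list(mode = f$mode, ci95 = as.list(f$ci95),
                         n_detected = f$n_detected, n_litters = f$n_litters)),
                  power = lapply(report$power, function(m)
                    list(rows = rownames(m), sizes = colnames(m),
                         pct = unname(as.data.frame(m)))),
                  meta = report$meta)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
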