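#' @title Fecundity and study-level summaries
#' @name fecundity_and_summary
NULL

#' Fecundity ANCOVA
#'
#' Linear model `litter_size ~ tl_mm + mating_system` with Type-II
#' (marginal, drop-one) F tests: does multiple mating add anything to litter
#' size once female size is accounted for?
#'
#' @param x data.frame with columns `n_embryos`, `tl_mm`, and logical
#'   `polyandrous`
#' @return list: `terms` data.frame (`term`, `df`, `F`, `p`), `n`, `note`
#' @export
fecundity_ancova <- function(x) {
  stopifnot(all(c("n_embryos", "tl_mm", "polyandrous") %in% colnames(x)))
  x <- x[stats::complete.cases(x[, c("n_embryos", "tl_mm", "polyandrous")]), ]
  if (nrow(x) < 5) stop("ANCOVA needs at least 5 litters")
  x$mating_system <- factor(ifelse(x$polyandrous, "polyandry", "monandry"),
                            levels = c("monandry", "polyandry"))
  note <- NA_character_
  if (nlevels(droplevels(x$mating_system)) < 2) {
    warning("only one mating-system level present; covariate-only model")
    fit <- stats::lm(n_embryos ~ tl_mm, data = x)
    note <- "single mating-system level: covariate-only model"
  } else {
    fit <- stats::lm(n_embryos ~ tl_mm + mating_system, data = x)
  }
  d1 <- stats::drop1(fit, test = "F")
  terms <- data.frame(term = rownames(d1)[-1],
                      df = d1$Df[-1],
                      F = d1$`F value`[-1],
                      p = d1$`Pr(>F)`[-1],
                      stringsAsFactors = FALSE)
  list(terms = terms, n = nrow(x), note = note, fit = fit)
}

parse_skew <- function(s) as.integer(strsplit(s, ":")[[1]])

#' Species-level mating-system summary
#'
#' From per-litter report rows of one species: polyandry frequency (direct
#' count), mean minimum sire number over polyandrous litters, maximum sires,
#' and the mean/SD of the top sire's share of assigned embryos.
#'
#' @param report data.frame with columns `polyandrous`, `k`, `skew`
#'   (colon-separated assigned-embryo counts)
#' @return list of summary fields (`polyandry_pct` etc.); percentages are
#'   exact values, `*_display` fields hold the conventionally rounded forms
#' @export
summarize_species <- function(report) {
  stopifnot(nrow(report) >= 1)
  n <- nrow(report)
  poly <- report[which(report$polyandrous), , drop = FALSE]
  np <- nrow(poly)
  top_share <- if (np) vapply(poly$skew, function(s) {
    cnt <- parse_skew(s)
    max(cnt) / sum(cnt)
  }, 0, USE.NAMES = FALSE) else numeric(0)
  mean_sires <- if (np) mean(poly$k) else NA_real_
  list(
    n_litters = n,
    n_polyandrous = np,
    polyandry_pct = 100 * np / n,
    polyandry_pct_display = round(100 * np / n),
    mean_sires = mean_sires,
    mean_sires_display = if (np) round(mean_sires, 1) else NA_real_,
    max_sires = if (np) max(poly$k) else NA_integer_,
    mean_top_share_pct = if (np) 100 * mean(top_share) else NA_real_,
    sd_top_share_pct = if (np >= 2) 100 * stats::sd(top_share) else NA_real_
  )
}
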