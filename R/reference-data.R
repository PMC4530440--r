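#' Shipped reference litter summaries
#'
#' The package ships the published per-litter summaries of the two-species
#' smooth-hound study as plain-text fixtures: all 32 litters (maternal total
#' length, litter size, site, date) and the 16 polyandrous litters with
#' their reconstructed minimum sire counts and assigned-embryo skew.
#' `reference_study()` merges them into a report-shaped table (litters absent
#' from the polyandrous fixture are monandrous, k = 1, all embryos assigned
#' to the single sire), suitable for [summarize_species()] and
#' [fecundity_ancova()].
#'
#' @return data.frame: `species`, `mother_id`, `tl_mm`, `n_embryos`,
#'   `polyandrous`, `k`, `skew`
#' @export
reference_study <- function() {
  lit <- utils::read.table(
    system.file("extdata", "smoothhound_litters.tsv", package = "litterkin"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  pol <- reference_polyandrous()
  i <- match(lit$mother_id, pol$mother_id)
  data.frame(
    species = lit$species,
    mother_id = lit$mother_id,
    tl_mm = lit$tl_mm,
    n_embryos = lit$n_embryos,
    polyandrous = !is.na(i),
    k = ifelse(is.na(i), 1L, pol$n_sires[i]),
    skew = ifelse(is.na(i), as.character(lit$n_embryos), pol$skew[i]),
    stringsAsFactors = FALSE)
}

#' @rdname reference_study
#' @export
reference_polyandrous <- function() {
  utils::read.table(
    system.file("extdata", "smoothhound_polyandrous.tsv", package = "litterkin"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = c("character", "character", "integer", "integer",
                   "integer", "character", "character"))
}
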