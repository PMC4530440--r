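#' @title Diagnostic-panel species identification
#'
#' @description
#' Two reproductively isolated smooth-hound species can be told apart with a
#' small panel of microsatellite loci whose allele sets are fixed or
#' non-overlapping between species. A pure individual carries only
#' species-A (or only species-B) alleles across the panel; an F1 hybrid is
#' heterozygous for one allele from each species at the diagnostic loci.
#' Loci with allelic/genotypic overlap between species (status `overlapping`)
#' vote only when an unambiguous allele is present and never drive hybrid
#' calls.
#' @name species_diagnosis
NULL

#' Default 6-locus diagnostic panel
#'
#' Species A is the larger smooth-hound (e.g. *Mustelus mustelus*-like allele
#' sets), species B the blackspotted congener. Two loci are fixed between
#' species, three have low-variation non-overlapping allele sets, and one
#' shows partial overlap.
#'
#' @return data.frame with columns `locus`, `alleles_A`, `alleles_B`
#'   (integer list columns) and `status`
#' @export
default_diagnostic_panel <- function() {
  panel <- data.frame(
    locus = c("Gg4", "Gg20", "MaTJ5", "Mca33", "McaB26", "Mh1"),
    status = c("fixed", "non_overlapping", "fixed", "non_overlapping",
               "overlapping", "non_overlapping"),
    stringsAsFactors = FALSE
  )
  panel$alleles_A <- list(198L, 280L, 159L, c(194L, 200L), c(224L, 229L), 203L)
  panel$alleles_B <- list(199L, c(281L, 282L), 157L, 197L, 224L, c(201L, 205L))
  validate_diagnostic_panel(panel)
  panel
}

validate_diagnostic_panel <- function(panel) {
  stopifnot(all(c("locus", "status", "alleles_A", "alleles_B") %in% colnames(panel)))
  stopifnot(!anyDuplicated(panel$locus))
  for (i in seq_len(nrow(panel))) {
    a <- panel$alleles_A[[i]]; b <- panel$alleles_B[[i]]
    st <- panel$status[i]
    if (st == "fixed" && !(length(a) == 1 && length(b) == 1)) {
      stop("fixed locus ", panel$locus[i], " must have one allele per species")
    }
    if (st == "non_overlapping" && length(intersect(a, b))) {
      stop("non_overlapping locus ", panel$locus[i], " has shared alleles")
    }
    if (st == "overlapping" && !length(intersect(a, b))) {
      stop("overlapping locus ", panel$locus[i], " has empty intersection")
    }
  }
  invisible(panel)
}

#' Read / write a diagnostic panel TSV
#'
#' Columns: `locus`, `alleles_A` and `alleles_B` as `;`-separated integers,
#' `status` in `fixed` / `non_overlapping` / `overlapping`.
#' @param path TSV file
#' @export
read_diagnostic_panel <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x$alleles_A <- lapply(strsplit(as.character(x$alleles_A), ";"), as.integer)
  x$alleles_B <- lapply(strsplit(as.character(x$alleles_B), ";"), as.integer)
  validate_diagnostic_panel(x)
  x
}

#' @rdname read_diagnostic_panel
#' @param panel diagnostic panel data.frame
#' @export
write_diagnostic_panel <- function(panel, path) {
  out <- data.frame(
    locus = panel$locus,
    alleles_A = vapply(panel$alleles_A, paste, "", collapse = ";"),
    alleles_B = vapply(panel$alleles_B, paste, "", collapse = ";"),
    status = panel$status, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# vote of one diagnostic locus for one genotype
diagnostic_vote <- function(a1, a2, alleles_A, alleles_B) {
  if (a1 == 0L || a2 == 0L) return("missing")
  ov <- intersect(alleles_A, alleles_B)
  cls <- function(a) {
    if (a %in% ov) "ov"
    else if (a %in% alleles_A) "A"
    else if (a %in% alleles_B) "B"
    else "unknown"
  }
  c1 <- cls(a1); c2 <- cls(a2)
  if (c1 %in% c("ov", "unknown") || c2 %in% c("ov", "unknown")) return("uninformative")
  if (c1 == c2) c1 else "mixed"
}

#' Classify one individual from the diagnostic panel
#'
#' Per-locus votes: both alleles species-A-specific gives `A`, both
#' species-B-specific gives `B`, one of each `mixed`; any allele in the
#' between-species overlap (or unseen in the panel) gives `uninformative`.
#' The final label is `A` (resp. `B`) when at least one informative vote
#' exists and all informative votes agree; `hybrid` when BOTH fixed loci vote
#' `mixed` and no fixed/non-overlapping locus votes pure; otherwise
#' `ambiguous`.
#'
#' @param ind one-row data.frame (a genotype-table row)
#' @param panel diagnostic panel, see [default_diagnostic_panel()]
#' @return list with `label`, `per_locus_votes` (named character),
#'   `n_informative`
#' @export
classify_individual <- function(ind, panel = default_diagnostic_panel()) {
  votes <- character(nrow(panel))
  names(votes) <- panel$locus
  for (i in seq_len(nrow(panel))) {
    loc <- panel$locus[i]
    c1 <- paste0(loc, "_1"); c2 <- paste0(loc, "_2")
    if (!c1 %in% colnames(ind)) { votes[i] <- "missing"; next }
    votes[i] <- diagnostic_vote(ind[[c1]][1], ind[[c2]][1],
                                panel$alleles_A[[i]], panel$alleles_B[[i]])
  }
  informative <- votes[votes %in% c("A", "B", "mixed")]
  n_inf <- length(informative)
  strict <- panel$locus[panel$status %in% c("fixed", "non_overlapping")]
  fixed <- panel$locus[panel$status == "fixed"]
  label <- if (n_inf == 0) {
    "ambiguous"
  } else if (all(informative == "A")) {
    "A"
  } else if (all(informative == "B")) {
    "B"
  } else if (length(fixed) && all(votes[fixed] == "mixed") &&
             !any(votes[strict] %in% c("A", "B"))) {
    "hybrid"
  } else {
    "ambiguous"
  }
  list(label = label, per_locus_votes = votes, n_informative = n_inf)
}

#' Classify every individual in a table
#'
#' A `species_hint` (e.g. an external mtDNA-based call) never overrides the
#' nuclear diagnosis; disagreements are reported in the `hint_conflict`
#' column. Hybrids are expected to carry the maternal species' hint.
#'
#' @param x individuals data.frame
#' @param panel diagnostic panel
#' @return data.frame: `sample_id`, `role`, `label`, `n_informative`,
#'   `hint_conflict`, `votes` (compact string)
#' @export
classify_species <- function(x, panel = default_diagnostic_panel()) {
  res <- lapply(seq_len(nrow(x)), function(i) classify_individual(x[i, , drop = FALSE], panel))
  label <- vapply(res, `[[`, "", "label")
  hint <- x$species_hint %||% rep(NA_character_, nrow(x))
  conflict <- !is.na(hint) & label %in% c("A", "B") & hint != label
  data.frame(
    sample_id = x$sample_id,
    role = x$role,
    label = label,
    n_informative = vapply(res, `[[`, 0L, "n_informative"),
    hint_conflict = conflict,
    votes = vapply(res, function(r) {
      paste0(names(r$per_locus_votes), "=", r$per_locus_votes, collapse = ";")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Check mother-embryo consistency of species calls
#'
#' A hybrid embryo under a pure mother is an expected pattern
#' (`hybrid_offspring`: the mother mated heterospecifically); two conflicting
#' pure labels indicate a sample/identity problem (`identity_conflict`).
#'
#' @param litter a `litter` object
#' @param calls classification table from [classify_species()]
#' @return data.frame `embryo_id`, `flag` (possibly 0 rows)
#' @export
check_family_consistency <- function(litter, calls) {
  lab <- stats::setNames(calls$label, calls$sample_id)
  mlab <- lab[[litter$mother$sample_id]]
  out <- data.frame(embryo_id = character(0), flag = character(0),
                    stringsAsFactors = FALSE)
  for (eid in litter$embryos$sample_id) {
    elab <- lab[[eid]]
    if (is.null(elab) || is.null(mlab)) next
    if (mlab %in% c("A", "B") && elab == "hybrid") {
      out[nrow(out) + 1L, ] <- c(eid, "hybrid_offspring")
    } else if (mlab %in% c("A", "B") && elab %in% c("A", "B") && elab != mlab) {
      out[nrow(out) + 1L, ] <- c(eid, "identity_conflict")
    }
  }
  out
}
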