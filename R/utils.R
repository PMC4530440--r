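`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired allele column names for a set of loci
#' @param loci character vector of locus names
#' @return character vector `<locus>_1, <locus>_2, ...`
#' @keywords internal
locus_columns <- function(loci) {
  as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
}

#' Infer locus names from a genotype table's column names
#'
#' A locus is any name `X` for which both `X_1` and `X_2` columns exist.
#' @param x data.frame
#' @return character vector of locus names, in column order
#' @export
infer_loci <- function(x) {
  cn <- colnames(x)
  a1 <- sub("_1$", "", cn[grepl("_1$", cn)])
  a2 <- sub("_2$", "", cn[grepl("_2$", cn)])
  intersect(a1, a2)
}

# two-column integer matrix of genotypes at one locus (0 = missing)
geno_at <- function(x, locus) {
  m <- cbind(x[[paste0(locus, "_1")]], x[[paste0(locus, "_2")]])
  storage.mode(m) <- "integer"
  m
}

# canonical order a1 <= a2; any 0 in a pair makes the whole pair missing
canonicalize_pair <- function(a1, a2) {
  a1[is.na(a1)] <- 0L
  a2[is.na(a2)] <- 0L
  miss <- a1 == 0L | a2 == 0L
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  lo[miss] <- 0L
  hi[miss] <- 0L
  cbind(lo, hi)
}

is_missing_pair <- function(m) m[, 1] == 0L | m[, 2] == 0L

# split a root seed into named per-stage seeds (kept below 2^31)
split_seed <- function(seed, stages) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}
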