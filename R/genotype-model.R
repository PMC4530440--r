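#' @title Genotype tables, litters and allele frequencies
#'
#' @description
#' The package represents a study as a rectangular genotype table: one row per
#' individual with identifying columns (`sample_id`, `role`, `mother_id`,
#' `species_hint`, `tl_mm`, optional metadata) followed by two integer allele
#' columns per microsatellite locus, named `<LOCUS>_1` / `<LOCUS>_2`, in binned
#' base-pair units. `0` encodes a missing allele; a pair with any missing
#' allele is treated as a wholly missing genotype. Genotypes are stored in
#' canonical order (`allele1 <= allele2`).
#' @name genotype_tables
NULL

ROLES <- c("mother", "embryo", "adult")

#' Read a genotype table
#'
#' Reads a TSV/CSV genotype table (extension decides the separator), validates
#' roles and allele columns, and canonicalizes genotypes. Blank or `0` alleles
#' become missing genotypes.
#'
#' @param path file path; `.csv` is comma-separated, anything else tab
#' @param loci optional character vector of expected locus names. When given,
#'   any `*_1`/`*_2` column pair outside this set is a hard error.
#' @return a `data.frame` of individuals with canonicalized genotype columns
#' @export
read_genotype_table <- function(path, loci = NULL) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = NA, na.strings = c("NA", ""))
  req <- c("sample_id", "role")
  if (!all(req %in% colnames(x))) {
    stop("genotype table must have columns: ", paste(req, collapse = ", "))
  }
  if (!"mother_id" %in% colnames(x)) x$mother_id <- NA_character_
  if (!"species_hint" %in% colnames(x)) x$species_hint <- NA_character_
  if (!"tl_mm" %in% colnames(x)) x$tl_mm <- NA_real_
  found <- infer_loci(x)
  if (!is.null(loci)) {
    extra <- setdiff(found, loci)
    if (length(extra)) {
      stop("unknown locus column(s): ", paste(locus_columns(extra), collapse = ", "))
    }
    found <- intersect(loci, found)
  }
  bad_role <- setdiff(unique(x$role), ROLES)
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  for (loc in found) {
    for (col in locus_columns(loc)) {
      v <- x[[col]]
      if (is.character(v)) v[v == ""] <- "0"
      v[is.na(v)] <- 0
      iv <- suppressWarnings(as.integer(v))
      bad_idx <- which(is.na(iv) | abs(suppressWarnings(as.numeric(v)) - iv) > 0)
      if (length(bad_idx)) {
        stop("non-integer allele in column ", col, " for individual ",
             x$sample_id[bad_idx[1]])
      }
      x[[col]] <- iv
    }
    cp <- canonicalize_pair(x[[paste0(loc, "_1")]], x[[paste0(loc, "_2")]])
    x[[paste0(loc, "_1")]] <- cp[, 1]
    x[[paste0(loc, "_2")]] <- cp[, 2]
  }
  tl <- x$tl_mm[!is.na(x$tl_mm)]
  if (length(tl) && any(tl < 100 | tl > 3000)) {
    stop("tl_mm outside plausible range 100-3000 mm")
  }
  x
}

#' Write a genotype table
#'
#' @param x individuals data.frame
#' @param path output path; `.csv` writes comma-separated, else tab
#' @export
write_genotype_table <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group embryos under their mothers
#'
#' @param x individuals data.frame
#' @return named list of `litter` objects (`list(mother=<1-row df>,
#'   embryos=<df>)`), one per mother with at least one embryo
#' @export
build_litters <- function(x) {
  mothers <- x[x$role == "mother", , drop = FALSE]
  embryos <- x[x$role == "embryo", , drop = FALSE]
  if (nrow(embryos)) {
    if (any(is.na(embryos$mother_id) | embryos$mother_id == "")) {
      bad <- embryos$sample_id[is.na(embryos$mother_id) | embryos$mother_id == ""]
      stop("embryo(s) without mother_id: ", paste(bad, collapse = ", "))
    }
    unknown <- setdiff(unique(embryos$mother_id), mothers$sample_id)
    if (length(unknown)) {
      if (any(unknown %in% x$sample_id)) {
        stop("embryo mother_id refers to non-mother individual(s): ",
             paste(intersect(unknown, x$sample_id), collapse = ", "))
      }
      stop("embryo(s) with unknown mother_id: ", paste(unknown, collapse = ", "))
    }
  }
  out <- list()
  for (i in seq_len(nrow(mothers))) {
    mid <- mothers$sample_id[i]
    emb <- embryos[embryos$mother_id == mid, , drop = FALSE]
    if (nrow(emb) == 0) next
    lit <- structure(list(mother = mothers[i, , drop = FALSE], embryos = emb),
                     class = "litter")
    out[[mid]] <- lit
  }
  out
}

#' @export
print.litter <- function(x, ...) {
  cat("litter: mother", x$mother$sample_id, "with", nrow(x$embryos), "embryos\n")
  invisible(x)
}

#' Estimate allele frequencies from reference individuals
#'
#' Frequencies are simple allele counts divided by `2 * n` non-missing
#' individuals per locus. Loci with no data are dropped with a warning.
#'
#' @param x individuals data.frame (typically classified adults of one species)
#' @param loci loci to use; default all loci found in `x`
#' @return an `allele_freqs` object: per locus `list(freq = named numeric,
#'   n = individuals genotyped)`
#' @export
estimate_allele_frequencies <- function(x, loci = NULL) {
  loci <- loci %||% infer_loci(x)
  out <- list()
  for (loc in loci) {
    g <- geno_at(x, loc)
    g <- g[!is_missing_pair(g), , drop = FALSE]
    if (nrow(g) == 0) {
      warning("locus ", loc, " has no genotyped individuals; excluded")
      next
    }
    tab <- table(as.vector(g))
    fr <- as.numeric(tab) / sum(tab)
    names(fr) <- names(tab)
    out[[loc]] <- list(freq = fr, n = nrow(g))
  }
  structure(out, class = "allele_freqs")
}

#' Build an allele_freqs object from explicit frequency vectors
#'
#' @param freqs named list: locus -> named numeric vector of allele frequencies
#' @param n nominal sample size(s) recorded per locus
#' @export
allele_freqs <- function(freqs, n = 100L) {
  n <- rep_len(n, length(freqs))
  out <- lapply(seq_along(freqs), function(i) {
    f <- freqs[[i]]
    stopifnot(!is.null(names(f)), abs(sum(f) - 1) < 1e-9, all(f > 0))
    list(freq = f, n = n[i])
  })
  names(out) <- names(freqs)
  structure(out, class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("allele frequencies for", length(x), "loci:\n")
  for (loc in names(x)) {
    cat(sprintf("  %-8s n=%-4d Na=%d\n", loc, x[[loc]]$n, length(x[[loc]]$freq)))
  }
  invisible(x)
}

# most frequent allele at a locus (integer); ties -> smallest allele
top_allele <- function(freqs, locus) {
  f <- freqs[[locus]]$freq
  as.integer(names(f)[which.max(f)])
}

# frequency lookup with a small-sample fallback for unseen alleles
allele_freq_of <- function(freqs, locus, allele) {
  fl <- freqs[[locus]]
  if (is.null(fl)) return(rep(NA_real_, length(allele)))
  f <- fl$freq[as.character(allele)]
  f[is.na(f)] <- 1 / (2 * fl$n + 2)
  unname(f)
}

#' Export individuals to GenePop format
#'
#' Writes a GenePop 4.x text file with rank-coded 3-digit alleles (smallest
#' allele at a locus is `001`). Individuals are grouped into one `Pop` block
#' per value of `pop`; missing genotypes are written `000000`.
#'
#' @param x individuals data.frame
#' @param path output path
#' @param loci loci to export (default: all)
#' @param pop population label per individual; default `species_hint`,
#'   unlabelled individuals form their own block
#' @param title first (comment) line of the file
#' @return invisibly, the allele -> code mapping (named list per locus)
#' @export
write_genepop <- function(x, path, loci = NULL, pop = NULL,
                          title = "litterkin GenePop export") {
  loci <- loci %||% infer_loci(x)
  pop <- pop %||% ifelse(is.na(x$species_hint), "unassigned", x$species_hint)
  maps <- list()
  for (loc in loci) {
    al <- sort(unique(as.vector(geno_at(x, loc))))
    al <- al[al != 0L]
    if (length(al) > 999) stop("locus ", loc, " has >999 distinct alleles")
    maps[[loc]] <- stats::setNames(seq_along(al), al)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  for (p in unique(pop)) {
    writeLines("Pop", con)
    idx <- which(pop == p)
    for (i in idx) {
      codes <- vapply(loci, function(loc) {
        a <- c(x[[paste0(loc, "_1")]][i], x[[paste0(loc, "_2")]][i])
        if (any(a == 0L)) return("000000")
        paste0(sprintf("%03d", maps[[loc]][as.character(a)]), collapse = "")
      }, character(1))
      writeLines(paste0(x$sample_id[i], " ,  ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(maps)
}

#' Read a GenePop file written by [write_genepop()]
#'
#' Minimal reader for round-trip checks: returns coded genotypes; combine with
#' the mapping returned by the writer to recover allele sizes.
#' @param path GenePop file
#' @return data.frame with `sample_id`, `pop`, and coded `<locus>_1/_2` columns
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[-1]
  pop_at <- which(toupper(trimws(body)) == "POP")
  stopifnot(length(pop_at) >= 1)
  loci <- trimws(body[seq_len(pop_at[1] - 1)])
  if (length(loci) == 1 && grepl(",", loci)) loci <- trimws(strsplit(loci, ",")[[1]])
  rows <- list()
  popname <- 0L
  for (ln in body[-seq_len(pop_at[1] - 1)]) {
    if (toupper(trimws(ln)) == "POP") { popname <- popname + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    stopifnot(length(codes) == length(loci))
    g <- lapply(codes, function(cc) {
      c(as.integer(substr(cc, 1, 3)), as.integer(substr(cc, 4, 6)))
    })
    row <- c(list(sample_id = id, pop = popname),
             stats::setNames(unlist(g), locus_columns(loci)))
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
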