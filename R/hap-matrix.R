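#' Phased haplotype matrix
#'
#' The substrate of every tree and comparison algorithm: one row per phased
#' sample haplotype, one column per biallelic marker, allele codes in
#' \{0, 1\} (REF/ALT), with per-marker metadata. All markers lie on a single
#' contig and positions are strictly increasing; coordinates are 1-based and
#' inclusive throughout the package.
#'
#' @param geno integer matrix of 0/1 allele codes, `n_haplotypes x n_markers`.
#' @param variants data frame with columns `contig`, `pos`, `id`, `ref`, `alt`,
#'   one row per marker, sorted by position.
#' @param samples character vector of sample identifiers, in input order.
#' @param ploidy rows per sample: 2 for diploid input, 1 after carrier
#'   selection.
#'
#' @return An object of class `hap_matrix`: a list with elements `geno`,
#'   `variants`, `samples`, `ploidy` and `row_labels`
#'   (`"<sample>_<hap index>"`, or the sample id when `ploidy` is 1).
#' @export
hap_matrix <- function(geno, variants, samples, ploidy = 2L) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ploidy <- as.integer(ploidy)
  validate_variants(variants)
  if (anyNA(geno)) {
    stop("missing alleles are not allowed in a haplotype matrix")
  }
  if (!all(geno %in% c(0L, 1L))) {
    stop("allele codes must be 0 or 1 (biallelic, phased)")
  }
  if (ncol(geno) != nrow(variants)) {
    stop("number of genotype columns (", ncol(geno),
         ") does not match number of variants (", nrow(variants), ")")
  }
  if (nrow(geno) != length(samples) * ploidy) {
    stop("n_haplotypes (", nrow(geno), ") != n_samples (", length(samples),
         ") x ploidy (", ploidy, ")")
  }
  row_labels <- if (ploidy == 1L) {
    as.character(samples)
  } else {
    paste0(rep(samples, each = ploidy), "_", rep(seq_len(ploidy), length(samples)))
  }
  rownames(geno) <- row_labels
  structure(
    list(geno = geno, variants = variants, samples = as.character(samples),
         ploidy = ploidy, row_labels = row_labels),
    class = "hap_matrix"
  )
}

validate_variants <- function(variants) {
  req <- c("contig", "pos", "id", "ref", "alt")
  if (!is.data.frame(variants) || !all(req %in% names(variants))) {
    stop("variants must be a data frame with columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(variants) == 0L) stop("empty variant set")
  if (length(unique(variants$contig)) != 1L) {
    stop("all variants must be on one contig")
  }
  if (any(variants$pos < 1L)) stop("positions must be 1-based (>= 1)")
  if (is.unsorted(variants$pos, strictly = TRUE)) {
    stop("variant positions must be strictly increasing")
  }
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  invisible(variants)
}

#' @method print hap_matrix
#' @export
print.hap_matrix <- function(x, ...) {
  cat("Phased haplotype matrix:", nrow(x$geno), "haplotypes x",
      ncol(x$geno), "markers\n")
  cat("  contig:", x$variants$contig[1], " span:", x$variants$pos[1], "-",
      x$variants$pos[nrow(x$variants)], "bp\n")
  cat("  samples:", length(x$samples), " ploidy:", x$ploidy, "\n")
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$geno)

n_haplotypes <- function(hm) nrow(hm$geno)
n_markers <- function(hm) ncol(hm$geno)

#' Subset a haplotype matrix
#'
#' @param hm a [hap_matrix()].
#' @param rows haplotype row indexes to keep (all by default). Subsetting rows
#'   other than whole samples drops the sample pairing, so the result has
#'   `ploidy = 1` unless every sample keeps all its rows.
#' @param markers marker column indexes to keep (all by default).
#' @return A `hap_matrix`.
#' @export
subset_hap_matrix <- function(hm, rows = NULL, markers = NULL) {
  if (is.null(rows)) rows <- seq_len(n_haplotypes(hm))
  if (is.null(markers)) markers <- seq_len(n_markers(hm))
  geno <- hm$geno[rows, markers, drop = FALSE]
  variants <- hm$variants[markers, , drop = FALSE]
  rownames(variants) <- NULL
  sample_of_row <- rep(seq_along(hm$samples), each = hm$ploidy)[rows]
  full <- hm$ploidy > 1L &&
    length(rows) == length(unique(sample_of_row)) * hm$ploidy &&
    all(tabulate(sample_of_row, length(hm$samples)) %in% c(0L, hm$ploidy))
  if (full) {
    hap_matrix(geno, variants, hm$samples[unique(sample_of_row)], hm$ploidy)
  } else {
    out <- hap_matrix(geno, variants, hm$row_labels[rows], 1L)
    out
  }
}

#' Locate the marker at (or nearest) a base-pair position
#'
#' Mirrors focal-marker selection around a locus of interest, e.g. picking the
#' closest genotyped marker upstream of a repeat expansion.
#'
#' @param hm a [hap_matrix()].
#' @param pos 1-based base-pair position.
#' @param select policy when no marker sits exactly at `pos`: `"upstream"`
#'   (largest position `<= pos`; the default), `"downstream"` (smallest
#'   position `>= pos`) or `"nearest"`.
#' @return A marker column index.
#' @export
marker_at <- function(hm, pos, select = c("upstream", "downstream", "nearest")) {
  select <- match.arg(select)
  p <- hm$variants$pos
  exact <- which(p == pos)
  if (length(exact)) return(exact[1])
  idx <- switch(select,
    upstream = { i <- which(p <= pos); if (!length(i)) NA_integer_ else max(i) },
    downstream = { i <- which(p >= pos); if (!length(i)) NA_integer_ else min(i) },
    nearest = which.min(abs(p - pos))
  )
  if (is.na(idx)) {
    stop("no marker ", select, " of position ", pos)
  }
  idx
}
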