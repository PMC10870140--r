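#' Read a phased VCF into a haplotype matrix
#'
#' Reads phased biallelic genotypes (GT fields) from a VCF or VCF.gz file.
#' Every sample contributes two rows in sample order
#' (`sample1_1, sample1_2, sample2_1, ...`). The file must contain a single
#' contig (after region restriction), only biallelic records, and fully
#' phased, non-missing, diploid GT fields.
#'
#' Multiallelic records are rejected rather than auto-split: splitting changes
#' branch order in downstream trees, so the records must be split (or removed)
#' explicitly upstream, e.g. with `bcftools norm -m -`.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param region optional `"contig:start-end"` string restricting the markers.
#' @return A [hap_matrix()] with `ploidy = 2`.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  contig <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    reg <- parse_region(region)
    keep <- contig == reg$contig & pos >= reg$start & pos <= reg$end
    if (!any(keep)) stop("no records in region ", region)
  }
  gt <- vcf@gt[, -1, drop = FALSE]  # drop FORMAT column
  samples <- colnames(gt)
  if (is.null(samples) || length(samples) == 0L) {
    stop("VCF has no sample columns")
  }
  contig <- contig[keep]; pos <- pos[keep]; id <- id[keep]
  ref <- ref[keep]; alt <- alt[keep]
  gt <- gt[keep, , drop = FALSE]

  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic record at ", contig[which(multi)[1]], ":",
         pos[which(multi)[1]],
         "; split before use (multiallelic sites should either be removed ",
         "or split into individual rows)")
  }
  # GT is the leading field of the genotype column per VCF spec
  gt_only <- sub(":.*$", "", gt)
  dim(gt_only) <- dim(gt)
  bad_phase <- grepl("/", gt_only, fixed = TRUE)
  if (any(bad_phase)) {
    w <- arrayInd(which(bad_phase)[1], dim(gt_only))
    stop("unphased genotype for sample ", samples[w[1, 2]], " at ",
         contig[w[1, 1]], ":", pos[w[1, 1]])
  }
  bad_missing <- grepl(".", gt_only, fixed = TRUE)
  if (any(bad_missing)) {
    w <- arrayInd(which(bad_missing)[1], dim(gt_only))
    stop("missing allele for sample ", samples[w[1, 2]], " at ",
         contig[w[1, 1]], ":", pos[w[1, 1]])
  }
  alleles <- strsplit(gt_only, "|", fixed = TRUE)
  n_al <- lengths(alleles)
  if (any(n_al != 2L)) {
    w <- arrayInd(which(n_al != 2L)[1], dim(gt_only))
    stop("non-diploid genotype for sample ", samples[w[1, 2]], " at ",
         contig[w[1, 1]], ":", pos[w[1, 1]])
  }
  codes <- suppressWarnings(as.integer(unlist(alleles)))
  if (anyNA(codes) || any(codes > 1L)) {
    stop("allele codes other than 0/1 found; input must be biallelic")
  }
  # unlist order: record-major within each sample column pair
  n_rec <- nrow(gt_only)
  n_sam <- length(samples)
  arr <- array(codes, dim = c(2L, n_rec, n_sam))
  geno <- matrix(0L, nrow = 2L * n_sam, ncol = n_rec)
  for (s in seq_len(n_sam)) {
    geno[2L * s - 1L, ] <- arr[1L, , s]
    geno[2L * s, ] <- arr[2L, , s]
  }
  variants <- data.frame(contig = contig, pos = pos, id = id,
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  hap_matrix(geno, variants, samples, ploidy = 2L)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("malformed region '", region, "'; expected contig:start-end")
  list(contig = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Write a haplotype matrix as a phased VCF
#'
#' Emits a minimal VCFv4.2 with GT-only genotype columns; used to materialise
#' simulated cohorts and fixtures. Rows are re-paired into diploid samples,
#' so `ploidy` must be 2 (one-haplotype-per-sample matrices are written as
#' haploid GTs).
#'
#' @param hm a [hap_matrix()].
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hm, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  v <- hm$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=hstkit",
    paste0("##contig=<ID=", v$contig[1], ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", hm$samples), collapse = "\t")
  )
  writeLines(hdr, con)
  n_sam <- length(hm$samples)
  gt_cols <- matrix("", nrow = nrow(v), ncol = n_sam)
  for (s in seq_len(n_sam)) {
    if (hm$ploidy == 2L) {
      gt_cols[, s] <- paste0(hm$geno[2L * s - 1L, ], "|", hm$geno[2L * s, ])
    } else {
      gt_cols[, s] <- as.character(hm$geno[s, ])
    }
  }
  body <- paste(v$contig, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste(body, apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
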