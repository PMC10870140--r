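#' Read a PLINK-format genetic map
#'
#' Parses a whitespace-delimited 4-column map (`chrom`, `id`, `cM`, `bp`) of
#' the kind distributed with Beagle, used to translate base-pair distances to
#' centimorgans. One contig per file; the map must be monotone (cM
#' non-decreasing in bp).
#'
#' @param path path to the map file (plain text or gzip).
#' @return An object of class `genetic_map`: a data frame with columns
#'   `contig`, `bp`, `cM`, sorted by `bp`.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 4L) {
    stop("expected 4 columns (chrom, id, cM, bp), found ", ncol(tab))
  }
  map <- data.frame(contig = as.character(tab[[1]]),
                    bp = as.integer(tab[[4]]),
                    cM = as.numeric(tab[[3]]),
                    stringsAsFactors = FALSE)
  genetic_map(map)
}

#' Construct a genetic map object
#'
#' @param map data frame with columns `contig`, `bp`, `cM`.
#' @return A validated `genetic_map`.
#' @export
genetic_map <- function(map) {
  if (nrow(map) < 2L) stop("a genetic map needs at least 2 points")
  if (length(unique(map$contig)) != 1L) stop("one contig per map file")
  map <- map[order(map$bp), , drop = FALSE]
  rownames(map) <- NULL
  if (anyDuplicated(map$bp)) stop("duplicated bp positions in genetic map")
  if (is.unsorted(map$cM)) stop("non-monotone genetic map: cM decreases with bp")
  structure(map, class = c("genetic_map", "data.frame"))
}

#' Write a genetic map in PLINK 4-column format
#'
#' @param map a `genetic_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  out <- data.frame(map$contig, ".", map$cM, map$bp)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a haplotype CSV
#'
#' Core and ancestral haplotypes travel as CSVs with header
#' `contig,pos,id,ref,alt,allele` (allele coded 0 = REF, 1 = ALT).
#'
#' @param path file path.
#' @return `read_haplotype`: an object of class `haplotype`.
#' @export
read_haplotype <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(contig = "character", id = "character",
                                       ref = "character", alt = "character"))
  as_haplotype(df)
}

#' @rdname read_haplotype
#' @param hap a `haplotype`.
#' @export
write_haplotype <- function(hap, path) {
  utils::write.csv(as.data.frame(hap), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coerce a data frame to a haplotype
#'
#' A haplotype is an ordered run of (marker, allele) pairs with strictly
#' increasing positions on one contig.
#'
#' @param df data frame with columns `contig,pos,id,ref,alt,allele`.
#' @return An object of class `haplotype` (a data frame).
#' @export
as_haplotype <- function(df) {
  req <- c("contig", "pos", "id", "ref", "alt", "allele")
  if (!all(req %in% names(df))) {
    stop("haplotype needs columns ", paste(req, collapse = ","))
  }
  df <- df[req]
  if (nrow(df)) {
    validate_variants(df[c("contig", "pos", "id", "ref", "alt")])
    if (!all(df$allele %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  }
  rownames(df) <- NULL
  class(df) <- c("haplotype", "data.frame")
  df
}

#' @method print haplotype
#' @export
print.haplotype <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<empty haplotype>\n")
    return(invisible(x))
  }
  cat("Haplotype of", nrow(x), "markers,", x$contig[1], ":", x$pos[1], "-",
      x$pos[nrow(x)], "(", x$pos[nrow(x)] - x$pos[1], "bp )\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more markers\n")
  invisible(x)
}
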