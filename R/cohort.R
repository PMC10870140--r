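# Cross-cohort analyses: comparing an external cohort to a published
# ancestral haplotype or tree, and repeat-class sharing with per-group MRCA.

#' Intersect marker sets across genotyping arrays
#'
#' Matches two variant tables on (contig, pos). Markers with identical
#' ref/alt are kept as-is; markers with ref/alt swapped are rescued with
#' their allele codes inverted; strand-ambiguous (A/T, C/G) markers are
#' dropped, as cross-array comparison cannot resolve their strand. With
#' `harmonize = FALSE` only exact (contig, pos, ref, alt) matches survive.
#'
#' @param va,vb variant data frames (`contig,pos,id,ref,alt`).
#' @param harmonize apply the flip rescue and ambiguity drop (default TRUE).
#' @return A data frame with columns `ia`, `ib` (row indexes into `va`, `vb`)
#'   and `flip` (logical; allele codes inverted in `vb` relative to `va`).
#' @export
intersect_markers <- function(va, vb, harmonize = TRUE) {
  key_a <- paste(va$contig, va$pos)
  key_b <- paste(vb$contig, vb$pos)
  ib <- match(key_a, key_b)
  ia <- which(!is.na(ib))
  ib <- ib[ia]
  if (!length(ia)) {
    return(data.frame(ia = integer(0), ib = integer(0), flip = logical(0)))
  }
  ra <- toupper(va$ref[ia]); aa <- toupper(va$alt[ia])
  rb <- toupper(vb$ref[ib]); ab <- toupper(vb$alt[ib])
  same <- ra == rb & aa == ab
  swapped <- ra == ab & aa == rb & !same
  if (!harmonize) {
    keep <- same
    return(data.frame(ia = ia[keep], ib = ib[keep],
                      flip = rep(FALSE, sum(keep))))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- !is.na(comp[ra]) & comp[ra] == aa
  keep <- (same | swapped) & !ambiguous
  data.frame(ia = ia[keep], ib = ib[keep], flip = swapped[keep])
}

#' Compare a cohort to an ancestral haplotype
#'
#' Restricts the ancestral haplotype to the markers shared with the query
#' matrix (harmonised intersection, see [intersect_markers()]), computes
#' every query haplotype's shared segment, and summarises sharing lengths in
#' markers and megabases.
#'
#' @param hm the query [hap_matrix()].
#' @param ancestral a `haplotype`.
#' @param start_idx focal marker column of `hm` (must survive the
#'   intersection).
#' @return A list of class `cohort_haplotype_comparison`: `segments` (a
#'   [shared_segments()] frame on the intersected markers), `summary`
#'   (mean/median/min/max of markers and Mb), `n_shared_markers`.
#' @export
cohort_to_haplotype <- function(hm, ancestral, start_idx) {
  stopifnot(inherits(hm, "hap_matrix"))
  ix <- intersect_markers(hm$variants, as.data.frame(ancestral))
  if (!nrow(ix)) stop("empty marker intersection between cohort and haplotype")
  hap <- as.data.frame(ancestral)[ix$ib, , drop = FALSE]
  # translate to the query matrix's allele coding
  hap$allele <- ifelse(ix$flip, 1L - hap$allele, hap$allele)
  hap$ref <- hm$variants$ref[ix$ia]
  hap$alt <- hm$variants$alt[ix$ia]
  hap <- hap[order(hap$pos), , drop = FALSE]
  hap <- as_haplotype(hap)
  if (!start_idx %in% ix$ia) {
    stop("the start marker did not survive the marker intersection")
  }
  segs <- shared_segments(hm, hap, start_idx)
  mb <- segs$bp_len / 1e6
  summ <- data.frame(
    stat = c("mean", "median", "min", "max"),
    markers = c(mean(segs$n_markers), stats::median(segs$n_markers),
                min(segs$n_markers), max(segs$n_markers)),
    mb = c(mean(mb), stats::median(mb), min(mb), max(mb))
  )
  structure(list(segments = segs, summary = summ, n_shared_markers = nrow(ix)),
            class = "cohort_haplotype_comparison")
}

#' @method print cohort_haplotype_comparison
#' @export
print.cohort_haplotype_comparison <- function(x, ...) {
  cat("Cohort-to-haplotype comparison over", x$n_shared_markers,
      "shared markers\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare a cohort to a haplotype sharing tree
#'
#' For every non-root node of a (possibly published, anonymized) tree, counts
#' how many query haplotypes are consistent with the node haplotype on the
#' intersecting markers. Nodes whose restricted haplotype is empty match
#' vacuously (count = number of query rows) and are flagged uninformative;
#' the root has no haplotype and is reported as not applicable. When sibling
#' nodes coincide after restriction, both count the same rows.
#'
#' @param hst an `hst`.
#' @param hm the query [hap_matrix()].
#' @return A data frame of class `node_concordance`: `node_id`, `n` (node
#'   size in the tree's own cohort), `count`, `proportion` (of query rows),
#'   `uninformative`.
#' @export
cohort_to_hst <- function(hst, hm) {
  stopifnot(inherits(hst, "hst"), inherits(hm, "hap_matrix"))
  ix <- intersect_markers(hst$variants, hm$variants)
  if (!nrow(ix)) stop("empty marker intersection between tree and cohort")
  n_query <- nrow(hm$geno)
  # query alleles translated into the tree's coding
  q <- hm$geno[, ix$ib, drop = FALSE]
  q[, ix$flip] <- 1L - q[, ix$flip]
  tree_col <- ix$ia  # tree marker index of each intersected column
  out <- lapply(hst$nodes, function(nd) {
    if (is.na(nd$lo)) {
      return(data.frame(node_id = nd$id, n = nd$n, count = NA_integer_,
                        proportion = NA_real_, uninformative = TRUE))
    }
    sel <- which(tree_col >= nd$lo & tree_col <= nd$hi)
    if (!length(sel)) {
      return(data.frame(node_id = nd$id, n = nd$n, count = n_query,
                        proportion = 1, uninformative = TRUE))
    }
    al <- nd$alleles[tree_col[sel] - nd$lo + 1L]
    hits <- .rowSums(q[, sel, drop = FALSE] ==
                       rep(al, each = n_query), n_query, length(sel))
    cnt <- sum(hits == length(sel))
    data.frame(node_id = nd$id, n = nd$n, count = cnt,
               proportion = cnt / n_query, uninformative = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("node_concordance", "data.frame")
  out
}

parse_bins <- function(bins) {
  if (is.character(bins)) {
    bins <- lapply(strsplit(bins, ",")[[1]], function(b) {
      as.integer(strsplit(trimws(b), "-")[[1]])
    })
  }
  bins <- lapply(bins, function(b) {
    if (length(b) == 1L) b <- c(b, b)
    if (length(b) != 2L || anyNA(b) || b[1] > b[2]) {
      stop("malformed repeat bin; use e.g. list(c(2, 6), c(7, 9))")
    }
    as.integer(b)
  })
  for (i in seq_along(bins)) {
    for (k in seq_along(bins)) {
      if (i < k && bins[[i]][2] >= bins[[k]][1] && bins[[k]][2] >= bins[[i]][1]) {
        stop("overlapping repeat bins")
      }
    }
  }
  bins
}

#' Ancestral-haplotype sharing by repeat-length class
#'
#' Groups samples by their largest repeat allele into predefined bins
#' (default 2-6, 7-9, 10-14, 15-19, 20-45 repeats) and reports, per bin, the
#' mean shared-segment length in markers and megabases and (when a genetic
#' map is supplied) the gamma-method MRCA estimate computed from the
#' longer-sharing haplotype of each sample. The mean can cover all
#' haplotypes of a bin's samples (default, the threshold-effect view) or
#' only the selected longer-sharing ones.
#'
#' @param segments a [shared_segments()] frame for the full diploid cohort.
#' @param annotation data frame `sample`, `rep1`, `rep2` (repeat counts of
#'   the two alleles, both >= 2). Samples without annotation are excluded
#'   with a warning.
#' @param bins list of `c(lo, hi)` repeat ranges (or a string like
#'   `"2-6,7-9"`); must be disjoint. Ignored when `discrete = TRUE`, which
#'   makes one group per distinct largest-repeat value.
#' @param use `"all"` haplotypes of the bin's samples, or only the
#'   `"selected"` (longer-sharing) one per sample, for the mean lengths.
#' @param map optional `genetic_map` enabling per-bin MRCA estimation.
#' @param locus_pos focal locus position (required with `map`).
#' @param mode,alpha,rho passed to [estimate_mrca()].
#' @param discrete one group per distinct largest repeat instead of bins.
#' @return A list: `table` (per-bin `n_samples`, `n_haplotypes`,
#'   `mean_markers`, `mean_mb`) and `mrca` (named list of `mrca_estimate`s,
#'   `NULL` entries for empty bins or when `map` is missing).
#' @export
group_sharing <- function(segments, annotation,
                          bins = list(c(2L, 6L), c(7L, 9L), c(10L, 14L),
                                      c(15L, 19L), c(20L, 45L)),
                          use = c("all", "selected"), map = NULL,
                          locus_pos = NULL, mode = "independent",
                          alpha = 0.05, rho = 1 / 3, discrete = FALSE) {
  use <- match.arg(use)
  req <- c("sample", "rep1", "rep2")
  if (!all(req %in% names(annotation))) {
    stop("annotation needs columns ", paste(req, collapse = ", "))
  }
  if (any(annotation$rep1 < 2L | annotation$rep2 < 2L)) {
    stop("repeat counts below 2; the shortest allele class starts at 2")
  }
  annotation$max_repeat <- pmax(annotation$rep1, annotation$rep2)
  known <- segments$sample %in% annotation$sample
  if (!all(known)) {
    warning(sum(!known), " haplotype row(s) without repeat annotation excluded")
    segments <- segments[known, , drop = FALSE]
  }
  segments$max_repeat <-
    annotation$max_repeat[match(segments$sample, annotation$sample)]
  if (discrete) {
    vals <- sort(unique(annotation$max_repeat))
    bins <- lapply(vals, function(v) c(v, v))
  } else {
    bins <- parse_bins(bins)
  }
  # per-sample longer-sharing row (for MRCA and use = "selected")
  sel_rows <- unlist(lapply(split(seq_len(nrow(segments)), segments$sample),
    function(i) {
      if (length(i) == 1L) return(i)
      o <- order(-segments$n_markers[i], -segments$bp_len[i], i)
      i[o[1]]
    }))
  selected <- segments[sel_rows, , drop = FALSE]
  rows <- vector("list", length(bins))
  mrca <- vector("list", length(bins))
  labels <- vapply(bins, function(b)
    if (b[1] == b[2]) as.character(b[1]) else paste0(b[1], "-", b[2]), "")
  names(mrca) <- labels
  for (k in seq_along(bins)) {
    b <- bins[[k]]
    seg_all <- segments[segments$max_repeat >= b[1] &
                          segments$max_repeat <= b[2], , drop = FALSE]
    seg_sel <- selected[selected$max_repeat >= b[1] &
                          selected$max_repeat <= b[2], , drop = FALSE]
    seg_use <- if (use == "all") seg_all else seg_sel
    n_samples <- length(unique(seg_all$sample))
    rows[[k]] <- data.frame(
      bin = labels[k], lo = b[1], hi = b[2], n_samples = n_samples,
      n_haplotypes = nrow(seg_use),
      mean_markers = if (nrow(seg_use)) mean(seg_use$n_markers) else NA_real_,
      mean_mb = if (nrow(seg_use)) mean(seg_use$bp_len) / 1e6 else NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(map) && nrow(seg_sel)) {
      if (is.null(locus_pos)) stop("locus_pos is required with a map")
      gl <- segment_genetic_lengths(seg_sel, map, locus_pos)
      if (sum(gl$l_morgans) > 0) {
        mrca[[k]] <- estimate_mrca(gl$l_morgans, mode = mode, alpha = alpha,
                                   rho = rho)
      }
    }
  }
  list(table = do.call(rbind, rows), mrca = mrca)
}
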