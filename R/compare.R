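# Comparing haplotype rows against an ancestral (reference) haplotype:
# shared segments, the sorted comparison matrix, carrier-haplotype selection
# and switch-error flagging.

# Align a haplotype's markers to matrix columns by exact
# (contig, pos, ref, alt) identity. Returns cols (matrix marker indexes,
# ascending), alleles (ancestral alleles in matrix coding) — see
# intersect_markers() for the cross-array harmonised variant.
align_exact <- function(hm, hap) {
  if (!nrow(hap)) stop("empty ancestral haplotype")
  key_m <- paste(hm$variants$contig, hm$variants$pos,
                 hm$variants$ref, hm$variants$alt)
  key_h <- paste(hap$contig, hap$pos, hap$ref, hap$alt)
  cols <- match(key_h, key_m)
  keep <- !is.na(cols)
  if (!any(keep)) stop("ancestral haplotype shares no markers with the matrix")
  o <- order(cols[keep])
  list(cols = cols[keep][o], alleles = as.integer(hap$allele[keep][o]))
}

# Contiguous matching run through the start marker of one match vector.
# Returns 1-based indexes into the aligned marker sequence.
run_through <- function(match_vec, j) {
  len <- length(match_vec)
  if (!match_vec[j]) return(c(lo = j, hi = j, n = 0L))
  mm_left <- which(!match_vec[seq_len(j - 1L)])
  lo <- if (length(mm_left)) max(mm_left) + 1L else 1L
  mm_right <- which(!match_vec[seq.int(j, len)])
  hi <- if (length(mm_right)) j + mm_right[1] - 2L else len
  c(lo = lo, hi = hi, n = hi - lo + 1L)
}

segment_record <- function(match_vec, positions, j) {
  r <- run_through(match_vec, j)
  if (r["n"] == 0L) {
    return(list(n_markers = 0L, left_break = positions[j],
                right_break = positions[j],
                left_censored = FALSE, right_censored = FALSE))
  }
  lc <- r["lo"] == 1L
  rc <- r["hi"] == length(match_vec)
  list(n_markers = as.integer(r["n"]),
       left_break = if (lc) positions[1] else positions[r["lo"] - 1L],
       right_break = if (rc) positions[length(positions)] else positions[r["hi"] + 1L],
       left_censored = lc, right_censored = rc)
}

#' Shared segment between one haplotype row and an ancestral haplotype
#'
#' The maximal contiguous run of markers containing the start marker where
#' the row's allele equals the ancestral allele. Breakpoints are the
#' positions of the nearest mismatching marker on each side of the start
#' marker (or the terminal marker position when the sharing is censored by
#' the data end, flagged `*_censored`). A row that mismatches at the start
#' marker has `n_markers = 0` and both breakpoints at the start position.
#'
#' @param hm a [hap_matrix()].
#' @param row_idx haplotype row index.
#' @param ancestral a `haplotype` covering the start marker.
#' @param start_idx focal marker column of `hm`.
#' @return A one-row data frame (see [shared_segments()]).
#' @export
shared_segment <- function(hm, row_idx, ancestral, start_idx) {
  shared_segments(hm, ancestral, start_idx, rows = row_idx)
}

#' Shared segments of every haplotype row
#'
#' @inheritParams shared_segment
#' @param rows haplotype row indexes (all by default).
#' @return A data frame of class `shared_segments` with columns `row`,
#'   `label`, `sample`, `n_markers`, `left_break`, `right_break`,
#'   `bp_len` (`right_break - left_break`), `left_censored`,
#'   `right_censored`; the focal position is in `attr(, "start_pos")`.
#' @export
shared_segments <- function(hm, ancestral, start_idx, rows = NULL) {
  stopifnot(inherits(hm, "hap_matrix"))
  al <- align_exact(hm, ancestral)
  start_pos <- hm$variants$pos[start_idx]
  j <- match(start_idx, al$cols)
  if (is.na(j)) stop("start marker is outside the ancestral haplotype range")
  if (is.null(rows)) rows <- seq_len(nrow(hm$geno))
  positions <- hm$variants$pos[al$cols]
  sample_of_row <- rep(hm$samples, each = hm$ploidy)
  recs <- lapply(rows, function(r) {
    mv <- hm$geno[r, al$cols] == al$alleles
    segment_record(mv, positions, j)
  })
  out <- data.frame(
    row = rows,
    label = hm$row_labels[rows],
    sample = sample_of_row[rows],
    n_markers = vapply(recs, `[[`, 0L, "n_markers"),
    left_break = vapply(recs, `[[`, 0, "left_break"),
    right_break = vapply(recs, `[[`, 0, "right_break"),
    left_censored = vapply(recs, `[[`, TRUE, "left_censored"),
    right_censored = vapply(recs, `[[`, TRUE, "right_censored"),
    stringsAsFactors = FALSE
  )
  out$bp_len <- out$right_break - out$left_break
  attr(out, "start_pos") <- start_pos
  class(out) <- c("shared_segments", "data.frame")
  out
}

#' Comparison of all haplotypes to the ancestral haplotype
#'
#' The visual-QC matrix: one match/mismatch vector per haplotype row over the
#' ancestral haplotype's markers, rows sorted by the amount of downstream
#' (left side, through the start marker) contiguous sharing, ties broken by
#' right-side sharing and then by row index. For diploid input each row is
#' additionally tagged as its sample's longer- or shorter-sharing haplotype
#' (the blue/white distinction; selection discards the shorter one).
#'
#' @inheritParams shared_segment
#' @return A list of class `hst_comparison`: `match` (logical matrix, sorted
#'   rows), `order` (original row indexes in display order), `segments`
#'   (unsorted [shared_segments()]), `left_run`/`right_run` per original row,
#'   `longer` (logical per original row; all `TRUE` for haploid input),
#'   `positions`, `start_pos`.
#' @export
comparison_matrix <- function(hm, ancestral, start_idx) {
  al <- align_exact(hm, ancestral)
  j <- match(start_idx, al$cols)
  if (is.na(j)) stop("start marker is outside the ancestral haplotype range")
  positions <- hm$variants$pos[al$cols]
  m <- hm$geno[, al$cols, drop = FALSE] ==
    rep(al$alleles, each = nrow(hm$geno))
  n <- nrow(m)
  left_run <- integer(n); right_run <- integer(n)
  for (r in seq_len(n)) {
    mv <- m[r, ]
    if (!mv[j]) next
    mm_left <- which(!mv[seq_len(j - 1L)])
    left_run[r] <- j - (if (length(mm_left)) max(mm_left) else 0L)
    mm_right <- which(!mv[seq.int(j, ncol(m))])
    right_run[r] <- if (length(mm_right)) mm_right[1] - 1L else ncol(m) - j + 1L
  }
  ord <- order(-left_run, -right_run, seq_len(n))
  segs <- shared_segments(hm, ancestral, start_idx)
  longer <- rep(TRUE, n)
  if (hm$ploidy == 2L) {
    for (s in seq_along(hm$samples)) {
      r1 <- 2L * s - 1L; r2 <- 2L * s
      longer[if (keep_first(segs[r1, ], segs[r2, ])) r2 else r1] <- FALSE
    }
  }
  structure(
    list(match = m[ord, , drop = FALSE], order = ord, segments = segs,
         left_run = left_run, right_run = right_run, longer = longer,
         labels = hm$row_labels, positions = positions,
         start_pos = hm$variants$pos[start_idx]),
    class = "hst_comparison"
  )
}

#' @method print hst_comparison
#' @export
print.hst_comparison <- function(x, ...) {
  cat("Haplotype comparison: ", nrow(x$match), " haplotypes x ",
      ncol(x$match), " ancestral markers\n", sep = "")
  cat("  mismatch fraction:", signif(mean(!x$match), 3), "\n")
  invisible(x)
}

# TRUE when segment a should be kept over segment b: more markers, then
# longer bp span, then the earlier row (tie).
keep_first <- function(a, b) {
  if (a$n_markers != b$n_markers) return(a$n_markers > b$n_markers)
  if (a$bp_len != b$bp_len) return(a$bp_len > b$bp_len)
  TRUE
}

#' Select the carrier haplotype of each sample
#'
#' Out of each sample's two phased haplotypes, keeps the one sharing the
#' longer segment of the ancestral haplotype (contiguous markers; bp length
#' breaks ties; a remaining tie keeps the first haplotype with a warning).
#' The result has one row per sample (`ploidy = 1`), in sample order, ready
#' for tree reconstruction.
#'
#' @inheritParams shared_segment
#' @param metric primary sharing metric: `"markers"` (default) or `"bp"`
#'   (the other is the tie-break).
#' @return A [hap_matrix()] with `ploidy = 1`; the kept row indexes are in
#'   `attr(, "kept_rows")`.
#' @export
select_carrier_haplotypes <- function(hm, ancestral, start_idx,
                                      metric = c("markers", "bp")) {
  metric <- match.arg(metric)
  if (hm$ploidy != 2L) stop("carrier selection requires diploid input (ploidy 2)")
  segs <- shared_segments(hm, ancestral, start_idx)
  if (metric == "bp") {
    segs2 <- segs
    segs2$n_markers <- segs$bp_len
    segs2$bp_len <- segs$n_markers
    segs <- segs2
  }
  kept <- integer(length(hm$samples))
  ties <- character(0)
  for (s in seq_along(hm$samples)) {
    r1 <- 2L * s - 1L; r2 <- 2L * s
    a <- segs[r1, ]; b <- segs[r2, ]
    if (a$n_markers == b$n_markers && a$bp_len == b$bp_len) {
      ties <- c(ties, hm$samples[s])
    }
    kept[s] <- if (keep_first(a, b)) r1 else r2
  }
  if (length(ties)) {
    warning("tied sharing for sample(s) ", paste(ties, collapse = ", "),
            "; kept the first haplotype")
  }
  out <- hap_matrix(hm$geno[kept, , drop = FALSE], hm$variants,
                    hm$samples, ploidy = 1L)
  attr(out, "kept_rows") <- kept
  out
}

#' Flag suspected switch errors
#'
#' After a haplotype has separated from the ancestral haplotype, a long run
#' of ancestral-matching markers beyond the breakpoint is unlikely under
#' genuine recombination and most likely marks a phasing switch (or
#' genotyping) error. For every row, all maximal runs of at least `min_run`
#' consecutive matching markers beyond either breakpoint are reported.
#' Suspected errors are reported, never auto-corrected.
#'
#' @inheritParams shared_segment
#' @param min_run minimum run length (markers) to flag; default 20, far above
#'   chance matching at typical array density.
#' @return A data frame with one row per flagged run: `row`, `label`, `side`
#'   (`"left"`/`"right"`), `start`, `end` (bp positions of the run),
#'   `n_markers`.
#' @export
flag_switch_errors <- function(hm, ancestral, start_idx, min_run = 20L) {
  if (min_run < 1L) stop("min_run must be >= 1")
  al <- align_exact(hm, ancestral)
  j <- match(start_idx, al$cols)
  if (is.na(j)) stop("start marker is outside the ancestral haplotype range")
  positions <- hm$variants$pos[al$cols]
  flags <- list()
  for (r in seq_len(nrow(hm$geno))) {
    mv <- hm$geno[r, al$cols] == al$alleles
    run <- run_through(mv, j)
    # regions strictly beyond the breakpoint markers
    regions <- list()
    if (run["n"] == 0L) {
      if (j > 1L) regions$left <- seq_len(j - 1L)
      if (j < length(mv)) regions$right <- seq.int(j + 1L, length(mv))
    } else {
      if (run["lo"] > 2L) regions$left <- seq_len(run["lo"] - 2L)
      if (run["hi"] < length(mv) - 1L) {
        regions$right <- seq.int(run["hi"] + 2L, length(mv))
      }
    }
    for (side in names(regions)) {
      idx <- regions[[side]]
      rl <- rle(mv[idx])
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      hit <- which(rl$values & rl$lengths >= min_run)
      for (h in hit) {
        flags[[length(flags) + 1L]] <- data.frame(
          row = r, label = hm$row_labels[r], side = side,
          start = positions[idx[starts[h]]], end = positions[idx[ends[h]]],
          n_markers = rl$lengths[h], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(flags)) {
    return(data.frame(row = integer(0), label = character(0),
                      side = character(0), start = numeric(0),
                      end = numeric(0), n_markers = integer(0)))
  }
  do.call(rbind, flags)
}
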