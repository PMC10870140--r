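# Haplotype sharing tree construction.
#
# Both builders share the same node bookkeeping: a node stores the haplotype
# rows travelling together, the contiguous marker range they are known to
# share (the node haplotype), and its children in majority-first order.
# Recursion is an explicit FIFO work queue, so tree depth never hits R's
# call-stack limit on large cohorts.

# First column in [from, to] (scanning by `step`) where `rows` carry both
# alleles, or NA if none. Scans in chunks so columns beyond the split are
# never touched.
scan_for_split <- function(geno, rows, from, to, step) {
  if (step > 0L && from > to) return(NA_integer_)
  if (step < 0L && from < to) return(NA_integer_)
  nr <- length(rows)
  if (nr < 2L) return(NA_integer_)
  cols <- seq.int(from, to, by = step)
  nc <- length(cols)
  chunk <- 256L
  i <- 1L
  while (i <= nc) {
    cc <- cols[i:min(i + chunk - 1L, nc)]
    cs <- .colSums(geno[rows, cc, drop = FALSE], nr, length(cc))
    hit <- which(cs != 0L & cs != nr)
    if (length(hit)) return(cc[hit[1]])
    i <- i + chunk
  }
  NA_integer_
}

# Extend a node's contiguous haplotype range in place.
extend_node <- function(nd, lo, hi, al) {
  if (is.na(nd$lo)) {
    nd$lo <- lo; nd$hi <- hi; nd$alleles <- al
  } else if (lo == nd$hi + 1L) {
    nd$alleles <- c(nd$alleles, al); nd$hi <- hi
  } else if (hi == nd$lo - 1L) {
    nd$alleles <- c(al, nd$alleles); nd$lo <- lo
  } else {
    stop("internal error: non-contiguous haplotype extension")
  }
  nd
}

new_hst <- function(direction, start_idx, nodes, hm, min_size) {
  for (i in seq_along(nodes)) nodes[[i]]$n <- length(nodes[[i]]$indexes)
  structure(
    list(direction = direction, start_idx = as.integer(start_idx), root = 1L,
         nodes = nodes, variants = hm$variants, samples = hm$samples,
         row_labels = hm$row_labels, n_haplotypes = nrow(hm$geno),
         min_node_size = as.integer(min_size), anonymized = FALSE,
         extra = NULL),
    class = "hst"
  )
}

check_build_args <- function(hm, start_idx, min_size) {
  stopifnot(inherits(hm, "hap_matrix"))
  if (nrow(hm$geno) < 1L) stop("empty matrix")
  start_idx <- as.integer(start_idx)
  if (is.na(start_idx) || start_idx < 1L || start_idx > ncol(hm$geno)) {
    stop("start_idx out of range [1, ", ncol(hm$geno), "]")
  }
  if (min_size < 1L) stop("min_size must be >= 1")
  start_idx
}

#' Build a unidirectional haplotype sharing tree
#'
#' Scans marker by marker from the start marker in one direction. Uniform
#' columns extend the current node's shared haplotype; the first column where
#' both alleles occur among a node's rows splits it into two children, each
#' inheriting the shared haplotype plus the contradictory marker with its own
#' allele. The larger child always comes first ("majority leftmost"); on equal
#' sizes the child carrying allele 0 at the split marker comes first, so the
#' majority branch is deterministic. A node stops branching when it holds a
#' single row, fewer than `min_size` rows, or the end of the data is reached.
#' The root holds all rows and an empty haplotype.
#'
#' @param hm a [hap_matrix()].
#' @param start_idx focal marker column (1-based); see [marker_at()].
#' @param direction `"right"` (increasing position, upstream here) or
#'   `"left"`.
#' @param min_size minimum node size to keep branching (default 1; also used
#'   as the visualisation / privacy stop).
#' @return An object of class `hst`.
#' @export
build_uhst <- function(hm, start_idx, direction = c("right", "left"),
                       min_size = 1L) {
  direction <- match.arg(direction)
  start_idx <- check_build_args(hm, start_idx, min_size)
  geno <- hm$geno
  nm <- ncol(geno)
  step <- if (direction == "right") 1L else -1L
  end_col <- if (direction == "right") nm else 1L

  nodes <- vector("list", 32L)
  n_nodes <- 0L
  add_node <- function(indexes, lo, hi, alleles, parent) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(nodes)) length(nodes) <<- 2L * length(nodes)
    nodes[[n_nodes]] <<- list(id = n_nodes, indexes = indexes, lo = lo,
                              hi = hi, alleles = alleles,
                              children = integer(0), parent = parent)
    n_nodes
  }
  root <- add_node(seq_len(nrow(geno)), NA_integer_, NA_integer_,
                   integer(0), NA_integer_)
  queue <- root
  qh <- 1L
  while (qh <= length(queue)) {
    id <- queue[qh]; qh <- qh + 1L
    nd <- nodes[[id]]
    rows <- nd$indexes
    from <- if (id == root) start_idx else
      if (step > 0L) nd$hi + 1L else nd$lo - 1L
    split <- scan_for_split(geno, rows, from, end_col, step)
    in_range <- if (step > 0L) from <= end_col else from >= end_col
    if (is.na(split)) {
      if (in_range) {
        rng <- sort.int(c(from, end_col))
        al <- geno[rows[1], rng[1]:rng[2]]
        if (id == root) {
          cid <- add_node(rows, rng[1], rng[2], al, id)
          nodes[[id]]$children <- cid
        } else {
          nodes[[id]] <- extend_node(nodes[[id]], rng[1], rng[2], al)
        }
      }
      next
    }
    if (split != from) {  # absorb the uniform columns before the split
      u_rng <- sort.int(c(from, split - step))
      u_al <- geno[rows[1], u_rng[1]:u_rng[2]]
      if (id != root) {
        nodes[[id]] <- extend_node(nodes[[id]], u_rng[1], u_rng[2], u_al)
      }
    }
    if (id == root) {
      if (split != from) {
        base_lo <- u_rng[1]; base_hi <- u_rng[2]; base_al <- u_al
      } else {
        base_lo <- NA_integer_; base_hi <- NA_integer_; base_al <- integer(0)
      }
    } else {
      nd <- nodes[[id]]
      base_lo <- nd$lo; base_hi <- nd$hi; base_al <- nd$alleles
    }
    g <- geno[rows, split]
    kids <- list(rows[g == 0L], rows[g == 1L])
    al_codes <- c(0L, 1L)
    if (length(kids[[2]]) > length(kids[[1]])) {
      kids <- kids[2:1]; al_codes <- c(1L, 0L)
    }
    for (k in 1:2) {
      if (step > 0L) {
        c_lo <- if (is.na(base_lo)) split else base_lo
        c_al <- c(base_al, al_codes[k])
        c_hi <- split
      } else {
        c_hi <- if (is.na(base_hi)) split else base_hi
        c_al <- c(al_codes[k], base_al)
        c_lo <- split
      }
      cid <- add_node(kids[[k]], c_lo, c_hi, c_al, id)
      nodes[[cid]]$branch <- split
      nodes[[id]]$children <- c(nodes[[id]]$children, cid)
      if (length(kids[[k]]) >= 2L && length(kids[[k]]) >= min_size) {
        queue <- c(queue, cid)
      }
    }
  }
  new_hst(direction, start_idx, nodes[seq_len(n_nodes)], hm, min_size)
}

#' Build a bidirectional haplotype sharing tree
#'
#' Each node scans left and right from its frontiers simultaneously,
#' absorbing uniform columns into its haplotype, until a contradictory column
#' is found on each side (or a side runs out of markers). Rows are then
#' partitioned by their allele pair at the two contradictory columns into two
#' to four nonempty children, ordered by size descending (ties by the
#' lexicographically smaller (left, right) allele pair). When only one side
#' can still branch, a two-way split on that side is performed so trees
#' extend to the contig ends. Termination follows [build_uhst()].
#'
#' @inheritParams build_uhst
#' @return An object of class `hst` with `direction = "bidirectional"`.
#' @export
build_bhst <- function(hm, start_idx, min_size = 1L) {
  start_idx <- check_build_args(hm, start_idx, min_size)
  geno <- hm$geno
  nm <- ncol(geno)

  nodes <- vector("list", 32L)
  n_nodes <- 0L
  add_node <- function(indexes, lo, hi, alleles, parent) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(nodes)) length(nodes) <<- 2L * length(nodes)
    nodes[[n_nodes]] <<- list(id = n_nodes, indexes = indexes, lo = lo,
                              hi = hi, alleles = alleles,
                              children = integer(0), parent = parent)
    n_nodes
  }
  root <- add_node(seq_len(nrow(geno)), NA_integer_, NA_integer_,
                   integer(0), NA_integer_)
  queue <- root
  qh <- 1L
  while (qh <= length(queue)) {
    id <- queue[qh]; qh <- qh + 1L
    nd <- nodes[[id]]
    rows <- nd$indexes
    from_l <- if (id == root) start_idx - 1L else nd$lo - 1L
    from_r <- if (id == root) start_idx else nd$hi + 1L
    split_l <- scan_for_split(geno, rows, from_l, 1L, -1L)
    split_r <- scan_for_split(geno, rows, from_r, nm, 1L)

    # absorb uniform columns on each side (up to the split, or to the end)
    l_stop <- if (is.na(split_l)) 1L else split_l + 1L
    r_stop <- if (is.na(split_r)) nm else split_r - 1L
    base_lo <- nd$lo; base_hi <- nd$hi; base_al <- nd$alleles
    absorb <- function(lo, hi) {
      al <- geno[rows[1], lo:hi]
      if (is.na(base_lo)) {
        base_lo <<- lo; base_hi <<- hi; base_al <<- al
      } else if (lo == base_hi + 1L) {
        base_al <<- c(base_al, al); base_hi <<- hi
      } else {
        base_al <<- c(al, base_al); base_lo <<- lo
      }
    }
    if (from_l >= l_stop) absorb(l_stop, from_l)
    if (from_r <= r_stop) absorb(from_r, r_stop)
    if (id != root && !is.na(base_lo)) {
      nodes[[id]]$lo <- base_lo; nodes[[id]]$hi <- base_hi
      nodes[[id]]$alleles <- base_al
    }

    if (is.na(split_l) && is.na(split_r)) {
      if (id == root && !is.na(base_lo)) {
        cid <- add_node(rows, base_lo, base_hi, base_al, id)
        nodes[[id]]$children <- cid
      }
      next
    }

    if (!is.na(split_l) && !is.na(split_r)) {
      gl <- geno[rows, split_l]
      gr <- geno[rows, split_r]
      key <- gl * 2L + gr
      groups <- split(rows, key)   # names "0".."3" = (left, right) pairs
      keys <- as.integer(names(groups))
      ord <- order(-lengths(groups), keys)
      groups <- groups[ord]; keys <- keys[ord]
      for (k in seq_along(groups)) {
        a_l <- keys[k] %/% 2L; a_r <- keys[k] %% 2L
        c_al <- c(a_l, base_al, a_r)
        cid <- add_node(groups[[k]], split_l, split_r, c_al, id)
        nodes[[cid]]$branch <- c(split_l, split_r)
        nodes[[id]]$children <- c(nodes[[id]]$children, cid)
        if (length(groups[[k]]) >= 2L && length(groups[[k]]) >= min_size) {
          queue <- c(queue, cid)
        }
      }
    } else {
      # one side exhausted: two-way split on the side that can still branch
      split <- if (is.na(split_l)) split_r else split_l
      g <- geno[rows, split]
      kids <- list(rows[g == 0L], rows[g == 1L])
      al_codes <- c(0L, 1L)
      if (length(kids[[2]]) > length(kids[[1]])) {
        kids <- kids[2:1]; al_codes <- c(1L, 0L)
      }
      for (k in 1:2) {
        if (is.na(split_l)) {
          c_lo <- if (is.na(base_lo)) split else base_lo
          c_al <- c(base_al, al_codes[k]); c_hi <- split
        } else {
          c_hi <- if (is.na(base_hi)) split else base_hi
          c_al <- c(al_codes[k], base_al); c_lo <- split
        }
        cid <- add_node(kids[[k]], c_lo, c_hi, c_al, id)
        nodes[[id]]$children <- c(nodes[[id]]$children, cid)
        if (length(kids[[k]]) >= 2L && length(kids[[k]]) >= min_size) {
          queue <- c(queue, cid)
        }
      }
    }
  }
  new_hst("bidirectional", start_idx, nodes[seq_len(n_nodes)], hm, min_size)
}

#' @method print hst
#' @export
print.hst <- function(x, ...) {
  leaves <- sum(vapply(x$nodes, function(nd) length(nd$children) == 0L,
                       logical(1)))
  cat("Haplotype sharing tree (", x$direction, ")\n", sep = "")
  cat("  ", length(x$nodes), " nodes (", leaves, " leaves), ",
      x$n_haplotypes, " haplotypes\n", sep = "")
  cat("  start marker: #", x$start_idx, " at ",
      x$variants$contig[x$start_idx], ":", x$variants$pos[x$start_idx],
      "\n", sep = "")
  if (x$anonymized) cat("  anonymized (counts only)\n")
  invisible(x)
}
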