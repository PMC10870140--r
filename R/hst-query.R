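# Queries on a built haplotype sharing tree.

#' Extract the haplotype stored at a tree node
#'
#' @param hst an `hst`.
#' @param id node id.
#' @return A `haplotype` (empty for the root).
#' @export
node_haplotype <- function(hst, id) {
  nd <- hst$nodes[[id]]
  if (is.null(nd)) stop("no node with id ", id)
  if (is.na(nd$lo)) {
    return(as_haplotype(cbind(hst$variants[0, , drop = FALSE], allele = integer(0))))
  }
  v <- hst$variants[nd$lo:nd$hi, , drop = FALSE]
  v$allele <- as.integer(nd$alleles)
  as_haplotype(v)
}

node_size <- function(hst, id) hst$nodes[[id]]$n

#' The majority branch of a tree
#'
#' The path from the root that always follows the first (largest) child, i.e.
#' walks recombination events back in time towards the majority-based
#' ancestral haplotype.
#'
#' @param hst an `hst`.
#' @return An integer vector of node ids from root to leaf.
#' @export
majority_branch <- function(hst) {
  stopifnot(inherits(hst, "hst"))
  path <- hst$root
  nd <- hst$nodes[[hst$root]]
  while (length(nd$children)) {
    path <- c(path, nd$children[1])
    nd <- hst$nodes[[nd$children[1]]]
  }
  path
}

#' Majority-based ancestral haplotype
#'
#' The haplotype of the deepest node on the majority branch still shared by
#' at least two haplotypes, including the uniform extensions scanned inside
#' that node but excluding its children's contradictory markers. For
#' unidirectional trees the two per-side ancestral haplotypes are combined
#' with [merge_ancestral()].
#'
#' @param hst an `hst` built from at least two haplotype rows.
#' @return A `haplotype`.
#' @export
ancestral_haplotype <- function(hst) {
  stopifnot(inherits(hst, "hst"))
  if (hst$n_haplotypes < 2L) {
    stop("ancestral haplotype needs a tree built from >= 2 haplotypes")
  }
  path <- majority_branch(hst)
  sizes <- vapply(path, function(id) hst$nodes[[id]]$n, integer(1))
  deepest <- path[max(which(sizes >= 2L))]
  node_haplotype(hst, deepest)
}

#' Merge per-side ancestral haplotypes
#'
#' Concatenates the downstream (left) and upstream (right) unidirectional
#' ancestral haplotypes into one, counting the shared start marker once. Both
#' inputs must include the start marker with the same allele; any overlapping
#' marker with conflicting alleles is an error.
#'
#' @param left,right `haplotype` objects from the two unidirectional trees.
#' @param start_pos optional base-pair position of the start marker; when
#'   given, both haplotypes must cover it.
#' @return A `haplotype`.
#' @export
merge_ancestral <- function(left, right, start_pos = NULL) {
  if (!nrow(left) || !nrow(right)) stop("cannot merge an empty haplotype")
  if (!is.null(start_pos)) {
    if (!(start_pos %in% left$pos) || !(start_pos %in% right$pos)) {
      stop("both haplotypes must include the start marker at ", start_pos)
    }
  }
  both <- intersect(left$pos, right$pos)
  if (!length(both)) stop("haplotypes do not overlap; nothing anchors the merge")
  la <- left$allele[match(both, left$pos)]
  ra <- right$allele[match(both, right$pos)]
  if (any(la != ra)) {
    stop("conflicting allele at overlapping marker position ",
         both[which(la != ra)[1]])
  }
  merged <- rbind(as.data.frame(left), as.data.frame(right))
  merged <- merged[!duplicated(merged$pos), , drop = FALSE]
  merged <- merged[order(merged$pos), , drop = FALSE]
  as_haplotype(merged)
}

#' Core haplotype of a cohort
#'
#' The maximal contiguous run of markers containing the start marker at which
#' every haplotype row carries the same allele. Empty when the start column
#' itself is not uniform.
#'
#' @param hm a [hap_matrix()].
#' @param start_idx focal marker column.
#' @return A `haplotype`, possibly with zero rows.
#' @export
core_haplotype <- function(hm, start_idx) {
  stopifnot(inherits(hm, "hap_matrix"))
  geno <- hm$geno
  n <- nrow(geno); nm <- ncol(geno)
  if (start_idx < 1L || start_idx > nm) stop("start_idx out of range")
  cs <- colSums(geno)
  uni <- cs == 0L | cs == n
  if (!uni[start_idx]) {
    return(as_haplotype(cbind(hm$variants[0, , drop = FALSE], allele = integer(0))))
  }
  lo <- start_idx
  while (lo > 1L && uni[lo - 1L]) lo <- lo - 1L
  hi <- start_idx
  while (hi < nm && uni[hi + 1L]) hi <- hi + 1L
  v <- hm$variants[lo:hi, , drop = FALSE]
  v$allele <- as.integer(geno[1, lo:hi])
  as_haplotype(v)
}

#' Shared run of a published tree
#'
#' Recovers the marker run shared by all haplotypes directly from a tree (no
#' genotype matrix needed, so it works on anonymized published trees): the
#' markers covered by the root's children at which all children agree, i.e.
#' everything scanned before the root's first contradictory column(s).
#'
#' @param hst an `hst`.
#' @return A `haplotype`, possibly empty.
#' @export
hst_shared_core <- function(hst) {
  stopifnot(inherits(hst, "hst"))
  kids <- hst$nodes[[hst$root]]$children
  if (!length(kids)) {
    return(as_haplotype(cbind(hst$variants[0, , drop = FALSE], allele = integer(0))))
  }
  first <- hst$nodes[[kids[1]]]
  if (is.na(first$lo)) {
    return(as_haplotype(cbind(hst$variants[0, , drop = FALSE], allele = integer(0))))
  }
  # children may have been extended beyond the split markers while they were
  # themselves processed; the comparable window is the common range
  rng_lo <- max(vapply(kids, function(id) hst$nodes[[id]]$lo, 0L))
  rng_hi <- min(vapply(kids, function(id) hst$nodes[[id]]$hi, 0L))
  if (rng_lo > rng_hi) {
    return(as_haplotype(cbind(hst$variants[0, , drop = FALSE], allele = integer(0))))
  }
  agree <- rep(TRUE, rng_hi - rng_lo + 1L)
  window <- function(id) {
    nd <- hst$nodes[[id]]
    nd$alleles[(rng_lo - nd$lo + 1L):(rng_hi - nd$lo + 1L)]
  }
  ref_al <- window(kids[1])
  for (cid in kids[-1]) agree <- agree & (window(cid) == ref_al)
  keep <- which(agree)
  if (!length(keep)) {
    return(as_haplotype(cbind(hst$variants[0, , drop = FALSE], allele = integer(0))))
  }
  # the shared run is contiguous by construction; take the run containing
  # the innermost agreed marker
  runs <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
  run <- runs[[which.max(lengths(runs))]]
  idx <- rng_lo + run - 1L
  v <- hst$variants[idx, , drop = FALSE]
  v$allele <- as.integer(ref_al[run])
  as_haplotype(v)
}

#' Prune and/or anonymize a tree
#'
#' Removes every node shared by fewer than `min_size` haplotypes (truncating
#' their subtrees) and optionally strips all sample identification, leaving
#' per-node counts only — the form used for publishing trees.
#'
#' @param hst an `hst`.
#' @param min_size minimum node size to keep (>= 1).
#' @param anonymize drop row indexes and sample labels, keeping counts.
#' @return A pruned `hst`.
#' @export
prune_anonymize <- function(hst, min_size = 1L, anonymize = FALSE) {
  stopifnot(inherits(hst, "hst"))
  min_size <- as.integer(min_size)
  if (min_size < 1L) stop("min_size must be >= 1")
  if (min_size > hst$n_haplotypes) {
    stop("min_size (", min_size, ") exceeds the number of haplotypes (",
         hst$n_haplotypes, ")")
  }
  keep <- logical(length(hst$nodes))
  # walk from root keeping nodes with n >= min_size
  stack <- hst$root
  keep[hst$root] <- TRUE
  while (length(stack)) {
    id <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (cid in hst$nodes[[id]]$children) {
      if (hst$nodes[[cid]]$n >= min_size) {
        keep[cid] <- TRUE
        stack <- c(stack, cid)
      }
    }
  }
  new_id <- cumsum(keep)
  nodes <- hst$nodes[keep]
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    nd$id <- new_id[nd$id]
    nd$children <- new_id[nd$children[keep[nd$children]]]
    nd$parent <- if (is.na(nd$parent)) NA_integer_ else new_id[nd$parent]
    if (anonymize) nd$indexes <- NULL
    nodes[[i]] <- nd
  }
  out <- hst
  out$nodes <- nodes
  out$min_node_size <- max(out$min_node_size, min_size)
  if (anonymize) {
    out$samples <- NULL
    out$row_labels <- NULL
    out$anonymized <- TRUE
  }
  out
}

#' Structural validation of a tree
#'
#' Asserts the defining invariants: the root holds every haplotype row and an
#' empty haplotype, children's index sets partition their parent's set, the
#' first child is never smaller than a sibling, every member row equals the
#' node haplotype at the haplotype's markers, and leaf sizes sum to the
#' number of haplotypes. Requires the matrix the tree was built from for the
#' row-consistency check; pass `hm = NULL` to check structure only.
#'
#' @param hst an `hst`.
#' @param hm the source [hap_matrix()] or `NULL`.
#' @return `TRUE`, invisibly; errors on any violation.
#' @export
check_hst <- function(hst, hm = NULL) {
  stopifnot(inherits(hst, "hst"))
  root <- hst$nodes[[hst$root]]
  if (!is.na(root$lo)) stop("root haplotype is not empty")
  leaf_n <- 0L
  for (nd in hst$nodes) {
    if (length(nd$children) == 0L) {
      leaf_n <- leaf_n + nd$n
      next
    }
    sizes <- vapply(nd$children, function(id) hst$nodes[[id]]$n, integer(1))
    if (any(sizes[1] < sizes[-1])) {
      stop("node ", nd$id, ": first child is smaller than a sibling")
    }
    if (!hst$anonymized) {
      kid_rows <- unlist(lapply(nd$children,
                                function(id) hst$nodes[[id]]$indexes))
      if (length(kid_rows) != nd$n || anyDuplicated(kid_rows) ||
          !setequal(kid_rows, nd$indexes)) {
        stop("node ", nd$id, ": children do not partition the parent's rows")
      }
    } else if (sum(sizes) != nd$n) {
      stop("node ", nd$id, ": children sizes do not sum to the node size")
    }
  }
  if (leaf_n != hst$n_haplotypes) {
    stop("leaf sizes sum to ", leaf_n, ", expected ", hst$n_haplotypes)
  }
  if (!is.null(hm) && !hst$anonymized) {
    for (nd in hst$nodes) {
      if (is.na(nd$lo)) next
      sub <- hm$geno[nd$indexes, nd$lo:nd$hi, drop = FALSE]
      ok <- sub == rep(nd$alleles, each = nrow(sub))
      if (!all(ok)) {
        stop("node ", nd$id, ": a member row contradicts the node haplotype")
      }
    }
  }
  invisible(TRUE)
}

#' @export
summary.hst <- function(object, ...) {
  path <- majority_branch(object)
  sizes <- vapply(path, function(id) object$nodes[[id]]$n, integer(1))
  out <- list(direction = object$direction,
              n_nodes = length(object$nodes),
              n_haplotypes = object$n_haplotypes,
              majority_chain_sizes = sizes,
              start_pos = object$variants$pos[object$start_idx])
  class(out) <- "summary.hst"
  out
}

#' @method print summary.hst
#' @export
print.summary.hst <- function(x, ...) {
  cat("HST (", x$direction, "): ", x$n_nodes, " nodes, ",
      x$n_haplotypes, " haplotypes, start at ", x$start_pos, "\n", sep = "")
  cat("majority chain sizes:", paste(x$majority_chain_sizes, collapse = " > "),
      "\n")
  invisible(x)
}
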