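# HST exchange format: gzipped JSON, one object per tree.
#
# Top-level keys: format_version, coords {contig, start_pos}, direction
# ("left"|"right"|"bidirectional"), variants [{contig,pos,id,ref,alt}],
# samples ([labels], absent when anonymized), min_node_size, nodes
# {id -> {indexes, n, start_idx, stop_idx, haplotype [[marker_idx, allele]]}},
# edges [[parent_id, child_id]] in child order. Node ids, marker indexes and
# row indexes are 0-based on disk (language-neutral); the R objects are
# 1-based. Unknown extra fields are tolerated on read and preserved on write.

#' Write a tree in the HST exchange format
#'
#' Always gzip-compressed; the conventional extension is `.hst.gz`.
#'
#' @param hst an `hst`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hst <- function(hst, path) {
  stopifnot(inherits(hst, "hst"))
  v <- hst$variants
  var_list <- lapply(seq_len(nrow(v)), function(i) {
    list(contig = v$contig[i], pos = v$pos[i], id = v$id[i],
         ref = v$ref[i], alt = v$alt[i])
  })
  nodes <- list()
  edges <- list()
  for (nd in hst$nodes) {
    hap <- if (is.na(nd$lo)) list() else {
      idx <- seq.int(nd$lo, nd$hi) - 1L
      lapply(seq_along(idx), function(i) c(idx[i], nd$alleles[i]))
    }
    rec <- list(n = nd$n)
    if (!hst$anonymized && !is.null(nd$indexes)) {
      rec$indexes <- as.integer(nd$indexes) - 1L
    }
    rec$start_idx <- if (is.na(nd$lo)) NULL else nd$lo - 1L
    rec$stop_idx <- if (is.na(nd$hi)) NULL else nd$hi - 1L
    rec$haplotype <- hap
    if (!is.null(nd$extra)) rec <- c(rec, nd$extra)
    nodes[[as.character(nd$id - 1L)]] <- rec
    for (cid in nd$children) edges[[length(edges) + 1L]] <- c(nd$id - 1L, cid - 1L)
  }
  obj <- list(
    format_version = "0.1",
    coords = list(contig = v$contig[1],
                  start_pos = v$pos[hst$start_idx]),
    direction = hst$direction,
    variants = var_list,
    min_node_size = hst$min_node_size,
    anonymized = hst$anonymized,
    nodes = nodes,
    edges = edges
  )
  if (!hst$anonymized && !is.null(hst$row_labels)) obj$samples <- hst$row_labels
  if (!is.null(hst$extra)) obj <- c(obj, hst$extra)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' Read a tree from the HST exchange format
#'
#' Accepts gzipped or plain JSON. Parsing is deliberately tolerant: required
#' keys are validated (errors name the offending node), unknown extra fields
#' are kept and written back by [write_hst()].
#'
#' @param path path to a `.hst.gz` (or plain `.json`) file.
#' @return An `hst`.
#' @export
read_hst <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  known <- c("format_version", "coords", "direction", "variants",
             "min_node_size", "anonymized", "nodes", "edges", "samples")
  for (key in c("direction", "variants", "nodes", "edges", "coords")) {
    if (is.null(obj[[key]])) stop("HST file missing required key '", key, "'")
  }
  if (!obj$direction %in% c("left", "right", "bidirectional")) {
    stop("unknown direction '", obj$direction, "'")
  }
  variants <- data.frame(
    contig = vapply(obj$variants, function(x) as.character(x$contig), ""),
    pos = vapply(obj$variants, function(x) as.integer(x$pos), 0L),
    id = vapply(obj$variants, function(x) as.character(x$id), ""),
    ref = vapply(obj$variants, function(x) as.character(x$ref), ""),
    alt = vapply(obj$variants, function(x) as.character(x$alt), ""),
    stringsAsFactors = FALSE
  )
  validate_variants(variants)
  anonymized <- isTRUE(obj$anonymized) ||
    (is.null(obj$samples) && any(vapply(obj$nodes, function(n) is.null(n$indexes), TRUE)))
  ids <- sort(as.integer(names(obj$nodes)))
  if (any(is.na(ids))) stop("non-integer node id in HST file")
  id_map <- stats::setNames(seq_along(ids), as.character(ids))
  nodes <- vector("list", length(ids))
  for (key in names(obj$nodes)) {
    raw <- obj$nodes[[key]]
    if (is.null(raw$n) && is.null(raw$indexes)) {
      stop("node ", key, " has neither 'n' nor 'indexes'")
    }
    if (is.null(raw$haplotype)) stop("node ", key, " is missing 'haplotype'")
    hap <- raw$haplotype
    if (length(hap)) {
      mk <- vapply(hap, function(p) as.integer(p[[1]]), 0L) + 1L
      al <- vapply(hap, function(p) as.integer(p[[2]]), 0L)
      o <- order(mk)
      mk <- mk[o]; al <- al[o]
      if (any(diff(mk) != 1L)) stop("node ", key, ": haplotype markers not contiguous")
      if (any(mk < 1L) || any(mk > nrow(variants))) {
        stop("node ", key, ": haplotype marker index out of range")
      }
      lo <- mk[1]; hi <- mk[length(mk)]
    } else {
      lo <- NA_integer_; hi <- NA_integer_; al <- integer(0)
    }
    indexes <- if (is.null(raw$indexes)) NULL else
      vapply(raw$indexes, as.integer, 0L) + 1L
    n <- if (!is.null(raw$n)) as.integer(raw$n) else length(indexes)
    extra <- raw[setdiff(names(raw), c("n", "indexes", "start_idx",
                                       "stop_idx", "haplotype"))]
    nid <- id_map[[key]]
    nodes[[nid]] <- list(id = nid, indexes = indexes, lo = lo, hi = hi,
                         alleles = al, children = integer(0),
                         parent = NA_integer_, n = n,
                         extra = if (length(extra)) extra else NULL)
  }
  for (e in obj$edges) {
    p <- as.character(as.integer(e[[1]])); c_ <- as.character(as.integer(e[[2]]))
    if (is.na(id_map[p])) stop("edge refers to nonexistent parent node ", p)
    if (is.na(id_map[c_])) stop("edge refers to nonexistent child node ", c_)
    pi <- id_map[[p]]; ci <- id_map[[c_]]
    nodes[[pi]]$children <- c(nodes[[pi]]$children, ci)
    nodes[[ci]]$parent <- pi
  }
  roots <- which(vapply(nodes, function(nd) is.na(nd$parent), TRUE))
  if (length(roots) != 1L) {
    stop("HST file must contain exactly one root node, found ", length(roots))
  }
  start_pos <- as.integer(obj$coords$start_pos)
  start_idx <- match(start_pos, variants$pos)
  if (is.na(start_idx)) stop("start position ", start_pos, " is not a marker")
  samples <- if (is.null(obj$samples)) NULL else
    vapply(obj$samples, as.character, "")
  extra <- obj[setdiff(names(obj), known)]
  structure(
    list(direction = obj$direction, start_idx = start_idx, root = roots,
         nodes = nodes, variants = variants, samples = samples,
         row_labels = samples, n_haplotypes = nodes[[roots]]$n,
         min_node_size = if (is.null(obj$min_node_size)) 1L else
           as.integer(obj$min_node_size),
         anonymized = anonymized,
         extra = if (length(extra)) extra else NULL),
    class = "hst"
  )
}
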