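# Shared fixtures and independent oracles, all built in code.

# Six-haplotype, seven-marker reference fixture; start marker column 4.
f1_rows <- rbind(
  h0 = c(0, 1, 0, 1, 0, 1, 1),
  h1 = c(0, 1, 0, 1, 0, 1, 0),
  h2 = c(1, 1, 0, 1, 0, 1, 1),
  h3 = c(0, 0, 1, 1, 0, 0, 1),
  h4 = c(0, 1, 0, 1, 1, 1, 1),
  h5 = c(0, 1, 0, 0, 0, 1, 1)
)

f1_variants <- function() {
  data.frame(contig = "9", pos = 100L * (1:7), id = paste0("m", 1:7),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

f1_matrix <- function() {
  hap_matrix(f1_rows, f1_variants(), paste0("h", 0:5), ploidy = 1L)
}

# Same six haplotypes paired into three diploid samples.
f1_diploid <- function() {
  hap_matrix(f1_rows, f1_variants(), paste0("s", 1:3), ploidy = 2L)
}

f1_haplotype <- function(row) {
  v <- f1_variants()
  v$allele <- as.integer(f1_rows[row, ])
  as_haplotype(v)
}

random_matrix <- function(n_rows, n_markers, seed, p = 0.5) {
  set.seed(seed)
  geno <- matrix(rbinom(n_rows * n_markers, 1L, p), n_rows, n_markers)
  v <- data.frame(contig = "1", pos = 1000L * seq_len(n_markers),
                  id = paste0("rs", seq_len(n_markers)), ref = "A", alt = "C",
                  stringsAsFactors = FALSE)
  hap_matrix(geno, v, paste0("r", seq_len(n_rows)), ploidy = 1L)
}

# Independent oracle: for every row, the first marker (scanning from the
# start in `direction`) where its allele differs from the consensus of the
# rows still co-travelling with it; NA for a row that never leaves the
# majority. Ties in the consensus resolve to allele 0, mirroring the
# documented leftmost-majority tie-break.
naive_divergence <- function(geno, start_idx, direction) {
  n <- nrow(geno)
  cols <- if (direction == "right") start_idx:ncol(geno) else start_idx:1
  div <- rep(NA_integer_, n)
  alive <- seq_len(n)
  for (col in cols) {
    if (length(alive) < 2L) break
    vals <- geno[alive, col]
    n1 <- sum(vals)
    if (n1 == 0L || n1 == length(alive)) next
    maj <- if (n1 > length(alive) - n1) 1L else 0L
    div[alive[vals != maj]] <- col
    alive <- alive[vals == maj]
  }
  div
}

# Tree-derived divergence: the split marker at which each row entered a
# non-majority child of a majority-branch node.
hst_divergence <- function(hst) {
  div <- rep(NA_integer_, hst$n_haplotypes)
  for (id in majority_branch(hst)) {
    nd <- hst$nodes[[id]]
    if (length(nd$children) < 2L) next
    split_col <- hst$nodes[[nd$children[1]]]$branch
    for (cid in nd$children[-1]) {
      div[hst$nodes[[cid]]$indexes] <- split_col
    }
  }
  div
}

# Minimal phased VCF text, one GT string per sample per record.
write_test_vcf <- function(path, gt, contig = "9", pos = NULL,
                           alt = NULL, samples = NULL) {
  n_rec <- nrow(gt)
  if (is.null(pos)) pos <- 100L * seq_len(n_rec)
  if (is.null(alt)) alt <- rep("G", n_rec)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(gt)))
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", contig, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  for (i in seq_len(n_rec)) {
    lines <- c(lines, paste(c(contig, pos[i], paste0("m", i), "A", alt[i],
                              ".", "PASS", ".", "GT", gt[i, ]),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Structural equality of two trees on the exchange-schema fields.
expect_hst_equal <- function(a, b) {
  expect_equal(length(a$nodes), length(b$nodes))
  expect_equal(a$direction, b$direction)
  expect_equal(a$variants$pos, b$variants$pos)
  expect_equal(a$start_idx, b$start_idx)
  for (i in seq_along(a$nodes)) {
    na <- a$nodes[[i]]; nb <- b$nodes[[i]]
    expect_equal(na$n, nb$n)
    expect_equal(na$lo, nb$lo)
    expect_equal(na$hi, nb$hi)
    expect_equal(as.integer(na$alleles), as.integer(nb$alleles))
    expect_equal(na$children, nb$children)
    if (!is.null(na$indexes) || !is.null(nb$indexes)) {
      expect_equal(as.integer(na$indexes), as.integer(nb$indexes))
    }
  }
}
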