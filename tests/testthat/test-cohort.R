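test_that("marker intersection rescues flipped alleles and drops ambiguous ones", {
  va <- data.frame(contig = "9", pos = c(100L, 200L, 300L, 400L),
                   id = paste0("a", 1:4),
                   ref = c("A", "A", "A", "A"),
                   alt = c("G", "G", "T", "G"), stringsAsFactors = FALSE)
  vb <- data.frame(contig = "9", pos = c(100L, 200L, 300L, 500L),
                   id = paste0("b", 1:4),
                   ref = c("A", "G", "A", "A"),
                   alt = c("G", "A", "T", "G"), stringsAsFactors = FALSE)
  ix <- intersect_markers(va, vb)
  # pos 100 exact, pos 200 flipped, pos 300 A/T ambiguous (dropped),
  # pos 400/500 unmatched
  expect_equal(ix$ia, c(1L, 2L))
  expect_equal(ix$flip, c(FALSE, TRUE))
  strict <- intersect_markers(va, vb, harmonize = FALSE)
  expect_equal(strict$ia, c(1L, 3L))
  expect_false(any(strict$flip))
})

test_that("cohort-to-haplotype reproduces within-cohort segment lengths", {
  hm <- f1_matrix()
  anc <- f1_haplotype("h0")
  res <- cohort_to_haplotype(hm, anc, 4)
  expect_equal(res$n_shared_markers, 7L)
  direct <- shared_segments(hm, anc, 4)
  expect_equal(res$segments$n_markers, direct$n_markers)
  expect_equal(res$segments$bp_len, direct$bp_len)
  expect_equal(res$summary$markers[res$summary$stat == "mean"],
               mean(direct$n_markers))
  # flipped query coding is rescued
  hm_flip <- hm
  hm_flip$geno <- 1L - hm_flip$geno
  hm_flip$variants$ref <- "G"
  hm_flip$variants$alt <- "A"
  res_flip <- cohort_to_haplotype(hm_flip, anc, 4)
  expect_equal(res_flip$segments$n_markers, direct$n_markers)
  # disjoint marker sets cannot be compared
  anc_off <- anc
  anc_off$pos <- anc_off$pos + 5L
  expect_error(cohort_to_haplotype(hm, as_haplotype(anc_off), 4),
               "empty marker intersection")
})

test_that("thinning the ancestral markers only widens breakpoints outward", {
  # on a marker subset every retained match stays a match, so the thinned
  # run can only end at or beyond the full-resolution breakpoints
  sim <- simulate_cohort(n_carriers = 25, n_markers = 300, tau = 40, seed = 9)
  hm <- sim$matrix
  anc <- sim$truth$founder
  full <- cohort_to_haplotype(hm, anc, sim$focal_idx)
  keep <- sort(unique(c(seq(1, 300, 2), sim$focal_idx)))
  thin <- cohort_to_haplotype(hm, as_haplotype(anc[keep, ]), sim$focal_idx)
  expect_equal(thin$n_shared_markers, length(keep))
  # censored rows stop at the terminal retained marker, which moves inward
  # with the thinning, so compare true breakpoints only
  lok <- !(full$segments$left_censored | thin$segments$left_censored)
  rok <- !(full$segments$right_censored | thin$segments$right_censored)
  expect_true(all(thin$segments$left_break[lok] <=
                    full$segments$left_break[lok]))
  expect_true(all(thin$segments$right_break[rok] >=
                    full$segments$right_break[rok]))
  expect_gt(sum(lok), 0L)
  expect_gt(sum(rok), 0L)
})

test_that("comparing a matrix to its own tree counts every node exactly", {
  for (hst_fun in list(function(m) build_uhst(m, 4),
                       function(m) build_bhst(m, 4))) {
    hm <- f1_matrix()
    hst <- hst_fun(hm)
    conc <- cohort_to_hst(hst, hm)
    non_root <- conc[conc$node_id != hst$root & !conc$uninformative, ]
    expect_equal(non_root$count, non_root$n)
    expect_true(is.na(conc$count[conc$node_id == hst$root]))
  }
  sim <- simulate_cohort(n_carriers = 30, n_markers = 200, tau = 20, seed = 3)
  hst <- build_bhst(sim$matrix, sim$focal_idx)
  conc <- cohort_to_hst(hst, sim$matrix)
  ok <- conc$node_id != hst$root
  expect_equal(conc$count[ok], conc$n[ok])
})

test_that("node counts are monotone non-increasing towards the leaves", {
  sim <- simulate_cohort(n_carriers = 20, n_controls = 20, n_markers = 150,
                         tau = 25, seed = 8)
  hst <- build_bhst(sim$matrix, sim$focal_idx)
  query <- simulate_cohort(n_carriers = 25, n_markers = 150, tau = 25,
                           seed = 88)$matrix
  conc <- cohort_to_hst(hst, query)
  for (nd in hst$nodes) {
    if (nd$id == hst$root || !length(nd$children)) next
    for (cid in nd$children) {
      expect_lte(conc$count[conc$node_id == cid],
                 conc$count[conc$node_id == nd$id])
    }
  }
})

test_that("repeat-class grouping follows the largest repeat", {
  segs <- data.frame(
    row = 1:6, label = paste0("s", rep(1:3, each = 2), "_", rep(1:2, 3)),
    sample = rep(paste0("s", 1:3), each = 2),
    n_markers = c(600L, 400L, 500L, 100L, 20L, 10L),
    left_break = 0, right_break = c(6e6, 4e6, 5e6, 1e6, 2e5, 1e5),
    left_censored = FALSE, right_censored = FALSE)
  segs$bp_len <- segs$right_break - segs$left_break
  ann <- data.frame(sample = c("s1", "s2", "s3"),
                    rep1 = c(2L, 2L, 8L), rep2 = c(24L, 21L, 2L))
  gs <- group_sharing(segs, ann)
  tab <- gs$table
  expect_equal(tab$n_samples[tab$bin == "20-45"], 2L)   # (2,24) and (2,21)
  expect_equal(tab$mean_markers[tab$bin == "20-45"], mean(c(600, 400, 500, 100)))
  expect_equal(tab$n_samples[tab$bin == "7-9"], 1L)
  expect_equal(tab$n_samples[tab$bin == "2-6"], 0L)
  expect_true(is.na(tab$mean_markers[tab$bin == "2-6"]))
  # selected-only averaging keeps the longer row per sample
  gs_sel <- group_sharing(segs, ann, use = "selected")
  expect_equal(gs_sel$table$mean_markers[tab$bin == "20-45"], mean(c(600, 500)))
  # per-bin MRCA uses the selected rows
  map <- genetic_map(data.frame(contig = "1", bp = c(0L, 10000000L),
                                cM = c(0, 10)))
  gs_m <- group_sharing(segs, ann, map = map, locus_pos = 0)
  expect_s3_class(gs_m$mrca[["20-45"]], "mrca_estimate")
  expect_null(gs_m$mrca[["2-6"]])
  expect_error(group_sharing(segs, ann, bins = list(c(2, 8), c(7, 9))),
               "overlapping")
  expect_error(group_sharing(segs, data.frame(sample = "s1", rep1 = 1L,
                                              rep2 = 5L)),
               "below 2")
  expect_warning(group_sharing(segs, ann[1:2, ]), "without repeat annotation")
  # discrete grouping: one group per distinct largest repeat
  gs_d <- group_sharing(segs, ann, discrete = TRUE)
  expect_equal(gs_d$table$bin, c("8", "21", "24"))
})

test_that("groups diverging earlier from the founder share less and date older", {
  sim_young <- simulate_cohort(n_carriers = 60, n_markers = 500,
                               spacing_bp = 2e4, tau = 10, seed = 21)
  sim_old <- simulate_cohort(n_carriers = 60, n_markers = 500,
                             spacing_bp = 2e4, tau = 100, seed = 21)
  # same seed => same founder and marker panel
  expect_equal(sim_young$truth$founder$allele, sim_old$truth$founder$allele)
  get_group <- function(sim) {
    hm <- subset_hap_matrix(sim$matrix, rows = sim$truth$carriers$row)
    segs <- shared_segments(hm, sim$truth$founder, sim$focal_idx)
    segs <- segment_genetic_lengths(segs, sim$map, sim$locus_pos)
    list(mean_markers = mean(segs$n_markers),
         tau_hat = estimate_mrca(segs$l_morgans)$tau_hat)
  }
  young <- get_group(sim_young)
  old <- get_group(sim_old)
  expect_gt(young$mean_markers, old$mean_markers)
  expect_lt(young$tau_hat, old$tau_hat)
})
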