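test_that("shared segments match the hand-computed fixture values", {
  hm <- f1_matrix()
  anc <- f1_haplotype("h0")
  s0 <- shared_segment(hm, 1, anc, 4)
  expect_equal(s0$n_markers, 7L)
  expect_equal(c(s0$left_break, s0$right_break), c(100, 700))
  expect_true(s0$left_censored && s0$right_censored)

  s3 <- shared_segment(hm, 4, anc, 4)  # row h3
  expect_equal(s3$n_markers, 2L)
  expect_equal(c(s3$left_break, s3$right_break), c(300, 600))
  expect_equal(s3$bp_len, 300)
  expect_false(s3$left_censored || s3$right_censored)

  s5 <- shared_segment(hm, 6, anc, 4)  # h5 mismatches at the start marker
  expect_equal(s5$n_markers, 0L)
  expect_equal(c(s5$left_break, s5$right_break), c(400, 400))

  expect_error(shared_segments(hm, anc[5:7, ], 4), "outside the ancestral")
})

test_that("segment sharing shrinks when a matching allele is flipped", {
  hm <- f1_matrix()
  anc <- f1_haplotype("h0")
  base <- shared_segment(hm, 1, anc, 4)$n_markers
  for (k in 1:7) {
    flipped <- hm
    flipped$geno[1, k] <- 1L - flipped$geno[1, k]
    expect_lt(shared_segment(flipped, 1, anc, 4)$n_markers, base)
  }
})

test_that("comparison matrix sorts by left then right sharing", {
  hm <- f1_matrix()
  anc <- f1_haplotype("h0")
  cmp <- comparison_matrix(hm, anc, 4)
  expect_equal(dim(cmp$match), c(6L, 7L))
  # left runs: h0 4, h1 4, h2 3, h3 1, h4 4, h5 0; right runs break the
  # h0/h1/h4 tie: h0 4, h1 3, h4 1
  expect_equal(cmp$left_run, c(4L, 4L, 3L, 1L, 4L, 0L))
  expect_equal(cmp$right_run, c(4L, 3L, 4L, 2L, 1L, 0L))
  expect_equal(cmp$order, c(1L, 2L, 5L, 3L, 4L, 6L))
  all_match <- comparison_matrix(
    hap_matrix(f1_rows[rep(1, 3), ], f1_variants(), paste0("x", 1:3), 1L),
    anc, 4)
  expect_true(all(all_match$match))
  expect_equal(all_match$order, 1:3)
  expect_error(comparison_matrix(hm, anc[0, ], 4), "empty ancestral")
})

test_that("carrier selection keeps the longer-sharing haplotype per sample", {
  hm <- f1_diploid()  # samples (h0,h1), (h2,h3), (h4,h5)
  anc <- f1_haplotype("h0")
  sel <- select_carrier_haplotypes(hm, anc, 4)
  expect_equal(sel$ploidy, 1L)
  expect_equal(nrow(sel$geno), 3L)
  expect_equal(attr(sel, "kept_rows"), c(1L, 3L, 5L))  # h0, h2, h4
  segs <- shared_segments(hm, anc, 4)
  for (s in 1:3) {
    kept <- attr(sel, "kept_rows")[s]
    other <- if (kept %% 2L) kept + 1L else kept - 1L
    expect_gte(segs$n_markers[kept], segs$n_markers[other])
  }
  expect_error(select_carrier_haplotypes(f1_matrix(), anc, 4), "ploidy 2")
})

test_that("tied haplotypes keep the first row with a warning", {
  v <- f1_variants()
  hm <- hap_matrix(f1_rows[c(1, 1), ], v, "dup", ploidy = 2L)
  expect_warning(sel <- select_carrier_haplotypes(hm, f1_haplotype("h0"), 4),
                 "tied")
  expect_equal(attr(sel, "kept_rows"), 1L)
  # both rows mismatching at the start also go down the tie path
  hm2 <- hap_matrix(f1_rows[c(6, 6), ], v, "dup", ploidy = 2L)
  expect_warning(sel2 <- select_carrier_haplotypes(hm2, f1_haplotype("h0"), 4),
                 "tied")
  expect_equal(attr(sel2, "kept_rows"), 1L)
})

test_that("long matching runs beyond the breakpoint are flagged", {
  set.seed(11)
  nm <- 60L
  v <- data.frame(contig = "1", pos = 1000L * (1:nm), id = paste0("v", 1:nm),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  anc_al <- rbinom(nm, 1, 0.5)
  anc <- as_haplotype(cbind(v, allele = anc_al))
  # row equals the ancestral except one interior mismatch: the run beyond
  # the break must be flagged on that side
  row1 <- anc_al; row1[40] <- 1L - row1[40]
  # row diverging at the same point into random background: no long run
  row2 <- anc_al
  row2[41:nm] <- rbinom(nm - 40L, 1, 0.5)
  row2[41] <- 1L - anc_al[41]
  hm <- hap_matrix(rbind(row1, row2), v, c("a", "b"), ploidy = 1L)
  flags <- flag_switch_errors(hm, anc, 30, min_run = 10L)
  expect_equal(flags$row, 1L)
  expect_equal(flags$side, "right")
  expect_equal(flags$start, 41000)
  expect_equal(flags$end, 60000)
  expect_equal(flags$n_markers, 20L)
  # vacuous when min_run exceeds the marker count
  expect_equal(nrow(flag_switch_errors(hm, anc, 30, min_run = nm + 1L)), 0L)
})

test_that("a planted switch error in a simulated carrier is flagged", {
  sim <- simulate_cohort(n_carriers = 30, n_markers = 400, tau = 10,
                         spacing_bp = 5e4, switch_error_rate = 0, seed = 5)
  hm <- sim$matrix
  anc <- sim$truth$founder
  tr <- sim$truth$carriers
  # pick a carrier retaining a wide interval and swap its strands midway
  # through the retained right side
  wide <- which(tr$right_break - sim$locus_pos > 6e6)[1]
  expect_false(is.na(wide))
  r_car <- tr$row[wide]
  r_oth <- if (r_car %% 2L) r_car + 1L else r_car - 1L
  cut <- sim$locus_pos + 3e6
  m <- which(hm$variants$pos >= cut)[1]
  tmp <- hm$geno[r_car, m:400]
  hm$geno[r_car, m:400] <- hm$geno[r_oth, m:400]
  hm$geno[r_oth, m:400] <- tmp
  flags <- flag_switch_errors(hm, anc, sim$focal_idx, min_run = 20L)
  hit <- flags[flags$row == r_oth & flags$side == "right", ]
  expect_gte(nrow(hit), 1L)
  expect_equal(hit$start[1], hm$variants$pos[m])
})
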