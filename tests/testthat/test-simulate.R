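test_that("simulation is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(n_carriers = 10, n_controls = 5, n_markers = 100,
                        tau = 20, switch_error_rate = 0.1, seed = 42,
                        dir = d1)
  s2 <- simulate_cohort(n_carriers = 10, n_controls = 5, n_markers = 100,
                        tau = 20, switch_error_rate = 0.1, seed = 42,
                        dir = d2)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth$carriers, s2$truth$carriers)
  expect_identical(readLines(gzfile(s1$paths$vcf)),
                   readLines(gzfile(s2$paths$vcf)))
  expect_identical(readLines(s1$paths$map), readLines(s2$paths$map))
  # a different seed changes the data
  s3 <- simulate_cohort(n_carriers = 10, n_controls = 5, n_markers = 100,
                        tau = 20, seed = 43)
  expect_false(identical(s1$matrix$geno, s3$matrix$geno))
})

test_that("carriers copy the founder exactly between their breakpoints", {
  sim <- simulate_cohort(n_carriers = 50, n_markers = 800, tau = 30, seed = 2)
  founder <- sim$truth$founder$allele
  pos <- sim$matrix$variants$pos
  tr <- sim$truth$carriers
  for (i in seq_len(nrow(tr))) {
    inside <- pos >= tr$left_break[i] & pos <= tr$right_break[i]
    expect_identical(sim$matrix$geno[tr$row[i], inside],
                     founder[inside])
  }
  # breakpoints flank the focal locus
  expect_true(all(tr$left_break <= sim$locus_pos))
  expect_true(all(tr$right_break >= sim$locus_pos))
})

test_that("a very old founder leaves only the focal marker", {
  sim <- simulate_cohort(n_carriers = 40, n_markers = 200, tau = 1e6,
                         seed = 6)
  tr <- sim$truth$carriers
  expect_true(all(tr$right_break - tr$left_break < 1000))
  hm <- subset_hap_matrix(sim$matrix, rows = tr$row)
  segs <- shared_segments(hm, sim$truth$founder, sim$focal_idx)
  # every carrier still matches at the focal marker itself
  expect_true(all(segs$n_markers >= 1L))
  expect_lt(mean(segs$n_markers), 5)
})

test_that("per-side genetic lengths have the exponential mean 1/tau", {
  sim <- simulate_cohort(n_carriers = 200, n_markers = 2000, tau = 30,
                         seed = 31)
  tr <- sim$truth$carriers
  sides <- c(sim$locus_pos - tr$left_break,
             tr$right_break - sim$locus_pos) / 1e8  # Morgans at 1 cM/Mb
  se <- (1 / 30) / sqrt(length(sides))
  expect_lt(abs(mean(sides) - 1 / 30), 3 * se)
})

test_that("planted switch errors are recorded and swap the strands", {
  sim <- simulate_cohort(n_carriers = 10, n_controls = 10, n_markers = 50,
                         tau = 20, switch_error_rate = 0.4, seed = 13)
  se <- sim$truth$switch_errors
  expect_gt(nrow(se), 0L)
  clean <- simulate_cohort(n_carriers = 10, n_controls = 10, n_markers = 50,
                           tau = 20, switch_error_rate = 0, seed = 13)
  for (i in seq_len(nrow(se))) {
    s <- match(se$sample[i], sim$matrix$samples)
    m <- match(se$pos[i], sim$matrix$variants$pos)
    nm <- ncol(sim$matrix$geno)
    expect_identical(sim$matrix$geno[2 * s - 1, m:nm],
                     unname(clean$matrix$geno[2 * s, m:nm]))
    expect_identical(sim$matrix$geno[2 * s, m:nm],
                     unname(clean$matrix$geno[2 * s - 1, m:nm]))
  }
})

test_that("truth files round-trip through the written artifacts", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(n_carriers = 8, n_controls = 2, n_markers = 60,
                         tau = 15, seed = 4, dir = dir)
  hm <- read_phased_vcf(sim$paths$vcf)
  expect_equal(hm$geno, sim$matrix$geno)
  expect_equal(hm$samples, sim$matrix$samples)
  map <- read_genetic_map(sim$paths$map)
  expect_equal(map$cM, sim$map$cM)
  truth <- utils::read.table(sim$paths$truth_tsv, header = TRUE,
                             stringsAsFactors = FALSE)
  expect_equal(truth$left_break, sim$truth$carriers$left_break)
  tj <- jsonlite::fromJSON(sim$paths$truth_json)
  expect_equal(tj$tau, 15)
  expect_equal(tj$founder, sim$truth$founder$allele)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulate_cohort(0, 0), "at least one sample")
  expect_error(simulate_cohort(5, tau = 0), "tau")
  expect_error(simulate_cohort(5, switch_error_rate = 1.5), "switch_error")
  expect_error(simulate_cohort(5, positions = c(10L, 10L)), "increasing")
})

test_that("end-to-end: trees on a simulated cohort recover the founder age", {
  reps <- 20
  ratios <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(n_carriers = 100, n_markers = 600,
                           spacing_bp = 4e4, tau = 30, seed = 500 + r)
    hm <- subset_hap_matrix(sim$matrix, rows = sim$truth$carriers$row)
    anc <- merge_ancestral(
      ancestral_haplotype(build_uhst(hm, sim$focal_idx, "left")),
      ancestral_haplotype(build_uhst(hm, sim$focal_idx, "right")),
      start_pos = sim$matrix$variants$pos[sim$focal_idx])
    segs <- shared_segments(hm, anc, sim$focal_idx)
    segs <- segment_genetic_lengths(segs, sim$map, sim$locus_pos)
    ratios[r] <- estimate_mrca(segs$l_morgans)$tau_hat / 30
  }
  expect_lt(abs(mean(ratios) - 1), 0.1)
})
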