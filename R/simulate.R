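# Founder-haplotype cohort simulator: the test substrate for the whole
# toolkit. Emulates the inheritance model the gamma method assumes — a
# founder haplotype inherited by n carriers, each retaining the founder
# around the focal locus up to per-side recombination breakpoints at
# Exponential(tau) genetic distance — over an LD-free background drawn from
# per-marker allele frequencies, with an optional planted switch-error
# process.

#' Simulate a phased cohort descending from a founder haplotype
#'
#' Draws a founder haplotype from the background allele-frequency law, then
#' gives each of `n_carriers` carrier haplotypes the founder alleles between
#' per-side breakpoints whose genetic distances from the focal locus are
#' Exponential(`tau`) (converted to bp through a uniform `cM_per_Mb` map)
#' and background alleles elsewhere. Each carrier haplotype is paired with a
#' background haplotype into a diploid sample, on a randomly chosen strand;
#' controls are background diploids. Switch errors are planted per haplotype
#' with probability `switch_error_rate` by swapping the sample's two strands
#' from a random marker onward. Markers are independent (no background LD),
#' so chance sharing is minimal by design. Fully deterministic given `seed`.
#'
#' @param n_carriers number of carrier samples (>= 0).
#' @param n_controls number of background-only samples (>= 0).
#' @param n_markers number of biallelic markers.
#' @param spacing_bp distance between adjacent markers (default 1000 bp).
#' @param positions explicit marker positions (overrides `spacing_bp`).
#' @param freq_range background ALT-allele frequencies are drawn uniformly
#'   from this interval (default `c(0.05, 0.95)`).
#' @param tau generations to the founder (> 0).
#' @param cM_per_Mb uniform recombination rate (default 1, so analytic
#'   expectations are exact).
#' @param switch_error_rate per-haplotype probability of a planted switch
#'   error (default 0).
#' @param locus_pos focal locus position (default: the middle marker).
#' @param contig contig name (default `"1"`).
#' @param seed integer seed; every source of randomness derives from it.
#' @param dir optional directory: when given, writes `cohort.vcf.gz`,
#'   `map.txt` (PLINK 4-column), `truth.tsv` and `truth.json` there.
#' @return A list of class `founder_sim`: `matrix` (a [hap_matrix()]),
#'   `map` (a `genetic_map`), `truth` (a list: `founder` haplotype,
#'   `carriers` data frame with `sample`, `row` (carrier row index),
#'   `strand`, `left_break`, `right_break` in bp, `tau`, `seed`,
#'   `switch_errors` data frame), `focal_idx`, `locus_pos`, and `paths`
#'   when `dir` was given.
#' @export
simulate_cohort <- function(n_carriers, n_controls = 0L, n_markers = 1000L,
                            spacing_bp = 1000L, positions = NULL,
                            freq_range = c(0.05, 0.95), tau = 30,
                            cM_per_Mb = 1, switch_error_rate = 0,
                            locus_pos = NULL, contig = "1", seed = 1L,
                            dir = NULL) {
  if (n_carriers < 0L || n_controls < 0L) stop("counts must be >= 0")
  if (n_carriers + n_controls < 1L) stop("need at least one sample")
  if (tau <= 0) stop("tau must be > 0")
  if (switch_error_rate < 0 || switch_error_rate > 1) {
    stop("switch_error_rate must be in [0, 1]")
  }
  if (is.null(positions)) {
    if (n_markers < 1L) stop("need at least one marker")
    positions <- as.integer(spacing_bp) * seq_len(n_markers)
  } else {
    positions <- as.integer(positions)
    n_markers <- length(positions)
    if (n_markers < 1L) stop("need at least one marker")
    if (is.unsorted(positions, strictly = TRUE)) {
      stop("positions must be strictly increasing")
    }
  }
  set.seed(as.integer(seed))
  focal_idx <- if (is.null(locus_pos)) as.integer(ceiling(n_markers / 2)) else
    which.min(abs(positions - locus_pos))
  locus_pos <- if (is.null(locus_pos)) positions[focal_idx] else locus_pos

  p_alt <- stats::runif(n_markers, freq_range[1], freq_range[2])
  background <- function(k) {
    matrix(stats::rbinom(k * n_markers, 1L, rep(p_alt, each = k)),
           nrow = k, ncol = n_markers, byrow = FALSE)
  }
  founder <- as.integer(stats::rbinom(n_markers, 1L, p_alt))

  n_samples <- n_carriers + n_controls
  geno <- matrix(stats::rbinom(2L * n_samples * n_markers, 1L,
                               rep(p_alt, each = 2L * n_samples)),
                 nrow = 2L * n_samples, ncol = n_markers)
  storage.mode(geno) <- "integer"

  bp_per_morgan <- 100 * 1e6 / cM_per_Mb
  carriers <- NULL
  if (n_carriers > 0L) {
    g_left <- stats::rexp(n_carriers, rate = tau)    # Morgans
    g_right <- stats::rexp(n_carriers, rate = tau)
    left_break <- locus_pos - round(g_left * bp_per_morgan)
    right_break <- locus_pos + round(g_right * bp_per_morgan)
    strand <- sample(1:2, n_carriers, replace = TRUE)
    rows <- 2L * seq_len(n_carriers) - 2L + strand
    for (i in seq_len(n_carriers)) {
      keep <- positions >= left_break[i] & positions <= right_break[i]
      geno[rows[i], keep] <- founder[keep]
    }
    carriers <- data.frame(
      sample = paste0("carrier", seq_len(n_carriers)), row = rows,
      strand = strand, left_break = left_break, right_break = right_break)
  }
  samples <- c(if (n_carriers > 0L) paste0("carrier", seq_len(n_carriers)),
               if (n_controls > 0L) paste0("control", seq_len(n_controls)))

  switch_errors <- data.frame(sample = character(0), pos = integer(0))
  if (switch_error_rate > 0) {
    hit <- stats::runif(2L * n_samples) < switch_error_rate
    # one planted switch per affected sample: swap strand suffixes
    affected <- unique((which(hit) + 1L) %/% 2L)
    for (s in affected) {
      m <- sample.int(n_markers, 1L)
      r1 <- 2L * s - 1L; r2 <- 2L * s
      tmp <- geno[r1, m:n_markers]
      geno[r1, m:n_markers] <- geno[r2, m:n_markers]
      geno[r2, m:n_markers] <- tmp
      switch_errors <- rbind(switch_errors,
                             data.frame(sample = samples[s],
                                        pos = positions[m]))
    }
  }

  variants <- data.frame(
    contig = contig, pos = positions,
    id = paste0("sim", seq_len(n_markers)),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  hm <- hap_matrix(geno, variants, samples, ploidy = 2L)
  map <- genetic_map(data.frame(
    contig = contig,
    bp = c(positions[1], positions[n_markers]),
    cM = c(positions[1], positions[n_markers]) * cM_per_Mb / 1e6))
  founder_hap <- variants
  founder_hap$allele <- founder
  truth <- list(founder = as_haplotype(founder_hap), carriers = carriers,
                tau = tau, seed = as.integer(seed),
                switch_errors = switch_errors)
  out <- list(matrix = hm, map = map, truth = truth,
              focal_idx = focal_idx, locus_pos = locus_pos)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "cohort.vcf.gz"),
                  map = file.path(dir, "map.txt"),
                  truth_tsv = file.path(dir, "truth.tsv"),
                  truth_json = file.path(dir, "truth.json"))
    write_phased_vcf(hm, paths$vcf)
    write_genetic_map(map, paths$map)
    if (!is.null(carriers)) {
      utils::write.table(carriers, paths$truth_tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(tau = tau, seed = as.integer(seed), locus_pos = locus_pos,
           founder = founder,
           switch_errors = switch_errors),
      paths$truth_json, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  class(out) <- "founder_sim"
  out
}

#' @method print founder_sim
#' @export
print.founder_sim <- function(x, ...) {
  nc <- if (is.null(x$truth$carriers)) 0L else nrow(x$truth$carriers)
  cat("Simulated cohort:", length(x$matrix$samples), "samples (", nc,
      "carriers ),", ncol(x$matrix$geno), "markers\n")
  cat("  tau =", x$truth$tau, "generations; focal locus at", x$locus_pos, "\n")
  invisible(x)
}
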