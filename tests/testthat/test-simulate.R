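# The synthetic multi-study generator: determinism, validator compliance,
# truth-label structure, pileup semantics.

small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_votus = 15, n_samples = 5, kitome_size = 5,
             genome_length_range = c(1500, 2500), ...)
}

test_that("genomes respect the configured sizes and are seed-deterministic", {
  cfg <- small_cfg(3)
  g1 <- simulate_genomes(cfg)
  g2 <- simulate_genomes(cfg)
  expect_identical(g1, g2)
  expect_length(g1, 15)
  expect_true(all(nchar(g1) >= 1500 & nchar(g1) <= 2500))
  expect_false(any(grepl("[^ACGT]", g1)))
  expect_false(identical(g1, simulate_genomes(small_cfg(4))))
})

test_that("mutate_strain plants exactly n substitutions", {
  set.seed(1)
  g <- random_dna(800)
  expect_identical(mutate_strain(g, 0, seed = 9)$sequence, g)
  mut <- mutate_strain(g, 5, seed = 9)
  hamming <- sum(strsplit(g, "")[[1]] != strsplit(mut$sequence, "")[[1]])
  expect_equal(hamming, 5)
  expect_length(mut$snp_positions, 5)
  # popANI of the pair under full coverage = 100(L-5)/L
  cmp <- compare_strains(profile_from_seq("v", "a", g),
                         profile_from_seq("v", "b", mut$sequence))
  expect_equal(cmp$popani, 100 * (800 - 5) / 800)
  expect_error(mutate_strain("ACGT", 5, seed = 1), "exceeds")
})

test_that("simulated datasets are deterministic and pass the validators", {
  cfg <- small_cfg(11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  expect_silent(validate_metadata(s1$metadata))
  expect_silent(validate_annotations(s1$annotations))
  # every truth cell is a nonzero count with positive breadth
  expect_true(all(s1$counts$counts[cbind(s1$truth$votu_id,
                                         s1$truth$sample_id)] > 0))
  # contaminants reference a strain present in >= 1 NC of the same study
  cont <- s1$truth[s1$truth$is_contaminant, ]
  nc_strains <- s1$truth[s1$truth$role == "nc",
                         c("study", "strain_id")]
  expect_true(all(paste(cont$study, cont$strain_id) %in%
                    paste(nc_strains$study, nc_strains$strain_id)))
})

test_that("contamination fraction 0 and 1 hit their extremes", {
  none <- simulate_study(small_cfg(21, contamination_fraction = 0))
  expect_equal(sum(none$truth$is_contaminant), 0)
  all_c <- simulate_study(small_cfg(22, contamination_fraction = 1))
  per_sample <- tapply(all_c$truth$is_contaminant[all_c$truth$role ==
                                                    "sample"],
                       all_c$truth$sample_id[all_c$truth$role == "sample"],
                       any)
  expect_true(all(per_sample))
})

test_that("realized infant richness tracks the configured model", {
  meds <- vapply(1:25, function(s) {
    sim <- simulate_study(sim_config(seed = s, n_votus = 50, n_samples = 8,
                                     genome_length_range = c(1000, 1200)))
    inf <- sim$metadata$sample_id[sim$metadata$group == "infant"]
    stats::median(richness(sim$counts$counts)[inf])
  }, 0)
  # configured infant richness is log-normal with median 8
  expect_true(abs(stats::median(meds) - 8) / 8 <= 0.2)
})

test_that("pileups respect coverage masks, depth and error semantics", {
  cfg <- small_cfg(31, gap_fraction = 0.3, depth_mean = 4)
  sim <- simulate_study(cfg)
  cell <- sim$truth[1, , drop = FALSE]
  pu <- simulate_pileups(sim, cells = cell)
  expect_silent(validate_pileup(pu, sim$annotations))
  L <- sim$annotations$length_bp[sim$annotations$votu_id == cell$votu_id]
  expect_equal(nrow(pu), L - cell$gap_len)
  # gap interval is contiguous and absent
  gap <- seq(cell$gap_start, length.out = cell$gap_len)
  expect_length(intersect(pu$pos, gap), 0)
  # depths >= 1 everywhere covered (min_cov semantics)
  expect_true(all(rowSums(pu[c("A", "C", "G", "T")]) >= 1))
  # gap fraction 0 -> breadth 1 everywhere
  full <- simulate_study(small_cfg(32))
  expect_true(all(full$counts$breadth[cbind(full$truth$votu_id,
                                            full$truth$sample_id)] == 1))
  # fraction compared of two 0.7-coverage cells ~ expected mask overlap
  two <- sim$truth[sim$truth$votu_id == sim$truth$votu_id[1], ]
  if (nrow(two) >= 2) {
    pr <- simulate_profiles(sim, two[1:2, ])
    cmp <- compare_strains(pr[[1]], pr[[2]])
    expect_true(cmp$fraction_compared >= 0.4 - 0.05 &&
                  cmp$fraction_compared <= 1)
  }
})

test_that("pileup-derived profiles equal the direct truth profiles", {
  sim <- simulate_study(small_cfg(41, gap_fraction = 0.2))
  cells <- sim$truth[1:6, ]
  pu <- simulate_pileups(sim, cells = cells)
  via_pileup <- pileup_profiles(pu, sim$annotations)
  direct <- simulate_profiles(sim, cells)
  for (k in names(direct)) {
    expect_identical(via_pileup[[k]]$pos, direct[[k]]$pos)
    expect_identical(via_pileup[[k]]$allele_mask, direct[[k]]$allele_mask)
    expect_identical(via_pileup[[k]]$consensus_mask,
                     direct[[k]]$consensus_mask)
  }
})

test_that("per-base errors add alleles without displacing the strain base", {
  sim <- simulate_study(small_cfg(51, error_rate = 0.05, depth_mean = 6))
  cells <- sim$truth[1:2, ]
  pu <- simulate_pileups(sim, cells = cells)
  profs <- pileup_profiles(pu, sim$annotations)
  direct_cfg <- small_cfg(51, depth_mean = 6)  # same seed, no errors
  direct <- simulate_profiles(simulate_study(direct_cfg), cells)
  k <- names(direct)[1]
  # consensus almost always the strain base (an error read can only tie
  # with a depth-1 strain base, a rare event at depth_mean 6)
  expect_gt(mean(profs[[k]]$consensus_mask == direct[[k]]$consensus_mask),
            0.99)
  # allele sets are supersets of the strain base
  expect_true(all(bitwAnd(profs[[k]]$allele_mask,
                          direct[[k]]$allele_mask) > 0))
  expect_true(any(profs[[k]]$allele_mask != direct[[k]]$allele_mask))
})

test_that("truth scoring equals a confusion-matrix oracle", {
  sim <- simulate_study(small_cfg(61))
  truth <- sim$truth
  cells <- truth[truth$role == "sample", ]
  # perfect removal
  perfect <- cells[cells$is_contaminant, c("sample_id", "votu_id")]
  m <- evaluate_against_truth(perfect, truth)
  expect_equal(unname(m[c("sensitivity", "specificity",
                          "false_removal_rate")]), c(1, 1, 0))
  # remove nothing
  none <- evaluate_against_truth(cells[0, c("sample_id", "votu_id")], truth)
  expect_equal(unname(none[["sensitivity"]]), 0)
  # random removal matches hand-computed confusion matrix
  set.seed(5)
  pick <- cells[sample.int(nrow(cells), 10), c("sample_id", "votu_id")]
  got <- evaluate_against_truth(pick, truth)
  key <- paste(cells$sample_id, cells$votu_id)
  rem <- key %in% paste(pick$sample_id, pick$votu_id)
  tp <- sum(rem & cells$is_contaminant)
  fp <- sum(rem & !cells$is_contaminant)
  fn <- sum(!rem & cells$is_contaminant)
  tn <- sum(!rem & !cells$is_contaminant)
  expect_equal(unname(got[c("tp", "fp", "fn", "tn")]), c(tp, fp, fn, tn))
  expect_equal(unname(got[["sensitivity"]]), tp / (tp + fn))
  expect_equal(unname(got[["false_removal_rate"]]), fp / (fp + tn))
})
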