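# Negativeome construction, sharing metrics and strain/species
# decontamination.

toy_setup <- function() {
  meta <- make_meta(c("a_s1", "a_s2", "a_nc", "b_s1", "b_nc"),
                    c("A", "A", "A", "B", "B"),
                    c("sample", "sample", "nc", "sample", "nc"))
  m <- matrix(0, 4, 5, dimnames = list(paste0("v", 1:4), meta$sample_id))
  m["v1", ] <- c(6, 0, 2, 3, 1)   # in NCs of both studies
  m["v2", ] <- c(3, 1, 1, 0, 0)   # in NC of study A only
  m["v3", ] <- c(1, 4, 0, 2, 0)   # never in an NC
  m["v4", ] <- c(0, 0, 0, 4, 2)   # in NC of study B only
  list(am = abundance_matrix(m, meta), meta = meta)
}

test_that("negativeome entries and cross-study overlap are correct", {
  s <- toy_setup()
  cat <- build_negativeome(s$am)
  expect_setequal(paste(cat$entries$votu_id, cat$entries$study),
                  c("v1 A", "v1 B", "v2 A", "v4 B"))
  # v1 in 2 studies; v2, v4 in 1 study each
  expect_equal(as.integer(cat$overlap[c("1", "2")]), c(2L, 1L))
  no_nc <- s$meta[s$meta$role == "sample", ]
  expect_error(build_negativeome(abundance_matrix(
    s$am$rpkm[, no_nc$sample_id], no_nc)), "no negative controls")
})

test_that("overlap histogram equals a set-intersection oracle on random data", {
  set.seed(8)
  for (i in 1:10) {
    meta <- make_meta(c("x_n1", "y_n1", "z_n1"), c("X", "Y", "Z"),
                      rep("nc", 3))
    m <- matrix(rbinom(15, 1, 0.5), 5, 3,
                dimnames = list(paste0("v", 1:5), meta$sample_id))
    if (all(m == 0)) m[1, 1] <- 1
    cat <- build_negativeome(abundance_matrix(m, meta))
    want <- table(rowSums(m > 0)[rowSums(m > 0) > 0])
    expect_equal(as.integer(cat$overlap), as.integer(want))
  }
})

test_that("vOTU sharing metrics match richness/abundance definitions", {
  s <- toy_setup()
  cat <- build_negativeome(s$am)
  vs <- votu_sharing(s$am, cat, scope = "own_study")
  m1 <- vs$metrics[vs$metrics$sample_id == "a_s1", ]
  # a_s1 detects v1,v2,v3; v1,v2 in study-A negativeome
  expect_equal(m1$richness, 3)
  expect_equal(m1$n_shared, 2)
  expect_equal(m1$pct_richness_shared, 100 * 2 / 3)
  expect_equal(m1$pct_abundance_shared, 100 * (6 + 3) / 10)
  # external scope: a_s1 shares v1 (study-B negativeome) only
  ve <- votu_sharing(s$am, cat, scope = "external")
  e1 <- ve$metrics[ve$metrics$sample_id == "a_s1", ]
  expect_equal(e1$n_shared, 1)
  # no-overlap sample
  m2 <- ve$metrics[ve$metrics$sample_id == "a_s2", ]
  expect_equal(m2$n_shared, 0)
  expect_equal(m2$pct_richness_shared, 0)
})

test_that("strain promotion honors the mode-specific identity rule", {
  s <- toy_setup()
  cat <- build_negativeome(s$am)
  vs <- votu_sharing(s$am, cat, scope = "own_study")
  rec <- vs$records[vs$records$sample_id == "a_s1", ]
  cmp <- data.frame(votu_id = c("v1", "v2"), sample_a = "a_s1",
                    sample_b = "a_nc", compared_positions = c(9000L, 4000L),
                    popani_diff_count = c(0L, 40L),
                    conani_diff_count = c(0L, 40L),
                    popani = c(100, 99), conani = c(100, 99),
                    fraction_compared = c(0.4, 1), stringsAsFactors = FALSE)
  # v1 identical but only 40% compared: promoted in decontamination mode only
  got_dec <- strain_sharing(rec, cmp, mode = "decontamination")
  expect_equal(got_dec$votu_id, "v1")
  got_ana <- strain_sharing(rec, cmp, mode = "analysis")
  expect_equal(nrow(got_ana), 0)
  # missing comparisons degrade to a warning, never silent promotion
  expect_warning(got <- strain_sharing(rec, cmp[1, , drop = FALSE]),
                 "no usable strain comparison")
  expect_equal(got$votu_id, "v1")
})

test_that("strain decontamination zeroes exactly the recorded cells", {
  s <- toy_setup()
  rec <- data.frame(sample_id = "a_s1", votu_id = "v1", level = "strain",
                    nc_ids = "a_nc", scope = "own_study",
                    stringsAsFactors = FALSE)
  out <- strain_decontaminate(s$am, rec)
  expect_equal(out$matrix$rpkm["v1", "a_s1"], 0)
  # every other cell bit-identical
  keep <- s$am$rpkm
  keep["v1", "a_s1"] <- 0
  expect_identical(out$matrix$rpkm, keep)
  expect_equal(out$report$n_removed[out$report$sample_id == "a_s1"], 1L)
  # a sample sharing the vOTU but not the strain is untouched
  expect_equal(out$matrix$rpkm["v1", "b_s1"], s$am$rpkm["v1", "b_s1"])
  # idempotent
  twice <- strain_decontaminate(out$matrix, rec)
  expect_identical(twice$matrix$rpkm, out$matrix$rpkm)
})

test_that("species decontamination zeroes all own-study NC vOTUs", {
  s <- toy_setup()
  cat <- build_negativeome(s$am)
  out <- species_decontaminate(s$am, cat)
  # v1/v2 zeroed in study-A samples; v1/v4 in study-B samples
  expect_equal(out$matrix$rpkm["v1", "a_s1"], 0)
  expect_equal(out$matrix$rpkm["v2", "a_s2"], 0)
  expect_equal(out$matrix$rpkm["v1", "b_s1"], 0)
  expect_equal(out$matrix$rpkm["v4", "b_s1"], 0)
  # vOTU only in another study's NCs untouched, NC columns untouched
  expect_equal(out$matrix$rpkm["v3", "a_s2"], s$am$rpkm["v3", "a_s2"])
  expect_equal(out$matrix$rpkm[, "a_nc"], s$am$rpkm[, "a_nc"])
  # decontamination only writes zeros
  expect_true(all(out$matrix$rpkm <= s$am$rpkm))
})

test_that("strain removals are a subset of species removals on simulations", {
  for (seed in 1:3) {
    sim <- simulate_study(sim_config(seed = seed, n_votus = 20,
                                     n_samples = 6, kitome_size = 6,
                                     genome_length_range = c(2000, 3000)))
    am <- sim_rpkm(sim)
    rep <- decontamination_report(am, sim_nc_comparisons(sim, am))
    for (sid in rep$per_sample$sample_id) {
      expect_true(all(rep$removed_strain[[sid]] %in%
                        rep$removed_species[[sid]]))
    }
    expect_true(all(rep$per_sample$richness_after_strain >=
                      rep$per_sample$richness_after_species))
    # percentages within [0, 100]
    p <- rep$per_sample
    ok <- !is.na(p$pct_richness_shared_votu)
    expect_true(all(p$pct_richness_shared_votu[ok] >= 0 &
                      p$pct_richness_shared_votu[ok] <= 100))
    expect_true(all(p$pct_abundance_shared_strain[ok] <=
                      p$pct_abundance_shared_votu[ok] + 1e-9))
  }
})

test_that("summary medians/IQRs equal an independent quantile oracle", {
  sim <- simulate_study(sim_config(seed = 4, n_votus = 20, n_samples = 6,
                                   kitome_size = 6,
                                   genome_length_range = c(2000, 3000)))
  am <- sim_rpkm(sim)
  rep <- decontamination_report(am, sim_nc_comparisons(sim, am))
  summ <- decontamination_summary(rep)
  ps <- rep$per_sample
  drops <- 100 * (ps$richness_before - ps$richness_after_strain) /
    ps$richness_before
  want <- stats::quantile(drops, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  all_row <- summ[summ$study == "all", ]
  expect_equal(c(all_row$drop_strain_median, all_row$drop_strain_q1,
                 all_row$drop_strain_q3), want)
  # an all-clean study has zero drops
  clean <- simulate_study(sim_config(seed = 5, n_votus = 20, n_samples = 4,
                                     kitome_size = 6,
                                     contamination_fraction = 0,
                                     genome_length_range = c(2000, 3000)))
  am_c <- sim_rpkm(clean)
  rep_c <- decontamination_report(am_c, sim_nc_comparisons(clean, am_c))
  summ_c <- decontamination_summary(rep_c)
  expect_equal(summ_c$drop_strain_median[summ_c$study == "all"], 0)
})
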