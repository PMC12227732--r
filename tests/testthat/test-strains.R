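# Allele profiles, popANI/conANI comparison, strain-sharing decision and
# ultrametric trees.

test_that("allele profiles encode coverage, alleles and modal consensus", {
  rows <- data.frame(sample_id = "s1", votu_id = "v1",
                     pos = c(5L, 7L, 9L),
                     A = c(3L, 2L, 0L), C = c(0L, 0L, 0L),
                     G = c(0L, 1L, 0L), T = c(0L, 0L, 2L))
  p <- build_allele_profile(rows, genome_length = 10)
  expect_equal(p$pos, c(5L, 7L, 9L))
  expect_equal(p$allele_mask, c(1L, 5L, 8L))     # {A}, {A,G}, {T}
  expect_equal(p$consensus_mask, c(1L, 1L, 8L))  # modal; A wins at pos 7
  # depth tie A/G at equal depth -> lexicographic 'A'
  tie <- data.frame(sample_id = "s", votu_id = "v", pos = 1L,
                    A = 2L, C = 0L, G = 2L, T = 0L)
  expect_equal(build_allele_profile(tie, 4)$consensus_mask, 1L)
  # min_cov excludes shallow positions
  p2 <- build_allele_profile(rows, 10, min_cov = 3)
  expect_equal(p2$pos, c(5L, 7L))
  expect_error(build_allele_profile(rows, genome_length = NULL),
               "genome_length")
})

test_that("consensus sequences emit N at uncovered positions", {
  rows <- data.frame(sample_id = "s", votu_id = "v", pos = c(1L, 3L),
                     A = c(1L, 0L), C = c(0L, 0L), G = c(0L, 2L),
                     T = c(0L, 0L))
  p <- build_allele_profile(rows, 4)
  expect_equal(consensus_sequence(p), "ANGN")
  empty <- allele_profile("v", "s", 4, integer(0), integer(0), integer(0))
  expect_equal(consensus_sequence(empty), "NNNN")
})

test_that("popANI and conANI follow their position rules", {
  L <- 1000L
  base <- rep(1L, L)  # all-A single alleles
  a <- allele_profile("v", "a", L, seq_len(L), base, base)
  b <- allele_profile("v", "b", L, seq_len(L), base, base)
  cmp <- compare_strains(a, b)
  expect_equal(cmp$popani, 100)
  expect_equal(cmp$conani, 100)
  expect_equal(cmp$fraction_compared, 1)

  # {A} vs {A,G} with consensus A vs G: popANI shared, conANI different
  mb <- base; cb <- base
  mb[10] <- 5L; cb[10] <- 4L
  b2 <- allele_profile("v", "b", L, seq_len(L), mb, cb)
  cmp2 <- compare_strains(a, b2)
  expect_equal(cmp2$popani_diff_count, 0L)
  expect_equal(cmp2$conani_diff_count, 1L)
  expect_true(cmp2$popani >= cmp2$conani)

  # disjoint alleles count for both
  mb[10] <- 2L; cb[10] <- 2L
  b3 <- allele_profile("v", "b", L, seq_len(L), mb, cb)
  cmp3 <- compare_strains(a, b3)
  expect_equal(cmp3$popani_diff_count, 1L)
  expect_equal(cmp3$popani, 100 * (L - 1) / L)

  # symmetric in arguments
  rev <- compare_strains(b3, a)
  expect_equal(rev$popani, cmp3$popani)
  expect_equal(rev$compared_positions, cmp3$compared_positions)

  # no mutual coverage -> null comparison
  a1 <- allele_profile("v", "a", 10, 1:5, rep(1L, 5), rep(1L, 5))
  b1 <- allele_profile("v", "b", 10, 6:10, rep(1L, 5), rep(1L, 5))
  null_cmp <- compare_strains(a1, b1)
  expect_true(is.na(null_cmp$popani))
  expect_error(is_shared_strain(null_cmp), "null comparison")
  expect_error(compare_strains(a1, allele_profile("w", "b", 10, 1:2,
                                                  c(1L, 1L), c(1L, 1L))),
               "different vOTUs")
})

test_that("comparison matches the brute-force position scan on random pairs", {
  set.seed(97)
  for (i in 1:25) {
    L <- sample(200:2000, 1)
    pa <- random_raw_profile("v", "a", L, cover_frac = runif(1, 0.3, 1),
                             multi_frac = runif(1, 0, 0.3))
    pb <- random_raw_profile("v", "b", L, cover_frac = runif(1, 0.3, 1),
                             multi_frac = runif(1, 0, 0.3))
    got <- compare_strains(pa$profile, pb$profile)
    want <- oracle_compare(pa$raw, pb$raw, L)
    expect_identical(got$compared_positions, want$compared)
    expect_identical(got$popani_diff_count, want$pop_d)
    expect_identical(got$conani_diff_count, want$con_d)
    expect_true(is.na(got$popani) || got$popani >= got$conani)
  }
})

test_that("planted differences are recovered exactly under full coverage", {
  set.seed(13)
  for (k in c(1L, 7L, 50L)) {
    L <- 5000L
    seq_a <- random_dna(L)
    seq_b <- mutate_dna(seq_a, k)
    cmp <- compare_strains(profile_from_seq("v", "a", seq_a),
                           profile_from_seq("v", "b", seq_b))
    expect_identical(cmp$popani_diff_count, k)
    expect_equal(cmp$popani, 100 * (L - k) / L)
  }
})

test_that("strain-sharing decision is inclusive and mode-aware", {
  mk <- function(popani, frac) {
    data.frame(popani = popani, fraction_compared = frac)
  }
  expect_true(is_shared_strain(mk(99.999, 0.80), mode = "analysis"))
  expect_false(is_shared_strain(mk(100, 0.50), mode = "analysis"))
  expect_true(is_shared_strain(mk(100, 0.50), mode = "decontamination"))
  expect_false(is_shared_strain(mk(99.998, 1.0), mode = "analysis"))
  expect_false(is_shared_strain(mk(99.998, 1.0), mode = "decontamination"))
  # monotone in popANI and (analysis) fraction
  expect_true(all(is_shared_strain(mk(c(99.999, 99.9995, 100), 1),
                                   mode = "analysis") == c(TRUE, TRUE, TRUE)))
  expect_equal(is_shared_strain(mk(100, c(0.74, 0.75, 0.76)),
                                mode = "analysis"), c(FALSE, TRUE, TRUE))
})

test_that("strain trees reproduce distances under complete linkage", {
  mk_cmp <- function(a, b, popani, frac = 1) {
    data.frame(votu_id = "v", sample_a = a, sample_b = b,
               compared_positions = 1000L, popani_diff_count = 0L,
               conani_diff_count = 0L, popani = popani, conani = popani,
               fraction_compared = frac, stringsAsFactors = FALSE)
  }
  # three leaves: A,B merge at 0.001; C joins at max(d) = 0.01
  cmp <- rbind(mk_cmp("A", "B", 99.9), mk_cmp("A", "C", 99.0),
               mk_cmp("B", "C", 99.0))
  tree <- build_strain_tree(cmp)
  expect_equal(sort(tree$hclust$height), c(0.001, 0.01), tolerance = 1e-12)
  expect_equal(sort(tree$leaves), c("A", "B", "C"))
  # star at height 0 when all popANI 100
  star <- rbind(mk_cmp("A", "B", 100), mk_cmp("A", "C", 100),
                mk_cmp("B", "C", 100))
  expect_equal(max(build_strain_tree(star)$hclust$height), 0)
  # low-fraction pairs are excluded; incomplete matrices error, no imputation
  cmp2 <- rbind(mk_cmp("A", "B", 99.9), mk_cmp("A", "C", 99.0, frac = 0.5),
                mk_cmp("B", "C", 99.0))
  expect_error(build_strain_tree(cmp2), "missing.*A--C")
  expect_error(build_strain_tree(mk_cmp("A", "B", 99.9, frac = 0.5)),
               "fewer than 2 leaves")
})

test_that("tree heights match a brute-force agglomeration on small cases", {
  set.seed(55)
  for (linkage in c("complete", "single")) {
    ids <- letters[1:5]
    combos <- utils::combn(ids, 2)
    popani <- runif(ncol(combos), 99, 100)
    cmp <- data.frame(votu_id = "v", sample_a = combos[1, ],
                      sample_b = combos[2, ], compared_positions = 1000L,
                      popani_diff_count = 0L, conani_diff_count = 0L,
                      popani = popani, conani = popani,
                      fraction_compared = 1, stringsAsFactors = FALSE)
    D <- matrix(0, 5, 5, dimnames = list(ids, ids))
    d <- 1 - popani / 100
    D[cbind(combos[1, ], combos[2, ])] <- d
    D <- D + t(D)
    # brute-force agglomeration oracle
    oracle_heights <- local({
      clusters <- as.list(ids)
      heights <- numeric(0)
      link <- function(ca, cb) {
        v <- D[ca, cb, drop = FALSE]
        if (linkage == "complete") max(v) else min(v)
      }
      while (length(clusters) > 1) {
        best <- c(Inf, NA, NA)
        for (i in seq_along(clusters)[-length(clusters)]) {
          for (j in seq((i + 1), length(clusters))) {
            h <- link(clusters[[i]], clusters[[j]])
            if (h < best[1]) best <- c(h, i, j)
          }
        }
        heights <- c(heights, best[1])
        clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
        clusters[[best[3]]] <- NULL
      }
      heights
    })
    tree <- build_strain_tree(cmp, linkage = linkage)
    expect_equal(sort(tree$hclust$height), sort(oracle_heights),
                 tolerance = 1e-12)
  }
})
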