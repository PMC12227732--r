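# Strain reconstruction and comparison: per-sample allele profiles from
# pileups (min_cov 1), consensus sequences, popANI/conANI between samples
# carrying the same vOTU, the >= 99.999% popANI strain-sharing rule, and
# ultrametric trees from 1 - popANI dissimilarities.
#
# Allele sets are packed as bitmasks (A=1, C=2, G=4, T=8); two sets are
# disjoint iff bitwAnd() of the masks is zero.

#' Construct an allele profile
#'
#' @param votu_id,sample_id Identifiers.
#' @param genome_length Length of the vOTU representative (bp).
#' @param pos Sorted 1-based covered positions.
#' @param allele_mask Integer bitmask of observed alleles per position
#'   (A=1, C=2, G=4, T=8), parallel to `pos`.
#' @param consensus_mask Integer bitmask of the single consensus base per
#'   position (one of 1, 2, 4, 8), parallel to `pos`.
#' @return An `allele_profile` object.
#' @export
allele_profile <- function(votu_id, sample_id, genome_length, pos,
                           allele_mask, consensus_mask) {
  abort_if(!is_count(genome_length), "genome_length must be a positive integer")
  abort_if(length(pos) != length(allele_mask) ||
             length(pos) != length(consensus_mask),
           "pos, allele_mask and consensus_mask must be parallel")
  abort_if(length(pos) > 0 && (min(pos) < 1 || max(pos) > genome_length),
           "covered positions outside [1, genome_length]")
  abort_if(any(allele_mask < 1 | allele_mask > 15),
           "allele_mask must encode a non-empty subset of {A,C,G,T}")
  abort_if(any(bitwAnd(allele_mask, consensus_mask) == 0),
           "consensus base must be among the observed alleles")
  o <- order(pos)
  structure(list(votu_id = votu_id, sample_id = sample_id,
                 genome_length = as.integer(genome_length),
                 pos = as.integer(pos)[o],
                 allele_mask = as.integer(allele_mask)[o],
                 consensus_mask = as.integer(consensus_mask)[o]),
            class = "allele_profile")
}

#' @export
print.allele_profile <- function(x, ...) {
  cat("allele_profile: vOTU ", x$votu_id, ", sample ", x$sample_id,
      "; ", length(x$pos), "/", x$genome_length, " positions covered (",
      round(100 * length(x$pos) / x$genome_length, 1), "%)\n", sep = "")
  invisible(x)
}

#' Build an allele profile from pileup rows
#'
#' A position is covered iff its total depth is >= `min_cov`; every base with
#' depth >= 1 at a covered position is an observed allele; the consensus is
#' the modal base (depth ties broken lexicographically A < C < G < T).
#'
#' @param pileup_rows Pileup data.frame rows for one (sample, vOTU).
#' @param genome_length Length of the vOTU representative (bp).
#' @param min_cov Minimum total depth for a position to count; default 1.
#' @return An `allele_profile`.
#' @export
build_allele_profile <- function(pileup_rows, genome_length, min_cov = 1) {
  abort_if(missing(genome_length) || is.null(genome_length) ||
             is.na(genome_length), "genome_length missing")
  abort_if(length(unique(pileup_rows$sample_id)) > 1 ||
             length(unique(pileup_rows$votu_id)) > 1,
           "pileup rows must belong to a single (sample, vOTU)")
  depths <- as.matrix(pileup_rows[BASES])
  keep <- rowSums(depths) >= min_cov
  pos <- pileup_rows$pos[keep]
  depths <- depths[keep, , drop = FALSE]
  mask <- as.integer((depths > 0) %*% BASE_MASK)
  # max.col(ties.method = "first") picks the lexicographically smallest
  # modal base because columns are ordered A, C, G, T
  cons <- BASE_MASK[max.col(depths, ties.method = "first")]
  allele_profile(pileup_rows$votu_id[1] %||% NA_character_,
                 pileup_rows$sample_id[1] %||% NA_character_,
                 genome_length, pos, mask, as.integer(cons))
}

#' Group a pileup table into allele profiles
#'
#' @param pileup Validated pileup data.frame (see [read_pileup()]).
#' @param annotations vOTU annotation data.frame supplying lengths.
#' @param min_cov Minimum coverage; default 1.
#' @return Named list of `allele_profile`s, names "sample_id/votu_id".
#' @export
pileup_profiles <- function(pileup, annotations, min_cov = 1) {
  lens <- stats::setNames(annotations$length_bp, annotations$votu_id)
  key <- paste(pileup$sample_id, pileup$votu_id, sep = "/")
  groups <- split(seq_len(nrow(pileup)), key)
  out <- lapply(groups, function(idx) {
    rows <- pileup[idx, ]
    build_allele_profile(rows, lens[[rows$votu_id[1]]], min_cov = min_cov)
  })
  out
}

#' Consensus sequence of an allele profile
#'
#' @param profile An `allele_profile`.
#' @return Character string of length `genome_length`; uncovered positions
#'   emit 'N'.
#' @export
consensus_sequence <- function(profile) {
  stopifnot(inherits(profile, "allele_profile"))
  chars <- rep("N", profile$genome_length)
  chars[profile$pos] <- BASES[match(profile$consensus_mask, BASE_MASK)]
  paste(chars, collapse = "")
}

#' Compare two strains of the same vOTU (popANI / conANI)
#'
#' Positions covered in both profiles are compared. A position counts toward
#' the popANI difference count iff the two allele sets are disjoint; toward
#' the conANI difference count iff the consensus bases differ. popANI =
#' 100 * (1 - popani_diff / compared); a pair with no mutually covered
#' position is a null comparison (popANI/conANI NA).
#'
#' @param profile_a,profile_b `allele_profile`s for the same vOTU.
#' @return A `strain_comparison`: one-row data.frame with votu_id, sample_a,
#'   sample_b, compared_positions, popani_diff_count, conani_diff_count,
#'   popani, conani, fraction_compared.
#' @export
compare_strains <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "allele_profile"),
            inherits(profile_b, "allele_profile"))
  abort_if(!identical(profile_a$votu_id, profile_b$votu_id),
           "profiles belong to different vOTUs: ",
           profile_a$votu_id, " vs ", profile_b$votu_id)
  abort_if(profile_a$genome_length != profile_b$genome_length,
           "profiles disagree on genome length")
  idx <- match(profile_a$pos, profile_b$pos)
  both <- !is.na(idx)
  compared <- sum(both)
  if (compared == 0) {
    pop_d <- con_d <- 0L
    popani <- conani <- NA_real_
  } else {
    ma <- profile_a$allele_mask[both]
    mb <- profile_b$allele_mask[idx[both]]
    pop_d <- sum(bitwAnd(ma, mb) == 0L)
    con_d <- sum(profile_a$consensus_mask[both] !=
                   profile_b$consensus_mask[idx[both]])
    popani <- 100 * (1 - pop_d / compared)
    conani <- 100 * (1 - con_d / compared)
  }
  res <- data.frame(votu_id = profile_a$votu_id,
                    sample_a = profile_a$sample_id,
                    sample_b = profile_b$sample_id,
                    compared_positions = compared,
                    popani_diff_count = pop_d,
                    conani_diff_count = con_d,
                    popani = popani, conani = conani,
                    fraction_compared = compared / profile_a$genome_length,
                    stringsAsFactors = FALSE)
  class(res) <- c("strain_comparison", "data.frame")
  res
}

#' Pairwise strain comparisons over a set of profiles
#'
#' @param profiles List of `allele_profile`s (mixed vOTUs allowed; only
#'   same-vOTU pairs are compared).
#' @param pairs Optional data.frame (sample_a, sample_b, votu_id) restricting
#'   which comparisons are computed; default all same-vOTU pairs.
#' @return Data.frame of strain comparisons (one row per pair).
#' @export
compare_strains_table <- function(profiles, pairs = NULL) {
  idx <- data.frame(
    votu_id = vapply(profiles, `[[`, "", "votu_id"),
    sample_id = vapply(profiles, `[[`, "", "sample_id"),
    i = seq_along(profiles), stringsAsFactors = FALSE)
  out <- list()
  if (is.null(pairs)) {
    for (v in unique(idx$votu_id)) {
      rows <- idx[idx$votu_id == v, ]
      if (nrow(rows) < 2) next
      for (a in seq_len(nrow(rows) - 1)) {
        for (b in seq((a + 1), nrow(rows))) {
          out[[length(out) + 1L]] <- compare_strains(
            profiles[[rows$i[a]]], profiles[[rows$i[b]]])
        }
      }
    }
  } else {
    for (r in seq_len(nrow(pairs))) {
      ia <- idx$i[idx$votu_id == pairs$votu_id[r] &
                    idx$sample_id == pairs$sample_a[r]]
      ib <- idx$i[idx$votu_id == pairs$votu_id[r] &
                    idx$sample_id == pairs$sample_b[r]]
      if (length(ia) != 1 || length(ib) != 1) next
      out[[length(out) + 1L]] <- compare_strains(profiles[[ia]],
                                                 profiles[[ib]])
    }
  }
  if (length(out) == 0) {
    return(data.frame(votu_id = character(0), sample_a = character(0),
                      sample_b = character(0), compared_positions = integer(0),
                      popani_diff_count = integer(0),
                      conani_diff_count = integer(0), popani = numeric(0),
                      conani = numeric(0), fraction_compared = numeric(0)))
  }
  res <- do.call(rbind, lapply(out, as.data.frame))
  rownames(res) <- NULL
  res
}

# Guard for floating-point representation of printed thresholds such as
# 99.999: the comparison must be inclusive at exact rational boundaries
# (e.g. 1 disjoint difference over 100,000 compared positions).
POPANI_EPS <- 1e-9

#' Decide whether two samples share an identical strain
#'
#' Analysis mode requires popANI >= `popani_min` (inclusive) AND a compared
#' fraction of the genome >= `min_fraction`. Decontamination mode waives the
#' fraction requirement, accepting strain identity even when less than 75% of
#' the genome is available for comparison.
#'
#' @param comparison A `strain_comparison` or data.frame with columns
#'   `popani` and `fraction_compared` (vectorized over rows).
#' @param popani_min Inclusive popANI threshold in percent; default 99.999.
#' @param min_fraction Minimum fraction of the genome compared (analysis
#'   mode); default 0.75.
#' @param mode "analysis" or "decontamination".
#' @return Logical vector, one per comparison row.
#' @export
is_shared_strain <- function(comparison, popani_min = 99.999,
                             min_fraction = 0.75,
                             mode = c("analysis", "decontamination")) {
  mode <- match.arg(mode)
  popani <- comparison$popani
  frac <- comparison$fraction_compared
  abort_if(any(is.na(popani)),
           "null comparison (no mutually covered positions): filter first")
  ok <- popani >= popani_min - POPANI_EPS
  if (mode == "analysis") ok <- ok & frac >= min_fraction
  ok
}

#' Build an ultrametric strain tree for one vOTU
#'
#' Pairs with a compared fraction below `min_fraction` (or null comparisons)
#' are excluded; the remaining leaves must form a complete distance matrix
#' (missing pairs are an error, never imputed). Hierarchical clustering is
#' applied to d = 1 - popANI/100 and converted to an ultrametric phylo tree.
#'
#' @param comparisons Data.frame of strain comparisons for a single vOTU.
#' @param min_fraction Exclusion threshold on fraction_compared; default 0.75.
#' @param linkage hclust agglomeration method; default "complete".
#' @param leaves Optional character vector restricting the leaf set.
#' @return A `strain_tree`: list(votu_id, phylo, hclust, linkage, leaves).
#' @export
build_strain_tree <- function(comparisons, min_fraction = 0.75,
                              linkage = "complete", leaves = NULL) {
  abort_if(length(unique(comparisons$votu_id)) != 1,
           "comparisons must cover exactly one vOTU")
  keep <- !is.na(comparisons$popani) &
    comparisons$fraction_compared >= min_fraction
  cmp <- comparisons[keep, ]
  if (!is.null(leaves)) {
    cmp <- cmp[cmp$sample_a %in% leaves & cmp$sample_b %in% leaves, ]
  }
  ids <- sort(unique(c(cmp$sample_a, cmp$sample_b)))
  abort_if(length(ids) < 2,
           "fewer than 2 leaves remain after fraction-compared exclusion")
  D <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(D) <- 0
  d <- 1 - cmp$popani / 100
  D[cbind(cmp$sample_a, cmp$sample_b)] <- d
  D[cbind(cmp$sample_b, cmp$sample_a)] <- d
  if (any(is.na(D))) {
    miss <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    abort_if(TRUE, "incomplete distance matrix after exclusions; missing ",
             "pair(s): ",
             paste(ids[miss[, 1]], ids[miss[, 2]], sep = "--",
                   collapse = ", "))
  }
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(votu_id = comparisons$votu_id[1], phylo = phy, hclust = hc,
                 linkage = linkage, leaves = ids),
            class = "strain_tree")
}

#' @export
print.strain_tree <- function(x, ...) {
  cat("strain_tree for vOTU ", x$votu_id, ": ", length(x$leaves),
      " leaves, ", x$linkage, " linkage, max height ",
      format(max(x$hclust$height)), "\n", sep = "")
  invisible(x)
}
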