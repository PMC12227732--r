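# Multi-study synthetic virome generator with ground-truth labels.
#
# The generator emulates the structure the decontamination method assumes:
# several studies, each with biological samples (infants with low richness,
# mothers with higher richness) and negative controls; a shared "kitome"
# pool of contaminant vOTUs detected in NCs; contaminated samples carrying
# NC strains identically; resident strains of the same vOTUs diverged by
# tens to hundreds of SNPs (exercising the strain-vs-species distinction);
# long-tailed (log-normal) contaminant abundance shares; optional coverage
# gaps and per-base errors. All randomness is funneled through the config
# seed; identical configs give byte-identical outputs.

#' Simulation configuration
#'
#' Defaults describe a scaled-down multi-study design: 3 studies of
#' 12 samples + 2 NCs each, 50 vOTUs of 10-15 kb, resident strains diverged
#' by 50-200 SNPs, 60% of samples contaminated, contaminant abundance share
#' log-normal with median 1%, full error-free coverage.
#'
#' @param n_studies Number of studies.
#' @param n_samples Biological samples per study.
#' @param n_ncs Negative controls per study.
#' @param n_votus Size of the global vOTU pool.
#' @param genome_length_range Min/max genome length (bp).
#' @param strain_snp_range Min/max SNP count separating strains.
#' @param contamination_fraction Fraction of samples receiving NC strains.
#' @param max_contaminants Maximum contaminant vOTUs per contaminated sample.
#' @param share_meanlog,share_sdlog Log-normal parameters of the contaminant
#'   abundance share (defaults give median 1%).
#' @param richness_infant,richness_mother Log-normal (meanlog, sdlog) of
#'   per-sample richness by group.
#' @param infant_fraction Fraction of biological samples that are infants.
#' @param kitome_size Size of the global NC-contaminant vOTU pool.
#' @param kitome_detect_study Probability a kitome vOTU enters a study's NCs.
#' @param kitome_detect_nc Probability an individual NC detects each of its
#'   study's kitome vOTUs.
#' @param depth_mean Mean per-position read depth on covered positions.
#' @param gap_fraction Fraction of each genome left uncovered (one
#'   contiguous gap per sample x vOTU cell).
#' @param error_rate Per-position probability of one spurious read of a
#'   different base (pileup route only).
#' @param reads_mean Mean mapped reads per biological sample.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_studies = 3, n_samples = 12, n_ncs = 2,
                       n_votus = 50, genome_length_range = c(10000, 15000),
                       strain_snp_range = c(50, 200),
                       contamination_fraction = 0.6, max_contaminants = 3,
                       share_meanlog = log(0.01), share_sdlog = 1.5,
                       richness_infant = c(meanlog = log(8), sdlog = 0.8),
                       richness_mother = c(meanlog = log(15), sdlog = 0.5),
                       infant_fraction = 0.75, kitome_size = 12,
                       kitome_detect_study = 0.7, kitome_detect_nc = 0.8,
                       depth_mean = 10, gap_fraction = 0, error_rate = 0,
                       reads_mean = 1e5, seed) {
  abort_if(missing(seed) || is.null(seed), "seed is mandatory")
  cfg <- list(n_studies = n_studies, n_samples = n_samples, n_ncs = n_ncs,
              n_votus = n_votus, genome_length_range = genome_length_range,
              strain_snp_range = strain_snp_range,
              contamination_fraction = contamination_fraction,
              max_contaminants = max_contaminants,
              share_meanlog = share_meanlog, share_sdlog = share_sdlog,
              richness_infant = richness_infant,
              richness_mother = richness_mother,
              infant_fraction = infant_fraction, kitome_size = kitome_size,
              kitome_detect_study = kitome_detect_study,
              kitome_detect_nc = kitome_detect_nc, depth_mean = depth_mean,
              gap_fraction = gap_fraction, error_rate = error_rate,
              reads_mean = reads_mean, seed = as.integer(seed))
  abort_if(cfg$n_studies < 1 || cfg$n_samples < 1 || cfg$n_ncs < 1 ||
             cfg$n_votus < 1, "counts must be >= 1")
  abort_if(cfg$contamination_fraction < 0 || cfg$contamination_fraction > 1 ||
             cfg$gap_fraction < 0 || cfg$gap_fraction >= 1 ||
             cfg$error_rate < 0 || cfg$error_rate > 1,
           "fractions must lie in [0, 1]")
  abort_if(cfg$kitome_size > cfg$n_votus,
           "kitome_size cannot exceed n_votus")
  structure(cfg, class = "sim_config")
}

#' Generate random vOTU representative genomes
#'
#' Uniform-random A/C/G/T sequences with lengths drawn from the configured
#' range; deterministic per seed.
#'
#' @param config A `sim_config`.
#' @return Named character vector votu_id -> sequence.
#' @export
simulate_genomes <- function(config) {
  with_seed(child_seed(config$seed, 1), {
    lens <- sample(seq(config$genome_length_range[1],
                       config$genome_length_range[2]),
                   config$n_votus, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(BASES, L, replace = TRUE), collapse = ""), "")
    stats::setNames(seqs, sprintf("votu_%03d", seq_len(config$n_votus)))
  })
}

#' Mutate a genome into a derived strain
#'
#' Exactly `n_snps` distinct positions are changed to a different base.
#'
#' @param genome Sequence string.
#' @param n_snps Number of substitutions (<= genome length).
#' @param seed Integer seed.
#' @return List(sequence, snp_positions, snp_bases).
#' @export
mutate_strain <- function(genome, n_snps, seed) {
  L <- nchar(genome)
  abort_if(n_snps > L, "n_snps exceeds genome length")
  with_seed(seed, {
    pos <- sort(sample.int(L, n_snps))
    chars <- strsplit(genome, "", fixed = TRUE)[[1]]
    new <- vapply(pos, function(p) sample(setdiff(BASES, chars[p]), 1), "")
    chars[pos] <- new
    list(sequence = paste(chars, collapse = ""), snp_positions = pos,
         snp_bases = new)
  })
}

rlnorm_clipped <- function(n, meanlog, sdlog, lo, hi) {
  pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), lo), hi)
}

#' Simulate a multi-study virome dataset with truth labels
#'
#' Generates genomes, per-study NC (kitome) content, per-sample resident and
#' contaminant strains, abundance counts/breadth, metadata, annotations and
#' ground-truth labels. Contaminant cells carry a strain identical to an NC
#' strain of the sample's own study; resident cells of NC-detected vOTUs
#' carry an independently mutated (divergent) strain.
#'
#' @param config A `sim_config`.
#' @return A `virome_sim`: list(config, genomes, metadata, annotations,
#'   counts (a `count_matrix`), truth (per-cell data.frame with sample_id,
#'   votu_id, role, study, strain_id, is_contaminant, share, gap_start,
#'   gap_len), strains (registry strain_id -> list(votu_id, snp_positions,
#'   snp_bases))).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genomes <- simulate_genomes(config)
  votu_ids <- names(genomes)
  lens <- nchar(genomes)
  with_seed(child_seed(config$seed, 2), {
    kitome <- sort(sample(votu_ids, config$kitome_size))
    strains <- list()
    new_strain <- function(votu, tag) {
      n_snps <- sample(seq(config$strain_snp_range[1],
                           config$strain_snp_range[2]), 1)
      mut <- mutate_strain(genomes[[votu]], n_snps,
                           seed = sample.int(2147483646, 1))
      sid <- paste0(votu, ":", tag)
      strains[[sid]] <<- list(votu_id = votu,
                              snp_positions = mut$snp_positions,
                              snp_bases = mut$snp_bases)
      sid
    }
    meta_rows <- list()
    truth_rows <- list()
    counts_list <- list()
    add_cells <- function(sample_id, role, study, votus, strain_ids,
                          is_cont, shares, reads) {
      cnt <- pmax(1, round(shares * reads))
      gl <- round(config$gap_fraction * lens[votus])
      gs <- ifelse(gl > 0,
                   vapply(lens[votus] - gl + 1,
                          function(m) sample.int(m, 1), 0L), 0L)
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        sample_id = sample_id, votu_id = votus, role = role, study = study,
        strain_id = strain_ids, is_contaminant = is_cont, share = shares,
        gap_start = as.integer(gs), gap_len = as.integer(gl),
        stringsAsFactors = FALSE)
      counts_list[[sample_id]] <<- stats::setNames(cnt, votus)
    }
    for (s in seq_len(config$n_studies)) {
      study <- sprintf("study_%02d", s)
      study_kit <- kitome[stats::runif(length(kitome)) <
                            config$kitome_detect_study]
      if (length(study_kit) == 0) study_kit <- sample(kitome, 1)
      nc_strain <- stats::setNames(
        vapply(study_kit, function(v) new_strain(v, paste0(study, ":nc")),
               ""), study_kit)
      # negative controls: each detects a subset of the study kitome
      nc_content <- list()
      for (k in seq_len(config$n_ncs)) {
        nc_id <- sprintf("%s_nc%02d", study, k)
        detected <- study_kit[stats::runif(length(study_kit)) <
                                config$kitome_detect_nc]
        if (length(detected) == 0) detected <- sample(study_kit, 1)
        nc_content[[nc_id]] <- detected
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          sample_id = nc_id, study = study, role = "nc", subject_id = "",
          group = "nc", age_months = NA_real_, nucleic_acid = "DNA",
          stringsAsFactors = FALSE)
        w <- stats::rlnorm(length(detected), 0, 1)
        reads <- round(stats::rlnorm(1, log(config$reads_mean / 10), 0.3))
        add_cells(nc_id, "nc", study, detected, nc_strain[detected],
                  rep(FALSE, length(detected)), w / sum(w), reads)
      }
      detected_in_ncs <- sort(unique(unlist(nc_content)))
      # biological samples
      n_inf <- round(config$n_samples * config$infant_fraction)
      for (k in seq_len(config$n_samples)) {
        sample_id <- sprintf("%s_s%02d", study, k)
        group <- if (k <= n_inf) "infant" else "mother"
        rp <- if (group == "infant") config$richness_infant else
          config$richness_mother
        r <- rlnorm_clipped(1, rp[["meanlog"]], rp[["sdlog"]], 2,
                            config$n_votus)
        residents <- sample(votu_ids, r)
        contaminated <- stats::runif(1) < config$contamination_fraction
        cont_votus <- character(0)
        if (contaminated) {
          n_c <- sample.int(min(config$max_contaminants,
                                length(detected_in_ncs)), 1)
          cont_votus <- sample(detected_in_ncs, n_c)
          residents <- setdiff(residents, cont_votus)
        }
        res_strains <- vapply(residents, function(v)
          new_strain(v, sample_id), "")
        w <- stats::rlnorm(length(residents), 0, 1)
        shares_res <- w / sum(w)
        shares <- shares_res
        votus <- residents
        strain_ids <- res_strains
        is_cont <- rep(FALSE, length(residents))
        if (length(cont_votus) > 0) {
          s_c <- pmin(stats::rlnorm(length(cont_votus), config$share_meanlog,
                                    config$share_sdlog), 0.9)
          s_tot <- sum(s_c)
          if (s_tot >= 0.95) s_c <- s_c * 0.95 / s_tot
          shares <- c(shares_res * (1 - sum(s_c)), s_c)
          votus <- c(residents, cont_votus)
          strain_ids <- c(res_strains, nc_strain[cont_votus])
          is_cont <- c(rep(FALSE, length(residents)),
                       rep(TRUE, length(cont_votus)))
        }
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          sample_id = sample_id, study = study, role = "sample",
          subject_id = sprintf("%s_subj%02d", study, k), group = group,
          age_months = if (group == "infant")
            round(stats::runif(1, 0, 60), 1) else NA_real_,
          nucleic_acid = "DNA", stringsAsFactors = FALSE)
        reads <- round(stats::rlnorm(1, log(config$reads_mean), 0.3))
        add_cells(sample_id, "sample", study, votus, strain_ids, is_cont,
                  shares, reads)
      }
    }
    metadata <- do.call(rbind, meta_rows)
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    sample_ids <- metadata$sample_id
    counts <- matrix(0, nrow = length(votu_ids), ncol = length(sample_ids),
                     dimnames = list(votu_ids, sample_ids))
    for (sid in names(counts_list)) {
      counts[names(counts_list[[sid]]), sid] <- counts_list[[sid]]
    }
    breadth <- matrix(0, nrow = length(votu_ids), ncol = length(sample_ids),
                      dimnames = list(votu_ids, sample_ids))
    breadth[cbind(truth$votu_id, truth$sample_id)] <-
      1 - truth$gap_len / lens[truth$votu_id]
    annotations <- data.frame(
      votu_id = votu_ids, length_bp = as.integer(lens),
      viral_gene_count = pmax(1L, as.integer(round(lens / 1500))),
      host_gene_count = 0L, plasmid_flag = FALSE,
      completeness_pct = round(stats::runif(length(votu_ids), 50, 100), 1),
      stringsAsFactors = FALSE)
    cm <- count_matrix(counts, stats::setNames(colSums(counts), sample_ids),
                       breadth)
    structure(list(config = config, genomes = genomes, metadata = metadata,
                   annotations = annotations, counts = cm, truth = truth,
                   strains = strains),
              class = "virome_sim")
  })
}

#' @export
print.virome_sim <- function(x, ...) {
  cat("virome_sim: ", x$config$n_studies, " studies, ",
      sum(x$metadata$role == "sample"), " samples + ",
      sum(x$metadata$role == "nc"), " NCs, ", x$config$n_votus,
      " vOTUs; ", sum(x$truth$is_contaminant),
      " planted contaminant cells\n", sep = "")
  invisible(x)
}

strain_chars <- function(sim, strain_id, cache) {
  st <- sim$strains[[strain_id]]
  key <- st$votu_id
  base <- cache[[key]]
  if (is.null(base)) {
    base <- strsplit(sim$genomes[[key]], "", fixed = TRUE)[[1]]
    cache[[key]] <- base
  }
  if (length(st$snp_positions) > 0) base[st$snp_positions] <- st$snp_bases
  base
}

covered_positions <- function(L, gap_start, gap_len) {
  if (gap_len == 0) return(seq_len(L))
  setdiff(seq_len(L), seq(gap_start, length.out = gap_len))
}

#' Build allele profiles directly from simulation truth
#'
#' Fast error-free route: every covered position of a cell carries exactly
#' the strain base. For nonzero `error_rate`, go through
#' [simulate_pileups()] + [pileup_profiles()] instead.
#'
#' @param sim A `virome_sim`.
#' @param cells Optional subset of `sim$truth` rows.
#' @return Named list of `allele_profile`s ("sample_id/votu_id").
#' @export
simulate_profiles <- function(sim, cells = NULL) {
  abort_if(sim$config$error_rate > 0,
           "simulate_profiles is the error-free route; use simulate_pileups")
  cells <- cells %||% sim$truth
  cache <- new.env(parent = emptyenv())
  lens <- nchar(sim$genomes)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    v <- cells$votu_id[i]
    L <- lens[[v]]
    chars <- strain_chars(sim, cells$strain_id[i], cache)
    pos <- covered_positions(L, cells$gap_start[i], cells$gap_len[i])
    mask <- unname(BASE_MASK[chars[pos]])
    out[[i]] <- allele_profile(v, cells$sample_id[i], L, pos, mask, mask)
  }
  stats::setNames(out, paste(cells$sample_id, cells$votu_id, sep = "/"))
}

#' Simulate a per-position pileup table
#'
#' Per covered position the depth is 1 + Poisson(depth_mean - 1) reads of
#' the strain base; with probability `error_rate` a position additionally
#' receives one read of a uniformly chosen different base.
#'
#' @param sim A `virome_sim`.
#' @param cells Optional subset of `sim$truth` rows.
#' @return Pileup data.frame (sample_id, votu_id, pos, A, C, G, T).
#' @export
simulate_pileups <- function(sim, cells = NULL) {
  cells <- cells %||% sim$truth
  cfg <- sim$config
  cache <- new.env(parent = emptyenv())
  lens <- nchar(sim$genomes)
  with_seed(child_seed(cfg$seed, 3), {
    chunks <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      v <- cells$votu_id[i]
      L <- lens[[v]]
      chars <- strain_chars(sim, cells$strain_id[i], cache)
      pos <- covered_positions(L, cells$gap_start[i], cells$gap_len[i])
      n <- length(pos)
      depth <- 1L + stats::rpois(n, max(cfg$depth_mean - 1, 0))
      base_idx <- match(chars[pos], BASES)
      depths <- matrix(0L, nrow = n, ncol = 4,
                       dimnames = list(NULL, BASES))
      depths[cbind(seq_len(n), base_idx)] <- depth
      if (cfg$error_rate > 0) {
        err <- which(stats::runif(n) < cfg$error_rate)
        if (length(err) > 0) {
          shift <- sample.int(3, length(err), replace = TRUE)
          err_idx <- ((base_idx[err] - 1L + shift) %% 4L) + 1L
          depths[cbind(err, err_idx)] <- depths[cbind(err, err_idx)] + 1L
        }
      }
      chunks[[i]] <- data.frame(sample_id = cells$sample_id[i],
                                votu_id = v, pos = pos,
                                A = depths[, "A"], C = depths[, "C"],
                                G = depths[, "G"], T = depths[, "T"],
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, chunks)
  })
}

#' Score a decontamination result against simulation truth
#'
#' Confusion-matrix metrics over the nonzero (sample, vOTU) cells of
#' biological samples: sensitivity = TP / (TP + FN) over planted
#' contaminant cells, specificity = TN / (TN + FP) over clean cells, and
#' false-removal rate = FP / (FP + TN) (the fraction of clean cells
#' wrongly zeroed).
#'
#' @param result A `decontam_result`, a `decontam_report` (its strain-level
#'   removals are scored) or a data.frame (sample_id, votu_id) of removals.
#' @param truth `sim$truth` from [simulate_study()].
#' @return Named vector c(sensitivity, specificity, false_removal_rate,
#'   tp, fp, fn, tn).
#' @export
evaluate_against_truth <- function(result, truth) {
  removed <- if (inherits(result, "decontam_result")) {
    df <- stack_removed(result$removed)
    df
  } else if (inherits(result, "decontam_report")) {
    stack_removed(result$removed_strain)
  } else {
    result[c("sample_id", "votu_id")]
  }
  cells <- truth[truth$role == "sample", ]
  key <- paste(cells$sample_id, cells$votu_id, sep = "/")
  rem_key <- paste(removed$sample_id, removed$votu_id, sep = "/")
  is_removed <- key %in% rem_key
  is_cont <- cells$is_contaminant
  tp <- sum(is_removed & is_cont)
  fp <- sum(is_removed & !is_cont)
  fn <- sum(!is_removed & is_cont)
  tn <- sum(!is_removed & !is_cont)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    false_removal_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    tp = tp, fp = fp, fn = fn, tn = tn)
}

stack_removed <- function(removed_list) {
  rows <- lapply(names(removed_list), function(s) {
    v <- removed_list[[s]]
    if (length(v) == 0) return(NULL)
    data.frame(sample_id = s, votu_id = v, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), votu_id = character(0))
}
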