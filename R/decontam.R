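# Negativeome construction, vOTU- and strain-level sharing between samples
# and negative controls, and strain- or species-level decontamination of the
# RPKM table with per-sample reports.

#' Build the per-study negativeome catalog
#'
#' One entry per (vOTU, study) where the vOTU has nonzero abundance in at
#' least one NC of that study. Also tabulates cross-study overlap: how many
#' vOTUs appear in the NCs of exactly 1, 2, 3, ... studies.
#'
#' @param am An `abundance_matrix` (or matrix, with `metadata` supplied).
#' @param metadata Sample metadata (defaults to the matrix's own).
#' @param sequences Optional named vector of vOTU representative sequences.
#' @return A `negativeome`: list(entries = data.frame(votu_id, study,
#'   nc_ids), overlap = table of study counts, sequences).
#' @export
build_negativeome <- function(am, metadata = NULL, sequences = NULL) {
  m <- as_rpkm(am)
  metadata <- metadata %||% am$metadata
  abort_if(is.null(metadata), "metadata required")
  metadata <- validate_metadata(metadata)
  ncs <- metadata[metadata$role == "nc", ]
  ncs <- ncs[ncs$sample_id %in% colnames(m), ]
  abort_if(nrow(ncs) == 0, "no negative controls present in metadata/matrix")
  entries <- list()
  for (st in unique(ncs$study)) {
    nc_ids <- ncs$sample_id[ncs$study == st]
    sub <- m[, nc_ids, drop = FALSE]
    for (v in rownames(sub)[rowSums(sub > 0) > 0]) {
      entries[[length(entries) + 1L]] <- data.frame(
        votu_id = v, study = st,
        nc_ids = collapse_ids(nc_ids[sub[v, ] > 0]),
        stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(votu_id = character(0), study = character(0),
               nc_ids = character(0))
  overlap <- table(tapply(entries$study, entries$votu_id,
                          function(s) length(unique(s))))
  structure(list(entries = entries, overlap = overlap,
                 sequences = sequences),
            class = "negativeome")
}

#' @export
print.negativeome <- function(x, ...) {
  cat("negativeome: ", length(unique(x$entries$votu_id)), " vOTUs across ",
      length(unique(x$entries$study)), " studies\n", sep = "")
  if (length(x$overlap)) {
    cat("cross-study overlap (vOTUs found in NCs of k studies):\n")
    print(x$overlap)
  }
  invisible(x)
}

negativeome_votus <- function(catalog, studies = NULL, exclude = FALSE) {
  e <- catalog$entries
  if (!is.null(studies)) {
    keep <- if (exclude) !e$study %in% studies else e$study %in% studies
    e <- e[keep, , drop = FALSE]
  }
  e
}

#' vOTU-level sharing between biological samples and the negativeome
#'
#' For each biological sample, the vOTUs it shares with negativeome entries
#' in scope ("own_study": the sample's own study's NCs; "external": all other
#' studies' NCs), with per-sample percentages of richness and of relative
#' abundance shared.
#'
#' @param am An `abundance_matrix` (QC-filtered RPKM).
#' @param catalog A `negativeome`.
#' @param metadata Sample metadata (defaults to the matrix's own).
#' @param scope "own_study" or "external".
#' @return List with `records` (sample_id, votu_id, level = "votu", nc_ids,
#'   scope) and `metrics` (sample_id, study, richness, n_shared,
#'   pct_richness_shared, pct_abundance_shared; NA metrics at richness 0).
#' @export
votu_sharing <- function(am, catalog, metadata = NULL,
                         scope = c("own_study", "external")) {
  scope <- match.arg(scope)
  m <- as_rpkm(am)
  metadata <- metadata %||% am$metadata
  abort_if(is.null(metadata), "metadata required")
  rel <- relative_abundance(m)
  rich <- richness(m)
  samples <- metadata[metadata$role == "sample" &
                        metadata$sample_id %in% colnames(m), ]
  records <- list()
  metrics <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    st <- samples$study[i]
    ent <- negativeome_votus(catalog, st, exclude = (scope == "external"))
    present <- rownames(m)[m[, sid] > 0]
    shared <- intersect(present, ent$votu_id)
    for (v in shared) {
      nc_ids <- unique(unlist(lapply(ent$nc_ids[ent$votu_id == v],
                                     split_ids)))
      records[[length(records) + 1L]] <- data.frame(
        sample_id = sid, votu_id = v, level = "votu",
        nc_ids = collapse_ids(sort(nc_ids)), scope = scope,
        stringsAsFactors = FALSE)
    }
    r <- rich[[sid]]
    metrics[[length(metrics) + 1L]] <- data.frame(
      sample_id = sid, study = st, richness = r,
      n_shared = length(shared),
      pct_richness_shared = if (r > 0) 100 * length(shared) / r else NA_real_,
      pct_abundance_shared = if (r > 0) 100 * sum(rel[shared, sid]) else
        NA_real_,
      stringsAsFactors = FALSE)
  }
  list(records = if (length(records)) do.call(rbind, records) else
    empty_sharing_records(),
    metrics = do.call(rbind, metrics))
}

empty_sharing_records <- function() {
  data.frame(sample_id = character(0), votu_id = character(0),
             level = character(0), nc_ids = character(0),
             scope = character(0), stringsAsFactors = FALSE)
}

#' Promote vOTU-level sharing records to strain level
#'
#' A vOTU-level record becomes strain-level iff at least one comparison
#' between the sample and one of the record's NCs on that vOTU satisfies
#' [is_shared_strain()]. Records whose every sample-NC comparison is missing
#' or null are skipped with a warning (never silently dropped).
#'
#' @param votu_records `records` from [votu_sharing()].
#' @param comparisons Data.frame of strain comparisons (sample vs NC).
#' @param mode "decontamination" (fraction-compared waived, the default) or
#'   "analysis".
#' @param popani_min,min_fraction Thresholds passed to [is_shared_strain()].
#' @return Data.frame of strain-level sharing records (nc_ids = the NCs with
#'   an identical strain).
#' @export
strain_sharing <- function(votu_records, comparisons,
                           mode = "decontamination", popani_min = 99.999,
                           min_fraction = 0.75) {
  out <- list()
  skipped <- 0L
  cmp_key <- paste(comparisons$votu_id, comparisons$sample_a,
                   comparisons$sample_b, sep = "\r")
  for (i in seq_len(nrow(votu_records))) {
    sid <- votu_records$sample_id[i]
    v <- votu_records$votu_id[i]
    nc_ids <- split_ids(votu_records$nc_ids[i])
    hit <- character(0)
    any_found <- FALSE
    for (nc in nc_ids) {
      j <- which(cmp_key == paste(v, sid, nc, sep = "\r") |
                   cmp_key == paste(v, nc, sid, sep = "\r"))
      if (length(j) == 0) next
      cmp <- comparisons[j[1], ]
      if (is.na(cmp$popani)) next
      any_found <- TRUE
      if (is_shared_strain(cmp, popani_min = popani_min,
                           min_fraction = min_fraction, mode = mode)) {
        hit <- c(hit, nc)
      }
    }
    if (!any_found) {
      skipped <- skipped + 1L
      next
    }
    if (length(hit) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, votu_id = v, level = "strain",
        nc_ids = collapse_ids(hit), scope = votu_records$scope[i],
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0) {
    warning(skipped, " vOTU-sharing record(s) had no usable strain ",
            "comparison and were not promoted")
  }
  if (length(out)) do.call(rbind, out) else empty_sharing_records()
}

zero_cells <- function(m, records) {
  if (nrow(records) > 0) {
    m[cbind(records$votu_id, records$sample_id)] <- 0
  }
  m
}

removed_by_sample <- function(records, samples) {
  out <- lapply(stats::setNames(samples, samples), function(s)
    sort(unique(records$votu_id[records$sample_id == s])))
  out
}

#' Strain-level decontamination
#'
#' Zeroes the RPKM value of every (vOTU, sample) cell backed by a
#' strain-level sharing record; all other cells are untouched.
#'
#' @param am An `abundance_matrix`.
#' @param strain_records Strain-level records from [strain_sharing()].
#' @return List(matrix = decontaminated `abundance_matrix`, report =
#'   data.frame(sample_id, richness_before, richness_after, n_removed,
#'   pct_richness_drop), removed = per-sample list of zeroed vOTUs).
#' @export
strain_decontaminate <- function(am, strain_records) {
  decontaminate_records(am, strain_records, level = "strain")
}

#' Species-level decontamination
#'
#' Zeroes every (vOTU, sample) cell where the vOTU appears in the sample's
#' own-study negativeome, regardless of strain identity. NC columns are
#' untouched.
#'
#' @param am An `abundance_matrix`.
#' @param catalog A `negativeome`.
#' @param metadata Sample metadata (defaults to the matrix's own).
#' @return Same shape as [strain_decontaminate()].
#' @export
species_decontaminate <- function(am, catalog, metadata = NULL) {
  m <- as_rpkm(am)
  metadata <- metadata %||% am$metadata
  abort_if(is.null(metadata), "metadata required")
  samples <- metadata[metadata$role == "sample" &
                        metadata$sample_id %in% colnames(m), ]
  records <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    ent <- negativeome_votus(catalog, samples$study[i])
    hit <- intersect(rownames(m)[m[, sid] > 0], ent$votu_id)
    for (v in hit) {
      records[[length(records) + 1L]] <- data.frame(
        sample_id = sid, votu_id = v, level = "votu", nc_ids = "",
        scope = "own_study", stringsAsFactors = FALSE)
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    empty_sharing_records()
  decontaminate_records(am, records, level = "species")
}

decontaminate_records <- function(am, records, level) {
  m <- as_rpkm(am)
  before <- richness(m)
  bad <- nrow(records) > 0 &&
    any(m[cbind(records$votu_id, records$sample_id)] == 0)
  if (bad) {
    records <- records[m[cbind(records$votu_id, records$sample_id)] > 0, ,
                       drop = FALSE]
  }
  m2 <- zero_cells(m, records)
  after <- richness(m2)
  report <- data.frame(
    sample_id = colnames(m),
    richness_before = as.integer(before),
    richness_after = as.integer(after),
    n_removed = as.integer(before - after),
    pct_richness_drop = ifelse(before > 0, 100 * (before - after) / before,
                               0),
    stringsAsFactors = FALSE)
  out <- list(matrix = abundance_matrix(m2, if (inherits(am,
    "abundance_matrix")) am$metadata),
    report = report,
    removed = removed_by_sample(records, colnames(m)),
    level = level)
  class(out) <- "decontam_result"
  out
}

#' @export
print.decontam_result <- function(x, ...) {
  cat("decontamination (", x$level, " level): ",
      sum(x$report$n_removed), " cells zeroed across ",
      sum(x$report$n_removed > 0), " samples\n", sep = "")
  invisible(x)
}

#' Full decontamination report (strain and species level)
#'
#' Runs vOTU- and strain-level sharing plus both decontamination levels and
#' assembles the per-sample report: removed vOTU sets, richness before/after
#' at each level, and the percentages of richness and abundance shared with
#' NCs at vOTU and strain level.
#'
#' @param am QC-filtered `abundance_matrix`.
#' @param comparisons Strain comparisons between samples and NCs.
#' @param metadata Sample metadata (defaults to the matrix's own).
#' @param mode Strain-sharing mode; default "decontamination".
#' @param popani_min,min_fraction Strain-identity thresholds.
#' @return A `decontam_report`: list with `per_sample` data.frame,
#'   `removed_strain`, `removed_species` per-sample lists, and the two
#'   decontaminated matrices.
#' @export
decontamination_report <- function(am, comparisons, metadata = NULL,
                                   mode = "decontamination",
                                   popani_min = 99.999,
                                   min_fraction = 0.75) {
  metadata <- metadata %||% am$metadata
  abort_if(is.null(metadata), "metadata required")
  catalog <- build_negativeome(am, metadata)
  vs <- votu_sharing(am, catalog, metadata, scope = "own_study")
  ss <- strain_sharing(vs$records, comparisons, mode = mode,
                       popani_min = popani_min, min_fraction = min_fraction)
  strain_res <- strain_decontaminate(am, ss)
  species_res <- species_decontaminate(am, catalog, metadata)
  rel <- relative_abundance(am)
  per_sample <- vs$metrics
  names(per_sample)[names(per_sample) == "pct_richness_shared"] <-
    "pct_richness_shared_votu"
  names(per_sample)[names(per_sample) == "pct_abundance_shared"] <-
    "pct_abundance_shared_votu"
  strain_by_sample <- split(ss$votu_id, ss$sample_id)
  n_strain <- vapply(per_sample$sample_id, function(s)
    length(strain_by_sample[[s]] %||% character(0)), 0L)
  abund_strain <- vapply(per_sample$sample_id, function(s) {
    v <- strain_by_sample[[s]] %||% character(0)
    if (length(v) == 0) 0 else sum(rel[v, s])
  }, 0)
  per_sample$pct_richness_shared_strain <-
    ifelse(per_sample$richness > 0, 100 * n_strain / per_sample$richness,
           NA_real_)
  per_sample$pct_abundance_shared_strain <-
    ifelse(per_sample$richness > 0, 100 * abund_strain, NA_real_)
  idx_s <- match(per_sample$sample_id, strain_res$report$sample_id)
  idx_p <- match(per_sample$sample_id, species_res$report$sample_id)
  per_sample$richness_before <- strain_res$report$richness_before[idx_s]
  per_sample$richness_after_strain <- strain_res$report$richness_after[idx_s]
  per_sample$richness_after_species <-
    species_res$report$richness_after[idx_p]
  out <- list(per_sample = per_sample,
              removed_strain = strain_res$removed[per_sample$sample_id],
              removed_species = species_res$removed[per_sample$sample_id],
              matrix_strain = strain_res$matrix,
              matrix_species = species_res$matrix,
              strain_records = ss,
              votu_records = vs$records,
              catalog = catalog)
  class(out) <- "decontam_report"
  out
}

#' @export
print.decontam_report <- function(x, ...) {
  ps <- x$per_sample
  cat("decontamination report for ", nrow(ps), " biological samples\n",
      sep = "")
  cat("median % richness shared with NCs (vOTU level): ",
      round(stats::median(ps$pct_richness_shared_votu, na.rm = TRUE), 2),
      "\n", sep = "")
  cat("median % richness shared with NCs (strain level): ",
      round(stats::median(ps$pct_richness_shared_strain, na.rm = TRUE), 2),
      "\n", sep = "")
  invisible(x)
}

#' Study-level medians and IQRs of decontamination metrics
#'
#' @param report A `decontam_report`.
#' @return Data.frame per study (plus "all"): median and quartiles of the
#'   per-sample richness drop percentages at strain and species level and of
#'   the shared-richness percentages.
#' @export
decontamination_summary <- function(report) {
  ps <- report$per_sample
  drop_strain <- ifelse(ps$richness_before > 0,
                        100 * (ps$richness_before - ps$richness_after_strain) /
                          ps$richness_before, 0)
  drop_species <- ifelse(ps$richness_before > 0,
                         100 * (ps$richness_before -
                                  ps$richness_after_species) /
                           ps$richness_before, 0)
  groups <- c(list(all = seq_len(nrow(ps))),
              split(seq_len(nrow(ps)), ps$study))
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    s1 <- median_iqr(drop_strain[i])
    s2 <- median_iqr(drop_species[i])
    s3 <- median_iqr(ps$pct_richness_shared_votu[i][
      !is.na(ps$pct_richness_shared_votu[i])])
    data.frame(study = g, n = length(i),
               drop_strain_median = s1[["median"]],
               drop_strain_q1 = s1[["q1"]], drop_strain_q3 = s1[["q3"]],
               drop_species_median = s2[["median"]],
               drop_species_q1 = s2[["q1"]], drop_species_q3 = s2[["q3"]],
               pct_shared_votu_median = s3[["median"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
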