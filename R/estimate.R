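# Contamination estimation for studies lacking internal NCs, against an
# external negativeome catalog: vOTU-sharing and read-mapping metrics plus
# their study-wise concordance with the internal strain-sharing metric.

#' Estimate contamination via vOTU sharing with an external catalog
#'
#' For each biological sample, the percentage of its detected vOTUs that are
#' negativeome entries of studies other than the sample's own
#' (leave-one-study-out scope). Presence is nonzero abundance after QC;
#' the estimate is invariant to abundance rescaling.
#'
#' @param am QC-filtered `abundance_matrix` (or matrix plus `metadata`).
#' @param catalog A `negativeome` with study-annotated entries.
#' @param metadata Sample metadata (defaults to the matrix's own).
#' @return Data.frame (sample_id, study, richness, n_shared_external,
#'   pct_votus_shared_external); NA at richness 0.
#' @export
estimate_by_votu_sharing <- function(am, catalog, metadata = NULL) {
  vs <- votu_sharing(am, catalog, metadata, scope = "external")
  out <- vs$metrics
  names(out)[names(out) == "n_shared"] <- "n_shared_external"
  names(out)[names(out) == "pct_richness_shared"] <-
    "pct_votus_shared_external"
  out$pct_abundance_shared <- NULL
  out
}

#' Estimate contamination via reads mapped to the external catalog
#'
#' The percentage of a sample's reads mapped to catalog contigs whose
#' breadth of coverage in that sample is strictly greater than `breadth_min`
#' ("more than" 50% or 75%). Reported as the weaker of the two estimators:
#' it is sensitive to spurious and multimapping alignments.
#'
#' @param read_assignments Data.frame (sample_id, contig_id, reads): reads
#'   mapped per catalog contig per sample.
#' @param breadth Data.frame (sample_id, contig_id, breadth) in [0, 1].
#' @param total_reads Named per-sample vector of total reads (positive).
#' @param breadth_min Strict breadth threshold, 0.50 or 0.75; default 0.75.
#' @return Data.frame (sample_id, qualified_reads, total_reads,
#'   pct_reads_mapped_qualified).
#' @export
estimate_by_read_mapping <- function(read_assignments, breadth, total_reads,
                                     breadth_min = 0.75) {
  samples <- names(total_reads)
  abort_if(is.null(samples), "total_reads must be a named vector")
  abort_if(any(total_reads <= 0), "total_reads must be positive for sample ",
           samples[total_reads <= 0][1])
  key_b <- paste(breadth$sample_id, breadth$contig_id, sep = "\r")
  b <- stats::setNames(breadth$breadth, key_b)
  key_r <- paste(read_assignments$sample_id, read_assignments$contig_id,
                 sep = "\r")
  contig_breadth <- b[key_r]
  abort_if(anyNA(contig_breadth), "breadth missing for assigned contig: ",
           gsub("\r", "/", key_r[is.na(contig_breadth)][1]))
  qualifies <- contig_breadth > breadth_min
  qual <- tapply(read_assignments$reads * qualifies,
                 read_assignments$sample_id, sum)
  out <- data.frame(sample_id = samples,
                    qualified_reads = as.numeric(qual[samples]),
                    total_reads = as.numeric(total_reads),
                    stringsAsFactors = FALSE)
  out$qualified_reads[is.na(out$qualified_reads)] <- 0
  out$pct_reads_mapped_qualified <- 100 * out$qualified_reads /
    out$total_reads
  out
}

#' Study-wise Spearman concordance between two per-sample metrics
#'
#' @param metric_a,metric_b Named (by sample_id) numeric vectors.
#' @param study Named character vector mapping sample_id to study.
#' @param min_n Minimum paired observations per group; default 3.
#' @return Data.frame (study, n, rho) with a pooled row; rho is NA for
#'   groups below `min_n` or with zero variance.
#' @export
concordance <- function(metric_a, metric_b, study, min_n = 3) {
  ids <- intersect(names(metric_a), names(metric_b))
  ids <- ids[!is.na(metric_a[ids]) & !is.na(metric_b[ids])]
  groups <- c(list(pooled = ids), split(ids, study[ids]))
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    rho <- if (length(i) >= min_n)
      spearman(metric_a[i], metric_b[i]) else NA_real_
    data.frame(study = g, n = length(i), rho = rho,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attach contamination estimates to sample metadata
#'
#' Joins the per-sample estimates onto the metadata so downstream models can
#' use contamination as a covariate or correction factor.
#'
#' @param metadata Sample metadata data.frame.
#' @param estimates Data.frame with a sample_id column plus estimate columns.
#' @return Metadata with the estimate columns appended (NA where absent).
#' @export
attach_estimates <- function(metadata, estimates) {
  idx <- match(metadata$sample_id, estimates$sample_id)
  for (col in setdiff(names(estimates), c("sample_id", "study"))) {
    metadata[[col]] <- estimates[[col]][idx]
  }
  metadata
}
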