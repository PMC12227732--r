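# Read-mapping evidence -> QC-filtered RPKM abundance matrix, plus the
# ecological summaries used downstream (richness, Shannon, 1 - Bray-Curtis).

#' Construct a count matrix object
#'
#' Bundles raw mapped-read counts with per-sample totals and per-cell breadth
#' of coverage (fraction of contig positions with depth >= 1).
#'
#' @param counts vOTU x sample matrix of non-negative integer counts.
#' @param mapped_total Named per-sample vector of reads mapped (positive).
#' @param breadth vOTU x sample matrix in [0, 1], same dimnames as `counts`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, mapped_total, breadth) {
  abort_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "counts must have vOTU rownames and sample colnames")
  abort_if(!identical(dim(counts), dim(breadth)) ||
             !identical(dimnames(counts), dimnames(breadth)),
           "breadth must share dimnames with counts")
  abort_if(any(counts < 0), "negative counts")
  abort_if(any(breadth < 0 | breadth > 1), "breadth outside [0,1]")
  abort_if(any(counts > 0 & breadth == 0),
           "nonzero count with zero breadth")
  abort_if(!all(colnames(counts) %in% names(mapped_total)),
           "mapped_total missing for some samples")
  structure(list(counts = counts,
                 mapped_total = mapped_total[colnames(counts)],
                 breadth = breadth),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " vOTUs x ", ncol(x$counts),
      " samples; total counts ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' Zero out counts with insufficient breadth of coverage
#'
#' Counts whose breadth of coverage is strictly below `min_breadth` are set
#' to 0 (a cell at exactly the threshold is retained). Per-sample mapped
#' totals are left untouched: "per million reads mapped" refers to the
#' mapping, not the filtered table.
#'
#' @param cm A `count_matrix`.
#' @param min_breadth Minimum breadth retained; default 0.75.
#' @return The filtered `count_matrix`.
#' @export
breadth_filter <- function(cm, min_breadth = 0.75) {
  stopifnot(inherits(cm, "count_matrix"))
  cm$counts[cm$breadth < min_breadth] <- 0
  cm
}

#' Transform counts to RPKM
#'
#' rpkm[v, s] = count[v, s] / (length_bp[v] / 1000) / (mapped_total[s] / 1e6).
#'
#' @param cm A `count_matrix` (typically after [breadth_filter()]).
#' @param annotations vOTU annotation data.frame supplying `length_bp`.
#' @param metadata Optional sample metadata carried on the result.
#' @return An `abundance_matrix`: list(rpkm = matrix, metadata).
#' @export
to_rpkm <- function(cm, annotations, metadata = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  lens <- stats::setNames(annotations$length_bp, annotations$votu_id)
  missing <- setdiff(rownames(cm$counts), names(lens))
  abort_if(length(missing) > 0, "no annotation for vOTU: ", missing[1])
  bad <- cm$mapped_total <= 0 & colSums(cm$counts) > 0
  abort_if(any(bad), "mapped_total is zero for sample with nonzero counts: ",
           names(cm$mapped_total)[bad][1])
  kb <- lens[rownames(cm$counts)] / 1000
  denom <- ifelse(cm$mapped_total > 0, cm$mapped_total / 1e6, 1)
  rpkm <- sweep(cm$counts / kb, 2, denom, "/")
  abundance_matrix(rpkm, metadata)
}

#' Construct an abundance matrix object
#'
#' @param rpkm vOTU x sample matrix of non-negative RPKM values (no NaN).
#' @param metadata Optional sample metadata data.frame (validated when given;
#'   every matrix column must appear in it).
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(rpkm, metadata = NULL) {
  abort_if(any(is.na(rpkm)), "NaN/NA in abundance matrix")
  abort_if(any(rpkm < 0), "negative abundance values")
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    missing <- setdiff(colnames(rpkm), metadata$sample_id)
    abort_if(length(missing) > 0, "sample missing from metadata: ",
             missing[1])
  }
  structure(list(rpkm = rpkm, metadata = metadata),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix: ", nrow(x$rpkm), " vOTUs x ", ncol(x$rpkm),
      " samples\n", sep = "")
  if (!is.null(x$metadata)) {
    tab <- table(x$metadata$role[match(colnames(x$rpkm),
                                       x$metadata$sample_id)])
    cat("roles: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Accept either an abundance_matrix or a bare matrix.
as_rpkm <- function(x) {
  if (inherits(x, "abundance_matrix")) x$rpkm else as.matrix(x)
}

#' Remove vOTUs failing quality filters
#'
#' Rows are dropped when the representative is shorter than `min_length` bp,
#' has strictly fewer viral genes than host genes, or carries the plasmid
#' flag. Surviving rows are value-identical.
#'
#' @param am An `abundance_matrix` (or bare matrix).
#' @param annotations vOTU annotation data.frame covering every row.
#' @param min_length Minimum representative length in bp; default 1000.
#' @return The filtered `abundance_matrix`.
#' @export
qc_filter_votus <- function(am, annotations, min_length = 1000) {
  m <- as_rpkm(am)
  idx <- match(rownames(m), annotations$votu_id)
  abort_if(anyNA(idx), "no annotation for vOTU: ",
           rownames(m)[is.na(idx)][1])
  ann <- annotations[idx, ]
  drop <- ann$length_bp < min_length |
    ann$viral_gene_count < ann$host_gene_count |
    ann$plasmid_flag
  abundance_matrix(m[!drop, , drop = FALSE],
                   if (inherits(am, "abundance_matrix")) am$metadata)
}

#' Per-sample vOTU richness
#' @param am An `abundance_matrix` or matrix.
#' @return Named integer vector: number of vOTUs with abundance > 0.
#' @export
richness <- function(am) {
  m <- as_rpkm(am)
  colSums(m > 0)
}

#' Per-sample relative abundances
#' @param am An `abundance_matrix` or matrix.
#' @return Matrix of per-sample relative abundances (all-zero samples stay 0).
#' @export
relative_abundance <- function(am) {
  m <- as_rpkm(am)
  tot <- colSums(m)
  sweep(m, 2, ifelse(tot > 0, tot, 1), "/")
}

#' Per-sample Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i on per-sample relative abundances; samples with zero
#' total abundance are undefined and reported as NA.
#'
#' @param am An `abundance_matrix` or matrix.
#' @return Named numeric vector of Shannon indices.
#' @export
shannon <- function(am) {
  m <- as_rpkm(am)
  h <- vegan::diversity(t(m), index = "shannon")
  h[colSums(m) == 0] <- NA_real_
  h
}

#' Pairwise sample similarity as 1 - Bray-Curtis dissimilarity
#'
#' Pairs where both samples are all-zero are undefined (NA, with a warning).
#'
#' @param am An `abundance_matrix` or matrix.
#' @return Symmetric sample x sample similarity matrix with unit diagonal for
#'   samples with nonzero totals.
#' @export
bray_curtis_similarity <- function(am) {
  m <- as_rpkm(am)
  n <- ncol(m)
  out <- matrix(NA_real_, n, n, dimnames = list(colnames(m), colnames(m)))
  nonzero <- colSums(m) > 0
  if (any(!nonzero)) {
    warning("all-zero sample(s): similarity undefined (NA) for ",
            paste(colnames(m)[!nonzero], collapse = ", "))
  }
  if (sum(nonzero) >= 2) {
    bc <- as.matrix(vegan::vegdist(t(m[, nonzero, drop = FALSE]),
                                   method = "bray"))
    out[nonzero, nonzero] <- 1 - bc
  }
  diag(out)[nonzero] <- 1
  out
}
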