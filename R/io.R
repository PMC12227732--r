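# Readers and writers for every external format the toolkit touches.
# All coordinates are 1-based inclusive. Optional metadata fields are
# encoded as empty strings in TSV files, never as "NA" literals.

META_COLS <- c("sample_id", "study", "role", "subject_id", "group",
               "age_months", "nucleic_acid")
ANNOT_COLS <- c("votu_id", "length_bp", "viral_gene_count", "host_gene_count",
                "plasmid_flag", "completeness_pct")
PILEUP_COLS <- c("sample_id", "votu_id", "pos", "A", "C", "G", "T")
ALN_COLS <- c("query_id", "target_id", "pct_identity", "aln_length",
              "mismatches", "gapopens", "qstart", "qend", "tstart", "tend",
              "evalue", "bitscore")

#' Read a FASTA file of contig sequences
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet.
#' Duplicate ids, empty sequences and characters outside that alphabet are
#' hard errors naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, names are contig ids
#'   (FASTA header up to the first whitespace).
#' @export
read_fasta <- function(path) {
  abort_if(!file.exists(path), "FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  abort_if(length(dup) > 0, "duplicate FASTA id: ", dup[1])
  seqs <- toupper(as.character(set))
  empty <- ids[!nzchar(seqs)]
  abort_if(length(empty) > 0, "empty sequence for FASTA record: ", empty[1])
  bad <- grepl("[^ACGTN]", seqs)
  abort_if(any(bad), "non-A/C/G/T/N character in FASTA record: ", ids[bad][1])
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  abort_if(is.null(names(seqs)) || any(!nzchar(names(seqs))),
           "all sequences must be named")
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  abort_if(!file.exists(path), what, " file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0,
           what, " file ", path, " is missing column(s): ",
           paste(missing, collapse = ", "))
  df[required]
}

num_or_na <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- nzchar(x) & is.na(out)
  abort_if(any(bad), "non-numeric ", what, " value: '", x[bad][1], "'")
  out[!nzchar(x)] <- NA_real_
  out
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `study`, `role` (sample/nc),
#' `subject_id`, `group` (infant/mother/nc), `age_months`, `nucleic_acid`
#' (DNA/RNA). Empty strings encode missing optional values.
#'
#' @param path Path to the metadata TSV.
#' @return Validated data.frame of sample metadata.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_checked(path, META_COLS, "metadata")
  df$age_months <- num_or_na(df$age_months, "age_months")
  validate_metadata(df)
}

#' Validate a sample metadata table
#'
#' @param df Data.frame with the metadata columns.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validate_metadata <- function(df) {
  missing <- setdiff(META_COLS, names(df))
  abort_if(length(missing) > 0, "metadata missing column(s): ",
           paste(missing, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  abort_if(length(dup) > 0, "duplicate sample_id in metadata: ", dup[1])
  bad_role <- !df$role %in% c("sample", "nc")
  abort_if(any(bad_role), "unknown role '", df$role[bad_role][1],
           "' for sample ", df$sample_id[bad_role][1])
  bad_group <- !df$group %in% c("infant", "mother", "nc")
  abort_if(any(bad_group), "unknown group '", df$group[bad_group][1],
           "' for sample ", df$sample_id[bad_group][1])
  nc_bad <- df$role == "nc" & df$group != "nc"
  abort_if(any(nc_bad), "NC sample ", df$sample_id[nc_bad][1],
           " must have group 'nc'")
  bad_na <- !is.na(df$age_months) & df$age_months < 0
  abort_if(any(bad_na), "negative age_months for sample ",
           df$sample_id[bad_na][1])
  bad_nuc <- nzchar(df$nucleic_acid) & !df$nucleic_acid %in% c("DNA", "RNA")
  abort_if(any(bad_nuc), "unknown nucleic_acid '",
           df$nucleic_acid[bad_nuc][1], "'")
  df
}

#' Write sample metadata to TSV
#' @param df Metadata data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(df, path) {
  out <- validate_metadata(df)
  out$age_months <- ifelse(is.na(out$age_months), "",
                           format(out$age_months, trim = TRUE, digits = 15))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-vOTU QC annotations
#'
#' TSV with columns `votu_id`, `length_bp`, `viral_gene_count`,
#' `host_gene_count`, `plasmid_flag` (TRUE/FALSE), `completeness_pct`
#' (empty when unknown).
#'
#' @param path Path to the annotations TSV.
#' @return Validated data.frame of vOTU annotations.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, ANNOT_COLS, "annotations")
  for (col in c("length_bp", "viral_gene_count", "host_gene_count")) {
    df[[col]] <- num_or_na(df[[col]], col)
  }
  abort_if(!all(df$plasmid_flag %in% c("TRUE", "FALSE")),
           "plasmid_flag must be TRUE or FALSE")
  df$plasmid_flag <- df$plasmid_flag == "TRUE"
  df$completeness_pct <- num_or_na(df$completeness_pct, "completeness_pct")
  validate_annotations(df)
}

#' Validate a vOTU annotation table
#' @param df Data.frame with the annotation columns.
#' @return The validated data.frame.
#' @export
validate_annotations <- function(df) {
  missing <- setdiff(ANNOT_COLS, names(df))
  abort_if(length(missing) > 0, "annotations missing column(s): ",
           paste(missing, collapse = ", "))
  dup <- df$votu_id[duplicated(df$votu_id)]
  abort_if(length(dup) > 0, "duplicate votu_id in annotations: ", dup[1])
  bad <- is.na(df$length_bp) | df$length_bp < 1 |
    df$length_bp != floor(df$length_bp)
  abort_if(any(bad), "length_bp must be a positive integer for vOTU ",
           df$votu_id[bad][1])
  for (col in c("viral_gene_count", "host_gene_count")) {
    bad <- is.na(df[[col]]) | df[[col]] < 0
    abort_if(any(bad), col, " must be non-negative for vOTU ",
             df$votu_id[bad][1])
  }
  bad <- !is.na(df$completeness_pct) &
    (df$completeness_pct < 0 | df$completeness_pct > 100)
  abort_if(any(bad), "completeness_pct outside [0,100] for vOTU ",
           df$votu_id[bad][1])
  df
}

#' Write vOTU annotations to TSV
#' @param df Annotation data.frame.
#' @param path Output path.
#' @export
write_annotations <- function(df, path) {
  out <- validate_annotations(df)
  out$completeness_pct <- ifelse(is.na(out$completeness_pct), "",
                                 format(out$completeness_pct, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-position pileup table
#'
#' TSV with header exactly `sample_id, votu_id, pos, A, C, G, T`; one row per
#' covered position per (sample, vOTU). Positions are 1-based; rows whose four
#' depths are all zero are forbidden (uncovered positions are simply absent).
#'
#' @param path Path to the pileup TSV.
#' @param annotations vOTU annotation data.frame used to bound positions.
#' @return Validated pileup data.frame with integer `pos` and depth columns.
#' @export
read_pileup <- function(path, annotations) {
  abort_if(!file.exists(path), "pileup file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  abort_if(!identical(header, PILEUP_COLS),
           "pileup header must be exactly: ",
           paste(PILEUP_COLS, collapse = ", "))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer",
                                         "integer", "integer", "integer",
                                         "integer"),
                          check.names = FALSE, quote = "")
  validate_pileup(df, annotations)
}

#' Validate a pileup table against vOTU lengths
#' @param df Pileup data.frame.
#' @param annotations vOTU annotation data.frame.
#' @return The validated data.frame.
#' @export
validate_pileup <- function(df, annotations) {
  missing <- setdiff(PILEUP_COLS, names(df))
  abort_if(length(missing) > 0, "pileup missing column(s): ",
           paste(missing, collapse = ", "))
  lens <- stats::setNames(annotations$length_bp, annotations$votu_id)
  unknown <- !df$votu_id %in% names(lens)
  abort_if(any(unknown), "pileup references unannotated vOTU: ",
           df$votu_id[unknown][1])
  depth_cols <- as.matrix(df[BASES])
  neg <- rowSums(depth_cols < 0) > 0
  abort_if(any(neg), "negative depth in pileup row ", which(neg)[1])
  zero <- rowSums(depth_cols) == 0
  abort_if(any(zero), "all-zero depth forbidden in pileup row ",
           which(zero)[1])
  oob <- df$pos < 1 | df$pos > lens[df$votu_id]
  abort_if(any(oob), "pileup position out of range in row ", which(oob)[1],
           " (vOTU ", df$votu_id[oob][1], ", pos ", df$pos[oob][1], ")")
  key <- paste(df$sample_id, df$votu_id, df$pos, sep = "\r")
  abort_if(anyDuplicated(key) > 0, "duplicate (sample, vOTU, pos) in pileup: ",
           gsub("\r", "/", key[duplicated(key)][1]))
  df
}

#' Write a pileup table to TSV
#' @param df Pileup data.frame.
#' @param path Output path.
#' @export
write_pileup <- function(df, path) {
  utils::write.table(df[PILEUP_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pairwise local-alignment records
#'
#' 12-column tabular dialect (the de-facto standard tabular alignment
#' format): query, target, pct_identity, aln_length, mismatches, gapopens,
#' qstart, qend, tstart, tend, evalue, bitscore. No header line.
#'
#' @param path Path to the alignment TSV.
#' @return Data.frame of alignment records with numeric columns parsed.
#' @export
read_alignments <- function(path) {
  abort_if(!file.exists(path), "alignment file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  abort_if(ncol(df) != 12L, "alignment file must have 12 columns, found ",
           ncol(df))
  names(df) <- ALN_COLS
  for (col in ALN_COLS[3:12]) df[[col]] <- num_or_na(df[[col]], col)
  bad <- df$qstart > df$qend
  abort_if(any(bad), "qstart > qend in alignment row ", which(bad)[1])
  df
}

#' Write alignment records (headerless 12-column TSV)
#' @param df Alignment data.frame with the 12 standard columns.
#' @param path Output path.
#' @export
write_alignments <- function(df, path) {
  utils::write.table(df[ALN_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a vOTU x sample matrix from TSV
#'
#' vOTUs as rows, samples as columns; first column holds vOTU ids.
#'
#' @param path Path to the matrix TSV.
#' @return Numeric matrix with vOTU rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  abort_if(!file.exists(path), "matrix file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "")
  abort_if(ncol(df) < 2L, "matrix file must have an id column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  abort_if(anyDuplicated(rownames(m)) > 0, "duplicate vOTU id in matrix")
  abort_if(any(is.na(m)), "NaN/NA in matrix file: ", path)
  m
}

#' Write a vOTU x sample matrix to TSV
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  m <- as_rpkm(m)
  abort_if(any(is.na(m)), "refusing to write NaN/NA values to matrix file")
  df <- data.frame(votu_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a strain tree (or any phylo object) to newick
#' @param tree A `strain_tree` or `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "strain_tree")) tree$phylo else tree
  abort_if(!inherits(phy, "phylo"), "not a phylo/strain_tree object")
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a report object as JSON
#' @param report A list or report object (coerced with unclass).
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else x
}

#' Read a run configuration (YAML)
#'
#' Keys mirror [run_config()]; missing keys fall back to documented defaults.
#'
#' @param path Path to a YAML config file.
#' @return A validated run_config list.
#' @export
read_config <- function(path) {
  abort_if(!file.exists(path), "config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals %||% list())
}
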