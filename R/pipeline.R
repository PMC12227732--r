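# End-to-end orchestration: a single run configuration, file-driven stage
# runners writing a machine-readable manifest, and in-memory composition
# helpers used on simulated datasets.

#' Run configuration
#'
#' Consolidates every threshold of the method with its documented default,
#' plus input/output paths for the file-driven runners.
#'
#' @param counts,breadth,annotations,metadata,pileup,comparisons,fasta,
#'   catalog_meta Optional input paths.
#' @param outdir Output directory; default "viroclean_out".
#' @param ani_min,af_min vOTU dereplication thresholds (%); defaults 95, 85.
#' @param breadth_min Breadth-of-coverage filter; default 0.75.
#' @param min_length Minimum vOTU representative length (bp); default 1000.
#' @param popani_min Strain-identity popANI threshold (%); default 99.999.
#' @param min_fraction Minimum fraction of genome compared; default 0.75.
#' @param min_cov Minimum depth for a covered position; default 1.
#' @param mode Decontamination mode: "strain" or "species".
#' @param scope Sharing scope: "own_study" or "external".
#' @param linkage hclust linkage for strain trees; default "complete".
#' @param seed Integer seed funneled to every stochastic step.
#' @return A validated `run_config` list.
#' @export
run_config <- function(counts = NULL, breadth = NULL, annotations = NULL,
                       metadata = NULL, pileup = NULL, comparisons = NULL,
                       fasta = NULL, catalog_meta = NULL,
                       outdir = "viroclean_out", ani_min = 95, af_min = 85,
                       breadth_min = 0.75, min_length = 1000,
                       popani_min = 99.999, min_fraction = 0.75,
                       min_cov = 1, mode = "strain", scope = "own_study",
                       linkage = "complete", seed = 1) {
  cfg <- list(counts = counts, breadth = breadth, annotations = annotations,
              metadata = metadata, pileup = pileup,
              comparisons = comparisons, fasta = fasta,
              catalog_meta = catalog_meta, outdir = outdir,
              ani_min = ani_min, af_min = af_min,
              breadth_min = breadth_min, min_length = min_length,
              popani_min = popani_min, min_fraction = min_fraction,
              min_cov = min_cov, mode = mode, scope = scope,
              linkage = linkage, seed = as.integer(seed))
  abort_if(!cfg$mode %in% c("strain", "species"),
           "mode must be 'strain' or 'species'")
  abort_if(!cfg$scope %in% c("own_study", "external"),
           "scope must be 'own_study' or 'external'")
  abort_if(cfg$ani_min < 0 || cfg$ani_min > 100 ||
             cfg$af_min < 0 || cfg$af_min > 100 ||
             cfg$popani_min < 0 || cfg$popani_min > 100,
           "percentage thresholds must lie in [0, 100]")
  abort_if(cfg$breadth_min < 0 || cfg$breadth_min > 1 ||
             cfg$min_fraction < 0 || cfg$min_fraction > 1,
           "fraction thresholds must lie in [0, 1]")
  paths <- unlist(cfg[c("counts", "breadth", "annotations", "metadata",
                        "pileup", "comparisons", "fasta", "catalog_meta")])
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  abort_if(length(missing) > 0, "config path does not exist: ", missing[1])
  structure(cfg, class = "run_config")
}

# Hash of everything that determines the outputs' values: inputs,
# thresholds and seed. The output directory is excluded so that equal runs
# into different destinations share a hash.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$outdir <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, outputs, outdir) {
  manifest <- list(
    tool = "viroclean",
    version = as.character(utils::packageVersion("viroclean")),
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    outputs = outputs)
  write_report(manifest, file.path(outdir, "manifest.json"))
  manifest
}

load_rpkm_inputs <- function(config) {
  abort_if(is.null(config$counts) || is.null(config$breadth) ||
             is.null(config$annotations) || is.null(config$metadata),
           "counts, breadth, annotations and metadata paths are required")
  counts <- read_matrix(config$counts)
  breadth <- read_matrix(config$breadth)
  annotations <- read_annotations(config$annotations)
  metadata <- read_metadata(config$metadata)
  cm <- count_matrix(counts, stats::setNames(colSums(counts),
                                             colnames(counts)), breadth)
  cm <- breadth_filter(cm, min_breadth = config$breadth_min)
  am <- to_rpkm(cm, annotations, metadata)
  am <- qc_filter_votus(am, annotations, min_length = config$min_length)
  list(am = am, annotations = annotations, metadata = metadata)
}

#' Characterize contamination: negativeome + sharing metrics
#'
#' Builds the QC-filtered RPKM table from the configured inputs, derives the
#' per-study negativeome and per-sample vOTU-sharing metrics, and writes
#' rpkm.tsv, negativeome.tsv, sharing_metrics.tsv and manifest.json into the
#' output directory.
#'
#' @param config A `run_config`.
#' @return Invisibly, list(am, catalog, sharing, manifest).
#' @export
run_characterize <- function(config) {
  inp <- load_rpkm_inputs(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  catalog <- build_negativeome(inp$am, inp$metadata)
  sharing <- votu_sharing(inp$am, catalog, inp$metadata,
                          scope = config$scope)
  write_matrix(inp$am, file.path(config$outdir, "rpkm.tsv"))
  utils::write.table(catalog$entries,
                     file.path(config$outdir, "negativeome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sharing$metrics,
                     file.path(config$outdir, "sharing_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- write_manifest(config,
                             c("rpkm.tsv", "negativeome.tsv",
                               "sharing_metrics.tsv"), config$outdir)
  invisible(list(am = inp$am, catalog = catalog, sharing = sharing,
                 manifest = manifest))
}

#' Decontaminate the abundance table
#'
#' Strain mode zeroes cells whose strain is identical to an NC strain
#' (comparisons from the configured comparisons file, or computed from the
#' configured pileup); species mode zeroes every own-study NC vOTU. Writes
#' clean.tsv, report.json and manifest.json.
#'
#' @param config A `run_config`.
#' @return Invisibly, list(result, report, manifest).
#' @export
run_decontaminate <- function(config) {
  inp <- load_rpkm_inputs(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  catalog <- build_negativeome(inp$am, inp$metadata)
  if (config$mode == "strain") {
    comparisons <- load_comparisons(config, inp)
    vs <- votu_sharing(inp$am, catalog, inp$metadata, scope = "own_study")
    ss <- strain_sharing(vs$records, comparisons,
                         mode = "decontamination",
                         popani_min = config$popani_min,
                         min_fraction = config$min_fraction)
    result <- strain_decontaminate(inp$am, ss)
  } else {
    result <- species_decontaminate(inp$am, catalog, inp$metadata)
  }
  write_matrix(result$matrix, file.path(config$outdir, "clean.tsv"))
  report <- list(level = result$level, per_sample = result$report,
                 removed = result$removed)
  write_report(report, file.path(config$outdir, "report.json"))
  manifest <- write_manifest(config, c("clean.tsv", "report.json"),
                             config$outdir)
  invisible(list(result = result, report = report, manifest = manifest))
}

load_comparisons <- function(config, inp) {
  if (!is.null(config$comparisons)) {
    return(read_comparisons(config$comparisons))
  }
  abort_if(is.null(config$pileup),
           "strain mode needs a comparisons or pileup path")
  pileup <- read_pileup(config$pileup, inp$annotations)
  profiles <- pileup_profiles(pileup, inp$annotations,
                              min_cov = config$min_cov)
  compare_strains_table(profiles)
}

#' Estimate contamination against an external negativeome catalog
#'
#' Uses the configured catalog membership table (TSV: votu_id, study,
#' nc_ids) in leave-one-study-out scope and writes estimates.tsv.
#'
#' @param config A `run_config`.
#' @return Invisibly, list(estimates, manifest).
#' @export
run_estimate <- function(config) {
  inp <- load_rpkm_inputs(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  catalog <- if (!is.null(config$catalog_meta)) {
    entries <- read_tsv_checked(config$catalog_meta,
                                c("votu_id", "study", "nc_ids"), "catalog")
    structure(list(entries = entries, overlap = table(integer(0)),
                   sequences = NULL), class = "negativeome")
  } else {
    build_negativeome(inp$am, inp$metadata)
  }
  estimates <- estimate_by_votu_sharing(inp$am, catalog, inp$metadata)
  utils::write.table(estimates, file.path(config$outdir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- write_manifest(config, "estimates.tsv", config$outdir)
  invisible(list(estimates = estimates, manifest = manifest))
}

#' Run characterize, decontaminate and estimate in sequence
#' @param config A `run_config`.
#' @return Invisibly, list of the three stage results.
#' @export
run_all <- function(config) {
  invisible(list(characterize = run_characterize(config),
                 decontaminate = run_decontaminate(config),
                 estimate = run_estimate(config)))
}

CMP_COLS <- c("votu_id", "sample_a", "sample_b", "compared_positions",
              "popani_diff_count", "conani_diff_count", "popani", "conani",
              "fraction_compared")

#' Read a strain-comparison table (TSV)
#' @param path Path to a comparisons TSV.
#' @return Data.frame of strain comparisons.
#' @export
read_comparisons <- function(path) {
  df <- read_tsv_checked(path, CMP_COLS, "comparisons")
  for (col in CMP_COLS[4:9]) df[[col]] <- num_or_na(df[[col]], col)
  df
}

#' Write a strain-comparison table (TSV)
#' @param df Data.frame of strain comparisons.
#' @param path Output path.
#' @export
write_comparisons <- function(df, path) {
  utils::write.table(df[CMP_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset as fixture files
#'
#' Emits genomes.fa, counts.tsv, breadth.tsv, meta.tsv, votus.tsv,
#' pileup.tsv and truth.json into a directory.
#'
#' @param sim A `virome_sim`.
#' @param outdir Output directory (created if needed).
#' @param pileup Whether to materialize pileup.tsv (can be large).
#' @return Invisibly, the output directory.
#' @export
write_sim_fixtures <- function(sim, outdir, pileup = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genomes, file.path(outdir, "genomes.fa"))
  write_matrix(sim$counts$counts, file.path(outdir, "counts.tsv"))
  write_matrix(sim$counts$breadth, file.path(outdir, "breadth.tsv"))
  write_metadata(sim$metadata, file.path(outdir, "meta.tsv"))
  write_annotations(sim$annotations, file.path(outdir, "votus.tsv"))
  if (pileup) {
    write_pileup(simulate_pileups(sim), file.path(outdir, "pileup.tsv"))
  }
  write_report(list(truth = sim$truth, config = unclass(sim$config)),
               file.path(outdir, "truth.json"))
  invisible(outdir)
}

# ---- In-memory composition helpers (simulated or pre-loaded data) ----

#' QC-filtered RPKM table from a simulated dataset
#'
#' Applies the breadth filter, RPKM transform and vOTU QC filters to the
#' simulator's count matrix.
#'
#' @param sim A `virome_sim`.
#' @param breadth_min,min_length Filter thresholds.
#' @return An `abundance_matrix`.
#' @export
sim_rpkm <- function(sim, breadth_min = 0.75, min_length = 1000) {
  cm <- breadth_filter(sim$counts, min_breadth = breadth_min)
  am <- to_rpkm(cm, sim$annotations, sim$metadata)
  qc_filter_votus(am, sim$annotations, min_length = min_length)
}

#' Sample-vs-NC strain comparisons for a simulated dataset
#'
#' Builds allele profiles only for the cells involved in own-study
#' vOTU sharing (each sharing sample and its NCs) and compares every
#' (sample, NC) pair on the shared vOTU.
#'
#' @param sim A `virome_sim`.
#' @param am QC-filtered `abundance_matrix` (default: [sim_rpkm()]).
#' @return Data.frame of strain comparisons.
#' @export
sim_nc_comparisons <- function(sim, am = NULL) {
  am <- am %||% sim_rpkm(sim)
  catalog <- build_negativeome(am, sim$metadata)
  vs <- votu_sharing(am, catalog, sim$metadata, scope = "own_study")
  rec <- vs$records
  if (nrow(rec) == 0) {
    return(compare_strains_table(list()))
  }
  pairs <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    ncs <- split_ids(rec$nc_ids[i])
    data.frame(votu_id = rec$votu_id[i], sample_a = rec$sample_id[i],
               sample_b = ncs, stringsAsFactors = FALSE)
  }))
  need <- unique(rbind(
    data.frame(sample_id = pairs$sample_a, votu_id = pairs$votu_id,
               stringsAsFactors = FALSE),
    data.frame(sample_id = pairs$sample_b, votu_id = pairs$votu_id,
               stringsAsFactors = FALSE)))
  key <- paste(sim$truth$sample_id, sim$truth$votu_id)
  cells <- sim$truth[key %in% paste(need$sample_id, need$votu_id), ]
  profiles <- simulate_profiles(sim, cells)
  compare_strains_table(profiles, pairs = pairs)
}
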