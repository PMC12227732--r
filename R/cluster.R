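# Species-level vOTU dereplication: pairwise ANI / alignment fraction from
# local alignments, greedy clustering at the MIUViG cut-offs (95% ANI over
# 85% alignment fraction of the shorter sequence), and mapping of query
# contigs onto an existing catalog.

#' Locally align two contig sequences on both strands
#'
#' Smith-Waterman local alignment of `seq_a` against `seq_b` and against its
#' reverse complement; the best alignment per strand with a positive score is
#' reported. Coordinates are 1-based inclusive on the original (plus-strand)
#' sequences; minus-strand hits have `tstart > tend` (the standard tabular
#' convention).
#'
#' @param seq_a,seq_b Uppercase A/C/G/T/N sequences.
#' @param a_id,b_id Ids used in the returned records.
#' @return Data.frame of alignment records (possibly 0 rows) with columns
#'   query_id, target_id, pct_identity, aln_length, mismatches, gapopens,
#'   qstart, qend, tstart, tend, evalue, bitscore, strand.
#' @export
align_pair <- function(seq_a, seq_b, a_id = "a", b_id = "b") {
  abort_if(!nzchar(seq_a) || !nzchar(seq_b), "cannot align empty sequence")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  one_strand <- function(subject, strand) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(seq_a),
      subject = Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    if (Biostrings::score(aln) <= 0) return(NULL)
    p <- aln@pattern
    s <- aln@subject
    aln_length <- nchar(as.character(Biostrings::alignedPattern(aln)))
    nmis <- Biostrings::nmismatch(aln)
    gaps <- Biostrings::nindel(aln)
    gapopens <- sum(gaps@insertion[, 1]) + sum(gaps@deletion[, 1])
    ts <- Biostrings::start(s); te <- Biostrings::end(s)
    if (strand == "-") {
      # report plus-strand coordinates on the original target, reversed
      L <- nchar(seq_b)
      tmp <- c(L - ts + 1L, L - te + 1L)
      ts <- tmp[1]; te <- tmp[2]           # ts > te flags minus strand
    }
    data.frame(query_id = a_id, target_id = b_id,
               pct_identity = 100 * (1 - nmis / aln_length),
               aln_length = aln_length, mismatches = nmis,
               gapopens = gapopens,
               qstart = Biostrings::start(p), qend = Biostrings::end(p),
               tstart = ts, tend = te,
               evalue = 0, bitscore = Biostrings::score(aln),
               strand = strand, stringsAsFactors = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_b)))
  out <- rbind(one_strand(seq_b, "+"), one_strand(rc, "-"))
  if (is.null(out)) {
    out <- data.frame(query_id = character(0), target_id = character(0),
                      pct_identity = numeric(0), aln_length = numeric(0),
                      mismatches = numeric(0), gapopens = numeric(0),
                      qstart = numeric(0), qend = numeric(0),
                      tstart = numeric(0), tend = numeric(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  }
  # keep the stronger strand first so downstream "best record" picks are
  # deterministic
  out[order(-out$bitscore, out$strand), , drop = FALSE]
}

merge_interval_length <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e + 1) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s + 1)
}

#' Compute ANI and alignment fraction for one contig pair
#'
#' ANI is the alignment-length-weighted mean of per-record percent identity.
#' The alignment fraction is taken relative to the shorter sequence: aligned
#' intervals are projected onto it, overlapping intervals merged, and the
#' union length divided by the shorter length.
#'
#' @param records Alignment records for a single (a, b) pair, as returned by
#'   [align_pair()] or [read_alignments()].
#' @param len_a,len_b Full lengths of the two sequences.
#' @param a_id,b_id Ids recorded in the result (defaults taken from records).
#' @return One-row data.frame (an AniPair): a_id, b_id, ani, af_shorter.
#' @export
compute_ani <- function(records, len_a, len_b, a_id = NULL, b_id = NULL) {
  a_id <- a_id %||% (if (nrow(records) > 0) records$query_id[1] else "a")
  b_id <- b_id %||% (if (nrow(records) > 0) records$target_id[1] else "b")
  if (nrow(records) == 0) {
    return(data.frame(a_id = a_id, b_id = b_id, ani = 0, af_shorter = 0,
                      stringsAsFactors = FALSE))
  }
  abort_if(length(unique(records$query_id)) > 1 ||
             length(unique(records$target_id)) > 1,
           "compute_ani expects records for a single sequence pair")
  ani <- sum(records$pct_identity * records$aln_length) /
    sum(records$aln_length)
  if (len_a <= len_b) {
    starts <- pmin(records$qstart, records$qend)
    ends <- pmax(records$qstart, records$qend)
    shorter <- len_a
  } else {
    starts <- pmin(records$tstart, records$tend)
    ends <- pmax(records$tstart, records$tend)
    shorter <- len_b
  }
  af <- 100 * merge_interval_length(starts, ends) / shorter
  data.frame(a_id = a_id, b_id = b_id, ani = ani,
             af_shorter = min(af, 100), stringsAsFactors = FALSE)
}

#' All-vs-all ANI table for a set of sequences
#'
#' Convenience wrapper running [align_pair()] + [compute_ani()] over every
#' unordered pair.
#'
#' @param seqs Named character vector of sequences.
#' @return Data.frame of AniPairs (a_id, b_id, ani, af_shorter).
#' @export
ani_table <- function(seqs) {
  ids <- names(seqs)
  abort_if(is.null(ids), "sequences must be named")
  out <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq((i + 1), length(ids))) {
        rec <- align_pair(seqs[[i]], seqs[[j]], ids[i], ids[j])
        out[[length(out) + 1L]] <- compute_ani(
          rec, nchar(seqs[[i]]), nchar(seqs[[j]]), ids[i], ids[j])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(a_id = character(0), b_id = character(0),
                      ani = numeric(0), af_shorter = numeric(0)))
  }
  do.call(rbind, out)
}

ani_lookup <- function(ani_pairs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  env <- new.env(hash = TRUE, parent = emptyenv())
  k <- key(ani_pairs$a_id, ani_pairs$b_id)
  for (i in seq_len(nrow(ani_pairs))) {
    assign(k[i], c(ani = ani_pairs$ani[i], af = ani_pairs$af_shorter[i]),
           envir = env)
  }
  function(a, b) {
    v <- mget(paste(min(a, b), max(a, b), sep = "\r"), envir = env,
              ifnotfound = list(NULL))[[1]]
    v %||% c(ani = 0, af = 0)
  }
}

#' Greedily dereplicate contigs into species-level vOTUs
#'
#' Contigs are sorted by length descending (ties broken by id ascending) and
#' scanned in order; a contig joins the first existing representative it
#' matches at `ani >= ani_min` and `af_shorter >= af_min` (both inclusive),
#' otherwise it seeds a new cluster. Representatives are therefore always the
#' longest member of their cluster.
#'
#' @param ani_pairs Data.frame of AniPairs (a_id, b_id, ani, af_shorter).
#' @param lengths Named numeric vector of contig lengths (every contig).
#' @param ani_min,af_min Inclusive thresholds; defaults 95 and 85.
#' @return A `votu_clustering`: list with `clusters` (named list
#'   representative -> member ids) and `membership` (named character vector
#'   contig -> representative).
#' @export
greedy_cluster <- function(ani_pairs, lengths, ani_min = 95, af_min = 85) {
  ids <- names(lengths)
  abort_if(is.null(ids), "lengths must be a named vector")
  in_pairs <- unique(c(ani_pairs$a_id, ani_pairs$b_id))
  missing <- setdiff(in_pairs, ids)
  abort_if(length(missing) > 0,
           "contig in ani_pairs but absent from lengths: ", missing[1])
  ord <- ids[order(-lengths, ids)]
  look <- ani_lookup(ani_pairs)
  reps <- character(0)
  membership <- stats::setNames(character(length(ids)), ord)
  for (contig in ord) {
    assigned <- NA_character_
    for (rep in reps) {
      v <- look(contig, rep)
      if (v[["ani"]] >= ani_min && v[["af"]] >= af_min) {
        assigned <- rep
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, contig)
      assigned <- contig
    }
    membership[contig] <- assigned
  }
  clusters <- split(names(membership), membership)[reps]
  structure(list(clusters = clusters, membership = membership,
                 ani_min = ani_min, af_min = af_min),
            class = "votu_clustering")
}

#' @export
print.votu_clustering <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("vOTU clustering: ", length(x$membership), " contigs in ",
      length(x$clusters), " clusters (ANI >= ", x$ani_min,
      ", AF >= ", x$af_min, ")\n", sep = "")
  cat("cluster sizes: ", paste(sort(sizes, decreasing = TRUE),
                               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Map query contigs onto an existing vOTU catalog
#'
#' Each query is aligned against every catalog sequence; among catalog hits
#' meeting both thresholds the best alignment fraction wins, ties broken by
#' higher ANI, then lexicographically smaller catalog id. Queries with no
#' qualifying hit are unassigned (NA).
#'
#' @param query_seqs,catalog_seqs Named character vectors of sequences.
#' @param ani_min,af_min Inclusive thresholds; defaults 95 and 85.
#' @return Named character vector query -> catalog id (NA when unassigned).
#' @export
map_to_catalog <- function(query_seqs, catalog_seqs, ani_min = 95,
                           af_min = 85) {
  abort_if(length(catalog_seqs) == 0, "catalog must be non-empty")
  out <- stats::setNames(rep(NA_character_, length(query_seqs)),
                         names(query_seqs))
  cat_ids <- sort(names(catalog_seqs))
  for (q in names(query_seqs)) {
    best <- NULL
    for (cid in cat_ids) {
      rec <- align_pair(query_seqs[[q]], catalog_seqs[[cid]], q, cid)
      pair <- compute_ani(rec, nchar(query_seqs[[q]]),
                          nchar(catalog_seqs[[cid]]), q, cid)
      if (pair$ani >= ani_min && pair$af_shorter >= af_min) {
        if (is.null(best) ||
            pair$af_shorter > best$af_shorter ||
            (pair$af_shorter == best$af_shorter && pair$ani > best$ani)) {
          best <- pair
        }
      }
    }
    if (!is.null(best)) out[q] <- best$b_id
  }
  out
}
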