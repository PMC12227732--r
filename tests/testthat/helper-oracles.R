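# Independent oracles and fixture builders used across the suite.
# Each oracle is deliberately coded as simple brute force, on a different
# representation than the implementation it checks.

ORACLE_BASES <- c("A", "C", "G", "T")

# --- greedy clustering oracle: plain data.frame scan, no lookup tables ---
oracle_greedy_cluster <- function(ani_pairs, lengths, ani_min = 95,
                                  af_min = 85) {
  ids <- names(lengths)[order(-lengths, names(lengths))]
  find_pair <- function(a, b) {
    hit <- (ani_pairs$a_id == a & ani_pairs$b_id == b) |
      (ani_pairs$a_id == b & ani_pairs$b_id == a)
    if (!any(hit)) return(c(0, 0))
    c(ani_pairs$ani[hit][1], ani_pairs$af_shorter[hit][1])
  }
  reps <- character(0)
  membership <- character(0)
  for (id in ids) {
    joined <- NA_character_
    for (r in reps) {
      v <- find_pair(id, r)
      if (v[1] >= ani_min && v[2] >= af_min) { joined <- r; break }
    }
    if (is.na(joined)) { reps <- c(reps, id); joined <- id }
    membership[id] <- joined
  }
  membership
}

# --- popANI oracle: position-by-position scan over allele-set lists ---
# profiles given as list(pos = covered positions, alleles = list of
# character vectors, consensus = character vector)
oracle_compare <- function(raw_a, raw_b, L) {
  occ <- function(raw) {
    m <- matrix(FALSE, nrow = L, ncol = 4, dimnames = list(NULL,
                                                           ORACLE_BASES))
    for (i in seq_along(raw$pos)) m[raw$pos[i], raw$alleles[[i]]] <- TRUE
    m
  }
  ma <- occ(raw_a); mb <- occ(raw_b)
  cov_a <- rowSums(ma) > 0; cov_b <- rowSums(mb) > 0
  compared <- which(cov_a & cov_b)
  cons_a <- rep(NA_character_, L); cons_a[raw_a$pos] <- raw_a$consensus
  cons_b <- rep(NA_character_, L); cons_b[raw_b$pos] <- raw_b$consensus
  pop_d <- 0L; con_d <- 0L
  for (p in compared) {
    if (!any(ma[p, ] & mb[p, ])) pop_d <- pop_d + 1L
    if (cons_a[p] != cons_b[p]) con_d <- con_d + 1L
  }
  list(compared = length(compared), pop_d = pop_d, con_d = con_d)
}

# random raw profile + the corresponding allele_profile object
random_raw_profile <- function(votu, sample_id, L, cover_frac = 0.7,
                               multi_frac = 0.1) {
  n <- max(1L, round(cover_frac * L))
  pos <- sort(sample.int(L, n))
  n_alleles <- 1L + (stats::runif(n) < multi_frac)
  alleles <- lapply(n_alleles, function(k) sample(ORACLE_BASES, k))
  consensus <- vapply(alleles, function(a) a[sample.int(length(a), 1)], "")
  mask_of <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  raw <- list(pos = pos, alleles = alleles, consensus = consensus)
  prof <- allele_profile(
    votu, sample_id, L, pos,
    vapply(alleles, function(a) sum(mask_of[a]), 0L),
    unname(mask_of[consensus]))
  list(raw = raw, profile = prof)
}

# --- exhaustive local alignment (Smith-Waterman, linear gap) oracle ---
oracle_sw_identity <- function(a, b, match = 1, mismatch = -1, gap = -7) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  # track (matches, length) of the best path into each cell
  Mt <- matrix(0L, n + 1, m + 1); Ln <- matrix(0L, n + 1, m + 1)
  best <- c(score = 0, matches = 0L, len = 0L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- H[i, j] + if (A[i] == B[j]) match else mismatch
      del <- H[i, j + 1] + gap
      ins <- H[i + 1, j] + gap
      s <- max(0, sub, del, ins)
      H[i + 1, j + 1] <- s
      if (s == 0) next
      if (s == sub) {
        Mt[i + 1, j + 1] <- Mt[i, j] + (A[i] == B[j])
        Ln[i + 1, j + 1] <- Ln[i, j] + 1L
      } else if (s == del) {
        Mt[i + 1, j + 1] <- Mt[i, j + 1]
        Ln[i + 1, j + 1] <- Ln[i, j + 1] + 1L
      } else {
        Mt[i + 1, j + 1] <- Mt[i + 1, j]
        Ln[i + 1, j + 1] <- Ln[i + 1, j] + 1L
      }
      if (s > best[["score"]]) {
        best <- c(score = s, matches = Mt[i + 1, j + 1],
                  len = Ln[i + 1, j + 1])
      }
    }
  }
  if (best[["len"]] == 0) return(NA_real_)
  100 * best[["matches"]] / best[["len"]]
}

# --- Spearman via explicit ranking + Pearson ---
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# --- exact two-sided permutation p for the rank-sum statistic ---
exact_perm_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  expected <- nx * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(nx)]) - expected)
  combos <- utils::combn(length(pooled), nx)
  devs <- apply(combos, 2, function(idx) abs(sum(r[idx]) - expected))
  mean(devs >= obs)
}

# --- tiny metadata / annotation builders ---
make_meta <- function(samples, studies, roles) {
  data.frame(sample_id = samples, study = studies, role = roles,
             subject_id = ifelse(roles == "nc", "", paste0("subj_", samples)),
             group = ifelse(roles == "nc", "nc", "infant"),
             age_months = ifelse(roles == "nc", NA_real_, 6),
             nucleic_acid = "DNA", stringsAsFactors = FALSE)
}

make_annot <- function(votus, lengths, viral = NULL, host = NULL,
                       plasmid = NULL) {
  data.frame(votu_id = votus, length_bp = as.integer(lengths),
             viral_gene_count = as.integer(viral %||% rep(2, length(votus))),
             host_gene_count = as.integer(host %||% rep(0, length(votus))),
             plasmid_flag = plasmid %||% rep(FALSE, length(votus)),
             completeness_pct = NA_real_, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(L) paste(sample(ORACLE_BASES, L, TRUE), collapse = "")

mutate_dna <- function(seq, n) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n)
  chars[pos] <- vapply(pos, function(p)
    sample(setdiff(ORACLE_BASES, chars[p]), 1), "")
  paste(chars, collapse = "")
}

# uniform full-coverage single-allele profile from a sequence string
profile_from_seq <- function(votu, sample_id, seq) {
  mask_of <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  chars <- strsplit(seq, "")[[1]]
  m <- unname(mask_of[chars])
  allele_profile(votu, sample_id, length(chars), seq_along(chars), m, m)
}
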