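# Independent brute-force oracles. Each recomputes its quantity by explicit
# enumeration or straight-line looping, sharing no code path with the
# package implementation it checks.

# Shared bases by enumerating covered integer positions.
oracle_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1)))
}

# Both overlap fractions computed explicitly (enumeration-based; use only on
# short toy chromosomes).
oracle_ro <- function(a, b) {
  ov <- oracle_overlap(a, b)
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}

# Arithmetic variants for oracles that run over megabase-scale intervals,
# where position enumeration is infeasible; still straight-line independent
# code.
oracle_overlap_arith <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  lo <- max(a$start, b$start)
  hi <- min(a$end, b$end)
  if (hi > lo) hi - lo else 0
}

oracle_ro_arith <- function(a, b) {
  ov <- oracle_overlap_arith(a, b)
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}

# Transitive closure of pairwise adjacency via O(n^2) union-find.
oracle_merge <- function(calls, max_gap, same_type = TRUE) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (calls$sample_id[i] != calls$sample_id[j]) next
    if (calls$chrom[i] != calls$chrom[j]) next
    if (same_type && calls$cnv_type[i] != calls$cnv_type[j]) next
    gap <- max(calls$start[i], calls$start[j]) -
      min(calls$end[i], calls$end[j])
    if (gap <= max_gap) parent[find(i)] <- find(j)
  }
  root <- vapply(seq_len(n), find, integer(1L))
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(ix) {
    data.frame(sample_id = calls$sample_id[ix[1L]],
               chrom = calls$chrom[ix[1L]],
               start = min(calls$start[ix]), end = max(calls$end[ix]),
               cnv_type = if (same_type) calls$cnv_type[ix[1L]] else NA,
               stringsAsFactors = FALSE)
  }))
  out[order(out$sample_id, out$chrom, out$start, out$end), , drop = FALSE]
}

# Cytoband by linear scan.
oracle_band <- function(chrom, pos, bands) {
  for (i in seq_len(nrow(bands))) {
    if (bands$chrom[i] == chrom && bands$start[i] <= pos &&
          pos < bands$end[i]) {
      return(bands$band[i])
    }
  }
  NA_character_
}

# Straight-line rule-by-rule recomputation of the classification points for
# one annotated CNV.
oracle_score <- function(call, genes_full, genes_partial, curation,
                         controls, manual = NULL,
                         pts = c(L1 = 1.0, G1 = 1.0, L2 = 0.30, P1 = 0.90,
                                 F1 = 0.15, F2 = -1.0, N1 = -0.60),
                         ro_thr = 0.5, max_freq = 0.001) {
  flag <- function(sym, col) {
    i <- match(sym, curation$symbol)
    v <- if (is.na(i)) NA else curation[[col]][i]
    !is.na(v) && v
  }
  known <- function(sym) {
    i <- match(sym, curation$symbol)
    !is.na(i) && curation$known_chd[i]
  }
  total <- 0
  is_del <- call$cnv_type == "deletion"
  dosage_full <- if (is_del) {
    Filter(function(s) known(s) && flag(s, "haploinsufficient"), genes_full)
  } else {
    Filter(function(s) flag(s, "triplosensitive"), genes_full)
  }
  dosage_part <- if (is_del) {
    Filter(function(s) flag(s, "haploinsufficient"), genes_partial)
  } else character(0L)
  if (length(dosage_full) > 0) {
    total <- total + pts[[if (is_del) "L1" else "G1"]]
  } else if (length(dosage_part) > 0) {
    total <- total + pts[["P1"]]
  }
  dosage_col <- if (is_del) "haploinsufficient" else "triplosensitive"
  nd <- Filter(function(s) known(s) && !flag(s, dosage_col),
               c(genes_full, genes_partial))
  nd <- setdiff(nd, c(dosage_full, dosage_part))
  if (length(nd) > 0) total <- total + pts[["L2"]]
  if (length(genes_full) + length(genes_partial) == 0) {
    total <- total + pts[["N1"]]
  }
  common <- FALSE; present <- FALSE
  if (!is.null(controls) && nrow(controls) > 0) {
    for (i in seq_len(nrow(controls))) {
      if (controls$chrom[i] != call$chrom) next
      if (controls$cnv_type[i] != call$cnv_type) next
      ro <- oracle_ro_arith(call, controls[i, ])
      if (ro >= ro_thr && controls$frequency[i] > max_freq) common <- TRUE
      if (ro >= ro_thr && controls$frequency[i] > 0) present <- TRUE
    }
  }
  if (common) total <- total + pts[["F2"]]
  else if (!present) total <- total + pts[["F1"]]
  if (!is.null(manual) && nrow(manual) > 0) {
    for (i in seq_len(nrow(manual))) {
      if (manual$sample_id[i] != call$sample_id) next
      if (manual$chrom[i] != call$chrom) next
      if (manual$cnv_type[i] != call$cnv_type) next
      if (oracle_ro_arith(call, manual[i, ]) >= ro_thr) {
        total <- total + manual$points[i]
      }
    }
  }
  total
}

# Random interval on a toy chromosome of the given length.
random_interval <- function(chrom = "T", max_len = 10000) {
  s <- sample.int(max_len - 1L, 1L) - 1L
  e <- s + sample.int(max_len - s, 1L)
  data.frame(chrom = chrom, start = s, end = e, stringsAsFactors = FALSE)
}

# Random CNV call set for merge/filter property tests.
random_calls <- function(n, samples = c("A", "B"), chroms = c("1", "2"),
                         max_pos = 1e6) {
  start <- sample.int(max_pos, n)
  size <- sample.int(5e4, n)
  type <- sample(c("deletion", "duplication"), n, replace = TRUE)
  cnv_calls(sample(samples, n, replace = TRUE),
            sample(chroms, n, replace = TRUE),
            start, start + size,
            copy_number = ifelse(type == "deletion", 1, 3),
            cnv_type = type)
}
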