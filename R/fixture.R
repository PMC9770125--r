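# Deterministic cohort fixture encoding the study conditions: 90 enrolled
# cases (50 female / 40 male; predominantly Cape mixed ancestry; TOF the
# most frequent diagnosis), one 47,XXY sample, the thirteen described CNVs
# of interest at band-consistent toy loci, gene-desert decoy CNVs that pass
# the size/rarity funnel without hitting a qualifying gene, a benign
# polymorphic background shared with the control table, and sub-100 kb
# nuisance calls. Entirely synthetic and entirely deterministic: no RNG is
# used, so repeated calls are identical.

fixture_metadata <- function() {
  ids <- sprintf("P%03d", 1:90)
  # 50 females, 40 males, with two swaps so the XXY case (P020) and the
  # proband carrying the 11q12.3 deletion (P011) are male.
  sex <- c(rep("female", 50), rep("male", 40))
  sex[c(11, 20)] <- "male"
  sex[c(51, 52) ] <- "female"
  ancestry <- c(rep("cape_mixed", 59), rep("black_african", 28),
                rep("european", 3))
  diag <- rep("other", 90)
  diag[c(12, 20, 21:31)] <- "TOF"                 # 13
  diag[c(13, 16, 32:40)] <- "VSD"                 # 11
  diag[c(19, 41:49)] <- "PDA"                     # 10
  diag[50:57] <- "pulmonary_atresia"              # 8
  diag[c(10, 15, 18, 58:63)] <- "ASD"             # 9
  diag[c(14, 64:68)] <- "AVSD"                    # 6
  diag[c(11, 69, 70)] <- "PAPVC"                  # 3
  diag[c(17, 71:74)] <- "DORV"                    # 5
  diag[75:81] <- "coarctation"                    # 7
  diag[82:87] <- "TGA"                            # 6
  # 88:90 plus any untouched slots stay "other"
  eca <- rep(FALSE, 90)
  eca[c(10, 11, 16, 60:74)] <- TRUE               # 18 with extracardiac anomalies
  data.frame(sample_id = ids, sex = sex, ancestry = ancestry,
             primary_diagnosis = diag, extracardiac_anomalies = eca,
             qc_pass = TRUE, stringsAsFactors = FALSE)
}

fixture_profiles <- function(metadata) {
  p <- data.frame(
    sample_id = metadata$sample_id,
    mean_cn_x = ifelse(metadata$sex == "female", 2, 1),
    mean_cn_y = ifelse(metadata$sex == "female", 0, 1),
    stringsAsFactors = FALSE
  )
  p$mean_cn_x[p$sample_id == "P020"] <- 2.02  # the 47,XXY case
  p$mean_cn_y[p$sample_id == "P020"] <- 0.98
  p
}

# Benign polymorphic regions; carrier frequencies are all far above the
# 0.1% rarity cutoff so background calls are unambiguously non-rare.
fixture_controls <- function() {
  x <- data.frame(
    chrom = c("1", "1", "1", "1", "2", "2", "2", "2", "3", "3", "5", "5",
              "6", "6", "8", "8", "11", "11", "15", "15", "22", "22"),
    start = c(30, 34, 38, 42, 30, 33, 36, 39, 30, 33, 13, 16, 24, 27, 16,
              21, 22, 24, 11, 16, 8.2, 10.2) * 1e6,
    end = c(33, 37, 41, 44, 32.5, 35.5, 38.5, 41.5, 32, 35, 15, 18, 26,
            29, 17, 22, 23, 25, 12, 17, 8.7, 10.7) * 1e6,
    cnv_type = rep(c("deletion", "duplication"), 11),
    stringsAsFactors = FALSE
  )
  freq <- c(0.08, 0.05, 0.02, 0.12, 0.03, 0.07, 0.15, 0.01, 0.06, 0.04,
            0.09, 0.02, 0.05, 0.11, 0.04, 0.08, 0.02, 0.06, 0.07, 0.03,
            0.05, 0.02)
  x$carrier_count <- as.integer(round(freq * 10000))
  x$cohort_size <- 10000L
  x$frequency <- x$carrier_count / x$cohort_size
  x
}

# The thirteen described CNVs of interest: eight hitting known disease genes
# (the 5q35.3 duplication split over two adjacent segments that merge into
# one event) and five hitting candidate genes.
fixture_spikes <- function() {
  x <- data.frame(
    sample_id = c("P010", "P011", "P012", "P012", "P012", "P013", "P014",
                  "P014", "P015", "P016", "P017", "P018", "P019"),
    chrom = c("8", "11", "22", "22", "22", "22", "5", "5", "5", "3", "6",
              "11", "15"),
    start = c(2.50e6, 13.80e6, 2.80e6, 3.38e6, 4.50e6, 4.40e6, 30.80e6,
              32.52e6, 30.90e6, 19.50e6, 4.80e6, 17.80e6, 2.80e6),
    end = c(3.60e6, 14.30e6, 3.30e6, 3.60e6, 4.80e6, 4.90e6, 32.50e6,
            33.10e6, 31.30e6, 23.00e6, 5.50e6, 18.40e6, 3.30e6),
    cnv_type = c("deletion", "deletion", "deletion", "deletion", "deletion",
                 "deletion", "duplication", "duplication", "duplication",
                 "duplication", "duplication", "duplication", "deletion"),
    locus_gene = c("GATA4", "B3GAT3", "TBX1", "DGCR8", "CRKL", "CRKL",
                   "FLT4", "NSD1(partial)", "FLT4", "FSTL1", "JARID2",
                   "KDM2A", "CYFIP1"),
    stringsAsFactors = FALSE
  )
  x
}

# Gene-desert decoys: large, rare, but hitting no gene, so they survive the
# funnel without becoming CNVs of interest. One 100 kb call sits exactly on
# the size boundary and one spans 6.1 Mb.
fixture_decoys <- function() {
  idx <- 1:24
  chrom <- ifelse(idx %% 2L == 1L, "1", "2")
  pos <- (idx + 1L) %/% 2L                       # 1..12 slot per chromosome
  start <- 1e6 + (pos - 1) * 1.9e6
  size <- 1e5 + ((idx - 1L) %% 6L) * 2.5e5       # 100 kb .. 1.35 Mb
  size[7L] <- 6.1e6                               # largest retained CNV
  type <- ifelse(idx %% 4L %in% c(1L, 2L), "deletion", "duplication")
  data.frame(sample_id = sprintf("P%03d", 20L + idx), chrom = chrom,
             start = start, end = start + size, cnv_type = type,
             stringsAsFactors = FALSE)
}

#' Build the deterministic cohort fixture
#'
#' Returns the complete input bundle for a pipeline run emulating the study
#' conditions: toy genome, raw CNV calls (benign background at control
#' frequencies, sub-100 kb nuisance calls, 24 gene-desert decoys, and the 13
#' described CNVs of interest), metadata for 90 samples, sex-chromosome
#' profiles with one 47,XXY case, the control frequency table, and the
#' manual points adjustments encoding expert literature/database review for
#' the three events whose tier depends on it. Construction uses no RNG;
#' repeated calls are byte-identical.
#'
#' @return \code{list(genome, calls, metadata, profiles, controls,
#'   manual_adjustments, spikes)}; \code{spikes} records the intended locus
#'   gene of each described CNV.
#' @export
make_paper_fixture <- function() {
  genome <- generate_genome()
  metadata <- fixture_metadata()
  profiles <- fixture_profiles(metadata)
  controls <- fixture_controls()
  spikes <- fixture_spikes()
  decoys <- fixture_decoys()

  pieces <- list()
  # benign background: region r is carried by samples at a deterministic
  # stride matching its control frequency
  for (r in seq_len(nrow(controls))) {
    period <- max(1L, as.integer(round(1 / controls$frequency[r])))
    hit <- which((seq_len(nrow(metadata)) + 3L * r) %% period == 0L)
    if (length(hit) > 0L) {
      b <- region_call(metadata$sample_id[hit], controls$chrom[r],
                       controls$start[r], controls$end[r],
                       controls$cnv_type[r])
      b$origin <- "benign"
      pieces[[length(pieces) + 1L]] <- b
    }
  }
  # nuisance calls under the size threshold
  nz_idx <- 1:30
  nz <- region_call(sprintf("P%03d", nz_idx), "1",
                    5e6 + (nz_idx - 1L) * 1.2e5,
                    5e6 + (nz_idx - 1L) * 1.2e5 + 5e4 + nz_idx * 1e3,
                    ifelse(nz_idx %% 2L == 0L, "deletion", "duplication"))
  nz$origin <- "nuisance"
  pieces[[length(pieces) + 1L]] <- nz
  d <- region_call(decoys$sample_id, decoys$chrom, decoys$start, decoys$end,
                   decoys$cnv_type)
  d$origin <- "decoy"
  pieces[[length(pieces) + 1L]] <- d
  s <- region_call(spikes$sample_id, spikes$chrom, spikes$start, spikes$end,
                   spikes$cnv_type)
  s$origin <- "spike"
  pieces[[length(pieces) + 1L]] <- s
  calls <- do.call(rbind, pieces)
  rownames(calls) <- NULL

  manual <- data.frame(
    sample_id = c("P012", "P013", "P014"),
    chrom = c("22", "22", "5"),
    start = c(4.50e6, 4.40e6, 30.80e6),
    end = c(4.80e6, 4.90e6, 33.10e6),
    cnv_type = c("deletion", "deletion", "duplication"),
    points = c(0.54, 0.45, 0.45),
    note = c(
      "recurrent 22q11.2 disease-region deletion; similar pathogenic CNVs reported",
      "CRKL-encompassing deletions reported in conotruncal defects",
      "similar 5q35 gains reported in structural heart disease"),
    stringsAsFactors = FALSE
  )
  list(genome = genome, calls = calls, metadata = metadata,
       profiles = profiles, controls = controls,
       manual_adjustments = manual, spikes = spikes)
}
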