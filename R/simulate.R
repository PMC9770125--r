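# Synthetic-data module: toy genomes, benign polymorphic CNV backgrounds,
# control cohorts, spiked case cohorts, sex-chromosome profiles, and a
# deterministic fixture that encodes the study conditions of a 90-patient
# nonsyndromic congenital heart disease cohort (one 47,XXY sample, 13
# described CNVs of interest at their loci, cohort demographics), so the
# whole analysis is testable without any download.
#
# All coordinates live on a toy genome (nine autosomes of 12-50 Mb plus X
# and Y) with the eleven genes of interest placed at band-consistent toy
# positions. Gene placements and curation flags are synthetic; the flags
# encode the narrative roles (six known disease genes, five
# candidate-qualifying genes), not real database records.

toy_chromosomes <- function() {
  data.frame(
    chrom = c("1", "2", "3", "5", "6", "8", "11", "15", "22", "X", "Y"),
    length = c(50e6, 45e6, 40e6, 36e6, 34e6, 30e6, 28e6, 20e6, 12e6,
               31e6, 11e6),
    stringsAsFactors = FALSE
  )
}

toy_bands <- function() {
  mk <- function(chrom, bounds, labels) {
    data.frame(chrom = chrom, start = bounds[-length(bounds)],
               end = bounds[-1L], band = labels, stringsAsFactors = FALSE)
  }
  b <- rbind(
    mk("1", c(0, 10, 20, 25, 32, 40, 50) * 1e6,
       c("p36", "p22", "p11", "q11", "q21", "q42")),
    mk("2", c(0, 9, 18, 22, 30, 37, 45) * 1e6,
       c("p25", "p16", "p11", "q11", "q22", "q33")),
    mk("3", c(0, 8, 12, 16, 22, 28, 40) * 1e6,
       c("p21", "p11", "q11", "q13.33", "q21.2", "q26")),
    mk("5", c(0, 6, 12, 18, 26, 30, 36) * 1e6,
       c("p15", "p13", "q11", "q23", "q35.1", "q35.3")),
    mk("6", c(0, 4, 9, 14, 22, 34) * 1e6,
       c("p24", "p22.3", "p21", "q11", "q22")),
    mk("8", c(0, 2, 7, 12, 15, 20, 25, 30) * 1e6,
       c("p23.3", "p23.1", "p22", "p11", "q11", "q21", "q24")),
    mk("11", c(0, 5, 10, 13, 17, 21, 28) * 1e6,
       c("p15", "p11", "q11", "q12.3", "q13.2", "q23")),
    mk("15", c(0, 2, 6, 10, 15, 20) * 1e6,
       c("p11", "q11.2", "q13", "q21", "q26")),
    mk("22", c(0, 1, 2.5, 6, 8, 10, 12) * 1e6,
       c("p11", "q11.1", "q11.21", "q11.23", "q12", "q13")),
    mk("X", c(0, 10, 15, 20, 31) * 1e6, c("p22", "p11", "q11", "q21")),
    mk("Y", c(0, 3, 11) * 1e6, c("p11", "q11"))
  )
  cytoband_map(b$chrom, b$start, b$end, b$band)
}

toy_gene_models <- function() {
  data.frame(
    symbol = c("GATA4", "B3GAT3", "TBX1", "DGCR8", "CRKL", "FLT4", "NSD1",
               "FSTL1", "JARID2", "KDM2A", "CYFIP1"),
    chrom = c("8", "11", "22", "22", "22", "5", "5", "3", "6", "11", "15"),
    start = c(3.0e6, 14.0e6, 3.0e6, 3.40e6, 4.60e6, 31.0e6, 33.0e6,
              20.0e6, 5.0e6, 18.0e6, 3.0e6),
    end = c(3.055e6, 14.05e6, 3.03e6, 3.435e6, 4.64e6, 31.1e6, 33.2e6,
            20.06e6, 5.3e6, 18.1e6, 3.11e6),
    strand = c("+", "+", "+", "+", "+", "-", "+", "-", "+", "+", "+"),
    stringsAsFactors = FALSE
  )
}

# Synthetic curation flags encoding the narrative roles: six known disease
# genes; five candidate-qualifying genes (pLI >= 0.9, murine heart
# expression, mouse cardiac/embryonic phenotype). pLI values are synthetic
# placeholders on the right side of the 0.9 threshold, not database lookups.
toy_gene_curation <- function() {
  data.frame(
    symbol = c("GATA4", "B3GAT3", "TBX1", "DGCR8", "CRKL", "FLT4", "NSD1",
               "FSTL1", "JARID2", "KDM2A", "CYFIP1"),
    known_chd = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                  FALSE, FALSE, FALSE, FALSE),
    haploinsufficient = c(TRUE, TRUE, TRUE, NA, FALSE, FALSE, TRUE,
                          NA, NA, NA, NA),
    triplosensitive = c(FALSE, FALSE, FALSE, NA, FALSE, FALSE, FALSE,
                        NA, NA, NA, NA),
    pli = c(0.92, 0.30, 0.55, 0.98, 0.77, 0.86, 1.00,
            0.91, 0.99, 1.00, 0.97),
    murine_heart_expression = c(TRUE, NA, TRUE, TRUE, TRUE, TRUE, NA,
                                TRUE, TRUE, TRUE, TRUE),
    mouse_cardiac_or_embryonic_phenotype = c(TRUE, NA, TRUE, TRUE, TRUE,
                                             TRUE, NA, TRUE, TRUE, TRUE,
                                             TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate the toy genome specification
#'
#' Deterministic: repeated calls return identical objects. The genome has
#' nine autosomes (12-50 Mb) plus X and Y, a cytoband map covering every
#' chromosome, eleven gene models at band-consistent positions and their
#' curation flags (six known disease genes; five candidate-qualifying
#' genes).
#'
#' @param include_genes if FALSE, the gene model and curation tables are
#'   empty (downstream annotation then yields empty gene lists).
#' @return \code{list(chromosomes, bands, models, curation)}.
#' @export
generate_genome <- function(include_genes = TRUE) {
  chroms <- toy_chromosomes()
  models <- if (include_genes) toy_gene_models() else
    toy_gene_models()[0L, , drop = FALSE]
  curation <- if (include_genes) toy_gene_curation() else
    toy_gene_curation()[0L, , drop = FALSE]
  len <- chroms$length[match(models$chrom, chroms$chrom)]
  if (any(is.na(len)) || any(models$end > len)) {
    stop("gene model exceeds chromosome length", call. = FALSE)
  }
  list(chromosomes = chroms, bands = toy_bands(), models = models,
       curation = curation)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 90 cases, a benign polymorphic CNV
#' background covering about 12\% of the (autosomal) genome with carrier
#' frequencies drawn log-uniformly in \code{[0.005, 0.2]} (decisively above
#' the 0.1\% rarity cutoff, so the truth labels are unambiguous), small
#' (<100 kb) nuisance calls, and rare spiked CNVs with known carriers.
#'
#' @param seed integer RNG seed; every random draw in [simulate_cohorts()]
#'   flows from it.
#' @param n_controls control cohort size used for carrier frequencies.
#' @param n_cases number of case samples.
#' @param benign_genome_fraction target fraction of the autosomal genome
#'   covered by benign polymorphic regions.
#' @param benign_size_range benign region sizes (bases, uniform).
#' @param benign_freq_range benign carrier-frequency range (log-uniform).
#' @param n_spikes number of rare spiked CNVs when \code{spikes} is NULL.
#' @param spike_size_range spiked CNV sizes (bases, uniform).
#' @param spikes optional explicit spike table (\code{chrom, start, end,
#'   cnv_type, carrier} with carrier a case index); a spike colliding with a
#'   same-type benign region is an error.
#' @param noise_rate mean number of small nuisance calls per sample
#'   (Poisson).
#' @param xxy_case index of the case receiving a 47,XXY profile, or NA for
#'   none.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L, n_controls = 1000L, n_cases = 90L,
                              benign_genome_fraction = 0.12,
                              benign_size_range = c(5e4, 8e5),
                              benign_freq_range = c(0.005, 0.2),
                              n_spikes = 10L,
                              spike_size_range = c(1.5e5, 3e6),
                              spikes = NULL, noise_rate = 2,
                              xxy_case = NA_integer_) {
  stopifnot(benign_genome_fraction >= 0, benign_genome_fraction <= 1,
            benign_freq_range[1L] > 0, benign_freq_range[2L] <= 1,
            n_cases >= 0, n_controls >= 1, noise_rate >= 0)
  structure(list(seed = as.integer(seed), n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases),
                 benign_genome_fraction = benign_genome_fraction,
                 benign_size_range = benign_size_range,
                 benign_freq_range = benign_freq_range,
                 n_spikes = as.integer(n_spikes),
                 spike_size_range = spike_size_range,
                 spikes = spikes, noise_rate = noise_rate,
                 xxy_case = xxy_case),
            class = "simulation_config")
}

# Case call for a region: deletion -> CN 1, duplication -> CN 3.
region_call <- function(sample_id, chrom, start, end, type) {
  cnv_calls(sample_id, chrom, start, end,
            copy_number = ifelse(type == "deletion", 1, 3), cnv_type = type,
            n_probes = pmax(2L, as.integer((end - start) / 5000)),
            confidence = 0.95)
}

#' Simulate a control table and a spiked case cohort
#'
#' Generates, under \code{config$seed}: disjoint benign polymorphic regions
#' covering the target fraction of the autosomal genome with log-uniform
#' carrier frequencies; case CNV calls composed of benign background (each
#' case carries each benign region with its control frequency), small
#' nuisance calls, and the spiked rare CNVs; sample metadata and
#' sex-chromosome profiles (one 47,XXY case if configured); and a truth
#' table recording each spike's expected fate under the default filter
#' configuration.
#'
#' Case calls carry an \code{origin} column (\code{"benign"},
#' \code{"nuisance"}, \code{"spike"}); readers/writers and the pipeline
#' ignore it, tests use it as ground truth. Spikes are placed (or, if
#' user-supplied, checked) to avoid same-type reciprocal overlap >= 0.5 with
#' any benign region, so their survival of the cascade is unambiguous.
#'
#' @param genome a [generate_genome()] specification.
#' @param config a [simulation_config()].
#' @return \code{list(controls, calls, metadata, profiles, truth)}.
#' @export
simulate_cohorts <- function(genome, config = simulation_config()) {
  set.seed(config$seed)
  autos <- genome$chromosomes[!genome$chromosomes$chrom %in% c("X", "Y"), ,
                              drop = FALSE]
  total <- sum(autos$length)
  target <- config$benign_genome_fraction * total

  # --- benign polymorphic regions (disjoint) --------------------------------
  regions <- list()
  covered <- 0
  guard <- 0L
  while (covered < target && guard < 10000L) {
    guard <- guard + 1L
    ci <- sample.int(nrow(autos), 1L, prob = autos$length)
    size <- round(stats::runif(1L, config$benign_size_range[1L],
                               config$benign_size_range[2L]))
    start <- round(stats::runif(1L, 0, autos$length[ci] - size))
    chrom <- autos$chrom[ci]
    clash <- FALSE
    for (r in regions) {
      if (r$chrom == chrom && start < r$end && r$start < start + size) {
        clash <- TRUE; break
      }
    }
    if (clash) next
    lf <- log(config$benign_freq_range)
    freq <- exp(stats::runif(1L, lf[1L], lf[2L]))
    carrier <- max(1L, as.integer(round(freq * config$n_controls)))
    regions[[length(regions) + 1L]] <- list(
      chrom = chrom, start = start, end = start + size,
      cnv_type = sample(c("deletion", "duplication"), 1L),
      carrier_count = carrier)
    covered <- covered + size
  }
  controls <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               cnv_type = r$cnv_type, carrier_count = r$carrier_count,
               cohort_size = config$n_controls, stringsAsFactors = FALSE)
  }))
  controls <- controls[order(controls$chrom, controls$start), , drop = FALSE]
  rownames(controls) <- NULL
  controls$frequency <- controls$carrier_count / controls$cohort_size

  # --- sample metadata and sex profiles -------------------------------------
  ids <- sprintf("S%03d", seq_len(config$n_cases))
  sex <- sample(c("female", "male"), config$n_cases, replace = TRUE)
  metadata <- data.frame(
    sample_id = ids, sex = sex,
    ancestry = sample(c("cape_mixed", "black_african", "european"),
                      config$n_cases, replace = TRUE,
                      prob = c(0.66, 0.32, 0.02)),
    primary_diagnosis = sample(c("TOF", "VSD", "PDA", "pulmonary_atresia",
                                 "ASD", "AVSD", "PAPVC", "DORV",
                                 "coarctation", "TGA", "PS", "other"),
                               config$n_cases, replace = TRUE),
    extracardiac_anomalies = stats::runif(config$n_cases) < 0.2,
    qc_pass = rep(TRUE, config$n_cases), stringsAsFactors = FALSE
  )
  profiles <- data.frame(
    sample_id = ids,
    mean_cn_x = ifelse(sex == "female", 2, 1),
    mean_cn_y = ifelse(sex == "female", 0, 1),
    stringsAsFactors = FALSE
  )
  if (!is.na(config$xxy_case) && config$n_cases >= config$xxy_case) {
    metadata$sex[config$xxy_case] <- "male"
    profiles$mean_cn_x[config$xxy_case] <- 2
    profiles$mean_cn_y[config$xxy_case] <- 1
  }

  # --- spikes ----------------------------------------------------------------
  ro_clash <- function(chrom, start, end, type) {
    sel <- controls$chrom == chrom & controls$cnv_type == type
    if (!any(sel)) return(FALSE)
    ctl <- controls[sel, , drop = FALSE]
    any(reciprocal_overlap(
      data.frame(chrom = chrom, start = start, end = end),
      ctl[, c("chrom", "start", "end")]) >= 0.5)
  }
  eligible <- setdiff(seq_len(config$n_cases),
                      if (is.na(config$xxy_case)) integer(0L)
                      else config$xxy_case)
  if (is.null(config$spikes)) {
    spikes <- list()
    guard <- 0L
    while (length(spikes) < config$n_spikes && guard < 10000L &&
             length(eligible) > 0L) {
      guard <- guard + 1L
      ci <- sample.int(nrow(autos), 1L, prob = autos$length)
      size <- round(stats::runif(1L, config$spike_size_range[1L],
                                 config$spike_size_range[2L]))
      start <- round(stats::runif(1L, 0, autos$length[ci] - size))
      type <- sample(c("deletion", "duplication"), 1L)
      if (ro_clash(autos$chrom[ci], start, start + size, type)) next
      spikes[[length(spikes) + 1L]] <- data.frame(
        chrom = autos$chrom[ci], start = start, end = start + size,
        cnv_type = type,
        carrier = if (length(eligible) == 1L) eligible else
          sample(eligible, 1L),
        stringsAsFactors = FALSE)
    }
    spikes <- if (length(spikes) == 0L) NULL else do.call(rbind, spikes)
  } else {
    spikes <- config$spikes
    for (i in seq_len(nrow(spikes))) {
      if (ro_clash(spikes$chrom[i], spikes$start[i], spikes$end[i],
                   spikes$cnv_type[i])) {
        stop(sprintf(
          "spike %s:%d-%d (%s) collides with a benign region of the same type",
          spikes$chrom[i], spikes$start[i], spikes$end[i],
          spikes$cnv_type[i]), call. = FALSE)
      }
    }
  }

  # --- case calls -------------------------------------------------------------
  pieces <- list()
  if (config$n_cases > 0L && nrow(controls) > 0L) {
    for (r in seq_len(nrow(controls))) {
      hit <- which(stats::runif(config$n_cases) < controls$frequency[r])
      if (length(hit) > 0L) {
        b <- region_call(ids[hit], controls$chrom[r], controls$start[r],
                         controls$end[r], controls$cnv_type[r])
        b$origin <- "benign"
        pieces[[length(pieces) + 1L]] <- b
      }
    }
    n_noise <- stats::rpois(config$n_cases, config$noise_rate)
    for (i in which(n_noise > 0L)) {
      for (k in seq_len(n_noise[i])) {
        ci <- sample.int(nrow(autos), 1L, prob = autos$length)
        size <- round(stats::runif(1L, 5e3, 9.5e4))
        start <- round(stats::runif(1L, 0, autos$length[ci] - size))
        nz <- region_call(ids[i], autos$chrom[ci], start, start + size,
                          sample(c("deletion", "duplication"), 1L))
        nz$origin <- "nuisance"
        pieces[[length(pieces) + 1L]] <- nz
      }
    }
  }
  if (!is.null(spikes)) {
    sp <- region_call(ids[spikes$carrier], spikes$chrom, spikes$start,
                      spikes$end, spikes$cnv_type)
    sp$origin <- "spike"
    pieces[[length(pieces) + 1L]] <- sp
  }
  calls <- if (length(pieces) == 0L) {
    cc <- cnv_calls(character(0L), character(0L), numeric(0L), numeric(0L),
                    numeric(0L), character(0L))
    cc$origin <- character(0L)
    cc
  } else do.call(rbind, pieces)
  rownames(calls) <- NULL

  # --- truth -------------------------------------------------------------------
  truth <- if (is.null(spikes)) {
    data.frame(sample_id = character(0L), chrom = character(0L),
               start = numeric(0L), end = numeric(0L),
               cnv_type = character(0L), expect_survive = logical(0L),
               known_gene = logical(0L), candidate = logical(0L),
               stringsAsFactors = FALSE)
  } else {
    ann <- annotate_genes(
      region_call(ids[spikes$carrier], spikes$chrom, spikes$start,
                  spikes$end, spikes$cnv_type),
      genome$models, genome$curation)
    cand <- nominate_candidates(ann, genome$curation)
    ckeys <- unique(paste(cand$sample_id[cand$nominated],
                          cand$chrom[cand$nominated],
                          cand$start[cand$nominated], sep = "\r"))
    data.frame(
      sample_id = ids[spikes$carrier], chrom = spikes$chrom,
      start = spikes$start, end = spikes$end, cnv_type = spikes$cnv_type,
      expect_survive = (spikes$end - spikes$start) >= 1e5,
      known_gene = lengths(ann$known_chd_genes) > 0L,
      candidate = paste(ids[spikes$carrier], spikes$chrom, spikes$start,
                        sep = "\r") %in% ckeys,
      stringsAsFactors = FALSE)
  }
  list(controls = controls, calls = calls, metadata = metadata,
       profiles = profiles, truth = truth)
}
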