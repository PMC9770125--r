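# Readers and writers for every table the pipeline touches.
#
# Two CNV call dialects are supported:
#   * "array_export": tab-separated with header {Sample, Chromosome, Start,
#     Stop, CN State, Type, Probe Count, Confidence}, 1-based inclusive
#     coordinates (the canonical array segment-export form);
#   * "bed": headerless 3+3 BED (chrom, start, end, sample, type, copy
#     number [, probes, confidence]), 0-based half-open.
# All other tables are tab-separated with a header row.

#' Construct a validated CNV call table
#'
#' One row per copy-number segment in one sample. Coordinates follow the
#' package-internal 0-based half-open convention.
#'
#' @param sample_id sample identifiers.
#' @param chrom,start,end segment coordinates.
#' @param copy_number called copy-number state (2 = neutral for autosomes).
#' @param cnv_type \code{"deletion"} or \code{"duplication"}.
#' @param n_probes optional supporting probe count (positive integer or NA).
#' @param confidence optional call confidence in \code{[0, 1]} or NA.
#' @return a \code{data.frame} of CNV calls.
#' @export
cnv_calls <- function(sample_id, chrom, start, end, copy_number, cnv_type,
                      n_probes = NA_integer_, confidence = NA_real_) {
  n <- max(length(sample_id), length(chrom), length(start))
  if (length(n_probes) == 1L) n_probes <- rep(n_probes, n)
  if (length(confidence) == 1L) confidence <- rep(confidence, n)
  x <- data.frame(
    sample_id = as.character(sample_id),
    chrom = normalize_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    copy_number = as.numeric(copy_number),
    cnv_type = as.character(cnv_type),
    n_probes = as.integer(n_probes),
    confidence = as.numeric(confidence),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(x)
  x
}

#' Validate a CNV call table
#'
#' Checks interval validity, the type vocabulary, and the consistency of
#' copy-number state with type on autosomes (deletion means below the diploid
#' baseline, duplication above). Sex-chromosome baselines depend on the
#' sample's sex, which a call table does not carry, so X/Y rows are exempt
#' from the state/type check.
#'
#' @param x candidate call table.
#' @param context label for error messages.
#' @return \code{x} invisibly; errors name the offending rows.
#' @export
validate_cnv_calls <- function(x, context = "cnv_calls") {
  need <- c("sample_id", "chrom", "start", "end", "copy_number", "cnv_type")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", context,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"n_probes" %in% names(x)) x$n_probes <- NA_integer_
  if (!"confidence" %in% names(x)) x$confidence <- NA_real_
  validate_intervals(x, context)
  badtype <- which(!x$cnv_type %in% c("deletion", "duplication"))
  if (length(badtype) > 0L) {
    stop(sprintf("%s: cnv_type must be 'deletion' or 'duplication' (row %s)",
                 context, paste(utils::head(badtype, 5L), collapse = ", ")),
         call. = FALSE)
  }
  auto <- !x$chrom %in% c("X", "Y")
  bad <- which(auto & ((x$cnv_type == "deletion" & x$copy_number >= 2) |
                         (x$cnv_type == "duplication" & x$copy_number <= 2)))
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s: copy_number inconsistent with cnv_type on autosome (row %s)",
      context, paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  badp <- which(!is.na(x$n_probes) & x$n_probes < 1)
  if (length(badp) > 0L) {
    stop(sprintf("%s: n_probes must be positive (row %s)", context,
                 paste(utils::head(badp, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(x, path, col.names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names, na = "NA")
}

require_columns <- function(x, cols, path) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Read CNV calls
#'
#' @param path file path.
#' @param dialect \code{"array_export"} (tab-separated, headered, 1-based
#'   inclusive) or \code{"bed"} (headerless, 0-based half-open).
#' @return a CNV call table in the internal convention; malformed rows are
#'   reported with their line numbers.
#' @export
read_cnv_calls <- function(path, dialect = c("array_export", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (dialect == "array_export") {
    raw <- read_tsv(path)
    require_columns(raw, c("Sample", "Chromosome", "Start", "Stop",
                           "CN State", "Type"), path)
    calls <- data.frame(
      sample_id = as.character(raw$Sample),
      chrom = normalize_chrom(raw$Chromosome),
      start = as.numeric(raw$Start) - 1,  # 1-based incl -> 0-based half-open
      end = as.numeric(raw$Stop),
      copy_number = as.numeric(raw[["CN State"]]),
      cnv_type = tolower(as.character(raw$Type)),
      n_probes = if ("Probe Count" %in% names(raw))
        as.integer(raw[["Probe Count"]]) else NA_integer_,
      confidence = if ("Confidence" %in% names(raw))
        as.numeric(raw$Confidence) else NA_real_,
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 6L) {
      stop(sprintf("%s: BED dialect needs >= 6 columns (chrom, start, end, sample, type, cn)",
                   path), call. = FALSE)
    }
    calls <- data.frame(
      sample_id = as.character(raw[[4L]]),
      chrom = normalize_chrom(raw[[1L]]),
      start = as.numeric(raw[[2L]]),
      end = as.numeric(raw[[3L]]),
      copy_number = as.numeric(raw[[6L]]),
      cnv_type = tolower(as.character(raw[[5L]])),
      n_probes = if (ncol(raw) >= 7L) as.integer(raw[[7L]]) else NA_integer_,
      confidence = if (ncol(raw) >= 8L) as.numeric(raw[[8L]]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  tryCatch(validate_cnv_calls(calls, context = path),
           error = function(e) stop(e))
  calls
}

#' Write CNV calls
#'
#' Inverse of [read_cnv_calls()]; internal coordinates are converted back to
#' the target dialect so that write-then-read is the identity.
#'
#' @param calls CNV call table.
#' @param path output path.
#' @param dialect see [read_cnv_calls()].
#' @return \code{path}, invisibly.
#' @export
write_cnv_calls <- function(calls, path, dialect = c("array_export", "bed")) {
  dialect <- match.arg(dialect)
  validate_cnv_calls(calls)
  if (dialect == "array_export") {
    out <- data.frame(
      Sample = calls$sample_id,
      Chromosome = calls$chrom,
      Start = calls$start + 1,  # back to 1-based inclusive
      Stop = calls$end,
      `CN State` = calls$copy_number,
      Type = calls$cnv_type,
      `Probe Count` = calls$n_probes,
      Confidence = calls$confidence,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    write_tsv(out, path)
  } else {
    out <- data.frame(calls$chrom, calls$start, calls$end, calls$sample_id,
                      calls$cnv_type, calls$copy_number, calls$n_probes,
                      calls$confidence, stringsAsFactors = FALSE)
    write_tsv(out, path, col.names = FALSE)
  }
  invisible(path)
}

#' Read gene models and curation flags
#'
#' The model table (\code{symbol, chrom, start, end, strand}) defines gene
#' coordinates; the curation table (\code{symbol, known_chd,
#' haploinsufficient, triplosensitive, pli, murine_heart_expression,
#' mouse_cardiac_or_embryonic_phenotype}) carries the disease-gene and
#' dosage-sensitivity flags. Curation rows whose symbol has no gene model are
#' dropped with a warning; genes with no curation row get
#' \code{known_chd = FALSE} and missing (NA) evidence everywhere else —
#' "no evidence" is deliberately distinct from "evidence against".
#'
#' @param models_path path to the gene model table.
#' @param curation_path path to the curation table; may contain only a header.
#' @return \code{list(models = <data.frame>, curation = <data.frame>)} with
#'   one curation row per model symbol.
#' @export
read_gene_resources <- function(models_path, curation_path) {
  models <- read_tsv(models_path)
  require_columns(models, c("symbol", "chrom", "start", "end"), models_path)
  models$chrom <- normalize_chrom(models$chrom)
  if (!"strand" %in% names(models)) models$strand <- "+"
  validate_intervals(models, models_path)
  if (any(models$symbol == "" | is.na(models$symbol))) {
    stop(sprintf("%s: empty gene symbol", models_path), call. = FALSE)
  }
  dup <- models$symbol[duplicated(models$symbol)]
  if (length(dup) > 0L) {
    conf <- unique(dup[vapply(dup, function(s) {
      m <- models[models$symbol == s, c("chrom", "start", "end")]
      nrow(unique(m)) > 1L
    }, logical(1L))])
    if (length(conf) > 0L) {
      stop(sprintf("%s: duplicate symbols with conflicting coordinates: %s",
                   models_path, paste(conf, collapse = ", ")), call. = FALSE)
    }
    models <- models[!duplicated(models$symbol), , drop = FALSE]
  }
  cur <- read_tsv(curation_path)
  require_columns(cur, "symbol", curation_path)
  orphan <- setdiff(cur$symbol, models$symbol)
  if (length(orphan) > 0L) {
    warning(sprintf("%s: dropping %d curation row(s) with no gene model: %s",
                    curation_path, length(orphan),
                    paste(orphan, collapse = ", ")), call. = FALSE)
    cur <- cur[cur$symbol %in% models$symbol, , drop = FALSE]
  }
  curation <- merge_curation(models$symbol, cur)
  message(sprintf("read_gene_resources: %d gene models, %d flagged known_chd",
                  nrow(models), sum(curation$known_chd)))
  rownames(models) <- NULL
  list(models = models, curation = curation)
}

# Expand a (possibly partial) curation table to one row per gene symbol,
# filling known_chd = FALSE and NA evidence for uncurated genes.
merge_curation <- function(symbols, cur) {
  as_flag <- function(v) {
    if (is.null(v)) return(rep(NA, nrow(cur)))
    if (is.logical(v)) return(v)
    ifelse(is.na(v) | v == "NA" | v == "", NA, toupper(v) == "TRUE")
  }
  k <- length(symbols)
  out <- data.frame(symbol = symbols, known_chd = rep(FALSE, k),
                    haploinsufficient = rep(NA, k),
                    triplosensitive = rep(NA, k),
                    pli = rep(NA_real_, k),
                    murine_heart_expression = rep(NA, k),
                    mouse_cardiac_or_embryonic_phenotype = rep(NA, k),
                    stringsAsFactors = FALSE)
  if (nrow(cur) == 0L) return(out)
  i <- match(cur$symbol, symbols)
  set <- function(col, v) {
    v <- v[!is.na(i)]
    out[[col]][i[!is.na(i)]] <<- v
  }
  set("known_chd", {
    k <- as_flag(cur$known_chd)
    ifelse(is.na(k), FALSE, k)
  })
  set("haploinsufficient", as_flag(cur$haploinsufficient))
  set("triplosensitive", as_flag(cur$triplosensitive))
  if (!is.null(cur$pli)) set("pli", as.numeric(cur$pli))
  set("murine_heart_expression", as_flag(cur$murine_heart_expression))
  set("mouse_cardiac_or_embryonic_phenotype",
      as_flag(cur$mouse_cardiac_or_embryonic_phenotype))
  out
}

#' Write gene resources
#' @param resources list as returned by [read_gene_resources()].
#' @param models_path,curation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_gene_resources <- function(resources, models_path, curation_path) {
  write_tsv(resources$models, models_path)
  write_tsv(resources$curation, curation_path)
  invisible(c(models_path, curation_path))
}

#' Read a control-population CNV frequency table
#'
#' Tab-separated with header \code{chrom, start, end, cnv_type,
#' carrier_count, cohort_size}; the carrier frequency is recomputed as
#' \code{carrier_count / cohort_size} on read.
#'
#' @param path file path.
#' @return validated control table with a \code{frequency} column. An empty
#'   table is valid (every case CNV will then pass the rarity filter).
#' @export
read_control_frequencies <- function(path) {
  x <- read_tsv(path)
  require_columns(x, c("chrom", "start", "end", "cnv_type", "carrier_count",
                       "cohort_size"), path)
  x$chrom <- normalize_chrom(x$chrom)
  if (nrow(x) > 0L) {
    validate_intervals(x, path)
    bad <- which(x$carrier_count > x$cohort_size | x$carrier_count < 0 |
                   x$cohort_size <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("%s: carrier_count/cohort_size invalid (row %s)", path,
                   paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
    badtype <- which(!x$cnv_type %in% c("deletion", "duplication"))
    if (length(badtype) > 0L) {
      stop(sprintf("%s: cnv_type must be deletion/duplication (row %s)", path,
                   paste(utils::head(badtype, 5L), collapse = ", ")),
           call. = FALSE)
    }
    message(sprintf("read_control_frequencies: %d regions, aggregate cohort size %d",
                    nrow(x), max(x$cohort_size)))
  }
  x$frequency <- ifelse(x$cohort_size > 0, x$carrier_count / x$cohort_size,
                        NA_real_)
  x
}

#' Write a control frequency table
#' @param controls control table.
#' @param path output path.
#' @export
write_control_frequencies <- function(controls, path) {
  keep <- c("chrom", "start", "end", "cnv_type", "carrier_count",
            "cohort_size")
  write_tsv(controls[, keep], path)
  invisible(path)
}

#' Read cohort sample metadata
#'
#' Tab-separated with header \code{sample_id, sex, ancestry,
#' primary_diagnosis, extracardiac_anomalies, qc_pass}.
#'
#' @param path file path.
#' @return validated metadata table; duplicate sample ids are an error.
#' @export
read_sample_metadata <- function(path) {
  x <- read_tsv(path)
  require_columns(x, c("sample_id", "sex", "ancestry", "primary_diagnosis",
                       "extracardiac_anomalies", "qc_pass"), path)
  if (anyDuplicated(x$sample_id)) {
    stop(sprintf("%s: duplicate sample_id", path), call. = FALSE)
  }
  bad <- which(!x$sex %in% c("female", "male", "unknown"))
  if (length(bad) > 0L) {
    stop(sprintf("%s: sex must be female/male/unknown (row %s)", path,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  x$extracardiac_anomalies <- as.logical(x$extracardiac_anomalies)
  x$qc_pass <- as.logical(x$qc_pass)
  x
}

#' Write cohort sample metadata
#' @param metadata metadata table.
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  write_tsv(metadata, path)
  invisible(path)
}

#' Read per-sample sex-chromosome copy-number profiles
#'
#' Tab-separated with header \code{sample_id, mean_cn_x, mean_cn_y}.
#'
#' @param path file path.
#' @return validated profile table (finite, non-negative means).
#' @export
read_sex_profiles <- function(path) {
  x <- read_tsv(path)
  require_columns(x, c("sample_id", "mean_cn_x", "mean_cn_y"), path)
  bad <- which(!is.finite(x$mean_cn_x) | !is.finite(x$mean_cn_y) |
                 x$mean_cn_x < 0 | x$mean_cn_y < 0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: mean CN values must be finite and >= 0 (row %s)", path,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  x
}

#' Write sex-chromosome profiles
#' @param profiles profile table.
#' @param path output path.
#' @export
write_sex_profiles <- function(profiles, path) {
  write_tsv(profiles, path)
  invisible(path)
}

# md5 of a table's canonical tab-separated serialization (content hash,
# independent of where the table came from).
table_md5 <- function(x) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  flat <- x
  for (j in seq_along(flat)) {
    if (is.list(flat[[j]])) {
      flat[[j]] <- vapply(flat[[j]], function(v) paste(v, collapse = ","),
                          character(1L))
    }
  }
  write_tsv(flat, tmp)
  unname(tools::md5sum(tmp))
}

#' Write the full result bundle of a pipeline run
#'
#' Writes, into \code{out_dir}: \code{classified_cnvs.tsv} (one row per
#' retained CNV with class, genes and evidence points),
#' \code{filter_trace.tsv}, \code{cohort_summary.tsv},
#' \code{candidate_genes.tsv}, and a machine-readable \code{manifest.json}
#' holding the configuration, seed, input checksums and headline yields.
#' Output is deterministic: identical inputs and configuration give
#' byte-identical files.
#'
#' @param report a cohort report from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
write_results <- function(report, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory %s", out_dir),
                  call. = FALSE)
  }
  cls <- report$classified
  flat <- data.frame(
    sample_id = cls$sample_id, chrom = cls$chrom, start = cls$start,
    end = cls$end, size_bp = cls$end - cls$start, cnv_type = cls$cnv_type,
    cytoband = cls$cytoband,
    genes_full = vapply(cls$genes_full, paste, character(1L), collapse = ","),
    genes_partial = vapply(cls$genes_partial, paste, character(1L),
                           collapse = ","),
    known_chd_genes = vapply(cls$known_chd_genes, paste, character(1L),
                             collapse = ","),
    evidence_points = cls$evidence_points,
    classification = cls$classification,
    interest_tag = if (is.null(cls$interest_tag)) "" else cls$interest_tag,
    stringsAsFactors = FALSE
  )
  p1 <- file.path(out_dir, "classified_cnvs.tsv")
  write_tsv(flat, p1)
  p2 <- file.path(out_dir, "filter_trace.tsv")
  write_tsv(report$trace$stages, p2)
  p3 <- file.path(out_dir, "cohort_summary.tsv")
  summ <- do.call(rbind, lapply(names(report$summary), function(nm) {
    s <- report$summary[[nm]]
    data.frame(table = nm, level = s$level, n = s$n, pct = s$pct,
               stringsAsFactors = FALSE)
  }))
  write_tsv(summ, p3)
  p4 <- file.path(out_dir, "candidate_genes.tsv")
  cand <- report$candidates
  write_tsv(cand[, setdiff(names(cand), c("genes_full", "genes_partial"))], p4)
  manifest <- list(
    tool = "cnvtriage",
    seed = report$seed,
    config = list(filter = unclass(report$filter_config),
                  classification = unclass(report$classification_config),
                  merge_max_gap = report$merge_max_gap),
    inputs_md5 = report$inputs_md5,
    n_enrolled = report$n_enrolled,
    n_cnv_analyzed = report$n_cnv_analyzed,
    n_retained_cnvs = nrow(report$classified),
    n_cnvs_of_interest = nrow(report$of_interest),
    yield_plp = report$yield_plp,
    yield_total = report$yield_total
  )
  p5 <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p5, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p1, p2, p3, p4, p5))
}
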