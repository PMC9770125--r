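# Gene-level annotation of retained CNVs, points-based pathogenicity
# classification, candidate-gene nomination, and karyotype inference.
#
# The rubric is a deliberately reduced, fully deterministic realization of
# the semiquantitative ACMG/ClinGen copy-number framework: only the
# dosage-gene content, gene-count and control-frequency sections are
# automated. The literature/case-count and inheritance sections — which
# require curation outside any call set — enter through an optional manual
# points adjustment, defaulting to 0.

#' Classification rubric configuration
#'
#' Evidence rules (points are signed and additive):
#' \describe{
#'   \item{L1 (+1.0)}{copy loss fully containing a haploinsufficient
#'     known-disease gene.}
#'   \item{G1 (+1.0)}{copy gain fully containing a triplosensitive gene.}
#'   \item{L2 (+0.30)}{a known-disease gene overlapped (fully or partially)
#'     without an established dosage flag for the event type.}
#'   \item{P1 (+0.90)}{a loss partially overlapping — therefore disrupting —
#'     a haploinsufficient gene it does not fully contain.}
#'   \item{F1 (+0.15)}{absent from controls at the run thresholds (no
#'     same-event control match).}
#'   \item{F2 (-1.0)}{common in controls: some matching control record
#'     crosses both the reciprocal-overlap and the frequency thresholds.}
#'   \item{N1 (-0.60)}{the CNV contains no genes at all.}
#' }
#' Cut-points map total points to the five tiers: \code{>= 0.99} Pathogenic,
#' \code{>= 0.90} Likely pathogenic, \code{> -0.90} Uncertain significance,
#' \code{> -0.99} Likely benign, else Benign. The mapping is monotone in
#' points.
#'
#' @param points named numeric vector of rule points.
#' @param cut_pathogenic,cut_likely_pathogenic,cut_likely_benign,cut_benign
#'   classification cut-points.
#' @param pli_threshold pLI at or above which a gene counts as highly
#'   loss-of-function intolerant (candidate nomination).
#' @return a \code{classification_config} list.
#' @export
classification_config <- function(points = c(L1 = 1.0, G1 = 1.0, L2 = 0.30,
                                             P1 = 0.90, F1 = 0.15, F2 = -1.0,
                                             N1 = -0.60),
                                  cut_pathogenic = 0.99,
                                  cut_likely_pathogenic = 0.90,
                                  cut_likely_benign = -0.90,
                                  cut_benign = -0.99,
                                  pli_threshold = 0.9) {
  stopifnot(all(c("L1", "G1", "L2", "P1", "F1", "F2", "N1") %in%
                  names(points)),
            cut_pathogenic >= cut_likely_pathogenic,
            cut_likely_benign >= cut_benign,
            pli_threshold >= 0, pli_threshold <= 1)
  structure(list(points = points,
                 cut_pathogenic = cut_pathogenic,
                 cut_likely_pathogenic = cut_likely_pathogenic,
                 cut_likely_benign = cut_likely_benign,
                 cut_benign = cut_benign,
                 pli_threshold = pli_threshold),
            class = "classification_config")
}

#' Map evidence points to the five-tier classification
#'
#' @param points numeric vector of accumulated evidence points.
#' @param config a [classification_config()].
#' @return character vector in \{Pathogenic, Likely pathogenic, Uncertain
#'   significance, Likely benign, Benign\}.
#' @export
classify_points <- function(points, config = classification_config()) {
  eps <- 1e-9  # points are sums of decimal fractions; guard the cut-points
  ifelse(points >= config$cut_pathogenic - eps, "Pathogenic",
    ifelse(points >= config$cut_likely_pathogenic - eps, "Likely pathogenic",
      ifelse(points > config$cut_likely_benign + eps,
             "Uncertain significance",
        ifelse(points > config$cut_benign + eps, "Likely benign",
               "Benign"))))
}

#' Annotate CNV calls with gene content
#'
#' For each call: \code{genes_full} are gene models the CNV encompasses end
#' to end; \code{genes_partial} are models it overlaps without containing;
#' \code{known_chd_genes} is the subset of either list flagged as known
#' disease genes (a partial hit counts — a duplication only partially
#' covering a known gene still flags the call). A cytoband label is attached
#' when a band map is supplied.
#'
#' @param calls CNV call table.
#' @param models gene model table (\code{symbol, chrom, start, end}).
#' @param curation curation table (see [read_gene_resources()]); may be NULL.
#' @param bands optional [cytoband_map()].
#' @return the call table with list-columns \code{genes_full},
#'   \code{genes_partial}, \code{known_chd_genes} and a \code{cytoband}
#'   column.
#' @export
annotate_genes <- function(calls, models, curation = NULL, bands = NULL) {
  validate_cnv_calls(calls)
  known <- if (is.null(curation)) character(0L) else
    curation$symbol[curation$known_chd]
  n <- nrow(calls)
  gf <- vector("list", n); gp <- vector("list", n); kg <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.null(models) || nrow(models) == 0L) {
      hit_full <- hit_part <- character(0L)
    } else {
      sel <- models$chrom == calls$chrom[i]
      m <- models[sel, , drop = FALSE]
      if (nrow(m) == 0L) {
        hit_full <- hit_part <- character(0L)
      } else {
        ci <- calls[i, c("chrom", "start", "end")]
        ov <- overlap_bp(ci, m[, c("chrom", "start", "end")])
        full <- contains_fully(ci, m[, c("chrom", "start", "end")])
        hit_full <- m$symbol[full]
        hit_part <- m$symbol[ov > 0 & !full]
      }
    }
    gf[[i]] <- sort(hit_full)
    gp[[i]] <- sort(hit_part)
    kg[[i]] <- sort(intersect(c(hit_full, hit_part), known))
  }
  out <- calls
  out$genes_full <- gf
  out$genes_partial <- gp
  out$known_chd_genes <- kg
  out$cytoband <- if (is.null(bands)) NA_character_ else
    cytoband_label(calls, bands)
  out
}

# Look up one curation row per symbol (NA-filled if absent).
curation_rows <- function(symbols, curation) {
  if (is.null(curation) || length(symbols) == 0L) {
    return(merge_curation(symbols,
                          data.frame(symbol = character(0L),
                                     stringsAsFactors = FALSE)))
  }
  i <- match(symbols, curation$symbol)
  out <- merge_curation(symbols, curation[i[!is.na(i)], , drop = FALSE])
  out
}

#' Score annotated CNVs with the points rubric
#'
#' Accumulates evidence points per CNV from the rules documented in
#' [classification_config()], records every contribution as an evidence
#' item, and maps the total through the classification cut-points.
#'
#' Manual adjustments (the encoded outcome of expert literature/database
#' review, outside the automated rubric) are matched to calls by sample,
#' CNV type and reciprocal overlap of at least
#' \code{filter_cfg$reciprocal_overlap_threshold}, and contribute their
#' points under rule id \code{"MANUAL"}.
#'
#' @param annotated output of [annotate_genes()].
#' @param curation gene curation table.
#' @param controls control frequency table (for the F1/F2 rules); may be
#'   NULL, in which case every CNV earns F1.
#' @param config a [classification_config()].
#' @param filter_cfg the [filter_config()] whose thresholds define "absent
#'   from controls".
#' @param manual optional manual-adjustment table with columns
#'   \code{sample_id, chrom, start, end, cnv_type, points, note}.
#' @return \code{annotated} with \code{evidence_points},
#'   \code{classification} and an \code{evidence_items} list-column (one
#'   data.frame of \code{rule, points, justification} per CNV).
#' @export
score_cnvs <- function(annotated, curation, controls = NULL,
                       config = classification_config(),
                       filter_cfg = filter_config(), manual = NULL) {
  if (!all(c("genes_full", "genes_partial") %in% names(annotated))) {
    stop("score_cnvs needs annotate_genes() output", call. = FALSE)
  }
  bad <- which(!annotated$cnv_type %in% c("deletion", "duplication"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown cnv_type (row %s)",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  pts <- config$points
  n <- nrow(annotated)
  matched <- control_matched(annotated, controls, filter_cfg)
  # truly absent: no same-event control match at any frequency
  zero_cfg <- filter_cfg
  zero_cfg$max_control_frequency <- 0
  present <- if (is.null(controls) || nrow(controls) == 0L) {
    rep(FALSE, n)
  } else {
    ctl_nz <- controls[controls$frequency > 0, , drop = FALSE]
    control_matched(annotated, ctl_nz, zero_cfg)
  }
  total <- numeric(n)
  cls <- character(n)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    full <- curation_rows(annotated$genes_full[[i]], curation)
    part <- curation_rows(annotated$genes_partial[[i]], curation)
    is_del <- annotated$cnv_type[i] == "deletion"
    ev <- list()
    add <- function(rule, p, just) {
      ev[[length(ev) + 1L]] <<- data.frame(rule = rule, points = p,
                                           justification = just,
                                           stringsAsFactors = FALSE)
    }
    dosage_full <- if (is_del) {
      full$symbol[full$known_chd & !is.na(full$haploinsufficient) &
                    full$haploinsufficient]
    } else {
      full$symbol[!is.na(full$triplosensitive) & full$triplosensitive]
    }
    dosage_part_loss <- if (is_del) {
      part$symbol[!is.na(part$haploinsufficient) & part$haploinsufficient]
    } else character(0L)
    if (length(dosage_full) > 0L) {
      add(if (is_del) "L1" else "G1", pts[[if (is_del) "L1" else "G1"]],
          sprintf("%s fully contained dosage-sensitive gene(s): %s",
                  if (is_del) "haploinsufficient" else "triplosensitive",
                  paste(dosage_full, collapse = ", ")))
    } else if (length(dosage_part_loss) > 0L) {
      add("P1", pts[["P1"]],
          sprintf("loss partially disrupts haploinsufficient gene(s): %s",
                  paste(dosage_part_loss, collapse = ", ")))
    }
    overl <- rbind(full, part)
    dflag <- if (is_del) overl$haploinsufficient else overl$triplosensitive
    nondosage_known <- overl$symbol[overl$known_chd &
                                      !(!is.na(dflag) & dflag)]
    nondosage_known <- setdiff(nondosage_known,
                               c(dosage_full, dosage_part_loss))
    if (length(nondosage_known) > 0L) {
      add("L2", pts[["L2"]],
          sprintf("known disease gene(s) overlapped without dosage flag: %s",
                  paste(nondosage_known, collapse = ", ")))
    }
    n_genes <- length(annotated$genes_full[[i]]) +
      length(annotated$genes_partial[[i]])
    if (n_genes == 0L) {
      add("N1", pts[["N1"]], "contains no genes")
    }
    if (matched[i]) {
      add("F2", pts[["F2"]], "matches a common control CNV region")
    } else if (!present[i]) {
      add("F1", pts[["F1"]], "absent from controls at run thresholds")
    }
    if (!is.null(manual) && nrow(manual) > 0L) {
      msel <- manual$sample_id == annotated$sample_id[i] &
        manual$cnv_type == annotated$cnv_type[i] &
        manual$chrom == annotated$chrom[i]
      if (any(msel)) {
        mm <- manual[msel, , drop = FALSE]
        ro <- reciprocal_overlap(annotated[i, c("chrom", "start", "end")],
                                 mm[, c("chrom", "start", "end")])
        mm <- mm[ro >= filter_cfg$reciprocal_overlap_threshold, ,
                 drop = FALSE]
        for (k in seq_len(nrow(mm))) {
          add("MANUAL", mm$points[k],
              if (is.null(mm$note)) "manual adjustment" else mm$note[k])
        }
      }
    }
    itab <- if (length(ev) == 0L) {
      data.frame(rule = character(0L), points = numeric(0L),
                 justification = character(0L), stringsAsFactors = FALSE)
    } else do.call(rbind, ev)
    items[[i]] <- itab
    total[i] <- sum(itab$points)
    cls[i] <- classify_points(total[i], config)
  }
  out <- annotated
  out$evidence_points <- total
  out$classification <- cls
  out$evidence_items <- items
  out
}

#' Nominate candidate disease genes from a CNV's gene content
#'
#' For every gene a retained (already large and rare) CNV overlaps that is
#' NOT on the known-disease list, the gene is nominated iff it is highly
#' loss-of-function intolerant (pLI at or above the threshold), expressed in
#' the developing murine heart, AND has a reported cardiac or embryonic
#' mouse-model phenotype. The three criteria are a conjunction; missing
#' evidence fails a criterion — "no evidence" never counts as support.
#'
#' @param annotated output of [annotate_genes()] for CNVs that passed the
#'   size/rarity cascade.
#' @param curation gene curation table.
#' @param config a [classification_config()] (supplies
#'   \code{pli_threshold}).
#' @return one row per (CNV, non-known gene) pair with the five criterion
#'   flags and \code{nominated}.
#' @export
nominate_candidates <- function(annotated, curation,
                                config = classification_config()) {
  rows <- list()
  for (i in seq_len(nrow(annotated))) {
    genes <- c(annotated$genes_full[[i]], annotated$genes_partial[[i]])
    if (length(genes) == 0L) next
    cu <- curation_rows(genes, curation)
    cu <- cu[!cu$known_chd, , drop = FALSE]
    if (nrow(cu) == 0L) next
    high_pli <- !is.na(cu$pli) & cu$pli >= config$pli_threshold
    heart <- !is.na(cu$murine_heart_expression) & cu$murine_heart_expression
    mouse <- !is.na(cu$mouse_cardiac_or_embryonic_phenotype) &
      cu$mouse_cardiac_or_embryonic_phenotype
    rows[[length(rows) + 1L]] <- data.frame(
      gene = cu$symbol,
      sample_id = annotated$sample_id[i],
      chrom = annotated$chrom[i], start = annotated$start[i],
      end = annotated$end[i], cnv_type = annotated$cnv_type[i],
      high_pli = high_pli,
      murine_heart_expression = heart,
      mouse_phenotype = mouse,
      not_known_chd = TRUE,
      rare_large_cnv = TRUE,
      nominated = high_pli & heart & mouse,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(0L), sample_id = character(0L),
                      chrom = character(0L), start = numeric(0L),
                      end = numeric(0L), cnv_type = character(0L),
                      high_pli = logical(0L),
                      murine_heart_expression = logical(0L),
                      mouse_phenotype = logical(0L),
                      not_known_chd = logical(0L),
                      rare_large_cnv = logical(0L), nominated = logical(0L),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infer a sex-chromosome karyotype from mean copy numbers
#'
#' Rounds the mean X and Y copy numbers to the nearest integers; if either
#' value deviates from its nearest integer by more than \code{tolerance} the
#' profile is ambiguous and labelled \code{"other"}. Integer pairs map
#' (X=2, Y=0) to 46,XX; (1, 1) to 46,XY; (2, 1) to 47,XXY; anything else to
#' \code{"other"}. Aneuploid means any label outside \{46,XX; 46,XY\}.
#'
#' @param profiles sex-chromosome profile table (\code{sample_id, mean_cn_x,
#'   mean_cn_y}); negative values are an error.
#' @param tolerance maximum deviation from an integer copy number
#'   (default 0.3).
#' @return data.frame with \code{sample_id}, \code{label},
#'   \code{aneuploid}.
#' @export
infer_karyotype <- function(profiles, tolerance = 0.3) {
  if (any(!is.finite(profiles$mean_cn_x) | !is.finite(profiles$mean_cn_y) |
            profiles$mean_cn_x < 0 | profiles$mean_cn_y < 0)) {
    stop("mean copy numbers must be finite and non-negative", call. = FALSE)
  }
  rx <- round(profiles$mean_cn_x)
  ry <- round(profiles$mean_cn_y)
  ok <- abs(profiles$mean_cn_x - rx) <= tolerance &
    abs(profiles$mean_cn_y - ry) <= tolerance
  label <- rep("other", nrow(profiles))
  label[ok & rx == 2 & ry == 0] <- "46,XX"
  label[ok & rx == 1 & ry == 1] <- "46,XY"
  label[ok & rx == 2 & ry == 1] <- "47,XXY"
  data.frame(sample_id = profiles$sample_id, label = label,
             aneuploid = !label %in% c("46,XX", "46,XY"),
             stringsAsFactors = FALSE)
}

#' Select CNVs of interest
#'
#' The union of CNVs overlapping at least one known disease gene and CNVs
#' carrying at least one nominated candidate gene, deduplicated by call
#' identity and tagged \code{"known_gene"}, \code{"candidate"} or
#' \code{"both"}.
#'
#' @param classified output of [score_cnvs()] (or [annotate_genes()]) on the
#'   retained CNV set.
#' @param candidates output of [nominate_candidates()] on the same set.
#' @return the subset of \code{classified} that is of interest, with an
#'   \code{interest_tag} column.
#' @export
select_cnvs_of_interest <- function(classified, candidates) {
  key <- function(sid, chrom, start, end, type) {
    paste(sid, chrom, start, end, type, sep = "\r")
  }
  k_calls <- key(classified$sample_id, classified$chrom, classified$start,
                 classified$end, classified$cnv_type)
  known <- lengths(classified$known_chd_genes) > 0L
  cand_keys <- if (nrow(candidates) == 0L) character(0L) else
    unique(key(candidates$sample_id[candidates$nominated],
               candidates$chrom[candidates$nominated],
               candidates$start[candidates$nominated],
               candidates$end[candidates$nominated],
               candidates$cnv_type[candidates$nominated]))
  cand <- k_calls %in% cand_keys
  tag <- rep(NA_character_, nrow(classified))
  tag[known & !cand] <- "known_gene"
  tag[!known & cand] <- "candidate"
  tag[known & cand] <- "both"
  out <- classified[!is.na(tag), , drop = FALSE]
  out$interest_tag <- tag[!is.na(tag)]
  out <- out[!duplicated(k_calls[!is.na(tag)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
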