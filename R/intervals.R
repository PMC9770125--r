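# Genomic-interval data model and exact interval arithmetic.
#
# Coordinates are 0-based, half-open everywhere inside the package; 1-based
# inclusive dialects are converted at the I/O boundary (see io.R).

#' Normalize chromosome labels
#'
#' Strips any leading \code{"chr"} prefix (case-insensitive) so that array
#' exports and BED dialects agree internally. Sex chromosomes stay as the
#' letters \code{"X"} and \code{"Y"}.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Construct a validated table of genomic intervals
#'
#' Intervals are 0-based, half-open: \code{start} is the first covered base,
#' \code{end} is one past the last. Length equals \code{end - start} and must
#' be strictly positive.
#'
#' @param chrom chromosome labels (any \code{"chr"} prefix is stripped).
#' @param start integer-valued start positions, 0-based inclusive.
#' @param end integer-valued end positions, exclusive.
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}.
#' @examples
#' genomic_intervals("8", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end) {
  x <- data.frame(
    chrom = normalize_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

#' Validate interval invariants
#'
#' Checks that every row has finite coordinates, \code{start >= 0} and
#' \code{end > start}. Called by every operation that consumes intervals.
#'
#' @param x data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @param context label used in error messages.
#' @return \code{x}, invisibly; errors on the first violation, naming rows.
#' @export
validate_intervals <- function(x, context = "interval") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop(sprintf("%s table is missing column(s): %s", context,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start < 0 | x$end <= x$start)
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s rows violate invariants (need finite coords, start >= 0, end > start): row %s",
      context, paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Interval lengths in bases
#' @param x interval table.
#' @return numeric vector \code{end - start}.
#' @export
interval_length <- function(x) x$end - x$start

# Recycle two interval tables to a common row count (either may have 1 row).
recycle_pair <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == nb) return(list(a = a, b = b))
  if (na == 1L) return(list(a = a[rep(1L, nb), , drop = FALSE], b = b))
  if (nb == 1L) return(list(a = a, b = b[rep(1L, na), , drop = FALSE]))
  stop("interval tables have incompatible row counts", call. = FALSE)
}

#' Overlap between two intervals, in bases
#'
#' Vectorized elementwise over rows (one-row tables recycle). Intervals on
#' different chromosomes overlap by 0 bases; this is not an error. The
#' operation is symmetric in its arguments.
#'
#' @param a,b interval tables (columns \code{chrom}, \code{start}, \code{end}).
#' @return numeric vector of shared bases,
#'   \code{max(0, min(end) - max(start))} per row.
#' @export
overlap_bp <- function(a, b) {
  validate_intervals(a, "overlap_bp 'a'")
  validate_intervals(b, "overlap_bp 'b'")
  p <- recycle_pair(a, b)
  same <- normalize_chrom(p$a$chrom) == normalize_chrom(p$b$chrom)
  ov <- pmax(0, pmin(p$a$end, p$b$end) - pmax(p$a$start, p$b$start))
  ifelse(same, ov, 0)
}

#' Reciprocal overlap of two intervals
#'
#' The standard criterion for deciding whether two CNV calls are "the same
#' event": the shared bases divided by each interval's length, taking the
#' minimum of the two fractions. Equals 1 iff the intervals are identical.
#'
#' @inheritParams overlap_bp
#' @return numeric vector of fractions in \code{[0, 1]}.
#' @export
reciprocal_overlap <- function(a, b) {
  ov <- overlap_bp(a, b)
  p <- recycle_pair(a, b)
  pmin(ov / (p$a$end - p$a$start), ov / (p$b$end - p$b$start))
}

#' Does one interval fully contain another?
#'
#' True iff both intervals are on the same chromosome and \code{outer}
#' encompasses \code{inner} end to end. Distinguishes genes a CNV
#' "encompasses" from genes it only partially disrupts.
#'
#' @param outer,inner interval tables; rows recycle as in [overlap_bp()].
#' @return logical vector.
#' @export
contains_fully <- function(outer, inner) {
  validate_intervals(outer, "contains_fully 'outer'")
  validate_intervals(inner, "contains_fully 'inner'")
  p <- recycle_pair(outer, inner)
  normalize_chrom(p$a$chrom) == normalize_chrom(p$b$chrom) &
    p$a$start <= p$b$start & p$a$end >= p$b$end
}

#' Merge adjacent CNV calls into single events
#'
#' Calls from the same sample, on the same chromosome (and of the same type
#' when \code{same_type = TRUE}), whose gap is at most \code{max_gap} bases
#' are merged into one call spanning both. Arrays sometimes split one
#' duplication into adjacent segments; event-level interpretation treats the
#' pair as a single CNV. Merging is idempotent and the output is sorted by
#' sample, chromosome and start.
#'
#' The merged call takes the copy number and type of its longest constituent,
#' sums probe counts (NA if any constituent's is missing) and keeps the
#' minimum confidence.
#'
#' @param calls a CNV call table (see [cnv_calls()]).
#' @param max_gap maximum gap in bases between mergeable calls; default
#'   50,000. Overlapping or book-ended calls always merge.
#' @param same_type if TRUE (default), only calls of the same
#'   deletion/duplication type merge.
#' @return merged CNV call table.
#' @export
merge_adjacent <- function(calls, max_gap = 50000, same_type = TRUE) {
  if (!is.numeric(max_gap) || length(max_gap) != 1L || is.na(max_gap) ||
      max_gap < 0) {
    stop("max_gap must be a single non-negative number", call. = FALSE)
  }
  validate_cnv_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  key <- paste(calls$sample_id, calls$chrom,
               if (same_type) calls$cnv_type else "", sep = "\r")
  pieces <- lapply(split(calls, key), function(g) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    grp <- integer(nrow(g))
    grp[1L] <- 1L
    if (nrow(g) > 1L) {
      hi <- g$end[1L]
      for (i in 2L:nrow(g)) {
        if (g$start[i] - hi <= max_gap) {
          grp[i] <- grp[i - 1L]
        } else {
          grp[i] <- grp[i - 1L] + 1L
        }
        hi <- max(hi, g$end[i])
      }
    }
    merged <- lapply(split(g, grp), function(m) {
      longest <- which.max(m$end - m$start)
      data.frame(
        sample_id = m$sample_id[1L],
        chrom = m$chrom[1L],
        start = min(m$start),
        end = max(m$end),
        copy_number = m$copy_number[longest],
        cnv_type = m$cnv_type[longest],
        n_probes = if (anyNA(m$n_probes)) NA_integer_ else sum(m$n_probes),
        confidence = if (all(is.na(m$confidence))) NA_real_
                     else min(m$confidence, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, merged)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample_id, out$chrom, out$start, out$end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a cytoband map
#'
#' Band coordinates used to render locus labels such as \code{"8p23.1"}.
#' Bands on one chromosome must tile without overlap.
#'
#' @param chrom,start,end band coordinates (0-based half-open).
#' @param band band label without the chromosome prefix (e.g. \code{"p23.1"}).
#' @return a sorted \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{band}.
#' @export
cytoband_map <- function(chrom, start, end, band) {
  x <- genomic_intervals(chrom, start, end)
  x$band <- as.character(band)
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  rownames(x) <- NULL
  for (ch in unique(x$chrom)) {
    b <- x[x$chrom == ch, , drop = FALSE]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)])) {
      stop(sprintf("cytoband map: overlapping bands on chromosome %s", ch),
           call. = FALSE)
    }
  }
  x
}

# Band label at a single position; position at a band boundary belongs to the
# following band (half-open convention).
band_at <- function(chrom, pos, bands) {
  hit <- bands$chrom == chrom & bands$start <= pos & pos < bands$end
  i <- which(hit)
  if (length(i) != 1L) {
    stop(sprintf("position %s:%d is outside the cytoband map", chrom, pos),
         call. = FALSE)
  }
  bands$band[i]
}

#' Cytogenetic label for an interval
#'
#' Returns \code{"<chrom><band>"} for an interval contained in one band, and
#' \code{"<chrom><band1> - <chrom><band2>"} when the start and the last
#' covered base fall in different bands (e.g. a duplication spanning
#' \code{3q13.33 - 3q21.2}).
#'
#' @param x interval table.
#' @param bands a [cytoband_map()].
#' @return character vector of labels; errors if an interval lies outside the
#'   map.
#' @export
cytoband_label <- function(x, bands) {
  validate_intervals(x, "cytoband_label")
  vapply(seq_len(nrow(x)), function(i) {
    ch <- normalize_chrom(x$chrom[i])
    b1 <- band_at(ch, x$start[i], bands)
    b2 <- band_at(ch, x$end[i] - 1, bands)
    if (identical(b1, b2)) paste0(ch, b1)
    else paste0(ch, b1, " - ", ch, b2)
  }, character(1L))
}
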