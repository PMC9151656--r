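# Per-sample SV burden summaries, subgroup comparison, translocation hotspot
# binning, elbow-based high-burden stratification, and paired-timepoint event
# diffing.

#' Summarize SV burden for one sample
#'
#' @param junctions Junction table restricted to one sample/timepoint.
#' @param sample_id Sample label; required when `junctions` is empty.
#' @return A one-row data.table: sample_id, n_total, n_intra, n_inter.
#' @export
summarize_sample <- function(junctions, sample_id = NULL) {
  j <- data.table::as.data.table(junctions)
  if (nrow(j) > 0L) {
    ids <- unique(j$sample_id)
    if (length(ids) > 1L) stopf("junctions from multiple samples: %s",
                                paste(ids, collapse = ", "))
    if (is.null(sample_id)) sample_id <- ids
    if (sample_id != ids) stopf("sample_id mismatch")
  }
  if (is.null(sample_id)) stopf("sample_id required for an empty junction set")
  n_inter <- sum(j$chrom1 != j$chrom2)
  data.table::data.table(sample_id = sample_id, n_total = nrow(j),
                         n_intra = nrow(j) - n_inter, n_inter = n_inter)
}

#' Summarize SV burden for a cohort
#'
#' @param junctions Junction table for the whole cohort.
#' @param sample_ids Optional full cohort roster, so samples without any
#'   junction get an all-zero row.
#' @return One row per sample (see [summarize_sample()]).
#' @export
summarize_cohort <- function(junctions, sample_ids = NULL) {
  j <- data.table::as.data.table(junctions)
  ids <- sample_ids %||% sort(unique(j$sample_id))
  data.table::rbindlist(lapply(ids, function(s) {
    summarize_sample(j[sample_id == s], sample_id = s)
  }))
}

#' Compare SV burden between sample groups
#'
#' Kruskal-Wallis rank test on total SV count across two or more groups.
#'
#' @param summaries Output of [summarize_cohort()].
#' @param labels Named character vector mapping sample_id to group label.
#' @return List with `statistic` (H), `p.value`, `df`, `method`.
#' @export
compare_burden <- function(summaries, labels) {
  s <- data.table::as.data.table(summaries)
  g <- labels[s$sample_id]
  if (any(is.na(g))) stopf("samples without a group label: %s",
                           paste(utils::head(s$sample_id[is.na(g)], 5), collapse = ", "))
  tab <- table(g)
  if (length(tab) < 2L) stopf("need >= 2 groups")
  if (any(tab == 0L)) stopf("empty group")
  kt <- stats::kruskal.test(s$n_total, factor(g))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter), method = kt$method)
}

#' Bin translocation breakends along the genome
#'
#' Tiles every chromosome into `bin_size` windows and counts, per bin, the
#' distinct samples with at least one TRA breakend in the bin (`n_samples`;
#' a sample with several breakends in one bin counts once) as well as the raw
#' breakend incidences (`n_breakends`). Both breakends of every TRA junction
#' are counted.
#'
#' @param junctions Cohort junction table.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return A data.table of bins: chrom, start, end, n_samples, n_breakends.
#' @export
bin_translocation_breakends <- function(junctions, chrom_lengths, bin_size = 1e6) {
  if (bin_size <= 0) stopf("bin_size must be positive")
  bins <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + bin_size, len))
  }))
  j <- data.table::as.data.table(junctions)[svclass == "TRA"]
  if (nrow(j) > 0L) {
    be <- breakends_long(j)
    unknown <- !(be$chrom %in% names(chrom_lengths))
    if (any(unknown)) stopf("breakend on chromosome absent from lengths: %s",
                            be$chrom[unknown][1])
    if (any(be$pos >= chrom_lengths[be$chrom] | be$pos < 0)) {
      bad <- be[be$pos >= chrom_lengths[be$chrom] | be$pos < 0][1]
      stopf("breakend beyond chromosome length: %s:%d", bad$chrom, bad$pos)
    }
    be[, bin := floor(pos / bin_size) * bin_size]
    cnt <- be[, list(n_samples = data.table::uniqueN(sample_id),
                     n_breakends = .N), by = list(chrom, bin)]
    bins <- merge(bins, cnt, by.x = c("chrom", "start"),
                  by.y = c("chrom", "bin"), all.x = TRUE)
  }
  if (!"n_samples" %in% names(bins)) bins[, `:=`(n_samples = 0L, n_breakends = 0L)]
  bins[is.na(n_samples), `:=`(n_samples = 0L, n_breakends = 0L)]
  data.table::setorder(bins, chrom, start)
  bins[]
}

#' Call translocation hotspots against a uniform genome-wide null
#'
#' The null success probability is the mean per-bin fraction of samples hit:
#' `p0 = sum(n_samples) / (n_bins * n_cohort)`. Each bin gets a one-sided
#' binomial tail p-value for excess over expectation (bins at or below the
#' expected count get p = 1), then Benjamini-Hochberg across bins; a hotspot
#' is a bin with q < alpha.
#'
#' @param bins Output of [bin_translocation_breakends()].
#' @param n_cohort Number of samples in the cohort.
#' @param alpha FDR level (default 0.05).
#' @return `bins` with added columns expected, p, q, is_hotspot.
#' @export
call_hotspots <- function(bins, n_cohort, alpha = 0.05) {
  if (n_cohort <= 0) stopf("n_cohort must be positive")
  b <- data.table::copy(data.table::as.data.table(bins))
  p0 <- sum(b$n_samples) / (nrow(b) * n_cohort)
  expected <- n_cohort * p0
  p <- ifelse(b$n_samples <= expected, 1,
              stats::pbinom(b$n_samples - 1L, n_cohort, p0, lower.tail = FALSE))
  b[, `:=`(expected = expected, p = p, q = stats::p.adjust(p, method = "BH"))]
  b[, is_hotspot := q < alpha]
  b[]
}

#' Split a cohort into high- and low-SV-burden groups by an elbow test
#'
#' Counts are sorted in descending order; the elbow is the index of the point
#' with maximal perpendicular distance to the chord joining the first and last
#' points of the sorted curve. Samples with counts strictly above the elbow
#' count are "high"; ties go low. Deterministic, order-invariant, and
#' scale-free (multiplying all counts by a positive constant does not move the
#' elbow).
#'
#' @param counts Named numeric vector of per-sample SV totals (names = sample
#'   ids).
#' @return List with `threshold` (count at the elbow), `high_ids`, `low_ids`,
#'   `elbow_index` on the sorted curve.
#' @export
elbow_split <- function(counts) {
  if (length(counts) < 3L) stopf("elbow test needs >= 3 samples")
  if (is.null(names(counts))) names(counts) <- paste0("s", seq_along(counts))
  y <- sort(counts, decreasing = TRUE)
  n <- length(y)
  x <- seq_len(n)
  # distance from (x_i, y_i) to the line through (1, y1) and (n, yn)
  dy <- y[n] - y[1]; dx <- n - 1
  d <- abs(dy * x - dx * y + dx * y[1] - dy * 1)  # / sqrt(dx^2+dy^2), common factor
  elbow <- which.max(d)
  threshold <- unname(y[elbow])
  high <- names(counts)[counts > threshold]
  list(threshold = threshold,
       high_ids = high,
       low_ids = setdiff(names(counts), high),
       elbow_index = unname(elbow))
}

# ---- paired-timepoint diff ---------------------------------------------------

# do two junction rows represent the same junction within tol bp?
junction_pair_matches <- function(j1, j2, tol) {
  direct <- j1$chrom1 == j2$chrom1 && j1$chrom2 == j2$chrom2 &&
    abs(j1$pos1 - j2$pos1) <= tol && abs(j1$pos2 - j2$pos2) <= tol
  crossed <- j1$chrom1 == j2$chrom2 && j1$chrom2 == j2$chrom1 &&
    abs(j1$pos1 - j2$pos2) <= tol && abs(j1$pos2 - j2$pos1) <= tol
  direct || crossed
}

# events: data.table with event_id and list-column junction_ids;
# junctions: the corresponding junction tables
event_pair_matches <- function(ids1, ids2, junctions1, junctions2, tol) {
  if (length(ids1) > length(ids2)) {  # symmetric: rule is on the smaller event
    tmp <- ids1; ids1 <- ids2; ids2 <- tmp
    tmpj <- junctions1; junctions1 <- junctions2; junctions2 <- tmpj
  }
  if (length(ids1) == 0L) return(FALSE)
  j1 <- junctions1[junctions1$id %in% ids1, ]
  j2 <- junctions2[junctions2$id %in% ids2, ]
  n_matched <- 0L
  for (a in seq_len(nrow(j1))) {
    hit <- FALSE
    for (b in seq_len(nrow(j2))) {
      if (junction_pair_matches(j1[a, ], j2[b, ], tol)) { hit <- TRUE; break }
    }
    if (hit) n_matched <- n_matched + 1L
  }
  n_matched / nrow(j1) >= 0.5
}

#' Compare complex events between two timepoints of one patient
#'
#' Two events match when at least half of the smaller event's junctions have a
#' counterpart (both breakends within `tolerance` bp, chromosomes equal, either
#' breakend pairing) in the other event. The match predicate is symmetric, so
#' `gained(t1, t2)` equals `lost(t2, t1)`. An event that acquires extra
#' junctions at the second timepoint (e.g. a two-chromosome chain growing a
#' third arm) is therefore reported stable, not gained.
#'
#' @param events_t1,events_t2 Complex event tables (see
#'   [call_complex_events()]) for the two timepoints.
#' @param junctions_t1,junctions_t2 The junction tables the events refer to.
#' @param tolerance Breakpoint match tolerance in bp (default 1 kb).
#' @return List with character vectors `stable_t1`, `stable_t2`, `gained`
#'   (event ids only at t2), `lost` (only at t1), and a data.table `pairs` of
#'   matched event id pairs.
#' @export
diff_timepoints <- function(events_t1, events_t2, junctions_t1, junctions_t2,
                            tolerance = 1000) {
  e1 <- data.table::as.data.table(events_t1)
  e2 <- data.table::as.data.table(events_t2)
  pairs <- list()
  m1 <- rep(FALSE, nrow(e1)); m2 <- rep(FALSE, nrow(e2))
  if (nrow(e1) > 0L && nrow(e2) > 0L) {
    for (a in seq_len(nrow(e1))) for (b in seq_len(nrow(e2))) {
      if (event_pair_matches(e1$junction_ids[[a]], e2$junction_ids[[b]],
                             junctions_t1, junctions_t2, tolerance)) {
        m1[a] <- TRUE; m2[b] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.table::data.table(
          event_t1 = e1$event_id[a], event_t2 = e2$event_id[b])
      }
    }
  }
  list(
    stable_t1 = e1$event_id[m1],
    stable_t2 = e2$event_id[m2],
    gained = e2$event_id[!m2],
    lost = e1$event_id[!m1],
    pairs = if (length(pairs)) data.table::rbindlist(pairs) else
      data.table::data.table(event_t1 = character(), event_t2 = character())
  )
}
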