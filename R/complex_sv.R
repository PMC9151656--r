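# Per-sample junction graph, chained candidate extraction, and classification
# of complex events as chromothripsis, chromoplexy or templated insertion.
#
# Definitions implemented:
#  - chromothripsis: localized clustered rearrangements with copy-number
#    oscillation between two dominant states and loss of heterozygosity;
#  - chromoplexy: chained rearrangements whose bridge segments (intervals
#    between chained breakends on one chromosome) show copy-number LOSS;
#  - templated insertion: chained rearrangements with copy-number GAIN bridges
#    ("complex" flavour when more than two chromosomes are involved).

#' Default parameters for complex event calling
#'
#' @param w_chain Chaining window, bp: two junctions are chained when they have
#'   breakends on the same chromosome within this distance.
#' @param min_junctions Minimum junctions for a candidate event.
#' @param min_breakends Minimum breakends in a cluster for chromothripsis.
#' @param window Maximum gap between adjacent breakends of one cluster, bp.
#' @param min_oscillations Minimum copy-number oscillations (transitions
#'   between the two dominant CN states) across the cluster span.
#' @param require_loh Require loss of heterozygosity (a segment with
#'   minor_cn = 0 and total_cn >= 1) inside the cluster span.
#' @param flank Flank width used for the bridge copy-number baseline, bp.
#' @return A named list of parameters.
#' @export
complex_params <- function(w_chain = 1e6, min_junctions = 3L,
                           min_breakends = 10L, window = 5e7,
                           min_oscillations = 7L, require_loh = TRUE,
                           flank = 1e6) {
  stopifnot(w_chain > 0, min_junctions >= 1, min_breakends >= 1,
            window > 0, min_oscillations >= 0, flank > 0)
  list(w_chain = w_chain, min_junctions = as.integer(min_junctions),
       min_breakends = as.integer(min_breakends), window = window,
       min_oscillations = as.integer(min_oscillations),
       require_loh = isTRUE(require_loh), flank = flank)
}

# edge list between junction ids: two junctions are adjacent iff they have
# breakends on the same chromosome within w_chain bp. Sorted sweep per chrom.
junction_adjacency <- function(junctions, w_chain = 1e6) {
  j <- data.table::as.data.table(junctions)
  empty <- data.table::data.table(id1 = character(), id2 = character())
  if (nrow(j) < 2L) return(empty)
  be <- breakends_long(j)
  data.table::setorder(be, chrom, pos)
  edges <- list()
  for (ch in unique(be$chrom)) {
    v <- be[chrom == ch]
    n <- nrow(v)
    if (n < 2L) next
    lo <- 1L
    for (i in 2L:n) {
      while (v$pos[i] - v$pos[lo] > w_chain) lo <- lo + 1L
      if (lo < i) {
        others <- v$junction_id[lo:(i - 1L)]
        others <- others[others != v$junction_id[i]]
        if (length(others)) {
          edges[[length(edges) + 1L]] <- data.table::data.table(
            id1 = pmin(others, v$junction_id[i]),
            id2 = pmax(others, v$junction_id[i]))
        }
      }
    }
  }
  if (!length(edges)) return(empty)
  unique(data.table::rbindlist(edges))
}

#' Build the per-sample junction graph
#'
#' Nodes are junctions; an edge joins two junctions when they each have a
#' breakend on the same chromosome within `w_chain` bp of one another.
#'
#' @param junctions Junction table for one sample.
#' @param w_chain Chaining window, bp (default 1 Mb).
#' @return An `igraph` graph whose vertex names are junction ids.
#' @export
build_junction_graph <- function(junctions, w_chain = 1e6) {
  if (w_chain <= 0) stopf("w_chain must be positive")
  j <- data.table::as.data.table(junctions)
  if (nrow(j) > 0L && length(unique(j$sample_id)) > 1L) {
    stopf("build_junction_graph expects junctions from one sample")
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(j), name = j$id)
  e <- junction_adjacency(j, w_chain)
  if (nrow(e) > 0L) g <- igraph::add_edges(g, rbind(e$id1, e$id2))
  g
}

#' Extract candidate complex events from a junction graph
#'
#' Connected components with at least `min_junctions` junctions become
#' candidates.
#'
#' @param graph Output of [build_junction_graph()].
#' @param junctions The junction table the graph was built from.
#' @param min_junctions Minimum component size (default 3).
#' @return A data.table, one candidate per row: event_id, sample_id,
#'   n_junctions, chroms (list), junction_ids (list).
#' @export
find_candidates <- function(graph, junctions, min_junctions = 3L) {
  j <- data.table::as.data.table(junctions)
  out <- data.table::data.table(event_id = character(), sample_id = character(),
                                n_junctions = integer(),
                                chroms = list(), junction_ids = list())
  if (igraph::vcount(graph) == 0L) return(out)
  comp <- igraph::components(graph)
  keep <- which(comp$csize >= min_junctions)
  if (!length(keep)) return(out)
  nm <- igraph::V(graph)$name
  rows <- lapply(seq_along(keep), function(k) {
    ids <- sort(nm[comp$membership == keep[k]])
    sub <- j[id %in% ids]
    data.table::data.table(
      event_id = sprintf("%s_ev%02d", sub$sample_id[1], k),
      sample_id = sub$sample_id[1],
      n_junctions = length(ids),
      chroms = list(sort(unique(c(sub$chrom1, sub$chrom2)))),
      junction_ids = list(ids))
  })
  data.table::rbindlist(rows)
}

#' Extract copy-number bridges of a candidate event
#'
#' For each chromosome touched by the event, adjacent breakends (in position
#' order) that belong to different junctions and lie within `w_chain` bp define
#' a bridge interval. The bridge's `cn_delta` is the overlap-weighted modal
#' total copy number inside the interval minus the modal total copy number of
#' the two flanking `flank`-bp regions (clipped at position 0); its kind is
#' `del`, `gain` or `neutral` by the sign of `cn_delta`.
#'
#' @param junction_ids Ids of the event's junctions.
#' @param junctions Junction table for the sample.
#' @param cn CN segment table for the sample.
#' @param w_chain,flank See [complex_params()].
#' @return A data.table of bridges: chrom, start, end, cn_bridge, cn_flank,
#'   cn_delta, kind.
#' @export
extract_bridges <- function(junction_ids, junctions, cn,
                            w_chain = 1e6, flank = 1e6) {
  j <- data.table::as.data.table(junctions)[id %in% junction_ids]
  cn <- data.table::as.data.table(cn)
  be <- breakends_long(j)
  data.table::setorder(be, chrom, pos)
  out <- list()
  for (ch in unique(be$chrom)) {
    v <- be[chrom == ch]
    cnc <- cn[chrom == ch]
    uncov <- !cn_covers(cnc, v$pos)
    if (any(uncov)) stopf("breakend outside CN coverage at %s:%d",
                          ch, as.integer(v$pos[uncov][1]))
    if (nrow(v) < 2L) next
    for (i in seq_len(nrow(v) - 1L)) {
      a <- v$pos[i]; b <- v$pos[i + 1L]
      if (v$junction_id[i] == v$junction_id[i + 1L]) next
      if (b - a > w_chain || b == a) next
      cn_bridge <- modal_cn(cnc, a, b)
      # flanking baseline: weighted mode over both flank windows combined
      left <- cnc[cnc$end > max(0, a - flank) & cnc$start < a]
      right <- cnc[cnc$end > b & cnc$start < b + flank]
      fl <- data.table::rbindlist(list(
        data.table::data.table(start = pmax(left$start, a - flank),
                               end = pmin(left$end, a),
                               total_cn = left$total_cn),
        data.table::data.table(start = pmax(right$start, b),
                               end = pmin(right$end, b + flank),
                               total_cn = right$total_cn)))
      cn_flank <- if (nrow(fl)) modal_cn(fl, min(fl$start), max(fl$end)) else NA_real_
      delta <- cn_bridge - cn_flank
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = ch, start = a, end = b,
        cn_bridge = cn_bridge, cn_flank = cn_flank, cn_delta = delta,
        kind = if (is.na(delta) || delta == 0) "neutral" else if (delta < 0) "del" else "gain")
    }
  }
  if (!length(out)) {
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), cn_bridge = numeric(),
                                  cn_flank = numeric(), cn_delta = numeric(),
                                  kind = character()))
  }
  data.table::rbindlist(out)
}

#' Count copy-number oscillations over an ordered segment run
#'
#' `n_cn_states` is the number of distinct total copy numbers. The two most
#' frequent states (by segment count; ties broken toward the smaller copy
#' number) define the oscillation set: `n_oscillations` counts the
#' adjacent-segment transitions whose two values both lie in that set and
#' differ — a transition through any other state breaks the run and is not
#' counted. `has_loh` flags any segment with minor_cn = 0 and total_cn >= 1.
#'
#' @param segments Data frame of positionally ordered, non-overlapping CN
#'   segments with columns total_cn and minor_cn.
#' @return List with n_oscillations, n_cn_states, has_loh.
#' @export
count_oscillations <- function(segments) {
  s <- data.table::as.data.table(segments)
  if (nrow(s) == 0L) {
    return(list(n_oscillations = 0L, n_cn_states = 0L, has_loh = FALSE))
  }
  cnv <- s$total_cn
  states <- sort(unique(cnv))
  freq <- vapply(states, function(v) sum(cnv == v), integer(1))
  ord <- order(-freq, states)
  top2 <- states[ord][seq_len(min(2L, length(states)))]
  osc <- 0L
  if (length(cnv) > 1L) {
    for (i in seq_len(length(cnv) - 1L)) {
      a <- cnv[i]; b <- cnv[i + 1L]
      if (a %in% top2 && b %in% top2 && a != b) osc <- osc + 1L
    }
  }
  list(n_oscillations = osc, n_cn_states = length(states),
       has_loh = any(s$minor_cn == 0 & s$total_cn >= 1))
}

#' Detect chromothripsis regions in one sample
#'
#' Breakends on each chromosome are grouped into maximal clusters in which
#' adjacent breakends are at most `window` bp apart. A cluster is called
#' chromothripsis when it has at least `min_breakends` breakends, the CN
#' segments overlapping its span oscillate at least `min_oscillations` times
#' between the two dominant CN states, and (if `require_loh`) the span contains
#' LOH.
#'
#' @param junctions Junction table for one sample.
#' @param cn CN segment table for the sample.
#' @param params See [complex_params()].
#' @return A data.table of clusters with metrics and a logical `called` column;
#'   chromothripsis regions are the called rows.
#' @export
detect_chromothripsis <- function(junctions, cn, params = complex_params()) {
  j <- data.table::as.data.table(junctions)
  cn <- data.table::as.data.table(cn)
  out <- data.table::data.table(
    sample_id = character(), chrom = character(), start = numeric(),
    end = numeric(), n_breakends = integer(), n_oscillations = integer(),
    n_cn_states = integer(), has_loh = logical(), called = logical())
  if (nrow(j) == 0L) return(out)
  be <- breakends_long(j)
  data.table::setorder(be, chrom, pos)
  rows <- list()
  for (ch in unique(be$chrom)) {
    v <- be[chrom == ch]
    gaps <- diff(v$pos)
    cl <- cumsum(c(0, gaps > params$window))
    for (k in unique(cl)) {
      p <- v$pos[cl == k]
      if (length(p) < params$min_breakends) next
      span <- c(min(p), max(p))
      seg <- cn[chrom == ch & end > span[1] & start <= span[2]]
      data.table::setorder(seg, start)
      m <- count_oscillations(seg)
      called <- m$n_oscillations >= params$min_oscillations &&
        (!params$require_loh || m$has_loh)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        sample_id = v$sample_id[1], chrom = ch, start = span[1], end = span[2],
        n_breakends = length(p), n_oscillations = m$n_oscillations,
        n_cn_states = m$n_cn_states, has_loh = m$has_loh, called = called)
    }
  }
  if (length(rows)) data.table::rbindlist(rows) else out
}

# oscillation metrics over the event's own breakend spans (max over chroms)
event_oscillation_metrics <- function(junction_ids, junctions, cn) {
  j <- data.table::as.data.table(junctions)[id %in% junction_ids]
  cn <- data.table::as.data.table(cn)
  be <- breakends_long(j)
  n_osc <- 0L; n_states <- 0L; loh <- FALSE
  for (ch in unique(be$chrom)) {
    p <- be$pos[be$chrom == ch]
    seg <- cn[chrom == ch & end > min(p) & start <= max(p)]
    data.table::setorder(seg, start)
    m <- count_oscillations(seg)
    n_osc <- max(n_osc, m$n_oscillations)
    n_states <- max(n_states, m$n_cn_states)
    loh <- loh || m$has_loh
  }
  list(n_oscillations = n_osc, n_cn_states = n_states, has_loh = loh)
}

#' Classify one candidate event
#'
#' Precedence: (1) if at least half of the candidate's junctions have a
#' breakend inside a called chromothripsis region, the event is
#' `chromothripsis` (chromothripsis regions generate incidental bridges, so
#' they are claimed first); (2) else if deletion bridges outnumber gain bridges
#' and there are at least two, `chromoplexy`; (3) else if gain bridges
#' outnumber deletion bridges and there are at least two,
#' `templated_insertion`; (4) else `unclassified_complex`. Templated insertions
#' involving more than two chromosomes are the "complex" flavour; two-chromosome
#' chains carry `simple_chain = TRUE`.
#'
#' @param candidate One row of [find_candidates()] output.
#' @param junctions,cn Sample junction and CN tables.
#' @param ct_calls Output of [detect_chromothripsis()] for the sample.
#' @param params See [complex_params()].
#' @return A one-row data.table with label and metrics.
#' @export
classify_event <- function(candidate, junctions, cn, ct_calls,
                           params = complex_params()) {
  ids <- candidate$junction_ids[[1]]
  j <- data.table::as.data.table(junctions)[id %in% ids]
  regions <- data.table::as.data.table(ct_calls)
  regions <- regions[regions$called == TRUE, ]

  in_region <- function(ch, p) {
    nrow(regions) > 0L &&
      any(regions$chrom == ch & regions$start <= p & regions$end >= p)
  }
  n_in <- sum(vapply(seq_len(nrow(j)), function(i) {
    in_region(j$chrom1[i], j$pos1[i]) || in_region(j$chrom2[i], j$pos2[i])
  }, logical(1)))

  bridges <- extract_bridges(ids, junctions, cn,
                             w_chain = params$w_chain, flank = params$flank)
  # bridges inside a called chromothripsis region are that region's
  # oscillation, not chain bridges; exclude them from the del/gain tally
  if (nrow(bridges) > 0L && nrow(regions) > 0L) {
    in_ct <- vapply(seq_len(nrow(bridges)), function(i) {
      any(regions$chrom == bridges$chrom[i] &
            regions$start <= bridges$end[i] & regions$end >= bridges$start[i])
    }, logical(1))
    bridges <- bridges[!in_ct, ]
  }
  n_del <- sum(bridges$kind == "del")
  n_gain <- sum(bridges$kind == "gain")
  n_neutral <- sum(bridges$kind == "neutral")
  osc <- event_oscillation_metrics(ids, junctions, cn)

  label <- if (n_in / nrow(j) >= 0.5) "chromothripsis"
  else if (n_del > n_gain && n_del >= 2L) "chromoplexy"
  else if (n_gain > n_del && n_gain >= 2L) "templated_insertion"
  else "unclassified_complex"

  chroms <- candidate$chroms[[1]]
  data.table::data.table(
    event_id = candidate$event_id, sample_id = candidate$sample_id,
    label = label, n_junctions = candidate$n_junctions,
    n_chroms = length(chroms),
    simple_chain = label == "templated_insertion" && length(chroms) <= 2L,
    n_oscillations = osc$n_oscillations, n_cn_states = osc$n_cn_states,
    has_loh = osc$has_loh,
    n_del_bridges = n_del, n_gain_bridges = n_gain,
    n_neutral_bridges = n_neutral,
    chroms = list(chroms), junction_ids = list(ids))
}

#' Call and classify all complex events in one sample
#'
#' Orchestrates graph construction, candidate extraction, chromothripsis region
#' detection and classification. Every junction belongs to at most one event
#' (connected components are disjoint).
#'
#' @param junctions Junction table for one sample.
#' @param cn CN segment table for the sample.
#' @param params See [complex_params()].
#' @return List with `events` (classified event table), `ct_regions`
#'   (chromothripsis cluster table) and `flags` (one-row table of per-sample
#'   has_chromothripsis / has_chromoplexy / has_templated_insertion).
#' @export
call_complex_events <- function(junctions, cn, params = complex_params()) {
  j <- data.table::as.data.table(junctions)
  sid <- if (nrow(j)) unique(j$sample_id) else NA_character_
  if (length(sid) > 1L) stopf("call_complex_events expects one sample")
  g <- build_junction_graph(j, params$w_chain)
  cand <- find_candidates(g, j, params$min_junctions)
  ct <- detect_chromothripsis(j, cn, params)
  events <- if (nrow(cand)) {
    data.table::rbindlist(lapply(seq_len(nrow(cand)), function(i) {
      classify_event(cand[i], j, cn, ct, params)
    }))
  } else {
    data.table::data.table(
      event_id = character(), sample_id = character(), label = character(),
      n_junctions = integer(), n_chroms = integer(), simple_chain = logical(),
      n_oscillations = integer(), n_cn_states = integer(), has_loh = logical(),
      n_del_bridges = integer(), n_gain_bridges = integer(),
      n_neutral_bridges = integer(), chroms = list(), junction_ids = list())
  }
  flags <- data.table::data.table(
    sample_id = sid,
    # chromothripsis is a region-level call: a sample carries it when a
    # breakend cluster passes the gate, whether or not the surrounding chained
    # component is majority-chromothriptic
    has_chromothripsis = any(events$label == "chromothripsis") ||
      any(ct$called),
    has_chromoplexy = any(events$label == "chromoplexy"),
    has_templated_insertion = any(events$label == "templated_insertion"))
  list(events = events, ct_regions = ct, flags = flags)
}

#' Call complex events across a cohort
#'
#' @param junctions Cohort junction table.
#' @param cn Cohort CN segment table.
#' @param params See [complex_params()].
#' @param sample_ids Optional roster including junction-free samples.
#' @return List with pooled `events` and per-sample `flags` tables.
#' @export
call_complex_events_cohort <- function(junctions, cn, params = complex_params(),
                                       sample_ids = NULL) {
  j <- data.table::as.data.table(junctions)
  cn <- data.table::as.data.table(cn)
  ids <- sample_ids %||% sort(unique(j$sample_id))
  ev <- list(); fl <- list()
  for (s in ids) {
    res <- call_complex_events(j[sample_id == s], cn[sample_id == s], params)
    res$flags$sample_id <- s
    ev[[s]] <- res$events; fl[[s]] <- res$flags
  }
  list(events = data.table::rbindlist(ev), flags = data.table::rbindlist(fl))
}
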