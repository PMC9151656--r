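# Mapping breakends to TADs, TAD-TAD rearrangement and neo-TAD detection, and
# the filtered two-group ANOVA + Benjamini-Hochberg scan that nominates genes
# dysregulated by TAD disruption.

TAD_BOUNDARY <- "boundary"  # position falls in an inter-TAD gap
TAD_NONE <- "no_tad"        # chromosome absent from the TAD set

#' Assign breakend positions to TADs
#'
#' Binary search per chromosome; containment is half-open (`start <= pos <
#' end`). Positions in inter-TAD gaps return the `"boundary"` sentinel;
#' positions on chromosomes with no TADs return `"no_tad"`.
#'
#' @param chrom,pos Vectors of breakend chromosomes and 0-based positions.
#' @param tads TAD table (see [read_tad_bed()]).
#' @return Character vector of tad ids / sentinels, one per position.
#' @export
assign_breakend_to_tad <- function(chrom, pos, tads) {
  t <- validate_tads(tads)
  out <- rep(TAD_NONE, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    tc <- t[t$chrom == ch, ]
    if (nrow(tc) == 0L) next
    idx <- findInterval(pos[sel], tc$start)  # last start <= pos
    hit <- idx >= 1L & ifelse(idx >= 1L, pos[sel] < tc$end[pmax(idx, 1L)], FALSE)
    out[sel] <- ifelse(hit, tc$tad_id[pmax(idx, 1L)], TAD_BOUNDARY)
  }
  out
}

#' Annotate junctions with their TAD assignments
#'
#' A TAD-TAD rearrangement is a junction whose two breakends fall inside two
#' different real TADs; junctions touching an inter-TAD gap or a TAD-less
#' chromosome are kept but flagged (`has_sentinel`) and excluded from the
#' TAD-TAD set.
#'
#' @param junctions Cohort junction table.
#' @param tads TAD table.
#' @return The junction table with added columns tad_a, tad_b, same_tad,
#'   has_sentinel, is_tad_tad.
#' @export
find_tad_rearrangements <- function(junctions, tads) {
  j <- data.table::as.data.table(junctions)
  if (nrow(j) == 0L) {
    j[, `:=`(tad_a = character(), tad_b = character(), same_tad = logical(),
             has_sentinel = logical(), is_tad_tad = logical())]
    return(j)
  }
  ta <- assign_breakend_to_tad(j$chrom1, j$pos1, tads)
  tb <- assign_breakend_to_tad(j$chrom2, j$pos2, tads)
  sent <- ta %in% c(TAD_BOUNDARY, TAD_NONE) | tb %in% c(TAD_BOUNDARY, TAD_NONE)
  j[, `:=`(tad_a = ta, tad_b = tb,
           same_tad = ta == tb & !sent,
           has_sentinel = sent,
           is_tad_tad = !sent & ta != tb)]
  j[]
}

#' Enumerate neo-TADs from TAD-TAD junctions
#'
#' Each TAD-TAD junction fuses the retained interval of its first TAD with the
#' retained interval of the second: a `head` breakend retains
#' `[tad.start, pos)`, a `tail` breakend retains `[pos, tad.end)`. `genes_ab`
#' lists the genes overlapping either retained interval.
#'
#' @param tad_junctions Output of [find_tad_rearrangements()].
#' @param tads TAD table.
#' @param genes Gene table (see [read_gene_bed()]).
#' @return A data.table, one neo-TAD per TAD-TAD junction, with retained
#'   intervals and a `genes_ab` list-column.
#' @export
enumerate_neo_tads <- function(tad_junctions, tads, genes) {
  j <- data.table::as.data.table(tad_junctions)
  j <- j[j$is_tad_tad == TRUE, ]
  t <- data.table::as.data.table(tads)
  g <- data.table::as.data.table(genes)
  if (nrow(j) > 0L && (any(is.na(j$orient1)) || any(is.na(j$orient2)))) {
    stopf("breakend orientation missing; neo-TADs need oriented junctions")
  }
  retained <- function(tid, pos, orient) {
    tt <- t[t$tad_id == tid, ]
    if (orient == "head") c(tt$start, pos) else c(pos, tt$end)
  }
  rows <- lapply(seq_len(nrow(j)), function(i) {
    ra <- retained(j$tad_a[i], j$pos1[i], j$orient1[i])
    rb <- retained(j$tad_b[i], j$pos2[i], j$orient2[i])
    cha <- t$chrom[t$tad_id == j$tad_a[i]]
    chb <- t$chrom[t$tad_id == j$tad_b[i]]
    ga <- g$gene_id[g$chrom == cha & g$start < ra[2] & g$end > ra[1]]
    gb <- g$gene_id[g$chrom == chb & g$start < rb[2] & g$end > rb[1]]
    data.table::data.table(
      neo_id = paste0("neo_", j$id[i]), junction_id = j$id[i],
      sample_id = j$sample_id[i],
      tad_a = j$tad_a[i], ret_a_start = ra[1], ret_a_end = ra[2],
      tad_b = j$tad_b[i], ret_b_start = rb[1], ret_b_end = rb[2],
      genes_ab = list(sort(unique(c(ga, gb)))))
  })
  if (!length(rows)) {
    return(data.table::data.table(
      neo_id = character(), junction_id = character(), sample_id = character(),
      tad_a = character(), ret_a_start = numeric(), ret_a_end = numeric(),
      tad_b = character(), ret_b_start = numeric(), ret_b_end = numeric(),
      genes_ab = list()))
  }
  data.table::rbindlist(rows)
}

#' Partition the cohort into carriers and controls per TAD
#'
#' A sample carries TAD T when it has at least one TAD-TAD junction touching T
#' (on either side); all other samples are controls. For every TAD the two
#' sets are disjoint and their union is the cohort.
#'
#' @param tad_junctions Output of [find_tad_rearrangements()].
#' @param all_samples Character vector: the full cohort.
#' @return A data.table: tad_id, n_carrier, carriers (list), controls (list).
#' @export
group_samples_by_tad <- function(tad_junctions, all_samples) {
  j <- data.table::as.data.table(tad_junctions)
  j <- j[j$is_tad_tad == TRUE, ]
  touched <- data.table::rbindlist(list(
    j[, list(tad_id = tad_a, sample_id)],
    j[, list(tad_id = tad_b, sample_id)]))
  touched <- unique(touched)
  tids <- sort(unique(touched$tad_id))
  rows <- lapply(tids, function(tid) {
    carriers <- sort(unique(touched$sample_id[touched$tad_id == tid]))
    data.table::data.table(tad_id = tid, n_carrier = length(carriers),
                           carriers = list(carriers),
                           controls = list(setdiff(all_samples, carriers)))
  })
  if (!length(rows)) {
    return(data.table::data.table(tad_id = character(), n_carrier = integer(),
                                  carriers = list(), controls = list()))
  }
  data.table::rbindlist(rows)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stopf("p-value outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# two-group one-way ANOVA p-value with degenerate-input handling:
# identical constant groups -> p = 1; zero within-group variance with
# different means -> p = 0.
anova_p <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2L || any(table(g) < 2L)) return(NA_real_)
  if (stats::var(x) == 0) return(1)
  means <- tapply(x, g, mean)
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  if (ssw == 0) return(if (diff(range(means)) == 0) 1 else 0)
  ot <- stats::oneway.test(x ~ g, var.equal = TRUE)
  unname(ot$p.value)
}

#' Map genes to the TADs they overlap
#'
#' @param genes Gene table.
#' @param tads TAD table.
#' @return A data.table (tad_id, gene_id); a boundary-spanning gene may map to
#'   two TADs.
#' @export
genes_in_tads <- function(genes, tads) {
  g <- data.table::as.data.table(genes)
  t <- data.table::as.data.table(tads)
  rows <- lapply(seq_len(nrow(t)), function(i) {
    hit <- g$chrom == t$chrom[i] & g$start < t$end[i] & g$end > t$start[i]
    if (!any(hit)) return(NULL)
    data.table::data.table(tad_id = t$tad_id[i], gene_id = g$gene_id[hit])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.table::data.table(tad_id = character(),
                                                   gene_id = character()))
  data.table::rbindlist(rows)
}

#' Test genes within rearranged TADs for expression change
#'
#' For every (TAD, gene-in-TAD) pair with a computable two-group comparison, a
#' one-way ANOVA of carriers vs controls on log2 expression; BH adjustment is
#' applied across ALL tests in the run. A result passes the filters when the
#' TAD has at least `min_cases` carriers, the median expression exceeds
#' `min_median` in at least one group, and q < `alpha`. Genes with fewer than
#' `min_cases` carriers are still reported, marked failed.
#'
#' @param expr Expression matrix (genes x samples, log2 scale).
#' @param partition Output of [group_samples_by_tad()].
#' @param gene_map Output of [genes_in_tads()].
#' @param min_cases Minimum carrier count (default 5).
#' @param min_median Minimum group median expression (default 2).
#' @param alpha FDR level (default 0.05).
#' @return A data.table of results: tad_id, gene_id, n_carrier, n_control,
#'   median_carrier, median_control, log2fc, p_anova, q, passes_filters.
#' @export
test_tad_genes <- function(expr, partition, gene_map, min_cases = 5L,
                           min_median = 2, alpha = 0.05) {
  part <- data.table::as.data.table(partition)
  gm <- data.table::as.data.table(gene_map)
  rows <- list()
  for (i in seq_len(nrow(part))) {
    tid <- part$tad_id[i]
    genes <- gm$gene_id[gm$tad_id == tid]
    if (!length(genes)) next
    carriers <- intersect(part$carriers[[i]], colnames(expr))
    controls <- intersect(part$controls[[i]], colnames(expr))
    for (gn in genes) {
      if (!gn %in% rownames(expr)) {
        warnf("gene %s absent from expression matrix; skipped", gn)
        next
      }
      xc <- expr[gn, carriers]; xo <- expr[gn, controls]
      p <- anova_p(c(xc, xo), rep(c("carrier", "control"), c(length(xc), length(xo))))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        tad_id = tid, gene_id = gn,
        n_carrier = length(xc), n_control = length(xo),
        median_carrier = stats::median(xc), median_control = stats::median(xo),
        log2fc = mean(xc) - mean(xo), p_anova = p)
    }
  }
  if (!length(rows)) {
    return(data.table::data.table(
      tad_id = character(), gene_id = character(), n_carrier = integer(),
      n_control = integer(), median_carrier = numeric(),
      median_control = numeric(), log2fc = numeric(), p_anova = numeric(),
      q = numeric(), passes_filters = logical()))
  }
  res <- data.table::rbindlist(rows)
  res$q <- bh_fdr(res$p_anova)
  res$passes_filters <- !is.na(res$q) & res$n_carrier >= min_cases &
    pmax(res$median_carrier, res$median_control) > min_median & res$q < alpha
  res
}

#' Full TAD-expression scan
#'
#' Convenience orchestration: TAD assignment, per-TAD carrier/control
#' partition, gene-TAD map, and the filtered ANOVA + BH scan.
#'
#' @inheritParams test_tad_genes
#' @param junctions Cohort junction table.
#' @param tads,genes TAD and gene tables.
#' @param all_samples Full cohort roster (defaults to the expression matrix's
#'   columns).
#' @return List with `results` ([test_tad_genes()] output), `tad_junctions`,
#'   `partition`, `neo_tads`.
#' @export
tad_gene_scan <- function(junctions, tads, genes, expr, all_samples = NULL,
                          min_cases = 5L, min_median = 2, alpha = 0.05) {
  all_samples <- all_samples %||% colnames(expr)
  tj <- find_tad_rearrangements(junctions, tads)
  part <- group_samples_by_tad(tj, all_samples)
  gm <- genes_in_tads(genes, tads)
  res <- test_tad_genes(expr, part, gm, min_cases = min_cases,
                        min_median = min_median, alpha = alpha)
  list(results = res, tad_junctions = tj, partition = part,
       neo_tads = enumerate_neo_tads(tj, tads, genes))
}

#' Within- vs outside-TAD boundary expression contrast for one gene
#'
#' Splits the cohort into samples with a breakend inside the gene's TAD
#' ("inside"), samples with a breakend within `flank` bp of the TAD but none
#' inside ("outside"; inside takes precedence for mixed samples), and the rest
#' ("none"), then tests the gene's expression across the groups with a
#' Kruskal-Wallis test.
#'
#' @param gene_id Gene to test.
#' @param junctions Cohort junction table.
#' @param tads,genes TAD and gene tables.
#' @param expr Expression matrix.
#' @param flank Flank width in bp (default 2 Mb).
#' @return List with the three sample sets, the containing `tad_id`, and `p`.
#' @export
boundary_contrast <- function(gene_id, junctions, tads, genes, expr,
                              flank = 2e6) {
  gid <- gene_id  # avoid data.table scoping against the gene_id column
  g <- data.table::as.data.table(genes)
  gi <- g[g$gene_id == gid, ]
  if (nrow(gi) == 0L) stopf("unknown gene: %s", gid)
  t <- data.table::as.data.table(tads)
  cand <- t[t$chrom == gi$chrom & t$start < gi$end & t$end > gi$start, ]
  if (nrow(cand) == 0L) stopf("gene %s lies in no TAD", gene_id)
  ov <- pmin(cand$end, gi$end) - pmax(cand$start, gi$start)
  tt <- cand[which.max(ov), ]

  be <- breakends_long(junctions)
  be <- be[be$chrom == tt$chrom, ]
  inside_ids <- unique(be$sample_id[be$pos >= tt$start & be$pos < tt$end])
  near <- be$pos >= tt$start - flank & be$pos < tt$end + flank &
    !(be$pos >= tt$start & be$pos < tt$end)
  outside_ids <- setdiff(unique(be$sample_id[near]), inside_ids)
  none_ids <- setdiff(colnames(expr), c(inside_ids, outside_ids))

  groups <- rep(c("inside", "outside", "none"),
                c(length(inside_ids), length(outside_ids), length(none_ids)))
  samples <- c(inside_ids, outside_ids, none_ids)
  keep <- samples %in% colnames(expr)
  x <- expr[gene_id, samples[keep]]
  gfac <- factor(groups[keep])
  p <- if (nlevels(droplevels(gfac)) >= 2L) {
    stats::kruskal.test(x, droplevels(gfac))$p.value
  } else NA_real_
  list(gene_id = gene_id, tad_id = tt$tad_id, inside_samples = inside_ids,
       outside_samples = outside_ids, none_samples = none_ids, p = p)
}
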