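# Seeded synthetic cohort generator: toy genome, TADs, genes, simple SV
# junctions, planted complex events with consistent CN segments, an expression
# matrix with TAD-linked effects, and the ground-truth record used by the
# recovery tests.

#' Parameters for the synthetic cohort generator
#'
#' Defaults emulate the structure of a newly diagnosed myeloma WGS cohort:
#' per-sample SV counts are negative binomial around a median of ~31 with a
#' ~10% high-burden subpopulation (~120 SVs), and complex events are planted in
#' 23% (chromothripsis), 10% (chromoplexy) and 37% (templated insertion) of
#' samples, at most one class per sample so recovery is unambiguous.
#'
#' @param seed Mandatory RNG seed.
#' @param n_samples Cohort size.
#' @param n_chroms,chrom_len Toy genome geometry (default 5 x 50 Mb).
#' @param tad_size TAD width, bp; TADs tile each chromosome with `tad_gap`
#'   inter-TAD boundary gaps.
#' @param tad_gap Gap between adjacent TADs, bp.
#' @param genes_per_tad Genes placed (evenly) in each TAD.
#' @param sv_mean,sv_size Negative-binomial mean/size of the simple SV count in
#'   low-burden samples.
#' @param sv_mean_high,sv_size_high Same for the high-burden subpopulation.
#' @param frac_high_burden Fraction of high-burden samples.
#' @param frac_tra Fraction of simple SVs that are translocations.
#' @param frac_chromothripsis,frac_chromoplexy,frac_ti Planted complex-event
#'   prevalences.
#' @param ct_breakends Breakends per planted chromothripsis event.
#' @param n_hijack_tads Number of TADs receiving planted enhancer-hijack
#'   translocations with an expression effect.
#' @param hijack_carriers Integer range (min, max) of carriers per hijack TAD.
#' @param effect_log2fc Planted expression effect, log2 units.
#' @param noise_sd,baseline_mean Expression noise SD and baseline (log2 scale).
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(seed, n_samples = 200L, n_chroms = 5L, chrom_len = 5e7,
                       tad_size = 1e6, tad_gap = 5e4, genes_per_tad = 3L,
                       sv_mean = 31, sv_size = 10, sv_mean_high = 120,
                       sv_size_high = 8, frac_high_burden = 0.10,
                       frac_tra = 0.2, frac_chromothripsis = 0.23,
                       frac_chromoplexy = 0.10, frac_ti = 0.37,
                       ct_breakends = 16L, n_hijack_tads = 5L,
                       hijack_carriers = c(6L, 12L), effect_log2fc = 2,
                       noise_sd = 1, baseline_mean = 5) {
  if (missing(seed)) stopf("seed is mandatory")
  fr <- c(frac_high_burden, frac_tra, frac_chromothripsis, frac_chromoplexy,
          frac_ti)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  if (frac_chromothripsis + frac_chromoplexy + frac_ti > 1) {
    stopf("complex-event fractions sum to > 1")
  }
  if (tad_size > chrom_len) stopf("infeasible geometry: tad_size > chrom_len")
  p <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
            n_chroms = as.integer(n_chroms), chrom_len = chrom_len,
            tad_size = tad_size, tad_gap = tad_gap,
            genes_per_tad = as.integer(genes_per_tad),
            sv_mean = sv_mean, sv_size = sv_size,
            sv_mean_high = sv_mean_high, sv_size_high = sv_size_high,
            frac_high_burden = frac_high_burden, frac_tra = frac_tra,
            frac_chromothripsis = frac_chromothripsis,
            frac_chromoplexy = frac_chromoplexy, frac_ti = frac_ti,
            ct_breakends = as.integer(ct_breakends),
            n_hijack_tads = as.integer(n_hijack_tads),
            hijack_carriers = as.integer(hijack_carriers),
            effect_log2fc = effect_log2fc, noise_sd = noise_sd,
            baseline_mean = baseline_mean)
  class(p) <- "sim_params"
  p
}

#' Draw per-sample simple-SV counts from the burden mixture
#'
#' @param n_samples Number of samples.
#' @param params A [sim_params()] object (the RNG stream of the caller is
#'   used; seed externally or via [simulate_cohort()]).
#' @return A data.table: sample_id, burden_class, n_sv.
#' @export
simulate_sv_counts <- function(n_samples, params) {
  high <- runif(n_samples) < params$frac_high_burden
  n <- ifelse(high,
              rnbinom(n_samples, size = params$sv_size_high, mu = params$sv_mean_high),
              rnbinom(n_samples, size = params$sv_size, mu = params$sv_mean))
  data.table::data.table(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    burden_class = ifelse(high, "high", "low"),
    n_sv = as.integer(n))
}

# toy genome TADs and genes (deterministic geometry, no RNG draws)
simulate_genome <- function(params) {
  chroms <- paste0("chr", seq_len(params$n_chroms))
  chrom_lengths <- stats::setNames(rep(params$chrom_len, params$n_chroms), chroms)
  tads <- list(); genes <- list()
  for (ci in seq_along(chroms)) {
    n_tads <- floor(params$chrom_len / params$tad_size)
    starts <- (seq_len(n_tads) - 1) * params$tad_size
    ends <- starts + params$tad_size - params$tad_gap
    ids <- sprintf("tad_%d_%03d", ci, seq_len(n_tads))
    tads[[ci]] <- data.table::data.table(
      tad_id = ids, chrom = chroms[ci], start = starts, end = ends,
      source = "synthetic")
    glen <- 1e4
    for (gi in seq_len(params$genes_per_tad)) {
      gs <- starts + round(gi * (ends - starts) / (params$genes_per_tad + 1))
      genes[[length(genes) + 1L]] <- data.table::data.table(
        gene_id = sprintf("g_%d_%03d_%d", ci, seq_len(n_tads), gi),
        chrom = chroms[ci], start = gs, end = gs + glen,
        strand = ifelse(gi %% 2 == 0, "-", "+"))
    }
  }
  list(chrom_lengths = chrom_lengths,
       tads = validate_tads(data.table::rbindlist(tads)),
       genes = data.table::rbindlist(genes))
}

# n simple junctions for one sample (copy-neutral; no CN features emitted)
simulate_simple_svs <- function(sample_id, n, chrom_lengths, params,
                                id_offset = 0L) {
  if (n == 0L) return(empty_junctions())
  chroms <- names(chrom_lengths)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    is_tra <- runif(1) < params$frac_tra
    id <- sprintf("%s_j%04d", sample_id, id_offset + i)
    if (is_tra && length(chroms) >= 2L) {
      ch <- sample(chroms, 2L)
      rows[[i]] <- data.table::data.table(
        id = id, sample_id = sample_id,
        chrom1 = ch[1], pos1 = floor(runif(1, 0, chrom_lengths[[ch[1]]])),
        orient1 = sample(ORIENTS, 1),
        chrom2 = ch[2], pos2 = floor(runif(1, 0, chrom_lengths[[ch[2]]])),
        orient2 = sample(ORIENTS, 1),
        svclass = "TRA", timepoint = NA_character_)
    } else {
      ch <- sample(chroms, 1L)
      size <- round(10^runif(1, 4, 6.7))  # 10 kb - 5 Mb
      p1 <- floor(runif(1, 0, chrom_lengths[[ch]] - size))
      svc <- sample(c("DEL", "DUP", "INV"), 1, prob = c(0.5, 0.25, 0.25))
      orients <- switch(svc, DEL = c("head", "tail"), DUP = c("tail", "head"),
                        INV = c("head", "head"))
      rows[[i]] <- data.table::data.table(
        id = id, sample_id = sample_id,
        chrom1 = ch, pos1 = p1, orient1 = orients[1],
        chrom2 = ch, pos2 = p1 + size, orient2 = orients[2],
        svclass = svc, timepoint = NA_character_)
    }
  }
  data.table::rbindlist(rows)
}

#' Simulate one chromothripsis event
#'
#' Plants `n_breakends` clustered breakends (adjacent gaps 50-900 kb, so the
#' junctions chain) on one chromosome and emits CN feature segments that
#' oscillate 2/1 across the cluster span, with minor_cn = 0 on the CN-1
#' segments (LOH). With the default 16 breakends the span yields >= 14
#' oscillating transitions. Draws from the current RNG stream.
#'
#' @param sample_id Sample label.
#' @param chrom Chromosome name.
#' @param chrom_len Its length, bp.
#' @param n_breakends Number of breakends (even; default 16).
#' @param id_offset Junction id numbering offset.
#' @return List with `junctions` and `cn_features` (start, end, total_cn,
#'   minor_cn on `chrom`).
#' @export
simulate_chromothripsis <- function(sample_id, chrom, chrom_len,
                                    n_breakends = 16L, id_offset = 0L) {
  if (n_breakends %% 2L != 0L) stopf("n_breakends must be even")
  gaps <- runif(n_breakends - 1L, 5e4, 9e5)
  span <- sum(gaps)
  start <- floor(runif(1, 0, chrom_len - span - 1))
  pos <- floor(start + cumsum(c(0, gaps)))
  rows <- lapply(seq_len(n_breakends / 2L), function(k) {
    o <- sample(ORIENTS, 2L, replace = TRUE)
    data.table::data.table(
      id = sprintf("%s_j%04d", sample_id, id_offset + k),
      sample_id = sample_id,
      chrom1 = chrom, pos1 = pos[2 * k - 1], orient1 = o[1],
      chrom2 = chrom, pos2 = pos[2 * k], orient2 = o[2],
      svclass = class_from_orients(o[1], o[2]), timepoint = NA_character_)
  })
  seg_start <- pos[-length(pos)]; seg_end <- pos[-1]
  total <- rep(c(2L, 1L), length.out = length(seg_start))
  cn_features <- data.table::data.table(
    chrom = chrom, start = seg_start, end = seg_end, total_cn = total,
    minor_cn = ifelse(total == 1L, 0L, 1L))
  list(junctions = data.table::rbindlist(rows), cn_features = cn_features)
}

#' Simulate a chained multi-chromosome event (chromoplexy / templated insertion)
#'
#' Builds a cyclic chain visiting the given chromosomes: each chromosome gets a
#' bridge interval (100-800 kb) and consecutive bridge ends are joined by
#' translocation junctions. Deletion bridges get total CN 1 (minor 0); gain
#' bridges get total CN 3 (minor 1). Draws from the current RNG stream.
#'
#' @param sample_id Sample label.
#' @param chroms Character vector of >= 2 distinct chromosomes.
#' @param chrom_lengths Named lengths.
#' @param bridge_kind `"del"` (chromoplexy) or `"gain"` (templated insertion).
#' @param id_offset Junction id numbering offset.
#' @return List with `junctions` and `cn_features` (with a chrom column).
#' @export
simulate_chain <- function(sample_id, chroms, chrom_lengths, bridge_kind,
                           id_offset = 0L) {
  chroms <- unique(chroms)
  if (length(chroms) < 2L) stopf("a chain needs >= 2 chromosomes")
  bridge_kind <- match.arg(bridge_kind, c("del", "gain"))
  k <- length(chroms)
  bl <- runif(k, 1e5, 8e5)
  bs <- floor(vapply(seq_len(k), function(i)
    runif(1, 0, chrom_lengths[[chroms[i]]] - bl[i] - 1), numeric(1)))
  be <- floor(bs + bl)
  # bridge-end orientations: del retains outside the bridge, gain duplicates it
  o_start <- if (bridge_kind == "del") "head" else "tail"
  o_end <- if (bridge_kind == "del") "tail" else "head"
  rows <- lapply(seq_len(k), function(i) {
    nxt <- if (i == k) 1L else i + 1L
    data.table::data.table(
      id = sprintf("%s_j%04d", sample_id, id_offset + i),
      sample_id = sample_id,
      chrom1 = chroms[i], pos1 = be[i], orient1 = o_end,
      chrom2 = chroms[nxt], pos2 = bs[nxt], orient2 = o_start,
      svclass = "TRA", timepoint = NA_character_)
  })
  cn_features <- data.table::data.table(
    chrom = chroms, start = bs, end = be,
    total_cn = if (bridge_kind == "del") 1L else 3L,
    minor_cn = if (bridge_kind == "del") 0L else 1L)
  list(junctions = data.table::rbindlist(rows), cn_features = cn_features)
}

# tile one chromosome: diploid baseline split around the feature segments
overlay_cn <- function(chrom, chrom_len, features) {
  base <- data.table::data.table(start = 0, end = chrom_len,
                                 total_cn = 2L, minor_cn = 1L)
  if (is.null(features) || nrow(features) == 0L) {
    return(cbind(data.table::data.table(chrom = chrom), base))
  }
  f <- data.table::as.data.table(features)
  data.table::setorder(f, start)
  pieces <- list(); cur <- 0
  for (i in seq_len(nrow(f))) {
    if (f$start[i] > cur) {
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        start = cur, end = f$start[i], total_cn = 2L, minor_cn = 1L)
    }
    pieces[[length(pieces) + 1L]] <- f[i, list(start, end, total_cn, minor_cn)]
    cur <- f$end[i]
  }
  if (cur < chrom_len) {
    pieces[[length(pieces) + 1L]] <- data.table::data.table(
      start = cur, end = chrom_len, total_cn = 2L, minor_cn = 1L)
  }
  cbind(data.table::data.table(chrom = chrom), data.table::rbindlist(pieces))
}

#' Simulate the expression matrix
#'
#' Baseline Normal(baseline_mean, noise_sd) per gene and sample on the log2
#' scale; carriers of a planted enhancer-hijack gene get `effect_log2fc` added.
#' Draws from the current RNG stream.
#'
#' @param genes Gene table.
#' @param sample_ids Cohort roster.
#' @param hijack Truth table (gene_id, carriers list, log2fc) or NULL.
#' @param params A [sim_params()] object.
#' @return Numeric matrix genes x samples.
#' @export
simulate_expression <- function(genes, sample_ids, hijack, params) {
  ng <- nrow(genes); ns <- length(sample_ids)
  m <- matrix(rnorm(ng * ns, mean = params$baseline_mean, sd = params$noise_sd),
              nrow = ng, dimnames = list(genes$gene_id, sample_ids))
  if (!is.null(hijack) && nrow(hijack) > 0L) {
    for (i in seq_len(nrow(hijack))) {
      m[hijack$gene_id[i], hijack$carriers[[i]]] <-
        m[hijack$gene_id[i], hijack$carriers[[i]]] + hijack$log2fc[i]
    }
  }
  m
}

#' Simulate a full synthetic cohort
#'
#' Deterministic given `params$seed` (the caller's RNG state is restored
#' afterwards). Emits junctions, CN segments tiling every chromosome of every
#' sample, TADs, genes, an expression matrix, chromosome lengths, and the
#' ground truth (per-sample burden/complex classes, planted events with their
#' junction ids, and planted expression effects).
#'
#' @param params A [sim_params()] object.
#' @return A list: junctions, cn, tads, genes, expression, chrom_lengths,
#'   truth.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    genome <- simulate_genome(params)
    chroms <- names(genome$chrom_lengths)
    burden <- simulate_sv_counts(params$n_samples, params)
    classes <- sample(
      c("chromothripsis", "chromoplexy", "templated_insertion", "none"),
      params$n_samples, replace = TRUE,
      prob = c(params$frac_chromothripsis, params$frac_chromoplexy,
               params$frac_ti,
               1 - params$frac_chromothripsis - params$frac_chromoplexy -
                 params$frac_ti))
    burden$complex_class <- classes

    # enhancer-hijack plan: donor locus on the last chromosome
    donor_chrom <- chroms[length(chroms)]
    tad_pool <- genome$tads[genome$tads$chrom != donor_chrom, ]
    n_hj <- min(params$n_hijack_tads, nrow(tad_pool))
    hijack <- NULL
    hj_tads <- if (n_hj > 0L) tad_pool[sample(nrow(tad_pool), n_hj), ] else NULL
    hj_carriers <- list()
    if (n_hj > 0L) {
      gm <- genes_in_tads(genome$genes, genome$tads)
      rows <- list()
      for (i in seq_len(n_hj)) {
        nc <- sample(seq(params$hijack_carriers[1], params$hijack_carriers[2]), 1)
        carriers <- sort(sample(burden$sample_id, min(nc, params$n_samples)))
        hj_carriers[[hj_tads$tad_id[i]]] <- carriers
        for (gn in gm$gene_id[gm$tad_id == hj_tads$tad_id[i]]) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            tad_id = hj_tads$tad_id[i], gene_id = gn,
            log2fc = params$effect_log2fc, carriers = list(carriers))
        }
      }
      hijack <- data.table::rbindlist(rows)
    }

    all_j <- list(); all_cn <- list(); truth_events <- list()
    donor_tad <- genome$tads[genome$tads$chrom == donor_chrom, ][1, ]
    for (si in seq_len(params$n_samples)) {
      s <- burden$sample_id[si]
      features <- list()  # per-chrom CN features
      offset <- 0L
      jn <- list()

      cls <- burden$complex_class[si]
      if (cls == "chromothripsis") {
        ch <- sample(chroms, 1)
        ev <- simulate_chromothripsis(s, ch, genome$chrom_lengths[[ch]],
                                      params$ct_breakends, id_offset = offset)
        offset <- offset + nrow(ev$junctions)
        jn[[length(jn) + 1L]] <- ev$junctions
        features[[length(features) + 1L]] <- ev$cn_features
        truth_events[[length(truth_events) + 1L]] <- data.table::data.table(
          sample_id = s, type = cls, chroms = list(ch),
          junction_ids = list(ev$junctions$id))
      } else if (cls %in% c("chromoplexy", "templated_insertion")) {
        evch <- sample(chroms, 3)
        ev <- simulate_chain(s, evch, genome$chrom_lengths,
                             if (cls == "chromoplexy") "del" else "gain",
                             id_offset = offset)
        offset <- offset + nrow(ev$junctions)
        jn[[length(jn) + 1L]] <- ev$junctions
        features[[length(features) + 1L]] <- ev$cn_features
        truth_events[[length(truth_events) + 1L]] <- data.table::data.table(
          sample_id = s, type = cls, chroms = list(sort(evch)),
          junction_ids = list(ev$junctions$id))
      }

      # planted enhancer-hijack translocations
      if (n_hj > 0L) {
        for (tid in names(hj_carriers)) {
          if (!s %in% hj_carriers[[tid]]) next
          tt <- hj_tads[hj_tads$tad_id == tid, ]
          offset <- offset + 1L
          jn[[length(jn) + 1L]] <- data.table::data.table(
            id = sprintf("%s_j%04d", s, offset), sample_id = s,
            chrom1 = donor_chrom,
            pos1 = floor(runif(1, donor_tad$start, donor_tad$end)),
            orient1 = sample(ORIENTS, 1),
            chrom2 = tt$chrom, pos2 = floor(runif(1, tt$start, tt$end)),
            orient2 = sample(ORIENTS, 1),
            svclass = "TRA", timepoint = NA_character_)
        }
      }

      simple <- simulate_simple_svs(s, burden$n_sv[si], genome$chrom_lengths,
                                    params, id_offset = offset)
      jn[[length(jn) + 1L]] <- simple
      all_j[[si]] <- data.table::rbindlist(jn)

      feat <- if (length(features)) data.table::rbindlist(features) else NULL
      cnr <- lapply(chroms, function(ch) {
        f <- if (!is.null(feat)) feat[feat$chrom == ch, ] else NULL
        overlay_cn(ch, genome$chrom_lengths[[ch]], f)
      })
      cnr <- data.table::rbindlist(cnr)
      cnr[, sample_id := s]
      all_cn[[si]] <- cnr
    }

    junctions <- canonicalize_junctions(data.table::rbindlist(all_j))
    cn <- validate_cn_segments(data.table::rbindlist(all_cn))
    expression <- simulate_expression(genome$genes, burden$sample_id, hijack,
                                      params)
    truth <- list(
      samples = burden,
      events = if (length(truth_events)) data.table::rbindlist(truth_events)
      else data.table::data.table(sample_id = character(), type = character(),
                                  chroms = list(), junction_ids = list()),
      hijack = hijack %||% data.table::data.table(
        tad_id = character(), gene_id = character(), log2fc = numeric(),
        carriers = list()))
    list(junctions = junctions, cn = cn, tads = genome$tads,
         genes = genome$genes, expression = expression,
         chrom_lengths = genome$chrom_lengths, truth = truth)
  })
}

#' Write a simulated cohort to plain-text files
#'
#' BEDPE junctions, CN TSV, TAD BED, gene BED, expression TSV, chromosome
#' lengths TSV and a JSON ground-truth record.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bedpe(sim$junctions, file.path(dir, "junctions.bedpe"))
  write_cn_segments(sim$cn, file.path(dir, "cn_segments.tsv"))
  write_tad_bed(sim$tads, file.path(dir, "tads.bed"))
  write_gene_bed(sim$genes, file.path(dir, "genes.bed"))
  write_expression_tsv(sim$expression, file.path(dir, "expression.tsv"))
  data.table::fwrite(
    data.table::data.table(chrom = names(sim$chrom_lengths),
                           length = as.numeric(sim$chrom_lengths)),
    file.path(dir, "chrom_lengths.tsv"), sep = "\t", col.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(samples = truth$samples, events = truth$events,
         hijack = truth$hijack),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
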