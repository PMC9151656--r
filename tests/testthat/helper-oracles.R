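# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately use the dumbest correct algorithm.

library(data.table)

jrow <- function(id, sample, c1, p1, o1, c2, p2, o2, svc,
                 tp = NA_character_) {
  data.table(id = id, sample_id = sample,
             chrom1 = c1, pos1 = p1, orient1 = o1,
             chrom2 = c2, pos2 = p2, orient2 = o2,
             svclass = svc, timepoint = tp)
}

# diploid CN baseline for a set of chromosomes
flat_cn <- function(sample, chrom_lengths, total = 2L, minor = 1L) {
  rbindlist(lapply(names(chrom_lengths), function(ch) {
    data.table(sample_id = sample, chrom = ch, start = 0,
               end = chrom_lengths[[ch]], total_cn = total, minor_cn = minor)
  }))
}

# tile one chromosome with baseline around explicit feature segments
cn_with_features <- function(sample, chrom, len, features) {
  features <- features[order(features$start), ]
  pieces <- list(); cur <- 0
  for (i in seq_len(nrow(features))) {
    if (features$start[i] > cur) {
      pieces[[length(pieces) + 1L]] <- data.table(
        start = cur, end = features$start[i], total_cn = 2L, minor_cn = 1L)
    }
    pieces[[length(pieces) + 1L]] <- features[i, c("start", "end", "total_cn", "minor_cn")]
    cur <- features$end[i]
  }
  if (cur < len) {
    pieces[[length(pieces) + 1L]] <- data.table(
      start = cur, end = len, total_cn = 2L, minor_cn = 1L)
  }
  out <- rbindlist(pieces)
  cbind(data.table(sample_id = sample, chrom = chrom), out)
}

# step-up BH, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# all-pairs junction adjacency: quadratic scan over the 4 breakend pairings
oracle_adjacency <- function(junctions, w) {
  j <- as.data.table(junctions)
  edges <- list()
  n <- nrow(j)
  if (n >= 2L) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    close <- function(ca, pa, cb, pb) ca == cb && abs(pa - pb) <= w
    hit <- close(j$chrom1[a], j$pos1[a], j$chrom1[b], j$pos1[b]) ||
      close(j$chrom1[a], j$pos1[a], j$chrom2[b], j$pos2[b]) ||
      close(j$chrom2[a], j$pos2[a], j$chrom1[b], j$pos1[b]) ||
      close(j$chrom2[a], j$pos2[a], j$chrom2[b], j$pos2[b])
    if (hit) edges[[length(edges) + 1L]] <- data.table(
      id1 = min(j$id[a], j$id[b]), id2 = max(j$id[a], j$id[b]))
  }
  if (!length(edges)) return(data.table(id1 = character(), id2 = character()))
  unique(rbindlist(edges))[order(id1, id2)]
}

# union-find connected components over junction ids
oracle_components <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$id1[i]); rb <- find(edges$id2[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(ids, find, character(1))
}

# linear-scan TAD assignment
oracle_assign_tad <- function(chrom, pos, tads) {
  out <- character(length(pos))
  for (i in seq_along(pos)) {
    row <- NULL
    for (k in seq_len(nrow(tads))) {
      if (tads$chrom[k] == chrom[i] && tads$start[k] <= pos[i] &&
          pos[i] < tads$end[k]) { row <- k; break }
    }
    if (!is.null(row)) out[i] <- tads$tad_id[row]
    else if (chrom[i] %in% tads$chrom) out[i] <- "boundary"
    else out[i] <- "no_tad"
  }
  out
}

# transition enumerator for copy-number oscillations, from the stated rule:
# the two most frequent total-CN states (ties to the smaller value) form the
# oscillation set; count adjacent transitions with both values in the set and
# different
oracle_oscillations <- function(total_cn) {
  if (length(total_cn) == 0L) return(0L)
  tab <- table(total_cn)
  vals <- as.numeric(names(tab))
  ord <- order(-as.integer(tab), vals)
  top2 <- vals[ord][seq_len(min(2, length(vals)))]
  n <- 0L
  if (length(total_cn) > 1L) for (i in 1:(length(total_cn) - 1)) {
    a <- total_cn[i]; b <- total_cn[i + 1]
    if (a %in% top2 && b %in% top2 && a != b) n <- n + 1L
  }
  n
}

# minimal Manta-style VCF writer
write_test_vcf <- function(records, path, sample = "S1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  writeLines(c(hdr, records), path)
}

vcf_rec <- function(chrom, pos, id, alt, info) {
  paste(chrom, pos, id, "N", alt, ".", "PASS", info, "GT", "0/1", sep = "\t")
}

# study conditions for the TAD-expression stage (breakend density per TAD
# calibrated to the real cohort's; see the methods vignette)
tad_stage_params <- function(seed, n_hijack = 25L) {
  sim_params(seed = seed, n_samples = 200L, n_chroms = 10L, chrom_len = 5e7,
             tad_size = 1e6, genes_per_tad = 1L, sv_mean = 6,
             sv_mean_high = 30, n_hijack_tads = n_hijack,
             hijack_carriers = c(8L, 14L))
}
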