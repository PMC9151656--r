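# Burden summaries, subgroup comparison, hotspot binning, elbow
# stratification and paired-timepoint diffing.

test_that("summarize_sample splits intra- and interchromosomal junctions", {
  j <- rbind(
    jrow("j1", "s1", "chr1", 10, "head", "chr2", 20, "tail", "TRA"),
    jrow("j2", "s1", "chr1", 10, "head", "chr3", 20, "tail", "TRA"),
    jrow("j3", "s1", "chr2", 10, "head", "chr4", 20, "tail", "TRA"),
    jrow("j4", "s1", "chr1", 10, "head", "chr1", 500, "tail", "DEL"),
    jrow("j5", "s1", "chr2", 10, "head", "chr2", 500, "tail", "DEL"))
  s <- summarize_sample(j)
  expect_equal(c(s$n_total, s$n_intra, s$n_inter), c(5L, 2L, 3L))
  expect_equal(unlist(summarize_sample(empty_junctions(), "sX")[, -1]),
               c(n_total = 0L, n_intra = 0L, n_inter = 0L))
  j$sample_id[2] <- "s2"
  expect_error(summarize_sample(j), "multiple samples")
})

test_that("cohort median SV count reflects the generator's burden model", {
  p <- sim_params(seed = 5, n_samples = 200, frac_high_burden = 0,
                  frac_chromothripsis = 0, frac_chromoplexy = 0, frac_ti = 0,
                  n_hijack_tads = 0)
  sim <- simulate_cohort(p)
  s <- summarize_cohort(sim$junctions, sim$truth$samples$sample_id)
  expect_lte(abs(median(s$n_total) - 31), 3)
})

test_that("compare_burden matches the Kruskal-Wallis rank formula", {
  s <- data.table(sample_id = paste0("s", 1:6),
                  n_total = c(1, 2, 3, 101, 102, 103),
                  n_intra = 0L, n_inter = 0L)
  labels <- setNames(rep(c("a", "b"), each = 3), s$sample_id)
  res <- compare_burden(s, labels)
  # ranks 1:3 vs 4:6 -> H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)

  s2 <- data.table(sample_id = paste0("s", 1:6),
                   n_total = rep(c(5, 9, 14), 2), n_intra = 0L, n_inter = 0L)
  expect_equal(compare_burden(s2, labels)$p.value, 1, tolerance = 1e-9)

  expect_error(compare_burden(s, setNames(rep("a", 6), s$sample_id)), "2 groups")
})

test_that("a planted burden shift is detected at high significance", {
  set.seed(42)
  n <- 100
  s <- data.table(sample_id = paste0("s", 1:(2 * n)),
                  n_total = c(rnbinom(n, size = 10, mu = 31),
                              rnbinom(n, size = 10, mu = 81)),
                  n_intra = 0L, n_inter = 0L)
  labels <- setNames(rep(c("a", "b"), each = n), s$sample_id)
  expect_lt(compare_burden(s, labels)$p.value, 1e-6)
})

test_that("translocation binning counts distinct samples and conserves mass", {
  lens <- c(chr1 = 5e6, chr2 = 3e6)
  j <- rbind(
    jrow("j1", "s1", "chr1", 1.5e6, "head", "chr2", 100, "tail", "TRA"),
    jrow("j2", "s1", "chr1", 1.6e6, "head", "chr2", 200, "tail", "TRA"),
    jrow("j3", "s1", "chr1", 1.7e6, "head", "chr2", 2.5e6, "tail", "TRA"),
    jrow("j4", "s2", "chr1", 1.1e6, "head", "chr2", 150, "tail", "TRA"),
    jrow("j5", "s1", "chr1", 10, "head", "chr1", 99, "tail", "DEL"))
  b <- bin_translocation_breakends(j, lens, bin_size = 1e6)
  get <- function(ch, st) b[b$chrom == ch & b$start == st, ]
  expect_equal(get("chr1", 1e6)$n_samples, 2L)   # 3 breakends of s1 count once
  expect_equal(get("chr1", 1e6)$n_breakends, 4L)
  expect_equal(get("chr2", 0)$n_samples, 2L)
  expect_equal(get("chr2", 2e6)$n_samples, 1L)
  expect_equal(sum(b$n_breakends), 2L * sum(j$svclass == "TRA"))
  expect_equal(nrow(b), 5L + 3L)                 # DEL ignored, full tiling

  jbad <- jrow("x", "s1", "chr1", 6e6, "head", "chr2", 1, "tail", "TRA")
  expect_error(bin_translocation_breakends(jbad, lens, 1e6), "beyond")
})

test_that("binning matches a brute-force recount on random cohorts", {
  set.seed(7)
  lens <- c(chr1 = 1e7, chr2 = 8e6)
  n <- 300
  j <- rbindlist(lapply(seq_len(n), function(i) {
    ch <- sample(names(lens), 2)
    jrow(paste0("j", i), sprintf("s%02d", sample(100, 1)),
         ch[1], floor(runif(1, 0, lens[[ch[1]]])), "head",
         ch[2], floor(runif(1, 0, lens[[ch[2]]])), "tail",
         if (ch[1] == ch[2]) "INV" else "TRA")
  }))
  j <- canonicalize_junctions(j)
  bin_size <- 1e6
  b <- bin_translocation_breakends(j, lens, bin_size)
  for (k in seq_len(nrow(b))) {
    hits <- character(); inc <- 0L
    tra <- j[j$svclass == "TRA", ]
    for (r in seq_len(nrow(tra))) for (side in 1:2) {
      ch <- tra[[paste0("chrom", side)]][r]; p <- tra[[paste0("pos", side)]][r]
      if (ch == b$chrom[k] && p >= b$start[k] && p < b$end[k]) {
        hits <- c(hits, tra$sample_id[r]); inc <- inc + 1L
      }
    }
    expect_equal(b$n_samples[k], length(unique(hits)))
    expect_equal(b$n_breakends[k], inc)
  }
})

test_that("hotspot calling is null-calibrated and flags planted bins", {
  # uniform counts: no hotspot at any alpha < 1
  b <- data.table(chrom = "chr1", start = (0:99) * 1e6, end = (1:100) * 1e6,
                  n_samples = rep(3L, 100), n_breakends = rep(3L, 100))
  h <- call_hotspots(b, n_cohort = 50, alpha = 0.999)
  expect_false(any(h$is_hotspot))
  expect_true(all(h$p == 1))

  # single-bin genome: p = 1 by construction of the excess test
  b1 <- data.table(chrom = "chr1", start = 0, end = 1e6,
                   n_samples = 12L, n_breakends = 20L)
  expect_equal(call_hotspots(b1, n_cohort = 50)$p, 1)

  expect_error(call_hotspots(b1, n_cohort = 0), "positive")

  # planted enrichment among binomial background
  set.seed(11)
  n_bins <- 1000; n_cohort <- 100
  counts <- rbinom(n_bins, n_cohort, 0.01)
  counts[500] <- 30L
  bp <- data.table(chrom = "chr1", start = (seq_len(n_bins) - 1) * 1e6,
                   end = seq_len(n_bins) * 1e6, n_samples = counts,
                   n_breakends = counts)
  hp <- call_hotspots(bp, n_cohort)
  expect_true(hp$is_hotspot[500])
  expect_lte(mean(hp$is_hotspot[-500]), 0.05)
})

test_that("elbow_split finds the knee and honors its invariances", {
  counts <- setNames(c(300, 290, 280, rep(30, 10)), paste0("s", 1:13))
  # oracle: exhaustive perpendicular-distance computation over all indices
  y <- sort(counts, decreasing = TRUE); n <- length(y)
  d <- vapply(seq_len(n), function(i) {
    x1 <- 1; y1 <- y[1]; x2 <- n; y2 <- y[n]
    abs((y2 - y1) * i - (x2 - x1) * y[i] + x2 * y1 - y2 * x1) /
      sqrt((x2 - x1)^2 + (y2 - y1)^2)
  }, numeric(1))
  es <- elbow_split(counts)
  expect_equal(es$elbow_index, which.max(d))
  expect_setequal(es$high_ids, c("s1", "s2", "s3"))

  expect_length(elbow_split(setNames(rep(7, 5), paste0("s", 1:5)))$high_ids, 0)

  # order invariance and scale invariance
  set.seed(1)
  counts2 <- setNames(rnbinom(50, size = 3, mu = 40) + 1, paste0("s", 1:50))
  a <- elbow_split(counts2)
  b <- elbow_split(sample(counts2))
  c3 <- elbow_split(counts2 * 17)
  expect_setequal(a$high_ids, b$high_ids)
  expect_setequal(a$high_ids, c3$high_ids)
  expect_error(elbow_split(c(a = 1, b = 2)), ">= 3")
})

test_that("timepoint diff matches events by junction overlap", {
  j1 <- rbind(
    jrow("a1", "p1", "chr8", 1e6, "head", "chr11", 2e6, "tail", "TRA"),
    jrow("a2", "p1", "chr8", 1.2e6, "tail", "chr11", 2.2e6, "head", "TRA"),
    jrow("a3", "p1", "chr8", 1.4e6, "head", "chr11", 2.4e6, "tail", "TRA"))
  e1 <- data.table(event_id = "ev1", junction_ids = list(c("a1", "a2", "a3")))
  # t2: same chain (within 1 kb jitter) plus one junction on a new chromosome
  j2 <- rbind(
    jrow("b1", "p1", "chr8", 1e6 + 300, "head", "chr11", 2e6 - 200, "tail", "TRA"),
    jrow("b2", "p1", "chr8", 1.2e6 + 100, "tail", "chr11", 2.2e6, "head", "TRA"),
    jrow("b3", "p1", "chr8", 1.4e6, "head", "chr11", 2.4e6 + 900, "tail", "TRA"),
    jrow("b4", "p1", "chr6", 5e6, "head", "chr8", 1.5e6, "tail", "TRA"))
  e2 <- data.table(event_id = "ev2", junction_ids = list(c("b1", "b2", "b3", "b4")))

  d <- diff_timepoints(e1, e2, j1, j2)
  expect_equal(d$stable_t1, "ev1")
  expect_equal(d$stable_t2, "ev2")   # grown chain is stable, not gained
  expect_length(d$gained, 0)
  expect_length(d$lost, 0)

  # identical lists -> all stable; disjoint -> gained + lost
  di <- diff_timepoints(e1, e1, j1, j1)
  expect_equal(di$stable_t1, di$stable_t2)
  j3 <- rbind(jrow("c1", "p1", "chr2", 1e6, "head", "chr3", 2e6, "tail", "TRA"),
              jrow("c2", "p1", "chr3", 2.1e6, "head", "chr4", 9e6, "tail", "TRA"))
  e3 <- data.table(event_id = "ev3", junction_ids = list(c("c1", "c2")))
  dd <- diff_timepoints(e1, e3, j1, j3)
  expect_equal(dd$gained, "ev3")
  expect_equal(dd$lost, "ev1")
})

test_that("gained(t1,t2) equals lost(t2,t1) on random event sets", {
  set.seed(9)
  mk <- function(prefix, n_events) {
    jl <- list(); ev <- list()
    for (e in seq_len(n_events)) {
      nj <- sample(3:6, 1)
      ids <- sprintf("%s_e%d_j%d", prefix, e, seq_len(nj))
      jl[[e]] <- rbindlist(lapply(seq_len(nj), function(k) {
        jrow(ids[k], "p1", sample(paste0("chr", 1:4), 1),
             floor(runif(1, 0, 1e7)), "head",
             sample(paste0("chr", 5:8), 1), floor(runif(1, 0, 1e7)), "tail",
             "TRA")
      }))
      ev[[e]] <- data.table(event_id = paste0(prefix, "_ev", e),
                            junction_ids = list(ids))
    }
    list(j = rbindlist(jl), e = rbindlist(ev))
  }
  for (rep in 1:5) {
    a <- mk(paste0("A", rep), 3); b <- mk(paste0("B", rep), 4)
    # overlap: make b's first event a jittered copy of a's first
    b$j[1:3, `:=`(chrom1 = a$j$chrom1[1:3], pos1 = a$j$pos1[1:3] + 100,
                  chrom2 = a$j$chrom2[1:3], pos2 = a$j$pos2[1:3] - 100)]
    fwd <- diff_timepoints(a$e, b$e, a$j, b$j)
    rev <- diff_timepoints(b$e, a$e, b$j, a$j)
    expect_setequal(fwd$gained, rev$lost)
    expect_setequal(fwd$lost, rev$gained)
  }
})
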