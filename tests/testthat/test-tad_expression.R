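# TAD assignment, neo-TADs, carrier partitioning, the filtered ANOVA + BH
# scan, and the boundary contrast.

mk_tads <- function() data.table(
  tad_id = c("t1", "t2", "t3"), chrom = c("chr1", "chr1", "chr2"),
  start = c(0, 1e6, 0), end = c(1e6, 2e6, 5e5), source = "test")

test_that("breakend-to-TAD assignment is half-open with sentinels", {
  tads <- mk_tads()
  expect_equal(assign_breakend_to_tad("chr1", 999999, tads), "t1")
  expect_equal(assign_breakend_to_tad("chr1", 1e6, tads), "t2")
  expect_equal(assign_breakend_to_tad("chr1", 2e6, tads), "boundary")
  expect_equal(assign_breakend_to_tad("chr9", 10, tads), "no_tad")
  # gap between TADs
  tg <- data.table(tad_id = c("a", "b"), chrom = "chr1",
                   start = c(0, 2e6), end = c(1e6, 3e6), source = "test")
  expect_equal(assign_breakend_to_tad("chr1", 1.5e6, tg), "boundary")
})

test_that("assignment agrees with a linear-scan oracle on random positions", {
  set.seed(41)
  tads <- rbindlist(lapply(1:3, function(ci) {
    starts <- sort(sample(seq(0, 9.5e6, by = 5e5), 8))
    data.table(tad_id = sprintf("c%d_t%d", ci, 1:8),
               chrom = paste0("chr", ci), start = starts,
               end = starts + sample(c(3e5, 4e5, 5e5), 8, replace = TRUE),
               source = "test")
  }))
  chrom <- sample(paste0("chr", 1:4), 1e4, replace = TRUE)
  pos <- floor(runif(1e4, 0, 1.05e7))
  expect_equal(assign_breakend_to_tad(chrom, pos, tads),
               oracle_assign_tad(chrom, pos, tads))
})

test_that("TAD-TAD junctions exclude sentinel-touching junctions", {
  tads <- mk_tads()
  j <- rbind(
    jrow("j1", "s1", "chr1", 5e5, "head", "chr2", 100, "tail", "TRA"),
    jrow("j2", "s1", "chr1", 10, "head", "chr1", 5e5, "tail", "DEL"),
    jrow("j3", "s1", "chr1", 5e5, "head", "chr1", 2.5e6, "tail", "DEL"))
  tj <- find_tad_rearrangements(j, tads)
  expect_equal(tj$is_tad_tad, c(TRUE, FALSE, FALSE))
  expect_equal(tj$same_tad, c(FALSE, TRUE, FALSE))
  expect_true(tj$has_sentinel[3])
})

test_that("neo-TAD retained intervals follow breakend orientation", {
  tads <- mk_tads()
  genes <- data.table(gene_id = c("gL", "gR", "gB"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(1e5, 8e5, 1e5), end = c(1.1e5, 8.1e5, 1.2e5),
                      strand = "+")
  j <- jrow("j1", "s1", "chr1", 5e5, "head", "chr2", 3e5, "tail", "TRA")
  tj <- find_tad_rearrangements(j, tads)
  nt <- enumerate_neo_tads(tj, tads, genes)
  expect_equal(nrow(nt), 1L)
  expect_equal(c(nt$ret_a_start, nt$ret_a_end), c(0, 5e5))     # left half
  expect_equal(c(nt$ret_b_start, nt$ret_b_end), c(3e5, 5e5))   # right part
  expect_setequal(nt$genes_ab[[1]], c("gL"))  # gR beyond pos; gB before pos

  # tail breakend at tad start retains the whole TAD
  j2 <- jrow("j2", "s1", "chr1", 0, "tail", "chr2", 3e5, "tail", "TRA")
  nt2 <- enumerate_neo_tads(find_tad_rearrangements(j2, tads), tads, genes)
  expect_equal(c(nt2$ret_a_start, nt2$ret_a_end), c(0, 1e6))
  expect_true(all(c("gL", "gR") %in% nt2$genes_ab[[1]]))
})

test_that("simulated enhancer hijack junctions capture the target gene in a neo-TAD", {
  sim <- simulate_cohort(tad_stage_params(seed = 43, n_hijack = 3L))
  tj <- find_tad_rearrangements(sim$junctions, sim$tads)
  nt <- enumerate_neo_tads(tj, sim$tads, sim$genes)
  hj <- sim$truth$hijack
  for (i in seq_len(nrow(hj))) {
    carriers <- hj$carriers[[i]]
    caught <- vapply(seq_len(nrow(nt)), function(k) {
      nt$sample_id[k] %in% carriers &&
        hj$tad_id[i] %in% c(nt$tad_a[k], nt$tad_b[k]) &&
        hj$gene_id[i] %in% nt$genes_ab[[k]]
    }, logical(1))
    # the planted junction lands inside the TAD, away from edges most of the
    # time; every hijack TAD must be recovered for at least one carrier
    expect_true(any(caught), label = paste("hijack TAD", hj$tad_id[i]))
  }
})

test_that("carrier/control partition is a disjoint cover and matches brute force", {
  tads <- mk_tads()
  cohort <- c("s1", "s2", "s3")
  j <- rbind(
    jrow("j1", "s1", "chr1", 5e5, "head", "chr2", 100, "tail", "TRA"),
    jrow("j2", "s1", "chr1", 6e5, "head", "chr2", 200, "tail", "TRA"))
  part <- group_samples_by_tad(find_tad_rearrangements(j, tads), cohort)
  p1 <- part[part$tad_id == "t1", ]
  expect_equal(p1$carriers[[1]], "s1")         # s1 counted once
  expect_setequal(p1$controls[[1]], c("s2", "s3"))

  set.seed(47)
  sim <- simulate_cohort(sim_params(seed = 47, n_samples = 25))
  cohort <- sim$truth$samples$sample_id
  tj <- find_tad_rearrangements(sim$junctions, sim$tads)
  part <- group_samples_by_tad(tj, cohort)
  tt <- tj[tj$is_tad_tad == TRUE, ]
  for (k in sample(nrow(part), 20)) {
    tid <- part$tad_id[k]
    expected <- sort(unique(tt$sample_id[tt$tad_a == tid | tt$tad_b == tid]))
    expect_equal(part$carriers[[k]], expected)
    expect_setequal(c(part$carriers[[k]], part$controls[[k]]), cohort)
    expect_length(intersect(part$carriers[[k]], part$controls[[k]]), 0)
  }
})

test_that("bh_fdr matches hand BH and the brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(53)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("two-group ANOVA equals the squared t-test and handles degeneracy", {
  set.seed(59)
  x <- rnorm(5, 5); y <- rnorm(5, 7)
  p_aov <- svtopo:::anova_p(c(x, y), rep(c("a", "b"), each = 5))
  p_t <- t.test(x, y, var.equal = TRUE)$p.value
  expect_equal(p_aov, p_t, tolerance = 1e-12)
  # identical groups: p = 1, and a common location shift changes nothing
  expect_equal(svtopo:::anova_p(rep(3, 10), rep(c("a", "b"), each = 5)), 1)
  p_shift <- svtopo:::anova_p(c(x, y) + 1, rep(c("a", "b"), each = 5))
  expect_equal(p_aov, p_shift, tolerance = 1e-9)
})

test_that("the TAD gene scan applies the case/median/q filters", {
  set.seed(61)
  cohort <- sprintf("s%02d", 1:40)
  tads <- mk_tads()
  genes <- data.table(gene_id = c("gHot", "gCold", "gLow"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(1e5, 1.2e6, 1e5), end = c(1.1e5, 1.21e6, 1.1e5),
                      strand = "+")
  carriers <- cohort[1:8]
  j <- rbindlist(lapply(seq_along(carriers), function(i) rbind(
    jrow(paste0("a", i), carriers[i], "chr1", 5e5, "head", "chr2", 1e5, "tail", "TRA"))))
  expr <- matrix(rnorm(3 * 40, mean = 5), nrow = 3,
                 dimnames = list(genes$gene_id, cohort))
  expr["gHot", carriers] <- expr["gHot", carriers] + 3
  expr["gLow", ] <- expr["gLow", ] - 10  # fails the median filter
  scan <- tad_gene_scan(j, tads, genes, expr)
  res <- scan$results
  hot <- res[res$gene_id == "gHot", ]
  expect_true(hot$passes_filters)
  expect_equal(hot$n_carrier, 8L)
  expect_gt(hot$log2fc, 2)
  low <- res[res$gene_id == "gLow", ]
  expect_false(low$passes_filters)  # q may be small but medians are low
  expect_false("gCold" %in% res$gene_id[res$passes_filters])
})

test_that("boundary contrast groups by breakend placement with inside precedence", {
  tads <- mk_tads()
  genes <- data.table(gene_id = "gX", chrom = "chr1", start = 1.2e6,
                      end = 1.25e6, strand = "+")
  # gX sits in t2 = [1e6, 2e6)
  j <- rbind(
    jrow("i1", "sIn", "chr1", 1.5e6, "head", "chr2", 100, "tail", "TRA"),
    jrow("o1", "sOut", "chr1", 1e6 - 1, "head", "chr2", 200, "tail", "TRA"),
    jrow("m1", "sMix", "chr1", 1.5e6, "head", "chr2", 300, "tail", "TRA"),
    jrow("m2", "sMix", "chr1", 2.5e6, "head", "chr2", 400, "tail", "TRA"))
  cohort <- c("sIn", "sOut", "sMix", "sNone1", "sNone2")
  expr <- matrix(rnorm(5, 5), nrow = 1, dimnames = list("gX", cohort))
  bc <- boundary_contrast("gX", j, tads, genes, expr, flank = 2e6)
  expect_setequal(bc$inside_samples, c("sIn", "sMix"))
  expect_equal(bc$outside_samples, "sOut")      # tad.start - 1 is outside
  expect_setequal(bc$none_samples, c("sNone1", "sNone2"))
  expect_error(boundary_contrast("gY", j, tads, genes, expr), "unknown gene")
  g2 <- data.table(gene_id = "gZ", chrom = "chr7", start = 1, end = 2,
                   strand = "+")
  expect_error(boundary_contrast("gZ", j, tads, g2, expr), "no TAD")
})

test_that("planted inside-TAD upregulation separates the boundary groups", {
  set.seed(67)
  tads <- mk_tads()
  genes <- data.table(gene_id = "gX", chrom = "chr1", start = 1.2e6,
                      end = 1.25e6, strand = "+")
  inside <- sprintf("in%02d", 1:20); outside <- sprintf("out%02d", 1:20)
  none <- sprintf("none%02d", 1:60)
  j <- rbindlist(c(
    lapply(inside, function(s) jrow(paste0(s, "_j"), s, "chr1",
                                    floor(runif(1, 1e6, 2e6)), "head",
                                    "chr2", 100, "tail", "TRA")),
    lapply(outside, function(s) jrow(paste0(s, "_j"), s, "chr1",
                                     floor(runif(1, 2.05e6, 3.5e6)), "head",
                                     "chr2", 100, "tail", "TRA"))))
  cohort <- c(inside, outside, none)
  expr <- matrix(rnorm(length(cohort), 5), nrow = 1,
                 dimnames = list("gX", cohort))
  expr["gX", inside] <- expr["gX", inside] + 2
  bc <- boundary_contrast("gX", j, tads, genes, expr, flank = 2e6)
  expect_lt(bc$p, 0.01)
})
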