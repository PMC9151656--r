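# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table setDT setorder rbindlist
#'   uniqueN fread fwrite copy := .N .SD
#' @importFrom stats p.adjust pbinom kruskal.test oneway.test rnorm rnbinom
#'   runif median ks.test pf
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "..keep", "chrom", "chrom1", "chrom2", "pos", "pos1", "pos2", "start",
  "end", "sample_id", "total_cn", "minor_cn", "tad_id", "gene_id", "bin",
  "junction_id", "n_samples", "n_breakends", "svclass", "id", "side"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with the global RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Overlap-length-weighted mode of total_cn over [start, end) for one sample's
# CN segments on one chromosome. Ties broken toward the smaller copy number.
# Returns NA_real_ if nothing overlaps.
modal_cn <- function(cn_chrom, start, end) {
  if (end <= start || nrow(cn_chrom) == 0L) return(NA_real_)
  ov_start <- pmax(cn_chrom$start, start)
  ov_end <- pmin(cn_chrom$end, end)
  w <- ov_end - ov_start
  keep <- w > 0
  if (!any(keep)) return(NA_real_)
  tot <- tapply(w[keep], cn_chrom$total_cn[keep], sum)
  vals <- as.numeric(names(tot))
  best <- vals[tot == max(tot)]
  min(best)
}

# TRUE where position pos is covered by some segment [start, end)
cn_covers <- function(cn_chrom, pos) {
  vapply(pos, function(p) any(cn_chrom$start <= p & cn_chrom$end > p), logical(1))
}
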