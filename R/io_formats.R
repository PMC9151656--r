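# Readers and writers for the external formats the pipeline consumes, plus the
# internal junction table convention every other module relies on.
#
# Internal coordinate convention: 0-based, half-open everywhere. Conversions
# from 1-based formats (VCF) happen here and only here.
#
# Breakend orientation vocabulary: "head" means the junction retains the
# sequence to the LEFT of pos in the derivative chromosome, "tail" retains the
# sequence to the RIGHT. BEDPE strand "+" maps to head, "-" to tail.

ORIENTS <- c("head", "tail")
SV_CLASSES <- c("DEL", "DUP", "INV", "TRA")

#' Construct an empty junction table
#'
#' The junction table is the package's internal SV representation: one row per
#' junction (pair of breakends), 0-based positions, orientations in
#' `c("head", "tail")`.
#'
#' @return A zero-row `data.table` with the junction columns.
#' @export
empty_junctions <- function() {
  data.table::data.table(
    id = character(), sample_id = character(),
    chrom1 = character(), pos1 = numeric(), orient1 = character(),
    chrom2 = character(), pos2 = numeric(), orient2 = character(),
    svclass = character(), timepoint = character()
  )
}

#' Put junctions into canonical breakend order and validate invariants
#'
#' Within a junction, breakends are ordered by (chromosome, position); this
#' makes VCF- and BEDPE-derived encodings of the same junction identical.
#' Interchromosomal junctions must be class `TRA`.
#'
#' @param junctions A junction table (see [empty_junctions()]).
#' @return The canonicalized junction table.
#' @export
canonicalize_junctions <- function(junctions) {
  j <- data.table::as.data.table(junctions)
  if (nrow(j) == 0L) return(j)
  if (!all(j$orient1 %in% ORIENTS) || !all(j$orient2 %in% ORIENTS)) {
    stopf("breakend orientations must be one of: %s", paste(ORIENTS, collapse = ", "))
  }
  bad <- !(j$svclass %in% SV_CLASSES)
  if (any(bad)) {
    stopf("unknown svclass token(s) '%s'; accepted tokens: %s",
          paste(unique(j$svclass[bad]), collapse = "', '"),
          paste(SV_CLASSES, collapse = ", "))
  }
  inter <- j$chrom1 != j$chrom2
  if (any(inter & j$svclass != "TRA")) {
    stopf("interchromosomal junction(s) with svclass != TRA: %s",
          paste(utils::head(j$id[inter & j$svclass != "TRA"], 5), collapse = ", "))
  }
  if (any(j$pos1 < 0 | j$pos2 < 0)) stopf("negative breakend position")
  swap <- (j$chrom1 == j$chrom2 & j$pos1 > j$pos2) |
    (j$chrom1 != j$chrom2 & j$chrom1 > j$chrom2)
  if (any(swap)) {
    tmp <- j[swap, list(chrom1, pos1, orient1)]
    j[swap, `:=`(chrom1 = chrom2, pos1 = pos2, orient1 = orient2)]
    j[swap, `:=`(chrom2 = tmp$chrom1, pos2 = tmp$pos1, orient2 = tmp$orient1)]
  }
  dup <- duplicated(j[, list(sample_id, timepoint, id)])
  if (any(dup)) stopf("duplicate junction id within a (sample, timepoint): %s",
                      paste(unique(j$id[dup]), collapse = ", "))
  j[]
}

# one row per breakend: junction_id, sample_id, chrom, pos, orient, side
breakends_long <- function(junctions) {
  j <- data.table::as.data.table(junctions)
  data.table::rbindlist(list(
    j[, list(junction_id = id, sample_id, chrom = chrom1, pos = pos1,
             orient = orient1, side = 1L)],
    j[, list(junction_id = id, sample_id, chrom = chrom2, pos = pos2,
             orient = orient2, side = 2L)]
  ))
}

strand_to_orient <- function(strand) {
  # accept ASCII and unicode minus
  out <- ifelse(strand == "+", "head",
                ifelse(strand %in% c("-", "−"), "tail", NA_character_))
  out
}

orient_to_strand <- function(orient) ifelse(orient == "head", "+", "-")

# class of a same-chromosome junction from its breakend orientations
class_from_orients <- function(o1, o2) {
  ifelse(o1 == "head" & o2 == "tail", "DEL",
         ifelse(o1 == "tail" & o2 == "head", "DUP", "INV"))
}

#' Read SV junctions from a BEDPE file
#'
#' Expects 10+ whitespace-separated columns:
#' `chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2
#' [svclass] [sample]`. Breakend position is the start coordinate of each side
#' (BEDPE is 0-based); strand `+` maps to orientation `head`, `-` to `tail`.
#' When the svclass column is absent the class is derived from chromosomes and
#' orientations.
#'
#' @param path Path to a BEDPE file.
#' @param sample_id Sample label used when the file has no 12th column.
#' @param timepoint Optional timepoint label applied to all junctions.
#' @return A canonical junction table.
#' @export
read_sv_bedpe <- function(path, sample_id = "sample", timepoint = NA_character_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warnf("empty BEDPE file: %s", path)
    return(empty_junctions())
  }
  rows <- strsplit(lines, "[ \t]+")
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 10L) {
      stopf("malformed BEDPE line %d in %s: expected >= 10 columns, got %d",
            i, path, length(f))
    }
    s1 <- suppressWarnings(as.numeric(f[2])); s2 <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s1) || is.na(s2)) stopf("malformed BEDPE line %d in %s: non-numeric coordinate", i, path)
    o1 <- strand_to_orient(f[9]); o2 <- strand_to_orient(f[10])
    if (is.na(o1) || is.na(o2)) stopf("malformed BEDPE line %d in %s: bad strand", i, path)
    svc <- if (length(f) >= 11L && f[11] != ".") f[11] else {
      if (f[1] != f[4]) "TRA" else class_from_orients(o1, o2)
    }
    if (!svc %in% SV_CLASSES) {
      stopf("unknown svclass token '%s' at line %d; accepted tokens: %s",
            svc, i, paste(SV_CLASSES, collapse = ", "))
    }
    smp <- if (length(f) >= 12L) f[12] else sample_id
    out[[i]] <- data.table::data.table(
      id = f[7], sample_id = smp,
      chrom1 = f[1], pos1 = s1, orient1 = o1,
      chrom2 = f[4], pos2 = s2, orient2 = o2,
      svclass = svc, timepoint = timepoint
    )
  }
  canonicalize_junctions(data.table::rbindlist(out))
}

#' Write a junction table to BEDPE
#'
#' Emits 12 tab-separated columns (the optional svclass and sample columns are
#' always written), so that `read_sv_bedpe(write_bedpe(x))` round-trips.
#'
#' @param junctions A junction table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(junctions, path) {
  j <- canonicalize_junctions(junctions)
  df <- data.table::data.table(
    chrom1 = j$chrom1, start1 = format(j$pos1, scientific = FALSE, trim = TRUE),
    end1 = format(j$pos1 + 1, scientific = FALSE, trim = TRUE),
    chrom2 = j$chrom2, start2 = format(j$pos2, scientific = FALSE, trim = TRUE),
    end2 = format(j$pos2 + 1, scientific = FALSE, trim = TRUE),
    name = j$id, score = ".",
    strand1 = orient_to_strand(j$orient1), strand2 = orient_to_strand(j$orient2),
    svclass = j$svclass, sample = j$sample_id
  )
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- VCF (Manta dialect: SVTYPE/END/MATEID, BND bracket ALTs) ----------------

parse_info <- function(info) {
  kv <- strsplit(info, ";", fixed = TRUE)[[1]]
  out <- list()
  for (item in kv) {
    eq <- regexpr("=", item, fixed = TRUE)
    if (eq > 0) out[[substr(item, 1, eq - 1)]] <- substr(item, eq + 1, nchar(item))
    else out[[item]] <- TRUE
  }
  out
}

# Decode a VCF 4.2 breakend ALT. Returns list(mate_chrom, mate_pos_1based,
# local_orient, mate_orient) or NULL if the ALT is not bracket notation.
#   t[p[  -> local head, mate tail      t]p]  -> local head, mate head
#   ]p]t  -> local tail, mate head      [p[t  -> local tail, mate tail
decode_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("^([ACGTNacgtn]*)([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])([ACGTNacgtn]*)$",
                               alt, perl = TRUE))[[1]]
  if (length(m) == 0L) return(NULL)
  prefix <- m[2]; br <- m[3]; chrom <- m[4]; pos <- as.numeric(m[5]); br2 <- m[6]
  if (br != br2) return(NULL)
  list(
    mate_chrom = chrom, mate_pos = pos,
    local_orient = if (nzchar(prefix)) "head" else "tail",
    mate_orient = if (br == "[") "tail" else "head"
  )
}

#' Read SV junctions from a Manta-style VCF
#'
#' Handles symbolic `<DEL>`, `<DUP>`, `<INV>` records (via INFO `END`) and
#' breakend (`SVTYPE=BND`) records paired through INFO `MATEID`, decoding the
#' four VCF 4.2 bracket orientations. 1-based VCF positions are converted to
#' the internal 0-based convention. Unpaired BND records are dropped with a
#' warning (their count is available as `attr(x, "n_dropped")`). Records that
#' are not SVs (e.g. SNVs) are ignored.
#'
#' @param path Path to an uncompressed VCF.
#' @param sample_id Sample label; defaults to the VCF's first genotype column
#'   name, or `"sample"` if the VCF has none.
#' @param timepoint Optional timepoint label.
#' @return A canonical junction table.
#' @export
read_sv_vcf <- function(path, sample_id = NULL, timepoint = NA_character_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  hdr <- lines[grepl("^#CHROM", lines)]
  if (is.null(sample_id)) {
    sample_id <- "sample"
    if (length(hdr) == 1L) {
      cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
      if (length(cols) >= 10L) sample_id <- cols[10]
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) return(empty_junctions())

  simple <- list(); bnd <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) stopf("malformed VCF record: %s", ln)
    info <- parse_info(f[8])
    svtype <- info$SVTYPE %||% NA_character_
    chrom <- f[1]; pos <- as.numeric(f[2]); id <- f[3]; alt <- f[5]
    if (is.na(svtype)) next  # SNV/indel record
    if (svtype %in% c("DEL", "DUP", "INV")) {
      if (is.null(info$END)) stopf("symbolic %s record '%s' missing INFO END", svtype, id)
      endp <- as.numeric(info$END)
      orients <- switch(svtype,
        DEL = c("head", "tail"), DUP = c("tail", "head"), INV = c("head", "head"))
      simple[[length(simple) + 1L]] <- data.table::data.table(
        id = id, sample_id = sample_id,
        chrom1 = chrom, pos1 = pos - 1, orient1 = orients[1],
        chrom2 = chrom, pos2 = endp, orient2 = orients[2],
        svclass = svtype, timepoint = timepoint
      )
    } else if (svtype == "BND") {
      dec <- decode_bnd_alt(alt)
      if (is.null(dec)) stopf("BND record '%s' has undecodable ALT '%s'", id, alt)
      bnd[[id]] <- c(dec, list(chrom = chrom, pos = pos, id = id,
                               mate_id = info$MATEID %||% NA_character_))
    }
  }

  jn <- list(); used <- character(); dropped <- 0L
  for (id in names(bnd)) {
    if (id %in% used) next
    rec <- bnd[[id]]
    mate <- if (!is.na(rec$mate_id)) bnd[[rec$mate_id]] else NULL
    if (is.null(mate)) { dropped <- dropped + 1L; next }
    used <- c(used, id, rec$mate_id)
    ch1 <- rec$chrom; ch2 <- rec$mate_chrom
    svc <- if (ch1 != ch2) "TRA" else class_from_orients(rec$local_orient, rec$mate_orient)
    jn[[length(jn) + 1L]] <- data.table::data.table(
      id = min(id, rec$mate_id), sample_id = sample_id,
      chrom1 = ch1, pos1 = rec$pos - 1, orient1 = rec$local_orient,
      chrom2 = ch2, pos2 = rec$mate_pos - 1, orient2 = rec$mate_orient,
      svclass = svc, timepoint = timepoint
    )
  }
  if (dropped > 0L) warnf("dropped %d unpaired BND record(s) in %s", dropped, path)
  out <- data.table::rbindlist(c(simple, jn))
  if (nrow(out) == 0L) out <- empty_junctions() else out <- canonicalize_junctions(out)
  data.table::setattr(out, "n_dropped", dropped)
  out
}

# ---- CN segments, TADs, genes, expression -----------------------------------

validate_cn_segments <- function(cn) {
  cn <- data.table::as.data.table(cn)
  need <- c("sample_id", "chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(cn))) stopf("CN table needs columns: %s", paste(need, collapse = ", "))
  if (any(cn$start >= cn$end)) stopf("CN segment with start >= end")
  if (any(cn$total_cn < 0 | cn$minor_cn < 0)) stopf("negative copy number")
  if (any(cn$minor_cn > cn$total_cn)) stopf("minor_cn exceeds total_cn")
  data.table::setorder(cn, sample_id, chrom, start)
  ov <- cn[, list(bad = any(start[-1] < end[-.N])), by = list(sample_id, chrom)]
  if (any(ov$bad)) {
    b <- ov[ov$bad][1]
    stopf("overlapping CN segments for sample '%s' on %s", b$sample_id, b$chrom)
  }
  cn[]
}

#' Read copy-number segments
#'
#' Tab-separated with header columns `sample_id chrom start end total_cn
#' minor_cn` (0-based half-open). Segments must be non-overlapping within a
#' (sample, chromosome); `minor_cn = 0` with `total_cn >= 1` encodes LOH.
#'
#' @param path Path to the TSV.
#' @return A sorted, validated `data.table` of segments.
#' @export
read_cn_segments <- function(path) {
  cn <- data.table::fread(path, sep = "\t", header = TRUE)
  validate_cn_segments(cn)
}

#' @rdname read_cn_segments
#' @param cn A CN segment table.
#' @export
write_cn_segments <- function(cn, path) {
  data.table::fwrite(validate_cn_segments(cn), path, sep = "\t")
  invisible(path)
}

validate_tads <- function(tads) {
  tads <- data.table::as.data.table(tads)
  if (any(tads$start >= tads$end)) stopf("TAD with start >= end")
  data.table::setorder(tads, chrom, start)
  ov <- tads[, list(bad = if (.N > 1) any(start[-1] < end[-.N]) else FALSE), by = chrom]
  if (any(ov$bad)) stopf("overlapping TADs on %s", ov$chrom[ov$bad][1])
  if (anyDuplicated(tads$tad_id)) stopf("duplicate tad_id")
  tads[]
}

#' Read TAD intervals from a BED file
#'
#' BED4 (+optional 5th column naming the Hi-C source): `chrom start end tad_id
#' [source]`. TADs on a chromosome must be non-overlapping; gaps between them
#' are inter-TAD boundary regions.
#'
#' @param path Path to the BED file.
#' @return A sorted `data.table` with columns tad_id, chrom, start, end, source.
#' @export
read_tad_bed <- function(path) {
  b <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(b) < 4L) stopf("TAD BED needs >= 4 columns")
  tads <- data.table::data.table(
    tad_id = as.character(b[[4]]), chrom = as.character(b[[1]]),
    start = as.numeric(b[[2]]), end = as.numeric(b[[3]]),
    source = if (ncol(b) >= 5L) as.character(b[[5]]) else NA_character_
  )
  validate_tads(tads)
}

#' @rdname read_tad_bed
#' @param tads A TAD table.
#' @export
write_tad_bed <- function(tads, path) {
  t <- validate_tads(tads)
  data.table::fwrite(t[, list(chrom, start, end, tad_id, source)], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED6 file
#'
#' `chrom start end gene_id score strand`, 0-based half-open.
#'
#' @param path Path to the BED file.
#' @return A `data.table` with columns gene_id, chrom, start, end, strand.
#' @export
read_gene_bed <- function(path) {
  b <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(b) < 6L) stopf("gene BED needs 6 columns")
  g <- data.table::data.table(
    gene_id = as.character(b[[4]]), chrom = as.character(b[[1]]),
    start = as.numeric(b[[2]]), end = as.numeric(b[[3]]),
    strand = as.character(b[[6]])
  )
  if (any(g$start >= g$end)) stopf("gene with start >= end")
  if (anyDuplicated(g$gene_id)) stopf("duplicate gene_id")
  g[]
}

#' @rdname read_gene_bed
#' @param genes A gene table.
#' @export
write_gene_bed <- function(genes, path) {
  data.table::fwrite(
    data.table::data.table(genes$chrom, genes$start, genes$end, genes$gene_id,
                           ".", genes$strand),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a normalized expression matrix
#'
#' Tab-separated, first column gene ids, header row sample ids; values are
#' normalized log2-scale expression.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE)
  genes <- as.character(d[[1]])
  if (anyDuplicated(genes)) stopf("duplicate gene id in expression matrix")
  m <- as.matrix(d[, -1, with = FALSE])
  rownames(m) <- genes
  if (anyDuplicated(colnames(m))) stopf("duplicate sample id in expression matrix")
  if (!all(is.finite(m))) stopf("non-finite value in expression matrix")
  m
}

#' @rdname read_expression_tsv
#' @param expr Expression matrix (genes x samples).
#' @export
write_expression_tsv <- function(expr, path) {
  d <- data.table::data.table(gene_id = rownames(expr))
  d <- cbind(d, data.table::as.data.table(expr))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
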