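#' Extract candidate reads for a window
#'
#' Returns the primary, non-duplicate alignments overlapping the padded
#' window, including soft-clipped reads and unmapped reads whose mapped mate
#' lies in the region (such records are placed at the mate's coordinate by
#' convention and therefore returned by a region query). Reads are
#' deduplicated by (name, first/second of pair).
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param contig Contig name.
#' @param begin,end 1-based inclusive window.
#' @param config A [realign_config()]; `config$padding` bp are added on each
#'   side.
#' @return data.frame: `qname`, `seq` (as stored in the file), `flag`, `pos`,
#'   `cigar`, `ref_end`, `is_paired`, `is_unmapped`, `is_first`,
#'   `mate_in_region`, `clipped`.
#' @export
extract_reads <- function(bam, contig, begin, end, config = realign_config()) {
  if (!file.exists(bam)) stop("alignment file not found: ", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("no index found for ", bam,
         "; create one (e.g. Rsamtools::indexBam) before extraction")
  lo <- max(1L, begin - config$padding); hi <- end + config$padding
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(contig, IRanges::IRanges(lo, hi)),
    what = c("qname", "flag", "pos", "cigar", "seq", "mrnm", "mpos"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0) {
    return(data.frame(qname = character(0), seq = character(0),
                      flag = integer(0), pos = integer(0), cigar = character(0),
                      ref_end = integer(0), is_paired = logical(0),
                      is_unmapped = logical(0), is_first = logical(0),
                      mate_in_region = logical(0), clipped = logical(0),
                      stringsAsFactors = FALSE))
  }
  flag <- res$flag
  is_unmapped <- bitwAnd(flag, 4L) > 0
  cig <- ifelse(is.na(res$cigar), "", res$cigar)
  rw <- rep(NA_integer_, n)
  ok <- nzchar(cig)
  rw[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig[ok])
  df <- data.frame(
    qname = res$qname, seq = as.character(res$seq), flag = flag,
    pos = res$pos, cigar = cig,
    ref_end = ifelse(is.na(rw), res$pos, res$pos + rw - 1L),
    is_paired = bitwAnd(flag, 1L) > 0,
    is_unmapped = is_unmapped,
    is_first = bitwAnd(flag, 64L) > 0,
    mate_in_region = !is.na(res$mrnm) & as.character(res$mrnm) == contig &
      !is.na(res$mpos) & res$mpos >= lo & res$mpos <= hi &
      bitwAnd(flag, 8L) == 0,
    clipped = grepl("[SH]", cig),
    stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$qname, df$is_first)), , drop = FALSE]
  df <- df[nzchar(df$seq) & df$seq != "*", , drop = FALSE]
  rownames(df) <- NULL
  df
}

align_scores <- function(reads, subject, config) {
  # best semi-global score of each read (either orientation) against subject
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = FALSE)
  pats <- Biostrings::DNAStringSet(reads)
  fwd <- Biostrings::pairwiseAlignment(
    pats, Biostrings::DNAString(subject), type = "global-local",
    substitutionMatrix = mat, gapOpening = config$gap_open,
    gapExtension = config$gap_extend, scoreOnly = TRUE)
  rev <- Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(pats), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend,
    scoreOnly = TRUE)
  pmax(fwd, rev)
}

site_alt_contexts <- function(site, reference, flank) {
  # junction-centered windows of the full local alternative haplotype, so the
  # alternative allele has the same flanking reach as the reference contexts
  ref <- as.character(reference); n <- nchar(ref)
  sub <- function(from, to) substr(ref, max(1L, from), min(n, to))
  b <- site$begin; e <- site$end; type <- site$sv_type
  left <- sub(b - flank + 1L, b)
  right <- sub(e + 1L, e + flank)
  span <- if (type %in% c("DUP", "INV")) sub(b + 1L, e) else ""
  if (type == "INS" && site$ins_fragment == "left") {
    hap <- paste0(left, site$alt_seq); junctions <- nchar(left)
  } else if (type == "INS" && site$ins_fragment == "right") {
    hap <- paste0(site$alt_seq, right); junctions <- nchar(site$alt_seq)
  } else {
    allele <- switch(type, DEL = "", INS = site$alt_seq,
                     DUP = paste0(span, span), INV = revcomp(span),
                     BND = site$alt_seq)
    hap <- paste0(left, allele, right)
    junctions <- switch(type,
      DEL = nchar(left),
      INS = c(nchar(left), nchar(left) + nchar(allele)),
      DUP = nchar(left) + nchar(span),     # the copy1|copy2 boundary
      INV = c(nchar(left), nchar(left) + nchar(allele)),
      BND = nchar(left))
  }
  vapply(unique(junctions), function(j)
    substr(hap, max(1L, j - flank + 1L), min(nchar(hap), j + flank)), "")
}

#' Realign extracted reads to a breakpoint graph
#'
#' For each biallelic SV site in the graph, candidate reads (linear placement
#' within a read length of a junction, or unmapped with the mate placed
#' there) are scored by semi-global alignment, in both orientations, against
#' the reference and alternative local haplotype contexts of each breakpoint.
#' A read supports the allele(s) achieving its best score; equally good
#' alignments to both alleles support both; if the best score fails the match
#' threshold (`config$min_score_frac` of the perfect score) the read supports
#' neither allele. Reads shorter than the minimum anchor are skipped and
#' counted.
#'
#' @param reads data.frame from [extract_reads()].
#' @param graph A `graphsv_graph` built for the window (its `$breakpoints`
#'   table drives the contexts).
#' @param reference Full contig sequence.
#' @param config A [realign_config()].
#' @param sample Optional sample name stamped onto the table.
#' @return data.frame of per-read allele support: `site_id`, `qname`,
#'   `supports_ref`, `supports_alt` (both FALSE = neither), `is_paired`,
#'   `mate_on_graph`, `score`, `sample`; attribute `n_skipped` counts skipped
#'   reads.
#' @export
realign_reads <- function(reads, graph, reference, config = realign_config(),
                          sample = NA_character_) {
  bps <- graph$breakpoints
  empty <- data.frame(site_id = character(0), qname = character(0),
                      supports_ref = logical(0), supports_alt = logical(0),
                      is_paired = logical(0), mate_on_graph = logical(0),
                      score = numeric(0), sample = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "n_skipped") <- 0L
  if (is.null(bps) || nrow(bps) == 0 || nrow(reads) == 0) return(empty)
  rl <- nchar(reads$seq)
  skip <- rl < graph$config$min_anchor
  n_skipped <- sum(skip)
  reads <- reads[!skip, , drop = FALSE]
  rl <- rl[!skip]
  if (!nrow(reads)) { attr(empty, "n_skipped") <- n_skipped; return(empty) }
  reach <- max(rl) + 10L
  out <- vector("list", length(unique(bps$site_id)))
  names(out) <- unique(bps$site_id)
  site_rows <- graph$sites
  refn <- nchar(reference)
  min_anchor <- graph$config$min_anchor
  # potential reach of each read beyond its placed interval: soft-clipped
  # bases, and a full read length for unmapped reads placed at their mate
  clip_l <- suppressWarnings(as.integer(sub("^([0-9]+)S.*$", "\\1", reads$cigar)))
  clip_l[is.na(clip_l) | !grepl("^[0-9]+S", reads$cigar)] <- 0L
  clip_r <- suppressWarnings(as.integer(sub("^.*[MIDN]([0-9]+)S$", "\\1", reads$cigar)))
  clip_r[is.na(clip_r) | !grepl("S$", reads$cigar)] <- 0L
  lo_ext <- reads$pos - clip_l - ifelse(reads$is_unmapped, rl, 0L)
  hi_ext <- reads$ref_end + clip_r + ifelse(reads$is_unmapped, rl, 0L)
  for (sid in unique(bps$site_id)) {
    srow <- site_rows[site_rows$site_id == sid, , drop = FALSE][1, ]
    anchors <- unique(c(srow$begin, srow$end))
    near <- rep(FALSE, nrow(reads))
    crossing <- rep(FALSE, nrow(reads))
    for (a in anchors) {
      near <- near | (reads$pos <= a + reach & reads$ref_end >= a - reach)
      # could the read place >= min_anchor bases on both sides of the
      # junction between a and a+1?
      crossing <- crossing |
        (lo_ext <= a - min_anchor + 1L & hi_ext >= a + min_anchor)
    }
    cand <- which(near)
    if (!length(cand)) next
    rs <- reads[cand, , drop = FALSE]
    do_align <- crossing[cand] | rs$is_unmapped
    s_ref <- rep(-Inf, nrow(rs)); s_alt <- rep(-Inf, nrow(rs))
    if (any(do_align)) {
      seqs <- rs$seq[do_align]
      sr <- rep(-Inf, length(seqs)); sa <- rep(-Inf, length(seqs))
      for (a in anchors) {
        rc <- substr(as.character(reference), max(1L, a - config$read_flank + 1L),
                     min(refn, a + config$read_flank))
        sr <- pmax(sr, align_scores(seqs, rc, config))
      }
      for (ctx in site_alt_contexts(srow, reference, config$read_flank)) {
        sa <- pmax(sa, align_scores(seqs, ctx, config))
      }
      s_ref[do_align] <- sr; s_alt[do_align] <- sa
    }
    best <- pmax(s_ref, s_alt)
    thr <- config$min_score_frac * config$match * nchar(rs$seq)
    pass <- best >= thr
    supports_ref <- pass & (s_ref >= best - 1e-9)
    supports_alt <- pass & (s_alt >= best - 1e-9)
    # the informative read multiset is the reads overlapping a breakpoint;
    # placed reads that cannot cross a junction tie between the alleles,
    # which leaves every genotype's likelihood unchanged
    passive <- which(!do_align)
    if (length(passive)) {
      supports_ref[passive] <- TRUE
      supports_alt[passive] <- TRUE
      best[passive] <- NA_real_
    }
    out[[sid]] <- data.frame(
      site_id = sid, qname = rs$qname,
      supports_ref = supports_ref,
      supports_alt = supports_alt,
      is_paired = rs$is_paired,
      mate_on_graph = rs$is_paired & rs$mate_in_region,
      score = best, sample = sample, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Write a per-read allele-support table as TSV (debugging aid)
#' @param supports Output of [realign_reads()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_support_tsv <- function(supports, path) {
  utils::write.table(supports, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
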