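#' Per-base alignment coverage for a region
#'
#' Coverage of reference-consuming aligned bases (soft-clipped bases do not
#' count), as the coverage genotyping model requires.
#'
#' @param bam Indexed BAM path.
#' @param contig Contig name.
#' @param begin,end 1-based inclusive region.
#' @return Integer vector of length `end - begin + 1`; attribute `offset`
#'   equals `begin - 1` for use with [coverage_profile()].
#' @export
region_coverage <- function(bam, contig, begin, end) {
  begin <- max(1L, begin)
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(contig, IRanges::IRanges(begin, end)),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE, isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  covl <- GenomicAlignments::coverage(ga)
  out <- integer(end - begin + 1L)
  if (contig %in% names(covl)) {
    rle <- covl[[contig]]
    hi <- min(end, length(rle))
    if (hi >= begin)
      out[seq_len(hi - begin + 1L)] <- as.integer(rle[begin:hi])
  }
  attr(out, "offset") <- begin - 1L
  out
}

#' Genotype SV sites in one window for one sample
#'
#' Runs the full per-window chain: read extraction, graph construction,
#' realignment, breakpoint-model likelihoods, coverage-model likelihoods for
#' deletions/duplications spanning at least the coverage-model minimum, and
#' the aggregated call.
#'
#' @param bam Indexed BAM for the sample.
#' @param reference Contig sequence (character or DNAString).
#' @param contig Contig name.
#' @param sites `graphsv_sites` rows whose `begin` lies in the window.
#' @param window c(begin, end), 1-based inclusive.
#' @param sample Sample name.
#' @param graph_cfg,realign_cfg,cov_cfg Configuration objects.
#' @return data.frame of `graphsv_call` rows (one per site).
#' @export
genotype_window <- function(bam, reference, contig, sites, window, sample,
                            graph_cfg = graph_config(),
                            realign_cfg = realign_config(),
                            cov_cfg = coverage_config()) {
  if (!nrow(sites)) return(NULL)
  graph <- build_graph(reference, contig, window[1], window[2],
                       sv_sites = sites, config = graph_cfg)
  reads <- extract_reads(bam, contig, window[1], window[2], realign_cfg)
  supports <- realign_reads(reads, graph, reference, realign_cfg, sample)
  cov_pad <- cov_cfg$window_len + cov_cfg$step
  cov <- region_coverage(bam, contig, max(1L, window[1] - cov_pad),
                         window[2] + cov_pad)
  spans <- cbind(sites$begin + 1L, sites$end)
  calls <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    sup <- supports[supports$site_id == s$site_id, , drop = FALSE]
    bp_lk <- breakpoint_genotype(sup, site_id = s$site_id, sample = sample)
    cov_lk <- NULL
    if (s$sv_type %in% c("DEL", "DUP")) {
      prof <- coverage_profile(cov, s$begin, s$end, cov_cfg,
                               exclude = spans[-i, , drop = FALSE],
                               offset = attr(cov, "offset"))
      cov_lk <- tryCatch(
        coverage_genotype(prof, s$sv_type, cov_cfg, s$site_id, sample),
        graphsv_na_model = function(e) NULL)
    }
    aggregate_call(bp_lk, cov_lk)
  })
  do.call(rbind, calls)
}

#' Genotype SV sites across samples
#'
#' Partitions each contig into overlapping SV windows, genotypes every site
#' in every window for every sample, deduplicates sites genotyped in two
#' overlapping windows by keeping the higher-GQ call (ties: the earlier
#' window), and drops sites at which no sample carries a non-reference
#' genotype.
#'
#' @param bams Named character vector of BAM paths (names are sample ids).
#' @param sites `graphsv_sites` data.frame, or a path to an SV VCF.
#' @param reference Path to a FASTA file, or a named character vector of
#'   contig sequences.
#' @param out_vcf Optional path; when given, the multi-sample VCF is written
#'   there (gzip-compressed).
#' @param graph_cfg,realign_cfg,cov_cfg Configuration objects.
#' @param apply_filter Drop sites with no non-reference genotype
#'   (default TRUE).
#' @return data.frame of per-sample calls; attribute `sites` carries the
#'   genotyped site table.
#' @export
genotype_svs <- function(bams, sites, reference, out_vcf = NULL,
                         graph_cfg = graph_config(),
                         realign_cfg = realign_config(),
                         cov_cfg = coverage_config(),
                         apply_filter = TRUE) {
  if (is.null(names(bams)) || any(!nzchar(names(bams))))
    names(bams) <- tools::file_path_sans_ext(basename(unlist(bams)))
  for (b in bams) if (!file.exists(b)) stop("unreadable input: ", b)
  if (is.character(sites) && length(sites) == 1 && file.exists(sites))
    sites <- read_sv_vcf(sites)
  refs <- load_reference(reference)
  if (!nrow(sites)) {
    calls <- data.frame(site_id = character(0), sample = character(0),
                        gt = character(0), gq = integer(0),
                        model = character(0))
    attr(calls, "sites") <- sites
    if (!is.null(out_vcf))
      write_genotype_vcf(calls, sites, out_vcf,
                         contig_lengths = vapply(refs, nchar, 1L))
    return(calls)
  }
  missing_ctg <- setdiff(unique(sites$contig), names(refs))
  if (length(missing_ctg))
    stop("contig(s) absent from reference: ", paste(missing_ctg, collapse = ", "))
  contig_lengths <- vapply(refs, nchar, 1L)
  windows <- partition_genome(contig_lengths[unique(sites$contig)],
                              graph_cfg, kind = "sv")
  all_calls <- list()
  for (w in seq_len(nrow(windows))) {
    ctg <- windows$contig[w]
    wsites <- sites[sites$contig == ctg & sites$begin >= windows$begin[w] &
                      sites$begin <= windows$end[w], , drop = FALSE]
    if (!nrow(wsites)) next
    for (sm in names(bams)) {
      res <- tryCatch(
        genotype_window(bams[[sm]], refs[[ctg]], ctg, wsites,
                        c(windows$begin[w], windows$end[w]), sm,
                        graph_cfg, realign_cfg, cov_cfg),
        error = function(e) stop(sprintf(
          "window %s:%d-%d failed for sample %s: %s", ctg, windows$begin[w],
          windows$end[w], sm, conditionMessage(e)), call. = FALSE))
      if (!is.null(res)) { res$window <- w; all_calls[[length(all_calls) + 1L]] <- res }
    }
  }
  calls <- if (length(all_calls)) do.call(rbind, all_calls) else
    data.frame(site_id = character(0), sample = character(0),
               gt = character(0), gq = integer(0), model = character(0))
  if (nrow(calls)) {
    # dedupe overlap-region duplicates: higher GQ wins, tie -> earlier window
    ord <- order(calls$site_id, calls$sample, -calls$gq, calls$window)
    calls <- calls[ord, , drop = FALSE]
    calls <- calls[!duplicated(paste(calls$site_id, calls$sample)), , drop = FALSE]
    calls <- calls[order(match(calls$site_id, sites$site_id), calls$sample), , drop = FALSE]
    rownames(calls) <- NULL
  }
  if (apply_filter) calls <- filter_calls(calls)
  attr(calls, "sites") <- sites[sites$site_id %in% unique(calls$site_id), , drop = FALSE]
  if (!is.null(out_vcf))
    write_genotype_vcf(calls, attr(calls, "sites"), out_vcf,
                       contig_lengths = contig_lengths)
  calls
}

load_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    dss <- Biostrings::readDNAStringSet(reference)
    names(dss) <- sub("\\s.*$", "", names(dss))
    return(vapply(seq_along(dss), function(i) as.character(dss[[i]]),
                  "", USE.NAMES = FALSE) |> stats::setNames(names(dss)))
  }
  if (is.null(names(reference))) stop("reference must be a FASTA path or a named vector")
  vapply(reference, as.character, "")
}

#' Write multi-sample genotype calls as VCF
#'
#' FORMAT is `GT:GQ:MD:PL:CPL`: aggregated genotype and quality, the model
#' used (BP or CM), and phred-scaled likelihoods of the breakpoint and
#' coverage models. FILTER carries `PASS`/`LOW_CONFIDENCE` from the
#' high-confidence annotation when present.
#'
#' @param calls Per-sample call data.frame.
#' @param sites Site table matching `calls$site_id`.
#' @param path Output path (gzip-compressed; use `.vcf.gz`).
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(calls, sites, path, contig_lengths = NULL) {
  sites <- sites[order(sites$contig, sites$begin, sites$end), , drop = FALSE]
  samples <- sort(unique(calls$sample))
  fmt <- "GT:GQ:MD:PL:CPL"
  gt <- matrix("./.:.:.:.:.", nrow = nrow(sites), ncol = length(samples),
               dimnames = list(NULL, samples))
  idx <- match(calls$site_id, sites$site_id)
  keep <- !is.na(idx)
  md <- ifelse(calls$model == "COVERAGE", "CM", "BP")
  cell <- sprintf("%s:%d:%s:%s:%s", calls$gt, calls$gq, md,
                  calls$pl_bp, calls$pl_cov)
  for (k in which(keep)) gt[idx[k], calls$sample[k]] <- cell[k]
  filt <- rep(".", nrow(sites))
  if ("high_confidence" %in% names(calls)) {
    hc <- tapply(calls$high_confidence, calls$site_id, all)
    filt <- ifelse(unname(hc[sites$site_id]), "PASS", "LOW_CONFIDENCE")
    filt[is.na(filt)] <- "."
  }
  fx <- sites_fix_matrix(sites)
  if (nrow(fx)) fx[, "FILTER"] <- filt
  meta <- vcf_meta(contig_lengths, c(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Aggregated genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality (phred best/second ratio, capped 99)\">",
    "##FORMAT=<ID=MD,Number=1,Type=String,Description=\"Model used: BP breakpoint, CM coverage\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Breakpoint-model phred likelihoods\">",
    "##FORMAT=<ID=CPL,Number=G,Type=Integer,Description=\"Coverage-model phred likelihoods\">",
    "##FILTER=<ID=LOW_CONFIDENCE,Description=\"Fails the configurable high-confidence genotype filter\">"))
  v <- methods::new("vcfR", meta = meta, fix = fx,
                    gt = cbind(FORMAT = rep(fmt, nrow(sites)), gt))
  vcfR::write.vcf(v, path)
  invisible(path)
}
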