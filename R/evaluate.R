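#' Read a PED pedigree file and derive trios
#'
#' Whitespace-delimited columns: FamilyID, ID, FatherID, MotherID, sex,
#' phenotype ("0" marks a missing parent). A trio is any individual with both
#' parents present.
#'
#' @param path PED file path.
#' @return list with `$ped` (the parsed table) and `$trios` (data.frame
#'   `father`, `mother`, `offspring`).
#' @export
read_ped <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"))
  has_both <- ped$father != "0" & ped$mother != "0"
  trios <- data.frame(father = ped$father[has_both],
                      mother = ped$mother[has_both],
                      offspring = ped$id[has_both], stringsAsFactors = FALSE)
  list(ped = ped, trios = trios)
}

#' Extract a truth SV set from a sequence-resolved VCF
#'
#' Decomposes multi-allelic records, left-normalizes each ref/alt pair, keeps
#' alleles whose length difference is at least `criteria$min_size` bp
#' (classified DEL when the reference allele is longer, INS otherwise), and
#' restricts to high-confidence regions expanded by
#' `criteria$region_expansion` bp on each side (both the begin and the end of
#' a site must fall inside an expanded region).
#'
#' @param vcf Path to the VCF.
#' @param regions Optional confidence regions: a BED path or a data.frame
#'   with `contig`, `begin`, `end` (1-based inclusive).
#' @param criteria A [match_criteria()].
#' @return A `graphsv_sites` data.frame.
#' @export
extract_truth_svs <- function(vcf, regions = NULL, criteria = match_criteria()) {
  sites <- read_sv_vcf(vcf, min_size = criteria$min_size)
  if (is.null(regions) || !nrow(sites)) return(sites)
  reg <- read_regions(regions)
  gr <- GenomicRanges::GRanges(reg$contig,
                               IRanges::IRanges(pmax(1L, reg$begin - criteria$region_expansion),
                                                reg$end + criteria$region_expansion))
  gr <- GenomicRanges::reduce(gr)
  pt <- function(pos) GenomicRanges::GRanges(sites$contig, IRanges::IRanges(pos, pos))
  inb <- IRanges::overlapsAny(pt(sites$begin), gr) &
    IRanges::overlapsAny(pt(sites$end), gr)
  out <- sites[inb, , drop = FALSE]
  rownames(out) <- NULL
  out
}

read_regions <- function(regions) {
  if (is.data.frame(regions)) {
    stopifnot(all(c("contig", "begin", "end") %in% names(regions)))
    return(regions)
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(regions, format = "BED")
    return(data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                      begin = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr), stringsAsFactors = FALSE))
  }
  bed <- utils::read.table(regions, header = FALSE, stringsAsFactors = FALSE)
  data.frame(contig = bed[[1]], begin = bed[[2]] + 1L, end = bed[[3]],
             stringsAsFactors = FALSE)
}

type_compatible <- function(type_a, type_b, criteria) {
  if (!criteria$require_type_match) return(rep(TRUE, length(type_a)))
  same <- type_a == type_b
  if (criteria$dup_as_ins)
    same <- same | (type_a == "DUP" & type_b == "INS") |
      (type_a == "INS" & type_b == "DUP")
  same
}

match_pairs <- function(calls, truth, threshold, criteria) {
  # greedy one-to-one matching, nearest pair first by max(d_begin, d_end)
  if (!nrow(calls) || !nrow(truth)) return(NULL)
  cand <- NULL
  for (i in seq_len(nrow(calls))) {
    same_ctg <- truth$contig == calls$contig[i]
    ok_type <- type_compatible(rep(calls$sv_type[i], nrow(truth)),
                               truth$sv_type, criteria)
    db <- abs(truth$begin - calls$begin[i])
    de <- abs(truth$end - calls$end[i])
    d <- pmax(db, de)
    hit <- which(same_ctg & ok_type & d <= threshold)
    if (length(hit))
      cand <- rbind(cand, data.frame(call = i, truth = hit, d = d[hit]))
  }
  if (is.null(cand)) return(NULL)
  cand <- cand[order(cand$d, cand$call, cand$truth), , drop = FALSE]
  used_c <- logical(nrow(calls)); used_t <- logical(nrow(truth))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_c[cand$call[k]] && !used_t[cand$truth[k]]) {
      keep[k] <- TRUE
      used_c[cand$call[k]] <- TRUE; used_t[cand$truth[k]] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Breakpoint-precision recall and FDR
#'
#' Matches a call set against a truth set by greedy one-to-one nearest-first
#' matching: a truth SV is recalled when a type-matching call has both
#' breakpoints within the precision threshold. Returns recall
#' (matched truth / |truth|) and FDR (unmatched calls / |calls|) per
#' threshold, plus recall per size bin (50-99, 100-249, 250-499, 500-999,
#' 1000-1999, >=2000 bp) at `size_bin_threshold`.
#'
#' @param calls,truth `graphsv_sites` data.frames.
#' @param thresholds Integer vector of precision thresholds in bp.
#' @param criteria A [match_criteria()].
#' @param size_bin_threshold Threshold (bp) used for the size-bin table
#'   (default 50).
#' @return list with `$by_threshold` (threshold, n_truth, n_calls, matched,
#'   recall, fdr) and `$by_size` (bin, n_truth, matched, recall).
#' @export
match_sv_sets <- function(calls, truth, thresholds = c(1:50, 100, 200),
                          criteria = match_criteria(),
                          size_bin_threshold = 50L) {
  by_thr <- do.call(rbind, lapply(thresholds, function(t) {
    m <- match_pairs(calls, truth, t, criteria)
    nm <- if (is.null(m)) 0L else nrow(m)
    data.frame(threshold = t, n_truth = nrow(truth), n_calls = nrow(calls),
               matched = nm,
               recall = if (nrow(truth)) nm / nrow(truth) else NA_real_,
               fdr = if (nrow(calls)) (nrow(calls) - nm) / nrow(calls) else NA_real_)
  }))
  bins <- c(50, 100, 250, 500, 1000, 2000, Inf)
  bin_lab <- c("50-99", "100-249", "250-499", "500-999", "1000-1999", ">=2000")
  m <- match_pairs(calls, truth, size_bin_threshold, criteria)
  matched_t <- if (is.null(m)) integer(0) else m$truth
  bin_of <- cut(truth$size, breaks = bins, labels = bin_lab, right = FALSE)
  by_size <- do.call(rbind, lapply(seq_along(bin_lab), function(k) {
    ix <- which(bin_of == bin_lab[k])
    data.frame(bin = bin_lab[k], n_truth = length(ix),
               matched = sum(ix %in% matched_t),
               recall = if (length(ix)) mean(ix %in% matched_t) else NA_real_)
  }))
  list(by_threshold = by_thr, by_size = by_size)
}

#' Concordance of a call set against a supported comparison set
#'
#' A call in `calls_a` is validated when a type-matching record in `calls_b`
#' with support count of at least `min_support` lies within `threshold` bp at
#' both breakpoints (one-to-one matching). Typical use: validating short-read
#' calls against long-read derived calls with per-record read support.
#'
#' @param calls_a `graphsv_sites` data.frame.
#' @param calls_b `graphsv_sites` data.frame with a `support` column.
#' @param min_support Minimum support in `calls_b` (default 2).
#' @param threshold Maximum breakpoint distance in bp (default 50).
#' @param criteria A [match_criteria()].
#' @return list(n = validated count, fraction = validated / |calls_a|).
#' @export
sv_concordance <- function(calls_a, calls_b, min_support = 2L, threshold = 50L,
                           criteria = match_criteria()) {
  if (!nrow(calls_a)) return(list(n = 0L, fraction = NA_real_))
  b <- calls_b
  if (!is.null(b$support)) b <- b[b$support >= min_support, , drop = FALSE]
  m <- match_pairs(calls_a, b, threshold, criteria)
  n <- if (is.null(m)) 0L else nrow(m)
  list(n = n, fraction = n / nrow(calls_a))
}

parse_gt <- function(gt) {
  # returns matrix with columns a1, a2; NA for missing
  g <- sub(":.*$", "", gt)
  g[g %in% c(".", "./.", ".|.")] <- NA
  parts <- strsplit(g, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p)) p[1] else NA_character_, "")))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")))
  cbind(a1 = a1, a2 = a2)
}

trio_consistent <- function(f1, f2, m1, m2, c1, c2) {
  # Mendelian consistency of biallelic trio genotypes (unphased), row-wise
  from <- function(a, p1, p2) a == p1 | a == p2
  (from(c1, f1, f2) & from(c2, m1, m2)) |
    (from(c2, f1, f2) & from(c1, m1, m2))
}

#' Genotype matrix from a cohort VCF or call table
#'
#' @param x Path to a multi-sample VCF, a per-sample call data.frame
#'   (`site_id`, `sample`, `gt`), or an already-built sites x samples matrix
#'   (returned unchanged).
#' @return Character matrix of GT strings, sites x samples.
#' @export
genotype_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    v <- vcfR::read.vcfR(x, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    ids <- v@fix[, "ID"]
    rownames(gt) <- ifelse(is.na(ids) | ids == ".",
                           paste0(v@fix[, "CHROM"], "_", v@fix[, "POS"]), ids)
    return(gt)
  }
  stopifnot(is.data.frame(x))
  samples <- sort(unique(x$sample)); sids <- unique(x$site_id)
  gt <- matrix(NA_character_, nrow = length(sids), ncol = length(samples),
               dimnames = list(sids, samples))
  gt[cbind(match(x$site_id, sids), match(x$sample, samples))] <- x$gt
  gt
}

#' Mendelian inheritance error rate over trios
#'
#' A (site, trio) pair with all three genotypes present is an error when the
#' offspring genotype is impossible under biallelic Mendelian transmission
#' given the parental genotypes. Trios with members missing from the cohort
#' are skipped with a warning.
#'
#' @param gt Genotype matrix ([genotype_matrix()]), VCF path, or call table.
#' @param trios data.frame `father`, `mother`, `offspring`.
#' @return list: `rate` (errors / evaluated pairs), `n_errors`, `n_evaluated`,
#'   `per_site` (data.frame site, evaluated, errors).
#' @export
mendelian_error_rate <- function(gt, trios) {
  gt <- genotype_matrix(gt)
  have <- trios$father %in% colnames(gt) & trios$mother %in% colnames(gt) &
    trios$offspring %in% colnames(gt)
  if (any(!have)) {
    warning(sprintf("skipping %d trio(s) with members absent from the cohort",
                    sum(!have)))
    trios <- trios[have, , drop = FALSE]
  }
  n_sites <- nrow(gt)
  err_site <- integer(n_sites); eval_site <- integer(n_sites)
  for (t in seq_len(nrow(trios))) {
    f <- parse_gt(gt[, trios$father[t]])
    m <- parse_gt(gt[, trios$mother[t]])
    o <- parse_gt(gt[, trios$offspring[t]])
    ok <- !is.na(f[, 1]) & !is.na(m[, 1]) & !is.na(o[, 1])
    cons <- trio_consistent(f[, 1], f[, 2], m[, 1], m[, 2], o[, 1], o[, 2])
    eval_site <- eval_site + ok
    err_site <- err_site + (ok & !cons)
  }
  list(rate = if (sum(eval_site)) sum(err_site) / sum(eval_site) else NA_real_,
       n_errors = sum(err_site), n_evaluated = sum(eval_site),
       per_site = data.frame(site = rownames(gt), evaluated = eval_site,
                             errors = err_site, stringsAsFactors = FALSE))
}

#' Parent-to-offspring transmission rate of SV alleles
#'
#' For every (site, trio, heterozygous parent), transmission is counted when
#' the allele the offspring received from that parent is uniquely determined
#' by the three genotypes (ambiguous configurations, e.g. het x het with a
#' het child, are skipped). An SV allele present in a parent's germline is
#' expected to transmit with probability 50%; systematically lower rates
#' indicate false positives or somatic events.
#'
#' @param gt Genotype matrix, VCF path, or call table.
#' @param trios data.frame `father`, `mother`, `offspring`.
#' @return list: `rate` (overall transmitted / resolvable), `n_transmitted`,
#'   `n_opportunities`, `per_site` (site, opportunities, transmitted, rate).
#' @export
transmission_rate <- function(gt, trios) {
  gt <- genotype_matrix(gt)
  have <- trios$father %in% colnames(gt) & trios$mother %in% colnames(gt) &
    trios$offspring %in% colnames(gt)
  trios <- trios[have, , drop = FALSE]
  n_sites <- nrow(gt)
  opp <- integer(n_sites); trans <- integer(n_sites)
  resolve <- function(p1, p2, c1, c2) {
    # allele received from parent1 (het), NA when ambiguous/inconsistent:
    # enumerate assignments (x from parent1, y from parent2) with {x,y} = child
    from1 <- unique(c(if (c1 %in% p1 && c2 %in% p2) c1 else NULL,
                      if (c2 %in% p1 && c1 %in% p2) c2 else NULL))
    if (length(from1) == 1) from1 else NA_integer_
  }
  for (t in seq_len(nrow(trios))) {
    f <- parse_gt(gt[, trios$father[t]])
    m <- parse_gt(gt[, trios$mother[t]])
    o <- parse_gt(gt[, trios$offspring[t]])
    for (which_par in 1:2) {
      p <- if (which_par == 1) f else m
      q <- if (which_par == 1) m else f
      het <- !is.na(p[, 1]) & p[, 1] + p[, 2] == 1 & !is.na(q[, 1]) & !is.na(o[, 1])
      for (i in which(het)) {
        a <- resolve(p[i, ], q[i, ], o[i, 1], o[i, 2])
        if (!is.na(a)) {
          opp[i] <- opp[i] + 1L
          trans[i] <- trans[i] + (a == 1L)
        }
      }
    }
  }
  per_site <- data.frame(site = rownames(gt), opportunities = opp,
                         transmitted = trans,
                         rate = ifelse(opp > 0, trans / opp, NA_real_),
                         stringsAsFactors = FALSE)
  list(rate = if (sum(opp)) sum(trans) / sum(opp) else NA_real_,
       n_transmitted = sum(trans), n_opportunities = sum(opp),
       per_site = per_site)
}

#' Carrier spectrum of a genotyped cohort
#'
#' Counts, per site, the samples carrying at least one alternative allele and
#' returns the frequency distribution of carrier counts.
#'
#' @param gt Genotype matrix, VCF path, or call table.
#' @return list: `per_site` (site, carriers), `spectrum` (carriers, n_sites).
#' @export
carrier_spectrum <- function(gt) {
  gt <- genotype_matrix(gt)
  carriers <- apply(gt, 1, function(g) {
    a <- parse_gt(g)
    sum(rowSums(a == 1, na.rm = TRUE) > 0 & !is.na(a[, 1]))
  })
  tab <- table(carriers)
  list(per_site = data.frame(site = rownames(gt), carriers = as.integer(carriers),
                             stringsAsFactors = FALSE),
       spectrum = data.frame(carriers = as.integer(names(tab)),
                             n_sites = as.integer(tab)))
}
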