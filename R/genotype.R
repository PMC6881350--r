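#' Per-read genotype likelihood
#'
#' The relative likelihood of observing read `r` given an unphased biallelic
#' genotype with alleles `x` and `y` is 1 when the read supports both alleles,
#' 1/2 when it supports exactly one of them, and a small constant
#' `eps_r` when it supports neither. `eps_r` is `1/2^8` when the read is
#' paired and its mate also mapped onto the graph (a confidently placed pair
#' contradicting both alleles is strong evidence against the genotype) and
#' `1/2^4` otherwise. For a homozygous genotype `x == y`, "both alleles" is
#' simply that allele.
#'
#' @param supports_ref,supports_alt Logical: does the read's best graph
#'   alignment support the reference / the alternative allele (ties support
#'   both).
#' @param x,y Genotype alleles, each 0 (reference) or 1 (alternative).
#' @param is_paired Logical; read is part of a pair.
#' @param mate_on_graph Logical; the mate also mapped onto the graph.
#' @return Likelihood value in (0, 1]. Vectorized over reads.
#' @export
per_read_likelihood <- function(supports_ref, supports_alt, x, y,
                                is_paired = FALSE, mate_on_graph = FALSE) {
  stopifnot(all(x %in% 0:1), all(y %in% 0:1))
  n <- max(length(supports_ref), length(supports_alt), length(x), length(y))
  supports_ref <- rep_len(supports_ref, n); supports_alt <- rep_len(supports_alt, n)
  x <- rep_len(x, n); y <- rep_len(y, n)
  eps <- ifelse(rep_len(is_paired, n) & rep_len(mate_on_graph, n), 2^-8, 2^-4)
  sup_x <- ifelse(x == 0, supports_ref, supports_alt)
  sup_y <- ifelse(y == 0, supports_ref, supports_alt)
  ifelse(sup_x & sup_y, 1, ifelse(sup_x | sup_y, 0.5, eps))
}

new_likelihoods <- function(site_id, sample, model, l00, l01, l11,
                            n_ref = NA_integer_, n_alt = NA_integer_,
                            n_ambiguous = NA_integer_, n_neither = NA_integer_) {
  structure(list(site_id = site_id, sample = sample, model = model,
                 log_l = c(l00 = l00, l01 = l01, l11 = l11),
                 n_ref = n_ref, n_alt = n_alt,
                 n_ambiguous = n_ambiguous, n_neither = n_neither),
            class = "graphsv_likelihoods")
}

#' Breakpoint-model genotype likelihoods for one site and sample
#'
#' Multiplies per-read likelihoods over the multiset of reads whose best
#' graph alignment overlaps the SV breakpoint, in log space. With no reads the
#' three genotype likelihoods are equal (uninformative; GQ 0).
#'
#' @param supports data.frame with one row per read: `site_id`, logical
#'   `supports_ref`, `supports_alt` (both FALSE = neither allele), `is_paired`,
#'   `mate_on_graph`, and optionally `sample`.
#' @param site_id,sample Identifiers stamped onto the result; default from
#'   `supports`.
#' @return A `graphsv_likelihoods` object with natural-log relative
#'   likelihoods `l00`, `l01`, `l11` and the support counts.
#' @export
breakpoint_genotype <- function(supports, site_id = NULL, sample = NULL) {
  if (is.null(site_id)) {
    sid <- unique(supports$site_id)
    if (length(sid) > 1)
      stop("supports mix ", length(sid), " sites; one site per call")
    site_id <- if (length(sid)) sid else NA_character_
  } else if (!is.null(supports$site_id) && nrow(supports) &&
             any(supports$site_id != site_id)) {
    stop("supports carry a different site_id than requested")
  }
  if (is.null(sample))
    sample <- if (!is.null(supports$sample) && nrow(supports))
      unique(supports$sample)[1] else NA_character_
  n <- nrow(supports)
  if (is.null(n) || n == 0) {
    return(new_likelihoods(site_id, sample, "BREAKPOINT", 0, 0, 0, 0L, 0L, 0L, 0L))
  }
  ll <- function(x, y) sum(log(per_read_likelihood(
    supports$supports_ref, supports$supports_alt, x, y,
    supports$is_paired, supports$mate_on_graph)))
  new_likelihoods(site_id, sample, "BREAKPOINT",
                  l00 = ll(0, 0), l01 = ll(0, 1), l11 = ll(1, 1),
                  n_ref = sum(supports$supports_ref & !supports$supports_alt),
                  n_alt = sum(supports$supports_alt & !supports$supports_ref),
                  n_ambiguous = sum(supports$supports_ref & supports$supports_alt),
                  n_neither = sum(!supports$supports_ref & !supports$supports_alt))
}

#' Coverage profile around a deletion/duplication
#'
#' Samples alignment coverage every `config$step` bp (grid positions are
#' multiples of the step) and takes the median inside the SV span
#' `(begin, end]` (`c_in`) and over two `config$window_len` bp windows
#' flanking it (`c_out`, one median over both windows' samples). The lower
#' median is used for even sample counts so pseudo-read counts stay integral.
#' Grid positions falling inside other SVs of the window can be excluded via
#' `exclude` so neighbouring events do not distort the medians.
#'
#' @param coverage Integer vector of per-base alignment coverage for the
#'   contig (or a window of it, see `offset`).
#' @param begin,end SV anchors: affected span is `(begin, end]`.
#' @param config A [coverage_config()].
#' @param exclude Optional two-column matrix/data.frame of 1-based inclusive
#'   intervals to exclude from the flank medians.
#' @param offset Reference position of `coverage[1]` minus one (default 0:
#'   `coverage[p]` is position `p`).
#' @return List of class `graphsv_coverage_profile`: `c_in`, `c_out`,
#'   sampled positions, and the config used.
#' @export
coverage_profile <- function(coverage, begin, end, config = coverage_config(),
                             exclude = NULL, offset = 0L) {
  step <- config$step; wl <- config$window_len
  grid <- function(lo, hi) {
    if (hi < lo) return(integer(0))
    p <- seq.int(from = ceiling(lo / step) * step, to = hi, by = step)
    p[p >= lo & p <= hi]
  }
  inside <- grid(begin + 1L, end)
  flank <- c(grid(begin - wl, begin), grid(end + 1L, end + wl))
  if (!is.null(exclude) && length(flank)) {
    ex <- as.matrix(exclude)
    for (i in seq_len(nrow(ex)))
      flank <- flank[flank < ex[i, 1] | flank > ex[i, 2]]
  }
  look <- function(p) {
    p <- p - offset
    p <- p[p >= 1 & p <= length(coverage)]
    coverage[p]
  }
  structure(list(begin = begin, end = end,
                 c_in = lower_median(look(inside)),
                 c_out = lower_median(look(flank)),
                 n_in = length(inside), n_out = length(flank),
                 pos_in = inside, pos_flank = flank, config = config),
            class = "graphsv_coverage_profile")
}

lower_median <- function(x) {
  if (!length(x)) return(NA_real_)
  sort(x)[ceiling(length(x) / 2)]
}

#' Coverage-model genotype likelihoods
#'
#' For deletions the coverage decrease `max(0, c_out - c_in)` counts as
#' pseudo-reads supporting the deletion and `c_in` as pseudo-reads supporting
#' the reference; for duplications (including inverted duplications) the
#' coverage increase `max(0, c_in - c_out)` supports the duplication and
#' `c_out` (the baseline copy support) the reference. Likelihoods then follow
#' the same product rule as the breakpoint model with every pseudo-read
#' unambiguous and `eps = config$eps` (pseudo-reads are unpaired by
#' definition).
#'
#' @param profile A [coverage_profile()].
#' @param sv_type "DEL" or "DUP"; other types signal a model-not-applicable
#'   condition (`graphsv_na_model` error) so the caller can fall back to the
#'   breakpoint model.
#' @param config A [coverage_config()].
#' @param site_id,sample Identifiers stamped onto the result.
#' @return A `graphsv_likelihoods` object (model "COVERAGE").
#' @export
coverage_genotype <- function(profile, sv_type, config = coverage_config(),
                              site_id = NA_character_, sample = NA_character_) {
  if (!sv_type %in% c("DEL", "DUP")) {
    cond <- structure(class = c("graphsv_na_model", "error", "condition"),
                      list(message = paste0("coverage model not applicable to ", sv_type),
                           call = sys.call()))
    stop(cond)
  }
  span <- profile$end - profile$begin
  if (span < config$min_span) {
    cond <- structure(class = c("graphsv_na_model", "error", "condition"),
                      list(message = sprintf(
                        "SV span %d below coverage-model minimum %d", span,
                        config$min_span), call = sys.call()))
    stop(cond)
  }
  c_in <- profile$c_in; c_out <- profile$c_out
  if (is.na(c_in) || is.na(c_out)) {
    cond <- structure(class = c("graphsv_na_model", "error", "condition"),
                      list(message = "coverage medians unavailable", call = sys.call()))
    stop(cond)
  }
  if (sv_type == "DEL") {
    n_alt <- max(0, c_out - c_in); n_ref <- c_in
  } else {
    n_alt <- max(0, c_in - c_out); n_ref <- c_out
  }
  leps <- log(config$eps)
  new_likelihoods(site_id, sample, "COVERAGE",
                  l00 = n_alt * leps,
                  l01 = (n_ref + n_alt) * log(0.5),
                  l11 = n_ref * leps,
                  n_ref = as.integer(n_ref), n_alt = as.integer(n_alt),
                  n_ambiguous = 0L, n_neither = 0L)
}

#' Genotype and quality from one model's likelihoods
#'
#' The called genotype maximizes the relative likelihood; the genotype
#' quality is the phred-scaled ratio of best to second-best likelihood,
#' `round(10 * log10(L_best / L_second))`, capped at 99. Ties give GQ 0 and
#' the first genotype in 0/0, 0/1, 1/1 order.
#'
#' @param lk A `graphsv_likelihoods` object.
#' @return list(gt, gq, pl) where `pl` are phred-scaled likelihoods
#'   normalized to the best genotype.
#' @export
likelihoods_call <- function(lk) {
  gts <- c("0/0", "0/1", "1/1")
  ll <- lk$log_l
  best <- which.max(ll)
  pl <- round(-10 * (ll - max(ll)) / log(10))
  gq <- min(99, round(10 * (max(ll) - max(ll[-best])) / log(10)))
  list(gt = gts[best], gq = as.integer(gq), pl = as.integer(pmin(pl, 999)))
}

#' Aggregate the breakpoint and coverage calls
#'
#' Each model calls the genotype maximizing its likelihoods with a
#' genotyping quality (phred-scaled best/second-best ratio, capped at 99); the
#' aggregated call is the call of the model with the higher GQ. Ties go to the
#' breakpoint model, which is defined for every SV type.
#'
#' @param breakpoint A `graphsv_likelihoods` (model BREAKPOINT).
#' @param coverage A `graphsv_likelihoods` (model COVERAGE) or NULL when the
#'   model is not applicable.
#' @return A one-row data.frame (class `graphsv_call`): `site_id`, `sample`,
#'   `gt`, `gq`, `model`, per-model genotypes/qualities, and phred likelihood
#'   strings `pl_bp`, `pl_cov`.
#' @export
aggregate_call <- function(breakpoint, coverage = NULL) {
  stopifnot(inherits(breakpoint, "graphsv_likelihoods"))
  bc <- likelihoods_call(breakpoint)
  cc <- if (!is.null(coverage)) likelihoods_call(coverage) else NULL
  use_cov <- !is.null(cc) && cc$gq > bc$gq
  chosen <- if (use_cov) cc else bc
  out <- data.frame(
    site_id = breakpoint$site_id, sample = breakpoint$sample,
    gt = chosen$gt, gq = chosen$gq,
    model = if (use_cov) "COVERAGE" else "BREAKPOINT",
    gt_bp = bc$gt, gq_bp = bc$gq,
    gt_cov = if (!is.null(cc)) cc$gt else NA_character_,
    gq_cov = if (!is.null(cc)) cc$gq else NA_integer_,
    pl_bp = paste(bc$pl, collapse = ","),
    pl_cov = if (!is.null(cc)) paste(cc$pl, collapse = ",") else ".",
    n_ref = breakpoint$n_ref, n_alt = breakpoint$n_alt,
    n_ambiguous = breakpoint$n_ambiguous, n_neither = breakpoint$n_neither,
    stringsAsFactors = FALSE)
  class(out) <- c("graphsv_call", "data.frame")
  out
}

#' Filter cohort calls
#'
#' Drops every site at which no sample carries a non-reference genotype.
#' Surviving sites are annotated by a configurable high-confidence flag
#' (thresholds on the cohort GQ distribution and call rate; the defaults
#' below are this package's own convention and deliberately conservative).
#'
#' @param calls data.frame of per-sample calls (`site_id`, `sample`, `gt`,
#'   `gq`).
#' @param hc_min_median_gq High-confidence flag: minimum median GQ across
#'   samples (default 20).
#' @param hc_min_call_rate High-confidence flag: minimum fraction of samples
#'   with a non-missing genotype (default 0.9).
#' @param hc_min_carriers High-confidence flag: minimum carrier count
#'   (default 1).
#' @return `calls` restricted to retained sites, with logical columns
#'   `nonref_seen` (always TRUE after filtering) and `high_confidence`.
#' @export
filter_calls <- function(calls, hc_min_median_gq = 20, hc_min_call_rate = 0.9,
                         hc_min_carriers = 1L) {
  if (!nrow(calls)) {
    calls$nonref_seen <- logical(0); calls$high_confidence <- logical(0)
    return(calls)
  }
  nonref <- calls$gt %in% c("0/1", "1/1")
  keep_sites <- unique(calls$site_id[nonref])
  out <- calls[calls$site_id %in% keep_sites, , drop = FALSE]
  if (!nrow(out)) { out$nonref_seen <- logical(0); out$high_confidence <- logical(0); return(out) }
  out$nonref_seen <- TRUE
  stats_by_site <- tapply(seq_len(nrow(out)), out$site_id, function(ix) {
    gq <- out$gq[ix]; gt <- out$gt[ix]
    c(med_gq = stats::median(gq, na.rm = TRUE),
      call_rate = mean(!is.na(gt) & gt != "./."),
      carriers = sum(gt %in% c("0/1", "1/1")))
  })
  hc <- vapply(stats_by_site, function(s)
    s["med_gq"] >= hc_min_median_gq && s["call_rate"] >= hc_min_call_rate &&
      s["carriers"] >= hc_min_carriers, TRUE)
  out$high_confidence <- unname(hc[out$site_id])
  rownames(out) <- NULL
  out
}
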