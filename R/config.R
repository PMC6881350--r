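#' Graph construction parameters
#'
#' Parameters controlling breakpoint-graph construction and genome
#' partitioning. Breakpoint sequences are bounded at `l_bp` bases because a
#' short read cannot span more alternative sequence than its own length;
#' bounding them keeps graph size independent of SV size so that realignment
#' is not biased toward large variants.
#'
#' @param l_bp Maximum breakpoint-sequence length in bp. The default, 152,
#'   corresponds to common short-read lengths; set it from the observed read
#'   length of the cohort if that differs.
#' @param small_region Tiling window size (bp) for small-variant genotyping
#'   regions. Default 50,000.
#' @param sv_region Window size (bp) for SV graphs. Default 1,200,000; large
#'   enough that both breakpoints of almost any SV fall in one graph.
#' @param sv_overlap Overlap (bp) between consecutive SV windows. Default
#'   200,000.
#' @param min_anchor Minimum usable breakpoint/alignment anchor length in bp;
#'   breakpoint sequences truncated below this (e.g. at a contig edge) are
#'   dropped with a warning. Default 16.
#' @return A list of class `graphsv_graph_config`.
#' @export
graph_config <- function(l_bp = 152L, small_region = 50000L,
                         sv_region = 1200000L, sv_overlap = 200000L,
                         min_anchor = 16L) {
  stopifnot(l_bp >= 1, small_region >= 1, sv_region >= 1,
            sv_overlap >= 0, sv_overlap < sv_region, min_anchor >= 1)
  structure(list(l_bp = as.integer(l_bp),
                 small_region = as.integer(small_region),
                 sv_region = as.integer(sv_region),
                 sv_overlap = as.integer(sv_overlap),
                 min_anchor = as.integer(min_anchor)),
            class = "graphsv_graph_config")
}

#' Realignment parameters
#'
#' Scoring scheme and acceptance thresholds for local semi-global realignment
#' of reads to breakpoint haplotype contexts. A read's best alignment must
#' reach `min_score_frac` of the maximum attainable score (match score times
#' read length), otherwise the read supports neither allele at the sites it
#' overlaps. These thresholds are configuration values of this implementation,
#' not claims about any other tool.
#'
#' @param match,mismatch,gap_open,gap_extend Alignment scores/penalties.
#' @param min_score_frac Minimum best-alignment score as a fraction of the
#'   perfect score. Default 0.65.
#' @param padding Extra bp added on each side of a window when extracting
#'   reads, so pairs spanning the window edge are kept. Default 1000.
#' @param read_flank Haplotype flank (bp) kept on each side of a junction in
#'   the alignment contexts; slightly more than the read length, so any
#'   junction-crossing read fits entirely inside the context.
#' @return A list of class `graphsv_realign_config`.
#' @export
realign_config <- function(match = 1, mismatch = -2, gap_open = 5,
                           gap_extend = 1, min_score_frac = 0.65,
                           padding = 1000L, read_flank = 161L) {
  stopifnot(match > 0, min_score_frac > 0, min_score_frac <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score_frac = min_score_frac,
                 padding = as.integer(padding),
                 read_flank = as.integer(read_flank)),
            class = "graphsv_realign_config")
}

#' Coverage-model parameters
#'
#' The coverage genotyping model samples alignment coverage every `step` bp
#' and compares the median inside a deletion/duplication with the median over
#' two flanking windows of `window_len` bp. 1000 bp flanks estimate local
#' coverage robustly while rarely overlapping neighbouring SVs. The model is
#' only applied to events spanning at least `min_span` bp; below that too few
#' positions are sampled for a stable median.
#'
#' @param window_len Flanking window length in bp (default 1000).
#' @param step Coverage sampling step in bp (default 20).
#' @param eps Per-pseudo-read mismatch likelihood used in the genotype model
#'   (default 1/2^4; coverage pseudo-reads are unpaired by definition).
#' @param min_span Minimum SV span (bp) for the model to apply (default 100).
#' @return A list of class `graphsv_coverage_config`.
#' @export
coverage_config <- function(window_len = 1000L, step = 20L, eps = 2^-4,
                            min_span = 100L) {
  stopifnot(window_len >= 1, step >= 1, eps > 0, eps < 1)
  structure(list(window_len = as.integer(window_len), step = as.integer(step),
                 eps = eps, min_span = as.integer(min_span)),
            class = "graphsv_coverage_config")
}

#' Cross-sample SV merging parameters
#'
#' Two sites of the same type are mergeable when their sizes differ by at most
#' `max_size_diff` and both begin and end positions differ by at most
#' `max_pos_diff`. A site may not join a group if its begin or end lies more
#' than `max_group_span` from any current member, which caps group growth in
#' repetitive regions.
#'
#' @param max_size_diff Maximum size difference in bp (default 100).
#' @param max_pos_diff Maximum begin/end position difference in bp (default 200).
#' @param max_group_span Maximum distance in bp between any two group members'
#'   begin (or end) positions (default 10,000).
#' @return A list of class `graphsv_merge_config`.
#' @export
merge_config <- function(max_size_diff = 100L, max_pos_diff = 200L,
                         max_group_span = 10000L) {
  stopifnot(max_size_diff > 0, max_pos_diff > 0, max_group_span > 0,
            max_pos_diff <= max_group_span)
  structure(list(max_size_diff = as.integer(max_size_diff),
                 max_pos_diff = as.integer(max_pos_diff),
                 max_group_span = as.integer(max_group_span)),
            class = "graphsv_merge_config")
}

#' Benchmark matching criteria
#'
#' @param precision_threshold Maximum allowed distance (bp) at each breakpoint
#'   for a call to match a truth SV.
#' @param require_type_match Require identical SV type (default TRUE).
#' @param dup_as_ins Also allow DUP calls to match INS truth records (callers
#'   disagree on the representation of tandem duplications). Default FALSE.
#' @param region_expansion bp added to each side of high-confidence regions
#'   before restricting truth/call sets (default 25), absorbing imprecise
#'   breakpoints at region edges.
#' @param min_size Minimum |length difference| (bp) for an allele to count as
#'   an SV when extracting truth sets (default 50).
#' @return A list of class `graphsv_match_criteria`.
#' @export
match_criteria <- function(precision_threshold = 50L, require_type_match = TRUE,
                           dup_as_ins = FALSE, region_expansion = 25L,
                           min_size = 50L) {
  stopifnot(precision_threshold >= 0, region_expansion >= 0, min_size >= 0)
  structure(list(precision_threshold = as.integer(precision_threshold),
                 require_type_match = isTRUE(require_type_match),
                 dup_as_ins = isTRUE(dup_as_ins),
                 region_expansion = as.integer(region_expansion),
                 min_size = as.integer(min_size)),
            class = "graphsv_match_criteria")
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Recognised keys are the arguments of [graph_config()], [realign_config()],
#' [coverage_config()], [merge_config()] and [match_criteria()]; unknown keys
#' are returned untouched under `$extra`.
#'
#' @param path File path.
#' @return Named list with one element per config object plus `$extra`.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else if (v %in% c("true", "TRUE", "false", "FALSE"))
      as.logical(toupper(v)) else v
  })
  names(vals) <- vapply(kv, `[`, "", 2L)
  assemble <- function(fn) {
    keep <- vals[names(vals) %in% names(formals(fn))]
    do.call(fn, keep)
  }
  known <- unique(unlist(lapply(list(graph_config, realign_config,
                                     coverage_config, merge_config,
                                     match_criteria), function(f) names(formals(f)))))
  list(graph = assemble(graph_config),
       realign = assemble(realign_config),
       coverage = assemble(coverage_config),
       merge = assemble(merge_config),
       match = assemble(match_criteria),
       extra = vals[!names(vals) %in% known])
}
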