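#' Pairwise SV mergeability
#'
#' Two sites are mergeable when they are of the same type, their sizes differ
#' by at most `max_size_diff`, and both their begin and their end positions
#' are within `max_pos_diff` of each other. Insertions have `end == begin`,
#' so the position criteria reduce to a single-position check plus the size
#' check.
#'
#' @param a,b One-row site data.frames (or lists with `sv_type`, `begin`,
#'   `end`, `size`).
#' @param config A [merge_config()].
#' @return TRUE or FALSE.
#' @export
sv_mergeable <- function(a, b, config = merge_config()) {
  a$sv_type == b$sv_type &&
    abs(a$size - b$size) <= config$max_size_diff &&
    abs(a$begin - b$begin) <= config$max_pos_diff &&
    abs(a$end - b$end) <= config$max_pos_diff
}

#' Group SV sites across samples
#'
#' Single left-to-right sweep over sites sorted by (contig, begin): each site
#' joins the first group in which it is mergeable with at least one member
#' and no member's begin or end position lies more than
#' `config$max_group_span` away; otherwise it founds a new group. Growth is
#' transitive: members need not be pairwise mergeable. When several open
#' groups qualify, the site joins the one whose current representative
#' candidate (most common begin/end pair so far) is nearest by
#' |d begin| + |d end|.
#'
#' @param sites `graphsv_sites` data.frame, sorted by (contig, begin);
#'   unsorted input is an error because sweep correctness depends on order.
#' @param config A [merge_config()].
#' @return List of `graphsv_merge_group` objects, each with `$members` (row
#'   indices into `sites`), `$sites` (the member rows) and `$representative`
#'   (one member row, elected by [elect_representative()]).
#' @export
group_svs <- function(sites, config = merge_config()) {
  n <- nrow(sites)
  if (!n) return(list())
  if (any(unlist(tapply(sites$begin, sites$contig, is.unsorted))))
    stop("sites must be sorted by (contig, begin) before grouping")
  groups <- list()      # closed groups
  open <- list()        # per contig sweep state
  cur_contig <- NULL
  flush_open <- function() {
    for (g in open) groups[[length(groups) + 1L]] <<- g
    open <<- list()
  }
  for (i in seq_len(n)) {
    s <- sites[i, ]
    if (is.null(cur_contig) || s$contig != cur_contig) {
      flush_open(); cur_contig <- s$contig
    }
    # retire groups that can no longer accept anything at or beyond s$begin
    if (length(open)) {
      alive <- vapply(open, function(g)
        s$begin - min(g$begin) <= config$max_group_span, TRUE)
      for (g in open[!alive]) groups[[length(groups) + 1L]] <- g
      open <- open[alive]
    }
    cand <- which(vapply(open, function(g) {
      if (g$sv_type != s$sv_type) return(FALSE)
      within_span <- all(abs(s$begin - g$begin) <= config$max_group_span) &&
        all(abs(s$end - g$end) <= config$max_group_span)
      if (!within_span) return(FALSE)
      any(abs(s$size - g$size) <= config$max_size_diff &
            abs(s$begin - g$begin) <= config$max_pos_diff &
            abs(s$end - g$end) <= config$max_pos_diff)
    }, TRUE))
    if (!length(cand)) {
      open[[length(open) + 1L]] <- list(sv_type = s$sv_type, members = i,
                                        begin = s$begin, end = s$end,
                                        size = s$size)
    } else {
      pick <- cand[1]
      if (length(cand) > 1) {
        d <- vapply(cand, function(k) {
          rep_be <- group_mode_pair(open[[k]])
          abs(s$begin - rep_be[1]) + abs(s$end - rep_be[2])
        }, 1)
        pick <- cand[which.min(d)]
      }
      g <- open[[pick]]
      g$members <- c(g$members, i)
      g$begin <- c(g$begin, s$begin); g$end <- c(g$end, s$end)
      g$size <- c(g$size, s$size)
      open[[pick]] <- g
    }
  }
  flush_open()
  lapply(groups, function(g) {
    members <- g$members
    grp <- structure(list(members = members,
                          sites = sites[members, , drop = FALSE]),
                     class = "graphsv_merge_group")
    grp$representative <- elect_representative(grp)
    grp
  })
}

group_mode_pair <- function(g) {
  key <- paste(g$begin, g$end)
  tab <- table(key)
  best <- names(tab)[tab == max(tab)]
  pairs <- do.call(rbind, strsplit(best, " "))
  pairs <- apply(pairs, 2, as.integer)
  if (is.null(dim(pairs))) pairs <- matrix(pairs, nrow = 1)
  ord <- order(pairs[, 1], pairs[, 2])
  pairs[ord[1], ]
}

#' Elect a group representative
#'
#' The representative is a member whose (begin, end) pair has maximal
#' multiplicity in the group; ties are broken by smallest begin, then
#' smallest end, then first seen. Its INFO field is carried to output
#' verbatim.
#'
#' @param group A `graphsv_merge_group` (needs `$sites`).
#' @return One member row.
#' @export
elect_representative <- function(group) {
  st <- group$sites
  stopifnot(nrow(st) >= 1)
  key <- paste(st$begin, st$end)
  tab <- table(key)
  cnt <- as.integer(tab[key])
  ord <- order(-cnt, st$begin, st$end, seq_len(nrow(st)))
  st[ord[1], , drop = FALSE]
}

#' Merge single-sample SV VCFs into one non-redundant site list
#'
#' Reads SV sites from each input (sample genotype columns are never
#' consulted and FILTER values are ignored, so non-PASS discoveries are
#' merged too), groups them per contig with [group_svs()], and writes one
#' record per group carrying the representative's coordinates, alleles and
#' verbatim INFO plus `NUM_MERGED_SVS` (member count) and `SVMODEL=AGGREGATED`
#' annotations.
#'
#' @param paths Character vector of single-sample VCF paths.
#' @param out_vcf Output VCF path (gzip-compressed), or NULL to skip writing.
#' @param config A [merge_config()].
#' @param min_size Minimum SV size to consider (default 50).
#' @return The merged `graphsv_sites` table (representatives), with a
#'   `num_merged` column; attribute `groups` holds the full group list.
#' @export
merge_sv_vcfs <- function(paths, out_vcf = NULL, config = merge_config(),
                          min_size = 50L) {
  site_l <- lapply(paths, read_sv_vcf, min_size = min_size)
  sites <- do.call(rbind, site_l)
  sites <- sites[order(sites$contig, sites$begin), , drop = FALSE]
  rownames(sites) <- NULL
  groups <- group_svs(sites, config)
  reps <- do.call(rbind, lapply(groups, `[[`, "representative"))
  reps$num_merged <- vapply(groups, function(g) length(g$members), 1L)
  ord <- order(reps$contig, reps$begin, reps$end)
  reps <- reps[ord, , drop = FALSE]
  rownames(reps) <- NULL
  if (!is.null(out_vcf)) {
    info <- ifelse(nzchar(reps$info), reps$info, site_info_string(reps))
    info <- sprintf("%s;NUM_MERGED_SVS=%d;SVMODEL=AGGREGATED", info,
                    reps$num_merged)
    write_sv_vcf(reps, out_vcf, info = info, extra_meta = c(
      "##INFO=<ID=NUM_MERGED_SVS,Number=1,Type=Integer,Description=\"Number of sites merged into this record\">",
      "##INFO=<ID=SVMODEL,Number=1,Type=String,Description=\"Genotyping model request\">"))
  }
  attr(reps, "groups") <- groups
  reps
}
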