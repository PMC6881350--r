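#' Breakpoint sequences for a structural variant
#'
#' An SV is encoded in the graph by the sequence of its alternative haplotype
#' near each junction, bounded at `config$l_bp` bases: the START breakpoint
#' carries the first bases of the alternative haplotype after it diverges from
#' the reference, the END breakpoint the last bases before it converges back.
#' Splicing rules per type (spans are `(begin, end]`):
#' \itemize{
#'  \item DEL: haplotype `ref[1..begin] + ref[end+1..]`; two breakpoints.
#'  \item INS: haplotype `ref[1..begin] + alt_seq + ref[begin+1..]`; two
#'    breakpoints when the insert is fully known, one (START) when only a
#'    left-assembled fragment exists, one (END) for a right fragment.
#'  \item DUP (tandem): one junction where the end of the duplicated span is
#'    followed by its own start, `... ref[end] | ref[begin+1] ...`.
#'  \item INV: the span is reverse-complemented in place; two junctions.
#'  \item BND: single junction; such sites use the breakpoint model only.
#' }
#' Breakpoints whose alternative sequence is truncated below
#' `config$min_anchor` bases (e.g. by a contig edge) are dropped with a
#' warning; an SV with no derivable junction sequence is rejected.
#'
#' @param site One-row `graphsv_sites` data.frame (or list with the same
#'   fields).
#' @param reference Contig sequence as a character string or
#'   [Biostrings::DNAString].
#' @param config A [graph_config()].
#' @return data.frame with columns `site_id`, `side` ("START"/"END"),
#'   `anchor` (1-based reference position), `orient` ("after": the
#'   alternative sequence follows the anchor; "before": it precedes the
#'   convergence point), `ref_seq`, `alt_seq`.
#' @export
make_breakpoints <- function(site, reference, config = graph_config()) {
  ref <- as.character(reference)
  n <- nchar(ref)
  L <- config$l_bp
  b <- as.integer(site$begin); e <- as.integer(site$end)
  if (b < 1 || e > n || b > n)
    stop(sprintf("site %s at [%d,%d] outside contig of length %d",
                 site$site_id, b, e, n))
  sub <- function(from, to) substr(ref, max(1L, from), min(n, to))
  first_l <- function(s) substr(s, 1L, min(L, nchar(s)))
  last_l <- function(s) substr(s, max(1L, nchar(s) - L + 1L), nchar(s))
  type <- site$sv_type
  bp <- switch(type,
    DEL = data.frame(
      side = c("START", "END"), anchor = c(b, e), orient = c("after", "before"),
      ref_seq = c(sub(b + 1L, b + L), sub(e - L + 1L, e)),
      alt_seq = c(first_l(sub(e + 1L, e + L)), last_l(sub(b - L + 1L, b))),
      stringsAsFactors = FALSE),
    INS = {
      if (!nzchar(site$alt_seq)) stop("insertion without any known sequence")
      ins <- site$alt_seq
      frag <- site$ins_fragment
      start_alt <- if (frag %in% c("full"))
        first_l(paste0(ins, sub(b + 1L, b + L))) else if (frag == "left")
        first_l(ins) else NA_character_
      end_alt <- if (frag %in% c("full"))
        last_l(paste0(sub(b - L + 1L, b), ins)) else if (frag == "right")
        last_l(ins) else NA_character_
      df <- data.frame(side = c("START", "END"), anchor = c(b, b),
                       orient = c("after", "before"),
                       ref_seq = c(sub(b + 1L, b + L), sub(b - L + 1L, b)),
                       alt_seq = c(start_alt, end_alt), stringsAsFactors = FALSE)
      df[!is.na(df$alt_seq), , drop = FALSE]
    },
    DUP = data.frame(
      side = "END", anchor = e, orient = "after",
      ref_seq = sub(e + 1L, e + L),
      alt_seq = first_l(sub(b + 1L, b + L)), stringsAsFactors = FALSE),
    INV = {
      span_rc <- revcomp(sub(b + 1L, e))
      data.frame(
        side = c("START", "END"), anchor = c(b, e), orient = c("after", "before"),
        ref_seq = c(sub(b + 1L, b + L), sub(e - L + 1L, e)),
        alt_seq = c(first_l(paste0(span_rc, sub(e + 1L, e + L))),
                    last_l(paste0(sub(b - L + 1L, b), span_rc))),
        stringsAsFactors = FALSE)
    },
    BND = data.frame(side = "START", anchor = b, orient = "after",
                     ref_seq = sub(b + 1L, b + L),
                     alt_seq = if (nzchar(site$alt_seq)) first_l(site$alt_seq)
                               else NA_character_, stringsAsFactors = FALSE),
    stop("unknown sv_type: ", type))
  bp <- bp[!is.na(bp$alt_seq) & nzchar(bp$alt_seq), , drop = FALSE]
  if (nrow(bp) == 0) stop("rejected site ", site$site_id,
                          ": no alternative junction sequence derivable")
  short <- nchar(bp$alt_seq) < config$min_anchor
  if (any(short)) {
    warning(sprintf("site %s: dropping %d breakpoint(s) shorter than %d bp",
                    site$site_id, sum(short), config$min_anchor))
    bp <- bp[!short, , drop = FALSE]
    if (nrow(bp) == 0) stop("rejected site ", site$site_id,
                            ": all breakpoints below minimum anchor")
  }
  cbind(site_id = site$site_id, bp, stringsAsFactors = FALSE)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Build a breakpoint-aware graph for one window
#'
#' Constructs a directed acyclic graph whose backbone is the window's
#' reference sequence split into segments, with one alternative node per
#' small-variant allele and per SV allele in parallel ("bubbles"). Every
#' source-to-sink path is a candidate local haplotype and the reference path
#' reconstructs the window exactly. Variants whose reference spans overlap an
#' already-placed bubble cannot be serialized into the DAG and are demoted to
#' independent biallelic overlay records (`$overlay`), genotyped against the
#' reference-only backbone.
#'
#' @param reference Full contig sequence (character or DNAString); breakpoint
#'   sequences may draw on bases outside the window.
#' @param contig Contig name.
#' @param window_begin,window_end 1-based inclusive window bounds.
#' @param small_variants Optional data.frame with `pos`, `ref`, `alt`
#'   (comma-separated alleles allowed).
#' @param sv_sites Optional `graphsv_sites` data.frame.
#' @param config A [graph_config()].
#' @return A list of class `graphsv_graph` with elements `contig`, `window`,
#'   `nodes` (id, kind, seq, ref_start, ref_end, site_id, allele), `edges`
#'   (from, to), `site_index` (site_id -> node ids), `breakpoints` (the
#'   [make_breakpoints()] table for all SV sites) and `overlay`.
#' @export
build_graph <- function(reference, contig, window_begin, window_end,
                        small_variants = NULL, sv_sites = NULL,
                        config = graph_config()) {
  ref <- as.character(reference)
  stopifnot(window_begin >= 1, window_end <= nchar(ref),
            window_begin <= window_end)
  bubbles <- list()
  if (!is.null(small_variants) && nrow(small_variants)) {
    sm <- decompose_multiallelic(small_variants)
    for (i in seq_len(nrow(sm))) {
      nr <- normalize_allele(sm$pos[i], sm$ref[i], sm$alt[i])
      bubbles[[length(bubbles) + 1L]] <- list(
        site_id = sprintf("%s_%d_%s_%s", contig, nr$pos, nr$ref, nr$alt),
        span_start = nr$pos, span_end = nr$pos + nchar(nr$ref) - 1L,
        alts = nr$alt, sv = FALSE)
    }
  }
  bps <- NULL
  if (!is.null(sv_sites) && nrow(sv_sites)) {
    for (i in seq_len(nrow(sv_sites))) {
      s <- sv_sites[i, ]
      bp <- make_breakpoints(s, ref, config)
      bps <- rbind(bps, bp)
      alt_allele <- switch(s$sv_type,
        DEL = "",
        INS = s$alt_seq,
        DUP = paste0(substr(ref, s$begin + 1L, s$end), substr(ref, s$begin + 1L, s$end)),
        INV = revcomp(substr(ref, s$begin + 1L, s$end)),
        BND = s$alt_seq)
      # span (begin, end] as [begin+1, end]; zero-length for INS/BND
      bubbles[[length(bubbles) + 1L]] <- list(
        site_id = s$site_id, span_start = s$begin + 1L, span_end = s$end,
        alts = alt_allele, sv = TRUE)
    }
  }
  # merge bubbles sharing an identical span into multi-allelic bubbles
  if (length(bubbles)) {
    key <- vapply(bubbles, function(b) sprintf("%d_%d", b$span_start, b$span_end), "")
    bubbles <- lapply(split(bubbles, key), function(grp) {
      list(site_id = unlist(lapply(grp, function(b) rep(b$site_id, length(b$alts)))),
           span_start = grp[[1]]$span_start, span_end = grp[[1]]$span_end,
           alts = unlist(lapply(grp, `[[`, "alts")),
           sv = any(vapply(grp, `[[`, TRUE, "sv")))
    })
    ord <- order(vapply(bubbles, `[[`, 1L, "span_start"),
                 vapply(bubbles, `[[`, 1L, "span_end"))
    bubbles <- bubbles[ord]
  }
  placed <- list(); overlay <- list()
  last_end <- window_begin - 1L  # last ref base consumed by a placed bubble
  for (b in bubbles) {
    # half-open overlap test; zero-length spans sit between span_start-1 and span_start
    lo <- b$span_start; hi <- max(b$span_end, b$span_start - 1L)
    if (lo <= last_end || lo < window_begin ||
        b$span_start - 1L > window_end) {
      overlay[[length(overlay) + 1L]] <- b
    } else {
      placed[[length(placed) + 1L]] <- b
      last_end <- max(last_end, hi)
    }
  }
  nodes <- data.frame(id = integer(0), kind = character(0), seq = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      site_id = character(0), allele = integer(0),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = integer(0), to = integer(0))
  site_index <- list()
  nid <- 0L
  add_node <- function(kind, seq, rs, re, site_id = NA_character_, allele = NA_integer_) {
    nid <<- nid + 1L
    nodes[nrow(nodes) + 1L, ] <<- list(nid, kind, seq, rs, re, site_id, allele)
    nid
  }
  cursor <- window_begin
  frontier <- integer(0)  # node ids whose out-edges attach to the next segment
  connect <- function(tos) {
    for (f in frontier) for (t in tos)
      edges[nrow(edges) + 1L, ] <<- list(f, t)
  }
  emit_ref_segment <- function(to_pos) {  # ref bases [cursor, to_pos]
    if (to_pos >= cursor) {
      id <- add_node("ref", substr(ref, cursor, to_pos), cursor, to_pos)
      connect(id); frontier <<- id; cursor <<- to_pos + 1L
      id
    } else NA_integer_
  }
  for (b in placed) {
    pre_id <- emit_ref_segment(b$span_start - 1L)
    ref_allele_id <- add_node("ref", substr(ref, b$span_start, max(b$span_start - 1L, b$span_end)),
                              b$span_start, b$span_end,
                              site_id = b$site_id[1], allele = 0L)
    connect(ref_allele_id)
    alt_ids <- integer(0)
    for (k in seq_along(b$alts)) {
      alt_ids[k] <- add_node("alt", b$alts[k], b$span_start, b$span_end,
                             site_id = b$site_id[k], allele = k)
      connect(alt_ids[k])
    }
    frontier <- c(ref_allele_id, alt_ids)
    cursor <- b$span_end + 1L
    for (sid in unique(b$site_id))
      site_index[[sid]] <- c(ref_allele_id, alt_ids[b$site_id == sid])
  }
  emit_ref_segment(window_end)
  g <- structure(list(contig = contig, window = c(window_begin, window_end),
                      nodes = nodes, edges = edges, site_index = site_index,
                      breakpoints = bps, sites = sv_sites,
                      overlay = overlay, config = config),
                 class = "graphsv_graph")
  stopifnot(graph_is_dag(g))
  g
}

#' Reconstruct the window reference from a graph's reference path
#' @param g A `graphsv_graph`.
#' @return Character string.
#' @export
graph_reference_path <- function(g) {
  refs <- g$nodes[g$nodes$kind == "ref", , drop = FALSE]
  refs <- refs[order(refs$ref_start, refs$ref_end), , drop = FALSE]
  paste(refs$seq, collapse = "")
}

#' Topological check of a graph
#' @param g A `graphsv_graph`.
#' @return TRUE iff the graph is acyclic.
#' @export
graph_is_dag <- function(g) {
  !is.null(topo_order(g))
}

topo_order <- function(g) {
  n <- nrow(g$nodes)
  if (n == 0) return(integer(0))
  indeg <- integer(n)
  adj <- split(g$edges$to, factor(g$edges$from, levels = g$nodes$id))
  for (t in g$edges$to) indeg[t] <- indeg[t] + 1L
  q <- which(indeg == 0L); out <- integer(0)
  while (length(q)) {
    v <- q[1]; q <- q[-1]; out <- c(out, v)
    for (t in adj[[as.character(v)]]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) q <- c(q, t)
    }
  }
  if (length(out) < n) NULL else out
}

#' Number of source-to-sink paths (candidate local haplotypes)
#' @param g A `graphsv_graph`.
#' @return Integer path count.
#' @export
graph_path_count <- function(g) {
  ord <- topo_order(g)
  if (!length(ord)) return(0L)
  indeg <- table(factor(g$edges$to, levels = g$nodes$id))
  outdeg <- table(factor(g$edges$from, levels = g$nodes$id))
  npaths <- numeric(nrow(g$nodes))
  npaths[indeg == 0] <- 1
  for (v in ord) {
    tos <- g$edges$to[g$edges$from == v]
    for (t in tos) npaths[t] <- npaths[t] + npaths[v]
  }
  sum(npaths[outdeg == 0])
}

#' Dump a graph as versioned JSON lines (debugging aid)
#'
#' One JSON object per line: a header (format version, contig, window), then
#' each node and each edge.
#'
#' @param g A `graphsv_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  con <- file(path, "w"); on.exit(close(con))
  hdr <- list(record = "header", format = "graphsv-graph/1",
              contig = g$contig, window = g$window)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE), con)
  for (i in seq_len(nrow(g$nodes))) {
    writeLines(jsonlite::toJSON(c(record = "node",
                                  as.list(g$nodes[i, ])), auto_unbox = TRUE), con)
  }
  for (i in seq_len(nrow(g$edges))) {
    writeLines(jsonlite::toJSON(c(record = "edge",
                                  as.list(g$edges[i, ])), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Partition contigs into genotyping windows
#'
#' Small-variant windows tile each contig without overlap at
#' `config$small_region` bp. SV windows are `config$sv_region` bp and
#' consecutive windows overlap by `config$sv_overlap` bp (step =
#' `sv_region - sv_overlap`), so both breakpoints of an SV typically fall in
#' one graph. Windows are clipped to the contig.
#'
#' @param contig_lengths Named integer vector.
#' @param config A [graph_config()].
#' @param kind "small" or "sv".
#' @return data.frame with `contig`, `begin`, `end` (1-based inclusive).
#' @export
partition_genome <- function(contig_lengths, config = graph_config(),
                             kind = c("sv", "small")) {
  kind <- match.arg(kind)
  stopifnot(length(contig_lengths) > 0, all(contig_lengths > 0),
            !is.null(names(contig_lengths)))
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- as.integer(contig_lengths[[ctg]])
    if (kind == "small") {
      starts <- seq.int(1L, len, by = config$small_region)
      ends <- pmin(starts + config$small_region - 1L, len)
    } else {
      step <- config$sv_region - config$sv_overlap
      starts <- seq.int(1L, max(1L, len), by = step)
      ends <- pmin(starts + config$sv_region - 1L, len)
      keep <- starts <= len & (starts == 1L | starts + config$sv_overlap - 1L < len)
      starts <- starts[keep]; ends <- ends[keep]
    }
    data.frame(contig = ctg, begin = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
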