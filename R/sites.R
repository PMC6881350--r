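#' Structural-variant site tables
#'
#' `graphsv` represents SV sites as plain data frames with one biallelic site
#' per row and columns:
#' \describe{
#'   \item{site_id}{stable identifier (character)}
#'   \item{contig}{contig name}
#'   \item{begin}{1-based position of the last reference base before the
#'     event (VCF POS convention for symbolic alleles)}
#'   \item{end}{1-based position of the last reference base of the event;
#'     the affected span is `(begin, end]`. For insertions `end == begin`.}
#'   \item{sv_type}{one of DEL, INS, DUP, INV, BND}
#'   \item{size}{event size in bp: span for DEL/DUP/INV, inserted length for
#'     INS}
#'   \item{alt_seq}{inserted/alternative sequence where known, else ""}
#'   \item{ins_fragment}{"full", "left" or "right": whether an insertion's
#'     sequence is fully known or only one assembled flank}
#'   \item{info}{the source VCF INFO string, carried verbatim}
#'   \item{sample}{sample of origin or NA}
#' }
#'
#' @param contig,begin,end,sv_type,size,alt_seq,ins_fragment,info,sample
#'   Site fields, recycled to a common length.
#' @param site_id Optional identifiers; autogenerated when missing.
#' @return A data.frame of class `graphsv_sites`.
#' @export
sv_sites <- function(contig, begin, end = begin, sv_type, size = NULL,
                     alt_seq = "", ins_fragment = "full", info = "",
                     sample = NA_character_, site_id = NULL) {
  sv_type <- toupper(sv_type)
  n <- max(length(contig), length(begin), length(end), length(sv_type))
  df <- data.frame(contig = rep_len(as.character(contig), n),
                   begin = rep_len(as.integer(begin), n),
                   end = rep_len(as.integer(end), n),
                   sv_type = rep_len(sv_type, n),
                   alt_seq = rep_len(toupper(as.character(alt_seq)), n),
                   ins_fragment = rep_len(ins_fragment, n),
                   info = rep_len(as.character(info), n),
                   sample = rep_len(as.character(sample), n),
                   stringsAsFactors = FALSE)
  if (is.null(size)) {
    size <- ifelse(df$sv_type == "INS", nchar(df$alt_seq), df$end - df$begin)
  }
  df$size <- rep_len(as.integer(size), n)
  df$site_id <- if (is.null(site_id))
    sprintf("%s_%d_%s_%d", df$contig, df$begin, df$sv_type, df$size)
  else rep_len(as.character(site_id), n)
  validate_sites(df)
  class(df) <- c("graphsv_sites", "data.frame")
  df
}

validate_sites <- function(df) {
  stopifnot(all(df$begin <= df$end), all(df$size >= 0))
  bad <- !df$sv_type %in% c("DEL", "INS", "DUP", "INV", "BND")
  if (any(bad)) stop("unknown sv_type: ", paste(unique(df$sv_type[bad]), collapse = ", "))
  nz <- nzchar(df$alt_seq)
  if (any(nz & grepl("[^ACGTRYSWKMBDHVN]", df$alt_seq)))
    stop("alt_seq contains non-IUPAC characters")
  invisible(df)
}

#' Extract one key from VCF INFO strings
#'
#' @param info Character vector of INFO strings.
#' @param key INFO key.
#' @return Character vector of values (NA when absent; "" for flags).
#' @export
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "(?:=([^;]*))?(?:;|$)")
  m <- regexec(pat, info)
  vapply(seq_along(info), function(i) {
    mm <- m[[i]]
    if (mm[1] == -1) NA_character_
    else if (length(mm) > 1 && mm[2] != -1) regmatches(info[i], m[i])[[1]][2]
    else ""
  }, "")
}

#' Left-normalize a ref/alt allele pair
#'
#' Trims the shared suffix, then the shared prefix, keeping at least one base
#' on each side, and adjusts the position (standard VCF left-trimming).
#'
#' @param pos 1-based position of `ref`.
#' @param ref,alt Allele strings.
#' @return list(pos, ref, alt).
#' @export
normalize_allele <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  # suffix trim
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # prefix trim
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Decompose multi-allelic records into biallelic rows
#'
#' Splits comma-separated ALT alleles so each output row pairs the reference
#' allele with a single alternative; genotyping treats each such biallelic
#' view independently and read support for other alternatives maps to
#' "neither allele".
#'
#' @param fix data.frame with at least `alt` (comma-separated allele strings);
#'   all other columns are duplicated onto each output row.
#' @return The expanded data.frame with an `allele_index` column (1-based
#'   index of the alternative among the record's original ALT list).
#' @export
decompose_multiallelic <- function(fix) {
  stopifnot(is.data.frame(fix), "alt" %in% names(fix))
  alts <- strsplit(as.character(fix$alt), ",", fixed = TRUE)
  k <- lengths(alts)
  out <- fix[rep(seq_len(nrow(fix)), k), , drop = FALSE]
  out$alt <- unlist(alts)
  out$allele_index <- unlist(lapply(k, seq_len))
  rownames(out) <- NULL
  out
}

sv_type_from_alt <- function(alt) {
  if (grepl("\\[|\\]", alt)) return("BND")
  m <- regmatches(alt, regexec("^<([A-Za-z]+)(:[^>]*)?>$", alt))[[1]]
  if (length(m)) {
    t <- toupper(m[2])
    if (t %in% c("DEL", "INS", "DUP", "INV", "CNV")) return(if (t == "CNV") "DUP" else t)
    return("BND")
  }
  NA_character_  # sequence-resolved
}

#' Read SV sites from a VCF file
#'
#' Recognises symbolic alleles (`<DEL>`, `<INS>`, `<DUP>`, `<INV>`), breakend
#' notation (classified BND) and sequence-resolved alleles whose length
#' difference is at least `min_size` bp. Multi-allelic records are decomposed
#' and sequence-resolved alleles left-normalized first. The INFO string of
#' each record is carried verbatim.
#'
#' @param path VCF file (.vcf or .vcf.gz).
#' @param sample Value for the `sample` column (defaults to the file's first
#'   sample name, or the basename when the VCF carries no samples).
#' @param min_size Minimum SV size in bp (default 50).
#' @param skip_malformed Skip records whose SV interpretation fails, with a
#'   warning giving the count (default TRUE).
#' @return A `graphsv_sites` data.frame.
#' @export
read_sv_vcf <- function(path, sample = NULL, min_size = 50L, skip_malformed = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  if (is.null(sample)) {
    sn <- colnames(v@gt)
    sample <- if (!is.null(sn) && length(sn) > 1) sn[2] else basename(path)
  }
  if (nrow(fx) == 0)
    return(sv_sites(character(0), integer(0), integer(0), character(0)))
  df <- data.frame(contig = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                   ref = fx[, "REF"], alt = fx[, "ALT"],
                   info = ifelse(is.na(fx[, "INFO"]), "", fx[, "INFO"]),
                   stringsAsFactors = FALSE)
  df <- decompose_multiallelic(df)
  n_bad <- 0L
  rows <- lapply(seq_len(nrow(df)), function(i) {
    rec <- df[i, ]
    out <- tryCatch(parse_sv_record(rec, min_size), error = function(e) e)
    if (inherits(out, "error")) {
      if (!skip_malformed) stop(out)
      n_bad <<- n_bad + 1L
      NULL
    } else out
  })
  if (n_bad > 0)
    warning(sprintf("skipped %d malformed/unusable record(s) in %s", n_bad, path))
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(sv_sites(character(0), integer(0), integer(0), character(0)))
  out <- do.call(rbind, rows)
  sv_sites(out$contig, out$begin, out$end, out$sv_type, out$size,
           out$alt_seq, out$ins_fragment, out$info, sample)
}

parse_sv_record <- function(rec, min_size) {
  type <- sv_type_from_alt(rec$alt)
  info <- rec$info
  end_i <- suppressWarnings(as.integer(info_field(info, "END")))
  len_i <- suppressWarnings(as.integer(info_field(info, "SVLEN")))
  svtype_i <- info_field(info, "SVTYPE")
  if (is.na(type)) {  # sequence-resolved
    nr <- normalize_allele(rec$pos, rec$ref, rec$alt)
    diff <- nchar(nr$alt) - nchar(nr$ref)
    if (abs(diff) < min_size) return(NULL)
    if (diff < 0) {  # deletion: pos anchors the retained base
      begin <- nr$pos
      return(data.frame(contig = rec$contig, begin = begin,
                        end = begin + abs(diff), sv_type = "DEL",
                        size = abs(diff), alt_seq = "", ins_fragment = "full",
                        info = info, stringsAsFactors = FALSE))
    }
    begin <- nr$pos
    return(data.frame(contig = rec$contig, begin = begin, end = begin,
                      sv_type = "INS", size = diff,
                      alt_seq = substr(nr$alt, nchar(nr$ref) + 1L, nchar(nr$alt)),
                      ins_fragment = "full", info = info, stringsAsFactors = FALSE))
  }
  if (type == "BND") {
    return(data.frame(contig = rec$contig, begin = rec$pos, end = rec$pos,
                      sv_type = "BND", size = max(0L, abs(len_i), na.rm = TRUE),
                      alt_seq = "", ins_fragment = "full", info = info,
                      stringsAsFactors = FALSE))
  }
  if (!is.na(svtype_i) && nzchar(svtype_i) && toupper(svtype_i) != type &&
      !(type == "DUP" && toupper(svtype_i) %in% c("DUP", "CNV")))
    type <- type  # ALT wins; INFO kept verbatim regardless
  if (type == "INS") {
    seq_i <- info_field(info, "SEQ")
    left_i <- info_field(info, "LEFT_SVINSSEQ")
    alt_seq <- if (!is.na(seq_i) && nzchar(seq_i)) toupper(seq_i)
               else if (!is.na(left_i) && nzchar(left_i)) toupper(left_i) else ""
    frag <- if (!is.na(seq_i) && nzchar(seq_i)) "full"
            else if (nzchar(alt_seq)) "left" else "full"
    size <- if (!is.na(len_i)) abs(len_i) else nchar(alt_seq)
    if (size < min_size) return(NULL)
    return(data.frame(contig = rec$contig, begin = rec$pos, end = rec$pos,
                      sv_type = "INS", size = size, alt_seq = alt_seq,
                      ins_fragment = frag, info = info, stringsAsFactors = FALSE))
  }
  # DEL / DUP / INV: need END or SVLEN
  end <- if (!is.na(end_i)) end_i
         else if (!is.na(len_i)) rec$pos + abs(len_i)
         else stop("symbolic SV without END or SVLEN")
  if (end < rec$pos) stop("END before POS")
  size <- end - rec$pos
  if (size < min_size) return(NULL)
  data.frame(contig = rec$contig, begin = rec$pos, end = end, sv_type = type,
             size = size, alt_seq = "", ins_fragment = "full", info = info,
             stringsAsFactors = FALSE)
}

site_info_string <- function(sites) {
  base <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d",
                  sites$sv_type,
                  ifelse(sites$sv_type == "DEL", -sites$size, sites$size),
                  sites$end)
  base <- ifelse(sites$sv_type == "INS" & nzchar(sites$alt_seq) &
                   sites$ins_fragment == "full",
                 paste0(base, ";SEQ=", sites$alt_seq), base)
  base <- ifelse(sites$sv_type == "INS" & nzchar(sites$alt_seq) &
                   sites$ins_fragment == "left",
                 paste0(base, ";LEFT_SVINSSEQ=", sites$alt_seq), base)
  base
}

sites_fix_matrix <- function(sites, info = NULL) {
  cols <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!nrow(sites))
    return(matrix(character(0), nrow = 0, ncol = 8,
                  dimnames = list(NULL, cols)))
  if (is.null(info)) {
    info <- ifelse(nzchar(sites$info), sites$info, site_info_string(sites))
  }
  alt <- ifelse(sites$sv_type == "INS" & nzchar(sites$alt_seq) &
                  sites$ins_fragment == "full",
                paste0("N", sites$alt_seq), paste0("<", sites$sv_type, ">"))
  cbind(CHROM = sites$contig, POS = as.character(sites$begin),
        ID = sites$site_id, REF = "N", ALT = alt, QUAL = ".", FILTER = ".",
        INFO = info)
}

vcf_meta <- function(contig_lengths = NULL, extra = character(0)) {
  m <- c("##fileformat=VCFv4.2",
         sprintf("##source=graphsv-%s", as.character(utils::packageVersion("graphsv"))),
         "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
         "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
         "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
         "##INFO=<ID=SEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
         "##INFO=<ID=LEFT_SVINSSEQ,Number=1,Type=String,Description=\"Known left flank of insertion\">")
  if (!is.null(contig_lengths))
    m <- c(m, sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                      as.integer(contig_lengths)))
  c(m, extra)
}

#' Write an SV site table as a site-only VCF
#'
#' @param sites `graphsv_sites` data.frame.
#' @param path Output path (written gzip-compressed; use a `.vcf.gz` name).
#' @param contig_lengths Optional named integer vector for `##contig` headers.
#' @param info Optional character vector overriding the INFO column.
#' @param extra_meta Additional meta header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(sites, path, contig_lengths = NULL, info = NULL,
                         extra_meta = character(0)) {
  ord <- order(sites$contig, sites$begin, sites$end)
  sites <- sites[ord, , drop = FALSE]
  if (!is.null(info)) info <- info[ord]
  fx <- sites_fix_matrix(sites, info)
  v <- methods::new("vcfR", meta = vcf_meta(contig_lengths, extra_meta),
                    fix = fx, gt = matrix(character(0), nrow = 0, ncol = 0))
  vcfR::write.vcf(v, path)
  invisible(path)
}
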