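#' Simulation parameters
#'
#' Defines the synthetic study conditions: a random reference contig, planted
#' SVs of the four main types with known diploid genotypes across a pedigree,
#' and paired short reads with naive linear-reference placements. Defaults
#' emulate a typical short-read cohort regime: 30x coverage, 151 bp reads,
#' ~450 bp fragments, 1% base error, SVs of 100-1000 bp planted at least
#' 2 kb apart (so 1000 bp coverage flanks never collide), founder allele
#' frequency 0.25 (segregating but mostly non-homozygous sites).
#'
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param contig_length Reference contig length in bp.
#' @param n_sv_per_type Named counts for DEL/INS/DUP/INV.
#' @param sv_size_range Length-2 vector, SV sizes drawn uniformly (bp).
#' @param coverage Mean diploid depth.
#' @param read_length Read length in bp.
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param base_error_rate Per-base substitution error probability.
#' @param allele_freq Founder haplotype SV allele frequency.
#' @param n_families,n_children Pedigree: families of two founders and
#'   `n_children` offspring each (one trio per child).
#' @param min_spacing Minimum bp between planted SVs.
#' @param breakpoint_jitter Uniform jitter (bp) applied by
#'   [degrade_callset()].
#' @param dropout Per-record dropout probability in [degrade_callset()].
#' @param contig Contig name.
#' @return A list of class `graphsv_sim_config`.
#' @export
sim_config <- function(seed = 1L, contig_length = 250000L,
                       n_sv_per_type = c(DEL = 20L, INS = 20L, DUP = 20L, INV = 20L),
                       sv_size_range = c(100L, 1000L), coverage = 30,
                       read_length = 151L, fragment_mean = 450, fragment_sd = 60,
                       base_error_rate = 0.01, allele_freq = 0.25,
                       n_families = 1L, n_children = 1L, min_spacing = 2000L,
                       breakpoint_jitter = 30L, dropout = 0,
                       contig = "sim1") {
  stopifnot(contig_length > 0, coverage > 0, read_length > 0,
            base_error_rate >= 0, base_error_rate < 1,
            allele_freq > 0, allele_freq < 1, breakpoint_jitter >= 0,
            dropout >= 0, dropout <= 1)
  nm <- names(n_sv_per_type)
  stopifnot(!is.null(nm), all(nm %in% c("DEL", "INS", "DUP", "INV")))
  structure(list(seed = as.integer(seed),
                 contig_length = as.integer(contig_length),
                 n_sv_per_type = n_sv_per_type,
                 sv_size_range = as.integer(sv_size_range),
                 coverage = coverage, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 base_error_rate = base_error_rate, allele_freq = allele_freq,
                 n_families = as.integer(n_families),
                 n_children = as.integer(n_children),
                 min_spacing = as.integer(min_spacing),
                 breakpoint_jitter = as.integer(breakpoint_jitter),
                 dropout = dropout, contig = contig),
            class = "graphsv_sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a random reference contig
#'
#' Uniform-random DNA, deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Character string of length `config$contig_length`.
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  random_dna(config$contig_length)
}

#' Pedigree structure for a simulation
#'
#' @param config A [sim_config()].
#' @return list: `$ped` (PED-style data.frame), `$trios`, `$samples`,
#'   `$founders`.
#' @export
sim_pedigree <- function(config = sim_config()) {
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%d", f)
    fa <- sprintf("%s_fa", fam); mo <- sprintf("%s_mo", fam)
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, id = c(fa, mo), father = "0", mother = "0",
      sex = c(1L, 2L), phenotype = 0L, stringsAsFactors = FALSE)
    kids <- sprintf("%s_c%d", fam, seq_len(config$n_children))
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, id = kids, father = fa, mother = mo,
      sex = rep_len(c(1L, 2L), length(kids)), phenotype = 0L,
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  has_both <- ped$father != "0"
  list(ped = ped,
       trios = data.frame(father = ped$father[has_both],
                          mother = ped$mother[has_both],
                          offspring = ped$id[has_both], stringsAsFactors = FALSE),
       samples = ped$id, founders = ped$id[!has_both])
}

#' Plant SVs with pedigree genotypes
#'
#' Draws non-overlapping SV positions at least `config$min_spacing` bp apart,
#' sizes uniform in `config$sv_size_range`, founder haplotype alleles
#' Bernoulli(`config$allele_freq`), and offspring haplotypes by Mendelian
#' transmission with each site transmitted independently (free recombination
#' between SV loci), recording which parental allele each offspring received.
#'
#' @param reference Contig sequence from [simulate_reference()].
#' @param config A [sim_config()].
#' @param pedigree Output of [sim_pedigree()]; built from `config` when NULL.
#' @return list of class `graphsv_truth`: `$sites` (truth `graphsv_sites`),
#'   `$genotypes` (samples x sites character matrix), `$hap_alleles` (per
#'   sample a 2 x n_sites logical matrix), `$transmissions` (offspring,
#'   site_id, parent, transmitted), `$pedigree`.
#' @export
plant_svs <- function(reference, config = sim_config(), pedigree = NULL) {
  set.seed(config$seed + 1L)
  if (is.null(pedigree)) pedigree <- sim_pedigree(config)
  ref_len <- nchar(reference)
  types <- rep(names(config$n_sv_per_type), config$n_sv_per_type)
  n <- length(types)
  types <- sample(types)  # interleave types along the contig
  sizes <- sample(seq(config$sv_size_range[1], config$sv_size_range[2]),
                  n, replace = TRUE)
  span <- ifelse(types == "INS", 0L, sizes)
  margin <- config$min_spacing
  need <- sum(span) + (n + 1L) * margin
  if (need > ref_len)
    stop(sprintf("contig too small: %d bp needed for %d SVs with %d bp spacing, have %d",
                 need, n, margin, ref_len))
  slack <- ref_len - need
  gaps <- diff(c(0, sort(sample.int(slack + 1L, n) - 1L)))
  begins <- integer(n); cursor <- 0L
  for (i in seq_len(n)) {
    begins[i] <- cursor + margin + gaps[i]
    cursor <- begins[i] + span[i]
  }
  alt_seq <- ifelse(types == "INS",
                    vapply(sizes, random_dna, ""), "")
  sites <- sv_sites(contig = config$contig, begin = begins,
                    end = begins + span, sv_type = types, size = sizes,
                    alt_seq = alt_seq,
                    site_id = sprintf("sv%03d_%s", seq_len(n), types))
  # founder haplotype alleles, offspring by per-site transmission
  hap <- list(); trans <- list()
  for (s in pedigree$founders) {
    hap[[s]] <- matrix(stats::runif(2 * n) < config$allele_freq, nrow = 2)
  }
  kids <- setdiff(pedigree$samples, pedigree$founders)
  ped <- pedigree$ped
  for (s in kids) {
    fa <- ped$father[ped$id == s]; mo <- ped$mother[ped$id == s]
    pick_f <- sample(1:2, n, replace = TRUE)
    pick_m <- sample(1:2, n, replace = TRUE)
    h1 <- hap[[fa]][cbind(pick_f, seq_len(n))]
    h2 <- hap[[mo]][cbind(pick_m, seq_len(n))]
    hap[[s]] <- rbind(h1, h2)
    trans[[length(trans) + 1L]] <- data.frame(
      offspring = s, site_id = rep(sites$site_id, 2),
      parent = rep(c("father", "mother"), each = n),
      parent_id = rep(c(fa, mo), each = n),
      parent_het = c(colSums(hap[[fa]]) == 1L, colSums(hap[[mo]]) == 1L),
      transmitted = c(h1, h2), stringsAsFactors = FALSE)
  }
  gt <- vapply(pedigree$samples, function(s)
    c("0/0", "0/1", "1/1")[colSums(hap[[s]]) + 1L], character(n))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, pedigree$samples))
  gt <- t(gt)
  colnames(gt) <- sites$site_id
  structure(list(sites = sites, genotypes = gt, hap_alleles = hap,
                 transmissions = do.call(rbind, trans), pedigree = pedigree,
                 config = config),
            class = "graphsv_truth")
}

#' Splice a haplotype and its reference block map
#'
#' Applies the carried SV alleles to the reference: deletions remove their
#' span, insertions add sequence, tandem duplications repeat their span,
#' inversions reverse-complement it in place. Returns the haplotype sequence
#' and a block map giving, for every haplotype interval, its reference
#' projection (or none, for inserted sequence), from which naive linear
#' read placements are derived.
#'
#' @param reference Contig sequence.
#' @param sites Truth `graphsv_sites`.
#' @param carried Logical vector: which sites the haplotype carries.
#' @return list(seq, blocks) where blocks has `hstart`, `hend`, `rstart`,
#'   `rend`, `strand` ("+", "-", or "I" for insertions).
#' @export
splice_haplotype <- function(reference, sites, carried) {
  stopifnot(length(carried) == nrow(sites))
  ord <- order(sites$begin)
  sites <- sites[ord, , drop = FALSE]
  carried <- carried[ord]
  keep <- which(carried)
  segs <- character(0)
  blocks <- list()
  hcur <- 1L; rcur <- 1L
  add_block <- function(seq, rstart, rend, strand) {
    w <- nchar(seq)
    if (w == 0L) return(invisible())
    blocks[[length(blocks) + 1L]] <<- data.frame(
      hstart = hcur, hend = hcur + w - 1L, rstart = rstart, rend = rend,
      strand = strand, stringsAsFactors = FALSE)
    segs[length(segs) + 1L] <<- seq
    hcur <<- hcur + w
  }
  for (i in keep) {
    b <- sites$begin[i]; e <- sites$end[i]; tp <- sites$sv_type[i]
    if (b >= rcur)
      add_block(substr(reference, rcur, b), rcur, b, "+")
    span_seq <- substr(reference, b + 1L, e)
    if (tp == "DEL") {
      rcur <- e + 1L
    } else if (tp == "INS") {
      add_block(sites$alt_seq[i], NA_integer_, NA_integer_, "I")
      rcur <- b + 1L
    } else if (tp == "DUP") {
      add_block(span_seq, b + 1L, e, "+")
      add_block(span_seq, b + 1L, e, "+")
      rcur <- e + 1L
    } else if (tp == "INV") {
      add_block(revcomp(span_seq), b + 1L, e, "-")
      rcur <- e + 1L
    } else {  # BND: no sequence effect in the simulator
      rcur <- rcur
    }
  }
  add_block(substr(reference, rcur, nchar(reference)), rcur,
            nchar(reference), "+")
  bl <- do.call(rbind, blocks)
  # merge reference-contiguous "+" blocks so only true junctions break blocks
  merged <- bl[1, , drop = FALSE]
  for (k in seq_len(nrow(bl))[-1]) {
    last <- nrow(merged)
    if (bl$strand[k] == "+" && merged$strand[last] == "+" &&
        !is.na(bl$rstart[k]) && !is.na(merged$rend[last]) &&
        bl$rstart[k] == merged$rend[last] + 1L &&
        bl$hstart[k] == merged$hend[last] + 1L) {
      merged$hend[last] <- bl$hend[k]; merged$rend[last] <- bl$rend[k]
    } else merged <- rbind(merged, bl[k, ])
  }
  rownames(merged) <- NULL
  list(seq = paste(segs, collapse = ""), blocks = merged)
}

place_read <- function(blocks, s, e, min_anchor = 16L) {
  # naive linear placement of hap interval [s, e]; NULL if unplaceable
  p <- place_reads(blocks, s, e, min_anchor)
  if (!p$ok) return(NULL)
  list(pos = p$pos, width = p$width, lclip = p$lclip, rclip = p$rclip,
       minus = p$minus)
}

place_reads <- function(blocks, s, e, min_anchor = 16L) {
  # vectorized over read intervals [s, e]
  n <- length(s)
  best_len <- integer(n); best_blk <- integer(n)
  mappable <- which(blocks$strand != "I")
  for (k in mappable) {
    a <- pmax(blocks$hstart[k], s); b <- pmin(blocks$hend[k], e)
    len <- b - a + 1L
    upd <- len > best_len
    best_len[upd] <- len[upd]; best_blk[upd] <- k
  }
  ok <- best_len >= min_anchor
  pos <- integer(n); lclip <- integer(n); rclip <- integer(n)
  width <- best_len; minus <- logical(n)
  kk <- best_blk[ok]
  a <- pmax(blocks$hstart[kk], s[ok]); b <- pmin(blocks$hend[kk], e[ok])
  lc <- a - s[ok]; rc <- e[ok] - b
  is_minus <- blocks$strand[kk] == "-"
  pos[ok] <- ifelse(is_minus, blocks$rend[kk] - (b - blocks$hstart[kk]),
                    blocks$rstart[kk] + (a - blocks$hstart[kk]))
  # cigar is reported reference-forward: swap clips on "-" placements
  lclip[ok] <- ifelse(is_minus, rc, lc)
  rclip[ok] <- ifelse(is_minus, lc, rc)
  minus[ok] <- is_minus
  data.frame(ok = ok, pos = pos, width = width, lclip = lclip, rclip = rclip,
             minus = minus)
}

revcomp_many <- function(x) {
  out <- x
  nz <- nzchar(x)
  if (any(nz))
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nz])))
  out
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  chars <- strsplit(seqs, "")
  lens <- lengths(chars)
  flat <- unlist(chars)
  idx <- which(stats::runif(length(flat)) < error_rate)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    repl <- sample(bases, length(idx), replace = TRUE)
    clash <- repl == flat[idx]
    while (any(clash)) {
      repl[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- repl == flat[idx]
    }
    flat[idx] <- repl
  }
  grp <- rep(seq_along(seqs), lens)
  vapply(split(flat, grp), paste, "", collapse = "")
}

#' Simulate paired reads with linear-reference placements
#'
#' Samples fragments from each haplotype at half the diploid coverage,
#' generates read pairs of `config$read_length` with i.i.d. base errors, and
#' assigns each read a naive linear placement by projecting its fragment onto
#' the reference through the haplotype block map: bases crossing a planted
#' junction are soft-clipped, reads without a sufficient reference-collinear
#' anchor (e.g. wholly inside an insertion) are emitted unmapped at their
#' mapped mate's position, and pairs where neither read is placeable are
#' dropped. Output is a coordinate-sorted, indexed BAM.
#'
#' @param haps list of two [splice_haplotype()] results.
#' @param config A [sim_config()].
#' @param bam Output BAM path (without or with `.bam` extension).
#' @param sample Sample name (written to `@RG`/read names).
#' @param seed Seed for this sample's reads.
#' @return Path to the sorted, indexed BAM; attributes `n_reads`,
#'   `n_unmapped`.
#' @export
simulate_reads <- function(haps, config, bam, sample = "S1",
                           seed = config$seed) {
  set.seed(seed)
  rl <- config$read_length
  qual <- strrep("?", rl)
  sam <- list()
  n_unmapped <- 0L
  for (h in 1:2) {
    hp <- haps[[h]]
    hlen <- nchar(hp$seq)
    nfrag <- ceiling(config$coverage * hlen / (4 * rl))
    fl <- pmax(rl + 20L, pmin(hlen, round(stats::rnorm(nfrag, config$fragment_mean,
                                                       config$fragment_sd))))
    st <- floor(stats::runif(nfrag) * (hlen - fl + 1)) + 1L
    r1 <- substring(hp$seq, st, st + rl - 1L)
    r2 <- revcomp_many(substring(hp$seq, st + fl - rl, st + fl - 1L))
    r1 <- apply_errors(r1, config$base_error_rate)
    r2 <- apply_errors(r2, config$base_error_rate)
    p1 <- place_reads(hp$blocks, st, st + rl - 1L)
    p2 <- place_reads(hp$blocks, st + fl - rl, st + fl - 1L)
    keep <- p1$ok | p2$ok
    nm <- sprintf("%s_h%d_f%06d", sample, h, seq_len(nfrag))
    pair_rec <- function(seq, p, is_first, mate, seq_is_hap_forward) {
      # stored SEQ is reference-forward; flag 16 when the sequenced read is
      # its reverse complement
      rev_sam <- p$ok & xor(!seq_is_hap_forward, p$minus)
      flag <- 1L + (if (is_first) 64L else 128L) +
        ifelse(p$ok, ifelse(rev_sam, 16L, 0L), 4L) +
        ifelse(mate$ok, ifelse(mate$minus, 32L, 0L), 8L)
      seq_out <- seq
      seq_out[rev_sam] <- revcomp_many(seq[rev_sam])
      pos <- ifelse(p$ok, p$pos, mate$pos)
      cg <- ifelse(p$ok,
                   paste0(ifelse(p$lclip > 0, paste0(p$lclip, "S"), ""),
                          p$width, "M",
                          ifelse(p$rclip > 0, paste0(p$rclip, "S"), "")),
                   "*")
      data.frame(flag = flag, pos = pos, mapq = ifelse(p$ok, 60L, 0L),
                 cigar = cg, pnext = ifelse(mate$ok, mate$pos, pos),
                 seq = seq_out, stringsAsFactors = FALSE)
    }
    a1 <- pair_rec(r1, p1, TRUE, p2, TRUE)
    a2 <- pair_rec(r2, p2, FALSE, p1, FALSE)
    hs <- rbind(cbind(qname = nm, a1)[keep, ], cbind(qname = nm, a2)[keep, ])
    n_unmapped <- n_unmapped + sum(bitwAnd(hs$flag, 4L) > 0)
    sam[[h]] <- hs
  }
  sam <- do.call(rbind, sam)
  sam$rname <- config$contig
  sam$qual <- qual
  sam <- sam[order(sam$pos, sam$qname), , drop = FALSE]
  bam <- sub("\\.bam$", "", bam)
  samfile <- paste0(bam, ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", config$contig, config$contig_length),
           sprintf("@RG\tID:%s\tSM:%s", sample, sample))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t0\t%s\t%s",
                   sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                   sam$cigar, sam$pnext, sam$seq, sam$qual)
  writeLines(c(hdr, lines), samfile)
  out <- Rsamtools::asBam(samfile, destination = bam, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(samfile)
  structure(out, n_reads = nrow(sam), n_unmapped = n_unmapped)
}


#' Write truth genotypes as a multi-sample VCF
#'
#' @param truth A `graphsv_truth` from [plant_svs()].
#' @param path Output VCF path (gzip-compressed).
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path) {
  sites <- truth$sites
  gt <- t(truth$genotypes)  # sites x samples
  fx <- sites_fix_matrix(sites)
  meta <- vcf_meta(stats::setNames(truth$config$contig_length, truth$config$contig),
                   "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Truth genotype\">")
  v <- methods::new("vcfR", meta = meta, fix = fx,
                    gt = cbind(FORMAT = rep("GT", nrow(sites)), gt))
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Emit jittered single-sample discovery callsets
#'
#' Re-emits the truth SVs once per sample with independent uniform jitter of
#' up to `config$breakpoint_jitter` bp on begin/end (on size, for
#' insertions) and optional dropout, emulating imprecise per-sample SV
#' discovery ahead of merging.
#'
#' @param truth A `graphsv_truth`.
#' @param out_dir Directory for the per-sample VCFs (created if needed);
#'   NULL returns the tables only.
#' @param samples Sample names (default: all pedigree samples).
#' @param config A [sim_config()] (uses `breakpoint_jitter`, `dropout`,
#'   `seed`).
#' @param carriers_only Emit only sites the sample carries (default FALSE).
#' @return Named list of per-sample `graphsv_sites` tables; when `out_dir`
#'   is given, attribute `paths` holds the VCF paths.
#' @export
degrade_callset <- function(truth, out_dir = NULL, samples = NULL,
                            config = truth$config, carriers_only = FALSE) {
  set.seed(config$seed + 2L)
  if (is.null(samples)) samples <- truth$pedigree$samples
  j <- config$breakpoint_jitter
  out <- list(); paths <- character(0)
  for (s in samples) {
    st <- truth$sites
    if (carriers_only) {
      carried <- truth$genotypes[s, st$site_id] != "0/0"
      st <- st[carried, , drop = FALSE]
    }
    if (config$dropout > 0 && nrow(st)) {
      st <- st[stats::runif(nrow(st)) >= config$dropout, , drop = FALSE]
    }
    if (nrow(st)) {
      jit <- function(n) if (j > 0) sample(seq(-j, j), n, replace = TRUE) else
        integer(n)
      is_ins <- st$sv_type == "INS"
      db <- jit(nrow(st)); de <- jit(nrow(st))
      st$begin <- pmax(1L, st$begin + db)
      st$end <- ifelse(is_ins, st$begin, pmax(st$begin, st$end + de))
      st$size <- ifelse(is_ins, pmax(50L, st$size + de), st$end - st$begin)
      st$alt_seq <- ifelse(is_ins, substr(st$alt_seq, 1L, st$size), st$alt_seq)
      st$sample <- s
      st$info <- ""
    }
    out[[s]] <- st
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- file.path(out_dir, paste0(s, ".vcf.gz"))
      write_sv_vcf(st, p, contig_lengths = stats::setNames(
        config$contig_length, config$contig))
      paths[s] <- p
    }
  }
  if (!is.null(out_dir)) attr(out, "paths") <- paths
  out
}

#' Run the full simulator and write all fixtures
#'
#' Writes the reference FASTA (+ .fai), truth site and genotype VCF, PED
#' file, per-sample sorted and indexed BAMs for `sequence_samples`, and a
#' JSON manifest of all truth values.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @param sequence_samples Samples to generate reads for (default: the first
#'   trio: both founders and the first child of family 1). Reads are the
#'   expensive part; truth genotypes exist for every pedigree member
#'   regardless.
#' @return list: `$reference`, `$truth`, `$paths` (fasta, truth_vcf, ped,
#'   bams), `$haplotypes` (block maps and sequences of sequenced samples).
#' @export
simulate_cohort <- function(config = sim_config(), out_dir,
                            sequence_samples = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  truth <- plant_svs(reference, config)
  ped <- truth$pedigree
  if (is.null(sequence_samples)) {
    fam1 <- ped$ped[ped$ped$family == ped$ped$family[1], ]
    sequence_samples <- c(fam1$id[fam1$father == "0"],
                          fam1$id[fam1$father != "0"][1])
  }
  fasta <- file.path(out_dir, "reference.fa")
  writeLines(c(paste0(">", config$contig), chunk_seq(reference)), fasta)
  Rsamtools::indexFa(fasta)
  truth_vcf <- file.path(out_dir, "truth.vcf.gz")
  write_truth_vcf(truth, truth_vcf)
  ped_path <- file.path(out_dir, "pedigree.ped")
  utils::write.table(ped$ped, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bams <- character(0); haplotypes <- list()
  for (k in seq_along(sequence_samples)) {
    s <- sequence_samples[k]
    carried <- truth$hap_alleles[[s]]
    haps <- list(splice_haplotype(reference, truth$sites, carried[1, ]),
                 splice_haplotype(reference, truth$sites, carried[2, ]))
    bam <- simulate_reads(haps, config, file.path(out_dir, s), sample = s,
                          seed = config$seed + 10L + k)
    bams[s] <- bam
    haplotypes[[s]] <- haps
  }
  manifest <- list(
    config = unclass(config),
    sites = truth$sites, genotypes = as.data.frame(truth$genotypes),
    transmissions = truth$transmissions,
    sequenced_samples = sequence_samples, bams = as.list(bams))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  list(reference = reference, truth = truth,
       paths = list(fasta = fasta, truth_vcf = truth_vcf, ped = ped_path,
                    bams = bams,
                    manifest = file.path(out_dir, "manifest.json")),
       haplotypes = haplotypes)
}

chunk_seq <- function(s, width = 70L) {
  n <- nchar(s)
  starts <- seq.int(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}
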