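test_that("reference simulation is deterministic and seed-sensitive", {
  cfg <- sim_config(seed = 5, contig_length = 100000L)
  r1 <- simulate_reference(cfg)
  expect_equal(nchar(r1), 100000L)
  expect_true(grepl("^[ACGT]+$", r1))
  expect_identical(r1, simulate_reference(cfg))
  r2 <- simulate_reference(sim_config(seed = 6, contig_length = 100000L))
  mism <- mean(strsplit(r1, "")[[1]] != strsplit(r2, "")[[1]])
  expect_gt(mism, 0.2)  # expected 0.75 for independent uniform sequences
})

test_that("planted SVs respect spacing and capacity limits", {
  cfg <- sim_config(seed = 5, contig_length = 120000L,
                    n_sv_per_type = c(DEL = 5L, INS = 5L, DUP = 5L, INV = 5L))
  truth <- plant_svs(simulate_reference(cfg), cfg)
  st <- truth$sites
  expect_equal(nrow(st), 20L)
  gaps <- st$begin[-1] - st$end[-nrow(st)]
  expect_true(all(gaps >= cfg$min_spacing))
  tiny <- sim_config(seed = 5, contig_length = 10000L)
  expect_error(plant_svs(simulate_reference(tiny), tiny), "contig too small")
})

test_that("haplotype splicing accounts for lengths and re-splices exactly", {
  cfg <- sim_config(seed = 9, contig_length = 80000L,
                    n_sv_per_type = c(DEL = 2L, INS = 2L, DUP = 2L, INV = 2L))
  ref <- simulate_reference(cfg)
  truth <- plant_svs(ref, cfg)
  st <- truth$sites
  # homozygous single-DEL haplotypes are exactly size bp shorter
  one_del <- st[st$sv_type == "DEL", ][1, ]
  hap <- splice_haplotype(ref, st, st$site_id == one_del$site_id)
  expect_equal(nchar(hap$seq), nchar(ref) - one_del$size)
  one_ins <- st[st$sv_type == "INS", ][1, ]
  hapi <- splice_haplotype(ref, st, st$site_id == one_ins$site_id)
  expect_equal(nchar(hapi$seq), nchar(ref) + one_ins$size)
  # independent oracle: plain string concatenation per SV
  for (k in seq_len(nrow(st))) {
    hap1 <- splice_haplotype(ref, st, seq_len(nrow(st)) == k)
    orc <- splice_oracle(ref, st$begin[k], st$end[k], st$sv_type[k],
                         st$alt_seq[k])
    expect_identical(hap1$seq, orc)
  }
  # block maps project back onto the reference faithfully
  all_on <- splice_haplotype(ref, st, rep(TRUE, nrow(st)))
  bl <- all_on$blocks
  for (k in seq_len(nrow(bl))) {
    seg <- substr(all_on$seq, bl$hstart[k], bl$hend[k])
    if (bl$strand[k] == "+") {
      expect_identical(seg, substr(ref, bl$rstart[k], bl$rend[k]))
    } else if (bl$strand[k] == "-") {
      expect_identical(seg, splice_oracle(substr(ref, bl$rstart[k], bl$rend[k]),
                                          0, bl$rend[k] - bl$rstart[k] + 1, "INV"))
    }
  }
})

test_that("offspring haplotypes obey the recorded transmissions", {
  pt <- pedigree_truth()
  truth <- pt$truth
  tr <- truth$transmissions
  kid <- truth$pedigree$trios$offspring[1]
  k_tr <- tr[tr$offspring == kid & tr$parent == "father", ]
  expect_identical(k_tr$transmitted,
                   unname(truth$hap_alleles[[kid]][1, ]))
  # genotype strings agree with haplotype allele content
  expect_identical(unname(truth$genotypes[kid, ]),
                   c("0/0", "0/1", "1/1")[colSums(truth$hap_alleles[[kid]]) + 1])
})

test_that("error-free reads are exact haplotype substrings with soft clips at junctions", {
  cfg <- sim_config(seed = 21, contig_length = 50000L,
                    n_sv_per_type = c(DEL = 2L, INS = 1L, DUP = 1L, INV = 1L),
                    base_error_rate = 0, coverage = 8)
  ref <- simulate_reference(cfg)
  truth <- plant_svs(ref, cfg)
  hap <- truth$hap_alleles[["F1_fa"]]
  hap[1, ] <- TRUE; hap[2, ] <- TRUE  # force all SVs onto both haplotypes
  haps <- list(splice_haplotype(ref, truth$sites, hap[1, ]),
               splice_haplotype(ref, truth$sites, hap[2, ]))
  dir <- tempfile(); dir.create(dir)
  bam <- simulate_reads(haps, cfg, file.path(dir, "ef"), "ef", seed = 3)
  reads <- extract_reads(bam, cfg$contig, 1, cfg$contig_length,
                         realign_config(padding = 0))
  hseq <- haps[[1]]$seq
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  in_hap <- vapply(reads$seq, function(s)
    grepl(s, hseq, fixed = TRUE) || grepl(rc(s), hseq, fixed = TRUE), TRUE)
  expect_true(all(in_hap))
  # deletion-spanning placements are clipped at the junction (hom DEL: every
  # read near the breakpoint comes from the deletion haplotype)
  del <- truth$sites[truth$sites$sv_type == "DEL", ][1, ]
  near <- reads[!reads$is_unmapped &
                  reads$pos <= del$begin - 20 & reads$ref_end >= del$begin - 20, ]
  expect_gt(nrow(near), 0)
  expect_true(any(grepl("S", near$cigar)))
  expect_true(all(near$ref_end <= del$begin))  # no alignment into the deletion
})

test_that("simulated depth is close to the configured coverage", {
  st <- small_trio()
  cfg <- st$config
  bam <- st$paths$bams[["F1_fa"]]
  mid <- 30000L
  cov <- region_coverage(bam, cfg$contig, mid - 5000L, mid + 5000L)
  expect_lt(abs(mean(cov) - cfg$coverage) / cfg$coverage, 0.1)
})

test_that("read counts in a window match the binomial coverage expectation", {
  st <- small_trio()
  cfg <- st$config
  # a window without any planted SV
  gap <- which(diff(st$truth$sites$begin) > 8000)[1]
  lo <- st$truth$sites$end[gap] + 2000L
  hi <- st$truth$sites$begin[gap + 1] - 2000L
  reads <- extract_reads(st$paths$bams[["F1_mo"]], cfg$contig, lo, hi,
                         realign_config(padding = 0))
  expected <- cfg$coverage * (hi - lo) / cfg$read_length
  expect_lt(abs(nrow(reads) - expected) / expected, 0.2)
})

test_that("unmapped reads with a mapped mate in the region are extracted", {
  cfg <- sim_config(seed = 31, contig_length = 40000L,
                    n_sv_per_type = c(DEL = 0L, INS = 1L, DUP = 0L, INV = 0L),
                    sv_size_range = c(800L, 900L), allele_freq = 0.99)
  dir <- tempfile(); dir.create(dir)
  sim <- simulate_cohort(cfg, dir, sequence_samples = "F1_fa")
  ins <- sim$truth$sites[1, ]
  expect_equal(sim$truth$genotypes["F1_fa", 1], "1/1")
  reads <- extract_reads(sim$paths$bams[["F1_fa"]], cfg$contig,
                         ins$begin - 500L, ins$begin + 500L)
  expect_gt(sum(reads$is_unmapped), 0)  # reads wholly inside the insertion
  expect_true(all(reads$mate_in_region[reads$is_unmapped]))
})

test_that("degraded callsets jitter within bounds and honour dropout", {
  st <- small_trio()
  truth <- st$truth
  cfg0 <- truth$config; cfg0$breakpoint_jitter <- 0L
  exact <- degrade_callset(truth, samples = "F1_fa", config = cfg0)
  expect_equal(exact$F1_fa$begin, truth$sites$begin)
  expect_equal(exact$F1_fa$size, truth$sites$size)
  jit <- degrade_callset(truth, samples = c("F1_fa", "F1_mo"))
  for (s in names(jit)) {
    expect_true(all(abs(jit[[s]]$begin - truth$sites$begin) <= 30))
    # every jittered copy remains mergeable with its own truth record
    for (k in seq_len(nrow(truth$sites))) {
      expect_true(sv_mergeable(jit[[s]][k, ], truth$sites[k, ], merge_config()))
    }
  }
  cfg1 <- truth$config; cfg1$dropout <- 1
  none <- degrade_callset(truth, samples = "F1_fa", config = cfg1)
  expect_equal(nrow(none$F1_fa), 0L)
})

test_that("degraded single-sample VCFs merge back to one site per truth SV", {
  st <- small_trio()
  dir <- tempfile()
  deg <- degrade_callset(st$truth, out_dir = dir,
                         samples = c("F1_fa", "F1_mo", "F1_c1"))
  merged <- merge_sv_vcfs(attr(deg, "paths"), NULL, min_size = 40L)
  expect_equal(nrow(merged), nrow(st$truth$sites))
  expect_true(all(merged$num_merged == 3L))
})

test_that("the cohort simulator writes a consistent fixture set", {
  st <- small_trio()
  expect_true(file.exists(st$paths$fasta))
  expect_true(file.exists(paste0(st$paths$fasta, ".fai")))
  expect_true(all(file.exists(st$paths$bams)))
  expect_true(file.exists(st$paths$ped))
  ped <- read_ped(st$paths$ped)
  expect_equal(nrow(ped$trios), st$config$n_children * st$config$n_families)
  vsites <- read_sv_vcf(st$paths$truth_vcf)
  expect_equal(nrow(vsites), nrow(st$truth$sites))
  expect_equal(vsites$begin, st$truth$sites$begin)
  expect_equal(vsites$sv_type, st$truth$sites$sv_type)
  man <- jsonlite::fromJSON(st$paths$manifest)
  expect_equal(nrow(man$sites), nrow(st$truth$sites))
  gtm <- genotype_matrix(st$paths$truth_vcf)
  expect_identical(unname(gtm[, "F1_c1"]),
                   unname(st$truth$genotypes["F1_c1", ]))
})
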