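# Shared fixtures, built once per test run and cached in this environment.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# deterministic 12 kb toy reference
toy_reference <- function() fixture("toy_ref", function() {
  set.seed(424242)
  paste(sample(c("A", "C", "G", "T"), 12000, replace = TRUE), collapse = "")
})

# small sequenced trio: 60 kb contig, 2 SVs per type, 30x reads
small_trio <- function() fixture("small_trio", function() {
  cfg <- sim_config(seed = 101, contig_length = 60000,
                    n_sv_per_type = c(DEL = 2L, INS = 2L, DUP = 2L, INV = 2L))
  dir <- file.path(tempdir(), "graphsv_small_trio")
  sim <- simulate_cohort(cfg, dir,
                         sequence_samples = c("F1_fa", "F1_mo", "F1_c1"))
  sim$config <- cfg
  sim
})

# genotype-only pedigree at the cohort evaluation scale:
# 4 families x 12 children = 48 trios, 200 SV sites
pedigree_truth <- function() fixture("pedigree_truth", function() {
  cfg <- sim_config(seed = 202, contig_length = 600000,
                    n_sv_per_type = c(DEL = 50L, INS = 50L, DUP = 50L, INV = 50L),
                    n_families = 4L, n_children = 12L)
  ref <- simulate_reference(cfg)
  list(config = cfg, truth = plant_svs(ref, cfg), reference = ref)
})

# independent string-splice oracle: alternative local haplotype of one SV
splice_oracle <- function(ref, begin, end, type, ins_seq = "") {
  left <- substr(ref, 1, begin)
  span <- substr(ref, begin + 1, end)
  right <- substr(ref, end + 1, nchar(ref))
  rc <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  switch(type,
         DEL = paste0(left, right),
         INS = paste0(left, ins_seq, right),
         DUP = paste0(left, span, span, right),
         INV = paste0(left, rc(span), right))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_sites <- function(n, contig = "c1", seed = 1) {
  set.seed(seed)
  begin <- sort(sample.int(5e6, n))
  size <- sample(50:2000, n, replace = TRUE)
  type <- sample(c("DEL", "INS", "DUP", "INV"), n, replace = TRUE)
  end <- ifelse(type == "INS", begin, begin + size)
  sv_sites(contig, begin, end, type, size,
           site_id = sprintf("fz%05d", seq_len(n)))
}
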