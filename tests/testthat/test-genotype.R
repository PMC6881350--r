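# direct product oracle over per-read terms, independent of the log-space path
oracle_likelihoods <- function(sup) {
  term <- function(x, y) {
    apply(sup, 1, function(r) {
      sr <- as.logical(r[["supports_ref"]]); sa <- as.logical(r[["supports_alt"]])
      eps <- if (as.logical(r[["is_paired"]]) && as.logical(r[["mate_on_graph"]]))
        1 / 2^8 else 1 / 2^4
      sx <- if (x == 0) sr else sa
      sy <- if (y == 0) sr else sa
      if (sx && sy) 1 else if (sx || sy) 1 / 2 else eps
    })
  }
  c(l00 = prod(term(0, 0)), l01 = prod(term(0, 1)), l11 = prod(term(1, 1)))
}

rand_support <- function(n) {
  kind <- sample(c("ref", "alt", "both", "none"), n, replace = TRUE)
  data.frame(site_id = rep("s", n), supports_ref = kind %in% c("ref", "both"),
             supports_alt = kind %in% c("alt", "both"),
             is_paired = sample(c(TRUE, FALSE), n, replace = TRUE),
             mate_on_graph = sample(c(TRUE, FALSE), n, replace = TRUE))
}

lower_median_probe <- function(x) {
  # recover the median convention through the public profile interface
  n <- length(x)
  cov <- integer(3000)
  pos <- seq(20, by = 20, length.out = n)
  cov[2000 + pos] <- as.integer(x)
  pr <- coverage_profile(cov, 2000, 2000 + pos[n])
  pr$c_in
}

test_that("per-read likelihood returns the three branch values exactly", {
  expect_identical(per_read_likelihood(TRUE, TRUE, 0, 1), 1)
  expect_identical(per_read_likelihood(TRUE, FALSE, 0, 1), 0.5)
  expect_identical(per_read_likelihood(FALSE, TRUE, 0, 1), 0.5)
  expect_identical(per_read_likelihood(FALSE, TRUE, 0, 0, TRUE, TRUE), 2^-8)
  expect_identical(per_read_likelihood(FALSE, TRUE, 0, 0, TRUE, FALSE), 2^-4)
  expect_identical(per_read_likelihood(FALSE, TRUE, 0, 0, FALSE, FALSE), 2^-4)
  expect_identical(per_read_likelihood(FALSE, FALSE, 0, 1, TRUE, TRUE), 2^-8)
  # homozygous genotypes: "both alleles" collapse to the one allele
  expect_identical(per_read_likelihood(TRUE, FALSE, 0, 0), 1)
  expect_identical(per_read_likelihood(FALSE, TRUE, 1, 1), 1)
})

test_that("worked example: 3 ref-only + 2 alt-only paired reads", {
  sup <- data.frame(site_id = "s",
                    supports_ref = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                    supports_alt = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                    is_paired = TRUE, mate_on_graph = TRUE)
  lk <- breakpoint_genotype(sup)
  expect_equal(lk$log_l[["l00"]], log((2^-8)^2), tolerance = 1e-12)
  expect_equal(lk$log_l[["l01"]], log((1 / 2)^5), tolerance = 1e-12)
  expect_equal(lk$log_l[["l11"]], log((2^-8)^3), tolerance = 1e-12)
  expect_equal(likelihoods_call(lk)$gt, "0/1")
  ten_ref <- data.frame(site_id = "s", supports_ref = TRUE,
                        supports_alt = FALSE, is_paired = FALSE,
                        mate_on_graph = FALSE)[rep(1, 10), ]
  lk10 <- breakpoint_genotype(ten_ref)
  expect_equal(likelihoods_call(lk10)$gt, "0/0")
  expect_equal(lk10$log_l[["l00"]], 0)
})

test_that("empty read set is uninformative with GQ 0", {
  lk <- breakpoint_genotype(data.frame(site_id = character(0),
                                       supports_ref = logical(0),
                                       supports_alt = logical(0),
                                       is_paired = logical(0),
                                       mate_on_graph = logical(0)))
  expect_equal(unname(lk$log_l), c(0, 0, 0))
  expect_equal(likelihoods_call(lk)$gq, 0L)
})

test_that("mixed-site support input is a contract violation", {
  sup <- data.frame(site_id = c("a", "b"), supports_ref = TRUE,
                    supports_alt = FALSE, is_paired = FALSE,
                    mate_on_graph = FALSE)
  expect_error(breakpoint_genotype(sup), "mix")
})

test_that("log-space likelihoods match the direct-product oracle to 1e-12", {
  set.seed(11)
  for (i in 1:200) {
    sup <- rand_support(sample(0:12, 1))
    lk <- breakpoint_genotype(sup)
    orc <- if (nrow(sup)) oracle_likelihoods(sup) else c(l00 = 1, l01 = 1, l11 = 1)
    for (g in c("l00", "l01", "l11")) {
      expect_equal(lk$log_l[[g]], log(orc[[g]]), tolerance = 1e-12)
    }
  }
})

test_that("likelihoods are invariant under read reordering", {
  set.seed(12)
  sup <- rand_support(10)
  lk1 <- breakpoint_genotype(sup)
  lk2 <- breakpoint_genotype(sup[sample(nrow(sup)), ])
  expect_equal(lk1$log_l, lk2$log_l, tolerance = 1e-12)
})

test_that("an extra alt-only read never raises L00 nor lowers L11", {
  set.seed(13)
  for (i in 1:30) {
    sup <- rand_support(sample(1:10, 1))
    extra <- data.frame(site_id = "s", supports_ref = FALSE,
                        supports_alt = TRUE, is_paired = FALSE,
                        mate_on_graph = FALSE)
    lk0 <- breakpoint_genotype(sup)
    lk1 <- breakpoint_genotype(rbind(sup, extra))
    expect_lte(lk1$log_l[["l00"]], lk0$log_l[["l00"]])
    expect_gte(lk1$log_l[["l11"]], lk0$log_l[["l11"]])
  }
})

test_that("coverage profile takes lower medians over the 20 bp grid", {
  cov <- rep(10L, 6000)
  cov[2001:2800] <- 3L
  pr <- coverage_profile(cov, 2000, 2800)
  expect_equal(pr$c_in, 3)
  expect_equal(pr$c_out, 10)
  # grid positions are multiples of the step, inside span (begin, end]
  expect_true(all(pr$pos_in %% 20 == 0))
  expect_true(all(pr$pos_in > 2000 & pr$pos_in <= 2800))
  expect_true(all(pr$pos_flank >= 1000 & pr$pos_flank <= 3800))
  # lower median on an even count of distinct values
  expect_equal(lower_median_probe(c(1, 2, 3, 4)), 2)
})

test_that("coverage genotyping follows the pseudo-read construction", {
  mkprof <- function(c_out, c_in, span = 500) {
    cov <- rep(as.integer(c_out), 5000)
    cov[2001:(2000 + span)] <- as.integer(c_in)
    coverage_profile(cov, 2000, 2000 + span)
  }
  g1 <- coverage_genotype(mkprof(30, 14), "DEL")
  expect_equal(g1$n_alt, 16L); expect_equal(g1$n_ref, 14L)
  expect_equal(likelihoods_call(g1)$gt, "0/1")
  g2 <- coverage_genotype(mkprof(30, 0), "DEL")
  expect_equal(g2$n_alt, 30L); expect_equal(g2$n_ref, 0L)
  expect_equal(likelihoods_call(g2)$gt, "1/1")
  g3 <- coverage_genotype(mkprof(30, 30), "DEL")
  expect_equal(g3$n_alt, 0L)
  expect_equal(likelihoods_call(g3)$gt, "0/0")
  # duplications: increase supports the SV, baseline supports the reference
  g4 <- coverage_genotype(mkprof(30, 45), "DUP")
  expect_equal(g4$n_alt, 15L); expect_equal(g4$n_ref, 30L)
  expect_equal(likelihoods_call(g4)$gt, "0/1")
  # oracle: pseudo-reads through the breakpoint-model product with eps 2^-4
  pseudo <- data.frame(site_id = "s",
                       supports_ref = rep(c(TRUE, FALSE), c(14, 16)),
                       supports_alt = rep(c(FALSE, TRUE), c(14, 16)),
                       is_paired = FALSE, mate_on_graph = FALSE)
  expect_equal(unname(g1$log_l), unname(breakpoint_genotype(pseudo)$log_l),
               tolerance = 1e-12)
})

test_that("coverage model refuses INS/INV and sub-minimum spans", {
  cov <- rep(30L, 5000)
  pr <- coverage_profile(cov, 2000, 2500)
  expect_error(coverage_genotype(pr, "INS"), class = "graphsv_na_model")
  expect_error(coverage_genotype(pr, "INV"), class = "graphsv_na_model")
  tiny <- coverage_profile(cov, 2000, 2060)
  expect_error(coverage_genotype(tiny, "DEL"), class = "graphsv_na_model")
})

test_that("aggregation picks the higher-GQ model, ties to breakpoint", {
  bp <- breakpoint_genotype(data.frame(
    site_id = "s", supports_ref = rep(c(TRUE, FALSE), c(10, 9)),
    supports_alt = rep(c(FALSE, TRUE), c(10, 9)),
    is_paired = TRUE, mate_on_graph = TRUE))
  cov <- rep(30L, 5000); cov[2001:2500] <- 28L
  weak_cov <- coverage_genotype(coverage_profile(cov, 2000, 2500), "DEL")
  agg <- aggregate_call(bp, weak_cov)
  expect_equal(agg$model, "BREAKPOINT")
  expect_equal(agg$gt, "0/1")
  # coverage model absent (e.g. INS): breakpoint call returned unchanged
  agg2 <- aggregate_call(bp, NULL)
  expect_equal(agg2$gt, agg$gt)
  expect_equal(agg2$model, "BREAKPOINT")
  expect_true(is.na(agg2$gt_cov))
  # agreement keeps the max of the two qualities
  cov2 <- rep(30L, 5000); cov2[2001:2500] <- 0L
  strong <- coverage_genotype(coverage_profile(cov2, 2000, 2500), "DEL")
  hom_bp <- breakpoint_genotype(data.frame(
    site_id = "s", supports_ref = FALSE, supports_alt = TRUE,
    is_paired = FALSE, mate_on_graph = FALSE)[rep(1, 4), ])
  agg3 <- aggregate_call(hom_bp, strong)
  expect_equal(agg3$gt, "1/1")
  expect_equal(agg3$gq, max(likelihoods_call(hom_bp)$gq,
                            likelihoods_call(strong)$gq))
})

test_that("multiallelic decomposition partitions the alt alleles", {
  fix <- data.frame(contig = "c1", pos = 100, ref = "A", alt = "T,G,C")
  out <- decompose_multiallelic(fix)
  expect_equal(nrow(out), 3L)
  expect_equal(out$allele_index, 1:3)
  expect_setequal(out$alt, c("T", "G", "C"))
  one <- decompose_multiallelic(data.frame(alt = "T"))
  expect_equal(nrow(one), 1L)
  set.seed(14)
  for (i in 1:10) {
    alts <- paste(replicate(sample(1:5, 1), rand_dna(3)), collapse = ",")
    out <- decompose_multiallelic(data.frame(alt = alts))
    expect_setequal(out$alt, strsplit(alts, ",")[[1]])
  }
})

test_that("sites with no non-reference genotype are dropped", {
  calls <- data.frame(site_id = rep(c("a", "b", "c"), each = 10),
                      sample = rep(sprintf("s%02d", 1:10), 3),
                      gt = c(rep("0/0", 10),
                             c("0/1", rep("0/0", 9)),
                             rep(c("0/1", "1/1"), 5)),
                      gq = 50L)
  out <- filter_calls(calls)
  expect_setequal(unique(out$site_id), c("b", "c"))
  expect_true(all(out$nonref_seen))
  empty <- filter_calls(calls[0, ])
  expect_equal(nrow(empty), 0L)
})
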