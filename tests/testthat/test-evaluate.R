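write_resolved_vcf <- function(rows, path) {
  fix <- do.call(rbind, rows)
  colnames(fix) <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  vcfR::write.vcf(methods::new("vcfR", meta = c("##fileformat=VCFv4.2",
                                                "##contig=<ID=c1,length=1000000>"),
                               fix = fix, gt = matrix(character(0), 0, 0)), path)
  path
}

test_that("truth extraction keeps >=50 bp alleles inside expanded regions", {
  p <- write_resolved_vcf(list(
    c("c1", "1000", ".", "A", paste0("A", rand_dna(50)), ".", ".", "."),
    c("c1", "2000", ".", paste0("A", rand_dna(29)), "A", ".", ".", "."),
    c("c1", "3000", ".", paste0("A", rand_dna(60)), "A", ".", ".", "."),
    c("c1", "9990", ".", "A", paste0("A", rand_dna(80)), ".", ".", ".")),
    tempfile(fileext = ".vcf.gz"))
  regions <- data.frame(contig = "c1", begin = 500, end = 9980)
  truth <- extract_truth_svs(p, regions, match_criteria())
  # 50 bp insertion retained, 29 bp deletion excluded, 60 bp deletion kept,
  # site 10 bp beyond the region edge rescued by the 25 bp expansion
  expect_setequal(truth$begin, c(1000L, 3000L, 9990L))
  expect_equal(truth$sv_type[truth$begin == 1000], "INS")
  expect_equal(truth$size[truth$begin == 1000], 50L)
  expect_equal(truth$sv_type[truth$begin == 3000], "DEL")
  no_exp <- extract_truth_svs(p, regions, match_criteria(region_expansion = 0))
  expect_false(9990 %in% no_exp$begin)
})

test_that("matching a set against itself is perfect at every threshold", {
  truth <- random_sites(60, seed = 41)
  m <- match_sv_sets(truth, truth, thresholds = c(0, 1, 10, 50))
  expect_true(all(m$by_threshold$recall == 1))
  expect_true(all(m$by_threshold$fdr == 0))
  expect_equal(sum(m$by_size$n_truth), nrow(truth))
  expect_equal(sum(m$by_size$matched), nrow(truth))
})

test_that("breakpoint distances are compared against the threshold exactly", {
  truth <- sv_sites("c1", 1000, 1500, "DEL")
  call49 <- sv_sites("c1", 1049, 1451, "DEL")
  m <- match_sv_sets(call49, truth, thresholds = c(48, 49, 50))
  expect_equal(m$by_threshold$matched, c(0L, 1L, 1L))
  expect_equal(m$by_threshold$recall, c(0, 1, 1))
  expect_equal(m$by_threshold$fdr, c(1, 0, 0))
  # type mismatch blocks matching unless DUP~INS is allowed
  dup_call <- sv_sites("c1", 1000, 1000, "INS", size = 500)
  dup_truth <- sv_sites("c1", 1000, 1000, "DUP", size = 500)
  dup_truth$end <- 1000L
  none <- match_sv_sets(dup_call, dup_truth, thresholds = 50)
  expect_equal(none$by_threshold$matched, 0L)
  soft <- match_sv_sets(dup_call, dup_truth, thresholds = 50,
                        criteria = match_criteria(dup_as_ins = TRUE))
  expect_equal(soft$by_threshold$matched, 1L)
})

test_that("recall under uniform jitter matches the empirical square law", {
  set.seed(42)
  truth <- random_sites(100, seed = 42)
  jb <- sample(-30:30, nrow(truth), replace = TRUE)
  je <- sample(-30:30, nrow(truth), replace = TRUE)
  calls <- truth
  calls$begin <- calls$begin + jb
  calls$end <- ifelse(calls$sv_type == "INS", calls$begin, calls$end + je)
  calls$size <- ifelse(calls$sv_type == "INS", calls$size,
                       calls$end - calls$begin)
  m <- match_sv_sets(calls, truth, thresholds = c(10, 20, 30, 50))
  # at threshold >= 30 every jittered call is recallable
  expect_equal(m$by_threshold$recall[m$by_threshold$threshold == 30], 1)
  # below 30, expected recall equals the empirical count of jitters inside t
  for (t in c(10, 20)) {
    d <- pmax(abs(jb), ifelse(truth$sv_type == "INS", abs(jb), abs(je)))
    expected <- mean(d <= t)
    got <- m$by_threshold$recall[m$by_threshold$threshold == t]
    expect_equal(got, expected, tolerance = 0.08)
  }
  # monotonicity of recall and FDR in the threshold
  mm <- match_sv_sets(calls, truth, thresholds = 1:50)
  expect_true(all(diff(mm$by_threshold$recall) >= 0))
  expect_true(all(diff(mm$by_threshold$fdr) <= 0))
})

test_that("swapping calls and truth swaps the matched-count roles", {
  truth <- random_sites(80, seed = 43)
  calls <- random_sites(50, seed = 44)
  a <- match_sv_sets(calls, truth, thresholds = 100)$by_threshold
  b <- match_sv_sets(truth, calls, thresholds = 100)$by_threshold
  expect_equal(a$matched, b$matched)  # one-to-one matching is symmetric
})

test_that("concordance requires type, distance and minimum support", {
  calls <- random_sites(30, seed = 45)
  b <- calls; b$support <- 2L
  expect_equal(sv_concordance(calls, b)$fraction, 1)
  b1 <- calls; b1$support <- 1L
  expect_equal(sv_concordance(calls, b1, min_support = 2)$fraction, 0)
  empty <- calls[0, ]; empty$support <- integer(0)
  expect_equal(sv_concordance(calls, empty)$fraction, 0)
})

test_that("Mendelian errors are flagged by trio consistency", {
  gt <- rbind(s1 = c(fa = "0/0", mo = "0/0", kid = "0/1"),
              s2 = c(fa = "0/1", mo = "0/0", kid = "0/1"),
              s3 = c(fa = "1/1", mo = "1/1", kid = "0/1"),
              s4 = c(fa = "0/1", mo = "0/1", kid = "1/1"),
              s5 = c(fa = "0/0", mo = "1/1", kid = "1/1"))
  trios <- data.frame(father = "fa", mother = "mo", offspring = "kid")
  res <- mendelian_error_rate(gt, trios)
  expect_equal(res$n_evaluated, 5L)
  expect_equal(res$n_errors, 3L)  # s1, s3 and s5 are impossible
  expect_equal(res$rate, 3 / 5)
  # trios with absent members are skipped with a warning
  expect_warning(
    res2 <- mendelian_error_rate(gt, rbind(trios,
      data.frame(father = "fa", mother = "nope", offspring = "kid"))),
    "absent")
  expect_equal(res2$n_evaluated, 5L)
})

test_that("error-free pedigrees have zero Mendelian error; flips raise it", {
  pt <- pedigree_truth()
  gt <- t(pt$truth$genotypes)
  trios <- pt$truth$pedigree$trios
  expect_equal(nrow(trios), 48L)
  res <- mendelian_error_rate(gt, trios)
  expect_equal(res$rate, 0)
  # inject genotype flips; errors must rise at least by the number of flips
  # that a brute-force trio-consistency oracle calls impossible
  set.seed(46)
  gtf <- gt
  flips <- data.frame(site = sample(nrow(gt), 30, replace = TRUE),
                      trio = sample(nrow(trios), 30, replace = TRUE))
  flips <- flips[!duplicated(flips), ]
  oracle_impossible <- 0L
  consistent_oracle <- function(f, m, o) {
    # brute force over the four possible transmissions
    fa <- as.integer(strsplit(f, "/")[[1]]); mo <- as.integer(strsplit(m, "/")[[1]])
    key <- function(x) paste(sort(x), collapse = "/")
    combos <- c(key(c(fa[1], mo[1])), key(c(fa[1], mo[2])),
                key(c(fa[2], mo[1])), key(c(fa[2], mo[2])))
    key(as.integer(strsplit(o, "/")[[1]])) %in% combos
  }
  for (k in seq_len(nrow(flips))) {
    tr <- trios[flips$trio[k], ]
    old <- gtf[flips$site[k], tr$offspring]
    new <- setdiff(c("0/0", "0/1", "1/1"), old)[1]
    gtf[flips$site[k], tr$offspring] <- new
    if (!consistent_oracle(gtf[flips$site[k], tr$father],
                           gtf[flips$site[k], tr$mother], new))
      oracle_impossible <- oracle_impossible + 1L
  }
  resf <- mendelian_error_rate(gtf, trios)
  expect_gte(resf$n_errors, oracle_impossible)
  expect_gt(oracle_impossible, 0L)
})

test_that("transmission counting resolves only unambiguous configurations", {
  gt <- rbind(s1 = c(fa = "0/1", mo = "0/0", kid = "0/1"),  # transmitted
              s2 = c(fa = "0/1", mo = "0/0", kid = "0/0"),  # not transmitted
              s3 = c(fa = "0/1", mo = "0/1", kid = "0/1"),  # ambiguous
              s4 = c(fa = "0/1", mo = "0/1", kid = "1/1"),  # both transmitted
              s5 = c(fa = "0/0", mo = "0/0", kid = "0/0"))  # no het parent
  trios <- data.frame(father = "fa", mother = "mo", offspring = "kid")
  res <- transmission_rate(gt, trios)
  expect_equal(res$per_site$opportunities, c(1L, 1L, 0L, 2L, 0L))
  expect_equal(res$per_site$transmitted, c(1L, 0L, 0L, 2L, 0L))
  expect_equal(res$rate, 3 / 4)
})

test_that("fair transmission in a simulated pedigree sits near 50%", {
  pt <- pedigree_truth()
  gt <- t(pt$truth$genotypes)
  trios <- pt$truth$pedigree$trios
  res <- transmission_rate(gt, trios)
  se <- sqrt(0.25 / res$n_opportunities)
  expect_lt(abs(res$rate - 0.5), 3 * se)
  # the per-site histogram is symmetric about 0.5 (two-sided binomial check)
  rates <- res$per_site$rate[res$per_site$opportunities >= 5]
  above <- sum(rates > 0.5); below <- sum(rates < 0.5)
  expect_gt(stats::binom.test(above, above + below)$p.value, 0.001)
  # and matches the recorded truth transmissions exactly
  tr <- pt$truth$transmissions
  tr <- tr[tr$parent_het, ]
  expect_equal(res$n_transmitted <= nrow(tr), TRUE)
})

test_that("carrier spectrum conserves the site count", {
  pt <- pedigree_truth()
  gt <- t(pt$truth$genotypes)
  cs <- carrier_spectrum(gt)
  expect_equal(sum(cs$spectrum$n_sites), nrow(gt))
  expect_equal(nrow(cs$per_site), nrow(gt))
  one <- carrier_spectrum(rbind(s = c(a = "0/1", b = "0/0")))
  expect_equal(one$per_site$carriers, 1L)
})

test_that("PED files parse into trios", {
  p <- tempfile()
  writeLines(c("F1\tfa\t0\t0\t1\t0", "F1\tmo\t0\t0\t2\t0",
               "F1\tkid\tfa\tmo\t1\t0"), p)
  ped <- read_ped(p)
  expect_equal(nrow(ped$trios), 1L)
  expect_equal(ped$trios$offspring, "kid")
})
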