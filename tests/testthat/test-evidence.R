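test_that("alignment log-likelihood matches the per-base closed form", {
  expect_equal(alignment_loglik(100, 0, 0.01), 100 * log(0.99))
  expect_equal(alignment_loglik(0, 0, 0.01), 0)
  # brute-force per-base summation
  per_base <- sum(rep(log(1 - 0.02), 50)) + sum(rep(log(0.02 / 3), 3))
  expect_equal(alignment_loglik(50, 3, 0.02), per_base)
  expect_error(alignment_loglik(10, 0, 0), "eps")
  expect_error(alignment_loglik(10, 0, 1), "eps")
  expect_error(alignment_loglik(-1, 0, 0.1), "non-negative")
})

test_that("log-likelihoods are nonpositive and strictly decrease with mismatches", {
  set.seed(7)
  for (rep in 1:50) {
    len <- sample(30:150, 1)
    x <- sample(0:(len %/% 10), 1)
    eps <- runif(1, 0.001, 0.2)
    l0 <- alignment_loglik(len - x, x, eps)
    l1 <- alignment_loglik(len - x - 1, x + 1, eps)
    expect_lte(l0, 0)
    expect_lt(l1, l0)
  }
})

test_that("a verbatim copy of an allele aligns back with zero mismatches", {
  p <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 5, seed = 5))
  read <- substr(p$seq[["A*03:01"]], 101, 200)
  hits <- naive_align(read, p)
  expect_true("A*03:01" %in% hits$allele)
  expect_equal(hits$mismatches[hits$allele == "A*03:01"], 0)
  expect_equal(hits$pos[hits$allele == "A*03:01"], 100)
})

test_that("a random read aligns nowhere at tight mismatch budgets", {
  p <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 5, seed = 5))
  set.seed(1)
  read <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  expect_equal(nrow(naive_align(read, p, max_mismatches = 3)), 0)
})

test_that("reported placements match an exhaustive sliding-window oracle", {
  set.seed(11)
  ref <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  p <- hla_panel(c("A*01:01" = ref))
  for (rep in 1:10) {
    pos <- sample(0:(400 - 60), 1)
    read <- substr(ref, pos + 1, pos + 60)
    # inject up to 2 substitutions
    for (k in seq_len(sample(0:2, 1))) {
      at <- sample(60, 1)
      substr(read, at, at) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(read, at, at)), 1)
    }
    if (sample(c(TRUE, FALSE), 1)) {
      read <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read)))
    }
    got <- naive_align(read, p, max_mismatches = 4, k = 15)
    oracle <- brute_align_best(read, ref, max_mm = 4)
    expect_equal(got$mismatches, oracle$mm)
  }
})

test_that("simulated error bookkeeping matches reported mismatch counts", {
  p <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 3, seed = 9))
  truth <- data.frame(sample = "s1", gene = "A",
                      allele1 = "A*02:01", allele2 = "A*03:01")
  sim <- simulate_reads(p, truth, coverage = 4, err_rate = 0.01, seed = 21)
  one <- hla_panel(p$seq["A*02:01"],
                   p$features[p$features$allele == "A*02:01", ])
  from_a2 <- sim$read_truth$allele == "A*02:01"
  checked <- 0
  for (k in which(from_a2)) {
    hits <- naive_align(sim$reads$seq[k], one, max_mismatches = 10)
    if (!nrow(hits)) next   # an error can break every seed; rare and allowed
    expect_equal(hits$mismatches, sim$read_truth$n_err[k])
    checked <- checked + 1
  }
  expect_gt(checked, 20)
})

test_that("evidence construction is deterministic and sorted by read id", {
  p <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 6, seed = 3))
  truth <- data.frame(sample = "s1", gene = "A",
                      allele1 = "A*01:01", allele2 = "A*04:01")
  sim <- simulate_reads(p, truth, coverage = 3, seed = 2)
  ev1 <- align_reads(sim$reads, p)
  shuffled <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  ev2 <- align_reads(shuffled, p)
  expect_identical(ev1$entries, ev2$entries)
  expect_false(is.unsorted(ev1$entries$read))
})

test_that("on error-free reads the source allele is always a top candidate", {
  p <- make_panel(panel_spec(n_genes = 2, alleles_per_gene = 8, seed = 13))
  truth <- data.frame(sample = "s1", gene = c("A", "B"),
                      allele1 = c("A*03:01", "B*05:01"),
                      allele2 = c("A*07:01", "B*06:01"))
  sim <- simulate_reads(p, truth, coverage = 5, err_rate = 0, seed = 8)
  ev <- align_reads(sim$reads, p)
  expect_equal(ev$n_dropped, 0)
  best <- tapply(ev$entries$log_lik, ev$entries$read, max)
  src <- sim$read_truth$allele[match(names(best), sim$read_truth$id)]
  key <- paste(names(best), src)
  ent_key <- paste(ev$entries$read, ev$entries$allele)
  src_ll <- ev$entries$log_lik[match(key, ent_key)]
  expect_true(all(src_ll == best))
})

write_sam <- function(path, sq, records) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq),
               records), path)
}

test_that("SAM evidence keeps multi-mapped candidates and honours NM", {
  p <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 3, seed = 2))
  read <- substr(p$seq[["A*01:01"]], 201, 300)
  sam <- tempfile(fileext = ".sam")
  write_sam(sam, allele_lengths(p), c(
    paste("r1", 0, "A*01:01", 201, 60, "100M", "*", 0, 0, read, "*",
          "NM:i:0", sep = "\t"),
    paste("r1", 256, "A*02:01", 201, 0, "100M", "*", 0, 0, "*", "*",
          "NM:i:3", sep = "\t")))
  ev <- evidence_from_sam(sam, p)
  expect_equal(nrow(ev$entries), 2)
  expect_setequal(ev$entries$allele, c("A*01:01", "A*02:01"))
  ll <- ev$entries$log_lik[order(ev$entries$allele)]
  expect_equal(ll, c(alignment_loglik(100, 0), alignment_loglik(97, 3)))
})

test_that("SAM evidence drops short alignments and merges mate pairs", {
  p <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 3, seed = 2))
  r1 <- substr(p$seq[["A*01:01"]], 101, 200)
  r2 <- substr(p$seq[["A*01:01"]], 401, 500)
  clipped <- substr(p$seq[["A*02:01"]], 101, 200)
  sam <- tempfile(fileext = ".sam")
  write_sam(sam, allele_lengths(p), c(
    paste("frag1", 64 + 1, "A*01:01", 101, 60, "100M", "*", 0, 0, r1, "*",
          "NM:i:0", sep = "\t"),
    paste("frag1", 128 + 1, "A*01:01", 401, 60, "100M", "*", 0, 0, r2, "*",
          "NM:i:1", sep = "\t"),
    paste("short", 0, "A*02:01", 101, 60, "40M60S", "*", 0, 0, clipped, "*",
          "NM:i:0", sep = "\t")))
  ev <- evidence_from_sam(sam, p, min_aligned_frac = 0.9)
  # the fragment contributes one row with summed mate log-likelihoods
  expect_equal(ev$entries$read, "frag1")
  expect_equal(ev$entries$log_lik,
               alignment_loglik(100, 0) + alignment_loglik(99, 1))
  expect_equal(unname(ev$read_len["frag1"]), 200L)
  expect_equal(ev$n_dropped, 1)  # the clipped read lost all candidates
})

test_that("SAM records against unknown targets are an error", {
  p <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 3, seed = 2))
  sam <- tempfile(fileext = ".sam")
  write_sam(sam, c("X*01:01" = 3000L), paste(
    "r1", 0, "X*01:01", 1, 60, "10M", "*", 0, 0, "ACGTACGTAC", "*",
    "NM:i:0", sep = "\t"))
  expect_error(evidence_from_sam(sam, p), "not a panel allele")
})

test_that("evidence matrices round-trip through TSV", {
  p <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 4, seed = 6))
  truth <- data.frame(sample = "s1", gene = "A",
                      allele1 = "A*01:01", allele2 = "A*02:01")
  sim <- simulate_reads(p, truth, coverage = 2, seed = 3)
  ev <- align_reads(sim$reads, p)
  tsv <- tempfile(fileext = ".tsv")
  write_evidence(ev, tsv)
  back <- read_evidence(tsv, alleles = panel_alleles(p))
  expect_equal(back$entries, ev$entries)
  expect_equal(back$read_len, ev$read_len)
})
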