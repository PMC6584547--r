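test_that("genotype matching is order-free and fails count zero", {
  expect_equal(match_genotype(c("A*02:01", "A*24:02"),
                              c("A*24:02", "A*02:01")), 2L)
  expect_equal(match_genotype(c("A*26:01", "A*02:06"),
                              c("A*26:01", "A*26:01")), 1L)
  expect_equal(match_genotype(c("fail", "fail"),
                              c("A*26:01", "A*26:01")), 0L)
  expect_error(match_genotype(c("A*01:01", "A*01:01"),
                              c("B*01:01", "B*01:01")), "gene mismatch")
})

test_that("matching equals the exhaustive maximum over both pairings", {
  set.seed(61)
  pool <- c(sprintf("A*%02d:01", 1:4), "fail")
  for (rep in 1:200) {
    called <- sample(pool, 2, replace = TRUE)
    truth <- sample(pool[1:4], 2, replace = TRUE)
    oracle <- max(
      sum(called == truth & called != "fail"),
      sum(called == rev(truth) & called != "fail"))
    expect_equal(match_genotype(called, truth, check_gene = FALSE),
                 as.integer(oracle))
  }
})

test_that("matching is invariant to within-pair permutation on both sides", {
  set.seed(67)
  pool <- c(sprintf("C*%02d:01", 1:3), "fail")
  for (rep in 1:50) {
    cc <- sample(pool, 2, replace = TRUE)
    tt <- sample(pool[1:3], 2, replace = TRUE)
    m <- match_genotype(cc, tt, check_gene = FALSE)
    expect_equal(match_genotype(rev(cc), tt, check_gene = FALSE), m)
    expect_equal(match_genotype(cc, rev(tt), check_gene = FALSE), m)
  }
})

make_typings <- function(n, gene = "A", prefix = "s") {
  data.frame(sample = sprintf("%s%03d", prefix, seq_len(n)), gene = gene,
             allele1 = sprintf("%s*%02d:01", gene, sample(1:9, n, TRUE)),
             allele2 = sprintf("%s*%02d:01", gene, sample(1:9, n, TRUE)))
}

test_that("perfect calls score 100.0 at any size", {
  set.seed(71)
  for (n in c(1, 7, 57)) {
    truth <- make_typings(n)
    tab <- accuracy_table(truth, truth)
    expect_equal(tab$accuracy_pct, 100.0)
    expect_equal(tab$n, 2 * n)
    expect_equal(nrow(discordance_table(truth, truth)), 0)
  }
})

test_that("percentages round half-up to one decimal", {
  expect_equal(hlacall:::round_half_up(100 * 226 / 228, 1), 99.1)
  expect_equal(hlacall:::round_half_up(100 * 224 / 228, 1), 98.2)
  expect_equal(hlacall:::round_half_up(100 * 206 / 228, 1), 90.4)
  expect_equal(hlacall:::round_half_up(98.25, 1), 98.3)
  expect_equal(hlacall:::round_half_up(98.24999, 1), 98.2)
})

test_that("duplicate calls for one sample and gene are rejected", {
  truth <- make_typings(3)
  calls <- rbind(truth, truth[1, ])
  expect_error(accuracy_table(calls, truth), "duplicate")
})

test_that("injected miscalls are recovered exactly by the discordance table", {
  set.seed(73)
  for (rep in 1:10) {
    truth <- make_typings(40)
    calls <- truth
    n_inject <- sample(1:8, 1)
    idx <- sample(40, n_inject)
    log <- list()
    for (k in idx) {
      wrong <- sprintf("A*%02d:01", sample(10:12, 1))
      log[[length(log) + 1L]] <- data.frame(
        true_type = calls$allele2[k], called_type = wrong)
      calls$allele2[k] <- wrong
    }
    log <- do.call(rbind, log)
    expected <- stats::aggregate(
      list(count = rep(1L, nrow(log))),
      by = log[, c("true_type", "called_type")], FUN = sum)
    got <- discordance_table(calls, truth)
    expect_equal(got[order(got$true_type, got$called_type),
                     c("true_type", "called_type", "count")],
                 expected[order(expected$true_type, expected$called_type), ],
                 ignore_attr = TRUE)
    # bookkeeping identity: discordant slots = n - n_correct
    acc <- accuracy_table(calls, truth)
    expect_equal(sum(got$count), sum(acc$n) - sum(acc$n_correct))
  }
})

test_that("truth counts accumulate over all slots of the true type", {
  truth <- data.frame(sample = c("s1", "s2"), gene = "A",
                      allele1 = c("A*01:01", "A*01:01"),
                      allele2 = c("A*01:01", "A*02:01"))
  calls <- truth
  calls$allele1[1] <- "A*03:01"
  got <- discordance_table(calls, truth)
  expect_equal(got$true_n, 3L)  # three A*01:01 slots in the truth
  expect_equal(got$count, 1L)
})

twin_panel <- function() {
  make_panel(panel_spec(n_genes = 1, alleles_per_gene = 6,
                        n_exon23_twins = 1, seed = 77))
}

test_that("exon-2/3 projection returns the allele's whole identity group", {
  p <- twin_panel()
  groups <- feature_identity_groups(p, "A")
  expect_equal(project_to_exon23("A*01:01", groups),
               c("A*01:01", "A*02:01"))
  expect_equal(project_to_exon23("A*03:01", groups), "A*03:01")
  expect_equal(project_to_exon23(c("A*02:01", "A*04:01"), groups),
               c("A*01:01", "A*02:01", "A*04:01"))
  expect_error(project_to_exon23("A*99:99", groups), "absent")
})

test_that("projection agrees with brute-force recomputation from sequences", {
  set.seed(79)
  p <- make_panel(panel_spec(n_genes = 1, alleles_per_gene = 12,
                             n_exon23_twins = 2, seed = 83))
  groups <- feature_identity_groups(p, "A")
  brute <- brute_partition(p, "A")
  for (a in panel_alleles(p)) {
    expect_equal(project_to_exon23(a, groups),
                 brute[[which(vapply(brute, function(m) a %in% m,
                                     logical(1)))]])
  }
})

test_that("conflicts between typing methods are flagged by group identity", {
  p <- twin_panel()
  groups <- feature_identity_groups(p, "A")
  ngs <- data.frame(sample = c("s1", "s2", "s3"), gene = "A",
                    allele1 = c("A*02:01", "A*03:01", "A*05:01"),
                    allele2 = c("A*04:01", "A*04:01", "A*05:01"))
  # an exon-2/3 method reports the twin group representative for s1 and a
  # genuinely different allele for s2; s3 agrees
  lum <- data.frame(sample = c("s1", "s2", "s3"), gene = "A",
                    allele1 = c("A*01:01", "A*06:01", "A*05:01"),
                    allele2 = c("A*04:01", "A*04:01", "A*05:01"))
  calls <- ngs
  rep <- ambiguity_report(ngs, lum, calls, groups)
  expect_equal(nrow(rep), 2)
  r1 <- rep[rep$sample == "s1", ]
  expect_true(r1$same_exon23_group)   # twins: methods could never agree
  expect_equal(r1$type_a, "A*02:01")
  expect_equal(r1$type_b, "A*01:01")
  expect_equal(r1$resolving_call, "A*02:01")
  expect_false(rep$same_exon23_group[rep$sample == "s2"])
})

test_that("alleles outside the grouping universe yield an unknown flag", {
  p <- twin_panel()
  groups <- feature_identity_groups(p, "A")
  ngs <- data.frame(sample = "s1", gene = "A",
                    allele1 = "A*77:01", allele2 = "A*04:01")
  lum <- data.frame(sample = "s1", gene = "A",
                    allele1 = "A*03:01", allele2 = "A*04:01")
  rep <- ambiguity_report(ngs, lum, NULL, groups)
  expect_equal(nrow(rep), 1)
  expect_true(is.na(rep$same_exon23_group))
  expect_true(is.na(rep$resolving_call))
})

test_that("identical typings produce an empty ambiguity report", {
  p <- twin_panel()
  groups <- feature_identity_groups(p, "A")
  t1 <- make_typings(5)
  expect_equal(nrow(ambiguity_report(t1, t1, NULL, groups)), 0)
})
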