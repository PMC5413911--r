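test_that("tabulation counts overlaps and drops unassigned genes", {
  ps <- profile_set(list(P1 = c("g1", "g2"), P2 = "g3"))
  counts <- tabulate_by_profile(c("g1", "g3", "g9"), ps)
  expect_equal(unname(counts$observed), c(1L, 1L))
  expect_identical(counts$n_dropped, 1L)
  expect_identical(counts$universe_size, 3L)
  empty <- tabulate_by_profile(character(0), ps)
  expect_true(all(empty$observed == 0))
  expect_identical(empty$n_dropped, 0L)
})

test_that("chi-square goodness of fit matches closed forms", {
  # proportional observed -> statistic 0, p 1
  prop <- make_counts(c(5, 10, 15), c(50, 100, 150))
  t0 <- chi2_gof(prop)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  # (10, 0) on equal sizes: statistic 10, df 1
  t1 <- chi2_gof(make_counts(c(10, 0), c(50, 50)))
  expect_equal(t1$statistic, 10)
  expect_identical(t1$df, 1L)
  expect_equal(t1$p, pchisq(10, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(t1$p, 1.565402e-3, tolerance = 1e-6)
  # (24, 3, 3) on equal sizes: 19.6 + 4.9 + 4.9
  t2 <- chi2_gof(make_counts(c(24, 3, 3), c(100, 100, 100)))
  expect_equal(t2$statistic, 29.4)
  expect_identical(t2$df, 2L)
})

test_that("chi-square agrees with chisq.test across random instances", {
  set.seed(13)
  for (i in 1:25) {
    k <- sample(3:30, 1)
    sizes <- sample(20:400, k, replace = TRUE)
    obs <- as.vector(rmultinom(1, sample(50:500, 1), sizes))
    counts <- make_counts(obs, sizes)
    mine <- chi2_gof(counts)
    ref <- suppressWarnings(chisq.test(obs, p = sizes / sum(sizes)))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Pearson contributions sum to the statistic and carry direction", {
  contrib <- pearson_contributions(make_counts(c(24, 3, 3),
                                               c(100, 100, 100)))
  expect_equal(contrib$contribution, c(19.6, 4.9, 4.9))
  expect_equal(contrib$direction, c("enriched", "depleted", "depleted"))
  prop <- pearson_contributions(make_counts(c(5, 10), c(50, 100)))
  expect_true(all(prop$contribution == 0))
  expect_true(all(prop$direction == "none"))
})

test_that("contribution identity holds over 1000 random instances", {
  set.seed(99)
  for (i in 1:1000) {
    k <- sample(2:40, 1)
    sizes <- sample(10:300, k, replace = TRUE)
    obs <- as.vector(rmultinom(1, sample(20:800, 1), runif(k) * sizes))
    counts <- make_counts(obs, sizes)
    expect_lt(abs(sum(pearson_contributions(counts)$contribution) -
                    chi2_gof(counts)$statistic), 1e-9)
  }
})

test_that("stepwise selection peels maximal contributors until flat", {
  # proportional counts -> empty selection, initial p = 1 recorded
  s0 <- stepwise_select(make_counts(c(5, 10, 15), c(50, 100, 150)))
  expect_identical(nrow(s0$steps), 0L)
  expect_equal(s0$chi2_initial$p, 1)
  # the documented two-step example
  s1 <- stepwise_select(make_counts(c(24, 3, 3), c(100, 100, 100)))
  expect_identical(s1$steps$profile_id, "P1")
  expect_identical(s1$steps$direction, "enriched")
  expect_equal(s1$steps$contribution, 19.6)
  expect_equal(s1$steps$p, 4.129249e-7, tolerance = 1e-5)
  expect_equal(s1$chi2_final$statistic, 0)
  expect_equal(s1$chi2_final$p, 1)
  # df drops by one per removal; terminates within k - 1 steps
  set.seed(4)
  for (i in 1:20) {
    k <- sample(3:15, 1)
    sizes <- sample(30:200, k, replace = TRUE)
    obs <- as.vector(rmultinom(1, 400, runif(k)^2 * sizes))
    s <- stepwise_select(make_counts(obs, sizes), alpha = 0.05)
    expect_lte(nrow(s$steps), k - 1L)
    if (nrow(s$steps) > 1)
      expect_identical(diff(s$steps$df), rep(-1L, nrow(s$steps) - 1L))
  }
})

test_that("exact test matches fisher.test and handles degenerate tables", {
  f <- fisher_contingency(1, 1, 1, 1)
  expect_equal(f$p, 1)
  expect_equal(f$odds_ratio, 1)
  expect_equal(fisher_contingency(3, 0, 0, 3, "greater")$p, 1 / 20)
  expect_identical(fisher_contingency(3, 0, 0, 3)$odds_ratio, Inf)
  expect_identical(fisher_contingency(0, 3, 3, 0)$odds_ratio, 0)
  expect_error(fisher_contingency(-1, 1, 1, 1), "non-negative")
  set.seed(8)
  for (i in 1:100) {
    cells <- as.vector(rmultinom(1, sample(10:300, 1), runif(4) + 0.05))
    for (alt in c("two.sided", "greater", "less")) {
      mine <- fisher_contingency(cells[1], cells[2], cells[3], cells[4],
                                 alt)$p
      ref <- fisher.test(matrix(cells, 2, 2, byrow = TRUE),
                         alternative = alt)$p.value
      expect_equal(mine, ref, tolerance = 1e-10)
    }
  }
})

test_that("profile-level exact test builds the 2x2 from gene sets", {
  universe <- sprintf("g%03d", 1:100)
  profile <- universe[1:20]
  responsive <- universe[c(1:10, 90:99)]
  f <- fisher_profile(profile, responsive, 100, "greater")
  expect_equal(unname(f$table), c(10, 10, 10, 70))
  ref <- fisher.test(matrix(c(10, 10, 10, 70), 2, 2, byrow = TRUE),
                     alternative = "greater")
  expect_equal(f$p, ref$p.value, tolerance = 1e-10)
  expect_error(fisher_profile(profile, responsive, 25), "negative")
})

test_that("full enrichment report flags a spiked profile and is symmetric", {
  set.seed(31)
  G <- 4000L
  genes <- sprintf("g%05d", 1:G)
  gene_sets <- split(genes, rep(1:10, each = G / 10))
  names(gene_sets) <- paste0("P", 1:10)
  ps <- profile_set(gene_sets)
  # responsive set concentrated in P3
  resp <- c(sample(gene_sets$P3, 120), sample(setdiff(genes, gene_sets$P3),
                                              180))
  other <- sample(genes, 300)
  rep1 <- run_enrichment(resp, other, ps)
  expect_true("P3" %in% rep1$up$steps$profile_id)
  expect_identical(rep1$up$steps$direction[rep1$up$steps$profile_id == "P3"],
                   "enriched")
  expect_lt(rep1$up$fisher_individual$p[
    rep1$up$fisher_individual$profile_id == "P3"], 1e-6)
  expect_false(is.null(rep1$up$fisher_combined_enriched))
  # swapping up and down swaps the reports exactly
  rep2 <- run_enrichment(other, resp, ps)
  expect_identical(rep1$up, rep2$down)
  expect_identical(rep1$down, rep2$up)
  # no responsive genes anywhere -> empty report, no error
  rep3 <- run_enrichment(character(0), character(0), ps)
  expect_identical(nrow(rep3$up$steps), 0L)
  expect_null(rep3$up$fisher_combined_enriched)
})

test_that("enrichment report serializes to JSON and TSV", {
  genes <- sprintf("g%04d", 1:500)
  ps <- profile_set(split(genes, rep(1:5, each = 100)) |>
                      setNames(paste0("P", 1:5)))
  resp <- c(genes[1:40], sample(genes[101:500], 20))
  rep <- run_enrichment(resp, genes[490:500], ps)
  dir <- withr::local_tempdir()
  write_enrichment_report(rep, dir)
  expect_true(file.exists(file.path(dir, "enrichment_up.json")))
  js <- jsonlite::read_json(file.path(dir, "enrichment_up.json"),
                            simplifyVector = TRUE)
  expect_equal(js$n_responsive_assigned, rep$up$counts$n_responsive_assigned)
  tsv <- read.delim(file.path(dir, "profile_counts_up.tsv"))
  expect_equal(nrow(tsv), 5L)
  expect_equal(sum(tsv$observed), rep$up$counts$n_responsive_assigned)
})
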