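test_that("Jaccard distance follows the set formula", {
  pa <- tibble::tibble(
    insect_id = c("x", "x", "x", "y", "y", "y", "z", "z", "z"),
    taxon = c("A", "B", "C", "B", "C", "D", "A", "B", "C"))
  d <- as.matrix(jaccard_distances(pa))
  expect_equal(d["x", "y"], 1 - 2 / 4)
  expect_equal(d["x", "z"], 0)          # identical profiles
  pa2 <- tibble::tibble(insect_id = c("a", "b"), taxon = c("T1", "T2"))
  expect_equal(as.matrix(jaccard_distances(pa2))["a", "b"], 1)  # disjoint
})

test_that("Jaccard output is a metric and matches vegan on random data", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:40) {
    pa <- random_pa_long(sample(4:9, 1), sample(3:8, 1))
    d <- as.matrix(jaccard_distances(pa))
    expect_equal(diag(d), setNames(numeric(nrow(d)), rownames(d)))
    expect_equal(d, t(d))
    n <- nrow(d)
    for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
    }
    wide <- tidyr::pivot_wider(
      dplyr::mutate(pa, v = 1), names_from = taxon, values_from = v,
      values_fill = 0)
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$insect_id
    dv <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
    expect_equal(d[rownames(dv), colnames(dv)], dv, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("PERMANOVA F and R2 match vegan::adonis2 on a fixture", {
  skip_if_not_installed("vegan")
  set.seed(21)
  pa <- random_pa_long(12, 7)
  d <- jaccard_distances(pa)
  grp <- rep(c("a", "b", "c"), each = 4)
  ours <- permanova(d, setNames(grp, labels(d)), n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = grp),
                        permutations = 99)
  expect_equal(ours$F, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(ours$df_between, ref$Df[1])
  td <- tidy(ours)
  expect_equal(td$sum_of_squares[3], ref$SumOfSqs[nrow(ref)],
               tolerance = 1e-10)
})

test_that("permutation p agrees with full enumeration on six samples", {
  # n = 6, two groups of 3: C(6,3) = 20 label arrangements
  set.seed(3)
  pa <- random_pa_long(6, 5)
  d2 <- as.matrix(jaccard_distances(pa))^2
  grp <- c("a", "a", "a", "b", "b", "b")
  f_of <- function(g) {
    gl <- factor(g)
    ss <- pollinet:::permanova_ss(d2, gl)
    pollinet:::permanova_f(ss, 6, 2)
  }
  fobs <- f_of(grp)
  combs <- utils::combn(6, 3)
  fs <- apply(combs, 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"; f_of(g)
  })
  p_exact <- mean(fs >= fobs - 1e-12)
  res <- permanova(stats::as.dist(sqrt(d2)), grp, n_perm = 1999, seed = 9)
  expect_equal(res$p, p_exact, tolerance = 0.05)
})

test_that("zero within-group distance yields an infinite F at honest p", {
  # 3 + 5 identical-within, disjoint-between profiles
  pa <- tibble::tibble(
    insect_id = rep(sprintf("i%d", 1:8), each = 2),
    taxon = c(rep(c("A", "B"), 3), rep(c("C", "D"), 5)))
  d <- jaccard_distances(pa)
  grp <- c(rep("g1", 3), rep("g2", 5))
  res <- permanova(d, setNames(grp, sprintf("i%d", 1:8)), n_perm = 199,
                   seed = 4)
  expect_identical(res$F, Inf)
  expect_equal(res$R2, 1)
  expect_equal(unname(res$ss["within"]), 0)
  # only partition-preserving relabellings tie with the observed statistic,
  # so p stays near 3!5!/8! = 1/56
  expect_lt(res$p, 0.06)
  expect_gte(res$p, 1 / 200)
})

test_that("strata confine permutations: site-confounded groups are untestable", {
  set.seed(6)
  pa <- random_pa_long(12, 6)
  d <- jaccard_distances(pa)
  ids <- labels(d)
  site <- setNames(rep(c("S1", "S2"), each = 6), ids)
  # groups identical to strata: within-site shuffles never change the
  # grouping, so every permuted F equals the observed one and p = 1
  res <- permanova(d, site, strata = site, n_perm = 99, seed = 2)
  expect_equal(res$p, 1)
  # the same groups without strata are testable (p < 1)
  res2 <- permanova(d, site, n_perm = 99, seed = 2)
  expect_lt(res2$p, 1)
  # group structure orthogonal to strata remains testable under strata
  grp <- setNames(rep(c("a", "b"), 6), ids)
  res3 <- permanova(d, grp, strata = site, n_perm = 99, seed = 2)
  expect_gt(res3$p, 0)
  expect_lte(res3$p, 1)
})

test_that("the permutation stream is reproducible under a seed", {
  set.seed(8)
  pa <- random_pa_long(10, 6)
  d <- jaccard_distances(pa)
  grp <- rep(c("a", "b"), 5)
  p1 <- permanova(d, setNames(grp, labels(d)), n_perm = 499, seed = 11)$p
  p2 <- permanova(d, setNames(grp, labels(d)), n_perm = 499, seed = 11)$p
  expect_identical(p1, p2)
  p3 <- permanova(d, setNames(grp, labels(d)), n_perm = 499, seed = 12)$p
  se <- sqrt(p1 * (1 - p1) / 499)
  expect_lt(abs(p3 - p1), 4 * se + 2 / 500)
})

test_that("Sidak cutoffs match the closed form", {
  expect_equal(sidak_cutoff(0.05, 7), 0.0073008, tolerance = 1e-5)
  expect_equal(sidak_cutoff(0.05, 1), 0.05)
  expect_error(sidak_cutoff(0.05, 0), class = "pollinet_bad_input")
})

test_that("the contrast battery builds the study design and flags via Sidak", {
  sim <- simulate_pollen_study(tiny_sim_config(seed = 12))
  cts <- study_contrasts(sim$insects)
  # 3 genera, each with 2 species: 3 one-vs-rest + 3 within-genus
  expect_length(cts, 6)
  expect_true(all(grepl("_vs_rest$|_species$", names(cts))))
  counts <- local({
    kept <- suppressMessages(length_filter(sim$reads, 250L))
    asg <- consensus_assign(select_top_hits(sim$hits, assignment_rule()),
                            sim$refdb$taxonomy, assignment_rule(),
                            query_ids = kept$read_id)
    tally_pollen(asg, sim$insects)
  })
  d <- jaccard_distances(jaccard_input_filter(counts))
  suite <- run_contrast_battery(d, sim$insects, n_perm = 99, seed = 5)
  expect_equal(nrow(suite), 6)
  expect_equal(attr(suite, "k"), 6)
  expect_equal(attr(suite, "sidak_cutoff"), sidak_cutoff(0.05, 6))
  expect_identical(suite$significant,
                   suite$p < attr(suite, "sidak_cutoff"))
  # a p-value of 0.013 against the 7-way cutoff is not significant
  expect_false(0.013 < sidak_cutoff(0.05, 7))
  bad <- list(broken = list(ids = sim$insects$insect_id,
                            groups = setNames(rep("only", nrow(sim$insects)),
                                              sim$insects$insect_id)))
  expect_error(run_contrast_battery(d, sim$insects, contrasts = bad,
                                    n_perm = 9, seed = 1),
               class = "pollinet_bad_input")
})

test_that("Kruskal-Wallis matches hand algebra and stats::kruskal.test", {
  df <- tibble::tibble(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  res <- kruskal_wallis(df, v, g)
  expect_equal(res$statistic, 2.4)
  expect_equal(res$df, 1L)
  # tie-corrected case: two identical groups
  df2 <- tibble::tibble(v = c(1, 2, 1, 2), g = c("a", "a", "b", "b"))
  res2 <- kruskal_wallis(df2, v, g)
  expect_equal(res2$statistic, 0)
  expect_gt(res2$p.value, 0.5)
  # random data with ties against the reference implementation
  set.seed(14)
  for (i in 1:20) {
    df3 <- tibble::tibble(
      v = sample(1:6, 30, replace = TRUE),
      g = sample(c("a", "b", "c"), 30, replace = TRUE))
    if (length(unique(df3$g)) < 2 || length(unique(df3$v)) < 2) next
    res3 <- kruskal_wallis(df3, v, g)
    ref <- stats::kruskal.test(df3$v, factor(df3$g))
    expect_equal(res3$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res3$p.value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(tibble::tibble(v = c(1, 1), g = c("a", "b")),
                              v, g),
               class = "pollinet_bad_input")
})
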