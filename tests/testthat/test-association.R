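# Allelic association: proportions, Wald test, Bengtsson-Thomson delta,
# Fisher's exact test.

test_that("allele proportions count chromosomes per group", {
  expect_identical(allele_proportions(FIX_TAB, "DXS1108", 171),
                   c(k_D = 23L, n_D = 24L, k_N = 29L, n_N = 96L))
  expect_identical(allele_proportions(FIX_TAB, "DXS7423", 189),
                   c(k_D = 18L, n_D = 24L, k_N = 15L, n_N = 96L))
  # absent allele
  expect_identical(allele_proportions(FIX_TAB, "DXS7423", 9999),
                   c(k_D = 0L, n_D = 24L, k_N = 0L, n_N = 96L))
  expect_error(allele_proportions(FIX_TAB, "nope", 1), "unknown marker")
})

test_that("missing alleles are excluded pairwise from marker counts", {
  map <- tiny_map()
  tab <- tiny_table(map, rbind(c(10L, 20L), c(NA, 20L)),
                    control = rbind(c(10L, 21L)))
  expect_identical(allele_proportions(tab, "A", 10),
                   c(k_D = 1L, n_D = 1L, k_N = 1L, n_N = 1L))
  expect_identical(allele_proportions(tab, "B", 20),
                   c(k_D = 2L, n_D = 2L, k_N = 0L, n_N = 1L))
})

test_that("difference-in-proportions Wald test matches printed intervals", {
  # 21/24 vs 16/96
  r <- diff_proportions_test(21, 24, 16, 96)
  expect_close(r$delta_p, 0.708, 0.0015)
  expect_close(r$ci_low, 0.556, 0.0015)
  expect_close(r$ci_high, 0.860, 0.0015)
  expect_lt(r$p_value, 1e-4)

  # direct Wald evaluation for 18/24 vs 15/96
  r2 <- diff_proportions_test(18, 24, 15, 96)
  expect_close(r2$ci_low, 0.4058986, 1e-6)
  expect_close(r2$ci_high, 0.7816014, 1e-6)

  # equal proportions -> zero difference, p = 1
  r3 <- diff_proportions_test(5, 10, 50, 100)
  expect_equal(r3$delta_p, 0)
  expect_equal(r3$p_value, 1)

  expect_error(diff_proportions_test(0, 0, 1, 10), "denominator")
})

test_that("Bengtsson-Thomson delta matches exact count ratios", {
  expect_close(bt_delta(23, 24, 29, 96), 0.940, 0.0005)
  expect_equal(bt_delta(22, 24, 80, 96), 0.5, tolerance = 1e-12)
  expect_equal(bt_delta(24, 24, 30, 100), 1)   # p_D = 1 -> delta = 1
  expect_error(bt_delta(5, 10, 96, 96), class = "founderage_undefined_delta")
})

test_that("delta is scale-invariant and increasing in p_D", {
  d0 <- bt_delta(18, 24, 15, 96)
  for (k in c(2L, 3L, 7L))
    expect_equal(bt_delta(18 * k, 24 * k, 15 * k, 96 * k), d0, tolerance = 1e-12)
  ds <- vapply(10:24, function(k) bt_delta(k, 24, 15, 96), numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("fisher_exact matches hand-derived and bounded values", {
  expect_equal(fisher_exact(matrix(c(2, 1, 1, 2), 2)), 1, tolerance = 1e-12)
  p <- fisher_exact(matrix(c(24, 0, 0, 96), 2))
  expect_lt(p, 1e-20)
  expect_equal(p, 1 / choose(120, 24), tolerance = 1e-9)
  expect_error(fisher_exact(matrix(c(0, 0, 0, 5), 2)), "degenerate")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("fisher_exact agrees with enumeration and stats oracle on small margins", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:60, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c_ <- sample(0:(n - a - b), 1); d <- n - a - b - c_
    m <- matrix(c(a, b, c_, d), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- fisher_exact(m)
    expect_equal(p, fisher_bruteforce(m), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("association table assembles all six markers in map order", {
  at <- association_table(FIX_TAB, FIX_ANC, n_boot = 2000, boot_seed = 7)
  expect_equal(nrow(at), 6L)
  expect_equal(at$marker, FIX_MAP$name)
  expect_equal(round(at$delta, 3),
               c(0.704, 0.850, 0.500, 0.758, 0.833, 0.940))
  str13 <- at[at$marker == "STR13", ]
  expect_close(str13$delta_p, 0.417, 0.0015)
  expect_close(str13$ci_low, 0.267, 0.0015)
  expect_close(str13$ci_high, 0.566, 0.0015)
  # bootstrap interval brackets the point estimate
  expect_true(all(at$delta_ci_low <= at$delta + 1e-9))
  expect_true(all(at$delta_ci_high >= at$delta - 1e-9))
  # invariants: proportions in [0,1], delta <= 1, CI brackets delta_p
  expect_true(all(at$p_D >= 0 & at$p_D <= 1))
  expect_true(all(at$p_N >= 0 & at$p_N <= 1))
  expect_true(all(at$delta <= 1))
  expect_true(all(at$ci_low <= at$delta_p & at$delta_p <= at$ci_high))
})

test_that("association on identical groups gives null signal", {
  map <- marker_map(data.frame(name = "A", position_mb = 99),
                    mutation_position_mb = 100)
  one <- matrix(c(10L, 10L, 11L, 11L), ncol = 1)
  tab <- tiny_table(map, one, control = one)
  at <- association_table(tab, structure(c(A = 10L), class = "haplotype"),
                          n_boot = 0)
  expect_equal(at$delta, 0)
  expect_equal(at$p_value, 1)
})

test_that("association requires both groups", {
  map <- tiny_map()
  dis_only <- tiny_table(map, rbind(c(10L, 20L)))
  expect_error(association_table(dis_only, n_boot = 0), "control")
})
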