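# wgd_tests: copy-tree classification, Ks medians and mixture fitting,
# LTR dating.

test_that("copy-tree verdicts follow the quartet on the four copies", {
  expect_identical(classify_copy_tree(parse_newick("((A1,A2),(B1,B2));"),
                                      "A", "B"), "independent")
  expect_identical(classify_copy_tree(parse_newick("((A1,B1),(A2,B2));"),
                                      "A", "B"), "shared")
  # the other cross pairing also places the duplication in the ancestor
  expect_identical(classify_copy_tree(parse_newick("((A1,B2),(A2,B1));"),
                                      "A", "B"), "shared")
  expect_identical(classify_copy_tree(parse_newick("(A1,A2,B1,B2);"),
                                      "A", "B"), "other")
  expect_error(classify_copy_tree(parse_newick("((A1,B1),B2);"), "A", "B"),
               "missing copies for species A")
})

test_that("verdicts are invariant to rooting, species swap and outgroups", {
  tr <- parse_newick("(((A1:1,A2:1):1,(B1:1,B2:1):1):1,OUT:3);")
  expect_identical(classify_copy_tree(tr, "A", "B"), "independent")
  expect_identical(classify_copy_tree(tr, "B", "A"), "independent")
  rerooted <- ape::root(tr, outgroup = "B1", resolve.root = TRUE)
  expect_identical(classify_copy_tree(rerooted, "A", "B"), "independent")

  sh <- parse_newick("((A1,B1),(A2,B2));")
  expect_identical(classify_copy_tree(ape::root(sh, "A2", resolve.root = TRUE),
                                      "B", "A"), "shared")
})

test_that("triplicated (3+3) trees require per-species monophyly", {
  ind <- parse_newick("(((A1,A2),A3),((B1,B2),B3));")
  expect_identical(classify_copy_tree(ind, "A", "B"), "independent")
  mix <- parse_newick("(((A1,B1),A3),((B2,A2),B3));")
  expect_identical(classify_copy_tree(mix, "A", "B"), "shared")
  soft <- parse_newick("((A1,A2,A3),(B1,B2,B3));")
  expect_identical(classify_copy_tree(soft, "A", "B"), "independent")
  poly <- parse_newick("(A1,A2,B1,B2,(A3,B3));") # unresolved mixture
  expect_identical(classify_copy_tree(poly, "A", "B"), "other")
})

test_that("independent proportion uses only classifiable trees", {
  ind <- parse_newick("((A1,A2),(B1,B2));")
  sh <- parse_newick("((A1,B1),(A2,B2));")
  star <- parse_newick("(A1,A2,B1,B2);")
  res <- independent_wgd_proportion(c(rep(list(ind), 8), rep(list(sh), 2),
                                      list(star)), "A", "B")
  expect_equal(res$proportion, 0.8)
  expect_equal(unname(res$counts), c(8, 2, 1))
  expect_error(independent_wgd_proportion(list(star), "A", "B"),
               "no classifiable")
})

test_that("block medians use the midpoint rule and ignore value order", {
  expect_equal(unname(block_median_ks(list(b1 = c(0.9, 1.1, 1.3)))), 1.1)
  expect_equal(unname(block_median_ks(list(b1 = c(0.9, 1.1)))), 1.0)
  set.seed(1)
  v <- runif(11)
  expect_equal(block_median_ks(list(x = v)), block_median_ks(list(x = sample(v))))
  df <- data.frame(block_id = c("a", "a", "b"), ks = c(1, 3, 5))
  expect_equal(block_median_ks(df), c(a = 2, b = 5))
  expect_error(block_median_ks(list(b = numeric(0))), "empty")
})

test_that("single-component EM recovers a known mean", {
  smp <- gen_ks_mixture_sample(data.frame(weight = 1, mean = 1.07, sd = 0.2),
                               n = 2000, seed = 3)
  fit <- fit_ks_mixture(smp$values, k = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$means - 1.07), 0.03)
  expect_equal(fit$weights, 1)
})

test_that("two-component EM recovers means and weights; loglik never drops", {
  smp <- gen_ks_mixture_sample(
    data.frame(weight = c(0.6, 0.4), mean = c(0.5, 1.07), sd = c(0.15, 0.2)),
    n = 2000, seed = 4)
  fit <- fit_ks_mixture(smp$values, k = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - 0.5), 0.05)
  expect_lt(abs(fit$means[2] - 1.07), 0.05)
  expect_lt(abs(fit$weights[1] - 0.6), 0.05)
  expect_equal(sum(fit$weights), 1)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(diff(sort(fit$means)) >= 0)) # canonical component order
})

test_that("BIC prefers one component on unimodal data", {
  smp <- gen_ks_mixture_sample(data.frame(weight = 1, mean = 1.0, sd = 0.15),
                               n = 1500, seed = 5)
  f1 <- fit_ks_mixture(smp$values, k = 1)
  f2 <- fit_ks_mixture(smp$values, k = 2)
  expect_true(f2$converged)
  expect_lt(f1$bic, f2$bic)
})

test_that("mixture fitting validates its inputs", {
  expect_error(fit_ks_mixture(runif(100), k = 0), "positive")
  expect_error(fit_ks_mixture(runif(15), k = 2), "insufficient")
  # truncation: values outside (0, max_ks] are discarded before the check
  expect_error(fit_ks_mixture(c(rep(-1, 50), runif(5)), k = 1),
               "insufficient")
})

test_that("LTR clock is T = K / 2r", {
  expect_equal(ltr_insertion_time(0.0076, 3.8e-9), 1e6)
  expect_equal(ltr_insertion_time(0), 0)
  K <- c(0.001, 0.019, 0.4)
  expect_equal(ltr_insertion_time(K, 7.6e-9), ltr_insertion_time(K) / 2)
  expect_error(ltr_insertion_time(0.01, 0), "positive")
  expect_error(ltr_insertion_time(-0.1), "non-negative")
  expect_equal(unname(clock_rates()["repeat_seq"]), 3.8e-9)
})
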