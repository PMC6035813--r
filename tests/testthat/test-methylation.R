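test_that("delta beta is the tumor minus paratumor group mean", {
  m <- toy_beta_matrix(rbind(c(0.8, 0.8, 0.5, 0.5),
                             c(0.4, 0.6, 0.4, 0.6)))
  expect_equal(unname(compute_delta_beta(m)), c(0.30, 0.0))
  m <- toy_beta_matrix(rbind(c(0.9, 0.7, 0.8, 0.2, 0.3, 0.1)))
  expect_equal(unname(compute_delta_beta(m)), 0.60)
})

test_that("delta beta is missing when a group has < 2 usable values", {
  m <- toy_beta_matrix(rbind(c(0.8, NA, NA, 0.5, 0.5, 0.4),
                             c(0.8, 0.7, 0.9, 0.5, 0.5, 0.4)))
  d <- compute_delta_beta(m)
  expect_true(is.na(d[1]))
  expect_false(is.na(d[2]))
})

test_that("paired tests give textbook p-values on worked examples", {
  # all differences zero: the null is exactly true
  m <- toy_beta_matrix(rbind(c(0.4, 0.6, 0.4, 0.6)))
  expect_equal(unname(paired_test(m, "ttest")), 1)
  expect_equal(unname(paired_test(m, "wilcoxon")), 1)

  # 6 pairs, all differences positive: exact signed-rank 2 * (1/64)
  d <- c(0.3, 0.31, 0.29, 0.3, 0.32, 0.28)
  m <- toy_beta_matrix(rbind(c(0.5 + d, rep(0.5, 6))))
  expect_equal(unname(paired_test(m, "wilcoxon")), 1 / 32)

  # a pair with a missing member is dropped: 2 usable pairs remain,
  # both positive, exact two-sided p = 2 * (1/4)
  m <- toy_beta_matrix(rbind(c(0.3, 0.5, 0.6, NA, 0.2, 0.2)))
  expect_equal(unname(paired_test(m, "wilcoxon")), 0.5)
})

test_that("exact signed-rank fast path matches wilcox.test", {
  set.seed(11)
  for (n in c(5, 8, 12)) {
    d <- round(rnorm(n, 0.1, 0.2), 6)
    m <- toy_beta_matrix(rbind(c(0.5 + d / 2, 0.5 - d / 2)))
    expect_equal(unname(paired_test(m, "wilcoxon")),
                 wilcox.test(d, exact = TRUE)$p.value)
    expect_equal(unname(paired_test(m, "ttest")), t.test(d)$p.value)
  }
})

test_that("swapping group labels negates delta beta, p unchanged", {
  set.seed(3)
  beta <- matrix(runif(8 * 10, 0.2, 0.8), 8, 10)
  m <- toy_beta_matrix(beta)
  swapped <- m
  swapped$samples$group <- ifelse(m$samples$group == "tumor",
                                  "paratumor", "tumor")
  expect_equal(compute_delta_beta(swapped), -compute_delta_beta(m))
  expect_equal(paired_test(swapped), paired_test(m))
})

test_that("BH adjustment reproduces hand-derived examples", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.5), 0.5)
  expect_equal(adjust_bh(c(0.04, 0.01)), c(0.04, 0.02))
})

test_that("BH adjustment validates input and passes missing through", {
  expect_error(adjust_bh(c(0.1, 1.2)), "index 2")
  expect_error(adjust_bh(c(-0.1)), "index 1")
  out <- adjust_bh(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], c(0.02, 0.04))
})

test_that("BH matches the step-up definition and is order-invariant", {
  set.seed(19)
  for (rep in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), bf_bh(p))
    perm <- sample(length(p))
    expect_equal(adjust_bh(p[perm]), adjust_bh(p)[perm])
  }
})

test_that("SDMC calling applies inclusive thresholds and sign rule", {
  rec <- data.frame(delta_beta = c(0.25, 0.249, -0.30, NA, 0.4),
                    adj_p = c(0.05, 0.001, 0.01, 0.01, NA))
  out <- call_sdmc(rec)
  expect_equal(out$is_sdmc, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$direction[1:3], c("hyper", "hyper", "hypo"))
  expect_equal(out$flagged, c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("beta matrix validation enforces pairing and value range", {
  beta <- matrix(0.5, 2, 4,
                 dimnames = list(c("a", "b"), c("T1", "T2", "N1", "N2")))
  samples <- data.frame(sample_id = colnames(beta),
                        group = rep(c("tumor", "paratumor"), each = 2),
                        pair_id = c("P1", "P2", "P1", "P2"))
  expect_s3_class(beta_matrix(beta, samples), "beta_matrix")
  bad <- beta; bad[1, 1] <- 1.2
  expect_error(beta_matrix(bad, samples), "\\[0, 1\\]")
  dup <- samples; dup$pair_id <- c("P1", "P1", "P1", "P2")
  expect_error(beta_matrix(beta, dup), "duplicated")
  one <- samples; one$pair_id <- c("P1", "P2", "P1", "P3")
  expect_error(beta_matrix(beta, one), "2 complete")
})

test_that("probe manifest positions are converted from 1-based on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tchrom\tpos", "cg1\tchr1\t1", "cg2\tchr1\t100"), f)
  man <- read_probe_manifest(f)
  expect_equal(man$pos, c(0, 99))
  writeLines(c("probe_id\tchrom\tpos", "cg1\tchr1\t0"), f)
  expect_error(read_probe_manifest(f), "1-based")
})
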