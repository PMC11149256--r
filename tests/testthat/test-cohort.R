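test_that("the bundled cohort table matches its documented invariants", {
  t <- load_table1()
  expect_s3_class(t, "cohort_table")
  expect_equal(nrow(t), 60L)
  expect_equal(sum(t$diagnosis == "AD"), 37L)
  expect_equal(sum(t$diagnosis == "Control"), 23L)
  r1 <- t[t$id == 1, ]
  expect_equal(r1$diagnosis, "AD")
  expect_equal(c(r1$frontal, r1$occipital, r1$parietal, r1$temporal),
               c(67.4, 31.8, 59.7, 36.6))
  r45 <- t[t$id == 45, ]
  expect_equal(r45$diagnosis, "Control")
  expect_equal(r45$frontal, 86.7)
  expect_true(all(t[, 3:6] > 0))
})

test_that("identical groups give z = 0 and p = 1", {
  rs <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rs$z, 0)
  expect_equal(rs$p, 1)
})

test_that("rank-sum z agrees with the generic implementation in stats", {
  set.seed(14)
  for (rep in 1:20) {
    a <- round(stats::rnorm(sample(5:25, 1), 10, 3), 1)  # rounding makes ties
    b <- round(stats::rnorm(sample(5:25, 1), 11, 3), 1)
    rs <- rank_sum_test(a, b)
    ref <- suppressWarnings(
      stats::wilcox.test(b, a, exact = FALSE, correct = FALSE))
    expect_equal(rs$p, ref$p.value, tolerance = 1e-10)
    expect_equal(rs$U, unname(ref$statistic))
  }
})

test_that("rank-sum z matches the exact-enumeration standardized U", {
  set.seed(6)
  cases <- list(
    list(a = c(1, 2), b = c(3, 4)),
    list(a = c(3, 4), b = c(1, 2)),
    list(a = c(1, 5, 2), b = c(4, 3)),
    list(a = c(1, 1, 2), b = c(2, 3, 3)),      # ties across groups
    list(a = c(7, 3, 5, 9), b = c(2, 8, 4, 6)),
    list(a = round(stats::runif(4), 1), b = round(stats::runif(4), 1))
  )
  for (cs in cases) {
    rs <- rank_sum_test(cs$a, cs$b)
    u_all <- oracle_u_distribution(c(cs$a, cs$b), length(cs$b))
    mu <- mean(u_all)
    sdev <- sqrt(mean((u_all - mu)^2))   # population sd over all splits
    expect_equal(rs$z, (rs$U - mu) / sdev, tolerance = 1e-9)
  }
})

test_that("larger |z| tracks smaller exact p for small samples", {
  set.seed(29)
  res <- t(replicate(30, {
    a <- stats::rnorm(4); b <- stats::rnorm(4, sample(c(0, 1.5, 3), 1))
    rs <- rank_sum_test(a, b)
    u_all <- oracle_u_distribution(c(a, b), 4)
    p_exact <- mean(abs(u_all - mean(u_all)) >= abs(rs$U - mean(u_all)))
    c(az = abs(rs$z), p = p_exact)
  }))
  o <- order(res[, "az"])
  # exact p must be non-increasing as |z| grows (allowing exact-p ties)
  expect_true(all(diff(res[o, "p"]) <= 1e-12))
})

test_that("rank-sum respects its symmetries", {
  set.seed(77)
  a <- stats::rnorm(12); b <- stats::rnorm(9, 0.8)
  rs <- rank_sum_test(a, b)
  swap <- rank_sum_test(b, a)
  expect_equal(swap$z, -rs$z)
  expect_equal(swap$p, rs$p)
  # strictly monotone transform of the pooled data
  mono <- rank_sum_test(exp(a), exp(b))
  expect_equal(mono$z, rs$z)
  # constant shift of both groups
  shift <- rank_sum_test(a + 100, b + 100)
  expect_equal(shift$z, rs$z)
  expect_error(rank_sum_test(numeric(0), b), "nonempty")
})

test_that("region medians reproduce the rounded reporting convention", {
  t <- load_table1()
  fr <- region_medians(t, "frontal")
  expect_equal(fr$median_ad_rounded, 68)
  expect_equal(fr$median_control_rounded, 71)
  te <- region_medians(t, "temporal")
  expect_equal(te$median_ad_rounded, 39)
  expect_equal(te$median_control_rounded, 43)
  # sample-sd convention against the stats implementation
  ad <- t$frontal[t$diagnosis == "AD"]
  expect_equal(fr$sd_ad, stats::sd(ad))
})

test_that("the cohort report separates the groups in all four lobes", {
  rep <- cohort_report()
  expect_equal(nrow(rep), 4L)
  expect_true(all(abs(rep$z) > 2))
  expect_true(all(rep$z > 0))   # controls rank higher throughout
  expect_true(all(rep$p < 0.05))
})

test_that("balanced shuffling of diagnoses shrinks the group separation", {
  t <- load_table1()
  set.seed(123)
  zs <- replicate(20, {
    t2 <- t
    t2$diagnosis <- sample(t$diagnosis)
    class(t2) <- class(t)
    mean(abs(cohort_report(t2)$z))
  })
  expect_lt(mean(zs), mean(abs(cohort_report(t)$z)))
})

test_that("a single-group table is rejected", {
  t <- load_table1()
  ctrl <- t[t$diagnosis == "Control", ]
  class(ctrl) <- class(t)
  expect_error(cohort_report(ctrl), "both AD and Control")
})
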