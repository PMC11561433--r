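test_that("Fleiss kappa matches hand and textbook computations", {
  unanimous <- rbind(c(3, 0), c(0, 3), c(3, 0), c(0, 3), c(3, 0))
  expect_equal(fleiss_kappa(unanimous)$kappa, 1)

  # 2 items, 2 raters, complete disagreement: P_bar = 0, P_e = 0.5, kappa = -1
  disagree <- rbind(c(1, 1), c(1, 1))
  expect_equal(fleiss_kappa(disagree)$kappa, -1)

  set.seed(5)
  for (rep in 1:10) {
    m <- t(stats::rmultinom(10, size = 3, prob = runif(4)))
    k <- fleiss_kappa(m)
    expect_equal(k$kappa, fleiss_oracle(m), tolerance = 1e-12)
    # invariant to category relabeling
    perm <- sample(ncol(m))
    expect_equal(fleiss_kappa(m[, perm])$kappa, k$kappa, tolerance = 1e-12)
  }
  expect_error(fleiss_kappa(rbind(c(3, 0), c(3, 0))),
               class = "telefocus_degenerate")
})

test_that("cluster-robust OLS equals the mean difference with a CR1 sandwich SE", {
  y <- c(2, 2, 2, 5, 5, 5)
  g <- c(0, 0, 0, 1, 1, 1)
  cl <- c("a", "b", "c", "a", "b", "c")
  f <- ols_cluster_robust(y, g, cl)
  expect_equal(f$estimate, 3)
  expect_equal(f$se_clustered, 0)

  set.seed(9)
  for (rep in 1:10) {
    n <- 30
    cl <- sample(letters[1:6], n, replace = TRUE)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) next
    y <- rnorm(n) + 2 * g + rnorm(6)[match(cl, letters[1:6])]
    f <- ols_cluster_robust(y, g, cl)
    expect_equal(f$estimate, mean(y[g == 1]) - mean(y[g == 0]),
                 tolerance = 1e-10)
    expect_equal(f$se_clustered, sandwich_oracle(y, g, cl), tolerance = 1e-10)
    # established-library cross-check
    lmfit <- lm(y ~ g)
    V <- sandwich::vcovCL(lmfit, cluster = cl, type = "HC1")
    expect_equal(f$se_clustered, sqrt(V[2, 2]), tolerance = 1e-8)
    expect_equal(f$p_value,
                 lmtest::coeftest(lmfit, vcov. = V,
                                  df = length(unique(cl)) - 1)[2, 4],
                 tolerance = 1e-8)
  }
})

test_that("with singleton clusters the CR1 SE equals the HC1 robust SE", {
  set.seed(21)
  n <- 40
  g <- rep(0:1, each = 20)
  y <- rnorm(n) + g
  f <- ols_cluster_robust(y, g, cluster = seq_len(n))
  V <- sandwich::vcovHC(lm(y ~ g), type = "HC1")
  expect_equal(f$se_clustered, sqrt(V[2, 2]), tolerance = 1e-10)
})

test_that("Holm-Bonferroni is the step-down adjustment", {
  expect_equal(holm_bonferroni(0.03)$adjusted, 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04))$adjusted,
               c(0.03, 0.04, 0.04))
  set.seed(13)
  for (rep in 1:10) {
    p <- runif(sample(2:8, 1))
    hb <- holm_bonferroni(p)
    expect_true(all(hb$adjusted >= hb$raw))
    expect_true(all(hb$adjusted <= 1))
    expect_equal(hb$adjusted, p.adjust(p, "holm"), tolerance = 1e-12)
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(holm_bonferroni(p[perm])$adjusted, hb$adjusted[perm])
  }
  expect_equal(holm_bonferroni(numeric())$adjusted, numeric())
})

test_that("Spearman uses midranks and the t approximation", {
  x <- 1:6
  expect_equal(spearman_test(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_test(x, -x)$rho, -1)
  y <- c(3, 1, 1, 5, 2, 4)  # tie
  st <- spearman_test(x, y)
  expect_equal(st$rho, spearman_oracle(x, y), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(st$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(st$p_value, ct$p.value, tolerance = 1e-10)
  expect_error(spearman_test(x, rep(1, 6)), class = "telefocus_degenerate")
})

test_that("Cohen's d uses the pooled SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5))$d, -2)
  set.seed(3)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(cohens_d(a, b)$d, -cohens_d(b, a)$d)
  expect_error(cohens_d(c(1), c(2, 3)), class = "telefocus_degenerate")
})

test_that("attribute-mention proportions count calls, not utterances", {
  calls <- data.frame(call_id = sprintf("c%d", 1:8), patient_id = "P1",
                      date = as.Date("2015-04-01") + 1:8, scheduled = TRUE)
  utts <- do.call(rbind, lapply(1:8, function(i)
    make_utts(sprintf("c%d", i), rep("symptom_checking", 3),
              attrs = if (i <= 3) c("frequency", "frequency", "") else "")))
  ds <- telecare_cohort(make_patients("P1"), calls, utts, vocab = voc)
  pr <- proportion_with_attribute(ds, calls$call_id)
  expect_equal(pr$proportion[pr$attribute == "frequency"], 0.375)
  expect_equal(pr$proportion[pr$attribute == "any"], 0.375)
  expect_equal(pr$proportion[pr$attribute == "location"], 0)
})
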