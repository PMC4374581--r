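test_that("same-signed cohorts reproduce the exact 2/2^n tail probabilities", {
  expect_equal(signed_rank_exact(c(-24, -78, -6, -31, -88, -3, -53, -19))$p.value,
               0.0078125)
  expect_equal(signed_rank_exact(rep(-26, 7) * c(1, 2, 3, 0.5, 0.9, 1.1, 3.2))$p.value,
               0.015625)
  expect_equal(signed_rank_exact(c(1, 2, 3, 4, 5, 6) * -1)$p.value, 0.03125)
  expect_equal(signed_rank_exact(c(1, -1))$p.value, 1.0)
})

test_that("the DP distribution equals brute-force sign enumeration", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n, 0, 10), 1)
    x <- x[x != 0]
    if (length(x) < 2) next
    expect_equal(signed_rank_exact(x)$p.value, signed_rank_bruteforce_p(x))
  }
  # with ties (midranks): agreement still holds
  expect_equal(signed_rank_exact(c(3, 3, -3, 5, -5, 8))$p.value,
               signed_rank_bruteforce_p(c(3, 3, -3, 5, -5, 8)))
})

test_that("the exact test is sign-symmetric and drops zeros", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(7)
    expect_equal(signed_rank_exact(x)$p.value, signed_rank_exact(-x)$p.value)
  }
  withzeros <- c(0, 0, -4, -9, -2)
  expect_equal(signed_rank_exact(withzeros)$n, 3L)
  expect_equal(signed_rank_exact(withzeros)$p.value,
               signed_rank_exact(c(-4, -9, -2))$p.value)
  deg <- signed_rank_exact(c(0, 0, 0))
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 1)
})

test_that("exact p agrees with the reference implementation when tie-free", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(8)
    expect_equal(signed_rank_exact(x)$p.value,
                 suppressWarnings(wilcox.test(x, exact = TRUE)$p.value))
  }
})

test_that("percentage changes follow the definition and refuse zero baselines", {
  expect_equal(percent_change(100, 50), -50)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(4.0, 3.04), -24.0)
  expect_warning(pc <- percent_change(0, 5), "zero baseline")
  expect_true(is.na(pc))
})

test_that("pearson r and p match the reference on trivial and random cases", {
  x <- 1:8
  perfect <- pearson_with_p(x, 2 * x)
  expect_equal(perfect$r, 1.0)
  expect_equal(perfect$p.value, 0)
  # constructed zero sample covariance
  xo <- c(-1, 1, -1, 1); yo <- c(-1, -1, 1, 1)
  orth <- pearson_with_p(xo, yo)
  expect_equal(orth$r, 0)
  expect_equal(orth$p.value, 1)
  # affine invariance (positive slope)
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(pearson_with_p(a, b)$r, pearson_with_p(3 * a + 7, b)$r,
               tolerance = 1e-12)
  # against the reference implementation
  for (i in 1:10) {
    a <- rnorm(9); b <- rnorm(9)
    ref <- cor.test(a, b)
    got <- pearson_with_p(a, b)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  }
  expect_warning(und <- pearson_with_p(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(und$r))
})

# small synthetic records table: 8 patients, values chosen so every ADC
# change is positive and every SUVmax change negative
records_fixture <- function() {
  set.seed(55)
  n <- 8
  tibble::tibble(
    patient = rep(sprintf("P%02d", 1:n), each = 3),
    timepoint = rep(c("baseline", "fx11", "fx21"), n),
    adc = as.numeric(sapply(1:n, function(i)
      cumprod(c(runif(1, 0.8, 1.2), runif(1, 1.2, 1.6), runif(1, 1.0, 1.1))))),
    suvmax = as.numeric(sapply(1:n, function(i)
      cumprod(c(runif(1, 10, 14), runif(1, 0.6, 0.9), runif(1, 0.6, 0.9))))))
}

test_that("change summaries report complete-case medians, ranges and exact p", {
  rec <- records_fixture()
  summ <- change_summary(rec, parameters = c("adc", "suvmax"))
  expect_equal(nrow(summ), 6)                    # 2 parameters x 3 intervals
  r <- summ[summ$parameter == "adc" & summ$interval == "baseline-fx11", ]
  expect_equal(r$n, 8)
  expect_equal(r$p_value, 0.0078125)             # all 8 changes positive
  expect_gt(r$median_pct, 0)
  s <- summ[summ$parameter == "suvmax" & summ$interval == "baseline-fx11", ]
  expect_lt(s$max_pct, 0)                        # all negative
  expect_equal(s$p_value, 0.0078125)

  # missing modality drops n, never imputes
  rec2 <- rec
  rec2$adc[rec2$patient == "P01"] <- NA
  summ2 <- change_summary(rec2, parameters = c("adc"))
  expect_equal(summ2$n[summ2$interval == "baseline-fx11"], 7)
  expect_equal(summ2$p_value[summ2$interval == "baseline-fx11"], 0.015625)

  # all-missing parameter is omitted with a message
  rec3 <- rec; rec3$adc <- NA_real_
  expect_message(summ3 <- change_summary(rec3, parameters = c("adc", "suvmax")),
                 "omitted")
  expect_false("adc" %in% summ3$parameter)

  # single patient: p unreportable
  rec4 <- rec[rec$patient == "P01", ]
  summ4 <- change_summary(rec4, parameters = "adc")
  expect_true(all(is.na(summ4$p_value)))
})

test_that("the correlation screen keeps pairs below alpha, uncorrected", {
  rec <- records_fixture()
  # construct a pair correlated by design: y = 2x on the change scale
  rec$pf <- rec$adc * 2
  scr <- correlation_screen(rec, parameters = c("adc", "suvmax", "pf"),
                            intervals = "baseline-fx11", alpha = 0.05)
  row <- scr[scr$parameter1 == "adc" & scr$parameter2 == "pf", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$r, 1.0, tolerance = 1e-12)
  expect_equal(row$p_value, 0)

  empty <- correlation_screen(rec, parameters = c("adc", "suvmax", "pf"),
                              alpha = 0)
  expect_equal(nrow(empty), 0)

  # Holm correction can only prune
  holm <- correlation_screen(rec, parameters = c("adc", "suvmax", "pf"),
                             intervals = "baseline-fx11", holm = TRUE)
  expect_lte(nrow(holm), nrow(scr))
})
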