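test_that("identical raters give perfect agreement and kappa 1", {
  r <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  res <- agreement(r, categories = 1:5)
  expect_identical(res$observed_agreement, 1)
  expect_identical(res$cohen_kappa, 1)
  expect_identical(res$weighted_kappa, 1)
  expect_true(all(res$per_item == 1))
})

test_that("hand-computed three-item example matches all weightings", {
  # raters A = (1,2,3), B = (1,3,2) on categories 1..3; by direct formula:
  # unweighted: po = 1/3, pe = 1/3, kappa = 0
  # linear:     po_w = 2/3, pe_w = 5/9, kappa_w = (1/9)/(4/9) = 0.25
  # quadratic:  po_w = 5/6, pe_w = 2/3, kappa_w = (1/6)/(1/3) = 0.5
  r <- rbind(A = c(1, 2, 3), B = c(1, 3, 2))
  expect_equal(agreement(r)$cohen_kappa, 0)
  expect_equal(agreement(r)$observed_agreement, 1 / 3)
  expect_equal(agreement(r, weighting = "linear")$weighted_kappa, 0.25)
  expect_equal(agreement(r, weighting = "quadratic")$weighted_kappa, 0.5)
})

test_that("null weighting reproduces unweighted Cohen's kappa", {
  set.seed(14)
  for (rep in 1:5) {
    r <- rbind(sample(1:5, 40, replace = TRUE),
               sample(1:5, 40, replace = TRUE))
    res <- agreement(r, weighting = "none", categories = 1:5)
    expect_identical(res$weighted_kappa, res$cohen_kappa)
  }
})

test_that("kappa matches an independent library implementation", {
  set.seed(25)
  for (rep in 1:5) {
    a <- sample(1:5, 60, replace = TRUE)
    b <- ifelse(runif(60) < 0.6, a, sample(1:5, 60, replace = TRUE))
    ours <- agreement(rbind(a, b), categories = 1:5)$cohen_kappa
    ref <- e1071::classAgreement(table(factor(a, 1:5),
                                       factor(b, 1:5)))$kappa
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("independent uniform raters give kappa near zero", {
  set.seed(70)
  n <- 10000
  r <- rbind(sample(1:5, n, replace = TRUE), sample(1:5, n, replace = TRUE))
  res <- agreement(r, categories = 1:5)
  # under independence po ~ pe ~ 1/5; SE of kappa ~ se(po)/(1-pe)
  se <- sqrt(0.2 * 0.8 / n) / 0.8
  expect_lt(abs(res$cohen_kappa), 3 * se)
  expect_lt(abs(res$observed_agreement - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("degenerate single-category ratings report kappa as undefined", {
  r <- rbind(rep(2, 10), rep(2, 10))
  res <- agreement(r)
  expect_identical(res$observed_agreement, 1)
  expect_true(is.na(res$cohen_kappa))
  expect_match(res$notes, "undefined")
})

test_that("permuting item order leaves every statistic unchanged", {
  set.seed(33)
  r <- rbind(sample(1:5, 30, replace = TRUE),
             sample(1:5, 30, replace = TRUE),
             sample(1:5, 30, replace = TRUE))
  perm <- sample(30)
  a1 <- agreement(r, weighting = "quadratic", categories = 1:5)
  a2 <- agreement(r[, perm], weighting = "quadratic", categories = 1:5)
  expect_equal(a1$observed_agreement, a2$observed_agreement)
  expect_equal(a1$cohen_kappa, a2$cohen_kappa)
  expect_equal(a1$weighted_kappa, a2$weighted_kappa)
  expect_equal(sort(a1$per_item), sort(a2$per_item))
})

test_that("more than two raters averages over pairs", {
  r <- rbind(a = c(1, 1, 2), b = c(1, 1, 2), c = c(1, 2, 2))
  res <- agreement(r, categories = 1:2)
  # pairwise exact-match fractions: (a,b)=1, (a,c)=2/3, (b,c)=2/3
  expect_equal(res$observed_agreement, mean(c(1, 2 / 3, 2 / 3)))
  expect_identical(res$n_raters, 3L)
})

test_that("ratings files in long format pivot to rater-by-item matrices", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- expand.grid(item_id = paste0("i", 1:4), rater_id = c("r1", "r2"),
                    stringsAsFactors = FALSE)
  df$rating <- c(1, 2, 3, 4, 1, 2, 3, 5)
  utils::write.csv(df, path, row.names = FALSE)
  m <- read_ratings(path)
  expect_identical(dim(m), c(2L, 4L))
  expect_identical(rownames(m), c("r1", "r2"))
  expect_equal(agreement(m, categories = 1:5)$observed_agreement, 0.75)

  df2 <- df[-3, ]
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_ratings(path), "incomplete")
})

test_that("two cohorts rated on the same visits compare per component", {
  a <- mncd_examples()
  b <- as.data.frame(a)
  b$m_tremor[2] <- 0   # rater B missed the tremor -> stage differs too
  b <- as_mncd_cohort(b)
  pc <- rater_component_agreement(a, b)
  expect_identical(unname(pc[["m_tremor"]]), 0.8)
  expect_identical(unname(pc[["stage"]]), 0.8)
  expect_true(all(pc[setdiff(names(pc), c("m_tremor", "stage"))] == 1))
})

test_that("degenerate shapes are rejected", {
  expect_error(agreement(matrix(1, 1, 5)), "2 raters")
  expect_error(agreement(rbind(c(1, NA), c(1, 2))), "NA")
  expect_error(agreement(rbind(1:3, 1:3), categories = 1:2), "outside")
})
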