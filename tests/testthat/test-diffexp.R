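test_that("NB GLM closed forms: intercept-only and saturated two-group fits", {
  y <- c(12L, 8L, 10L, 14L, 6L)
  fit <- fit_nb_glm(y, matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)")),
                    rep(0, 5), dispersion = 0.1)
  expect_equal(unname(fit$coefficients), log(mean(y)), tolerance = 1e-8)

  y2 <- c(rep(40L, 4), rep(10L, 4))
  design <- cbind(`(Intercept)` = 1, grp = rep(c(0, 1), each = 4))
  fit2 <- fit_nb_glm(y2, design, rep(0, 8), dispersion = 0.1)
  expect_equal(unname(fit2$coefficients["grp"]), log(10 / 40),
               tolerance = 1e-8)
})

test_that("NB GLM deviance agrees with a generic likelihood optimizer", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- 12
      design <- cbind(1, stats::rnorm(n), stats::rbinom(n, 1, 0.5))
      colnames(design) <- c("(Intercept)", "x1", "x2")
      beta <- c(3, 0.5, -0.8)
      off <- stats::rnorm(n, 0, 0.2)
      phi <- 0.15
      y <- stats::rnbinom(n, mu = exp(design %*% beta + off), size = 1 / phi)
      fit <- fit_nb_glm(y, design, off, phi)
      nll <- function(b) -sum(stats::dnbinom(
        y, size = 1 / phi, mu = exp(design %*% b + off), log = TRUE))
      opt <- stats::optim(fit$coefficients, nll, method = "BFGS")
      # equal maximized likelihoods => equal deviances up to the optimizer's
      # own tolerance
      expect_equal(nll(fit$coefficients), opt$value, tolerance = 1e-4)
      expect_gte(nll(fit$coefficients) - opt$value, -1e-4)
    }
  })
})

test_that("dispersion estimation recovers known truth", {
  meta <- withr::with_seed(30, data.frame(
    sample_id = sprintf("S%02d", 1:30),
    group = rep(c("PC", "BTC", "HC"), each = 10),
    age = round(stats::runif(30, 35, 75)),
    gender = rep(c("M", "F"), 15),
    bmi = round(stats::runif(30, 19, 30), 1)))
  make_counts <- function(seed, phi) withr::with_seed(seed, {
    mu <- stats::rlnorm(500, log(100), 1)
    counts <- sapply(1:30, function(j) {
      if (phi == 0) stats::rpois(500, mu)
      else stats::rnbinom(500, mu = mu, size = 1 / phi)
    })
    dimnames(counts) <- list(sprintf("mir-%03d", 1:500), meta$sample_id)
    count_matrix(counts, meta)
  })
  des <- group_design(meta)$full
  cm_pois <- make_counts(31, 0)
  d0 <- estimate_dispersion(cm_pois, des, offsets = rep(0, 30))
  expect_lte(d0$common, 0.05)

  cm_nb <- make_counts(32, 0.2)
  d2 <- estimate_dispersion(cm_nb, des, offsets = rep(0, 30))
  expect_gte(d2$common, 0.1)
  expect_lte(d2$common, 0.3)
})

test_that("constant counts hit the dispersion floor with a warning", {
  counts <- matrix(7L, nrow = 3, ncol = 6,
                   dimnames = list(paste0("m", 1:3), sprintf("S%02d", 1:6)))
  meta <- data.frame(sample_id = colnames(counts),
                     group = rep(c("PC", "BTC", "HC"), 2),
                     age = 50:55, gender = "F", bmi = 22)
  cm <- count_matrix(counts, meta)
  expect_warning(d <- estimate_dispersion(cm, group_design(meta)$full,
                                          offsets = rep(0, 6)),
                 "floor")
  expect_equal(unname(d$dispersion), rep(1e-6, 3))
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  withr::with_seed(41, {
    for (rep in 1:100) {
      p <- stats::runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), bf_bh(p))
    }
    # permutation invariance
    p <- stats::runif(30)
    perm <- sample(30)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  })
})

test_that("confounded designs are rejected naming the collinear columns", {
  meta <- data.frame(sample_id = sprintf("S%02d", 1:9),
                     group = rep(c("PC", "BTC", "HC"), each = 3),
                     age = 50, gender = rep(c("M", "M", "F"), each = 3),
                     bmi = 22)
  # constant age column collapses to the intercept after centering
  expect_error(group_design(meta), "age")
})

test_that("group LRT has BH-consistent FDR and a single p passes through", {
  cm <- make_cm(40, 18, seed = 13, lambda = 100)
  de <- lrt_group_effect(cm)
  expect_true(all(de$fdr >= de$p_value - 1e-12, na.rm = TRUE))
  expect_equal(de$fdr[!is.na(de$p_value)], bf_bh(de$p_value[!is.na(de$p_value)]))
  expect_true(all(de$lr_statistic >= 0))
  # BH with m = 1 is the identity
  expect_equal(bh_adjust(0.03), 0.03)
})

test_that("LR statistic is invariant to a redundant covariate representation", {
  cm <- make_cm(25, 18, seed = 17, lambda = 100)
  f <- tmm_factors(cm)
  de_ag <- lrt_group_effect(cm, covariates = c("age", "gender"), factors = f)
  # recompute with bmi set to a linear function of age: adding a column
  # spanned by existing ones must be rejected, while the age+gender model is
  # unchanged by the bmi values present in metadata
  cm2 <- cm
  cm2$metadata$bmi <- 2 * cm2$metadata$age + 1
  de_ag2 <- lrt_group_effect(cm2, covariates = c("age", "gender"), factors = f)
  expect_equal(de_ag$lr_statistic, de_ag2$lr_statistic)
  expect_error(lrt_group_effect(cm2, covariates = c("age", "gender", "bmi"),
                                factors = f),
               "collinear")
})

test_that("descriptive pairwise fold changes match the row-mean difference", {
  cm <- make_cm(30, 12, seed = 19, lambda = 120)
  expr <- log2cpm(cm)
  fc <- pairwise_log2fc(expr, threshold_fold = 2)
  labels <- expr$metadata$group
  bf <- rowMeans(expr$log2cpm[, labels == "PC"]) -
        rowMeans(expr$log2cpm[, labels == "HC"])
  expect_equal(fc$log2fc_PN, unname(bf))
  expect_equal(fc$flag_PN, unname(abs(bf) > 1))
  expect_equal(fc$direction_PN, unname(ifelse(bf >= 0, "up", "down")))
  expect_error(pairwise_log2fc(expr, pairs = "XX"), "unknown pair")

  # identical groups give zero, unflagged
  same <- expr
  same$log2cpm[, labels == "PC"] <-
    rowMeans(same$log2cpm[, labels == "HC", drop = FALSE])
  fc0 <- pairwise_log2fc(same, pairs = "PN")
  expect_equal(fc0$log2fc_PN, rep(0, 30))
  expect_false(any(fc0$flag_PN))
})
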