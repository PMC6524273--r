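#' Simulate a serum miRNA sequencing cohort with planted differential expression
#'
#' Generates a miRNA x sample negative-binomial read-count matrix plus sample
#' metadata that emulates a three-group serum miRNA study: 24 pancreatic
#' cancer (PC), 10 biliary tract cancer (BTC) and 21 healthy control (HC)
#' samples over ~677 expressed miRNAs, with ~42 planted group-dysregulated
#' miRNAs, unequal library sizes and deliberately confounded covariates (the
#' cancer groups are ~19 years older on average than the controls, gender
#' proportions and BMI differ by group). A fraction of the planted miRNAs
#' carry the same effect in both cancer groups, emulating the near-identical
#' PC/BTC serum profiles such studies report; the remainder are dysregulated
#' in one cancer only.
#'
#' Baseline relative abundances are heavy-tailed log-normal; counts are
#' NB(mu, phi) with `mu = abundance x library size x group and covariate
#' multipliers` and constant dispersion `phi`. Generation is deterministic
#' given `seed` and leaves the global RNG state untouched.
#'
#' @param n_pc,n_btc,n_hc Group sizes (defaults 24/10/21).
#' @param n_mirna Number of miRNAs (default 677).
#' @param n_de Number of planted differentially expressed miRNAs (default 42).
#' @param log2fc Absolute planted effect size in log2 units (default 1).
#' @param shared_cancer_effect_fraction Fraction of planted miRNAs carrying
#'   the identical effect in PC and BTC (default 0.8).
#' @param dispersion NB dispersion phi (default 0.2).
#' @param libsize_range Range library sizes are drawn from, uniformly
#'   (default 5e5..2e6).
#' @param confound Keep the group/age confounding on (default TRUE); when
#'   FALSE all groups share the control covariate distributions.
#' @param covariate_effects Logical; when TRUE (default) a random 10% of
#'   miRNAs respond to age, gender or BMI, so covariate adjustment is
#'   meaningfully exercised.
#' @param n_outliers Number of HC samples given the cancer effect profile
#'   (default 0), mimicking controls with cancer-like serum profiles.
#' @param seed Integer seed.
#' @return List with `cm` (a [count_matrix()]) and `truth` (class
#'   `sim_truth`): planted ids, per-group log2 effects, baseline means,
#'   dispersion, library sizes, covariate effect table, outlier ids and the
#'   seed.
#' @export
simulate_cohort <- function(n_pc = 24, n_btc = 10, n_hc = 21,
                            n_mirna = 677, n_de = 42,
                            log2fc = 1.0,
                            shared_cancer_effect_fraction = 0.8,
                            dispersion = 0.2,
                            libsize_range = c(5e5, 2e6),
                            confound = TRUE,
                            covariate_effects = TRUE,
                            n_outliers = 0,
                            seed = 1) {
  stopifnot(n_de <= n_mirna, n_pc >= 2, n_btc >= 2, n_hc >= 2,
            shared_cancer_effect_fraction >= 0,
            shared_cancer_effect_fraction <= 1,
            n_outliers <= n_hc)
  withr::with_seed(seed, {
    n <- n_pc + n_btc + n_hc
    group <- c(rep("PC", n_pc), rep("BTC", n_btc), rep("HC", n_hc))
    sample_id <- sprintf("%s%02d", c(rep("P", n_pc), rep("B", n_btc),
                                     rep("N", n_hc)),
                         c(seq_len(n_pc), seq_len(n_btc), seq_len(n_hc)))
    mirna_id <- sprintf("sim-mir-%04d", seq_len(n_mirna))

    # covariates per Table-3-like cohort structure; HC distributions reused
    # for all groups when confounding is switched off
    age_mean <- c(PC = 62.8, BTC = 62.8, HC = 43.9)
    age_sd   <- c(PC = 11.1, BTC = 7.8,  HC = 11.8)
    male_p   <- c(PC = 11 / 24, BTC = 7 / 10, HC = 15 / 21)
    bmi_mean <- c(PC = 21.7, BTC = 23.2, HC = 23.8)
    bmi_sd   <- c(PC = 2.9,  BTC = 3.9,  HC = 3.8)
    src <- if (confound) group else rep("HC", n)
    age <- round(stats::rnorm(n, age_mean[src], age_sd[src]), 1)
    gender <- ifelse(stats::runif(n) < male_p[src], "M", "F")
    bmi <- round(stats::rnorm(n, bmi_mean[src], bmi_sd[src]), 1)

    # heavy-tailed baseline relative abundances
    base <- stats::rlnorm(n_mirna, meanlog = log(200), sdlog = 1.6)
    rel <- base / sum(base)

    # planted effects: log2 multipliers per group (HC baseline 0)
    de_ids <- sort(sample(mirna_id, n_de))
    n_shared <- round(n_de * shared_cancer_effect_fraction)
    sign_fc <- sample(c(-1, 1), n_de, replace = TRUE)
    eff <- matrix(0, nrow = n_mirna, ncol = 3,
                  dimnames = list(mirna_id, c("PC", "BTC", "HC")))
    de_idx <- match(de_ids, mirna_id)
    shared <- seq_len(n_shared)
    eff[de_idx[shared], "PC"]  <- sign_fc[shared] * log2fc
    eff[de_idx[shared], "BTC"] <- sign_fc[shared] * log2fc
    if (n_shared < n_de) {
      rest <- (n_shared + 1):n_de
      # cancer-specific effects alternate between PC-only and BTC-only
      pc_only <- rest[seq_along(rest) %% 2 == 1]
      btc_only <- setdiff(rest, pc_only)
      eff[de_idx[pc_only], "PC"] <- sign_fc[pc_only] * log2fc
      eff[de_idx[btc_only], "BTC"] <- sign_fc[btc_only] * log2fc
    }

    # covariate responses on a random 10% of miRNAs (log2 scale)
    cov_eff <- matrix(0, nrow = n_mirna, ncol = 3,
                      dimnames = list(mirna_id, c("age", "genderM", "bmi")))
    if (covariate_effects) {
      n_cov <- max(1, round(0.1 * n_mirna))
      rows <- sample.int(n_mirna, n_cov)
      which_cov <- sample(1:3, n_cov, replace = TRUE)
      slope <- c(age = 0.015, genderM = 0.4, bmi = 0.03)
      for (i in seq_len(n_cov))
        cov_eff[rows[i], which_cov[i]] <-
          sample(c(-1, 1), 1) * slope[which_cov[i]]
    }

    libsize <- round(stats::runif(n, libsize_range[1], libsize_range[2]))

    outlier_ids <- character(0)
    eff_col <- match(group, colnames(eff))
    log2mult <- eff[, eff_col, drop = FALSE]          # miRNA x sample
    if (n_outliers > 0) {
      hc_pos <- which(group == "HC")[seq_len(n_outliers)]
      outlier_ids <- sample_id[hc_pos]
      log2mult[, hc_pos] <- eff[, "PC"]               # cancer-like profile
    }
    age_c <- age - mean(age); bmi_c <- bmi - mean(bmi)
    covmult <- outer(cov_eff[, "age"], age_c) +
               outer(cov_eff[, "genderM"], as.numeric(gender == "M")) +
               outer(cov_eff[, "bmi"], bmi_c)
    mu <- rel * 2^(log2mult + covmult)
    mu <- sweep(mu, 2, libsize, `*`)

    counts <- matrix(stats::rnbinom(n_mirna * n, mu = mu,
                                    size = 1 / dispersion),
                     nrow = n_mirna,
                     dimnames = list(mirna_id, sample_id))
    metadata <- data.frame(sample_id = sample_id, group = group,
                           age = age, gender = gender, bmi = bmi,
                           stringsAsFactors = FALSE)
    cm <- count_matrix(counts, metadata)
    truth <- structure(list(de_ids = de_ids,
                            effects_log2 = eff[de_idx, , drop = FALSE],
                            baseline_rel_abundance = rel,
                            dispersion = dispersion,
                            library_sizes = stats::setNames(libsize, sample_id),
                            covariate_effects_log2 = cov_eff,
                            outlier_ids = outlier_ids,
                            seed = seed),
                       class = "sim_truth")
    list(cm = cm, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth: ", length(x$de_ids), " planted DE miRNAs, dispersion ",
      x$dispersion, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a qPCR-style validation expression table
#'
#' Gaussian per-sample expression for a small panel of miRNAs with specified
#' mean shifts in the cancer group, emulating an independent validation
#' cohort (default 34 cancer vs 19 control samples).
#'
#' @param n_cancer,n_control Group sizes (defaults 34/19).
#' @param mirnas Character vector of miRNA names.
#' @param effect_sizes Mean shift (cancer minus control, in expression
#'   units) per miRNA, aligned with `mirnas`.
#' @param sd Within-group standard deviation (default 1).
#' @param seed Integer seed.
#' @return List with `expr` (sample x miRNA matrix), `labels`
#'   (cancer/control) and `truth` (the arguments).
#' @export
simulate_qpcr <- function(n_cancer = 34, n_control = 19,
                          mirnas = c("sim-mir-A", "sim-mir-B", "sim-mir-C"),
                          effect_sizes = c(1, -1, 0.5), sd = 1, seed = 1) {
  stopifnot(length(effect_sizes) == length(mirnas),
            n_cancer >= 2, n_control >= 2)
  withr::with_seed(seed, {
    n <- n_cancer + n_control
    labels <- c(rep("cancer", n_cancer), rep("control", n_control))
    expr <- vapply(seq_along(mirnas), function(j) {
      shift <- ifelse(labels == "cancer", effect_sizes[j], 0)
      stats::rnorm(n, mean = 5 + shift, sd = sd)
    }, numeric(n))
    dimnames(expr) <- list(sprintf("V%02d", seq_len(n)), mirnas)
    list(expr = expr, labels = labels,
         truth = list(mirnas = mirnas, effect_sizes = effect_sizes,
                      sd = sd, seed = seed))
  })
}
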