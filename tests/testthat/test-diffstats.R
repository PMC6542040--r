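norm_matrix <- function(m, design) {
  attr(m, "transform") <- "normalized-log2"
  m
}

test_that("one-way ANOVA matches textbook arithmetic and oneway.test", {
  design <- generate_design(2, c(0, 10, 40))
  cols <- design$sample[design$fluid == "serum"]
  m <- matrix(NA_real_, 1, nrow(design),
              dimnames = list("F1", design$sample))
  m[1, cols] <- c(1, 2, 3, 4, 5, 6)  # groups {1,2},{3,4},{5,6}
  res <- anova_per_feature(norm_matrix(m, design), design, "serum")
  # textbook arithmetic: SSB = 16 on 2 df, SSW = 1.5 on 3 df -> F = 8 / 0.5
  expect_equal(res$f_stat, 16)
  expect_equal(res$p_value, pf(16, 2, 3, lower.tail = FALSE))
  ref <- oneway.test(m[1, cols] ~ factor(rep(c(0, 10, 40), each = 2)),
                     var.equal = TRUE)
  expect_equal(res$f_stat, unname(ref$statistic))

  # two groups: F equals the square of the equal-variance t statistic
  design2 <- generate_design(4, c(0, 40))
  cols2 <- design2$sample[design2$fluid == "serum"]
  set.seed(5)
  x <- rnorm(8)
  m2 <- matrix(NA_real_, 1, nrow(design2), dimnames = list("F1", design2$sample))
  m2[1, cols2] <- x
  res2 <- anova_per_feature(norm_matrix(m2, design2), design2, "serum")
  tt <- t.test(x[1:4], x[5:8], var.equal = TRUE)
  expect_equal(res2$f_stat, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-10)

  # agreement with stats::oneway.test on random data
  set.seed(6)
  m3 <- matrix(rnorm(5 * nrow(design)), 5,
               dimnames = list(sprintf("F%d", 1:5), design$sample))
  res3 <- anova_per_feature(norm_matrix(m3, design), design, "serum")
  for (i in 1:5) {
    ref <- oneway.test(m3[i, cols] ~ factor(design$dose[design$fluid == "serum"]),
                       var.equal = TRUE)
    expect_equal(res3$f_stat[i], unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("degenerate and untestable features get conventional p = 1", {
  design <- generate_design(3, c(0, 40))
  m <- matrix(NA_real_, 2, nrow(design),
              dimnames = list(c("const", "sparse"), design$sample))
  m["const", design$sample[design$fluid == "serum"]] <- 7
  m["sparse", design$sample[design$fluid == "serum"][1L]] <- 3
  res <- anova_per_feature(norm_matrix(m, design), design, "serum")
  expect_equal(res$p_value, c(1, 1))
  expect_equal(res$testable, c(TRUE, FALSE))
})

test_that("null p values are uniform", {
  design <- generate_design(6, c(0, 10, 40))
  set.seed(31)
  m <- matrix(rnorm(1000 * nrow(design)), 1000,
              dimnames = list(sprintf("F%d", 1:1000), design$sample))
  res <- anova_per_feature(norm_matrix(m, design), design, "serum")
  ks <- ks.test(res$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH step-up matches closed-form examples and the brute-force oracle", {
  r <- bh_adjust(c(0.01, 0.02, 0.03))
  expect_equal(r$q, c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2)$q, 0.2)
  expect_false(any(bh_adjust(rep(1, 10))$significant))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(13)
  for (rep in 1:10) {
    p <- round(runif(sample(5:40, 1L)), 3)
    r <- bh_adjust(p)
    expect_equal(r$q, oracle_bh_q(p), tolerance = 1e-12)
    expect_equal(r$q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_identical(r$significant, r$q <= 0.05)
  }
})

test_that("BH controls the flagged fraction under the full null", {
  design <- generate_design(6, c(0, 10, 40))
  set.seed(41)
  total_flags <- 0L
  total <- 0L
  for (rep in 1:20) {
    m <- matrix(rnorm(400 * nrow(design)), 400,
                dimnames = list(sprintf("F%d", 1:400), design$sample))
    res <- anova_per_feature(norm_matrix(m, design), design, "serum")
    total_flags <- total_flags + sum(bh_adjust(res$p_value)$significant)
    total <- total + 400L
  }
  # expected flagged fraction is the FDR <= 0.05; allow the 99.9% binomial bound
  expect_lte(total_flags, qbinom(0.999, total, 0.05))
})

test_that("planted effects at CV 30%, n = 6 are flagged with >= 80% power", {
  design <- generate_design(6, c(0, 10, 40))
  set.seed(51)
  n <- 400
  modulated <- rep(c(TRUE, FALSE), each = n / 2)
  sdlog2 <- sqrt(log(1 + 0.3^2)) / log(2)
  m <- matrix(NA_real_, n, nrow(design),
              dimnames = list(sprintf("F%d", 1:n), design$sample))
  for (j in seq_len(nrow(design))) {
    eff <- ifelse(modulated, design$dose[j] / 40, 0)
    m[, j] <- rnorm(n, eff, sdlog2)
  }
  res <- anova_per_feature(norm_matrix(m, design), design, "serum")
  flags <- bh_adjust(res$p_value)$significant
  expect_gte(mean(flags[modulated]), 0.80)
})

test_that("exclusivity classes follow the detection-call definitions", {
  det <- data.table::data.table(
    feature_id = rep(c("excl", "lost", "mid"), each = 3),
    fluid = "serum",
    dose = rep(c(0, 10, 40), 3),
    n_detected = c(0L, 0L, 6L,  6L, 0L, 0L,  5L, 6L, 6L),
    group_size = 6L)
  cls <- classify_exclusivity(det, c(mid = TRUE))
  expect_equal(cls$class[match(c("excl", "lost", "mid"), cls$feature_id)],
               c("exclusive", "lost", "modulated"))
  cls2 <- classify_exclusivity(det)
  expect_equal(cls2$class[cls2$feature_id == "mid"], "null")
})

test_that("cross-fluid regression is exact on identity and null on independence", {
  design <- generate_design(6, c(0, 40))
  set.seed(61)
  n <- 300
  serum_cols <- design$sample[design$fluid == "serum" & design$dose == 40]
  balf_cols <- design$sample[design$fluid == "BALF" & design$dose == 40]
  m <- matrix(rnorm(n * nrow(design), 12), n,
              dimnames = list(sprintf("F%d", 1:n), design$sample))
  # identity: serum == BALF
  m[, serum_cols] <- m[, balf_cols[match(
    design$animal[match(serum_cols, design$sample)],
    design$animal[match(balf_cols, design$sample)])]]
  # exact identity triggers summary.lm's perfect-fit warning by design
  fit <- suppressWarnings(crossfluid_regression(norm_matrix(m, design), design,
                                                rownames(m), 40))
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$slope, 1, tolerance = 1e-9)

  # independence: |R| small at n >= 500 points
  m2 <- matrix(rnorm(n * nrow(design), 12), n,
               dimnames = list(sprintf("F%d", 1:n), design$sample))
  fit2 <- crossfluid_regression(norm_matrix(m2, design), design,
                                rownames(m2), 40)
  expect_gt(fit2$n_points, 500)
  expect_lt(abs(fit2$r), 0.1)

  const <- m2; const[, balf_cols] <- 5
  expect_error(crossfluid_regression(norm_matrix(const, design), design,
                                     rownames(const), 40), "variance")
  expect_error(crossfluid_regression(norm_matrix(m2, design), design,
                                     character(0), 40), "fewer than 3")
})

test_that("differential table is volcano-ready and internally consistent", {
  w <- default_world()
  fil <- reproducibility_filter(cluster_events(w$events), w$design)
  m <- feature_matrix(fil, w$design)
  nm <- normalize_log2(impute_below_lod(m, w$design,
                                        estimate_group_loq(m, w$design),
                                        seed = 71))
  dt <- differential_table(nm, w$design, attr(fil, "detections"), "serum")
  expect_true(all(c("f_stat", "p_value", "q_value", "significant", "class",
                    "log2_fc_10", "log2_fc_40", "neg_log10_p") %in% names(dt)))
  expect_true(all(dt$q_value >= dt$p_value - 1e-12))
  expect_identical(dt$significant, dt$q_value <= 0.05)
  expect_true(all(dt$class %in% c("exclusive", "lost", "modulated", "null")))
  # modulated implies flagged
  expect_true(all(dt$significant[dt$class == "modulated"]))
})
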