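test_that("fold change is the difference of group means of log2 values", {
  m <- toy_matrix(rbind(A = c(26, 27, 28, 22, 23, 24),
                        B = c(20, 21, 22, 20, 21, 22)))
  enr <- compute_enrichment(m)
  expect_equal(enr$log2_fc[enr$group_id == "A"], 4)
  expect_equal(enr$mean_log2_sample[enr$group_id == "A"], 27)
  # identical groups: no fold change, not significant
  expect_equal(enr$log2_fc[enr$group_id == "B"], 0)
  expect_false(enr$significant[enr$group_id == "B"])
})

test_that("p-values match an independent two-sample t computation to 1e-10", {
  # closed-form pooled-variance Student t on the worked six values
  x <- c(26, 27, 28); y <- c(22, 23, 24)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  p_closed <- 2 * pt(-abs(t_stat), df = 4)
  enr <- compute_enrichment(toy_matrix(rbind(A = c(x, y))))
  expect_equal(enr$p_value, p_closed, tolerance = 1e-12)

  # random non-imputed matrices against stats::t.test as the oracle
  set.seed(51)
  for (rep in 1:5) {
    vals <- matrix(rnorm(120, 25, 2), 20, 6)
    enr <- compute_enrichment(toy_matrix(vals))
    p_oracle <- apply(vals, 1, function(v)
      t.test(v[1:3], v[4:6], var.equal = TRUE)$p.value)
    expect_equal(enr$p_value, unname(p_oracle), tolerance = 1e-10)
    expect_equal(enr$neg_log10_p, -log10(enr$p_value))
  }
  # Welch option against t.test(var.equal = FALSE)
  vals <- matrix(rnorm(60, 25, c(1, 4)), 10, 6)
  enr_w <- compute_enrichment(toy_matrix(vals), var_equal = FALSE)
  p_w <- apply(vals, 1, function(v) t.test(v[1:3], v[4:6])$p.value)
  expect_equal(enr_w$p_value, unname(p_w), tolerance = 1e-10)
})

test_that("degenerate all-identical values give p = 1 by convention", {
  enr <- compute_enrichment(toy_matrix(rbind(A = rep(25, 6))))
  expect_equal(enr$p_value, 1)
  expect_equal(enr$log2_fc, 0)
})

test_that("missing cells are rejected before testing", {
  vals <- rbind(A = c(26, 27, NA, 22, 23, 24))
  expect_error(compute_enrichment(toy_matrix(vals)),
               "impute before testing")
})

test_that("enrichment is invariant to row and column order", {
  set.seed(61)
  vals <- matrix(rnorm(120, 25, 2), 20, 6,
                 dimnames = list(paste0("P", 1:20), NULL))
  d <- design_3v3()
  enr <- compute_enrichment(toy_matrix(vals, d))

  rperm <- sample(20); cperm <- sample(6)
  d2 <- sample_design(d$sample_id[cperm], d$group[cperm],
                      d$replicate[cperm])
  enr2 <- compute_enrichment(toy_matrix(vals[rperm, cperm], d2))
  enr2 <- enr2[match(enr$group_id, enr2$group_id), ]
  expect_equal(enr2$log2_fc, enr$log2_fc)
  expect_equal(enr2$p_value, enr$p_value)
})

test_that("significance uses strict thresholds and ordering is stable", {
  m <- toy_matrix(rbind(
    Exact1 = c(25, 26, 27, 24, 25, 26),        # fc exactly 1 -> excluded
    Strong = c(28.0, 28.1, 27.9, 24.0, 24.1, 23.9),
    Weak   = c(25.2, 26.1, 24.9, 24.1, 23.2, 25.0)))
  enr <- compute_enrichment(m)
  expect_equal(enr$log2_fc[1], 1)
  expect_false(enr$significant[1])
  sig <- significant_set(enr)
  expect_equal(sig, "Strong")

  # loosening either threshold never removes a hit
  looser_fc <- significant_set(
    compute_enrichment(m, enrichment_thresholds(min_log2_fc = 0.5)))
  looser_p <- significant_set(
    compute_enrichment(m, enrichment_thresholds(max_p = 0.2)))
  expect_true(all(sig %in% looser_fc))
  expect_true(all(sig %in% looser_p))

  # descending fold change, ties by p then id
  m2 <- toy_matrix(rbind(B = c(30, 31, 32, 24, 25, 26),
                         A = c(30, 31, 32, 24, 25, 26),
                         C = c(33, 34, 35, 24, 25, 26)))
  expect_equal(significant_set(compute_enrichment(m2)),
               c("C", "A", "B"))
})

test_that("intersect_significant is a set intersection in a's order", {
  expect_equal(intersect_significant(c("x", "y"), c("a", "b")),
               character(0))
  expect_equal(intersect_significant(c("x", "y"), c("y", "x")),
               c("x", "y"))
  expect_equal(intersect_significant(c("c", "a", "b"), c("b", "c")),
               c("c", "b"))
})

test_that("volcano and MA tables are pure projections", {
  m <- toy_matrix(rbind(
    A = c(26, 27, 28, 22, 23, 24),
    B = c(20.1, 20.2, 19.9, 20.0, 20.1, 20.3),
    C = c(30, 30.5, 31, 24, 24.5, 25),
    D = c(22, 23, 24, 26, 27, 28),
    E = rep(25, 6)))
  enr <- compute_enrichment(m)
  v <- volcano_table(enr)
  expect_equal(names(v), c("log2_fc", "neg_log10_p", "significant",
                           "label"))
  expect_equal(v$log2_fc, enr$log2_fc)
  expect_equal(v$neg_log10_p, -log10(enr$p_value))
  expect_equal(v$label, enr$group_id)

  a <- ma_table(enr, labels = c(A = "spd-5"))
  expect_equal(a$mean_log2_sample, enr$mean_log2_sample)
  expect_equal(a$log2_fc, enr$log2_fc)
  expect_equal(a$label[1], "spd-5")
  expect_equal(a$label[-1], enr$group_id[-1])

  empty <- compute_enrichment(toy_matrix(matrix(numeric(0), 0, 6)))
  expect_equal(nrow(volcano_table(empty)), 0)
  expect_equal(nrow(ma_table(empty)), 0)
})

test_that("abundant both-group background stays non-significant", {
  sim <- generate_proteome(proteome_sim_config(seed = 8))
  res <- apply_filters(sim$table)
  enr <- compute_enrichment(impute_lod(log_transform(res$table)))
  sig <- significant_set(enr)
  carb <- sim$truth$group_id[sim$truth$class == "carboxylase_like"]
  expect_false(any(carb %in% sig))
})
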