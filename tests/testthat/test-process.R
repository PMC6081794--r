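test_that("VFA fractions are percentages of the sample total", {
  t1 <- rumen_vfa_table1()
  vf <- vfa_fractions(t1)
  # cow 1, t0: acetic 62.4 of total 95.9
  row <- vf$per_sample[t1$cow == "1" & !is.na(t1$timepoint) &
                         t1$timepoint == "t0", ]
  expect_equal(row$acetic_pct, 100 * 62.4 / 95.9, tolerance = 1e-12)
  # per-sample percentages sum to ~100 (printed rounding)
  pct_cols <- paste0(intersect(vfa_acid_columns(), names(t1)), "_pct")
  sums <- rowSums(vf$per_sample[, pct_cols])
  expect_true(all(abs(sums - 100) < 0.5))
  # unit invariance
  t1k <- t1
  acid_cols <- intersect(vfa_acid_columns(), names(t1))
  t1k[, c(acid_cols, "total")] <- t1k[, c(acid_cols, "total")] * 1000
  vfk <- vfa_fractions(t1k)
  expect_equal(vfk$summary$mean_pct, vf$summary$mean_pct, tolerance = 1e-12)
  # single-acid sample
  one <- data.frame(acetic = 5, total = 5)
  expect_equal(vfa_fractions(one)$per_sample$acetic_pct, 100)
  expect_error(vfa_fractions(data.frame(acetic = 0, total = 0)), "total")
})

test_that("pH-VFA correlation matches a closed-form Pearson oracle", {
  # 4-point toy with hand-computable covariance
  toy <- data.frame(total = c(1, 2, 3, 4), ph = c(8, 6, 5, 3))
  r_oracle <- sum((toy$total - 2.5) * (toy$ph - 5.5)) /
    sqrt(sum((toy$total - 2.5)^2) * sum((toy$ph - 5.5)^2))
  res <- ph_vfa_correlation(toy)
  expect_equal(res$coefficient, r_oracle, tolerance = 1e-12)
  expect_equal(res$df, 2)
  # perfect decreasing line
  lin <- data.frame(total = 1:5, ph = 10 - 2 * (1:5))
  expect_equal(ph_vfa_correlation(lin)$coefficient, -1)
  # records lacking pH are excluded
  t1 <- rumen_vfa_table1()
  expect_equal(ph_vfa_correlation(t1)$n, 16)
  expect_error(ph_vfa_correlation(data.frame(total = c(1, 2), ph = c(1, 2))),
               ">= 3")
  expect_error(ph_vfa_correlation(data.frame(total = c(1, 1, 1),
                                             ph = c(1, 2, 3))), "variance")
})

test_that("feeding response folds are window mean ratios", {
  gas <- data.frame(cow = "c1", hour = seq(-1.75, 3, by = 0.25))
  gas$ch4 <- ifelse(gas$hour > 0, 20, 10)   # step doubling at feeding
  gas$co2 <- 100                            # flat
  f <- feeding_response(gas)
  expect_equal(unname(f$mean[["ch4"]]), 2)
  expect_equal(unname(f$mean[["co2"]]), 1)
  expect_error(feeding_response(gas, pre_window = c(-1, 1),
                                post_window = c(0, 1)), "overlap")
  gas$ch4[gas$hour <= 0] <- 0
  expect_error(feeding_response(gas), "zero pre-feeding")
})

test_that("transcript-process correlation matches a rank oracle", {
  tr <- series_df("c1", paste0("t", 1:5), c(3, 1, 4, 1.5, 5))
  pr <- series_df("c1", paste0("t", 1:5), c(30, 9, 35, 14, 60))
  res <- correlate_transcripts_process(tr, pr)
  rho_oracle <- {
    m <- merge(tr, pr, by = c("cow", "timepoint"))
    r1 <- rank(m$value.x); r2 <- rank(m$value.y)
    sum((r1 - mean(r1)) * (r2 - mean(r2))) /
      sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  }
  expect_equal(res$coefficient, rho_oracle, tolerance = 1e-12)
  expect_equal(res$coefficient, 1)  # identical ordering -> rho = 1
  # monotone-transform invariance of Spearman
  pr2 <- pr; pr2$value <- log(pr2$value)
  expect_equal(correlate_transcripts_process(tr, pr2)$coefficient, 1)
  # misalignment is an error
  expect_error(correlate_transcripts_process(tr[-1, ], pr), "misaligned")
})

test_that("paired timepoint tests match a closed-form t oracle", {
  # 4 cows, differences (2, 3, 1, 2) between t1 and t0
  base <- c(10, 12, 9, 11)
  s <- rbind(series_df(paste0("c", 1:4), "t0", base)[c(1, 2, 3, 4), ],
             data.frame(cow = paste0("c", 1:4), timepoint = "t1",
                        value = base + c(2, 3, 1, 2)))
  res <- paired_timepoint_tests(s, timepoints = c("t0", "t1"))
  d <- c(2, 3, 1, 2)
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 3)
  expect_equal(res$t_statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  # shift invariance
  s2 <- s; s2$value <- s2$value + 100
  expect_equal(paired_timepoint_tests(s2, c("t0", "t1"))$p_value, res$p_value)
  # zero-difference degenerate rule
  s3 <- s; s3$value <- rep(base, 2)
  expect_message(r3 <- paired_timepoint_tests(s3, c("t0", "t1")),
                 "zero-variance")
  expect_equal(r3$p_value, 1)
})

test_that("RNA yield growth response is flagged significant t0 to t1", {
  d <- study_design()
  y <- simulate_rna_yields(generator_params(rna_yield_cv = 0.05, seed = 8), d)
  res <- paired_timepoint_tests(
    data.frame(cow = y$cow, timepoint = y$timepoint,
               value = y$micrograms_per_gram))
  r01 <- res[res$from == "t0" & res$to == "t1", ]
  expect_lt(r01$p_value, 0.05)
  expect_true(r01$stars %in% c("*", "**"))
  expect_gt(r01$mean_difference, 0)
})

test_that("function screen recovers a designed ribosomal-protein shift", {
  d <- study_design()
  p <- generator_params(seed = 21, taxon_coupling = FALSE,
                        methylotroph_response = 1)
  com <- simulate_community(p, d)
  fc <- simulate_function_counts(p, d, com)
  # inject a strong t1 up-shift in ribosomal-protein functions
  up <- grepl("^Ribosomal_protein", fc$function_id) & fc$timepoint == "t1"
  fc$reads[up] <- round(fc$reads[up] * 2)
  res <- paired_function_screen(fc, d, c("t0", "t1"))
  hits <- res$function_id[res$significant]
  expect_gt(length(hits), 0)
  expect_gt(mean(grepl("^Ribosomal_protein", hits)), 0.5)
  # all-zero functions are excluded by the filter
  fc2 <- rbind(fc, data.frame(sample = fc$sample[1], cow = fc$cow[1],
                              timepoint = fc$timepoint[1],
                              function_id = "dead_gene",
                              function_system = "seed",
                              taxon = fc$taxon[1], reads = 0))
  res2 <- paired_function_screen(fc2, d, c("t0", "t1"))
  expect_false("dead_gene" %in% res2$function_id)
})
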