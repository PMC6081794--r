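test_that("noise-free community reproduces the cow base composition at every timepoint", {
  d <- toy_design()
  p <- generator_params(within_cow_noise = 0, ssu_subsample_size = 2e6,
                        seed = 11)
  com <- simulate_community(p, d)
  # with no temporal noise, relative abundances at different timepoints of
  # one cow differ only by multinomial sampling of a huge subsample
  rel <- relative_abundance(com, "family")
  for (cow in d$cows) {
    sub <- rel[grepl(cow, rel$sample), ]
    wide <- stats::xtabs(fraction ~ taxon + sample, data = sub)
    spread <- apply(wide, 1, function(x) max(x) - min(x))
    expect_lt(max(spread), 0.005)
  }
})

test_that("default community matches the calibrated domain shares", {
  d <- study_design()
  euk <- arc <- c()
  for (s in 1:4) {
    com <- simulate_community(generator_params(seed = s), d)
    dom <- relative_abundance(com, "domain")
    euk <- c(euk, dom$fraction[dom$taxon == "Eukaryota"])
    arc <- c(arc, dom$fraction[dom$taxon == "Archaea"])
  }
  # within 3 standard errors of the calibrated means
  expect_lt(abs(mean(euk) - 0.251), 3 * sd(euk) / sqrt(length(euk)))
  expect_lt(abs(mean(arc) - 0.003), 3 * sd(arc) / sqrt(length(arc)))
  expect_equal(mean(euk) + mean(arc) +
                 mean(1 - euk - arc), 1, tolerance = 1e-12)
})

test_that("between-cow community distances exceed within-cow distances", {
  d <- toy_design(2)
  hits <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    # strong-separation scenario: high between-cow spread, low drift
    com <- simulate_community(generator_params(cow_individuality = 4,
                                               within_cow_noise = 0.005,
                                               seed = s), d)
    m <- abundance_matrix_for_test(com)
    bc <- bray_curtis(m)
    cows <- sub("_t[0-9]$", "", rownames(m))
    same <- outer(cows, cows, "==") & upper.tri(bc)
    diff <- (!outer(cows, cows, "==")) & upper.tri(bc)
    if (min(bc[diff]) > max(bc[same])) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("RNA yields are exact at zero CV and correctly dispersed otherwise", {
  d <- study_design()
  y0 <- simulate_rna_yields(generator_params(rna_yield_cv = 0), d)
  expect_equal(sort(unique(y0$micrograms_per_gram)),
               sort(c(34.1, 69.2, 70.0, 37.0)))
  expect_true(all(y0$micrograms_per_gram > 0))
  # determinism: same seed, bit-identical
  y1 <- simulate_rna_yields(generator_params(seed = 5), d)
  y2 <- simulate_rna_yields(generator_params(seed = 5), d)
  expect_identical(y1, y2)
  # large-n dispersion check at t0
  big <- study_design(cows = paste0("cow", 1:250))
  yb <- simulate_rna_yields(generator_params(rna_yield_cv = 0.19, seed = 2), big)
  t0 <- yb$micrograms_per_gram[yb$timepoint == "t0"]
  expect_lt(abs(sd(t0) - 34.1 * 0.19), 0.15 * 34.1 * 0.19)
  expect_error(simulate_rna_yields(generator_params(rna_yield_cv = -1)),
               "non-negative")
})

test_that("function counts honour the catalog and its restrictions", {
  d <- toy_design()
  p <- generator_params(seed = 3)
  com <- simulate_community(p, d)
  # catalog restricted to mcrA -> only methanogen-labelled rows
  cat_mcra <- data.frame(function_id = "mcrA", function_system = "gene",
                         taxon = c("Methanobrevibacter",
                                   "Methanomassiliicoccales"),
                         fraction = c(0.6, 0.4), stringsAsFactors = FALSE)
  fc <- simulate_function_counts(p, d, com, catalog = cat_mcra)
  expect_setequal(unique(fc$function_id), "mcrA")
  expect_true(all(fc$taxon %in% c("Methanobrevibacter",
                                  "Methanomassiliicoccales")))
  # unknown taxon label errors
  bad <- data.frame(function_id = "x", function_system = "gene",
                    taxon = "NotATaxon", fraction = 1)
  expect_error(simulate_function_counts(p, d, com, catalog = bad),
               "absent from community")
})

test_that("mean function counts match catalog fractions without taxon coupling", {
  d <- toy_design()
  p0 <- generator_params(taxon_coupling = FALSE, methylotroph_response = 1,
                         seed = 1)
  com <- simulate_community(p0, d)
  catalog <- data.frame(function_id = c("fA", "fB", "fC"),
                        function_system = "seed",
                        taxon = "Prevotellaceae",
                        fraction = c(0.5, 0.3, 0.2), stringsAsFactors = FALSE)
  n_seeds <- 200
  tot <- matrix(0, n_seeds, 3)
  for (s in seq_len(n_seeds)) {
    p <- generator_params(taxon_coupling = FALSE, methylotroph_response = 1,
                          seed = s)
    fc <- simulate_function_counts(p, d, com, catalog = catalog)
    tot[s, ] <- tapply(fc$reads, fc$function_id, sum)[c("fA", "fB", "fC")]
  }
  n_reads <- sum(tot[1, ])
  for (j in 1:3) {
    expected <- n_reads * catalog$fraction[j]
    se <- sd(tot[, j]) / sqrt(n_seeds)
    expect_lt(abs(mean(tot[, j]) - expected), 3 * se + 1e-9)
  }
})

test_that("process series honour their designed couplings", {
  d <- study_design()
  # noise-free pH coupling: exact correlation -1
  p0 <- generator_params(ph_noise = 0, seed = 4)
  pr0 <- simulate_process_series(p0, d)
  expect_equal(cor(pr0$vfa$ph, pr0$vfa$total), -1)
  # H2 confined to the pulse window
  pr <- simulate_process_series(generator_params(seed = 4), d)
  expect_true(all(pr$gas$h2[pr$gas$hour <= 0 | pr$gas$hour > 1] == 0))
  expect_true(all(pr$gas$h2[pr$gas$hour > 0 & pr$gas$hour <= 1] > 0))
  # CH4 feeding fold near the configured 1.9
  f <- feeding_response(pr$gas)
  expect_lt(abs(f$mean[["ch4"]] / 1.9 - 1), 0.1)
  expect_error(simulate_process_series(generator_params(gas_fold_ch4 = -1)),
               ">= 0")
})

test_that("pH noise calibration yields the intended pH-VFA correlation", {
  d <- study_design()
  r <- sapply(1:60, function(s) {
    pr <- simulate_process_series(generator_params(seed = s), d)
    ph_vfa_correlation(pr$vfa)$coefficient
  })
  expect_lt(abs(mean(r) - (-0.84)), 0.05)
})

test_that("the generator is deterministic and substreams are independent", {
  d <- study_design()
  p <- generator_params(seed = 42)
  s1 <- simulate_study(p, d)
  s2 <- simulate_study(p, d)
  for (nm in c("community", "rna_yield", "read_class", "function_counts",
               "vfa", "gas")) {
    expect_identical(s1[[nm]], s2[[nm]])
  }
  # community draw unaffected by whether other tables are generated
  expect_identical(simulate_community(p, d), s1$community)
})

test_that("per-sample counts close to the subsample size", {
  com <- simulate_community(generator_params(seed = 9), study_design())
  sums <- tapply(com$reads, com$sample, sum)
  expect_true(all(sums == 50000))
})
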