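test_that("class fractions follow the policy", {
  rc <- toy_read_class()[1, ]
  fixed <- class_fraction_policy("fixed_ratio")
  obs <- class_fraction_policy("observed")
  expect_equal(class_fraction(fixed, rc, "mRNA"), 0.04)
  expect_equal(class_fraction(obs, rc, "mRNA"), 8000 / 200000)
  # SSU uses the observed share under either mode
  expect_equal(class_fraction(fixed, rc, "SSU-prok"), 80000 / 200000)
  expect_equal(class_fraction(obs, rc, "SSU-euk"), 0.10 * 4)
  rc$mrna_reads <- 0
  expect_equal(class_fraction(obs, rc, "mRNA"), 0)
  rc$total_reads <- 0
  expect_error(class_fraction(obs, rc, "mRNA"), "positive")
})

test_that("single-transcript quantification matches stepwise mass arithmetic", {
  # oracle: 50 ug/g x 0.04 x (100/10000) = 0.02 ug of the transcript, then
  # 0.02 / (330e6 ug/mol x 1000 nt) mol x Avogadro
  mass <- 50 * 0.04 * (100 / 10000)
  oracle <- mass * 6.02214076e23 / (330e6 * 1000)
  expect_equal(quantify_transcript(50, 0.04, 100, 10000, 1000), oracle,
               tolerance = 1e-14)
  expect_equal(oracle, 3.649782e10, tolerance = 1e-6)
  expect_equal(quantify_transcript(50, 0.04, 0, 10000, 1000), 0)
  # unit sanity: all-unit inputs reduce to Avogadro / M(Nt)
  expect_equal(quantify_transcript(1, 1, 1, 1, 1),
               6.02214076e23 / 330e6)
  expect_error(quantify_transcript(50, 0.04, 100, 0, 1000), ">= 1")
  expect_error(quantify_transcript(-1, 0.04, 100, 10000, 1000), "negative")
  expect_error(quantify_transcript(50, 0.04, 101, 100, 1000), "exceed")
})

test_that("vectorized quantification equals a per-record loop oracle", {
  set.seed(101)
  n <- 2000
  yields <- runif(n, 10, 100)
  fractions <- runif(n, 0.01, 0.5)
  subsample <- sample(1000:50000, n, replace = TRUE)
  assigned <- floor(runif(n) * subsample)
  lengths <- sample(c(1000, 1500, 1900), n, replace = TRUE)
  fast <- quantify_transcript(yields, fractions, assigned, subsample, lengths)
  slow <- vapply(seq_len(n), function(i) {
    yields[i] * fractions[i] * (assigned[i] / subsample[i]) *
      6.02214076e23 / (330e6 * lengths[i])
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("table quantification applies the length model per domain", {
  counts <- toy_taxon_counts()
  counts$domain <- c("Bacteria", "Eukaryota", "Bacteria", NA)
  q <- quantify_table(toy_yields(), toy_read_class(), counts)
  expect_equal(q$kind, c("SSU-prok", "SSU-euk", "SSU-prok", "SSU-prok"))
  expect_equal(q$length_defaulted, c(FALSE, FALSE, FALSE, TRUE))
  # single row reproduces quantify_transcript exactly
  expect_equal(q$transcripts_per_gram[1],
               quantify_transcript(50, 80000 / 200000, 30, 100, 1500))
  expect_equal(q$transcripts_per_gram[2],
               quantify_transcript(50, 80000 / 200000, 70, 100, 1900))
  # missing metadata names the sample
  expect_error(quantify_table(toy_yields("s1"), toy_read_class(), counts),
               "s2")
})

test_that("mass is conserved when entities partition the subsample", {
  set.seed(7)
  n_entities <- 50
  reads <- as.vector(rmultinom(1, 100, rep(1, n_entities)))
  counts <- data.frame(
    sample = "s1", cow = "cow1", timepoint = "t0",
    domain = "Bacteria", phylum = NA, class = NA,
    family = paste0("F", seq_len(n_entities)), genus = NA,
    reads = reads, stringsAsFactors = FALSE)
  q <- quantify_table(toy_yields("s1"), toy_read_class("s1"), counts)
  # sum over entities of transcripts x length x M(Nt) / N_A returns the
  # class mass: yield x class fraction
  mass <- sum(q$transcripts_per_gram * 1500 * 330e6 / 6.02214076e23)
  expect_equal(mass, 50 * (80000 / 200000), tolerance = 1e-9)
})

test_that("quantification is linear and scale-invariant in relative terms", {
  counts <- toy_taxon_counts()
  q1 <- quantify_table(toy_yields(ug = 50), toy_read_class(), counts)
  q2 <- quantify_table(toy_yields(ug = 150), toy_read_class(), counts)
  # tripling the yield triples every quantified abundance ...
  expect_equal(q2$transcripts_per_gram, 3 * q1$transcripts_per_gram,
               tolerance = 1e-12)
  # ... and leaves relative abundances unchanged
  rel1 <- q1$transcripts_per_gram / sum(q1$transcripts_per_gram)
  rel2 <- q2$transcripts_per_gram / sum(q2$transcripts_per_gram)
  expect_equal(rel1, rel2, tolerance = 1e-12)
})
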