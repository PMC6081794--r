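test_that("relative abundances close to one and fall back to deeper ranks", {
  counts <- toy_taxon_counts()
  rel <- relative_abundance(counts, "family")
  expect_equal(as.vector(tapply(rel$fraction, rel$sample, sum)), c(1, 1))
  expect_equal(rel$fraction[rel$sample == "s1" & rel$taxon == "RF16"], 0.7)
  # a row unassigned at family level is reported at its class
  counts$family[2] <- NA
  rel2 <- relative_abundance(counts, "family")
  expect_true("Bacteroidia" %in% rel2$taxon[rel2$sample == "s1"])
  expect_equal(rel2$rank[rel2$taxon == "Bacteroidia"][1], "class")
  # single-taxon sample
  one <- counts[1, ]
  expect_equal(relative_abundance(one, "family")$fraction, 1)
  one$reads <- 0
  expect_error(relative_abundance(one, "family"), "empty sample")
})

test_that("core family share counts only family-assigned bacterial reads", {
  counts <- data.frame(
    sample = "s1", cow = "cow1", timepoint = "t0",
    domain = c("Bacteria", "Bacteria", "Bacteria", "Bacteria", "Eukaryota"),
    phylum = "P", class = "C",
    family = c("A", "B", "C", NA, "EukFam"), genus = NA,
    reads = c(50, 30, 20, 100, 500), stringsAsFactors = FALSE)
  share <- core_family_share(relative_abundance(counts, "family"),
                             family_set = c("A", "B"))
  expect_equal(share$mean, 0.80)
  # exhaustive set -> 1
  all_share <- core_family_share(relative_abundance(counts, "family"),
                                 family_set = c("A", "B", "C"))
  expect_equal(all_share$mean, 1)
  expect_error(core_family_share(counts, character()), "non-empty")
})

test_that("block z-scoring standardizes within cows", {
  x <- cbind(v1 = c(1, 2, 3, 10, 20, 30), v2 = c(5, 5, 5, 1, 2, 3))
  blocks <- rep(c("a", "b"), each = 3)
  z <- zscore_by_block(x, blocks)
  expect_equal(z[1:3, "v1"], c(-1, 0, 1))
  expect_equal(z[1:3, "v2"], c(0, 0, 0))          # zero-variance rule
  for (b in c("a", "b")) {
    expect_equal(colMeans(z[blocks == b, ]), c(v1 = 0, v2 = 0),
                 tolerance = 1e-12)
  }
  expect_error(zscore_by_block(x, c("a", rep("b", 5))), ">= 2 samples")
})

test_that("PCA agrees with an eigendecomposition oracle", {
  set.seed(3)
  x <- matrix(rnorm(15), 5, 3)
  p <- pca_profile(x)
  ev <- eigen(stats::cov(x))
  expect_equal(sort(p$explained, decreasing = TRUE),
               ev$values / sum(ev$values), tolerance = 1e-12)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  # scores of duplicated samples are identical
  xd <- rbind(x, x[1, ])
  pd <- pca_profile(xd)
  expect_equal(unname(pd$scores[1, ]), unname(pd$scores[6, ]), tolerance = 1e-12)
  # rank-1 input: PC1 explains everything
  r1 <- pca_profile(outer(1:4, c(1, 2, 3)))
  expect_equal(r1$explained[1], 1, tolerance = 1e-12)
  # sign-invariance to variable reordering
  pr <- pca_profile(x[, c(2, 1, 3)])
  expect_equal(abs(unname(pr$scores)), abs(unname(p$scores)), tolerance = 1e-9)
})

test_that("Bray-Curtis has its defining properties", {
  m <- rbind(a = c(0.6, 0.4), b = c(0.4, 0.6), c = c(0.6, 0.4),
             d = c(1, 0), e = c(0, 1))
  bc <- bray_curtis(m)
  expect_equal(bc["a", "c"], 0)            # identical samples
  expect_equal(bc["d", "e"], 1)            # disjoint supports
  expect_equal(bc["a", "b"], 0.2)          # sum|diff| / sum(sums)
  expect_true(isSymmetric(bc))
  expect_true(all(diag(bc) == 0))
  expect_error(bray_curtis(rbind(c(-1, 2))), "non-negative")
})

test_that("PERMANOVA matches an exhaustive enumeration oracle on 4 samples", {
  # two tight pairs far apart
  x <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5, 5.1))
  d <- as.matrix(dist(x))
  g <- c("A", "A", "B", "B")
  res <- permanova(d, g, exact = TRUE)

  # brute-force oracle: all 4! label orders, F computed from first
  # principles (within-group sum of squared distances)
  f_oracle <- function(d, g) {
    n <- nrow(d)
    ss_t <- sum(d[upper.tri(d)]^2) / n
    ss_w <- 0
    for (gr in unique(g)) {
      i <- which(g == gr)
      ss_w <- ss_w + sum((d[i, i][upper.tri(d[i, i])])^2) / length(i)
    }
    ((ss_t - ss_w) / 1) / (ss_w / (n - 2))
  }
  perms <- expand.grid(i1 = 1:4, i2 = 1:4, i3 = 1:4, i4 = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  f_obs <- f_oracle(d, g)
  f_all <- apply(perms, 1, function(p) f_oracle(d, g[unlist(p)]))
  p_exact <- mean(f_all >= f_obs - 1e-12)
  expect_equal(res$p_value, p_exact)
  expect_equal(res$pseudo_f, f_obs, tolerance = 1e-12)
  # 2 tight pairs: only the 8 permutations preserving the partition give
  # F as large, so p = 8/24
  expect_equal(p_exact, 1 / 3)
})

test_that("PERMANOVA agrees with vegan::adonis2 on R-squared", {
  com <- simulate_community(generator_params(seed = 2), study_design())
  m <- abundance_matrix_for_test(com)
  cows <- sub("_t[0-9]+$", "", rownames(m))
  bc <- bray_curtis(m)
  ours <- permanova(bc, cows, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(bc) ~ cows, permutations = 99)
  expect_equal(ours$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)
  # invariance to sample reordering
  ord <- sample(seq_len(nrow(bc)))
  ours2 <- permanova(bc[ord, ord], cows[ord], n_perm = 99, seed = 1)
  expect_equal(ours2$r_squared, ours$r_squared, tolerance = 1e-12)
})

test_that("PERMANOVA degenerate and reproducibility contracts", {
  bc <- bray_curtis(rbind(c(1, 0), c(0.5, 0.5), c(0, 1)))
  expect_equal(permanova(bc, rep("g", 3))$r_squared, 0)
  r1 <- permanova(bc, c("a", "a", "b"), n_perm = 99, seed = 9)
  r2 <- permanova(bc, c("a", "a", "b"), n_perm = 99, seed = 9)
  expect_identical(r1, r2)
})

test_that("indicator analysis finds a group-exclusive taxon with minimal p", {
  # 2 cows x 2 timepoints; taxon X only at t1
  counts <- cbind(X = c(0, 5, 0, 6), Y = c(5, 5, 6, 4))
  rownames(counts) <- c("c1_t0", "c1_t1", "c2_t0", "c2_t1")
  groups <- c("t0", "t1", "t0", "t1")
  blocks <- c("c1", "c1", "c2", "c2")
  res <- indicator_analysis(counts, groups, blocks, n_perm = 99, seed = 1)
  rx <- res[res$taxon == "X", ]
  expect_equal(rx$best_group, "t1")
  # within-block permutations: 2 per block -> 4 label configurations, only
  # the original (and the double swap giving the mirrored max) reach the
  # observed max; exact oracle below
  # brute-force oracle over the 4 within-block label configurations
  stat <- function(g) max(tapply(counts[, "X"], g, mean))
  obs <- stat(groups)
  cfgs <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3))
  ge <- sum(sapply(cfgs, function(o) stat(groups[o]) >= obs - 1e-12))
  # sampled permutations must estimate the same exceedance probability
  big <- indicator_analysis(counts, groups, blocks, n_perm = 4999, seed = 2)
  expect_lt(abs(big[big$taxon == "X", "p_value"] - ge / 4), 0.03)
})

test_that("indicator analysis skips all-zero taxa and is seed-stable", {
  counts <- cbind(X = c(1, 2, 3, 4), Z = c(0, 0, 0, 0))
  rownames(counts) <- paste0("s", 1:4)
  groups <- c("a", "a", "b", "b")
  expect_message(res <- indicator_analysis(counts, groups, n_perm = 99,
                                           seed = 3), "all-zero")
  expect_false("Z" %in% res$taxon)
  res2 <- suppressMessages(indicator_analysis(counts, groups, n_perm = 99,
                                              seed = 3))
  expect_identical(res, res2)
})
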