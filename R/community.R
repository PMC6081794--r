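#' Per-sample relative abundances at a taxonomic rank
#'
#' Aggregates a taxon count table at the chosen rank. Rows that are not
#' assigned at that rank are reported at their deepest assigned higher
#' rank (so fractions still sum to 1 over the reported labels).
#'
#' @param counts taxon count table (columns `sample`, `domain` ...
#'   `genus`, `reads`).
#' @param level one of "domain", "phylum", "class", "family", "genus".
#' @return data.frame with columns `sample`, `domain`, `taxon`, `rank`
#'   (the rank at which the label is reported) and `fraction`;
#'   per-sample fractions sum to 1. `cow`/`timepoint` are carried along
#'   when present.
#' @export
relative_abundance <- function(counts, level = "family") {
  ranks <- c("domain", "phylum", "class", "family", "genus")
  level <- match.arg(level, ranks)
  assert_columns(counts, c("sample", ranks[seq_len(match(level, ranks))],
                           "reads"), "counts")
  if (any(counts$reads < 0)) stop("read counts must be non-negative")
  use <- ranks[seq_len(match(level, ranks))]
  label <- rep(NA_character_, nrow(counts))
  rank_at <- rep(NA_character_, nrow(counts))
  for (r in rev(use)) {
    idx <- is.na(label) & !is.na(counts[[r]])
    label[idx] <- counts[[r]][idx]
    rank_at[idx] <- r
  }
  label[is.na(label)] <- "unassigned"
  rank_at[is.na(rank_at)] <- "unassigned"

  key <- data.frame(sample = counts$sample, domain = counts$domain,
                    taxon = label, rank = rank_at, stringsAsFactors = FALSE)
  for (col in c("cow", "timepoint")) {
    if (col %in% names(counts)) key[[col]] <- counts[[col]]
  }
  agg <- stats::aggregate(list(reads = counts$reads), by = key, FUN = sum)
  totals <- tapply(agg$reads, agg$sample, sum)
  if (any(totals == 0)) {
    stop("empty sample(s): ", paste(names(totals)[totals == 0], collapse = ", "))
  }
  agg$fraction <- agg$reads / as.vector(totals[agg$sample])
  agg$reads <- NULL
  agg[order(agg$sample, -agg$fraction), , drop = FALSE]
}

#' Share of bacterial family-assigned reads held by a family set
#'
#' Computes, per sample, the share of bacterial SSU rRNA reads assigned at
#' the family level that fall into a named family set (e.g. the nine core
#' rumen families), plus the mean share across samples.
#'
#' @param rel output of [relative_abundance()] at `level = "family"` (or
#'   a taxon count table, which is aggregated first).
#' @param family_set non-empty character vector of family names.
#' @return list with `per_sample` (data.frame: sample, share) and `mean`
#'   (unweighted mean share across samples).
#' @export
core_family_share <- function(rel, family_set = core_rumen_families()) {
  if (length(family_set) == 0) stop("family_set must be non-empty")
  if ("reads" %in% names(rel)) rel <- relative_abundance(rel, "family")
  assert_columns(rel, c("sample", "domain", "taxon", "rank", "fraction"), "rel")
  bac <- rel[!is.na(rel$domain) & rel$domain == "Bacteria" &
               rel$rank == "family", , drop = FALSE]
  if (nrow(bac) == 0) stop("no family-assigned bacterial reads")
  per <- sapply(split(bac, bac$sample), function(b) {
    denom <- sum(b$fraction)
    if (denom == 0) return(NA_real_)
    sum(b$fraction[b$taxon %in% family_set]) / denom
  })
  list(per_sample = data.frame(sample = names(per), share = as.vector(per),
                               stringsAsFactors = FALSE),
       mean = mean(per, na.rm = TRUE))
}

#' Standardize a matrix within blocks (per-cow z-scoring)
#'
#' Centers and scales every column to mean 0 and sample SD 1 within each
#' block of rows (typically one block per cow), so dimensionally
#' heterogeneous metadata become comparable while cow-level offsets are
#' removed. Zero-variance variables map to all zeros within their block.
#'
#' @param x numeric matrix or data.frame (samples x variables).
#' @param blocks block label per row (e.g. cow identifiers).
#' @return numeric matrix of the same shape.
#' @export
zscore_by_block <- function(x, blocks) {
  x <- as.matrix(x)
  if (length(blocks) != nrow(x)) stop("one block label per row required")
  sizes <- table(blocks)
  if (any(sizes < 2)) {
    stop("every block needs >= 2 samples; offending block(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  out <- x
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    sub <- x[idx, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    z <- sweep(sub, 2, mu, "-")
    nz <- sdv > 0
    z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
    z[, !nz] <- 0
    out[idx, ] <- z
  }
  out
}

#' Principal component analysis of a profile matrix
#'
#' Thin wrapper around [stats::prcomp()] (centered, unscaled) returning
#' scores, loadings and explained-variance fractions.
#'
#' @param x numeric matrix (samples x variables), typically the per-cow
#'   z-scored, library-size-normalized profile matrix.
#' @return list with `scores` (samples x components), `loadings`
#'   (variables x components) and `explained` (variance fractions, summing
#'   to 1 over the full rank).
#' @export
pca_profile <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("PCA needs >= 2 samples and >= 2 variables")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  list(scores = p$x, loadings = p$rotation, explained = ev / sum(ev))
}

#' Bray-Curtis dissimilarity matrix
#'
#' Abundance-based community distance in [0,1] for closed compositions,
#' computed with [vegan::vegdist()].
#'
#' @param x non-negative matrix (samples x taxa), counts or relative
#'   abundances.
#' @return symmetric numeric distance matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis requires non-negative abundances")
  as.matrix(vegan::vegdist(x, method = "bray"))
}

# Long relative-abundance table -> samples x taxa matrix.
abundance_matrix <- function(rel) {
  assert_columns(rel, c("sample", "taxon", "fraction"), "rel")
  as.matrix(unclass(stats::xtabs(fraction ~ sample + taxon, data = rel)))
}

permanova_f <- function(d2, grouping) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  a <- length(unique(grouping))
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(r_squared = ss_between / ss_total, pseudo_f = f)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the sum of squares of a distance matrix by a single grouping
#' factor (Gower-centered partition, equivalent to the within/between
#' decomposition of squared distances) and tests the pseudo-F statistic by
#' free permutation of sample labels. The p-value is
#' `(1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' @param dist symmetric distance matrix (or `dist` object).
#' @param grouping factor-like grouping covering all samples.
#' @param n_perm number of permutations (>= 99); ignored when
#'   `exact = TRUE`.
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all label permutations (feasible up to ~8
#'   samples) and report the exact permutation p (the identity
#'   permutation is part of the reference set, so p >= 1/n!).
#' @return object of class `permanova_result`: list with `r_squared`,
#'   `pseudo_f`, `p_value`, `n_permutations`.
#' @export
permanova <- function(dist, grouping, n_perm = 999, seed = 1, exact = FALSE) {
  d <- as.matrix(dist)
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(d)) stop("grouping must cover all samples")
  if (!exact && n_perm < 99) stop("use at least 99 permutations")
  sizes <- table(grouping)
  if (any(sizes == 0)) stop("empty group")
  d2 <- d^2
  if (length(unique(grouping)) == 1) {
    return(structure(list(r_squared = 0, pseudo_f = NA_real_, p_value = 1,
                          n_permutations = 0L), class = "permanova_result"))
  }
  obs <- permanova_f(d2, grouping)
  if (exact) {
    if (length(grouping) > 8) stop("exact enumeration feasible only for <= 8 samples")
    perms <- all_permutations(length(grouping))
    perm_f <- vapply(seq_len(ncol(perms)), function(i) {
      permanova_f(d2, grouping[perms[, i]])[["pseudo_f"]]
    }, numeric(1))
    n_perm <- ncol(perms)
    p <- sum(perm_f >= obs[["pseudo_f"]] - 1e-12) / n_perm
  } else {
    perm_f <- with_substream(seed, "permanova", {
      vapply(seq_len(n_perm), function(i) {
        permanova_f(d2, sample(grouping))[["pseudo_f"]]
      }, numeric(1))
    })
    p <- (1 + sum(perm_f >= obs[["pseudo_f"]])) / (1 + n_perm)
  }
  structure(list(r_squared = unname(obs[["r_squared"]]),
                 pseudo_f = unname(obs[["pseudo_f"]]),
                 p_value = p, n_permutations = as.integer(n_perm)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.3f, pseudo-F = %.2f, p = %.4g (%d permutations)\n",
              x$r_squared, x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}

#' Indicator analysis of taxa against a sample grouping
#'
#' For every taxon, the association statistic is its mean abundance in the
#' best group (the group where the taxon's mean abundance is maximal).
#' Significance is assessed by permuting group labels within blocks
#' (cows), respecting the paired longitudinal design, with the same
#' max-over-groups statistic recomputed on each permutation; p-values are
#' `(1 + #perm >= obs) / (1 + n_perm)` and corrected across taxa by the
#' Sidak formula (default) or Benjamini-Hochberg.
#'
#' @param counts matrix (samples x taxa) of counts or relative
#'   abundances, with row names identifying samples.
#' @param groups group label per sample (e.g. timepoints).
#' @param blocks block label per sample (e.g. cows); labels are permuted
#'   within blocks. `NULL` for free permutation.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param correction "sidak" or "bh".
#' @return data.frame with columns `taxon`, `best_group`, `statistic`,
#'   `p_value`, `p_adjusted`, sorted by adjusted p. All-zero taxa are
#'   skipped with a message.
#' @export
indicator_analysis <- function(counts, groups, blocks = NULL, n_perm = 999,
                               seed = 1, correction = c("sidak", "bh")) {
  correction <- match.arg(correction)
  x <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) stop("one group label per sample required")
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  if (n_perm < 99) stop("use at least 99 permutations")
  keep <- colSums(x) > 0
  if (any(!keep)) {
    message(sum(!keep), " all-zero taxa skipped")
    x <- x[, keep, drop = FALSE]
  }
  if (is.null(blocks)) blocks <- rep("all", nrow(x))
  blocks <- as.character(blocks)

  group_means <- function(g) {
    # groups x taxa matrix of mean abundances
    rowsum(x, g) / as.vector(table(g)[sort(unique(g))])
  }
  obs_gm <- group_means(groups)
  obs_stat <- apply(obs_gm, 2, max)
  best <- rownames(obs_gm)[apply(obs_gm, 2, which.max)]

  ge <- with_substream(seed, "indicator", {
    counts_ge <- numeric(ncol(x))
    idx_by_block <- split(seq_len(nrow(x)), blocks)
    for (i in seq_len(n_perm)) {
      g <- groups
      for (idx in idx_by_block) g[idx] <- g[idx][sample(length(idx))]
      perm_stat <- apply(group_means(g), 2, max)
      counts_ge <- counts_ge + (perm_stat >= obs_stat - 1e-12)
    }
    counts_ge
  })
  p <- (1 + ge) / (1 + n_perm)
  p_adj <- if (correction == "sidak") {
    pmin(1, 1 - (1 - p)^ncol(x))
  } else {
    stats::p.adjust(p, method = "BH")
  }
  out <- data.frame(taxon = colnames(x), best_group = best,
                    statistic = unname(obs_stat), p_value = unname(p),
                    p_adjusted = unname(p_adj), stringsAsFactors = FALSE)
  out[order(out$p_adjusted, out$p_value), , drop = FALSE]
}
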