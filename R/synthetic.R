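#' Generator parameters for a synthetic feeding trial
#'
#' Bundles every tunable of the synthetic-data generator. Defaults encode
#' the marginal summaries of the emulated feeding trial: mean domain shares
#' of (25.1, 74.6, 0.3)% for (eukaryotes, bacteria, archaea); 50,000-read
#' SSU subsamples; total RNA yields of 34.1, 69.2, 70.0 and 37.0 ug per g
#' rumen fluid at t0/t1/t3/t5; major VFA fractions (acetate, propionate,
#' butyrate, minor acids) of (60.4, 21.9, 11.6, 6.1)% peaking at t3;
#' post-feeding CH4 and CO2 fold increases of 1.9 and 1.5; an H2 pulse
#' confined to the first hour after feeding; and an mRNA/total-RNA read
#' ratio of 1:25.
#'
#' @param domain_mean_fractions named numeric (eukaryote, bacteria,
#'   archaea) mean proportions, summing to 1.
#' @param cow_individuality Dirichlet concentration controlling
#'   between-cow compositional spread; 16 gives a between-cow SD of the
#'   eukaryote share of about 0.105, matching the emulated trial.
#' @param within_cow_noise dispersion of per-timepoint composition around
#'   the cow base (per-timepoint profiles are Dirichlet with concentration
#'   `base/within_cow_noise`); 0 means temporally constant composition.
#'   The default 0.025 makes cow identity explain roughly 64% of
#'   Bray-Curtis community variation in a 4x4 design.
#' @param ssu_subsample_size SSU rRNA reads drawn per sample.
#' @param rna_yield_means named numeric, ug total RNA per g rumen fluid at
#'   each timepoint.
#' @param rna_yield_cv coefficient of variation of per-sample yields
#'   (log-normal noise).
#' @param vfa_mean_fractions named numeric (acetate, propionate, butyrate,
#'   minor) mean fractions of total VFA, summing to 1.
#' @param vfa_peak_timepoint timepoint label at which total VFA peaks.
#' @param vfa_total_mean,vfa_total_cv mean and between-cow CV of the
#'   pre-feeding total VFA concentration (nmol per g rumen fluid).
#' @param ph_intercept,ph_slope,ph_noise linear pH = intercept +
#'   slope * totalVFA + Gaussian noise coupling (fitted once from the
#'   packaged VFA table; noise SD 0.12 reproduces a 16-sample Pearson
#'   correlation of about -0.84).
#' @param gas_fold_ch4,gas_fold_co2 post-feeding fold increases of CH4 and
#'   CO2 emission rates.
#' @param gas_noise_cv multiplicative noise CV on gas rates.
#' @param h2_pulse_duration_h hours after feeding start during which H2 is
#'   detectable.
#' @param mrna_total_ratio mRNA/total RNA read ratio (class-fraction
#'   default 1/25).
#' @param total_reads,mrna_subsample_size sequencing depth per sample and
#'   the mRNA subsample used for functional annotation.
#' @param methylotroph_response fold increase of methylamine/methanol
#'   methyltransferase expression (mtMA, Methanosphaera mtaB) at the
#'   post-feeding timepoints t1/t3; Methanomassiliicoccales mtaB moves
#'   inversely. 1 = constant relative activity.
#' @param taxon_coupling couple per-sample function-count expectations to
#'   the sample's realized taxon abundances (cow individuality propagates
#'   into the functional tables). FALSE gives catalog fractions exactly.
#' @param seed integer; fully determines all generator output.
#' @return object of class `generator_params` (a validated list).
#' @export
generator_params <- function(domain_mean_fractions = c(eukaryote = 0.251,
                                                       bacteria = 0.746,
                                                       archaea = 0.003),
                             cow_individuality = 16,
                             within_cow_noise = 0.025,
                             ssu_subsample_size = 50000,
                             rna_yield_means = c(t0 = 34.1, t1 = 69.2,
                                                 t3 = 70.0, t5 = 37.0),
                             rna_yield_cv = 0.18,
                             vfa_mean_fractions = c(acetate = 0.604,
                                                    propionate = 0.219,
                                                    butyrate = 0.116,
                                                    minor = 0.061),
                             vfa_peak_timepoint = "t3",
                             vfa_total_mean = 92,
                             vfa_total_cv = 0.07,
                             ph_intercept = 8.15,
                             ph_slope = -0.0167,
                             ph_noise = 0.12,
                             gas_fold_ch4 = 1.9,
                             gas_fold_co2 = 1.5,
                             gas_noise_cv = 0.03,
                             h2_pulse_duration_h = 1,
                             mrna_total_ratio = 1 / 25,
                             total_reads = 2e6,
                             mrna_subsample_size = 20000,
                             methylotroph_response = 2,
                             taxon_coupling = TRUE,
                             seed = 1) {
  check_simplex <- function(x, what) {
    if (any(x < 0) || any(x > 1) || abs(sum(x) - 1) > 1e-8) {
      stop(sprintf("%s must lie in [0,1] and sum to 1", what))
    }
  }
  check_simplex(domain_mean_fractions, "domain_mean_fractions")
  check_simplex(vfa_mean_fractions, "vfa_mean_fractions")
  if (ssu_subsample_size < 1) stop("ssu_subsample_size must be >= 1")
  if (any(rna_yield_means <= 0)) stop("RNA yields must be positive")
  if (rna_yield_cv < 0) stop("rna_yield_cv must be non-negative")
  if (gas_fold_ch4 < 0 || gas_fold_co2 < 0) stop("gas fold factors must be >= 0")
  if (mrna_total_ratio <= 0 || mrna_total_ratio >= 1) {
    stop("mrna_total_ratio must lie in (0,1)")
  }
  if (within_cow_noise < 0) stop("within_cow_noise must be >= 0")
  structure(as.list(environment())[names(formals(generator_params))],
            class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf(paste0("generator_params: %d SSU reads/sample, domain means ",
                     "(%.3f, %.3f, %.3f), seed %d\n"),
              x$ssu_subsample_size, x$domain_mean_fractions[1],
              x$domain_mean_fractions[2], x$domain_mean_fractions[3],
              as.integer(x$seed)))
  invisible(x)
}

# Rescale the taxon catalog so its per-domain totals match the requested
# domain mean fractions.
scale_catalog_domains <- function(catalog, domain_fractions) {
  key <- c(Eukaryota = "eukaryote", Bacteria = "bacteria", Archaea = "archaea")
  for (d in names(key)) {
    idx <- catalog$domain == d
    tot <- sum(catalog$fraction[idx])
    if (tot > 0) {
      catalog$fraction[idx] <- catalog$fraction[idx] / tot *
        domain_fractions[[key[[d]]]]
    }
  }
  catalog$fraction <- catalog$fraction / sum(catalog$fraction)
  catalog
}

#' Simulate SSU rRNA community count tables
#'
#' Hierarchical compositional model. Per cow, a latent base composition is
#' drawn in two levels: the eukaryote/bacteria split from a Beta
#' distribution with concentration `cow_individuality` (between-cow SD of
#' the eukaryote share about 0.105 at the default 16), the small archaeal
#' share from a much tighter Beta (concentration 3000, matching the tight
#' 0.3 +- 0.1% archaeal share across animals), and within-domain taxon
#' proportions from a Dirichlet with concentration
#' `3 * cow_individuality` around the catalog's within-domain means (the
#' higher concentration keeps rare community members such as the
#' methanogen genera present in every cow). Per timepoint, the cow's
#' domain structure is held fixed and the within-domain compositions are
#' perturbed by a Dirichlet draw with concentration
#' `base/within_cow_noise` (temporally stable communities whose residual
#' drift sits at the family level, not the domain level). Finally
#' `ssu_subsample_size` reads are drawn from a multinomial per sample.
#'
#' @param params [generator_params()].
#' @param design [study_design()].
#' @param catalog taxon catalog data.frame (default
#'   [default_taxon_catalog()]) with columns `domain` ... `genus` and
#'   `fraction`.
#' @return data.frame (taxon count table) with columns `sample`, `cow`,
#'   `timepoint`, `domain`, `phylum`, `class`, `family`, `genus`, `reads`;
#'   per-sample reads sum to `ssu_subsample_size`.
#' @export
simulate_community <- function(params, design = study_design(),
                               catalog = default_taxon_catalog()) {
  stopifnot(inherits(params, "generator_params"), is_study_design(design))
  if (nrow(catalog) == 0) stop("empty taxon catalog")
  if (params$ssu_subsample_size < 1) stop("non-positive subsample size")
  catalog <- scale_catalog_domains(catalog, params$domain_mean_fractions)
  dom_of <- catalog$domain
  domains <- unique(dom_of)
  dom_means <- vapply(domains, function(d) sum(catalog$fraction[dom_of == d]),
                      numeric(1))
  # the archaeal share is small but tight across animals (relative SD of
  # about a third), so it gets its own concentration; the eukaryote/
  # bacteria split carries the cow individuality
  archaea_stability <- 3000
  canonical <- setequal(domains, c("Eukaryota", "Bacteria", "Archaea"))
  draw_domains <- function() {
    if (!canonical) {
      return(rdirichlet1(dom_means * params$cow_individuality))
    }
    p_a <- dom_means[["Archaea"]]
    arc <- if (p_a == 0) 0 else
      stats::rbeta(1, p_a * archaea_stability, (1 - p_a) * archaea_stability)
    euk_rel <- dom_means[["Eukaryota"]] / (1 - p_a)
    euk <- (1 - arc) * stats::rbeta(1, euk_rel * params$cow_individuality,
                                    (1 - euk_rel) * params$cow_individuality)
    c(Eukaryota = euk, Bacteria = 1 - arc - euk, Archaea = arc)
  }
  with_substream(params$seed, "community", {
    base <- lapply(design$cows, function(cow) {
      dom <- draw_domains()
      p <- numeric(nrow(catalog))
      for (d in domains) {
        idx <- dom_of == d
        within <- catalog$fraction[idx] / sum(catalog$fraction[idx])
        p[idx] <- dom[[d]] * rdirichlet1(within * 3 * params$cow_individuality)
      }
      p
    })
    names(base) <- design$cows
    out <- lapply(seq_len(nrow(design$samples)), function(i) {
      s <- design$samples[i, ]
      p <- base[[s$cow]]
      if (params$within_cow_noise > 0) {
        # domain structure stays at the cow base; families drift
        for (d in domains) {
          idx <- dom_of == d
          within <- p[idx] / sum(p[idx])
          p[idx] <- sum(base[[s$cow]][idx]) *
            rdirichlet1(within / params$within_cow_noise)
        }
      }
      reads <- as.vector(stats::rmultinom(1, params$ssu_subsample_size, p))
      data.frame(sample = s$sample, cow = s$cow, timepoint = s$timepoint,
                 catalog[, c("domain", "phylum", "class", "family", "genus")],
                 reads = reads, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-sample total RNA yields
#'
#' Log-normal draws around the per-timepoint mean yields with coefficient
#' of variation `rna_yield_cv`; strictly positive by construction.
#'
#' @inheritParams simulate_community
#' @return data.frame with columns `sample`, `cow`, `timepoint`,
#'   `micrograms_per_gram`.
#' @export
simulate_rna_yields <- function(params, design = study_design()) {
  stopifnot(inherits(params, "generator_params"), is_study_design(design))
  if (params$rna_yield_cv < 0) stop("negative CV")
  means <- params$rna_yield_means[design$samples$timepoint]
  if (anyNA(means)) stop("rna_yield_means must name every design timepoint")
  with_substream(params$seed, "rna_yield", {
    y <- rlnorm_mean_cv(nrow(design$samples), unname(means), params$rna_yield_cv)
    data.frame(design$samples[, c("sample", "cow", "timepoint")],
               micrograms_per_gram = y, stringsAsFactors = FALSE)
  })
}

#' Simulate per-sample read-class totals
#'
#' Emulates the sequencing bookkeeping: total reads, SSU/LSU rRNA and mRNA
#' read counts (mRNA consistent with `mrna_total_ratio`), and the SSU and
#' mRNA subsample sizes used for classification and annotation.
#'
#' @inheritParams simulate_community
#' @return data.frame with columns `sample`, `total_reads`, `ssu_reads`,
#'   `lsu_reads`, `mrna_reads`, `ssu_subsample_size`,
#'   `mrna_subsample_size`.
#' @export
simulate_read_class <- function(params, design = study_design()) {
  stopifnot(inherits(params, "generator_params"), is_study_design(design))
  n <- nrow(design$samples)
  total <- rep_len(round(params$total_reads), n)
  mrna <- round(total * params$mrna_total_ratio)
  ssu <- round(total * 0.40)
  lsu <- round(total * 0.35)
  data.frame(sample = design$samples$sample, total_reads = total,
             ssu_reads = ssu, lsu_reads = lsu, mrna_reads = mrna,
             ssu_subsample_size = rep_len(params$ssu_subsample_size, n),
             mrna_subsample_size = pmin(rep_len(params$mrna_subsample_size, n),
                                        mrna),
             stringsAsFactors = FALSE)
}

# Relative abundance of a (possibly higher-rank) taxon label within one
# sample's community rows; matches the label against every rank column.
taxon_label_weight <- function(community, label) {
  hit <- community$domain == label | community$phylum == label |
    community$class == label | community$family == label |
    community$genus == label
  hit[is.na(hit)] <- FALSE
  sum(community$reads[hit]) / sum(community$reads)
}

#' Simulate functionally annotated mRNA count tables
#'
#' Draws `mrna_subsample_size` annotated mRNA reads per sample from a
#' multinomial over a (function, taxon) catalog containing CAZyme Pfam
#' accessions, VFA-pathway EC numbers, methanogenesis marker genes and
#' generic housekeeping functions. With `taxon_coupling = TRUE` the
#' expected share of each catalog row is weighted by the sample's realized
#' abundance of the producing taxon, so cow-individual communities yield
#' cow-individual functional profiles. `methylotroph_response` modulates
#' the methyl-reducing methanogen genes at the post-feeding timepoints.
#'
#' @inheritParams simulate_community
#' @param community taxon count table from [simulate_community()],
#'   covering every design sample.
#' @param catalog function catalog data.frame with columns `function_id`,
#'   `function_system`, `taxon`, `fraction` (default: built-in synthetic
#'   catalog).
#' @return data.frame (function count table) with columns `sample`, `cow`,
#'   `timepoint`, `function_id`, `function_system`, `taxon`, `reads`.
#' @export
simulate_function_counts <- function(params, design = study_design(),
                                     community = NULL, catalog = NULL) {
  stopifnot(inherits(params, "generator_params"), is_study_design(design))
  if (is.null(community)) community <- simulate_community(params, design)
  catalog <- catalog %||% default_function_catalog()
  assert_columns(catalog, c("function_id", "function_system", "taxon", "fraction"),
                 "function catalog")
  missing_samples <- setdiff(design$samples$sample, unique(community$sample))
  if (length(missing_samples) > 0) {
    stop("community table lacks sample(s): ",
         paste(missing_samples, collapse = ", "))
  }
  ranks <- c("domain", "phylum", "class", "family", "genus")
  known <- unique(stats::na.omit(unlist(community[ranks])))
  unknown <- setdiff(unique(catalog$taxon), known)
  if (length(unknown) > 0) {
    stop("function catalog taxon label(s) absent from community catalog: ",
         paste(unknown, collapse = ", "))
  }

  # mean catalog-taxon weight across samples, used to normalize coupling
  # multipliers so that expected fractions stay near the catalog values
  taxa <- unique(catalog$taxon)
  by_sample <- split(community, community$sample)
  w_by_sample <- matrix(
    unlist(lapply(by_sample, function(cs) {
      vapply(taxa, function(t) taxon_label_weight(cs, t), numeric(1))
    })),
    nrow = length(taxa), dimnames = list(taxa, names(by_sample)))
  w_mean <- rowMeans(w_by_sample)

  methyl_up <- (catalog$function_system == "gene" &
                  (catalog$function_id %in% c("mtmB", "mtbB", "mttB") |
                     (catalog$function_id == "mtaB" &
                        catalog$taxon == "Methanosphaera")))
  methyl_down <- (catalog$function_system == "gene" &
                    catalog$function_id == "mtaB" &
                    catalog$taxon == "Methanomassiliicoccales")

  with_substream(params$seed, "function_counts", {
    out <- lapply(seq_len(nrow(design$samples)), function(i) {
      s <- design$samples[i, ]
      w <- catalog$fraction
      if (isTRUE(params$taxon_coupling)) {
        # smoothed multiplier: taxa below the SSU detection limit keep a
        # baseline activity instead of dropping out of the mRNA pool
        eps <- 1e-4
        mult <- ((w_by_sample[, s$sample] + eps) / (w_mean + eps))[catalog$taxon]
        mult[!is.finite(mult)] <- 0
        w <- w * mult
      }
      if (s$hour > 0 && s$hour <= 4) {   # post-feeding response window
        w[methyl_up] <- w[methyl_up] * params$methylotroph_response
        w[methyl_down] <- w[methyl_down] / params$methylotroph_response
      }
      n_reads <- min(params$mrna_subsample_size,
                     round(params$total_reads * params$mrna_total_ratio))
      reads <- as.vector(stats::rmultinom(1, n_reads, w / sum(w)))
      data.frame(sample = s$sample, cow = s$cow, timepoint = s$timepoint,
                 catalog[, c("function_id", "function_system", "taxon")],
                 reads = reads, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate VFA, pH and gas-emission process series
#'
#' Total VFA per cow follows a log-normal between-cow base with a diurnal
#' shape peaking at `vfa_peak_timepoint`; per-acid concentrations follow a
#' Dirichlet draw around `vfa_mean_fractions` (acetate, propionate,
#' butyrate, and a fixed split of minor acids). pH is a decreasing linear
#' function of total VFA plus Gaussian noise. CH4 and CO2 rates step up
#' `gas_fold_ch4`/`gas_fold_co2`-fold during the first hour after feeding
#' and decay back to baseline by 5 h; H2 is a rectangular pulse confined
#' to `h2_pulse_duration_h` after feeding start.
#'
#' @inheritParams simulate_community
#' @return list with elements `vfa` (data.frame: cow, timepoint, hour, one
#'   column per acid, total, ph) and `gas` (data.frame: cow, hour, ch4,
#'   co2, h2; hour is relative to feeding start).
#' @export
simulate_process_series <- function(params, design = study_design()) {
  stopifnot(inherits(params, "generator_params"), is_study_design(design))
  if (params$gas_fold_ch4 < 0 || params$gas_fold_co2 < 0) {
    stop("gas fold factors must be >= 0")
  }
  tp <- names(design$timepoints)
  if (!params$vfa_peak_timepoint %in% tp) {
    stop("vfa_peak_timepoint must be one of the design timepoints")
  }
  # diurnal shape: 1 before feeding, rising to a peak, relaxing afterwards
  hours <- design$timepoints
  peak_h <- hours[[params$vfa_peak_timepoint]]
  shape <- ifelse(hours <= 0, 1,
                  ifelse(hours <= peak_h, 1 + 0.15 * hours / peak_h,
                         pmax(0.92, 1.15 - 0.10 * (hours - peak_h))))
  names(shape) <- tp

  minor_split <- c(formic = 0.005, iso_butyric = 0.14, iso_valeric = 0.08,
                   valeric = 0.33, caproic = 0.075, heptanoic = 0.01,
                   lactic = 0.33, succinic = 0.03)
  minor_split <- minor_split / sum(minor_split)

  with_substream(params$seed, "process", {
    base_total <- rlnorm_mean_cv(length(design$cows), params$vfa_total_mean,
                                 params$vfa_total_cv)
    names(base_total) <- design$cows
    vfa <- lapply(seq_len(nrow(design$samples)), function(i) {
      s <- design$samples[i, ]
      total <- base_total[[s$cow]] * shape[[s$timepoint]] *
        rlnorm_mean_cv(1, 1, 0.04)
      fr <- rdirichlet1(params$vfa_mean_fractions * 150)
      acids <- c(acetic = fr[["acetate"]], propionic = fr[["propionate"]],
                 butyric = fr[["butyrate"]], fr[["minor"]] * minor_split)
      ph <- params$ph_intercept + params$ph_slope * total +
        stats::rnorm(1, 0, params$ph_noise)
      data.frame(cow = s$cow, timepoint = s$timepoint, hour = s$hour,
                 as.list(acids * total), total = total, ph = ph,
                 stringsAsFactors = FALSE, check.names = FALSE)
    })
    vfa <- do.call(rbind, vfa)
    rownames(vfa) <- NULL

    grid <- seq(-2, 8, by = 0.25)
    resp <- function(h) {
      ifelse(h <= 0, 0, ifelse(h <= 1, 1, pmax(0, (5 - h) / 4)))
    }
    gas <- lapply(design$cows, function(cow) {
      base_ch4 <- rlnorm_mean_cv(1, 14, 0.10)   # liters per hour
      base_co2 <- rlnorm_mean_cv(1, 140, 0.10)
      noise <- function(n) rlnorm_mean_cv(n, 1, params$gas_noise_cv)
      data.frame(cow = cow, hour = grid,
                 ch4 = base_ch4 * (1 + (params$gas_fold_ch4 - 1) * resp(grid)) *
                   noise(length(grid)),
                 co2 = base_co2 * (1 + (params$gas_fold_co2 - 1) * resp(grid)) *
                   noise(length(grid)),
                 h2 = ifelse(grid > 0 & grid <= params$h2_pulse_duration_h,
                             0.5 * noise(length(grid)), 0),
                 stringsAsFactors = FALSE)
    })
    gas <- do.call(rbind, gas)
    rownames(gas) <- NULL
    list(vfa = vfa, gas = gas)
  })
}

#' Simulate a complete synthetic feeding-trial dataset
#'
#' One-stop generator: community counts, RNA yields, read-class totals,
#' function counts, and process (VFA/pH/gas) series, all driven by the
#' single seed in `params` through independent named substreams.
#'
#' @inheritParams simulate_community
#' @return named list with elements `design`, `params`, `community`,
#'   `rna_yield`, `read_class`, `function_counts`, `vfa`, `gas`.
#' @export
simulate_study <- function(params = generator_params(),
                           design = study_design()) {
  community <- simulate_community(params, design)
  proc <- simulate_process_series(params, design)
  list(design = design, params = params,
       community = community,
       rna_yield = simulate_rna_yields(params, design),
       read_class = simulate_read_class(params, design),
       function_counts = simulate_function_counts(params, design, community),
       vfa = proc$vfa, gas = proc$gas)
}
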