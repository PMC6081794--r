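# Default catalogs: the synthetic taxon catalog driving the community
# generator, the synthetic function catalog driving the mRNA generator, and
# loaders for the editable CAZyme-category and VFA-pathway TSV resources.

#' Default synthetic taxon catalog
#'
#' A synthetic catalog of rumen taxa with mean relative SSU rRNA fractions.
#' The marginals are calibrated to the printed community summaries of the
#' underlying feeding trial: domain shares of roughly 25.1% eukaryotes,
#' 74.5% bacteria and 0.3% archaea; nine core bacterial families holding
#' about 92.3% of the family-assigned bacterial reads; a ciliate-dominated
#' eukaryote community; and a methanogen community split between
#' Methanomassiliicoccales and Methanobacteriaceae (Methanobrevibacter,
#' Methanosphaera). Ranks are reporting labels, not a strict Linnean
#' hierarchy: order-level names (e.g. Clostridiales) appear in the class
#' column where the field reports at that level. `NA` marks ranks without
#' an assignment.
#'
#' @return data.frame with columns `domain`, `phylum`, `class`, `family`,
#'   `genus`, `fraction`; fractions sum to 1.
#' @export
default_taxon_catalog <- function() {
  tx <- function(domain, phylum, class, family, genus, fraction) {
    data.frame(domain = domain, phylum = phylum, class = class,
               family = family, genus = genus, fraction = fraction,
               stringsAsFactors = FALSE)
  }
  cat <- rbind(
    # eukaryotes: 0.251
    tx("Eukaryota", "Ciliophora", "Litostomatea", "Ophryoscolecidae", "Entodinium", 0.090),
    tx("Eukaryota", "Ciliophora", "Litostomatea", "Ophryoscolecidae", "Epidinium", 0.045),
    tx("Eukaryota", "Ciliophora", "Litostomatea", "Ophryoscolecidae", "Eudiplodinium", 0.030),
    tx("Eukaryota", "Ciliophora", "Litostomatea", NA, NA, 0.016),
    tx("Eukaryota", "Parabasalia", "Trichomonadea", "Trichomonadidae", NA, 0.005),
    tx("Eukaryota", "Neocallimastigomycota", "Neocallimastigomycetes", "Neocallimastigaceae", NA, 0.020),
    tx("Eukaryota", "Ascomycota", NA, NA, NA, 0.005),
    tx("Eukaryota", "Amoebozoa", "Tubulinea", NA, NA, 0.004),
    tx("Eukaryota", NA, NA, NA, NA, 0.036),
    # bacteria: 0.746 (nine core families 0.640 = 92.3% of family-assigned 0.6934)
    tx("Bacteria", "Bacteroidetes", "Bacteroidia", "Prevotellaceae", "Prevotella", 0.250),
    tx("Bacteria", "Proteobacteria", "Gammaproteobacteria", "Succinivibrionaceae", NA, 0.095),
    tx("Bacteria", "Firmicutes", "Clostridiales", "Lachnospiraceae", NA, 0.075),
    tx("Bacteria", "Firmicutes", "Clostridiales", "Ruminococcaceae", NA, 0.075),
    tx("Bacteria", "Fibrobacteres", "Fibrobacteria", "Fibrobacteraceae", "Fibrobacter", 0.045),
    tx("Bacteria", "Spirochaetes", "Spirochaetia", "Spirochaetaceae", "Treponema", 0.030),
    tx("Bacteria", "Firmicutes", "Erysipelotrichia", "Erysipelotrichaceae", NA, 0.018),
    tx("Bacteria", "Firmicutes", "Negativicutes", "Veillonellaceae", NA, 0.038),
    tx("Bacteria", "Bacteroidetes", "Bacteroidia", "RF16", NA, 0.014),
    # minor families (non-core)
    tx("Bacteria", "Bacteroidetes", "Bacteroidia", "Bacteroidaceae", "Bacteroides", 0.010),
    tx("Bacteria", "Synergistetes", "Synergistia", "Synergistaceae", NA, 0.008),
    tx("Bacteria", "Firmicutes", "Bacilli", "Lactobacillaceae", NA, 0.007),
    tx("Bacteria", "Lentisphaerae", "Lentisphaeria", "Victivallaceae", NA, 0.006),
    tx("Bacteria", "Tenericutes", "Mollicutes", "Anaeroplasmataceae", NA, 0.006),
    tx("Bacteria", "Proteobacteria", "Alphaproteobacteria", "Rhodospirillaceae", NA, 0.008),
    tx("Bacteria", "Proteobacteria", "Deltaproteobacteria", "Desulfovibrionaceae", NA, 0.0084),
    # bacteria unassigned at family level
    tx("Bacteria", "Firmicutes", "Clostridiales", NA, NA, 0.030),
    tx("Bacteria", "Bacteroidetes", "Bacteroidia", NA, NA, 0.015),
    tx("Bacteria", NA, NA, NA, NA, 0.0076),
    # archaea: 0.003, all methanogens
    tx("Archaea", "Euryarchaeota", "Thermoplasmata", "Methanomassiliicoccales", NA, 0.0012),
    tx("Archaea", "Euryarchaeota", "Methanobacteria", "Methanobacteriaceae", "Methanobrevibacter", 0.0014),
    tx("Archaea", "Euryarchaeota", "Methanobacteria", "Methanobacteriaceae", "Methanosphaera", 0.0001),
    tx("Archaea", "Euryarchaeota", "Methanobacteria", "Methanobacteriaceae", NA, 0.0003)
  )
  stopifnot(abs(sum(cat$fraction) - 1) < 1e-12)
  cat
}

#' The nine core bacterial families of the bovine rumen
#'
#' Family names used for the core-community share summary: together these
#' capture on the order of 92% of all bacterial SSU rRNA reads assigned at
#' the family level in dairy-cow rumen metatranscriptomes.
#' @return character vector of nine family names.
#' @export
core_rumen_families <- function() {
  c("Prevotellaceae", "Succinivibrionaceae", "Lachnospiraceae",
    "Ruminococcaceae", "Fibrobacteraceae", "Spirochaetaceae",
    "Erysipelotrichaceae", "Veillonellaceae", "RF16")
}

#' Load the CAZyme category catalog
#'
#' Maps Pfam accessions of carbohydrate-active enzymes to substrate
#' categories (cellulases, hemicellulases, starch-degrading enzymes,
#' oligosaccharide hydrolases, plus minor categories). Shipped as an
#' editable TSV; pass `path` to use a custom catalog.
#'
#' @param path optional path to a TSV with columns `pfam`, `category`.
#' @return data.frame with columns `pfam`, `category`.
#' @export
cazyme_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cazyme_categories.tsv",
                                package = "rumiquant", mustWork = TRUE)
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_columns(cat, c("pfam", "category"), "cazyme catalog")
  if (anyDuplicated(cat$pfam)) {
    stop("a Pfam accession may appear in only one CAZyme category")
  }
  cat
}

#' The four dominant CAZyme categories
#' @return character vector of the four substrate categories summarized in
#'   the CAZyme share statistic.
#' @export
dominant_cazyme_categories <- function() {
  c("cellulases", "hemicellulases", "starch-degrading",
    "oligosaccharide hydrolases")
}

#' Load the VFA production pathway catalog
#'
#' Ordered EC-number lists for the fermentation pathways producing acetate
#' (directly from pyruvate via poxB, via acetyl-CoA, via acetyl-CoA and
#' acetyl-P), propionate (succinate and acrylate pathways) and butyrate
#' (butyrate kinase and butyryl-CoA:acetate CoA-transferase pathways).
#' ECs shared between routes appear in every pathway containing them;
#' production-specific steps are flagged, as are steps whose membership is
#' tentative. Shipped as an editable TSV.
#'
#' @param path optional path to a custom catalog TSV.
#' @return list of `pathway_definition` objects, one per pathway, each with
#'   fields `name`, `product`, `route`, `ec_numbers`, `n_steps`,
#'   `production_specific`, `expected_taxa`.
#' @export
vfa_pathway_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "vfa_pathways.tsv",
                                package = "rumiquant", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_columns(tab, c("pathway", "product", "route", "ec", "step",
                        "production_specific", "tentative", "taxa"),
                 "pathway catalog")
  lapply(split(tab, tab$pathway), function(p) {
    p <- p[order(p$step), ]
    pathway_definition(
      name = p$pathway[1], product = p$product[1], route = p$route[1],
      ec_numbers = p$ec, n_steps = max(p$step),
      production_specific = p$ec[p$production_specific],
      expected_taxa = unique(unlist(strsplit(p$taxa, ";", fixed = TRUE))))
  })
}

#' Construct a VFA pathway definition
#'
#' @param name pathway identifier.
#' @param product end product, one of "acetate", "propionate", "butyrate".
#' @param route human-readable route label.
#' @param ec_numbers ordered character vector of EC numbers.
#' @param n_steps number of enzymatic steps (activity normalizer).
#' @param production_specific EC numbers specific to the production
#'   direction.
#' @param expected_taxa taxa expected to run the pathway.
#' @return object of class `pathway_definition`.
#' @export
pathway_definition <- function(name, product, route, ec_numbers,
                               n_steps = length(ec_numbers),
                               production_specific = character(),
                               expected_taxa = character()) {
  if (length(ec_numbers) == 0) stop("a pathway needs at least one EC number")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (!product %in% c("acetate", "propionate", "butyrate")) {
    stop("product must be acetate, propionate or butyrate")
  }
  structure(list(name = name, product = product, route = route,
                 ec_numbers = ec_numbers, n_steps = n_steps,
                 production_specific = production_specific,
                 expected_taxa = expected_taxa),
            class = "pathway_definition")
}

#' Default methanogenesis marker sets
#'
#' Marker gene groupings used to profile methanogen activity: `mcrA`
#' (methyl-coenzyme M reductase alpha subunit, universal methanogen
#' marker), `mtMA` (the methylamine-specific methyltransferases mtmB, mtbB
#' and mttB of Methanomassiliicoccales), `mtrA`
#' (methyl-H4MPT:HS-CoM methyltransferase of the CO2-reducing pathway,
#' Methanobrevibacter) and `mtaB` (methanol-specific methyltransferase,
#' expressed by both Methanosphaera and Methanomassiliicoccales).
#'
#' @return named list of marker sets; each has `genes` (member gene names)
#'   and `taxa` (taxa of interest, empty = any).
#' @export
marker_sets <- function() {
  list(
    mcrA = list(genes = "mcrA", taxa = character()),
    mtMA = list(genes = c("mtmB", "mtbB", "mttB"),
                taxa = "Methanomassiliicoccales"),
    mtrA = list(genes = "mtrA", taxa = "Methanobrevibacter"),
    mtaB = list(genes = "mtaB",
                taxa = c("Methanosphaera", "Methanomassiliicoccales"))
  )
}

# Synthetic function catalog: one row per (function_id, system, taxon) with
# the expected fraction of annotated mRNA reads. Marginals are calibrated
# so CAZymes hold ~6% of mRNA reads with the four dominant categories at
# 77.5% of CAZyme reads, VFA-pathway ECs ~3%, methanogenesis genes ~0.5%
# (mttB at 75% of the mtMA pool), and generic housekeeping functions the
# remainder.
default_function_catalog <- function() {
  rows <- list()
  add <- function(id, system, taxon, fraction) {
    rows[[length(rows) + 1L]] <<- data.frame(
      function_id = id, function_system = system, taxon = taxon,
      fraction = fraction, stringsAsFactors = FALSE)
  }

  # housekeeping (SEED-style labels): 0.905 of mRNA reads
  hk <- c(paste0("Ribosomal_protein_S", 1:12),
          paste0("Ribosomal_protein_L", 1:15),
          "Translation_elongation_factor_G",
          "RNA_polymerase_beta_subunit", "RNA_polymerase_beta_prime_subunit",
          "DNA_gyrase_subunit_A", "Chaperonin_GroEL",
          "Enolase", "Pyruvate_kinase", "ATP_synthase_F1_alpha")
  hk_taxa <- c(Prevotellaceae = 0.40, Clostridiales = 0.25,
               Succinivibrionaceae = 0.12, Ciliophora = 0.15,
               Fibrobacter = 0.05, Negativicutes = 0.03)
  for (f in hk) {
    for (t in names(hk_taxa)) {
      add(f, "seed", t, 0.905 * hk_taxa[[t]] / length(hk))
    }
  }

  # CAZymes: 0.06 of mRNA reads, category split 0.19/0.215/0.185/0.185
  # (four dominant = 0.775) + 0.225 minor categories
  caz <- cazyme_catalog()
  cat_frac <- c("cellulases" = 0.190, "hemicellulases" = 0.215,
                "starch-degrading" = 0.185,
                "oligosaccharide hydrolases" = 0.185)
  minor_cats <- setdiff(unique(caz$category), names(cat_frac))
  cat_frac <- c(cat_frac, stats::setNames(rep(0.225 / length(minor_cats),
                                              length(minor_cats)), minor_cats))
  cat_taxa <- list(
    "cellulases" = c(Neocallimastigaceae = 0.30, Ciliophora = 0.25,
                     Fibrobacter = 0.25, Clostridiales = 0.20),
    "hemicellulases" = c(Ciliophora = 0.30, Clostridiales = 0.25,
                         Prevotellaceae = 0.25, Neocallimastigaceae = 0.10,
                         Fibrobacter = 0.10),
    "starch-degrading" = c(Prevotellaceae = 0.55, Clostridiales = 0.30,
                           Succinivibrionaceae = 0.10, Ciliophora = 0.05),
    "oligosaccharide hydrolases" = c(Prevotellaceae = 0.60,
                                     Clostridiales = 0.30,
                                     Succinivibrionaceae = 0.10))
  default_caz_taxa <- c(Prevotellaceae = 0.4, Clostridiales = 0.4,
                        Ciliophora = 0.2)
  for (category in unique(caz$category)) {
    pf <- caz$pfam[caz$category == category]
    tw <- cat_taxa[[category]] %||% default_caz_taxa
    for (p in pf) {
      for (t in names(tw)) {
        add(p, "pfam", t, 0.06 * cat_frac[[category]] * tw[[t]] / length(pf))
      }
    }
  }

  # VFA pathway ECs: 0.03 of mRNA reads. Prevotellaceae dominates the
  # acetate/propionate routes, Clostridiales the butyrate kinase route,
  # Negativicutes the CoA-transferase route; poxB is 1-2 orders of
  # magnitude below the CoA routes with Clostridiales dominating.
  ec_rows <- list(
    list("1.2.5.1",   c(Clostridiales = 0.010, Prevotellaceae = 0.002)),
    list("1.2.7.1",   c(Prevotellaceae = 0.60, Clostridiales = 0.12, Negativicutes = 0.05)),
    list("2.8.3.8",   c(Prevotellaceae = 0.25, Clostridiales = 0.05, Negativicutes = 0.08)),
    list("2.3.1.8",   c(Prevotellaceae = 0.45, Clostridiales = 0.08, Negativicutes = 0.04)),
    list("2.7.2.1",   c(Prevotellaceae = 0.40, Clostridiales = 0.07, Negativicutes = 0.03)),
    list("5.4.99.2",  c(Prevotellaceae = 0.30, Clostridiales = 0.04, Negativicutes = 0.03)),
    list("5.1.99.1",  c(Prevotellaceae = 0.22, Clostridiales = 0.03, Negativicutes = 0.02)),
    list("4.1.1.41",  c(Prevotellaceae = 0.26, Clostridiales = 0.03, Negativicutes = 0.02)),
    list("2.8.3.1",   c(Prevotellaceae = 0.18, Clostridiales = 0.05, Negativicutes = 0.06)),
    list("4.2.1.54",  c(Negativicutes = 0.05, Clostridiales = 0.02)),
    list("1.3.8.7",   c(Negativicutes = 0.05, Clostridiales = 0.02)),
    list("2.3.1.9",   c(Clostridiales = 0.18, Negativicutes = 0.06)),
    list("1.1.1.157", c(Clostridiales = 0.14, Negativicutes = 0.05)),
    list("4.2.1.55",  c(Clostridiales = 0.14, Negativicutes = 0.05)),
    list("1.3.8.1",   c(Clostridiales = 0.14, Negativicutes = 0.05)),
    list("2.3.1.19",  c(Clostridiales = 0.12)),
    list("2.7.2.7",   c(Clostridiales = 0.12)))
  ec_total <- sum(vapply(ec_rows, function(r) sum(r[[2]]), numeric(1)))
  for (r in ec_rows) {
    for (t in names(r[[2]])) {
      add(r[[1]], "ec", t, 0.03 * r[[2]][[t]] / ec_total)
    }
  }

  # methanogenesis marker genes: 0.005 of mRNA reads
  gene_rows <- list(
    list("mcrA", c(Methanobrevibacter = 0.0010, Methanomassiliicoccales = 0.0008,
                   Methanosphaera = 0.0002)),
    list("mtmB", c(Methanomassiliicoccales = 0.00016)),
    list("mtbB", c(Methanomassiliicoccales = 0.00024)),
    list("mttB", c(Methanomassiliicoccales = 0.00120)),
    list("mtrA", c(Methanobrevibacter = 0.00080)),
    list("mtaB", c(Methanosphaera = 0.00036, Methanomassiliicoccales = 0.00024)))
  for (r in gene_rows) {
    for (t in names(r[[1 + 1]])) {
      add(r[[1]], "gene", t, r[[2]][[t]])
    }
  }

  cat <- do.call(rbind, rows)
  cat$fraction <- cat$fraction / sum(cat$fraction)
  rownames(cat) <- NULL
  cat
}
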