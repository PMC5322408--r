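#' Run the full gradient-delineation analysis
#'
#' Orchestrates the stages in survey order: obtain data (simulate a preset
#' or read the configured genotype/phenotype files), fit gear selectivity
#' and derive SL classes, delineate growth clusters (normality, mixtures,
#' tree cut), population genetics under the alternative groupings (AMOVA by
#' date / depth / mesh / SL class, pairwise F_ST with FDR, diversity, HWE,
#' LD, rarefaction), and individual-level Mantel associations of genetic
#' distance with standard length, gill-raker count and capture depth.
#' Deterministic given `config$seed`.
#'
#' @param config a [load_config()] result (or `NULL` for defaults +
#'   `preset = "lucerne3"`).
#' @param full use publication-scale permutation counts (10,000 F_ST;
#'   10,000,000 HWE samples) instead of the configured desk-scale values.
#' @return a `run_report` list with per-stage results and provenance.
#' @export
run_pipeline <- function(config = NULL, full = FALSE) {
  cfg <- config %||% local({ c0 <- default_config(); c0$preset <- "lucerne3"; c0 })
  if (full) {
    cfg$fst_permutations <- 10000L
    cfg$amova_permutations <- 10000L
    cfg$hwe_samples <- 10000000L
    cfg$hwe_burnin <- 10000L
  }
  seed <- cfg$seed
  if (!is.null(cfg$preset)) {
    if (cfg$preset != "lucerne3") abort(paste0("unknown preset: ", cfg$preset))
    sim <- simulate_lucerne3(seed = seed)
    geno <- sim$genotypes; pheno <- sim$phenotypes
  } else {
    if (is.null(cfg$genotypes) || is.null(cfg$phenotypes)) {
      abort("config must give a preset or both input file paths")
    }
    geno <- read_genepop(cfg$genotypes)
    pheno <- read_phenotypes(cfg$phenotypes)
  }

  # --- selectivity -----------------------------------------------------
  sel_model <- fit_mesh_selectivity(pheno)
  partition <- class_boundaries(sel_model)
  pheno <- assign_selectivity_classes(pheno, partition)
  age_cmp <- tryCatch(age_class_comparison(pheno), error = function(e) NULL)

  # --- delineation (three-year-olds: SL-at-age-3 proxies growth rate) --
  age3 <- !is.na(pheno$age) & pheno$age == 3
  if (sum(age3) < 30) {
    warn("fewer than 30 three-year-old fish; delineating on all ages")
    age3 <- rep(TRUE, nrow(pheno))
  }
  sl3 <- pheno$sl[age3]
  norm_sl <- normality_test(sl3)
  mix <- fit_gaussian_mixtures(sl3, k_max = cfg$mixture_k_max,
                               seed = split_seed(seed, "mixtures"))
  cut <- hybrid_tree_cut(sl3, min_frac = cfg$min_cluster_frac)
  pheno$sl_cluster <- NA_character_
  pheno$sl_cluster[age3] <- paste0("K", assign_to_clusters(sl3, cut))

  # --- population genetics (three-year-olds) ---------------------------
  ph3 <- pheno[age3, , drop = FALSE]
  ord <- match(ph3$id, geno$id)
  stopifnot(!anyNA(ord))
  geno <- geno[ord, , drop = FALSE]
  groupings <- list(date = as.character(ph3$date),
                    depth = as.character(ph3$depth),
                    mesh = as.character(ph3$mesh),
                    sl_class = ph3$sl_cluster)
  amovas <- purrr::imap(groupings, function(gv, nm) {
    a <- amova(geno, gv, permutations = cfg$amova_permutations,
               seed = split_seed(seed, paste0("amova_", nm)))
    a$grouping_name <- nm
    a
  })
  fst <- pairwise_fst(geno, ph3$sl_cluster,
                      permutations = cfg$fst_permutations, q = cfg$fdr_q,
                      seed = split_seed(seed, "fst"))
  div <- diversity_summary(geno, ph3$sl_cluster, g_std = cfg$rarefaction_g)
  hwe <- hwe_test(geno, ph3$sl_cluster, n_samples = cfg$hwe_samples,
                  burnin = cfg$hwe_burnin, seed = split_seed(seed, "hwe"))
  ld <- ld_pairwise_tests(geno, ph3$sl_cluster,
                          permutations = cfg$ld_permutations,
                          seed = split_seed(seed, "ld"))
  rar <- rarefied_richness(geno, ph3$sl_cluster, g = cfg$rarefaction_g,
                           combinations = TRUE)

  # --- gradient associations ------------------------------------------
  trends <- dplyr::bind_rows(
    sl_vs_depth = linear_trend(pheno, "sl", "depth"),
    gr_vs_depth = linear_trend(pheno, "gr", "depth"),
    sl_vs_date = linear_trend(pheno, "sl", "date_num"),
    gr_vs_date = linear_trend(pheno, "gr", "date_num"),
    .id = "trend")
  Dg <- smouse_peakall_distance(geno)
  mantels <- dplyr::bind_rows(
    sl = mantel(Dg, trait_distance(ph3$sl), cfg$mantel_permutations,
                seed = split_seed(seed, "mantel_sl")),
    gr = mantel(Dg, trait_distance(ph3$gr), cfg$mantel_permutations,
                seed = split_seed(seed, "mantel_gr")),
    depth = mantel(Dg, trait_distance(ph3$depth), cfg$mantel_permutations,
                   seed = split_seed(seed, "mantel_depth")),
    .id = "trait")
  pm_depth <- dplyr::bind_rows(
    sl = partial_mantel(Dg, trait_distance(ph3$sl),
                        trait_distance(ph3$depth), cfg$mantel_permutations,
                        seed = split_seed(seed, "pm_sl"), control_name = "depth"),
    gr = partial_mantel(Dg, trait_distance(ph3$gr),
                        trait_distance(ph3$depth), cfg$mantel_permutations,
                        seed = split_seed(seed, "pm_gr"), control_name = "depth"),
    .id = "trait")

  structure(list(
    provenance = list(seed = seed, config = cfg, full = full,
                      package_version = as.character(utils::packageVersion("depthcline")),
                      timestamp = format(Sys.time(), tz = "UTC")),
    phenotypes = pheno, genotypes = geno,
    selectivity = sel_model, partition = partition, age_comparison = age_cmp,
    normality = norm_sl, mixtures = mix, clusters = cut,
    amova = amovas, fst = fst, diversity = div, hwe = hwe, ld = ld,
    rarefaction = rar, trends = trends, mantel = mantels,
    partial_mantel = pm_depth), class = "run_report")
}

#' Headline summary of a run report
#' @param object a `run_report`.
#' @param ... unused.
#' @return one-row tibble: delineated k, selected mixture k, global Phi_ST
#'   per grouping, F_ST range, Mantel r per trait.
#' @export
summary.run_report <- function(object, ...) {
  phis <- vapply(object$amova, function(a) a$phi_st, numeric(1))
  out <- tibble::tibble(
    k_clusters = attr(object$clusters, "k"),
    k_mixture = selected_k(object$mixtures),
    fst_min = min(object$fst$theta), fst_max = max(object$fst$theta),
    all_fst_significant = all(object$fst$significant))
  for (nm in names(phis)) out[[paste0("phi_", nm)]] <- phis[[nm]]
  for (i in seq_len(nrow(object$mantel))) {
    out[[paste0("mantel_r_", object$mantel$trait[i])]] <- object$mantel$r[i]
  }
  out
}

#' Write a run report to delimited files
#'
#' Machine-readable provenance (JSON) plus human-readable tables: the
#' selectivity fit, the AICc table, cluster labels merged into the
#' phenotypes, the diversity table with weighted and unweighted overall
#' rows, the F_ST matrix, AMOVA and Mantel summaries.
#'
#' @param report a `run_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(paste0("cannot create ", outdir))
  pr <- report$provenance
  pr$config <- unclass(pr$config)
  jsonlite::write_json(pr, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  w <- function(x, f) readr::write_csv(x, file.path(outdir, f))
  if (!is.null(report$selectivity)) w(tibble::as_tibble(report$selectivity), "selectivity.csv")
  if (!is.null(report$mixtures)) {
    w(dplyr::select(tibble::as_tibble(report$mixtures), -dplyr::where(is.list)),
      "mixture_aicc.csv")
  }
  if (!is.null(report$phenotypes)) w(report$phenotypes, "phenotypes_labeled.csv")
  if (!is.null(report$diversity)) {
    w(tibble::as_tibble(report$diversity), "diversity_per_locus.csv")
    w(add_overall_rows(diversity_by_group(report$diversity)), "diversity_by_group.csv")
  }
  if (!is.null(report$fst)) w(tibble::as_tibble(report$fst), "fst_pairwise.csv")
  if (!is.null(report$amova)) {
    w(purrr::map_dfr(report$amova, function(a) {
      tibble::tibble(grouping = a$grouping_name, sigma2_among = a$sigma2_among,
                     sigma2_within = a$sigma2_within, phi_st = a$phi_st,
                     p_value = a$p_value, permutations = a$permutations)
    }), "amova.csv")
  }
  if (!is.null(report$mantel)) w(report$mantel, "mantel.csv")
  if (!is.null(report$partial_mantel)) w(report$partial_mantel, "partial_mantel.csv")
  if (!is.null(report$trends)) w(report$trends, "trends.csv")
  if (!is.null(report$hwe)) w(report$hwe, "hwe.csv")
  if (!is.null(report$ld)) w(tibble::as_tibble(report$ld), "ld_pairwise.csv")
  if (!is.null(report$rarefaction)) {
    w(report$rarefaction$by_group, "rarefaction_by_group.csv")
    if (!is.null(report$rarefaction$combinations)) {
      w(report$rarefaction$combinations, "private_allele_combinations.csv")
    }
  }
  invisible(outdir)
}
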