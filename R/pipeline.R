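# End-to-end "compare the processing methods" experiment: one synthetic
# community pushed through every reconstruction route (variant denoising
# plus OTU clustering at each threshold), protein QC, diversity, the
# permutation-test layer, driver selection and tree congruence, collected
# into a single comparison report. Fully reproducible from (config, seed).

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 37L + stage) %% 2147483647L
}

#' Configuration for an end-to-end comparison run
#'
#' Defaults encode the study conditions the package emulates: two sample
#' groups (e.g. ridge vs runnel sediment) with replicates, OTU thresholds
#' 0.97/0.95/0.90/0.85 alongside the variant route, rarefaction depth
#' 10,000, Mantel with 9,999 permutations and PERMANOVA with 999.
#'
#' @param aa_length reference protein length (residues).
#' @param n_taxa community richness.
#' @param target_identity mean taxon identity to the reference gene.
#' @param thresholds strictly decreasing OTU identity thresholds in (0, 1].
#' @param variant_mode include the exact-variant route (default `TRUE`).
#' @param n_groups,n_replicates sample layout.
#' @param effect_fold,effect_frac planted group-2 abundance effect.
#' @param n_reads_per_sample sequencing depth per sample.
#' @param sub_rate,indel_rate,chimera_fraction error-model rates.
#' @param rarefaction_depth depth for alpha diversity (default 10000).
#' @param n_perm_mantel,n_perm_permanova permutation counts (9999 / 999).
#' @param run_taxonomy include the classifier contrast stage.
#' @param seed master seed; every stage derives its own seed from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(aa_length = 100, n_taxa = 12, target_identity = 0.93,
                       thresholds = c(0.97, 0.95, 0.90, 0.85),
                       variant_mode = TRUE, n_groups = 2, n_replicates = 3,
                       effect_fold = 4, effect_frac = 0.25,
                       n_reads_per_sample = 2000, sub_rate = 0.002,
                       indel_rate = 0, chimera_fraction = 0.01,
                       rarefaction_depth = 10000,
                       n_perm_mantel = 9999, n_perm_permanova = 999,
                       run_taxonomy = FALSE, seed = 1) {
  if (any(diff(thresholds) >= 0) || any(thresholds <= 0 | thresholds > 1)) {
    abort("thresholds must be strictly decreasing and in (0, 1]")
  }
  if (rarefaction_depth < 1) abort("rarefaction depth must be >= 1")
  structure(as.list(environment()), class = "run_config")
}

#' Simulated physicochemical covariate table
#'
#' Standard-normal covariates named after the usual sediment drivers (NH3,
#' NO2, NO3, ChlA, pH, SGS, TOC, DOC, TDN). When `driver` is given, that
#' column is overwritten with a group indicator plus noise so it genuinely
#' structures any community that differs between groups.
#'
#' @param samples sample ids.
#' @param groups named group vector (required when `driver` is set).
#' @param driver optional name of the column tied to the groups.
#' @param noise_sd sd of the driver's noise term (default 0.3).
#' @param seed integer seed.
#' @return tibble with `sample` plus nine covariate columns.
#' @export
covariate_table <- function(samples, groups = NULL, driver = NULL,
                            noise_sd = 0.3, seed = 1) {
  vars <- c("NH3", "NO2", "NO3", "ChlA", "pH", "SGS", "TOC", "DOC", "TDN")
  set.seed(seed)
  out <- tibble(sample = samples)
  for (v in vars) out[[v]] <- stats::rnorm(length(samples))
  if (!is.null(driver)) {
    g <- as.integer(as.factor(groups[samples]))
    out[[driver]] <- g + stats::rnorm(length(samples), 0, noise_sd)
  }
  out
}

#' Run the full method-comparison pipeline
#'
#' simulate -> dereplicate -> singleton discard -> cluster at each
#' threshold / denoise -> de novo bimera removal -> protein QC -> feature
#' tables -> alpha/beta diversity -> Mantel / PERMANOVA -> Hellinger + CCA
#' stepwise selection -> incremental tree congruence (-> classifier
#' contrast). Two runs with the same config are identical.
#'
#' @param config a [run_config()].
#' @return list of class `comparison_report`; see the vignette for the
#'   component tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  panel <- make_reference_panel(1, cfg$aa_length, stage_seed(cfg$seed, 1L))
  gene <- panel[1, ]
  taxa <- derive_taxa(gene, cfg$n_taxa, cfg$target_identity,
                      stage_seed(cfg$seed, 2L))
  design <- assign_abundances(taxa, cfg$n_groups, cfg$n_replicates,
                              cfg$effect_fold, cfg$effect_frac,
                              seed = stage_seed(cfg$seed, 3L))
  sim <- simulate_amplicons(design, cfg$n_reads_per_sample,
                            error_model(cfg$sub_rate, cfg$indel_rate,
                                        cfg$chimera_fraction),
                            seed = stage_seed(cfg$seed, 4L))
  groups <- setNames(sim$reads$group, sim$reads$sample)
  groups <- groups[!duplicated(names(groups))]

  uniques <- discard_singletons(dereplicate(sim$reads))
  methods <- list()
  if (cfg$variant_mode) {
    methods[["ASV"]] <- denoise(uniques)
  }
  for (t in cfg$thresholds) {
    methods[[sprintf("OTU-%d%%", round(100 * t))]] <- greedy_cluster(uniques, t)
  }

  qc_cfg <- qc_config(gene$name, 3L * cfg$aa_length, gene$protein)
  per_method <- imap(methods, function(feat, name) {
    tab <- build_feature_table(feat, sim$reads)
    reps <- tibble(sequence = tab$sequence,
                   abundance = rowSums(feature_counts(tab)))
    chim <- flag_chimeras_denovo(reps)
    tab <- tab[!chim, , drop = FALSE]
    qc <- qc_feature_set(tab, qc_cfg)
    summ <- qc_summary(qc$verdicts, tab)
    list(name = name, table = qc$curated, verdicts = qc$verdicts,
         qc = summ, n_chimeric = sum(chim))
  })

  depth <- min(cfg$rarefaction_depth,
               min(map_dbl(per_method,
                           function(m) min(colSums(feature_counts(m$table))))))
  alpha <- bind_rows(imap(per_method, function(m, name)
    alpha_diversity(m$table, depth, seed = stage_seed(cfg$seed, 5L)) |>
      mutate(method = name)))

  dists <- imap(per_method, function(m, name) {
    d <- list(BC = bray_curtis(m$table))
    if (nrow(m$table) >= 3) {
      # tree-based metrics need at least 3 features; a route that collapses
      # the community below that is reported with Bray-Curtis only
      seqs <- setNames(m$table$sequence, m$table$feature_id)
      tree <- nj_tree(nt_distance_matrix(seqs))
      d$U <- unifrac_matrix(m$table, tree, weighted = FALSE)
      d$WU <- unifrac_matrix(m$table, tree, weighted = TRUE)
    }
    d
  })

  perm_grid <- bind_rows(imap(dists, function(d, name)
    bind_rows(imap(d, function(D, metric) {
      pr <- permanova(D, groups, cfg$n_perm_permanova,
                      seed = stage_seed(cfg$seed, 6L))
      tibble(method = name, metric = metric, pseudo_F = pr$pseudo_F,
             R2 = pr$R2, p = pr$p)
    }))))
  perm_grid <- perm_grid[is.finite(perm_grid$pseudo_F), , drop = FALSE]

  method_names <- names(dists)
  mantel_grid <- list()
  for (metric in c("BC", "U", "WU")) {
    for (i in seq_along(method_names)) {
      for (j in seq_len(i - 1L)) {
        if (is.null(dists[[i]][[metric]]) || is.null(dists[[j]][[metric]])) next
        mr <- tryCatch(
          mantel_test(dists[[i]][[metric]], dists[[j]][[metric]],
                      cfg$n_perm_mantel, seed = stage_seed(cfg$seed, 7L)),
          error = function(e) NULL)  # constant matrix: correlation undefined
        if (is.null(mr)) next
        mantel_grid[[length(mantel_grid) + 1]] <- tibble(
          metric = metric, method_a = method_names[i],
          method_b = method_names[j], r = mr$r, p = mr$p)
      }
    }
  }
  mantel_grid <- bind_rows(mantel_grid)

  covars <- covariate_table(names(groups), groups, driver = "NH3",
                            seed = stage_seed(cfg$seed, 8L))
  # keep fewer candidate drivers than samples so the full model stays
  # identifiable under stepwise search
  n_covar <- max(1L, min(ncol(covars) - 1L, length(groups) - 2L))
  cca_drivers <- bind_rows(imap(per_method, function(m, name) {
    h <- hellinger(t(feature_counts(m$table)))
    sel <- stepwise_select(h, covars[match(rownames(h), covars$sample),
                                     1L + seq_len(n_covar), drop = FALSE],
                           seed = stage_seed(cfg$seed, 9L))
    if (nrow(sel$selected) == 0) {
      tibble(method = name, variable = NA_character_, p = NA_real_)
    } else {
      mutate(sel$selected, method = name)
    }
  }))

  congruence <- NULL
  if (length(per_method) >= 2) {
    fa <- feature_abundance_tbl(per_method[[1]]$table)
    fb <- feature_abundance_tbl(per_method[[length(per_method)]]$table)
    refs <- setNames(design$taxa$sequence[seq_len(min(6, nrow(design$taxa)))],
                     paste0("ref_", seq_len(min(6, nrow(design$taxa)))))
    curve <- incremental_congruence(fa, fb, refs, max_iter = 8)
    congruence <- list(curve = curve,
                       fit = if (nrow(curve) >= 2) fit_log_curve(curve) else NULL,
                       methods = c(per_method[[1]]$name,
                                   per_method[[length(per_method)]]$name))
  }

  taxonomy <- NULL
  if (cfg$run_taxonomy) {
    dbs <- build_synthetic_db(gene, seed = stage_seed(cfg$seed, 10L))
    queries <- design$taxa$sequence[seq_len(min(8, nrow(design$taxa)))]
    taxonomy <- compare_classifiers(queries, dbs$db_near, dbs$db_far,
                                    seed = stage_seed(cfg$seed, 11L))
  }

  structure(
    list(config = cfg, design = design, truth = sim$truth,
         feature_summary = bind_rows(imap(per_method, function(m, name)
           tibble(method = name, n_features = nrow(m$table),
                  n_chimeric = m$n_chimeric,
                  pct_wrong_features = m$qc$pct_wrong_features,
                  pct_reads_retained = m$qc$pct_reads_retained))),
         tables = map(per_method, "table"),
         verdicts = map(per_method, "verdicts"),
         alpha = alpha, distances = dists,
         permanova = perm_grid, mantel = mantel_grid,
         cca_drivers = cca_drivers, congruence = congruence,
         taxonomy = taxonomy),
    class = "comparison_report"
  )
}

feature_abundance_tbl <- function(table) {
  tibble(feature_id = table$feature_id, sequence = table$sequence,
         abundance = rowSums(feature_counts(table))) |>
    arrange(desc(.data$abundance), .data$sequence)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  methods: %s\n",
              paste(x$feature_summary$method, collapse = ", ")))
  cat(sprintf("  features: %s\n",
              paste(x$feature_summary$n_features, collapse = ", ")))
  cat(sprintf("  PERMANOVA rows: %d, Mantel rows: %d\n",
              nrow(x$permanova), nrow(x$mantel)))
  invisible(x)
}
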