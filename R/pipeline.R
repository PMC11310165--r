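# End-to-end orchestration: one config drives synthetic generation (or file
# input), diversity, assembly inference, multifunctionality, networks and
# QMEC processing, plus a cross-stage Spearman correlation report. Every
# stochastic stage derives its seed deterministically from the master seed
# and the stage name, so a config fully determines every output file.

#' Deterministic per-stage seed from a master seed
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(master) * 7919 + h) %% (2^31 - 1))
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param regime Synthetic assembly regime (ignored when `inputs` paths are
#'   supplied to [run_pipeline()]).
#' @param n_null Null replicates for the assembly stage.
#' @param stages Named logical list toggling stages.
#' @return A config list.
#' @export
default_config <- function(out_dir = tempfile("soilassembly_run_"), seed = 1L,
                           regime = "neutral", n_null = 999,
                           stages = list(diversity = TRUE, assembly = TRUE,
                                         multifunctionality = TRUE,
                                         network = TRUE, qmec = TRUE,
                                         correlations = TRUE)) {
  list(out_dir = out_dir, seed = as.integer(seed),
       synthetic = list(regime = regime, n_taxa = 1024L,
                        n_samples_per_group = 3L, n_groups = 8L,
                        trait_conservation = 0.95, selection_strength = 30,
                        migration_rate = 0.5, depth = 2000L,
                        effect_size = 1, noise_sd = 1,
                        detection_fraction = 0.7),
       inputs = NULL,
       assembly = list(n_null = n_null, abundance_weighted = TRUE,
                       bnti_threshold = 2, rc_threshold = 0.95,
                       grouping = c("plantation", "season")),
       network = list(rho_min = 0.6, alpha_fdr = 0.05, min_prevalence = 0.5),
       permanova = list(n_perm = 999, factors = c("plantation", "season")),
       stages = stages)
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return A config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  modifyList(cfg, user)
}

log_line <- function(con, ...) {
  writeLines(paste0(...), con)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: input (synthetic or files), diversity
#' (alpha, Bray-Curtis, PERMANOVA), assembly (betaNTI, RCbray, five-way
#' partition), multifunctionality, co-occurrence network, QMEC, and a
#' cross-stage Spearman correlation report with Benjamini-Hochberg
#' adjustment. Each stage writes tidy CSVs under `config$out_dir`; a
#' `manifest.json` records the config, its hash and all derived seeds, and
#' `log.txt` records per-stage record counts.
#'
#' @param config A config list from [default_config()] or [read_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.txt")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  seeds <- list()
  use_stage <- function(s) isTRUE(config$stages[[s]])

  # --- inputs -------------------------------------------------------------
  if (is.null(config$inputs)) {
    seeds$synthetic <- stage_seed(config$seed, "synthetic")
    sy <- config$synthetic
    spec <- regime_spec(sy$regime, n_taxa = sy$n_taxa,
                        n_samples_per_group = sy$n_samples_per_group,
                        n_groups = sy$n_groups,
                        trait_conservation = sy$trait_conservation,
                        selection_strength = sy$selection_strength,
                        migration_rate = sy$migration_rate,
                        depth = sy$depth, seed = seeds$synthetic)
    tree <- simulate_tree(sy$n_taxa, seed = seeds$synthetic)
    sim <- simulate_communities(tree, spec)
    table <- sim$table; tree <- sim$tree; frame <- sim$frame
    attrs <- simulate_attribute_matrix(frame, design_spec(), sy$effect_size,
                                       sy$noise_sd,
                                       seed = stage_seed(config$seed,
                                                         "attributes"))
    ctm <- simulate_ct_matrix(frame$sample, sy$detection_fraction,
                              seed = stage_seed(config$seed, "qmec_sim"))
    log_line(con, "input: synthetic regime=", sy$regime,
             " taxa=", nrow(table), " samples=", ncol(table))
  } else {
    table <- read_community_table(config$inputs$table)
    tree <- read_phylogeny(config$inputs$tree)
    frame <- read_sample_frame(config$inputs$metadata)
    attrs <- if (!is.null(config$inputs$attributes))
      read_attribute_matrix(config$inputs$attributes,
                            config$inputs$attribute_categories) else NULL
    ctm <- NULL
    if (!is.null(config$inputs$ct)) {
      ct_df <- read.csv(config$inputs$ct, check.names = FALSE)
      eff_df <- read.csv(config$inputs$efficiency, check.names = FALSE)
      ctm <- list(ct = as.matrix(ct_df[-1]), efficiency = as.matrix(eff_df[-1]))
      rownames(ctm$ct) <- ct_df[[1]]; rownames(ctm$efficiency) <- eff_df[[1]]
    }
    log_line(con, "input: files taxa=", nrow(table),
             " samples=", ncol(table))
  }
  al <- align_table_to_tree(table, tree, policy = "intersect")
  table <- al$table; tree <- al$tree

  per_sample <- data.frame(sample = colnames(table),
                           stringsAsFactors = FALSE)

  # --- diversity ----------------------------------------------------------
  if (use_stage("diversity")) {
    seeds$diversity <- stage_seed(config$seed, "diversity")
    alpha <- data.frame(sample = colnames(table),
                        shannon = alpha_diversity(table, "shannon"),
                        simpson = alpha_diversity(table, "simpson"),
                        sobs = alpha_diversity(table, "sobs"),
                        chao1 = alpha_diversity(table, "chao1"),
                        faith_pd = alpha_diversity(table, "faith_pd",
                                                   tree = tree),
                        row.names = NULL)
    write.csv(alpha, file.path(config$out_dir, "alpha_diversity.csv"),
              row.names = FALSE)
    bc <- bray_curtis(table)
    write.csv(data.frame(sample = rownames(bc), bc, check.names = FALSE),
              file.path(config$out_dir, "bray_curtis.csv"),
              row.names = FALSE)
    pmv <- tryCatch(
      permanova(bc, frame, config$permanova$factors,
                n_perm = config$permanova$n_perm, seed = seeds$diversity),
      error = function(e) NULL)
    if (!is.null(pmv))
      write.csv(pmv, file.path(config$out_dir, "permanova.csv"),
                row.names = FALSE)
    per_sample <- merge(per_sample, alpha, by = "sample")
    log_line(con, "diversity: samples=", nrow(alpha),
             " permanova_terms=", if (is.null(pmv)) 0 else nrow(pmv))
  }

  # --- assembly -----------------------------------------------------------
  if (use_stage("assembly")) {
    seeds$assembly <- stage_seed(config$seed, "assembly")
    asm <- assembly_analysis(table, tree, frame,
                             grouping = config$assembly$grouping,
                             n_null = config$assembly$n_null,
                             abundance_weighted = config$assembly$abundance_weighted,
                             bnti_threshold = config$assembly$bnti_threshold,
                             rc_threshold = config$assembly$rc_threshold,
                             seed = seeds$assembly)
    write.csv(asm$pairs, file.path(config$out_dir, "assembly_pairs.csv"),
              row.names = FALSE)
    write.csv(asm$fractions,
              file.path(config$out_dir, "assembly_fractions.csv"),
              row.names = FALSE)
    bnti_by_sample <- vapply(per_sample$sample, function(s) {
      v <- asm$pairs$bnti[asm$pairs$sample_i == s | asm$pairs$sample_j == s]
      mean(v, na.rm = TRUE)
    }, 0)
    per_sample$mean_bnti <- bnti_by_sample
    log_line(con, "assembly: pairs=", nrow(asm$pairs),
             " undefined=", sum(asm$pairs$process == "undefined"))
  }

  # --- multifunctionality ---------------------------------------------------
  if (use_stage("multifunctionality") && !is.null(attrs)) {
    mf <- multifunctionality(attrs)
    write.csv(mf, file.path(config$out_dir, "multifunctionality.csv"),
              row.names = FALSE)
    z <- attr(mf, "z")
    write.csv(data.frame(sample = rownames(z), z, check.names = FALSE),
              file.path(config$out_dir, "zscores.csv"), row.names = FALSE)
    enz <- attrs$values[, intersect(ENZYMES, colnames(attrs$values)),
                        drop = FALSE]
    if (all(c("BGC", "NAG", "LAP", "ALP") %in% colnames(enz))) {
      ees <- enzyme_stoichiometry(enz)
      write.csv(ees, file.path(config$out_dir, "enzyme_stoichiometry.csv"),
                row.names = FALSE)
    }
    per_sample <- merge(per_sample, mf, by = "sample")
    log_line(con, "multifunctionality: attributes=", ncol(z),
             " samples=", nrow(mf))
  }

  # --- network --------------------------------------------------------------
  if (use_stage("network")) {
    net <- build_network(list(community = table), attrs = attrs,
                         rho_min = config$network$rho_min,
                         alpha_fdr = config$network$alpha_fdr,
                         min_prevalence = config$network$min_prevalence)
    sm <- summarize_network(net)
    write_network(net, file.path(config$out_dir, "network_edges.tsv"),
                  file.path(config$out_dir, "network.graphml"))
    write.csv(data.frame(metric = c("average_degree",
                                    "average_clustering_coefficient",
                                    "average_path_length", "n_nodes",
                                    "n_edges"),
                         value = c(sm$average_degree,
                                   sm$average_clustering_coefficient,
                                   sm$average_path_length, sm$n_nodes,
                                   sm$n_edges)),
              file.path(config$out_dir, "network_summary.csv"),
              row.names = FALSE)
    write.csv(sm$key_nodes, file.path(config$out_dir, "key_nodes.csv"),
              row.names = FALSE)
    write.csv(sm$cross_kingdom,
              file.path(config$out_dir, "cross_kingdom_links.csv"),
              row.names = FALSE)
    log_line(con, "network: nodes=", sm$n_nodes, " edges=", sm$n_edges)
  }

  # --- qmec -----------------------------------------------------------------
  if (use_stage("qmec") && !is.null(ctm)) {
    qr <- qmec_relative_copies(ctm$ct, ctm$efficiency)
    write.csv(data.frame(gene = rownames(qr$copies), qr$copies,
                         check.names = FALSE),
              file.path(config$out_dir, "qmec_copies.csv"),
              row.names = FALSE)
    if (!is.null(qr$cycle_sums))
      write.csv(data.frame(cycle = rownames(qr$cycle_sums), qr$cycle_sums,
                           check.names = FALSE),
                file.path(config$out_dir, "qmec_cycle_sums.csv"),
                row.names = FALSE)
    log_line(con, "qmec: detected=", sum(qr$present),
             " of ", length(qr$present))
  }

  # --- cross-stage correlations --------------------------------------------
  if (use_stage("correlations") && ncol(per_sample) > 2) {
    num <- per_sample[, vapply(per_sample, is.numeric, TRUE), drop = FALSE]
    rep_rows <- list()
    vars <- names(num)
    for (i in seq_along(vars)) for (j in seq_along(vars)) if (i < j) {
      ok <- complete.cases(num[[i]], num[[j]])
      if (sum(ok) >= 4) {
        r <- suppressWarnings(cor(num[[i]][ok], num[[j]][ok],
                                  method = "spearman"))
        n <- sum(ok)
        tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
        rep_rows[[length(rep_rows) + 1]] <-
          data.frame(var_a = vars[i], var_b = vars[j], rho = r,
                     p = 2 * pt(-abs(tt), n - 2))
      }
    }
    if (length(rep_rows)) {
      rep_df <- do.call(rbind, rep_rows)
      rep_df$p_adj <- p.adjust(rep_df$p, method = "BH")
      write.csv(rep_df, file.path(config$out_dir, "correlation_report.csv"),
                row.names = FALSE)
      log_line(con, "correlations: pairs=", nrow(rep_df))
    }
    grp_rows <- group_comparisons(num, frame, per_sample$sample)
    if (!is.null(grp_rows))
      write.csv(grp_rows, file.path(config$out_dir,
                                    "group_comparisons.csv"),
                row.names = FALSE)
  }

  # --- manifest -------------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.json")
  # the output location must not enter the persisted config or its hash:
  # identical configs must yield byte-identical output sets wherever run
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], cfg_path,
                       auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- list(package = "soilassembly",
                   version = as.character(utils::packageVersion("soilassembly")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   master_seed = config$seed, stage_seeds = seeds)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

# One-way ANOVA with Tukey HSD per numeric variable across
# plantation-by-season cells, reported as tidy rows.
group_comparisons <- function(num, frame, samples) {
  grp <- factor(paste(frame$plantation, frame$season, sep = "_")[
    match(samples, frame$sample)])
  if (nlevels(grp) < 2 || any(table(grp) < 2)) return(NULL)
  rows <- list()
  for (v in names(num)) {
    y <- num[[v]]
    if (sd(y, na.rm = TRUE) == 0 || anyNA(y)) next
    fit <- aov(y ~ grp)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$grp
    rows[[v]] <- data.frame(variable = v,
                            f = an$`F value`[1], p = an$`Pr(>F)`[1],
                            contrast = rownames(tk),
                            diff = tk[, "diff"], p_adj = tk[, "p adj"],
                            row.names = NULL)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
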