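# Configuration-driven end-to-end runner: SMR gene ranking -> per-pair NP
# GSEA -> Stouffer consensus -> herb GSEA -> adjusted candidate table.

#' Read a pipeline run configuration
#'
#' YAML key-value document; relative paths are resolved against the
#' config file's directory.
#'
#' @param path Path to a YAML config file.
#' @return The config as a list, with `base_dir` recorded.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("input error: config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  cfg
}

.resolve_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (!is.null(cfg$base_dir) && !grepl("^(/|[A-Za-z]:)", p))
    file.path(cfg$base_dir, p) else p
}

#' Validate a run configuration
#'
#' Collects every problem (missing files, invalid thresholds, absent
#' dataset lists) into one report instead of failing at the first.
#'
#' @param config Config list from [read_run_config()] or built in code.
#' @return Character vector of findings; empty means runnable.
#' @export
validate_config <- function(config) {
  findings <- character(0)
  add <- function(msg) findings <<- c(findings, msg)

  for (key in c("gwas_datasets", "qtl_datasets")) {
    ds <- config[[key]]
    if (is.null(ds) || length(ds) < 1L) {
      add(paste0(key, ": at least one dataset required"))
    } else {
      for (d in ds) {
        if (is.null(d$id) || is.null(d$path)) {
          add(paste0(key, ": each dataset needs id and path"))
        } else {
          f <- .resolve_path(config, d$path)
          if (!file.exists(f)) add(paste0(key, " [", d$id, "]: file not found: ", f))
        }
      }
    }
  }
  for (key in c("np_to_gene_path", "herb_to_np_path")) {
    if (is.null(config[[key]])) {
      add(paste0(key, ": missing required path"))
    } else if (!file.exists(.resolve_path(config, config[[key]]))) {
      add(paste0(key, ": file not found: ", .resolve_path(config, config[[key]])))
    }
  }
  if (!is.null(config$ld_path) &&
      !file.exists(.resolve_path(config, config$ld_path)))
    add(paste0("ld_path: file not found: ", .resolve_path(config, config$ld_path)))

  fdr <- config$fdr_threshold %||% 0.05
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1)
    add("fdr_threshold: must be in (0,1)")
  r2t <- config$clump$r2_threshold %||% 0.001
  if (!is.numeric(r2t) || r2t <= 0 || r2t > 1)
    add("clump.r2_threshold: must be in (0,1]")
  if (!is.null(config$seed) && !is.numeric(config$seed))
    add("seed: must be an integer")
  findings
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.gsea_params_from <- function(x, seed) {
  x <- x %||% list()
  gsea_params(weight_exponent = x$weight_exponent %||% 1,
              n_perm = x$n_perm %||% 1000L,
              n_perm_max = x$n_perm_max %||% 1e6,
              eps = x$eps %||% 0,
              min_size = x$min_size %||% 1L,
              max_size = x$max_size %||% Inf,
              seed = seed)
}

#' Run the full prioritization pipeline
#'
#' For every QTL x GWAS dataset pair: instrument selection (FDR filter),
#' LD clumping, harmonization, per-gene SMR and the `-log10 p` gene
#' ranking; then per-pair NP enrichment, Stouffer consensus across pairs,
#' herb-level enrichment and multiple-testing adjustment. Every stage's
#' table is written under `out_dir`; re-running with identical config and
#' seed reproduces the tables byte for byte.
#'
#' @param config Config list (see [read_run_config()]) or a path to a
#'   YAML config.
#' @return Invisibly, a list with the herb table (`herbs`), the NP
#'   consensus table (`np_consensus`), per-pair gene rankings
#'   (`gene_rankings`), per-pair NP results (`np_results`) and the output
#'   file paths (`files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  findings <- validate_config(config)
  if (length(findings))
    stop("configuration error:\n  ", paste(findings, collapse = "\n  "))

  out_dir <- .resolve_path(config, config$out_dir %||% "results")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(stage, ...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ",
                   paste0(..., collapse = ""))
    writeLines(line, log_con)
  }
  seed <- as.integer(config$seed %||% 1L)
  logf("init", "herbscreen ",
       as.character(utils::packageVersion("herbscreen")), " seed=", seed)
  for (key in c("fdr_threshold", "palindrome_eaf_window"))
    logf("init", key, "=", config[[key]] %||% "(default)")

  smr_opts <- smr_options(
    proxies = isTRUE(config$proxies$enabled),
    proxy_min_r2 = config$proxies$min_r2 %||% 0.8,
    palindrome_eaf_window = config$palindrome_eaf_window %||% 0.08,
    min_p_over_instruments = isTRUE(config$min_p_over_instruments))
  fdr_threshold <- config$fdr_threshold %||% 0.05
  r2_threshold <- config$clump$r2_threshold %||% 0.001
  window_kb <- config$clump$window_kb %||% 10000

  ld <- if (!is.null(config$ld_path))
    read_ld(.resolve_path(config, config$ld_path)) else NULL

  qtl_ids <- vapply(config$qtl_datasets, `[[`, "", "id")
  gwas_ids <- vapply(config$gwas_datasets, `[[`, "", "id")

  logf("sumstats", "reading ", length(qtl_ids), " QTL and ",
       length(gwas_ids), " GWAS dataset(s)")
  instruments_by_qtl <- list()
  for (d in config$qtl_datasets) {
    tab <- read_sumstats(.resolve_path(config, d$path), d$schema)
    inst <- select_instruments(tab, fdr_threshold)
    inst <- lapply(inst, ld_clump, ld = ld, r2_threshold = r2_threshold,
                   window_kb = window_kb)
    instruments_by_qtl[[d$id]] <- inst
    logf("instruments", d$id, ": ", length(inst), " gene(s) with instruments")
  }
  outcome_by_gwas <- list()
  for (d in config$gwas_datasets) {
    tab <- read_sumstats(.resolve_path(config, d$path), d$schema)
    data.table::setkey(tab, snp)
    outcome_by_gwas[[d$id]] <- tab
  }

  np_sets <- read_relationships(.resolve_path(config, config$np_to_gene_path),
                                "np_to_gene")
  herb_sets <- read_relationships(.resolve_path(config, config$herb_to_np_path),
                                  "herb_to_np")

  files <- list(gene_rankings = character(0), np_results = character(0))
  gene_rankings <- list()
  np_results <- list()
  pair_i <- 0L
  for (qid in qtl_ids) {
    for (gid in gwas_ids) {
      pair_i <- pair_i + 1L
      pair_id <- paste0(qid, "_x_", gid)
      outcome <- outcome_by_gwas[[gid]]
      assocs <- lapply(names(instruments_by_qtl[[qid]]), function(g)
        gene_association(instruments_by_qtl[[qid]][[g]], outcome, ld,
                         smr_opts, gene_id = g, dataset_pair_id = pair_id))
      rl <- rank_genes(assocs)
      tab <- attr(rl, "table")
      f <- file.path(out_dir, paste0("genes_", pair_id, ".tsv"))
      out <- tab[, .(GENE = gene_id, TOP_SNP = top_snp, B_SMR = b_smr,
                     T_SMR = t_smr, P_SMR = p_smr, RANK_STAT = rank_stat)]
      data.table::fwrite(out, f, sep = "\t", eol = "\n")
      files$gene_rankings <- c(files$gene_rankings, f)
      gene_rankings[[pair_id]] <- rl
      logf("smr", pair_id, ": ", length(rl$items), " gene(s) ranked")

      np_params <- .gsea_params_from(config$gsea_np,
                                     seed = .child_seed(seed, pair_i))
      res <- gsea_preranked(rl, np_sets, np_params)
      data.table::setorder(res, p, set_id)
      f <- file.path(out_dir, paste0("np_", pair_id, ".tsv"))
      data.table::fwrite(
        res[, .(NP = set_id, ES = es, NES = nes, P_VALUE = p,
                EFFECTIVE_SIZE = effective_size, N_PERM = n_perm_used)],
        f, sep = "\t", eol = "\n")
      files$np_results <- c(files$np_results, f)
      np_results[[pair_id]] <- res
      logf("gsea_np", pair_id, ": ", nrow(res), " NP set(s) tested, ",
           sum(res$at_floor), " at the permutation resolution floor")
    }
  }

  np_rank <- consensus_np_ranking(np_results)
  cons <- attr(np_rank, "table")
  f_cons <- file.path(out_dir, "np_consensus.tsv")
  data.table::fwrite(
    cons[, .(NP = np_id, K_ANALYSES = k, Z_SUM = z_sum, META_P = meta_p,
             RANK_STAT = rank_stat)],
    f_cons, sep = "\t", eol = "\n")
  logf("consensus", nrow(cons), " NP(s) combined over ", pair_i, " analyses")

  herb_params <- .gsea_params_from(config$gsea_herb,
                                   seed = .child_seed(seed, 1000L))
  herbs <- prioritize_herbs(np_rank, herb_sets, herb_params)
  f_herbs <- file.path(out_dir, "herbs.tsv")
  data.table::fwrite(
    herbs[, .(INGREDIENT = herb_id, NES = nes, P_VALUE = p, P_FDR = p_fdr,
              P_BONFERRONI = p_bonferroni, N_NP_TARGETS = n_np_targets,
              SELECTED = selected)],
    f_herbs, sep = "\t", eol = "\n")
  logf("herbs", nrow(herbs), " herb(s) tested (Bonferroni m = ",
       nrow(herbs), "); ", sum(herbs$selected), " selected at adjusted p < 0.05")

  files$np_consensus <- f_cons
  files$herbs <- f_herbs
  files$log <- log_path
  invisible(list(herbs = herbs, np_consensus = cons,
                 gene_rankings = gene_rankings, np_results = np_results,
                 files = files))
}

utils::globalVariables(c("top_snp", "b_smr", "t_smr", "at_floor",
                         "n_perm_used"))
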