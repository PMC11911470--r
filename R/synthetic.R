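# Seeded synthetic GWAS/QTL benchmark with planted ground truth.

#' Benchmark specification
#'
#' Defines the generative conditions for a synthetic benchmark: planted
#' causal genes with strong cis instruments, per-dataset measurement
#' noise, effective NPs whose target sets are enriched for causal genes,
#' and planted herbs whose NP sets are enriched for effective NPs.
#'
#' @param n_genes Number of genes (default 500).
#' @param n_causal Number of causal genes (default 50).
#' @param n_snps_per_gene Instrument SNPs per gene (default 3).
#' @param qtl_z_scale Mean |z| of true instrument QTL associations
#'   (default 8).
#' @param gene_effect Outcome effect per unit exposure for causal genes
#'   (delta; default 0.5; 0 for all other genes).
#' @param n_qtl_datasets,n_gwas_datasets Dataset counts (defaults 2, 2).
#' @param qtl_n,gwas_n Per-dataset sample sizes used in the SE model
#'   `se = 1/sqrt(2 n maf (1-maf))` (defaults 30000, 50000; recycled).
#' @param n_nps,n_effective_nps NP counts (defaults 200, 40).
#' @param targets_per_np Genes targeted per NP (default 20).
#' @param causal_target_fraction Fraction (rho) of an effective NP's
#'   targets drawn from causal genes (default 0.6).
#' @param n_herbs,n_planted_herbs Herb counts (defaults 200, 20).
#' @param nps_per_herb NPs per herb (default 10).
#' @param effective_np_fraction Fraction of a planted herb's NPs drawn
#'   from effective NPs (default 0.6).
#' @param maf_range Minor-allele-frequency interval (default c(0.05, 0.5)).
#' @param ld_mode `"independent"` (empty LD table; clumping is a
#'   pass-through) or `"block"` (constant within-gene r2, exercising the
#'   clumper).
#' @param block_r2 Within-gene r2 under `ld_mode = "block"` (default 0.9).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Object of class `benchmark_spec` (a validated list).
#' @export
benchmark_spec <- function(n_genes = 500L, n_causal = 50L,
                           n_snps_per_gene = 3L, qtl_z_scale = 8,
                           gene_effect = 0.5,
                           n_qtl_datasets = 2L, n_gwas_datasets = 2L,
                           qtl_n = 30000L, gwas_n = 50000L,
                           n_nps = 200L, n_effective_nps = 40L,
                           targets_per_np = 20L,
                           causal_target_fraction = 0.6,
                           n_herbs = 200L, n_planted_herbs = 20L,
                           nps_per_herb = 10L,
                           effective_np_fraction = 0.6,
                           maf_range = c(0.05, 0.5),
                           ld_mode = c("independent", "block"),
                           block_r2 = 0.9, seed = 1L) {
  ld_mode <- match.arg(ld_mode)
  spec <- list(n_genes = as.integer(n_genes), n_causal = as.integer(n_causal),
               n_snps_per_gene = as.integer(n_snps_per_gene),
               qtl_z_scale = qtl_z_scale, gene_effect = gene_effect,
               n_qtl_datasets = as.integer(n_qtl_datasets),
               n_gwas_datasets = as.integer(n_gwas_datasets),
               qtl_n = rep_len(as.integer(qtl_n), n_qtl_datasets),
               gwas_n = rep_len(as.integer(gwas_n), n_gwas_datasets),
               n_nps = as.integer(n_nps),
               n_effective_nps = as.integer(n_effective_nps),
               targets_per_np = as.integer(targets_per_np),
               causal_target_fraction = causal_target_fraction,
               n_herbs = as.integer(n_herbs),
               n_planted_herbs = as.integer(n_planted_herbs),
               nps_per_herb = as.integer(nps_per_herb),
               effective_np_fraction = effective_np_fraction,
               maf_range = maf_range, ld_mode = ld_mode, block_r2 = block_r2,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_causal <= n_genes, n_effective_nps <= n_nps,
              n_planted_herbs <= n_herbs,
              targets_per_np <= n_genes, nps_per_herb <= n_nps,
              causal_target_fraction >= 0, causal_target_fraction <= 1,
              effective_np_fraction >= 0, effective_np_fraction <= 1,
              maf_range[1] > 0, maf_range[2] <= 0.5,
              maf_range[1] <= maf_range[2])
  })
  structure(spec, class = "benchmark_spec")
}

# Deterministic child seed (kept below 2^31) so network generation does not
# depend on how many random draws the sumstats stage consumed.
.child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 69069 + 12345 + offset * 1013904223) %%
               2147483647)
}

# Truncated-positive normal via inverse CDF (exact, vectorized).
.rtruncnorm_pos <- function(n, mean, sd = 1) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

# Non-palindromic SNV allele pairs used for the scaffold.
.ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Simulate QTL and GWAS summary statistics with planted causal genes
#'
#' A shared variant scaffold (positions, alleles, MAF) underlies all
#' datasets. Each instrument SNP gets one latent true exposure effect with
#' `|z| ~ Normal(qtl_z_scale, 1)` truncated positive and random sign (at a
#' reference QTL sample size); each QTL dataset observes it plus
#' independent `Normal(0, se_x)` noise, and each GWAS dataset observes
#' `delta_g * b_true + Normal(0, se_y)`, where `delta_g = gene_effect` for
#' causal genes and 0 otherwise. Standard errors follow
#' `1/sqrt(2 n maf (1-maf))` with dataset-specific n; p-values are
#' two-sided normal tails and per-dataset BH FDR is included.
#'
#' @param spec A [benchmark_spec()].
#' @return List with `qtl` (named list of QTL tables, each with a `gene`
#'   column), `gwas` (named list of GWAS tables), `truth` (list with
#'   `causal_genes`, and placeholders filled by [simulate_networks()]),
#'   and `variants` (the scaffold).
#' @export
simulate_sumstats <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  n_snp <- spec$n_genes * spec$n_snps_per_gene
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  gene_idx <- rep(seq_len(spec$n_genes), each = spec$n_snps_per_gene)
  # genes cycle over 22 chromosomes; loci 1 Mb apart within a chromosome
  scaffold <- data.table::data.table(
    gene = rep(genes, each = spec$n_snps_per_gene),
    snp = sprintf("rs%07d", seq_len(n_snp)),
    chr = as.character(((gene_idx - 1L) %% 22L) + 1L),
    pos = ((gene_idx - 1L) %/% 22L + 1L) * 1000000L +
      rep(seq_len(spec$n_snps_per_gene), spec$n_genes) * 1000L)
  pair_idx <- sample.int(nrow(.ALLELE_PAIRS), n_snp, replace = TRUE)
  scaffold[, `:=`(ea = .ALLELE_PAIRS[pair_idx, 1],
                  oa = .ALLELE_PAIRS[pair_idx, 2],
                  maf = stats::runif(n_snp, spec$maf_range[1],
                                     spec$maf_range[2]))]

  causal <- sort(sample(genes, spec$n_causal))
  delta <- ifelse(scaffold$gene %in% causal, spec$gene_effect, 0)

  ref_n <- spec$qtl_n[1]
  se_ref <- 1 / sqrt(2 * ref_n * scaffold$maf * (1 - scaffold$maf))
  z_true <- .rtruncnorm_pos(n_snp, spec$qtl_z_scale) *
    sample(c(-1, 1), n_snp, replace = TRUE)
  b_true <- z_true * se_ref

  make_table <- function(b_obs, se_obs, n_obs, with_gene) {
    z <- b_obs / se_obs
    dt <- data.table::data.table(
      snp = scaffold$snp, chr = scaffold$chr, pos = scaffold$pos,
      ea = scaffold$ea, oa = scaffold$oa, eaf = scaffold$maf,
      beta = b_obs, se = se_obs,
      p = 2 * stats::pnorm(-abs(z)), n = n_obs)
    if (with_gene) {
      dt[, gene := scaffold$gene]
      dt[, fdr := stats::p.adjust(p, method = "BH")]
    }
    dt[]
  }

  qtl <- lapply(seq_len(spec$n_qtl_datasets), function(d) {
    se_x <- 1 / sqrt(2 * spec$qtl_n[d] * scaffold$maf * (1 - scaffold$maf))
    make_table(b_true + stats::rnorm(n_snp, 0, se_x), se_x,
               spec$qtl_n[d], with_gene = TRUE)
  })
  names(qtl) <- sprintf("qtl%02d", seq_len(spec$n_qtl_datasets))

  gwas <- lapply(seq_len(spec$n_gwas_datasets), function(d) {
    se_y <- 1 / sqrt(2 * spec$gwas_n[d] * scaffold$maf * (1 - scaffold$maf))
    make_table(delta * b_true + stats::rnorm(n_snp, 0, se_y), se_y,
               spec$gwas_n[d], with_gene = FALSE)
  })
  names(gwas) <- sprintf("gwas%02d", seq_len(spec$n_gwas_datasets))

  list(qtl = qtl, gwas = gwas,
       truth = list(causal_genes = causal,
                    effective_nps = character(0),
                    planted_herbs = character(0)),
       variants = scaffold[])
}

#' Simulate two-layer NP and herb relationship networks
#'
#' Effective NPs draw `ceiling(rho * targets_per_np)` targets from the
#' causal genes and the rest uniformly from the remaining genes;
#' background NPs draw uniformly. Planted herbs draw
#' `ceiling(effective_np_fraction * nps_per_herb)` NPs from the effective
#' NPs, the rest uniformly; background herbs draw uniformly.
#'
#' @param spec A [benchmark_spec()].
#' @param truth Truth list from [simulate_sumstats()] (needs
#'   `causal_genes`).
#' @return List with `np_to_gene` and `herb_to_np` membership tables
#'   (`set_id`, `member_id`) and the completed `truth` labels.
#' @export
simulate_networks <- function(spec, truth) {
  stopifnot(inherits(spec, "benchmark_spec"),
            length(truth$causal_genes) == spec$n_causal)
  set.seed(.child_seed(spec$seed, 1L))
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  nps <- sprintf("NP%04d", seq_len(spec$n_nps))
  herbs <- sprintf("HERB%04d", seq_len(spec$n_herbs))
  causal <- truth$causal_genes
  noncausal <- setdiff(genes, causal)

  effective <- sort(sample(nps, spec$n_effective_nps))
  n_from_causal <- min(ceiling(spec$causal_target_fraction *
                                 spec$targets_per_np), spec$n_causal)
  if (n_from_causal > 0 &&
      spec$targets_per_np - n_from_causal > length(noncausal))
    stop("spec error: requested set sizes exceed available gene pools")

  np_targets <- lapply(nps, function(np) {
    if (np %in% effective && n_from_causal > 0) {
      sort(c(sample(causal, n_from_causal),
             sample(noncausal, spec$targets_per_np - n_from_causal)))
    } else {
      sort(sample(genes, spec$targets_per_np))
    }
  })
  names(np_targets) <- nps

  planted <- sort(sample(herbs, spec$n_planted_herbs))
  n_from_eff <- min(ceiling(spec$effective_np_fraction * spec$nps_per_herb),
                    spec$n_effective_nps)
  background_nps <- setdiff(nps, effective)
  if (spec$nps_per_herb - n_from_eff > length(background_nps))
    stop("spec error: requested set sizes exceed available NP pools")

  herb_nps <- lapply(herbs, function(h) {
    if (h %in% planted && n_from_eff > 0) {
      sort(c(sample(effective, n_from_eff),
             sample(background_nps, spec$nps_per_herb - n_from_eff)))
    } else {
      sort(sample(nps, spec$nps_per_herb))
    }
  })
  names(herb_nps) <- herbs

  to_table <- function(lst) data.table::data.table(
    set_id = rep(names(lst), lengths(lst)), member_id = unlist(lst))

  truth$effective_nps <- effective
  truth$planted_herbs <- planted
  list(np_to_gene = to_table(np_targets), herb_to_np = to_table(herb_nps),
       truth = truth)
}

# Write a sumstats table in the canonical TSV dialect.
.write_sumstats_tsv <- function(dt, path, with_gene) {
  out <- data.table::copy(dt)
  cols <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p",
            if (with_gene) c("fdr", "gene"), "n")
  out <- out[, cols, with = FALSE]
  data.table::setnames(out, toupper(cols))
  data.table::fwrite(out, path, sep = "\t", eol = "\n")
}

#' Materialize a full benchmark bundle on disk
#'
#' Writes every pipeline input exactly once — QTL and GWAS sumstats TSVs,
#' the two relationship TSVs, an LD table (header-only under
#' `ld_mode = "independent"`, constant within-gene r2 under `"block"`), a
#' ready-to-run YAML config, plain-text truth labels — plus a manifest of
#' MD5 file hashes. Output is byte-identical for identical specs.
#'
#' @param spec A [benchmark_spec()].
#' @param out_dir Writable directory (created if missing).
#' @return Invisibly, a list with `manifest` (named MD5 vector), `config`
#'   (path to the YAML config) and `truth`.
#' @export
make_benchmark <- function(spec, out_dir) {
  stopifnot(inherits(spec, "benchmark_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_sumstats(spec)
  net <- simulate_networks(spec, sim$truth)

  written <- character(0)
  wfile <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  qtl_files <- list()
  for (d in names(sim$qtl)) {
    f <- wfile(paste0(d, ".tsv"))
    .write_sumstats_tsv(sim$qtl[[d]], f, with_gene = TRUE)
    qtl_files[[d]] <- basename(f)
  }
  gwas_files <- list()
  for (d in names(sim$gwas)) {
    f <- wfile(paste0(d, ".tsv"))
    .write_sumstats_tsv(sim$gwas[[d]], f, with_gene = FALSE)
    gwas_files[[d]] <- basename(f)
  }

  data.table::fwrite(stats::setNames(net$np_to_gene, c("SET_ID", "MEMBER_ID")),
                     wfile("np_to_gene.tsv"), sep = "\t", eol = "\n")
  data.table::fwrite(stats::setNames(net$herb_to_np, c("SET_ID", "MEMBER_ID")),
                     wfile("herb_to_np.tsv"), sep = "\t", eol = "\n")

  ld <- if (spec$ld_mode == "block") {
    v <- sim$variants
    pairs <- v[, {
      if (.N > 1L) {
        cmb <- utils::combn(snp, 2L)
        .(snp_a = cmb[1, ], snp_b = cmb[2, ])
      } else .(snp_a = character(0), snp_b = character(0))
    }, by = gene][, .(snp_a, snp_b)]
    pairs[, r2 := spec$block_r2]
    pairs
  } else {
    data.table::data.table(snp_a = character(0), snp_b = character(0),
                           r2 = numeric(0))
  }
  data.table::fwrite(stats::setNames(ld, c("SNP_A", "SNP_B", "R2")),
                     wfile("ld.tsv"), sep = "\t", eol = "\n")

  writeLines(c("# causal_genes", net$truth$causal_genes,
               "# effective_nps", net$truth$effective_nps,
               "# planted_herbs", net$truth$planted_herbs),
             wfile("truth_labels.txt"))

  config <- list(
    seed = spec$seed,
    out_dir = "results",
    qtl_datasets = lapply(names(qtl_files), function(d)
      list(id = d, path = qtl_files[[d]])),
    gwas_datasets = lapply(names(gwas_files), function(d)
      list(id = d, path = gwas_files[[d]])),
    ld_path = "ld.tsv",
    np_to_gene_path = "np_to_gene.tsv",
    herb_to_np_path = "herb_to_np.tsv",
    fdr_threshold = 0.05,
    clump = list(r2_threshold = 0.001, window_kb = 10000),
    proxies = list(enabled = FALSE, min_r2 = 0.8),
    palindrome_eaf_window = 0.08,
    gsea_np = list(weight_exponent = 1, n_perm = 1000, n_perm_max = 100000,
                   eps = 0, min_size = 1),
    gsea_herb = list(weight_exponent = 1, n_perm = 1000, n_perm_max = 100000,
                     eps = 0, min_size = 1))
  cfg_path <- wfile("config.yaml")
  yaml::write_yaml(config, cfg_path)

  hashes <- tools::md5sum(sort(written))
  names(hashes) <- basename(names(hashes))
  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(paste(names(hashes), hashes, sep = "\t"), manifest_path)
  ok <- TRUE
  invisible(list(manifest = hashes, config = cfg_path, truth = net$truth))
}

utils::globalVariables("maf")
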