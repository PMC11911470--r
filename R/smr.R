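# Summary-data-based Mendelian randomization statistics and gene ranking.

#' SMR statistic for one exposure-outcome variant
#'
#' With `z_x = b_x/se_x` and `z_y = b_y/se_y`, computes the Wald-ratio
#' effect `b_smr = b_y/b_x` and the SMR test statistic
#' `t_smr = z_x^2 z_y^2 / (z_x^2 + z_y^2)`, referred to a chi-square
#' distribution with 1 degree of freedom. `t_smr` is symmetric in
#' `(z_x, z_y)` and bounded above by `min(z_x^2, z_y^2)`.
#'
#' @param b_x,se_x Exposure (QTL) effect and standard error; `se_x > 0`,
#'   `b_x != 0`.
#' @param b_y,se_y Outcome (GWAS) effect and standard error; `se_y > 0`.
#' @return List with `b_smr`, `t_smr`, `p_smr`.
#' @export
smr_statistic <- function(b_x, se_x, b_y, se_y) {
  if (!is.finite(se_x) || se_x <= 0 || !is.finite(se_y) || se_y <= 0)
    stop("contract violation: standard errors must be positive")
  if (!is.finite(b_x) || b_x == 0)
    stop("undefined ratio: b_x must be nonzero")
  z_x2 <- (b_x / se_x)^2
  z_y2 <- (b_y / se_y)^2
  t_smr <- if (z_y2 == 0) 0 else z_x2 * z_y2 / (z_x2 + z_y2)
  p_smr <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE)
  list(b_smr = b_y / b_x, t_smr = t_smr, p_smr = p_smr)
}

.P_FLOOR <- 1e-300  # keeps -log10(p) finite after underflow

#' Default options for per-gene SMR
#'
#' @param proxies Use [find_proxy()] for instruments absent from the
#'   outcome table (default `FALSE`).
#' @param proxy_min_r2 Minimum r2 for proxy search.
#' @param palindrome_eaf_window Passed to [harmonize()].
#' @param min_p_over_instruments If `TRUE`, run SMR on every usable
#'   instrument and keep the smallest p; default is the canonical top-SNP
#'   policy (smallest exposure p, falling through on harmonization drops).
#' @return Options list for [gene_association()].
#' @export
smr_options <- function(proxies = FALSE, proxy_min_r2 = 0.8,
                        palindrome_eaf_window = 0.08,
                        min_p_over_instruments = FALSE) {
  list(proxies = proxies, proxy_min_r2 = proxy_min_r2,
       palindrome_eaf_window = palindrome_eaf_window,
       min_p_over_instruments = min_p_over_instruments)
}

#' Per-gene SMR association against an outcome GWAS
#'
#' Takes the gene's instruments in ascending exposure-p order (ties by snp
#' id), fetches the matching outcome record (optionally via a proxy),
#' harmonizes the pair, and applies [smr_statistic()]. Instruments dropped
#' at harmonization (or with `b_x = 0`, or missing from the outcome) fall
#' through to the next best instrument; `NULL` is returned when none is
#' usable.
#'
#' @param instruments A `data.table` of exposure variants for one gene
#'   (one element of [select_instruments()] output).
#' @param outcome Outcome `data.table` keyed or indexable by `snp`.
#' @param ld LD table for proxy search (may be `NULL`).
#' @param options See [smr_options()].
#' @param gene_id,dataset_pair_id Identifiers carried into the result.
#' @return List with `gene_id`, `dataset_pair_id`, `top_snp`, `b_smr`,
#'   `t_smr`, `p_smr`, `rank_stat` (`-log10` of the floored p), or `NULL`.
#' @export
gene_association <- function(instruments, outcome, ld = NULL,
                             options = smr_options(),
                             gene_id = NULL, dataset_pair_id = NA_character_) {
  instruments <- data.table::as.data.table(instruments)
  if (nrow(instruments) == 0L) stop("contract violation: empty instrument set")
  if (is.null(gene_id))
    gene_id <- if ("gene" %in% names(instruments)) instruments$gene[1] else NA
  data.table::setorder(instruments, p, snp)

  best <- NULL
  for (i in seq_len(nrow(instruments))) {
    expo <- as.list(instruments[i])
    hit <- outcome[snp == expo$snp]
    rec <- if (nrow(hit) > 0L) as.list(hit[1]) else if (isTRUE(options$proxies))
      find_proxy(expo$snp, outcome, ld, options$proxy_min_r2) else NULL
    if (is.null(rec)) next
    h <- harmonize(expo, rec, options$palindrome_eaf_window)
    if (h$dropped) next
    if (h$exposure$beta == 0) next  # undefined ratio; fall through
    s <- smr_statistic(h$exposure$beta, h$exposure$se,
                       h$outcome$beta, h$outcome$se)
    cand <- list(gene_id = gene_id, dataset_pair_id = dataset_pair_id,
                 top_snp = expo$snp, b_smr = s$b_smr, t_smr = s$t_smr,
                 p_smr = s$p_smr,
                 rank_stat = -log10(max(s$p_smr, .P_FLOOR)))
    if (!isTRUE(options$min_p_over_instruments)) return(cand)
    if (is.null(best) || cand$p_smr < best$p_smr) best <- cand
  }
  best
}

#' Rank genes by SMR significance
#'
#' Orders per-gene associations by descending `rank_stat`
#' (`-log10(p_smr)`), with ties broken lexicographically by gene id.
#'
#' @param assocs List of [gene_association()] results (NULLs allowed and
#'   skipped) or a data.frame with `gene_id` and `rank_stat` columns.
#' @return A [ranked_list()] over genes (`score_type = "pos"`), with the
#'   full association table attached as attribute `"table"`.
#' @export
rank_genes <- function(assocs) {
  if (is.data.frame(assocs)) {
    dt <- data.table::as.data.table(assocs)
  } else {
    assocs <- Filter(Negate(is.null), assocs)
    if (length(assocs) == 0L) stop("input error: no gene associations to rank")
    dt <- data.table::rbindlist(lapply(assocs, data.table::as.data.table))
  }
  if (anyDuplicated(dt$gene_id))
    stop("contract violation: duplicate gene_id within a dataset pair")
  rl <- ranked_list(dt$gene_id, dt$rank_stat, score_type = "pos")
  data.table::setorder(dt, -rank_stat, gene_id)
  attr(rl, "table") <- dt[]
  rl
}

utils::globalVariables(c("gene_id"))
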