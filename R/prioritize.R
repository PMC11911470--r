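# Consensus NP ranking, herb-level enrichment, adjustment, output table.

#' Construct a set collection
#'
#' Two-layer membership maps: natural-product (NP) to target genes, or
#' herb to NPs.
#'
#' @param members Named list, set id to character vector of member ids.
#' @param layer `"np_to_gene"` or `"herb_to_np"`.
#' @return Object of class `set_collection`.
#' @export
set_collection <- function(members, layer = c("np_to_gene", "herb_to_np")) {
  layer <- match.arg(layer)
  stopifnot(is.list(members), !is.null(names(members)))
  if (any(lengths(members) == 0L))
    stop("contract violation: empty member set in collection")
  structure(list(layer = layer, members = members), class = "set_collection")
}

#' @export
print.set_collection <- function(x, ...) {
  cat("set_collection (", x$layer, "): ", length(x$members), " sets, ",
      sum(lengths(x$members)), " memberships\n", sep = "")
  invisible(x)
}

#' Read a two-layer relationship file
#'
#' Two-column delimited file (`SET_ID`, `MEMBER_ID` or any two columns in
#' that order), one membership per line, in the style of a BATMAN-TCM
#' export. Identifiers are whitespace-trimmed with case preserved;
#' duplicate pairs are deduplicated and rows with an empty field dropped
#' with a warning. Files ending in `.gmt` are parsed as GMT (set id,
#' description, members...).
#'
#' @param path File path.
#' @param layer `"np_to_gene"` or `"herb_to_np"`.
#' @return A [set_collection()].
#' @export
read_relationships <- function(path, layer = c("np_to_gene", "herb_to_np")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    if (length(lines) == 0L) stop("input error: empty relationship file: ", path)
    members <- lapply(lines, function(l) {
      f <- trimws(strsplit(l, "\t", fixed = TRUE)[[1]])
      unique(f[-(1:2)][nzchar(f[-(1:2)])])
    })
    names(members) <- vapply(lines, function(l)
      trimws(strsplit(l, "\t", fixed = TRUE)[[1]][1]), character(1))
    members <- members[lengths(members) > 0L]
    return(set_collection(members, layer))
  }
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (nrow(dt) == 0L) stop("input error: empty relationship file: ", path)
  dt <- dt[, 1:2]
  data.table::setnames(dt, c("set_id", "member_id"))
  dt[, `:=`(set_id = trimws(set_id), member_id = trimws(member_id))]
  bad <- !nzchar(dt$set_id) | !nzchar(dt$member_id) |
    is.na(dt$set_id) | is.na(dt$member_id)
  if (any(bad)) {
    warning("read_relationships: dropped ", sum(bad),
            " malformed row(s) with empty fields")
    dt <- dt[!bad]
  }
  n_before <- nrow(dt)
  dt <- unique(dt)
  if (nrow(dt) < n_before)
    message("read_relationships: deduplicated ", n_before - nrow(dt),
            " repeated pair(s)")
  if (nrow(dt) == 0L) stop("input error: no valid rows in ", path)
  members <- split(dt$member_id, dt$set_id)
  set_collection(members, layer)
}

#' Combine one-sided p-values by Stouffer's method
#'
#' Each p is transformed to `z = qnorm(1 - p)` (small p, large positive
#' z), summed and scaled by `sqrt(k)`; the combined p is the upper normal
#' tail of the sum. Values at 0 or 1 are clamped to the floor/ceiling
#' before the transform.
#'
#' @param p_values Numeric vector of one-sided p-values, `k >= 1`.
#' @param p_floor Clamp applied below (default 1e-300) and mirrored above
#'   as `1 - 1e-16`.
#' @return List with `z_sum` (the combined Z) and `meta_p`.
#' @export
stouffer_combine <- function(p_values, p_floor = 1e-300) {
  p_values <- p_values[!is.na(p_values)]
  k <- length(p_values)
  if (k < 1L) stop("input error: no p-values to combine")
  clamped <- pmin(pmax(p_values, p_floor), 1 - 1e-16)
  if (any(clamped != p_values))
    message("stouffer_combine: clamped ", sum(clamped != p_values),
            " boundary p-value(s)")
  z <- stats::qnorm(clamped, lower.tail = FALSE)
  z_sum <- sum(z) / sqrt(k)
  list(z_sum = z_sum, meta_p = stats::pnorm(z_sum, lower.tail = FALSE))
}

#' Consensus NP ranking across analyses
#'
#' Pools each NP's one-sided enrichment p-values over the available
#' dataset-pair analyses with [stouffer_combine()] (an NP missing from
#' some analyses uses only the k where it was tested), then ranks NPs by
#' `-log10(meta_p)` descending, ties broken by NP id.
#'
#' @param per_analysis Named list (one element per dataset pair) of
#'   [gsea_preranked()] result tables.
#' @param p_floor Floor applied before `-log10`; default 1e-300.
#' @return A [ranked_list()] over NPs (`score_type = "pos"`), with a
#'   per-NP consensus table (`np_id, k, z_sum, meta_p, rank_stat`)
#'   attached as attribute `"table"`.
#' @export
consensus_np_ranking <- function(per_analysis, p_floor = 1e-300) {
  stopifnot(is.list(per_analysis), length(per_analysis) >= 1L)
  long <- data.table::rbindlist(
    lapply(per_analysis, function(x)
      data.table::as.data.table(x)[, .(set_id, p)]),
    idcol = "analysis")
  if (nrow(long) == 0L) stop("input error: no enrichment results to combine")
  cons <- long[, {
    s <- stouffer_combine(p, p_floor)
    .(k = .N, z_sum = s$z_sum, meta_p = s$meta_p)
  }, by = set_id]
  data.table::setnames(cons, "set_id", "np_id")
  cons[, rank_stat := -log10(pmax(meta_p, p_floor))]
  rl <- ranked_list(cons$np_id, cons$rank_stat, score_type = "pos")
  data.table::setorder(cons, -rank_stat, np_id)
  attr(rl, "table") <- cons[]
  rl
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up with
#' monotonicity enforcement, preserving input order.
#'
#' @param p Numeric p-values in (0,1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Herb-level prioritization
#'
#' Runs the second-level preranked GSEA of herb sets (herbs as sets, NPs
#' as items) against the consensus NP ranking, then reports
#' Bonferroni-adjusted (family size = number of herbs actually tested) and
#' BH-adjusted p-values. A herb is selected when its Bonferroni-adjusted p
#' is strictly below 0.05.
#'
#' @param np_rank A [ranked_list()] over NPs.
#' @param herb_sets A [set_collection()] (layer `herb_to_np`) or named list.
#' @param params A [gsea_params()] list.
#' @return A `data.table` sorted by ascending p with columns `herb_id,
#'   nes, p, p_fdr, p_bonferroni, n_np_targets, selected` (and `es`,
#'   `n_perm_used` for inspection).
#' @export
prioritize_herbs <- function(np_rank, herb_sets, params = gsea_params()) {
  if (length(np_rank$items) == 0L) stop("input error: empty NP universe")
  res <- gsea_preranked(np_rank, herb_sets, params)
  if (nrow(res) == 0L) stop("input error: no herb set passed the size filter")
  out <- data.table::data.table(
    herb_id = res$set_id, es = res$es, nes = res$nes, p = res$p,
    p_fdr = adjust_pvalues(res$p, "bh"),
    p_bonferroni = adjust_pvalues(res$p, "bonferroni"),
    n_np_targets = res$effective_size,
    n_perm_used = res$n_perm_used)
  out[, selected := p_bonferroni < 0.05]
  data.table::setorder(out, p, herb_id)
  out[]
}

#' Compare scores between two labelled groups
#'
#' Wilcoxon rank-sum comparison of a score between the `TRUE` and `FALSE`
#' groups: exact when the smaller group has at most 10 observations and
#' there are no ties, normal approximation with tie correction otherwise.
#'
#' @param scores Numeric scores.
#' @param labels Logical vector aligned to `scores`; both groups must be
#'   non-empty.
#' @return List with `rank_sum_stat` (the Mann-Whitney W for the `TRUE`
#'   group) and `p_two_sided`.
#' @export
compare_scores_by_label <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  x <- scores[labels]
  y <- scores[!labels]
  if (length(x) == 0L || length(y) == 0L)
    stop("input error: both label groups must be non-empty")
  ties <- anyDuplicated(scores) > 0L
  use_exact <- min(length(x), length(y)) <= 10L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact))
  list(rank_sum_stat = unname(wt$statistic), p_two_sided = wt$p.value)
}
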