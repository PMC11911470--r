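# Reading, filtering, clumping and harmonizing summary statistics.

.CANONICAL_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE",
                     "P", "FDR", "N", "GENE")
.REQUIRED_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE", "P")

#' Read a summary-statistics table
#'
#' Reads a tab-separated GWAS or QTL association table into a typed
#' `data.table`, applying an optional column-name remapping and dropping rows
#' that violate the per-variant invariants (`SE > 0`, `P` in (0,1], effect
#' allele distinct from the other allele, `EAF` in \[0,1\] when present).
#'
#' Canonical columns are `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, FDR, N`
#' plus `GENE` for QTL tables; `EAF`, `FDR`, `N` and `GENE` are optional.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(EA = "A1", OA = "A2")`.
#' @return A `data.table` with lower-case canonical columns (`snp`, `chr`,
#'   `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`, and `fdr`/`n`/`gene` when
#'   present). The number of dropped rows is attached as attribute
#'   `"n_dropped"` and reported via `message()`.
#' @export
read_sumstats <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1L))
  if (nrow(dt) == 0L) stop("input error: empty summary-statistics file: ", path)

  if (!is.null(schema)) {
    bad <- setdiff(names(schema), .CANONICAL_COLS)
    if (length(bad))
      stop("configuration error: unknown canonical column(s) in schema: ",
           paste(bad, collapse = ", "))
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(dt))
        data.table::setnames(dt, schema[[canon]], canon)
    }
  }
  missing_req <- setdiff(.REQUIRED_COLS, names(dt))
  if (length(missing_req))
    stop("configuration error: missing required column(s): ",
         paste(missing_req, collapse = ", "))

  keep <- intersect(.CANONICAL_COLS, names(dt))
  dt <- dt[, keep, with = FALSE]
  data.table::setnames(dt, keep, tolower(keep))

  dt[, `:=`(snp = as.character(snp), chr = as.character(chr),
            pos = as.integer(pos),
            ea = toupper(as.character(ea)), oa = toupper(as.character(oa)),
            beta = as.numeric(beta), se = as.numeric(se), p = as.numeric(p))]
  if ("eaf" %in% names(dt)) dt[, eaf := as.numeric(eaf)]
  if ("fdr" %in% names(dt)) dt[, fdr := as.numeric(fdr)]
  if ("n" %in% names(dt)) dt[, n := as.integer(n)]
  if ("gene" %in% names(dt)) dt[, gene := as.character(gene)]

  ok <- !is.na(dt$snp) & !is.na(dt$beta) &
    !is.na(dt$se) & dt$se > 0 &
    !is.na(dt$p) & dt$p > 0 & dt$p <= 1 &
    dt$ea != dt$oa
  if ("eaf" %in% names(dt))
    ok <- ok & (is.na(dt$eaf) | (dt$eaf >= 0 & dt$eaf <= 1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message("read_sumstats: dropped ", n_dropped,
            " row(s) violating variant invariants [", basename(path), "]")
  dt <- dt[ok]
  data.table::setattr(dt, "n_dropped", n_dropped)
  dt[]
}

#' Select QTL instruments per gene at an FDR threshold
#'
#' Keeps, for each gene, the significant QTL variants (`fdr <
#' fdr_threshold`). When the table carries no `fdr` column,
#' Benjamini-Hochberg adjustment of `p` is applied across the entire table
#' first; when `fdr` is present it is used as-is and never recomputed.
#' Genes with no surviving variant are omitted.
#'
#' @param qtl A `data.table` from [read_sumstats()] with a `gene` column.
#' @param fdr_threshold Significance threshold in (0,1); default 0.05.
#' @return Named list of instrument sets, one per gene: each a `data.table`
#'   of the surviving variants, ordered by `p` then `snp`.
#' @export
select_instruments <- function(qtl, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(qtl))
  if (!"gene" %in% names(qtl))
    stop("configuration error: QTL table lacks a gene column")
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("configuration error: fdr_threshold must be in (0,1)")
  qtl <- data.table::as.data.table(qtl)
  if (!"fdr" %in% names(qtl) || all(is.na(qtl$fdr))) {
    qtl <- data.table::copy(qtl)
    qtl[, fdr := stats::p.adjust(p, method = "BH")]
  }
  sig <- qtl[!is.na(fdr) & fdr < fdr_threshold]
  if (nrow(sig) == 0L) return(structure(list(), names = character(0)))
  data.table::setorder(sig, p, snp)
  split(sig, by = "gene", sorted = TRUE)
}

#' Read a pairwise LD table
#'
#' Tab-separated columns `SNP_A, SNP_B, R2` and optionally `PHASED_ALLELES`
#' (format `"EA_A/OA_A=EA_B/OA_B"`: the alleles of SNP B that travel with
#' the effect/other allele of SNP A on the same haplotype). Lookups are
#' symmetric.
#'
#' @param path Path to the LD file.
#' @return A `data.table` with columns `snp_a, snp_b, r2` (and
#'   `phased_alleles` if present); zero rows allowed (independent SNPs).
#' @export
read_ld <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  expected <- c("SNP_A", "SNP_B", "R2")
  if (!all(expected %in% names(dt)))
    stop("configuration error: LD file must have columns SNP_A, SNP_B, R2")
  keep <- intersect(c(expected, "PHASED_ALLELES"), names(dt))
  dt <- dt[, keep, with = FALSE]
  data.table::setnames(dt, keep, tolower(keep))
  if (nrow(dt) > 0L) {
    dt[, `:=`(snp_a = as.character(snp_a), snp_b = as.character(snp_b),
              r2 = as.numeric(r2))]
    if (any(is.na(dt$r2) | dt$r2 < 0 | dt$r2 > 1))
      stop("input error: LD r2 values must lie in [0,1]")
  }
  dt[]
}

# r2 between two SNP ids under a (possibly NULL/empty) LD table; 0 if absent.
.ld_r2 <- function(ld, a, b) {
  if (is.null(ld) || nrow(ld) == 0L) return(0)
  hit <- ld[(snp_a == a & snp_b == b) | (snp_a == b & snp_b == a)]
  if (nrow(hit) == 0L) 0 else max(hit$r2)
}

#' Greedy LD clumping of a variant list
#'
#' Variants are sorted by ascending p-value (ties broken by `snp` id); the
#' best remaining variant is retained and every remaining variant with
#' `r2 >= r2_threshold` within `window_kb` of it is discarded. Pairs absent
#' from the LD table, or farther apart than the window (or on different
#' chromosomes), count as r2 = 0, so the retained set is mutually below the
#' threshold.
#'
#' @param variants `data.table` of variants with `snp`, `chr`, `pos`, `p`.
#' @param ld LD table from [read_ld()], or `NULL` for independent SNPs.
#' @param r2_threshold Clumping threshold in (0,1\]; default 0.001.
#' @param window_kb Window in kilobases; default 10000.
#' @return The retained variants, in greedy retention order.
#' @export
ld_clump <- function(variants, ld = NULL, r2_threshold = 0.001,
                     window_kb = 10000) {
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1)
    stop("configuration error: r2_threshold must be in (0,1]")
  variants <- data.table::as.data.table(variants)
  if (nrow(variants) <= 1L) return(variants[])
  data.table::setorder(variants, p, snp)
  active <- rep(TRUE, nrow(variants))
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    if (!active[i]) next
    keep[i] <- TRUE
    active[i] <- FALSE
    for (j in which(active)) {
      same_chr <- variants$chr[i] == variants$chr[j]
      within <- same_chr &&
        abs(variants$pos[i] - variants$pos[j]) <= window_kb * 1000
      if (within &&
          .ld_r2(ld, variants$snp[i], variants$snp[j]) >= r2_threshold)
        active[j] <- FALSE
    }
  }
  variants[keep][]
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.complement_allele <- function(x) {
  if (nchar(x) != 1L || !x %in% names(.COMPLEMENT)) return(NA_character_)
  unname(.COMPLEMENT[[x]])
}

.is_palindromic <- function(a1, a2) {
  nchar(a1) == 1L && nchar(a2) == 1L &&
    !is.na(.complement_allele(a1)) && identical(.complement_allele(a1), a2)
}

#' Harmonize an exposure-outcome variant pair
#'
#' Aligns the outcome record so both effect sizes refer to the exposure's
#' effect allele. Swapped alleles are swapped back (negating the outcome
#' beta and flipping its EAF); alleles matching only after strand
#' complement are complemented; palindromic (A/T, G/C) variants are aligned
#' by allele frequency when both EAFs lie strictly outside
#' `0.5 +/- palindrome_eaf_window` and dropped as ambiguous otherwise.
#' Irreconcilable alleles are dropped as mismatches. Indel alleles are
#' compared as exact strings and never strand-complemented.
#'
#' @param exposure,outcome Single variant records (a list or one-row
#'   data.frame with fields `snp, ea, oa, beta, se, p` and optionally
#'   `eaf`), sharing the same `snp` id.
#' @param palindrome_eaf_window Half-width of the EAF ambiguity window
#'   around 0.5; default 0.08.
#' @return A list with elements `snp_id`, `exposure`, `outcome` (aligned),
#'   `action` (one of `none`, `swap_flip`, `strand_complement`,
#'   `dropped_palindrome`, `dropped_mismatch`), `dropped` (logical) and
#'   `proxy_of` (`NA` unless the outcome record was a proxy).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  ex <- as.list(exposure)
  out <- as.list(outcome)
  if (!identical(as.character(ex$snp), as.character(out$snp)))
    stop("contract violation: harmonize() requires matching snp ids (",
         ex$snp, " vs ", out$snp, ")")
  proxy_of <- if (!is.null(out$proxy_of)) out$proxy_of else NA_character_
  w <- palindrome_eaf_window
  a1 <- toupper(ex$ea); a2 <- toupper(ex$oa)
  b1 <- toupper(out$ea); b2 <- toupper(out$oa)
  ex_eaf <- if (is.null(ex$eaf)) NA_real_ else as.numeric(ex$eaf)
  out_eaf <- if (is.null(out$eaf)) NA_real_ else as.numeric(out$eaf)

  done <- function(action, dropped = FALSE) {
    out$ea <- a1; out$oa <- a2
    out$eaf <- out_eaf
    list(snp_id = as.character(ex$snp), exposure = ex, outcome = out,
         action = action, dropped = dropped, proxy_of = proxy_of)
  }
  drop_as <- function(action) {
    list(snp_id = as.character(ex$snp), exposure = ex, outcome = as.list(outcome),
         action = action, dropped = TRUE, proxy_of = proxy_of)
  }
  swap <- function() {
    out$beta <<- -out$beta
    if (!is.na(out_eaf)) out_eaf <<- 1 - out_eaf
  }

  if (.is_palindromic(a1, a2)) {
    if (!((b1 == a1 && b2 == a2) || (b1 == a2 && b2 == a1)))
      return(drop_as("dropped_mismatch"))
    if (is.na(ex_eaf) || is.na(out_eaf))
      return(drop_as("dropped_palindrome"))
    if (abs(ex_eaf - 0.5) <= w || abs(out_eaf - 0.5) <= w)
      return(drop_as("dropped_palindrome"))
    flipped <- FALSE
    if (b1 == a2) { swap(); flipped <- !flipped }  # string alignment
    if ((ex_eaf < 0.5) != (out_eaf < 0.5)) {       # frequency alignment
      swap(); flipped <- !flipped
    }
    return(done(if (flipped) "swap_flip" else "none"))
  }

  if (b1 == a1 && b2 == a2) return(done("none"))
  if (b1 == a2 && b2 == a1) { swap(); return(done("swap_flip")) }

  c1 <- .complement_allele(b1); c2 <- .complement_allele(b2)
  if (!is.na(c1) && !is.na(c2)) {
    if (c1 == a1 && c2 == a2) return(done("strand_complement"))
    if (c1 == a2 && c2 == a1) { swap(); return(done("strand_complement")) }
  }
  drop_as("dropped_mismatch")
}

#' Find a proxy SNP in the outcome table
#'
#' Among outcome variants with `r2 >= min_r2` to the query SNP, returns the
#' one with the highest r2 (ties broken by lexicographically smaller snp
#' id), with its alleles re-phased to the query SNP via the LD table's
#' `phased_alleles` column when available. The returned record keeps the
#' proxy's association values but carries the query's `snp` id; the proxy's
#' own id is stored in `proxy_of`.
#'
#' @param snp_id Query SNP id absent from the outcome table.
#' @param outcome Outcome `data.table` from [read_sumstats()].
#' @param ld LD table from [read_ld()].
#' @param min_r2 Minimum r2 in (0,1\]; default 0.8.
#' @return A one-row variant record as a list, or `NULL` if no candidate.
#' @export
find_proxy <- function(snp_id, outcome, ld, min_r2 = 0.8) {
  if (!is.numeric(min_r2) || min_r2 <= 0 || min_r2 > 1)
    stop("configuration error: min_r2 must be in (0,1]")
  if (is.null(ld) || nrow(ld) == 0L) return(NULL)
  cand <- ld[(snp_a == snp_id | snp_b == snp_id) & r2 >= min_r2]
  if (nrow(cand) == 0L) return(NULL)
  cand[, partner := ifelse(snp_a == snp_id, snp_b, snp_a)]
  cand <- cand[partner %in% outcome$snp]
  if (nrow(cand) == 0L) return(NULL)
  data.table::setorder(cand, -r2, partner)
  best <- cand[1]
  rec <- as.list(outcome[snp == best$partner][1])
  rec$proxy_of <- rec$snp
  rec$snp <- snp_id

  phase <- if ("phased_alleles" %in% names(best)) best$phased_alleles else NA
  if (!is.na(phase) && nzchar(phase)) {
    sides <- strsplit(phase, "=", fixed = TRUE)[[1]]
    if (length(sides) == 2L) {
      q_side <- if (best$snp_a == snp_id) sides[1] else sides[2]
      p_side <- if (best$snp_a == snp_id) sides[2] else sides[1]
      q_al <- strsplit(q_side, "/", fixed = TRUE)[[1]]
      p_al <- strsplit(p_side, "/", fixed = TRUE)[[1]]
      if (length(q_al) == 2L && length(p_al) == 2L) {
        if (identical(rec$ea, p_al[1]) && identical(rec$oa, p_al[2])) {
          rec$ea <- q_al[1]; rec$oa <- q_al[2]
        } else if (identical(rec$ea, p_al[2]) && identical(rec$oa, p_al[1])) {
          rec$ea <- q_al[2]; rec$oa <- q_al[1]
        }
      }
    }
  }
  rec
}

utils::globalVariables("partner")
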