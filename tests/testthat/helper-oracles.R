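# Independent oracles and small fixture builders used across test files.

# Brute-force weighted running-sum ES over the full list, position by
# position (independent of the package's hit-indexed computation).
brute_es <- function(stats, is_member, q = 1, pos_only = TRUE) {
  N <- length(stats)
  k <- sum(is_member)
  w <- abs(stats)^q
  W <- sum(w[is_member])
  if (W <= 0) { w[is_member] <- 1; W <- k }
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (is_member[i]) w[i] / W else -1 / (N - k)
    running[i] <- cur
  }
  if (pos_only) return(max(running))
  mx <- max(running); mn <- min(running)
  if (mx >= -mn) mx else mn
}

# Step-up Benjamini-Hochberg, written from the definition.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

brute_bonferroni <- function(p) pmin(1, p * length(p))

# chi-square(1 df) upper tail via the normal tail (independent closed form).
chisq1_tail <- function(t) 2 * pnorm(-sqrt(t))

# Random variant record with non-palindromic or palindromic SNV alleles.
random_variant <- function(snp = "rs1", palindromic = FALSE, eaf = NULL) {
  pairs <- if (palindromic)
    list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  else
    list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
         c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  al <- pairs[[sample.int(length(pairs), 1)]]
  list(snp = snp, chr = "1", pos = 1000L, ea = al[1], oa = al[2],
       eaf = if (is.null(eaf)) runif(1) else eaf,
       beta = rnorm(1), se = runif(1, 0.01, 0.5), p = runif(1))
}

comp_allele <- c(A = "T", T = "A", C = "G", G = "C")

# Re-encode a variant on the opposite allele labelling (same association).
flip_variant <- function(v) {
  v2 <- v
  v2$ea <- v$oa; v2$oa <- v$ea
  v2$beta <- -v$beta
  if (!is.null(v$eaf) && !is.na(v$eaf)) v2$eaf <- 1 - v$eaf
  v2
}

write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", eol = "\n")
  path
}

# Minimal sumstats table in the canonical on-disk dialect.
tiny_sumstats <- function() {
  data.table::data.table(
    SNP = c("rs1", "rs2", "rs3"), CHR = "1", POS = c(100L, 200L, 300L),
    EA = c("A", "T", "C"), OA = c("G", "C", "A"), EAF = c(0.2, 0.3, 0.4),
    BETA = c(0.1, -0.2, 0.05), SE = c(0.02, 0.03, 0.01),
    P = c(1e-6, 1e-4, 0.2), N = 10000L)
}
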