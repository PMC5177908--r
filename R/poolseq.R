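BASES <- c("A", "T", "C", "G")
SYNC_COLS <- c("A", "T", "C", "G", "N", "del")

#' Construct a pool-seq counts table
#'
#' Per-site, per-population base counts in sync column order
#' (A:T:C:G:N:del), plus a site table with chromosome, 1-based position
#' (sync/mpileup convention) and ref/alt base assignment.
#'
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param counts list with one `L x 6` integer matrix per population,
#'   columns named A, T, C, G, N, del.
#' @return An object of class `counts_table`.
#' @export
counts_table <- function(sites, counts) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  for (m in counts) {
    stopifnot(is.matrix(m), ncol(m) == 6, nrow(m) == nrow(sites),
              all(m >= 0))
  }
  counts <- lapply(counts, function(m) {
    colnames(m) <- SYNC_COLS
    storage.mode(m) <- "integer"
    m
  })
  structure(list(sites = sites, counts = counts), class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat("counts_table:", nrow(x$sites), "sites x", length(x$counts),
      "populations\n")
  invisible(x)
}

#' Per-population coverage matrix
#'
#' @param table a `counts_table`.
#' @return `L x P` integer matrix of total counts per site per population.
#' @export
pool_coverage <- function(table) {
  L <- nrow(table$sites)
  cov <- vapply(table$counts, rowSums, numeric(L))
  if (!is.matrix(cov)) cov <- matrix(cov, nrow = L)
  cov
}

# per-site pooled counts of each base across populations
pooled_base_counts <- function(table) {
  Reduce(`+`, lapply(table$counts, function(m) m[, 1:4, drop = FALSE]))
}

#' Pooled minor-allele frequency per site
#'
#' Minor allele = second most frequent base in the counts pooled across all
#' populations.
#'
#' @param table a `counts_table`.
#' @return Numeric vector of pooled minor-allele frequencies.
#' @export
pooled_maf <- function(table) {
  pc <- pooled_base_counts(table)
  tot <- rowSums(pc)
  srt <- t(apply(pc, 1, sort, decreasing = TRUE))
  ifelse(tot > 0, srt[, 2] / tot, NA_real_)
}

#' Sample pool-seq read counts from exact allele frequencies
#'
#' Emulates pooled sequencing of each deme: per-site depth is drawn from a
#' negative binomial (defaults giving mean 60, SD ~ 15, matching typical
#' per-population coverages of ~60-70X), each read carries the alternate
#' allele with probability equal to the deme frequency, and sequencing
#' error flips a read to each of the three other bases with probability
#' `error_rate / 3`.  Ref/alt bases are assigned to sites at random
#' (seeded) at this export step, since no upstream statistic depends on
#' base identity.
#'
#' @param freqs `L x P` matrix of alternate-allele frequencies (e.g.
#'   `run$freqs`).
#' @param positions_bp site physical positions (0-based; stored 1-based).
#' @param mean_depth target mean depth, scalar or per population.
#' @param depth_dispersion negative-binomial size parameter; the default
#'   21.8 gives SD ~ 15 at mean 60.
#' @param error_rate per-read probability of a miscall.
#' @param seed optional integer seed.
#' @param chrom chromosome label.
#' @return A `counts_table`.
#' @export
sample_pool_reads <- function(freqs, positions_bp, mean_depth = 60,
                              depth_dispersion = 21.8, error_rate = 0.001,
                              seed = NULL, chrom = "3R") {
  if (!is.null(seed)) set.seed(seed)
  freqs <- as.matrix(freqs)
  stopifnot(all(freqs >= 0 & freqs <= 1), all(mean_depth > 0))
  L <- nrow(freqs); P <- ncol(freqs)
  mean_depth <- rep_len(mean_depth, P)
  ref_i <- sample.int(4, L, replace = TRUE)
  alt_i <- ((ref_i - 1 + sample.int(3, L, replace = TRUE)) %% 4) + 1
  sites <- data.frame(chrom = chrom, pos = as.integer(positions_bp) + 1L,
                      ref = BASES[ref_i], alt = BASES[alt_i])
  e <- error_rate
  counts <- vector("list", P)
  for (p in seq_len(P)) {
    depth <- stats::rnbinom(L, mu = mean_depth[p], size = depth_dispersion)
    alt_true <- stats::rbinom(L, depth, freqs[, p])
    ref_true <- depth - alt_true
    m <- matrix(0L, L, 6, dimnames = list(NULL, SYNC_COLS))
    for (s in seq_len(L)) {
      cnt <- integer(4)
      if (ref_true[s] > 0)
        cnt <- cnt + as.integer(stats::rmultinom(
          1, ref_true[s], base_error_probs(ref_i[s], e)))
      if (alt_true[s] > 0)
        cnt <- cnt + as.integer(stats::rmultinom(
          1, alt_true[s], base_error_probs(alt_i[s], e)))
      m[s, 1:4] <- cnt
    }
    counts[[p]] <- m
  }
  counts_table(sites, counts)
}

base_error_probs <- function(true_base, e) {
  pr <- rep(e / 3, 4)
  pr[true_base] <- 1 - e
  pr
}

#' Apply the SNP-table coverage and frequency filters
#'
#' A site is retained iff coverage in every population lies in
#' `[min_cov, max_cov]` (sites with coverage below 20X or above 150X in
#' any population are discarded) and the minor-allele frequency reaches
#' `min_maf` — by default pooled across all populations; set
#' `per_population = TRUE` to require it in each population separately.
#' Removal reasons are recorded in the `filter_log` attribute.
#'
#' @param table a `counts_table`.
#' @param min_cov,max_cov inclusive coverage bounds.
#' @param min_maf minimum minor-allele frequency.
#' @param per_population apply the MAF rule per population.
#' @return The filtered `counts_table`, with attribute `filter_log` (data
#'   frame of dropped site indices and reason codes `low_cov`, `high_cov`,
#'   `low_maf`).
#' @export
filter_snp_table <- function(table, min_cov = 20, max_cov = 150,
                             min_maf = 0.02, per_population = FALSE) {
  cov <- pool_coverage(table)
  low <- apply(cov < min_cov, 1, any)
  high <- apply(cov > max_cov, 1, any)
  if (per_population) {
    maf_ok <- rep(TRUE, nrow(table$sites))
    for (m in table$counts) {
      bc <- m[, 1:4, drop = FALSE]
      tot <- rowSums(bc)
      srt <- t(apply(bc, 1, sort, decreasing = TRUE))
      maf_ok <- maf_ok & tot > 0 & (srt[, 2] / tot >= min_maf)
    }
  } else {
    maf <- pooled_maf(table)
    maf_ok <- !is.na(maf) & maf >= min_maf
  }
  keep <- !low & !high & maf_ok
  reason <- ifelse(low, "low_cov", ifelse(high, "high_cov", "low_maf"))
  log <- data.frame(site = which(!keep), reason = reason[!keep])
  out <- counts_table(table$sites[keep, , drop = FALSE],
                      lapply(table$counts,
                             function(m) m[keep, , drop = FALSE]))
  attr(out, "filter_log") <- log
  out
}

#' Subsample a counts table to uniform depth
#'
#' Sites with coverage at least `target` in a population are downsampled
#' without replacement (multivariate hypergeometric) to exactly `target`
#' reads; sites below `target` are flagged insufficient and should be
#' excluded from depth-sensitive estimators such as Watterson's theta.
#'
#' @param table a `counts_table`.
#' @param target uniform depth (default 30X).
#' @param seed optional integer seed.
#' @return The subsampled `counts_table` with attribute `insufficient`, an
#'   `L x P` logical matrix.
#' @export
subsample_to_depth <- function(table, target = 30, seed = NULL) {
  stopifnot(target >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(table$sites)
  insufficient <- matrix(FALSE, L, length(table$counts))
  counts <- table$counts
  for (p in seq_along(counts)) {
    m <- counts[[p]]
    cov <- rowSums(m)
    for (s in seq_len(L)) {
      if (cov[s] < target) {
        insufficient[s, p] <- TRUE
      } else if (cov[s] > target) {
        reads <- rep.int(1:6, m[s, ])
        kept <- sample(reads, target)
        m[s, ] <- tabulate(kept, 6)
      }
    }
    counts[[p]] <- m
  }
  out <- counts_table(table$sites, counts)
  attr(out, "insufficient") <- insufficient
  out
}

#' Read a sync-format allele count file
#'
#' PoPoolation2 dialect: `chrom TAB pos TAB ref` then one
#' `A:T:C:G:N:del` count string per population.  Since sync does not carry
#' an alt column, the alt base is set to the most frequent pooled non-ref
#' base (or `N` at pure-ref sites).
#'
#' @param path sync file.
#' @return A `counts_table`.
#' @export
read_sync <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != nf[1]) || nf[1] < 4)
    stop("malformed sync line ", which(nf != nf[1] | nf < 4)[1])
  P <- nf[1] - 3
  L <- length(parts)
  chrom <- vapply(parts, `[[`, "", 1)
  pos <- as.integer(vapply(parts, `[[`, "", 2))
  ref <- vapply(parts, `[[`, "", 3)
  counts <- vector("list", P)
  for (p in seq_len(P)) {
    cs <- strsplit(vapply(parts, `[[`, "", 3 + p), ":", fixed = TRUE)
    bad <- which(lengths(cs) != 6)
    if (length(bad)) stop("malformed sync count field at line ", bad[1])
    m <- matrix(as.integer(unlist(cs)), ncol = 6, byrow = TRUE,
                dimnames = list(NULL, SYNC_COLS))
    if (anyNA(m)) stop("non-numeric sync count at line ",
                       which(apply(is.na(m), 1, any))[1])
    counts[[p]] <- m
  }
  pooled <- Reduce(`+`, lapply(counts, function(m) m[, 1:4, drop = FALSE]))
  alt <- vapply(seq_len(L), function(s) {
    cand <- setdiff(order(pooled[s, ], decreasing = TRUE),
                    match(ref[s], BASES))
    if (pooled[s, cand[1]] > 0) BASES[cand[1]] else "N"
  }, "")
  counts_table(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt),
               counts)
}

#' Write a counts table in sync format
#'
#' @param table a `counts_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sync <- function(table, path) {
  fields <- sapply(table$counts, function(m)
    apply(m, 1, paste, collapse = ":"))
  if (is.null(dim(fields))) fields <- matrix(fields, nrow = 1)
  lines <- paste(table$sites$chrom, table$sites$pos, table$sites$ref,
                 apply(fields, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write one population of a counts table as an mpileup file
#'
#' samtools dialect, single sample: chrom, 1-based pos, ref, depth, read
#' bases and a constant-quality string.  Reads matching the ref base are
#' written as `.`, others as the base letter.
#'
#' @param table a `counts_table`.
#' @param path output path.
#' @param population population index (default 1).
#' @param qual_char quality character used for every base.
#' @return Invisibly, `path`.
#' @export
write_mpileup <- function(table, path, population = 1, qual_char = "I") {
  m <- table$counts[[population]]
  ref <- table$sites$ref
  lines <- vapply(seq_len(nrow(m)), function(s) {
    cnt <- m[s, 1:4]
    bases <- character(0)
    for (b in 1:4) {
      if (cnt[b] == 0) next
      ch <- if (BASES[b] == ref[s]) "." else BASES[b]
      bases <- c(bases, rep(ch, cnt[b]))
    }
    depth <- length(bases)
    bstr <- if (depth == 0) "*" else paste(bases, collapse = "")
    qstr <- if (depth == 0) "*" else paste(rep(qual_char, depth),
                                           collapse = "")
    paste(table$sites$chrom[s], table$sites$pos[s], ref[s], depth,
          bstr, qstr, sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
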