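# small handmade counts table: P populations, given ref/alt count pairs
make_table <- function(ref_counts, alt_counts, pos = NULL) {
  L <- nrow(ref_counts); P <- ncol(ref_counts)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  sites <- data.frame(chrom = "3R", pos = pos,
                      ref = rep("A", L), alt = rep("T", L))
  counts <- lapply(seq_len(P), function(p) {
    m <- matrix(0L, L, 6, dimnames = list(NULL,
      c("A", "T", "C", "G", "N", "del")))
    m[, 1] <- ref_counts[, p]; m[, 2] <- alt_counts[, p]
    m
  })
  counts_table(sites, counts)
}

test_that("read sampling reproduces boundary frequencies exactly", {
  pos <- c(100L, 200L)
  tab1 <- sample_pool_reads(matrix(c(1, 1), 2, 1), pos, mean_depth = 50,
                            error_rate = 0, seed = 1)
  for (s in 1:2) {
    cnt <- tab1$counts[[1]][s, ]
    alt <- cnt[tab1$sites$alt[s]]
    expect_equal(unname(alt), unname(sum(cnt)))  # all reads alternate
  }
  tab0 <- sample_pool_reads(matrix(c(0, 0), 2, 1), pos, mean_depth = 50,
                            error_rate = 0, seed = 2)
  for (s in 1:2)
    expect_equal(unname(tab0$counts[[1]][s, tab0$sites$alt[s]]), 0L)
})

test_that("sampled allele fractions are binomial around the input frequency", {
  tab <- sample_pool_reads(matrix(0.5, 1, 1), 100L, mean_depth = 1e6,
                           depth_dispersion = 1e9, error_rate = 0, seed = 3)
  cnt <- tab$counts[[1]][1, ]
  depth <- sum(cnt)
  frac <- cnt[tab$sites$alt[1]] / depth
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / depth))
})

test_that("frequency estimates from sampled counts are unbiased", {
  set.seed(4)
  L <- 10000
  p <- runif(L)
  tab <- sample_pool_reads(matrix(p, ncol = 1), seq_len(L), mean_depth = 60,
                           error_rate = 0, seed = 5)
  m <- tab$counts[[1]]
  alt <- m[cbind(seq_len(L), match(tab$sites$alt, c("A", "T", "C", "G")))]
  cov <- rowSums(m)
  est <- alt[cov > 0] / cov[cov > 0]
  expect_lt(abs(mean(est - p[cov > 0])), 3 * sqrt(mean(0.25 / 60) / L))
})

test_that("SNP-table filters apply the stated coverage and MAF rules", {
  # coverage 19 in one population: discarded; exactly 150 retained
  ref <- cbind(c(10, 100, 100), c(15, 140, 100))
  alt <- cbind(c(9, 50, 50), c(10, 10, 3))
  tab <- make_table(ref, alt)
  kept <- filter_snp_table(tab)
  expect_equal(kept$sites$pos, c(2000L, 3000L))  # site 1 dropped (19X)
  log <- attr(kept, "filter_log")
  expect_equal(log$reason, "low_cov")
  # coverage 151 discarded
  tab2 <- make_table(cbind(101), cbind(50))
  expect_equal(nrow(filter_snp_table(tab2)$sites), 0)
  # pooled MAF below 2% discarded
  tab3 <- make_table(cbind(99, 99), cbind(1, 1))
  expect_equal(nrow(filter_snp_table(tab3)$sites), 0)
  expect_equal(attr(filter_snp_table(tab3), "filter_log")$reason, "low_maf")
})

test_that("a ten-site toy with three single-rule violations keeps seven", {
  ref <- matrix(60, 10, 2)
  alt <- matrix(30, 10, 2)
  ref[3, 1] <- 10; alt[3, 1] <- 5       # low coverage in population 1
  ref[6, 2] <- 200                      # high coverage in population 2
  alt[9, ] <- 1; ref[9, ] <- 89         # pooled MAF ~1.1%
  tab <- make_table(ref, alt)
  kept <- filter_snp_table(tab)
  expect_equal(nrow(kept$sites), 7)
  expect_setequal(attr(kept, "filter_log")$site, c(3, 6, 9))
  # filtering is idempotent
  again <- filter_snp_table(kept)
  expect_identical(again$sites, kept$sites)
  expect_identical(again$counts, kept$counts)
})

test_that("subsampling reaches exact uniform depth, below-target flagged", {
  ref <- cbind(c(15, 30, 40)); alt <- cbind(c(10, 0, 20))
  tab <- make_table(ref, alt)
  sub <- subsample_to_depth(tab, target = 30, seed = 6)
  covs <- rowSums(sub$counts[[1]])
  expect_equal(unname(covs[2]), 30)       # exactly 30: untouched
  expect_identical(sub$counts[[1]][2, ], tab$counts[[1]][2, ])
  expect_equal(unname(covs[3]), 30)       # 60 -> 30
  expect_true(attr(sub, "insufficient")[1, 1])   # 25X flagged
})

test_that("subsampled counts follow hypergeometric moments", {
  ref <- cbind(30); alt <- cbind(30)
  tab <- make_table(ref, alt)
  set.seed(7)
  draws <- replicate(3000, subsample_to_depth(tab, 30)$counts[[1]][1, "T"])
  # hypergeometric: mean 15, var 30 * .5 * .5 * (60-30)/(60-1)
  v <- 30 * 0.25 * 30 / 59
  expect_lt(abs(mean(draws) - 15), 4 * sqrt(v / 3000))
  expect_lt(abs(var(draws) - v), 0.35)
})

test_that("sync files round-trip bit-exactly", {
  set.seed(8)
  L <- 100
  freqs <- matrix(runif(3 * L), L, 3)
  tab <- sample_pool_reads(freqs, seq_len(L) * 10L, mean_depth = 40,
                           seed = 9)
  path <- withr::local_tempfile(fileext = ".sync")
  write_sync(tab, path)
  back <- read_sync(path)
  expect_identical(back$counts, tab$counts)
  expect_equal(back$sites$pos, tab$sites$pos)
  expect_equal(back$sites$ref, tab$sites$ref)
})

test_that("sync fields follow the A:T:C:G:N:del column order", {
  tab <- make_table(cbind(12), cbind(3))
  path <- withr::local_tempfile(fileext = ".sync")
  write_sync(tab, path)
  line <- readLines(path)
  expect_equal(line, "3R\t1000\tA\t12:3:0:0:0:0")
})

test_that("malformed sync lines are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("3R\t1\tA\t1:2:0:0:0:0", "3R\t2\tA\t1:2:0:0"), path)
  expect_error(read_sync(path), "line 2")
})

test_that("mpileup depth equals the length of the read-bases string", {
  set.seed(10)
  freqs <- matrix(runif(20), 20, 1)
  tab <- sample_pool_reads(freqs, seq_len(20) * 5L, mean_depth = 30,
                           seed = 11)
  path <- withr::local_tempfile(fileext = ".mpileup")
  write_mpileup(tab, path)
  fields <- strsplit(readLines(path), "\t")
  for (f in fields) {
    if (f[5] == "*") { expect_equal(as.integer(f[4]), 0L); next }
    expect_equal(as.integer(f[4]), nchar(f[5]))
    expect_equal(nchar(f[5]), nchar(f[6]))
  }
  # a fixed site with zero error shows a single base symbol
  tabf <- sample_pool_reads(matrix(1, 1, 1), 100L, mean_depth = 50,
                            error_rate = 0, seed = 12)
  pathf <- withr::local_tempfile(fileext = ".mpileup")
  write_mpileup(tabf, pathf)
  bases <- strsplit(readLines(pathf), "\t")[[1]][5]
  expect_equal(length(unique(strsplit(bases, "")[[1]])), 1)
})
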