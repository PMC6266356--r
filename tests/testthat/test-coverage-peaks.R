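make_genome <- function(seqs) structure(list(seq = seqs),
                                        class = "genome_model")

test_that("read extension follows the 3' fragment model with clipping", {
  genome <- make_genome(c(chrA = strrep("A", 1000)))
  reads <- data.frame(chrom = "chrA", start = c(100, 100, 900),
                      end = c(250, 250, 1000),
                      strand = c("+", "-", "+"))
  fr <- extend_reads(reads, 250, genome)
  expect_equal(fr$start, c(100, 0, 900))
  expect_equal(fr$end, c(350, 250, 1000))  # clipped at both ends

  expect_error(extend_reads(data.frame(chrom = "chrX", start = 0, end = 10,
                                       strand = "+"), 250, genome),
               "unknown chromosome")

  # total fragment bp equals sum of min(ext, available space)
  set.seed(4)
  n <- 200
  r <- data.frame(chrom = "chrA",
                  start = sample(0:900, n, replace = TRUE),
                  strand = sample(c("+", "-"), n, replace = TRUE))
  r$end <- pmin(r$start + sample(50:150, n, replace = TRUE), 1000)
  fr <- extend_reads(r, 250, genome)
  expected <- ifelse(r$strand == "+", pmin(250, 1000 - r$start),
                     pmin(250, r$end))
  expect_equal(sum(fr$end - fr$start), sum(expected))
})

test_that("coverage equals per-base membership counts", {
  genome <- make_genome(c(chrA = strrep("C", 5000)))
  empty <- compute_coverage(data.frame(chrom = character(),
                                       start = numeric(), end = numeric()),
                            genome)
  expect_equal(sum(empty$chrA$depth), 0)
  expect_length(empty$chrA$depth, 5000)

  two <- compute_coverage(data.frame(chrom = "chrA", start = c(10, 10),
                                     end = c(60, 60)), genome)
  expect_equal(unique(two$chrA$depth[11:60]), 2)
  expect_equal(sum(two$chrA$depth), 100)

  set.seed(7)
  fr <- data.frame(chrom = "chrA",
                   start = sample(0:4800, 100, replace = TRUE))
  fr$end <- pmin(fr$start + sample(1:400, 100, replace = TRUE), 5000)
  cov <- compute_coverage(fr, genome)
  expect_equal(cov$chrA$depth, bf_coverage(fr$start, fr$end, 5000),
               ignore_attr = TRUE)
  # conservation: total depth equals total clipped fragment length
  expect_equal(sum(cov$chrA$depth), sum(fr$end - fr$start))
})

test_that("peak calling is null on identical IP and input", {
  cfg <- tiny_cfg(seed = 41, frac_bound = 0, frac_bound_with_hre = 0,
                  chrom_length = 50000, n_genes = 4,
                  reads_per_sample = 5000)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg)
  pl <- plant_hre(genome, genes, cfg)
  reads <- simulate_reads(pl$genome, genes, pl$truth, cfg)
  fr <- extend_reads(reads[reads$condition == "control" &
                             reads$sample == "input", ], 250, genome)
  cov <- compute_coverage(fr, genome)
  peaks <- call_peaks(cov, cov)
  expect_equal(nrow(peaks), 0)
})

test_that("a strongly bound promoter yields one peak at the motif", {
  cfg <- sim_config(seed = 55, n_chroms = 1, chrom_length = 50000,
                    n_genes = 1, frac_bound = 1, frac_bound_with_hre = 1,
                    reads_per_sample = 2000, bind_rate_control = 400,
                    bind_rate_exposed = 400)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg)
  pl <- plant_hre(genome, genes, cfg)
  reads <- simulate_reads(pl$genome, genes, pl$truth, cfg)
  ip <- extend_reads(reads[reads$sample == "IP" &
                             reads$condition == "control", ], 250, genome)
  inp <- extend_reads(reads[reads$sample == "input" &
                              reads$condition == "control", ], 250,
                      genome)
  peaks <- call_peaks(compute_coverage(ip, genome),
                      compute_coverage(inp, genome))
  expect_equal(nrow(peaks), 1)
  expect_true(peaks$start <= pl$truth$motif_pos &&
                pl$truth$motif_pos < peaks$end)

  # peak p-values equal an independent Poisson survival computation
  lambda <- pmax(peaks$input_count,
                 (peaks$end - peaks$start) *
                   attr(compute_coverage(inp, genome), "total_fragments") /
                   50000 * (nrow(ip) / nrow(inp)), 0.25)
  p_oracle <- 1 - sum(dpois(0:(peaks$ip_count - 1), lambda))
  expect_equal(peaks$pvalue, p_oracle, tolerance = 1e-8)
})

test_that("raising min_depth never increases the peak count", {
  cfg <- tiny_cfg(seed = 61)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg)
  pl <- plant_hre(genome, genes, cfg)
  reads <- simulate_reads(pl$genome, genes, pl$truth, cfg)
  fr <- extend_reads(reads, 250, genome)
  ip <- compute_coverage(fr[fr$sample == "IP", ], genome)
  inp <- compute_coverage(fr[fr$sample == "input", ], genome)
  counts <- vapply(c(1, 5, 25, 60, 120, 200),
                   function(md) nrow(call_peaks(ip, inp, min_depth = md)),
                   0)
  expect_true(all(diff(counts) <= 0))
})

test_that("with zero background the summit tracks the planted motif", {
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, n_chroms = 1, chrom_length = 15000,
                      n_genes = 1, frac_bound = 1, frac_bound_with_hre = 1,
                      background_rate = 0, reads_per_sample = 0,
                      bind_rate_control = 300, bind_rate_exposed = 75)
    genome <- generate_genome(cfg)
    genes <- generate_genes(genome, cfg)
    pl <- plant_hre(genome, genes, cfg)
    reads <- simulate_reads(pl$genome, genes, pl$truth, cfg)
    ip <- extend_reads(reads[reads$sample == "IP" &
                               reads$condition == "control", ], 250,
                       genome)
    inp <- reads[reads$sample == "input", ]  # empty at zero background
    peaks <- call_peaks(compute_coverage(ip, genome),
                        compute_coverage(extend_reads(inp, 250, genome),
                                         genome))
    nrow(peaks) == 1 && abs(peaks$summit - pl$truth$motif_pos) <= 300
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("peak summaries conserve totals", {
  s0 <- summarize_peaks(data.frame(chrom = character(), start = numeric(),
                                   end = numeric()))
  expect_equal(s0$n_peaks, 0)
  expect_equal(nrow(s0$length_hist), 0)

  set.seed(8)
  pk <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                   start = sample(0:10000, 40))
  pk$end <- pk$start + sample(50:900, 40, replace = TRUE)
  s <- summarize_peaks(pk)
  expect_equal(sum(s$length_hist$count), 40)
  bf <- table(pk$chrom)
  expect_equal(s$per_chrom$n[match(names(bf), s$per_chrom$chrom)],
               as.numeric(bf))
})
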