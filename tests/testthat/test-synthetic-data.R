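test_that("genome generation is seed-deterministic with declared shapes", {
  cfg <- sim_config(seed = 1, n_chroms = 2, chrom_length = 50000,
                    n_genes = 4)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(names(g1$seq), c("chr1", "chr2"))
  expect_identical(unname(chrom_lengths(g1)), c(50000L, 50000L))
  g3 <- generate_genome(sim_config(seed = 2, n_chroms = 2,
                                   chrom_length = 50000, n_genes = 4))
  expect_false(identical(g1$seq, g3$seq))
})

test_that("base composition of a 1 Mb chromosome is uniform within 1%", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 1e6,
                    n_genes = 0)
  g <- generate_genome(cfg)
  tab <- table(strsplit(g$seq[[1]], "")[[1]])
  expect_setequal(names(tab), c("A", "C", "G", "T"))
  # binomial sd of a base frequency at n = 1e6 is ~4.3e-4; 1% is >20 sd
  expect_true(all(abs(tab / 1e6 - 0.25) < 0.01))
})

test_that("gene layout respects strand/TSS conventions and window spacing", {
  cfg <- tiny_cfg(seed = 3, n_genes = 15)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg)
  expect_equal(nrow(genes), 15)

  plus <- genes$strand == "+"
  expect_equal(genes$tss[plus], genes$start[plus])
  expect_equal(genes$tss[!plus], genes$end[!plus] - 1)

  # promoter windows pairwise disjoint (brute-force check)
  w <- cbind(genes$tss - 2000, genes$tss + 2000)
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(genes))) {
    if (i >= j || genes$chrom[i] != genes$chrom[j]) next
    expect_true(w[i, 2] <= w[j, 1] || w[j, 2] <= w[i, 1])
  }

  # exons: 1-5, sorted, non-overlapping, inside the span
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    expect_true(nrow(ex) >= 1 && nrow(ex) <= 5)
    expect_true(all(ex[, 1] < ex[, 2]))
    expect_true(all(ex[, 1] >= genes$start[i] & ex[, 2] <= genes$end[i]))
    if (nrow(ex) > 1) expect_true(all(ex[-1, 1] >= ex[-nrow(ex), 2]))
  }

  expect_equal(nrow(generate_genes(genome, tiny_cfg(2, n_genes = 0))), 0)
  expect_error(generate_genes(genome, tiny_cfg(2, n_genes = 500)),
               "too small")
})

test_that("HRE planting gives unambiguous promoter truth", {
  cfg <- tiny_cfg(seed = 9)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg)
  pl <- plant_hre(genome, genes, cfg)
  truth <- pl$truth
  expect_equal(nrow(truth), round(cfg$frac_bound * cfg$n_genes))
  expect_true(all(truth$bind_rate_exposed < truth$bind_rate_control))
  expect_true(all(truth$motif_offset >= -2000 & truth$motif_offset < 2000))

  lens <- chrom_lengths(pl$genome)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- max(g$tss - 2000, 0); e <- min(g$tss + 2000, lens[[g$chrom]])
    hits <- scan_hre(extract_region_sequence(pl$genome, g$chrom, s, e))
    if (g$gene_id %in% truth$gene_id[truth$has_hre]) {
      expect_gte(nrow(hits), 1)
    } else {
      expect_equal(nrow(hits), 0)
    }
  }

  # planted k-mer is really at the recorded genomic position
  for (i in seq_len(nrow(truth))) {
    seen <- extract_region_sequence(pl$genome, truth$chrom[i],
                                    truth$motif_pos[i],
                                    truth$motif_pos[i] + 5)
    expected <- if (truth$motif_strand[i] == "+") truth$motif_kmer[i]
      else revcomp(truth$motif_kmer[i])
    expect_identical(seen, expected)
  }

  # no targets requested -> empty truth, HRE-free promoters
  cfg0 <- tiny_cfg(seed = 9, frac_bound = 0, frac_bound_with_hre = 0)
  pl0 <- plant_hre(genome, genes, cfg0)
  expect_equal(nrow(pl0$truth), 0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- max(g$tss - 2000, 0); e <- min(g$tss + 2000, lens[[g$chrom]])
    expect_equal(nrow(scan_hre(extract_region_sequence(pl0$genome,
                                                       g$chrom, s, e))), 0)
  }
})

test_that("read placements satisfy coordinate and scale invariants", {
  cfg <- tiny_cfg(seed = 21)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg)
  pl <- plant_hre(genome, genes, cfg)
  reads <- simulate_reads(pl$genome, genes, pl$truth, cfg)

  lens <- chrom_lengths(genome)
  expect_true(all(reads$start >= 0))
  expect_true(all(reads$start < reads$end))
  expect_true(all(reads$end <= lens[reads$chrom]))
  expect_true(all(reads$end - reads$start <= cfg$read_length))
  expect_setequal(unique(reads$sample), c("IP", "input"))
  expect_setequal(unique(reads$condition), c("control", "exposed"))

  # input read count is Poisson(background_rate * genome length)
  lambda <- cfg$background_rate * sum(lens)
  for (cond in c("control", "exposed")) {
    n_in <- sum(reads$sample == "input" & reads$condition == cond)
    expect_lt(abs(n_in - lambda), 4 * sqrt(lambda))
  }

  # no condition effect => IP signal near bound promoters is symmetric
  cfg_eq <- tiny_cfg(seed = 21, bind_rate_exposed = 300)
  pl_eq <- plant_hre(genome, genes, cfg_eq)
  reads_eq <- simulate_reads(pl_eq$genome, genes, pl_eq$truth, cfg_eq)
  near <- function(cond) {
    r <- reads_eq[reads_eq$sample == "IP" & reads_eq$condition == cond, ]
    sum(vapply(seq_len(nrow(pl_eq$truth)), function(i)
      sum(r$chrom == pl_eq$truth$chrom[i] &
            abs((r$start + r$end) / 2 - pl_eq$truth$motif_pos[i]) < 1000),
      0))
  }
  n_c <- near("control"); n_e <- near("exposed")
  expect_lt(abs(n_c - n_e) / max(n_c, n_e), 0.2)

  expect_error(simulate_reads(genome, genes[0, ], pl$truth,
                              tiny_cfg(1, frac_bound = 0.5)),
               "empty")
})

test_that("bound-promoter enrichment grows monotonically with bind rate", {
  ratios <- vapply(c(20, 100, 400), function(rate) {
    cfg <- tiny_cfg(seed = 31, n_genes = 6, frac_bound = 0.5,
                    frac_bound_with_hre = 0.5, chrom_length = 100000,
                    reads_per_sample = 10000,
                    bind_rate_control = rate, bind_rate_exposed = rate)
    genome <- generate_genome(cfg)
    genes <- generate_genes(genome, cfg)
    pl <- plant_hre(genome, genes, cfg)
    reads <- simulate_reads(pl$genome, genes, pl$truth, cfg)
    ip <- extend_reads(reads[reads$sample == "IP" &
                               reads$condition == "control", ], 250,
                       genome)
    cov <- compute_coverage(ip, genome)
    prom_depth <- mean(vapply(seq_len(nrow(pl$truth)), function(i) {
      d <- cov[[pl$truth$chrom[i]]]$depth
      mean(d[(pl$truth$motif_pos[i] - 250):(pl$truth$motif_pos[i] + 250)])
    }, 0))
    prom_depth / mean(cov[[1]]$depth)
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("datasets round-trip through FASTA/GFF3/BED byte-identically", {
  cfg <- tiny_cfg(seed = 13, n_genes = 6, chrom_length = 60000,
                  reads_per_sample = 3000, n_chroms = 2)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg)
  pl <- plant_hre(genome, genes, cfg)
  reads <- simulate_reads(pl$genome, genes, pl$truth, cfg)

  dir1 <- withr::local_tempdir()
  files <- write_dataset(pl$genome, genes, reads, pl$truth, dir1)
  back <- read_dataset(dir1)

  expect_identical(back$genome$seq, pl$genome$seq)

  # gene table round trip (exon matrices compared per gene)
  expect_identical(back$genes$gene_id, genes$gene_id)
  expect_equal(back$genes$start, genes$start)
  expect_equal(back$genes$end, genes$end)
  expect_equal(back$genes$tss, genes$tss)
  for (i in seq_len(nrow(genes)))
    expect_equal(unname(back$genes$exons[[i]]),
                 unname(genes$exons[[i]]))

  # GFF3 is 1-based closed: file coordinates differ by exactly the shift
  gff <- read.delim(files[["genes"]], header = FALSE, comment.char = "#")
  gene_lines <- gff[gff$V3 == "gene", ]
  ord <- order(gene_lines$V1, gene_lines$V4)
  expect_equal(gene_lines$V4[ord],
               genes$start[order(genes$chrom, genes$start)] + 1)
  expect_equal(gene_lines$V5[ord],
               genes$end[order(genes$chrom, genes$start)])

  # BED line counts equal read counts per sample
  key <- paste0(reads$condition, "-", reads$sample, reads$replicate)
  for (k in unique(key)) {
    expect_equal(length(readLines(file.path(dir1, paste0(k, ".bed")))),
                 sum(key == k))
  }

  # read table round trip
  ord1 <- with(reads, order(condition, sample, replicate, chrom, start,
                            end, strand))
  ord2 <- with(back$reads, order(condition, sample, replicate, chrom,
                                 start, end, strand))
  expect_equal(back$reads[ord2, c("chrom", "start", "end", "strand",
                                  "sample", "condition", "replicate")],
               reads[ord1, c("chrom", "start", "end", "strand", "sample",
                             "condition", "replicate")],
               ignore_attr = TRUE)

  # truth round trip
  expect_equal(back$truth$gene_id, pl$truth$gene_id)
  expect_equal(back$truth$motif_offset, pl$truth$motif_offset)

  # byte-identical rerun
  dir2 <- withr::local_tempdir()
  write_dataset(pl$genome, genes, reads, pl$truth, dir2)
  f1 <- sort(list.files(dir1)); f2 <- sort(list.files(dir2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
})
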