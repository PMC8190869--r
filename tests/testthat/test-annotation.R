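test_that("promoters follow the strand-aware 1500/500 TSS rule", {
  genes <- data.frame(gene_id = c("g+", "g-", "gclip"),
                      gene_name = c("A", "B", "C"),
                      chrom = "chr1",
                      start = c(10000L, 5000L, 100L),
                      end = c(12000L, 10000L, 400L),
                      strand = c("+", "-", "+"),
                      feature = "gene")
  pr <- extract_promoters(genes)
  expect_equal(c(pr$start[1], pr$end[1]), c(8500L, 10500L))
  expect_equal(c(pr$start[2], pr$end[2]), c(9500L, 11500L))
  expect_equal(c(pr$start[3], pr$end[3]), c(1L, 600L))  # clipped at 1
  unclipped <- pr$end - pr$start + 1
  expect_equal(unclipped[1:2], c(2001L, 2001L))
  expect_error(extract_promoters(transform(genes, strand = ".")), "strand")
})

test_that("strand flip reflects each promoter about its TSS", {
  set.seed(17)
  genes <- data.frame(gene_id = paste0("g", 1:30),
                      gene_name = paste0("G", 1:30),
                      chrom = "chr1",
                      start = sort(sample(10000:500000, 30)),
                      strand = sample(c("+", "-"), 30, TRUE),
                      feature = "gene")
  genes$end <- genes$start + 5000L
  pr <- extract_promoters(genes)
  flipped <- transform(genes, strand = ifelse(strand == "+", "-", "+"))
  # put the TSS at the same coordinate after the flip
  flipped$start <- pr$tss; flipped$end <- pr$tss
  pf <- extract_promoters(flipped)
  expect_equal(pf$start - pr$tss, -(pr$end - pr$tss))
  expect_equal(pf$end - pr$tss, -(pr$start - pr$tss))
})

test_that("gene context precedence is promoter > gene body > intergenic", {
  genes <- data.frame(gene_id = c("g1", "g2"), gene_name = c("TNNI2", "OTHER"),
                      chrom = "chr11",
                      start = c(1861800L, 1300000L), end = c(1870000L, 1400000L),
                      strand = "+", feature = "gene")
  pr <- extract_promoters(genes)
  # window overlapping g1's promoter
  expect_equal(unlist(classify_window("chr11", 1861001, 1862000, pr, genes)),
               c(context = "promoter", gene_name = "TNNI2"))
  # window inside g2's body, no promoter overlap
  expect_equal(unlist(classify_window("chr11", 1350001, 1351000, pr, genes)),
               c(context = "gene_body", gene_name = "OTHER"))
  # window on an unannotated chromosome
  expect_equal(unname(unlist(classify_window("chr7", 1, 1000, pr, genes))),
               c("intergenic", NA))
})

test_that("multiple promoter hits resolve to the nearest TSS deterministically", {
  genes <- data.frame(gene_id = c("far", "near"), gene_name = c("FAR", "NEAR"),
                      chrom = "chr1", start = c(9000L, 10400L),
                      end = c(20000L, 20000L), strand = "+", feature = "gene")
  pr <- extract_promoters(genes)
  got <- classify_window("chr1", 10001, 11000, pr, genes)  # midpoint 10500.5
  expect_equal(got$gene_name, "NEAR")
})

test_that("promoter overlap filtering matches a brute-force scan incl. 1-bp touches", {
  set.seed(23)
  W <- 400
  windows <- data.frame(chrom = sample(c("chr1", "chr2"), W, TRUE),
                        start = (sample.int(2000, W, TRUE) - 1L) * 1000L + 1L)
  windows$end <- windows$start + 999L
  windows <- unique(windows)
  genes <- data.frame(gene_id = paste0("g", 1:80),
                      gene_name = paste0("G", 1:80),
                      chrom = sample(c("chr1", "chr2"), 80, TRUE),
                      start = sample(1:2000000, 80),
                      strand = sample(c("+", "-"), 80, TRUE),
                      feature = "gene")
  genes$end <- genes$start + sample(2000:20000, 80)
  pr <- extract_promoters(genes)
  # add exact 1-bp-touch promoters flanking the first window
  touch <- data.frame(gene_id = c("tL", "tR"), gene_name = c("TL", "TR"),
                      chrom = windows$chrom[1],
                      start = c(windows$start[1] - 2000L, windows$end[1]),
                      end = c(windows$start[1], windows$end[1] + 2000L),
                      strand = "+", tss = c(windows$start[1] - 500L,
                                            windows$end[1] + 1500L))
  pr <- rbind(pr, touch)
  kept <- promoter_filter(windows, pr)
  oracle <- overlap_bruteforce(windows, pr)
  expect_equal(window_key(kept$chrom, kept$start, kept$end),
               window_key(windows$chrom[oracle], windows$start[oracle],
                          windows$end[oracle]))
  expect_true(all(window_key(windows$chrom[1], windows$start[1],
                             windows$end[1]) %in%
                    window_key(kept$chrom, kept$start, kept$end)))
  # empty promoter set drops everything
  expect_equal(nrow(promoter_filter(windows, pr[0, ])), 0L)
})

test_that("window classification agrees with the brute-force overlap scan", {
  set.seed(29)
  W <- 500
  windows <- data.frame(chrom = "chr1",
                        start = (sample.int(3000, W) - 1L) * 1000L + 1L)
  windows$end <- windows$start + 999L
  genes <- data.frame(gene_id = sprintf("g%03d", 1:150),
                      gene_name = sprintf("G%03d", 1:150),
                      chrom = "chr1", start = sample(1:3000000, 150),
                      strand = sample(c("+", "-"), 150, TRUE),
                      feature = "gene")
  genes$end <- genes$start + sample(1000:30000, 150)
  pr <- extract_promoters(genes)
  ctx <- classify_windows(windows, pr, genes)
  in_prom <- overlap_bruteforce(windows, pr)
  in_gene <- overlap_bruteforce(windows, genes)
  expect_equal(ctx$context == "promoter", in_prom)
  expect_equal(ctx$context == "gene_body", !in_prom & in_gene)
  expect_equal(ctx$context == "intergenic", !in_prom & !in_gene)
  expect_true(all(is.na(ctx$gene_name[ctx$context == "intergenic"])))
  expect_true(all(!is.na(ctx$gene_name[ctx$context != "intergenic"])))
})
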