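test_that("the pileup dialect is decoded correctly", {
  s <- parse_pileup("chrI\t100\tA\t4\t..,,\tIIII")[[1]]
  expect_equal(s$depth, 4L)
  expect_identical(s$allele, rep("A", 4))
  expect_identical(s$strand, c("+", "+", "-", "-"))
  expect_identical(s$bq, rep(40L, 4))
  expect_identical(s$mq, rep(60L, 4))   # 6-column dialect: assumed high

  # read-start mark with its mapping-quality char is stripped
  s2 <- parse_pileup("chrI\t7\tC\t1\t^].\tF")[[1]]
  expect_identical(s2$allele, "C")
  expect_identical(s2$strand, "+")
  expect_identical(s2$bq, 37L)

  # read-end marks, deletion placeholders, mismatch case
  s3 <- parse_pileup("chrII\t9\tG\t5\t.$TtA,\tIIIII")[[1]]
  expect_identical(s3$allele, c("G", "T", "T", "A", "G"))
  expect_identical(s3$strand, c("+", "+", "-", "+", "-"))

  s4 <- parse_pileup("chrII\t10\tT\t3\t.*,\tIII")[[1]]
  expect_identical(s4$allele, c("T", "*", "T"))

  # indels attach to the anchoring call
  s5 <- parse_pileup("chrIII\t4\tA\t3\t.+2AG,.\tIII")[[1]]
  expect_identical(s5$allele, c("+AG", "A", "A"))
  s6 <- parse_pileup("chrIII\t5\tA\t2\t.-1t,\tII")[[1]]
  expect_identical(s6$allele, c("-T", "A"))

  expect_identical(parse_pileup(character(0)), list())

  expect_error(parse_pileup("chrI\t1\tA\t3\t..\tIII"), "line 1")
  expect_error(parse_pileup("chrI\t1\tA\t2\t..\tIIII"), "quality")
  expect_error(parse_pileup("chrI\t1\tA\t2"), "fewer than 6")
  expect_error(parse_pileup("chrI\t0\tA\t1\t.\tI"), "position")
})

test_that("the site filter applies the published thresholds in order", {
  mk <- function(allele, strand, bq = 40L, mq = 60L) {
    n <- length(allele)
    structure(list(contig = "chrI", pos = 10L, ref = "A", depth = n,
                   allele = allele, strand = strand,
                   bq = rep_len(bq, n), mq = rep_len(mq, n)),
              class = "pileup_site")
  }
  # 9/10 support, 5 forward / 4 reverse: bias 1.25, pass
  site <- mk(c(rep("G", 9), "A"), c(rep("+", 5), rep("-", 5)))
  v <- filter_site(site)
  expect_identical(v$verdict, "pass")
  expect_equal(v$support_fraction, 0.9)
  expect_equal(v$strand_bias, 1.25)

  # 8/10 all forward: both-strands rule fails first
  one_strand <- mk(c(rep("G", 8), "A", "A"),
                   c(rep("+", 8), "-", "-"))
  expect_identical(filter_site(one_strand)$reason, "strand")

  # 4 supporting reads out of 4 quality reads: min_reads fails
  few <- mk(rep("G", 4), c("+", "+", "-", "-"))
  expect_identical(filter_site(few)$reason, "min_reads")

  # fraction fails before anything else
  frac <- mk(c(rep("G", 5), rep("A", 5)),
             rep(c("+", "-"), 5))
  expect_identical(filter_site(frac)$reason, "fraction")

  # bias outside (0.2, 5): 9 supporting reads, 8 forward / 1 reverse
  biased <- mk(c(rep("G", 9), "A"), c(rep("+", 8), "-", "-"))
  expect_identical(filter_site(biased)$reason, "strand_bias")

  # boundary biases are excluded (strict inequalities): 5/1 and 1/5
  hi <- mk(c(rep("G", 6), rep("A", 24)),
           c(rep("+", 5), "-", rep(c("+", "-"), 12)))
  expect_identical(filter_site(hi, min_fraction = 0.1)$reason, "strand_bias")
  lo <- mk(c(rep("G", 6), rep("A", 24)),
           c("-", "+", rep("-", 4), rep(c("+", "-"), 12)))
  expect_identical(filter_site(lo, min_fraction = 0.1)$reason, "strand_bias")

  # quality reads only: low-quality support vanishes before evaluation
  lowq <- mk(c(rep("G", 9), "A"), c(rep("+", 5), rep("-", 5)),
             bq = c(rep(10L, 9), 40L))
  expect_null(filter_site(lowq))
  lowmq <- mk(c(rep("G", 9), "A"), c(rep("+", 5), rep("-", 5)),
              mq = c(rep(5L, 9), 60L))
  expect_null(filter_site(lowmq))

  # all-reference site: nothing to call
  expect_null(filter_site(mk(rep("A", 10), rep(c("+", "-"), 5))))

  # indel alleles go through the same rules
  indel <- mk(c(rep("+AG", 9), "A"), c(rep("+", 5), rep("-", 5)))
  vi <- filter_site(indel)
  expect_identical(vi$verdict, "pass")
  expect_identical(vi$alt, "+AG")
})

test_that("raising any threshold never converts a fail into a pass", {
  set.seed(31)
  severity <- function(v) {
    if (is.null(v)) return(0L)
    match(ifelse(is.na(v$reason), "pass", v$reason),
          c("pass", "strand_bias", "strand", "min_reads", "fraction"))
  }
  for (i in 1:60) {
    depth <- sample(5:20, 1)
    n_alt <- sample(0:depth, 1)
    site <- structure(list(
      contig = "c", pos = 1L, ref = "A", depth = depth,
      allele = sample(c(rep("G", n_alt), rep("A", depth - n_alt))),
      strand = sample(c("+", "-"), depth, replace = TRUE),
      bq = sample(c(20L, 40L), depth, replace = TRUE),
      mq = sample(c(10L, 60L), depth, replace = TRUE)), class = "pileup_site")
    base <- filter_site(site)
    stricter <- list(
      filter_site(site, min_bq = 41), filter_site(site, min_mq = 61),
      filter_site(site, min_fraction = 0.95), filter_site(site, min_reads = 8),
      filter_site(site, bias_low = 0.9, bias_high = 1.1))
    if (is.null(base) || base$verdict == "fail") {
      for (v in stricter)
        expect_false(!is.null(v) && v$verdict == "pass")
    }
  }
})

test_that("whole-genome calling is exact on clean planted truth", {
  lines <- gen_pileup(2000, variant_positions = c(150, 900, 1700), depth = 12,
                      error_rate = 0, seed = 8)
  calls <- call_variants(lines)
  expect_equal(calls$pos, c(150L, 900L, 1700L))
  expect_true(all(calls$verdict == "pass"))

  # perfect recovery holds down to depth 7 with moderate noise
  lines7 <- gen_pileup(5000, variant_positions = c(100, 2500, 4900), depth = 7,
                       error_rate = 0.01, seed = 9)
  calls7 <- call_variants(lines7)
  expect_equal(calls7$pos, c(100L, 2500L, 4900L))

  expect_error(call_variants(rev(lines[1:10])), "sorted")
})

test_that("the VCF writer emits a valid minimal dialect", {
  lines <- gen_pileup(500, variant_positions = c(50, 220), depth = 10,
                      error_rate = 0, seed = 10)
  calls <- call_variants(lines)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  vcf <- readLines(path)
  expect_identical(vcf[1], "##fileformat=VCFv4.2")
  body <- vcf[!startsWith(vcf, "#")]
  expect_length(body, 2)
  fields <- strsplit(body, "\t")
  expect_true(all(lengths(fields) == 8))
  expect_true(all(vapply(fields, `[`, character(1), 7) == "PASS"))
  expect_match(fields[[1]][8], "^DP=10;SR=\\d+;SB=\\d+,\\d+$")

  # empty call set: valid header, empty body
  empty <- call_variants(character(0))
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(empty, path2)
  vcf2 <- readLines(path2)
  expect_true(all(startsWith(vcf2, "#")))
  expect_identical(tail(vcf2, 1),
                   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

  # indel representation: insertion pads ALT, deletion pads REF
  ins <- call_variants(parse_pileup(
    "chrI\t5\tA\t6\t.+2GG,+2gg.+2GG,+2gg.+2GG,\tIIIIII"))
  del <- call_variants(parse_pileup(
    "chrI\t9\tC\t6\t.-1T,-1t.-1T,-1t.-1T,\tIIIIII"))
  path3 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(rbind(ins, del), path3)
  body3 <- grep("^[^#]", readLines(path3), value = TRUE)
  f <- strsplit(body3, "\t")
  expect_identical(f[[1]][4:5], c("A", "AGG"))
  expect_identical(f[[2]][4:5], c("CT", "C"))
})

test_that("pairwise distances follow the SNP/kb definition", {
  parts <- c(chrI = "nuclear", chrII = "nuclear", chrIII = "nuclear",
             chrMT = "mitochondrial")
  comp <- c(nuclear = 1000, mitochondrial = 500)
  mkcalls <- function(pos, alt, contig = "chrI") {
    n <- length(pos)
    df <- data.frame(contig = rep_len(contig, n), pos = pos,
                     ref = rep_len("A", n), alt = alt,
                     verdict = rep_len("pass", n), stringsAsFactors = FALSE)
    class(df) <- c("variant_calls", "data.frame")
    df
  }
  a <- mkcalls(c(100L, 200L, 300L), c("G", "T", "C"))
  none <- mkcalls(integer(0), character(0))

  expect_equal(pairwise_distance(a, a, parts, comp)$distance, c(0, 0))

  d <- pairwise_distance(a, none, parts, comp)
  expect_equal(d$distance[d$partition == "nuclear"], 3.0)
  expect_equal(d$snp_differences[d$partition == "nuclear"], 3)

  # alt-vs-alt at the same position counts once
  b <- mkcalls(100L, "T")
  a1 <- mkcalls(100L, "G")
  expect_equal(sum(pairwise_distance(a1, b, parts, comp)$snp_differences), 1)

  # indels are filtered alike but excluded from SNP distances
  with_indel <- mkcalls(c(100L, 150L), c("G", "+AG"))
  expect_equal(sum(pairwise_distance(with_indel, none, parts,
                                     comp)$snp_differences), 1)

  # unknown contig is an error
  weird <- mkcalls(10L, "G", contig = "chrX")
  expect_error(pairwise_distance(weird, none, parts, comp), "chrX")
})

test_that("distance matrices are symmetric pseudometrics per partition", {
  parts <- c(chrI = "nuclear", chrMT = "mitochondrial")
  comp <- c(nuclear = 10000, mitochondrial = 2000)
  gen_calls <- function(seed) {
    set.seed(seed)
    n <- sample(3:10, 1)
    contig <- sample(names(parts), n, replace = TRUE)
    pos <- sample.int(2000, n)
    df <- data.frame(contig = contig, pos = pos, ref = "A",
                     alt = sample(c("C", "G", "T"), n, replace = TRUE),
                     verdict = "pass", stringsAsFactors = FALSE)
    df <- df[!duplicated(df[c("contig", "pos")]), ]
    df <- df[order(df$contig, df$pos), ]
    class(df) <- c("variant_calls", "data.frame")
    df
  }
  genomes <- lapply(1:4, gen_calls)
  names(genomes) <- paste0("g", 1:4)
  mats <- distance_matrix(genomes, parts, comp)
  for (m in mats) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 4))
    expect_true(all(m >= 0))
  }
  # adding a genome leaves existing entries unchanged
  mats5 <- distance_matrix(c(genomes, list(g5 = gen_calls(99))), parts, comp)
  expect_equal(mats5$nuclear[1:4, 1:4], mats$nuclear)

  expect_error(distance_matrix(genomes[1], parts, comp), "at least 2")

  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(mats$nuclear, path)
  back <- read.csv(path, check.names = FALSE)
  expect_identical(back$strain, paste0("g", 1:4))
  expect_equal(as.matrix(back[, -1]),
               unname(mats$nuclear), ignore_attr = TRUE)
})

test_that("BED partitions assign positions by interval", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t0\t5000\tnuclear",
               "chrII\t0\t1000\tnuclear",
               "chrII\t1000\t1400\tmating",
               "chrMT\t0\t800\tmitochondrial"), bed)
  parts <- read_partition_bed(bed)
  comp <- c(nuclear = 6000, mating = 400, mitochondrial = 800)
  mk <- function(contig, pos) {
    n <- length(pos)
    df <- data.frame(contig = contig, pos = pos, ref = rep_len("A", n),
                     alt = rep_len("G", n), verdict = rep_len("pass", n),
                     stringsAsFactors = FALSE)
    class(df) <- c("variant_calls", "data.frame")
    df
  }
  none <- mk(character(0), integer(0))
  # position 1200 on chrII falls in the mating interval (1001..1400, 1-based)
  d <- pairwise_distance(mk("chrII", 1200L), none, parts, comp)
  expect_equal(d$snp_differences[d$partition == "mating"], 1)
  expect_equal(d$distance[d$partition == "mating"], 1000 / 400)
  # position 1000 is still nuclear
  d2 <- pairwise_distance(mk("chrII", 1000L), none, parts, comp)
  expect_equal(d2$snp_differences[d2$partition == "nuclear"], 1)
  expect_error(pairwise_distance(mk("chrII", 5000L), none, parts, comp),
               "not covered")
})
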