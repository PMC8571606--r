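#' Parse samtools mpileup text
#'
#' Reads the 6-column samtools pileup dialect (chrom, 1-based position,
#' reference base, depth, read bases, base qualities), decoding strand from
#' case (`.`/uppercase = forward, `,`/lowercase = reverse), stripping `^X`
#' read-start marks (with their mapping-quality character) and `$` read-end
#' marks, attaching `+n`/`-n` indel strings to the anchoring call, and keeping
#' `*` deletion placeholders as non-allele calls. An optional 7th column of
#' per-read mapping qualities (the `samtools mpileup -s` dialect, phred+33)
#' is used when present; otherwise every read gets mapping quality 60.
#'
#' @param x Path to an mpileup file, or a character vector of mpileup lines.
#' @return List of `pileup_site` objects: each a list with `contig`, `pos`,
#'   `ref`, `depth`, and parallel vectors `allele` (base, `+SEQ`, `-SEQ`, or
#'   `*`), `strand` (`"+"`/`"-"`), `bq`, `mq`.
#' @export
parse_pileup <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed mpileup line ", which(nf < 6L)[1], ": fewer than 6 fields")
  lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    site <- try(parse_pileup_record(f), silent = TRUE)
    if (inherits(site, "try-error"))
      stop("malformed mpileup line ", i, ": ",
           attr(site, "condition")$message, call. = FALSE)
    site
  })
}

parse_pileup_record <- function(f) {
  contig <- f[1]
  pos <- suppressWarnings(as.integer(f[2]))
  if (is.na(pos) || pos < 1) stop("invalid position '", f[2], "'")
  ref <- toupper(f[3])
  depth <- suppressWarnings(as.integer(f[4]))
  if (is.na(depth)) stop("invalid depth '", f[4], "'")
  bases <- f[5]
  quals <- f[6]
  mq_str <- if (length(f) >= 7L) f[7] else NULL

  if (!grepl("[\\^$+*-]", bases)) {
    # fast path: no marks, indels or deletion placeholders
    ch <- strsplit(bases, "", fixed = TRUE)[[1]]
    if (length(ch) != depth)
      stop("depth field says ", depth, " but ", length(ch), " calls parsed")
    up <- toupper(ch)
    bad <- !(ch %in% c(".", ",") | up %in% c("A", "C", "G", "T", "N"))
    if (any(bad)) stop("unexpected pileup character '", ch[bad][1], "'")
    allele <- ifelse(ch == "." | ch == ",", ref, up)
    strand <- ifelse(ch == "." | ch %in% c("A", "C", "G", "T", "N"), "+", "-")
    bq <- utf8ToInt(quals) - 33L
    if (length(bq) != depth)
      stop("base-quality string length ", length(bq), " != depth ", depth)
    mq <- if (is.null(mq_str)) rep(60L, depth) else utf8ToInt(mq_str) - 33L
    if (length(mq) != depth)
      stop("mapping-quality string length ", length(mq), " != depth ", depth)
    return(structure(list(contig = contig, pos = pos, ref = ref, depth = depth,
                          allele = allele, strand = strand, bq = bq, mq = mq),
                     class = "pileup_site"))
  }
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  allele <- character(depth); strand <- character(depth)
  k <- 0L; j <- 1L; n <- length(ch)
  while (j <= n) {
    c0 <- ch[j]
    if (c0 == "^") { j <- j + 2L; next }    # start mark + mapq char
    if (c0 == "$") { j <- j + 1L; next }    # end mark
    if (c0 == "+" || c0 == "-") {
      # indel attached to the previous call
      if (k == 0L) stop("indel with no anchoring call")
      j <- j + 1L
      num <- ""
      while (j <= n && ch[j] >= "0" && ch[j] <= "9") { num <- paste0(num, ch[j]); j <- j + 1L }
      len <- as.integer(num)
      if (is.na(len) || j + len - 1L > n) stop("truncated indel")
      seq <- paste(ch[j:(j + len - 1L)], collapse = "")
      j <- j + len
      allele[k] <- paste0(c0, toupper(seq))
      next
    }
    k <- k + 1L
    if (k > depth) stop("more calls than the stated depth")
    if (c0 == ".") { allele[k] <- ref; strand[k] <- "+" }
    else if (c0 == ",") { allele[k] <- ref; strand[k] <- "-" }
    else if (c0 == "*") { allele[k] <- "*"; strand[k] <- "+" }
    else if (c0 %in% c("A", "C", "G", "T", "N")) { allele[k] <- c0; strand[k] <- "+" }
    else if (c0 %in% c("a", "c", "g", "t", "n")) { allele[k] <- toupper(c0); strand[k] <- "-" }
    else stop("unexpected pileup character '", c0, "'")
    j <- j + 1L
  }
  if (k != depth)
    stop("depth field says ", depth, " but ", k, " calls parsed")
  bq <- utf8ToInt(quals) - 33L
  if (length(bq) != depth)
    stop("base-quality string length ", length(bq), " != depth ", depth)
  mq <- if (is.null(mq_str)) rep(60L, depth) else utf8ToInt(mq_str) - 33L
  if (length(mq) != depth)
    stop("mapping-quality string length ", length(mq), " != depth ", depth)
  structure(list(contig = contig, pos = pos, ref = ref, depth = depth,
                 allele = allele, strand = strand, bq = bq, mq = mq),
            class = "pileup_site")
}

#' Apply the naive variant filter to one pileup site
#'
#' Reads failing the mapping-quality or base-quality cut are discarded first
#' ("quality reads"). Among the remaining reads the best-supported
#' non-reference allele (SNP base or indel) is evaluated against, in order:
#' support fraction `>= min_fraction`, supporting reads `>= min_reads`,
#' support on both strands, and forward/reverse strand bias strictly inside
#' `(bias_low, bias_high)`. The verdict carries the first failing reason.
#' Defaults are the pipeline's published thresholds: MQ 20, BQ 30, 80%
#' support, 5 reads, bias in (0.2, 5.0).
#'
#' @param site A `pileup_site` from [parse_pileup()].
#' @param min_mq,min_bq Minimum per-read mapping/base quality.
#' @param min_fraction Minimum fraction of quality reads supporting the
#'   variant.
#' @param min_reads Minimum number of supporting quality reads.
#' @param bias_low,bias_high Open interval the forward/reverse support ratio
#'   must fall in; zero reverse support counts as infinite bias.
#' @return A `variant_call` (list with `contig`, `pos`, `ref`, `alt`,
#'   `depth`, `quality_reads`, `supporting_reads`, `support_fraction`,
#'   `fwd`, `rev`, `strand_bias`, `verdict` = `"pass"`/`"fail"`, `reason`),
#'   or `NULL` when no non-reference allele remains after quality filtering.
#' @export
filter_site <- function(site, min_mq = 20, min_bq = 30, min_fraction = 0.80,
                        min_reads = 5, bias_low = 0.2, bias_high = 5.0) {
  stopifnot(inherits(site, "pileup_site"))
  keep <- site$bq >= min_bq & site$mq >= min_mq
  if (!any(keep)) return(NULL)
  allele <- site$allele[keep]
  strand <- site$strand[keep]
  nonref <- allele != site$ref & allele != "*" & allele != "N"
  if (!any(nonref)) return(NULL)
  tab <- sort(table(allele[nonref]), decreasing = TRUE)
  top <- max(tab)
  alt <- sort(names(tab)[tab == top])[1]   # deterministic tie-break
  sup <- allele == alt
  n_quality <- sum(keep)
  n_sup <- sum(sup)
  fwd <- sum(sup & strand == "+")
  rev <- n_sup - fwd
  frac <- n_sup / n_quality
  bias <- if (rev == 0) Inf else fwd / rev
  reason <- if (frac < min_fraction) "fraction"
            else if (n_sup < min_reads) "min_reads"
            else if (fwd == 0 || rev == 0) "strand"
            else if (!(bias > bias_low && bias < bias_high)) "strand_bias"
            else NA_character_
  structure(list(contig = site$contig, pos = site$pos, ref = site$ref,
                 alt = alt, depth = site$depth, quality_reads = n_quality,
                 supporting_reads = n_sup, support_fraction = frac,
                 fwd = fwd, rev = rev, strand_bias = bias,
                 verdict = if (is.na(reason)) "pass" else "fail",
                 reason = reason),
            class = "variant_call")
}

#' Call variants across a pileup stream
#'
#' Applies [filter_site()] to every site of a (sorted) pileup and collects the
#' verdicts in a tidy table.
#'
#' @param x Pileup input: a file path, mpileup lines, or a list of
#'   `pileup_site` objects.
#' @param ... Threshold arguments passed to [filter_site()].
#' @param include_fails Keep filtered-out candidate variants (verdict
#'   `"fail"`) in the result? Default `FALSE`.
#' @return A `variant_calls` data.frame (possibly 0-row) with columns
#'   `contig`, `pos`, `ref`, `alt`, `depth`, `quality_reads`,
#'   `supporting_reads`, `support_fraction`, `fwd`, `rev`, `strand_bias`,
#'   `verdict`, `reason`.
#' @export
call_variants <- function(x, ..., include_fails = FALSE) {
  sites <- if (is.list(x) && (length(x) == 0L || inherits(x[[1]], "pileup_site")))
    x else parse_pileup(x)
  if (length(sites)) {
    key_contig <- vapply(sites, `[[`, character(1), "contig")
    key_pos <- vapply(sites, `[[`, integer(1), "pos")
    o <- order(key_contig, key_pos)
    if (!identical(o, seq_along(sites)))
      stop("pileup input must be sorted by contig then position")
  }
  calls <- lapply(sites, filter_site, ...)
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!include_fails)
    calls <- calls[vapply(calls, function(cl) cl$verdict == "pass", logical(1))]
  empty <- data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      quality_reads = integer(), supporting_reads = integer(),
                      support_fraction = numeric(), fwd = integer(),
                      rev = integer(), strand_bias = numeric(),
                      verdict = character(), reason = character(),
                      stringsAsFactors = FALSE)
  out <- if (length(calls))
    do.call(rbind, lapply(calls, function(cl)
      data.frame(cl[setdiff(names(cl), NULL)], stringsAsFactors = FALSE)))
  else empty
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Write variant calls as minimal VCF
#'
#' Emits a VCF 4.2 body with `DP` (site depth), `SR` (supporting reads) and
#' `SB` (forward,reverse support) INFO fields. Insertions are written as
#' `REF -> REF+SEQ`, deletions as `REF+SEQ -> REF`. Failing calls (if present
#' in the table) carry their reason in the FILTER column.
#'
#' @param calls A `variant_calls` table from [call_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=strainfate naive pileup filter",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site read depth\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Reads supporting ALT\">",
    "##INFO=<ID=SB,Number=2,Type=Integer,Description=\"ALT support forward,reverse\">",
    "##FILTER=<ID=fraction,Description=\"Support fraction below threshold\">",
    "##FILTER=<ID=min_reads,Description=\"Too few supporting reads\">",
    "##FILTER=<ID=strand,Description=\"Support missing on one strand\">",
    "##FILTER=<ID=strand_bias,Description=\"Strand bias outside accepted interval\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls)) {
    refalt <- vcf_ref_alt(calls$ref, calls$alt)
    filt <- ifelse(calls$verdict == "pass", "PASS", calls$reason)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;SR=%d;SB=%d,%d",
                    calls$contig, calls$pos, refalt$ref, refalt$alt, filt,
                    calls$depth, calls$supporting_reads, calls$fwd, calls$rev)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

vcf_ref_alt <- function(ref, alt) {
  ins <- startsWith(alt, "+")
  del <- startsWith(alt, "-")
  out_ref <- ifelse(del, paste0(ref, sub("^-", "", alt)), ref)
  out_alt <- ifelse(ins, paste0(ref, sub("^\\+", "", alt)),
                    ifelse(del, ref, alt))
  list(ref = out_ref, alt = out_alt)
}

#' Read a partition definition from BED
#'
#' BED rows (contig, 0-based start, end, partition name) assigning genome
#' regions to the distance partitions (nuclear, mitochondrial, mating).
#'
#' @param path BED file path (tab-separated, at least 4 columns, no header).
#' @return data.frame with `contig`, `start`, `end` (1-based inclusive),
#'   `partition`.
#' @export
read_partition_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("partition BED needs 4 columns: contig, start, end, name")
  data.frame(contig = df[[1]], start = df[[2]] + 1L, end = df[[3]],
             partition = df[[4]], stringsAsFactors = FALSE)
}

partition_lookup <- function(partitions) {
  if (is.character(partitions) && !is.null(names(partitions))) {
    force(partitions)
    return(function(contig, pos) {
      p <- partitions[contig]
      if (any(is.na(p)))
        stop("contig(s) absent from partition map: ",
             paste(unique(contig[is.na(p)]), collapse = ", "))
      unname(p)
    })
  }
  if (is.data.frame(partitions)) {
    return(function(contig, pos) {
      vapply(seq_along(contig), function(i) {
        hit <- which(partitions$contig == contig[i] &
                     partitions$start <= pos[i] & partitions$end >= pos[i])
        if (!length(hit))
          stop("position ", contig[i], ":", pos[i],
               " not covered by the partition definition")
        partitions$partition[hit[1]]
      }, character(1))
    })
  }
  stop("'partitions' must be a named character vector (contig -> partition) ",
       "or a BED-derived data.frame")
}

snp_set <- function(calls) {
  is_snp <- calls$verdict == "pass" & calls$alt %in% c("A", "C", "G", "T")
  calls[is_snp, c("contig", "pos", "alt"), drop = FALSE]
}

#' Pairwise partitioned genomic distance
#'
#' Counts single-nucleotide differences between two call sets made against the
#' same reference: positions where exactly one genome carries a passing SNP,
#' plus positions where both carry different alternative alleles (one
#' difference each). Indels pass through the same filter but are excluded from
#' distances. Each partition's count is scaled to SNPs per kilobase by the
#' supplied number of comparable bases (positions adequately covered in both
#' genomes -- supplied by the caller, since coverage is not visible to this
#' operation).
#'
#' @param calls_a,calls_b `variant_calls` tables from [call_variants()].
#' @param partitions Named character vector (contig -> partition) or
#'   BED-derived data.frame from [read_partition_bed()].
#' @param comparable_bases Named numeric vector of comparable bases per
#'   partition (> 0).
#' @return data.frame with `partition`, `snp_differences`, `compared_bases`,
#'   `distance` (SNP/kb).
#' @export
pairwise_distance <- function(calls_a, calls_b, partitions, comparable_bases) {
  if (is.null(names(comparable_bases)))
    stop("'comparable_bases' must be named by partition")
  if (any(comparable_bases <= 0))
    stop("'comparable_bases' must be positive")
  lookup <- partition_lookup(partitions)
  a <- snp_set(calls_a); b <- snp_set(calls_b)
  key_a <- paste(a$contig, a$pos, sep = ":")
  key_b <- paste(b$contig, b$pos, sep = ":")
  only_a <- !(key_a %in% key_b)
  only_b <- !(key_b %in% key_a)
  shared <- match(key_b, key_a)
  diff_shared <- !is.na(shared) & b$alt != a$alt[ifelse(is.na(shared), 1L, shared)]
  diffs <- rbind(a[only_a, ], b[only_b | diff_shared, ])
  parts <- names(comparable_bases)
  n_diff <- stats::setNames(numeric(length(parts)), parts)
  if (nrow(diffs)) {
    p <- lookup(diffs$contig, diffs$pos)
    unknown <- setdiff(unique(p), parts)
    if (length(unknown))
      stop("no comparable-base count for partition(s): ",
           paste(unknown, collapse = ", "))
    tb <- table(p)
    n_diff[names(tb)] <- as.numeric(tb)
  }
  data.frame(partition = parts, snp_differences = unname(n_diff),
             compared_bases = unname(comparable_bases[parts]),
             distance = unname(1000 * n_diff / comparable_bases[parts]),
             stringsAsFactors = FALSE)
}

#' Partitioned pairwise distance matrices for a set of genomes
#'
#' @param genomes Named list of `variant_calls` tables (>= 2), all called
#'   against the same reference.
#' @param partitions,comparable_bases As in [pairwise_distance()].
#' @return Named list of symmetric zero-diagonal matrices (SNP/kb), one per
#'   partition.
#' @export
distance_matrix <- function(genomes, partitions, comparable_bases) {
  if (length(genomes) < 2L)
    stop("at least 2 genomes are required")
  if (is.null(names(genomes)))
    names(genomes) <- paste0("genome", seq_along(genomes))
  n <- length(genomes)
  parts <- names(comparable_bases)
  mats <- lapply(parts, function(p)
    matrix(0, n, n, dimnames = list(names(genomes), names(genomes))))
  names(mats) <- parts
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- pairwise_distance(genomes[[i]], genomes[[j]], partitions,
                           comparable_bases)
    for (p in parts) {
      v <- d$distance[d$partition == p]
      mats[[p]][i, j] <- v
      mats[[p]][j, i] <- v
    }
  }
  mats
}

#' Write a distance matrix to CSV
#'
#' Strain-by-strain layout with a leading `strain` column.
#'
#' @param mat A matrix from [distance_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(mat, path) {
  df <- data.frame(strain = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
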