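#' Derive promoter regions from gene records
#'
#' A promoter is the interval from `upstream` bp upstream to `downstream`
#' bp downstream of the transcription start site (TSS), strand-aware: for a
#' plus-strand gene the TSS is the gene start and the promoter is
#' `[TSS - upstream, TSS + downstream]`; for a minus-strand gene the TSS is
#' the gene end and the promoter is `[TSS - downstream, TSS + upstream]`.
#' Coordinates are clipped at 1.
#'
#' @param genes Data frame of annotation records (see [read_gtf_genes()]);
#'   rows with `feature == "gene"` are used by default.
#' @param upstream,downstream Promoter extent in bp (defaults 1500/500).
#' @param feature Which feature level defines a TSS: `"gene"` (one promoter
#'   per gene, default) or `"transcript"`.
#' @return Data frame with `gene_id`, `gene_name`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
extract_promoters <- function(genes, upstream = 1500, downstream = 500,
                              feature = c("gene", "transcript")) {
  feature <- match.arg(feature)
  if ("feature" %in% names(genes)) {
    genes <- genes[genes$feature == feature, , drop = FALSE]
  }
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), tss = integer()))
  }
  if (any(!(genes$strand %in% c("+", "-"))))
    stop("gene records must carry strand '+' or '-'")
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  start <- ifelse(plus, tss - upstream, tss - downstream)
  end <- ifelse(plus, tss + downstream, tss + upstream)
  data.frame(gene_id = genes$gene_id, gene_name = genes$gene_name,
             chrom = genes$chrom,
             start = as.integer(pmax(1, start)), end = as.integer(end),
             strand = genes$strand, tss = as.integer(tss))
}

.as_granges <- function(df, seqlevels = unique(df$chrom)) {
  GenomicRanges::GRanges(factor(df$chrom, levels = seqlevels),
                         IRanges::IRanges(df$start, df$end))
}

# overlap hits between two interval tables on a shared chromosome namespace
.overlap_hits <- function(a, b) {
  lv <- union(unique(a$chrom), unique(b$chrom))
  GenomicRanges::findOverlaps(.as_granges(a, lv), .as_granges(b, lv))
}

#' Classify windows by gene context
#'
#' Assigns each window a gene context with precedence
#' promoter > gene body > intergenic, where overlap means at least one
#' shared base between 1-based inclusive intervals. When a window overlaps
#' several promoters, the gene whose TSS is nearest to the window midpoint
#' is reported (ties broken by lexicographic `gene_id`); the same rule
#' applies to multiple gene-body hits using the gene start.
#'
#' @param windows Data frame with `chrom`, `start`, `end`.
#' @param promoters Promoter data frame from [extract_promoters()].
#' @param genes Gene records (rows with `feature == "gene"` are used);
#'   may be `NULL` to classify promoter vs intergenic only.
#' @return Data frame with `context` (`"promoter"`, `"gene_body"`,
#'   `"intergenic"`) and `gene_name` (`NA` for intergenic), one row per
#'   window, input order.
#' @export
classify_windows <- function(windows, promoters, genes = NULL) {
  n <- nrow(windows)
  context <- rep("intergenic", n)
  gene_name <- rep(NA_character_, n)
  if (n == 0L) return(data.frame(context = context, gene_name = gene_name))
  mid <- (windows$start + windows$end) / 2

  pick <- function(hits, ref_pos, ids, names_) {
    # nearest ref_pos to window midpoint, then lexicographic gene_id
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    d <- abs(ref_pos[sh] - mid[qh])
    ord <- order(qh, d, ids[sh])
    qh <- qh[ord]; sh <- sh[ord]
    first <- !duplicated(qh)
    list(q = qh[first], name = names_[sh[first]])
  }

  if (!is.null(promoters) && nrow(promoters) > 0L) {
    hits <- .overlap_hits(windows, promoters)
    if (length(hits) > 0L) {
      sel <- pick(hits, promoters$tss, promoters$gene_id, promoters$gene_name)
      context[sel$q] <- "promoter"
      gene_name[sel$q] <- sel$name
    }
  }
  if (!is.null(genes) && nrow(genes) > 0L) {
    if ("feature" %in% names(genes))
      genes <- genes[genes$feature == "gene", , drop = FALSE]
    todo <- context == "intergenic"
    if (any(todo) && nrow(genes) > 0L) {
      hits <- .overlap_hits(windows, genes)
      hits <- hits[todo[S4Vectors::queryHits(hits)]]
      if (length(hits) > 0L) {
        sel <- pick(hits, genes$start, genes$gene_id, genes$gene_name)
        context[sel$q] <- "gene_body"
        gene_name[sel$q] <- sel$name
      }
    }
  }
  data.frame(context = context, gene_name = gene_name)
}

#' Classify a single window
#'
#' @param chrom,start,end Window coordinates (1-based inclusive).
#' @param promoters,genes As in [classify_windows()].
#' @return A one-row data frame with `context` and `gene_name`.
#' @export
classify_window <- function(chrom, start, end, promoters, genes = NULL) {
  classify_windows(data.frame(chrom = chrom, start = start, end = end),
                   promoters, genes)
}

#' Keep DMRs whose window overlaps at least one promoter
#'
#' Overlap is >= 1 shared base between the 1-based inclusive window and
#' promoter intervals.
#'
#' @param dmrs DMR result data frame (needs `chrom`, `start`, `end`).
#' @param promoters Promoter data frame from [extract_promoters()].
#' @return The overlapping rows, input order preserved.
#' @export
promoter_filter <- function(dmrs, promoters) {
  if (nrow(dmrs) == 0L || is.null(promoters) || nrow(promoters) == 0L)
    return(dmrs[integer(0), , drop = FALSE])
  hits <- .overlap_hits(dmrs, promoters)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  dmrs[keep, , drop = FALSE]
}

#' Export promoters as BED (0-based half-open)
#'
#' Convenience for cross-checking overlap semantics against bedtools.
#'
#' @param promoters Promoter data frame.
#' @param path Output path.
#' @export
write_promoters_bed <- function(promoters, path) {
  bed <- data.frame(chrom = promoters$chrom,
                    start = promoters$start - 1L,
                    end = promoters$end,
                    name = promoters$gene_id,
                    score = 0L,
                    strand = promoters$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
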