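#' Read a Bismark coverage file
#'
#' Parses the 6-column per-cytosine coverage output of the Bismark bisulfite
#' aligner (chrom, start, end, percent methylation, methylated count,
#' unmethylated count). The percent column is ignored and methylation is
#' always recomputed from the counts; `start` is taken as the 1-based
#' position of the cytosine (files with `end = start` or `end = start + 1`
#' are both accepted). Plain and gzip-compressed files are handled
#' transparently.
#'
#' @param path Path to a `.cov` or `.cov.gz` file.
#' @return A data frame with columns `chrom`, `pos`, `meth` and `unmeth`,
#'   one row per input line, in file order.
#' @export
read_bismark_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer()))
  }
  bad <- which(nf != 6L)
  if (length(bad) > 0L) {
    stop("malformed Bismark coverage line ", bad[1L], " in ", path,
         ": expected 6 tab-separated columns, found ", nf[bad[1L]])
  }
  x <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                         colClasses = c("character", "integer", "integer",
                                        "numeric", "integer", "integer"))
  if (any(x[[5L]] < 0L) || any(x[[6L]] < 0L)) {
    stop("negative read counts in ", path)
  }
  data.frame(chrom = x[[1L]], pos = x[[2L]],
             meth = x[[5L]], unmeth = x[[6L]])
}

.tissue_levels <- c("primary", "adjacent", "metastatic")
.stage_levels  <- c("adjacent", "I", "II", "IV")

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Read a cohort sample sheet
#'
#' Reads the tab-separated sample sheet that carries all group labels used
#' by the pipeline: tissue type, tumor stage, prognosis, liver/lung
#' metastasis status and survival follow-up. The sheet is the single source
#' of truth for sample metadata; methylome files are linked by `sample_id`.
#'
#' Required columns: `sample_id`, `patient_id`, `tissue`, `stage`. Optional
#' columns (`prognosis`, `lim`, `lum`, `followup_days`, `lim_event`, `age`,
#' `sex`, `smoker`) are filled with `NA` when absent.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data frame with one validated row per sample.
#' @export
read_sample_sheet <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  req <- c("sample_id", "patient_id", "tissue", "stage")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L) stop("sample sheet missing columns: ",
                              paste(miss, collapse = ", "))
  validate_sample_sheet(x)
}

#' Validate a cohort sample sheet
#'
#' Checks uniqueness of sample ids, the tissue/stage vocabularies and the
#' constraint that tumor-adjacent tissue carries stage `"adjacent"`, and
#' coerces the optional columns to their canonical types.
#'
#' @param x A data frame of sample metadata.
#' @return The validated (and type-coerced) data frame.
#' @export
validate_sample_sheet <- function(x) {
  x$sample_id <- as.character(x$sample_id)
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0L) stop("duplicate sample_id: ",
                             paste(unique(dup), collapse = ", "))
  bad <- which(!(x$tissue %in% .tissue_levels))
  if (length(bad) > 0L) stop("unknown tissue '", x$tissue[bad[1L]],
                             "' in sample sheet row ", bad[1L])
  bad <- which(!(x$stage %in% .stage_levels))
  if (length(bad) > 0L) stop("unknown stage '", x$stage[bad[1L]],
                             "' in sample sheet row ", bad[1L])
  bad <- which(x$tissue == "adjacent" & x$stage != "adjacent")
  if (length(bad) > 0L) stop("tissue 'adjacent' requires stage 'adjacent' ",
                             "(sample sheet row ", bad[1L], ")")
  bad <- which(x$stage == "adjacent" & x$tissue != "adjacent")
  if (length(bad) > 0L) stop("stage 'adjacent' requires tissue 'adjacent' ",
                             "(sample sheet row ", bad[1L], ")")
  opt <- c("prognosis", "lim", "lum", "followup_days", "lim_event",
           "age", "sex", "smoker")
  for (col in setdiff(opt, names(x))) x[[col]] <- NA
  if (!all(is.na(x$prognosis) | x$prognosis %in% c("favorable", "unfavorable")))
    stop("prognosis must be favorable/unfavorable/NA")
  if (!all(is.na(x$sex) | x$sex %in% c("male", "female")))
    stop("sex must be male/female/NA")
  if (!all(is.na(x$smoker) | x$smoker %in% c("yes", "no")))
    stop("smoker must be yes/no/NA")
  x$lim <- .as_flag(x$lim)
  x$lum <- .as_flag(x$lum)
  x$lim_event <- .as_flag(x$lim_event)
  x$followup_days <- as.numeric(x$followup_days)
  if (any(!is.na(x$followup_days) & x$followup_days < 0))
    stop("followup_days must be non-negative")
  x$age <- as.numeric(x$age)
  x
}

#' Read gene and transcript records from a GTF annotation
#'
#' Imports a GENCODE-dialect GTF and keeps only `gene` and `transcript`
#' features, returning their 1-based inclusive coordinates exactly as in
#' the file together with strand, `gene_id` and `gene_name`.
#'
#' @param path Path to a GTF file (plain or gzipped).
#' @param features Feature types to retain.
#' @return A data frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`, `feature`.
#' @export
read_gtf_genes <- function(path, features = c("gene", "transcript")) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type %in% features]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), feature = character()))
  }
  gid <- S4Vectors::mcols(gr)$gene_id
  if (is.null(gid) || anyNA(gid))
    stop("GTF gene/transcript record without a gene_id attribute in ", path)
  gname <- S4Vectors::mcols(gr)$gene_name
  if (is.null(gname)) gname <- gid
  gname[is.na(gname)] <- gid[is.na(gname)]
  data.frame(
    gene_id = as.character(gid),
    gene_name = as.character(gname),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(S4Vectors::mcols(gr)$type)
  )
}

.dmr_cols <- c("chrom", "start", "end", "meth_diff", "p", "q",
               "direction", "gene_context", "gene_name")

#' Write a DMR table
#'
#' Serializes a DMR result table as TSV with 1-based inclusive window
#' coordinates, matching the `chr11:1861001-1862000` window naming used
#' throughout the package. Missing annotation columns are written as `NA`.
#'
#' @param dmrs A DMR result data frame (see [dmr_test()]).
#' @param path Output path.
#' @export
write_dmr_table <- function(dmrs, path) {
  out <- dmrs
  for (col in setdiff(.dmr_cols, names(out))) out[[col]] <- rep(NA, nrow(out))
  out <- out[, .dmr_cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a DMR table written by [write_dmr_table()]
#'
#' @param path Path to the TSV file.
#' @return A DMR result data frame.
#' @export
read_dmr_table <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "NA")
  miss <- setdiff(.dmr_cols, names(x))
  if (length(miss) > 0L) stop("DMR table missing columns: ",
                              paste(miss, collapse = ", "))
  x$chrom <- as.character(x$chrom)
  if ("gene_name" %in% names(x)) x$gene_name <- as.character(x$gene_name)
  if ("gene_context" %in% names(x)) x$gene_context <- as.character(x$gene_context)
  x
}

#' Format window keys
#'
#' @param chrom,start,end Window coordinates (1-based inclusive).
#' @return Character keys of the form `"chrom:start-end"`.
#' @export
window_key <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}
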