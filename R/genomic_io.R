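#' @importFrom methods is
#' @importFrom utils read.delim write.table
NULL

.PEAK_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                "signal", "pvalue_neglog10", "qvalue_neglog10",
                "summit_offset")

.dialect_ncol <- c(bed6 = 6L, narrowPeak = 10L, broadPeak = 9L)

#' Read genomic intervals in BED-family dialects
#'
#' Parses BED6, ENCODE narrowPeak (BED6+4) or broadPeak (BED6+3) files into a
#' peak data frame. Coordinates are 0-based half-open throughout the package.
#' Lines starting with `#`, `track` or `browser` are skipped. A `"."` score is
#' parsed as 0. For narrowPeak, column 10 is the summit offset from `start`;
#' the MACS2 sentinel `-1` maps to `NA` (summit absent), in which case
#' downstream summit consumers fall back to the interval midpoint.
#'
#' @param path Path to the interval file.
#' @param dialect One of `"bed6"`, `"narrowPeak"`, `"broadPeak"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal`, `pvalue_neglog10`, `qvalue_neglog10`,
#'   `summit_offset` (columns absent from the dialect are `NA`), rows in file
#'   order.
#' @export
read_intervals <- function(path, dialect = c("narrowPeak", "broadPeak", "bed6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  want <- .dialect_ncol[[dialect]]
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != want)) {
    bad <- which(nf != want)[1L]
    stop(sprintf("line %d: expected %d columns for %s, got %d",
                 idx[bad], want, dialect, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  num <- function(j, what) {
    x <- m[, j]
    x[x == "."] <- "0"
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("line %d: non-numeric %s field '%s'",
                   idx[bad], what, m[bad, j]))
    }
    v
  }
  start <- num(2L, "start"); end <- num(3L, "end")
  if (any(start < 0 | end < 0)) {
    bad <- which(start < 0 | end < 0)[1L]
    stop(sprintf("line %d: negative coordinate", idx[bad]))
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("line %d: start >= end (%d >= %d)",
                 idx[bad], as.integer(start[bad]), as.integer(end[bad])))
  }
  df <- data.frame(
    chrom = m[, 1L], start = as.integer(start), end = as.integer(end),
    name = m[, 4L], score = num(5L, "score"), strand = m[, 6L],
    signal = NA_real_, pvalue_neglog10 = NA_real_, qvalue_neglog10 = NA_real_,
    summit_offset = NA_integer_, stringsAsFactors = FALSE
  )
  if (dialect %in% c("narrowPeak", "broadPeak")) {
    df$signal <- num(7L, "signalValue")
    df$pvalue_neglog10 <- num(8L, "pValue")
    df$qvalue_neglog10 <- num(9L, "qValue")
  }
  if (dialect == "narrowPeak") {
    so <- as.integer(num(10L, "summit"))
    so[so < 0L] <- NA_integer_
    bad <- which(!is.na(so) & df$start + so >= df$end)
    if (length(bad))
      stop(sprintf("line %d: summit offset %d outside peak", idx[bad[1L]], so[bad[1L]]))
    df$summit_offset <- so
  }
  df
}

#' Write genomic intervals in BED-family dialects
#'
#' Inverse of [read_intervals()]; absent summits are written as `-1` per the
#' narrowPeak convention.
#'
#' @param peaks Peak data frame as returned by [read_intervals()].
#' @param path Output path.
#' @param dialect One of `"bed6"`, `"narrowPeak"`, `"broadPeak"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(peaks, path, dialect = c("narrowPeak", "broadPeak", "bed6")) {
  dialect <- match.arg(dialect)
  fmt <- function(x) {
    # drop trailing zeros the way MACS2 output reads, but keep full precision
    ifelse(x == round(x), sprintf("%d", as.integer(round(x))), sprintf("%g", x))
  }
  cols <- list(peaks$chrom, peaks$start, peaks$end, peaks$name,
               fmt(peaks$score), peaks$strand)
  if (dialect %in% c("narrowPeak", "broadPeak"))
    cols <- c(cols, list(fmt(peaks$signal), fmt(peaks$pvalue_neglog10),
                         fmt(peaks$qvalue_neglog10)))
  if (dialect == "narrowPeak") {
    so <- peaks$summit_offset
    so[is.na(so)] <- -1L
    cols <- c(cols, list(so))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Loads a FASTA file as an uppercase-normalized `DNAStringSet`. Headers are
#' truncated at the first whitespace and must be unique.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome <- function(path) {
  gen <- Biostrings::readDNAStringSet(path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (anyDuplicated(names(gen)))
    stop("duplicate FASTA header: ", names(gen)[duplicated(names(gen))][1L])
  if (any(Biostrings::width(gen) == 0L))
    stop("empty sequence: ", names(gen)[Biostrings::width(gen) == 0L][1L])
  gen <- Biostrings::DNAStringSet(toupper(gen))
  bad <- grepl("[^ACGTN]", as.character(gen))
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ", names(gen)[bad][1L])
  gen
}

#' Slice a chromosome with 0-based half-open coordinates
#'
#' @param genome `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds; `0 <= start < end <= length`.
#' @return Character string of length `end - start`.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop(sprintf("slice [%d,%d) outside %s bounds [0,%d)", start, end, chrom, len))
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Write a genome to FASTA
#' @param genome Named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

.TABLE_SCHEMAS <- list(
  de = list(required = c("gene_id", "log2fc", "fdr"),
            numeric = c("log2fc", "fdr")),
  survival = list(required = c("sample_id", "time", "event", "expression"),
                  numeric = c("time", "event", "expression")),
  tracks = list(required = c("frame", "x", "y", "quality"),
                numeric = c("frame", "x", "y", "quality"))
)

#' Read a typed tab-delimited table
#'
#' Reads the tab-delimited tables the pipeline consumes, enforcing the schema's
#' required columns and numeric coercion. Extra columns are kept, row order is
#' preserved. Schema `"expression"` reads a genes-by-samples matrix whose first
#' column holds gene identifiers.
#'
#' @param path Table path (tab-delimited, header row; `#` comment lines
#'   skipped).
#' @param schema One of `"de"`, `"expression"`, `"survival"`, `"tracks"`.
#' @return For `"expression"`, a numeric matrix with gene rownames and sample
#'   colnames; otherwise a `data.frame`. DE rows additionally validate
#'   `fdr` in \[0,1\].
#' @export
read_table <- function(path, schema = c("de", "expression", "survival", "tracks")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, colClasses = "character")
  if (schema == "expression") {
    if (ncol(df) < 2L) stop("expression matrix needs gene column plus samples")
    genes <- df[[1L]]
    if (anyDuplicated(genes)) stop("duplicate gene row: ", genes[duplicated(genes)][1L])
    if (anyDuplicated(colnames(df)[-1L]))
      stop("duplicate sample column: ", colnames(df)[-1L][duplicated(colnames(df)[-1L])][1L])
    m <- vapply(df[-1L], function(col) {
      v <- suppressWarnings(as.numeric(col))
      if (anyNA(v)) stop("non-numeric cell in expression matrix, row ",
                         which(is.na(v))[1L])
      v
    }, numeric(nrow(df)))
    m <- matrix(m, nrow = nrow(df),
                dimnames = list(genes, colnames(df)[-1L]))
    if (any(m < 0)) stop("negative expression value at row ",
                         which(rowSums(m < 0) > 0)[1L])
    return(m)
  }
  sch <- .TABLE_SCHEMAS[[schema]]
  req <- sch$required
  if (schema == "tracks" && "track_id" %in% colnames(df)) req <- c("track_id", req)
  missing <- setdiff(sch$required, colnames(df))
  if (length(missing)) stop("missing required column: ", missing[1L])
  out <- df[, unique(c(req, setdiff(colnames(df), req))), drop = FALSE]
  for (col in sch$numeric) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column '%s' at row %d", col,
                   which(is.na(v))[1L]))
    out[[col]] <- v
  }
  if (schema == "de") {
    if (any(out$fdr < 0 | out$fdr > 1))
      stop("fdr outside [0,1] at row ", which(out$fdr < 0 | out$fdr > 1)[1L])
    if (any(!nzchar(out$gene_id))) stop("empty gene_id")
  }
  rownames(out) <- NULL
  out
}

#' Write a tab-delimited table with optional parameter header
#'
#' @param x `data.frame` or matrix (matrices are written with a leading
#'   `gene_id` column from rownames).
#' @param path Output path.
#' @param params Optional named list recorded as `# key: value` comment lines
#'   so every emitted number is traceable to its run parameters.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params))
    writeLines(sprintf("# %s: %s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = ","), "")),
               con)
  if (is.matrix(x))
    x <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6
#'
#' @param path BED6 file; the name column is the gene identifier and must be
#'   unique; strand must be `+` or `-`.
#' @return `data.frame` with `chrom`, `start`, `end`, `gene_id`, `score`,
#'   `strand`.
#' @export
read_gene_models <- function(path) {
  b <- read_intervals(path, "bed6")
  if (!all(b$strand %in% c("+", "-")))
    stop("gene strand must be + or -: ", b$name[!b$strand %in% c("+", "-")][1L])
  if (anyDuplicated(b$name))
    stop("duplicate gene_id: ", b$name[duplicated(b$name)][1L])
  data.frame(chrom = b$chrom, start = b$start, end = b$end,
             gene_id = b$name, score = b$score, strand = b$strand,
             stringsAsFactors = FALSE)
}

# GRanges view of a peak or gene data frame (internal; 0-based half-open ->
# 1-based closed).
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}
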