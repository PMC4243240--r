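# File formats. Internal coordinates are 0-based half-open everywhere; SEG
# files (1-based inclusive) are converted at the boundary. TSV tables carry
# headers; BED-dialect files do not.

#' Read a probe/gene annotation BED-like file
#'
#' Four tab-separated columns without header: chromosome, start, end, name
#' (0-based half-open).
#'
#' @param path File path.
#' @param name_col Name for the fourth column (`"probe_id"` or `"gene_id"`).
#' @return Data.frame with `chromosome`, `start`, `end` and the name column.
#' @export
read_bed4 <- function(path, name_col = "probe_id") {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("expected 4 columns in ", path)
  df <- df[, 1:4]
  names(df) <- c("chromosome", "start", "end", name_col)
  if (any(df$end <= df$start)) stop("end must exceed start in ", path)
  df
}

#' @rdname read_bed4
#' @param df Annotation data.frame (`chromosome`, `start`, `end`, name).
#' @export
write_bed4 <- function(df, path) {
  write.table(df[, c("chromosome", "start", "end", setdiff(names(df),
                     c("chromosome", "start", "end"))[1])],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write a probe x sample TSV matrix
#'
#' Tab-separated with a header row; the first column holds row identifiers.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_matrix_tsv
#' @param m Matrix with row and column names.
#' @param id_col Header of the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments in SEG format
#'
#' SEG: header line then tab-separated sample, chrom, loc.start, loc.end,
#' num.mark, seg.mean. Input coordinates are treated as 1-based inclusive
#' and converted to the internal 0-based half-open convention
#' (`start = loc.start - 1`, `end = loc.end`). Malformed rows raise an error
#' naming the line.
#'
#' @param path File path.
#' @return Data.frame: `sample_id`, `chromosome`, `start`, `end`,
#'   `n_probes`, `seg_mean`.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("SEG file must have 6 columns: ", path)
  df <- df[, 1:6]
  names(df) <- c("sample_id", "chromosome", "loc_start", "loc_end",
                 "num_mark", "seg_mean")
  for (col in c("loc_start", "loc_end", "num_mark", "seg_mean")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("malformed SEG line %d in %s: non-numeric %s",
                   bad[1] + 1L, path, col))
    df[[col]] <- v
  }
  bad <- which(df$loc_start > df$loc_end)
  if (length(bad))
    stop(sprintf("malformed SEG line %d in %s: start > end", bad[1] + 1L,
                 path))
  data.frame(sample_id = df$sample_id, chromosome = df$chromosome,
             start = df$loc_start - 1, end = df$loc_end,
             n_probes = df$num_mark, seg_mean = df$seg_mean,
             stringsAsFactors = FALSE)
}

#' @rdname read_seg
#' @param segments Segment data.frame in internal convention (`sample_id`,
#'   `chromosome`, `start`, `end`, `n_probes`, `seg_mean`).
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(sample = segments$sample_id,
                    chrom = segments$chromosome,
                    loc.start = segments$start + 1,
                    loc.end = segments$end,
                    num.mark = segments$n_probes,
                    seg.mean = segments$seg_mean,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table TSV
#'
#' Expects columns sample_id, arm, pfs_days, event, cycles,
#' death_progression, msi, tumour_cell_pct (header row, tab-separated).
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "arm", "pfs_days", "event", "cycles",
           "death_progression", "msi", "tumour_cell_pct")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$death_progression <- as.logical(df$death_progression)
  df$msi <- as.logical(df$msi)
  df
}

#' Read a UCSC-dialect cytoband file
#'
#' Five tab-separated columns without header: chrom, start, end, band,
#' stain. The centromere position per chromosome is taken as the boundary
#' between p and q bands (or the midpoint of `acen` bands when present).
#'
#' @param path File path.
#' @return List with `bands` (data.frame) and `centromeres` (`chromosome`,
#'   `position`).
#' @export
read_cytoband <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:5] <- c("chromosome", "start", "end", "band", "stain")
  cent <- do.call(rbind, lapply(split(df, df$chromosome), function(b) {
    acen <- b[b$stain == "acen", , drop = FALSE]
    pos <- if (nrow(acen)) mean(c(min(acen$start), max(acen$end)))
    else max(b$end[startsWith(b$band, "p")], 0)
    data.frame(chromosome = b$chromosome[1], position = pos,
               stringsAsFactors = FALSE)
  }))
  rownames(cent) <- NULL
  list(bands = df, centromeres = cent)
}
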