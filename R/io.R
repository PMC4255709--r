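# I/O for the standard formats the pipeline touches: FASTA sequences, BED
# intervals, and TSV annotation tables. Coordinates are 0-based half-open
# everywhere inside the package (BED-native); 1-based coordinates appear only
# in human-readable messages.

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased on read. Soft-masked (lowercase) bases are by
#' default kept as their uppercase residue; with `mask_mode = "remove"` they
#' are replaced by `N`, which never matches any IUPAC motif letter and never
#' counts towards CpG or G/C tallies downstream.
#'
#' @param path path to a FASTA file.
#' @param mask_mode `"keep"` (default) or `"remove"` for soft-masked bases.
#' @return named character vector of sequences over `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path, mask_mode = c("keep", "remove")) {
  mask_mode <- match.arg(mask_mode)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- as.character(set)
  # FASTA ids: first whitespace-delimited token of the header
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (mask_mode == "remove") seqs <- gsub("[a-z]", "N", seqs)
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path, call. = FALSE)
  names(seqs) <- ids
  assert_dna(seqs, "FASTA")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a BED3/BED6(+) file into an interval table
#'
#' Returns a data.frame with 0-based half-open `start`/`end`, `strand` in
#' `{+,-,*}` (`*` = unknown; BED `.` maps to `*` and back on write), and any
#' extra columns retained as `extra1`, `extra2`, ... so that
#' [write_bed()] round-trips the six standard columns byte-identically.
#'
#' @param path path to a tab-separated BED file.
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`, extras.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          quote = "", colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file must have >= 3 tab-separated columns: ",
                          path, call. = FALSE)
  std <- c("chrom", "start", "end", "name", "score", "strand")
  n_std <- min(ncol(df), 6L)
  names(df)[seq_len(n_std)] <- std[seq_len(n_std)]
  if (ncol(df) > 6L)
    names(df)[7:ncol(df)] <- paste0("extra", seq_len(ncol(df) - 6L))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$end <= df$start | df$start < 0L)
  if (length(bad))
    stop("invalid interval (end <= start or negative start) at line ",
         bad[1], " of ", path, call. = FALSE)
  if ("strand" %in% names(df)) {
    if (!all(df$strand %in% c("+", "-", ".")))
      stop("invalid strand value in column 6 of ", path, call. = FALSE)
    df$strand <- ifelse(df$strand == ".", "*", df$strand)
  }
  df
}

#' Write an interval table to BED
#'
#' Inverse of [read_bed()]: the six standard columns round-trip
#' byte-identically.
#'
#' @param intervals data.frame as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  out <- intervals
  if ("strand" %in% names(out))
    out$strand <- ifelse(out$strand == "*", ".", out$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Do two intervals overlap by at least 1 bp?
#'
#' Half-open arithmetic: `[100,200)` and `[200,300)` abut but do not overlap.
#' Intervals on different chromosomes never overlap. Vectorised with
#' recycling.
#'
#' @param chrom_a,start_a,end_a first interval(s), 0-based half-open.
#' @param chrom_b,start_b,end_b second interval(s).
#' @return logical vector.
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & pmax(start_a, start_b) < pmin(end_a, end_b)
}

#' Extract a (flanked) interval's sequence from a genome
#'
#' Returns the residues of `[start - flank, end + flank)`, clipped silently to
#' the chromosome bounds; the amount clipped on each side is recorded in
#' attributes `clipped_left` / `clipped_right`, and the realised coordinates in
#' `ex_start` / `ex_end`.
#'
#' @param genome named character vector of chromosome sequences
#'   (e.g. from [read_fasta()]).
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param flank bp of flanking sequence on each side (>= 0).
#' @return a single character string with coordinate attributes.
#' @export
extract_sequence <- function(genome, chrom, start, end, flank = 0L) {
  if (!chrom %in% names(genome))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  if (flank < 0L) stop("flank must be >= 0", call. = FALSE)
  if (end <= start || start < 0L) stop("invalid interval [", start, ",", end, ")",
                                       call. = FALSE)
  len <- nchar(genome[[chrom]])
  if (end > len) stop("interval end ", end, " exceeds length of ", chrom,
                      " (", len, ")", call. = FALSE)
  s <- max(start - flank, 0L)
  e <- min(end + flank, len)
  res <- substr(genome[[chrom]], s + 1L, e)
  structure(res,
            chrom = chrom, ex_start = s, ex_end = e,
            clipped_left = s - (start - flank),
            clipped_right = (end + flank) - e)
}

#' Extract sequences for a table of intervals
#'
#' Vectorised driver over [extract_sequence()]. Sequence ids come from the
#' `name` column when present, else `chrom:start-end`.
#'
#' @param genome named character vector of chromosome sequences.
#' @param intervals data.frame with `chrom`, `start`, `end` (e.g. from
#'   [read_bed()]).
#' @param flank bp of flanking sequence on each side.
#' @return named character vector of sequences.
#' @export
extract_sequences <- function(genome, intervals, flank = 0L) {
  ids <- if ("name" %in% names(intervals)) intervals$name else
    paste0(intervals$chrom, ":", intervals$start, "-", intervals$end)
  out <- vapply(seq_len(nrow(intervals)), function(i) {
    as.character(extract_sequence(genome, intervals$chrom[i],
                                  intervals$start[i], intervals$end[i], flank))
  }, character(1))
  stats::setNames(out, ids)
}

#' Read a TSV annotation table (header row, '#' comments)
#'
#' @param path path to a tab-separated file with a header row.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a TSV report with a commented provenance header
#'
#' All tabular outputs of the pipeline use this format: tab-separated, header
#' row, preceded by '#' comment lines naming the package version and the
#' parameters of the run.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list recorded in the comment header.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cgisig ", as.character(utils::packageVersion("cgisig"))), con)
  for (nm in names(params))
    writeLines(paste0("# ", nm, "=", paste(params[[nm]], collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
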