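#' @useDynLib pavscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Internal coordinate convention: 0-based half-open everywhere. GFF3, AGP and
# BLAST-style tabular files are converted at the read/write boundary (those
# formats are 1-based inclusive).

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' @param start,end integer vectors, 1-based inclusive.
#' @return list with elements `start` (0-based) and `end` (exclusive).
#' @export
coords_to_internal <- function(start, end) list(start = start - 1L, end = end)

#' Convert 0-based half-open coordinates to 1-based inclusive
#'
#' @param start,end integer vectors, 0-based half-open.
#' @return list with elements `start` and `end`, 1-based inclusive.
#' @export
coords_to_external <- function(start, end) list(start = start + 1L, end = end)

IUPAC_AMBIGUITY <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read sequences from FASTA or FASTQ
#'
#' Sequences are upper-cased (lower-case soft masking is treated as data for
#' matching purposes). Record order is preserved; duplicated identifiers are an
#' error.
#'
#' @param path file path.
#' @param format "fasta" or "fastq"; default guessed from the extension.
#' @return named character vector of sequences (names are record ids).
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  if (format == "fastq") validate_fastq(path)
  set <- Biostrings::readBStringSet(path, format = format)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  if (any(nchar(seqs) == 0)) stop("empty sequence record in ", path)
  names(seqs) <- ids
  seqs
}

# FASTQ structural check with line numbers (Biostrings' error messages do not
# report where a record is broken).
validate_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  }
  for (i in seq(1, length(lines), by = 4)) {
    if (!startsWith(lines[i], "@")) {
      stop("malformed FASTQ record at line ", i, ": header must start with '@'")
    }
    if (!startsWith(lines[i + 2], "+")) {
      stop("malformed FASTQ record at line ", i + 2, ": expected '+' separator")
    }
    if (nchar(lines[i + 1]) != nchar(lines[i + 3])) {
      stop("malformed FASTQ record at line ", i + 3,
           ": quality length differs from sequence length")
    }
  }
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param format "fasta" (default) or "fastq" (qualities written as "I").
#' @param width line width for FASTA wrapping.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq"),
                            width = 70L) {
  format <- match.arg(format)
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(paste0(">", names(seqs)[i]), con)
      s <- seqs[[i]]
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  } else {
    qual <- strrep("I", nchar(seqs))
    writeLines(rbind(paste0("@", names(seqs)), unname(seqs), "+", qual), path)
  }
  invisible(path)
}

#' Fraction of ambiguity characters (N and IUPAC codes) in strings
#'
#' @param seqs character vector of (sub)sequences.
#' @return numeric vector of fractions in \[0,1\].
#' @export
ambiguity_fraction <- function(seqs) {
  n_amb <- nchar(gsub("[ACGT]", "", toupper(seqs)))
  ifelse(nchar(seqs) > 0, n_amb / nchar(seqs), 0)
}

#' Read a GFF3 annotation into a feature table
#'
#' Coordinates are converted from GFF3's 1-based inclusive convention to the
#' internal 0-based half-open convention. Records with start > end are
#' rejected; the number rejected is reported as a warning.
#'
#' @param path GFF3 file.
#' @return data.frame with columns seq_id, start, end, strand, type, id.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), type = character(), id = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_cols <- lengths(parts) < 9
  if (any(bad_cols)) stop("malformed GFF3 line (fewer than 9 columns)")
  m <- do.call(rbind, parts)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) stop("non-numeric coordinate in GFF3")
  rejected <- start1 > end1
  if (any(rejected)) {
    warning(sum(rejected), " GFF3 record(s) rejected (start > end)")
  }
  ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  ids[!grepl("ID=", m[, 9])] <- NA_character_
  out <- data.frame(seq_id = m[, 1], start = start1 - 1L, end = end1,
                    strand = m[, 7], type = m[, 3], id = ids,
                    stringsAsFactors = FALSE)
  out[!rejected, , drop = FALSE]
}

#' Write a feature table as GFF3
#'
#' @param features data.frame as returned by [read_annotation()].
#' @param path output path.
#' @param source source column value.
#' @export
write_annotation <- function(features, path, source = "pavscape") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0) {
    attr_col <- ifelse(is.na(features$id), ".", paste0("ID=", features$id))
    writeLines(paste(features$seq_id, source, features$type,
                     features$start + 1L, features$end, ".",
                     features$strand, ".", attr_col, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BedGraph file into a dense coverage track
#'
#' BedGraph is 0-based half-open, matching the internal convention. Positions
#' absent from the file get depth 0; overlapping intervals are an error.
#'
#' @param path BedGraph file.
#' @param seq_lengths named integer vector declaring sequence lengths.
#' @return named list of integer depth vectors (a coverage track).
#' @export
read_coverage <- function(path, seq_lengths) {
  stopifnot(!is.null(names(seq_lengths)))
  track <- lapply(seq_lengths, function(L) integer(L))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) > 0) {
    parts <- do.call(rbind, strsplit(lines, "[ \t]+"))
    df <- data.frame(seq_id = parts[, 1],
                     start = as.integer(parts[, 2]),
                     end = as.integer(parts[, 3]),
                     depth = as.integer(parts[, 4]),
                     stringsAsFactors = FALSE)
    for (sid in unique(df$seq_id)) {
      if (!sid %in% names(track)) stop("undeclared sequence in BedGraph: ", sid)
      sub <- df[df$seq_id == sid, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
        stop("overlapping BedGraph intervals on ", sid)
      }
      if (any(sub$end > length(track[[sid]]))) {
        stop("BedGraph interval beyond declared length of ", sid)
      }
      for (i in seq_len(nrow(sub))) {
        track[[sid]][(sub$start[i] + 1L):sub$end[i]] <- sub$depth[i]
      }
    }
  }
  track
}

#' Write a coverage track as BedGraph
#'
#' Zero-depth runs are omitted (the reader restores them).
#'
#' @param track named list of integer depth vectors.
#' @param path output path.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sid in names(track)) {
    r <- rle(track[[sid]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(paste(sid, starts[keep], ends[keep], r$values[keep],
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read BLAST-style 12-column tabular alignment hits
#'
#' Accepts the common tab-separated 12-column layout (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore). Coordinates are 1-based inclusive; a
#' subject start greater than the subject end encodes a minus-strand hit.
#' Output coordinates follow the internal 0-based half-open convention with
#' start < end and the strand carried separately.
#'
#' @param path tabular hits file.
#' @return data.frame of hits with identity as a fraction in \[0,1\].
#' @export
read_tabular_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      identity = numeric(), aligned_length = integer(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), evalue = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) < 12)) {
    stop("tabular hits line ", which(lengths(parts) < 12)[1],
         " has fewer than 12 columns")
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1]
    stop("non-numeric field in tabular hits at line ", bad)
  }
  sstart <- num[, 7]; send <- num[, 8]
  minus <- sstart > send
  s_lo <- ifelse(minus, send, sstart)
  s_hi <- ifelse(minus, sstart, send)
  data.frame(query_id = m[, 1], subject_id = m[, 2],
             identity = num[, 1] / 100,
             aligned_length = as.integer(num[, 2]),
             q_start = as.integer(num[, 5]) - 1L,
             q_end = as.integer(num[, 6]),
             s_start = as.integer(s_lo) - 1L,
             s_end = as.integer(s_hi),
             strand = ifelse(minus, "-", "+"),
             evalue = num[, 9], score = num[, 10],
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' BED shares the internal 0-based half-open convention, so no conversion
#' is applied. The name column defaults to ".".
#'
#' @param intervals data.frame with seq_id, start, end and optionally
#'   `name`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  nm <- if (is.null(intervals$name)) "." else intervals$name
  writeLines(paste(intervals$seq_id, intervals$start, intervals$end, nm,
                   sep = "\t"), path)
  invisible(path)
}

#' Write an AGP v2.0 file from ordered scaffold placements
#'
#' @param assignments data.frame with columns object, component_id, start, end
#'   (0-based half-open object coordinates), strand, and optionally
#'   component_start/component_end (0-based half-open within the component;
#'   default full length end - start). Rows are components only; gap rows are
#'   inserted automatically between consecutive components of one object.
#' @param path output path.
#' @param gap_type "scaffold" or "contig" for the generated gap rows.
#' @return the path, invisibly.
#' @export
write_agp <- function(assignments, path, gap_type = c("scaffold", "contig")) {
  gap_type <- match.arg(gap_type)
  a <- assignments[order(assignments$object, assignments$start), , drop = FALSE]
  if (is.null(a$component_start)) a$component_start <- 0L
  if (is.null(a$component_end)) a$component_end <- a$end - a$start
  rows <- character(0)
  for (obj in unique(a$object)) {
    sub <- a[a$object == obj, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping placements on object ", obj)
    }
    part <- 0L
    for (i in seq_len(nrow(sub))) {
      if (i > 1) {
        gap_len <- sub$start[i] - sub$end[i - 1]
        if (gap_len > 0) {
          part <- part + 1L
          rows <- c(rows, paste(obj, sub$end[i - 1] + 1L, sub$start[i], part,
                                "N", gap_len, gap_type, "yes", "align_genus",
                                sep = "\t"))
        }
      }
      part <- part + 1L
      rows <- c(rows, paste(obj, sub$start[i] + 1L, sub$end[i], part, "W",
                            sub$component_id[i],
                            sub$component_start[i] + 1L, sub$component_end[i],
                            sub$strand[i], sep = "\t"))
    }
  }
  writeLines(c("##agp-version\t2.0", rows), path)
  invisible(path)
}

#' Parse an AGP v2.0 file back into component placements
#'
#' Gap (N/U) rows are dropped; coordinates return to the internal 0-based
#' half-open convention. Inverse of [write_agp()].
#'
#' @param path AGP file.
#' @return data.frame with the same columns [write_agp()] accepts.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  comp <- parts[, 5] == "W"
  parts <- parts[comp, , drop = FALSE]
  data.frame(object = parts[, 1],
             start = as.integer(parts[, 2]) - 1L,
             end = as.integer(parts[, 3]),
             component_id = parts[, 6],
             component_start = as.integer(parts[, 7]) - 1L,
             component_end = as.integer(parts[, 8]),
             strand = parts[, 9],
             stringsAsFactors = FALSE)
}
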