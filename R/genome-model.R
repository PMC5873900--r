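#' Genome assembly
#'
#' A genome assembly is an ordered set of chromosome names with lengths.
#' The chromosome order is stable and defines the sort order used by every
#' interval container in the package.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp;
#'   names are chromosome names, order is preserved.
#' @return An object of class \code{genome_assembly}: a named integer vector.
#' @examples
#' genome_assembly(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_assembly <- function(chromosomes) {
  if (length(chromosomes) == 0L) stop("assembly must have at least one chromosome")
  nm <- names(chromosomes)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop("all chromosomes must be named")
  }
  if (anyDuplicated(nm)) stop("duplicate chromosome names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  len <- as.numeric(chromosomes)
  if (anyNA(len) || any(len <= 0) || any(len != floor(len))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(stats::setNames(as.integer(len), nm), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", length(x), " chromosome(s), ",
      format(sum(as.numeric(x)), big.mark = ","), " bp total\n", sep = "")
  print(utils::head(data.frame(chrom = names(x), length = as.integer(x)), 10))
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path file path.
#' @return A \code{\link{genome_assembly}}.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_assembly(stats::setNames(df$length, df$chrom))
}

#' Write a chrom.sizes file
#' @param assembly a \code{genome_assembly}.
#' @param path output path.
#' @export
write_chrom_sizes <- function(assembly, path) {
  utils::write.table(data.frame(names(assembly), as.integer(assembly)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

empty_peak_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
              name = character(), score = numeric(), strand = character(),
              summit = integer(), stringsAsFactors = FALSE)
}

#' Peak set container
#'
#' A set of genomic intervals (peaks, blacklist regions, sequenced
#' fragments) in 0-based half-open coordinates, sorted by (chromosome order
#' of the assembly, start, end).  The single coordinate convention used
#' throughout the package; conversion to the 1-based closed convention of
#' GenomicRanges happens only inside internal helpers.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (\code{start < end}).
#' @param assembly a \code{\link{genome_assembly}}; coordinates are
#'   validated against it and it defines the sort order.
#' @param name optional peak identifiers (\code{NA} allowed).
#' @param score optional numeric scores.
#' @param strand one of \code{"+"}, \code{"-"}, \code{"."} per interval.
#' @param summit optional non-negative summit offset from \code{start}
#'   (narrowPeak column 10 semantics); \code{NA} means absent.
#' @param label a label for the whole set (e.g. a subunit name).
#' @return An object of class \code{peak_set}: a data frame with columns
#'   \code{chrom,start,end,name,score,strand,summit} and attributes
#'   \code{label} and \code{assembly}.
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     assembly, name = NA, score = NA, strand = ".",
                     summit = NA, label = "peaks") {
  stopifnot(inherits(assembly, "genome_assembly"))
  n <- length(start)
  df <- data.frame(chrom = as.character(rep_len(chrom, n)),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(rep_len(name, n)),
                   score = as.numeric(rep_len(score, n)),
                   strand = as.character(rep_len(strand, n)),
                   summit = as.integer(rep_len(summit, n)),
                   stringsAsFactors = FALSE)
  validate_peak_df(df, assembly)
  df <- sort_peak_df(df, assembly)
  structure(df, label = label, assembly = assembly,
            class = c("peak_set", "data.frame"))
}

validate_peak_df <- function(df, assembly) {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- !(df$chrom %in% names(assembly))
  if (any(bad)) stop("chromosome(s) not in assembly: ",
                     paste(unique(df$chrom[bad]), collapse = ", "))
  if (anyNA(df$start) || anyNA(df$end)) stop("start/end must not be NA")
  if (any(df$start < 0L)) stop("start must be >= 0")
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  if (any(df$end > as.integer(assembly[df$chrom]))) {
    stop("interval end exceeds chromosome length")
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  s <- df$summit
  bad_summit <- !is.na(s) & (s < 0L | s >= df$end - df$start)
  if (any(bad_summit)) stop("summit offset must lie within the interval")
  invisible(df)
}

sort_peak_df <- function(df, assembly) {
  o <- order(match(df$chrom, names(assembly)), df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# rebuild a peak_set from a plain data.frame, keeping label/assembly
as_peak_set <- function(df, assembly, label) {
  rownames(df) <- NULL
  structure(df, label = label, assembly = assembly,
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> '", attr(x, "label"), "': ", nrow(x), " interval(s)\n",
      sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @rdname peak_set
#' @param x a \code{peak_set}.
#' @export
peak_label <- function(x) attr(x, "label")

#' @rdname peak_set
#' @export
peak_assembly <- function(x) attr(x, "assembly")

#' Interval midpoints
#'
#' Floor of (start + end) / 2, the anchor used for reference-point matrices
#' and nearest-peak distances.
#'
#' @param x a \code{peak_set}.
#' @return integer vector of midpoint positions (0-based).
#' @export
peak_midpoint <- function(x) as.integer(floor((x$start + x$end) / 2))

#' Summit positions with midpoint fallback
#'
#' Absolute summit position (\code{start + summit}) where a summit offset is
#' recorded, interval midpoint otherwise.
#'
#' @param x a \code{peak_set}.
#' @return integer vector of anchor positions (0-based).
#' @export
peak_summit_position <- function(x) {
  pos <- peak_midpoint(x)
  has <- !is.na(x$summit)
  pos[has] <- x$start[has] + x$summit[has]
  pos
}

## ---- BED / narrowPeak I/O -------------------------------------------------

#' Read BED3/BED6/narrowPeak peak calls
#'
#' Parses BED3, BED6 or ENCODE narrowPeak (BED6+4).  narrowPeak column 10 is
#' stored as the summit offset; the conventional \code{-1} maps to an absent
#' summit.  The returned set is sorted by the assembly's chromosome order.
#'
#' @param path file path.
#' @param assembly a \code{\link{genome_assembly}}.
#' @param label label for the set; default the file base name.
#' @param strict if \code{TRUE} (default) a record on a chromosome absent
#'   from the assembly is an error; if \code{FALSE} such records are dropped
#'   with a message giving the count (real ENCODE files carry alt contigs).
#' @return A \code{\link{peak_set}}.
#' @export
read_bed <- function(path, assembly, label = NULL, strict = TRUE) {
  stopifnot(inherits(assembly, "genome_assembly"))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(peak_set(assembly = assembly, label = label))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
         ": fewer than 3 fields")
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_,
                            character(1))
  chrom <- get(1)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1L], " in ",
         path, ": non-numeric coordinates")
  }
  name <- if (any(nf >= 4L)) get(4) else rep(NA_character_, length(chrom))
  name[!is.na(name) & name == "."] <- NA_character_
  score <- if (any(nf >= 5L)) suppressWarnings(as.numeric(get(5))) else NA_real_
  strand <- if (any(nf >= 6L)) get(6) else rep(".", length(chrom))
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "."
  summit <- rep(NA_integer_, length(chrom))
  if (all(nf == 10L)) {  # narrowPeak
    summit <- suppressWarnings(as.integer(get(10)))
    summit[!is.na(summit) & summit < 0L] <- NA_integer_
  }
  known <- chrom %in% names(assembly)
  if (!all(known)) {
    if (strict) {
      stop("chromosome(s) not in assembly: ",
           paste(unique(chrom[!known]), collapse = ", "),
           " (line ", which(!known)[1L], " of ", path,
           "); use strict = FALSE to drop them")
    }
    message("read_bed: dropped ", sum(!known),
            " record(s) on chromosomes absent from the assembly")
    keep <- known
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
    name <- name[keep]; score <- score[keep]; strand <- strand[keep]
    summit <- summit[keep]
  }
  peak_set(chrom, start, end, assembly, name = name, score = score,
           strand = strand, summit = summit, label = label)
}

#' Write a peak set as BED6 or narrowPeak
#'
#' If any interval carries a summit offset (or \code{format = "narrowPeak"})
#' the 10-column narrowPeak layout is written, with signalValue set to the
#' score and p/q columns to \code{-1}.  Reading the file back reproduces the
#' BED6 fields and the summit.
#'
#' @param x a \code{\link{peak_set}}.
#' @param path output path.
#' @param format \code{"auto"} (default), \code{"bed6"} or \code{"narrowPeak"}.
#' @export
write_bed <- function(x, path, format = c("auto", "bed6", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (nrow(x) && any(!is.na(x$summit))) "narrowPeak" else "bed6"
  }
  name <- ifelse(is.na(x$name), ".", x$name)
  score <- ifelse(is.na(x$score), "0", sprintf("%.15g", x$score))
  lines <- paste(x$chrom, x$start, x$end, name, score, x$strand, sep = "\t")
  if (format == "narrowPeak") {
    summit <- ifelse(is.na(x$summit), -1L, x$summit)
    lines <- paste(lines, score, "-1", "-1", summit, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- gene table and expression -------------------------------------------

#' Gene model table
#'
#' Builds a gene table with strand-aware TSS and TES.  For a \code{+} gene
#' the TSS is \code{start} and the TES is \code{end - 1}; for a \code{-}
#' gene the TSS is \code{end - 1} and the TES is \code{start} (positions of
#' the 5' and 3' terminal bases in 0-based coordinates).
#'
#' @param gene_id unique gene identifiers.
#' @param chrom,start,end 0-based half-open gene body coordinates.
#' @param strand \code{"+"} or \code{"-"} (required: metagene rows are
#'   orientation-flipped by strand).
#' @param assembly a \code{\link{genome_assembly}}.
#' @return A data frame of class \code{gene_table} with columns
#'   \code{gene_id, chrom, start, end, strand, tss, tes}.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand, assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-' (strand is required for metagene orientation)")
  }
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  bad <- !(df$chrom %in% names(assembly))
  if (any(bad)) stop("gene chromosome(s) not in assembly: ",
                     paste(unique(df$chrom[bad]), collapse = ", "))
  if (any(df$start < 0L | df$start >= df$end |
          df$end > as.integer(assembly[df$chrom]))) {
    stop("gene coordinates out of range")
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tes <- ifelse(df$strand == "+", df$end - 1L, df$start)
  o <- order(match(df$chrom, names(assembly)), df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, assembly = assembly, class = c("gene_table", "data.frame"))
}

#' Read a gene table TSV
#'
#' Expected columns (with header): \code{gene_id, chrom, start, end, strand}.
#'
#' @param path file path.
#' @param assembly a \code{\link{genome_assembly}}.
#' @return A \code{\link{gene_table}}.
#' @export
read_gene_table <- function(path, assembly) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("gene table missing column(s): ",
                            paste(missing, collapse = ", "))
  gene_table(df$gene_id, df$chrom, df$start, df$end, df$strand, assembly)
}

#' Write a gene table TSV
#' @param genes a \code{\link{gene_table}}.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level expression table
#'
#' TSV with header columns \code{gene_id} and \code{tpm} (any non-negative
#' abundance unit).  Duplicate gene ids and negative abundances are
#' rejected.
#'
#' @param path file path.
#' @return A data frame of class \code{expression_table} with columns
#'   \code{gene_id, tpm}.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tpm") %in% names(df))) {
    stop("expression table must have columns gene_id and tpm")
  }
  expression_table(df$gene_id, df$tpm)
}

#' @rdname read_expression
#' @param gene_id unique gene identifiers.
#' @param tpm non-negative abundances.
#' @export
expression_table <- function(gene_id, tpm) {
  gene_id <- as.character(gene_id)
  tpm <- as.numeric(tpm)
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene_id in expression table: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  if (anyNA(tpm) || any(tpm < 0)) stop("abundances must be non-negative")
  structure(data.frame(gene_id = gene_id, tpm = tpm,
                       stringsAsFactors = FALSE),
            class = c("expression_table", "data.frame"))
}

## ---- IRanges bridge (internal) --------------------------------------------

# 0-based half-open -> IRanges (1-based closed). The only place in the
# package where the convention changes.
df_to_ir <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# apply f(query_idx, query_ir, subject_idx, subject_ir) per chromosome over
# the chromosomes present in `query`
per_chrom <- function(query, subject, f) {
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    f(qi, df_to_ir(query$start[qi], query$end[qi]),
      si, df_to_ir(subject$start[si], subject$end[si]))
  }
  invisible(NULL)
}
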