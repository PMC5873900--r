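#' Remove peaks overlapping a blacklist
#'
#' Drops every peak that shares at least one base with any blacklist
#' interval (half-open semantics).  The relative order of the surviving
#' peaks is unchanged and the number removed is reported via
#' \code{message()}.
#'
#' @param peaks a \code{\link{peak_set}}.
#' @param blacklist a \code{\link{peak_set}} of regions to exclude; an empty
#'   blacklist is legal and returns the input unchanged.
#' @return The filtered \code{peak_set}.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  stopifnot(inherits(peaks, "peak_set"), inherits(blacklist, "peak_set"))
  if (nrow(peaks) == 0L || nrow(blacklist) == 0L) return(peaks)
  hit <- overlap_any(peaks, blacklist)
  if (any(hit)) {
    message("filter_blacklist [", peak_label(peaks), "]: removed ", sum(hit),
            " of ", nrow(peaks), " peak(s)")
  }
  as_peak_set(as.data.frame(peaks)[!hit, , drop = FALSE],
              peak_assembly(peaks), peak_label(peaks))
}

#' Recursively merge nearby peaks
#'
#' Replaces, until no further change, any two intervals on the same
#' chromosome that overlap or whose gap (\code{next.start - prev.end}) is at
#' most \code{max_gap} by their union.  Because merging is transitive on
#' sorted intervals, a chain of peaks each within \code{max_gap} of the next
#' collapses into one interval even when the first and last are far apart
#' (the "recursive" case).  Output intervals are sorted, non-overlapping,
#' and every adjacent pair is separated by more than \code{max_gap}.
#'
#' Merged intervals keep the maximum score of their members; names and
#' summits are dropped (a merged region has no single summit).  With
#' \code{max_gap = 0} this is the classic overlap/book-end merge.
#'
#' @param peaks a \code{\link{peak_set}}.
#' @param max_gap maximum gap in bp at which two peaks are still merged
#'   (inclusive; default 500).
#' @return A merged \code{peak_set}.
#' @export
recursive_merge <- function(peaks, max_gap = 500) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0) {
    stop("max_gap must be a single non-negative number")
  }
  if (nrow(peaks) <= 1L) return(peaks)
  chrom <- character(0); start <- integer(0); end <- integer(0)
  score <- numeric(0)
  for (ch in unique(peaks$chrom)) {
    i <- which(peaks$chrom == ch)
    red <- IRanges::reduce(df_to_ir(peaks$start[i], peaks$end[i]),
                           min.gapwidth = max_gap + 1L)
    rs <- IRanges::start(red)
    # each input lies inside exactly one merged interval; locate it by start
    grp <- findInterval(peaks$start[i] + 1L, rs)
    sc <- vapply(split(peaks$score[i], factor(grp, seq_along(rs))),
                 function(s) {
                   if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
                 }, numeric(1), USE.NAMES = FALSE)
    chrom <- c(chrom, rep(ch, length(red)))
    start <- c(start, rs - 1L)
    end <- c(end, IRanges::end(red))
    score <- c(score, sc)
  }
  peak_set(chrom, start, end, peak_assembly(peaks), name = NA_character_,
           score = score, strand = ".", summit = NA_integer_,
           label = peak_label(peaks))
}

#' Any-base overlap indicator
#'
#' For each query interval, whether it shares at least one base with any
#' subject interval (0-based half-open semantics: \code{[100,200)} and
#' \code{[199,250)} overlap, \code{[100,200)} and \code{[200,250)} do not).
#'
#' @param query,subject \code{\link{peak_set}} objects on the same assembly.
#' @param min_overlap minimum number of shared bases to count as an overlap
#'   (default 1, i.e. any overlap).
#' @return Logical vector, one element per query interval.
#' @export
overlap_any <- function(query, subject, min_overlap = 1L) {
  stopifnot(inherits(query, "peak_set"), inherits(subject, "peak_set"))
  if (nrow(query) == 0L) return(logical(0))
  out <- rep(FALSE, nrow(query))
  if (nrow(subject) == 0L) return(out)
  per_chrom(query, subject, function(qi, qr, si, sr) {
    if (length(si)) {
      out[qi] <<- IRanges::overlapsAny(qr, sr,
                                       minoverlap = as.integer(min_overlap))
    }
  })
  out
}

#' Subunit peak panel
#'
#' The multi-subunit ChIP-seq peak collection that classification operates
#' on: the scaffold ATPase peak set plus at least one accessory-subunit
#' peak set.  All sets are expected to be post-processed
#' (\code{\link{filter_blacklist}} then \code{\link{recursive_merge}})
#' before classification; \code{\link{run_all}} enforces that order.
#'
#' @param atpase a \code{\link{peak_set}} for the catalytic ATPase.
#' @param accessories named list of \code{peak_set} objects, one per
#'   accessory subunit.
#' @return An object of class \code{subunit_panel}.
#' @export
subunit_panel <- function(atpase, accessories) {
  stopifnot(inherits(atpase, "peak_set"))
  if (!is.list(accessories) || length(accessories) == 0L) {
    stop("at least one accessory peak set is required")
  }
  if (is.null(names(accessories)) || any(names(accessories) == "")) {
    stop("accessories must be a named list")
  }
  ok <- vapply(accessories, inherits, logical(1), what = "peak_set")
  if (!all(ok)) stop("all accessories must be peak_set objects")
  structure(list(atpase = atpase, accessories = accessories),
            class = "subunit_panel")
}

#' @export
print.subunit_panel <- function(x, ...) {
  cat("<subunit_panel> ATPase '", peak_label(x$atpase), "' (",
      nrow(x$atpase), " peaks) + ", length(x$accessories),
      " accessory set(s): ",
      paste(sprintf("%s (%d)", names(x$accessories),
                    vapply(x$accessories, nrow, integer(1))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify ATPase peaks as canonical or non-canonical
#'
#' An ATPase peak co-occupied by (sharing any base with) at least one
#' accessory subunit peak is \emph{canonical}; an ATPase peak with zero
#' overlap against every accessory set is \emph{non-canonical}.  The two
#' classes partition the ATPase peak set exactly.
#'
#' @param panel a \code{\link{subunit_panel}} of post-processed peak sets.
#' @param min_overlap minimum shared bases for co-occupancy (default 1).
#' @return An object of class \code{classified_peaks}: a list with elements
#'   \code{canonical} and \code{noncanonical} (both \code{peak_set}) and
#'   \code{provenance} (parameters and per-class counts, including the
#'   non-canonical fraction).
#' @export
classify_peaks <- function(panel, min_overlap = 1L) {
  stopifnot(inherits(panel, "subunit_panel"))
  atpase <- panel$atpase
  hit_any <- rep(FALSE, nrow(atpase))
  for (acc in panel$accessories) {
    hit_any <- hit_any | overlap_any(atpase, acc, min_overlap = min_overlap)
  }
  df <- as.data.frame(atpase)
  assembly <- peak_assembly(atpase)
  canonical <- as_peak_set(df[hit_any, , drop = FALSE], assembly, "canonical")
  noncanonical <- as_peak_set(df[!hit_any, , drop = FALSE], assembly,
                              "noncanonical")
  n_c <- nrow(canonical); n_nc <- nrow(noncanonical)
  message("classify_peaks: ", n_c, " canonical, ", n_nc,
          " non-canonical (", sprintf("%.1f", 100 * n_nc / max(1, n_c + n_nc)),
          "% NC)")
  structure(list(
    canonical = canonical,
    noncanonical = noncanonical,
    provenance = list(min_overlap = as.integer(min_overlap),
                      accessories = names(panel$accessories),
                      n_canonical = n_c, n_noncanonical = n_nc,
                      nc_fraction = n_nc / (n_c + n_nc))
  ), class = "classified_peaks")
}

#' @export
print.classified_peaks <- function(x, ...) {
  p <- x$provenance
  cat("<classified_peaks> ", p$n_canonical, " canonical + ",
      p$n_noncanonical, " non-canonical (",
      sprintf("%.1f", 100 * p$nc_fraction), "% NC) vs accessories: ",
      paste(p$accessories, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Genomic distribution of peaks over gene features
#'
#' Assigns every peak, by its midpoint, to exactly one of
#' \code{promoter}, \code{gene_body} or \code{distal}, with priority
#' promoter > gene body > distal.  The promoter window is strand-aware:
#' \code{promoter_upstream} bp 5' of the TSS through
#' \code{promoter_downstream} bp 3' of it.
#'
#' @param peaks a non-empty \code{\link{peak_set}}.
#' @param genes a \code{\link{gene_table}}.
#' @param promoter_upstream,promoter_downstream promoter window half-widths
#'   in bp (defaults 1000/1000).
#' @return Named numeric vector of fractions over
#'   \code{c(promoter, gene_body, distal)}; sums to 1.
#' @export
genomic_distribution <- function(peaks, genes, promoter_upstream = 1000,
                                 promoter_downstream = 1000) {
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_table"))
  if (nrow(peaks) == 0L) stop("genomic_distribution: empty peak set")
  mid <- peak_midpoint(peaks)
  n <- nrow(peaks)
  in_promoter <- rep(FALSE, n)
  in_body <- rep(FALSE, n)
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    on_chrom <- peaks$chrom == g$chrom
    if (!any(on_chrom)) next
    m <- mid[on_chrom]
    if (g$strand == "+") {
      prom <- m >= g$tss - promoter_upstream & m <= g$tss + promoter_downstream
    } else {
      prom <- m >= g$tss - promoter_downstream & m <= g$tss + promoter_upstream
    }
    in_promoter[on_chrom] <- in_promoter[on_chrom] | prom
    in_body[on_chrom] <- in_body[on_chrom] | (m >= g$start & m < g$end)
  }
  cls <- ifelse(in_promoter, "promoter", ifelse(in_body, "gene_body", "distal"))
  counts <- table(factor(cls, levels = c("promoter", "gene_body", "distal")))
  stats::setNames(as.numeric(counts) / n, names(counts))
}
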