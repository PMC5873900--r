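#' Chromatin-state segmentation
#'
#' A ChromHMM-style genome partition: labeled, sorted, non-overlapping
#' intervals.  \code{state_labels} fixes the label order used for
#' tie-breaking in \code{\link{dominant_state}}; \code{groups} optionally
#' maps each state label to a coarse group (e.g. active / weak /
#' repressive).
#'
#' @param chrom,start,end 0-based half-open interval coordinates.
#' @param state state label per interval.
#' @param assembly a \code{\link{genome_assembly}}.
#' @param state_labels ordered character vector of legal labels; defaults
#'   to the order of first appearance.
#' @param groups optional named character vector: state label -> group.
#' @return A data frame of class \code{segmentation}.
#' @export
segmentation <- function(chrom, start, end, state, assembly,
                         state_labels = NULL, groups = NULL) {
  stopifnot(inherits(assembly, "genome_assembly"))
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), state = as.character(state),
                   stringsAsFactors = FALSE)
  if (is.null(state_labels)) state_labels <- unique(df$state)
  if (!all(df$state %in% state_labels)) {
    stop("state(s) not in state_labels: ",
         paste(setdiff(unique(df$state), state_labels), collapse = ", "))
  }
  bad <- !(df$chrom %in% names(assembly))
  if (any(bad)) stop("segmentation chromosome(s) not in assembly: ",
                     paste(unique(df$chrom[bad]), collapse = ", "))
  if (nrow(df) && any(df$start < 0L | df$start >= df$end |
                      df$end > as.integer(assembly[df$chrom]))) {
    stop("segmentation coordinates out of range")
  }
  o <- order(match(df$chrom, names(assembly)), df$start, df$end)
  df <- df[o, , drop = FALSE]
  for (ch in unique(df$chrom)) {
    r <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
      stop("overlapping segmentation intervals on ", ch)
    }
  }
  rownames(df) <- NULL
  if (!is.null(groups)) {
    missing <- setdiff(state_labels, names(groups))
    if (length(missing)) stop("grouping map missing state(s): ",
                              paste(missing, collapse = ", "))
  }
  structure(df, assembly = assembly, state_labels = state_labels,
            groups = groups, class = c("segmentation", "data.frame"))
}

#' Read a ChromHMM dense BED segmentation
#'
#' Four columns used: chrom, start, end, state label.
#'
#' @param path file path.
#' @param assembly a \code{\link{genome_assembly}}.
#' @param groups optional named character vector (state -> group), e.g.
#'   from \code{\link{read_state_groups}}.
#' @return A \code{\link{segmentation}}.
#' @export
read_segmentation <- function(path, assembly, groups = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("segmentation BED needs at least 4 columns")
  segmentation(df[[1L]], df[[2L]], df[[3L]], df[[4L]], assembly,
               groups = groups)
}

#' Read a state grouping map
#'
#' Two-column TSV without header: state label, group.
#'
#' @param path file path.
#' @return Named character vector mapping state to group.
#' @export
read_state_groups <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("state", "group"),
                          colClasses = "character")
  stats::setNames(df$group, df$state)
}

#' Dominant chromatin state of each peak
#'
#' The label whose segmentation intervals share the most bases with the
#' peak.  Ties are broken by earlier position in \code{state_labels};
#' a peak with zero overlap against the whole segmentation is labeled
#' \code{"unsegmented"}.
#'
#' @param peaks a \code{\link{peak_set}}.
#' @param seg a \code{\link{segmentation}}.
#' @return Character vector of state labels, one per peak.
#' @export
dominant_state <- function(peaks, seg) {
  stopifnot(inherits(peaks, "peak_set"), inherits(seg, "segmentation"))
  labels <- attr(seg, "state_labels")
  out <- rep("unsegmented", nrow(peaks))
  if (nrow(peaks) == 0L || nrow(seg) == 0L) return(out)
  qh <- integer(0); sh <- integer(0); ov <- integer(0)
  per_chrom(peaks, seg, function(qi, qr, si, sr) {
    if (!length(si)) return(NULL)
    hits <- IRanges::findOverlaps(qr, sr)
    if (!length(hits)) return(NULL)
    h_q <- S4Vectors::queryHits(hits)
    h_s <- S4Vectors::subjectHits(hits)
    qh <<- c(qh, qi[h_q])
    sh <<- c(sh, si[h_s])
    ov <<- c(ov, IRanges::width(IRanges::pintersect(qr[h_q], sr[h_s])))
  })
  if (length(qh) == 0L) return(out)
  state_idx <- match(seg$state[sh], labels)
  # per (peak, state) total overlap, then max with positional tie-break
  key <- paste(qh, state_idx, sep = ":")
  tot <- rowsum(ov, key)
  parts <- strsplit(rownames(tot), ":", fixed = TRUE)
  peak_i <- as.integer(vapply(parts, `[`, character(1), 1L))
  state_i <- as.integer(vapply(parts, `[`, character(1), 2L))
  o <- order(peak_i, -tot[, 1L], state_i)
  first <- !duplicated(peak_i[o])
  out[peak_i[o][first]] <- labels[state_i[o][first]]
  out
}

#' Per-class chromatin-state fractions
#'
#' For each peak class, the fraction of peaks whose
#' \code{\link{dominant_state}} is each state (or, with \code{group =
#' TRUE}, each group of the segmentation's grouping map).  Fractions within
#' a class sum to 1.
#'
#' @param classified a \code{\link{classify_peaks}} result.
#' @param seg a \code{\link{segmentation}}.
#' @param group collapse states to groups before normalization?
#' @return A long-format data frame of class \code{state_fraction_table}
#'   with columns \code{class, state, fraction}; empty classes are omitted
#'   with a warning.
#' @export
state_fractions <- function(classified, seg, group = FALSE) {
  stopifnot(inherits(classified, "classified_peaks"),
            inherits(seg, "segmentation"))
  groups <- attr(seg, "groups")
  if (group && is.null(groups)) {
    stop("segmentation has no grouping map; pass groups= when reading it")
  }
  labels <- attr(seg, "state_labels")
  lv <- if (group) unique(unname(groups[labels])) else labels
  lv <- c(lv, "unsegmented")
  out <- list()
  for (cls in c("canonical", "noncanonical")) {
    peaks <- classified[[cls]]
    if (nrow(peaks) == 0L) {
      warning("state_fractions: class '", cls, "' is empty; omitted")
      next
    }
    st <- dominant_state(peaks, seg)
    if (group) {
      seg_states <- st != "unsegmented"
      st[seg_states] <- unname(groups[st[seg_states]])
    }
    counts <- table(factor(st, levels = lv))
    out[[cls]] <- data.frame(class = cls, state = names(counts),
                             fraction = as.numeric(counts) / nrow(peaks),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, grouped = group,
            class = c("state_fraction_table", "data.frame"))
}
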