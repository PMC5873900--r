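#' Fixed-binsize signal track
#'
#' Dense per-chromosome signal on a fixed bin grid: bin \code{j} (0-based)
#' covers bases \code{[j*binsize, (j+1)*binsize)} and the last bin is
#' truncated at the chromosome end.
#'
#' @param values named list (one element per assembly chromosome) of
#'   non-negative numeric vectors of length \code{ceiling(length/binsize)}.
#' @param binsize bin width in bp.
#' @param assembly a \code{\link{genome_assembly}}.
#' @return An object of class \code{signal_track}.
#' @export
signal_track <- function(values, binsize, assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  if (length(binsize) != 1L || binsize <= 0) stop("binsize must be positive")
  binsize <- as.integer(binsize)
  if (!setequal(names(values), names(assembly))) {
    stop("values must have one element per assembly chromosome")
  }
  for (chrom in names(assembly)) {
    nb <- ceiling(assembly[[chrom]] / binsize)
    if (length(values[[chrom]]) != nb) {
      stop("track for ", chrom, " has ", length(values[[chrom]]),
           " bins, expected ", nb)
    }
  }
  structure(list(values = values[names(assembly)], binsize = binsize,
                 assembly = assembly),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> binsize ", x$binsize, " bp, ",
      length(x$values), " chromosome(s), total signal ",
      format(sum(vapply(x$values, sum, numeric(1)))), "\n", sep = "")
  invisible(x)
}

n_bins <- function(assembly, binsize) {
  stats::setNames(as.integer(ceiling(as.numeric(assembly) / binsize)),
                  names(assembly))
}

zero_track <- function(assembly, binsize) {
  nb <- n_bins(assembly, binsize)
  signal_track(lapply(as.list(nb), numeric), binsize, assembly)
}

#' Binned coverage from sequenced fragments
#'
#' Each fragment is replaced by an \code{extend_to} bp interval anchored at
#' its 5' end in strand direction (the approximate nucleosome footprint),
#' clipped at chromosome edges; a bin's value is the number of extended
#' fragments overlapping it.
#'
#' @param fragments a \code{\link{peak_set}} of stranded fragment intervals
#'   (strand \code{+} or \code{-} required).
#' @param extend_to extension length in bp (default 150).
#' @param binsize bin width in bp (default 10).
#' @return A \code{\link{signal_track}}.
#' @export
coverage_track <- function(fragments, extend_to = 150, binsize = 10) {
  stopifnot(inherits(fragments, "peak_set"))
  if (length(extend_to) != 1L || extend_to <= 0) stop("extend_to must be positive")
  if (nrow(fragments) && !all(fragments$strand %in% c("+", "-"))) {
    stop("fragment strand must be '+' or '-' for 5' extension")
  }
  assembly <- peak_assembly(fragments)
  binsize <- as.integer(binsize)
  extend_to <- as.integer(extend_to)
  nb <- n_bins(assembly, binsize)
  values <- lapply(as.list(nb), numeric)
  for (chrom in unique(fragments$chrom)) {
    f <- fragments[fragments$chrom == chrom, , drop = FALSE]
    s <- ifelse(f$strand == "+", f$start, f$end - extend_to)
    e <- s + extend_to
    s <- pmax(s, 0L)
    e <- pmin(e, as.integer(assembly[[chrom]]))
    keep <- s < e
    s <- s[keep]; e <- e[keep]
    if (!length(s)) next
    b0 <- s %/% binsize
    b1 <- (e - 1L) %/% binsize
    # difference-array accumulation of per-bin fragment counts
    d <- numeric(nb[[chrom]] + 1L)
    add <- tabulate(b0 + 1L, nbins = nb[[chrom]])
    rem <- tabulate(b1 + 2L, nbins = nb[[chrom]] + 1L)
    d[seq_len(nb[[chrom]])] <- add
    d <- d - rem
    values[[chrom]] <- cumsum(d[seq_len(nb[[chrom]])])
  }
  signal_track(values, binsize, assembly)
}

#' Read a bedGraph file onto a fixed bin grid
#'
#' Records must be non-overlapping.  Values are resampled by
#' length-weighted mean over each bin; bases not covered by any record
#' count as zero.
#'
#' @param path file path.
#' @param assembly a \code{\link{genome_assembly}}.
#' @param binsize target bin width in bp.
#' @return A \code{\link{signal_track}}.
#' @export
read_bedgraph <- function(path, assembly, binsize = 10) {
  stopifnot(inherits(assembly, "genome_assembly"))
  binsize <- as.integer(binsize)
  track <- zero_track(assembly, binsize)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "integer", "integer",
                                     "numeric")),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) return(track)
  bad <- !(df$chrom %in% names(assembly))
  if (any(bad)) stop("bedGraph chromosome(s) not in assembly: ",
                     paste(unique(df$chrom[bad]), collapse = ", "))
  if (any(df$start < 0L | df$start >= df$end |
          df$end > as.integer(assembly[df$chrom]))) {
    stop("bedGraph coordinates out of range")
  }
  values <- track$values
  for (chrom in unique(df$chrom)) {
    r <- df[df$chrom == chrom, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
      stop("overlapping bedGraph records on ", chrom)
    }
    nb <- length(values[[chrom]])
    acc <- numeric(nb)
    for (i in seq_len(nrow(r))) {
      b0 <- r$start[i] %/% binsize
      b1 <- (r$end[i] - 1L) %/% binsize
      b <- b0:b1
      w <- pmin(r$end[i], (b + 1) * binsize) - pmax(r$start[i], b * binsize)
      acc[b + 1L] <- acc[b + 1L] + r$value[i] * w
    }
    chrlen <- as.numeric(assembly[[chrom]])
    bw <- pmin(seq_len(nb) * binsize, chrlen) - (seq_len(nb) - 1) * binsize
    values[[chrom]] <- acc / bw
  }
  signal_track(values, binsize, assembly)
}

#' Write a signal track as bedGraph
#'
#' Emits one record per run of equal-valued bins; zero-valued runs are
#' omitted.  Reading the file back at the same binsize reproduces the
#' track.
#'
#' @param track a \code{\link{signal_track}}.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$binsize
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    chrlen <- track$assembly[[chrom]]
    lines <- sprintf("%s\t%d\t%d\t%.15g", chrom,
                     as.integer(starts_bin[keep] * bs),
                     as.integer(pmin(ends_bin[keep] * bs, chrlen)),
                     r$values[keep])
    writeLines(lines, con)
  }
  invisible(path)
}

# value of the track at single base positions (0 when off-chromosome)
track_value_at <- function(track, chrom, pos) {
  v <- track$values[[chrom]]
  chrlen <- track$assembly[[chrom]]
  out <- numeric(length(pos))
  ok <- pos >= 0 & pos < chrlen
  out[ok] <- v[pos[ok] %/% track$binsize + 1L]
  out
}

# length-weighted mean of the track over a real-valued interval [from, to);
# bases outside the chromosome contribute zero
track_mean_interval <- function(track, chrom, from, to) {
  stopifnot(to > from)
  v <- track$values[[chrom]]
  bs <- track$binsize
  chrlen <- track$assembly[[chrom]]
  lo <- max(from, 0)
  hi <- min(to, chrlen)
  if (hi <= lo) return(0)
  b0 <- floor(lo / bs)
  b1 <- ceiling(hi / bs) - 1
  b <- b0:b1
  w <- pmin(hi, (b + 1) * bs) - pmax(lo, b * bs)
  sum(v[b + 1L] * w) / (to - from)
}

new_signal_matrix <- function(m, mode, binsize, meta) {
  structure(m, mode_type = mode, binsize = binsize, meta = meta,
            class = c("signal_matrix", class(m)))
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", attr(x, "mode_type"), ", ", nrow(x), " x ",
      ncol(x), " (binsize ", attr(x, "binsize"), " bp)\n", sep = "")
  invisible(x)
}

#' Reference-point signal matrix
#'
#' One row per region, aligned on an anchor (interval midpoint, or recorded
#' summit with midpoint fallback).  Column \code{j} holds the track value
#' at the bin covering \code{anchor - flank + j*binsize}.  Rows of
#' minus-strand regions are flipped so column 1 is always 5'/upstream.
#' Positions off the chromosome contribute zero; their count is kept in the
#' \code{meta} attribute.
#'
#' @param track a \code{\link{signal_track}} with matching binsize.
#' @param regions a non-empty \code{\link{peak_set}}.
#' @param flank flank in bp on each side of the anchor; must be a multiple
#'   of \code{binsize}.
#' @param binsize bin width in bp (default 10).
#' @param anchor \code{"midpoint"} (default) or \code{"summit"}.
#' @return A \code{signal_matrix} with \code{2*flank/binsize} columns.
#' @export
reference_point_matrix <- function(track, regions, flank, binsize = 10,
                                   anchor = c("midpoint", "summit")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(track, "signal_track"), inherits(regions, "peak_set"))
  if (nrow(regions) == 0L) stop("reference_point_matrix: empty region set")
  if (flank %% binsize != 0) stop("flank must be a multiple of binsize")
  if (track$binsize != binsize) {
    stop("track binsize (", track$binsize, ") != requested binsize (",
         binsize, ")")
  }
  a <- if (anchor == "summit") peak_summit_position(regions) else
    peak_midpoint(regions)
  ncol <- as.integer(2 * flank / binsize)
  offs <- (seq_len(ncol) - 1L) * binsize - flank
  m <- matrix(0, nrow = nrow(regions), ncol = ncol)
  n_oob <- 0L
  for (i in seq_len(nrow(regions))) {
    pos <- a[i] + offs
    vals <- track_value_at(track, regions$chrom[i], pos)
    n_oob <- n_oob + sum(pos < 0 | pos >= track$assembly[[regions$chrom[i]]])
    if (regions$strand[i] == "-") vals <- rev(vals)
    m[i, ] <- vals
  }
  rownames(m) <- row_ids(regions)
  colnames(m) <- sprintf("p%+d", offs)
  new_signal_matrix(m, "reference_point", binsize,
                    list(flank = flank, anchor = anchor, n_out_of_bounds = n_oob))
}

row_ids <- function(regions) {
  id <- regions$name
  fallback <- sprintf("peak_%d", seq_len(nrow(regions)))
  id[is.na(id)] <- fallback[is.na(id)]
  if (anyDuplicated(id)) id <- make.unique(id)
  id
}

#' Scaled-region (metagene) signal matrix
#'
#' One row per gene, reading TSS to TES regardless of strand: an unscaled
#' upstream flank (\code{upstream/binsize} bins before the TSS), a gene
#' body rescaled to \code{body_bins} bins (each the length-weighted mean of
#' the track over its fraction of the body), and an unscaled downstream
#' flank after the TES.  Genes shorter than one bin get a constant body
#' equal to the whole-body mean and are flagged in \code{meta}.
#'
#' @param track a \code{\link{signal_track}} with matching binsize.
#' @param genes a non-empty \code{\link{gene_table}}.
#' @param upstream,downstream flank lengths in bp (defaults 1500/1000);
#'   must be multiples of \code{binsize}.
#' @param body_bins number of scaled gene-body bins (default 100).
#' @param binsize bin width in bp (default 10).
#' @return A \code{signal_matrix} with
#'   \code{upstream/binsize + body_bins + downstream/binsize} columns.
#' @export
scaled_region_matrix <- function(track, genes, upstream = 1500,
                                 downstream = 1000, body_bins = 100,
                                 binsize = 10) {
  stopifnot(inherits(track, "signal_track"), inherits(genes, "gene_table"))
  if (nrow(genes) == 0L) stop("scaled_region_matrix: empty gene table")
  if (upstream %% binsize != 0 || downstream %% binsize != 0) {
    stop("upstream and downstream must be multiples of binsize")
  }
  if (track$binsize != binsize) {
    stop("track binsize (", track$binsize, ") != requested binsize (",
         binsize, ")")
  }
  nu <- as.integer(upstream / binsize)
  nd <- as.integer(downstream / binsize)
  m <- matrix(0, nrow = nrow(genes), ncol = nu + body_bins + nd)
  short <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- g$end - g$start
    if (g$strand == "+") {
      up_pos <- g$tss - upstream + (seq_len(nu) - 1L) * binsize
      down_pos <- g$end + (seq_len(nd) - 1L) * binsize
      body_from <- g$start + (seq_len(body_bins) - 1) * (L / body_bins)
      body_to <- g$start + seq_len(body_bins) * (L / body_bins)
    } else {
      up_pos <- g$tss + upstream - (seq_len(nu) - 1L) * binsize
      down_pos <- g$start - 1L - (seq_len(nd) - 1L) * binsize
      body_to <- g$end - (seq_len(body_bins) - 1) * (L / body_bins)
      body_from <- g$end - seq_len(body_bins) * (L / body_bins)
    }
    if (L < binsize) {
      short <- c(short, g$gene_id)
      body <- rep(track_mean_interval(track, g$chrom, g$start, g$end),
                  body_bins)
    } else {
      body <- vapply(seq_len(body_bins), function(k) {
        track_mean_interval(track, g$chrom, body_from[k], body_to[k])
      }, numeric(1))
    }
    m[i, ] <- c(track_value_at(track, g$chrom, up_pos), body,
                track_value_at(track, g$chrom, down_pos))
  }
  rownames(m) <- genes$gene_id
  colnames(m) <- c(sprintf("u%+d", (seq_len(nu) - 1L) * binsize - upstream),
                   sprintf("body_%d", seq_len(body_bins)),
                   sprintf("d%+d", (seq_len(nd) - 1L) * binsize))
  new_signal_matrix(m, "scaled_region", binsize,
                    list(upstream = upstream, downstream = downstream,
                         body_bins = body_bins, short_genes = short))
}

#' Column-mean profile of a signal matrix
#'
#' @param m a \code{signal_matrix} (or any numeric matrix) with at least
#'   one row.
#' @return Named numeric vector of column means (the metaplot profile).
#' @export
mean_profile <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0L) stop("mean_profile: empty matrix")
  colMeans(m)
}

#' Reorder matrix rows by an external value
#'
#' Stable descending sort: rows with equal values keep their input order
#' (used e.g. to order metagene rows by gene expression).
#'
#' @param m a \code{signal_matrix} with row names.
#' @param values named numeric vector covering every row id of \code{m}.
#' @return The reordered matrix (attributes preserved).
#' @export
order_rows_by <- function(m, values) {
  ids <- rownames(m)
  missing <- setdiff(ids, names(values))
  if (length(missing)) {
    stop("order_rows_by: no value for row id(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  v <- as.numeric(values[ids])
  o <- order(-v)  # radix sort: stable, so ties keep input order
  out <- m[o, , drop = FALSE]
  attributes(out)$mode_type <- attr(m, "mode_type")
  attributes(out)$binsize <- attr(m, "binsize")
  attributes(out)$meta <- attr(m, "meta")
  class(out) <- class(m)
  out
}

#' Write a signal matrix (or profile) as TSV
#' @param m a \code{signal_matrix}.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(row_id = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal metaplot of one or more profiles
#'
#' Base-graphics line plot of column-mean profiles, e.g. comparing a track
#' over canonical vs non-canonical sites.
#'
#' @param profiles named list of numeric vectors of equal length (output of
#'   \code{\link{mean_profile}}).
#' @param xlab,ylab,main plot annotation.
#' @export
plot_profiles <- function(profiles, xlab = "bin", ylab = "mean signal",
                          main = "") {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  n <- length(profiles[[1L]])
  ylim <- range(unlist(profiles), 0)
  graphics::plot(NA, xlim = c(1, n), ylim = ylim, xlab = xlab, ylab = ylab,
                 main = main)
  cols <- seq_along(profiles)
  for (i in cols) graphics::lines(seq_len(n), profiles[[i]], col = i, lwd = 2)
  if (!is.null(names(profiles))) {
    graphics::legend("topright", legend = names(profiles), col = cols,
                     lwd = 2, bty = "n")
  }
  invisible(NULL)
}

#' @export
plot.signal_matrix <- function(x, ...) {
  plot_profiles(list(profile = mean_profile(x)), ...)
}
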