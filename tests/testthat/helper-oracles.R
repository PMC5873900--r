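# Naive per-base reference implementations, independent of the package's
# GRanges-backed code paths.  Everything here works on plain data frames /
# vectors and scans bases directly; used as oracles throughout the suite.

tiny_assembly <- function(len = 10000, chroms = c("chrA", "chrB")) {
  genome_assembly(stats::setNames(rep(len, length(chroms)), chroms))
}

# random interval set as a plain data.frame
rand_intervals <- function(n, assembly, max_width = 400) {
  chrom <- sample(names(assembly), n, replace = TRUE)
  len <- as.integer(assembly[chrom])
  width <- sample.int(max_width, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(len[i] - width[i], 1L) - 1L
  }, integer(1))
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

rand_peak_set <- function(n, assembly, label = "x", max_width = 400) {
  df <- rand_intervals(n, assembly, max_width)
  peak_set(df$chrom, df$start, df$end, assembly,
           name = sprintf("%s_%d", label, seq_len(n)),
           score = sample(0:1000, n, replace = TRUE), label = label)
}

# per-base occupancy mask of a set of intervals, one logical vector per chrom
base_mask <- function(df, assembly) {
  masks <- lapply(names(assembly), function(ch) logical(assembly[[ch]]))
  names(masks) <- names(assembly)
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    masks[[ch]][(df$start[i] + 1L):df$end[i]] <- TRUE
  }
  masks
}

bf_overlap_any <- function(query, subject, assembly) {
  masks <- base_mask(subject, assembly)
  vapply(seq_len(nrow(query)), function(i) {
    any(masks[[query$chrom[i]]][(query$start[i] + 1L):query$end[i]])
  }, logical(1))
}

bf_filter_blacklist <- function(peaks, blacklist, assembly) {
  if (nrow(blacklist) == 0L) return(peaks)
  peaks[!bf_overlap_any(peaks, blacklist, assembly), , drop = FALSE]
}

# fixpoint oracle: repeatedly merge any mergeable pair until convergence
bf_recursive_merge <- function(df, max_gap) {
  df <- df[, c("chrom", "start", "end")]
  repeat {
    merged <- FALSE
    n <- nrow(df)
    for (i in seq_len(max(0L, n - 1L))) {
      for (j in (i + 1L):n) {
        if (df$chrom[i] != df$chrom[j]) next
        gap <- max(df$start[i] - df$end[j], df$start[j] - df$end[i])
        if (gap <= max_gap) {  # negative gap = overlap
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# classification by exhaustive per-base overlap tables
bf_classify <- function(atpase, accessory_list, assembly) {
  hit <- rep(FALSE, nrow(atpase))
  for (acc in accessory_list) {
    hit <- hit | bf_overlap_any(atpase, acc, assembly)
  }
  list(canonical = which(hit), noncanonical = which(!hit))
}

# per-bin coverage by direct interval-intersection counting per (frag, bin)
bf_coverage <- function(fragments, assembly, extend_to, binsize) {
  out <- list()
  for (ch in names(assembly)) {
    chrlen <- assembly[[ch]]
    nb <- ceiling(chrlen / binsize)
    v <- numeric(nb)
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      s <- if (f$strand[i] == "+") f$start[i] else f$end[i] - extend_to
      e <- s + extend_to
      s <- max(s, 0); e <- min(e, chrlen)
      if (s >= e) next
      for (b in seq_len(nb)) {
        bs <- (b - 1) * binsize
        be <- min(b * binsize, chrlen)
        if (s < be && e > bs) v[b] <- v[b] + 1
      }
    }
    out[[ch]] <- v
  }
  out
}

# expand a signal_track to one value per base
base_values <- function(track, chrom) {
  chrlen <- track$assembly[[chrom]]
  rep(track$values[[chrom]], each = track$binsize)[seq_len(chrlen)]
}

bf_reference_matrix <- function(track, regions, flank, binsize,
                                anchor = "midpoint") {
  ncol <- 2 * flank / binsize
  m <- matrix(0, nrow(regions), ncol)
  for (i in seq_len(nrow(regions))) {
    bv <- base_values(track, regions$chrom[i])
    a <- if (anchor == "summit" && !is.na(regions$summit[i])) {
      regions$start[i] + regions$summit[i]
    } else floor((regions$start[i] + regions$end[i]) / 2)
    vals <- vapply(seq_len(ncol), function(j) {
      p <- a - flank + (j - 1) * binsize
      if (p >= 0 && p < length(bv)) bv[p + 1] else 0
    }, numeric(1))
    if (regions$strand[i] == "-") vals <- rev(vals)
    m[i, ] <- vals
  }
  m
}

# length-weighted mean of per-base values over a real interval [from, to);
# integrates base by base with fractional end weights
bf_interval_mean <- function(bv, from, to) {
  total <- 0
  for (b in floor(from):(ceiling(to) - 1)) {
    w <- min(to, b + 1) - max(from, b)
    if (w <= 0) next
    v <- if (b >= 0 && b < length(bv)) bv[b + 1] else 0
    total <- total + v * w
  }
  total / (to - from)
}

bf_scaled_matrix <- function(track, genes, upstream, downstream, body_bins,
                             binsize) {
  nu <- upstream / binsize
  nd <- downstream / binsize
  m <- matrix(0, nrow(genes), nu + body_bins + nd)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    bv <- base_values(track, g$chrom)
    L <- g$end - g$start
    at <- function(p) if (p >= 0 && p < length(bv)) bv[p + 1] else 0
    if (g$strand == "+") {
      up <- vapply(seq_len(nu), function(j) at(g$tss - upstream + (j - 1) * binsize),
                   numeric(1))
      down <- vapply(seq_len(nd), function(j) at(g$end + (j - 1) * binsize),
                     numeric(1))
      body <- vapply(seq_len(body_bins), function(k) {
        bf_interval_mean(bv, g$start + (k - 1) * L / body_bins,
                         g$start + k * L / body_bins)
      }, numeric(1))
    } else {
      up <- vapply(seq_len(nu), function(j) at(g$tss + upstream - (j - 1) * binsize),
                   numeric(1))
      down <- vapply(seq_len(nd), function(j) at(g$start - 1 - (j - 1) * binsize),
                     numeric(1))
      body <- vapply(seq_len(body_bins), function(k) {
        bf_interval_mean(bv, g$end - k * L / body_bins,
                         g$end - (k - 1) * L / body_bins)
      }, numeric(1))
    }
    m[i, ] <- c(up, body, down)
  }
  m
}

# dominant state by per-base label counting
bf_dominant_state <- function(peaks, seg, labels, assembly) {
  lab_vec <- list()
  for (ch in names(assembly)) {
    v <- rep(NA_character_, assembly[[ch]])
    r <- seg[seg$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      v[(r$start[i] + 1L):r$end[i]] <- r$state[i]
    }
    lab_vec[[ch]] <- v
  }
  vapply(seq_len(nrow(peaks)), function(i) {
    bases <- lab_vec[[peaks$chrom[i]]][(peaks$start[i] + 1L):peaks$end[i]]
    bases <- bases[!is.na(bases)]
    if (!length(bases)) return("unsegmented")
    counts <- vapply(labels, function(l) sum(bases == l), numeric(1))
    labels[which.max(counts)]  # which.max: first max = earlier label wins
  }, character(1))
}

# rank-sum W by exhaustive pair enumeration (Mann-Whitney with 1/2 for ties)
bf_rank_sum_W <- function(x, y) {
  total <- 0
  for (xi in x) for (yi in y) {
    total <- total + (xi > yi) + 0.5 * (xi == yi)
  }
  total
}
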