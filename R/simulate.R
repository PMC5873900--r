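#' Configuration for the synthetic study generator
#'
#' Defaults describe a miniature two-chromosome study with the class
#' structure the pipeline is designed to detect: a panel of five subunit
#' peak sets (one ATPase plus four accessories) sharing a co-occupied
#' canonical fraction, an ATPase-only non-canonical fraction of about 22%
#' of sites, a segmentation placing canonical sites in active states and
#' non-canonical sites in repressive states, signal tracks concordant with
#' sites and states, and an expression table in which genes near
#' non-canonical sites are lowly expressed.
#'
#' @param seed integer RNG seed; generation is a pure function of the
#'   config.
#' @param n_chroms,chrom_length genome shape (default 2 x 1 Mb).
#' @param n_canonical_sites,n_nc_sites planted site counts (defaults
#'   200/55, i.e. a 21.6% non-canonical fraction, the ~4:1 class ratio the
#'   classifier is expected to report).
#' @param peak_width_meanlog,peak_width_sdlog log-normal site width
#'   (median 300 bp by default).
#' @param jitter_sd per-subunit peak-boundary noise in bp (default 50).
#' @param dropout per-accessory probability that a canonical site is
#'   missing from that accessory's peak file (default 0.2; models
#'   antibody-efficiency variation).
#' @param accessories accessory subunit names.
#' @param atpase ATPase subunit name.
#' @param n_blacklist number of blacklist regions; each also receives one
#'   decoy peak per subunit so blacklist filtering is exercised.
#' @param segment_halfwidth half-width in bp of the state segment planted
#'   around each site.
#' @param expr_meanlog_canonical,expr_meanlog_nc,expr_sdlog log-normal TPM
#'   parameters for genes linked to each class (defaults meanlog 3 vs 0.5,
#'   sdlog 1).
#' @param fragments_per_peak mean fragment count per site per concordant
#'   track (Poisson).
#' @param background_rate uniform background fragments per bp per track.
#' @param fragment_length raw fragment length in bp before 5' extension.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 1e6,
                       n_canonical_sites = 200L, n_nc_sites = 55L,
                       peak_width_meanlog = log(300), peak_width_sdlog = 0.3,
                       jitter_sd = 50, dropout = 0.2,
                       accessories = c("RUVBL1", "RUVBL2", "MCRS1", "YY1"),
                       atpase = "INO80",
                       n_blacklist = 10L,
                       segment_halfwidth = 2500,
                       expr_meanlog_canonical = 3, expr_meanlog_nc = 0.5,
                       expr_sdlog = 1,
                       fragments_per_peak = 100, background_rate = 1e-4,
                       fragment_length = 36L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length > 0,
            cfg$n_canonical_sites >= 0L, cfg$n_nc_sites >= 0L,
            cfg$jitter_sd >= 0, cfg$dropout >= 0, cfg$dropout <= 1,
            length(cfg$accessories) >= 1L)
  structure(cfg, class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a complete synthetic study on disk
#'
#' Writes, under \code{dir}: \code{chrom.sizes}, \code{blacklist.bed}, one
#' narrowPeak per subunit (canonical sites present in every subunit file
#' subject to jitter and dropout, non-canonical sites only in the
#' ATPase's), \code{segmentation.bed} and \code{state_groups.tsv}
#' (canonical sites inside active-state segments, non-canonical inside
#' repressive ones), one \code{<track>_fragments.bed} per signal track
#' (ATPase-like signal at all sites, H3K27ac-like at canonical sites,
#' H3K27me3-like at non-canonical sites), \code{genes.tsv} (one gene near
#' each site) and \code{expression.tsv} (class-conditional log-normal
#' TPM).  Identical configs produce byte-identical trees.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list of class \code{sim_truth}: \code{sites} (data
#'   frame of chrom, center, width, class), \code{genes} (gene_id, class),
#'   \code{paths} (named file paths), \code{assembly} and \code{config}.
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, simulate_study_impl(config, dir))
}

simulate_study_impl <- function(cfg, dir) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  assembly <- genome_assembly(stats::setNames(rep(cfg$chrom_length,
                                                  cfg$n_chroms), chroms))
  n_sites <- cfg$n_canonical_sites + cfg$n_nc_sites

  ## --- site layout: jittered grid, margin at chromosome ends -------------
  per_chrom <- diff(round(seq(0, n_sites, length.out = cfg$n_chroms + 1L)))
  spacing <- (cfg$chrom_length - 2e4) / max(1L, max(per_chrom))
  if (spacing < 3000) {
    stop("infeasible placement: too many sites for the genome length ",
         "(spacing would be ", round(spacing), " bp)")
  }
  sites <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(ci) {
    k <- per_chrom[ci]
    if (k == 0L) return(NULL)
    centers <- 1e4 + (seq_len(k) - 0.5) * spacing +
      round(stats::runif(k, -spacing / 8, spacing / 8))
    data.frame(chrom = chroms[ci], center = as.integer(centers))
  }))
  cls <- sample(rep(c("canonical", "noncanonical"),
                    c(cfg$n_canonical_sites, cfg$n_nc_sites)))
  sites$class <- cls
  sites$width <- pmax(50L, as.integer(round(stats::rlnorm(
    n_sites, cfg$peak_width_meanlog, cfg$peak_width_sdlog))))
  sites$id <- sprintf("site_%03d", seq_len(n_sites))

  ## --- blacklist in inter-site gaps, plus decoy peak positions -----------
  gap_mid <- integer(0)
  for (ch in chroms) {
    cs <- sort(sites$center[sites$chrom == ch])
    if (length(cs) > 1L) {
      gap_mid <- c(gap_mid, stats::setNames(
        as.integer((cs[-length(cs)] + cs[-1L]) / 2), rep(ch, length(cs) - 1L)))
    }
  }
  nb <- min(cfg$n_blacklist, length(gap_mid))
  bl_idx <- if (nb > 0) sort(sample(length(gap_mid), nb)) else integer(0)
  blacklist <- peak_set(names(gap_mid)[bl_idx],
                        gap_mid[bl_idx] - 250L, gap_mid[bl_idx] + 250L,
                        assembly, label = "blacklist")

  ## --- per-subunit peak files --------------------------------------------
  subunits <- c(cfg$atpase, cfg$accessories)
  peak_paths <- character(0)
  jitter <- function(n) as.integer(round(stats::rnorm(n, 0, cfg$jitter_sd)))
  for (su in subunits) {
    is_atpase <- su == cfg$atpase
    use <- if (is_atpase) rep(TRUE, n_sites) else
      sites$class == "canonical" & stats::runif(n_sites) >= cfg$dropout
    s <- sites[use, , drop = FALSE]
    n <- nrow(s)
    start <- pmax(0L, s$center - s$width %/% 2L + jitter(n))
    end <- pmin(as.integer(cfg$chrom_length),
                s$center + s$width %/% 2L + jitter(n))
    bad <- start >= end
    if (any(bad)) { mid <- s$center[bad]; start[bad] <- mid - 25L; end[bad] <- mid + 25L }
    # decoy peaks inside blacklist regions, removed by filtering
    d_chrom <- blacklist$chrom
    d_start <- blacklist$start + 100L
    d_end <- blacklist$end - 100L
    ps <- peak_set(c(s$chrom, d_chrom), c(start, d_start), c(end, d_end),
                   assembly,
                   name = c(sprintf("%s_%s", su, s$id),
                            sprintf("%s_decoy_%d", su, seq_along(d_chrom))),
                   score = round(stats::runif(n + length(d_chrom), 50, 1000)),
                   summit = c(pmin((end - start) %/% 2L,
                                   pmax(0L, s$center - start)),
                              rep((d_end - d_start) %/% 2L, length(d_chrom))),
                   label = su)
    peak_paths[su] <- file.path(dir, paste0(su, ".narrowPeak"))
    write_bed(ps, peak_paths[su], format = "narrowPeak")
  }

  ## --- segmentation: active/repressive segment around each site ----------
  state_pool <- list(canonical = c("Tss", "Enh"),
                     noncanonical = c("ReprPC", "Het"))
  seg_rows <- list()
  for (ch in chroms) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    s <- s[order(s$center), , drop = FALSE]
    pos <- 0L
    for (i in seq_len(nrow(s))) {
      a <- max(pos, s$center[i] - cfg$segment_halfwidth)
      b <- min(cfg$chrom_length, s$center[i] + cfg$segment_halfwidth)
      if (a > pos) seg_rows[[length(seg_rows) + 1L]] <-
          data.frame(chrom = ch, start = pos, end = a, state = "Quies")
      lab <- sample(state_pool[[s$class[i]]], 1L)
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(chrom = ch, start = a, end = b, state = lab)
      pos <- b
    }
    if (pos < cfg$chrom_length) seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(chrom = ch, start = pos, end = cfg$chrom_length,
                   state = "Quies")
  }
  seg_df <- do.call(rbind, seg_rows)
  groups <- c(Tss = "active", Enh = "active", Quies = "weak",
              ReprPC = "repressive", Het = "repressive")
  seg_path <- file.path(dir, "segmentation.bed")
  utils::write.table(seg_df, seg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  groups_path <- file.path(dir, "state_groups.tsv")
  utils::write.table(data.frame(names(groups), unname(groups)), groups_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  ## --- concordant fragment tracks ----------------------------------------
  track_sites <- list(INO80_signal = c("canonical", "noncanonical"),
                      H3K27ac = "canonical",
                      H3K27me3 = "noncanonical")
  track_paths <- character(0)
  for (tr in names(track_sites)) {
    s <- sites[sites$class %in% track_sites[[tr]], , drop = FALSE]
    frag <- list()
    for (i in seq_len(nrow(s))) {
      k <- stats::rpois(1L, cfg$fragments_per_peak)
      if (k == 0L) next
      centers <- as.integer(round(stats::rnorm(k, s$center[i], s$width[i] / 4)))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      start <- ifelse(strand == "+", centers - 75L,
                      centers + 75L - cfg$fragment_length)
      frag[[length(frag) + 1L]] <-
        data.frame(chrom = s$chrom[i], start = start, strand = strand)
    }
    n_bg <- stats::rpois(1L, cfg$background_rate * cfg$chrom_length *
                           cfg$n_chroms)
    if (n_bg > 0L) {
      frag[[length(frag) + 1L]] <- data.frame(
        chrom = sample(chroms, n_bg, replace = TRUE),
        start = as.integer(floor(stats::runif(n_bg, 0,
                                              cfg$chrom_length - 200))),
        strand = sample(c("+", "-"), n_bg, replace = TRUE))
    }
    f <- do.call(rbind, frag)
    f$start <- pmax(0L, pmin(f$start,
                             as.integer(cfg$chrom_length) -
                               cfg$fragment_length))
    ps <- peak_set(f$chrom, f$start, f$start + cfg$fragment_length, assembly,
                   strand = f$strand, label = tr)
    track_paths[tr] <- file.path(dir, paste0(tr, "_fragments.bed"))
    write_bed(ps, track_paths[tr], format = "bed6")
  }

  ## --- genes near sites, class-conditional expression --------------------
  offset <- as.integer(round(stats::runif(n_sites, 300, 800))) *
    sample(c(-1L, 1L), n_sites, replace = TRUE)
  strand <- sample(c("+", "-"), n_sites, replace = TRUE)
  glen <- as.integer(round(stats::runif(n_sites, 1000, 3000)))
  tss <- pmax(5000L, pmin(as.integer(cfg$chrom_length) - 5000L,
                          sites$center + offset))
  gstart <- ifelse(strand == "+", tss, tss - glen + 1L)
  gend <- gstart + glen
  gene_id <- sprintf("gene_%03d", seq_len(n_sites))
  genes <- gene_table(gene_id, sites$chrom, gstart, gend, strand, assembly)
  genes_path <- file.path(dir, "genes.tsv")
  write_gene_table(genes, genes_path)
  meanlog <- ifelse(sites$class == "canonical", cfg$expr_meanlog_canonical,
                    cfg$expr_meanlog_nc)
  tpm <- round(stats::rlnorm(n_sites, meanlog, cfg$expr_sdlog), 4)
  expr_path <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene_id = gene_id, tpm = tpm),
                     expr_path, sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- chrom.sizes, blacklist, truth -------------------------------------
  sizes_path <- file.path(dir, "chrom.sizes")
  write_chrom_sizes(assembly, sizes_path)
  bl_path <- file.path(dir, "blacklist.bed")
  write_bed(blacklist, bl_path, format = "bed6")

  invisible(structure(list(
    sites = sites[, c("id", "chrom", "center", "width", "class")],
    genes = data.frame(gene_id = gene_id, class = sites$class,
                       stringsAsFactors = FALSE),
    assembly = assembly,
    config = cfg,
    paths = c(list(chrom_sizes = sizes_path, blacklist = bl_path,
                   segmentation = seg_path, state_groups = groups_path,
                   genes = genes_path, expression = expr_path),
              list(peaks = peak_paths, tracks = track_paths))
  ), class = "sim_truth"))
}

#' Site-level recovery of planted classes
#'
#' Matches each classified peak to the planted site whose center lies
#' within half a site width of the peak midpoint, and tabulates the
#' truth-class by called-class confusion matrix.  Truth sites matched by
#' no peak are reported in \code{unmatched_truth}, never silently dropped;
#' peaks matching no site (e.g. unfiltered decoys) are counted in
#' \code{unmatched_peaks}.
#'
#' @param classified a \code{\link{classify_peaks}} result computed from
#'   the simulated files.
#' @param truth the \code{sim_truth} returned by
#'   \code{\link{simulate_study}}.
#' @return A list of class \code{recovery}: \code{confusion} (2x2 matrix,
#'   rows = truth, cols = called), \code{accuracy},
#'   \code{nc_fraction_called}, \code{nc_fraction_planted},
#'   \code{unmatched_truth} (character ids), \code{unmatched_peaks}
#'   (count).
#' @export
evaluate_recovery <- function(classified, truth) {
  stopifnot(inherits(classified, "classified_peaks"),
            inherits(truth, "sim_truth"))
  called <- rbind(
    data.frame(chrom = classified$canonical$chrom,
               mid = peak_midpoint(classified$canonical),
               called = rep("canonical", nrow(classified$canonical)),
               stringsAsFactors = FALSE),
    data.frame(chrom = classified$noncanonical$chrom,
               mid = peak_midpoint(classified$noncanonical),
               called = rep("noncanonical", nrow(classified$noncanonical)),
               stringsAsFactors = FALSE))
  sites <- truth$sites
  truth_match <- rep(NA_integer_, nrow(called))
  for (i in seq_len(nrow(called))) {
    cand <- which(sites$chrom == called$chrom[i] &
                    abs(sites$center - called$mid[i]) <= sites$width / 2)
    if (length(cand)) {
      truth_match[i] <- cand[which.min(abs(sites$center[cand] -
                                             called$mid[i]))]
    }
  }
  lv <- c("canonical", "noncanonical")
  ok <- !is.na(truth_match)
  confusion <- table(truth = factor(sites$class[truth_match[ok]], levels = lv),
                     called = factor(called$called[ok], levels = lv))
  matched_sites <- unique(truth_match[ok])
  unmatched_truth <- sites$id[!(seq_len(nrow(sites)) %in% matched_sites)]
  structure(list(
    confusion = unclass(confusion),
    accuracy = sum(diag(confusion)) / max(1L, sum(confusion)),
    nc_fraction_called = classified$provenance$nc_fraction,
    nc_fraction_planted = sum(sites$class == "noncanonical") / nrow(sites),
    unmatched_truth = unmatched_truth,
    unmatched_peaks = sum(!ok)
  ), class = "recovery")
}

#' @export
print.recovery <- function(x, ...) {
  cat("<recovery> accuracy ", sprintf("%.3f", x$accuracy),
      "; NC fraction called ", sprintf("%.3f", x$nc_fraction_called),
      " vs planted ", sprintf("%.3f", x$nc_fraction_planted), "\n", sep = "")
  print(x$confusion)
  if (length(x$unmatched_truth)) {
    cat("unmatched truth sites: ", length(x$unmatched_truth), "\n")
  }
  invisible(x)
}
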