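#' Pipeline run configuration
#'
#' Collects the input paths and parameters for \code{\link{run_all}}.
#' Every file path is validated at construction.  Parameter defaults are
#' the processing values the pipeline is built around: merge gap 500 bp,
#' 10 bp bins, 150 bp fragment extension, 1.5 kb/1 kb metagene flanks.
#'
#' @param atpase path to the ATPase narrowPeak/BED file.
#' @param accessories named character vector of accessory peak files.
#' @param chrom_sizes path to the chrom.sizes file.
#' @param blacklist optional blacklist BED.
#' @param tracks optional named character vector of fragment BED files
#'   (signal tracks to profile over the two classes).
#' @param segmentation,state_groups optional segmentation BED and state ->
#'   group TSV; enables the chromatin-state stage.
#' @param genes,expression optional gene table and expression TSVs; genes
#'   enables the genomic-distribution stage, both together enable the
#'   expression stage.
#' @param out_dir output directory.
#' @param max_gap,min_overlap peak post-processing and classification
#'   parameters.
#' @param binsize,extend_to,flank signal parameters (bp).
#' @param promoter_upstream,promoter_downstream promoter window (bp).
#' @param max_distance,ambiguity_window gene assignment parameters (bp).
#' @param strict strict chromosome checking when reading BED files.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(atpase, accessories, chrom_sizes, out_dir,
                       blacklist = NULL, tracks = NULL,
                       segmentation = NULL, state_groups = NULL,
                       genes = NULL, expression = NULL,
                       max_gap = 500, min_overlap = 1L,
                       binsize = 10, extend_to = 150, flank = 1500,
                       promoter_upstream = 1000, promoter_downstream = 1000,
                       max_distance = 1e6, ambiguity_window = 0,
                       strict = TRUE) {
  cfg <- as.list(environment())
  if (is.null(names(accessories)) || any(names(accessories) == "")) {
    stop("accessories must be a named vector of file paths")
  }
  paths <- c(atpase, accessories, chrom_sizes, blacklist, tracks,
             segmentation, state_groups, genes, expression)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  if (!is.null(segmentation) && is.null(state_groups)) {
    stop("state_groups is required when a segmentation is given")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param sim a \code{sim_truth} from \code{\link{simulate_study}}; builds
#'   the matching \code{run_config} for its on-disk files.
#' @param ... overrides passed on to \code{run_config}.
#' @export
run_config_from_sim <- function(sim, out_dir, ...) {
  stopifnot(inherits(sim, "sim_truth"))
  p <- sim$paths
  atpase_name <- sim$config$atpase
  run_config(atpase = p$peaks[[atpase_name]],
             accessories = p$peaks[setdiff(names(p$peaks), atpase_name)],
             chrom_sizes = p$chrom_sizes, blacklist = p$blacklist,
             tracks = p$tracks, segmentation = p$segmentation,
             state_groups = p$state_groups, genes = p$genes,
             expression = p$expression, out_dir = out_dir, ...)
}

#' Run the full classification and characterization pipeline
#'
#' Stage order: read inputs; per peak set blacklist-filter then
#' recursively merge; classify ATPase peaks against the accessory panel;
#' then, as inputs allow, genomic distribution over gene features,
#' reference-point matrices and mean profiles of every track over each
#' class, chromatin-state fractions (raw and grouped), and nearest-peak
#' gene assignment with the class-wise expression comparison.  Stage
#' outputs are written under \code{config$out_dir} (class BED files,
#' profile TSVs, per-gene TSV, \code{report.json}) and every count in the
#' report equals the corresponding on-disk output.  Reports are
#' deterministic: identical inputs give byte-identical \code{report.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @return A list of class \code{run_report}.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # stage messages go to stderr as usual and are mirrored into run.log
  log_con <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(log_con))
  withCallingHandlers(
    run_all_impl(config),
    message = function(m) cat(conditionMessage(m), file = log_con))
}

run_all_impl <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  report <- list(version = as.character(utils::packageVersion("peakclasses")),
                 parameters = config[!(names(config) %in%
                                         c("accessories", "tracks"))],
                 stages = list())

  assembly <- stage("read_assembly", read_chrom_sizes(config$chrom_sizes))
  blacklist <- if (!is.null(config$blacklist)) {
    stage("read_blacklist",
          read_bed(config$blacklist, assembly, label = "blacklist",
                   strict = config$strict))
  } else peak_set(assembly = assembly, label = "blacklist")

  peak_files <- c(stats::setNames(config$atpase, "..atpase.."),
                  config$accessories)
  processed <- list()
  counts <- list()
  for (nm in names(peak_files)) {
    label <- if (nm == "..atpase..") "atpase" else nm
    raw <- stage(paste0("read_peaks:", label),
                 read_bed(peak_files[[nm]], assembly, label = label,
                          strict = config$strict))
    filt <- stage(paste0("filter_blacklist:", label),
                  filter_blacklist(raw, blacklist))
    merged <- stage(paste0("recursive_merge:", label),
                    recursive_merge(filt, max_gap = config$max_gap))
    processed[[nm]] <- merged
    counts[[label]] <- list(input = nrow(raw),
                            removed_by_blacklist = nrow(raw) - nrow(filt),
                            after_merge = nrow(merged))
  }
  report$stages$peak_processing <- counts

  panel <- subunit_panel(processed[["..atpase.."]],
                         processed[names(config$accessories)])
  classified <- stage("classify", classify_peaks(panel,
                                                 min_overlap = config$min_overlap))
  write_bed(classified$canonical, file.path(config$out_dir, "canonical.bed"))
  write_bed(classified$noncanonical,
            file.path(config$out_dir, "noncanonical.bed"))
  report$stages$classification <- classified$provenance

  genes <- NULL
  if (!is.null(config$genes)) {
    genes <- stage("read_genes", read_gene_table(config$genes, assembly))
    report$stages$genomic_distribution <- list(
      atpase = as.list(stage("genomic_distribution",
                             genomic_distribution(
                               processed[["..atpase.."]], genes,
                               config$promoter_upstream,
                               config$promoter_downstream))))
  }

  if (!is.null(config$tracks)) {
    prof <- list()
    for (tr in names(config$tracks)) {
      frags <- stage(paste0("read_fragments:", tr),
                     read_bed(config$tracks[[tr]], assembly, label = tr,
                              strict = config$strict))
      track <- stage(paste0("coverage_track:", tr),
                     coverage_track(frags, extend_to = config$extend_to,
                                    binsize = config$binsize))
      for (cls in c("canonical", "noncanonical")) {
        if (nrow(classified[[cls]]) == 0L) next
        m <- stage(paste0("matrix:", tr, ":", cls),
                   reference_point_matrix(track, classified[[cls]],
                                          flank = config$flank,
                                          binsize = config$binsize))
        p <- mean_profile(m)
        prof[[tr]][[cls]] <- p
        utils::write.table(
          data.frame(position = names(p), mean_signal = as.numeric(p)),
          file.path(config$out_dir, sprintf("profile_%s_%s.tsv", tr, cls)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    center <- function(p) as.numeric(p[length(p) / 2 + 1L])
    report$stages$profiles <- lapply(prof, function(x) {
      lapply(x, function(p) list(center = center(p), mean = mean(p)))
    })
  }

  if (!is.null(config$segmentation)) {
    groups <- stage("read_state_groups", read_state_groups(config$state_groups))
    seg <- stage("read_segmentation",
                 read_segmentation(config$segmentation, assembly,
                                   groups = groups))
    sf <- stage("state_fractions", state_fractions(classified, seg))
    sfg <- stage("state_fractions_grouped",
                 state_fractions(classified, seg, group = TRUE))
    utils::write.table(as.data.frame(sf),
                       file.path(config$out_dir, "state_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(sfg),
                       file.path(config$out_dir,
                                 "state_fractions_grouped.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$state_fractions <- sf_to_list(sf)
    report$stages$state_fractions_grouped <- sf_to_list(sfg)
  }

  if (!is.null(config$expression)) {
    if (is.null(genes)) {
      stop("stage 'expression': a gene table is required for the expression ",
           "comparison", call. = FALSE)
    }
    expr <- stage("read_expression", read_expression(config$expression))
    assignment <- stage("assign_genes",
                        assign_genes(genes, classified,
                                     max_distance = config$max_distance,
                                     ambiguity_window = config$ambiguity_window))
    write_assignment_tsv(assignment,
                         file.path(config$out_dir, "gene_assignment.tsv"),
                         expr = expr)
    comparison <- stage("compare_expression",
                        compare_expression(assignment, expr))
    report$stages$expression <- list(
      n_ambiguous = sum(assignment$class == "AMBIGUOUS"),
      n_unassigned = sum(assignment$class == "UNASSIGNED"),
      canonical = comparison$canonical,
      noncanonical = comparison$noncanonical,
      rank_sum_W = comparison$rank_sum_W,
      rank_sum_z = comparison$rank_sum_z)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  structure(report, class = c("run_report", "list"))
}

sf_to_list <- function(sf) {
  out <- list()
  for (cls in unique(sf$class)) {
    r <- sf[sf$class == cls, ]
    out[[cls]] <- as.list(stats::setNames(r$fraction, r$state))
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cl <- x$stages$classification
  cat("<run_report> peakclasses ", x$version, "\n", sep = "")
  if (!is.null(cl)) {
    cat(sprintf("  classes: %d canonical, %d non-canonical (%.1f%% NC)\n",
                cl$n_canonical, cl$n_noncanonical, 100 * cl$nc_fraction))
  }
  if (!is.null(x$stages$expression)) {
    e <- x$stages$expression
    cat(sprintf("  expression: median TPM %.2f (canonical) vs %.2f (NC), z = %.2f\n",
                e$canonical$median, e$noncanonical$median, e$rank_sum_z))
  }
  invisible(x)
}
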