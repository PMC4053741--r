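# End-to-end orchestration: ingest -> sites -> re-definition -> mixture ->
# motif profiles -> cluster scoring and correlation, with a manifest for
# reproducibility.

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields as documented in [run_pipeline()].
#' @return a named list.
#' @export
pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

.cfg_default <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

#' Run the cross-link analysis pipeline
#'
#' Executes ingest (barcode collapse or position join), truncation- and
#' deletion-site derivation, TTT re-definition of deletion sites, optional
#' read-through mixture estimation (when reference and background libraries
#' are given), motif occurrence/closest/background/enrichment and composition
#' profiles, and YCAY cluster scoring with score-count correlation. All
#' outputs are written under `config$outdir` together with a JSON manifest
#' recording the configuration, seed, package version, stage log and md5 of
#' every output file.
#'
#' Config fields (defaults in parentheses): `cdnas` (path or data.frame),
#' `genome` (FASTA path or DNAStringSet), `segments` (path or data.frame,
#' optional), `reference_cdnas`/`background_cdnas` (optional, enable the
#' mixture stage), `barcoded` (TRUE), `window_nt` (25), `min_library`
#' (10000), `motif` ("YCAY"), `n_background` (100), `background_window` (50),
#' `profile_window` (30), `score_flank` (20), `site_source` ("truncation":
#' which site set feeds the profiles and correlation; `"deletion"` uses the
#' re-defined deletion sites), `region` (list chrom/start/end/strand for the
#' cluster stage; default the whole first chromosome), `seed` (1), `outdir`.
#'
#' @param config named list or path to a YAML file.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- pipeline_config(config)
  outdir <- config$outdir
  if (is.null(outdir)) stop("config$outdir is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  barcoded <- .cfg_default(config, "barcoded", TRUE)
  window_nt <- .cfg_default(config, "window_nt", 25L)
  min_library <- .cfg_default(config, "min_library", 10000L)
  motif <- .cfg_default(config, "motif", "YCAY")
  n_background <- .cfg_default(config, "n_background", 100L)
  background_window <- .cfg_default(config, "background_window", 50L)
  profile_window <- .cfg_default(config, "profile_window", 30L)
  score_flank <- .cfg_default(config, "score_flank", 20L)
  site_source <- .cfg_default(config, "site_source", "truncation")
  seed <- .cfg_default(config, "seed", 1L)

  log <- list()
  files <- character(0)
  emit <- function(name) {
    p <- file.path(outdir, name)
    files <<- c(files, stats::setNames(p, name))
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genome <- stage("genome", .as_genome(config$genome))
  chrlen <- .chrom_lengths(genome)
  load_cdnas <- function(x)
    if (is.character(x)) read_cdnas(x) else validate_cdnas(x)

  # ingest
  records <- stage("ingest", load_cdnas(config$cdnas))
  unique_cdnas <- stage("ingest",
    if (barcoded) collapse_barcoded(records) else join_no_barcode(records))
  log$reads_in <- nrow(records)
  log$unique_cdnas <- nrow(unique_cdnas)
  write_cdnas(unique_cdnas, emit("unique_cdnas.tsv"))

  # sites
  tsites <- stage("sites", withCallingHandlers(
    truncation_sites(unique_cdnas, chrom_lengths = chrlen),
    warning = function(w) invokeRestart("muffleWarning")))
  log$truncation_boundary_skips <-
    attr(derive_truncation_sites(
      unique_cdnas[unique_cdnas$deletions == "", ], chrlen), "n_skipped")
  dsites <- stage("sites", deletion_sites(unique_cdnas))
  write_sites(tsites, emit("truncation_sites.bed"))

  # re-definition
  rsites <- NULL
  if (nrow(dsites)) {
    rd <- stage("redefine", redefine_deletions(dsites, genome))
    rsites <- merge_redefined(rd)
    log$deletions_redefined <- sum(rd$redefined)
    log$redefine_boundary <- attr(rd, "n_boundary")
    log$redefine_in_longer_run <- attr(rd, "n_in_longer_run")
    write_sites(rsites, emit("deletion_sites_redefined.bed"))
  }

  # mixture (optional)
  mixture <- NULL
  if (!is.null(config$reference_cdnas) && !is.null(config$background_cdnas)) {
    mixture <- stage("mixture", {
      ref <- if (barcoded) collapse_barcoded(load_cdnas(config$reference_cdnas))
             else join_no_barcode(load_cdnas(config$reference_cdnas))
      bg <- join_no_barcode(load_cdnas(config$background_cdnas))
      estimate_mixture(
        deletion_stats(unique_cdnas, window_nt, min_library),
        deletion_stats(ref, window_nt, min_library),
        deletion_stats(bg, window_nt, min_library))
    })
    mx <- data.frame(p_target = mixture$p_target, p_rt = mixture$p_rt,
                     p_bg = mixture$p_bg, f = mixture$f, k = mixture$k,
                     readthrough_no_del = mixture$readthrough_no_del,
                     truncated_no_del = mixture$truncated_no_del,
                     window_nt = mixture$window_nt)
    utils::write.table(mx, emit("mixture.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    log$mixture <- "skipped (no reference/background library)"
  }

  # profiles
  psites <- if (identical(site_source, "deletion") && !is.null(rsites))
    rsites else tsites
  profiles <- stage("profile", {
    occ <- motif_occurrence(psites, motif, genome, profile_window)
    clo <- closest_motif(psites, motif, genome, profile_window)
    comp <- nucleotide_composition(psites, genome, profile_window)
    out <- list(occurrence = occ, closest = clo, composition = comp)
    if (!is.null(config$segments)) {
      segments <- if (is.character(config$segments))
        read_segments(config$segments) else config$segments
      obs50 <- motif_occurrence(psites, motif, genome, background_window)
      bg <- randomized_background(psites, segments, motif, genome,
                                  n = n_background,
                                  window = background_window,
                                  seed = seed)
      out$enrichment <- motif_enrichment(obs50, bg)
    }
    out
  })
  utils::write.table(as.data.frame(profiles$occurrence),
                     emit("motif_occurrence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(profiles$closest),
                     emit("closest_motif.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(offset = as.integer(colnames(profiles$composition)),
                           t(profiles$composition)),
                     emit("nucleotide_composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(profiles$enrichment)) {
    utils::write.table(as.data.frame(profiles$enrichment),
                       emit("motif_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    reg <- attr(profiles$enrichment, "enriched_region")
    if (!is.null(reg)) log$enriched_region <- as.list(reg)
  }

  # clusters
  region <- config$region %||% list(chrom = names(genome)[1L], start = 0L,
                                    end = unname(chrlen[1L]), strand = "+")
  clres <- stage("clusters", {
    track <- ycay_score(genome, region$chrom, region$start, region$end,
                        strand = region$strand %||% "+", motif = motif,
                        flank = score_flank)
    clusters <- find_clusters(track)
    corr <- tryCatch(correlate_clusters(clusters, psites),
                     error = function(e) {
                       log$correlation <<- conditionMessage(e)
                       NULL
                     })
    list(track = track, clusters = clusters, correlation = corr)
  })
  write_bedgraph(clres$track, emit("ycay_score.bedgraph"))
  utils::write.table(clres$clusters, emit("ycay_clusters.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(clres$correlation)) {
    utils::write.table(
      data.frame(rho = clres$correlation$rho,
                 p_value = clres$correlation$p_value,
                 n_clusters = clres$correlation$n_clusters),
      emit("correlation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # manifest: relative paths + md5 so a re-run can be verified byte-for-byte
  cfg_record <- config
  cfg_record$cdnas <- if (is.character(config$cdnas)) config$cdnas
                      else "<in-memory>"
  for (fld in c("reference_cdnas", "background_cdnas", "segments", "genome"))
    if (!is.null(cfg_record[[fld]]) && !is.character(cfg_record[[fld]]))
      cfg_record[[fld]] <- "<in-memory>"
  cfg_record$outdir <- NULL
  manifest <- list(
    package = "crosslinkr",
    version = as.character(utils::packageVersion("crosslinkr")),
    seed = seed,
    config = cfg_record,
    log = log,
    outputs = lapply(stats::setNames(nm = names(files)), function(nm)
      unname(tools::md5sum(files[[nm]]))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(unique_cdnas = unique_cdnas, truncation_sites = tsites,
                 deletion_sites = rsites, mixture = mixture,
                 profiles = profiles, track = clres$track,
                 clusters = clres$clusters,
                 correlation = clres$correlation,
                 manifest = manifest_path, log = log))
}
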