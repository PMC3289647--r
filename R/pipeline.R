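#' Pipeline configuration
#'
#' Collects every input path and tuning parameter for [run_pipeline()].
#' `ped` maps each disease label to its PLINK text prefix (expects
#' `<prefix>.ped` and `<prefix>.map`).
#'
#' @param fasta Masked genome FASTA path.
#' @param chip_beds Character vector (>= 2) of ChIP-region BED paths.
#' @param snp_map Genome-wide SNP MAP path (known SNPs with positions).
#' @param ld_table LD text file path.
#' @param ped Named list/vector: disease label -> PED/MAP prefix.
#' @param out_dir Output directory.
#' @param genes Optional gene-model BED6 path for nearest-gene annotation.
#' @param r2_min LD-proxy threshold (inclusive), default 0.89.
#' @param thresholds [qc_thresholds()] list.
#' @param multiplier `"auto"` or fixed integer Bonferroni factor.
#' @param patterns Motif patterns for the scan, default the two ERE
#'   half-site cores.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, chip_beds, snp_map, ld_table, ped,
                            out_dir, genes = NULL, r2_min = 0.89,
                            thresholds = qc_thresholds(),
                            multiplier = "auto",
                            patterns = ere_patterns()) {
  cfg <- list(fasta = fasta, chip_beds = chip_beds, snp_map = snp_map,
              ld_table = ld_table, ped = as.list(ped), out_dir = out_dir,
              genes = genes, r2_min = r2_min, thresholds = thresholds,
              multiplier = multiplier, patterns = patterns)
  if (length(cfg$chip_beds) < 2L)
    stop("config: need at least two ChIP BED files")
  if (is.null(names(cfg$ped)) || any(!nzchar(names(cfg$ped))))
    stop("config: 'ped' must be named by disease")
  if (!identical(cfg$multiplier, "auto") &&
      (!is.numeric(cfg$multiplier) || cfg$multiplier < 1))
    stop("config: multiplier must be \"auto\" or an integer >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; `thresholds` is an
#' optional mapping with the [qc_thresholds()] names.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  thr <- if (is.null(y$thresholds)) qc_thresholds() else
    do.call(qc_thresholds, y$thresholds)
  pats <- if (is.null(y$patterns)) ere_patterns() else unlist(y$patterns)
  pipeline_config(
    fasta = y$fasta, chip_beds = unlist(y$chip_beds), snp_map = y$snp_map,
    ld_table = y$ld_table, ped = y$ped, out_dir = y$out_dir,
    genes = y$genes, r2_min = if (is.null(y$r2_min)) 0.89 else y$r2_min,
    thresholds = thr,
    multiplier = if (is.null(y$multiplier)) "auto" else y$multiplier,
    patterns = pats)
}

#' SNP positions implied by the masked positions of motif hits
#'
#' @param hits Data.frame from [filter_snp_disrupting()].
#' @return data.frame with `chrom` and 1-based `pos`, one row per masked
#'   position per hit.
#' @keywords internal
hit_snp_positions <- function(hits) {
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    offs <- hits$masked_offsets[[i]]
    if (length(offs))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = hits$chrom[i], pos = hits$start[i] + offs + 1L,
        stringsAsFactors = FALSE)
  }
  if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(chrom = character(), pos = integer(), stringsAsFactors = FALSE)
}

#' Run the full binding-site variant association pipeline
#'
#' Stages: scan the masked genome for SNP-disrupting ERE half-sites;
#' intersect the ChIP region sets to the consensus and their union;
#' select candidate SNPs (all SNPs in consensus regions, plus disrupting
#' half-site SNPs supported by any region set); substitute LD proxies for
#' ungenotyped candidates; per disease and sex, apply genotype QC and run
#' the allelic Fisher exact association with a shared Bonferroni
#' multiplier. All stage outputs and a run manifest (input checksums,
#' stage counts, thresholds) are written under `out_dir` as plain text.
#'
#' @param config A [pipeline_config()], or the path to its YAML file.
#' @return Invisibly, a list with `hits`, `consensus`, `union`,
#'   `candidates`, per-disease `panels`, `assoc` (see [run_stratified()]),
#'   `manifest`, and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  inputs <- c(fasta = config$fasta,
              stats::setNames(config$chip_beds,
                              paste0("chip", seq_along(config$chip_beds))),
              snp_map = config$snp_map, ld_table = config$ld_table)
  for (d in names(config$ped)) {
    inputs[[paste0("ped_", d)]] <- paste0(config$ped[[d]], ".ped")
    inputs[[paste0("map_", d)]] <- paste0(config$ped[[d]], ".map")
  }
  if (!is.null(config$genes)) inputs[["genes"]] <- config$genes
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop("input not found: ", paste(missing_in, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  seqs <- stage("scan", read_masked_fasta(config$fasta))
  hits <- stage("scan", scan_halfsites(seqs, config$patterns))
  disrupting <- stage("scan",
                      filter_snp_disrupting(hits, seqs, config$patterns))

  bed_sets <- stage("consensus", lapply(config$chip_beds, read_bed))
  consensus <- stage("consensus", intersect_all(bed_sets))
  union <- stage("consensus", union_any(bed_sets))

  snp_map <- stage("select", read_snp_map(config$snp_map))
  groupA <- stage("select",
                  snps_in_regions(snp_map, consensus, "consensus_region"))
  ere_pos <- hit_snp_positions(disrupting)
  ere_snps <- merge(snp_map, ere_pos, by = c("chrom", "pos"))
  ere_snps <- ere_snps[, c("rsid", "chrom", "pos")]
  groupB <- stage("select",
                  snps_in_regions(ere_snps, union, "ere_halfsite"))
  candidates <- stage("select", assemble_candidates(groupA, groupB))
  ld <- stage("select", read_ld_table(config$ld_table))

  panels <- list()
  datasets <- list()
  for (disease in names(config$ped)) {
    prefix <- config$ped[[disease]]
    ds <- stage(paste0("genotypes_", disease),
                read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map")))
    panel <- stage(paste0("proxies_", disease),
                   find_proxies(candidates, ds$snps$rsid, ld,
                                config$r2_min))
    keep <- intersect(panel$rsid, ds$snps$rsid)
    panels[[disease]] <- panel
    datasets[[disease]] <- subset_dataset(ds, snps = keep)
  }

  assoc <- stage("association",
                 run_stratified(datasets, config$thresholds,
                                config$multiplier))

  n_dup <- nrow(groupA) + nrow(groupB) - nrow(candidates)
  counts <- list(
    motif_hits = nrow(hits), disrupting_hits = nrow(disrupting),
    consensus_regions = length(consensus), union_regions = length(union),
    snps_in_consensus = nrow(groupA), ere_snps_in_union = nrow(groupB),
    duplicate_candidates = n_dup, candidates = nrow(candidates),
    per_disease = lapply(stats::setNames(nm = names(panels)), function(d) {
      p <- panels[[d]]
      list(genotyped = sum(p$provenance != "ld_proxy"),
           proxied = sum(p$provenance == "ld_proxy"),
           dropped_no_proxy = length(attr(p, "dropped")),
           panel = nrow(datasets[[d]]$snps))
    }),
    post_qc_panels = as.list(assoc$panel_sizes),
    tested = nrow(assoc$results))

  paths <- list(
    hits = file.path(config$out_dir, "hits.bed"),
    consensus = file.path(config$out_dir, "consensus.bed"),
    union = file.path(config$out_dir, "union.bed"),
    candidates = file.path(config$out_dir, "candidates.tsv"),
    results = file.path(config$out_dir, "results.tsv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_hits_bed(disrupting, paths$hits)
  write_bed(consensus, paths$consensus)
  write_bed(union, paths$union)
  cand_out <- candidates
  for (d in names(panels)) {
    cand_out[[paste0("in_panel_", d)]] <-
      cand_out$rsid %in% panels[[d]]$rsid |
      cand_out$rsid %in% panels[[d]]$proxy_source
  }
  utils::write.table(cand_out, paths$candidates, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(assoc$results, paths$results, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "erevar",
    version = as.character(utils::packageVersion("erevar")),
    inputs = as.list(tools::md5sum(inputs)),
    thresholds = config$thresholds,
    r2_min = config$r2_min,
    multiplier = assoc$multiplier,
    counts = counts)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(hits = disrupting, consensus = consensus, union = union,
                 candidates = candidates, panels = panels, assoc = assoc,
                 manifest = manifest, paths = paths))
}
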