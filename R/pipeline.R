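# pipeline: configuration, orchestration of the per-species analysis
# chain (scan -> classify -> dedup -> RPW8 groups -> census) and run
# metadata. A thin command-line wrapper over these functions ships in
# exec/nlrpipe.R.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' identity cutoffs (0.97 redundancy removal, 0.60 RPW8 representative
#' clustering, 0.80 within-group clustering), the full-length RPW8
#' minimum (100 aa, exclusive), the broad domain pre-filter and the
#' model/hit e-value thresholds of the domain-table reader, the count
#' filter (>5 in >= 2 libraries), the FDR level, the number of
#' expression groups, and the seed.
#'
#' @param dedup_cutoff identity cutoff for redundancy removal.
#' @param rpw8_representative_cutoff RPW8 representative-set cutoff.
#' @param within_group_cutoff within-group clustering cutoff.
#' @param rpw8_min_length full-length RPW8 threshold (exclusive).
#' @param evalue_prefilter broad domain pre-filter e-value.
#' @param evalue_model,evalue_hit scanner significance thresholds; the
#'   hit-level value is what [read_domain_table()] applies per domain.
#' @param count_min,count_min_libraries count filter parameters.
#' @param fdr adjusted-p threshold.
#' @param k_groups number of expression groups.
#' @param seed default seed for synthetic stages.
#' @param motif_config_path optional path to a motif YAML (packaged
#'   default when `NULL`).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(dedup_cutoff = 0.97,
                            rpw8_representative_cutoff = 0.60,
                            within_group_cutoff = 0.80,
                            rpw8_min_length = 100,
                            evalue_prefilter = 1.0,
                            evalue_model = 0.01,
                            evalue_hit = 0.03,
                            count_min = 5,
                            count_min_libraries = 2,
                            fdr = 0.05,
                            k_groups = 14,
                            seed = 20190812,
                            motif_config_path = NULL) {
  cfg <- list(dedup_cutoff = dedup_cutoff,
              rpw8_representative_cutoff = rpw8_representative_cutoff,
              within_group_cutoff = within_group_cutoff,
              rpw8_min_length = rpw8_min_length,
              evalue_prefilter = evalue_prefilter,
              evalue_model = evalue_model,
              evalue_hit = evalue_hit,
              count_min = count_min,
              count_min_libraries = count_min_libraries,
              fdr = fdr, k_groups = k_groups, seed = seed,
              motif_config_path = motif_config_path)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && x > 0 && x <= 1
  if (!in01(cfg$dedup_cutoff) || !in01(cfg$rpw8_representative_cutoff) ||
      !in01(cfg$within_group_cutoff)) {
    stop_input("identity cutoffs must be in (0, 1]")
  }
  if (!in01(cfg$fdr)) stop_input("fdr must be in (0, 1]")
  if (cfg$rpw8_min_length < 0 || cfg$count_min < 0 ||
      cfg$count_min_libraries < 1 || cfg$k_groups < 1) {
    stop_input("invalid pipeline configuration value")
  }
  for (ev in c("evalue_prefilter", "evalue_model", "evalue_hit")) {
    if (cfg[[ev]] < 0) stop_input(ev, " must be >= 0")
  }
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip unchanged through their file format.
#'
#' @param path YAML path.
#' @return for the reader, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

run_metadata <- function(cfg, seed, log) {
  tmp <- tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, tmp)
  on.exit(unlink(tmp))
  list(package = "nlrcensus",
       version = as.character(packageVersion("nlrcensus")),
       seed = seed,
       config_hash = unname(tools::md5sum(tmp)),
       filters = log)
}

#' Run the classification pipeline on one or more proteomes
#'
#' Chains motif scanning, classification, redundancy removal (0.97),
#' RPW8 domain extraction with representative clustering (0.60) and
#' group assignment, and the cross-species census. Every filtering step
#' logs its before/after counts; when `out_dir` is given, per-stage TSV
#' outputs and a run-metadata JSON are written.
#'
#' @param proteomes named list (species -> `protein_records`), or a
#'   single `protein_records` data frame with a `species` column.
#' @param hits a `domain_hits` data frame covering all sequences.
#' @param transcriptome_sizes named vector (species -> assembly size);
#'   defaults to the per-species input sequence counts (census ratios are
#'   then relative to the scanned set, not a full assembly).
#' @param anchors RPW8 anchor set (see [load_rpw8_anchors()]); `NULL`
#'   skips group assignment.
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory.
#' @return list: `calls`, `dedup` (records + clusters), `census`,
#'   `rpw8_domains`, `rpw8_groups`, `log`, `metadata`.
#' @export
run_pipeline <- function(proteomes, hits,
                         transcriptome_sizes = NULL,
                         anchors = NULL,
                         config = pipeline_config(),
                         out_dir = NULL) {
  if (is.data.frame(proteomes)) {
    records <- proteomes
  } else {
    records <- do.call(rbind, lapply(names(proteomes), function(s) {
      r <- proteomes[[s]]
      r$species <- s
      r
    }))
    class(records) <- c("protein_records", "data.frame")
  }
  if (anyDuplicated(records$id)) stop_input("duplicate ids across proteomes")
  motif_cfg <- load_motif_config(config$motif_config_path)
  log <- list()
  note <- function(step, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(step = step, n_in = n_in,
                                           n_out = n_out,
                                           stringsAsFactors = FALSE)
  }

  calls <- classify_records(records, hits, motif_cfg)
  keep <- calls$category != "EXCLUDED"
  note("exclude_non_nlr", nrow(records), sum(keep))
  nlr_records <- records[records$id %in% calls$seq_id[keep], , drop = FALSE]
  class(nlr_records) <- c("protein_records", "data.frame")

  dd <- deduplicate(nlr_records, calls[keep, , drop = FALSE],
                    identity_cutoff = config$dedup_cutoff)
  note("deduplicate", nrow(nlr_records), nrow(dd$records))

  sizes <- transcriptome_sizes %||%
    vapply(split(records$id, records$species), length, 0L)
  census <- build_census(census_counts_from_calls(dd$calls), sizes)

  rpw8 <- extract_rpw8(dd$records, hits[hits$seq_id %in% dd$records$id, ,
                                        drop = FALSE],
                       min_length = config$rpw8_min_length)
  note("extract_rpw8", attr(rpw8, "log")$n_in, nrow(rpw8))
  groups <- NULL
  if (!is.null(anchors) && nrow(rpw8) > 0) {
    reps <- greedy_cluster(rpw8, config$rpw8_representative_cutoff)
    rep_ids <- vapply(reps, `[[`, "", "representative")
    note("rpw8_representatives", nrow(rpw8), length(rep_ids))
    rep_rec <- rpw8[match(rep_ids, rpw8$id), , drop = FALSE]
    class(rep_rec) <- c("protein_records", "data.frame")
    groups <- assign_groups(rep_rec, anchors)
  }

  log_df <- do.call(rbind, log)
  meta <- run_metadata(config, config$seed, log_df)
  out <- list(calls = calls, dedup = dd, census = census,
              rpw8_domains = rpw8, rpw8_groups = groups,
              log = log_df, metadata = meta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_report(calls, file.path(out_dir, "classification.tsv"))
    write_tsv_report(census$counts, file.path(out_dir, "census.tsv"))
    if (!is.null(groups)) {
      write_tsv_report(groups, file.path(out_dir, "rpw8_groups.tsv"))
    }
    write_tsv_report(log_df, file.path(out_dir, "filter_log.tsv"))
    write_json_report(meta, file.path(out_dir, "run_metadata.json"))
  }
  out
}
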