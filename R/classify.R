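# classify: combine domain architecture and NB-ARC signature into the
# subfamily category system (CNL / CNL2 / RNL / TNL plus truncated,
# atypical, undetermined and excluded forms).

CATEGORY_LEVELS <- c("CNL", "CNL2", "RNL", "TNL", "ATYPICAL",
                     "UNDETERMINED", "EXCLUDED")
CANONICAL_DOMAINS <- c("TIR", "RPW8", "NBARC", "LRR")

related_of <- function(category) {
  switch(category,
         TNL = "TNL_related", RNL = "RNL_related",
         CNL = "non_TIR", CNL2 = "non_TIR", "none")
}

#' Classify one sequence into an NLR subfamily category
#'
#' Decision procedure, in order: (1) no TIR, no RPW8 and no NB-ARC
#' evidence is excluded (coiled-coil-only and LRR-only sequences may be
#' mispredicted or unspecific); (2) without NB-ARC, a TIR (with or
#' without LRR) is a truncated TNL-related form and an RPW8 a truncated
#' RNL-related form; (3) with NB-ARC, the three signature slots (RNBS-A,
#' RNBS-D, MHD) vote and a 2-of-3 majority assigns the subfamily unless
#' the N-terminal domain contradicts it (e.g. a TIR over an RNL
#' signature), which is atypical; no majority (or all slots ambiguous or
#' absent) is undetermined; (4) an NB-ARC fused to a non-canonical extra
#' domain (e.g. a kinase) is atypical regardless of its vote. NB-ARC
#' presence is taken from the domain hits or, failing that, inferred from
#' a located motif chain.
#'
#' @param record a single-row `protein_records` data frame.
#' @param hits a `domain_hits` data frame (all sequences; the relevant
#'   rows are selected and merged internally).
#' @param signature the record's row from [nbarc_signatures()] (or
#'   `NULL`/a `nbarc_signature` from [locate_nbarc()]).
#' @return a one-row data frame (`subfamily_call`): `seq_id`, `species`,
#'   `category`, `related_group`, `architecture`, `truncated`, domain
#'   flags, the three signature calls and the NB-ARC anchor span.
#' @export
call_category <- function(record, hits, signature = NULL) {
  h <- hits[hits$seq_id == record$id[1], , drop = FALSE]
  if (nrow(h) > 0) h <- merge_domain_hits(h)
  doms <- unique(h$domain)
  has_tir <- "TIR" %in% doms
  has_rpw8 <- "RPW8" %in% doms
  has_lrr <- "LRR" %in% doms
  other <- setdiff(doms, CANONICAL_DOMAINS)

  if (is.null(signature)) {
    sig <- list(found = FALSE, rnbs_a_call = "absent",
                rnbs_d_call = "absent", mhd_call = "absent",
                anchor_start = NA_integer_, anchor_end = NA_integer_)
  } else if (inherits(signature, "nbarc_signature")) {
    sig <- c(signature, found = TRUE)
  } else {
    sig <- as.list(signature)
  }
  has_nbarc <- ("NBARC" %in% doms) || isTRUE(sig$found)

  calls <- c(sig$rnbs_a_call, sig$rnbs_d_call, sig$mhd_call)
  votes <- table(factor(calls, levels = c("CNL", "CNL2", "RNL", "TNL")))
  winner <- names(votes)[votes >= 2]
  winner <- if (length(winner) == 1) winner else NA_character_

  if (!has_tir && !has_rpw8 && !has_nbarc) {
    category <- "EXCLUDED"
  } else if (!has_nbarc) {
    category <- if (has_tir && has_rpw8) "ATYPICAL"
                else if (has_tir) "TNL" else "RNL"
  } else if (length(other) > 0) {
    category <- "ATYPICAL"
  } else if (!is.na(winner)) {
    contradicted <- (has_tir && winner != "TNL") ||
      (has_rpw8 && winner != "RNL")
    category <- if (contradicted) "ATYPICAL" else winner
  } else {
    category <- "UNDETERMINED"
  }

  truncated <- category %in% c("CNL", "CNL2", "RNL", "TNL") &&
    (!has_nbarc ||
       (category == "TNL" && !has_tir) ||
       (category == "RNL" && !has_rpw8))

  nb_tag <- if (has_nbarc) {
    if (!is.na(winner)) paste0("NB_", winner) else "NB"
  } else NULL
  pieces <- c(if (has_tir) "TIR", if (has_rpw8) "RPW8", nb_tag, other,
              if (has_lrr) "(LRR)")
  architecture <- paste(pieces, collapse = "-")

  out <- data.frame(seq_id = record$id[1], species = record$species[1],
                    category = category, related_group = related_of(category),
                    architecture = architecture, truncated = truncated,
                    has_tir = has_tir, has_rpw8 = has_rpw8,
                    has_nbarc = has_nbarc, has_lrr = has_lrr,
                    rnbs_a = sig$rnbs_a_call, rnbs_d = sig$rnbs_d_call,
                    mhd = sig$mhd_call,
                    anchor_start = sig$anchor_start %||% NA_integer_,
                    anchor_end = sig$anchor_end %||% NA_integer_,
                    stringsAsFactors = FALSE)
  class(out) <- c("subfamily_call", "data.frame")
  out
}

#' Classify every record in a dataset
#'
#' Computes NB-ARC signatures with [nbarc_signatures()] and applies
#' [call_category()] to each record. The result partitions the input:
#' every record receives exactly one category.
#'
#' @param records a `protein_records` data frame.
#' @param hits a `domain_hits` data frame.
#' @param config a `motif_config`.
#' @return a `subfamily_call` data frame with one row per record.
#' @export
classify_records <- function(records, hits, config = default_motif_config()) {
  sigs <- nbarc_signatures(records, config)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    call_category(records[i, , drop = FALSE], hits,
                  sigs[sigs$seq_id == records$id[i], , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("subfamily_call", "data.frame")
  out
}

#' Remove redundant near-identical sequences
#'
#' Greedy clustering at a high identity cutoff (default 0.97, targeting
#' allelic variants and alternative transcripts of one gene) keeps one
#' representative per cluster: the longest member, ties broken by the
#' lexicographically smallest id. All downstream censuses should run on
#' the deduplicated set.
#'
#' @param records a `protein_records` data frame.
#' @param calls optional `subfamily_call` data frame filtered alongside.
#' @param identity_cutoff identity threshold (default 0.97).
#' @return list with `records` (representatives), `calls` (matching
#'   subset or `NULL`), `clusters`, and `log` (before/after counts).
#' @export
deduplicate <- function(records, calls = NULL, identity_cutoff = 0.97) {
  cl <- greedy_cluster(records, identity_cutoff)
  keep <- vapply(cl, `[[`, "", "representative")
  rec <- records[match(keep, records$id), , drop = FALSE]
  rownames(rec) <- NULL
  out_calls <- if (!is.null(calls)) {
    calls[calls$seq_id %in% keep, , drop = FALSE]
  }
  list(records = rec, calls = out_calls, clusters = cl,
       log = data.frame(step = "deduplicate", n_in = nrow(records),
                        n_out = nrow(rec), stringsAsFactors = FALSE))
}
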