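# motifs: degenerate-consensus motif model, scanning, and NB-ARC chain
# anchoring. Subfamily-discriminant positions must match exactly; other
# positions tolerate a configurable number of mismatches.

MOTIF_SUBFAMILIES <- c("CNL", "CNL2", "RNL", "TNL", "SHARED")

#' Define a degenerate consensus motif
#'
#' @param name motif name (e.g. `"RNBS_D_RNL"`).
#' @param pattern compact pattern string: uppercase residue = exact,
#'   `h` = hydrophobic, `x` = any.
#' @param discriminant 1-based positions that must match exactly; they
#'   must point at exact-residue symbols and are never relaxed.
#' @param subfamily one of `CNL`, `CNL2`, `RNL`, `TNL`, `SHARED`.
#' @return a `motif_def` list.
#' @export
motif_def <- function(name, pattern, discriminant = integer(), subfamily = "SHARED") {
  syms <- strsplit(pattern, "")[[1]]
  if (length(syms) < 3) stop_input("motif '", name, "': pattern length < 3")
  legal <- syms %in% c(AA_STANDARD, "h", "x")
  if (!all(legal)) {
    stop_input("motif '", name, "': illegal pattern symbol(s) '",
               paste(unique(syms[!legal]), collapse = "' '"), "'")
  }
  discriminant <- as.integer(discriminant)
  if (any(discriminant < 1L) || any(discriminant > length(syms))) {
    stop_input("motif '", name, "': discriminant position out of range")
  }
  if (any(!syms[discriminant] %in% AA_STANDARD)) {
    stop_input("motif '", name, "': discriminant positions must be exact residues")
  }
  if (!subfamily %in% MOTIF_SUBFAMILIES) {
    stop_input("motif '", name, "': unknown subfamily tag '", subfamily, "'")
  }
  if (subfamily != "SHARED" && length(discriminant) == 0) {
    stop_input("motif '", name, "': subfamily-tagged motif needs >= 1 ",
               "discriminant position")
  }
  structure(list(name = name, pattern = syms,
                 discriminant = sort(unique(discriminant)),
                 subfamily = subfamily),
            class = "motif_def")
}

#' Load a motif configuration
#'
#' Reads a YAML motif configuration (see the packaged
#' `motifs_default.yaml` for the format) and validates every motif. The
#' configuration holds the hydrophobic residue set used for `h` symbols,
#' the default mismatch tolerance, and the inter-motif spacing window of
#' the NB-ARC chain.
#'
#' @param path path to a YAML config; the packaged default when `NULL`.
#' @return a `motif_config` list with elements `motifs` (named list of
#'   [motif_def()]), `hydrophobic`, `max_mismatch`, `spacing`.
#' @export
load_motif_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motifs_default.yaml", package = "nlrcensus")
  }
  if (!file.exists(path)) stop_input("motif config not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$motifs)) stop_input("motif config has no 'motifs' entry")
  motifs <- lapply(raw$motifs, function(m) {
    motif_def(m$name, m$pattern, m$discriminant %||% integer(),
              m$subfamily %||% "SHARED")
  })
  names(motifs) <- vapply(motifs, `[[`, "", "name")
  if (anyDuplicated(names(motifs))) stop_input("duplicate motif names in config")
  hyd <- strsplit(raw$hydrophobic %||% "AVLIMFWY", "")[[1]]
  if (any(!hyd %in% AA_STANDARD)) stop_input("illegal hydrophobic set")
  spacing <- c(min = as.numeric(raw$spacing$min %||% 20),
               max = as.numeric(raw$spacing$max %||% 180))
  if (spacing["min"] < 0 || spacing["max"] < spacing["min"]) {
    stop_input("invalid spacing window")
  }
  structure(list(motifs = motifs, hydrophobic = hyd,
                 max_mismatch = as.integer(raw$max_mismatch %||% 1L),
                 spacing = spacing),
            class = "motif_config")
}

#' The packaged default motif configuration
#' @return a `motif_config` (see [load_motif_config()]).
#' @export
default_motif_config <- function() load_motif_config(NULL)

#' Scan a sequence for a degenerate motif
#'
#' Returns every start position at which all discriminant positions match
#' exactly, `h` positions fall in the hydrophobic set, `x` positions
#' always match, and the total number of mismatches at non-discriminant
#' positions is at most `max_mismatch`. An `X` in the sequence matches
#' nothing (it fails a discriminant and counts as a mismatch elsewhere).
#'
#' @param record a single-row `protein_records` data frame, or a plain
#'   sequence string.
#' @param motif a [motif_def()].
#' @param window optional `c(from, to)` residue interval the whole motif
#'   must lie in; the whole sequence when `NULL`.
#' @param max_mismatch mismatch tolerance at non-discriminant positions.
#' @param hydrophobic hydrophobic residue set for `h` symbols.
#' @return data frame (`seq_id`, `motif`, `start`, `mismatches`) sorted
#'   by (mismatches, start); zero rows when there is no hit.
#' @export
scan_motif <- function(record, motif, window = NULL, max_mismatch = 1,
                       hydrophobic = strsplit("AVLIMFWY", "")[[1]]) {
  if (is.character(record)) {
    seq <- record[1]
    seq_id <- names(record)[1] %||% "seq"
  } else {
    seq <- record$seq[1]
    seq_id <- record$id[1]
  }
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  L <- length(motif$pattern)
  if (is.null(window)) window <- c(1L, n)
  from <- max(1L, as.integer(window[1]))
  to <- min(n, as.integer(window[2]))
  empty <- data.frame(seq_id = character(), motif = character(),
                      start = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (to - from + 1L < L) return(empty)
  starts <- from:(to - L + 1L)
  ok <- rep(TRUE, length(starts))
  mm <- integer(length(starts))
  disc <- motif$discriminant
  for (p in seq_len(L)) {
    res <- chars[starts + p - 1L]
    sym <- motif$pattern[p]
    hit <- switch(sym,
                  h = res %in% hydrophobic,
                  x = rep(TRUE, length(res)),
                  res == sym)
    hit[res == "X"] <- FALSE
    if (p %in% disc) ok <- ok & hit else mm <- mm + !hit
  }
  keep <- which(ok & mm <= max_mismatch)
  out <- data.frame(seq_id = rep(seq_id, length(keep)),
                    motif = rep(motif$name, length(keep)),
                    start = starts[keep], mismatches = mm[keep],
                    stringsAsFactors = FALSE)
  out[order(out$mismatches, out$start), , drop = FALSE]
}

# Scan one sequence for several motif variants; adds 'subfamily' and 'end'.
scan_variants <- function(record, motifs, config, window = NULL) {
  out <- lapply(motifs, function(m) {
    h <- scan_motif(record, m, window = window,
                    max_mismatch = config$max_mismatch,
                    hydrophobic = config$hydrophobic)
    if (nrow(h) > 0) {
      h$end <- h$start + length(m$pattern) - 1L
      h$subfamily <- m$subfamily
    }
    h
  })
  out <- out[vapply(out, nrow, 0L) > 0]
  if (length(out) == 0) {
    return(data.frame(seq_id = character(), motif = character(),
                      start = integer(), mismatches = integer(),
                      end = integer(), subfamily = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Resolve a slot call from variant hits inside a window: one subfamily
# tag -> that tag; several distinct tags -> "ambiguous"; none -> "absent".
slot_call <- function(hits) {
  if (nrow(hits) == 0) return("absent")
  tags <- unique(hits$subfamily)
  if (length(tags) == 1) tags else "ambiguous"
}

#' Locate the NB-ARC region and extract its subfamily signature
#'
#' Finds the best chain P-loop < Kinase-2 < GLPL < MHD-variant in
#' sequence order with inter-motif gaps (end of one to start of the next)
#' inside the configured spacing window. Among competing chains the one
#' with the fewest total mismatches wins; ties are broken by leftmost
#' P-loop, then Kinase-2, GLPL and MHD starts. The RNBS-A slot is then
#' scanned between P-loop and Kinase-2 and the RNBS-D slot between GLPL
#' and the MHD variant; each slot call is the subfamily tag of the
#' matching variant, `ambiguous` when variants of two subfamilies match,
#' `absent` when none does.
#'
#' @param record a single-row `protein_records` data frame.
#' @param config a `motif_config` (default: packaged).
#' @return an `nbarc_signature` list (`seq_id`, `rnbs_a_call`,
#'   `rnbs_d_call`, `mhd_call`, `anchor_start`, `anchor_end`), or `NULL`
#'   when no chain exists.
#' @export
locate_nbarc <- function(record, config = default_motif_config()) {
  mo <- config$motifs
  sp_min <- config$spacing[["min"]]
  sp_max <- config$spacing[["max"]]
  one <- function(name) {
    h <- scan_motif(record, mo[[name]], max_mismatch = config$max_mismatch,
                    hydrophobic = config$hydrophobic)
    if (nrow(h) > 0) h$end <- h$start + length(mo[[name]]$pattern) - 1L
    h
  }
  ploop <- one("PLOOP"); kin2 <- one("KIN2"); glpl <- one("GLPL")
  mhd_defs <- mo[grepl("^MHD_", names(mo))]
  mhd <- scan_variants(record, mhd_defs, config)
  if (nrow(ploop) == 0 || nrow(kin2) == 0 || nrow(glpl) == 0 || nrow(mhd) == 0) {
    return(NULL)
  }
  gap_ok <- function(prev_end, next_start) {
    g <- next_start - prev_end
    g >= sp_min & g <= sp_max
  }
  best <- NULL
  for (i in seq_len(nrow(ploop))) for (j in seq_len(nrow(kin2))) {
    if (!gap_ok(ploop$end[i], kin2$start[j])) next
    for (k in seq_len(nrow(glpl))) {
      if (!gap_ok(kin2$end[j], glpl$start[k])) next
      for (l in seq_len(nrow(mhd))) {
        if (!gap_ok(glpl$end[k], mhd$start[l])) next
        cand <- c(ploop$mismatches[i] + kin2$mismatches[j] +
                    glpl$mismatches[k] + mhd$mismatches[l],
                  ploop$start[i], kin2$start[j], glpl$start[k], mhd$start[l],
                  i, j, k, l)
        if (is.null(best)) {
          best <- cand
        } else {
          for (z in 1:5) {
            if (cand[z] < best[z]) { best <- cand; break }
            if (cand[z] > best[z]) break
          }
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  i <- best[6]; j <- best[7]; k <- best[8]; l <- best[9]
  # MHD call: tags of variants matching at the chain's MHD start
  mhd_here <- mhd[mhd$start == mhd$start[l], , drop = FALSE]
  rnbs_a_defs <- mo[grepl("^RNBS_A_", names(mo))]
  rnbs_d_defs <- mo[grepl("^RNBS_D_", names(mo))]
  wa <- c(ploop$end[i] + 1L, kin2$start[j] - 1L)
  wd <- c(glpl$end[k] + 1L, mhd$start[l] - 1L)
  ra <- scan_variants(record, rnbs_a_defs, config, window = wa)
  rd <- scan_variants(record, rnbs_d_defs, config, window = wd)
  structure(list(seq_id = record$id[1],
                 rnbs_a_call = slot_call(ra),
                 rnbs_d_call = slot_call(rd),
                 mhd_call = slot_call(mhd_here),
                 anchor_start = ploop$start[i],
                 anchor_end = mhd$end[l]),
            class = "nbarc_signature")
}

#' NB-ARC signatures for a whole set of records
#'
#' @param records a `protein_records` data frame.
#' @param config a `motif_config`.
#' @return data frame with one row per record: `seq_id`, `found`,
#'   `rnbs_a_call`, `rnbs_d_call`, `mhd_call`, `anchor_start`,
#'   `anchor_end` (NA when no chain was found).
#' @export
nbarc_signatures <- function(records, config = default_motif_config()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    sig <- locate_nbarc(records[i, , drop = FALSE], config)
    if (is.null(sig)) {
      data.frame(seq_id = records$id[i], found = FALSE,
                 rnbs_a_call = "absent", rnbs_d_call = "absent",
                 mhd_call = "absent", anchor_start = NA_integer_,
                 anchor_end = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(seq_id = sig$seq_id, found = TRUE,
                 rnbs_a_call = sig$rnbs_a_call, rnbs_d_call = sig$rnbs_d_call,
                 mhd_call = sig$mhd_call, anchor_start = sig$anchor_start,
                 anchor_end = sig$anchor_end, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
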