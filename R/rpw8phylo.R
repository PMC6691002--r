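# rpw8phylo: extraction of full-length RPW8 domains, pairwise distance
# matrices, neighbor-joining trees and assignment of sequences to the
# four RNL groups via reference anchors (ADR1 for group 2; NRG1, RPW8.1
# and RPW8.2 for group 4; packaged conifer exemplars for groups 1 and 3).

#' Extract full-length RPW8 domains
#'
#' One extracted domain per RPW8 hit strictly longer than `min_length`
#' residues (the full-length criterion); shorter hits are dropped and
#' counted in the attached log.
#'
#' @param records a `protein_records` data frame.
#' @param hits a `domain_hits` data frame.
#' @param min_length minimum length, exclusive (default 100: only
#'   domains of more than 100 amino acids qualify).
#' @return a `protein_records` data frame of extracted domains (ids are
#'   `<seq_id>_RPW8_<start>` when a sequence has several hits, else the
#'   source id), with attributes `source` (seq_id/start/end table) and
#'   `log`.
#' @export
extract_rpw8 <- function(records, hits, min_length = 100) {
  h <- hits[hits$domain == "RPW8", , drop = FALSE]
  if (nrow(h) > 0) h <- merge_domain_hits(h)
  n_in <- nrow(h)
  len <- h$end - h$start + 1L
  h <- h[len > min_length, , drop = FALSE]
  if (nrow(h) == 0) {
    out <- protein_records(character(), character())
  } else {
    idx <- match(h$seq_id, records$id)
    if (anyNA(idx)) stop_input("RPW8 hit for unknown sequence id")
    multi <- h$seq_id %in% h$seq_id[duplicated(h$seq_id)]
    ids <- ifelse(multi, paste0(h$seq_id, "_RPW8_", h$start), h$seq_id)
    seqs <- substring(records$seq[idx], h$start, h$end)
    out <- protein_records(ids, seqs, species = records$species[idx])
  }
  attr(out, "source") <- if (nrow(h) > 0) {
    data.frame(id = out$id, seq_id = h$seq_id, start = h$start, end = h$end,
               stringsAsFactors = FALSE)
  }
  attr(out, "log") <- data.frame(step = "extract_rpw8", n_in = n_in,
                                 n_out = nrow(out), stringsAsFactors = FALSE)
  out
}

#' Pairwise alignment-distance matrix
#'
#' Distance = 1 - global identity (see [global_identity()]); symmetric,
#' non-negative, zero diagonal.
#'
#' @param domains a `protein_records` data frame (>= 2 rows).
#' @param scoring optional scoring override.
#' @return a symmetric numeric matrix with sequence ids as labels.
#' @export
pairwise_distances <- function(domains, scoring = NULL) {
  n <- nrow(domains)
  if (n < 2) stop_input("need at least two sequences")
  d <- matrix(0, n, n, dimnames = list(domains$id, domains$id))
  for (i in seq_len(n - 1)) {
    ids <- identity_to_many(domains$seq[i], domains$seq[(i + 1):n], scoring)
    d[i, (i + 1):n] <- 1 - ids
    d[(i + 1):n, i] <- 1 - ids
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]), which recovers additive
#' distance matrices exactly. On non-additive inputs, any negative branch
#' length is clamped to zero and its deficit transferred to the sibling
#' branch so that sibling path lengths are preserved.
#'
#' @param dm symmetric distance matrix with labels (>= 3).
#' @return an unrooted [ape::phylo] tree whose leaves are the labels.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop_input("neighbor joining needs at least 3 labels")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop_input("distance matrix is not symmetric")
  }
  tr <- ape::nj(as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    tr$edge.length[e] <- 0
    if (length(sib) > 0) {
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
      if (tr$edge.length[sib[1]] < 0) tr$edge.length[sib[1]] <- 0
    }
  }
  tr
}

#' Load RPW8 reference anchors
#'
#' Reads an anchor FASTA whose headers carry `group=<n>` tokens and
#' returns records plus the id-to-group map. The packaged default is a
#' synthetic stand-in set (see `rpw8_anchors_synthetic.fasta`): the
#' anchor ids follow the real reference names (ADR1, NRG1, RPW8.1,
#' RPW8.2, plus conifer group 1/3 exemplars) but the sequences are
#' generated, not database records.
#'
#' @param path anchor FASTA; packaged default when `NULL`.
#' @return list with `records` (`protein_records`) and `groups` (named
#'   character vector id -> group label).
#' @export
load_rpw8_anchors <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rpw8_anchors_synthetic.fasta",
                        package = "nlrcensus")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^>", lines)]
  ids <- sub("^>(\\S+).*", "\\1", hdr)
  grp <- sub(".*group=(\\S+).*", "\\1", hdr)
  rec <- read_fasta(path, species = "anchor")
  list(records = rec, groups = setNames(grp, ids))
}

validate_anchor_groups <- function(groups) {
  need <- c("1", "2", "3", "4")
  missing <- setdiff(need, unique(groups))
  if (length(missing) > 0) {
    stop_input("anchor set lacks group(s): ", paste(missing, collapse = ", "))
  }
  if (!any(grepl("^ADR1", names(groups)[groups == "2"]))) {
    stop_input("group 2 anchors must contain ADR1")
  }
  g4 <- names(groups)[groups == "4"]
  for (nm in c("NRG1", "RPW8.1", "RPW8.2")) {
    if (!any(startsWith(g4, nm))) {
      stop_input("group 4 anchors must contain ", nm)
    }
  }
  invisible(TRUE)
}

#' Assign RPW8 domains to RNL groups
#'
#' Each query is assigned the group of its nearest anchor, either by
#' patristic distance on a neighbor-joining tree over queries plus
#' anchors (`mode = "patristic"`) or by raw alignment distance
#' (`mode = "nearest_reference"`). The margin is the distance gap to the
#' nearest anchor of any other group; a query equidistant (within 1e-12)
#' from two groups is left unassigned.
#'
#' @param domains query `protein_records` (extracted RPW8 domains).
#' @param anchors anchor set from [load_rpw8_anchors()] (or a compatible
#'   list with `records` and `groups`).
#' @param mode `"patristic"` or `"nearest_reference"`.
#' @param scoring optional scoring override.
#' @return data frame: `seq_id`, `group`, `nearest_anchor`, `margin`.
#' @export
assign_groups <- function(domains, anchors = load_rpw8_anchors(),
                          mode = c("patristic", "nearest_reference"),
                          scoring = NULL) {
  mode <- match.arg(mode)
  validate_anchor_groups(anchors$groups)
  if (any(domains$id %in% anchors$records$id)) {
    stop_input("query ids collide with anchor ids")
  }
  all_rec <- rbind(domains[, c("id", "species", "seq", "length")],
                   anchors$records[, c("id", "species", "seq", "length")])
  class(all_rec) <- c("protein_records", "data.frame")
  dm <- pairwise_distances(all_rec, scoring)
  if (mode == "patristic") {
    tr <- nj_tree(dm)
    dm <- cophenetic(tr)[all_rec$id, all_rec$id]
  }
  anchor_ids <- anchors$records$id
  rows <- lapply(domains$id, function(q) {
    d <- dm[q, anchor_ids]
    grp <- anchors$groups[anchor_ids]
    best <- which.min(d)
    best_group <- grp[best]
    other <- d[grp != best_group]
    margin <- if (length(other) > 0) min(other) - d[best] else Inf
    assigned <- if (is.finite(margin) && margin < 1e-12) "unassigned"
                else unname(best_group)
    data.frame(seq_id = q, group = assigned,
               nearest_anchor = anchor_ids[best], margin = unname(margin),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
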