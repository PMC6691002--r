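# clusterseq: pairwise global-alignment identity and CD-HIT-style greedy
# incremental clustering at configurable identity cutoffs.

# BLOSUM62 with the Biostrings affine-gap convention: a gap of length L
# costs gapOpening + L * gapExtension.
align_scoring <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- list(sub = e$BLOSUM62, open = 11, ext = 1)
    }
    cache
  }
})

seq_to_idx <- function(seq, alphabet) {
  i <- match(strsplit(seq, "")[[1]], alphabet)
  if (anyNA(i)) stop_input("residue outside the scoring alphabet in: ", seq)
  i - 1L
}

#' Global-alignment identity between two protein sequences
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1). Identity is the number of identical aligned
#' residue pairs divided by the length of the shorter sequence (the
#' CD-HIT global-identity convention). Among co-optimal alignments the
#' maximal match count is used, so the result is deterministic.
#'
#' @param a,b single-row `protein_records` data frames or plain strings.
#' @param scoring optional list (`sub`, `open`, `ext`) overriding the
#'   default scoring.
#' @return a `pairwise_identity` list: `id_a`, `id_b`, `identity`,
#'   `matches`, `score`, `shorter_length`.
#' @export
global_identity <- function(a, b, scoring = NULL) {
  get1 <- function(x, default_id) {
    if (is.character(x)) list(id = names(x)[1] %||% default_id, seq = x[[1]])
    else list(id = x$id[1], seq = x$seq[1])
  }
  ra <- get1(a, "a"); rb <- get1(b, "b")
  if (!nzchar(ra$seq) || !nzchar(rb$seq)) stop_input("empty sequence")
  sc <- scoring %||% align_scoring()
  alphabet <- rownames(sc$sub)
  res <- .align_global_stats(seq_to_idx(ra$seq, alphabet),
                             seq_to_idx(rb$seq, alphabet),
                             sc$sub, sc$open, sc$ext)
  shorter <- min(nchar(ra$seq), nchar(rb$seq))
  structure(list(id_a = ra$id, id_b = rb$id,
                 identity = res$matches / shorter,
                 matches = res$matches, score = res$score,
                 shorter_length = shorter),
            class = "pairwise_identity")
}

# identity of one query against many subject sequences (same scoring)
identity_to_many <- function(query_seq, subject_seqs, scoring = NULL) {
  sc <- scoring %||% align_scoring()
  alphabet <- rownames(sc$sub)
  qi <- seq_to_idx(query_seq, alphabet)
  vapply(subject_seqs, function(s) {
    res <- .align_global_stats(qi, seq_to_idx(s, alphabet), sc$sub, sc$open, sc$ext)
    res$matches / min(length(qi), nchar(s))
  }, 0)
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style clustering: records are processed in deterministic order
#' (length descending, ties by id ascending); each record joins the first
#' existing cluster whose representative has identity >= `cutoff` to it,
#' otherwise it founds a new cluster with itself as representative.
#' Because identity is measured against the shorter sequence, a record
#' can never out-rank an earlier (longer) representative, so
#' representatives are always the longest members.
#'
#' @param records a `protein_records` data frame.
#' @param cutoff identity cutoff in (0, 1].
#' @param scoring optional scoring override (see [global_identity()]).
#' @return a `nlr_clusters` list of clusters, each with `representative`,
#'   `members` (ids), `identities` (to the representative) and `cutoff`;
#'   ordered by representative length (descending).
#' @export
greedy_cluster <- function(records, cutoff, scoring = NULL) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop_input("cutoff must be in (0, 1]")
  }
  ord <- order(-records$length, records$id)
  rec <- records[ord, , drop = FALSE]
  reps <- integer(0)           # row indices (in rec) of representatives
  assign <- integer(nrow(rec)) # cluster index per row
  idents <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    placed <- FALSE
    if (length(reps) > 0) {
      # length short-circuit: identity is capped by len_i / len_rep
      viable <- which(rec$length[i] / rec$length[reps] >= cutoff |
                        rec$length[reps] == rec$length[i])
      if (length(viable) > 0) {
        ids <- identity_to_many(rec$seq[i], rec$seq[reps[viable]], scoring)
        hit <- which(ids >= cutoff)
        if (length(hit) > 0) {
          k <- viable[hit[1]]
          assign[i] <- k
          idents[i] <- ids[hit[1]]
          placed <- TRUE
        }
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
      idents[i] <- 1
    }
  }
  clusters <- lapply(seq_along(reps), function(k) {
    rows <- which(assign == k)
    list(representative = rec$id[reps[k]],
         members = rec$id[rows],
         identities = idents[rows],
         cutoff = cutoff)
  })
  structure(clusters, class = "nlr_clusters")
}

#' Flatten clusters into a TSV-ready table
#'
#' @param clusters a `nlr_clusters` object.
#' @return data frame: `representative`, `member`,
#'   `identity_to_representative`, `cutoff`.
#' @export
clusters_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(representative = cl$representative, member = cl$members,
               identity_to_representative = cl$identities,
               cutoff = cl$cutoff, stringsAsFactors = FALSE)
  }))
}
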