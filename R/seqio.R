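# seqio: sequence/domain data model and readers/writers for every external
# format the pipeline touches (protein FASTA, hmmscan-style domain tables,
# TSV/JSON reports, Newick trees).

# Pfam accessions recognised by the domain-table reader. LRR covers the
# nine LRR families plus LRRNT.
PFAM_DOMAIN_MAP <- c(
  PF00931 = "NBARC",
  PF01582 = "TIR",
  PF05659 = "RPW8",
  PF00560 = "LRR", PF07723 = "LRR", PF07725 = "LRR", PF12799 = "LRR",
  PF13306 = "LRR", PF13516 = "LRR", PF13855 = "LRR", PF14580 = "LRR",
  PF01462 = "LRR"
)

DOMAIN_LEVELS <- c("TIR", "RPW8", "NBARC", "LRR", "OTHER")

#' Construct a set of protein records
#'
#' The core sequence container: a data frame with columns `id`, `species`,
#' `seq` and `length`. Sequences are uppercased; terminal `*` stop
#' characters are stripped; ids must be unique and sequences non-empty.
#' Only the 20 standard residues plus `X` are accepted.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of amino-acid sequences.
#' @param species species tag, recycled (default `"unknown"`).
#' @return a data frame of class `protein_records`.
#' @export
protein_records <- function(id, seq, species = "unknown") {
  if (length(id) != length(seq)) stop_input("id and seq lengths differ")
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  seq <- sub("\\*+$", "", seq)
  if (anyDuplicated(id)) {
    stop_input("duplicate sequence id(s): ",
               paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seq))) {
    stop_input("empty sequence for id(s): ",
               paste(id[!nzchar(seq)], collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(c(AA_STANDARD, "X"), collapse = ""), "]"), seq)
  if (any(bad)) {
    if (any(grepl("[BDHUVN]", seq[bad]) & !grepl("[EFILPQZ*]", seq[bad]))) {
      # crude guard: a residue alphabet confined to nucleotide-compatible
      # letters suggests nucleotide input, which is out of scope
    }
    stop_input("non-amino-acid characters in sequence(s): ",
               paste(id[bad], collapse = ", "),
               " (nucleotide input and ORF prediction are not supported; ",
               "supply predicted peptides)")
  }
  out <- data.frame(id = id, species = rep_len(as.character(species), length(id)),
                    seq = seq, length = nchar(seq), stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] with a validation pass that
#' reports malformed headers and empty entries with their line numbers,
#' and rejects duplicate ids. Sequences are uppercased and terminal stop
#' characters (`*`) removed. The first whitespace-delimited token of each
#' header is the id.
#'
#' @param path path to a FASTA file of predicted peptides.
#' @param species species tag attached to every record.
#' @return a `protein_records` data frame.
#' @export
read_fasta <- function(path, species = "unknown") {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^;", lines)]
  if (length(lines) == 0) stop_input("FASTA format error at line 1: empty file")
  hdr <- grepl("^>", lines)
  if (!hdr[1] && any(nzchar(trimws(lines)))) {
    stop_input("FASTA format error at line 1: expected '>' header")
  }
  hpos <- which(hdr)
  for (k in seq_along(hpos)) {
    i <- hpos[k]
    if (!nzchar(trimws(sub("^>", "", lines[i])))) {
      stop_input("FASTA format error at line ", i, ": empty header")
    }
    to <- if (k < length(hpos)) hpos[k + 1] - 1 else length(lines)
    body <- paste(trimws(lines[seq(i + 1, length.out = max(0, to - i))]),
                  collapse = "")
    body <- sub("\\*+$", "", body)
    if (!nzchar(body)) {
      stop_input("FASTA format error at line ", i, ": empty sequence for '",
                 sub("^>(\\S+).*", "\\1", lines[i]), "'")
    }
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  protein_records(ids, as.character(aa), species = species)
}

#' Write protein records to FASTA
#'
#' @param records a `protein_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Construct a table of domain hits
#'
#' Coordinates are 1-based inclusive residue positions on the protein.
#'
#' @param seq_id sequence identifiers.
#' @param domain domain labels: `TIR`, `RPW8`, `NBARC`, `LRR`, or any
#'   other name (kept as-is and treated as non-canonical).
#' @param start,end 1-based inclusive interval.
#' @param evalue hit e-value (>= 0).
#' @param source one of `external_table`, `planted`, `motif_inferred`.
#' @return a data frame of class `domain_hits`.
#' @export
domain_hits <- function(seq_id, domain, start, end, evalue = 0,
                        source = "external_table") {
  n <- length(seq_id)
  out <- data.frame(seq_id = as.character(seq_id),
                    domain = as.character(domain),
                    start = as.integer(start), end = as.integer(end),
                    evalue = rep_len(as.numeric(evalue), n),
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  if (n > 0) {
    if (anyNA(out$seq_id) || anyNA(out$start) || anyNA(out$end) ||
        anyNA(out$evalue)) {
      stop_input("missing values in domain hits")
    }
    if (any(out$start < 1L) || any(out$end < out$start)) {
      stop_input("invalid domain interval (need 1 <= start <= end)")
    }
    if (any(out$evalue < 0)) stop_input("negative e-value")
  }
  class(out) <- c("domain_hits", "data.frame")
  out
}

#' Read domain hits from an hmmscan-style per-domain table
#'
#' Parses the whitespace-delimited per-domain tabular dialect of a
#' profile-HMM scanner (one domain hit per row, `#` comment lines).
#' Column 1 is the model name, column 2 its accession, column 4 the query
#' sequence id, column 13 the per-domain independent e-value, and columns
#' 18/19 the alignment coordinates on the sequence. Pfam accessions are
#' mapped to canonical labels (PF00931 to NBARC, PF01582 to TIR, PF05659
#' to RPW8, the LRR family accessions to LRR); anything else becomes an
#' `OTHER` hit carrying the model name. Hits above `evalue_max` are
#' dropped; unparseable rows are skipped with a warning and counted in
#' the `n_skipped` attribute.
#'
#' @param path path to the table.
#' @param evalue_max maximum per-domain e-value retained (default 0.03,
#'   the hit-level significance threshold; the model-level 0.01 and the
#'   broad Pfam pre-filter 1.0 are exposed separately in
#'   [pipeline_config()]).
#' @return a `domain_hits` data frame with attribute `n_skipped`.
#' @export
read_domain_table <- function(path, evalue_max = 0.03) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  skipped <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    ok <- length(f) >= 19
    if (ok) {
      ev <- suppressWarnings(as.numeric(f[13]))
      st <- suppressWarnings(as.integer(f[18]))
      en <- suppressWarnings(as.integer(f[19]))
      ok <- !is.na(ev) && !is.na(st) && !is.na(en) && ev >= 0 &&
        st >= 1L && en >= st
    }
    if (!ok) {
      skipped <- skipped + 1L
      next
    }
    acc <- sub("\\..*$", "", f[2])
    dom <- unname(PFAM_DOMAIN_MAP[acc])
    if (is.na(dom)) dom <- f[1]
    rows[[i]] <- data.frame(seq_id = f[4], domain = dom, start = st, end = en,
                            evalue = ev, stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    warning(skipped, " unparseable row(s) skipped in ", path, call. = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    out <- domain_hits(character(), character(), integer(), integer())
  } else {
    tab <- tab[tab$evalue <= evalue_max, , drop = FALSE]
    out <- domain_hits(tab$seq_id, tab$domain, tab$start, tab$end,
                       evalue = tab$evalue, source = "external_table")
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Write domain hits in the hmmscan-style per-domain dialect
#'
#' Emits the 19 leading columns of the per-domain tabular dialect that
#' [read_domain_table()] parses (unused columns padded with `-`/`0`), so
#' synthetic annotations round-trip through the same reader as real ones.
#'
#' @param hits a `domain_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  rev_map <- setNames(names(PFAM_DOMAIN_MAP)[match(c("NBARC", "TIR", "RPW8"),
                                                   PFAM_DOMAIN_MAP)],
                      c("NBARC", "TIR", "RPW8"))
  rev_map <- c(rev_map, LRR = "PF13855")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-domain hits (hmmscan-style dialect)", con)
  for (i in seq_len(nrow(hits))) {
    acc <- rev_map[hits$domain[i]]
    if (is.na(acc)) acc <- "-"
    len <- hits$end[i] - hits$start[i] + 1L
    writeLines(paste(hits$domain[i], acc, len, hits$seq_id[i], "-", 0,
                     hits$evalue[i], 0, 0, 1, 1,
                     hits$evalue[i], hits$evalue[i], 0, 0,
                     1, len, hits$start[i], hits$end[i],
                     sep = " "), con)
  }
  invisible(path)
}

#' Merge overlapping hits of the same domain
#'
#' Repeat domains (LRR in particular) produce tiled hits; architecture
#' calling works on their union intervals. Hits of the same
#' (sequence, domain) pair that overlap or touch are merged; the smallest
#' e-value is retained.
#'
#' @param hits a `domain_hits` data frame.
#' @return a merged `domain_hits` data frame.
#' @export
merge_domain_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  key <- paste(hits$seq_id, hits$domain, sep = "\r")
  parts <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    h <- hits[idx, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    st <- h$start[1]; en <- h$end[1]; ev <- h$evalue[1]; src <- h$source[1]
    out <- NULL
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] <= en + 1L) {
        en <- max(en, h$end[i]); ev <- min(ev, h$evalue[i])
      } else {
        out <- rbind(out, data.frame(seq_id = h$seq_id[1], domain = h$domain[1],
                                     start = st, end = en, evalue = ev,
                                     source = src, stringsAsFactors = FALSE))
        st <- h$start[i]; en <- h$end[i]; ev <- h$evalue[i]
      }
    }
    rbind(out, data.frame(seq_id = h$seq_id[1], domain = h$domain[1],
                          start = st, end = en, evalue = ev, source = src,
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  domain_hits(out$seq_id, out$domain, out$start, out$end, out$evalue, out$source)
}

#' Write a TSV report
#'
#' Tab-separated, no quoting, deterministic column order (as given).
#'
#' @param df a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON report
#'
#' @param x a list or data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are always written; the string is terminated by `;`.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
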