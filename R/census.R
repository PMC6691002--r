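# census_stats: per-species category census and the cross-species
# statistics built on it (distribution percentages, transcriptome
# ratios, chi-square homogeneity, RNL-vs-TNL regression).

CENSUS_ROWS <- data.frame(
  category = c("CNL", "CNL2", "RNL", "RNL", "RNL",
               "TNL", "TNL", "TNL", "TNL", "ATYPICAL", "UNDETERMINED"),
  row = c("NB_CNL-(LRR)", "NB_CNL2-(LRR)",
          "RPW8", "NB_RNL-(LRR)", "RPW8-NB_RNL-(LRR)",
          "TIR", "NB_TNL-(LRR)", "TIR-NB_TNL-(LRR)", "TIR-LRR",
          "Atypical", "Undetermined"),
  stringsAsFactors = FALSE
)

#' Census row label for one classified sequence
#'
#' Maps a subfamily call and its domain flags onto the canonical census
#' row labels (truncated forms get their own rows: `RPW8` for RPW8-only
#' RNL-related sequences, `TIR` and `TIR-LRR` for NB-less TNL-related
#' ones). The `(LRR)` in full-architecture labels marks an optional LRR.
#'
#' @param call a one-row `subfamily_call` data frame.
#' @return the census row label, or `NA` for excluded sequences.
#' @export
census_row <- function(call) {
  with(call, switch(category,
    CNL = "NB_CNL-(LRR)",
    CNL2 = "NB_CNL2-(LRR)",
    RNL = if (!has_nbarc) "RPW8"
          else if (has_rpw8) "RPW8-NB_RNL-(LRR)" else "NB_RNL-(LRR)",
    TNL = if (!has_nbarc) { if (has_lrr) "TIR-LRR" else "TIR" }
          else if (has_tir) "TIR-NB_TNL-(LRR)" else "NB_TNL-(LRR)",
    ATYPICAL = "Atypical",
    UNDETERMINED = "Undetermined",
    EXCLUDED = NA_character_))
}

#' Build a cross-species census from an architecture-row count table
#'
#' Takes per-species counts for each architecture row (as produced by
#' [census_counts_from_calls()] or supplied directly, e.g. the packaged
#' seven-conifer fixture) and the per-species assembled-transcriptome
#' sizes, and derives: total NLR per species, NLR-to-transcriptome ratios
#' (percent, half-up to 2 decimals), per-subfamily ratios, and the
#' distribution (percent of each subfamily among all assigned sequences
#' across species, half-up to integers). Truncated forms count within
#' their related subfamily (RPW8-only under RNL-related, TIR-only and
#' TIR-LRR under TNL-related); atypical and undetermined sequences count
#' in the NLR total but not in the assigned distribution denominator.
#'
#' @param counts data frame with columns `category`, `row`, then one
#'   numeric column per species. Missing rows count as zero.
#' @param transcriptome_sizes named numeric vector (species -> number of
#'   transcripts in the assembly).
#' @return an `nlr_census` list; see Details.
#' @details The returned list holds `counts` (the completed row table),
#'   `species`, `transcriptome_sizes`, `total_nlr`, `nlr_ratio_pct`,
#'   `subfamily_totals` (subfamily x species), `subfamily_ratio_pct`,
#'   `distribution_pct` (named CNL/CNL2/RNL/TNL vector) and
#'   `assigned_total`.
#' @export
build_census <- function(counts, transcriptome_sizes) {
  species <- names(transcriptome_sizes)
  if (is.null(species) || length(species) == 0) {
    stop_input("transcriptome_sizes must be a named vector")
  }
  full <- CENSUS_ROWS
  for (s in species) {
    idx <- if (nrow(counts) > 0) {
      match(paste(full$category, full$row), paste(counts$category, counts$row))
    } else rep(NA_integer_, nrow(full))
    v <- rep(0, nrow(full))
    if (s %in% names(counts)) v[!is.na(idx)] <- counts[[s]][idx[!is.na(idx)]]
    full[[s]] <- v
  }
  mat <- as.matrix(full[, species, drop = FALSE])
  rownames(mat) <- full$row
  subfam <- c("CNL", "CNL2", "RNL", "TNL")
  all_cats <- c(subfam, "ATYPICAL", "UNDETERMINED")
  sub_tot <- matrix(0, length(all_cats), length(species),
                    dimnames = list(all_cats, species))
  for (cat in all_cats) {
    sub_tot[cat, ] <- colSums(mat[full$category == cat, , drop = FALSE])
  }
  total_nlr <- colSums(sub_tot)
  ratio <- round_half_up(100 * total_nlr / transcriptome_sizes, 2)
  sub_ratio <- round_half_up(100 * sweep(sub_tot[subfam, , drop = FALSE], 2,
                                         transcriptome_sizes, "/"), 2)
  assigned <- sum(sub_tot[subfam, ])
  dist_pct <- if (assigned > 0) {
    round_half_up(100 * rowSums(sub_tot[subfam, , drop = FALSE]) / assigned, 0)
  } else setNames(rep(0, 4), subfam)
  structure(list(counts = full, species = species,
                 transcriptome_sizes = transcriptome_sizes,
                 total_nlr = total_nlr, nlr_ratio_pct = ratio,
                 subfamily_totals = sub_tot,
                 subfamily_ratio_pct = sub_ratio,
                 distribution_pct = dist_pct,
                 assigned_total = assigned),
            class = "nlr_census")
}

#' @export
print.nlr_census <- function(x, ...) {
  cat("NLR census across", length(x$species), "species\n")
  cat("Total NLR:", paste(x$species, x$total_nlr, sep = "=", collapse = " "),
      "\n")
  cat("NLR/transcriptome ratio (%):",
      paste(x$species, sprintf("%.2f", x$nlr_ratio_pct), sep = "=",
            collapse = " "), "\n")
  cat("Distribution over assigned sequences (%):",
      paste(names(x$distribution_pct), x$distribution_pct, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Aggregate subfamily calls into architecture-row counts
#'
#' @param calls a `subfamily_call` data frame with a `species` column.
#' @return wide data frame (`category`, `row`, one column per species)
#'   suitable for [build_census()]. Excluded sequences are dropped.
#' @export
census_counts_from_calls <- function(calls) {
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    census_row(calls[i, , drop = FALSE]) %||% NA_character_
  }, "")
  keep <- !is.na(rows)
  species <- sort(unique(calls$species))
  out <- CENSUS_ROWS
  for (s in species) {
    tab <- table(factor(rows[keep & calls$species == s], levels = CENSUS_ROWS$row))
    out[[s]] <- as.integer(tab[CENSUS_ROWS$row])
  }
  out
}

#' Load the packaged seven-conifer census fixture
#'
#' The architecture-row counts and assembled-transcriptome sizes for the
#' seven conifer species, as packaged data.
#'
#' @return list with `counts` (data frame) and `transcriptome_sizes`
#'   (named vector).
#' @export
load_conifer_census_fixture <- function() {
  counts <- read.delim(system.file("extdata", "table1_counts.tsv",
                                   package = "nlrcensus"),
                       stringsAsFactors = FALSE, check.names = FALSE)
  sizes <- read.delim(system.file("extdata", "table1_transcriptomes.tsv",
                                  package = "nlrcensus"),
                      stringsAsFactors = FALSE)
  list(counts = counts,
       transcriptome_sizes = setNames(sizes$transcripts, sizes$species))
}

#' NLR-to-transcriptome ratio
#'
#' @param total_nlr NLR sequence count.
#' @param transcriptome_size number of transcripts in the assembly.
#' @return percentage, rounded half-up to 2 decimals.
#' @export
nlr_ratio <- function(total_nlr, transcriptome_size) {
  if (any(transcriptome_size <= 0)) stop_input("transcriptome size must be > 0")
  round_half_up(100 * total_nlr / transcriptome_size, 2)
}

#' Chi-square homogeneity test of subfamily proportions
#'
#' Pearson chi-square without continuity correction on a species-by-
#' category count table; the p-value comes from the upper tail of the
#' chi-square distribution with (r-1)(c-1) degrees of freedom.
#'
#' @param counts numeric matrix (species x category).
#' @return list (`chi_square_result`): `statistic`, `df`, `p_value`,
#'   `observed`, `expected`.
#' @export
chi_square_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_input("negative counts")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop_input("degenerate table: expected cell count of zero")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), observed = counts,
                 expected = ct$expected),
            class = "chi_square_result")
}

#' Ordinary least-squares regression of subfamily counts
#'
#' Fits `y ~ x` with intercept and reports the overall F test on
#' (1, n-2) degrees of freedom. Used for the cross-species RNL-vs-TNL
#' relationship (and the RNL-vs-CNL null comparison).
#'
#' @param x predictor counts (e.g. TNL per species).
#' @param y response counts (e.g. RNL per species).
#' @return list (`regression_result`): `n`, `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
ols_regression <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y lengths differ")
  if (length(x) < 3) stop_input("need at least 3 points")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  n <- length(x)
  f <- unname(sm$fstatistic[1])
  structure(list(n = n, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared, f_statistic = f,
                 df1 = 1, df2 = n - 2,
                 p_value = pf(f, 1, n - 2, lower.tail = FALSE)),
            class = "regression_result")
}
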