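# synthetic: seed-deterministic generators that emulate the statistical
# structure every pipeline stage assumes, each with a machine-readable
# truth table.
#
# Proteome sequences are synthetic scaffolds: planted motif instances
# joined by linkers drawn from a "neutral" alphabet that cannot complete
# any discriminant residue combination, so the planted signal is the only
# signal. Mutations are applied through per-position uniform draws made
# independently of the mutation rate, so the mutated position set at a
# lower rate is nested inside the set at a higher rate for the same seed.

SAFE_LINKER_ALPHABET <- c("A", "E", "N", "R", "S", "T")
RPW8_ALPHABET <- c("A", "E", "N", "R", "S", "T", "V", "I", "L", "F", "Y")

rand_chars <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# instantiate a motif pattern; returns the sequence and the 1-based
# relative positions of its discriminant residues
instantiate_motif <- function(motif, hydrophobic) {
  chars <- vapply(motif$pattern, function(sym) {
    switch(sym,
           h = sample(hydrophobic, 1),
           x = sample(SAFE_LINKER_ALPHABET, 1),
           sym)
  }, "")
  list(seq = paste(chars, collapse = ""), disc = motif$discriminant)
}

build_nbarc_block <- function(category, config) {
  mo <- config$motifs
  hyd <- config$hydrophobic
  lk <- function(n) list(seq = rand_chars(n, SAFE_LINKER_ALPHABET))
  mseg <- function(name) {
    inst <- instantiate_motif(mo[[name]], hyd)
    list(seq = inst$seq, disc = inst$disc, motif = name)
  }
  rnbs_a <- switch(category, CNL = "RNBS_A_CNL", RNL = "RNBS_A_RNL",
                   TNL = "RNBS_A_TNL", CNL2 = NULL)
  rnbs_d <- paste0("RNBS_D_", category)
  mhd <- switch(category, CNL = "MHD_CNL", CNL2 = "MHD_CNL2",
                RNL = "MHD_RNL", TNL = "MHD_CNL")
  segs <- list(mseg("PLOOP"), lk(25))
  if (!is.null(rnbs_a)) {
    segs <- c(segs, list(mseg(rnbs_a), lk(25)))
  } else {
    segs <- c(segs, list(lk(55)))
  }
  segs <- c(segs, list(mseg("KIN2"), lk(25), mseg("KIN3"), lk(12),
                       mseg("RNBS_C"), lk(12), mseg("GLPL"), lk(25),
                       mseg(rnbs_d), lk(25), mseg(mhd)))
  segs
}

build_tir_block <- function(config) {
  mo <- config$motifs
  hyd <- config$hydrophobic
  lk <- function(n) list(seq = rand_chars(n, SAFE_LINKER_ALPHABET))
  mseg <- function(name) {
    inst <- instantiate_motif(mo[[name]], hyd)
    list(seq = inst$seq, motif = name)
  }
  list(lk(8), mseg("TIR1"), lk(10), mseg("TIR2"), lk(8), mseg("TIR3"),
       lk(8), mseg("TIR4"), lk(6), mseg("TIR5"), lk(8))
}

build_lrr_units <- function(n_units = 5) {
  unit <- "LRELDLSNNSL"
  lapply(seq_len(n_units), function(i) list(seq = unit, label = "LRR_unit"))
}

category_forms <- function(category, n) {
  alloc <- function(fracs, labels) {
    k <- floor(fracs * n)
    rest <- n - sum(k)
    rep(c(labels, "nb_lrr"), c(k, rest))
  }
  switch(category,
    CNL = rep("nb_lrr", n),
    CNL2 = rep("nb_lrr", n),
    RNL = alloc(c(0.2, 0.2), c("rpw8_only", "nb_only")),
    TNL = alloc(c(0.15, 0.10, 0.20), c("tir_only", "tir_lrr", "nb_only")),
    ATYPICAL = rep("nb_kinase", n),
    EXCLUDED = rep("lrr_only", n))
}

#' Generate a synthetic proteome with planted NLR architectures
#'
#' Builds sequences from category-specific templates: an N-terminal block
#' (TIR for TNL, RPW8 for RNL, a neutral region otherwise), the NB-ARC
#' block carrying the category's motif chain (subfamily-correct RNBS-A,
#' RNBS-D and MHD variants with the conserved P-loop, Kinase motifs and
#' GLPL), and optional LRR repeats. Truncated forms (RPW8-only, NB-only,
#' TIR-only, TIR-LRR), kinase-fusion atypical forms and LRR-only excluded
#' decoys are emitted at fixed within-category fractions. Matching domain
#' hits (`source = "planted"`, with tiled per-repeat LRR hits) and a
#' truth table are returned alongside. Point mutations are applied at
#' rate `mutation_rate` at every position except the planted discriminant
#' residues; for a fixed seed the mutated position set at a lower rate is
#' a subset of the set at any higher rate.
#'
#' @param n_per_category named integer vector over
#'   `CNL`, `CNL2`, `RNL`, `TNL`, `ATYPICAL`, `EXCLUDED` (missing names
#'   mean zero).
#' @param mutation_rate per-residue substitution probability.
#' @param seed RNG seed (generators are seed-deterministic).
#' @param species species tag.
#' @param corrupt_discriminants optional character vector of motif names
#'   whose discriminant residues are deliberately corrupted (first
#'   residue swapped, e.g. QHD becomes MHD), overriding their protection.
#' @param config a `motif_config`.
#' @return list with `records` (`protein_records`), `hits`
#'   (`domain_hits`, planted), and `truth` (data frame: `seq_id`,
#'   `species`, `category`, `form`, `census_row`).
#' @export
synth_proteome <- function(n_per_category = c(CNL = 50, CNL2 = 50, RNL = 50,
                                              TNL = 50),
                           mutation_rate = 0, seed = 1,
                           species = "synthetic",
                           corrupt_discriminants = NULL,
                           config = default_motif_config()) {
  set.seed(seed)
  cats <- c("CNL", "CNL2", "RNL", "TNL", "ATYPICAL", "EXCLUDED")
  n_per_category <- n_per_category[names(n_per_category) %in% cats]
  ids <- character(); seqs <- character()
  hit_rows <- list(); truth_rows <- list()
  counter <- 0L
  for (cat in names(n_per_category)) {
    n <- n_per_category[[cat]]
    if (n <= 0) next
    forms <- category_forms(cat, n)
    for (j in seq_len(n)) {
      counter <- counter + 1L
      id <- sprintf("%s_%s_%03d", species, cat, j)
      form <- forms[j]
      segs <- list()
      lk <- function(n) list(seq = rand_chars(n, SAFE_LINKER_ALPHABET))
      has <- c(tir = FALSE, rpw8 = FALSE, nb = FALSE, lrr = FALSE,
               kinase = FALSE)
      if (cat == "TNL" && form %in% c("tir_only", "tir_lrr", "nb_lrr")) {
        segs <- c(segs, list(list(marker = "TIR_start")), build_tir_block(config),
                  list(list(marker = "TIR_end")))
        has["tir"] <- TRUE
      }
      if (cat == "RNL" && form %in% c("rpw8_only", "nb_lrr")) {
        segs <- c(segs, list(list(marker = "RPW8_start"),
                             list(seq = rand_chars(115, RPW8_ALPHABET)),
                             list(marker = "RPW8_end")))
        has["rpw8"] <- TRUE
      }
      if (cat %in% c("CNL", "CNL2")) segs <- c(segs, list(lk(40)))
      if (form %in% c("nb_lrr", "nb_only", "nb_kinase")) {
        nb_cat <- if (cat == "ATYPICAL") "CNL" else cat
        segs <- c(segs, list(lk(15), list(marker = "NB_start")),
                  build_nbarc_block(nb_cat, config),
                  list(list(marker = "NB_end")))
        has["nb"] <- TRUE
      }
      if (form %in% c("nb_lrr", "tir_lrr", "lrr_only") &&
          !(cat == "RNL" && form != "nb_lrr")) {
        segs <- c(segs, list(lk(12), list(marker = "LRR_start")),
                  build_lrr_units(5), list(list(marker = "LRR_end")))
        has["lrr"] <- TRUE
      }
      if (form == "nb_kinase") {
        segs <- c(segs, list(lk(10), list(marker = "KIN_start"),
                             list(seq = rand_chars(80, RPW8_ALPHABET)),
                             list(marker = "KIN_end")))
        has["kinase"] <- TRUE
      }
      segs <- c(segs, list(lk(10)))
      # markers carry no sequence; drop them but remember their positions
      seq <- ""; pos <- 0L; marks <- c(); protected <- integer()
      motif_names <- character(); lrr_units <- list()
      for (seg in segs) {
        if (!is.null(seg$marker)) {
          marks[seg$marker] <- pos + if (grepl("_start$", seg$marker)) 1L else 0L
          next
        }
        start <- pos + 1L
        seq <- paste0(seq, seg$seq)
        pos <- pos + nchar(seg$seq)
        if (!is.null(seg$disc)) protected <- c(protected, start - 1L + seg$disc)
        if (!is.null(seg$motif)) {
          motif_names <- c(motif_names, seg$motif)
          if (!is.null(corrupt_discriminants) &&
              seg$motif %in% corrupt_discriminants) {
            cs <- strsplit(seq, "")[[1]]
            tgt <- start - 1L + seg$disc[1]
            cs[tgt] <- if (cs[tgt] == "M") "A" else "M"
            seq <- paste(cs, collapse = "")
          }
        }
        if (identical(seg$label, "LRR_unit")) {
          lrr_units[[length(lrr_units) + 1L]] <- c(start, pos)
        }
      }
      # mutations: draws are made for every position regardless of rate
      L <- nchar(seq)
      u <- runif(L)
      shift <- sample.int(19L, L, replace = TRUE)
      if (mutation_rate > 0) {
        cs <- strsplit(seq, "")[[1]]
        mut <- which(u < mutation_rate & !(seq_len(L) %in% protected))
        if (length(mut) > 0) {
          cur <- match(cs[mut], AA_STANDARD)
          cur[is.na(cur)] <- 1L
          cs[mut] <- AA_STANDARD[((cur - 1L + shift[mut]) %% 20L) + 1L]
          seq <- paste(cs, collapse = "")
        }
      }
      ids <- c(ids, id); seqs <- c(seqs, seq)
      add_hit <- function(domain, start, end) {
        hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
          seq_id = id, domain = domain, start = start, end = end,
          stringsAsFactors = FALSE)
      }
      if (has["tir"]) add_hit("TIR", marks["TIR_start"], marks["TIR_end"])
      if (has["rpw8"]) add_hit("RPW8", marks["RPW8_start"], marks["RPW8_end"])
      if (has["nb"]) add_hit("NBARC", marks["NB_start"], marks["NB_end"])
      if (has["lrr"]) for (un in lrr_units) add_hit("LRR", un[1], un[2])
      if (has["kinase"]) add_hit("Pkinase", marks["KIN_start"], marks["KIN_end"])
      truth_cat <- cat
      census_row <- switch(paste(cat, form),
        "CNL nb_lrr" = "NB_CNL-(LRR)", "CNL2 nb_lrr" = "NB_CNL2-(LRR)",
        "RNL rpw8_only" = "RPW8", "RNL nb_only" = "NB_RNL-(LRR)",
        "RNL nb_lrr" = "RPW8-NB_RNL-(LRR)",
        "TNL tir_only" = "TIR", "TNL tir_lrr" = "TIR-LRR",
        "TNL nb_only" = "NB_TNL-(LRR)", "TNL nb_lrr" = "TIR-NB_TNL-(LRR)",
        "ATYPICAL nb_kinase" = "Atypical", NA_character_)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        seq_id = id, species = species, category = truth_cat, form = form,
        census_row = census_row, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows) > 0) {
    h <- do.call(rbind, hit_rows)
    domain_hits(h$seq_id, h$domain, h$start, h$end, evalue = 1e-10,
                source = "planted")
  } else domain_hits(character(), character(), integer(), integer())
  truth <- do.call(rbind, truth_rows)
  stopifnot(!anyDuplicated(truth$seq_id), nrow(truth) == length(ids))
  list(records = protein_records(ids, seqs, species = species),
       hits = hits, truth = truth)
}

#' Generate a synthetic species panel with a planted RNL-TNL relationship
#'
#' Per-species TNL counts are drawn from a negative-binomial count
#' distribution; RNL counts follow `max(0, round(slope * TNL + noise))`
#' with Gaussian noise; CNL counts are drawn independently (a planted
#' null for the RNL-vs-CNL comparison).
#'
#' @param n_species number of species (default 49).
#' @param slope planted RNL-per-TNL slope (default 0.1, i.e. 1:10).
#' @param noise_sd Gaussian noise SD on the RNL counts (default 6, which
#'   puts the panel's explained variance near the level seen in real
#'   cross-species count data).
#' @param seed RNG seed.
#' @param tnl_mu,tnl_size negative-binomial parameters of the TNL count
#'   distribution.
#' @return data frame (`species`, `TNL`, `RNL`, `CNL`) with attribute
#'   `truth` (planted slope, intercept, noise SD, seed).
#' @export
synth_species_panel <- function(n_species = 49, slope = 0.1, noise_sd = 6,
                                seed = 1, tnl_mu = 150, tnl_size = 2) {
  set.seed(seed)
  tnl <- rnbinom(n_species, mu = tnl_mu, size = tnl_size) + 1L
  rnl <- pmax(0, round(slope * tnl + rnorm(n_species, 0, noise_sd)))
  cnl <- rnbinom(n_species, mu = tnl_mu, size = tnl_size) + 1L
  out <- data.frame(species = sprintf("sp%02d", seq_len(n_species)),
                    TNL = tnl, RNL = as.integer(rnl), CNL = cnl,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(slope = slope, intercept = 0,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic RNA-seq count matrix with planted drought effects
#'
#' Negative-binomial counts over the drought design with per-library size
#' factors and treatment-by-time effects that ramp in from day 14 (half
#' effect at day 14, full effect at days 18 and 22, none earlier),
#' mirroring a response that builds with water deprivation.
#'
#' @param n_genes number of genes.
#' @param sheet a `sample_sheet` (default [make_sample_sheet()]).
#' @param sf per-library size factors; `NULL` draws them log-normally.
#' @param de_fraction fraction of genes with a planted effect.
#' @param log2fc absolute planted log2 fold change (sign random per gene).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param seed RNG seed.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline expression.
#' @return list with `counts` (genes x libraries), `sheet`, `sf`, and
#'   `truth` (data frame `gene`, `is_de`, `log2fc`).
#' @export
synth_counts <- function(n_genes = 1000, sheet = make_sample_sheet(),
                         sf = NULL, de_fraction = 0.1, log2fc = 2,
                         dispersion = 0.05, seed = 1,
                         baseline_meanlog = log(100), baseline_sdlog = 1) {
  set.seed(seed)
  n_lib <- nrow(sheet)
  if (is.null(sf)) {
    sf <- exp(rnorm(n_lib, 0, 0.25))
    sf <- sf / exp(mean(log(sf)))
  }
  base <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  n_de <- round(de_fraction * n_genes)
  is_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))
  sign_de <- ifelse(rbinom(n_genes, 1, 0.5) == 1, 1, -1)
  lfc <- ifelse(is_de, sign_de * log2fc, 0)
  ramp <- ifelse(sheet$treatment == "drought",
                 ifelse(sheet$day >= 18, 1, ifelse(sheet$day >= 14, 0.5, 0)),
                 0)
  mu <- outer(base, sf) * 2^(outer(lfc, ramp))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = n_genes,
                   dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                   sheet$library_id))
  truth <- data.frame(gene = rownames(counts), is_de = is_de, log2fc = lfc,
                      stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(truth$gene))
  list(counts = counts, sheet = sheet, sf = sf, truth = truth)
}

#' Generate synthetic RPW8 domain families
#'
#' Draws `n_parents` unrelated parent domains (distinct lengths) and
#' emits `n_members` mutated copies assigned to parents round-robin, each
#' diverged by a uniform fraction of substituted positions.
#'
#' @param n_parents number of families (default 45).
#' @param n_members total emitted domains (default 300).
#' @param divergence `c(min, max)` substitution fraction per member.
#' @param length_range parent length range (lengths are distinct).
#' @param seed RNG seed.
#' @return `protein_records` with attribute `truth` (data frame `id`,
#'   `parent`).
#' @export
synth_rpw8_set <- function(n_parents = 45, n_members = 300,
                           divergence = c(0.02, 0.2),
                           length_range = c(110, 170), seed = 1) {
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n_parents)
  parents <- vapply(lens, function(L) rand_chars(L, AA_STANDARD), "")
  parent_of <- rep(seq_len(n_parents), length.out = n_members)
  ids <- sprintf("rpw8_%03d_p%02d", seq_len(n_members), parent_of)
  seqs <- vapply(seq_len(n_members), function(i) {
    p <- strsplit(parents[parent_of[i]], "")[[1]]
    L <- length(p)
    d <- runif(1, divergence[1], divergence[2])
    k <- round(d * L)
    if (k > 0) {
      posn <- sample.int(L, k)
      cur <- match(p[posn], AA_STANDARD)
      p[posn] <- AA_STANDARD[((cur - 1L + sample.int(19L, k, replace = TRUE))
                              %% 20L) + 1L]
    }
    paste(p, collapse = "")
  }, "")
  out <- protein_records(ids, seqs, species = "synthetic")
  attr(out, "truth") <- data.frame(id = ids,
                                   parent = sprintf("p%02d", parent_of),
                                   stringsAsFactors = FALSE)
  out
}

#' Mutate each record by a bounded substitution fraction
#'
#' Used e.g. to derive query RPW8 domains from anchor sequences while
#' keeping the truth (the source record) known.
#'
#' @param records `protein_records` to mutate.
#' @param n_copies copies per record.
#' @param divergence_max maximum substitution fraction (drawn uniformly
#'   from `[0, divergence_max]` per copy).
#' @param seed RNG seed.
#' @return `protein_records` with attribute `truth` (`id`, `source`).
#' @export
mutate_records <- function(records, n_copies = 3, divergence_max = 0.15,
                           seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(records))) {
    for (j in seq_len(n_copies)) {
      p <- strsplit(records$seq[i], "")[[1]]
      L <- length(p)
      k <- round(runif(1, 0, divergence_max) * L)
      if (k > 0) {
        posn <- sample.int(L, k)
        cur <- match(p[posn], AA_STANDARD)
        cur[is.na(cur)] <- 1L
        p[posn] <- AA_STANDARD[((cur - 1L + sample.int(19L, k, replace = TRUE))
                                %% 20L) + 1L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_mut%02d", records$id[i], j),
        source = records$id[i], seq = paste(p, collapse = ""),
        species = records$species[i], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  out <- protein_records(tab$id, tab$seq, species = tab$species)
  attr(out, "truth") <- tab[, c("id", "source")]
  out
}
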