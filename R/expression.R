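# expression: drought RNA-seq stage — count filtering, median-of-ratios
# normalization, per-gene negative-binomial likelihood-ratio tests with
# BH FDR control, and expression grouping of the significant genes.
#
# The differential-expression model is a deliberately simplified
# negative-binomial GLM: gene-wise dispersions by method of moments on
# normalized counts (no shrinkage, no outlier refitting), mean models
# fitted at fixed dispersion, and a chi-square LRT between the full
# (treatment-by-day) and reduced (day-only) designs.

#' Build a sample sheet for the drought design
#'
#' Two conditions (well-watered control, unwatered drought) over five
#' sampling days with clonally propagated genotypes and replicates.
#'
#' @param genotypes genotype labels (default clones `8`, `11`, `95`).
#' @param treatments treatment labels.
#' @param days sampling days.
#' @param replicates replicates per combination.
#' @return data frame (`sample_sheet`): `library_id`, `genotype`,
#'   `treatment`, `day`, `replicate`.
#' @export
make_sample_sheet <- function(genotypes = c("8", "11", "95"),
                              treatments = c("control", "drought"),
                              days = c(0, 7, 14, 18, 22),
                              replicates = 2) {
  g <- expand.grid(replicate = seq_len(replicates), day = days,
                   treatment = treatments, genotype = genotypes,
                   stringsAsFactors = FALSE)
  out <- data.frame(
    library_id = sprintf("g%s_%s_d%02d_r%d", g$genotype, g$treatment, g$day,
                         g$replicate),
    genotype = as.character(g$genotype), treatment = g$treatment,
    day = g$day, replicate = g$replicate, stringsAsFactors = FALSE)
  if (anyDuplicated(out$library_id)) stop_input("duplicate library ids")
  class(out) <- c("sample_sheet", "data.frame")
  out
}

check_count_matrix <- function(cm) {
  if (!is.matrix(cm)) stop_input("counts must be a matrix (genes x libraries)")
  if (any(cm < 0) || any(cm != floor(cm))) {
    stop_input("counts must be non-negative integers")
  }
  invisible(TRUE)
}

#' Filter genes with low counts
#'
#' Keeps genes whose count strictly exceeds `min_count` in at least
#' `min_libraries` libraries (a gene at exactly `min_count` everywhere is
#' dropped).
#'
#' @param cm count matrix (genes x libraries).
#' @param min_count count threshold, exclusive (default 5).
#' @param min_libraries minimum number of qualifying libraries (default 2).
#' @return the filtered matrix, with a `log` attribute recording
#'   before/after gene counts.
#' @export
filter_low_counts <- function(cm, min_count = 5, min_libraries = 2) {
  check_count_matrix(cm)
  keep <- rowSums(cm > min_count) >= min_libraries
  out <- cm[keep, , drop = FALSE]
  attr(out, "log") <- data.frame(step = "filter_low_counts",
                                 n_in = nrow(cm), n_out = nrow(out),
                                 stringsAsFactors = FALSE)
  out
}

#' Median-of-ratios size factors
#'
#' Per-gene geometric means over libraries (genes containing any zero are
#' excluded from the reference) give a pseudo-reference; each library's
#' size factor is the median ratio of its counts to that reference,
#' rescaled to geometric mean 1 so that log size factors sum to zero.
#'
#' @param cm count matrix (genes x libraries).
#' @return positive numeric vector of size factors (one per library) with
#'   attribute `geometric_mean_raw` (the pre-rescaling geometric mean).
#' @export
size_factors <- function(cm) {
  check_count_matrix(cm)
  ref_ok <- rowSums(cm == 0) == 0
  if (!any(ref_ok)) {
    stop_input("no zero-free genes available for the reference")
  }
  lg <- log(cm[ref_ok, , drop = FALSE])
  ref <- rowMeans(lg)
  s <- exp(apply(lg - ref, 2, median))
  gm <- exp(mean(log(s)))
  out <- s / gm
  attr(out, "geometric_mean_raw") <- gm
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (the standard BH
#' procedure, via [stats::p.adjust()]).
#'
#' @param pvalues raw p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

de_designs <- function(sheet, genotype_covariate = FALSE) {
  df <- data.frame(day = factor(sheet$day),
                   treatment = factor(sheet$treatment,
                                      levels = c("control", "drought")),
                   genotype = factor(sheet$genotype))
  f_full <- if (genotype_covariate) ~genotype + day * treatment
            else ~day * treatment
  f_red <- if (genotype_covariate) ~genotype + day else ~day
  Xf <- model.matrix(f_full, df)
  Xr <- model.matrix(f_red, df)
  # drop unestimable columns (e.g. a day sampled in one condition only)
  Xf <- Xf[, qr(Xf)$pivot[seq_len(qr(Xf)$rank)], drop = FALSE]
  Xr <- Xr[, qr(Xr)$pivot[seq_len(qr(Xr)$rank)], drop = FALSE]
  list(full = Xf, reduced = Xr, data = df)
}

nb_loglik <- function(y, mu, theta) {
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

fit_nb_mean <- function(y, X, offset, theta) {
  fam <- MASS::negative.binomial(theta = theta)
  fit <- suppressWarnings(glm.fit(X, y, family = fam, offset = offset,
                                  control = list(maxit = 100)))
  list(mu = fit$fitted.values, coef = fit$coefficients)
}

#' Negative-binomial likelihood-ratio test per gene
#'
#' For each gene: normalized counts give a method-of-moments dispersion
#' estimate `alpha = max((var - mean) / mean^2, floor)`; the NB mean
#' model is then fitted at fixed dispersion under the full design
#' (day-by-treatment, optionally with genotype as covariate) and the
#' reduced design (day only, treatment dropped), both with log size
#' factors as offsets. Twice the log-likelihood difference is referred to
#' a chi-square distribution with degrees of freedom equal to the
#' difference in parameter counts, and BH adjustment is applied over all
#' tested genes. The reported log2 fold change is drought versus control
#' at `lfc_day` (default day 22), averaged over genotypes when present.
#'
#' @param cm filtered count matrix (genes x libraries).
#' @param sheet matching `sample_sheet` (rows ordered as the columns of
#'   `cm`).
#' @param genotype_covariate add genotype to both designs (default FALSE).
#' @param alpha_floor dispersion floor (default 1e-8).
#' @param lfc_day day at which the log2 fold change is reported.
#' @param fdr adjusted-p threshold for the up/down status (default 0.05).
#' @return data frame (`de_result`): `gene`, `log2fc`, `lrt_stat`, `df`,
#'   `pvalue`, `padj`, `status` (`up`/`down`/`ns`); genes that could not
#'   be tested (all-zero) are excluded and listed in the `excluded`
#'   attribute.
#' @export
nb_lrt <- function(cm, sheet, genotype_covariate = FALSE, alpha_floor = 1e-8,
                   lfc_day = 22, fdr = 0.05) {
  check_count_matrix(cm)
  if (ncol(cm) != nrow(sheet)) stop_input("count matrix and sample sheet differ")
  s <- size_factors(cm)
  off <- log(s)
  des <- de_designs(sheet, genotype_covariate)
  df_test <- ncol(des$full) - ncol(des$reduced)
  # contrast rows for the log2FC at lfc_day
  newd <- des$data[c(1, 1), , drop = FALSE]
  newd$day <- factor(c(lfc_day, lfc_day), levels = levels(des$data$day))
  newd$treatment <- factor(c("drought", "control"),
                           levels = levels(des$data$treatment))
  geno_levels <- levels(des$data$genotype)
  contrast_row <- function(coef_names) {
    rows <- lapply(geno_levels, function(g) {
      nd <- newd
      nd$genotype <- factor(c(g, g), levels = geno_levels)
      mm <- model.matrix(if (genotype_covariate) ~genotype + day * treatment
                         else ~day * treatment, nd)
      mm[, coef_names, drop = FALSE]
    })
    (Reduce(`+`, lapply(rows, function(m) m[1, ] - m[2, ]))) / length(geno_levels)
  }
  ctr <- contrast_row(colnames(des$full))

  excluded <- character()
  rows <- vector("list", nrow(cm))
  for (i in seq_len(nrow(cm))) {
    y <- cm[i, ]
    if (all(y == 0)) {
      excluded <- c(excluded, rownames(cm)[i])
      next
    }
    q <- y / s
    m <- mean(q)
    v <- var(q)
    alpha <- max((v - m) / m^2, alpha_floor)
    theta <- 1 / alpha
    ff <- tryCatch(fit_nb_mean(y, des$full, off, theta), error = function(e) NULL)
    fr <- tryCatch(fit_nb_mean(y, des$reduced, off, theta), error = function(e) NULL)
    if (is.null(ff) || is.null(fr)) {
      excluded <- c(excluded, rownames(cm)[i])
      next
    }
    stat <- max(0, 2 * (nb_loglik(y, ff$mu, theta) - nb_loglik(y, fr$mu, theta)))
    cf <- ff$coef
    cf[is.na(cf)] <- 0
    lfc <- sum(ctr * cf) / log(2)
    rows[[i]] <- data.frame(gene = rownames(cm)[i] %||% as.character(i),
                            log2fc = lfc, lrt_stat = stat, df = df_test,
                            pvalue = pchisq(stat, df_test, lower.tail = FALSE),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop_input("no testable genes")
  out$padj <- bh_adjust(out$pvalue)
  out$status <- ifelse(out$padj < fdr, ifelse(out$log2fc > 0, "up", "down"),
                       "ns")
  if (length(excluded) > 0) {
    message(length(excluded), " gene(s) excluded (untestable)")
  }
  attr(out, "excluded") <- excluded
  attr(out, "model") <- paste0(
    "simplified NB GLM: moment dispersion (floor ", alpha_floor,
    "), no shrinkage, no outlier filtering; LRT full=",
    if (genotype_covariate) "~genotype+day*treatment" else "~day*treatment",
    " vs reduced=", if (genotype_covariate) "~genotype+day" else "~day")
  class(out) <- c("de_result", "data.frame")
  out
}

#' Cluster differentially expressed genes into expression groups
#'
#' Per-gene profiles are z-scores of log2(normalized count + 1) across
#' libraries; genes are clustered by agglomerative hierarchical
#' clustering with manhattan distance and Ward.D2 linkage, and the tree
#' is cut into `k` groups.
#'
#' @param de_genes character vector of gene ids to cluster.
#' @param cm count matrix containing those genes.
#' @param sheet matching sample sheet (used for column ordering only).
#' @param k number of groups (default 14); must not exceed the number of
#'   genes (`k` equal to the gene count yields singletons).
#' @return list (`expression_groups`): `membership` (named integer
#'   vector), `groups` (list of gene-id vectors), `profiles` (per-group
#'   mean z-profile matrix), `tree` (the hclust object).
#' @export
expression_groups <- function(de_genes, cm, sheet, k = 14) {
  de_genes <- as.character(de_genes)
  if (!all(de_genes %in% rownames(cm))) {
    stop_input("de_genes missing from the count matrix")
  }
  if (k < 1 || k > length(de_genes)) {
    stop_input("k must be between 1 and the number of genes")
  }
  s <- size_factors(cm)
  q <- sweep(cm[de_genes, , drop = FALSE], 2, s, "/")
  lq <- log2(q + 1)
  z <- t(apply(lq, 1, function(r) {
    sdr <- sd(r)
    if (sdr == 0) r * 0 else (r - mean(r)) / sdr
  }))
  hc <- hclust(dist(z, method = "manhattan"), method = "ward.D2")
  membership <- cutree(hc, k = k)
  groups <- split(names(membership), membership)
  profiles <- t(vapply(groups, function(g) {
    colMeans(z[g, , drop = FALSE])
  }, numeric(ncol(z))))
  structure(list(membership = membership, groups = groups,
                 profiles = profiles, tree = hc, k = k),
            class = "expression_groups")
}

#' Summarise differential expression by NLR subfamily
#'
#' @param de_results a `de_result` data frame.
#' @param calls a `subfamily_call` data frame mapping genes (seq_ids) to
#'   categories.
#' @return data frame per category: `n_de`, `n_up`, `n_down`,
#'   `log2fc_min`, `log2fc_max`, `up_fraction`. Empty when there are no
#'   DE genes.
#' @export
subfamily_de_summary <- function(de_results, calls) {
  de <- de_results[de_results$status != "ns", , drop = FALSE]
  if (nrow(de) == 0) {
    return(data.frame(category = character(), n_de = integer(),
                      n_up = integer(), n_down = integer(),
                      log2fc_min = numeric(), log2fc_max = numeric(),
                      up_fraction = numeric(), stringsAsFactors = FALSE))
  }
  cat_of <- setNames(calls$category, calls$seq_id)
  de$category <- unname(cat_of[de$gene])
  de$category[is.na(de$category)] <- "UNDETERMINED"
  parts <- split(de, de$category)
  out <- do.call(rbind, lapply(names(parts), function(cat) {
    d <- parts[[cat]]
    data.frame(category = cat, n_de = nrow(d),
               n_up = sum(d$status == "up"), n_down = sum(d$status == "down"),
               log2fc_min = min(d$log2fc), log2fc_max = max(d$log2fc),
               up_fraction = sum(d$status == "up") / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
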