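# Locus quality control for mapping populations: segregation-distortion
# testing, Mendelian-error inference from parental genotypes, the combined
# locus filter, two-point suspect-linkage diagnostics for haploid data, and
# spacing/informativeness-based anchor selection.

# Mendelian expected ratio for a locus.  Dosage loci depend on the cross:
# with parental dosages available the ratio is enumerated from the four
# transmission combinations; otherwise it is inferred from the observed
# class set (three classes -> 1:2:1 intercross, two -> 1:1 testcross).
expected_segregation <- function(segregation_type, classes,
                                 parents = NULL, observed = NULL) {
  if (segregation_type == "dosage") {
    if (!is.null(parents) && !anyNA(parents)) {
      al <- expand.grid(parent_alleles(parents[1]),
                        parent_alleles(parents[2]))
      dos <- rowSums(al == "b")
      ratio <- stats::setNames(rep(0, length(classes)), classes)
      tb <- table(as.character(dos))
      ratio[names(tb)] <- as.numeric(tb)
      return(ratio)
    }
    obs_classes <- sort(unique(observed))
    ratio <- stats::setNames(rep(0, length(classes)), classes)
    if (length(obs_classes) >= 3) ratio[] <- c(1, 2, 1)
    else ratio[obs_classes] <- 1
    return(ratio)
  }
  switch(segregation_type,
         haploid = , testcross = , lmxll = , nnxnp = rep(1, 2),
         hkxhk = c(hh = 1, hk = 2, kk = 1),
         rep(1, length(classes)))
}

#' Chi-square test for segregation distortion
#'
#' Pearson goodness-of-fit of observed genotype-class counts against the
#' Mendelian expectation (1:1 for haploid and testcross loci, 1:2:1 for
#' hk x hk or F2 dosage loci).
#'
#' @param class_counts Non-negative counts per genotype class.
#' @param expected_ratio Expected ratio, recycled to the classes; default
#'   1:1 for two classes, 1:2:1 for three.
#' @return List with `chisq`, `df` (= classes - 1) and `p`.
#' @examples
#' distortion_test(c(36, 36))         # chisq 0, p 1
#' distortion_test(c(60, 12))         # chisq 32
#' distortion_test(c(25, 50, 25))     # chisq 0 vs 1:2:1
#' @export
distortion_test <- function(class_counts, expected_ratio = NULL) {
  n <- sum(class_counts)
  if (n == 0) stop_fmt("zero total count: distortion test undefined")
  if (is.null(expected_ratio))
    expected_ratio <- if (length(class_counts) == 3) c(1, 2, 1)
      else rep(1, length(class_counts))
  if (length(expected_ratio) != length(class_counts))
    stop_fmt("expected ratio has %d classes but counts have %d",
             length(expected_ratio), length(class_counts))
  expd <- n * expected_ratio / sum(expected_ratio)
  chisq <- sum((class_counts - expd)^2 / expd)
  df <- length(class_counts) - 1L
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

parent_alleles <- function(code) {
  if (is.na(code)) return(NULL)
  if (code %in% c("0", "1", "2")) {
    switch(code, "0" = c("a", "a"), "1" = c("a", "b"), "2" = c("b", "b"))
  } else strsplit(code, "")[[1]]
}

legal_progeny <- function(p1, p2) {
  a1 <- parent_alleles(p1); a2 <- parent_alleles(p2)
  if (is.null(a1) || is.null(a2)) return(NULL)
  combos <- unique(apply(expand.grid(a1, a2), 1, function(x)
    paste(sort(as.character(x)), collapse = "")))
  if (all(c(a1, a2) %in% c("a", "b"))) {
    # dosage coding: count of allele b
    as.character(vapply(strsplit(combos, ""), function(x)
      sum(x == "b"), numeric(1)))
  } else combos
}

#' Infer genotyping errors from parental genotypes
#'
#' A progeny call is scored as an error iff it is impossible under Mendelian
#' transmission from the recorded parents (e.g. call `mm` from an
#' ll x lm cross).  Loci with a missing parental genotype are flagged and
#' not scored.
#'
#' @param gm A [genotype_matrix()] of progeny calls (CP or dosage dialect).
#' @param parental_genotypes Data frame with columns `marker_id`, `parent1`,
#'   `parent2` holding parental genotype codes (`NA` = missing).
#' @return List with `error_mask` (logical matrix, `NA` where not scorable),
#'   `error_rate` (per-locus errors / non-missing calls, `NA` when parents
#'   missing), `n_errors`, and `parent_missing` (logical per locus).
#' @export
infer_genotype_errors <- function(gm, parental_genotypes) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pg <- parental_genotypes
  idx <- match(gm$loci$marker_id, pg$marker_id)
  mask <- matrix(NA, nrow(gm$calls), ncol(gm$calls),
                 dimnames = dimnames(gm$calls))
  rate <- rep(NA_real_, ncol(gm$calls))
  nerr <- rep(NA_integer_, ncol(gm$calls))
  pmis <- rep(TRUE, ncol(gm$calls))
  for (j in seq_len(ncol(gm$calls))) {
    if (is.na(idx[j])) next
    legal <- legal_progeny(pg$parent1[idx[j]], pg$parent2[idx[j]])
    if (is.null(legal)) next
    pmis[j] <- FALSE
    calls <- gm$calls[, j]
    ok <- !is.na(calls)
    mask[ok, j] <- !calls[ok] %in% legal
    nerr[j] <- sum(mask[ok, j])
    rate[j] <- if (any(ok)) nerr[j] / sum(ok) else NA_real_
  }
  list(error_mask = mask, error_rate = rate, n_errors = nerr,
       parent_missing = pmis)
}

#' Filter loci on mapping-population quality criteria
#'
#' Drops loci that are monoallelic, are missing a parental genotype (when
#' parental genotypes are supplied), show segregation distortion at
#' `p < p_threshold`, have a parent-inferred genotyping error rate strictly
#' above `error_threshold`, or (optionally) have a missing-call fraction at
#' or above `missing_threshold`.  Loci whose error rate is positive but at
#' or below the threshold are retained with the erroneous calls recoded as
#' missing.
#'
#' @param gm A [genotype_matrix()].
#' @param parental_genotypes Optional parental genotype table, see
#'   [infer_genotype_errors()].  When `NULL`, the parental-genotype and
#'   error-rate rules are skipped.
#' @param p_threshold Distortion p-value threshold (default 0.001).
#' @param error_threshold Error-rate threshold (default 0.05; "more than" is
#'   strict, so a rate of exactly 0.05 recodes rather than drops).
#' @param missing_threshold Optional missing-fraction threshold (e.g. 0.125
#'   keeps loci with less than 12.5% missing); `NULL` disables the rule.
#' @return List with `gm` (filtered, recoded genotype matrix) and `report`,
#'   a data frame with per-locus `status`, comma-separated `reasons`,
#'   `chisq`, `p`, `n_errors`, `error_rate`, `missing_frac`, `recoded`.
#' @export
filter_loci <- function(gm, parental_genotypes = NULL, p_threshold = 0.001,
                        error_threshold = 0.05, missing_threshold = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- ncol(gm$calls)
  reasons <- vector("list", p)
  chisq <- pval <- err_rate <- rep(NA_real_, p)
  nerr <- rep(NA_integer_, p)
  recoded <- rep(FALSE, p)
  calls <- gm$calls

  err <- if (!is.null(parental_genotypes))
    infer_genotype_errors(gm, parental_genotypes) else NULL

  for (j in seq_len(p)) {
    obs <- calls[, j][!is.na(calls[, j])]
    if (length(unique(obs)) <= 1L)
      reasons[[j]] <- c(reasons[[j]], "monoallelic")
    if (!is.null(err)) {
      if (err$parent_missing[j]) {
        reasons[[j]] <- c(reasons[[j]], "missing_parental_genotype")
      } else {
        err_rate[j] <- err$error_rate[j]
        nerr[j] <- err$n_errors[j]
        if (!is.na(err_rate[j]) && err_rate[j] > error_threshold) {
          reasons[[j]] <- c(reasons[[j]], "error_rate_gt_threshold")
        } else if (!is.na(nerr[j]) && nerr[j] > 0) {
          calls[which(err$error_mask[, j]), j] <- NA
          recoded[j] <- TRUE
        }
      }
    }
  }
  # distortion and missingness are assessed after error recoding, over the
  # Mendelian classes only (off-type error codes are not segregation classes)
  pg_idx <- if (!is.null(parental_genotypes))
    match(gm$loci$marker_id, parental_genotypes$marker_id)
  for (j in seq_len(p)) {
    seg <- gm$loci$segregation_type[j]
    classes <- MENDELIAN_CLASSES[[seg]] %||% legal_codes(seg)
    obs <- calls[, j][!is.na(calls[, j]) & calls[, j] %in% classes]
    counts <- table(factor(obs, levels = classes))
    if (length(unique(obs)) > 1L) {
      parents <- if (!is.null(parental_genotypes) && !is.na(pg_idx[j]))
        c(parental_genotypes$parent1[pg_idx[j]],
          parental_genotypes$parent2[pg_idx[j]])
      ratio <- expected_segregation(seg, classes, parents = parents,
                                    observed = obs)
      nz <- ratio > 0
      dt <- distortion_test(as.integer(counts)[nz], ratio[nz])
      chisq[j] <- dt$chisq; pval[j] <- dt$p
      if (dt$p < p_threshold)
        reasons[[j]] <- c(reasons[[j]], "distortion_p_lt_threshold")
    }
    mf <- mean(is.na(calls[, j]))
    if (!is.null(missing_threshold) && mf >= missing_threshold)
      reasons[[j]] <- c(reasons[[j]], "excess_missing")
  }
  missing_frac <- colMeans(is.na(calls))
  dropped <- lengths(reasons) > 0
  report <- data.frame(
    marker_id = gm$loci$marker_id,
    status = ifelse(dropped, "dropped", "retained"),
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    chisq = chisq, p = pval, n_errors = nerr, error_rate = err_rate,
    missing_frac = missing_frac, recoded = recoded,
    stringsAsFactors = FALSE)
  keep <- which(!dropped)
  gm_out <- genotype_matrix(calls[, keep, drop = FALSE],
                            loci = gm$loci[keep, , drop = FALSE])
  list(gm = gm_out, report = report)
}

#' Two-point linkage diagnostics for haploid genotypes
#'
#' For every locus pair, estimates the recombination fraction RF as the
#' mismatch fraction among pairwise-complete individuals (coupling-phase
#' coding, so RF near 1 signals a phase/mirroring artifact) and the
#' two-point LOD as the base-10 binomial likelihood ratio of linkage at the
#' estimated RF against RF = 0.5, with RF capped into [0.001, 0.999] for
#' degenerate all-parental or all-recombinant pairs.  A pair is flagged
#' suspect when RF > 0.60 and LOD > 1.5.
#'
#' @param gm A haploid [genotype_matrix()] (0/1 calls).
#' @param rf_threshold,lod_threshold Suspect-linkage thresholds (defaults
#'   0.60 and 1.5).
#' @return Data frame with one row per pair: `locus_a`, `locus_b`, `n`,
#'   `rf`, `lod`, `suspect`.  Pairs with fewer than 2 complete individuals
#'   are skipped with a warning.
#' @export
two_point_diagnostics <- function(gm, rf_threshold = 0.6,
                                  lod_threshold = 1.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(gm$loci$segregation_type %in% c("haploid", "testcross")))
    stop_fmt("two-point diagnostics require haploid/testcross 0-1 calls")
  x <- dosage(gm)
  m <- !is.na(x)
  x0 <- x; x0[!m] <- 0
  n <- crossprod(m)                               # complete individuals
  s11 <- crossprod(x0 * m)                        # both 1
  s1. <- crossprod(x0 * m, m)                     # a=1 (any b)
  mism <- (s1. - s11) + t(s1. - s11)              # a!=b counts
  p <- ncol(x)
  pairs <- which(upper.tri(n), arr.ind = TRUE)
  nn <- n[pairs]
  skip <- nn < 2
  if (any(skip)) warning(sprintf("%d pair(s) skipped: <2 complete individuals",
                                 sum(skip)))
  k <- mism[pairs]
  rf <- k / nn
  rc <- pmin(pmax(rf, 0.001), 0.999)
  lod <- k * log10(rc / 0.5) + (nn - k) * log10((1 - rc) / 0.5)
  out <- data.frame(locus_a = colnames(x)[pairs[, 1]],
                    locus_b = colnames(x)[pairs[, 2]],
                    n = nn, rf = rf, lod = lod,
                    suspect = rf > rf_threshold & lod > lod_threshold,
                    stringsAsFactors = FALSE)
  out[!skip, , drop = FALSE]
}

# markers consistent with a reference order: keep the longest increasing
# subsequence of reference ranks (O(n^2), fine at map scale)
lis_keep <- function(ranks) {
  n <- length(ranks)
  if (n <= 1) return(rep(TRUE, n))
  len <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (ranks[j] < ranks[i] && len[j] + 1L > len[i]) {
      len[i] <- len[j] + 1L; prev[i] <- j
    }
  keep <- rep(FALSE, n)
  i <- which.max(len)
  while (!is.na(i)) { keep[i] <- TRUE; i <- prev[i] }
  keep
}

#' Select anchor loci by spacing and informativeness
#'
#' Greedy left-to-right scan per linkage group: markers are grouped into
#' windows, each window being the maximal run of markers lying closer than
#' `min_spacing_cM` to the window's first marker; within each window the
#' locus with the highest cohort-summed GIC is kept (ties break to the
#' smallest marker id).  When a reference map is given, loci whose order
#' conflicts with the reference (not on the longest order-concordant
#' subsequence) are excluded before windowing.
#'
#' @param map An [input_map()].
#' @param gic GIC records (columns `marker_id`, `gic_sum`).
#' @param min_spacing_cM Minimum spacing window, > 0 (10 cM for fixed-order
#'   anchors, 5 cM for start-order loci).
#' @param reference_map Optional [input_map()] supplying the reference
#'   order.
#' @return Data frame of selected anchors (`linkage_group`, `marker_id`,
#'   `position_cM`, `gic_sum`).
#' @export
select_anchor_loci <- function(map, gic, min_spacing_cM,
                               reference_map = NULL) {
  stopifnot(inherits(map, "input_map"), min_spacing_cM > 0)
  g <- unique(gic[, c("marker_id", "gic_sum")])
  out <- list()
  for (lg in sort(unique(map$linkage_group))) {
    sub <- map[map$linkage_group == lg, , drop = FALSE]
    sub <- sub[order(sub$position_cM, sub$marker_id), , drop = FALSE]
    sub$gic_sum <- g$gic_sum[match(sub$marker_id, g$marker_id)]
    if (!is.null(reference_map)) {
      ref <- reference_map[reference_map$linkage_group == lg, , drop = FALSE]
      ref <- ref[order(ref$position_cM), ]
      rank_in_ref <- match(sub$marker_id, ref$marker_id)
      shared <- which(!is.na(rank_in_ref))
      if (length(shared) > 1) {
        drop <- shared[!lis_keep(rank_in_ref[shared])]
        if (length(drop)) sub <- sub[-drop, , drop = FALSE]
      }
    }
    if (!nrow(sub)) next
    win_start <- sub$position_cM[1]
    win_rows <- 1L
    sel <- integer(0)
    pick <- function(rows) {
      rows[order(-sub$gic_sum[rows], sub$marker_id[rows])][1]
    }
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$position_cM[i] - win_start < min_spacing_cM) {
        win_rows <- c(win_rows, i)
      } else {
        sel <- c(sel, pick(win_rows))
        win_start <- sub$position_cM[i]
        win_rows <- i
      }
    }
    sel <- c(sel, pick(win_rows))
    out[[as.character(lg)]] <-
      sub[sel, c("linkage_group", "marker_id", "position_cM", "gic_sum")]
  }
  res <- do.call(rbind, out) %||%
    data.frame(linkage_group = integer(0), marker_id = character(0),
               position_cM = numeric(0), gic_sum = numeric(0))
  rownames(res) <- NULL
  res
}
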