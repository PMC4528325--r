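# Linkage disequilibrium: pairwise r-squared of genotype dosages, raw and
# adjusted for kinship (whitening by the inverse square root of the
# relationship matrix) or subpopulation structure (regression on admixture
# proportions), tabulated by map-distance class and minor-allele-frequency
# threshold, with kernel decay regression and an extended-LD critical
# value.

#' Expected additive relationship matrix from a pedigree
#'
#' Recursive tabular method: founders are unrelated and non-inbred
#' (diagonal 1, off-diagonal 0); for offspring j of s and d,
#' \eqn{a_{ij} = (a_{is} + a_{id})/2} and
#' \eqn{a_{jj} = 1 + a_{sd}/2}.  Off-diagonal entries are the expected
#' identity-by-descent proportions: 0.5 for full sibs and parent-offspring,
#' 0.25 for half sibs.
#'
#' @param ped A [pedigree()].
#' @return Symmetric numeric matrix with individual ids as dimnames.
#' @export
pedigree_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))   # pedigree() guarantees acyclicity
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- ped$sire[j]; d <- ped$dam[j]
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (j > 1) for (i in seq_len(j - 1)) {
      a <- 0
      if (!is.na(s)) a <- a + 0.5 * A[ped$id[i], s]
      if (!is.na(d)) a <- a + 0.5 * A[ped$id[i], d]
      A[ped$id[i], ped$id[j]] <- A[ped$id[j], ped$id[i]] <- a
    }
  }
  A
}

#' Minor allele frequency from dosages
#'
#' @param dosages Numeric vector of diploid dosages (0/1/2) or haploid
#'   calls (0/1); `NA` allowed.
#' @param ploidy 2 (default) or 1.
#' @return MAF = min(f, 1 - f); `NA` if all calls missing.
#' @export
minor_allele_frequency <- function(dosages, ploidy = 2) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) return(NA_real_)
  f <- mean(d) / ploidy
  min(f, 1 - f)
}

#' Squared correlation of genotype dosages
#'
#' Squared Pearson correlation over pairwise-complete individuals; the
#' standard composite LD measure for unphased dosages.
#'
#' @param dos_a,dos_b Numeric dosage vectors.
#' @return r-squared in [0, 1]; `NA` (with attribute `reason`) when fewer
#'   than 3 complete pairs remain or either locus is monomorphic among
#'   them.
#' @export
r_squared <- function(dos_a, dos_b) {
  cc <- !is.na(dos_a) & !is.na(dos_b)
  if (sum(cc) < 3)
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  a <- dos_a[cc]; b <- dos_b[cc]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(NA_real_, reason = "monomorphic after completion"))
  stats::cor(a, b)^2
}

# inverse symmetric square root with eigenvalue floor
inv_sqrt <- function(V, floor = 1e-8) {
  e <- eigen(V, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

# correlation of two vectors after projecting out a covariate matrix
resid_r2 <- function(a, b, X) {
  qx <- qr(X)
  ra <- qr.resid(qx, a); rb <- qr.resid(qx, b)
  if (sqrt(sum(ra^2)) < 1e-12 || sqrt(sum(rb^2)) < 1e-12)
    return(structure(NA_real_, reason = "zero variance after adjustment"))
  (sum(ra * rb))^2 / (sum(ra^2) * sum(rb^2))
}

#' Kinship- or structure-adjusted r-squared
#'
#' Kinship: both dosage vectors are whitened by the inverse symmetric
#' square root of the relationship matrix `V` (eigenvalue floor 1e-8) and
#' the squared correlation is computed on the whitened vectors after
#' projecting out the whitened intercept (the generalized-least-squares
#' mean).  Structure: both vectors are replaced by residuals of a
#' least-squares regression on an intercept plus K-1 admixture columns
#' (one column is dropped because rows of Q sum to 1), and the squared
#' correlation of the residuals is returned.  With `V` the identity, or
#' `Q` uninformative (constant columns), the adjusted value equals the raw
#' r-squared.
#'
#' @param dos_a,dos_b Numeric dosage vectors.
#' @param adjustment `"kinship"` or `"structure"`.
#' @param V Relationship/kinship covariance (individuals x individuals),
#'   for `"kinship"`.
#' @param Q Admixture matrix (individuals x K), for `"structure"`.
#' @return Adjusted r-squared.
#' @export
adjusted_r_squared <- function(dos_a, dos_b,
                               adjustment = c("kinship", "structure"),
                               V = NULL, Q = NULL) {
  adjustment <- match.arg(adjustment)
  cc <- !is.na(dos_a) & !is.na(dos_b)
  if (sum(cc) < 3)
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  a <- dos_a[cc]; b <- dos_b[cc]
  if (adjustment == "kinship") {
    if (is.null(V)) stop_fmt("kinship adjustment requires V")
    W <- inv_sqrt(V[cc, cc, drop = FALSE])
    resid_r2(as.numeric(W %*% a), as.numeric(W %*% b),
             W %*% rep(1, sum(cc)))
  } else {
    if (is.null(Q)) stop_fmt("structure adjustment requires Q")
    Qc <- Q[cc, , drop = FALSE]
    X <- cbind(1, Qc[, -ncol(Qc), drop = FALSE])
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      if (ncol(X) < 1)
        stop_fmt(paste("structure design singular after dropping a column;",
                       "try a different number of subpopulations K"))
    }
    resid_r2(a, b, X)
  }
}

#' Tabulate pairwise LD by distance class and MAF threshold
#'
#' Computes raw (and, when requested, adjusted) r-squared for every locus
#' pair, classifies pairs as within-gene, within-LG at less than 1 cM,
#' within-LG at 1 cM or more, between-LG, or unmapped, and counts pairs
#' with r-squared above `r2_threshold` per class and per MAF threshold
#' (both loci strictly above the threshold).  Same-gene pairs and pairs
#' involving unmapped loci are excluded from the distance-classed counts
#' but retained in the record stream.  Loci with a missing fraction of
#' `missing_max` or more are excluded.  Raw r-squared uses
#' pairwise-complete individuals; the adjusted matrix is computed on
#' per-locus mean-imputed dosages (a single whitening/regression for all
#' pairs), which equals the exact per-pair value when data are complete.
#'
#' @param gm A [genotype_matrix()] of dosage (or haploid) calls.
#' @param consensus_map A `consensus_map` object or its `map` data frame
#'   (`marker`, `linkage_group`, `position_cM`); loci are matched by
#'   gene-level merge key.
#' @param adjustment `"none"`, `"kinship"`, or `"structure"`.
#' @param V,Q Adjustment inputs, see [adjusted_r_squared()].
#' @param maf_thresholds MAF strata (default 0.001, 0.1, 0.2).
#' @param r2_threshold LD call threshold (default 0.1).
#' @param missing_max Per-locus missing-fraction exclusion (default 0.5).
#' @return Object of class `ld_table`: list with `pairs` (one row per
#'   locus pair), `table` (counts by MAF x class x raw/adjusted),
#'   `adjustment`, `n_loci_used`, `excluded_loci`.
#' @export
ld_pair_table <- function(gm, consensus_map,
                          adjustment = c("none", "kinship", "structure"),
                          V = NULL, Q = NULL,
                          maf_thresholds = c(0.001, 0.1, 0.2),
                          r2_threshold = 0.1, missing_max = 0.5) {
  adjustment <- match.arg(adjustment)
  stopifnot(inherits(gm, "genotype_matrix"))
  cmap <- if (inherits(consensus_map, "consensus_map")) consensus_map$map
    else as.data.frame(consensus_map)
  X <- dosage(gm)
  ploidy <- ifelse(gm$loci$segregation_type == "haploid", 1, 2)
  miss <- colMeans(is.na(X))
  use <- miss < missing_max
  excluded <- gm$loci$marker_id[!use]
  X <- X[, use, drop = FALSE]
  loci <- gm$loci[use, , drop = FALSE]
  ploidy <- ploidy[use]
  p <- ncol(X)
  if (p < 2) stop_fmt("fewer than 2 usable loci")
  maf <- vapply(seq_len(p), function(j)
    minor_allele_frequency(X[, j], ploidy[j]), numeric(1))
  key <- normalize_marker_name(loci$marker_id)
  hit <- match(key, normalize_marker_name(cmap$marker))
  lg <- cmap$linkage_group[hit]
  pos <- cmap$position_cM[hit]

  r2_raw <- suppressWarnings(
    stats::cor(X, use = "pairwise.complete.obs")^2)
  r2_adj <- NULL
  if (adjustment != "none") {
    Xi <- X
    for (j in seq_len(p)) {
      mj <- is.na(Xi[, j])
      if (any(mj)) Xi[mj, j] <- mean(Xi[, j], na.rm = TRUE)
    }
    # residual columns are already centered in the working metric, so the
    # squared correlation is the plain cosine (cor() would re-center)
    cosine_sq <- function(U) {
      cp <- crossprod(U)
      nrm <- sqrt(diag(cp))
      out <- (cp / outer(nrm, nrm))^2
      out[nrm < 1e-12, ] <- NA; out[, nrm < 1e-12] <- NA
      out
    }
    if (adjustment == "kinship") {
      if (is.null(V)) stop_fmt("kinship adjustment requires V")
      W <- inv_sqrt(V)
      U <- W %*% Xi
      w1 <- W %*% rep(1, nrow(Xi))
      qx <- qr(w1)
      U <- qr.resid(qx, U)
      r2_adj <- cosine_sq(U)
    } else {
      if (is.null(Q)) stop_fmt("structure adjustment requires Q")
      Xd <- cbind(1, Q[, -ncol(Q), drop = FALSE])
      qx <- qr(Xd)
      if (qx$rank < ncol(Xd))
        Xd <- Xd[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      if (ncol(Xd) < 1)
        stop_fmt(paste("structure design singular after dropping a column;",
                       "try a different number of subpopulations K"))
      U <- qr.resid(qr(Xd), Xi)
      r2_adj <- cosine_sq(U)
    }
  }

  idx <- which(upper.tri(r2_raw), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same_gene <- loci$gene_id[i] == loci$gene_id[j]
  mapped <- !is.na(lg[i]) & !is.na(lg[j])
  same_lg <- mapped & lg[i] == lg[j]
  dist <- ifelse(same_lg, abs(pos[i] - pos[j]), NA_real_)
  class <- ifelse(same_gene, "within_gene",
           ifelse(!mapped, "unmapped",
           ifelse(same_lg & dist < 1, "within_LG_lt1cM",
           ifelse(same_lg, "within_LG_ge1cM", "between_LG"))))
  pairs <- data.frame(
    locus_a = loci$marker_id[i], locus_b = loci$marker_id[j],
    gene_a = loci$gene_id[i], gene_b = loci$gene_id[j],
    lg_a = lg[i], lg_b = lg[j], distance_cM = dist, class = class,
    maf_a = maf[i], maf_b = maf[j],
    r2_raw = r2_raw[idx],
    r2_adjusted = if (is.null(r2_adj)) NA_real_ else r2_adj[idx],
    stringsAsFactors = FALSE)

  classes <- c("within_LG_lt1cM", "within_LG_ge1cM", "between_LG")
  tab <- list()
  for (t in maf_thresholds) {
    sel <- pairs$maf_a > t & pairs$maf_b > t & pairs$class %in% classes
    for (cl in classes) {
      s <- sel & pairs$class == cl
      n_tot <- sum(s, na.rm = TRUE)
      n_raw <- sum(pairs$r2_raw[s] > r2_threshold, na.rm = TRUE)
      n_adj <- if (adjustment == "none") NA_integer_
        else sum(pairs$r2_adjusted[s] > r2_threshold, na.rm = TRUE)
      tab[[length(tab) + 1L]] <- data.frame(
        maf_threshold = t, class = cl, n_pairs = n_tot,
        n_raw_gt = n_raw,
        pct_raw = if (n_tot) 100 * n_raw / n_tot else NA_real_,
        n_adj_gt = n_adj,
        pct_adj = if (n_tot && adjustment != "none")
          100 * n_adj / n_tot else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = pairs, table = do.call(rbind, tab),
                 adjustment = adjustment, r2_threshold = r2_threshold,
                 n_loci_used = p, excluded_loci = excluded),
            class = "ld_table")
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("ld_table: %d locus pairs from %d loci (adjustment: %s)\n",
              nrow(x$pairs), x$n_loci_used, x$adjustment))
  print.data.frame(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ld_table <- function(object, ...) {
  cl <- object$pairs$class
  agg <- stats::aggregate(list(mean_r2_raw = object$pairs$r2_raw),
                          by = list(class = cl), FUN = mean, na.rm = TRUE)
  if (object$adjustment != "none")
    agg$mean_r2_adjusted <- stats::aggregate(
      object$pairs$r2_adjusted, by = list(cl), FUN = mean,
      na.rm = TRUE)$x
  agg
}

#' @export
plot.ld_table <- function(x, which = c("decay", "classes"), ...) {
  which <- match.arg(which)
  pp <- x$pairs[x$pairs$class %in% c("within_LG_lt1cM", "within_LG_ge1cM"), ]
  if (which == "decay") {
    graphics::plot(pp$distance_cM, pp$r2_raw, pch = 16,
                   col = grDevices::adjustcolor("grey30", 0.4),
                   xlab = "genetic distance (cM)", ylab = expression(r^2),
                   ...)
    dr <- ld_decay_regression(pp)
    graphics::lines(dr$distance_cM, dr$r2_smooth, col = "red", lwd = 2)
  } else {
    graphics::boxplot(r2_raw ~ class, data = x$pairs,
                      ylab = expression(r^2), ...)
  }
  invisible(x)
}

#' Kernel regression of r-squared on genetic distance
#'
#' Nadaraya-Watson (normal kernel) regression of within-LG r-squared
#' against map distance, evaluated on a 0.5 cM grid; grid points with no
#' kernel mass are `NA`.
#'
#' @param pairs `pairs` data frame from [ld_pair_table()] (or an `ld_table`
#'   object), needing >= 10 within-LG pairs.
#' @param bandwidth_cM Kernel bandwidth (default 2 cM, the `ksmooth`
#'   quartile convention).
#' @param value Column smoothed: `"r2_raw"` or `"r2_adjusted"`.
#' @return Data frame `distance_cM`, `r2_smooth`.
#' @export
ld_decay_regression <- function(pairs, bandwidth_cM = 2,
                                value = c("r2_raw", "r2_adjusted")) {
  value <- match.arg(value)
  if (inherits(pairs, "ld_table")) pairs <- pairs$pairs
  pp <- pairs[!is.na(pairs$distance_cM) & !is.na(pairs[[value]]), ]
  if (nrow(pp) < 10) stop_fmt("need >= 10 within-LG pairs")
  grid <- seq(0, max(pp$distance_cM), by = 0.5)
  ks <- stats::ksmooth(pp$distance_cM, pp[[value]], kernel = "normal",
                       bandwidth = bandwidth_cM, x.points = grid)
  data.frame(distance_cM = ks$x, r2_smooth = ks$y)
}

#' Critical r-squared for extended LD from a reference distribution
#'
#' A beta distribution is fitted by the method of moments to a set of
#' reference r-squared values (e.g. adjusted r-squared of pairs with strong
#' evidence of extended LD within linkage groups), and the critical value
#' is the fitted quantile at 1 - alpha/n_tests (Bonferroni-adjusted level).
#' The empirical maximum is reported alongside, since a direct empirical
#' quantile at such extreme levels is unsupported by typical reference set
#' sizes.
#'
#' @param r2_values Reference values, >= 20 of them, in (0, 1).
#' @param n_tests Number of tests Bonferroni-corrected for (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return List with `critical_value`, `per_test_level`, `shape1`,
#'   `shape2`, `empirical_max`, `n_reference`.
#' @export
extended_ld_critical_value <- function(r2_values, n_tests, alpha = 0.05) {
  r2_values <- r2_values[!is.na(r2_values)]
  if (length(r2_values) < 20)
    stop_fmt("need >= 20 reference values (got %d)", length(r2_values))
  if (any(r2_values <= 0 | r2_values >= 1))
    stop_fmt("reference values must lie in (0, 1)")
  if (n_tests < 1) stop_fmt("n_tests must be >= 1")
  m <- mean(r2_values); v <- stats::var(r2_values)
  if (v < 1e-12) stop_fmt("degenerate variance in reference values")
  common <- m * (1 - m) / v - 1
  if (common <= 0)
    stop_fmt("moments incompatible with a beta distribution")
  a <- m * common; b <- (1 - m) * common
  lvl <- alpha / n_tests
  list(critical_value = stats::qbeta(1 - lvl, a, b),
       per_test_level = lvl, shape1 = a, shape2 = b,
       empirical_max = max(r2_values), n_reference = length(r2_values))
}
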