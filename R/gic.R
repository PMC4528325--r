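# Genotype information content (GIC): the marker-informativeness score used
# to select one marker per gene and to weight input maps in the consensus
# merge.  GIC = G_e * N_indiv, where G_e = 1 / sum(p_j^2) is the effective
# number of genotypic classes.  G_e is maximal (= number of classes) under
# undistorted Mendelian ratios and shrinks as segregation distortion grows,
# so GIC rewards both sample size and clean segregation.

#' Effective number of genotypic classes
#'
#' \eqn{G_e = 1 / \sum_j p_j^2} over the usable genotypic classes.  For
#' biparentally heterozygous (hk x hk) loci, which segregate 1 hh : 2 hk :
#' 1 kk, only the homozygous classes hh and kk are used, with their
#' proportions renormalized over homozygotes; excluding the heterozygote
#' keeps G_e on the same 1-2 scale as testcross loci and keeps GIC inversely
#' related to the distortion chi-square.
#'
#' @param class_counts Named or unnamed non-negative integer vector of
#'   genotype-class counts.  For `segregation_type = "hkxhk"` the counts must
#'   be named `hh`, `hk`, `kk`.
#' @param segregation_type `"generic"` (use all classes) or `"hkxhk"`.
#' @return G_e, a number in [1, number of classes used].  `NA` with a
#'   warning for an hk x hk locus with no homozygotes.
#' @examples
#' effective_genotype_classes(c(50, 50))                    # 2
#' effective_genotype_classes(c(90, 10))                    # 1.2195
#' effective_genotype_classes(c(hh = 30, hk = 40, kk = 30), "hkxhk")  # 2
#' @export
effective_genotype_classes <- function(class_counts,
                                       segregation_type = c("generic",
                                                            "hkxhk")) {
  segregation_type <- match.arg(segregation_type)
  if (any(class_counts < 0)) stop_fmt("class counts must be >= 0")
  if (segregation_type == "hkxhk") {
    if (!all(c("hh", "kk") %in% names(class_counts)))
      stop_fmt("hkxhk counts must be named (hh, hk, kk)")
    class_counts <- class_counts[c("hh", "kk")]
  }
  total <- sum(class_counts)
  if (total == 0) {
    warning("no usable genotype classes; G_e undefined")
    return(NA_real_)
  }
  p <- class_counts / total
  1 / sum(p^2)
}

#' Genotype information content of a marker in one cohort
#'
#' GIC = G_e x number of individuals genotyped.  For hk x hk loci the
#' individual count includes heterozygotes even though G_e is computed from
#' homozygotes only.
#'
#' @param g_e Effective number of genotypic classes, from
#'   [effective_genotype_classes()].
#' @param n_genotyped Number of genotyped individuals (> 0).
#' @return GIC (dimensionless).
#' @export
genotype_information_content <- function(g_e, n_genotyped) {
  if (any(n_genotyped <= 0)) stop_fmt("n_genotyped must be > 0")
  g_e * n_genotyped
}

#' Per-marker, per-cohort GIC records from an input map
#'
#' Count columns named `count_<cohort>_<class>` are parsed into per-cohort
#' genotype-class counts; classes `hh`/`hk`/`kk` trigger the hk x hk rule.
#'
#' @param map An [input_map()] with count columns.
#' @return Data frame with one row per (marker, cohort): `marker_id`,
#'   `gene_id`, `cohort`, `g_e`, `n_genotyped`, `gic`, plus attribute-free
#'   column `gic_sum` repeated per marker (cohort-summed GIC).
#' @export
gic_records <- function(map) {
  stopifnot(inherits(map, "input_map"))
  cnt <- grep("^count_", names(map), value = TRUE)
  if (!length(cnt)) stop_fmt("map '%s' has no count_ columns",
                             map$map_id[1])
  parts <- strsplit(sub("^count_", "", cnt), "_", fixed = TRUE)
  cohort <- vapply(parts, `[`, character(1), 1)
  klass <- vapply(parts, `[`, character(1), 2)
  out <- list()
  for (co in unique(cohort)) {
    cols <- cnt[cohort == co]
    kls <- klass[cohort == co]
    counts <- as.matrix(map[, cols, drop = FALSE])
    hk <- all(c("hh", "kk") %in% kls)
    rec <- data.frame(marker_id = map$marker_id, gene_id = map$gene_id,
                      cohort = co, g_e = NA_real_,
                      n_genotyped = rowSums(counts, na.rm = TRUE),
                      gic = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(counts))) {
      ci <- counts[i, ]
      names(ci) <- kls
      if (all(is.na(ci)) || sum(ci, na.rm = TRUE) == 0) next
      ci[is.na(ci)] <- 0L
      rec$g_e[i] <- if (hk)
        suppressWarnings(effective_genotype_classes(ci, "hkxhk"))
      else effective_genotype_classes(ci)
      if (!is.na(rec$g_e[i]))
        rec$gic[i] <- genotype_information_content(rec$g_e[i],
                                                   rec$n_genotyped[i])
    }
    out[[co]] <- rec
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  sums <- tapply(out$gic, out$marker_id, sum, na.rm = TRUE)
  out$gic_sum <- as.numeric(sums[out$marker_id])
  out
}

#' Per-cohort GIC records from a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param cohorts Character vector assigning each individual to a cohort
#'   (recycled single value allowed).
#' @return As [gic_records()].
#' @export
gic_from_genotypes <- function(gm, cohorts = "all") {
  stopifnot(inherits(gm, "genotype_matrix"))
  cohorts <- rep_len(as.character(cohorts), nrow(gm$calls))
  out <- list()
  for (co in unique(cohorts)) {
    sub <- gm$calls[cohorts == co, , drop = FALSE]
    rec <- data.frame(marker_id = gm$loci$marker_id,
                      gene_id = gm$loci$gene_id, cohort = co,
                      g_e = NA_real_, n_genotyped = NA_integer_,
                      gic = NA_real_, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(sub))) {
      calls <- sub[, j]
      calls <- calls[!is.na(calls)]
      if (!length(calls)) next
      tab <- table(calls)
      ci <- as.integer(tab); names(ci) <- names(tab)
      hk <- identical(gm$loci$segregation_type[j], "hkxhk")
      if (hk) ci <- ci[c("hh", "hk", "kk")[c("hh", "hk", "kk") %in%
                                             names(ci)]]
      if (hk && !all(c("hh", "kk") %in% names(ci))) next
      rec$g_e[j] <- if (hk)
        suppressWarnings(effective_genotype_classes(ci, "hkxhk"))
      else effective_genotype_classes(ci)
      rec$n_genotyped[j] <- length(calls)
      if (!is.na(rec$g_e[j]))
        rec$gic[j] <- genotype_information_content(rec$g_e[j], length(calls))
    }
    out[[co]] <- rec
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  sums <- tapply(out$gic, out$marker_id, sum, na.rm = TRUE)
  out$gic_sum <- as.numeric(sums[out$marker_id])
  out
}

#' Select the most informative marker per gene
#'
#' Multi-SNP genes (several markers sharing a `gene_id`, e.g. SNPs within one
#' EST) are reduced to the single marker with maximal cohort-summed GIC;
#' ties break to the lexicographically smallest `marker_id`.
#'
#' @param gic GIC record data frame (columns `marker_id`, `gene_id`,
#'   `gic_sum`), e.g. from [gic_records()].
#' @return Character vector of retained marker ids.
#' @export
select_max_gic_per_gene <- function(gic) {
  gic <- unique(gic[, c("marker_id", "gene_id", "gic_sum")])
  gic$gic_sum[is.na(gic$gic_sum)] <- -Inf
  gic <- gic[order(gic$gene_id, -gic$gic_sum, gic$marker_id), ]
  keep <- gic[!duplicated(gic$gene_id), "marker_id"]
  sort(keep)
}

#' Input-map merge weights from average GIC
#'
#' Each map's average GIC is the mean over its markers of cohort-summed GIC;
#' weights scale the averages to sum to 1:
#' \eqn{w_l = \bar{GIC}_l / \sum_l \bar{GIC}_l}.
#'
#' @param x Either a named numeric vector of per-map average GICs, or a
#'   named list of GIC record data frames (one per map, as returned by
#'   [gic_records()]).
#' @return Data frame with columns `map_id`, `avg_gic`, `weight`; weights
#'   sum to 1.
#' @examples
#' map_weights(c(A = 402, B = 462, C = 941, D = 121))
#' @export
map_weights <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    avg <- vapply(x, function(rec) {
      per_marker <- tapply(rec$gic, rec$marker_id, sum, na.rm = TRUE)
      mean(per_marker, na.rm = TRUE)
    }, numeric(1))
  } else {
    avg <- as.numeric(x)
    names(avg) <- names(x) %||% paste0("map", seq_along(avg))
  }
  if (any(is.na(avg)) || all(avg == 0))
    stop_fmt("average GIC must be available and not all zero")
  data.frame(map_id = names(avg), avg_gic = unname(avg),
             weight = unname(avg / sum(avg)), stringsAsFactors = FALSE)
}
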