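# Synthetic mapping populations with known ground truth: a true map,
# Balding-Nichols structured founders, full-sib / circular multi-family /
# unrelated pedigrees, gene-dropping meiosis with Kosambi-derived
# recombination fractions, genotyping defects (error, missingness,
# viability-selection distortion), and noisy realized input maps.

#' Simulate a true genetic map
#'
#' Markers are placed at sorted uniform positions along each linkage group
#' (strictly increasing; minimum separation 1e-6 cM enforced).  A fraction
#' of genes carries two SNPs (ids `G<g>-<pos>` sharing the gene id
#' `G<g>`), emulating multi-SNP ESTs.  Base allele frequencies are drawn
#' uniformly on (0.1, 0.9).
#'
#' @param n_lg Number of linkage groups (1-12).
#' @param markers_per_lg Markers per linkage group.
#' @param lg_length_cM Linkage-group length in cM.
#' @param prop_multi_snp Fraction of genes carrying a second SNP (the second
#'   SNP is co-located within 0.05 cM of the first).
#' @param seed Integer seed (mandatory).
#' @return Data frame of class `true_map`: `linkage_group`, `marker_id`,
#'   `gene_id`, `position_cM`, `base_freq`.
#' @export
simulate_true_map <- function(n_lg = 2, markers_per_lg = 50,
                              lg_length_cM = 100, prop_multi_snp = 0,
                              seed) {
  stopifnot(n_lg >= 1, n_lg <= 12, markers_per_lg >= 2)
  with_seed(seed, {
    rows <- list()
    gene_counter <- 0L
    for (lg in seq_len(n_lg)) {
      n_genes <- markers_per_lg
      pos <- sort(stats::runif(n_genes, 0, lg_length_cM))
      pos <- pos + seq_along(pos) * 1e-6   # strict increase
      genes <- sprintf("G%05d", gene_counter + seq_len(n_genes))
      gene_counter <- gene_counter + n_genes
      df <- data.frame(linkage_group = lg,
                       marker_id = paste0(genes, "-", 101),
                       gene_id = genes, position_cM = pos,
                       base_freq = stats::runif(n_genes, 0.1, 0.9),
                       stringsAsFactors = FALSE)
      if (prop_multi_snp > 0) {
        extra <- which(stats::runif(n_genes) < prop_multi_snp)
        if (length(extra)) {
          df2 <- df[extra, ]
          df2$marker_id <- paste0(df2$gene_id, "-", 202)
          df2$position_cM <- df2$position_cM + 0.05
          df2$base_freq <- stats::runif(length(extra), 0.1, 0.9)
          df <- rbind(df, df2)
        }
      }
      df <- df[order(df$position_cM), ]
      rows[[lg]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("true_map", "data.frame")
    out
  })
}

#' Convert a true map to an input map
#'
#' @param true_map A [simulate_true_map()] result.
#' @param map_id Map identifier.
#' @return An [input_map()] (marker type `SNP`).
#' @export
as_input_map <- function(true_map, map_id = "truth") {
  input_map(data.frame(map_id = map_id,
                       linkage_group = true_map$linkage_group,
                       marker_id = true_map$marker_id,
                       gene_id = true_map$gene_id, marker_type = "SNP",
                       position_cM = true_map$position_cM,
                       stringsAsFactors = FALSE))
}

#' Simulate structured founder haplotypes
#'
#' Subpopulation allele frequencies are drawn from the Balding-Nichols beta
#' model around each marker's base frequency with divergence `F`:
#' \eqn{p_k \sim Beta(p(1-F)/F, (1-p)(1-F)/F)}; `F = 0` keeps the base
#' frequencies.  Founders carry two haplotypes with alleles drawn
#' independently from their subpopulation's frequencies (hence
#' Hardy-Weinberg within subpopulations).  With `admixture_alpha` set, each
#' founder's ancestry vector is Dirichlet-distributed and every allele's
#' subpopulation of origin is drawn from it, producing admixed individuals;
#' the true Q matrix is recorded either way.
#'
#' @param true_map A [simulate_true_map()] result.
#' @param K Number of subpopulations.
#' @param F_div Balding-Nichols divergence, in [0, 1).
#' @param n_per_subpop Founders per subpopulation (recycled to K).
#' @param seed Integer seed.
#' @param ids Optional founder ids (default `F1..Fn`).
#' @param admixture_alpha Optional Dirichlet concentration for admixed
#'   ancestry (scalar); `NULL` gives one-subpopulation-per-founder.
#' @param pool_size Optional ancestral haplotype pool size per
#'   subpopulation.  When set, founder haplotypes are mosaics of the pool
#'   (template switches between adjacent markers with probability
#'   \eqn{1 - \exp(-g d / 100)} for interval d cM and `pool_generations`
#'   g), so alleles at nearby markers share ancestry and r-squared decays
#'   with map distance.  `NULL` (default) draws every allele
#'   independently, i.e. founders carry no baseline LD.
#' @param pool_generations Mosaic switching scale (default 5).
#' @return List of class `founder_set`: `haplotypes` (named list of
#'   loci x 2 0/1 matrices), `Q` (n x K truth), `subpop_freqs`
#'   (loci x K), `ids`.
#' @export
simulate_founders <- function(true_map, K = 1, F_div = 0, n_per_subpop = 10,
                              seed, ids = NULL, admixture_alpha = NULL,
                              pool_size = NULL, pool_generations = 5) {
  if (F_div < 0 || F_div >= 1)
    stop_fmt("divergence F must lie in [0, 1)")
  n_per_subpop <- rep_len(n_per_subpop, K)
  n <- sum(n_per_subpop)
  if (is.null(ids)) ids <- paste0("F", seq_len(n))
  stopifnot(length(ids) == n)
  m <- nrow(true_map)
  with_seed(seed, {
    freqs <- matrix(NA_real_, m, K)
    for (k in seq_len(K)) {
      freqs[, k] <- if (F_div == 0) true_map$base_freq
      else stats::rbeta(m, true_map$base_freq * (1 - F_div) / F_div,
                        (1 - true_map$base_freq) * (1 - F_div) / F_div)
    }
    subpop <- rep(seq_len(K), n_per_subpop)
    Q <- matrix(0, n, K, dimnames = list(ids, paste0("pop", seq_len(K))))
    pool <- NULL
    if (!is.null(pool_size)) {
      # ancestral haplotype pool per subpopulation; founders are mosaics
      pool <- lapply(seq_len(K), function(k)
        matrix(stats::rbinom(m * pool_size, 1, freqs[, k]), m, pool_size))
      sw_prob <- numeric(m)   # template-switch prob before each marker
      for (lg in unique(true_map$linkage_group)) {
        i <- which(true_map$linkage_group == lg)
        sw_prob[i] <- c(1, 1 - exp(-pool_generations *
                                     diff(true_map$position_cM[i]) / 100))
      }
      mosaic <- function(k) {
        tpl <- integer(m)
        cur <- sample.int(pool_size, 1)
        for (j in seq_len(m)) {
          if (stats::runif(1) < sw_prob[j]) cur <- sample.int(pool_size, 1)
          tpl[j] <- cur
        }
        pool[[k]][cbind(seq_len(m), tpl)]
      }
    }
    haps <- vector("list", n); names(haps) <- ids
    for (i in seq_len(n)) {
      if (is.null(admixture_alpha)) {
        Q[i, subpop[i]] <- 1
        if (is.null(pool)) {
          pk <- freqs[, subpop[i]]
          h <- matrix(stats::rbinom(2 * m, 1, pk), m, 2)
        } else {
          h <- cbind(mosaic(subpop[i]), mosaic(subpop[i]))
        }
      } else {
        g <- stats::rgamma(K, admixture_alpha)
        Q[i, ] <- g / sum(g)
        orig <- matrix(sample.int(K, 2 * m, replace = TRUE, prob = Q[i, ]),
                       m, 2)
        h <- matrix(stats::rbinom(2 * m, 1, freqs[cbind(rep(seq_len(m), 2),
                                                        as.vector(orig))]),
                    m, 2)
      }
      rownames(h) <- true_map$marker_id
      haps[[i]] <- h
    }
    structure(list(haplotypes = haps, Q = Q, subpop_freqs = freqs,
                   ids = ids), class = "founder_set")
  })
}

#' Simulate a mapping-population pedigree
#'
#' Designs: `single_fullsib` (two founder parents, one full-sib cohort);
#' `multi_cohort_fullsib` (two founder parents, several full-sib cohorts);
#' `circular_multifamily` (n parents mated in rings -- family f pairs parent
#' i with parent i+offset (mod n), offsets 1, 2, ... -- with progeny split
#' evenly over families, each family a cohort); `unrelated` (founders
#' only).
#'
#' @param design One of the four design names.
#' @param n_parents Number of founder parents (circular design).
#' @param n_families Number of full-sib families (circular design); at most
#'   `n_parents * (n_parents - 1) / 2`.
#' @param n_progeny Total progeny (circular) or per-cohort sizes
#'   (full-sib designs, vector = cohorts).
#' @param n Number of founders (`unrelated` design).
#' @return A [pedigree()].
#' @export
simulate_pedigree <- function(design = c("single_fullsib",
                                         "multi_cohort_fullsib",
                                         "circular_multifamily",
                                         "unrelated"),
                              n_parents = 4, n_families = 4,
                              n_progeny = 100, n = 10) {
  design <- match.arg(design)
  if (design == "unrelated") {
    return(pedigree(data.frame(id = paste0("U", seq_len(n)), sire = NA,
                               dam = NA, cohort = "unrelated")))
  }
  if (design %in% c("single_fullsib", "multi_cohort_fullsib")) {
    sizes <- if (design == "single_fullsib") n_progeny[1] else n_progeny
    rows <- data.frame(id = c("P1", "P2"), sire = NA, dam = NA,
                       cohort = "parents", stringsAsFactors = FALSE)
    k <- 0L
    for (ci in seq_along(sizes)) {
      ids <- paste0("C", ci, "_", seq_len(sizes[ci]))
      rows <- rbind(rows, data.frame(id = ids, sire = "P1", dam = "P2",
                                     cohort = paste0("cohort", ci)))
      k <- k + sizes[ci]
    }
    return(pedigree(rows))
  }
  # circular multi-family
  max_fam <- n_parents * (n_parents - 1) / 2
  if (n_families > max_fam)
    stop_fmt("%d families requested but only %d parent pairs possible",
             n_families, max_fam)
  pairs <- list()
  for (off in seq_len(n_parents - 1)) {
    for (i in seq_len(n_parents)) {
      j <- ((i - 1L + off) %% n_parents) + 1L
      key <- paste(sort(c(i, j)), collapse = "-")
      if (!key %in% names(pairs)) pairs[[key]] <- c(i, j)
      if (length(pairs) >= n_families) break
    }
    if (length(pairs) >= n_families) break
  }
  pairs <- pairs[seq_len(n_families)]
  sizes <- diff(round(seq(0, n_progeny, length.out = n_families + 1)))
  rows <- data.frame(id = paste0("P", seq_len(n_parents)), sire = NA,
                     dam = NA, cohort = "parents", stringsAsFactors = FALSE)
  for (f in seq_len(n_families)) {
    if (sizes[f] == 0) next
    pr <- pairs[[f]]
    ids <- paste0("fam", f, "_", seq_len(sizes[f]))
    rows <- rbind(rows, data.frame(id = ids, sire = paste0("P", pr[1]),
                                   dam = paste0("P", pr[2]),
                                   cohort = paste0("fam", f)))
  }
  pedigree(rows)
}

# one meiotic gamete from a diploid: per LG, pick a start haplotype and
# switch between adjacent markers independently with the Kosambi-derived
# recombination fraction (no interference across intervals)
meiose <- function(hap, true_map) {
  m <- nrow(true_map)
  gamete <- integer(m)
  origin <- integer(m)
  for (lg in unique(true_map$linkage_group)) {
    i <- which(true_map$linkage_group == lg)
    r <- kosambi_d_to_r(diff(true_map$position_cM[i]))
    cur <- sample.int(2, 1)
    origin[i[1]] <- cur
    if (length(i) > 1) {
      sw <- stats::rbinom(length(r), 1, r) == 1
      for (k in seq_along(sw)) {
        if (sw[k]) cur <- 3L - cur
        origin[i[k + 1L]] <- cur
      }
    }
  }
  gamete <- hap[cbind(seq_len(m), origin)]
  list(gamete = gamete, origin = origin)
}

#' Drop genotypes through a pedigree
#'
#' Simulates meiosis per linkage group (independent Bernoulli recombination
#' between adjacent markers with probability `kosambi_d_to_r(interval)`),
#' transmitting founder haplotypes down the pedigree.  Diploid individuals
#' receive one gamete from each parent; with `dialect = "haploid"` each
#' individual is a single maternal gamete (megagametophyte-style), its sire
#' entry ignored.  CP coding maps genotypes family-wise onto hh/hk/kk
#' (both parents heterozygous), ll/lm (dam heterozygous) or nn/np (sire
#' heterozygous); loci with both parents homozygous are coded `ll`
#' (monoallelic).
#'
#' @param true_map A [simulate_true_map()] result.
#' @param ped A [pedigree()]; every founder needs haplotypes.
#' @param founders A [simulate_founders()] result.
#' @param seed Integer seed.
#' @param dialect Output coding: `"dosage"`, `"CP"` (single-family
#'   pedigrees only), or `"haploid"`.
#' @param cohorts Restrict output to these cohorts (default: all
#'   non-founder cohorts, or founders too for the `unrelated` design).
#' @return A [genotype_matrix()]; attribute `origins` carries the realized
#'   haplotype-of-origin matrices used by identity-by-descent checks.
#' @export
drop_genotypes <- function(true_map, ped, founders, seed,
                           dialect = c("dosage", "CP", "haploid"),
                           cohorts = NULL) {
  dialect <- match.arg(dialect)
  fids <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  missing_f <- setdiff(fids, names(founders$haplotypes))
  if (length(missing_f))
    stop_fmt("founder '%s' has no simulated haplotypes", missing_f[1])
  m <- nrow(true_map)
  with_seed(seed, {
    haps <- founders$haplotypes
    origins <- list()
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      if (id %in% fids) next
      if (dialect == "haploid") {
        gm <- meiose(haps[[ped$dam[i]]], true_map)
        haps[[id]] <- matrix(gm$gamete, m, 2)  # carried for completeness
        origins[[id]] <- cbind(dam = gm$origin, sire = NA_integer_)
      } else {
        gs <- meiose(haps[[ped$sire[i]]], true_map)
        gd <- meiose(haps[[ped$dam[i]]], true_map)
        haps[[id]] <- cbind(gs$gamete, gd$gamete)
        origins[[id]] <- cbind(sire = gs$origin, dam = gd$origin)
      }
    }
    if (is.null(cohorts)) {
      cohorts <- setdiff(unique(ped$cohort), "parents")
      if (!length(cohorts)) cohorts <- unique(ped$cohort)
    }
    keep <- ped$id[ped$cohort %in% cohorts]
    if (dialect == "haploid") {
      calls <- t(vapply(keep, function(id) haps[[id]][, 1], numeric(m)))
      calls <- matrix(as.character(calls), length(keep), m,
                      dimnames = list(keep, true_map$marker_id))
      loci <- data.frame(marker_id = true_map$marker_id,
                         gene_id = true_map$gene_id,
                         segregation_type = "haploid")
    } else if (dialect == "dosage") {
      calls <- t(vapply(keep, function(id) rowSums(haps[[id]]), numeric(m)))
      calls <- matrix(as.character(calls), length(keep), m,
                      dimnames = list(keep, true_map$marker_id))
      loci <- data.frame(marker_id = true_map$marker_id,
                         gene_id = true_map$gene_id,
                         segregation_type = "dosage")
    } else {
      prs <- unique(ped[ped$id %in% keep, c("sire", "dam")])
      if (nrow(prs) != 1)
        stop_fmt("CP coding requires a single full-sib family")
      ds <- rowSums(haps[[prs$sire]]); dd <- rowSums(haps[[prs$dam]])
      seg <- ifelse(ds == 1 & dd == 1, "hkxhk",
                    ifelse(dd == 1, "lmxll",
                           ifelse(ds == 1, "nnxnp", "lmxll")))
      dos <- t(vapply(keep, function(id) rowSums(haps[[id]]), numeric(m)))
      calls <- matrix(NA_character_, length(keep), m,
                      dimnames = list(keep, true_map$marker_id))
      for (j in seq_len(m)) {
        dj <- dos[, j]
        calls[, j] <- switch(seg[j],
          hkxhk = c("hh", "hk", "kk")[dj + 1],
          # dam het: sire contributes ds/2 copies to everyone, dam 0 or 1
          lmxll = if (dd[j] == 1) ifelse(dj == ds[j] / 2, "ll", "lm")
                  else "ll",                    # both parents homozygous
          nnxnp = ifelse(dj == dd[j] / 2, "nn", "np"))
      }
      loci <- data.frame(marker_id = true_map$marker_id,
                         gene_id = true_map$gene_id, segregation_type = seg)
    }
    gm <- genotype_matrix(calls, loci = loci)
    attr(gm, "origins") <- origins[keep[keep %in% names(origins)]]
    gm
  })
}

#' Degrade genotypes with error, missingness, and segregation distortion
#'
#' Distortion is applied first as viability selection: at each affected
#' locus an individual carrying k copies of the disfavored allele (the "1"
#' allele) survives with probability \eqn{(1-s)^k}; non-survivors' calls are
#' redrawn from the locus's genotype-class distribution reweighted by
#' survival, which reproduces the marginal distorted ratios (a haploid locus
#' with s = 0.5 segregates 2:1).  Genotyping errors then replace calls with
#' a uniformly chosen different legal code, and missingness is applied
#' independently.
#'
#' @param gm A [genotype_matrix()].
#' @param error_rate,missing_rate Per-call rates in [0, 1).
#' @param distortion_s Named vector of selection coefficients per marker
#'   (or a single value applied to all loci); `NULL` for none.
#' @param seed Integer seed.
#' @return A degraded [genotype_matrix()].
#' @export
degrade_genotypes <- function(gm, error_rate = 0, missing_rate = 0,
                              distortion_s = NULL, seed) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (error_rate < 0 || error_rate >= 1 || missing_rate < 0 ||
        missing_rate >= 1)
    stop_fmt("rates must lie in [0, 1)")
  calls <- gm$calls
  lut <- c("0" = 0, "1" = 1, "2" = 2, hh = 0, hk = 1, kk = 2,
           ll = 0, lm = 1, nn = 0, np = 1)
  with_seed(seed, {
    if (!is.null(distortion_s)) {
      s_vec <- if (is.null(names(distortion_s)))
        stats::setNames(rep_len(distortion_s, ncol(calls)),
                        gm$loci$marker_id)
      else distortion_s
      for (j in seq_len(ncol(calls))) {
        s <- s_vec[gm$loci$marker_id[j]]
        if (is.na(s) || s <= 0) next
        col <- calls[, j]
        ok <- !is.na(col)
        k <- lut[col[ok]]
        surv <- stats::rbinom(sum(ok), 1, (1 - s)^k) == 1
        if (any(!surv)) {
          classes <- table(col[ok])
          wts <- as.numeric(classes) * (1 - s)^lut[names(classes)]
          col[ok][!surv] <- sample(names(classes), sum(!surv),
                                   replace = TRUE, prob = wts)
        }
        calls[, j] <- col
      }
    }
    if (error_rate > 0) {
      for (j in seq_len(ncol(calls))) {
        legal <- legal_codes(gm$loci$segregation_type[j])
        ok <- which(!is.na(calls[, j]))
        hit <- ok[stats::runif(length(ok)) < error_rate]
        if (length(hit))
          calls[hit, j] <- vapply(calls[hit, j], function(cc)
            sample(setdiff(legal, cc), 1), character(1))
      }
    }
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(length(calls)) < missing_rate,
                     nrow(calls))
      calls[drop] <- NA
    }
  })
  out <- genotype_matrix(calls, loci = gm$loci)
  attr(out, "origins") <- attr(gm, "origins")
  out
}

#' Realize noisy population-specific input maps from a true map
#'
#' Each realized map keeps a marker subset (a shared quota present in every
#' map plus an independent `subsample_fraction` of the rest), jitters
#' positions with Gaussian noise of sd `order_noise_sd` (so local order
#' errors arise naturally), rescales each linkage group's length by
#' `length_scale`, re-sorts by jittered position and re-anchors at 0.
#'
#' @param true_map A [simulate_true_map()] result.
#' @param map_ids Character vector of map identifiers.
#' @param subsample_fraction Fraction in (0, 1] of non-quota markers kept
#'   (recycled per map).
#' @param order_noise_sd Position jitter sd in cM (recycled).
#' @param length_scale Length rescaling factor (recycled).
#' @param shared_quota Number of markers guaranteed shared by all maps
#'   (default: 20% of markers).
#' @param seed Integer seed.
#' @return Named list of [input_map()] objects.
#' @export
realize_input_maps <- function(true_map, map_ids, subsample_fraction = 1,
                               order_noise_sd = 0, length_scale = 1,
                               shared_quota = NULL, seed) {
  nmap <- length(map_ids)
  subsample_fraction <- rep_len(subsample_fraction, nmap)
  order_noise_sd <- rep_len(order_noise_sd, nmap)
  length_scale <- rep_len(length_scale, nmap)
  if (any(subsample_fraction <= 0 | subsample_fraction > 1))
    stop_fmt("subsample_fraction must lie in (0, 1]")
  m <- nrow(true_map)
  if (is.null(shared_quota)) shared_quota <- ceiling(0.2 * m)
  if (shared_quota > m)
    stop_fmt("shared-marker quota (%d) exceeds marker count (%d)",
             shared_quota, m)
  with_seed(seed, {
    shared <- sort(sample.int(m, shared_quota))
    out <- list()
    for (i in seq_len(nmap)) {
      rest <- setdiff(seq_len(m), shared)
      keep <- sort(c(shared, rest[stats::runif(length(rest)) <=
                                    subsample_fraction[i]]))
      df <- true_map[keep, , drop = FALSE]
      df$position_cM <- df$position_cM +
        stats::rnorm(nrow(df), 0, order_noise_sd[i])
      for (lg in unique(df$linkage_group)) {
        sel <- df$linkage_group == lg
        p <- df$position_cM[sel]
        df$position_cM[sel] <- (p - min(p)) * length_scale[i]
      }
      out[[map_ids[i]]] <- input_map(data.frame(
        map_id = map_ids[i], linkage_group = df$linkage_group,
        marker_id = df$marker_id, gene_id = df$gene_id,
        marker_type = "SNP", position_cM = df$position_cM,
        stringsAsFactors = FALSE))
    }
    out
  })
}
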