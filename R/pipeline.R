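# End-to-end orchestration: simulate -> qc -> gic/weights -> merge ->
# density -> ld, with every stage's outputs written as TSV plus a JSON
# manifest.  Re-running with the same configuration reproduces
# byte-identical outputs (all stage seeds derive from the run seed).

#' Default pipeline configuration
#'
#' A compact fully-synthetic run: a two-LG true map with multi-SNP genes;
#' three mapping populations (two multi-cohort full-sib, one haploid
#' megagametophyte set) yielding three realized input maps; a circular
#' multi-family pedigree analysed for kinship-adjusted LD and a
#' two-subpopulation admixed unrelated sample analysed for
#' structure-adjusted LD.
#'
#' @param seed Run seed (every stage derives its own stream from it).
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    sim = list(
      n_lg = 2, markers_per_lg = 40, lg_length_cM = 100,
      prop_multi_snp = 0.15,
      error_rate = 0.01, missing_rate = 0.02,
      map_noise_sd = 0.75, map_fraction = 0.85, shared_quota = 20,
      fullsib_cohorts = c(60, 60), fullsib2_cohorts = 80, n_haploid = 72,
      n_parents = 20, n_families = 20, n_family_progeny = 200,
      K = 2, F_div = 0.2, n_per_subpop = c(60, 60)),
    thresholds = list(distortion_p = 0.001, error_rate = 0.05,
                      missing = 0.5, maf = c(0.001, 0.1, 0.2),
                      r2 = 0.1, alpha = 0.05),
    merge = list(reps = 20, noise_sd = 0.1))
}

#' Run the full pipeline
#'
#' Executes simulation (unless `config$input` supplies file paths),
#' locus QC, GIC/weight computation, weighted consensus merging with
#' replicate position CIs, marker-density profiling with the Poisson
#' deviation test, and LD tabulation with kinship and structure
#' adjustments.  All stage outputs are written under `out_dir` as TSV,
#' plus `manifest.json` recording the configuration hash, derived seeds,
#' and per-file row counts.  When only maps are supplied (no genotypes),
#' the merge and density stages run and LD is skipped with a notice.
#'
#' @param config Configuration list (see [default_run_config()]) or path
#'   to a YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  results <- list()
  log <- function(...) message(sprintf(...))

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  external_maps <- !is.null(config$input$maps)
  if (external_maps) {
    log("stage simulate: skipped (external maps supplied)")
    imaps <- lapply(config$input$maps, read_map)
    names(imaps) <- vapply(imaps, function(m) m$map_id[1], character(1))
    wtab <- read_tsv(config$input$weights)
    weights <- stats::setNames(wtab$weight, wtab$map_id)
    genos <- NULL
  } else {
    sc <- config$sim
    log("stage simulate: %d LGs x %d markers", sc$n_lg, sc$markers_per_lg)
    tm <- simulate_true_map(sc$n_lg, sc$markers_per_lg, sc$lg_length_cM,
                            sc$prop_multi_snp, seed = derive_seed(seed, "truemap"))
    write_tsv(as.data.frame(tm), file.path(out_dir, "true_map.tsv"))

    pops <- list(
      fullsib = simulate_pedigree("multi_cohort_fullsib",
                                  n_progeny = sc$fullsib_cohorts),
      fullsib2 = simulate_pedigree("multi_cohort_fullsib",
                                   n_progeny = sc$fullsib2_cohorts),
      haploid = pedigree(data.frame(
        id = c("HT", paste0("mg", seq_len(sc$n_haploid))),
        sire = c(NA, rep(NA, sc$n_haploid)),
        dam = c(NA, rep("HT", sc$n_haploid)),
        cohort = c("parents", rep("megagametophytes", sc$n_haploid)))),
      families = simulate_pedigree("circular_multifamily",
                                   n_parents = sc$n_parents,
                                   n_families = sc$n_families,
                                   n_progeny = sc$n_family_progeny),
      unrelated = simulate_pedigree("unrelated", n = sum(sc$n_per_subpop)))

    genos <- list()
    for (pop in names(pops)) {
      ped <- pops[[pop]]
      fids <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
      founders <- if (pop == "unrelated")
        simulate_founders(tm, K = sc$K, F_div = sc$F_div,
                          n_per_subpop = sc$n_per_subpop,
                          seed = derive_seed(seed, paste0("founders_", pop)),
                          ids = fids, admixture_alpha = 0.5)
      else simulate_founders(tm, K = 1, F_div = 0,
                             n_per_subpop = length(fids),
                             seed = derive_seed(seed, paste0("founders_", pop)),
                             ids = fids)
      dial <- if (pop == "haploid") "haploid" else "dosage"
      gm <- drop_genotypes(tm, ped, founders,
                           seed = derive_seed(seed, paste0("drop_", pop)),
                           dialect = dial)
      gm <- degrade_genotypes(gm, sc$error_rate, sc$missing_rate,
                              seed = derive_seed(seed, paste0("degrade_", pop)))
      genos[[pop]] <- list(ped = ped, gm = gm, founders = founders)
      write_pedigree(ped, file.path(out_dir,
                                    sprintf("pedigree_%s.tsv", pop)))
      write_genotypes(gm, file.path(out_dir,
                                    sprintf("genotypes_%s.tsv", pop)))
      if (pop == "unrelated") {
        q <- data.frame(id = rownames(founders$Q), founders$Q,
                        check.names = FALSE)
        write_tsv(q, file.path(out_dir, "q_truth.tsv"))
      }
    }

    imaps <- realize_input_maps(
      tm, map_ids = c("fullsib", "fullsib2", "haploid"),
      subsample_fraction = sc$map_fraction,
      order_noise_sd = sc$map_noise_sd, length_scale = 1,
      shared_quota = sc$shared_quota,
      seed = derive_seed(seed, "realize"))
    log("stage qc")
    th <- config$thresholds
    qc_reports <- list()
    for (pop in c("fullsib", "fullsib2", "haploid")) {
      fl <- filter_loci(genos[[pop]]$gm,
                        p_threshold = th$distortion_p,
                        missing_threshold = th$missing)
      qc_reports[[pop]] <- fl$report
      genos[[pop]]$gm_filtered <- fl$gm
    }
    qc_all <- do.call(rbind, Map(function(r, p)
      cbind(population = p, r), qc_reports, names(qc_reports)))
    write_tsv(qc_all, file.path(out_dir, "qc_report.tsv"))
    log("stage qc: %d loci dropped of %d",
        sum(qc_all$status == "dropped"), nrow(qc_all))
    results$qc <- qc_all

    log("stage gic")
    gics <- lapply(c("fullsib", "fullsib2", "haploid"), function(pop) {
      ped <- genos[[pop]]$ped
      gm <- genos[[pop]]$gm_filtered
      co <- ped$cohort[match(gm$individuals, ped$id)]
      gic_from_genotypes(gm, co)
    })
    names(gics) <- c("fullsib", "fullsib2", "haploid")
    # restrict GIC records to markers actually on each realized map, then
    # keep only the most informative marker per gene on every map
    for (nm in names(gics)) {
      on_map <- gics[[nm]]$marker_id %in% imaps[[nm]]$marker_id
      gics[[nm]] <- gics[[nm]][on_map, , drop = FALSE]
      sel <- select_max_gic_per_gene(gics[[nm]])
      n_red <- length(unique(gics[[nm]]$marker_id)) - length(sel)
      if (n_red > 0)
        log("stage gic: %s: %d redundant same-gene marker(s) excluded",
            nm, n_red)
      gics[[nm]] <- gics[[nm]][gics[[nm]]$marker_id %in% sel, , drop = FALSE]
      keep_map <- imaps[[nm]]$marker_id %in% sel
      imaps[[nm]] <- input_map(as.data.frame(imaps[[nm]])[keep_map, ,
                                                          drop = FALSE])
    }
    for (nm in names(imaps))
      write_map(imaps[[nm]], file.path(out_dir,
                                       sprintf("input_map_%s.tsv", nm)))
    wdf <- map_weights(gics)
    weights <- stats::setNames(wdf$weight, wdf$map_id)
    write_tsv(do.call(rbind, gics), file.path(out_dir, "gic.tsv"))
    write_tsv(wdf, file.path(out_dir, "weights.tsv"))
    results$weights <- wdf
    log("stage gic: weights %s",
        paste(sprintf("%s=%.2f", wdf$map_id, wdf$weight), collapse = " "))
  }

  log("stage merge: %d input maps", length(imaps))
  cm <- merge_maps(imaps, weights)
  pu <- position_uncertainty(imaps, weights,
                             n_reps = config$merge$reps %||% 20,
                             noise_sd = config$merge$noise_sd %||% 0.1,
                             seed = derive_seed(seed, "ci"))
  cons <- cm$map
  cons$ci_lo <- pu$ci$ci_lo; cons$ci_hi <- pu$ci$ci_hi
  cons$ci_half <- pu$ci$ci_half
  write_tsv(cons, file.path(out_dir, "consensus.tsv"))
  write_tsv(cm$conflicts, file.path(out_dir, "conflicts.tsv"))
  rmse <- do.call(rbind, lapply(names(imaps), function(nm)
    cbind(map_id = nm, rmse_order_agreement(cm, imaps[[nm]]))))
  write_tsv(rmse, file.path(out_dir, "rmse.tsv"))
  write_tsv(map_summary(cons), file.path(out_dir, "summary.tsv"))
  results$consensus <- cm
  results$rmse <- rmse

  log("stage density")
  alpha <- config$thresholds$alpha %||% 0.05
  dens_rows <- list(); int_rows <- list()
  for (lg in unique(cons$linkage_group)) {
    pos <- cons$position_cM[cons$linkage_group == lg]
    prof <- density_profile(pos, lg_length = max(pos))
    dt <- density_deviation_test(prof, alpha = alpha)
    dens_rows[[as.character(lg)]] <- cbind(linkage_group = lg, dt$flags)
    if (nrow(dt$intervals))
      int_rows[[as.character(lg)]] <- cbind(linkage_group = lg,
                                            dt$intervals)
  }
  write_tsv(do.call(rbind, dens_rows), file.path(out_dir, "density.tsv"))
  write_tsv(do.call(rbind, int_rows) %||%
              data.frame(linkage_group = integer(0), start_cM = numeric(0),
                         end_cM = numeric(0), flag = character(0)),
            file.path(out_dir, "density_intervals.tsv"))

  if (external_maps || is.null(genos)) {
    log("stage ld: skipped (no genotype data in this run)")
  } else {
    log("stage ld")
    th <- config$thresholds
    A <- pedigree_relationship_matrix(genos$families$ped)
    gmf <- genos$families$gm
    Af <- A[gmf$individuals, gmf$individuals]
    ld_kin <- ld_pair_table(gmf, cm, adjustment = "kinship", V = Af,
                            maf_thresholds = th$maf,
                            r2_threshold = th$r2)
    gmu <- genos$unrelated$gm
    Qu <- genos$unrelated$founders$Q[gmu$individuals, , drop = FALSE]
    ld_str <- ld_pair_table(gmu, cm, adjustment = "structure", Q = Qu,
                            maf_thresholds = th$maf,
                            r2_threshold = th$r2)
    tab <- rbind(cbind(population = "families", ld_kin$table),
                 cbind(population = "unrelated", ld_str$table))
    write_tsv(tab, file.path(out_dir, "table3.tsv"))
    write_tsv(ld_kin$pairs, file.path(out_dir, "ld_pairs_families.tsv"))
    write_tsv(ld_str$pairs, file.path(out_dir, "ld_pairs_unrelated.tsv"))
    decay <- tryCatch(ld_decay_regression(ld_kin), error = function(e) NULL)
    if (!is.null(decay))
      write_tsv(decay, file.path(out_dir, "decay_curve.tsv"))
    results$ld <- list(families = ld_kin, unrelated = ld_str)
  }

  files <- list.files(out_dir, pattern = "\\.tsv$")
  counts <- vapply(files, function(f)
    length(readLines(file.path(out_dir, f))) - 1L, integer(1))
  manifest <- list(package_version = as.character(
                     utils::packageVersion("conmapLD")),
                   seed = seed, config_hash = cfg_hash,
                   row_counts = as.list(counts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
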