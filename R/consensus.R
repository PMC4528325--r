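# Weighted consensus merging of linkage maps.  Input maps are reduced to
# gene-level merge keys, combined per linkage group into a directed order
# graph (one edge per adjacent marker pair per map, carrying the map's
# weight), order conflicts are resolved by deleting the minimum-weight set
# of marker occurrences that breaks the cycles, and consensus positions are
# the monotone weighted least-squares fit to the input inter-marker
# distances.

#' Gene-level merge key for a marker name
#'
#' EST-derived SNP ids carry the SNP's nucleotide position as a trailing
#' dash-separated numeric token (e.g. `UMN_1234-567` is SNP at position 567
#' of EST `UMN_1234`); the key drops that token so SNPs from the same gene
#' merge.  Ids without such a suffix are returned unchanged.
#'
#' @param marker_id Character vector of marker ids.
#' @return Character vector of merge keys.
#' @examples
#' normalize_marker_name(c("UMN_1234-567", "PtSIFG_0345", "X-101", "X-222"))
#' @export
normalize_marker_name <- function(marker_id) {
  sub("-[0-9]+$", "", marker_id)
}

#' Markers shared between two input maps
#'
#' Markers are matched by gene-level merge key.  Matches on the same linkage
#' group are returned as `pairs`; matches placed on different linkage groups
#' in the two maps are anomalies, returned separately and excluded from
#' merging.
#'
#' @param map_a,map_b [input_map()] objects.
#' @return List with data frames `pairs` (key, lg, positions in both maps)
#'   and `cross_lg`.
#' @export
shared_markers <- function(map_a, map_b) {
  a <- data.frame(key = normalize_marker_name(map_a$marker_id),
                  lg = map_a$linkage_group, pos = map_a$position_cM)
  b <- data.frame(key = normalize_marker_name(map_b$marker_id),
                  lg = map_b$linkage_group, pos = map_b$position_cM)
  m <- merge(a, b, by = "key", suffixes = c("_a", "_b"))
  same <- m$lg_a == m$lg_b
  list(pairs = data.frame(key = m$key[same], lg = m$lg_a[same],
                          pos_a = m$pos_a[same], pos_b = m$pos_b[same],
                          stringsAsFactors = FALSE),
       cross_lg = data.frame(key = m$key[!same], lg_a = m$lg_a[!same],
                             lg_b = m$lg_b[!same], stringsAsFactors = FALSE))
}

# per-map, per-LG ordered key/position tables with cross-LG occurrences
# removed (each key is assigned to the LG carrying its maximum total weight)
prepare_sequences <- function(input_maps, w) {
  occ <- do.call(rbind, lapply(names(input_maps), function(m) {
    im <- input_maps[[m]]
    data.frame(map = m, key = normalize_marker_name(im$marker_id),
               lg = im$linkage_group, pos = im$position_cM,
               stringsAsFactors = FALSE)
  }))
  # collapse duplicate keys within one map/LG (multi-SNP genes that escaped
  # per-gene selection): keep the lowest-position occurrence
  occ <- occ[order(occ$map, occ$lg, occ$pos, occ$key), ]
  dup <- duplicated(occ[, c("map", "lg", "key")])
  if (any(dup)) {
    warning(sprintf("%d duplicate merge key occurrence(s) collapsed", sum(dup)))
    occ <- occ[!dup, ]
  }
  wt <- stats::aggregate(list(weight = w[occ$map]),
                         by = list(key = occ$key, lg = occ$lg), FUN = sum)
  wt <- wt[order(wt$key, -wt$weight, wt$lg), ]
  home <- wt[!duplicated(wt$key), c("key", "lg")]
  occ$home_lg <- home$lg[match(occ$key, home$key)]
  cross <- occ[occ$lg != occ$home_lg, c("map", "key", "lg", "home_lg")]
  occ <- occ[occ$lg == occ$home_lg, ]
  list(occ = occ, cross_lg = cross)
}

# cheap DFS cycle test on an adjacency list restricted to a key set
has_cycle <- function(adj, keys) {
  color <- stats::setNames(rep(0L, length(keys)), keys)
  found <- FALSE
  visit <- function(v) {
    color[[v]] <<- 1L
    for (u in adj[[v]]) {
      if (found) return()
      cu <- color[[u]]
      if (is.null(cu)) next
      if (cu == 1L) { found <<- TRUE; return() }
      if (cu == 0L) visit(u)
    }
    color[[v]] <<- 2L
  }
  for (v in keys) { if (found) break; if (color[[v]] == 0L) visit(v) }
  found
}

seq_adjacency <- function(seqs, keys = NULL) {
  adj <- list()
  for (s in seqs) {
    ks <- if (is.null(keys)) s$key else s$key[s$key %in% keys]
    if (length(ks) < 2) next
    for (i in seq_len(length(ks) - 1L))
      adj[[ks[i]]] <- c(adj[[ks[i]]], ks[i + 1L])
  }
  adj
}

resolve_conflicts <- function(seqs, w, lg, max_exact_markers = 12L) {
  conflicts <- list()
  repeat {
    edges <- do.call(rbind, lapply(names(seqs), function(m) {
      s <- seqs[[m]]
      if (nrow(s) < 2) return(NULL)
      data.frame(from = s$key[-nrow(s)], to = s$key[-1],
                 stringsAsFactors = FALSE)
    }))
    keys <- unique(unlist(lapply(seqs, `[[`, "key")))
    if (is.null(edges) || !nrow(edges)) break
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = keys))
    comp <- igraph::components(g, mode = "strong")
    sizes <- tabulate(comp$membership)
    bad <- which(sizes > 1)
    if (!length(bad)) break
    # deterministic: resolve the SCC containing the smallest key first
    scc_keys_all <- lapply(bad, function(b)
      sort(names(comp$membership)[comp$membership == b]))
    scc_keys <- scc_keys_all[[order(vapply(scc_keys_all, `[`, character(1), 1))[1]]]

    cand <- do.call(rbind, lapply(names(seqs), function(m) {
      hit <- seqs[[m]]$key[seqs[[m]]$key %in% scc_keys]
      if (!length(hit)) return(NULL)
      data.frame(map = m, key = hit, weight = w[[m]],
                 stringsAsFactors = FALSE)
    }))
    cand <- cand[order(cand$weight, cand$map, cand$key), ]
    rownames(cand) <- NULL

    apply_del <- function(ss, rows) {
      for (r in rows) {
        m <- cand$map[r]; k <- cand$key[r]
        ss[[m]] <- ss[[m]][ss[[m]]$key != k, , drop = FALSE]
      }
      ss
    }
    breaks_cycle <- function(rows) {
      ss <- apply_del(seqs, rows)
      !has_cycle(seq_adjacency(ss, scc_keys), scc_keys)
    }

    chosen <- NULL; method <- "exact"
    if (length(scc_keys) <= max_exact_markers) {
      # all deletion sets up to size 3, tried in order of total weight
      subsets <- list(); tw <- numeric(0)
      for (size in 1:3) {
        if (nrow(cand) < size) break
        subs <- utils::combn(nrow(cand), size)
        subsets <- c(subsets, asplit(subs, 2))
        tw <- c(tw, colSums(matrix(cand$weight[subs], nrow = size)))
      }
      lex <- vapply(subsets, paste, character(1), collapse = ",")
      for (ci in order(tw, lengths(subsets), lex)) {
        rows <- subsets[[ci]]
        if (breaks_cycle(rows)) { chosen <- rows; break }
      }
    }
    if (is.null(chosen)) {
      method <- "greedy"
      rows <- integer(0)
      for (r in seq_len(nrow(cand))) {
        rows <- c(rows, r)
        if (breaks_cycle(rows)) { chosen <- rows; break }
      }
      if (is.null(chosen)) chosen <- seq_len(nrow(cand))
    }
    seqs <- apply_del(seqs, chosen)
    conflicts[[length(conflicts) + 1L]] <- data.frame(
      linkage_group = lg,
      scc_markers = paste(scc_keys, collapse = ";"),
      deleted = paste(sprintf("%s:%s", cand$map[chosen], cand$key[chosen]),
                      collapse = ";"),
      weight_deleted = sum(cand$weight[chosen]),
      method = method, stringsAsFactors = FALSE)
  }
  list(seqs = seqs, conflicts = do.call(rbind, conflicts))
}

# weighted pooled-adjacent-violators (non-decreasing fit)
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n <= 1) return(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1L] + 1e-12) {
      nv <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) / (wt[i] + wt[i + 1L])
      val[i] <- nv; wt[i] <- wt[i] + wt[i + 1L]
      idx[[i]] <- c(idx[[i]], idx[[i + 1L]])
      val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; idx <- idx[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  out <- numeric(n)
  for (b in seq_along(val)) out[idx[[b]]] <- val[b]
  out
}

# Kahn topological order, ties broken by weighted mean standardized input
# position, then key
topo_order <- function(seqs, w) {
  keys <- unique(unlist(lapply(seqs, `[[`, "key")))
  tb <- stats::setNames(rep(0, length(keys)), keys)
  tw <- stats::setNames(rep(0, length(keys)), keys)
  for (m in names(seqs)) {
    s <- seqs[[m]]
    if (!nrow(s)) next
    span <- max(s$pos) - min(s$pos)
    std <- if (span > 0) (s$pos - min(s$pos)) / span * 100 else rep(0, nrow(s))
    tb[s$key] <- tb[s$key] + w[[m]] * std
    tw[s$key] <- tw[s$key] + w[[m]]
  }
  tb <- ifelse(tw > 0, tb / tw, 0)
  indeg <- stats::setNames(rep(0L, length(keys)), keys)
  adj <- list()
  for (m in names(seqs)) {
    s <- seqs[[m]]
    if (nrow(s) < 2) next
    for (i in seq_len(nrow(s) - 1L)) {
      a <- s$key[i]; b <- s$key[i + 1L]
      adj[[a]] <- c(adj[[a]], b)
      indeg[b] <- indeg[b] + 1L
    }
  }
  out <- character(0)
  ready <- keys[indeg[keys] == 0L]
  while (length(ready)) {
    ready <- ready[order(tb[ready], ready)]
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    for (u in adj[[v]]) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) ready <- c(ready, u)
    }
  }
  if (length(out) != length(keys))
    stop_fmt("internal: order graph still cyclic after conflict resolution")
  out
}

# monotone weighted least squares for consensus positions
consensus_positions <- function(seqs, w, order_keys) {
  p <- length(order_keys)
  rows <- list()
  for (m in names(seqs)) {
    s <- seqs[[m]]
    if (nrow(s) < 2) next
    for (i in seq_len(nrow(s) - 1L))
      rows[[length(rows) + 1L]] <- list(a = s$key[i], b = s$key[i + 1L],
                                        d = s$pos[i + 1L] - s$pos[i],
                                        w = w[[m]])
  }
  x <- stats::setNames(rep(NA_real_, p), order_keys)
  if (!length(rows)) return(stats::setNames(rep(0, p), order_keys))
  # connected components of the undirected constraint graph
  # (simple repeated relabel; p is small)
  lab <- stats::setNames(seq_len(p), order_keys)
  for (r in rows) {
    la <- lab[[r$a]]; lb <- lab[[r$b]]
    if (la != lb) lab[lab == lb] <- la
  }
  offset <- 0
  for (cl in unique(lab[order_keys])) {
    ck <- order_keys[lab[order_keys] == cl]
    crows <- Filter(function(r) r$a %in% ck, rows)
    if (length(ck) == 1 || !length(crows)) { x[ck] <- offset; next }
    pin <- ck[1]
    free <- setdiff(ck, pin)
    A <- matrix(0, length(crows), length(free),
                dimnames = list(NULL, free))
    rhs <- numeric(length(crows)); wts <- numeric(length(crows))
    for (i in seq_along(crows)) {
      r <- crows[[i]]
      if (r$b != pin) A[i, r$b] <- 1
      if (r$a != pin) A[i, r$a] <- -1
      rhs[i] <- r$d; wts[i] <- r$w
    }
    AtW <- t(A * wts)
    sol <- tryCatch(solve(AtW %*% A, AtW %*% rhs),
                    error = function(e) qr.coef(qr(A * sqrt(wts)),
                                                rhs * sqrt(wts)))
    xi <- stats::setNames(rep(0, length(ck)), ck)
    xi[free] <- as.numeric(sol)[match(free, colnames(A))]
    xi[is.na(xi)] <- 0
    x[ck] <- xi + offset - min(xi)
    offset <- max(x[ck]) + 1  # disconnected blocks stacked with 1 cM gap
  }
  # isotonic repair in consensus order, then anchor at 0
  xv <- x[order_keys]
  if (any(diff(xv) < -1e-9)) xv <- pava(xv)
  xv <- xv - xv[1]
  stats::setNames(xv, order_keys)
}

#' Merge weighted input maps into a consensus map
#'
#' Per linkage group, marker orders from all input maps are combined into a
#' directed order graph (markers reduced to gene-level merge keys, one edge
#' per adjacent pair per map, edge weight = map weight).  Order conflicts
#' (cycles) are resolved by deleting the set of marker occurrences of
#' minimum total weight that breaks them -- exact search when the strongly
#' connected component spans at most `max_exact_markers` markers, greedy
#' lowest-weight-occurrence deletion otherwise (the method used is recorded
#' per conflict).  The conflict-free graph is topologically ordered and
#' consensus positions minimize
#' \eqn{\sum_l w_l \sum_{(a,b)} (x_b - x_a - d_{ab}^{(l)})^2}
#' over adjacent pairs within each map, subject to monotonicity in consensus
#' order (unconstrained weighted least squares followed by
#' pooled-adjacent-violators repair), anchored at 0.  Keys matched across
#' different linkage groups are assigned to their maximum-weight linkage
#' group and reported.  A linkage group present in a single map passes
#' through unchanged.
#'
#' @param input_maps Named list of [input_map()] objects.
#' @param weights Either a data frame from [map_weights()] or a named
#'   numeric vector of weights; names must match `names(input_maps)`.
#' @param max_exact_markers Largest strongly connected component resolved by
#'   exact minimum-weight search (default 12).
#' @return An object of class `consensus_map`: list with `map` (data frame
#'   `linkage_group`, `marker`, `position_cM`, one logical `in_<map>`
#'   presence column per input), `conflicts`, `cross_lg`, `weights`,
#'   `dropped` (markers whose every occurrence was deleted).
#' @examples
#' m1 <- input_map(data.frame(map_id = "A", linkage_group = 1,
#'   marker_id = c("x-1", "y-1", "z-1"), gene_id = c("x", "y", "z"),
#'   marker_type = "SNP", position_cM = c(0, 10, 20)))
#' m2 <- input_map(data.frame(map_id = "B", linkage_group = 1,
#'   marker_id = c("x-2", "y-2", "z-2"), gene_id = c("x", "y", "z"),
#'   marker_type = "SNP", position_cM = c(0, 20, 40)))
#' cm <- merge_maps(list(A = m1, B = m2), c(A = 0.5, B = 0.5))
#' cm$map
#' @export
merge_maps <- function(input_maps, weights, max_exact_markers = 12L) {
  stopifnot(is.list(input_maps), length(input_maps) >= 1,
            !is.null(names(input_maps)))
  w <- if (is.data.frame(weights))
    stats::setNames(weights$weight, weights$map_id)
  else stats::setNames(as.numeric(weights), names(weights))
  if (!all(names(input_maps) %in% names(w)))
    stop_fmt("weights missing for map(s): %s",
             paste(setdiff(names(input_maps), names(w)), collapse = ", "))
  w <- w[names(input_maps)]
  w <- w / sum(w)

  prep <- prepare_sequences(input_maps, w)
  occ <- prep$occ
  all_conflicts <- list(); out_rows <- list(); dropped <- character(0)
  for (lg in sort(unique(occ$lg))) {
    sub <- occ[occ$lg == lg, ]
    seqs <- lapply(split(sub, sub$map), function(s)
      s[order(s$pos, s$key), c("key", "pos")])
    seqs <- seqs[vapply(seqs, nrow, integer(1)) > 0]
    keys_before <- unique(sub$key)
    if (length(seqs) == 1L) {
      s <- seqs[[1]]
      pos <- s$pos - min(s$pos)
      res_keys <- s$key; res_pos <- pos; confl <- NULL
      message(sprintf("LG %d present in a single map (%s): passed through",
                      lg, names(seqs)))
    } else {
      rc <- resolve_conflicts(seqs, w, lg, max_exact_markers)
      seqs <- rc$seqs; confl <- rc$conflicts
      res_keys <- topo_order(seqs, w)
      res_pos <- consensus_positions(seqs, w, res_keys)
    }
    dropped <- c(dropped, setdiff(keys_before, res_keys))
    pres <- vapply(names(input_maps), function(m) {
      s <- seqs[[m]]
      if (is.null(s)) rep(FALSE, length(res_keys))
      else res_keys %in% s$key
    }, logical(length(res_keys)))
    if (length(res_keys) == 1L) pres <- matrix(pres, nrow = 1,
      dimnames = list(NULL, names(input_maps)))
    df <- data.frame(linkage_group = lg, marker = res_keys,
                     position_cM = as.numeric(res_pos),
                     stringsAsFactors = FALSE)
    colnames(pres) <- paste0("in_", names(input_maps))
    out_rows[[as.character(lg)]] <- cbind(df, as.data.frame(pres))
    if (!is.null(confl)) all_conflicts[[as.character(lg)]] <- confl
  }
  map <- do.call(rbind, out_rows)
  rownames(map) <- NULL
  structure(list(map = map,
                 conflicts = do.call(rbind, all_conflicts) %||%
                   data.frame(linkage_group = integer(0),
                              scc_markers = character(0),
                              deleted = character(0),
                              weight_deleted = numeric(0),
                              method = character(0)),
                 cross_lg = prep$cross_lg,
                 weights = w, dropped = unique(dropped),
                 n_input_maps = length(input_maps)),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("consensus_map: %d markers on %d linkage groups (from %d input maps)\n",
              nrow(x$map), length(unique(x$map$linkage_group)),
              x$n_input_maps))
  cat(sprintf("total length: %.2f cM; order conflicts resolved: %d; markers dropped: %d\n",
              sum(tapply(x$map$position_cM, x$map$linkage_group, max)),
              nrow(x$conflicts), length(x$dropped)))
  invisible(x)
}

#' Per-linkage-group summary of a map
#'
#' For each linkage group: marker count, length (last minus first
#' position), average adjacent spacing `length / (N - 1)`, maximum adjacent
#' spacing, and mean position-CI half-width when available; plus a `Total`
#' row (sums) and an `Average` row (across-LG means).
#'
#' @param map A `consensus_map`, an [input_map()], or a data frame with
#'   columns `linkage_group` and `position_cM` (optionally `ci_half`).
#' @return Data frame with rows per LG plus `Total` and `Average`.
#' @export
map_summary <- function(map) {
  df <- if (inherits(map, "consensus_map")) map$map else as.data.frame(map)
  if (!"position_cM" %in% names(df))
    stop_fmt("map_summary needs a position_cM column")
  lgs <- sort(unique(df$linkage_group))
  rows <- lapply(lgs, function(lg) {
    pos <- sort(df$position_cM[df$linkage_group == lg])
    n <- length(pos)
    len <- if (n) max(pos) - min(pos) else NA_real_
    data.frame(lg = as.character(lg), n_markers = n, length_cM = len,
               avg_spacing_cM = if (n > 1) len / (n - 1) else NA_real_,
               max_spacing_cM = if (n > 1) max(diff(pos)) else NA_real_,
               mean_ci_cM = if ("ci_half" %in% names(df))
                 mean(df$ci_half[df$linkage_group == lg], na.rm = TRUE)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_lg <- do.call(rbind, rows)
  total <- data.frame(lg = "Total", n_markers = sum(per_lg$n_markers),
                      length_cM = sum(per_lg$length_cM),
                      avg_spacing_cM = NA_real_, max_spacing_cM = NA_real_,
                      mean_ci_cM = NA_real_)
  avg <- data.frame(lg = "Average",
                    n_markers = mean(per_lg$n_markers),
                    length_cM = mean(per_lg$length_cM),
                    avg_spacing_cM = mean(per_lg$avg_spacing_cM, na.rm = TRUE),
                    max_spacing_cM = mean(per_lg$max_spacing_cM, na.rm = TRUE),
                    mean_ci_cM = mean(per_lg$mean_ci_cM, na.rm = TRUE))
  out <- rbind(per_lg, total, avg)
  rownames(out) <- NULL
  out
}

#' Map summary from printed marker counts and lengths
#'
#' Computes the same average-spacing and across-LG summary statistics as
#' [map_summary()] directly from per-LG marker counts and lengths (the form
#' in which published map summaries are reported).
#'
#' @param n_markers Integer vector of per-LG marker counts.
#' @param length_cM Numeric vector of per-LG lengths.
#' @param lg Optional LG labels.
#' @return Data frame with per-LG `avg_spacing_cM` plus `Total`/`Average`
#'   rows.
#' @export
map_summary_from_counts <- function(n_markers, length_cM,
                                    lg = seq_along(n_markers)) {
  stopifnot(length(n_markers) == length(length_cM))
  per_lg <- data.frame(lg = as.character(lg), n_markers = n_markers,
                       length_cM = length_cM,
                       avg_spacing_cM = length_cM / (n_markers - 1),
                       stringsAsFactors = FALSE)
  rbind(per_lg,
        data.frame(lg = "Total", n_markers = sum(n_markers),
                   length_cM = sum(length_cM), avg_spacing_cM = NA_real_),
        data.frame(lg = "Average", n_markers = mean(n_markers),
                   length_cM = mean(length_cM),
                   avg_spacing_cM = mean(per_lg$avg_spacing_cM)))
}

#' @export
summary.consensus_map <- function(object, ...) {
  s <- map_summary(object)
  class(s) <- c("summary.consensus_map", "data.frame")
  s
}

#' @export
print.summary.consensus_map <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.consensus_map <- function(x, input_maps = NULL, lg = NULL, ...) {
  df <- x$map
  if (is.null(lg)) lg <- df$linkage_group[1]
  sub <- df[df$linkage_group == lg, ]
  if (is.null(input_maps)) {
    graphics::plot(sub$position_cM, seq_len(nrow(sub)), type = "s",
                   xlab = "consensus position (cM)", ylab = "marker rank",
                   main = sprintf("LG %s", lg), ...)
    return(invisible(x))
  }
  cols <- grDevices::hcl.colors(length(input_maps), "Dark 3")
  graphics::plot(NA, xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "input position (standardized)",
                 ylab = "consensus position (standardized)",
                 main = sprintf("LG %s collinearity", lg), ...)
  std <- function(p) if (max(p) > min(p))
    (p - min(p)) / (max(p) - min(p)) * 100 else rep(0, length(p))
  cs <- std(sub$position_cM)
  for (i in seq_along(input_maps)) {
    im <- input_maps[[i]]
    iml <- im[im$linkage_group == lg, ]
    key <- normalize_marker_name(iml$marker_id)
    hit <- match(key, sub$marker)
    ok <- !is.na(hit)
    if (!any(ok)) next
    graphics::points(std(iml$position_cM)[ok], cs[hit[ok]], col = cols[i],
                     pch = i)
  }
  graphics::legend("bottomright", legend = names(input_maps),
                   col = cols, pch = seq_along(input_maps), bty = "n")
  invisible(x)
}

#' Replicate-based position confidence intervals
#'
#' The merge itself is deterministic, so position uncertainty is profiled by
#' perturbing every input-map inter-marker distance with multiplicative
#' log-normal noise (sdlog = `noise_sd`), re-merging, and taking 2.5/97.5
#' percentiles of each marker's consensus position across replicates.
#' Markers absent from any replicate's consensus (deleted by conflict
#' resolution) are flagged and get `NA` intervals.
#'
#' @param input_maps Named list of [input_map()] objects.
#' @param weights As in [merge_maps()].
#' @param n_reps Number of replicates (default 100).
#' @param noise_sd Log-scale sd of the multiplicative distance noise.
#' @param seed Integer seed.
#' @return List with `ci` (per-marker `linkage_group`, `marker`, `ci_lo`,
#'   `ci_hi`, `ci_half`, `n_present`), `per_lg` mean half-widths, and
#'   `genome_mean_ci`.
#' @export
position_uncertainty <- function(input_maps, weights, n_reps = 100,
                                 noise_sd = 0.1, seed = 1) {
  stopifnot(n_reps >= 2)
  base <- merge_maps(input_maps, weights)
  key0 <- paste(base$map$linkage_group, base$map$marker)
  acc <- matrix(NA_real_, nrow(base$map), n_reps)
  with_seed(seed, for (r in seq_len(n_reps)) {
    pert <- lapply(input_maps, function(im) {
      df <- as.data.frame(im)
      for (lg in unique(df$linkage_group)) {
        i <- which(df$linkage_group == lg)
        i <- i[order(df$position_cM[i])]
        if (length(i) < 2) next
        d <- diff(df$position_cM[i])
        d <- d * stats::rlnorm(length(d), 0, noise_sd)
        df$position_cM[i] <- c(df$position_cM[i][1],
                               df$position_cM[i][1] + cumsum(d))
      }
      input_map(df)
    })
    cm <- suppressMessages(merge_maps(pert, weights))
    hit <- match(key0, paste(cm$map$linkage_group, cm$map$marker))
    acc[, r] <- cm$map$position_cM[hit]
  })
  n_present <- rowSums(!is.na(acc))
  full <- n_present == n_reps
  lo <- hi <- rep(NA_real_, nrow(acc))
  lo[full] <- apply(acc[full, , drop = FALSE], 1, stats::quantile,
                    probs = 0.025)
  hi[full] <- apply(acc[full, , drop = FALSE], 1, stats::quantile,
                    probs = 0.975)
  ci <- data.frame(linkage_group = base$map$linkage_group,
                   marker = base$map$marker, ci_lo = lo, ci_hi = hi,
                   ci_half = (hi - lo) / 2, n_present = n_present,
                   stringsAsFactors = FALSE)
  per_lg <- stats::aggregate(list(mean_ci_half = ci$ci_half),
                             by = list(linkage_group = ci$linkage_group),
                             FUN = mean, na.rm = TRUE)
  list(ci = ci, per_lg = per_lg,
       genome_mean_ci = mean(ci$ci_half, na.rm = TRUE))
}

#' Root mean squared error in marker order between two maps
#'
#' Shared markers' positions on each linkage group are standardized to a
#' 0-100 scale (using each map's full LG span) and the RMSE of the
#' standardized position differences is reported per LG; raw-cM RMSE is
#' also emitted.
#'
#' @param consensus A `consensus_map` (or data frame with `marker`,
#'   `linkage_group`, `position_cM`).
#' @param input_map An [input_map()].
#' @return Data frame per LG: `n_shared`, `rmse_standardized`, `rmse_cM`.
#'   LGs with fewer than 2 shared markers are skipped.
#' @export
rmse_order_agreement <- function(consensus, input_map) {
  cdf <- if (inherits(consensus, "consensus_map")) consensus$map
    else as.data.frame(consensus)
  idf <- data.frame(key = normalize_marker_name(input_map$marker_id),
                    lg = input_map$linkage_group,
                    pos = input_map$position_cM, stringsAsFactors = FALSE)
  out <- list()
  for (lg in sort(intersect(cdf$linkage_group, idf$lg))) {
    cs <- cdf[cdf$linkage_group == lg, ]
    is <- idf[idf$lg == lg, ]
    hit <- match(is$key, cs$marker)
    ok <- !is.na(hit)
    if (sum(ok) < 2) next
    std <- function(p, all) if (max(all) > min(all))
      (p - min(all)) / (max(all) - min(all)) * 100 else rep(0, length(p))
    d_std <- std(cs$position_cM[hit[ok]], cs$position_cM) -
      std(is$pos[ok], is$pos)
    d_raw <- cs$position_cM[hit[ok]] - is$pos[ok]
    out[[as.character(lg)]] <- data.frame(
      linkage_group = lg, n_shared = sum(ok),
      rmse_standardized = sqrt(mean(d_std^2)),
      rmse_cM = sqrt(mean(d_raw^2)))
  }
  res <- do.call(rbind, out) %||%
    data.frame(linkage_group = integer(0), n_shared = integer(0),
               rmse_standardized = numeric(0), rmse_cM = numeric(0))
  rownames(res) <- NULL
  res
}
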