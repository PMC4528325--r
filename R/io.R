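# Readers and writers for the TSV interchange formats.  All downstream
# modules operate on the validated in-memory types constructed here:
# `input_map`, `genotype_matrix`, `pedigree`, and plain matrices for kinship
# (V) and admixture (Q) inputs.  Files are tab-delimited UTF-8 with a
# mandatory header row; the missing-data sentinel is the literal "NA".

MARKER_TYPES <- c("SNP", "SSR", "RFLP", "ESTP", "PAV", "EST-SSR")
MAP_COLUMNS  <- c("map_id", "linkage_group", "marker_id", "gene_id",
                  "marker_type", "position_cM")

#' Construct a validated input linkage map
#'
#' An input map is an ordered set of (marker, linkage group, cM position)
#' records from one mapping population, optionally carrying per-cohort
#' genotype-class counts (columns named `count_<cohort>_<class>`) used for
#' genotype information content.  Linkage groups are identified by integers
#' 1-12 following the historical orientation convention; the constructor
#' never renumbers them.
#'
#' @param df A data frame with columns `map_id`, `linkage_group`,
#'   `marker_id`, `gene_id`, `marker_type`, `position_cM` and optional count
#'   columns.
#' @return A data frame of class `input_map`, sorted by linkage group and
#'   position.
#' @export
input_map <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MAP_COLUMNS, names(df))
  if (length(missing_cols))
    stop_fmt("map is missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  df$linkage_group <- as.integer(df$linkage_group)
  df$position_cM <- as.numeric(df$position_cM)
  bad <- which(is.na(df$linkage_group) | df$linkage_group < 1L |
                 df$linkage_group > 12L)
  if (length(bad))
    stop_fmt("linkage_group must be an integer in 1..12 (row %d)", bad[1])
  bad <- which(is.na(df$position_cM) | df$position_cM < 0)
  if (length(bad))
    stop_fmt("position_cM must be a number >= 0 (row %d, marker %s)",
             bad[1], df$marker_id[bad[1]])
  bad <- which(!df$marker_type %in% MARKER_TYPES)
  if (length(bad))
    stop_fmt("unknown marker_type '%s' (row %d); expected one of %s",
             df$marker_type[bad[1]], bad[1],
             paste(MARKER_TYPES, collapse = ", "))
  for (m in unique(df$map_id)) {
    ids <- df$marker_id[df$map_id == m]
    dup <- ids[duplicated(ids)]
    if (length(dup))
      stop_fmt("duplicate marker_id '%s' within map '%s'", dup[1], m)
  }
  cnt <- grep("^count_", names(df), value = TRUE)
  for (cc in cnt) {
    df[[cc]] <- as.integer(df[[cc]])
    if (any(df[[cc]] < 0, na.rm = TRUE))
      stop_fmt("negative genotype-class count in column %s", cc)
  }
  df <- df[order(df$map_id, df$linkage_group, df$position_cM, df$marker_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("input_map", "data.frame")
  df
}

#' Read or write an input linkage map TSV
#'
#' @param path Path to a tab-delimited file with the `input_map` columns.
#' @param map An `input_map` object.
#' @return `read_map` returns a validated [input_map()]; `write_map` returns
#'   `path` invisibly.  `write_map(read_map(f))` is byte-identical for files
#'   in canonical form (sorted, 6-significant-digit positions).
#' @export
read_map <- function(path) {
  df <- read_tsv(path)
  tryCatch(input_map(df), error = function(e) {
    stop_fmt("%s: %s", path, conditionMessage(e))
  })
}

#' @rdname read_map
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "input_map"))
  write_tsv(as.data.frame(map), path)
}

# ---------------------------------------------------------------------------

# legal codes include the off-type calls (mm, pp) that genotyping error can
# produce; Mendelian expectations use MENDELIAN_CLASSES only
CP_CODES <- list(hkxhk = c("hh", "hk", "kk"),
                 lmxll = c("ll", "lm", "mm"),
                 nnxnp = c("nn", "np", "pp"))
MENDELIAN_CLASSES <- list(hkxhk = c("hh", "hk", "kk"),
                          lmxll = c("ll", "lm"),
                          nnxnp = c("nn", "np"),
                          dosage = c("0", "1", "2"),
                          haploid = c("0", "1"),
                          testcross = c("0", "1"))

legal_codes <- function(segregation_type) {
  switch(segregation_type,
         dosage  = c("0", "1", "2"),
         haploid = c("0", "1"),
         testcross = c("0", "1"),
         CP_CODES[[segregation_type]] %||%
           stop_fmt("unknown segregation type '%s'", segregation_type))
}

#' Construct a validated genotype matrix
#'
#' Genotype calls for a set of individuals at a set of loci.  Three coding
#' dialects are supported: diploid allele dosage (0/1/2), haploid gametic
#' calls (0/1, e.g. megagametophytes), and outcrossing CP codes
#' (hh/hk/kk for loci heterozygous in both parents, ll/lm and nn/np for
#' testcross loci heterozygous in one parent).
#'
#' @param calls Character (or numeric, for dosage/haploid) matrix,
#'   individuals in rows, loci in columns; `NA` marks missing calls.
#' @param loci Data frame with columns `marker_id`, `gene_id`,
#'   `segregation_type`; one row per column of `calls`.  If `NULL`, locus
#'   metadata is derived from column names and `dialect`.
#' @param dialect One of `"dosage"`, `"haploid"`, `"CP"`; used to infer
#'   per-locus segregation types when `loci` is `NULL`.
#' @return A list of class `genotype_matrix` with elements `calls`
#'   (character matrix), `loci`, and `individuals`.
#' @export
genotype_matrix <- function(calls, loci = NULL,
                            dialect = c("dosage", "haploid", "CP")) {
  dialect <- match.arg(dialect)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(colnames(calls)) && ncol(calls) > 0)
    colnames(calls) <- paste0("m", seq_len(ncol(calls)))
  if (is.null(loci)) {
    seg <- switch(dialect, dosage = "dosage", haploid = "haploid", CP = NA)
    if (dialect == "CP") {
      seg <- vapply(seq_len(ncol(calls)), function(j) {
        obs <- unique(stats::na.omit(calls[, j]))
        hit <- names(CP_CODES)[vapply(CP_CODES, function(cl)
          all(obs %in% cl), logical(1))]
        if (!length(hit))
          stop_fmt("locus %s: calls %s match no CP segregation type",
                   colnames(calls)[j], paste(obs, collapse = ","))
        hit[1]
      }, character(1))
    }
    loci <- data.frame(marker_id = colnames(calls),
                       gene_id = normalize_marker_name(colnames(calls)),
                       segregation_type = seg,
                       stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (nrow(loci) != ncol(calls))
    stop_fmt("loci table has %d rows but calls has %d columns",
             nrow(loci), ncol(calls))
  for (j in seq_len(ncol(calls))) {
    legal <- legal_codes(loci$segregation_type[j])
    bad <- which(!is.na(calls[, j]) & !calls[, j] %in% legal)
    if (length(bad))
      stop_fmt("illegal code '%s' for %s locus %s (individual %s)",
               calls[bad[1], j], loci$segregation_type[j],
               loci$marker_id[j], rownames(calls)[bad[1]])
  }
  structure(list(calls = calls, loci = loci,
                 individuals = rownames(calls)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%s)\n",
              nrow(x$calls), ncol(x$calls),
              paste(unique(x$loci$segregation_type), collapse = "/")))
  cat(sprintf("missing calls: %.1f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read or write a genotype matrix TSV
#'
#' Rows are individuals (first column `id`), remaining columns are loci
#' named by marker id; missing calls are `NA`.
#'
#' @param path File path.
#' @param dialect Coding dialect, see [genotype_matrix()].
#' @param gm A `genotype_matrix`.
#' @return `read_genotypes` returns a validated [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("dosage", "haploid", "CP")) {
  dialect <- match.arg(dialect)
  df <- read_tsv(path, colClasses = "character")
  if (names(df)[1] != "id")
    stop_fmt("%s: first column must be 'id'", path)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$id
  tryCatch(genotype_matrix(calls, dialect = dialect),
           error = function(e) stop_fmt("%s: %s", path, conditionMessage(e)))
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.frame(id = gm$individuals, gm$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Extract numeric dosages from a genotype matrix
#'
#' Diploid dosage loci map to 0/1/2 and haploid loci to 0/1; CP codes map to
#' counts of the second parental allele (hh=0, hk=1, kk=2; ll=0, lm=1;
#' nn=0, np=1).
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric matrix, `NA` where calls are missing.
#' @export
dosage <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  lut <- c("0" = 0, "1" = 1, "2" = 2, hh = 0, hk = 1, kk = 2,
           ll = 0, lm = 1, nn = 0, np = 1)
  out <- matrix(lut[gm$calls], nrow = nrow(gm$calls),
                dimnames = dimnames(gm$calls))
  out
}

# ---------------------------------------------------------------------------

#' Construct a validated pedigree
#'
#' @param df Data frame with columns `id`, `sire`, `dam`, `cohort`; founders
#'   have `NA` parents.  Every named parent must itself be a row.  The
#'   pedigree must be acyclic.
#' @return A data frame of class `pedigree`, topologically sorted so parents
#'   precede offspring.
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam", "cohort")
  if (!all(need %in% names(df)))
    stop_fmt("pedigree requires columns %s", paste(need, collapse = ", "))
  df$id <- as.character(df$id); df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam); df$cohort <- as.character(df$cohort)
  if (anyDuplicated(df$id))
    stop_fmt("duplicate individual id '%s'", df$id[duplicated(df$id)][1])
  parents <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(parents))
    stop_fmt("parent '%s' has no pedigree row", parents[1])
  # Kahn topological sort doubles as the acyclicity check
  order <- character(0)
  placed <- character(0)
  remaining <- df
  while (nrow(remaining)) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% placed) &
      (is.na(remaining$dam) | remaining$dam %in% placed)
    if (!any(ready)) {
      self <- remaining$id[remaining$id == remaining$sire |
                             remaining$id == remaining$dam]
      culprit <- if (length(self)) self[1] else remaining$id[1]
      stop_fmt("pedigree cycle involving individual '%s'", culprit)
    }
    placed <- c(placed, remaining$id[ready])
    order <- c(order, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  df <- df[match(order, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read or write a pedigree TSV
#'
#' @param path File path (columns `id`, `sire`, `dam`, `cohort`).
#' @param ped A `pedigree`.
#' @return `read_pedigree` returns a validated [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  tryCatch(pedigree(df),
           error = function(e) stop_fmt("%s: %s", path, conditionMessage(e)))
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  write_tsv(as.data.frame(ped), path)
}

#' Read a square matrix TSV (kinship / relationship input)
#'
#' The file carries a header of ids and an `id` first column; row and column
#' ids must match.  Kinship matrices must be symmetric.
#'
#' @param path File path.
#' @param symmetric Require symmetry (default `TRUE`; use `FALSE` for
#'   non-kinship square inputs).
#' @return Numeric matrix with dimnames.
#' @export
read_square_matrix <- function(path, symmetric = TRUE) {
  df <- read_tsv(path)
  if (names(df)[1] != "id") stop_fmt("%s: first column must be 'id'", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop_fmt("%s: matrix is %dx%d, not square", path, nrow(m), ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop_fmt("%s: row ids do not match column ids", path)
  if (symmetric && max(abs(m - t(m))) > 1e-8)
    stop_fmt("%s: kinship matrix is not symmetric", path)
  m
}

#' @rdname read_square_matrix
#' @param m Square numeric matrix with dimnames.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' Read an admixture (Q) matrix TSV
#'
#' Rows are individuals (`id` column), remaining columns are subpopulation
#' membership proportions; each row must sum to 1 within 1e-6 and entries
#' must lie in [0, 1].
#'
#' @param path File path.
#' @return Numeric matrix, individuals x K.
#' @export
read_structure_matrix <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "id") stop_fmt("%s: first column must be 'id'", path)
  q <- as.matrix(df[, -1, drop = FALSE])
  rownames(q) <- df$id
  storage.mode(q) <- "double"
  if (any(q < -1e-9 | q > 1 + 1e-9))
    stop_fmt("%s: admixture proportions outside [0, 1]", path)
  if (any(abs(rowSums(q) - 1) > 1e-6))
    stop_fmt("%s: admixture rows must sum to 1", path)
  q
}

#' Validate every recognized input file in a directory
#'
#' Runs the appropriate reader on each TSV whose name identifies its role
#' (`*map*.tsv`, `genotypes_*.tsv`, `pedigree.tsv`, `kinship.tsv`,
#' `q*.tsv`) and collects validation failures.
#'
#' @param dir Directory of input files.
#' @return Data frame with columns `file`, `error` (`NA` when the file is
#'   valid).
#' @export
validate_inputs <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  res <- lapply(files, function(f) {
    base <- basename(f)
    reader <- if (grepl("pedigree", base)) read_pedigree
      else if (grepl("kinship", base)) read_square_matrix
      else if (grepl("^q", base)) read_structure_matrix
      else if (grepl("genotypes_hap", base))
        function(p) read_genotypes(p, "haploid")
      else if (grepl("genotypes", base)) read_genotypes
      else if (grepl("map", base)) read_map
      else NULL
    if (is.null(reader))
      return(data.frame(file = base, error = "unrecognized file role"))
    err <- tryCatch({ reader(f); NA_character_ },
                    error = function(e) conditionMessage(e))
    data.frame(file = base, error = err, stringsAsFactors = FALSE)
  })
  do.call(rbind, res) %||% data.frame(file = character(0),
                                      error = character(0))
}
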