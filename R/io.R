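# Tab-separated on-disk formats: inspectable, diff-able, round-trip exact.

#' Read / write an ancestry dosage matrix
#'
#' On disk: tab-separated, first column `ril`, remaining columns window ids,
#' cells in \{0, 1, 2, NA\}. Reading validates every cell and reports the
#' offending row and column on failure; write-then-read is the identity.
#'
#' @param path File path.
#' @return `read_ancestry_matrix`: integer dosage matrix with RIL rownames.
#' @export
read_ancestry_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(d)[1] != "ril") stop("first column must be 'ril'", call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  bad <- which(!(m %in% c("0", "1", "2", "NA", "")) & !is.na(m))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("invalid dosage '%s' at RIL %s, window %s",
                 m[bad[1]], d$ril[i], colnames(m)[j]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- d$ril
  m
}

#' @rdname read_ancestry_matrix
#' @param geno Dosage matrix (or `ril_panel`, whose matrix is written).
#' @export
write_ancestry_matrix <- function(geno, path) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  assert_dosage(geno)
  d <- data.frame(ril = rownames(geno), geno, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a window map
#'
#' Tab-separated with columns window_id, arm, start, end (bp, 0-based
#' half-open), cM, n_snps.
#'
#' @param path File path.
#' @return `read_window_map`: the map data.frame.
#' @export
read_window_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("window_id", "arm", "start", "end", "cM", "n_snps")
  if (!all(need %in% names(d))) {
    stop("window map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' @rdname read_window_map
#' @param map Window map data.frame.
#' @export
write_window_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a permutation null distribution
#'
#' Single column of statistics with `#` header comments recording the seed,
#' size, and statistic label.
#'
#' @param null A `null_dist`.
#' @param path File path.
#' @export
write_null_distribution <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label: %s", null$label),
               sprintf("# n_perm: %d", null$n_perm),
               sprintf("# seed: %s", format(null$seed %||% NA)),
               "stat"), con)
  writeLines(format(null$stat, digits = 17), con)
  invisible(path)
}

#' @rdname write_null_distribution
#' @export
read_null_distribution <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "", grep(key, hdr, value = TRUE)[1])
  stat <- as.numeric(lines[-c(seq_along(hdr), length(hdr) + 1L)])
  structure(list(stat = sort(stat),
                 n_perm = as.integer(get("n_perm")),
                 seed = suppressWarnings(as.integer(get("seed"))),
                 label = get("label")),
            class = "null_dist")
}

#' Empirical QTL catalog for the Ethiopia-Zambia and France-Zambia RIL panels
#'
#' The 14 QTLs mapped across pigmentation, wing length, ethanol resistance,
#' and courtship-song traits in the two Drosophila melanogaster RIL panels
#' this package models, with their LOD scores, per-allele trait
#' coefficients, heritabilities, genome-wide QTL P-values (10,000
#' permutations; 0 means more extreme than any permutation), and
#' genome-wide interaction P-values from the focal-QTL epistasis scans.
#' `overlap_group` marks QTLs for correlated traits whose intervals
#' overlap; only the top-LOD member of a group enters the meta-analysis.
#'
#' @return Data.frame with one row per QTL.
#' @export
example_qtl_catalog <- function() {
  utils::read.delim(system.file("extdata", "ef_fr_qtls.tsv",
                                package = "rilqtl"),
                    stringsAsFactors = FALSE)
}

#' Representative interaction P-values for meta-analysis
#'
#' Drops all but the highest-LOD QTL from each overlap group of the
#' [example_qtl_catalog()] (or any table with columns `qtl_id`, `lod`,
#' `p_epistasis`, `overlap_group`) and returns the remaining interaction
#' P-values, the input to [fisher_combined()].
#'
#' @param catalog A QTL catalog data.frame.
#' @return Named numeric vector of interaction P-values.
#' @export
meta_input_pvalues <- function(catalog = example_qtl_catalog()) {
  keep <- rep(TRUE, nrow(catalog))
  grouped <- !is.na(catalog$overlap_group) & catalog$overlap_group != ""
  for (g in unique(catalog$overlap_group[grouped])) {
    rows <- which(grouped & catalog$overlap_group == g)
    keep[rows] <- FALSE
    keep[rows[which.max(catalog$lod[rows])]] <- TRUE
  }
  stats::setNames(catalog$p_epistasis[keep], catalog$qtl_id[keep])
}

#' Run the full pipeline on a panel and phenotype
#'
#' Executes scan -> permutation null -> peak calling -> per-QTL epistasis
#' scan and null -> meta-analysis, writing every stage's table under
#' `out_dir` together with a JSON manifest (package version, seeds, input
#' checksums, stage timings) sufficient to reproduce the run.
#'
#' @param geno Dosage matrix or `ril_panel`, or a path readable by
#'   [read_ancestry_matrix()].
#' @param map Window map (or path); defaults to the panel's map.
#' @param phenotype Named phenotype vector, or a two-column tab-separated
#'   file path (ril, value).
#' @param out_dir Output directory (created if needed).
#' @param n_perm Permutations for both the additive and interaction nulls.
#' @param alpha,lod_drop,min_sep_cM,skew_threshold Scan and peak-calling
#'   settings.
#' @param seed Root seed; stage seeds are derived from it.
#' @return The manifest (invisibly), a list also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(geno, phenotype, map = NULL, out_dir,
                         n_perm = 1000L, alpha = 0.10, lod_drop = 1.5,
                         min_sep_cM = 10, skew_threshold = 0.9, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  checksums <- list()
  if (is.character(geno)) {
    checksums$geno <- unname(tools::md5sum(geno))
    geno <- read_ancestry_matrix(geno)
  }
  if (is.character(map)) {
    checksums$map <- unname(tools::md5sum(map))
    map <- read_window_map(map)
  }
  if (inherits(geno, "ril_panel")) {
    if (is.null(map)) map <- geno$map
    geno <- geno$geno
  }
  if (is.character(phenotype)) {
    checksums$phenotype <- unname(tools::md5sum(phenotype))
    ph <- utils::read.delim(phenotype, stringsAsFactors = FALSE)
    phenotype <- stats::setNames(ph[[2]], ph[[1]])
  }
  if (is.null(map)) stop("a window map is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    out <- expr
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t1, 3)
    out
  }

  summ <- stage("window_summary", window_summary(geno, skew_threshold))
  scan <- stage("scan", scan_additive(geno, phenotype, summ, map))
  null <- stage("permutation_null",
                permutation_null(geno, phenotype, summ, n_perm,
                                 seed = derive_seed(seed, 1L)))
  scan <- genomewide_p(scan, null)
  qtls <- stage("peaks", call_qtl_peaks(scan, map, alpha, lod_drop, min_sep_cM))
  utils::write.table(scan, file.path(out_dir, "scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_null_distribution(null, file.path(out_dir, "null_additive.tsv"))
  utils::write.table(qtls, file.path(out_dir, "qtls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  epi <- stage("epistasis", {
    lapply(seq_len(nrow(qtls)), function(i) {
      isc <- interaction_scan(geno, phenotype, qtls[i, ], summ)
      inull <- interaction_null(geno, phenotype, qtls[i, ], summ, n_perm,
                                seed = derive_seed(seed, 100L + i))
      isc <- interaction_p(isc, inull)
      utils::write.table(
        data.frame(partner = names(isc$lod), lod = isc$lod,
                   degenerate = isc$degenerate, row.names = NULL),
        file.path(out_dir, sprintf("epistasis_%s.tsv", qtls$peak[i])),
        sep = "\t", quote = FALSE, row.names = FALSE)
      data.frame(focal = isc$focal, max_lod = isc$max_lod,
                 partner = isc$max_partner, p = isc$p,
                 stringsAsFactors = FALSE)
    })
  })
  epi_tab <- if (length(epi)) do.call(rbind, epi) else
    data.frame(focal = character(0), max_lod = numeric(0),
               partner = character(0), p = numeric(0))
  utils::write.table(epi_tab, file.path(out_dir, "epistasis_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  meta <- if (nrow(epi_tab)) {
    fisher_combined(epi_tab$p, n_perm = n_perm)
  } else NULL

  manifest <- list(
    package = "rilqtl",
    version = as.character(utils::packageVersion("rilqtl")),
    seed = seed,
    n_perm = n_perm,
    settings = list(alpha = alpha, lod_drop = lod_drop,
                    min_sep_cM = min_sep_cM, skew_threshold = skew_threshold),
    input_checksums = checksums,
    n_rils = nrow(geno), n_windows = ncol(geno),
    n_excluded_windows = sum(summ$skew_excluded),
    n_qtls = nrow(qtls),
    qtls = qtls$peak,
    epistasis = epi_tab,
    meta = meta,
    timings = timings,
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
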