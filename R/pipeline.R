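# End-to-end pipeline: read -> validate -> variance components ->
# repeatability -> BLUP matrix -> correlations -> pattern analysis, with
# plain-text artifacts and a hashed run manifest.

.write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  for (col in names(df)[num]) df[[col]] <- .fmt_double(df[[col]])
  lines <- c(paste(.csv_quote(names(df)), collapse = ","),
             do.call(paste, c(lapply(df, function(v) .csv_quote(as.character(v))),
                              sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Reads a long-format trait table, validates the design, fits variance
#' components for every trait (single-year and, when several years are
#' present, across-years), computes repeatabilities and least significant
#' differences, builds the BLUP accession x trait matrix under the requested
#' scope, computes the phenotypic correlation matrix (and trait-environment
#' correlations when site metadata is supplied), runs the pattern analysis,
#' and writes every result as full-precision CSV plus a JSON run manifest
#' with an MD5 hash of each artifact.  Outputs are deterministic functions
#' of the input file and arguments.
#'
#' @param input path to a trait CSV (see [read_trait_table()]), or a
#'   [trait_dataset()].
#' @param output_dir directory for artifacts (created if needed).
#' @param scope scope of the BLUP matrix and pattern analysis:
#'   `"across_years"` (default) or `"single_year"`.
#' @param year year filter for `scope = "single_year"`.
#' @param k number of cluster groups for the pattern analysis.
#' @param linkage clustering linkage (see [cluster_accessions()]).
#' @param alpha significance level for the least significant differences.
#' @param meta optional path to a site-metadata CSV
#'   ([read_site_metadata()]) for trait-environment correlations.
#' @param quiet suppress progress messages on stderr.
#' @return Invisibly, a list with the in-memory results (`design`,
#'   `varcomp`, `repeatability`, `blup`, `correlation`, `pattern`,
#'   `manifest`) and the paths of the written files.
#' @export
run_pipeline <- function(input, output_dir, scope = c("across_years",
                                                      "single_year"),
                         year = NULL, k = 3, linkage = "ward", alpha = 0.05,
                         meta = NULL, quiet = FALSE) {
  scope <- match.arg(scope)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  ds <- if (inherits(input, "trait_dataset")) input else read_trait_table(input)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    .write_csv_full(df, p)
    paths[[name]] <<- p
  }

  say("[validate] %d records", nrow(ds$records))
  design <- validate_design(ds)
  if (!design$balanced) {
    say("[validate] WARNING: unbalanced design (%d incomplete cells)",
        nrow(design$missing_cells))
  }

  say("[fit] %d traits, scope %s", length(ds$traits), scope)
  multi_year <- length(ds$years) > 1L
  vc_rows <- list()
  rep_rows <- list()
  fits <- list()
  for (tr in ds$traits) {
    for (yr in ds$years) {
      vc <- fit_single_year(ds, tr, yr)
      R <- repeatability(vc)
      L <- lsd(vc, alpha = alpha)
      vc_rows[[length(vc_rows) + 1L]] <- data.frame(
        trait = tr, model = "single_year", year = yr,
        sigma_g2 = vc$sigma_g2, se_g = vc$se_g,
        sigma_gy2 = NA_real_, se_gy = NA_real_,
        sigma_e2 = vc$sigma_e2, se_e = vc$se_e,
        lsd = L$lsd, truncated = vc$truncated, stringsAsFactors = FALSE)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        trait = tr, scope = "single_year", year = yr, R = R$value,
        nl = 1L, nr = vc$nr, stringsAsFactors = FALSE)
    }
    if (multi_year) {
      vc <- fit_across_years(ds, tr)
      fits[[tr]] <- vc
      R <- repeatability(vc)
      L <- lsd(vc, alpha = alpha)
      vc_rows[[length(vc_rows) + 1L]] <- data.frame(
        trait = tr, model = "across_years", year = NA_integer_,
        sigma_g2 = vc$sigma_g2, se_g = vc$se_g,
        sigma_gy2 = vc$sigma_gy2, se_gy = vc$se_gy,
        sigma_e2 = vc$sigma_e2, se_e = vc$se_e,
        lsd = L$lsd, truncated = length(vc$truncated_components) > 0,
        stringsAsFactors = FALSE)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        trait = tr, scope = "across_years", year = NA_integer_, R = R$value,
        nl = vc$nl, nr = vc$nr, stringsAsFactors = FALSE)
    }
  }
  emit(do.call(rbind, vc_rows), "varcomp.csv")
  emit(do.call(rbind, rep_rows), "repeatability.csv")

  say("[blup] building accession x trait matrix")
  bm <- build_blup_matrix(ds, scope = scope, year = year)
  blup_df <- data.frame(accession = bm$accessions,
                        as.data.frame(bm$values, check.names = FALSE),
                        check.names = FALSE, stringsAsFactors = FALSE)
  emit(blup_df, "blup.csv")

  # a trait whose genotypic variance was clamped at zero yields a constant
  # BLUP column (no accession discrimination); correlations over accessions
  # and standardized scores are undefined for it, so it is excluded from the
  # multi-trait stages (it stays in varcomp/repeatability/blup outputs)
  varying <- apply(bm$values, 2L, stats::sd) > 0
  dropped <- bm$traits[!varying]
  if (length(dropped)) {
    say("[blup] excluding constant BLUP column(s) from multi-trait stages: %s",
        paste(dropped, collapse = ", "))
  }
  bm_mv <- bm
  bm_mv$values <- bm$values[, varying, drop = FALSE]
  bm_mv$traits <- bm$traits[varying]
  bm_mv$grand_means <- bm$grand_means[varying]
  bm_mv$shrinkage <- bm$shrinkage[varying]

  say("[correlate] phenotypic correlations over %d accessions",
      length(bm$accessions))
  corr <- phenotypic_correlation(bm_mv)
  emit(as.data.frame(corr), "corr.csv")
  env <- NULL
  if (!is.null(meta)) {
    sm <- if (inherits(meta, "site_metadata")) meta else read_site_metadata(meta)
    env <- env_correlation(bm_mv, sm)
    emit(as.data.frame(env), "env_corr.csv")
  }

  say("[pattern] %s linkage, k = %d", linkage, k)
  pat <- pattern_analysis(bm_mv, k = k, linkage = linkage)
  emit(data.frame(accession = rownames(pat$scores),
                  as.data.frame(pat$scores), check.names = FALSE),
       "scores.csv")
  emit(data.frame(trait = rownames(pat$loadings),
                  as.data.frame(pat$loadings), check.names = FALSE),
       "loadings.csv")
  emit(data.frame(component = colnames(pat$scores), pct_var = pat$pct_var),
       "pctvar.csv")
  emit(data.frame(accession = names(pat$clusters), group = pat$clusters),
       "clusters.csv")
  emit(data.frame(group = rownames(pat$group_means),
                  size = pat$group_sizes,
                  as.data.frame(pat$group_means), check.names = FALSE),
       "groupmeans.csv")

  manifest <- list(
    package = "seedvar",
    version = as.character(utils::packageVersion("seedvar")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = list(scope = scope, year = year, k = k, linkage = linkage,
                  alpha = alpha),
    multitrait_traits_dropped = as.list(dropped),
    design = list(n_accessions = design$n_accessions, nl = design$nl,
                  nr = design$nr, balanced = design$balanced),
    outputs = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  paths[["manifest.json"]] <- manifest_path
  say("[done] %d artifacts in %s (%.2f s)", length(paths), output_dir,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(design = design, varcomp = do.call(rbind, vc_rows),
                 repeatability = do.call(rbind, rep_rows), blup = bm,
                 correlation = corr, env_correlation = env, pattern = pat,
                 manifest = manifest, paths = paths))
}
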