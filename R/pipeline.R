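## End-to-end orchestration: configuration, staged execution, reports.

#' Read a plain-text run configuration
#'
#' `key = value` lines with optional `[section]` headers (keys become
#' `section.key`); `#` starts a comment. Values are auto-converted to
#' numeric or logical where possible.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  section <- ""
  out <- list()
  for (ln in trimws(lines)) {
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop_ps("cannot parse config line: %s", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (is.finite(num)) val <- num
    else if (val %in% c("true", "TRUE", "false", "FALSE"))
      val <- as.logical(toupper(val))
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    out[[key]] <- val
  }
  out
}

default_config <- function() {
  list(seed = 1, n_sites = 490, model = "final_2019",
       `synth.nrows` = 32, `synth.ncols` = 32, `synth.cellsize` = 100,
       `synth.relief` = 800, `synth.smoothness` = 0.5,
       `arisa.enabled` = TRUE, `arisa.rfu_floor` = 30,
       `arisa.rel_threshold` = 0.003,
       `spatial.selection` = "all", `spatial.truncation` = "auto",
       `nestedness.n_perm` = 199, `nestedness.null` = "r00")
}

#' Run the full analysis pipeline on a synthetic landscape
#'
#' Generates (or accepts) a sample bundle, then runs the staged analysis:
#' ARISA richness calling, community statistics (nestedness + NMDS +
#' richness-axis correlations for the multicellular matrix), PCNM spatial
#' filtering with residualization and s1/s2 extraction, and the structural
#' equation model with fit indices, total effects and net effects. Every
#' random stage is seeded from the configuration, so a fixed config is
#' fully reproducible.
#'
#' @param config named list (see [read_config()] and `default_config`);
#'   missing entries fall back to defaults.
#' @param bundle optional pre-built bundle from [generate_bundle()]; by
#'   default one is generated from the config.
#' @param out_dir optional directory for per-stage CSV/JSON artifacts.
#' @return list with per-stage results: `samples`, `arisa`, `community`,
#'   `spatial`, `sem`, `net_effects`, `report`.
#' @export
run_all <- function(config = list(), bundle = NULL, out_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  seed <- cfg$seed
  stage <- "synth"
  res <- tryCatch({
    if (is.null(bundle))
      bundle <- generate_bundle(
        n_sites = cfg$n_sites, nrows = cfg$synth.nrows,
        ncols = cfg$synth.ncols, cellsize = cfg$synth.cellsize,
        relief = cfg$synth.relief, smoothness = cfg$synth.smoothness,
        electropherograms = isTRUE(cfg$arisa.enabled), seed = seed)
    samples <- bundle$samples

    stage <- "arisa"
    arisa_res <- NULL
    if (isTRUE(cfg$arisa.enabled) && !is.null(bundle$electropherograms)) {
      arisa_res <- lapply(
        stats::setNames(nm = names(bundle$electropherograms)),
        function(g) {
          grp <- if (g == "fungi") "fungi" else "cyanobacteria"
          tabs <- lapply(bundle$electropherograms[[g]], call_true_peaks,
                         group = grp, rfu_floor = cfg$arisa.rfu_floor,
                         rel_threshold = cfg$arisa.rel_threshold)
          list(richness = vapply(tabs, arisa_richness, 0L),
               binned = bin_peaks(tabs))
        })
      samples$cyano_richness <- unname(arisa_res$cyanobacteria$richness)
      samples$fungal_richness <- unname(arisa_res$fungi$richness)
    }

    stage <- "community"
    mm <- bundle$communities$multicellular
    ok <- rowSums(mm) > 0
    nt <- nestedness_test(mm[ok, , drop = FALSE],
                          null_model = cfg$nestedness.null,
                          n_perm = cfg$nestedness.n_perm, seed = seed + 10)
    ord <- nmds(bray_curtis(mm[ok, , drop = FALSE]), n_starts = 5,
                seed = seed + 11)
    rac <- richness_axis_correlation(samples$multi_richness[ok], ord,
                                     n_perm = 499, seed = seed + 12)
    community_res <- list(nestedness = nt, ordination = ord,
                          richness_axis = rac)

    stage <- "spatial"
    basis <- pcnm_basis(samples[c("x", "y")],
                        truncation = cfg$spatial.truncation)
    env_cols <- c("elevation", "slope", "aspect", "dist_coast", "wetness",
                  "temperature", "ph", "conductivity", "water", "nitrogen",
                  "carbon")
    rbasis <- residualize(basis, as.matrix(samples[env_cols]))
    comps <- spatial_components(
      rbasis, as.matrix(samples[c("cyano_richness", "fungal_richness",
                                  "multi_richness")]))
    spatial_res <- list(basis = basis, residual = rbasis,
                        components = comps)

    stage <- "sem"
    model <- parse_model(cfg$model)
    fit <- fit_ml(model, samples)
    fi <- fit_indices(fit)
    te <- total_effects(fit)
    ne <- net_effects(fit)

    report <- list(
      seed = seed, n_sites = nrow(samples), model = model$name,
      chi2 = fi$chi2, df = fi$df, p_value = fi$p_value, cfi = fi$cfi,
      nestedness_temperature = nt$temperature,
      nestedness_p = nt$p_value,
      nmds_stress = ord$stress,
      s_variance_explained = comps$variance_explained[1:2],
      net_effects = ne)
    list(samples = samples, arisa = arisa_res, community = community_res,
         spatial = spatial_res, sem = fit, fit_indices = fi,
         total_effects = te, net_effects = ne, report = report)
  }, error = function(e) {
    stop_ps("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    header <- sprintf("# seed = %d", as.integer(seed))
    write_with_header <- function(df, file) {
      con <- file(file.path(out_dir, file), "w")
      writeLines(header, con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    write_with_header(res$samples, "samples.csv")
    write_with_header(as.data.frame(res$net_effects), "net_effects.csv")
    write_with_header(res$total_effects$table, "total_effects.csv")
    write_with_header(res$sem$estimates, "sem_estimates.csv")
    jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Write a sample table / community matrix as CSV
#'
#' @param x data.frame or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = inherits(x, "matrix"))
  invisible(path)
}
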