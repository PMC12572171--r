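# End-to-end driver: preprocessing -> band decomposition -> orthogonalized
# IAC -> average strength -> cumulants -> group statistics, driven by a
# single declarative config so every analysis decision is named, logged and
# reproducible.

#' Default pipeline configuration
#'
#' One declarative list naming every decision the other stages expose:
#' filter parameters, trim policy, orthogonalization, normalization mode,
#' cumulant convention, statistics design and seeds. Round-trips losslessly
#' through YAML via [writeConfig()] / [readConfig()].
#'
#' @param ... Named overrides of the defaults (nested lists are replaced
#'   whole).
#' @return A `pipeline_config` list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    input = list(mode = "simulate", manifest = NULL),
    cohort = list(
      seed = 1L,
      # "n_subjects" rather than "n": YAML 1.1 parses a bare "n" key as a
      # boolean, which would corrupt the config on a write/read round-trip
      groups = list(
        HC  = list(n_subjects = 10, spec = list(seed = 1L)),
        PAT = list(n_subjects = 10, spec = list(seed = 1L))
      ),
      covariate = NULL                  # e.g. list(name="cpz", mean=800, sd=400, groups="PAT")
    ),
    preprocess = list(order = 500, bp_lo = 0.5, bp_hi = 98,
                      notch_lo = 48, notch_hi = 52, segment = NULL),
    bands = "canonical",
    dfc = list(orthogonalize = TRUE, trim = 0, normalization = "zscore",
               engine = "cpp"),
    cumulants = list(kurtosis = "pearson"),
    stats = list(alpha = 0.05, fdr_family = "per-contrast",
                 contrasts = NULL, covariate = NULL)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(dots[[nm]])) {
        cfg[[nm]][k] <- list(dots[[nm]][[k]])   # keeps explicit NULLs
      }
    } else {
      cfg[nm] <- list(dots[[nm]])
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipelineConfig()].
#' @param path YAML file path.
#' @return `path` / the configuration.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

cohort_spec_from_config <- function(config) {
  cov_fn <- NULL
  cv <- config$cohort$covariate
  if (!is.null(cv)) {
    cov_fn <- function(label, index) {
      if (!is.null(cv$groups) && !(label %in% cv$groups)) return(NULL)
      stats::setNames(max(0, rnorm(1, cv$mean, cv$sd)), cv$name)
    }
  }
  groups <- lapply(config$cohort$groups, function(g) {
    list(n = g$n_subjects %||% g$n,
         spec = do.call(subjectSpec, g$spec %||% list()))
  })
  cohortSpec(groups, covariate_fn = cov_fn,
             seed = config$cohort$seed %||% 1L)
}

load_recordings_from_manifest <- function(manifest_path) {
  man <- readManifest(manifest_path)
  if (is.null(man$path)) stop("manifest must have a 'path' column", call. = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    rec <- readRecording(p)
    rec$subject_id <- man$subject_id[i] %||% rec$subject_id
    rec$group <- man$group[i] %||% rec$group
    extra <- setdiff(names(man), c("subject_id", "group", "path", "seed"))
    if (length(extra)) {
      rec$covariates <- stats::setNames(as.numeric(man[i, extra]), extra)
    }
    rec
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (synthetic generation or reading
#' files named by a manifest), broadband + notch preprocessing, canonical
#' band decomposition, orthogonalized per-sample IAC, average-strength
#' reduction, cumulant extraction, and group statistics. Deterministic for a
#' given config. Writes the cumulant table, the comparison and covariate
#' screen tables, the manifest and a run manifest (package version, config
#' hash, retained samples) to `out_dir`.
#'
#' @param config A [pipelineConfig()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return List: `cumulants` (long table), `analysis`
#'   ([runGroupAnalysis()] output or `NULL` with < 2 groups), `manifest`,
#'   `run_manifest`.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$input$mode == "simulate") {
    recs <- generateCohort(cohort_spec_from_config(config))
    manifest <- attr(recs, "manifest")
  } else {
    recs <- load_recordings_from_manifest(config$input$manifest)
    manifest <- data.frame(
      subject_id = vapply(recs, function(r) r$subject_id, ""),
      group = vapply(recs, function(r) r$group, ""),
      stringsAsFactors = FALSE
    )
  }
  seg <- config$preprocess$segment
  if (!is.null(seg)) {
    recs <- lapply(recs, selectSegment, start = seg$start %||% 0,
                   duration = seg$duration)
  }
  bands <- if (identical(config$bands, "canonical")) {
    canonicalBands(recs[[1]]$fs)
  } else {
    as.data.frame(do.call(rbind, lapply(config$bands, as.data.frame)))
  }
  tab <- cohortCumulants(
    recs, bands = bands, order = config$preprocess$order,
    orthogonalize = isTRUE(config$dfc$orthogonalize),
    trim = config$dfc$trim %||% 0, engine = config$dfc$engine %||% "cpp"
  )
  analysis <- NULL
  if (length(unique(tab$group[!is.na(tab$group)])) >= 2) {
    analysis <- runGroupAnalysis(
      tab, contrasts = config$stats$contrasts,
      alpha = config$stats$alpha %||% 0.05,
      covariate = config$stats$covariate,
      fdr_family = config$stats$fdr_family %||% "per-contrast"
    )
  }
  n0 <- ncol(recs[[1]]$data)
  run_manifest <- data.frame(
    package_version = as.character(packageVersion("iacdfc")),
    n_subjects = length(recs),
    fs = recs[[1]]$fs,
    samples = n0,
    retained_samples = n0 - 2 * (config$dfc$trim %||% 0),
    orthogonalize = isTRUE(config$dfc$orthogonalize),
    trim = config$dfc$trim %||% 0,
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    writeConfig(config, cfg_path)
    run_manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    write.table(tab, file.path(out_dir, "cumulants.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    writeManifest(manifest, file.path(out_dir, "manifest.csv"))
    if (!is.null(analysis)) {
      write.table(analysis$comparisons, file.path(out_dir, "comparisons.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      for (g in names(analysis$screen %||% list())) {
        write.table(analysis$screen[[g]],
                    file.path(out_dir, paste0("covariate_screen_", g, ".tsv")),
                    sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    write.table(run_manifest, file.path(out_dir, "run_manifest.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(cumulants = tab, analysis = analysis, manifest = manifest,
       run_manifest = run_manifest)
}
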