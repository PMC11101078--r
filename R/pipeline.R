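#' Pipeline configuration
#'
#' Settings for [run_pipeline()]. May also be loaded from a YAML file with
#' [read_pipeline_config()].
#'
#' @param input Path to a peak-area CSV, or a [peak_area_table()].
#' @param out_dir Output directory (created if absent).
#' @param reference Reference sample id for normalization; default the
#'   first sample of the first (control) group in the table.
#' @param p13 Natural 13C abundance for the correction matrices.
#' @param purity,tracer,rounds,enrichment Template settings for the mixture
#'   fit; `enrichment` may be a single value or named per group.
#' @param group_x,group_y Groups compared by Welch's t test; default the
#'   first two groups present.
#' @param tails,alpha,family Statistics settings (see [compare_groups()]).
#' @param fit Logical: run the pathway-mixture deconvolution?
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return List of class `ppp_config`.
#' @export
pipeline_config <- function(input, out_dir, reference = NULL,
                            p13 = 0.0107, purity = 1,
                            tracer = "glucose_m6", rounds = 2L,
                            enrichment = 1, group_x = NULL, group_y = NULL,
                            tails = 2L, alpha = 0.05,
                            family = "metabolite", fit = TRUE, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  structure(list(input = input, out_dir = out_dir, reference = reference,
                 p13 = p13, purity = purity, tracer = tracer,
                 rounds = as.integer(rounds), enrichment = enrichment,
                 group_x = group_x, group_y = group_y,
                 tails = as.integer(tails), alpha = alpha, family = family,
                 fit = isTRUE(fit), seed = as.integer(seed)),
            class = "ppp_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys are `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

# carbon counts of the reported species, from the shipped network
reported_carbons <- function(net = default_network()) {
  nc <- vapply(net$metabolites, `[[`, 1L, "n_carbons")
  for (g in names(net$reporting))
    nc[g] <- nc[net$reporting[[g]][1]]
  nc
}

#' Run the tracing analysis pipeline
#'
#' Executes normalize -> correct -> fractions -> compare -> (optionally)
#' fit on a peak-area table, writing each stage's output and a
#' machine-readable JSON report (normalization factors, correction
#' residuals, comparison table, mixture weights, seed and config hash)
#' under `cfg$out_dir`. Progress is logged to standard error.
#'
#' @param cfg A [pipeline_config()].
#' @param net Carbon-transition network.
#' @param quiet Suppress log messages.
#' @return The report, invisibly (class `ppp_report`).
#' @export
run_pipeline <- function(cfg, net = default_network(), quiet = FALSE) {
  log_ <- function(...) if (!quiet) message("[ppptracer] ", ...)
  tab <- if (is.character(cfg$input)) {
    log_("reading ", cfg$input)
    read_peak_areas(cfg$input)
  } else peak_area_table(as.data.frame(cfg$input))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  groups <- unique(tab$group)
  reference <- cfg$reference
  if (is.null(reference))
    reference <- tab$sample_id[tab$group == groups[1]][1]
  log_("normalizing against reference sample ", reference)
  norm <- normalize_table(tab, reference)
  factors <- attr(norm, "factors")
  write_peak_areas(norm, file.path(cfg$out_dir, "normalized.csv"))

  ncar_known <- reported_carbons(net)
  mets <- unique(norm$metabolite)
  ncar <- vapply(mets, function(mb) {
    if (mb %in% names(ncar_known)) ncar_known[[mb]]
    else max(norm$mass_shift[norm$metabolite == mb])
  }, 1L)

  log_("computing isotopologue fractions")
  fracs <- fraction_table(norm, n_carbons = ncar)
  utils::write.csv(fracs, file.path(cfg$out_dir, "fractions.csv"),
                   row.names = FALSE)

  log_("correcting for natural abundance (p13 = ", cfg$p13, ")")
  mats <- lapply(sort(unique(ncar)), build_correction_matrix, p13 = cfg$p13)
  names(mats) <- as.character(sort(unique(ncar)))
  corr_rows <- list(); resid <- c()
  for (b in split(fracs, list(fracs$sample_id, fracs$metabolite),
                  drop = TRUE)) {
    cm <- correct_mid(b$fraction, mats[[as.character(nrow(b) - 1L)]])
    b$corrected_fraction <- as.numeric(cm$fractions)
    resid[paste(b$sample_id[1], b$metabolite[1])] <- cm$residual
    corr_rows[[length(corr_rows) + 1L]] <- b
  }
  corrected <- do.call(rbind, corr_rows)
  corrected <- corrected[order(corrected$metabolite, corrected$sample_id,
                               corrected$mass_shift), ]
  rownames(corrected) <- NULL
  utils::write.csv(corrected, file.path(cfg$out_dir, "corrected.csv"),
                   row.names = FALSE)

  comparisons <- NULL
  gx <- if (is.null(cfg$group_x)) groups[1] else cfg$group_x
  gy <- if (is.null(cfg$group_y)) groups[2] else cfg$group_y
  if (!is.na(gy) && length(groups) >= 2L) {
    log_("comparing groups ", gx, " vs ", gy)
    cf <- corrected
    cf$fraction <- cf$corrected_fraction
    comparisons <- compare_groups(cf, gx, gy, tails = cfg$tails,
                                  alpha = cfg$alpha, family = cfg$family)
    utils::write.csv(comparisons,
                     file.path(cfg$out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }

  mixtures <- NULL
  if (cfg$fit) {
    log_("fitting pathway mixtures")
    tpl_mets <- intersect(c("G6P", "F6P_G1P", "Ru5P_R5P", "S7P", "lactate"),
                          mets)
    mixtures <- list()
    for (g in groups) {
      e <- if (length(cfg$enrichment) > 1L) cfg$enrichment[[g]]
           else cfg$enrichment
      tpl <- template_mids(net, tracer = cfg$tracer, enrichment = e,
                           rounds = cfg$rounds, purity = cfg$purity,
                           metabolites = tpl_mets)
      sids <- unique(corrected$sample_id[corrected$group == g])
      mean_mids <- lapply(tpl_mets, function(mb) {
        v <- vapply(sids, function(s) {
          b <- corrected[corrected$sample_id == s &
                           corrected$metabolite == mb, ]
          b$corrected_fraction[order(b$mass_shift)]
        }, numeric(ncar[[mb]] + 1L))
        r <- rowMeans(v)
        names(r) <- paste0("m", seq_along(r) - 1L)
        r
      })
      names(mean_mids) <- tpl_mets
      fit <- fit_pathway_mixture(mean_mids, tpl)
      mixtures[[g]] <- list(weights = as.list(coef(fit)),
                            residual = fit$residual,
                            enrichment = e)
    }
  }

  cfg_echo <- file.path(cfg$out_dir, "config.yaml")
  cfg_list <- unclass(cfg)
  cfg_list$input <- if (is.character(cfg$input)) cfg$input else "<in-memory>"
  yaml::write_yaml(cfg_list, cfg_echo)
  # hash the analysis-relevant settings only (not the output location)
  hash_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list[setdiff(names(cfg_list), "out_dir")], hash_file)
  cfg_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)

  report <- list(
    config_hash = cfg_hash, seed = cfg$seed, reference = reference,
    normalization_factors = stats::setNames(as.list(factors$factor),
                                            factors$sample_id),
    correction_residuals = list(max = max(resid), mean = mean(resid)),
    n_comparisons = if (is.null(comparisons)) 0L else nrow(comparisons),
    mixtures = mixtures)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_("report written to ", file.path(cfg$out_dir, "report.json"))
  report$comparisons <- comparisons
  class(report) <- "ppp_report"
  invisible(report)
}

#' @export
print.ppp_report <- function(x, ...) {
  cat("Pipeline report (config", substr(x$config_hash, 1, 8), ", seed",
      x$seed, ")\n  reference:", x$reference, "\n  comparisons:",
      x$n_comparisons, "\n")
  if (!is.null(x$mixtures))
    for (g in names(x$mixtures))
      cat(sprintf("  %s mixture: [%s]\n", g,
                  paste(sprintf("%s=%.3f", names(x$mixtures[[g]]$weights),
                                unlist(x$mixtures[[g]]$weights)),
                        collapse = ", ")))
  invisible(x)
}
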