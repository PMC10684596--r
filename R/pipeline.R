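#' Configure an end-to-end trial analysis
#'
#' Bundles every choice the pipeline needs: the data source (a CSV path or
#' the built-in simulator), which traits enter the analysis, the dependent
#' traits with their per-analysis predictor exclusions, the collinearity
#' threshold and protected traits, the correlation levels to run, and
#' serialization rounding.
#'
#' @param input path to a plot-table CSV, or `NULL` to simulate with
#'   [amaranth_fixture()] at `seed`.
#' @param seed integer seed used when simulating (and recorded in the
#'   provenance block either way).
#' @param traits trait codes entering the screen and correlations.
#' @param dependents named list; each element is a list with an optional
#'   `exclude` character vector of predictors dropped for that dependent
#'   (e.g. `list(LY = list(exclude = "GSFR"))`).
#' @param levels correlation levels to run paths at.
#' @param vif_threshold,protected collinearity-screen settings; dependents
#'   are always protected in addition to `protected`.
#' @param screen_level which correlation matrix feeds the screen.
#' @param basis phenotypic-variance basis (see [estimate_components()]).
#' @param blocks block handling (see [mean_squares()]).
#' @param rounding decimals used when serializing reports.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input = NULL, seed = 1,
                            traits,
                            dependents = list(),
                            levels = c("phenotypic", "genotypic"),
                            vif_threshold = 10,
                            protected = character(),
                            screen_level = c("phenotypic", "genotypic"),
                            basis = c("mean", "plot"),
                            blocks = c("ignore", "absorb"),
                            rounding = 4) {
  screen_level <- match.arg(screen_level)
  basis <- match.arg(basis)
  blocks <- match.arg(blocks)
  levels <- match.arg(levels, several.ok = TRUE)
  deps <- names(dependents)
  if (length(dependents) && (is.null(deps) || any(!nzchar(deps))))
    stop("`dependents` must be a named list", call. = FALSE)
  bad <- setdiff(deps, traits)
  if (length(bad))
    stop("dependent trait(s) not in `traits`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (d in deps) {
    ex <- dependents[[d]]$exclude
    if (!is.null(ex)) {
      bad <- setdiff(ex, traits)
      if (length(bad))
        stop("excluded trait(s) for ", d, " not in `traits`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      if (d %in% ex)
        stop("dependent ", d, " cannot exclude itself", call. = FALSE)
    }
  }
  structure(list(
    input = input, seed = as.integer(seed), traits = traits,
    dependents = dependents, levels = levels,
    vif_threshold = vif_threshold,
    protected = union(protected, deps),
    screen_level = screen_level, basis = basis, blocks = blocks,
    rounding = rounding), class = "analysis_config")
}

#' Analysis configuration mirroring the reference amaranth study
#'
#' All 24 traits enter the multicollinearity screen; leaf yield (LY,
#' excluding GSFR from its predictors) and grain yield (GY, excluding DM)
#' are the dependents, each decomposed at both correlation levels; both
#' yields are protected from the screen.
#'
#' @param seed simulation seed.
#' @return An [analysis_config()].
#' @export
amaranth_config <- function(seed = 42) {
  analysis_config(
    input = NULL, seed = seed,
    traits = amaranth_traits()$code,
    dependents = list(LY = list(exclude = "GSFR"),
                      GY = list(exclude = "DM")),
    levels = c("phenotypic", "genotypic"),
    vif_threshold = 10,
    protected = c("LY", "GY"))
}

#' Read a long-format plot table from CSV
#'
#' Expects the header `genotype,season,rep,block,trait,value`. Trait codes
#' are matched case-insensitively against `registry` when one is given.
#' The table is validated and balance-checked.
#'
#' @param path CSV file path.
#' @param registry optional character vector of canonical trait codes.
#' @return A validated `plot_table` data frame.
#' @export
read_plot_table <- function(path, registry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "season", "rep", "block", "trait", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("plot-table CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(tab$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$value))))[1]
    stop("non-numeric `value` at data row ", bad, call. = FALSE)
  }
  if (!is.null(registry)) {
    idx <- match(toupper(tab$trait), toupper(registry))
    if (anyNA(idx)) {
      unknown <- unique(tab$trait[is.na(idx)])
      stop("unknown trait code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    tab$trait <- registry[idx]
  }
  check_balance(tab)
  class(tab) <- c("plot_table", "data.frame")
  tab
}

#' Write a plot table as CSV
#'
#' Long-format, UTF-8, header `genotype,season,rep,block,trait,value`; the
#' exact inverse of [read_plot_table()].
#'
#' @param table a plot table.
#' @param path destination file.
#' @return The path, invisibly.
#' @export
write_plot_table <- function(table, path) {
  cols <- c("genotype", "season", "rep", "block", "trait", "value")
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the plot table; estimate variance and
#' covariance components and both correlation matrices for all configured
#' traits; screen for multicollinearity (dependents protected); restrict the
#' matrices to the retained traits; and decompose each dependent at each
#' requested level into direct and indirect effects. Fully deterministic
#' given the configuration and seed.
#'
#' @param config an [analysis_config()].
#' @param table optionally, a ready-made plot table (overrides
#'   `config$input`).
#' @param quiet suppress per-stage progress messages.
#' @return An object of class `report_bundle`: `correlations`
#'   (`correlation_pair` over retained traits), `screen`
#'   (`collinearity_report`), `paths` (named list of `path_decomposition`,
#'   names `<dependent>.<level>`), and a `provenance` list.
#' @export
run_pipeline <- function(config, table = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(table)) {
    if (is.null(config$input)) {
      say("simulating fixture trial (seed %d)", config$seed)
      table <- amaranth_fixture(seed = config$seed)$table
    } else {
      say("reading plot table from %s", config$input)
      table <- read_plot_table(config$input, registry = config$traits)
    }
  }
  say("estimating components and correlations for %d traits",
      length(config$traits))
  corr_all <- correlation_matrices(table, config$traits,
                                   blocks = config$blocks,
                                   basis = config$basis)
  say("screening multicollinearity at the %s level (VIF threshold %s)",
      config$screen_level, format(config$vif_threshold))
  R_screen <- if (config$screen_level == "phenotypic") corr_all$rp else corr_all$rg
  screen <- screen_traits(R_screen, vif_threshold = config$vif_threshold,
                          protected = config$protected)
  retained <- screen$retained

  sub <- function(m) m[retained, retained, drop = FALSE]
  correlations <- corr_all
  correlations$traits <- retained
  correlations$rp <- sub(corr_all$rp)
  correlations$rg <- sub(corr_all$rg)
  correlations$sig_p <- sub(corr_all$sig_p)
  correlations$sig_g <- sub(corr_all$sig_g)
  correlations$rg_out_of_range <- sub(corr_all$rg_out_of_range)
  correlations$rg_undefined <- corr_all$rg_undefined[match(retained, corr_all$traits)]

  paths <- list()
  for (dep in names(config$dependents)) {
    exclude <- config$dependents[[dep]]$exclude
    predictors <- setdiff(retained, c(dep, exclude))
    if (length(predictors) < 1)
      stop("no predictors left for dependent ", dep, call. = FALSE)
    for (lv in config$levels) {
      Rm <- if (lv == "phenotypic") correlations$rp else correlations$rg
      Rxx <- Rm[predictors, predictors, drop = FALSE]
      rxy <- Rm[predictors, dep]
      say("path analysis: %s at the %s level (%d predictors)",
          dep, lv, length(predictors))
      paths[[paste(dep, lv, sep = ".")]] <-
        path_analysis(Rxx, rxy, dependent = dep, level = lv)
    }
  }
  out <- list(
    correlations = correlations, screen = screen, paths = paths,
    provenance = list(
      seed = config$seed,
      input = if (is.null(config$input)) "simulated" else config$input,
      traits = config$traits, retained = retained,
      screen_level = config$screen_level, basis = config$basis,
      blocks = config$blocks,
      package_version = as.character(utils::packageVersion("traitpath"))))
  class(out) <- "report_bundle"
  out
}

#' Write a report bundle to disk
#'
#' Serializes every matrix and decomposition as TSV (values rounded to the
#' configured number of decimals at write time only), the combined
#' correlation table and removal log as plain text, and a provenance file.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @param rounding decimals for serialized values.
#' @return Character vector of the files written (the manifest), invisibly.
#' @export
write_report <- function(bundle, dir, rounding = 4) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) formatC(x, digits = rounding, format = "f")
  write_mat <- function(m, file, sig = NULL) {
    out <- matrix(fmt(m), nrow(m), dimnames = dimnames(m))
    if (!is.null(sig)) out[] <- paste0(out, ifelse(sig == "" | is.na(sig), "", sig))
    utils::write.table(out, file, sep = "\t", quote = FALSE, col.names = NA)
    file
  }
  manifest <- character()
  co <- bundle$correlations
  manifest <- c(manifest,
    write_mat(co$rp, file.path(dir, "correlations_phenotypic.tsv"), co$sig_p),
    write_mat(co$rg, file.path(dir, "correlations_genotypic.tsv"), co$sig_g))
  f <- file.path(dir, "correlation_table.txt")
  writeLines(format_correlation_table(co), f)
  manifest <- c(manifest, f)

  f <- file.path(dir, "collinearity.tsv")
  utils::write.table(
    data.frame(trait = bundle$screen$vif$trait,
               vif = fmt(bundle$screen$vif$vif),
               tol = fmt(bundle$screen$vif$tol)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(manifest, f)
  f <- file.path(dir, "collinearity_removals.txt")
  writeLines(c(
    sprintf("VIF threshold: %s", format(bundle$screen$vif_threshold)),
    if (nrow(bundle$screen$removed))
      sprintf("removed %s (VIF %.4f at removal)",
              bundle$screen$removed$trait, bundle$screen$removed$vif)
    else "no traits removed",
    sprintf("retained: %s", paste(bundle$screen$retained, collapse = ", ")),
    sprintf("retained-set condition number: %.2f (%s)",
            bundle$screen$eigen$condition_number, bundle$screen$eigen$severity)),
    f)
  manifest <- c(manifest, f)

  for (nm in names(bundle$paths)) {
    pd <- bundle$paths[[nm]]
    f <- file.path(dir, paste0("path_", gsub("\\.", "_", nm), ".tsv"))
    k <- length(pd$predictors)
    eff <- pd$indirect
    diag(eff) <- pd$direct
    block <- rbind(
      `Direct effect` = fmt(pd$direct),
      matrix(fmt(t(eff)), k, k, byrow = TRUE,
             dimnames = list(paste("Indirect of", pd$predictors, "via"),
                             pd$predictors)))
    # rows after the first: row i lists predictor i's indirect effects via
    # the column traits; the diagonal repeats its direct effect
    lines <- c(
      sprintf("# %s-level path decomposition of %s", pd$level, pd$dependent),
      sprintf("# rows 'Indirect of X via' list X's indirect effects via the column traits"),
      paste(c("effect", pd$predictors), collapse = "\t"),
      paste("Direct effect", paste(fmt(pd$direct), collapse = "\t"), sep = "\t"))
    for (i in seq_len(k)) {
      vals <- eff[i, ]
      vals[i] <- NA
      lines <- c(lines, paste(c(paste("Indirect of", pd$predictors[i], "via"),
                                ifelse(is.na(vals), ".", fmt(vals))),
                              collapse = "\t"))
    }
    lines <- c(lines, paste(c("Percent direct",
                              fmt(diag(pd$percent))), collapse = "\t"))
    lines <- c(lines,
               sprintf("# R2 = %s; residual factor = %s%s", fmt(pd$R2),
                       ifelse(is.na(pd$RF), "undefined", fmt(pd$RF)),
                       if (pd$over_determined) " (over-determined)" else ""),
               sprintf("# reconstructed r_xy: %s",
                       paste(fmt(reconstruct_correlations(pd)), collapse = " ")))
    writeLines(lines, f)
    manifest <- c(manifest, f)
  }

  f <- file.path(dir, "provenance.txt")
  pv <- bundle$provenance
  writeLines(c(
    sprintf("seed: %d", pv$seed),
    sprintf("input: %s", pv$input),
    sprintf("traits: %s", paste(pv$traits, collapse = ", ")),
    sprintf("retained: %s", paste(pv$retained, collapse = ", ")),
    sprintf("screen_level: %s", pv$screen_level),
    sprintf("basis: %s", pv$basis),
    sprintf("blocks: %s", pv$blocks),
    sprintf("traitpath_version: %s", pv$package_version)), f)
  manifest <- c(manifest, f)
  invisible(manifest)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Trial analysis bundle\n")
  cat(sprintf("  correlations: %d retained traits (n = %d genotypes)\n",
              length(x$correlations$traits), x$correlations$n))
  cat(sprintf("  screen: removed %d trait(s) [%s]\n",
              nrow(x$screen$removed),
              paste(x$screen$removed$trait, collapse = ", ")))
  for (nm in names(x$paths)) {
    pd <- x$paths[[nm]]
    cat(sprintf("  path %s: R2 = %.4f, RF = %s\n", nm, pd$R2,
                ifelse(is.na(pd$RF), "undefined", sprintf("%.4f", pd$RF))))
  }
  invisible(x)
}
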