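# Readers/writers for the bundle directory format, run configuration,
# and the end-to-end pipeline.

write_tsv <- function(x, path, rownames_as = NULL) {
  df <- as.data.frame(x)
  if (!is.null(rownames_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(x)), rownames_as), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a synthetic bundle as a directory of TSV files plus truth.json
#'
#' Canonical dialect: UTF-8, tab separator, '.' decimal, no quoting.
#' Files: samples.tsv, otu_matrix.tsv, plant_matrix.tsv, taxonomy.tsv,
#' plant_attributes.tsv, truth.json.
#'
#' @param bundle a `gradient_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$samples, file.path(dir, "samples.tsv"))
  write_tsv(bundle$otu_matrix, file.path(dir, "otu_matrix.tsv"),
            rownames_as = "sample_id")
  write_tsv(bundle$plant_matrix, file.path(dir, "plant_matrix.tsv"),
            rownames_as = "sample_id")
  write_tsv(bundle$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(bundle$plant_attributes, file.path(dir, "plant_attributes.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' Validates presence of required files and cross-file key agreement; every
#' problem found is reported in a single aggregated error. A missing
#' taxonomy file only disables phylum-level analyses (with a warning).
#'
#' @param dir directory written by [write_bundle()] (or hand-assembled in the
#'   same layout; CSV is accepted if files use the .tsv names with tabs).
#' @return a `gradient_bundle` (truth present only if truth.json exists).
#' @export
read_bundle <- function(dir) {
  problems <- character()
  need <- c("samples.tsv", "otu_matrix.tsv", "plant_matrix.tsv",
            "plant_attributes.tsv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      problems <- c(problems, paste("missing file:", f))
  fail_all(problems, "invalid bundle directory")
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  if (!all(c("sample_id", "site_id", "elevation") %in% names(samples)))
    problems <- c(problems,
                  "samples.tsv needs sample_id, site_id, elevation")
  read_mat <- function(f) {
    df <- read_tsv(file.path(dir, f))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  otu <- read_mat("otu_matrix.tsv")
  plant <- read_mat("plant_matrix.tsv")
  attrs <- read_tsv(file.path(dir, "plant_attributes.tsv"))
  for (nm in c("otu_matrix", "plant_matrix")) {
    m <- if (nm == "otu_matrix") otu else plant
    extra <- setdiff(rownames(m), samples$sample_id)
    if (length(extra))
      problems <- c(problems, paste0(nm, " samples absent from metadata: ",
                                     paste(extra, collapse = ", ")))
    gone <- setdiff(samples$sample_id, rownames(m))
    if (length(gone))
      problems <- c(problems, paste0(nm, " missing samples: ",
                                     paste(gone, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id))
    problems <- c(problems, "duplicate sample ids")
  if (any(!is.finite(samples$elevation)))
    problems <- c(problems, "non-finite elevations")
  fail_all(problems, "invalid bundle")
  taxonomy <- NULL
  tax_path <- file.path(dir, "taxonomy.tsv")
  if (file.exists(tax_path)) {
    taxonomy <- read_tsv(tax_path)
    if (!nrow(taxonomy)) taxonomy <- NULL
  }
  if (is.null(taxonomy))
    warning("no taxonomy: bacterial phylum-level analyses disabled")
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json")))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
  structure(list(samples = samples,
                 otu_matrix = otu[samples$sample_id, , drop = FALSE],
                 plant_matrix = plant[samples$sample_id, , drop = FALSE],
                 plant_attributes = attrs, taxonomy = taxonomy,
                 truth = truth, params = NULL),
            class = "gradient_bundle")
}

#' Pipeline run configuration
#'
#' @param band breakpoint search band in m (default 1800-3000).
#' @param rarefaction_depth reads per sample (default 10000).
#' @param n_perm permutations for PERMANOVA/turnover tests (>= 99).
#' @param n_boot bootstrap replicates for breakpoint CIs (>= 99).
#' @param n_null permutations for the slope-change test (>= 99).
#' @param emf_perms subsets per k of the EMF robustness curve.
#' @param seed integer master seed; all stage seeds are derived from it.
#' @param data_dir bundle directory to read (ignored when a bundle object is
#'   passed to [run_pipeline()] directly).
#' @param out_dir directory for result files.
#' @return object of class `run_config`.
#' @export
run_config <- function(band = c(1800, 3000), rarefaction_depth = 10000,
                       n_perm = 199, n_boot = 199, n_null = 199,
                       emf_perms = 199, seed = 1, data_dir = NULL,
                       out_dir = tempfile("elevbreak_run_")) {
  for (v in c(n_perm, n_boot, n_null, emf_perms))
    if (v < 99) stop("permutation/bootstrap counts must be >= 99")
  if (length(band) != 2 || band[1] >= band[2]) stop("band must be (lo, hi)")
  structure(list(band = band, rarefaction_depth = rarefaction_depth,
                 n_perm = n_perm, n_boot = n_boot, n_null = n_null,
                 emf_perms = emf_perms, seed = seed, data_dir = data_dir,
                 out_dir = out_dir),
            class = "run_config")
}

# Hash of the analysis-relevant configuration (paths excluded, so the same
# analysis in a different directory hashes identically).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg <- cfg[setdiff(names(cfg), c("data_dir", "out_dir"))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full elevational-gradient analysis
#'
#' Orchestrates diversity -> ordination -> breakpoints -> multifunctionality
#' -> drivers on a bundle, writing TSV/JSON results, a structured log with
#' every derived seed, and a machine-readable summary.json. Identical
#' config + seed (and bundle) give byte-identical summary files. If a stage
#' fails, partial outputs are retained and the error is re-thrown.
#'
#' @param config a `run_config`.
#' @param bundle optional `gradient_bundle`; default reads
#'   `config$data_dir`.
#' @return (invisibly) the summary list; side effect: files in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, bundle = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(out, "run.log")
  cat(sprintf("config_hash=%s seed=%d\n", hash, as.integer(config$seed)),
      file = logf)
  stage <- function(name, code) {
    t0 <- proc.time()[3]
    r <- tryCatch(force(code), error = function(e) {
      cat(sprintf("stage=%s status=error message=%s\n", name,
                  conditionMessage(e)), file = logf, append = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    cat(sprintf("stage=%s status=ok seconds=%.2f\n", name,
                proc.time()[3] - t0), file = logf, append = TRUE)
    r
  }
  seeds <- stats::setNames(
    vapply(1:9, function(k) derive_seed(config$seed, 1000 + k), integer(1)),
    c("rarefy", "turnover_otu", "turnover_plant", "fits", "boot",
      "emf_curve", "drivers", "unused1", "unused2"))
  cat(paste(sprintf("derived_seed %s=%d", names(seeds), seeds),
            collapse = "\n"), "\n", file = logf, append = TRUE)

  if (is.null(bundle))
    bundle <- stage("read", read_bundle(config$data_dir))
  samples <- bundle$samples
  elev <- samples$elevation
  fg <- function_groups()
  fn_cols <- intersect(fg$fn, names(samples))
  if (length(fn_cols) < 2) stop("bundle lacks the function columns")

  div <- stage("diversity", {
    otu <- rarefy_counts(bundle$otu_matrix, config$rarefaction_depth,
                         seed = seeds["rarefy"])
    comp <- data.frame(plant_richness = apply(bundle$plant_matrix, 1,
                                              richness),
                       bacterial_richness = apply(otu, 1, richness))
    if (!is.null(bundle$taxonomy)) {
      phy <- aggregate_taxa(otu, bundle$taxonomy, "phylum")
      dom <- prevalence_filter(phy, min_frac = 0.8)
      # per-sample richness within each dominant phylum (classes for
      # Proteobacteria, consistent with aggregate_taxa)
      idx <- match(colnames(otu), bundle$taxonomy$taxon_id)
      grp <- bundle$taxonomy$phylum[idx]
      cls <- bundle$taxonomy$class[idx]
      swap <- grp == "Proteobacteria" & !is.na(cls) & nzchar(cls)
      grp[swap] <- cls[swap]
      rich_phy <- t(rowsum((t(otu) > 0) * 1L, grp))
      rich_phy <- rich_phy[, colnames(rich_phy) %in% colnames(dom),
                           drop = FALSE]
      comp <- cbind(comp, rich_phy)
    }
    md <- multidiversity(comp)
    list(otu = otu, components = comp, md = md)
  })

  emf_res <- stage("emf", {
    groups <- stats::setNames(fg$group, fg$fn)[fn_cols]
    mf <- multifunctionality(samples[fn_cols], groups)
    curve <- emf_subset_curve(mf$z, k_min = min(10, length(fn_cols)),
                              n_perm = config$emf_perms,
                              seed = seeds["emf_curve"])
    list(mf = mf, curve = curve)
  })

  ords <- stage("ordination", {
    fn_pos <- pmax(as.matrix(samples[fn_cols]), 0)
    list(bact = ordinate_dca(div$otu),
         plant = ordinate_dca(bundle$plant_matrix),
         fun = ordinate_dca(fn_pos))
  })

  fits <- stage("breakpoints", {
    responses <- c(
      list(multidiversity = div$md$md,
           plant_richness = div$components$plant_richness,
           bacterial_richness = div$components$bacterial_richness,
           emf = emf_res$mf$emf,
           dca1_bacteria = ords$bact$scores[, 1],
           dca1_plants = ords$plant$scores[, 1],
           dca1_functions = ords$fun$scores[, 1]),
      as.list(as.data.frame(emf_res$mf$group_emf)))
    facets <- c("biodiversity", "biodiversity", "biodiversity",
                "functions", "bacteria_comp", "plants_comp",
                "functions_comp",
                rep("functions", ncol(emf_res$mf$group_emf)))
    fl <- lapply(seq_along(responses), function(i)
      piecewise_fit(elev, responses[[i]], band = config$band,
                    n_null = config$n_null,
                    seed = derive_seed(seeds["fits"], i)))
    names(fl) <- names(responses)
    fl$emf <- breakpoint_bootstrap(elev, responses$emf, config$band,
                                   n_boot = config$n_boot,
                                   seed = seeds["boot"], fit = fl$emf)
    list(fits = fl, facets = facets,
         consensus = consensus_breakpoints(fl, facets))
  })

  turns <- stage("turnover", {
    site_elev <- tapply(elev, samples$site_id, unique)
    list(otu = adjacent_turnover(div$otu, samples$site_id, site_elev,
                                 band = config$band, n_perm = config$n_perm,
                                 seed = seeds["turnover_otu"]),
         plant = adjacent_turnover(bundle$plant_matrix, samples$site_id,
                                   site_elev, band = config$band,
                                   n_perm = config$n_perm,
                                   seed = seeds["turnover_plant"]))
  })

  sd_ <- stage("split_density", split_density(div$otu, elev))

  drv <- stage("drivers", {
    minerals <- c("quartz", "plagioclase", "kfeldspar", "amphibole",
                  "muscovite", "chlorite")
    metals <- c("Ca", "Fe", "Mg", "Al", "K", "Na", "Mn", "Ti")
    have_geo <- all(c(minerals, metals, "CIA") %in% names(samples))
    if (!have_geo) return(NULL)
    pc_min <- ordinate_pca(samples[minerals])$scores[, 1:2]
    pc_met <- ordinate_pca(samples[metals])$scores[, 1:2]
    contemp <- samples[c("MAT", "MAP", "pH", "moisture")]
    geo <- data.frame(CIA = samples$CIA, Ti_Fe = samples$Ti_Fe,
                      Ti_Al = samples$Ti_Al, Mg_Al = samples$Mg_Al,
                      Ca_Al = samples$Ca_Al,
                      mineral_pc1 = pc_min[, 1], mineral_pc2 = pc_min[, 2],
                      metal_pc1 = pc_met[, 1], metal_pc2 = pc_met[, 2])
    per_response <- function(y) {
      preds <- cbind(contemp, geo)
      der <- dereplicate_predictors(preds, y)
      avg <- all_subsets_average(y, der$retained)
      ginc <- geo_increment(y, contemp,
                            geo[, colnames(geo) %in%
                                  c(colnames(der$retained),
                                    "CIA", "Ca_Al"), drop = FALSE])
      vp <- variation_partition(y, contemp, geo)
      list(average = avg, increment = ginc, vpa = vp,
           dereplication = der$log)
    }
    md_drv <- per_response(div$md$md)
    emf_drv <- per_response(emf_res$mf$emf)
    # composite path model for EMF with MD as the biotic node
    dat <- data.frame(
      climate = composite_score(contemp[c("MAT", "MAP")],
                                emf_res$mf$emf)$composite,
      parent_rock = composite_score(
        data.frame(pc_min), emf_res$mf$emf)$composite,
      weathering = composite_score(geo[c("CIA", "Ti_Fe", "Mg_Al", "Ca_Al")],
                                   emf_res$mf$emf)$composite,
      local = composite_score(contemp[c("pH", "moisture")],
                              emf_res$mf$emf)$composite,
      MD = div$md$md, EMF = emf_res$mf$emf)
    edges_emf <- data.frame(
      from = c("parent_rock", "weathering", "climate", "climate",
               "weathering", "local", "climate", "weathering", "local",
               "MD"),
      to = c("weathering", "local", "local", "MD", "MD", "MD", "EMF",
             "EMF", "EMF", "EMF"))
    dat_md <- dat
    dat_md$climate <- composite_score(contemp[c("MAT", "MAP")],
                                      div$md$md)$composite
    dat_md$weathering <- composite_score(
      geo[c("CIA", "Ti_Fe", "Mg_Al", "Ca_Al")], div$md$md)$composite
    dat_md$local <- composite_score(contemp[c("pH", "moisture")],
                                    div$md$md)$composite
    edges_md <- edges_emf[edges_emf$to != "EMF" & edges_emf$from != "MD", ]
    list(md = md_drv, emf = emf_drv,
         path_emf = path_fit(dat, edges_emf, "EMF"),
         path_md = path_fit(dat_md, edges_md, "MD"))
  })

  stage("write", {
    rnd <- function(x) round(x, 10)  # stable text representation
    fit_tab <- do.call(rbind, lapply(names(fits$fits), function(nm) {
      f <- fits$fits[[nm]]
      data.frame(response = nm, facet = fits$facets[match(nm,
                 names(fits$fits))], psi = f$psi, beta1 = rnd(f$beta1),
                 beta2 = rnd(f$beta2), r2 = rnd(f$r2),
                 p_improvement = f$p_improvement, ci_low = f$ci_low,
                 ci_high = f$ci_high)
    }))
    write_tsv(fit_tab, file.path(out, "breakpoint_fits.tsv"))
    write_tsv(turns$otu$profile, file.path(out, "turnover_otu.tsv"))
    write_tsv(turns$plant$profile, file.path(out, "turnover_plant.tsv"))
    write_tsv(data.frame(elevation = sd_$grid, raw = rnd(sd_$raw),
                         data_density = rnd(sd_$data_density),
                         standardized = rnd(sd_$standardized)),
              file.path(out, "split_density.tsv"))
    write_tsv(data.frame(sample_id = samples$sample_id,
                         multidiversity = rnd(div$md$md),
                         emf = rnd(emf_res$mf$emf),
                         rnd(emf_res$mf$group_emf)),
              file.path(out, "emf_table.tsv"))
    if (!is.null(drv)) {
      write_tsv(cbind(response = "MD", drv$md$average$table),
                file.path(out, "model_average_md.tsv"))
      write_tsv(cbind(response = "EMF", drv$emf$average$table),
                file.path(out, "model_average_emf.tsv"))
    }
    summary <- list(
      config_hash = hash, seed = as.integer(config$seed),
      consensus_breakpoints = fits$consensus,
      emf_breakpoint = list(psi = fits$fits$emf$psi,
                            ci = c(fits$fits$emf$ci_low,
                                   fits$fits$emf$ci_high),
                            p = fits$fits$emf$p_improvement),
      turnover_breakpoint_otu = turns$otu$breakpoint,
      turnover_breakpoint_plant = turns$plant$breakpoint,
      split_density_peak = sd_$peak,
      emf_mean = rnd(mean(emf_res$mf$emf)),
      subset_curve = emf_res$curve$curve)
    if (!is.null(drv)) {
      summary$drivers <- list(
        md = list(percent_increase = drv$md$increment$percent_increase,
                  anova_p = drv$md$increment$anova_p,
                  vpa = drv$md$vpa[c("a", "b", "c", "d")]),
        emf = list(percent_increase = drv$emf$increment$percent_increase,
                   anova_p = drv$emf$increment$anova_p,
                   vpa = drv$emf$vpa[c("a", "b", "c", "d")]),
        path_emf = list(srmr = drv$path_emf$srmr,
                        effects = drv$path_emf$effects),
        path_md = list(srmr = drv$path_md$srmr,
                       effects = drv$path_md$effects))
    }
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns", pretty = TRUE)
    summary
  })
}
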