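# Seeded synthetic elevational-gradient generator with a planted fault.
# Every downstream stage (diversity, ordination, breakpoints, EMF, drivers)
# can be exercised against the known truth stored in the bundle.

#' Expected abundance under a Gaussian (coenocline) niche response
#'
#' A * exp(-(elevation - optimum)^2 / (2 tolerance^2)): unimodal, symmetric,
#' maximal at the optimum. The standard coenocline model used to plant
#' species turnover along the gradient.
#'
#' @param elevation elevation(s) in m.
#' @param optimum niche optimum (m).
#' @param tolerance niche breadth (m, > 0).
#' @param height maximum expected abundance at the optimum.
#' @return expected abundance, same length as `elevation`.
#' @export
#' @examples
#' gaussian_niche(2700, optimum = 2400, tolerance = 300, height = 10)
gaussian_niche <- function(elevation, optimum, tolerance, height = 1) {
  if (any(tolerance <= 0)) stop("tolerance must be positive")
  height * exp(-(elevation - optimum)^2 / (2 * tolerance^2))
}

#' Simulation parameters for a synthetic elevational gradient
#'
#' Defaults emulate an 18-site, 10-plots-per-site survey spanning
#' 700-3760 m with a fault planted at 2400 m (inside the 1800-3000 m band
#' within which breakpoints are searched). Species pools are replaced across
#' the fault with abruptness `pool_mixing`; geological variables step at the
#' fault; ecosystem functions respond piecewise-linearly.
#'
#' @param n_sites number of sites (default 18).
#' @param plots_per_site composite samples per site (default 10).
#' @param elev_min,elev_max gradient range in m (defaults 700 and 3760).
#' @param site_elevations optional explicit site elevations (overrides the
#'   even spacing).
#' @param fault_elev planted fault elevation psi* in m (default 2400).
#' @param pool_mixing kappa in `[0, 1]`: fraction by which the expected
#'   abundance of a taxon is suppressed on the far side of the fault
#'   (0 = no fault effect, 1 = complete pool replacement). Default 0.98.
#' @param evenness_step increase in the log-normal abundance dispersion on
#'   the strongly weathered (above-fault) terrane; larger values concentrate
#'   reads in dominant taxa and depress detected richness there, planting a
#'   direct weathering -> diversity effect. 0 disables it. Default 0.9.
#' @param n_plant_species,n_otus pool sizes (defaults 60 and 300).
#' @param mat_intercept,mat_lapse mean-annual-temperature model
#'   MAT = intercept - lapse * elevation (defaults 25 degC and
#'   0.0055 degC/m); no breakpoint is planted in MAT.
#' @param geo_step step size of geological variables at the fault, in units
#'   of their within-site SD (10% of the variable's base value; default 3).
#' @param fun_break_scale multiplier on the planted slope changes of the
#'   generated function columns (0 disables all planted function
#'   breakpoints; default 1).
#' @param noise_sd named list of noise SDs per variable family:
#'   `mat` (degC), `env`, `geo`, `fun` (function-table units).
#' @param sequencing_depth reads per sample for the OTU table (default
#'   10000).
#' @param seed integer seed (default 1).
#' @return object of class `sim_params` (validated list).
#' @export
sim_params <- function(n_sites = 18, plots_per_site = 10, elev_min = 700,
                       elev_max = 3760, site_elevations = NULL,
                       fault_elev = 2400, pool_mixing = 0.98,
                       evenness_step = 0.9,
                       n_plant_species = 60, n_otus = 300,
                       mat_intercept = 25, mat_lapse = 0.0055,
                       geo_step = 3, fun_break_scale = 1,
                       noise_sd = list(mat = 0.3, env = 0.5, geo = 1,
                                       fun = 0.5),
                       sequencing_depth = 10000, seed = 1) {
  p <- as.list(environment())
  if (is.null(p$site_elevations))
    p$site_elevations <- seq(elev_min, elev_max, length.out = n_sites)
  else p$n_sites <- length(p$site_elevations)
  if (!(elev_min < fault_elev && fault_elev < elev_max))
    stop("require elev_min < fault_elev < elev_max")
  if (pool_mixing < 0 || pool_mixing > 1) stop("pool_mixing must be in [0,1]")
  if (evenness_step < 0) stop("evenness_step must be >= 0")
  if (sequencing_depth < 1) stop("sequencing_depth must be >= 1")
  if (plots_per_site < 1 || n_sites < 4) stop("need >= 4 sites, >= 1 plot")
  for (f in c("mat", "env", "geo", "fun"))
    if (is.null(p$noise_sd[[f]]) || p$noise_sd[[f]] < 0)
      stop("noise_sd$", f, " must be a non-negative number")
  structure(p, class = "sim_params")
}

# The 38 ecosystem functions and their five functional groups.
#' Ecosystem-function group map of the synthetic bundle
#'
#' @return data.frame with columns `fn` and `group` (38 rows; groups:
#'   plant_biomass, microbial_biomass, enzyme_activity,
#'   photosynthetic_bacteria, soil_nutrients).
#' @export
function_groups <- function() {
  plant <- c("fir_biomass", "hardwood_biomass", "softwood_biomass",
             "shrub_biomass", "herb_biomass",
             "tree_density", "shrub_density", "herb_density",
             "tree_height", "shrub_height", "herb_height",
             "tree_coverage", "shrub_coverage", "herb_coverage")
  microbial <- c("plfa_bacteria", "plfa_fungi", "plfa_actinomycetes",
                 "plfa_protozoa", "bgdgt", "igdgt", "gdgt0", "crenarchaeol")
  enzyme <- c("beta_glucosidase", "amylase", "invertase", "phenol_oxidase",
              "cellulase")
  photo <- c("cyanobacteria_ra", "rhodospirillales_ra", "rhodocyclales_ra",
             "chlorobi_ra")
  nutrient <- c("toc", "tn", "tp", "wsoc", "wson", "nh4_n", "no3_n")
  data.frame(
    fn = c(plant, microbial, enzyme, photo, nutrient),
    group = rep(c("plant_biomass", "microbial_biomass", "enzyme_activity",
                  "photosynthetic_bacteria", "soil_nutrients"),
                c(length(plant), length(microbial), length(enzyme),
                  length(photo), length(nutrient))))
}

# Draw the shared truth block (niches, pools, taxonomy, coefficients).
# Two mountains sharing a fault reuse one truth with independent noise.
draw_truth <- function(params) {
  with_seed(derive_seed(params$seed, 1), {
    fault <- params$fault_elev
    span <- params$elev_max - params$elev_min
    # niche optima uniform (slightly beyond the sampled range, so edge
    # sites do not face artificially truncated pools)
    otu <- data.frame(
      taxon_id = sprintf("OTU%04d", seq_len(params$n_otus)),
      optimum = params$elev_min - 0.1 * span +
        1.2 * span * stats::runif(params$n_otus),
      tolerance = stats::runif(params$n_otus, 250, 550),
      height = stats::rlnorm(params$n_otus, 0, 1))
    otu$pool <- ifelse(otu$optimum < fault, "below", "above")
    phyla <- c("Actinobacteria", "Acidobacteria", "Chloroflexi",
               "Bacteroidetes", "Firmicutes", "Verrucomicrobia",
               "Planctomycetes", "Gemmatimonadetes", "Nitrospirae",
               "Cyanobacteria", "Chlorobi", "Proteobacteria")
    probs <- c(0.12, 0.12, 0.08, 0.07, 0.05, 0.06, 0.05, 0.04, 0.03,
               0.04, 0.04, 0.30)
    taxonomy <- data.frame(
      taxon_id = otu$taxon_id,
      phylum = sample(phyla, params$n_otus, replace = TRUE, prob = probs))
    taxonomy$class <- ifelse(
      taxonomy$phylum == "Proteobacteria",
      sample(c("Alphaproteobacteria", "Betaproteobacteria",
               "Gammaproteobacteria", "Deltaproteobacteria"),
             params$n_otus, replace = TRUE),
      NA_character_)
    plant <- data.frame(
      species = sprintf("sp%03d", seq_len(params$n_plant_species)),
      optimum = stats::runif(params$n_plant_species,
                             params$elev_min - 0.05 * span,
                             params$elev_max + 0.05 * span),
      tolerance = stats::runif(params$n_plant_species, 200, 450),
      height_n = stats::rlnorm(params$n_plant_species, log(5), 0.5))
    plant$pool <- ifelse(plant$optimum < fault, "below", "above")
    # vegetation types stratified by optimum elevation
    third <- stats::quantile(plant$optimum, c(1 / 3, 2 / 3))
    plant$type <- vapply(plant$optimum, function(mu) {
      if (mu <= third[1])
        sample(c("hardwood", "softwood", "shrub", "herb"), 1,
               prob = c(0.4, 0.2, 0.2, 0.2))
      else if (mu <= third[2])
        sample(c("softwood", "hardwood", "shrub", "herb"), 1,
               prob = c(0.3, 0.2, 0.25, 0.25))
      else
        sample(c("fir", "shrub", "herb"), 1, prob = c(0.4, 0.3, 0.3))
    }, character(1))
    gen <- function_groups()
    gen <- gen$fn[!gen$group %in% "plant_biomass"]
    nfun <- length(gen)
    has_bp <- rep(c(TRUE, FALSE), length.out = nfun)
    # Functions carrying a planted fault discontinuity respond to the
    # (linear-in-elevation) abiotic drivers plus the hinge, so their
    # elevational profile is genuinely piecewise-linear; the others are
    # biotically driven and inherit the communities' fault signature.
    # slope changes share a predominantly negative sign (most functions
    # decline more steeply above the fault) and functions tend to increase
    # with temperature, so the averaged multifunctionality index inherits a
    # coherent breakpoint instead of cancelling it out
    fun <- data.frame(
      fn = gen,
      intercept = stats::runif(nfun, 5, 15),
      b_mat = stats::rnorm(nfun, 0.3, 0.4),
      b_moist = stats::rnorm(nfun, 0, 0.5),
      b_pbio = ifelse(has_bp, 0, stats::rnorm(nfun, 0, 0.5)),
      b_div = ifelse(has_bp, 0, stats::rnorm(nfun, 0, 0.5)),
      b_break = ifelse(has_bp,
                       sample(c(-1, 1), nfun, replace = TRUE,
                              prob = c(0.75, 0.25)) *
                         stats::runif(nfun, 1.5, 2.5), 0) *
        params$fun_break_scale)
    geo_vars <- c("quartz", "plagioclase", "kfeldspar", "amphibole",
                  "muscovite", "chlorite",
                  "Ca", "Fe", "Mg", "Al", "K", "Na", "Mn", "Ti",
                  "Al2O3", "CaO_star", "Na2O", "K2O")
    geo <- data.frame(
      var = geo_vars,
      base = c(30, 20, 15, 8, 10, 7,          # minerals (%)
               3, 4, 2, 8, 2.5, 2, 0.1, 0.5,  # metals (%)
               45, 20, 18, 17),               # molar oxide proportions
      # terrane contrast: mineral steps are random per draw, but the metal
      # and oxide steps have fixed lithologically coherent signs so the
      # weathering indices (CIA, element ratios) shift consistently across
      # the fault instead of cancelling
      direction = c(sample(c(-1, 1), 6, replace = TRUE),
                    c(-1, -1, -1, 1, -1, -1, 1, 1),
                    c(1, -1, -1, -1)),
      trend = stats::rnorm(length(geo_vars), 0, 0.3))
    list(fault_elev = fault, pool_mixing = params$pool_mixing,
         mat_intercept = params$mat_intercept, mat_lapse = params$mat_lapse,
         geo_step = params$geo_step, otu_niche = otu, taxonomy = taxonomy,
         plant_niche = plant, fun_coef = fun, geo_coef = geo)
  })
}

# Per-side suppression factor of the planted fault.
fault_gate <- function(elev, pool, fault, kappa) {
  below <- pool == "below"
  ifelse((below & elev > fault) | (!below & elev <= fault), 1 - kappa, 1)
}

#' Simulate one mountain's elevational-gradient dataset
#'
#' Realizes a full plot-level dataset from [sim_params()]: Gaussian-niche
#' species pools replaced across the planted fault, multinomially sampled
#' OTU counts at fixed sequencing depth, Poisson plant counts with a plot
#' attribute table (density, coverage, height), linear climate, stepped
#' geological variables, and 38 ecosystem-function columns (plant-biomass
#' functions derived from the plant attributes via the allometric equations;
#' the others as linear/piecewise combinations of temperature, moisture,
#' plant biomass and bacterial richness plus noise). Identical parameters
#' and seed give a bit-identical bundle.
#'
#' @param params a `sim_params` object.
#' @param truth optional pre-drawn truth block (used to share species pools
#'   and the fault between mountains).
#' @param mountain mountain tag used in sample ids (default "A").
#' @param realization_offset integer added to the derived sub-seeds so a
#'   second mountain gets independent noise under the same truth.
#' @return object of class `gradient_bundle`: list with `samples`
#'   (plot-level data.frame), `otu_matrix`, `plant_matrix`,
#'   `plant_attributes`, `taxonomy`, `truth`, and `params`.
#' @export
simulate_mountain <- function(params, truth = NULL, mountain = "A",
                              realization_offset = 0) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(truth)) truth <- draw_truth(params)
  sub <- function(k) derive_seed(params$seed, 10 * (k + realization_offset))
  elev_site <- params$site_elevations
  n <- params$n_sites * params$plots_per_site
  site_id <- rep(sprintf("%s_S%02d", mountain, seq_len(params$n_sites)),
                 each = params$plots_per_site)
  sample_id <- paste0(site_id, sprintf("_P%02d",
                                       rep(seq_len(params$plots_per_site),
                                           params$n_sites)))
  elev <- rep(elev_site, each = params$plots_per_site)
  fault <- truth$fault_elev
  kappa <- truth$pool_mixing

  # --- OTU counts: multinomial at fixed depth over gated niche abundances
  otu <- truth$otu_niche
  lam <- vapply(seq_len(nrow(otu)), function(s)
    gaussian_niche(elev, otu$optimum[s], otu$tolerance[s], otu$height[s]),
    numeric(n))
  gate <- t(vapply(elev, function(e)
    fault_gate(e, otu$pool, fault, kappa), numeric(nrow(otu))))
  lam <- lam * gate
  otu_matrix <- with_seed(sub(2), {
    # communities on the strongly weathered (above-fault) terrane are less
    # even: larger multiplicative dispersion concentrates reads in dominant
    # taxa and depresses detected richness, planting a direct
    # weathering -> diversity link on top of the pool replacement
    jit_sd <- 0.3 + params$evenness_step * (elev > fault)
    jitter_ <- matrix(stats::rlnorm(n * nrow(otu), 0, rep(jit_sd, nrow(otu))),
                      n)
    ex <- lam * jitter_ + 1e-12
    t(vapply(seq_len(n), function(i)
      stats::rmultinom(1, params$sequencing_depth, ex[i, ])[, 1],
      integer(nrow(otu))))
  })
  dimnames(otu_matrix) <- list(sample_id, otu$taxon_id)

  # --- plant counts and plot attribute table
  plant <- truth$plant_niche
  plam <- t(vapply(elev, function(e)
    gaussian_niche(e, plant$optimum, plant$tolerance, plant$height_n) *
      fault_gate(e, plant$pool, fault, kappa), numeric(nrow(plant))))
  pl <- with_seed(sub(3), {
    counts <- matrix(stats::rpois(n * nrow(plant), plam), n)
    base_h <- c(fir = 25, hardwood = 18, softwood = 15, shrub = 1.5,
                herb = 0.3)[plant$type]
    base_c <- c(fir = 0.03, hardwood = 0.03, softwood = 0.03, shrub = 0.02,
                herb = 0.015)[plant$type]
    attrs <- lapply(seq_len(n), function(i) {
      pres <- which(counts[i, ] > 0)
      if (!length(pres)) return(NULL)
      k <- length(pres)
      data.frame(sample_id = sample_id[i], species = plant$species[pres],
                 type = plant$type[pres], density = counts[i, pres],
                 coverage = pmin(0.9, counts[i, pres] * base_c[pres] *
                                   stats::rlnorm(k, 0, 0.2)),
                 height = base_h[pres] * stats::rlnorm(k, 0, 0.2),
                 row.names = NULL)
    })
    list(counts = counts, attrs = do.call(rbind, attrs))
  })
  plant_matrix <- pl$counts
  dimnames(plant_matrix) <- list(sample_id, plant$species)
  plant_attributes <- pl$attrs

  # --- climate, local, geological variables
  # climate is site-scale (small interpolation error); soil pH and moisture
  # carry substantial plot-scale heterogeneity
  env <- with_seed(sub(4), data.frame(
    MAT = truth$mat_intercept - truth$mat_lapse * elev +
      stats::rnorm(n, 0, params$noise_sd$mat),
    MAP = 2800 - 0.45 * elev + stats::rnorm(n, 0, 100),
    pH = 6.8 - 0.0005 * elev + stats::rnorm(n, 0, 0.4),
    moisture = 15 + 0.01 * elev +
      stats::rnorm(n, 0, 6 * params$noise_sd$env)))
  geo <- with_seed(sub(5), {
    gc <- truth$geo_coef
    ez <- (elev - mean(range(elev_site))) / diff(range(elev_site))
    out <- vapply(seq_len(nrow(gc)), function(j) {
      scale_j <- 0.1 * gc$base[j]  # noise and step scale with the base value
      pmax(0.01,
           gc$base[j] + gc$trend[j] * gc$base[j] * ez +
             truth$geo_step * gc$direction[j] * scale_j * (elev > fault) +
             stats::rnorm(n, 0, params$noise_sd$geo * scale_j))
    }, numeric(n))
    colnames(out) <- gc$var
    as.data.frame(out)
  })

  # --- ecosystem functions
  pa <- plant_attributes
  plant_funs <- do.call(rbind, lapply(sample_id, function(sid) {
    s <- pa[pa$sample_id == sid, , drop = FALSE]
    tree <- s$type %in% c("fir", "hardwood", "softwood")
    by_type <- function(type) s[s$type == type, , drop = FALSE]
    bm <- function(type) {
      b <- by_type(type)
      if (!nrow(b)) return(0)
      sum(suppressWarnings(
        plant_biomass(b$type, b$height, b$coverage)) * b$density)
    }
    grp <- function(rows) c(
      density = sum(rows$density),
      height = if (nrow(rows)) mean(rows$height) else 0,
      coverage = min(1, sum(rows$coverage)))
    tr <- grp(s[tree, , drop = FALSE])
    sh <- grp(by_type("shrub")); hb <- grp(by_type("herb"))
    data.frame(fir_biomass = bm("fir"), hardwood_biomass = bm("hardwood"),
               softwood_biomass = bm("softwood"), shrub_biomass = bm("shrub"),
               herb_biomass = bm("herb"),
               tree_density = tr["density"], shrub_density = sh["density"],
               herb_density = hb["density"],
               tree_height = tr["height"], shrub_height = sh["height"],
               herb_height = hb["height"],
               tree_coverage = tr["coverage"], shrub_coverage = sh["coverage"],
               herb_coverage = hb["coverage"], row.names = NULL)
  }))
  rich <- apply(otu_matrix, 1, richness)
  pbio <- rowSums(plant_funs[, c("fir_biomass", "hardwood_biomass",
                                 "softwood_biomass", "shrub_biomass",
                                 "herb_biomass")])
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
                    else v * 0
  drivers <- cbind(mat = zs(env$MAT), moist = zs(env$moisture),
                   pbio = zs(pbio), div = zs(rich))
  hinge_km <- pmax(elev - fault, 0) / 1000
  gen_funs <- with_seed(sub(6), {
    fc <- truth$fun_coef
    out <- vapply(seq_len(nrow(fc)), function(j) {
      fc$intercept[j] + fc$b_mat[j] * drivers[, "mat"] +
        fc$b_moist[j] * drivers[, "moist"] +
        fc$b_pbio[j] * drivers[, "pbio"] + fc$b_div[j] * drivers[, "div"] +
        fc$b_break[j] * hinge_km +
        stats::rnorm(n, 0, params$noise_sd$fun)
    }, numeric(n))
    colnames(out) <- fc$fn
    as.data.frame(out)
  })
  samples <- cbind(
    data.frame(sample_id = sample_id, site_id = site_id, elevation = elev,
               mountain = mountain),
    env, geo, geochem_indices(geo), plant_funs, gen_funs)
  rownames(samples) <- NULL
  structure(list(samples = samples, otu_matrix = otu_matrix,
                 plant_matrix = plant_matrix,
                 plant_attributes = plant_attributes,
                 taxonomy = truth$taxonomy, truth = truth, params = params),
            class = "gradient_bundle")
}

#' Simulate two mountains sharing a fault and species pools
#'
#' Mountain B shares the truth block (fault elevation, niches, pools,
#' coefficients) of mountain A but has its own site elevations and
#' independent sampling noise, emulating a regional-consistency comparison
#' between gradients on different mountain ranges.
#'
#' @param params `sim_params` for mountain A.
#' @param offset named list of parameter overrides for mountain B (e.g.
#'   `elev_min`, `elev_max`, `n_sites`, `seed`); overlapping elevation
#'   ranges are required.
#' @param pairing_tol tolerance (m) for the matched-elevation pair metadata.
#' @return list with `A` and `B` (two `gradient_bundle`s) and `pairing`
#'   (data.frame of matched site elevations).
#' @export
simulate_two_mountains <- function(params, offset = list(), pairing_tol = 100) {
  stopifnot(inherits(params, "sim_params"))
  args <- utils::modifyList(
    params[setdiff(names(params), "n_sites")], offset,
    keep.null = TRUE)
  if (!is.null(offset$n_sites)) args$n_sites <- offset$n_sites
  if (is.null(offset$site_elevations) &&
      (!is.null(offset$elev_min) || !is.null(offset$elev_max) ||
       !is.null(offset$n_sites)))
    args$site_elevations <- NULL
  params_b <- do.call(sim_params, args[names(args) %in%
                                         names(formals(sim_params))])
  if (params_b$elev_min > params$elev_max ||
      params_b$elev_max < params$elev_min)
    stop("mountain elevation ranges do not overlap")
  truth <- draw_truth(params)
  a <- simulate_mountain(params, truth = truth, mountain = "A")
  b <- simulate_mountain(params_b, truth = truth, mountain = "B",
                         realization_offset = 1000)
  ea <- params$site_elevations
  eb <- params_b$site_elevations
  pairing <- do.call(rbind, lapply(eb, function(e) {
    gap <- abs(ea - e)
    if (min(gap) <= pairing_tol)
      data.frame(elev_b = e, elev_a = ea[which.min(gap)],
                 gap = min(gap))
  }))
  list(A = a, B = b, pairing = pairing)
}

#' @export
print.gradient_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic gradient bundle: %d samples at %d sites (%.0f-%.0f m), fault at %.0f m (kappa = %.2f)\n",
    nrow(x$samples), x$params$n_sites, min(x$params$site_elevations),
    max(x$params$site_elevations), x$truth$fault_elev, x$truth$pool_mixing))
  cat(sprintf("  %d OTUs, %d plant species, %d function columns\n",
              ncol(x$otu_matrix), ncol(x$plant_matrix),
              nrow(function_groups())))
  invisible(x)
}
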