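#' Configuration for the synthetic tumor cohort generator
#'
#' Defines the statistical structure of a simulated cohort: race and subtype
#' composition, log2-scale expression with planted differentially expressed
#' genes, correlated co-expression blocks, GISTIC-style copy-number states,
#' and censored survival with planted race-specific disparity genes whose
#' overexpression multiplies the hazard in the target race only.
#'
#' Defaults mirror a published breast-carcinoma cohort composition
#' (69% White, 17% Black/African American, 6% Asian, 8% unspecified;
#' subtype mix dominated by basal-like/TNBC and Luminal A) at a desk-scale
#' sample size. The survival scale (exponential baseline hazard
#' 0.01 events/month, uniform administrative censoring on [0, 240] months)
#' is event-rich so that survival contrasts are estimable at moderate n.
#'
#' @param n_samples number of samples.
#' @param race_fractions named fractions summing to 1.
#' @param subtype_fractions named fractions summing to 1.
#' @param n_genes number of genes.
#' @param n_de_genes planted differentially expressed genes (target race
#'   group mean shifted by `de_log2_shift`).
#' @param de_log2_shift log2-units group mean shift for planted DE genes.
#' @param n_disparity_genes planted race-specific survival-disparity genes.
#' @param overexpression_fraction fraction of target-race samples planted
#'   above the z > 2 overexpression threshold for disparity genes. The
#'   comparator race receives half this fraction with no hazard effect.
#' @param disparity_hazard_ratio multiplicative hazard for overexpressed
#'   target-race samples.
#' @param baseline_hazard exponential baseline hazard, events per month.
#' @param censor_horizon months; censoring times are uniform on [0, horizon].
#' @param n_modules number of correlated co-expression blocks.
#' @param module_size genes per block.
#' @param module_correlation target within-block Pearson correlation.
#' @param target_race,comparator_race race labels used for planting.
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 600,
                          race_fractions = c(White = 0.69, BAA = 0.17,
                                             Asian = 0.06, Unknown = 0.08),
                          subtype_fractions = c(Basal = 0.354, LumA = 0.343,
                                                LumB = 0.157, Her2 = 0.09,
                                                Normal = 0.056),
                          n_genes = 2000,
                          n_de_genes = 100,
                          de_log2_shift = 1,
                          n_disparity_genes = 20,
                          overexpression_fraction = 0.15,
                          disparity_hazard_ratio = 4,
                          baseline_hazard = 0.01,
                          censor_horizon = 240,
                          n_modules = 3,
                          module_size = 150,
                          module_correlation = 0.8,
                          target_race = "BAA",
                          comparator_race = "White",
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              race_fractions = race_fractions,
              subtype_fractions = subtype_fractions,
              n_genes = as.integer(n_genes),
              n_de_genes = as.integer(n_de_genes),
              de_log2_shift = de_log2_shift,
              n_disparity_genes = as.integer(n_disparity_genes),
              overexpression_fraction = overexpression_fraction,
              disparity_hazard_ratio = disparity_hazard_ratio,
              baseline_hazard = baseline_hazard,
              censor_horizon = censor_horizon,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_correlation = module_correlation,
              target_race = target_race,
              comparator_race = comparator_race,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  check_fractions(cfg$race_fractions, "race_fractions")
  check_fractions(cfg$subtype_fractions, "subtype_fractions")
  counts <- c("n_samples", "n_genes", "n_de_genes", "n_disparity_genes",
              "n_modules", "module_size")
  for (f in counts) if (cfg[[f]] < 0) stop(f, " must be >= 0")
  if (cfg$disparity_hazard_ratio <= 0) stop("disparity_hazard_ratio must be > 0")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (cfg$censor_horizon <= 0) stop("censor_horizon must be > 0")
  if (cfg$module_correlation < 0 || cfg$module_correlation >= 1)
    stop("module_correlation must lie in [0, 1)")
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop("module_size * n_modules exceeds n_genes")
  if (cfg$n_modules * cfg$module_size + cfg$n_de_genes + cfg$n_disparity_genes >
        cfg$n_genes)
    stop("planted gene sets (modules + DE + disparity) exceed n_genes; ",
         "they are kept disjoint")
  if (!cfg$target_race %in% names(cfg$race_fractions))
    stop("target_race not among race_fractions")
  if (!cfg$comparator_race %in% names(cfg$race_fractions))
    stop("comparator_race not among race_fractions")
  invisible(cfg)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces a log2(x+1)-scale expression matrix, a clinical table (race,
#' subtype, overall survival), GISTIC-style copy-number calls, and a `truth`
#' record of everything planted. Baseline expression is per-gene Gaussian on
#' the log2 scale (mean ~ U\[3,10\], sd ~ U\[0.5,1.5\]) truncated at 0; copy
#' number is 90% diploid with \{-2: 1%, -1: 4%, +1: 4%, +2: 1%\} and amplified
#' samples get a +1 log2 boost; survival is exponential with uniform
#' administrative censoring.
#'
#' Disparity genes receive (a) the group-level `de_log2_shift` in the target
#' race, so they traverse the differential-expression gates, and (b) planted
#' overexpression at diploid mean + 3 diploid sd for a shared per-race "risk
#' pool" of samples (a coordinated overexpression program); pool samples of
#' the target race draw their survival with hazard multiplied by
#' `disparity_hazard_ratio`. The comparator-race pool (half the fraction)
#' carries no hazard effect.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort_bundle`: list with `expression`
#'   (genes x samples), `clinical` (data.frame: sample_id, race, subtype,
#'   os_months, os_event), `copy_number` (genes x samples, values in
#'   \{-2,...,2\}), `gene_ids`, and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes

  sample_ids <- sprintf("S%04d", seq_len(n))
  race <- sample(rep(names(config$race_fractions),
                     apportion(n, config$race_fractions)))
  subtype <- sample(rep(names(config$subtype_fractions),
                        apportion(n, config$subtype_fractions)))
  gene_ids <- sprintf("G%04d", seq_len(g))

  # disjoint planted index sets
  pool_idx <- sample.int(g)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- pool_idx[seq_len(k)]
    pool_idx <<- pool_idx[-seq_len(k)]
    out
  }
  module_idx <- if (config$n_modules > 0)
    lapply(seq_len(config$n_modules), function(i) take(config$module_size))
  else list()
  de_idx <- take(config$n_de_genes)
  disp_idx <- take(config$n_disparity_genes)

  mu_g <- stats::runif(g, 3, 10)
  sd_g <- stats::runif(g, 0.5, 1.5)
  eps <- matrix(stats::rnorm(g * n), nrow = g)
  rho <- config$module_correlation
  for (b in seq_along(module_idx)) {
    f <- stats::rnorm(n)
    idx <- module_idx[[b]]
    eps[idx, ] <- sqrt(rho) * matrix(f, length(idx), n, byrow = TRUE) +
      sqrt(1 - rho) * eps[idx, ]
  }
  expr <- mu_g + sd_g * eps

  cn <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), g * n, replace = TRUE,
                      prob = c(0.01, 0.04, 0.90, 0.04, 0.01)), nrow = g)
  expr[cn == 2L] <- expr[cn == 2L] + 1

  is_target <- race == config$target_race
  is_comp <- race == config$comparator_race
  if (length(de_idx))
    expr[de_idx, is_target] <- expr[de_idx, is_target] + config$de_log2_shift
  if (length(disp_idx))
    expr[disp_idx, is_target] <- expr[disp_idx, is_target] + config$de_log2_shift

  # shared per-race risk pools for the disparity program
  target_pool <- integer(0)
  comp_pool <- integer(0)
  if (config$n_disparity_genes > 0 && config$overexpression_fraction > 0) {
    target_pool <- sample(which(is_target),
                          round(config$overexpression_fraction * sum(is_target)))
    comp_pool <- sample(which(is_comp),
                        round(config$overexpression_fraction / 2 * sum(is_comp)))
    planted <- c(target_pool, comp_pool)
    for (i in disp_idx) {
      dip <- cn[i, ] == 0L
      m <- mean(expr[i, dip])
      s <- stats::sd(expr[i, dip])
      expr[i, planted] <- m + 3 * s +
        stats::rnorm(length(planted), 0, 0.05 * s)
    }
  }
  expr[expr < 0] <- 0

  hazard <- rep(config$baseline_hazard, n)
  hazard[target_pool] <- hazard[target_pool] * config$disparity_hazard_ratio
  t_event <- stats::rexp(n, hazard)
  t_censor <- stats::runif(n, 0, config$censor_horizon)
  os_months <- pmin(t_event, t_censor)
  os_event <- as.integer(t_event <= t_censor)

  dimnames(expr) <- list(gene_ids, sample_ids)
  dimnames(cn) <- list(gene_ids, sample_ids)
  clinical <- data.frame(sample_id = sample_ids, race = race,
                         subtype = subtype, os_months = os_months,
                         os_event = os_event, stringsAsFactors = FALSE)
  modules <- stats::setNames(rep("unassigned", g), gene_ids)
  for (b in seq_along(module_idx))
    modules[module_idx[[b]]] <- paste0("B", b)

  truth <- list(de_genes = gene_ids[de_idx],
                disparity_genes = gene_ids[disp_idx],
                modules = modules,
                target_pool = sample_ids[target_pool],
                comparator_pool = sample_ids[comp_pool],
                de_log2_shift = config$de_log2_shift,
                disparity_hazard_ratio = config$disparity_hazard_ratio,
                target_race = config$target_race,
                comparator_race = config$comparator_race)
  structure(list(expression = expr, clinical = clinical, copy_number = cn,
                 gene_ids = gene_ids, truth = truth,
                 config = config),
            class = "cohort_bundle")
}

#' Generate named gene sets, optionally with a planted driver association
#'
#' Draws `n_sets` random sets from `universe`. When `planted_driver` and a
#' `cohort_bundle` are supplied, the members of the first `n_planted_sets`
#' sets are redrawn in the bundle's expression matrix so that each member is
#' correlated (target Pearson `planted_correlation`) with the driver gene's
#' expression; GSEA on driver-high vs driver-low phenotypes then enriches
#' those sets.
#'
#' @param universe character vector of gene ids.
#' @param n_sets number of sets.
#' @param set_size members per set.
#' @param seed RNG seed.
#' @param planted_driver gene id or NULL.
#' @param n_planted_sets number of leading sets to associate with the driver.
#' @param planted_correlation target gene-driver correlation.
#' @param bundle `cohort_bundle` whose expression is modified for planting.
#' @return list with `sets` (named list), `truth` (planted metadata) and
#'   `bundle` (the possibly modified bundle, or NULL).
#' @export
generate_gene_sets <- function(universe, n_sets, set_size, seed = 1L,
                               planted_driver = NULL, n_planted_sets = 0,
                               planted_correlation = 0.8, bundle = NULL) {
  if (length(universe) == 0) stop("empty universe")
  if (set_size > length(universe)) stop("set_size exceeds universe size")
  set.seed(as.integer(seed))
  sets <- lapply(seq_len(n_sets), function(i) sample(universe, set_size))
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  truth <- list(planted_sets = character(0), planted_genes = character(0),
                driver = planted_driver)
  if (!is.null(planted_driver) && n_planted_sets > 0) {
    if (is.null(bundle)) stop("planting a driver requires a cohort bundle")
    if (!planted_driver %in% rownames(bundle$expression))
      stop("planted_driver not in bundle expression")
    z_drv <- as.numeric(scale(bundle$expression[planted_driver, ]))
    nsmp <- length(z_drv)
    planted_sets <- names(sets)[seq_len(min(n_planted_sets, n_sets))]
    planted_genes <- setdiff(unique(unlist(sets[planted_sets])), planted_driver)
    rho <- planted_correlation
    for (gid in planted_genes) {
      row <- bundle$expression[gid, ]
      m <- mean(row); s <- stats::sd(row)
      if (s == 0) s <- 1
      bundle$expression[gid, ] <- m + s * (sqrt(rho) * z_drv +
        sqrt(1 - rho) * stats::rnorm(nsmp))
    }
    bundle$expression[bundle$expression < 0] <- 0
    truth$planted_sets <- planted_sets
    truth$planted_genes <- planted_genes
    truth$planted_correlation <- rho
  }
  list(sets = sets, truth = truth, bundle = bundle)
}

#' Generate a class-labeled segmentation mask with exact ground truth
#'
#' Places `n_nests` disjoint circular tumor nests (class 1) on a canvas and
#' fills the remaining pixels with the background classes \{0 ignore,
#' 2 stroma, 3 TILs, 4 necrosis, 5 other\} in exact largest-remainder
#' proportions of `class_fractions`. Nests are separated by at least two
#' pixels so they remain distinct 8-connected components.
#'
#' @param width,height canvas size in pixels.
#' @param n_nests number of tumor nests.
#' @param nest_radius_range length-2 radius range in pixels.
#' @param class_fractions named fractions over background classes
#'   `c(ignore, stroma, tils, necrosis, other)`, summing to 1.
#' @param seed RNG seed.
#' @param max_attempts placement attempts before giving up.
#' @return list with `mask` (integer matrix) and `truth` (class pixel counts,
#'   per-nest area/centroid/radius, exact global ratios).
#' @export
generate_masks <- function(width, height, n_nests,
                           nest_radius_range = c(5, 15),
                           class_fractions = c(ignore = 0.1, stroma = 0.5,
                                               tils = 0.2, necrosis = 0.1,
                                               other = 0.1),
                           seed = 1L, max_attempts = 200 * max(1, n_nests)) {
  check_fractions(class_fractions, "class_fractions")
  needed <- c("ignore", "stroma", "tils", "necrosis", "other")
  if (!setequal(names(class_fractions), needed))
    stop("class_fractions must be named: ", paste(needed, collapse = ", "))
  set.seed(as.integer(seed))
  mask <- matrix(0L, nrow = height, ncol = width)
  nests <- data.frame(nest = integer(0), cx = numeric(0), cy = numeric(0),
                      radius = numeric(0), area = integer(0))
  placed <- 0L
  attempts <- 0L
  centers <- matrix(numeric(0), ncol = 3)  # cx, cy, r
  while (placed < n_nests) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n_nests, " nests after ", max_attempts,
           " attempts")
    r <- stats::runif(1, nest_radius_range[1], nest_radius_range[2])
    cx <- stats::runif(1, r + 2, width - r - 1)
    cy <- stats::runif(1, r + 2, height - r - 1)
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (any(d < centers[, 3] + r + 3)) next
    }
    xs <- pmax(1L, floor(cx - r)):pmin(width, ceiling(cx + r))
    ys <- pmax(1L, floor(cy - r)):pmin(height, ceiling(cy + r))
    grid <- expand.grid(y = ys, x = xs)
    inside <- (grid$x - cx)^2 + (grid$y - cy)^2 <= r^2
    pix <- grid[inside, ]
    if (nrow(pix) == 0) next
    mask[cbind(pix$y, pix$x)] <- 1L
    placed <- placed + 1L
    centers <- rbind(centers, c(cx, cy, r))
    nests <- rbind(nests, data.frame(nest = placed, cx = mean(pix$x),
                                     cy = mean(pix$y), radius = r,
                                     area = nrow(pix)))
  }
  bg <- which(mask == 0L)
  counts <- apportion(length(bg), class_fractions)
  labels <- c(0L, 2L, 3L, 4L, 5L)
  mask[sample(bg)] <- rep(labels, counts)
  class_counts <- stats::setNames(
    vapply(0:5, function(k) sum(mask == k), integer(1)),
    as.character(0:5))
  n_tumor <- class_counts[["1"]]
  n_stroma <- class_counts[["2"]]
  truth <- list(class_counts = class_counts,
                nests = nests,
                tumor_stroma_ratio = if (n_stroma > 0) n_tumor / n_stroma else NA_real_,
                stromal_til_score = if (n_stroma + class_counts[["3"]] > 0)
                  class_counts[["3"]] / (class_counts[["3"]] + n_stroma) else NA_real_,
                necrosis_tumor_ratio = if (n_tumor > 0)
                  class_counts[["4"]] / n_tumor else NA_real_)
  list(mask = mask, truth = truth)
}
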