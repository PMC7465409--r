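#' Write a cohort bundle to TSV/JSON files
#'
#' Writes `expression.tsv`, `clinical.tsv`, `copy_number.tsv` and, when
#' ground truth is present, `truth.json`.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  write_matrix_tsv(bundle$copy_number, file.path(dir, "copy_number.tsv"))
  utils::write.table(bundle$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    tr$modules <- as.list(tr$modules)
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

required_clinical_cols <- c("sample_id", "race", "subtype", "os_months",
                            "os_event")

#' Load a cohort bundle from TSV files
#'
#' Validates the clinical schema, aligns the expression and copy-number
#' columns to the clinical rows by sample id (dropping, with a warning,
#' samples absent from any one of the three files), and checks value
#' domains.
#'
#' @param dir directory containing `expression.tsv`, `clinical.tsv`,
#'   `copy_number.tsv` (and optionally `truth.json`).
#' @return a `cohort_bundle`.
#' @export
load_cohort <- function(dir) {
  expr <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  cn <- read_matrix_tsv(file.path(dir, "copy_number.tsv"))
  clin <- utils::read.delim(file.path(dir, "clinical.tsv"),
                            stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_clinical_cols, names(clin))
  if (length(missing_cols) > 0)
    stop("clinical table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(clin$sample_id)) stop("duplicate sample ids in clinical")
  if (!all(clin$os_event %in% c(0, 1))) stop("os_event must be 0/1")
  if (any(clin$os_months < 0)) stop("os_months must be >= 0")
  if (!all(cn %in% c(-2, -1, 0, 1, 2)))
    stop("copy-number calls must lie in {-2,-1,0,1,2}")
  common <- Reduce(intersect, list(clin$sample_id, colnames(expr),
                                   colnames(cn)))
  dropped <- length(unique(c(clin$sample_id, colnames(expr),
                             colnames(cn)))) - length(common)
  if (dropped > 0)
    warning(dropped, " sample(s) not shared by all three files were dropped")
  if (length(common) == 0) stop("no samples shared across files")
  clin <- clin[match(common, clin$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  if (!identical(sort(rownames(expr)), sort(rownames(cn))))
    stop("expression and copy-number gene sets differ")
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    if (!is.null(truth$modules)) truth$modules <- unlist(truth$modules)
  }
  storage.mode(cn) <- "integer"
  structure(list(expression = expr[, common, drop = FALSE],
                 clinical = clin,
                 copy_number = cn[rownames(expr), common, drop = FALSE],
                 gene_ids = rownames(expr), truth = truth),
            class = "cohort_bundle")
}

#' Cohort composition summary
#'
#' Race counts with whole-number percentages of the cohort, and subtype
#' counts within each race (with a consistency check that subtype counts sum
#' to the race total).
#'
#' @param clinical clinical table with `race` and `subtype`.
#' @return list with `n`, `race` (data.frame: race, n, pct) and
#'   `subtype_by_race` (table).
#' @export
cohort_summary <- function(clinical) {
  n <- nrow(clinical)
  tab <- sort(table(clinical$race), decreasing = TRUE)
  race <- data.frame(race = names(tab), n = as.integer(tab),
                     pct = round(100 * as.integer(tab) / n),
                     stringsAsFactors = FALSE)
  sub_tab <- table(clinical$race, clinical$subtype)
  stopifnot(all(rowSums(sub_tab) == table(clinical$race)[rownames(sub_tab)]))
  list(n = n, race = race, subtype_by_race = sub_tab)
}

#' Run the full disparity analysis pipeline
#'
#' Executes simulate (or load) -> differential expression -> overexpression
#' status -> co-expression modules -> survival-disparity prioritization ->
#' GSEA, honoring stage toggles, and writes all artifacts plus a JSON run
#' report. The global seed is fanned out to per-stage child seeds by stable
#' hashing of the stage names, so disabling one stage does not shift the
#' randomness of the others.
#'
#' @param config nested list (or path to a YAML file) with entries:
#'   `simulate` (arguments for [cohort_config()]) or `input_dir`; optional
#'   `stages` (named logicals: de, modules, prioritize, gsea); optional
#'   threshold overrides (`q_threshold`, `min_pct_difference`,
#'   `min_over_fraction`, `min_module_size`, `n_permutations`, `n_gene_sets`,
#'   `gene_set_size`); `outdir`; `seed`.
#' @return the run report (list), invisibly written to
#'   `<outdir>/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir %||% tempfile("disparity_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- utils::modifyList(list(de = TRUE, modules = TRUE,
                                   prioritize = TRUE, gsea = TRUE),
                              config$stages %||% list())
  report <- list(seed = seed, stages = stages)

  if (!is.null(config$input_dir)) {
    bundle <- load_cohort(config$input_dir)
    target <- config$target_race %||% "BAA"
    comparator <- config$comparator_race %||% "White"
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- stage_seed(seed, "simulate")
    cfg <- do.call(cohort_config, sim_args)
    bundle <- generate_cohort(cfg)
    write_cohort(bundle, file.path(outdir, "cohort"))
    target <- cfg$target_race
    comparator <- cfg$comparator_race
  }
  report$cohort <- list(n_samples = nrow(bundle$clinical),
                        n_genes = nrow(bundle$expression))
  report$summary <- cohort_summary(bundle$clinical)["race"]

  q_threshold <- config$q_threshold %||% 0.001
  min_pct <- config$min_pct_difference %||% 20
  min_over <- config$min_over_fraction %||% 0.05

  gene_classes <- NULL
  status <- NULL
  if (stages$de) {
    de <- de_table(bundle$expression, bundle$clinical, group_a = target,
                   group_b = comparator, q_threshold = q_threshold,
                   min_pct_difference = min_pct)
    status <- expression_status_matrix(bundle$expression, bundle$copy_number)
    gene_classes <- classify_de_genes(de, status, bundle$clinical,
                                      q_threshold, min_pct, min_over, target)
    utils::write.table(de, file.path(outdir, "de_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_matrix_tsv(status$status, file.path(outdir, "status_matrix.tsv"))
    report$de <- list(n_tested = nrow(de),
                      n_baa_high = length(gene_classes$BAA_high),
                      n_baa_low = length(gene_classes$BAA_low),
                      n_baa_ovr = length(gene_classes$BAA_OVR))
  }

  if (stages$modules && stages$de) {
    de_genes <- c(gene_classes$BAA_high, gene_classes$BAA_low)
    min_mod <- config$min_module_size %||% 100
    if (length(de_genes) >= 50 && ncol(bundle$expression) >= 10) {
      sub <- bundle$expression[de_genes, , drop = FALSE]
      pst <- pick_soft_threshold(sub)
      adj <- signed_adjacency(stats::cor(t(sub)), pst$beta)
      tom <- topological_overlap(adj)
      mods <- detect_modules(tom, min_module_size = min_mod)
      utils::write.table(
        data.frame(gene = names(mods$assignment), module = mods$assignment),
        file.path(outdir, "modules.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      report$modules <- list(beta = pst$beta,
                             reached_target = pst$reached_target,
                             n_modules = length(mods$sizes),
                             sizes = as.list(mods$sizes))
    } else {
      report$modules <- list(skipped = "fewer than 50 DE genes")
    }
  }

  if (stages$prioritize && stages$de) {
    candidates <- gene_classes$BAA_OVR
    if (length(candidates) > 0) {
      profiles <- survival_profiles(candidates, bundle, status,
                                    target_race = target,
                                    comparator_race = comparator)
      pri <- apply_prioritization(profiles)
      utils::write.table(pri, file.path(outdir, "prioritization.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      groups <- c(i = sum(pri$group_i), ii = sum(pri$group_ii),
                  iii = sum(pri$group_iii), iv = sum(pri$group_iv))
      stopifnot(groups["ii"] <= groups["i"], groups["iii"] <= groups["ii"],
                groups["iv"] <= groups["iii"])
      report$prioritize <- list(n_candidates = length(candidates),
                                group_sizes = as.list(groups),
                                group_iv_genes = pri$gene[pri$group_iv])
      if (!is.null(bundle$truth$disparity_genes)) {
        planted <- bundle$truth$disparity_genes
        found <- pri$gene[pri$group_iv]
        report$prioritize$recall <-
          if (length(planted) > 0)
            length(intersect(found, planted)) / length(planted) else NA
        report$prioritize$false_positives <- length(setdiff(found, planted))
      }
    } else {
      report$prioritize <- list(n_candidates = 0L)
    }
  }

  if (stages$gsea && stages$de) {
    driver <- config$gsea_phenotype_gene %||%
      (if (!is.null(bundle$truth$disparity_genes) &&
           length(bundle$truth$disparity_genes) > 0)
        bundle$truth$disparity_genes[1] else bundle$gene_ids[1])
    gs <- generate_gene_sets(bundle$gene_ids,
                             n_sets = config$n_gene_sets %||% 10,
                             set_size = config$gene_set_size %||% 50,
                             seed = stage_seed(seed, "gene_sets"))
    res <- gsea(bundle$expression, driver, gs$sets,
                n_permutations = config$n_permutations %||% 200,
                seed = stage_seed(seed, "gsea"))
    utils::write.table(res$table, file.path(outdir, "gsea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gmt(res$leading_edges, file.path(outdir, "leading_edges.gmt"))
    report$gsea <- list(phenotype_gene = driver,
                        n_sets = nrow(res$table),
                        n_significant = sum(res$table$p < 0.05),
                        core_genes = length(core_enrichment_union(res)))
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$outdir <- outdir
  invisible(report)
}
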