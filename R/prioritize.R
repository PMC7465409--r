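#' Race-stratified survival profile of one gene's overexpression
#'
#' Within each race, samples are split by the gene's expression status into
#' overexpressed vs normal (underexpressed and undefined samples are
#' excluded); the two strata are compared by log-rank and summarized by
#' restricted mean survival time (MST). A cross-race log-rank compares the
#' two races' overexpressed strata. Strata with fewer than
#' `min_over_samples` overexpressed (or normal) samples yield undefined
#' statistics with a sufficiency flag, never silent zeros.
#'
#' MST integration uses each stratum's own maximum observed time by default
#' (`common_horizon = FALSE`); with `common_horizon = TRUE` all strata of a
#' comparison share the larger maximum, which makes ratios cleaner.
#'
#' @param gene gene id.
#' @param bundle a `cohort_bundle` (or any list with `clinical`).
#' @param status_matrix an [expression_status_matrix()] result covering the gene.
#' @param target_race,comparator_race race labels (default "BAA" vs "White").
#' @param min_over_samples minimum stratum size (default 3).
#' @param common_horizon logical; see above.
#' @return one-row data.frame with over/normal counts and frequencies,
#'   p_target, p_comparator, p_cross (log-rank p), the four MSTs,
#'   `mst_fold_target` (MST_norm/MST_over in the target race),
#'   `mst_race_ratio` (MST_over_comparator/MST_over_target), and a
#'   `sufficient` flag.
#' @export
gene_survival_profile <- function(gene, bundle, status_matrix,
                                  target_race = "BAA",
                                  comparator_race = "White",
                                  min_over_samples = 3,
                                  common_horizon = FALSE) {
  if (!gene %in% rownames(status_matrix$status))
    stop("gene absent from status matrix: ", gene)
  clin <- bundle$clinical
  st <- status_matrix$status[gene, ]
  one_race <- function(race) {
    idx <- clin$race == race
    if (!any(idx))
      return(list(ok = FALSE, n_over = 0L, n_norm = 0L, freq = NA_real_,
                  p = NA_real_, mst_over = NA_real_, mst_norm = NA_real_))
    over <- idx & st == "over"
    norm <- idx & st == "normal"
    n_def <- sum(idx & st != "undefined")
    freq <- if (n_def > 0) sum(over) / n_def else NA_real_
    if (sum(over) < min_over_samples || sum(norm) < min_over_samples)
      return(list(ok = FALSE, n_over = sum(over), n_norm = sum(norm),
                  freq = freq, p = NA_real_, mst_over = NA_real_,
                  mst_norm = NA_real_, over = over, norm = norm))
    lr <- logrank(clin$os_months[over], clin$os_event[over],
                  clin$os_months[norm], clin$os_event[norm])
    hz <- if (common_horizon)
      max(clin$os_months[over | norm]) else NULL
    mst_over <- mean_survival_time(km_fit(clin$os_months[over],
                                          clin$os_event[over]), hz)
    mst_norm <- mean_survival_time(km_fit(clin$os_months[norm],
                                          clin$os_event[norm]), hz)
    list(ok = TRUE, n_over = sum(over), n_norm = sum(norm), freq = freq,
         p = lr$p, mst_over = mst_over, mst_norm = mst_norm,
         over = over, norm = norm)
  }
  tgt <- one_race(target_race)
  cmp <- one_race(comparator_race)
  p_cross <- NA_real_
  mst_race_ratio <- NA_real_
  if (tgt$ok && cmp$ok) {
    lr <- logrank(clin$os_months[cmp$over], clin$os_event[cmp$over],
                  clin$os_months[tgt$over], clin$os_event[tgt$over])
    p_cross <- lr$p
    if (common_horizon) {
      hz <- max(clin$os_months[cmp$over | tgt$over])
      m_cmp <- mean_survival_time(km_fit(clin$os_months[cmp$over],
                                         clin$os_event[cmp$over]), hz)
      m_tgt <- mean_survival_time(km_fit(clin$os_months[tgt$over],
                                         clin$os_event[tgt$over]), hz)
      mst_race_ratio <- m_cmp / m_tgt
    } else {
      mst_race_ratio <- cmp$mst_over / tgt$mst_over
    }
  }
  data.frame(gene = gene,
             n_over_target = tgt$n_over, n_over_comparator = cmp$n_over,
             over_freq_target = tgt$freq, over_freq_comparator = cmp$freq,
             p_target = tgt$p, p_comparator = cmp$p, p_cross = p_cross,
             mst_over_target = tgt$mst_over, mst_norm_target = tgt$mst_norm,
             mst_over_comparator = cmp$mst_over,
             mst_norm_comparator = cmp$mst_norm,
             mst_fold_target = tgt$mst_norm / tgt$mst_over,
             mst_race_ratio = mst_race_ratio,
             sufficient = tgt$ok && cmp$ok,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Survival profiles for a set of candidate genes
#'
#' @param genes character vector (typically the BAA_OVR set).
#' @inheritParams gene_survival_profile
#' @return data.frame, one row per gene.
#' @export
survival_profiles <- function(genes, bundle, status_matrix,
                              target_race = "BAA", comparator_race = "White",
                              min_over_samples = 3, common_horizon = FALSE) {
  do.call(rbind, lapply(genes, gene_survival_profile, bundle = bundle,
                        status_matrix = status_matrix,
                        target_race = target_race,
                        comparator_race = comparator_race,
                        min_over_samples = min_over_samples,
                        common_horizon = common_horizon))
}

#' Apply the nested Group I-IV survival-disparity criteria
#'
#' Group I: overexpression correlates with decreased target-race survival
#' (p_target < 0.05). Group II: additionally more than `mst_fold_min`-fold
#' decreased restricted mean survival (MST_normal/MST_over). Group III:
#' additionally no comparator-race effect (p_comparator > 0.1). Group IV:
#' the most stringent race-specific tier: p_target < 0.01, p_comparator >
#' 0.1, cross-race log-rank p < 0.05 among overexpressed patients, and the
#' comparator-to-target overexpressed MST ratio above `mst_race_ratio_min`;
#' membership is additionally intersected with Group III so the tiers nest.
#' Genes with insufficient strata are excluded from all groups.
#'
#' @param profiles a [survival_profiles()] data.frame.
#' @param p_target_i Group I gate on p_target (default 0.05).
#' @param mst_fold_min Group II fold gate (default 2).
#' @param p_comparator_min Group III gate (default 0.1).
#' @param p_target_iv Group IV gate on p_target (default 0.01).
#' @param p_cross_max Group IV cross-race gate (default 0.05).
#' @param mst_race_ratio_min Group IV MST ratio gate (default 2).
#' @return data.frame sorted by p_target ascending with logical columns
#'   group_i..group_iv; nesting (II within I, III within II, IV within III)
#'   is asserted.
#' @export
apply_prioritization <- function(profiles, p_target_i = 0.05,
                                 mst_fold_min = 2, p_comparator_min = 0.1,
                                 p_target_iv = 0.01, p_cross_max = 0.05,
                                 mst_race_ratio_min = 2) {
  pr <- profiles
  ok <- pr$sufficient & !is.na(pr$p_target)
  gi <- ok & pr$p_target < p_target_i
  gii <- gi & !is.na(pr$mst_fold_target) & pr$mst_fold_target > mst_fold_min
  giii <- gii & !is.na(pr$p_comparator) & pr$p_comparator > p_comparator_min
  giv <- giii & pr$p_target < p_target_iv &
    !is.na(pr$p_cross) & pr$p_cross < p_cross_max &
    !is.na(pr$mst_race_ratio) & pr$mst_race_ratio > mst_race_ratio_min
  pr$group_i <- gi; pr$group_ii <- gii
  pr$group_iii <- giii; pr$group_iv <- giv
  stopifnot(all(pr$group_ii <= pr$group_i),
            all(pr$group_iii <= pr$group_ii),
            all(pr$group_iv <= pr$group_iii))
  pr[order(pr$p_target), , drop = FALSE]
}
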