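#' Protein-to-lipid ratio
#'
#' The dimensionless P:L mass ratio of a pollen provision or diet, the
#' standard nutritional-geometry proxy for a bee's nutritional niche
#' position. Scale-invariant: only the ratio of the two concentrations
#' matters, not their units, as long as both use the same ones.
#'
#' @param protein Protein concentration (>= 0), e.g. in µg per mg dry mass.
#' @param lipid Lipid concentration (> 0), same units. Vectorized.
#' @return `protein / lipid`.
#' @examples
#' pl_ratio(191.40, 443.18)  # high-lipid diet, ~0.4
#' pl_ratio(217.76, 34.38)   # red maple pollen, ~6.3
#' @export
pl_ratio <- function(protein, lipid) {
  if (any(!is.finite(protein)) || any(!is.finite(lipid))) {
    stop("protein and lipid must be finite numbers")
  }
  if (any(protein < 0)) stop("protein concentration must be >= 0")
  if (any(lipid <= 0)) stop("lipid concentration must be > 0")
  protein / lipid
}

#' Nutritional niche summary of provision samples
#'
#' Per group (all samples, per site, or per week) and per metric (protein,
#' lipid, and the per-sample P:L ratio — never the ratio of means),
#' summarises n, mean, standard error (sample SD over the square root of n;
#' `NA` when n = 1), minimum and maximum. The mean ratio locates the
#' species' nutritional target; the range describes its realized niche
#' breadth.
#'
#' @param samples Data frame with columns `protein_ug_mg`, `lipid_ug_mg`,
#'   and, when grouping, `site` or `week`.
#' @param group_by `"none"` (default), `"site"` or `"week"`.
#' @return Data frame with columns `group`, `metric`, `n`, `mean`, `se`,
#'   `min`, `max`.
#' @export
niche_summary <- function(samples, group_by = c("none", "site", "week")) {
  group_by <- match.arg(group_by)
  stopifnot(is.data.frame(samples),
            all(c("protein_ug_mg", "lipid_ug_mg") %in% names(samples)))
  if (nrow(samples) == 0L) stop("no samples to summarize")
  grp <- if (group_by == "none") rep("all", nrow(samples)) else {
    if (!group_by %in% names(samples)) {
      stop("grouping column '", group_by, "' not present")
    }
    as.character(samples[[group_by]])
  }
  ratio <- pl_ratio(samples$protein_ug_mg, samples$lipid_ug_mg)
  metrics <- list(protein = samples$protein_ug_mg,
                  lipid = samples$lipid_ug_mg, ratio = ratio)
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    do.call(rbind, lapply(names(metrics), function(mname) {
      x <- metrics[[mname]][sel]
      data.frame(group = g, metric = mname, n = length(x), mean = mean(x),
                 se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_,
                 min = min(x), max = max(x), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Formulate a diet to a target P:L ratio
#'
#' Computes the additive masses needed to bring a base pollen from its
#' native P:L ratio to a target ratio, by adding a protein additive (e.g.
#' casein) or a lipid additive (e.g. canola oil) — never both, since a
#' single additive suffices to move the ratio in one direction.
#'
#' The default convention expresses resulting concentrations per mg of base
#' pollen, ignoring the mass the additive itself contributes (so adding only
#' lipid leaves the protein concentration unchanged, the convention
#' experimental diet tables use). `dilution_aware = TRUE` instead divides
#' both resulting concentrations by the total mixture mass; the additive
#' masses and the resulting ratio are identical under either convention,
#' because dilution scales protein and lipid equally.
#'
#' @param base_protein,base_lipid Base pollen concentrations in µg per mg.
#' @param target_ratio Desired P:L ratio (> 0).
#' @param protein_purity,lipid_purity Fraction of additive mass that is
#'   protein (resp. lipid), in `(0, 1]`; both default to 1 (pure additives).
#' @param dilution_aware Report concentrations per mg of total mixture
#'   instead of per mg of base pollen (default `FALSE`).
#' @return A list: `protein_additive_mg`, `lipid_additive_mg` (mg additive
#'   per mg base pollen), `protein_ug_mg`, `lipid_ug_mg` (resulting
#'   composition), `ratio` (the achieved P:L ratio).
#' @examples
#' # take 5.5:1 base pollen down to the 0.4:1 high-lipid diet
#' formulate_diet(191.40, 34.40, target_ratio = 191.40 / 443.18)
#' @export
formulate_diet <- function(base_protein, base_lipid, target_ratio,
                           protein_purity = 1, lipid_purity = 1,
                           dilution_aware = FALSE) {
  stopifnot(base_protein >= 0, base_lipid > 0)
  if (!is.finite(target_ratio) || target_ratio <= 0) {
    stop("target ratio must be > 0")
  }
  if (protein_purity <= 0 || protein_purity > 1 ||
      lipid_purity <= 0 || lipid_purity > 1) {
    stop("additive purities must be in (0, 1]")
  }
  r0 <- base_protein / base_lipid
  a_p <- 0; a_l <- 0
  if (target_ratio < r0) {
    a_l <- (base_protein / target_ratio - base_lipid) / (1000 * lipid_purity)
  } else if (target_ratio > r0) {
    a_p <- (target_ratio * base_lipid - base_protein) / (1000 * protein_purity)
  }
  p <- base_protein + 1000 * protein_purity * a_p
  l <- base_lipid + 1000 * lipid_purity * a_l
  if (isTRUE(dilution_aware)) {
    tot <- 1 + a_p + a_l
    p <- p / tot
    l <- l / tot
  }
  list(protein_additive_mg = a_p, lipid_additive_mg = a_l,
       protein_ug_mg = p, lipid_ug_mg = l, ratio = pl_ratio(p, l))
}

#' Rearing-outcome survival summary per diet group
#'
#' Summarises in vitro rearing records into per-diet survival and timing
#' tables ready for downstream statistics. Larval survival (% cocoons
#' completed) is computed over all individuals in the group; pupation and
#' adult survival percentages are computed over cocoon completers only, the
#' convention under which later-stage models include only survivors of the
#' larval stage. Medians ignore unknown timings.
#'
#' @param records Data frame with columns `individual_id`, `diet`,
#'   `cocoon_completed`, `pupated`, `adult_survived` (logicals) and
#'   optionally `days_to_cocoon`, `days_to_pupation` (numeric, `NA` =
#'   unknown). Stage outcomes must be nested: pupated implies cocoon
#'   completed, adult survival implies pupated.
#' @return Data frame with one row per diet: `diet`, `n`, `pct_cocoon`,
#'   `pct_pupated`, `pct_adult`, `median_days_to_cocoon`,
#'   `median_days_to_pupation`. Percentages over an empty denominator are
#'   `NA`.
#' @export
survival_summary <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("individual_id", "diet", "cocoon_completed", "pupated",
                  "adult_survived") %in% names(records)))
  bad <- records$individual_id[(records$pupated & !records$cocoon_completed) |
                                 (records$adult_survived & !records$pupated)]
  if (length(bad)) {
    stop("stage outcomes out of order for individual(s): ",
         paste(bad, collapse = ", "))
  }
  dtc <- if ("days_to_cocoon" %in% names(records)) {
    records$days_to_cocoon
  } else rep(NA_real_, nrow(records))
  dtp <- if ("days_to_pupation" %in% names(records)) {
    records$days_to_pupation
  } else rep(NA_real_, nrow(records))
  out <- do.call(rbind, lapply(sort(unique(records$diet)), function(d) {
    sel <- records$diet == d
    n <- sum(sel)
    n_coc <- sum(records$cocoon_completed[sel])
    data.frame(
      diet = d, n = n,
      pct_cocoon = 100 * n_coc / n,
      pct_pupated = if (n_coc > 0) 100 * sum(records$pupated[sel]) / n_coc
                    else NA_real_,
      pct_adult = if (n_coc > 0) 100 * sum(records$adult_survived[sel]) / n_coc
                  else NA_real_,
      median_days_to_cocoon = median(dtc[sel], na.rm = TRUE),
      median_days_to_pupation = median(dtp[sel], na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
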