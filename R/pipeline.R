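#' End-to-end analysis of a study dataset
#'
#' Drives the full analysis over a `study_dataset` (generated by [gen_study]
#' or loaded by [read_study]): per-cell morphometry, per-bird aggregation,
#' stereological quantification, and the group-comparison battery.
#'
#' @name pipeline
NULL

# plain-numeric descriptor computation (hot path for simulations)
soma_metrics_num <- function(c) {
  a <- signed_area2(c) / 2
  n <- nrow(c)
  d <- c[c(2:n, 1L), , drop = FALSE] - c
  p <- sum(sqrt(rowSums(d^2)))
  fmax <- feret_max(c)
  fmin <- feret_min(c)
  c(area = a, perimeter = p, feret_max = fmax, feret_min = fmin,
    aspect_ratio = fmin / fmax, compactness = sqrt(4 * a / pi) / fmax,
    roundness = 4 * a / (pi * fmax^2), shape_factor = p / sqrt(a),
    form_factor = 4 * pi * a / p^2)
}

#' Measure all traced cells of a study
#'
#' Applies [soma_metrics] to every traced cell contour.
#'
#' @param study a `study_dataset`.
#' @return tibble: `bird_id`, `group`, `region`, `population`, `cell_id`,
#'   plus the nine metric columns.
#' @export
measure_cells <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  m <- t(vapply(study$cells$contour, soma_metrics_num, numeric(9L)))
  out <- tibble::tibble(
    bird_id = study$cells$bird_id, region = study$cells$region,
    population = study$cells$phenotype, cell_id = study$cells$cell_id)
  out <- dplyr::left_join(out, study$birds[, c("bird_id", "group")], by = "bird_id")
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

metric_names <- c("area", "perimeter", "feret_max", "feret_min", "aspect_ratio",
                  "compactness", "roundness", "shape_factor", "form_factor")

# the descriptor family entered into the FDR correction (perimeter excluded:
# five dimensionless descriptors + area + the two Feret diameters)
fdr_family <- c("area", "feret_max", "feret_min", "aspect_ratio",
                "compactness", "roundness", "shape_factor", "form_factor")

#' Per-bird mean morphometrics
#'
#' The analysis unit is the bird: each bird's cells are averaged (unweighted
#' mean across that bird's cells) per population and metric before any group
#' test. Weighting by cell count is available but off by default.
#'
#' @param measures output of [measure_cells].
#' @return tibble: one row per bird x population with mean metric columns and
#'   `n_cells`.
#' @export
bird_morphology <- function(measures) {
  dplyr::summarise(
    dplyr::group_by(measures, .data$bird_id, .data$group, .data$population),
    dplyr::across(dplyr::all_of(metric_names), mean),
    n_cells = dplyr::n(), .groups = "drop")
}

#' Run the full statistical battery on a study
#'
#' Computes: independent t-tests on new-neuron and DCX densities per region,
#' on HVC volume and per-region cell totals; per-metric independent t-tests on
#' bird-mean morphometrics for each HVC population, with Benjamini-Hochberg
#' correction within each population's descriptor family; the 2 x 2 mixed
#' ANOVA (group x population, population within bird) on soma area with
#' post-hoc paired t-tests per group; and OLS regressions of every
#' experimental covariate on densities and on bird-mean morphometrics.
#'
#' @param study a `study_dataset`.
#' @param alpha FDR level for the morphology families.
#' @return a `study_analysis` list of tidy tibbles: `quantification`,
#'   `density_tests`, `volume_test`, `total_tests`, `morphology`,
#'   `morphology_tests`, `anova_area`, `paired_area`, `regressions`.
#' @export
analyze_study <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "study_dataset"))
  birds <- study$birds
  grp <- function(df, g) df$value[df$group == g]

  quant <- quantify_regions(study)

  dens_tests <- list(); tot_tests <- list()
  for (r in unique(quant$region)) for (ph in unique(quant$phenotype)) {
    q <- quant[quant$region == r & quant$phenotype == ph, ]
    dt <- t_independent(q$density_per_mm2[q$group == "statin"],
                        q$density_per_mm2[q$group == "control"])
    dens_tests[[length(dens_tests) + 1L]] <-
      tibble::add_column(dt, region = r, phenotype = ph, .before = 1L)
    tt <- t_independent(q$total_cells[q$group == "statin"],
                        q$total_cells[q$group == "control"])
    tot_tests[[length(tot_tests) + 1L]] <-
      tibble::add_column(tt, region = r, phenotype = ph, .before = 1L)
  }
  vols <- unique(quant[quant$region == "HVC", c("bird_id", "group", "volume_mm3")])
  vol_test <- t_independent(vols$volume_mm3[vols$group == "statin"],
                            vols$volume_mm3[vols$group == "control"])

  measures <- measure_cells(study)
  morph <- bird_morphology(measures)
  mt <- list()
  for (pop in unique(morph$population)) {
    mp <- morph[morph$population == pop, ]
    rows <- lapply(fdr_family, function(nm) {
      tt <- t_independent(mp[[nm]][mp$group == "statin"],
                          mp[[nm]][mp$group == "control"])
      tibble::add_column(tt, population = pop, metric = nm, .before = 1L)
    })
    fam <- dplyr::bind_rows(rows)
    adj <- bh_fdr(fam$p_value, alpha)
    fam$p_adjusted <- adj$p_adjusted
    fam$reject_fdr <- adj$reject
    mt[[length(mt) + 1L]] <- fam
  }

  area_long <- morph[, c("bird_id", "group", "population", "area")]
  names(area_long)[4L] <- "value"
  anova_area <- mixed_anova_2x2(area_long)
  paired <- lapply(unique(morph$group), function(g) {
    w <- tidyr::pivot_wider(area_long[area_long$group == g, ],
                            names_from = "population", values_from = "value")
    pt <- t_paired(w$HU_ONLY, w$BRDU_HU)
    tibble::add_column(pt, group = g, comparison = "HU_ONLY - BRDU_HU area",
                       .before = 1L)
  })

  covariates <- c("age_at_treatment_start_d", "treatment_duration_d",
                  "age_at_first_brdu_d", "age_at_perfusion_d")
  outcomes <- list()
  for (r in unique(quant$region)) for (ph in unique(quant$phenotype)) {
    q <- quant[quant$region == r & quant$phenotype == ph, ]
    outcomes[[paste0("density_", ph, "_", r)]] <-
      q$density_per_mm2[match(birds$bird_id, q$bird_id)]
  }
  for (pop in unique(morph$population)) {
    mp <- morph[morph$population == pop, ]
    for (nm in fdr_family) {
      outcomes[[paste0(nm, "_", pop)]] <- mp[[nm]][match(birds$bird_id, mp$bird_id)]
    }
  }
  reg <- list()
  for (cv in covariates) for (nm in names(outcomes)) {
    rr <- ols_regress(birds[[cv]], outcomes[[nm]])
    reg[[length(reg) + 1L]] <-
      tibble::add_column(rr, covariate = cv, outcome = nm, .before = 1L)
  }

  structure(list(
    quantification = quant,
    density_tests = dplyr::bind_rows(dens_tests),
    volume_test = vol_test,
    total_tests = dplyr::bind_rows(tot_tests),
    morphology = morph,
    morphology_tests = dplyr::bind_rows(mt),
    anova_area = anova_area,
    paired_area = dplyr::bind_rows(paired),
    regressions = dplyr::bind_rows(reg)
  ), class = "study_analysis")
}

#' Effect-direction recovery of one analyzed study
#'
#' Checks whether an analysis reproduces the declared effect pattern: bird-
#' mean aspect ratio lower, shape factor higher and form factor lower in
#' statin-treated birds for the new (`BRDU_HU`) neurons; bird-mean soma area
#' lower for the older (`HU_ONLY`) population; and no rejection of the null
#' for the HVC new-neuron density comparison.
#'
#' @param analysis a `study_analysis` (or a `study_dataset`, analyzed first).
#' @param alpha level for the density null check.
#' @return named logical vector with elements `aspect_down`, `shape_up`,
#'   `form_down`, `older_area_down`, `density_null`, `all`.
#' @export
effect_directions <- function(analysis, alpha = 0.05) {
  if (inherits(analysis, "study_dataset")) analysis <- analyze_study(analysis)
  mt <- analysis$morphology_tests
  dir_of <- function(pop, met) {
    mt$direction[mt$population == pop & mt$metric == met]
  }
  dens <- analysis$density_tests
  d_p <- dens$p_value[dens$region == "HVC" & dens$phenotype == "BRDU_HU"]
  out <- c(aspect_down = dir_of("BRDU_HU", "aspect_ratio") < 0,
           shape_up = dir_of("BRDU_HU", "shape_factor") > 0,
           form_down = dir_of("BRDU_HU", "form_factor") < 0,
           older_area_down = dir_of("HU_ONLY", "area") < 0,
           density_null = d_p > alpha)
  c(out, all = all(out))
}

# lean per-study recovery evaluation (skips the covariate/regression grid)
study_recovers <- function(study, alpha = 0.05) {
  measures <- measure_cells(study)
  morph <- bird_morphology(measures)
  dirsign <- function(pop, nm) {
    mp <- morph[morph$population == pop, ]
    sign(mean(mp[[nm]][mp$group == "statin"]) - mean(mp[[nm]][mp$group == "control"]))
  }
  sec <- study$sections[study$sections$region == "HVC", ]
  mk <- study$markers[study$markers$region == "HVC" &
                        study$markers$phenotype == "BRDU_HU", ]
  n_by_bird <- table(mk$bird_id)
  area_by_bird <- vapply(split(sec$area_um2, sec$bird_id), sum, 0)
  cnt <- as.vector(n_by_bird[names(area_by_bird)])
  cnt[is.na(cnt)] <- 0
  dens <- cnt / (area_by_bird / 1e6)
  names(dens) <- names(area_by_bird)
  g <- study$birds$group[match(names(dens), study$birds$bird_id)]
  dt <- t_independent(dens[g == "statin"], dens[g == "control"])
  c(aspect_down = dirsign("BRDU_HU", "aspect_ratio") < 0,
    shape_up = dirsign("BRDU_HU", "shape_factor") > 0,
    form_down = dirsign("BRDU_HU", "form_factor") < 0,
    older_area_down = dirsign("HU_ONLY", "area") < 0,
    density_null = dt$p_value > alpha)
}

#' Direction-recovery simulation over many seeded studies
#'
#' Generates `n_studies` full studies under the given effects and evaluates
#' the recovery pattern of [effect_directions] for each (via a lean path that
#' computes exactly those quantities).
#'
#' @param n_studies number of simulated studies.
#' @param effects an [effect_spec].
#' @param seed master seed.
#' @return tibble of per-study logicals plus an `all` column.
#' @export
simulate_recovery <- function(n_studies = 200L, effects = study_effects(),
                              seed = 1L) {
  rows <- lapply(seq_len(n_studies), function(s) {
    study <- gen_study(effects = effects, seed = sub_seed(seed, "study", s))
    r <- study_recovers(study)
    tibble::tibble(study = s, !!!as.list(r), all = all(r))
  })
  dplyr::bind_rows(rows)
}

#' Type-I error calibration of the group t-test
#'
#' Simulates `n_studies` studies under the null effect specification at the
#' parameter level ([gen_study_means]) and applies the pooled independent
#' t-test to the bird-mean flatness parameter of the new-neuron population,
#' returning the rejection rate at the given level.
#'
#' @param n_studies number of simulated null studies (default 2000).
#' @param alpha test level.
#' @param seed master seed.
#' @return rejection rate (proportion of studies with p < alpha).
#' @export
simulate_null_calibration <- function(n_studies = 2000L, alpha = 0.05, seed = 1L) {
  rej <- vapply(seq_len(n_studies), function(s) {
    m <- gen_study_means(effects = null_effects(), seed = sub_seed(seed, "null", s))
    m <- m[m$population == "BRDU_HU", ]
    t_independent(m$axis_ratio[m$group == "statin"],
                  m$axis_ratio[m$group == "control"])$p_value < alpha
  }, logical(1L))
  mean(rej)
}
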