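#' Hierarchical synthetic-study generator
#'
#' Generates soma contours and whole studies with the hierarchical structure
#' the analysis assumes: two treatment groups of birds, bird-level random
#' effects on generative shape parameters, per-cell jitter, traced-cell counts
#' matching the study's printed per-bird ranges, sectioned regions with
#' counted markers, and declared group-level effects that serve as ground
#' truth for calibration and parameter-recovery tests.
#'
#' Somata are modeled as radial Fourier ellipses: an ellipse of given axis
#' ratio whose radius is modulated by random cosine harmonics in two bands — a
#' low-frequency band (k in 2..6) producing large-scale convolutions that
#' raise the shape factor, and a high-frequency band (k in 12..40) producing
#' fine roughness that lowers the form factor. The descriptor set separates
#' exactly along these generator axes, which is what makes direction-recovery
#' testing meaningful.
#'
#' @name synthetic_data
NULL

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a named substream seed
#'
#' Hashes a master seed together with a path of labels (e.g. study / bird /
#' component) into a new 31-bit seed, so any component of a generated study
#' can be regenerated independently of the others.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- (as.double(seed) %% 2147483647) * 48271 %% 2147483647
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Generative shape parameters for one soma population
#'
#' @param target_area soma cross-section area, um^2.
#' @param axis_ratio minor/major semi-axis ratio of the base ellipse, (0, 1].
#' @param convolution_amp RMS-scale radial amplitude of the low-frequency
#'   harmonic band (`conv_band`), dimensionless.
#' @param roughness_amp amplitude of the high-frequency band (`rough_band`).
#' @param n_vertices vertices per generated contour.
#' @param conv_band,rough_band harmonic index ranges of the two bands.
#' @return a `morph_params` list.
#' @export
morph_params <- function(target_area = 80, axis_ratio = 0.75,
                         convolution_amp = 0.02, roughness_amp = 0.01,
                         n_vertices = 256L, conv_band = 2:6, rough_band = 12:40) {
  stopifnot(target_area > 0, axis_ratio > 0, axis_ratio <= 1,
            convolution_amp >= 0, roughness_amp >= 0, n_vertices >= 16)
  structure(list(target_area = target_area, axis_ratio = axis_ratio,
                 convolution_amp = convolution_amp, roughness_amp = roughness_amp,
                 n_vertices = as.integer(n_vertices),
                 conv_band = conv_band, rough_band = rough_band),
            class = "morph_params")
}

#' Baseline generative parameters per neuron population
#'
#' New neurons (`BRDU_HU`) are generated smaller (80 um^2) than the older
#' heterogeneous population (`HU_ONLY`, 120 um^2), matching the within-control
#' size ordering of the two populations; both share the baseline flatness and
#' boundary-complexity settings.
#'
#' @param population `"BRDU_HU"` or `"HU_ONLY"`.
#' @return a [morph_params] object.
#' @export
default_morph_params <- function(population = c("BRDU_HU", "HU_ONLY")) {
  population <- match.arg(population)
  morph_params(target_area = if (population == "BRDU_HU") 80 else 120)
}

#' Declared group-level effects and hierarchical noise
#'
#' An effect specification holds, per neuron population, the statin-minus-
#' control shifts applied to generative parameters (additive for `axis_ratio`
#' and the two amplitudes, multiplicative for `target_area`), plus the
#' bird-level random-effect SDs, the per-cell jitter SDs, and the traced-cell
#' count distributions (log-normal, clipped to the study's printed ranges).
#'
#' @param deltas named list per population of named parameter shifts.
#' @param bird_sd,cell_sd named lists of SDs: `axis_ratio`,
#'   `log_target_area`, `convolution_amp`, `roughness_amp`.
#' @param counts per-population traced-cell count distributions
#'   (`min`, `max`, `meanlog`, `sdlog`).
#' @param density mean areal densities (cells/mm^2) of counted phenotypes,
#'   identical in both groups (the study found no density differences).
#' @param density_log_sd bird-level log-SD of density.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(deltas = list(BRDU_HU = list(), HU_ONLY = list()),
                        bird_sd = list(axis_ratio = 0.03, log_target_area = 0.08,
                                       convolution_amp = 0.005, roughness_amp = 0.005),
                        cell_sd = list(axis_ratio = 0.08, log_target_area = 0.25,
                                       convolution_amp = 0.01, roughness_amp = 0.005),
                        counts = list(
                          BRDU_HU = list(min = 13, max = 100, meanlog = log(38), sdlog = 0.35),
                          HU_ONLY = list(min = 14, max = 66, meanlog = log(36), sdlog = 0.30)),
                        density = c(BRDU_HU = 35, DCX = 300),
                        density_log_sd = 0.2) {
  structure(list(deltas = deltas, bird_sd = bird_sd, cell_sd = cell_sd,
                 counts = counts, density = density, density_log_sd = density_log_sd),
            class = "effect_spec")
}

#' Null effects (both groups from the same generator)
#' @return an [effect_spec] with no group shifts.
#' @export
null_effects <- function() effect_spec()

#' The study-direction effect specification
#'
#' The declared effects whose directions mirror the study's findings: new
#' neurons flatter (aspect-ratio shift -0.06) and rougher (roughness
#' amplitude +0.03) in the statin group; the older population smaller (area
#' x 0.90); no density shift.
#'
#' @return an [effect_spec].
#' @export
study_effects <- function() {
  effect_spec(deltas = list(
    BRDU_HU = list(axis_ratio = -0.06, roughness_amp = 0.03),
    HU_ONLY = list(target_area = 0.90)
  ))
}

# shift mode per generative field
.delta_mode <- c(target_area = "multiplicative", axis_ratio = "additive",
                 convolution_amp = "additive", roughness_amp = "additive")

apply_deltas <- function(params, deltas) {
  for (nm in names(deltas)) {
    if (is.null(.delta_mode[nm]) || is.na(.delta_mode[nm])) stop("unknown effect field: ", nm)
    params[[nm]] <- if (.delta_mode[nm] == "multiplicative")
      params[[nm]] * deltas[[nm]] else params[[nm]] + deltas[[nm]]
  }
  params
}

clamp_params <- function(p) {
  p$axis_ratio <- min(1, max(0.05, p$axis_ratio))
  p$convolution_amp <- max(0, p$convolution_amp)
  p$roughness_amp <- max(0, p$roughness_amp)
  p
}

perturb_params <- function(p, sd) {
  p$axis_ratio <- p$axis_ratio + stats::rnorm(1, 0, sd$axis_ratio)
  p$target_area <- p$target_area * exp(stats::rnorm(1, 0, sd$log_target_area))
  p$convolution_amp <- p$convolution_amp + stats::rnorm(1, 0, sd$convolution_amp)
  p$roughness_amp <- p$roughness_amp + stats::rnorm(1, 0, sd$roughness_amp)
  clamp_params(p)
}

#' Generate one soma contour
#'
#' Radial Fourier ellipse: r(theta) = r_ellipse(theta; axis_ratio) *
#' (1 + sum_k a_k cos(k theta + phi_k)), with amplitudes a_k drawn
#' independently in the convolution and roughness bands (scaled so each
#' band's total RMS equals its amplitude parameter) and uniform phases,
#' sampled at `n_vertices` angles and rescaled to the target area. A draw
#' whose radius dips below 5% of the ellipse radius is rejected and resampled
#' (at most 100 times); accepted contours are star-shaped, hence simple.
#'
#' @param params a [morph_params].
#' @param seed optional integer; when given the draw is a deterministic
#'   function of it (caller RNG state untouched).
#' @return a [contour] with area equal to `target_area` (exactly, up to
#'   floating point).
#' @export
.basis_cache <- new.env(parent = emptyenv())

# cos/sin harmonic basis at the sampling angles, memoized per (n, bands)
harmonic_basis <- function(n, ks) {
  key <- paste(n, paste(ks, collapse = ","), sep = ":")
  b <- .basis_cache[[key]]
  if (is.null(b)) {
    th <- 2 * pi * (seq_len(n) - 1L) / n
    kth <- outer(th, ks)
    b <- list(th = th, cth = cos(th), sth = sin(th), C = cos(kth), S = sin(kth))
    .basis_cache[[key]] <- b
  }
  b
}

gen_contour <- function(params, seed = NULL) {
  stopifnot(inherits(params, "morph_params"))
  if (!is.null(seed)) return(with_seed(seed, gen_contour(params)))
  n <- params$n_vertices
  ks <- c(params$conv_band, params$rough_band)
  bs <- harmonic_basis(n, ks)
  b <- params$axis_ratio
  r_ell <- b / sqrt((b * bs$cth)^2 + bs$sth^2)  # ellipse a = 1, b = axis_ratio
  amp <- c(rep(params$convolution_amp / sqrt(length(params$conv_band)), length(params$conv_band)),
           rep(params$roughness_amp / sqrt(length(params$rough_band)), length(params$rough_band)))
  for (try in seq_len(100L)) {
    a_k <- amp * stats::rnorm(length(ks))
    phi <- stats::runif(length(ks), 0, 2 * pi)
    # sum_k a_k cos(k theta + phi_k) expanded on the cached basis
    mod <- 1 + drop(bs$C %*% (a_k * cos(phi))) - drop(bs$S %*% (a_k * sin(phi)))
    if (min(mod) > 0.05) {
      r <- r_ell * mod
      xy <- cbind(r * bs$cth, r * bs$sth)
      s <- sqrt(params$target_area / (signed_area2(xy) / 2))
      return(new_contour(xy * s))
    }
  }
  stop("generation failure: could not draw a positive-radius contour in 100 attempts")
}

# draw a clipped log-normal traced-cell count
gen_cell_count <- function(spec) {
  n <- round(stats::rlnorm(1, spec$meanlog, spec$sdlog))
  as.integer(min(spec$max, max(spec$min, n)))
}

#' Elliptical region-outline contour
#'
#' @param area_um2 outline area in um^2.
#' @param axis_ratio minor/major ratio.
#' @param n vertices.
#' @param center outline center (um).
#' @return a [contour] whose polygon area is exactly `area_um2`.
#' @export
ellipse_outline <- function(area_um2, axis_ratio = 0.5, n = 64L, center = c(0, 0)) {
  stopifnot(area_um2 > 0)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  xy <- cbind(cos(th), axis_ratio * sin(th))
  s <- sqrt(area_um2 / (signed_area2(xy) / 2))
  new_contour(sweep(xy * s, 2L, center, "+"))
}

# uniform points strictly inside an ellipse_outline polygon: sample the
# inscribed-disc preimage with a margin below cos(pi/n)
sample_in_outline <- function(m, outline) {
  n <- nrow(outline)
  ctr <- colMeans(outline)
  xy0 <- sweep(unclass(outline), 2L, ctr)
  # recover semi-axes from the polygon (axis-aligned by construction)
  a <- max(abs(xy0[, 1L])); bb <- max(abs(xy0[, 2L]))
  rad <- sqrt(stats::runif(m)) * cos(pi / n) * 0.995
  ang <- stats::runif(m, 0, 2 * pi)
  cbind(x = ctr[1L] + a * rad * cos(ang), y = ctr[2L] + bb * rad * sin(ang))
}

#' Generate one bird's traced cells for one population
#'
#' Draws the bird-level generative parameters (group mean shifted by the
#' declared effect when the bird is statin-treated, plus a bird random
#' effect), a traced-cell count from the population's count distribution, and
#' per-cell contours with cell-level parameter jitter; cells are positioned
#' uniformly inside the supplied section outlines (round-robin across
#' sections).
#'
#' @param group `"statin"` or `"control"`.
#' @param population `"BRDU_HU"` or `"HU_ONLY"`.
#' @param effects an [effect_spec].
#' @param outlines list of section outline [contour]s (one generated by
#'   default).
#' @param base baseline [morph_params] for the population.
#' @param seed optional integer substream seed.
#' @return list with `cells` (tibble: `cell_id`, `section_slot`, `x_um`,
#'   `y_um`, `phenotype`, `contour` list-column) and `params` (the bird-level
#'   true generative parameters).
#' @export
gen_bird <- function(group = c("control", "statin"),
                     population = c("BRDU_HU", "HU_ONLY"),
                     effects = study_effects(), outlines = NULL,
                     base = default_morph_params(population), seed = NULL) {
  group <- match.arg(group)
  population <- match.arg(population)
  if (!is.null(seed)) {
    return(with_seed(seed, gen_bird(group, population, effects, outlines, base)))
  }
  if (is.null(outlines)) outlines <- list(ellipse_outline(5e5))
  p_group <- if (group == "statin") apply_deltas(base, effects$deltas[[population]]) else base
  p_bird <- perturb_params(p_group, effects$bird_sd)
  n_cells <- gen_cell_count(effects$counts[[population]])
  slot <- rep_len(seq_along(outlines), n_cells)
  cells <- vector("list", n_cells)
  pos <- matrix(0, n_cells, 2L)
  for (i in seq_len(n_cells)) {
    p_cell <- perturb_params(p_bird, effects$cell_sd)
    cc <- gen_contour(p_cell)
    pos[i, ] <- sample_in_outline(1L, outlines[[slot[i]]])
    # recentre the soma at its marker position
    cells[[i]] <- new_contour(cbind(cc[, 1L] + pos[i, 1L], cc[, 2L] + pos[i, 2L]))
  }
  list(
    cells = tibble::tibble(
      cell_id = sprintf("%s_%03d", population, seq_len(n_cells)),
      section_slot = slot, x_um = pos[, 1L], y_um = pos[, 2L],
      phenotype = population,
      contour = cells
    ),
    params = tibble::as_tibble(p_bird[c("target_area", "axis_ratio",
                                        "convolution_amp", "roughness_amp")])
  )
}

#' Generate a complete synthetic study
#'
#' Emulates the study design end to end: `n_statin` + `n_control` birds with
#' covariates drawn from the study's ranges (treatment start 18-49 d,
#' perfusion at 107-111 d, first BrdU injection 32 d before perfusion),
#' 10-12 sections per region (HVC and NCM) of 6 um thickness sampled every
#' 8th section, counted markers (new `BRDU_HU` neurons and `DCX` cells) at
#' bird-varying densities with no group difference, and traced soma contours
#' for both HVC populations under the declared [effect_spec]. The per-bird
#' generative parameters are returned as a ground-truth table.
#'
#' @param n_statin,n_control group sizes (defaults 6 and 7).
#' @param effects an [effect_spec] (default [study_effects()]).
#' @param seed master seed; every component draws from a named substream of
#'   it, so regeneration is byte-identical.
#' @return a `study_dataset`: list with tibbles `birds`, `sections` (with an
#'   `outline` list-column and `area_um2`), `markers`, `cells` (with a
#'   `contour` list-column), `truth`, plus `seed` and `effects`.
#' @export
gen_study <- function(n_statin = 6L, n_control = 7L, effects = study_effects(),
                      seed = 1L) {
  stopifnot(n_statin >= 2, n_control >= 2)
  groups <- c(rep("statin", n_statin), rep("control", n_control))
  bird_ids <- sprintf("%s%02d", ifelse(groups == "statin", "S", "C"),
                      c(seq_len(n_statin), seq_len(n_control)))

  birds <- with_seed(sub_seed(seed, "covariates"), {
    start <- sample(18:49, length(groups), replace = TRUE)
    perf <- sample(107:111, length(groups), replace = TRUE)
    tibble::tibble(
      bird_id = bird_ids, group = groups,
      age_at_treatment_start_d = start,
      treatment_duration_d = perf - start,
      age_at_first_brdu_d = perf - 32L,
      age_at_perfusion_d = perf
    )
  })

  sections <- list(); markers <- list(); cells <- list(); truth <- list()
  for (bi in seq_along(bird_ids)) {
    b <- bird_ids[bi]
    for (region in c("HVC", "NCM")) {
      sec <- with_seed(sub_seed(seed, "sections", b, region), {
        n_sec <- sample(10:12, 1L)
        a_max <- stats::rlnorm(1, log(if (region == "HVC") 0.5 else 0.4), 0.1)
        f <- seq_len(n_sec) / (n_sec + 1)
        areas_mm2 <- a_max * (0.4 + 0.6 * sin(pi * f))
        tibble::tibble(
          bird_id = b, region = region, section_index = seq_len(n_sec),
          thickness_um = 6, sampling_interval = 8L,
          lateral_position_um = seq_len(n_sec) * 48,
          area_um2 = areas_mm2 * 1e6,
          outline = lapply(areas_mm2 * 1e6, ellipse_outline)
        )
      })
      sections[[length(sections) + 1L]] <- sec
      markers[[length(markers) + 1L]] <-
        with_seed(sub_seed(seed, "markers", b, region), {
          out <- list()
          for (ph in names(effects$density)) {
            dens_b <- effects$density[[ph]] *
              exp(stats::rnorm(1, 0, effects$density_log_sd))
            cnt <- stats::rpois(nrow(sec), dens_b * sec$area_um2 / 1e6)
            pos <- lapply(which(cnt > 0), function(j) {
              sample_in_outline(cnt[j], sec$outline[[j]])
            })
            pos <- do.call(rbind, pos)
            if (is.null(pos)) next
            out[[length(out) + 1L]] <- tibble::tibble(
              bird_id = b, region = region,
              section_index = rep.int(seq_len(nrow(sec)), cnt),
              cell_id = sprintf("%s_%04d", ph, seq_len(sum(cnt))),
              phenotype = ph, x_um = pos[, 1L], y_um = pos[, 2L])
          }
          dplyr::bind_rows(out)
        })
    }
    hvc <- sections[[length(sections) - 1L]]  # HVC comes before NCM for this bird
    for (pop in c("BRDU_HU", "HU_ONLY")) {
      gb <- gen_bird(groups[bi], pop, effects, outlines = hvc$outline,
                     seed = sub_seed(seed, "bird", b, pop))
      cc <- gb$cells
      cc$section_index <- hvc$section_index[cc$section_slot]
      cc$section_slot <- NULL
      cc <- tibble::add_column(cc, bird_id = b, region = "HVC", .before = 1L)
      cells[[length(cells) + 1L]] <- cc
      truth[[length(truth) + 1L]] <- tibble::add_column(
        gb$params, bird_id = b, group = groups[bi], population = pop, .before = 1L)
    }
  }

  structure(list(
    birds = birds,
    sections = dplyr::bind_rows(sections),
    markers = dplyr::bind_rows(markers),
    cells = dplyr::bind_rows(cells),
    truth = dplyr::bind_rows(truth),
    seed = seed, effects = effects
  ), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(paste0("<study_dataset: %d birds (%d statin, %d control), ",
                     "%d sections, %d markers, %d traced cells>\n"),
              nrow(x$birds), sum(x$birds$group == "statin"),
              sum(x$birds$group == "control"),
              nrow(x$sections), nrow(x$markers), nrow(x$cells)))
  invisible(x)
}

#' Parameter-level bird means under the hierarchical generator
#'
#' Fast path used for statistical calibration: draws, for every bird and
#' population, the bird-mean generative parameters exactly as the full
#' generator would realise them in the bird's traced-cell average — group mean
#' (plus declared effect), plus the bird random effect, plus the mean of the
#' per-cell jitter over the bird's drawn cell count — without rendering
#' polygons. Descriptors are deterministic functions of these parameters, so
#' the bird-level sampling distribution a t-test sees is the generator's.
#'
#' @inheritParams gen_study
#' @return tibble: `bird_id`, `group`, `population`, `axis_ratio`,
#'   `log_target_area`, `convolution_amp`, `roughness_amp`, `n_cells`.
#' @export
gen_study_means <- function(n_statin = 6L, n_control = 7L,
                            effects = null_effects(), seed = 1L) {
  with_seed(seed, {
    groups <- c(rep("statin", n_statin), rep("control", n_control))
    nb <- length(groups)
    sdb <- effects$bird_sd; sdc <- effects$cell_sd
    out <- list()
    for (pop in c("BRDU_HU", "HU_ONLY")) {
      base <- default_morph_params(pop)
      shifted <- apply_deltas(base, effects$deltas[[pop]])
      pick <- function(field) {
        ifelse(groups == "statin", shifted[[field]], base[[field]])
      }
      n_cells <- vapply(seq_len(nb), function(i) gen_cell_count(effects$counts[[pop]]), 0L)
      se <- 1 / sqrt(n_cells)
      out[[length(out) + 1L]] <- tibble::tibble(
        bird_id = seq_len(nb), group = groups, population = pop,
        axis_ratio = pick("axis_ratio") + stats::rnorm(nb, 0, sdb$axis_ratio) +
          stats::rnorm(nb, 0, sdc$axis_ratio * se),
        log_target_area = log(pick("target_area")) +
          stats::rnorm(nb, 0, sdb$log_target_area) +
          stats::rnorm(nb, 0, sdc$log_target_area * se),
        convolution_amp = pick("convolution_amp") +
          stats::rnorm(nb, 0, sdb$convolution_amp) +
          stats::rnorm(nb, 0, sdc$convolution_amp * se),
        roughness_amp = pick("roughness_amp") +
          stats::rnorm(nb, 0, sdb$roughness_amp) +
          stats::rnorm(nb, 0, sdc$roughness_amp * se),
        n_cells = n_cells
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Planted-cell synthetic region for stereology recovery
#'
#' Plants `n_cells` uniformly in a rectangular tissue block and sections it
#' systematically: every `interval`-th section of the given thickness is
#' "counted" (cells whose depth falls inside the section slab), starting at a
#' random sub-interval offset. Ground truth (planted count, true volume) is
#' returned alongside the observable counts and areas.
#'
#' @param n_cells planted cell count.
#' @param extent_um block extent `c(x, y, z)` in um.
#' @param thickness_um section thickness (6).
#' @param interval sampling interval (8).
#' @param seed optional substream seed.
#' @return list: `counts` (per counted section), `areas_um2`, `thickness_um`,
#'   `interval`, `n_planted`, `volume_mm3` (true block volume).
#' @export
gen_planted_box <- function(n_cells = 2000L, extent_um = c(1000, 1000, 1920),
                            thickness_um = 6, interval = 8L, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, gen_planted_box(n_cells, extent_um, thickness_um, interval)))
  }
  z <- stats::runif(n_cells, 0, extent_um[3L])
  step <- thickness_um * interval
  z0 <- stats::runif(1, 0, step)
  starts <- seq(z0, extent_um[3L] - thickness_um, by = step)
  counts <- vapply(starts, function(s) sum(z >= s & z < s + thickness_um), 0L)
  list(counts = counts,
       areas_um2 = rep(extent_um[1L] * extent_um[2L], length(starts)),
       thickness_um = thickness_um, interval = interval,
       n_planted = n_cells,
       volume_mm3 = prod(extent_um) / 1e9)
}
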