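#' Specify a synthetic multi-site cohort
#'
#' Defines the study conditions for the synthetic-cohort generator: a
#' multi-site, multi-atlas resting-state cohort with a binary diagnosis,
#' site-correlated connectivity structure, and class-dependent extra coupling
#' planted on chosen ROI pairs. The defaults describe the standard cohort used
#' throughout the package's examples and tests: 150 subjects over 4 sites,
#' three toy parcellations of 10/12/16 regions, and one planted effect pair
#' per atlas.
#'
#' Time series follow a latent-factor model (see
#' [generate_subject_timeseries()]), so every derived functional-connectivity
#' matrix is a valid correlation matrix by construction. All generative
#' choices are synthetic stand-ins for real acquisition: the generator makes
#' no claim to emulate BOLD physiology, motion, or scanner artifacts.
#'
#' @param n_subjects Number of subjects (>= 2 * `n_sites`).
#' @param n_sites Number of acquisition sites.
#' @param atlas_sizes Named integer vector of ROI counts, one per atlas.
#' @param n_timepoints Timepoints per scan (>= 3 so Pearson correlation is
#'   defined).
#' @param effect_pairs List of planted effects, each `list(atlas =, pair =)`
#'   with `atlas` an index into `atlas_sizes` and `pair` two distinct 1-based
#'   ROI indices. Cases (and only cases) receive extra shared coupling on
#'   these pairs.
#' @param effect_size Loading of the planted class-dependent latent
#'   (dimensionless; 0 gives a null cohort).
#' @param site_effect_sd Standard deviation of site-specific ROI loadings on
#'   the shared site latent (dimensionless).
#' @param site_age_means Mean age per site in years (recycled to `n_sites`).
#' @param age_sd Within-site age standard deviation in years; ages are
#'   truncated to \[6, 45\].
#' @param class_balance Case fraction in (0, 1).
#' @param prop_male Probability a subject is male.
#' @param seed Integer master seed; every quantity in the cohort is a
#'   deterministic function of it.
#' @return A `popconn_cohort_spec` list.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 20, n_sites = 2, atlas_sizes = c(A = 6))
#' ph <- generate_phenotypes(spec)
#' head(ph)
cohort_spec <- function(n_subjects = 150,
                        n_sites = 4,
                        atlas_sizes = c(A = 10, B = 12, C = 16),
                        n_timepoints = 150,
                        effect_pairs = default_effect_pairs(atlas_sizes),
                        effect_size = 1,
                        site_effect_sd = 0.3,
                        site_age_means = seq(12, 28, length.out = n_sites),
                        age_sd = 5,
                        class_balance = 0.5,
                        prop_male = 0.85,
                        seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2)
  n_sites <- check_count(n_sites, "n_sites", min = 1)
  if (n_subjects < 2 * n_sites) abort("`n_subjects` must be >= 2 * `n_sites`")
  if (length(atlas_sizes) < 1) abort("`atlas_sizes` must name at least one atlas")
  atlas_sizes <- vapply(atlas_sizes, check_count, integer(1), name = "atlas_sizes", min = 2)
  if (is.null(names(atlas_sizes))) {
    names(atlas_sizes) <- paste0("atlas", seq_along(atlas_sizes))
  }
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 3)
  effect_size <- check_number(effect_size, "effect_size", min = 0)
  site_effect_sd <- check_number(site_effect_sd, "site_effect_sd", min = 0)
  class_balance <- check_number(class_balance, "class_balance", min = 0, max = 1)
  if (class_balance <= 0 || class_balance >= 1) abort("`class_balance` must be in (0, 1)")
  prop_male <- check_number(prop_male, "prop_male", min = 0, max = 1)
  age_sd <- check_number(age_sd, "age_sd", min = 0)
  site_age_means <- rep_len(as.numeric(site_age_means), n_sites)
  seed <- check_count(seed, "seed", min = 0)

  for (ef in effect_pairs) {
    a <- ef$atlas
    if (is.null(a) || a < 1 || a > length(atlas_sizes)) {
      abort("effect_pair references an atlas index out of range")
    }
    p <- ef$pair
    if (length(p) != 2 || any(p < 1) || any(p > atlas_sizes[[a]]) || p[1] == p[2]) {
      abort(sprintf("effect_pair (%s) has ROI indices out of range for atlas %d",
                    paste(p, collapse = ","), a))
    }
  }

  structure(
    list(
      n_subjects = n_subjects, n_sites = n_sites, atlas_sizes = atlas_sizes,
      n_timepoints = n_timepoints, effect_pairs = effect_pairs,
      effect_size = effect_size, site_effect_sd = site_effect_sd,
      site_age_means = site_age_means, age_sd = age_sd,
      class_balance = class_balance, prop_male = prop_male, seed = seed
    ),
    class = "popconn_cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_effect_pairs <- function(atlas_sizes) {
  lapply(seq_along(atlas_sizes), function(a) {
    m <- atlas_sizes[[a]]
    list(atlas = a, pair = c(min(3L, m - 1L), min(6L, m)))
  })
}

#' Generate the phenotype table of a synthetic cohort
#'
#' One row per subject with ABIDE-style column names: `SUB_ID`, `SITE_ID`,
#' `AGE_AT_SCAN` (years, normal per site and truncated to 6--45), `SEX`
#' (1 = male, 2 = female), `DX_GROUP` (1 = case, 0 = control, drawn at
#' `class_balance`), plus synthetic `EYE_STATUS_AT_SCAN`,
#' `HANDEDNESS_CATEGORY` and `FIQ` columns. Fully determined by `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `n_subjects` rows.
#' @export
generate_phenotypes <- function(spec) {
  if (!inherits(spec, "popconn_cohort_spec")) abort("`spec` must come from cohort_spec()")
  n <- spec$n_subjects
  with_stream(spec$seed, 101, expr = {
    site_idx <- sort(rep_len(seq_len(spec$n_sites), n))
    age <- spec$site_age_means[site_idx] + rnorm(n, 0, spec$age_sd)
    age <- pmin(pmax(age, 6), 45)
    sex <- ifelse(runif(n) < spec$prop_male, 1L, 2L)
    dx <- as.integer(runif(n) < spec$class_balance)
    eye <- ifelse(runif(n) < 0.7, 1L, 2L)
    hand <- ifelse(runif(n) < 0.9, "R", "L")
    fiq <- round(100 + 7 * dx_shift(dx) + rnorm(n, 0, 12), 1)
    tibble::tibble(
      SUB_ID = 50000L + seq_len(n),
      SITE_ID = sprintf("SITE%02d", site_idx),
      AGE_AT_SCAN = round(age, 2),
      SEX = sex,
      DX_GROUP = dx,
      EYE_STATUS_AT_SCAN = eye,
      HANDEDNESS_CATEGORY = hand,
      FIQ = fiq
    )
  })
}

# Mild case/control IQ shift so the optional FIQ phenotype is label-correlated.
dx_shift <- function(dx) ifelse(dx == 1L, -1, 0)

# Site loading vector: one draw per (seed, site, atlas), shared by all
# subjects of the site, inducing site-correlated FC structure.
site_loadings <- function(spec, site_idx, atlas_idx) {
  m <- spec$atlas_sizes[[atlas_idx]]
  with_stream(spec$seed, 307, site_idx, atlas_idx,
              expr = rnorm(m, 0, spec$site_effect_sd))
}

#' Simulate one subject's ROI time series under one atlas
#'
#' Latent-factor model: every ROI loads on a subject-wide shared signal, on a
#' site latent through a site-specific loading vector (sd `site_effect_sd`),
#' and -- for cases only -- the two ROIs of each planted `effect_pair` load
#' with weight `effect_size` on an extra shared latent, which raises their
#' mutual correlation. White noise of unit variance is added. The draw is a
#' deterministic function of `(spec$seed, subject, atlas)`, independent of
#' generation order.
#'
#' @param row One row of [generate_phenotypes()] output (a list or
#'   single-row data frame).
#' @param atlas Atlas index or name into `spec$atlas_sizes`.
#' @param spec The [cohort_spec()].
#' @return A `n_timepoints` x M numeric matrix (arbitrary BOLD-like units)
#'   with attributes `subject` and `atlas`.
#' @export
generate_subject_timeseries <- function(row, atlas, spec) {
  if (!inherits(spec, "popconn_cohort_spec")) abort("`spec` must come from cohort_spec()")
  if (is.character(atlas)) atlas <- match(atlas, names(spec$atlas_sizes))
  if (is.na(atlas) || atlas < 1 || atlas > length(spec$atlas_sizes)) {
    abort("unknown atlas")
  }
  if (spec$n_timepoints < 3) abort("n_timepoints must be >= 3")
  m <- spec$atlas_sizes[[atlas]]
  tt <- spec$n_timepoints
  site_idx <- as.integer(sub("SITE", "", row$SITE_ID))
  w_site <- site_loadings(spec, site_idx, atlas)
  pairs <- purrr::keep(spec$effect_pairs, ~ .x$atlas == atlas)

  y <- with_stream(spec$seed, 509, row$SUB_ID, atlas, expr = {
    g <- rnorm(tt)                       # subject-wide shared signal
    u <- rnorm(tt)                       # site latent realisation
    y <- 0.5 * outer(g, rep(1, m)) + outer(u, w_site)
    if (row$DX_GROUP == 1L && spec$effect_size > 0) {
      for (ef in pairs) {
        cpair <- rnorm(tt)
        y[, ef$pair] <- y[, ef$pair] + spec$effect_size * cpair
      }
    }
    y + matrix(rnorm(tt * m), tt, m)
  })
  structure(y, subject = row$SUB_ID, atlas = names(spec$atlas_sizes)[atlas])
}

#' Generate a complete synthetic cohort
#'
#' Runs [generate_phenotypes()] and [generate_subject_timeseries()] for every
#' subject and atlas.
#'
#' @inheritParams generate_phenotypes
#' @return A `popconn_cohort` list with elements `phenotypes` (tibble),
#'   `series` (list by atlas of lists of time-series matrices, ordered as the
#'   phenotype table), and `spec`.
#' @export
generate_cohort <- function(spec) {
  ph <- generate_phenotypes(spec)
  series <- lapply(seq_along(spec$atlas_sizes), function(a) {
    lapply(seq_len(nrow(ph)), function(i) {
      generate_subject_timeseries(ph[i, ], a, spec)
    })
  })
  names(series) <- names(spec$atlas_sizes)
  structure(list(phenotypes = ph, series = series, spec = spec),
            class = "popconn_cohort")
}

#' @export
print.popconn_cohort <- function(x, ...) {
  cat(sprintf("<popconn_cohort> %d subjects, %d sites, atlases: %s\n",
              nrow(x$phenotypes), length(unique(x$phenotypes$SITE_ID)),
              paste(sprintf("%s(M=%d)", names(x$spec$atlas_sizes),
                            x$spec$atlas_sizes), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk in the plain-text exchange layout
#'
#' Writes `phenotypes.csv` plus one tab-delimited time-series file per subject
#' per atlas (no header, one row per timepoint, one column per ROI), named
#' `<SUB_ID>_<atlas>.1D`.
#'
#' @param cohort A `popconn_cohort`, or a phenotype tibble if `series` is
#'   given separately.
#' @param out_dir Output directory (created if missing).
#' @param series Optional series list (as in `popconn_cohort$series`).
#' @return A tibble manifest with columns `path`, `kind`, `subject`, `atlas`.
#' @export
write_cohort <- function(cohort, out_dir, series = NULL) {
  if (inherits(cohort, "popconn_cohort")) {
    ph <- cohort$phenotypes
    series <- cohort$series
  } else {
    ph <- cohort
  }
  if (is.null(series) || nrow(ph) == 0) abort("empty cohort: nothing to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph_path <- file.path(out_dir, "phenotypes.csv")
  readr::write_csv(ph, ph_path)
  rows <- list(tibble::tibble(path = ph_path, kind = "phenotypes",
                              subject = NA_integer_, atlas = NA_character_))
  for (atlas in names(series)) {
    mats <- series[[atlas]]
    if (length(mats) != nrow(ph)) {
      missing_idx <- setdiff(seq_len(nrow(ph)), seq_along(mats))
      abort(sprintf("missing time series for subject %s under atlas %s",
                    ph$SUB_ID[missing_idx[1]], atlas))
    }
    for (i in seq_len(nrow(ph))) {
      p <- file.path(out_dir, sprintf("%d_%s.1D", ph$SUB_ID[i], atlas))
      utils::write.table(format(mats[[i]], digits = 17, trim = TRUE,
                                scientific = TRUE),
                         p, sep = "\t", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        path = p, kind = "timeseries", subject = ph$SUB_ID[i], atlas = atlas)
    }
  }
  dplyr::bind_rows(rows)
}
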