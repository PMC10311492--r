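#' Cohort simulation configuration
#'
#' Class-conditional distributions for demographics and fracture morphology.
#' Defaults emulate the cohort shape reported for distal-femur fracture
#' mapping studies: a bimodal age distribution (younger high-energy trauma,
#' older low-energy falls), class-specific sex/side/mechanism frequencies,
#' and fragment-count / comminution distributions whose class means match
#' the reported morphometrics (33A: ~4 fragments, comminution in ~62% of
#' cases with small (~0.2 cm^3) zone fragments on the lateral/anterior/
#' posterior diaphysis; 33C: ~8 fragments, comminution in ~38% of cases
#' with larger (~0.7 cm^3) zone fragments anteromedially).
#'
#' @param ... overrides for individual top-level entries.
#' @return A nested list of class \code{cohort_config}.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    age = list(p_young = 0.3, young_mean = 42, young_sd = 10,
               old_mean = 71, old_sd = 9, min = 18, max = 92),
    height = list(mean = 1.68, sd = 0.08, min = 1.45, max = 1.95),
    bmi = list(mean = 23.9, sd = 3.1, min = 16, max = 35),
    sex_male_prob = list(`33A` = 25 / 53, `33C` = 15 / 21),
    side_left_prob = list(`33A` = 29 / 53, `33C` = 13 / 21),
    mechanism_prob = list(`33A` = c(MVA = 13, slip = 31, fall = 5, crushing = 4) / 53,
                          `33C` = c(MVA = 8, slip = 7, fall = 5, crushing = 1) / 21),
    # main (non-comminuted) fragment count: min + negative binomial
    main_fragments = list(`33A` = list(min = 2, mu = 1.04, size = 1.0, max = 6),
                          `33C` = list(min = 3, mu = 1.91, size = 1.2, max = 7)),
    comminution = list(
      `33A` = list(prob = 33 / 53, n_mu = 0.48, n_size = 1, n_max = 6,
                   vol_meanlog = log(0.18), vol_sdlog = 0.55,
                   sectors = c("lateral", "anterior", "posterior"),
                   z_lo_mean = 45, z_lo_sd = 8, height_mean = 55, height_sd = 10),
      `33C` = list(prob = 8 / 21, n_mu = 7.7, n_size = 2, n_max = 12,
                   vol_meanlog = log(0.62), vol_sdlog = 0.35,
                   sectors = "anteromedial",
                   z_lo_mean = 30, z_lo_sd = 5, height_mean = 40, height_sd = 6)),
    cuts = list(`33A` = list(z_mean = 55, z_sd = 12, z_min = 35, z_max = 110,
                             obliquity_deg_mean = 25, obliquity_deg_sd = 7),
                `33C` = list(z_mean = 60, z_sd = 10, z_min = 40, z_max = 110,
                             obliquity_deg_mean = 15, obliquity_deg_sd = 5,
                             split_x_sd = 2.5, split_z_max_mean = 45, split_z_max_sd = 5)),
    displacement = list(enabled = FALSE, max_rotation_deg = 10, max_translation_mm = 8),
    roughness_amplitude = 1, roughness_wavelength = 25)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(hi, pmax(lo, x))
}

draw_record <- function(ao, cfg) {
  a <- cfg$age
  age <- if (runif(1) < a$p_young)
    rtrunc_norm(1, a$young_mean, a$young_sd, a$min, a$max)
  else rtrunc_norm(1, a$old_mean, a$old_sd, a$min, a$max)
  height <- rtrunc_norm(1, cfg$height$mean, cfg$height$sd, cfg$height$min, cfg$height$max)
  bmi <- rtrunc_norm(1, cfg$bmi$mean, cfg$bmi$sd, cfg$bmi$min, cfg$bmi$max)
  mech <- cfg$mechanism_prob[[ao]]
  list(age = round(age), sex = if (runif(1) < cfg$sex_male_prob[[ao]]) "male" else "female",
       side = if (runif(1) < cfg$side_left_prob[[ao]]) "left" else "right",
       height = round(height, 2), bmi = round(bmi, 1),
       weight = round(round(bmi, 1) * round(height, 2)^2, 1),
       mechanism = sample(names(mech), 1, prob = mech), ao_class = ao)
}

draw_morphology <- function(ao, cfg) {
  mf <- cfg$main_fragments[[ao]]
  n_main <- mf$min + min(rnbinom(1, mu = mf$mu, size = mf$size), mf$max - mf$min)
  cm <- cfg$comminution[[ao]]
  has <- runif(1) < cm$prob
  n_comm <- 0L
  vols <- numeric(0)
  if (has) {
    n_comm <- 1L + min(rnbinom(1, mu = cm$n_mu, size = cm$n_size), cm$n_max - 1L)
    vols <- pmin(0.95, pmax(0.03, exp(rnorm(n_comm, cm$vol_meanlog, cm$vol_sdlog))))
  }
  list(n_main = n_main, has_comminution = has, n_comminuted = n_comm,
       comminuted_volumes = vols)
}

#' Simulate cohort case records (table level)
#'
#' Draws demographics and per-case fracture morphometrics from the
#' class-conditional distributions without building voxel volumes. This is
#' the fast path for statistical work; \code{\link{simulate_cohort}} builds
#' the full voxel cases from the same draws.
#'
#' @param n_33A,n_33C case counts per AO/OTA class.
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer seed; fixes every draw.
#' @return data.frame with one row per case: demographics plus
#'   n_fragments, has_comminution, n_comminuted, mean_comminuted_volume.
#' @export
simulate_cohort_records <- function(n_33A, n_33C, config = cohort_config(), seed = 1L) {
  if (n_33A < 0 || n_33C < 0) stop("case counts must be >= 0")
  withr::with_seed(seed, {
    ao <- rep(c("33A", "33C"), c(n_33A, n_33C))
    rows <- lapply(seq_along(ao), function(i) {
      rec <- draw_record(ao[i], config)
      mor <- draw_morphology(ao[i], config)
      data.frame(case_id = sprintf("case_%03d", i), rec[c("age", "sex", "side",
                 "height", "weight", "bmi", "mechanism", "ao_class")],
                 n_fragments = mor$n_main + mor$n_comminuted,
                 has_comminution = mor$has_comminution,
                 n_comminuted = mor$n_comminuted,
                 mean_comminuted_volume = if (mor$n_comminuted) mean(mor$comminuted_volumes) else 0,
                 stringsAsFactors = FALSE)
    })
    if (!length(rows)) return(data.frame())
    do.call(rbind, rows)
  })
}

sector_box <- function(sector, half_w, z_lo, z_hi) {
  lo <- c(-half_w, -half_w, z_lo); hi <- c(half_w, half_w, z_hi)
  if (grepl("medial", sector)) lo[1] <- -6
  if (grepl("lateral", sector)) hi[1] <- 6
  if (grepl("anterior", sector) || sector == "anteromedial") lo[2] <- -6
  if (grepl("posterior", sector)) hi[2] <- 6
  list(lo = lo, hi = hi)
}

draw_plan <- function(ao, mor, cfg, spec, case_seed) {
  cc <- cfg$cuts[[ao]]
  n_cuts <- mor$n_main - 1L
  cuts <- list()
  n_supra <- if (ao == "33C") n_cuts - 1L else n_cuts
  zc <- sort(rtrunc_norm(n_supra, cc$z_mean, cc$z_sd, cc$z_min, cc$z_max))
  # enforce >= 8 mm between parallel cuts so no planned fragment degenerates
  if (n_supra > 1) zc <- zc[1] + cumsum(c(0, pmax(diff(zc), 8)))
  for (z in zc) {
    theta <- rtrunc_norm(1, cc$obliquity_deg_mean, cc$obliquity_deg_sd, 2, 45) * pi / 180
    tilt <- if (ao == "33A") -tan(theta) else tan(theta)  # descending lateral vs medial
    normal <- c(tilt, rnorm(1, 0, 0.08), 1)
    cuts[[length(cuts) + 1L]] <- cut_surface(
      point = c(0, 0, z), normal = normal,
      roughness_amplitude = cfg$roughness_amplitude,
      roughness_wavelength = cfg$roughness_wavelength)
  }
  if (ao == "33C") {
    xs <- rtrunc_norm(1, 0, cc$split_x_sd, -5, 5)
    zmx <- rtrunc_norm(1, cc$split_z_max_mean, cc$split_z_max_sd, 30, 60)
    cuts[[length(cuts) + 1L]] <- cut_surface(
      point = c(xs, 0, 0), normal = c(1, rnorm(1, 0, 0.08), rnorm(1, 0, 0.08)),
      roughness_amplitude = cfg$roughness_amplitude,
      roughness_wavelength = cfg$roughness_wavelength, z_max = zmx)
  }
  region <- NULL
  if (mor$n_comminuted > 0) {
    cm <- cfg$comminution[[ao]]
    sector <- if (length(cm$sectors) > 1) sample(cm$sectors, 1) else cm$sectors
    z_lo <- rtrunc_norm(1, cm$z_lo_mean, cm$z_lo_sd, 20, 70)
    h <- rtrunc_norm(1, cm$height_mean, cm$height_sd, 25, 80)
    region <- sector_box(sector, spec$condylar_width / 2, z_lo, z_lo + h)
  }
  displacements <- NULL
  if (isTRUE(cfg$displacement$enabled)) {
    displacements <- lapply(seq_len(mor$n_main), function(i) {
      if (i == 1) return(identity_transform())  # largest fragment anchors the frame
      random_rigid_transform(max_angle_deg = cfg$displacement$max_rotation_deg,
                             max_translation = cfg$displacement$max_translation_mm)
    })
  }
  fracture_plan(ao_class = ao, cuts = cuts, comminution_region = region,
                comminuted_volume_targets = mor$comminuted_volumes,
                displacements = displacements, seed = case_seed,
                auto_trim = TRUE)
}

#' Simulate a full voxel-level fracture cohort
#'
#' Deterministic in \code{seed}: demographics, fracture plans and all
#' carving randomness derive from it. Cases are simulated on a shared
#' phantom; each case yields a labeled volume in the template frame, ground
#' truth, and a case record whose morphometrics come from the realized
#' voxel partition.
#'
#' @param n_33A,n_33C case counts per AO/OTA class.
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer seed.
#' @param spec phantom specification shared by all cases.
#' @param case_fn optional function(case) applied to each case as it is
#'   generated; when given, its return value is stored instead of the full
#'   case (volumes can then be discarded to bound memory).
#' @return list with \code{template} (mesh + volume), \code{records}
#'   (data.frame), and \code{cases} (list; each a list with volume,
#'   ground_truth, fragment_surfaces, record — or the value of
#'   \code{case_fn}).
#' @export
simulate_cohort <- function(n_33A, n_33C, config = cohort_config(), seed = 1L,
                            spec = phantom_spec(), case_fn = NULL) {
  if (n_33A < 0 || n_33C < 0) stop("case counts must be >= 0")
  tpl <- make_template(spec)
  n <- n_33A + n_33C
  records <- simulate_cohort_records(n_33A, n_33C, config, seed)
  plans <- withr::with_seed(seed + 1L, {
    case_seeds <- sample.int(2^30, n)
    lapply(seq_len(n), function(i) {
      ao <- if (i <= n_33A) "33A" else "33C"
      mor <- list(n_main = records$n_fragments[i] - records$n_comminuted[i],
                  has_comminution = records$has_comminution[i],
                  n_comminuted = records$n_comminuted[i],
                  comminuted_volumes = numeric(0))
      withr::with_seed(case_seeds[i], {
        if (mor$n_comminuted > 0) {
          cm <- config$comminution[[ao]]
          mor$comminuted_volumes <- pmin(0.95, pmax(0.03,
            exp(rnorm(mor$n_comminuted, cm$vol_meanlog, cm$vol_sdlog))))
        }
        draw_plan(ao, mor, config, spec, case_seeds[i])
      })
    })
  })
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_fracture(tpl$volume, plans[[i]], template = tpl$mesh)
    fs <- label_fragments(sim$volume, relabel = FALSE)
    fs <- classify_comminution(fs)
    met <- case_morphometrics(fs)
    records[i, names(met)] <- met
    sim$record <- records[i, , drop = FALSE]
    sim$plan <- plans[[i]]
    fm_log("case %s (%s): %d fragments, %d comminuted", records$case_id[i],
           records$ao_class[i], met$n_fragments, met$n_comminuted)
    cases[[i]] <- if (is.null(case_fn)) sim else case_fn(sim)
  }
  list(template = tpl, records = records, cases = cases)
}
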