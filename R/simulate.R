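## Family-size counts as printed for the group-1 cohort: 76 families with
## one imaged FDR, 25 with two, ..., one with 11 and one with 14.
GROUP1_FDR_COUNTS <- c(`1` = 76, `2` = 25, `3` = 6, `4` = 4, `5` = 4,
                       `6` = 3, `7` = 2, `11` = 1, `14` = 1)
GROUP2_FDR_COUNTS <- c(`1` = 87, `2` = 20, `3` = 4, `4` = 7, `5` = 3,
                       `6` = 1)

#' Parameters of the synthetic family-cohort generator
#'
#' The generator emulates the structure the concordance analysis relies
#' on: the family-size distribution (defaulting to the printed group-1
#' counts), per-variant prevalences (defaulting to Table-2-like values),
#' free co-occurrence of the three non-classical variants within an
#' individual, and a per-variant familial aggregation strength. Aggregation
#' is a family-level normal random intercept on the logit scale: members of
#' family *f* carry variant *v* independently with probability
#' `plogis(qlogis(p_v) + b_fv)`, `b_fv ~ N(0, sigma_v^2)`. A classical
#' circle is derived, not drawn: a member with no variant is classical with
#' probability `p_classical / q0`, where `q0` is the baseline no-variant
#' mass `prod(1 - p_v)`, so mutual exclusion holds by construction and the
#' marginal classical prevalence matches `p_classical` (exactly at
#' `sigma = 0`, approximately for `sigma > 0`). Members carrying nothing
#' and not assigned classical have an empty profile, mirroring real
#' configurations that fit none of the four categories.
#'
#' @param n_families Number of families.
#' @param fdr_count_distribution Named numeric vector: names are FDR
#'   counts per family, values are probabilities (normalised internally).
#' @param variant_prevalence Named probabilities for `classical`,
#'   `a1_asymmetry`, `incomplete_pcom`, `fetal_pc`.
#' @param familial_sd Named non-negative sds (logit scale) for the three
#'   non-classical variants; 0 (the default) means no familial
#'   aggregation.
#' @param emit_diameters Also generate six vessel diameters per member
#'   consistent with the profile (see [profiles_to_diameters()]).
#' @param seed Integer seed used by [generate_cohort()].
#' @return Object of class `cow_sim_params`.
#' @export
sim_params <- function(n_families = 122L,
                       fdr_count_distribution = GROUP1_FDR_COUNTS,
                       variant_prevalence = c(classical = 0.18,
                                              a1_asymmetry = 0.22,
                                              incomplete_pcom = 0.62,
                                              fetal_pc = 0.26),
                       familial_sd = c(a1_asymmetry = 0,
                                       incomplete_pcom = 0, fetal_pc = 0),
                       emit_diameters = FALSE, seed = 1L) {
  stopifnot(n_families >= 1, all(fdr_count_distribution >= 0),
            sum(fdr_count_distribution) > 0)
  sizes <- as.integer(names(fdr_count_distribution))
  if (anyNA(sizes) || any(sizes < 1))
    stop("fdr_count_distribution names must be positive integer sizes",
         call. = FALSE)
  pv <- variant_prevalence[names(COW_VARIANTS)]
  if (anyNA(pv) || any(pv <= 0) || any(pv >= 1))
    stop("variant_prevalence must name all four variants with values in ",
         "(0,1)", call. = FALSE)
  nc <- setdiff(names(COW_VARIANTS), "classical")
  sd_v <- rep(0, 3); names(sd_v) <- nc
  sd_v[names(familial_sd)] <- familial_sd
  if (any(sd_v < 0)) stop("familial_sd must be >= 0", call. = FALSE)
  q0 <- prod(1 - pv[nc])
  if (pv[["classical"]] > q0)
    stop(sprintf(paste0("infeasible prevalences: classical target %.3f ",
                        "exceeds the no-variant mass %.3f"),
                 pv[["classical"]], q0), call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 sizes = sizes,
                 size_prob = as.numeric(fdr_count_distribution) /
                   sum(fdr_count_distribution),
                 variant_prevalence = pv, familial_sd = sd_v,
                 p_classical_given_none = pv[["classical"]] / q0,
                 emit_diameters = isTRUE(emit_diameters),
                 seed = as.integer(seed)),
            class = "cow_sim_params")
}

#' Sample variant profiles for a synthetic cohort
#'
#' Draws family sizes, family-level aggregation intercepts and member
#' profiles under the model described in [sim_params()]. Uses R's current
#' RNG state; [generate_cohort()] is the seeded entry point. The first
#' member of each family is the proband.
#'
#' @param params A [sim_params()] object.
#' @param group_label Cohort label.
#' @return A `cow_cohort` whose members carry profiles but no diameters.
#' @export
sample_profiles <- function(params, group_label = "synthetic") {
  stopifnot(inherits(params, "cow_sim_params"))
  nc <- names(params$familial_sd)
  logit_p <- stats::qlogis(params$variant_prevalence[nc])
  n_fdr <- sample(params$sizes, params$n_families, replace = TRUE,
                  prob = params$size_prob)
  fam_ids <- sprintf("F%04d", seq_len(params$n_families))
  families <- vector("list", params$n_families)
  for (f in seq_len(params$n_families)) {
    b <- stats::rnorm(length(nc), 0, params$familial_sd)
    p_mem <- stats::plogis(logit_p + b)
    n_mem <- n_fdr[f] + 1L
    carry <- matrix(stats::runif(n_mem * length(nc)) < rep(p_mem,
                                                           each = n_mem),
                    nrow = n_mem)
    none <- rowSums(carry) == 0L
    classical <- none & stats::runif(n_mem) < params$p_classical_given_none
    profiles <- lapply(seq_len(n_mem), function(i)
      if (classical[i]) "classical" else nc[carry[i, ]])
    members <- lapply(seq_len(n_mem), function(i)
      list(member_id = if (i == 1L) "P" else paste0("R", i - 1L),
           role = if (i == 1L) "proband" else "fdr",
           diameters = NULL, profile = profiles[[i]],
           sex = NA, modality = "MRA", slice_thickness_mm = NA_real_,
           quality_ok = TRUE))
    families[[f]] <- structure(list(family_id = fam_ids[f],
                                    proband = members[[1L]],
                                    fdrs = members[-1L]),
                               class = "cow_family")
  }
  names(families) <- fam_ids
  structure(list(group_label = group_label, families = families),
            class = "cow_cohort")
}

#' Generate six vessel diameters consistent with a variant profile
#'
#' Draws plausible diameters (normal arteries 1.5-3.0 mm) and adjusts them
#' so that [classify_cow()] applied to the result reproduces the profile
#' exactly; the construction is verified and re-sampled on failure (at
#' most `max_attempts` times). An empty profile is realised as bilateral
#' symmetric A1 hypoplasia, which fits none of the four categories. Uses
#' the current RNG state.
#'
#' @param profile Character vector of variant labels (possibly empty).
#' @param rules [cow_rules()] to round-trip against.
#' @param max_attempts Rejection-sampling cap.
#' @return Named numeric vector of the six diameters (mm).
#' @export
profiles_to_diameters <- function(profile, rules = cow_rules(),
                                  max_attempts = 100L) {
  profile_to_mask(profile)  # validate
  thr <- rules$hypoplasia_threshold_mm
  fet <- 1 + rules$fetal_excess_fraction
  for (attempt in seq_len(max_attempts)) {
    p1 <- stats::runif(2, 1.5, 3.0)
    if (length(profile) == 0L) {
      ## sub-threshold but symmetric A1s: breaks classical, fires nothing
      a1l <- stats::runif(1, 0.45 * thr, 0.98 * thr)
      a1 <- c(a1l, a1l * stats::runif(1, 0.8, 1.0))
      pcom <- pmin(stats::runif(2, 1.1 * thr, 1.02 * fet * p1),
                   0.98 * fet * p1)
    } else {
      a1 <- if ("a1_asymmetry" %in% profile) {
        l <- stats::runif(1, 1.5, 3.0)
        c(l, l * stats::runif(1, 0.05, 0.6))
      } else {
        l <- stats::runif(1, 1.5, 2.5)
        c(l, l * stats::runif(1, 0.75, 1.3))
      }
      has_inc <- "incomplete_pcom" %in% profile
      has_fet <- "fetal_pc" %in% profile
      pcom <- numeric(2)
      pcom[1] <- if (has_inc) stats::runif(1, 0.2, 0.9 * thr)
      else stats::runif(1, 1.1 * thr, 0.95 * fet * p1[1])
      pcom[2] <- if (has_fet) p1[2] * stats::runif(1, 1.05 * fet, 1.6)
      else stats::runif(1, 1.1 * thr, 0.95 * fet * p1[2])
    }
    d <- c(a1_left = a1[1], a1_right = a1[2], p1_left = p1[1],
           p1_right = p1[2], pcom_left = pcom[1], pcom_right = pcom[2])
    if (setequal(classify_cow(d, rules), profile)) return(d)
  }
  stop("could not realise diameters for profile {",
       paste(profile, collapse = ","), "} in ", max_attempts, " attempts",
       call. = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Seeded composition of [sample_profiles()] and, when
#' `params$emit_diameters` is set, [profiles_to_diameters()] for every
#' member. Deterministic given `params$seed`; the output passes
#' [read_cohort()] round-trip validation.
#'
#' @param params A [sim_params()] object.
#' @param group_label Cohort label.
#' @return A `cow_cohort`; the generating parameters are attached as the
#'   `"sim_params"` attribute.
#' @export
#' @examples
#' coh <- generate_cohort(sim_params(n_families = 20, seed = 7))
#' coh
generate_cohort <- function(params, group_label = "synthetic") {
  stopifnot(inherits(params, "cow_sim_params"))
  set.seed(params$seed)
  cohort <- sample_profiles(params, group_label)
  if (params$emit_diameters) {
    cohort$families <- lapply(cohort$families, function(fam) {
      fam$proband$diameters <- profiles_to_diameters(fam$proband$profile)
      fam$fdrs <- lapply(fam$fdrs, function(m) {
        m$diameters <- profiles_to_diameters(m$profile)
        m
      })
      fam
    })
  }
  attr(cohort, "sim_params") <- params
  cohort
}

#' Simulate matched events/trials strata with a known common odds ratio
#'
#' Directly generates strata for checking estimator consistency: each
#' stratum draws a comparison-arm probability `p2 ~ U(0.2, 0.6)`, sets the
#' index-arm probability so that the odds ratio is exactly `psi`, draws
#' arm sizes from the family-size distribution and binomial event counts.
#' Uses the current RNG state.
#'
#' @param n_strata Number of strata.
#' @param psi True common odds ratio (> 0).
#' @param size_distribution Named probability vector of arm sizes (default
#'   the group-1 family-size distribution).
#' @return Data frame of strata suitable for [fit_clogit_et()].
#' @export
simulate_strata <- function(n_strata, psi,
                            size_distribution = GROUP1_FDR_COUNTS) {
  stopifnot(n_strata >= 1, psi > 0)
  sizes <- as.integer(names(size_distribution))
  pr <- size_distribution / sum(size_distribution)
  n1 <- sample(sizes, n_strata, TRUE, pr)
  n2 <- sample(sizes, n_strata, TRUE, pr)
  p2 <- stats::runif(n_strata, 0.2, 0.6)
  odds1 <- psi * p2 / (1 - p2)
  p1 <- odds1 / (1 + odds1)
  data.frame(index_events = stats::rbinom(n_strata, n1, p1),
             index_trials = n1,
             comparison_events = stats::rbinom(n_strata, n2, p2),
             comparison_trials = n2)
}
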