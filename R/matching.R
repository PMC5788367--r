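## Compact representation of a cohort for the resampling loop: proband
## profile bitmasks and per-family FDR mask vectors. Families whose proband
## has an empty profile cannot anchor a concordance column and are excluded
## from all analyses (with a warning).
.compile_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cow_cohort"))
  fams <- cohort$families
  ord <- order(vapply(fams, `[[`, "", "family_id"))
  fams <- fams[ord]
  pm <- vapply(fams, function(f) profile_to_mask(f$proband$profile), 1L)
  empty <- pm == 0L
  if (any(empty)) {
    warning(sum(empty), " famil", if (sum(empty) == 1) "y" else "ies",
            " excluded: proband carries no named variant (",
            paste(vapply(fams[empty], `[[`, "", "family_id"),
                  collapse = ", "), ")", call. = FALSE)
    fams <- fams[!empty]
    pm <- pm[!empty]
  }
  if (length(fams) < 2L)
    stop("need at least two analysable families", call. = FALSE)
  list(family_id = vapply(fams, `[[`, "", "family_id"),
       proband_mask = pm,
       fdr_masks = lapply(fams, function(f)
         vapply(f$fdrs, function(m) profile_to_mask(m$profile), 1L)),
       n_fdr = vapply(fams, function(f) length(f$fdrs), 1L),
       families = fams)
}

.pool_indices <- function(pm, pool_rule) {
  lapply(seq_along(pm), function(i) {
    ok <- if (pool_rule == "disjoint") bitwAnd(pm, pm[i]) == 0L
          else pm != pm[i]
    ok[i] <- FALSE
    which(ok)
  })
}

#' Candidate comparison families for one index family
#'
#' The comparison family is drawn from families whose proband's circle of
#' Willis configuration is different from the index proband's. Under the
#' default `"disjoint"` rule the two probands share no variant, so the
#' comparison proband is discordant with the index proband by construction;
#' `"not_identical"` only requires the variant sets to differ.
#'
#' @param cohort A `cow_cohort`.
#' @param family_id Id of the index family.
#' @param pool_rule `"disjoint"` (default) or `"not_identical"`.
#' @return Named list of eligible families (in `family_id` order).
#' @export
comparison_pool <- function(cohort, family_id,
                            pool_rule = c("disjoint", "not_identical")) {
  pool_rule <- match.arg(pool_rule)
  cc <- .compile_cohort(cohort)
  i <- match(as.character(family_id), cc$family_id)
  if (is.na(i)) stop("unknown (or excluded) family: ", family_id,
                     call. = FALSE)
  idx <- .pool_indices(cc$proband_mask, pool_rule)[[i]]
  if (!length(idx))
    stop("empty comparison pool for family ", family_id,
         ": no proband with a ", pool_rule, " configuration", call. = FALSE)
  stats::setNames(cc$families[idx], cc$family_id[idx])
}

#' Draw one random index-to-comparison matching
#'
#' Each index family is independently matched, uniformly and with
#' replacement, to a family from its comparison pool; the same family may
#' serve several index families. One matching is shared by all outcomes
#' within a resampling iteration. Uses R's current RNG state; seed with
#' `set.seed()` for reproducibility.
#'
#' @inheritParams comparison_pool
#' @return Named character vector: index `family_id` -> comparison
#'   `family_id`.
#' @export
draw_matching <- function(cohort, pool_rule = c("disjoint", "not_identical")) {
  pool_rule <- match.arg(pool_rule)
  cc <- .compile_cohort(cohort)
  pools <- .pool_indices(cc$proband_mask, pool_rule)
  empty <- !vapply(pools, length, 1L)
  if (any(empty))
    stop("empty comparison pool for family ",
         paste(cc$family_id[empty], collapse = ", "), call. = FALSE)
  pick <- vapply(pools, function(p) p[sample.int(length(p), 1L)], 1L)
  stats::setNames(cc$family_id[pick], cc$family_id)
}

## Per-outcome index-arm strata. The index arm never changes across
## iterations; only the comparison arm is resampled.
.index_arms <- function(cc, outcome) {
  if (outcome == "any") {
    sel <- seq_along(cc$proband_mask)
    ref <- cc$proband_mask
  } else {
    bit <- COW_VARIANTS[[outcome]]
    sel <- which(bitwAnd(cc$proband_mask, bit) > 0L)
    ref <- rep.int(bit, length(sel))
  }
  ev <- vapply(seq_along(sel), function(k)
    sum(bitwAnd(cc$fdr_masks[[sel[k]]], ref[k]) > 0L), 1L)
  list(sel = sel, ref = ref, events = ev, trials = cc$n_fdr[sel])
}

.comparison_arms <- function(cc, arms, pick) {
  m <- pick[arms$sel]
  ev <- vapply(seq_along(m), function(k)
    sum(bitwAnd(cc$fdr_masks[[m[k]]], arms$ref[k]) > 0L), 1L)
  list(events = ev, trials = cc$n_fdr[m])
}

#' Run one matching-and-fitting iteration
#'
#' Draws (or takes) one index-to-comparison matching, computes per-outcome
#' events/trials strata — the index arm is the family's own FDR concordance
#' with its proband, the comparison arm is the matched family's FDR
#' concordance with the *index* proband, never counting the comparison
#' proband — and fits the conditional logistic model per outcome.
#'
#' @inheritParams comparison_pool
#' @param outcomes Character vector of outcomes to evaluate.
#' @param matching Optional fixed matching (as from [draw_matching()]);
#'   drawn at random when `NULL`.
#' @return List of class `cow_iteration`, one element per outcome with
#'   `strata`, `fit`, `index_concordance`, `comparison_concordance`,
#'   `converged`; outcomes no index proband carries get `NULL` strata.
#' @export
iterate_once <- function(cohort, outcomes = OUTCOMES, matching = NULL,
                         pool_rule = c("disjoint", "not_identical")) {
  pool_rule <- match.arg(pool_rule)
  vapply(outcomes, .check_outcome, "")
  cc <- .compile_cohort(cohort)
  if (is.null(matching)) {
    matching <- draw_matching(cohort, pool_rule)
  }
  pick <- match(matching[cc$family_id], cc$family_id)
  if (anyNA(pick))
    stop("matching must assign a comparison family to every index family",
         call. = FALSE)
  out <- lapply(outcomes, function(o) {
    arms <- .index_arms(cc, o)
    if (!length(arms$sel))
      return(list(outcome = o, strata = NULL, fit = NULL,
                  index_concordance = NA_real_,
                  comparison_concordance = NA_real_, converged = NA))
    comp <- .comparison_arms(cc, arms, pick)
    strata <- data.frame(family_id = cc$family_id[arms$sel],
                         index_events = arms$events,
                         index_trials = arms$trials,
                         comparison_events = comp$events,
                         comparison_trials = comp$trials)
    fit <- fit_clogit_et(strata[-1])
    list(outcome = o, strata = strata, fit = fit,
         index_concordance = sum(arms$events) / sum(arms$trials),
         comparison_concordance = sum(comp$events) / sum(comp$trials),
         converged = fit$converged)
  })
  structure(stats::setNames(out, outcomes), class = "cow_iteration")
}

#' Resample random matchings and aggregate by medians
#'
#' The full resampling design: in each iteration every index family is
#' matched at random (with replacement) to a comparison family whose
#' proband has a different circle of Willis configuration, per-outcome
#' events/trials strata are formed, and the conditional logistic model is
#' fitted. Medians over the iterations of the odds ratio, of each CI bound
#' (componentwise), and of the pooled index and comparison concordance
#' proportions are reported. Iterations whose fit fails to converge (e.g.
#' separation) are excluded from the medians; an outcome with more than
#' half its iterations non-converged is an error.
#'
#' @inheritParams iterate_once
#' @param n_iterations Number of matching iterations; the default 1001 is
#'   odd so every median is a middle order statistic.
#' @param seed Integer seed; per-iteration sub-seeds are pre-drawn from it
#'   so results do not depend on execution order.
#' @return A `cow_aggregate` data frame, one row per outcome: `outcome`,
#'   `n_index_families`, `median_index_concordance`,
#'   `median_comparison_concordance`, `median_or`, `median_ci_low`,
#'   `median_ci_high`, `n_iterations_used`. Attributes record
#'   `n_iterations`, `seed`, `pool_rule` and the cohort's `group_label`.
#' @export
run_resampling <- function(cohort, outcomes = OUTCOMES,
                           n_iterations = 1001L, seed = 1L,
                           pool_rule = c("disjoint", "not_identical")) {
  pool_rule <- match.arg(pool_rule)
  stopifnot(n_iterations >= 1)
  vapply(outcomes, .check_outcome, "")
  cc <- .compile_cohort(cohort)
  pools <- .pool_indices(cc$proband_mask, pool_rule)
  empty <- !vapply(pools, length, 1L)
  if (any(empty))
    stop("empty comparison pool for family ",
         paste(cc$family_id[empty], collapse = ", "), call. = FALSE)
  arms <- lapply(outcomes, function(o) .index_arms(cc, o))
  names(arms) <- outcomes

  set.seed(seed)
  iter_seeds <- sample.int(2147483646L, n_iterations)
  res <- lapply(outcomes, function(o)
    list(or = rep(NA_real_, n_iterations), lo = rep(NA_real_, n_iterations),
         hi = rep(NA_real_, n_iterations),
         comp = rep(NA_real_, n_iterations)))
  names(res) <- outcomes

  for (it in seq_len(n_iterations)) {
    set.seed(iter_seeds[it])
    pick <- vapply(pools, function(p) p[sample.int(length(p), 1L)], 1L)
    for (o in outcomes) {
      ao <- arms[[o]]
      if (!length(ao$sel)) next
      comp <- .comparison_arms(cc, ao, pick)
      fit <- fit_clogit_et(data.frame(index_events = ao$events,
                                      index_trials = ao$trials,
                                      comparison_events = comp$events,
                                      comparison_trials = comp$trials))
      res[[o]]$comp[it] <- sum(comp$events) / sum(comp$trials)
      if (fit$converged) {
        res[[o]]$or[it] <- fit$or_hat
        res[[o]]$lo[it] <- fit$ci_low
        res[[o]]$hi[it] <- fit$ci_high
      }
    }
  }

  rows <- lapply(outcomes, function(o) {
    ao <- arms[[o]]
    if (!length(ao$sel))
      return(data.frame(outcome = o, n_index_families = 0L,
                        median_index_concordance = NA_real_,
                        median_comparison_concordance = NA_real_,
                        median_or = NA_real_, median_ci_low = NA_real_,
                        median_ci_high = NA_real_, n_iterations_used = 0L))
    ok <- !is.na(res[[o]]$or)
    if (sum(ok) < n_iterations / 2)
      stop("outcome '", o, "': ", n_iterations - sum(ok), " of ",
           n_iterations, " iterations failed to converge", call. = FALSE)
    data.frame(outcome = o, n_index_families = length(ao$sel),
               median_index_concordance = sum(ao$events) / sum(ao$trials),
               median_comparison_concordance =
                 stats::median(res[[o]]$comp, na.rm = TRUE),
               median_or = stats::median(res[[o]]$or[ok]),
               median_ci_low = stats::median(res[[o]]$lo[ok]),
               median_ci_high = stats::median(res[[o]]$hi[ok]),
               n_iterations_used = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cow_aggregate", "data.frame"),
            n_iterations = n_iterations, seed = seed, pool_rule = pool_rule,
            group_label = cohort$group_label)
}

#' @export
print.cow_aggregate <- function(x, digits = 3, ...) {
  cat("Resampled familial concordance ('",
      attr(x, "group_label"), "', ", attr(x, "n_iterations"),
      " iterations, seed ", attr(x, "seed"), ", pool rule ",
      attr(x, "pool_rule"), ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
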